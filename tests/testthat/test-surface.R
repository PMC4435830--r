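two_peak_data <- function(tree, seed,
                          theta = c(1.126, -11.027),
                          alpha = 0.974, sigma2 = 7.42) {
  pa <- regime_painting(tree, stats::setNames(
    2L, as.character(attr(tree, "shift_edge"))))
  list(x = simulate_traits(tree, "HANSEN",
                           params = list(alpha = alpha, sigma2 = sigma2,
                                         theta = theta),
                           painting = pa, n_replicates = 1, seed = seed)[1, ],
       painting = pa)
}

test_that("regime paintings propagate shifts to whole subtrees", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  # find the edge leading to the MRCA of C and D
  mrca_cd <- ape::getMRCA(tr, c("C", "D"))
  e <- which(tr$edge[, 2] == mrca_cd)
  p <- regime_painting(tr, stats::setNames(2L, as.character(e)))
  cache <- peakscape:::.tree_cache(tr)
  tip_edge <- sapply(seq_len(4), function(i) {
    which(tr$edge[, 2] == i)
  })
  regimes <- p$edge_regime[tip_edge]
  names(regimes) <- tr$tip.label
  expect_equal(unname(regimes[c("A", "B")]), c(1L, 1L))
  expect_equal(unname(regimes[c("C", "D")]), c(2L, 2L))
  expect_equal(p$root_regime, 1L)
})

test_that("forward search keeps one regime on single-peak data", {
  tr <- gen_tree(32, seed = 3)
  ones <- 0L
  for (s in 1:10) {
    x <- simulate_traits(tr, "OU1",
                         params = list(alpha = 6.77, sigma2 = 15.84,
                                       theta = 0),
                         n_replicates = 1, seed = 100 + s)[1, ]
    fwd <- surface_forward(x, tr)
    if (fwd$stats$k == 1L) {
      ones <- ones + 1L
      # with no accepted shift the incumbent single-peak fit is returned
      expect_equal(fwd$fit$kind, "OU1")
      expect_length(fwd$painting$shifts, 0)
    }
  }
  expect_gte(ones, 7L)
})

test_that("backward phase leaves a one-regime model unchanged", {
  tr <- gen_tree(16, seed = 4)
  x <- simulate_traits(tr, "OU1",
                       params = list(alpha = 5, sigma2 = 8, theta = 0),
                       n_replicates = 1, seed = 9)[1, ]
  fwd <- surface_forward(x, tr)
  bwd <- surface_backward(fwd, x, tr)
  if (fwd$stats$k == 1) {
    expect_equal(bwd$stats$k_prime, 1L)
    expect_equal(bwd$stats$delta_k, 0L)
    expect_equal(bwd$stats$c, 0L)
  }
  expect_equal(bwd$stats$k, fwd$stats$k)
})

test_that("the criterion is non-increasing along the accepted history", {
  tr <- gen_tree(32, seed = 3)
  d <- two_peak_data(tr, seed = 1)
  sm <- run_surface(d$x, tr)
  expect_true(all(diff(sm$history$AICc) <= 1e-9))
  # a model with at least one accepted shift beats the starting OU1
  if (sm$stats$k > 1) {
    expect_lt(utils::tail(sm$history$AICc, 1), sm$history$AICc[1])
  }
})

test_that("search recovers a strong two-peak landscape and is deterministic", {
  tr <- gen_tree(32, seed = 3)
  d <- two_peak_data(tr, seed = 1)
  sm1 <- run_surface(d$x, tr)
  sm2 <- run_surface(d$x, tr)
  expect_identical(sm1$painting$shifts, sm2$painting$shifts)
  expect_identical(sm1$history, sm2$history)
  expect_true(attr(tr, "shift_edge") %in%
                as.integer(names(sm1$painting$shifts)))
  expect_gte(sm1$stats$k_prime, 2)
  # theta estimates separate in the generating direction
  th <- sm1$fit$params$theta
  expect_lt(min(th), max(th) - 3)
  expect_gt(max(th), -2)
})

test_that("convergent regimes with identical optima are collapsed", {
  tr <- gen_tree(32, seed = 8, shift_clade_size = 8)
  cache <- peakscape:::.tree_cache(tr)
  n <- ape::Ntip(tr)
  # two sizeable, disjoint clades share one shifted optimum
  sizes <- sapply(seq_len(nrow(tr$edge)), function(e) {
    nd <- tr$edge[e, 2]
    if (nd <= n) 1L else ape::Ntip(ape::extract.clade(tr, nd))
  })
  cand <- which(sizes >= 5 & sizes <= 10)
  pick <- c()
  for (e in cand) {
    tips_e <- ape::extract.clade(tr, tr$edge[e, 2])$tip.label
    overlap <- any(sapply(pick, function(o) {
      length(intersect(tips_e,
                       ape::extract.clade(tr, tr$edge[o, 2])$tip.label)) > 0
    }))
    if (!overlap) pick <- c(pick, e)
    if (length(pick) == 2) break
  }
  expect_length(pick, 2)   # this tree has two disjoint mid-sized clades
  pa <- regime_painting(tr, stats::setNames(c(2L, 3L), as.character(pick)))
  hits <- 0
  for (s in 1:5) {
    x <- simulate_traits(tr, "HANSEN",
                         params = list(alpha = 4, sigma2 = 6,
                                       theta = c(0, -9, -9)),
                         painting = pa, n_replicates = 1, seed = 40 + s)[1, ]
    sm <- run_surface(x, tr)
    if (sm$stats$k >= 3 && sm$stats$k_prime_conv >= 1) hits <- hits + 1
  }
  expect_gte(hits, 3)
})

test_that("peak statistics follow their definitions on a known painting", {
  tr <- gen_tree(16, seed = 9, shift_clade_size = 5)
  # fabricate a backward result: 3 forward regimes, two shifts merged
  p <- regime_painting(tr, stats::setNames(c(2L, 2L), c("3", "8")))
  st <- peakscape:::.surface_stats(3L, p)
  expect_equal(st$k, 3L)
  expect_equal(st$k_prime, 2L)       # regimes 1 and 2
  expect_equal(st$c, 2L)             # both shifts point at a shared regime
  expect_equal(st$k_prime_conv, 1L)
  expect_equal(st$delta_k, 1L)
  expect_equal(st$c_over_k, 2 / 3)
})

test_that("BM null reports extreme P for an unreachable observed statistic", {
  tr <- gen_tree(16, seed = 10)
  d <- two_peak_data(tr, seed = 2, theta = c(3, -9), alpha = 2, sigma2 = 4)
  obs <- run_surface(d$x, tr)
  null <- bm_null_peaks(d$x, tr, n_sim = 12, seed = 5, observed = obs)
  expect_true(all(null$P >= 0 & null$P <= 1))
  expect_equal(null$n_sim, 12)
  expect_lte(null$n_failed, 1)
  if (obs$stats$k_prime > max(null$sims[, "k_prime"], na.rm = TRUE)) {
    expect_equal(unname(null$P["k_prime"]), 0)
  }
  # P for a statistic observed at its minimum possible value is 1
  expect_equal(unname(null$P["c"]),
               mean(null$sims[, "c"] >= obs$stats$c, na.rm = TRUE))
})

test_that("reduced null simulation counts agree within Monte-Carlo error", {
  tr <- gen_tree(16, seed = 10)
  d <- two_peak_data(tr, seed = 2, theta = c(3, -9), alpha = 2, sigma2 = 4)
  obs <- run_surface(d$x, tr)
  n_a <- 24; n_b <- 12
  null_a <- bm_null_peaks(d$x, tr, n_sim = n_a, seed = 5, observed = obs)
  null_b <- bm_null_peaks(d$x, tr, n_sim = n_b, seed = 11, observed = obs)
  p_a <- null_a$P["k"]; p_b <- null_b$P["k"]
  mc <- 3 * sqrt(0.25 / n_b + 0.25 / n_a)
  expect_lt(abs(p_a - p_b), mc + 1e-9)
})
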