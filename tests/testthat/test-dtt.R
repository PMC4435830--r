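test_that("disparity is the mean squared pairwise distance", {
  expect_equal(disparity(c(2, 2, 2)), 0)
  expect_equal(disparity(c(0, 2)), 4)
  expect_equal(disparity(c(0, 1, 3)), 14 / 3)   # pairs 1, 9, 4
  expect_equal(disparity(5), 0)                 # single tip
  expect_error(disparity(numeric(0)), "empty")
  # multivariate rows
  expect_equal(disparity(rbind(c(0, 0), c(3, 4))), 25)
})

test_that("two-taxon DTT curve is flat at one", {
  tr <- read_newick("(A:1,B:1);")
  cv <- dtt_curve(c(A = 0, B = 2), tr)
  expect_equal(cv$times, 0)
  expect_equal(cv$disparity, 1)
})

test_that("4-taxon DTT curve matches brute-force enumeration", {
  tr <- read_newick("((A:0.6,B:0.6):0.4,(C:0.3,D:0.3):0.7);")
  x <- c(A = 0, B = 2, C = 1, D = 3)
  cv <- dtt_curve(x, tr)
  # hand enumeration: total disparity = 10/3; at t = 0.4 the lineages are
  # {A}, {B}, {C,D} with disparities 0, 0, 4 -> mean rel = (4 / (10/3)) / 3
  expect_equal(cv$times, c(0, 0.4, 0.7))
  expect_equal(cv$disparity, c(1, (4 / (10 / 3)) / 3, 0))
  or <- dtt_oracle(x, tr)
  expect_equal(cv$times, or$times)
  expect_equal(cv$disparity, or$disparity)
})

test_that("DTT curve equals the enumeration oracle on random trees", {
  set.seed(1)
  for (i in 1:8) {
    tr <- rand_unit_tree(sample(5:10, 1))
    x <- stats::setNames(rnorm(ape::Ntip(tr)), tr$tip.label)
    cv <- dtt_curve(x, tr)
    or <- dtt_oracle(x, tr)
    expect_equal(cv$times, or$times)
    expect_equal(cv$disparity, or$disparity, tolerance = 1e-12)
    expect_equal(cv$disparity[1], 1)
    expect_true(all(cv$disparity >= 0))
  }
})

test_that("degenerate disparity inputs are rejected", {
  tr <- rand_unit_tree(4)
  x <- stats::setNames(rep(1, 4), tr$tip.label)
  expect_error(dtt_curve(x, tr), "zero")
})

test_that("MDI integrates the observed-minus-expected difference", {
  grid <- list(times = c(0, 1 / 3, 2 / 3, 1), disparity = c(0, 0, 0, 0))
  expected <- rep(1, 4)
  expect_equal(mdi(grid, expected, truncation = 2 / 3), -2 / 3)
  # observed identical to expectation
  same <- list(times = grid$times, disparity = expected)
  expect_equal(mdi(same, expected), 0)
  # interpolation at a truncation point off the grid
  expect_equal(mdi(grid, expected, truncation = 0.5), -0.5)
  # antisymmetry under swapping observed and expected
  set.seed(2)
  obs <- list(times = c(0, 0.2, 0.5, 0.9), disparity = runif(4))
  exp2 <- runif(4)
  a <- mdi(obs, exp2)
  b <- mdi(list(times = obs$times, disparity = exp2), obs$disparity)
  expect_equal(a, -b, tolerance = 1e-12)
  expect_error(mdi(obs, rep(1, 3)), "time grid")
})

test_that("truncation monotonicity holds for a one-signed integrand", {
  obs <- list(times = c(0, 0.25, 0.5, 0.75, 1),
              disparity = c(1, 0.2, 0.1, 0.05, 0))
  expected <- rep(1, 5)    # difference always <= 0
  m_small <- mdi(obs, expected, truncation = 1 / 3)
  m_big <- mdi(obs, expected, truncation = 2 / 3)
  expect_lte(abs(m_small), abs(m_big))
})

test_that("posterior-predictive p follows the one-sided sign rule", {
  expect_equal(suppressWarnings(posterior_predictive_p(-5, c(-1, -2, 0, 1))), 0)
  expect_equal(suppressWarnings(posterior_predictive_p(-1, c(-1, -2, 0, 1))),
               0.5)
  expect_equal(suppressWarnings(posterior_predictive_p(0.5, c(-1, 0.4, 0.6, 1))),
               0.5)
  expect_error(posterior_predictive_p(0, numeric(0)), "no simulated")
  expect_warning(posterior_predictive_p(0, rnorm(10)), "fewer than 100")
})

test_that("DTT pipeline is deterministic with identical trees and seed", {
  tr <- gen_tree(12, seed = 6)
  x <- simulate_traits(tr, "BM", params = list(sigma2 = 1, z0 = 0),
                       seed = 7)[1, ]
  cs <- chronogram_set(list(tr, tr), mcc = tr)
  d1 <- dtt_pipeline(x, cs, model = "BM", n_sim = 120, seed = 3)
  d2 <- dtt_pipeline(x, cs, model = "BM", n_sim = 120, seed = 3)
  expect_identical(d1$mdi_mean, d2$mdi_mean)
  expect_identical(d1$p_mean, d2$p_mean)
  # identical trees + same per-tree seed stream: per-tree results need not
  # be equal across trees (independent simulation streams), but the result
  # must carry one entry per tree
  expect_length(d1$per_tree, 2)
  expect_equal(d1$per_tree[[1]]$times[1], 0)
})
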