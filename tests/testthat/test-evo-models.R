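test_that("single-tip BM density is the standard normal at the mean", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  # 1-tip likelihood is not representable as a phylo; use a 2-tip star and
  # check the exact closed form instead
  x <- c(A = 0, B = 0)
  ll <- bm_loglik(x, tr, sigma2 = 1, z0 = 0)
  expect_equal(ll, mvn_logdens(c(0, 0), c(0, 0), diag(2)), tolerance = 1e-12)
  expect_equal(ll, 2 * (-0.5 * log(2 * pi)), tolerance = 1e-12)
})

test_that("all four likelihoods match the dense MVN oracle on random trees", {
  set.seed(10)
  for (i in 1:25) {
    n <- sample(3:5, 1)
    tr <- rand_unit_tree(n)
    x <- stats::setNames(rnorm(n, 0, 2), tr$tip.label)
    sigma2 <- runif(1, 0.3, 3)
    alpha <- runif(1, 0.2, 4)
    z0 <- rnorm(1)
    C <- ape::vcv.phylo(tr)[tr$tip.label, tr$tip.label]

    expect_equal(bm_loglik(x, tr, sigma2, z0),
                 mvn_logdens(x, rep(z0, n), sigma2 * C), tolerance = 1e-8)

    V <- ou_cov_oracle(tr, alpha, sigma2)[tr$tip.label, tr$tip.label]
    expect_equal(ou1_loglik(x, tr, alpha, sigma2, theta = z0),
                 mvn_logdens(x, rep(z0, n), V), tolerance = 1e-8)

    r <- runif(1, -2, 0)
    Ceb <- (exp(r * C) - 1) / r
    expect_equal(eb_loglik(x, tr, sigma2, r, z0),
                 mvn_logdens(x, rep(z0, n), sigma2 * Ceb), tolerance = 1e-8)

    e <- sample(nrow(tr$edge), 1)
    p <- regime_painting(tr, stats::setNames(2L, as.character(e)))
    theta <- rnorm(2, 0, 3)
    mu <- hansen_mean_oracle(tr, p, alpha, theta)[tr$tip.label]
    expect_equal(hansen_loglik(x, tr, p, alpha, sigma2, theta),
                 mvn_logdens(x, mu, V), tolerance = 1e-8)
  }
})

test_that("analytic limits hold: OU to BM, EB at r = 0, one-regime Hansen", {
  set.seed(11)
  tr <- rand_unit_tree(6)
  x <- stats::setNames(rnorm(6), tr$tip.label)
  expect_equal(ou1_loglik(x, tr, alpha = 1e-8, sigma2 = 1.3, theta = 0.2),
               bm_loglik(x, tr, sigma2 = 1.3, z0 = 0.2), tolerance = 1e-4)
  expect_identical(eb_loglik(x, tr, 1.3, r = 0, z0 = 0.2),
                   bm_loglik(x, tr, 1.3, 0.2))
  p1 <- regime_painting(tr)
  expect_equal(hansen_loglik(x, tr, p1, 1.7, 2.1, theta = 0.5),
               ou1_loglik(x, tr, 1.7, 2.1, 0.5), tolerance = 1e-12)
})

test_that("EB warped branch lengths equal the quadrature of the decaying rate", {
  tr <- read_newick("((A:0.4,B:0.4):0.6,C:1);")
  r <- -1.3
  C <- shared_path_matrix(tr, canonical = FALSE)
  warp <- peakscape:::.eb_cov_unit(peakscape:::.tree_cache(tr), r)
  for (i in 1:3) for (j in 1:3) {
    q <- stats::integrate(function(t) exp(r * t), 0, C[i, j])$value
    expect_equal(warp[i, j], q, tolerance = 1e-8)
  }
})

test_that("Hansen regime weights sum to one for random paintings", {
  set.seed(12)
  for (i in 1:10) {
    tr <- rand_unit_tree(8)
    ne <- nrow(tr$edge)
    sh <- sample(ne, 2)
    p <- regime_painting(tr, stats::setNames(c(2L, 3L), as.character(sh)))
    cache <- peakscape:::.tree_cache(tr)
    W <- peakscape:::.hansen_weights(cache, peakscape:::.canonical_painting(p),
                                     alpha = runif(1, 0.1, 10))
    expect_equal(unname(rowSums(W)), rep(1, 8), tolerance = 1e-10)
  }
})

test_that("likelihood contracts reject invalid input", {
  tr <- rand_unit_tree(4)
  x <- stats::setNames(rnorm(4), tr$tip.label)
  expect_error(bm_loglik(x, tr, sigma2 = -1, z0 = 0), "positive")
  expect_error(ou1_loglik(x, tr, alpha = 0, sigma2 = 1, theta = 0), "positive")
  nonultra <- read_newick("((A:1,B:2):1,C:2);")
  xx <- c(A = 1, B = 2, C = 0)
  expect_error(ou1_loglik(xx, nonultra, 1, 1, 0), "ultrametric")
  p <- regime_painting(tr)
  expect_error(hansen_loglik(x, tr, p, 1, 1, theta = c(0, 1)), "per regime")
})

test_that("ML fitting recovers BM parameters and respects time rescaling", {
  tr <- rand_unit_tree(60)
  x <- simulate_traits(tr, "BM", params = list(sigma2 = 2, z0 = 1),
                       seed = 13)[1, ]
  f <- fit_model(x, tr, "BM")
  expect_lt(abs(f$params$sigma2 - 2) / 2, 0.5)
  expect_equal(f$AIC, 2 * 2 - 2 * f$loglik)
  expect_equal(f$AICc, f$AIC + 2 * 2 * 3 / (60 - 3))

  # OU1 time-rescaling: a 10x stretched tree fits alpha and sigma2 10x
  # smaller at identical maximised log-likelihood Jacobian aside
  set.seed(14)
  tr2 <- rand_unit_tree(24)
  y <- simulate_traits(tr2, "OU1",
                       params = list(alpha = 2, sigma2 = 1.5, theta = 0),
                       seed = 15)[1, ]
  f1 <- fit_model(y, tr2, "OU1")
  tr10 <- tr2; tr10$edge.length <- tr10$edge.length * 10
  f10 <- fit_model(y, tr10, "OU1")
  expect_equal(f10$params$alpha * 10, f1$params$alpha, tolerance = 1e-3)
  expect_equal(f10$params$sigma2 * 10, f1$params$sigma2, tolerance = 1e-3)
  expect_equal(f10$loglik, f1$loglik, tolerance = 1e-6)
})

test_that("two-regime Hansen fit recovers the generating optima", {
  tr <- gen_tree(32, seed = 3)
  pa <- regime_painting(tr, stats::setNames(
    2L, as.character(attr(tr, "shift_edge"))))
  th <- matrix(NA_real_, 6, 2)
  for (s in 1:6) {
    x <- simulate_traits(tr, "HANSEN",
                         params = list(alpha = 0.974, sigma2 = 7.42,
                                       theta = c(1.126, -11.027)),
                         painting = pa, n_replicates = 1, seed = s)[1, ]
    f <- fit_model(x, tr, "HANSEN", painting = pa)
    expect_equal(f$n_params, 4L)
    expect_gt(f$loglik, fit_model(x, tr, "OU1")$loglik)
    th[s, ] <- f$params$theta
  }
  # averaged over replicates the optima sit near the generating values;
  # single-replicate estimates of a weakly occupied optimum are noisy
  expect_lt(abs(mean(th[, 1]) - 1.126), 2)
  expect_lt(abs(mean(th[, 2]) - (-11.027)), 4)
  expect_true(all(th[, 2] < th[, 1]))
})

test_that("fit_model is deterministic and EB fits satisfy r <= 0", {
  tr <- rand_unit_tree(20)
  x <- simulate_traits(tr, "BM", params = list(sigma2 = 1, z0 = 0),
                       seed = 16)[1, ]
  f1 <- fit_model(x, tr, "EB")
  f2 <- fit_model(x, tr, "EB")
  expect_identical(f1$params, f2$params)
  expect_lte(f1$params$r, 0)
})

test_that("aic_table computes weights, deltas, and guards data identity", {
  tr <- rand_unit_tree(12)
  x <- simulate_traits(tr, "BM", params = list(sigma2 = 1, z0 = 0),
                       seed = 17)[1, ]
  fits <- list(BM = fit_model(x, tr, "BM"), OU = fit_model(x, tr, "OU1"))
  tab <- aic_table(fits)
  expect_equal(min(tab$dAIC), 0)
  expect_equal(sum(tab$wAIC), 1, tolerance = 1e-10)
  expect_equal(tab$wAIC, exp(-tab$dAIC / 2) / sum(exp(-tab$dAIC / 2)),
               tolerance = 1e-12)

  # closed form: dAIC = (0, 2) gives weights 1/(1+e^-1), e^-1/(1+e^-1)
  f_a <- fits$BM; f_b <- fits$BM
  f_b$AIC <- f_a$AIC + 2
  tab2 <- aic_table(list(a = f_a, b = f_b))
  expect_equal(tab2$wAIC, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)

  # identical AICs give equal weights
  tab3 <- aic_table(list(a = f_a, b = f_a))
  expect_equal(tab3$wAIC, c(0.5, 0.5))

  y <- x; y[1] <- y[1] + 1
  fits_bad <- list(BM = fits$BM, OU = fit_model(y, tr, "OU1"))
  expect_error(aic_table(fits_bad), "identical data")
})
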