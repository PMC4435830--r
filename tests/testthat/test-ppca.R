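star_tree <- function(n) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(1, n)
  tr
}

test_that("star-tree phylogenetic PCA equals ordinary covariance PCA", {
  set.seed(1)
  n <- 20
  star <- star_tree(n)
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(star$tip.label, paste0("v", 1:5)))
  pp <- phylo_pca(X, star)
  ref <- eigen(stats::cov(X), symmetric = TRUE)
  expect_equal(unname(pp$eigenvalues), ref$values, tolerance = 1e-10)
  expect_equal(unname(pp$gls_mean), unname(colMeans(X)), tolerance = 1e-10)
  expect_lt(max(abs(abs(pp$loadings) - abs(ref$vectors))), 1e-10)
})

test_that("3-taxon 2-trait pPCA matches the explicit matrix oracle", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  X <- cbind(t1 = c(A = 1, B = 2, C = 4), t2 = c(A = 0, B = 1, C = 1))
  pp <- phylo_pca(X, tr)
  C <- shared_path_matrix(tr)
  Ci <- solve(C)
  one <- rep(1, 3)
  a <- drop(t(one) %*% Ci %*% X) / drop(t(one) %*% Ci %*% one)
  Xc <- sweep(X[rownames(C), ], 2, a)
  R <- t(Xc) %*% Ci %*% Xc / 2
  ref <- eigen(R, symmetric = TRUE)
  expect_equal(unname(pp$eigenvalues), ref$values, tolerance = 1e-10)
  expect_equal(unname(abs(pp$scores)), unname(abs(Xc %*% ref$vectors)),
               tolerance = 1e-10)
})

test_that("pPCA invariants: eigen sum, translation invariance, sign rule", {
  set.seed(2)
  tr <- rand_unit_tree(15)
  X <- matrix(rnorm(15 * 6), 15, 6,
              dimnames = list(tr$tip.label, paste0("v", 1:6)))
  pp <- phylo_pca(X, tr)
  expect_true(all(diff(pp$eigenvalues) <= 1e-12))
  expect_equal(sum(pp$pct_variance), 100, tolerance = 1e-10)
  expect_equal(unname(sqrt(colSums(pp$loadings^2))), rep(1, 6),
               tolerance = 1e-10)
  for (j in 1:6) {
    expect_gt(pp$loadings[which.max(abs(pp$loadings[, j])), j], 0)
  }
  # eigenvalue sum equals the trace of the evolutionary covariance
  C <- shared_path_matrix(tr); Ci <- solve(C)
  Xo <- X[rownames(C), ]
  a <- drop(rep(1, 15) %*% Ci %*% Xo) / sum(Ci)
  Xc <- sweep(Xo, 2, a)
  expect_equal(sum(pp$eigenvalues), sum(diag(t(Xc) %*% Ci %*% Xc / 14)),
               tolerance = 1e-10)
  # recentring columns changes nothing
  shifted <- sweep(X, 2, c(3, -1, 0, 2, 5, -4), "+")
  pp2 <- phylo_pca(shifted, tr)
  expect_equal(pp2$scores, pp$scores, tolerance = 1e-10)
  expect_equal(pp2$eigenvalues, pp$eigenvalues, tolerance = 1e-10)
})

test_that("pPCA agrees with the reference implementation", {
  set.seed(3)
  tr <- rand_unit_tree(12)
  X <- matrix(rnorm(12 * 4), 12, 4,
              dimnames = list(tr$tip.label, paste0("v", 1:4)))
  pp <- phylo_pca(X, tr)
  ref <- phytools::phyl.pca(tr, X, method = "BM", mode = "cov")
  expect_equal(unname(pp$eigenvalues), unname(diag(ref$Eval)),
               tolerance = 1e-8)
  expect_lt(max(abs(abs(pp$loadings) - abs(unclass(ref$Evec)))), 1e-8)
})

test_that("identical trees give zero spread in the replicated pPCA", {
  set.seed(4)
  tr <- rand_unit_tree(10)
  X <- matrix(rnorm(40), 10, 4,
              dimnames = list(tr$tip.label, paste0("v", 1:4)))
  cs <- chronogram_set(list(tr, tr, tr), mcc = tr)
  ps <- ppca_over_trees(X, cs)
  expect_equal(unname(ps$summary$eigenvalues["sd", ]), rep(0, 4))
  expect_equal(max(abs(ps$summary$loadings_sd)), 0)
})

test_that("cross-tree spread of eigenvalues grows with branch-length jitter", {
  set.seed(5)
  tr <- gen_tree(16, seed = 5)
  X <- matrix(rnorm(16 * 4), 16, 4,
              dimnames = list(tr$tip.label, paste0("v", 1:4)))
  sds <- sapply(c(0.02, 0.4), function(j) {
    cs <- gen_posterior_set(tr, n_trees = 15, jitter_sd = j, seed = 9)
    mean(ppca_over_trees(X, cs)$summary$eigenvalues["sd", 1:2])
  })
  expect_lt(sds[1], sds[2])
})

test_that("permutation preserves each variable's marginal values", {
  set.seed(6)
  tr <- rand_unit_tree(10)
  X <- matrix(rnorm(30), 10, 3,
              dimnames = list(tr$tip.label, c("a", "b", "c")))
  cs <- chronogram_set(list(tr), mcc = tr)
  # run with tiny n_perm and intercept the permuted data via the identical
  # marginal-sorted property of the returned loading statistics: instead,
  # check the scheme directly on the internals by reproducing it
  set.seed(42)
  Xp <- X
  for (j in seq_len(ncol(X))) Xp[, j] <- X[sample.int(nrow(X)), j]
  for (j in seq_len(ncol(X))) {
    expect_equal(sort(unname(Xp[, j])), sort(unname(X[, j])))
  }
})

test_that("permutation axis test input contracts hold", {
  set.seed(7)
  tr <- rand_unit_tree(8)
  X <- matrix(rnorm(24), 8, 3, dimnames = list(tr$tip.label, c("a", "b", "c")))
  cs <- chronogram_set(list(tr), mcc = tr)
  expect_error(permutation_axis_test(X, cs, n_perm = 1), "at least 2")
  expect_warning(permutation_axis_test(X, cs, n_perm = 10, seed = 1),
                 "unstable")
})

test_that("structured two-block traits yield critical axes, noise does not", {
  st <- gen_study(synthetic_spec(), seed = 1, n_posterior = 6)
  means <- log_species_means(st$specimens)
  res <- phylo_size_correct(means, st$trees$mcc)
  at <- permutation_axis_test(res, st$trees, n_perm = 150, seed = 2)
  expect_gte(at$n_critical_axes, 1)
  expect_true(at$critical["PC1"])
  # flags exist only for critical axes
  expect_equal(ncol(at$loading_flags), at$n_critical_axes)
  # determinism under identical seeds
  at2 <- permutation_axis_test(res, st$trees, n_perm = 150, seed = 2)
  expect_identical(at$observed_ci, at2$observed_ci)
  expect_identical(at$permuted_ci, at2$permuted_ci)
})
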