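make_specimens <- function(df) {
  data.frame(species = df$sp, specimen_id = seq_len(nrow(df)),
             variable = df$var, value = df$val, stringsAsFactors = FALSE)
}

test_that("log_species_means averages log measurements per species", {
  sp <- make_specimens(data.frame(
    sp = c("a", "a", "b"), var = "SL", val = c(exp(1), exp(1), exp(3))))
  m <- log_species_means(sp)
  expect_equal(m["a", "SL"], 1)
  expect_equal(m["b", "SL"], 3)   # single specimen: mean equals its log

  # wide format agrees with long format
  wide <- data.frame(species = c("a", "a", "b"),
                     SL = c(2, 4, 8), fin = c(1, 1, 5))
  long <- data.frame(species = rep(c("a", "a", "b"), 2),
                     specimen_id = rep(1:3, 2),
                     variable = rep(c("SL", "fin"), each = 3),
                     value = c(2, 4, 8, 1, 1, 5))
  expect_equal(log_species_means(wide), log_species_means(long))
  expect_equal(log_species_means(wide)["a", "SL"], mean(log(c(2, 4))))
})

test_that("non-positive measurements are rejected with the culprit named", {
  bad <- make_specimens(data.frame(sp = c("a", "b"), var = "SL",
                                   val = c(2, -1)))
  expect_error(log_species_means(bad), "'b'.*'SL'")
  bad0 <- make_specimens(data.frame(sp = "a", var = "fin", val = 0))
  expect_error(log_species_means(bad0), "'a'.*'fin'")
})

test_that("specimen-heavy tables collapse to one row per species", {
  st <- gen_study(synthetic_spec(n_species = 10), seed = 4, n_posterior = 1)
  m <- log_species_means(st$specimens)
  expect_equal(nrow(m), 10)
  expect_equal(ncol(m), 16)  # SL + 15 locomotor traits
  expect_false(anyNA(m))
})

test_that("phylogenetic size correction matches a dense GLS oracle", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  X <- cbind(SL = c(A = 0, B = 1, C = 2), y = c(A = 1, B = 2, C = 4))
  res <- phylo_size_correct(X, tr)
  C <- shared_path_matrix(tr)
  or <- gls_oracle(X[rownames(C), "y"], cbind(1, X[rownames(C), "SL"]), C)
  expect_equal(unname(res[, "y"]), unname(or$residuals), tolerance = 1e-10)

  # exact linear trait has zero residuals
  X2 <- cbind(SL = c(A = 0, B = 1, C = 2), y = c(A = 3, B = 5, C = 7))
  expect_lt(max(abs(phylo_size_correct(X2, tr))), 1e-10)
})

test_that("star-tree GLS residuals equal OLS residuals", {
  star <- ape::stree(6, "star")
  star$edge.length <- rep(1, 6)
  set.seed(1)
  X <- cbind(SL = rnorm(6, 4), y = rnorm(6))
  rownames(X) <- star$tip.label
  res <- phylo_size_correct(X, star)
  ols <- stats::residuals(stats::lm(X[, "y"] ~ X[, "SL"]))
  expect_equal(unname(res[names(ols), "y"]), unname(ols), tolerance = 1e-10)
})

test_that("GLS residuals are invariant to covariance scale and y-shifts", {
  set.seed(2)
  tr <- rand_unit_tree(8)
  X <- cbind(SL = rnorm(8, 4), y = rnorm(8), z = rnorm(8))
  rownames(X) <- tr$tip.label
  base <- phylo_size_correct(X, tr)
  tr10 <- tr; tr10$edge.length <- tr10$edge.length * 10
  expect_equal(unclass(phylo_size_correct(X, tr10)), unclass(base),
               tolerance = 1e-10, ignore_attr = TRUE)
  Xs <- X; Xs[, "y"] <- Xs[, "y"] + 7
  expect_equal(unclass(phylo_size_correct(Xs, tr))[, "y"],
               unclass(base)[, "y"], tolerance = 1e-10)
})

test_that("GLS-weighted mean of every residual column is zero", {
  set.seed(3)
  tr <- rand_unit_tree(12)
  X <- cbind(SL = rnorm(12, 4), matrix(rnorm(36), 12, 3,
                                       dimnames = list(NULL, c("a", "b", "c"))))
  rownames(X) <- tr$tip.label
  res <- phylo_size_correct(X, tr)
  Ci <- solve(shared_path_matrix(tr))
  one <- rep(1, 12)
  for (v in colnames(res)) {
    expect_lt(abs(sum(Ci %*% res[, v]) / sum(Ci)), 1e-8)
  }
})

test_that("residuals agree with the reference phylogenetic regression", {
  set.seed(4)
  tr <- rand_unit_tree(10)
  X <- cbind(SL = rnorm(10, 4, 0.5), t1 = rnorm(10), t2 = rnorm(10))
  rownames(X) <- tr$tip.label
  res <- phylo_size_correct(X, tr)
  ref <- phytools::phyl.resid(tr, X[, "SL", drop = FALSE],
                              X[, c("t1", "t2")])$resid
  expect_lt(max(abs(res[rownames(ref), c("t1", "t2")] - ref)), 1e-8)
})
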