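#' Phylogenetic principal components analysis
#'
#' PCA of the evolutionary (phylogenetically corrected) trait covariance
#' matrix. With shared-path matrix `C` and trait matrix `X`, the GLS
#' ancestral mean is `a = (1'C^-1 1)^-1 1'C^-1 X`, the evolutionary
#' covariance is `R = (X - 1a)' C^-1 (X - 1a) / (n - 1)`, and components are
#' the eigenvectors of `R` (covariance mode, the default) or of the
#' corresponding correlation matrix. Scores are `(X - 1a) V`, i.e. species
#' positions relative to the inferred ancestral state. On a star phylogeny
#' with equal branch lengths this reduces exactly to ordinary PCA of the
#' sample covariance matrix.
#'
#' Sign convention: within each axis the loading of largest magnitude is made
#' positive, so axes are comparable across trees and permutations.
#'
#' @param traits Species-by-variable matrix (e.g. a `"residual_traits"`
#'   object); row names are species.
#' @param tree A `"phylo"` chronogram with the same tip set.
#' @param mode `"cov"` (default) or `"cor"`.
#' @return A list of class `"ppca"`: `eigenvalues` (descending), `loadings`
#'   (variables x axes, unit columns), `scores` (species x axes),
#'   `pct_variance`, `gls_mean`, `mode`, `tip_order`.
#' @export
phylo_pca <- function(traits, tree, mode = c("cov", "cor")) {
  mode <- match.arg(mode)
  X <- as.matrix(traits)
  if (!setequal(rownames(X), tree$tip.label)) {
    stop("species in trait table and tree tips differ")
  }
  C <- shared_path_matrix(tree, canonical = TRUE)
  X <- X[rownames(C), , drop = FALSE]
  n <- nrow(X)
  R <- .chol_or_stop(C)
  one <- matrix(1, n, 1)
  onew <- backsolve(R, one, transpose = TRUE)
  Xw <- backsolve(R, X, transpose = TRUE)
  a <- drop(crossprod(onew, Xw) / sum(onew^2))      # GLS ancestral mean
  Xc <- sweep(X, 2L, a)
  Xcw <- backsolve(R, Xc, transpose = TRUE)
  Rcov <- crossprod(Xcw) / (n - 1)
  if (mode == "cor") {
    s <- sqrt(diag(Rcov))
    Rcov <- Rcov / tcrossprod(s)
    Xc <- sweep(Xc, 2L, s, "/")
  }
  eig <- eigen(Rcov, symmetric = TRUE)
  vals <- eig$values
  neg <- vals < 0
  if (any(vals < -1e-8 * max(abs(vals)))) {
    warning("evolutionary covariance matrix is rank deficient; ",
            "negative eigenvalues clipped to zero")
  }
  vals[neg] <- 0
  V <- eig$vectors
  # sign rule: largest-|loading| entry positive per axis
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(ncol(V))))
  scores <- Xc %*% V
  dimnames(scores) <- list(rownames(X), colnames(V))
  structure(list(
    eigenvalues = stats::setNames(vals, colnames(V)),
    loadings = V,
    scores = scores,
    pct_variance = stats::setNames(100 * vals / sum(vals), colnames(V)),
    gls_mean = a,
    mode = mode,
    tip_order = rownames(X)
  ), class = "ppca")
}

#' @export
print.ppca <- function(x, ...) {
  k <- min(4L, length(x$eigenvalues))
  cat("Phylogenetic PCA (", x$mode, " mode), ",
      nrow(x$scores), " species, ", ncol(x$loadings), " axes\n", sep = "")
  cat("Leading eigenvalues:",
      paste(sprintf("%.3f (%.1f%%)", x$eigenvalues[1:k],
                    x$pct_variance[1:k]), collapse = ", "), "\n")
  invisible(x)
}

# Match the axes of `pp` to the reference loadings by maximal absolute
# correlation (greedy over axes in reference order), guarding against axis
# swapping when eigenvalues are close. Returns the permutation.
.match_axes <- function(ref_loadings, loadings) {
  k <- ncol(ref_loadings)
  taken <- logical(k)
  perm <- integer(k)
  cors <- abs(suppressWarnings(stats::cor(ref_loadings, loadings)))
  cors[!is.finite(cors)] <- 0
  for (j in seq_len(k)) {
    cand <- order(cors[j, ], decreasing = TRUE)
    pick <- cand[!taken[cand]][1L]
    perm[j] <- pick
    taken[pick] <- TRUE
  }
  perm
}

#' Phylogenetic PCA replicated over a set of chronograms
#'
#' Runs [phylo_pca()] on every tree of a posterior set, aligns each result's
#' axes to the summary (MCC) tree's axes by maximal absolute loading-vector
#' correlation, and summarises eigenvalues, loadings and percent variance as
#' mean and standard deviation across trees.
#'
#' @param traits Species-by-variable matrix.
#' @param trees A `"chronogram_set"` (see [chronogram_set()]).
#' @param mode Passed to [phylo_pca()].
#' @return A list of class `"ppca_set"`: `mcc` (the MCC-tree `"ppca"`),
#'   `per_tree` (list of `"ppca"`), and `summary` — a list with
#'   `eigenvalues`, `pct_variance` (2 x axes matrices: mean, sd) and
#'   `loadings_mean`, `loadings_sd` (variables x axes).
#' @export
ppca_over_trees <- function(traits, trees, mode = c("cov", "cor")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trees, "chronogram_set"))
  mcc <- phylo_pca(traits, trees$mcc, mode = mode)
  per_tree <- lapply(trees$trees, function(t) {
    pp <- phylo_pca(traits, t, mode = mode)
    perm <- .match_axes(mcc$loadings, pp$loadings)
    pp$eigenvalues <- pp$eigenvalues[perm]
    pp$loadings <- pp$loadings[, perm, drop = FALSE]
    pp$scores <- pp$scores[, perm, drop = FALSE]
    pp$pct_variance <- pp$pct_variance[perm]
    names(pp$eigenvalues) <- names(pp$pct_variance) <-
      colnames(pp$loadings) <- colnames(pp$scores) <- colnames(mcc$loadings)
    pp
  })
  eig <- sapply(per_tree, function(p) p$eigenvalues)
  pct <- sapply(per_tree, function(p) p$pct_variance)
  loads <- simplify2array(lapply(per_tree, function(p) p$loadings))
  sd0 <- function(m) apply(m, 1L, stats::sd)
  summary <- list(
    eigenvalues = rbind(mean = rowMeans(eig), sd = sd0(eig)),
    pct_variance = rbind(mean = rowMeans(pct), sd = sd0(pct)),
    loadings_mean = apply(loads, c(1L, 2L), mean),
    loadings_sd = apply(loads, c(1L, 2L), stats::sd)
  )
  structure(list(mcc = mcc, per_tree = per_tree, summary = summary),
            class = "ppca_set")
}

#' Permutation test for critical principal component axes
#'
#' Identifies the axes of a phylogenetic PCA that carry more variance than
#' expected under a null of no structured covariation, in the spirit of
#' Horn's parallel analysis. The observed distribution of each eigenvalue is
#' taken across the posterior tree set; the null distribution is built by
#' permuting species assignments independently within each variable column
#' (destroying trait-trait and trait-phylogeny structure) and rerunning the
#' phylogenetic PCA on the summary tree. An axis is critical when its
#' observed 95% interval lies wholly above the permuted 95% interval. For
#' critical axes, variables whose absolute-loading intervals do not overlap
#' the permuted loading intervals are flagged as influential.
#'
#' By default axes are compared on their share of total variance rather
#' than on raw eigenvalues (`compare = "proportion"`): destroying
#' phylogenetic signal by permutation inflates every variable's implied
#' evolutionary rate by roughly `tr(C^-1)/(n-1)`, so permuted covariance
#' eigenvalues sit on a wholly different scale and a raw comparison is
#' uninformative; the variance share is the scale-free analogue, in the
#' spirit of parallel analysis on correlation matrices. Raw-eigenvalue
#' comparison remains available via `compare = "eigenvalue"`.
#'
#' @param traits Species-by-variable matrix.
#' @param trees A `"chronogram_set"`.
#' @param n_perm Number of permutations (>= 2 required, >= 100 recommended).
#' @param seed Integer RNG seed; recorded in the result.
#' @param mode Passed to [phylo_pca()].
#' @param scheme `"column"` (default: independent within-column shuffles) or
#'   `"row"` (joint shuffle of whole species rows).
#' @param compare `"proportion"` (default: axes compared on percent
#'   variance) or `"eigenvalue"` (raw eigenvalues).
#' @return A list of class `"axis_selection"`: `n_critical_axes`, `critical`
#'   (logical per axis), `observed_ci` / `permuted_ci` (eigenvalue 2.5/97.5%
#'   bounds per axis), `loading_flags` (variables x critical axes logical),
#'   `observed_loading_ci`, `permuted_loading_ci`, `n_perm`, `seed`.
#' @export
permutation_axis_test <- function(traits, trees, n_perm = 1000, seed = 1,
                                  mode = c("cov", "cor"),
                                  scheme = c("column", "row"),
                                  compare = c("proportion", "eigenvalue")) {
  mode <- match.arg(mode)
  scheme <- match.arg(scheme)
  compare <- match.arg(compare)
  if (n_perm < 2) stop("n_perm must be at least 2")
  if (n_perm < 100) warning("n_perm < 100: permutation intervals will be unstable")
  stopifnot(inherits(trees, "chronogram_set"))
  obs <- ppca_over_trees(traits, trees, mode = mode)
  stat <- function(p) if (compare == "proportion") p$pct_variance else
    p$eigenvalues
  eig_obs <- sapply(obs$per_tree, stat)
  if (is.null(dim(eig_obs))) eig_obs <- matrix(eig_obs, nrow = 1)
  abs_load_obs <- simplify2array(lapply(obs$per_tree,
                                        function(p) abs(p$loadings)))
  X <- as.matrix(traits)
  set.seed(seed)
  k <- length(obs$mcc$eigenvalues)
  eig_perm <- matrix(NA_real_, k, n_perm)
  abs_load_perm <- array(NA_real_, c(nrow(obs$mcc$loadings), k, n_perm))
  for (b in seq_len(n_perm)) {
    Xp <- X
    if (scheme == "column") {
      for (j in seq_len(ncol(X))) Xp[, j] <- X[sample.int(nrow(X)), j]
    } else {
      Xp <- X[sample.int(nrow(X)), , drop = FALSE]
      rownames(Xp) <- rownames(X)
    }
    rownames(Xp) <- rownames(X)
    pp <- phylo_pca(Xp, trees$mcc, mode = mode)
    eig_perm[, b] <- stat(pp)              # rank order, as in parallel analysis
    abs_load_perm[, , b] <- abs(pp$loadings)
  }
  ci <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  obs_ci <- apply(eig_obs, 1L, ci)               # 2 x axes
  perm_ci <- apply(eig_perm, 1L, ci)
  critical <- obs_ci[1L, ] > perm_ci[2L, ]
  axes <- names(obs$mcc$eigenvalues)
  obs_load_ci <- apply(abs_load_obs, c(1L, 2L), ci)   # 2 x var x axes
  perm_load_ci <- apply(abs_load_perm, c(1L, 2L), ci)
  crit_idx <- which(critical)
  flags <- NULL
  if (length(crit_idx)) {
    flags <- sapply(crit_idx, function(j) {
      obs_load_ci[1L, , j] > perm_load_ci[2L, , j] |
        obs_load_ci[2L, , j] < perm_load_ci[1L, , j]
    })
    flags <- matrix(flags, ncol = length(crit_idx),
                    dimnames = list(rownames(obs$mcc$loadings),
                                    axes[crit_idx]))
  }
  structure(list(
    n_critical_axes = sum(critical),
    critical = stats::setNames(critical, axes),
    observed_ci = obs_ci, permuted_ci = perm_ci,
    loading_flags = flags,
    observed_loading_ci = obs_load_ci, permuted_loading_ci = perm_load_ci,
    ppca = obs, n_perm = n_perm, seed = seed, scheme = scheme,
    compare = compare
  ), class = "axis_selection")
}

#' @export
print.axis_selection <- function(x, ...) {
  cat("Permutation axis test (", x$n_perm, " permutations, seed ", x$seed,
      "): ", x$n_critical_axes, " critical axes\n", sep = "")
  if (x$n_critical_axes > 0) {
    for (ax in colnames(x$loading_flags)) {
      cat(" ", ax, "influential variables:",
          paste(rownames(x$loading_flags)[x$loading_flags[, ax]],
                collapse = ", "), "\n")
    }
  }
  invisible(x)
}
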