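#' Run the full adaptive-landscape study workflow
#'
#' Orchestrates the whole analysis over a posterior set of chronograms:
#'
#' 1. specimen measurements are log-transformed and collapsed to species
#'    means, then size-corrected by phylogenetic GLS on each tree;
#' 2. phylogenetic PCA is replicated over the tree set and critical axes are
#'    identified by the permutation test (on the summary tree);
#' 3. for each critical axis (at most `max_axes`), BM / OU1 / EB models are
#'    fitted on every tree; the regime search runs on the summary tree and —
#'    when `surface_per_tree` — on every tree, giving a Hansen ("SURFACE")
#'    column in the model table;
#' 4. the regime-search statistics are tested against the BM null on the
#'    summary tree;
#' 5. disparity-through-time analyses compare the first axis to BM / EB /
#'    Hansen simulations and the second axis to OU1 simulations, each with a
#'    posterior-predictive p.
#'
#' Scores for model fitting are taken from each tree's own PCA (axes aligned
#' to the summary tree). All randomness derives from `seed`.
#'
#' @param specimens Long- or wide-format specimen table (see
#'   [log_species_means()]), or a `"synthetic_study"` (in which case
#'   `trees` is taken from it).
#' @param trees A `"chronogram_set"`.
#' @param n_perm Permutations for the axis test.
#' @param n_sim_null BM-null simulations for the regime-search statistics.
#' @param n_sim_dtt DTT simulations per tree.
#' @param n_trees Optional subsample size of the posterior set (first
#'   `n_trees` trees), for desk-scale runs.
#' @param max_axes Maximum number of axes analysed (default 2).
#' @param surface_per_tree Run the regime search on every tree (default
#'   `TRUE`); otherwise the summary tree's painting is refitted per tree.
#' @param dtt_models_axis1 Generating models compared to axis 1 (default
#'   BM, EB and the Hansen regime model).
#' @param seed Integer seed.
#' @param size_var Name of the size variable (default `"SL"`).
#' @return A list of class `"study_report"`: `axis_test`, `table1`
#'   (loadings/eigenvalue/percent-variance summary with significance
#'   flags), `table2` (regime-search statistics with BM-null P), `table3`
#'   (per-axis model-comparison summaries, mean and SD over trees), `dtt`
#'   (named list of `"dtt_result"`), `surface` (summary-tree
#'   `"surface_model"` per axis), `provenance` (seed, sizes).
#' @export
run_study <- function(specimens, trees = NULL, n_perm = 1000,
                      n_sim_null = 500, n_sim_dtt = 1000, n_trees = NULL,
                      max_axes = 2, surface_per_tree = TRUE,
                      dtt_models_axis1 = c("BM", "EB", "HANSEN"),
                      seed = 1, size_var = "SL") {
  if (inherits(specimens, "synthetic_study")) {
    if (is.null(trees)) trees <- specimens$trees
    specimens <- specimens$specimens
  }
  stopifnot(inherits(trees, "chronogram_set"))
  if (!is.null(n_trees) && n_trees < length(trees$trees)) {
    trees <- chronogram_set(trees$trees[seq_len(n_trees)], mcc = trees$mcc)
  }
  nt <- length(trees$trees)

  ## 1. trait preparation (residuals per tree)
  means <- log_species_means(specimens)
  resid_by_tree <- lapply(trees$trees, function(t)
    phylo_size_correct(means, t, size_var = size_var))
  resid_mcc <- phylo_size_correct(means, trees$mcc, size_var = size_var)

  ## 2. pPCA over trees + permutation axis test
  ## (size correction varies by tree, so the replicated pPCA uses each
  ## tree's own residuals; the axis test takes the summary-tree residuals)
  mcc_pp <- phylo_pca(resid_mcc, trees$mcc)
  per_tree_pp <- vector("list", nt)
  for (i in seq_len(nt)) {
    pp <- phylo_pca(resid_by_tree[[i]], trees$trees[[i]])
    perm <- .match_axes(mcc_pp$loadings, pp$loadings)
    pp$eigenvalues <- pp$eigenvalues[perm]
    pp$loadings <- pp$loadings[, perm, drop = FALSE]
    pp$scores <- pp$scores[, perm, drop = FALSE]
    pp$pct_variance <- pp$pct_variance[perm]
    names(pp$eigenvalues) <- names(pp$pct_variance) <-
      colnames(pp$loadings) <- colnames(pp$scores) <- colnames(mcc_pp$loadings)
    per_tree_pp[[i]] <- pp
  }
  axis_test <- permutation_axis_test(resid_mcc, trees, n_perm = n_perm,
                                     seed = .substream_seed(seed, 11))
  n_axes <- max(1L, min(max_axes, axis_test$n_critical_axes, na.rm = TRUE))
  axes <- paste0("PC", seq_len(n_axes))

  eig <- sapply(per_tree_pp, function(p) p$eigenvalues)
  pct <- sapply(per_tree_pp, function(p) p$pct_variance)
  loads <- simplify2array(lapply(per_tree_pp, function(p) p$loadings))
  table1 <- list(
    eigenvalues = rbind(mean = rowMeans(eig), sd = apply(eig, 1, stats::sd)),
    pct_variance = rbind(mean = rowMeans(pct), sd = apply(pct, 1, stats::sd)),
    loadings_mean = apply(loads, c(1, 2), mean),
    loadings_sd = apply(loads, c(1, 2), stats::sd),
    loading_flags = axis_test$loading_flags,
    n_critical_axes = axis_test$n_critical_axes)

  ## 3. model fits per axis over trees
  scores_mcc <- lapply(axes, function(ax) mcc_pp$scores[, ax])
  names(scores_mcc) <- axes
  surface_mcc <- lapply(scores_mcc, function(s)
    run_surface(s, trees$mcc))
  table3 <- list()
  fits_store <- list()
  for (ax in axes) {
    rows <- vector("list", nt)
    for (i in seq_len(nt)) {
      s_i <- per_tree_pp[[i]]$scores[, ax]
      t_i <- trees$trees[[i]]
      fits <- list(BM = fit_model(s_i, t_i, "BM"),
                   OU = fit_model(s_i, t_i, "OU1"),
                   EB = fit_model(s_i, t_i, "EB"))
      surf_i <- if (surface_per_tree) {
        run_surface(s_i, t_i)
      } else {
        # refit the summary tree's painting on this tree (same topology)
        p <- surface_mcc[[ax]]$painting
        list(fit = fit_model(s_i, t_i, "HANSEN", painting = p), painting = p)
      }
      # a single-regime search result duplicates OU1; keep it as SURFACE
      fits$SURFACE <- surf_i$fit
      tab <- aic_table(fits, criterion = "AIC")
      rows[[i]] <- tab
    }
    arr <- simplify2array(lapply(rows, function(r)
      as.matrix(r[, c("AIC", "dAIC", "wAIC")])))
    dimnames(arr)[[1]] <- rows[[1]]$model
    table3[[ax]] <- list(mean = apply(arr, c(1, 2), mean),
                         sd = apply(arr, c(1, 2), stats::sd),
                         per_tree = rows)
    fits_store[[ax]] <- rows
  }

  ## 4. BM null for the regime-search statistics (summary tree, axis 1)
  null1 <- bm_null_peaks(scores_mcc[[1]], trees$mcc, n_sim = n_sim_null,
                         seed = .substream_seed(seed, 21),
                         observed = surface_mcc[[1]])
  table2 <- data.frame(observed = null1$observed,
                       bm_mean = null1$null_mean, bm_sd = null1$null_sd,
                       P = null1$P)

  ## 5. DTT posterior-predictive checks
  dtt <- list()
  ax1 <- axes[1]
  for (m in dtt_models_axis1) {
    nm <- paste0(ax1, "_vs_", m)
    dtt[[nm]] <- dtt_pipeline(
      scores_mcc[[1]], trees, model = m,
      painting = if (m == "HANSEN") surface_mcc[[ax1]]$painting else NULL,
      n_sim = n_sim_dtt, seed = .substream_seed(seed, 31))
  }
  if (n_axes >= 2) {
    dtt[[paste0(axes[2], "_vs_OU1")]] <- dtt_pipeline(
      scores_mcc[[2]], trees, model = "OU1",
      n_sim = n_sim_dtt, seed = .substream_seed(seed, 32))
  }

  structure(list(axis_test = axis_test, table1 = table1, table2 = table2,
                 table3 = table3, dtt = dtt, surface = surface_mcc,
                 ppca_mcc = mcc_pp, ppca_per_tree = per_tree_pp,
                 residuals_mcc = resid_mcc,
                 provenance = list(seed = seed, n_trees = nt,
                                   n_perm = n_perm,
                                   n_sim_null = n_sim_null,
                                   n_sim_dtt = n_sim_dtt,
                                   timestamp = format(Sys.time()))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Adaptive-landscape study report (", x$provenance$n_trees,
      " trees, seed ", x$provenance$seed, ")\n", sep = "")
  cat("Critical axes:", x$table1$n_critical_axes, "\n")
  cat("Percent variance (mean over trees):",
      paste(sprintf("%s %.1f", colnames(x$table1$pct_variance),
                    x$table1$pct_variance["mean", ]), collapse = ", "), "\n")
  cat("\nRegime-search statistics vs BM null (summary tree, axis 1):\n")
  print(round(x$table2, 3))
  for (ax in names(x$table3)) {
    cat("\nModel comparison,", ax, "(mean over trees):\n")
    print(round(x$table3[[ax]]$mean, 3))
  }
  cat("\nDTT posterior-predictive checks:\n")
  for (nm in names(x$dtt)) {
    d <- x$dtt[[nm]]
    cat(sprintf("  %-16s MDI = %7.3f +/- %.3f   p = %.3f +/- %.3f\n",
                nm, d$mdi_mean, ifelse(is.na(d$mdi_sd), 0, d$mdi_sd),
                d$p_mean, ifelse(is.na(d$p_sd), 0, d$p_sd)))
  }
  invisible(x)
}

#' Morphospace scatter of phylogenetic PCA scores
#'
#' Minimal two-axis scatter with optional convex hulls around groups
#' (e.g. the regimes of a fitted adaptive-landscape model).
#'
#' @param ppca A `"ppca"` object.
#' @param axes Two axis names or indices (default first two).
#' @param groups Optional factor over species (names matched to score rows).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_ppca <- function(ppca, axes = c(1, 2), groups = NULL, ...) {
  sc <- ppca$scores[, axes, drop = FALSE]
  lab <- sprintf("%s (%.1f%%)", colnames(sc), ppca$pct_variance[axes])
  graphics::plot(sc, xlab = lab[1], ylab = lab[2], pch = 19, ...)
  if (!is.null(groups)) {
    groups <- groups[rownames(sc)]
    cols <- grDevices::hcl.colors(nlevels(as.factor(groups)), "Dark 3")
    gf <- as.factor(groups)
    for (g in seq_len(nlevels(gf))) {
      pts <- sc[gf == levels(gf)[g], , drop = FALSE]
      if (nrow(pts) >= 3) {
        hull <- grDevices::chull(pts)
        graphics::polygon(pts[hull, ],
                          border = cols[g],
                          col = grDevices::adjustcolor(cols[g], 0.2))
      }
      graphics::points(pts, col = cols[g], pch = 19)
    }
  }
  invisible(ppca)
}
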