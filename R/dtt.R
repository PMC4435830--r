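#' Morphological disparity of a set of tip values
#'
#' Mean squared pairwise Euclidean distance over unordered pairs; a single
#' tip has disparity 0.
#'
#' @param values Numeric vector (univariate) or matrix (tips x variables).
#' @return Non-negative scalar.
#' @export
disparity <- function(values) {
  m <- as.matrix(values)
  if (nrow(m) == 0) stop("disparity of an empty set is undefined")
  if (nrow(m) == 1) return(0)
  d2 <- stats::dist(m)^2
  mean(d2)
}

#' Disparity-through-time curve
#'
#' At each internal-node height `t` (relative to tree height, root at 0) the
#' curve value is the average, over the lineages crossing just after `t`, of
#' the disparity of the subclade descending from that lineage divided by the
#' disparity of the whole clade. The value at the root (time 0) is 1 by
#' convention. Subclades of a single tip contribute 0.
#'
#' @param x Named (or tree-ordered) numeric tip values.
#' @param tree An ultrametric `"phylo"` chronogram.
#' @return A list of class `"dtt_curve"`: `times` (relative node heights,
#'   ascending, starting at 0) and `disparity` (same length).
#' @export
dtt_curve <- function(x, tree) {
  .assert_ultrametric(tree, "dtt_curve")
  cache <- .tree_cache(tree)
  x <- .match_tips(x, cache$tips)
  total <- disparity(x)
  if (total <= 0) stop("total disparity is zero; relative disparity undefined")
  n <- cache$n
  # tips below each node
  tips_below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) tips_below[[i]] <- i
  ord_post <- order(cache$edge_h0, decreasing = TRUE)
  for (e in ord_post) {
    p <- cache$edge[e, 1L]; ch <- cache$edge[e, 2L]
    tips_below[[p]] <- c(tips_below[[p]], tips_below[[ch]])
  }
  clade_disp <- vapply(seq_len(n + tree$Nnode), function(node) {
    disparity(x[tips_below[[node]]])
  }, 0)
  node_h <- cache$heights[(n + 1L):(n + tree$Nnode)] / cache$T
  times <- sort(unique(round(node_h, 12)))
  rel <- numeric(length(times))
  rel[1L] <- 1
  h0 <- cache$edge_h0 / cache$T
  h1 <- cache$edge_h1 / cache$T
  if (length(times) > 1L) {
    for (i in 2:length(times)) {
      t <- times[i]
      crossing <- which(h0 <= t + 1e-12 & h1 > t + 1e-12)
      rel[i] <- mean(clade_disp[cache$edge[crossing, 2L]] / total)
    }
  }
  structure(list(times = times, disparity = rel), class = "dtt_curve")
}

#' Morphological disparity index (MDI)
#'
#' Signed trapezoidal integral, over relative time `[0, truncation]`, of the
#' observed curve minus the expected (mean simulated) curve. Negative values
#' mean subclade disparity sits below the model expectation — disparity
#' partitioned among (not within) subclades, i.e. concentrated early.
#' Simulated curves must share the observed curve's time grid (they do
#' natively when computed on the same tree); the integrand is linearly
#' interpolated at the truncation point. Truncating below 1 (default 2/3 of
#' the tree height) avoids biases from incomplete taxon sampling toward the
#' present.
#'
#' @param observed A `"dtt_curve"` (or list with `times`, `disparity`).
#' @param sims A matrix of simulated curves (n_sim x times) or a single
#'   expected curve vector, on the observed grid.
#' @param truncation Upper limit of integration on relative time (default
#'   `2/3`).
#' @return Signed scalar.
#' @export
mdi <- function(observed, sims, truncation = 2 / 3) {
  times <- observed$times
  obs <- observed$disparity
  expected <- if (is.matrix(sims)) {
    if (ncol(sims) != length(times)) {
      stop("simulated curves are not on the observed time grid")
    }
    colMeans(sims)
  } else {
    if (length(sims) != length(times)) {
      stop("expected curve is not on the observed time grid")
    }
    as.numeric(sims)
  }
  .trapz_diff(times, obs - expected, truncation)
}

# trapezoidal integral of `diff` over [0, trunc] with interpolation at trunc
.trapz_diff <- function(times, d, trunc) {
  if (trunc <= times[1L]) return(0)
  keep <- times <= trunc
  tt <- times[keep]
  dd <- d[keep]
  if (max(times) > trunc && any(!keep)) {
    j <- which(!keep)[1L]
    w <- (trunc - times[j - 1L]) / (times[j] - times[j - 1L])
    tt <- c(tt, trunc)
    dd <- c(dd, d[j - 1L] + w * (d[j] - d[j - 1L]))
  }
  if (length(tt) < 2L) return(0)
  sum(diff(tt) * (utils::head(dd, -1) + utils::tail(dd, -1)) / 2)
}

#' Posterior-predictive p-value for an MDI
#'
#' One-sided tail frequency in the direction of the observed MDI's sign:
#' for a negative observed MDI, the proportion of simulated MDIs at least as
#' negative; for a positive one, at least as positive.
#'
#' @param observed_mdi Observed MDI (scalar).
#' @param sim_mdis Numeric vector of simulated MDIs, each computed
#'   exchangeably with the observed one (e.g. leave-one-out against the
#'   remaining simulations, as in [dtt_pipeline()]).
#' @return p in `[0, 1]`.
#' @export
posterior_predictive_p <- function(observed_mdi, sim_mdis) {
  if (!length(sim_mdis)) stop("no simulated MDI values supplied")
  if (length(sim_mdis) < 100) {
    warning("fewer than 100 simulated MDIs; p-value will be coarse")
  }
  if (observed_mdi < 0) mean(sim_mdis <= observed_mdi)
  else mean(sim_mdis >= observed_mdi)
}

# DTT machinery for one tree: observed curve, simulated curves from a fitted
# generating model, observed MDI vs mean simulated curve, and leave-one-out
# simulated MDIs (each simulation scored against the mean of the others so
# that observed and simulated MDIs are exchangeable under the model).
.dtt_one_tree <- function(x, tree, model, n_sim, seed, truncation,
                          painting = NULL, params = NULL) {
  if (is.null(params)) {
    fit <- if (model == "HANSEN") {
      fit_model(x, tree, "HANSEN", painting = painting)
    } else {
      fit_model(x, tree, model)
    }
    params <- fit$params
  }
  obs_curve <- dtt_curve(x, tree)
  sims <- simulate_traits(tree, model = model, params = params,
                          painting = painting, n_replicates = n_sim,
                          seed = seed)
  ntimes <- length(obs_curve$times)
  sim_curves <- matrix(NA_real_, n_sim, ntimes)
  ok <- logical(n_sim)
  for (r in seq_len(n_sim)) {
    cr <- tryCatch(dtt_curve(sims[r, ], tree), error = function(e) NULL)
    if (!is.null(cr)) { sim_curves[r, ] <- cr$disparity; ok[r] <- TRUE }
  }
  sim_curves <- sim_curves[ok, , drop = FALSE]
  ns <- nrow(sim_curves)
  if (ns < 2) stop("all DTT simulations failed")
  mean_curve <- colMeans(sim_curves)
  observed_mdi <- .trapz_diff(obs_curve$times,
                              obs_curve$disparity - mean_curve, truncation)
  # leave-one-out mean: (ns * mean - row) / (ns - 1)
  sim_mdis <- vapply(seq_len(ns), function(r) {
    loo_mean <- (ns * mean_curve - sim_curves[r, ]) / (ns - 1)
    .trapz_diff(obs_curve$times, sim_curves[r, ] - loo_mean, truncation)
  }, 0)
  p <- posterior_predictive_p(observed_mdi, sim_mdis)
  list(times = obs_curve$times, observed_curve = obs_curve$disparity,
       mean_sim_curve = mean_curve,
       envelope = apply(sim_curves, 2L, stats::quantile,
                        probs = c(0.025, 0.975)),
       mdi = observed_mdi, sim_mdis = sim_mdis, p = p,
       params = params, truncation = truncation)
}

#' Disparity-through-time analysis over a posterior set of chronograms
#'
#' For each tree: the generating model is (re)fitted to the tip values by
#' maximum likelihood, `n_sim` datasets are simulated from the fit, observed
#' and simulated DTT curves are computed on that tree's node-height grid,
#' and the MDI and posterior-predictive p are recorded. Cross-tree means and
#' standard deviations summarise the posterior set.
#'
#' @param x Named numeric tip values.
#' @param trees A `"chronogram_set"`.
#' @param model Generating model: `"BM"`, `"OU1"`, `"EB"`, or `"HANSEN"`.
#' @param painting A `"regime_painting"` on the MCC tree (HANSEN only);
#'   shifts are assumed to be identifiable by edge on every tree of the set
#'   only when topologies are identical — otherwise supply `per_tree_paintings`.
#' @param per_tree_paintings Optional list of paintings, one per tree.
#' @param n_sim Simulations per tree (default 1000).
#' @param seed Integer seed.
#' @param truncation Upper integration limit on relative time (default 2/3).
#' @return A list of class `"dtt_result"`: `per_tree` (list as returned by
#'   the single-tree analysis), `mdi_mean`, `mdi_sd`, `p_mean`, `p_sd`,
#'   `model`, `n_sim`, `seed`.
#' @export
dtt_pipeline <- function(x, trees, model = c("BM", "OU1", "EB", "HANSEN"),
                         painting = NULL, per_tree_paintings = NULL,
                         n_sim = 1000, seed = 1, truncation = 2 / 3) {
  model <- match.arg(model)
  stopifnot(inherits(trees, "chronogram_set"))
  nt <- length(trees$trees)
  per_tree <- vector("list", nt)
  for (i in seq_len(nt)) {
    p_i <- if (!is.null(per_tree_paintings)) per_tree_paintings[[i]] else painting
    per_tree[[i]] <- .dtt_one_tree(
      x, trees$trees[[i]], model = model, n_sim = n_sim,
      seed = .substream_seed(seed, 100000 + i), truncation = truncation,
      painting = p_i)
  }
  mdis <- vapply(per_tree, function(z) z$mdi, 0)
  ps <- vapply(per_tree, function(z) z$p, 0)
  structure(list(per_tree = per_tree,
                 mdi_mean = mean(mdis), mdi_sd = stats::sd(mdis),
                 p_mean = mean(ps), p_sd = stats::sd(ps),
                 model = model, n_sim = n_sim, seed = seed,
                 truncation = truncation),
            class = "dtt_result")
}

#' @export
print.dtt_result <- function(x, ...) {
  cat("DTT vs ", x$model, " simulations over ", length(x$per_tree),
      " trees (", x$n_sim, " sims/tree, truncation ",
      format(x$truncation, digits = 3), ")\n", sep = "")
  cat(sprintf("  MDI = %.3f +/- %.3f, p = %.3f +/- %.3f\n",
              x$mdi_mean, ifelse(is.na(x$mdi_sd), 0, x$mdi_sd),
              x$p_mean, ifelse(is.na(x$p_sd), 0, x$p_sd)))
  invisible(x)
}

#' Plot a DTT envelope
#'
#' Observed curve (solid), mean simulated curve (dashed) and the 95%
#' simulation envelope (shaded) for one tree's DTT analysis.
#'
#' @param result A `"dtt_result"` from [dtt_pipeline()].
#' @param tree_index Which tree's curves to draw (default 1).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_dtt <- function(result, tree_index = 1, ...) {
  z <- result$per_tree[[tree_index]]
  graphics::plot(z$times, z$observed_curve, type = "n",
                 xlab = "Relative time", ylab = "Relative subclade disparity",
                 ylim = range(0, z$envelope, z$observed_curve), ...)
  graphics::polygon(c(z$times, rev(z$times)),
                    c(z$envelope[1L, ], rev(z$envelope[2L, ])),
                    col = grDevices::adjustcolor("grey60", 0.4), border = NA)
  graphics::lines(z$times, z$mean_sim_curve, lty = 2)
  graphics::lines(z$times, z$observed_curve, lwd = 2)
  graphics::abline(v = z$truncation, lty = 3)
  invisible(result)
}
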