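#' @name evo_models
#' @title Likelihoods for continuous-trait models on chronograms
#'
#' @description
#' Exact log-likelihoods for a univariate trait observed at the tips of a
#' chronogram under four models of evolution:
#'
#' * **BM** — Brownian motion: tips are multivariate normal with mean
#'   `z0` and covariance `sigma2 * C`, `C` the shared-path matrix.
#' * **OU1** — single-peak Ornstein-Uhlenbeck with the root at the optimum
#'   `theta`: covariance `V_ij = sigma2/(2 alpha) * exp(-alpha d_ij) *
#'   (1 - exp(-2 alpha t_ij))` with `t_ij` the shared path length and `d_ij`
#'   the patristic distance; mean `theta` for every tip.
#' * **EB** — early burst: Brownian motion whose rate decays as
#'   `sigma0^2 * exp(r t)`; equivalent to BM on a time-warped tree where the
#'   segment `[t1, t2]` contributes `sigma0^2 (exp(r t2) - exp(r t1))/r`.
#' * **Hansen** — multi-regime OU: same covariance as OU1, but each tip's
#'   expectation is a weighted mix of the regime optima, the weight of
#'   regime k on tip i summing `exp(-alpha (T - t_end)) - exp(-alpha
#'   (T - t_start))` over the segments of the root-to-tip lineage painted
#'   with k, with the root regime additionally receiving `exp(-alpha T)`
#'   (the root state is the root regime's optimum). Weights sum to 1 per
#'   tip.
#'
#' The OU and Hansen likelihoods require an ultrametric tree (contemporaneous
#' tips). Trait vectors may be named, in which case they are matched to tip
#' labels.
NULL

# ---- regime paintings -----------------------------------------------------

#' Paint adaptive regimes onto the branches of a tree
#'
#' A painting assigns one regime to every branch (edge) and to the root. A
#' shift placed on a branch takes effect at the branch's rootward end and is
#' inherited by the whole subtree until overridden by a later shift — the
#' standard convention of stepwise regime searches.
#'
#' @param tree A `"phylo"` tree.
#' @param shifts Named integer vector: names are edge indices (rows of
#'   `tree$edge`, as characters), values are regime ids. May be empty.
#' @param root_regime Regime id at the root (default 1).
#' @return A list of class `"regime_painting"`: `edge_regime` (integer per
#'   edge), `root_regime`, `shifts`, `n_regimes`.
#' @export
regime_painting <- function(tree, shifts = integer(0), root_regime = 1L) {
  ne <- nrow(tree$edge)
  shift_edges <- as.integer(names(shifts))
  if (length(shift_edges) && (any(shift_edges < 1L) || any(shift_edges > ne))) {
    stop("shift edge index out of range")
  }
  edge_regime <- integer(ne)
  # preorder propagation: ape edge table from read/simulated trees is in
  # preorder (parents precede children); enforce by ordering on parent height
  ord <- order(ape::node.depth.edgelength(tree)[tree$edge[, 1L]])
  parent_edge <- integer(max(tree$edge))
  for (e in seq_len(ne)) parent_edge[tree$edge[e, 2L]] <- e
  root <- ape::Ntip(tree) + 1L
  for (e in ord) {
    hit <- match(e, shift_edges)
    if (!is.na(hit)) {
      edge_regime[e] <- as.integer(shifts[hit])
    } else {
      p <- tree$edge[e, 1L]
      edge_regime[e] <- if (p == root) root_regime else edge_regime[parent_edge[p]]
    }
  }
  ids <- sort(unique(c(root_regime, edge_regime)))
  structure(list(edge_regime = edge_regime,
                 root_regime = as.integer(root_regime),
                 shifts = shifts,
                 n_regimes = length(ids), regime_ids = ids),
            class = "regime_painting")
}

# Relabel regimes to 1..m contiguously (root regime keeps lowest id order).
.canonical_painting <- function(painting) {
  ids <- sort(unique(c(painting$root_regime, painting$edge_regime)))
  map <- stats::setNames(seq_along(ids), ids)
  painting$edge_regime <- as.integer(map[as.character(painting$edge_regime)])
  painting$root_regime <- as.integer(map[as.character(painting$root_regime)])
  if (length(painting$shifts)) {
    painting$shifts <- stats::setNames(
      as.integer(map[as.character(painting$shifts)]), names(painting$shifts))
  }
  painting$n_regimes <- length(ids)
  painting$regime_ids <- seq_along(ids)
  painting
}

# Hansen regime-weight matrix: n tips x m regimes, rows sum to 1.
.hansen_weights <- function(cache, painting, alpha) {
  n <- cache$n
  m <- painting$n_regimes
  W <- matrix(0, n, m)
  Tm <- cache$T
  h0 <- cache$edge_h0
  h1 <- cache$edge_h1
  for (i in seq_len(n)) {
    path <- cache$tip_paths[[i]]
    k <- painting$edge_regime[path]
    w <- exp(-alpha * (Tm - h1[path])) - exp(-alpha * (Tm - h0[path]))
    for (s in seq_along(path)) W[i, k[s]] <- W[i, k[s]] + w[s]
  }
  W[, painting$root_regime] <- W[, painting$root_regime] + exp(-alpha * Tm)
  W
}

# OU covariance with unit sigma2 (root conditioned at the optimum).
.ou_cov_unit <- function(cache, alpha) {
  exp(-alpha * cache$D) * (1 - exp(-2 * alpha * cache$C)) / (2 * alpha)
}

# EB-warped shared-path matrix with unit sigma0^2.
.eb_cov_unit <- function(cache, r) {
  if (r == 0) return(cache$C)
  (exp(r * cache$C) - 1) / r
}

# MVN log density via Cholesky.
.mvn_loglik <- function(x, mu, V) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) stop("model covariance matrix is not positive definite")
  z <- backsolve(R, x - mu, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

.assert_ultrametric <- function(tree, what) {
  if (!is_ultrametric(tree)) {
    stop(what, " requires an ultrametric tree (contemporaneous tips)")
  }
}

#' Brownian-motion log-likelihood
#'
#' @param x Named (or tree-ordered) numeric vector of tip values.
#' @param tree A `"phylo"` chronogram.
#' @param sigma2 Diffusion rate (> 0), trait units squared per unit time.
#' @param z0 Root state.
#' @return Log-likelihood (scalar).
#' @rdname evo_models
#' @export
bm_loglik <- function(x, tree, sigma2, z0) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  cache <- .tree_cache(tree)
  x <- .match_tips(x, cache$tips)
  .mvn_loglik(x, rep(z0, cache$n), sigma2 * cache$C)
}

#' Single-peak Ornstein-Uhlenbeck log-likelihood
#'
#' @param alpha Selection strength (> 0), per unit time.
#' @param theta Optimum (also the root state).
#' @rdname evo_models
#' @export
ou1_loglik <- function(x, tree, alpha, sigma2, theta) {
  if (alpha <= 0) stop("alpha must be positive")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  .assert_ultrametric(tree, "ou1_loglik")
  cache <- .tree_cache(tree)
  x <- .match_tips(x, cache$tips)
  V <- sigma2 * .ou_cov_unit(cache, alpha)
  .mvn_loglik(x, rep(theta, cache$n), V)
}

#' Early-burst log-likelihood
#'
#' @param sigma0_2 Initial diffusion rate (> 0).
#' @param r Exponential rate-change parameter; `r = 0` recovers BM exactly,
#'   `r < 0` is an early burst.
#' @rdname evo_models
#' @export
eb_loglik <- function(x, tree, sigma0_2, r, z0) {
  if (sigma0_2 <= 0) stop("sigma0_2 must be positive")
  cache <- .tree_cache(tree)
  x <- .match_tips(x, cache$tips)
  .mvn_loglik(x, rep(z0, cache$n), sigma0_2 * .eb_cov_unit(cache, r))
}

#' Multi-regime Hansen log-likelihood
#'
#' @param painting A `"regime_painting"` for `tree`.
#' @param theta Numeric vector of optima, one per regime id.
#' @rdname evo_models
#' @export
hansen_loglik <- function(x, tree, painting, alpha, sigma2, theta) {
  if (alpha <= 0) stop("alpha must be positive")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  .assert_ultrametric(tree, "hansen_loglik")
  painting <- .canonical_painting(painting)
  if (length(theta) != painting$n_regimes) {
    stop("theta must have one optimum per regime (", painting$n_regimes, ")")
  }
  present <- unique(c(painting$root_regime, painting$edge_regime))
  if (length(present) != painting$n_regimes) {
    stop("painting has a regime with no painted branch")
  }
  cache <- .tree_cache(tree)
  x <- .match_tips(x, cache$tips)
  W <- .hansen_weights(cache, painting, alpha)
  V <- sigma2 * .ou_cov_unit(cache, alpha)
  .mvn_loglik(x, drop(W %*% theta), V)
}

# ---- ML fitting -----------------------------------------------------------

# Profile log-likelihood machinery: for a covariance V = sigma2 * V0(shape)
# and mean W %*% theta, both theta and sigma2 have closed-form ML solutions
# given the shape parameter, leaving a 1-D optimisation.
.profile_fit <- function(x, V0, W) {
  n <- length(x)
  R <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  xw <- backsolve(R, x, transpose = TRUE)
  Ww <- backsolve(R, W, transpose = TRUE)
  qr_ <- qr(Ww)
  if (qr_$rank < ncol(W)) return(NULL)
  theta <- qr.coef(qr_, xw)
  resw <- xw - Ww %*% theta
  Q <- sum(resw^2)
  if (Q <= 0) return(NULL)
  sigma2 <- Q / n
  logdet <- 2 * sum(log(diag(R)))
  ll <- -0.5 * n * (log(2 * pi) + log(sigma2) + 1) - 0.5 * logdet
  list(loglik = ll, sigma2 = sigma2, theta = drop(theta))
}

# Deterministic 1-D search: optimise over `grid`-split subintervals of
# [lo, hi] and return the best optimum found.
.optimise_1d <- function(f, lo, hi, n_intervals = 5L, tol = 1e-8) {
  cuts <- seq(lo, hi, length.out = n_intervals + 1L)
  best <- NULL
  for (i in seq_len(n_intervals)) {
    opt <- stats::optimize(f, lower = cuts[i], upper = cuts[i + 1L],
                           maximum = TRUE, tol = tol)
    if (is.null(best) || opt$objective > best$objective) best <- opt
  }
  best
}

#' Fit a trait-evolution model by maximum likelihood
#'
#' Fits BM, OU1, EB, or a multi-regime Hansen model to tip values on a
#' chronogram. Location parameters (`z0` or the optima) and the rate `sigma2`
#' are profiled out analytically by GLS conditional on the remaining shape
#' parameter (`alpha` for OU/Hansen on a log scale, `r` for EB), which is
#' optimised by a deterministic bounded 1-D search split over five
#' subintervals, so fits are reproducible without a seed. `sigma2` is the ML
#' (1/n) estimate.
#'
#' Parameter counts for AIC: BM and EB count their rate(s) plus root state
#' (2 and 3); OU1 counts `alpha`, `sigma2`, `theta` (3); a Hansen model with
#' m regimes counts `alpha`, `sigma2` and m optima (2 + m).
#'
#' @param x Named (or tree-ordered) numeric vector of tip values.
#' @param tree A `"phylo"` chronogram.
#' @param kind One of `"BM"`, `"OU1"`, `"EB"`, `"HANSEN"`.
#' @param painting A `"regime_painting"`, required for `kind = "HANSEN"`.
#' @param alpha_range Bounds for `alpha` (OU/Hansen), default `c(1e-8, 1e4)`
#'   appropriate for a unit-height tree.
#' @param r_range Bounds for the EB rate parameter; default lower bound
#'   `log(1e-5)/height` (rate decayed to 1e-5 of its initial value), upper 0.
#' @return A list of class `"evo_fit"`: `kind`, `params` (named list),
#'   `loglik`, `n_params`, `n_obs`, `AIC`, `AICc`, plus the painting for
#'   Hansen fits.
#' @export
fit_model <- function(x, tree, kind = c("BM", "OU1", "EB", "HANSEN"),
                      painting = NULL,
                      alpha_range = c(1e-8, 1e4), r_range = NULL) {
  kind <- match.arg(kind)
  if (ape::Ntip(tree) < 3) stop("need at least 3 tips to fit a model")
  cache <- .tree_cache(tree)
  x <- .match_tips(x, cache$tips)
  n <- cache$n
  one <- matrix(1, n, 1)
  out <- switch(kind,
    BM = {
      pf <- .profile_fit(x, cache$C, one)
      if (is.null(pf)) stop("BM fit failed (degenerate data or tree)")
      list(params = list(sigma2 = pf$sigma2, z0 = unname(pf$theta)),
           loglik = pf$loglik, n_params = 2L)
    },
    OU1 = {
      .assert_ultrametric(tree, "OU1 fitting")
      f <- function(la) {
        pf <- .profile_fit(x, .ou_cov_unit(cache, exp(la)), one)
        if (is.null(pf)) -Inf else pf$loglik
      }
      opt <- .optimise_1d(f, log(alpha_range[1L]), log(alpha_range[2L]))
      if (!is.finite(opt$objective)) {
        stop("OU1 fit failed to converge from all start intervals")
      }
      alpha <- exp(opt$maximum)
      pf <- .profile_fit(x, .ou_cov_unit(cache, alpha), one)
      list(params = list(alpha = alpha, sigma2 = pf$sigma2,
                         theta = unname(pf$theta)),
           loglik = pf$loglik, n_params = 3L)
    },
    EB = {
      if (is.null(r_range)) r_range <- c(log(1e-5) / cache$T, 0)
      f <- function(r) {
        pf <- .profile_fit(x, .eb_cov_unit(cache, r), one)
        if (is.null(pf)) -Inf else pf$loglik
      }
      opt <- .optimise_1d(f, r_range[1L], r_range[2L])
      # the boundary r = 0 (exact BM) is a legitimate optimum; compare
      f0 <- f(0)
      if (f0 >= opt$objective) {
        opt <- list(maximum = 0, objective = f0)
      }
      if (!is.finite(opt$objective)) {
        stop("EB fit failed to converge from all start intervals")
      }
      r <- opt$maximum
      pf <- .profile_fit(x, .eb_cov_unit(cache, r), one)
      list(params = list(sigma0_2 = pf$sigma2, r = r, z0 = unname(pf$theta)),
           loglik = pf$loglik, n_params = 3L)
    },
    HANSEN = {
      if (is.null(painting)) stop("HANSEN fitting requires a painting")
      .assert_ultrametric(tree, "Hansen fitting")
      .fit_hansen_core(x, cache, painting,
                       log_range = log(alpha_range), n_intervals = 5L)
    })
  k <- out$n_params
  aic <- 2 * k - 2 * out$loglik
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
  structure(c(out, list(kind = kind, n_obs = n, AIC = aic, AICc = aicc,
                        data_key = .data_key(x))),
            class = "evo_fit")
}

.data_key <- function(x) paste(format(unname(x), digits = 15), collapse = ",")

# Hansen profile fit over a given log-alpha range (shared by fit_model and
# the regime search, which restricts the range to a window around the
# incumbent's alpha).
.fit_hansen_core <- function(x, cache, painting, log_range, n_intervals = 3L) {
  painting <- .canonical_painting(painting)
  present <- unique(c(painting$root_regime, painting$edge_regime))
  if (length(present) != painting$n_regimes) {
    stop("painting has a regime with no painted branch")
  }
  f <- function(la) {
    a <- exp(la)
    pf <- .profile_fit(x, .ou_cov_unit(cache, a),
                       .hansen_weights(cache, painting, a))
    if (is.null(pf)) -Inf else pf$loglik
  }
  opt <- .optimise_1d(f, log_range[1L], log_range[2L],
                      n_intervals = n_intervals)
  if (!is.finite(opt$objective)) {
    stop("Hansen fit failed to converge from all start intervals")
  }
  alpha <- exp(opt$maximum)
  pf <- .profile_fit(x, .ou_cov_unit(cache, alpha),
                     .hansen_weights(cache, painting, alpha))
  list(params = list(alpha = alpha, sigma2 = pf$sigma2, theta = pf$theta),
       loglik = pf$loglik, n_params = 2L + painting$n_regimes,
       painting = painting)
}

# assemble an "evo_fit" from a core fit result (used by the regime search)
.as_evo_fit <- function(core, kind, x, n) {
  k <- core$n_params
  aic <- 2 * k - 2 * core$loglik
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
  structure(c(core, list(kind = kind, n_obs = n, AIC = aic, AICc = aicc,
                         data_key = .data_key(x))),
            class = "evo_fit")
}

#' @export
print.evo_fit <- function(x, ...) {
  cat(x$kind, "fit: logL =", format(x$loglik, digits = 6),
      " AIC =", format(x$AIC, digits = 6),
      " AICc =", format(x$AICc, digits = 6), "\n")
  p <- x$params
  cat("  ", paste(names(p), sapply(p, function(v)
    paste(format(v, digits = 4), collapse = "/")),
    sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Model-comparison table (AIC, delta-AIC, Akaike weights)
#'
#' @param fits A named list of `"evo_fit"` objects fitted to identical data.
#' @param criterion `"AIC"` (default) or `"AICc"`.
#' @return A data frame with one row per model: `n_params`, `loglik`, `AIC`,
#'   `AICc`, `dAIC`, `wAIC`, sorted as given. The best model is the minimum
#'   of the chosen criterion, ties broken toward fewer parameters.
#' @export
aic_table <- function(fits, criterion = c("AIC", "AICc")) {
  criterion <- match.arg(criterion)
  if (length(fits) < 2) stop("need at least two fits to compare")
  keys <- vapply(fits, function(f) f$data_key, "")
  if (length(unique(keys)) != 1L) {
    stop("fits were not computed on identical data")
  }
  crit <- vapply(fits, function(f) f[[criterion]], 0)
  k <- vapply(fits, function(f) f$n_params, 0L)
  best <- order(crit, k)[1L]
  d <- crit - crit[best]
  w <- exp(-d / 2)
  w <- w / sum(w)
  nm <- names(fits)
  if (is.null(nm)) nm <- vapply(fits, function(f) f$kind, "")
  data.frame(model = nm, n_params = k,
             loglik = vapply(fits, function(f) f$loglik, 0),
             AIC = vapply(fits, function(f) f$AIC, 0),
             AICc = vapply(fits, function(f) f$AICc, 0),
             dAIC = d, wAIC = w, row.names = NULL)
}
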