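#' @name surface_search
#' @title Stepwise adaptive-peak (SURFACE-style) regime search
#'
#' @description
#' Searches for the placement of adaptive-peak regime shifts on a chronogram
#' without a priori hypotheses, in two phases. The *forward* phase starts
#' from a single-regime OU model and repeatedly adds the regime shift (on
#' any branch not already carrying one) that most improves AICc, stopping
#' when no candidate improves it. The *backward* phase then repeatedly
#' merges the pair of regimes whose collapse most improves AICc, detecting
#' convergent evolution toward shared peaks. Candidate models are Hansen
#' fits via [fit_model()], so each step is a full deterministic profile fit.
#'
#' Summary statistics of the final model follow the standard definitions:
#' `k` — regimes after the forward phase; `k_prime` — distinct regimes after
#' collapse; `c` — number of shifts toward convergent regimes (regimes with
#' at least two origins, the root counting as an origin); `k_prime_conv` —
#' number of convergent regimes; `delta_k = k - k_prime`; and `c_over_k`.
NULL

# height of the rootward end of each edge plus smallest tip label of its
# subtree: the deterministic tie-break for candidate shifts.
.edge_tiebreak <- function(cache) {
  ne <- cache$n_edge
  min_tip <- character(ne)
  # subtree tip sets, computed once
  tips_below <- vector("list", cache$n + cache$tree$Nnode)
  ord <- order(cache$heights[cache$edge[, 1L]], decreasing = TRUE)
  for (i in seq_len(cache$n)) tips_below[[i]] <- cache$tips[i]
  for (e in ord) {   # postorder-ish: deepest parents first
    p <- cache$edge[e, 1L]; ch <- cache$edge[e, 2L]
    tips_below[[p]] <- c(tips_below[[p]], tips_below[[ch]])
  }
  for (e in seq_len(ne)) {
    min_tip[e] <- min(tips_below[[cache$edge[e, 2L]]])
  }
  list(root_h = cache$edge_h0, min_tip = min_tip)
}

.surface_stats <- function(k_forward, painting) {
  origins <- c(painting$root_regime, unname(painting$shifts))
  tab <- table(origins)
  convergent <- as.integer(names(tab)[tab >= 2L])
  k_prime <- length(unique(origins))
  c_shifts <- sum(unname(painting$shifts) %in% convergent)
  list(k = k_forward, k_prime = k_prime, c = c_shifts,
       k_prime_conv = length(convergent),
       delta_k = k_forward - k_prime,
       c_over_k = if (k_forward > 0) c_shifts / k_forward else 0)
}

# score a painting by GLS at a fixed alpha, given the precomputed Cholesky
# pieces of that alpha's unit-rate OU covariance: returns AICc (or Inf).
.score_at_alpha <- function(cache, painting, alpha, R, xw, logdet, n) {
  W <- .hansen_weights(cache, painting, alpha)
  Ww <- backsolve(R, W, transpose = TRUE)
  qr_ <- qr(Ww)
  if (qr_$rank < ncol(W)) return(Inf)
  resw <- xw - Ww %*% qr.coef(qr_, xw)
  Q <- sum(resw^2)
  if (Q <= 0) return(Inf)
  ll <- -0.5 * n * (log(2 * pi) + log(Q / n) + 1) - 0.5 * logdet
  .search_aicc(ll, painting$n_regimes, n, cache$n_edge)
}

# Search criterion: AICc over the model parameters (alpha, sigma2, m
# optima) plus a placement term charging each of the m - 1 shifts
# 2 log(#branches) -- the code length of its estimated location. Without
# it the criterion ignores that every step selects the best of ~2n - 2
# candidate branches and accepts spurious shifts freely.
.search_aicc <- function(loglik, m, n, n_edges) {
  k <- 2L + m
  if (n - k - 1 <= 0) return(Inf)
  2 * k - 2 * loglik + 2 * k * (k + 1) / (n - k - 1) +
    2 * (m - 1L) * log(n_edges)
}

# full profile refit of a candidate painting over the standard alpha range
.refit_full <- function(x, cache, painting,
                        alpha_range = c(1e-8, 1e4)) {
  core <- .fit_hansen_core(x, cache, painting,
                           log_range = log(alpha_range), n_intervals = 5L)
  .as_evo_fit(core, "HANSEN", x, cache$n)
}

#' Forward phase: stepwise addition of regime shifts
#'
#' @param x Named (or tree-ordered) numeric tip values.
#' @param tree An ultrametric `"phylo"` chronogram (>= 4 tips).
#' @param threshold Minimum AICc improvement to accept a step (default 0:
#'   any improvement counts).
#' @param max_regimes Safety cap on the number of regimes.
#' @param n_refit Number of top-scoring candidates per step refit with the
#'   full alpha profile; remaining candidates are screened by a fast GLS
#'   score at the incumbent's alpha (warm-start convention).
#' @return A list of class `"surface_model"` (pre-collapse): `painting`,
#'   `fit`, `history` (data frame of accepted steps), `stats` (k only, the
#'   backward statistics are filled by [surface_backward()]).
#' @rdname surface_search
#' @export
surface_forward <- function(x, tree, threshold = 0, max_regimes = Inf,
                            n_refit = 5L) {
  if (ape::Ntip(tree) < 4) stop("need at least 4 tips for a regime search")
  .assert_ultrametric(tree, "surface search")
  cache <- .tree_cache(tree)
  x <- .match_tips(x, cache$tips)
  n <- cache$n
  tb <- .edge_tiebreak(cache)
  shifts <- stats::setNames(integer(0), character(0))
  incumbent <- fit_model(x, tree, "OU1")
  alpha_inc <- incumbent$params$alpha
  incumbent_painting <- regime_painting(tree)
  crit_inc <- .search_aicc(incumbent$loglik, 1L, n, cache$n_edge)
  history <- data.frame(step = 0L, action = "start",
                        edge = NA_integer_, regime = 1L,
                        AICc = crit_inc, stringsAsFactors = FALSE)
  next_id <- 2L
  repeat {
    if (length(unique(c(1L, shifts))) >= max_regimes) break
    candidates <- setdiff(seq_len(cache$n_edge), as.integer(names(shifts)))
    V0 <- .ou_cov_unit(cache, alpha_inc)
    R <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(R)) break
    xw <- backsolve(R, x, transpose = TRUE)
    logdet <- 2 * sum(log(diag(R)))
    scores <- rep(Inf, length(candidates))
    for (i in seq_along(candidates)) {
      e <- candidates[i]
      sh <- c(shifts, stats::setNames(next_id, as.character(e)))
      scores[i] <- .score_at_alpha(cache, regime_painting(tree, sh),
                                   alpha_inc, R, xw, logdet, n)
    }
    # candidates are prefiltered at the incumbent alpha (warm-start scores),
    # then the most promising few are refit with the full alpha profile and
    # the refit criterion decides; the incumbent's OU1 alpha can sit near 0
    # on shifted data, so the first-step scores alone would miss real shifts
    top <- candidates[order(scores)[seq_len(min(n_refit, length(candidates)))]]
    top <- top[is.finite(scores[order(scores)][seq_along(top)])]
    best <- NULL
    for (e in top) {
      sh <- c(shifts, stats::setNames(next_id, as.character(e)))
      p <- regime_painting(tree, sh)
      refit <- tryCatch(.refit_full(x, cache, p), error = function(err) NULL)
      if (is.null(refit)) next
      crit <- .search_aicc(refit$loglik, refit$painting$n_regimes, n,
                           cache$n_edge)
      if (is.null(best) || crit < best$crit - 1e-12 ||
          (abs(crit - best$crit) <= 1e-12 && .prefer_edge(e, best$edge, tb))) {
        best <- list(edge = e, crit = crit, fit = refit, shifts = sh)
      }
    }
    if (is.null(best) || best$crit >= crit_inc - threshold) break
    shifts <- best$shifts
    incumbent <- best$fit
    crit_inc <- best$crit
    alpha_inc <- incumbent$params$alpha
    incumbent_painting <- incumbent$painting
    history <- rbind(history, data.frame(
      step = nrow(history), action = "add_shift", edge = best$edge,
      regime = next_id, AICc = crit_inc, stringsAsFactors = FALSE))
    next_id <- next_id + 1L
  }
  k <- length(unique(c(incumbent_painting$root_regime,
                       incumbent_painting$edge_regime)))
  structure(list(painting = incumbent_painting, fit = incumbent,
                 history = history, stats = list(k = k), x = x,
                 phase = "forward"),
            class = "surface_model")
}

# TRUE when edge a is preferred over incumbent edge b on ties: closer to the
# root, then lexicographically smallest subtree tip label.
.prefer_edge <- function(a, b, tb) {
  if (is.null(b)) return(TRUE)
  if (tb$root_h[a] != tb$root_h[b]) return(tb$root_h[a] < tb$root_h[b])
  tb$min_tip[a] < tb$min_tip[b]
}

#' Backward phase: collapse of similar regimes
#'
#' @param model A `"surface_model"` from [surface_forward()].
#' @rdname surface_search
#' @export
surface_backward <- function(model, x, tree, threshold = 0,
                             n_refit = 5L) {
  stopifnot(inherits(model, "surface_model"))
  cache <- .tree_cache(tree)
  x <- .match_tips(x, cache$tips)
  n <- cache$n
  painting <- model$painting
  incumbent <- model$fit
  alpha_inc <- incumbent$params$alpha
  m_inc <- length(unique(c(painting$root_regime, painting$edge_regime)))
  crit_inc <- .search_aicc(incumbent$loglik, m_inc, n, cache$n_edge)
  history <- model$history
  repeat {
    ids <- sort(unique(c(painting$root_regime, painting$edge_regime)))
    if (length(ids) < 2L) break
    pairs <- utils::combn(ids, 2L)
    V0 <- .ou_cov_unit(cache, alpha_inc)
    R <- tryCatch(chol(V0), error = function(e) NULL)
    if (is.null(R)) break
    xw <- backsolve(R, x, transpose = TRUE)
    logdet <- 2 * sum(log(diag(R)))
    merges <- vector("list", ncol(pairs))
    mscores <- rep(Inf, ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1L, j]; b <- pairs[2L, j]   # merge b into a (a < b)
      p2 <- painting
      p2$edge_regime[p2$edge_regime == b] <- a
      if (p2$root_regime == b) p2$root_regime <- a
      if (length(p2$shifts)) p2$shifts[p2$shifts == b] <- a
      # drop shifts that no longer change the regime (shift into the regime
      # already active on the parent edge) -- they are pure relabelling
      p2$shifts <- .drop_null_shifts(tree, p2)
      p2c <- regime_painting(tree, p2$shifts, p2$root_regime)
      merges[[j]] <- list(a = a, b = b, painting = p2c)
      mscores[j] <- .score_at_alpha(cache, .canonical_painting(p2c),
                                    alpha_inc, R, xw, logdet, n)
    }
    best <- NULL
    for (j in order(mscores)[seq_len(min(n_refit, length(mscores)))]) {
      if (!is.finite(mscores[j])) next
      mg <- merges[[j]]
      refit <- tryCatch(.refit_full(x, cache, mg$painting),
                        error = function(err) NULL)
      if (is.null(refit)) next
      crit <- .search_aicc(refit$loglik, refit$painting$n_regimes, n,
                           cache$n_edge)
      if (is.null(best) || crit < best$crit - 1e-12 ||
          (abs(crit - best$crit) <= 1e-12 &&
           (mg$a < best$a || (mg$a == best$a && mg$b < best$b)))) {
        best <- list(a = mg$a, b = mg$b, crit = crit, fit = refit,
                     painting = mg$painting)
      }
    }
    if (is.null(best) || best$crit >= crit_inc - threshold) break
    painting <- best$painting
    incumbent <- best$fit
    crit_inc <- best$crit
    alpha_inc <- incumbent$params$alpha
    history <- rbind(history, data.frame(
      step = nrow(history), action = "collapse",
      edge = NA_integer_, regime = best$a,
      AICc = crit_inc, stringsAsFactors = FALSE))
  }
  stats <- .surface_stats(model$stats$k, painting)
  structure(list(painting = painting, fit = incumbent, history = history,
                 stats = stats, x = x, phase = "backward"),
            class = "surface_model")
}

# After a merge, a shift whose regime equals its parent's regime is inert:
# remove it so that regime-origin counting reflects real shifts.
.drop_null_shifts <- function(tree, painting) {
  sh <- painting$shifts
  if (!length(sh)) return(sh)
  repeat {
    p <- regime_painting(tree, sh, painting$root_regime)
    parent_edge <- integer(max(tree$edge))
    for (e in seq_len(nrow(tree$edge))) parent_edge[tree$edge[e, 2L]] <- e
    root <- ape::Ntip(tree) + 1L
    inert <- vapply(seq_along(sh), function(i) {
      e <- as.integer(names(sh)[i])
      pn <- tree$edge[e, 1L]
      parent_reg <- if (pn == root) p$root_regime else
        p$edge_regime[parent_edge[pn]]
      sh[i] == parent_reg
    }, logical(1))
    if (!any(inert)) return(sh)
    sh <- sh[!inert]
  }
}

#' Run the full forward + backward regime search
#'
#' @rdname surface_search
#' @export
run_surface <- function(x, tree, threshold = 0, max_regimes = Inf,
                        n_refit = 5L) {
  fwd <- surface_forward(x, tree, threshold = threshold,
                         max_regimes = max_regimes, n_refit = n_refit)
  surface_backward(fwd, x, tree, threshold = threshold, n_refit = n_refit)
}

#' @export
print.surface_model <- function(x, ...) {
  s <- x$stats
  cat("Regime search (", x$phase, " phase complete): ", sep = "")
  if (!is.null(s$k_prime)) {
    cat(sprintf("k = %d, k' = %d, c = %d, k'_conv = %d, dk = %d, c/k = %.2f\n",
                s$k, s$k_prime, s$c, s$k_prime_conv, s$delta_k, s$c_over_k))
  } else {
    cat("k =", s$k, "\n")
  }
  cat("Final Hansen AICc:", format(x$fit$AICc, digits = 6), "\n")
  invisible(x)
}

#' Brownian-motion null distribution for regime-search statistics
#'
#' Tests whether the peak structure recovered from the observed data could
#' have arisen under a random walk: the BM model is fitted to the observed
#' tips, `n_sim` datasets are simulated from that fit, the full
#' forward/backward search is run on each, and each statistic's one-sided P
#' is the proportion of simulations producing a value at least as large as
#' observed.
#'
#' @param x Named (or tree-ordered) numeric tip values.
#' @param tree An ultrametric `"phylo"` chronogram.
#' @param n_sim Number of BM simulations (default 500).
#' @param seed Integer seed.
#' @param observed A completed `"surface_model"` for `x` (computed if
#'   omitted).
#' @param threshold Passed to the search.
#' @return A list of class `"peak_null"`: `observed` (named statistics),
#'   `null_mean`, `null_sd`, `P`, `n_sim`, `n_failed`, `seed`, and the
#'   per-simulation statistics matrix `sims`.
#' @export
bm_null_peaks <- function(x, tree, n_sim = 500, seed = 1, observed = NULL,
                          threshold = 0) {
  cache <- .tree_cache(tree)
  x <- .match_tips(x, cache$tips)
  if (is.null(observed)) observed <- run_surface(x, tree, threshold = threshold)
  bm <- fit_model(x, tree, "BM")
  sims <- simulate_traits(tree, model = "BM",
                          params = list(sigma2 = bm$params$sigma2,
                                        z0 = bm$params$z0),
                          n_replicates = n_sim, seed = seed)
  stat_names <- c("k", "k_prime", "c", "k_prime_conv", "delta_k", "c_over_k")
  out <- matrix(NA_real_, n_sim, length(stat_names),
                dimnames = list(NULL, stat_names))
  n_failed <- 0L
  for (r in seq_len(n_sim)) {
    res <- tryCatch(run_surface(sims[r, ], tree, threshold = threshold),
                    error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    out[r, ] <- unlist(res$stats)[stat_names]
  }
  if (n_failed > 0.05 * n_sim) {
    stop("more than 5% of null simulations failed (", n_failed, "/", n_sim, ")")
  }
  obs <- unlist(observed$stats)[stat_names]
  ok <- stats::complete.cases(out)
  P <- colMeans(out[ok, , drop = FALSE] >=
                  matrix(obs, sum(ok), length(obs), byrow = TRUE))
  structure(list(observed = obs,
                 null_mean = colMeans(out[ok, , drop = FALSE]),
                 null_sd = apply(out[ok, , drop = FALSE], 2L, stats::sd),
                 P = P, n_sim = n_sim, n_failed = n_failed, seed = seed,
                 sims = out),
            class = "peak_null")
}

#' @export
print.peak_null <- function(x, ...) {
  cat("BM null for regime-search statistics (", x$n_sim, " simulations)\n",
      sep = "")
  tab <- data.frame(observed = x$observed,
                    null_mean = round(x$null_mean, 2),
                    null_sd = round(x$null_sd, 2), P = x$P)
  print(tab)
  invisible(x)
}
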