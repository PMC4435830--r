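#' Simulate univariate trait evolution on a chronogram
#'
#' Exact (transition-density) simulation in preorder down the tree: no time
#' discretisation, so results are correct at any branch length.
#'
#' * `BM`: child ~ Normal(parent, `sigma2 * t`); root value `z0`.
#' * `OU1` / `HANSEN`: along a branch segment of length `t` in regime k,
#'   child ~ Normal(`theta_k + (parent - theta_k) exp(-alpha t)`,
#'   `sigma2 (1 - exp(-2 alpha t)) / (2 alpha)`); the root starts at the
#'   root regime's optimum.
#' * `EB`: BM on the time-warped branch, a segment `[t1, t2]` contributing
#'   variance `sigma0_2 (exp(r t2) - exp(r t1)) / r` (`r = 0` is BM).
#'
#' Each replicate uses its own RNG substream derived from `seed` and the
#' replicate index, so replicate r is reproducible independently of
#' `n_replicates`.
#'
#' @param tree A `"phylo"` chronogram.
#' @param model One of `"BM"`, `"OU1"`, `"EB"`, `"HANSEN"`.
#' @param params Named list of parameters: BM `sigma2, z0`; OU1
#'   `alpha, sigma2, theta`; EB `sigma0_2, r, z0`; HANSEN
#'   `alpha, sigma2, theta` (vector of optima per regime).
#' @param painting A `"regime_painting"` (HANSEN only).
#' @param n_replicates Number of replicate datasets.
#' @param seed Integer seed.
#' @return An `n_replicates` x `Ntip` matrix, columns named by tip label.
#' @export
simulate_traits <- function(tree, model = c("BM", "OU1", "EB", "HANSEN"),
                            params, painting = NULL, n_replicates = 1,
                            seed = 1) {
  model <- match.arg(model)
  .validate_sim_params(model, params)
  if (model == "HANSEN") {
    if (is.null(painting)) stop("HANSEN simulation requires a painting")
    painting <- .canonical_painting(painting)
    if (length(params$theta) != painting$n_regimes) {
      stop("theta must have one optimum per regime")
    }
  }
  if (model == "OU1") {
    # one-regime Hansen; uniform code path
    painting <- regime_painting(tree)
    params$theta <- params$theta[1L]
  }
  cache <- .tree_cache(tree)
  n <- cache$n
  ne <- cache$n_edge
  ord <- order(cache$edge_h0)      # preorder: parents before children
  out <- matrix(NA_real_, n_replicates, n,
                dimnames = list(NULL, cache$tips))
  nodes_total <- n + tree$Nnode
  for (r in seq_len(n_replicates)) {
    set.seed(.substream_seed(seed, r))
    state <- numeric(nodes_total)
    state[cache$root] <- switch(model,
      BM = params$z0, EB = params$z0,
      OU1 = , HANSEN = params$theta[painting$root_regime])
    eps <- stats::rnorm(ne)        # one draw per edge, in preorder
    for (idx in seq_len(ne)) {
      e <- ord[idx]
      p <- cache$edge[e, 1L]; ch <- cache$edge[e, 2L]
      t <- cache$edge_h1[e] - cache$edge_h0[e]
      state[ch] <- switch(model,
        BM = state[p] + eps[idx] * sqrt(params$sigma2 * t),
        EB = {
          wt <- if (params$r == 0) t else
            (exp(params$r * cache$edge_h1[e]) -
               exp(params$r * cache$edge_h0[e])) / params$r
          state[p] + eps[idx] * sqrt(params$sigma0_2 * wt)
        },
        OU1 = , HANSEN = {
          th <- params$theta[painting$edge_regime[e]]
          a <- params$alpha
          m <- th + (state[p] - th) * exp(-a * t)
          v <- params$sigma2 * (1 - exp(-2 * a * t)) / (2 * a)
          m + eps[idx] * sqrt(v)
        })
    }
    out[r, ] <- state[seq_len(n)]
  }
  out
}

# deterministic per-replicate substream seed (kept below 2^31)
.substream_seed <- function(seed, r) {
  as.integer((1664525 * ((as.numeric(seed) + r) %% 65536) + 1013904223) %%
               2147483647)
}

.validate_sim_params <- function(model, params) {
  need <- switch(model,
    BM = c("sigma2", "z0"), OU1 = c("alpha", "sigma2", "theta"),
    EB = c("sigma0_2", "r", "z0"), HANSEN = c("alpha", "sigma2", "theta"))
  missing <- setdiff(need, names(params))
  if (length(missing)) stop("missing parameters: ",
                            paste(missing, collapse = ", "))
  if (model %in% c("OU1", "HANSEN") && params$alpha <= 0) {
    stop("alpha must be positive")
  }
  rate <- if (model == "EB") params$sigma0_2 else params$sigma2
  if (rate < 0) stop("rate parameter must be non-negative")
  invisible(TRUE)
}
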