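#' Log-transform specimen measurements and collapse to species means
#'
#' Applies a natural-log transform to every measurement, then averages within
#' species and variable. Log transformation puts linear and area measurements
#' on comparable multiplicative scales before any downstream analysis.
#'
#' @param specimens A data frame of specimen-level measurements, either long
#'   (columns `species`, `specimen_id`, `variable`, `value`) or wide (column
#'   `species`, optional `specimen_id`, one column per variable).
#' @param log_base Base of the logarithm; `exp(1)` (natural log, the default)
#'   or any positive base.
#' @return A numeric matrix of species (rows, sorted) by variables (columns)
#'   of mean log measurements, of class `"trait_table"`.
#' @export
log_species_means <- function(specimens, log_base = exp(1)) {
  specimens <- as.data.frame(specimens)
  if (!"species" %in% names(specimens)) stop("need a 'species' column")
  long <- if (all(c("variable", "value") %in% names(specimens))) {
    specimens[, c("species", "variable", "value")]
  } else {
    vars <- setdiff(names(specimens), c("species", "specimen_id"))
    if (!length(vars)) stop("no measurement columns found")
    data.frame(
      species = rep(specimens$species, times = length(vars)),
      variable = rep(vars, each = nrow(specimens)),
      value = unlist(specimens[vars], use.names = FALSE)
    )
  }
  bad <- which(!is.finite(long$value) | long$value <= 0)
  if (length(bad)) {
    b <- bad[1L]
    stop(sprintf(
      "non-positive or missing measurement for species '%s', variable '%s'",
      long$species[b], long$variable[b]))
  }
  long$value <- log(long$value, base = log_base)
  species <- sort(unique(as.character(long$species)))
  vars <- unique(as.character(long$variable))
  out <- matrix(NA_real_, length(species), length(vars),
                dimnames = list(species, vars))
  agg <- tapply(long$value, list(as.character(long$species),
                                 as.character(long$variable)), mean)
  out[] <- agg[species, vars]
  if (anyNA(out)) {
    miss <- which(is.na(out), arr.ind = TRUE)[1L, ]
    stop(sprintf("no measurements for species '%s', variable '%s'",
                 species[miss[1L]], vars[miss[2L]]))
  }
  class(out) <- c("trait_table", "matrix", "array")
  out
}

# GLS regression of y on design X with error covariance proportional to C,
# via the Cholesky factor of C. Returns coefficients, residuals and the
# quadratic form of the residuals.
.gls_fit <- function(y, X, R_chol) {
  # whiten: solve(t(L)) %*% . with C = t(R) %*% R (R upper triangular)
  yw <- backsolve(R_chol, y, transpose = TRUE)
  Xw <- backsolve(R_chol, X, transpose = TRUE)
  qr_ <- qr(Xw)
  if (qr_$rank < ncol(X)) stop("singular design in GLS fit (collinear columns)")
  beta <- qr.coef(qr_, yw)
  fitted <- X %*% beta
  res <- y - fitted
  resw <- yw - Xw %*% beta
  list(beta = drop(beta), residuals = drop(res),
       rss_gls = sum(resw^2))
}

.chol_or_stop <- function(C) {
  out <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(out)) stop("phylogenetic covariance matrix is not positive definite")
  out
}

#' Phylogenetic (GLS) size correction of trait means
#'
#' Regresses each trait column against the designated size variable by
#' generalised least squares with error covariance proportional to the
#' tree's shared-path matrix (Brownian-motion errors), and returns the
#' residuals. This removes allometric scaling while accounting for the
#' non-independence of related species, the standard preliminary to a
#' phylogenetic PCA of shape.
#'
#' @param traits A species-by-variable matrix of (log) trait means, e.g. from
#'   [log_species_means()]; row names are species.
#' @param tree A `"phylo"` chronogram whose tip set equals the trait species
#'   set.
#' @param size_var Name of the size column regressed out (default `"SL"`,
#'   standard length).
#' @return A species-by-variable matrix of residuals (the size variable is
#'   dropped), class `"residual_traits"`, with attributes `coefficients`
#'   (2 x variables: intercept, slope) and `size_var`.
#' @export
phylo_size_correct <- function(traits, tree, size_var = "SL") {
  traits <- as.matrix(traits)
  if (!size_var %in% colnames(traits)) {
    stop("size variable '", size_var, "' not found in trait table")
  }
  if (!setequal(rownames(traits), tree$tip.label)) {
    stop("species in trait table and tree tips differ")
  }
  C <- shared_path_matrix(tree, canonical = TRUE)
  traits <- traits[rownames(C), , drop = FALSE]
  R <- .chol_or_stop(C)
  size <- traits[, size_var]
  X <- cbind(intercept = 1, size = size)
  vars <- setdiff(colnames(traits), size_var)
  res <- matrix(NA_real_, nrow(traits), length(vars),
                dimnames = list(rownames(traits), vars))
  coefs <- matrix(NA_real_, 2L, length(vars),
                  dimnames = list(c("intercept", "slope"), vars))
  for (v in vars) {
    fit <- .gls_fit(traits[, v], X, R)
    res[, v] <- fit$residuals
    coefs[, v] <- fit$beta
  }
  structure(res, class = c("residual_traits", "matrix", "array"),
            coefficients = coefs, size_var = size_var)
}
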