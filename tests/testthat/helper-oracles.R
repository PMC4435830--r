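# Independent brute-force oracles used across the suite. These deliberately
# use dense solve()/determinant() linear algebra, not the package's
# Cholesky/profile code paths.

# dense multivariate-normal log density
mvn_logdens <- function(x, mu, V) {
  n <- length(x)
  d <- x - mu
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(V, logarithm = TRUE)$modulus +
                       t(d) %*% solve(V) %*% d))
}

# dense GLS fit of y on X with covariance C
gls_oracle <- function(y, X, C) {
  Ci <- solve(C)
  beta <- solve(t(X) %*% Ci %*% X) %*% t(X) %*% Ci %*% y
  list(beta = drop(beta), residuals = drop(y - X %*% beta))
}

# OU covariance between contemporaneous tips, built from first principles
ou_cov_oracle <- function(tree, alpha, sigma2) {
  C <- ape::vcv.phylo(tree)
  D <- outer(diag(C), diag(C), "+") - 2 * C
  sigma2 / (2 * alpha) * exp(-alpha * D) * (1 - exp(-2 * alpha * C))
}

# Hansen tip expectations by explicit root-to-tip segment enumeration
hansen_mean_oracle <- function(tree, painting, alpha, theta) {
  n <- ape::Ntip(tree)
  h <- ape::node.depth.edgelength(tree)
  Tm <- max(h[seq_len(n)])
  parent <- integer(max(tree$edge)); pedge <- integer(max(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    pedge[tree$edge[e, 2]] <- e
  }
  pnt <- peakscape:::.canonical_painting(painting)
  mu <- numeric(n)
  for (i in seq_len(n)) {
    node <- i
    w <- numeric(length(theta))
    while (node != n + 1L) {
      e <- pedge[node]
      k <- pnt$edge_regime[e]
      w[k] <- w[k] +
        exp(-alpha * (Tm - h[node])) - exp(-alpha * (Tm - h[parent[node]]))
      node <- parent[node]
    }
    w[pnt$root_regime] <- w[pnt$root_regime] + exp(-alpha * Tm)
    mu[i] <- sum(w * theta)
  }
  stats::setNames(mu, tree$tip.label)
}

# random ultrametric tree of n tips, unit height, with tip labels
rand_unit_tree <- function(n) {
  scale_to_unit_height(ape::rcoal(n))
}

# relative disparity-through-time curve by direct enumeration: for each
# internal node height, find the lineages alive just after it and average
# their subclade disparities (mean squared pairwise distance) over the
# whole-clade disparity
dtt_oracle <- function(x, tree) {
  n <- ape::Ntip(tree)
  h <- ape::node.depth.edgelength(tree)
  Tm <- max(h[seq_len(n)])
  x <- x[tree$tip.label]
  disp <- function(v) if (length(v) < 2) 0 else mean(stats::dist(v)^2)
  total <- disp(x)
  times <- sort(unique(round(h[(n + 1):(n + tree$Nnode)] / Tm, 12)))
  vals <- numeric(length(times))
  vals[1] <- 1
  if (length(times) > 1) for (i in 2:length(times)) {
    t <- times[i]
    cross <- which(h[tree$edge[, 1]] / Tm <= t + 1e-12 &
                     h[tree$edge[, 2]] / Tm > t + 1e-12)
    vals[i] <- mean(vapply(tree$edge[cross, 2], function(nd) {
      tips <- if (nd <= n) tree$tip.label[nd] else
        ape::extract.clade(tree, nd)$tip.label
      disp(x[tips]) / total
    }, 0))
  }
  list(times = times, disparity = vals)
}
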