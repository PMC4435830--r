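#' Read a chronogram from a Newick file or string
#'
#' Thin, validating wrapper around [ape::read.tree()]. The returned tree is a
#' standard `"phylo"` object; all downstream functions in this package take
#' `"phylo"` trees. In addition to parsing, the input is pre-scanned so that
#' malformed Newick is reported with the character offset of the first
#' offending character, and trees without branch lengths are rejected
#' (chronograms carry time, so edge lengths are mandatory).
#'
#' @param source Path to a Newick file, or a Newick string (detected by the
#'   presence of `"("`).
#' @return An object of class `"phylo"` with `edge.length` set.
#' @seealso [prune_to_taxa()], [scale_to_unit_height()], [shared_path_matrix()]
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
read_newick <- function(source) {
  txt <- if (length(source) == 1L && !grepl("(", source, fixed = TRUE) &&
             file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "")
  } else {
    paste(as.character(source), collapse = "")
  }
  .check_newick_syntax(txt)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("failed to parse Newick string")
  }
  if (is.null(tr$edge.length)) {
    stop("tree has no branch lengths; a chronogram requires them")
  }
  if (anyNA(tr$edge.length)) {
    stop("one or more branch lengths are missing (NA)")
  }
  if (any(tr$edge.length < 0)) {
    stop("negative branch lengths are not allowed in a chronogram")
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicated tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

# Pre-scan for the errors ape reports unhelpfully: unbalanced parentheses and
# a missing terminal semicolon, located by character offset.
.check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("malformed Newick: unmatched ')' at character %d", i))
      }
    }
  }
  if (in_quote) stop("malformed Newick: unterminated quoted label")
  if (depth > 0L) {
    stop(sprintf(
      "malformed Newick: %d unclosed '(' (input ends at character %d)",
      depth, length(chars)))
  }
  if (!grepl(";", txt, fixed = TRUE)) {
    stop(sprintf("malformed Newick: missing ';' (input ends at character %d)",
                 nchar(txt)))
  }
  invisible(TRUE)
}

#' Write a tree to Newick
#'
#' @param tree A `"phylo"` tree.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Tree height (maximum root-to-tip distance)
#'
#' Includes the root edge, when one is present (e.g. after pruning).
#'
#' @param tree A `"phylo"` tree with branch lengths.
#' @return Numeric scalar.
#' @export
tree_height <- function(tree) {
  h <- max(ape::node.depth.edgelength(tree))
  if (!is.null(tree$root.edge)) h <- h + tree$root.edge
  h
}

#' Check that a tree is ultrametric (contemporaneous tips)
#'
#' All root-to-tip path lengths must agree within `tol * height`. The OU and
#' Hansen likelihoods in this package assume contemporaneous tips and call
#' this check.
#'
#' @param tree A `"phylo"` tree.
#' @param tol Relative tolerance (default `1e-6` of the tree height).
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  h <- max(d)
  if (h == 0) return(FALSE)
  (max(d) - min(d)) <= tol * h
}

#' Prune a chronogram to a set of taxa
#'
#' Retains only the requested tips, suppressing unary internal nodes so that
#' path lengths between retained tips are unchanged. A requested taxon absent
#' from the tree may be supplied through `alias`: a named character vector
#' mapping the requested name to the label of a stand-in tip present in the
#' tree; the stand-in is kept and renamed to the requested name. This mirrors
#' the common practice of substituting a close relative when the exact
#' species in the trait table is missing from the phylogeny.
#'
#' @param tree A `"phylo"` tree.
#' @param keep Character vector of tip labels to retain.
#' @param alias Optional named character vector, `names(alias)` being
#'   requested taxa and values being stand-in tip labels in the tree.
#' @return The pruned `"phylo"` tree.
#' @export
prune_to_taxa <- function(tree, keep, alias = NULL) {
  keep <- as.character(keep)
  resolved <- keep
  if (!is.null(alias)) {
    sub <- !(keep %in% tree$tip.label) & keep %in% names(alias)
    resolved[sub] <- alias[keep[sub]]
  }
  missing <- setdiff(resolved, tree$tip.label)
  if (length(missing)) {
    stop("taxa not in tree (and not resolved by alias): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(resolved)) {
    stop("alias resolution produced duplicate tips: ",
         paste(resolved[duplicated(resolved)], collapse = ", "))
  }
  drop <- setdiff(tree$tip.label, resolved)
  out <- if (length(drop)) {
    pruned <- ape::keep.tip(tree, resolved)
    # keep the stem below the new root as a root edge so that root-to-tip
    # distances of the retained taxa are preserved
    ref <- resolved[1L]
    d_old <- ape::node.depth.edgelength(tree)[match(ref, tree$tip.label)]
    d_new <- ape::node.depth.edgelength(pruned)[match(ref, pruned$tip.label)]
    stem <- d_old - d_new
    if (stem > 1e-12) pruned$root.edge <- stem
    pruned
  } else {
    tree
  }
  # rename stand-ins to the requested taxa
  idx <- match(out$tip.label, resolved)
  out$tip.label <- keep[idx]
  out
}

#' Rescale a chronogram to unit height
#'
#' Divides every branch length by the tree height so that the maximum
#' root-to-tip distance becomes exactly 1. Rescaling makes rate and selection
#' parameters comparable across trees whose absolute depths differ, and puts
#' node times on the same relative \[0, 1\] axis used by disparity-through-time
#' plots.
#'
#' @param tree A `"phylo"` tree with positive height.
#' @return The rescaled `"phylo"` tree.
#' @export
scale_to_unit_height <- function(tree) {
  h <- tree_height(tree)
  if (h <= 0) stop("tree height must be positive to rescale")
  tree$edge.length <- tree$edge.length / h
  tree
}

#' Shared-path (Brownian covariance) matrix of a tree
#'
#' Returns the n-by-n matrix `C` with `C[i, j]` the shared root-to-MRCA path
#' length of tips i and j and `C[i, i]` the root-to-tip distance — the
#' covariance structure of Brownian motion on the tree. Rows and columns
#' follow the canonical (lexicographic) tip order so that matrices are
#' directly comparable across trees with the same tip set.
#'
#' @param tree A `"phylo"` tree with branch lengths.
#' @param canonical Sort tips lexicographically (default `TRUE`); if `FALSE`
#'   the tree's own tip order is kept.
#' @return A symmetric positive semi-definite matrix with dimnames set to the
#'   tip labels.
#' @export
shared_path_matrix <- function(tree, canonical = TRUE) {
  C <- ape::vcv.phylo(tree)
  if (canonical) {
    ord <- order(rownames(C))
    C <- C[ord, ord, drop = FALSE]
  }
  C
}

#' Bundle a posterior set of chronograms with a designated summary tree
#'
#' @param trees A list of `"phylo"` trees or a `"multiPhylo"` object.
#' @param mcc The designated summary (e.g. maximum-clade-credibility) tree;
#'   defaults to the first tree.
#' @return A list of class `"chronogram_set"` with elements `trees`
#'   (`multiPhylo`) and `mcc`.
#' @export
chronogram_set <- function(trees, mcc = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, function(t) {
    stopifnot(inherits(t, "phylo"))
    t
  })
  if (is.null(mcc)) mcc <- trees[[1L]]
  ref <- sort(mcc$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref)) {
      stop("tree ", i, " does not share the tip-label set of the MCC tree")
    }
  }
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, mcc = mcc), class = "chronogram_set")
}

#' @export
print.chronogram_set <- function(x, ...) {
  cat("Chronogram set:", length(x$trees), "trees,",
      ape::Ntip(x$mcc), "tips (plus a designated summary tree)\n")
  invisible(x)
}

# ---- internal tree geometry cache -----------------------------------------
# Everything the likelihoods need, computed once per tree: shared-path matrix
# C (tree tip order), patristic distances D, node heights, per-tip root->tip
# edge paths, and per-edge start/end heights.
.tree_cache <- function(tree) {
  n <- ape::Ntip(tree)
  C <- ape::vcv.phylo(tree)
  hgt <- ape::node.depth.edgelength(tree)   # all nodes, root = 0
  Tmax <- max(hgt[seq_len(n)])
  diagC <- diag(C)
  D <- outer(diagC, diagC, "+") - 2 * C     # patristic distances
  parent <- integer(n + tree$Nnode)
  parent_edge <- integer(n + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2L]
    parent[ch] <- tree$edge[e, 1L]
    parent_edge[ch] <- e
  }
  root <- n + 1L
  tip_paths <- vector("list", n)            # edge indices, root -> tip order
  for (i in seq_len(n)) {
    path <- integer(0)
    node <- i
    while (node != root) {
      path <- c(parent_edge[node], path)
      node <- parent[node]
    }
    tip_paths[[i]] <- path
  }
  list(tree = tree, n = n, tips = tree$tip.label, C = C, D = D,
       heights = hgt, T = Tmax, root = root,
       edge = tree$edge, n_edge = nrow(tree$edge),
       edge_h0 = hgt[tree$edge[, 1L]], edge_h1 = hgt[tree$edge[, 2L]],
       tip_paths = tip_paths)
}

# Reorder a trait vector (or matrix rows) to the tree's tip order, matching
# by name when names are present.
.match_tips <- function(x, tips) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    if (!is.null(rownames(x))) {
      missing <- setdiff(tips, rownames(x))
      if (length(missing)) stop("trait rows missing for tips: ",
                                paste(missing, collapse = ", "))
      x <- x[tips, , drop = FALSE]
    } else if (nrow(x) != length(tips)) {
      stop("unnamed trait matrix with wrong number of rows")
    }
    return(x)
  }
  if (!is.null(names(x))) {
    missing <- setdiff(tips, names(x))
    if (length(missing)) stop("trait values missing for tips: ",
                              paste(missing, collapse = ", "))
    x <- x[tips]
  } else if (length(x) != length(tips)) {
    stop("unnamed trait vector with wrong length")
  }
  x
}
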