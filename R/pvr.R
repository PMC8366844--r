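#' Patristic distance matrix of a phylogeny
#'
#' Pairwise distances between tips: the sum of branch lengths along the
#' unique path connecting each pair of leaves.
#'
#' @param tree A `phylo` object with branch lengths on every edge.
#' @return Symmetric matrix with zero diagonal, rows/columns in
#'   `tree$tip.label` order.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have a branch length on every edge")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Principal coordinates analysis of a distance matrix
#'
#' Gower double-centering of \eqn{-\tfrac12 D^2} followed by a symmetric
#' eigendecomposition. Axes are ordered by descending eigenvalue and scaled
#' so each column's sum of squares equals its eigenvalue; column signs are
#' fixed so the largest-magnitude loading is positive. Relative eigenvalues
#' are taken over the sum of positive eigenvalues only (small negative
#' eigenvalues can arise from round-off and are never retained). Axis
#' retention follows the broken-stick rule (see [broken_stick()]).
#'
#' @param D Symmetric distance matrix with zero diagonal and finite
#'   entries, with row/column names identifying the objects.
#' @return Object of class `pcoa_axes`: `eigenvalues` (descending, all),
#'   `relative_eigenvalues` (positive axes over their sum), `vectors`
#'   (objects x positive axes, columns `PV1`, `PV2`, ...), `retained`
#'   (indices from the broken-stick rule), `cumulative_variance_retained`.
#' @export
pcoa_axes <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || !isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("D must be a symmetric square matrix")
  if (any(!is.finite(D))) stop("D must be finite")
  if (any(abs(diag(D)) > 1e-12)) stop("D must have a zero diagonal")
  n <- nrow(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("obj", seq_len(n))
  A <- -0.5 * D^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  ev <- e$values
  tol <- max(abs(ev)) * 1e-10
  pos <- which(ev > tol)
  if (!length(pos)) stop("no positive eigenvalues; degenerate distances")
  V <- e$vectors[, pos, drop = FALSE]
  scores <- sweep(V, 2, sqrt(ev[pos]), `*`)
  ## deterministic sign: largest-magnitude loading positive per column
  for (k in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, k]))
    if (scores[i, k] < 0) scores[, k] <- -scores[, k]
  }
  rownames(scores) <- labels
  colnames(scores) <- paste0("PV", seq_along(pos))
  rel <- ev[pos] / sum(ev[pos])
  retained <- broken_stick(rel)
  structure(list(
    eigenvalues = ev,
    relative_eigenvalues = rel,
    vectors = scores,
    retained = retained,
    cumulative_variance_retained = sum(rel[retained]),
    labels = labels
  ), class = "pcoa_axes")
}

#' @export
print.pcoa_axes <- function(x, ...) {
  cat("Principal coordinates of", length(x$labels), "objects:",
      length(x$relative_eigenvalues), "positive axes\n")
  cat("  broken-stick retains", length(x$retained), "axes (",
      sprintf("%.1f%%", 100 * x$cumulative_variance_retained),
      "of positive variance )\n")
  invisible(x)
}

#' Broken-stick axis retention
#'
#' The broken-stick null spectrum for `S` axes assigns axis `k` the
#' expected share \eqn{b_k = \frac{1}{S}\sum_{i=k}^{S} 1/i}. The leading
#' run of axes whose relative eigenvalue exceeds its broken-stick
#' expectation is retained, stopping at the first axis that fails.
#'
#' @param relative_eigenvalues Descending non-negative values summing to 1.
#' @return Integer vector of retained axis indices (possibly empty).
#' @export
broken_stick <- function(relative_eigenvalues) {
  v <- as.numeric(relative_eigenvalues)
  if (!length(v)) stop("empty eigenvalue vector")
  S <- length(v)
  b <- rev(cumsum(1 / rev(seq_len(S)))) / S
  ok <- v > b
  if (!ok[1L]) return(integer(0))
  run <- which(!ok)
  if (!length(run)) seq_len(S) else seq_len(run[1L] - 1L)
}

#' Species-level phylogenetic eigenvector design
#'
#' Extracts the first `n_axes` principal-coordinate scores aligned to a
#' requested species ordering, for use as predictor columns that absorb
#' phylogenetic similarity.
#'
#' @param es A [pcoa_axes()] result.
#' @param species Character vector of species identifiers giving the row
#'   order of the design (default: the ordination's own labels).
#' @param n_axes Number of leading axes (default: the broken-stick
#'   retention; may be 0, giving a zero-column design).
#' @return Numeric matrix, `length(species)` x `n_axes`, rownames =
#'   species, colnames `PV1..`.
#' @export
pv_design <- function(es, species = NULL, n_axes = NULL) {
  stopifnot(inherits(es, "pcoa_axes"))
  if (is.null(species)) species <- es$labels
  if (is.null(n_axes)) n_axes <- length(es$retained)
  if (n_axes > ncol(es$vectors))
    stop("n_axes exceeds the number of positive axes")
  missing_sp <- setdiff(species, es$labels)
  if (length(missing_sp))
    stop("species absent from the phylogeny: ",
         paste(missing_sp, collapse = ", "))
  es$vectors[species, seq_len(n_axes), drop = FALSE]
}
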