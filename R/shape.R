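#' Procrustes alignment of one curve onto another
#'
#' Estimated structures are identified only up to scale, translation,
#' rotation and reflection, so curves are compared after solving the
#' orthogonal Procrustes problem over the full orthogonal group (reflections
#' permitted) with optimal scaling of the source onto the target. The
#' alignment itself is computed with [vegan::procrustes()].
#'
#' @param X source curve (n x 3), scaled and rotated onto the target.
#' @param Y target curve (n x 3), same n.
#' @return a list of class `"curve_alignment"`: `rotation` (3 x 3
#'   orthogonal, determinant +-1), `scale`, `translation`, `rmsd`
#'   (`sqrt(mean(rowSums((T(x_i) - y_i)^2)))`), and `aligned` (the
#'   transformed source, overlaying `Y`).
#' @export
#' @examples
#' X <- make_test_helix(30)
#' R <- diag(c(-1, 1, 1))        # reflection
#' Y <- 2 * X %*% R + 5
#' align_curves(X, Y)$rmsd       # ~0: similarity copies are equivalent
align_curves <- function(X, Y) {
  X <- as_curve(X)
  Y <- as_curve(Y)
  if (nrow(X) != nrow(Y)) stop("curves must have the same number of points")
  n <- nrow(X)
  if (n < 3) stop("alignment needs at least 3 points")
  if (sum(center_curve(X)^2) < .DIST_EPS^2 ||
      sum(center_curve(Y)^2) < .DIST_EPS^2) {
    stop("degenerate curve with zero centered norm")
  }
  p <- vegan::procrustes(Y, X, scale = TRUE, symmetric = FALSE)
  aligned <- unname(sweep(p$Yrot, 2, p$xmean, `+`))
  # rmsd from the aligned coordinates directly: vegan's closed-form ss
  # suffers catastrophic cancellation for near-identical shapes
  rmsd <- sqrt(mean(rowSums((aligned - Y)^2)))
  structure(list(rotation = unname(p$rotation), scale = p$scale,
                 translation = as.vector(p$translation), rmsd = rmsd,
                 aligned = aligned),
            class = "curve_alignment")
}

#' @export
print.curve_alignment <- function(x, ...) {
  cat(sprintf("curve_alignment: rmsd = %.6g, scale = %.4g, det(R) = %+d\n",
              x$rmsd, x$scale, as.integer(round(det(x$rotation)))))
  invisible(x)
}

#' RMSD between a solution and a reference after alignment
#'
#' Convenience wrapper around [align_curves()]: optimally scales and aligns
#' `X` onto the reference and returns the root mean square distance.
#'
#' @param X solution curve.
#' @param reference reference (e.g. ground-truth) curve.
#' @return a non-negative number.
#' @export
rmsd_to_reference <- function(X, reference) align_curves(X, reference)$rmsd

#' Pairwise RMSD matrix of a solution ensemble
#'
#' One-sided optimal scaling makes `rmsd(X, Y) != rmsd(Y, X)`, so for
#' ensemble comparisons both curves are first rescaled to unit centered
#' Frobenius norm and then Procrustes-aligned (the symmetric convention of
#' [vegan::procrustes()]), giving a symmetric, zero-diagonal matrix.
#'
#' @param solutions list of at least two n x 3 curves (all the same n), or a
#'   list of `structure_fit` objects.
#' @return a symmetric matrix with zero diagonal.
#' @export
pairwise_rmsd <- function(solutions) {
  curves <- lapply(solutions, function(s) {
    if (inherits(s, "structure_fit")) s$curve else as_curve(s)
  })
  m <- length(curves)
  if (m < 2) stop("need at least two solutions")
  ns <- vapply(curves, nrow, integer(1))
  if (length(unique(ns)) != 1) stop("solutions differ in size")
  n <- ns[1]
  D <- matrix(0, m, m)
  for (p in seq_len(m - 1)) {
    for (q in (p + 1):m) {
      pr <- vegan::procrustes(curves[[p]], curves[[q]], scale = TRUE,
                              symmetric = TRUE)
      D[p, q] <- D[q, p] <- sqrt(sum((pr$Yrot - pr$X)^2) / n)
    }
  }
  D
}

#' Hierarchical clustering of solutions in shape space
#'
#' Agglomerative clustering (default average linkage) on a pairwise RMSD
#' matrix, as used to ask whether solutions originating from the same cell
#' occupy the same region of shape space.
#'
#' @param D symmetric non-negative matrix with zero diagonal, typically from
#'   [pairwise_rmsd()].
#' @param k optional number of flat clusters to cut the tree into.
#' @param method linkage method passed to [stats::hclust()].
#' @return a list with `tree` (an `hclust` object) and `labels` (integer
#'   cluster labels, or `NULL` when `k` is missing).
#' @export
cluster_solutions <- function(D, k = NULL, method = "average") {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || !isSymmetric(unname(D))) {
    stop("D must be a symmetric matrix")
  }
  if (any(D < 0) || any(abs(diag(D)) > 1e-12)) {
    stop("D must be non-negative with zero diagonal")
  }
  tree <- stats::hclust(stats::as.dist(D), method = method)
  labels <- if (is.null(k)) NULL else stats::cutree(tree, k = k)
  list(tree = tree, labels = labels)
}
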