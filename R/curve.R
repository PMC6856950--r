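#' Curve utilities
#'
#' A chromosome structure is represented as an ordered n x 3 numeric matrix:
#' row i is the spatial center of mass of genomic bin i. Structures are
#' identified only up to scale, translation, rotation and reflection.
#'
#' @name curve-utils
NULL

as_curve <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) != 3) stop("curve must be an n x 3 coordinate matrix")
  if (!is.numeric(X) || anyNA(X)) stop("curve coordinates must be numeric and finite")
  unname(X)
}

#' Lengths of the gaps between consecutive curve points
#'
#' @param X n x 3 coordinate matrix.
#' @return numeric vector of length `n - 1`.
#' @export
gap_lengths <- function(X) {
  X <- as_curve(X)
  d <- diff(X)
  sqrt(rowSums(d^2))
}

#' Total length of the piecewise-linear curve
#'
#' @param X n x 3 coordinate matrix.
#' @return sum of the gap lengths.
#' @export
curve_length <- function(X) sum(gap_lengths(X))

#' Center a curve at the origin
#'
#' @param X n x 3 coordinate matrix.
#' @return the curve translated to zero centroid.
#' @export
center_curve <- function(X) {
  X <- as_curve(X)
  sweep(X, 2, colMeans(X))
}

#' Deterministic helix curve for examples and tests
#'
#' @param n number of points.
#' @param turns number of full turns.
#' @param radius helix radius.
#' @param pitch vertical rise per turn.
#' @return an n x 3 coordinate matrix.
#' @export
make_test_helix <- function(n = 100, turns = 3, radius = 1, pitch = 1) {
  t <- seq(0, turns * 2 * pi, length.out = n)
  cbind(radius * cos(t), radius * sin(t), pitch * t / (2 * pi))
}

#' Radius of gyration
#'
#' Root mean square distance of the curve's points from their centroid;
#' the natural scale reference when judging RMSD values.
#'
#' @param X n x 3 coordinate matrix.
#' @return a non-negative number.
#' @export
radius_of_gyration <- function(X) {
  Xc <- center_curve(X)
  sqrt(mean(rowSums(Xc^2)))
}
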