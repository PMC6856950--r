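#' Construct a validated contact matrix
#'
#' A contact matrix records pairwise interaction counts between `n` genomic
#' bins. It must be square, symmetric and non-negative; diagonal entries
#' (self-contacts) carry no information about the 3D path and are zeroed on
#' construction. All model computations run strictly over the upper triangle.
#'
#' @param counts square numeric matrix of non-negative counts. Real-valued
#'   entries are permitted: prior-absorbed effective matrices are generally
#'   non-integer.
#' @param warn_diagonal emit a warning when non-zero diagonal entries are
#'   discarded.
#' @return a numeric matrix of class `"contact_matrix"` with zero diagonal.
#' @seealso [total_contacts()], [read_contact_matrix()]
#' @export
#' @examples
#' C <- contact_matrix(rbind(c(0, 2, 1), c(2, 0, 0), c(1, 0, 0)))
#' total_contacts(C)
contact_matrix <- function(counts, warn_diagonal = TRUE) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) {
    stop("contact matrix must be square, got ", nrow(counts), " x ",
         ncol(counts))
  }
  if (!is.numeric(counts)) stop("contact matrix must be numeric")
  if (anyNA(counts)) stop("contact matrix contains missing values")
  if (any(counts < 0)) stop("contact matrix contains negative counts")
  if (!isSymmetric(unname(counts))) {
    stop("contact matrix must be symmetric")
  }
  if (warn_diagonal && any(diag(counts) != 0)) {
    warning("non-zero diagonal entries discarded (self-contacts are ignored)")
  }
  diag(counts) <- 0
  dimnames(counts) <- NULL
  class(counts) <- c("contact_matrix", class(counts))
  counts
}

#' @export
print.contact_matrix <- function(x, ...) {
  n <- nrow(x)
  nz <- sum(x[upper.tri(x)] > 0)
  cat(sprintf(
    "contact_matrix: %d x %d bins, M = %g, %d/%d non-zero upper pairs\n",
    n, n, total_contacts(x), nz, n * (n - 1) / 2))
  invisible(x)
}

as_contact_matrix <- function(x, warn_diagonal = FALSE) {
  if (inherits(x, "contact_matrix")) return(x)
  contact_matrix(x, warn_diagonal = warn_diagonal)
}

#' Total upper-triangular contact count
#'
#' Returns `M`, the sum of the strictly upper-triangular entries of a contact
#' matrix. `M` normalizes the data likelihood in the posterior energy and
#' sets the mixing weight when a bulk prior is absorbed.
#'
#' @param C contact matrix (any symmetric matrix is accepted).
#' @return a single non-negative number.
#' @export
total_contacts <- function(C) {
  C <- as.matrix(C)
  sum(C[upper.tri(C)])
}

#' Sum contact matrices into a bulk matrix
#'
#' Aggregates a list of single-cell contact matrices by elementwise
#' summation, optionally leaving one cell out. The leave-one-out form is the
#' standard construction of a population prior for the excluded cell: its
#' own data must not enter its prior.
#'
#' @param matrices list of contact matrices sharing the same bin count.
#' @param exclude_index optional index of a matrix to leave out.
#' @return a `contact_matrix` with `M` equal to the sum of the member `M`s
#'   (minus the excluded one).
#' @export
sum_bulk <- function(matrices, exclude_index = NULL) {
  if (length(matrices) == 0) stop("empty list of matrices")
  if (!is.null(exclude_index)) {
    if (exclude_index < 1 || exclude_index > length(matrices)) {
      stop("exclude_index out of range")
    }
    matrices <- matrices[-exclude_index]
    if (length(matrices) == 0) {
      stop("excluding the only matrix leaves an empty sum")
    }
  }
  ns <- vapply(matrices, nrow, integer(1))
  if (length(unique(ns)) != 1) stop("matrices differ in bin count")
  total <- Reduce(`+`, lapply(matrices, function(m) unclass(as.matrix(m))))
  contact_matrix(total, warn_diagonal = FALSE)
}

#' Coarsen a contact matrix by merging adjacent bin pairs
#'
#' Merges adjacent genomic bins pairwise: coarse bin `I` aggregates fine bins
#' `2I - 1` and `2I` (the last coarse bin is a singleton when `n` is odd), so
#' one pass roughly halves the matrix dimension. Off-diagonal coarse entries
#' sum the mapped fine entries; fine counts that land on the coarse diagonal
#' (contacts within a merged bin) are dropped, mirroring the treatment of the
#' diagonal at full resolution.
#'
#' @param C contact matrix with at least 4 bins.
#' @return a `contact_matrix` of dimension `ceiling(n / 2)`.
#' @seealso [build_scale_series()]
#' @export
coarsen_matrix <- function(C) {
  C <- as_contact_matrix(C)
  n <- nrow(C)
  if (n < 4) stop("need at least 4 bins to coarsen, got ", n)
  group <- (seq_len(n) + 1L) %/% 2L
  coarse <- rowsum(unclass(C), group)
  coarse <- t(rowsum(t(coarse), group))
  contact_matrix(coarse, warn_diagonal = FALSE)
}

#' Build a coarse-to-fine series of contact matrices
#'
#' Repeatedly coarsens the input until its dimension is at most `min_n`,
#' returning the levels smallest-first with the full-resolution matrix last.
#' A bulk matrix, when supplied, is coarsened with the identical bin
#' mapping so that both matrices stay aligned at every scale.
#'
#' @param C full-resolution contact matrix.
#' @param C_bulk optional bulk contact matrix of the same dimension.
#' @param min_n coarsening stops once `n <= min_n` (default 64). A `min_n`
#'   at or above `n` yields a single-level series.
#' @return list with elements `matrices` (list, smallest first), `sizes`
#'   (integer vector), and `bulk` (parallel list or `NULL`).
#' @export
#' @examples
#' C <- simulate_contact_matrix(make_test_helix(128), a = -3, b = 50, seed = 1)
#' build_scale_series(C, min_n = 30)$sizes
build_scale_series <- function(C, C_bulk = NULL, min_n = 64) {
  C <- as_contact_matrix(C)
  if (min_n < 4) stop("min_n must be at least 4")
  if (!is.null(C_bulk)) {
    C_bulk <- as_contact_matrix(C_bulk)
    if (nrow(C_bulk) != nrow(C)) {
      stop("bulk matrix dimension does not match the single-cell matrix")
    }
  }
  mats <- list(C)
  bulks <- if (is.null(C_bulk)) NULL else list(C_bulk)
  while (nrow(mats[[1]]) > min_n) {
    mats <- c(list(coarsen_matrix(mats[[1]])), mats)
    if (!is.null(bulks)) bulks <- c(list(coarsen_matrix(bulks[[1]])), bulks)
  }
  list(matrices = mats,
       sizes = vapply(mats, nrow, integer(1)),
       bulk = bulks)
}
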