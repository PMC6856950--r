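#' Read a contact matrix from a text file
#'
#' Two plain-text layouts are supported. `"dense"`: an n x n numeric grid,
#' whitespace- or comma-separated; the grid must be symmetric up to exact
#' equality. `"coo"`: three columns `i j count` with 0-based bin indices;
#' the upper triangle is sufficient and entries are mirrored on load (a pair
#' given on both sides must agree). Non-zero diagonal entries are zeroed
#' with a warning in either mode.
#'
#' @param path file path.
#' @param format `"dense"` or `"coo"`.
#' @param n optional bin count for COO input; inferred as `max(index) + 1`
#'   when missing.
#' @return a `contact_matrix`.
#' @export
read_contact_matrix <- function(path, format = c("dense", "coo"), n = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense") {
    first <- readLines(path, n = 1)
    sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
    tab <- utils::read.table(path, sep = sep, header = FALSE,
                             strip.white = TRUE)
    m <- as.matrix(tab)
    if (nrow(m) != ncol(m)) {
      stop("dense contact matrix must be square, got ", nrow(m), " x ",
           ncol(m))
    }
    if (!is.numeric(m)) stop("dense contact matrix has non-numeric entries")
    if (!isSymmetric(unname(m))) stop("dense contact matrix is asymmetric")
    contact_matrix(m)
  } else {
    tab <- utils::read.table(path, header = FALSE)
    if (ncol(tab) != 3) stop("COO input must have 3 columns: i j count")
    i <- tab[[1]]; j <- tab[[2]]; x <- tab[[3]]
    if (any(i != floor(i)) || any(j != floor(j)) || any(i < 0) || any(j < 0)) {
      stop("COO indices must be non-negative integers (0-based)")
    }
    if (any(x < 0)) stop("negative counts in COO input")
    if (is.null(n)) n <- max(i, j) + 1
    if (any(i >= n) || any(j >= n)) stop("COO index out of range for n = ", n)
    C <- matrix(0, n, n)
    for (r in seq_along(i)) {
      a <- i[r] + 1; b <- j[r] + 1
      if (a != b) {
        if ((C[a, b] != 0 || C[b, a] != 0) && C[a, b] != x[r]) {
          stop("conflicting duplicate entry at (", i[r], ", ", j[r], ")")
        }
        C[a, b] <- C[b, a] <- x[r]
      } else if (x[r] != 0) {
        warning("diagonal COO entry at bin ", i[r], " ignored")
      }
    }
    contact_matrix(C, warn_diagonal = FALSE)
  }
}

#' Write a contact matrix to a text file
#'
#' @param C contact matrix.
#' @param path output file path.
#' @param format `"dense"` (whitespace-separated grid) or `"coo"` (0-based
#'   `i j count` triples for the non-zero upper triangle).
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(C, path, format = c("dense", "coo")) {
  format <- match.arg(format)
  C <- as_contact_matrix(C)
  if (format == "dense") {
    utils::write.table(unclass(C), path, row.names = FALSE,
                       col.names = FALSE)
  } else {
    idx <- which(upper.tri(C) & C != 0, arr.ind = TRUE)
    lines <- sprintf("%d %d %g", idx[, 1] - 1, idx[, 2] - 1, C[idx])
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write a curve to CSV or pseudo-PDB
#'
#' CSV output has one row per node, `index,x,y,z`, with the index strictly
#' increasing. PDB output writes one CA pseudo-atom per node (sequential
#' residue numbers, single chain) via [bio3d::write.pdb()] so structures can
#' be opened in standard molecular viewers; coordinates are rescaled to fit
#' the fixed-width PDB columns.
#'
#' @param X n x 3 coordinate matrix.
#' @param path output file path.
#' @param format `"csv"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_curve <- function(X, path, format = c("csv", "pdb")) {
  format <- match.arg(format)
  X <- as_curve(X)
  n <- nrow(X)
  if (format == "csv") {
    df <- data.frame(index = seq_len(n), x = X[, 1], y = X[, 2], z = X[, 3])
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    Xs <- center_curve(X)
    mx <- max(abs(Xs))
    if (mx > 0) Xs <- Xs * (99 / mx)   # keep within PDB fixed columns
    bio3d::write.pdb(file = path, xyz = as.vector(t(Xs)),
                     resno = seq_len(n), resid = rep("GLY", n),
                     elety = rep("CA", n), chain = rep("A", n))
  }
  invisible(path)
}

#' Read a curve written by [write_curve()] in CSV format
#'
#' @param path CSV file with columns `index,x,y,z`.
#' @return an n x 3 coordinate matrix ordered by index.
#' @export
read_curve <- function(path) {
  df <- utils::read.csv(path)
  need <- c("index", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("curve CSV must have columns index,x,y,z")
  }
  df <- df[order(df$index), ]
  unname(as.matrix(df[, c("x", "y", "z")]))
}

config_defaults <- function() {
  list(contacts = NULL, bulk = NULL, a = -3, b = 1,
       lambda1 = 0.5, lambda2 = 1, lambda3 = 0.1,
       seed = 1, min_n = 64, multiscale = TRUE, out = NULL)
}

#' Load and validate an estimation config file
#'
#' Reads a JSON config with keys `contacts`, `bulk`, `a`, `b`, `lambda1`,
#' `lambda2`, `lambda3`, `seed`, `min_n`, `multiscale`, `out`; missing keys
#' take the documented defaults (`a = -3`, `b = 1`,
#' `lambda = (0.5, 1, 0.1)`, multiscale on). Unknown keys and invalid
#' parameter values are errors; a positive `lambda3` without a bulk path is
#' rejected.
#'
#' @param path JSON file path.
#' @return a named list of validated parameters.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, raw)
  if (is.null(cfg$contacts)) stop("config must name a contacts file")
  if (!is.numeric(cfg$a) || cfg$a >= 0) stop("config: a must be negative")
  if (!is.numeric(cfg$b) || cfg$b <= 0) stop("config: b must be positive")
  for (key in c("lambda1", "lambda2", "lambda3")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] < 0) {
      stop("config: ", key, " must be non-negative")
    }
  }
  if (cfg$lambda3 > 0 && is.null(cfg$bulk)) {
    stop("config: lambda3 > 0 requires a bulk matrix path")
  }
  if (!is.logical(cfg$multiscale)) stop("config: multiscale must be logical")
  if (cfg$min_n < 4) stop("config: min_n must be at least 4")
  cfg
}

BUNDLE_FORMAT_VERSION <- "1.0"

#' Write a structure-fit result bundle
#'
#' Serializes a [estimate_structure()] result to self-describing JSON: the
#' curve coordinates, final and per-scale energies, iteration counts, scale
#' sizes, seed, full parameter set and a format version tag. A bundle can be
#' read back with [read_result_bundle()] and contains everything needed to
#' re-run the estimation.
#'
#' @param fit `structure_fit` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_result_bundle <- function(fit, path) {
  if (!inherits(fit, "structure_fit")) stop("fit must be a structure_fit")
  bundle <- list(
    format_version = BUNDLE_FORMAT_VERSION,
    curve = unname(as.matrix(fit$curve)),
    energy = fit$energy,
    energy_per_scale = fit$energy_per_scale,
    iterations_per_scale = fit$iterations_per_scale,
    sizes = fit$sizes,
    seed = fit$seed,
    multiscale = fit$multiscale,
    converged = fit$converged,
    params = unclass(fit$params))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a structure-fit result bundle
#'
#' @param path JSON file written by [write_result_bundle()].
#' @return a `structure_fit` object.
#' @export
read_result_bundle <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(b$format_version)) stop("not a result bundle: ", path)
  structure(list(curve = as.matrix(b$curve), energy = b$energy,
                 energy_per_scale = b$energy_per_scale,
                 iterations_per_scale = b$iterations_per_scale,
                 sizes = b$sizes, seed = b$seed,
                 params = do.call(model_params, as.list(b$params)),
                 multiscale = b$multiscale, converged = b$converged),
            class = "structure_fit")
}
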