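#' Construct a connectome object
#'
#' A connectome is a square, symmetric, zero-diagonal weight matrix with a
#' modality tag. Structural connectomes carry non-negative streamline-derived
#' weights; functional connectomes carry Pearson correlations in \[-1, 1\].
#'
#' @param weights Square numeric matrix. Must be symmetric within `tol`;
#'   it is then made exactly symmetric by averaging `w` and `t(w)`.
#' @param modality `"structural"` or `"functional"`.
#' @param node_ids Optional character/integer vector of region identifiers
#'   (defaults to `1:n`).
#' @param tol Maximum tolerated absolute asymmetry before erroring.
#' @return An object of class `connectome`: a list with elements `weights`,
#'   `modality` and `node_ids`.
#' @export
connectome <- function(weights, modality = c("structural", "functional"),
                       node_ids = NULL, tol = 1e-8) {
  modality <- match.arg(modality)
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("`weights` must be a numeric matrix")
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop(sprintf("non-square matrix: %d x %d", n, ncol(weights)))
  if (anyNA(weights) || any(!is.finite(weights)))
    stop("weights contain non-finite values")
  asym <- abs(weights - t(weights))
  if (any(asym > tol)) {
    idx <- sort(which(asym == max(asym), arr.ind = TRUE)[1, ])
    stop(sprintf(
      "asymmetry %.3g at (%d, %d) exceeds tolerance %g",
      max(asym), idx[1], idx[2], tol))
  }
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) {
    warning("nonzero diagonal entries set to 0")
    diag(weights) <- 0
  }
  if (modality == "structural" && any(weights < 0))
    stop("structural weights must be non-negative")
  if (modality == "functional" && any(abs(weights) > 1 + 1e-12))
    stop("functional weights must lie in [-1, 1]")
  if (is.null(node_ids)) node_ids <- seq_len(n)
  if (length(node_ids) != n)
    stop("length(node_ids) must equal matrix dimension")
  dimnames(weights) <- NULL
  structure(list(weights = weights, modality = modality,
                 node_ids = node_ids),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  nz <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("<connectome: %s, %d nodes, %d non-zero edges (density %.3f)>\n",
              x$modality, n, nz, nz / (n * (n - 1) / 2)))
  invisible(x)
}

#' @export
dim.connectome <- function(x) dim(x$weights)

#' Test whether an object is a connectome
#' @param x Any object.
#' @return Logical scalar.
#' @export
is_connectome <- function(x) inherits(x, "connectome")

# shared parser: delimited square matrix, optional header row / id column
.parse_matrix_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("empty file: %s", path))
  sep <- if (grepl(",", lines[[1]], fixed = TRUE)) "," else ""
  split1 <- function(l) {
    if (sep == ",") trimws(strsplit(l, ",", fixed = TRUE)[[1]])
    else strsplit(trimws(l), "[[:space:]]+")[[1]]
  }
  cells <- lapply(lines, split1)
  # a header / id column is only recognized when *no* token in it parses
  # as a number, so a stray bad cell in numeric data is reported as such
  all_nonnum <- function(v)
    all(is.na(suppressWarnings(as.numeric(v))))
  header <- NULL
  if (all_nonnum(cells[[1]])) {
    header <- cells[[1]]
    cells <- cells[-1]
  }
  first_col <- vapply(cells, `[[`, character(1), 1)
  rowids <- NULL
  if (length(first_col) && all_nonnum(first_col)) {
    rowids <- first_col
    cells <- lapply(cells, function(v) v[-1])
    if (!is.null(header) && length(header) == length(cells[[1]]) + 1)
      header <- header[-1]
  }
  widths <- lengths(cells)
  if (length(unique(widths)) != 1)
    stop("ragged rows: row widths differ")
  m <- matrix(NA_real_, length(cells), widths[1])
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(v))
      stop(sprintf("non-numeric cell in data row %d (value '%s')",
                   i, cells[[i]][which(is.na(v))[1]]))
    m[i, ] <- v
  }
  list(m = m, ids = if (!is.null(header)) header else rowids)
}

#' Read a connectome from a delimited matrix file
#'
#' Accepts comma- or whitespace-delimited square numeric matrices, with an
#' optional single header row and/or leading column of node identifiers.
#' The matrix must be symmetric within `tol`; it is then exactly symmetrized
#' by averaging, and any non-zero diagonal is zeroed with a warning.
#'
#' @param path Path to the matrix file.
#' @param expected_n Required matrix dimension (e.g. 360); `NULL` to skip
#'   the check.
#' @param modality Connectome modality, `"structural"` or `"functional"`.
#' @param tol Asymmetry tolerance.
#' @return A [connectome].
#' @export
read_connectome <- function(path, expected_n = NULL,
                            modality = c("structural", "functional"),
                            tol = 1e-8) {
  modality <- match.arg(modality)
  parsed <- .parse_matrix_file(path)
  m <- parsed$m
  if (nrow(m) != ncol(m))
    stop(sprintf("non-square matrix in %s: %d x %d", path, nrow(m), ncol(m)))
  if (!is.null(expected_n) && nrow(m) != expected_n)
    stop(sprintf("matrix in %s is %d x %d, expected %d x %d",
                 path, nrow(m), ncol(m), expected_n, expected_n))
  connectome(m, modality = modality, node_ids = parsed$ids, tol = tol)
}

#' Write a connectome to a CSV file
#'
#' Writes a plain comma-delimited matrix with 17 significant digits so that
#' a read/write round trip reproduces finite weights bit-identically.
#'
#' @param x A [connectome].
#' @param path Output path.
#' @param node_ids Logical; write a header row of node identifiers.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(x, path, node_ids = FALSE) {
  stopifnot(is_connectome(x))
  w <- x$weights
  lines <- apply(w, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  if (node_ids)
    lines <- c(paste(x$node_ids, collapse = ","), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Functional connectome from ROI time series
#'
#' Computes the Pearson correlation between every pair of regional time
#' courses; the diagonal is set to zero. Columns with zero variance get a
#' zero row/column (their correlations are undefined) with a warning.
#'
#' @param ts Numeric matrix, timepoints x regions (T >= 3).
#' @param node_ids Optional region identifiers.
#' @return A functional [connectome].
#' @export
fc_from_timeseries <- function(ts, node_ids = NULL) {
  if (!is.matrix(ts) || !is.numeric(ts)) stop("`ts` must be a numeric matrix")
  if (nrow(ts) < 3) stop("need at least 3 timepoints")
  sds <- apply(ts, 2, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  r <- suppressWarnings(stats::cor(ts))
  if (length(bad)) {
    warning(sprintf("zero-variance column(s) %s: correlations set to 0",
                    paste(bad, collapse = ", ")))
    r[bad, ] <- 0
    r[, bad] <- 0
  }
  diag(r) <- 0
  r[r > 1] <- 1
  r[r < -1] <- -1
  connectome(r, modality = "functional", node_ids = node_ids)
}

#' Structural connectome from streamline counts and node volumes
#'
#' Scales each edge's streamline count by the inverse volumes of its two
#' endpoint regions: `weight(i, j) = counts(i, j) * (1/vol_i + 1/vol_j) / 2`,
#' which corrects for larger regions accumulating more streamlines.
#'
#' @param counts Symmetric, zero-diagonal, non-negative streamline-count
#'   matrix.
#' @param node_volumes Positive region volumes (mm^3), length `nrow(counts)`.
#' @param node_ids Optional region identifiers.
#' @return A structural [connectome].
#' @export
sc_from_streamline_counts <- function(counts, node_volumes, node_ids = NULL) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts))
    stop("`counts` must be a square matrix")
  if (any(counts < 0)) stop("streamline counts must be non-negative")
  if (length(node_volumes) != nrow(counts))
    stop("length(node_volumes) must match matrix dimension")
  if (any(node_volumes <= 0) || any(!is.finite(node_volumes)))
    stop("node volumes must be positive")
  inv <- 1 / node_volumes
  w <- counts * outer(inv, inv, `+`) / 2
  diag(w) <- 0
  connectome(w, modality = "structural", node_ids = node_ids)
}
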