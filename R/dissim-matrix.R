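#' Labelled drug-drug dissimilarity matrix
#'
#' A `dissim_matrix` is a square numeric matrix with drug identifiers as
#' both row and column names, symmetric to within 1e-12, with a zero
#' diagonal. All matrices produced by the layer constructors additionally
#' have entries in \[0, 1\] (the target and expression layers after range
#' normalization).
#'
#' @param values square numeric matrix with identical row and column names.
#' @param check_range if `TRUE`, require all entries in \[0, 1\] (with a
#'   1e-9 tolerance for accumulated rounding).
#' @return `values` with class `dissim_matrix`, exactly symmetrized and
#'   with the diagonal set to zero.
#' @export
dissim_matrix <- function(values, check_range = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("dissimilarity values must be a numeric matrix")
  if (nrow(values) != ncol(values))
    stop("dissimilarity matrix must be square")
  ids <- rownames(values)
  if (is.null(ids) || anyDuplicated(ids))
    stop("dissimilarity matrix needs unique drug ids as row names")
  if (!identical(ids, colnames(values)))
    stop("row and column names of a dissimilarity matrix must agree")
  if (anyNA(values) || any(!is.finite(values)))
    stop("dissimilarity matrix contains non-finite values")
  if (max(abs(values - t(values))) > 1e-12)
    stop("dissimilarity matrix is asymmetric beyond 1e-12")
  if (max(abs(diag(values))) > 1e-12)
    stop("dissimilarity matrix diagonal is not zero")
  if (check_range && (min(values) < -1e-9 || max(values) > 1 + 1e-9))
    stop("dissimilarity entries outside [0, 1]")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  structure(values, class = c("dissim_matrix", class(values)))
}

#' @export
print.dissim_matrix <- function(x, ...) {
  cat(sprintf("dissim_matrix: %d drugs, entries in [%.4g, %.4g]\n",
              nrow(x), min(x), max(x)))
  invisible(x)
}

#' Range-normalize a symmetric matrix over its off-diagonal entries
#'
#' Maps off-diagonal entries through (x - min) / (max - min), computed over
#' all off-diagonal entries, so the result lies in \[0, 1\]. A degenerate
#' range (max equal to min, e.g. all raw values identical) maps everything
#' to zero. The diagonal stays zero.
#'
#' @param m symmetric numeric matrix with zero diagonal.
#' @return matrix of the same shape.
#' @export
range_normalize <- function(m) {
  off <- m[row(m) != col(m)]
  if (length(off) == 0L) return(m)
  lo <- min(off); hi <- max(off)
  if (hi - lo <= 0) {
    m[] <- 0
    return(m)
  }
  out <- (m - lo) / (hi - lo)
  diag(out) <- 0
  out
}

# shared id-alignment helper: principal submatrix in the given id order
subset_dissim <- function(m, ids) {
  dissim_matrix(unclass(m)[ids, ids, drop = FALSE],
                check_range = FALSE)
}
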