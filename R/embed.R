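#' Classical multidimensional scaling of a dissimilarity matrix
#'
#' Standard principal coordinates analysis: the squared dissimilarities
#' are double-centered, \eqn{B = -\frac{1}{2} J K^{(2)} J} with
#' \eqn{J = I - \frac{1}{n} 1 1'}, and the coordinates are the
#' eigenvectors of \eqn{B} scaled by the square roots of the positive
#' eigenvalues. Only eigenvalues above `tol_factor` times the largest
#' eigenvalue are kept; negative eigenvalues (a non-Euclidean input) are
#' dropped, not corrected. For a Euclidean `K`, pairwise distances of the
#' full-dimensional coordinates reproduce `K`.
#'
#' @param k a [dissim_matrix] (or symmetric labelled matrix with zero
#'   diagonal).
#' @param tol_factor relative eigenvalue tolerance (default 1e-9).
#' @return object of class `cmds_embedding`: list with `drug_ids`,
#'   `coords` (n x d, columns by descending eigenvalue), `eigenvalues`
#'   (all n, descending), `n_positive`.
#' @export
cmds_embed <- function(k, tol_factor = 1e-9) {
  if (!is.matrix(k) || nrow(k) != ncol(k) ||
      max(abs(k - t(k))) > 1e-12)
    stop("cmds_embed needs a symmetric square matrix")
  k <- unclass(k)
  n <- nrow(k)
  j <- diag(n) - 1 / n
  b <- -0.5 * j %*% (k * k) %*% j
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  tol <- tol_factor * max(e$values, 0)
  pos <- which(e$values > tol & e$values > 0)
  if (length(pos) == 0L)
    stop("degenerate embedding: no positive eigenvalues")
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  rownames(coords) <- rownames(k)
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(drug_ids = rownames(k),
                 coords = coords,
                 eigenvalues = e$values,
                 n_positive = length(pos)),
            class = "cmds_embedding")
}

#' @export
print.cmds_embedding <- function(x, ...) {
  cat(sprintf(
    "cmds_embedding: %d drugs, %d positive eigenvalues (of %d)\n",
    length(x$drug_ids), x$n_positive, length(x$eigenvalues)))
  invisible(x)
}
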