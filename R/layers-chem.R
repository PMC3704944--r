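#' Jaccard, cosine and Dice similarities of two binary sets
#'
#' Both arguments may be binary 0/1 vectors of equal length or sets given
#' as character/integer vectors of member ids. With intersection size
#' \eqn{n_i} and set sizes \eqn{n_a, n_b}: Jaccard
#' \eqn{JI = n_i / (n_a + n_b - n_i)}, cosine
#' \eqn{CS = n_i / \sqrt{n_a n_b}}, Dice \eqn{DC = 2 n_i / (n_a + n_b)}.
#' Empty sets are an error: all three measures are undefined (or
#' degenerate) without members, and drugs lacking a fingerprint or target
#' set are excluded upstream.
#'
#' @param a,b binary vectors (same length) or member-id vectors.
#' @return named numeric vector `c(JI =, CS =, DC =)`.
#' @export
binary_set_similarities <- function(a, b) {
  if (is.numeric(a) || is.logical(a)) {
    if (length(a) != length(b))
      stop("bit-vectors differ in length (", length(a), " vs ",
           length(b), ")")
    if (any(!(a %in% c(0, 1))) || any(!(b %in% c(0, 1))))
      stop("bit-vectors may contain only 0 and 1")
    na <- sum(a); nb <- sum(b); ni <- sum(a & b)
  } else {
    a <- unique(a); b <- unique(b)
    na <- length(a); nb <- length(b); ni <- length(intersect(a, b))
  }
  if (na == 0 || nb == 0)
    stop("binary set similarities are undefined for an empty set")
  c(JI = ni / (na + nb - ni),
    CS = ni / sqrt(na * nb),
    DC = 2 * ni / (na + nb))
}

#' Chemical (fingerprint) dissimilarity between two drugs
#'
#' One minus the mean of the Jaccard, cosine and Dice similarities of the
#' two binary fingerprints: 0 for identical non-empty fingerprints, 1 for
#' disjoint ones.
#'
#' @inheritParams binary_set_similarities
#' @return dissimilarity in \[0, 1\].
#' @export
chem_dissimilarity <- function(a, b) {
  unname(1 - mean(binary_set_similarities(a, b)))
}

#' Target-set overlap dissimilarity
#'
#' The chemical dissimilarity formula applied to the two drugs' target
#' protein sets instead of their fingerprints.
#'
#' @param t_i,t_j non-empty character vectors of protein ids.
#' @return dissimilarity in \[0, 1\].
#' @export
target_overlap_dissimilarity <- function(t_i, t_j) {
  chem_dissimilarity(as.character(t_i), as.character(t_j))
}

# vectorized 1 - (JI+CS+DC)/3 over the rows of a binary incidence matrix
set_dissimilarity_matrix <- function(inc) {
  sizes <- rowSums(inc)
  if (any(sizes == 0))
    stop("empty fingerprint/target set for drug(s): ",
         paste(rownames(inc)[sizes == 0], collapse = ", "))
  inter <- tcrossprod(inc)
  ssum <- outer(sizes, sizes, "+")
  ji <- inter / (ssum - inter)
  cs <- inter / sqrt(outer(sizes, sizes))
  dc <- 2 * inter / ssum
  out <- 1 - (ji + cs + dc) / 3
  diag(out) <- 0
  dissim_matrix(pmin(pmax(out, 0), 1))
}

#' Chemical dissimilarity matrix for a cohort
#'
#' @param fingerprints integer 0/1 matrix, drugs in rows (as returned by
#'   [read_fingerprints()]); every drug must have at least one bit set.
#' @param drugs optional drug ids selecting/ordering the rows.
#' @return a [dissim_matrix].
#' @export
chem_dissimilarity_matrix <- function(fingerprints, drugs = NULL) {
  if (is.null(drugs)) drugs <- rownames(fingerprints)
  if (length(drugs) < 2L) stop("need at least 2 drugs")
  set_dissimilarity_matrix(fingerprints[drugs, , drop = FALSE])
}
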