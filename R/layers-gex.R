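#' Signed p-value rank profile of one drug
#'
#' Genes are ranked so that over-expressed genes with low p-values come
#' first, under-expressed genes with low p-values come last, and
#' non-significant genes sit in the middle. The default sort key is
#' `-fc_sign * (1 - p)`: for an up-regulated gene it approaches -1 as p
#' shrinks, for a down-regulated gene +1, and it vanishes as p approaches
#' 1 from either side, which realizes that ordering exactly.
#' `rank_key = "literal"` uses `-fc_sign * p` instead, which orders
#' significant genes by sign but places high-p up-regulated genes ahead
#' of low-p ones. Ties receive average ranks. The per-gene weight is
#' `1 - p`.
#'
#' @param pvals named numeric vector of p-values in (0, 1\].
#' @param signs named numeric vector of fold-change signs (-1/+1), same
#'   genes as `pvals`.
#' @param rank_key `"significance"` (default) or `"literal"`.
#' @return list with components `ranks` and `weights`, both named by
#'   gene, of class `ranked_profile`.
#' @export
signed_rank_profile <- function(pvals, signs,
                                rank_key = c("significance", "literal")) {
  rank_key <- match.arg(rank_key)
  if (!identical(names(pvals), names(signs)))
    stop("pvals and signs must cover the same genes in the same order")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  if (any(!(signs %in% c(-1, 1)))) stop("signs must be -1 or +1")
  key <- if (rank_key == "significance") -signs * (1 - pvals)
         else -signs * pvals
  structure(list(ranks = rank(key, ties.method = "average"),
                 weights = 1 - pvals),
            class = "ranked_profile")
}

#' Weighted Spearman's Footrule between two rank profiles
#'
#' The raw (unnormalized) footrule
#' \eqn{\sum_g |R_i(g) - R_j(g)| \, (W_i(g) + W_j(g)) / 2} over the shared
#' gene universe.
#'
#' @param prof_i,prof_j `ranked_profile` objects over identical genes.
#' @return non-negative raw dissimilarity.
#' @export
wsf_dissimilarity <- function(prof_i, prof_j) {
  if (!identical(names(prof_i$ranks), names(prof_j$ranks)))
    stop("profiles are over different gene universes")
  sum(abs(prof_i$ranks - prof_j$ranks) *
        (prof_i$weights + prof_j$weights) / 2)
}

#' Gene-expression dissimilarity matrix (weighted Spearman's Footrule)
#'
#' Builds the signed rank profile of every drug, evaluates the raw
#' weighted footrule for each pair, and range-normalizes the result to
#' \[0, 1\] over all off-diagonal entries.
#'
#' @param expr list with matrices `pvals` and `signs` (drugs in rows,
#'   genes in columns), as returned by [read_expression_stats()].
#' @param drugs optional drug ids selecting/ordering the rows.
#' @param rank_key passed to [signed_rank_profile()].
#' @return a [dissim_matrix].
#' @export
wsf_dissimilarity_matrix <- function(expr, drugs = NULL,
                                     rank_key = "significance") {
  if (is.null(drugs)) drugs <- rownames(expr$pvals)
  if (length(drugs) < 2L) stop("need at least 2 drugs")
  pv <- expr$pvals[drugs, , drop = FALSE]
  sg <- expr$signs[drugs, , drop = FALSE]
  n <- length(drugs)
  ranks <- matrix(0, n, ncol(pv))
  for (i in seq_len(n)) {
    prof <- signed_rank_profile(pv[i, ], sg[i, ], rank_key = rank_key)
    ranks[i, ] <- prof$ranks
  }
  w <- 1 - pv
  raw <- matrix(0, n, n, dimnames = list(drugs, drugs))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      raw[i, j] <- raw[j, i] <-
        sum(abs(ranks[i, ] - ranks[j, ]) * (w[i, ] + w[j, ]) / 2)
    }
  }
  dissim_matrix(range_normalize(raw))
}
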