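#' Shortest-path distance between two drugs' target sets on a PPI network
#'
#' The minimum, over all pairs of one target from each drug, of the
#' shortest-path edge count in the protein-protein interaction network.
#' Drugs sharing a target are at distance 0 regardless of the network.
#' Targets absent from the network are ignored for the path search; if no
#' finite path exists between any remaining pair (or a drug has no target
#' in the network) the result is `Inf`, which
#' [target_dissimilarity_matrix()] replaces by one more than the longest
#' finite raw distance observed in the cohort.
#'
#' @param t_i,t_j non-empty character vectors of protein ids.
#' @param net undirected [igraph::graph] with protein ids as vertex names.
#' @return non-negative integer-valued distance, or `Inf`.
#' @export
ppi_target_distance <- function(t_i, t_j, net) {
  t_i <- as.character(t_i); t_j <- as.character(t_j)
  if (length(t_i) == 0L || length(t_j) == 0L)
    stop("ppi_target_distance needs non-empty target sets")
  if (length(intersect(t_i, t_j)) > 0L) return(0)
  vn <- igraph::V(net)$name
  t_i <- intersect(t_i, vn); t_j <- intersect(t_j, vn)
  if (length(t_i) == 0L || length(t_j) == 0L) return(Inf)
  min(igraph::distances(net, v = t_i, to = t_j))
}

#' Molecular-target dissimilarity matrix
#'
#' Mean of two components: the target-set overlap dissimilarity
#' (Jaccard/cosine/Dice on target sets) and the range-normalized minimum
#' PPI shortest-path distance between target sets. Raw path distances are
#' computed for every drug pair first (unreachable pairs set to the
#' longest finite distance plus one), then range-normalized over all
#' off-diagonal entries; a degenerate range yields an all-zero path
#' component.
#'
#' @param targets named list of non-empty protein-id vectors.
#' @param net undirected [igraph::graph].
#' @param drugs optional drug ids selecting/ordering `targets`.
#' @return a [dissim_matrix].
#' @export
target_dissimilarity_matrix <- function(targets, net, drugs = NULL) {
  if (is.null(drugs)) drugs <- names(targets)
  if (length(drugs) < 2L) stop("need at least 2 drugs")
  targets <- targets[drugs]
  if (any(lengths(targets) == 0L) || anyNA(names(targets)))
    stop("empty or missing target set for drug(s): ",
         paste(drugs[lengths(targets) == 0L | is.na(names(targets))],
               collapse = ", "))

  prots <- sort(unique(unlist(targets)))
  inc <- matrix(0L, length(drugs), length(prots),
                dimnames = list(drugs, prots))
  for (d in drugs) inc[d, targets[[d]]] <- 1L
  k_overlap <- set_dissimilarity_matrix(inc)

  # one all-pairs shortest-path computation over the in-network targets
  vn <- igraph::V(net)$name
  innet <- intersect(prots, vn)
  pd <- if (length(innet))
    igraph::distances(net, v = innet, to = innet)
  else
    matrix(numeric(0), 0, 0)
  n <- length(drugs)
  raw <- matrix(0, n, n, dimnames = list(drugs, drugs))
  tn <- lapply(targets, intersect, innet)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (length(intersect(targets[[i]], targets[[j]])) > 0L) {
        d <- 0
      } else if (length(tn[[i]]) == 0L || length(tn[[j]]) == 0L) {
        d <- Inf
      } else {
        d <- min(pd[tn[[i]], tn[[j]]])
      }
      raw[i, j] <- raw[j, i] <- d
    }
  }
  off <- raw[row(raw) != col(raw)]
  if (any(!is.finite(off))) {
    finite <- off[is.finite(off)]
    sentinel <- if (length(finite)) max(finite) + 1 else 1
    raw[!is.finite(raw)] <- sentinel
  }
  k_path <- range_normalize(raw)
  dissim_matrix((unclass(k_overlap) + k_path) / 2)
}
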