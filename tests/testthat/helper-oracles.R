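# Independent oracles, deliberately naive: direct set arithmetic, plain
# breadth-first search, and a double-loop footrule. They never call the
# package's own layer code.

oracle_set_sims <- function(a, b) {
  a <- unique(a); b <- unique(b)
  ni <- length(intersect(a, b))
  c(JI = ni / length(union(a, b)),
    CS = ni / sqrt(length(a) * length(b)),
    DC = 2 * ni / (length(a) + length(b)))
}

# unweighted BFS shortest path (edge count) on an adjacency list
oracle_bfs <- function(adj, from, to) {
  if (from == to) return(0)
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        if (w == to) return(unname(dist[w]))
        queue <- c(queue, w)
      }
    }
  }
  Inf
}

oracle_min_target_distance <- function(t_i, t_j, adj) {
  if (length(intersect(t_i, t_j))) return(0)
  t_i <- intersect(t_i, names(adj)); t_j <- intersect(t_j, names(adj))
  if (!length(t_i) || !length(t_j)) return(Inf)
  min(vapply(t_i, function(s)
    min(vapply(t_j, function(t) oracle_bfs(adj, s, t), numeric(1L))),
    numeric(1L)))
}

# adjacency list of a random undirected Erdos-Renyi graph
random_adjacency <- function(n, p) {
  nodes <- paste0("p", seq_len(n))
  adj <- stats::setNames(rep(list(character(0)), n), nodes)
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    if (stats::runif(1) < p) {
      adj[[nodes[i]]] <- c(adj[[nodes[i]]], nodes[j])
      adj[[nodes[j]]] <- c(adj[[nodes[j]]], nodes[i])
    }
  }
  adj
}

adjacency_to_igraph <- function(adj) {
  edges <- do.call(rbind, lapply(names(adj), function(v) {
    w <- adj[[v]][adj[[v]] > v]
    if (length(w)) cbind(v, w) else NULL
  }))
  g <- igraph::make_empty_graph(n = length(adj), directed = FALSE)
  igraph::V(g)$name <- names(adj)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  g
}

oracle_wsf <- function(ranks_i, ranks_j, w_i, w_j) {
  total <- 0
  for (g in seq_along(ranks_i))
    total <- total + abs(ranks_i[g] - ranks_j[g]) * (w_i[g] + w_j[g]) / 2
  total
}

# small labelled dissimilarity fixture: well-separated class structure
make_test_cohort <- function(n_classes = 3, per_class = 8, seed = 1,
                             ...) {
  generate_cohort(cohort_spec(
    n_classes = n_classes, drugs_per_class = per_class, fp_length = 128,
    n_proteins = 120, ppi_edge_prob = 0.05, n_genes = 150,
    de_genes_per_class = 15, seed = seed, ...))
}

expect_valid_dissim <- function(m) {
  expect_s3_class(m, "dissim_matrix")
  expect_lte(max(abs(m - t(m))), 1e-12)
  expect_equal(unname(diag(m)), rep(0, nrow(m)))
  expect_gte(min(m), 0)
  expect_lte(max(m), 1)
}
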