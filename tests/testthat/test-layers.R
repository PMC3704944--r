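test_that("binary set similarities match direct set arithmetic", {
  expect_equal(binary_set_similarities(c("x", "y"), c("x", "y")),
               c(JI = 1, CS = 1, DC = 1))
  expect_equal(binary_set_similarities(c("x"), c("y")),
               c(JI = 0, CS = 0, DC = 0))
  expect_equal(binary_set_similarities(c("1", "2"), c("2", "3")),
               c(JI = 1 / 3, CS = 1 / 2, DC = 1 / 2))
  # bit-vector and set forms agree
  expect_equal(binary_set_similarities(c(1, 1, 0), c(0, 1, 1)),
               binary_set_similarities(c("b1", "b2"), c("b2", "b3")))
  expect_error(binary_set_similarities(c(1, 0), c(1, 0, 1)), "length")
  expect_error(binary_set_similarities(character(0), "x"), "empty")
  expect_error(binary_set_similarities(c(0, 0), c(1, 0)), "empty")
})

test_that("chemical dissimilarity is 1 - mean(JI, CS, DC)", {
  expect_equal(chem_dissimilarity(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(chem_dissimilarity(c(1, 0), c(0, 1)), 1)
  expect_equal(chem_dissimilarity(c("1", "2"), c("2", "3")), 5 / 9)
  expect_equal(target_overlap_dissimilarity(c("p1", "p2"), c("p2", "p3")),
               5 / 9)
})

test_that("pairwise dissimilarities agree with the set-arithmetic oracle on exhaustive small sets", {
  # all pairs of non-empty subsets of a 4-element universe, exhaustively
  universe <- paste0("e", 1:4)
  subsets <- lapply(1:15, function(m) universe[bitwAnd(m, 2^(0:3)) > 0])
  for (a in subsets) for (b in subsets) {
    expect_equal(binary_set_similarities(a, b), oracle_set_sims(a, b))
    expect_equal(chem_dissimilarity(a, b), 1 - mean(oracle_set_sims(a, b)))
  }
  # random pairs on a 10-bit universe
  set.seed(31)
  u10 <- paste0("e", 1:10)
  for (i in 1:200) {
    a <- sample(u10, sample(10, 1))
    b <- sample(u10, sample(10, 1))
    expect_equal(binary_set_similarities(a, b), oracle_set_sims(a, b))
  }
})

test_that("dissimilarity decreases strictly in the intersection at fixed set sizes", {
  u <- paste0("e", 1:12)
  vals <- vapply(0:6, function(k) {
    a <- u[1:6]
    b <- c(u[seq_len(k)], u[6 + seq_len(6 - k)])
    chem_dissimilarity(a, b)
  }, numeric(1L))
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[1], 1)
  expect_equal(vals[7], 0)
})

test_that("PPI target distance matches a breadth-first-search oracle", {
  # hand case: shared target, simple path
  adj <- list(p1 = "p2", p2 = c("p1", "p3"), p3 = "p2")
  g <- adjacency_to_igraph(adj)
  expect_equal(ppi_target_distance("p1", "p1", g), 0)
  expect_equal(ppi_target_distance("p1", "p3", g), 2)
  expect_equal(ppi_target_distance(c("p1", "p9"), "p3", g), 2)
  expect_equal(ppi_target_distance("p9", "p8", g), Inf)

  set.seed(77)
  cases <- 0
  while (cases < 1000) {
    n <- sample(4:12, 1)
    adj <- random_adjacency(n, runif(1, 0.1, 0.5))
    g <- adjacency_to_igraph(adj)
    for (k in 1:5) {
      t_i <- sample(names(adj), sample(3, 1))
      t_j <- sample(names(adj), sample(3, 1))
      expect_equal(ppi_target_distance(t_i, t_j, g),
                   oracle_min_target_distance(t_i, t_j, adj))
      cases <- cases + 1
    }
  }
})

test_that("target matrix averages overlap and range-normalized path components", {
  # 3 drugs on a path network: raw path distances {0, 1, 2} -> {0, 0.5, 1}
  adj <- list(p1 = "p2", p2 = c("p1", "p3"), p3 = "p2")
  g <- adjacency_to_igraph(adj)
  targets <- list(dA = c("p1", "p2"), dB = c("p2", "p3"), dC = "p3")
  # raw path: A-B share p2 -> 0; B-C share p3 -> 0; A-C: p2-p3 -> 1
  k <- target_dissimilarity_matrix(targets, g)
  expect_valid_dissim(k)
  raw_path <- c(AB = 0, AC = 1, BC = 0)
  norm_path <- (raw_path - min(raw_path)) / diff(range(raw_path))
  overlap <- c(AB = target_overlap_dissimilarity(targets$dA, targets$dB),
               AC = target_overlap_dissimilarity(targets$dA, targets$dC),
               BC = target_overlap_dissimilarity(targets$dB, targets$dC))
  expect_equal(unname(k["dA", "dB"]), unname((overlap + norm_path) / 2)[1])
  expect_equal(unname(k["dA", "dC"]), unname((overlap + norm_path) / 2)[2])
  expect_equal(unname(k["dB", "dC"]), unname((overlap + norm_path) / 2)[3])

  # identical target sets -> 0 entry; empty set -> error
  k2 <- target_dissimilarity_matrix(list(d1 = "p1", d2 = "p1"), g)
  expect_equal(unname(k2["d1", "d2"]), 0)
  expect_error(
    target_dissimilarity_matrix(list(d1 = "p1", d2 = character(0)), g),
    "d2")
})

test_that("unreachable target pairs get the longest-finite-plus-one sentinel", {
  # two components: p1-p2 and p3-p4; plus an isolated drug target p9
  adj <- list(p1 = "p2", p2 = "p1", p3 = "p4", p4 = "p3", p9 = character(0))
  g <- adjacency_to_igraph(adj)
  targets <- list(d1 = c("p1"), d2 = c("p2"), d3 = c("p3"), d4 = "p9")
  k <- target_dissimilarity_matrix(targets, g)
  expect_valid_dissim(k)
  # raw paths: d1-d2 = 1 (finite max), cross-component pairs = 2 (sentinel)
  # after range normalization the sentinel pairs share the maximum 1;
  # all target sets are disjoint, so the overlap component is 1 throughout
  overlap <- 1 - diag(4)
  dimnames(overlap) <- dimnames(k)
  path_part <- 2 * unclass(k) - overlap
  expect_equal(unname(path_part["d1", "d2"]), 0)   # (1 - 1)/(2 - 1)
  expect_equal(unname(path_part["d1", "d3"]), 1)
  expect_equal(unname(path_part["d1", "d4"]), 1)
})

test_that("signed rank profile orders genes as significance demands", {
  p <- c(gA = 0.001, gB = 0.9, gC = 0.001)
  s <- c(gA = 1, gB = 1, gC = -1)
  prof <- signed_rank_profile(p, s)
  expect_equal(prof$ranks, c(gA = 1, gB = 2, gC = 3))
  expect_equal(prof$weights, 1 - p)

  # literal key instead ranks the high-p up-regulated gene first
  lit <- signed_rank_profile(p, s, rank_key = "literal")
  expect_equal(unname(lit$ranks["gB"]), 1)

  # total tie: all p = 1
  tieprof <- signed_rank_profile(c(g1 = 1, g2 = 1, g3 = 1),
                                 c(g1 = 1, g2 = -1, g3 = 1))
  expect_equal(unname(tieprof$ranks), rep(2, 3))

  expect_equal(signed_rank_profile(c(g = 0.2), c(g = -1))$ranks, c(g = 1))
  expect_error(signed_rank_profile(c(g = 0), c(g = 1)), "\\(0, 1\\]")
})

test_that("reversing all fold-change signs reverses the rank order", {
  set.seed(9)
  for (rep in 1:20) {
    genes <- paste0("g", 1:30)
    p <- stats::setNames(1 - runif(30), genes)
    s <- stats::setNames(sample(c(-1, 1), 30, TRUE), genes)
    fwd <- signed_rank_profile(p, s)$ranks
    rev <- signed_rank_profile(p, -s)$ranks
    expect_equal(unname(fwd + rev), rep(31, 30))
  }
})

test_that("raw weighted footrule matches the double-loop oracle", {
  prof <- function(r, w) structure(list(ranks = r, weights = w),
                                   class = "ranked_profile")
  # hand case: 2 genes, swapped ranks, weights 0.5
  expect_equal(wsf_dissimilarity(prof(c(1, 2), c(0.5, 0.5)),
                                 prof(c(2, 1), c(0.5, 0.5))), 1.0)
  set.seed(13)
  for (rep in 1:50) {
    p1 <- 1 - runif(20); p2 <- 1 - runif(20)
    s1 <- sample(c(-1, 1), 20, TRUE); s2 <- sample(c(-1, 1), 20, TRUE)
    a <- signed_rank_profile(p1, s1); b <- signed_rank_profile(p2, s2)
    expect_equal(wsf_dissimilarity(a, b),
                 oracle_wsf(a$ranks, b$ranks, a$weights, b$weights),
                 tolerance = 1e-10)
    expect_equal(wsf_dissimilarity(a, b), wsf_dissimilarity(b, a))
  }
})

test_that("expression dissimilarity matrix is range-normalized and gene-label invariant", {
  set.seed(21)
  n <- 6; G <- 25
  genes <- paste0("g", seq_len(G))
  expr <- list(pvals = matrix(1 - runif(n * G), n, G,
                              dimnames = list(paste0("d", 1:n), genes)),
               signs = matrix(sample(c(-1, 1), n * G, TRUE), n, G,
                              dimnames = list(paste0("d", 1:n), genes)))
  k <- wsf_dissimilarity_matrix(expr)
  expect_valid_dissim(k)
  expect_equal(min(k[row(k) != col(k)]), 0)
  expect_equal(max(k), 1)

  # permuting the gene columns of both profiles leaves the matrix unchanged
  perm <- sample(G)
  expr2 <- list(pvals = expr$pvals[, perm], signs = expr$signs[, perm])
  expect_equal(unclass(wsf_dissimilarity_matrix(expr2)), unclass(k))

  # identical profiles give a zero entry
  expr3 <- list(pvals = expr$pvals[c(1, 1, 2), ],
                signs = expr$signs[c(1, 1, 2), ])
  rownames(expr3$pvals) <- rownames(expr3$signs) <- c("a", "b", "c")
  expect_equal(unname(wsf_dissimilarity_matrix(expr3)["a", "b"]), 0)
})
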