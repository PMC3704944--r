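test_that("the cohort spec validates its parameters", {
  expect_error(cohort_spec(), "seed")
  expect_error(cohort_spec(n_classes = 1, seed = 1), "2 classes")
  expect_error(cohort_spec(mislabel_fraction = 1.5, seed = 1), "fractions")
  expect_error(cohort_spec(n_genes = 50, de_genes_per_class = 10,
                           n_classes = 10, seed = 1), "gene universe")
  expect_error(cohort_spec(n_proteins = 10, targets_per_class_module = 6,
                           seed = 1), "network size")
})

test_that("generated cohorts are deterministic and carry the planted structure", {
  spec <- cohort_spec(n_classes = 3, drugs_per_class = 5, fp_length = 64,
                      n_proteins = 100, ppi_edge_prob = 0.06,
                      n_genes = 120, de_genes_per_class = 10, seed = 99)
  co <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co$fingerprints, co2$fingerprints)
  expect_identical(co$expr, co2$expr)
  expect_identical(co$targets, co2$targets)
  expect_identical(igraph::as_edgelist(co$ppi),
                   igraph::as_edgelist(co2$ppi))

  expect_equal(nrow(co$fingerprints), 15)
  expect_true(all(co$fingerprints %in% 0:1))
  expect_true(all(lengths(co$targets) >= 2))
  expect_true(all(co$expr$pvals > 0 & co$expr$pvals <= 1))
  expect_true(all(co$expr$signs %in% c(-1, 1)))
  expect_true(all(grepl("^[A-Z][0-9]{2}$", co$atc)))
  expect_equal(nrow(co$truth), 0)   # no mislabelling requested

  # class target modules are connected subgraphs of the network
  for (cl in unique(co$atc)) {
    members <- names(co$atc)[co$atc == cl]
    module <- unique(unlist(co$targets[members]))
    sub <- igraph::induced_subgraph(co$ppi, module)
    expect_true(igraph::is_connected(sub))
  }
})

test_that("zero flip rate collapses within-class chemical dissimilarity", {
  co <- generate_cohort(cohort_spec(
    n_classes = 3, drugs_per_class = 4, fp_length = 64, fp_flip_rate = 0,
    n_proteins = 100, ppi_edge_prob = 0.06, n_genes = 100,
    de_genes_per_class = 10, seed = 7))
  k <- chem_dissimilarity_matrix(co$fingerprints)
  same <- outer(co$atc, co$atc, "==")
  expect_equal(max(k[same]), 0)
  expect_gt(min(k[!same]), 0)
})

test_that("within-class fingerprint Hamming distances match the binomial expectation", {
  rate <- 0.05; L <- 512L
  co <- generate_cohort(cohort_spec(
    n_classes = 2, drugs_per_class = 40, fp_length = L,
    fp_flip_rate = rate, n_proteins = 100, ppi_edge_prob = 0.06,
    n_genes = 50, de_genes_per_class = 10, seed = 123))
  fp <- co$fingerprints
  ham <- c()
  for (cl in unique(co$atc)) {
    idx <- which(co$atc == cl)
    for (i in idx) for (j in idx[idx > i])
      ham <- c(ham, sum(fp[i, ] != fp[j, ]))
  }
  expected <- 2 * L * rate * (1 - rate)
  se <- sd(ham) / sqrt(length(ham))
  expect_lt(abs(mean(ham) - expected), 4 * se + 1)
})

test_that("class modules make within-class target distances smaller than between", {
  co <- make_test_cohort(seed = 5)
  ids <- names(co$targets)
  within <- c(); between <- c()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    d <- ppi_target_distance(co$targets[[i]], co$targets[[j]], co$ppi)
    if (co$atc[ids[i]] == co$atc[ids[j]]) within <- c(within, d)
    else between <- c(between, d)
  }
  expect_true(all(is.finite(within)))   # modules are connected
  expect_gt(mean(between[is.finite(between)]), mean(within))
})

test_that("planted mislabelled drugs sit nearest their feature class in the joint layer", {
  co <- make_test_cohort(n_classes = 4, per_class = 6, seed = 31,
                         mislabel_fraction = 0.1)
  expect_gt(nrow(co$truth), 0)
  ids <- rownames(co$fingerprints)
  chem <- chem_dissimilarity_matrix(co$fingerprints)
  tar <- target_dissimilarity_matrix(co$targets, co$ppi)
  gex <- wsf_dissimilarity_matrix(co$expr)
  joint <- integrate_layers(gex, tar, chem)
  feature <- stats::setNames(co$atc, ids)
  feature[co$truth$drug_id] <- co$truth$feature_class
  for (r in seq_len(nrow(co$truth))) {
    d <- co$truth$drug_id[r]
    others <- setdiff(rownames(joint), d)
    mean_to <- tapply(joint[d, others], feature[others], mean)
    expect_identical(names(which.min(mean_to)), co$truth$feature_class[r])
  }
  expect_identical(colnames(co$truth),
                   c("drug_id", "label_class", "feature_class"))
})

test_that("cohort files round-trip through the readers and are byte-stable", {
  co <- make_test_cohort(n_classes = 2, per_class = 4, seed = 17,
                         mislabel_fraction = 0.15)
  dir1 <- withr::local_tempdir()
  write_cohort(co, dir1, force = TRUE)
  expect_setequal(dir(dir1), c("fingerprints.tsv", "targets.tsv", "ppi.tsv",
                               "expr_stats.tsv", "atc.tsv", "truth.tsv"))
  back <- read_cohort(dir1)
  expect_identical(back$fingerprints, co$fingerprints)
  expect_identical(back$targets[names(co$targets)], co$targets)
  expect_equal(back$expr$pvals[rownames(co$expr$pvals),
                               colnames(co$expr$pvals)],
               co$expr$pvals)
  expect_identical(back$atc, co$atc)
  expect_identical(back$truth, co$truth)
  expect_equal(igraph::ecount(back$ppi), igraph::ecount(co$ppi))

  # same seed, second write: byte-identical files
  dir2 <- withr::local_tempdir()
  write_cohort(generate_cohort(co$spec), dir2, force = TRUE)
  for (f in dir(dir1))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))

  # refuses to clobber a non-empty directory without force
  expect_error(write_cohort(co, dir1), "force")
})
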