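#' Specification of a synthetic drug cohort
#'
#' Collects the parameters of the generator in one validated object.
#' Defaults describe a cohort with clear class structure at desk scale:
#' 10 therapeutic classes of 12 drugs; 256-bit fingerprints derived from
#' a per-class prototype (bits set with density 0.3) by independent bit
#' flips at rate 0.02; a 400-protein Erdős–Rényi interaction network
#' (edge probability 0.015, mean degree 6) with one connected 6-protein
#' target module per class from which each drug draws 2-6 targets; 1000
#' genes of which 40 per class are differentially expressed with p-values
#' scaled below 0.01 and class-coherent fold-change signs, all other
#' p-values uniform on (0, 1\]. `mislabel_fraction` of the drugs keep
#' their feature-generating class but receive the ATC label of a
#' different class, creating planted repositioning events.
#'
#' @param n_classes number of ATC classes.
#' @param drugs_per_class drugs per class.
#' @param fp_length fingerprint length in bits.
#' @param fp_prototype_density probability a prototype bit is set.
#' @param fp_flip_rate per-bit flip probability for class members.
#' @param n_proteins proteins in the interaction network.
#' @param ppi_edge_prob Erdős–Rényi edge probability.
#' @param targets_per_class_module proteins per class target module.
#' @param n_genes genes in the expression universe.
#' @param de_genes_per_class class-specific differentially expressed genes.
#' @param de_p_scale upper bound of differential p-values (p = scale * u,
#'   u uniform on (0, 1\]).
#' @param mislabel_fraction fraction of drugs deliberately mislabelled.
#' @param ppi_model `"erdos-renyi"` (default) or `"barabasi-albert"`
#'   (heavy-tailed degrees, as in real interaction networks).
#' @param seed mandatory integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_classes = 10, drugs_per_class = 12,
                        fp_length = 256, fp_prototype_density = 0.3,
                        fp_flip_rate = 0.02, n_proteins = 400,
                        ppi_edge_prob = 0.015,
                        targets_per_class_module = 6, n_genes = 1000,
                        de_genes_per_class = 40, de_p_scale = 0.01,
                        mislabel_fraction = 0,
                        ppi_model = c("erdos-renyi", "barabasi-albert"),
                        seed) {
  if (missing(seed)) stop("cohort_spec requires an explicit seed")
  ppi_model <- match.arg(ppi_model)
  spec <- list(n_classes = as.integer(n_classes),
               drugs_per_class = as.integer(drugs_per_class),
               fp_length = as.integer(fp_length),
               fp_prototype_density = fp_prototype_density,
               fp_flip_rate = fp_flip_rate,
               n_proteins = as.integer(n_proteins),
               ppi_edge_prob = ppi_edge_prob,
               targets_per_class_module = as.integer(targets_per_class_module),
               n_genes = as.integer(n_genes),
               de_genes_per_class = as.integer(de_genes_per_class),
               de_p_scale = de_p_scale,
               mislabel_fraction = mislabel_fraction,
               ppi_model = ppi_model,
               seed = as.integer(seed))
  fracs <- c(spec$fp_prototype_density, spec$fp_flip_rate,
             spec$ppi_edge_prob, spec$mislabel_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (spec$n_classes < 2L) stop("need at least 2 classes")
  if (spec$n_classes > 26L) stop("at most 26 classes supported")
  if (spec$de_genes_per_class * spec$n_classes > spec$n_genes)
    stop("too many differentially expressed genes for the gene universe")
  if (spec$targets_per_class_module * spec$n_classes > spec$n_proteins)
    stop("too many module proteins for the network size")
  if (spec$de_p_scale <= 0 || spec$de_p_scale > 1)
    stop("de_p_scale must lie in (0, 1]")
  structure(spec, class = "cohort_spec")
}

# ATC-level-2-shaped class codes: A01, B02, ...
class_codes <- function(n) paste0(LETTERS[seq_len(n)], sprintf("%02d", seq_len(n)))

# connected module of size m drawn by BFS over the still-unused vertices
sample_connected_module <- function(g, m, used) {
  free <- setdiff(igraph::V(g)$name, used)
  for (attempt in 1:50) {
    if (length(free) < m) break
    start <- sample(free, 1L)
    visited <- start
    frontier <- start
    while (length(visited) < m && length(frontier) > 0L) {
      nb_all <- unique(unlist(lapply(
        igraph::adjacent_vertices(g, frontier), function(v) v$name)))
      nb <- setdiff(intersect(nb_all, free), visited)
      if (length(nb) == 0L) break
      take <- sample(nb, min(length(nb), m - length(visited)))
      visited <- c(visited, take)
      frontier <- take
    }
    if (length(visited) == m) return(visited)
  }
  stop("infeasible module size ", m,
       " for this network; increase n_proteins or ppi_edge_prob")
}

#' Generate a synthetic drug cohort with planted class structure
#'
#' Produces all five inputs of the pipeline — fingerprints, target sets,
#' interaction network, differential-expression statistics and ATC
#' labels — with class structure planted in every layer, plus a truth
#' table of deliberately mislabelled drugs. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `drug_cohort`: list with `fingerprints`
#'   (drugs x bits 0/1 matrix), `targets` (named list), `ppi` (igraph),
#'   `expr` (list of `pvals`/`signs` matrices), `atc` (named vector),
#'   `truth` (data frame `drug_id`, `label_class`, `feature_class`, one
#'   row per planted mislabelling), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  nc <- spec$n_classes; npc <- spec$drugs_per_class
  n <- nc * npc
  codes <- class_codes(nc)
  drug_ids <- sprintf("D%03d", seq_len(n))
  feature_class <- rep(codes, each = npc)

  # interaction network and disjoint connected class target modules
  g <- if (spec$ppi_model == "erdos-renyi")
    igraph::sample_gnp(spec$n_proteins, spec$ppi_edge_prob)
  else
    igraph::sample_pa(spec$n_proteins, m = max(1L, round(
      spec$ppi_edge_prob * spec$n_proteins / 2)), directed = FALSE)
  igraph::V(g)$name <- sprintf("P%04d", seq_len(spec$n_proteins))
  modules <- list(); used <- character(0)
  for (cl in codes) {
    modules[[cl]] <- sample_connected_module(
      g, spec$targets_per_class_module, used)
    used <- c(used, modules[[cl]])
  }

  # fingerprints: class prototype + bit flips
  protos <- matrix(stats::rbinom(nc * spec$fp_length, 1L,
                                 spec$fp_prototype_density),
                   nc, spec$fp_length, dimnames = list(codes, NULL))
  # guard against an all-zero prototype at extreme settings
  zero <- rowSums(protos) == 0L
  protos[zero, 1L] <- 1L
  fp <- protos[feature_class, , drop = FALSE]
  flips <- matrix(stats::rbinom(n * spec$fp_length, 1L, spec$fp_flip_rate),
                  n, spec$fp_length)
  fp <- abs(fp - flips)
  zero <- rowSums(fp) == 0L
  fp[zero, 1L] <- 1L
  rownames(fp) <- drug_ids
  storage.mode(fp) <- "integer"

  # targets: 2..module-size proteins from the class module
  m <- spec$targets_per_class_module
  ks <- seq.int(min(2L, m), m)
  targets <- lapply(seq_len(n), function(i) {
    k <- if (length(ks) == 1L) ks else sample(ks, 1L)
    sort(sample(modules[[feature_class[i]]], k))
  })
  names(targets) <- drug_ids

  # expression: class-specific low-p genes with coherent signs
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  de_sets <- split(sample(genes, nc * spec$de_genes_per_class),
                   rep(codes, each = spec$de_genes_per_class))
  de_signs <- lapply(stats::setNames(codes, codes), function(cl)
    stats::setNames(sample(c(-1, 1), spec$de_genes_per_class,
                           replace = TRUE), de_sets[[cl]]))
  pvals <- matrix(1 - stats::runif(n * spec$n_genes), n, spec$n_genes,
                  dimnames = list(drug_ids, genes))    # uniform on (0, 1]
  signs <- matrix(sample(c(-1, 1), n * spec$n_genes, replace = TRUE),
                  n, spec$n_genes, dimnames = list(drug_ids, genes))
  for (i in seq_len(n)) {
    cl <- feature_class[i]
    de <- de_sets[[cl]]
    pvals[i, de] <- spec$de_p_scale * (1 - stats::runif(length(de)))
    signs[i, de] <- de_signs[[cl]]
  }

  # labels, with a planted mislabelled subset
  atc <- stats::setNames(feature_class, drug_ids)
  n_mis <- round(spec$mislabel_fraction * n)
  truth <- data.frame(drug_id = character(0), label_class = character(0),
                      feature_class = character(0),
                      stringsAsFactors = FALSE)
  if (n_mis > 0L) {
    planted <- sort(sample(drug_ids, n_mis))
    wrong <- vapply(planted, function(d)
      sample(setdiff(codes, feature_class[match(d, drug_ids)]), 1L),
      character(1L))
    atc[planted] <- wrong
    truth <- data.frame(drug_id = planted, label_class = unname(wrong),
                        feature_class = feature_class[match(planted, drug_ids)],
                        stringsAsFactors = FALSE)
  }

  structure(list(fingerprints = fp, targets = targets, ppi = g,
                 expr = list(pvals = pvals, signs = signs),
                 atc = atc, truth = truth, spec = spec),
            class = "drug_cohort")
}

#' @export
print.drug_cohort <- function(x, ...) {
  cat(sprintf(
    "drug_cohort: %d drugs, %d classes, %d-bit fingerprints, %d genes, %d planted mislabelling(s)\n",
    nrow(x$fingerprints), x$spec$n_classes, x$spec$fp_length,
    x$spec$n_genes, nrow(x$truth)))
  invisible(x)
}

#' Write a synthetic cohort to disk in the pipeline's file dialects
#'
#' Emits exactly `fingerprints.tsv`, `targets.tsv`, `ppi.tsv`,
#' `expr_stats.tsv`, `atc.tsv` and `truth.tsv` into `outdir`, in the
#' formats the corresponding readers accept, so the full pipeline can run
#' from files. The stored `log_fc` column carries only the sign (-1/+1);
#' magnitudes play no role downstream.
#'
#' @param cohort a `drug_cohort`.
#' @param outdir output directory, created if absent.
#' @param force overwrite a non-empty existing directory.
#' @return invisibly, the six file paths.
#' @export
write_cohort <- function(cohort, outdir, force = FALSE) {
  stopifnot(inherits(cohort, "drug_cohort"))
  if (dir.exists(outdir) && length(dir(outdir)) > 0L && !force)
    stop("output directory is not empty (use force = TRUE): ", outdir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(outdir, f)
  tsv <- function(f, header, lines)
    writeLines(c(header, lines), path(f))

  ids <- rownames(cohort$fingerprints)
  tsv("fingerprints.tsv", "drug_id\tfingerprint",
      paste(ids, apply(cohort$fingerprints, 1L, paste, collapse = ""),
            sep = "\t"))
  tsv("targets.tsv", "drug_id\tprotein_id",
      unlist(lapply(ids, function(d)
        paste(d, cohort$targets[[d]], sep = "\t"))))
  el <- igraph::as_edgelist(cohort$ppi)
  tsv("ppi.tsv", "protein_a\tprotein_b",
      if (nrow(el)) paste(el[, 1L], el[, 2L], sep = "\t") else character(0))
  genes <- colnames(cohort$expr$pvals)
  tsv("expr_stats.tsv", "drug_id\tgene_id\tp_value\tlog_fc",
      unlist(lapply(ids, function(d)
        sprintf("%s\t%s\t%.17g\t%d", d, genes,
                cohort$expr$pvals[d, ], as.integer(cohort$expr$signs[d, ])))))
  tsv("atc.tsv", "drug_id\tatc2",
      paste(ids, cohort$atc[ids], sep = "\t"))
  tsv("truth.tsv", "drug_id\tlabel_class\tfeature_class",
      if (nrow(cohort$truth))
        paste(cohort$truth$drug_id, cohort$truth$label_class,
              cohort$truth$feature_class, sep = "\t")
      else character(0))
  invisible(path(c("fingerprints.tsv", "targets.tsv", "ppi.tsv",
                   "expr_stats.tsv", "atc.tsv", "truth.tsv")))
}

#' Read a cohort back from the files written by [write_cohort()]
#'
#' @param dir directory holding the six cohort files.
#' @return list with `fingerprints`, `targets`, `ppi`, `expr`, `atc`,
#'   `truth` in the readers' native representations.
#' @export
read_cohort <- function(dir) {
  truth_tab <- read_tsv_table(file.path(dir, "truth.tsv"),
                              c("drug_id", "label_class", "feature_class"))
  list(fingerprints = read_fingerprints(file.path(dir, "fingerprints.tsv")),
       targets = read_targets(file.path(dir, "targets.tsv")),
       ppi = read_ppi(file.path(dir, "ppi.tsv")),
       expr = read_expression_stats(file.path(dir, "expr_stats.tsv")),
       atc = read_atc(file.path(dir, "atc.tsv")),
       truth = data.frame(drug_id = unname(truth_tab[, 1L]),
                          label_class = unname(truth_tab[, 2L]),
                          feature_class = unname(truth_tab[, 3L]),
                          stringsAsFactors = FALSE, row.names = NULL))
}
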