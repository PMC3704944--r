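#' Run the full repositioning pipeline on a cohort
#'
#' Chains every stage: the three dissimilarity layers are computed over
#' the drugs that carry the corresponding data (a drug needs a non-empty
#' fingerprint, a non-empty target set and an expression profile), fused
#' by elementwise mean over their common drugs, filtered to ATC classes
#' with at least `min_class_size` members, embedded by classical MDS,
#' the embedding dimension is selected by stratified cross-validated SVM
#' error, the subsampling loop accumulates per-drug prediction
#' distributions at the selected dimension, and the scored repositioning
#' report is assembled.
#'
#' @param cohort a `drug_cohort` from [generate_cohort()], or any list
#'   with elements `fingerprints`, `targets`, `ppi`, `expr`, `atc` in the
#'   readers' representations.
#' @param min_class_size minimum ATC class size kept (default 8).
#' @param folds cross-validation folds for dimension selection.
#' @param dims candidate dimensions (default: all positive-eigenvalue
#'   dimensions).
#' @param iterations subsampling iterations.
#' @param holdout held-out fraction per iteration.
#' @param seed master seed; fold assignment and subsampling draw
#'   distinct streams derived from it.
#' @param min_score minimum reported repositioning score.
#' @param rank_key passed to [wsf_dissimilarity_matrix()].
#' @param stratified passed to [bootstrap_predict()].
#' @return list of class `repositioning_result` with elements `layers`
#'   (the three matrices), `joint`, `cohort` (filtered
#'   `labelled_cohort`), `embedding`, `cv`, `dist`, `report`, `flows`,
#'   `accuracy_mode`, `accuracy_heldout`.
#' @export
run_repositioning <- function(cohort, min_class_size = 8, folds = 6,
                              dims = NULL, iterations = 1000,
                              holdout = 0.1, seed = 1, min_score = 0,
                              rank_key = "significance",
                              stratified = FALSE) {
  fp_ok <- rownames(cohort$fingerprints)[rowSums(cohort$fingerprints) > 0]
  tg_ok <- names(cohort$targets)[lengths(cohort$targets) > 0]
  ex_ok <- rownames(cohort$expr$pvals)
  common <- sort(Reduce(intersect, list(fp_ok, tg_ok, ex_ok)))
  if (length(common) < 2L)
    stop("fewer than 2 drugs carry all three data layers")

  chem <- chem_dissimilarity_matrix(cohort$fingerprints, drugs = common)
  tar <- target_dissimilarity_matrix(cohort$targets, cohort$ppi,
                                     drugs = common)
  gex <- wsf_dissimilarity_matrix(cohort$expr, drugs = common,
                                  rank_key = rank_key)
  joint <- integrate_layers(gex, tar, chem)
  filt <- filter_by_class_size(joint, cohort$atc, min_size = min_class_size)
  emb <- cmds_embed(filt$dissim)
  cv <- select_dimension(emb, filt$labels, folds = folds, dims = dims,
                         seed = seed)
  coords <- emb$coords[, seq_len(cv$selected_dim), drop = FALSE]
  dist <- bootstrap_predict(coords, filt$labels, iterations = iterations,
                            holdout = holdout, seed = seed + 1L,
                            stratified = stratified)
  report <- repositioning_report(dist, filt$labels, min_score = min_score)
  structure(list(layers = list(chem = chem, tar = tar, gex = gex),
                 joint = joint, cohort = filt, embedding = emb, cv = cv,
                 dist = dist, report = report,
                 flows = class_flow_summary(report),
                 accuracy_mode = attr(report, "accuracy"),
                 accuracy_heldout = dist$heldout_accuracy),
            class = "repositioning_result")
}

#' @export
print.repositioning_result <- function(x, ...) {
  cat(sprintf(
    paste0("repositioning_result: %d drugs, %d classes\n",
           "  positive eigenvalues: %d; selected dimension: %d (CV error %.3f)\n",
           "  mode-prediction accuracy: %.3f; heldout accuracy: %.3f\n",
           "  repositioning records: %d (%d with score 1)\n"),
    length(x$cohort$labels), length(unique(x$cohort$labels)),
    x$embedding$n_positive, x$cv$selected_dim, x$cv$selected_error,
    x$accuracy_mode, x$accuracy_heldout,
    nrow(x$report), sum(x$report$score == 1)))
  invisible(x)
}

#' Write a repositioning report as TSV
#'
#' @param report data frame from [repositioning_report()] (or the
#'   `report` element of a `repositioning_result`).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(report), collapse = "\t"), con)
  if (nrow(report))
    writeLines(sprintf("%s\t%s\t%s\t%.17g\t%d\t%s",
                       report$drug_id, report$original_atc2,
                       report$predicted_atc2, report$score,
                       report$n_eval, report$is_confirmation), con)
  invisible(path)
}
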