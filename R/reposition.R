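#' Accumulate per-drug prediction distributions by repeated subsampling
#'
#' Each iteration draws a random training subset of (1 - holdout) of the
#' drugs without replacement, trains the Gaussian-kernel SVM on it, and
#' predicts the held-out drugs; only the held-out predictions are counted
#' (set `accumulate = "all"` to also count in-sample predictions). A
#' draw whose training set covers fewer than 2 classes is resampled.
#' After the main loop, drugs that were never held out get extra
#' iterations in which they are forced into the held-out set, so every
#' drug ends with at least one prediction.
#'
#' @param coords numeric n x d coordinate matrix with drug ids as row
#'   names.
#' @param labels class labels (named vector matched by id, or aligned).
#' @param iterations number of subsampling iterations (the reference
#'   protocol uses 10,000; scale down for small cohorts).
#' @param holdout held-out fraction per iteration (default 0.1).
#' @param seed integer seed; the whole procedure is deterministic given
#'   `seed`.
#' @param stratified draw the held-out set per class instead of uniformly.
#' @param accumulate `"heldout"` (default) or `"all"`.
#' @param gamma,cost passed to [train_svm()].
#' @return object of class `prediction_dist`: list with `counts` (drugs x
#'   classes integer matrix), `n_eval` (predictions per drug),
#'   `heldout_accuracy` (fraction of all held-out predictions matching
#'   the training label), `iterations`, `resampled`, `topup`.
#' @export
bootstrap_predict <- function(coords, labels, iterations = 10000,
                              holdout = 0.1, seed = 1,
                              stratified = FALSE,
                              accumulate = c("heldout", "all"),
                              gamma = NULL, cost = 1) {
  accumulate <- match.arg(accumulate)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  labels <- align_labels(labels, rownames(coords), n)
  ids <- rownames(coords)
  if (is.null(ids)) ids <- paste0("drug", seq_len(n))
  classes <- sort(levels(labels))
  n_hold <- max(1L, ceiling(holdout * n))
  small <- table(labels) < ceiling(1 / holdout)
  if (any(small))
    warning("class(es) ", paste(names(small)[small], collapse = ", "),
            " smaller than 1/holdout; their members are rarely co-held-out")
  counts <- matrix(0L, n, length(classes), dimnames = list(ids, classes))
  correct <- 0L; total <- 0L; resampled <- 0L
  lab_chr <- as.character(labels)

  draw_holdout <- function() {
    if (!stratified) return(sample.int(n, n_hold))
    unlist(lapply(split(seq_len(n), labels), function(idx)
      idx[sample.int(length(idx), max(1L, round(holdout * length(idx))))]))
  }
  run_iteration <- function(hold) {
    train <- setdiff(seq_len(n), hold)
    if (length(unique(lab_chr[train])) < 2L) return(FALSE)
    fit <- train_svm(coords[train, , drop = FALSE], labels[train],
                     gamma = gamma, cost = cost)
    eval_idx <- if (accumulate == "all") seq_len(n) else hold
    pred <- predict_svm(fit, coords[eval_idx, , drop = FALSE])
    idx <- cbind(eval_idx, match(pred, classes))
    counts[idx] <<- counts[idx] + 1L
    hp <- pred[match(hold, eval_idx)]
    correct <<- correct + sum(hp == lab_chr[hold])
    total <<- total + length(hold)
    TRUE
  }

  set.seed(seed)
  for (it in seq_len(iterations)) {
    ok <- FALSE
    for (try in 1:100) {
      if (run_iteration(draw_holdout())) { ok <- TRUE; break }
      resampled <- resampled + 1L
    }
    if (!ok)
      stop("could not draw a training set covering 2 classes in 100 tries")
  }
  topup <- 0L
  while (any(rowSums(counts) == 0L) && topup < 100L) {
    never <- which(rowSums(counts) == 0L)
    forced <- never[seq_len(min(n_hold, length(never)))]
    extra <- setdiff(sample.int(n), forced)[seq_len(n_hold - length(forced))]
    run_iteration(c(forced, extra))
    topup <- topup + 1L
  }
  if (topup > 0L)
    message("bootstrap_predict: ", topup,
            " extra iteration(s) for never-held-out drugs")
  structure(list(counts = counts,
                 n_eval = rowSums(counts),
                 heldout_accuracy = if (total) correct / total else NA_real_,
                 iterations = iterations,
                 resampled = resampled,
                 topup = topup),
            class = "prediction_dist")
}

#' @export
print.prediction_dist <- function(x, ...) {
  cat(sprintf(
    "prediction_dist: %d drugs, %d classes, %d iteration(s); heldout accuracy %.3f\n",
    nrow(x$counts), ncol(x$counts), x$iterations, x$heldout_accuracy))
  invisible(x)
}

#' Final (mode) prediction per drug
#'
#' The most frequently predicted class per drug; its frequency among the
#' drug's predictions is the score. Ties are broken toward the
#' lexicographically smallest class and flagged.
#'
#' @param dist a `prediction_dist`.
#' @return data frame with columns `drug_id`, `predicted_atc2`, `score`,
#'   `n_eval`, `tie`.
#' @export
final_prediction <- function(dist) {
  counts <- dist$counts
  classes <- colnames(counts)   # sorted at construction
  pick <- apply(counts, 1L, which.max)
  tie <- apply(counts, 1L, function(r) sum(r == max(r)) > 1L)
  n_eval <- rowSums(counts)
  data.frame(drug_id = rownames(counts),
             predicted_atc2 = classes[pick],
             score = counts[cbind(seq_len(nrow(counts)), pick)] / n_eval,
             n_eval = n_eval,
             tie = tie,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Scored repositioning report
#'
#' One record per (drug, predicted class) pair whose class differs from
#' the drug's ATC label, was predicted at least once, and has score at
#' least `min_score`; set `include_confirmations = TRUE` to also list the
#' own-class records. The score of class c for drug j is the frequency of
#' c among j's accumulated predictions, so each drug's scores sum to 1
#' over all classes. Records are sorted by descending score, then drug
#' id. The overall mode-prediction accuracy (fraction of drugs whose most
#' frequent prediction equals their label) is attached as attribute
#' `accuracy`.
#'
#' @param dist a `prediction_dist`.
#' @param labels named character vector of ATC labels covering all drugs
#'   in `dist`.
#' @param min_score minimum reported score (default 0).
#' @param include_confirmations also report own-class records.
#' @return data frame with columns `drug_id`, `original_atc2`,
#'   `predicted_atc2`, `score`, `n_eval`, `is_confirmation`; attribute
#'   `accuracy`.
#' @export
repositioning_report <- function(dist, labels, min_score = 0,
                                 include_confirmations = FALSE) {
  counts <- dist$counts
  ids <- rownames(counts)
  missing <- setdiff(ids, names(labels))
  if (length(missing))
    stop("no label for drug(s): ", paste(missing, collapse = ", "))
  lab <- labels[ids]
  n_eval <- rowSums(counts)
  long <- data.frame(
    drug_id = rep(ids, times = ncol(counts)),
    original_atc2 = rep(unname(lab), times = ncol(counts)),
    predicted_atc2 = rep(colnames(counts), each = nrow(counts)),
    count = as.vector(counts),
    n_eval = rep(unname(n_eval), times = ncol(counts)),
    stringsAsFactors = FALSE)
  long$score <- long$count / long$n_eval
  long$is_confirmation <- long$predicted_atc2 == long$original_atc2
  keep <- long$count > 0L & long$score >= min_score &
    (include_confirmations | !long$is_confirmation)
  out <- long[keep, c("drug_id", "original_atc2", "predicted_atc2",
                      "score", "n_eval", "is_confirmation")]
  out <- out[order(-out$score, out$drug_id, out$predicted_atc2), ]
  rownames(out) <- NULL
  fp <- final_prediction(dist)
  attr(out, "accuracy") <- mean(fp$predicted_atc2 == unname(lab[fp$drug_id]))
  out
}

#' Score-weighted class-to-class repositioning flows
#'
#' Aggregates repositioning records into one row per ordered
#' (original class, predicted class) pair with the summed score, the
#' edge-list form used to draw class-flow networks. Flows are
#' direction-sensitive.
#'
#' @param records data frame from [repositioning_report()].
#' @return data frame with columns `class_from`, `class_to`,
#'   `total_score`, `n_records`, sorted by descending total score.
#' @export
class_flow_summary <- function(records) {
  records <- records[!records$is_confirmation, , drop = FALSE]
  if (nrow(records) == 0L)
    return(data.frame(class_from = character(0), class_to = character(0),
                      total_score = numeric(0), n_records = integer(0),
                      stringsAsFactors = FALSE))
  key <- interaction(records$original_atc2, records$predicted_atc2,
                     drop = TRUE, sep = "\r")
  agg <- lapply(split(records, key), function(r)
    data.frame(class_from = r$original_atc2[1L],
               class_to = r$predicted_atc2[1L],
               total_score = sum(r$score),
               n_records = nrow(r),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  out <- out[order(-out$total_score, out$class_from, out$class_to), ]
  rownames(out) <- NULL
  out
}
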