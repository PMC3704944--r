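#' Gaussian-kernel multiclass SVM on embedding coordinates
#'
#' Thin wrapper around [e1071::svm()] with radial kernel
#' \eqn{k(x, y) = \exp(-\gamma \|x - y\|^2)}, no rescaling of the inputs
#' (the cMDS coordinates already carry the geometry), and the default
#' bandwidth heuristic \eqn{\gamma = 1 / (d \cdot \mathrm{var}(coords))}
#' where the variance is taken over all coordinate entries.
#'
#' @param coords numeric n x d matrix.
#' @param labels factor or character vector of length n with at least 2
#'   distinct classes.
#' @param gamma kernel bandwidth; `NULL` for the heuristic above.
#' @param cost soft-margin cost C (default 1).
#' @return fitted [e1071::svm] model.
#' @export
train_svm <- function(coords, labels, gamma = NULL, cost = 1) {
  coords <- as.matrix(coords)
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L)
    stop("train_svm needs at least 2 classes")
  if (is.null(gamma)) gamma <- svm_gamma(coords)
  e1071::svm(x = coords, y = labels, kernel = "radial",
             gamma = gamma, cost = cost, scale = FALSE)
}

svm_gamma <- function(coords) {
  v <- stats::var(as.vector(coords))
  if (!is.finite(v) || v <= 0) return(1 / ncol(coords))
  1 / (ncol(coords) * v)
}

#' @rdname train_svm
#' @param model fitted model from `train_svm`.
#' @param newdata coordinate matrix to classify.
#' @return `predict_svm` returns a character vector of class labels.
#' @export
predict_svm <- function(model, newdata) {
  as.character(stats::predict(model, as.matrix(newdata)))
}

# class-stratified fold assignment; errors on classes smaller than k
stratified_folds <- function(labels, k, seed) {
  labels <- factor(labels)
  sizes <- table(labels)
  if (any(sizes < k))
    stop("class ", names(sizes)[which(sizes < k)[1L]], " has ",
         min(sizes), " member(s), fewer than ", k, " folds")
  folds <- integer(length(labels))
  set.seed(seed)
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Choose the embedding dimension by cross-validated SVM error
#'
#' For each candidate dimension i, the classifier is evaluated by
#' stratified k-fold cross-validation on the first i principal
#' coordinates, and the dimension minimizing the misclassification rate
#' is selected (ties broken toward the smallest dimension). The fold
#' assignment is drawn once from `seed` and reused for every dimension,
#' and the kernel bandwidth follows the same heuristic rule throughout,
#' so the error curve is comparable across dimensions.
#'
#' @param embedding a `cmds_embedding` (or bare coordinate matrix).
#' @param labels named or aligned class labels for the embedded drugs.
#' @param folds number of cross-validation folds (default 6).
#' @param dims integer vector of candidate dimensions (default
#'   `1:ncol(coords)`).
#' @param seed integer seed for the fold assignment.
#' @param gamma,cost passed to [train_svm()].
#' @return object of class `cv_curve`: list with `dims`, `errors`,
#'   `selected_dim`, `selected_error`, `folds`.
#' @export
select_dimension <- function(embedding, labels, folds = 6, dims = NULL,
                             seed = 1, gamma = NULL, cost = 1) {
  coords <- if (inherits(embedding, "cmds_embedding")) embedding$coords
            else as.matrix(embedding)
  labels <- align_labels(labels, rownames(coords), nrow(coords))
  if (is.null(dims)) dims <- seq_len(ncol(coords))
  dims <- sort(unique(as.integer(dims)))
  if (min(dims) < 1L || max(dims) > ncol(coords))
    stop("candidate dimensions outside 1..", ncol(coords))
  fold_id <- stratified_folds(labels, folds, seed)
  errors <- vapply(dims, function(d) {
    x <- coords[, seq_len(d), drop = FALSE]
    wrong <- 0L
    for (f in seq_len(folds)) {
      test <- fold_id == f
      fit <- train_svm(x[!test, , drop = FALSE], labels[!test],
                       gamma = gamma, cost = cost)
      pred <- predict_svm(fit, x[test, , drop = FALSE])
      wrong <- wrong + sum(pred != as.character(labels[test]))
    }
    wrong / length(labels)
  }, numeric(1L))
  best <- which.min(errors)   # first minimum = smallest dimension
  structure(list(dims = dims, errors = errors,
                 selected_dim = dims[best],
                 selected_error = errors[best],
                 folds = folds),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf(
    "cv_curve: %d-fold CV over %d dimensions; selected %d (error %.3f)\n",
    x$folds, length(x$dims), x$selected_dim, x$selected_error))
  invisible(x)
}

# labels given as a named vector are matched by drug id; otherwise they
# must already align positionally
align_labels <- function(labels, ids, n) {
  if (!is.null(names(labels)) && !is.null(ids)) {
    missing <- setdiff(ids, names(labels))
    if (length(missing))
      stop("no label for drug(s): ", paste(missing, collapse = ", "))
    labels <- labels[ids]
  }
  if (length(labels) != n)
    stop("labels do not align with the coordinate rows")
  factor(as.character(labels))
}
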