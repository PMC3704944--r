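#' Fuse the three dissimilarity layers into a joint matrix
#'
#' Elementwise arithmetic mean of the gene-expression, target and
#' chemical layers over the drugs common to all three, in sorted id
#' order.
#'
#' @param gex,tar,chem [dissim_matrix] objects (any drug order; only the
#'   intersection of their id sets is used).
#' @return a [dissim_matrix] over the sorted common drugs.
#' @export
integrate_layers <- function(gex, tar, chem) {
  ids <- sort(Reduce(intersect, list(rownames(gex), rownames(tar),
                                     rownames(chem))))
  if (length(ids) < 2L)
    stop("fewer than 2 drugs are shared by all three layers")
  k <- (unclass(gex)[ids, ids] + unclass(tar)[ids, ids] +
          unclass(chem)[ids, ids]) / 3
  dissim_matrix(k)
}

#' Restrict a labelled cohort to sufficiently populated ATC classes
#'
#' Drugs without a label are removed first (with a message giving their
#' count); then every drug whose ATC level-2 class has fewer than
#' `min_size` members is removed. The matrix is reduced to the matching
#' principal submatrix, preserving the relative drug order.
#'
#' @param dissim a [dissim_matrix].
#' @param labels named character vector, drug id to ATC level-2 code.
#' @param min_size minimum class size (default 8).
#' @return list of class `labelled_cohort` with elements `dissim` and
#'   `labels` (aligned to the surviving drugs).
#' @export
filter_by_class_size <- function(dissim, labels, min_size = 8) {
  ids <- rownames(dissim)
  unlabelled <- setdiff(ids, names(labels))
  if (length(unlabelled))
    message("filter_by_class_size: dropped ", length(unlabelled),
            " unlabelled drug(s)")
  ids <- setdiff(ids, unlabelled)
  lab <- labels[ids]
  sizes <- table(lab)
  keep_classes <- names(sizes)[sizes >= min_size]
  if (length(keep_classes) == 0L)
    stop("no ATC class has at least ", min_size, " members")
  ids <- ids[lab %in% keep_classes]
  structure(list(dissim = subset_dissim(dissim, ids),
                 labels = labels[ids]),
            class = "labelled_cohort")
}

#' @export
print.labelled_cohort <- function(x, ...) {
  cat(sprintf("labelled_cohort: %d drugs in %d ATC classes\n",
              length(x$labels), length(unique(x$labels))))
  print(table(x$labels))
  invisible(x)
}
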