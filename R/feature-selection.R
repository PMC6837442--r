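#' Pooled-variance two-sample t statistics per feature
#'
#' Classic equal-variance two-sample t statistic of each feature between the
#' two classes, computed only on the rows named by `indices`. Degenerate cases
#' follow fixed conventions: zero pooled variance with a nonzero mean gap gives
#' a signed infinite sentinel (such features outrank every finite-t feature);
#' zero pooled variance with zero gap gives 0.
#'
#' @param dataset a [vb_dataset].
#' @param indices row indices to use (default: all rows).
#' @return named numeric vector of t values, one per feature.
#' @export
compute_t_statistics <- function(dataset, indices = NULL) {
  dataset <- check_dataset(dataset)
  if (is.null(indices)) indices <- seq_along(dataset$labels)
  x <- dataset$features[indices, , drop = FALSE]
  y <- dataset$labels[indices]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < 2L || n0 < 2L)
    vb_stop("t statistics need both classes present with at least 2 samples each")
  x1 <- x[y == 1L, , drop = FALSE]
  x0 <- x[y == 0L, , drop = FALSE]
  gap <- colMeans(x1) - colMeans(x0)
  sp2 <- ((n1 - 1) * apply(x1, 2, var) + (n0 - 1) * apply(x0, 2, var)) / (n1 + n0 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  t <- ifelse(se > 0, gap / se, ifelse(gap == 0, 0, Inf * sign(gap)))
  names(t) <- colnames(dataset$features)
  t
}

new_selection <- function(method, selected, scores, ...) {
  structure(c(list(method = method, selected = as.integer(selected),
                   scores = scores), list(...)),
            class = "vb_selection")
}

#' @export
print.vb_selection <- function(x, ...) {
  cat(sprintf("<vb_selection> %s: %d features [%s]\n", x$method,
              length(x$selected), paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Serialize a selection or validation result to JSON
#' @param x object to serialize.
#' @param ... passed to [jsonlite::toJSON()].
#' @export
as_json <- function(x, ...) UseMethod("as_json")

#' @export
as_json.vb_selection <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA, ...)
}

#' Select the top-k features by absolute t statistic
#'
#' @inheritParams compute_t_statistics
#' @param k number of features to keep.
#' @return a `vb_selection` with `selected` ordered by decreasing `|t|`
#'   (ties broken by lower feature index) and `scores` holding all t values.
#' @export
ttest_select <- function(dataset, indices = NULL, k = 10) {
  dataset <- check_dataset(dataset)
  k <- check_count(k, "k", min = 1L)
  p <- ncol(dataset$features)
  if (k > p) vb_stop(sprintf("k = %d exceeds the %d available features", k, p))
  t <- compute_t_statistics(dataset, indices)
  ord <- order(-abs(t), seq_along(t))
  new_selection("ttest", ord[seq_len(k)], t, k = k)
}

#' SVM-RFE feature selection
#'
#' Backward elimination with a linear soft-margin SVM: starting from the full
#' feature set, each iteration fits the SVM (penalty `rfe_C`) on the rows in
#' `indices`, records the classification accuracy of the current subset, and
#' removes the `elimination_step` features with the smallest squared weight
#' (ties broken by lower feature index). The returned set is the visited subset
#' with the highest step accuracy; accuracy ties prefer the smallest subset.
#'
#' Step accuracy is measured, by default, by stratified `eval_folds`-fold CV of
#' the linear SVM on the same rows (folds reseeded per call from `seed`);
#' `eval_method = "resubstitution"` scores the training rows instead.
#'
#' @inheritParams compute_t_statistics
#' @param elimination_step features removed per iteration.
#' @param rfe_C linear SVM misclassification penalty.
#' @param eval_method how each step's accuracy is measured.
#' @param eval_folds folds for the CV evaluation.
#' @param seed seed for the evaluation folds.
#' @return a `vb_selection` with fields `selected`, `scores` (elimination rank;
#'   1 = removed first), `elimination_order` (features removed before the final
#'   set, so `elimination_order` plus `selected` is a permutation of the
#'   inputs), `full_order`, `step_accuracies` (data frame of size/accuracy),
#'   and `n_unconverged` solver-cap hits.
#' @export
svm_rfe <- function(dataset, indices = NULL, elimination_step = 1, rfe_C = 1,
                    eval_method = c("cv", "resubstitution"), eval_folds = 10,
                    seed = 1) {
  dataset <- check_dataset(dataset)
  eval_method <- match.arg(eval_method)
  if (is.null(indices)) indices <- seq_along(dataset$labels)
  x <- dataset$features[indices, , drop = FALSE]
  y <- dataset$labels[indices]
  if (length(unique(y)) < 2L) vb_stop("SVM-RFE needs both classes present")
  step <- check_count(elimination_step, "elimination_step", min = 1L)
  p <- ncol(x)
  fold <- if (eval_method == "cv" && p >= 1L) {
    make_folds(y, min(eval_folds, length(y)), derive_seed(seed, 9101L))
  } else integer(0)
  res <- cpp_svm_rfe(x, as.integer(2L * y - 1L), rfe_C, fold, step,
                     1e-3, 100000L)

  sizes <- res$sizes
  accs <- res$accuracies
  # best accuracy; ties -> smallest feature count (sizes are decreasing)
  best <- which(accs >= max(accs))
  best <- best[length(best)]
  n_removed_before <- p - sizes[best]
  full_order <- as.integer(res$order)
  removed_before <- full_order[seq_len(n_removed_before)]
  selected <- setdiff(seq_len(p), removed_before)
  # rank: position in removal order; survivors of the full run get top rank
  rank <- rep(p, p)
  rank[full_order] <- seq_along(full_order)
  # order the final set by importance (latest-removed first)
  selected <- selected[order(-rank[selected])]
  new_selection("svm-rfe", selected, rank,
                elimination_order = removed_before,
                full_order = full_order,
                step_accuracies = data.frame(size = sizes, accuracy = accs),
                step_accuracy = accs[best],
                n_unconverged = res$n_capped,
                eval_method = eval_method, rfe_C = rfe_C,
                elimination_step = step)
}

# dispatcher used by the validation schemes
select_features <- function(dataset, indices, spec, seed) {
  switch(spec$selector,
    "none" = new_selection("none", seq_len(ncol(dataset$features)), NULL),
    # pipelines clamp k to the feature count (ratio-sweep points can have p < k)
    "ttest" = ttest_select(dataset, indices,
                           k = min(spec$k, ncol(dataset$features))),
    "svm-rfe" = svm_rfe(dataset, indices, elimination_step = spec$rfe_step,
                        rfe_C = spec$rfe_C, eval_method = spec$rfe_eval,
                        eval_folds = spec$inner_folds, seed = seed),
    vb_stop(sprintf("unknown selector '%s'", spec$selector)))
}
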