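#' Model-development recipes (pipeline specifications)
#'
#' A `vb_pipeline` describes one model-development recipe: a feature selector
#' (two-sample t-test ranking, SVM-RFE, or none) and a grid-tuned classifier.
#' The two canonical presets are `"svm"` (SVM-RFE + RBF-SVM, the complex
#' pipeline) and `"logreg"` (t-test top-10 + penalized logistic, the simple
#' pipeline).
#'
#' @param selector `"ttest"`, `"svm-rfe"` or `"none"`.
#' @param classifier `"logistic"` or `"rbf-svm"`.
#' @param k features kept by the t-test selector.
#' @param rfe_C,rfe_step,rfe_eval SVM-RFE settings (see [svm_rfe()]).
#' @param grid a `vb_grid`; default [default_grid()] of the classifier.
#' @param inner_folds inner CV folds used for tuning (and RFE step scoring).
#' @param tune_feature_space for [partial_nested_tune_out()]: whether the
#'   single global tuning step sees the globally `"selected"` features
#'   (default) or `"all"` features.
#' @return a `vb_pipeline`.
#' @export
pipeline_spec <- function(selector = c("ttest", "svm-rfe", "none"),
                          classifier = c("logistic", "rbf-svm"),
                          k = 10, rfe_C = 1, rfe_step = 1,
                          rfe_eval = c("cv", "resubstitution"),
                          grid = NULL, inner_folds = 10,
                          tune_feature_space = c("selected", "all")) {
  selector <- match.arg(selector)
  classifier <- match.arg(classifier)
  if (is.null(grid)) grid <- default_grid(classifier)
  if (!inherits(grid, "vb_grid") || grid$kind != classifier)
    vb_stop("`grid` must be a `vb_grid` matching the classifier kind")
  structure(list(selector = selector, classifier = classifier, k = k,
                 rfe_C = rfe_C, rfe_step = rfe_step,
                 rfe_eval = match.arg(rfe_eval), grid = grid,
                 inner_folds = inner_folds,
                 tune_feature_space = match.arg(tune_feature_space)),
            class = "vb_pipeline")
}

#' @rdname pipeline_spec
#' @param name preset name: `"svm"` or `"logreg"`.
#' @export
preset_pipeline <- function(name) {
  switch(name,
    svm = pipeline_spec(selector = "svm-rfe", classifier = "rbf-svm"),
    logreg = pipeline_spec(selector = "ttest", classifier = "logistic"),
    vb_stop(sprintf("unknown pipeline preset '%s' (use 'svm' or 'logreg')", name)))
}

#' @export
print.vb_pipeline <- function(x, ...) {
  cat(sprintf("<vb_pipeline> selector=%s, classifier=%s (%d-combo grid, %d inner folds)\n",
              x$selector, x$classifier, nrow(x$grid$combos), x$inner_folds))
  invisible(x)
}

# ---- ledger ----------------------------------------------------------------

# each record: which rows a development/evaluation stage saw; fold 0 = global
ledger_record <- function(stage, fold, rows) {
  list(stage = stage, fold = as.integer(fold), rows = sort(as.integer(rows)))
}

#' Rows a stage saw, according to a result's ledger
#'
#' @param result a `vb_validation`.
#' @param stage `"selection"`, `"tuning"`, `"fit"` or `"evaluation"`.
#' @param fold fold number (0 = a stage performed once globally).
#' @return sorted integer row indices (empty if no such record).
#' @export
ledger_rows <- function(result, stage, fold = NULL) {
  recs <- Filter(function(r) r$stage == stage &&
                   (is.null(fold) || r$fold == fold), result$ledger)
  sort(unique(unlist(lapply(recs, `[[`, "rows"), use.names = FALSE)))
}

#' Audit a validation result for development/evaluation leakage
#'
#' For each fold, counts the evaluation rows that any development stage
#' (selection, tuning, final fit) of that fold — or any global stage — also
#' touched. Leakage-free protocols (train/test split, nested CV) must show
#' zero overlap in every fold; the deliberately leaky protocols must not.
#'
#' @param result a `vb_validation`.
#' @return data frame with one row per evaluation fold: `fold`, `n_eval`,
#'   `n_overlap`.
#' @export
audit_ledger <- function(result) {
  folds <- sort(unique(vapply(Filter(function(r) r$stage == "evaluation",
                                     result$ledger), `[[`, 0L, "fold")))
  dev_stages <- c("selection", "tuning", "fit")
  do.call(rbind, lapply(folds, function(k) {
    ev <- ledger_rows(result, "evaluation", k)
    dev <- unlist(lapply(dev_stages, function(s)
      c(ledger_rows(result, s, k), ledger_rows(result, s, 0L))), use.names = FALSE)
    data.frame(fold = k, n_eval = length(ev),
               n_overlap = length(intersect(ev, unique(dev))))
  }))
}

# ---- shared machinery ------------------------------------------------------

new_validation <- function(scheme, fold_acc, ledger, details) {
  structure(list(scheme = scheme,
                 accuracy = mean(fold_acc),
                 fold_accuracies = fold_acc,
                 ledger = ledger,
                 details = details),
            class = "vb_validation")
}

#' @export
print.vb_validation <- function(x, ...) {
  cat(sprintf("<vb_validation> %s: ACC = %.1f%% over %d fold(s)\n",
              x$scheme, x$accuracy, length(x$fold_accuracies)))
  invisible(x)
}

#' @export
as_json.vb_validation <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA, ...)
}

# full model development (selection + tuning/fit) on one row set
develop_model <- function(dataset, rows, spec, seed) {
  sel <- select_features(dataset, rows, spec, derive_seed(seed, 11L))
  tuned <- grid_search(dataset, rows, sel$selected, spec$grid,
                       inner_folds = spec$inner_folds,
                       seed = derive_seed(seed, 12L))
  list(selection = sel, tuned = tuned, features = sel$selected,
       model = tuned$model)
}

eval_rows <- function(dataset, model, features, rows) {
  accuracy_pct(predict_labels(model, dataset$features[rows, features, drop = FALSE]),
               dataset$labels[rows])
}

# ---- the five protocols ----------------------------------------------------

#' Train/test split validation
#'
#' A stratified `test_fraction` portion is set aside before any development;
#' selection, tuning and the final fit see only the training portion, and the
#' held-out portion is scored once. The gold-standard leakage-free protocol.
#'
#' @param dataset a [vb_dataset].
#' @param spec a [pipeline_spec()].
#' @param test_fraction held-out fraction (default 0.2).
#' @param seed integer seed (split, selector folds, tuning folds).
#' @return a `vb_validation` (fold_accuracies has length 1).
#' @export
train_test_split_validate <- function(dataset, spec, test_fraction = 0.2, seed = 1) {
  dataset <- check_dataset(dataset)
  test <- split_holdout(dataset$labels, test_fraction, derive_seed(seed, 1L))
  train <- setdiff(seq_along(dataset$labels), test)
  dev <- develop_model(dataset, train, spec, derive_seed(seed, 2L))
  acc <- eval_rows(dataset, dev$model, dev$features, test)
  ledger <- list(ledger_record("selection", 1L, train),
                 ledger_record("tuning", 1L, train),
                 ledger_record("fit", 1L, train),
                 ledger_record("evaluation", 1L, test))
  new_validation("split", acc, ledger,
                 list(features = dev$features, hyperparams = dev$tuned$hyperparams,
                      test_fraction = test_fraction, seed = seed))
}

#' Non-nested K-fold cross-validation (the biased protocol under study)
#'
#' Feature selection and hyperparameter tuning are performed once on all rows;
#' the resulting fixed model recipe is then refitted on each K-1 training-fold
#' set and scored on the held-out fold. Because the evaluation rows took part
#' in selection and tuning, accuracy on pure noise exceeds the 50% chance
#' level, increasingly so at small sample sizes.
#'
#' @inheritParams train_test_split_validate
#' @param K outer folds (default 10).
#' @return a `vb_validation`.
#' @export
kfold_validate <- function(dataset, spec, K = 10, seed = 1) {
  dataset <- check_dataset(dataset)
  all_rows <- seq_along(dataset$labels)
  dev <- develop_model(dataset, all_rows, spec, derive_seed(seed, 2L))
  fold <- make_folds(dataset$labels, K, derive_seed(seed, 3L))
  ledger <- list(ledger_record("selection", 0L, all_rows),
                 ledger_record("tuning", 0L, all_rows))
  acc <- numeric(max(fold))
  for (k in seq_len(max(fold))) {
    tr <- which(fold != k); te <- which(fold == k)
    m <- fit_classifier(spec$classifier, dev$tuned$hyperparams,
                        dataset$features[tr, dev$features, drop = FALSE],
                        dataset$labels[tr])
    acc[k] <- eval_rows(dataset, m, dev$features, te)
    ledger <- c(ledger, list(ledger_record("fit", k, tr),
                             ledger_record("evaluation", k, te)))
  }
  new_validation("kfold", acc, ledger,
                 list(features = dev$features, hyperparams = dev$tuned$hyperparams,
                      K = K, seed = seed))
}

#' Nested K-fold cross-validation
#'
#' Per outer fold, a complete model — selection, tuning, fit — is developed
#' from scratch on the K-1 training folds and scored on the held-out fold,
#' which no development stage touched. Unbiased at any sample size.
#'
#' @inheritParams kfold_validate
#' @return a `vb_validation`.
#' @export
nested_cv_validate <- function(dataset, spec, K = 10, seed = 1) {
  dataset <- check_dataset(dataset)
  fold <- make_folds(dataset$labels, K, derive_seed(seed, 3L))
  ledger <- list()
  acc <- numeric(max(fold))
  details <- list(K = K, seed = seed, folds = list())
  for (k in seq_len(max(fold))) {
    tr <- which(fold != k); te <- which(fold == k)
    dev <- develop_model(dataset, tr, spec, derive_seed(seed, 2L, k))
    acc[k] <- eval_rows(dataset, dev$model, dev$features, te)
    ledger <- c(ledger, list(ledger_record("selection", k, tr),
                             ledger_record("tuning", k, tr),
                             ledger_record("fit", k, tr),
                             ledger_record("evaluation", k, te)))
    details$folds[[k]] <- list(features = dev$features,
                               hyperparams = dev$tuned$hyperparams)
  }
  new_validation("nested", acc, ledger, details)
}

#' Partially nested validation: feature selection outside, tuning nested
#'
#' Feature selection runs once on all rows (the leak); per outer fold, tuning
#' and fitting use only the training folds, restricted to the globally
#' selected features.
#'
#' @inheritParams kfold_validate
#' @return a `vb_validation`.
#' @export
partial_nested_fs_out <- function(dataset, spec, K = 10, seed = 1) {
  dataset <- check_dataset(dataset)
  all_rows <- seq_along(dataset$labels)
  sel <- select_features(dataset, all_rows, spec, derive_seed(seed, 11L))
  fold <- make_folds(dataset$labels, K, derive_seed(seed, 3L))
  ledger <- list(ledger_record("selection", 0L, all_rows))
  acc <- numeric(max(fold))
  details <- list(features = sel$selected, K = K, seed = seed, folds = list())
  for (k in seq_len(max(fold))) {
    tr <- which(fold != k); te <- which(fold == k)
    tuned <- grid_search(dataset, tr, sel$selected, spec$grid,
                         inner_folds = spec$inner_folds,
                         seed = derive_seed(seed, 12L, k))
    acc[k] <- eval_rows(dataset, tuned$model, sel$selected, te)
    ledger <- c(ledger, list(ledger_record("tuning", k, tr),
                             ledger_record("fit", k, tr),
                             ledger_record("evaluation", k, te)))
    details$folds[[k]] <- list(hyperparams = tuned$hyperparams)
  }
  new_validation("fs_out", acc, ledger, details)
}

#' Partially nested validation: tuning outside, feature selection nested
#'
#' Hyperparameters are chosen once by grid search on all rows (the leak; by
#' default the global tuning sees the features selected on all rows, used
#' solely for that step — set `tune_feature_space = "all"` in the pipeline for
#' the alternative wiring). Per outer fold, selection is redone on the
#' training folds and the classifier with the global hyperparameters is
#' refitted on the training folds only.
#'
#' @inheritParams kfold_validate
#' @return a `vb_validation`.
#' @export
partial_nested_tune_out <- function(dataset, spec, K = 10, seed = 1) {
  dataset <- check_dataset(dataset)
  all_rows <- seq_along(dataset$labels)
  tune_feats <- if (spec$tune_feature_space == "selected") {
    select_features(dataset, all_rows, spec, derive_seed(seed, 11L))$selected
  } else seq_len(ncol(dataset$features))
  tuned <- grid_search(dataset, all_rows, tune_feats, spec$grid,
                       inner_folds = spec$inner_folds,
                       seed = derive_seed(seed, 12L))
  fold <- make_folds(dataset$labels, K, derive_seed(seed, 3L))
  ledger <- list(ledger_record("tuning", 0L, all_rows))
  acc <- numeric(max(fold))
  details <- list(hyperparams = tuned$hyperparams, K = K, seed = seed, folds = list())
  for (k in seq_len(max(fold))) {
    tr <- which(fold != k); te <- which(fold == k)
    sel <- select_features(dataset, tr, spec, derive_seed(seed, 11L, k))
    m <- fit_classifier(spec$classifier, tuned$hyperparams,
                        dataset$features[tr, sel$selected, drop = FALSE],
                        dataset$labels[tr])
    acc[k] <- eval_rows(dataset, m, sel$selected, te)
    ledger <- c(ledger, list(ledger_record("selection", k, tr),
                             ledger_record("fit", k, tr),
                             ledger_record("evaluation", k, te)))
    details$folds[[k]] <- list(features = sel$selected)
  }
  new_validation("tune_out", acc, ledger, details)
}

# scheme registry used by experiments and the CLI
scheme_fun <- function(name) {
  switch(name,
    split = function(dataset, spec, seed) train_test_split_validate(dataset, spec, seed = seed),
    kfold = function(dataset, spec, seed) kfold_validate(dataset, spec, seed = seed),
    nested = function(dataset, spec, seed) nested_cv_validate(dataset, spec, seed = seed),
    fs_out = function(dataset, spec, seed) partial_nested_fs_out(dataset, spec, seed = seed),
    tune_out = function(dataset, spec, seed) partial_nested_tune_out(dataset, spec, seed = seed),
    vb_stop(sprintf("unknown validation scheme '%s'", name)))
}

#' Names of the five validation protocols
#' @return character vector of scheme identifiers.
#' @export
scheme_names <- function() c("split", "kfold", "nested", "fs_out", "tune_out")
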