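#' Hyperparameter grids
#'
#' [default_grid()] builds the canonical tuning grids: for the RBF-SVM,
#' `C = 2^j, j = 1..7` crossed with `gamma = 2^i, i = -1..-7` (49 combos); for
#' logistic regression, penalty L1/L2 crossed with `C = e^i, i = 0..9`
#' (20 combos). [make_grid()] builds the grid-size-sweep variants: an `m x m`
#' RBF grid with exponents `j = 2..m+1` and `i = -2..-(m+1)`, or an `m x 2`
#' logistic grid with `m` C exponents evenly spaced over `[-4, 4]` crossed
#' with both penalties.
#'
#' Combos are stored in tie-break order: smallest `C` first, then smallest
#' `gamma` (RBF) or `L2` before `L1` (logistic). Grid search resolves score
#' ties by taking the earliest combo, i.e. the most regularized model.
#'
#' @param classifier_kind `"rbf-svm"` or `"logistic"`.
#' @param m grid size parameter (at least 2).
#' @return a `vb_grid` (list with `kind` and a `combos` data frame).
#' @export
default_grid <- function(classifier_kind) {
  switch(classifier_kind,
    "rbf-svm" = new_grid("rbf-svm", expand_rbf(2^(1:7), 2^(-(7:1)))),
    "logistic" = new_grid("logistic", expand_logistic(exp(0:9))),
    vb_stop(sprintf("unknown classifier kind '%s'", classifier_kind)))
}

#' @rdname default_grid
#' @export
make_grid <- function(classifier_kind, m) {
  m <- check_count(m, "m", min = 2L)
  switch(classifier_kind,
    "rbf-svm" = new_grid("rbf-svm", expand_rbf(2^(2:(m + 1)), 2^(-((m + 1):2)))),
    "logistic" = new_grid("logistic", expand_logistic(exp(seq(-4, 4, length.out = m)))),
    vb_stop(sprintf("unknown classifier kind '%s'", classifier_kind)))
}

new_grid <- function(kind, combos) {
  if (nrow(combos) < 1L) vb_stop("a tuning grid needs at least one combo")
  structure(list(kind = kind, combos = combos), class = "vb_grid")
}

expand_rbf <- function(C, gamma) {
  stopifnot(all(C > 0), all(gamma > 0))
  data.frame(C = rep(sort(C), each = length(gamma)), gamma = sort(gamma))
}

expand_logistic <- function(C) {
  stopifnot(all(C > 0))
  data.frame(C = rep(sort(C), each = 2), penalty = c("L2", "L1"))
}

#' @export
print.vb_grid <- function(x, ...) {
  cat(sprintf("<vb_grid> %s: %d combos\n", x$kind, nrow(x$combos)))
  invisible(x)
}

#' Grid-search hyperparameter tuning by inner K-fold CV
#'
#' Scores every combo of `grid` by the mean stratified `inner_folds`-fold CV
#' accuracy on exactly the rows in `indices`, restricted to `features`; the
#' best combo (ties: earliest in grid order, i.e. most regularized) is refitted
#' on all those rows. Deterministic given `seed`: the fold assignment is drawn
#' once and shared by all combos. `inner_folds` may exceed the per-class counts
#' (down to leave-one-out, which the fold-count sweep requires); assignments
#' then stay as class-balanced as the counts allow.
#'
#' @param dataset a [vb_dataset].
#' @param indices rows available for tuning (default: all).
#' @param features feature (column) indices the pipeline has selected.
#' @param grid a `vb_grid`.
#' @param inner_folds inner CV folds.
#' @param seed integer seed for the fold assignment.
#' @return a `vb_tuned`: chosen hyperparameters, `inner_cv_accuracy` (%), the
#'   per-combo score vector `combo_scores`, per-combo-by-fold matrix
#'   `fold_scores`, the fold assignment, and the refitted `model`.
#' @export
grid_search <- function(dataset, indices = NULL, features = NULL, grid,
                        inner_folds = 10, seed = 1) {
  dataset <- check_dataset(dataset)
  if (!inherits(grid, "vb_grid")) vb_stop("`grid` must be a `vb_grid`")
  if (is.null(indices)) indices <- seq_along(dataset$labels)
  if (is.null(features)) features <- seq_len(ncol(dataset$features))
  x <- dataset$features[indices, features, drop = FALSE]
  y <- dataset$labels[indices]
  if (length(unique(y)) < 2L) vb_stop("tuning rows must contain both classes")
  K <- check_count(inner_folds, "inner_folds", min = 2L)
  K <- min(K, nrow(x)) # leave-one-out at most
  fold <- make_folds(y, K, derive_seed(seed, 7001L))

  fold_scores <- score_grid(x, y, grid, fold)
  combo_scores <- rowMeans(fold_scores)
  best <- which.max(combo_scores) # first maximum = tie-break order
  hp <- as.list(grid$combos[best, , drop = FALSE])
  model <- fit_classifier(grid$kind, hp, x, y)
  structure(list(kind = grid$kind, hyperparams = hp,
                 inner_cv_accuracy = combo_scores[[best]],
                 combo_scores = combo_scores, fold_scores = fold_scores,
                 best_index = best, fold = fold, grid = grid,
                 features = features, model = model),
            class = "vb_tuned")
}

#' @export
print.vb_tuned <- function(x, ...) {
  cat(sprintf("<vb_tuned> %s: %s; inner-CV accuracy %.1f%%\n", x$kind,
              paste(names(x$hyperparams), unlist(lapply(x$hyperparams, format)),
                    sep = "=", collapse = ", "),
              x$inner_cv_accuracy))
  invisible(x)
}

# per-combo-by-fold accuracy matrix; fast paths per classifier family
score_grid <- function(x, y, grid, fold) {
  scores <- if (grid$kind == "rbf-svm") {
    cpp_svm_cv_grid(x, 2L * y - 1L, grid$combos$C, grid$combos$gamma,
                    fold, FALSE, 1e-3, 100000L)
  } else if (grid$kind == "logistic") {
    logreg_cv_scores(x, y, grid$combos, fold)
  } else {
    generic_cv_scores(x, y, grid, fold)
  }
  rownames(scores) <- NULL
  scores
}

# batched glmnet: one path fit per (fold, penalty) scores all C values at once
logreg_cv_scores <- function(x, y, combos, fold) {
  K <- max(fold)
  n <- nrow(x)
  scores <- matrix(NA_real_, nrow(combos), K)
  for (k in seq_len(K)) {
    tr <- which(fold != k); te <- which(fold == k)
    xtr <- pad_glmnet(x[tr, , drop = FALSE])
    xte <- pad_glmnet(x[te, , drop = FALSE])
    ytr <- y[tr]
    for (pen in unique(combos$penalty)) {
      rows <- which(combos$penalty == pen)
      lam <- 1 / (length(tr) * combos$C[rows])
      ord <- order(lam, decreasing = TRUE)
      fit <- quiet_glmnet(glmnet::glmnet(
        xtr, factor(ytr, levels = c(0, 1)), family = "binomial",
        alpha = if (pen == "L1") 1 else 0,
        lambda = lam[ord], standardize = FALSE, thresh = 1e-8, maxit = 1e5))
      eta <- predict(fit, xte, s = lam[ord], type = "link", exact = FALSE)
      pred <- (eta >= 0) * 1L
      acc <- 100 * colMeans(pred == y[te])
      scores[rows[ord], k] <- acc
    }
  }
  scores
}

# reference path: one fit_classifier()/predict_labels() per combo and fold;
# slow but shared-code-free, kept as the oracle route for tests
generic_cv_scores <- function(x, y, grid, fold) {
  K <- max(fold)
  scores <- matrix(NA_real_, nrow(grid$combos), K)
  for (c in seq_len(nrow(grid$combos))) {
    hp <- as.list(grid$combos[c, , drop = FALSE])
    for (k in seq_len(K)) {
      tr <- which(fold != k); te <- which(fold == k)
      m <- fit_classifier(grid$kind, hp, x[tr, , drop = FALSE], y[tr])
      scores[c, k] <- accuracy_pct(predict_labels(m, x[te, , drop = FALSE]), y[te])
    }
  }
  scores
}
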