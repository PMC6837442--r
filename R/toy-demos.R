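#' Toy demonstration: parameter tuning on pooled data overfits
#'
#' Per repeat, 10 standard-normal samples (5 per class, 2 features) are drawn
#' and one row per class is designated as the validation pair (a balanced pair
#' makes 50% the exact null). Two grid-tuned RBF-SVMs are built from the same
#' draw with identical settings: the *pooled* model is tuned and fitted on all
#' 10 rows (so the validation pair leaked into development), the *held-out*
#' model only on the 8 training rows. Both are scored on the validation pair;
#' both are also scored on their own training rows. Inner tuning folds on 10
#' (or 8) rows degrade to leave-one-out.
#'
#' With enough repeats the pooled model scores far above chance on "validation"
#' data it helped fit (~81%), the held-out model sits at the 50% chance level,
#' and both fit their training noise well above 80%.
#'
#' @param reps number of repeats (paper scale: 1000).
#' @param seed master seed.
#' @param tune if `FALSE`, skip grid search and use fixed `C = 2`,
#'   `gamma = 0.5` (sensitivity mode).
#' @param grid tuning grid (default [default_grid()] for the RBF-SVM).
#' @return a `vb_toy_boundary`: per-repeat accuracy table and aggregate means
#'   `pooled_validation`, `heldout_validation`, `pooled_training`,
#'   `heldout_training`, `training` (both models averaged).
#' @export
toy_boundary <- function(reps = 1000, seed = 1, tune = TRUE,
                         grid = default_grid("rbf-svm")) {
  reps <- check_count(reps, "reps", min = 1L)
  labels <- rep(c(1L, 0L), each = 5L)
  val <- c(5L, 10L) # one row per class
  tr_b <- setdiff(1:10, val)
  res <- matrix(NA_real_, reps, 4,
                dimnames = list(NULL, c("pooled_val", "heldout_val",
                                        "pooled_train", "heldout_train")))
  for (r in seq_len(reps)) {
    x <- withr::with_seed(derive_seed(seed, 21L, r),
                          matrix(rnorm(20), 10, 2))
    d <- new_dataset(x, labels, list(generator = "toy", seed = seed, rep = r))
    fit_one <- function(rows, sub_seed) {
      if (tune) {
        grid_search(d, rows, 1:2, grid, inner_folds = 10,
                    seed = derive_seed(seed, 22L, r, sub_seed))$model
      } else {
        fit_classifier("rbf-svm", list(C = 2, gamma = 0.5),
                       d$features[rows, , drop = FALSE], d$labels[rows])
      }
    }
    mA <- fit_one(1:10, 1L)
    mB <- fit_one(tr_b, 2L)
    res[r, ] <- c(eval_rows(d, mA, 1:2, val), eval_rows(d, mB, 1:2, val),
                  eval_rows(d, mA, 1:2, 1:10), eval_rows(d, mB, 1:2, tr_b))
  }
  agg <- colMeans(res)
  structure(list(per_repeat = as.data.frame(res),
                 pooled_validation = agg[["pooled_val"]],
                 heldout_validation = agg[["heldout_val"]],
                 pooled_training = agg[["pooled_train"]],
                 heldout_training = agg[["heldout_train"]],
                 training = mean(c(res[, "pooled_train"], res[, "heldout_train"])),
                 reps = reps, seed = seed, tuned = tune),
            class = "vb_toy_boundary")
}

#' @export
print.vb_toy_boundary <- function(x, ...) {
  cat(sprintf(paste0("<vb_toy_boundary> %d repeats\n",
                     "  pooled model:   validation %.1f%%, training %.1f%%\n",
                     "  held-out model: validation %.1f%%, training %.1f%%\n"),
              x$reps, x$pooled_validation, x$pooled_training,
              x$heldout_validation, x$heldout_training))
  invisible(x)
}

#' Toy demonstration: feature selection on pooled data overfits
#'
#' Gaussian-noise data of `n` samples (balanced classes); per repeat a
#' stratified `val_fraction` of rows is held out. For feature pools of
#' `pool_sizes` features, the top `k` features by absolute t statistic are
#' selected either on all rows (pooled regime) or on the training rows only
#' (split regime). The mean `|t|` of the selected features is then recomputed
#' separately on the training and on the validation rows.
#'
#' Pooled selection makes the held-out rows look discriminative (validation
#' mean `|t|` grows with the pool size); split selection leaves them at the
#' chance level expected for independent noise.
#'
#' @param pool_sizes feature-pool sizes (paper: 20 to 100).
#' @param reps repeats per pool size (paper: 100).
#' @param n samples per dataset (balanced; paper: 50).
#' @param k features selected.
#' @param val_fraction held-out fraction (paper: 0.2).
#' @param seed master seed.
#' @return a `vb_toy_selection` with a tidy `summary` data frame (per pool
#'   size and regime: mean selected `|t|` on training and validation rows)
#'   and the per-repeat table `raw`.
#' @export
toy_selection <- function(pool_sizes = seq(20, 100, 10), reps = 100, n = 50,
                          k = 10, val_fraction = 0.2, seed = 1) {
  if (any(pool_sizes < k)) vb_stop("`k` must not exceed the smallest pool size")
  if (is.unsorted(pool_sizes, strictly = TRUE))
    vb_stop("`pool_sizes` must be strictly increasing")
  rows <- list()
  for (i in seq_along(pool_sizes)) {
    p <- pool_sizes[i]
    for (r in seq_len(reps)) {
      d <- generate_noise(n, p, derive_seed(seed, 31L, i, r))
      val <- split_holdout(d$labels, val_fraction, derive_seed(seed, 32L, i, r))
      tr <- setdiff(seq_len(n), val)
      mean_abs_t <- function(sel, idx)
        mean(abs(compute_t_statistics(d, idx)[sel]))
      sel_pooled <- ttest_select(d, seq_len(n), k = k)$selected
      sel_split <- ttest_select(d, tr, k = k)$selected
      rows[[length(rows) + 1L]] <- data.frame(
        pool_size = p, run = r,
        pooled_train = mean_abs_t(sel_pooled, tr),
        pooled_val = mean_abs_t(sel_pooled, val),
        split_train = mean_abs_t(sel_split, tr),
        split_val = mean_abs_t(sel_split, val))
    }
  }
  raw <- do.call(rbind, rows)
  agg <- stats::aggregate(raw[c("pooled_train", "pooled_val",
                                "split_train", "split_val")],
                          by = raw["pool_size"], FUN = mean)
  structure(list(raw = raw, summary = agg, pool_sizes = pool_sizes,
                 reps = reps, n = n, k = k, val_fraction = val_fraction,
                 seed = seed),
            class = "vb_toy_selection")
}

#' @export
print.vb_toy_selection <- function(x, ...) {
  cat(sprintf("<vb_toy_selection> pools %s; %d repeats\n",
              paste(range(x$pool_sizes), collapse = "-"), x$reps))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Class-decision grid over a 2-D mesh
#'
#' Evaluates a fitted 2-feature model over a regular mesh, for decision
#' boundary pictures.
#'
#' @param model a `vb_model` trained on two features.
#' @param xlim,ylim mesh ranges.
#' @param n mesh resolution per axis.
#' @return list with vectors `x`, `y` and an `n x n` integer label matrix `z`
#'   (`z[i, j]` is the prediction at `(x[i], y[j])`).
#' @export
render_boundary <- function(model, xlim = c(-3, 3), ylim = c(-3, 3), n = 100) {
  xs <- seq(xlim[1], xlim[2], length.out = n)
  ys <- seq(ylim[1], ylim[2], length.out = n)
  mesh <- cbind(rep(xs, times = n), rep(ys, each = n))
  colnames(mesh) <- model$features[1:2]
  z <- matrix(predict_labels(model, mesh), n, n)
  list(x = xs, y = ys, z = z)
}
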