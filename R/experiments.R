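#' Experiment configuration for the Monte-Carlo sweeps
#'
#' Describes one sweep: which design variable is manipulated, at which values,
#' which pipelines and validation schemes are compared, and how many fresh
#' datasets are drawn per design point. At every point all schemes and
#' pipelines share the same `runs_per_point` datasets, so between-scheme
#' comparisons are paired by construction.
#'
#' @param variable one of `"sample_size"`, `"n_features"`, `"grid_size"`,
#'   `"n_folds"`, `"ratio"`, `"discriminable_sample_size"`.
#' @param values sweep values (for `"ratio"`, the ratio values; the sample
#'   sizes then come from `n_samples`).
#' @param pipelines named list of [pipeline_spec()] objects (or preset names).
#' @param schemes validation schemes to run (see [scheme_names()]).
#' @param runs_per_point datasets drawn per design point (paper scale: 50).
#' @param seed master seed; all randomness derives from it.
#' @param n_samples fixed sample size for the fixed-N sweeps (default 100),
#'   or the sample-size vector for the ratio sweep.
#' @param n_features noise feature count where fixed (default 50).
#' @return a `vb_experiment_config`.
#' @export
experiment_config <- function(variable, values, pipelines, schemes = "kfold",
                              runs_per_point = 50, seed = 1,
                              n_samples = 100, n_features = 50) {
  variable <- match.arg(variable, c("sample_size", "n_features", "grid_size",
                                    "n_folds", "ratio", "discriminable_sample_size"))
  if (length(values) < 1L) vb_stop("`values` must be non-empty")
  runs_per_point <- check_count(runs_per_point, "runs_per_point", min = 2L)
  if (is.character(pipelines)) {
    pipelines <- stats::setNames(lapply(pipelines, preset_pipeline), pipelines)
  }
  if (is.null(names(pipelines)) || any(names(pipelines) == ""))
    vb_stop("`pipelines` must be a named list")
  for (p in pipelines) if (!inherits(p, "vb_pipeline"))
    vb_stop("each pipeline must be a `vb_pipeline`")
  schemes <- vapply(schemes, function(s) { scheme_fun(s); s }, "")
  if (variable %in% c("sample_size", "discriminable_sample_size") &&
      any(values %% 2 != 0))
    vb_stop("sample sizes must be even (balanced classes)")
  structure(list(variable = variable, values = values, pipelines = pipelines,
                 schemes = unname(schemes), runs_per_point = runs_per_point,
                 seed = seed, n_samples = n_samples, n_features = n_features),
            class = "vb_experiment_config")
}

#' Run a configured sweep
#'
#' Iterates design points x runs x pipelines x schemes. Per (point, run) one
#' dataset is generated and shared by every scheme and pipeline compared at
#' that point. Returns the raw tidy accuracy table, per-cell summaries
#' (mean, 95% CI, one-sample t vs the 50% chance level, share of 100% runs)
#' and pairwise between-scheme tests (unpaired two-sample t-tests as reported
#' in the source analyses, with the paired variant alongside).
#'
#' @param config a [experiment_config()].
#' @param quiet suppress per-point progress messages.
#' @return a `vb_sweep` with elements `raw`, `summary`, `pairwise`, `config`.
#' @export
run_sweep <- function(config, quiet = TRUE) {
  if (!inherits(config, "vb_experiment_config"))
    vb_stop("`config` must come from experiment_config()")
  points <- sweep_points(config)
  rows <- vector("list", nrow(points) * config$runs_per_point *
                   length(config$pipelines) * length(config$schemes))
  ri <- 0L
  for (i in seq_len(nrow(points))) {
    pt <- points[i, ]
    t0 <- Sys.time()
    for (r in seq_len(config$runs_per_point)) {
      dseed <- derive_seed(config$seed, 100L + i, r)
      dataset <- if (config$variable == "discriminable_sample_size") {
        generate_discriminable(pt$n_samples, dseed, n_features = pt$n_features)
      } else {
        generate_noise(pt$n_samples, pt$n_features, dseed)
      }
      for (pi in seq_along(config$pipelines)) {
        spec <- point_pipeline(config$pipelines[[pi]], config$variable, pt)
        for (si in seq_along(config$schemes)) {
          vseed <- derive_seed(config$seed, 200L + i, r, pi, si)
          vr <- scheme_fun(config$schemes[si])(dataset, spec, vseed)
          ri <- ri + 1L
          rows[[ri]] <- data.frame(pipeline = names(config$pipelines)[pi],
                                   scheme = config$schemes[si],
                                   point = pt$label, value = pt$value,
                                   n_samples = pt$n_samples,
                                   n_features = pt$n_features,
                                   run = r, accuracy = vr$accuracy)
        }
      }
    }
    if (!quiet)
      message(sprintf("[%s = %s] done in %.1fs", config$variable, points$label[i],
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  raw <- do.call(rbind, rows[seq_len(ri)])
  structure(list(raw = raw, summary = summarize_sweep(raw),
                 pairwise = pairwise_sweep(raw), config = config),
            class = "vb_sweep")
}

# expand the design points of a sweep into a data frame
sweep_points <- function(config) {
  v <- config$variable
  if (v %in% c("sample_size", "discriminable_sample_size")) {
    data.frame(label = as.character(config$values), value = config$values,
               n_samples = config$values, n_features = config$n_features)
  } else if (v == "n_features") {
    data.frame(label = as.character(config$values), value = config$values,
               n_samples = config$n_samples, n_features = config$values)
  } else if (v == "ratio") {
    grid <- expand.grid(ratio = config$values, n_samples = config$n_samples)
    data.frame(label = sprintf("ratio=%s,N=%d", format(grid$ratio), grid$n_samples),
               value = grid$ratio, n_samples = grid$n_samples,
               n_features = pmax(1L, as.integer(round(grid$ratio * grid$n_samples))))
  } else { # grid_size, n_folds
    data.frame(label = as.character(config$values), value = config$values,
               n_samples = config$n_samples, n_features = config$n_features)
  }
}

# apply a point's variable to the pipeline (grid size, inner fold count)
point_pipeline <- function(spec, variable, pt) {
  if (variable == "grid_size") {
    spec$grid <- make_grid(spec$classifier, pt$value)
  } else if (variable == "n_folds") {
    spec$inner_folds <- pt$value
  }
  spec
}

summarize_sweep <- function(raw) {
  cells <- unique(raw[c("pipeline", "scheme", "point", "value",
                        "n_samples", "n_features")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    acc <- raw$accuracy[raw$pipeline == cell$pipeline &
                          raw$scheme == cell$scheme & raw$point == cell$point]
    s <- summarize_accuracy(acc)
    cbind(cell, data.frame(runs = length(acc), mean = s$mean,
                           ci_lo = s$ci_lo, ci_hi = s$ci_hi,
                           ci_width = s$ci_hi - s$ci_lo,
                           t = s$t, p = s$p, degenerate = s$degenerate,
                           freq100 = mean(acc == 100)))
  }))
  rownames(out) <- NULL
  out
}

pairwise_sweep <- function(raw) {
  out <- list()
  for (pl in unique(raw$pipeline)) {
    for (pt in unique(raw$point)) {
      sub <- raw[raw$pipeline == pl & raw$point == pt, ]
      sch <- unique(sub$scheme)
      if (length(sch) < 2L) next
      for (a in seq_along(sch)) for (b in seq_along(sch)) {
        if (a >= b) next
        xa <- sub$accuracy[sub$scheme == sch[a]][order(sub$run[sub$scheme == sch[a]])]
        xb <- sub$accuracy[sub$scheme == sch[b]][order(sub$run[sub$scheme == sch[b]])]
        tt <- tryCatch(stats::t.test(xa, xb, var.equal = TRUE),
                       error = function(e) NULL)
        pt2 <- tryCatch(stats::t.test(xa - xb), error = function(e) NULL)
        out[[length(out) + 1L]] <- data.frame(
          pipeline = pl, point = pt, scheme_a = sch[a], scheme_b = sch[b],
          mean_diff = mean(xa) - mean(xb),
          t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
          p = if (is.null(tt)) NA_real_ else tt$p.value,
          p_paired = if (is.null(pt2)) NA_real_ else pt2$p.value)
      }
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' @export
print.vb_sweep <- function(x, ...) {
  cat(sprintf("<vb_sweep> %s: %d points x %d runs; schemes: %s\n",
              x$config$variable, length(unique(x$raw$point)),
              x$config$runs_per_point, paste(x$config$schemes, collapse = ", ")))
  invisible(x)
}

# ---- the six sweeps --------------------------------------------------------

check_variable <- function(config, expected) {
  if (!inherits(config, "vb_experiment_config"))
    vb_stop("`config` must come from experiment_config()")
  if (!config$variable %in% expected)
    vb_stop(sprintf("config variable '%s' does not match this sweep (expected %s)",
                    config$variable, paste(expected, collapse = "/")))
  config
}

#' The six study sweeps
#'
#' Thin wrappers over [run_sweep()] that check the configured design variable:
#' sample size on pure noise (all five schemes), feature count, tuning-grid
#' size and inner-fold count at fixed N (K-fold only), feature-to-sample
#' ratio, and sample size on discriminable data (K-fold vs nested vs split,
#' with CI-width and perfect-accuracy series in the summary). Paper-scale and
#' `*-quick` presets are available from [preset_experiment()].
#'
#' @inheritParams run_sweep
#' @return a `vb_sweep`.
#' @export
run_sample_size_sweep <- function(config, quiet = TRUE)
  run_sweep(check_variable(config, "sample_size"), quiet)

#' @rdname run_sample_size_sweep
#' @export
run_feature_count_sweep <- function(config, quiet = TRUE)
  run_sweep(check_variable(config, "n_features"), quiet)

#' @rdname run_sample_size_sweep
#' @export
run_grid_size_sweep <- function(config, quiet = TRUE)
  run_sweep(check_variable(config, "grid_size"), quiet)

#' @rdname run_sample_size_sweep
#' @export
run_folds_sweep <- function(config, quiet = TRUE)
  run_sweep(check_variable(config, "n_folds"), quiet)

#' @rdname run_sample_size_sweep
#' @export
run_ratio_sweep <- function(config, quiet = TRUE)
  run_sweep(check_variable(config, "ratio"), quiet)

#' @rdname run_sample_size_sweep
#' @export
run_discriminable_sweep <- function(config, quiet = TRUE)
  run_sweep(check_variable(config, "discriminable_sample_size"), quiet)

#' Summarize an accuracy sample
#'
#' Mean, 95% t-interval (`mean +/- t[0.975, R-1] * SD / sqrt(R)`) and the
#' two-sided one-sample t-test against the 50% chance level. A zero-variance
#' sample yields a zero-width interval and a degenerate-test flag.
#'
#' @param x numeric accuracy sample (%), length at least 2.
#' @return list with `mean`, `ci_lo`, `ci_hi`, `t`, `p`, `df`, `degenerate`.
#' @export
summarize_accuracy <- function(x) {
  if (length(x) < 2L) vb_stop("need at least 2 accuracy values to summarize")
  m <- mean(x)
  s <- sd(x)
  df <- length(x) - 1L
  if (s == 0) {
    return(list(mean = m, ci_lo = m, ci_hi = m, t = NA_real_, p = NA_real_,
                df = df, degenerate = TRUE))
  }
  half <- qt(0.975, df) * s / sqrt(length(x))
  tt <- (m - 50) / (s / sqrt(length(x)))
  list(mean = m, ci_lo = m - half, ci_hi = m + half,
       t = tt, p = 2 * pt(-abs(tt), df), df = df, degenerate = FALSE)
}

#' Least-squares polynomial trend fit
#'
#' The plotting aid used for sweep trend lines: an order-`order` polynomial
#' fitted by ordinary least squares (order is reduced when fewer than
#' `order + 1` distinct points are available, giving exact interpolation at
#' `order + 1` points).
#'
#' @param x,y coordinates of the points.
#' @param order polynomial order (default 5).
#' @return named coefficient vector, constant term first.
#' @export
fit_trend <- function(x, y, order = 5) {
  if (length(x) != length(y)) vb_stop("`x` and `y` lengths differ")
  deg <- min(order, length(unique(x)) - 1L)
  if (deg < 1L) return(c(c0 = mean(y)))
  fit <- lm(y ~ poly(x, degree = deg, raw = TRUE))
  stats::setNames(coef(fit), paste0("c", 0:deg))
}

#' Paper-scale and quick experiment presets
#'
#' Publication-scale presets encode the study settings exactly (50 runs per
#' point, the full point grids); `*-quick` presets downscale runs and points,
#' never the protocol logic.
#'
#' @param name preset name; one of `"fig3-svm"`, `"fig3-logreg"`,
#'   `"fig3-quick"`, `"fig4-features"`, `"fig5-features"`, `"fig4-grid"`,
#'   `"fig5-grid"`, `"fig4-folds"`, `"fig5-folds"`, `"fig6-svm"`,
#'   `"fig6-logreg"`, `"fig7"`, `"fig7-quick"`, `"quick"`.
#' @param seed master seed stored in the config.
#' @return a `vb_experiment_config`.
#' @export
preset_experiment <- function(name, seed = 1) {
  both_sel <- function(cls) list(
    "svm-rfe" = pipeline_spec(selector = "svm-rfe", classifier = cls),
    "ttest" = pipeline_spec(selector = "ttest", classifier = cls))
  switch(name,
    "fig3-svm" = experiment_config("sample_size", seq(20, 1000, 20), "svm",
                                   schemes = scheme_names(), runs_per_point = 50,
                                   seed = seed),
    "fig3-logreg" = experiment_config("sample_size", seq(20, 1000, 20), "logreg",
                                      schemes = scheme_names(), runs_per_point = 50,
                                      seed = seed),
    "fig3-quick" = ,
    "quick" = experiment_config("sample_size", c(20, 60, 100), "logreg",
                                schemes = scheme_names(), runs_per_point = 10,
                                seed = seed),
    "fig4-features" = experiment_config("n_features", seq(20, 200, 20),
                                        both_sel("rbf-svm"), runs_per_point = 50,
                                        seed = seed),
    "fig5-features" = experiment_config("n_features", seq(20, 200, 20),
                                        both_sel("logistic"), runs_per_point = 50,
                                        seed = seed),
    "fig4-grid" = experiment_config("grid_size", 2:20, both_sel("rbf-svm"),
                                    runs_per_point = 50, seed = seed),
    "fig5-grid" = experiment_config("grid_size", c(2, 5, 10, 20, 50, 100, 150, 200),
                                    both_sel("logistic"), runs_per_point = 50,
                                    seed = seed),
    "fig4-folds" = experiment_config("n_folds", c(2, 3, 4, 5, 8, 10, 15, 20, 30, 40, 50, 100),
                                     both_sel("rbf-svm"), runs_per_point = 50,
                                     seed = seed),
    "fig5-folds" = experiment_config("n_folds", c(2, 3, 4, 5, 8, 10, 15, 20, 30, 40, 50, 100),
                                     both_sel("logistic"), runs_per_point = 50,
                                     seed = seed),
    "fig6-svm" = experiment_config("ratio", c(1/3, 1/2, 1, 2, 3, 10, 20), "svm",
                                   runs_per_point = 50, seed = seed,
                                   n_samples = c(14, 22, 42, 66, 100, 148, 222, 334, 446)),
    "fig6-logreg" = experiment_config("ratio", c(1/3, 1/2, 1, 2, 3, 10, 20), "logreg",
                                      runs_per_point = 50, seed = seed,
                                      n_samples = c(14, 22, 42, 66, 100, 148, 222, 334, 446)),
    "fig7" = experiment_config("discriminable_sample_size", seq(20, 1000, 20), "svm",
                               schemes = c("kfold", "nested", "split"),
                               runs_per_point = 50, seed = seed),
    "fig7-quick" = experiment_config("discriminable_sample_size", c(40, 100), "svm",
                                     schemes = c("kfold", "nested", "split"),
                                     runs_per_point = 3, seed = seed),
    vb_stop(sprintf("unknown experiment preset '%s'", name)))
}
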