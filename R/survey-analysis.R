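#' Load a literature-survey table
#'
#' One row per surveyed study with the columns `study` (unique id), `n`
#' (sample size, participants), `accuracy` (reported %, in (0, 100]), `year`,
#' `modality` (`brain imaging`, `motion tracking` or `other`) and
#' `classifier`. A validation error lists every offending row.
#'
#' @param source a CSV path or a data frame with the required columns.
#' @return a validated `vb_survey` data frame.
#' @export
load_survey <- function(source) {
  df <- if (is.character(source)) read.csv(source, check.names = FALSE) else as.data.frame(source)
  required <- c("study", "n", "accuracy", "year", "modality", "classifier")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    vb_stop(sprintf("survey table is missing columns: %s", paste(missing, collapse = ", ")))
  bad <- which(!is.finite(df$n) | df$n < 2 |
                 !is.finite(df$accuracy) | df$accuracy <= 0 | df$accuracy > 100)
  if (anyDuplicated(df$study))
    bad <- union(bad, which(duplicated(df$study) | duplicated(df$study, fromLast = TRUE)))
  if (length(bad) > 0L)
    vb_stop(sprintf("invalid survey rows (need n >= 2, accuracy in (0,100], unique study ids): %s",
                    paste(sort(bad), collapse = ", ")))
  class(df) <- c("vb_survey", "data.frame")
  df
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' One-sample KS test against a normal distribution with mean and SD estimated
#' from the data, with the Dallal-Wilkinson (1986) p-value approximation
#' (the composite-hypothesis correction; a plain known-parameter KS test is
#' available via `estimated = FALSE`).
#'
#' @param x numeric sample (n >= 5 for the corrected p-value).
#' @param estimated estimate mean/SD from the data (Lilliefors) or treat the
#'   standardized sample as fully specified.
#' @return list with `D`, `p` and `n`.
#' @export
ks_normality_test <- function(x, estimated = TRUE) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 5L) vb_stop("need at least 5 observations")
  if (sd(x) == 0) return(list(D = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  z <- sort((x - mean(x)) / sd(x))
  Fz <- pnorm(z)
  D <- max(pmax(seq_len(n) / n - Fz, Fz - (seq_len(n) - 1) / n))
  if (!estimated) {
    p <- suppressWarnings(stats::ks.test(z, "pnorm")$p.value)
    return(list(D = D, p = p, n = n, degenerate = FALSE))
  }
  # Dallal & Wilkinson (1986) approximation as used by standard Lilliefors
  # implementations; for n > 100 rescale D and use the n = 100 formula
  nd <- if (n > 100) { Dn <- D * (n / 100)^0.49; 100 } else { Dn <- D; n }
  p <- exp(-7.01256 * Dn^2 * (nd + 2.78019) + 2.99587 * Dn *
             sqrt(nd + 2.78019) - 0.122119 + 0.974598 / sqrt(nd) + 1.67997 / nd)
  if (p > 0.1) {
    KK <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * D
    p <- if (KK <= 0.302) 1
    else if (KK <= 0.5) 2.76773 - 19.828315 * KK + 80.709644 * KK^2 -
      138.55152 * KK^3 + 81.218052 * KK^4
    else if (KK <= 0.9) -4.901232 + 40.662806 * KK - 97.490286 * KK^2 +
      94.029866 * KK^3 - 32.355711 * KK^4
    else if (KK <= 1.31) 6.198765 - 19.558097 * KK + 23.186922 * KK^2 -
      12.234627 * KK^3 + 2.423045 * KK^4
    else 0
  }
  list(D = D, p = min(max(p, 0), 1), n = n, degenerate = FALSE)
}

#' Survey statistics: reported accuracy versus sample size
#'
#' Computes the summary statistics of the literature survey: KS normality
#' tests of the sample sizes on the raw and the log10 scale, the Pearson
#' correlation between log10 sample size and reported accuracy (with df and
#' R^2 from the simple linear fit), the Spearman rank correlation on the raw
#' sample sizes, the median sample size, and per-modality Pearson
#' correlations (modalities with fewer than 3 studies are flagged and
#' skipped).
#'
#' @param table a `vb_survey` (or anything [load_survey()] accepts).
#' @return a `vb_survey_stats` list.
#' @export
survey_statistics <- function(table) {
  df <- load_survey(table)
  if (nrow(df) < 3L) vb_stop("need at least 3 studies")
  logn <- log10(df$n)
  const <- sd(df$accuracy) == 0 || sd(logn) == 0
  pear <- if (const) NULL else cor.test(logn, df$accuracy, method = "pearson")
  spear <- if (const) NULL else
    suppressWarnings(cor.test(df$n, df$accuracy, method = "spearman"))
  per_mod <- lapply(split(df, df$modality), function(sub) {
    if (nrow(sub) < 3L || sd(sub$accuracy) == 0 || sd(log10(sub$n)) == 0)
      return(list(n_studies = nrow(sub), skipped = TRUE))
    ct <- cor.test(log10(sub$n), sub$accuracy, method = "pearson")
    list(n_studies = nrow(sub), skipped = FALSE, r = unname(ct$estimate),
         df = unname(ct$parameter), p = ct$p.value)
  })
  structure(list(
    n_studies = nrow(df),
    median_n = median(df$n),
    ks_raw = ks_normality_test(df$n),
    ks_log10 = ks_normality_test(logn),
    pearson = if (const) list(degenerate = TRUE) else
      list(r = unname(pear$estimate), df = unname(pear$parameter),
           p = pear$p.value, r2 = unname(pear$estimate)^2),
    spearman = if (const) list(degenerate = TRUE) else
      list(rho = unname(spear$estimate), p = spear$p.value),
    by_modality = per_mod,
    degenerate = const), class = "vb_survey_stats")
}

#' @export
print.vb_survey_stats <- function(x, ...) {
  cat(sprintf("<vb_survey_stats> %d studies, median N = %s\n", x$n_studies,
              format(x$median_n)))
  if (!isTRUE(x$degenerate)) {
    cat(sprintf("  KS raw N: D = %.2f, p = %.3g; KS log10 N: D = %.2f, p = %.3g\n",
                x$ks_raw$D, x$ks_raw$p, x$ks_log10$D, x$ks_log10$p))
    cat(sprintf("  Pearson r(%d) = %.2f, p = %.3g, R2 = %.2f; Spearman rho = %.2f, p = %.3g\n",
                x$pearson$df, x$pearson$r, x$pearson$p, x$pearson$r2,
                x$spearman$rho, x$spearman$p))
  }
  invisible(x)
}

#' @export
as_json.vb_survey_stats <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA, ...)
}

#' Generate a synthetic survey fixture
#'
#' A stand-in for the surveyed-studies table, for testing without the real
#' supplement: sample sizes are log-uniform on 20..2000 (so positively
#' skewed on the raw scale), and accuracy is
#' `intercept + slope * log10(n) + N(0, noise_sd)`, clipped to (50, 100].
#'
#' @param n_studies number of studies.
#' @param slope accuracy change per decade of sample size (negative to emulate
#'   the small-sample optimism the survey shows).
#' @param noise_sd residual SD of the accuracy values.
#' @param seed integer seed.
#' @param intercept accuracy intercept at n = 1.
#' @return a `vb_survey` data frame.
#' @export
make_survey_fixture <- function(n_studies = 55, slope = -15, noise_sd = 5,
                                seed = 1, intercept = 115) {
  n_studies <- check_count(n_studies, "n_studies", min = 3L)
  withr::with_seed(seed, {
    n <- round(10^runif(n_studies, log10(20), log10(2000)))
    acc <- intercept + slope * log10(n) + rnorm(n_studies, 0, noise_sd)
    acc <- pmin(pmax(acc, 50.5), 100)
    modality <- sample(c("brain imaging", "motion tracking", "other"),
                       n_studies, replace = TRUE, prob = c(0.7, 0.1, 0.2))
    classifier <- sample(c("SVM", "logistic regression", "neural network", "other"),
                         n_studies, replace = TRUE, prob = c(0.5, 0.2, 0.15, 0.15))
    load_survey(data.frame(study = sprintf("synthetic-%03d", seq_len(n_studies)),
                           n = n, accuracy = round(acc, 1),
                           year = sample(2005:2019, n_studies, replace = TRUE),
                           modality = modality, classifier = classifier))
  })
}
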