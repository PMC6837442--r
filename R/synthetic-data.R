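#' Synthetic dataset container
#'
#' A `vb_dataset` bundles an `N x p` feature matrix, balanced binary labels
#' (`1` = the class that carries any mean shift, `0` = the reference class),
#' and a `meta` record sufficient to regenerate the identical dataset.
#' Rows are generated class-blocked and then shuffled by the seed, so nothing
#' downstream can silently rely on input order.
#'
#' @name vb_dataset
NULL

new_dataset <- function(features, labels, meta) {
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  structure(list(features = features, labels = as.integer(labels), meta = meta),
            class = "vb_dataset")
}

check_dataset <- function(x) {
  if (!inherits(x, "vb_dataset")) vb_stop("expected a `vb_dataset` object")
  x
}

gen_checks <- function(n_samples, n_features) {
  if (length(n_samples) != 1L || !is.finite(n_samples) ||
      n_samples != round(n_samples) || n_samples < 4L || n_samples %% 2 != 0)
    vb_stop("`n_samples` must be an even integer >= 4: classes are balanced ",
            "with exactly n_samples/2 samples each")
  n <- as.integer(n_samples)
  p <- check_count(n_features, "n_features", min = 1L)
  list(n = n, p = p)
}

#' Generate a pure-noise dataset
#'
#' All entries are i.i.d. standard normal and bear no relationship to the
#' balanced binary labels, so any validation protocol free of leakage should
#' estimate 50% accuracy.
#'
#' @param n_samples even number of samples, at least 4 (half per class).
#' @param n_features number of features.
#' @param seed integer seed; the dataset is a deterministic function of it.
#' @return a [vb_dataset].
#' @export
#' @examples
#' d <- generate_noise(20, 50, seed = 1)
#' table(d$labels)
generate_noise <- function(n_samples, n_features, seed) {
  dims <- gen_checks(n_samples, n_features)
  generate_gaussian(dims$n, dims$p, n_informative = 0L, mean_shift = 0,
                    seed = seed, generator = "noise")
}

#' Generate a discriminable dataset
#'
#' `n_informative` columns have class-conditional mean `mean_shift` in class 1
#' and 0 in class 0; the remaining columns are pure noise for both classes.
#' Defaults follow the canonical setting: 50 features of which 10 carry a mean
#' shift of 0.5 (unit SD throughout). Informative column indices are recorded
#' in `meta$informative`.
#'
#' @inheritParams generate_noise
#' @param n_informative number of shifted columns (0 degenerates to noise).
#' @param mean_shift class-1 mean of the informative columns.
#' @return a [vb_dataset].
#' @export
generate_discriminable <- function(n_samples, seed, n_features = 50,
                                   n_informative = 10, mean_shift = 0.5) {
  dims <- gen_checks(n_samples, n_features)
  ni <- check_count(n_informative, "n_informative", min = 0L)
  if (ni > dims$p) vb_stop("`n_informative` must not exceed `n_features`")
  generate_gaussian(dims$n, dims$p, n_informative = ni, mean_shift = mean_shift,
                    seed = seed, generator = "discriminable")
}

# shared generator: draw the noise block, add the shift to class-1 rows of the
# informative columns, then shuffle rows. A zero shift reproduces the noise
# family bit-for-bit at the same seed.
generate_gaussian <- function(n, p, n_informative, mean_shift, seed, generator) {
  out <- withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p)
    labels <- rep(c(1L, 0L), each = n %/% 2L)
    if (n_informative > 0L && mean_shift != 0) {
      inf_cols <- seq_len(n_informative)
      x[labels == 1L, inf_cols] <- x[labels == 1L, inf_cols] + mean_shift
    }
    perm <- sample(n)
    list(x = x[perm, , drop = FALSE], labels = labels[perm])
  })
  meta <- list(generator = generator, n_samples = n, n_features = p,
               n_informative = n_informative, mean_shift = mean_shift,
               seed = as.integer(seed),
               informative = if (n_informative > 0L) seq_len(n_informative) else integer(0))
  new_dataset(out$x, out$labels, meta)
}

#' Regenerate a dataset from its meta record
#'
#' @param meta either a `vb_dataset` or its `meta` list.
#' @return a [vb_dataset] identical (bit-for-bit) to the original.
#' @export
regenerate_dataset <- function(meta) {
  if (inherits(meta, "vb_dataset")) meta <- meta$meta
  switch(meta$generator,
    noise = generate_noise(meta$n_samples, meta$n_features, meta$seed),
    discriminable = generate_discriminable(meta$n_samples, meta$seed,
                                           n_features = meta$n_features,
                                           n_informative = meta$n_informative,
                                           mean_shift = meta$mean_shift),
    vb_stop(sprintf("cannot regenerate datasets of generator kind '%s'", meta$generator)))
}

#' @export
print.vb_dataset <- function(x, ...) {
  cat(sprintf("<vb_dataset> %d x %d (%s, seed %s); labels: %d/%d\n",
              nrow(x$features), ncol(x$features), x$meta$generator,
              format(x$meta$seed), sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Write / read a dataset as CSV
#'
#' Plain-text interchange with header `f1..fp,label`. The meta record is not
#' round-tripped; a dataset read back carries a `csv` generator tag.
#'
#' @param dataset a [vb_dataset].
#' @param path file path.
#' @export
write_dataset_csv <- function(dataset, path) {
  dataset <- check_dataset(dataset)
  df <- as.data.frame(dataset$features)
  df$label <- dataset$labels
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- read.csv(path)
  if (!"label" %in% names(df)) vb_stop("CSV is missing the `label` column")
  labels <- as.integer(df$label)
  if (!all(labels %in% c(0L, 1L))) vb_stop("`label` must be coded 0/1")
  x <- as.matrix(df[setdiff(names(df), "label")])
  if (!all(is.finite(x))) vb_stop("features must be finite with no missing values")
  new_dataset(x, labels, list(generator = "csv", path = path,
                              n_samples = nrow(x), n_features = ncol(x)))
}
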