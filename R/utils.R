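#' @useDynLib valbias, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var cor cor.test lm coef pnorm qt pt predict quantile median
#' @importFrom utils read.csv write.csv packageVersion
NULL

vb_stop <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    vb_stop(sprintf("`%s` must be a single integer >= %d (got %s)",
                    name, min, paste(format(x), collapse = ",")))
  as.integer(x)
}

#' Derive a child seed from a master seed
#'
#' Every stochastic operation in the package derives its own seed from a single
#' master seed and a path of integer identifiers (e.g. sweep point, run index,
#' scheme index) through a fixed multiplicative-congruential mix. Runs are
#' therefore reproducible independent of execution order, and all derived seeds
#' stay below 2^31.
#'
#' @param seed master seed (single integer).
#' @param ... integer path components identifying the consumer.
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, 3, 7)
derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in ids) s <- (s * 69069 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}

# Fold assignment: seeded shuffle within class blocks, then a single global
# round-robin pass. Exactly stratified whenever K <= per-class counts; for
# larger K (up to leave-one-out) it degrades to the most balanced assignment
# possible. Fold sizes always differ by at most one.
make_folds <- function(labels, K, seed) {
  n <- length(labels)
  K <- check_count(K, "K", min = 2L)
  if (K > n) vb_stop(sprintf("K = %d folds exceed the %d available samples", K, n))
  ord <- withr::with_seed(seed, {
    unlist(lapply(sort(unique(labels)), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > 1L) sample(idx) else idx
    }), use.names = FALSE)
  })
  fold <- integer(n)
  fold[ord] <- (seq_len(n) - 1L) %% K + 1L
  fold
}

# stratified holdout: returns test-row indices of approximately frac * n rows
split_holdout <- function(labels, frac, seed) {
  if (!is.numeric(frac) || frac <= 0 || frac >= 1)
    vb_stop("`test_fraction` must be in (0, 1)")
  classes <- sort(unique(labels))
  test <- withr::with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      idx <- which(labels == cl)
      k <- round(frac * length(idx))
      if (k < 1L || k >= length(idx))
        vb_stop("degenerate train/test split: each class needs >= 1 sample on both sides")
      sample(idx, k)
    }), use.names = FALSE)
  })
  sort(test)
}
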