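make_dataset <- function(x, labels) {
  valbias:::new_dataset(as.matrix(x), labels,
                        list(generator = "manual", seed = NA))
}

test_that("t statistics match the pooled-variance textbook formula", {
  # class 1: {1, 2}; class 0: {3, 4}: means 1.5 / 3.5, pooled var 0.5,
  # SE = sqrt(0.5 * (1/2 + 1/2)) = 1/sqrt(2), t = -2 / (1/sqrt(2)) = -2*sqrt(2)
  d <- make_dataset(cbind(c(1, 2, 3, 4)), c(1L, 1L, 0L, 0L))
  expect_equal(unname(compute_t_statistics(d)), -2 * sqrt(2), tolerance = 1e-12)

  # random instances against a brute-force oracle written from the formula
  for (s in 1:5) {
    d <- generate_noise(30, 8, seed = s)
    y <- d$labels
    oracle <- apply(d$features, 2, function(col) {
      a <- col[y == 1L]; b <- col[y == 0L]
      sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
        (length(a) + length(b) - 2)
      (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    })
    expect_equal(unname(compute_t_statistics(d)), unname(oracle), tolerance = 1e-10)
  }
})

test_that("degenerate features get the documented sentinels", {
  y <- rep(c(1L, 0L), each = 4)
  d <- make_dataset(cbind(label_copy = y, constant = 2, noise = rnorm(8)), y)
  t <- compute_t_statistics(d)
  expect_identical(unname(t[1]), Inf)
  expect_identical(unname(t[2]), 0)
  expect_identical(ttest_select(d, k = 1)$selected, 1L)

  expect_error(compute_t_statistics(d, indices = which(y == 1L)), "both classes")
})

test_that("ttest_select equals brute-force top-k and handles edges", {
  for (s in 1:5) {
    d <- generate_noise(26, 15, seed = 100 + s)
    k <- 1 + (s %% 14)
    sel <- ttest_select(d, k = k)
    t <- compute_t_statistics(d)
    brute <- order(-abs(t), seq_along(t))[seq_len(k)]
    expect_identical(sel$selected, as.integer(brute))
  }
  d <- generate_noise(20, 10, seed = 1)
  expect_identical(sort(ttest_select(d, k = 10)$selected), 1:10) # p = k
  expect_length(unique(ttest_select(generate_noise(20, 50, 2), k = 10)$selected), 10)
  expect_error(ttest_select(d, k = 11), "exceeds")
})

test_that("selectors depend only on the rows named by `indices`", {
  d <- generate_noise(40, 12, seed = 7)
  rows <- 1:30
  mutated <- d
  mutated$features[31:40, ] <- 1e3 * matrix(rnorm(10 * 12), 10)
  expect_identical(ttest_select(d, rows, k = 5), ttest_select(mutated, rows, k = 5))
  expect_identical(svm_rfe(d, rows, seed = 3), svm_rfe(mutated, rows, seed = 3))
})

test_that("SVM-RFE bookkeeping: permutation, elimination count, p = 1", {
  d <- generate_noise(30, 12, seed = 11)
  r <- svm_rfe(d, seed = 5)
  expect_identical(sort(c(r$elimination_order, r$selected)), 1:12)
  expect_length(r$elimination_order, 12 - length(r$selected))
  expect_identical(sort(c(r$full_order, r$selected[which.max(
    r$scores[r$selected])])), 1:12)
  expect_identical(r$step_accuracies$size, 12:1)
  expect_equal(r$step_accuracy, max(r$step_accuracies$accuracy))
  # ties in step accuracy must resolve to the smallest subset
  best_sizes <- r$step_accuracies$size[
    r$step_accuracies$accuracy == max(r$step_accuracies$accuracy)]
  expect_identical(length(r$selected), min(best_sizes))

  d1 <- generate_noise(20, 1, seed = 2)
  r1 <- svm_rfe(d1, seed = 1)
  expect_identical(r1$selected, 1L)
  expect_length(r1$elimination_order, 0)

  expect_error(svm_rfe(d, indices = which(d$labels == 1L)), "both classes")
})

test_that("SVM-RFE retains a strongly informative feature (Monte-Carlo)", {
  hits <- 0L
  for (s in 1:100) {
    d <- generate_discriminable(40, seed = 9000 + s, n_features = 6,
                                n_informative = 1, mean_shift = 2)
    r <- svm_rfe(d, seed = s)
    hits <- hits + (1L %in% r$selected)
  }
  expect_gte(hits, 95L)
})

test_that("elimination step > 1 removes chunks and still covers all features", {
  d <- generate_noise(30, 9, seed = 13)
  r <- svm_rfe(d, elimination_step = 3, seed = 2)
  expect_identical(r$step_accuracies$size, c(9L, 6L, 3L, 1L))
  expect_identical(sort(c(r$elimination_order, r$selected)), 1:9)
})

test_that("selection results serialize to JSON", {
  d <- generate_noise(20, 6, seed = 3)
  j <- jsonlite::fromJSON(as_json(svm_rfe(d, seed = 1)))
  expect_identical(j$method, "svm-rfe")
  expect_true(all(c("selected", "scores", "elimination_order",
                    "step_accuracies") %in% names(j)))
})
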