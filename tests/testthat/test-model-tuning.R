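test_that("default grids encode the canonical hyperparameter spaces", {
  g <- default_grid("rbf-svm")
  expect_identical(nrow(g$combos), 49L)
  expect_setequal(unique(g$combos$C), 2^(1:7))
  expect_setequal(unique(g$combos$gamma), 2^(-(1:7)))

  gl <- default_grid("logistic")
  expect_identical(nrow(gl$combos), 20L)
  expect_setequal(unique(gl$combos$C), exp(0:9))
  expect_setequal(unique(gl$combos$penalty), c("L1", "L2"))
  # tie-break order: C ascending, L2 before L1
  expect_identical(gl$combos$penalty[1:2], c("L2", "L1"))
  expect_true(!is.unsorted(gl$combos$C))

  expect_error(default_grid("forest"), "unknown")
})

test_that("make_grid expands the sweep grids per the caption rules", {
  g2 <- make_grid("rbf-svm", 2)
  expect_setequal(unique(g2$combos$C), c(4, 8))
  expect_setequal(unique(g2$combos$gamma), c(1 / 4, 1 / 8))
  expect_identical(nrow(make_grid("rbf-svm", 20)$combos), 400L)

  gl <- make_grid("logistic", 200)
  expect_identical(nrow(gl$combos), 400L)
  ex <- sort(unique(log(gl$combos$C)))
  expect_equal(ex, seq(-4, 4, length.out = 200), tolerance = 1e-12)
  expect_equal(diff(ex), rep(diff(ex)[1], 199), tolerance = 1e-9) # even spacing

  expect_error(make_grid("rbf-svm", 1), "m")
})

test_that("grid search picks the best combo (brute-force rescoring oracle)", {
  d <- separable_dataset(n = 24, gap = 4)
  g <- default_grid("rbf-svm")
  gs <- grid_search(d, grid = g, inner_folds = 5, seed = 3)
  oracle <- rowMeans(valbias:::generic_cv_scores(d$features, d$labels, g, gs$fold))
  # the independently rescored value of the chosen combo must be at the top
  # (tolerance: one borderline sample flip per fold under solver tolerance)
  expect_gte(oracle[gs$best_index], max(oracle) - 2.5)
  expect_equal(gs$inner_cv_accuracy, max(gs$combo_scores))
  expect_equal(gs$inner_cv_accuracy, 100)

  # single-combo grid is returned untouched
  g1 <- valbias:::new_grid("rbf-svm", data.frame(C = 2, gamma = 0.5))
  gs1 <- grid_search(d, grid = g1, inner_folds = 5, seed = 3)
  expect_identical(gs1$hyperparams$C, 2)
  expect_identical(gs1$hyperparams$gamma, 0.5)
})

test_that("batched logistic scoring agrees with the per-fit loop", {
  d <- generate_discriminable(40, seed = 17, n_features = 8,
                              n_informative = 3, mean_shift = 1)
  g <- default_grid("logistic")
  fold <- valbias:::make_folds(d$labels, 5, 11)
  fast <- valbias:::logreg_cv_scores(d$features, d$labels, g$combos, fold)
  slow <- valbias:::generic_cv_scores(d$features, d$labels, g, fold)
  expect_lte(max(abs(fast - slow)), 100 / 8) # <= 1 borderline sample per fold
  expect_gt(mean(fast == slow), 0.9)
})

test_that("re-running grid search reproduces the recorded scores exactly", {
  d <- generate_noise(30, 6, seed = 23)
  gs1 <- grid_search(d, grid = default_grid("logistic"), seed = 5)
  gs2 <- grid_search(d, grid = default_grid("logistic"), seed = 5)
  expect_identical(gs1$combo_scores, gs2$combo_scores)
  expect_identical(gs1$hyperparams, gs2$hyperparams)
  expect_identical(gs1$fold, gs2$fold)
})

test_that("monotone nesting: a superset grid never scores lower", {
  d <- generate_noise(40, 5, seed = 31)
  full <- default_grid("logistic")
  for (keep in list(1:4, c(2, 9, 15), 1:19)) {
    sub <- valbias:::new_grid("logistic", full$combos[keep, ])
    a_sub <- grid_search(d, grid = sub, seed = 7)$inner_cv_accuracy
    a_full <- grid_search(d, grid = full, seed = 7)$inner_cv_accuracy
    expect_gte(a_full, a_sub)
  }
})

test_that("tuning touches only the rows in `indices`", {
  d <- generate_noise(40, 6, seed = 37)
  rows <- 1:28
  mutated <- d
  mutated$features[29:40, ] <- 50 + matrix(rnorm(12 * 6), 12)
  for (g in list(default_grid("logistic"), default_grid("rbf-svm"))) {
    a <- grid_search(d, rows, grid = g, seed = 2)
    b <- grid_search(mutated, rows, grid = g, seed = 2)
    expect_identical(a$combo_scores, b$combo_scores)
    expect_identical(a$hyperparams, b$hyperparams)
  }
})

test_that("grid search on noise selects the max of noisy estimates (> 50%)", {
  d <- generate_noise(100, 10, seed = 41)
  gs <- grid_search(d, grid = default_grid("rbf-svm"), seed = 13)
  expect_gte(gs$inner_cv_accuracy, 50)
})

test_that("fold handling: degeneracy to leave-one-out, errors otherwise", {
  d <- generate_noise(10, 3, seed = 43)
  gs <- grid_search(d, grid = default_grid("logistic"), inner_folds = 10, seed = 1)
  expect_identical(max(gs$fold), 10L) # leave-one-out on 10 rows
  expect_error(grid_search(d, grid = default_grid("logistic"),
                           inner_folds = 11, seed = 1), NA)
  expect_error(valbias:::make_folds(d$labels, 11, 1), "exceed")
  expect_error(valbias:::make_folds(d$labels, 1, 1), "K")
})
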