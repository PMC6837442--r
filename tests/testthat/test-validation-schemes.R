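lr <- preset_pipeline("logreg")

test_that("pipeline presets encode the two canonical recipes", {
  sv <- preset_pipeline("svm")
  expect_identical(sv$selector, "svm-rfe")
  expect_identical(sv$classifier, "rbf-svm")
  expect_identical(lr$selector, "ttest")
  expect_identical(lr$classifier, "logistic")
  expect_identical(lr$k, 10)
  expect_error(preset_pipeline("tree"), "preset")
  expect_error(pipeline_spec(grid = default_grid("rbf-svm")), "matching")
})

test_that("every scheme's ledger proves exactly the nesting it claims", {
  d <- generate_noise(60, 20, seed = 5)
  n <- length(d$labels)
  for (s in scheme_names()) {
    v <- valbias:::scheme_fun(s)(d, lr, 7)
    audit <- audit_ledger(v)
    # CV schemes evaluate every row once; the split scheme only the held 20%
    expect_equal(sum(audit$n_eval), if (s == "split") round(0.2 * n) else n)
    if (s %in% c("split", "nested")) {
      expect_true(all(audit$n_overlap == 0))
    } else {
      expect_true(all(audit$n_overlap > 0)) # deliberate leak present
    }
    # scheme-specific wiring
    if (s == "kfold") {
      expect_identical(ledger_rows(v, "selection", 0L), seq_len(n))
      expect_identical(ledger_rows(v, "tuning", 0L), seq_len(n))
    }
    if (s == "fs_out") {
      expect_identical(ledger_rows(v, "selection", 0L), seq_len(n))
      for (k in seq_along(v$fold_accuracies))
        expect_length(intersect(ledger_rows(v, "tuning", k),
                                ledger_rows(v, "evaluation", k)), 0)
    }
    if (s == "tune_out") {
      expect_identical(ledger_rows(v, "tuning", 0L), seq_len(n))
      for (k in seq_along(v$fold_accuracies))
        expect_length(intersect(ledger_rows(v, "selection", k),
                                ledger_rows(v, "evaluation", k)), 0)
    }
    # fit stage never sees its own evaluation rows (models are refitted on
    # training folds in every scheme)
    for (k in seq_along(v$fold_accuracies))
      expect_length(intersect(ledger_rows(v, "fit", k),
                              ledger_rows(v, "evaluation", k)), 0)
  }
})

test_that("fold partitions are disjoint, exhaustive and balanced", {
  labels <- rep(c(0L, 1L), each = 25)
  for (K in c(2, 5, 10, 50)) {
    fold <- valbias:::make_folds(labels, K, seed = K)
    expect_identical(sort(unique(fold)), seq_len(K))
    sizes <- as.vector(table(fold))
    expect_lte(max(sizes) - min(sizes), 1L)
    if (K <= 25) { # stratification exact when feasible
      per_class <- table(fold, labels)
      expect_lte(max(abs(per_class[, 1] - per_class[, 2])), 1)
    }
  }
})

test_that("leave-one-out K-fold gives per-fold accuracies in {0, 100}", {
  d <- generate_noise(16, 8, seed = 9)
  v <- kfold_validate(d, lr, K = 16, seed = 2)
  expect_length(v$fold_accuracies, 16)
  expect_true(all(v$fold_accuracies %in% c(0, 100)))
  expect_equal(v$accuracy, mean(v$fold_accuracies))
})

test_that("identical seed and dataset give bit-identical results", {
  d <- generate_noise(40, 15, seed = 12)
  for (s in c("split", "kfold", "nested")) {
    a <- valbias:::scheme_fun(s)(d, lr, 31)
    b <- valbias:::scheme_fun(s)(d, lr, 31)
    expect_identical(a, b)
  }
  # a different seed reshuffles the folds
  expect_false(identical(kfold_validate(d, lr, seed = 31)$ledger,
                         kfold_validate(d, lr, seed = 32)$ledger))
})

test_that("overall ACC is the unweighted mean of fold accuracies", {
  d <- generate_noise(34, 10, seed = 3) # 17 per class, uneven folds
  v <- kfold_validate(d, lr, K = 10, seed = 4)
  expect_equal(v$accuracy, mean(v$fold_accuracies))
  expect_true(all(v$fold_accuracies >= 0 & v$fold_accuracies <= 100))
})

test_that("degenerate splits are rejected", {
  d <- generate_noise(8, 5, seed = 2)
  expect_error(train_test_split_validate(d, lr, test_fraction = 0.01, seed = 1),
               "degenerate")
  expect_error(train_test_split_validate(d, lr, test_fraction = 1.2, seed = 1),
               "test_fraction")
})

test_that("bias ordering on noise: kfold >= fs_out >= tune_out ~ nested ~ split", {
  runs <- 60 # scaled from the 100-run design for the test-time budget
  acc <- matrix(NA_real_, runs, 5, dimnames = list(NULL, scheme_names()))
  for (r in seq_len(runs)) {
    d <- generate_noise(60, 50, seed = 5000 + r)
    for (s in scheme_names()) {
      acc[r, s] <- valbias:::scheme_fun(s)(d, lr, derive_seed(17, r))$accuracy
    }
  }
  m <- colMeans(acc)
  se_run <- chance_se(60, runs)          # ~1.3 points at these sizes
  expect_gt(m[["kfold"]] - 50, 3 * se_run)
  expect_gte(m[["kfold"]], m[["fs_out"]] - se_run)
  expect_gte(m[["fs_out"]], m[["tune_out"]] - se_run)
  for (s in c("tune_out", "nested", "split")) {
    expect_lt(abs(m[[s]] - 50), 4 * se_run)
  }
})

test_that("validation results serialize to JSON with the ledger", {
  d <- generate_noise(20, 8, seed = 21)
  j <- jsonlite::fromJSON(as_json(train_test_split_validate(d, lr, seed = 1)))
  expect_identical(j$scheme, "split")
  expect_true(all(c("accuracy", "fold_accuracies", "ledger") %in% names(j)))
})

test_that("tune_out supports tuning on all features as the alternative wiring", {
  d <- generate_noise(30, 12, seed = 33)
  spec2 <- pipeline_spec("ttest", "logistic", tune_feature_space = "all")
  v <- partial_nested_tune_out(d, spec2, seed = 3)
  expect_s3_class(v, "vb_validation")
  expect_true(v$accuracy >= 0 && v$accuracy <= 100)
})
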