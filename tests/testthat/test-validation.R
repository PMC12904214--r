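test_that("sensitivity and specificity come straight from the observed counts", {
  recs <- omg_training_records()
  ss <- sens_spec(recs, "edrophonium")
  expect_equal(ss$sensitivity, 29 / 31)
  expect_equal(ss$specificity, 36 / 40)
  expect_identical(as.integer(ss$counts), c(36L, 2L, 4L, 29L))
  # empty stratum: no OMG-positive case with an observed ice test
  sub <- recs[!(recs$omg == "positive" & !is.na(recs$ice)), ]
  ss2 <- sens_spec(sub, "ice")
  expect_true(is.na(ss2$sensitivity))
  expect_false(is.na(ss2$specificity))
  expect_error(sens_spec(recs, "besinger"), "binary")
})

test_that("training-set evaluation reproduces the published single-predictor errors", {
  recs <- omg_training_records()
  ach <- evaluate_predictors(default_fit, recs, "achr",
                             n_samples = 4000, seed = 1)
  expect_identical(ach$n_cases, 89L)
  expect_equal(ach$error_rate * 89, 8)
  edr <- evaluate_predictors(default_fit, recs, "edrophonium",
                             n_samples = 4000, seed = 1)
  expect_identical(edr$n_cases, 71L)
  expect_equal(edr$error_rate * 71, 6)
})

test_that("rank-based AUC equals the explicit pairwise Mann-Whitney oracle", {
  recs <- omg_training_records(seed = 5)
  for (preds in list("achr", "edrophonium", c("upgaze", "ice"))) {
    rep <- evaluate_predictors(default_fit, recs, preds,
                               n_samples = 2000, seed = 2)
    want <- oracle_auc(rep$scores$score, rep$scores$actual == "positive")
    expect_identical(rep$auc, want)
  }
})

test_that("degenerate scoring collapses the AUC to one half", {
  recs <- omg_training_records()
  sub <- recs[!is.na(recs$diplopia) & recs$diplopia == "positive", ]
  rep <- evaluate_predictors(default_fit, sub, "diplopia",
                             n_samples = 1000, seed = 4)
  expect_identical(rep$auc, 0.5)   # all scores tie
  # with one score per record, the classifier is the majority rule:
  # error equals the smaller outcome fraction
  frac_pos <- mean(sub$omg == "positive")
  expect_equal(rep$error_rate, min(frac_pos, 1 - frac_pos))
})

test_that("a single binary predictor's AUC is (sensitivity + specificity) / 2", {
  recs <- omg_training_records()
  rep <- evaluate_predictors(default_fit, recs, "edrophonium",
                             n_samples = 2000, seed = 6)
  ss <- sens_spec(recs, "edrophonium")
  expect_equal(rep$auc, (ss$sensitivity + ss$specificity) / 2)
})

test_that("evaluation enforces its preconditions", {
  recs <- omg_training_records()
  expect_error(evaluate_predictors(default_fit, recs, character()),
               "non-empty")
  expect_error(evaluate_predictors(default_fit, recs, "omg"), "outcome")
  expect_error(evaluate_predictors(default_fit, recs, "ghost"), "unknown")
  none <- recs
  none$ice <- NA_character_
  expect_error(evaluate_predictors(default_fit, none, "ice"), "complete")
})

test_that("cross-validation is seeded, fold-balanced and reproducible", {
  recs <- omg_training_records(seed = 9)
  cv1 <- cross_validate(recs, "achr", k = 5, n_samples = 1000, seed = 77)
  cv2 <- cross_validate(recs, "achr", k = 5, n_samples = 1000, seed = 77)
  expect_identical(cv1, cv2)
  expect_identical(cv1$n_cases, 89L)
  expect_identical(sum(cv1$per_fold$n), 89L)
  expect_true(max(cv1$per_fold$n) - min(cv1$per_fold$n) <= 1L)
  cv3 <- cross_validate(recs, "achr", k = 5, n_samples = 1000, seed = 78)
  expect_false(identical(cv1$per_fold, cv3$per_fold))
})

test_that("leave-one-out returns one single-record fold per case", {
  recs <- omg_training_records()[1:10, ]
  cv <- cross_validate(recs, "sex", k = 10, n_samples = 200, seed = 3)
  expect_identical(nrow(cv$per_fold), 10L)
  expect_true(all(cv$per_fold$n == 1L))
  # single-class folds cannot define an AUC but still count for the error
  expect_true(all(is.na(cv$per_fold$auc)))
  expect_identical(cv$auc_folds_skipped, 10L)
  expect_true(is.na(cv$auc))
  expect_false(anyNA(cv$per_fold$error_rate))
})
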