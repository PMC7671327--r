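test_that("multiclass metrics hit their closed forms", {
  perfect <- multiclass_metrics(c("a", "b", "a", "b"), c("a", "b", "a", "b"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)
  expect_equal(perfect$mcc, 1)
  # binary confusion TP=40, TN=30, FP=10, FN=20
  truth <- c(rep("pos", 60), rep("neg", 40))
  pred <- c(rep("pos", 40), rep("neg", 20), rep("pos", 10), rep("neg", 30))
  m <- multiclass_metrics(pred, truth)
  expect_equal(m$mcc, (40 * 30 - 10 * 20) / sqrt(50 * 60 * 40 * 50),
               tolerance = 1e-12)
  expect_equal(m$mcc, 0.4082, tolerance = 1e-3)
  # degenerate single-class predictor on balanced truth
  d <- multiclass_metrics(rep("a", 10), rep(c("a", "b"), 5))
  expect_equal(d$accuracy, 0.5)
  expect_equal(d$mcc, 0)
})

test_that("metrics are invariant under consistent class relabeling", {
  set.seed(501)
  truth <- sample(letters[1:3], 40, replace = TRUE)
  pred <- sample(letters[1:3], 40, replace = TRUE)
  m1 <- multiclass_metrics(pred, truth)
  relab <- c(a = "zz", b = "yy", c = "xx")
  m2 <- multiclass_metrics(unname(relab[pred]), unname(relab[truth]))
  expect_equal(m2$accuracy, m1$accuracy)
  expect_equal(m2$macro_f1, m1$macro_f1)
  expect_equal(m2$mcc, m1$mcc)
})

test_that("multiclass MCC equals the one-hot Pearson-correlation oracle", {
  set.seed(502)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    n <- sample(15:40, 1)
    truth <- sample(letters[1:k], n, replace = TRUE)
    pred <- sample(letters[1:k], n, replace = TRUE)
    expect_equal(multiclass_metrics(pred, truth)$mcc,
                 oracle_onehot_mcc(pred, truth), tolerance = 1e-12)
  }
})

test_that("binomial tail probabilities match closed forms", {
  expect_equal(binomial_significance(6, 6, 1 / 6), (1 / 6)^6,
               tolerance = 1e-12)
  expect_equal(binomial_significance(6, 6, 1 / 6), 2.143e-5,
               tolerance = 1e-3)
  expect_equal(binomial_significance(0, 10, 0.3), 1.0)
  expect_equal(binomial_significance(5, 10, 0.5),
               sum(choose(10, 5:10)) / 2^10, tolerance = 1e-12)
  expect_equal(binomial_significance(5, 10, 0.5), 0.6230, tolerance = 1e-4)
  expect_error(binomial_significance(5, 10, 0), "p0")
  expect_error(binomial_significance(5, 10, 1.2), "p0")
})

test_that("nested CV is bit-reproducible under a fixed seed", {
  sim <- separable_blobs(seed = 6, n_per_tissue = 10)
  r1 <- nested_cv(sim$m, model_spec("logreg_ovr"), cv_scheme(seed = 3))
  r2 <- nested_cv(sim$m, model_spec("logreg_ovr"), cv_scheme(seed = 3))
  expect_identical(r1$logreg_ovr$per_split, r2$logreg_ovr$per_split)
  expect_identical(r1$logreg_ovr$chosen_hyper, r2$logreg_ovr$chosen_hyper)
})

test_that("nested CV refuses categories smaller than the inner fold count", {
  sim <- simulate_expression(n_genes = 10, tissues = c("a", "b"),
                             samples_per_cell = 4, seed = 7)
  expect_error(nested_cv(sim$m, model_spec("logreg_ovr"),
                         cv_scheme(inner_folds = 5, seed = 1)),
               "merge categories|fewer than")
})

test_that("per-split scaling is fitted on training rows only", {
  xtr <- matrix(c(0, 10, 5, 2), ncol = 2)
  fit <- ribofam:::fit_minmax_train(xtr)
  expect_equal(fit$mins, c(0, 2))
  # a test row outside the training range maps outside [0,1]: proof the
  # test rows contributed nothing to the fitted mins/maxs
  xte <- matrix(c(1000, 100), ncol = 2)
  out <- ribofam:::apply_minmax_train(xte, fit)
  expect_gt(out[1, 1], 1)
  expect_gt(out[1, 2], 1)
  tr_scaled <- ribofam:::apply_minmax_train(xtr, fit)
  expect_equal(range(tr_scaled[, 1]), c(0, 1))
})

test_that("transfer on a verbatim training subset is perfect", {
  sim <- separable_blobs(seed = 8, n_per_tissue = 10)
  train <- sim$m
  keep <- train$sample_meta$donor %in% c("1", "2")
  test <- train
  test$values <- train$values[, keep, drop = FALSE]
  test$sample_meta <- train$sample_meta[keep, ]
  tr <- cross_species_transfer(train, test, model_spec("logreg_ovr"),
                               cv_scheme(seed = 2))
  expect_equal(tr$n_correct, tr$n_test)
  expect_equal(tr$chance_p0, 1 / 3)
  expect_equal(tr$binomial_p, (1 / 3)^tr$n_test, tolerance = 1e-12)
})

test_that("transfer demands at least two shared tissue categories", {
  sim <- simulate_expression(n_genes = 10, tissues = c("a", "b"),
                             species = c("Homo", "Gallus"),
                             samples_per_cell = 6, seed = 9)
  train <- subset_species(sim$m, "Homo")
  test <- subset_species(sim$m, "Gallus")
  test1 <- test
  keep <- test1$sample_meta$tissue_category == "a"
  test1$values <- test1$values[, keep, drop = FALSE]
  test1$sample_meta <- test1$sample_meta[keep, ]
  expect_error(cross_species_transfer(train, test1), "fewer than 2")
})

test_that("genes with missing test values are dropped before transfer", {
  sim <- simulate_expression(n_genes = 12, tissues = c("a", "b", "c"),
                             species = c("Homo", "Gallus"),
                             samples_per_cell = c(Homo = 6, Gallus = 2),
                             seed = 10)
  train <- subset_species(sim$m, "Homo")
  test <- subset_species(sim$m, "Gallus")
  test$values[1:2, 1] <- NA
  tr <- cross_species_transfer(train, test, model_spec("logreg_ovr"),
                               cv_scheme(seed = 1))
  expect_equal(length(tr$genes_used), 10L)
  expect_false(any(rownames(sim$m$values)[1:2] %in% tr$genes_used))
})
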