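# Baseline classifiers, metrics and the Friedman comparison.

test_that("every supported classifier trains and predicts on a small set", {
  ds <- separableWindows(60, len = 30L, gap = 3)
  sp <- splitTrainTest(ds, 0.25, seed = 1)
  ctrl <- list(epochs = 3L, arch = tinyArch(), nrounds = 10L, ntree = 50L)
  for (name in classifierNames()) {
    fit <- fitBaseline(name, sp$train, seed = 2, control = ctrl)
    pred <- predictLabels(fit, sp$test)
    expect_length(pred, nWindows(sp$test))
    expect_true(all(pred %in% 0:2), info = name)
  }
})

test_that("1-nearest-neighbor memorizes its training set", {
  ds <- separableWindows(30, len = 10L, gap = 1)
  fit <- fitBaseline("knn", ds, seed = 1, control = list(k = 1L))
  expect_identical(predictLabels(fit, ds), windowLabels(ds))
})

test_that("unknown classifier names are rejected with the valid list", {
  ds <- separableWindows(9, len = 10L)
  expect_error(fitBaseline("mlp", ds), "valid names.*decision_tree")
})

test_that("all classical baselines beat chance on a separable simulation", {
  ds <- separableWindows(90, len = 30L, gap = 3)
  sp <- splitTrainTest(ds, 1 / 3, seed = 3)
  n <- nWindows(sp$test)
  for (name in c("decision_tree", "random_forest", "svm", "knn", "xgboost")) {
    fit <- fitBaseline(name, sp$train, seed = 4,
                       control = list(nrounds = 10L, ntree = 50L))
    correct <- sum(predictLabels(fit, sp$test) == windowLabels(sp$test))
    p <- stats::binom.test(correct, n, p = 1 / 3,
                           alternative = "greater")$p.value
    expect_lt(p, 0.01)
  }
})

test_that("confusion matrix counts and accuracy are correct", {
  # perfect prediction -> diagonal, accuracy 1
  truth <- rep(0:2, each = 4)
  res <- confusionAndAccuracy(truth, truth)
  expect_equal(res$accuracy, 1)
  expect_equal(unname(diag(res$confusion)), c(4L, 4L, 4L))
  expect_equal(sum(res$confusion) - sum(diag(res$confusion)), 0)
  # constant prediction on balanced truth -> accuracy 1/3, first column
  allZero <- confusionAndAccuracy(truth, rep(0L, 12))
  expect_equal(allZero$accuracy, 1 / 3)
  expect_equal(unname(allZero$confusion[, 1]), c(4L, 4L, 4L))
  expect_true(all(allZero$confusion[, 2:3] == 0))
})

test_that("confusion tally matches base table() on random labels", {
  set.seed(20)
  truth <- sample(0:2, 30, replace = TRUE)
  pred <- sample(0:2, 30, replace = TRUE)
  res <- confusionAndAccuracy(truth, pred)
  oracle <- unclass(table(factor(truth, 0:2), factor(pred, 0:2)))
  expect_equal(unname(res$confusion), unname(oracle))
  # row sums equal the true class counts
  expect_equal(unname(rowSums(res$confusion)),
               unname(as.vector(table(factor(truth, 0:2)))))
  expect_error(confusionAndAccuracy(c(0, 3), c(0, 1)), "labels")
})

test_that("Friedman statistic is zero for identical columns", {
  m <- matrix(rep(c(0.5, 0.7, 0.9), 3), 3, 3)
  res <- friedmanTest(m)
  expect_equal(res@statistic, 0)
  expect_equal(res@kendallsW, 0)
  expect_equal(res@cohensF, 0)
})

test_that("Friedman test matches stats::friedman.test on small tables", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(runif(3 * 3), 3, 3)
    mine <- friedmanTest(m)
    ref <- stats::friedman.test(m)
    expect_equal(mine@statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine@pValue, ref$p.value, tolerance = 1e-12)
  }
  # with ties (mid-ranks + correction)
  m <- rbind(c(0.5, 0.5, 0.8), c(0.2, 0.4, 0.4), c(0.9, 0.1, 0.9))
  expect_equal(friedmanTest(m)@statistic,
               unname(stats::friedman.test(m)$statistic), tolerance = 1e-12)
})

test_that("an 18-run x 9-classifier table is accepted and summarized", {
  set.seed(22)
  m <- matrix(runif(18 * 9, 0.4, 0.9), 18, 9,
              dimnames = list(NULL, paste0("clf", 1:9)))
  res <- friedmanTest(m)
  expect_identical(res@nRuns, 18L)
  expect_identical(res@kClassifiers, 9L)
  expect_length(res@medians, 9L)
  expect_equal(unname(res@medians), unname(apply(m, 2, stats::median)))
  expect_gte(res@kendallsW, 0); expect_lte(res@kendallsW, 1)
  expect_equal(res@cohensF, sqrt(res@kendallsW / (1 - res@kendallsW)))
})

test_that("Friedman statistic is invariant under monotone transforms", {
  set.seed(23)
  m <- matrix(runif(12 * 4), 12, 4)
  expect_equal(friedmanTest(m)@statistic, friedmanTest(exp(3 * m))@statistic,
               tolerance = 1e-12)
  expect_error(friedmanTest(m[1, , drop = FALSE]), "at least 2 runs")
})

test_that("compareAll produces the run x classifier table deterministically", {
  ds <- separableWindows(60, len = 10L, gap = 3)
  res <- compareAll(ds, c("decision_tree", "knn"), nRuns = 3L, seed = 5,
                    control = list(k = 3L))
  expect_identical(dim(res$accuracy), c(3L, 2L))
  expect_identical(names(res$reports), c("decision_tree", "knn"))
  expect_s4_class(res$friedman, "FriedmanResult")
  # confusion matrices sum to nRuns x test size
  expect_equal(sum(confusionMatrix(res$reports$knn)), 3 * 12)
  res2 <- compareAll(ds, c("decision_tree", "knn"), nRuns = 3L, seed = 5,
                     control = list(k = 3L))
  expect_identical(res$accuracy, res2$accuracy)
})

test_that("the CNN-Transformer median matches or beats classical baselines when separable", {
  ds <- separableWindows(72, len = 30L, gap = 3)
  ctrl <- list(epochs = 8L, arch = tinyArch(), batchSize = 8L,
               nrounds = 10L, ntree = 50L)
  res <- compareAll(ds, c("decision_tree", "random_forest", "svm", "knn",
                          "xgboost", "cnn_transformer"),
                    nRuns = 10L, seed = 6, control = ctrl)
  meds <- apply(res$accuracy, 2, stats::median)
  expect_true(all(meds["cnn_transformer"] >= meds[names(meds) != "cnn_transformer"]))
})

test_that("accuracy boxplots can be exported to file", {
  set.seed(30)
  m <- matrix(runif(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  f <- withr::local_tempfile(fileext = ".png")
  accuracyBoxplot(m, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
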