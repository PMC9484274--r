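test_that("stratified split honors counts, disjointness and the seed", {
  labels <- mineralContent(defaultDataset())
  sp <- splitSpec(seed = 1)
  idx <- splitDataset(labels, sp)
  expect_length(idx$train, 70)
  expect_length(idx$test, 21)
  expect_length(intersect(idx$train, idx$test), 0)
  expect_equal(unname(c(table(labels[idx$train]))), c(12, 12, 12, 12, 9, 13))
  expect_equal(unname(c(table(labels[idx$test]))), c(4, 4, 4, 3, 3, 3))

  idx2 <- splitDataset(labels, splitSpec(seed = 2))
  expect_false(identical(idx$train, idx2$train))
  expect_equal(unname(c(table(labels[idx2$train]))),
               c(12, 12, 12, 12, 9, 13))
  expect_identical(splitDataset(labels, sp), idx)

  expect_error(
    splitDataset(labels, splitSpec(trainCounts = c(12, 12, 12, 12, 20, 13))),
    "class 80 has 12")
})

test_that("all four classifiers separate a linearly separable toy exactly", {
  set.seed(9)
  x <- matrix(c(rnorm(10, -1, 0.05), rnorm(10, 1, 0.05)), ncol = 1)
  y <- rep(c(0, 100), each = 10)
  for (kind in c("logistic", "v_svm", "neural_network", "random_forest")) {
    model <- trainClassifier(classifierSpec(kind, seed = 4), x, y)
    pred <- predictLabels(model, x)
    expect_equal(as.numeric(as.character(pred)), y,
                 label = paste(kind, "training accuracy"))
  }
  expect_error(trainClassifier(classifierSpec("v_svm"), x, rep(0, 20)),
               "single class")
})

test_that("training and prediction are deterministic given spec, data, seed", {
  set.seed(2)
  x <- matrix(rnorm(60), ncol = 2)
  y <- rep(c(0, 50, 100), each = 10)
  for (kind in c("logistic", "v_svm", "neural_network", "random_forest")) {
    p1 <- predictLabels(trainClassifier(classifierSpec(kind, seed = 7), x, y), x)
    p2 <- predictLabels(trainClassifier(classifierSpec(kind, seed = 7), x, y), x)
    expect_identical(p1, p2, label = kind)
  }
})

test_that("evaluation metrics match a hand-computed confusion example", {
  actual <- rep(c("a", "b", "c"), each = 3)
  pred <- c("a", "a", "b", "b", "b", "b", "c", "c", "a")
  r <- evaluateClassifier(pred, actual, classOrder = c("a", "b", "c"))
  expect_equal(unname(confusionMatrix(r)),
               matrix(c(2, 1, 0, 0, 3, 0, 1, 0, 2), 3, byrow = TRUE))
  expect_equal(accuracy(r), 7 / 9)
  expect_equal(perClassMetrics(r)$precision, c(2 / 3, 3 / 4, 1))
  expect_equal(precisionScore(r), (3 * 2 / 3 + 3 * 3 / 4 + 3 * 1) / 9)
  expect_equal(precisionScore(r, "macro"), mean(c(2 / 3, 3 / 4, 1)))

  # perfect predictions give a diagonal matrix
  rp <- evaluateClassifier(actual, actual)
  expect_equal(accuracy(rp), 1)
  expect_equal(unname(diag(confusionMatrix(rp))), c(3L, 3L, 3L))

  # collapsing onto one class on balanced truth scores at chance
  actual6 <- rep(c(0, 20, 40, 60, 80, 100), each = 2)
  rc <- evaluateClassifier(rep(0, 12), actual6,
                           classOrder = c(0, 20, 40, 60, 80, 100))
  expect_equal(accuracy(rc), 1 / 6)

  expect_error(evaluateClassifier(c("a", "b"), c("a")), "same length")
})

test_that("confusion bookkeeping holds for arbitrary predictions", {
  set.seed(77)
  classes <- c(0, 20, 40, 60, 80, 100)
  for (i in 1:10) {
    actual <- sample(classes, 21, replace = TRUE)
    pred <- sample(classes, 21, replace = TRUE)
    r <- evaluateClassifier(pred, actual, classOrder = classes)
    cm <- confusionMatrix(r)
    expect_equal(sum(cm), 21)
    expect_equal(sum(diag(cm)) / 21, accuracy(r))
    expect_equal(unname(rowSums(cm)), unname(c(table(factor(actual,
                                                            levels = classes)))))
  }
})

test_that("the seed-7 pipeline reproduces the study-scale performance", {
  res <- pipelineSeed7()
  cmp <- res$comparison
  expect_equal(nrow(cmp), 8)

  # every classifier clearly beats 6-class chance on both feature sets
  expect_true(all(cmp$accuracy > 1 / 6))

  # fits behind the combined features are sound
  tab <- fitTable(res$fits)
  expect_gte(median(tab$r_squared), 0.99)
  expect_true(all(tab$converged))

  # confusion matrices are aligned with the split design
  rep <- res$reports$combined$v_svm
  expect_equal(unname(rowSums(confusionMatrix(rep))), c(4, 4, 4, 3, 3, 3))
})

test_that("combined features never trail impedance-only features for the v-SVM", {
  accs <- vapply(1:5, function(s) {
    cmp <- runPipeline(seed = s, classifiers = "v_svm")$comparison
    c(combined = cmp$accuracy[cmp$mode == "combined"],
      impedance = cmp$accuracy[cmp$mode == "impedance_only"])
  }, numeric(2))
  expect_gte(median(accs["combined", ]), median(accs["impedance", ]))
  expect_gte(median(accs["combined", ]), 0.8)
})

test_that("identical master seeds reproduce the whole pipeline", {
  a <- runPipeline(seed = 3, modes = "impedance_only", classifiers = "v_svm",
                   config = tinyConfig(nPerClass = rep(4, 6)),
                   split = splitSpec(trainCounts = rep(3, 6),
                                     testCounts = rep(1, 6)))
  b <- runPipeline(seed = 3, modes = "impedance_only", classifiers = "v_svm",
                   config = tinyConfig(nPerClass = rep(4, 6)),
                   split = splitSpec(trainCounts = rep(3, 6),
                                     testCounts = rep(1, 6)))
  expect_identical(a$comparison, b$comparison)
  expect_identical(confusionMatrix(a$reports$impedance_only$v_svm),
                   confusionMatrix(b$reports$impedance_only$v_svm))
})
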