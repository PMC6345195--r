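separableCohort <- function(seed = 1, n = 40, gap = 10) {
  withr::with_seed(seed, {
    labels <- rep(c("ET", "CONTROL"), each = n / 2)
    X <- cbind(f1 = rnorm(n) + ifelse(labels == "ET", gap, 0),
               f2 = rnorm(n))
  })
  SpiralFeatures(X, labels = labels)
}

test_that("unit-norm scaling behaves globally and per training fold", {
  fm <- SpiralFeatures(cbind(a = c(3, 4), b = c(1, 0)),
                       labels = c("ET", "CONTROL"))
  g <- normalizeFeatures(fm, "global")
  expect_equal(unname(featureMatrix(g)[, "a"]), c(0.6, 0.8))
  withr::with_seed(6, big <- matrix(rnorm(80), 20, 4,
                                    dimnames = list(NULL, paste0("f", 1:4))))
  fmB <- SpiralFeatures(big, labels = rep(c("ET", "CONTROL"), 10))
  gB <- normalizeFeatures(fmB, "global")
  expect_equal(unname(sqrt(colSums(featureMatrix(gB)^2))), rep(1, 4),
               tolerance = 1e-12)
  tf <- normalizeFeatures(fmB, "trainfold", trainIdx = 1:10)
  Xtf <- featureMatrix(tf)
  expect_equal(unname(sqrt(colSums(Xtf[1:10, ]^2))), rep(1, 4),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(unname(sqrt(colSums(Xtf^2))), rep(1, 4))))
  fmZ <- SpiralFeatures(cbind(z = c(0, 0), a = c(1, 2)),
                        labels = c("ET", "CONTROL"))
  expect_warning(gz <- normalizeFeatures(fmZ, "global"), "zero-norm")
  expect_equal(unname(featureMatrix(gz)[, "z"]), c(0, 0))
})

test_that("well-separated clusters are perfectly classified by all three classifiers", {
  fm <- separableCohort()
  for (clf in c("lda", "knn", "svmRbf")) {
    # the RBF kernel scale must be commensurate with the raw data scale
    expect_equal(accuracy(evaluateClassifier(fm, clf, cv = "loo",
                                             svmScale = 5, svmCost = 10)),
                 100)
    expect_equal(accuracy(evaluateClassifier(fm, clf, cv = "kfold",
                                             svmScale = 5, svmCost = 10)),
                 100)
  }
})

test_that("leave-one-out matches a brute-force retrain loop for all classifiers", {
  skip_if_not_installed("class")
  fm <- randomFeatureCohort(n = 24, p = 3, seed = 31)
  X <- featureMatrix(fm)
  y <- sampleLabels(fm)
  n <- nrow(X)

  ldaPred <- knnPred <- svmPred <- character(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    fit <- MASS::lda(X[tr, ], grouping = factor(y[tr]))
    ldaPred[i] <- as.character(predict(fit, X[i, , drop = FALSE])$class)
    knnPred[i] <- as.character(class::knn(X[tr, ], X[i, , drop = FALSE],
                                          cl = factor(y[tr]), k = 3))
    sv <- e1071::svm(X[tr, ], factor(y[tr]), scale = FALSE,
                     kernel = "radial", gamma = 1 / 0.5^2, cost = 10)
    svmPred[i] <- as.character(predict(sv, X[i, , drop = FALSE]))
  }
  expect_identical(evaluateClassifier(fm, "lda")@predicted, ldaPred)
  expect_identical(evaluateClassifier(fm, "knn", knnK = 3)@predicted,
                   knnPred)
  expect_identical(evaluateClassifier(fm, "svmRbf", svmCost = 10,
                                      svmScale = 0.5)@predicted, svmPred)
})

test_that("random labels give chance-level LOO accuracy", {
  accs <- vapply(1:20, function(seed) {
    fm <- randomFeatureCohort(n = 40, p = 3, seed = seed)
    accuracy(evaluateClassifier(fm, "lda"))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 20)
})

test_that("k-NN with k = n - 1 votes with the opposite-heavy majority", {
  fm <- randomFeatureCohort(n = 20, p = 2, seed = 12)
  res <- evaluateClassifier(fm, "knn", knnK = 19)
  # in LOO on a balanced cohort the opposite class always holds the
  # majority among the remaining n - 1 samples
  expect_equal(accuracy(res), 0)
  expect_lte(accuracy(res), 50)
})

test_that("stratified folds are deterministic, disjoint and cover every sample", {
  y <- rep(c("ET", "CONTROL"), c(24, 27))
  f1 <- SpiralDCT:::stratifiedFolds(y, 10, seed = 99)
  f2 <- SpiralDCT:::stratifiedFolds(y, 10, seed = 99)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:10)
  expect_equal(length(f1), 51)
  perFold <- table(f1, y)
  expect_true(all(perFold[, "ET"] >= 2))

  fm <- separableCohort(seed = 4)
  r1 <- evaluateClassifier(fm, "lda", cv = "kfold", seed = 7)
  r2 <- evaluateClassifier(fm, "lda", cv = "kfold", seed = 7)
  expect_identical(r1@predicted, r2@predicted)
})

test_that("CV accuracy always equals its confusion-matrix ratio", {
  for (seed in c(2, 8)) {
    fm <- randomFeatureCohort(n = 30, p = 4, seed = seed)
    res <- evaluateClassifier(fm, "knn", knnK = 5)
    cm <- confusion(res)
    expect_equal(accuracy(res), accuracy(cm))
    expect_equal(length(res@predicted), length(res@truth))
  }
})

test_that("SVM predictions are invariant to feature column order", {
  fm <- randomFeatureCohort(n = 30, p = 5, seed = 17)
  X <- featureMatrix(fm)
  fmPerm <- SpiralFeatures(X[, c(4, 2, 5, 1, 3)],
                           labels = sampleLabels(fm))
  a <- evaluateClassifier(fm, "svmRbf", svmCost = 100, svmScale = 0.3)
  b <- evaluateClassifier(fmPerm, "svmRbf", svmCost = 100, svmScale = 0.3)
  expect_identical(a@predicted, b@predicted)
})

test_that("accuracy grids have the requested shape and agree with direct calls", {
  fm <- separableCohort(seed = 3, n = 20)
  direct <- evaluateClassifier(fm, "svmRbf", svmCost = 10, svmScale = 0.5)
  g1 <- svmGridSearch(fm, costs = 10, scales = 0.5)
  expect_equal(unname(g1$matrix[1, 1]), accuracy(direct))
  g2 <- svmGridSearch(fm, costs = c(1, 10), scales = c(0.2, 0.5, 1))
  expect_equal(dim(g2$matrix), c(2, 3))
  gk <- accuracyGrid(list(`17` = fm), classifier = "knn",
                     knnKs = c(1, 3, 5))
  expect_equal(nrow(gk$table), 3)
  gl <- accuracyGrid(list(`10` = fm, `17` = fm), classifier = "lda")
  expect_equal(nrow(gl$table), 2)
  expect_true(all(gl$best$accuracy == max(gl$table$accuracy)))
})

test_that("nested ReliefF selection evaluates without leaking and stays deterministic", {
  fm <- separableCohort(seed = 21, n = 30)
  X <- cbind(featureMatrix(fm),
             matrix(rnorm(30 * 4), 30, dimnames = list(NULL, paste0("n", 1:4))))
  fmWide <- SpiralFeatures(X, labels = sampleLabels(fm))
  r1 <- evaluateClassifier(fmWide, "lda", selection = "relieffNested",
                           nFeatures = 2, relieffNeighbors = 5)
  r2 <- evaluateClassifier(fmWide, "lda", selection = "relieffNested",
                           nFeatures = 2, relieffNeighbors = 5)
  expect_identical(r1@predicted, r2@predicted)
  expect_equal(accuracy(r1), 100)
  rg <- evaluateClassifier(fmWide, "lda", selection = "relieffGlobal",
                           nFeatures = 2, relieffNeighbors = 5)
  expect_equal(accuracy(rg), 100)
})

test_that("feature-set combination concatenates named subsets by origin", {
  withr::with_seed(44, {
    Xa <- matrix(rnorm(20 * 35), 20,
                 dimnames = list(NULL, featureNamesCanonical()))
    Xb <- matrix(rnorm(20 * 35), 20,
                 dimnames = list(NULL, featureNamesCanonical()))
  })
  labels <- rep(c("ET", "CONTROL"), 10)
  fmA <- SpiralFeatures(Xa, labels = labels)
  fmB <- SpiralFeatures(Xb, labels = labels)
  comb <- combineFeatureSets(fmA, fmB)
  expect_equal(nrow(comb), 7)  # 5 residue + 2 radius
  expect_identical(rownames(comb),
                   c(paste0(referenceTopFeatures("residue"), "_residue"),
                     paste0(c("MFL", "FD"), "_radius")))
  noRadius <- combineFeatureSets(fmA, fmB, radiusFeatures = character(0))
  expect_equal(unname(featureMatrix(noRadius)),
               unname(Xa[, referenceTopFeatures("residue")]))
  fmC <- SpiralFeatures(Xb[1:10, ], labels = labels[1:10])
  expect_error(combineFeatureSets(fmA, fmC), "same samples")
})
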