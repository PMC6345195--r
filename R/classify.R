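#' Standard hyperparameter grids
#'
#' The evaluation grids used throughout: DCT coefficient counts
#' L in \{10, 15, 16, 17, 18, 20, 21, 22, 23, 25, 30, 50\}; odd k-NN
#' neighbor counts 1..33; SVM-RBF box-constraint costs 10^-5..10^4 and
#' kernel scales 0.1..1.1.
#'
#' @return numeric vector of grid values.
#' @name standardGrids
NULL

#' @rdname standardGrids
#' @export
coefficientGrid <- function() c(10, 15, 16, 17, 18, 20, 21, 22, 23, 25, 30, 50)

#' @rdname standardGrids
#' @export
knnGrid <- function() seq(1, 33, by = 2)

#' @rdname standardGrids
#' @export
svmCostGrid <- function() 10^(-5:4)

#' @rdname standardGrids
#' @export
svmScaleGrid <- function() seq(0.1, 1.1, by = 0.1)

#' Scale every feature column to unit Euclidean norm
#'
#' `"global"` fits the scale on all samples; `"trainfold"` fits it on the
#' rows in `trainIdx` only and applies it to every row (so held-out rows
#' need not produce unit-norm columns — the leakage-safe variant used
#' inside cross-validation). A zero-norm column is mapped to all zeros
#' with a warning.
#'
#' @param fm a [SpiralFeatures-class].
#' @param mode `"global"` or `"trainfold"`.
#' @param trainIdx sample indices defining the training fold (required for
#'   `"trainfold"`).
#' @return a [SpiralFeatures-class] with the applied per-feature scale
#'   factors recorded in `S4Vectors::metadata(x)$normScales`.
#' @export
normalizeFeatures <- function(fm, mode = c("global", "trainfold"),
                              trainIdx = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(fm, "SpiralFeatures"))
  X <- featureMatrix(fm)
  fitRows <- if (mode == "global") seq_len(nrow(X)) else trainIdx
  if (mode == "trainfold" && is.null(trainIdx))
    stop("trainfold normalization needs trainIdx")
  norms <- sqrt(colSums(X[fitRows, , drop = FALSE]^2))
  if (any(norms == 0)) {
    warning("zero-norm feature column(s) scaled to all zeros: ",
            paste(colnames(X)[norms == 0], collapse = ", "))
  }
  scales <- ifelse(norms > 0, 1 / norms, 0)
  Xs <- sweep(X, 2, scales, "*")
  out <- SpiralFeatures(Xs, labels = sampleLabels(fm),
                        subjectIds = subjectIds(fm))
  S4Vectors::metadata(out)$normScales <- stats::setNames(scales, colnames(X))
  out
}

# ---- individual classifiers (train on trainX/trainY, predict testX) ----

# two-class linear discriminant with pooled covariance and empirical priors;
# ridge of 1e-6 * trace/d is added if the pooled covariance is singular
ldaTrainPredict <- function(trainX, trainY, testX) {
  classes <- sort(unique(trainY))
  stopifnot(length(classes) == 2)
  d <- ncol(trainX)
  mus <- lapply(classes, function(cl) colMeans(trainX[trainY == cl, , drop = FALSE]))
  ns <- vapply(classes, function(cl) sum(trainY == cl), numeric(1))
  Sp <- matrix(0, d, d)
  for (i in seq_along(classes)) {
    Xi <- trainX[trainY == classes[i], , drop = FALSE]
    if (nrow(Xi) > 1) Sp <- Sp + stats::cov(Xi) * (nrow(Xi) - 1)
  }
  Sp <- Sp / (nrow(trainX) - 2)
  inv <- tryCatch(solve(Sp), error = function(e) NULL)
  if (is.null(inv) || !all(is.finite(inv))) {
    Sp <- Sp + diag(1e-6 * sum(diag(Sp)) / d, d)
    inv <- solve(Sp)
  }
  priors <- ns / sum(ns)
  scores <- vapply(seq_along(classes), function(i) {
    mu <- mus[[i]]
    as.numeric(testX %*% inv %*% mu - 0.5 * drop(mu %*% inv %*% mu) +
                 log(priors[i]))
  }, numeric(nrow(testX)))
  scores <- matrix(scores, nrow = nrow(testX))
  classes[max.col(scores, ties.method = "first")]
}

# Euclidean k-NN with majority vote; any vote tie is decided by the label
# of the single nearest neighbor; equidistant neighbors are taken in
# training-index order (deterministic)
knnTrainPredict <- function(trainX, trainY, testX, k) {
  k <- min(as.integer(k), nrow(trainX))
  apply(testX, 1, function(q) {
    d <- sqrt(colSums((t(trainX) - q)^2))
    nb <- order(d, seq_along(d))[seq_len(k)]
    votes <- table(trainY[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) top else trainY[nb[1]]
  })
}

# soft-margin SVM with RBF kernel K(u,v) = exp(-||u-v||^2 / scale^2)
svmTrainPredict <- function(trainX, trainY, testX, cost, scale) {
  fit <- e1071::svm(trainX, factor(trainY), scale = FALSE,
                    kernel = "radial", gamma = 1 / scale^2, cost = cost)
  as.character(stats::predict(fit, testX))
}

trainPredict <- function(trainX, trainY, testX, classifier, cfg) {
  switch(classifier,
         lda = ldaTrainPredict(trainX, trainY, testX),
         knn = knnTrainPredict(trainX, trainY, testX, cfg$knnK),
         svmRbf = svmTrainPredict(trainX, trainY, testX, cfg$svmCost,
                                  cfg$svmScale))
}

# stratified fold assignment, deterministic given seed
stratifiedFolds <- function(y, k, seed) {
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < k)
        warning(sprintf("class %s has fewer than %d members; folds are as stratified as possible", cl, k))
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Cross-validated evaluation of one classifier configuration
#'
#' Predicts every sample from models trained on the remaining samples,
#' under leave-one-out (`cv = "loo"`) or seed-deterministic stratified
#' k-fold CV (`cv = "kfold"`). Classifiers: two-class linear discriminant
#' with pooled covariance (`"lda"`), Euclidean k-NN with deterministic tie
#' handling (`"knn"`), and a soft-margin SVM with RBF kernel
#' `K(u, v) = exp(-||u-v||^2 / svmScale^2)` and box constraint `svmCost`
#' (`"svmRbf"`; this kernel-scale convention matters — other conventions
#' shift the cost/scale grid).
#'
#' Feature handling per fold: optional unit-norm scaling (`normalize`),
#' then either a fixed named subset (`features`), a ReliefF ranking fitted
#' once on the full cohort (`selection = "relieffGlobal"`), or a ranking
#' re-fitted inside every training fold (`selection = "relieffNested"`,
#' the leakage-safe mode).
#'
#' @param fm a [SpiralFeatures-class] with ET/CONTROL labels.
#' @param classifier `"lda"`, `"knn"` or `"svmRbf"`.
#' @param cv `"loo"` or `"kfold"`.
#' @param k number of folds for `cv = "kfold"` (default 10).
#' @param knnK neighbor count for `"knn"`.
#' @param svmCost,svmScale SVM-RBF box constraint and kernel scale.
#' @param features optional character vector naming the feature subset to
#'   use (applied before any selection).
#' @param selection `"none"`, `"relieffGlobal"` or `"relieffNested"`.
#' @param nFeatures how many top-ranked features to keep when `selection`
#'   is not `"none"`.
#' @param relieffNeighbors ReliefF neighbor count.
#' @param normalize `"none"`, `"global"` (unit norm fitted on all samples)
#'   or `"trainfold"` (fitted per training fold).
#' @param seed seed for fold assignment.
#' @return a [CVResult-class].
#' @examples
#' set.seed(1)
#' m <- cbind(a = c(rnorm(10), rnorm(10, 6)), b = rnorm(20))
#' sf <- SpiralFeatures(m, labels = rep(c("CONTROL", "ET"), each = 10))
#' accuracy(evaluateClassifier(sf, "lda"))
#' @export
evaluateClassifier <- function(fm, classifier = c("svmRbf", "lda", "knn"),
                               cv = c("loo", "kfold"), k = 10L, knnK = 3L,
                               svmCost = 1, svmScale = 0.2, features = NULL,
                               selection = c("none", "relieffGlobal",
                                             "relieffNested"),
                               nFeatures = 5L, relieffNeighbors = 10L,
                               normalize = c("none", "global", "trainfold"),
                               seed = 1L) {
  classifier <- match.arg(classifier)
  cv <- match.arg(cv)
  selection <- match.arg(selection)
  normalize <- match.arg(normalize)
  stopifnot(is(fm, "SpiralFeatures"))
  if (!is.null(features)) fm <- selectFeatures(fm, features)
  y <- sampleLabels(fm)
  if (length(unique(y)) != 2)
    stop("evaluation requires exactly two classes")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")

  if (normalize == "global") fm <- normalizeFeatures(fm, "global")
  if (selection == "relieffGlobal") {
    rk <- relieffRank(fm, nNeighbors = relieffNeighbors)
    fm <- selectFeatures(fm, selectTop(rk, nFeatures))
  }
  X <- featureMatrix(fm)
  n <- nrow(X)

  folds <- if (cv == "loo") seq_len(n) else stratifiedFolds(y, k, seed)
  pred <- character(n)
  for (f in sort(unique(folds))) {
    test <- which(folds == f)
    train <- setdiff(seq_len(n), test)
    if (length(unique(y[train])) < 2)
      stop("a training fold lost one class entirely; use fewer folds")
    Xtr <- X[train, , drop = FALSE]
    Xte <- X[test, , drop = FALSE]
    if (normalize == "trainfold") {
      norms <- sqrt(colSums(Xtr^2))
      scales <- ifelse(norms > 0, 1 / norms, 0)
      Xtr <- sweep(Xtr, 2, scales, "*")
      Xte <- sweep(Xte, 2, scales, "*")
    }
    if (selection == "relieffNested") {
      sub <- SpiralFeatures(Xtr, labels = y[train])
      rk <- relieffRank(sub, nNeighbors = min(relieffNeighbors,
                                              min(table(y[train])) - 1))
      keep <- selectTop(rk, nFeatures)
      Xtr <- Xtr[, keep, drop = FALSE]
      Xte <- Xte[, keep, drop = FALSE]
    }
    pred[test] <- trainPredict(Xtr, y[train], Xte, classifier,
                               list(knnK = knnK, svmCost = svmCost,
                                    svmScale = svmScale))
  }
  cm <- confusionFromPredictions(y, pred)
  new("CVResult", truth = y, predicted = pred, accuracy = accuracy(cm),
      confusion = cm,
      config = list(classifier = classifier, cv = cv, k = k, knnK = knnK,
                    svmCost = svmCost, svmScale = svmScale,
                    selection = selection, nFeatures = nFeatures,
                    normalize = normalize, seed = seed,
                    features = colnames(X)))
}

#' Accuracy over a hyperparameter grid
#'
#' Cartesian evaluation of one classifier over DCT coefficient counts
#' (given a named list of per-L feature cohorts) and its hyperparameter
#' grid, emitting a tidy accuracy table plus the argmax (ties listed).
#'
#' @param fmByL named list of [SpiralFeatures-class] cohorts, one per
#'   coefficient count L (names are the L values); a single cohort may be
#'   given for L-free evaluations such as the radius method.
#' @param classifier `"lda"`, `"knn"` or `"svmRbf"`.
#' @param knnKs neighbor grid (for `"knn"`).
#' @param costs,scales SVM-RBF grids (for `"svmRbf"`).
#' @param ... passed to [evaluateClassifier()] (cv, features, selection,
#'   normalize, seed, ...).
#' @return list with `table` (data.frame of L, hyperparameters, accuracy)
#'   and `best` (rows achieving the maximum accuracy).
#' @export
accuracyGrid <- function(fmByL, classifier = c("svmRbf", "lda", "knn"),
                         knnKs = knnGrid(), costs = svmCostGrid(),
                         scales = svmScaleGrid(), ...) {
  classifier <- match.arg(classifier)
  if (is(fmByL, "SpiralFeatures")) fmByL <- list(`NA` = fmByL)
  if (is.null(names(fmByL))) stop("fmByL must be a named list (names = L)")
  grid <- switch(classifier,
    lda = expand.grid(L = names(fmByL), stringsAsFactors = FALSE),
    knn = expand.grid(L = names(fmByL), knnK = knnKs,
                      stringsAsFactors = FALSE),
    svmRbf = expand.grid(L = names(fmByL), cost = costs, scale = scales,
                         stringsAsFactors = FALSE))
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    args <- list(fm = fmByL[[grid$L[i]]], classifier = classifier, ...)
    if (classifier == "knn") args$knnK <- grid$knnK[i]
    if (classifier == "svmRbf") {
      args$svmCost <- grid$cost[i]
      args$svmScale <- grid$scale[i]
    }
    do.call(evaluateClassifier, args)@accuracy
  }, numeric(1))
  list(table = grid, best = grid[grid$accuracy == max(grid$accuracy), ,
                                 drop = FALSE])
}

#' SVM-RBF cost x scale accuracy matrix
#'
#' Convenience wrapper around [accuracyGrid()] for a single cohort,
#' returning the accuracy table as a cost x scale matrix.
#'
#' @param fm a [SpiralFeatures-class].
#' @param costs,scales grids (defaults: the standard grids).
#' @param ... passed to [evaluateClassifier()].
#' @return list with `matrix` (rows = costs, columns = scales),
#'   `best` (data.frame of argmax cells) and `bestAccuracy`.
#' @export
svmGridSearch <- function(fm, costs = svmCostGrid(), scales = svmScaleGrid(),
                          ...) {
  res <- accuracyGrid(list(fm = fm), classifier = "svmRbf", costs = costs,
                      scales = scales, ...)
  m <- matrix(NA_real_, length(costs), length(scales),
              dimnames = list(format(costs, scientific = TRUE, digits = 3),
                              format(scales)))
  for (i in seq_len(nrow(res$table)))
    m[match(res$table$cost[i], costs), match(res$table$scale[i], scales)] <-
      res$table$accuracy[i]
  list(matrix = m, best = res$best, bestAccuracy = max(res$table$accuracy))
}

#' Combine residue- and radius-method feature sets
#'
#' Column-concatenates the top residue features with the top radius
#' features of the same cohort (names suffixed `_residue` / `_radius`),
#' e.g. the reference combination of the five residue features with the
#' two leading radius features (MFL, FD).
#'
#' @param residueFm,radiusFm [SpiralFeatures-class] cohorts over the same
#'   samples (matched by subject id and order).
#' @param residueFeatures,radiusFeatures character vectors of feature names
#'   to take from each cohort, in rank order. `radiusFeatures` may be
#'   empty, in which case the result is the residue subset alone.
#' @return a [SpiralFeatures-class] with
#'   `length(residueFeatures) + length(radiusFeatures)` features.
#' @export
combineFeatureSets <- function(residueFm, radiusFm,
                               residueFeatures = referenceTopFeatures("residue"),
                               radiusFeatures = referenceTopFeatures("radius")[1:2]) {
  stopifnot(is(residueFm, "SpiralFeatures"), is(radiusFm, "SpiralFeatures"))
  if (!identical(subjectIds(residueFm), subjectIds(radiusFm)) ||
      !identical(sampleLabels(residueFm), sampleLabels(radiusFm)))
    stop("residue and radius cohorts must cover the same samples in the same order")
  Xa <- featureMatrix(selectFeatures(residueFm, residueFeatures))
  colnames(Xa) <- paste0(colnames(Xa), "_residue")
  if (length(radiusFeatures)) {
    Xb <- featureMatrix(selectFeatures(radiusFm, radiusFeatures))
    colnames(Xb) <- paste0(colnames(Xb), "_radius")
    Xa <- cbind(Xa, Xb)
  }
  SpiralFeatures(Xa, labels = sampleLabels(residueFm),
                 subjectIds = subjectIds(residueFm))
}
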