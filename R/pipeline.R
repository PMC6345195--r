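#' Extract the feature bank for a whole cohort
#'
#' Runs each drawing through resampling, the chosen sequence construction
#' (DCT residue-distance at L coefficients, or polar radius), and the
#' 35-value feature bank, stacking the results into a labelled
#' [SpiralFeatures-class].
#'
#' @param drawings list of [DrawingSample-class] (e.g.
#'   `generateCohort(...)$drawings`, or drawings read from disk).
#' @param method `"residue"` or `"radius"`.
#' @param L DCT coefficients kept per axis for the residue method
#'   (default 17); ignored for the radius method.
#' @param nPoints resampling length (default 4096).
#' @param params a [featureParams()] list.
#' @param center centre coordinates before the sequence construction;
#'   default TRUE for the radius method (origin-dependent) and FALSE for
#'   the residue method (offset lives in the discarded DC coefficient).
#' @return a [SpiralFeatures-class] (35 features x length(drawings)
#'   samples).
#' @export
extractCohortFeatures <- function(drawings, method = c("residue", "radius"),
                                  L = 17L, nPoints = 4096L,
                                  params = featureParams(),
                                  center = NULL) {
  method <- match.arg(method)
  if (is.null(center)) center <- method == "radius"
  stopifnot(length(drawings) >= 1)
  rows <- lapply(drawings, function(d) {
    cs <- resampleToN(d, nPoints)
    s <- if (method == "residue")
      residueDistanceSequence(cs, L, center = center)
    else radiusSequence(cs, center = center)
    extractFeatures(s, params)
  })
  X <- do.call(rbind, rows)
  SpiralFeatures(X,
                 labels = vapply(drawings, function(d) d@label, character(1)),
                 subjectIds = vapply(drawings, function(d) d@subjectId,
                                     character(1)))
}

#' Read a cohort of drawings from a directory
#'
#' Expects one coordinate file per drawing plus a `manifest.csv` with
#' `subject_id` and `label` columns (as written by [writeCohort()]).
#' Drawings without a manifest label are excluded with a warning; files
#' that fail to parse are logged and skipped.
#'
#' @param dir directory of drawing files.
#' @param format passed to [readDrawing()].
#' @param fsNominal nominal sampling rate, Hz.
#' @return list of labelled [DrawingSample-class] objects.
#' @export
readCohort <- function(dir, format = "auto", fsNominal = 100) {
  manifestPath <- file.path(dir, "manifest.csv")
  if (!file.exists(manifestPath))
    stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  files <- list.files(dir, pattern = "\\.(csv|svc)$", full.names = TRUE)
  files <- files[basename(files) != "manifest.csv"]
  if (!length(files)) stop("no drawing files in ", dir)
  out <- list()
  nFailed <- 0
  for (f in files) {
    sid <- sub("\\.[^.]*$", "", basename(f))
    row <- match(sid, manifest$subject_id)
    if (is.na(row)) {
      warning("no manifest label for ", sid, "; sample excluded")
      next
    }
    lab <- manifest$label[row]
    d <- tryCatch(readDrawing(f, format = format, fsNominal = fsNominal),
                  error = function(e) {
                    message("skipping ", basename(f), ": ",
                            conditionMessage(e))
                    NULL
                  })
    if (is.null(d)) { nFailed <- nFailed + 1; next }
    d@label <- if (lab %in% c("ET", "CONTROL")) lab else "UNKNOWN"
    out[[length(out) + 1]] <- d
  }
  if (nFailed > 0.1 * length(files))
    stop(sprintf("%d of %d drawing files failed to parse", nFailed,
                 length(files)))
  out
}

#' End-to-end evaluation of the residue pipeline on one cohort
#'
#' The full screening chain on a list of labelled drawings: resample,
#' residue-distance sequence at `L` coefficients, 35-feature bank,
#' unit-norm scaling, ReliefF top-`nFeatures` selection, and an SVM-RBF
#' cost x scale grid under cross-validation. Returns the best achieved
#' accuracy together with the full grid.
#'
#' @param drawings list of labelled [DrawingSample-class] objects.
#' @param L DCT coefficients (default 17).
#' @param nFeatures ReliefF features kept (default 5).
#' @param costs,scales SVM grids (defaults: standard grids).
#' @param cv `"loo"` or `"kfold"`.
#' @param nPoints resampling length (default 4096).
#' @param params a [featureParams()] list.
#' @param seed seed for fold assignment (k-fold only).
#' @return list with `bestAccuracy`, `best` (argmax cells), `matrix`
#'   (cost x scale accuracies), `selected` (the chosen feature names) and
#'   `features` (the [SpiralFeatures-class] used).
#' @export
runResiduePipeline <- function(drawings, L = 17L, nFeatures = 5L,
                               costs = svmCostGrid(),
                               scales = svmScaleGrid(), cv = "loo",
                               nPoints = 4096L, params = featureParams(),
                               seed = 1L) {
  fm <- extractCohortFeatures(drawings, method = "residue", L = L,
                              nPoints = nPoints, params = params)
  fm <- normalizeFeatures(fm, "global")
  nN <- min(10L, min(table(sampleLabels(fm))) - 1L)
  rk <- relieffRank(fm, nNeighbors = nN)
  selected <- selectTop(rk, nFeatures)
  sub <- selectFeatures(fm, selected)
  gs <- svmGridSearch(sub, costs = costs, scales = scales, cv = cv,
                      seed = seed)
  list(bestAccuracy = gs$bestAccuracy, best = gs$best, matrix = gs$matrix,
       selected = selected, features = fm, ranking = rk)
}

#' Extract per-L residue features plus radius features for a cohort
#'
#' The bulk extraction used for grid studies: the DCT spectra of each
#' resampled drawing are computed once per axis and re-used across all
#' coefficient counts.
#'
#' @param drawings list of labelled [DrawingSample-class] objects.
#' @param Ls coefficient grid (default [coefficientGrid()]).
#' @param nPoints resampling length.
#' @param params a [featureParams()] list.
#' @return list with `residue` (named list of [SpiralFeatures-class], one
#'   per L) and `radius` (one [SpiralFeatures-class]).
#' @export
extractFeatureGrids <- function(drawings, Ls = coefficientGrid(),
                                nPoints = 4096L, params = featureParams()) {
  labels <- vapply(drawings, function(d) d@label, character(1))
  sids <- vapply(drawings, function(d) d@subjectId, character(1))
  seqs <- lapply(drawings, resampleToN, nPoints = nPoints)
  spectra <- lapply(seqs, function(cs)
    list(x = dct2Forward(cs@x), y = dct2Forward(cs@y), cs = cs))
  residue <- lapply(Ls, function(L) {
    X <- do.call(rbind, lapply(spectra, function(sp) {
      rx <- sp$cs@x - partialReconstruction(sp$x, L)
      ry <- sp$cs@y - partialReconstruction(sp$y, L)
      rd <- ScalarSequence(sqrt(rx^2 + ry^2), fs = sp$cs@fs,
                           kind = "RESIDUE_DISTANCE")
      extractFeatures(rd, params)
    }))
    SpiralFeatures(X, labels = labels, subjectIds = sids)
  })
  names(residue) <- as.character(Ls)
  Xr <- do.call(rbind, lapply(seqs, function(cs)
    extractFeatures(radiusSequence(cs), params)))
  list(residue = residue,
       radius = SpiralFeatures(Xr, labels = labels, subjectIds = sids))
}
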