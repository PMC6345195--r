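#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.LABELS <- c("ET", "CONTROL", "UNKNOWN")
.HANDS <- c("DOMINANT", "NONDOMINANT", "UNKNOWN")
.SEQ_KINDS <- c("RADIUS", "RESIDUE_DISTANCE", "RAW_AXIS")

#' DrawingSample: one digitized spiral drawing
#'
#' Holds the raw pen trajectory of a single Archimedes' spiral drawing
#' exactly as acquired (or simulated): the x/y coordinate streams in tablet
#' length units, an optional timestamp vector, the nominal sampling rate of
#' the digitizer, and subject metadata. This is the entry object of the
#' pipeline; [resampleToN()] turns it into a fixed-length
#' [CoordinateSequence-class].
#'
#' @slot subjectId opaque subject/sample identifier.
#' @slot label class label: `"ET"` (essential tremor, the positive class),
#'   `"CONTROL"`, or `"UNKNOWN"`.
#' @slot hand `"DOMINANT"`, `"NONDOMINANT"` or `"UNKNOWN"`.
#' @slot x,y numeric coordinate streams of equal length (>= 8 points).
#' @slot t optional strictly increasing timestamps in seconds (length 0 when
#'   absent).
#' @slot fsNominal nominal digitizer sampling rate in Hz (default 100).
#'
#' @seealso [readDrawing()], [generateSpiral()], [resampleToN()]
#' @export
setClass("DrawingSample",
  representation(
    subjectId = "character",
    label = "character",
    hand = "character",
    x = "numeric",
    y = "numeric",
    t = "numeric",
    fsNominal = "numeric"
  ),
  prototype(
    subjectId = NA_character_, label = "UNKNOWN", hand = "UNKNOWN",
    t = numeric(0), fsNominal = 100
  )
)

setValidity("DrawingSample", function(object) {
  msg <- character(0)
  if (length(object@x) != length(object@y))
    msg <- c(msg, "x and y must have equal length")
  if (length(object@x) < 8)
    msg <- c(msg, "a drawing needs at least 8 coordinate points")
  if (!all(is.finite(object@x)) || !all(is.finite(object@y)))
    msg <- c(msg, "coordinates must be finite")
  if (!object@label %in% .LABELS)
    msg <- c(msg, sprintf("label must be one of %s", paste(.LABELS, collapse = ", ")))
  if (!object@hand %in% .HANDS)
    msg <- c(msg, sprintf("hand must be one of %s", paste(.HANDS, collapse = ", ")))
  if (length(object@t) > 0) {
    if (length(object@t) != length(object@x))
      msg <- c(msg, "timestamps must match coordinate length")
    else if (any(diff(object@t) <= 0))
      msg <- c(msg, "timestamps must be strictly increasing")
  }
  if (length(object@fsNominal) != 1 || !is.finite(object@fsNominal) ||
      object@fsNominal <= 0)
    msg <- c(msg, "fsNominal must be a positive number")
  if (length(msg)) msg else TRUE
})

#' CoordinateSequence: a fixed-length resampled trajectory
#'
#' A drawing after resampling onto a fixed number of uniformly spaced
#' positions along the sample-index axis (4096 by default, so every drawing
#' supports the same DCT length). Records the effective sampling rate
#' implied by the resampling and whether the coordinates have been centered.
#'
#' @slot x,y numeric coordinates, equal length.
#' @slot fs effective sampling rate in Hz after resampling.
#' @slot centered `TRUE` once per-axis means have been subtracted.
#'
#' @seealso [resampleToN()], [centerCoordinates()], [radiusSequence()],
#'   [residueDistanceSequence()]
#' @export
setClass("CoordinateSequence",
  representation(x = "numeric", y = "numeric", fs = "numeric",
                 centered = "logical"),
  prototype(centered = FALSE)
)

setValidity("CoordinateSequence", function(object) {
  msg <- character(0)
  if (length(object@x) != length(object@y))
    msg <- c(msg, "x and y must have equal length")
  if (!all(is.finite(object@x)) || !all(is.finite(object@y)))
    msg <- c(msg, "coordinates must be finite")
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a positive number")
  if (length(object@centered) != 1 || is.na(object@centered))
    msg <- c(msg, "centered must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' ScalarSequence: a single real sequence characterizing a drawing
#'
#' The two coordinate streams of a spiral are collapsed into one real
#' sequence before feature extraction, either as the polar radius
#' r\[n\] = sqrt(x\[n\]^2 + y\[n\]^2) or as the residue distance
#' rd\[n\] = sqrt(xres\[n\]^2 + yres\[n\]^2) built from per-axis DCT
#' residues. The `kind` slot records which construction produced it.
#'
#' @slot values numeric sequence (non-negative for the RADIUS and
#'   RESIDUE_DISTANCE kinds).
#' @slot fs sampling rate in Hz carried over from the coordinates.
#' @slot kind `"RADIUS"`, `"RESIDUE_DISTANCE"` or `"RAW_AXIS"`.
#'
#' @seealso [radiusSequence()], [residueDistanceSequence()],
#'   [extractFeatures()]
#' @export
setClass("ScalarSequence",
  representation(values = "numeric", fs = "numeric", kind = "character"),
  prototype(kind = "RAW_AXIS")
)

setValidity("ScalarSequence", function(object) {
  msg <- character(0)
  if (!all(is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (!object@kind %in% .SEQ_KINDS)
    msg <- c(msg, sprintf("kind must be one of %s", paste(.SEQ_KINDS, collapse = ", ")))
  if (object@kind %in% c("RADIUS", "RESIDUE_DISTANCE") &&
      any(object@values < 0))
    msg <- c(msg, sprintf("%s values must be non-negative", object@kind))
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a positive number")
  if (length(msg)) msg else TRUE
})

#' DCTSpectrum: DCT-II coefficients of a sequence
#'
#' The N orthonormal type-II DCT coefficients of a length-N real sequence.
#' Under the orthonormal convention used throughout this package the
#' transform is an orthogonal map, so Parseval's identity holds:
#' sum(x^2) == sum(coeffs^2).
#'
#' @slot coeffs numeric coefficient vector X\[k\], k = 0..N-1.
#'
#' @seealso [dct2Forward()], [dct2Inverse()], [partialReconstruction()]
#' @export
setClass("DCTSpectrum", representation(coeffs = "numeric"))

setValidity("DCTSpectrum", function(object) {
  if (!all(is.finite(object@coeffs))) "coefficients must be finite" else TRUE
})

#' SpiralFeatures: a labelled cohort feature matrix
#'
#' Container for the per-drawing feature bank of a whole cohort, extending
#' `SummarizedExperiment`: the assay `"features"` is a features x samples
#' matrix, row names are the canonical feature names, and `colData` carries
#' `subject_id` and `label` for every sample. All selection and
#' classification functions consume this class.
#'
#' @seealso [SpiralFeatures()], [featureMatrix()], [sampleLabels()],
#'   [relieffRank()], [evaluateClassifier()]
#' @export
setClass("SpiralFeatures", contains = "SummarizedExperiment")

setValidity("SpiralFeatures", function(object) {
  msg <- character(0)
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  else if (any(!is.finite(SummarizedExperiment::assay(object, "features"))))
    msg <- c(msg, "feature values must be finite")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("subject_id", "label") %in% colnames(cd)))
    msg <- c(msg, "colData must contain subject_id and label")
  else if (!all(cd$label %in% .LABELS))
    msg <- c(msg, "labels must be ET, CONTROL or UNKNOWN")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature names must be present and unique")
  if (length(msg)) msg else TRUE
})

#' FeatureRanking: ReliefF relevance weights and order
#'
#' @slot featureNames feature names in original matrix order.
#' @slot weights per-feature ReliefF relevance scores (original order).
#' @slot order permutation of feature indices, most relevant first; ties in
#'   weight are broken by original index.
#'
#' @seealso [relieffRank()], [selectTop()]
#' @export
setClass("FeatureRanking",
  representation(featureNames = "character", weights = "numeric",
                 order = "integer")
)

setValidity("FeatureRanking", function(object) {
  msg <- character(0)
  p <- length(object@featureNames)
  if (length(object@weights) != p || length(object@order) != p)
    msg <- c(msg, "featureNames, weights and order must have equal length")
  if (p && !setequal(object@order, seq_len(p)))
    msg <- c(msg, "order must be a permutation of the feature indices")
  if (p && is.unsorted(-object@weights[object@order]))
    msg <- c(msg, "order must sort weights non-increasingly")
  if (length(msg)) msg else TRUE
})

#' ConfusionMatrix: 2x2 tally with essential tremor as positive class
#'
#' @slot TP,FN,FP,TN non-negative integer counts. ET is the positive class
#'   throughout: TP counts ET drawings predicted ET, TN counts controls
#'   predicted control.
#'
#' @seealso [confusionMatrix()], [confusionFromPredictions()],
#'   [sensitivity()], [specificity()], [accuracy()]
#' @export
setClass("ConfusionMatrix",
  representation(TP = "integer", FN = "integer", FP = "integer",
                 TN = "integer")
)

setValidity("ConfusionMatrix", function(object) {
  counts <- c(object@TP, object@FN, object@FP, object@TN)
  msg <- character(0)
  if (length(counts) != 4 || any(is.na(counts)) || any(counts < 0))
    msg <- c(msg, "TP, FN, FP, TN must be non-negative integers")
  else if (sum(counts) < 1)
    msg <- c(msg, "confusion matrix must tally at least one sample")
  if (length(msg)) msg else TRUE
})

#' CVResult: cross-validated predictions for one configuration
#'
#' @slot truth,predicted per-sample true and predicted labels (each sample
#'   predicted exactly once).
#' @slot accuracy percent correct, always equal to
#'   100 * (TP + TN) / total of the confusion slot.
#' @slot confusion the [ConfusionMatrix-class] tallied from the predictions.
#' @slot config list describing the evaluated configuration (classifier,
#'   hyperparameters, CV protocol, seed).
#'
#' @seealso [evaluateClassifier()], [svmGridSearch()]
#' @export
setClass("CVResult",
  representation(truth = "character", predicted = "character",
                 accuracy = "numeric", confusion = "ConfusionMatrix",
                 config = "list")
)

setValidity("CVResult", function(object) {
  msg <- character(0)
  if (length(object@truth) != length(object@predicted))
    msg <- c(msg, "truth and predicted must have equal length")
  cm <- object@confusion
  tot <- cm@TP + cm@FN + cm@FP + cm@TN
  if (tot != length(object@truth))
    msg <- c(msg, "confusion total must equal the number of samples")
  acc <- 100 * (cm@TP + cm@TN) / tot
  if (abs(object@accuracy - acc) > 1e-9)
    msg <- c(msg, "accuracy must equal 100*(TP+TN)/total")
  if (length(msg)) msg else TRUE
})
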