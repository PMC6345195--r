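#' Construct a DrawingSample
#'
#' @param x,y numeric coordinate streams (equal length, >= 8 points).
#' @param subjectId sample identifier.
#' @param label `"ET"`, `"CONTROL"` or `"UNKNOWN"`.
#' @param hand `"DOMINANT"`, `"NONDOMINANT"` or `"UNKNOWN"`.
#' @param t optional strictly increasing timestamps (seconds).
#' @param fsNominal nominal sampling rate, Hz.
#' @return a [DrawingSample-class].
#' @examples
#' d <- DrawingSample(x = sin(1:100), y = cos(1:100), subjectId = "s1")
#' nPoints(d)
#' @export
DrawingSample <- function(x, y, subjectId = NA_character_,
                          label = c("UNKNOWN", "ET", "CONTROL"),
                          hand = c("UNKNOWN", "DOMINANT", "NONDOMINANT"),
                          t = numeric(0), fsNominal = 100) {
  new("DrawingSample", x = as.numeric(x), y = as.numeric(y),
      subjectId = as.character(subjectId), label = match.arg(label),
      hand = match.arg(hand), t = as.numeric(t),
      fsNominal = as.numeric(fsNominal))
}

#' Construct a ScalarSequence
#'
#' @param values numeric sequence.
#' @param fs sampling rate, Hz.
#' @param kind `"RAW_AXIS"`, `"RADIUS"` or `"RESIDUE_DISTANCE"`.
#' @return a [ScalarSequence-class].
#' @export
ScalarSequence <- function(values, fs = 100,
                           kind = c("RAW_AXIS", "RADIUS", "RESIDUE_DISTANCE")) {
  new("ScalarSequence", values = as.numeric(values), fs = as.numeric(fs),
      kind = match.arg(kind))
}

#' @describeIn nPoints number of raw coordinate points.
#' @export
setMethod("nPoints", "DrawingSample", function(x) length(x@x))

#' @describeIn nPoints number of resampled coordinate points.
#' @export
setMethod("nPoints", "CoordinateSequence", function(x) length(x@x))

#' @describeIn nPoints sequence length.
#' @export
setMethod("nPoints", "ScalarSequence", function(x) length(x@values))

#' @describeIn nPoints number of DCT coefficients.
#' @export
setMethod("nPoints", "DCTSpectrum", function(x) length(x@coeffs))

#' @describeIn samplingRate nominal digitizer rate.
#' @export
setMethod("samplingRate", "DrawingSample", function(x) x@fsNominal)

#' @describeIn samplingRate effective rate after resampling.
#' @export
setMethod("samplingRate", "CoordinateSequence", function(x) x@fs)

#' @describeIn samplingRate rate carried by the sequence.
#' @export
setMethod("samplingRate", "ScalarSequence", function(x) x@fs)

#' @describeIn coordinates raw coordinates.
#' @export
setMethod("coordinates", "DrawingSample", function(x)
  cbind(x = x@x, y = x@y))

#' @describeIn coordinates resampled coordinates.
#' @export
setMethod("coordinates", "CoordinateSequence", function(x)
  cbind(x = x@x, y = x@y))

#' @describeIn seqValues sequence values.
#' @export
setMethod("seqValues", "ScalarSequence", function(x) x@values)

#' @describeIn seqValues DCT-II coefficients X\[k\].
#' @export
setMethod("seqValues", "DCTSpectrum", function(x) x@coeffs)

#' Kind of a scalar sequence
#'
#' @param x a [ScalarSequence-class].
#' @return `"RADIUS"`, `"RESIDUE_DISTANCE"` or `"RAW_AXIS"`.
#' @export
seqKind <- function(x) {
  stopifnot(is(x, "ScalarSequence"))
  x@kind
}

setMethod("show", "DrawingSample", function(object) {
  cat(sprintf("DrawingSample '%s' (%s, %s hand): %d points @ %g Hz nominal%s\n",
              object@subjectId, object@label, tolower(object@hand),
              length(object@x), object@fsNominal,
              if (length(object@t)) ", timestamped" else ""))
})

setMethod("show", "CoordinateSequence", function(object) {
  cat(sprintf("CoordinateSequence: %d points @ %.4g Hz effective, %s\n",
              length(object@x), object@fs,
              if (object@centered) "centered" else "uncentered"))
})

setMethod("show", "ScalarSequence", function(object) {
  v <- object@values
  cat(sprintf("ScalarSequence (%s): %d points @ %.4g Hz, range [%.4g, %.4g]\n",
              object@kind, length(v), object@fs,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

setMethod("show", "DCTSpectrum", function(object) {
  cat(sprintf("DCTSpectrum: %d coefficients, energy %.6g\n",
              length(object@coeffs), sum(object@coeffs^2)))
})

setMethod("show", "FeatureRanking", function(object) {
  cat(sprintf("FeatureRanking over %d features; top 5: %s\n",
              length(object@featureNames),
              paste(object@featureNames[utils::head(object@order, 5)],
                    collapse = ", ")))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (positive class: ET)\n")
  m <- matrix(c(object@TP, object@FN, object@FP, object@TN), 2, 2,
              byrow = TRUE,
              dimnames = list(c("Actual ET", "Actual CONTROL"),
                              c("Pred ET", "Pred CONTROL")))
  print(m)
  cat(sprintf("accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%\n",
              accuracy(object), sensitivity(object), specificity(object)))
})

setMethod("show", "CVResult", function(object) {
  cfg <- object@config
  cat(sprintf("CVResult: %s / %s on %d samples, accuracy %.2f%%\n",
              if (is.null(cfg$classifier)) "?" else cfg$classifier,
              if (is.null(cfg$cv)) "?" else cfg$cv,
              length(object@truth), object@accuracy))
})
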