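#' Number of points in a drawing, sequence or spectrum
#'
#' @param x a [DrawingSample-class], [CoordinateSequence-class],
#'   [ScalarSequence-class] or [DCTSpectrum-class].
#' @return integer number of samples/coefficients.
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' Sampling rate accessor
#'
#' @param x an object carrying a sampling rate (Hz).
#' @return the sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Coordinate accessor
#'
#' @param x a [DrawingSample-class] or [CoordinateSequence-class].
#' @return a two-column numeric matrix with columns `x` and `y`.
#' @export
setGeneric("coordinates", function(x) standardGeneric("coordinates"))

#' Values of a scalar sequence or spectrum
#'
#' @param x a [ScalarSequence-class] or [DCTSpectrum-class].
#' @return numeric vector of sequence values or DCT coefficients.
#' @export
setGeneric("seqValues", function(x) standardGeneric("seqValues"))

#' Sensitivity (true positive rate), in percent
#'
#' @param x a [ConfusionMatrix-class] or [CVResult-class].
#' @return 100 * TP / (TP + FN), with essential tremor as the positive class.
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))

#' Specificity (true negative rate), in percent
#'
#' @param x a [ConfusionMatrix-class] or [CVResult-class].
#' @return 100 * TN / (TN + FP).
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))

#' Classification accuracy, in percent
#'
#' @param x a [ConfusionMatrix-class] or [CVResult-class].
#' @return 100 * (TP + TN) / (TP + FN + FP + TN).
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
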