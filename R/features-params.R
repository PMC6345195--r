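#' Parameters of the feature bank
#'
#' Bundles every tunable of the temporal and spectral descriptors. Defaults
#' follow the conventional settings for tremor/EMG-style signal banks:
#' sample entropy with embedding dimension m = 3 and tolerance 0.2 times
#' the sequence standard deviation; Higuchi's fractal dimension with
#' k_max = 5; an order-4 Yule-Walker autoregressive fit; and a Welch
#' periodogram with 256-sample Hamming segments at 50% overlap.
#'
#' @param sampenM sample-entropy embedding dimension (>= 1).
#' @param sampenR sample-entropy tolerance factor, applied as
#'   `sampenR * sd(values)`.
#' @param higuchiKmax largest curve-length scale for Higuchi's estimator
#'   (>= 2).
#' @param arOrder autoregressive model order (>= 1).
#' @param welchSegment Welch segment length in samples.
#' @param welchOverlap Welch segment overlap fraction in \[0, 1).
#' @param welchWindow taper: `"hamming"`, `"hann"` or `"rectangular"`.
#' @param autocorrLags number of autocorrelation coefficients (time domain,
#'   lags 1..autocorrLags).
#' @param fsOverride if non-NULL, this sampling rate (Hz) replaces the rate
#'   stored in the sequence for all spectral features — e.g. force the
#'   nominal digitizer rate to mimic processing chains that ignore
#'   resampling. Default NULL (use the effective rate).
#' @return a named list of class `FeatureParams`.
#' @export
featureParams <- function(sampenM = 3L, sampenR = 0.2, higuchiKmax = 5L,
                          arOrder = 4L, welchSegment = 256L,
                          welchOverlap = 0.5,
                          welchWindow = c("hamming", "hann", "rectangular"),
                          autocorrLags = 3L, fsOverride = NULL) {
  welchWindow <- match.arg(welchWindow)
  p <- list(sampenM = as.integer(sampenM), sampenR = sampenR,
            higuchiKmax = as.integer(higuchiKmax),
            arOrder = as.integer(arOrder),
            welchSegment = as.integer(welchSegment),
            welchOverlap = welchOverlap, welchWindow = welchWindow,
            autocorrLags = as.integer(autocorrLags), fsOverride = fsOverride)
  if (p$sampenM < 1) stop("sampenM must be >= 1")
  if (p$sampenR <= 0) stop("sampenR must be positive")
  if (p$higuchiKmax < 2) stop("higuchiKmax must be >= 2")
  if (p$arOrder < 1) stop("arOrder must be >= 1")
  if (p$welchSegment < 8) stop("welchSegment must be >= 8")
  if (p$welchOverlap < 0 || p$welchOverlap >= 1)
    stop("welchOverlap must be in [0, 1)")
  if (p$autocorrLags < 1) stop("autocorrLags must be >= 1")
  class(p) <- "FeatureParams"
  p
}

#' Canonical feature names
#'
#' The fixed order of the 35 descriptors produced by [extractFeatures()]:
#' 20 temporal (sample entropy, amplitude/waveform statistics, Higuchi
#' fractal dimension, counts, four autoregressive coefficients) followed by
#' 15 spectral (Welch periodogram summaries and three time-domain
#' autocorrelation coefficients).
#'
#' @return character vector of length 35.
#' @export
featureNamesCanonical <- function() {
  c("SENT", "MAV", "VAR", "RMS", "LOG", "WL", "STD", "AAC", "FD", "MFL",
    "MYO", "IEMG", "SSI", "ZC", "SSC", "WAMP", "AR1", "AR2", "AR3", "AR4",
    "Pmax", "Fmax", "MP", "TP", "MNF", "MDF", "STDp", "SM1", "SM2", "SM3",
    "KUR", "SKW", "Auto1", "Auto2", "Auto3")
}
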