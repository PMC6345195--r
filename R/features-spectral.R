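#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: the sequence is cut into overlapping
#' segments, each is demeaned implicitly by nothing (no detrending, as in
#' the classic estimator), tapered, transformed, and the one-sided
#' periodograms are averaged. The PSD is density-scaled so that
#' `sum(psd) * fs / nfft` approximates the signal power.
#'
#' @param x numeric sequence (length >= `segment`).
#' @param fs sampling rate, Hz.
#' @param segment segment length in samples.
#' @param overlap overlap fraction in \[0, 1).
#' @param window `"hamming"`, `"hann"` or `"rectangular"`.
#' @return list with `freq` (Hz, length segment/2 + 1) and `power`
#'   (one-sided PSD).
#' @export
welchPsd <- function(x, fs, segment = 256L, overlap = 0.5,
                     window = c("hamming", "hann", "rectangular")) {
  window <- match.arg(window)
  n <- length(x)
  segment <- as.integer(segment)
  if (n < segment)
    stop(sprintf("sequence (%d) shorter than Welch segment (%d)", n, segment))
  if (!is.finite(fs) || fs <= 0) stop("fs must be a positive number")
  w <- switch(window,
              hamming = as.numeric(signal::hamming(segment)),
              hann = as.numeric(signal::hanning(segment)),
              rectangular = rep(1, segment))
  step <- max(1L, as.integer(round(segment * (1 - overlap))))
  starts <- seq(1L, n - segment + 1L, by = step)
  nHalf <- segment %/% 2
  acc <- numeric(nHalf + 1)
  for (s in starts) {
    seg <- x[s:(s + segment - 1L)] * w
    sp <- abs(stats::fft(seg))^2 / (fs * sum(w^2))
    one <- sp[1:(nHalf + 1)]
    if (segment %% 2 == 0) {
      if (nHalf > 1) one[2:nHalf] <- 2 * one[2:nHalf]
    } else {
      one[2:(nHalf + 1)] <- 2 * one[2:(nHalf + 1)]
    }
    acc <- acc + one
  }
  list(freq = (0:nHalf) * fs / segment, power = acc / length(starts))
}

#' Spectral-domain feature bank
#'
#' Evaluates the 15 spectral descriptors on the one-sided Welch
#' periodogram P_i at frequencies f_i (plus three time-domain
#' autocorrelation coefficients):
#' \itemize{
#'   \item Pmax, Fmax: height and frequency of the largest peak.
#'   \item MP `mean(P)`; TP `sum(P)`; STDp standard deviation of P (N-1
#'     denominator).
#'   \item MNF `sum(f * P) / sum(P)`; MDF the smallest frequency where the
#'     cumulative power reaches half of TP.
#'   \item SM1..SM3 `sum(P * f^m)`, m = 1, 2, 3.
#'   \item KUR, SKW: kurtosis `m4/m2^2` and skewness `m3/m2^(3/2)` of the
#'     P_i values (central moment definitions).
#'   \item Auto1..Auto3: normalized autocorrelation of the time sequence at
#'     lags 1..3 (0 with a warning for a constant sequence).
#' }
#'
#' @param seq a [ScalarSequence-class].
#' @param params a [featureParams()] list; `fsOverride` replaces the stored
#'   sampling rate if set.
#' @return named numeric vector of the 15 spectral features.
#' @export
spectralFeatures <- function(seq, params = featureParams()) {
  stopifnot(is(seq, "ScalarSequence"))
  x <- seq@values
  fs <- if (!is.null(params$fsOverride)) params$fsOverride else seq@fs
  psd <- welchPsd(x, fs, params$welchSegment, params$welchOverlap,
                  params$welchWindow)
  P <- psd$power
  f <- psd$freq

  iMax <- which.max(P)
  Pmax <- P[iMax]
  Fmax <- f[iMax]
  MP <- mean(P)
  TP <- sum(P)
  MNF <- if (TP > 0) sum(f * P) / TP else 0
  MDF <- if (TP > 0) f[which(cumsum(P) >= TP / 2)[1]] else 0
  STDp <- stats::sd(P)
  SM1 <- sum(P * f)
  SM2 <- sum(P * f^2)
  SM3 <- sum(P * f^3)
  m2 <- mean((P - MP)^2)
  KUR <- if (m2 > 0) mean((P - MP)^4) / m2^2 else 0
  SKW <- if (m2 > 0) mean((P - MP)^3) / m2^1.5 else 0

  nl <- params$autocorrLags
  if (stats::sd(x) == 0) {
    warning("constant sequence: autocorrelation undefined, returning 0")
    autos <- rep(0, nl)
  } else {
    ac <- stats::acf(x, lag.max = nl, plot = FALSE, demean = TRUE)$acf
    autos <- as.numeric(ac)[2:(nl + 1)]
  }
  names(autos) <- paste0("Auto", seq_len(nl))

  c(Pmax = Pmax, Fmax = Fmax, MP = MP, TP = TP, MNF = MNF, MDF = MDF,
    STDp = STDp, SM1 = SM1, SM2 = SM2, SM3 = SM3, KUR = KUR, SKW = SKW,
    autos)
}

#' Extract the full 35-value feature bank
#'
#' Concatenates [temporalFeatures()] and [spectralFeatures()] in the
#' canonical order of [featureNamesCanonical()].
#'
#' @param seq a [ScalarSequence-class].
#' @param params a [featureParams()] list.
#' @return named numeric vector of length 35.
#' @examples
#' s <- ScalarSequence(sin(2 * pi * 8 * (0:1023) / 100) + rnorm(1024, 0, .1),
#'                     fs = 100)
#' extractFeatures(s)[c("MAV", "Fmax", "MNF")]
#' @export
extractFeatures <- function(seq, params = featureParams()) {
  out <- c(temporalFeatures(seq, params), spectralFeatures(seq, params))
  stopifnot(identical(names(out), featureNamesCanonical()))
  out
}
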