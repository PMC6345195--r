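#' Temporal-domain feature bank
#'
#' Evaluates the 20 temporal descriptors of a scalar sequence, each by its
#' literal defining formula:
#' \itemize{
#'   \item SENT: sample entropy with embedding `sampenM` and tolerance
#'     `sampenR * sd(x)`, Chebyshev distance, self-matches excluded.
#'   \item MAV `mean(|x|)`; IEMG `sum(|x|)`; SSI `sum(x^2)`;
#'     RMS `sqrt(mean(x^2))`.
#'   \item VAR and STD with the N-1 denominator.
#'   \item LOG `exp(mean(log(|x|)))` (zeros floored at 1e-12).
#'   \item WL `sum(|diff(x)|)`; MFL `log(WL)`;
#'     AAC `sqrt(sum(diff(x)^2)/(N-1))`.
#'   \item FD: Higuchi's fractal dimension with `k_max = higuchiKmax`.
#'   \item MYO: percentage of samples exceeding twice the mean.
#'   \item ZC: mean-crossings between consecutive samples (exact zeros of
#'     x - mean take the sign of the following sample).
#'   \item SSC: strict sign changes of consecutive first differences (zero
#'     differences skipped).
#'   \item WAMP: count of `|x[i] - x[i+1]| > eps` with eps the mean of the
#'     signal (taken literally, not the mean of |x|).
#'   \item AR1..AR4: Yule-Walker autoregressive coefficients (biased
#'     autocovariance, demeaned; prediction-polynomial sign convention
#'     excluding the leading 1).
#' }
#'
#' @param seq a [ScalarSequence-class] (or numeric vector).
#' @param params a [featureParams()] list.
#' @return named numeric vector of the 20 temporal features.
#' @export
temporalFeatures <- function(seq, params = featureParams()) {
  x <- if (is(seq, "ScalarSequence")) seq@values else as.numeric(seq)
  n <- length(x)
  if (n < 2 * (params$sampenM + 1))
    stop(sprintf("sequence too short for temporal features: %d < %d",
                 n, 2 * (params$sampenM + 1)))
  mu <- mean(x)
  d <- diff(x)
  isConstant <- stats::sd(x) == 0

  MAV <- mean(abs(x))
  VAR <- sum((x - mu)^2) / (n - 1)
  RMS <- sqrt(sum(x^2) / n)
  LOG <- exp(mean(log(pmax(abs(x), 1e-12))))
  WL <- sum(abs(d))
  STD <- sqrt(VAR)
  AAC <- sqrt(sum(d^2) / (n - 1))
  MFL <- log(max(WL, 1e-300))
  MYO <- 100 * mean(x > 2 * mu)
  IEMG <- sum(abs(x))
  SSI <- sum(x^2)
  ZC <- zeroCrossings(x)
  SSC <- slopeSignChanges(x)
  WAMP <- sum(abs(d) > mu)

  if (isConstant) {
    warning("constant sequence: SENT and FD set to 0")
    SENT <- 0
    FD <- 0
    ar <- rep(0, 4)
  } else {
    SENT <- sampleEntropy(x, params$sampenM, params$sampenR * stats::sd(x))
    FD <- higuchiFD(x, params$higuchiKmax)
    ar <- yuleWalkerAR(x, params$arOrder)
  }

  out <- c(SENT = SENT, MAV = MAV, VAR = VAR, RMS = RMS, LOG = LOG, WL = WL,
           STD = STD, AAC = AAC, FD = FD, MFL = MFL, MYO = MYO, IEMG = IEMG,
           SSI = SSI, ZC = ZC, SSC = SSC, WAMP = WAMP)
  arOut <- rep(0, 4)
  arOut[seq_along(ar)] <- ar
  names(arOut) <- paste0("AR", 1:4)
  c(out, arOut)
}

# mean-crossing count; zeros of the demeaned signal take the sign of the
# following sample
zeroCrossings <- function(x) {
  s <- sign(x - mean(x))
  # propagate signs backwards so an exact zero adopts the next sample's sign
  for (i in rev(seq_len(length(s) - 1)))
    if (s[i] == 0) s[i] <- s[i + 1]
  s <- s[s != 0]
  if (length(s) < 2) return(0)
  sum(s[-1] != s[-length(s)])
}

# strict sign changes of consecutive first differences, zero diffs skipped
slopeSignChanges <- function(x) {
  d <- diff(x)
  d <- d[d != 0]
  if (length(d) < 2) return(0)
  sum(sign(d[-1]) != sign(d[-length(d)]))
}

#' Sample entropy
#'
#' `-log(A/B)` where B counts template pairs of length `m` within Chebyshev
#' distance `r` and A the pairs still matching at length `m + 1`;
#' self-matches excluded. Returns 0 with a warning when no matches exist
#' (the statistic is undefined there).
#'
#' @param x numeric sequence.
#' @param m embedding dimension.
#' @param r tolerance, in the units of `x` (absolute, already scaled).
#' @return sample entropy (natural log).
#' @export
sampleEntropy <- function(x, m = 3L, r = 0.2 * stats::sd(x)) {
  v <- .sampleEntropyCpp(as.numeric(x), as.integer(m), as.numeric(r))
  if (is.na(v)) {
    warning("sample entropy undefined (no template matches); returning 0")
    return(0)
  }
  v
}

#' Higuchi's fractal dimension
#'
#' Builds the k coarse-grained curve lengths L(k) for k = 1..kMax
#' (averaging over the k possible offsets, with the standard end-correction
#' factor) and returns the negated least-squares slope of log L(k) against
#' log k.
#'
#' @param x numeric sequence.
#' @param kMax largest scale (default 5).
#' @return estimated fractal dimension (about 1 for smooth curves, up to 2
#'   for white noise).
#' @export
higuchiFD <- function(x, kMax = 5L) {
  n <- length(x)
  kMax <- as.integer(kMax)
  stopifnot(kMax >= 2, n > kMax + 1)
  Lk <- vapply(seq_len(kMax), function(k) {
    Lm <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      nm <- length(idx) - 1
      if (nm < 1) return(NA_real_)
      sum(abs(diff(x[idx]))) * (n - 1) / (nm * k) / k
    }, numeric(1))
    mean(Lm, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(log(Lk))
  if (sum(ok) < 2) return(0)
  -stats::coef(stats::lm(log(Lk[ok]) ~ log(seq_len(kMax)[ok])))[[2]]
}

# Yule-Walker AR coefficients: solve the Toeplitz system built from the
# biased autocovariance of the demeaned series; returns the prediction
# coefficients a_1..a_p of x_t = sum_i a_i x_{t-i} + e_t
yuleWalkerAR <- function(x, order = 4L) {
  fit <- stats::ar.yw(x, aic = FALSE, order.max = order, demean = TRUE)
  co <- as.numeric(fit$ar)
  if (length(co) < order) co <- c(co, rep(0, order - length(co)))
  co
}
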