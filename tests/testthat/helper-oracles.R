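# Independent oracles used across the suite. Everything here is written
# from the defining formulas, deliberately avoiding the package's own code
# paths (direct sums instead of FFTs, explicit loops instead of vectorized
# kernels).

# O(N^2) direct-sum orthonormal DCT-II
oracleDct2 <- function(x) {
  n <- length(x)
  ck <- c(sqrt(1 / n), rep(sqrt(2 / n), max(0, n - 1)))
  vapply(0:(n - 1), function(k) {
    ck[k + 1] * sum(x * cos(pi / n * ((0:(n - 1)) + 0.5) * k))
  }, numeric(1))
}

# O(N^2) direct-sum inverse (orthonormal DCT-III)
oracleDct2Inv <- function(X) {
  n <- length(X)
  ck <- c(sqrt(1 / n), rep(sqrt(2 / n), max(0, n - 1)))
  vapply(0:(n - 1), function(nn) {
    sum(ck * X * cos(pi / n * (nn + 0.5) * (0:(n - 1))))
  }, numeric(1))
}

# literal sample entropy: loop over template pairs, Chebyshev distance,
# self-matches excluded
oracleSampEn <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    js <- (i + 1):nt
    dm <- rep(0, length(js))
    for (k in 0:(m - 1))
      dm <- pmax(dm, abs(x[i + k] - x[js + k]))
    hit <- dm <= r
    B <- B + sum(hit)
    A <- A + sum(hit & abs(x[i + m] - x[js + m]) <= r)
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# literal Higuchi curve lengths and log-log slope
oracleHiguchi <- function(x, kMax) {
  n <- length(x)
  Lk <- numeric(kMax)
  for (k in seq_len(kMax)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      nm <- length(idx) - 1
      s <- 0
      for (j in seq_len(nm)) s <- s + abs(x[idx[j + 1]] - x[idx[j]])
      Lm[m] <- s * (n - 1) / (nm * k) / k
    }
    Lk[k] <- mean(Lm)
  }
  fit <- stats::lm(log(Lk) ~ log(seq_len(kMax)))
  -unname(stats::coef(fit)[2])
}

# Yule-Walker from the biased autocovariance of the demeaned series
oracleYuleWalker <- function(x, p) {
  n <- length(x)
  mu <- mean(x)
  acov <- vapply(0:p, function(l)
    sum((x[seq_len(n - l)] - mu) * (x[seq_len(n - l) + l] - mu)) / n,
    numeric(1))
  as.numeric(solve(toeplitz(acov[1:p]), acov[2:(p + 1)]))
}

# Welch PSD written independently: explicit segment loop, hand-built
# Hamming taper, one-sided density scaling
oracleWelch <- function(x, fs, segment = 256, overlap = 0.5) {
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(segment - 1)) / (segment - 1))
  step <- round(segment * (1 - overlap))
  starts <- seq(1, length(x) - segment + 1, by = step)
  nHalf <- segment %/% 2
  acc <- rep(0, nHalf + 1)
  for (s in starts) {
    seg <- x[s:(s + segment - 1)] * w
    sp <- abs(stats::fft(seg))^2 / (fs * sum(w^2))
    one <- sp[1:(nHalf + 1)]
    one[2:nHalf] <- 2 * one[2:nHalf]
    acc <- acc + one
  }
  list(freq = (0:nHalf) * fs / segment, power = acc / length(starts))
}

# literal (loop-heavy) evaluation of all 35 features
oracleFeatures <- function(x, fs, params = featureParams()) {
  n <- length(x)
  mu <- mean(x)
  absSum <- 0; sqSum <- 0; logSum <- 0
  for (v in x) {
    absSum <- absSum + abs(v)
    sqSum <- sqSum + v^2
    logSum <- logSum + log(max(abs(v), 1e-12))
  }
  wl <- 0; aacSum <- 0; wamp <- 0
  for (i in seq_len(n - 1)) {
    d <- x[i + 1] - x[i]
    wl <- wl + abs(d)
    aacSum <- aacSum + d^2
    if (abs(d) > mu) wamp <- wamp + 1
  }
  varSum <- 0
  for (v in x) varSum <- varSum + (v - mu)^2
  myo <- 0
  for (v in x) if (v > 2 * mu) myo <- myo + 1
  s <- sign(x - mu)
  for (i in rev(seq_len(n - 1))) if (s[i] == 0) s[i] <- s[i + 1]
  s <- s[s != 0]
  zc <- 0
  for (i in seq_len(length(s) - 1)) if (s[i] != s[i + 1]) zc <- zc + 1
  d <- diff(x); d <- d[d != 0]
  ssc <- 0
  for (i in seq_len(length(d) - 1))
    if (sign(d[i]) != sign(d[i + 1])) ssc <- ssc + 1

  sdx <- sqrt(varSum / (n - 1))
  temporal <- c(
    SENT = oracleSampEn(x, params$sampenM, params$sampenR * sdx),
    MAV = absSum / n, VAR = varSum / (n - 1), RMS = sqrt(sqSum / n),
    LOG = exp(logSum / n), WL = wl, STD = sdx,
    AAC = sqrt(aacSum / (n - 1)),
    FD = oracleHiguchi(x, params$higuchiKmax), MFL = log(wl),
    MYO = 100 * myo / n, IEMG = absSum, SSI = sqSum, ZC = zc, SSC = ssc,
    WAMP = wamp)
  ar <- oracleYuleWalker(x, params$arOrder)
  names(ar) <- paste0("AR", seq_along(ar))

  psd <- oracleWelch(x, fs, params$welchSegment, params$welchOverlap)
  P <- psd$power; f <- psd$freq
  tp <- 0; sm <- c(0, 0, 0); wf <- 0
  for (i in seq_along(P)) {
    tp <- tp + P[i]
    wf <- wf + f[i] * P[i]
    for (m in 1:3) sm[m] <- sm[m] + P[i] * f[i]^m
  }
  mp <- tp / length(P)
  cs <- 0; mdf <- NA
  for (i in seq_along(P)) {
    cs <- cs + P[i]
    if (is.na(mdf) && cs >= tp / 2) mdf <- f[i]
  }
  m2 <- mean((P - mp)^2); m3 <- mean((P - mp)^3); m4 <- mean((P - mp)^4)
  ac <- numeric(params$autocorrLags)
  denom <- sum((x - mu)^2)
  for (l in seq_len(params$autocorrLags))
    ac[l] <- sum((x[seq_len(n - l)] - mu) * (x[seq_len(n - l) + l] - mu)) / denom
  names(ac) <- paste0("Auto", seq_len(params$autocorrLags))
  spectral <- c(Pmax = max(P), Fmax = f[which.max(P)], MP = mp, TP = tp,
                MNF = wf / tp, MDF = mdf,
                STDp = sqrt(sum((P - mp)^2) / (length(P) - 1)),
                SM1 = sm[1], SM2 = sm[2], SM3 = sm[3],
                KUR = m4 / m2^2, SKW = m3 / m2^1.5, ac)
  c(temporal, ar, spectral)
}

# drawing with a known smooth template and optional sinusoidal tremor,
# built without the package generator (for ingest/dct tests)
makeSpiralXY <- function(n = 1024, turns = 3, fs = 100, tremorHz = 0,
                         tremorAmp = 0) {
  t <- (seq_len(n) - 1) / fs
  u <- t / max(t)
  theta <- 2 * pi * turns * (3 * u^2 - 2 * u^3)
  x <- 10 * theta * cos(theta)
  y <- 10 * theta * sin(theta)
  if (tremorAmp > 0) {
    x <- x + tremorAmp * sin(2 * pi * tremorHz * t)
    y <- y + 0.8 * tremorAmp * sin(2 * pi * tremorHz * t)
  }
  list(x = x, y = y, t = t)
}

randomFeatureCohort <- function(n = 24, p = 3, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("F", seq_len(p))))
    labels <- rep(c("ET", "CONTROL"), length.out = n)
  })
  SpiralFeatures(X, labels = labels)
}
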