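#' Orthonormal DCT-II forward transform
#'
#' Computes the type-II discrete cosine transform in the orthonormal
#' convention,
#' \deqn{X_k = c_k \sum_{n=0}^{N-1} x_n \cos\left(\frac{\pi}{N}\left(n+\tfrac12\right)k\right)}
#' with \eqn{c_0 = \sqrt{1/N}} and \eqn{c_k = \sqrt{2/N}} for k > 0, so the
#' transform matrix is orthogonal and Parseval's identity holds exactly.
#' Evaluated in O(N log N) via a length-N FFT of the even/odd reordered
#' sequence (Makhoul's algorithm).
#'
#' @param x real sequence (finite values).
#' @return a [DCTSpectrum-class] of the same length.
#' @examples
#' seqValues(dct2Forward(c(1, 1, 1, 1)))  # c(2, 0, 0, 0)
#' @export
dct2Forward <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 1) stop("input must have at least one sample")
  if (!all(is.finite(x))) stop("input must be finite")
  if (n == 1) return(new("DCTSpectrum", coeffs = x))
  raw <- dct2Raw(x)
  scale <- c(sqrt(1 / n), rep(sqrt(2 / n), n - 1))
  new("DCTSpectrum", coeffs = raw * scale)
}

# unnormalized DCT-II: raw_k = sum_n x_n cos(pi*(2n+1)k/(2N))
dct2Raw <- function(x) {
  n <- length(x)
  v <- c(x[seq(1, n, by = 2)],
         if (n > 1) x[seq(if (n %% 2 == 0) n else n - 1, 2, by = -2)])
  V <- stats::fft(v)
  k <- 0:(n - 1)
  Re(exp(-1i * pi * k / (2 * n)) * V)
}

# inverse of dct2Raw (unnormalized DCT-III up to the c_k weights)
dct3Raw <- function(raw) {
  n <- length(raw)
  k <- 0:(n - 1)
  rawRev <- c(0, raw[n:2])            # raw[N-k] with raw[N] := 0
  V <- exp(1i * pi * k / (2 * n)) * (raw - 1i * rawRev)
  v <- Re(stats::fft(V, inverse = TRUE)) / n
  x <- numeric(n)
  nEven <- ceiling(n / 2)
  x[seq(1, n, by = 2)] <- v[seq_len(nEven)]
  if (n > 1)
    x[seq(if (n %% 2 == 0) n else n - 1, 2, by = -2)] <- v[(nEven + 1):n]
  x
}

#' Orthonormal DCT-II inverse transform
#'
#' Reconstructs the sequence from all N coefficients:
#' \deqn{x_n = \sum_{k=0}^{N-1} c_k X_k \cos\left(\frac{\pi}{N}\left(n+\tfrac12\right)k\right)}
#' Exact inverse of [dct2Forward()] up to floating-point rounding.
#'
#' @param spec a [DCTSpectrum-class].
#' @return numeric sequence of length N.
#' @export
dct2Inverse <- function(spec) {
  stopifnot(is(spec, "DCTSpectrum"))
  X <- spec@coeffs
  n <- length(X)
  if (n == 1) return(X)
  scale <- c(sqrt(1 / n), rep(sqrt(2 / n), n - 1))
  dct3Raw(X / scale)
}

#' Partial reconstruction from the first L DCT coefficients
#'
#' Rebuilds the smooth approximation of a sequence using only coefficients
#' k = 0 .. L-1 (the DC term is inside the reconstruction whenever L >= 1).
#' Because the basis is orthonormal, the squared error of the approximation
#' equals the energy of the discarded tail coefficients.
#'
#' @param spec a [DCTSpectrum-class].
#' @param L number of leading coefficients to keep, 0 <= L <= N. `L = N`
#'   reproduces the full inverse; `L = 0` returns all zeros.
#' @return numeric sequence of length N.
#' @export
partialReconstruction <- function(spec, L) {
  stopifnot(is(spec, "DCTSpectrum"))
  n <- length(spec@coeffs)
  if (!is.numeric(L) || length(L) != 1 || L != round(L) || L < 0 || L > n)
    stop("L must be an integer in [0, N]")
  L <- as.integer(L)
  if (L == 0) return(numeric(n))
  kept <- spec@coeffs
  if (L < n) kept[(L + 1):n] <- 0
  dct2Inverse(new("DCTSpectrum", coeffs = kept))
}

#' DCT residue of a sequence
#'
#' The residue is the original sequence minus its partial reconstruction
#' from the first L coefficients, `x - partialReconstruction(dct2Forward(x), L)`,
#' so original = approximation + residue holds exactly by construction. For
#' a smooth spiral trajectory the low-order coefficients capture the
#' template shape and the residue carries the high-order tremor content.
#'
#' @param x real sequence.
#' @param L number of leading coefficients removed, 0 <= L <= N.
#' @return numeric residue sequence of length N.
#' @export
dctResidue <- function(x, L) {
  x <- as.numeric(x)
  x - partialReconstruction(dct2Forward(x), L)
}

#' Polar radius sequence of a drawing
#'
#' Transforms the Cartesian coordinates to polar form about the origin and
#' keeps the radius, r\[n\] = sqrt(x\[n\]^2 + y\[n\]^2). The radius is
#' origin-dependent, so coordinates are centered first by default (tablet
#' coordinates are absolute and an uncentered radius is dominated by the
#' offset).
#'
#' @param seq a [CoordinateSequence-class].
#' @param center centre the coordinates first (default TRUE; skipped if the
#'   sequence is already centered).
#' @return a [ScalarSequence-class] of kind `"RADIUS"`.
#' @export
radiusSequence <- function(seq, center = TRUE) {
  stopifnot(is(seq, "CoordinateSequence"))
  if (center && !seq@centered) seq <- centerCoordinates(seq)
  new("ScalarSequence", values = sqrt(seq@x^2 + seq@y^2), fs = seq@fs,
      kind = "RADIUS")
}

#' Residue-distance sequence of a drawing
#'
#' Applies the DCT-II to each coordinate axis separately, removes the
#' partial reconstruction from the first L coefficients of each, and
#' collapses the two residues into a single non-negative sequence
#' \deqn{rd_n = \sqrt{\hat{x}_n^2 + \hat{y}_n^2}}
#' Residues are computed per axis and then combined; they are never taken
#' on the radius. Centering is off by default: for L >= 1 the residue
#' discards the DC coefficient, so a coordinate offset has no effect.
#'
#' @param seq a [CoordinateSequence-class].
#' @param L number of leading DCT coefficients removed per axis.
#' @param center centre the coordinates first (default FALSE).
#' @return a [ScalarSequence-class] of kind `"RESIDUE_DISTANCE"`.
#' @export
residueDistanceSequence <- function(seq, L, center = FALSE) {
  stopifnot(is(seq, "CoordinateSequence"))
  if (center && !seq@centered) seq <- centerCoordinates(seq)
  rx <- dctResidue(seq@x, L)
  ry <- dctResidue(seq@y, L)
  new("ScalarSequence", values = sqrt(rx^2 + ry^2), fs = seq@fs,
      kind = "RESIDUE_DISTANCE")
}

#' Write a scalar sequence as single-column CSV
#'
#' The header records the sequence kind, the number of removed coefficients
#' (if given) and the sampling rate, e.g. `value # kind=RESIDUE_DISTANCE L=17 fs=409.6`.
#'
#' @param seq a [ScalarSequence-class].
#' @param path output path.
#' @param L optional coefficient count to record in the header.
#' @return `path`, invisibly.
#' @export
writeScalarSequence <- function(seq, path, L = NA) {
  stopifnot(is(seq, "ScalarSequence"))
  header <- sprintf("value # kind=%s L=%s fs=%.10g", seq@kind,
                    ifelse(is.na(L), "NA", as.character(L)), seq@fs)
  writeLines(c(header, sprintf("%.10g", seq@values)), path)
  invisible(path)
}
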