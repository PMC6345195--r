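#' Read a digitized spiral drawing from disk
#'
#' Reads a pen trajectory from a comma-separated file (optional header
#' containing `x` and `y` column names) or from an SVC handwriting file
#' (whitespace-separated, no header, columns ordered x, y, timestamp,
#' pen-status, azimuth, altitude, pressure; an optional leading line holding
#' the point count is tolerated). Only the x/y columns are consumed: pen
#' status, angles and pressure are discarded, and pen-up points are kept.
#' Rows with non-finite coordinates are dropped with a message.
#'
#' @param path path to the file.
#' @param format `"auto"` (by extension, `.svc` -> svc, otherwise csv),
#'   `"csv"` or `"svc"`.
#' @param label,hand,subjectId metadata to attach; `subjectId` defaults to
#'   the file name without extension.
#' @param fsNominal nominal sampling rate of the digitizer, Hz.
#' @return a [DrawingSample-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(x = sin(1:50), y = cos(1:50)), f, row.names = FALSE)
#' readDrawing(f)
#' @export
readDrawing <- function(path, format = c("auto", "csv", "svc"),
                        label = c("UNKNOWN", "ET", "CONTROL"),
                        hand = c("UNKNOWN", "DOMINANT", "NONDOMINANT"),
                        subjectId = NULL, fsNominal = 100) {
  format <- match.arg(format)
  label <- match.arg(label)
  hand <- match.arg(hand)
  if (!file.exists(path))
    stop("cannot read drawing: file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.svc$", path, ignore.case = TRUE)) "svc" else "csv"
  if (is.null(subjectId))
    subjectId <- sub("\\.[^.]*$", "", basename(path))

  if (format == "csv") {
    first <- readLines(path, n = 1)
    hasHeader <- grepl("x", first, ignore.case = TRUE) &&
      grepl("y", first, ignore.case = TRUE) &&
      !grepl("^[-+0-9.eE, \t]*$", first)
    tab <- utils::read.csv(path, header = hasHeader,
                           stringsAsFactors = FALSE)
    if (hasHeader) {
      cn <- tolower(colnames(tab))
      xi <- match("x", cn); yi <- match("y", cn)
      if (is.na(xi) || is.na(yi))
        stop("CSV header must name x and y columns: ", path)
    } else {
      xi <- 1L; yi <- 2L
    }
    if (ncol(tab) < max(xi, yi))
      stop("CSV needs at least two coordinate columns: ", path)
    x <- suppressWarnings(as.numeric(tab[[xi]]))
    y <- suppressWarnings(as.numeric(tab[[yi]]))
    t <- numeric(0)
    ti <- if (hasHeader) match("timestamp", tolower(colnames(tab))) else NA
    if (!is.na(ti)) t <- suppressWarnings(as.numeric(tab[[ti]]))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    # SVC dialect: an optional first line holding only the point count
    if (length(lines) && length(strsplit(trimws(lines[1]), "\\s+")[[1]]) == 1)
      lines <- lines[-1]
    tab <- utils::read.table(text = lines, header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2)
      stop("SVC file needs at least two coordinate columns: ", path)
    x <- suppressWarnings(as.numeric(tab[[1]]))
    y <- suppressWarnings(as.numeric(tab[[2]]))
    t <- numeric(0)
  }

  keep <- is.finite(x) & is.finite(y)
  nDropped <- sum(!keep)
  if (nDropped > 0) {
    message(sprintf("readDrawing: dropped %d row(s) with non-finite coordinates in %s",
                    nDropped, basename(path)))
    x <- x[keep]; y <- y[keep]
    if (length(t)) t <- t[keep]
  }
  if (length(x) < 8)
    stop(sprintf("degenerate drawing '%s': only %d valid coordinate rows (need >= 8)",
                 path, length(x)))
  if (length(t) && (anyNA(t) || any(diff(t) <= 0)))
    t <- numeric(0)  # unusable timestamps are ignored, index axis is used
  DrawingSample(x = x, y = y, subjectId = subjectId, label = label,
                hand = hand, t = t, fsNominal = fsNominal)
}

#' Write coordinates as a two-column CSV
#'
#' Serializes a [CoordinateSequence-class] (or [DrawingSample-class]) as a
#' CSV with header `x,y`, 10 significant digits, so a read/write round-trip
#' reproduces the coordinates as decimal text.
#'
#' @param obj object with coordinates.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCoordinates <- function(obj, path) {
  xy <- coordinates(obj)
  lines <- c("x,y", sprintf("%.10g,%.10g", xy[, 1], xy[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' Resample a drawing to a fixed number of points
#'
#' Linearly interpolates x and y independently onto `nPoints` uniformly
#' spaced positions along the original sample-index axis, so every drawing
#' in a cohort supports a DCT of the same length. The first and last
#' original points are preserved exactly, and the effective sampling rate
#' is scaled by `nPoints / nPoints(sample)`.
#'
#' @param sample a [DrawingSample-class].
#' @param nPoints target length (default 4096).
#' @param method `"linear"` (default; robust for non-bandlimited strokes) or
#'   `"fourier"` (periodic sinc interpolation of the linearly detrended
#'   signal, for band-limited inputs).
#' @return a [CoordinateSequence-class] with `fs = fsNominal * nPoints / n0`.
#' @examples
#' d <- generateSpiral(spiralParams(seed = 1))
#' s <- resampleToN(d, 4096)
#' samplingRate(s)  # 409.6 Hz for a 1000-point drawing at 100 Hz... etc.
#' @export
resampleToN <- function(sample, nPoints = 4096,
                        method = c("linear", "fourier")) {
  method <- match.arg(method)
  stopifnot(is(sample, "DrawingSample"))
  if (!is.numeric(nPoints) || length(nPoints) != 1 || nPoints < 2)
    stop("nPoints must be an integer >= 2")
  nPoints <- as.integer(nPoints)
  n0 <- length(sample@x)
  grid <- seq(1, n0, length.out = nPoints)
  resampleAxis <- function(v) {
    if (method == "linear") {
      stats::approx(seq_len(n0), v, xout = grid, method = "linear")$y
    } else {
      # detrend so the periodic extension implicit in the DFT has no jump
      slope <- (v[n0] - v[1]) / (n0 - 1)
      trend <- v[1] + slope * (seq_len(n0) - 1)
      d <- v - trend
      sp <- stats::fft(d)
      # zero-pad / truncate the spectrum symmetrically, then evaluate
      out <- Re(sincInterp(sp, n0, grid))
      out + v[1] + slope * (grid - 1)
    }
  }
  new("CoordinateSequence",
      x = resampleAxis(sample@x), y = resampleAxis(sample@y),
      fs = sample@fsNominal * nPoints / n0, centered = FALSE)
}

# evaluate the trigonometric interpolant of a length-n0 DFT at arbitrary
# (1-based) positions
sincInterp <- function(sp, n0, grid) {
  k <- 0:(n0 - 1)
  k[k > n0 / 2] <- k[k > n0 / 2] - n0  # signed frequencies
  if (n0 %% 2 == 0) sp[n0 / 2 + 1] <- Re(sp[n0 / 2 + 1])  # Nyquist
  vapply(grid, function(g) {
    Re(sum(sp * exp(2i * pi * k * (g - 1) / n0))) / n0
  }, numeric(1))
}

#' Center coordinates on their mean
#'
#' Subtracts the per-axis mean from x and y. The polar radius sequence is
#' origin-dependent, so the absolute tablet offset must be removed before
#' the radius method; the DCT residue discards the DC coefficient for
#' L >= 1 and so is unaffected by centering.
#'
#' @param seq a [CoordinateSequence-class].
#' @return the centered sequence with `centered = TRUE`. Idempotent up to
#'   numerical tolerance.
#' @export
centerCoordinates <- function(seq) {
  stopifnot(is(seq, "CoordinateSequence"))
  new("CoordinateSequence", x = seq@x - mean(seq@x), y = seq@y - mean(seq@y),
      fs = seq@fs, centered = TRUE)
}
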