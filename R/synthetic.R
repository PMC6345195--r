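#' Parameters of the synthetic spiral generator
#'
#' Describes one simulated Archimedes' spiral drawing: the base trajectory
#' is `x = pitch * theta * cos(theta)`, `y = pitch * theta * sin(theta)`
#' with `theta` increasing monotonically from 0 to `2 * pi * turns` over
#' `durationS` seconds at sampling rate `fs`. Kinetic tremor is added as a
#' sinusoid of frequency `tremorFreqHz` and amplitude `tremorAmp` directed
#' either across the stroke (`"perpendicular"`, the default — kinetic
#' tremor acts across the drawing direction) or along the radius
#' (`"radial"`). Slow drift (low-pass-filtered white noise, 0.5 Hz cutoff,
#' RMS `driftAmp`) and white positional jitter (`jitterSd`) model
#' non-tremor acquisition noise. All randomness is governed by `seed`.
#'
#' @param turns number of spiral revolutions (default 3).
#' @param durationS drawing duration, seconds (default 15).
#' @param fs sampling rate, Hz (default 100).
#' @param pitch spiral pitch, length units per radian (default 10).
#' @param tremorFreqHz tremor frequency in \[0, fs/2) Hz; the kinetic
#'   tremor band of interest is 4-12 Hz.
#' @param tremorAmp tremor amplitude, length units (default 0: no tremor).
#' @param tremorMode `"perpendicular"` or `"radial"`.
#' @param driftAmp RMS of the slow drift, length units (default 0).
#' @param jitterSd SD of white positional jitter, length units (default 0).
#' @param angularProfile `"easeInOut"` (smoothstep: the pen accelerates
#'   from rest and decelerates to rest, the default) or `"constant"`
#'   (uniform angular rate).
#' @param seed integer seed.
#' @return a named list of class `SpiralParams`.
#' @export
spiralParams <- function(turns = 3, durationS = 15, fs = 100, pitch = 10,
                         tremorFreqHz = 8, tremorAmp = 0,
                         tremorMode = c("perpendicular", "radial"),
                         driftAmp = 0, jitterSd = 0,
                         angularProfile = c("easeInOut", "constant"),
                         seed = 1L) {
  p <- list(turns = turns, durationS = durationS, fs = fs, pitch = pitch,
            tremorFreqHz = tremorFreqHz, tremorAmp = tremorAmp,
            tremorMode = match.arg(tremorMode), driftAmp = driftAmp,
            jitterSd = jitterSd, angularProfile = match.arg(angularProfile),
            seed = as.integer(seed))
  if (p$fs <= 0) stop("fs must be positive")
  if (p$durationS <= 0) stop("durationS must be positive")
  if (p$turns <= 0) stop("turns must be positive")
  if (p$tremorFreqHz < 0 || p$tremorFreqHz >= p$fs / 2)
    stop("tremorFreqHz must lie in [0, fs/2)")
  if (p$tremorAmp < 0 || p$driftAmp < 0 || p$jitterSd < 0)
    stop("amplitudes must be non-negative")
  class(p) <- "SpiralParams"
  p
}

#' Generate one synthetic spiral drawing
#'
#' Deterministic given `p$seed`: the same parameters always produce a
#' bit-identical drawing. The returned sample carries label `"UNKNOWN"`;
#' cohort generation attaches labels separately so that feature extraction
#' can never see the ground truth.
#'
#' @param p a [spiralParams()] list.
#' @return a [DrawingSample-class] with `durationS * fs` points.
#' @examples
#' d <- generateSpiral(spiralParams(tremorAmp = 5, seed = 42))
#' nPoints(d)
#' @export
generateSpiral <- function(p) {
  stopifnot(inherits(p, "SpiralParams"))
  n <- round(p$durationS * p$fs)
  t <- (seq_len(n) - 1) / p$fs
  u <- t / p$durationS
  prog <- switch(p$angularProfile,
                 constant = u,
                 easeInOut = 3 * u^2 - 2 * u^3)
  theta <- 2 * pi * p$turns * prog
  x <- p$pitch * theta * cos(theta)
  y <- p$pitch * theta * sin(theta)

  if (p$tremorAmp > 0) {
    withr::with_seed(p$seed, phase <- stats::runif(1, 0, 2 * pi))
    osc <- p$tremorAmp * sin(2 * pi * p$tremorFreqHz * t + phase)
    if (p$tremorMode == "radial") {
      ux <- cos(theta); uy <- sin(theta)
    } else {
      # unit tangent of the noiseless path, rotated by 90 degrees
      dx <- p$pitch * (cos(theta) - theta * sin(theta))
      dy <- p$pitch * (sin(theta) + theta * cos(theta))
      nrm <- sqrt(dx^2 + dy^2)
      nrm[nrm == 0] <- 1
      ux <- -dy / nrm; uy <- dx / nrm
    }
    x <- x + osc * ux
    y <- y + osc * uy
  }

  withr::with_seed(p$seed + 1L, {
    if (p$driftAmp > 0) {
      bw <- signal::butter(2, min(0.5 / (p$fs / 2), 0.99), type = "low")
      for (axis in 1:2) {
        w <- stats::rnorm(n)
        dr <- as.numeric(signal::filtfilt(bw, w))
        rms <- sqrt(mean(dr^2))
        if (rms > 0) dr <- dr * p$driftAmp / rms
        if (axis == 1) x <- x + dr else y <- y + dr
      }
    }
    if (p$jitterSd > 0) {
      x <- x + stats::rnorm(n, 0, p$jitterSd)
      y <- y + stats::rnorm(n, 0, p$jitterSd)
    }
  })

  DrawingSample(x = x, y = y, subjectId = sprintf("sim%08d", p$seed),
                label = "UNKNOWN", t = t, fsNominal = p$fs)
}

#' Specification of a synthetic cohort
#'
#' Class sizes default to 24 tremor and 27 control drawings. Tremor
#' amplitude ranges are expressed relative to the spiral pitch so cohorts
#' are scale-free; the tremor-class range must lie strictly above the
#' control range. Per-drawing tremor frequencies are drawn uniformly from
#' `freqRange` (default the 4-12 Hz kinetic tremor band) for both classes
#' (controls carry low-amplitude physiological oscillation in the same
#' band).
#'
#' @param nEt,nControl class sizes (default 24 / 27).
#' @param etAmpRange tremor-class amplitude interval, in units of pitch
#'   (default 0.5-2.0: tremor displacement comparable to the gap between
#'   spiral arms).
#' @param controlAmpRange control amplitude interval, units of pitch
#'   (default 0.02-0.1: barely visible physiological oscillation).
#' @param freqRange tremor frequency interval, Hz.
#' @param driftAmp,jitterSd shared acquisition-noise levels, units of
#'   pitch (defaults 0.3 and 0.05).
#' @param baseParams template [spiralParams()] for the noiseless spiral.
#' @param seed cohort master seed; per-drawing sub-seeds derive from it.
#' @return a named list of class `CohortSpec`.
#' @export
cohortSpec <- function(nEt = 24L, nControl = 27L,
                       etAmpRange = c(0.5, 2.0),
                       controlAmpRange = c(0.02, 0.1),
                       freqRange = c(4, 12), driftAmp = 0.3,
                       jitterSd = 0.05, baseParams = spiralParams(),
                       seed = 1L) {
  sp <- list(nEt = as.integer(nEt), nControl = as.integer(nControl),
             etAmpRange = etAmpRange, controlAmpRange = controlAmpRange,
             freqRange = freqRange, driftAmp = driftAmp,
             jitterSd = jitterSd, baseParams = baseParams,
             seed = as.integer(seed))
  if (sp$nEt < 1 || sp$nControl < 1) stop("class sizes must be >= 1")
  if (any(etAmpRange < 0) || any(controlAmpRange < 0))
    stop("amplitude ranges must be non-negative")
  if (min(etAmpRange) < max(controlAmpRange))
    stop("the tremor-class amplitude range must lie strictly above the control range")
  class(sp) <- "CohortSpec"
  sp
}

#' Generate a labelled synthetic cohort
#'
#' Draws per-sample tremor frequencies and amplitudes from the cohort
#' ranges under the master seed, then generates each drawing with its own
#' derived sub-seed. Ground-truth parameters are returned in a manifest
#' separate from the drawings.
#'
#' @param spec a [cohortSpec()] list.
#' @return list with `drawings` (list of [DrawingSample-class], labelled)
#'   and `manifest` (data.frame of subject_id, label, tremor frequency and
#'   amplitude in pitch units, noise levels, sub-seed).
#' @examples
#' coh <- generateCohort(cohortSpec(nEt = 3, nControl = 3, seed = 7))
#' coh$manifest
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  n <- spec$nEt + spec$nControl
  labels <- c(rep("ET", spec$nEt), rep("CONTROL", spec$nControl))
  withr::with_seed(spec$seed, {
    freqs <- stats::runif(n, spec$freqRange[1], spec$freqRange[2])
    amps <- numeric(n)
    amps[labels == "ET"] <- stats::runif(spec$nEt, spec$etAmpRange[1],
                                         spec$etAmpRange[2])
    amps[labels == "CONTROL"] <- stats::runif(spec$nControl,
                                              spec$controlAmpRange[1],
                                              spec$controlAmpRange[2])
  })
  subSeeds <- (as.numeric(spec$seed) * 1009 + 17 * seq_len(n)) %% 2147483647
  bp <- spec$baseParams
  drawings <- vector("list", n)
  for (i in seq_len(n)) {
    p <- spiralParams(turns = bp$turns, durationS = bp$durationS,
                      fs = bp$fs, pitch = bp$pitch,
                      tremorFreqHz = freqs[i],
                      tremorAmp = amps[i] * bp$pitch,
                      tremorMode = bp$tremorMode,
                      driftAmp = spec$driftAmp * bp$pitch,
                      jitterSd = spec$jitterSd * bp$pitch,
                      angularProfile = bp$angularProfile,
                      seed = as.integer(subSeeds[i]))
    d <- generateSpiral(p)
    d@subjectId <- sprintf("%s_%02d", tolower(labels[i]), i)
    d@label <- labels[i]
    drawings[[i]] <- d
  }
  manifest <- data.frame(subject_id = vapply(drawings, function(d) d@subjectId,
                                             character(1)),
                         label = labels, tremor_freq_hz = freqs,
                         tremor_amp_pitch = amps,
                         drift_amp_pitch = spec$driftAmp,
                         jitter_sd_pitch = spec$jitterSd,
                         seed = as.integer(subSeeds))
  list(drawings = drawings, manifest = manifest)
}

#' Write a cohort to disk
#'
#' One coordinate CSV per drawing plus `manifest.csv` holding the labels
#' and ground-truth generator parameters.
#'
#' @param cohort result of [generateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in cohort$drawings)
    writeCoordinates(d, file.path(dir, paste0(d@subjectId, ".csv")))
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
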