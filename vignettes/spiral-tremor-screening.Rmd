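---
title: "Screening kinetic tremor from Archimedes' spiral drawings with DCT residues"
author: "SpiralDCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening kinetic tremor from Archimedes' spiral drawings with DCT residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpiralDCT)
```

## The problem and the model

Essential tremor (ET) produces a kinetic, rhythmic oscillation in the
4–12 Hz band that appears when the affected muscle works — for example
while drawing. The Archimedes' spiral is the standard clinical drawing
test for it, and modern digitizing tablets record the pen trajectory as a
stream of $(x_n, y_n)$ coordinates (nominally at 100 Hz). SpiralDCT
implements a screening pipeline that uses *only* those two coordinates,
the minimum any digitizer provides.

The central idea is a frequency-separation argument. An Archimedes'
spiral $r = b\theta$ drawn over tens of seconds is a very smooth,
low-frequency trajectory; under the type-II discrete cosine transform
(DCT-II) almost all of its energy collapses into the first few
coefficients — the transform's well-known spectral compaction. A 4–12 Hz
tremor superimposed on a 15-second drawing, by contrast, completes dozens
to hundreds of cycles and therefore lives in high-order coefficients.
Removing the first $L$ coefficients removes the spiral template and keeps
the tremor.

With the orthonormal convention used throughout,

$$X_k = c_k \sum_{n=0}^{N-1} x_n \cos\!\Big(\frac{\pi}{N}\big(n+\tfrac12\big)k\Big),
\qquad c_0 = \sqrt{1/N},\; c_k = \sqrt{2/N}\ (k>0),$$

the transform matrix is orthogonal: the inverse is the transpose,
Parseval's identity holds exactly, and the squared error of a partial
reconstruction $\tilde{x}$ from coefficients $k < L$ equals the energy of
the discarded tail. The package computes the transform in $O(N\log N)$
via an FFT of the even/odd-reordered sequence and verifies it in the test
suite against a direct $O(N^2)$ evaluation of the defining sum.

Each drawing is collapsed to a single real sequence in one of two ways:

* **radius method** — centre the coordinates and take
  $r_n = \sqrt{x_n^2 + y_n^2}$;
* **residue method** — transform each axis, subtract the partial
  reconstruction from the first $L$ coefficients, and combine the two
  residues as $rd_n = \sqrt{\hat{x}_n^2 + \hat{y}_n^2}$.

The residues are always computed per axis and then combined; the radius
is origin-dependent, so centering defaults to on for the radius method
and off for the residue method (for $L \ge 1$ a coordinate offset lives
entirely in the discarded DC coefficient).

A practical note on $rd_n$: it is a modulus. If the two axis residues
oscillate in phase, $rd_n \approx |a\sin\omega t|$, which is a rectified
oscillation whose spectrum concentrates at $2\omega$; an exact quadrature
pair would even give a constant. The feature bank below therefore never
relies on the tremor line sitting exactly at its injected frequency — it
summarizes amplitude, irregularity and spectral shape instead. The test
suite accepts a dominant periodogram peak at either the injected
frequency or its rectified double.

## The feature bank

From either sequence the package extracts 35 descriptors: 20 temporal
(sample entropy; mean absolute value, variance, RMS, log detector;
waveform length and its log, the maximum fractal length; difference
statistics; Higuchi's fractal dimension; myopulse percentage; integrated
and squared amplitude; mean-crossing, slope-sign-change and Wilson
amplitude counts; four Yule–Walker autoregressive coefficients) and 15
spectral (Welch-periodogram peak, mean, total and spread statistics, mean
and median frequency, three spectral moments, kurtosis and skewness of
the periodogram values, and the first three autocorrelation coefficients
of the time sequence). The exact formulas are documented in
`?temporalFeatures` and `?spectralFeatures`, and every one of them is
checked against a literal loop-based re-implementation in the tests.

Interpretation conventions that the formulas leave open were fixed once:

* sample entropy uses embedding $m = 3$, Chebyshev distance, tolerance
  $r = 0.2\,\mathrm{sd}(x)$, self-matches excluded;
* Higuchi's estimator uses $k_{\max} = 5$ with a least-squares fit in
  log–log;
* the Wilson amplitude threshold is literally the mean of the signal (not
  of its absolute value);
* mean crossings resolve exact zeros toward the following sample; slope
  sign changes skip zero differences;
* natural logarithms throughout;
* the three "autocorrelation" coefficients are lags 1–3 of the normalized
  autocorrelation of the *time* sequence (the periodogram reading of that
  name is also defensible; this one was chosen and is fixed);
* the Welch estimator uses 256-sample Hamming segments at 50% overlap —
  values the source material leaves unstated — and the sampling rate it
  sees is the *effective* rate after resampling (4096 points over the
  drawing duration), with `featureParams(fsOverride =)` available to
  force the nominal tablet rate instead;
* AR coefficients come from `stats::ar.yw` (biased autocovariance,
  demeaned series), reported in the prediction-polynomial sign convention
  without the leading 1.

Degenerate inputs are guarded rather than propagated: a constant sequence
gets sample entropy, fractal dimension and autocorrelations of 0 with a
warning.

## Selection and classification

ReliefF ranks the features: every sample is used as an anchor (no
stochastic subsampling, so the ranking is deterministic), with 10
nearest hits and misses under Manhattan distance on range-normalized
features; constant features get weight exactly 0. The classifiers are a
two-class linear discriminant with pooled covariance (ridge
$10^{-6}\,\mathrm{tr}(\Sigma)/d$ if singular), Euclidean $k$-NN whose
vote ties are decided by the single nearest neighbour, and a soft-margin
SVM with kernel $K(u,v) = \exp(-\lVert u-v\rVert^2/s^2)$. The kernel
scale convention matters: grids quoted over $s \in [0.1, 1.1]$ assume
exactly this parameterization, and `e1071`'s `gamma` is set to $1/s^2$
accordingly.

Evaluation offers leave-one-out (the headline protocol) and stratified
10-fold CV, over the standard grids: $L \in \{10,15,16,17,18,20,21,22,
23,25,30,50\}$, odd $k \in [1,33]$, costs $10^{-5}\ldots10^4$, scales
$0.1\ldots1.1$. Feature columns are scaled to unit Euclidean norm; the
`"global"` mode fits that scale on all samples (matching the historical
protocol this package reproduces), while `"trainfold"` fits it on each
training fold only. Likewise ReliefF selection can be fitted globally or
re-fitted inside every training fold (`selection = "relieffNested"`), the
leakage-safe choice we recommend for any new data; both are provided
because the historical results appear to have used the global variant,
and the package takes no position on which a given study used. The
reference five-feature subsets for the two methods (residue: MNF, WAMP,
MAV, MFL, FD; radius: MFL, FD, MYO, MAV, STD) are available via
`referenceTopFeatures()` so classifiers can be run on exactly those named
features without re-ranking.

## The synthetic cohort generator

The BIODARW/BIODARWO clinical drawings are private, so the package ships
a simulator that makes every stage testable. A drawing is
$x = b\theta\cos\theta$, $y = b\theta\sin\theta$ with $\theta$ rising
monotonically to $2\pi \cdot \text{turns}$ over 15 s at 100 Hz; kinetic
tremor is a sinusoid at a per-subject frequency drawn from 4–12 Hz,
injected perpendicular to the instantaneous path (kinetic tremor acts
across the stroke; a radial mode exists for radius-method studies);
acquisition noise is slow drift (low-pass-filtered white noise, 0.5 Hz
cutoff) plus white jitter. Everything is seed-deterministic, and cohort
ground truth lives in a manifest separate from the drawings so extraction
code cannot see it.

Default geometry: 3 turns with a smoothstep ease-in-out angular profile
(the pen accelerates from rest and decelerates to rest). These defaults
were chosen so the noiseless template is deeply compact under the
transform — the premise of the residue method. With them, the first 17
DCT coefficients of each centered axis carry more than 99.99% of the
variance and the tremor-free residue has RMS below 1% of a tremor
preset's; at 5 constant-rate turns the template's instantaneous
index-frequency approaches the $k = 17$ boundary and that premise
visibly degrades (compaction ~98.5%), which is why 3 smooth turns is the
shipped default rather than a faster, busier spiral.

Cohort defaults mirror a 24 ET / 27 control study. Amplitudes are
expressed relative to the spiral pitch: ET tremor 0.5–2.0 pitch units
(displacement comparable to the gap between spiral arms — clearly
visible, as in clinical ET drawings), controls 0.02–0.1 (barely visible
physiological oscillation), drift 0.3 and jitter 0.05 for both classes.
The two amplitude ranges are disjoint by construction (ratio at least
5x), which is what makes a >= 90% LOO accuracy expectation reasonable at
this sample size.

What the simulator does *not* emulate: biomechanics (tremor
amplitude/frequency modulation over the stroke, intention components near
direction reversals), pen-up excursions, pressure and pen-angle channels,
template deviations like arm crossings, and inter-subject variability in
drawing speed profiles beyond the smoothstep. Passing the surrogate study
therefore shows the pipeline recovers a band-limited oscillation of the
stated amplitude from a smooth template under noise — it does not certify
clinical accuracy on real drawings.

## Numerical choices and edge cases

* Resampling to a common 4096 points uses linear interpolation over the
  sample-index axis (robust for non-bandlimited pen strokes; endpoints
  preserved exactly); a Fourier variant (trigonometric interpolation of
  the linearly detrended signal) is available and preferable only for
  smooth, nearly periodic inputs. The effective sampling rate is scaled
  by $4096/n_0$ and carried on the sequence.
* `L` counts coefficients from $k = 0$ inclusive, so the DC term is
  inside every reconstruction with $L \ge 1$.
* LOO on $n$ samples trains each model on $n-1$; with at least two
  samples per class no fold can lose a class. Stratified folds are
  seed-deterministic and fall back to as-stratified-as-possible with a
  warning when a class has fewer members than folds.
* Zero-norm feature columns normalize to all zeros with a warning (the
  residue-distance WAMP column is structurally zero, for example:
  a non-negative sequence's mean typically exceeds all its consecutive
  differences).
* ReliefF ties in distance break by sample index; ranking ties in weight
  break by original feature index; `seed` arguments are accepted for
  interface stability but the procedure is deterministic.
* Percentages are carried at full precision and only rounded for
  display.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data:
transform checks at $N$ up to 4096; feature-formula checks on 50 random
sequences of ~512 points; the surrogate cohort study on 20 cohorts of
51 drawings (1500 raw points each, resampled to 4096) with the full
10 x 11 SVM grid under LOO. These sizes were chosen to exercise every
code path at the fidelity the method needs while keeping a full run in
the minutes range on one CPU.

## Known limitations

* The 34-vs-35 feature-count ambiguity in the source material is resolved
  by implementing all 35 enumerated descriptors.
* Welch settings, the ReliefF neighbour count, and the
  global-vs-nested placement of normalization and selection are not
  pinned by the historical protocol; the defaults above are reasonable
  choices, exposed as parameters, and recorded in outputs.
* The clinical headline accuracies from the private cohort are not
  reproducible here; the surrogate study is a property check of the
  pipeline, not a replication.
* Pen-up segments are retained (in-air points are not distinguished), and
  drawings are not trimmed before resampling.
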