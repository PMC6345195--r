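# SpiralDCT

Screening of essential-tremor-like kinetic tremor from digitized
Archimedes' spiral drawings, using only the x/y pen coordinates.

Drawing an Archimedes' spiral is the standard clinical test for essential
tremor (ET), a 4–12 Hz kinetic movement disorder. A digitizing tablet
records the pen trajectory as coordinate streams \((x_n, y_n)\) at
~100 Hz. This package is for researchers and engineers building
drawing-based tremor screens: it turns raw trajectories into a small set
of interpretable descriptors and cross-validated classification results,
and it ships a synthetic spiral simulator so the whole pipeline can be
developed and tested without clinical data.

## The method

The spiral template is smooth and low-frequency, so under the orthonormal
type-II discrete cosine transform

$$X_k = c_k \sum_{n=0}^{N-1} x_n \cos\!\Big(\tfrac{\pi}{N}\big(n+\tfrac12\big)k\Big),
\qquad c_0=\sqrt{1/N},\ c_k=\sqrt{2/N}\ (k>0),$$

nearly all of its energy sits in the first few coefficients, while a
4–12 Hz tremor over a 15 s drawing lives far above them. Each drawing
(resampled to N = 4096 points) is collapsed to one real sequence either
as the polar radius \(r_n=\sqrt{x_n^2+y_n^2}\) or as the **residue
distance** \(rd_n=\sqrt{\hat x_n^2+\hat y_n^2}\), where
\(\hat x = x - \tilde x\) is the per-axis residue after removing the
reconstruction from the first L coefficients (L = 17 is the canonical
choice). From either sequence, 35 temporal and spectral descriptors are
extracted (sample entropy, Higuchi fractal dimension, waveform and
amplitude statistics, Yule–Walker AR coefficients, Welch-periodogram
summaries); ReliefF ranks them; and LDA, k-NN and SVM-RBF classifiers are
evaluated under leave-one-out or stratified 10-fold CV, with
confusion-matrix sensitivity/specificity/accuracy reporting (ET is the
positive class).

## Worked example

Simulate a 24 ET / 27 control cohort, run the residue pipeline at L = 17,
rank features, and evaluate an SVM under leave-one-out CV:

```r
library(SpiralDCT)

coh <- generateCohort(cohortSpec(seed = 42))
fm  <- extractCohortFeatures(coh$drawings, method = "residue", L = 17)
fm  <- normalizeFeatures(fm, "global")
fm
#> SpiralFeatures: 35 features x 51 samples (24 ET, 27 CONTROL)
#> features: SENT, MAV, VAR, RMS, LOG, WL, STD, AAC ...

rk <- relieffRank(fm)
selectTop(rk, 5)
#> [1] "MYO" "MFL" "SSC" "AR4" "FD"

res <- evaluateClassifier(selectFeatures(fm, selectTop(rk, 5)),
                          "svmRbf", svmCost = 1000, svmScale = 0.2)
confusion(res)
#> ConfusionMatrix (positive class: ET)
#>                Pred ET Pred CONTROL
#> Actual ET           24            0
#> Actual CONTROL       0           27
#> accuracy 100.00%  sensitivity 100.00%  specificity 100.00%
```

On this synthetic cohort the tremor class carries oscillation amplitudes
0.5–2.0 spiral-pitch units against 0.02–0.1 for controls, so a clean
separation is the expected outcome; the interesting content is *which*
descriptors carry it (here myopulse rate, maximum fractal length, slope
sign changes, an AR coefficient and the fractal dimension — amplitude and
irregularity measures of the residue sequence, consistent with the
reference subsets in `referenceTopFeatures()`).

Named-subset evaluation, hyperparameter grids
(`svmGridSearch()`, `accuracyGrid()` over
`coefficientGrid()`/`knnGrid()`/`svmCostGrid()`/`svmScaleGrid()`),
combined residue+radius feature sets (`combineFeatureSets()`), and
file-based cohorts (`readDrawing()`, `readCohort()`, CSV and SVC formats)
are documented in the help pages and the vignette
(`vignettes/spiral-tremor-screening.Rmd`). A thin command-line front end
lives at `inst/cli/spiraldct.R` (subcommands `simulate`, `extract`,
`rank`, `evaluate`, `reproduce`).

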