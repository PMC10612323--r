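---
title: "Peak quality metrics and likelihood-calibrated feature curation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak quality metrics and likelihood-calibrated feature curation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakgrader)
```

## The problem and the model

Peak-picking algorithms for untargeted LC–MS favor false positives: a
noise feature can be discarded later, a missed feature is gone. On noisy
separations (HILIC in particular) the majority of reported mass features
can be artifacts, and manual review of every extracted ion chromatogram
(EIC) is slow and irreproducible. `peakgrader` replaces the binary
keep/drop judgement with a calibrated likelihood: a logistic regression of
expert Good/Bad labels on quality metrics, so that the analyst chooses an
operating point (e.g. a 0.9 likelihood threshold for a low false discovery
rate on novel data, 0.5 for exploratory work) instead of trusting a black
box.

The two metrics that carry most of the signal are recomputed from the raw
data inside each peak's m/z × RT bounding box:

**Peak shape.** Retention times are linearly scaled onto $[0,1]$
(subtract the minimum, divide by the maximum of the shifted values). The
intensities are correlated (Pearson) against the beta-distribution pdf
evaluated at those scaled positions, for $\alpha \in \{2.5, 3, 4, 5\}$
with $\beta = 5$ — a family running from nearly symmetric bell curves to
strongly right-tailed ones, chosen because the beta pdf lives exactly on
the unit interval and is cheap to evaluate. The metric is the maximum of
the four correlations. Pearson's $r$ is invariant to intensity scaling and
RT shifts, so no peak-height normalization is needed for the correlation
itself.

**Within-peak SNR.** Both the intensity trace and the best-fitting beta
pdf are scaled to $[0,1]$ and subtracted; the standard deviation of these
residuals (sample sd, $n-1$) times the maximum peak height estimates the
noise *inside* the peak, and SNR = max height / noise, which reduces
algebraically to $1/\mathrm{sd}(\text{scaled residuals})$. Estimating
noise from the fit residuals avoids relying on data outside the peak
boundary, which may not exist or may contain other signals. A perfect fit
(zero residual sd) is capped at $10^6$ so the downstream $\log_{10}$
transform stays finite; the cap maps to exactly 6 on the log scale used by
the model.

Both metrics return missing for traces with fewer than 5 points or with
constant intensities or retention times — there is no shape information to
score. Missing is a value here, not an error; every summary statistic
drops missing inputs silently.

**Missed scans.** The fraction of scans the file actually acquired inside
the peak's RT window (at any mass) that have no centroid inside the peak's
m/z window. The denominator deliberately uses the file's own scan grid, so
irregular acquisition rates do not bias the metric.

**Isotope verification.** A genuine analyte has a ¹³C companion at
m/z + 1.003355, with a ± 4 ppm window applied to the shifted mass. Two
checks: the per-file Pearson correlation between the ¹²C and ¹³C traces
paired by exact shared scan time (median across files; a file needs ≥ 5
shared points to contribute), and the Pearson correlation between
trapezoidal ¹³C and ¹²C areas across files (a true isotope keeps a fixed
abundance ratio). At least 3 complete files are required for the area
correlation, because two points always correlate at ± 1 — the source
method states no minimum, so this package imposes the smallest meaningful
one. Both metrics pile up just below 1, so the model consumes
$\log_{10}(1 - x)$, with $x$ clamped at $1 - 10^{-12}$ (an exact 1 maps to
−12) and $x > 1$ rejected as an invalid correlation.

**Peak-list summaries.** Per feature: mean/sd of RT and peak width
(rtmax − rtmin, seconds); mean m/z and its spread in ppm (each peak's m/z
divided by the feature's median m/z × 10⁶); mean and sd of log10 peak
areas; mean log10 of the picker's own signal-to-noise after discarding
negative values and replacing zeros with ones; plain means of the opaque
picker diagnostics (`f`, `scale`, `lmin`); detection fractions (all files,
non-gap-filled "initially found", and the same restricted to sample runs
and standard runs); and the pooled-QC coefficient of variation, classic
(sd/mean of pooled-run areas) and robust (MAD/median, *without* the 1.4826
consistency constant — the robust CV is a plain ratio here, not a normal
sd estimate). The across-file medians of shape $r$, log10 SNR and missed
proportion complete the metric vector.

Two deliberately literal readings are worth flagging. `sd_log_area` is the
sd of the log10 areas (not the log of the sd): the source text is
ambiguous ("log10 then mean … repeated for the SD") and the sd-of-logs
reading keeps the quantity on the same scale as `mean_log_area`.
Single-peak features get missing sd fields, never 0 — a sample sd of one
observation is undefined.

## Units, defaults, and degenerate inputs

Retention time is seconds everywhere internally (the XCMS convention); the
CLI accepts minutes behind an explicit `--rt-units min` flag and converts
on ingest. Bounding boxes are closed intervals on both axes. The
feature-level RT filter defaults to [30 s, 1200 s], dropping features
eluting during solvent washes. Multiple centroids inside the m/z window at
one scan are summed into a single EIC point — an EIC has one intensity per
scan. Gap-filled peaks are excluded from the "initially found" fractions
but included in area summaries and raw-data metrics (their EICs exist in
the raw data; they are flagged, not discarded).

## Imputation and pruning

Missing metric cells carry information — no pooled peaks, no isotope
signal, no standards run — so before model fitting each missing cell is
filled one order of magnitude of the column's observed span *beyond the
column's worst value*, per a fixed quality-direction registry (fractions,
shape, SNR: low side; sds, CVs, missed proportion, the log-isotope
transforms: high side). Metrics with no quality direction (mean RT, mean
m/z, the opaque picker diagnostics) fill one span beyond whichever extreme
is farther from the median, i.e. away from the bulk. The rule is
deterministic and keeps imputed values visibly outside the observed range.
A column that is entirely missing cannot be imputed and is a hard error;
drop it from the model instead (e.g. `frac_stans_found` when no standards
were run).

Redundant metrics (|Pearson r| > 0.9 on the imputed table) are pruned by a
greedy scan in the fixed canonical column order, always removing the later
column — the source method does not say which of a redundant pair was
dropped, so determinism won the tie.

## The logistic models

Three specifications: `two_param` (median shape $r$ + median log10 SNR),
`xcms_only` (the summaries available without revisiting raw data), and
`full` (all surviving columns after pruning). Fitting is standard
maximum-likelihood logistic regression (`stats::glm`, binomial) of Good = 1
vs Bad = 0; Ambiguous, standards-only and unlabeled features are dropped
from fitting and excluded from confusion counts entirely. Predictors are
standardized by the training mean/sd, and those parameters are stored in
the fitted model and re-applied at prediction — the source describes
"scaling and normalization" without formulas, so z-scoring was chosen as
the simplest scheme that makes coefficients comparable across training
sets; it is recorded in the serialized model file for transparency.

Complete separation is *expected* on easy data (the fitted likelihoods are
strongly bimodal); the fit warns and returns the iteration-capped
coefficients rather than erroring. Likelihood rankings remain usable under
separation; coefficient magnitudes and Wald SEs do not.

Evaluation: a feature is predicted Good iff its likelihood ≥ threshold
(ties count as Good; the source does not specify). FDR = 100·FP/(FP+TP)
(missing when nothing is predicted positive), GFF = 100·TP/(TP+FN).
Model-stability diagnostics: `agreement_stats()` compares two models'
predictions in raw probability space (Pearson) and ranked space
(Spearman); `training_fraction_stability()` refits on subsamples at given
training fractions (10 replicates by default, per-replicate seeds derived
deterministically from one user seed; a subsample that loses a class is
skipped and logged) and reports the estimates against the full fit's 1- and
2-SE bands.

## What the synthetic generator emulates — and what it does not

`generate_feature_set()` builds a labeled multi-file bundle: per-file
centroided scans, an XCMS-style peak table, a manifest and labels. The
defaults are fixed once and state the modeled world:

- 200 features, 9 files (6 samples, 2 pooled QC, 1 standard mix) — enough
  files to exercise every run-type fraction;
- 30% Good features — fully-labeled real datasets of this kind run ~70%
  Bad;
- Good peaks: beta-shaped profiles ($\alpha$ drawn from the model's own
  {2.5, 3, 4, 5}, $\beta = 5$), 20–80 s wide on a 2 s scan grid (10–40
  points per peak, an Orbitrap-like HILIC rate), heights $10^{5.5}$–$10^{7.5}$
  with lognormal per-file variation (sdlog 0.4), additive Gaussian noise
  at 5% of peak height, a ¹³C companion at ratio 0.011, and a 90%
  per-file detection probability (missed files are sometimes gap-filled);
- Bad features: uncorrelated noise (point presence Bernoulli(0.6) per
  scan, to exercise the missed-scan metric) or, for 30% of them,
  re-integrations of the trailing 30% of a Good parent's profile *mass*
  (from the 0.7 beta quantile to the peak end). The mass-based tail was a
  deliberate choice over a time-based one: the time-based trailing window
  contains almost no signal of a beta-shaped peak, whereas the real
  artifact this emulates is a partial integration that retains the
  parent's biological signal — which is what makes it pseudo-replication;
- a persistent background ion (m/z ≈ 445.12) in every file so the scan
  grid is defined everywhere, giving the missed-scan metric its
  denominator.

Generation is fully deterministic given the config seed; the same config
produces byte-identical bundles and `write_bundle()`/`read_bundle()`
round-trip exactly (mzML arrays are uncompressed 64-bit floats).

A green end-to-end test on this bundle establishes that the pipeline's
plumbing, metric arithmetic, and model calibration behave as specified on
well-separated classes. It does *not* establish real-world performance:
the generator has no chemical background structure, no adducts or
in-source fragments, no retention drift or alignment error, no
correlated noise, and its Good/Bad separation is far cleaner than manual
labels on environmental samples.

## Numerical choices

- Beta pdf evaluated exactly at scaled positions, including the endpoints
  $u = 0, 1$ (finite for all $\alpha$ used); no grid interpolation and no
  endpoint trimming.
- Sample sd ($n-1$) throughout.
- SNR cap $10^6$; isotope-transform clamp $10^{-12}$ with the clamped
  result set to exactly −12 (computing $\log_{10}(1 - (1 - 10^{-12}))$ in
  floating point is off by $10^{-7}$).
- Metric tables serialize numerics with 17 significant digits, so finite
  values round-trip bit-exactly and missingness is preserved as `NA`.
- mzML I/O is implemented in-package (xml2 + base64): reads uncompressed
  or zlib 32/64-bit float arrays, converts minute-valued scan times to
  seconds, and hard-errors on profile-mode spectra, which would break the
  one-centroid-per-scan assumption of every metric.

## Known limitations

- Only M+1 isotope checking; no charge-state deconvolution, adducts, or
  higher isotopologues.
- No smoothing-based noise estimator; the residual-sd SNR punishes very
  spiky but real peaks.
- The across-file median of shape $r$ under-scores features present in
  only a few files.
- Regularized regression and random-forest comparisons are out of scope by
  design (documented extension point); the logistic model was preferred
  for interpretability and cross-dataset stability.
- The mzML reader indexes nothing and loads whole files; it is meant for
  the moderate file sizes of this workflow, not for raw-data browsers.
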