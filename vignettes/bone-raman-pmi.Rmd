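---
title: "Classifying post-mortem interval from bone Raman spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying post-mortem interval from bone Raman spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boneraman)
```

## The problem

After skeletonization, bone keeps changing: collagen degrades, the
hydroxyapatite mineral dissolves and recrystallizes, carbonate substitutes
into the apatite lattice, and fluorescent degradation products accumulate.
Raman spectroscopy reads these diagenetic changes non-destructively. The
mineral bands (phosphate ν~1~ at 958 cm^-1^, ν~2~ at 450 cm^-1^, carbonate
ν~1~ at 1070 cm^-1^) and the organic bands (amide III at 1246 cm^-1^, CH~2~
at 1450 cm^-1^, amide I at 1656 cm^-1^, C–H stretches at 2800–3000 cm^-1^)
shift in relative intensity and width with time since death, so band-derived
markers can discriminate post-mortem interval (PMI) classes — here five
classes spanning fresh (0–2 weeks) to archeological (>100 years).

`boneraman` implements that analysis as a tested pipeline: spectrum I/O,
pretreatment, baseline-corrected band metrics, a six-marker bone-quality
panel, per-marker class statistics, windowed PCA, and a fluorescence
quality gate — plus a synthetic bone-spectrum generator that emulates two
instruments (a handheld spectrometer and a Raman microscope) so that every
stage can be verified end to end without access to human specimens.

## Pretreatment

Every spectrum passes through `pretreat()`: point reduction → Savitzky–Golay
smoothing → area normalization, in that order, with the settings recorded in
a `pretreatment_record()` that travels with the spectrum and is checked
downstream (PCA refuses to mix provenance).

* **Point reduction** (`reduce_points`). "Reduction factor *f*" is read as
  block averaging: consecutive non-overlapping blocks of *f* points are
  replaced by their mean position and mean intensity. Block means
  anti-alias, unlike decimation; replicate averaging is a separate,
  explicit step (`mean_spectrum`). Both alternative readings of a reduction
  factor (decimation; replicate averaging) remain available through the API,
  but block averaging is the default because the factor is listed among
  per-spectrum pretreatments. Vendor raw grids carry thousands of channels,
  where a factor of 36 is sensible; the generator samples at the optical
  resolution (317 points for the handheld), so the pipeline default is
  `reduction_factor = 1` and the factor-36 path is exercised directly in the
  unit tests.
* **Savitzky–Golay** (`savitzky_golay`). Local least-squares polynomial
  smoothing, default window 5 points on generator grids (15 points on
  vendor-density grids), order 2. Order 2 is the common spectral default;
  the order is configurable. Edge samples are evaluated from the edge
  polynomial fits rather than truncated, so band shapes at the range ends
  survive. The filter is exact on polynomials up to the chosen order, and
  its white-noise variance transfer equals the squared coefficient norm —
  both are tested.
* **Area normalization** (`area_normalize`). Intensities are divided by the
  trapezoidal integral over the full axis. Bone is porous and heterogeneous;
  excitation volume and focus vary between spots, so only normalized
  intensities are comparable across samples. Normalization is idempotent
  and makes every ratio marker and all PCA scores invariant to global
  intensity scaling (tested end to end).

Wavenumber axes are canonicalized to ascending on read; all band arithmetic
uses absolute spacing, so the direction a vendor file was written in can
never change a result.

## Band metrics and the marker panel

Peak analytics follow the spreadsheet convention: inside a fixed integration
window, a straight line through the first and last (x, y) points of the
window is subtracted (`subtract_linear_baseline`), then

* **H** — maximum corrected intensity in the window;
* **I** — corrected intensity at the grid point nearest the band's nominal
  center. Tying I to the nominal wavenumber (rather than the local maximum)
  keeps intensity markers comparable across samples whose peak positions
  wander by a grid step;
* **A** — trapezoidal partial area, `peak_area_eq1`;
* **Asi** — plain intensity sum, `intensity_sum_eq2` (the two area
  conventions differ by the grid step and an edge term; tested);
* **FWHM** — width between the two half-maximum crossings, each located by
  linear interpolation on its flank. If a flank never crosses H/2 inside
  the window, the width is reported missing with a truncation warning —
  never extrapolated.

Conventions for degenerate inputs: an all-non-positive corrected segment
gets H = 0 and an undefined FWHM; negative corrected areas are reported
as-is (quality control, not the metric layer, decides usability); ratios
with non-positive denominators are missing, never zero.

The six-marker panel (`compute_marker_panel`):

| marker | determination | reads |
|---|---|---|
| phosphate | I~958~ | mineral amount |
| CI | 1/FWHM~958~ | mineral crystallinity |
| MMR | A~958~/A~1656~ | mineral-to-matrix ratio |
| carb_phos | A~1070~/A~958~ | carbonate substitution |
| min_carb | A~1070~/A~1450~ | mineral carbonate content |
| amide_I | I~1656~ | collagen amount/arrangement |

plus an optional C–H aliphatic content, defined here as the baseline-
corrected 2800–3000 cm^-1^ area over the total spectral area. That
definition is non-canonical (no standard formula exists); it is only
assessable on the microscope, whose range reaches the C–H stretches — on
the handheld it is reported missing. A named "overall mineral content"
marker sometimes listed alongside these six has no agreed determination and
is excluded from the default panel.

Integration windows default to the diagnostic regions used for the PCA
(958 → 920–990, 1246 → 1200–1320, 1450 → 1410–1490, 1656 → 1550–1730), with
1070 → 1040–1100 and 450 → 420–480 chosen symmetric about their centers;
all windows are configurable. Markers are computed on the replicate-mean
spectrum by default; per-replicate computation with subsequent averaging is
available (`by = "replicate"`), since either convention is defensible.

## Class statistics

`one_way_anova` is the classical fixed-effects F-test (delegating to
`stats::aov`), with explicit conventions at the degenerate edges: zero
between-group variance gives F = 0, p = 1; zero within-group variance with
distinct means gives p = 0 with a warning. `pairwise_class_contrasts`
compares a reference class (class 1) against every other class per marker.
The default method is the pairwise t-test on the ANOVA pooled standard
deviation (`stats::pairwise.t.test`, `pool.sd = TRUE`) with no multiplicity
adjustment — the least-significant-difference reading of per-pair p-values
from a single-factor ANOVA. Its per-contrast type-I error is the nominal
alpha, which is what the calibration study verifies. An F-protected variant
and Tukey's HSD are selectable, as is Benjamini–Hochberg adjustment across
markers; none is the default because the reference analysis reports
unadjusted per-pair values. The two-sample path (`two_sample_ttest`) is
Welch's test: the class sizes (32/46/11/10) are too unequal to lean on a
homogeneity assumption. Star coding uses strict upper bounds: `*` p < 0.05,
`**` p < 0.01, `***` p < 0.001, `****` p < 0.0001, `ns` otherwise.

Missing marker values are dropped per marker and contrast with the n's
reported, so a marker that is non-assessable on one instrument cannot
poison the others.

## Windowed PCA

`fit_pca` is column-mean-centered PCA by SVD. No unit-variance scaling:
channels share units and are already area-normalized (scaling would inflate
quiet channels). Explained variance per component is taken over the total
variance, not the retained subset. Determinism: each component is flipped
so its largest-magnitude loading is positive, making repeated fits
bit-identical across linear-algebra backends. Correlation loadings —
Pearson correlations of each channel with each score, bounded in [−1, 1] —
are the interpretable view of which wavenumbers drive a component.
`region_report` fits a PCA per diagnostic region:

| region | window (cm^-1^) | assignment |
|---|---|---|
| I | 400–450 | ν~2~PO~4~^3−^ |
| II | 920–990 | ν~1~PO~4~^3−^ |
| III | 1200–1320 | amide III |
| IV | 1410–1490 | CH~2~ |
| V | 1550–1730 | amide I |

These five regions are the canonical set; samples enter as replicate-mean
spectra. PCA correctness is pinned to a brute-force covariance
eigendecomposition on small matrices (1e-9), and class separation in score
space is summarized by the mean silhouette (`score_silhouette`).

## Fluorescence quality control

Archeological bone fluoresces strongly enough to swamp the Raman signal.
`fluorescence_fraction` estimates the broad-background share of a
spectrum's area with a morphological opening: a rolling minimum over a
~200 cm^-1^ window erases features narrower than the window, a rolling
maximum undoes the erosion bias on smooth backgrounds, and a rolling mean
smooths the residual staircase. The fraction is baseline area over total
area, clipped to [0, 1], and is scale-invariant. `qc_gate` excludes
replicates above a threshold (default 0.9, configurable) before any marker
or PCA computation. Two deliberate limitations: the threshold is a
surrogate for a qualitative usability judgment, not a calibrated quantity;
and the estimated baseline is never subtracted — fluorescence *removal* is
out of scope, matching an analysis in which no suppression was applied.

## The synthetic generator

`generate_dataset` emulates the study design so the pipeline is testable:

* **Design**: 104 samples in classes of 32/46/11/10/5; handheld
  (400–2300 cm^-1^, 6 cm^-1^ resolution, 5 replicates/sample) and
  microscope (200–3600 cm^-1^, 4 cm^-1^ resolution, 36 replicates/ROI)
  profiles. Grids sample at the optical resolution by default; a finer
  `step` is available for numerical studies of the forward model.
* **Bands**: pseudo-Voigt shapes (Lorentzian fraction η = 0.3, the common
  Raman compromise) at the canonical bone positions, convolved with a
  Gaussian instrument kernel of FWHM equal to the resolution. The 577
  cm^-1^ phosphate ν~4~ and the C–H stretch envelope render only on the
  microscope, mirroring its broader effective sensitivity.
* **Class effects**: per-class multiplicative amplitude factors and
  additive FWHM shifts per band. Defaults encode the qualitative
  diagenesis picture — amide I falls steeply with PMI (factors
  1.00/0.80/0.65/0.55 for classes 1–4), amide III and CH~2~ fall
  moderately, phosphate falls mildly while its band broadens (+1/+2/+3
  cm^-1^: crystallinity drops), carbonate substitution rises
  (1.08/1.14/1.22). The magnitudes are free parameters exposed in
  `class_effect_table()`; they are chosen to be plausible and are *not*
  claimed to match any measured bone series. Every marker band carries a
  monotone effect so that each marker has a defined trend direction — the
  cross-instrument consistency study needs that, and a flat band would make
  its trend sign a coin flip.
* **Fluorescence**: a smooth single-humped 4th-order polynomial envelope,
  peak height 8 (in band-amplitude units) at scale 1, with per-class scales
  0.2/0.4/0.7/1.0/20 — classes 1–4 have mild, rising background; class 5 is
  dominated (background fraction ≈ 0.99), which is what the QC gate is
  calibrated against.
* **Noise and variation**: between-sample lognormal amplitude variation
  (mean 1, CV 0.08 — a plausible bone-composition scatter) drawn once per
  sample and shared across instruments (one piece of bone, two devices);
  per-replicate additive Gaussian noise with sd = 0.3 + 0.15·√intensity
  (shot-noise-like with a floor).
* **Reproducibility**: one master seed drives a hierarchical stream
  (dataset → sample → replicate) through multiplicative Lehmer-style
  mixing, so identical seeds give bit-identical datasets and growing a
  class does not perturb existing samples.

What the generator does **not** emulate: spatial structure within an ROI,
cosmic-ray spikes, wavenumber calibration drift, detector etaloning,
physically calibrated Raman cross-sections, or the actual chemistry of
diagenesis. Passing tests therefore demonstrate that the pipeline recovers
what this forward model puts in — correctness of the analysis machinery —
not that the default effect sizes describe real bone.

## Verification studies and problem sizes

The test-suite and `scripts/acceptance.R` rerun these studies from scratch:

* **Oracle agreement**: trapezoidal band areas vs an independent fine-grid
  Riemann sum on 100 random pseudo-Voigt bands (≤0.5%) and exact agreement
  on piecewise-linear segments; FWHM closure on analytic Gaussian widths on
  1 cm^-1^ and 6 cm^-1^ grids; PCA explained variances vs brute-force
  eigenvalues; SG exactness on quadratics; unit integrals after
  normalization on 1000 random spectra.
* **Type-I calibration**: 2000 datasets from the no-effect generator
  (4 classes × 15 samples × 3 replicates), full pipeline, per-contrast
  rejection rate at α = 0.05 — measured ≈ 0.043–0.045.
* **Power and recovery**: 200 two-class datasets at the study sizes 32/46;
  the amide-I class-1-vs-2 contrast is significant in 100% of runs, and
  simulation-averaged marker class means sit within 1% of the generator
  ground truth (tolerance 5%).
* **Region behavior**: with class effects confined to the bands of regions
  I, IV and V, those regions carry >95% of their variance on PC-1/PC-2 and
  the null generator separates nothing (silhouette ≤ 0).
* **QC**: 100% of class-5 and 0% of class-1 handheld replicates excluded
  at threshold 0.9 under the default scales.
* **Cross-instrument consistency**: the trend direction of all six markers
  across classes 1–4 agrees between handheld and microscope renderings of
  the same simulated bones in 100 of 100 simulations.

Replicate counts in the repeated-simulation studies are reduced to 3 (and
the microscope to 6 in the analysis scripts): per-sample markers are
computed on replicate means, where extra replicates only shrink a noise
term that is already small against the between-sample scatter. The full
36-replicate design remains available in the generator.

## Known limitations

* The confined-effects silhouette is marginal by construction: area
  normalization compresses between-class amplitude gaps (the laddered bands
  carry ~1/3 of total area) and folds the unaffected bands' and
  background's sample-to-sample scatter into every channel, capping the
  mean 2-D silhouette near 0.1–0.3 at the default CV of 0.08. The default
  full study (effects in all bands plus the fluorescence ladder) separates
  classes much more clearly (silhouettes 0.45–0.73 per region).
* FWHM by linear flank interpolation is phase-sensitive on coarse grids:
  off-grid band centers on the 6 cm^-1^ handheld grid can push the width
  error beyond 5% for narrow bands. The diagnostic 958 band sits on-grid
  for the handheld profile, where the error stays below 1% at realistic
  widths.
* Endpoint baselines under Lorentzian tails bias widths low unless windows
  are generous (≥4 widths); the windowed-arithmetic method deliberately
  does no peak fitting, so overlapping bands share windows rather than
  being deconvolved.
* The QC gate flags, but does not rescue, fluorescence-dominated spectra;
  no supervised classifier is built on the PCA scores — separation is
  reported descriptively, and no classification accuracy is claimed.
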