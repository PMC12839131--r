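---
title: "Methods: from brightfield spheroid images to a PCA-weighted dose-response metric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from brightfield spheroid images to a PCA-weighted dose-response metric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheromet)
```

`spheromet` turns label-free brightfield images of single tumour
spheroids into a one-number-per-well response metric and an IC50. This
vignette explains the model behind each stage, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where more than one
reasonable option existed.

## 1. Segmentation and shape descriptors

One spheroid per well is the assay design, so segmentation is
deliberately simple: the grey levels are rescaled to [0, 1] (with a
polarity flag, since spheroids may image bright-on-dark or
dark-on-bright), globally thresholded by Otsu's method, the largest
8-connected component is kept (equal-size ties broken deterministically
towards the topmost-leftmost component, with a warning), and interior
holes are filled. No expand/shrink, split/merge or object-filling
post-processing is applied: at low magnification with one large object
per frame these steps add segmentation artifacts rather than remove
them.

The six shape descriptors follow CellProfiler conventions so that tables
from the native extractor and from CellProfiler CSV exports are
interchangeable:

* **area** — foreground pixel count (px²);
* **perimeter** — length of the closed boundary polygon through
  boundary-pixel centres, after a 3-point circular moving average. The
  smoothing is a numerical choice worth stating: the raw 8-connected
  chain overestimates the length of smooth digitised boundaries by
  roughly 5% (a digitised disc of radius 50 measures ~329 px instead of
  2π·50 ≈ 314), which would bias the form factor of a circle to ~0.91.
  The 3-point window removes the single-pixel staircase (disc form
  factor 1.006) while barely rounding true corners (a 200-px square
  loses ~1.5% of its perimeter, form factor 0.797 vs π/4 ≈ 0.785);
* **form factor** — 4π·area/perimeter², 1 for a circle;
* **solidity** — area over convex-hull area, with the hull taken over
  pixel *corners* so the ratio can never exceed 1;
* **compactness** — mean squared pixel distance from the centroid,
  normalised by area/2π so a filled circle scores 1;
* **median radius** — median of the Euclidean distance transform over
  the object, a thickness measure.

All six are checked in the test suite against brute-force
reimplementations (independent boundary tracing, gift-wrapping hull,
exhaustive distance transform) on randomly generated blob masks, and
against analytic values on discs and squares.

### Granularity

Internal texture is summarised by a granulometry: the in-mask image is
opened with disc structuring elements of radius 1, 2, …, `n_scales`
(default 16, matching common CellProfiler settings), and the spectrum
value at scale *k* is the percentage of the initial in-mask signal
removed by step *k*. Scales contributing less than 5% of the spectrum
maximum are discarded as background or minor brightness fluctuation
(`filter_granularity()`, threshold configurable; the arg-max scale is
always kept, and an all-zero spectrum keeps nothing, with a warning).
The 5% rule is implemented relative to the spectrum maximum; a
relative-to-total variant can be obtained by pre-scaling, but the
maximum-relative reading is the default because it is invariant to how
much of the signal the first opening removes.

## 2. Quality control

Two different assays get two different, never-mixed procedures.

**Morphometric triplicates** use Dixon's Q test,
Q = |suspect − nearest| / |highest − lowest|, with the n = 3, 95%
critical value 0.970 (the standard r10 table; the suspect is the value
most distant from the other two). A flagged suspect is replaced by the
mean of the remaining pair — at most one replacement per triplicate —
subject to a monotonicity guard: the replacement must not increase the
number of dose-ordered triplicate means that violate monotonicity
within a 5% relative tolerance band (direction set by the first and
last doses). The guard is evaluated with all concurrent candidate
replacements of the same series applied, so one outlier cannot mask
another. The procedure is idempotent: replaced triplicates have Q = 0.5
and are never re-flagged.

Two power facts shape expectations here. First, at the 0.970 cutoff the
test's false-positive rate on clean triplicates is its nominal size,
about 5%, *independently of the replicate CV* (Q is scale-free), so
roughly one clean triplicate in twenty will be lightly modified; the
replacement in that case shifts the triplicate mean by only a fraction
of the replicate spread. Second, detection power for a ×3–×5 outlier
falls with replicate CV: at 2% CV essentially every injected outlier
exceeds 0.970 (>99% detected in the test suite), while at 5% CV the
clean-pair spread eats into the Q numerator and a ×3 outlier is caught
only ~60–80% of the time. The decisiveness checks therefore run at 2%
replicate CV; users screening noisier features should expect Q's power
to degrade accordingly.

**Fluorescence triplicates** use the coefficient of variation (sample
SD over mean, ×100; the SD convention is n − 1). In order: a triplicate
with CV > 20% is rescued by removing the single value whose removal
minimises the remaining CV, if that lands within the limit; otherwise
the point is excluded; the curve is invalidated if an excluded or
rescued point lies in the IC50/inflection region (operationalised as
the two concentrations bracketing the half-maximal mean response — the
source procedure names the region without defining a window); at most
one exclusion is allowed, and only in the plateau; and the plate is
invalid if the negative control cannot be rescued by a single removal.

## 3. The composite metric

Per cell line:

1. **Normalisation** — every feature is divided by the mean of the
   zero-dose control wells, so controls average exactly 1. The fraction
   scale (rather than percent) is used throughout because the inversion
   rule below compares means to 1; multiplying by 100 is display
   formatting only.
2. **Conditional inversion** — per feature, over treatment wells only
   (controls are excluded from the decision because their mean is 1 by
   construction and would dilute the trend test): if mean(x) > 1 and
   mean(1/x) < mean(x), the column is replaced by its reciprocal. This
   aligns directionality — form factor rising with dose becomes a
   falling signal like area — and nothing more; relative contributions
   are decided later by the PCA.
3. **Re-check** — inverted columns whose current treatment-well mean
   exceeds the recorded pre-inversion mean are reverted (inversion is an
   involution). With the column-level decision rule above, an inversion
   applied and immediately re-checked on unchanged data cannot trigger
   the revert (the second inversion condition guarantees the mean
   fell); the re-check is a safety net for the realistic pipeline in
   which edits — QC replacements, row filtering — happen between the
   inversion decision and the final matrix, or when inversion decisions
   are imported from a different grouping level.
4. **PCA weighting** — the treatment-well feature matrix is centred and
   standardised to unit variance (raw features span orders of
   magnitude — areas in the tens of thousands of px², form factors near
   1 — so unscaled PCA would be an area detector; `scale = FALSE` is
   available). With explained-variance ratios aᵢ and loadings cᵢⱼ, the
   smallest k with Σᵢ≤k aᵢ ≥ 0.90 is selected (threshold configurable
   in (0, 1]) and feature j receives raw weight Σᵢ≤k aᵢ·|cᵢⱼ|,
   normalised so Σω = 1. Absolute values make the weights invariant to
   eigenvector sign, which is arbitrary. Rows are wells (replicates
   kept) rather than concentration means, preserving replicate variance
   in the decomposition; weights are computed per cell line, never
   pooled across lines.
5. **Metric** — σ = Σⱼ ω(j)·xⱼ per well: exactly 1 for clean controls
   (all features 1, weights sum to 1), falling with impairment.

Degenerate cases are defined, not accidental: a single feature gets
weight 1; exactly duplicated features split their weight evenly (the
correlation matrix's leading eigenvector is (1,1)/√2); a zero-variance
matrix is an error.

## 4. Dose–response and censoring

`fit_4pl()` fits `bottom + (top − bottom)/(1 + (c/IC50)^h)` to the mean
response per positive concentration (zero dose is the normalisation
anchor, not a fitted point; SD-weighted fitting is available but off by
default since the inputs are already per-concentration summaries). The
midpoint is parameterised as log10(IC50) and constrained to within two
decades of the tested range; initialisation takes top/bottom from the
extreme-dose means, the midpoint from the dose nearest half-maximal
response and h = 1, plus a fixed grid of shifted restarts (±1 and ±0.5
decades, halved/doubled and sign-flipped slope) — deterministic, so
fits are exactly reproducible. A fit ending on a bound is flagged
unconverged. At least four distinct positive concentrations are
required.

`classify_ic50()` makes censoring explicit rather than numeric: a
series whose observed span is below 30% of its mean level is *flat* and
reported as `greater_than` the top tested dose (`flat_rel_span`
configurable; for control-normalised readouts whose genuine responses
span ≥ 50% of control this margin is wide on both sides); a converged
fit with the midpoint inside the tested range and at least half of the
fitted span actually observed is `definite`; midpoints beyond the range
or sub-half-maximal responses are `greater_than`; QC-invalidated or
unfittable series are `not_determinable`. Ratios between censored
values follow bound arithmetic (bound/definite gives a one-sided
ratio; two bounds give n/a), rounded to two decimals.

## 5. The synthetic-data generator

`dose_scenario()` encodes the study conditions the pipeline assumes:
a ten-point half-log concentration ladder from 0 to 10 µM (1 nM–10 µM
plus a zero-dose control), three technical replicates, six features
with mixed directions (area-, perimeter- and radius-like features fall
to 20% of control; form-factor-, compactness- and solidity-like
features rise to 180%), a shared true IC50 and Hill slope 1.2, 10%
lognormal multiplicative replicate noise (mean-1 factors, so features
stay positive — the domain the 1/x inversion needs), and optional gross
outliers: with a configurable probability per triplicate, one replicate
is multiplied by a factor uniform in [3, 5], a magnitude chosen so the
Q statistic exceeds 0.970 in the noiseless limit. Every generated
dataset carries a truth record (feature parameters, injected-outlier
positions) so recovery can be scored, and identical seeds give
identical output. The replicate noise level is a modelling choice — the
source assay reports only that fluorescence CVs stayed below 20% — set
at 10% as a realistic mid-range for imaging-derived features.

`make_spheroid_image()` renders one disc-like object per frame with a
radial boundary function r(θ) = R(1 + ρ·p(θ)) (p a normalised random
3-harmonic perturbation, ρ the roughness), optional interior speckle
whose granulometry peaks at the requested grain radius, additive
Gaussian noise and configurable polarity; the analytic area of the
rendered region is returned for oracle tests.

What the generator does *not* emulate — and what passing tests
therefore do not show about real data: optical blur and illumination
gradients, debris and multi-spheroid wells, necrotic-core texture
physiology, plate-edge effects, and any correlation structure between
features beyond what the shared dose response induces. The validation
against real numbers rests instead on the shipped reference IC50 panel
(`ic50_reference()`: four colorectal/pancreatic lines × six
cytostatics under proliferation, area and metric readouts), on which
the package reproduces the readout concordances (metric vs
proliferation r ≈ 0.90, ρ ≈ 0.89; area vs proliferation r ≈ 0.84,
ρ ≈ 0.95, definite pairs only, linear scale — the log10 scale is also
computed and reported for audit) and the relation ratios.

## 6. Problem sizes and reproducibility

The test suite and the acceptance script size their simulations to be
decisive yet quick: 20 seeds for end-to-end IC50 recovery (median
|log₂(est/true)| ≤ 0.3 at 10% noise) and for the threshold-robustness
scan (pairwise Pearson r across cumulative-variance thresholds
0.80/0.90/0.95 ≥ 0.95 — in practice ≈ 1, because with six
near-equally-loaded features the selected component count changes the
weights only marginally), 200 seeds for QC decisiveness, 50 random
matrices for the PCA oracle and 20 random blobs for the morphometry
oracle. All randomness is seed-derived; `scripts/acceptance.R --seed N`
reproduces every number bit-for-bit for a given N.

## 7. Known limitations

* Single-object segmentation by global threshold: frames with several
  comparable objects, strong vignetting or out-of-focus spheroids need
  upstream curation (the largest-component rule handles small debris
  only).
* Dixon's Q at n = 3 has the power profile described above; it cannot
  be both sensitive to mild outliers and quiet on clean data.
* The composite metric of mixed-direction sigmoids is itself only
  approximately a four-parameter logistic; its fitted midpoint sits
  systematically slightly below the per-feature true IC50 (≈ −15% at
  the default configuration), within the ±20% recovery band but worth
  remembering when comparing absolute potencies across readouts.
* Weights are per cell line by design; comparing σ values *across* cell
  lines compares differently-weighted sums.
* 96-well geometry only in the layout writer; the filename parser and
  everything downstream are plate-agnostic.
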