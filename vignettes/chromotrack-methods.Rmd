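---
title: "Methods: statistics for two-colour 3D chromatin locus tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics for two-colour 3D chromatin locus tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromotrack)
```

## The measurement problem

Two chromosomal loci on the same chromosome are made visible in live cells by
inserting bacterial operator arrays (lacO, tetO) bound by GFP- and
mCherry-fused repressors, so each locus appears as a diffraction-limited spot
in its own colour channel. Tracking both spots in 3D over time gives, per
video, a series of paired coordinates from which we estimate: how far apart
the loci sit (and hence how compact the intervening chromatin is), whether
their relative orientation is maintained, how coupled their motions are, how
the inter-locus distance decorrelates over time, and whether a cell's
chromatin configuration is passed to its daughter.

Because the two channels are imaged through different optics, raw red and
green coordinates are misaligned, and localisation noise inflates every
distance. The package therefore implements the full post-tracking workflow:
channel alignment, error estimation, quality control, and the downstream
statistics — plus a synthetic trajectory generator so that every stage can be
tested quantitatively without microscopy data.

## Data model and units

All coordinates are in nm with z along the optical axis, and all times in
seconds. A `cell_video` holds one cell's paired observations (time, green and
red 3D position, spot intensity, contrast) plus strain, lineage (mother /
daughter / unpaired with a `pair_id`) and acquisition metadata. Tables are
plain delimited text, one row per frame with both channels side by side; a
second reader accepts the long one-row-per-spot dialect typical of tracking
exports, pairing channels by nearest time within half a frame interval.
Missing frames are allowed and all statistics use the recorded time stamps,
never frame indices.

The effective genomic separation of a two-array reporter is
`z = a + 0.5 x_p + 0.5 x_q` (bp): the fluorescent signal centres on each
array's midpoint, so half of each flanking array adds to the intragenic
spacer `a`. The compaction ratio is `0.34 * alpha / d` — the contour length of
`alpha` bp of B-DNA (0.34 nm/bp) over the measured 3D distance `d` in nm; a
value of 1 means the chromatin path is as extended as naked B-DNA.

## Channel alignment and measurement error

Coarse alignment (translation + rotation + magnification from calibration
targets) is accepted as externally supplied `affine_transform` parameters and
applied to coordinates; estimating it from bead images is out of scope. Fine
alignment uses a colocalising control strain whose single locus binds both
fluorophores, so the true inter-channel separation is zero: the per-axis mean
of (red − green) over all control frames is the residual offset, and
subtracting it from the red channel is a final translation. After alignment,
the mean 3D red–green distance over the control frames is the measurement
error. With per-axis localisation noise of SD `s` in each channel the
inter-channel difference per axis has SD `s * sqrt(2)`, so the error distance
is Maxwell-distributed with mean `4 s / sqrt(pi)`; at `s = 27.9` nm this is
63 nm, the regime the default simulator reproduces.

Quality control removes whole frames (both channels) when either spot's z
lies within 1 µm of a stack boundary, either channel's contrast falls below
12, or the maximum spot intensity falls below 25 (red) / 16 (green). These
thresholds are taken as given calibration outputs. Removals are attributed in
the fixed precedence order z-margin → contrast → intensity so that per-rule
counts are unambiguous; the counts always sum to the input frame count.

## Orientation anisotropy

Each frame's inter-locus vector (red − green, a pinned convention) is mapped
onto the unit square: `u = (atan2(y, x) + pi) / (2 pi)` wrapped to `[0, 1)`
and `v = (|r| − z) / (2 |r|)`. This map is area-preserving: isotropic
directions give (u, v) uniform on the square. Note the full-angle two-argument
arctangent is essential — a single-argument `tan⁻¹(y/x)/2π` has range
(−¼, ¼) and cannot fill the square, destroying the uniformity property the
statistic relies on. A vector with `x = y = 0` maps to `u = 0.5`; zero-length
vectors are skipped and counted.

Anisotropy is the one-sample two-dimensional Kolmogorov–Smirnov statistic
`D` of the UV points against uniform: the maximum over data points and the
four quadrant orientations anchored at each point of |empirical fraction −
quadrant area|, with the "lower" comparisons closed and their complements
open. `D ∈ [0, 1]`; isotropy gives `D = O(n^{-1/2})` while a maintained
orientation gives large `D`. The conventions are pinned so that the statistic
equals a brute-force enumeration exactly (the test suite checks 1000 random
instances). No p-value is attached: `D` itself is the anisotropy measure.

One caveat: a rotation of all vectors about the optical axis shifts every `u`
by a constant modulo 1. Because the quadrant anchors move with the data but
the quadrants stay axis-aligned, `D` is invariant only up to boundary effects
of order `1/sqrt(n)` (measured ≈ 0.005 at n = 300). Exact rotational
invariance would need a circular construction in `u`, which would change the
statistic's value on the pinned worked examples; we keep the standard
quadrant form.

## RV coefficient

Coupling between the two loci's motions is the RV coefficient, the
multivariate generalisation of a squared Pearson correlation: with
column-centred T×3 matrices X, Y and cross-products `S_ab`,
`RV = tr(S_xy S_yx) / sqrt(tr(S_xx²) tr(S_yy²)) ∈ [0, 1]`. By default X and Y
are the per-frame displacement vectors of the green and red locus — the
motion-coupling reading; a positions mode is available since both readings
appear in practice, and the choice is an explicit argument, never silent.
Independent trajectories give RV near 0, decreasing with series length;
identical or rigidly rotated motion gives exactly 1.

## MSCD, bootstrap baseline and plateau

The mean square change in distance generalises the MSD to the scalar
inter-locus distance: every ordered within-video pair of time points (t,
t+τ) contributes `(d(t+τ) − d(t))²`. Pairs are pooled across a strain's
videos and binned by τ into 6-s bins (`[k·6, (k+1)·6)`, labelled by centre),
with per-bin mean, count and standard error. Overlapping pairs are not
independent, so the SE is an optimistic scale bar, not a confidence interval.

For the stationary mean-reverting simulation the closed form is known: the
distance of an isotropic zero-mean Gaussian vector with per-axis SD σ is
Maxwell with variance `σ²(3 − 8/π)`, and for large lags
`MSCD(∞) = 2 Var(d) = 2σ²(3 − 8/π)`, approached on the relaxation timescale
θ (half-plateau near `θ ln 2`). The plateau estimator is the count-weighted
mean of bins with centre ≥ 150 s, where the curve has levelled off.

The between-cell baseline asks whether within-cell variability explains
between-cell variability: bootstrap draws pick a video, one of its time
points, a *different* video and one of its time points, and average the
squared distance difference. For a homogeneous (ergodic) population this
matches the within-cell plateau; an exclusion list supports re-estimating it
without outlier cells. Per-locus MSD uses the identical pooling/binning on
`|p(t+τ) − p(t)|²` and recovers the confined-motion closed form
`6σ_c²(1 − e^{−τ/θ_c})` per independent OU component.

## Inheritance test

Mother/daughter pairs are identified from lineage metadata. Per video,
compaction is the mean of per-frame compaction ratios (a median option
exists); each related pair contributes `log2(compaction_mother /
compaction_daughter)`, and an equal number of random unrelated
mother×daughter pairs (with replacement, lineage pairs excluded;
mother/mother and daughter/daughter modes available) contributes the
comparison set. For same-strain pairs the genomic separation cancels, so the
ratio reflects distances only. The two sets are compared with a two-sided
Mann–Whitney test — exact by full enumeration when `n_a + n_b ≤ 12` with no
ties, else the tie-corrected normal approximation with continuity correction.
The primary comparison is on |log2 ratio| (inheritance shrinks the
*magnitude* of the compaction change between related cells); the signed
comparison is reported alongside because the signed distributions are what a
symmetric plot shows, and the two can differ.

## The synthetic generator: what it emulates

The generator is first-class, tested code; its defaults define the study
conditions used throughout the tests:

- Inter-locus vector: per-axis stationary Ornstein–Uhlenbeck with stationary
  SD `sigma = 150` nm and relaxation time `theta = 30` s, discretised with
  the *exact* conditional update (not Euler), so the stationary SD and the
  lag autocorrelation `exp(−τ/θ)` hold at any frame interval. θ = 30 s puts
  the MSCD rise in the tens of seconds and the plateau well before 150 s,
  matching the rise-then-plateau regime of interest.
- Midpoint: an independent confined OU process (SD 200 nm, θ 60 s) centred
  mid-stack; independence lets anisotropy and motion-coupling properties be
  controlled separately from the separation process.
- Channels: green = midpoint − vector/2 + noise, red = midpoint + vector/2 +
  noise + constant `channel_offset`; per-axis, per-channel Gaussian noise of
  27.9 nm by default, which makes the colocalising control's mean error 63 nm.
- Acquisition: 6-s frame interval, 100 frames per video, 0–5000 nm stack
  (videos of up to 100 time points in a 5-µm stack). True z is always
  recorded and boundary frames are *flagged by QC rather than deleted*, so
  the filter itself is testable.
- Covariates: intensity and contrast are Gaussian draws per channel whose
  defaults sit a few SDs above the QC thresholds, giving realistic occasional
  rejections.
- Anisotropy mode: "fixed-direction" holds the separation direction constant
  and lets only the magnitude fluctuate (a reflected OU whose stationary mean
  and SD match the Maxwell magnitude statistics of the isotropic mode, so the
  two modes are comparable at equal `sigma`).
- Population structure: each cell draws its mean separation from a log-normal
  between-cell distribution (meanlog log(250 nm), sdlog 0.35 — a roughly
  ±40% spread consistent with strong cell-to-cell heterogeneity; the true
  distribution is unknown and this is an explicit config choice, not a claim
  of fidelity). A daughter's mean is `c·mother + (1−c)·fresh draw` with the
  inheritance coefficient `c ∈ [0, 1]`.
- Determinism: all randomness flows from one integer seed; per-video
  sub-seeds are derived arithmetically, so a population is reproducible and
  videos are independent.

What the generator does **not** emulate: polymer physics beyond the two-locus
effective process (no Rouse modes, no anomalous-diffusion exponents),
photobleaching or intensity decay over a video, tracking failures and
misidentified spots, nuclear envelope confinement geometry, or z-dependent
localisation error (QC's z-margin rule is motivated by the latter, but the
simulator's noise is homogeneous). Passing tests therefore demonstrate that
the estimators recover the statistics of data with this correlation
structure; they do not certify behaviour on pathologies real tracking data
may contain.

## Numerical and design choices

- Histogram bins for distances are half-open `[lo, hi)` starting at 0,
  default width 63 nm (the measurement error), so boundary values fall in the
  upper bin deterministically.
- Per-strain compaction is displayed as `0.34·z / mean(d)` (one value per
  strain); the mean of per-frame ratios is emitted alongside since either
  averaging order is defensible.
- The 2D KS statistic is evaluated at data points only, with closed lower
  quadrants; the implementation chunks the n² comparisons to bound memory and
  is tested for exact equality against a brute-force double loop.
- Bootstrap draws are uniform over videos, then uniform over that video's
  time points (not uniform over pooled frames), so long videos do not
  dominate; the alternative weighting would differ for unequal video lengths.
- MSCD/MSD standard errors treat pairs as independent; see the caveat above.
- Exact Mann–Whitney enumeration is capped at `n_a + n_b ≤ 12` (924
  subsets); beyond that the normal approximation's error is far below the
  test's discreteness at those sizes.
- Problem sizes in the test suite (e.g. 30 videos × 150 frames for MSCD
  physics, 100 replicate populations of 100–200 pairs for the inheritance
  calibration, 10⁵ frames for error convergence) were chosen so each Monte
  Carlo check has at least ~3-SE resolution against its closed form.

## Known limitations

- Coarse alignment parameters must come from outside; only the fine
  translation is estimated here.
- `D` has no attached significance level, and its value depends on n; compare
  like-sized sets (the fixed-direction vs isotropic comparison in the tests
  is at matched n).
- The inheritance test's power statement is specific to the generator's
  effect-size conventions (inheritance coefficient, between-cell spread,
  video length); it does not translate directly to real populations.
- The SE fields of MSCD/MSD curves understate uncertainty for strongly
  overlapping pairs, as documented above.
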