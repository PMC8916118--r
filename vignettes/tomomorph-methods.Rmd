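---
title: "Quantifying axonal ultrastructure annotations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying axonal ultrastructure annotations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomomorph)
```

# Scope

`tomomorph` quantifies annotations derived from cryo-electron tomograms of
developing axons: manually traced actin filaments, picked ribosome
coordinates, and manually measured organelle dimensions, plus a minimal
subtomogram-averaging engine for orienting particles and estimating the
resolution of their average. Everything upstream of the annotations --
tilt-series acquisition, alignment, reconstruction, denoising, and the
manual segmentation itself -- is out of scope; the package consumes
coordinates and measurements, not raw images.

A synthetic-data module generates annotation sets with the same statistical
structure as the real ones, so that every analysis can be validated by
parameter recovery without tomographic data.

# Units and coordinate conventions

All spatial annotation quantities are in nanometres; volume and resolution
quantities are in Angstrom. The single conversion (10 Angstrom per nm)
happens in one place: the point-file reader, which turns pixel coordinates
into nm via `voxel_size / 10`. Whether picks were made on binned or
unbinned tomograms is the caller's knowledge, so `voxel_size` is an
explicit argument (the study's pixel sizes were 5.46 Angstrom unbinned and
21.8 Angstrom at 4x binning). Volume coordinates are 0-based voxel-centre
positions: physical position = index times voxel size, which keeps distance
computations offset-free.

# Filament morphometry

Traced filaments are resampled into 10 nm segments by linear interpolation
along the polyline, the convention under which the reported actin length
and orientation statistics were produced. Two decisions the procedure
itself does not dictate:

* **Trailing remainder.** A final partial segment shorter than half the
  spacing is dropped; one of at least half the spacing is kept. This keeps
  the expected length bias small (about 1.25 nm per filament, i.e. under
  1% at the observed median lengths) without inflating segment counts.
  Traces shorter than one spacing yield no segments but still count in the
  length summaries.
* **Angle folding.** Traced filaments carry no polarity, so the angle of a
  segment to the reference axis is `acos(|d . r|)`, folded to [0, 90]
  degrees. Rose-type plots over 0-180 degrees can be recovered by
  unfolding if a polarity convention is ever adopted.

The reference axis (the neuron's longitudinal direction) is
operator-defined in practice; it is therefore a caller-supplied vector,
with `estimate_reference_axis()` offered as a helper that takes the
principal axis of landmark points such as microtubule picks.

Quantiles everywhere use linear interpolation between order statistics
(R's type-7 rule), fixed so that interquartile ranges are deterministic
and testable.

# Ribosome spatial statistics

Nearest-neighbour distances are computed in 3D -- the only convention
consistent with volumetric picking -- with no correction for particles
near the boundary of the analysed volume; the original analysis applies
none either, and the resulting mild upward bias of isolated fractions is a
known property of the estimator.

The distance histogram below 40 nm is fitted with a single Gaussian
`a * exp(-(x - mu)^2 / (2 sigma^2))` by Levenberg-Marquardt least squares
on bin-centre counts. The 40 nm window follows the published histogram of
the sub-population around the polysome spacing; the bin width of 2 nm
gives roughly five or more expected counts per bin at the typical
per-tomogram pick counts. Whether a published "mean +/- SD" of such data
refers to the fit parameters or to the windowed sample moments is often
ambiguous, so `fit_gaussian()` reports both.

Polysome/monosome fractions use the inclusive window [25, 35] nm (the
inter-ribosome spacing of a polysome) and an isolation threshold of 50 nm.
Chains for visualization are connected components of the graph linking
particles closer than 35 nm -- the window's upper edge, since no linking
rule is dictated by the analysis itself -- ordered by greedy
nearest-neighbour traversal from a chain end.

# Organelle statistics

Measurements arrive as scalars (mitochondrion length = longest
longitudinal axis; ER tube and ER wrap diameters are distinct structure
labels). Group comparisons use the Mann-Whitney rank-sum test implemented
two ways and labelled accordingly: exact, by full enumeration of rank
assignments, when the pooled sample size is at most 16 and there are no
ties (12,870 splits at n = 8 + 8 -- cheap, and enumeration is cached per
size pair); otherwise a normal approximation with tie-corrected variance
and continuity correction. The reference implementation in
`stats::wilcox.test` is used as an independent cross-check in the test
suite, never as the implementation. Which variant the original analysis
used is not stated; both are available and the output records the method.

Enrichment is deliberately simple -- structures per surveyed tomogram
category -- because the survey counts arrive as precomputed tallies, not
images.

# Synthetic data: what it emulates and what it does not

Every generator is a pure function of its config and seed, and emits
ground truth alongside the data; recovery tests consume only the data.

**Filaments.** Lengths are lognormal parameterized by the median
(`meanlog = log(median)`), strictly positive and right-skewed like the
observed interquartile scatter. The observed medians -- 182.4 nm (mature
branch, n = 325), 140.3 nm (premature branch, n = 414), 203.1 nm (shaft,
n = 148) -- are the per-region defaults. The log-scale spread is not
published beyond graphical IQR ranges, so `sigma_log = 0.4` is a free
parameter of the generator, chosen once as a realistic right-skew for
cytoskeletal length data and reported with every dataset. Orientations are
von Mises about a mean angle to the reference axis; curvature is a mean
absolute turn per 10 nm of arc (default 10 degrees). Traces are grown at
2 nm vertex spacing so the 10 nm resampling is well inside its asymptotic
regime.

**Particles.** The generator composes three populations:

* *Chains* (polysomes): rigid helices with 50 degrees of turn per subunit
  and 10 nm radius, emulating the spiral-like arrays seen in situ without
  asserting real polysome geometry. One inter-subunit spacing per chain is
  drawn from a truncated normal with the observed mean 29.5 nm and SD
  3.4 nm; because the helix is rigid, every chained particle's nearest
  neighbour distance equals its chain's spacing, so the nearest-neighbour
  histogram of the chained population is exactly the spacing law and the
  Gaussian fit is an unbiased recovery target. Chain lengths are geometric
  with support >= 2 and mean 5.
* *Isolated* particles (monosomes), kept at least 55 nm from everything,
  hence always beyond the 50 nm isolation threshold.
* *Scattered pairs* separated by 41-49 nm: nearest neighbours in
  (40, 50) nm, outside both the polysome window and the fit window.

The composition is solved analytically rather than tuned: with
`P(spacing in [25, 35]) = 0.854`, a chained fraction of 0.82 yields an
expected in-window fraction of `0.82 * 0.854 = 0.70`, and the isolated
fraction is set directly to 0.13 -- the two published fractions. The
remaining 5% are the scattered pairs. `particle_composition()` exposes
this arithmetic so tests compare realized fractions against the
generator's own targets. Objects are placed by rejection sampling with a
55 nm inter-object clearance in a 3000 x 3000 x 400 nm slab (a
tomogram-scale volume at realistic ribosome densities).

What the particle generator does **not** emulate: localization error of
picking, exclusion volumes of other organelles, membrane-associated
ordering, and boundary truncation of chains. Passing recovery tests
therefore show that the estimators are correct for a point pattern with
the stated spacing statistics -- not that real tomograms satisfy those
statistics.

**Particle volumes.** A particle volume is the template rotated by a
uniform random orientation (random unit quaternion), shifted by up to
box/8 voxels, masked in Fourier space by a binary missing wedge (tilting
about the y axis; the default half-angle of 30 degrees missing from the
pole corresponds to data within +/- 60 degrees), plus white noise scaled
so that `var(signal) / var(noise)` equals the configured SNR. The default
template is an asymmetric arrangement of three compact Gaussian lobes --
two unequal lobes plus an off-axis protrusion. Compactness matters: overly
smooth templates make the correlation landscape angularly flat and cap the
accuracy of any alignment scheme, while the lack of any rotational or
pseudo-2-fold symmetry keeps orientations uniquely recoverable. No CTF is
simulated (the source data were collected with a phase plate at zero
defocus) and no tilt-series projection model is attempted.

**Measurements.** Lognormal per (structure, region) group, parameterized
by the published medians (445 nm branch / 589 nm shaft mitochondria in
tomograms; 360/470/710 nm branch/shaft/dendrite by light microscopy; 7.19
and 12.21 nm ER diameters) at the published sample sizes, with free
`sigma_log` defaults of 0.4 (0.25 for ER) reported alongside.

# Subtomogram averaging

The engine is deliberately minimal but structurally faithful to
standard practice:

* **Alignment** is an exhaustive search over a quasi-uniform ZXZ Euler
  grid (azimuthal sampling scaled by `sin(theta)`), with the translation
  for each rotation taken as the argmax of the FFT cross-correlation
  constrained to a shift radius, refined to subvoxel precision by
  parabolic interpolation of the correlation peak. Scores are normalized
  cross-correlations computed under the binary missing-wedge mask with
  both volumes zero-meaned, hence in [-1, 1]. The handful of top-scoring
  grid orientations (default 6) are each refined through the remaining
  angular steps; keeping several candidates guards against the coarse
  grid landing outside the narrow correlation basin of a compact
  structure. Rotation uses trilinear real-space interpolation (compiled),
  which is the accuracy limiter at these box sizes.
* **Averaging** splits particles by index parity into odd and even
  half-sets, accumulates each half in Fourier space after rotating
  particles back to the reference frame, and normalizes per voxel by the
  summed rotated wedge masks (floor-clamped at 1) -- the simplest
  consistent missing-wedge compensation.
* **Adaptive bandpass.** After each iteration the half-averages are
  low-pass filtered (raised-cosine edge, two Fourier voxels wide) at the
  current FSC-0.143 resolution before forming the next reference, which
  prevents noise overfitting. The exact bandpass rule of the original
  software is unpublished; the 0.143-crossing low-pass is this package's
  documented stand-in. Fully independent ("gold-standard") half-set
  refinement is intentionally not the default, since the emulated
  procedure filtered from the joint half-set comparison.
* **FSC and resolution.** Per-shell correlation
  `Re(sum(Fa conj(Fb))) / sqrt(sum|Fa|^2 sum|Fb|^2)` over 1-voxel shells.
  The threshold crossing (0.143 or 0.5) is linearly interpolated between
  shells; the reciprocal frequency is the resolution. The zero-frequency
  shell is excluded from crossing detection (its value is only the sign of
  the product of the means). If the curve starts below threshold the
  resolution is "not reached" (`NA`); if it never drops below threshold
  the estimate is Nyquist-limited and `2 * voxel_size` is returned with an
  attribute saying so.

The ZXZ intrinsic Euler convention is stated wherever orientations are
serialized. The initial reference is low-pass filtered to 100 Angstrom by
default, matching the usual practice of starting from a shape-only
reference.

Reproducing the published ribosome average (38.4 Angstrom at FSC 0.143,
49.3 Angstrom at FSC 0.5) is out of scope: it requires the deposited
tilt-series data, real picking, and cluster-scale computation. The engine
is instead validated by parameter recovery on synthetic volumes: grid-exact
rotations are recovered perfectly without noise; at SNR 1 under a
+/- 60 degree wedge at box 32, angular errors are a few degrees (median
about 4-5 degrees with a 30/15/7.5-degree schedule, at least 90% of
particles within twice the final step), and half-set resolution improves
monotonically with particle count.

# Problem sizes and numerical choices

The validation suite uses the study-scale sample sizes where they matter
statistically (1,614 particles per replicate over 50 replicates; 325
filaments over 100 replicates; n = 34 measurements over 200 replicates)
and compact volumes (box 32 at 21.8 Angstrom per voxel, 50-128 particles)
for the subtomogram engine, which keeps a full run on a single CPU within
minutes while leaving every estimator in the regime its asymptotics
assume. Nonlinear fits use Levenberg-Marquardt with moment-based starts
and positivity bounds; fits on histograms with at most two occupied bins
are refused rather than returned degenerate. Duplicate pick coordinates
yield zero nearest-neighbour distances with a warning rather than an
error, since duplicated picks do occur in manual annotation.

# Known limitations

* No edge correction in nearest-neighbour statistics (matching the
  emulated analysis, but a bias near volume boundaries).
* The Gaussian histogram fit uses unweighted least squares; Poisson
  weighting would change fitted parameters slightly at low counts.
* Binned histogram fitting inflates the fitted sigma by about
  `bin_width^2 / 12` in variance (about 0.05 nm at the defaults) --
  visible only below the reporting precision.
* Trilinear interpolation limits angular accuracy of alignment; Fourier
  interpolation schemes would be the next step for smaller targets.
* The missing wedge is a binary mask; soft-edged or dose-weighted wedges
  are not modelled.
* Exact rank-sum enumeration stops at pooled n = 16; beyond that the
  tie-corrected normal approximation is reported, never silently mixed.
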