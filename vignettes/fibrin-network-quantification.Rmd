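---
title: "Quantifying fibrin network microstructure from fluorescence images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibrin network microstructure from fluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrinet)
```

## The measurement problem

A plasma clot is a three-dimensional mesh of fibrin fibers a few hundred
nanometres thick. In multiphoton or confocal fluorescence images the fibers
appear as bright ridges on a dark background; their brightness grows with the
number of laterally aggregated protofibrils, so intensity is an (approximate)
proxy for fiber mass and diameter. The package turns one calibrated 2D image
(typically 1024×1024 px over a 59×59 µm² field, 57.6 nm/px, 8-bit) or a small
z-stack into a standard set of clot parameters: fiber count and density,
local-maximum intensity, FWHM diameter, the thin/thick diameter ratio (TTR),
trifunctional branch junctions, crossing-fiber contacts, clot void area and
volume, and the densities of two abnormal structures — fibrin clusters and
fibrin agglomerates.

## Test-line stereology

Fibers are counted where they cross a set of equally spaced horizontal test
lines (`make_test_lines()`; rows `floor(h·k/(n+1))`, five by default — rows
170/341/512/682/853 on a 1024-row image). Because fiber orientation in a
network is random, line sampling is an unbiased stereological sample, and
**fiber density** is simply crossings per 100 µm of test line. A fiber
crossing several lines is counted once per line: the unit is "fibers per 100
µm of test line", not a per-object census, so no de-duplication across lines
is attempted.

Peaks in each line's intensity profile are found from the first-derivative
sign change of a 3-px moving-average smoothed profile
(`detect_fibers_on_line()`). Two thresholds control the operation:

* `min_peak_au` (default 27 au) — the same cut used for binarization;
* `min_separation_px` (default 5 px ≈ 290 nm, below the thinnest fibers) —
  closer peaks merge to the higher one.

A third, `min_prominence_au`, defaults to an estimate from the profile's own
first differences (capped at `min_peak_au`): an oblique fiber crosses a
horizontal line as a wide plateau, and without a prominence requirement,
noise ripple on such a plateau splits into spurious fibers. Clean constructed
profiles are unaffected because their peak prominences equal their full
heights.

Automated detection is auditable (`edit_fibers()`): confirmations, rejections
and manual additions produce the TP/FP/FN counts and the positive predictive
value `PPV = 100·TP/(TP+FP)`. Editing is a machine-readable batch operation;
no GUI is provided.

## Preprocessing and binarization

All images pass through the same chain (`preprocess()`): background
subtraction, then rescaling so the maximum equals 255 au. The background
estimator defaults to the modal intensity — fibrin images are mostly dark
void, so the mode tracks the detector offset; a block-wise rolling-percentile
surface is available for uneven illumination. Normalizing to a fixed 0–255 au
range is what makes a single global threshold meaningful across images; the
fiber/void threshold is 27 au, applied inclusively (a pixel exactly at 27 au
is fiber — the comparison sense is a package convention). Preprocessing never
changes image dimensions and is idempotent on already-normalized,
background-free images. One consequence to be aware of: an image with no real
signal would have its noise stretched to full range, so `analyze_clot()`
short-circuits to an empty read-out when the raw maximum is below the
threshold.

## Fiber metrics

Each detected fiber is characterised at its local intensity maximum within a
±5 px window of the test-line crossing (`local_max_intensity()`; ties break
toward the crossing). The fiber axis there is estimated from the
intensity-weighted structure tensor in a 15×15 px window, and the **diameter**
is the full width at half maximum of the intensity profile sampled
perpendicular to the axis (bilinear interpolation, 0.5 px steps, sub-pixel
interpolation at the two half-maximum crossings). FWHM was chosen as the
width measure because it is invariant to intensity rescaling and robust to
the exact background level. Three safeguards keep bad measurements out of the
statistics, all reported as flags rather than numbers:

* *unresolved* — the profile never falls to half maximum inside the window,
  or its minimum sits above half the peak (window too small to see
  background);
* *merged* — a second distinct peak above half maximum inside the measured
  width, with prominence above the profile's own noise level; or a flat-top
  shape (80%-width / 50%-width ratio > 0.70, against 0.567 for a Gaussian),
  which betrays two fused parallel fibers;
* the half-maximum search runs on a lightly smoothed profile because the raw
  maximum of a noisy profile is biased upward, which would bias FWHM
  downward.

**Diameter distribution.** Diameters are tested for normality (Shapiro–Wilk,
α = 0.05). If normality holds a single Gaussian is fitted; otherwise a
two-component Gaussian mixture is fitted by EM (k-means initialisation plus
10 random quantile-based restarts, log-likelihood tolerance 1e-8, seeded RNG)
and the interior local minimum of the fitted density between the component
means is located by 0.1 nm grid search. That minimum is the **thin/thick
threshold**; the package default is 761.9 nm, the control-clot-derived value,
used across conditions so that TTR changes are comparable (it can be
re-derived per dataset via `fit_distribution()`). `TTR = n_thin/n_thick`,
with thin strictly below the threshold; an all-thin sample reports `Inf` with
a note. The read-out summarises diameters by the mean for normal fits and the
median for bimodal fits.

The internal consistency check `diameter_intensity_relation()` regresses
diameter on local-maximum intensity; the generator encodes an exactly linear
relation, so a healthy pipeline shows a positive slope at p < 0.001.

## Network topology

Two kinds of fiber–fiber meetings are distinguished:

* **Trifunctional branch junctions** obey width conservation: the widest of
  the three meeting segments approximately equals the sum of the other two
  (F1 = F2 + F3). `classify_branch()` calls a branch when
  `|F1 − (F2+F3)|/F1 ≤ 0.15`; the 15% tolerance operationalizes
  "approximately equal" and is configurable. Meetings of more than three
  segments are treated as crossings, not branches.
* **Crossing-fiber contacts**: fluorophore content is additive where fibers
  actually touch, so a contact shows a proportional intensity increase
  greater than 40% on *both* fibers relative to their own along-fiber
  baselines (median intensity excluding a 7-px window around the meeting).
  The comparison is strict (> 0.40): exactly 40% is a pass-over, where one
  fiber passes above or below the other. The rule is scale-invariant by
  construction.

`candidate_meetings()` traces each measured fiber along its axis
(steepest-ridge following, 1 px steps, re-centred on the perpendicular
maximum, orientation refreshed every 5 steps, at most 200 steps per
direction) and emits positions where intensity exceeds the fiber's own
baseline by > 40%, paired with any second trace within 3 px. Junction
identification in the original workflow was operator-driven (contour and
surface plots); the package supplies the classifiers and the candidate
search, and `topology_stats()` reduces counts to per-field, per-mm² and
per-fiber rates plus the fiber/branch and fiber/crossing count ratios.

## Void and abnormal structures

On a binarized image white is fiber, black is void; `void_area()` is the
black percentage, and `void_area + fiber_area = 100` exactly. For a stack,
`void_volume()` is the unweighted mean of slice void percentages — an
equal-slab model, appropriate for equally spaced optical sections — and
`projected_void()` is the void fraction of the pixelwise OR of the fiber
masks (classically three slices at 40/50/60 µm), which can never exceed any
single slice's void.

**Fibrin clusters** are irregular high-intensity cores with ≥ 8 thin fibers
radiating from the periphery. `detect_clusters()` operationalizes this:
core pixels are those above the 99th intensity percentile and an absolute
floor of 180 au (cores approach saturation; single-fiber ridges stay well
below); candidate cores must exceed 0.5 µm², have solidity < 0.9 (irregular)
and moment aspect ratio < 3 (compact). Protruding fibers are angular
intensity peaks on a ring just outside the core that persist at the same
angle on rings 5 and 10 px further out — a protrusion is radial, so its
angular position is stable across radii, whereas a network fiber passing the
core crosses successive rings at different angles — and whose perpendicular
FWHM is below the thin threshold. All of these thresholds are exposed as
arguments.

**Fibrin agglomerates** are isolated particles (0.5–8 µm) found when network
formation is fully inhibited. `detect_agglomerates()` first requires that no
spanning network is present: any binarized connected component with a major
axis of at least 20 µm (capped at half the field edge for small crops) marks
a network, in which case the detector refuses and directs the caller to
network analysis. A simple per-test-line rule was rejected here because
isolated blobs lying on a test line also produce peaks; component elongation
separates the two regimes cleanly. Agglomerates are connected components
with equivalent diameter ≥ 0.3 µm, measured by moment-based major-axis
length; aspect ratio < 1.3 classes a particle as spherical, and solidity
< 0.85 flags blunted protruding fibers. `agglomerate_summary()` reports the
mean long axis, a 0.5 µm-binned histogram and the fraction exceeding a
capillary diameter (default 5 µm) — the clinically interesting tail.

## The synthetic scene generator

`render_scene()` produces images with complete ground truth so that every
operator is testable without real data. What it emulates:

* straight fibers with Gaussian cross-section whose FWHM *is* the nominal
  diameter, peak intensity strictly proportional to diameter
  (0.15 au/nm: a 700 nm fiber peaks at 105 au);
* additive intensity where fibers overlap (crossings of equal fibers show a
  ~100% local increase, comfortably above the 40% rule);
* branch junctions rendered as three co-terminal arms with exactly conserved
  widths;
* irregular star-polygon cluster cores with 9–13 thin radiating fibers;
* isolated elliptical agglomerates with log-normal long axes clipped to
  0.5–8 µm;
* additive Gaussian detector noise (default SD 5 au — frame-averaged
  multiphoton acquisitions are comparably clean; SNR ≈ 21 for a 700 nm
  fiber), clipped to 0–255 and quantized to integers (8-bit).

Deliberate simplifications, made for unambiguous ground truth and documented
here because they bound what passing tests show about real data: fibers are
straight full-field chords with orientations 45–135° from horizontal; fiber
crossings on any standard test line are kept ≥ 22 px apart by rejection
sampling (so every crossing is optically resolvable); branch junctions,
crossings and cluster cores keep ≥ 150 px mutual distance, sit clear of the
test-line rows (structures are measured at their own positions, so line
sampling sees only network chords), and cluster cores stay 45 px clear of
network fibers. Real clots have curved fibers, fibers
meeting test lines at glancing angles, unresolvably close crossings and
clusters embedded in dense network — in those regimes the per-line counts and
protrusion counts will degrade toward the interactive-editing workflow the
method was designed around. The truth tables record segment endpoints,
diameters, peak intensities, exact branch triples, crossing positions,
cluster protrusion counts, agglomerate axes, and the pre-noise footprint
fraction at the 27 au threshold (the oracle for void arithmetic).

`render_dose_series()` produces the virtual dose-response used in the
end-to-end tests. The default trend (`default_dose_trend()`) follows the
structural phenotype sequence of nitrosothiol-modulated clots: fiber count
falls monotonically to zero (30 → 0 across eight doses), mean diameter rises
to an interior maximum (677 → 822 nm at the fourth dose) before falling,
clusters appear at an intermediate dose, and the final dose contains only
agglomerates. Counts and diameters below the cluster-onset dose are paired
so the total fiber footprint (∝ n·diameter) is approximately conserved —
thicker but sparser fibers occupy the same space, which is what keeps void
volume flat at low doses. Because line crossings are stochastic in placement,
each dose renders a few candidate scenes from derived sub-seeds and keeps
the one whose ground-truth crossing count is highest while sitting at least
6 below the previous dose's — enough margin that detection noise cannot
invert the measured order, while staying near the expected count so the
margin cannot drift the series downward. The whole procedure is
deterministic for a fixed seed.

## Numerical choices and degenerate inputs

* Coordinates are row-major and 0-based; physical position = index ×
  pixel size. All sub-pixel sampling is bilinear.
* The EM mixture fit restores the caller's RNG state; scenes render under a
  local seed the same way.
* `percent_change()` is computed from unrounded values and rounded only at
  report time (nearest integer in the read-out).
* Degenerate inputs fail loudly: uniform images cannot be normalized;
  all-equal diameter samples cannot be fitted; zero-length test lines,
  empty dose lists and single-slice stacks are parameter errors. A
  zero-baseline crossing profile is a degenerate-profile error.
* The density–diameter regression flags rows whose deleted (externally
  studentized) residual exceeds 2; the deleted form is computed explicitly
  so a perfectly collinear table yields residual 0 everywhere while a gross
  outlier against a perfect line is flagged with an unbounded residual.
* The read-out caption field "TTR vs control" is implemented as the plain
  ratio TTR ÷ control TTR — an interpretation, exposed as such.

## Problem sizes in the test-suite

The bundled suites run at desk scale: twenty 1024² detection scenes with
15–35 fibers; seven noise-free diameter scenes spanning 400–1000 nm; twenty
n = 300 mixture fits; ten topology scenes giving 30 branch and 30 crossing
events; three-slice stacks for the void oracles; and one eight-dose virtual
series with three-slice stacks per network dose. These sizes keep the whole
suite to a few minutes while leaving every acceptance property with a clear
margin.

## Limitations

Beyond the generator simplifications above: the analysis is 2D within
slices (no 3D topology across a stack); no deconvolution, PSF modelling or
photobleaching correction is applied (none is assumed by the method);
diameters are optical FWHM values, not EM-calibrated widths; dose-response
statistics (ANOVA, multiple comparisons) are intentionally left to standard
tools — the dose table exports cleanly. The branch-point area unit in
published work is ambiguous, so both per-field and per-mm² rates are
reported and neither is treated as canonical.
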