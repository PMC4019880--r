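---
title: "Benchmarking 3D cell detection against stereologic counting: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking 3D cell detection against stereologic counting: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Stereologic cell counting estimates total cell numbers in a brain region
from systematically sampled thick tissue sections, using geometric rules
(the unbiased counting frame and the top-of-cell rule inside an unbiased
virtual counting space, UVCS) that count each cell exactly once regardless
of its size, shape or orientation. The rules are applied by a human
observer, which is what makes the method slow. Automated 3D cell detection
is the obvious replacement, and this package implements the machinery
needed to judge whether a detector is good enough: synthetic 3D image
stacks with exactly known ground truth, a baseline detector, a
centroid-matching evaluation that produces true-positive and
false-positive rates, method combination, and the stereologic rules
themselves as the reference standard.

The evaluation model is deliberately centroid-based: two methods found the
same cell if their centroids nearly coincide. Volumetric overlap scores
(IoU, Dice) are out of scope; segmentation-extent errors appear only in
the per-marker assignment files.

## Coordinate conventions

One convention is used everywhere. A stack is stored as an array with
`dim = c(ny, nx, nz)`; voxel indices are 0-based in the physical mapping,
`x = column * spacing_x` micrometres (no half-voxel offset), `y` and `z`
analogously. Centroids are voxel-coordinate means mirrored in
micrometres, so the matching stage and the stereology stage share one
frame. Marker files carry micrometre coordinates only; a marker set can
additionally declare the voxel spacing of the frame it came from, and the
matcher refuses to compare sets whose declared spacings differ.

## The synthetic generator

`generate_stack()` is first-class, tested code, not a fixture: it defines
the study conditions every downstream claim is tested under.

**Placement.** Cell centers are drawn by hard-core rejection sampling
(minimum center-to-center separation in micrometres), optionally around
Thomas-process parents whose offspring dispersion is the `clustering`
parameter. Rejection sampling fails explicitly after a bounded number of
attempts, so an infeasible density is an error rather than a hang.

**Shape and scale.** Cells are axis-aligned ellipsoids with per-cell
radii drawn uniformly from stated ranges. Nuclear labels default to
2–2.5 µm radii (a 4–5 µm XY nucleus diameter); cytoplasmic labels to
3–4 µm (whole somata). Arbitrary orientation and non-ellipsoidal shapes
are non-goals here — the shape/orientation argument for stereology is
made abstractly in the profile-bias simulation instead.

**Rendering.** The intensity image is the ellipsoid indicator scaled by a
per-cell intensity (default 0.6–0.9, normalized), convolved with an
anisotropic Gaussian (defaults: lateral σ 0.25 µm, axial σ 0.75 µm)
standing in for the out-of-focus axial blur of widefield imaging of thick
sections, on a background of 0.08 with additive Gaussian noise of σ 0.02
and optional Poisson shot noise. Stacks quantize to 8 bits by default
(16 optional), rounding half up. Brightfield profiles render as RGB: a
bright neutral background (0.90) blended toward a DAB-brown cell color
(0.55, 0.35, 0.20) in proportion to the blurred cell signal, so cells are
darker than background in the red channel while their red chromaticity
exceeds the neutral 1/3.

**Ground truth.** Each placed cell yields one marker at its analytic
center, flagged `boundary = 1` exactly when its voxelized support leaves
the stack or occupies a face voxel; an option snaps the marker z to the
nearest image plane, emulating manual marking of the median plane of
appearance. The matching tolerance is expected to absorb the difference
between the two z conventions, and the default keeps the analytic center.

**Determinism.** One master seed is split per stage (placement,
rendering, noise) through a fixed scheme, so identical inputs are
bit-identical and stages can be re-run independently. All internal draws
save and restore the caller's RNG state.

**What the generator does not emulate.** Stain spectra, tissue shrinkage,
vignetting, intra-cell texture, and non-convex or oriented cell shapes.
Passing tests on synthetic stacks therefore demonstrate that the
*evaluation machinery* is correct and that the baseline detector behaves
as theory predicts on clean blob-like data; they do not certify detector
performance on real tissue, where the published benchmark found much
worse rates.

## Preprocessing

Detectors expect a single bright-on-dark channel. Fluorescence stacks
pass through unchanged (or via `extract_channel()` for multi-channel
data). Brightfield RGB offers two routes: red-channel inversion
(`invert_red_channel()`, `(2^d − 1) − R`) and the Lrg red-chromaticity
conversion (`red_chromaticity()`, `r = R/(R+G+B)` per voxel). The
degenerate black voxel (R+G+B = 0) is defined to have r = 0, since a
black voxel in brightfield can only be background. Chromaticity is kept
real-valued in [0, 1] internally and quantized (round half up) at the
stack's bit depth when exported for detection. The pipeline applies color
conversion first and smoothing second; the order is recorded in the run
manifest. Smoothing sigmas are specified in voxels, independent of
optical resolution, because the filter targets camera noise rather than
the PSF.

`gaussian_smooth_3d()` uses separable sampled-Gaussian kernels normalized
to unit mass, truncated at 4σ, with symmetric (edge-including) reflection
at the boundaries — a standard mass-preserving choice.

## The baseline detector

The detector is intentionally the simplest appearance model in use:
global threshold, 3D connected components, size filter. Conventions that
the contract leaves open are fixed and tested:

- foreground is `intensity >= threshold` (inclusive, ImageJ-style);
- default connectivity 26 (6 and 18 selectable); labels are assigned in
  raster-scan order of each component's first voxel, so labeling is
  deterministic;
- the size filter removes regions *strictly* smaller than `min_voxels`
  ("much smaller than a typical cell" implies keeping the boundary
  case); there is no maximum-size filter.

The per-profile size filters are 1000 voxels at the 0.102/0.075 µm
lateral spacings and 25 voxels at the 0.46 µm spacing. This assignment
follows the voxel-volume arithmetic (1000 × 0.102134 × 0.101507 × 0.5 ≈
5.2 µm³; 25 × 0.46056² × 1.0 ≈ 5.3 µm³; 1000 voxels at the brightfield
spacing ≈ 2.8 µm³), which uniquely determines which filter belongs to
which geometry even though prose descriptions of such filters can attach
dataset labels ambiguously.

The known failure mode is retained by design: touching cells fall into
one foreground component and are counted once. The dense-regime tests
verify exactly this degradation.

## Matching and rates

`match_markers()` is a single greedy pass over ground-truth markers in
input order. For each marker, detections within a *cylinder* (lateral
radius `r_xy`, axial half-height `r_z`) that are not yet consumed are
candidates; the nearest is taken and removed from further consideration.
Unmatched ground truth are false-negatives; leftover detections are
false-positives. Rates are `R_tp = N_tp/N_gt` and `R_fp = N_fp/N_s`,
kept as exact ratios until rendering.

Choices made where the contract is silent:

- **"Nearest" metric.** Inside the cylinder, the normalized elliptic
  distance `sqrt((Δxy/r_xy)² + (Δz/r_z)²)` — it respects the same
  anisotropy that motivates the cylinder (XY centroids are more precise
  than Z). Plain Euclidean distance is available as an option.
- **Order.** Greedy results can depend on ground-truth order; the default
  is file order, and `order = "sorted"` gives a canonical lexicographic
  run. Ties among equidistant detections break to the lowest detection
  id.
- **Tolerances.** Lateral 3 µm (the lower end of observed nucleus radii);
  axial 1.5 µm, or 2.0 µm for the low-numerical-aperture confocal
  profile.
- **Stratification.** Boundary-flagged cells are matched like all others;
  `R_tpi` (interior) and `R_tpb` (boundary) are computed post hoc.

Greedy matching never exceeds the optimal assignment, and equals it
whenever ground-truth markers are separated widely enough that no
detection is eligible for two of them; both facts are tested against a
maximum-cardinality bipartite matching oracle.

**Combination.** The union of two results marks a ground-truth cell
true-positive if either result did, and pools the false-positives. Pooled
false-positives lying mutually within the tolerance cylinder are merged
into one (greedy nearest pairing) by default: a no-dedup pooled count is
inconsistent with at least one published combined rate, so merging is the
conservative reading, and the no-dedup variant remains available. The
intersection requires both methods; a combined false-positive is a
mutually-close pair of individual false-positives. Neither combination
has a natural detection count, so `N_s = N_tp + N_fp` by definition,
preserving the count identities. No claim is made that either variant
reproduces the published combined-rate table, whose exact denominator is
not recoverable.

## Stereologic rules

The counting frame uses the classic convention: exclusion lines are the
left and bottom edges plus a vertical ray upward from the top-left corner
and downward from the bottom-right corner; top and right edges are
inclusion lines. Footprints are circles (cells as spheroids), which keeps
the rules exactly testable; the sides are conventional and configurable.
A cell passes the 3D rules iff its footprint obeys the frame rule *and*
its top (first plane of focus) lies inside the counting depth interval,
which sits inside the section with guard zones above and below. Cells cut
at sectioning carry their top in the section above and are never counted
in this section.

`estimate_total()` is the standard fractionator product — the raw count
divided by section, area and height sampling fractions. The unbiasedness
simulation samples sections systematically with a random start and places
the frame grid with a random offset (toroidal wrap, so every location has
equal inclusion probability); over replicates the mean estimate matches
the true count within Monte Carlo error. The profile-bias simulation
shows why the rules matter: thin-section 2D profile counts scale as
`N(d + t)/H` with cell diameter `d`, while UVCS counts do not move with
diameter.

## Numerical choices

- Reported rates round *half away from zero* (0.98709 → 0.99, 0.0362 →
  0.04), the convention consistent with every printed cell checked; a
  1e-9 guard absorbs the binary representation of decimal halves and is
  provably safe for count ratios with denominators below 1e5.
- Quantization rounds half up; inversion and chromaticity are exact per
  voxel.
- Gaussian kernels truncate at 4σ; boundary handling is symmetric
  reflection; σ = 0 along an axis is an exact identity.
- Degenerate inputs are defined, not accidental: empty marker sets give
  zero rates with a warning, black voxels give r = 0, empty strata give
  rate 0 with a warning, infeasible placements fail loudly.

## Problem sizes

The test-suite and acceptance scales were chosen to exercise every code
path in minutes on one core: easy-regime recovery uses the widefield
geometry at 256 × 256 × 30 voxels with 20 well-separated cells over 10
seeds (the full-size grids of the presets remain available); oracle
cross-checks use 50 seeded masks up to 30 × 30 × 15 at all three
connectivities; matching oracles use 50 configurations up to 100 markers;
combination uses 20 two-detector replicates; stereology uses 200
replicates of a 2000-point population. The analysis scripts under
`analysis/` run the same machinery with per-condition cell densities
scaled from the published ground-truth counts.

## Known limitations

- The baseline detector is the only detector implemented; the published
  comparison's other methods (graph-cut/LoG pipelines, multiple level
  sets) exist here only as rows of the reference count table.
- Greedy matching is order-dependent by construction; the canonical
  sorted order is provided but is not the default, because file order is
  what the original procedure used.
- The generator's ellipsoid-plus-blur model contains no texture, so
  threshold selection on synthetic data is far easier than on tissue;
  synthetic rates are upper bounds, not predictions.
- Three rows of the shipped reference table are flagged as internally
  inconsistent (printed cell vs printed counts) and are excluded from the
  exact-reproduction checks; the flags and the arithmetic are in the
  table itself.
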