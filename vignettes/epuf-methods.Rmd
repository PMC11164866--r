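---
title: "Authenticating electrosprayed edible PUF patterns: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authenticating electrosprayed edible PUF patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An edible physical unclonable function (ePUF) is a stochastic pattern of
dye micro-stains electrospray-deposited directly onto a drug tablet.
Because droplet deposition is uncontrollable at the single-droplet level,
no two patterns are alike and a pattern cannot be reproduced on demand —
the physical prerequisites of an unforgeable per-dose identifier. The
manufacturer images every tablet at enrolment and stores the images in a
reference database; at the point of care, a patient photographs the tablet
with a cellphone and the photograph is matched against the database. The
package implements that matching pipeline, together with a seeded
simulator of the deposition and capture processes so that the whole system
can be exercised and tested without physical hardware or a proprietary
image set.

## The matching algorithm

The core statistic chain is:

1. **Pattern extraction.** The photograph is converted to HSV. Otsu
   thresholding of the value channel segments the (bright) tablet from the
   (dark) background; the largest connected component is taken as the
   pill, the image is cropped to it and the background blanked. Otsu
   thresholding of the saturation channel then segments the dyed spots; a
   minimum-area rotated rectangle is fitted to the spot pixels, and the
   image is rotated and cropped to that rectangle and converted to
   grayscale (ITU-R BT.601 luma).
2. **Feature extraction.** SIFT keypoints and 128-component integer
   descriptors are computed from the grayscale pattern.
3. **Feature matching.** For a query feature with descriptor $D_1$ and a
   database feature with descriptor $D_2$, similarity is the L2 norm
   $d = \lVert D_1 - D_2 \rVert_2$. For each query feature the two
   nearest database descriptors at distances $d_1 \le d_2$ are found
   (exact search) and the match is kept only if it passes Lowe's ratio
   test $d_1 / d_2 \le k$. With symmetry checking enabled, matching is
   repeated in the reverse direction and a match $(f_a, f_b)$ survives
   only if the reverse matching pairs $(f_b, f_a)$.
4. **Decision.** Matching yields one surviving count $N_i$ per database
   entry. With $N_1$ the largest and $N_2$ the second largest count, the
   query is *confidently* matched to the best entry iff both
   $N_1 \ge \lambda \cdot \mathrm{len}(F)$ (the matching threshold,
   $\mathrm{len}(F)$ = the query's feature count) and
   $(N_1 - N_2)/N_1 \ge p$ (the prominence threshold) hold; otherwise the
   verdict is *unconfident* and no entry is named. When ground truth is
   available, confident verdicts are further labelled correct/incorrect;
   unconfident verdicts are never tested for correctness.

The default operating point is $k = 0.7$, $p = 0.5$, $\lambda = 0.02$,
symmetry on. The ratio test suppresses ambiguous per-feature matches, the
matching threshold discards verdicts supported by a negligible fraction of
the query's features, and prominence demands that the best entry stand
clearly above the runner-up — the property that protects against false
accepts of unregistered patterns.

Decision-rule conventions the literature leaves open, fixed here:

* A tie among database features ($d_1 = d_2$, including the duplicate
  descriptor case $d_2 = 0$) is defined as ratio 1, so it survives only at
  $k = 1$; a duplicated best match is maximally ambiguous.
* Ties between database features for nearest neighbour keep the lowest
  index (deterministic, order-stable).
* A tie in the top per-entry counts ($N_1 = N_2$) has prominence 0 and is
  unconfident for any $p > 0$ — the safe reading for anti-counterfeiting.
* $\lambda \cdot \mathrm{len}(F)$ is compared as an exact real-valued
  product, no rounding.
* Extraction failures (unreadable file, no pill, blank tablet) produce a
  third machine outcome, `unprocessable`, so I/O problems are never
  reported as authentication results.

## The SIFT implementation

No R package provides SIFT, so the package carries a native
implementation (C++): Gaussian scale-space pyramid, difference-of-Gaussian
extrema with quadratic sub-pixel refinement, low-contrast and edge
rejection, 36-bin orientation assignment, and the standard $4 \times 4
\times 8$ descriptor grid with trilinear interpolation, normalised,
clipped at 0.2 and quantised to 8-bit integers. Defaults follow the
conventional parameterisation (3 layers per octave, contrast threshold
0.04 on the unit intensity scale, edge threshold 10, base sigma 1.6,
initial 2x upsampling), surfaced in `sift_params()` and recorded in every
feature cache and database manifest.

Two deliberate deviations from the most common parameterisation:

* Descriptor sampling offsets are taken relative to the *sub-pixel*
  refined keypoint position rather than the nearest integer pixel. For
  the small, high-curvature blobs that dominate spot patterns, the
  half-pixel rounding error measurably destabilises descriptors.
* The Gaussian window of the orientation histogram uses $2.5\sigma$
  rather than the customary $1.5\sigma$. An isolated dye spot is nearly
  radially symmetric, so its own gradients give an essentially arbitrary,
  noise-driven orientation; a wider support anchors the orientation on the
  surrounding spot constellation, which is stable and discriminative.
  Both settings were compared on seeded corpora by measuring retention of
  true matches under rotation, tilt and exposure perturbations (mean
  retention 0.31 vs 0.27 over the stress set); the wider window wins and
  is the package default.

Nearest-neighbour search is exact, in one compiled pass that returns the
two smallest distances per feature in both directions (the reverse
direction serves symmetry checking). Descriptors are integer vectors with
squared distances below $2^{24}$, so single-precision accumulation is
exact.

## The deposition simulator

`sample_spots()` models deposition as a Poisson process along the zig-zag
raster path (8 passes, 1 mm pitch, 8 x 8 mm stencil window, 16 mm tablet):

* The expected number of spots per mm of path is
  `deposition_efficiency * flow_rate / translation_speed`. The
  proportionality constant (default 4) is calibrated so that default
  settings (10 uL/min, 12 mm/s) give roughly 270 expected spots and the
  corpus parameter ranges span roughly 60–900 — visually comparable to
  published example patterns from sparse to dense.
* Spot radii are lognormal with median
  `radius_coef * flow_rate^radius_exponent` (defaults 0.032 mm, exponent
  0.5, log-sd 0.35). The droplet-size scaling literature gives
  flow-rate-dependent droplet sizes but no reusable closed form for this
  ink, so this is a documented phenomenological stand-in; the exponent
  and coefficient are exposed in `spray_config()` so the scaling can be
  changed without code edits.
* Lateral plume spread about the path is Gaussian (`plume_sigma`,
  default 0.35 mm), clipped to the stencil window (the stencil physically
  blocks overspray).
* Dye mass loading scales stain opacity only (about 0.45 per wt%, with a
  small multiplicative jitter); it does not touch the spot count or
  geometry, so two runs differing only in mass loading produce identical
  geometry at the same seed.

`render_tablet()` rasterises the spots as soft-edged (0.6 px edge)
carmine-red stains on a near-white, spectrally neutral tablet over a dark
neutral background; overlapping stains compound multiplicatively, so
double deposits darken. The tablet is deliberately texture-free and the
background deliberately dark and plain: this keeps both Otsu segmentations
well posed and is the smallest faithful scene for the extraction chain.

`perturb_capture()` emulates a cellphone capture, in a fixed order:
projective tilt about a random in-plane axis (a homography of the tablet
plane under a perspective camera with focal length twice the image size;
no lens distortion), in-plane rotation, resampling to the output
resolution, Gaussian blur, additive Gaussian sensor noise, and an exposure
gain. Rotations that are exact multiples of 90 degrees (at zero tilt) are
performed without interpolation. Query images are written as JPEG
(quality 85 by default) to mimic cellphone compression.

**Brightness semantics.** Published capture conditions quote mean 8-bit
image brightnesses of 130–200. Real cellphone frames are dominated by the
subject and its surroundings under shared illumination; the synthetic
scene instead pairs a bright tablet with a deliberately dark background.
Forcing the *frame* mean to 200 under that composition requires an
exposure gain that clips the entire tablet to white and physically erases
the pattern — the two conditions are mutually inconsistent for this
scene. The capture model therefore defines `brightness_target` as the
mean 8-bit brightness of the *subject* (tablet region), solved by
bisection under clipping. This preserves the intent of the stated range
(under- to over-exposed captures) without destroying the signal the range
was measured on.

## What the simulator does and does not emulate

Emulated: spot-count scaling with flow rate and translation speed, stain
intensity scaling with mass loading, stencil confinement, enrolment
(lossless PNG) vs field capture (JPEG) asymmetry, orientation, tilt,
exposure, blur, noise and resolution changes of handheld photography.

Not emulated: drying morphology (coffee rings, satellite droplets),
tablet surface granularity, dust, glare, illumination gradients, lens
distortion, and background clutter. Two consequences matter for
interpreting test results. First, synthetic spots are radially symmetric
and smooth, which makes SIFT orientations *less* stable than on real
stains — the synthetic corpus is, if anything, adversarial for match
retention. Second, and in the opposite direction, real images of
*different* tablets share abundant ambient texture that generates spurious
descriptor matches even at strict distance ratios; the texture-free
synthetic tablets share almost none. Reported false-accept counts at
$p = 0$ with small $k$ therefore sit below what textured real-world
images produce, while at $k \ge 0.9$ the synthetic corpus reproduces the
universal false-accept result exactly. Passing tests demonstrate the
decision rule's behaviour, not photometric realism.

## Evaluation procedures

* `sweep_k()` — fractions of correct / incorrect / unconfident verdicts
  per distance ratio, with and without symmetry checking.
* `cross_validate()` — leave-true-entry-out: every query is evaluated
  against the database with its own entry removed, so every confident
  match is by construction invalid; this isolates the false-accept
  behaviour that the prominence threshold controls.
* `specificity_trace()` — the per-entry match-count vector for one query
  under several configurations: unconstrained matching ($k = 1$, no
  symmetry) gives a flat trace at the query's feature count (prominence
  0); constrained matching gives a single peak over a near-zero floor.
* `grid_eta()` — the accuracy surface $\eta = P \times R$ over a
  $(k, p)$ grid, with precision $P = TP/(TP+FP)$ and recall
  $R = TP/(TP+FN)$. A true positive is a confident-correct verdict; a
  confident verdict that is wrong — incorrect for a registered query, or
  any confident match of an unregistered query — is a false positive; a
  non-confident verdict for a registered query is a false negative.
  Unconfident verdicts of unregistered queries are the desired outcome
  and enter no cell. Zero-denominator ratios are defined as 0 and
  flagged. Match counts are cached per $(k,$ symmetry$)$ and shared
  across $p$, since the prominence threshold acts only at decision time.

## Numerical and engineering choices

* HSV uses the base-R convention (all channels in $[0,1]$); Otsu
  thresholds are computed by EBImage on 256-bin histograms.
* Grayscale is ITU-R BT.601; de-rotation and tilt warps use bilinear
  interpolation (quality/speed compromise).
* The minimum-area rectangle is computed by rotating calipers over the
  convex hull of the spot-pixel set and canonicalised to width >= height;
  the residual 180 (and square-window 90) degree ambiguity is harmless
  because SIFT descriptors are rotation-invariant.
* The blank-tablet guard requires the segmented "pattern" to be both
  minimally saturated (mean S >= 0.08) and clearly more saturated than
  the rest of the pill (3x) — an absolute threshold alone misclassifies
  legitimately overexposed captures.
* Feature caches are RDS files carrying a magic tag, schema version and
  the SIFT parameters; mismatches raise explicit errors rather than being
  silently reinterpreted. Database builds are atomic: any unreadable
  image fails the whole build with a per-file report, and rebuilds reuse
  caches whose SIFT parameters match.
* The reference-database layout is a directory with `manifest.json`,
  `references/` and `features/`; corpus layout is `references/` (PNG),
  `queries/` (JPEG), `key.csv` and `corpus.json`.

## Problem sizes

The test suite exercises small corpora (4 patterns) for unit and property
tests and acceptance-scale corpora — 50-pattern databases with 50–60
perturbed queries, the package's standard study size — for the
system-level checks; `scripts/acceptance.R` re-generates the same three
50-pattern corpora from a command-line seed and recomputes every headline
quantity from scratch.

## Known limitations

* Rotation invariance on synthetic dot constellations retains roughly
  40% of matches at off-axis angles (exact 90-degree rotations retain
  ~100%); real, textured stains fare better. The decision rule needs only
  a prominent count, not high retention, so authentication tolerates this
  comfortably at the default operating point.
* The simulator clips spots to the stencil window and ignores overspray;
  whether overspray occurs physically is not characterised.
* In-situ ramping of flow rate or translation speed during a single
  deposition is not modelled.
* Databases are held in memory during matching; the design targets
  hundreds of entries, not millions (exact search is linear per query).
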