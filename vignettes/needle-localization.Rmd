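---
title: "Two-image needle localization: methods and design notes"
author: "needleloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-image needle localization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needleloc)
```

## The problem

Biopsy needles are hard to see in conventional B-mode ultrasound: speckle
obscures them, other linear reflectors (bone, fascia) mimic them, and at
steep insertion angles the shaft reflects the beam away from the transducer
so the needle all but disappears. A practical remedy is to vibrate the
needle with a small piezoelectric buzzer clamped near its base and image it
in power Doppler mode: the vibrating shaft lights up as a trail of
high-intensity Doppler blobs. Those blobs are conspicuous but irregular —
they bloom around the shaft rather than tracing it — so Doppler alone only
localizes the needle approximately. This package implements a two-image
pipeline that uses each modality for what it is good at: the power Doppler
image for *finding* the needle and the B-mode image for *pinning it down*.

Inputs are a co-registered pair of 2D grayscale images (power Doppler and
B-mode, identical dimensions) with two pieces of physical metadata: the
pixel spacing in mm/px and the needle diameter in mm. Images are matrices
indexed `(row, col)`, 1-based, row 1 at the transducer face; angles are
degrees from the horizontal image axis, increasing toward larger rows.

## Stage 1 — power Doppler analysis

1. **Thresholding.** The iterative intermeans (Ridler–Calvard) threshold is
   computed — iterate `T <- (mean below + mean at/above)/2` from the global
   mean until the update falls below half a gray level — and every pixel
   strictly below it is zeroed.
2. **Clustering.** The surviving pixels are grouped by DBSCAN with
   neighborhood radius `R = 6` px and minimum neighborhood size `M = 100`
   pixels (a pixel counts itself, as in the common library convention);
   non-clustered pixels are discarded as noise. The defaults are the tuned
   operating point shipped with the method; both are exposed in
   `pipeline_config()`. Note their geometric meaning: with `R = 6` a disc
   holds 113 lattice points, so `M = 100` only clusters regions that are a
   dozen or more pixels across — exactly the scale of real Doppler blooming,
   and far wider than the needle itself.
3. **Initial axis.** The clustered pixels, carrying their Doppler
   intensities, are scanned with a discrete Radon transform over integration
   angles 0–179° in 1° steps; the sinogram maximum is the strongest and
   longest line through the Doppler evidence and becomes the initial needle
   axis. (Angles 180–359° are mirror images of 0–179° and are not scanned;
   the line is reconstructed analytically from its `(theta, rho)` rather
   than through an inverse transform.)
4. **Candidate regions.** Each cluster is replaced by the ellipse with the
   same centroid and second central moments (axis length
   `4 * sqrt(eigenvalue)`, the standard region-properties convention), and
   ellipses that do not touch the initial axis are eliminated — they are
   spurious responses. Tangency counts as touching, decided by the exact
   support-function test.

## Stage 2 — B-mode refinement

The B-mode image is convolved with a single complex Gabor kernel

$$g(x,y) = \exp\!\left(-\tfrac12\left(\frac{x'^2}{\sigma_x^2} +
\frac{y'^2}{\sigma_y^2}\right)\right)\, e^{\,j 2\pi x' / \lambda},$$

where the primed frame is rotated so that $x'$ runs *across* the needle and
$y'$ along it. The wavelength is matched to the needle: $\lambda$ = diameter
in pixels. The two envelope widths are fixed by requiring 50% amplitude at
$(x' = \lambda/2, y' = 0)$ and at $(x' = 0, y' = \lambda)$, which gives
$\sigma_x = \lambda / (2\sqrt{2\ln 2})$ and
$\sigma_y = \lambda / \sqrt{2\ln 2}$. These two conditions are asserted to
`1e-9` in the tests for arbitrary wavelengths, which pins the formulas
exactly. The filter response is taken as the complex magnitude (phase-shift
invariant along the needle), the kernel is truncated at $\pm 3$ of the
larger sigma on an odd-sized support, and the convolution uses zero padding
(`EBImage::filter2`).

The response is kept only inside the union of the candidate ellipses and
zeroed elsewhere — this masking is what defeats distractor reflectors that a
Gabor filter alone would also enhance. Filtering the full image and masking
afterwards is mathematically identical to filtering within the regions
except at region borders; the border behavior is a free choice and we chose
the simpler one. Finally the Radon projection is computed at the *single*
angle of the initial axis and the offset maximizing it becomes the refined
axis. The angle is deliberately not re-estimated: the Doppler stage owns the
angle, the B-mode stage owns the offset.

## Stage 3 — tip localization

A rectangular window (length two diameters along the axis, width one
diameter) slides one pixel at a time from the entry point (the shallowest
boundary intersection of the axis), recording the mean Doppler and B-mode
intensities $\bar I_{PD}(l)$, $\bar I_{BM}(l)$ at each 0-based axis position
$l$. Means use bilinear sampling on a half-pixel subgrid (4 samples per
pixel area) for rotation robustness, and out-of-image parts of the window
are excluded.

The Doppler profile is thresholded at its own mean to a binary indicator
$B_{PD}$, and the separation score

$$S_{PD}(l) = \frac{\sum_{i=0}^{l} B_{PD}(i) + \sum_{i=l+1}^{L-1}
\left(1 - B_{PD}(i)\right)}{L}$$

is maximized; its argmax is the best "strong before, weak after" split and
approximates the tip. (The upper summation limit is $L-1$: profile indices
run 0 to $L-1$, and summing to $L$ would read past the profile; the
denominator stays $L$. The implementation is verified against brute force
for every binary vector up to length 12.) The B-mode profile then refines
this: within two diameters of the Doppler estimate, the most negative
forward difference of $\bar I_{BM}$ — the needle-to-background drop — is the
tip. We use the *signed* derivative, since an absolute value has no negative
peaks to find. Ties in both criteria resolve to the larger $l$ (the needle
extends as deep as the evidence supports); the tip is placed at the sample
before the drop, without sub-pixel interpolation. If no negative difference
exists in the window the Doppler estimate is kept and flagged low
confidence.

## Error metrics

* **Axis error**: project the true entry and tip onto the estimated axis;
  the error is the larger of the two point-to-line distances, in mm. It is
  invariant to which endpoint is called entry.
* **Angle error**: undirected line-angle difference, wrapped to [0°, 90°].
* **Tip error**: Euclidean distance between estimated and true tip, mm.
* **Failure**: axis error ≥ 3 mm. Batch summaries report the failure rate
  over all trials and mean ± sd errors over successes only, per
  insertion-angle bin — shallow [0°, 20°], moderate (20°, 40°], steep
  (40°, 65°] and the full range. Bin edges are closed on the right (a 20°
  trial is shallow); the bound angles are shared by the ranges and edge
  membership had to be fixed somehow.

## The synthetic phantom

Real acquisitions are not reproducible from a description, so the package
carries a seeded generator (`generate_phantom_pair()`) that emulates the
statistical structure the pipeline assumes, with exact ground truth.
Defaults describe the acquisition geometry the method targets: a
300 × 300 px field at 0.3 mm/px (a 90 mm imaging depth), an 18G needle
(1.27 mm), entry on the top edge, insertion angles 0–65° and depths
40–80 mm. The geometry is rectangular (linear-array-like) rather than the
curvilinear fan of a convex probe: the algorithm operates on pixel grids
either way and never uses the fan geometry, so modeling scan conversion
would add a step without adding information.

**B-mode.** Rayleigh-distributed multiplicative speckle, log-compressed to
[0, 1]; an added needle ridge of width one diameter (Gaussian cross-section,
FWHM = diameter) whose amplitude 0.8 decays linearly with insertion angle at
0.009/degree — steep needles are dimmer, as in practice — plus two
distractor line reflectors at least 15° off the needle angle.

**Power Doppler.** Near-zero Rayleigh noise plus 16 elliptical Gaussian
blobs strung from the entry to one diameter short of the tip, spacing
shrinking toward the tip, with along-axis sigma 1.3–2 diameters and
cross-axis sigma 1.2–1.8 diameters (Doppler blooming is much wider than the
shaft — this is what makes DBSCAN's `M = 100` satisfiable, as on real
images). The terminal blob is strong (amplitude 0.85–1) and extended: the
tip is the vibration anti-node and terminates the trail crisply. Blob
centers are laterally displaced by a per-acquisition common bias (0.3–0.8 of
the jitter, random side) plus small scatter, everything clamped within
`doppler_blob_jitter` = 1 mm of the axis. The common bias is deliberate: it
makes the Doppler-only centerline systematically off by a millimeter or so —
which is precisely why the method needs the B-mode stage — while keeping the
centerline straight, as a rigid shaft demands. Three spurious blobs are
placed at least 10 diameters off axis to exercise the ellipse-elimination
step. All randomness flows from the single seed and the caller's RNG state
is untouched.

What the phantom does *not* emulate: curvilinear geometry, depth-dependent
resolution loss, reverberation and comet-tail artifacts, flow- or
motion-induced Doppler clutter, tissue heterogeneity. Passing the synthetic
batch therefore demonstrates correctness of the pipeline's logic under the
structure it assumes, not clinical performance.

## Numerical choices

* **Radon discretization.** Each pixel is a unit square whose shadow at
  angle θ is the trapezoid `box(|cos θ|) ⊛ box(|sin θ|)`; unit-spaced offset
  bins accumulate the exact trapezoid mass (closed-form CDF). A point-mass
  model (nearest or linearly-split binning) is measurably biased at 0°, 45°,
  90°, 135°, where whole diagonals of pixel centers project coherently into
  single bins — with 1° scanning this pulled estimates at e.g. 43° to
  exactly 45°. The square-pixel model is the standard tomography fix and is
  verified against an independent numerically-integrated oracle.
* **Ties.** Radon maxima: smallest angle, then smallest offset. $S_{PD}$
  and the B-mode drop: largest (deepest) index.
* **Intermeans tolerance.** "Half a gray level" is 0.5 on integer-scaled
  images and 0.5/255 on [0, 1]-normalized ones; a constant image returns
  itself with a degeneracy flag.
* **DBSCAN determinism.** Cluster seeds are visited in a fixed scan order
  and a border pixel joins the first cluster that reaches it, making labels
  reproducible. Note that exact density connectivity has unintuitive
  consequences at this operating point: the four corners of a solid 12 × 12
  or 20 × 20 block are farther than `R` from every core pixel and are
  dropped as noise (the brute-force oracle in the tests agrees).
* **Degenerate inputs.** All-zero Doppler evidence, empty candidate-region
  lists and all-zero filtered images produce a structured failure result
  with a reason (`run_pipeline` never crashes on them); constant profiles
  fall back with low-confidence flags.

## Problem sizes used in the tests

The test suite and the acceptance script run the full pipeline on 30
phantoms (300 × 300 px) with insertion angles uniform on 0–65° and depths
uniform on 40–80 mm, the generator's study conditions; oracle-equivalence
checks (brute-force DBSCAN, numerically integrated Radon, exhaustive
$S_{PD}$ enumeration to length 12) run on fixtures up to 64 × 64 px, where
exhaustive computation is exact and fast. On one CPU the whole suite
completes in about a minute.

## Known limitations

* The refined axis keeps the initial angle, so the final accuracy is bounded
  by the 1° Doppler angle grid and the Doppler trail's straightness; only
  the offset benefits from the B-mode stage.
* $S_{PD}$'s threshold is the mean of the *whole* profile, including the
  post-tip tail; profiles whose in-image tail is short get a high threshold
  and a conservative (shallow) Doppler tip estimate. The B-mode refinement
  absorbs this only within its two-diameter search window.
* A single straight needle is assumed: no curved shafts, no multiple
  needles, no temporal tracking.
* Needles steeper than 65° are out of the supported range, as the underlying
  imaging physics gives neither modality a usable signal there.
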