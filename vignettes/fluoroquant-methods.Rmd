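---
title: "Quantifying dental fluorosis from fluorescence images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dental fluorosis from fluorescence images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Under ~405 nm illumination viewed through a long-pass filter, sound enamel
fluoresces and hypomineralized enamel fluoresces less: fluorotic lesions
appear dark in the green channel of a quantitative light-induced fluorescence
(QLF) capture. Classical QLF caries analysis reconstructs a *discrete* lesion
from the sound enamel around it. Fluorosis defeats that approach: its lesions
are diffuse and can extend across the whole tooth surface, leaving no clean
sound region to act as a reference. `fluoroquant` implements the two
reconstruction strategies developed for this situation, applied to the two
maxillary central incisors, plus the statistics used to test whether their
outputs track fluorosis severity.

Both techniques consume only the green channel `g(x, y)` of an 8-bit RGB
capture, restricted to operator-drawn binary tooth masks (one per incisor,
labels `UR1`/`UL1`). No pixel outside a mask is ever analyzed.

## Technique 1: unsharp-mask blur subtraction

The "blur" technique estimates the sound brightness at each pixel as the mean
of a large window around it (default 30 × 30 px, the published optimum), then
subtracts:

\[ \ell(x,y) \;=\; \max\{0,\; \bar g_{30}(x,y) - g(x,y)\} \]

The blurred image acts as the local sound-enamel control; pixels darker than
it are candidate fluorosis. Two choices matter:

* **Mask-aware averaging** (default on). Window means are renormalized over
  in-mask pixels only. Including the near-black background in edge windows
  would manufacture spurious "loss" all along the tooth outline.
* **Base-level selection at k SD** (default `k = 2`). Lesion pixels are those
  with loss above `mean + k · SD` of the loss over an automatically selected
  *reference area* (below). If the reference SD is exactly zero the rule
  degenerates to `loss > mean`, documented and tested.

Metrics per tooth: `delta_f` (mean percentage loss of lesion pixels relative
to the local blurred estimate), `area` (lesion extent, mm² when the pixel
pitch is known, otherwise a flagged pixel count — the capture hardware's
pitch is not published, so there is no default scale), and the summary
`delta_q = delta_f × area`.

The adaptive base level has a consequence worth knowing: as severity grows,
loss bleeds into the reference statistics, the cut rises, and the selected
area can shrink. `delta_f` deepens monotonically with lesion depth on seeded
phantom ladders, but `area` (and through it `delta_q`) need not — the
technique's known artifact at high severity, which we observe and do not
correct.

### Automatic reference area

The original workflow required the operator to pick a reference region. Here
it is automatic: a gingival anchor point is triangulated from the two masks
(horizontal midpoint of the centroids, offset above the higher mask top edge
by 0.25 of the mean mask height — gingiva is at the image top), and for each
tooth the square window (default 9 × 9 px) centred on the segment from that
point through the tooth centroid, lying in the incisal half of the mask, with
the **brightest median** green value is chosen; ties resolve to the smallest
(row, column) centre. Bright windows are sound enamel, so the objective
avoids lesions implicitly; a window more than half covered by a dark defect
can no longer win. The anchor construction is not specified quantitatively
in the source work; the offset fraction and window side are exposed
parameters.

## Technique 2: convex-hull clean-surface reconstruction

The "hull" technique treats every in-mask pixel as a 3D point
`(x, y, g(x,y))` and computes the upper surface of the 3D convex hull of
that cloud (Quickhull-family incremental algorithm, implemented in C++).
The upper facets — outward normal with positive brightness component — form
the smallest concave piecewise-planar surface dominating every sample: a
"clean" tooth in which dark areas are filled by planar interpolation between
the surrounding sound areas. Only the upper envelope is rendered; the lower
hull would reconstruct the lesions themselves.

Processing stages per tooth:

1. **Morphological opening** (grayscale erosion then dilation, disk radius
   1 px by default) removes bright speckle noise before the hull; the
   structuring element of the original software is unstated, so the radius
   is a parameter. The operation is mask-aware: out-of-mask neighbours are
   ignored rather than treated as zero, which would erode the rim.
2. **Upper hull and rasterization.** Facets are rasterized over their (x, y)
   projection by planar interpolation; facet-edge pixels take the first
   facet in a deterministic (sorted vertex-index) order, and any pixel missed
   by rasterization falls back to the exact identity
   `envelope = min over upper-facet planes`. Hulls are built per tooth so a
   diastema gap can never become part of a facet.
3. **Loss and threshold.** `loss = clean − g` (non-negative by construction);
   values strictly below the threshold (default 5 out of 255, the study's
   setting chosen to include mild fluorosis) are zeroed as background noise.
4. **Metrics.** `area` = fraction of tooth pixels with nonzero loss;
   `delta_f` = mean fractional loss `loss/clean` over those pixels;
   `delta_q` = mean fractional loss over the *entire* tooth. The identity
   `delta_q = area × delta_f` holds by construction and is asserted to
   numerical precision on every analyzed phantom.

Degenerate inputs are handled exactly: a mask whose pixels are collinear in
(x, y) gets the 1D upper concave chain; a fully coplanar cloud (constant or
planar-ramp brightness) is returned unchanged; fewer than 3 pixels is an
error. Envelope values within 1e-6 of the data snap onto it, so pixels that
lie on the hull carry exactly zero loss rather than floating-point dust.

## Synthetic phantoms and what they do (not) show

No study images are available, so every pipeline stage is exercised on a
seeded generator (`make_phantom()`, `make_population()`):

* two superellipse incisors over black background; concave sound surface
  (dome + affine cervico-incisal gradient, default 180 ± 12 brightness
  units); green channel dominant (R = 0.35 G, B = 0.22 G);
* diffuse lesions by thresholding a smooth correlated Gaussian field
  (box-smoothed white noise, correlation length 7 px) at the quantile giving
  the target area fraction, then multiplying brightness by `1 − depth`
  inside the lesion. Ground truth is recorded *as realized*, not as
  targeted;
* additive Gaussian noise (SD 2), 8-bit quantization, optional confounders
  (stain patch, demarcated opacity, missing tooth), and repeat captures with
  integer translation, illumination gain and fresh noise;
* dose-response populations: five cooking-water fluoride intervals
  (boundaries 0.20/0.60/0.90/1.60 ppm, lower-inclusive after rounding to the
  2 dp precision at which they are defined), equal subject counts, per-tooth
  Thylstrup–Fejerskov (TF) scores from a discretized truncated normal with
  the published per-interval means and SDs (0.70/0.93, 1.01/1.02, 1.28/1.30,
  1.65/1.47, 2.30/1.90), clipped to 0–7, latent inter-tooth correlation 0.8
  (the true joint distribution across incisors is unreported — an assumption);
  severity maps to lesion parameters through monotone anchors
  TF 0 → (0, 0), 1 → (0.10, 0.04), 3 → (0.35, 0.08), 5+ → (0.70, 0.15),
  linear in between — magnitudes placed inside the observed ranges of the
  hull metrics, purely a generator convention.

Phantoms emulate geometry, brightness statistics and the dose-response
*structure* — not real enamel texture, specular highlights, plaque,
inter-operator mask variability or the biology linking fluoride dose to
severity. Green tests therefore show that the algorithms measure what they
claim on images with known truth, and that the statistics behave; they do
not certify performance on clinical captures.

### Quantization and the continuous-intensity mode

An 8-bit image carries ±0.5 rounding noise. With a loss threshold of zero,
*any* nonzero loss counts as lesion, so quantization noise alone would flag
large parts of a sound tooth — precisely the background noise the study's
threshold of 5 exists to remove. Ground-truth recovery of the reconstruction
is therefore validated on the generator's continuous-intensity mode
(`quantize = FALSE`) with threshold 0 and no noise — isolating the estimator
from quantization — while the quantized, noisy path is validated at the
study's threshold elsewhere in the suite. On the continuous 3 × 3 grid of
(area, depth) settings the hull recovers realized area within ±0.03 and mean
depth within ±0.02 (measured mean absolute errors are an order of magnitude
smaller).

## Statistics

The read-out mirrors the study's pipeline:

* **Subject level.** TF per subject is the *higher* of the two incisor
  scores; metrics follow the analogous rule (the tooth with the larger
  `delta_q` contributes its full metric triple — the source work states the
  max rule only for TF, so this extension is our design choice, made for
  coherence of the subject-level comparison).
* **Interval separation.** One-way ANOVA with a Levene homogeneity check
  (median-centred); when homogeneity is rejected (p < 0.05) the decision
  path falls back to pairwise two-sided Mann-Whitney U tests — exact
  enumeration when both groups are ≤ 8 and untied, otherwise the
  tie-corrected normal approximation without continuity correction (the
  asymptotic p of the usual survey software). All 10 unordered pairs are
  corrected by a simple Bonferroni ×10 (the 10-pair family; the published
  table's mirrored cells are consistent with either family — flagged).
* **Correlation.** Spearman's rho with average ranks, p by the t
  approximation.
* **Repeatability.** ICC from the two-way crossed ANOVA decomposition;
  the headline form is ICC(2,1) absolute agreement (the source work does not
  state its form), with the consistency form reported alongside.
* **ROC.** Cases are subjects with TF ≥ 3 (the published classifier
  boundary); the curve sweeps observed metric values, AUC is trapezoidal
  (equal to the tie-adjusted `U/(n₁n₂)`, asserted on random fixtures), and
  the operating point maximizes Youden's J with ties resolved to the lower
  threshold.

## Validation design and problem sizes

Validation is two-tier, and the tiers are deliberate:

* **Image tier** (oracle equivalence, recovery, monotonicity): the hull
  surface is checked against a brute-force upper-envelope oracle (minimum
  over all dominating three-point planes) on 50 random masked grids up to
  10 × 10; the blur against a double-loop window average on 50 grids up to
  12 × 12; recovery and monotone ladders run on full 120 × 160 phantoms.
* **Statistics tier** (error control, power): replicate studies use the
  generator's *metrics-scale observation model* — ground-truth lesion
  parameters plus a measurement bias/noise model calibrated once against the
  rendered pipeline's measured error (noise floor ≈ +0.02 area / +0.032
  depth at zero severity from residual supra-threshold loss; mild
  high-severity underestimation from hull-edge effects; additive SD ≈
  0.010 / 0.003). This makes 200 null-population and 100 dose-response
  replicates at 30 subjects/interval affordable while the image tier pins
  the fidelity of what the surrogate imitates.

Under the null (identical TF distributions in all intervals) the
Bonferroni-corrected pairwise procedure flags well under 5% of pairs.
Under the calibrated dose-response, the extreme intervals 0 vs 4 separate on
`delta_q` in about 93% of replicates at n = 30/interval — the same order as
the TF score itself (97%) under identical conditions; the published
interval-4 TF spread (SD 1.9, range 0–7) makes occasional unlucky draws
in which the extreme intervals genuinely overlap.

## Numerical choices

* Hull visibility tolerance `1e-9 ×` coordinate scale; facet-edge ties by
  sorted-vertex order; rasterization misses fall back to the min-plane
  identity; the clean surface is clamped to dominate the input and to stay
  within the in-mask brightness range.
* Even blur windows anchor the extra row/column right/down; image-border
  windows renormalize over in-image pixels.
* Interval boundaries compare after decimal rounding of the stored double
  (`sprintf`-based), so 0.595 ppm falls in interval 1 on every platform.
* Masks are reduced to their largest 8-connected component on construction;
  excluded subjects are retained in outputs with their reason rather than
  silently dropped.
* Every generator entry point takes a seed and restores the caller's RNG
  state; end-to-end runs are byte-for-byte reproducible (no timestamps in
  outputs; paths stored relative to the run directory).

## Known limitations

* The blur technique's adaptive base level makes its `area`/`delta_q`
  non-monotone at high severity (observed and documented above); the hull
  technique is the better-behaved of the two, as the study also concluded.
* Confounders (stain, demarcated opacities, caries-like defects) are
  *generated* but not classified: both techniques score them as fluorosis,
  reproducing the methods' published failure mode. Opacities that increase
  fluorescence are out of scope.
* The hull bridges chords across strictly concave sound surfaces, so lesion
  pixels touching the mask rim are hull vertices and carry zero loss — a
  small boundary underestimate of `area` covered by the stated tolerances.
* Physical-unit blur areas require a user-supplied pixel pitch.
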