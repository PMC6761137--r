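---
title: "Quantifying tight-junction fragmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tight-junction fragmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tjquant)
```

## The measurement

Epithelial tight junctions, immunolabelled against ZO-1, appear as a thin
bright polygonal network on a dark background. Oxidative insult fragments
this network, and the length distribution of the remaining continuous
membrane segments quantifies the damage. `tjquant` implements the
measurement as a fixed chain of image operations, each exposed as its own
function so every stage can be tested in isolation:

maximum-intensity projection → Hessian ridge enhancement → binarization →
skeletonization → junction detection (hit-or-miss) → junction subtraction →
branch measurement → histograms / large-segment counts → rank-sum
comparison.

The assumptions are those of the image model: junctions are thin (a few
pixels), bright relative to background, and quasi-one-dimensional, so that
the smallest eigenvalue of the intensity Hessian is a reliable line
indicator; and the pixel size is known, so pixel counts convert to
micrometres.

## Ridge enhancement

At scale $\sigma$ the image is convolved with sampled Gaussian-derivative
kernels to obtain $I_{xx}, I_{yy}, I_{xy}$, and the smallest eigenvalue

$$\lambda_{\min} = \tfrac{1}{2}(I_{xx}+I_{yy}) -
\sqrt{\tfrac{1}{4}(I_{xx}-I_{yy})^2 + I_{xy}^2}$$

is computed pixel-wise. Bright ridges have $\lambda_{\min} < 0$ across
them, so the reported strength is $\max(0, -\lambda_{\min})$: positive on
lines, exactly zero on constant images (the derivative kernels are
corrected to annihilate constants, and a constant input short-circuits to a
zero map). Boundaries are handled by mirror reflection.

For a line of Gaussian cross-section $A e^{-x^2/(2w^2)}$, optionally blurred
by a PSF of sd $p$, the convolutions compose and the centerline strength has
the closed form $A\,w/(w^2+p^2+\sigma^2)^{3/2}$ (`line_ridge_strength()`).
This is the package's analytic anchor: the detector must reproduce it within
2%. Sampled derivative kernels were chosen over smoothing followed by finite
central differences because the second-order difference operator
underestimates the curvature of a Gaussian profile of total sd $s$ by a
factor $\approx 1 - 1/(4s^2)$ — a 5% error at $s^2 = 5$, which would fail
the 2% anchor; the sampled kernels are accurate to the sampling error
(≈ 0.02% on the anchor case).

* `scale_sigma` (px, default **1.5**): matched to junction line widths of
  roughly 2–4 px in typical 40×–63× acquisitions. Configurable; detection is
  best when $\sigma$ is comparable to the line's cross-section sd.
* `threshold_method` (default **"otsu"**): Otsu's threshold over 256
  equal-width bins spanning the strength range, maximizing between-class
  variance with a first-maximum tie-break; the threshold is the upper edge of
  the last low-class bin and foreground is strictly above it. An all-constant
  map is a degenerate-input error. `"fixed"` takes a user threshold for
  reproducibility and calibration studies.

## Skeleton, junctions, branches

Binarized masks are thinned to 1-px medial curves by sequential simple-point
deletion: a pixel is deleted only if it is 2-D simple (one 8-connected
foreground component and one 4-adjacent background component in its 3×3
neighborhood — deletion provably preserves topology) and not an endpoint.
Four directional sub-passes per iteration keep the result approximately
medial; sequential processing in fixed raster order makes it deterministic.
The 256-entry simple-point table is built by explicit enumeration in R; the
pass itself is a small C++ routine. Consequences, tested as invariants: the
skeleton is a subset of the mask, preserves the number of 8-connected
components exactly, and contains no 2×2 foreground block.

**Junction points** are skeleton pixels from which three or more branches
leave: at least three background→foreground transitions around the circular
sequence of the 8 neighbors. The implementation evaluates the union of
binary hit-or-miss matches over the catalogue of all 3×3 templates with that
property (each pixel's neighborhood is encoded as an 8-bit configuration
code and looked up); an independent implementation counts ring transitions
from shifted images, and the two are checked equal on all 512 possible
neighborhoods. A plain ≥ 3-neighbor count was rejected as the definition:
next to a clean 4-way crossing the arm pixels themselves have 4 neighbors
(two of them diagonal), so neighbor counting marks a 5-pixel cross rather
than the single crossing point, and the measured branches lose a pixel at
every junction.

**Junction subtraction** removes exactly the junction pixels. One subtlety
makes the subtraction meaningful under 8-connectivity: two branch pixels
that touch only diagonally *across* a removed junction (their shared
orthogonal neighbor was the junction) would otherwise remain connected,
silently undoing the split. Branch labeling therefore drops a diagonal
adjacency when either of its two shared orthogonal cells is a subtracted
junction pixel. Ordinary staircase diagonals, whose shared cells are
background, are unaffected. With this rule a plus-shaped skeleton with arms
of 5 px yields exactly one junction and four 5-px branches.

**Branch measurement** labels the remaining 8-connected components in raster
order of each component's first pixel (so outputs are byte-identical across
runs), discards components below `min_branch_px` (default **3 px**: 1–2 px
fragments are dominated by skeletonization artifacts; no spur pruning is
applied beyond this size filter), and reports per segment:

* `length_um = pixel_count × pixel_size` — the particle-size metric of a
  1-px skeleton, the primary readout;
* `geodesic_um = (orthogonal steps + √2 · diagonal steps) × pixel_size` — a
  physically truer length carried alongside for sensitivity analysis. The
  pixel-count metric undercounts a straight line at angle θ by the factor
  $\max(|\cos\theta|,|\sin\theta|)$, i.e. ≈ 10% on average over random
  orientations; the geodesic metric does not.

Pixel conservation — |skeleton| = |junctions| + Σ segment pixels + discarded
pixels — holds exactly on every input and is asserted on random masks.

## Comparison between conditions

Histograms use half-open bins $[e_i, e_{i+1})$; out-of-range lengths are
excluded but counted. The *large-segment count* is the number of segments
with $x < \ell < y$ (strict); defaults $x = 5$, $y = 100$ µm, always
configurable, and the full histogram is always emitted so conclusions can be
re-examined under other windows.

The sampling unit is the image: per-image large-segment counts are compared
with a two-sided Mann-Whitney rank-sum test. Pooling individual segments
across images would treat segments as independent replicates
(pseudo-replication); it is available behind `pooled = TRUE` but flagged as
such. The test uses the exact null distribution of U whenever the combined
sample is ≤ 20 observations without ties (enumeration stays desk-scale
there and covers typical replicate counts), otherwise a normal approximation
with tie and continuity corrections; the method used is recorded in the
result. Exactness is verified against full permutation enumeration, and the
empirical type-I error at α = 0.05 is checked to stay within [0.03, 0.07]
under the null. No multiple-testing correction is applied across windows or
gene panels.

## The synthetic monolayer generator

The generator exists so that every stage, and the chain end-to-end, can be
validated against known truth.

* **Geometry**: cell centers are sampled uniformly on a periodic (toroidal)
  domain under a hard-core minimum spacing (default $0.55\sqrt{HW/n}$ —
  loose enough for rejection sampling to succeed, tight enough to exclude
  sliver cells); the junction network is the exact Voronoi boundary,
  computed by half-plane clipping against the 3×3 replicated seed set. On
  the torus every cell averages exactly 6 edges (Euler's formula), which the
  tests assert at n = 200.
* **Fragmentation**: gaps of fixed length (default **10 px**) are placed
  uniformly at random along the boundary without overlap until a fraction
  *f* of the total length is removed (overshoot ≤ one gap; edges shorter
  than a gap may be erased whole). Retained arcs and their true lengths are
  the ground truth.
* **Rendering**: intensity = background + A·exp(−d²/(2w²)) with d the
  distance to the nearest retained arc (periodic wrap, so the cropped field
  has no border bias), then Gaussian PSF blur, then per-frame noise.
  Defaults: w = 2 px, A = 100 counts, background = 10 counts, PSF σ = 1 px,
  Gaussian noise sd = 10 (SNR = A/sd = 10), 3 frames, 0.5 µm/px — a 20×-class
  sampling at which a 15 µm RPE cell spans ≈ 30 px and junction lines are a
  few px wide. A master seed derives geometry, fragmentation and noise seeds
  by fixed offsets, so each stage is independently reproducible.

What the generator does **not** emulate: photobleaching, uneven
illumination, 3-D sectioning, intensity variation along membranes, curved
edges (arcs are straight segments), and biological heterogeneity of cell
sizes beyond what hard-core Voronoi gives. Passing the recovery tests
therefore shows the measurement chain is geometrically faithful under the
stated image model, not that it is robust to every real-world artifact.

## The calibrated validation protocol

For validation against ground truth the measurement is configured from the
known rendering model rather than from the data
(`ridge_calibration()`):

* detection scale $\sigma = \sqrt{w^2 + p^2}$ — the rendered line's total
  cross-section sd, the textbook scale-matching choice;
* fixed threshold = half the analytic centerline strength
  $A w/(w^2+p^2+\sigma^2)^{3/2}$. The half-maximum contour at the end of a
  blurred line passes through the true endpoint, so this threshold localizes
  cut ends without bias. A data-driven Otsu threshold on these images sits
  near a third of the line peak; the mask then extends
  $d \approx s\sqrt{2\ln(S/2T)}$ beyond every cut end (s the line sd, S the
  line strength, T the threshold) — about 2–3 px per end here, which at
  f = 0.5 (many gap ends, default 10 px gaps) inflates total recovered
  length far beyond the gap budget. This is a property of data-driven
  thresholds on blurred line ends, documented here deliberately: for
  *relative* comparisons between conditions (the intended use, mirrored by
  the discrimination study) the inflation is common-mode; for *absolute*
  recovery it is not, hence the calibrated protocol.
* recovery is compared on the geodesic metric, the one commensurable with
  Euclidean ground-truth lengths (see the 10% orientation bias above).

Validation problem sizes (chosen once as realistic desk-scale studies, and
stated here so the numbers in `scripts/acceptance.R` are interpretable):
recovery uses n_cells = 80 on a 256×256 px field, 6 seeds per fragmentation
level f ∈ {0, 0.25, 0.5}, asserting mean recovered/true within 15% and
median segment length strictly decreasing in f; discrimination uses
n_cells = 24 on 144×144 px (the per-image readout is a count, which does not
need a large field), 6 images per condition, f = 0 vs f = 0.4, 100
replicates, asserting p ≤ 0.01 in at least 95.

## qPCR relative expression

`ΔCt = mean Ct(target) − mean Ct(reference)` over replicate wells
(arithmetic mean, no outlier rejection; the replicate SD is reported for
QC). Fold change = $2^{-(\Delta Ct_{sample} - \Delta Ct_{control})}$ with
the control ΔCt taken as the mean of per-sample ΔCt values over the control
*condition* — results are expressed per treatment group, which is how such
experiments are reported; a per-sample control pairing is not identifiable
from a condition-labelled table. Identities that follow and are tested: the
reference gene is exactly 1 in every sample; fold changes are invariant to
adding a constant to all Cts of a sample; one cycle earlier doubles
expression. No amplification-efficiency correction or standard-curve fitting
is performed — the comparative method is taken at face value.

## Numerical and interface choices

* Indices are 1-based (row, col), row-major raster order for all
  deterministic orderings — R's native convention.
* Kernel radius is ⌈4σ⌉ (≥ 2), mirror-reflected boundaries everywhere
  (convolution, blur, Hessian).
* TIFF: reading via the `tiff` package, original integer units preserved
  (no [0,1] rescaling). Pixel size comes from an explicit override, else
  resolution tags (inch/cm, or pixels-per-µm when the unit is "none");
  a file with neither is an error — lengths are physical, so 1 µm/px is
  never silently assumed. Writing uses a minimal baseline-TIFF writer
  because the `tiff` package cannot emit resolution tags; calibration
  round-trips by construction.
* Degenerate inputs: empty masks give empty (not failing) skeletons and
  segment sets; an all-equal strength map fails Otsu loudly; junction
  coordinates off the skeleton are a consistency error.
* RNG: generator functions take explicit seeds and restore the caller's RNG
  state.

## Known limitations

* Segment lengths shorter than ~3 px are unmeasurable by construction
  (`min_branch_px`), so extreme fragmentation saturates the readout.
* The pixel-count length metric carries its orientation bias into any
  absolute statement; use `geodesic_um` when comparing to physical truth.
* At SNR ≲ 2 ridge detection degrades and recovery is not guaranteed; the
  validated regime is SNR ≥ 10.
* Junction subtraction shortens branches by the junction pixels themselves;
  with the branch-count junction definition this is a single pixel per
  clean crossing but can be more in dense clusters.
* The Mann-Whitney exact p at 3 vs 3 images cannot go below 0.1; design
  comparisons with ≥ 5–6 images per condition if significance at 0.01 is
  required.
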