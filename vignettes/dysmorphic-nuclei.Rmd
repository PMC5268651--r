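---
title: "Segmenting and classifying dysmorphic nuclei: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and classifying dysmorphic nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blebseg)
```

## The problem

Nuclei with abnormal morphology — folds, lobes, crevices and, most subtly,
low-intensity protrusions called blebs — are a hallmark of laminopathies,
cancers and some viral infections. In DNA-counterstained fluorescence images
these nuclei defeat routine segmentation: a bleb is often several-fold dimmer
than the nuclear body, so intensity thresholds either swallow background or
amputate the bleb, and shape priors (convexity, circularity) are exactly what
dysmorphic nuclei violate. blebseg implements a segmentation strategy designed
around these failure modes, a quantitative validation framework against
multi-observer manual ground truth, and a morpho-textural classifier that
labels each nucleus normal or dysmorphic.

## The pipeline

A `calibrated_image` (intensity raster plus an isotropic micrometer pixel
size) flows through four stages. All micrometer parameters are converted to
pixels by one rounding rule (`um_to_px()`), so a configuration means the same
physical thing at any magnification. Anisotropic pixels are rejected at read
time because every micrometer-valued default assumes isotropy.

### 1. Preprocessing

Optional background correction (grayscale opening with a flat square window,
subtracted from the image — the top-hat construction; radius default 50 µm, a
scale well above any nucleus) and one optional smoothing filter (Gaussian,
median, mean, minimum, maximum or variance) at a user scale. For the synthetic
benchmarks in this package a 0.5 µm Gaussian is used: it suppresses shot noise
that would otherwise fragment threshold masks, while blurring the ~0.3 µm
nuclear edge much less than the band used for refinement.

### 2. Two-pass thresholding

A single global threshold cannot serve bright and dim nuclei simultaneously,
and dim blebs fall below image-level thresholds entirely. The two-pass scheme
therefore:

1. applies a global automatic threshold to find *seed* regions (8-connected,
   hole-filled, area-filtered);
2. dilates each seed by at most 3 µm of Euclidean distance, restricted to the
   seed's cell in a Voronoi tessellation computed by distance to the seed
   *region*, so neighboring regions can never fuse;
3. recomputes an automatic threshold from the pixel population *inside each
   dilated region only*, keeping the largest resulting component as the
   *initial* ROI. A region whose histogram is degenerate (constant) falls back
   to the global threshold value.

Sixteen automatic threshold methods are provided (`threshold_methods()`),
computed on 256-bin histograms spanning the population min–max range
regardless of bit depth — the convention of the common reference
implementations. The package default pairs a triangle global threshold with a
mean local threshold; both choices are configuration, not dogma, and the right
pair is data-dependent (the validation module exists precisely to choose it).

### 3. Contour refinement by optimal path finding

Thresholding alone leaves crevices and bleb borders ragged. Each initial
contour is refined by:

- resampling the contour to `r = max(32, round(perimeter_px))` arc positions
  and sampling a band of `q = 2·round(half_width/pixel_size)+1` values along
  the outward normal at each position (bilinear interpolation, border values
  clamped). The band half-width default is 1 µm, i.e. a 2 µm band;
- enhancing the nuclear edge with a vertical Sobel kernel signed so that
  bright-inside → dark-outside transitions are positive; negative responses
  (debris edges running the wrong way) are clamped to zero;
- dividing each column by its maximum, so weak bleb edges weigh as much as
  bright body edges;
- finding the left-to-right path maximizing *path strength* = gain / loss,
  where a step from row *k* to row *i* traverses the intervening cells of the
  predecessor column plus the landing cell, gain sums their normalized
  responses and loss counts the traversed cells (a straight path has loss
  `r`). Vertical runs of any height are allowed, so the path can turn up to
  90° and descend into crevices.

The strength objective is a ratio, which is not decomposable with a single
gain/loss pair per matrix element: the prefix that is best *in ratio* at an
element need not extend to the best full path. The dynamic program is
therefore stratified by the (integer) loss: for every element and every
possible loss, the maximal gain over all paths ending there is maintained
(compiled code; `optimal_path()`). This computes, exactly, the maximum
strength over all column-monotone paths to each element — the stated intent of
the recursion — and the test suite verifies equality with exhaustive path
enumeration to 1e-12 on hundreds of random instances. Ties are broken toward
the smallest vertical displacement, then the smaller row, making the output
deterministic.

Closure is handled by wrapping the first ⌈r/10⌉ columns onto the right edge
before the DP, discarding the duplicate afterwards, and blending any residual
start/end mismatch linearly over the final 5% of columns. Two smoothing steps
keep reconstructions well-posed: band anchors come from the resampled contour
smoothed with a circular Gaussian (σ 1.5 samples), which prevents the
staircase vertices of rasterized contours from producing crossing normal rays,
and the optimal path is smoothed with a circular 3-column moving average,
which removes single-column zigzags while leaving the ≥ 10-column dips that
describe crevices untouched. If a reconstructed polygon still self-intersects,
the step is retried with heavier path smoothing and, failing that, the
pre-refinement contour is kept with a warning.

Refinement iterates (default 5 cycles, convergence when the maximal
displacement falls below 0.5 px) so that crevices deeper than the 1 µm band
half-width are reached across cycles; a single cycle can move the contour at
most one half-width.

### 4. Conditional watershed

Touching nuclei that survive the Voronoi constraint are separated by a
distance-transform watershed (on the Gaussian-smoothed distance map, σ 1 px,
to suppress spurious maxima). Because a watershed would also happily amputate
a bleb at its neck, every proposed separation line must justify itself:

- both resulting fragments must reach the minimal area (`min_area_um2`);
- the intensity must genuinely drop across the line: for every line pixel a
  profile is sampled perpendicular to the local line direction (5-point
  window, 0.5 px steps) across a 3 µm subregion; the per-offset median over
  all line pixels forms a median profile, and the split is vetoed when its
  min/max ratio exceeds the cutoff (default 0.75). A ratio exactly at the
  cutoff retains the split; the median makes the measure robust to debris on
  the line.

Vetoed splits are merged back (multi-fragment proposals are evaluated in
ascending ratio order with iterative merging); accepted splits produce new
contours that are re-refined by the optimal-path stage.

## Validation metrics

Automatic contours *C* are scored against *K* ≥ 2 manual ground-truth contours
per nucleus:

- **AHD** — per observer, the directed average distance h(A,B) (mean over A's
  densely resampled points of the minimal distance to B) is symmetrized by
  max(h(C,GT), h(GT,C)) and averaged over observers (µm). Contours are
  resampled at ≤ 0.5 px spacing first so vertex density cannot bias the mean.
- **NSI** — non-overlapping area over summed area,
  (A + B − 2·I)/(A + B) on rasterized masks, averaged over observers;
  0 for identical regions, 1 for disjoint ones. The definition is taken in the
  form that makes identical contours score exactly 0.
- **Positive control** — the same two metrics averaged over all unordered
  observer pairs; this is the irreducible inter-observer disagreement. (With
  K = 3 the ordered-pair sum with a 1/6 prefactor equals the unordered-pair
  mean by symmetry; self-pairs are excluded, as including them would deflate
  the control by a third while adding no information.)
- **Integrated error** — mean of AHD/AHD_PC and NSI/NSI_PC. An error below 1
  means the automatic contour sits within inter-observer variability. Nuclei
  whose positive control is zero (identical observers) are flagged degenerate
  and excluded from summaries rather than dividing by zero.

Correspondence between detected contours and ground-truth nuclei is
established by maximal mask overlap with an optimal one-to-one assignment;
unmatched detections are reported, not scored.

## Features and classification

Per nucleus: area, perimeter, fitted-ellipse axes (from second-order central
moments), aspect ratio, circularity, solidity; total absolute boundary
curvature (contour resampled at 0.5 µm steps — below bleb scale, above pixel
noise — turning angles wrapped into (−π, π] and summed; 2π for convex
shapes); elliptic Fourier descriptors (Kuhl–Giardina line integrals on the
polygon, normalized for size, rotation and starting point; per-harmonic
amplitude √(a²+b²)+√(c²+d²); the *summed EFD* adds harmonics 2..20, since
harmonic 1 is the normalization ellipse); and gray-level co-occurrence texture
(64 levels over the per-nucleus intensity range, symmetric matrices at 0°,
45°, 90°, 135°, features averaged over angles: ASM, contrast, correlation,
homogeneity, entropy). Border-touching nuclei are excluded from feature
extraction by default because their shapes are truncated.

One property of the EFD deserves honesty: with the arc-length parameterization
of the reference formulation, a smooth but eccentric ellipse traversed at
constant speed retains small odd harmonics (≈ 0.01–0.05 of the summed score
for nucleus-like aspect ratios up to ~1.3), so "a plain ellipse scores ≈ 0"
holds exactly only for circles. Deformation scores of blebbed or lobed shapes
are several-fold larger, and the summed EFD rises strictly and monotonically
with protrusion amplitude, which is the property the ranking and the
classifier actually use.

Classification balances the two classes by downsampling the majority class,
splits 2/3 train / 1/3 test with preserved class ratios, z-scores features
with training-set parameters only, tunes hyperparameters by stratified
10-fold cross-validation on the training set (SVM-RBF: cost × kernel-width
grid; random forest: trees/variables-per-split), and reports the
misclassification rate plus the false-negative rate with *dysmorphic* as the
positive class — a false negative is a missed dysmorphic nucleus, the costly
mistake in screening. `retrain_from_labels()` grows the training table and
refits under the same protocol, supporting the iterative labeling workflow.
Exploratory `explore()` provides Ward clustering on Manhattan distances (as
configured — note Ward's method classically assumes squared Euclidean
distances; the report carries this caveat) and PCA with variance fractions
and loadings.

## The synthetic benchmark

Because the original microscopy datasets are not available in machine-usable
form, all quantitative claims are exercised on synthetic fields with known
ground truth (`standard_benchmark()`, fully determined by one seed):

- **Segmentation set** — 10 fields of 256² px at 0.25 µm/px, 10 nuclei each
  (50 normal, 50 dysmorphic in total). Nuclei are soft-edged ellipses (semi-
  axes 3.2–4.8 µm, bodies 120–220 intensity units over a background of 10,
  i.e. deliberately heterogeneous so that no single global threshold fits
  all), with blebs (radius 1–2.2 µm, 30–60% of body intensity, smooth
  junction, crevice grooves at the neck flanks), chromatin-ruffling intensity
  gradients, a 15% planar illumination gradient, Poisson noise and Gaussian
  read noise (σ 3). Three pseudo-observer ground truths are generated by
  perturbing each true contour with low-frequency radial noise (3–5 Fourier
  modes, 1–2 px), so the positive control is non-degenerate by construction.
- **Watershed battery** — 20 touching pairs whose contact valley is carved to
  a requested median-profile ratio (0.25–0.5; the generator calibrates the
  dip against the soft edges and background offset so the *measured* ratio
  matches the request within 0.05), and 20 blebbed singles whose neck is
  nearly isointense (ratio ≥ 0.85), rendered noise-free.
- **Classification set** — 160 normal + 160 dysmorphic single-nucleus fields;
  dysmorphic nuclei carry blebs and/or ruffling (about 30% are ruffled-only,
  i.e. shape-normal and separable only by texture). Features are extracted
  from the ground-truth contours so classifier performance is not confounded
  with segmentation performance.

What the generator does *not* emulate: optical point-spread blurring beyond a
soft edge, depth effects, debris and apoptotic fragments, mitotic figures,
densely packed colonies, or inter-image illumination drift. Green results here
show the algorithmic machinery behaves as designed under controlled
conditions; they do not certify performance on any particular microscope or
cell type — the validation module exists so users can measure that on their
own ground truth.

## Problem sizes and numerical choices

The shipped experiments use the sizes above (100 benchmark nuclei, 40
watershed cases, 320 classification nuclei, 200 random matrices for the
path-finder oracle, 10 bleb-recovery fields, 8 retraining replicates); the
whole acceptance script completes in about a minute on one core. The
retraining experiment starts from 20 labels and adds 20 per round against a
fixed 100-nucleus holdout — the steep part of the learning curve, where the
median across replicates declines monotonically on the standard benchmark;
once the curve flattens near its plateau, single-holdout-error fluctuations
can appear under other seeds, so the overall first-to-last decline is the
robust summary.

Other numerical decisions, collected: histogram thresholds use 256 bins on the
population range; hole filling is applied after each thresholding pass; seeds
touching the image border are kept but flagged, and flagged nuclei are
excluded from feature extraction by default; Voronoi assignment ties go to the
lower label; the watershed size criterion is applied before the decay
criterion (cheaper, same outcome); rank filters commute with monotone integer
rescaling; and all randomness in generators, splits and forests flows through
explicitly passed seeds with the caller's RNG state restored afterwards.

## A worked example

```{r example, eval = FALSE}
library(blebseg)

# render a small field with one blebbed nucleus and segment it
fr <- render_field(field_spec(
  size_px = c(160, 160), pixel_size_um = 0.25,
  nuclei = list(
    nucleus_spec(c(10, 10), c(3.6, 3.1), 0.4, 170),
    nucleus_spec(c(28, 12), c(3.2, 2.9), 1.3, 210,
                 blebs = list(list(neck_angle = 1.2, neck_width_um = 1,
                                   bleb_radius_um = 1.5,
                                   intensity_fraction = 0.4)),
                 class_label = "dysmorphic")),
  noise = list(gaussian_sd = 2, poisson = TRUE), seed = 61))

cfg <- pipeline_config(
  preprocess = preprocess_config(background_radius_um = 0,
                                 filter = "gaussian", filter_radius_um = 0.5),
  segment = twopass_config(min_seed_area_um2 = 5))
res <- run_pipeline(fr$image, cfg)
res$features[, c("nucleus_id", "area_um2", "circularity", "solidity",
                 "efd_sum")]
```

## Known limitations

- The refinement band cannot represent structures thinner than the pixel
  grid; crevices narrower than ~2 px are smoothed over.
- Non-star-shaped, deeply folded nuclei can defeat the self-intersection
  guard, in which case the initial (unrefined) contour is kept and flagged by
  a warning.
- The watershed separation line is ordered by projection on its principal
  axis, which assumes reasonably straight necks; strongly curved contact
  lines between three or more nuclei are evaluated pairwise.
- The classifier is only as good as its features; phenotypes expressed purely
  in sub-resolution texture will not be separable at the default 64-level
  quantization.
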