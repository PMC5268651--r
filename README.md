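# blebseg

Accurate segmentation and classification of **dysmorphic nuclei** —
blebbed, folded or lobulated nuclei typical of laminopathies, cancers and
some viral infections — in DNA-counterstained fluorescence microscopy
images. It is written for cell-biology and image-analysis groups who need
per-nucleus contours faithful enough to score subtle shape aberrations, a
quantitative way to compare automatic contours with manual ground truth,
and a classifier that flags dysmorphic nuclei for screening.

## What it does

Standard intensity thresholding fails on these images in two ways: no single
global threshold fits nuclei of heterogeneous brightness, and nuclear blebs
are often several-fold dimmer than the nuclear body, so they are assigned to
background. blebseg combines three ideas:

1. **Two-pass thresholding.** A global automatic threshold finds seed
   regions; each seed is dilated by at most 3 µm within its Voronoi cell
   (so neighbors cannot fuse); a second, *local* threshold computed from the
   pixels of each dilated region alone delineates the initial contour.
   Sixteen automatic threshold methods (Huang, Isodata, Li, Otsu, Triangle,
   Yen, ...) are available for either pass.

2. **Contour refinement by optimal path finding.** A 2 µm band around each
   initial contour is straightened (rows = normal offsets, columns = arc
   positions), edge-enhanced with a vertical Sobel kernel, and column-
   normalized so weak bleb edges count as much as bright body edges. A
   dynamic program then finds the left-to-right path maximizing the *path
   strength*

   *s* = gain / loss,

   where the gain sums the normalized edge responses along the path and the
   loss counts its cells; vertical runs of any height are allowed, so the
   path can turn up to 90° and trace the crevices around blebs. Because a
   ratio objective is not decomposable with one gain/loss pair per cell,
   the program is stratified by integer loss and computes the exact optimum
   (verified against exhaustive path enumeration). Refinement iterates until
   the contour stops moving, reaching crevices deeper than the band
   half-width.

3. **Conditional watershed.** Touching nuclei are split on the distance
   transform, but a split is accepted only if both fragments exceed a
   minimal area *and* the median intensity profile perpendicular to the
   separation line drops below a cutoff (min/max ratio ≤ 0.75 by default) —
   so genuine contact valleys are split while bleb necks are protected.

Around the core: validation metrics against multi-observer ground truth
(average Hausdorff distance, non-similarity index, positive-control scaling,
integrated error — error < 1 means the automatic contour is within
inter-observer variability); morpho-textural features (shape, total boundary
curvature, rotation-invariant elliptic Fourier descriptors, angle-averaged
gray-level co-occurrence texture); SVM/random-forest classification of
normal vs dysmorphic nuclei with balanced sampling, a stratified 2/3–1/3
split and 10-fold cross-validated tuning; and a synthetic image generator
that renders calibrated fields with known per-nucleus ground truth
(blebs, crevices, touching pairs with parametric valleys, chromocenters,
chromatin-ruffling gradients, uneven illumination, Poisson/Gaussian noise).

## A worked example

```r
library(blebseg)

# render a small calibrated field: one plain nucleus, one blebbed nucleus
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
res$features[, c("nucleus_id", "area_um2", "perimeter_um", "circularity",
                 "solidity", "efd_sum")]
#>   nucleus_id area_um2 perimeter_um circularity solidity efd_sum
#> 1          1     33.0         20.5       0.986     1.00  0.0961
#> 2          2     32.7         22.2       0.834     0.95  0.4436
```

The plain nucleus scores near-perfect circularity and solidity and a small
summed elliptic-Fourier deviation; the blebbed nucleus — same area — drops
in circularity and solidity and its summed EFD rises about four-fold, which
is exactly the signal the dysmorphy classifier feeds on.

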