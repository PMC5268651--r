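#' Two-pass segmentation configuration
#'
#' @param global_method threshold method for the image-level pass.
#' @param local_method threshold method applied per dilated seed region.
#' @param dilation_um conditional dilation distance in micrometers (default 3).
#' @param min_seed_area_um2 seeds smaller than this are discarded.
#' @return a `twopass_config` list.
#' @export
twopass_config <- function(global_method = "triangle", local_method = "mean",
                           dilation_um = 3, min_seed_area_um2 = 10) {
  stopifnot(dilation_um >= 0, min_seed_area_um2 >= 0)
  for (m in c(global_method, local_method))
    if (!m %in% threshold_methods()) stop("unknown threshold method '", m, "'")
  structure(list(global_method = global_method, local_method = local_method,
                 dilation_um = dilation_um,
                 min_seed_area_um2 = min_seed_area_um2),
            class = "twopass_config")
}

fill_holes <- function(bw) {
  f <- EBImage::fillHull(bw != 0)
  matrix(as.integer(f) != 0L, nrow(bw), ncol(bw))
}

# binary mask -> labeled, hole-filled, area-filtered components
components_from_binary <- function(bw, min_area_px = 0) {
  lab <- label8(fill_holes(bw))
  if (max(lab) > 0 && min_area_px > 0) {
    areas <- tabulate(lab[lab > 0], max(lab))
    drop <- which(areas < min_area_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
    keep <- sort(unique(lab[lab > 0]))
    lab[lab > 0] <- match(lab[lab > 0], keep)
  }
  lab
}

#' Global thresholding pass (seed detection)
#'
#' Thresholds the whole image with the configured global method; 8-connected
#' components of pixels at or above the threshold are hole-filled, filtered by
#' minimal seed area, and returned as `stage = "seed"` contours. Components
#' touching the image border are kept but flagged.
#'
#' @param image a preprocessed [calibrated_image()].
#' @param cfg a [twopass_config()].
#' @return list of seed [nucleus_contour()]s (possibly empty).
#' @export
global_pass <- function(image, cfg = twopass_config()) {
  px <- image$pixels
  v <- tryCatch(auto_threshold(px, cfg$global_method),
                error = function(e) Inf) # blank image: no seeds
  if (!is.finite(v)) return(list())
  min_px <- cfg$min_seed_area_um2 / image$pixel_size_um^2
  lab <- components_from_binary(px >= v, min_px)
  if (max(lab) == 0) return(list())
  mask_to_contours(lab, stage = "seed")
}

#' Voronoi-constrained conditional dilation of seed regions
#'
#' Each seed is grown by at most `dilation_um` of Euclidean distance and
#' intersected with its Voronoi cell, where assignment is by Euclidean
#' distance to the seed *region* (nearest-seed transform), so neighboring
#' regions can never merge. Ties on the bisector go to the lower label.
#'
#' @param seeds list of seed [nucleus_contour()]s, or a label mask.
#' @param image_shape raster shape `c(nrow, ncol)`.
#' @param dilation_um maximal growth distance in micrometers.
#' @param pixel_size_um micrometers per pixel.
#' @return dilated label mask; regions are pairwise disjoint and contain
#'   their seeds.
#' @export
conditional_dilate <- function(seeds, image_shape, dilation_um, pixel_size_um) {
  seed_mask <- if (is.matrix(seeds)) seeds else contours_to_mask(seeds, image_shape)
  ids <- sort(unique(seed_mask[seed_mask > 0]))
  if (!length(ids)) return(seed_mask)
  dil_px <- um_to_px(dilation_um, pixel_size_um)
  if (dil_px <= 0) return(seed_mask)
  dmin <- matrix(Inf, image_shape[1], image_shape[2])
  nearest <- matrix(0L, image_shape[1], image_shape[2])
  for (k in ids) {
    # distance from every pixel to seed region k
    d <- EBImage::distmap(matrix(as.numeric(seed_mask != k), image_shape[1],
                                 image_shape[2]))
    d <- matrix(as.numeric(d), image_shape[1], image_shape[2])
    closer <- d < dmin - 1e-9 # ties keep the lower (earlier) label
    dmin[closer] <- d[closer]
    nearest[closer] <- k
  }
  out <- matrix(0L, image_shape[1], image_shape[2])
  grow <- dmin <= dil_px + 1e-9
  out[grow] <- nearest[grow]
  out
}

#' Per-seed local thresholding pass
#'
#' For each dilated seed region a local threshold is computed from the pixel
#' population inside that region only; the largest thresholded component in
#' the region is kept and hole-filled, yielding `stage = "initial"` contours.
#' Regions with a degenerate (constant) histogram fall back to the global
#' threshold value.
#'
#' @param image a preprocessed [calibrated_image()].
#' @param dilated label mask from [conditional_dilate()].
#' @param cfg a [twopass_config()].
#' @param global_value fallback threshold (the global pass value).
#' @return list of initial [nucleus_contour()]s.
#' @export
local_threshold_pass <- function(image, dilated, cfg = twopass_config(),
                                 global_value = NULL) {
  px <- image$pixels
  if (is.null(global_value))
    global_value <- tryCatch(auto_threshold(px, cfg$global_method),
                             error = function(e) Inf)
  ids <- sort(unique(dilated[dilated > 0]))
  out <- matrix(0L, nrow(px), ncol(px))
  for (k in ids) {
    region <- dilated == k
    pop <- px[region]
    v <- tryCatch(auto_threshold(pop, cfg$local_method),
                  error = function(e) global_value)
    bw <- region & px >= v
    if (!any(bw)) next
    lab <- label8(bw)
    areas <- tabulate(lab[lab > 0], max(lab))
    big <- which.max(areas)
    comp <- fill_holes(lab == big)
    out[comp] <- k
  }
  if (max(out) == 0) return(list())
  mask_to_contours(out, stage = "initial")
}

#' Two-pass thresholding segmentation
#'
#' Global seed detection, conditional dilation constrained by Voronoi
#' tessellation, then per-seed local thresholding (the "initial ROI" stage).
#'
#' @param image a preprocessed [calibrated_image()].
#' @param cfg a [twopass_config()].
#' @return list with `seeds`, `dilated` (label mask), `contours` (initial
#'   ROIs) and `global_value`.
#' @export
two_pass_segment <- function(image, cfg = twopass_config()) {
  seeds <- global_pass(image, cfg)
  if (!length(seeds))
    return(list(seeds = seeds, dilated = matrix(0L, nrow(image$pixels),
                                                ncol(image$pixels)),
                contours = list(), global_value = NA_real_))
  gv <- auto_threshold(image$pixels, cfg$global_method)
  dil <- conditional_dilate(seeds, dim(image$pixels), cfg$dilation_um,
                            image$pixel_size_um)
  contours <- local_threshold_pass(image, dil, cfg, gv)
  list(seeds = seeds, dilated = dil, contours = contours, global_value = gv)
}
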