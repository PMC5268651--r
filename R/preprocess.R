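#' Preprocessing configuration
#'
#' Background correction and smoothing ahead of segmentation. Background
#' subtraction removes smooth illumination/background fields by grayscale
#' opening with a flat square window (top-hat); one optional filter is applied
#' afterwards, mirroring a single-choice filter step.
#'
#' @param background_radius_um scale of the background window in micrometers
#'   (0 disables background subtraction). Default 50.
#' @param filter one of `"none"`, `"gaussian"`, `"median"`, `"mean"`,
#'   `"min"`, `"max"`, `"variance"`.
#' @param filter_radius_um spatial scale of the filter in micrometers.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(background_radius_um = 50, filter = "none",
                              filter_radius_um = 1) {
  filters <- c("none", "gaussian", "median", "mean", "min", "max", "variance")
  if (!filter %in% filters)
    stop("unknown filter '", filter, "'; choose one of: ",
         paste(filters, collapse = ", "))
  if (background_radius_um < 0 || filter_radius_um < 0)
    stop("radii must be >= 0")
  structure(list(background_radius_um = background_radius_um,
                 filter = filter, filter_radius_um = filter_radius_um),
            class = "preprocess_config")
}

box_mean <- function(px, rad) {
  k <- matrix(1 / (2 * rad + 1)^2, 2 * rad + 1, 2 * rad + 1)
  EBImage::filter2(px, k, boundary = "replicate")
}

#' Preprocess a calibrated image
#'
#' @param image a [calibrated_image()].
#' @param cfg a [preprocess_config()]; the all-disabled configuration is the
#'   identity.
#' @return a [calibrated_image()] of the same shape and calibration with
#'   non-negative intensities.
#' @export
preprocess <- function(image, cfg = preprocess_config()) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- image$pixels
  ps <- image$pixel_size_um
  brad <- um_to_px(cfg$background_radius_um, ps)
  if (brad > 0) {
    # grayscale opening with replicate padding so border columns are not
    # clipped by the truncated window
    pad <- function(m, k) {
      m <- m[c(rep(1, k), seq_len(nrow(m)), rep(nrow(m), k)), , drop = FALSE]
      m[, c(rep(1, k), seq_len(ncol(m)), rep(ncol(m), k)), drop = FALSE]
    }
    pp <- pad(px, brad)
    bg <- win_extreme_cpp(win_extreme_cpp(pp, brad, FALSE), brad, TRUE)
    bg <- bg[brad + seq_len(nrow(px)), brad + seq_len(ncol(px)), drop = FALSE]
    px <- pmax(px - bg, 0)
  }
  frad <- um_to_px(cfg$filter_radius_um, ps)
  if (cfg$filter != "none" && frad > 0) {
    px <- switch(cfg$filter,
      gaussian = {
        out <- EBImage::gblur(px, sigma = frad)
        matrix(as.numeric(out), nrow(px), ncol(px))
      },
      median = {
        hi <- max(px)
        if (hi == 0) px
        else {
          out <- EBImage::medianFilter(px / hi, frad)
          matrix(as.numeric(out), nrow(px), ncol(px)) * hi
        }
      },
      mean = box_mean(px, frad),
      min = win_extreme_cpp(px, frad, FALSE),
      max = win_extreme_cpp(px, frad, TRUE),
      variance = {
        m <- box_mean(px, frad)
        pmax(box_mean(px^2, frad) - m^2, 0)
      })
  }
  calibrated_image(pmax(px, 0), pixel_size_um = ps, bit_depth = image$bit_depth)
}
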