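# Segmentation quality against multi-observer ground truth: average Hausdorff
# distance (AHD), non-similarity index (NSI), positive-control scaling and the
# integrated error.

densify <- function(contour, spacing_px = 0.5) {
  pts <- if (inherits(contour, "nucleus_contour")) contour$points else contour
  resample_contour(pts, spacing = spacing_px)
}

#' Directed average contour distance
#'
#' Mean, over the points of A, of the minimum Euclidean distance to the point
#' set of B (both densely resampled at <= 0.5 px spacing), in micrometers.
#' This is the directed component h(A, B) of the average Hausdorff distance.
#'
#' @param A,B [nucleus_contour()]s (or vertex matrices).
#' @param pixel_size_um micrometers per pixel.
#' @param spacing_px resampling density (default 0.5 px).
#' @return directed average distance in micrometers.
#' @export
directed_avg_distance <- function(A, B, pixel_size_um = 1, spacing_px = 0.5) {
  a <- densify(A, spacing_px); b <- densify(B, spacing_px)
  if (!nrow(a) || !nrow(b)) stop("empty contour")
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  mean(sqrt(apply(d2, 1, min))) * pixel_size_um
}

ahd_pair <- function(A, B, pixel_size_um, spacing_px = 0.5) {
  max(directed_avg_distance(A, B, pixel_size_um, spacing_px),
      directed_avg_distance(B, A, pixel_size_um, spacing_px))
}

#' Average Hausdorff distance to a set of ground-truth contours
#'
#' For each observer k the symmetrized directed distance
#' `max(h(C, GT_k), h(GT_k, C))` is computed; the mean over observers is
#' returned (micrometers).
#'
#' @param C detected [nucleus_contour()].
#' @param gts list of ground-truth contours matched to C (one per observer).
#' @param pixel_size_um micrometers per pixel.
#' @return AHD in micrometers.
#' @export
ahd <- function(C, gts, pixel_size_um = 1) {
  if (!length(gts)) stop("no ground-truth contour matched to nucleus ",
                         if (inherits(C, "nucleus_contour")) C$nucleus_id else "")
  mean(vapply(gts, function(g) ahd_pair(C, g, pixel_size_um), 1.0))
}

rasterize_pair <- function(A, B) {
  pa <- if (inherits(A, "nucleus_contour")) A$points else A
  pb <- if (inherits(B, "nucleus_contour")) B$points else B
  xr <- range(pa[, 1], pb[, 1]); yr <- range(pa[, 2], pb[, 2])
  cx <- floor(xr[1]):ceiling(xr[2]); cy <- floor(yr[1]):ceiling(yr[2])
  g <- expand.grid(x = cx, y = cy)
  list(a = point_in_polygon(g$x, g$y, pa), b = point_in_polygon(g$x, g$y, pb))
}

nsi_pair <- function(A, B) {
  m <- rasterize_pair(A, B)
  area_a <- sum(m$a); area_b <- sum(m$b)
  inter <- sum(m$a & m$b)
  tot <- area_a + area_b
  if (tot == 0) stop("zero total area in NSI computation")
  (tot - 2 * inter) / tot
}

#' Non-similarity index against ground-truth contours
#'
#' Per observer, NSI = non-overlapping area / summed area =
#' `(Area(C) + Area(GT) - 2 Area(C intersect GT)) / (Area(C) + Area(GT))`,
#' computed on rasterized masks; the mean over observers is returned.
#' 0 means identical regions, 1 disjoint regions.
#'
#' @param C detected [nucleus_contour()].
#' @param gts list of matched ground-truth contours (one per observer).
#' @return NSI in `[0, 1]`.
#' @export
nsi <- function(C, gts) {
  if (!length(gts)) stop("no ground-truth contour matched")
  mean(vapply(gts, function(g) nsi_pair(C, g), 1.0))
}

#' Inter-observer positive control for one nucleus
#'
#' Mean over all unordered observer pairs k != l of the pairwise AHD and NSI
#' (the ordered-pair sum with its 1/(K(K-1)) prefactor reduces to this by
#' symmetry). The positive control quantifies inter-observer variability and
#' is the scale for [scale_and_error()].
#'
#' @param gt a [ground_truth_set()] (K >= 2 observers).
#' @param nucleus_id nucleus to evaluate.
#' @param pixel_size_um micrometers per pixel.
#' @return list with `ahd_pc` (micrometers) and `nsi_pc`.
#' @export
positive_control <- function(gt, nucleus_id, pixel_size_um = 1) {
  K <- length(gt$contours_by_observer)
  if (K < 2) stop("positive control requires >= 2 observers")
  cts <- lapply(seq_len(K), function(k) gt_contour(gt, k, nucleus_id))
  pairs <- utils::combn(K, 2)
  av <- apply(pairs, 2, function(kl)
    c(ahd_pair(cts[[kl[1]]], cts[[kl[2]]], pixel_size_um),
      nsi_pair(cts[[kl[1]]], cts[[kl[2]]])))
  list(ahd_pc = mean(av[1, ]), nsi_pc = mean(av[2, ]))
}

#' Scale raw metrics to the positive control and integrate
#'
#' Scaled metrics are raw / positive-control componentwise; the integrated
#' error is their mean. An error below 1 means the automatic segmentation is
#' within inter-observer variability.
#'
#' @param raw list or vector with `ahd_raw` and `nsi_raw`.
#' @param pc list or vector with `ahd_pc` and `nsi_pc`.
#' @param nucleus_id identifier carried into the record.
#' @return a `validation_record` list with raw, pc, scaled components, the
#'   integrated `error`, and a `degenerate_pc` flag (set when a pc component
#'   is 0; such records are excluded from summaries).
#' @export
scale_and_error <- function(raw, pc, nucleus_id = 1L) {
  raw <- as.list(raw); pc <- as.list(pc)
  degen <- pc$ahd_pc == 0 || pc$nsi_pc == 0
  rec <- list(nucleus_id = as.integer(nucleus_id),
              ahd_raw = raw$ahd_raw, nsi_raw = raw$nsi_raw,
              ahd_pc = pc$ahd_pc, nsi_pc = pc$nsi_pc,
              ahd_scaled = if (degen) NA_real_ else raw$ahd_raw / pc$ahd_pc,
              nsi_scaled = if (degen) NA_real_ else raw$nsi_raw / pc$nsi_pc,
              degenerate_pc = degen)
  rec$error <- if (degen) NA_real_ else (rec$ahd_scaled + rec$nsi_scaled) / 2
  class(rec) <- "validation_record"
  rec
}

# overlap-pixel matrix between two contour lists on a common raster
overlap_matrix <- function(pred, gts, shape) {
  mp <- lapply(pred, function(ct) contours_to_mask(list(ct), shape) > 0)
  mg <- lapply(gts, function(ct) contours_to_mask(list(ct), shape) > 0)
  out <- matrix(0, length(pred), length(gts))
  for (i in seq_along(pred)) for (j in seq_along(gts))
    out[i, j] <- sum(mp[[i]] & mg[[j]])
  out
}

# maximal-overlap assignment (Hungarian via clue when available)
assign_overlap <- function(ov) {
  n <- nrow(ov); m <- ncol(ov)
  if (!n || !m) return(integer(0))
  if (requireNamespace("clue", quietly = TRUE)) {
    k <- max(n, m)
    pad <- matrix(0, k, k)
    pad[1:n, 1:m] <- ov
    sol <- as.integer(clue::solve_LSAP(pad, maximum = TRUE))[1:n]
    sol[sol > m] <- NA_integer_
  } else {
    sol <- rep(NA_integer_, n)
    o <- ov
    repeat {
      if (all(o <= 0)) break
      ij <- arrayInd(which.max(o), dim(o))
      sol[ij[1]] <- ij[2]
      o[ij[1], ] <- -1; o[, ij[2]] <- -1
    }
  }
  sol[!is.na(sol) & ov[cbind(seq_len(n), ifelse(is.na(sol), 1L, sol))] == 0] <- NA_integer_
  sol
}

#' Validate detected contours against multi-observer ground truth
#'
#' Matches detected contours to ground-truth nuclei by maximal mask overlap
#' (optimal assignment), computes per-nucleus AHD and NSI, scales them to the
#' inter-observer positive control and integrates the error.
#'
#' @param pred list of detected [nucleus_contour()]s.
#' @param gt a [ground_truth_set()].
#' @param shape raster shape `c(nrow, ncol)` used for overlap and NSI.
#' @param pixel_size_um micrometers per pixel.
#' @return data frame with one row per matched nucleus (unmatched detections
#'   are reported in the `unmatched` attribute, not scored).
#' @export
validate_segmentation <- function(pred, gt, shape, pixel_size_um = 1) {
  K <- length(gt$contours_by_observer)
  ids <- gt$nucleus_ids
  gt1 <- lapply(ids, function(id) gt_contour(gt, 1, id))
  ov <- overlap_matrix(pred, gt1, shape)
  sol <- assign_overlap(ov)
  rows <- list()
  for (i in seq_along(pred)) {
    j <- sol[i]
    if (is.na(j)) next
    id <- ids[j]
    gts <- lapply(seq_len(K), function(k) gt_contour(gt, k, id))
    raw <- list(ahd_raw = ahd(pred[[i]], gts, pixel_size_um),
                nsi_raw = nsi(pred[[i]], gts))
    pc <- positive_control(gt, id, pixel_size_um)
    rec <- scale_and_error(raw, list(ahd_pc = pc$ahd_pc, nsi_pc = pc$nsi_pc), id)
    rows[[length(rows) + 1]] <- as.data.frame(unclass(rec))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(nucleus_id = integer(0), ahd_raw = numeric(0),
               nsi_raw = numeric(0), ahd_pc = numeric(0), nsi_pc = numeric(0),
               ahd_scaled = numeric(0), nsi_scaled = numeric(0),
               degenerate_pc = logical(0), error = numeric(0))
  attr(out, "unmatched") <- which(is.na(sol))
  out
}
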