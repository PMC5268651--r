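#' @useDynLib blebseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median sd prcomp cutree hclust dist predict quantile rnorm runif rpois
#' @importFrom utils read.csv write.csv head modifyList
#' @importFrom grDevices chull
NULL

# ---- coordinate conventions -------------------------------------------------
# Pixels are matrices indexed [row, col]; 0-based image coordinates are
# x = col - 1, y = row - 1, with polygon vertices on pixel centers.
# Contours are stored with positive shoelace signed area ("counter-clockwise"
# in the x-right / y-down raster frame used throughout); the outward normal
# of an edge (dx, dy) under this orientation is (dy, -dx).

#' Convert a micrometer-valued parameter to whole pixels
#'
#' Single conversion routine used by every stage so that all micrometer
#' parameters discretize identically.
#'
#' @param value_um length in micrometers.
#' @param pixel_size_um micrometers per pixel (> 0, isotropic).
#' @return integer number of pixels, `round(value_um / pixel_size_um)`.
#' @export
um_to_px <- function(value_um, pixel_size_um) {
  stopifnot(pixel_size_um > 0)
  as.integer(round(value_um / pixel_size_um))
}

#' Calibrated intensity image
#'
#' A 2-D non-negative intensity raster with an isotropic spatial calibration,
#' the substrate of every pipeline stage.
#'
#' @param pixels numeric matrix (rows = y, columns = x), finite, >= 16 x 16.
#' @param pixel_size_um micrometers per pixel, > 0.
#' @param bit_depth source bit depth (informational).
#' @return an object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size_um = 1, bit_depth = 16L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (any(dim(pixels) < 16L))
    stop(sprintf("image too small (%d x %d); need at least 16 x 16",
                 nrow(pixels), ncol(pixels)))
  if (!all(is.finite(pixels))) stop("pixels must be finite")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 bit_depth = as.integer(bit_depth)),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("calibrated_image: %d x %d px, %.4g um/px, %d-bit\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$bit_depth))
  invisible(x)
}

signed_area <- function(points) {
  x <- points[, 1]; y <- points[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

polygon_area <- function(points) abs(signed_area(points))

polygon_perimeter <- function(points) {
  d <- points - points[c(2:nrow(points), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' Closed nucleus contour
#'
#' Ordered polygon in 0-based pixel coordinates representing one nucleus ROI.
#' Vertices are stored with positive signed area (one orientation convention
#' pipeline-wide); the polygon is implicitly closed.
#'
#' @param points n x 2 numeric matrix of (x, y) vertices, n >= 8.
#' @param stage lifecycle stage: `"seed"`, `"initial"` or `"refined"`.
#' @param nucleus_id integer identifier.
#' @param border_flag whether the underlying component touched the image edge.
#' @return an object of class `nucleus_contour`.
#' @export
nucleus_contour <- function(points, stage = c("seed", "initial", "refined"),
                            nucleus_id = 1L, border_flag = FALSE) {
  stage <- match.arg(stage)
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 8)
    stop("contour needs an n x 2 matrix with at least 8 vertices")
  if (!all(is.finite(points))) stop("contour vertices must be finite")
  a <- signed_area(points)
  if (a == 0) stop("degenerate contour: zero area")
  if (a < 0) points <- points[nrow(points):1, , drop = FALSE]
  structure(list(points = unname(points), stage = stage,
                 nucleus_id = as.integer(nucleus_id),
                 border_flag = isTRUE(border_flag)),
            class = "nucleus_contour")
}

#' @export
print.nucleus_contour <- function(x, ...) {
  cat(sprintf("nucleus_contour #%d (%s): %d vertices, area %.1f px^2\n",
              x$nucleus_id, x$stage, nrow(x$points), polygon_area(x$points)))
  invisible(x)
}

# Resample a closed polygon to n points equally spaced in arc length,
# starting at the first vertex.
resample_contour <- function(points, n = NULL, spacing = NULL) {
  pts <- rbind(points, points[1, , drop = FALSE])
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  per <- cum[length(cum)]
  if (per <= 0) stop("degenerate contour: zero perimeter")
  if (is.null(n)) n <- max(8L, as.integer(ceiling(per / spacing)))
  s <- seq(0, per, length.out = n + 1)[-(n + 1)]
  xi <- stats::approx(cum, pts[, 1], xout = s, ties = "ordered")$y
  yi <- stats::approx(cum, pts[, 2], xout = s, ties = "ordered")$y
  cbind(xi, yi, deparse.level = 0)
}

# Even-odd point-in-polygon test, vectorized over query points.
# Points exactly on an edge may land on either side; contours produced by
# mask tracing keep pixel centers strictly off the polygon boundary.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) * (xj - xi) / (yj - yi)
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
    j <- i
  }
  inside
}

#' Rasterize contours into a label mask
#'
#' Pixel-center-inside-polygon rasterization; label k is taken from each
#' contour's `nucleus_id`.
#'
#' @param contours list of [nucleus_contour()] objects.
#' @param shape integer vector `c(nrow, ncol)` of the target raster.
#' @return integer label matrix (0 = background).
#' @export
contours_to_mask <- function(contours, shape) {
  labels <- matrix(0L, shape[1], shape[2])
  overlaps <- integer(0)
  for (ct in contours) {
    poly <- ct$points
    xr <- range(poly[, 1]); yr <- range(poly[, 2])
    cx <- max(0L, floor(xr[1])):min(shape[2] - 1L, ceiling(xr[2]))
    cy <- max(0L, floor(yr[1])):min(shape[1] - 1L, ceiling(yr[2]))
    if (!length(cx) || !length(cy)) next
    g <- expand.grid(x = cx, y = cy)
    inside <- point_in_polygon(g$x, g$y, poly)
    idx <- cbind(g$y[inside] + 1L, g$x[inside] + 1L)
    prev <- labels[idx]
    if (any(prev != 0L))
      overlaps <- union(overlaps, c(ct$nucleus_id, unique(prev[prev != 0L])))
    labels[idx] <- ct$nucleus_id
  }
  if (length(overlaps))
    stop("overlapping contours for nucleus_ids: ",
         paste(sort(overlaps), collapse = ", "))
  labels
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge labels that
# touch diagonally with a union-find pass.
label8 <- function(bw) {
  lab <- EBImage::bwlabel(bw != 0)
  lab <- matrix(as.integer(lab), nrow(bw), ncol(bw))
  n <- max(lab)
  if (n < 2) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (dd in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[1:(nr - 1), if (dd[2] > 0) 1:(nc - 1) else 2:nc]
    b <- lab[2:nr,       if (dd[2] > 0) 2:nc       else 1:(nc - 1)]
    sel <- which(a > 0L & b > 0L & a != b)
    for (s in sel) {
      ra <- find(a[s]); rb <- find(b[s])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

# Trace the outer boundary of binary mask `bw` (single 8-connected component)
# along pixel cracks; returns vertices at half-integer 0-based coordinates so
# that pixel centers are strictly inside or outside the polygon.
trace_boundary <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  fg <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && bw[r, c] != 0
  start <- which(bw != 0, arr.ind = TRUE)
  if (!nrow(start)) stop("empty mask")
  o <- order(start[, 1], start[, 2])
  r0 <- start[o[1], 1]; c0 <- start[o[1], 2]
  # corners: corner (R, C) = top-left corner of pixel (R, C)
  # directions: 1 = E (+col), 2 = S (+row), 3 = W, 4 = N
  dirs <- list(c(0L, 1L), c(1L, 0L), c(0L, -1L), c(-1L, 0L))
  cr <- r0; cc <- c0; d <- 1L  # start at top-left corner of first pixel, going E
  verts_r <- numeric(0); verts_c <- numeric(0)
  repeat {
    verts_r <- c(verts_r, cr); verts_c <- c(verts_c, cc)
    nr2 <- cr + dirs[[d]][1]; nc2 <- cc + dirs[[d]][2]
    # pixels adjacent to the corner (nr2, nc2), relative to direction d:
    # left-ahead and right-ahead pixel of the next step
    pix <- switch(d,
      `1` = list(l = c(nr2 - 1L, nc2), r = c(nr2, nc2)),        # E: above / below
      `2` = list(l = c(nr2, nc2), r = c(nr2, nc2 - 1L)),        # S: right / left
      `3` = list(l = c(nr2, nc2 - 1L), r = c(nr2 - 1L, nc2 - 1L)), # W: below / above
      `4` = list(l = c(nr2 - 1L, nc2 - 1L), r = c(nr2 - 1L, nc2))) # N: left / right
    lfg <- fg(pix$l[1], pix$l[2]); rfg <- fg(pix$r[1], pix$r[2])
    cr <- nr2; cc <- nc2
    if (lfg) d <- (d + 2L) %% 4L + 1L          # turn left (8-connected fg)
    else if (rfg) d <- d                        # straight
    else d <- d %% 4L + 1L                      # turn right
    if (cr == r0 && cc == c0 && d == 1L) break
    if (length(verts_r) > 4L * (nr * nc + 4L)) stop("boundary tracing failed")
  }
  # corner (R, C) -> 0-based (x, y) = (C - 1.5, R - 1.5)
  cbind(verts_c - 1.5, verts_r - 1.5, deparse.level = 0)
}

# Remove collinear runs from a closed polygon.
simplify_collinear <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  if (n < 4) return(pts)
  prev <- pts[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- pts[c(2:n, 1), , drop = FALSE]
  v1 <- pts - prev; v2 <- nxt - pts
  cross <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  keep <- abs(cross) > tol
  if (sum(keep) < 3) keep <- rep(TRUE, n)
  pts[keep, , drop = FALSE]
}

#' Extract per-label contours from a label mask
#'
#' Traces the outer boundary of each labeled component along pixel cracks so
#' that `contours_to_mask(mask_to_contours(m), dim(m))` reproduces `m` exactly.
#'
#' @param mask integer label matrix.
#' @param stage lifecycle stage assigned to the contours.
#' @return list of [nucleus_contour()] objects (one per positive label).
#' @export
mask_to_contours <- function(mask, stage = "seed") {
  ids <- sort(unique(mask[mask > 0]))
  nr <- nrow(mask); nc <- ncol(mask)
  lapply(ids, function(k) {
    bw <- mask == k
    raw <- trace_boundary(bw)
    pts <- simplify_collinear(raw)
    if (nrow(pts) < 8) pts <- raw
    while (nrow(pts) < 8) { # tiny components: subdivide edges
      nxt <- pts[c(2:nrow(pts), 1), , drop = FALSE]
      pts <- matrix(rbind(t(pts), t((pts + nxt) / 2)), ncol = 2, byrow = TRUE)
    }
    border <- any(bw[1, ]) || any(bw[nr, ]) || any(bw[, 1]) || any(bw[, nc])
    nucleus_contour(pts, stage = stage, nucleus_id = k, border_flag = border)
  })
}

# micrometer pixel size from TIFF resolution attributes (or NULL if absent)
pixel_size_from_info <- function(info) {
  xr <- info$x.resolution; yr <- info$y.resolution
  if (is.null(xr) || !is.finite(xr) || xr <= 0) return(NULL)
  if (!is.null(yr) && is.finite(yr) && yr > 0 && abs(xr - yr) > 1e-6 * xr)
    stop(sprintf("anisotropic pixels unsupported (x.resolution %g != y.resolution %g)",
                 xr, yr))
  unit <- info$resolution.unit
  per_unit_um <- if (identical(unit, "inch") || identical(unit, 2L)) 25400
                 else 10000  # centimeters (TIFF default "cm"), also used when unitless
  per_unit_um / xr
}

#' Read a single-channel image with spatial calibration
#'
#' Reads a 2-D grayscale TIFF (or PNG for fixtures). The pixel size is taken
#' from TIFF resolution metadata, overridden by `pixel_size_override`; when
#' neither is available, 1 um/px is assumed with a warning.
#'
#' @param path file path (.tif/.tiff/.png).
#' @param pixel_size_override optional micrometers per pixel, wins over metadata.
#' @return a [calibrated_image()].
#' @export
read_image <- function(path, pixel_size_override = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, info = TRUE, as.is = TRUE)
    info <- attributes(px)
    bits <- if (!is.null(info$bits.per.sample)) as.integer(info$bits.per.sample) else 16L
  } else if (ext == "png") {
    px <- png::readPNG(path)
    info <- list()
    bits <- 8L
    px <- px * (2^bits - 1)
  } else stop("unsupported image format: .", ext)
  d <- dim(px)
  if (length(d) != 2)
    stop(sprintf("expected single channel 2-D image, got shape %s",
                 paste(d, collapse = " x ")))
  ps <- pixel_size_override
  if (is.null(ps)) ps <- pixel_size_from_info(info)
  if (is.null(ps)) {
    warning("no pixel size metadata in ", basename(path), "; assuming 1.0 um/px")
    ps <- 1.0
  }
  calibrated_image(matrix(as.numeric(px), d[1], d[2]), pixel_size_um = ps,
                   bit_depth = bits)
}

contours_to_df <- function(contours) {
  if (!length(contours))
    return(data.frame(nucleus_id = integer(0), vertex_index = integer(0),
                      x = numeric(0), y = numeric(0), stage = character(0)))
  do.call(rbind, lapply(contours, function(ct)
    data.frame(nucleus_id = ct$nucleus_id,
               vertex_index = seq_len(nrow(ct$points)),
               x = ct$points[, 1], y = ct$points[, 2], stage = ct$stage)))
}

df_to_contours <- function(df) {
  lapply(split(df, df$nucleus_id), function(d) {
    d <- d[order(d$vertex_index), ]
    nucleus_contour(cbind(d$x, d$y), stage = as.character(d$stage[1]),
                    nucleus_id = d$nucleus_id[1])
  })
}

#' Write segmentation results to disk
#'
#' Writes the label mask as a 16-bit TIFF, contour vertices and the per-nucleus
#' table as CSV files with headers.
#'
#' @param contours list of [nucleus_contour()] objects.
#' @param table per-nucleus feature/metric data frame (may have zero rows).
#' @param out_dir output directory (created if needed).
#' @param shape raster shape `c(nrow, ncol)` for the label mask.
#' @return invisibly, the paths written.
#' @export
write_results <- function(contours, table, out_dir, shape) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("unwritable directory: ", out_dir)
  mask <- contours_to_mask(contours, shape)
  mask_path <- file.path(out_dir, "labels.tif")
  tiff::writeTIFF(mask / 65535, mask_path, bits.per.sample = 16L)
  contour_path <- file.path(out_dir, "contours.csv")
  write.csv(contours_to_df(contours), contour_path, row.names = FALSE)
  table_path <- file.path(out_dir, "table.csv")
  write.csv(table, table_path, row.names = FALSE)
  invisible(c(mask = mask_path, contours = contour_path, table = table_path))
}

#' Read a label mask written by [write_results()]
#' @param path path to a 16-bit label TIFF.
#' @return integer label matrix.
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Ground-truth contour sets from multiple observers
#'
#' @param contours_by_observer list (length K >= 2) of lists of
#'   [nucleus_contour()]; nucleus correspondence across observers is by
#'   `nucleus_id`.
#' @return object of class `ground_truth_set`.
#' @export
ground_truth_set <- function(contours_by_observer) {
  k <- length(contours_by_observer)
  if (k < 2) stop("ground truth requires at least 2 observers")
  ids <- lapply(contours_by_observer, function(obs)
    sort(vapply(obs, function(ct) ct$nucleus_id, 1L)))
  for (i in 2:k)
    if (!identical(ids[[1]], ids[[i]]))
      stop("observers disagree on nucleus_ids present")
  structure(list(contours_by_observer = contours_by_observer,
                 nucleus_ids = ids[[1]]), class = "ground_truth_set")
}

gt_contour <- function(gt, observer, nucleus_id) {
  obs <- gt$contours_by_observer[[observer]]
  for (ct in obs) if (ct$nucleus_id == nucleus_id) return(ct)
  stop("no ground truth for nucleus_id ", nucleus_id, " (observer ", observer, ")")
}

# evaluate expr with a temporarily seeded RNG, restoring global state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
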