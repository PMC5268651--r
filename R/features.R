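# Morpho-textural features of segmented nuclei: standard shape descriptors,
# total boundary curvature, rotation-invariant elliptic Fourier descriptors
# and angle-averaged gray-level co-occurrence texture.

#' Standard shape features of a nucleus contour
#'
#' Area (shoelace), perimeter, fitted-ellipse axes (from second-order central
#' moments of the rasterized region), aspect ratio, circularity
#' (`4 pi A / P^2`) and solidity (area / convex-hull area), all in micrometer
#' units.
#'
#' @param contour a [nucleus_contour()].
#' @param pixel_size_um micrometers per pixel.
#' @return named list of shape features.
#' @export
shape_features <- function(contour, pixel_size_um = 1) {
  pts <- contour$points
  A_px <- polygon_area(pts)
  P_px <- polygon_perimeter(pts)
  if (A_px <= 0 || P_px <= 0) stop("degenerate polygon")
  hull <- pts[chull(pts), , drop = FALSE]
  A_hull <- polygon_area(hull)
  # ellipse with matching second-order central moments of the filled region
  xr <- range(pts[, 1]); yr <- range(pts[, 2])
  ox <- floor(xr[1]); oy <- floor(yr[1])
  cx <- ox:ceiling(xr[2]); cy <- oy:ceiling(yr[2])
  g <- expand.grid(x = cx, y = cy)
  inside <- point_in_polygon(g$x, g$y, pts)
  xs <- g$x[inside]; ys <- g$y[inside]
  if (length(xs) < 4) { xs <- pts[, 1]; ys <- pts[, 2] }
  cv <- stats::cov.wt(cbind(xs, ys), method = "ML")$cov
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  semi_major <- 2 * sqrt(ev[1]); semi_minor <- 2 * sqrt(ev[2])
  ps <- pixel_size_um
  list(area_um2 = A_px * ps^2,
       perimeter_um = P_px * ps,
       ellipse_major_um = 2 * semi_major * ps,
       ellipse_minor_um = 2 * semi_minor * ps,
       aspect_ratio = if (semi_minor > 0) semi_major / semi_minor else NA_real_,
       circularity = min(1, 4 * pi * A_px / P_px^2),
       solidity = min(1, A_px / A_hull))
}

#' Total absolute boundary curvature
#'
#' The contour is resampled at a fixed arc step; the total curvature is the
#' sum of absolute turning angles between consecutive segments (wrapped into
#' `(-pi, pi]`). Convex shapes give 2*pi; boundary lobes and blebs add turning.
#'
#' @param contour a [nucleus_contour()].
#' @param pixel_size_um micrometers per pixel.
#' @param step_um resampling arc step (default 0.5 um).
#' @return total curvature in radians (>= 2*pi for simple closed contours).
#' @export
total_curvature <- function(contour, pixel_size_um = 1, step_um = 0.5) {
  pts <- contour$points
  per_um <- polygon_perimeter(pts) * pixel_size_um
  if (per_um < 4 * step_um) stop("contour too short for curvature step")
  n <- max(8L, as.integer(round(per_um / step_um)))
  rs <- resample_contour(pts, n = n)
  seg <- rs[c(2:n, 1), , drop = FALSE] - rs
  th <- atan2(seg[, 2], seg[, 1])
  dth <- diff(c(th, th[1]))
  dth <- ((dth + pi) %% (2 * pi)) - pi
  sum(abs(dth))
}

# Kuhl-Giardina elliptic Fourier coefficients of a closed polygon
# (piecewise-linear, exact line integrals); rows n = 1..H of (a, b, c, d).
efd_coefficients <- function(pts, n_harmonics) {
  dxy <- pts[c(2:nrow(pts), 1), , drop = FALSE] - pts
  dt <- sqrt(rowSums(dxy^2))
  keep <- dt > 0
  dxy <- dxy[keep, , drop = FALSE]; dt <- dt[keep]
  t <- c(0, cumsum(dt)); T <- t[length(t)]
  phi <- 2 * pi * t / T
  co <- matrix(0, n_harmonics, 4)
  for (n in seq_len(n_harmonics)) {
    cn <- cos(n * phi); sn <- sin(n * phi)
    dcos <- diff(cn); dsin <- diff(sn)
    k <- T / (2 * n^2 * pi^2)
    co[n, 1] <- k * sum(dxy[, 1] / dt * dcos)
    co[n, 2] <- k * sum(dxy[, 1] / dt * dsin)
    co[n, 3] <- k * sum(dxy[, 2] / dt * dcos)
    co[n, 4] <- k * sum(dxy[, 2] / dt * dsin)
  }
  co
}

#' Rotation-invariant elliptic Fourier descriptors
#'
#' Kuhl-Giardina coefficients normalized for size (first-harmonic semi-major
#' axis), starting point and rotation. Per-harmonic amplitude is
#' `sqrt(a^2 + b^2) + sqrt(c^2 + d^2)`; the summed EFD over harmonics 2..H
#' scores deviation from a plain ellipse (a smooth ellipse scores ~0, blebs
#' and lobes raise it).
#'
#' @param contour a [nucleus_contour()].
#' @param n_harmonics number of harmonics H (default 20).
#' @return list with `amplitudes` (length H) and `efd_sum` (sum over n >= 2).
#' @export
efd_features <- function(contour, n_harmonics = 20) {
  pts <- contour$points
  if (nrow(pts) < 3 * n_harmonics)
    pts <- resample_contour(pts, n = 3 * n_harmonics)
  co <- efd_coefficients(pts, n_harmonics)
  a1 <- co[1, 1]; b1 <- co[1, 2]; c1 <- co[1, 3]; d1 <- co[1, 4]
  # starting-point phase of the first harmonic
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
  for (n in seq_len(n_harmonics)) {
    rot <- matrix(c(cos(n * theta), sin(n * theta),
                    -sin(n * theta), cos(n * theta)), 2, 2)
    m <- matrix(co[n, ], 2, 2, byrow = TRUE) %*% rot
    co[n, ] <- as.numeric(t(m))
  }
  # spatial rotation of the first semi-major axis
  psi <- atan2(co[1, 3], co[1, 1])
  R <- matrix(c(cos(psi), -sin(psi), sin(psi), cos(psi)), 2, 2)
  for (n in seq_len(n_harmonics)) {
    m <- R %*% matrix(co[n, ], 2, 2, byrow = TRUE)
    co[n, ] <- as.numeric(t(m))
  }
  scale <- abs(co[1, 1])
  if (scale == 0) stop("degenerate contour for EFD normalization")
  co <- co / scale
  amp <- sqrt(co[, 1]^2 + co[, 2]^2) + sqrt(co[, 3]^2 + co[, 4]^2)
  list(amplitudes = amp, efd_sum = sum(amp[-1]))
}

#' Angle-averaged gray-level co-occurrence texture features
#'
#' Intensities inside the mask are quantized to `levels` gray levels over the
#' in-mask min-max range; symmetric normalized co-occurrence matrices are
#' accumulated at 0, 45, 90 and 135 degrees (both pixels inside the mask) and
#' ASM, contrast, correlation, IDM (homogeneity) and entropy (bits) are
#' averaged over the four angles. A constant patch returns entropy 0, ASM 1,
#' contrast 0.
#'
#' @param image a [calibrated_image()] (or numeric matrix).
#' @param mask logical/0-1 matrix selecting the nucleus pixels (>= 64 px).
#' @param levels number of gray levels (default 64).
#' @param distance_px co-occurrence offset in pixels (default 1).
#' @return named list: `glcm_asm`, `glcm_contrast`, `glcm_correlation`,
#'   `glcm_idm`, `glcm_entropy`.
#' @export
glcm_features <- function(image, mask, levels = 64, distance_px = 1) {
  px <- if (inherits(image, "calibrated_image")) image$pixels else image
  mk <- mask != 0
  if (sum(mk) < 64) stop("mask must cover at least 64 pixels")
  vals <- px[mk]
  rng <- range(vals)
  qz <- matrix(NA_integer_, nrow(px), ncol(px))
  if (rng[2] > rng[1]) {
    qz[mk] <- pmin(as.integer(floor((px[mk] - rng[1]) / (rng[2] - rng[1]) * levels)),
                   levels - 1L) + 1L
  } else qz[mk] <- 1L
  d <- as.integer(distance_px)
  offsets <- list(c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d)) # 0,45,90,135 deg
  nr <- nrow(px); nc <- ncol(px)
  feats <- matrix(NA_real_, 4, 5)
  for (oi in seq_along(offsets)) {
    dr <- offsets[[oi]][1]; dc <- offsets[[oi]][2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    A <- qz[r1, c1, drop = FALSE]
    B <- qz[r1 + dr, c1 + dc, drop = FALSE]
    sel <- !is.na(A) & !is.na(B)
    if (!any(sel)) next
    tab <- matrix(0, levels, levels)
    counts <- table(factor(A[sel], levels = 1:levels),
                    factor(B[sel], levels = 1:levels))
    tab <- tab + counts + t(counts) # symmetric
    p <- tab / sum(tab)
    i <- matrix(1:levels, levels, levels)
    j <- t(i)
    mu_i <- sum(i * p); mu_j <- sum(j * p)
    sd_i <- sqrt(sum((i - mu_i)^2 * p)); sd_j <- sqrt(sum((j - mu_j)^2 * p))
    corr <- if (sd_i > 0 && sd_j > 0)
      sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j) else 0
    pe <- p[p > 0]
    feats[oi, ] <- c(sum(p^2), sum((i - j)^2 * p), corr,
                     sum(p / (1 + (i - j)^2)), -sum(pe * log2(pe)))
  }
  f <- colMeans(feats, na.rm = TRUE)
  list(glcm_asm = f[1], glcm_contrast = f[2], glcm_correlation = f[3],
       glcm_idm = f[4], glcm_entropy = f[5])
}

#' Feature extraction configuration
#' @param n_harmonics EFD harmonics (default 20).
#' @param glcm_levels GLCM gray levels (default 64).
#' @param curvature_step_um curvature resampling step (default 0.5).
#' @param include_border include border-flagged nuclei (default FALSE).
#' @return a `feature_config` list.
#' @export
feature_config <- function(n_harmonics = 20, glcm_levels = 64,
                           curvature_step_um = 0.5, include_border = FALSE) {
  structure(list(n_harmonics = n_harmonics, glcm_levels = glcm_levels,
                 curvature_step_um = curvature_step_um,
                 include_border = include_border), class = "feature_config")
}

#' Extract the full morpho-textural feature table
#'
#' One row per nucleus with shape, curvature, EFD and GLCM features. Nuclei
#' flagged as touching the image border are excluded by default (truncated
#' shapes would distort the shape features).
#'
#' @param image a [calibrated_image()].
#' @param contours list of [nucleus_contour()]s.
#' @param cfg a [feature_config()].
#' @param labels optional named/ordered class labels (one per contour).
#' @return data frame of features, with `nucleus_id` and `border_flag`.
#' @export
extract_all <- function(image, contours, cfg = feature_config(), labels = NULL) {
  rows <- list()
  for (ci in seq_along(contours)) {
    ct <- contours[[ci]]
    if (ct$border_flag && !cfg$include_border) {
      message("excluding border nucleus ", ct$nucleus_id)
      next
    }
    sf <- shape_features(ct, image$pixel_size_um)
    tc <- total_curvature(ct, image$pixel_size_um, cfg$curvature_step_um)
    ef <- efd_features(ct, cfg$n_harmonics)
    mask <- contours_to_mask(list(ct), dim(image$pixels)) > 0
    gl <- glcm_features(image, mask, cfg$glcm_levels)
    row <- c(list(nucleus_id = ct$nucleus_id, border_flag = ct$border_flag),
             sf, list(total_curvature_rad = tc, efd_sum = ef$efd_sum), gl)
    if (!is.null(labels)) row$class <- labels[[ci]]
    rows[[length(rows) + 1]] <- as.data.frame(row)
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Z-score feature columns
#' @param df feature data frame.
#' @param exclude columns to leave untouched.
#' @return list with `scaled` data frame, `center`, `scale`.
#' @export
scale_features <- function(df, exclude = c("nucleus_id", "border_flag", "class")) {
  num <- setdiff(names(df)[vapply(df, is.numeric, TRUE)], exclude)
  ctr <- vapply(df[num], mean, 1.0)
  scl <- vapply(df[num], sd, 1.0)
  scl[scl == 0 | !is.finite(scl)] <- 1
  out <- df
  for (k in num) out[[k]] <- (df[[k]] - ctr[k]) / scl[k]
  list(scaled = out, center = ctr, scale = scl)
}
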