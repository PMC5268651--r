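# Synthetic fluorescence images of DNA-counterstained nuclei with per-nucleus
# ground truth: ovoid bodies, dim blebs attached through smooth necks with
# crevices, touching pairs with a parametric intensity valley, chromocenters,
# intensity gradients (chromatin ruffling), uneven illumination and
# Poisson/Gaussian noise. All randomness flows from the field seed.

#' Specification of one synthetic nucleus
#'
#' @param center_um (x, y) center in micrometers.
#' @param semi_axes_um ellipse semi-axes (a, b) in micrometers.
#' @param orientation_rad ellipse orientation.
#' @param body_intensity peak body intensity (arbitrary units).
#' @param blebs list of blebs, each
#'   `list(neck_angle, neck_width_um, bleb_radius_um, intensity_fraction)`;
#'   bleb intensity is `intensity_fraction * body_intensity` (<= 1, blebs are
#'   typically dimmer than the body) and the junction is smooth with a
#'   crevice dip at its flanks.
#' @param ruffling_gradient linear intensity gradient fraction across the
#'   nucleus (0 = none), emulating chromatin ruffling.
#' @param chromocenters `list(count, radius_um, boost)` bright intranuclear
#'   spots, or NULL.
#' @param class_label `"normal"` or `"dysmorphic"`.
#' @return a `nucleus_spec` list.
#' @export
nucleus_spec <- function(center_um, semi_axes_um, orientation_rad = 0,
                         body_intensity = 180, blebs = list(),
                         ruffling_gradient = 0, chromocenters = NULL,
                         class_label = "normal") {
  for (b in blebs)
    if (b$intensity_fraction <= 0 || b$intensity_fraction > 1)
      stop("bleb intensity_fraction must lie in (0, 1]")
  structure(list(center_um = center_um, semi_axes_um = semi_axes_um,
                 orientation_rad = orientation_rad,
                 body_intensity = body_intensity, blebs = blebs,
                 ruffling_gradient = ruffling_gradient,
                 chromocenters = chromocenters,
                 class_label = match.arg(class_label, c("normal", "dysmorphic"))),
            class = "nucleus_spec")
}

#' Specification of one synthetic field
#'
#' @param size_px image size `c(nrow, ncol)`.
#' @param pixel_size_um micrometers per pixel (default 0.25).
#' @param nuclei list of [nucleus_spec()]s.
#' @param touching_pairs list of `list(pair = c(i, j), valley_ratio)`: the two
#'   nuclei share a boundary whose perpendicular median-profile min/max ratio
#'   equals `valley_ratio` (before noise).
#' @param illumination planar illumination gradient amplitude (fraction).
#' @param noise `list(gaussian_sd, poisson)`.
#' @param background background intensity level (default 10).
#' @param seed RNG seed for all stochastic elements.
#' @return a `field_spec` list.
#' @export
field_spec <- function(size_px = c(256, 256), pixel_size_um = 0.25,
                       nuclei = list(), touching_pairs = list(),
                       illumination = 0, noise = list(gaussian_sd = 2,
                                                      poisson = TRUE),
                       background = 10, seed = 1L) {
  structure(list(size_px = size_px, pixel_size_um = pixel_size_um,
                 nuclei = nuclei, touching_pairs = touching_pairs,
                 illumination = illumination, noise = noise,
                 background = background, seed = as.integer(seed)),
            class = "field_spec")
}

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# render one nucleus onto intensity/mask matrices (in place via return)
render_nucleus <- function(I, M, spec, k, ps, edge_um = 0.3) {
  nr <- nrow(I); nc <- ncol(I)
  a <- spec$semi_axes_um[1]; b <- spec$semi_axes_um[2]
  reach_um <- max(a, b) +
    if (length(spec$blebs)) max(vapply(spec$blebs, function(x)
      2 * x$bleb_radius_um, 1.0)) else 0
  cx <- spec$center_um[1] / ps; cy <- spec$center_um[2] / ps
  rpx <- ceiling((reach_um + 2 * edge_um) / ps) + 2
  xs <- max(0, floor(cx - rpx)):min(nc - 1, ceiling(cx + rpx))
  ys <- max(0, floor(cy - rpx)):min(nr - 1, ceiling(cy + rpx))
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE) * ps
  Y <- matrix(ys, length(ys), length(xs)) * ps
  dx <- X - spec$center_um[1]; dy <- Y - spec$center_um[2]
  co <- cos(spec$orientation_rad); si <- sin(spec$orientation_rad)
  u <- dx * co + dy * si; v <- -dx * si + dy * co
  rho <- sqrt((u / a)^2 + (v / b)^2)
  dist_um <- (1 - rho) * min(a, b)               # approx signed distance
  body_in <- smoothstep(dist_um / edge_um + 0.5) # soft edge
  body_mask <- rho <= 1
  intensity <- spec$body_intensity * body_in
  if (spec$ruffling_gradient > 0) {
    g <- spec$ruffling_gradient
    s <- pmin(pmax((u / a + 1) / 2, 0), 1)
    intensity <- intensity * (1 - g / 2 + g * s)
  }
  mask <- body_mask
  for (bl in spec$blebs) {
    ang <- bl$neck_angle
    bp <- c(a * cos(ang), b * sin(ang))            # attachment point (frame)
    nrm <- c(cos(ang) / a, sin(ang) / b)
    nrm <- nrm / sqrt(sum(nrm^2))
    bc <- bp + nrm * bl$bleb_radius_um * 0.6       # bleb center, overlaps body
    db <- sqrt((u - bc[1])^2 + (v - bc[2])^2)
    bleb_in <- smoothstep((bl$bleb_radius_um - db) / (edge_um * 0.7) + 0.5)
    bleb_mask <- db <= bl$bleb_radius_um
    # smooth junction: the bleb envelope is continuous with the body, so its
    # intensity blends gradually towards the body over ~1.2 um; only the
    # bleb's outer rim is a sharp edge
    blend <- smoothstep((dist_um + 0.2) / 1.2)     # 1 well inside the body
    bleb_int <- spec$body_intensity *
      (bl$intensity_fraction + (1 - bl$intensity_fraction) * blend) * bleb_in
    intensity <- pmax(intensity, bleb_int)
    mask <- mask | bleb_mask
    # crevice: dark groove along the body boundary at the junction flanks,
    # strictly outside the bleb footprint (the indentation where the contour
    # dips in on either side of the neck)
    ang_pt <- atan2(v / b, u / a)
    dang <- abs(((ang_pt - ang + pi) %% (2 * pi)) - pi)
    bleb_ang <- bl$bleb_radius_um / sqrt(a * b)
    crev <- abs(dist_um) < 0.35 & dang > 0.9 * bleb_ang &
      dang < bleb_ang + bl$neck_width_um / sqrt(a * b) & db > bl$bleb_radius_um
    dip <- 1 - 0.55 * exp(-(dist_um / 0.25)^2)
    intensity[crev] <- intensity[crev] * dip[crev]
  }
  if (!is.null(spec$chromocenters) && spec$chromocenters$count > 0) {
    for (ci in seq_len(spec$chromocenters$count)) {
      pu <- runif(1, -0.5, 0.5) * a; pv <- runif(1, -0.5, 0.5) * b
      dcc <- sqrt((u - pu)^2 + (v - pv)^2)
      intensity <- intensity *
        (1 + spec$chromocenters$boost * exp(-(dcc / spec$chromocenters$radius_um)^2))
    }
  }
  ridx <- ys + 1; cidx <- xs + 1
  patchI <- I[ridx, cidx]
  prevM <- M[ridx, cidx]
  clash <- prevM > 0L & mask
  I[ridx, cidx] <- pmax(patchI, intensity)
  newM <- prevM
  newM[mask & prevM == 0L] <- k
  M[ridx, cidx] <- newM
  list(I = I, M = M, clash_with = unique(prevM[clash]))
}

#' Render a synthetic field
#'
#' Deterministic given the spec seed. The ground-truth mask assigns bleb
#' pixels to their parent nucleus; declared touching pairs share a boundary
#' along the perpendicular bisector of their centers, with an intensity
#' valley whose median perpendicular-profile min/max ratio equals the
#' requested `valley_ratio` (within ~0.05 before noise).
#'
#' @param spec a [field_spec()].
#' @return list with `image` ([calibrated_image()]), `mask` (label matrix)
#'   and `labels` (data frame: nucleus_id, class_label).
#' @export
render_field <- function(spec) {
  with_seed(spec$seed, {
    nr <- spec$size_px[1]; nc <- spec$size_px[2]
    ps <- spec$pixel_size_um
    I <- matrix(0, nr, nc)
    M <- matrix(0L, nr, nc)
    pair_of <- integer(length(spec$nuclei))
    for (tp in spec$touching_pairs) {
      pair_of[tp$pair[1]] <- tp$pair[2]
      pair_of[tp$pair[2]] <- tp$pair[1]
    }
    for (k in seq_along(spec$nuclei)) {
      res <- render_nucleus(I, M, spec$nuclei[[k]], k, ps)
      clash <- setdiff(res$clash_with, c(0L, pair_of[k]))
      if (length(clash))
        stop("undeclared nucleus overlap: ", k, " with ",
             paste(clash, collapse = ", "))
      I <- res$I; M <- res$M
    }
    # touching pairs: resolve shared pixels by bisector side + carve valley
    for (tp in spec$touching_pairs) {
      i <- tp$pair[1]; j <- tp$pair[2]
      ci <- spec$nuclei[[i]]$center_um; cj <- spec$nuclei[[j]]$center_um
      dirv <- cj - ci; dirv <- dirv / sqrt(sum(dirv^2))
      midp <- (ci + cj) / 2
      sel <- which(M == i | M == j)
      rr <- (sel - 1) %% nr; cc <- (sel - 1) %/% nr
      d <- ((cc * ps) - midp[1]) * dirv[1] + ((rr * ps) - midp[2]) * dirv[2]
      M[sel] <- ifelse(d < 0, i, j)
      sigma <- 0.5 # um; flanks recover within the 1.5 um profile half-width
      # choose the dip depth so the *final* median-profile min/max ratio
      # (background added below; soft ellipse edges already lower the
      # intensity at the contact) equals the requested valley_ratio
      b <- spec$nuclei[[i]]$body_intensity
      at_line <- abs(d) < 0.3
      i_line <- if (any(at_line)) median(I[sel][at_line]) else b
      f0 <- min(1, max(0, (tp$valley_ratio * (b + spec$background) -
                             spec$background) / max(i_line, 1e-6)))
      I[sel] <- I[sel] * (1 - (1 - f0) * exp(-(d / sigma)^2))
    }
    I <- I + spec$background
    if (spec$illumination > 0) {
      plane <- matrix(seq(0, 1, length.out = nc), nr, nc, byrow = TRUE)
      I <- I * (1 - spec$illumination / 2 + spec$illumination * plane)
    }
    if (isTRUE(spec$noise$poisson)) I <- matrix(rpois(nr * nc, pmax(I, 0)),
                                                nr, nc)
    if (spec$noise$gaussian_sd > 0)
      I <- I + matrix(rnorm(nr * nc, 0, spec$noise$gaussian_sd), nr, nc)
    I <- pmax(I, 0)
    labels <- data.frame(
      nucleus_id = seq_along(spec$nuclei),
      class_label = vapply(spec$nuclei, function(n) n$class_label, ""))
    list(image = calibrated_image(I, pixel_size_um = ps), mask = M,
         labels = labels)
  })
}

#' Perturb a contour with smooth radial noise (pseudo-observer ground truth)
#'
#' Adds low-frequency radial displacement (3-5 Fourier modes) of the given
#' amplitude, emulating inter-observer delineation variability.
#'
#' @param contour a [nucleus_contour()].
#' @param amplitude_px displacement amplitude in pixels (default 1.5).
#' @param n_modes number of Fourier modes (default sampled in 3:5).
#' @return perturbed [nucleus_contour()].
#' @export
perturb_contour <- function(contour, amplitude_px = 1.5, n_modes = NULL) {
  pts <- resample_contour(contour$points, n = max(64, nrow(contour$points)))
  n <- nrow(pts)
  ctr <- colMeans(pts)
  if (is.null(n_modes)) n_modes <- sample(3:5, 1)
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  disp <- rep(0, n)
  for (m in seq_len(n_modes))
    disp <- disp + rnorm(1, 0, 1) * cos((m + 1) * t + runif(1, 0, 2 * pi))
  disp <- disp / max(abs(disp)) * amplitude_px * runif(1, 0.7, 1)
  rad <- pts - matrix(ctr, n, 2, byrow = TRUE)
  rl <- sqrt(rowSums(rad^2)); rl[rl == 0] <- 1
  out <- pts + rad / rl * disp
  nucleus_contour(out, stage = contour$stage, nucleus_id = contour$nucleus_id,
                  border_flag = contour$border_flag)
}

random_nucleus <- function(center_um, class_label, body_range = c(120, 220),
                           radius_range = c(3.2, 4.8), bleb_fraction = c(0.3, 0.6),
                           ruffled_share = 0.3) {
  a <- runif(1, radius_range[1], radius_range[2])
  b <- a * runif(1, 0.75, 1)
  blebs <- list()
  ruff <- 0
  if (class_label == "dysmorphic") {
    ruffled_only <- runif(1) < ruffled_share
    if (ruffled_only) {
      ruff <- runif(1, 0.35, 0.6)
    } else {
      nb <- sample(1:2, 1)
      angs <- runif(1, 0, 2 * pi) + seq(0, by = 2.5, length.out = nb)
      blebs <- lapply(seq_len(nb), function(i)
        list(neck_angle = angs[i] %% (2 * pi),
             neck_width_um = runif(1, 0.8, 1.4),
             bleb_radius_um = runif(1, 1.0, 2.2),
             intensity_fraction = runif(1, bleb_fraction[1], bleb_fraction[2])))
      if (runif(1) < 0.3) ruff <- runif(1, 0.2, 0.4)
    }
  }
  nucleus_spec(center_um = center_um, semi_axes_um = c(a, b),
               orientation_rad = runif(1, 0, pi),
               body_intensity = runif(1, body_range[1], body_range[2]),
               blebs = blebs, ruffling_gradient = ruff,
               class_label = class_label)
}

#' Build the standard synthetic benchmark
#'
#' Deterministic given `seed`. Emits (a) segmentation fields totalling 50
#' dysmorphic + 50 normal nuclei with 3 pseudo-observer ground-truth contour
#' sets; (b) a watershed battery of 20 touching pairs (valley ratio <= 0.5)
#' and 20 blebbed singles (neck ratio >= 0.85); (c) a 160 + 160 classification
#' set; plus a manifest of seeds and parameters.
#'
#' @param seed integer master seed.
#' @param out_dir optional directory; when given, images/masks/contours and
#'   the manifest JSON are written there.
#' @return list with `segmentation`, `watershed`, `classification`, `manifest`.
#' @export
standard_benchmark <- function(seed = 1L, out_dir = NULL) {
  seed <- as.integer(seed)
  params <- list(pixel_size_um = 0.25, fields = 10, nuclei_per_field = 10,
                 observers = 3, gt_amplitude_px = c(1.0, 2.0),
                 watershed_pairs = 20, watershed_singles = 20,
                 classification_per_class = 160)
  ps <- params$pixel_size_um

  # (a) segmentation fields: 10 fields x 10 nuclei, half dysmorphic
  fields <- lapply(seq_len(params$fields), function(f) {
    fseed <- seed * 1000L + f
    classes <- rep(c("normal", "dysmorphic"), each = 5)
    spec <- with_seed(fseed, {
      classes <- sample(classes)
      centers <- expand.grid(gx = 1:4, gy = 1:3)[1:10, ]
      nuclei <- lapply(1:10, function(k) {
        cx <- (centers$gx[k] - 0.5) * 64 + runif(1, -5, 5)
        cy <- (centers$gy[k] - 0.5) * 85 + runif(1, -5, 5)
        random_nucleus(c(cx, cy) * ps, classes[k])
      })
      field_spec(size_px = c(256, 256), pixel_size_um = ps, nuclei = nuclei,
                 illumination = 0.15,
                 noise = list(gaussian_sd = 3, poisson = TRUE),
                 seed = fseed + 500L)
    })
    fr <- render_field(spec)
    true_contours <- mask_to_contours(fr$mask, stage = "refined")
    gt_obs <- with_seed(fseed + 900L, lapply(1:params$observers, function(o)
      lapply(true_contours, function(ct)
        perturb_contour(ct, amplitude_px = runif(1, params$gt_amplitude_px[1],
                                                 params$gt_amplitude_px[2])))))
    list(spec = spec, image = fr$image, mask = fr$mask, labels = fr$labels,
         gt = ground_truth_set(gt_obs))
  })

  # (b) watershed battery
  make_pair <- function(valley, cseed) {
    spec <- with_seed(cseed, {
      a <- runif(1, 3.0, 3.8)
      body <- runif(1, 150, 200)
      gap <- 0.93 * 2 * a
      cx <- (96 * ps) / 2
      n1 <- nucleus_spec(c(cx - gap / 2, 12), c(a, a * 0.9), 0,
                         body_intensity = body)
      n2 <- nucleus_spec(c(cx + gap / 2, 12), c(a, a * 0.9), 0,
                         body_intensity = body)
      field_spec(size_px = c(96, 96), pixel_size_um = ps,
                 nuclei = list(n1, n2),
                 touching_pairs = list(list(pair = c(1L, 2L),
                                            valley_ratio = valley)),
                 noise = list(gaussian_sd = 0, poisson = FALSE),
                 seed = cseed)
    })
    c(render_field(spec), list(kind = "touching_pair", valley_ratio = valley))
  }
  make_single <- function(cseed) {
    spec <- with_seed(cseed, {
      a <- runif(1, 3.0, 3.8)
      bl <- list(neck_angle = runif(1, 0, 2 * pi), neck_width_um = 0.9,
                 bleb_radius_um = runif(1, 1.6, 2.2),
                 intensity_fraction = runif(1, 0.93, 1.0))
      n <- nucleus_spec(c(12, 12), c(a, a * 0.9), runif(1, 0, pi),
                        body_intensity = runif(1, 150, 200), blebs = list(bl))
      field_spec(size_px = c(96, 96), pixel_size_um = ps, nuclei = list(n),
                 noise = list(gaussian_sd = 0, poisson = FALSE), seed = cseed)
    })
    c(render_field(spec), list(kind = "blebbed_single"))
  }
  valleys <- with_seed(seed + 77L, runif(params$watershed_pairs, 0.25, 0.5))
  ws_cases <- c(
    lapply(seq_len(params$watershed_pairs), function(i)
      make_pair(valleys[i], seed * 100L + 3000L + i)),
    lapply(seq_len(params$watershed_singles), function(i)
      make_single(seed * 100L + 4000L + i)))

  # (c) classification set: single-nucleus fields, features from GT contours
  cls_specs <- lapply(seq_len(2 * params$classification_per_class), function(i) {
    cl <- if (i <= params$classification_per_class) "normal" else "dysmorphic"
    cseed <- seed * 10L + 50000L + i
    with_seed(cseed, {
      n <- random_nucleus(c(12, 12), cl)
      if (runif(1) < 0.4)
        n$chromocenters <- list(count = sample(2:4, 1),
                                radius_um = 0.5, boost = 0.5)
      field_spec(size_px = c(96, 96), pixel_size_um = ps, nuclei = list(n),
                 noise = list(gaussian_sd = 3, poisson = TRUE),
                 seed = cseed + 1L)
    })
  })

  manifest <- list(seed = seed, parameters = params,
                   field_seeds = vapply(fields, function(f) f$spec$seed, 1L),
                   valley_ratios = round(valleys, 6))
  bench <- list(segmentation = fields, watershed = ws_cases,
                classification = cls_specs, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (f in seq_along(fields)) {
      tiff::writeTIFF(fields[[f]]$image$pixels / max(fields[[f]]$image$pixels),
                      file.path(out_dir, sprintf("field_%02d.tif", f)),
                      bits.per.sample = 16L)
      write.csv(contours_to_df(mask_to_contours(fields[[f]]$mask)),
                file.path(out_dir, sprintf("field_%02d_gt.csv", f)),
                row.names = FALSE)
    }
  }
  bench
}

#' Analytic bleb-amplitude contour family
#'
#' Closed contours of an ovoid nucleus carrying one protrusion of increasing
#' amplitude (0 to `max_protrusion_um`), used to relate summed elliptic
#' Fourier descriptors to deformation severity. Contours are analytic (no
#' rasterization), so shape scores reflect the protrusion only.
#'
#' @param n_steps number of family members (default 10).
#' @param max_protrusion_um largest protrusion amplitude (default 3).
#' @param semi_axes_um nucleus semi-axes (default 5 x 4.2, a ~10 um nucleus).
#' @param pixel_size_um micrometers per pixel for the returned coordinates.
#' @return list of [nucleus_contour()]s ordered by protrusion amplitude.
#' @export
bleb_shape_family <- function(n_steps = 10, max_protrusion_um = 3,
                              semi_axes_um = c(5, 4.2), pixel_size_um = 0.25) {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  a <- semi_axes_um[1]; b <- semi_axes_um[2]
  r_ell <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  amps <- seq(0, max_protrusion_um, length.out = n_steps)
  lapply(seq_len(n_steps), function(i) {
    bump <- amps[i] * exp(-((th - pi / 3)^2) / (2 * 0.35^2))
    r <- (r_ell + bump) / pixel_size_um
    ctr <- (max(r) + 4)
    nucleus_contour(cbind(ctr + r * cos(th), ctr + r * sin(th)),
                    stage = "refined", nucleus_id = i)
  })
}

#' Extract the benchmark classification feature table
#'
#' Renders each single-nucleus classification field and extracts features
#' from the ground-truth contour, isolating classifier performance from
#' segmentation.
#'
#' @param bench a [standard_benchmark()] result.
#' @param cfg a [feature_config()].
#' @return data frame of features with a `class` column.
#' @export
benchmark_features <- function(bench, cfg = feature_config()) {
  rows <- lapply(bench$classification, function(spec) {
    fr <- render_field(spec)
    cts <- mask_to_contours(fr$mask, stage = "refined")
    extract_all(fr$image, cts, cfg, labels = fr$labels$class_label)
  })
  do.call(rbind, rows)
}
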