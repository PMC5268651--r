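# Shared fixture builders and independent oracles.

# image with one or more disks on a dark background
disk_image <- function(shape = c(96, 96), disks = list(list(c(48, 48), 20)),
                       fg = 150, bg = 10, pixel_size = 0.25) {
  g <- expand.grid(x = 0:(shape[2] - 1), y = 0:(shape[1] - 1))
  px <- matrix(bg, shape[1], shape[2])
  for (d in disks) {
    sel <- (g$x - d[[1]][1])^2 + (g$y - d[[1]][2])^2 <= d[[2]]^2
    px[cbind(g$y[sel] + 1, g$x[sel] + 1)] <- fg
  }
  calibrated_image(px, pixel_size_um = pixel_size)
}

circle_contour <- function(center = c(48, 48), radius = 20, n = 128,
                           stage = "initial", id = 1L) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  nucleus_contour(cbind(center[1] + radius * cos(th),
                        center[2] + radius * sin(th)),
                  stage = stage, nucleus_id = id)
}

square_contour <- function(x0, y0, side, n_per_edge = 8, id = 1L,
                           stage = "seed") {
  s <- seq(0, side, length.out = n_per_edge + 1)[-(n_per_edge + 1)]
  pts <- rbind(cbind(x0 + s, y0),
               cbind(x0 + side, y0 + s),
               cbind(x0 + side - s, y0 + side),
               cbind(x0, y0 + side - s))
  nucleus_contour(pts, stage = stage, nucleus_id = id)
}

# independent brute-force path enumerator for the OPF (same step semantics,
# written against the path-sum definition rather than any recursion)
opf_enumerate <- function(N) {
  q <- nrow(N); r <- ncol(N)
  paths <- as.matrix(expand.grid(rep(list(1:q), r)))
  Cm <- apply(N, 2, cumsum)
  g <- N[cbind(paths[, 1], 1)]
  l <- rep(1, nrow(paths))
  for (j in 2:r) {
    i <- paths[, j]; k <- paths[, j - 1]
    Cj <- c(0, Cm[, j - 1])
    segs <- ifelse(i < k, Cj[k] - Cj[i],
                   ifelse(i > k, Cj[i + 1] - Cj[k + 1], 0))
    g <- g + segs + N[cbind(i, j)]
    l <- l + abs(i - k) + 1
  }
  s <- g / l
  list(strengths = s, paths = paths, best = max(s))
}

random_normalized_matrix <- function(q, r) {
  N <- matrix(runif(q * r), q, r)
  sweep(N, 2, apply(N, 2, max), "/")
}

# one blebbed-nucleus field (dim bleb on brighter body)
bleb_field <- function(seed, intensity_fraction = 0.3, noise_sd = 2) {
  blebseg:::with_seed(seed, {
    bl <- list(neck_angle = runif(1, 0, 2 * pi),
               neck_width_um = runif(1, 0.9, 1.3),
               bleb_radius_um = runif(1, 1.2, 2.0),
               intensity_fraction = intensity_fraction)
    n <- nucleus_spec(c(12, 12), c(runif(1, 3.2, 4.2), runif(1, 3.0, 3.8)),
                      runif(1, 0, pi), body_intensity = runif(1, 150, 210),
                      blebs = list(bl), class_label = "dysmorphic")
    field_spec(size_px = c(96, 96), pixel_size_um = 0.25, nuclei = list(n),
               noise = list(gaussian_sd = noise_sd, poisson = noise_sd > 0),
               seed = seed + 1L)
  })
}

expect_no_na <- function(df) expect_false(anyNA(df))
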