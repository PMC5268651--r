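test_that("straightened bands have the documented geometry", {
  img <- calibrated_image(matrix(7, 128, 128), 0.25)
  ct <- circle_contour(c(64, 64), 20)
  band <- straighten_band(img, ct, 1)
  q <- nrow(band$values); r <- ncol(band$values)
  expect_equal(q, 2 * um_to_px(1, 0.25) + 1)
  expect_gte(r, 32)
  expect_equal(r, max(32, round(polygon_perimeter(ct$points))))
  # constant image -> constant band
  expect_equal(max(abs(band$values - 7)), 0, tolerance = 1e-9)
})

test_that("radially symmetric images give identical band columns", {
  g <- expand.grid(x = 0:127, y = 0:127)
  rr <- sqrt((g$x - 64)^2 + (g$y - 64)^2)
  px <- matrix(0, 128, 128)
  px[cbind(g$y + 1, g$x + 1)] <- 200 * exp(-((rr - 20) / 6)^2)
  img <- calibrated_image(px, 0.25)
  band <- straighten_band(img, circle_contour(c(64, 64), 20, n = 256), 1)
  spread <- apply(band$values, 1, function(row) max(row) - min(row))
  expect_lt(max(spread), 1e-2 * max(band$values))
})

test_that("a disk edge crosses half intensity at the middle band row", {
  img <- disk_image(shape = c(128, 128), disks = list(list(c(64, 64), 20)),
                    fg = 100, bg = 0)
  band <- straighten_band(img, circle_contour(c(64, 64), 20), 1)
  q <- nrow(band$values)
  mid <- (q + 1) / 2
  crossings <- apply(band$values, 2, function(col) {
    below <- which(col < 50)
    if (!length(below)) return(NA_real_)
    min(below)
  })
  expect_true(all(abs(crossings - mid) <= 1.5, na.rm = TRUE))
  # inner rows bright, outer rows dark
  expect_true(all(band$values[1, ] > 90))
  expect_true(all(band$values[q, ] < 10))
})

test_that("edge derivative is signed for bright-inside transitions", {
  mkband <- function(vals) {
    q <- length(vals)
    structure(list(values = matrix(vals, q, 40),
                   anchors = list(x = 1:40, y = 1:40, nx = rep(1, 40),
                                  ny = rep(0, 40)),
                   half_width_um = 1, pixel_size_um = 0.25),
              class = "straightened_band")
  }
  const <- edge_derivative(mkband(rep(5, 9)))
  expect_equal(max(abs(const$values)), 0)
  step <- edge_derivative(mkband(c(rep(100, 4), 50, rep(0, 4))))
  expect_gt(max(step$values[4:6, ]), 0)
  expect_equal(max(step$values[c(1, 9), ]), 0)
  inverted <- edge_derivative(mkband(c(rep(0, 4), 50, rep(100, 4))))
  expect_equal(max(inverted$values), 0) # clamped
})

test_that("column normalization maps to [0, 1] with zero-safe columns", {
  expect_equal(normalize_columns(matrix(c(2, 4), 2, 1)), matrix(c(0.5, 1), 2, 1))
  expect_equal(normalize_columns(matrix(0, 3, 2)), matrix(0, 3, 2))
  expect_equal(normalize_columns(matrix(c(3, 5, 2), 1, 3)),
               matrix(1, 1, 3))
  set.seed(4)
  P <- matrix(runif(60), 6, 10)
  N <- normalize_columns(P)
  expect_true(all(N >= 0 & N <= 1))
  expect_true(all(abs(apply(N, 2, max) - 1) < 1e-12))
  expect_error(normalize_columns(matrix(-1, 2, 2)), "non-negative")
})

test_that("degenerate optimal-path shapes behave", {
  # single row: path is that row, strength is the running mean
  N <- matrix(c(0.2, 0.8, 0.5), 1, 3)
  pm <- optimal_path(N)
  expect_equal(pm$path, rep(1L, 3))
  expect_equal(pm$strength, mean(N))
  # dominant row attracts the whole path
  N2 <- matrix(0, 5, 8); N2[2, ] <- 1
  pm2 <- optimal_path(N2)
  expect_equal(pm2$path, rep(2L, 8))
  expect_equal(pm2$strength, 1)
  expect_error(optimal_path(matrix(0.5, 3, 0)), "empty|columns")
})

test_that("dynamic program equals exhaustive enumeration on random instances", {
  set.seed(123)
  for (t in 1:100) {
    q <- sample(2:5, 1); r <- sample(2:7, 1)
    N <- random_normalized_matrix(q, r)
    pm <- optimal_path(N)
    en <- opf_enumerate(N)
    expect_lt(abs(pm$strength - en$best), 1e-12)
    # the DP path itself attains the enumeration optimum
    hit <- which(apply(en$paths, 1, function(p) all(p == pm$path)))
    expect_lt(abs(en$strengths[hit] - en$best), 1e-12)
    # S = G / L wherever L > 0
    expect_lt(max(abs(pm$S - pm$G / pm$L)), 1e-12)
  }
})

test_that("path strength is invariant to rescaling single raw columns", {
  set.seed(9)
  for (t in 1:10) {
    P <- matrix(runif(35), 5, 7)
    j <- sample(7, 1)
    P2 <- P; P2[, j] <- P2[, j] * runif(1, 0.1, 10)
    a <- optimal_path(normalize_columns(P))
    b <- optimal_path(normalize_columns(P2))
    expect_lt(abs(a$strength - b$strength), 1e-12)
    expect_equal(a$path, b$path)
  }
})

test_that("reconstruction maps paths back through the band anchors", {
  img <- disk_image(shape = c(128, 128), disks = list(list(c(64, 64), 20)),
                    fg = 100, bg = 0)
  ct <- circle_contour(c(64, 64), 20, n = 160)
  band <- straighten_band(img, ct, 1)
  q <- nrow(band$values); r <- ncol(band$values); mid <- (q + 1) / 2
  # identity path reproduces the contour
  same <- reconstruct_contour(rep(mid, r), band)
  d <- sqrt(rowSums((blebseg:::resample_contour(same$points, n = 64) -
                       blebseg:::resample_contour(ct$points, n = 64))^2))
  expect_lt(max(d), 0.5)
  # +2 rows everywhere -> circle of radius + 2 px
  out <- reconstruct_contour(rep(mid + 2, r), band)
  rr <- sqrt(rowSums(sweep(out$points, 2, c(64, 64))^2))
  expect_equal(mean(rr), 22, tolerance = 0.2)
  expect_equal(out$stage, "refined")
  # inward dip across 10 columns reduces the enclosed area
  dip <- rep(mid, r); dip[20:29] <- mid - 3
  dipped <- reconstruct_contour(dip, band)
  expect_lt(polygon_area(dipped$points), polygon_area(same$points))
})

test_that("refinement is a fixed point on a clean hard edge", {
  img <- disk_image(shape = c(128, 128), disks = list(list(c(64, 64), 20)),
                    fg = 150, bg = 5)
  res <- refine(img, circle_contour(c(64, 64), 20), refine_config())
  expect_lte(res$n_iterations, 2)
  expect_true(res$converged)
  rr <- sqrt(rowSums(sweep(res$contour$points, 2, c(64, 64))^2))
  expect_lt(sqrt(mean((rr - 20)^2)), 1) # within 1 px RMSD of the true edge
})

test_that("refinement never moves a vertex beyond the band half-width", {
  img <- disk_image(shape = c(128, 128), disks = list(list(c(64, 64), 20)),
                    fg = 150, bg = 5)
  ct <- circle_contour(c(64, 64), 23)
  step <- blebseg:::refine_once(img, ct, 1)
  hw_px <- um_to_px(1, img$pixel_size_um)
  expect_lte(step$displacement_px, hw_px + 1e-9)
  # one iteration cannot reach an edge 3 px away, but it moves toward it
  rr <- sqrt(rowSums(sweep(step$contour$points, 2, c(64, 64))^2))
  expect_lt(mean(rr), 23)
})

test_that("refining an oversized contour on a blebbed nucleus lowers NSI", {
  fr <- render_field(bleb_field(303, noise_sd = 1))
  img <- fr$image
  gt_ct <- mask_to_contours(fr$mask, stage = "refined")[[1]]
  start <- nucleus_contour(
    blebseg:::resample_contour(perturb_contour_free <- {
      ctr <- colMeans(gt_ct$points)
      sweep(sweep(gt_ct$points, 2, ctr), 1, 1.12, "*") +
        matrix(ctr, nrow(gt_ct$points), 2, byrow = TRUE)
    }, n = 128), stage = "initial")
  gts <- list(gt_ct)
  nsi0 <- nsi(start, gts)
  ref <- refine(img, start, refine_config())$contour
  nsi1 <- nsi(ref, gts)
  expect_lt(nsi1, 0.5 * nsi0)
})

test_that("deep crevices need more than one refinement cycle", {
  # crevice deeper than the 1 um band half-width: a 2 um inward wedge
  ps <- 0.25
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  r_um <- 4 - 2 * exp(-((th - pi)^2) / (2 * 0.3^2)) # 2 um deep notch
  g <- expand.grid(x = 0:127, y = 0:127)
  ang <- atan2(g$y - 64, g$x - 64); ang[ang < 0] <- ang[ang < 0] + 2 * pi
  rad <- sqrt((g$x - 64)^2 + (g$y - 64)^2) * ps
  r_at <- approx(th, r_um, xout = ang, rule = 2)$y
  px <- matrix(5, 128, 128)
  px[cbind(g$y + 1, g$x + 1)] <- ifelse(rad <= r_at, 160, 5)
  img <- calibrated_image(px, ps)
  start <- circle_contour(c(64, 64), 4 / ps, n = 128) # smooth start, no notch
  gt_mask <- matrix(0L, 128, 128)
  gt_mask[px > 50] <- 1L
  gt_ct <- mask_to_contours(gt_mask, stage = "refined")[[1]]
  one <- refine(img, start, refine_config(max_iterations = 1))$contour
  three <- refine(img, start, refine_config(max_iterations = 4))$contour
  nsi1 <- nsi(one, list(gt_ct)); nsi3 <- nsi(three, list(gt_ct))
  expect_lt(nsi3, nsi1)
})
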