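test_that("shape features match closed forms on reference shapes", {
  circ <- circle_contour(c(40, 40), 40, n = 512) # radius 10 um at 0.25 um/px
  sf <- shape_features(circ, 0.25)
  expect_gte(sf$circularity, 0.99)
  expect_gte(sf$solidity, 0.99)
  expect_equal(sf$area_um2, pi * 100, tolerance = 0.01 * pi * 100)
  expect_equal(sf$ellipse_major_um, 20, tolerance = 0.6)
  expect_equal(sf$aspect_ratio, 1, tolerance = 0.02)
  sq <- square_contour(10, 10, 20)
  sfq <- shape_features(sq, 1)
  expect_equal(sfq$circularity, pi / 4, tolerance = 0.01)
  # a starred polygon is less solid than its convex hull
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  star <- nucleus_contour(cbind(40 + (15 + 4 * cos(6 * th)) * cos(th),
                                40 + (15 + 4 * cos(6 * th)) * sin(th)))
  expect_lt(shape_features(star, 1)$solidity, 0.95)
})

test_that("shape features are translation invariant and scale correctly", {
  base <- perturb_contour_fixture <- circle_contour(c(30, 30), 10, n = 128)
  sf1 <- shape_features(base, 1)
  moved <- nucleus_contour(sweep(base$points, 2, c(13.7, -4.2), "+"),
                           stage = base$stage)
  sf2 <- shape_features(moved, 1)
  expect_equal(sf1$area_um2, sf2$area_um2, tolerance = 1e-9)
  expect_equal(sf1$perimeter_um, sf2$perimeter_um, tolerance = 1e-9)
  scaled <- nucleus_contour(base$points * 2)
  sf3 <- shape_features(scaled, 1)
  expect_equal(sf3$area_um2 / sf1$area_um2, 4, tolerance = 0.02)
  expect_equal(sf3$perimeter_um / sf1$perimeter_um, 2, tolerance = 0.01)
})

test_that("total curvature is 2*pi for convex contours and larger for lobed", {
  expect_equal(total_curvature(circle_contour(c(30, 30), 12, n = 256), 1),
               2 * pi, tolerance = 0.01 * 2 * pi)
  ell <- nucleus_contour({
    th <- seq(0, 2 * pi, length.out = 257)[-257]
    cbind(40 + 16 * cos(th), 40 + 9 * sin(th))
  })
  expect_equal(total_curvature(ell, 1), 2 * pi, tolerance = 0.01 * 2 * pi)
  # 6 sinusoidal lobes of 1 um amplitude on an ellipse: exceeds 2*pi and
  # matches a dense finite-difference turning integral within 2%
  th <- seq(0, 2 * pi, length.out = 2049)[-2049]
  r <- 10 + 1 * cos(6 * th)
  lobed_pts <- cbind(30 + r * cos(th), 30 + r * sin(th))
  lobed <- nucleus_contour(lobed_pts)
  tc <- total_curvature(lobed, 1, step_um = 0.5)
  expect_gt(tc, 2 * pi)
  dense <- blebseg:::resample_contour(lobed_pts, spacing = 0.05)
  seg <- dense[c(2:nrow(dense), 1), ] - dense
  thd <- atan2(seg[, 2], seg[, 1])
  dth <- diff(c(thd, thd[1]))
  oracle <- sum(abs(((dth + pi) %% (2 * pi)) - pi))
  expect_equal(tc, oracle, tolerance = 0.02 * oracle)
  expect_error(total_curvature(circle_contour(c(5, 5), 0.2), 1), "too short")
})

test_that("EFD normalization concentrates smooth shapes in harmonic 1", {
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  circ <- nucleus_contour(cbind(50 + 15 * cos(th), 50 + 15 * sin(th)))
  expect_lt(efd_features(circ)$efd_sum, 0.001)
  # constant-speed traversal of an eccentric ellipse leaves small odd
  # harmonics; nucleus-like ovals stay well below deformed shapes
  ell <- nucleus_contour(cbind(50 + 20 * cos(th + 0.4), 50 + 15 * sin(th + 0.4)))
  ef <- efd_features(ell)
  expect_lt(ef$efd_sum, 0.08)
  expect_length(ef$amplitudes, 20)
  blebbed <- bleb_shape_family(n_steps = 2, max_protrusion_um = 3)[[2]]
  expect_gt(efd_features(blebbed)$efd_sum, 3 * ef$efd_sum)
})

test_that("EFD amplitudes are invariant to rotation and starting vertex", {
  set.seed(31)
  base_pts <- perturb_contour(circle_contour(c(0, 0), 15, n = 240), 3)$points
  ef0 <- efd_features(nucleus_contour(base_pts))
  phi <- 37 * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  rot <- base_pts %*% R
  shift <- rbind(rot[101:240, ], rot[1:100, ]) # different starting vertex
  ef1 <- efd_features(nucleus_contour(shift))
  expect_lt(max(abs(ef0$amplitudes - ef1$amplitudes)), 1e-6)
  # translation and scaling invariance
  ef2 <- efd_features(nucleus_contour(base_pts * 3.2 +
                                        matrix(c(100, 50), 240, 2, byrow = TRUE)))
  expect_lt(max(abs(ef0$amplitudes - ef2$amplitudes)), 1e-6)
})

test_that("summed EFD increases strictly along the bleb-amplitude family", {
  fam <- bleb_shape_family(n_steps = 10, max_protrusion_um = 3)
  vals <- vapply(fam, function(ct) efd_features(ct)$efd_sum, 1.0)
  expect_true(all(diff(vals) > 0))
})

test_that("GLCM features behave on constant, rotated and checkerboard patches", {
  img <- calibrated_image(matrix(25, 32, 32), 1)
  mask <- matrix(TRUE, 32, 32)
  g0 <- glcm_features(img, mask)
  expect_equal(g0$glcm_entropy, 0)
  expect_equal(g0$glcm_asm, 1)
  expect_equal(g0$glcm_contrast, 0)
  # 90-degree rotation leaves angle-averaged features unchanged
  set.seed(8)
  patch <- matrix(runif(32 * 32, 0, 100), 32, 32)
  a <- glcm_features(calibrated_image(patch, 1), mask)
  b <- glcm_features(calibrated_image(t(patch[32:1, ]), 1), mask)
  for (k in names(a)) expect_equal(a[[k]], b[[k]], tolerance = 1e-10)
  # two-level checkerboard at distance 1: contrast equals the squared level
  # gap of a hand-built co-occurrence matrix
  cb <- outer(1:32, 1:32, function(i, j) (i + j) %% 2) * 60 + 20
  gc <- glcm_features(calibrated_image(cb, 1), mask, levels = 64)
  lev <- 64 - 1 # quantized levels 1 and 64 -> index gap 63
  # horizontal + vertical neighbors always differ, diagonal neighbors never
  expect_equal(gc$glcm_contrast, mean(c(lev^2, 0, lev^2, 0)), tolerance = 1e-9)
  expect_error(glcm_features(img, matrix(FALSE, 32, 32)), "64 pixels")
})

test_that("extract_all produces complete rows and honors border exclusion", {
  fr <- render_field(field_spec(
    size_px = c(128, 128), pixel_size_um = 0.25,
    nuclei = list(nucleus_spec(c(9, 9), c(3.4, 3), 0.2, 170),
                  nucleus_spec(c(23, 23), c(4, 3.1), 1.0, 200)),
    noise = list(gaussian_sd = 2, poisson = TRUE), seed = 44L))
  cts <- mask_to_contours(fr$mask, stage = "refined")
  f <- extract_all(fr$image, cts, labels = fr$labels$class_label)
  expect_equal(nrow(f), 2)
  expect_no_na(f)
  expect_true(all(c("area_um2", "circularity", "solidity", "efd_sum",
                    "total_curvature_rad", "glcm_entropy", "class") %in% names(f)))
  # border-flagged nucleus is excluded by default
  cts[[1]]$border_flag <- TRUE
  expect_message(f2 <- extract_all(fr$image, cts), "excluding border")
  expect_equal(nrow(f2), 1)
  f3 <- suppressMessages(extract_all(fr$image, cts,
                                     feature_config(include_border = TRUE)))
  expect_equal(nrow(f3), 2)
})

test_that("entropy separates ruffled from plain nuclei of identical shape", {
  score <- function(ruff, seed) {
    sp <- blebseg:::with_seed(seed, field_spec(
      size_px = c(96, 96), pixel_size_um = 0.25,
      nuclei = list(nucleus_spec(c(12, 12), c(4, 3.4), 0.6, 180,
                                 ruffling_gradient = ruff)),
      noise = list(gaussian_sd = 2, poisson = TRUE), seed = seed))
    fr <- render_field(sp)
    ct <- mask_to_contours(fr$mask, stage = "refined")[[1]]
    mask <- contours_to_mask(list(ct), dim(fr$image$pixels)) > 0
    glcm_features(fr$image, mask)$glcm_entropy
  }
  plain <- vapply(1:20, function(s) score(0, 700 + s), 1.0)
  ruffled <- vapply(1:20, function(s) score(0.5, 900 + s), 1.0)
  # AUC of entropy as a ruffling score
  auc <- mean(outer(ruffled, plain, ">")) + 0.5 * mean(outer(ruffled, plain, "=="))
  expect_gt(auc, 0.9)
})
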