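test_that("global pass finds bright components and ignores blank images", {
  img <- disk_image(disks = list(list(c(28, 30), 12), list(c(68, 60), 14)))
  seeds <- global_pass(img, twopass_config(global_method = "otsu",
                                           min_seed_area_um2 = 2))
  expect_length(seeds, 2)
  expect_true(all(vapply(seeds, function(s) s$stage, "") == "seed"))
  blank <- calibrated_image(matrix(3, 64, 64), 0.25)
  expect_length(global_pass(blank, twopass_config()), 0)
})

test_that("a dim bleb is mostly lost by the global threshold", {
  fr <- render_field(bleb_field(201, noise_sd = 0))
  img <- fr$image
  v <- auto_threshold(img$pixels, "otsu")
  gmask <- img$pixels >= v
  gt <- fr$mask > 0
  # bleb pixels = ground truth outside the global mask's core body:
  bleb_px <- gt & img$pixels < 0.5 * max(img$pixels)
  recall <- sum(bleb_px & gmask) / sum(bleb_px)
  expect_lt(recall, 0.5)
})

test_that("conditional dilation matches brute-force nearest-seed labeling", {
  shape <- c(40, 40)
  seed_mask <- matrix(0L, 40, 40)
  seed_mask[21, 11] <- 1L # (x=10, y=20)
  seed_mask[21, 21] <- 2L # (x=20, y=20), 10 px apart
  out <- conditional_dilate(seed_mask, shape, dilation_um = 8, pixel_size_um = 1)
  g <- expand.grid(x = 0:39, y = 0:39)
  d1 <- sqrt((g$x - 10)^2 + (g$y - 20)^2)
  d2 <- sqrt((g$x - 20)^2 + (g$y - 20)^2)
  lab <- ifelse(pmin(d1, d2) > 8, 0L, ifelse(d1 <= d2, 1L, 2L))
  ref <- matrix(0L, 40, 40)
  ref[cbind(g$y + 1, g$x + 1)] <- lab
  expect_identical(out, ref)
  # regions are disjoint and separated along the perpendicular bisector
  expect_true(all(out[, 1:15][out[, 1:15] > 0] == 1))
  expect_true(all(out[, 17:40][out[, 17:40] > 0] == 2))
})

test_that("zero dilation returns the seed mask unchanged", {
  seed_mask <- matrix(0L, 30, 30)
  seed_mask[10:14, 10:14] <- 1L
  out <- conditional_dilate(seed_mask, c(30, 30), 0, 1)
  expect_identical(out, seed_mask)
})

test_that("single-seed dilation is plain Euclidean dilation", {
  seed_mask <- matrix(0L, 41, 41)
  seed_mask[21, 21] <- 1L
  out <- conditional_dilate(seed_mask, c(41, 41), 3, 1)
  g <- expand.grid(x = 0:40, y = 0:40)
  ref <- matrix(0L, 41, 41)
  sel <- (g$x - 20)^2 + (g$y - 20)^2 <= 9 + 1e-9
  ref[cbind(g$y[sel] + 1, g$x[sel] + 1)] <- 1L
  expect_identical(out, ref)
})

test_that("local thresholding recovers more of the bleb than the global pass", {
  fr <- render_field(bleb_field(202, noise_sd = 0))
  img <- fr$image
  cfg <- twopass_config(global_method = "otsu", local_method = "triangle",
                        min_seed_area_um2 = 5)
  gv <- auto_threshold(img$pixels, "otsu")
  seg <- two_pass_segment(img, cfg)
  expect_length(seg$contours, 1)
  expect_equal(seg$contours[[1]]$stage, "initial")
  gt <- fr$mask > 0
  gmask_px <- sum(gt & img$pixels >= gv)
  init <- contours_to_mask(seg$contours, dim(img$pixels)) > 0
  expect_gt(sum(gt & init), gmask_px)
})

test_that("initial ROIs are disjoint and confined to their dilated regions", {
  fr <- render_field(field_spec(
    size_px = c(128, 128), pixel_size_um = 0.25,
    nuclei = list(nucleus_spec(c(9, 9), c(3.5, 3), 0.3, 160),
                  nucleus_spec(c(22, 22), c(4, 3.2), 1.2, 200)),
    noise = list(gaussian_sd = 2, poisson = TRUE), seed = 17L))
  seg <- two_pass_segment(fr$image, twopass_config(min_seed_area_um2 = 5))
  expect_length(seg$contours, 2)
  masks <- lapply(seg$contours, function(ct)
    contours_to_mask(list(ct), dim(fr$image$pixels)) > 0)
  expect_equal(sum(masks[[1]] & masks[[2]]), 0)
  for (ct in seg$contours) {
    m <- contours_to_mask(list(ct), dim(fr$image$pixels)) > 0
    expect_true(all(seg$dilated[m] == ct$nucleus_id))
  }
})

test_that("juxtaposed nuclei split by Voronoi regions give two contours", {
  # two touching nuclei with a shallow valley: global threshold merges them,
  # but the Voronoi-restricted dilation keeps their regions apart as long as
  # the global pass seeds them separately
  fr <- render_field(field_spec(
    size_px = c(96, 96), pixel_size_um = 0.25,
    nuclei = list(nucleus_spec(c(8.5, 12), c(3.2, 2.9), 0, 150),
                  nucleus_spec(c(15.4, 12), c(3.2, 2.9), 0, 230)),
    touching_pairs = list(list(pair = c(1L, 2L), valley_ratio = 0.55)),
    noise = list(gaussian_sd = 0, poisson = FALSE), seed = 5L))
  # choose a global method that thresholds above the valley so seeds separate
  seg <- two_pass_segment(fr$image, twopass_config(global_method = "otsu",
                                                   local_method = "mean",
                                                   min_seed_area_um2 = 5))
  expect_length(seg$contours, 2)
  masks <- lapply(seg$contours, function(ct)
    contours_to_mask(list(ct), dim(fr$image$pixels)) > 0)
  expect_equal(sum(masks[[1]] & masks[[2]]), 0)
})

test_that("degenerate local histograms fall back to the global threshold", {
  px <- matrix(5, 48, 48)
  px[15:32, 15:32] <- 100 # flat square: local histogram is degenerate
  img <- calibrated_image(px, 0.5)
  seeds <- global_pass(img, twopass_config(global_method = "mean",
                                           min_seed_area_um2 = 1))
  dil <- conditional_dilate(seeds, c(48, 48), 3, 0.5)
  cts <- local_threshold_pass(img, dil, twopass_config(local_method = "mean"),
                              global_value = auto_threshold(px, "mean"))
  expect_length(cts, 1)
  m <- contours_to_mask(cts, c(48, 48))
  expect_equal(sum(m > 0), 18 * 18)
})
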