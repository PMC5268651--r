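sym_ahd <- function(A, B, ps = 1) {
  max(directed_avg_distance(A, B, ps), directed_avg_distance(B, A, ps))
}

test_that("directed average distance identities and concentric circles", {
  C <- circle_contour(c(30, 30), 10, n = 200)
  expect_equal(directed_avg_distance(C, C, 1), 0, tolerance = 1e-9)
  outer_c <- circle_contour(c(30, 30), 12, n = 200)
  expect_equal(directed_avg_distance(C, outer_c, 0.5), 1.0, tolerance = 0.02)
  expect_equal(directed_avg_distance(outer_c, C, 0.5), 1.0, tolerance = 0.02)
})

test_that("directed distance equals a brute-force all-pairs oracle", {
  # independent densifier: walk each edge at fixed small steps
  densify_indep <- function(pts, step = 0.25) {
    out <- NULL
    n <- nrow(pts)
    for (i in seq_len(n)) {
      a <- pts[i, ]; b <- pts[if (i == n) 1 else i + 1, ]
      len <- sqrt(sum((b - a)^2))
      t <- seq(0, 1, by = step / max(len, step))
      t <- t[t < 1]
      out <- rbind(out, cbind(a[1] + t * (b[1] - a[1]),
                              a[2] + t * (b[2] - a[2])))
    }
    out
  }
  A <- square_contour(5, 5, 8)
  B <- square_contour(8, 5, 8)
  da <- densify_indep(A$points); db <- densify_indep(B$points)
  d2 <- outer(da[, 1], db[, 1], "-")^2 + outer(da[, 2], db[, 2], "-")^2
  oracle <- mean(sqrt(apply(d2, 1, min)))
  got <- directed_avg_distance(A, B, 1, spacing_px = 0.25)
  expect_equal(got, oracle, tolerance = 0.02)
  expect_gte(got, 0); expect_lte(got, 3)
})

test_that("AHD averages the per-observer symmetrized distances", {
  C <- circle_contour(c(40, 40), 10, n = 128)
  gts <- list(circle_contour(c(41, 40), 10, n = 128),
              circle_contour(c(40, 42), 10, n = 128),
              circle_contour(c(43, 40), 10, n = 128))
  per_obs <- vapply(gts, function(g) sym_ahd(C, g), 1.0)
  expect_equal(ahd(C, gts, 1), mean(per_obs), tolerance = 1e-12)
  expect_equal(ahd(C, list(C, C, C), 1), 0, tolerance = 1e-9)
  expect_error(ahd(C, list()), "no ground-truth")
})

test_that("AHD is symmetric in its two arguments", {
  set.seed(21)
  for (i in 1:5) {
    A <- perturb_contour(circle_contour(c(30, 30), runif(1, 8, 12)), 2)
    B <- perturb_contour(circle_contour(c(31, 30), runif(1, 8, 12)), 2)
    expect_equal(ahd(A, list(B), 1), ahd(B, list(A), 1), tolerance = 1e-12)
  }
})

test_that("NSI identities: identical 0, disjoint 1, half overlap 0.5", {
  sq <- square_contour(4.5, 4.5, 10)
  expect_equal(nsi(sq, list(sq)), 0)
  far <- square_contour(24.5, 24.5, 10)
  expect_equal(nsi(sq, list(far)), 1)
  half <- square_contour(9.5, 4.5, 10) # overlap = half of each square
  expect_equal(nsi(sq, list(half)), 0.5, tolerance = 1e-9)
  set.seed(2)
  for (i in 1:5) {
    A <- perturb_contour(circle_contour(c(30, 30), 9), 2)
    B <- perturb_contour(circle_contour(c(33, 30), 9), 2)
    v <- nsi(A, list(B))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("positive control equals the mean over unordered observer pairs", {
  gt_cts <- list(
    list(circle_contour(c(30, 30), 10, n = 96, id = 1L)),
    list(circle_contour(c(31.5, 30), 10, n = 96, id = 1L)),
    list(circle_contour(c(30, 32), 9.5, n = 96, id = 1L)))
  gt <- ground_truth_set(gt_cts)
  pc <- positive_control(gt, 1L, pixel_size_um = 0.5)
  pairs <- combn(3, 2)
  ahd_hand <- mean(apply(pairs, 2, function(kl)
    sym_ahd(gt_cts[[kl[1]]][[1]], gt_cts[[kl[2]]][[1]], 0.5)))
  nsi_hand <- mean(apply(pairs, 2, function(kl)
    nsi(gt_cts[[kl[1]]][[1]], list(gt_cts[[kl[2]]][[1]]))))
  expect_equal(pc$ahd_pc, ahd_hand, tolerance = 1e-12)
  expect_equal(pc$nsi_pc, nsi_hand, tolerance = 1e-12)
  # ordered-pair sum with the 1/6 prefactor gives the same value (symmetry)
  ordered <- expand.grid(k = 1:3, l = 1:3)
  ordered <- ordered[ordered$k != ordered$l, ]
  expect_equal(pc$ahd_pc,
               sum(mapply(function(k, l) sym_ahd(gt_cts[[k]][[1]],
                                                 gt_cts[[l]][[1]], 0.5),
                          ordered$k, ordered$l)) / 6, tolerance = 1e-12)
})

test_that("scaling and integrated error arithmetic", {
  rec <- scale_and_error(list(ahd_raw = 2, nsi_raw = 0.1),
                         list(ahd_pc = 2, nsi_pc = 0.1))
  expect_equal(rec$error, 1)
  rec0 <- scale_and_error(list(ahd_raw = 0, nsi_raw = 0),
                          list(ahd_pc = 1, nsi_pc = 0.2))
  expect_equal(rec0$error, 0)
  rec2 <- scale_and_error(list(ahd_raw = 4, nsi_raw = 0.05),
                          list(ahd_pc = 2, nsi_pc = 0.1))
  expect_equal(rec2$error, 1.25)
  degen <- scale_and_error(list(ahd_raw = 1, nsi_raw = 0.1),
                           list(ahd_pc = 0, nsi_pc = 0.1))
  expect_true(degen$degenerate_pc)
  expect_true(is.na(degen$error))
  # scale equivariance: doubling raw doubles scaled values and the error
  r1 <- scale_and_error(list(ahd_raw = 1.2, nsi_raw = 0.06),
                        list(ahd_pc = 0.8, nsi_pc = 0.12))
  r2 <- scale_and_error(list(ahd_raw = 2.4, nsi_raw = 0.12),
                        list(ahd_pc = 0.8, nsi_pc = 0.12))
  expect_equal(r2$error, 2 * r1$error, tolerance = 1e-12)
})

test_that("validation matches contours to ground truth by overlap", {
  gt_obs <- lapply(1:3, function(o) list(
    circle_contour(c(20 + 0.4 * o, 20), 8 + 0.2 * o, n = 96, id = 1L),
    circle_contour(c(50, 50 + 0.4 * o), 9 - 0.2 * o, n = 96, id = 2L)))
  gt <- ground_truth_set(gt_obs)
  pred <- list(circle_contour(c(50.5, 50), 9, n = 96, id = 7L),
               circle_contour(c(20.5, 20), 8, n = 96, id = 8L),
               circle_contour(c(70, 12), 4, n = 96, id = 9L)) # spurious
  v <- validate_segmentation(pred, gt, c(80, 80), 0.5)
  expect_equal(sort(v$nucleus_id), c(1, 2))
  expect_equal(attr(v, "unmatched"), 3L)
  expect_true(all(v$error >= 0))
})
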