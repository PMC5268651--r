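#' Conditional watershed configuration
#'
#' @param min_area_um2 minimal area of an accepted fragment, square micrometers.
#' @param decay_cutoff min/max ratio of the median perpendicular intensity
#'   profile above which a proposed split is vetoed (default 0.75).
#' @param profile_halfwidth_um half-width of the profile subregion around a
#'   separation line (default 1.5, i.e. a 3 um wide subregion).
#' @return a `watershed_config` list.
#' @export
watershed_config <- function(min_area_um2 = 20, decay_cutoff = 0.75,
                             profile_halfwidth_um = 1.5) {
  stopifnot(min_area_um2 > 0, decay_cutoff > 0, decay_cutoff < 1,
            profile_halfwidth_um > 0)
  structure(list(min_area_um2 = min_area_um2, decay_cutoff = decay_cutoff,
                 profile_halfwidth_um = profile_halfwidth_um),
            class = "watershed_config")
}

order_line_points <- function(pts) {
  if (nrow(pts) < 3) return(pts)
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  v <- eigen(crossprod(cen) / nrow(pts), symmetric = TRUE)$vectors[, 1]
  pts[order(cen %*% v), , drop = FALSE]
}

#' Watershed split proposals for one ROI
#'
#' Runs a distance-transform watershed (on the Gaussian-smoothed distance map,
#' sigma 1 px, to suppress spurious maxima) on the binary mask of a refined
#' ROI. Returns the fragments and, for each pair of adjacent fragments, the
#' ordered pixel chain of their separation line.
#'
#' @param roi_mask logical/0-1 matrix of one ROI.
#' @return list with `fragments` (label matrix) and `lines` (list of
#'   `list(a, b, points)` where `points` are ordered 0-based (x, y) positions
#'   along the boundary between fragments a and b).
#' @export
watershed_candidates <- function(roi_mask) {
  bw <- roi_mask != 0
  d <- EBImage::distmap(matrix(as.numeric(bw), nrow(bw), ncol(bw)))
  ds <- EBImage::gblur(d, sigma = 1)
  ds[!bw] <- 0
  w <- EBImage::watershed(ds)
  frag <- matrix(as.integer(w), nrow(bw), ncol(bw))
  frag[!bw] <- 0L
  nfrag <- length(unique(frag[frag > 0]))
  if (nfrag <= 1)
    return(list(fragments = frag, lines = list()))
  # boundary pixels: mask pixels 4-adjacent to a different positive label;
  # line points are the midpoints of adjacent differing pixel pairs
  nr <- nrow(frag); nc <- ncol(frag)
  pairs <- list()
  collect <- function(a_idx, b_idx) {
    A <- frag[a_idx]; B <- frag[b_idx]
    sel <- A > 0L & B > 0L & A != B
    if (!any(sel)) return(NULL)
    cbind(lab_a = pmin(A[sel], B[sel]), lab_b = pmax(A[sel], B[sel]),
          ai = a_idx[sel], bi = b_idx[sel])
  }
  idx <- matrix(seq_len(nr * nc), nr, nc)
  h <- collect(idx[, 1:(nc - 1)], idx[, 2:nc])
  v <- collect(idx[1:(nr - 1), ], idx[2:nr, ])
  adj <- rbind(h, v)
  if (is.null(adj) || !nrow(adj))
    return(list(fragments = frag, lines = list()))
  key <- paste(adj[, 1], adj[, 2])
  lines <- lapply(split(seq_len(nrow(adj)), key), function(sel) {
    s <- adj[sel, , drop = FALSE]
    ar <- (s[, 3] - 1) %% nr; ac <- (s[, 3] - 1) %/% nr
    br <- (s[, 4] - 1) %% nr; bc <- (s[, 4] - 1) %/% nr
    pts <- unique(cbind((ac + bc) / 2, (ar + br) / 2)) # 0-based (x, y)
    list(a = s[1, 1], b = s[1, 2], points = order_line_points(pts))
  })
  names(lines) <- NULL
  list(fragments = frag, lines = lines)
}

#' Median perpendicular intensity-decay ratio of a separation line
#'
#' For every line pixel an intensity profile is sampled perpendicular to the
#' local line direction (estimated from a 5-point centered window) across
#' twice the profile half-width at 0.5 px steps; the per-offset median across
#' all line pixels forms the median profile, and min/max of that profile is
#' returned. A featureless (all-zero) profile yields 1.
#'
#' @param image a [calibrated_image()].
#' @param line matrix of ordered 0-based (x, y) line points (>= 2 rows).
#' @param cfg a [watershed_config()].
#' @return ratio in `[0, 1]`.
#' @export
median_decay_ratio <- function(image, line, cfg = watershed_config()) {
  pts <- as.matrix(line)
  n <- nrow(pts)
  if (n < 2) stop("separation line needs at least 2 pixels")
  ps <- image$pixel_size_um
  hw_px <- cfg$profile_halfwidth_um / ps
  offs <- seq(-hw_px, hw_px, by = 0.5)
  profs <- matrix(NA_real_, n, length(offs))
  for (i in seq_len(n)) {
    w <- max(1, i - 2):min(n, i + 2)
    dirv <- pts[max(w), ] - pts[min(w), ]
    nv <- sqrt(sum(dirv^2))
    if (nv == 0) dirv <- c(1, 0) else dirv <- dirv / nv
    perp <- c(-dirv[2], dirv[1])
    xs <- pts[i, 1] + offs * perp[1]
    ys <- pts[i, 2] + offs * perp[2]
    profs[i, ] <- interp_bilinear_cpp(image$pixels, xs, ys)
  }
  med <- apply(profs, 2, median)
  if (max(med) <= 0) return(1)
  max(0, min(med)) / max(med)
}

#' Conditionally split one ROI into touching nuclei
#'
#' Separation lines proposed by the watershed are evaluated in ascending
#' decay-ratio order; a split is accepted only if both resulting fragments
#' reach `min_area_um2` and the intensity-decay ratio does not exceed
#' `decay_cutoff` (a ratio exactly at the cutoff retains the split). Vetoed
#' splits are merged back. Newly created contours are re-refined when a
#' [refine_config()] is supplied.
#'
#' @param image a [calibrated_image()].
#' @param roi a refined [nucleus_contour()] (or binary mask).
#' @param cfg a [watershed_config()].
#' @param refine_cfg optional [refine_config()] for re-refining new contours.
#' @return list of [nucleus_contour()]s (length 1 when no split survives).
#' @export
conditional_split <- function(image, roi, cfg = watershed_config(),
                              refine_cfg = NULL) {
  shape <- dim(image$pixels)
  if (inherits(roi, "nucleus_contour")) {
    mask <- contours_to_mask(list(roi), shape) > 0
    base_id <- roi$nucleus_id
    border <- roi$border_flag
  } else {
    mask <- roi != 0
    base_id <- 1L
    border <- FALSE
  }
  cand <- watershed_candidates(mask)
  frag <- cand$fragments
  if (!length(cand$lines)) {
    if (inherits(roi, "nucleus_contour")) return(list(roi))
    return(mask_to_contours(frag > 0, stage = "refined"))
  }
  ratios <- vapply(cand$lines, function(ln)
    median_decay_ratio(image, ln$points, cfg), 1.0)
  ord <- order(ratios)
  ps2 <- image$pixel_size_um^2
  nfrag <- max(frag)
  parent <- seq_len(nfrag)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  areas <- tabulate(frag[frag > 0], nfrag) * ps2
  group_area <- function(g) sum(areas[vapply(seq_len(nfrag), findp, 1L) == g])
  for (li in ord) {
    ln <- cand$lines[[li]]
    ga <- findp(ln$a); gb <- findp(ln$b)
    if (ga == gb) next
    ok_size <- group_area(ga) >= cfg$min_area_um2 &&
      group_area(gb) >= cfg$min_area_um2
    ok_decay <- ratios[li] <= cfg$decay_cutoff
    if (!(ok_size && ok_decay)) parent[max(ga, gb)] <- min(ga, gb) # veto: merge
  }
  roots <- vapply(seq_len(nfrag), findp, 1L)
  groups <- sort(unique(roots))
  if (length(groups) == 1) {
    if (inherits(roi, "nucleus_contour")) return(list(roi))
    return(mask_to_contours(mask * 1L, stage = "refined"))
  }
  out <- matrix(0L, shape[1], shape[2])
  out[frag > 0] <- match(roots[frag[frag > 0]], groups)
  contours <- mask_to_contours(out, stage = "refined")
  contours <- lapply(seq_along(contours), function(i) {
    ct <- contours[[i]]
    ct$nucleus_id <- as.integer(base_id * 1000L + i)
    ct$border_flag <- border
    ct
  })
  if (!is.null(refine_cfg))
    contours <- lapply(contours, function(ct) refine(image, ct, refine_cfg)$contour)
  contours
}
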