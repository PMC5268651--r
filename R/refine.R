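#' Contour refinement configuration
#'
#' @param half_width_um half-width of the straightened peri-contour band in
#'   micrometers (default 1, i.e. a 2 um band).
#' @param max_iterations maximal number of refinement cycles (default 5).
#' @param convergence_tol_px stop when the maximal vertex displacement between
#'   successive contours falls below this (default 0.5 px).
#' @return a `refine_config` list.
#' @export
refine_config <- function(half_width_um = 1, max_iterations = 5,
                          convergence_tol_px = 0.5) {
  stopifnot(half_width_um > 0, max_iterations >= 1, convergence_tol_px >= 0)
  structure(list(half_width_um = half_width_um,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol_px = convergence_tol_px),
            class = "refine_config")
}

#' Straighten a peri-contour band
#'
#' Resamples the contour to `r = max(32, round(perimeter_px))` equally spaced
#' arc positions and samples `q = 2 * round(half_width_um / pixel_size) + 1`
#' values along the outward normal at each, by bilinear interpolation (border
#' values clamped). Row 1 is innermost (offset -half_width), the middle row
#' lies on the input contour, row q is outermost.
#'
#' @param image a [calibrated_image()].
#' @param contour a [nucleus_contour()] with >= 8 vertices.
#' @param half_width_um band half-width in micrometers.
#' @return a `straightened_band`: `values` (q x r), `anchors` (per-column
#'   x, y and outward normal), `half_width_um`, `pixel_size_um`.
#' @export
straighten_band <- function(image, contour, half_width_um = 1) {
  stopifnot(inherits(image, "calibrated_image"))
  pts <- contour$points
  if (nrow(pts) < 8) stop("contour shorter than 8 vertices")
  ps <- image$pixel_size_um
  per <- polygon_perimeter(pts)
  r <- max(32L, as.integer(round(per)))
  rs <- resample_contour(pts, n = r)
  # smooth the closed curve (circular Gaussian, sigma 1.5 samples) so that
  # staircase vertices from rasterized contours do not produce zigzagging
  # normals whose offset rays cross inside the band
  kw <- 3L
  kern <- exp(-(-kw:kw)^2 / (2 * 1.5^2)); kern <- kern / sum(kern)
  circ_smooth <- function(v) {
    out <- numeric(r)
    for (d in -kw:kw) out <- out + kern[d + kw + 1] * v[((seq_len(r) - 1 + d) %% r) + 1]
    out
  }
  rs <- cbind(circ_smooth(rs[, 1]), circ_smooth(rs[, 2]))
  # tangents by central differences on the closed resampled polyline
  nxt <- rs[c(2:r, 1), , drop = FALSE]
  prv <- rs[c(r, 1:(r - 1)), , drop = FALSE]
  tg <- nxt - prv
  tl <- sqrt(rowSums(tg^2)); tl[tl == 0] <- 1
  tg <- tg / tl
  # outward normal for positive-signed-area orientation: (dy, -dx)
  nx <- tg[, 2]; ny <- -tg[, 1]
  hw_px <- um_to_px(half_width_um, ps)
  if (hw_px < 1) hw_px <- 1L
  q <- 2L * hw_px + 1L
  offsets <- seq(-hw_px, hw_px, length.out = q)
  X <- outer(offsets, nx, "*") + matrix(rs[, 1], q, r, byrow = TRUE)
  Y <- outer(offsets, ny, "*") + matrix(rs[, 2], q, r, byrow = TRUE)
  vals <- interp_bilinear_cpp(image$pixels, as.numeric(X), as.numeric(Y))
  structure(list(values = matrix(vals, q, r),
                 anchors = list(x = rs[, 1], y = rs[, 2], nx = nx, ny = ny),
                 half_width_um = half_width_um, pixel_size_um = ps),
            class = "straightened_band")
}

#' Signed vertical edge response of a straightened band
#'
#' Convolves the band with a vertical Sobel kernel, signed so the
#' bright-inside to dark-outside transition is positive; negative responses
#' (dark-to-bright, e.g. debris edges) are clamped to zero. The result is the
#' input matrix P of the optimal path finder.
#'
#' @param band a `straightened_band`.
#' @return a `straightened_band` whose `values` hold the clamped response.
#' @export
edge_derivative <- function(band) {
  B <- band$values
  q <- nrow(B); r <- ncol(B)
  if (q < 3) stop("band must have at least 3 rows")
  up <- B[c(1, 1:(q - 1)), , drop = FALSE]      # row above (replicated edge)
  dn <- B[c(2:q, q), , drop = FALSE]            # row below
  d <- up - dn                                   # + when inside (top) brighter
  left <- d[, c(r, 1:(r - 1)), drop = FALSE]     # circular in arc position
  right <- d[, c(2:r, 1), drop = FALSE]
  P <- left + 2 * d + right
  P[P < 0] <- 0
  band$values <- P
  band
}

#' Normalize matrix columns by their maxima
#'
#' @param P non-negative matrix.
#' @return matrix with each column divided by its maximum; all-zero columns
#'   stay zero; entries lie in `[0, 1]`.
#' @export
normalize_columns <- function(P) {
  if (any(P < 0)) stop("P must be non-negative")
  mx <- apply(P, 2, max)
  mx[mx == 0] <- 1
  sweep(P, 2, mx, "/")
}

#' Optimal path through a normalized edge-response matrix
#'
#' Left-to-right dynamic program maximizing path strength = gain / loss, where
#' stepping from row k to row i traverses the cells strictly between them in
#' the predecessor column (landing row included, predecessor cell excluded)
#' plus the landing cell; gain sums their normalized responses and loss counts
#' them, so a straight path has loss `r`. Vertical runs may span any height
#' (propagation up to 90 degrees). For every element the true maximum strength
#' over all paths ending there is computed (loss-stratified exact DP), so the
#' result matches exhaustive path enumeration. Ties are broken towards the
#' smallest vertical displacement, then the smaller row index.
#'
#' @param N q x r matrix with entries in `[0, 1]` (see [normalize_columns()]).
#' @return a `path_matrices` list: `N`, `S`, `G`, `L` (per-element optimal
#'   strength/gain/loss), `path` (row index per column) and `strength`.
#' @export
optimal_path <- function(N) {
  N <- as.matrix(N)
  if (any(N < 0) || any(N > 1 + 1e-12)) stop("N entries must lie in [0, 1]")
  q <- nrow(N); r <- ncol(N)
  if (r < 2) {
    if (r < 1) stop("empty matrix")
    if (q == 1) {
      return(structure(list(N = N, S = N, G = N, L = matrix(1, 1, 1),
                            path = 1L, strength = N[1, 1]),
                       class = "path_matrices"))
    }
    stop("optimal path requires at least 2 columns")
  }
  if (q == 1) {
    g <- cumsum(N[1, ])
    return(structure(list(N = N, S = matrix(g / seq_len(r), 1),
                          G = matrix(g, 1), L = matrix(seq_len(r), 1),
                          path = rep(1L, r), strength = g[r] / r),
                     class = "path_matrices"))
  }
  res <- opf_cpp(N)
  structure(list(N = N, S = res$S, G = res$G, L = res$L,
                 path = as.integer(res$path), strength = res$strength),
            class = "path_matrices")
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

is_self_intersecting <- function(pts) {
  n <- nrow(pts)
  a <- pts; b <- pts[c(2:n, 1), , drop = FALSE]
  for (i in 1:(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)] # skip adjacent (shared-vertex) pairs
    if (!length(js)) next
    x1 <- a[i, 1]; y1 <- a[i, 2]; x2 <- b[i, 1]; y2 <- b[i, 2]
    d1 <- (x2 - x1) * (a[js, 2] - y1) - (y2 - y1) * (a[js, 1] - x1)
    d2 <- (x2 - x1) * (b[js, 2] - y1) - (y2 - y1) * (b[js, 1] - x1)
    cand <- js[(d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)]
    for (j in cand) {
      if (segments_intersect(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

#' Map an optimal path back to image coordinates
#'
#' Each column's path row is converted to a signed normal offset from the
#' column anchor; the points are assembled in order, collinear runs removed.
#' If the resulting polygon self-intersects the caller should fall back to
#' the pre-refinement contour.
#'
#' @param path numeric vector of row positions (possibly fractional), one per
#'   column of the band.
#' @param band the `straightened_band` the path was computed on.
#' @param nucleus_id identifier for the output contour.
#' @param border_flag carried through from the input contour.
#' @return a `stage = "refined"` [nucleus_contour()], or `NULL` when the
#'   reconstruction self-intersects.
#' @export
reconstruct_contour <- function(path, band, nucleus_id = 1L, border_flag = FALSE) {
  q <- nrow(band$values); r <- ncol(band$values)
  if (length(path) != r) stop("path length must equal the number of columns")
  mid <- (q + 1) / 2
  hw_px <- (q - 1) / 2
  off <- (path - mid) # rows are 1 px apart
  off <- pmin(pmax(off, -hw_px), hw_px)
  x <- band$anchors$x + off * band$anchors$nx
  y <- band$anchors$y + off * band$anchors$ny
  pts <- simplify_collinear(cbind(x, y, deparse.level = 0), tol = 1e-9)
  if (nrow(pts) < 8 || abs(signed_area(pts)) < 1e-9) return(NULL)
  if (is_self_intersecting(pts)) return(NULL)
  nucleus_contour(pts, stage = "refined", nucleus_id = nucleus_id,
                  border_flag = border_flag)
}

# one refinement cycle: straighten -> derivative -> normalize -> OPF (with
# circular wrap handling) -> reconstruct; returns contour + max displacement
refine_once <- function(image, contour, half_width_um, smooth_passes = 1L) {
  band <- straighten_band(image, contour, half_width_um)
  P <- edge_derivative(band)$values
  N <- normalize_columns(P)
  r <- ncol(N)
  # the band is circular in arc position: wrap the first ceil(r/10) columns
  # to the right edge, run the open-path DP, then discard the duplicate
  e <- as.integer(ceiling(r / 10))
  Next <- cbind(N, N[, seq_len(e), drop = FALSE])
  pm <- optimal_path(Next)
  path <- as.numeric(pm$path[seq_len(r)])
  # blend any residual start/end mismatch over the final 5% of columns
  n5 <- max(1L, as.integer(round(0.05 * r)))
  delta <- path[1] - path[r]
  if (delta != 0) {
    js <- (r - n5 + 1):r
    path[js] <- path[js] + delta * (js - (r - n5)) / n5
  }
  # suppress single-column zigzags (which self-intersect on reconstruction)
  # with a circular 3-column moving average; >= 10-column crevice dips survive
  for (sp in seq_len(smooth_passes))
    path <- (path[c(r, 1:(r - 1))] + path + path[c(2:r, 1)]) / 3
  ct <- reconstruct_contour(path, band, nucleus_id = contour$nucleus_id,
                            border_flag = contour$border_flag)
  disp <- max(abs(path - (nrow(band$values) + 1) / 2))
  list(contour = ct, displacement_px = disp, strength = pm$strength)
}

#' Iterative contour refinement by optimal path finding
#'
#' Repeats straightening, edge enhancement, column normalization, optimal
#' path finding and contour reconstruction until the contour no longer moves
#' (maximal displacement below `convergence_tol_px`) or `max_iterations` is
#' reached. Iteration lets the refinement capture crevices deeper than the
#' band half-width. If a reconstruction self-intersects, the pre-refinement
#' contour for that nucleus is returned with a warning.
#'
#' @param image a [calibrated_image()].
#' @param contour the initial [nucleus_contour()].
#' @param cfg a [refine_config()].
#' @return list with `contour` (stage `"refined"`), `n_iterations` and
#'   `converged`.
#' @export
refine <- function(image, contour, cfg = refine_config()) {
  cur <- contour
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(cfg$max_iterations)) {
    step <- refine_once(image, cur, cfg$half_width_um)
    if (is.null(step$contour)) # retry with heavier path smoothing
      step <- refine_once(image, cur, cfg$half_width_um, smooth_passes = 3L)
    iters <- it
    if (is.null(step$contour)) {
      warning("refined contour self-intersects for nucleus ",
              contour$nucleus_id, "; keeping previous contour")
      break
    }
    cur <- step$contour
    if (step$displacement_px < cfg$convergence_tol_px) { converged <- TRUE; break }
  }
  if (cur$stage != "refined")
    cur <- nucleus_contour(cur$points, stage = "refined",
                           nucleus_id = cur$nucleus_id,
                           border_flag = cur$border_flag)
  list(contour = cur, n_iterations = iters, converged = converged)
}
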