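# Automatic threshold registry (FIJI auto-threshold family).
#
# All methods operate on a 256-bin histogram built over the min-max range of
# the supplied pixel population (matching ImageJ behavior regardless of bit
# depth). Index-based methods return the cut between background bin t and the
# first foreground bin; segmentation treats pixels >= value as foreground.

build_hist256 <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    stop("degenerate histogram: fewer than 2 distinct intensity values")
  w <- (rng[2] - rng[1]) / 256
  idx <- pmin(floor((x - rng[1]) / w), 255)
  counts <- tabulate(idx + 1L, 256L)
  list(counts = counts, p = counts / sum(counts),
       mids = rng[1] + (0:255 + 0.5) * w,
       edges = rng[1] + (0:256) * w)
}

# index of cut -> threshold value at the bin boundary between t and t+1
cut_value <- function(h, t) h$edges[t + 2]

first_nz <- function(cnt) which(cnt > 0)[1] - 1L
last_nz <- function(cnt) max(which(cnt > 0)) - 1L

th_mean <- function(h) sum(h$p * h$mids)

th_otsu <- function(h) {
  p <- h$p; i <- 0:255
  w0 <- cumsum(p); mu <- cumsum(p * i); mt <- mu[256]
  t <- 0:254
  w0t <- w0[t + 1]; w1t <- 1 - w0t
  valid <- w0t > 0 & w1t > 0
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mt * w0t[valid] - mu[t + 1][valid])^2 / (w0t[valid] * w1t[valid])
  cut_value(h, which.max(bcv) - 1L)
}

th_isodata <- function(h) {
  p <- h$p; i <- 0:255
  t <- sum(p * i)
  for (it in 1:1000) {
    lo <- i <= t
    if (!any(p[lo] > 0) || !any(p[!lo] > 0)) break
    mB <- sum(p[lo] * i[lo]) / sum(p[lo])
    mF <- sum(p[!lo] * i[!lo]) / sum(p[!lo])
    tn <- (mB + mF) / 2
    if (abs(tn - t) < 0.5) { t <- tn; break }
    t <- tn
  }
  cut_value(h, min(254L, max(0L, as.integer(floor(t)))))
}

th_ij_isodata <- function(h) {
  cnt <- h$counts; i <- 0:255
  mn <- first_nz(cnt); mx <- last_nz(cnt)
  if (mn == mx) return(cut_value(h, mn))
  mov <- mn
  repeat {
    lo <- i <= mov
    s2 <- sum(cnt[lo]); s4 <- sum(cnt[!lo])
    if (s2 == 0 || s4 == 0) { mov <- mov + 1L; next }
    res <- (sum(cnt[lo] * i[lo]) / s2 + sum(cnt[!lo] * i[!lo]) / s4) / 2
    mov <- mov + 1L
    if (!((mov + 1) <= res && mov < mx - 1L)) break
  }
  cut_value(h, min(254L, max(0L, as.integer(round(res)))))
}

th_li <- function(h) {
  p <- h$p; v <- 1:256  # offset values to keep logs finite
  t <- sum(p * v)
  for (it in 1:200) {
    lo <- v <= t
    sB <- sum(p[lo]); sF <- sum(p[!lo])
    if (sB <= 0 || sF <= 0) break
    mB <- sum(p[lo] * v[lo]) / sB
    mF <- sum(p[!lo] * v[!lo]) / sF
    if (mB == mF) break
    tn <- (mB - mF) / (log(mB) - log(mF))
    if (abs(tn - t) < 0.5) { t <- tn; break }
    t <- tn
  }
  cut_value(h, min(254L, max(0L, as.integer(floor(t - 1)))))
}

th_max_entropy <- function(h) {
  p <- h$p
  P1 <- cumsum(p)
  ent <- ifelse(p > 0, -p * log(p), 0)
  H1 <- cumsum(ent); Ht <- H1[256]
  t <- 0:254
  P1t <- P1[t + 1]; P2t <- 1 - P1t
  valid <- P1t > 1e-12 & P2t > 1e-12
  phi <- rep(-Inf, 255)
  phi[valid] <- log(P1t[valid] * P2t[valid]) + H1[t + 1][valid] / P1t[valid] +
    (Ht - H1[t + 1][valid]) / P2t[valid]
  cut_value(h, which.max(phi) - 1L)
}

th_huang <- function(h) {
  cnt <- h$counts; i <- 0:255
  mn <- first_nz(cnt); mx <- last_nz(cnt)
  if (mn == mx) return(cut_value(h, mn))
  C <- mx - mn
  W <- cumsum(cnt); WI <- cumsum(cnt * i)
  tot <- W[256]; toti <- WI[256]
  shannon <- function(mu) ifelse(mu <= 0 | mu >= 1, 0,
                                 -mu * log(mu) - (1 - mu) * log(1 - mu))
  best <- Inf; bt <- mn
  for (t in mn:(mx - 1L)) {
    wb <- W[t + 1]; wf <- tot - wb
    if (wb == 0 || wf == 0) next
    mu0 <- WI[t + 1] / wb
    mu1 <- (toti - WI[t + 1]) / wf
    mub <- 1 / (1 + abs(i - mu0) / C)
    muf <- 1 / (1 + abs(i - mu1) / C)
    E <- sum(cnt[1:(t + 1)] * shannon(mub[1:(t + 1)])) +
      sum(cnt[(t + 2):256] * shannon(muf[(t + 2):256]))
    if (E < best) { best <- E; bt <- t }
  }
  cut_value(h, bt)
}

th_yen <- function(h) {
  p <- h$p
  P1 <- cumsum(p); P1sq <- cumsum(p^2)
  P2sq <- rev(cumsum(rev(p^2)))
  t <- 0:254
  a <- P1sq[t + 1]; b <- P2sq[t + 2]; pr <- P1[t + 1]
  valid <- a > 0 & b > 0 & pr > 0 & pr < 1
  crit <- rep(-Inf, 255)
  crit[valid] <- -log(a[valid] * b[valid]) + 2 * log(pr[valid] * (1 - pr[valid]))
  cut_value(h, which.max(crit) - 1L)
}

th_triangle <- function(h) {
  cnt <- as.numeric(h$counts)
  mn <- first_nz(h$counts); mx <- last_nz(h$counts)
  pk <- which.max(cnt) - 1L
  flipped <- (pk - mn) > (mx - pk)   # put the long tail on the right
  if (flipped) {
    cnt <- rev(cnt)
    tmp <- mn; mn <- 255L - mx; mx <- 255L - tmp
    pk <- 255L - pk
  }
  if (pk >= mx) return(cut_value(h, if (flipped) 255L - pk else pk))
  # maximize distance from (i, h_i) to the line (pk, h_pk) -- (mx, h_mx)
  i <- pk:mx
  dx <- mx - pk; dy <- cnt[mx + 1] - cnt[pk + 1]
  d <- abs(dy * (i - pk) - dx * (cnt[i + 1] - cnt[pk + 1])) / sqrt(dx^2 + dy^2)
  t <- i[which.max(d)]
  if (flipped) t <- 255L - t
  cut_value(h, min(254L, t))
}

th_percentile <- function(h) {
  cum <- cumsum(h$p)
  cut_value(h, min(254L, which(cum >= 0.5)[1] - 1L))
}

th_moments <- function(h) {
  p <- h$p; i <- 0:255
  m1 <- sum(i * p); m2 <- sum(i^2 * p); m3 <- sum(i^3 * p)
  cd <- m2 - m1^2
  if (cd <= 0) return(cut_value(h, 127L))
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) return(cut_value(h, 127L))
  z0 <- 0.5 * (-c1 - sqrt(disc)); z1 <- 0.5 * (-c1 + sqrt(disc))
  pd <- (z1 - m1) / (z1 - z0)
  cum <- cumsum(p)
  t <- which(cum >= pd)[1] - 1L
  if (is.na(t)) t <- 127L
  cut_value(h, min(254L, max(0L, t)))
}

th_min_error <- function(h) {
  p <- h$p; i <- 0:255
  W <- cumsum(p); M <- cumsum(p * i); Q <- cumsum(p * i^2)
  best <- Inf; bt <- 127L
  for (t in 0:254) {
    P1 <- W[t + 1]; P2 <- 1 - P1
    if (P1 <= 0 || P2 <= 0) next
    mu1 <- M[t + 1] / P1; mu2 <- (M[256] - M[t + 1]) / P2
    v1 <- Q[t + 1] / P1 - mu1^2; v2 <- (Q[256] - Q[t + 1]) / P2 - mu2^2
    if (v1 <= 0 || v2 <= 0) next
    J <- 1 + 2 * (P1 * log(sqrt(v1)) + P2 * log(sqrt(v2))) -
      2 * (P1 * log(P1) + P2 * log(P2))
    if (J < best) { best <- J; bt <- t }
  }
  cut_value(h, bt)
}

smooth_until_bimodal <- function(cnt) {
  x <- as.numeric(cnt)
  n <- length(x)
  peaks <- function(v) sum(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n])
  it <- 0
  while (peaks(x) > 2 && it < 10000) {
    x <- (c(x[1], x[-n]) + x + c(x[-1], x[n])) / 3
    it <- it + 1
  }
  x
}

th_minimum <- function(h) {
  x <- smooth_until_bimodal(h$counts)
  n <- length(x)
  pk <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  if (length(pk) < 2) return(cut_value(h, 127L))
  lo <- pk[1]; hi <- pk[length(pk)]
  t <- (lo:hi)[which.min(x[lo:hi])] - 1L
  cut_value(h, min(254L, t))
}

th_intermodes <- function(h) {
  x <- smooth_until_bimodal(h$counts)
  n <- length(x)
  pk <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  if (length(pk) < 2) return(cut_value(h, 127L))
  t <- as.integer(round((pk[1] + pk[length(pk)]) / 2)) - 1L
  cut_value(h, min(254L, max(0L, t)))
}

# Renyi entropy maximization at order alpha = 2
th_renyi_entropy <- function(h) {
  p <- h$p
  P1 <- cumsum(p); S1 <- cumsum(p^2); S2 <- rev(cumsum(rev(p^2)))
  t <- 0:254
  a <- P1[t + 1]; b <- 1 - a
  valid <- a > 1e-12 & b > 1e-12 & S1[t + 1] > 0 & S2[t + 2] > 0
  crit <- rep(-Inf, 255)
  crit[valid] <- -log(S1[t + 1][valid] / a[valid]^2) -
    log(S2[t + 2][valid] / b[valid]^2)
  cut_value(h, which.max(crit) - 1L)
}

th_shanbhag <- function(h) {
  p <- h$p
  P1 <- cumsum(p); P2 <- 1 - P1
  best <- Inf; bt <- 127L
  for (t in 0:254) {
    if (P1[t + 1] <= 1e-12 || P2[t + 1] <= 1e-12) next
    term <- 1 / (2 * P1[t + 1])
    eb <- 0
    if (t >= 1) for (ih in 1:t) {
      arg <- 1 - term * P1[ih]
      if (arg > 0) eb <- eb - p[ih + 1] * log(arg)
    }
    eb <- eb * term
    term <- 1 / (2 * P2[t + 1])
    eo <- 0
    if (t + 2 <= 255) for (ih in (t + 1):254) {
      arg <- 1 - term * P2[ih + 2]
      if (arg > 0) eo <- eo - p[ih + 1] * log(arg)
    }
    eo <- eo * term
    tot <- abs(eb - eo)
    if (tot < best) { best <- tot; bt <- t }
  }
  cut_value(h, bt)
}

threshold_registry <- list(
  huang = th_huang, intermodes = th_intermodes, isodata = th_isodata,
  ij_isodata = th_ij_isodata, li = th_li, max_entropy = th_max_entropy,
  mean = th_mean, min_error = th_min_error, minimum = th_minimum,
  moments = th_moments, otsu = th_otsu, percentile = th_percentile,
  renyi_entropy = th_renyi_entropy, shanbhag = th_shanbhag,
  triangle = th_triangle, yen = th_yen)

#' Names of the available automatic threshold methods
#' @return character vector of registry names.
#' @export
threshold_methods <- function() names(threshold_registry)

#' Automatic intensity threshold
#'
#' Computes a threshold for the supplied pixel population as a deterministic
#' function of its 256-bin histogram (bins span the population min-max range).
#' Pixels at or above the returned value are treated as foreground.
#'
#' @param pixels numeric vector or matrix of intensities (>= 2 distinct values).
#' @param method registry name, see [threshold_methods()].
#' @return numeric threshold value within the intensity range.
#' @export
auto_threshold <- function(pixels, method = "otsu") {
  fn <- threshold_registry[[method]]
  if (is.null(fn)) stop("unknown threshold method '", method, "'")
  fn(build_hist256(as.numeric(pixels)))
}
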