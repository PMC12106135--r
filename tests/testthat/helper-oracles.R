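# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's implementation paths.

# set-arithmetic overlap metrics on index sets
oracle_dice <- function(P, GT) {
  p <- which(P > 0); g <- which(GT > 0)
  if (length(p) + length(g) == 0) return(1)
  2 * length(intersect(p, g)) / (length(p) + length(g))
}

oracle_iou <- function(P, GT) {
  p <- which(P > 0); g <- which(GT > 0)
  u <- union(p, g)
  if (length(u) == 0) return(1)
  length(intersect(p, g)) / length(u)
}

oracle_vs <- function(P, GT) {
  vp <- sum(P > 0); vg <- sum(GT > 0)
  if (vp + vg == 0) return(1)
  1 - abs(vp - vg) / (vp + vg)
}

# boundary pixels by explicit 4-neighbour loop
oracle_boundary <- function(m) {
  m <- (as.matrix(m) > 0) * 1L
  H <- nrow(m); W <- ncol(m)
  out <- NULL
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    if (m[r, cc] == 0) next
    # image border counts as background, matching the pinned convention
    nb <- c(
      if (r > 1) m[r - 1, cc] else 0L,
      if (r < H) m[r + 1, cc] else 0L,
      if (cc > 1) m[r, cc - 1] else 0L,
      if (cc < W) m[r, cc + 1] else 0L
    )
    if (any(nb == 0L)) out <- rbind(out, c(r, cc))
  }
  out
}

# exhaustive all-pairs percentile Hausdorff distance
oracle_hd <- function(P, GT, percentile = 95) {
  bp <- oracle_boundary(P); bg <- oracle_boundary(GT)
  d_ab <- apply(bp, 1, function(a) {
    min(sqrt((bg[, 1] - a[1])^2 + (bg[, 2] - a[2])^2))
  })
  d_ba <- apply(bg, 1, function(a) {
    min(sqrt((bp[, 1] - a[1])^2 + (bp[, 2] - a[2])^2))
  })
  unname(stats::quantile(c(d_ab, d_ba), percentile / 100, type = 7))
}

# brute-force signed distance to the 4-neighbour boundary set
oracle_sdm <- function(m) {
  m <- (as.matrix(m) > 0) * 1L
  b <- oracle_boundary(m)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    d <- min(sqrt((b[, 1] - r)^2 + (b[, 2] - cc)^2))
    out[r, cc] <- if (m[r, cc] == 1) -d else d
  }
  out
}

# random blobby binary mask (possibly empty)
random_mask <- function(n = 16, p_empty = 0.1) {
  if (stats::runif(1) < p_empty) return(matrix(0L, n, n))
  f <- matrix(stats::rnorm(n * n), n, n)
  f <- (f + f[n:1, ] + f[, n:1]) / 3
  sm <- f
  for (i in 1:2) {
    sm <- (sm +
      rbind(sm[-1, ], sm[n, ]) + rbind(sm[1, ], sm[-n, ]) +
      cbind(sm[, -1], sm[, n]) + cbind(sm[, 1], sm[, -n])) / 5
  }
  (sm > stats::quantile(sm, 0.8)) * 1L
}

# filled ellipse mask, optionally rotated (degrees CCW as displayed)
ellipse_mask <- function(n = 64, a = 0.25 * n, b = 0.4 * n, angle = 0) {
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  cx <- (n + 1) / 2
  x <- cc - cx
  y <- -(rr - cx)
  th <- -angle * pi / 180
  xr <- cos(th) * x - sin(th) * y
  yr <- sin(th) * x + cos(th) * y
  ((xr / a)^2 + (yr / b)^2 <= 1) * 1L
}

# centered filled square mask
square_mask <- function(n, lo, hi) {
  m <- matrix(0L, n, n)
  m[lo:hi, lo:hi] <- 1L
  m
}

tiny_phantom_spec <- function(seed = 1L, n_scans = 4) {
  phantom_spec(n_scans = n_scans, slices_per_scan = c(3, 4), image_size = 48,
               fraction_positive = 0.75, lesion_area_px = c(30, 120),
               seed = seed)
}

tiny_test_model <- function(seed = 1L, adapters = TRUE, dd = 1) {
  enc <- encoder_config(image_size = 32, patch_size = 8, embed_dim = 32,
                        depth = 2, heads = 2, global_attn_indices = 0:1,
                        mlp_ratio = 2)
  m <- build_model(enc, decoder_depth = dd, seed = seed)
  if (adapters) insert_adapters(m, adapter_config(m = 4), seed = seed + 1L)
  m
}
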