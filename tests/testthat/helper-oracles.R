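# Independent brute-force oracles and fixture builders. Every oracle here
# is a deliberately naive re-implementation (loops, sorting, exhaustive
# search) kept separate from the package's code paths.

# Chebyshev (chessboard) distances: outside = distance to nearest object
# pixel; inside = distance to nearest background pixel, counting the image
# border as background (matching clipped morphology).
oracle_cheb_outside <- function(obj) {
  pts <- which(obj, arr.ind = TRUE)
  out <- matrix(Inf, nrow(obj), ncol(obj))
  for (i in seq_len(nrow(obj)))
    for (j in seq_len(ncol(obj)))
      out[i, j] <- min(pmax(abs(pts[, 1] - i), abs(pts[, 2] - j)))
  out
}

oracle_cheb_inside <- function(obj) {
  bg <- which(!obj, arr.ind = TRUE)
  out <- matrix(Inf, nrow(obj), ncol(obj))
  for (i in seq_len(nrow(obj)))
    for (j in seq_len(ncol(obj))) {
      d_border <- min(i, j, nrow(obj) - i + 1, ncol(obj) - j + 1)
      d_bg <- if (nrow(bg)) min(pmax(abs(bg[, 1] - i), abs(bg[, 2] - j)))
        else Inf
      out[i, j] <- min(d_bg, d_border)
    }
  out
}

# Exact Euclidean signed boundary distance by brute force (outer products).
oracle_signed_euclid <- function(obj) {
  nr <- nrow(obj); nc <- ncol(obj)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  op <- which(obj)
  bp <- which(!obj)
  d_to <- function(targets) {
    tr <- (targets - 1) %% nr + 1
    tc <- (targets - 1) %/% nr + 1
    apply(cbind(as.vector(rr), as.vector(cc)), 1, function(p)
      sqrt(min((tr - p[1])^2 + (tc - p[2])^2)))
  }
  s <- matrix(d_to(op), nr, nc)
  s[obj] <- -matrix(d_to(bp), nr, nc)[obj]
  s
}

# Type-7 quantile written from the textbook definition.
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
}

# Exhaustive Otsu: maximise between-class variance over the same candidate
# edges the implementation uses, computed from raw values with loops.
oracle_otsu <- function(x, n_bins = 256) {
  v <- as.vector(x)
  edges <- seq(min(v), max(v), length.out = n_bins + 1)
  best <- -Inf; best_t <- edges[1]
  for (k in 2:n_bins) {
    t <- edges[k]
    g0 <- v[v <= t]; g1 <- v[v > t]
    if (length(g0) == 0 || length(g1) == 0) next
    w0 <- length(g0) / length(v); w1 <- 1 - w0
    bc <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (bc > best) { best <- bc; best_t <- t }
  }
  best_t
}

# O(n^2) pairwise RMS-vs-length curve with explicit loops.
oracle_rms_curve <- function(pre, post, bin_width, n_bins, pixel_size = 1) {
  n <- nrow(pre)
  sums <- numeric(n_bins); counts <- integer(n_bins)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      L <- sqrt(sum((pre[i, ] - pre[j, ])^2)) * pixel_size
      Lp <- sqrt(sum((post[i, ] - post[j, ])^2)) * pixel_size
      b <- floor(L / bin_width) + 1
      if (b >= 1 && b <= n_bins) {
        sums[b] <- sums[b] + (L - Lp)^2
        counts[b] <- counts[b] + 1L
      }
    }
  }
  list(rms = ifelse(counts > 0, sqrt(sums / pmax(counts, 1)), NA_real_),
       n = counts)
}

# Random connected blob for ring-algebra tests: threshold smoothed noise,
# keep the component containing the strongest pixel.
random_blob <- function(n, seed, density = 0.45) {
  set.seed(seed)
  sm <- gaussian_blur(matrix(runif(n * n), n, n), 2)
  fg <- sm >= quantile(sm, 1 - density)
  lab <- label_components(fg)
  strongest <- lab[which.max(sm * fg)]
  lab == strongest
}

# Small two-vessel phantom spec reused across anchoring tests.
demo_layers <- function(amplitude = 50) list(
  list(marker = "SAA", offset_px = -10, thickness_px = 2,
       amplitude = amplitude),
  list(marker = "GLUT1", offset_px = 0, thickness_px = 2,
       amplitude = amplitude),
  list(marker = "CollagenIV", offset_px = 3, thickness_px = 2,
       amplitude = amplitude),
  list(marker = "GlnSyn", offset_px = 8, thickness_px = 2,
       amplitude = amplitude))

# Grid of jittered vessels for multi-vessel phantoms.
grid_vessels <- function(n_grid, spacing, jitter = 6, seed = 11,
                         lumen = 12, wall = 4) {
  set.seed(seed)
  g <- expand.grid(r = seq(spacing, spacing * n_grid, by = spacing),
                   c = seq(spacing, spacing * n_grid, by = spacing))
  lapply(seq_len(nrow(g)), function(i)
    list(center = c(g$r[i], g$c[i]) + runif(2, -jitter, jitter),
         lumen_radius_px = lumen, wall_thickness_px = wall))
}

# Textured reference image for registration tests.
textured_image <- function(n = 200, seed = 21, sigma = 2.2) {
  set.seed(seed)
  gaussian_blur(matrix(runif(n * n, 0, 100), n, n), sigma)
}
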