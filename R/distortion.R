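## Deformation quantification between paired images (e.g. pre- vs
## post-compression gels): rolling-ball background subtraction, landmark
## detection, affine + nonrigid alignment, and the RMS curve of pairwise
## feature-distance changes versus measurement length. The affine stage
## removes global pose and scale; the nonrigid field supplies the
## correspondence whose residual pairwise-distance changes measure
## distortion.

#' Rolling-ball background subtraction
#'
#' The background is the grayscale morphological opening with a disc of the
#' given radius (the classical rolling-ball estimate); the result is the
#' input minus this background, floored at zero. A constant image maps to
#' all zeros; peaks narrower than the ball are preserved.
#'
#' @param x Numeric matrix or [multiplex_image()] (applied per channel).
#' @param radius_px Ball radius in pixels (default 50).
#' @return Background-subtracted object of the same type.
#' @export
rolling_ball_background <- function(x, radius_px = 50) {
  stopifnot(radius_px >= 1)
  se <- se_offsets("disc", radius_px)
  sub1 <- function(m) {
    bg <- gray_dilate(gray_erode(m, se), se)
    pmax(m - bg, 0)
  }
  if (inherits(x, "multiplex_image")) {
    x$channels <- lapply(x$channels, sub1)
    x
  } else sub1(x)
}

#' Detect point landmarks as smoothed local maxima
#'
#' Local maxima of the Gaussian-smoothed channel above
#' `threshold_rel * max`, greedily thinned so no two kept landmarks are
#' closer than `min_distance_px`. Candidates are visited in deterministic
#' order: descending intensity, ties by reading order.
#'
#' @param x Numeric matrix or [multiplex_image()].
#' @param channel Channel name (required for a [multiplex_image()]).
#' @param min_distance_px Minimum separation of kept landmarks.
#' @param threshold_rel Relative intensity threshold in (0, 1).
#' @param sigma_px Smoothing sigma.
#' @param exclude_border_px Ignore maxima within this margin of the image
#'   border (border maxima are artefacts of the clipped neighbourhood, and
#'   displacement fields are least reliable there).
#' @return A `landmark_set`: numeric matrix of (row, col), 0-based, with
#'   attribute `intensity`.
#' @export
detect_landmarks <- function(x, channel = NULL, min_distance_px = 10,
                             threshold_rel = 0.1, sigma_px = 2,
                             exclude_border_px = 0) {
  m <- if (inherits(x, "multiplex_image")) get_channel(x, channel) else x
  sm <- gaussian_blur(m, sigma_px)
  mx <- gray_dilate(sm, se_offsets("square"))
  keep <- sm >= mx & sm > threshold_rel * max(sm)
  if (exclude_border_px > 0) {
    b <- exclude_border_px
    keep[c(seq_len(min(b, nrow(m))),
           seq(max(1, nrow(m) - b + 1), nrow(m))), ] <- FALSE
    keep[, c(seq_len(min(b, ncol(m))),
             seq(max(1, ncol(m) - b + 1), ncol(m)))] <- FALSE
  }
  cand <- which(keep)
  if (length(cand) == 0)
    stop("no landmarks found; lower threshold_rel or sigma_px")
  r0 <- (cand - 1) %% nrow(m)
  c0 <- (cand - 1) %/% nrow(m)
  ord <- order(-sm[cand], r0, c0)
  r0 <- r0[ord]; c0 <- c0[ord]; val <- sm[cand][ord]
  keep_r <- numeric(0); keep_c <- numeric(0); keep_v <- numeric(0)
  for (i in seq_along(r0)) {
    if (length(keep_r) == 0 ||
        all((keep_r - r0[i])^2 + (keep_c - c0[i])^2 >= min_distance_px^2)) {
      keep_r <- c(keep_r, r0[i]); keep_c <- c(keep_c, c0[i])
      keep_v <- c(keep_v, val[i])
    }
  }
  pts <- cbind(row = keep_r, col = keep_c)
  attr(pts, "intensity") <- keep_v
  class(pts) <- c("landmark_set", class(pts))
  pts
}

.affine_resample <- function(moving, theta, center) {
  nr <- nrow(moving); nc <- ncol(moving)
  R <- matrix(0:(nr - 1), nr, nc) - center[1]
  C <- matrix(0:(nc - 1), nr, nc, byrow = TRUE) - center[2]
  qr <- theta[3] * R + theta[4] * C + center[1] + theta[1]
  qc <- theta[5] * R + theta[6] * C + center[2] + theta[2]
  matrix(cpp_bilinear(moving, as.vector(qr), as.vector(qc)), nr, nc)
}

#' Register a moving image to a fixed image
#'
#' The affine stage minimises the mean squared intensity difference over a
#' multi-resolution pyramid (full 6-parameter affine, Nelder-Mead). The
#' optional nonrigid stage then estimates a smooth residual displacement
#' field on a control grid by local block matching against the
#' affine-registered moving image, with subpixel quadratic refinement, and
#' interpolates it with tensor-product natural cubic splines. An externally
#' computed displacement field can be supplied through `true_field`, in
#' which case no nonrigid estimation is performed.
#'
#' @param fixed,moving Single-channel numeric matrices of equal size.
#' @param stage `"affine"` or `"affine+nonrigid"`.
#' @param control_spacing_px Control-grid spacing for the nonrigid stage.
#' @param search_px Integer block-matching search radius (default
#'   `ceiling(control_spacing_px / 4)`).
#' @param true_field Optional [warp_field()] to use instead of nonrigid
#'   estimation.
#' @param maxit Optimiser iteration cap per pyramid level.
#' @return A `registration`: list with `theta` (tx, ty, a11, a12, a21, a22),
#'   `center`, `field` (a [warp_field()] or NULL), `registered` (the moving
#'   image resampled into the fixed frame) and `loss` (initial/final mean
#'   squared difference).
#' @export
register_images <- function(fixed, moving,
                            stage = c("affine", "affine+nonrigid"),
                            control_spacing_px = 32, search_px = NULL,
                            true_field = NULL, maxit = 400) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(fixed), identical(dim(fixed), dim(moving)))
  # image pyramid, coarsest ~>= 32 px
  pyr_f <- list(fixed); pyr_m <- list(moving)
  while (min(dim(pyr_f[[1]])) >= 64) {
    pyr_f <- c(list(.downsample2(pyr_f[[1]])), pyr_f)
    pyr_m <- c(list(.downsample2(pyr_m[[1]])), pyr_m)
  }
  identity6 <- c(0, 0, 1, 0, 0, 1)
  theta <- identity6
  for (lev in seq_along(pyr_f)) {
    f <- pyr_f[[lev]]; m <- pyr_m[[lev]]
    ctr <- (dim(f) - 1) / 2
    obj <- function(th) mean((f - .affine_resample(m, th, ctr))^2)
    fit <- optim(theta, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit,
                                parscale = c(1, 1, 0.01, 0.01, 0.01, 0.01),
                                reltol = 1e-10))
    theta <- fit$par
    if (lev < length(pyr_f)) theta[1:2] <- theta[1:2] *
        dim(pyr_f[[lev + 1]])[1] / dim(f)[1]
  }
  ctr <- (dim(fixed) - 1) / 2
  registered <- .affine_resample(moving, theta, ctr)
  loss0 <- mean((fixed - moving)^2) # identity-alignment loss at full res
  loss1 <- mean((fixed - registered)^2)
  if (loss1 > loss0 * (1 + 1e-6) && loss1 > 1e-12)
    stop(sprintf(paste0("registration did not converge: loss %.4g -> %.4g ",
                        "(try more levels or smoother inputs)"),
                 loss0, loss1))
  field <- NULL
  if (!is.null(true_field)) {
    field <- true_field
  } else if (stage == "affine+nonrigid") {
    # iterative block matching: estimate, apply, re-estimate the residual
    search <- if (is.null(search_px)) ceiling(control_spacing_px / 4)
      else search_px
    cur <- registered
    for (it in 1:3) {
      f_it <- .block_match_field(fixed, cur, control_spacing_px,
                                 if (it == 1) search else max(2, ceiling(search / 2)))
      if (is.null(field)) {
        field <- f_it
      } else {
        # compose: total(p) = f(p) + f_it(p + f(p))
        nr <- nrow(fixed); nc <- ncol(fixed)
        R <- matrix(0:(nr - 1), nr, nc) + field$drow
        C <- matrix(0:(nc - 1), nr, nc, byrow = TRUE) + field$dcol
        add_r <- matrix(cpp_bilinear(f_it$drow, as.vector(R), as.vector(C)),
                        nr, nc)
        add_c <- matrix(cpp_bilinear(f_it$dcol, as.vector(R), as.vector(C)),
                        nr, nc)
        field <- warp_field(field$drow + add_r, field$dcol + add_c)
      }
      cur <- apply_warp(registered, field)
      if (max(abs(f_it$drow), abs(f_it$dcol)) < 0.05) break
    }
  }
  if (!is.null(field) && is.null(true_field)) {
    registered <- cur
  } else if (!is.null(field)) {
    registered <- apply_warp(registered, field)
  }
  structure(list(theta = theta, center = ctr, field = field,
                 registered = registered, loss = c(initial = loss0,
                                                   final = loss1)),
            class = "registration")
}

## Estimate a smooth residual displacement field by block matching on a
## control grid (integer search + 1-D quadratic subpixel refinement), then
## spline-interpolate to a dense field.
.block_match_field <- function(fixed, aligned, spacing, search) {
  nr <- nrow(fixed); nc <- ncol(fixed)
  # include border nodes so the spline never extrapolates inside the image
  ctrl_r <- unique(c(0, seq(spacing, nr - 1 - spacing, by = spacing), nr - 1))
  ctrl_c <- unique(c(0, seq(spacing, nc - 1 - spacing, by = spacing), nc - 1))
  if (length(ctrl_r) < 2 || length(ctrl_c) < 2)
    stop("control_spacing_px too large for the image")
  half <- floor(spacing / 2)
  ur <- matrix(0, length(ctrl_r), length(ctrl_c))
  uc <- ur
  for (i in seq_along(ctrl_r)) {
    for (j in seq_along(ctrl_c)) {
      r <- ctrl_r[i]; c <- ctrl_c[j]
      rs <- max(0, r - half):min(nr - 1, r + half)
      cs <- max(0, c - half):min(nc - 1, c + half)
      patch <- fixed[rs + 1, cs + 1]
      ssd <- matrix(NA_real_, 2 * search + 1, 2 * search + 1)
      for (dr in -search:search) {
        rs2 <- rs + dr
        if (min(rs2) < 0 || max(rs2) > nr - 1) next
        for (dc in -search:search) {
          cs2 <- cs + dc
          if (min(cs2) < 0 || max(cs2) > nc - 1) next
          ssd[dr + search + 1, dc + search + 1] <-
            mean((patch - aligned[rs2 + 1, cs2 + 1])^2)
        }
      }
      best <- which(ssd == min(ssd, na.rm = TRUE), arr.ind = TRUE)[1, ]
      dr <- best[1] - search - 1; dc <- best[2] - search - 1
      # quadratic subpixel refinement along each axis where interior
      sub <- function(a, b, c_) if (is.finite(a) && is.finite(c_) &&
                                    (a - 2 * b + c_) > 0)
        0.5 * (a - c_) / (a - 2 * b + c_) else 0
      fr <- if (abs(dr) < search)
        sub(ssd[dr + search, dc + search + 1],
            ssd[dr + search + 1, dc + search + 1],
            ssd[dr + search + 2, dc + search + 1]) else 0
      fc <- if (abs(dc) < search)
        sub(ssd[dr + search + 1, dc + search],
            ssd[dr + search + 1, dc + search + 1],
            ssd[dr + search + 1, dc + search + 2]) else 0
      ur[i, j] <- dr + fr
      uc[i, j] <- dc + fc
    }
  }
  drow <- interp_spline_grid(ur, ctrl_r, ctrl_c, nr, nc)
  dcol <- interp_spline_grid(uc, ctrl_r, ctrl_c, nr, nc)
  warp_field(drow, dcol)
}

#' Displace landmark positions by a warp field
#'
#' Returns `p + u(p)` for each landmark, sampling the field bilinearly:
#' the affine-frame positions whose pairwise distances carry the residual
#' (nonrigid) distortion.
#'
#' @param landmarks Matrix of (row, col) positions, 0-based.
#' @param field A [warp_field()] (NULL = identity).
#' @return Matrix of displaced (row, col) positions.
#' @export
map_landmarks <- function(landmarks, field) {
  pts <- unclass(landmarks)[, 1:2, drop = FALSE]
  if (is.null(field)) return(pts)
  dr <- bilinear_sample(field$drow, pts[, 1], pts[, 2])
  dc <- bilinear_sample(field$dcol, pts[, 1], pts[, 2])
  cbind(row = pts[, 1] + dr, col = pts[, 2] + dc)
}

#' Map landmarks through a full registration transform
#'
#' Returns `A (p + f(p) - ctr) + ctr + t`: the position in the moving image
#' corresponding to fixed-frame landmark `p` under the composed affine +
#' nonrigid transform. Use [map_landmarks()] with `reg$field` instead when
#' the global pose/scale should be removed (the distortion-curve
#' convention).
#'
#' @param reg A [register_images()] result.
#' @param landmarks Matrix of fixed-frame (row, col) positions, 0-based.
#' @return Matrix of corresponding moving-frame positions.
#' @export
transform_landmarks <- function(reg, landmarks) {
  stopifnot(inherits(reg, "registration"))
  p <- map_landmarks(landmarks, reg$field) # identity when field is NULL
  th <- reg$theta
  r <- p[, 1] - reg$center[1]; c <- p[, 2] - reg$center[2]
  cbind(row = th[3] * r + th[4] * c + reg$center[1] + th[1],
        col = th[5] * r + th[6] * c + reg$center[2] + th[2])
}

#' RMS distortion versus measurement length
#'
#' For every unordered landmark pair the physical distance `L` in the
#' reference positions and `L'` in the mapped positions are compared;
#' `e = |L - L'|` is binned by `L` into `n_bins` contiguous bins of width
#' `bin_width_um` and summarised as per-bin RMS. Defaults follow the
#' standard presentation: 12.15 um bins, 100 bins.
#'
#' @param landmarks_pre Matrix of reference (row, col) positions, 0-based
#'   pixels.
#' @param mapped_post Matrix of corresponding mapped positions (same order),
#'   e.g. from [map_landmarks()].
#' @param bin_width_um Bin width in micrometres.
#' @param n_bins Number of bins.
#' @param pixel_size_um Micrometres per pixel of the position grid.
#' @return A `distortion_curve` data frame: `bin_lo_um`, `bin_hi_um`,
#'   `bin_center_um`, `rms_um`, `n_pairs` (`rms_um` is `NA` for empty
#'   bins).
#' @export
rms_vs_length <- function(landmarks_pre, mapped_post, bin_width_um = 12.15,
                          n_bins = 100, pixel_size_um = 1) {
  pre <- unclass(landmarks_pre)[, 1:2, drop = FALSE]
  post <- unclass(mapped_post)[, 1:2, drop = FALSE]
  stopifnot(nrow(pre) == nrow(post), bin_width_um > 0, n_bins >= 1)
  if (nrow(pre) < 2) stop("need at least 2 landmarks")
  L <- as.vector(dist(pre)) * pixel_size_um
  Lp <- as.vector(dist(post)) * pixel_size_um
  e <- abs(L - Lp)
  bin <- findInterval(L, seq(0, n_bins * bin_width_um, by = bin_width_um),
                      rightmost.closed = FALSE)
  keep <- bin >= 1 & bin <= n_bins
  rms <- rep(NA_real_, n_bins)
  npair <- integer(n_bins)
  if (any(keep)) {
    agg <- tapply(e[keep]^2, factor(bin[keep], levels = seq_len(n_bins)),
                  mean)
    rms <- sqrt(as.numeric(agg))
    npair <- as.integer(table(factor(bin[keep], levels = seq_len(n_bins))))
  }
  lo <- (seq_len(n_bins) - 1) * bin_width_um
  out <- data.frame(bin_lo_um = lo, bin_hi_um = lo + bin_width_um,
                    bin_center_um = lo + bin_width_um / 2, rms_um = rms,
                    n_pairs = npair)
  class(out) <- c("distortion_curve", class(out))
  out
}

#' Aggregate distortion curves across replicate regions
#'
#' @param curves List of [rms_vs_length()] results with identical binning.
#' @return Data frame with per-bin `mean_rms_um`, `sd_rms_um` and
#'   `n_curves` (replicates with pairs in that bin; empty bins are excluded
#'   from that bin's aggregation).
#' @export
aggregate_curves <- function(curves) {
  stopifnot(length(curves) >= 1)
  ref <- curves[[1]]
  for (cv in curves)
    if (!identical(cv$bin_lo_um, ref$bin_lo_um))
      stop("curves have mismatched binning")
  vals <- vapply(curves, function(cv) cv$rms_um, numeric(nrow(ref)))
  vals <- matrix(vals, nrow = nrow(ref))
  n <- rowSums(!is.na(vals))
  out <- data.frame(
    bin_lo_um = ref$bin_lo_um, bin_hi_um = ref$bin_hi_um,
    bin_center_um = ref$bin_center_um,
    mean_rms_um = ifelse(n > 0, rowMeans(vals, na.rm = TRUE), NA_real_),
    sd_rms_um = apply(vals, 1, function(x)
      if (sum(!is.na(x)) >= 2) sd(x, na.rm = TRUE)
      else if (sum(!is.na(x)) == 1) 0 else NA_real_),
    n_curves = n)
  class(out) <- c("distortion_curve_summary", class(out))
  out
}
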