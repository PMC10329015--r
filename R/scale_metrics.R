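## Expansion-fold estimation by three concordant strategies, line-scan
## profiles, edge-spread resolution by the 16-84% criterion, and per-FOV
## channel sums.

#' Matched landmark pairs between a pre- and post-expansion image
#'
#' @param pre,post Numeric matrices (n x 2) of (row, col) coordinates of the
#'   same features in the pre- and post-expansion images.
#' @param pixel_size_pre_um,pixel_size_post_um Physical pixel sizes.
#' @return A `landmark_pairs` object.
#' @export
landmark_pairs <- function(pre, post, pixel_size_pre_um = 1,
                           pixel_size_post_um = pixel_size_pre_um) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  stopifnot(ncol(pre) == 2, ncol(post) == 2, nrow(pre) == nrow(post),
            all(is.finite(pre)), all(is.finite(post)),
            pixel_size_pre_um > 0, pixel_size_post_um > 0)
  if (nrow(pre) < 2) stop("at least 2 matched landmarks are required")
  structure(list(pre = pre, post = post,
                 pixel_size_pre_um = pixel_size_pre_um,
                 pixel_size_post_um = pixel_size_post_um),
            class = "landmark_pairs")
}

.fold_estimate <- function(method, fold, dispersion = NA_real_, n = NA_integer_) {
  stopifnot(fold > 0)
  structure(list(method = method, fold = fold, dispersion = dispersion,
                 n = n), class = "fold_estimate")
}

#' @export
print.fold_estimate <- function(x, ...) {
  cat(sprintf("<fold_estimate> method=%s fold=%.4f sd=%s n=%s\n", x$method,
              x$fold, format(x$dispersion), format(x$n)))
  invisible(x)
}

#' Linear expansion fold from landmark distances
#'
#' For every unordered pair of matched landmarks the ratio of physical
#' distances (post / pre) is computed; the estimate is the mean over pairs
#' with its SD. Pairs with coincident pre-landmarks are skipped with a
#' warning.
#'
#' @param pairs A [landmark_pairs()].
#' @return A `fold_estimate` (method "linear").
#' @export
fold_linear <- function(pairs) {
  stopifnot(inherits(pairs, "landmark_pairs"))
  d_pre <- as.vector(dist(pairs$pre)) * pairs$pixel_size_pre_um
  d_post <- as.vector(dist(pairs$post)) * pairs$pixel_size_post_um
  bad <- d_pre < 1e-9
  if (any(bad)) {
    warning(sum(bad), " coincident pre-landmark pair(s) skipped")
    d_pre <- d_pre[!bad]; d_post <- d_post[!bad]
  }
  if (length(d_pre) == 0) stop("no usable landmark pairs")
  ratios <- d_post / d_pre
  .fold_estimate("linear", mean(ratios),
                 if (length(ratios) > 1) sd(ratios) else 0,
                 length(ratios))
}

#' Linear expansion fold from tissue areas
#'
#' `sqrt` of the ratio of physical foreground areas, so the result is on
#' the same linear axis as the other estimators.
#'
#' @param mask_pre,mask_post Logical or [label_mask()] matrices (foreground
#'   = tissue).
#' @param pixel_size_pre_um,pixel_size_post_um Physical pixel sizes.
#' @return A `fold_estimate` (method "area").
#' @export
fold_area <- function(mask_pre, mask_post, pixel_size_pre_um = 1,
                      pixel_size_post_um = pixel_size_pre_um) {
  a_pre <- sum(mask_pre > 0) * pixel_size_pre_um^2
  a_post <- sum(mask_post > 0) * pixel_size_post_um^2
  if (a_pre == 0 || a_post == 0) stop("empty tissue mask")
  .fold_estimate("area", sqrt(a_post / a_pre), NA_real_, 1L)
}

#' Linear expansion fold from cell-size distributions
#'
#' `sqrt` of the ratio of a location statistic (median or mean) of physical
#' cell areas between a post- and a pre-expansion cell table.
#'
#' @param cells_pre,cells_post [quantify_cells()] tables.
#' @param statistic `"median"` (default) or `"mean"`.
#' @param pixel_size_pre_um,pixel_size_post_um Physical pixel sizes.
#' @param min_cells Minimum cells required in each table.
#' @return A `fold_estimate` (method "segmentation").
#' @export
fold_segmentation <- function(cells_pre, cells_post,
                              statistic = c("median", "mean"),
                              pixel_size_pre_um = 1,
                              pixel_size_post_um = pixel_size_pre_um,
                              min_cells = 20) {
  statistic <- match.arg(statistic)
  if (nrow(cells_pre) < min_cells || nrow(cells_post) < min_cells)
    stop("need at least ", min_cells, " cells in each table")
  f <- if (statistic == "median") median else mean
  a_pre <- f(cells_pre$area_px) * pixel_size_pre_um^2
  a_post <- f(cells_post$area_px) * pixel_size_post_um^2
  .fold_estimate("segmentation", sqrt(a_post / a_pre), NA_real_,
                 min(nrow(cells_pre), nrow(cells_post)))
}

#' Line-scan intensity profile
#'
#' Samples a channel at unit-pixel spacing along a segment with bilinear
#' interpolation. Positions are reported in pre-expansion micrometres
#' (pixel distance * pixel size / expansion fold), the scale-bar convention
#' for expanded gels.
#'
#' @param image A [multiplex_image()].
#' @param channel Channel name.
#' @param p0,p1 Endpoints `c(row, col)` in 0-based pixel coordinates, inside
#'   the image.
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @return A `line_profile`: list with `position_um` (strictly increasing),
#'   `intensity`, `channel`, `endpoints`, `pixel_size_um`,
#'   `expansion_fold`.
#' @export
line_profile <- function(image, channel, p0, p1,
                         interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(image, "multiplex_image"), length(p0) == 2,
            length(p1) == 2)
  d <- dim(image)
  for (p in list(p0, p1))
    if (p[1] < 0 || p[1] > d[1] - 1 || p[2] < 0 || p[2] > d[2] - 1)
      stop("line endpoint outside the image: (", p[1], ", ", p[2], ")")
  ch <- get_channel(image, channel)
  len <- sqrt(sum((p1 - p0)^2))
  n <- floor(len) + 1
  t <- if (len > 0) seq(0, 1, length.out = n) * len else 0
  u <- if (len > 0) (p1 - p0) / len else c(0, 0)
  rows <- p0[1] + t * u[1]
  cols <- p0[2] + t * u[2]
  intensity <- if (interpolation == "linear") bilinear_sample(ch, rows, cols)
    else ch[cbind(pmin(pmax(round(rows), 0), d[1] - 1) + 1,
                  pmin(pmax(round(cols), 0), d[2] - 1) + 1)]
  structure(list(position_um = t * image$pixel_size_um / image$expansion_fold,
                 intensity = as.numeric(intensity), channel = channel,
                 endpoints = rbind(p0, p1),
                 pixel_size_um = image$pixel_size_um,
                 expansion_fold = image$expansion_fold),
            class = "line_profile")
}

#' Construct a line profile from raw vectors
#'
#' Convenience constructor for resolution analysis of externally produced
#' scans.
#'
#' @param position_um Strictly increasing physical positions.
#' @param intensity Intensities at those positions.
#' @param channel Channel name annotation.
#' @return A `line_profile`.
#' @export
as_line_profile <- function(position_um, intensity, channel = "") {
  stopifnot(length(position_um) == length(intensity),
            all(diff(position_um) > 0))
  structure(list(position_um = position_um, intensity = intensity,
                 channel = channel, endpoints = NULL, pixel_size_um = NA,
                 expansion_fold = NA), class = "line_profile")
}

#' Edge-spread resolution by the 16-84% criterion
#'
#' The profile must cross a single monotone edge between two plateaus. The
#' low/high plateaus are estimated as the means of the first and last
#' `plateau_frac` of samples; the positions where the profile crosses
#' low + 0.16 (high - low) and low + 0.84 (high - low) are found by linear
#' interpolation, and their distance (in the profile's physical units) is
#' the resolution estimate. For a Gaussian-blurred edge of width sigma this
#' distance equals 2 sigma. Falling edges are handled by reversal; the
#' estimate is invariant to affine intensity transforms a*I + b (a > 0).
#'
#' @param profile A [line_profile()].
#' @param plateau_frac Fraction of samples in each plateau window (default
#'   0.1).
#' @return The 16-84% distance (same units as `position_um`).
#' @export
resolution_16_84 <- function(profile, plateau_frac = 0.1) {
  stopifnot(inherits(profile, "line_profile"), plateau_frac > 0,
            plateau_frac < 0.5)
  x <- profile$position_um
  v <- profile$intensity
  n <- length(v)
  if (n < 5) stop("profile too short for plateau estimation")
  nw <- max(1, floor(plateau_frac * n))
  lo <- mean(v[seq_len(nw)])
  hi <- mean(v[seq(n - nw + 1, n)])
  if (hi < lo) { v <- rev(v); x <- rev(-x); tmp <- lo; lo <- hi; hi <- tmp }
  if (hi - lo <= 0 ||
      hi - lo < 1e-9 * max(abs(c(lo, hi)), 1))
    stop("plateau check failed: no edge amplitude between end plateaus")
  cross <- function(level) {
    above <- v >= level
    ix <- which(diff(above) != 0)
    if (length(ix) == 0)
      stop("crossing check failed: profile never crosses the ",
           "interpolation level")
    if (length(ix) > 1)
      stop("monotonicity check failed: profile crosses a level more ",
           "than once (not a single edge)")
    i <- ix[1]
    x[i] + (level - v[i]) / (v[i + 1] - v[i]) * (x[i + 1] - x[i])
  }
  x16 <- cross(lo + 0.16 * (hi - lo))
  x84 <- cross(lo + 0.84 * (hi - lo))
  abs(x84 - x16)
}

#' Summarise resolution across line scans
#'
#' @param distances Numeric vector of per-scan 16-84% distances, or a list
#'   of [line_profile()] objects (each measured first).
#' @return A `resolution_estimate`: list with `distances`, `mean`, `sd`,
#'   `n_scans`.
#' @export
summarize_resolution <- function(distances) {
  if (is.list(distances))
    distances <- vapply(distances, resolution_16_84, numeric(1))
  stopifnot(length(distances) >= 1, all(distances > 0))
  structure(list(distances = distances, mean = mean(distances),
                 sd = if (length(distances) > 1) sd(distances) else 0,
                 n_scans = length(distances)),
            class = "resolution_estimate")
}

#' Per-FOV channel sums
#'
#' Total counts per channel per field of view (e.g. nuclear-signal totals
#' for long-term storage monitoring).
#'
#' @param fovs List of [multiplex_image()] objects.
#' @param channels Channel names, present in every FOV.
#' @return Data frame: `fov` plus one column per channel.
#' @export
sum_channels <- function(fovs, channels) {
  stopifnot(length(fovs) >= 1)
  rows <- lapply(fovs, function(img) {
    stopifnot(inherits(img, "multiplex_image"))
    sums <- vapply(channels, function(ch) sum(get_channel(img, ch)),
                   numeric(1))
    c(list(fov = img$fov_id), as.list(sums))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Screening success percentage
#'
#' Percentage of successes among trials (e.g. antibodies validated out of
#' antibodies screened).
#'
#' @param n_success,n_total Non-negative counts, `n_success <= n_total > 0`.
#' @return Percentage (0-100).
#' @export
success_rate <- function(n_success, n_total) {
  stopifnot(n_total > 0, n_success >= 0, n_success <= n_total)
  100 * n_success / n_total
}
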