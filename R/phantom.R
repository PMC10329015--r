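## Synthetic phantoms with analytic ground truth: circular vessel
## cross-sections carrying concentric marker layers at known signed radial
## offsets, nuclear cell fields, Poisson count noise, known rescalings and
## known smooth warp fields. Every generator is a pure function of
## (spec, seed).

#' Phantom specification for vessel images
#'
#' Vessels are circular cross-sections: a lumen disc of radius
#' `lumen_radius_px` dilated by `wall_thickness_px` forms the vessel object.
#' Each marker layer paints `amplitude` expected counts/px on the annulus of
#' signed Euclidean boundary distance `[offset_px - thickness_px/2,
#' offset_px + thickness_px/2]` around every vessel object (negative offsets
#' lie inside the object, toward the lumen), on top of `background_rate`
#' everywhere. The signed distance is measured from the discretised object
#' mask by distance transform, the same convention used by Euclidean step
#' rings.
#'
#' @param width_px,height_px Image size in pixels.
#' @param vessels List of vessels, each `list(center = c(row, col),
#'   lumen_radius_px =, wall_thickness_px =)` (0-based centres, may be
#'   fractional).
#' @param layers List of marker layers, each `list(marker =, offset_px =,
#'   thickness_px =, amplitude =)`; marker names must be unique.
#' @param background_rate Expected background counts/px (all markers).
#' @param pixel_size_um Physical pixel size.
#' @param expansion_fold Expansion-fold annotation of the generated image.
#' @param border_safe If TRUE (default) every vessel object disc must lie
#'   fully inside the image; violations raise an error naming the vessel.
#' @param seed Integer seed used when Poisson noise is requested.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(width_px, height_px, vessels = list(),
                         layers = list(), background_rate = 0,
                         pixel_size_um = 0.39, expansion_fold = 3.7,
                         border_safe = TRUE, seed = 1L) {
  stopifnot(width_px >= 1, height_px >= 1, background_rate >= 0,
            pixel_size_um > 0)
  for (v in vessels)
    stopifnot(length(v$center) == 2, v$lumen_radius_px > 0,
              v$wall_thickness_px > 0)
  nm <- vapply(layers, function(l) l$marker, character(1))
  if (anyDuplicated(nm)) stop("layer marker names must be unique")
  for (l in layers) stopifnot(l$thickness_px > 0, l$amplitude >= 0)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px), vessels = vessels,
                 layers = layers, background_rate = background_rate,
                 pixel_size_um = pixel_size_um,
                 expansion_fold = expansion_fold,
                 border_safe = isTRUE(border_safe), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a vessel phantom
#'
#' @param spec A [phantom_spec()].
#' @param poisson If TRUE, channels are Poisson samples of the expected
#'   counts (deterministic under `spec$seed`); otherwise the noise-free
#'   expectations are returned.
#' @return List with `image` (a [multiplex_image()]), `mask` (a
#'   [label_mask()] of vessel objects, one label per vessel in input order)
#'   and `truth` (named numeric vector marker -> offset_px).
#' @export
make_vessel_phantom <- function(spec, poisson = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height_px; w <- spec$width_px
  mask <- matrix(0L, h, w)
  rr <- matrix(0:(h - 1), h, w)
  cc <- matrix(0:(w - 1), h, w, byrow = TRUE)
  obj_masks <- list()
  for (i in seq_along(spec$vessels)) {
    v <- spec$vessels[[i]]
    r_obj <- v$lumen_radius_px + v$wall_thickness_px
    if (spec$border_safe &&
        (v$center[1] - r_obj < 0 || v$center[1] + r_obj > h - 1 ||
         v$center[2] - r_obj < 0 || v$center[2] + r_obj > w - 1))
      stop("vessel ", i, " violates border_safe: object disc of radius ",
           r_obj, " leaves the image")
    inside <- (rr - v$center[1])^2 + (cc - v$center[2])^2 <= r_obj^2
    obj_masks[[i]] <- inside
    mask[inside] <- i
  }
  channels <- lapply(spec$layers, function(l) {
    ch <- matrix(spec$background_rate, h, w)
    lo <- l$offset_px - l$thickness_px / 2
    hi <- l$offset_px + l$thickness_px / 2
    for (om in obj_masks) {
      s <- signed_boundary_distance(om)
      ch[s >= lo & s <= hi] <- l$amplitude # replaces background on the annulus
    }
    ch
  })
  names(channels) <- vapply(spec$layers, `[[`, character(1), "marker")
  img <- multiplex_image(channels, pixel_size_um = spec$pixel_size_um,
                         expansion_fold = spec$expansion_fold,
                         fov_id = "phantom")
  if (poisson) img <- add_poisson_noise(img, seed = spec$seed)
  truth <- vapply(spec$layers, `[[`, numeric(1), "offset_px")
  names(truth) <- names(channels)
  list(image = img, mask = label_mask(mask), truth = truth)
}

#' Generate a nuclear cell field
#'
#' Circular cells with lognormal areas placed by rejection sampling (no
#' overlaps, bounded retries). The nuclear channels "HistoneH3" and "dsDNA"
#' are positive exactly on cell pixels before noise.
#'
#' @param n_cells Number of cells requested.
#' @param shape `c(height, width)` in pixels.
#' @param mean_area_px Mean cell area in px.
#' @param area_cv Coefficient of variation of cell areas (0 = equal areas).
#' @param seed Integer seed.
#' @param pixel_size_um,expansion_fold Image annotations.
#' @param amplitudes Expected counts/px on cell pixels for the two nuclear
#'   channels.
#' @param max_tries Placement attempts per cell before giving up (then fewer
#'   cells are returned with a warning).
#' @return List with `image` ([multiplex_image()]) and `mask`
#'   ([label_mask()]).
#' @export
make_cell_field <- function(n_cells, shape, mean_area_px, area_cv = 0.3,
                            seed = 1L, pixel_size_um = 0.39,
                            expansion_fold = 1,
                            amplitudes = c(HistoneH3 = 50, dsDNA = 100),
                            max_tries = 200L) {
  stopifnot(n_cells >= 0, length(shape) == 2, mean_area_px > 0, area_cv >= 0)
  h <- shape[1]; w <- shape[2]
  if (n_cells * mean_area_px >= 0.5 * h * w)
    stop("infeasible packing: total cell area must stay below half the image")
  set.seed(seed)
  if (area_cv > 0) {
    sdlog <- sqrt(log(1 + area_cv^2))
    areas <- rlnorm(n_cells, meanlog = log(mean_area_px) - sdlog^2 / 2,
                    sdlog = sdlog)
  } else {
    areas <- rep(mean_area_px, n_cells)
  }
  radii <- sqrt(areas / pi)
  mask <- matrix(0L, h, w)
  rr <- matrix(0:(h - 1), h, w)
  cc <- matrix(0:(w - 1), h, w, byrow = TRUE)
  centers <- matrix(NA_real_, n_cells, 2)
  placed <- 0L
  for (i in seq_len(n_cells)) {
    r <- radii[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ctr <- c(runif(1, r, h - 1 - r), runif(1, r, w - 1 - r))
      # overlap check against already placed discs (1 px clearance)
      if (placed > 0) {
        d <- sqrt((centers[seq_len(placed), 1] - ctr[1])^2 +
                    (centers[seq_len(placed), 2] - ctr[2])^2)
        if (any(d < radii[seq_len(placed)] + r + 1)) next
      }
      placed <- placed + 1L
      centers[placed, ] <- ctr
      disc <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= r^2
      mask[disc] <- placed
      ok <- TRUE
      break
    }
    if (!ok) {
      warning("placed only ", placed, " of ", n_cells,
              " cells after bounded retries")
      break
    }
  }
  on_cell <- mask > 0
  channels <- lapply(amplitudes, function(a) {
    ch <- matrix(0, h, w)
    ch[on_cell] <- a
    ch
  })
  img <- multiplex_image(channels, pixel_size_um = pixel_size_um,
                         expansion_fold = expansion_fold,
                         fov_id = "cell_field")
  list(image = img, mask = label_mask(mask))
}

#' Rescale an image or label mask by a known expansion fold
#'
#' The output shape is `round(fold * shape)`; `pixel_size_um` is unchanged
#' while the `expansion_fold` annotation is multiplied by `fold` (the grid
#' keeps its physical pixel pitch; the sample inside it is magnified). Label
#' masks must use nearest-neighbour interpolation so label identities are
#' preserved.
#'
#' @param x A [multiplex_image()], [label_mask()] or plain matrix.
#' @param fold Linear scale factor (>= 1).
#' @param interpolation `"linear"` (bilinear) or `"nearest"`.
#' @return Scaled object of the same type.
#' @export
apply_scale <- function(x, fold, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(fold >= 1)
  if (inherits(x, "label_mask")) {
    if (interpolation != "nearest")
      stop("label masks must be scaled with nearest-neighbour interpolation")
    out <- .scale_matrix(unclass(x), fold, "nearest")
    return(label_mask(out))
  }
  if (inherits(x, "multiplex_image")) {
    x$channels <- lapply(x$channels, .scale_matrix, fold = fold,
                         interpolation = interpolation)
    x$expansion_fold <- x$expansion_fold * fold
    return(x)
  }
  .scale_matrix(x, fold, interpolation)
}

.scale_matrix <- function(m, fold, interpolation) {
  if (fold == 1) return(m)
  nr <- round(fold * nrow(m)); nc <- round(fold * ncol(m))
  # centre-aligned reverse mapping: output pixel centre -> input coordinate
  r_in <- ((0:(nr - 1)) + 0.5) / fold - 0.5
  c_in <- ((0:(nc - 1)) + 0.5) / fold - 0.5
  R <- matrix(r_in, nr, nc)
  C <- matrix(c_in, nr, nc, byrow = TRUE)
  if (interpolation == "nearest") {
    ri <- pmin(pmax(round(R), 0), nrow(m) - 1)
    ci <- pmin(pmax(round(C), 0), ncol(m) - 1)
    out <- matrix(m[cbind(as.vector(ri) + 1, as.vector(ci) + 1)], nr, nc)
  } else {
    out <- matrix(cpp_bilinear(m, as.vector(R), as.vector(C)), nr, nc)
  }
  out
}

#' Smooth random warp field
#'
#' Random control-point offsets on a regular grid, interpolated to a dense
#' C1-smooth displacement field by tensor-product natural cubic splines and
#' rescaled, if needed, so the maximum pixel displacement magnitude does not
#' exceed `amplitude_px`.
#'
#' @param shape `c(height, width)` of the target image.
#' @param control_spacing_px Control-point spacing (>= 4 px).
#' @param amplitude_px Maximum displacement magnitude (0 = identity field).
#' @param seed Integer seed.
#' @return A `warp_field` object with numeric matrices `drow`, `dcol` and
#'   `max_magnitude_px`.
#' @export
make_smooth_warp <- function(shape, control_spacing_px, amplitude_px,
                             seed = 1L) {
  stopifnot(control_spacing_px >= 4, amplitude_px >= 0, length(shape) == 2)
  h <- shape[1]; w <- shape[2]
  set.seed(seed)
  ctrl_r <- seq(-control_spacing_px, h - 1 + control_spacing_px,
                by = control_spacing_px)
  ctrl_c <- seq(-control_spacing_px, w - 1 + control_spacing_px,
                by = control_spacing_px)
  field <- lapply(1:2, function(k) {
    off <- matrix(runif(length(ctrl_r) * length(ctrl_c), -amplitude_px,
                        amplitude_px), length(ctrl_r), length(ctrl_c))
    interp_spline_grid(off, ctrl_r, ctrl_c, h, w)
  })
  mag <- sqrt(field[[1]]^2 + field[[2]]^2)
  mx <- max(mag)
  if (mx > amplitude_px && mx > 0) {
    field[[1]] <- field[[1]] * amplitude_px / mx
    field[[2]] <- field[[2]] * amplitude_px / mx
  }
  warp_field(field[[1]], field[[2]], max_magnitude_px = amplitude_px)
}

#' Construct a warp field from displacement grids
#'
#' @param drow,dcol Row/column displacement matrices in pixels (same shape
#'   as the target image).
#' @param max_magnitude_px Declared bound on displacement magnitude; checked.
#' @return A `warp_field` object.
#' @export
warp_field <- function(drow, dcol, max_magnitude_px = NULL) {
  stopifnot(is.matrix(drow), identical(dim(drow), dim(dcol)))
  mag <- sqrt(max(drow^2 + dcol^2))
  if (is.null(max_magnitude_px)) max_magnitude_px <- mag
  if (mag > max_magnitude_px + 1e-9)
    stop("displacement magnitude exceeds declared max_magnitude_px")
  structure(list(drow = drow, dcol = dcol,
                 max_magnitude_px = max_magnitude_px),
            class = "warp_field")
}

#' Tensor-product natural cubic spline interpolation of a control grid
#'
#' Interpolates values given at `ctrl_r` x `ctrl_c` grid positions to the
#' dense integer pixel grid `0..(nr-1)` x `0..(nc-1)`; natural cubic splines
#' are applied along columns, then along rows (the tensor-product
#' interpolant is order-independent since 1-D spline interpolation is linear
#' in the data).
#'
#' @param vals Matrix of control values (length(ctrl_r) x length(ctrl_c)).
#' @param ctrl_r,ctrl_c Control-point coordinates (strictly increasing).
#' @param nr,nc Output grid size.
#' @return nr x nc numeric matrix.
#' @export
interp_spline_grid <- function(vals, ctrl_r, ctrl_c, nr, nc) {
  stopifnot(nrow(vals) == length(ctrl_r), ncol(vals) == length(ctrl_c))
  xs <- 0:(nc - 1)
  tmp <- t(apply(vals, 1, function(row)
    splinefun(ctrl_c, row, method = "natural")(xs)))
  apply(tmp, 2, function(col)
    splinefun(ctrl_r, col, method = "natural")(0:(nr - 1)))
}

#' Apply a warp field by reverse mapping
#'
#' Output pixel (r, c) samples the input at (r + drow, c + dcol);
#' coordinates are clamped at the image border.
#'
#' @param x A [multiplex_image()] or numeric matrix.
#' @param field A [warp_field()] with the same shape as `x`.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return Warped object of the same type.
#' @export
apply_warp <- function(x, field, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(field, "warp_field"))
  warp1 <- function(m) {
    if (!identical(dim(m), dim(field$drow)))
      stop("warp field shape does not match the image")
    nr <- nrow(m); nc <- ncol(m)
    R <- matrix(0:(nr - 1), nr, nc) + field$drow
    C <- matrix(0:(nc - 1), nr, nc, byrow = TRUE) + field$dcol
    if (interpolation == "nearest") {
      ri <- pmin(pmax(round(R), 0), nr - 1)
      ci <- pmin(pmax(round(C), 0), nc - 1)
      matrix(m[cbind(as.vector(ri) + 1, as.vector(ci) + 1)], nr, nc)
    } else {
      matrix(cpp_bilinear(m, as.vector(R), as.vector(C)), nr, nc)
    }
  }
  if (inherits(x, "multiplex_image")) {
    x$channels <- lapply(x$channels, warp1)
    x
  } else warp1(x)
}

#' Add Poisson count noise
#'
#' Each pixel is replaced by an independent Poisson draw with the pixel's
#' value as expectation. Deterministic under `seed`.
#'
#' @param image A [multiplex_image()] or non-negative numeric matrix.
#' @param seed Integer seed.
#' @return Same type as `image`, integer-valued.
#' @export
add_poisson_noise <- function(image, seed = 1L) {
  set.seed(seed)
  noise1 <- function(m) {
    if (any(m < 0)) stop("Poisson noise requires non-negative expectations")
    matrix(rpois(length(m), as.vector(m)), nrow(m), ncol(m))
  }
  if (inherits(image, "multiplex_image")) {
    image$channels <- lapply(image$channels, noise1)
    image
  } else noise1(image)
}
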