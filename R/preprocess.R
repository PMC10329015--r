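## Channel preprocessing, composite-channel feature segmentation, per-cell
## quantification and a deliberately simple argmax phenotyper (a stand-in
## for cluster-based phenotyping, which is out of scope here).

#' Cap channel intensities at a percentile
#'
#' Per channel, values above that channel's q-th percentile are set to it.
#' The percentile uses linear interpolation between order statistics
#' (`stats::quantile()` type 7); the default 99.7 is the standard cap used
#' before ion-count image segmentation.
#'
#' @param image A [multiplex_image()] or numeric matrix.
#' @param q Percentile in (0, 100].
#' @return Same type as `image`.
#' @export
cap_percentile <- function(image, q = 99.7) {
  stopifnot(q > 0, q <= 100)
  cap1 <- function(m) {
    cap <- as.numeric(quantile(m, q / 100, type = 7))
    m[m > cap] <- cap
    m
  }
  if (inherits(image, "multiplex_image")) {
    image$channels <- lapply(image$channels, cap1)
    image
  } else cap1(image)
}

#' Normalise a tile by its dsDNA median
#'
#' Every channel is divided by the median of the *nonzero* dsDNA pixel
#' counts of the tile, so the dsDNA median of the output is 1. Zero pixels
#' are excluded because ion-count channels are zero-inflated and a median
#' over all pixels can vanish.
#'
#' @param image A [multiplex_image()].
#' @param dsdna_channel Name of the reference channel.
#' @return Normalised [multiplex_image()].
#' @export
normalize_tile_by_dsdna <- function(image, dsdna_channel = "dsDNA") {
  stopifnot(inherits(image, "multiplex_image"))
  ds <- get_channel(image, dsdna_channel)
  nz <- ds[ds > 0]
  if (length(nz) == 0) stop("dsDNA channel is all zero; cannot normalise")
  if (length(nz) < 0.01 * length(ds))
    stop("fewer than 1% of dsDNA pixels are nonzero; refusing to normalise")
  divisor <- median(nz)
  image$channels <- lapply(image$channels, function(m) m / divisor)
  image
}

#' Weighted composite of channels
#'
#' @param image A [multiplex_image()].
#' @param markers Channel names to combine.
#' @param weights Numeric weights (default all 1).
#' @return Numeric matrix: the weighted pixelwise sum.
#' @export
composite <- function(image, markers, weights = rep(1, length(markers))) {
  stopifnot(length(weights) == length(markers))
  out <- 0
  for (i in seq_along(markers))
    out <- out + weights[i] * get_channel(image, markers[i])
  out
}

#' Otsu threshold
#'
#' Histogram-based threshold maximising between-class variance, computed on
#' `n_bins` equal-width bins spanning the data range. Returns the threshold
#' value (upper edge of the chosen bin); foreground is `x > threshold`.
#'
#' @param x Numeric vector or matrix.
#' @param n_bins Number of histogram bins.
#' @return Threshold value.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  v <- as.vector(x)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between[-n_bins])
  edges[k + 1]
}

#' Segmentation parameters for non-nuclear features
#'
#' @param blur_sigma_px Gaussian pre-blur sigma (0 = none).
#' @param threshold `"otsu"` or a numeric absolute threshold.
#' @param min_size_px Objects smaller than this are removed.
#' @param closing_radius_px Radius of the morphological closing disc
#'   (0 = no closing).
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(blur_sigma_px = 1, threshold = "otsu",
                                min_size_px = 10, closing_radius_px = 1) {
  stopifnot(blur_sigma_px >= 0, min_size_px >= 0, closing_radius_px >= 0)
  if (!(identical(threshold, "otsu") || is.numeric(threshold)))
    stop("threshold must be \"otsu\" or a numeric value")
  structure(list(blur_sigma_px = blur_sigma_px, threshold = threshold,
                 min_size_px = as.integer(min_size_px),
                 closing_radius_px = as.integer(closing_radius_px)),
            class = "segmentation_params")
}

#' Segment features from a composite channel
#'
#' Gaussian blur, threshold (Otsu or absolute), morphological closing,
#' 8-connected component labelling, then removal of objects below
#' `min_size_px`. Labels are consecutive from 1 in reading order of each
#' object's first pixel. An empty foreground yields an empty mask with a
#' message, not an error.
#'
#' @param comp Non-negative numeric matrix (see [composite()]).
#' @param params A [segmentation_params()].
#' @return A [label_mask()].
#' @export
segment_features <- function(comp, params = segmentation_params()) {
  stopifnot(is.matrix(comp), inherits(params, "segmentation_params"))
  if (any(comp < 0)) stop("composite must be non-negative")
  sm <- gaussian_blur(comp, params$blur_sigma_px)
  thr <- if (identical(params$threshold, "otsu")) otsu_threshold(sm)
    else params$threshold
  fg <- sm > thr
  if (params$closing_radius_px > 0) {
    se <- se_offsets("disc", params$closing_radius_px)
    fg <- binary_erode(binary_dilate(fg, se), se)
  }
  lab <- label_components(fg, connectivity = 8)
  if (params$min_size_px > 0 && any(lab > 0)) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= params$min_size_px)
    relab <- integer(length(sizes))
    relab[keep] <- seq_along(keep) # preserves reading order
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  if (!any(lab > 0)) message("segment_features: empty foreground")
  label_mask(lab)
}

#' Quantify per-cell marker expression
#'
#' @param image A [multiplex_image()].
#' @param cell_mask A [label_mask()] with the same shape.
#' @return Data frame with one row per label: `label`, `area_px`,
#'   `centroid_row`, `centroid_col`, and `mean_<marker>` columns. Empty mask
#'   gives an empty table.
#' @export
quantify_cells <- function(image, cell_mask) {
  stopifnot(inherits(image, "multiplex_image"),
            identical(dim(image), dim(cell_mask)))
  labs <- mask_labels(cell_mask)
  if (length(labs) == 0) {
    out <- data.frame(label = integer(0), area_px = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0))
    for (m in names(image$channels)) out[[paste0("mean_", m)]] <- numeric(0)
    return(out)
  }
  idx <- which(cell_mask > 0)
  lab <- as.integer(cell_mask[idx])
  f <- factor(lab, levels = labs)
  area <- as.integer(table(f))
  r0 <- (idx - 1) %% nrow(cell_mask)      # 0-based row
  c0 <- (idx - 1) %/% nrow(cell_mask)     # 0-based col
  out <- data.frame(label = labs, area_px = area,
                    centroid_row = as.numeric(tapply(r0, f, mean)),
                    centroid_col = as.numeric(tapply(c0, f, mean)))
  for (m in names(image$channels)) {
    v <- image$channels[[m]][idx]
    out[[paste0("mean_", m)]] <- as.numeric(tapply(v, f, mean))
  }
  rownames(out) <- NULL
  out
}

#' Argmax class assignment (phenotyping stand-in)
#'
#' Each cell (rows of a [quantify_cells()] table) or pixel (of a
#' [multiplex_image()]) is assigned the class whose summed marker signal is
#' maximal. Ties go to the first declared class; zero-signal entries stay
#' unassigned.
#'
#' @param x A cell table (data.frame with `mean_<marker>` columns) or a
#'   [multiplex_image()].
#' @param class_markers Named list: class name -> character vector of
#'   markers.
#' @return For a table: a character vector of class names (`NA` =
#'   unassigned), in row order. For an image: a [class_map()] with class ids
#'   in declaration order.
#' @export
assign_classes_argmax <- function(x, class_markers) {
  stopifnot(length(class_markers) > 0,
            all(vapply(class_markers, length, integer(1)) > 0))
  cls <- names(class_markers)
  if (inherits(x, "multiplex_image")) {
    h <- dim(x)[1]; w <- dim(x)[2]
    scores <- vapply(class_markers, function(mk)
      as.vector(composite(x, mk)), numeric(h * w))
    best <- max.col(scores, ties.method = "first")
    top <- scores[cbind(seq_along(best), best)]
    best[top <= 0] <- NA
    mp <- matrix(ifelse(is.na(best), 0L, best), h, w)
    return(class_map(mp, setNames(seq_along(cls), cls)))
  }
  stopifnot(is.data.frame(x))
  scores <- vapply(class_markers, function(mk) {
    cols <- paste0("mean_", mk)
    miss <- setdiff(cols, names(x))
    if (length(miss)) stop("unknown marker column(s): ",
                           paste(miss, collapse = ", "))
    rowSums(x[, cols, drop = FALSE])
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x))
  best <- max.col(scores, ties.method = "first")
  out <- cls[best]
  out[scores[cbind(seq_along(best), best)] <= 0] <- NA
  out
}
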