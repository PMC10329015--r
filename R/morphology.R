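## Low-level raster primitives shared by the segmentation, anchoring and
## distortion modules. All masks are logical or integer matrices in (row,
## col) orientation, 0-based pixel-centre coordinate convention.

#' Structuring-element offsets
#'
#' @param se `"square"` (3x3, 8-connected, chessboard metric), `"cross"`
#'   (3x3 plus shape, 4-connected, city-block metric) or `"disc"` with a
#'   `radius` (Euclidean disc, used e.g. for rolling-ball backgrounds).
#' @param radius Disc radius in pixels (ignored for the 3x3 elements).
#' @return Integer matrix of (drow, dcol) offsets, one row per neighbour
#'   (the centre pixel is included).
#' @export
se_offsets <- function(se = c("square", "cross", "disc"), radius = 1) {
  se <- match.arg(se)
  if (se == "square") {
    g <- expand.grid(dr = -1:1, dc = -1:1)
  } else if (se == "cross") {
    g <- data.frame(dr = c(0, -1, 1, 0, 0), dc = c(0, 0, 0, -1, 1))
  } else {
    r <- ceiling(radius)
    g <- expand.grid(dr = -r:r, dc = -r:r)
    g <- g[g$dr^2 + g$dc^2 <= radius^2, ]
  }
  as.matrix(g)
}

#' Binary dilation / erosion
#'
#' Pixels outside the image count as background: dilation is clipped at the
#' borders and erosion removes border-touching object pixels.
#'
#' @param mask Logical matrix.
#' @param se Offset matrix from [se_offsets()] (or a keyword accepted by it).
#' @param k Number of unit applications.
#' @return Logical matrix.
#' @export
binary_dilate <- function(mask, se = "square", k = 1) {
  .binary_morph(mask, se, k, dilate = TRUE)
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, se = "square", k = 1) {
  .binary_morph(mask, se, k, dilate = FALSE)
}

.binary_morph <- function(mask, se, k, dilate) {
  stopifnot(is.matrix(mask))
  if (is.character(se)) se <- se_offsets(se)
  storage.mode(se) <- "integer"
  m <- mask
  storage.mode(m) <- "logical"
  for (i in seq_len(k)) m <- cpp_binary_morph(m, se, dilate)
  m
}

#' Grayscale erosion / dilation (min/max filter)
#'
#' @inheritParams binary_dilate
#' @param m Numeric matrix.
#' @return Numeric matrix.
#' @export
gray_erode <- function(m, se) {
  if (is.character(se)) se <- se_offsets(se)
  storage.mode(se) <- "integer"
  cpp_gray_morph(m, se, FALSE)
}

#' @rdname gray_erode
#' @export
gray_dilate <- function(m, se) {
  if (is.character(se)) se <- se_offsets(se)
  storage.mode(se) <- "integer"
  cpp_gray_morph(m, se, TRUE)
}

#' Connected-component labelling
#'
#' Labels are consecutive from 1 in reading order (row-major) of each
#' component's first pixel.
#'
#' @param mask Logical matrix (foreground = TRUE).
#' @param connectivity 8 (default) or 4.
#' @return Integer label matrix, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  storage.mode(mask) <- "logical"
  cpp_label_components(mask, as.integer(connectivity))
}

#' Euclidean distance transform
#'
#' Exact distance from every pixel to the nearest `TRUE` pixel
#' (Felzenszwalb-Huttenlocher two-pass algorithm).
#'
#' @param mask Logical matrix.
#' @return Numeric matrix of distances in pixels (`Inf` if `mask` is empty).
#' @export
distance_transform <- function(mask) {
  storage.mode(mask) <- "logical"
  sqrt(cpp_edt_sq(mask))
}

#' Signed Euclidean distance from an object boundary
#'
#' Positive outside the object (distance to the nearest object pixel),
#' negative inside (minus the distance to the nearest background pixel).
#' This is the radial coordinate used both by the phantom generator's
#' concentric marker layers and by Euclidean ("disc") step rings, so the two
#' share one geometric convention.
#'
#' @param object Logical matrix, TRUE on the object.
#' @return Numeric matrix of signed distances in pixels.
#' @export
signed_boundary_distance <- function(object) {
  storage.mode(object) <- "logical"
  d_out <- sqrt(cpp_edt_sq(object))
  d_in <- sqrt(cpp_edt_sq(!object))
  out <- d_out
  out[object] <- -d_in[object]
  out
}

#' Gaussian blur
#'
#' Separable Gaussian convolution with a kernel truncated at 3.5 sigma and
#' renormalised at the image borders (replicate-free: border weights are
#' rescaled so each output pixel averages only in-image pixels).
#'
#' @param m Numeric matrix.
#' @param sigma Standard deviation in pixels; `0` returns `m` unchanged.
#' @return Numeric matrix.
#' @export
gaussian_blur <- function(m, sigma) {
  stopifnot(is.matrix(m), sigma >= 0)
  if (sigma == 0) return(m)
  conv1 <- function(n) {
    r <- ceiling(3.5 * sigma)
    w <- exp(-(-r:r)^2 / (2 * sigma^2))
    K <- matrix(0, n, n)
    for (d in -r:r) {
      idx <- seq_len(n)
      ok <- idx + d >= 1 & idx + d <= n
      K[cbind(idx[ok], idx[ok] + d)] <- w[d + r + 1]
    }
    K / rowSums(K)
  }
  conv1(nrow(m)) %*% m %*% t(conv1(ncol(m)))
}

## average-pooling downsample by integer factor (registration pyramids)
.downsample2 <- function(m) {
  nr <- floor(nrow(m) / 2) * 2
  nc <- floor(ncol(m) / 2) * 2
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  (m[seq(1, nr, 2), seq(1, nc, 2)] + m[seq(2, nr, 2), seq(1, nc, 2)] +
     m[seq(1, nr, 2), seq(2, nc, 2)] + m[seq(2, nr, 2), seq(2, nc, 2)]) / 4
}

#' Bilinear sampling at fractional pixel coordinates
#'
#' Coordinates are 0-based (pixel centres at integers) and clamped to the
#' image domain.
#'
#' @param m Numeric matrix.
#' @param rows,cols Numeric vectors of equal length.
#' @return Numeric vector of sampled values.
#' @export
bilinear_sample <- function(m, rows, cols) {
  stopifnot(length(rows) == length(cols))
  cpp_bilinear(m, as.numeric(rows), as.numeric(cols))
}
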