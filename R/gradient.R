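## Marker gradients along the long axis of a stitched tissue strip
## (e.g. traversing gray to white matter): perpendicular summation,
## quantile min-max normalisation, and overlapping sliding windows with
## confidence intervals.

#' Sum channels perpendicular to the long axis
#'
#' @param image A [multiplex_image()].
#' @param channels Channel names.
#' @param axis `"col"` (default; the long axis runs along columns and each
#'   profile entry is one column sum) or `"row"`.
#' @return An `axis_profile` data frame: `position` (0-based index along
#'   the long axis) plus one column of summed counts per channel, with
#'   attribute `axis`.
#' @export
perpendicular_sum <- function(image, channels, axis = c("col", "row")) {
  axis <- match.arg(axis)
  out <- NULL
  for (ch in channels) {
    m <- get_channel(image, ch)
    s <- if (axis == "col") colSums(m) else rowSums(m)
    if (is.null(out)) out <- data.frame(position = seq_along(s) - 1)
    out[[ch]] <- as.numeric(s)
  }
  attr(out, "axis") <- axis
  class(out) <- c("axis_profile", class(out))
  out
}

#' Quantile min-max normalisation of an axis profile
#'
#' Per channel, `x -> (x - Q_low) / (Q_high - Q_low)` with the 5% and 95%
#' quantiles as Min and Max by default (linear-interpolation quantiles,
#' `stats::quantile()` type 7, the same convention as [cap_percentile()]).
#' Values outside `[0, 1]` are permitted and not clipped.
#'
#' @param profile An [perpendicular_sum()] result.
#' @param q_low,q_high Quantile probabilities, `q_low < q_high`.
#' @return Normalised `axis_profile`.
#' @export
quantile_minmax <- function(profile, q_low = 0.05, q_high = 0.95) {
  stopifnot(inherits(profile, "axis_profile"), q_low < q_high)
  for (ch in setdiff(names(profile), "position")) {
    qs <- quantile(profile[[ch]], c(q_low, q_high), type = 7, names = FALSE)
    if (qs[1] == qs[2])
      stop("channel ", ch, " is constant between the chosen quantiles; ",
           "cannot min-max normalise")
    profile[[ch]] <- (profile[[ch]] - qs[1]) / (qs[2] - qs[1])
  }
  profile
}

#' Sliding-window means with confidence intervals
#'
#' Overlapping windows along the profile: window `w` covers positions
#' `[(w-1) stride, (w-1) stride + window)`; the number of windows is
#' `floor((L - window) / stride) + 1`. Per window and channel the mean over
#' the window's positions is reported with a 95% CI across those positions
#' (`mean +/- 1.96 sd / sqrt(window)`).
#'
#' @param profile An `axis_profile` (typically [quantile_minmax()]
#'   normalised).
#' @param window Window size in pixel lines (default 200).
#' @param stride Slide between consecutive windows (default 50).
#' @param conf Confidence level.
#' @return A `window_profile` data frame: `window`, `center` plus
#'   `<channel>_mean`, `<channel>_ci_lo`, `<channel>_ci_hi` per channel.
#' @export
sliding_windows <- function(profile, window = 200, stride = 50,
                            conf = 0.95) {
  stopifnot(inherits(profile, "axis_profile"), window >= 2, stride >= 1)
  L <- nrow(profile)
  if (L < window)
    stop("profile length ", L, " is shorter than the window (", window, ")")
  n_win <- floor((L - window) / stride) + 1
  starts <- (seq_len(n_win) - 1) * stride
  z <- stats::qnorm((1 + conf) / 2)
  out <- data.frame(window = seq_len(n_win),
                    center = starts + (window - 1) / 2)
  for (ch in setdiff(names(profile), "position")) {
    v <- profile[[ch]]
    mu <- vapply(starts, function(s) mean(v[(s + 1):(s + window)]),
                 numeric(1))
    sdv <- vapply(starts, function(s) sd(v[(s + 1):(s + window)]),
                  numeric(1))
    out[[paste0(ch, "_mean")]] <- mu
    out[[paste0(ch, "_ci_lo")]] <- mu - z * sdv / sqrt(window)
    out[[paste0(ch, "_ci_hi")]] <- mu + z * sdv / sqrt(window)
  }
  class(out) <- c("window_profile", class(out))
  out
}
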