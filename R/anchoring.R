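## Perivascular "anchoring" analysis: a layer-by-layer walk around each
## segmented vessel object. Step +k is the k-th one-pixel ring outside the
## object (dilation difference), step -k the k-th ring inside it (erosion
## difference); step 0 does not exist (the object interior is covered by the
## negative steps). Per-step marker means and class-fraction statistics are
## aggregated across vessels with confidence intervals, square-root
## transformed for display, z-normalised per channel across steps, and each
## channel's peak step is localised.

#' One-pixel step rings around a labelled object
#'
#' With `D_k`/`E_k` the k-fold unit dilation/erosion of the object by the
#' structuring element (`D_0 = E_0 =` object), ring(+k) `= D_k \ D_{k-1}`
#' and ring(-k) `= E_{k-1} \ E_k`. For `se = "disc"` the stepping uses exact
#' Euclidean distances instead (ring(+k) = pixels at outside distance in
#' (k-1, k], ring(-k) analogously inside), i.e. dilation by growing
#' Euclidean discs; this metric matches the phantom generator's radial
#' layers. Rings are clipped at image borders; pixels outside the image
#' count as background. Empty rings are recorded as empty.
#'
#' @param mask A [label_mask()].
#' @param object_id Positive label present in `mask`.
#' @param k_min Most negative step (< 0). Default -40, the inward range used
#'   for expanded-gel vessels (use -10 for unexpanded samples).
#' @param k_max Most positive step (>= 0). Default +20 (use +5 for
#'   unexpanded samples).
#' @param se `"square"` (3x3, chessboard metric; default), `"cross"`
#'   (city-block) or `"disc"` (Euclidean).
#' @return A `step_ring_set`: list with `object_id`, `k_min`, `k_max`, `se`,
#'   `dim`, and `steps`, a named list (names `"k"`) of integer pixel indices
#'   (column-major, into the full mask).
#' @export
step_rings <- function(mask, object_id, k_min = -40, k_max = 20,
                       se = c("square", "cross", "disc")) {
  se <- match.arg(se)
  stopifnot(k_min < 0, k_max >= 0)
  obj_idx <- which(mask == object_id)
  if (length(obj_idx) == 0) stop("no object with label ", object_id)
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- (obj_idx - 1) %% nr + 1
  cols <- (obj_idx - 1) %/% nr + 1
  marg <- k_max + 1
  r0 <- max(1, min(rows) - marg); r1 <- min(nr, max(rows) + marg)
  c0 <- max(1, min(cols) - marg); c1 <- min(nc, max(cols) + marg)
  sub <- matrix(FALSE, r1 - r0 + 1, c1 - c0 + 1)
  sub[cbind(rows - r0 + 1, cols - c0 + 1)] <- TRUE
  to_global <- function(which_sub) {
    rs <- (which_sub - 1) %% nrow(sub) + r0
    cs <- (which_sub - 1) %/% nrow(sub) + c0
    sort(as.integer((cs - 1) * nr + rs))
  }
  steps <- list()
  if (se %in% c("square", "cross")) {
    off <- se_offsets(se)
    prev <- sub
    for (k in seq_len(k_max)) {
      cur <- binary_dilate(prev, off)
      steps[[as.character(k)]] <- to_global(which(cur & !prev))
      prev <- cur
    }
    prev <- sub
    for (k in seq_len(-k_min)) {
      cur <- binary_erode(prev, off)
      steps[[as.character(-k)]] <- to_global(which(prev & !cur))
      prev <- cur
    }
  } else {
    d_out <- distance_transform(sub)
    # pad so that the image border counts as background for inside distances
    padded <- rbind(FALSE, cbind(FALSE, sub, FALSE), FALSE)
    d_in_p <- distance_transform(!padded)
    d_in <- d_in_p[2:(nrow(padded) - 1), 2:(ncol(padded) - 1), drop = FALSE]
    for (k in seq_len(k_max))
      steps[[as.character(k)]] <-
        to_global(which(!sub & d_out > k - 1 & d_out <= k))
    for (k in seq_len(-k_min))
      steps[[as.character(-k)]] <-
        to_global(which(sub & d_in > k - 1 & d_in <= k))
  }
  ks <- c(seq(k_min, -1), seq_len(k_max))
  structure(list(object_id = object_id, k_min = k_min, k_max = k_max,
                 se = se, dim = c(nr, nc),
                 steps = steps[as.character(ks)][as.character(ks) %in%
                                                   names(steps)]),
            class = "step_ring_set")
}

#' Remove ring pixels overlapping other objects
#'
#' Every ring pixel lying inside any *other* object's original
#' (non-dilated) mask is removed, so neighbouring vessels do not
#' contaminate each other's outward steps.
#'
#' @param rings A [step_rings()] result.
#' @param full_mask The [label_mask()] the rings derive from.
#' @return A `step_ring_set` with pruned rings.
#' @export
exclude_overlaps <- function(rings, full_mask) {
  stopifnot(inherits(rings, "step_ring_set"),
            identical(rings$dim, dim(full_mask)))
  other <- which(full_mask > 0 & full_mask != rings$object_id)
  rings$steps <- lapply(rings$steps, function(ix) setdiff(ix, other))
  rings
}

#' Per-step statistics for one object
#'
#' @param image A [multiplex_image()] (typically already normalised, see
#'   [normalize_tile_by_dsdna()]).
#' @param rings A [step_rings()] result (after [exclude_overlaps()]).
#' @param classmaps Named list of [class_map()] objects (e.g. phenotypes,
#'   feature segments); each contributes `frac_<class>` columns: the
#'   fraction of ring pixels carrying that class.
#' @return Data frame with one row per step: `step`, `n_pixels`, one column
#'   per channel (mean count over ring pixels) and per class fraction.
#'   Empty rings yield `NA`, not zeros.
#' @export
profile_object <- function(image, rings, classmaps = list()) {
  stopifnot(inherits(image, "multiplex_image"),
            inherits(rings, "step_ring_set"),
            identical(dim(image), rings$dim))
  ks <- as.integer(names(rings$steps))
  out <- data.frame(step = ks,
                    n_pixels = vapply(rings$steps, length, integer(1)))
  for (m in names(image$channels)) {
    ch <- image$channels[[m]]
    out[[m]] <- vapply(rings$steps, function(ix)
      if (length(ix)) mean(ch[ix]) else NA_real_, numeric(1))
  }
  for (cm in classmaps) {
    stopifnot(inherits(cm, "class_map"))
    for (cl in names(cm$classes)) {
      id <- cm$classes[[cl]]
      out[[paste0("frac_", cl)]] <- vapply(rings$steps, function(ix)
        if (length(ix)) mean(cm$map[ix] == id) else NA_real_, numeric(1))
    }
  }
  rownames(out) <- NULL
  out
}

#' Profile all vessels of a mask
#'
#' Runs [step_rings()], [exclude_overlaps()] and [profile_object()] for
#' every label. Objects whose `k_max`-dilation would touch the image border
#' are excluded by default (their outer rings would be truncated and bias
#' the means); their labels are returned in `excluded`.
#'
#' @inheritParams step_rings
#' @inheritParams profile_object
#' @param exclude_border Drop border-reaching objects (default TRUE).
#' @return List with `records` (named list of per-object data frames) and
#'   `excluded` (integer labels).
#' @export
profile_vessels <- function(image, mask, classmaps = list(), k_min = -40,
                            k_max = 20, se = "square",
                            exclude_border = TRUE) {
  labs <- mask_labels(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  records <- list()
  excluded <- integer(0)
  for (id in labs) {
    idx <- which(mask == id)
    rows <- (idx - 1) %% nr + 1
    cols <- (idx - 1) %/% nr + 1
    if (exclude_border &&
        (min(rows) - k_max < 1 || max(rows) + k_max > nr ||
         min(cols) - k_max < 1 || max(cols) + k_max > nc)) {
      excluded <- c(excluded, id)
      next
    }
    rg <- exclude_overlaps(step_rings(mask, id, k_min, k_max, se), mask)
    records[[as.character(id)]] <- profile_object(image, rg, classmaps)
  }
  if (length(records) == 0) stop("no profilable vessel objects")
  list(records = records, excluded = excluded)
}

#' Aggregate per-object profiles across vessels
#'
#' Optionally square-root transforms every per-object value (display
#' convention for count data), then computes, per step and variable, the
#' mean, SD and confidence interval across objects. Aggregation averages
#' per-object means rather than pooling pixels, because each vessel is the
#' replicate unit.
#'
#' @param records List of data frames from [profile_object()] (identical
#'   step ranges), or the `records` element of [profile_vessels()].
#' @param transform `"sqrt"` (default) or `"none"`.
#' @param ci `"normal"` (mean +/- z * SE) or `"t"` (t-quantile).
#' @param conf Confidence level (default 0.95).
#' @return An `anchor_profile`: long data frame with columns `step`,
#'   `variable`, `mean`, `sd`, `n`, `ci_lo`, `ci_hi`. CI entries are `NA`
#'   when fewer than 2 objects define the value.
#' @export
aggregate_profiles <- function(records, transform = c("sqrt", "none"),
                               ci = c("normal", "t"), conf = 0.95) {
  transform <- match.arg(transform)
  ci <- match.arg(ci)
  if (is.list(records) && !is.null(records$records))
    records <- records$records
  stopifnot(length(records) >= 1)
  steps <- records[[1]]$step
  for (r in records)
    if (!identical(r$step, steps)) stop("records have differing step ranges")
  vars <- setdiff(names(records[[1]]), c("step", "n_pixels"))
  rows <- list()
  for (v in vars) {
    vals <- vapply(records, function(r) r[[v]], numeric(length(steps)))
    vals <- matrix(vals, nrow = length(steps))
    if (transform == "sqrt") vals <- sqrt(vals)
    n <- rowSums(!is.na(vals))
    mu <- ifelse(n > 0, rowMeans(vals, na.rm = TRUE), NA_real_)
    s <- apply(vals, 1, function(x) if (sum(!is.na(x)) >= 2)
      sd(x, na.rm = TRUE) else NA_real_)
    half <- ifelse(n >= 2,
                   (if (ci == "normal") stats::qnorm((1 + conf) / 2)
                    else qt((1 + conf) / 2, pmax(n - 1, 1))) * s / sqrt(n),
                   NA_real_)
    rows[[v]] <- data.frame(step = steps, variable = v, mean = mu, sd = s,
                            n = n, ci_lo = mu - half, ci_hi = mu + half)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "transform") <- transform
  class(out) <- c("anchor_profile", class(out))
  out
}

#' Z-normalised step heatmap and per-channel peak steps
#'
#' Each variable's aggregated means are z-normalised across steps
#' (population SD) and the peak step (argmax) localised. Peak ties are
#' broken toward the smallest `|step|` (the object boundary), then toward
#' the lumen. Variables constant across steps (or defined on fewer than two
#' steps) are flagged and excluded.
#'
#' @param profile An [aggregate_profiles()] result.
#' @return List with `z` (matrix, variables x steps, `NA` where undefined),
#'   `peaks` (data frame `variable`, `peak_step`) and `excluded` (character
#'   vector of flagged variables).
#' @export
heatmap_and_peaks <- function(profile) {
  stopifnot(inherits(profile, "anchor_profile"))
  vars <- unique(profile$variable)
  steps <- sort(unique(profile$step))
  z <- matrix(NA_real_, length(vars), length(steps),
              dimnames = list(vars, as.character(steps)))
  peaks <- data.frame(variable = character(0), peak_step = integer(0))
  excluded <- character(0)
  for (v in vars) {
    sub <- profile[profile$variable == v, ]
    m <- sub$mean[match(steps, sub$step)]
    def <- which(!is.na(m))
    if (length(def) < 2 || max(m[def]) == min(m[def])) {
      excluded <- c(excluded, v)
      next
    }
    mu <- mean(m[def])
    sd_pop <- sqrt(mean((m[def] - mu)^2))
    z[v, def] <- (m[def] - mu) / sd_pop
    cand <- def[m[def] == max(m[def])]
    ck <- steps[cand]
    ck <- ck[order(abs(ck), ck)] # toward the boundary, then the lumen
    peaks <- rbind(peaks, data.frame(variable = v, peak_step = ck[1]))
  }
  list(z = z, peaks = peaks, excluded = excluded)
}
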