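## Containers and on-disk formats. A field of view (FOV) lives on disk as a
## directory of single-channel grayscale TIFFs named "<marker>.tiff", a
## panel.csv (marker, mass_tag, role) giving the channel order, and a
## fov.json with pixel_size_um, expansion_fold and fov_id. Physical
## distances are pixel distance * pixel_size_um; "pre-expansion" distances
## are additionally divided by expansion_fold (the scale-bar convention for
## expanded gels).

#' Multichannel ion-count image
#'
#' @param channels Named list of numeric matrices, one per marker, all with
#'   the same dimensions and no negative or non-finite values.
#' @param pixel_size_um Physical pixel size in micrometres per pixel (of the
#'   acquired, i.e. post-expansion, grid).
#' @param expansion_fold Linear expansion fold of the sample (>= 1);
#'   1 for unexpanded samples.
#' @param fov_id Identifier string.
#' @return A `multiplex_image` object.
#' @export
multiplex_image <- function(channels, pixel_size_um, expansion_fold = 1,
                            fov_id = "fov") {
  if (!is.list(channels) || length(channels) == 0)
    stop("channels must be a non-empty named list of matrices")
  nm <- names(channels)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("channel names must be unique and non-empty")
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all channels must share one shape")
  for (m in nm) {
    ch <- channels[[m]]
    if (any(!is.finite(ch))) stop("non-finite values in channel ", m)
    if (any(ch < 0)) stop("negative values in channel ", m)
  }
  stopifnot(pixel_size_um > 0, expansion_fold >= 1)
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 expansion_fold = expansion_fold, fov_id = fov_id),
            class = "multiplex_image")
}

#' @export
print.multiplex_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<multiplex_image '%s'> %d x %d px, %d channels, %.3f um/px, fold %.2f\n",
    x$fov_id, d[1], d[2], length(x$channels), x$pixel_size_um,
    x$expansion_fold))
  cat(" channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.multiplex_image <- function(x) dim(x$channels[[1]])

#' Extract a channel matrix
#' @param image A [multiplex_image()].
#' @param marker Channel name.
#' @return Numeric matrix.
#' @export
get_channel <- function(image, marker) {
  stopifnot(inherits(image, "multiplex_image"))
  if (!marker %in% names(image$channels))
    stop("channel not present: ", marker)
  image$channels[[marker]]
}

#' Integer label mask
#'
#' @param m Matrix of non-negative integers; 0 is background, each positive
#'   label is one object.
#' @return A `label_mask` object (an integer matrix).
#' @export
label_mask <- function(m) {
  stopifnot(is.matrix(m))
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
    stop("label mask must contain non-negative integers")
  storage.mode(m) <- "integer"
  class(m) <- c("label_mask", class(m))
  m
}

#' Labels present in a mask
#' @param mask A [label_mask()].
#' @return Sorted integer vector of positive labels.
#' @export
mask_labels <- function(mask) sort(unique(as.integer(mask[mask > 0])))

#' Per-pixel class assignment map
#'
#' @param m Matrix of small non-negative integers (0 = unassigned).
#' @param classes Named integer vector mapping class name -> class id; every
#'   nonzero pixel value must appear among the ids.
#' @return A `class_map` object.
#' @export
class_map <- function(m, classes) {
  stopifnot(is.matrix(m), is.numeric(classes), !is.null(names(classes)))
  ids <- sort(unique(as.integer(m[m > 0])))
  undeclared <- setdiff(ids, as.integer(classes))
  if (length(undeclared))
    stop("undeclared class id(s) in map: ", paste(undeclared, collapse = ", "))
  storage.mode(m) <- "integer"
  structure(list(map = m, classes = classes), class = "class_map")
}

#' Write / read a field of view directory
#'
#' `write_fov()` writes one grayscale TIFF per channel plus `panel.csv` and
#' `fov.json`; `read_fov()` round-trips integer channel data bit-exactly and
#' orders channels by the panel.
#'
#' @param image A [multiplex_image()].
#' @param dir Directory path (created if missing).
#' @param panel Optional data.frame with columns marker, mass_tag, role; a
#'   minimal panel is synthesised when omitted.
#' @return `write_fov()` returns `dir` invisibly; `read_fov()` returns a
#'   [multiplex_image()].
#' @export
write_fov <- function(image, dir, panel = NULL) {
  stopifnot(inherits(image, "multiplex_image"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nm <- names(image$channels)
  if (is.null(panel)) {
    panel <- data.frame(marker = nm, mass_tag = rep("", length(nm)),
                        role = rep("", length(nm)))
  }
  if (!all(nm %in% panel$marker))
    stop("panel lacks rows for: ",
         paste(setdiff(nm, panel$marker), collapse = ", "))
  write.csv(panel, file.path(dir, "panel.csv"), row.names = FALSE)
  for (m in nm) write_tiff(image$channels[[m]],
                           file.path(dir, paste0(m, ".tiff")))
  meta <- list(pixel_size_um = image$pixel_size_um,
               expansion_fold = image$expansion_fold, fov_id = image$fov_id)
  jsonlite::write_json(meta, file.path(dir, "fov.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_fov
#' @export
read_fov <- function(dir) {
  if (!dir.exists(dir)) stop("no such FOV directory: ", dir)
  panel_path <- file.path(dir, "panel.csv")
  if (!file.exists(panel_path)) stop("FOV directory lacks panel.csv: ", dir)
  panel <- read.csv(panel_path, stringsAsFactors = FALSE)
  tiffs <- list.files(dir, pattern = "\\.tiff?$")
  found <- sub("\\.tiff?$", "", tiffs)
  orphan <- setdiff(found, panel$marker)
  missing <- setdiff(panel$marker, found)
  if (length(orphan))
    stop("channel TIFF(s) without a panel row: ",
         paste(orphan, collapse = ", "))
  if (length(missing))
    stop("panel row(s) without a channel TIFF: ",
         paste(missing, collapse = ", "))
  meta_path <- file.path(dir, "fov.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
    else list(pixel_size_um = 1, expansion_fold = 1, fov_id = basename(dir))
  channels <- list()
  ref_dim <- NULL
  for (m in panel$marker) {
    f <- file.path(dir, tiffs[match(m, found)])
    ch <- read_tiff(f)
    if (any(!is.finite(ch))) stop("non-finite pixels in ", basename(f))
    if (any(ch < 0)) stop("negative counts in ", basename(f))
    if (is.null(ref_dim)) ref_dim <- dim(ch)
    if (!identical(dim(ch), ref_dim))
      stop("channel shape mismatch in ", basename(f), ": ",
           paste(dim(ch), collapse = "x"), " vs ",
           paste(ref_dim, collapse = "x"))
    channels[[m]] <- ch
  }
  multiplex_image(channels, pixel_size_um = meta$pixel_size_um,
                  expansion_fold = meta$expansion_fold, fov_id = meta$fov_id)
}

#' Write / read a label mask as integer TIFF
#'
#' @param mask A [label_mask()] (for writing) or path (for reading).
#' @param path File path.
#' @return `read_mask()` returns a [label_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  write_tiff(unclass(mask), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- read_tiff(path)
  if (any(m != round(m)))
    stop("float TIFF cannot be a label mask: ", path)
  label_mask(m)
}

#' Write / read a class map (integer TIFF plus JSON class dictionary)
#'
#' @param cm A [class_map()].
#' @param path TIFF path; the dictionary goes to `<path>.classes.json`.
#' @return `read_classmap()` returns a [class_map()].
#' @export
write_classmap <- function(cm, path) {
  stopifnot(inherits(cm, "class_map"))
  write_tiff(cm$map, path)
  jsonlite::write_json(as.list(cm$classes), paste0(path, ".classes.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_classmap
#' @export
read_classmap <- function(path) {
  m <- read_tiff(path)
  if (any(m != round(m))) stop("float TIFF cannot be a class map: ", path)
  cls <- unlist(jsonlite::read_json(paste0(path, ".classes.json")))
  class_map(m, cls)
}

#' Write / read an analysis table as CSV
#'
#' UTF-8, comma-separated, header row, `.` decimal; numeric columns
#' round-trip to full double precision.
#'
#' @param df Data frame.
#' @param path CSV path.
#' @return `read_table_csv()` returns a data.frame.
#' @export
write_table_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
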