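## Minimal baseline TIFF support: uncompressed, single-plane grayscale,
## unsigned 8/16/32-bit integer or 32-bit float samples. This is the subset
## the MIBI/IMC single-channel export convention uses; no installed package
## provides TIFF access in this environment, so the format is handled here.

.tiff_tags <- c(
  ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
  Compression = 259L, Photometric = 262L, StripOffsets = 273L,
  SamplesPerPixel = 277L, RowsPerStrip = 278L, StripByteCounts = 279L,
  SampleFormat = 339L
)

#' Read a single-plane grayscale TIFF
#'
#' Supports uncompressed baseline TIFF with one sample per pixel, 8/16/32-bit
#' unsigned integer or 32-bit IEEE float data, in either byte order.
#'
#' @param path Path to a `.tiff`/`.tif` file.
#' @return A numeric matrix (rows = image rows).
#' @export
read_tiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  order_bytes <- readBin(con, "raw", 2)
  endian <- if (identical(rawToChar(order_bytes), "II")) "little" else
    if (identical(rawToChar(order_bytes), "MM")) "big" else
      stop("not a TIFF file: ", path)
  u16 <- function() readBin(con, "integer", 1, size = 2, signed = FALSE,
                            endian = endian)
  u32 <- function() {
    v <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (v < 0) v + 2^32 else as.numeric(v)
  }
  magic <- u16()
  if (magic != 42L) stop("bad TIFF magic number in ", path)
  ifd_off <- u32()
  seek(con, ifd_off)
  n_entries <- u16()
  tags <- list()
  for (i in seq_len(n_entries)) {
    tag <- u16(); type <- u16(); count <- u32()
    value_pos <- seek(con, NA)
    # inline value if it fits in 4 bytes, else it is an offset
    size_of <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `5` = 8, `11` = 4,
                 `12` = 8)[[as.character(type)]]
    nbytes <- size_of * count
    read_vals <- function() {
      if (type == 3) readBin(con, "integer", count, size = 2, signed = FALSE,
                             endian = endian)
      else if (type == 4) vapply(seq_len(count), function(k) u32(), numeric(1))
      else if (type == 1) as.numeric(readBin(con, "raw", count))
      else readBin(con, "integer", count, size = size_of, endian = endian)
    }
    if (nbytes <= 4) {
      vals <- read_vals()
    } else {
      off <- u32()
      here <- seek(con, off)
      vals <- read_vals()
      seek(con, here)
    }
    seek(con, value_pos + 4)
    tags[[as.character(tag)]] <- vals
  }
  need <- function(id, default = NULL) {
    v <- tags[[as.character(.tiff_tags[[id]])]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF lacks required tag ", id, ": ", path)
      default
    } else v
  }
  w <- need("ImageWidth"); h <- need("ImageLength")
  bits <- need("BitsPerSample", 1)
  if (length(bits) > 1 || need("SamplesPerPixel", 1) != 1)
    stop("only single-sample grayscale TIFFs are supported: ", path)
  if (need("Compression", 1) != 1)
    stop("compressed TIFFs are not supported: ", path)
  fmt <- need("SampleFormat", 1)
  offs <- need("StripOffsets"); counts <- need("StripByteCounts")
  raw_data <- raw(0)
  for (k in seq_along(offs)) {
    seek(con, offs[k])
    raw_data <- c(raw_data, readBin(con, "raw", counts[k]))
  }
  npx <- as.integer(w) * as.integer(h)
  vals <- if (fmt == 3) {
    if (bits != 32) stop("float TIFF must be 32-bit: ", path)
    readBin(raw_data, "double", npx, size = 4, endian = endian)
  } else if (bits == 8) {
    as.numeric(readBin(raw_data, "integer", npx, size = 1, signed = FALSE))
  } else if (bits == 16) {
    as.numeric(readBin(raw_data, "integer", npx, size = 2, signed = FALSE,
                       endian = endian))
  } else if (bits == 32) {
    v <- readBin(raw_data, "integer", npx, size = 4, endian = endian)
    ifelse(v < 0, v + 2^32, as.numeric(v))
  } else stop("unsupported bit depth ", bits, ": ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a matrix as a single-plane grayscale TIFF
#'
#' @param m Numeric matrix. Integer-valued matrices are stored as unsigned
#'   8/16/32-bit (smallest depth that holds the maximum); non-integer data
#'   as 32-bit float.
#' @param path Output path.
#' @param bits Bit depth override (8, 16 or 32) for integer data.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(m, path, bits = NULL) {
  stopifnot(is.matrix(m))
  if (any(!is.finite(m))) stop("cannot write non-finite pixel values")
  is_int <- all(m == round(m))
  if (is_int && any(m < 0)) is_int <- FALSE # store signed data as float
  if (is_int) {
    if (is.null(bits))
      bits <- if (max(m, 0) <= 255) 8L else if (max(m, 0) <= 65535) 16L
        else 32L
    if (max(m, 0) > 2^bits - 1)
      stop("values exceed ", bits, "-bit range")
    fmt <- 1L
  } else {
    bits <- 32L
    fmt <- 3L
  }
  h <- nrow(m); w <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  wu16 <- function(x) writeBin(as.integer(ifelse(x > 32767, x - 65536, x)),
                               con, size = 2, endian = "little")
  wu32 <- function(x) writeBin(as.integer(ifelse(x > 2^31 - 1, x - 2^32, x)),
                               con, size = 4, endian = "little")
  entries <- list( # tag, type, count, value
    c(256, 4, 1, w), c(257, 4, 1, h), c(258, 3, 1, bits), c(259, 3, 1, 1),
    c(262, 3, 1, 1), c(273, 4, 1, NA), c(277, 3, 1, 1), c(278, 4, 1, h),
    c(279, 4, 1, h * w * bits / 8), c(339, 3, 1, fmt)
  )
  n <- length(entries)
  data_off <- 8 + 2 + n * 12 + 4
  writeBin(charToRaw("II"), con); wu16(42); wu32(8)
  wu16(n)
  for (e in entries) {
    if (e[1] == 273) e[4] <- data_off
    wu16(e[1]); wu16(e[2]); wu32(e[3])
    if (e[2] == 3) { wu16(e[4]); wu16(0) } else wu32(e[4])
  }
  wu32(0) # no next IFD
  v <- as.vector(t(m)) # TIFF stores rows sequentially
  if (fmt == 3) writeBin(v, con, size = 4, endian = "little")
  else if (bits == 8) writeBin(as.raw(v), con)
  else if (bits == 16) wu16(v)
  else wu32(v)
  invisible(path)
}
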