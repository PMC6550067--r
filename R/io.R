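# Multi-page TIFF I/O for image stacks and label volumes.
#
# A deliberately small baseline-TIFF codec (uncompressed, single-sample
# grayscale, little-endian written; both byte orders read) — the R stack
# here has no TIFF package, and the subset below round-trips everything
# this package produces.  Voxel sizes travel in an ImageDescription JSON
# payload, with an optional "<path>.json" sidecar as fallback.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, ImageDescription = 270L,
               StripOffsets = 273L, SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

uint16_to_raw <- function(x) {
  x <- as.integer(round(x))
  r <- raw(2L * length(x))
  r[seq(1, length(r), 2)] <- as.raw(x %% 256L)
  r[seq(2, length(r), 2)] <- as.raw(x %/% 256L)
  r
}

uint32_to_raw <- function(x) {
  r <- raw(4L * length(x))
  for (b in 0:3) r[seq(b + 1L, length(r), 4)] <- as.raw((x %/% 256^b) %% 256)
  r
}

# One IFD entry: tag, type, count, value/offset (value fits in 4 bytes here).
ifd_entry <- function(tag, type, count, value) {
  c(uint16_to_raw(tag), uint16_to_raw(type), uint32_to_raw(count),
    if (type == 3L && count == 1L) c(uint16_to_raw(value), as.raw(c(0, 0)))
    else uint32_to_raw(value))
}

#' Write a 3D array as an uncompressed multi-page grayscale TIFF
#'
#' @param data 2D or 3D numeric array (rows, cols, planes).
#' @param path output file.
#' @param voxel_size numeric triple (um) stored in the embedded JSON
#'   description (keys `axes`, `voxel_size_um`, plus `...` extras).
#' @param bits 8 or 16 for unsigned integer data, 32 for IEEE float.
#'   Default picks 8 for integer data in [0,255], 16 for integer data in
#'   [0,65535], else 32-bit float.
#' @param ... extra scalar metadata stored in the description JSON
#'   (e.g. `modality`).
#' @export
write_tiff <- function(data, path, voxel_size = NULL, bits = NULL, ...) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  d <- dim(data)
  if (is.null(bits)) {
    is_int <- is.integer(data) ||
      (is.numeric(data) && max(abs(data - round(data))) == 0)
    bits <- if (is_int && min(data) >= 0 && max(data) <= 255) 8L
    else if (is_int && min(data) >= 0 && max(data) <= 65535) 16L
    else 32L
  }
  fmt <- if (bits == 32L) 3L else 1L
  meta <- c(list(axes = "row,col,plane"),
            if (!is.null(voxel_size)) list(voxel_size_um = as.numeric(voxel_size)),
            list(...))
  desc <- as.character(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  desc_raw <- c(charToRaw(desc), as.raw(0L))
  if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0L))

  npix <- d[1] * d[2]
  bytes_per_page <- npix * bits / 8L
  n_entries <- 11L
  ifd_size <- 2L + n_entries * 12L + 4L
  # layout: 8-byte header | desc | page data x n | IFDs x n
  desc_off <- 8L
  data_off <- desc_off + length(desc_raw)
  ifd0_off <- data_off + d[3] * bytes_per_page
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), as.raw(c(42L, 0L))), con)  # little-endian magic
  writeBin(uint32_to_raw(ifd0_off), con)
  writeBin(desc_raw, con)
  for (k in seq_len(d[3])) {
    page <- t(data[, , k])            # row-major pixel order within a row
    page <- as.vector(page)           # cols fastest -> TIFF row-major
    if (bits == 8L) writeBin(as.raw(as.integer(round(page))), con)
    else if (bits == 16L) writeBin(uint16_to_raw(page), con)
    else writeBin(as.numeric(page), con, size = 4L, endian = "little")
  }
  for (k in seq_len(d[3])) {
    entries <- c(
      ifd_entry(TIFF_TAGS[["ImageWidth"]], 4L, 1L, d[2]),
      ifd_entry(TIFF_TAGS[["ImageLength"]], 4L, 1L, d[1]),
      ifd_entry(TIFF_TAGS[["BitsPerSample"]], 3L, 1L, bits),
      ifd_entry(TIFF_TAGS[["Compression"]], 3L, 1L, 1L),
      ifd_entry(TIFF_TAGS[["Photometric"]], 3L, 1L, 1L),
      ifd_entry(TIFF_TAGS[["ImageDescription"]], 2L, length(desc_raw), desc_off),
      ifd_entry(TIFF_TAGS[["StripOffsets"]], 4L, 1L,
                data_off + (k - 1L) * bytes_per_page),
      ifd_entry(TIFF_TAGS[["SamplesPerPixel"]], 3L, 1L, 1L),
      ifd_entry(TIFF_TAGS[["RowsPerStrip"]], 4L, 1L, d[1]),
      ifd_entry(TIFF_TAGS[["StripByteCounts"]], 4L, 1L, bytes_per_page),
      ifd_entry(TIFF_TAGS[["SampleFormat"]], 3L, 1L, fmt))
    next_off <- if (k < d[3]) ifd0_off + k * ifd_size else 0L
    writeBin(c(uint16_to_raw(n_entries), entries, uint32_to_raw(next_off)), con)
  }
  invisible(path)
}

read_uint <- function(r, off, size, endian) {
  v <- readBin(r[(off + 1):(off + size)], "integer", n = 1L, size = size,
               signed = size >= 4L, endian = endian)
  if (size == 4L && v < 0) v <- v + 2^32
  v
}

#' Read an uncompressed grayscale multi-page TIFF
#'
#' Supports the subset written by [write_tiff()]: both byte orders,
#' 8/16-bit unsigned, 32-bit signed/unsigned integer, and 32-bit float
#' samples, strip-based storage, one sample per pixel.
#'
#' @param path TIFF file.
#' @return 3D array with attribute `description` (the ImageDescription
#'   string of the first page, if any).
#' @export
read_tiff <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  order <- rawToChar(r[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big"
  else stop("not a TIFF file: ", path)
  if (read_uint(r, 2L, 2L, endian) != 42L) stop("bad TIFF magic: ", path)
  ifd_off <- read_uint(r, 4L, 4L, endian)
  pages <- list()
  desc <- NULL
  while (ifd_off != 0L) {
    n <- read_uint(r, ifd_off, 2L, endian)
    tags <- list()
    for (e in seq_len(n)) {
      eo <- ifd_off + 2L + (e - 1L) * 12L
      tag <- read_uint(r, eo, 2L, endian)
      type <- read_uint(r, eo + 2L, 2L, endian)
      count <- read_uint(r, eo + 4L, 4L, endian)
      tsz <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)[type]
      vo <- if (count * tsz <= 4L) eo + 8L else read_uint(r, eo + 8L, 4L, endian)
      tags[[as.character(tag)]] <- list(type = type, count = count, off = vo)
    }
    get1 <- function(id, default = NULL) {
      t <- tags[[as.character(id)]]
      if (is.null(t)) return(default)
      sz <- if (t$type == 3L) 2L else 4L
      read_uint(r, t$off, sz, endian)
    }
    getvec <- function(id) {
      t <- tags[[as.character(id)]]
      sz <- if (t$type == 3L) 2L else 4L
      vapply(seq_len(t$count) - 1L,
             function(i) read_uint(r, t$off + i * sz, sz, endian), numeric(1))
    }
    w <- get1(256L); h <- get1(257L)
    bits <- get1(258L, 8L)
    if (get1(259L, 1L) != 1L) stop("only uncompressed TIFF supported")
    if (get1(277L, 1L) != 1L) stop("only single-sample TIFF supported")
    fmt <- get1(339L, 1L)
    offs <- getvec(273L)
    cnts <- getvec(279L)
    if (is.null(desc)) {
      t <- tags[["270"]]
      if (!is.null(t)) {
        bytes <- r[(t$off + 1):(t$off + t$count)]
        bytes <- bytes[bytes != as.raw(0L)]
        desc <- rawToChar(bytes)
      }
    }
    buf <- unlist(lapply(seq_along(offs), function(i)
      r[(offs[i] + 1):(offs[i] + cnts[i])]), use.names = FALSE)
    vals <- if (fmt == 3L)
      readBin(buf, "double", n = w * h, size = 4L, endian = endian)
    else if (bits == 8L) as.integer(buf)
    else {
      v <- readBin(buf, "integer", n = w * h, size = bits / 8L,
                   signed = bits >= 32L, endian = endian)
      v
    }
    pages[[length(pages) + 1L]] <- t(matrix(vals, nrow = w, ncol = h))
    ifd_off <- read_uint(r, ifd_off + 2L + n * 12L, 4L, endian)
  }
  d1 <- dim(pages[[1]])
  out <- array(unlist(pages, use.names = FALSE), c(d1, length(pages)))
  attr(out, "description") <- desc
  out
}

parse_stack_metadata <- function(path, desc) {
  meta <- NULL
  if (!is.null(desc))
    meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
  if (is.null(meta$voxel_size_um)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) meta <- jsonlite::fromJSON(sidecar)
  }
  if (is.null(meta$voxel_size_um))
    stop("no voxel size in TIFF metadata of '", path,
         "'; provide a '", basename(path), ".json' sidecar with voxel_size_um")
  meta
}

#' Write an image stack (or label volume) to TIFF
#'
#' Voxel sizes, origin and modality are embedded in the ImageDescription
#' JSON; integer data round-trips losslessly through [read_stack()].
#'
#' @param stack an [image_stack()] or [label_volume()].
#' @param path output TIFF path.
#' @param ... passed to [write_tiff()] (e.g. `bits`).
#' @export
write_stack <- function(stack, path, ...) {
  is_labels <- inherits(stack, "label_volume")
  md <- stack$modality %||% if (is_labels) "labels" else "unknown"
  write_tiff(stack$data, path, voxel_size = stack$grid$voxel_size,
             origin_um = stack$grid$origin, modality = md, ...)
  if (is_labels) {
    sidecar <- paste0(path, ".materials.json")
    jsonlite::write_json(as.list(stack$materials), sidecar, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read an image stack from TIFF
#'
#' Voxel sizes are taken from the embedded metadata, falling back to a
#' `<path>.json` sidecar; an error demands the sidecar if both are absent.
#' A 2D TIFF is returned as a single-plane stack.  If a
#' `<path>.materials.json` sidecar exists the result is a
#' [label_volume()], otherwise an [image_stack()].
#'
#' @param path TIFF file.
#' @export
read_stack <- function(path) {
  arr <- read_tiff(path)
  meta <- parse_stack_metadata(path, attr(arr, "description"))
  attr(arr, "description") <- NULL
  grid <- grid_spec(dim(arr), meta$voxel_size_um,
                    origin = meta$origin_um %||% c(0, 0, 0))
  matfile <- paste0(path, ".materials.json")
  if (file.exists(matfile)) {
    mats <- unlist(jsonlite::fromJSON(matfile))
    label_volume(arr, grid, materials = mats)
  } else {
    image_stack(arr, grid, modality = meta$modality %||% "unknown")
  }
}
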