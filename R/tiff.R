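## Minimal baseline TIFF codec for volumetric stacks.
##
## No TIFF reader is available in the supported dependency set, so the
## package carries its own implementation of the small corner of the format
## it needs: little-endian, uncompressed, single-sample grayscale pages
## (uint8 / uint16 / float32), one page per z plane in increasing-z order.
## Stack metadata (pixel size, plane spacing, intensity scale) travels in an
## ImageDescription JSON on the first page.  Anything fancier (compression,
## tiles, RGB, BigTIFF) is rejected with a clear error.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, ImageDescription = 270L,
               StripOffsets = 273L, SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

#' Write an image stack as multi-page TIFF
#'
#' Pages are written in increasing-z order. For integer output the voxel
#' values are linearly scaled by `(2^bits - 1) / max(voxels)` (identity if
#' the stack is empty of signal) and rounded; the scale factor is recorded in
#' the ImageDescription JSON so [read_stack()] can undo it. `bits = "float32"`
#' stores the values losslessly.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @param bits one of `8`, `16` (default) or `"float32"`.
#' @return Invisibly, the intensity scale factor that was applied.
#' @export
write_stack <- function(stack, path, bits = 16) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  d <- dim(v)
  float_out <- identical(bits, "float32")
  if (!float_out && !bits %in% c(8, 16)) {
    stop_invalid_parameter("`bits` must be 8, 16 or \"float32\"")
  }
  mx <- max(v)
  scale <- if (float_out || mx <= 0) 1 else (2^bits - 1) / mx
  desc <- jsonlite::toJSON(list(pixel_size_um = stack$pixel_size,
                                plane_spacing_um = stack$plane_spacing,
                                intensity_scale = scale),
                           auto_unbox = TRUE, digits = NA)
  desc_raw <- c(charToRaw(as.character(desc)), as.raw(0L))

  nz <- d[1]; ny <- d[2]; nx <- d[3]
  bps <- if (float_out) 32L else as.integer(bits)
  bytes_pp <- bps %/% 8L
  page_bytes <- ny * nx * bytes_pp
  sample_format <- if (float_out) 3L else 1L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(c(42L), con, size = 2, endian = "little")
  data_start <- 8L
  ifd_area <- data_start + nz * page_bytes          # description, then IFDs
  desc_off <- ifd_area
  first_ifd <- desc_off + length(desc_raw)
  if (first_ifd %% 2L == 1L) first_ifd <- first_ifd + 1L
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")
  ## pixel data, one page at a time, rows within a page contiguous
  for (k in seq_len(nz)) {
    vals <- as.vector(t(v[k, , ]))
    if (float_out) {
      writeBin(as.numeric(vals), con, size = 4, endian = "little")
    } else {
      writeBin(as.integer(round(vals * scale)), con, size = bytes_pp,
               endian = "little")
    }
  }
  writeBin(desc_raw, con)
  if ((desc_off + length(desc_raw)) %% 2L == 1L) writeBin(as.raw(0L), con)

  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L && count == 1L) {        # SHORT packed into 4-byte slot
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  ifd_size <- function(n_entries) 2L + n_entries * 12L + 4L
  ifd_offsets <- first_ifd + (seq_len(nz) - 1L) * ifd_size(11L)
  for (k in seq_len(nz)) {
    writeBin(11L, con, size = 2, endian = "little")
    entry(256L, 4L, 1L, nx)
    entry(257L, 4L, 1L, ny)
    entry(258L, 3L, 1L, bps)
    entry(259L, 3L, 1L, 1L)                  # no compression
    entry(262L, 3L, 1L, 1L)                  # BlackIsZero
    entry(270L, 2L, length(desc_raw), desc_off)
    entry(273L, 4L, 1L, data_start + (k - 1L) * page_bytes)
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, ny)
    entry(279L, 4L, 1L, page_bytes)
    entry(339L, 3L, 1L, sample_format)
    writeBin(if (k < nz) as.integer(ifd_offsets[k + 1L]) else 0L,
             con, size = 4, endian = "little")
  }
  invisible(scale)
}

read_uint <- function(raw, off, size, endian) {
  b <- as.integer(raw[off + seq_len(size)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1))
}

#' Read a multi-page TIFF stack
#'
#' Supports the grayscale baseline subset written by [write_stack()] (and by
#' common scientific writers when saving uncompressed single-channel data):
#' uncompressed, 8/16-bit unsigned or 32-bit float, one sample per pixel,
#' strip-organized. Pages are stacked in file order as increasing z.
#'
#' @param path TIFF file path.
#' @param rescale if `TRUE` (default) and the file carries an
#'   `intensity_scale` written by [write_stack()], divide it back out to
#'   recover the original intensities.
#' @return An [image_stack()]; pixel size and plane spacing are taken from
#'   the embedded description when present, else 1.
#' @export
read_stack <- function(path, rescale = TRUE) {
  if (!file.exists(path)) stop_invalid_input(sprintf("no such file: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stop_invalid_input(sprintf("truncated TIFF: %s", path))
  byte_order <- rawToChar(raw[1:2])
  endian <- if (byte_order == "II") "little" else if (byte_order == "MM") "big" else
    stop_invalid_input(sprintf("not a TIFF file: %s", path))
  if (read_uint(raw, 2, 2, endian) != 42) {
    stop_invalid_input(sprintf("not a baseline TIFF (bad magic): %s", path))
  }
  ifd_off <- read_uint(raw, 4, 4, endian)
  planes <- list()
  desc <- NULL
  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)
  while (ifd_off != 0) {
    if (ifd_off + 2 > length(raw)) stop_invalid_input("truncated TIFF IFD")
    n <- read_uint(raw, ifd_off, 2, endian)
    tags <- list()
    for (e in seq_len(n)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- read_uint(raw, base, 2, endian)
      typ <- read_uint(raw, base + 2, 2, endian)
      cnt <- read_uint(raw, base + 4, 4, endian)
      ts <- type_size[as.character(typ)]
      if (is.na(ts)) { tags[[as.character(tag)]] <- NULL; next }
      nbytes <- ts * cnt
      voff <- if (nbytes <= 4) base + 8 else read_uint(raw, base + 8, 4, endian)
      vals <- if (typ == 2L) {
        rawToChar(raw[voff + seq_len(max(cnt - 1, 0))])
      } else {
        vapply(seq_len(cnt), function(i)
          read_uint(raw, voff + (i - 1) * ts, ts, endian), numeric(1))
      }
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) {
      x <- tags[[as.character(TIFF_TAGS[[tag]])]]
      if (is.null(x)) default else x
    }
    width <- g("ImageWidth"); height <- g("ImageLength")
    if (is.null(width) || is.null(height)) stop_invalid_input("TIFF page missing dimensions")
    if (g("Compression", 1) != 1) {
      stop_invalid_input(sprintf("unsupported TIFF compression %d (only uncompressed is supported)",
                                 g("Compression")))
    }
    if (g("SamplesPerPixel", 1) != 1) {
      stop_invalid_input("only single-sample (grayscale) TIFF is supported")
    }
    bps <- g("BitsPerSample", 1)
    fmt <- g("SampleFormat", 1)
    offs <- g("StripOffsets"); cnts <- g("StripByteCounts")
    if (is.null(offs) || is.null(cnts)) stop_invalid_input("TIFF page missing strip layout")
    payload <- raw(0)
    for (s in seq_along(offs)) {
      if (offs[s] + cnts[s] > length(raw)) stop_invalid_input("truncated TIFF strip")
      payload <- c(payload, raw[offs[s] + seq_len(cnts[s])])
    }
    npix <- width * height
    vals <- if (fmt == 3 && bps == 32) {
      readBin(payload, "double", n = npix, size = 4, endian = endian)
    } else if (fmt %in% c(1, 4) && bps %in% c(8, 16)) {
      readBin(payload, "integer", n = npix, size = bps / 8, signed = FALSE,
              endian = endian)
    } else {
      stop_invalid_input(sprintf("unsupported TIFF sample layout (bits %d, format %d)",
                                 bps, fmt))
    }
    if (length(vals) < npix) stop_invalid_input("TIFF strip data shorter than page")
    if (is.null(desc)) desc <- g("ImageDescription")
    planes[[length(planes) + 1L]] <- matrix(vals, nrow = height, ncol = width,
                                            byrow = TRUE)
    ifd_off <- read_uint(raw, ifd_off + 2 + n * 12, 4, endian)
  }
  if (length(planes) == 0) stop_invalid_input("TIFF contains no pages")
  ny <- nrow(planes[[1]]); nx <- ncol(planes[[1]])
  vol <- array(0, c(length(planes), ny, nx))
  for (k in seq_along(planes)) {
    if (!all(dim(planes[[k]]) == c(ny, nx))) {
      stop_invalid_input("TIFF pages have inconsistent dimensions")
    }
    vol[k, , ] <- planes[[k]]
  }
  px <- 1; dz <- 1
  meta <- NULL
  if (!is.null(desc)) {
    meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
  }
  if (!is.null(meta)) {
    if (!is.null(meta$pixel_size_um)) px <- meta$pixel_size_um
    if (!is.null(meta$plane_spacing_um)) dz <- meta$plane_spacing_um
    if (rescale && !is.null(meta$intensity_scale) && meta$intensity_scale > 0) {
      vol <- vol / meta$intensity_scale
    }
  }
  image_stack(vol, px, dz)
}
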