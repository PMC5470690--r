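# Raster I/O. PNG is delegated to the png package; TIFF is a minimal
# baseline codec written here (uncompressed, chunky, 8-bit RGB only)
# because no TIFF reader is available in the dependency set. Anything the
# baseline subset cannot represent raises a format error naming the
# offending property.

PNG_SIGNATURE <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))

sniff_format <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 8L)
  if (length(head) >= 8L && identical(head, PNG_SIGNATURE)) return("png")
  if (length(head) >= 4L) {
    ii <- head[1] == as.raw(0x49) && head[2] == as.raw(0x49) &&
      head[3] == as.raw(42) && head[4] == as.raw(0)
    mm <- head[1] == as.raw(0x4d) && head[2] == as.raw(0x4d) &&
      head[3] == as.raw(0) && head[4] == as.raw(42)
    if (ii || mm) return("tiff")
  }
  stop_io(sprintf("unrecognized image format in '%s' (expected PNG or TIFF)", path))
}

# PNG IHDR fields; png::readPNG normalizes away the bit depth, so it is
# re-read from the header to reject non-8-bit input explicitly.
png_header_info <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 26L)
  if (length(head) < 26L) stop_io(sprintf("truncated PNG file '%s'", path))
  list(bit_depth = as.integer(head[25]), color_type = as.integer(head[26]))
}

read_png_rgb <- function(path) {
  info <- png_header_info(path)
  if (info$bit_depth != 8L)
    stop_validation(sprintf("'%s': bit depth is %d, only 8-bit images are supported",
                            path, info$bit_depth))
  if (!info$color_type %in% c(2L, 6L))
    stop_validation(sprintf(
      "'%s': PNG color type %d is not RGB/RGBA (grayscale or palette input)",
      path, info$color_type))
  a <- png::readPNG(path)
  px <- round(a[, , 1:3, drop = FALSE] * 255)
  if (dim(a)[3] == 4L) {
    # drop alpha; fully transparent pixels become background white
    transparent <- a[, , 4] == 0
    if (any(transparent)) {
      for (ch in 1:3) {
        plane <- px[, , ch]
        plane[transparent] <- 255
        px[, , ch] <- plane
      }
    }
  }
  px
}

#' Read a section image from PNG or TIFF
#'
#' Accepts 8-bit RGB (or RGBA; alpha is dropped and fully transparent
#' pixels are treated as white background) PNG, and baseline uncompressed
#' 8-bit RGB TIFF. The format is detected from the file's magic bytes, not
#' its extension.
#'
#' @param path path to the image file.
#' @param source_id provenance tag stored on the result; defaults to the
#'   file name.
#' @return a [section_image()].
#' @export
read_section_image <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) stop_io(sprintf("image file '%s' does not exist", path))
  fmt <- sniff_format(path)
  px <- if (fmt == "png") read_png_rgb(path) else read_tiff_rgb(path)
  section_image(px, source_id = source_id)
}

#' Write a section image as PNG or TIFF
#'
#' @param image a [section_image()].
#' @param path destination; `.tif`/`.tiff` extensions select the baseline
#'   TIFF writer, anything else writes PNG.
#' @return `path`, invisibly.
#' @export
write_section_image <- function(image, path) {
  if (!inherits(image, "section_image")) stop_validation("not a section_image")
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop_io(sprintf("directory '%s' does not exist", dirname(path)))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_tiff_rgb(image$pixels, path)
  } else {
    png::writePNG(image$pixels / 255, path)
  }
  invisible(path)
}

#' Read a binary ROI mask from a single-channel PNG
#'
#' Nonzero pixels are inside the thrombus region.
#'
#' @param path path to a grayscale PNG.
#' @param shape expected `c(H, W)` of the paired section image.
#' @return an [roi_mask()] with at least one `TRUE` pixel.
#' @export
read_roi_mask <- function(path, shape) {
  if (!file.exists(path)) stop_io(sprintf("mask file '%s' does not exist", path))
  fmt <- sniff_format(path)
  if (fmt != "png") stop_validation("ROI masks must be single-channel PNG")
  info <- png_header_info(path)
  if (!info$color_type %in% c(0L, 4L))
    stop_validation(sprintf(
      "'%s': mask PNG must be single-channel (color type 0), got color type %d",
      path, info$color_type))
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  if (!identical(as.integer(dim(a)), as.integer(shape)))
    stop_validation(sprintf("mask is %d x %d but expected %d x %d",
                            nrow(a), ncol(a), shape[1], shape[2]))
  m <- a > 0
  if (!any(m)) stop_validation(sprintf("empty ROI: mask '%s' has no nonzero pixel", path))
  roi_mask(m)
}

#' Write an ROI mask as a single-channel PNG
#'
#' @param mask an [roi_mask()] or logical matrix.
#' @param path destination PNG path.
#' @return `path`, invisibly.
#' @export
write_roi_mask <- function(mask, path) {
  if (!dir.exists(dirname(path)))
    stop_io(sprintf("directory '%s' does not exist", dirname(path)))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  png::writePNG(m, path)
  invisible(path)
}

## ---- minimal baseline TIFF codec -------------------------------------

TIFF_TAGS <- c(width = 256L, length = 257L, bits_per_sample = 258L,
               compression = 259L, photometric = 262L, strip_offsets = 273L,
               samples_per_pixel = 277L, rows_per_strip = 278L,
               strip_byte_counts = 279L, planar_config = 284L)

tiff_u16 <- function(raw, i, little) {
  b <- as.integer(raw[i + 0:1])
  if (little) b[1] + 256L * b[2] else b[2] + 256L * b[1]
}

tiff_u32 <- function(raw, i, little) {
  b <- as.numeric(as.integer(raw[i + 0:3]))
  if (!little) b <- rev(b)
  b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
}

# read one IFD entry's values (types: 1 BYTE, 3 SHORT, 4 LONG)
tiff_entry_values <- function(raw, at, little) {
  type <- tiff_u16(raw, at + 2, little)
  count <- tiff_u32(raw, at + 4, little)
  size <- switch(as.character(type), "1" = 1L, "3" = 2L, "4" = 4L, NA_integer_)
  if (is.na(size) || count == 0) return(NULL)
  total <- size * count
  src <- if (total <= 4) at + 8 else tiff_u32(raw, at + 8, little) + 1
  vapply(seq_len(count), function(k) {
    off <- src + (k - 1L) * size
    switch(as.character(size),
           "1" = as.numeric(as.integer(raw[off])),
           "2" = as.numeric(tiff_u16(raw, off, little)),
           "4" = tiff_u32(raw, off, little))
  }, numeric(1))
}

read_tiff_rgb <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  little <- raw[1] == as.raw(0x49)
  ifd <- tiff_u32(raw, 5, little) + 1
  n_entries <- tiff_u16(raw, ifd, little)
  tags <- list()
  for (k in seq_len(n_entries)) {
    at <- ifd + 2 + (k - 1L) * 12L
    tag <- tiff_u16(raw, at, little)
    tags[[as.character(tag)]] <- tiff_entry_values(raw, at, little)
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(TIFF_TAGS[[tag]])]]
    if (is.null(v)) {
      if (is.null(default))
        stop_validation(sprintf("TIFF '%s': required tag '%s' missing", path, tag))
      default
    } else v
  }
  compression <- need("compression", 1)
  if (compression != 1)
    stop_validation(sprintf(
      "TIFF '%s': compression scheme %d unsupported (only uncompressed baseline)",
      path, compression))
  bits <- need("bits_per_sample", 8)
  if (any(bits != 8))
    stop_validation(sprintf(
      "TIFF '%s': bit depth is %s, only 8-bit images are supported",
      path, paste(unique(bits), collapse = "/")))
  spp <- need("samples_per_pixel", 1)
  if (spp != 3)
    stop_validation(sprintf(
      "TIFF '%s': %d samples per pixel, only 3-channel RGB is supported",
      path, spp))
  if (need("planar_config", 1) != 1)
    stop_validation(sprintf("TIFF '%s': planar configuration must be chunky", path))
  w <- need("width"); h <- need("length")
  offsets <- need("strip_offsets")
  counts <- need("strip_byte_counts", h * w * 3)
  data <- raw(0)
  for (k in seq_along(offsets))
    data <- c(data, raw[(offsets[k] + 1):(offsets[k] + counts[k])])
  if (length(data) < h * w * 3)
    stop_io(sprintf("TIFF '%s': truncated pixel data", path))
  vals <- as.integer(data[seq_len(h * w * 3)])
  # chunky RGBRGB..., row-major scanlines -> H x W x 3
  px <- array(0L, dim = c(h, w, 3))
  for (ch in 1:3)
    px[, , ch] <- matrix(vals[seq(ch, h * w * 3, by = 3)], nrow = h,
                         ncol = w, byrow = TRUE)
  px
}

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

tiff_ifd_entry <- function(tag, type, count, value) {
  v <- u32le(value)
  if (type == 3L && count == 1L) v <- c(u16le(value), as.raw(c(0, 0)))
  c(u16le(tag), u16le(type), u32le(count), v)
}

write_tiff_rgb <- function(pixels, path) {
  d <- dim(pixels)
  h <- d[1]; w <- d[2]
  # interleave to chunky row-major scanlines
  flat <- integer(h * w * 3)
  for (ch in 1:3)
    flat[seq(ch, h * w * 3, by = 3)] <- as.integer(t(pixels[, , ch]))
  data <- as.raw(flat)
  data_offset <- 8L
  ifd_offset <- data_offset + length(data)
  n_entries <- 10L
  bps_offset <- ifd_offset + 2L + n_entries * 12L + 4L
  entries <- c(
    tiff_ifd_entry(256L, 4L, 1L, w),
    tiff_ifd_entry(257L, 4L, 1L, h),
    tiff_ifd_entry(258L, 3L, 3L, bps_offset),
    tiff_ifd_entry(259L, 3L, 1L, 1L),   # uncompressed
    tiff_ifd_entry(262L, 3L, 1L, 2L),   # RGB
    tiff_ifd_entry(273L, 4L, 1L, data_offset),
    tiff_ifd_entry(277L, 3L, 1L, 3L),
    tiff_ifd_entry(278L, 4L, 1L, h),    # single strip
    tiff_ifd_entry(279L, 4L, 1L, length(data)),
    tiff_ifd_entry(284L, 3L, 1L, 1L)    # chunky
  )
  out <- c(
    as.raw(c(0x49, 0x49, 0x2a, 0x00)), u32le(ifd_offset),
    data,
    u16le(n_entries), entries, u32le(0L),
    u16le(8L), u16le(8L), u16le(8L)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}
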