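# Core record types shared by all stages. Plain S3: a section image is an
# integer H x W x 3 array plus metadata, a mask is a logical matrix, a
# composition is a named numeric triple on the simplex.

PARTS <- c("head", "body", "tail")
SERIES_PARTS <- c(PARTS, "whole")
QUANTITIES <- c("ym_kpa", "Rr", "Rp", "Rb")

# Device scale of the elastography unit (kPa); Emean outside it is rejected.
YM_SCALE_KPA <- c(0, 80)
STUDY_DAYS <- 1:14

#' Construct a section image
#'
#' An 8-bit RGB raster of a scanned, HE-stained thrombus cross-section.
#'
#' @param pixels integer array of dimension H x W x 3 with values in 0..255.
#'   Coordinates are 0-based in reports, row-major, origin top-left.
#' @param resolution_um_per_px optional positive scalar; metadata only, never
#'   used by any computation (scanner pixel size is rarely known).
#' @param source_id free-text provenance tag.
#' @return an object of class `section_image`.
#' @export
section_image <- function(pixels, resolution_um_per_px = NULL, source_id = "") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_validation("pixels must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L)
    stop_validation("image must have at least one row and one column")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_validation("channel values must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  if (!is.null(resolution_um_per_px)) {
    if (!is.numeric(resolution_um_per_px) || length(resolution_um_per_px) != 1L ||
        resolution_um_per_px <= 0)
      stop_validation("resolution_um_per_px must be a positive scalar")
  }
  structure(
    list(pixels = pixels,
         resolution_um_per_px = resolution_um_per_px,
         source_id = as.character(source_id)[1]),
    class = "section_image"
  )
}

#' @export
dim.section_image <- function(x) dim(x$pixels)

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("section_image: %d x %d px, 8-bit RGB%s\n", d[1], d[2],
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' Construct a region-of-interest mask
#'
#' @param mask logical matrix; `TRUE` marks pixels inside the thrombus
#'   cross-section. Must contain at least one `TRUE` pixel to be usable for
#'   quantification.
#' @return an object of class `roi_mask` (a classed logical matrix).
#' @export
roi_mask <- function(mask) {
  if (!is.matrix(mask)) stop_validation("mask must be a matrix")
  if (anyNA(mask)) stop_validation("mask must not contain NA")
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  structure(mask, class = c("roi_mask", "matrix"))
}

check_mask_matches <- function(image, mask) {
  di <- dim(image$pixels)[1:2]
  dm <- dim(mask)
  if (!identical(as.integer(di), as.integer(dm)))
    stop_validation(sprintf("mask is %d x %d but image is %d x %d",
                            dm[1], dm[2], di[1], di[2]))
  if (!any(mask)) stop_validation("empty ROI: mask has no TRUE pixel")
  invisible(TRUE)
}

#' Bundle an image and its ROI mask with study coordinates
#'
#' @param animal_id free text identifier.
#' @param day integer study day (1-14).
#' @param part one of `"head"`, `"body"`, `"tail"` — the trisection of the
#'   thrombus along the vessel axis.
#' @param image a [section_image()].
#' @param mask a [roi_mask()] of the same height and width.
#' @return an object of class `thrombus_section`.
#' @export
thrombus_section <- function(animal_id, day, part, image, mask) {
  part <- match.arg(tolower(as.character(part)), PARTS)
  day <- as.integer(day)
  if (is.na(day) || day < min(STUDY_DAYS) || day > max(STUDY_DAYS))
    stop_validation("day must be an integer in 1..14")
  if (!inherits(image, "section_image")) stop_validation("image must be a section_image")
  if (!inherits(mask, "roi_mask")) stop_validation("mask must be an roi_mask")
  check_mask_matches(image, mask)
  structure(
    list(animal_id = as.character(animal_id)[1], day = day, part = part,
         image = image, mask = mask),
    class = "thrombus_section"
  )
}

#' Construct a composition-fraction triple
#'
#' Relative content of a section: `Rr` (red blood cells + platelet
#' trabecula), `Rp` (fibrin), `Rb` (nuclei + calcium salt deposition). `Rb`
#' is defined as the remainder `1 - Rr - Rp`, so the triple sums to 1
#' exactly by construction.
#'
#' @param rr,rp red and pink fractions in `[0, 1]` with `rr + rp <= 1`.
#' @param rb optional blue fraction; if supplied it is checked against the
#'   remainder at tolerance `1e-9` and then replaced by the exact remainder.
#' @return named numeric vector `c(Rr=, Rp=, Rb=)` of class
#'   `composition_fractions`.
#' @export
composition_fractions <- function(rr, rp, rb = NULL) {
  if (!is.numeric(rr) || !is.numeric(rp) || length(rr) != 1L || length(rp) != 1L)
    stop_validation("rr and rp must be numeric scalars")
  if (!is.finite(rr) || !is.finite(rp) || rr < 0 || rp < 0 || rr > 1 || rp > 1)
    stop_validation("fractions must lie in [0, 1]")
  if (rr + rp > 1 + 1e-9)
    stop_validation(sprintf("rr + rp = %.6f exceeds 1", rr + rp))
  if (rr + rp > 1) rp <- 1 - rr   # float overshoot within tolerance: clamp
  # remainder computed as 1 - (rr + rp) so that the triple sums to 1 exactly
  remainder <- max(0, 1 - (rr + rp))
  if (!is.null(rb)) {
    if (abs(rb - remainder) > 1e-9)
      stop_invariant(sprintf(
        "composition does not sum to 1: Rb = %.10f but remainder is %.10f",
        rb, remainder))
  }
  structure(c(Rr = rr, Rp = rp, Rb = remainder),
            class = "composition_fractions")
}

#' @export
print.composition_fractions <- function(x, ...) {
  cat(sprintf("composition: Rr %.2f%%  Rp %.2f%%  Rb %.2f%%\n",
              100 * x[["Rr"]], 100 * x[["Rp"]], 100 * x[["Rb"]]))
  invisible(x)
}

#' Construct a daily measurement series
#'
#' One value per study day for one part and one quantity (Young's modulus
#' in kPa, or a composition fraction). Missing days are simply absent; no
#' imputation is performed anywhere downstream.
#'
#' @param part `"head"`, `"body"`, `"tail"` or `"whole"`.
#' @param quantity `"ym_kpa"`, `"Rr"`, `"Rp"` or `"Rb"`.
#' @param days strictly increasing integer days within 1..14.
#' @param values finite numeric, one per day.
#' @param sds optional non-negative per-day standard deviations (across
#'   animals when several contribute).
#' @return an object of class `daily_series`.
#' @export
daily_series <- function(part, quantity, days, values, sds = NULL) {
  part <- match.arg(tolower(as.character(part)), SERIES_PARTS)
  quantity <- match.arg(as.character(quantity), QUANTITIES)
  days <- as.integer(days)
  if (anyNA(days) || any(diff(days) <= 0))
    stop_validation("days must be strictly increasing integers")
  if (min(days) < min(STUDY_DAYS) || max(days) > max(STUDY_DAYS))
    stop_validation("days must lie within the 1..14 study window")
  values <- as.numeric(values)
  if (length(values) != length(days))
    stop_validation("values must have one entry per day")
  if (any(!is.finite(values)))
    stop_validation("values must be finite")
  if (!is.null(sds)) {
    sds <- as.numeric(sds)
    if (length(sds) != length(days))
      stop_validation("sds must have one entry per day")
    if (any(sds < 0, na.rm = TRUE))
      stop_validation("sds must be non-negative")
  }
  structure(
    list(part = part, quantity = quantity, days = days,
         values = values, sds = sds),
    class = "daily_series"
  )
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("daily_series: %s %s over days %d..%d (n = %d)\n",
              x$part, x$quantity, min(x$days), max(x$days), length(x$days)))
  invisible(x)
}

#' @export
length.daily_series <- function(x) length(x$days)
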