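# HE-stain pixel classification and composition quantification.
#
# Model: every in-ROI pixel is either background (bright and unsaturated:
# lumen, white space) or tissue; tissue pixels are assigned the nearest of
# three reference hues in RGB space — red (RBC + platelet trabecula), pink
# (fibrin), blue (nuclei + calcium salt). Red pixels are then down-weighted
# by a nonlinear function of their fractional red intensity f_red =
# R/(R+G+B), so that weakly red pixels count less toward Rr; pink and blue
# pixels carry unit mass. Rb is the remainder 1 - Rr - Rp by definition.

CLASS_LEVELS <- c("red", "pink", "blue", "background", "outside_roi")

#' Reference palette for HE pixel classification
#'
#' Reference colors are typical HE hues, not stain-chemistry constants;
#' they are configurable and are exercised through synthetic data. A pixel
#' is background when its brightness (max channel) exceeds `b0` *and* its
#' saturation `(max - min)/max` is below `s0`.
#'
#' @param red,pink,blue length-3 RGB reference triples in 0..255.
#' @param b0 background brightness threshold in `[0, 255]`.
#' @param s0 background saturation threshold in `[0, 1]`.
#' @return an object of class `qpia_palette`.
#' @export
he_palette <- function(red = c(150, 30, 40), pink = c(230, 160, 180),
                       blue = c(70, 60, 140), b0 = 230, s0 = 0.12) {
  refs <- rbind(red = red, pink = pink, blue = blue)
  if (ncol(refs) != 3L || anyNA(refs) || min(refs) < 0 || max(refs) > 255)
    stop_validation("reference colors must be RGB triples in 0..255")
  if (anyDuplicated(refs))
    stop_validation("reference colors must be pairwise distinct")
  if (b0 < 0 || b0 > 255) stop_validation("b0 must lie in [0, 255]")
  if (s0 < 0 || s0 > 1) stop_validation("s0 must lie in [0, 1]")
  structure(list(refs = refs, b0 = b0, s0 = s0), class = "qpia_palette")
}

#' Nonlinear red-weighting parameters
#'
#' The weight of a red-classified pixel is
#' `w = (max(0, (f_red - f0)/(1 - f0)))^gamma`: zero at the achromatic
#' floor `f0`, one at pure red. `gamma = 0` degenerates to unweighted
#' pixel counting (every red pixel counts 1), which is the sensitivity
#' baseline.
#'
#' @param f0 red-fraction floor in `[0, 1)`; default `1/3`, the value of
#'   `f_red` for any gray pixel.
#' @param gamma non-negative exponent; default 2.
#' @return an object of class `weighting_params`.
#' @export
weighting_params <- function(f0 = 1 / 3, gamma = 2) {
  if (!is.numeric(f0) || length(f0) != 1L || f0 < 0 || f0 >= 1)
    stop_validation("f0 must lie in [0, 1)")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0)
    stop_validation("gamma must be non-negative")
  structure(list(f0 = f0, gamma = gamma), class = "weighting_params")
}

#' Nonlinear weight of the fractional red intensity
#'
#' @param f_red fractional red intensity `R/(R+G+B)` in `[0, 1]`
#'   (defined as 0 for a black pixel); vectorized.
#' @param params a [weighting_params()].
#' @return weights in `[0, 1]`, monotone non-decreasing in `f_red`.
#' @export
red_weight <- function(f_red, params = weighting_params()) {
  pmax(0, (f_red - params$f0) / (1 - params$f0))^params$gamma
}

new_pixel_class_map <- function(codes) {
  storage.mode(codes) <- "integer"
  structure(codes, class = c("pixel_class_map", "matrix"),
            levels = CLASS_LEVELS)
}

#' Classify the pixels of a thrombus section
#'
#' In-ROI pixels that are bright and unsaturated are labeled background;
#' the rest are assigned the nearest palette reference color by Euclidean
#' distance in RGB, ties broken in the fixed order red < pink < blue.
#' Pixels outside the ROI are labeled `outside_roi`.
#'
#' @param section a [thrombus_section()].
#' @param palette a [he_palette()].
#' @return a `pixel_class_map`: an integer H x W matrix coding the levels
#'   `red, pink, blue, background, outside_roi` as 1..5.
#' @export
classify_pixels <- function(section, palette = he_palette()) {
  if (!inherits(section, "thrombus_section"))
    stop_validation("section must be a thrombus_section")
  mask <- section$mask
  if (!any(mask)) stop_validation("empty ROI: mask has no TRUE pixel")
  px <- section$image$pixels
  d <- dim(px)
  flat <- matrix(as.numeric(px), d[1] * d[2], 3)
  inside <- as.vector(mask)
  codes <- rep.int(5L, d[1] * d[2])        # outside_roi

  sub <- flat[inside, , drop = FALSE]
  brightness <- pmax(sub[, 1], sub[, 2], sub[, 3])
  darkest <- pmin(sub[, 1], sub[, 2], sub[, 3])
  saturation <- ifelse(brightness > 0, (brightness - darkest) / brightness, 0)
  is_bg <- brightness > palette$b0 & saturation < palette$s0

  refs <- palette$refs
  d2 <- sapply(1:3, function(k) {
    (sub[, 1] - refs[k, 1])^2 + (sub[, 2] - refs[k, 2])^2 + (sub[, 3] - refs[k, 3])^2
  })
  d2 <- matrix(d2, nrow = nrow(sub))
  nearest <- max.col(-d2, ties.method = "first")  # tie-break red < pink < blue
  lab <- ifelse(is_bg, 4L, nearest)
  codes[inside] <- lab
  new_pixel_class_map(matrix(codes, d[1], d[2]))
}

#' Tabulate a pixel class map
#'
#' @param labels a `pixel_class_map`.
#' @return named integer vector of pixel counts per class.
#' @export
class_counts <- function(labels) {
  counts <- tabulate(unclass(labels), nbins = length(CLASS_LEVELS))
  names(counts) <- CLASS_LEVELS
  counts
}

#' Compute composition fractions from a classified section
#'
#' Each red pixel contributes mass [red_weight()] of its fractional red
#' intensity; pink and blue pixels contribute unit mass; background and
#' out-of-ROI pixels contribute nothing (the denominator is tissue, not
#' lumen). `Rr` and `Rp` are the red and pink mass shares and `Rb` is the
#' remainder, so the triple sums to 1 exactly.
#'
#' @param labels a `pixel_class_map` from [classify_pixels()].
#' @param image the [section_image()] the labels were computed from.
#' @param params a [weighting_params()].
#' @return a [composition_fractions()] with attributes `masses` (numeric,
#'   red/pink/blue) and `counts` (per-class pixel counts).
#' @export
compute_fractions <- function(labels, image, params = weighting_params()) {
  if (!inherits(labels, "pixel_class_map"))
    stop_validation("labels must be a pixel_class_map")
  px <- image$pixels
  if (!identical(dim(px)[1:2], dim(unclass(labels))[1:2]))
    stop_validation("labels and image dimensions differ")
  codes <- as.vector(unclass(labels))
  counts <- class_counts(labels)
  n_tissue <- sum(counts[c("red", "pink", "blue")])
  if (n_tissue == 0L)
    stop_validation("degenerate section: all in-ROI pixels are background (no tissue)")

  red_idx <- which(codes == 1L)
  if (length(red_idx)) {
    flat <- matrix(as.numeric(px), length(codes), 3)
    rgb_sum <- rowSums(flat[red_idx, , drop = FALSE])
    f_red <- ifelse(rgb_sum > 0, flat[red_idx, 1] / rgb_sum, 0)
    red_mass <- sum(red_weight(f_red, params))
  } else {
    red_mass <- 0
  }
  pink_mass <- as.numeric(counts[["pink"]])
  blue_mass <- as.numeric(counts[["blue"]])
  total <- red_mass + pink_mass + blue_mass
  if (total <= 0)
    stop_validation("degenerate section: total tissue mass is zero")
  out <- composition_fractions(rr = red_mass / total, rp = pink_mass / total)
  attr(out, "masses") <- c(red = red_mass, pink = pink_mass, blue = blue_mass)
  attr(out, "counts") <- counts
  out
}

#' Quantify a thrombus section end to end
#'
#' Convenience wrapper: classify then compute fractions.
#'
#' @inheritParams classify_pixels
#' @inheritParams compute_fractions
#' @return a [composition_fractions()].
#' @export
quantify_section <- function(section, palette = he_palette(),
                             params = weighting_params()) {
  labels <- classify_pixels(section, palette)
  compute_fractions(labels, section$image, params)
}

#' Collapse triplicate replicate measurements
#'
#' The elastography protocol repeats each measurement three times and
#' takes the mean as the final Young's modulus value.
#'
#' @param values replicate Emean values (kPa).
#' @param strict if `TRUE` (default), anything other than exactly three
#'   replicates is a cardinality error; if `FALSE`, the mean of the
#'   available replicates is used and a message is logged.
#' @return arithmetic mean of the replicates.
#' @export
triplicate_mean <- function(values, strict = TRUE) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop_validation("replicate values must be finite")
  if (length(values) != 3L) {
    if (strict)
      stop_validation(sprintf("expected exactly 3 replicates, got %d", length(values)))
    if (length(values) == 0L)
      stop_validation("no replicates available")
    message(sprintf("triplicate_mean: %d replicate(s) instead of 3; using their mean",
                    length(values)))
  }
  mean(values)
}

#' Whole-thrombus elasticity from the three parts
#'
#' The whole-thrombus Young's modulus is the mean of the head, body and
#' tail values, reported to 2 decimals.
#'
#' @param head,body,tail per-part YM values (kPa) for one animal-day.
#' @return mean YM in kPa, rounded to 2 decimals.
#' @export
aggregate_whole_elasticity <- function(head, body, tail) {
  vals <- list(head = head, body = body, tail = tail)
  for (p in names(vals)) {
    v <- vals[[p]]
    if (is.null(v) || length(v) != 1L || !is.finite(as.numeric(v)))
      stop_validation(sprintf("missing or non-finite value for part '%s'", p))
  }
  round(mean(c(head, body, tail)), 2)
}

#' Whole-thrombus composition from the three parts
#'
#' Componentwise mean of the three per-part fraction triples; the result
#' still lies on the simplex (Rb recomputed as the exact remainder).
#'
#' @param head,body,tail [composition_fractions()] triples.
#' @return a [composition_fractions()].
#' @export
aggregate_whole_composition <- function(head, body, tail) {
  parts <- list(head = head, body = body, tail = tail)
  for (p in names(parts)) {
    v <- parts[[p]]
    if (!is.numeric(v) || length(v) != 3L)
      stop_validation(sprintf("part '%s' is not a fraction triple", p))
    if (abs(sum(v) - 1) > 1e-9)
      stop_invariant(sprintf("part '%s' composition sums to %.12f, not 1", p, sum(v)))
  }
  m <- (as.numeric(head) + as.numeric(body) + as.numeric(tail)) / 3
  composition_fractions(rr = m[1], rp = m[2])
}
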