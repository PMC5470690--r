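# Seeded synthetic-data generators: histology-like section images with
# planted class maps, elasticity and composition day-series with planted
# changepoints and reversal, and a full multi-animal cohort emitting the
# exact file formats the pipeline consumes.
#
# Every generator uses a single RNG stream seeded explicitly from its
# spec; the caller's RNG state is saved and restored. Identical spec +
# seed therefore yields bitwise-identical artifacts.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Defaults taken from the study's printed per-part Young's-modulus
# endpoints (day 1 -> day 14, kPa).
PART_YM_ENDPOINTS <- list(
  head = c(2.01, 13.29), body = c(3.27, 15.91),
  tail = c(1.79, 10.51), whole = c(2.36, 13.24)
)
# Observed recanalization days per part; "whole" uses the latest side.
PART_REVERSAL_DAY <- c(head = 9L, tail = 10L, body = 11L, whole = 10L)

# Fraction of the total rise/decline attributed to each of the three
# segments. With default changepoints (4, 7) over days 1..14 this yields
# the low/high/medium slope ordering seen in the study curves.
SEGMENT_RISE_SHARES <- c(0.10, 0.55, 0.35)

#' Specification of a synthetic section image
#'
#' @param height,width raster size in pixels.
#' @param target_fractions named or positional `(red, pink, blue)` target
#'   area fractions of the ROI; non-negative, summing to at most 1. The
#'   remainder of the ROI is white background (lumen).
#' @param blob_scale spatial correlation length of the class regions, in
#'   pixels (Gaussian smoothing sigma of the underlying random field).
#' @param color_noise_sd per-channel Gaussian color noise SD in 8-bit
#'   units (0 = exact palette colors).
#' @param seed integer RNG seed.
#' @return an object of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(height = 256L, width = 256L,
                                 target_fractions = c(red = 0.55, pink = 0.27, blue = 0.08),
                                 blob_scale = 8, color_noise_sd = 12,
                                 seed = 1L) {
  tf <- as.numeric(target_fractions)
  if (length(tf) != 3L || anyNA(tf) || any(tf < 0) || any(tf > 1))
    stop_validation("target_fractions must be three values in [0, 1]")
  if (sum(tf) > 1 + 1e-12)
    stop_validation(sprintf("target_fractions sum to %.4f > 1", sum(tf)))
  if (sum(tf) <= 0)
    stop_validation("target_fractions must plant some tissue")
  if (height < 8L || width < 8L)
    stop_validation("image must be at least 8 x 8")
  if (blob_scale <= 0) stop_validation("blob_scale must be positive")
  if (color_noise_sd < 0) stop_validation("color_noise_sd must be non-negative")
  structure(list(height = as.integer(height), width = as.integer(width),
                 target_fractions = c(red = tf[1], pink = tf[2], blue = tf[3]),
                 blob_scale = blob_scale, color_noise_sd = color_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

# circular Gaussian smoothing of a matrix via FFT
smooth_field <- function(z, sigma) {
  h <- nrow(z); w <- ncol(z)
  gy <- stats::dnorm(pmin(0:(h - 1), h - (0:(h - 1))), sd = sigma)
  gx <- stats::dnorm(pmin(0:(w - 1), w - (0:(w - 1))), sd = sigma)
  k <- outer(gy, gx)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (h * w)
}

ellipse_mask <- function(h, w) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ry <- h / 2 - 1; rx <- w / 2 - 1
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
}

#' Generate a synthetic HE-like section with planted ground truth
#'
#' A Gaussian random field is smoothed at `blob_scale` and its in-ROI
#' quantiles are assigned to red, pink, blue and background in target
#' proportions, producing interleaved blob-shaped regions similar to real
#' section texture. Pixels are colored with the default palette reference
#' colors plus clipped Gaussian channel noise; the ROI is the inscribed
#' ellipse; out-of-ROI pixels are white.
#'
#' @param spec a [synthetic_image_spec()].
#' @param palette the [he_palette()] whose reference colors are painted.
#' @return a list of class `synthetic_section`: `image`
#'   ([section_image()]), `mask` ([roi_mask()]), `labels` (the planted
#'   `pixel_class_map`), `fractions` (planted [composition_fractions()]
#'   over tissue pixels), `achieved_area_fractions` (per-class share of
#'   the ROI) and `spec`.
#' @export
generate_section_image <- function(spec, palette = he_palette()) {
  if (!inherits(spec, "synthetic_image_spec"))
    stop_validation("spec must be a synthetic_image_spec")
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    field <- smooth_field(matrix(stats::rnorm(h * w), h, w), spec$blob_scale)
    mask <- ellipse_mask(h, w)
    inside <- which(mask)
    n <- length(inside)

    # quantile assignment: exact planted counts, within 1 px of target
    tf <- spec$target_fractions
    n_red <- round(tf[["red"]] * n)
    n_pink <- round(tf[["pink"]] * n)
    n_blue <- round(tf[["blue"]] * n)
    while (n_red + n_pink + n_blue > n) n_blue <- n_blue - 1L
    ord <- inside[order(field[inside])]
    codes <- rep.int(5L, h * w)
    codes[inside] <- 4L                                   # background
    take <- 0L
    for (cls in list(c(1L, n_red), c(2L, n_pink), c(3L, n_blue))) {
      if (cls[2] > 0)
        codes[ord[(take + 1L):(take + cls[2])]] <- cls[1]
      take <- take + cls[2]
    }
    labels <- new_pixel_class_map(matrix(codes, h, w))

    colors <- rbind(palette$refs, background = c(255, 255, 255),
                    outside_roi = c(255, 255, 255))
    px <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) px[, , ch] <- matrix(colors[codes, ch], h, w)
    if (spec$color_noise_sd > 0) {
      noise <- array(stats::rnorm(h * w * 3, sd = spec$color_noise_sd),
                     dim = c(h, w, 3))
      for (ch in 1:3) noise[, , ch][!mask] <- 0   # outside stays clean white
      px <- px + noise
    }
    px <- array(round(pmin(255, pmax(0, px))), dim = c(h, w, 3))

    n_tissue <- n_red + n_pink + n_blue
    fractions <- composition_fractions(rr = n_red / n_tissue,
                                       rp = n_pink / n_tissue)
    structure(
      list(image = section_image(px, source_id = sprintf("synthetic:seed=%d", spec$seed)),
           mask = roi_mask(mask),
           labels = labels,
           fractions = fractions,
           achieved_area_fractions = c(red = n_red / n, pink = n_pink / n,
                                       blue = n_blue / n,
                                       background = (n - n_tissue) / n),
           spec = spec),
      class = "synthetic_section"
    )
  })
}

#' Specification of a synthetic daily series
#'
#' Defaults are the study's stated world: per-part Young's modulus rising
#' between the printed day-1/day-14 endpoints with changepoints at days 4
#' and 7; composition declining from Rr about 0.95 with a recanalization
#' reversal on day 9 (head), 10 (tail) or 11 (body); measurement noise
#' growing with day.
#'
#' @param part `"head"`, `"body"`, `"tail"` or `"whole"`.
#' @param quantity `"ym_kpa"` or `"Rr"` (composition generator).
#' @param start_value,end_value series endpoints; defaults per part from
#'   the printed ranges (elasticity) or 0.96 -> floor 0.45 (Rr).
#' @param changepoints ordered interior day pair; default `c(4, 7)`.
#' @param noise_sd0 baseline noise SD at day 1 (kPa, or fraction units);
#'   defaults 0.3 kPa / 0.02.
#' @param noise_growth per-day relative noise inflation; the day-d SD is
#'   `noise_sd0 * (1 + noise_growth * (d - 1))`. Defaults 0.35 / 0.15.
#' @param reversal_day composition only: day the Rr rise begins (the
#'   planted curve bottoms out on `reversal_day - 1`); `NA` disables it.
#' @param seed integer RNG seed.
#' @return an object of class `synthetic_series_spec`.
#' @export
synthetic_series_spec <- function(part = "whole", quantity = "ym_kpa",
                                  start_value = NULL, end_value = NULL,
                                  changepoints = c(4L, 7L),
                                  noise_sd0 = NULL, noise_growth = NULL,
                                  reversal_day = NULL, seed = 1L) {
  part <- match.arg(tolower(as.character(part)), SERIES_PARTS)
  quantity <- match.arg(as.character(quantity), c("ym_kpa", "Rr"))
  changepoints <- as.integer(changepoints)
  if (length(changepoints) != 2L || changepoints[1] >= changepoints[2] ||
      changepoints[1] < 2L || changepoints[2] > 13L)
    stop_validation("changepoints must be an ordered interior pair within days 2..13")
  if (quantity == "ym_kpa") {
    ep <- PART_YM_ENDPOINTS[[part]]
    if (is.null(start_value)) start_value <- ep[1]
    if (is.null(end_value)) end_value <- ep[2]
    if (end_value < start_value)
      stop_validation("end_value < start_value: only the stiffening regime is emulated")
    if (is.null(noise_sd0)) noise_sd0 <- 0.3
    if (is.null(noise_growth)) noise_growth <- 0.35
    reversal_day <- NA_integer_
  } else {
    if (is.null(start_value)) start_value <- 0.96
    if (is.null(end_value)) end_value <- 0.45
    if (end_value > start_value)
      stop_validation("composition Rr must decline: end_value (floor) > start_value")
    if (is.null(noise_sd0)) noise_sd0 <- 0.02
    if (is.null(noise_growth)) noise_growth <- 0.15
    if (is.null(reversal_day)) reversal_day <- PART_REVERSAL_DAY[[part]]
    if (!is.na(reversal_day)) {
      reversal_day <- as.integer(reversal_day)
      if (reversal_day <= changepoints[2])
        stop_validation("reversal_day must lie after the second changepoint")
      if (reversal_day > 13L)
        stop_validation("reversal_day must leave at least one post-reversal day")
    }
  }
  if (noise_sd0 < 0 || noise_growth < 0)
    stop_validation("noise parameters must be non-negative")
  structure(list(part = part, quantity = quantity,
                 start_value = start_value, end_value = end_value,
                 changepoints = changepoints,
                 noise_sd0 = noise_sd0, noise_growth = noise_growth,
                 reversal_day = if (is.null(reversal_day)) NA_integer_ else reversal_day,
                 seed = as.integer(seed)),
            class = "synthetic_series_spec")
}

# noiseless three-segment mean curve through days 1..14
piecewise_mean_curve <- function(start_value, end_value, changepoints,
                                 days = STUDY_DAYS) {
  total <- end_value - start_value
  knots_x <- c(days[1], changepoints[1], changepoints[2], days[length(days)])
  knots_y <- start_value + total * cumsum(c(0, SEGMENT_RISE_SHARES))
  stats::approx(knots_x, knots_y, xout = days)$y
}

series_noise_sd <- function(spec, days = STUDY_DAYS) {
  spec$noise_sd0 * (1 + spec$noise_growth * (days - 1))
}

#' Generate a per-part Young's-modulus day series
#'
#' Continuous three-segment piecewise-linear mean curve between the spec
#' endpoints (slope ordering low/high/medium around the changepoints),
#' plus heteroscedastic Gaussian noise, clipped at 0.
#'
#' @param spec a [synthetic_series_spec()] with `quantity = "ym_kpa"`.
#' @return a [daily_series()] over days 1..14; the nominal per-day noise
#'   SDs are attached as `sds`.
#' @export
generate_elasticity_series <- function(spec) {
  if (!inherits(spec, "synthetic_series_spec") || spec$quantity != "ym_kpa")
    stop_validation("spec must be a synthetic_series_spec for ym_kpa")
  days <- STUDY_DAYS
  mu <- piecewise_mean_curve(spec$start_value, spec$end_value,
                             spec$changepoints, days)
  sds <- series_noise_sd(spec, days)
  values <- with_seed(spec$seed, pmax(0, mu + stats::rnorm(length(days), sd = sds)))
  daily_series(spec$part, "ym_kpa", days, values, sds = sds)
}

# composition mean curves: Rr declines to its floor on reversal_day - 1,
# then rises; Rp and Rb absorb the complement in fixed 0.8 / 0.2 shares
COMPLEMENT_SHARES <- c(Rp = 0.8, Rb = 0.2)
REVERSAL_RISE_PER_DAY <- 0.02

composition_mean_rr <- function(spec, days = STUDY_DAYS) {
  if (is.na(spec$reversal_day)) {
    return(piecewise_mean_curve(spec$start_value, spec$end_value,
                                spec$changepoints, days))
  }
  bottom_day <- spec$reversal_day - 1L
  decline_days <- days[1]:bottom_day
  mu <- numeric(length(days))
  mu[seq_along(decline_days)] <-
    piecewise_mean_curve(spec$start_value, spec$end_value,
                         spec$changepoints, decline_days)
  late <- days > bottom_day
  mu[late] <- spec$end_value + REVERSAL_RISE_PER_DAY * (days[late] - bottom_day)
  mu
}

#' Generate composition day series (Rr, Rp, Rb)
#'
#' Rr declines piecewise-linearly from about 0.95 with the planted
#' changepoints, bottoms out the day before `reversal_day`, then rises
#' (recanalization). Rp and Rb absorb the complement `1 - Rr` in fixed
#' 0.8/0.2 proportion. Noise is applied on the simplex: Gaussian
#' perturbation of all three components, clipping at 0, then
#' renormalization, so the triple sums to 1 exactly every day.
#'
#' @param spec a [synthetic_series_spec()] with `quantity = "Rr"`.
#' @return named list of three [daily_series()]: `Rr`, `Rp`, `Rb`.
#' @export
generate_composition_series <- function(spec) {
  if (!inherits(spec, "synthetic_series_spec") || spec$quantity != "Rr")
    stop_validation("spec must be a synthetic_series_spec for Rr")
  days <- STUDY_DAYS
  rr <- composition_mean_rr(spec, days)
  comp <- cbind(Rr = rr,
                Rp = COMPLEMENT_SHARES[["Rp"]] * (1 - rr),
                Rb = COMPLEMENT_SHARES[["Rb"]] * (1 - rr))
  sds <- series_noise_sd(spec, days)
  comp <- with_seed(spec$seed, {
    noisy <- comp + matrix(stats::rnorm(length(days) * 3, sd = rep(sds, 3)),
                           ncol = 3)
    noisy <- pmax(noisy, 0)
    noisy <- noisy / rowSums(noisy)
    noisy[, 3] <- pmax(0, 1 - (noisy[, 1] + noisy[, 2]))  # remainder rule: exact sum
    noisy
  })
  out <- lapply(c("Rr", "Rp", "Rb"), function(q)
    daily_series(spec$part, q, days, comp[, q]))
  names(out) <- c("Rr", "Rp", "Rb")
  out
}

#' Generate a full synthetic cohort on disk
#'
#' Emulates the study design with a longitudinal stand-in: `n_animals`
#' animals followed over days 1..14, each with head/body/tail elasticity
#' (three replicates per measurement) and, per animal-day-part, a section
#' image + ROI mask whose planted tissue fractions follow that part's
#' composition curve. Per-animal biological variability is a seeded
#' multiplicative offset on the series endpoints. All planted truths are
#' written to `manifest.json`.
#'
#' @param n_animals number of animals (>= 1).
#' @param out_dir output directory (created if needed); `NULL` keeps
#'   everything in memory only.
#' @param seed master seed; animal `i` derives seed `seed + i` and each
#'   generator a further fixed offset.
#' @param image_size section raster side in pixels (square; default 128
#'   keeps a full cohort fast).
#' @param changepoints planted elasticity/composition changepoint pair.
#' @param noise_sd0,noise_growth elasticity noise parameters.
#' @param comp_noise_sd0,comp_noise_growth composition noise parameters
#'   (fraction units).
#' @param animal_spread SD of the lognormal per-animal endpoint offset.
#' @param write_images if `FALSE`, skip PNG output (CSV + manifest only).
#' @return (invisibly) a list: `records` (measurement data.frame),
#'   `sections` (list of per-animal-day-part planted sections, only when
#'   `image_size > 0`), `manifest` (planted truths), `paths`.
#' @export
generate_cohort <- function(n_animals = 3L, out_dir = NULL, seed = 1L,
                            image_size = 128L, changepoints = c(4L, 7L),
                            noise_sd0 = 0.3, noise_growth = 0.35,
                            comp_noise_sd0 = 0.02, comp_noise_growth = 0.15,
                            animal_spread = 0.08, write_images = TRUE) {
  n_animals <- as.integer(n_animals)
  if (n_animals < 1L) stop_validation("n_animals must be >= 1")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  records <- list()
  sections <- list()
  manifest_animals <- list()
  for (i in seq_len(n_animals)) {
    animal_seed <- as.integer(seed) + i
    animal_id <- sprintf("rabbit%02d", i)
    offset <- with_seed(animal_seed, exp(stats::rnorm(1, sd = animal_spread)))
    animal_parts <- list()
    for (p in PARTS) {
      ep <- PART_YM_ENDPOINTS[[p]]
      espec <- synthetic_series_spec(
        part = p, quantity = "ym_kpa",
        start_value = ep[1] * offset, end_value = ep[2] * offset,
        changepoints = changepoints,
        noise_sd0 = noise_sd0, noise_growth = noise_growth,
        seed = animal_seed * 101L + match(p, PARTS))
      eseries <- generate_elasticity_series(espec)
      cspec <- synthetic_series_spec(
        part = p, quantity = "Rr", changepoints = changepoints,
        noise_sd0 = comp_noise_sd0, noise_growth = comp_noise_growth,
        seed = animal_seed * 211L + match(p, PARTS))
      cseries <- generate_composition_series(cspec)

      # triplicate replicates: small multiplicative measurement jitter,
      # Q-Box within-ROI SD stand-in at 10% of Emean
      reps <- with_seed(animal_seed * 307L + match(p, PARTS), {
        lapply(seq_along(eseries$days), function(k) {
          e <- pmin(YM_SCALE_KPA[2], pmax(
            YM_SCALE_KPA[1], eseries$values[k] * (1 + stats::rnorm(3, sd = 0.03))))
          data.frame(animal_id = animal_id, day = eseries$days[k], part = p,
                     replicate = 1:3, emean_kpa = round(e, 3),
                     sd_kpa = round(0.1 * e, 3))
        })
      })
      records[[length(records) + 1L]] <- do.call(rbind, reps)

      part_sections <- NULL
      if (write_images && image_size > 0) {
        part_sections <- lapply(seq_along(STUDY_DAYS), function(k) {
          comp <- c(cseries$Rr$values[k], cseries$Rp$values[k], cseries$Rb$values[k])
          ispec <- synthetic_image_spec(
            height = image_size, width = image_size,
            target_fractions = comp * 0.92,   # 8% of the ROI is lumen/white
            seed = animal_seed * 1009L + match(p, PARTS) * 29L + k)
          syn <- generate_section_image(ispec)
          if (!is.null(out_dir)) {
            stem <- sprintf("%s_day%02d_%s", animal_id, STUDY_DAYS[k], p)
            write_section_image(syn$image, file.path(out_dir, paste0(stem, ".png")))
            write_roi_mask(syn$mask, file.path(out_dir, paste0(stem, "_mask.png")))
          }
          syn
        })
        names(part_sections) <- sprintf("day%02d", STUDY_DAYS)
        sections[[paste(animal_id, p, sep = ".")]] <- part_sections
      }
      animal_parts[[p]] <- list(
        elasticity = list(
          start_value = espec$start_value, end_value = espec$end_value,
          changepoints = espec$changepoints, noise_sd0 = espec$noise_sd0,
          noise_growth = espec$noise_growth, seed = espec$seed,
          values = eseries$values),
        composition = list(
          reversal_day = cspec$reversal_day, changepoints = cspec$changepoints,
          seed = cspec$seed,
          Rr = cseries$Rr$values, Rp = cseries$Rp$values, Rb = cseries$Rb$values,
          planted_image_fractions = if (is.null(part_sections)) NULL else
            lapply(part_sections, function(s) as.numeric(s$fractions)))
      )
    }
    manifest_animals[[animal_id]] <- list(endpoint_offset = offset,
                                          seed = animal_seed,
                                          parts = animal_parts)
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL
  manifest <- list(
    generator = "qpia::generate_cohort",
    version = as.character(utils::packageVersion("qpia")),
    n_animals = n_animals, seed = as.integer(seed),
    image_size = as.integer(image_size),
    changepoints = as.integer(changepoints),
    reversal_days = as.list(PART_REVERSAL_DAY[PARTS]),
    note = paste("day-by-day composition defaults between the documented",
                 "day-2/5/11 anchors are interpolations"),
    animals = manifest_animals
  )
  paths <- NULL
  if (!is.null(out_dir)) {
    csv_path <- file.path(out_dir, "measurements.csv")
    utils::write.csv(records, csv_path, row.names = FALSE, quote = FALSE)
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- list(dir = out_dir, csv = csv_path, manifest = manifest_path)
  }
  invisible(list(records = records, sections = sections,
                 manifest = manifest, paths = paths))
}
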