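# synthetic_data: planted ground truth, determinism, noise structure

test_that("section generation is deterministic and hits its targets", {
  spec <- synthetic_image_spec(height = 64, width = 64,
                               target_fractions = c(0.6, 0.3, 0.1), seed = 3)
  a <- generate_section_image(spec)
  b <- generate_section_image(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(unclass(a$labels), unclass(b$labels))
  c2 <- generate_section_image(synthetic_image_spec(
    height = 64, width = 64, target_fractions = c(0.6, 0.3, 0.1), seed = 4))
  expect_false(identical(a$image$pixels, c2$image$pixels))

  # achieved in-ROI area fractions within 0.5% of target
  expect_true(all(abs(a$achieved_area_fractions[c("red", "pink", "blue")] -
                        c(0.6, 0.3, 0.1)) < 0.005))
  # planted label counts agree with the reported planted fractions
  counts <- class_counts(a$labels)
  n_tissue <- sum(counts[c("red", "pink", "blue")])
  expect_equal(as.numeric(a$fractions),
               as.numeric(counts[c("red", "pink", "blue")] / n_tissue))
})

test_that("a pure-red noise-free spec paints the reference color everywhere in ROI", {
  spec <- synthetic_image_spec(height = 32, width = 32,
                               target_fractions = c(1, 0, 0),
                               color_noise_sd = 0, seed = 1)
  syn <- generate_section_image(spec)
  expect_equal(as.numeric(syn$fractions), c(1, 0, 0))
  pal <- he_palette()
  inside <- which(as.vector(syn$mask))
  flat <- matrix(as.vector(syn$image$pixels), 32 * 32, 3)
  expect_true(all(flat[inside, 1] == pal$refs["red", 1] &
                    flat[inside, 2] == pal$refs["red", 2] &
                    flat[inside, 3] == pal$refs["red", 3]))
})

test_that("invalid image specs are rejected", {
  expect_error(synthetic_image_spec(target_fractions = c(0.8, 0.3, 0.1)),
               "sum", class = "qpia_validation_error")
  expect_error(synthetic_image_spec(target_fractions = c(0, 0, 0)),
               class = "qpia_validation_error")
  expect_error(synthetic_image_spec(color_noise_sd = -1),
               class = "qpia_validation_error")
})

test_that("generated artifacts are readable by the io module unchanged", {
  dir <- withr::local_tempdir()
  spec <- synthetic_image_spec(height = 48, width = 40, seed = 12)
  syn <- generate_section_image(spec)
  ip <- file.path(dir, "s.png"); mp <- file.path(dir, "m.png")
  write_section_image(syn$image, ip)
  write_roi_mask(syn$mask, mp)
  img <- read_section_image(ip)
  msk <- read_roi_mask(mp, c(48, 40))
  expect_identical(img$pixels, syn$image$pixels)
  expect_identical(as.vector(msk), as.vector(syn$mask))
})

test_that("elasticity series hit the printed endpoints and round-trip changepoints", {
  spec <- synthetic_series_spec(part = "head", noise_sd0 = 0)
  s <- generate_elasticity_series(spec)
  expect_equal(s$values[1], 2.01)
  expect_equal(s$values[14], 13.29)
  tr <- detect_transitions(s)
  expect_identical(tr$changepoint_days, c(4L, 7L))

  # slope ordering low / high / medium around the planted changepoints
  expect_true(tr$segment_slopes[2] > tr$segment_slopes[3])
  expect_true(tr$segment_slopes[3] > tr$segment_slopes[1])

  # every part's noiseless series starts and ends on its printed endpoints
  eps <- list(head = c(2.01, 13.29), body = c(3.27, 15.91),
              tail = c(1.79, 10.51), whole = c(2.36, 13.24))
  for (p in names(eps)) {
    sp <- generate_elasticity_series(synthetic_series_spec(part = p, noise_sd0 = 0))
    expect_equal(sp$values[c(1, 14)], eps[[p]], info = p)
  }
  expect_error(synthetic_series_spec(part = "head", start_value = 10, end_value = 2),
               "stiffening", class = "qpia_validation_error")
})

test_that("day-growing noise inflates late-day spread (planted heteroscedasticity)", {
  vals <- sapply(1:100, function(i)
    generate_elasticity_series(synthetic_series_spec(
      part = "whole", noise_sd0 = 0.3, noise_growth = 0.35, seed = i))$values)
  expect_gt(oracle_sd(vals[14, ]), oracle_sd(vals[2, ]))
  # determinism of the series generator
  s1 <- generate_elasticity_series(synthetic_series_spec(part = "body", seed = 9))
  s2 <- generate_elasticity_series(synthetic_series_spec(part = "body", seed = 9))
  expect_identical(s1$values, s2$values)
})

test_that("composition series live on the simplex and plant the reversal", {
  for (seed in 1:10) {
    cs <- generate_composition_series(synthetic_series_spec(
      part = "body", quantity = "Rr", seed = seed))
    expect_true(all(cs$Rr$values + cs$Rp$values + cs$Rb$values == 1))
    expect_true(all(cs$Rr$values >= 0 & cs$Rp$values >= 0 & cs$Rb$values >= 0))
  }
  cs0 <- generate_composition_series(synthetic_series_spec(
    part = "tail", quantity = "Rr", noise_sd0 = 0, reversal_day = 10))
  expect_identical(detect_reversal(cs0$Rr)$reversal_day, 10L)
  # day-2 Rr near the documented day-2 mean of 0.9513
  expect_lt(abs(cs0$Rr$values[2] - 0.9513), 0.05)

  expect_error(synthetic_series_spec(part = "head", quantity = "Rr",
                                     changepoints = c(4, 7), reversal_day = 7),
               "reversal_day", class = "qpia_validation_error")
})

test_that("reversal detection is modal at the planted day across seeds", {
  for (part in c("head", "tail", "body")) {
    planted <- c(head = 9L, tail = 10L, body = 11L)[[part]]
    got <- vapply(1:20, function(seed) {
      cs <- generate_composition_series(synthetic_series_spec(
        part = part, quantity = "Rr", noise_sd0 = 0.004, noise_growth = 0,
        seed = seed))
      detect_reversal(cs$Rr)$reversal_day
    }, integer(1))
    mode_day <- as.integer(names(which.max(table(got))))
    expect_identical(mode_day, planted, info = part)
  }
})

test_that("cohort generation emits consumable, fully-manifested artifacts", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(n_animals = 3, out_dir = dir, seed = 11,
                        image_size = 32)
  # 3 animals x 14 days x 3 parts x 3 replicates
  expect_identical(nrow(co$records), 3L * 14L * 3L * 3L)
  rec <- read_elasticity_csv(file.path(dir, "measurements.csv"))
  expect_identical(nrow(rec), nrow(co$records))

  # manifest records planted truths on the simplex
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  expect_identical(man$n_animals, 3L)
  for (a in names(man$animals)) {
    for (p in names(man$animals[[a]]$parts)) {
      comp <- man$animals[[a]]$parts[[p]]$composition
      expect_equal(comp$Rr + comp$Rp + comp$Rb, rep(1, 14), tolerance = 1e-12)
    }
  }

  # determinism: same seed gives an identical manifest
  dir2 <- withr::local_tempdir()
  co2 <- generate_cohort(n_animals = 3, out_dir = dir2, seed = 11,
                         image_size = 32)
  expect_identical(co$manifest, co2$manifest)

  # emitted images are pipeline-consumable
  f <- file.path(dir, "rabbit01_day03_body.png")
  img <- read_section_image(f)
  msk <- read_roi_mask(file.path(dir, "rabbit01_day03_body_mask.png"), dim(img)[1:2])
  expect_s3_class(img, "section_image")
  expect_true(any(msk))
})
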