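# qpia_core: pixel classification, red weighting, fraction computation,
# aggregation rules

test_that("red_weight matches its closed form and is monotone", {
  wp <- weighting_params(f0 = 1 / 3, gamma = 2)
  expect_equal(red_weight(1 / 3, wp), 0)
  expect_equal(red_weight(1, wp), 1)
  expect_equal(red_weight(2 / 3, wp), 0.25)
  expect_equal(red_weight(1, weighting_params(gamma = 0.7)), 1)
  # below the floor the weight stays 0
  expect_equal(red_weight(c(0, 0.1, 0.3), wp), c(0, 0, 0))
  # monotone non-decreasing over a grid, several gammas
  f <- seq(0, 1, by = 0.01)
  for (g in c(0.5, 1, 2, 4)) {
    w <- red_weight(f, weighting_params(gamma = g))
    expect_true(all(diff(w) >= 0), info = paste("gamma", g))
    expect_true(all(w >= 0 & w <= 1))
  }
  # gamma = 0 degenerates to unit weights (pixel counting)
  expect_true(all(red_weight(f, weighting_params(gamma = 0)) == 1))
})

test_that("classification labels uniform fields and gates background", {
  pal <- he_palette()
  mk <- function(rgb) {
    img <- section_image(array(rep(as.integer(rgb), each = 16), dim = c(4, 4, 3)))
    thrombus_section("t", 1, "head", img, roi_mask(matrix(TRUE, 4, 4)))
  }
  lab_red <- classify_pixels(mk(pal$refs["red", ]), pal)
  expect_true(all(unclass(lab_red) == 1L))
  lab_white <- classify_pixels(mk(c(255, 255, 255)), pal)
  expect_true(all(unclass(lab_white) == 4L))
  # equidistant between red and pink resolves to red (fixed class order)
  mid <- (pal$refs["red", ] + pal$refs["pink", ]) / 2
  expect_true(all(unclass(classify_pixels(mk(mid), pal)) == 1L))
})

test_that("out-of-ROI pixels are labeled outside_roi exactly where mask is false", {
  for (seed in 1:5) {
    set.seed(seed)
    h <- sample(8:20, 1); w <- sample(8:20, 1)
    px <- array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
    mask <- matrix(runif(h * w) > 0.4, h, w)
    if (!any(mask)) mask[1, 1] <- TRUE
    sec <- thrombus_section("t", 1, "body", section_image(px), roi_mask(mask))
    lab <- classify_pixels(sec)
    expect_identical(unclass(lab) == 5L, !unclass(mask) & TRUE,
                     ignore_attr = TRUE)
  }
})

test_that("fraction masses reproduce the printed day-11 head composition", {
  # 10000 tissue pixels with planted class counts 4739/4217/1044 and unit
  # red weights must yield exactly (47.39, 42.17, 10.44) percent
  codes <- matrix(c(rep(1L, 4739), rep(2L, 4217), rep(3L, 1044)), 100, 100)
  colors <- rbind(c(200, 40, 40), c(230, 170, 180), c(60, 60, 150),
                  c(255, 255, 255), c(255, 255, 255))
  fx <- section_from_codes(codes, colors)
  fr <- compute_fractions(fx$labels, fx$image, weighting_params(gamma = 0))
  expect_equal(fr[["Rr"]], 0.4739)
  expect_equal(fr[["Rp"]], 0.4217)
  expect_equal(fr[["Rb"]], 0.1044)
})

test_that("a pure-red section with f_red = 1 gives (1, 0, 0) under any gamma", {
  codes <- matrix(1L, 8, 8)
  colors <- rbind(c(255, 0, 0), c(0, 0, 0), c(0, 0, 0),
                  c(255, 255, 255), c(255, 255, 255))
  fx <- section_from_codes(codes, colors)
  for (g in c(0.5, 1, 2)) {
    fr <- compute_fractions(fx$labels, fx$image, weighting_params(gamma = g))
    expect_equal(as.numeric(fr), c(1, 0, 0))
  }
})

test_that("conservation, mask restriction and scale invariance hold", {
  for (seed in 1:6) {
    spec <- synthetic_image_spec(height = 40, width = 40,
                                 target_fractions = c(0.5, 0.25, 0.15),
                                 seed = seed)
    syn <- generate_section_image(spec)
    sec <- thrombus_section("t", 1, "head", syn$image, syn$mask)
    fr <- quantify_section(sec)
    # conservation: exact sum, every in-ROI pixel in exactly one class
    expect_identical(sum(fr), 1)
    counts <- class_counts(classify_pixels(sec))
    expect_identical(sum(counts), 1600L)
    expect_identical(counts[["outside_roi"]], sum(!syn$mask))

    # mask restriction: scrambling pixels outside the ROI changes nothing
    px2 <- syn$image$pixels
    outside <- which(!as.vector(syn$mask))
    for (ch in 1:3) {
      plane <- px2[, , ch]
      plane[outside] <- rev(plane[outside] %% 251L)
      px2[, , ch] <- plane
    }
    sec2 <- thrombus_section("t", 1, "head", section_image(px2), syn$mask)
    expect_identical(as.numeric(quantify_section(sec2)), as.numeric(fr))

    # scale invariance: 2x2 pixel replication leaves fractions unchanged
    rep_rows <- rep(seq_len(40), each = 2)
    big_px <- syn$image$pixels[rep_rows, rep_rows, , drop = FALSE]
    big_mask <- unclass(syn$mask)[rep_rows, rep_rows]
    sec3 <- thrombus_section("t", 1, "head", section_image(big_px),
                             roi_mask(big_mask))
    expect_equal(as.numeric(quantify_section(sec3)), as.numeric(fr))
  }
})

test_that("increasing gamma never increases Rr for fixed labels", {
  spec <- synthetic_image_spec(height = 48, width = 48,
                               target_fractions = c(0.5, 0.3, 0.1), seed = 11)
  syn <- generate_section_image(spec)
  labels <- classify_pixels(
    thrombus_section("t", 1, "head", syn$image, syn$mask))
  gammas <- c(0, 0.5, 1, 2, 4, 8)
  rr <- vapply(gammas, function(g)
    compute_fractions(labels, syn$image, weighting_params(gamma = g))[["Rr"]],
    numeric(1))
  expect_true(all(diff(rr) <= 1e-12))
})

test_that("degenerate sections are rejected", {
  codes <- matrix(4L, 4, 4)   # all background in ROI
  colors <- matrix(255, 5, 3)
  fx <- section_from_codes(matrix(c(4L, rep(4L, 15)), 4, 4), colors)
  # force mask TRUE despite background-only tissue
  lab <- qpia:::new_pixel_class_map(codes)
  expect_error(compute_fractions(lab, fx$image), "degenerate",
               class = "qpia_validation_error")
})

test_that("triplicate_mean follows the protocol and matches a brute-force mean", {
  expect_equal(triplicate_mean(c(3.0, 3.2, 3.1)), 3.1)
  expect_equal(triplicate_mean(c(7.7, 7.7, 7.7)), 7.7)
  set.seed(42)
  for (i in 1:20) {
    v <- runif(3, 0, 20)
    expect_equal(triplicate_mean(v), oracle_mean(v))
  }
  expect_error(triplicate_mean(c(1, 2)), "3 replicates",
               class = "qpia_validation_error")
  expect_message(got <- triplicate_mean(c(1, 2), strict = FALSE), "2 replicate")
  expect_equal(got, 1.5)
})

test_that("whole-thrombus elasticity is the 2-decimal mean of the parts", {
  expect_equal(aggregate_whole_elasticity(2.01, 3.27, 1.79), 2.36)
  expect_equal(aggregate_whole_elasticity(13.29, 15.91, 10.51), 13.24)
  expect_equal(aggregate_whole_elasticity(5, 5, 5), 5)
  expect_error(aggregate_whole_elasticity(2, NULL, 3), "body",
               class = "qpia_validation_error")
  expect_error(aggregate_whole_elasticity(2, NA, 3), "body",
               class = "qpia_validation_error")
})

test_that("whole-thrombus composition averages componentwise on the simplex", {
  t1 <- composition_fractions(0.5, 0.3)
  expect_equal(as.numeric(aggregate_whole_composition(t1, t1, t1)),
               as.numeric(t1))
  # mean of the documented day-2 rows
  h <- composition_fractions(0.9702, 0.0247)
  b <- composition_fractions(0.9575, 0.0354)
  tl <- composition_fractions(0.9263, 0.0627)
  whole <- aggregate_whole_composition(h, b, tl)
  expect_equal(round(100 * whole[["Rr"]], 2), 95.13)
  expect_equal(whole[["Rr"]], oracle_mean(c(0.9702, 0.9575, 0.9263)))
  expect_identical(sum(whole), 1)
  # symmetry of the simplex corners
  corners <- aggregate_whole_composition(composition_fractions(1, 0),
                                         composition_fractions(0, 1),
                                         composition_fractions(0, 0))
  expect_equal(as.numeric(corners), rep(1 / 3, 3))
  # sum-to-one violation is an invariant error
  bad <- c(Rr = 0.5, Rp = 0.4, Rb = 0.2)
  expect_error(aggregate_whole_composition(t1, t1, bad), "sums",
               class = "qpia_invariant_error")
})
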