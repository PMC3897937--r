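test_that("orientation screen requires villi, crypts and longitudinal axes", {
  g <- generate_mucosa_image(small_spec())
  expect_true(assess_orientation(g$annotation))
  gt <- generate_mucosa_image(small_spec(orientation_adequate = FALSE))
  expect_false(assess_orientation(gt$annotation))
  # villi but no crypts: not a longitudinal section
  no_crypts <- g$annotation
  no_crypts$crypt_polylines <- list()
  expect_false(assess_orientation(no_crypts))
  expect_error(assess_orientation(NULL), "unassessable")
})

test_that("automatic threshold separates a noise-free bimodal image exactly", {
  g <- generate_mucosa_image(small_spec())
  th <- auto_threshold(g$image)
  expect_identical(th$mask, g$image$pixels == 60)
  expect_gt(th$threshold, 60)
  expect_lt(th$threshold, 200)
  expect_error(auto_threshold(calibrated_image(matrix(100, 5, 5), 1)),
               "no threshold separable")
})

test_that("threshold misclassification stays below 1% at noise sd 10", {
  clean <- auto_threshold(generate_mucosa_image(small_spec(seed = 7))$image)$mask
  noisy <- auto_threshold(generate_mucosa_image(small_spec(noise_sd = 10, seed = 7))$image)$mask
  expect_lt(mean(clean != noisy), 0.01)
})

test_that("polarity flag recovers the same mask from an inverted image", {
  g <- generate_mucosa_image(small_spec())
  inv <- calibrated_image(255 - g$image$pixels, g$image$um_per_pixel)
  m1 <- auto_threshold(g$image)$mask
  m2 <- auto_threshold(inv, polarity = "light")$mask
  expect_identical(m1, m2)
})

test_that("threshold agrees with an independent Otsu implementation", {
  skip_if_not_installed("EBImage")
  g <- generate_mucosa_image(small_spec(noise_sd = 15, seed = 3))
  ours <- auto_threshold(g$image)$threshold
  ref <- EBImage::otsu(EBImage::Image(t(g$image$pixels) / 255), range = c(0, 1)) * 255
  expect_lt(abs(ours - ref), 2)   # within one grey bin of each other
})

test_that("contour extraction finds one contour per rendered villus", {
  for (k in c(1, 3)) {
    g <- generate_mucosa_image(mucosa_spec(n_villi = k, muscularis_length_um = 200 * k,
                                           seed = k))
    th <- auto_threshold(g$image)
    contours <- extract_villous_contours(g$image, th$mask, th$threshold)
    expect_length(contours, k)
    # ordered left to right
    if (k > 1) {
      xs <- vapply(contours, function(ct) mean(ct$base_segment[, 1]), numeric(1))
      expect_true(all(diff(xs) > 0))
    }
  }
  # flat mucosa: no protrusions above the plateau
  flat <- generate_mucosa_image(mucosa_spec(n_villi = 1, villus_height_um = 10,
                                            villus_width_um = 20,
                                            crypt_depth_um = 60,
                                            muscularis_length_um = 200))
  th <- auto_threshold(flat$image)
  expect_length(extract_villous_contours(flat$image, th$mask, th$threshold), 0)
})

test_that("closely spaced villi remain separated by the plateau-level cut", {
  g <- generate_mucosa_image(mucosa_spec(n_villi = 2, villus_width_um = 110,
                                         muscularis_length_um = 270,
                                         noise_sd = 8, seed = 5))
  th <- auto_threshold(g$image)
  expect_length(extract_villous_contours(g$image, th$mask, th$threshold), 2)
})

test_that("measure_villus matches closed forms for hand-built polygons", {
  # rectangle 300 x 60, base = bottom edge
  rect <- list(polygon = rbind(c(0, 0), c(0, 300), c(60, 300), c(60, 0)),
               base_segment = rbind(c(0, 0), c(60, 0)))
  m <- measure_villus(rect)
  expect_equal(unname(m["area_um2"]), 18000)
  expect_equal(unname(m["perimeter_um"]), 660)
  # unit square, base = one side
  sq <- list(polygon = rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0)),
             base_segment = rbind(c(0, 0), c(1, 0)))
  expect_equal(unname(measure_villus(sq)), c(1, 3))
  # scale factor applies to lengths and areas correctly
  m2 <- measure_villus(rect, um_per_pixel = 2)
  expect_equal(unname(m2["area_um2"]), 18000 * 4)
  expect_equal(unname(m2["perimeter_um"]), 660 * 2)
  expect_error(measure_villus(list(polygon = rbind(c(0, 0), c(1, 1)),
                                   base_segment = rbind(c(0, 0), c(1, 1)))))
})

test_that("rasterised contours recover continuous truth within 2% at 1 um/pixel", {
  for (spec in list(rect_spec(), small_spec(), mucosa_spec())) {
    g <- generate_mucosa_image(spec)
    th <- auto_threshold(g$image)
    contours <- extract_villous_contours(g$image, th$mask, th$threshold)
    meas <- vapply(contours, measure_villus, numeric(2))
    tr <- villimorph:::villus_truth(spec$profile, spec$villus_height_um,
                                    spec$villus_width_um)
    expect_equal(sum(meas["area_um2", ]), spec$n_villi * tr$area,
                 tolerance = 0.02)
    expect_equal(sum(meas["perimeter_um", ]), spec$n_villi * tr$perimeter,
                 tolerance = 0.02)
  }
})

test_that("per-muscularis normalisation is plain arithmetic with guards", {
  expect_equal(normalize_per_muscularis(18000, 200), 9000)
  expect_equal(normalize_per_muscularis(0, 123), 0)
  expect_error(normalize_per_muscularis(10, 0), "positive")
  expect_error(normalize_per_muscularis(10, -5), "positive")
})

test_that("normalisation is invariant to tiling the section", {
  one <- generate_mucosa_image(mucosa_spec(n_villi = 2, muscularis_length_um = 400, seed = 1))
  two <- generate_mucosa_image(mucosa_spec(n_villi = 4, muscularis_length_um = 800, seed = 1))
  r1 <- summarize_biopsy(one$image, one$annotation)
  r2 <- summarize_biopsy(two$image, two$annotation)
  expect_equal(r1$VP_per100, r2$VP_per100, tolerance = 0.01)
  expect_equal(r1$VA_per100, r2$VA_per100, tolerance = 0.01)
})

test_that("landmark measurements apply arc length, max-VH and mean-CD rules", {
  # 3-4-5 triangle polyline measures 5 at unit scale
  lm <- list(vh_polylines = list(rbind(c(0, 0), c(3, 4))),
             cd_polylines = list(rbind(c(0, 0), c(0, 2)), rbind(c(0, 0), c(0, 4))),
             vw_segment = rbind(c(0, 0), c(2, 0)),
             muscularis_polyline = rbind(c(0, 0), c(10, 0)))
  m <- measure_landmarks(lm)
  expect_equal(m$VH, 5)
  expect_equal(m$CD, 3)           # mean of 2 and 4
  expect_equal(m$VW, 2)
  expect_equal(m$muscularis_um, 10)
  # VH is the maximum across villi; scale multiplies through
  lm$vh_polylines <- list(rbind(c(0, 0), c(0, 200)), rbind(c(0, 0), c(0, 250)))
  expect_equal(measure_landmarks(lm)$VH, 250)
  expect_equal(measure_landmarks(lm, um_per_pixel = 2)$VH, 500)
  lm$vw_segment <- NULL
  expect_error(measure_landmarks(lm), "vw_segment")
})

test_that("summarize_biopsy recovers generator truth within tolerance", {
  spec <- mucosa_spec(villus_height_um = 300, crypt_depth_um = 160,
                      villus_width_um = 110, n_villi = 3,
                      muscularis_length_um = 600, noise_sd = 5, seed = 2)
  g <- generate_mucosa_image(spec)
  rec <- summarize_biopsy(g$image, g$annotation)
  tr <- g$annotation$true_record
  expect_equal(rec$VH, tr$VH, tolerance = 0.02)
  expect_equal(rec$CD, tr$CD, tolerance = 0.02)
  expect_equal(rec$VA_per100, tr$VA_per100, tolerance = 0.03)
  expect_equal(rec$VP_per100, tr$VP_per100, tolerance = 0.03)
  expect_equal(rec$n_villi, 3L)
  # re-measuring the same image gives the identical record
  expect_identical(rec, summarize_biopsy(g$image, g$annotation))
  # inadequate sections come back flagged, without measurements
  gi <- generate_mucosa_image(small_spec(orientation_adequate = FALSE))
  ri <- summarize_biopsy(gi$image, gi$annotation)
  expect_false(ri$adequate)
  expect_true(is.na(ri$VA_per100))
})

test_that("measured morphometry increases strictly with true villous height", {
  recs <- lapply(c(200, 260, 320), function(h) {
    g <- generate_mucosa_image(small_spec(villus_height_um = h, seed = 4))
    summarize_biopsy(g$image, g$annotation)
  })
  vh <- vapply(recs, `[[`, numeric(1), "VH")
  vp <- vapply(recs, `[[`, numeric(1), "VP_per100")
  va <- vapply(recs, `[[`, numeric(1), "VA_per100")
  expect_true(all(diff(vh) > 0))
  expect_true(all(diff(vp) > 0))
  expect_true(all(diff(va) > 0))
})

test_that("polygon area agrees with a Monte-Carlo point-in-polygon estimate", {
  set.seed(11)
  poly <- villimorph:::villus_outline("capped", 0, 0, 200, 80)
  a_true <- polygon_area(poly)
  # rejection sampling over the bounding box
  n <- 40000
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  px <- runif(n, xr[1], xr[2]); py <- runif(n, yr[1], yr[2])
  # even-odd ray casting
  inside <- vapply(seq_len(n), function(i) {
    x <- px[i]; y <- py[i]
    j <- c(2:nrow(poly), 1)
    cross <- (poly[, 2] > y) != (poly[j, 2] > y)
    xi <- poly[, 1] + (y - poly[, 2]) / (poly[j, 2] - poly[, 2]) * (poly[j, 1] - poly[, 1])
    sum(cross & x < xi) %% 2 == 1
  }, logical(1))
  box <- diff(xr) * diff(yr)
  a_mc <- mean(inside) * box
  se <- box * sqrt(mean(inside) * (1 - mean(inside)) / n)
  expect_lt(abs(a_mc - a_true), 3 * se)
})
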