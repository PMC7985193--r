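# phantom: synthetic generators and their ground truth.

test_that("noiseless B-mode phantom renders cavity darker than wall band", {
  ph <- short_bmode_phantom()
  f <- ph$cine$frames[[ph$ed_frame]]
  spec <- ph$spec
  mask <- lvecho:::bmode_mask(spec, spec$lv_diameter_ed_mm)
  # erode margins by comparing deep-interior vs wall-band means
  inside <- mean(f[mask == 1])
  wall <- lvecho:::bmode_render(spec, spec$lv_diameter_ed_mm) == lvecho:::WALL_I
  expect_lt(inside, mean(f[wall]))
})

test_that("phantom generation is a pure function of (spec, seed)", {
  spec <- bmode_phantom_spec(n_frames = 4, speckle_scale = 0.4, rng_seed = 9)
  a <- make_bmode_phantom(spec)
  b <- make_bmode_phantom(spec)
  expect_identical(a$cine$frames, b$cine$frames)
  # generation does not disturb the caller's RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(make_bmode_phantom(spec)); x2 <- runif(1)
  expect_identical(x1, x2)
  m1 <- make_mmode_phantom(mmode_phantom_spec(rng_seed = 2, speckle_scale = 0.3))
  m2 <- make_mmode_phantom(mmode_phantom_spec(rng_seed = 2, speckle_scale = 0.3))
  expect_identical(m1$image$grid, m2$image$grid)
})

test_that("returned ED contour matches the analytic half-ellipse boundary", {
  ph <- short_bmode_phantom()
  spec <- ph$spec
  # the loop starts at end-diastole, so the selected ED frame diameter is D_ed
  a_poly <- contour_area(ph$contour_ed)
  a_true <- pi * spec$lv_length_mm * spec$lv_diameter_ed_mm / 4  # half-ellipse
  expect_lt(abs(a_poly - a_true) / a_true, 0.01)
  # contour agrees with the rasterized mask it was rendered from
  mask <- lvecho:::bmode_mask(spec, spec$lv_diameter_ed_mm)
  expect_lt(abs(sum(mask) * spec$pixel_spacing_mm^2 - a_true) / a_true, 0.02)
})

test_that("library generation yields paired phase entries with clean masks", {
  lib <- small_library()
  expect_s3_class(lib, "reference_library")
  expect_length(lib$entries, 12)
  expect_equal(sum(vapply(lib$entries, function(e) e$phase == "ED", logical(1))), 6)
  for (e in lib$entries) {
    expect_gt(sum(e$mask), 0)
    lab <- EBImage::bwlabel(e$mask)
    expect_equal(max(lab), 1)  # single 4-connected component
  }
  expect_error(make_library(1), "n >= 2")
  expect_error(make_library(3, list(lv_length_mm = c(9, 6))), "degenerate range")
  # zero-width ranges give identical geometry
  rg <- lapply(default_library_ranges(), function(r) rep(mean(r), 2))
  lib2 <- make_library(2, rg, rng_seed = 4)
  expect_identical(lib2$entries[[1]]$mask, lib2$entries[[3]]$mask)
})

test_that("M-mode phantom ground truth attains the specified extremes", {
  mp <- default_mmode_phantom()
  tr <- mp$truth$traces
  lvid <- tr$POST_ENDO$depth_mm - tr$ANT_ENDO$depth_mm
  expect_equal(max(lvid), mp$spec$lvid_d_mm)
  expect_equal(min(lvid), mp$spec$lvid_s_mm, tolerance = 1e-6)
  # cycles in the window: floor(450/60 * 5) full cycles
  ex <- lvecho:::local_extrema(lvid)
  expect_lte(abs(length(ex$max) - 37), 1)
  expect_error(mmode_phantom_spec(lvid_d_mm = 3, lvid_s_mm = 3.5),
               "smaller than diastolic")
  expect_error(mmode_phantom_spec(duration_ms = 200), "two beats")
})
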