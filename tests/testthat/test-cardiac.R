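# cardiac_params: disks, volumes, areas, endpoint formulas.

half_ellipse_contour <- function(L = 8, D = 4, n_arc = 241L) {
  th <- seq(-pi / 2, pi / 2, length.out = n_arc)
  lv_contour(cbind(1 + L * cos(th), 5 + (D / 2) * sin(th)),
             basal_indices = c(1L, n_arc), phase = "ED")
}

test_that("disk diameters match the analytic elliptical chords", {
  ct <- half_ellipse_contour()
  st <- contour_axis_and_disks(ct, 20)
  expect_equal(st$L, 8, tolerance = 1e-6)
  centres <- (1:20 - 0.5) * st$L / 20
  expect_equal(st$diameters, half_ellipse_chord(centres, 8, 4), tolerance = 0.01)
  # n_disks = 1: the single mid-axis chord
  st1 <- contour_axis_and_disks(ct, 1)
  expect_equal(st1$diameters, half_ellipse_chord(4, 8, 4), tolerance = 0.01)
  expect_equal(contour_dimension(ct, st), 4, tolerance = 0.01)
})

test_that("20-disk volume reproduces the analytic half-ellipsoid volume", {
  ct <- half_ellipse_contour()
  v_true <- pi * 8 * 4^2 / 6  # 67.02 uL
  st <- contour_axis_and_disks(ct, 20)
  expect_lt(abs(disk_volume(st) - v_true) / v_true, 0.005)
  # convergence monotone in disk count
  errs <- vapply(c(5, 10, 20, 40, 80), function(n)
    abs(disk_volume(contour_axis_and_disks(ct, n)) - v_true), numeric(1))
  expect_true(all(diff(errs) < 0))
  # scaling laws
  expect_equal(disk_volume(disk_stack(8, rep(0, 20))), 0)
  d <- runif(20, 1, 3)
  expect_equal(disk_volume(disk_stack(8, 2 * d)), 4 * disk_volume(disk_stack(8, d)))
})

test_that("contour area follows the shoelace formula", {
  sq <- lv_contour(cbind(c(0, 0.5, 1, 1, 1, 0.5, 0, 0),
                         c(0, 0, 0, 0.5, 1, 1, 1, 0.5)), c(1, 3))
  expect_equal(contour_area(sq), 1)
  ct <- half_ellipse_contour()
  expect_lt(abs(contour_area(ct) - pi * 8 * 4 / 4) / (pi * 8), 0.01)
})

test_that("B-mode measures compose correctly from the two phases", {
  ed <- half_ellipse_contour(8, 4)
  # no contraction: all indices zero
  m0 <- bmode_measures(ed, lv_contour(ed$vertices, ed$basal_indices, "ES"))
  expect_equal(m0$values$EF_pct, 0)
  expect_equal(m0$values$FS_pct, 0)
  expect_equal(m0$values$FAC_pct, 0)
  expect_equal(m0$values$SV_uL, 0)
  # contracted ES: EF equals the independently composed disk-sum value
  es <- half_ellipse_contour(7.4, 2.9)
  es <- lv_contour(es$vertices, es$basal_indices, "ES")
  m <- bmode_measures(ed, es, heart_rate = 450)
  edv <- disk_volume(contour_axis_and_disks(ed, 20))
  esv <- disk_volume(contour_axis_and_disks(es, 20))
  expect_equal(m$values$EF_pct, 100 * (edv - esv) / edv, tolerance = 1e-6)
  # against the closed-form chord oracle, independent of the contour code
  vol_o <- function(L, D) sum(pi / 4 * half_ellipse_chord((1:20 - 0.5) * L / 20,
                                                          L, D)^2) * L / 20
  ef_o <- 100 * (1 - vol_o(7.4, 2.9) / vol_o(8, 4))
  expect_equal(m$values$EF_pct, ef_o, tolerance = 0.005)
  expect_equal(m$values$SV_uL + m$values$ESV_uL, m$values$EDV_uL)
  expect_equal(m$values$CO_mL_min, m$values$SV_uL * 450 / 1000)
  expect_true(m$values$EF_pct > 0 && m$values$EF_pct < 100)
})

test_that("Teichholz conversion matches hand arithmetic and is monotone", {
  expect_equal(teichholz_volume(4.0), 7 / 6.4 * 64)           # 70.0 uL
  expect_equal(teichholz_volume(2.8), 7 / 5.2 * 2.8^3)        # 29.55 uL
  expect_equal(round(teichholz_volume(4.0), 1), 70.0)
  d <- seq(0.5, 8, by = 0.05)
  expect_true(all(diff(teichholz_volume(d)) > 0))
})

test_that("M-mode endpoint formulas match hand arithmetic", {
  dims <- mmode_dimensions(4.0, 2.8, 0.8, 1.0, 0.8, 1.0)
  m <- mmode_measures(dims, heart_rate = 450)
  expect_equal(m$values$FS_pct, 30.0)
  expect_equal(m$values$LV_mass_mg, 1.053 * (5.6^3 - 4^3))    # 117.53 mg
  expect_equal(round(m$values$LV_mass_mg, 2), 117.53)
  expect_lt(abs(m$values$LV_mass_corr_mg - 94.02), 0.01)  # 0.8 x 117.5317
  expect_equal(m$values$LV_mass_corr_mg / m$values$LV_mass_mg, 0.8)
  expect_equal(m$values$EDV_uL, teichholz_volume(4.0))
  # warning, not failure, for a non-contracting ventricle
  expect_warning(mmode_dimensions(2.8, 4.0, 0.8, 1, 0.8, 1), "systolic")
})

test_that("mask-derived contours reproduce phantom areas", {
  lib <- small_library()
  e <- lib$entries[[1]]
  ct <- mask_to_contour(e$mask, lib$pixel_spacing, phase = "ED")
  expect_s3_class(ct, "lv_contour")
  a_mask <- sum(e$mask) * lib$pixel_spacing^2
  expect_lt(abs(contour_area(ct) - a_mask) / a_mask, 0.05)
  st <- contour_axis_and_disks(ct, 20)
  expect_lt(abs(st$L - e$spec$lv_length_mm) / e$spec$lv_length_mm, 0.05)
})
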