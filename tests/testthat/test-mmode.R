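# mmode_walls: regions, cost images, DP tracing, spectral filter, phases.

test_that("search regions normalize seed order and respect image bounds", {
  mp <- default_mmode_phantom()
  s1 <- seed_point_pair("ANT_ENDO", c(0, 2.0), c(0, 3.0))
  r1 <- make_region(s1, mp$image, margin_px = 0)
  sp <- mp$image$meta$pixel_spacing_axial
  expect_equal((r1$row_range - 1) * sp, c(2.0, 3.0))
  expect_identical(r1$polarity, "bright-to-dark")
  # reversed depth order is rejected at construction
  expect_error(seed_point_pair("ANT_ENDO", c(0, 3.0), c(0, 2.0)), "shallower")
  expect_error(make_region(seed_point_pair("ANT_ENDO", c(0, 1), c(0, 99)),
                           mp$image), "outside image")
  expect_error(make_region(seed_point_pair("ANT_ENDO", c(0, 2.0), c(0, 2.02)),
                           mp$image, margin_px = 0), "3 rows")
})

test_that("cost image is minimal on a matching-polarity step edge", {
  band <- matrix(0.2, 30, 40)
  band[16:30, ] <- 0.9  # dark above, bright below: dark-to-bright going down
  ci <- cost_image(band, "dark-to-bright")
  expect_true(all(ci$grid >= 0 & ci$grid <= 1))
  argmins <- apply(ci$grid, 2, which.min)
  expect_true(all(abs(argmins - 15.5) <= 1))
  # inverted polarity rectifies the edge away: its cost stays high
  ci2 <- cost_image(band, "bright-to-dark")
  expect_true(all(ci2$grid[14:17, ] > 0.9))
  expect_warning(ci3 <- cost_image(matrix(0.5, 10, 5), "dark-to-bright"),
                 "uniform")
  expect_true(all(ci3$grid == 1))
})

test_that("dynamic programming matches exhaustive enumeration", {
  # trivial: an all-zero row is followed exactly
  g <- matrix(1, 8, 10); g[5, ] <- 0
  p <- optimal_path(g, max_step = 2)
  expect_true(all(p == 5))
  # a zero-cost zigzag seam needing |dr| = 3 cannot be followed at step 2
  z <- matrix(1, 7, 6)
  rows <- c(1, 4, 1, 4, 1, 4)
  z[cbind(rows, 1:6)] <- 0
  pz <- optimal_path(z, max_step = 2)
  expect_gt(attr(pz, "total_cost"), 0)
  expect_true(all(abs(diff(pz)) <= 2))
  # oracle equivalence on random instances
  set.seed(99)
  for (i in 1:60) {
    nr <- sample(3:6, 1); nc <- sample(4:10, 1)
    g <- matrix(runif(nr * nc), nr, nc)
    p <- optimal_path(g, max_step = 2)
    expect_equal(attr(p, "total_cost"), brute_force_path_cost(g, 2),
                 tolerance = 1e-12)
  }
})

test_that("spectral filter keeps the dominant component and is idempotent", {
  n <- 200; rate <- 100  # 2 s record
  t <- (0:(n - 1)) / rate
  pure <- 3 + 1.0 * sin(2 * pi * 7.5 * t)    # integer bin: exact
  f1 <- spectral_filter(pure, rate)
  expect_lt(max(abs(f1 - pure)), 1e-6)
  expect_equal(attr(f1, "dominant_hz"), 7.5)
  two <- 3 + 1.0 * sin(2 * pi * 7.5 * t) + 0.2 * sin(2 * pi * 30 * t)
  f2 <- spectral_filter(two, rate)
  expect_lt(max(abs(f2 - pure)) / 1.0, 0.05)  # amplitude error < 5%
  expect_lt(max(abs(spectral_filter(as.numeric(f2), rate) - f2)), 1e-9)
  cst <- rep(2.5, 50)
  expect_identical(spectral_filter(cst, rate), cst)
})

test_that("phase detection finds alternating extrema of the diameter signal", {
  mp <- default_mmode_phantom()
  marks <- detect_phases(mp$truth)
  expect_lte(abs(length(marks$ed_cols) - 37), 1)
  # analytic extrema: ED at whole periods (cols 1 + k*T), tolerance 1 column
  tpc <- 5; period_cols <- 60000 / 450 / tpc
  pred <- 1 + round((seq_along(marks$ed_cols) - 0) * period_cols)
  near <- vapply(marks$ed_cols, function(c0)
    min(abs(c0 - (1 + round((0:40) * period_cols)))), numeric(1))
  expect_lte(max(near), 1)
  # constant LVID errors out
  flat <- wall_set(lapply(stats::setNames(nm = c("ANT_EPI", "ANT_ENDO",
                                                 "POST_ENDO", "POST_EPI")),
                          function(w) wall_trace(w, rep(match(w, c("ANT_EPI",
                            "ANT_ENDO", "POST_ENDO", "POST_EPI")), 50), 1:50)))
  expect_error(detect_phases(flat), "constant")
})

test_that("noiseless phantom dimensions are recovered within 2%", {
  mp <- default_mmode_phantom()
  sm <- segment_mmode(mp$image, mmode_seeds_for_spec(mp$spec))
  d <- sm$dims
  truth <- c(mp$spec$lvid_d_mm, mp$spec$lvid_s_mm, mp$spec$lvaw_d_mm,
             mp$spec$lvaw_s_mm, mp$spec$lvpw_d_mm, mp$spec$lvpw_s_mm)
  got <- c(d$lvid_d, d$lvid_s, d$lvaw_d, d$lvaw_s, d$lvpw_d, d$lvpw_s)
  expect_true(all(abs(got / truth - 1) < 0.02))
  # wall ordering invariant holds everywhere
  tr <- sm$wallset$traces
  expect_true(all(tr$ANT_EPI$depth_mm <= tr$ANT_ENDO$depth_mm))
  expect_true(all(tr$POST_ENDO$depth_mm <= tr$POST_EPI$depth_mm))
})

test_that("triplicate segmentation runs are identical", {
  mp <- default_mmode_phantom()
  seeds <- mmode_seeds_for_spec(mp$spec)
  runs <- lapply(1:3, function(i) segment_mmode(mp$image, seeds))
  expect_identical(runs[[1]]$wallset, runs[[2]]$wallset)
  expect_identical(runs[[2]]$wallset, runs[[3]]$wallset)
  efs <- vapply(runs, function(r) {
    m <- mmode_measures(r$dims)
    m$values$EF_pct
  }, numeric(1))
  expect_equal(cv_percent(efs), 0)
})

test_that("manual edits splice in but cannot break wall ordering", {
  mp <- default_mmode_phantom()
  ws <- mp$truth
  same <- edit_trace(ws, "ANT_ENDO", c(10, 12),
                     ws$traces$ANT_ENDO$depth_mm[10:12])
  expect_identical(same$traces, ws$traces)
  # push ANT_ENDO below POST_ENDO: rejected
  bad <- ws$traces$POST_ENDO$depth_mm[10:12] + 1
  expect_error(edit_trace(ws, "ANT_ENDO", c(10, 12), bad), "rejected")
  # a legal local edit changes only the affected beat's mean
  marks <- detect_phases(ws)
  d0 <- measure_walls(ws, marks, refine = FALSE)
  col <- marks$ed_cols[2]
  ws2 <- edit_trace(ws, "POST_ENDO", c(col, col),
                    ws$traces$POST_ENDO$depth_mm[col] + 0.05)
  d1 <- measure_walls(ws2, marks, refine = FALSE)
  expect_equal(d1$lvid_s, d0$lvid_s)
  expect_equal(d1$lvid_d, d0$lvid_d + 0.05 / length(marks$ed_cols))
})
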