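# bmode_atlas: preprocessing, NMI, registration, fusion, thresholding.

test_that("preprocess median-filters and halves the grid", {
  f <- matrix(0.3, 512, 512)
  out <- preprocess(f)
  expect_equal(dim(out), c(256, 256))
  expect_true(all(out == 0.3))  # constant in, constant out
  # an isolated hot pixel is removed by the median stage
  f[100, 100] <- 50
  out2 <- preprocess(f)
  expect_lt(max(out2), 1)
  # odd dimensions: last row/col cropped
  expect_equal(dim(preprocess(matrix(1, 9, 7))), c(4, 3))
})

test_that("NMI satisfies its identities and detects independence", {
  set.seed(1)
  x <- matrix(runif(256 * 256), 256, 256)
  expect_equal(nmi(x, x), 2.0)
  y <- matrix(runif(256 * 256), 256, 256)
  expect_lt(abs(nmi(x, y, bins = 32) - 1), 0.05)  # independent -> ~1
  expect_identical(nmi(x, y), nmi(y, x))
  # invariant to positive linear rescaling (edges recomputed per image)
  expect_equal(nmi(x, y), nmi(2.5 * x + 7, y), tolerance = 1e-12)
  expect_error(nmi(x, y[1:10, 1:10]), "shape")
})

test_that("affine registration recovers identity and known shifts", {
  lib <- small_library()
  e <- lib$entries[[1]]
  pe <- preprocess(e$frame)
  pm <- lvecho:::preprocess_mask(e$mask)
  sp <- lib$pixel_spacing * 2
  r <- register_affine(pe, pm, pe, spacing = sp)
  expect_lt(sqrt(sum(r$transform[1:2]^2)) / sp, 0.5)       # < 0.5 px shift
  expect_lt(max(abs(exp(r$transform[4:5]) - 1)), 0.01)     # < 1% scale
  # known lateral shift of +5 preprocessed pixels on a noiseless frame
  # (with shared speckle the similarity peak narrows to a single pixel,
  # which no local optimizer is expected to find); the affine decomposition
  # is not unique, so judge the recovered mapping by its action at the
  # object centroid (it must move the source 5 px laterally, < 0.5 px off)
  ph <- short_bmode_phantom()
  pe <- preprocess(ph$cine$frames[[ph$ed_frame]])
  pm <- lvecho:::preprocess_mask(lvecho:::bmode_mask(ph$spec,
                                                     ph$spec$lv_diameter_ed_mm))
  sp <- ph$spec$pixel_spacing_mm * 2
  shift_px <- 5L
  tgt <- pe
  tgt[, (shift_px + 1):ncol(pe)] <- pe[, 1:(ncol(pe) - shift_px)]
  tgt[, 1:shift_px] <- pe[, 1]
  r2 <- register_affine(pe, pm, tgt, spacing = sp)
  ctr <- c((ncol(pe) - 1), (nrow(pe) - 1)) * sp / 2          # image centre (x, y)
  idx <- which(pm == 1, arr.ind = TRUE)
  cobj <- c(mean(idx[, 2] - 1), mean(idx[, 1] - 1)) * sp + c(shift_px * sp, 0)
  mapped <- as.numeric(r2$matrix %*% (cobj - ctr)) + ctr + r2$transform[1:2]
  expect_lt(sqrt(sum((mapped - (cobj - c(shift_px * sp, 0)))^2)) / sp, 0.5)
  # never worse than the identity alignment
  id_score <- nmi(pe, tgt)
  expect_gte(r2$nmi_score, id_score)
})

test_that("label fusion averages the top-k and is order-invariant", {
  mk <- function(score, id, mask) {
    r <- structure(list(nmi_score = score, warped_mask = mask),
                   class = "registration_result")
    r$id <- id
    r
  }
  m1 <- matrix(c(1, 1, 0, 0), 2, 2)
  m0 <- matrix(0, 2, 2)
  res <- list(mk(1.9, "a", m1), mk(1.8, "b", m1), mk(1.7, "c", m1),
              mk(1.6, "d", m0), mk(1.5, "e", m0), mk(1.1, "f", m1 * 0 + 1))
  pm <- fuse_top_k(res, k = 5)
  expect_equal(pm$grid[1, 1], 0.6)  # 3 of 5 agree
  expect_true(all(pm$grid >= 0 & pm$grid <= 1))
  # values on the k-lattice
  expect_true(all(abs(pm$grid * 5 - round(pm$grid * 5)) < 1e-12))
  pm2 <- fuse_top_k(rev(res), k = 5)
  expect_identical(pm$grid, pm2$grid)
  # identical masks fuse to exactly that mask
  same <- fuse_top_k(res[1:3], k = 3)
  expect_identical(same$grid, m1)
  expect_warning(fuse_top_k(res[1:3], k = 5), "fusing all")
})

test_that("thresholding keeps the largest component and fills holes", {
  m <- matrix(0, 20, 20)
  m[3:12, 3:12] <- 0.8           # 100 px component
  m[7:8, 7:8] <- 0               # hole
  m[16:17, 16:17] <- 0.9         # 4 px satellite
  out <- threshold_map(structure(list(grid = m), class = "probability_map"), 0.5)
  expect_equal(sum(out), 100)    # satellite dropped, hole filled
  expect_equal(out[7, 7], 1)
  expect_true(all(threshold_map(matrix(1, 4, 4)) == 1))
  expect_error(threshold_map(matrix(0, 4, 4)), "no consensus")
  expect_error(threshold_map(m, 1.5), "threshold")
})

test_that("segment_frame finds a near-self atlas and repeats bit-identically", {
  # a cohort-like library: similar morphologies, as an atlas would contain
  rg <- lapply(default_library_ranges(), function(r) mean(r) * c(0.97, 1.03))
  rg$speckle_scale <- c(0.3, 0.3)
  lib <- make_library(6, rg, rng_seed = 21)
  e <- lib$entries[[1]]
  seg1 <- segment_frame(e$frame, lib, phase = "ED")
  truth <- lvecho:::preprocess_mask(e$mask)
  expect_gte(dice(seg1$mask, truth), 0.95)  # its own mask is in the atlas
  seg2 <- segment_frame(e$frame, lib, phase = "ED")
  expect_identical(seg1$mask, seg2$mask)
  ed_only <- Filter(function(x) x$phase == "ED", lib$entries)
  expect_error(segment_frame(e$frame, reference_library(ed_only,
                                                        lib$pixel_spacing), "ES"),
               "no entries")
})

test_that("dice satisfies its identities", {
  a <- matrix(0, 10, 10); a[1:5, 1:5] <- 1
  expect_equal(dice(a, a), 1)
  b <- matrix(0, 10, 10); b[6:10, 6:10] <- 1
  expect_equal(dice(a, b), 0)
  # |a| = |b| = 100, overlap 80
  a2 <- matrix(0, 20, 20); a2[1:10, 1:10] <- 1
  b2 <- matrix(0, 20, 20); b2[1:10, 3:12] <- 1
  expect_equal(dice(a2, b2), 0.8)
  expect_equal(dice(matrix(0, 2, 2), matrix(0, 2, 2)), 1)
  expect_error(dice(a, matrix(0, 2, 2)), "shape")
})
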