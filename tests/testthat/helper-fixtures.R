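# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# seed pairs spanning each wall's true excursion range for an M-mode spec
mmode_seeds_for_spec <- function(spec) {
  c0 <- (spec$depth_px - 1) * spec$pixel_spacing_axial_mm / 2
  aw <- range(spec$lvaw_d_mm, spec$lvaw_s_mm)
  pw <- range(spec$lvpw_d_mm, spec$lvpw_s_mm)
  ae <- c(c0 - spec$lvid_d_mm / 2 - aw[2], c0 - spec$lvid_s_mm / 2 - aw[1])
  an <- c(c0 - spec$lvid_d_mm / 2, c0 - spec$lvid_s_mm / 2)
  pn <- c(c0 + spec$lvid_s_mm / 2, c0 + spec$lvid_d_mm / 2)
  pe <- c(c0 + spec$lvid_s_mm / 2 + pw[1], c0 + spec$lvid_d_mm / 2 + pw[2])
  list(seed_point_pair("ANT_EPI", c(0, ae[1]), c(0, ae[2])),
       seed_point_pair("ANT_ENDO", c(0, an[1]), c(0, an[2])),
       seed_point_pair("POST_ENDO", c(0, pn[1]), c(0, pn[2])),
       seed_point_pair("POST_EPI", c(0, pe[1]), c(0, pe[2])))
}

small_library <- function() memo("small_library", function() make_library(6, rng_seed = 11))

default_mmode_phantom <- function() memo("default_mmode", function()
  make_mmode_phantom(mmode_phantom_spec(lvaw_s_mm = 0.8, lvpw_s_mm = 0.8,
                                        speckle_scale = 0, rng_seed = 3)))

# a short noiseless B-mode phantom loop plus its exact contours
short_bmode_phantom <- function() memo("short_bmode", function()
  make_bmode_phantom(bmode_phantom_spec(n_frames = 30, speckle_scale = 0,
                                        rng_seed = 5)))

# a tiny on-disk study: 2 subjects (B-mode loop + M-mode sweep + seeds),
# a saved 6-phantom library and a manifest; returns paths
build_study_fixture <- function(root) {
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  lib <- small_library()
  lib_dir <- file.path(root, "library")
  save_library(lib, lib_dir)
  subjects <- list()
  for (i in 1:2) {
    ph <- make_bmode_phantom(bmode_phantom_spec(
      n_frames = 24, speckle_scale = 0.3, rng_seed = 20 + i,
      lv_length_mm = 7.5 + 0.4 * i, lv_diameter_ed_mm = 3.8 + 0.2 * i,
      lv_diameter_es_mm = (3.8 + 0.2 * i) * 0.7))
    bp <- file.path(root, sprintf("s%d_bmode.tif", i))
    write_cine(ph$cine, bp)
    msp <- mmode_phantom_spec(speckle_scale = 0.3, rng_seed = 30 + i,
                              lvid_d_mm = 3.8 + 0.2 * i,
                              lvid_s_mm = (3.8 + 0.2 * i) * 0.7,
                              lvaw_s_mm = 0.8, lvpw_s_mm = 0.8)
    mp <- make_mmode_phantom(msp)
    mm <- file.path(root, sprintf("s%d_mmode.tif", i))
    write_mmode(mp$image, mm)
    sp <- file.path(root, sprintf("s%d_seeds.json", i))
    write_seeds(mmode_seeds_for_spec(msp), sp)
    subjects[[i]] <- list(id = sprintf("s%d", i), bmode_path = bp, mmode_path = mm,
                          ed_frame = ph$ed_frame, es_frame = ph$es_frame,
                          seeds_path = sp, heart_rate = 450, timepoint = "baseline")
  }
  manifest_path <- file.path(root, "study.json")
  jsonlite::write_json(list(library = lib_dir, subjects = subjects),
                       manifest_path, auto_unbox = TRUE, digits = NA)
  list(manifest = manifest_path, library = lib_dir, root = root)
}
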