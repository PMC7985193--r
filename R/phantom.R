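# phantom: synthetic B-mode cine loops, reference libraries and M-mode
# sweeps with exact analytic ground truth.
#
# The B-mode cavity is a half-ellipsoid long-axis section: a half-ellipse
# truncated at the base, semi-axis L along the long axis and minor diameter
# D(t) oscillating sinusoidally at the heart rate between the ED and ES
# values. The myocardium is a bright band of fixed thickness around the
# cavity. Speckle is modelled as unit-mean multiplicative gamma noise
# followed by a Gaussian PSF blur (sigma 1 px) - a minimal model of the low
# signal-to-noise of high-frequency ultrasound, with no wave physics.

CAVITY_I <- 0.10  # relative echo intensity of blood pool
WALL_I <- 0.85    # myocardium
BACKGROUND_I <- 0.30

#' B-mode phantom specification
#'
#' Geometry, motion and noise parameters of the synthetic beating-LV
#' long-axis loop. Defaults follow a typical murine acquisition: a 300-frame
#' loop at 6.67 ms/frame, heart rate 450 beats/min (mid point of the 400-500
#' bpm window maintained under anaesthesia), an 8 mm base-to-apex length and
#' a 4 mm end-diastolic internal diameter.
#'
#' @param lv_length_mm Base-to-apex cavity length L, mm.
#' @param lv_diameter_ed_mm,lv_diameter_es_mm Maximal minor (short-axis)
#'   internal diameter at end-diastole / end-systole, mm; ES < ED.
#' @param wall_thickness_mm Myocardial band thickness, mm.
#' @param heart_rate_bpm Heart rate, beats/min, in [200, 800].
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval_ms Frame interval, ms.
#' @param speckle_scale Speckle strength: standard deviation of the
#'   unit-mean multiplicative gamma noise (0 = noiseless).
#' @param rng_seed Integer seed; generation is a pure function of the spec.
#' @param pixel_spacing_mm Isotropic pixel size, mm/px.
#' @param depth_px,lateral_px Grid dimensions (rows = depth).
#' @param center_dx_mm,center_dy_mm Offsets of the cavity centre from the
#'   image centre (lateral, depth), mm - used to vary placement across
#'   library entries.
#' @return An object of class `bmode_phantom_spec`.
#' @export
bmode_phantom_spec <- function(lv_length_mm = 8, lv_diameter_ed_mm = 4,
                               lv_diameter_es_mm = 2.8, wall_thickness_mm = 0.8,
                               heart_rate_bpm = 450, n_frames = 300,
                               frame_interval_ms = 6.67, speckle_scale = 0.3,
                               rng_seed = 1L, pixel_spacing_mm = 0.08,
                               depth_px = 112L, lateral_px = 160L,
                               center_dx_mm = 0, center_dy_mm = 0) {
  s <- list(lv_length_mm = lv_length_mm, lv_diameter_ed_mm = lv_diameter_ed_mm,
            lv_diameter_es_mm = lv_diameter_es_mm, wall_thickness_mm = wall_thickness_mm,
            heart_rate_bpm = heart_rate_bpm, n_frames = as.integer(n_frames),
            frame_interval_ms = frame_interval_ms, speckle_scale = speckle_scale,
            rng_seed = as.integer(rng_seed), pixel_spacing_mm = pixel_spacing_mm,
            depth_px = as.integer(depth_px), lateral_px = as.integer(lateral_px),
            center_dx_mm = center_dx_mm, center_dy_mm = center_dy_mm)
  for (nm in c("lv_length_mm", "lv_diameter_ed_mm", "lv_diameter_es_mm",
               "wall_thickness_mm", "pixel_spacing_mm", "frame_interval_ms"))
    stopifnot_scalar_pos(s[[nm]], nm)
  if (s$lv_diameter_es_mm >= s$lv_diameter_ed_mm)
    stop("ES diameter must be smaller than ED diameter", call. = FALSE)
  if (s$heart_rate_bpm < 200 || s$heart_rate_bpm > 800)
    stop("heart_rate_bpm must lie in [200, 800]", call. = FALSE)
  if (s$n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  if (s$speckle_scale < 0) stop("speckle_scale must be >= 0", call. = FALSE)
  structure(s, class = "bmode_phantom_spec")
}

# geometry of the half-ellipse cavity for a given spec and diameter
bmode_geometry <- function(spec, D) {
  x_extent <- (spec$lateral_px - 1) * spec$pixel_spacing_mm
  y_extent <- (spec$depth_px - 1) * spec$pixel_spacing_mm
  list(
    xb = (x_extent - spec$lv_length_mm) / 2 + spec$center_dx_mm,  # base x
    y0 = y_extent / 2 + spec$center_dy_mm,                        # axis depth
    L = spec$lv_length_mm, D = D, w = spec$wall_thickness_mm)
}

# render one frame (no noise); returns matrix rows = depth
bmode_render <- function(spec, D) {
  g <- bmode_geometry(spec, D)
  x <- (seq_len(spec$lateral_px) - 1) * spec$pixel_spacing_mm
  y <- (seq_len(spec$depth_px) - 1) * spec$pixel_spacing_mm
  X <- matrix(x, spec$depth_px, spec$lateral_px, byrow = TRUE)
  Y <- matrix(y, spec$depth_px, spec$lateral_px)
  u <- (X - g$xb) / g$L
  v <- (Y - g$y0) / (g$D / 2)
  cavity <- u >= 0 & u * u + v * v <= 1
  uo <- (X - g$xb) / (g$L + g$w)
  vo <- (Y - g$y0) / (g$D / 2 + g$w)
  outer_half <- uo >= 0 & uo * uo + vo * vo <= 1
  basal_cap <- X >= g$xb - g$w & X < g$xb & abs(Y - g$y0) <= g$D / 2 + g$w
  img <- matrix(BACKGROUND_I, spec$depth_px, spec$lateral_px)
  img[outer_half | basal_cap] <- WALL_I
  img[cavity] <- CAVITY_I
  img
}

bmode_mask <- function(spec, D) {
  g <- bmode_geometry(spec, D)
  x <- (seq_len(spec$lateral_px) - 1) * spec$pixel_spacing_mm
  y <- (seq_len(spec$depth_px) - 1) * spec$pixel_spacing_mm
  X <- matrix(x, spec$depth_px, spec$lateral_px, byrow = TRUE)
  Y <- matrix(y, spec$depth_px, spec$lateral_px)
  u <- (X - g$xb) / g$L
  v <- (Y - g$y0) / (g$D / 2)
  (u >= 0 & u * u + v * v <= 1) * 1
}

# exact endocardial polygon: elliptical arc from the lower to the upper
# basal corner; the closing edge is the basal chord
bmode_contour <- function(spec, D, phase, n_arc = 121L) {
  g <- bmode_geometry(spec, D)
  th <- seq(-pi / 2, pi / 2, length.out = n_arc)
  verts <- cbind(g$xb + g$L * cos(th), g$y0 + (g$D / 2) * sin(th))
  lv_contour(verts, basal_indices = c(1L, n_arc), phase = phase)
}

apply_speckle <- function(img, scale) {
  if (scale > 0) {
    s2 <- scale^2
    img <- img * matrix(stats::rgamma(length(img), shape = 1 / s2, rate = 1 / s2),
                        nrow(img), ncol(img))
  }
  EBImage::gblur(img, sigma = 1)
}

# diameter waveform: cosine at the heart rate, ED at t = 0
bmode_diameter_at <- function(spec, t_ms) {
  f <- spec$heart_rate_bpm / 60 / 1000  # cycles per ms
  mid <- (spec$lv_diameter_ed_mm + spec$lv_diameter_es_mm) / 2
  amp <- (spec$lv_diameter_ed_mm - spec$lv_diameter_es_mm) / 2
  mid + amp * cos(2 * pi * f * t_ms)
}

#' Generate a synthetic beating-LV B-mode cine loop
#'
#' Renders the half-ellipse cavity/wall model at every frame, applies
#' speckle, and returns the loop together with exact endocardial contours of
#' the selected ED and ES frames. The ED/ES frame indices are the
#' argmax/argmin of cavity area over one mid-loop cardiac cycle, mirroring
#' the frame-selection step an analyst performs.
#'
#' @param spec A [bmode_phantom_spec()].
#' @return List with elements `cine` ([cine_loop()]), `contour_ed`,
#'   `contour_es` ([lv_contour()]s of the rendered boundaries at the chosen
#'   frames), `ed_frame`, `es_frame` (1-based indices), and `spec`.
#' @export
make_bmode_phantom <- function(spec) {
  stopifnot(inherits(spec, "bmode_phantom_spec"))
  t_ms <- (seq_len(spec$n_frames) - 1) * spec$frame_interval_ms
  D <- bmode_diameter_at(spec, t_ms)
  frames <- with_seed(spec$rng_seed, lapply(D, function(d)
    apply_speckle(bmode_render(spec, d), spec$speckle_scale)))
  meta <- image_meta(pixel_spacing_axial = spec$pixel_spacing_mm,
                     pixel_spacing_lateral = spec$pixel_spacing_mm,
                     frame_interval = spec$frame_interval_ms,
                     heart_rate = spec$heart_rate_bpm, mode_tag = "B-mode",
                     subject_id = sprintf("phantom_seed%d", spec$rng_seed))
  cine <- cine_loop(frames, meta)
  # one full cycle centred mid-loop (or the whole record if shorter)
  period_ms <- 60000 / spec$heart_rate_bpm
  t_mid <- t_ms[length(t_ms)] / 2
  win <- which(t_ms >= t_mid - period_ms / 2 & t_ms < t_mid + period_ms / 2)
  if (length(win) < 2L) win <- seq_along(t_ms)
  ed <- win[which.max(D[win])]
  es <- win[which.min(D[win])]
  list(cine = cine,
       contour_ed = bmode_contour(spec, D[ed], "ED"),
       contour_es = bmode_contour(spec, D[es], "ES"),
       ed_frame = ed, es_frame = es, spec = spec)
}

#' Reference library of (frame, LV mask) pairs
#'
#' The atlas that drives multi-atlas B-mode segmentation: labelled example
#' frames with exact binary LV cavity masks, tagged by cardiac phase.
#'
#' @param entries List of entries, each `list(frame, mask, phase, id)` with
#'   `mask` binary, same shape as `frame`, non-empty.
#' @param pixel_spacing Isotropic pixel size of the entries, mm/px.
#' @return An object of class `reference_library`.
#' @export
reference_library <- function(entries, pixel_spacing) {
  if (!length(entries)) stop("reference library must be non-empty", call. = FALSE)
  for (e in entries) {
    if (!identical(dim(e$frame), dim(e$mask)))
      stop("every mask must match its frame's shape", call. = FALSE)
    if (sum(e$mask) == 0) stop("library masks must be non-empty", call. = FALSE)
    if (!e$phase %in% c("ED", "ES")) stop("entry phase must be ED or ES", call. = FALSE)
  }
  structure(list(entries = entries, pixel_spacing = pixel_spacing),
            class = "reference_library")
}

#' Default parameter ranges for synthetic library generation
#'
#' Uniform sampling ranges spanning plausible adult-mouse LV geometry:
#' lengths 6.5-9.5 mm, ED diameters 3.2-4.8 mm, ES/ED diameter ratios
#' 0.60-0.80 (fractional shortening 20-40%), wall thicknesses 0.6-1.0 mm,
#' heart rates 400-500 beats/min, and sub-millimetre placement jitter.
#'
#' @return Named list of `c(min, max)` ranges.
#' @export
default_library_ranges <- function() {
  list(lv_length_mm = c(6.5, 9.5),
       lv_diameter_ed_mm = c(3.2, 4.8),
       es_fraction = c(0.60, 0.80),
       wall_thickness_mm = c(0.6, 1.0),
       heart_rate_bpm = c(400, 500),
       center_dx_mm = c(-0.5, 0.5),
       center_dy_mm = c(-0.5, 0.5),
       speckle_scale = c(0.3, 0.3))
}

#' Generate a synthetic reference library
#'
#' Draws `n` phantom specifications uniformly from `spec_ranges` and renders
#' one ED and one ES (frame, exact mask) pair per phantom, giving `2n`
#' library entries. A synthetic surrogate for a manually traced atlas of
#' long-axis frames.
#'
#' @param n Number of phantoms (>= 2).
#' @param spec_ranges Named list of `c(min, max)` ranges as in
#'   [default_library_ranges()].
#' @param rng_seed Integer seed; the library is a pure function of
#'   `(n, spec_ranges, rng_seed)`.
#' @return A [reference_library()] with `2n` entries; each entry additionally
#'   carries its generating `spec`.
#' @export
make_library <- function(n, spec_ranges = default_library_ranges(), rng_seed = 1L) {
  if (n < 2L) stop("library needs n >= 2 phantoms", call. = FALSE)
  ranges <- utils::modifyList(default_library_ranges(), spec_ranges)
  for (nm in names(ranges))
    if (ranges[[nm]][1] > ranges[[nm]][2])
      stop(sprintf("degenerate range for '%s' (min > max)", nm), call. = FALSE)
  draw <- function(rg) stats::runif(1, rg[1], rg[2])
  entries <- with_seed(rng_seed, {
    out <- vector("list", 2L * n)
    for (i in seq_len(n)) {
      ded <- draw(ranges$lv_diameter_ed_mm)
      spec <- bmode_phantom_spec(
        lv_length_mm = draw(ranges$lv_length_mm),
        lv_diameter_ed_mm = ded,
        lv_diameter_es_mm = ded * draw(ranges$es_fraction),
        wall_thickness_mm = draw(ranges$wall_thickness_mm),
        heart_rate_bpm = draw(ranges$heart_rate_bpm),
        speckle_scale = draw(ranges$speckle_scale),
        center_dx_mm = draw(ranges$center_dx_mm),
        center_dy_mm = draw(ranges$center_dy_mm),
        rng_seed = rng_seed + i)
      for (ph in c("ED", "ES")) {
        D <- if (ph == "ED") spec$lv_diameter_ed_mm else spec$lv_diameter_es_mm
        frame <- apply_speckle(bmode_render(spec, D), spec$speckle_scale)
        mask <- bmode_mask(spec, D)
        out[[2L * (i - 1L) + (ph == "ES") + 1L]] <-
          list(frame = frame, mask = mask, phase = ph,
               id = sprintf("ph%03d_%s", i, ph), spec = spec)
      }
    }
    out
  })
  reference_library(entries, entries[[1]]$spec$pixel_spacing_mm)
}

#' M-mode phantom specification
#'
#' Parameters of the synthetic four-wall short-axis M-mode sweep. Defaults
#' emulate a 5-second sweep at 450 beats/min with a 4.0/2.8 mm
#' diastolic/systolic internal diameter and 0.8 mm diastolic walls that
#' thicken in systole.
#'
#' @param lvid_d_mm,lvid_s_mm LV internal diameter at diastole / systole, mm.
#' @param lvaw_d_mm,lvaw_s_mm Anterior wall thickness at diastole / systole, mm.
#' @param lvpw_d_mm,lvpw_s_mm Posterior wall thickness at diastole / systole, mm.
#' @param heart_rate_bpm Heart rate, beats/min.
#' @param duration_ms Sweep duration, ms (must exceed two beats).
#' @param columns Number of time columns.
#' @param depth_px Number of depth rows.
#' @param pixel_spacing_axial_mm Axial pixel size, mm/px.
#' @param speckle_scale Speckle strength as in [bmode_phantom_spec()].
#' @param rng_seed Integer seed.
#' @return An object of class `mmode_phantom_spec`.
#' @export
mmode_phantom_spec <- function(lvid_d_mm = 4.0, lvid_s_mm = 2.8,
                               lvaw_d_mm = 0.8, lvaw_s_mm = 1.1,
                               lvpw_d_mm = 0.8, lvpw_s_mm = 1.1,
                               heart_rate_bpm = 450, duration_ms = 5000,
                               columns = 1000L, depth_px = 220L,
                               pixel_spacing_axial_mm = 0.04,
                               speckle_scale = 0.3, rng_seed = 1L) {
  s <- list(lvid_d_mm = lvid_d_mm, lvid_s_mm = lvid_s_mm,
            lvaw_d_mm = lvaw_d_mm, lvaw_s_mm = lvaw_s_mm,
            lvpw_d_mm = lvpw_d_mm, lvpw_s_mm = lvpw_s_mm,
            heart_rate_bpm = heart_rate_bpm, duration_ms = duration_ms,
            columns = as.integer(columns), depth_px = as.integer(depth_px),
            pixel_spacing_axial_mm = pixel_spacing_axial_mm,
            speckle_scale = speckle_scale, rng_seed = as.integer(rng_seed))
  for (nm in c("lvid_d_mm", "lvid_s_mm", "lvaw_d_mm", "lvaw_s_mm",
               "lvpw_d_mm", "lvpw_s_mm", "duration_ms", "pixel_spacing_axial_mm"))
    stopifnot_scalar_pos(s[[nm]], nm)
  if (s$lvid_s_mm >= s$lvid_d_mm)
    stop("systolic LVID must be smaller than diastolic LVID", call. = FALSE)
  if (s$duration_ms <= 2 * 60000 / s$heart_rate_bpm)
    stop("duration_ms must cover more than two beats", call. = FALSE)
  # interfaces must stay ordered and inside the image at all phases
  depth_mm <- (s$depth_px - 1) * s$pixel_spacing_axial_mm
  cd <- depth_mm / 2
  wmax <- max(s$lvaw_d_mm, s$lvaw_s_mm, s$lvpw_d_mm, s$lvpw_s_mm)
  if (cd - s$lvid_d_mm / 2 - wmax <= 0 || cd + s$lvid_d_mm / 2 + wmax >= depth_mm)
    stop("geometry exceeds image depth extent", call. = FALSE)
  structure(s, class = "mmode_phantom_spec")
}

# the four interface depth signals (mm) at times t_ms; diastole at t = 0
mmode_interfaces <- function(spec, t_ms) {
  f <- spec$heart_rate_bpm / 60 / 1000
  osc <- cos(2 * pi * f * t_ms)
  lvid <-(spec$lvid_d_mm + spec$lvid_s_mm) / 2 +
    (spec$lvid_d_mm - spec$lvid_s_mm) / 2 * osc
  lvaw <- (spec$lvaw_d_mm + spec$lvaw_s_mm) / 2 -
    (spec$lvaw_s_mm - spec$lvaw_d_mm) / 2 * osc
  lvpw <- (spec$lvpw_d_mm + spec$lvpw_s_mm) / 2 -
    (spec$lvpw_s_mm - spec$lvpw_d_mm) / 2 * osc
  c0 <- (spec$depth_px - 1) * spec$pixel_spacing_axial_mm / 2
  list(ANT_ENDO = c0 - lvid / 2,
       ANT_EPI = c0 - lvid / 2 - lvaw,
       POST_ENDO = c0 + lvid / 2,
       POST_EPI = c0 + lvid / 2 + lvpw)
}

#' Generate a synthetic four-wall M-mode sweep
#'
#' The four wall-interface depths are sinusoids at the heart rate, phased so
#' the internal diameter attains its diastolic and systolic values exactly;
#' walls thicken in systole. Walls render bright, the cavity dark; speckle
#' as in [make_bmode_phantom()]. The exact interface depths are returned as
#' a ground-truth [wall_set()] at full column resolution.
#'
#' @param spec An [mmode_phantom_spec()].
#' @return List with elements `image` ([mmode_image()]), `truth`
#'   ([wall_set()]), and `spec`.
#' @export
make_mmode_phantom <- function(spec) {
  stopifnot(inherits(spec, "mmode_phantom_spec"))
  t_ms <- (seq_len(spec$columns) - 1) * spec$duration_ms / spec$columns
  ifc <- mmode_interfaces(spec, t_ms)
  y <- (seq_len(spec$depth_px) - 1) * spec$pixel_spacing_axial_mm
  img <- matrix(BACKGROUND_I, spec$depth_px, spec$columns)
  for (j in seq_len(spec$columns)) {
    col <- rep(BACKGROUND_I, spec$depth_px)
    col[y >= ifc$ANT_EPI[j] & y < ifc$ANT_ENDO[j]] <- WALL_I
    col[y >= ifc$ANT_ENDO[j] & y < ifc$POST_ENDO[j]] <- CAVITY_I
    col[y >= ifc$POST_ENDO[j] & y < ifc$POST_EPI[j]] <- WALL_I
    img[, j] <- col
  }
  img <- with_seed(spec$rng_seed, apply_speckle(img, spec$speckle_scale))
  meta <- image_meta(pixel_spacing_axial = spec$pixel_spacing_axial_mm,
                     time_per_column = spec$duration_ms / spec$columns,
                     heart_rate = spec$heart_rate_bpm, mode_tag = "M-mode",
                     subject_id = sprintf("mmode_seed%d", spec$rng_seed))
  truth <- wall_set(lapply(
    stats::setNames(nm = c("ANT_EPI", "ANT_ENDO", "POST_ENDO", "POST_EPI")),
    function(w) wall_trace(w, ifc[[w]], t_ms)))
  list(image = mmode_image(img, meta), truth = truth, spec = spec)
}
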