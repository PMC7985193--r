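# io_formats: calibrated image containers, sidecar metadata, ROI and seed
# JSON, and the CSV/PNG study report.
#
# Pixel <-> physical convention: pixel (row i, col j), 1-based in R, has
# physical position x_mm = (j-1)*lateral spacing, y_mm = (i-1)*axial spacing,
# origin at the image top-left, depth increasing downward (transducer at
# row 1).

#' Image acquisition metadata
#'
#' Calibration and header information carried with every image. For B-mode
#' cine loops `pixel_spacing_lateral` is mm/px; for M-mode sweeps the lateral
#' axis is time and `time_per_column` (ms/px) is used instead.
#'
#' @param pixel_spacing_axial Axial (depth) spacing, mm/px.
#' @param pixel_spacing_lateral Lateral spacing, mm/px (B-mode).
#' @param time_per_column Time per image column, ms/px (M-mode).
#' @param frame_interval Frame interval, ms (cine loops).
#' @param heart_rate Heart rate, beats/min, or `NA` when the header lacks it.
#'   A missing heart rate never aborts a run; only heart-rate-dependent
#'   endpoints (cardiac output) are withheld downstream.
#' @param mode_tag Image type tag, `"B-mode"` or `"M-mode"`.
#' @param subject_id Subject identifier.
#' @param acquisition_time Acquisition timestamp (string) or `NA`.
#' @return An object of class `image_meta`.
#' @export
image_meta <- function(pixel_spacing_axial, pixel_spacing_lateral = NA_real_,
                       time_per_column = NA_real_, frame_interval = NA_real_,
                       heart_rate = NA_real_, mode_tag = "B-mode",
                       subject_id = "unknown", acquisition_time = NA_character_) {
  stopifnot_scalar_pos(pixel_spacing_axial, "pixel_spacing_axial")
  if (!is.na(pixel_spacing_lateral)) stopifnot_scalar_pos(pixel_spacing_lateral, "pixel_spacing_lateral")
  if (!is.na(time_per_column)) stopifnot_scalar_pos(time_per_column, "time_per_column")
  if (!is.na(frame_interval)) stopifnot_scalar_pos(frame_interval, "frame_interval")
  if (!nzchar(mode_tag)) stop("mode_tag must be non-empty", call. = FALSE)
  structure(list(
    pixel_spacing_axial = pixel_spacing_axial,
    pixel_spacing_lateral = pixel_spacing_lateral,
    time_per_column = time_per_column,
    frame_interval = frame_interval,
    heart_rate = heart_rate,
    mode_tag = mode_tag,
    subject_id = subject_id,
    acquisition_time = acquisition_time
  ), class = "image_meta")
}

#' B-mode cine loop
#'
#' An ordered list of 2-D intensity frames (rows = depth, row 1 shallowest;
#' columns = lateral) with calibration metadata.
#'
#' @param frames List of numeric matrices, all the same shape, finite and
#'   non-negative.
#' @param meta An [image_meta()].
#' @return An object of class `cine_loop`.
#' @export
cine_loop <- function(frames, meta) {
  if (!is.list(frames) || length(frames) < 2L)
    stop("a cine loop requires >= 2 frames", call. = FALSE)
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), d))
      stop("all frames must be matrices of identical shape", call. = FALSE)
    if (any(!is.finite(f)) || any(f < 0))
      stop("frame intensities must be finite and >= 0", call. = FALSE)
  }
  if (is.na(meta$frame_interval))
    stop("cine metadata requires frame_interval", call. = FALSE)
  structure(list(frames = frames, meta = meta), class = "cine_loop")
}

#' M-mode sweep image
#'
#' A single 2-D grid, rows = depth, columns = time (increasing left to
#' right), with calibration metadata.
#'
#' @param grid Numeric matrix of intensities, finite and non-negative.
#' @param meta An [image_meta()] with `time_per_column` set.
#' @return An object of class `mmode_image`.
#' @export
mmode_image <- function(grid, meta) {
  if (!is.matrix(grid) || ncol(grid) < 2L)
    stop("an M-mode image requires >= 2 time columns", call. = FALSE)
  if (any(!is.finite(grid)) || any(grid < 0))
    stop("intensities must be finite and >= 0", call. = FALSE)
  if (is.na(meta$time_per_column))
    stop("M-mode metadata requires time_per_column", call. = FALSE)
  structure(list(grid = grid, meta = meta), class = "mmode_image")
}

#' Left-ventricle endocardial contour
#'
#' A closed simple polygon in physical mm coordinates with two vertices
#' flagged as the basal (mitral annulus) points; the chord between them is
#' the base of the ventricle.
#'
#' @param vertices Two-column matrix of (x_mm, y_mm) vertices, >= 8 rows,
#'   implicitly closed (last vertex connects to first).
#' @param basal_indices Two distinct 1-based vertex indices flagging the base.
#' @param phase `"ED"` (end-diastole) or `"ES"` (end-systole).
#' @return An object of class `lv_contour`.
#' @export
lv_contour <- function(vertices, basal_indices, phase = c("ED", "ES")) {
  phase <- match.arg(phase)
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 8L) stop("a contour requires >= 8 vertices", call. = FALSE)
  if (ncol(vertices) != 2L || any(!is.finite(vertices)))
    stop("vertices must be a finite 2-column (x, y) matrix", call. = FALSE)
  basal_indices <- as.integer(basal_indices)
  if (length(basal_indices) != 2L || anyNA(basal_indices) ||
      basal_indices[1] == basal_indices[2] ||
      any(basal_indices < 1L) || any(basal_indices > nrow(vertices)))
    stop("basal_indices must be two distinct valid vertex indices", call. = FALSE)
  if (!polygon_is_simple(vertices))
    stop("contour polygon is self-intersecting", call. = FALSE)
  structure(list(vertices = vertices, basal_indices = basal_indices, phase = phase),
            class = "lv_contour")
}

#' Seed-point pair bounding one M-mode wall
#'
#' The user-placed upper and lower boundary points that define the search
#' region for one of the four wall interfaces.
#'
#' @param wall_id One of `"ANT_EPI"`, `"ANT_ENDO"`, `"POST_ENDO"`, `"POST_EPI"`.
#' @param upper,lower Numeric `c(t_ms, depth_mm)` points; `upper` must be
#'   shallower than `lower`.
#' @return An object of class `seed_point_pair`.
#' @export
seed_point_pair <- function(wall_id, upper, lower) {
  wall_id <- match.arg(wall_id, c("ANT_EPI", "ANT_ENDO", "POST_ENDO", "POST_EPI"))
  upper <- as.numeric(upper); lower <- as.numeric(lower)
  if (length(upper) != 2L || length(lower) != 2L || any(!is.finite(c(upper, lower))))
    stop("seed points must be finite (t_ms, depth_mm) pairs", call. = FALSE)
  if (upper[2] >= lower[2])
    stop("upper seed must be shallower than lower seed", call. = FALSE)
  structure(list(wall_id = wall_id, upper = upper, lower = lower),
            class = "seed_point_pair")
}

# -- sidecar helpers ---------------------------------------------------------

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop(sprintf("metadata error: sidecar '%s' not found", sp), call. = FALSE)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

meta_from_sidecar <- function(sc, mode) {
  num <- function(x) { x <- unlist(x); if (!length(x)) NA_real_ else as.numeric(x[1]) }
  chr <- function(x, d) { x <- unlist(x); if (!length(x) || is.na(x[1])) d else as.character(x[1]) }
  if (is.na(num(sc$pixel_spacing_axial)))
    stop("metadata error: pixel_spacing_axial missing from sidecar", call. = FALSE)
  image_meta(
    pixel_spacing_axial = num(sc$pixel_spacing_axial),
    pixel_spacing_lateral = num(sc$pixel_spacing_lateral),
    time_per_column = num(sc$time_per_column),
    frame_interval = num(sc$frame_interval),
    heart_rate = num(sc$heart_rate),
    mode_tag = chr(sc$mode_tag, mode),
    subject_id = chr(sc$subject_id, "unknown"),
    acquisition_time = chr(sc$acquisition_time, NA_character_)
  )
}

check_not_dicom <- function(path) {
  if (grepl("\\.dcm$", path, ignore.case = TRUE))
    stop("format error: DICOM input is not supported; convert to multi-page TIFF with a JSON sidecar",
         call. = FALSE)
}

# Intensities are stored as 16-bit grayscale TIFF scaled by a sidecar
# intensity_scale, so stored values lie on the lattice k/65535 * scale.
# Writing quantizes once; subsequent write/read cycles are bit-exact.
INT16 <- 65535

#' Read a B-mode cine loop
#'
#' Reads a multi-page TIFF (or single-page, which errors: a loop needs at
#' least two frames) and its JSON sidecar (same basename, `.json`) carrying
#' pixel spacing, frame interval and optional heart rate. DICOM is not
#' supported.
#'
#' @param path Path to a multi-page TIFF file.
#' @return A [cine_loop()]. If the sidecar `mode_tag` is not `"B-mode"` a
#'   mode-mismatch warning is raised (the loop is still returned).
#' @export
read_cine <- function(path) {
  if (!file.exists(path)) stop(sprintf("format error: '%s' does not exist", path), call. = FALSE)
  check_not_dicom(path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e) stop(sprintf("format error reading '%s': %s", path, conditionMessage(e)), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop(">=2 frames required in a cine loop", call. = FALSE)
  sc <- read_sidecar(path)
  meta <- meta_from_sidecar(sc, "B-mode")
  if (is.na(meta$pixel_spacing_lateral))
    stop("metadata error: pixel_spacing_lateral missing", call. = FALSE)
  if (!identical(meta$mode_tag, "B-mode"))
    warning(sprintf("mode mismatch: expected B-mode, header says '%s'", meta$mode_tag))
  scale <- as.numeric(sc$intensity_scale %||% 1)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p * scale
  })
  cine_loop(frames, meta)
}

#' Write a B-mode cine loop
#'
#' Stores frames as 16-bit multi-page TIFF plus a JSON sidecar holding the
#' metadata and the intensity scale. Values are quantized to the 16-bit
#' lattice; a write/read cycle after the first quantization is lossless.
#'
#' @param cine A [cine_loop()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_cine <- function(cine, path) {
  stopifnot(inherits(cine, "cine_loop"))
  mx <- max(1e-12, max(vapply(cine$frames, max, numeric(1))))
  pages <- lapply(cine$frames, function(f) round(f / mx * INT16) / INT16)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sc <- unclass(cine$meta)
  sc$intensity_scale <- mx
  jsonlite::write_json(sc, sidecar_path(path), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read an M-mode sweep image
#'
#' @param path Path to a single-page TIFF with JSON sidecar carrying
#'   `pixel_spacing_axial` (mm/px) and `time_per_column` (ms/px).
#' @return An [mmode_image()]. A `B-mode` mode tag raises a mode-mismatch
#'   warning.
#' @export
read_mmode <- function(path) {
  if (!file.exists(path)) stop(sprintf("format error: '%s' does not exist", path), call. = FALSE)
  check_not_dicom(path)
  g <- tryCatch(tiff::readTIFF(path),
                error = function(e) stop(sprintf("format error reading '%s': %s", path, conditionMessage(e)), call. = FALSE))
  if (length(dim(g)) == 3L) g <- g[, , 1]
  sc <- read_sidecar(path)
  meta <- meta_from_sidecar(sc, "M-mode")
  if (is.na(meta$time_per_column))
    stop("metadata error: time_per_column missing", call. = FALSE)
  if (!identical(meta$mode_tag, "M-mode"))
    warning(sprintf("mode mismatch: expected M-mode, header says '%s'", meta$mode_tag))
  scale <- as.numeric(sc$intensity_scale %||% 1)
  mmode_image(g * scale, meta)
}

#' Write an M-mode sweep image
#' @param img An [mmode_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mmode <- function(img, path) {
  stopifnot(inherits(img, "mmode_image"))
  mx <- max(1e-12, max(img$grid))
  tiff::writeTIFF(round(img$grid / mx * INT16) / INT16, path, bits.per.sample = 16L)
  sc <- unclass(img$meta)
  sc$intensity_scale <- mx
  jsonlite::write_json(sc, sidecar_path(path), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read / write an LV contour as JSON
#'
#' Schema: `{"phase": "ED"|"ES", "vertices": [[x_mm, y_mm], ...],
#' "basal_indices": [i, j]}` with 1-based vertex indices. Round trips are
#' lossless to full double precision.
#'
#' @param path JSON file path.
#' @return [lv_contour()] for `read_roi`; `path` invisibly for `write_roi`.
#' @export
read_roi <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lv_contour(matrix(as.numeric(j$vertices), ncol = 2,
                    byrow = !is.matrix(j$vertices)) ,
             as.integer(j$basal_indices), as.character(j$phase))
}

#' @rdname read_roi
#' @param contour An [lv_contour()].
#' @export
write_roi <- function(contour, path) {
  stopifnot(inherits(contour, "lv_contour"))
  jsonlite::write_json(
    list(phase = contour$phase,
         vertices = unname(contour$vertices),
         basal_indices = contour$basal_indices),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read / write M-mode seed points as JSON
#'
#' Schema: a list of four objects `{"wall_id": ..., "upper": [t_ms, depth_mm],
#' "lower": [t_ms, depth_mm]}`.
#' @param path JSON file path.
#' @return A list of [seed_point_pair()] for `read_seeds`.
#' @export
read_seeds <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(j, function(s)
    seed_point_pair(s$wall_id, unlist(s$upper), unlist(s$lower)))
}

#' @rdname read_seeds
#' @param seeds List of [seed_point_pair()].
#' @export
write_seeds <- function(seeds, path) {
  jsonlite::write_json(
    lapply(seeds, function(s) list(wall_id = s$wall_id, upper = s$upper, lower = s$lower)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# fixed report column order; units embedded in names
REPORT_COLUMNS <- c(
  "subject_id", "timepoint", "mode", "heart_rate_bpm",
  "EDA_mm2", "ESA_mm2", "EDD_mm", "ESD_mm", "EDV_uL", "ESV_uL",
  "EF_pct", "FS_pct", "FAC_pct", "SV_uL", "CO_mL_min",
  "LVID_d_mm", "LVID_s_mm", "LVAW_d_mm", "LVAW_s_mm", "LVPW_d_mm", "LVPW_s_mm",
  "LV_mass_mg", "LV_mass_corr_mg")

#' Write (or update) the study measurement report
#'
#' Writes one CSV row per measure set, keyed by (subject, timepoint, mode),
#' in a fixed documented column order with units in the header. If the CSV
#' already exists, rows with matching keys are overwritten and others are
#' preserved, so re-running an analysis updates the report in place. A
#' companion PNG overlay is written for any measure set carrying an
#' `overlay` attribute (a grayscale matrix in [0,1] or RGB array).
#'
#' @param measures Non-empty list of [measure_set()] objects.
#' @param path Output CSV path.
#' @return The report data frame, invisibly.
#' @export
write_report <- function(measures, path) {
  if (!is.list(measures) || length(measures) == 0L ||
      inherits(measures, "measure_set"))
    measures <- if (inherits(measures, "measure_set")) list(measures) else measures
  if (length(measures) == 0L) stop("empty measures list", call. = FALSE)
  rows <- lapply(measures, function(m) {
    stopifnot(inherits(m, "measure_set"))
    row <- as.list(rep(NA_real_, length(REPORT_COLUMNS)))
    names(row) <- REPORT_COLUMNS
    row$subject_id <- m$subject_id
    row$timepoint <- m$timepoint
    row$mode <- m$mode
    row$heart_rate_bpm <- m$heart_rate %||% NA_real_
    for (nm in names(m$values)) if (nm %in% REPORT_COLUMNS) row[[nm]] <- m$values[[nm]]
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  new <- do.call(rbind, rows)
  if (file.exists(path)) {
    old <- utils::read.csv(path, stringsAsFactors = FALSE)
    # align old file to the current schema
    for (nm in setdiff(REPORT_COLUMNS, names(old))) old[[nm]] <- NA_real_
    old <- old[, REPORT_COLUMNS, drop = FALSE]
    key <- function(d) paste(d$subject_id, d$timepoint, d$mode, sep = "\r")
    old <- old[!(key(old) %in% key(new)), , drop = FALSE]
    new <- rbind(old, new)
  }
  new <- new[order(new$subject_id, new$timepoint, new$mode), , drop = FALSE]
  utils::write.csv(new, path, row.names = FALSE, na = "")
  # companion overlay snapshots
  for (m in measures) {
    ov <- attr(m, "overlay")
    if (!is.null(ov)) {
      pngpath <- file.path(dirname(path),
                           sprintf("%s_%s_%s_overlay.png", m$subject_id, m$timepoint, m$mode))
      png::writePNG(ov, pngpath)
    }
  }
  invisible(new)
}

#' Named LV endpoint set for one subject, timepoint and imaging mode
#'
#' @param subject_id,timepoint,mode Report key fields (`mode` is `"B-mode"`
#'   or `"M-mode"`).
#' @param values Named list of endpoint values using the report column names
#'   (e.g. `EF_pct`, `EDV_uL`); see [write_report()] for the full set.
#' @param heart_rate Heart rate in beats/min or `NA`.
#' @return An object of class `measure_set`.
#' @export
measure_set <- function(subject_id, timepoint, mode, values, heart_rate = NA_real_) {
  structure(list(subject_id = subject_id, timepoint = timepoint, mode = mode,
                 values = values, heart_rate = heart_rate),
            class = "measure_set")
}
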