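# cli_workflow: batch study processing. A study manifest lists per-subject
# image files, ED/ES frame indices and seed-point files; run_study()
# processes every subject (isolating failures), stores the segmentations
# alongside a structured log, and writes the aggregated CSV report.
# regenerate_reports() rebuilds the report from the stored segmentations so
# manual edits propagate without re-running the segmenters.

#' Read and validate a study manifest
#'
#' JSON schema: `{"library": "<dir-or-rds-free library path>", "subjects":
#' [{"id", "bmode_path", "mmode_path", "ed_frame", "es_frame", "seeds_path",
#' "heart_rate" (optional), "timepoint" (optional)} ...]}`. Subject ids must
#' be unique; file paths are resolved relative to the manifest's directory.
#'
#' @param path Manifest JSON path.
#' @return A list of class `study_manifest`.
#' @export
read_manifest <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  root <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else file.path(root, p)
  subjects <- lapply(j$subjects, function(s) {
    s$bmode_path <- resolve(s$bmode_path)
    s$mmode_path <- resolve(s$mmode_path)
    s$seeds_path <- resolve(s$seeds_path)
    s
  })
  ids <- vapply(subjects, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("subject ids must be unique", call. = FALSE)
  structure(list(subjects = subjects, library = resolve(j$library)),
            class = "study_manifest")
}

write_mask_png <- function(mask, path) {
  png::writePNG(pmin(pmax(mask, 0), 1), path)
  invisible(path)
}

overlay_rgb <- function(frame, mask) {
  f <- frame / max(frame, 1e-12)
  edge <- pmin(pmax(mask - (EBImage::erode(mask, EBImage::makeBrush(3, "box")) > 0), 0), 1)
  rgb <- array(f, dim = c(dim(f), 3))
  rgb[, , 1] <- pmin(1, f + edge)
  rgb[, , 2] <- f * (1 - edge)
  rgb[, , 3] <- f * (1 - edge)
  rgb
}

process_subject_bmode <- function(s, library, opts, subj_dir) {
  cine <- read_cine(s$bmode_path)
  hr <- s$heart_rate %||% cine$meta$heart_rate %||% NA_real_
  spacing2 <- library$pixel_spacing * 2
  contours <- list()
  log <- list()
  for (ph in c("ED", "ES")) {
    idx <- if (ph == "ED") s$ed_frame else s$es_frame
    frame <- cine$frames[[idx]]
    seg <- segment_frame(frame, library, phase = ph, opts = opts)
    contours[[ph]] <- mask_to_contour(seg$mask, spacing2, phase = ph)
    write_mask_png(seg$mask, file.path(subj_dir, sprintf("bmode_%s_mask.png", ph)))
    write_roi(contours[[ph]], file.path(subj_dir, sprintf("bmode_%s_contour.json", ph)))
    log[[ph]] <- list(frame = idx, fused = seg$prob_map$chosen,
                      nmi = lapply(seg$registrations,
                                   function(r) list(id = r$id, nmi = r$nmi_score)))
  }
  ms <- bmode_measures(contours$ED, contours$ES, heart_rate = hr,
                       subject_id = s$id, timepoint = s$timepoint %||% "t0")
  frame <- preprocess(cine$frames[[s$ed_frame]])
  segmask <- png::readPNG(file.path(subj_dir, "bmode_ED_mask.png"))
  attr(ms, "overlay") <- overlay_rgb(frame, (segmask > 0.5) * 1)
  list(measures = ms, log = log, heart_rate = hr)
}

process_subject_mmode <- function(s, subj_dir) {
  img <- read_mmode(s$mmode_path)
  hr <- s$heart_rate %||% img$meta$heart_rate %||% NA_real_
  seeds <- read_seeds(s$seeds_path)
  seg <- segment_mmode(img, seeds)
  tr <- seg$wallset$traces
  df <- data.frame(column = seq_along(tr$ANT_EPI$depth_mm),
                   time_ms = tr$ANT_EPI$col_times_ms,
                   ANT_EPI = tr$ANT_EPI$depth_mm, ANT_ENDO = tr$ANT_ENDO$depth_mm,
                   POST_ENDO = tr$POST_ENDO$depth_mm, POST_EPI = tr$POST_EPI$depth_mm)
  utils::write.csv(df, file.path(subj_dir, "mmode_traces.csv"), row.names = FALSE)
  jsonlite::write_json(list(ed_cols = seg$marks$ed_cols, es_cols = seg$marks$es_cols),
                       file.path(subj_dir, "mmode_marks.json"), auto_unbox = FALSE)
  ms <- mmode_measures(seg$dims, heart_rate = hr, subject_id = s$id,
                       timepoint = s$timepoint %||% "t0")
  list(measures = ms, log = list(low_confidence = seg$low_confidence),
       heart_rate = hr)
}

#' Run a full study from a manifest
#'
#' For every subject: multi-atlas B-mode segmentation of the ED and ES
#' frames followed by [bmode_measures()], then M-mode wall tracing followed
#' by [mmode_measures()]. Per-subject segmentations, contours, traces and a
#' structured log are stored under `out_dir/<subject>/`; all endpoints are
#' aggregated with [write_report()]. A failure in one subject is logged and
#' does not stop the run.
#'
#' @param manifest A `study_manifest` (from [read_manifest()]) or a path to
#'   one.
#' @param out_dir Output directory (created if needed).
#' @param library A [reference_library()]; if `NULL`, loaded from the
#'   manifest's `library` entry (a directory produced by
#'   [save_library()]).
#' @param opts Segmentation options ([atlas_opts()]).
#' @return List with `report` (data frame), `failures` (named list of error
#'   messages), and `partial` (TRUE when any subject failed), invisibly.
#' @export
run_study <- function(manifest, out_dir, library = NULL, opts = atlas_opts()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "study_manifest"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(library)) library <- load_library(manifest$library)
  all_measures <- list()
  failures <- list()
  logs <- list()
  for (s in manifest$subjects) {
    subj_dir <- file.path(out_dir, s$id)
    dir.create(subj_dir, showWarnings = FALSE)
    res <- tryCatch({
      out <- list()
      if (!is.null(s$bmode_path)) out$b <- process_subject_bmode(s, library, opts, subj_dir)
      if (!is.null(s$mmode_path)) out$m <- process_subject_mmode(s, subj_dir)
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[s$id]] <- conditionMessage(res)
      logs[[s$id]] <- list(status = "failed", error = conditionMessage(res))
    } else {
      if (!is.null(res$b)) all_measures <- c(all_measures, list(res$b$measures))
      if (!is.null(res$m)) all_measures <- c(all_measures, list(res$m$measures))
      logs[[s$id]] <- list(status = "ok",
                           bmode = res$b$log %||% NULL, mmode = res$m$log %||% NULL,
                           heart_rate = (res$b %||% res$m)$heart_rate)
      # subject metadata needed for report regeneration
      jsonlite::write_json(list(id = s$id, timepoint = s$timepoint %||% "t0",
                                heart_rate = (res$b %||% res$m)$heart_rate),
                           file.path(subj_dir, "subject.json"),
                           auto_unbox = TRUE, na = "null")
    }
  }
  jsonlite::write_json(logs, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, na = "null", digits = NA)
  report <- NULL
  if (length(all_measures))
    report <- write_report(all_measures, file.path(out_dir, "report.csv"))
  invisible(list(report = report, failures = failures,
                 partial = length(failures) > 0))
}

#' Regenerate the study report from stored segmentations
#'
#' Re-reads every subject's stored contours and wall traces (possibly
#' manually edited since the run), recomputes all endpoints, and rewrites
#' `report.csv`, so the report always reflects the latest segmentations.
#' Subjects with missing segmentation files are listed and skipped.
#'
#' @param results_dir Directory produced by [run_study()].
#' @return List with `report` and `missing` (subject ids lacking stored
#'   segmentations), invisibly.
#' @export
regenerate_reports <- function(results_dir) {
  subj_dirs <- list.dirs(results_dir, recursive = FALSE)
  measures <- list()
  missing <- character(0)
  for (d in subj_dirs) {
    meta_p <- file.path(d, "subject.json")
    if (!file.exists(meta_p)) next
    meta <- jsonlite::read_json(meta_p, simplifyVector = TRUE)
    hr <- as.numeric(meta$heart_rate %||% NA_real_)
    ed_p <- file.path(d, "bmode_ED_contour.json")
    es_p <- file.path(d, "bmode_ES_contour.json")
    tr_p <- file.path(d, "mmode_traces.csv")
    mk_p <- file.path(d, "mmode_marks.json")
    got <- FALSE
    if (file.exists(ed_p) && file.exists(es_p)) {
      measures <- c(measures, list(bmode_measures(
        read_roi(ed_p), read_roi(es_p), heart_rate = hr,
        subject_id = meta$id, timepoint = meta$timepoint)))
      got <- TRUE
    }
    if (file.exists(tr_p) && file.exists(mk_p)) {
      df <- utils::read.csv(tr_p)
      traces <- lapply(stats::setNames(nm = WALL_IDS), function(w)
        wall_trace(w, df[[w]], df$time_ms))
      ws <- wall_set(traces)
      mk <- jsonlite::read_json(mk_p, simplifyVector = TRUE)
      dims <- measure_walls(ws, phase_marks(mk$ed_cols, mk$es_cols))
      measures <- c(measures, list(mmode_measures(
        dims, heart_rate = hr, subject_id = meta$id, timepoint = meta$timepoint)))
      got <- TRUE
    }
    if (!got) missing <- c(missing, meta$id)
  }
  report <- NULL
  path <- file.path(results_dir, "report.csv")
  if (file.exists(path)) unlink(path)  # rebuild from scratch: edits only
  if (length(measures)) report <- write_report(measures, path)
  invisible(list(report = report, missing = missing))
}

#' Save / load a reference library as plain files
#'
#' Each entry is stored as a 16-bit TIFF frame, a PNG mask and a JSON record
#' under `dir/`; `library.json` indexes the entries. Round trips preserve
#' masks exactly and frames on the 16-bit lattice.
#'
#' @param library A [reference_library()].
#' @param dir Directory path.
#' @return `dir` (`save_library`) or a [reference_library()]
#'   (`load_library`).
#' @export
save_library <- function(library, dir) {
  stopifnot(inherits(library, "reference_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- list(pixel_spacing = library$pixel_spacing, ids = character(0))
  for (e in library$entries) {
    mx <- max(e$frame, 1e-12)
    tiff::writeTIFF(round(e$frame / mx * INT16) / INT16,
                    file.path(dir, paste0(e$id, "_frame.tif")), bits.per.sample = 16L)
    png::writePNG(e$mask, file.path(dir, paste0(e$id, "_mask.png")))
    jsonlite::write_json(list(id = e$id, phase = e$phase, intensity_scale = mx),
                         file.path(dir, paste0(e$id, ".json")), auto_unbox = TRUE)
    idx$ids <- c(idx$ids, e$id)
  }
  jsonlite::write_json(idx, file.path(dir, "library.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_library
#' @export
load_library <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "library.json"), simplifyVector = TRUE)
  entries <- lapply(idx$ids, function(id) {
    meta <- jsonlite::read_json(file.path(dir, paste0(id, ".json")), simplifyVector = TRUE)
    frame <- tiff::readTIFF(file.path(dir, paste0(id, "_frame.tif"))) * meta$intensity_scale
    mask <- (png::readPNG(file.path(dir, paste0(id, "_mask.png"))) > 0.5) * 1
    list(frame = frame, mask = mask, phase = meta$phase, id = id)
  })
  reference_library(entries, idx$pixel_spacing)
}
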