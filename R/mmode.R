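# mmode_walls: semi-automated tracing of the four M-mode wall interfaces.
#
# For each wall the user places two seed points bounding a depth band; a
# polarity-rectified gradient cost image is built over the band, a dynamic
# program finds the minimum-cost depth path across time, the path is
# filtered in the spectral domain down to its dominant periodic component,
# and systolic/diastolic dimensions are read off at the peaks of the
# filtered internal-diameter signal.

WALL_IDS <- c("ANT_EPI", "ANT_ENDO", "POST_ENDO", "POST_EPI")

# expected axial intensity transition when moving deeper (increasing row):
# entering a wall is dark-to-bright, leaving it bright-to-dark
WALL_POLARITY <- c(ANT_EPI = "dark-to-bright", ANT_ENDO = "bright-to-dark",
                   POST_ENDO = "dark-to-bright", POST_EPI = "bright-to-dark")

#' Per-wall boundary trace
#'
#' One interface depth per time column.
#'
#' @param wall_id One of `ANT_EPI`, `ANT_ENDO`, `POST_ENDO`, `POST_EPI`.
#' @param depth_mm Numeric vector of interface depths, mm.
#' @param col_times_ms Time of each column, ms (same length).
#' @return An object of class `wall_trace`.
#' @export
wall_trace <- function(wall_id, depth_mm, col_times_ms) {
  wall_id <- match.arg(wall_id, WALL_IDS)
  if (length(depth_mm) != length(col_times_ms))
    stop("depth_mm and col_times_ms must have equal length", call. = FALSE)
  structure(list(wall_id = wall_id, depth_mm = as.numeric(depth_mm),
                 col_times_ms = as.numeric(col_times_ms)),
            class = "wall_trace")
}

#' Set of the four wall traces
#'
#' Validates the depth ordering ANT_EPI <= ANT_ENDO <= POST_ENDO <= POST_EPI
#' at every column.
#'
#' @param traces Named list of four [wall_trace()]s.
#' @return An object of class `wall_set`.
#' @export
wall_set <- function(traces) {
  if (!all(WALL_IDS %in% names(traces)))
    stop("wall_set requires all four wall traces", call. = FALSE)
  traces <- traces[WALL_IDS]
  n <- length(traces$ANT_EPI$depth_mm)
  for (tr in traces) if (length(tr$depth_mm) != n)
    stop("all traces must share the column grid", call. = FALSE)
  tol <- 1e-9
  if (any(traces$ANT_EPI$depth_mm > traces$ANT_ENDO$depth_mm + tol) ||
      any(traces$ANT_ENDO$depth_mm > traces$POST_ENDO$depth_mm + tol) ||
      any(traces$POST_ENDO$depth_mm > traces$POST_EPI$depth_mm + tol))
    stop("wall depth ordering violated (ANT_EPI <= ANT_ENDO <= POST_ENDO <= POST_EPI)",
         call. = FALSE)
  structure(list(traces = traces), class = "wall_set")
}

#' End-diastole / end-systole column marks
#' @param ed_cols,es_cols Column indices of end-diastole (LVID maxima) and
#'   end-systole (LVID minima); non-empty and alternating in time.
#' @return An object of class `phase_marks`.
#' @export
phase_marks <- function(ed_cols, es_cols) {
  if (!length(ed_cols) || !length(es_cols))
    stop("insufficient beats: need at least one ED and one ES mark", call. = FALSE)
  lab <- c(rep("ED", length(ed_cols)), rep("ES", length(es_cols)))
  ord <- order(c(ed_cols, es_cols))
  if (any(lab[ord][-1] == lab[ord][-length(lab)]))
    stop("phase marks must alternate in time", call. = FALSE)
  structure(list(ed_cols = as.integer(sort(ed_cols)),
                 es_cols = as.integer(sort(es_cols))), class = "phase_marks")
}

#' Build the seed-bounded search region for one wall
#'
#' The depth band spans the two seed depths, padded by `margin_px` and
#' clipped to the image; the full time extent is used. The expected gradient
#' polarity is assigned from the wall identity.
#'
#' @param seeds A [seed_point_pair()].
#' @param image An [mmode_image()].
#' @param margin_px Band padding in rows; `NULL` (default) uses 10% of the
#'   band height.
#' @return An object of class `search_region`: `wall_id`, `row_range`,
#'   `polarity`.
#' @export
make_region <- function(seeds, image, margin_px = NULL) {
  stopifnot(inherits(seeds, "seed_point_pair"), inherits(image, "mmode_image"))
  sp <- image$meta$pixel_spacing_axial
  tpc <- image$meta$time_per_column
  nr <- nrow(image$grid); nc <- ncol(image$grid)
  depth_extent <- (nr - 1) * sp
  time_extent <- (nc - 1) * tpc
  for (pt in list(seeds$upper, seeds$lower))
    if (pt[1] < 0 || pt[1] > time_extent || pt[2] < 0 || pt[2] > depth_extent)
      stop("seed point outside image extent", call. = FALSE)
  d <- sort(c(seeds$upper[2], seeds$lower[2]))
  r <- c(floor(d[1] / sp) + 1L, ceiling(d[2] / sp) + 1L)
  if (is.null(margin_px)) margin_px <- ceiling(0.1 * (r[2] - r[1] + 1L))
  r <- c(max(1L, r[1] - margin_px), min(nr, r[2] + margin_px))
  if (r[2] - r[1] + 1L < 3L) stop("search band shorter than 3 rows", call. = FALSE)
  structure(list(wall_id = seeds$wall_id, row_range = r,
                 col_range = c(1L, nc),
                 polarity = unname(WALL_POLARITY[seeds$wall_id])),
            class = "search_region")
}

#' Gradient cost image over a search region
#'
#' Gaussian smoothing (sigma 1 px, along the depth axis: smoothing across
#' time would blur the moving interface and bite into the excursion peaks)
#' followed by the signed axial (depth-direction) derivative; the
#' derivative sign is flipped for bright-to-dark polarity, negative values
#' are rectified to zero, and the result is min-max normalized over the
#' region. Cost = 1 - normalized rectified gradient, so the expected
#' interface has cost near 0.
#'
#' @param region_pixels Intensity matrix of the band (rows = depth).
#' @param polarity `"dark-to-bright"` or `"bright-to-dark"`.
#' @return An object of class `cost_image` (list with `grid`; attribute
#'   `uniform` is TRUE when the region had zero gradient everywhere).
#' @export
cost_image <- function(region_pixels, polarity = c("dark-to-bright", "bright-to-dark")) {
  polarity <- match.arg(polarity)
  if (nrow(region_pixels) < 3L) stop("region must have >= 3 rows", call. = FALSE)
  k <- stats::dnorm(-3:3, sd = 1); k <- k / sum(k)
  sm <- EBImage::filter2(region_pixels, matrix(k, ncol = 1), boundary = "replicate")
  nr <- nrow(sm)
  g <- (sm[c(2:nr, nr), ] - sm[c(1L, 1:(nr - 1L)), ]) / 2  # central diff, replicated ends
  if (polarity == "bright-to-dark") g <- -g
  g <- pmax(g, 0)
  uniform <- FALSE
  rng <- range(g)
  if (rng[2] - rng[1] <= 0) {
    warning("uniform region: zero gradient everywhere, cost is flat")
    grid <- matrix(1, nrow(g), ncol(g))
    uniform <- TRUE
  } else {
    grid <- 1 - (g - rng[1]) / (rng[2] - rng[1])
  }
  structure(list(grid = grid), class = "cost_image", uniform = uniform)
}

#' Minimum-cost depth path across a cost image
#'
#' Dynamic programming over columns: finds the row sequence r(1..T) with
#' |r(t+1) - r(t)| <= `max_step` minimizing the summed cost, the exact
#' global optimum under the step constraint. Ties break toward the smaller
#' (shallower) row at every backtrack step, so the result is deterministic.
#'
#' @param cost A `cost_image` or plain cost matrix (finite, >= 0).
#' @param max_step Maximum row change per column (>= 1; default 2).
#' @return Integer vector of row indices, one per column, with attribute
#'   `total_cost`.
#' @export
optimal_path <- function(cost, max_step = 2L) {
  grid <- if (inherits(cost, "cost_image")) cost$grid else cost
  if (!is.matrix(grid) || ncol(grid) < 1L) stop("cost image has zero width", call. = FALSE)
  if (max_step < 1L) stop("max_step must be >= 1", call. = FALSE)
  nr <- nrow(grid); nc <- ncol(grid)
  max_step <- as.integer(max_step)
  dp <- grid[, 1]
  back <- matrix(0L, nr, nc)
  offs <- (-max_step):max_step
  for (t in 2:nc) {
    best <- rep(Inf, nr)
    bprev <- integer(nr)
    for (o in offs) {
      # previous row = current row + o (valid where within bounds)
      idx <- seq_len(nr) + o
      valid <- idx >= 1L & idx <= nr
      cand <- rep(Inf, nr)
      cand[valid] <- dp[idx[valid]]
      # strict improvement keeps the earliest (processed in offset order);
      # to break ties toward the smaller previous row, prefer smaller idx
      upd <- cand < best | (cand == best & valid & idx < bprev)
      upd[!valid] <- FALSE
      best[upd] <- cand[upd]
      bprev[upd] <- idx[upd]
    }
    dp <- best + grid[, t]
    back[, t] <- bprev
  }
  if (nc == 1L) return(structure(which.min(dp), total_cost = min(dp)))
  path <- integer(nc)
  path[nc] <- which.min(dp)  # which.min: first (smallest row) on ties
  for (t in nc:2L) path[t - 1L] <- back[path[t], t]
  structure(path, total_cost = min(dp))
}

#' Spectral filtering of a wall trace
#'
#' Subtracts the mean, takes the discrete Fourier transform, retains only
#' the positive-frequency bin of maximal magnitude (with its conjugate),
#' inverts, and restores the mean - i.e. keeps the dominant periodic
#' component (the cardiac motion) plus baseline. Idempotent. A constant
#' trace is returned unchanged.
#'
#' @param trace A [wall_trace()] (or plain numeric vector).
#' @param frame_rate Columns per second; used only to report the retained
#'   frequency (attribute `dominant_hz`).
#' @return Filtered object of the same type.
#' @export
spectral_filter <- function(trace, frame_rate = NULL) {
  y <- if (inherits(trace, "wall_trace")) trace$depth_mm else trace
  n <- length(y)
  if (n < 8L) stop("spectral filtering requires >= 8 columns", call. = FALSE)
  mu <- mean(y)
  z <- y - mu
  if (all(abs(z) < 1e-15)) return(trace)
  Y <- stats::fft(z)
  half <- 2:(floor(n / 2) + 1L)
  k <- half[which.max(Mod(Y[half]))]
  Z <- complex(n)
  Z[k] <- Y[k]
  conj_k <- n - k + 2L
  if (conj_k != k && conj_k <= n) Z[conj_k] <- Y[conj_k]
  out <- Re(stats::fft(Z, inverse = TRUE)) / n + mu
  dom <- if (is.null(frame_rate)) NA_real_ else (k - 1L) * frame_rate / n
  if (inherits(trace, "wall_trace")) {
    trace$depth_mm <- out
    attr(trace, "dominant_hz") <- dom
    trace
  } else structure(out, dominant_hz = dom)
}

#' Detect end-diastole and end-systole columns
#'
#' Computes the internal diameter LVID(t) = POST_ENDO(t) - ANT_ENDO(t) from
#' the filtered wall set; end-diastole marks are its plateau-safe local
#' maxima (first index of any plateau) and end-systole marks its minima.
#'
#' @param wallset A (filtered) [wall_set()].
#' @return A [phase_marks()].
#' @export
detect_phases <- function(wallset) {
  stopifnot(inherits(wallset, "wall_set"))
  lvid <- wallset$traces$POST_ENDO$depth_mm - wallset$traces$ANT_ENDO$depth_mm
  if (max(lvid) - min(lvid) < 1e-12)
    stop("insufficient beats: internal diameter is constant", call. = FALSE)
  ex <- local_extrema(lvid)
  if (!length(ex$max) || !length(ex$min))
    stop("insufficient beats: less than one full cycle detected", call. = FALSE)
  phase_marks(ex$max, ex$min)
}

#' M-mode structural dimensions
#'
#' @param lvid_d,lvid_s,lvaw_d,lvaw_s,lvpw_d,lvpw_s Mean internal diameter
#'   and wall thicknesses at diastole/systole, mm.
#' @param per_beat Named list of per-beat value vectors, kept for audit.
#' @return An object of class `mmode_dimensions`.
#' @export
mmode_dimensions <- function(lvid_d, lvid_s, lvaw_d, lvaw_s, lvpw_d, lvpw_s,
                             per_beat = list()) {
  vals <- c(lvid_d = lvid_d, lvid_s = lvid_s, lvaw_d = lvaw_d,
            lvaw_s = lvaw_s, lvpw_d = lvpw_d, lvpw_s = lvpw_s)
  if (any(vals <= 0)) stop("all M-mode dimensions must be > 0", call. = FALSE)
  if (lvid_s >= lvid_d)
    warning("systolic LVID >= diastolic LVID: check phase detection")
  structure(c(as.list(vals), list(per_beat = per_beat)), class = "mmode_dimensions")
}

#' Measure wall dimensions at the detected phases
#'
#' At every end-diastole column: LVID;d = POST_ENDO - ANT_ENDO,
#' LVAW;d = ANT_ENDO - ANT_EPI, LVPW;d = POST_EPI - POST_ENDO, and
#' analogously at end-systole columns. Each reported dimension is the mean
#' over all detected beats; per-beat values are retained.
#'
#' When `refine` is TRUE (the default) each mark column is first snapped to
#' the local extremum of the raw internal-diameter signal within half a
#' beat: the marks come from the spectrally filtered signal, whose single
#' retained frequency can drift against the true beats by up to a quarter
#' cycle when the record holds a non-integer number of beats, and reading
#' the raw trace at a drifted column underestimates the excursion.
#'
#' @param wallset A [wall_set()] (raw dynamic-programming traces).
#' @param marks A [phase_marks()].
#' @param refine Snap marks to raw-signal extrema before measuring.
#' @return An [mmode_dimensions()].
#' @export
measure_walls <- function(wallset, marks, refine = TRUE) {
  stopifnot(inherits(wallset, "wall_set"), inherits(marks, "phase_marks"))
  tr <- wallset$traces
  lvid <- tr$POST_ENDO$depth_mm - tr$ANT_ENDO$depth_mm
  lvaw <- tr$ANT_ENDO$depth_mm - tr$ANT_EPI$depth_mm
  lvpw <- tr$POST_EPI$depth_mm - tr$POST_ENDO$depth_mm
  n <- length(lvid)
  ed <- marks$ed_cols; es <- marks$es_cols
  if (refine) {
    gaps <- diff(sort(c(ed, es)))            # ~ half a beat between marks
    w <- if (length(gaps)) max(1L, as.integer(round(stats::median(gaps)))) else n
    snap <- function(col, fun) {
      win <- max(1L, col - w):min(n, col + w)
      win[fun(lvid[win])]                     # first index on ties
    }
    ed <- vapply(ed, snap, integer(1), fun = which.max)
    es <- vapply(es, snap, integer(1), fun = which.min)
  }
  at <- function(v, cols) v[cols]
  pb <- list(lvid_d = at(lvid, ed), lvid_s = at(lvid, es),
             lvaw_d = at(lvaw, ed), lvaw_s = at(lvaw, es),
             lvpw_d = at(lvpw, ed), lvpw_s = at(lvpw, es))
  mmode_dimensions(mean(pb$lvid_d), mean(pb$lvid_s), mean(pb$lvaw_d),
                   mean(pb$lvaw_s), mean(pb$lvpw_d), mean(pb$lvpw_s),
                   per_beat = pb)
}

#' Full semi-automated M-mode segmentation
#'
#' For each of the four walls: build the seed-bounded search region, the
#' gradient cost image and the dynamic-programming optimal path, then filter
#' each trace in the spectral domain, detect phases and measure dimensions.
#' Deterministic for fixed inputs.
#'
#' Phase detection runs on the spectrally filtered traces, whose single
#' retained frequency gives clean, noise-free peak locations; the
#' dimensions themselves are measured on the raw dynamic-programming traces
#' at those columns, because single-bin filtering attenuates amplitude
#' whenever the record does not hold a whole number of beats (spectral
#' leakage) while the raw trace keeps the true excursion.
#'
#' @param image An [mmode_image()].
#' @param seeds List of four [seed_point_pair()]s, one per wall.
#' @param max_step DP step constraint, rows/column (default 2).
#' @param margin_px Search-band padding; see [make_region()].
#' @param subpixel Refine each column of the DP path to sub-pixel depth by
#'   a parabolic fit of the cost minimum (default TRUE); removes the
#'   half-pixel quantization bias of the integer path.
#' @return List with `wallset` (the raw DP [wall_set()], the measurement
#'   surface), `filtered` (the spectrally filtered [wall_set()] used for
#'   phase detection), `marks`, `dims`, and `low_confidence` (wall ids
#'   whose search band had uniform cost).
#' @export
segment_mmode <- function(image, seeds, max_step = 2L, margin_px = NULL,
                          subpixel = TRUE) {
  stopifnot(inherits(image, "mmode_image"))
  if (length(seeds) != 4L) stop("need exactly 4 seed pairs", call. = FALSE)
  ids <- vapply(seeds, function(s) s$wall_id, character(1))
  if (!setequal(ids, WALL_IDS)) stop("need one seed pair per wall", call. = FALSE)
  seeds <- seeds[match(WALL_IDS, ids)]
  sp <- image$meta$pixel_spacing_axial
  tpc <- image$meta$time_per_column
  t_ms <- (seq_len(ncol(image$grid)) - 1) * tpc
  frame_rate <- 1000 / tpc
  low_conf <- character(0)
  raw <- list()
  filt <- list()
  for (s in seeds) {
    reg <- make_region(s, image, margin_px)
    band <- image$grid[reg$row_range[1]:reg$row_range[2], , drop = FALSE]
    ci <- withCallingHandlers(
      cost_image(band, reg$polarity),
      warning = function(w) {
        low_conf <<- union(low_conf, s$wall_id)
        invokeRestart("muffleWarning")
      })
    path <- optimal_path(ci, max_step)
    rows <- as.numeric(path)
    if (subpixel) rows <- rows + subpixel_offset(ci$grid, path)
    tr <- wall_trace(s$wall_id, (reg$row_range[1] - 1L + rows - 1L) * sp, t_ms)
    raw[[s$wall_id]] <- tr
    filt[[s$wall_id]] <- spectral_filter(tr, frame_rate)
  }
  ws <- wall_set(raw)
  wsf <- wall_set(filt)
  marks <- detect_phases(wsf)
  dims <- measure_walls(ws, marks)
  list(wallset = ws, filtered = wsf, marks = marks, dims = dims,
       low_confidence = low_conf)
}

# parabolic interpolation of the per-column cost minimum about the DP row;
# offsets are clipped to +/- 0.5 row
subpixel_offset <- function(grid, path) {
  nr <- nrow(grid)
  off <- numeric(length(path))
  ok <- path > 1L & path < nr
  if (any(ok)) {
    t_ok <- which(ok)
    cm <- grid[cbind(path[t_ok] - 1L, t_ok)]
    c0 <- grid[cbind(path[t_ok], t_ok)]
    cp <- grid[cbind(path[t_ok] + 1L, t_ok)]
    den <- cm - 2 * c0 + cp
    o <- ifelse(den > 1e-12, 0.5 * (cm - cp) / den, 0)
    off[t_ok] <- pmin(pmax(o, -0.5), 0.5)
  }
  off
}

#' Splice a manual edit into a wall trace
#'
#' Replaces the depths of one wall over a column range and revalidates the
#' depth-ordering invariant; an edit that would break the ordering is
#' rejected with a diagnostic. Measurements are recomputed by the caller.
#'
#' @param wallset A [wall_set()].
#' @param wall_id Wall to edit.
#' @param column_range `c(first, last)` columns (1-based, inclusive).
#' @param new_depths Replacement depths, mm (length = range width).
#' @return The edited [wall_set()].
#' @export
edit_trace <- function(wallset, wall_id, column_range, new_depths) {
  stopifnot(inherits(wallset, "wall_set"))
  wall_id <- match.arg(wall_id, WALL_IDS)
  cols <- column_range[1]:column_range[2]
  tr <- wallset$traces[[wall_id]]
  if (any(cols < 1L) || any(cols > length(tr$depth_mm)))
    stop("column_range outside trace extent", call. = FALSE)
  if (length(new_depths) != length(cols))
    stop("new_depths length must match the column range", call. = FALSE)
  tr$depth_mm[cols] <- new_depths
  traces <- wallset$traces
  traces[[wall_id]] <- tr
  tryCatch(wall_set(traces),
           error = function(e) stop(sprintf(
             "edit rejected: %s", conditionMessage(e)), call. = FALSE))
}
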