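# bmode_atlas: multi-atlas segmentation of a B-mode frame.
#
# Pipeline: preprocess (median denoise + 2x downsample) -> affine-register
# every phase-matched library entry to the target with normalized mutual
# information as the objective -> fuse the labels of the top-5 registrations
# into a probability map -> threshold to the final LV mask.
#
# Everything is deterministic: the optimizer is Nelder-Mead from a fixed
# start, ties in label fusion break on entry id, so repeat analyses of the
# same frame are bit-identical.

#' Default multi-atlas segmentation options
#'
#' @param bins Histogram bins per axis for NMI (default 32).
#' @param k Number of top-scoring registrations fused (default 5).
#' @param threshold Probability-map threshold in (0, 1) (default 0.5, a
#'   majority vote of 5).
#' @param levels Pyramid levels for registration (default 3: downsample
#'   factors 4, 2, 1).
#' @param maxit Nelder-Mead iteration cap per level, coarse to fine.
#' @return Named list of options.
#' @export
atlas_opts <- function(bins = 32L, k = 5L, threshold = 0.5, levels = 3L,
                       maxit = c(300L, 200L, 120L)) {
  stopifnot(bins >= 2L, k >= 1L, threshold > 0, threshold < 1, levels >= 1L)
  maxit <- rep_len(as.integer(maxit), levels)
  list(bins = as.integer(bins), k = as.integer(k), threshold = threshold,
       levels = as.integer(levels), maxit = maxit)
}

#' Denoise and downsample a frame for registration
#'
#' 3x3 median filter followed by 2x2 block-mean downsampling; the pixel
#' spacing of the result is doubled. Odd trailing rows/columns are cropped
#' before downsampling.
#'
#' @param frame Numeric intensity matrix, at least 4x4.
#' @return Matrix of half the size (attribute `scale_factor` = 2).
#' @export
preprocess <- function(frame) {
  if (!is.matrix(frame) || nrow(frame) < 4L || ncol(frame) < 4L)
    stop("frame must be a matrix of at least 4x4", call. = FALSE)
  mx <- max(frame)
  med <- if (mx > 0) EBImage::medianFilter(frame / mx, size = 1L) * mx else frame
  out <- block_mean(med, 2L)
  attr(out, "scale_factor") <- 2L
  out
}

# downsample a binary mask consistently with preprocess (no median filter;
# block mean then majority)
preprocess_mask <- function(mask) {
  (block_mean(mask, 2L) >= 0.5) * 1
}

#' Normalized mutual information of two images
#'
#' `NMI = (H(a) + H(b)) / H(a, b)` from a joint histogram with `bins`
#' equal-width bins per axis, bin edges computed per image over its own
#' intensity range (making the score invariant to linear rescaling of either
#' image). Ranges over [1, 2]; 2 for identical images, 1 for independent
#' ones.
#'
#' @param a,b Numeric matrices of identical shape.
#' @param bins Number of histogram bins per axis (>= 2).
#' @return NMI score, unitless.
#' @export
nmi <- function(a, b, bins = 32L) {
  if (!identical(dim(a), dim(b))) stop("images must share a shape", call. = FALSE)
  if (bins < 2L) stop("bins must be >= 2", call. = FALSE)
  ia <- bin_index(a, bins); ib <- bin_index(b, bins)
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins)
  p <- joint / sum(joint)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pj <- matrix(p, bins, bins)
  ha <- h(rowSums(pj)); hb <- h(colSums(pj)); hab <- h(p)
  if (hab == 0) return(2)  # both images constant
  (ha + hb) / hab
}

bin_index <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1L, length(x)))
  i <- floor((x - rng[1]) / (rng[2] - rng[1]) * bins) + 1L
  pmin(as.integer(i), bins)
}

# -- affine transform parameterization ---------------------------------------
# params p = (tx, ty, theta, log_sx, log_sy, shear), mapping target physical
# coords (mm, about the target centre) to source physical coords:
#   q = A (p - c) + c + t,  A = R(theta) Shear(h) diag(sx, sy)

affine_matrix <- function(p) {
  th <- p[3]; sx <- exp(p[4]); sy <- exp(p[5]); h <- p[6]
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Sh <- matrix(c(1, 0, h, 1), 2, 2)
  R %*% Sh %*% diag(c(sx, sy))
}

# warp source image into the target grid; grids share `spacing` mm/px
warp_image <- function(src, p, spacing, dim_out, interp = c("bilinear", "nearest"),
                       fill = 0) {
  interp <- match.arg(interp)
  A <- affine_matrix(p)
  nr <- dim_out[1]; nc <- dim_out[2]
  cx <- (nc - 1) * spacing / 2; cy <- (nr - 1) * spacing / 2
  xt <- rep((seq_len(nc) - 1) * spacing, each = nr) - cx
  yt <- rep((seq_len(nr) - 1) * spacing, times = nc) - cy
  xs <- A[1, 1] * xt + A[1, 2] * yt + cx + p[1]
  ys <- A[2, 1] * xt + A[2, 2] * yt + cy + p[2]
  r <- ys / spacing + 1; c <- xs / spacing + 1
  v <- if (interp == "bilinear") bilinear_sample(src, r, c, fill)
       else nearest_sample(src, r, c, fill)
  matrix(v, nr, nc)
}

#' Affine registration of a library entry to a target frame
#'
#' Maximizes [nmi()] between the warped entry frame and the target over
#' 6-parameter affines (translation, rotation, anisotropic scale, shear)
#' with a multi-resolution Nelder-Mead ascent (coarse-to-fine pyramid,
#' deterministic fixed initialization at the identity). If the optimum found
#' scores below the identity transform, the identity is returned instead, so
#' the result never undercuts the trivial alignment. The entry mask is
#' resampled into target space with nearest-neighbour interpolation.
#'
#' @param entry_frame,entry_mask Preprocessed atlas frame and its binary
#'   mask.
#' @param target Preprocessed target frame (same pixel spacing).
#' @param spacing Pixel spacing of the preprocessed grids, mm/px.
#' @param opts Options from [atlas_opts()].
#' @return An object of class `registration_result`: `transform` (the
#'   6-parameter vector), `matrix` (2x2 affine part), `nmi_score` (at full
#'   preprocessed resolution), `warped_mask`, `converged`.
#' @export
register_affine <- function(entry_frame, entry_mask, target, spacing = 1,
                            opts = atlas_opts()) {
  stopifnot(is.matrix(entry_frame), is.matrix(target))
  fill <- stats::median(c(entry_frame[1, ], entry_frame[nrow(entry_frame), ],
                          entry_frame[, 1], entry_frame[, ncol(entry_frame)]))
  factors <- 2^((opts$levels - 1L):0L)
  # translation initialization: align dark-weighted centroids (the cavity is
  # the dark structure of interest), then refine on a coarse translation grid
  cen <- function(img) {
    w <- max(img) - img
    s <- sum(w)
    if (s <= 0) return(c(0, 0))
    c(sum(w * (col(img) - 1)), sum(w * (row(img) - 1))) / s * spacing
  }
  p <- c(cen(entry_frame) - cen(target), 0, 0, 0, 0)
  # joint histograms need several pixels per occupied bin to be informative,
  # so the bin count shrinks with the pyramid level
  level_bins <- function(npix) max(8L, min(opts$bins, as.integer(sqrt(npix) / 2)))
  f0 <- factors[1]
  tgt0 <- block_mean(target, f0)
  src0 <- block_mean(entry_frame, f0)
  sp0 <- spacing * f0
  b0 <- level_bins(length(tgt0))
  step <- sp0 * seq(-6, 6, by = 2)
  cand <- as.matrix(expand.grid(dx = step, dy = step))
  sc0 <- apply(cand, 1, function(d)
    nmi(warp_image(src0, p + c(d, 0, 0, 0, 0), sp0, dim(tgt0), fill = fill),
        tgt0, b0))
  p[1:2] <- p[1:2] + cand[which.max(sc0), ]
  converged <- TRUE
  for (li in seq_along(factors)) {
    f <- factors[li]
    tgt <- block_mean(target, f)
    src <- block_mean(entry_frame, f)
    sp <- spacing * f
    bl <- level_bins(length(tgt))
    obj <- function(q) -nmi(warp_image(src, q, sp, dim(tgt), fill = fill),
                            tgt, bl)
    # parameter scaling: translations in mm, angles/log-scales/shear unitless
    res <- stats::optim(p, obj, method = "Nelder-Mead",
                        control = list(maxit = opts$maxit[li],
                                       parscale = c(sp, sp, 0.05, 0.05, 0.05, 0.05)))
    p <- res$par
    if (li == length(factors)) converged <- res$convergence == 0L
  }
  score <- nmi(warp_image(entry_frame, p, spacing, dim(target), fill = fill),
               target, opts$bins)
  id_score <- nmi(warp_image(entry_frame, rep(0, 6), spacing, dim(target), fill = fill),
                  target, opts$bins)
  if (id_score > score) {
    p <- rep(0, 6); score <- id_score
  }
  wm <- warp_image(entry_mask, p, spacing, dim(target), interp = "nearest", fill = 0)
  structure(list(transform = p, matrix = affine_matrix(p), nmi_score = score,
                 warped_mask = wm, converged = converged),
            class = "registration_result")
}

#' Fuse the top-k registrations into a probability map
#'
#' Selects the `k` registrations with the highest NMI score (ties broken by
#' ascending entry id, so the selection is deterministic) and averages their
#' warped masks pixelwise. Values lie on the lattice {0, 1/k, ..., 1}.
#'
#' @param results List of `registration_result`s, each carrying an `id`
#'   element (attached by [segment_frame()]) used for tie-breaking.
#' @param k Number of atlases fused; if fewer results are available, all are
#'   used with a warning.
#' @return An object of class `probability_map` (list with `grid`, `chosen`
#'   ids).
#' @export
fuse_top_k <- function(results, k = 5L) {
  if (!length(results)) stop("no registration results to fuse", call. = FALSE)
  if (length(results) < k) {
    warning(sprintf("only %d registrations available; fusing all", length(results)))
    k <- length(results)
  }
  ids <- vapply(results, function(r) r$id %||% "", character(1))
  scores <- vapply(results, function(r) r$nmi_score, numeric(1))
  ord <- order(-scores, ids)
  sel <- ord[seq_len(k)]
  grid <- Reduce(`+`, lapply(results[sel], function(r) r$warped_mask)) / k
  structure(list(grid = grid, chosen = ids[sel]), class = "probability_map")
}

#' Threshold a probability map to the final segmentation
#'
#' Applies `grid >= t`, keeps the largest 4-connected component and fills
#' interior holes.
#'
#' @param map A `probability_map` (or plain matrix of values in [0, 1]).
#' @param t Threshold in (0, 1); default 0.5.
#' @return Binary mask matrix.
#' @export
threshold_map <- function(map, t = 0.5) {
  if (t <= 0 || t >= 1) stop("threshold must lie in (0, 1)", call. = FALSE)
  grid <- if (inherits(map, "probability_map")) map$grid else map
  m <- (grid >= t) * 1
  if (sum(m) == 0) stop("no consensus segmentation (empty mask after threshold)",
                        call. = FALSE)
  fill_holes4(largest_component4(m))
}

#' Multi-atlas segmentation of one B-mode frame
#'
#' Full composition: [preprocess()] the target, register every phase-matched
#' library entry with [register_affine()], fuse the top-k with
#' [fuse_top_k()], and [threshold_map()] the result. Deterministic for fixed
#' inputs and options.
#'
#' @param frame Raw intensity matrix (native resolution).
#' @param library A [reference_library()].
#' @param phase `"ED"` or `"ES"`; only entries of this phase are used.
#' @param opts Options from [atlas_opts()].
#' @return List with `mask` (binary, at the preprocessed half-resolution
#'   grid; attribute `pixel_spacing` gives its mm/px), `prob_map`, and
#'   `registrations` (all results, with NMI scores and ids).
#' @export
segment_frame <- function(frame, library, phase = c("ED", "ES"),
                          opts = atlas_opts()) {
  phase <- match.arg(phase)
  stopifnot(inherits(library, "reference_library"))
  entries <- Filter(function(e) e$phase == phase, library$entries)
  if (!length(entries)) stop("library has no entries for phase ", phase, call. = FALSE)
  tgt <- preprocess(frame)
  spacing <- library$pixel_spacing * 2
  results <- lapply(entries, function(e) {
    r <- register_affine(preprocess(e$frame), preprocess_mask(e$mask), tgt,
                         spacing = spacing, opts = opts)
    r$id <- e$id
    r
  })
  pm <- fuse_top_k(results, opts$k)
  mask <- threshold_map(pm, opts$threshold)
  attr(mask, "pixel_spacing") <- spacing
  list(mask = mask, prob_map = pm, registrations = results)
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A∩B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b Binary matrices of identical shape.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must share a shape", call. = FALSE)
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}
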