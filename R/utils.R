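# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so generators are pure functions
#' of their seed argument.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name), call. = FALSE)
  invisible(x)
}

#' Block-mean downsample by an integer factor, cropping trailing rows/cols
#' @noRd
block_mean <- function(x, f) {
  if (f == 1L) return(x)
  nr <- (nrow(x) %/% f) * f
  nc <- (ncol(x) %/% f) * f
  x <- x[seq_len(nr), seq_len(nc), drop = FALSE]
  # average f x f blocks via row then column group means
  xr <- rowsum(x, rep(seq_len(nr %/% f), each = f)) / f
  t(rowsum(t(xr), rep(seq_len(nc %/% f), each = f)) / f)
}

#' Bilinear sampling of a matrix at fractional (row, col) positions
#'
#' Positions outside the grid return `fill`.
#' @noRd
bilinear_sample <- function(img, r, c, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(fill, length(r))
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc & is.finite(r) & is.finite(c)
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  v <- img[i00] * (1 - fr) * (1 - fc) + img[i10] * fr * (1 - fc) +
    img[i01] * (1 - fr) * fc + img[i11] * fr * fc
  out[ok] <- v
  out
}

#' Nearest-neighbour sampling (label-preserving)
#' @noRd
nearest_sample <- function(img, r, c, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(fill, length(r))
  ri <- round(r); ci <- round(c)
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc & is.finite(ri) & is.finite(ci)
  if (any(ok)) out[ok] <- img[cbind(ri[ok], ci[ok])]
  out
}

#' Polygon area by the shoelace formula (absolute value)
#' @noRd
shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Test whether a closed polygon is simple (no self-intersections)
#'
#' O(n^2) segment pair test; adequate for contours of a few hundred vertices.
#' @noRd
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(FALSE)
  p1 <- xy
  p2 <- xy[c(2:n, 1L), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    # skip adjacent edges (shared endpoint)
    js <- js[js != i + 1L & !(i == 1L & js == n)]
    if (!length(js)) next
    d1 <- cross(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p1[js, 1], p1[js, 2])
    d2 <- cross(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p2[js, 1], p2[js, 2])
    d3 <- cross(p1[js, 1], p1[js, 2], p2[js, 1], p2[js, 2], rep(p1[i, 1], length(js)), rep(p1[i, 2], length(js)))
    d4 <- cross(p1[js, 1], p1[js, 2], p2[js, 1], p2[js, 2], rep(p2[i, 1], length(js)), rep(p2[i, 2], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

#' Keep the largest 4-connected foreground component of a binary matrix
#' @noRd
largest_component4 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) <= 1L) return(mask)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)  # ties: lowest label (raster order) - deterministic
  (lab == keep) * 1
}

#' Fill interior holes (background regions not reachable from the border)
#' @noRd
fill_holes4 <- function(mask) {
  as.numeric(EBImage::fillHull(mask)) |> matrix(nrow(mask), ncol(mask))
}

#' Plateau-safe local extrema of a 1-D signal
#'
#' Returns the first index of every strict local maximum/minimum run.
#' Endpoints are not extrema.
#' @noRd
local_extrema <- function(y) {
  r <- rle(y)
  k <- length(r$values)
  if (k < 3L) return(list(max = integer(0), min = integer(0)))
  starts <- cumsum(c(1L, r$lengths[-k]))
  mx <- integer(0); mn <- integer(0)
  for (i in 2:(k - 1L)) {
    if (r$values[i] > r$values[i - 1L] && r$values[i] > r$values[i + 1L])
      mx <- c(mx, starts[i])
    if (r$values[i] < r$values[i - 1L] && r$values[i] < r$values[i + 1L])
      mn <- c(mn, starts[i])
  }
  list(max = mx, min = mn)
}
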