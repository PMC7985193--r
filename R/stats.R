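# validation_stats: the statistics used to qualify the segmentation tool -
# Pearson r^2 between methods/analysts, triplicate coefficients of
# variation, within-subjects t-tests, and seeded leave-n-out Dice
# experiments against a reference library.

#' Pearson regression report
#'
#' Bivariate Pearson correlation with r^2 expressed as a percent and a
#' two-sided p-value from the t transform with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, non-zero variance.
#' @return An object of class `regression_report`: `r`, `r_squared` (%),
#'   `p_value`, `n`.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), r_squared = 100 * unname(ct$estimate)^2,
                 p_value = ct$p.value, n = length(x)),
            class = "regression_report")
}

#' Coefficient of variation, percent
#'
#' `100 * sd / mean` with the sample (n - 1) standard deviation - the
#' repeatability measure applied to triplicate segmentations of the same
#' image.
#'
#' @param values Numeric vector, n >= 2, non-zero mean.
#' @return CV, percent.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2L) stop("need >= 2 replicate values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("zero mean: CV undefined", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Paired (within-subjects) t-test on coefficient-of-variation lists
#'
#' @param cv_a,cv_b Paired numeric vectors (e.g. per-endpoint CVs under two
#'   segmentation methods), equal length, n >= 2.
#' @return List with `t`, `p` (two-sided, df = n - 1), `df`, and
#'   `exact_tie = TRUE` in place of t/p when all differences are zero.
#' @export
paired_t <- function(cv_a, cv_b) {
  if (length(cv_a) != length(cv_b)) stop("paired lists must have equal length", call. = FALSE)
  if (length(cv_a) < 2L) stop("need n >= 2 pairs", call. = FALSE)
  d <- cv_a - cv_b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(exact_tie = TRUE, t = NA_real_, p = NA_real_,
                                 df = length(d) - 1L))
    stop("zero variance of non-zero differences: t undefined", call. = FALSE)
  }
  tt <- stats::t.test(cv_a, cv_b, paired = TRUE)
  list(exact_tie = FALSE, t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Leave-n-out Dice experiment on a reference library
#'
#' Randomly splits the library's phantoms into atlas and test sets (seeded,
#' reproducible), segments each held-out ED and ES frame against the
#' remaining atlas with [segment_frame()], and scores each result against
#' the held-out ground-truth mask with [dice()] (truth downsampled to the
#' analysis grid by the same block rule the segmenter uses).
#'
#' @param library A [reference_library()] whose entry ids follow the
#'   `<phantom>_<phase>` convention of [make_library()].
#' @param n_test Number of phantoms held out (>= 1, < number of phantoms).
#' @param opts Segmentation options ([atlas_opts()]).
#' @param rng_seed Integer seed controlling the split.
#' @return List with `cases` (data frame: id, phase, dice), `mean`, `sd`,
#'   `range`, and the held-out/atlas phantom ids.
#' @export
leave_n_out_dice <- function(library, n_test = 5L, opts = atlas_opts(),
                             rng_seed = 1L) {
  stopifnot(inherits(library, "reference_library"))
  if (n_test < 1L) stop("n_test must be >= 1", call. = FALSE)
  ids <- vapply(library$entries, function(e) e$id, character(1))
  phantoms <- unique(sub("_(ED|ES)$", "", ids))
  if (length(phantoms) <= n_test)
    stop("library must hold more phantoms than n_test", call. = FALSE)
  test_ids <- with_seed(rng_seed, sort(sample(phantoms, n_test)))
  is_test <- sub("_(ED|ES)$", "", ids) %in% test_ids
  atlas <- reference_library(library$entries[!is_test], library$pixel_spacing)
  scores <- lapply(library$entries[is_test], function(e) {
    seg <- segment_frame(e$frame, atlas, phase = e$phase, opts = opts)
    truth <- preprocess_mask(e$mask)
    data.frame(id = e$id, phase = e$phase,
               dice = dice(seg$mask, truth), stringsAsFactors = FALSE)
  })
  cases <- do.call(rbind, scores)
  list(cases = cases, mean = mean(cases$dice), sd = stats::sd(cases$dice),
       range = range(cases$dice), test_phantoms = test_ids,
       atlas_phantoms = setdiff(phantoms, test_ids))
}
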