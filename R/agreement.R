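#' Bland-Altman agreement between two measurement series
#'
#' Computes the mean bias and 95% limits of agreement between paired
#' measurements: differences `d = b - a`, `bias = mean(d)`, limits
#' `bias +/- 1.96 * sd(d)` (sample SD). Per-pair means are returned for
#' plotting difference-vs-mean.
#'
#' @param a,b numeric series of equal length (>= 2), paired.
#' @return object of class `agreement_result` with `bias`, `loa_low`,
#'   `loa_high`, `n`, and the per-pair `means` and `diffs`.
#' @examples
#' bland_altman(c(1, 2, 3), c(2, 3, 4))
#' @export
bland_altman <- function(a, b) {
  check_pairs(a, b, min_n = 2L)
  d <- b - a
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias,
                 loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s,
                 sd_diff = s, n = length(d),
                 means = (a + b) / 2, diffs = d),
            class = "agreement_result")
}

#' Regression agreement between two measurement series
#'
#' Ordinary least squares of `b` on `a` plus Pearson correlation on the same
#' pairs. Perfect method agreement gives slope 1, intercept 0, r 1.
#'
#' @param a,b numeric series of equal length (>= 3); `a` must not be
#'   constant.
#' @return object of class `agreement_result` with `slope`, `intercept`,
#'   `pearson_r`, `n`.
#' @examples
#' regression_agreement(1:10, 2 * (1:10) + 1)
#' @export
regression_agreement <- function(a, b) {
  check_pairs(a, b, min_n = 3L)
  if (stats::sd(a) == 0)
    stop("degenerate input: series a is constant; slope undefined",
         call. = FALSE)
  fit <- stats::lm(b ~ a)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 pearson_r = stats::cor(a, b),
                 n = length(a)),
            class = "agreement_result")
}

check_pairs <- function(a, b, min_n) {
  if (length(a) != length(b))
    stop("input error: series lengths differ (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  if (length(a) < min_n)
    stop("input error: need at least ", min_n, " pairs", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("input error: non-finite values in series", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("agreement_result (n =", x$n, ")\n")
  if (!is.null(x$bias))
    cat(sprintf("  Bland-Altman bias %.6g, limits [%.6g, %.6g]\n",
                x$bias, x$loa_low, x$loa_high))
  if (!is.null(x$slope))
    cat(sprintf("  regression slope %.6g, intercept %.6g, Pearson r %.6g\n",
                x$slope, x$intercept, x$pearson_r))
  invisible(x)
}

#' Per-analyst deviance from a reference series
#'
#' Aligns each analyst's per-slice measurements to a reference series and
#' summarizes the per-slice differences (analyst - reference) per analyst as
#' median, quartiles, and range — the box-plot view of inter-reader
#' variability. The reference defaults to the across-analyst mean at each
#' slice; alternatively a designated (expert) analyst can serve as reference.
#'
#' @param analysts named list; each element a numeric vector of per-slice
#'   measurements named by slice index.
#' @param reference `"mean"` (default), the name of an analyst in
#'   `analysts`, or a numeric vector named by slice index.
#' @return data frame with one row per analyst: `analyst, n, median, q1, q3,
#'   min, max` of the per-slice deviations.
#' @export
analyst_deviance <- function(analysts, reference = "mean") {
  stopifnot(is.list(analysts), length(analysts) >= 1L,
            !is.null(names(analysts)))
  analysts <- lapply(analysts, function(x) {
    if (is.null(names(x)))
      stop("input error: analyst series must be named by slice index",
           call. = FALSE)
    x
  })
  slices <- Reduce(intersect, lapply(analysts, names))
  if (length(slices) == 0L)
    stop("input error: analysts share no overlapping slices", call. = FALSE)
  mat <- vapply(analysts, function(x) x[slices], numeric(length(slices)))
  mat <- matrix(mat, nrow = length(slices),
                dimnames = list(slices, names(analysts)))
  ref <- if (identical(reference, "mean")) {
    rowMeans(mat)
  } else if (is.character(reference) && reference %in% names(analysts)) {
    mat[, reference]
  } else if (is.numeric(reference)) {
    if (is.null(names(reference)) || !all(slices %in% names(reference)))
      stop("input error: numeric reference must cover all shared slices",
           call. = FALSE)
    reference[slices]
  } else {
    stop("input error: unknown reference '", reference, "'", call. = FALSE)
  }
  dev <- mat - ref
  out <- data.frame(
    analyst = colnames(mat),
    n = length(slices),
    median = apply(dev, 2L, stats::median),
    q1 = apply(dev, 2L, stats::quantile, probs = 0.25, names = FALSE),
    q3 = apply(dev, 2L, stats::quantile, probs = 0.75, names = FALSE),
    min = apply(dev, 2L, min),
    max = apply(dev, 2L, max),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "deviations") <- dev
  out
}
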