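#' @title Method-agreement statistics for paired SUVR measurements
#' @description The statistical battery for comparing two SUVR
#'   quantification methods on the same subjects: ordinary least squares
#'   regression of the test method on the reference method (slope,
#'   intercept, R-squared), the two-way mixed-effects single-measure
#'   consistency intraclass correlation ICC(3,1), and Bland-Altman bias
#'   with 95% limits of agreement.
#' @name agreement
NULL

#' Paired measurements of one region by two methods
#'
#' @param subject_ids character vector
#' @param x reference-method SUVRs
#' @param y test-method SUVRs
#' @param region composite VOI name
#' @return A `pn_paired` object.
#' @export
paired_measurements <- function(subject_ids, x, y, region = "region") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) != length(subject_ids))
    stop("subject_ids, x and y must have equal length")
  if (length(x) < 3) stop("at least 3 paired measurements required")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0))
    stop("all SUVR values must be finite and positive")
  structure(list(subject_ids = as.character(subject_ids), x = x, y = y,
                 region = region),
            class = "pn_paired")
}

#' Ordinary least squares regression of y on x
#'
#' @param pairs a `pn_paired`
#' @return list with `slope`, `intercept`, `r_squared` (squared Pearson
#'   correlation) and `n`.
#' @export
pearson_regression <- function(pairs) {
  stopifnot(inherits(pairs, "pn_paired"))
  if (stats::var(pairs$x) == 0) stop("zero variance in x: slope undefined")
  fit <- stats::lm(y ~ x, data = list(x = pairs$x, y = pairs$y))
  r <- stats::cor(pairs$x, pairs$y)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r^2, n = length(pairs$x))
}

#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed-effects, single-measure, consistency ICC between the two
#' methods, computed from the two-way ANOVA mean squares:
#' `(MS_subjects - MS_error) / (MS_subjects + (k-1) MS_error)` with k = 2
#' raters. Consistency ICC ignores a fixed offset between methods.
#'
#' @param pairs a `pn_paired`
#' @return list with `icc` and `model` descriptor.
#' @export
icc_consistency <- function(pairs) {
  stopifnot(inherits(pairs, "pn_paired"))
  dat <- rbind(pairs$x, pairs$y)  # k x n: raters in rows
  k <- 2L; n <- length(pairs$x)
  if (stats::sd(dat) == 0) stop("degenerate data: all values identical")
  grand <- mean(dat)
  subj_means <- colMeans(dat)
  rater_means <- rowMeans(dat)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_rater <- n * sum((rater_means - grand)^2)
  ss_total <- sum((dat - grand)^2)
  ss_err <- ss_total - ss_subj - ss_rater
  ms_subj <- ss_subj / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  list(icc = (ms_subj - ms_err) / (ms_subj + (k - 1) * ms_err),
       model = "two-way mixed, single measure, consistency (ICC(3,1))")
}

#' Bland-Altman analysis
#'
#' Differences `d = y - x`; bias is their mean, limits of agreement are
#' `bias +/- 1.96 * SD(d)` with the sample (n-1) standard deviation.
#'
#' @param pairs a `pn_paired` (or any list with `x` and `y` of length
#'   at least 2)
#' @return list with `bias`, `sd_diff`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(pairs) {
  d <- pairs$y - pairs$x
  if (length(d) < 2) stop("Bland-Altman requires at least 2 pairs")
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  list(bias = bias, sd_diff = sd_diff,
       loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
       n = length(d))
}

#' Per-region agreement table between two sets of SUVR reports
#'
#' Joins the two collections by subject and region and runs regression,
#' ICC(3,1) and Bland-Altman per region. Regions with fewer than 3 common
#' subjects are flagged and carry NA statistics.
#'
#' @param reports_x reference-method reports: list of `pn_suvr_report` or a
#'   long-format data.frame from [suvr_table()]
#' @param reports_y test-method reports, same formats
#' @return data.frame with one row per region: n, slope, intercept,
#'   r_squared, icc, bias, loa_low, loa_high, flagged.
#' @export
compare_methods <- function(reports_x, reports_y) {
  tx <- if (is.data.frame(reports_x)) reports_x else suvr_table(reports_x)
  ty <- if (is.data.frame(reports_y)) reports_y else suvr_table(reports_y)
  merged <- merge(tx[c("subject_id", "region", "suvr")],
                  ty[c("subject_id", "region", "suvr")],
                  by = c("subject_id", "region"), suffixes = c("_x", "_y"))
  if (nrow(merged) == 0) stop("no common subject/region pairs")
  regions <- intersect(COMPOSITE_NAMES, unique(merged$region))
  if (length(regions) == 0) regions <- sort(unique(merged$region))
  rows <- lapply(regions, function(rg) {
    d <- merged[merged$region == rg, ]
    base <- data.frame(region = rg, n = nrow(d), slope = NA_real_,
                       intercept = NA_real_, r_squared = NA_real_,
                       icc = NA_real_, bias = NA_real_, loa_low = NA_real_,
                       loa_high = NA_real_, flagged = TRUE)
    if (nrow(d) < 3) return(base)
    pr <- paired_measurements(d$subject_id, d$suvr_x, d$suvr_y, region = rg)
    reg <- pearson_regression(pr)
    icc <- icc_consistency(pr)
    ba <- bland_altman(pr)
    data.frame(region = rg, n = reg$n, slope = reg$slope,
               intercept = reg$intercept, r_squared = reg$r_squared,
               icc = icc$icc, bias = ba$bias, loa_low = ba$loa_low,
               loa_high = ba$loa_high, flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
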