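#' Validation statistics for joint-angle traces
#'
#' Three families of statistics quantify how trustworthy the wearable
#' pipeline is: repeatability of the joint angles across repeated functional
#' calibrations applied to the same trial (offset and precision), waveform
#' similarity across those repetitions (coefficient of multiple
#' correlation), and sample-by-sample agreement with a reference system
#' (accuracy = mean error, precision = SD of error, Pearson correlation).
#' Statistics that are undefined on degenerate input (zero variance) carry
#' an explicit `defined` flag instead of silently propagating NaN.
#'
#' @name validate-stats
NULL

#' Repeatability of a joint angle across repeated calibrations
#'
#' Given the same trial processed with F different functional calibrations:
#' the average curve over calibrations is subtracted from each curve; per
#' calibration the difference series is summarised by its mean and SD over
#' time; the repeatability offset is the mean absolute deviation of those
#' means and the precision the mean of the SDs.
#'
#' @param curves numeric T x F matrix (or list of equal-length vectors):
#'   one angle series per calibration, degrees, time-aligned.
#' @return list with `offset` (deg), `precision` (deg) and `per_calibration`
#'   (data.frame of the per-calibration mean and SD).
#' @export
repeatability <- function(curves) {
  m <- if (is.list(curves)) {
    len <- lengths(curves)
    if (length(unique(len)) != 1L) stop("curves must have equal length")
    do.call(cbind, curves)
  } else as.matrix(curves)
  if (ncol(m) < 2L) stop("repeatability needs at least 2 calibrations")
  avg <- rowMeans(m)
  d <- m - avg
  mu <- colMeans(d)
  sdv <- apply(d, 2L, stats::sd)
  list(offset = mean(abs(mu)), precision = mean(sdv),
       per_calibration = data.frame(calibration = seq_len(ncol(m)),
                                    mean_deg = mu, sd_deg = sdv))
}

#' Coefficient of multiple correlation (CMC)
#'
#' Waveform-similarity statistic for M repeated curves: one minus the ratio
#' of the between-curve variance about the pointwise mean curve to the total
#' variance about the grand mean, square-rooted:
#' \deqn{CMC = \sqrt{1 - \frac{\sum_{f,t} (Y_{ft} - \bar Y_t)^2 / (T(M-1))}
#'                        {\sum_{f,t} (Y_{ft} - \bar Y)^2 / (MT-1)}}}
#' Identical non-constant curves give 1; curves dominated by independent
#' noise give values near 0. When the total variance is (near) zero the
#' statistic is undefined and flagged as such; when the ratio exceeds 1
#' (curves more dissimilar than the grand-mean model) the square root is
#' imaginary and also reported as undefined.
#'
#' @param curves numeric T x M matrix (or list of equal-length vectors).
#' @return list with `value` (NA when undefined), `defined` (logical) and
#'   `reason` (character, empty when defined).
#' @export
cmc <- function(curves) {
  m <- if (is.list(curves)) {
    len <- lengths(curves)
    if (length(unique(len)) != 1L) stop("curves must have equal length")
    do.call(cbind, curves)
  } else as.matrix(curves)
  M <- ncol(m); T_ <- nrow(m)
  if (M < 2L) stop("CMC needs at least 2 curves")
  ybar_t <- rowMeans(m)
  ybar <- mean(m)
  within <- sum((m - ybar_t)^2) / (T_ * (M - 1))
  total <- sum((m - ybar)^2) / (M * T_ - 1)
  if (total < 1e-12) {
    return(list(value = NA_real_, defined = FALSE,
                reason = "total variance ~ 0 (constant curves)"))
  }
  ratio <- within / total
  if (ratio > 1) {
    return(list(value = NA_real_, defined = FALSE,
                reason = "within-curve variance exceeds total (CMC imaginary)"))
  }
  list(value = sqrt(1 - ratio), defined = TRUE, reason = "")
}

#' Accuracy, precision and correlation against a reference
#'
#' Sample-by-sample error `e(t) = wearable(t) - reference(t)`; accuracy is
#' its mean over time, precision its standard deviation, and the
#' relationship between the two systems is Pearson's correlation.
#'
#' @param wearable,reference numeric angle series, degrees, synchronised
#'   and at the same rate (resample the wearable first if needed).
#' @return list with `accuracy` (deg), `precision` (deg), `correlation`,
#'   `correlation_defined` (FALSE when either series is constant).
#' @export
error_metrics <- function(wearable, reference) {
  if (length(wearable) != length(reference)) {
    stop("wearable and reference series differ in length")
  }
  e <- wearable - reference
  corr_def <- stats::sd(wearable) > 1e-12 && stats::sd(reference) > 1e-12
  list(accuracy = mean(e), precision = stats::sd(e),
       correlation = if (corr_def) stats::cor(wearable, reference) else NA_real_,
       correlation_defined = corr_def)
}
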