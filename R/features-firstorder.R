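#' First-order intensity statistics (18 features)
#'
#' The 18 canonical first-order features. All are computed from the raw
#' (normalized, undiscretized) ROI intensities except entropy and
#' uniformity, which use the discretized gray-level histogram. Moment-based
#' features use the population (1/N) convention; skewness and kurtosis are
#' the standardized third and fourth moments (kurtosis is not
#' excess-corrected). Percentiles use linear interpolation.
#'
#' @param raw_roi_values Numeric vector of raw ROI intensities.
#' @param discretized_roi A `discretized_roi` from [fbs_discretize()] (or an
#'   integer vector of bin indices) over the same pixels.
#' @param pixel_area_mm2 Pixel area used by total energy (default 1).
#' @return Named numeric vector of 18 values (names `firstorder.*`), with a
#'   `"degenerate"` attribute naming flagged features (skewness/kurtosis on
#'   a zero-variance ROI).
#' @export
first_order_features <- function(raw_roi_values, discretized_roi,
                                 pixel_area_mm2 = 1) {
  x <- as.numeric(raw_roi_values)
  if (length(x) == 0L) stop("ROI is empty", call. = FALSE)
  d <- if (inherits(discretized_roi, "discretized_roi")) discretized_roi$values
       else as.integer(discretized_roi)
  n <- length(x)
  p <- as.vector(table(d)) / n
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  degenerate <- character(0)
  if (m2 > 0) {
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2
  } else {
    skew <- 0
    kurt <- 0
    degenerate <- c("firstorder.Skewness", "firstorder.Kurtosis")
  }
  q <- stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  inner <- x[x >= q[1] & x <= q[5]]
  out <- c(
    "firstorder.Energy" = sum(x^2),
    "firstorder.TotalEnergy" = pixel_area_mm2 * sum(x^2),
    "firstorder.Entropy" = -sum(p[p > 0] * log2(p[p > 0])),
    "firstorder.Minimum" = min(x),
    "firstorder.10Percentile" = q[1],
    "firstorder.90Percentile" = q[5],
    "firstorder.Maximum" = max(x),
    "firstorder.Mean" = mu,
    "firstorder.Median" = q[3],
    "firstorder.InterquartileRange" = q[4] - q[2],
    "firstorder.Range" = max(x) - min(x),
    "firstorder.MeanAbsoluteDeviation" = mean(abs(x - mu)),
    "firstorder.RobustMeanAbsoluteDeviation" = mean(abs(inner - mean(inner))),
    "firstorder.RootMeanSquared" = sqrt(mean(x^2)),
    "firstorder.Skewness" = skew,
    "firstorder.Kurtosis" = kurt,
    "firstorder.Variance" = m2,
    "firstorder.Uniformity" = sum(p^2)
  )
  attr(out, "degenerate") <- degenerate
  out
}
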