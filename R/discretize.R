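#' Cohort-derived fixed-bin-size discretization scheme
#'
#' The bin width is tied to the cohort rather than to one image: each
#' image's whole-image gray-level range (max - min) is computed under the
#' normalization arm being processed, the ranges are averaged, and the bin
#' width is `W = range_mean / n_bins`. This keeps a given bin count
#' comparable across normalization arms whose absolute scales differ.
#'
#' @param cohort_images List of numeric matrices (already normalized under
#'   the arm in question).
#' @param n_bins Number of gray levels (>= 2).
#' @param ranges Optional precomputed per-image ranges (overrides
#'   `cohort_images`).
#' @return A `discretization_scheme`: list(n_bins, range_mean, bin_width).
#' @export
cohort_bin_width <- function(cohort_images, n_bins, ranges = NULL) {
  stopifnot(n_bins >= 2)
  if (is.null(ranges)) {
    stopifnot(length(cohort_images) >= 1L)
    ranges <- vapply(cohort_images,
                     function(im) diff(range(as.vector(im))), numeric(1))
  }
  if (any(ranges <= 0)) {
    stop("constant image in cohort: gray-level range is zero", call. = FALSE)
  }
  range_mean <- mean(ranges)
  structure(list(n_bins = as.integer(n_bins), range_mean = range_mean,
                 bin_width = range_mean / n_bins),
            class = "discretization_scheme")
}

#' Fixed-bin-size gray-level discretization
#'
#' Maps ROI intensities to positive integer bin indices with bins of width
#' `W` anchored so the minimum discretized level is always 1:
#' `floor(x / W) - floor(min(x) / W) + 1`, the minimum taken over the ROI
#' being discretized.
#'
#' @param roi_values Numeric vector of ROI intensities (nonempty).
#' @param scheme A `discretization_scheme` from [cohort_bin_width()], or any
#'   list with a positive `bin_width`.
#' @return A `discretized_roi`: list(values = integer bin indices,
#'   n_levels_observed, scheme).
#' @export
fbs_discretize <- function(roi_values, scheme) {
  if (length(roi_values) == 0L) stop("ROI is empty", call. = FALSE)
  w <- scheme$bin_width
  if (is.null(w) || !is.finite(w) || w <= 0) {
    stop("bin width must be > 0", call. = FALSE)
  }
  v <- as.integer(floor(roi_values / w) - floor(min(roi_values) / w) + 1)
  structure(list(values = v, n_levels_observed = length(unique(v)),
                 scheme = scheme),
            class = "discretized_roi")
}
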