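#' Z-score intensity normalization
#'
#' Normalizes a qualitative MR image by the mean and standard deviation of
#' the entire image (background included): `(X - mu) / sigma`.
#'
#' @param image Numeric matrix.
#' @return Matrix of the same shape with mean 0 and SD 1; the `"spacing"`
#'   attribute is preserved.
#' @export
zscore_normalize <- function(image) {
  if (length(image) == 0L) stop("image is empty", call. = FALSE)
  mu <- mean(image)
  sigma <- stats::sd(as.vector(image))
  if (!is.finite(sigma) || sigma == 0) {
    stop("degenerate normalization: image standard deviation is zero", call. = FALSE)
  }
  out <- (image - mu) / sigma
  attr(out, "spacing") <- attr(image, "spacing")
  out
}

#' Reference-tissue intensity normalization
#'
#' Affinely maps the whole image so that the reference region (here the
#' psoas muscle, hypointense on T2-weighted images) has mean 100 and
#' standard deviation 10: `X' = 10 (X - mu_ref) / sigma_ref + 100`.
#'
#' @param image Numeric matrix.
#' @param reference_mask Logical matrix congruent with `image`.
#' @param target_mean,target_sd Target moments of the reference region.
#' @return Normalized matrix; `"spacing"` preserved.
#' @export
reference_normalize <- function(image, reference_mask,
                                target_mean = 100, target_sd = 10) {
  stop_if_not_congruent(image, reference_mask, "image and reference mask")
  vals <- image[reference_mask]
  if (length(vals) == 0L) stop("reference mask is empty", call. = FALSE)
  mu <- mean(vals)
  sigma <- stats::sd(vals)
  if (!is.finite(sigma) || sigma == 0) {
    stop("degenerate normalization: reference region standard deviation is zero",
         call. = FALSE)
  }
  out <- target_sd * (image - mu) / sigma + target_mean
  attr(out, "spacing") <- attr(image, "spacing")
  out
}

## Nearest-neighbor source indices for a resized axis, pixel-center
## alignment; exact half-way ties go to the lower source index.
nn_index <- function(n_out, n_src, scale) {
  p <- (seq_len(n_out) - 0.5) * scale   # output centers in source pixel units
  pmin(pmax(ceiling(p), 1L), n_src)
}

#' Resize an image or mask to a square matrix
#'
#' Nearest-neighbor interpolation with pixel-center alignment; the pixel
#' spacing is rescaled so the physical extent is preserved. Masks keep their
#' label set because no averaging occurs.
#'
#' @param x Matrix (numeric image or logical/binary mask).
#' @param target_px Output side length in pixels.
#' @param is_mask Unused for the resampling itself (nearest neighbor is used
#'   for everything); kept to make call sites self-documenting.
#' @return `target_px` x `target_px` matrix with updated `"spacing"`.
#' @export
resize_to_matrix <- function(x, target_px, is_mask = FALSE) {
  stopifnot(target_px > 0)
  target_px <- as.integer(target_px)
  nr <- nrow(x); nc <- ncol(x)
  ri <- nn_index(target_px, nr, nr / target_px)
  ci <- nn_index(target_px, nc, nc / target_px)
  out <- x[ri, ci, drop = FALSE]
  sp <- attr(x, "spacing")
  if (!is.null(sp)) attr(out, "spacing") <- sp[[1L]] * nr / target_px
  out
}

#' Resample an image or mask to a target pixel spacing
#'
#' Nearest-neighbor resampling onto a grid of `round(extent / target)` pixels
#' per axis; the output carries the target spacing. Requires spacing
#' metadata on `x` (the `"spacing"` attribute, mm).
#'
#' @param x Matrix with a `"spacing"` attribute.
#' @param target_spacing_mm Target pixel size in mm.
#' @param is_mask See [resize_to_matrix()].
#' @return Resampled matrix with `"spacing" = target_spacing_mm`.
#' @export
resample_to_spacing <- function(x, target_spacing_mm, is_mask = FALSE) {
  sp <- pixel_spacing(x)
  stopifnot(target_spacing_mm > 0)
  n_out_r <- max(1L, as.integer(round(nrow(x) * sp / target_spacing_mm)))
  n_out_c <- max(1L, as.integer(round(ncol(x) * sp / target_spacing_mm)))
  ri <- nn_index(n_out_r, nrow(x), target_spacing_mm / sp)
  ci <- nn_index(n_out_c, ncol(x), target_spacing_mm / sp)
  out <- x[ri, ci, drop = FALSE]
  attr(out, "spacing") <- target_spacing_mm
  out
}

#' Noncystic parenchyma mask
#'
#' Set difference kidney minus cysts: the noncystic kidney parenchyma, the
#' tissue of interest once hyperintense cysts are excluded.
#'
#' @param kidney_mask,cyst_mask Congruent logical matrices.
#' @return Logical matrix `kidney_mask & !cyst_mask`; errors if empty.
#' @export
noncystic_mask <- function(kidney_mask, cyst_mask) {
  stop_if_not_congruent(kidney_mask, cyst_mask)
  out <- kidney_mask & !cyst_mask
  if (!any(out)) stop("noncystic ROI is empty: cysts cover the whole kidney",
                      call. = FALSE)
  out
}

#' The preprocessing design grid
#'
#' @param normalizations Normalization arms, subset of
#'   c("original", "zscore", "reference").
#' @param resamplings Pixel-resampling schemes, subset of
#'   c("up_1.0mm", "down_2.0mm").
#' @param n_gray_levels Gray-level counts for fixed-bin-size discretization.
#' @return Data frame with one row per (normalization, resampling,
#'   n_gray_levels) cell.
#' @export
preprocess_settings <- function(normalizations = c("original", "zscore", "reference"),
                                resamplings = c("up_1.0mm", "down_2.0mm"),
                                n_gray_levels = c(8L, 16L, 32L, 64L, 128L, 256L)) {
  normalizations <- match.arg(normalizations,
                              c("original", "zscore", "reference"),
                              several.ok = TRUE)
  resamplings <- match.arg(resamplings, c("up_1.0mm", "down_2.0mm"),
                           several.ok = TRUE)
  stopifnot(all(n_gray_levels >= 2))
  expand.grid(normalization = normalizations, resampling = resamplings,
              n_gray_levels = as.integer(n_gray_levels),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

resampling_target_mm <- function(resampling) {
  switch(resampling,
         "up_1.0mm" = 1.0,
         "down_2.0mm" = 2.0,
         stop(sprintf("unknown resampling scheme '%s'", resampling), call. = FALSE))
}

#' Apply one preprocessing arm to a phantom case
#'
#' Pipeline order: intensity normalization on the native image (reference
#' statistics from the native-resolution psoas mask), then resize to
#' `target_matrix` (256 by default), then resample to the scheme's pixel
#' spacing. Masks always use nearest-neighbor.
#'
#' @param case A `phantom_case`.
#' @param normalization One of "original", "zscore", "reference".
#' @param resampling One of "up_1.0mm", "down_2.0mm".
#' @param target_matrix Matrix size for the resize step.
#' @return List with preprocessed `image`, `kidney_mask`, `cyst_mask`,
#'   `psoas_mask` (all congruent, spacing = scheme target) and the arm labels.
#' @export
apply_preprocessing <- function(case, normalization, resampling,
                                target_matrix = 256L) {
  img <- switch(normalization,
                original = case$image,
                zscore = zscore_normalize(case$image),
                reference = reference_normalize(case$image, case$psoas_mask),
                stop(sprintf("unknown normalization '%s'", normalization),
                     call. = FALSE))
  img <- set_spacing(img, pixel_spacing(case$image))
  tgt <- resampling_target_mm(resampling)
  sp <- pixel_spacing(case$image)
  step <- function(m, is_mask) {
    m <- set_spacing(m, sp)
    m <- resize_to_matrix(m, target_matrix, is_mask = is_mask)
    resample_to_spacing(m, tgt, is_mask = is_mask)
  }
  list(image = step(img, FALSE),
       kidney_mask = step(case$kidney_mask, TRUE),
       cyst_mask = step(case$cyst_mask, TRUE),
       psoas_mask = step(case$psoas_mask, TRUE),
       normalization = normalization, resampling = resampling)
}
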