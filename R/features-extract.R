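glcm_names <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
                "ClusterTendency", "Contrast", "Correlation",
                "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
                "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
                "JointAverage", "JointEnergy", "JointEntropy", "MCC",
                "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares")
glrlm_names <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                 "GrayLevelVariance", "HighGrayLevelRunEmphasis",
                 "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
                 "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
                 "RunEntropy", "RunLengthNonUniformity",
                 "RunLengthNonUniformityNormalized", "RunPercentage",
                 "RunVariance", "ShortRunEmphasis",
                 "ShortRunHighGrayLevelEmphasis", "ShortRunLowGrayLevelEmphasis")
glszm_names <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                 "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
                 "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
                 "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
                 "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                 "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
                 "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy",
                 "ZonePercentage", "ZoneVariance")
ngtdm_names <- c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
gldm_names <- c("DependenceEntropy", "DependenceNonUniformity",
                "DependenceNonUniformityNormalized", "DependenceVariance",
                "GrayLevelNonUniformity", "GrayLevelVariance",
                "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
                "LargeDependenceHighGrayLevelEmphasis",
                "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
                "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
                "SmallDependenceLowGrayLevelEmphasis")
firstorder_names <- c("Energy", "TotalEnergy", "Entropy", "Minimum",
                      "10Percentile", "90Percentile", "Maximum", "Mean",
                      "Median", "InterquartileRange", "Range",
                      "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
                      "RootMeanSquared", "Skewness", "Kurtosis", "Variance",
                      "Uniformity")

#' The 93-feature panel manifest
#'
#' Names and family membership of the fixed 2D feature panel: first-order
#' (18), GLCM (24), GLRLM (16), GLSZM (16), NGTDM (5), GLDM (14).
#'
#' @return Data frame with columns `family`, `feature`, `name` (93 rows);
#'   `name` is `family.feature` and is the column naming used in all
#'   feature tables.
#' @export
feature_name_manifest <- function() {
  fam <- list(firstorder = firstorder_names, glcm = glcm_names,
              glrlm = glrlm_names, glszm = glszm_names,
              ngtdm = ngtdm_names, gldm = gldm_names)
  out <- do.call(rbind, lapply(names(fam), function(f) {
    data.frame(family = f, feature = fam[[f]],
               name = paste0(f, ".", fam[[f]]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Extract the 93-feature vector for one ROI of one case
#'
#' Runs the full per-ROI extraction: picks the ROI (noncystic parenchyma =
#' kidney minus cysts, or the entire kidney), discretizes it with the
#' cohort-level fixed-bin-size scheme, and evaluates all six feature
#' families. First-order features (except entropy/uniformity) use the raw
#' normalized intensities; all texture families use the discretized grid
#' masked to the ROI, ignoring out-of-mask neighbors.
#'
#' @param preprocessed Output of [apply_preprocessing()] (image + masks).
#' @param roi_kind `"noncystic"` or `"entire_kidney"`.
#' @param scheme A `discretization_scheme` for the arm being processed.
#' @return Named numeric vector of exactly 93 features, ordered as in
#'   [feature_name_manifest()], with a `"degenerate"` attribute listing
#'   flagged features.
#' @export
extract_feature_vector <- function(preprocessed, roi_kind = c("noncystic", "entire_kidney"),
                                   scheme) {
  roi_kind <- match.arg(roi_kind)
  roi <- if (roi_kind == "noncystic") {
    noncystic_mask(preprocessed$kidney_mask, preprocessed$cyst_mask)
  } else {
    preprocessed$kidney_mask
  }
  if (!any(roi)) stop("ROI has no pixels", call. = FALSE)
  img <- preprocessed$image
  raw <- img[roi]
  disc <- fbs_discretize(raw, scheme)
  grid <- matrix(NA_integer_, nrow(img), ncol(img))
  grid[roi] <- disc$values
  sp <- pixel_spacing(img)
  fo <- first_order_features(raw, disc, pixel_area_mm2 = sp^2)
  out <- c(fo, glcm_features(grid), glrlm_features(grid), glszm_features(grid),
           ngtdm_features(grid), gldm_features(grid))
  expected <- feature_name_manifest()$name
  stopifnot(identical(sort(names(out)), sort(expected)))
  out <- out[expected]
  attr(out, "degenerate") <- attr(fo, "degenerate")
  out
}
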