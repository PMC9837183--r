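#' Radiomics extraction settings
#'
#' Defaults follow the reference configuration used throughout the package:
#' fixed bin width 0.005 (in the package's ADC unit convention of
#' 10^-3 mm^2/s), voxel array shift 1 applied to the energy-type first-order
#' features, neighbourhood distance 1 with 3D direction-averaged
#' aggregation, and dependence threshold alpha = 0.
#'
#' @param bin_width Fixed bin width for gray-level discretization, > 0.
#' @param voxel_array_shift Intensity offset added before computing energy,
#'   total energy and root-mean-squared.
#' @param distance Neighbourhood distance in voxels (texture matrices).
#' @param alpha Gray-level dependence threshold.
#' @return A `radiomics_config` list.
#' @export
radiomics_config <- function(bin_width = 0.005, voxel_array_shift = 1,
                             distance = 1, alpha = 0) {
  stopifnot_scalar_number(bin_width, "bin_width", 0, strict = TRUE)
  structure(list(bin_width = bin_width, voxel_array_shift = voxel_array_shift,
                 distance = as.integer(distance), alpha = alpha),
            class = "radiomics_config")
}

#' Discretize ROI intensities with a fixed bin width
#'
#' Gray level of a voxel with value v is `floor((v - min) / bin_width) + 1`,
#' anchored at the ROI minimum, so adding a constant to all intensities
#' leaves the levels unchanged.
#'
#' @param volume Numeric 3D array.
#' @param mask Binary 3D array or `seg_mask` of the same shape.
#' @param bin_width Bin width, > 0.
#' @param spacing Voxel spacing (mm).
#' @return A `discretized_roi`: list with `gray` (integer array, 0 outside
#'   the ROI), `Ng`, `values` (original ROI intensities), `mask` (logical
#'   array), `spacing`.
#' @export
discretize <- function(volume, mask, bin_width = 0.005, spacing = c(1, 1, 1)) {
  vox <- if (inherits(mask, "seg_mask")) mask$voxels else mask
  if (inherits(mask, "seg_mask")) spacing <- mask$spacing
  if (!identical(dim(volume), dim(vox))) abort("Volume and mask shapes differ.")
  if (!is_binary_array(vox)) abort("`mask` must be binary.")
  idx <- which(vox == 1)
  if (length(idx) == 0) abort("Mask is empty; nothing to discretize.")
  stopifnot_scalar_number(bin_width, "bin_width", 0, strict = TRUE)
  vals <- volume[idx]
  # small epsilon absorbs floating-point error at exact bin edges
  lev <- as.integer(floor((vals - min(vals)) / bin_width + 1e-9)) + 1L
  gray <- array(0L, dim(volume))
  gray[idx] <- lev
  structure(list(gray = gray, Ng = max(lev), values = vals,
                 mask = array(vox == 1, dim(vox)), spacing = as.numeric(spacing)),
            class = "discretized_roi")
}

# -- feature name manifest ---------------------------------------------------

.fo_names <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
  "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange", "Range",
  "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation", "RootMeanSquared",
  "Skewness", "Kurtosis", "Variance", "Uniformity")

.shape_names <- c(
  "MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
  "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
  "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "MajorAxisLength",
  "MinorAxisLength", "LeastAxisLength", "Elongation", "Flatness")

.glcm_names <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy",
  "MaximumProbability", "MCC", "SumAverage", "SumEntropy", "SumSquares")

.glrlm_names <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
  "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis")

.glszm_names <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
  "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "ZoneEntropy", "ZonePercentage", "ZoneVariance")

.ngtdm_names <- c("Busyness", "Coarseness", "Complexity", "Contrast",
                  "Strength")

.gldm_names <- c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis")

#' The frozen 107-feature manifest
#'
#' 18 first-order, 14 shape, 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM and 14
#' GLDM features, in the fixed order produced by [extract_all()].
#'
#' @return Tibble with columns `family`, `feature`.
#' @export
feature_manifest <- function() {
  tibble::tibble(
    family = rep(c("firstorder", "shape", "glcm", "glrlm", "glszm", "ngtdm",
                   "gldm"),
                 c(length(.fo_names), length(.shape_names), length(.glcm_names),
                   length(.glrlm_names), length(.glszm_names),
                   length(.ngtdm_names), length(.gldm_names))),
    feature = c(.fo_names, .shape_names, .glcm_names, .glrlm_names,
                .glszm_names, .ngtdm_names, .gldm_names)
  )
}

#' Extract the full 107-feature radiomics vector of one ROI
#'
#' Computes first-order statistics on the raw ROI intensities, shape
#' descriptors on the mask geometry, and the five texture families on the
#' fixed-bin-width discretized gray levels, all in 3D.
#'
#' @param volume Intensity array (here: an ADC map).
#' @param mask Binary array or `seg_mask` defining the ROI (non-empty).
#' @param spacing Voxel spacing in mm (taken from `mask` if it is a
#'   `seg_mask`).
#' @param config A [radiomics_config()].
#' @return Tibble with columns `family`, `feature`, `value` (107 rows, in
#'   manifest order).
#' @export
extract_all <- function(volume, mask, spacing = c(1, 1, 1),
                        config = radiomics_config()) {
  vox <- if (inherits(mask, "seg_mask")) mask$voxels else mask
  if (inherits(mask, "seg_mask")) spacing <- mask$spacing
  d <- discretize(volume, vox, config$bin_width, spacing)
  out <- c(
    first_order_features(d$values, shift = config$voxel_array_shift,
                         bin_width = config$bin_width, spacing = spacing),
    shape_features(vox, spacing),
    glcm_features(d, config),
    glrlm_features(d, config),
    glszm_features(d, config),
    ngtdm_features(d, config),
    gldm_features(d, config)
  )
  man <- feature_manifest()
  if (!identical(names(out), man$feature)) {
    abort("Internal error: extracted feature names do not match the manifest.")
  }
  tibble::tibble(family = man$family, feature = man$feature,
                 value = unname(out))
}
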