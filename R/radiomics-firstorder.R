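#' First-order intensity statistics (18 features)
#'
#' Standard histogram and moment statistics of the raw ROI intensities.
#' `Entropy` and `Uniformity` are computed on the fixed-bin-width
#' discretized histogram; `Energy`, `TotalEnergy` and `RootMeanSquared`
#' apply the voxel array shift `c`: Energy = sum((x + c)^2). Skewness uses
#' the population moment ratio m3 / m2^(3/2) and Kurtosis the (non-excess)
#' ratio m4 / m2^2; both are defined as 0 for a constant ROI. Percentiles
#' use linear interpolation.
#'
#' @param values Numeric vector of ROI intensities (>= 1 voxel).
#' @param shift Voxel array shift `c` (default 1).
#' @param bin_width Bin width of the entropy/uniformity histogram.
#' @param spacing Voxel spacing in mm (for TotalEnergy).
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(values, shift = 1, bin_width = 0.005,
                                 spacing = c(1, 1, 1)) {
  if (length(values) == 0) abort("Empty ROI.")
  n <- length(values)
  vv <- prod(spacing)
  xs <- values + shift
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  lev <- floor((values - min(values)) / bin_width + 1e-9)
  p <- as.numeric(table(lev)) / n
  pr <- quantile(values, c(0.1, 0.25, 0.75, 0.9), type = 7, names = FALSE)
  robust <- values[values >= pr[1] & values <= pr[4]]
  c(
    Energy = sum(xs^2),
    TotalEnergy = vv * sum(xs^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(values),
    "10Percentile" = pr[1],
    "90Percentile" = pr[4],
    Maximum = max(values),
    Mean = m,
    Median = median(values),
    InterquartileRange = pr[3] - pr[2],
    Range = max(values) - min(values),
    MeanAbsoluteDeviation = mean(abs(values - m)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(xs^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2)
  )
}
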