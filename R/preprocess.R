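#' Resize a 2D slice to the model grid
#'
#' Intensity slices are interpolated bilinearly; masks are resampled with
#' nearest-neighbour interpolation so the output stays strictly binary.
#' Non-square inputs are resized anisotropically (no padding).
#'
#' @param image 2D numeric matrix, at least 8x8.
#' @param size Output side length in pixels (default 128).
#' @param is_mask Set `TRUE` for binary masks.
#' @return A `size` x `size` matrix.
#' @export
resize_to_model_grid <- function(image, size = 128, is_mask = FALSE) {
  if (!is.matrix(image) || any(dim(image) < 8)) {
    abort("`image` must be a matrix with both dimensions >= 8.")
  }
  if (is_mask && !is_binary_array(image)) {
    abort("`image` flagged as mask but contains values outside {0, 1}.")
  }
  if (all(dim(image) == size) && is_mask) {
    return(matrix(as.numeric(image), size, size))
  }
  out <- EBImage::resize(image, w = size, h = size,
                         filter = if (is_mask) "none" else "bilinear")
  out <- matrix(as.numeric(out), size, size)
  if (is_mask) out <- round(out)
  out
}

#' Normalize signal intensities of a volume
#'
#' Applies `(SI - mean_SI) / (divisor * SD_SI)` over the whole volume, the
#' standard-score normalization with an extra divisor (default 12) that
#' compresses intensities to a narrow range around zero. The statistics are
#' computed per volume (one acquisition of one patient).
#'
#' @param volume Numeric array (any shape).
#' @param divisor Dimensionless scaling constant, > 0 (default 12).
#' @return List with `volume` (normalized array) and `stats`, a
#'   `norm_stats` object holding `mean_si`, `sd_si`, `divisor`.
#' @export
normalize_intensity <- function(volume, divisor = 12) {
  stopifnot_scalar_number(divisor, "divisor", 0, strict = TRUE)
  mean_si <- mean(volume)
  sd_si <- sd(as.numeric(volume))
  if (!is.finite(sd_si) || sd_si == 0) {
    abort("Volume is constant (SD of signal intensity is zero); cannot normalize.")
  }
  stats <- structure(
    list(mean_si = mean_si, sd_si = sd_si, divisor = divisor),
    class = "norm_stats"
  )
  list(volume = (volume - mean_si) / (divisor * sd_si), stats = stats)
}

#' Invert [normalize_intensity()]
#'
#' @param volume Normalized array.
#' @param stats `norm_stats` returned by [normalize_intensity()].
#' @return Array on the original intensity scale.
#' @export
denormalize_intensity <- function(volume, stats) {
  if (!inherits(stats, "norm_stats")) abort("`stats` must be a norm_stats object.")
  volume * (stats$divisor * stats$sd_si) + stats$mean_si
}

#' Assemble normalized three-channel model input for a case
#'
#' In `multi` mode the three sequences are placed in channel order
#' (b0, b1000, ADC), each normalized independently; in a single-sequence
#' mode the chosen normalized sequence is replicated into all three
#' channels. Slices are resized to `size` x `size`.
#'
#' @param case A `patient_case`.
#' @param channel_mode One of `"multi"`, `"b0"`, `"b1000"`, `"adc"`.
#' @param size Model grid side length (default 128).
#' @param divisor Normalization divisor (default 12).
#' @return A `channel_stack`: array of dim (size, size, 3, n_slices) with
#'   attributes `case_id` and `channel_mode`.
#' @export
assemble_channels <- function(case, channel_mode = c("multi", "b0", "b1000", "adc"),
                              size = 128, divisor = 12) {
  channel_mode <- match.arg(channel_mode)
  needed <- if (channel_mode == "multi") c("b0", "b1000", "adc") else channel_mode
  for (nm in needed) {
    if (is.null(case[[nm]])) {
      abort(sprintf("Case `%s` is missing the `%s` sequence.", case$case_id, nm))
    }
  }
  norm_resized <- function(vol) {
    nv <- normalize_intensity(vol, divisor)$volume
    nz <- dim(nv)[3]
    out <- array(0, c(size, size, nz))
    for (z in seq_len(nz)) out[, , z] <- resize_to_model_grid(nv[, , z], size)
    out
  }
  nz <- dim(case$b0)[3]
  stack <- array(0, c(size, size, 3, nz))
  if (channel_mode == "multi") {
    chans <- lapply(c("b0", "b1000", "adc"), function(nm) norm_resized(case[[nm]]))
    for (k in 1:3) stack[, , k, ] <- chans[[k]]
  } else {
    one <- norm_resized(case[[channel_mode]])
    for (k in 1:3) stack[, , k, ] <- one
  }
  structure(stack, case_id = case$case_id, channel_mode = channel_mode,
            class = c("channel_stack", "array"))
}

# Reference mask resampled to the model grid (nearest neighbour, stays binary).
mask_to_model_grid <- function(mask, size = 128) {
  vox <- if (inherits(mask, "seg_mask")) mask$voxels else mask
  d <- dim(vox)
  out <- array(0L, c(size, size, d[3]))
  for (z in seq_len(d[3])) {
    out[, , z] <- as.integer(resize_to_model_grid(vox[, , z], size, is_mask = TRUE))
  }
  out
}
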