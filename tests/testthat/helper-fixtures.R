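# Shared fixtures: deterministic small phantoms and the frozen-oracle ROI.

noiseless_tissue <- function() {
  list(
    background = tissue_params(300, 1.5),
    wall = tissue_params(500, 1.8),
    urine = tissue_params(1000, 3.0),
    tumor = tissue_params(600, 0.9)
  )
}

small_case <- function(seed = 1, noise_sigma = 40, n_tumors = 1,
                       shape = c(64, 64, 8), tissue = default_tissue_set()) {
  synthesize_case(shape = shape, tissue = tissue, noise_sigma = noise_sigma,
                  n_tumors = n_tumors, seed = seed)
}

oracle_roi <- function() {
  roi <- utils::read.csv(test_path("fixtures", "oracle_roi.csv"))
  d <- c(14L, 13L, 8L)
  vol <- array(0, d)
  msk <- array(0L, d)
  vol[cbind(roi$x, roi$y, roi$z)] <- roi$value
  msk[cbind(roi$x, roi$y, roi$z)] <- 1L
  list(volume = vol, mask = msk, spacing = c(1.2, 1.5, 3.0))
}

# A tiny discretized ROI built from an explicit level array.
tiny_droi <- function(levels, spacing = c(1, 1, 1)) {
  arr <- array(as.integer(levels), dim = dim(levels) %||% c(length(levels), 1, 1))
  if (length(dim(arr)) != 3) dim(arr) <- c(dim(arr), 1)
  mask <- arr > 0
  vals <- as.numeric(arr[mask])
  structure(list(gray = arr, Ng = max(arr), values = vals, mask = mask,
                 spacing = spacing),
            class = "discretized_roi")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
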