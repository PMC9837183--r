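#' Tissue signal parameters for the mono-exponential DWI model
#'
#' Each tissue compartment of a phantom is described by the baseline signal
#' `s0_mean` (arbitrary units, the b = 0 intensity) and its apparent
#' diffusion coefficient `adc_mean`, stored throughout the package in units
#' of 10^-3 mm^2/s (typical clinical values 0.5--3.0). The diffusion signal
#' at b = 1000 s/mm^2 follows the mono-exponential decay
#' S(b) = S0 * exp(-b * ADC), which with this unit convention reduces to
#' `s0_mean * exp(-adc_mean)`. `s0_sd` and `adc_sd` give within-tissue
#' voxel-to-voxel variability.
#'
#' @param s0_mean Baseline (b = 0) signal, > 0.
#' @param adc_mean ADC in 10^-3 mm^2/s, > 0.
#' @param s0_sd,adc_sd Within-tissue standard deviations, >= 0.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(s0_mean, adc_mean, s0_sd = 0, adc_sd = 0) {
  stopifnot_scalar_number(s0_mean, "s0_mean", 0, strict = TRUE)
  stopifnot_scalar_number(adc_mean, "adc_mean", 0, strict = TRUE)
  stopifnot_scalar_number(s0_sd, "s0_sd", 0)
  stopifnot_scalar_number(adc_sd, "adc_sd", 0)
  structure(
    list(s0_mean = s0_mean, adc_mean = adc_mean,
         s0_sd = s0_sd, adc_sd = adc_sd),
    class = "tissue_params"
  )
}

# Predicted noiseless b = 1000 signal of a tissue.
b1000_signal <- function(tp) tp$s0_mean * exp(-tp$adc_mean)

#' Default tissue compartments of the bladder phantom
#'
#' Background pelvic tissue, bladder wall, urine and tumor, with contrasts
#' that mirror clinical diffusion-weighted bladder imaging: urine has high
#' b0/ADC and near-zero b1000 signal, tumor shows diffusion restriction
#' (low ADC, hence high residual b1000 signal).
#'
#' @param variability Multiplier applied to the default within-tissue
#'   standard deviations (0 gives perfectly homogeneous tissues).
#' @return Named list of [tissue_params()]: background, wall, urine, tumor.
#' @export
default_tissue_set <- function(variability = 1) {
  list(
    background = tissue_params(300, 1.5, 25 * variability, 0.12 * variability),
    wall = tissue_params(500, 1.8, 30 * variability, 0.12 * variability),
    urine = tissue_params(1000, 3.0, 40 * variability, 0.10 * variability),
    tumor = tissue_params(600, 0.9, 30 * variability, 0.10 * variability)
  )
}

#' Tissue set in which the tumor is only separable by combining channels
#'
#' Used for input-mode ablation experiments: the bladder wall shares the
#' tumor's b0 intensity, and two decoy tissues (placed as tumor-like blobs in
#' the background) share its b1000 and ADC values respectively, so that no
#' single channel separates tumor from all confounders, while the
#' three-channel combination does.
#'
#' @param variability As in [default_tissue_set()].
#' @return Named list with compartments background, wall, urine, tumor and a
#'   `decoys` list of two [tissue_params()].
#' @export
confusable_tissue_set <- function(variability = 1) {
  sdv <- function(s, a) tissue_params(s, a, 20 * variability, 0.08 * variability)
  list(
    background = sdv(150, 0.8),
    wall = sdv(500, 1.7),       # b0 identical to tumor
    urine = sdv(1000, 3.0),
    tumor = sdv(500, 1.0),      # b1000 = 500*exp(-1) = 183.9
    decoys = list(
      sdv(304, 0.5),            # b1000 = 184.4, mimics tumor on b1000
      sdv(250, 1.0)             # ADC identical to tumor
    )
  )
}

#' Construct a binary segmentation mask
#'
#' @param voxels Binary 3D array.
#' @param spacing Voxel spacing (dx, dy, dz) in mm.
#' @return A `seg_mask` object.
#' @export
new_seg_mask <- function(voxels, spacing) {
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, spacing = as.numeric(spacing)),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %s voxels on %s grid, spacing (%s) mm\n",
              sum(x$voxels), paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = ", ")))
  invisible(x)
}

# Logical ellipsoid on an (nx, ny, nz) grid.
ellipsoid_mask <- function(shape, center, semi) {
  x <- seq_len(shape[1]); y <- seq_len(shape[2]); z <- seq_len(shape[3])
  dx2 <- ((x - center[1]) / semi[1])^2
  dy2 <- ((y - center[2]) / semi[2])^2
  dz2 <- ((z - center[3]) / semi[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

rician_noise <- function(signal, sigma) {
  if (sigma == 0) return(signal)
  n <- length(signal)
  sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

#' Synthesize one bladder DWI phantom case
#'
#' Builds aligned b0, b1000 and ADC volumes plus a ground-truth tumor mask.
#' The bladder is an ellipsoid (wall shell around a urine-filled lumen);
#' tumors are randomized ellipsoids attached to the interior of the bladder
#' wall, protruding into the lumen. Noiseless signals obey the
#' mono-exponential law S(b) = S0 exp(-b ADC); the returned ADC channel is
#' recomputed as log(b0/b1000) from the noiseless signals so it is exactly
#' consistent with that law. Magnitude (Rician) noise is then applied to the
#' b0 and b1000 channels.
#'
#' @param shape Grid dimensions (nx, ny, nz); in-plane dims must lie in
#'   64--192.
#' @param tissue Named list with compartments `background`, `wall`, `urine`,
#'   `tumor` (see [default_tissue_set()]) and optionally `decoys`.
#' @param noise_sigma Noise standard deviation in signal units (default 40,
#'   which puts the tumor/urine b1000 contrast-to-noise near 5 for the
#'   default tissues).
#' @param n_tumors Number of disconnected tumors (>= 1).
#' @param seed Integer seed; output is fully deterministic given it.
#' @param spacing Voxel spacing (dx, dy, dz) in mm.
#' @param noise_model `"rician"` (magnitude MRI, default) or `"gaussian"`.
#' @param tumor_semi_range In-plane tumor semi-axis range, voxels.
#' @param n_decoys Number of tumor-like decoy blobs placed in the
#'   background (requires `tissue$decoys`).
#' @param partial_volume_sigma In-plane Gaussian sigma (voxels) applied to
#'   the S0/ADC parameter fields before the signals are formed, emulating
#'   partial-volume averaging at tissue boundaries. 0 (default) keeps
#'   boundaries sharp so noiseless signals match the decay law exactly.
#' @param tumor_gradient_range Range of the per-tumor internal ADC slope
#'   (10^-3 mm^2/s from core to rim); `c(0, 0)` (default) keeps tumors
#'   internally homogeneous.
#' @param case_id Optional case identifier.
#' @return A `patient_case`: list with `case_id`, volumes `b0`, `b1000`,
#'   `adc`, `spacing`, `reference_mask` ([new_seg_mask] object), `age`,
#'   `muscle_invasion`.
#' @export
synthesize_case <- function(shape = c(128, 128, 16),
                            tissue = default_tissue_set(),
                            noise_sigma = 40,
                            n_tumors = 1,
                            seed = 1,
                            spacing = c(1.5, 1.5, 4),
                            noise_model = c("rician", "gaussian"),
                            tumor_semi_range = c(5, 11),
                            n_decoys = 0,
                            partial_volume_sigma = 0,
                            tumor_gradient_range = c(0, 0),
                            case_id = NULL) {
  noise_model <- match.arg(noise_model)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L)) {
    abort("`shape` must be three positive grid dimensions.")
  }
  if (any(shape[1:2] < 64L) || any(shape[1:2] > 192L)) {
    abort("In-plane dimensions must lie within 64-192 voxels.")
  }
  if (n_tumors < 1) abort("`n_tumors` must be >= 1.")
  stopifnot_scalar_number(noise_sigma, "noise_sigma", 0)
  if (any(spacing <= 0)) abort("`spacing` components must be > 0.")
  for (nm in c("background", "wall", "urine", "tumor")) {
    if (!inherits(tissue[[nm]], "tissue_params")) {
      abort(sprintf("`tissue$%s` must be a tissue_params object.", nm))
    }
  }
  if (tissue$tumor$adc_mean >= tissue$urine$adc_mean) {
    abort("Tumor ADC must be below urine ADC (diffusion restriction).")
  }
  if (b1000_signal(tissue$tumor) <= b1000_signal(tissue$urine)) {
    abort("Tumor b1000 signal must exceed urine b1000 signal.")
  }
  if (n_decoys > 0 && length(tissue$decoys %||% list()) == 0) {
    abort("`n_decoys` > 0 requires `tissue$decoys`.")
  }

  with_seed(seed, {
    nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
    center <- c(nx / 2 + runif(1, -2, 2), ny / 2 + runif(1, -2, 2),
                (nz + 1) / 2)
    outer_semi <- c(runif(1, 0.28, 0.34) * nx, runif(1, 0.28, 0.34) * ny,
                    max(2.5, 0.40 * nz))
    wall_t <- c(2, 2, 1)
    lumen_semi <- outer_semi - wall_t
    bladder <- ellipsoid_mask(shape, center, outer_semi)
    lumen <- ellipsoid_mask(shape, center, lumen_semi)
    wall <- bladder & !lumen

    t_semi <- matrix(0, n_tumors, 3)
    t_semi[, 1] <- runif(n_tumors, tumor_semi_range[1], tumor_semi_range[2])
    t_semi[, 2] <- runif(n_tumors, tumor_semi_range[1], tumor_semi_range[2])
    z_hi <- max(0.9, min(3.2, 0.35 * nz, 0.85 * lumen_semi[3]))
    t_semi[, 3] <- runif(n_tumors, min(1.2, 0.75 * z_hi), z_hi)
    if (any(t_semi[, 1] >= lumen_semi[1] | t_semi[, 2] >= lumen_semi[2] |
              t_semi[, 3] >= lumen_semi[3])) {
      abort("Tumor does not fit inside the bladder lumen; reduce tumor size.")
    }

    # attach tumors to the lumen/wall interface at well-separated angles
    place <- NULL
    for (attempt in seq_len(25)) {
      theta <- 2 * pi * (seq_len(n_tumors) - 1) / n_tumors +
        runif(1, 0, 2 * pi) + runif(n_tumors, 0, pi / (2 * n_tumors))
      zfrac <- runif(n_tumors, -0.3, 0.3)
      cx <- center[1] + lumen_semi[1] * cos(theta) * sqrt(1 - zfrac^2)
      cy <- center[2] + lumen_semi[2] * sin(theta) * sqrt(1 - zfrac^2)
      cz <- center[3] + lumen_semi[3] * zfrac
      centers <- cbind(cx, cy, cz)
      ok <- TRUE
      if (n_tumors > 1) {
        rmax <- apply(t_semi, 1, max)
        for (i in seq_len(n_tumors - 1)) {
          for (j in seq(i + 1, n_tumors)) {
            if (sqrt(sum((centers[i, ] - centers[j, ])^2)) <
                  rmax[i] + rmax[j] + 3) ok <- FALSE
          }
        }
      }
      if (ok) { place <- centers; break }
    }
    if (is.null(place)) {
      abort("Could not place the requested number of disconnected tumors.")
    }
    tumor <- array(FALSE, shape)
    for (i in seq_len(n_tumors)) {
      tumor <- tumor | (ellipsoid_mask(shape, place[i, ], t_semi[i, ]) & bladder)
    }
    if (sum(tumor) == 0) abort("Tumor placement produced an empty mask.")

    decoy_list <- vector("list", n_decoys)
    if (n_decoys > 0) {
      z_hi_d <- max(0.9, min(3.2, 0.35 * nz, 0.85 * lumen_semi[3]))
      dsem <- cbind(runif(n_decoys, tumor_semi_range[1], tumor_semi_range[2]),
                    runif(n_decoys, tumor_semi_range[1], tumor_semi_range[2]),
                    runif(n_decoys, min(1.2, 0.75 * z_hi_d), z_hi_d))
      phi <- 2 * pi * (seq_len(n_decoys) - 0.5) / n_decoys + runif(1, 0, 2 * pi)
      rad <- pmin(nx, ny) * 0.42
      for (i in seq_len(n_decoys)) {
        dc <- c(center[1] + rad * cos(phi[i]), center[2] + rad * sin(phi[i]),
                center[3] + runif(1, -0.2, 0.2) * nz)
        dc[1] <- min(max(dc[1], dsem[i, 1] + 2), nx - dsem[i, 1] - 1)
        dc[2] <- min(max(dc[2], dsem[i, 2] + 2), ny - dsem[i, 2] - 1)
        decoy_list[[i]] <- ellipsoid_mask(shape, dc, dsem[i, ]) & !bladder
      }
    }

    # compartment label: 1 bg, 2 wall, 3 urine, 4 tumor, 5.. decoys
    lab <- array(1L, shape)
    lab[wall] <- 2L
    lab[lumen] <- 3L
    lab[tumor] <- 4L
    if (n_decoys > 0) {
      for (i in seq_len(n_decoys)) lab[decoy_list[[i]]] <- 4L + i
    }
    comps <- list(tissue$background, tissue$wall, tissue$urine, tissue$tumor)
    if (n_decoys > 0) {
      for (i in seq_len(n_decoys)) {
        comps[[4L + i]] <- tissue$decoys[[((i - 1) %% length(tissue$decoys)) + 1]]
      }
    }

    nvox <- prod(shape)
    s0 <- numeric(nvox); adc <- numeric(nvox)
    for (k in seq_along(comps)) {
      idx <- which(lab == k)
      if (length(idx) == 0) next
      tp <- comps[[k]]
      s0[idx] <- tp$s0_mean + if (tp$s0_sd > 0) rnorm(length(idx), 0, tp$s0_sd) else 0
      adc[idx] <- tp$adc_mean + if (tp$adc_sd > 0) rnorm(length(idx), 0, tp$adc_sd) else 0
    }
    if (max(tumor_gradient_range) > 0) {
      # internal ADC gradient from tumor core to rim (per-patient
      # heterogeneity signature shared by any plausible ROI)
      for (i in seq_len(n_tumors)) {
        slope <- runif(1, tumor_gradient_range[1], tumor_gradient_range[2])
        tv <- which(lab == 4L)
        if (length(tv) > 0) {
          coords <- arrayInd(tv, shape)
          r <- sqrt(((coords[, 1] - place[i, 1]) / t_semi[i, 1])^2 +
                      ((coords[, 2] - place[i, 2]) / t_semi[i, 2])^2 +
                      ((coords[, 3] - place[i, 3]) / t_semi[i, 3])^2)
          near <- r <= 1.05
          adc[tv[near]] <- adc[tv[near]] + slope * (1 - pmin(r[near], 1))
        }
      }
    }
    if (partial_volume_sigma > 0) {
      s0_a <- array(s0, shape); adc_a <- array(adc, shape)
      for (z in seq_len(nz)) {
        s0_a[, , z] <- EBImage::gblur(s0_a[, , z], sigma = partial_volume_sigma)
        adc_a[, , z] <- EBImage::gblur(adc_a[, , z], sigma = partial_volume_sigma)
      }
      s0 <- as.numeric(s0_a); adc <- as.numeric(adc_a)
    }
    s0 <- pmax(s0, 1e-3)
    adc <- pmax(adc, 0.05)
    b0_clean <- s0
    b1000_clean <- s0 * exp(-adc)
    noisify <- if (noise_model == "rician") {
      function(x) rician_noise(x, noise_sigma)
    } else {
      function(x) x + if (noise_sigma > 0) rnorm(length(x), 0, noise_sigma) else 0
    }
    b0 <- array(noisify(b0_clean), shape)
    b1000 <- array(noisify(b1000_clean), shape)
    adc_map <- array(log(b0_clean / b1000_clean), shape)

    age <- round(min(max(rnorm(1, 73.6, 9.1), 47), 94))
    structure(
      list(
        case_id = case_id %||% sprintf("case_s%d", seed),
        b0 = b0, b1000 = b1000, adc = adc_map,
        spacing = as.numeric(spacing),
        reference_mask = new_seg_mask(array(as.integer(tumor), shape), spacing),
        age = age,
        muscle_invasion = runif(1) < 0.36
      ),
      class = "patient_case"
    )
  })
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf(
    "<patient_case> %s: %s grid, %d tumor voxel(s), age %d, %s\n",
    x$case_id, paste(dim(x$b0), collapse = "x"),
    sum(x$reference_mask$voxels), x$age,
    if (x$muscle_invasion) "MIBC" else "NMIBC"
  ))
  invisible(x)
}

#' Generate a cohort of phantom cases
#'
#' Per-case seeds are derived deterministically from the master seed. Tumor
#' multiplicity is sampled from `n_tumors_prob`, and tissue means receive
#' mild per-patient jitter (multiplicative on S0, additive on ADC) so the
#' cohort carries realistic between-patient feature variance.
#'
#' @param n_patients Number of cases (>= 1).
#' @param seed Master seed.
#' @param shape,tissue,noise_sigma,spacing,noise_model,tumor_semi_range,n_decoys
#'   Passed to [synthesize_case()].
#' @param n_tumors_prob Probabilities of 1, 2, ... tumors per case.
#' @param s0_jitter_cv Per-patient coefficient of variation of tissue S0
#'   means (0 disables jitter).
#' @param adc_jitter_sd Per-patient SD added to tissue ADC means.
#' @param sd_jitter_cv Log-scale SD of the per-patient multiplier applied
#'   to the within-tissue variabilities (`s0_sd`, `adc_sd`); tumors differ
#'   in heterogeneity across patients, which gives dispersion-type
#'   radiomics features genuine between-patient variance.
#' @param partial_volume_sigma Partial-volume blur of the parameter
#'   fields (voxels, in-plane); on by default for cohorts, see
#'   [synthesize_case()].
#' @param tumor_gradient_range Per-tumor internal ADC slope range; on by
#'   default for cohorts.
#' @return List of `patient_case` objects with unique `case_id`s.
#' @export
generate_cohort <- function(n_patients,
                            seed = 1,
                            shape = c(128, 128, 16),
                            tissue = default_tissue_set(),
                            noise_sigma = 40,
                            spacing = c(1.5, 1.5, 4),
                            noise_model = "rician",
                            tumor_semi_range = c(5, 11),
                            n_tumors_prob = c(0.85, 0.12, 0.03),
                            n_decoys = 0,
                            s0_jitter_cv = 0.06,
                            adc_jitter_sd = 0.08,
                            sd_jitter_cv = 0.4,
                            partial_volume_sigma = 0.7,
                            tumor_gradient_range = c(0.1, 0.45)) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    abort("`n_patients` must be >= 1.")
  }
  n_patients <- as.integer(n_patients)
  purrr::map(seq_len(n_patients), function(i) {
    meta_seed <- derive_seed(seed, 100000L + i)
    cfg <- with_seed(meta_seed, {
      nt <- sample.int(length(n_tumors_prob), 1, prob = n_tumors_prob)
      ts <- tissue
      jit <- function(tp) {
        s0 <- tp$s0_mean * exp(if (s0_jitter_cv > 0) rnorm(1, 0, s0_jitter_cv) else 0)
        adc <- max(tp$adc_mean + if (adc_jitter_sd > 0) rnorm(1, 0, adc_jitter_sd) else 0,
                   0.1)
        het <- exp(if (sd_jitter_cv > 0) rnorm(2, 0, sd_jitter_cv) else c(0, 0))
        tissue_params(s0, adc, tp$s0_sd * het[1], tp$adc_sd * het[2])
      }
      for (nm in c("background", "wall", "urine", "tumor")) ts[[nm]] <- jit(ts[[nm]])
      if (!is.null(ts$decoys)) ts$decoys <- lapply(ts$decoys, jit)
      # keep the diffusion-contrast invariants after jitter
      if (ts$tumor$adc_mean >= ts$urine$adc_mean - 0.3) {
        ts$tumor$adc_mean <- ts$urine$adc_mean - 0.3
      }
      list(nt = nt, ts = ts)
    })
    synthesize_case(
      shape = shape, tissue = cfg$ts, noise_sigma = noise_sigma,
      n_tumors = cfg$nt, seed = derive_seed(seed, i), spacing = spacing,
      noise_model = noise_model, tumor_semi_range = tumor_semi_range,
      n_decoys = n_decoys, partial_volume_sigma = partial_volume_sigma,
      tumor_gradient_range = tumor_gradient_range,
      case_id = sprintf("case_%04d", i)
    )
  })
}

#' Randomly perturb a segmentation mask
#'
#' Emulates the disagreement between a manual reference ROI and an automatic
#' segmentation: the mask boundary is moved by a smooth random field added to
#' its per-slice signed distance transform, after a small random in-plane
#' translation. The expected Dice overlap with the original decreases
#' monotonically as `magnitude` grows; `magnitude = 0` returns the input
#' unchanged.
#'
#' When `volume` is supplied the perturbation is intensity-coherent:
#' voxels added outside the reference ROI are kept only if their intensity
#' is plausible for it (within `affinity_mult` interquartile ranges of the
#' ROI median). Intensity-driven segmentation models err along intensity
#' boundaries, so their disagreement with a manual ROI rarely includes
#' drastically foreign tissue; a purely geometric perturbation does, which
#' destroys the high-tail and dispersion features that an automatic
#' segmentation would preserve.
#'
#' @param mask A `seg_mask` (or binary 3D array).
#' @param magnitude Perturbation scale in voxels, >= 0.
#' @param seed Integer seed.
#' @param field_sigma Gaussian smoothing sigma (voxels) of the boundary
#'   noise field.
#' @param volume Optional intensity volume (e.g. the ADC map) enabling the
#'   intensity-coherent mode.
#' @param affinity_mult IQR multiplier of the plausibility gate.
#' @return A perturbed `seg_mask` of the same shape.
#' @export
perturb_mask <- function(mask, magnitude, seed = 1, field_sigma = 2.5,
                         volume = NULL, affinity_mult = 2.5) {
  vox <- if (inherits(mask, "seg_mask")) mask$voxels else mask
  spacing <- if (inherits(mask, "seg_mask")) mask$spacing else c(1, 1, 1)
  if (!is_binary_array(vox)) abort("`mask` must be binary.")
  if (sum(vox) == 0) abort("Cannot perturb an empty mask: no boundary.")
  stopifnot_scalar_number(magnitude, "magnitude", 0)
  if (magnitude == 0) return(new_seg_mask(vox, spacing))
  d <- dim(vox)
  with_seed(seed, {
    dx <- round(rnorm(1, 0, magnitude / 4))
    dy <- round(rnorm(1, 0, magnitude / 4))
    shifted <- shift_array_3d(vox, dx, dy, 0)
    out <- array(0L, d)
    noise <- array(rnorm(prod(d)), d)
    for (z in seq_len(d[3])) {
      s <- shifted[, , z]
      dist_in <- EBImage::distmap(s)
      dist_out <- EBImage::distmap(1 - s)
      sdist <- as.numeric(dist_in) - as.numeric(dist_out)
      f <- EBImage::gblur(noise[, , z], sigma = field_sigma)
      f <- f / max(sd(f), 1e-12)
      out[, , z] <- as.integer(matrix(sdist, d[1], d[2]) + magnitude * f > 0)
    }
    if (!is.null(volume)) {
      ref_vals <- volume[vox == 1]
      med <- median(ref_vals)
      spread <- max(diff(q13(ref_vals)), 1e-6)
      added <- out == 1L & vox == 0L
      implausible <- added & abs(volume - med) > affinity_mult * spread
      out[implausible] <- 0L
    }
    new_seg_mask(out, spacing)
  })
}
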