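#' Configuration for the end-to-end pipeline
#'
#' Bundles the phantom, network, ensemble and radiomics settings with a
#' single master seed from which every stage derives its own stream. The
#' default profile is the desk-scale study: 50 phantoms (80% five-fold
#' cross-validation, 20% held-out test), 64 x 64 model grid, reduced U-Net.
#'
#' @param n_patients Cohort size.
#' @param test_fraction Held-out test fraction (patient-level split made
#'   before cross-validation).
#' @param shape,tissue,noise_sigma,spacing,n_decoys Phantom settings, see
#'   [synthesize_case()].
#' @param channel_mode Input mode for the network.
#' @param unet A [unet_config()] (its seed is overridden by `seed`).
#' @param vote_threshold Ensemble vote threshold (default 3 of 5).
#' @param radiomics A [radiomics_config()].
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_patients = 50, test_fraction = 0.2,
                            shape = c(64, 64, 8),
                            tissue = default_tissue_set(),
                            noise_sigma = 40,
                            spacing = c(1.5, 1.5, 4),
                            n_decoys = 0,
                            channel_mode = "multi",
                            unet = test_scale_config(input_size = shape[1]),
                            vote_threshold = 3,
                            radiomics = radiomics_config(),
                            seed = 1) {
  structure(
    list(n_patients = n_patients, test_fraction = test_fraction,
         shape = shape, tissue = tissue, noise_sigma = noise_sigma,
         spacing = spacing, n_decoys = n_decoys, channel_mode = channel_mode,
         unet = unet, vote_threshold = vote_threshold, radiomics = radiomics,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full phantom study
#'
#' Stages: cohort simulation, patient-level train/test split, five-fold
#' cross-validated U-Net training, majority-vote ensemble segmentation of
#' the held-out test cases, Dice evaluation, radiomics extraction on the
#' native ADC maps under both the manual (reference) and automatic
#' (ensemble) masks, and per-feature ICC(2,1) with per-family summaries.
#' Fully deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for NIfTI/CSV/YAML artifacts.
#' @param quiet Suppress progress messages.
#' @return A `pipeline_result` list: `cv` (per-fold DSC and models),
#'   `test_dsc` (a `dsc_report`), `features` (tidy table), `icc`
#'   (per-feature), `family_summary`, `excluded_cases`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = TRUE) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config.")
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  say("Simulating cohort of %d phantoms...", config$n_patients)
  cohort <- generate_cohort(
    config$n_patients, seed = derive_seed(config$seed, 1),
    shape = config$shape, tissue = config$tissue,
    noise_sigma = config$noise_sigma, spacing = config$spacing,
    n_decoys = config$n_decoys
  )
  ids <- vapply(cohort, `[[`, "", "case_id")
  n_test <- max(1L, round(config$n_patients * config$test_fraction))
  test_ids <- with_seed(derive_seed(config$seed, 2), sample(ids, n_test))
  train_cases <- cohort[!(ids %in% test_ids)]
  test_cases <- cohort[ids %in% test_ids]

  say("Cross-validating U-Net (%d train cases)...", length(train_cases))
  ucfg <- replace_seed(config$unet, derive_seed(config$seed, 3))
  cv <- cross_validate(train_cases, ucfg, channel_mode = config$channel_mode,
                       quiet = quiet)

  say("Ensemble-segmenting %d test cases...", length(test_cases))
  preds <- lapply(test_cases, function(cs) {
    ensemble_predict(cv$models, cs, channel_mode = config$channel_mode,
                     min_votes = config$vote_threshold, native = TRUE)
  })
  dsc <- vapply(seq_along(test_cases), function(i) {
    dice_coefficient(test_cases[[i]]$reference_mask, preds[[i]]$consensus)
  }, numeric(1))
  names(dsc) <- vapply(test_cases, `[[`, "", "case_id")
  test_report <- dsc_report(dsc, "test")

  say("Extracting radiomics (manual and automatic masks)...")
  excluded <- character(0)
  feats <- purrr::map_dfr(seq_along(test_cases), function(i) {
    cs <- test_cases[[i]]
    auto <- preds[[i]]$consensus
    if (sum(auto$voxels) == 0) {
      excluded <<- c(excluded, cs$case_id)
      return(NULL)
    }
    dplyr::bind_rows(
      extract_all(cs$adc, cs$reference_mask, config = config$radiomics) |>
        dplyr::mutate(case_id = cs$case_id, mask_source = "manual"),
      extract_all(cs$adc, auto, config = config$radiomics) |>
        dplyr::mutate(case_id = cs$case_id, mask_source = "auto")
    )
  })
  if (length(excluded) > 0) {
    warn(sprintf("Excluded %d case(s) with empty automatic mask: %s.",
                 length(excluded), paste(excluded, collapse = ", ")))
  }
  icc <- feature_icc(feats)
  fam <- feature_group_summary(icc)

  res <- structure(
    list(cv = cv, test_dsc = test_report, features = feats, icc = icc,
         family_summary = fam, excluded_cases = excluded, config = config),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    readr::write_csv(cv$per_fold, file.path(out_dir, "cv_dsc.csv"))
    readr::write_csv(tibble::as_tibble(test_report),
                     file.path(out_dir, "test_dsc.csv"))
    write_feature_table(feats, file.path(out_dir, "features.csv"))
    readr::write_csv(icc, file.path(out_dir, "icc.csv"))
    readr::write_csv(fam, file.path(out_dir, "icc_by_family.csv"))
    log <- list(seed = config$seed, n_patients = config$n_patients,
                test_ids = sort(test_ids), channel_mode = config$channel_mode,
                shape = config$shape,
                unet = unclass(config$unet),
                radiomics = unclass(config$radiomics),
                excluded_cases = excluded)
    yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  agg <- attr(x$test_dsc, "aggregate")
  cat(sprintf(
    "<pipeline_result> CV val DSC %.3f (%.3f-%.3f); test median DSC %.2f (IQR %.2f-%.2f)\n",
    x$cv$summary$mean_dsc, x$cv$summary$min_dsc, x$cv$summary$max_dsc,
    agg$median_dsc, agg$q1_dsc, agg$q3_dsc))
  print(x$family_summary)
  invisible(x)
}

#' Calibrate the mask-perturbation magnitude to a target Dice overlap
#'
#' Bisection on the perturbation magnitude so that the mean DSC between
#' original and perturbed reference masks over the cohort is close to
#' `target_dsc`.
#'
#' @param masks List of `seg_mask` objects.
#' @param target_dsc Target mean DSC (default 0.85).
#' @param seed Seed for the perturbation draws.
#' @param lower,upper Magnitude bracket.
#' @param iter Bisection iterations.
#' @param volumes Optional list of intensity volumes enabling the
#'   intensity-coherent perturbation mode (see [perturb_mask()]).
#' @return The calibrated magnitude.
#' @export
calibrate_perturbation <- function(masks, target_dsc = 0.85, seed = 1,
                                   lower = 0.05, upper = 10, iter = 10,
                                   volumes = NULL) {
  if (is.null(volumes)) volumes <- vector("list", length(masks))
  mean_dsc <- function(mag) {
    mean(vapply(seq_along(masks), function(i) {
      pm <- perturb_mask(masks[[i]], mag, seed = derive_seed(seed, i),
                         volume = volumes[[i]])
      dice_coefficient(masks[[i]], pm)
    }, numeric(1)))
  }
  lo <- lower; hi <- upper
  for (it in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (mean_dsc(mid) > target_dsc) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Mask-perturbation reproducibility experiment
#'
#' Training-free emulation of the manual-versus-automatic comparison:
#' features are extracted from each case's ADC map under the reference
#' mask and under randomly perturbed masks of increasing magnitude, and
#' per-feature ICC(2,1) is computed at each magnitude.
#'
#' @param cohort List of `patient_case` objects.
#' @param magnitudes Numeric vector of perturbation magnitudes.
#' @param config A [radiomics_config()].
#' @param seed Seed for the perturbation draws.
#' @return List with `icc` (tibble: magnitude, family, feature, icc, ...),
#'   `family_summary` (per magnitude), `mean_dsc` (tibble: magnitude,
#'   mean_dsc).
#' @export
reproducibility_experiment <- function(cohort, magnitudes,
                                       config = radiomics_config(),
                                       seed = 1) {
  manual <- purrr::map_dfr(cohort, function(cs) {
    extract_all(cs$adc, cs$reference_mask, config = config) |>
      dplyr::mutate(case_id = cs$case_id, mask_source = "manual")
  })
  res <- purrr::map(seq_along(magnitudes), function(mi) {
    mag <- magnitudes[mi]
    dscs <- numeric(length(cohort))
    auto <- purrr::map_dfr(seq_along(cohort), function(i) {
      cs <- cohort[[i]]
      pm <- perturb_mask(cs$reference_mask, mag,
                         seed = derive_seed(seed, mi * 10000L + i),
                         volume = cs$adc)
      dscs[i] <<- dice_coefficient(cs$reference_mask, pm)
      extract_all(cs$adc, pm, config = config) |>
        dplyr::mutate(case_id = cs$case_id, mask_source = "auto")
    })
    icc <- feature_icc(dplyr::bind_rows(manual, auto)) |>
      dplyr::mutate(magnitude = mag, .before = 1)
    list(icc = icc, mean_dsc = mean(dscs))
  })
  icc_all <- purrr::map_dfr(res, "icc")
  fam <- icc_all |>
    dplyr::group_by(.data$magnitude) |>
    dplyr::group_modify(~ feature_group_summary(.x)) |>
    dplyr::ungroup()
  list(
    icc = icc_all,
    family_summary = fam,
    mean_dsc = tibble::tibble(magnitude = magnitudes,
                              mean_dsc = vapply(res, `[[`, numeric(1),
                                                "mean_dsc"))
  )
}

#' Input-mode ablation on a channel-confusable phantom
#'
#' Trains one network per input mode (b0, b1000, ADC, multi) on a cohort
#' built from [confusable_tissue_set()], in which the bladder wall shares
#' the tumor's b0 intensity and two decoy blobs share its b1000 and ADC
#' intensities, so only the channel combination separates tumor from every
#' confounder. Reports mean volumetric validation DSC per mode.
#'
#' @param n_cases Cohort size (single train/validation split, 75/25).
#' @param unet A [unet_config()]; its seed is re-derived per mode and
#'   restart from `seed`.
#' @param seed Master seed.
#' @param shape,noise_sigma,spacing Phantom settings.
#' @param tumor_semi_range Tumor (and decoy) in-plane semi-axis range.
#' @param restarts Independent training restarts per mode; the model with
#'   the lowest final validation Dice loss is kept. The aliased task has
#'   sharp competing optima (a network can lock onto a decoy), so a
#'   single run of the reduced profile is high-variance for every mode.
#' @param quiet Suppress progress.
#' @return Tibble with columns `mode`, `val_dsc`.
#' @export
input_mode_experiment <- function(n_cases = 16,
                                  unet = test_scale_config(epochs = 40,
                                                           learning_rate = 0.01,
                                                           input_size = 32),
                                  seed = 1,
                                  shape = c(64, 64, 8),
                                  noise_sigma = 25,
                                  spacing = c(1.5, 1.5, 4),
                                  tumor_semi_range = c(8, 13),
                                  restarts = 2,
                                  quiet = TRUE) {
  # the engineered intensity coincidences of the confusable design must
  # survive cohort generation: no internal gradients or partial-volume
  # blur, and no heterogeneity jitter
  cohort <- generate_cohort(
    n_cases, seed = derive_seed(seed, 41), shape = shape,
    tissue = confusable_tissue_set(), noise_sigma = noise_sigma,
    spacing = spacing, n_decoys = 2, n_tumors_prob = 1,
    sd_jitter_cv = 0, partial_volume_sigma = 0,
    tumor_gradient_range = c(0, 0)
  )
  n_val <- max(2L, round(n_cases / 4))
  val <- cohort[seq_len(n_val)]
  tr <- cohort[-seq_len(n_val)]
  purrr::map_dfr(c("b0", "b1000", "adc", "multi"), function(mode) {
    fits <- lapply(seq_len(restarts), function(r) {
      cfg <- replace_seed(unet, derive_seed(seed, 43L + r))
      train_fold(NULL, tr, val, cfg, channel_mode = mode, quiet = quiet)
    })
    final_val <- vapply(fits, function(f) tail(f$history$val_loss, 1),
                        numeric(1))
    fit <- fits[[which.min(final_val)]]
    dsc <- mean(vapply(val, function(cs) {
      pred <- predict_mask(fit, assemble_channels(cs, mode,
                                                  fit$config$input_size))
      dice_coefficient(mask_to_model_grid(cs$reference_mask,
                                          fit$config$input_size),
                       pred$voxels)
    }, numeric(1)))
    if (!quiet) message(sprintf("mode %s: val DSC %.3f", mode, dsc))
    tibble::tibble(mode = mode, val_dsc = dsc)
  })
}
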