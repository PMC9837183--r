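test_that("noiseless tumor b1000 signal follows the mono-exponential decay exactly", {
  cs <- synthesize_case(shape = c(64, 64, 8), tissue = noiseless_tissue(),
                        noise_sigma = 0, seed = 7)
  tum <- cs$reference_mask$voxels == 1
  expect_true(sum(tum) > 0)
  expect_equal(unique(cs$b1000[tum]), 600 * exp(-0.9), tolerance = 1e-12)
  expect_equal(unique(cs$b0[tum]), 600)
})

test_that("ADC channel equals log(b0/b1000) of the noiseless signals", {
  # heterogeneous tissues (per-voxel S0/ADC variability) but no
  # measurement noise: the recomputed log-ratio must equal the ADC map.
  cs <- synthesize_case(shape = c(64, 64, 8), noise_sigma = 0, seed = 3)
  expect_equal(log(cs$b0 / cs$b1000), cs$adc, tolerance = 1e-9)
  expect_true(all(cs$adc >= 0))
  expect_true(all(cs$b0 > 0))
})

test_that("multiple non-overlapping tumors give the requested component count", {
  cs <- synthesize_case(shape = c(96, 96, 10), tissue = noiseless_tissue(),
                        noise_sigma = 0, n_tumors = 2, seed = 11)
  lab <- vesica:::label_components_3d(cs$reference_mask$voxels == 1)
  expect_identical(lab$n, 2L)
})

test_that("synthesis is deterministic given the seed", {
  a <- small_case(seed = 42)
  b <- small_case(seed = 42)
  expect_identical(a, b)
  c2 <- small_case(seed = 43)
  expect_false(identical(a$b0, c2$b0))
})

test_that("tissue and sizing validation errors are raised", {
  expect_error(tissue_params(-1, 1), "s0_mean")
  expect_error(tissue_params(10, 0), "adc_mean")
  bad <- noiseless_tissue()
  bad$tumor <- tissue_params(600, 3.5)  # no diffusion restriction
  expect_error(synthesize_case(tissue = bad, seed = 1), "urine ADC")
  expect_error(
    synthesize_case(shape = c(64, 64, 8), tumor_semi_range = c(30, 40),
                    seed = 1),
    "lumen"
  )
  expect_error(synthesize_case(shape = c(32, 32, 8)), "64-192")
})

test_that("cohorts have unique ids, are seed-reproducible, and match the single-case path", {
  co <- generate_cohort(6, seed = 9, shape = c(64, 64, 8))
  ids <- vapply(co, `[[`, "", "case_id")
  expect_identical(anyDuplicated(ids), 0L)
  co2 <- generate_cohort(6, seed = 9, shape = c(64, 64, 8))
  expect_identical(co, co2)

  one <- generate_cohort(1, seed = 5, shape = c(64, 64, 8),
                         n_tumors_prob = 1, s0_jitter_cv = 0,
                         adc_jitter_sd = 0, sd_jitter_cv = 0,
                         partial_volume_sigma = 0,
                         tumor_gradient_range = c(0, 0))
  direct <- synthesize_case(shape = c(64, 64, 8),
                            seed = vesica:::derive_seed(5, 1),
                            case_id = "case_0001")
  expect_equal(one[[1]][c("b0", "b1000", "adc")],
               direct[c("b0", "b1000", "adc")])
  expect_error(generate_cohort(0), "n_patients")
})

test_that("mask perturbation is identity at magnitude zero and degrades overlap monotonically", {
  cohort <- generate_cohort(10, seed = 21, shape = c(64, 64, 8))
  masks <- lapply(cohort, `[[`, "reference_mask")
  expect_identical(perturb_mask(masks[[1]], 0, seed = 1)$voxels,
                   masks[[1]]$voxels)
  mags <- c(0.5, 1, 2, 4)
  mean_dsc <- vapply(mags, function(m) {
    mean(vapply(seq_along(masks), function(i) {
      pm <- perturb_mask(masks[[i]], m, seed = 100 + i)
      expect_true(all(pm$voxels %in% c(0L, 1L)))
      expect_identical(dim(pm$voxels), dim(masks[[i]]$voxels))
      dice_coefficient(masks[[i]], pm)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_dsc) < 0))
  empty <- new_seg_mask(array(0L, c(8, 8, 3)), c(1, 1, 1))
  expect_error(perturb_mask(empty, 1), "empty")
})
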