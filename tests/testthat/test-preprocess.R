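test_that("resizing maps native slices to the model grid", {
  sl <- matrix(rnorm(192 * 128), 192, 128)
  out <- resize_to_model_grid(sl, 128)
  expect_identical(dim(out), c(128L, 128L))
  small <- resize_to_model_grid(sl, 64)
  expect_identical(dim(small), c(64L, 64L))

  same <- matrix(rnorm(128 * 128), 128, 128)
  expect_equal(resize_to_model_grid(same, 128), same, tolerance = 1e-6)

  mk <- matrix(rbinom(110 * 80, 1, 0.2), 110, 80)
  rmk <- resize_to_model_grid(mk, 128, is_mask = TRUE)
  expect_true(all(rmk %in% c(0, 1)))
  expect_error(resize_to_model_grid(matrix(1, 4, 4)), ">= 8")
  expect_error(resize_to_model_grid(matrix(2, 20, 20), is_mask = TRUE),
               "mask")
})

test_that("resizing twice to the same grid is idempotent within tolerance", {
  sl <- matrix(rnorm(100 * 90), 100, 90)
  once <- resize_to_model_grid(sl, 64)
  twice <- resize_to_model_grid(once, 64)
  expect_equal(twice, once, tolerance = 1e-6)
})

test_that("intensity normalization matches its closed form and is invertible", {
  vol <- array(rnorm(32 * 32 * 4, 500, 80), c(32, 32, 4))
  nr <- normalize_intensity(vol)
  st <- nr$stats
  expect_equal(mean(nr$volume), 0, tolerance = 1e-9)
  expect_equal(sd(as.numeric(nr$volume)), 1 / 12, tolerance = 1e-9)
  # a voxel at mean_SI maps to 0; at mean_SI + 12 SD_SI maps to 1
  probe <- array(c(st$mean_si, st$mean_si + 12 * st$sd_si,
                   rep(st$mean_si, 6)), c(2, 2, 2))
  np <- (probe - st$mean_si) / (12 * st$sd_si)
  expect_equal(np[1], 0)
  expect_equal(np[2], 1)
  # worked scalar example: SI 110, mean 100, SD 5 -> 10/60
  expect_equal((110 - 100) / (12 * 5), 1 / 6)
  back <- denormalize_intensity(nr$volume, st)
  expect_equal(back, vol, tolerance = 1e-9)
  expect_error(normalize_intensity(array(7, c(4, 4, 2))), "constant")
})

test_that("channel assembly replicates single sequences and orders multi channels", {
  cs <- small_case(seed = 2)
  single <- assemble_channels(cs, "b1000", size = 64)
  expect_identical(dim(unclass(single)), c(64L, 64L, 3L, 8L))
  expect_identical(single[, , 1, ], single[, , 2, ])
  expect_identical(single[, , 1, ], single[, , 3, ])

  multi <- assemble_channels(cs, "multi", size = 64)
  expect_false(identical(multi[, , 1, ], multi[, , 2, ]))
  # channel order (b0, b1000, adc): each channel equals the independently
  # normalized and resized volume
  nb0 <- normalize_intensity(cs$b0)$volume
  exp_c1 <- vapply(seq_len(dim(nb0)[3]), function(z) {
    resize_to_model_grid(nb0[, , z], 64)
  }, matrix(0, 64, 64))
  expect_equal(multi[, , 1, ], exp_c1, tolerance = 1e-12)
  expect_identical(attr(multi, "channel_mode"), "multi")

  cs$adc <- NULL
  expect_error(assemble_channels(cs, "multi", size = 64), "adc")
})

test_that("mask resampling to the model grid stays binary", {
  cs <- small_case(seed = 6, shape = c(96, 96, 8))
  mg <- vesica:::mask_to_model_grid(cs$reference_mask, 64)
  expect_true(all(mg %in% c(0L, 1L)))
  expect_identical(dim(mg), c(64L, 64L, 8L))
})
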