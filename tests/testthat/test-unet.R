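test_that("configuration is validated", {
  expect_error(unet_config(depth = 5, input_size = 100), "divisible")
  expect_error(unet_config(learning_rate = 0), "learning_rate")
  cfg <- test_scale_config()
  expect_identical(cfg$depth, 5L)
  expect_identical(cfg$base_filters, 8L)
})

test_that("the network has the declared five-level structure and valid outputs", {
  cfg <- test_scale_config(seed = 3)
  m <- build_unet(cfg)
  # 5 encoder levels, 4 up-samplings/decoder levels, one output head
  expect_length(grep("^enc[0-9]+_conv1_W$", names(m$params)), 5L)
  expect_length(grep("^up[0-9]+_W$", names(m$params)), 4L)
  expect_length(grep("^dec[0-9]+_conv1_W$", names(m$params)), 4L)
  # filter doubling per level
  expect_identical(vapply(1:5, function(l) {
    ncol(m$params[[sprintf("enc%d_conv1_W", l)]])
  }, integer(1)), as.integer(8 * 2^(0:4)))

  x <- array(rnorm(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  fw <- vesica:::unet_forward(m$params, m$state, x, cfg, training = FALSE)
  expect_identical(dim(fw$prob), c(64L, 64L, 1L, 2L))
  expect_true(all(fw$prob >= 0 & fw$prob <= 1))
  expect_false(anyNA(fw$prob))

  m2 <- build_unet(cfg)
  expect_identical(m$params, m2$params)
})

test_that("dice loss matches its closed forms", {
  n <- 64
  tgt <- array(rep(c(1, 0), each = n / 2), c(8, 8, 1, 1))
  expect_equal(dice_loss(tgt, tgt, smooth = 1e-12), 0, tolerance = 1e-9)
  expect_equal(dice_loss(1 - tgt, tgt, smooth = 1e-12), 1, tolerance = 1e-9)
  half <- array(0.5, dim(tgt))
  expect_equal(dice_loss(half, tgt, smooth = 0), 0.5)
  expect_error(dice_loss(half, tgt[, 1:4, , , drop = FALSE]), "shape")
  expect_error(dice_loss(half * 3, tgt), "0, 1")
})

test_that("backpropagation matches finite-difference gradients", {
  withr::local_options(vesica.conv_double = TRUE)
  cfg <- unet_config(depth = 3, base_filters = 4, epochs = 1, batch_size = 2,
                     input_size = 16, seed = 7)
  m <- build_unet(cfg)
  set.seed(99)
  x <- array(rnorm(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))
  loss_fn <- function(params) {
    fw <- vesica:::unet_forward(params, m$state, x, cfg, training = TRUE)
    vesica:::dice_loss_batch(fw$prob, y, cfg$smooth)$loss
  }
  fw <- vesica:::unet_forward(m$params, m$state, x, cfg, training = TRUE)
  dl <- vesica:::dice_loss_batch(fw$prob, y, cfg$smooth)
  dz <- vesica:::dice_loss_grad(dl, dim(fw$prob)) * fw$prob * (1 - fw$prob)
  grads <- vesica:::unet_backward(m$params, fw$caches, dz, cfg)
  eps <- 1e-5
  for (nm in c("enc1_conv1_W", "enc2_bn1_gamma", "dec1_conv2_W", "up1_W",
               "out_W", "dec2_bn2_beta")) {
    p <- m$params[[nm]]
    for (ii in sample(length(p), min(3, length(p)))) {
      pp <- m$params
      pp[[nm]][ii] <- pp[[nm]][ii] + eps
      lp <- loss_fn(pp)
      pp[[nm]][ii] <- pp[[nm]][ii] - 2 * eps
      lm <- loss_fn(pp)
      num <- (lp - lm) / (2 * eps)
      ana <- grads[[nm]][ii]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-2)
    }
  }
})

test_that("single- and double-precision convolution kernels agree", {
  set.seed(31)
  x <- array(rnorm(16 * 16 * 6 * 2), c(16, 16, 6, 2))
  W <- matrix(rnorm(9 * 6 * 4, 0, 0.3), 9 * 6, 4)
  b <- rnorm(4)
  fd <- vesica:::cpp_conv3_fw(x, W, b, 16, 16, 6, 2)
  ff <- vesica:::cpp_conv3f_fw(x, W, b, 16, 16, 6, 2)
  expect_equal(ff$y, fd, tolerance = 1e-5)
  dy <- array(rnorm(length(fd)), dim(fd))
  bd_w <- vesica:::cpp_conv3_bw_w(x, dy, 16, 16, 6, 2, 4)
  bd_x <- vesica:::cpp_conv3_bw_x(dy, W, 16, 16, 6, 2)
  bf <- vesica:::cpp_conv3f_bw(ff$xf, dy, W, 16, 16, 6, 2)
  expect_equal(bf$dW, bd_w$dW, tolerance = 1e-4)
  expect_equal(bf$db, bd_w$db, tolerance = 1e-5)
  expect_equal(bf$dx, bd_x, tolerance = 1e-4)
})

test_that("folds partition patients evenly and deterministically", {
  ids <- sprintf("p%03d", 1:140)
  f <- make_folds(ids, k = 5, seed = 4)
  expect_identical(sort(unique(f$fold)), 1:5)
  expect_true(all(table(f$fold) == 28))
  expect_setequal(f$patient_id, ids)
  expect_identical(f, make_folds(ids, k = 5, seed = 4))
  # uneven counts differ by at most one
  f2 <- make_folds(sprintf("q%02d", 1:23), k = 5, seed = 1)
  expect_lte(diff(range(table(f2$fold))), 1)
  expect_error(make_folds(c("a", "b"), k = 5), "at least")
  expect_error(make_folds(c("a", "a", "b", "c", "d"), k = 2), "unique")
})

test_that("training rejects patient leakage and returns the model unchanged at zero epochs", {
  cohort <- generate_cohort(6, seed = 15, shape = c(64, 64, 8))
  cfg <- test_scale_config(epochs = 0, seed = 2)
  m0 <- build_unet(cfg)
  m <- train_fold(NULL, cohort[1:4], cohort[5:6], cfg)
  expect_identical(m$params, m0$params)
  expect_error(train_fold(NULL, cohort[1:4], cohort[4:5], cfg), "overlap")
  expect_error(train_fold(NULL, list(), cohort[1:2], cfg), "Empty")
})

test_that("a short training run reduces the Dice loss on separable phantoms", {
  cohort <- generate_cohort(8, seed = 33, shape = c(64, 64, 8),
                            noise_sigma = 20)
  cfg <- test_scale_config(epochs = 4, seed = 8)
  m <- train_fold(NULL, cohort[1:6], cohort[7:8], cfg)
  expect_identical(nrow(m$history), 4L)
  expect_lt(tail(m$history$train_loss, 1), m$history$train_loss[1])
  expect_false(anyNA(m$history$val_loss))
})
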