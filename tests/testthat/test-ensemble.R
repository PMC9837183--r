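test_that("majority vote matches a brute-force per-voxel count", {
  set.seed(101)
  for (rep in 1:200) {
    masks <- lapply(1:5, function(i) {
      array(rbinom(5 * 5 * 3, 1, runif(1, 0.2, 0.8)), c(5, 5, 3))
    })
    cons <- majority_vote(masks, min_votes = 3)$voxels
    brute <- array(0L, c(5, 5, 3))
    for (x in 1:5) for (y in 1:5) for (z in 1:3) {
      votes <- sum(vapply(masks, function(m) m[x, y, z], numeric(1)))
      brute[x, y, z] <- as.integer(votes >= 3)
    }
    expect_identical(cons, brute)
  }
})

test_that("the 3-of-5 vote rule includes 3 votes and excludes 2", {
  base <- array(0L, c(4, 4, 1))
  three <- lapply(1:5, function(i) {
    m <- base
    if (i <= 3) m[2, 2, 1] <- 1L
    if (i <= 2) m[3, 3, 1] <- 1L
    m
  })
  cons <- majority_vote(three, min_votes = 3)$voxels
  expect_identical(cons[2, 2, 1], 1L)  # exactly 3 votes -> in
  expect_identical(cons[3, 3, 1], 0L)  # exactly 2 votes -> out
  same <- lapply(1:5, function(i) three[[1]])
  expect_identical(majority_vote(same)$voxels, three[[1]])
  expect_error(majority_vote(c(three[1:4], list(base[1:2, , , drop = FALSE]))),
               "shape")
})

test_that("dice coefficient matches Eq.-style closed forms and conventions", {
  m <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
  expect_equal(dice_coefficient(m, m), 1)
  a <- array(0L, c(4, 4, 4)); a[1:2, 1, 1] <- 1L
  b <- array(0L, c(4, 4, 4)); b[3:4, 4, 4] <- 1L
  expect_equal(dice_coefficient(a, b), 0)
  # |T| = 4, |P| = 4, |T intersect P| = 2 -> 0.5
  t4 <- array(0L, c(4, 4, 1)); t4[1:4, 1, 1] <- 1L
  p4 <- array(0L, c(4, 4, 1)); p4[3:4, 1, 1] <- 1L; p4[1:2, 2, 1] <- 1L
  expect_equal(dice_coefficient(t4, p4), 0.5)
  empty <- array(0L, c(4, 4, 4))
  expect_equal(dice_coefficient(empty, empty), 1)
  expect_equal(dice_coefficient(empty, m), 0)
  expect_error(dice_coefficient(m, m[1:2, , , drop = FALSE]), "shape")
})

test_that("dice coefficient is symmetric and consistent with the dice loss", {
  set.seed(7)
  for (i in 1:25) {
    a <- array(rbinom(60, 1, 0.5), c(5, 4, 3))
    b <- array(rbinom(60, 1, 0.5), c(5, 4, 3))
    expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
    if (sum(a) + sum(b) > 0) {
      expect_equal(1 - dice_loss(b, a, smooth = 1e-9),
                   dice_coefficient(a, b), tolerance = 1e-6)
    }
  }
})

test_that("prediction thresholds probabilities with the >= rule", {
  cfg <- test_scale_config(seed = 12)
  m <- build_unet(cfg)
  cs <- small_case(seed = 13)
  stack <- assemble_channels(cs, "multi", 64)
  pred <- predict_mask(m, stack, prob_threshold = 0.5)
  prob <- vesica:::predict_prob_array(m$params, m$state, unclass(stack),
                                      cfg)
  expect_identical(sum(pred$voxels), sum(prob >= 0.5))
  # all-below-threshold probabilities give an empty mask
  none <- predict_mask(m, stack, prob_threshold = 1.01)
  expect_identical(sum(none$voxels), 0L)
  # boundary inclusion of the exact threshold value
  expect_identical(sum(prob >= min(prob)), length(prob))
})

test_that("cross-validation summaries use mean/range and median/IQR", {
  cv <- summarize_cv(c(0.78, 0.81, 0.79, 0.80, 0.82))
  expect_equal(cv$mean_dsc, 0.80)
  expect_equal(c(cv$min_dsc, cv$max_dsc), c(0.78, 0.82))
  const <- summarize_cv(rep(0.5, 5))
  expect_equal(const$min_dsc, const$max_dsc)
  expect_true(cv$mean_dsc >= cv$min_dsc && cv$mean_dsc <= cv$max_dsc)
  expect_error(summarize_cv(numeric(0)), "No DSC")

  ts <- summarize_test(c(0.7, 0.8, 0.9))
  expect_equal(ts$median_dsc, 0.8)
  one <- summarize_test(0.66)
  expect_equal(c(one$median_dsc, one$q1_dsc, one$q3_dsc), rep(0.66, 3))
  set.seed(1)
  rnd <- summarize_test(runif(17))
  expect_true(rnd$q1_dsc <= rnd$median_dsc && rnd$median_dsc <= rnd$q3_dsc)
})

test_that("ensemble consensus respects member bounds", {
  set.seed(5)
  masks <- lapply(1:5, function(i) array(rbinom(200, 1, 0.4), c(10, 10, 2)))
  cons <- majority_vote(masks)$voxels
  un <- Reduce(`|`, lapply(masks, function(m) m == 1))
  inter <- Reduce(`&`, lapply(masks, function(m) m == 1))
  expect_true(all(cons[inter]))       # unanimous voxels survive
  expect_true(all(cons[!un] == 0L))   # voxels no member flagged stay out
})
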