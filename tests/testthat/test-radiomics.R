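test_that("fixed-bin-width discretization follows the floor rule anchored at the minimum", {
  vol <- array(c(1.000, 1.004, 1.005, 0), c(4, 1, 1))
  msk <- array(c(1L, 1L, 1L, 0L), c(4, 1, 1))
  d <- discretize(vol, msk, bin_width = 0.005)
  expect_identical(d$gray[msk == 1], c(1L, 1L, 2L))
  expect_identical(d$Ng, 2L)
  # constant ROI
  dc <- discretize(array(2, c(3, 3, 1)), array(1L, c(3, 3, 1)), 0.005)
  expect_identical(dc$Ng, 1L)
  # shifting all intensities leaves the levels unchanged
  d2 <- discretize(vol + 5, msk, bin_width = 0.005)
  expect_identical(d2$gray, d$gray)
  expect_error(discretize(vol, msk * 0L, 0.005), "empty")
})

test_that("first-order features match hand computations and emit 18 names", {
  fo <- first_order_features(c(1, 2, 3), shift = 1, bin_width = 0.005)
  expect_length(fo, 18L)
  expect_equal(unname(fo["Mean"]), 2)
  expect_equal(unname(fo["Energy"]), 2^2 + 3^2 + 4^2)  # shifted energy
  expect_equal(unname(fo["RootMeanSquared"]), sqrt(29 / 3))
  expect_equal(unname(fo["Median"]), 2)
  expect_equal(unname(fo["Variance"]), 2 / 3)  # population variance
  const <- first_order_features(rep(4, 5))
  expect_equal(unname(const[c("Skewness", "Kurtosis")]), c(0, 0))
  expect_equal(unname(const["Uniformity"]), 1)
})

test_that("shape features recover voxel volume and near-unit ball sphericity", {
  msk <- array(0L, c(5, 4, 3)); msk[2:3, 2:3, 2] <- 1L
  sf <- shape_features(msk, spacing = c(1, 1, 1))
  expect_length(sf, 14L)
  expect_equal(unname(sf["VoxelVolume"]), 4)
  aniso <- shape_features(msk, spacing = c(2, 1, 3))
  expect_equal(unname(aniso["VoxelVolume"]), 24)

  # digital ball: sphericity approaches 1 and mesh volume the sphere volume
  r <- 9.5
  n <- 21
  ctr <- (n + 1) / 2
  ball <- array(0L, c(n, n, n))
  co <- arrayInd(seq_len(n^3), c(n, n, n))
  ball[(co[, 1] - ctr)^2 + (co[, 2] - ctr)^2 + (co[, 3] - ctr)^2 <= r^2] <- 1L
  bs <- shape_features(ball, spacing = c(1, 1, 1))
  # midpoint iso-surfaces of binary data carry a persistent staircase
  # area bias of a few percent, so sphericity plateaus slightly below 1
  expect_gt(unname(bs["Sphericity"]), 0.88)
  expect_lte(unname(bs["Sphericity"]), 1)
  expect_equal(unname(bs["MeshVolume"]), 4 / 3 * pi * r^3, tolerance = 0.05)
  expect_equal(unname(bs["Maximum3DDiameter"]), 2 * r, tolerance = 0.1)

  single <- array(0L, c(3, 3, 3)); single[2, 2, 2] <- 1L
  ss <- shape_features(single)
  expect_equal(unname(ss[c("MajorAxisLength", "Elongation", "Flatness")]),
               c(0, 1, 1))
})

test_that("co-occurrence matrices match hand-enumerated pair counts", {
  g <- array(c(1L, 1L, 2L, 2L), c(2, 2, 1))  # level 1 at x-column 1, 2 at 2
  d <- tiny_droi(g)
  mats <- vesica:::glcm_matrices(d)
  expect_length(mats, 4L)  # only the four in-plane directions have pairs
  # direction (1,0,0): both pairs same-level -> diagonal matrix
  expect_equal(mats[[1]], matrix(c(0.5, 0, 0, 0.5), 2, 2))
  fx <- glcm_features(d)
  expect_length(fx, 24L)
  # contrast: 0 along x, 1 along y and both diagonals -> mean 0.75
  expect_equal(unname(fx["Contrast"]), 0.75)
  const <- glcm_features(tiny_droi(array(1L, c(3, 3, 1))))
  expect_equal(unname(const["Contrast"]), 0)
  expect_equal(unname(const["Correlation"]), 1)
  expect_equal(unname(const["MCC"]), 1)
})

test_that("run-length features match brute-force run enumeration", {
  # constant 1x1x4 line: one run of length 4 along z
  line <- tiny_droi(array(1L, c(1, 1, 4)))
  rz <- vesica:::runs_one_direction(line, c(0, 0, 1))
  expect_identical(nrow(rz), 1L)
  expect_equal(unname(rz[1, ]), c(1, 4))
  # along x each voxel is its own run
  rx <- vesica:::runs_one_direction(line, c(1, 0, 0))
  expect_identical(nrow(rx), 4L)
  # all-distinct line: all runs length 1, short-run emphasis 1
  dist <- tiny_droi(array(1:4, c(4, 1, 1)))
  fx <- glrlm_features(dist)
  expect_length(fx, 16L)
  expect_equal(unname(fx["ShortRunEmphasis"]), 1)
  expect_equal(unname(fx["RunPercentage"]), 1)
})

test_that("size zones match connected-component enumeration", {
  g <- array(0L, c(7, 3, 1))
  g[1:2, 1, 1] <- 2L            # zone of size 2, level 2
  g[5:7, 1, 1] <- 2L            # zone of size 3, level 2
  g[1:3, 3, 1] <- 1L            # zone of size 3, level 1
  d <- tiny_droi(g)
  z <- vesica:::glszm_zones(d)
  expect_identical(nrow(z), 3L)
  expect_setequal(z[z[, "level"] == 2, "size"], c(2, 3))
  expect_equal(unname(z[z[, "level"] == 1, "size"]), 3)
  fx <- glszm_features(d)
  expect_length(fx, 16L)
  # zone sizes sum to the ROI voxel count
  expect_equal(sum(z[, "size"]), sum(d$mask))
  # constant ROI -> a single zone
  zc <- vesica:::glszm_zones(tiny_droi(array(3L, c(4, 2, 2))))
  expect_identical(nrow(zc), 1L)
  expect_equal(unname(zc[1, "size"]), 16)
})

test_that("gray-tone difference components match exhaustive neighbour averaging", {
  g <- array(c(1L, 2L, 3L, 2L, 2L, 2L, 3L, 2L, 1L), c(3, 3, 1))
  d <- tiny_droi(g)
  cm <- vesica:::ngtdm_components(d)
  # brute force: average of in-ROI neighbours for each voxel
  s_brute <- numeric(d$Ng)
  for (x in 1:3) for (y in 1:3) {
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      if (x + dx >= 1 && x + dx <= 3 && y + dy >= 1 && y + dy <= 3) {
        nb <- c(nb, g[x + dx, y + dy, 1])
      }
    }
    lvl <- g[x, y, 1]
    s_brute[lvl] <- s_brute[lvl] + abs(lvl - mean(nb))
  }
  expect_equal(cm$s, s_brute, tolerance = 1e-12)
  fx <- ngtdm_features(d)
  expect_length(fx, 5L)
  const <- ngtdm_features(tiny_droi(array(2L, c(3, 3, 1))))
  expect_equal(unname(const["Contrast"]), 0)
})

test_that("dependence counts follow the neighbours-only convention", {
  d <- tiny_droi(array(1L, c(3, 3, 3)))
  dc <- vesica:::gldm_counts(d, alpha = 0)
  expect_equal(max(dc[, "count"]), 26)  # interior voxel of constant cube
  single <- tiny_droi(array(c(0L, 1L, 0L), c(3, 1, 1)))
  ds <- vesica:::gldm_counts(single, alpha = 0)
  expect_identical(nrow(ds), 1L)
  expect_equal(unname(ds[1, "count"]), 0)
  fx <- gldm_features(d)
  expect_length(fx, 14L)
  fs <- gldm_features(single)
  expect_equal(unname(fs["SmallDependenceEmphasis"]), 1)  # j = count + 1 = 1
})

test_that("the full vector is complete, deterministic, and properly invariant", {
  orc <- oracle_roi()
  fv <- extract_all(orc$volume, orc$mask, orc$spacing)
  man <- feature_manifest()
  expect_identical(nrow(fv), 107L)
  expect_identical(fv$feature, man$feature)
  expect_identical(as.integer(table(factor(fv$family,
                                           levels = unique(man$family)))),
                   c(18L, 14L, 24L, 16L, 16L, 5L, 14L))
  expect_identical(fv, extract_all(orc$volume, orc$mask, orc$spacing))
  expect_true(all(is.finite(fv$value)))

  # translation invariance of the ROI within the grid
  big <- array(0, c(20, 20, 12)); bm <- array(0L, c(20, 20, 12))
  big[3:16, 3:15, 2:9] <- orc$volume
  bm[3:16, 3:15, 2:9] <- orc$mask
  fv_t <- extract_all(big, bm, orc$spacing)
  expect_equal(fv_t$value, fv$value, tolerance = 1e-9)

  # adding a constant shifts location statistics, not texture
  fv_s <- extract_all(orc$volume + 0.37 * (orc$mask == 1), orc$mask,
                      orc$spacing)
  tex <- fv$family %in% c("glcm", "glrlm", "glszm", "ngtdm", "gldm")
  expect_equal(fv_s$value[tex], fv$value[tex], tolerance = 1e-9)
  expect_equal(fv_s$value[fv$feature == "Mean" & fv$family == "firstorder"],
               fv$value[fv$feature == "Mean" & fv$family == "firstorder"] +
                 0.37,
               tolerance = 1e-9)

  # normalized texture matrices sum to one
  d <- discretize(orc$volume, orc$mask, 0.005, orc$spacing)
  for (p in vesica:::glcm_matrices(d)) expect_equal(sum(p), 1)
  expect_error(extract_all(orc$volume, orc$mask * 0L, orc$spacing), "empty")
})

test_that("all 107 features agree with the independent reference implementation", {
  orc <- oracle_roi()
  fv <- extract_all(orc$volume, orc$mask, orc$spacing)
  expected <- utils::read.csv(test_path("fixtures", "radiomics_oracle.csv"))
  merged <- merge(fv, expected, by = c("family", "feature"),
                  suffixes = c("_ours", "_ref"))
  expect_identical(nrow(merged), 107L)
  mesh <- merged$feature %in% c("MeshVolume", "SurfaceArea",
                                "SurfaceVolumeRatio", "Sphericity")
  rel <- abs(merged$value_ours - merged$value_ref) /
    pmax(abs(merged$value_ref), 1e-12)
  expect_lt(max(rel[!mesh]), 1e-4)
  expect_lt(max(rel[mesh]), 0.02)
})
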