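# ROI translation, ICC(1,1) and the stability screen

test_that("translation magnitude is 10% of the bounding box, invertible, and
          bounded by the grid", {
  m <- array(0L, c(40, 20, 20)); m[11:30, 6:14, 6:14] <- 1L  # bbox x: 20
  msk <- roi_mask(m, c(1, 1, 1))
  tx <- translate_mask(msk, axis = 1, sign = 1)
  expect_equal(sum(tx$voxels), sum(m))                  # voxel count kept
  expect_equal(which(tx$voxels[, 10, 10] == 1L), 13:32) # shifted by 2

  back <- translate_mask(tx, axis = 1, sign = -1)
  expect_identical(back$voxels, m)

  tiny <- array(0L, c(10, 10, 10)); tiny[4:6, 4:6, 4:6] <- 1L
  expect_error(translate_mask(roi_mask(tiny, c(1, 1, 1)), 1, 1),
               "zero voxels")
  edge <- array(0L, c(12, 12, 12)); edge[1:11, 2:11, 2:11] <- 1L
  expect_error(translate_mask(roi_mask(edge, c(1, 1, 1)), 1, -1), "bounds")
})

test_that("the perturbation set holds the original plus six axis-aligned
          translations", {
  m <- array(0L, c(30, 30, 30)); m[9:22, 9:22, 9:22] <- 1L
  ps <- perturbation_set(roi_mask(m, c(1, 1, 1)))
  expect_length(ps, 7)
  expect_identical(ps[[1]]$voxels, m)
  counts <- vapply(ps, function(x) sum(x$voxels), 0)
  expect_true(all(counts == sum(m)))
})

test_that("ICC(1,1) matches the variance-components oracle and handles the
          degenerate limits", {
  x <- matrix(c(1, 1.1, 2, 2.1, 3, 2.9), nrow = 3, byrow = TRUE)
  expect_equal(icc(x), oracle_icc(x), tolerance = 1e-9)

  # identical measurement columns, patients differ: perfect agreement
  y <- cbind(1:4, 1:4, 1:4)
  expect_equal(icc(y), 1)

  # zero total variance is flagged degenerate
  z <- matrix(5, 3, 3)
  expect_equal(as.numeric(icc(z)), 1)
  expect_true(attr(icc(z), "degenerate"))

  # identical patients, pure-noise measurements: ICC centred at/below zero
  set.seed(7)
  meds <- replicate(100, icc(matrix(rnorm(50 * 2), 50, 2)))
  expect_lte(median(meds), 0.1)
})

test_that("stability screen keeps perturbation-invariant features and
          rejects features replaced by fresh noise", {
  set.seed(88)
  n <- 50
  base <- cbind(stable = rnorm(n), noise = rnorm(n))
  tables <- lapply(1:7, function(k)
    cbind(stable = base[, "stable"],             # identical across masks
          noise = rnorm(n)))                     # redrawn per mask
  sel <- select_stable(tables)
  expect_true("stable" %in% sel$features)
  expect_false("noise" %in% sel$features)
  expect_lt(sel$report$icc[sel$report$feature == "noise"], 0.75)

  # ICC is scale free: rescaling a feature flips no pass flag
  tables10 <- lapply(tables, function(t) { t[, "stable"] <- 10 * t[, "stable"]; t })
  expect_identical(select_stable(tables10)$report$pass, sel$report$pass)

  expect_error(select_stable(lapply(tables, function(t) {
    t[, 1] <- rnorm(n); t[, 2] <- rnorm(n); t
  })), "no feature")
})

test_that("voxel-count-preserving translations give shape features zero
          within-patient variance, so VoxelVolume always passes", {
  pre <- small_patient()
  masks <- perturbation_set(pre$mask)
  fm <- radsig:::extract_features_multi(pre$image, masks)
  vv <- fm[, "original_shape_VoxelVolume"]
  expect_equal(max(vv) - min(vv), 0)
})
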