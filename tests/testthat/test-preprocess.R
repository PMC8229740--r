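# Gaussian denoising and isotropic B-spline resampling

test_that("normalised Gaussian kernel preserves constants and reproduces the
          closed-form impulse response", {
  const <- image_volume(array(7.5, c(8, 8, 8)), c(1, 1, 1))
  expect_equal(gaussian_denoise(const)$voxels, array(7.5, c(8, 8, 8)))

  imp <- array(0, c(7, 7, 7)); imp[4, 4, 4] <- 1
  out <- gaussian_denoise(image_volume(imp, c(1, 1, 1)))$voxels
  # 1D weights at sigma 0.5: w ~ exp(-k^2/(2 s^2)), k = -1..1, normalised
  w <- exp(-(-1:1)^2 / (2 * 0.5^2)); w <- w / sum(w)
  expect_equal(out[4, 4, 4], w[2]^3, tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-12)        # kernel sums to one
  expect_equal(out[3, 4, 4], w[1] * w[2]^2, tolerance = 1e-12)
})

test_that("denoising never widens the intensity range", {
  set.seed(21)
  img <- image_volume(array(rnorm(12^3, 40, 30), c(12, 12, 12)), c(1, 1, 3))
  out <- gaussian_denoise(img)
  expect_gte(min(out$voxels), min(img$voxels))
  expect_lte(max(out$voxels), max(img$voxels))
})

test_that("non-finite intensities are rejected", {
  v <- array(0, c(5, 5, 5))
  expect_error(image_volume(v * NA, c(1, 1, 1)), "finite")
})

test_that("resampling grid arithmetic: 1 mm 40^3 maps to 2 mm 20^3 and an
          already-isotropic grid is reproduced", {
  set.seed(3)
  v <- array(rnorm(40^3), c(40, 40, 40))
  m <- array(0L, c(40, 40, 40)); m[15:25, 15:25, 15:25] <- 1L
  res <- resample_isotropic(image_volume(v, c(1, 1, 1)),
                            roi_mask(m, c(1, 1, 1)))
  expect_equal(dim(res$image$voxels), c(20, 20, 20))
  expect_equal(res$image$spacing, c(2, 2, 2))

  v2 <- array(rnorm(16^3), c(16, 16, 16))
  m2 <- array(0L, dim(v2)); m2[6:10, 6:10, 6:10] <- 1L
  res2 <- resample_isotropic(image_volume(v2, c(2, 2, 2)),
                             roi_mask(m2, c(2, 2, 2)))
  # interpolation identity on grid points
  expect_equal(res2$image$voxels, v2, tolerance = 1e-9)
  expect_identical(res2$mask$voxels, m2)
})

test_that("mask physical volume is preserved within 10% by nearest-neighbour
          resampling", {
  for (r in c(6, 9)) {
    msk <- ball_mask(r, spacing = c(1, 1, 3), n = 31)
    img <- image_volume(array(0, dim(msk$voxels)), c(1, 1, 3))
    res <- resample_isotropic(img, msk)
    v_in <- sum(msk$voxels) * prod(msk$spacing)
    v_out <- sum(res$mask$voxels) * prod(res$mask$spacing)
    expect_lt(abs(v_out / v_in - 1), 0.10)
  }
})

test_that("anisotropic volumes resample to the documented z extent", {
  img <- image_volume(array(0, c(64, 64, 64)), c(1, 1, 3))
  msk <- roi_mask(array(rep(c(0L, 1L), c(63, 1)), c(64, 64, 64)), c(1, 1, 3))
  res <- resample_isotropic(img, msk)
  expect_equal(dim(res$image$voxels), c(32, 32, 96))
})
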