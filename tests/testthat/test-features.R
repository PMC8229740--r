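# feature extraction: discretisation, rosters, texture matrices vs oracles,
# shape geometry, wavelet conventions

test_that("fixed-bin-width discretisation follows the level formula", {
  v <- array(0, c(3, 1, 1)); v[, 1, 1] <- c(10.0, 10.4, 11.0)
  m <- array(1L, c(3, 1, 1))
  d <- discretize(image_volume(v, c(1, 1, 1)), roi_mask(m, c(1, 1, 1)))
  expect_equal(as.integer(d$levels), c(1L, 1L, 3L))
  expect_equal(d$n_levels, 3L)
  expect_equal(d$bin_anchor, 10.0)
  expect_equal(d$bin_width, 0.5)

  vc <- array(5, c(2, 2, 1)); mc <- array(1L, c(2, 2, 1))
  dc <- suppressMessages(
    discretize(image_volume(vc, c(1, 1, 1)), roi_mask(mc, c(1, 1, 1))))
  expect_true(all(dc$levels == 1L))
  expect_equal(dc$n_levels, 1L)
  expect_true(attr(dc, "degenerate"))
})

test_that("the roster has 536 uniquely named features: 14 shape, 18 first
          order, 24 GLCM, 16 GLRLM, and 58 per wavelet band", {
  nm <- feature_names()
  expect_length(nm, 536)
  expect_equal(anyDuplicated(nm), 0L)
  expect_equal(sum(grepl("^original_shape_", nm)), 14)
  expect_equal(sum(grepl("^original_firstorder_", nm)), 18)
  expect_equal(sum(grepl("^original_glcm_", nm)), 24)
  expect_equal(sum(grepl("^original_glrlm_", nm)), 16)
  expect_equal(sum(grepl("^wavelet-", nm)), 464)
  for (b in c("LLL", "HLH", "HHH"))
    expect_equal(sum(grepl(paste0("^wavelet-", b, "_"), nm)), 58)
})

test_that("extraction yields exactly the 536-feature roster on a synthetic
          patient, finite and in canonical order", {
  pre <- small_patient()
  fv <- extract_features(pre$image, pre$mask)
  expect_length(fv, 536)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
})

test_that("first-order statistics match hand values and conventions", {
  v <- array(0, c(4, 1, 1)); v[, 1, 1] <- c(-1, 1, -1, 1)
  m <- array(1L, c(4, 1, 1))
  fo <- first_order_features(image_volume(v, c(1, 1, 1)),
                             roi_mask(m, c(1, 1, 1)))
  expect_equal(unname(fo["original_firstorder_Kurtosis"]), 1)  # m4/m2^2
  expect_equal(unname(fo["original_firstorder_Mean"]), 0)
  expect_equal(unname(fo["original_firstorder_Variance"]), 1)
  expect_equal(unname(fo["original_firstorder_Energy"]), 4)

  # non-excess kurtosis: large normal sample converges to 3
  set.seed(9)
  vn <- array(rnorm(1e5), c(100, 100, 10))
  fo2 <- first_order_features(image_volume(vn, c(1, 1, 1)),
                              roi_mask(array(1L, dim(vn)), c(1, 1, 1)))
  expect_equal(unname(fo2["original_firstorder_Kurtosis"]), 3,
               tolerance = 0.1 / 3)
})

test_that("GLCM probabilities equal exhaustive pair enumeration", {
  # the worked 2x2x1 example
  lev <- array(c(1L, 1L, 2L, 2L), c(2, 2, 1))
  droi <- structure(list(levels = lev, bin_width = 0.5, bin_anchor = 0,
                         n_levels = 2L, dim = dim(lev)),
                    class = "discretized_roi")
  got <- glcm_matrix(droi)
  want <- oracle_glcm(lev)
  expect_equal(nrow(got), nrow(want))
  for (r in seq_len(nrow(want))) {
    hit <- got[got$direction == want$direction[r] & got$i == want$i[r] &
                 got$j == want$j[r], "p"]
    expect_equal(hit, want$p[r], tolerance = 1e-9)
  }

  # random 5^3 fixture with masked-out voxels
  set.seed(14)
  lev2 <- array(sample(0:4, 125, TRUE), c(5, 5, 5))
  droi2 <- structure(list(levels = lev2, bin_width = 0.5, bin_anchor = 0,
                          n_levels = 4L, dim = dim(lev2)),
                     class = "discretized_roi")
  got2 <- glcm_matrix(droi2)
  want2 <- oracle_glcm(lev2)
  # per direction the probabilities must sum to one
  expect_true(all(abs(tapply(got2$p, got2$direction, sum) - 1) < 1e-12))
  key <- function(d) paste(d$direction, d$i, d$j)
  expect_setequal(key(got2), key(want2))
  m <- match(key(got2), key(want2))
  expect_equal(got2$p, want2$p[m], tolerance = 1e-9)
})

test_that("constant ROI has zero GLCM contrast", {
  lev <- array(1L, c(4, 4, 4))
  droi <- structure(list(levels = lev, bin_width = 0.5, bin_anchor = 0,
                         n_levels = 1L, dim = dim(lev)),
                    class = "discretized_roi")
  f <- glcm_features(droi)
  expect_equal(unname(f["original_glcm_Contrast"]), 0)
  expect_equal(unname(f["original_glcm_JointEnergy"]), 1)
})

test_that("GLCM maximal correlation coefficient matches a dense eigen
          decomposition", {
  set.seed(4)
  lev <- array(sample(1:4, 6^3, TRUE, prob = c(.4, .3, .2, .1)), c(6, 6, 6))
  droi <- structure(list(levels = lev, bin_width = 0.5, bin_anchor = 0,
                         n_levels = 4L, dim = dim(lev)),
                    class = "discretized_roi")
  f <- glcm_features(droi)
  tr <- glcm_matrix(droi)
  mccs <- vapply(unique(tr$direction), function(d) {
    s <- tr[tr$direction == d, ]
    P <- matrix(0, 4, 4); P[cbind(s$i, s$j)] <- s$p
    px <- rowSums(P)
    M <- diag(1 / sqrt(px)) %*% P %*% diag(1 / sqrt(px))
    sort(abs(eigen(M, symmetric = TRUE)$values), decreasing = TRUE)[2]
  }, numeric(1))
  expect_equal(unname(f["original_glcm_MaximalCorrelationCoefficient"]),
               mean(mccs), tolerance = 1e-9)
})

test_that("GLRLM run counting matches hand enumeration on single rows", {
  row1 <- array(0L, c(6, 1, 1)); row1[, 1, 1] <- c(1L, 1L, 2L, 2L, 2L, 3L)
  droi <- structure(list(levels = row1, bin_width = 0.5, bin_anchor = 0,
                         n_levels = 3L, dim = dim(row1)),
                    class = "discretized_roi")
  gm <- glrlm_matrix(droi)
  t1 <- gm$triplets[gm$triplets$direction == 1, ]
  expect_equal(gm$n_runs[1], 3)                     # runs (1,2),(2,3),(3,1)
  expect_equal(t1$count, c(1, 1, 1))
  expect_equal(t1$i, c(1L, 2L, 3L)); expect_equal(t1$j, c(2L, 3L, 1L))
  # RunLengthNonUniformity along that direction: (1^2+1^2+1^2)/3 = 1
  rl <- tapply(t1$count, t1$j, sum)
  expect_equal(sum(rl^2) / gm$n_runs[1], 1)

  row2 <- array(0L, c(4, 1, 1)); row2[, 1, 1] <- c(2L, 2L, 3L, 3L)
  droi2 <- structure(list(levels = row2, bin_width = 0.5, bin_anchor = 0,
                          n_levels = 3L, dim = dim(row2)),
                     class = "discretized_roi")
  gm2 <- glrlm_matrix(droi2)
  t2 <- gm2$triplets[gm2$triplets$direction == 1, ]
  expect_equal(sum(tapply(t2$count, t2$j, sum)^2) / gm2$n_runs[1], 2)

  # constant single row of n voxels: one run, RLN = 1
  rowc <- array(0L, c(5, 1, 1)); rowc[, 1, 1] <- 1L
  droic <- structure(list(levels = rowc, bin_width = 0.5, bin_anchor = 0,
                          n_levels = 1L, dim = dim(rowc)),
                     class = "discretized_roi")
  gmc <- glrlm_matrix(droic)
  expect_equal(gmc$n_runs[1], 1)
  expect_equal(gmc$triplets$count[gmc$triplets$direction == 1], 1)
})

test_that("GLRLM features match the brute-force run-enumeration oracle and
          conserve voxel counts in every direction", {
  set.seed(33)
  lev <- array(sample(0:3, 6^3, TRUE, prob = c(.2, .4, .25, .15)), c(6, 6, 6))
  droi <- structure(list(levels = lev, bin_width = 0.5, bin_anchor = 0,
                         n_levels = 3L, dim = dim(lev)),
                    class = "discretized_roi")
  got <- glrlm_features(droi)
  want <- oracle_glrlm_features(lev)
  expect_equal(unname(got), unname(want), tolerance = 1e-9)

  gm <- glrlm_matrix(droi)
  np <- sum(lev > 0)
  for (d in 1:13) {
    td <- gm$triplets[gm$triplets$direction == d, ]
    expect_equal(sum(td$j * td$count), np)          # run-length conservation
    expect_equal(sum(td$count), gm$n_runs[d])
  }
})

test_that("shape features: voxel volume arithmetic and digital-ball
          sphericity", {
  m <- array(0L, c(6, 6, 6)); m[2:3, 2:3, 2] <- 1L; m[2:3, 2, 3] <- 1L
  expect_equal(sum(m), 6)
  m[4, 4, 4] <- 1L; m[4, 4, 5] <- 1L; m[5, 4, 4] <- 1L; m[4, 5, 4] <- 1L
  expect_equal(sum(m), 10)
  sf <- shape_features(roi_mask(m, c(2, 2, 2)))
  expect_equal(unname(sf["original_shape_VoxelVolume"]), 10 * 8)

  for (r in c(8, 10)) {
    sfb <- shape_features(ball_mask(r))
    sph <- unname(sfb["original_shape_Sphericity"])
    expect_gte(sph, 0.9); expect_lte(sph, 1.0)
    expect_equal(unname(sfb["original_shape_MeshVolume"]),
                 4 / 3 * pi * r^3, tolerance = 0.12)
    expect_equal(unname(sfb["original_shape_Maximum3DDiameter"]),
                 2 * r, tolerance = 0.15)
    expect_equal(unname(sfb["original_shape_Elongation"]), 1,
                 tolerance = 0.05)
  }
})

test_that("shape features depend on the mask only", {
  pre <- small_patient()
  shifted <- image_volume(pre$image$voxels + 100, pre$image$spacing)
  f1 <- extract_features(pre$image, pre$mask)
  f2 <- extract_features(shifted, pre$mask)
  shp <- grep("^original_shape_", names(f1))
  expect_identical(f1[shp], f2[shp])
})

test_that("wavelet bands: count, constant-image behaviour and axis-label
          convention", {
  const <- image_volume(array(3, c(10, 10, 10)), c(1, 1, 1))
  bands <- wavelet_bands(const)
  expect_length(bands, 8)
  expect_identical(names(bands),
                   c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  expect_lt(max(abs(range(bands$LLL$voxels) - mean(bands$LLL$voxels))), 1e-9)
  for (b in c("LLH", "LHL", "HLL", "HLH", "HHH"))
    expect_lt(max(abs(bands[[b]]$voxels)), 1e-9)

  # an image varying only along y is annihilated by any x or z high-pass,
  # so HLH must vanish while LHL (high-pass along y) carries the structure
  vy <- array(0, c(12, 12, 12))
  vy[] <- (slice.index(vy, 2) %% 2)    # alternating stripes along y
  by_ <- wavelet_bands(image_volume(vy, c(1, 1, 1)))
  expect_lt(max(abs(by_$HLH$voxels)), 1e-9)
  expect_lt(max(abs(by_$HHL$voxels)), 1e-9)
  expect_gt(max(abs(by_$LHL$voxels)), 0.1)
})

test_that("direction-averaged texture features are invariant to a 90-degree
          rotation of an isotropic fixture", {
  set.seed(12)
  n <- 8
  lev <- array(sample(0:5, n^3, TRUE), c(n, n, n))
  rot <- aperm(lev, c(2, 1, 3))[n:1, , ]            # 90 deg about z
  mk <- function(l) structure(
    list(levels = l, bin_width = 0.5, bin_anchor = 0, n_levels = 5L,
         dim = dim(l)), class = "discretized_roi")
  expect_equal(glcm_features(mk(lev)), glcm_features(mk(rot)),
               tolerance = 1e-6)
  expect_equal(glrlm_features(mk(lev)), glrlm_features(mk(rot)),
               tolerance = 1e-6)
})
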