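# synthetic cohort generator: determinism, split arithmetic, planted effects

test_that("cohort generation is a pure function of its configuration", {
  cfg <- cohort_config(n_patients = 10, seed = 3)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$patients[[4]]$image$voxels, b$patients[[4]]$image$voxels)
  expect_identical(a$patients[[4]]$mask$voxels, b$patients[[4]]$mask$voxels)
})

test_that("chronological split arithmetic matches the cohort design", {
  cl85 <- generate_cohort(cohort_config(n_patients = 85, seed = 2),
                          images = FALSE)$clinical
  expect_equal(sum(cl85$split == "training"), 68)
  expect_equal(sum(cl85$split == "test"), 17)
  expect_equal(cl85$split, rep(c("training", "test"), c(68, 17)))

  cl10 <- generate_cohort(cohort_config(n_patients = 10,
                                        train_fraction = 0.5, seed = 4),
                          images = FALSE)$clinical
  expect_equal(as.integer(table(cl10$split)[c("training", "test")]),
               c(5L, 5L))
})

test_that("labels concentrate at the configured event rate", {
  cl <- generate_cohort(cohort_config(n_patients = 1000, event_rate = 0.5,
                                      seed = 8), images = FALSE)$clinical
  expect_gte(mean(cl$label), 0.45)
  expect_lte(mean(cl$label), 0.55)
})

test_that("clinical covariates respect their structural constraints", {
  cl <- generate_cohort(cohort_config(n_patients = 200, seed = 6),
                        images = FALSE)$clinical
  expect_true(all(cl$n_organs <= cl$n_lesions))
  expect_true(all(cl$n_lesions >= 1))
  expect_true(all(cl$performance_status %in% 0:2))
  expect_true(all(cl$non_metastatic %in% 0:1))
  expect_true(all(cl$total_volume_mm3 >= cl$largest_volume_mm3))
})

test_that("identical RNG state reproduces identical tumors; unit effect sizes
          make the classes identical in law", {
  cfg <- cohort_config(n_patients = 10, volume_effect = 1,
                       heterogeneity_effect = 1, seed = 1)
  set.seed(42); t0 <- generate_tumor(0, cfg)
  set.seed(42); t0b <- generate_tumor(0, cfg)
  expect_identical(t0$image$voxels, t0b$image$voxels)
  # with both effects at 1 the class label enters nowhere
  set.seed(42); t1 <- generate_tumor(1, cfg)
  expect_identical(t0$image$voxels, t1$image$voxels)
  expect_identical(t0$mask$voxels, t1$mask$voxels)
})

test_that("volume_effect scales mean mask volume by its cube", {
  cfg <- cohort_config(n_patients = 10, volume_effect = 1.5, seed = 11)
  set.seed(101)
  v0 <- replicate(50, sum(generate_tumor(0, cfg)$mask$voxels))
  v1 <- replicate(50, sum(generate_tumor(1, cfg)$mask$voxels))
  ratio <- mean(v1) / mean(v0)
  expect_lt(abs(ratio / 1.5^3 - 1), 0.15)
})

test_that("degenerate configurations are rejected", {
  expect_error(cohort_config(n_patients = 5), "at least 10")
  expect_error(cohort_config(train_fraction = 1), "train_fraction")
  expect_error(cohort_config(event_rate = 0), "event_rate")
  expect_error(cohort_config(voxel_spacing = c(1, -1, 3)), "positive")
  # a seed whose training labels collapse to one class must error
  expect_error(
    generate_cohort(cohort_config(n_patients = 10, event_rate = 0.01,
                                  seed = 1), images = FALSE),
    "single class")
})

test_that("cohort round-trips exactly through NIfTI + CSV", {
  coh <- generate_cohort(cohort_config(n_patients = 10, seed = 3))
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  expect_equal(nrow(read.csv(file.path(d, "clinical.csv"))), 10)
  expect_identical(
    names(read.csv(file.path(d, "clinical.csv"))),
    c("patient_id", "split", "label", "n_lesions", "n_organs",
      "performance_status", "non_metastatic", "total_volume_mm3"))
  coh2 <- read_cohort(d)
  for (i in c(1, 5, 10)) {
    expect_identical(coh$patients[[i]]$image$voxels,
                     coh2$patients[[i]]$image$voxels)
    expect_identical(coh$patients[[i]]$mask$voxels,
                     coh2$patients[[i]]$mask$voxels)
    expect_identical(coh$patients[[i]]$image$spacing,
                     coh2$patients[[i]]$image$spacing)
    expect_true(all(coh2$patients[[i]]$mask$voxels %in% c(0L, 1L)))
  }
})

test_that("downstream test AUC is non-decreasing in the planted
          heterogeneity effect", {
  # volume_effect is held at 1 so heterogeneity is the only planted signal
  a10 <- mean_study_auc(1.0, 60)
  a15 <- mean_study_auc(1.5, 60)
  a25 <- mean_study_auc(2.5, 60)
  # non-decreasing up to sampling error of the 20-seed means
  expect_gte(a15, a10 - 0.04)
  expect_gte(a25, a15 - 0.04)
  expect_gt(a25, a10)
})
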