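#' Configuration for a synthetic imaging cohort
#'
#' Describes the statistical structure of a simulated cohort of patients,
#' each with one segmented (largest) lesion on a CT-like volume, a binary
#' 10-month overall-survival label, and clinical covariates. Class-dependent
#' signal is planted through two knobs: `volume_effect`, the ratio of mean
#' tumor diameter between short survivors (label 1) and long survivors
#' (label 0), and `heterogeneity_effect`, the ratio of intra-lesional
#' texture contrast between the classes. With both at 1 the two classes are
#' identical in law and the downstream pipeline should perform at chance.
#'
#' Tumors are lobulated ellipsoids; interior intensities are a base tissue
#' level plus a spatially correlated Gaussian random field (Gaussian-smoothed
#' white noise with correlation length `texture_length` mm) whose standard
#' deviation is `texture_sd` HU, scaled by `heterogeneity_effect` for
#' short survivors. The background is `background_hu` plus white noise of
#' `noise_sd` HU. Clinical covariates are drawn from categorical
#' distributions typical of recurrent/metastatic head-and-neck cohorts
#' (performance status 0/1/2 at 32/65/3%, median 3 lesions, median 2
#' affected organs, ~44% non-metastatic) and are independent of the label.
#'
#' @param n_patients number of patients (>= 10).
#' @param train_fraction chronological training fraction in (0, 1); the
#'   first `floor(train_fraction * n_patients)` patients form the training
#'   set.
#' @param event_rate proportion of short survivors (label 1, OS <= 10
#'   months) in (0, 1).
#' @param volume_effect ratio of mean tumor diameter, class 1 vs class 0.
#' @param heterogeneity_effect ratio of texture contrast, class 1 vs class 0.
#' @param voxel_spacing voxel spacing in mm (anisotropic by default so that
#'   isotropic resampling is exercised).
#' @param noise_sd background acquisition noise, HU.
#' @param image_dim grid size of the simulated volumes.
#' @param mean_diameter mean largest-lesion diameter for class 0, mm.
#' @param diameter_sdlog log-scale SD of the patient-level diameter draw.
#' @param base_hu mean intra-tumoral intensity, HU.
#' @param background_hu mean background intensity, HU.
#' @param texture_sd SD of the intra-tumoral correlated texture field, HU.
#' @param texture_length correlation length of the texture field, mm.
#' @param n_lobes number of surface lobulations added to the ellipsoid.
#' @param seed integer seed; the cohort is a pure function of the
#'   configuration, identical seed and settings give an identical cohort.
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [generate_tumor()]
#' @export
cohort_config <- function(n_patients = 85, train_fraction = 0.8,
                          event_rate = 0.3, volume_effect = 1.3,
                          heterogeneity_effect = 1.5,
                          voxel_spacing = c(1, 1, 3), noise_sd = 10,
                          image_dim = c(64, 64, 64), mean_diameter = 20,
                          diameter_sdlog = 0.1, base_hu = 60,
                          background_hu = 0, texture_sd = 15,
                          texture_length = 3, n_lobes = 3, seed = 1) {
  cfg <- list(n_patients = as.integer(n_patients),
              train_fraction = train_fraction, event_rate = event_rate,
              volume_effect = volume_effect,
              heterogeneity_effect = heterogeneity_effect,
              voxel_spacing = as.numeric(voxel_spacing),
              noise_sd = noise_sd, image_dim = as.integer(image_dim),
              mean_diameter = mean_diameter,
              diameter_sdlog = diameter_sdlog, base_hu = base_hu,
              background_hu = background_hu, texture_sd = texture_sd,
              texture_length = texture_length, n_lobes = as.integer(n_lobes),
              seed = as.integer(seed))
  if (cfg$n_patients < 10) stop("n_patients must be at least 10")
  if (!(cfg$train_fraction > 0 && cfg$train_fraction < 1))
    stop("train_fraction must lie in (0, 1)")
  if (!(cfg$event_rate > 0 && cfg$event_rate < 1))
    stop("event_rate must lie in (0, 1)")
  if (any(cfg$voxel_spacing <= 0)) stop("voxel spacings must be positive")
  if (cfg$volume_effect <= 0 || cfg$heterogeneity_effect <= 0)
    stop("effect ratios must be positive")
  if (length(cfg$image_dim) != 3 || any(cfg$image_dim < 16))
    stop("image_dim must be three integers >= 16")
  structure(cfg, class = "cohort_config")
}

# draw one tumor (image + mask) for a patient of the given class, using the
# caller's RNG stream; attr(out, "resized") flags a diameter cap
#' Simulate one lobulated tumor on a noisy background volume
#'
#' Draws a lobulated ellipsoidal lesion whose size scales with
#' `volume_effect` for short survivors (class 1) and fills its interior with
#' a spatially correlated Gaussian random field whose contrast scales with
#' `heterogeneity_effect`. Uses (and advances) the caller's RNG stream;
#' [generate_cohort()] manages seeding.
#'
#' @param patient_class 0 (long survivor) or 1 (short survivor).
#' @param config a [cohort_config()].
#' @return list with elements `image` ([image_volume]) and `mask`
#'   ([roi_mask]); attribute `"resized"` is `TRUE` when the drawn diameter
#'   had to be capped to fit the field of view (reported in the cohort log).
#' @export
generate_tumor <- function(patient_class, config) {
  stopifnot(inherits(config, "cohort_config"),
            patient_class %in% c(0, 1))
  dimv <- config$image_dim
  sp <- config$voxel_spacing
  extent <- dimv * sp
  veff <- if (patient_class == 1) config$volume_effect else 1
  dd <- config$mean_diameter * veff * exp(rnorm(1, 0, config$diameter_sdlog))
  # cap so the lesion plus lobes plus the 10%-of-bbox translation margin fits
  dmax <- (min(extent) - 6) / 1.75
  resized <- FALSE
  if (dd > dmax) { dd <- dmax; resized <- TRUE }
  radii <- dd / 2 * exp(rnorm(3, 0, 0.08))
  lobes <- vector("list", config$n_lobes)
  for (l in seq_len(config$n_lobes)) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    t_surf <- 1 / sqrt(sum((u / radii)^2))
    lobes[[l]] <- list(center = u * t_surf,
                       radius = dd / 2 * runif(1, 0.25, 0.4))
  }
  center <- extent / 2 + rnorm(3, 0, 1.5)

  # voxel-centre physical coordinates: (index - 1) * spacing
  span <- max(radii) + max(vapply(lobes, function(l)
    sqrt(sum(l$center^2)) + l$radius, 0))
  lo <- pmax(1, floor((center - span) / sp) - 1)
  hi <- pmin(dimv, ceiling((center + span) / sp) + 3)
  nx <- hi - lo + 1
  xs <- (seq(lo[1], hi[1]) - 1) * sp[1] - center[1]
  ys <- (seq(lo[2], hi[2]) - 1) * sp[2] - center[2]
  zs <- (seq(lo[3], hi[3]) - 1) * sp[3] - center[3]
  gx <- array(xs, nx)
  gy <- aperm(array(ys, nx[c(2, 1, 3)]), c(2, 1, 3))
  gz <- aperm(array(zs, nx[c(3, 1, 2)]), c(2, 3, 1))
  inside <- (gx / radii[1])^2 + (gy / radii[2])^2 + (gz / radii[3])^2 <= 1
  for (l in lobes) {
    inside <- inside |
      ((gx - l$center[1])^2 + (gy - l$center[2])^2 +
         (gz - l$center[3])^2 <= l$radius^2)
  }
  mask <- array(0L, dimv)
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]][inside] <- 1L

  # correlated texture field inside the lesion: smoothed white noise,
  # normalised to unit variance by the kernel l2 norms
  het <- if (patient_class == 1) config$heterogeneity_effect else 1
  field <- array(rnorm(prod(nx)), nx)
  norm <- 1
  for (a in 1:3) {
    sdv <- config$texture_length / sp[a]
    r <- max(1L, as.integer(ceiling(2.5 * sdv)))
    g <- exp(-(seq(-r, r))^2 / (2 * sdv^2))
    g <- g / sum(g)
    field <- array(cpp_conv_axis(as.numeric(field), dim(field), g,
                                 a - 1L, r), nx)
    norm <- norm * sqrt(sum(g^2))
  }
  field <- field / norm

  vox <- array(config$background_hu + rnorm(prod(dimv), 0, config$noise_sd),
               dimv)
  sub <- vox[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  sub[inside] <- config$base_hu + config$texture_sd * het * field[inside]
  vox[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub

  out <- list(image = image_volume(vox, sp), mask = roi_mask(mask, sp))
  attr(out, "resized") <- resized
  out
}

#' Generate a synthetic patient cohort
#'
#' Draws labels, clinical covariates and (optionally) images and masks for
#' `n_patients` patients, then splits them chronologically: the first
#' `floor(train_fraction * n)` patients form the training set, the remainder
#' the test set. The cohort is a pure function of the configuration
#' (including its seed).
#'
#' @param config a [cohort_config()].
#' @param images if `FALSE`, skip image synthesis and return labels and
#'   clinical covariates only (fast; lesion volumes are then the analytic
#'   ellipsoid volumes instead of voxel counts).
#' @return An object of class `synthetic_cohort`: list with `patients` (a
#'   list of per-patient records carrying `image`, `mask`, `label`, `split`
#'   and covariates), `clinical` (a data frame, one row per patient) and
#'   `config`. Messages report any lesion that had to be resized to fit the
#'   field of view.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 10, image_dim = c(32, 32, 32),
#'                                      mean_diameter = 12, seed = 7))
#' table(coh$clinical$split)
#' @export
generate_cohort <- function(config, images = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  n_train <- floor(config$train_fraction * n)
  with_seed(config$seed, {
    labels <- rbinom(n, 1, config$event_rate)
    if (length(unique(labels[seq_len(n_train)])) < 2)
      stop("training split contains a single class; ",
           "choose another seed or event_rate")
    patients <- vector("list", n)
    for (i in seq_len(n)) {
      id <- sprintf("P%03d", i)
      n_lesions <- 1L + rpois(1, 2)
      n_organs <- 1L + rbinom(1, n_lesions - 1L, 0.4)
      ps <- sample(0:2, 1, prob = c(0.32, 0.65, 0.03))
      non_met <- rbinom(1, 1, 0.44)
      if (images) {
        tum <- generate_tumor(labels[i], config)
        if (isTRUE(attr(tum, "resized")))
          rs_log("patient ", id, ": lesion resized to fit field of view")
        largest <- sum(tum$mask$voxels) * prod(config$voxel_spacing)
      } else {
        tum <- list(image = NULL, mask = NULL)
        dd <- config$mean_diameter *
          (if (labels[i] == 1) config$volume_effect else 1) *
          exp(rnorm(1, 0, config$diameter_sdlog))
        largest <- pi / 6 * dd^3
      }
      total <- largest * (1 + 0.5 * (n_lesions - 1L) * runif(1, 0.2, 0.8))
      patients[[i]] <- structure(
        list(patient_id = id, image = tum$image, mask = tum$mask,
             label = labels[i],
             split = if (i <= n_train) "training" else "test",
             n_lesions = n_lesions, n_organs = n_organs,
             performance_status = ps, non_metastatic = non_met,
             largest_volume = largest, total_volume = total),
        class = "synthetic_patient")
    }
    clinical <- data.frame(
      patient_id = vapply(patients, `[[`, "", "patient_id"),
      split = vapply(patients, `[[`, "", "split"),
      label = vapply(patients, `[[`, 0, "label"),
      n_lesions = vapply(patients, `[[`, 0L, "n_lesions"),
      n_organs = vapply(patients, `[[`, 0L, "n_organs"),
      performance_status = vapply(patients, `[[`, 0L, "performance_status"),
      non_metastatic = vapply(patients, `[[`, 0L, "non_metastatic"),
      largest_volume_mm3 = vapply(patients, `[[`, 0, "largest_volume"),
      total_volume_mm3 = vapply(patients, `[[`, 0, "total_volume"),
      stringsAsFactors = FALSE)
    structure(list(patients = patients, clinical = clinical, config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cl <- x$clinical
  cat("<synthetic_cohort> ", nrow(cl), " patients (",
      sum(cl$split == "training"), " training / ", sum(cl$split == "test"),
      " test), ", sum(cl$label), " short survivors\n", sep = "")
  invisible(x)
}

#' Write / read a cohort as NIfTI volumes plus a clinical CSV
#'
#' `write_cohort()` writes `<id>_img.nii.gz` and `<id>_mask.nii.gz` per
#' patient plus `clinical.csv` (columns `patient_id, split, label,
#' n_lesions, n_organs, performance_status, non_metastatic,
#' total_volume_mm3`). `read_cohort()` reads the set back; voxel arrays and
#' spacing round-trip exactly, and largest-lesion volumes are recomputed
#' from the masks.
#'
#' @param cohort a `synthetic_cohort` with images.
#' @param dir target directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   a `synthetic_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$patients[[1]]$image))
    stop("cohort was generated without images")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cohort$patients) {
    write_nifti_volume(p$image, file.path(dir, paste0(p$patient_id, "_img.nii.gz")))
    write_nifti_volume(p$mask, file.path(dir, paste0(p$patient_id, "_mask.nii.gz")))
  }
  cl <- cohort$clinical[, c("patient_id", "split", "label", "n_lesions",
                            "n_organs", "performance_status",
                            "non_metastatic", "total_volume_mm3")]
  write.csv(cl, file.path(dir, "clinical.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cl <- read.csv(file.path(dir, "clinical.csv"), stringsAsFactors = FALSE)
  patients <- vector("list", nrow(cl))
  largest <- numeric(nrow(cl))
  for (i in seq_len(nrow(cl))) {
    id <- cl$patient_id[i]
    img <- read_image_volume(file.path(dir, paste0(id, "_img.nii.gz")))
    msk <- read_roi_mask(file.path(dir, paste0(id, "_mask.nii.gz")))
    stopifnot_aligned(img, msk)
    largest[i] <- sum(msk$voxels) * prod(msk$spacing)
    patients[[i]] <- structure(
      list(patient_id = id, image = img, mask = msk, label = cl$label[i],
           split = cl$split[i], n_lesions = cl$n_lesions[i],
           n_organs = cl$n_organs[i],
           performance_status = cl$performance_status[i],
           non_metastatic = cl$non_metastatic[i],
           largest_volume = largest[i],
           total_volume = cl$total_volume_mm3[i]),
      class = "synthetic_patient")
  }
  cl$largest_volume_mm3 <- largest
  structure(list(patients = patients, clinical = cl, config = NULL),
            class = "synthetic_cohort")
}
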