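# End-to-end orchestration: simulate -> preprocess -> extract -> select ->
# train -> evaluate, from a single validated configuration, with logging and
# fixed seeds. run_study() is the in-memory engine; run_pipeline() chains
# the four file-based stages (simulate / extract / fit / evaluate).

BASELINE_VARS <- c("largest_volume_mm3", "total_volume_mm3", "n_lesions",
                   "n_organs", "performance_status", "non_metastatic")

#' Full pipeline configuration
#'
#' Bundles the cohort settings, preprocessing knobs, extraction knobs,
#' selection thresholds and model settings, plus one master seed from which
#' every stage seed is derived (cohort generation, SMOTE/CV folds,
#' bootstrap). A run's outputs carry a copy of the exact configuration used.
#'
#' @param cohort a [cohort_config()].
#' @param sigma,kernel Gaussian denoising settings (voxels).
#' @param target_spacing isotropic resampling target, mm.
#' @param bin_width discretisation bin width, HU.
#' @param wavelet wavelet family.
#' @param icc_threshold stability threshold on ICC.
#' @param perturb_fraction ROI translation magnitude (fraction of bounding
#'   box).
#' @param signature a [signature_config()].
#' @param n_boot bootstrap draws for the AUC interval.
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), sigma = 0.5,
                       kernel = c(3, 3, 3), target_spacing = 2.0,
                       bin_width = 0.5, wavelet = "coif1",
                       icc_threshold = 0.75, perturb_fraction = 0.10,
                       signature = signature_config(), n_boot = 2000,
                       seed = 1) {
  stopifnot(inherits(cohort, "cohort_config"))
  cohort$seed <- derive_seed(seed, 1L)
  structure(list(cohort = cohort, sigma = sigma, kernel = kernel,
                 target_spacing = target_spacing, bin_width = bin_width,
                 wavelet = wavelet, icc_threshold = icc_threshold,
                 perturb_fraction = perturb_fraction, signature = signature,
                 n_boot = n_boot, seed = as.integer(seed)),
            class = "run_config")
}

# restrict preprocessing to a generous neighbourhood of the lesion: 16 mm
# (at least 6 voxels) of margin keeps denoising, B-spline resampling and the
# wavelet support unaffected within the ROI while skipping distant
# background
crop_patient <- function(image, mask, margin_mm = 16) {
  bb <- mask_bbox(mask$voxels)
  pad <- pmax(ceiling(margin_mm / image$spacing), 6)
  d <- dim(image$voxels)
  lo <- pmax(bb$lo - pad, 1)
  hi <- pmin(bb$hi + pad, d)
  iv <- image$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  mv <- mask$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  list(image = image_volume(iv, image$spacing, image$origin),
       mask = new_roi_mask(mv, mask$spacing, mask$origin))
}

# recursively reject configuration keys the schema does not know
check_known_keys <- function(x, known, where) {
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown configuration key", if (length(unknown) > 1) "s", " in ",
         where, ": ", paste(unknown, collapse = ", "))
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds flat key/value sections (`cohort`, `preprocess`,
#' `extract`, `select`, `model`, `evaluate`, `seed`); any key the schema
#' does not know is an error, not a warning.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  check_known_keys(y, c("cohort", "preprocess", "extract", "select",
                        "model", "evaluate", "seed"), "top level")
  ccall <- y$cohort
  check_known_keys(ccall, names(formals(cohort_config)), "cohort")
  cohort <- do.call(cohort_config, ccall %||% list())
  pre <- y$preprocess %||% list()
  check_known_keys(pre, c("sigma", "kernel", "target_spacing"), "preprocess")
  ext <- y$extract %||% list()
  check_known_keys(ext, c("bin_width", "wavelet"), "extract")
  sel <- y$select %||% list()
  check_known_keys(sel, c("icc_threshold", "perturb_fraction",
                          "spearman_threshold", "auc_threshold", "n_folds",
                          "n_lambda", "smote_k"), "select")
  mod <- y$model %||% list()
  check_known_keys(mod, c("C", "degree", "coef0", "gamma", "auc_fallback"),
                   "model")
  ev <- y$evaluate %||% list()
  check_known_keys(ev, c("n_boot"), "evaluate")
  sig <- signature_config(
    spearman_threshold = sel$spearman_threshold %||% 0.85,
    auc_threshold = sel$auc_threshold %||% 0.7,
    n_folds = sel$n_folds %||% 5, n_lambda = sel$n_lambda %||% 50,
    smote_k = sel$smote_k %||% 5, svm_C = mod$C %||% 1,
    svm_degree = mod$degree %||% 3, svm_coef0 = mod$coef0 %||% 0,
    svm_gamma = mod$gamma, auc_fallback = mod$auc_fallback %||% TRUE)
  run_config(cohort = cohort, sigma = pre$sigma %||% 0.5,
             kernel = pre$kernel %||% c(3, 3, 3),
             target_spacing = pre$target_spacing %||% 2.0,
             bin_width = ext$bin_width %||% 0.5,
             wavelet = ext$wavelet %||% "coif1",
             icc_threshold = sel$icc_threshold %||% 0.75,
             perturb_fraction = sel$perturb_fraction %||% 0.10,
             signature = sig, n_boot = ev$n_boot %||% 2000,
             seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preprocess and extract features for a whole cohort
#'
#' Denoises and resamples every patient, extracts the 536-feature vector,
#' and — for training patients — repeats the extraction under the seven-mask
#' perturbation set (unperturbed + six 10%-of-bounding-box translations of
#' the resampled mask) for the stability analysis. Wavelet bands and shape
#' features are computed once per patient; translated masks reuse them
#' (bands depend only on the image, shape features are
#' translation-invariant).
#'
#' @param cohort a `synthetic_cohort` (or any cohort read by
#'   [read_cohort()]).
#' @param config a [run_config()].
#' @param logfile optional log file.
#' @return list with `features` (patients x 536 matrix, row names = patient
#'   ids), `perturbed` (list of 7 matrices over training patients, or
#'   `NULL` if no training rows), `clinical` and `train` (logical index).
#' @export
extract_cohort <- function(cohort, config = run_config(), logfile = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cl <- cohort$clinical
  n <- nrow(cl)
  train <- cl$split == "training"
  feats <- matrix(NA_real_, n, 536,
                  dimnames = list(cl$patient_id, feature_names()))
  pert <- NULL
  if (any(train))
    pert <- replicate(7, matrix(NA_real_, sum(train), 536,
                                dimnames = list(cl$patient_id[train],
                                                feature_names())),
                      simplify = FALSE)
  ti <- 0L
  for (i in seq_len(n)) {
    p <- cohort$patients[[i]]
    cr <- crop_patient(p$image, p$mask)
    pre <- preprocess_patient(cr$image, cr$mask, sigma = config$sigma,
                              kernel = config$kernel,
                              target = config$target_spacing,
                              patient_id = p$patient_id)
    if (train[i]) {
      masks <- perturbation_set(pre$mask, config$perturb_fraction)
      fm <- extract_features_multi(pre$image, masks, config$bin_width,
                                   config$wavelet)
      feats[i, ] <- fm[1, ]
      ti <- ti + 1L
      for (k in 1:7) pert[[k]][ti, ] <- fm[k, ]
    } else {
      feats[i, ] <- extract_features_multi(pre$image, list(pre$mask),
                                           config$bin_width,
                                           config$wavelet)[1, ]
    }
  }
  bad <- which(!is.finite(feats), arr.ind = TRUE)
  if (nrow(bad))
    rs_log("non-finite features for patients: ",
           paste(unique(rownames(feats)[bad[, 1]]), collapse = ", "),
           logfile = logfile)
  list(features = feats, perturbed = pert, clinical = cl, train = train)
}

#' Run the full study in memory
#'
#' Generates the synthetic cohort, preprocesses and extracts features,
#' performs the stability analysis on the training patients, fits the
#' radiomic signature on the training set and evaluates it frozen on the
#' test set, including the clinical-baseline comparison and the
#' signature-volume correlation.
#'
#' @param config a [run_config()].
#' @param logfile optional log file.
#' @return list with `cohort` (clinical table), `features`, `stability`
#'   (ICC report), `model` (the `radiomic_signature`), `predictions`
#'   (test-set calls) and `report` (an `evaluation_report`).
#' @export
run_study <- function(config = run_config(), logfile = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(config$cohort)
  ex <- extract_cohort(cohort, config, logfile)
  stab <- select_stable(ex$perturbed, config$icc_threshold)
  model <- fit_signature(ex$features[ex$train, stab$features, drop = FALSE],
                         ex$clinical$label[ex$train],
                         config = config$signature,
                         seed = derive_seed(config$seed, 2L))
  test <- !ex$train
  pred <- predict(model,
                  ex$features[test, stab$features, drop = FALSE])
  clin <- ex$clinical[test, ]
  clin$largest_volume_mm3 <- ex$features[test, "original_shape_VoxelVolume"]
  report <- evaluation_report(
    scores = pred$score, calls = pred$call, labels = clin$label,
    clinical = clin[, BASELINE_VARS], volumes = clin$largest_volume_mm3,
    n_boot = config$n_boot, seed = derive_seed(config$seed, 3L))
  list(cohort = ex$clinical, features = ex$features,
       stability = stab$report, model = model, predictions = pred,
       report = report)
}

# ---------------------------------------------------------------------------
# file-based stages; run_pipeline() chains them and equals their composition
# ---------------------------------------------------------------------------

#' Pipeline stages with file artifacts
#'
#' Each stage reads the previous stage's artifacts from `out_dir` and writes
#' its own: `simulate` writes the cohort (NIfTI volumes + `clinical.csv`),
#' `extract` writes `features.csv` and `stability_report.csv`, `fit` writes
#' `model.json` and `signature_scores.csv`, `evaluate` writes `report.json`
#' and `report.csv`. [run_pipeline()] chains the four and also stores the
#' configuration (`config.yaml`) and a `run.log`.
#'
#' @param config a [run_config()] (or, for [run_pipeline()], a path to a
#'   YAML configuration).
#' @param out_dir output directory.
#' @return each stage invisibly returns the paths it wrote;
#'   `run_pipeline()` invisibly returns `out_dir`.
#' @export
pipeline_simulate <- function(config, out_dir) {
  log <- file.path(out_dir, "run.log")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rs_log("stage simulate: n = ", config$cohort$n_patients, logfile = log)
  cohort <- generate_cohort(config$cohort)
  write_cohort(cohort, file.path(out_dir, "cohort"))
  invisible(file.path(out_dir, "cohort"))
}

#' @rdname pipeline_simulate
#' @export
pipeline_extract <- function(config, out_dir) {
  log <- file.path(out_dir, "run.log")
  rs_log("stage extract", logfile = log)
  cohort <- read_cohort(file.path(out_dir, "cohort"))
  ex <- extract_cohort(cohort, config, logfile = log)
  stab <- select_stable(ex$perturbed, config$icc_threshold)
  rs_log("stability: ", length(stab$features), " of ",
         ncol(ex$features), " features stable (ICC >= ",
         config$icc_threshold, ")", logfile = log)
  fdf <- data.frame(patient_id = rownames(ex$features), ex$features,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(fdf, file.path(out_dir, "features.csv"), row.names = FALSE)
  write.csv(stab$report, file.path(out_dir, "stability_report.csv"),
            row.names = FALSE)
  invisible(file.path(out_dir, c("features.csv", "stability_report.csv")))
}

#' @rdname pipeline_simulate
#' @export
pipeline_fit <- function(config, out_dir) {
  log <- file.path(out_dir, "run.log")
  rs_log("stage fit", logfile = log)
  feats <- read_features_csv(file.path(out_dir, "features.csv"))
  stab <- read.csv(file.path(out_dir, "stability_report.csv"),
                   stringsAsFactors = FALSE)
  cl <- read.csv(file.path(out_dir, "cohort", "clinical.csv"),
                 stringsAsFactors = FALSE)
  cl <- cl[match(rownames(feats), cl$patient_id), ]
  train <- cl$split == "training"
  stable <- stab$feature[stab$pass]
  model <- fit_signature(feats[train, stable, drop = FALSE],
                         cl$label[train], config = config$signature,
                         seed = derive_seed(config$seed, 2L))
  signature_to_json(model, file.path(out_dir, "model.json"))
  pred <- predict(model, feats[, stable, drop = FALSE])
  pred$split <- cl$split
  pred$label <- cl$label
  write.csv(pred[, c("patient_id", "split", "label", "score", "call")],
            file.path(out_dir, "signature_scores.csv"), row.names = FALSE)
  invisible(file.path(out_dir, c("model.json", "signature_scores.csv")))
}

#' @rdname pipeline_simulate
#' @export
pipeline_evaluate <- function(config, out_dir) {
  log <- file.path(out_dir, "run.log")
  rs_log("stage evaluate", logfile = log)
  sc <- read.csv(file.path(out_dir, "signature_scores.csv"),
                 stringsAsFactors = FALSE)
  feats <- read_features_csv(file.path(out_dir, "features.csv"))
  cl <- read.csv(file.path(out_dir, "cohort", "clinical.csv"),
                 stringsAsFactors = FALSE)
  cl <- cl[match(sc$patient_id, cl$patient_id), ]
  cl$largest_volume_mm3 <- feats[sc$patient_id, "original_shape_VoxelVolume"]
  test <- sc$split == "test"
  report <- evaluation_report(
    scores = sc$score[test], calls = sc$call[test], labels = sc$label[test],
    clinical = cl[test, BASELINE_VARS],
    volumes = cl$largest_volume_mm3[test],
    n_boot = config$n_boot, seed = derive_seed(config$seed, 3L))
  write_report(report, out_dir)
  invisible(file.path(out_dir, c("report.json", "report.csv")))
}

read_features_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$patient_id
  m
}

#' @rdname pipeline_simulate
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass_deep(config), file.path(out_dir, "config.yaml"))
  log <- file.path(out_dir, "run.log")
  stages <- list(simulate = pipeline_simulate, extract = pipeline_extract,
                 fit = pipeline_fit, evaluate = pipeline_evaluate)
  for (nm in names(stages)) {
    ok <- tryCatch({ stages[[nm]](config, out_dir); TRUE },
                   error = function(e) {
                     rs_log("stage ", nm, " FAILED: ", conditionMessage(e),
                            logfile = log)
                     stop("pipeline stage '", nm, "' failed: ",
                          conditionMessage(e), call. = FALSE)
                   })
  }
  rs_log("pipeline complete", logfile = log)
  invisible(out_dir)
}

# strip S3 classes recursively so yaml serialisation is plain
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
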