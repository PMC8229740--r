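# Radiomic feature extraction: 536 features per patient
#   original image:  shape (14) + first-order (18) + GLCM (24) + GLRLM (16)
#   8 wavelet bands: first-order (18) + GLCM (24) + GLRLM (16) each
# Texture matrices use fixed-bin-width discretisation (default 0.5 HU),
# distance 1, the 13 unique 3D directions, and direction-averaged features.

FO_NAMES <- c("Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
              "90Percentile", "Maximum", "Mean", "Median",
              "InterquartileRange", "Range", "MeanAbsoluteDeviation",
              "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
              "Kurtosis", "Variance", "Uniformity")

GLCM_NAMES <- c("Autocorrelation", "JointAverage", "ClusterProminence",
                "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
                "DifferenceAverage", "DifferenceEntropy",
                "DifferenceVariance", "JointEnergy", "JointEntropy", "Imc1",
                "Imc2", "Idm", "Idmn", "Id", "Idn", "InverseVariance",
                "MaximalCorrelationCoefficient", "MaximumProbability",
                "SumAverage", "SumEntropy", "SumSquares")

GLRLM_NAMES <- c("ShortRunEmphasis", "LongRunEmphasis",
                 "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                 "RunLengthNonUniformity",
                 "RunLengthNonUniformityNormalized", "RunPercentage",
                 "GrayLevelVariance", "RunVariance", "RunEntropy",
                 "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
                 "ShortRunLowGrayLevelEmphasis",
                 "ShortRunHighGrayLevelEmphasis",
                 "LongRunLowGrayLevelEmphasis",
                 "LongRunHighGrayLevelEmphasis")

SHAPE_NAMES <- c("MeshVolume", "VoxelVolume", "SurfaceArea",
                 "SurfaceVolumeRatio", "Sphericity", "Maximum3DDiameter",
                 "Maximum2DDiameterSlice", "Maximum2DDiameterColumn",
                 "Maximum2DDiameterRow", "MajorAxisLength",
                 "MinorAxisLength", "LeastAxisLength", "Elongation",
                 "Flatness")

WAVELET_BAND_NAMES <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL",
                        "HHH")

#' Names of the full 536-feature roster, in extraction order
#'
#' The naming schema is `<image>_<family>_<feature>` with image `original`
#' or `wavelet-LLL` ... `wavelet-HHH` (band letters give the filter applied
#' along x, y, z: H = high-pass, L = low-pass).
#'
#' @return character vector of length 536.
#' @export
feature_names <- function() {
  orig <- c(paste0("original_shape_", SHAPE_NAMES),
            paste0("original_firstorder_", FO_NAMES),
            paste0("original_glcm_", GLCM_NAMES),
            paste0("original_glrlm_", GLRLM_NAMES))
  wav <- unlist(lapply(WAVELET_BAND_NAMES, function(b)
    c(paste0("wavelet-", b, "_firstorder_", FO_NAMES),
      paste0("wavelet-", b, "_glcm_", GLCM_NAMES),
      paste0("wavelet-", b, "_glrlm_", GLRLM_NAMES))))
  c(orig, wav)
}

# ---------------------------------------------------------------------------
# discretisation
# ---------------------------------------------------------------------------

# array-level discretiser; grid = numeric 3D array, mask = integer 0/1 array
discretize_grid <- function(grid, mask, bin_width) {
  vals <- grid[mask == 1L]
  anchor <- min(vals)
  lev_roi <- as.integer(1L + floor((vals - anchor) / bin_width))
  levels <- array(0L, dim(grid))
  levels[mask == 1L] <- lev_roi
  ng <- max(lev_roi)
  structure(list(levels = levels, bin_width = bin_width, bin_anchor = anchor,
                 n_levels = ng, dim = dim(grid)),
            class = "discretized_roi",
            degenerate = ng == 1L)
}

#' Fixed-bin-width discretisation of the ROI intensities
#'
#' Maps each ROI voxel intensity to an integer grey level
#' `1 + floor((I - min_ROI) / bin_width)`; the ROI minimum anchors bin 1 and
#' the ROI maximum maps to the highest level `N_g`.
#'
#' @param image an [image_volume].
#' @param mask the aligned [roi_mask].
#' @param bin_width bin width in HU (default 0.5).
#' @return A `discretized_roi`: list with `levels` (integer grid, 0 outside
#'   the ROI), `bin_width`, `bin_anchor` and `n_levels`. A constant ROI
#'   yields a single level and is flagged via `attr(, "degenerate")`.
#' @export
discretize <- function(image, mask, bin_width = 0.5) {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "roi_mask"))
  stopifnot_aligned(image, mask)
  if (bin_width <= 0) stop("bin_width must be positive")
  d <- discretize_grid(image$voxels, mask$voxels, bin_width)
  d$spacing <- image$spacing
  if (isTRUE(attr(d, "degenerate")))
    rs_log("constant ROI: single grey level, texture features degenerate")
  d
}

# ---------------------------------------------------------------------------
# shape features (mask-only; computed on the original mask once)
# ---------------------------------------------------------------------------

#' Morphological (shape) features of a mask
#'
#' Fourteen size-and-shape descriptors. Surface quantities come from a
#' marching-tetrahedra mesh of the mollified mask (Gaussian-smoothed binary
#' indicator, sigma 0.8 voxel, iso-level 0.5, linear edge interpolation),
#' which removes voxelisation staircase bias: a digital ball of radius >= 8
#' voxels measures sphericity ~0.99. Axis lengths derive from the principal
#' components of the foreground voxel-centre coordinates (2 sqrt of
#' eigenvalues times 2); maximum diameters are the largest pairwise surface
#' voxel distances in 3D and within each grid plane.
#'
#' @param mask a [roi_mask].
#' @return named numeric vector of length 14 (mm-based units).
#' @export
shape_features <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  m <- mask$voxels
  sp <- mask$spacing
  cnt <- sum(m)
  voxvol <- prod(sp)

  # crop for speed; geometry is translation invariant
  bb <- mask_bbox(m)
  mc <- crop_array(m, bb, pad = 4)

  # mollified indicator for the surface mesh
  f <- mc * 1.0
  g <- exp(-(-3:3)^2 / (2 * 0.8^2)); g <- g / sum(g)
  for (a in 1:3)
    f <- array(cpp_conv_axis(as.numeric(f), dim(f), g, a - 1L, 3L), dim(f))
  if (max(f) <= 0.5)     # tiny mask: fall back to the binary indicator
    f <- mc * 1.0
  mesh <- cpp_mesh_shape(as.numeric(f), dim(f), sp, 0.5)
  area <- mesh$surface_area
  vol <- mesh$mesh_volume

  # principal axes from physical voxel-centre coordinates
  idx <- which(mc == 1L, arr.ind = TRUE)
  phys <- sweep(idx, 2, sp, `*`)
  if (nrow(phys) > 1) {
    cv <- stats::cov(phys) * (nrow(phys) - 1) / nrow(phys)
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  axis_len <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  # boundary voxels: foreground with at least one 6-neighbour background
  dmc <- dim(mc)
  pad <- array(0L, dmc + 2L)
  pad[2:(dmc[1] + 1), 2:(dmc[2] + 1), 2:(dmc[3] + 1)] <- mc
  core <- pad[2:(dmc[1] + 1), 2:(dmc[2] + 1), 2:(dmc[3] + 1)] == 1L
  nb <- pad[1:dmc[1], 2:(dmc[2] + 1), 2:(dmc[3] + 1)] &
        pad[3:(dmc[1] + 2), 2:(dmc[2] + 1), 2:(dmc[3] + 1)] &
        pad[2:(dmc[1] + 1), 1:dmc[2], 2:(dmc[3] + 1)] &
        pad[2:(dmc[1] + 1), 3:(dmc[2] + 2), 2:(dmc[3] + 1)] &
        pad[2:(dmc[1] + 1), 2:(dmc[2] + 1), 1:dmc[3]] &
        pad[2:(dmc[1] + 1), 2:(dmc[2] + 1), 3:(dmc[3] + 2)]
  boundary <- which(core & !nb, arr.ind = TRUE)
  bphys <- sweep(boundary, 2, sp, `*`)
  dm <- cpp_max_diameters(bphys, boundary)

  out <- c(vol, cnt * voxvol, area, area / vol,
           (36 * pi * vol^2)^(1 / 3) / area,
           dm[1], dm[2], dm[3], dm[4],
           axis_len[1], axis_len[2], axis_len[3], elong, flat)
  names(out) <- paste0("original_shape_", SHAPE_NAMES)
  out
}

# ---------------------------------------------------------------------------
# first order / texture families
# ---------------------------------------------------------------------------

#' First-order intensity statistics
#'
#' Eighteen distributional features of the ROI intensities. `Entropy` and
#' `Uniformity` are computed on the fixed-bin-width discretised levels;
#' `Kurtosis` follows the non-excess (Pearson) convention, so a normal
#' distribution scores 3. A zero-variance ROI yields `NaN` skewness and
#' kurtosis and is flagged downstream.
#'
#' @param image an [image_volume].
#' @param mask the aligned [roi_mask].
#' @param bin_width discretisation bin width, HU.
#' @return named numeric vector of length 18.
#' @export
first_order_features <- function(image, mask, bin_width = 0.5) {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "roi_mask"))
  stopifnot_aligned(image, mask)
  if (sum(mask$voxels) < 2) stop("first-order features need >= 2 ROI voxels")
  droi <- discretize_grid(image$voxels, mask$voxels, bin_width)
  vals <- image$voxels[mask$voxels == 1L]
  out <- cpp_firstorder(vals, droi$levels[mask$voxels == 1L], droi$n_levels,
                        prod(image$spacing))
  names(out) <- paste0("original_firstorder_", FO_NAMES)
  out
}

#' Grey-level co-occurrence features
#'
#' Twenty-four GLCM features from symmetric co-occurrence matrices at
#' distance 1 over the 13 unique 3D directions, each feature computed per
#' direction and then averaged. With a single grey level, contrast-type
#' features are 0 and correlation-type features are returned as their
#' degenerate limits.
#'
#' @param droi a [discretize()]d ROI.
#' @return named numeric vector of length 24.
#' @export
glcm_features <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  out <- cpp_glcm_features(droi$levels, droi$dim, droi$n_levels)
  names(out) <- paste0("original_glcm_", GLCM_NAMES)
  out
}

#' @rdname glcm_features
#' @return `glcm_matrix()` returns the normalised symmetric co-occurrence
#'   probabilities as a data frame with columns `direction`, `i`, `j`, `p`
#'   (each direction sums to 1).
#' @export
glcm_matrix <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  cpp_glcm_triplets(droi$levels, droi$dim, droi$n_levels)
}

#' Grey-level run-length features
#'
#' Sixteen GLRLM features. A run is a maximal collinear segment of
#' same-level ROI voxels; runs are counted per direction (13 unique 3D
#' directions) and features averaged across directions. Conservation holds
#' per direction: the run-length-weighted sum of counts equals the number of
#' ROI voxels.
#'
#' @param droi a [discretize()]d ROI.
#' @return named numeric vector of length 16.
#' @export
glrlm_features <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  out <- cpp_glrlm_features(droi$levels, droi$dim, droi$n_levels)
  names(out) <- paste0("original_glrlm_", GLRLM_NAMES)
  out
}

#' @rdname glrlm_features
#' @return `glrlm_matrix()` returns a list with `triplets` (data frame
#'   `direction`, `i` = grey level, `j` = run length, `count`) plus per-
#'   direction totals `n_runs` and `n_voxels`.
#' @export
glrlm_matrix <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  cpp_glrlm_triplets(droi$levels, droi$dim, droi$n_levels)
}

# ---------------------------------------------------------------------------
# wavelet decomposition
# ---------------------------------------------------------------------------

wavelet_filters <- function(wavelet = c("coif1", "haar")) {
  wavelet <- match.arg(wavelet)
  if (wavelet == "coif1") {
    lo <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
            0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
    hi <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
            0.3848648468648578, 0.07273261951252645, -0.015655728135791993)
  } else {
    lo <- c(1, 1) / sqrt(2)
    hi <- c(-1, 1) / sqrt(2)
  }
  list(lo = lo, hi = hi)
}

# array-level single-level undecimated separable decomposition
wavelet_bands_grid <- function(grid, wavelet = "coif1") {
  fl <- wavelet_filters(wavelet)
  ctr <- as.integer(length(fl$lo) %/% 2L)
  d <- dim(grid)
  if (any(d < length(fl$lo)))
    stop("image smaller than the wavelet filter support (",
         length(fl$lo), " voxels per axis)")
  conv <- function(a, f, axis)
    array(cpp_conv_axis(as.numeric(a), d, f, axis, ctr), d)
  bx <- list(L = conv(grid, fl$lo, 0L), H = conv(grid, fl$hi, 0L))
  out <- vector("list", 8)
  names(out) <- WAVELET_BAND_NAMES
  for (cx in c("L", "H")) {
    for (cy in c("L", "H")) {
      bxy <- conv(bx[[cx]], if (cy == "L") fl$lo else fl$hi, 1L)
      for (cz in c("L", "H")) {
        out[[paste0(cx, cy, cz)]] <-
          conv(bxy, if (cz == "L") fl$lo else fl$hi, 2L)
      }
    }
  }
  out
}

#' One-level undecimated 3D wavelet decomposition
#'
#' Separable stationary (undecimated) wavelet transform, one level, eight
#' sub-bands. Band labels give the filter applied along each axis in x, y,
#' z order: `HLH` means high-pass along x, low-pass along y, high-pass
#' along z. Default wavelet is Coiflet-1; boundaries are mirror-padded.
#'
#' @param image an [image_volume].
#' @param wavelet `"coif1"` (default) or `"haar"`.
#' @return named list of eight [image_volume]s (`LLL` ... `HHH`).
#' @export
wavelet_bands <- function(image, wavelet = "coif1") {
  stopifnot(inherits(image, "image_volume"))
  lapply(wavelet_bands_grid(image$voxels, wavelet),
         image_volume, spacing = image$spacing, origin = image$origin)
}

# ---------------------------------------------------------------------------
# full extraction
# ---------------------------------------------------------------------------

# first-order + GLCM + GLRLM (58 values) for one intensity grid and mask
intensity_family_features <- function(grid, mask, bin_width, voxvol, prefix) {
  droi <- discretize_grid(grid, mask, bin_width)
  vals <- grid[mask == 1L]
  fo <- cpp_firstorder(vals, droi$levels[mask == 1L], droi$n_levels, voxvol)
  gl <- cpp_glcm_features(droi$levels, droi$dim, droi$n_levels)
  rl <- cpp_glrlm_features(droi$levels, droi$dim, droi$n_levels)
  out <- c(fo, gl, rl)
  names(out) <- c(paste0(prefix, "_firstorder_", FO_NAMES),
                  paste0(prefix, "_glcm_", GLCM_NAMES),
                  paste0(prefix, "_glrlm_", GLRLM_NAMES))
  out
}

# shared workhorse: one preprocessed image, one or more aligned masks.
# Wavelet bands are computed once; shape features come from the first
# (unperturbed) mask only, since rigid translation leaves them unchanged.
extract_features_multi <- function(image, masks, bin_width = 0.5,
                                   wavelet = "coif1") {
  stopifnot(inherits(image, "image_volume"))
  for (m in masks) stopifnot_aligned(image, m)
  # crop to the union bounding box (+ margin for filter support)
  um <- masks[[1]]$voxels
  if (length(masks) > 1)
    for (m in masks[-1]) um <- pmax(um, m$voxels)
  bb <- mask_bbox(um)
  grid <- crop_array(image$voxels, bb, pad = 5)
  voxvol <- prod(image$spacing)
  bands <- wavelet_bands_grid(grid, wavelet)
  shp <- shape_features(masks[[1]])
  out <- matrix(NA_real_, nrow = length(masks), ncol = 536,
                dimnames = list(NULL, feature_names()))
  for (k in seq_along(masks)) {
    mgrid <- crop_array(masks[[k]]$voxels, bb, pad = 5)
    if (sum(mgrid) < 2) stop("mask has fewer than 2 voxels after cropping")
    row <- c(shp,
             intensity_family_features(grid, mgrid, bin_width, voxvol,
                                       "original"))
    for (b in WAVELET_BAND_NAMES)
      row <- c(row, intensity_family_features(bands[[b]], mgrid, bin_width,
                                              voxvol, paste0("wavelet-", b)))
    out[k, ] <- row[colnames(out)]
  }
  out
}

#' Extract the full 536-feature vector
#'
#' Computes all radiomic features from a preprocessed image and mask: 14
#' shape features (original mask only), then 18 first-order + 24 GLCM + 16
#' GLRLM features on the original image and on each of the 8 undecimated
#' wavelet sub-bands (rediscretised per band with the same bin width).
#'
#' @param image a preprocessed [image_volume].
#' @param mask the aligned [roi_mask].
#' @param bin_width discretisation bin width, HU (default 0.5).
#' @param wavelet wavelet family for the sub-band decomposition.
#' @return named numeric vector of length 536. Non-finite entries (possible
#'   for degenerate ROIs) are flagged via `attr(, "nonfinite")`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_patients = 10, seed = 3))
#' p <- coh$patients[[1]]
#' pre <- preprocess_patient(p$image, p$mask)
#' fv <- extract_features(pre$image, pre$mask)
#' length(fv)  # 536
#' }
#' @export
extract_features <- function(image, mask, bin_width = 0.5,
                             wavelet = "coif1") {
  out <- extract_features_multi(image, list(mask), bin_width, wavelet)[1, ]
  bad <- !is.finite(out)
  if (any(bad)) {
    rs_log("non-finite features: ", paste(names(out)[bad], collapse = ", "))
    attr(out, "nonfinite") <- names(out)[bad]
  }
  out
}
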