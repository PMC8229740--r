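# Feature stability under ROI perturbation: features are recomputed with the
# mask translated by 10% of its bounding box along each axis and screened by
# a one-way random-effects intraclass correlation coefficient.

#' Translate a mask by a fraction of its bounding box
#'
#' Shifts the mask rigidly by `round(fraction * bounding-box extent)` voxels
#' along one axis. The shift must round to at least one voxel, and the
#' translated mask must stay inside the grid (synthetic cohorts pad their
#' field of view accordingly); the voxel count is preserved exactly.
#'
#' @param mask a [roi_mask].
#' @param axis 1, 2 or 3.
#' @param sign +1 or -1.
#' @param fraction fraction of the bounding-box extent (default 0.10).
#' @return the translated [roi_mask].
#' @export
translate_mask <- function(mask, axis, sign, fraction = 0.10) {
  stopifnot(inherits(mask, "roi_mask"), axis %in% 1:3, sign %in% c(-1, 1))
  m <- mask$voxels
  bb <- mask_bbox(m)
  extent <- bb$hi[axis] - bb$lo[axis] + 1L
  shift <- as.integer(round(fraction * extent))
  if (shift < 1L)
    stop("translation rounds to zero voxels (bounding box too small)")
  d <- dim(m)
  if ((sign > 0 && bb$hi[axis] + shift > d[axis]) ||
      (sign < 0 && bb$lo[axis] - shift < 1L))
    stop("translation would move the mask outside the image bounds")
  out <- array(0L, d)
  src <- lapply(seq_len(3), function(a) seq_len(d[a]))
  dst <- src
  if (sign > 0) {
    src[[axis]] <- 1:(d[axis] - shift); dst[[axis]] <- (shift + 1):d[axis]
  } else {
    src[[axis]] <- (shift + 1):d[axis]; dst[[axis]] <- 1:(d[axis] - shift)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  new_roi_mask(out, mask$spacing, mask$origin)  # voxel set shifted rigidly
}

#' Build the perturbation set for one mask
#'
#' The unperturbed mask plus its six axis-aligned translations
#' (+x, -x, +y, -y, +z, -z), each by 10% of the bounding-box extent —
#' seven measurements per feature.
#'
#' @inheritParams translate_mask
#' @return list of seven [roi_mask]s, the first being the original.
#' @export
perturbation_set <- function(mask, fraction = 0.10) {
  out <- list(mask)
  for (axis in 1:3)
    for (s in c(1, -1))
      out[[length(out) + 1L]] <- translate_mask(mask, axis, s, fraction)
  out
}

#' One-way random-effects intraclass correlation coefficient, ICC(1,1)
#'
#' `ICC(1,1) = (MS_between - MS_within) / (MS_between + (k-1) MS_within)`
#' from the one-way ANOVA decomposition of a patients x measurements
#' matrix. The one-way form treats the perturbed segmentations as
#' exchangeable rather than as fixed raters. The coefficient can be
#' negative; a matrix with zero total variance returns 1 with
#' `attr(, "degenerate") = TRUE`.
#'
#' @param values numeric matrix, patients in rows (>= 2), repeated
#'   measurements in columns (>= 2).
#' @return a single ICC value in (-Inf, 1].
#' @export
icc <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) stop("icc needs >= 2 patients and >= 2 measurements")
  rm_ <- rowMeans(values)
  gm <- mean(values)
  ssb <- k * sum((rm_ - gm)^2)
  ssw <- sum((values - rm_)^2)
  if (ssb + ssw < .Machine$double.eps * max(1, gm^2) * n * k)
    return(structure(1, degenerate = TRUE))
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  if (msw == 0) return(1)
  (msb - msw) / (msb + (k - 1) * msw)
}

#' Select features stable under ROI perturbation
#'
#' Computes ICC(1,1) across the perturbation measurements for every feature
#' (training patients only) and keeps those with ICC at or above the
#' threshold (default 0.75).
#'
#' @param tables list of feature matrices (patients x features), one per
#'   perturbation, identical row and column order; the first is usually the
#'   unperturbed measurement.
#' @param threshold stability threshold on ICC (default 0.75).
#' @return list with `features` (character vector of retained names) and
#'   `report` (data frame `feature`, `icc`, `pass`).
#' @export
select_stable <- function(tables, threshold = 0.75) {
  stopifnot(is.list(tables), length(tables) >= 2)
  nm <- colnames(tables[[1]])
  for (t in tables[-1])
    if (!identical(colnames(t), nm))
      stop("feature names differ across perturbation tables")
  iccs <- vapply(seq_along(nm), function(j) {
    icc(vapply(tables, function(t) t[, j], numeric(nrow(tables[[1]]))))
  }, numeric(1))
  report <- data.frame(feature = nm, icc = iccs, pass = iccs >= threshold,
                       stringsAsFactors = FALSE)
  keep <- nm[report$pass]
  if (length(keep) == 0)
    stop("no feature reaches ICC >= ", threshold,
         "; inspect the stability threshold or the perturbation magnitude")
  list(features = keep, report = report)
}
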