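#' Image volumes and ROI masks
#'
#' `image_volume()` wraps a 3D scalar grid of CT-like intensities (Hounsfield
#' units) together with its anisotropic voxel spacing and origin;
#' `roi_mask()` wraps a binary lesion mask aligned to such a volume. These
#' are the containers every preprocessing and feature-extraction function
#' operates on.
#'
#' @param voxels a 3D numeric array (intensities) or 0/1 array (mask).
#' @param spacing voxel spacing in mm, length-3, all positive.
#' @param origin physical origin in mm, length 3.
#' @return An object of class `image_volume` or `roi_mask`: a list with
#'   elements `voxels`, `spacing` and `origin`.
#' @examples
#' img <- image_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 3))
#' msk <- roi_mask(array(c(0, 1), c(4, 4, 4)), spacing = c(1, 1, 3))
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("voxels must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers (mm)")
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop("image intensities must be finite")
  storage.mode(voxels) <- "double"
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' @rdname image_volume
#' @export
roi_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3)
    stop("mask voxels must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be three positive numbers (mm)")
  v <- voxels
  storage.mode(v) <- "integer"
  if (!all(v %in% c(0L, 1L))) stop("mask values must be 0 or 1")
  if (sum(v) == 0L) stop("mask must contain at least one foreground voxel")
  structure(list(voxels = v, spacing = spacing, origin = as.numeric(origin)),
            class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels @ ", paste(x$spacing, collapse = " x "), " mm, range [",
      round(min(x$voxels), 1), ", ", round(max(x$voxels), 1), "] HU\n",
      sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", paste(dim(x$voxels), collapse = " x "),
      " voxels @ ", paste(x$spacing, collapse = " x "), " mm, ",
      sum(x$voxels), " foreground voxels\n", sep = "")
  invisible(x)
}

# internal constructor for masks whose validity is guaranteed by
# construction (translations, resampling of a validated mask)
new_roi_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "roi_mask")
}

stopifnot_aligned <- function(image, mask) {
  if (!identical(dim(image$voxels), dim(mask$voxels)))
    stop("image and mask have different grid dimensions")
  if (max(abs(image$spacing - mask$spacing)) > 1e-9)
    stop("image and mask have different voxel spacing")
}

#' Read and write volumes as NIfTI
#'
#' Thin wrappers around \pkg{RNifti} that preserve the voxel array and the
#' spacing metadata exactly on a round trip. Images are stored as 64-bit
#' floats, masks as 32-bit integers.
#'
#' @param x an [image_volume] or [roi_mask].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_image_volume()` returns an [image_volume];
#'   `read_roi_mask()` returns a [roi_mask]. The writers return `path`
#'   invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  stopifnot(inherits(x, "image_volume") || inherits(x, "roi_mask"))
  img <- RNifti::asNifti(x$voxels)
  img <- RNifti::asNifti(img, reference = NULL)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @export
read_image_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  image_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing = sp)
}

#' @rdname write_nifti_volume
#' @export
read_roi_mask <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  v <- array(as.integer(img), dim = dim(img)[1:3])
  if (!all(v %in% c(0L, 1L)))
    stop("mask file contains values other than 0/1: ", path)
  roi_mask(v, spacing = sp)
}
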