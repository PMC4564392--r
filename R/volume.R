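#' 3-D image volume
#'
#' The carrier type for all image-valued data in the package: intensity
#' images, tissue probability maps, statistic maps and binary masks.  A
#' volume couples a 3-D numeric array with a 4x4 voxel-to-world affine
#' (RAS+ convention, 0-based voxel indices, voxel-centre sampling) and a
#' space tag recording whether the grid is a subject's native grid or the
#' group-template grid.
#'
#' @param data 3-D numeric array
#' @param voxel_size_mm scalar or length-3 voxel size in mm; ignored when
#'   `affine` is supplied
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal map with
#'   the given voxel size
#' @param space `"native"` or `"group"`
#' @return an object of class `volume`
#' @export
volume <- function(data, voxel_size_mm = 1, affine = NULL, space = "native") {
  stop_if(length(dim(data)) != 3L, "volume data must be a 3-D array")
  space <- match.arg(space, c("native", "group"))
  if (is.null(affine)) {
    vs <- rep_len(voxel_size_mm, 3L)
    affine <- diag(c(vs, 1))
  }
  affine <- unname(as.matrix(affine))
  stop_if(!all(is.finite(affine)) || nrow(affine) != 4L || ncol(affine) != 4L,
          "affine must be a finite 4x4 matrix")
  stop_if(abs(det(affine)) < 1e-12, "affine must be invertible")
  storage.mode(data) <- "double"
  structure(list(data = data, affine = affine, space = space),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  vs <- voxel_size(x)
  cat(sprintf("volume: %d x %d x %d voxels, %.3g x %.3g x %.3g mm, space '%s'\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3], x$space))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel size of a volume, from its affine column norms
#' @param v volume
#' @return length-3 numeric vector (mm)
#' @export
voxel_size <- function(v) sqrt(colSums(v$affine[1:3, 1:3]^2))

#' Volume of one voxel in mm^3
#' @param v volume
#' @export
voxel_volume <- function(v) abs(det(v$affine[1:3, 1:3]))

#' Replace the data array of a volume, keeping its grid
#' @keywords internal
vol_like <- function(v, data) {
  storage.mode(data) <- "double"
  stop_if(!identical(dim(data), dim(v$data)), "replacement data has wrong dimension")
  v$data <- data
  v
}

#' Test that two volumes share dimension and affine (to 1e-6)
#' @keywords internal
same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) < 1e-6
}

check_grid <- function(...) {
  vols <- list(...)
  for (i in seq_along(vols)[-1])
    stop_if(!same_grid(vols[[1]], vols[[i]]), "volumes are not on the same grid")
  invisible(TRUE)
}

#' Read a 3-D NIfTI-1 volume
#'
#' @param path path to a `.nii` / `.nii.gz` file holding a single 3-D frame
#' @param space space tag to attach (`"native"` or `"group"`)
#' @return a [volume]
#' @export
read_volume <- function(path, space = "native") {
  stop_if(!file.exists(path), sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stop_if(length(d) != 3L, "expected a single 3-D NIfTI frame")
  aff <- unclass(RNifti::xform(img))
  stop_if(!all(is.finite(aff)), "non-finite affine in NIfTI header")
  volume(array(as.numeric(img), dim = d), affine = aff, space = space)
}

#' Write a volume as NIfTI-1
#'
#' Binary masks are written as uint8, everything else as float32.  The
#' affine is stored in both the sform and qform.
#'
#' @param vol a [volume]
#' @param path output path (`.nii` or `.nii.gz`)
#' @return `path`, invisibly
#' @export
write_volume <- function(vol, path) {
  is_mask <- all(vol$data %in% c(0, 1))
  img <- RNifti::asNifti(vol$data)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = if (is_mask) "uint8" else "float")
  invisible(path)
}

#' Gaussian smoothing with a renormalised truncated kernel
#'
#' Separable Gaussian filter with sigma = FWHM / (2 sqrt(2 ln 2)) per axis,
#' expressed in mm so anisotropic voxels are handled.  At the field-of-view
#' edge the truncated kernel is renormalised to unit sum, which preserves
#' the local mean instead of leaking mass out of the grid.
#'
#' @param vol a [volume]
#' @param fwhm_mm full-width-at-half-maximum in mm; 0 returns the input
#'   unchanged
#' @return smoothed [volume]
#' @export
gaussian_smooth <- function(vol, fwhm_mm) {
  stop_if(!is.finite(fwhm_mm) || fwhm_mm < 0, "fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(vol)
  vs <- voxel_size(vol)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs
  vol_like(vol, smooth_array(vol$data, sigma_vox))
}

# separable smoothing of a raw array; sigma per axis in voxel units
smooth_array <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  d <- dim(a)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    n <- d[axis]
    r <- min(n - 1L, as.integer(ceiling(4 * s)))
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, `-`)^2 / (2 * s^2))
    K[abs(outer(idx, idx, `-`)) > r] <- 0
    K <- K / rowSums(K)
    a <- apply_along(a, axis, K)
  }
  a
}

# multiply kernel matrix K (n x n) along the given axis of a 3-D array
apply_along <- function(a, axis, K) {
  d <- dim(a)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- K %*% matrix(ap, nrow = dp[1])
  ap <- array(m, dp)
  aperm(ap, order(perm))
}

#' Resample a volume onto a target grid
#'
#' Values are sampled at the target voxel centres, mapped through both
#' affines, with B-spline interpolation of the requested degree (0 =
#' nearest neighbour, 1 = trilinear, 2-4 = prefiltered B-spline).
#' Out-of-field voxels are set to 0.
#'
#' @param vol source [volume]
#' @param target target grid: a [volume] or a list with elements `dim` and
#'   `affine`
#' @param order interpolation degree, 0..4
#' @return [volume] on the target grid
#' @export
resample <- function(vol, target, order = 1L) {
  stop_if(!(order %in% 0:4), "interpolation order must be in 0..4")
  tdim <- if (inherits(target, "volume")) dim(target$data) else target$dim
  taff <- if (inherits(target, "volume")) target$affine else unname(as.matrix(target$affine))
  stop_if(abs(det(taff)) < 1e-12, "target affine is singular")
  map <- solve(vol$affine) %*% taff     # target voxel -> source voxel
  ig <- index_grid(tdim)
  coords <- cbind(ig, 1) %*% t(map)
  arr <- vol$data
  if (order >= 2) arr <- array(cpp_bspline_prefilter(as.numeric(arr), dim(arr), order), dim(arr))
  vals <- cpp_sample3d(as.numeric(arr), dim(vol$data), coords[, 1:3, drop = FALSE], order)
  volume(array(vals, tdim), affine = taff, space = vol$space)
}

#' Binary dilation of a mask volume
#'
#' 6-connected dilation, `n` layers.
#'
#' @param mask binary mask [volume]
#' @param n number of dilation layers
#' @return dilated binary mask [volume]
#' @export
dilate_mask <- function(mask, n = 1L) {
  vol_like(mask, dilate6(mask$data, n))
}

#' Threshold a probability map into a binary mask
#'
#' @param prob probability [volume]
#' @param threshold value in \[0, 1\]; voxels with `data >= threshold`
#'   become 1
#' @return binary mask [volume]
#' @export
binarise <- function(prob, threshold) {
  stop_if(!is.finite(threshold) || threshold < 0 || threshold > 1,
          "threshold must lie in [0, 1]")
  vol_like(prob, (prob$data >= threshold) * 1)
}
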