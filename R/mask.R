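#' Binary mask on a spaced voxel grid
#'
#' The unit of comparison throughout the package: a 3D array of \{0,1\}
#' labels together with the grid geometry. The array is indexed
#' `(z, y, x)` and axial slices are fixed-`z` planes. Voxel `(k, j, i)`
#' (0-based) has its centre at world position `origin + index * spacing`,
#' so all downstream distances are in millimetres.
#'
#' @param labels 3D array of 0/1 (logical or numeric; any nonzero value is
#'   coerced to 1).
#' @param spacing_mm numeric length 3, voxel size in mm along `(z, y, x)`.
#' @param origin_mm numeric length 3, world position (mm) of the centre of
#'   voxel `(0, 0, 0)`.
#' @return An object of class `binary_mask` with elements `labels`
#'   (integer array), `spacing` and `origin`.
#' @examples
#' m <- binary_mask(array(1L, c(4, 4, 4)), spacing_mm = c(2, 1, 1))
#' mask_volume_mm3(m)
#' @export
binary_mask <- function(labels, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array")
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive finite values")
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("origin_mm must be 3 finite values")
  if (any(!is.finite(labels)))
    stop("labels contain non-finite values")
  lab <- array(as.integer(labels != 0), dim = dim(labels))
  structure(
    list(labels = lab, spacing = as.numeric(spacing_mm),
         origin = as.numeric(origin_mm)),
    class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<binary_mask> %d x %d x %d voxels (z,y,x), spacing %s mm, %d foreground\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              sum(x$labels)))
  invisible(x)
}

#' @rdname binary_mask
#' @param x object to test.
#' @export
is_binary_mask <- function(x) inherits(x, "binary_mask")

stopifnot_mask <- function(x, arg = "mask") {
  if (!is_binary_mask(x)) stop(sprintf("%s must be a binary_mask", arg))
  invisible(x)
}

#' Number of foreground voxels
#' @param mask a [binary_mask()].
#' @return integer count.
#' @export
mask_count <- function(mask) {
  stopifnot_mask(mask)
  sum(mask$labels)
}

#' Foreground volume in cubic millimetres
#' @param mask a [binary_mask()].
#' @return volume in mm^3 (voxel count times voxel volume).
#' @export
mask_volume_mm3 <- function(mask) {
  mask_count(mask) * prod(mask$spacing)
}

#' Do two masks share a grid?
#'
#' Same array dimensions, spacing (to 1e-9 mm) and origin.
#' @param a,b [binary_mask()] objects.
#' @return logical.
#' @export
same_grid <- function(a, b) {
  stopifnot_mask(a, "a"); stopifnot_mask(b, "b")
  identical(dim(a$labels), dim(b$labels)) &&
    all(abs(a$spacing - b$spacing) < 1e-9) &&
    all(abs(a$origin - b$origin) < 1e-9)
}

check_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("masks are not on the same grid")
  invisible(TRUE)
}

# World coordinates (mm) of voxel centres for 1-based array indices (k,j,i).
voxel_world_mm <- function(mask, idx) {
  sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
}

# Foreground voxel indices as an n x 3 matrix of 1-based (k,j,i).
mask_indices <- function(mask) {
  which(mask$labels != 0, arr.ind = TRUE)
}

# Foreground centroid in 1-based voxel index space, length 3.
mask_centroid_voxel <- function(mask) {
  idx <- mask_indices(mask)
  if (nrow(idx) == 0L) stop("empty mask has no centroid")
  colMeans(idx)
}

#' Anisotropy-aware Euclidean distance transform
#'
#' Exact distance (mm) from every voxel centre to the nearest foreground
#' voxel centre of `mask`, honouring per-axis spacing. Voxels of an empty
#' mask map to `Inf`.
#'
#' @param mask a [binary_mask()].
#' @param spacing_mm optional spacing override (e.g. `c(1, 1, 1)` for
#'   voxel-unit distances used in morphological dilation).
#' @return numeric 3D array of distances, same shape as the mask.
#' @export
distance_transform <- function(mask, spacing_mm = NULL) {
  stopifnot_mask(mask)
  sp <- if (is.null(spacing_mm)) mask$spacing else as.numeric(spacing_mm)
  cpp_edt(mask$labels, sp)
}

# Binary dilation by a Euclidean radius measured in voxel units.
dilate_voxels <- function(mask, radius_voxels) {
  d <- distance_transform(mask, spacing_mm = c(1, 1, 1))
  binary_mask(array(as.integer(d <= radius_voxels), dim = dim(mask$labels)),
              mask$spacing, mask$origin)
}

# Translate labels by an integer voxel offset (z,y,x); error if foreground
# would leave the grid.
translate_mask <- function(mask, shift) {
  shift <- as.integer(round(shift))
  if (all(shift == 0L)) return(mask)
  idx <- mask_indices(mask)
  if (nrow(idx) == 0L) return(mask)
  new_idx <- sweep(idx, 2, shift, `+`)
  d <- dim(mask$labels)
  if (any(new_idx < 1L) || any(sweep(new_idx, 2, d, `>`)))
    stop("translation pushes foreground off the grid")
  lab <- array(0L, dim = d)
  lab[new_idx] <- 1L
  binary_mask(lab, mask$spacing, mask$origin)
}
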