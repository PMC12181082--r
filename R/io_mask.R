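#' Read a binary mask from a NIfTI volume
#'
#' Populates the grid (spacing, origin) from the NIfTI header and coerces any
#' nonzero voxel to 1, so label maps from external tools are tolerated. The
#' on-disk `(x, y, z)` axis order is transposed to the package's `(z, y, x)`
#' convention.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [binary_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("mask file not found: %s", path))
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop(sprintf("unreadable NIfTI file %s: %s",
                                                   path, conditionMessage(e))))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop(sprintf("expected a 3D volume in %s, got %d dims", path, length(dim(arr))))
  if (any(!is.finite(arr)))
    stop(sprintf("non-finite voxel values in %s", path))
  sp_xyz <- RNifti::pixdim(img)
  xf <- RNifti::xform(img)
  origin_xyz <- xf[1:3, 4]
  binary_mask(aperm(arr, c(3, 2, 1)),
              spacing_mm = rev(sp_xyz[1:3]),
              origin_mm = rev(origin_xyz))
}

#' Write a binary mask as NIfTI
#'
#' Spacing and origin are written into the qform so that [read_mask()]
#' round-trips the grid exactly (spacing to float precision).
#'
#' @param mask a [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot_mask(mask)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("output directory does not exist: %s", dir))
  arr_xyz <- aperm(mask$labels, c(3, 2, 1))
  img <- RNifti::asNifti(arr_xyz)
  sp_xyz <- rev(mask$spacing)
  or_xyz <- rev(mask$origin)
  m <- diag(c(sp_xyz, 1))
  m[1:3, 4] <- or_xyz
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  img <- RNifti::`pixdim<-`(img, sp_xyz)
  RNifti::writeNifti(img, path)
  invisible(path)
}
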