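#' Extract the voxel surface of a mask
#'
#' Surface elements are foreground voxels with at least one six-connected
#' background neighbour (the grid border counts as background), positioned
#' at their voxel centres in world millimetres.
#'
#' @param mask a non-empty [binary_mask()].
#' @return object of class `contour_surface`: `voxel` (n x 3 matrix of
#'   1-based `(k, j, i)` indices), `coord_mm` (n x 3 world coordinates,
#'   `(z, y, x)`), `spacing`, `origin`, `grid_dim`.
#' @export
extract_surface <- function(mask) {
  stopifnot_mask(mask)
  if (mask_count(mask) == 0L) stop("cannot extract the surface of an empty mask")
  surf <- boundary_voxels(mask)
  idx <- which(surf != 0, arr.ind = TRUE)
  structure(list(voxel = idx,
                 coord_mm = voxel_world_mm(mask, idx),
                 spacing = mask$spacing, origin = mask$origin,
                 grid_dim = dim(mask$labels)),
            class = "contour_surface")
}

#' @export
print.contour_surface <- function(x, ...) {
  cat(sprintf("<contour_surface> %d elements on a %s grid\n",
              nrow(x$voxel), paste(x$grid_dim, collapse = "x")))
  invisible(x)
}

#' Signed deviation of an annotator contour from the consensus surface
#'
#' For each consensus surface element, the magnitude is the nearest 3D
#' Euclidean distance (mm, anisotropy-aware, via the exact distance
#' transform of the annotator's surface) and the sign is positive where the
#' element lies inside the annotator mask — i.e. the annotator's contour
#' extends beyond the consensus there — and negative otherwise.
#'
#' By default deviation is computed in the native frame, since all masks of
#' a case share one scan's coordinate system and translating away systematic
#' positional disagreement would hide it; set `align = TRUE` to translate
#' the annotator mask onto the consensus centroid first (see
#' [align_centroid()]).
#'
#' @param consensus,annotator non-empty [binary_mask()] objects on one grid.
#' @param align translate the annotator mask to the consensus centroid
#'   before measuring.
#' @return numeric vector of signed distances (mm), one per consensus
#'   surface element (ordered as [extract_surface()] of the consensus).
#' @export
signed_deviation <- function(consensus, annotator, align = FALSE) {
  stopifnot_mask(consensus, "consensus"); stopifnot_mask(annotator, "annotator")
  check_same_grid(consensus, annotator)
  if (mask_count(consensus) == 0L) stop("consensus mask is empty")
  if (mask_count(annotator) == 0L) stop("annotator mask is empty")
  if (align) annotator <- align_centroid(annotator, consensus)
  surf <- extract_surface(consensus)
  dist <- cpp_edt(boundary_voxels(annotator), annotator$spacing)
  mag <- dist[surf$voxel]
  inside <- annotator$labels[surf$voxel] != 0
  ifelse(inside, mag, -mag)
}

#' Cross-annotator deviation percentiles on the consensus surface
#'
#' Element-wise percentiles (linear interpolation between order statistics,
#' `stats::quantile` type 7 — so two annotators at +2 and -2 mm have median
#' 0) of the signed deviations across annotators, plus the 10th-90th
#' percentile range and structure-level summaries.
#'
#' @param deviations numeric matrix, elements x annotators (>= 2 columns),
#'   e.g. `cbind()` of [signed_deviation()] results.
#' @param levels percentile levels in (0, 1); default
#'   `c(0.1, 0.3, 0.5, 0.7, 0.9)`.
#' @param surface optional `contour_surface` the rows refer to (carried
#'   into the result for plotting/reporting).
#' @return object of class `deviation_map`: `percentiles` (elements x
#'   levels), `range_10_90`, `surface`, `n_annotators`, and `summary`
#'   (median of element-wise medians, max 10-90 range and its location).
#' @export
deviation_percentiles <- function(deviations,
                                  levels = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                  surface = NULL) {
  deviations <- as.matrix(deviations)
  if (ncol(deviations) < 2L)
    stop("deviation percentiles need >= 2 annotators")
  if (any(levels <= 0 | levels >= 1)) stop("levels must lie in (0, 1)")
  levels <- sort(levels)
  qs <- t(apply(deviations, 1, quantile, probs = levels, type = 7,
                names = FALSE))
  if (length(levels) == 1L) qs <- matrix(qs, ncol = 1L)
  colnames(qs) <- sprintf("p%02d", round(levels * 100))
  extremes <- t(apply(deviations, 1, quantile, probs = c(0.1, 0.9), type = 7,
                      names = FALSE))
  rng <- extremes[, 2] - extremes[, 1]
  med <- apply(deviations, 1, stats::median)
  i_max <- which.max(rng)
  structure(list(
    percentiles = qs, range_10_90 = rng, levels = levels,
    surface = surface, n_annotators = ncol(deviations),
    deviations = deviations,
    summary = list(
      median_of_medians_mm = stats::median(med),
      max_range_10_90_mm = rng[i_max],
      max_range_element = i_max,
      max_range_coord_mm = if (!is.null(surface)) surface$coord_mm[i_max, ] else NULL)),
    class = "deviation_map")
}

#' @export
print.deviation_map <- function(x, ...) {
  cat(sprintf(
    "<deviation_map> %d surface elements x %d annotators; median of medians %.2f mm; max 10-90 range %.2f mm\n",
    nrow(x$percentiles), x$n_annotators,
    x$summary$median_of_medians_mm, x$summary$max_range_10_90_mm))
  invisible(x)
}

#' Translate a mask onto another mask's centroid
#'
#' Rigid translation by the voxel-rounded difference of foreground
#' centroids; no rotation or scaling.
#'
#' @param moving,target non-empty [binary_mask()] objects on one grid.
#' @return the translated `moving` mask.
#' @export
align_centroid <- function(moving, target) {
  stopifnot_mask(moving, "moving"); stopifnot_mask(target, "target")
  check_same_grid(moving, target)
  if (mask_count(moving) == 0L || mask_count(target) == 0L)
    stop("cannot align empty masks")
  shift <- round(mask_centroid_voxel(target) - mask_centroid_voxel(moving))
  translate_mask(moving, shift)
}
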