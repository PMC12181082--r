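#' Dice similarity coefficient
#'
#' Voxel-count overlap `DSC(A, B) = 2|A intersect B| / (|A| + |B|)`.
#'
#' @param a,b [binary_mask()] objects on the same grid, not both empty.
#' @return a fraction in `[0, 1]`.
#' @examples
#' a <- binary_mask(array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2)))
#' b <- binary_mask(array(c(1, 1, 0, 0, 1, 1, 0, 0), c(2, 2, 2)))
#' dsc(a, b)  # 2 * 2 / (4 + 4) = 0.5
#' @export
dsc <- function(a, b) {
  stopifnot_mask(a, "a"); stopifnot_mask(b, "b")
  check_same_grid(a, b)
  na <- sum(a$labels); nb <- sum(b$labels)
  if (na + nb == 0) stop("DSC undefined for two empty masks")
  2 * sum(a$labels & b$labels) / (na + nb)
}

#' Total in-plane contour length of a mask
#'
#' Sum over axial (fixed-z) slices of the 2D boundary length, measured as
#' exposed in-plane voxel-edge length scaled by the voxel spacing. Under
#' this edge-counting convention a 20 x 20 voxel square at 1 mm spacing has
#' perimeter 80 mm, and lengths are exactly additive across slices.
#'
#' @param mask a [binary_mask()].
#' @return length in mm (0 for an empty mask).
#' @export
contour_length <- function(mask) {
  stopifnot_mask(mask)
  total <- 0
  for (k in seq_len(dim(mask$labels)[1])) {
    e <- slice_edges(mask$labels[k, , ], mask$spacing[2], mask$spacing[3])
    total <- total + sum(e$len_mm)
  }
  total
}

# Exposed in-plane voxel edges of a 2D slice (rows = y, cols = x).
# Returns midpoint coordinates (mm, 0-based voxel-centre frame) and the
# length of each edge: an edge facing +/-x runs along y (length sy) and
# vice versa.
slice_edges <- function(L, sy, sx) {
  d <- dim(L)
  L <- L != 0
  shift <- function(dy, dx) {
    out <- matrix(FALSE, d[1], d[2])
    ys <- seq_len(d[1]) + dy; xs <- seq_len(d[2]) + dx
    ok_y <- ys >= 1 & ys <= d[1]; ok_x <- xs >= 1 & xs <= d[2]
    out[ok_y, ok_x] <- L[ys[ok_y], xs[ok_x]]
    out
  }
  ys <- numeric(0); xs <- numeric(0); len <- numeric(0)
  for (dir in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
    exposed <- which(L & !shift(dir[1], dir[2]), arr.ind = TRUE)
    if (nrow(exposed) == 0) next
    ys <- c(ys, (exposed[, 1] - 1 + dir[1] / 2) * sy)
    xs <- c(xs, (exposed[, 2] - 1 + dir[2] / 2) * sx)
    len <- c(len, rep(if (dir[1] == 0) sy else sx, nrow(exposed)))
  }
  data.frame(y_mm = ys, x_mm = xs, len_mm = len)
}

#' Added path length at a distance tolerance
#'
#' The length of the reference (consensus) contour lying farther than
#' `tolerance_mm` from the test contour — the portion of the reference path
#' an editor would still have to draw. Computed slice by slice in the axial
#' plane, mirroring how contouring tools edit: reference boundary edges on a
#' slice are compared against the test boundary on the same slice only, and
#' a slice where the test has no contour counts fully. Reported both
#' absolute and relative to the total reference contour length.
#'
#' @param reference non-empty [binary_mask()] (the consensus / ground truth).
#' @param test [binary_mask()] on the same grid (may be empty).
#' @param tolerance_mm distance tolerance in mm (>= 0); default 2.
#' @return object of class `metric_record`: `dsc`, `apl_mm`, `relative_apl`,
#'   `tolerance_mm`, `reference_length_mm`.
#' @export
added_path_length <- function(reference, test, tolerance_mm = 2) {
  stopifnot_mask(reference, "reference"); stopifnot_mask(test, "test")
  check_same_grid(reference, test)
  if (mask_count(reference) == 0L) stop("reference mask is empty")
  if (tolerance_mm < 0) stop("tolerance_mm must be >= 0")

  sy <- reference$spacing[2]; sx <- reference$spacing[3]
  apl <- 0; ref_len <- 0
  for (k in seq_len(dim(reference$labels)[1])) {
    re <- slice_edges(reference$labels[k, , ], sy, sx)
    if (nrow(re) == 0) next
    ref_len <- ref_len + sum(re$len_mm)
    te <- slice_edges(test$labels[k, , ], sy, sx)
    if (nrow(te) == 0) {           # nothing drawn on this slice: all added
      apl <- apl + sum(re$len_mm)
      next
    }
    d2 <- outer(re$y_mm, te$y_mm, `-`)^2 + outer(re$x_mm, te$x_mm, `-`)^2
    nearest <- sqrt(apply(d2, 1, min))
    apl <- apl + sum(re$len_mm[nearest > tolerance_mm])
  }
  structure(list(
    dsc = if (mask_count(test) > 0) dsc(reference, test) else 0,
    apl_mm = apl,
    relative_apl = apl / ref_len,
    tolerance_mm = tolerance_mm,
    reference_length_mm = ref_len), class = "metric_record")
}

#' @export
print.metric_record <- function(x, ...) {
  cat(sprintf(
    "<metric_record> DSC %.3f | APL %.1f mm (relative %.3f) at %.1f mm tolerance; reference %.1f mm\n",
    x$dsc, x$apl_mm, x$relative_apl, x$tolerance_mm, x$reference_length_mm))
  invisible(x)
}
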