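#' Configuration of a synthetic tumour-like shape
#'
#' Shapes are star-convex about their centre: the boundary radius along a
#' direction `u` is `base_radius_mm * (1 + irregularity * S(u))`, with `S` a
#' smooth band-limited random field normalised to `max |S| = 1`. Requiring
#' `irregularity < 1` keeps the radius positive everywhere, so the surface is
#' a single closed sheet and the voxelised mask is connected.
#'
#' @param grid_shape integer length 3, voxel counts `(z, y, x)`.
#' @param spacing_mm numeric length 3, voxel size in mm `(z, y, x)`.
#' @param base_radius_mm mean radial extent in mm.
#' @param irregularity amplitude of the radial perturbation, in `[0, 1)`.
#' @param lobe_count angular frequency of the perturbation (integer >= 0);
#'   roughly the number of lobes across the shape.
#' @param centre_mm optional world-coordinate centre; defaults to the grid
#'   centre.
#' @return object of class `shape_config`.
#' @export
shape_config <- function(grid_shape, spacing_mm, base_radius_mm,
                         irregularity = 0, lobe_count = 0L, centre_mm = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be 3 positive integers")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be positive on all axes")
  if (base_radius_mm <= 0) stop("base_radius_mm must be positive")
  if (irregularity < 0 || irregularity >= 1)
    stop("irregularity must be in [0, 1) to keep the shape star-convex")
  if (lobe_count < 0) stop("lobe_count must be >= 0")
  extent <- (grid_shape - 1) * spacing_mm
  if (is.null(centre_mm)) centre_mm <- extent / 2
  r_max <- base_radius_mm * (1 + irregularity)
  axis_names <- c("z", "y", "x")
  for (a in 1:3) {
    room <- min(centre_mm[a], extent[a] - centre_mm[a]) - spacing_mm[a]
    if (r_max > room)
      stop(sprintf(
        "shape exceeds grid along %s: needs %.1f mm but only %.1f mm available",
        axis_names[a], r_max, room))
  }
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 base_radius_mm = base_radius_mm, irregularity = irregularity,
                 lobe_count = as.integer(lobe_count),
                 centre_mm = as.numeric(centre_mm)),
            class = "shape_config")
}

# Voxel-centre offsets from the shape centre: n x 3 matrix (mm), plus radii
# and unit directions. The centre voxel gets an arbitrary direction; its
# radius 0 keeps it inside regardless.
grid_geometry <- function(grid_shape, spacing_mm, centre_mm) {
  ax <- lapply(1:3, function(a) (seq_len(grid_shape[a]) - 1) * spacing_mm[a] - centre_mm[a])
  dz <- ax[[1]][slice.index(array(0, grid_shape), 1)]
  dy <- ax[[2]][slice.index(array(0, grid_shape), 2)]
  dx <- ax[[3]][slice.index(array(0, grid_shape), 3)]
  delta <- cbind(as.vector(dz), as.vector(dy), as.vector(dx))
  r <- sqrt(rowSums(delta^2))
  U <- delta / pmax(r, 1e-12)
  U[r < 1e-12, ] <- rep(c(0, 0, 1), each = sum(r < 1e-12))
  list(r = r, U = U)
}

#' Generate a star-convex tumour-like binary mask
#'
#' @param config a [shape_config()].
#' @param seed integer seed; the same `(config, seed)` always yields the
#'   identical mask.
#' @return a [binary_mask()], connected and strictly interior to the grid.
#' @examples
#' cfg <- shape_config(c(44, 44, 44), c(1, 1, 1), base_radius_mm = 20)
#' ball <- generate_base_shape(cfg, seed = 1)
#' mask_volume_mm3(ball) / (4 / 3 * pi * 20^3)  # ~1
#' @export
generate_base_shape <- function(config, seed = 1L) {
  stopifnot(inherits(config, "shape_config"))
  geo <- grid_geometry(config$grid_shape, config$spacing_mm, config$centre_mm)
  if (config$irregularity > 0 && config$lobe_count > 0) {
    f <- radial_field(1, pi * config$lobe_count, seed = subseed(seed, "shape"))
    s <- f(geo$U)
    s <- s / max(abs(s))
  } else {
    s <- 0
  }
  radius <- config$base_radius_mm * (1 + config$irregularity * s)
  lab <- array(as.integer(geo$r <= radius), dim = config$grid_shape)
  mask <- binary_mask(lab, config$spacing_mm)
  if (mask_count(mask) == 0L) stop("generated shape is empty")
  d <- config$grid_shape
  if (any(lab[c(1, d[1]), , ] != 0) || any(lab[, c(1, d[2]), ] != 0) ||
      any(lab[, , c(1, d[3])] != 0))
    stop("generated shape touches the grid boundary")
  mask
}
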