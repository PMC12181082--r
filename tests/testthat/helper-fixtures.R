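# Small fixtures built in code.

# Digital ball constructed directly from voxel-centre distances,
# independently of the shape generator.
make_ball <- function(radius_mm, grid = NULL, spacing = c(1, 1, 1),
                      centre_vox = NULL) {
  if (is.null(grid)) grid <- rep(2L * ceiling(radius_mm / min(spacing)) + 7L, 3)
  if (is.null(centre_vox)) centre_vox <- (grid + 1) / 2
  ax <- lapply(1:3, function(a) ((seq_len(grid[a]) - centre_vox[a]) * spacing[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  binary_mask(array(as.integer(d2 <= radius_mm^2), grid), spacing)
}

# Single-slice axis-aligned rectangle.
make_square_slice <- function(ny = 24L, nx = 24L, y = 3:22, x = 3:22,
                              spacing = c(1, 1, 1)) {
  arr <- array(0L, c(1L, ny, nx))
  arr[1, y, x] <- 1L
  binary_mask(arr, spacing)
}

random_mask <- function(dims, p = 0.3, seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  binary_mask(array(as.integer(runif(prod(dims)) < p), dims), spacing)
}

# A tiny hand-written well-formed event log.
toy_events <- function() {
  data.frame(
    t_ms = c(0, 2000, 5000, 8000, 10000, 15000, 20000),
    kind = c("move", "drag_start", "drag", "drag", "drag_end", "move", "move"),
    tool = c("none", "lasso", "lasso", "lasso", "lasso", "none", "none"),
    stringsAsFactors = FALSE)
}
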