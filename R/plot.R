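#' Plot a deviation map projected on the consensus surface
#'
#' Three orthogonal scatter projections of the consensus surface elements,
#' colour-coded by the chosen statistic: the 10th-90th percentile range of
#' annotator deviation (sequential palette) or the element-wise median
#' (diverging palette, white at zero). The stored artifact of record is the
#' numeric map; this rendering is for inspection.
#'
#' @param x a [deviation_percentiles()] result with a surface attached.
#' @param what `"range"` (default) or `"median"`.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.deviation_map <- function(x, what = c("range", "median"), ...) {
  what <- match.arg(what)
  if (is.null(x$surface)) stop("deviation map carries no surface coordinates")
  val <- if (what == "range") x$range_10_90 else x$percentiles[, "p50"]
  if (what == "range") {
    pal <- grDevices::colorRampPalette(c("#2c7bb6", "#ffffbf", "#d7191c"))(100)
    brk <- seq(0, max(val) + 1e-9, length.out = 101)
  } else {
    pal <- grDevices::colorRampPalette(c("#0571b0", "white", "#ca0020"))(100)
    lim <- max(abs(val)) + 1e-9
    brk <- seq(-lim, lim, length.out = 101)
  }
  col <- pal[cut(val, brk, include.lowest = TRUE, labels = FALSE)]
  cm <- x$surface$coord_mm
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  proj <- list(axial = c(3, 2), coronal = c(3, 1), sagittal = c(2, 1))
  lab <- c("z (mm)", "y (mm)", "x (mm)")
  for (nm in names(proj)) {
    ax <- proj[[nm]]
    graphics::plot(cm[, ax[1]], cm[, ax[2]], col = col, pch = 16, cex = 0.6,
                   asp = 1, xlab = lab[ax[1]], ylab = lab[ax[2]],
                   main = sprintf("%s (%s, %s)", nm, what,
                                  if (what == "range") "mm" else "signed mm"))
  }
  invisible(x)
}
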