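#' STAPLE consensus segmentation
#'
#' Simultaneous Truth And Performance Level Estimation for binary masks:
#' an EM algorithm that treats the unknown true segmentation as a hidden
#' per-voxel indicator and each rater `j` as a noisy channel with
#' sensitivity `p_j = P(rater 1 | truth 1)` and specificity
#' `q_j = P(rater 0 | truth 0)`.
#'
#' E-step, with `d_ij` the decision of rater `j` at voxel `i` and foreground
#' prior `gamma`:
#' \deqn{a_i = \gamma \prod_j p_j^{d_{ij}} (1-p_j)^{1-d_{ij}}, \quad
#'       b_i = (1-\gamma) \prod_j q_j^{1-d_{ij}} (1-q_j)^{d_{ij}}, \quad
#'       W_i = a_i / (a_i + b_i)}
#' M-step:
#' \deqn{p_j = \sum_i W_i d_{ij} / \sum_i W_i, \quad
#'       q_j = \sum_i (1-W_i)(1-d_{ij}) / \sum_i (1-W_i)}
#'
#' Estimation is restricted to a region of interest (by default the union of
#' rater foregrounds dilated by `roi_margin` voxels): including the whole
#' scan background makes specificity estimates degenerate and swamps the
#' prior. Products are computed in log space with probabilities clamped to
#' `[1e-10, 1 - 1e-10]` to avoid underflow with many raters; the clamp is
#' part of the algorithm's definition here. Initialisation is deterministic
#' (`p_j = q_j = 0.9999`). The observed-data log-likelihood
#' `sum_i log(a_i + b_i)` is recorded each iteration and is non-decreasing.
#'
#' @param raters list of >= 2 [binary_mask()] objects on one grid, at least
#'   one non-empty.
#' @param threshold posterior probability cut for the consensus mask; ties
#'   (`W == threshold`) are foreground.
#' @param tol convergence tolerance: max absolute change over all `p_j`,
#'   `q_j` between iterations.
#' @param max_iter iteration cap; hitting it sets `converged = FALSE` with a
#'   warning rather than an error.
#' @param prior_gamma scalar foreground prior; default is the mean rater
#'   foreground fraction within the ROI.
#' @param roi optional [binary_mask()] region of interest overriding the
#'   dilated-union default.
#' @param roi_margin dilation radius (voxels) for the default ROI.
#' @param keep_trace record per-iteration `(p, q)` and weight vectors
#'   (memory-heavy; for validation).
#' @return object of class `staple_result`: `weight_map` (array, 0 outside
#'   the ROI), `consensus_mask` ([binary_mask()]), `performances`
#'   (data.frame rater/sensitivity/specificity), `prior_gamma`,
#'   `n_iterations`, `converged`, `log_likelihood` (per-iteration trace),
#'   `roi`, and optionally `trace`.
#' @examples
#' m <- binary_mask(array(c(0, 1, 1, 0, 1, 0, 0, 0), c(2, 2, 2)))
#' res <- staple(list(m, m, m))
#' res$performances
#' @export
staple <- function(raters, threshold = 0.5, tol = 1e-7, max_iter = 200L,
                   prior_gamma = NULL, roi = NULL, roi_margin = 10,
                   keep_trace = FALSE) {
  if (length(raters) < 2L) stop("need at least 2 raters")
  lapply(raters, stopifnot_mask, arg = "each rater")
  for (j in seq_along(raters)[-1]) check_same_grid(raters[[1]], raters[[j]])
  counts <- vapply(raters, mask_count, numeric(1))
  if (all(counts == 0)) stop("all rater masks are empty")
  g <- raters[[1]]
  dims <- dim(g$labels)

  if (is.null(roi)) {
    uni <- Reduce(`|`, lapply(raters, function(m) m$labels != 0))
    uni_mask <- binary_mask(array(as.integer(uni), dims), g$spacing, g$origin)
    roi <- dilate_voxels(uni_mask, roi_margin)
  } else {
    stopifnot_mask(roi, "roi")
    check_same_grid(g, roi)
  }
  idx <- which(roi$labels != 0)
  J <- length(raters)
  D <- vapply(raters, function(m) as.numeric(m$labels[idx]), numeric(length(idx)))

  gamma <- if (is.null(prior_gamma)) mean(colMeans(D)) else prior_gamma
  if (gamma <= 0 || gamma >= 1)
    stop("prior_gamma must lie strictly between 0 and 1")

  clamp <- function(x) pmin(pmax(x, 1e-10), 1 - 1e-10)
  p <- rep(0.9999, J)
  q <- rep(0.9999, J)
  ll <- numeric(0)
  trace <- if (keep_trace) list() else NULL
  converged <- FALSE
  it <- 0L
  W <- NULL
  repeat {
    it <- it + 1L
    pc <- clamp(p); qc <- clamp(q)
    loga <- log(gamma) + D %*% log(pc) + (1 - D) %*% log1p(-pc)
    logb <- log1p(-gamma) + (1 - D) %*% log(qc) + D %*% log1p(-qc)
    m <- pmax(loga, logb)
    ll <- c(ll, sum(m + log(exp(loga - m) + exp(logb - m))))
    W <- as.vector(1 / (1 + exp(logb - loga)))
    sw <- sum(W)
    sw0 <- length(W) - sw
    p_new <- as.vector(crossprod(D, W)) / sw
    q_new <- as.vector(crossprod(1 - D, 1 - W)) / sw0
    if (keep_trace)
      trace[[it]] <- list(p = p_new, q = q_new, W = W)
    delta <- max(abs(c(p_new - p, q_new - q)))
    p <- p_new; q <- q_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged)
    warning(sprintf("STAPLE did not converge in %d iterations (last delta %.2e)",
                    it, delta))

  wmap <- array(0, dims)
  wmap[idx] <- W
  cons <- array(0L, dims)
  cons[idx] <- as.integer(W >= threshold)
  structure(list(
    weight_map = wmap,
    consensus_mask = binary_mask(cons, g$spacing, g$origin),
    performances = data.frame(rater = seq_len(J), sensitivity = p,
                              specificity = q),
    prior_gamma = gamma, n_iterations = it, converged = converged,
    log_likelihood = ll, roi = roi, threshold = threshold,
    trace = trace), class = "staple_result")
}

#' @export
print.staple_result <- function(x, ...) {
  cat(sprintf("<staple_result> %d raters, %d iterations (%s), prior %.3f\n",
              nrow(x$performances), x$n_iterations,
              if (x$converged) "converged" else "NOT converged", x$prior_gamma))
  cat(sprintf("  consensus: %d voxels; sensitivity %.3f-%.3f, specificity %.3f-%.3f\n",
              mask_count(x$consensus_mask),
              min(x$performances$sensitivity), max(x$performances$sensitivity),
              min(x$performances$specificity), max(x$performances$specificity)))
  invisible(x)
}
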