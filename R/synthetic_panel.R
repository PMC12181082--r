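#' Configuration of a simulated annotator panel
#'
#' Each annotator displaces the base shape's boundary along the outward
#' radial direction by a smooth per-annotator bias field (shared across that
#' annotator's sessions — the inter-observer component) plus an independent
#' smooth per-session noise field (the intra-observer component). An optional
#' focal term makes some annotators include an extra directional bump of
#' tissue, mimicking localised disagreement such as adjacent collapsed lung.
#'
#' @param n_annotators number of annotators (>= 1).
#' @param sigma_inter_mm SD (mm) of the per-annotator radial bias field.
#' @param sigma_intra_mm SD (mm) of the per-session radial noise field.
#' @param focal optional `list(direction =, extent_mm =, probability =)`:
#'   each annotator independently includes (with the given probability) a
#'   radial bump of height `extent_mm` centred on `direction` (z, y, x).
#' @param seed integer master seed for the panel.
#' @return object of class `annotator_panel_config`.
#' @export
annotator_panel_config <- function(n_annotators, sigma_inter_mm = 0,
                                   sigma_intra_mm = 0, focal = NULL, seed = 1L) {
  if (n_annotators < 1) stop("n_annotators must be >= 1")
  if (sigma_inter_mm < 0 || sigma_intra_mm < 0) stop("sigma values must be >= 0")
  if (!is.null(focal)) {
    stopifnot(is.list(focal), all(c("direction", "extent_mm", "probability") %in% names(focal)))
    if (focal$extent_mm < 0) stop("focal extent_mm must be >= 0")
    if (focal$probability < 0 || focal$probability > 1)
      stop("focal probability must be in [0, 1]")
    focal$direction <- focal$direction / sqrt(sum(focal$direction^2))
  }
  structure(list(n_annotators = as.integer(n_annotators),
                 sigma_inter_mm = sigma_inter_mm, sigma_intra_mm = sigma_intra_mm,
                 focal = focal, seed = as.integer(seed)),
            class = "annotator_panel_config")
}

#' Simulate a panel of annotator contours around a base shape
#'
#' The base mask's boundary is displaced along its outward normal by the
#' value of each annotator/session displacement field: a voxel is labelled
#' foreground when its signed Euclidean distance to the base surface is at
#' most the local displacement. With all sigmas zero and no focal term every
#' output equals the base exactly.
#'
#' `bias_scale` scales the inter-observer component (bias field and focal
#' bump) per session; a scale below 1 emulates a contouring aid that pulls
#' annotators towards the common shape while leaving session-to-session
#' noise untouched.
#'
#' @param base a non-empty [binary_mask()].
#' @param panel an [annotator_panel_config()].
#' @param n_sessions sessions per annotator (>= 1).
#' @param bias_scale scalar or length-`n_sessions` multiplier on the
#'   inter-observer component.
#' @return nested list `masks[[annotator]][[session]]` of [binary_mask()],
#'   with annotators named `A1...`, sessions `s1...`.
#' @export
simulate_annotator_contours <- function(base, panel, n_sessions = 1L,
                                        bias_scale = 1) {
  stopifnot_mask(base, "base")
  stopifnot(inherits(panel, "annotator_panel_config"))
  if (mask_count(base) == 0L) stop("base mask is empty")
  if (n_sessions < 1L) stop("n_sessions must be >= 1")
  bias_scale <- rep_len(bias_scale, n_sessions)

  sdist <- signed_distance_to_surface(base)
  ctr_vox <- mask_centroid_voxel(base)
  ctr_mm <- (ctr_vox - 1) * base$spacing
  geo <- grid_geometry(dim(base$labels), base$spacing, ctr_mm)
  d <- dim(base$labels)

  out <- vector("list", panel$n_annotators)
  names(out) <- paste0("A", seq_len(panel$n_annotators))
  for (a in seq_len(panel$n_annotators)) {
    bias <- if (panel$sigma_inter_mm > 0) {
      f <- radial_field(panel$sigma_inter_mm, 2 * pi,
                        seed = subseed(panel$seed, "bias", a))
      f(geo$U)
    } else 0
    bump <- 0
    if (!is.null(panel$focal) && panel$focal$extent_mm > 0) {
      include <- with_seed(subseed(panel$seed, "focal", a),
                           runif(1) < panel$focal$probability)
      if (include)
        bump <- panel$focal$extent_mm *
          pmax(0, geo$U %*% panel$focal$direction)^8
    }
    sess <- vector("list", n_sessions)
    names(sess) <- paste0("s", seq_len(n_sessions))
    for (s in seq_len(n_sessions)) {
      noise <- if (panel$sigma_intra_mm > 0) {
        f <- radial_field(panel$sigma_intra_mm, 3 * pi,
                          seed = subseed(panel$seed, "noise", a, s))
        f(geo$U)
      } else 0
      disp <- bias_scale[s] * (bias + bump) + noise
      lab <- array(as.integer(as.vector(sdist) <= disp), dim = d)
      sess[[s]] <- binary_mask(lab, base$spacing, base$origin)
    }
    out[[a]] <- sess
  }
  out
}

# Signed Euclidean distance (mm) to the base surface: <= 0 inside the mask
# (surface voxels are exactly 0), > 0 outside.
signed_distance_to_surface <- function(mask) {
  surf <- boundary_voxels(mask)
  dist <- cpp_edt(surf, mask$spacing)
  sign <- ifelse(mask$labels != 0, -1, 1)
  dist * sign
}

# Foreground voxels with at least one 6-connected background neighbour
# (off-grid counts as background). Returns a 0/1 array.
boundary_voxels <- function(mask) {
  lab <- mask$labels
  d <- dim(lab)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- lab
  core <- function(dz, dy, dx)
    pad[(2:(d[1] + 1)) + dz, (2:(d[2] + 1)) + dy, (2:(d[3] + 1)) + dx]
  nbg <- (core(-1, 0, 0) == 0L) | (core(1, 0, 0) == 0L) |
         (core(0, -1, 0) == 0L) | (core(0, 1, 0) == 0L) |
         (core(0, 0, -1) == 0L) | (core(0, 0, 1) == 0L)
  array(as.integer(lab != 0L & nbg), dim = d)
}

#' Ground-truth rater performance for consensus validation
#'
#' @param sensitivity_p probability a true-foreground voxel is labelled
#'   foreground; in (0, 1].
#' @param specificity_q probability a true-background voxel is labelled
#'   background; in (0, 1].
#' @return object of class `rater_truth`.
#' @export
rater_truth <- function(sensitivity_p, specificity_q) {
  if (sensitivity_p <= 0 || sensitivity_p > 1)
    stop("sensitivity_p must be in (0, 1]")
  if (specificity_q <= 0 || specificity_q > 1)
    stop("specificity_q must be in (0, 1]")
  structure(list(sensitivity_p = sensitivity_p, specificity_q = specificity_q),
            class = "rater_truth")
}

#' Simulate raters with known voxelwise sensitivity and specificity
#'
#' Within the region of interest, rater `j` labels each true-foreground
#' voxel 1 with probability `p_j` and each true-background voxel 1 with
#' probability `1 - q_j`, independently across voxels. Everything outside
#' the ROI is background. This is the generative model whose parameters a
#' consensus algorithm should recover.
#'
#' @param base the true [binary_mask()].
#' @param truths list of [rater_truth()] objects, one per rater.
#' @param roi [binary_mask()] containing the base; defaults to the base
#'   dilated by 10 voxels.
#' @param seed integer seed; rater `j` uses an independent sub-stream.
#' @return list of [binary_mask()], one per rater.
#' @export
simulate_voxelflip_raters <- function(base, truths, roi = NULL, seed = 1L) {
  stopifnot_mask(base, "base")
  if (is.null(roi)) roi <- dilate_voxels(base, 10)
  stopifnot_mask(roi, "roi")
  check_same_grid(base, roi)
  if (any(base$labels > roi$labels)) stop("roi must contain the base mask")
  lapply(truths, function(t) if (!inherits(t, "rater_truth"))
    stop("truths must be rater_truth objects"))
  idx <- which(roi$labels != 0)
  fg <- base$labels[idx] == 1L
  d <- dim(base$labels)
  lapply(seq_along(truths), function(j) {
    t <- truths[[j]]
    u <- with_seed(subseed(seed, "voxelflip", j), runif(length(idx)))
    keep <- ifelse(fg, u < t$sensitivity_p, u < 1 - t$specificity_q)
    lab <- array(0L, dim = d)
    lab[idx[keep]] <- 1L
    binary_mask(lab, base$spacing, base$origin)
  })
}
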