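make_panel <- function(seed, n_raters = 5, dims = c(10, 10, 10), p_fg = 0.35) {
  set.seed(seed)
  truth <- array(as.integer(runif(prod(dims)) < p_fg), dims)
  lapply(seq_len(n_raters), function(j) {
    flip <- runif(prod(dims)) < 0.15
    binary_mask(array(as.integer(xor(truth == 1L, flip)), dims))
  })
}

test_that("unanimous raters are a fixed point with near-perfect performance", {
  m <- make_ball(6)
  res <- staple(list(m, m, m))
  expect_identical(res$consensus_mask$labels, m$labels)
  expect_true(all(res$performances$sensitivity >= 1 - 1e-6))
  expect_true(all(res$performances$specificity >= 1 - 1e-6))
})

test_that("staple matches the straight-from-the-equations EM oracle per iteration", {
  for (seed in 1:3) {
    raters <- make_panel(seed, dims = c(8, 9, 8))
    roi <- binary_mask(array(1L, c(8, 9, 8)))
    res <- suppressWarnings(staple(raters, roi = roi, max_iter = 12, tol = 0,
                                   keep_trace = TRUE))
    D <- sapply(raters, function(m) as.numeric(m$labels))
    orc <- staple_oracle(D, res$prior_gamma, n_iter = 12)
    for (it in seq_len(12)) {
      expect_lt(max(abs(res$trace[[it]]$W - orc[[it]]$W)), 1e-8)
      expect_lt(max(abs(res$trace[[it]]$p - orc[[it]]$p)), 1e-8)
      expect_lt(max(abs(res$trace[[it]]$q - orc[[it]]$q)), 1e-8)
    }
  }
})

test_that("EM log-likelihood never decreases", {
  raters <- make_panel(4, dims = c(12, 12, 12))
  res <- staple(raters)
  expect_true(all(diff(res$log_likelihood) > -1e-8))
})

test_that("permuting rater order permutes performances, not the weight map", {
  raters <- make_panel(5)
  perm <- c(3, 1, 5, 2, 4)
  a <- staple(raters)
  b <- staple(raters[perm])
  expect_equal(b$weight_map, a$weight_map, tolerance = 1e-12)
  expect_equal(b$performances$sensitivity, a$performances$sensitivity[perm],
               tolerance = 1e-12)
  expect_equal(b$performances$specificity, a$performances$specificity[perm],
               tolerance = 1e-12)
})

test_that("symmetric identical-error raters reproduce the majority vote", {
  # 5 exchangeable raters on a small instance: consensus must agree with
  # exhaustive per-voxel majority voting
  raters <- make_panel(6, dims = c(6, 6, 6))
  votes <- Reduce(`+`, lapply(raters, `[[`, "labels"))
  majority <- votes >= 3
  res <- staple(raters, roi = binary_mask(array(1L, c(6, 6, 6))))
  expect_equal(res$consensus_mask$labels != 0, majority)
})

test_that("weight map is invariant to enlarging the ROI margin", {
  # raters without false positives and a fixed prior: the all-background
  # margin then carries negligible posterior weight, so widening it changes
  # nothing (with false positives the specificity estimate depends on the
  # amount of background included, and exact invariance cannot hold)
  base <- make_ball(5, grid = c(40, 40, 40))
  truths <- replicate(4, rater_truth(0.98, 1), simplify = FALSE)
  raters <- simulate_voxelflip_raters(base, truths,
                                      roi = contoureval:::dilate_voxels(base, 3),
                                      seed = 2)
  a <- staple(raters, roi_margin = 10, prior_gamma = 0.3)
  b <- staple(raters, roi_margin = 14, prior_gamma = 0.3)
  expect_lt(max(abs(a$weight_map - b$weight_map)), 1e-6)
  expect_identical(a$consensus_mask$labels, b$consensus_mask$labels)
})

test_that("degenerate panels are rejected", {
  m <- make_ball(5)
  empty <- binary_mask(array(0L, dim(m$labels)))
  expect_error(staple(list(m)), "at least 2")
  expect_error(staple(list(empty, empty)), "all rater masks are empty")
  other <- binary_mask(array(0L, dim(m$labels) + 1L))
  expect_error(staple(list(m, other)), "same grid")
})

test_that("staple recovers known rater sensitivity and specificity", {
  base <- make_ball(8, grid = c(24, 24, 24))
  truths <- replicate(5, rater_truth(0.9, 0.95), simplify = FALSE)
  errs <- sapply(1:3, function(seed) {
    rs <- simulate_voxelflip_raters(base, truths, seed = seed)
    res <- staple(rs)
    c(mean(abs(res$performances$sensitivity - 0.9)),
      mean(abs(res$performances$specificity - 0.95)))
  })
  expect_lt(mean(errs[1, ]), 0.02)
  expect_lt(mean(errs[2, ]), 0.02)
})
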