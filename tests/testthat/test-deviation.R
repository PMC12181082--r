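test_that("surface extraction counts boundary voxels correctly", {
  one <- binary_mask(array(c(rep(0L, 13), 1L, rep(0L, 13)), c(3, 3, 3)))
  expect_equal(nrow(extract_surface(one)$voxel), 1)
  cube <- binary_mask(array(1L, c(5, 5, 5)))
  cube$labels[] <- 0L; cube$labels[2:4, 2:4, 2:4] <- 1L
  expect_equal(nrow(extract_surface(cube)$voxel), 26)  # all but the centre
  expect_error(extract_surface(binary_mask(array(0L, c(2, 2, 2)))), "empty")
})

test_that("surface extraction matches a brute-force neighbour scan on a ball", {
  ball <- make_ball(10, grid = c(26, 26, 26))
  surf <- extract_surface(ball)
  lab <- ball$labels; d <- dim(lab)
  count <- 0
  for (k in 1:d[1]) for (j in 1:d[2]) for (i in 1:d[3]) {
    if (lab[k, j, i] == 0) next
    nb <- rbind(c(k - 1, j, i), c(k + 1, j, i), c(k, j - 1, i),
                c(k, j + 1, i), c(k, j, i - 1), c(k, j, i + 1))
    exposed <- FALSE
    for (r in 1:6) {
      v <- nb[r, ]
      if (any(v < 1) || any(v > d) || lab[v[1], v[2], v[3]] == 0)
        exposed <- TRUE
    }
    if (exposed) count <- count + 1
  }
  expect_equal(nrow(surf$voxel), count)
})

test_that("signed deviation recovers concentric offsets with the right sign", {
  consensus <- make_ball(10, grid = c(34, 34, 34))
  outer <- make_ball(13, grid = c(34, 34, 34))
  inner <- make_ball(7, grid = c(34, 34, 34))
  half_diag <- sqrt(3) / 2

  expect_equal(signed_deviation(consensus, consensus),
               rep(0, nrow(extract_surface(consensus)$voxel)))
  dv_out <- signed_deviation(consensus, outer)
  expect_true(all(abs(dv_out - 3) <= half_diag))
  dv_in <- signed_deviation(consensus, inner)
  expect_true(all(abs(dv_in + 3) <= half_diag))
})

test_that("dilating the annotator never decreases any signed deviation", {
  consensus <- make_ball(8, grid = c(26, 26, 26))
  ann <- make_ball(8, grid = c(26, 26, 26), centre_vox = c(14.5, 13.5, 13.5))
  grown <- contoureval:::dilate_voxels(ann, 2)
  expect_true(all(signed_deviation(consensus, grown) >=
                    signed_deviation(consensus, ann) - 1e-12))
})

test_that("deviation percentiles follow the linear-interpolation convention", {
  two <- cbind(rep(2, 5), rep(-2, 5))
  dm <- deviation_percentiles(two, levels = c(0.1, 0.5, 0.9))
  expect_equal(unname(dm$percentiles[, "p50"]), rep(0, 5))

  offsets <- seq(-4, 4)  # 9 annotators at fixed offsets
  devs <- matrix(offsets, nrow = 3, ncol = 9, byrow = TRUE)
  dm9 <- deviation_percentiles(devs)
  for (lv in c(0.1, 0.3, 0.5, 0.7, 0.9))
    expect_equal(unname(dm9$percentiles[1, sprintf("p%02d", lv * 100)]),
                 percentile_oracle(offsets, lv))
  expect_equal(unname(dm9$range_10_90[1]),
               percentile_oracle(offsets, 0.9) - percentile_oracle(offsets, 0.1))
  expect_error(deviation_percentiles(matrix(1, 4, 1)), ">= 2")
  expect_error(deviation_percentiles(devs, levels = c(0, 0.5)), "levels")
})

test_that("percentiles are monotone across levels on random panels", {
  set.seed(42)
  for (rep in 1:20) {
    devs <- matrix(rnorm(40 * 7, sd = 3), 40, 7)
    dm <- deviation_percentiles(devs)
    expect_true(all(apply(dm$percentiles, 1, function(r) all(diff(r) >= 0))))
  }
})

test_that("centroid alignment recovers constructed shifts", {
  m <- make_ball(6, grid = c(26, 26, 26))
  expect_identical(align_centroid(m, m)$labels, m$labels)
  sh <- contoureval:::translate_mask(m, c(0, 5, 0))
  expect_identical(align_centroid(sh, m)$labels, m$labels)
  set.seed(7)
  for (rep in 1:5) {
    shift <- sample(-3:3, 3, replace = TRUE)
    moved <- contoureval:::translate_mask(m, shift)
    back <- align_centroid(moved, m)
    delta <- contoureval:::mask_centroid_voxel(back) -
      contoureval:::mask_centroid_voxel(m)
    expect_true(all(abs(delta) < 1))
  }
})

test_that("a zero-noise panel yields an identically zero deviation map", {
  base <- generate_base_shape(
    shape_config(c(26, 30, 30), c(2, 1, 1), 10, 0.2, 3), seed = 6)
  pm <- simulate_annotator_contours(
    base, annotator_panel_config(4, 0, 0, seed = 3), n_sessions = 1)
  masks <- lapply(pm, `[[`, 1)
  res <- staple(masks)
  surf <- extract_surface(res$consensus_mask)
  devs <- vapply(masks, function(m) signed_deviation(res$consensus_mask, m),
                 numeric(nrow(surf$voxel)))
  dm <- deviation_percentiles(devs, surface = surf)
  expect_true(all(dm$percentiles == 0))
  expect_true(all(dm$range_10_90 == 0))
})
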