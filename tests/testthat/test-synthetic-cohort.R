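test_that("zero-irregularity shape is a digital ball with the right volume", {
  cfg <- shape_config(c(44, 44, 44), c(1, 1, 1), base_radius_mm = 20)
  ball <- generate_base_shape(cfg, seed = 1)
  expect_lt(abs(mask_volume_mm3(ball) - 4 / 3 * pi * 20^3),
            0.05 * 4 / 3 * pi * 20^3)
})

test_that("shape generation is deterministic and stays connected and interior", {
  cfg <- shape_config(c(36, 36, 36), c(1, 1, 1), 12,
                      irregularity = 0.3, lobe_count = 3)
  a <- generate_base_shape(cfg, seed = 1)
  b <- generate_base_shape(cfg, seed = 1)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$labels,
                         generate_base_shape(cfg, seed = 2)$labels))
  expect_true(flood_fill_connected(a))
  d <- dim(a$labels)
  expect_equal(sum(a$labels[c(1, d[1]), , ]) + sum(a$labels[, c(1, d[2]), ]) +
                 sum(a$labels[, , c(1, d[3])]), 0)
})

test_that("oversized shapes are rejected naming the violated axis", {
  expect_error(shape_config(c(10, 40, 40), c(1, 1, 1), 12), "along z")
  expect_error(shape_config(c(40, 40, 12), c(1, 1, 1), 12,
                            irregularity = 0.5, lobe_count = 2), "along x")
  expect_error(shape_config(c(30, 30, 30), c(1, 1, 1), 10, irregularity = 1),
               "star-convex")
})

test_that("annotator panels reduce to the base exactly when noise is off", {
  base <- generate_base_shape(
    shape_config(c(26, 30, 30), c(2, 1, 1), 10, 0.2, 3), seed = 4)
  pm <- simulate_annotator_contours(
    base, annotator_panel_config(3, 0, 0, seed = 9), n_sessions = 2)
  for (a in names(pm))
    for (s in names(pm[[a]]))
      expect_identical(pm[[a]][[s]]$labels, base$labels)
})

test_that("inter-observer spread increases monotonically with sigma_inter", {
  base <- generate_base_shape(
    shape_config(c(36, 38, 38), c(1, 1, 1), 13, 0.2, 3), seed = 4)
  mean_pairwise <- function(sig) {
    pm <- simulate_annotator_contours(
      base, annotator_panel_config(4, sig, 0, seed = 11), n_sessions = 1)
    ms <- lapply(pm, `[[`, 1)
    pairs <- combn(length(ms), 2)
    mean(apply(pairs, 2, function(ij) dsc(ms[[ij[1]]], ms[[ij[2]]])))
  }
  dscs <- vapply(c(0.5, 1, 2, 4), mean_pairwise, numeric(1))
  expect_true(all(diff(dscs) < 0))
})

test_that("session noise off makes an annotator's sessions identical", {
  base <- generate_base_shape(
    shape_config(c(30, 30, 30), c(1, 1, 1), 11), seed = 2)
  pm <- simulate_annotator_contours(
    base, annotator_panel_config(3, 2, 0, seed = 5), n_sessions = 2)
  for (a in names(pm)) {
    expect_identical(pm[[a]]$s1$labels, pm[[a]]$s2$labels)
    expect_equal(dsc(pm[[a]]$s1, pm[[a]]$s2), 1)
  }
})

test_that("focal disagreement adds a directional bump for selected annotators", {
  base <- generate_base_shape(
    shape_config(c(40, 40, 40), c(1, 1, 1), 12), seed = 3)
  pm <- simulate_annotator_contours(
    base,
    annotator_panel_config(6, 0, 0,
                           focal = list(direction = c(-1, 0, 0),
                                        extent_mm = 5, probability = 0.5),
                           seed = 21),
    n_sessions = 1)
  extra <- vapply(pm, function(s) mask_count(s$s1) - mask_count(base),
                  numeric(1))
  expect_true(any(extra > 0))    # some annotators include the bump
  expect_true(any(extra == 0))   # some do not
  expect_true(all(extra >= 0))
  grown <- pm[[which(extra > 0)[1]]]$s1
  added <- which(grown$labels == 1L & base$labels == 0L, arr.ind = TRUE)
  ctr <- contoureval:::mask_centroid_voxel(base)
  expect_true(all(added[, 1] < ctr[1]))  # bump lies on the -z side
})

test_that("voxel-flip raters honour their sensitivity and specificity", {
  base <- make_ball(10, grid = c(28, 28, 28))
  roi <- binary_mask(array(1L, c(28, 28, 28)))
  expect_error(rater_truth(0, 0.9), "sensitivity")
  expect_error(rater_truth(0.9, 1.2), "specificity")

  perfect <- simulate_voxelflip_raters(base, list(rater_truth(1, 1)),
                                       roi = roi, seed = 1)
  expect_identical(perfect[[1]]$labels, base$labels)

  truths <- list(rater_truth(0.9, 0.95), rater_truth(0.9, 0.95))
  rs <- simulate_voxelflip_raters(base, truths, roi = roi, seed = 7)
  n_fg <- mask_count(base)
  for (r in rs) {
    tpf <- sum(r$labels == 1L & base$labels == 1L) / n_fg
    se3 <- 3 * sqrt(0.9 * 0.1 / n_fg)
    expect_lt(abs(tpf - 0.9), max(se3, 0.01))
  }
  # same truth, different sub-streams: different masks
  expect_false(identical(rs[[1]]$labels, rs[[2]]$labels))
})

test_that("simulated logs are deterministic and respect active_fraction bounds", {
  cfg <- log_config(session_duration_s = 400, seed = 13)
  a <- simulate_interaction_log(cfg)
  b <- simulate_interaction_log(cfg)
  expect_identical(a$events, b$events)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "a.jsonl"); fb <- file.path(dir, "b.jsonl")
  write_interaction_log(a, fa); write_interaction_log(b, fb)
  expect_identical(readLines(fa), readLines(fb))  # byte-identical

  quiet <- simulate_interaction_log(
    log_config(session_duration_s = 300, active_fraction = 0, seed = 2))
  expect_false(any(grepl("drag", quiet$events$kind)))
})

test_that("pooled active fraction converges to its configured value", {
  target <- 0.33
  tot <- c(active = 0, obs = 0)
  for (i in 1:100) {
    tl <- segment_timeline(simulate_interaction_log(
      log_config(session_duration_s = 1320, active_fraction = target,
                 interruption_rate = 0, seed = i)))
    tot <- tot + c(tl$totals$active_s, tl$totals$observation_s)
  }
  expect_lt(abs(tot[1] / sum(tot) - target), 0.02)
})
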