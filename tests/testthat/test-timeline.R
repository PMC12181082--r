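test_that("a hand-computed toy log segments into the expected totals", {
  # drag stroke 2-10 s (active 8 s), observation 0-2 s and 10-20 s (12 s)
  tl <- segment_timeline(interaction_log(toy_events()))
  expect_equal(tl$totals$active_s, 8)
  expect_equal(tl$totals$observation_s, 12)
  expect_equal(tl$totals$excluded_s, 0)
  expect_equal(tl$totals$span_s, 20)
  acts <- tl$episodes[tl$episodes$class == "active", ]
  expect_equal(nrow(acts), 1)
  expect_equal(acts$tool, "lasso")
})

test_that("gaps longer than the break threshold are excluded, not observation", {
  ev <- data.frame(t_ms = c(0, 5000, 125000, 130000),
                   kind = "move", tool = "none", stringsAsFactors = FALSE)
  tl <- segment_timeline(interaction_log(ev), break_threshold_s = 85)
  expect_equal(tl$totals$excluded_s, 120)
  expect_equal(tl$totals$observation_s, 10)
  # the same 120 s gap is observation once the threshold allows it
  tl2 <- segment_timeline(interaction_log(ev), break_threshold_s = 121)
  expect_equal(tl2$totals$excluded_s, 0)
  expect_equal(tl2$totals$observation_s, 130)
})

test_that("a log with only moves is pure observation", {
  ev <- data.frame(t_ms = seq(0, 9000, 1000), kind = "move", tool = "none",
                   stringsAsFactors = FALSE)
  tl <- segment_timeline(interaction_log(ev))
  expect_equal(tl$totals$active_s, 0)
  expect_equal(tl$totals$observation_s, 9)
  expect_error(segment_timeline(interaction_log(ev[1, ])), "at least 2")
})

test_that("active + observation + excluded equals the log span exactly", {
  for (seed in 1:8) {
    lg <- simulate_interaction_log(
      log_config(session_duration_s = 300, interruption_rate = 2, seed = seed))
    tl <- segment_timeline(lg)
    expect_equal(tl$totals$active_s + tl$totals$observation_s +
                   tl$totals$excluded_s, tl$totals$span_s,
                 tolerance = 1e-12)
    # the class-wise interval sums account for the same partition
    expect_equal(sum(tl$intervals$dur_s), tl$totals$span_s, tolerance = 1e-9)
  }
})

test_that("raising the break threshold is monotone in observation/excluded time", {
  lg <- simulate_interaction_log(
    log_config(session_duration_s = 600, interruption_rate = 3, seed = 4))
  obs <- excl <- numeric(0)
  for (thr in c(20, 50, 85, 200, 1e5)) {
    tl <- segment_timeline(lg, break_threshold_s = thr)
    obs <- c(obs, tl$totals$observation_s)
    excl <- c(excl, tl$totals$excluded_s)
  }
  expect_true(all(diff(obs) >= 0))
  expect_true(all(diff(excl) <= 0))
})

test_that("observation histogram bins intervals and durations as stated", {
  ev <- data.frame(
    t_ms = c(0, 500, 1000, 21000),
    kind = "move", tool = "none", stringsAsFactors = FALSE)
  tl <- segment_timeline(interaction_log(ev))
  h <- observation_histogram(tl)  # intervals 0.5, 0.5, 20 s
  expect_equal(h$count, c(2, 0, 1, 0))
  expect_equal(h$duration_s, c(1, 0, 20, 0))
  expect_error(observation_histogram(tl, bin_edges_s = c(1, 0, 10)),
               "increasing")
  # no observation at all
  ev2 <- data.frame(t_ms = c(0, 1000), kind = c("drag_start", "drag_end"),
                    tool = "brush", stringsAsFactors = FALSE)
  h0 <- observation_histogram(segment_timeline(interaction_log(ev2)))
  expect_true(all(h0$count == 0))
})

test_that("histogram agrees with an independent recount on simulated logs", {
  lg <- simulate_interaction_log(log_config(session_duration_s = 500, seed = 9))
  tl <- segment_timeline(lg)
  edges <- c(0, 1, 10, 50, 85)
  h <- observation_histogram(tl, edges)
  obs <- tl$intervals$dur_s[tl$intervals$class == "observation"]
  for (b in 1:4) {
    expect_equal(h$count[b], sum(obs >= edges[b] & obs < edges[b + 1]))
    expect_equal(h$duration_s[b], sum(obs[obs >= edges[b] & obs < edges[b + 1]]))
  }
})

test_that("relative change reproduces the headline arithmetic", {
  expect_equal(relative_change(100, 77), -0.23)
  expect_equal(relative_change(150, 150), 0)
  expect_equal(relative_change(100, 206), 1.06)
  expect_error(relative_change(0, 10), "before_s")
})

test_that("time summaries aggregate sessions, tools and paired changes", {
  mk_log <- function(a, c, m, dur, tool) {
    ev <- data.frame(
      t_ms = c(0, 1000, 1000 + dur * 1000, 2000 + dur * 1000),
      kind = c("move", "drag_start", "drag_end", "move"),
      tool = c("none", tool, tool, "none"), stringsAsFactors = FALSE)
    segment_timeline(interaction_log(ev, a, c, m))
  }
  tls <- list(mk_log("A1", "C1", "manual", 100, "lasso"),
              mk_log("A1", "C2", "manual", 200, "lasso"),
              mk_log("A1", "C1", "dl", 77, "brush"),
              mk_log("A1", "C2", "dl", 154, "brush"))
  man <- study_manifest(data.frame(
    annotator_id = "A1", case_id = c("C1", "C2", "C1", "C2"),
    method = rep(c("manual", "dl"), each = 2), session = c(1, 1, 2, 2),
    mask_path = NA, log_path = NA, stringsAsFactors = FALSE),
    check_files = FALSE)
  ts <- summarize_times(tls, man)
  expect_equal(ts$sessions$lasso[1], 1)          # all manual active on lasso
  expect_equal(ts$sessions$brush[3], 1)
  agg <- ts$by_annotator
  expect_equal(agg$mean_active_s[agg$method == "manual"], 150)
  expect_equal(ts$changes$active_change, c(-0.23, -0.23))
  expect_error(summarize_times(tls[1:3], man), "missing timelines")
})

test_that("recovered tool composition matches the configured mix", {
  mix <- c(lasso = 0.5, brush = 0.3, eraser = 0.15, scissors = 0.05)
  tot <- setNames(numeric(4), names(mix))
  n_strokes <- 0
  for (seed in 1:40) {
    tl <- segment_timeline(simulate_interaction_log(
      log_config(session_duration_s = 400, tool_mix = mix, seed = seed)))
    act <- tl$intervals[tl$intervals$class == "active", ]
    by_tool <- tapply(act$dur_s, factor(act$tool, names(mix)), sum,
                      default = 0)
    tot <- tot + by_tool
    n_strokes <- n_strokes + sum(tl$episodes$class == "active")
  }
  frac <- tot / sum(tot)
  se3 <- 3 * sqrt(mix * (1 - mix) / n_strokes)
  expect_true(all(abs(frac - mix) < pmax(se3, 0.03)))
})
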