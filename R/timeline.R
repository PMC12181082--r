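#' Segment a session log into active, observation and excluded time
#'
#' Every interval between consecutive events is classified: *active* if it
#' lies within a drag stroke (between `drag_start` and its `drag_end`);
#' *excluded* if it is outside a stroke and longer than `break_threshold_s`
#' (an interruption to the contouring task); *observation* otherwise.
#' Clicks that trigger a DL prediction are observation — only dragging the
#' cursor counts as drawing. Adjacent intervals of the same class (and tool,
#' for active time) merge into episodes; an excluded interval always breaks
#' an observation episode.
#'
#' @param log an [interaction_log()] with >= 2 events.
#' @param break_threshold_s interruption threshold in seconds; default 85.
#' @return object of class `session_timeline`: `intervals` (raw classified
#'   inter-event intervals), `episodes` (merged), `totals` (`active_s`,
#'   `observation_s`, `excluded_s`, `tracked_s`, `span_s`), plus the session
#'   metadata. `active_s + observation_s + excluded_s` equals the log span
#'   exactly.
#' @export
segment_timeline <- function(log, break_threshold_s = 85) {
  stopifnot(inherits(log, "interaction_log"))
  ev <- log$events
  if (nrow(ev) < 2L) stop("need at least 2 events to segment a timeline")
  if (break_threshold_s <= 0) stop("break_threshold_s must be positive")

  n <- nrow(ev)
  # stroke open after event i: starts seen minus ends seen
  open_after <- cumsum(ev$kind == "drag_start") - cumsum(ev$kind == "drag_end")
  start_s <- ev$t_ms[-n] / 1000
  end_s <- ev$t_ms[-1] / 1000
  dur <- end_s - start_s
  active <- open_after[-n] > 0L
  cls <- ifelse(active, "active",
                ifelse(dur > break_threshold_s, "excluded", "observation"))
  tool <- ifelse(active, ev$tool[-n], "none")
  intervals <- data.frame(start_s = start_s, end_s = end_s, dur_s = dur,
                          class = cls, tool = tool, stringsAsFactors = FALSE)

  grp <- cumsum(c(TRUE, cls[-1] != cls[-length(cls)] |
                    tool[-1] != tool[-length(tool)]))
  episodes <- data.frame(
    start_s = tapply(start_s, grp, min),
    end_s = tapply(end_s, grp, max),
    class = tapply(cls, grp, `[`, 1),
    tool = tapply(tool, grp, `[`, 1),
    row.names = NULL, stringsAsFactors = FALSE)
  episodes$dur_s <- episodes$end_s - episodes$start_s

  # excluded time is the untracked remainder of the span, so that
  # active + observation + excluded == span holds by construction
  span <- ev$t_ms[n] / 1000 - ev$t_ms[1] / 1000
  totals <- list(active_s = sum(dur[cls == "active"]),
                 observation_s = sum(dur[cls == "observation"]))
  totals$excluded_s <- span - (totals$active_s + totals$observation_s)
  totals$tracked_s <- totals$active_s + totals$observation_s
  totals$span_s <- span
  structure(list(intervals = intervals, episodes = episodes, totals = totals,
                 annotator_id = log$annotator_id, case_id = log$case_id,
                 method = log$method, break_threshold_s = break_threshold_s),
            class = "session_timeline")
}

#' @export
print.session_timeline <- function(x, ...) {
  cat(sprintf(
    "<session_timeline> %s/%s/%s: active %.1f s, observation %.1f s, excluded %.1f s\n",
    x$annotator_id, x$case_id, x$method, x$totals$active_s,
    x$totals$observation_s, x$totals$excluded_s))
  invisible(x)
}

#' Histogram of observation intervals
#'
#' Bins the raw (unmerged) observation intervals — the times between mouse
#' events classified as observation — into half-open bins
#' `[edge_k, edge_k+1)`. Both interval counts and summed duration per bin
#' are returned, since shares of "observation time" can be read either way.
#'
#' @param timeline a [segment_timeline()] result.
#' @param bin_edges_s increasing bin edges in seconds; default
#'   `c(0, 1, 10, 50, 85)`.
#' @return data.frame with `bin`, `count`, `duration_s`.
#' @export
observation_histogram <- function(timeline, bin_edges_s = c(0, 1, 10, 50, 85)) {
  stopifnot(inherits(timeline, "session_timeline"))
  if (is.unsorted(bin_edges_s, strictly = TRUE))
    stop("bin_edges_s must be strictly increasing")
  obs <- timeline$intervals$dur_s[timeline$intervals$class == "observation"]
  k <- length(bin_edges_s) - 1L
  bin <- findInterval(obs, bin_edges_s, rightmost.closed = FALSE)
  keep <- bin >= 1L & bin <= k & obs < bin_edges_s[k + 1L]
  bin <- bin[keep]; obs <- obs[keep]
  data.frame(
    bin = sprintf("[%g,%g)", bin_edges_s[-(k + 1L)], bin_edges_s[-1L]),
    count = as.integer(tabulate(bin, nbins = k)),
    duration_s = as.numeric(tapply(c(obs, rep(0, k)), c(bin, seq_len(k)), sum)))
}

#' Relative change between paired durations
#'
#' `(after - before) / before`: the form in which time savings are quoted,
#' e.g. 100 s manual vs 77 s DL-assisted is a change of -0.23.
#'
#' @param before_s,after_s durations in seconds; `before_s > 0`.
#' @return signed fraction.
#' @export
relative_change <- function(before_s, after_s) {
  if (any(before_s <= 0)) stop("relative change undefined for before_s <= 0")
  (after_s - before_s) / before_s
}

#' Aggregate session timelines over a study
#'
#' Per-session totals and tool composition of active time, per-annotator and
#' per-case aggregates, and paired relative changes (DL vs manual) of active
#' and observation time per (annotator, case) — each case contributing
#' equally within an annotator.
#'
#' @param timelines named list of [segment_timeline()] results; names
#'   `"annotator|case|method"` (see [timeline_key()]), or any list whose
#'   elements carry their own metadata.
#' @param manifest a [study_manifest()]; every manifest session must have a
#'   timeline.
#' @return object of class `time_summary`: `sessions` (per-session table
#'   with tool fractions), `by_annotator`, `by_case` (mean/median active and
#'   observation), `changes` (per annotator x case relative changes).
#' @export
summarize_times <- function(timelines, manifest) {
  stopifnot(inherits(manifest, "study_manifest"))
  keys <- timeline_key(manifest$annotator_id, manifest$case_id, manifest$method)
  have <- vapply(timelines, function(t)
    timeline_key(t$annotator_id, t$case_id, t$method), character(1))
  missing <- setdiff(keys, have)
  if (length(missing))
    stop(sprintf("missing timelines for session(s): %s",
                 paste(missing, collapse = ", ")))
  tl <- timelines[match(keys, have)]

  tool_frac <- function(t) {
    a <- t$intervals[t$intervals$class == "active", ]
    out <- setNames(numeric(4), setdiff(TOOLS, "none"))
    if (nrow(a)) {
      by_tool <- tapply(a$dur_s, a$tool, sum)
      out[names(by_tool)] <- by_tool / sum(a$dur_s)
    }
    out
  }
  fr <- t(vapply(tl, tool_frac, numeric(4)))
  sessions <- data.frame(
    annotator_id = manifest$annotator_id, case_id = manifest$case_id,
    method = manifest$method, session = manifest$session,
    active_s = vapply(tl, function(t) t$totals$active_s, numeric(1)),
    observation_s = vapply(tl, function(t) t$totals$observation_s, numeric(1)),
    excluded_s = vapply(tl, function(t) t$totals$excluded_s, numeric(1)),
    stringsAsFactors = FALSE)
  sessions <- cbind(sessions, fr)
  rownames(sessions) <- NULL

  agg <- function(by) {
    g <- interaction(sessions[[by]], sessions$method, drop = TRUE)
    data.frame(
      group = vapply(strsplit(levels(g), "\\."), `[`, character(1), 1),
      method = vapply(strsplit(levels(g), "\\."), `[`, character(1), 2),
      mean_active_s = as.numeric(tapply(sessions$active_s, g, mean)),
      median_active_s = as.numeric(tapply(sessions$active_s, g, median)),
      mean_observation_s = as.numeric(tapply(sessions$observation_s, g, mean)),
      median_observation_s = as.numeric(tapply(sessions$observation_s, g, median)),
      row.names = NULL, stringsAsFactors = FALSE)
  }

  changes <- NULL
  if (all(METHODS %in% sessions$method)) {
    man <- sessions[sessions$method == "manual", ]
    dl <- sessions[sessions$method == "dl", ]
    key_m <- paste(man$annotator_id, man$case_id)
    key_d <- paste(dl$annotator_id, dl$case_id)
    common <- intersect(key_m, key_d)
    man <- man[match(common, key_m), ]; dl <- dl[match(common, key_d), ]
    changes <- data.frame(
      annotator_id = man$annotator_id, case_id = man$case_id,
      active_change = relative_change(man$active_s, dl$active_s),
      observation_change = relative_change(man$observation_s, dl$observation_s),
      stringsAsFactors = FALSE)
  }

  structure(list(sessions = sessions,
                 by_annotator = agg("annotator_id"),
                 by_case = agg("case_id"),
                 changes = changes), class = "time_summary")
}

#' Key identifying a session within a study
#' @param annotator_id,case_id,method session coordinates.
#' @return character key `"annotator|case|method"`.
#' @export
timeline_key <- function(annotator_id, case_id, method) {
  paste(annotator_id, case_id, method, sep = "|")
}
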