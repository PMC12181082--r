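#' Configuration of a simulated contouring session log
#'
#' Sessions are renewal processes alternating observation gaps and active
#' drag strokes. Gaps between mouse events are log-normal with a heavy right
#' tail (a mix of sub-second repositioning and long pauses); stroke
#' durations are gamma. Occasional interruptions — gaps longer than the
#' break threshold — are inserted at a configurable rate and are what the
#' downstream 85 s rule excludes.
#'
#' Stroke durations are calibrated so that the expected fraction of tracked
#' (non-excluded) time that is active equals `active_fraction`; the realized
#' fraction converges to it as sessions accumulate.
#'
#' @param session_duration_s target tracked span of the session in seconds.
#' @param active_fraction expected active share of tracked time, in `[0, 0.95]`.
#' @param tool_mix named non-negative weights over lasso, brush, eraser,
#'   scissors; strokes pick their tool by these weights.
#' @param observation_scale_s mean of the (untruncated) observation-gap
#'   distribution in seconds.
#' @param interruption_rate expected number of >threshold interruptions per
#'   session (Poisson).
#' @param break_threshold_s the interruption threshold the log is generated
#'   around; normal gaps are kept below it.
#' @param obs_per_cycle mean number of observation gaps between strokes.
#' @param seed integer seed.
#' @return object of class `log_config`.
#' @export
log_config <- function(session_duration_s = 1320, active_fraction = 0.33,
                       tool_mix = c(lasso = 0.6, brush = 0.2, eraser = 0.15,
                                    scissors = 0.05),
                       observation_scale_s = 4.4, interruption_rate = 1,
                       break_threshold_s = 85, obs_per_cycle = 4, seed = 1L) {
  if (session_duration_s <= 0) stop("session_duration_s must be positive")
  if (active_fraction < 0 || active_fraction > 0.95)
    stop("active_fraction must be in [0, 0.95]")
  if (is.null(names(tool_mix)) || !all(names(tool_mix) %in% TOOLS))
    stop("tool_mix must be named by tools")
  if (any(tool_mix < 0) || sum(tool_mix) <= 0)
    stop("tool_mix weights must be >= 0 and not all zero")
  if (observation_scale_s <= 0) stop("observation_scale_s must be positive")
  if (interruption_rate < 0) stop("interruption_rate must be >= 0")
  structure(list(session_duration_s = session_duration_s,
                 active_fraction = active_fraction, tool_mix = tool_mix,
                 observation_scale_s = observation_scale_s,
                 interruption_rate = interruption_rate,
                 break_threshold_s = break_threshold_s,
                 obs_per_cycle = obs_per_cycle, seed = as.integer(seed)),
            class = "log_config")
}

# Log-normal sdlog chosen so that ~40% of gaps are sub-second while long
# pauses still carry ~20% of observation duration, the mix reported for real
# contouring sessions.
OBS_SDLOG <- 1.5

#' Simulate an interaction-event log for one contouring session
#'
#' @param config a [log_config()].
#' @param annotator_id,case_id,method session metadata.
#' @return an [interaction_log()]; identical for identical `(config, seed)`.
#' @export
simulate_interaction_log <- function(config, annotator_id = "A1",
                                     case_id = "C1", method = "manual") {
  stopifnot(inherits(config, "log_config"))
  with_seed(config$seed,
            build_session_events(config, annotator_id, case_id, method))
}

build_session_events <- function(config, annotator_id, case_id, method) {
  f <- config$active_fraction
  sdlog <- OBS_SDLOG
  meanlog <- log(config$observation_scale_s) - sdlog^2 / 2
  cap <- 0.98 * config$break_threshold_s
  # truncated-at-cap gap distribution: inverse-CDF sampling and its mean
  p_cap <- stats::plnorm(cap, meanlog, sdlog)
  mean_trunc <- config$observation_scale_s *
    stats::pnorm((log(cap) - meanlog - sdlog^2) / sdlog) / p_cap
  draw_gap <- function(n) stats::qlnorm(runif(n) * p_cap, meanlog, sdlog)
  # expected active time per cycle balances expected observation per cycle;
  # the 0.2-gap settle pause before each stroke counts as observation too
  mu_active <- if (f > 0)
    f / (1 - f) * (config$obs_per_cycle + 0.2) * mean_trunc else 0

  n_breaks <- if (config$interruption_rate > 0)
    stats::rpois(1, config$interruption_rate) else 0L
  break_at <- sort(runif(n_breaks)) * config$session_duration_s

  obs_kinds <- c("move", "scroll", "zoom")
  obs_prob <- c(0.85, 0.09, 0.06)
  if (method == "dl") {
    obs_kinds <- c(obs_kinds, "predict")
    obs_prob <- c(0.8, 0.09, 0.06, 0.05)
  }
  tools <- names(config$tool_mix)[config$tool_mix > 0]
  wts <- config$tool_mix[config$tool_mix > 0]

  # The drawing effort is what a case fixes: a session ends once its active
  # budget has been drawn (observation time is stochastic around its
  # expectation), or once the target span is tracked for a stroke-free
  # session. This keeps realized active time tightly around
  # session_duration_s * active_fraction.
  active_target <- config$session_duration_s * f
  t <- 0
  tracked <- 0
  active_acc <- 0
  cur_tool <- ""
  chunks <- vector("list", 1024L)
  n_chunk <- 1L
  chunks[[1L]] <- list(t = 0, kind = "move", tool = "none")
  push <- function(tv, kv, lv) {
    n_chunk <<- n_chunk + 1L
    if (n_chunk > length(chunks)) length(chunks) <<- 2L * n_chunk
    chunks[[n_chunk]] <<- list(t = tv, kind = kv, tool = lv)
  }

  while (if (f > 0) active_acc < active_target
         else tracked < config$session_duration_s) {
    # observation run
    n_obs <- 1L
    if (config$obs_per_cycle > 1)
      n_obs <- 1L + rgeom(1, 1 / config$obs_per_cycle)
    gaps <- draw_gap(n_obs)
    kinds <- sample(obs_kinds, n_obs, replace = TRUE, prob = obs_prob)
    stroke_tool <- if (f > 0) sample(tools, 1, prob = wts) else ""
    toolv <- rep("none", n_obs)
    if (f > 0 && stroke_tool != cur_tool) {
      kinds[n_obs] <- "tool_select"
      toolv[n_obs] <- stroke_tool
    }
    push(t + cumsum(gaps), kinds, toolv)
    t <- t + sum(gaps)
    tracked <- tracked + sum(gaps)
    # pending interruption: a long silent gap, excluded downstream
    if (length(break_at) && tracked >= break_at[1]) {
      break_at <- break_at[-1]
      gap <- config$break_threshold_s * 1.5 + rexp(1, 1 / 60)
      t <- t + gap
      push(t, "move", "none")
    }
    if (f > 0) {
      dur <- rgamma(1, shape = 1.5, scale = mu_active / 1.5)
      settle <- draw_gap(1) * 0.2  # short pause before the stroke
      start <- t + settle
      n_drag <- min(40L, max(1L, floor(dur / 0.25)))
      stroke_t <- c(start, start + dur * seq_len(n_drag - 1L) / n_drag,
                    start + dur)
      push(stroke_t,
           c("drag_start", rep("drag", n_drag - 1L), "drag_end"),
           rep(stroke_tool, n_drag + 1L))
      t <- start + dur
      tracked <- tracked + settle + dur
      active_acc <- active_acc + dur
      cur_tool <- stroke_tool
    }
  }
  chunks <- chunks[seq_len(n_chunk)]
  ev <- data.frame(
    t_ms = round(unlist(lapply(chunks, `[[`, "t")) * 1000, 1),
    kind = unlist(lapply(chunks, `[[`, "kind")),
    tool = unlist(lapply(chunks, `[[`, "tool")),
    stringsAsFactors = FALSE)
  interaction_log(ev, annotator_id = annotator_id, case_id = case_id,
                  method = method)
}
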