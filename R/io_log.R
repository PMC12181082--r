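EVENT_KINDS <- c("move", "drag_start", "drag", "drag_end",
                 "tool_select", "scroll", "zoom", "predict")
TOOLS <- c("lasso", "brush", "eraser", "scissors", "none")
METHODS <- c("manual", "dl")

#' Interaction log of a contouring session
#'
#' A time-ordered stream of GUI events for one annotator working on one case
#' with one contouring method. Drag strokes (`drag_start` ... `drag_end`,
#' carrying a tool) are what downstream analysis counts as active contouring;
#' everything else is observation.
#'
#' @param events data.frame with columns `t_ms` (numeric, non-decreasing),
#'   `kind` (one of move, drag_start, drag, drag_end, tool_select, scroll,
#'   zoom, predict) and `tool` (lasso, brush, eraser, scissors or none).
#' @param annotator_id,case_id identifiers.
#' @param method `"manual"` or `"dl"`.
#' @return object of class `interaction_log`.
#' @export
interaction_log <- function(events, annotator_id = "A1", case_id = "C1",
                            method = c("manual", "dl")) {
  method <- match.arg(method)
  events <- validate_events(events)
  structure(list(events = events, annotator_id = annotator_id,
                 case_id = case_id, method = method),
            class = "interaction_log")
}

#' @export
print.interaction_log <- function(x, ...) {
  cat(sprintf("<interaction_log> %s/%s/%s: %d events over %.1f s\n",
              x$annotator_id, x$case_id, x$method, nrow(x$events),
              diff(range(x$events$t_ms)) / 1000))
  invisible(x)
}

validate_events <- function(events) {
  need <- c("t_ms", "kind", "tool")
  if (!all(need %in% names(events)))
    stop("events need columns t_ms, kind, tool")
  events <- events[, need]
  events$t_ms <- as.numeric(events$t_ms)
  events$kind <- as.character(events$kind)
  events$tool <- as.character(events$tool)
  bad <- which(!(events$kind %in% EVENT_KINDS))
  if (length(bad))
    stop(sprintf("unknown event kind '%s' at line %d", events$kind[bad[1]], bad[1]))
  bad <- which(!(events$tool %in% TOOLS))
  if (length(bad))
    stop(sprintf("unknown tool '%s' at line %d", events$tool[bad[1]], bad[1]))
  if (is.unsorted(events$t_ms))
    stop("event timestamps must be non-decreasing")
  drag <- events$kind %in% c("drag_start", "drag", "drag_end")
  if (any(events$tool[drag] == "none"))
    stop(sprintf("drag event without a tool at line %d",
                 which(drag & events$tool == "none")[1]))
  # strict nesting of strokes
  depth <- 0L
  for (i in seq_len(nrow(events))) {
    k <- events$kind[i]
    if (k == "drag_start") {
      if (depth > 0L) stop(sprintf("nested drag_start at line %d", i))
      depth <- 1L
    } else if (k == "drag") {
      if (depth == 0L) stop(sprintf("drag outside a stroke at line %d", i))
    } else if (k == "drag_end") {
      if (depth == 0L) stop(sprintf("drag_end before drag_start at line %d", i))
      depth <- 0L
    }
  }
  if (depth != 0L) stop("unterminated drag stroke at end of log")
  rownames(events) <- NULL
  events
}

#' Read an interaction log (JSON Lines or CSV)
#'
#' JSONL files carry one event object per line, preceded by a metadata
#' record `{"annotator_id":..., "case_id":..., "method":...}`. CSV files
#' carry the metadata as constant columns. Both encodings parse to the same
#' [interaction_log()]. Events are sorted by timestamp and stroke nesting is
#' validated.
#'
#' @param path path to a `.jsonl`/`.ndjson` or `.csv` file.
#' @return an [interaction_log()].
#' @export
read_interaction_log <- function(path) {
  if (!file.exists(path)) stop(sprintf("log file not found: %s", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("annotator_id", "case_id", "method")
    if (!all(need %in% names(df)))
      stop(sprintf("CSV log %s lacks metadata columns", path))
    meta <- df[1, need]
    ev <- df[, c("t_ms", "kind", "tool")]
  } else {
    lines <- readLines(path)
    if (length(lines) < 2L) stop(sprintf("log %s has no events", path))
    meta <- jsonlite::fromJSON(lines[1])
    recs <- lapply(lines[-1], jsonlite::fromJSON)
    ev <- data.frame(
      t_ms = vapply(recs, function(r) as.numeric(r$t_ms), numeric(1)),
      kind = vapply(recs, function(r) as.character(r$kind), character(1)),
      tool = vapply(recs, function(r) as.character(r$tool), character(1)),
      stringsAsFactors = FALSE)
  }
  ev <- ev[order(ev$t_ms), , drop = FALSE]
  interaction_log(ev, annotator_id = as.character(meta$annotator_id),
                  case_id = as.character(meta$case_id),
                  method = as.character(meta$method))
}

#' Write an interaction log
#'
#' @param log an [interaction_log()].
#' @param path output path; `.csv` selects CSV, anything else JSON Lines.
#' @return `path`, invisibly.
#' @export
write_interaction_log <- function(log, path) {
  stopifnot(inherits(log, "interaction_log"))
  ev <- log$events
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- data.frame(annotator_id = log$annotator_id, case_id = log$case_id,
                     method = log$method, ev, stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE)
  } else {
    meta <- sprintf('{"annotator_id":"%s","case_id":"%s","method":"%s"}',
                    log$annotator_id, log$case_id, log$method)
    body <- sprintf('{"t_ms":%s,"kind":"%s","tool":"%s"}',
                    format(ev$t_ms, trim = TRUE, scientific = FALSE, digits = 15),
                    ev$kind, ev$tool)
    writeLines(c(meta, body), path)
  }
  invisible(path)
}
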