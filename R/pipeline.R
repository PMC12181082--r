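#' Run a full observer-study analysis
#'
#' One-command orchestration: simulate (or load) a study of annotator masks
#' and session logs, build a STAPLE consensus per case and method, score
#' every contour against its consensus (DSC, APL at the configured
#' tolerance), map signed surface deviations and their cross-annotator
#' percentiles, segment and aggregate interaction time, and compare the two
#' methods with paired Wilcoxon signed-rank tests.
#'
#' Re-running with the same configuration reproduces every numeric output
#' bit for bit; the provenance block records the configuration hash, seed
#' and the decision flags in effect. When `write_outputs` is on, an
#' `INCOMPLETE` marker is present in `out_dir` while the run is in flight
#' and removed on success; any stage failure aborts with the stage name.
#'
#' @param config a configuration list (see [default_study_config()]) or a
#'   path to a YAML/JSON config file. Set `config$simulate = FALSE` and
#'   `config$manifest` to analyse data on disk instead of simulating.
#' @param out_dir output directory for tables, consensus masks, deviation
#'   maps, figures and the run log.
#' @param write_outputs write files (default: only when `out_dir` given).
#' @param verbose print one line per stage.
#' @return object of class `study_report`; see [validate_report()] for the
#'   schema.
#' @export
run_study <- function(config = default_study_config(), out_dir = NULL,
                      write_outputs = !is.null(out_dir), verbose = FALSE) {
  t0 <- Sys.time()
  if (is.character(config)) config <- read_study_config(config)
  config <- merge_config(default_study_config(), config)
  if (write_outputs) {
    if (is.null(out_dir)) stop("write_outputs requires out_dir")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.create(file.path(out_dir, "INCOMPLETE"))
  }
  log_lines <- character(0)
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    line <- sprintf("stage %-12s %6.1f s", name,
                    as.numeric(difftime(Sys.time(), ts, units = "secs")))
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
    out
  }

  data <- stage("inputs", if (isTRUE(config$simulate))
    simulate_study(config) else load_study(config))
  cons <- stage("consensus", build_consensus(data, config))
  metrics <- stage("metrics", score_contours(data, cons, config))
  devs <- stage("deviation", map_deviations(data, cons, config))
  times <- stage("times", analyse_times(data, config))
  stats <- stage("stats", compare_methods(metrics, times, config))

  report <- structure(list(
    schema_version = "1.0",
    provenance = list(
      config_hash = config_hash(config),
      seed = config$study$seed,
      package_version = as.character(utils::packageVersion("contoureval")),
      decision_flags = list(
        consensus_scope = config$staple$scope,
        centroid_alignment = isTRUE(config$deviation$align),
        apl_orientation = "reference_to_test",
        break_threshold_s = config$time$break_threshold_s,
        apl_tolerance_mm = config$apl$tolerance_mm,
        staple_threshold = config$staple$threshold,
        zero_difference_rule = "drop"),
      generated = format(t0, "%Y-%m-%d %H:%M:%S")),
    config = config,
    consensus = cons$table,
    performances = cons$performances,
    metrics = metrics$table,
    intra_observer = metrics$intra,
    deviation = devs$table,
    time = list(sessions = times$summary$sessions,
                by_annotator = times$summary$by_annotator,
                by_case = times$summary$by_case,
                changes = times$summary$changes,
                histograms = times$histograms),
    stats = stats,
    artifacts = list(consensus = cons$results, deviation_maps = devs$maps,
                     timelines = times$timelines)),
    class = "study_report")
  validate_report(report)

  if (write_outputs) {
    stage("write", write_report_files(report, data, out_dir))
    file.remove(file.path(out_dir, "INCOMPLETE"))
    report$provenance$runtime_s <-
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    writeLines(c(log_lines,
                 sprintf("total %.1f s", report$provenance$runtime_s)),
               file.path(out_dir, "run_log.txt"))
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d cases x %d annotators, methods: %s\n",
              length(unique(x$metrics$case_id)),
              length(unique(x$metrics$annotator_id)),
              paste(unique(x$metrics$method), collapse = ", ")))
  s <- x$stats$summaries
  for (m in names(s$dsc_by_method))
    cat(sprintf("  %-6s consensus DSC %.3f +/- %.3f, relative APL %.3f\n", m,
                s$dsc_by_method[[m]]$mean, s$dsc_by_method[[m]]$sd,
                s$apl_by_method[[m]]$mean))
  if (!is.null(s$intra_dsc))
    cat(sprintf("  intra-observer DSC %.3f +/- %.3f\n",
                s$intra_dsc$mean, s$intra_dsc$sd))
  if (!is.null(s$active_change))
    cat(sprintf("  mean relative active-time change %.3f (Wilcoxon p = %.2g)\n",
                s$active_change$mean, x$stats$tests$active_time$p_value))
  invisible(x)
}

#' Validate the study-report schema
#'
#' @param report a [run_study()] result.
#' @return `TRUE` invisibly; errors listing missing fields otherwise.
#' @export
validate_report <- function(report) {
  need <- c("schema_version", "provenance", "config", "consensus",
            "performances", "metrics", "deviation", "time", "stats")
  miss <- setdiff(need, names(report))
  if (length(miss))
    stop(sprintf("report lacks field(s): %s", paste(miss, collapse = ", ")))
  if (!identical(report$schema_version, "1.0"))
    stop("unsupported report schema version")
  for (f in c("config_hash", "seed", "decision_flags"))
    if (is.null(report$provenance[[f]]))
      stop(sprintf("provenance lacks '%s'", f))
  need_cols <- c("case_id", "method", "annotator_id", "dsc", "apl_mm",
                 "relative_apl", "reference_length_mm")
  miss <- setdiff(need_cols, names(report$metrics))
  if (length(miss))
    stop(sprintf("metrics table lacks column(s): %s", paste(miss, collapse = ", ")))
  invisible(TRUE)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

# ---- stages ----------------------------------------------------------------

simulate_study <- function(config) {
  st <- config$study
  master <- st$seed
  methods <- st$methods
  ann_ids <- paste0("A", seq_len(st$n_annotators))
  case_ids <- paste0("C", seq_len(st$n_cases))
  sh <- config$shape
  pn <- config$panel
  bias_scale <- ifelse(methods == "dl", pn$dl_bias_scale, 1)

  masks <- list(); logs <- list()
  for (ci in seq_along(case_ids)) {
    radius <- with_seed(subseed(master, "radius", ci),
                        runif(1, sh$base_radius_range_mm[1],
                              sh$base_radius_range_mm[2]))
    scfg <- shape_config(sh$grid_shape, sh$spacing_mm, radius,
                         sh$irregularity, sh$lobe_count)
    base <- generate_base_shape(scfg, seed = subseed(master, "shape", ci))
    pcfg <- annotator_panel_config(st$n_annotators, pn$sigma_inter_mm,
                                   pn$sigma_intra_mm, focal = pn$focal,
                                   seed = subseed(master, "panel", ci))
    pm <- simulate_annotator_contours(base, pcfg,
                                      n_sessions = length(methods),
                                      bias_scale = bias_scale)
    masks[[case_ids[ci]]] <- setNames(lapply(seq_along(methods), function(s)
      setNames(lapply(ann_ids, function(a) pm[[a]][[s]]), ann_ids)), methods)
    for (m in methods)
      for (a in ann_ids) {
        lc <- config$logs[[m]]
        lcfg <- log_config(
          session_duration_s = lc$session_duration_s,
          active_fraction = lc$active_fraction,
          tool_mix = unlist(lc$tool_mix),
          observation_scale_s = lc$observation_scale_s,
          interruption_rate = lc$interruption_rate,
          break_threshold_s = config$time$break_threshold_s,
          seed = subseed(master, "log", a, case_ids[ci], m))
        logs[[timeline_key(a, case_ids[ci], m)]] <-
          simulate_interaction_log(lcfg, a, case_ids[ci], m)
      }
  }
  manifest <- study_manifest(expand_manifest(ann_ids, case_ids, methods),
                             check_files = FALSE)
  list(masks = masks, logs = logs, manifest = manifest,
       annotators = ann_ids, cases = case_ids, methods = methods)
}

expand_manifest <- function(ann_ids, case_ids, methods) {
  g <- expand.grid(annotator_id = ann_ids, case_id = case_ids,
                   method = methods, stringsAsFactors = FALSE)
  g$session <- match(g$method, methods)
  g$mask_path <- NA_character_
  g$log_path <- NA_character_
  g
}

load_study <- function(config) {
  manifest <- read_manifest(config$manifest, check_files = TRUE)
  ann_ids <- unique(manifest$annotator_id)
  case_ids <- unique(manifest$case_id)
  methods <- unique(manifest$method)
  masks <- list(); logs <- list()
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    masks[[r$case_id]][[r$method]][[r$annotator_id]] <- read_mask(r$mask_path)
    if (!is.na(r$log_path))
      logs[[timeline_key(r$annotator_id, r$case_id, r$method)]] <-
        read_interaction_log(r$log_path)
  }
  list(masks = masks, logs = logs, manifest = manifest,
       annotators = ann_ids, cases = case_ids, methods = methods)
}

build_consensus <- function(data, config) {
  sc <- config$staple
  results <- list()
  rows <- list(); perfs <- list()
  for (case_id in data$cases) {
    pooled <- NULL
    if (identical(sc$scope, "pooled")) {
      all_masks <- unlist(data$masks[[case_id]], recursive = FALSE,
                          use.names = FALSE)
      pooled <- staple(all_masks, threshold = sc$threshold, tol = sc$tol,
                       max_iter = sc$max_iter, roi_margin = sc$roi_margin)
    }
    for (m in data$methods) {
      res <- if (!is.null(pooled)) pooled else
        staple(data$masks[[case_id]][[m]], threshold = sc$threshold,
               tol = sc$tol, max_iter = sc$max_iter,
               roi_margin = sc$roi_margin)
      results[[case_id]][[m]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = case_id, method = m, scope = sc$scope,
        n_iterations = res$n_iterations, converged = res$converged,
        prior_gamma = res$prior_gamma,
        consensus_voxels = mask_count(res$consensus_mask),
        stringsAsFactors = FALSE)
      pf <- res$performances
      pf$rater <- if (!is.null(pooled))
        paste0("pooled", pf$rater) else data$annotators[pf$rater]
      perfs[[length(perfs) + 1L]] <-
        cbind(data.frame(case_id = case_id, method = m,
                         stringsAsFactors = FALSE), pf)
    }
  }
  list(results = results, table = do.call(rbind, rows),
       performances = do.call(rbind, perfs))
}

score_contours <- function(data, cons, config) {
  tol <- config$apl$tolerance_mm
  rows <- list()
  for (case_id in data$cases)
    for (m in data$methods) {
      ref <- cons$results[[case_id]][[m]]$consensus_mask
      for (a in data$annotators) {
        rec <- added_path_length(ref, data$masks[[case_id]][[m]][[a]], tol)
        rows[[length(rows) + 1L]] <- data.frame(
          case_id = case_id, method = m, annotator_id = a, dsc = rec$dsc,
          apl_mm = rec$apl_mm, relative_apl = rec$relative_apl,
          reference_length_mm = rec$reference_length_mm,
          stringsAsFactors = FALSE)
      }
    }
  intra <- NULL
  if (all(METHODS %in% data$methods)) {
    irows <- list()
    for (case_id in data$cases)
      for (a in data$annotators)
        irows[[length(irows) + 1L]] <- data.frame(
          case_id = case_id, annotator_id = a,
          dsc = dsc(data$masks[[case_id]][["manual"]][[a]],
                    data$masks[[case_id]][["dl"]][[a]]),
          stringsAsFactors = FALSE)
    intra <- do.call(rbind, irows)
  }
  list(table = do.call(rbind, rows), intra = intra)
}

map_deviations <- function(data, cons, config) {
  maps <- list(); rows <- list()
  for (case_id in data$cases)
    for (m in data$methods) {
      consensus <- cons$results[[case_id]][[m]]$consensus_mask
      surf <- extract_surface(consensus)
      dv <- vapply(data$annotators, function(a)
        signed_deviation(consensus, data$masks[[case_id]][[m]][[a]],
                         align = isTRUE(config$deviation$align)),
        numeric(nrow(surf$voxel)))
      dm <- deviation_percentiles(dv, levels = config$deviation$levels,
                                  surface = surf)
      maps[[case_id]][[m]] <- dm
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = case_id, method = m,
        n_elements = nrow(dm$percentiles),
        median_of_medians_mm = dm$summary$median_of_medians_mm,
        max_range_10_90_mm = dm$summary$max_range_10_90_mm,
        stringsAsFactors = FALSE)
    }
  list(maps = maps, table = do.call(rbind, rows))
}

analyse_times <- function(data, config) {
  if (length(data$logs) == 0L)
    return(list(timelines = NULL, summary = NULL, histograms = NULL))
  timelines <- lapply(data$logs, segment_timeline,
                      break_threshold_s = config$time$break_threshold_s)
  summary <- summarize_times(timelines, data$manifest)
  hrows <- list()
  for (m in data$methods) {
    tls <- Filter(function(t) t$method == m, timelines)
    hs <- lapply(tls, observation_histogram,
                 bin_edges_s = config$time$bin_edges_s)
    h <- hs[[1]]
    if (length(hs) > 1L)
      for (i in 2:length(hs)) {
        h$count <- h$count + hs[[i]]$count
        h$duration_s <- h$duration_s + hs[[i]]$duration_s
      }
    h$count_share <- h$count / sum(h$count)
    h$duration_share <- h$duration_s / sum(h$duration_s)
    hrows[[m]] <- cbind(data.frame(method = m, stringsAsFactors = FALSE), h)
  }
  list(timelines = timelines, summary = summary,
       histograms = do.call(rbind, c(hrows, list(make.row.names = FALSE))))
}

compare_methods <- function(metrics, times, config) {
  tests <- list(); summaries <- list()
  # degenerate studies (e.g. a noise-free panel) have no nonzero differences;
  # record an undefined test rather than failing the whole run
  wilcoxon_or_na <- function(a, b, alternative) {
    tryCatch(wilcoxon_signed_rank(a, b, alternative),
             error = function(e) structure(
               list(statistic_w = NA_real_, p_value = NA_real_,
                    n_effective = 0L, alternative = alternative,
                    method = "undefined", note = conditionMessage(e)),
               class = "wilcoxon_result"))
  }
  tab <- metrics$table
  for (m in unique(tab$method)) {
    summaries$dsc_by_method[[m]] <- summarize_values(tab$dsc[tab$method == m])
    summaries$apl_by_method[[m]] <-
      summarize_values(tab$relative_apl[tab$method == m])
  }
  if (all(METHODS %in% tab$method)) {
    man <- tab[tab$method == "manual", ]
    dl <- tab[tab$method == "dl", ]
    key_m <- paste(man$annotator_id, man$case_id)
    dl <- dl[match(key_m, paste(dl$annotator_id, dl$case_id)), ]
    tests$dsc <- wilcoxon_or_na(dl$dsc, man$dsc, "two_sided")
    tests$relative_apl <- wilcoxon_or_na(dl$relative_apl,
                                               man$relative_apl, "two_sided")
  }
  if (!is.null(metrics$intra))
    summaries$intra_dsc <- summarize_values(metrics$intra$dsc)
  if (!is.null(times$summary) && !is.null(times$summary$changes)) {
    ch <- times$summary$changes
    summaries$active_change <- summarize_values(ch$active_change)
    summaries$observation_change <- summarize_values(ch$observation_change)
    sess <- times$summary$sessions
    for (m in unique(sess$method)) {
      s <- sess[sess$method == m, ]
      summaries$observation_share[[m]] <-
        sum(s$observation_s) / sum(s$active_s + s$observation_s)
    }
    man <- sess[sess$method == "manual", ]
    dl <- sess[sess$method == "dl", ]
    key_m <- paste(man$annotator_id, man$case_id)
    dl <- dl[match(key_m, paste(dl$annotator_id, dl$case_id)), ]
    tests$active_time <- wilcoxon_or_na(dl$active_s, man$active_s, "less")
    tests$observation_time <- wilcoxon_or_na(dl$observation_s,
                                                   man$observation_s,
                                                   "two_sided")
  }
  list(tests = tests, summaries = summaries, alpha = 0.01)
}

# ---- output files ----------------------------------------------------------

write_report_files <- function(report, data, out_dir) {
  wj <- function(x, name)
    jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", null = "null")
  write.csv(report$metrics, file.path(out_dir, "metrics.csv"),
            row.names = FALSE)
  if (!is.null(report$intra_observer))
    write.csv(report$intra_observer, file.path(out_dir, "intra_dsc.csv"),
              row.names = FALSE)
  write.csv(report$performances, file.path(out_dir, "staple_performance.csv"),
            row.names = FALSE)
  if (!is.null(report$time$sessions)) {
    write.csv(report$time$sessions, file.path(out_dir, "times.csv"),
              row.names = FALSE)
    if (!is.null(report$time$changes))
      write.csv(report$time$changes, file.path(out_dir, "time_changes.csv"),
                row.names = FALSE)
  }
  stats_out <- list(
    tests = lapply(report$stats$tests, unclass),
    summaries = report$stats$summaries, alpha = report$stats$alpha)
  wj(stats_out, "stats.json")
  for (case_id in names(report$artifacts$consensus))
    for (m in names(report$artifacts$consensus[[case_id]])) {
      res <- report$artifacts$consensus[[case_id]][[m]]
      write_mask(res$consensus_mask,
                 file.path(out_dir, sprintf("consensus_%s_%s.nii.gz",
                                            case_id, m)))
      dm <- report$artifacts$deviation_maps[[case_id]][[m]]
      wj(list(case_id = case_id, method = m,
              coordinates_mm = as.data.frame(dm$surface$coord_mm),
              percentiles = as.data.frame(dm$percentiles),
              range_10_90 = dm$range_10_90,
              summary = dm$summary[c("median_of_medians_mm",
                                     "max_range_10_90_mm")]),
         sprintf("devmap_%s_%s.json", case_id, m))
      grDevices::png(file.path(out_dir, sprintf("devmap_%s_%s.png",
                                                case_id, m)),
                     width = 1200, height = 420)
      plot(dm)
      grDevices::dev.off()
    }
  slim <- report[c("schema_version", "provenance", "consensus", "metrics",
                   "intra_observer", "deviation")]
  slim$time <- report$time[c("by_annotator", "by_case", "changes",
                             "histograms")]
  slim$stats <- stats_out
  wj(slim, "report.json")
  invisible(out_dir)
}
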