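#' Study manifest: the annotator x case x method bookkeeping
#'
#' One record per contouring session, mapping files to their place in the
#' study design. `(annotator_id, case_id, method)` must be unique — in this
#' design each annotator contours each case once per method.
#'
#' @param records data.frame with columns `annotator_id`, `case_id`,
#'   `method`, `session`, `mask_path`, `log_path` (`log_path` may be `NA`).
#' @param check_files verify that referenced files exist.
#' @return object of class `study_manifest` (a validated data.frame).
#' @export
study_manifest <- function(records, check_files = TRUE) {
  need <- c("annotator_id", "case_id", "method", "session", "mask_path", "log_path")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop(sprintf("manifest lacks columns: %s", paste(miss, collapse = ", ")))
  records <- as.data.frame(records)[, need]
  if (!all(records$method %in% METHODS))
    stop("manifest method must be 'manual' or 'dl'")
  key <- paste(records$annotator_id, records$case_id, records$method)
  if (anyDuplicated(key))
    stop(sprintf("duplicate manifest entry: %s", key[duplicated(key)][1]))
  if (check_files) {
    paths <- c(records$mask_path, records$log_path)
    paths <- paths[!is.na(paths)]
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop(sprintf("manifest references missing file(s): %s",
                   paste(missing, collapse = ", ")))
  }
  class(records) <- c("study_manifest", "data.frame")
  records
}

#' Read a study manifest from YAML or CSV
#'
#' YAML manifests hold a top-level `sessions:` list of records; CSV
#' manifests are flat tables. Relative paths are resolved against the
#' manifest's directory.
#'
#' @param path manifest file.
#' @param check_files verify referenced files exist.
#' @return a [study_manifest()].
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- read.csv(path, stringsAsFactors = FALSE)
  } else {
    y <- yaml::read_yaml(path)
    sess <- if (!is.null(y$sessions)) y$sessions else y
    df <- do.call(rbind, lapply(sess, function(r)
      data.frame(annotator_id = r$annotator_id, case_id = r$case_id,
                 method = r$method, session = r$session,
                 mask_path = r$mask_path %||% NA_character_,
                 log_path = r$log_path %||% NA_character_,
                 stringsAsFactors = FALSE)))
  }
  base <- dirname(normalizePath(path))
  for (col in c("mask_path", "log_path")) {
    rel <- !is.na(df[[col]]) & !grepl("^/", df[[col]])
    df[[col]][rel] <- file.path(base, df[[col]][rel])
  }
  study_manifest(df, check_files = check_files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
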