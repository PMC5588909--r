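# Configuration loading and the field-result file format.
#
# Field results are plain CSV with '#'-prefixed header comment lines for
# the session metadata, so a result file is self-describing and
# round-trips losslessly.

config_scalar_keys <- c("version", "eye", "pattern_name", "seed_start_db",
                        "fixation_tol_deg", "dwell_ms", "direction_tol_deg",
                        "amplitude_tol_frac", "window_ms", "priority_weight",
                        "retry_budget", "rng_seed")

#' Load a session configuration from YAML
#'
#' Missing keys take the documented defaults (including the
#' version-dependent dwell and priority weight); unknown keys are
#' rejected.  Nested `stimulus` (level_db, size, duration_ms,
#' background_cdm2) and `screen` (width_mm, height_mm, background_cdm2,
#' lut path) blocks are supported.
#'
#' @param path YAML file path.
#' @return An `svop_config`.
#' @export
load_config <- function(path) {
  rec <- yaml::read_yaml(path)
  if (is.null(rec)) rec <- list()
  known <- c(config_scalar_keys, "stimulus", "screen")
  bad <- setdiff(names(rec), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(rec$version) && !rec$version %in% c("v1", "v2")) {
    stop("version must be v1 or v2, got: ", rec$version)
  }
  args <- rec[intersect(names(rec), config_scalar_keys)]
  if (!is.null(rec$stimulus)) {
    args$stimulus <- do.call(stimulus_spec, rec$stimulus)
  }
  if (!is.null(rec$screen)) {
    sc <- rec$screen
    if (!is.null(sc$lut)) sc$lut <- read_lut(sc$lut)
    args$screen <- do.call(screen_model, sc)
  }
  do.call(session_config, args)
}

#' Save a session configuration as YAML
#'
#' Inverse of [load_config()] for the scalar keys and the stimulus block
#' (the screen LUT is referenced by path, not embedded).
#'
#' @param config An `svop_config`.
#' @param path Output path.
#' @export
save_config <- function(config, path) {
  rec <- config[config_scalar_keys]
  rec$stimulus <- list(level_db = config$stimulus$level_db,
                       duration_ms = config$stimulus$duration_ms,
                       background_cdm2 = config$stimulus$background_cdm2)
  yaml::write_yaml(rec, path)
  invisible(path)
}

#' Write a visual-field result to CSV
#'
#' Columns `x_deg`, `y_deg`, `threshold_db`, `n_presentations`,
#' `is_blind_spot`; header comment lines carry the eye, version,
#' completeness and duration.
#'
#' @param field An `svop_field`.
#' @param path Output path.
#' @export
write_field <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# pattern: %s", field$pattern_name),
    sprintf("# eye: %s", field$eye),
    sprintf("# version: %s", field$version),
    sprintf("# complete: %s", tolower(as.character(field$complete))),
    sprintf("# duration_s: %s", format(field$duration_s)),
    sprintf("# fp_rate: %s", format(field$fp_rate))
  ), con)
  utils::write.csv(
    field$points[c("x_deg", "y_deg", "threshold_db", "n_presentations",
                   "is_blind_spot")],
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a visual-field result from CSV
#'
#' @param path File written by [write_field()].
#' @return An `svop_field`; malformed files (missing columns, wrong
#'   location count, out-of-range thresholds) raise errors.
#' @export
read_field <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*:\\s*", "", kv))
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  need <- c("x_deg", "y_deg", "threshold_db", "n_presentations",
            "is_blind_spot")
  if (!all(need %in% names(df))) {
    stop("field file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  pattern <- generate_pattern(meta$pattern %||% "24-2",
                              meta$eye %||% "right")
  if (nrow(df) != nrow(pattern)) {
    stop("field file has ", nrow(df), " rows; pattern ",
         meta$pattern %||% "24-2", " requires ", nrow(pattern))
  }
  # align file rows with the canonical pattern ordering
  key <- function(x, y) paste(x, y)
  m <- match(key(pattern$x_deg, pattern$y_deg), key(df$x_deg, df$y_deg))
  if (anyNA(m)) stop("field file coordinates do not match the pattern")
  df <- df[m, ]
  dur <- suppressWarnings(as.numeric(meta$duration_s %||% NA))
  fp <- suppressWarnings(as.numeric(meta$fp_rate %||% NA))
  visual_field(pattern,
               threshold_db = df$threshold_db,
               n_presentations = df$n_presentations,
               version = meta$version %||% "v2",
               complete = identical(meta$complete, "true"),
               duration_s = dur, fp_rate = fp)
}

#' Write a run manifest
#'
#' Records the configuration, seed and output paths of a run so it can be
#' reproduced bit-identically.
#'
#' @param path Manifest path (JSON).
#' @param config_path,observer_path,outputs Paths recorded in the
#'   manifest.
#' @param seed Session seed.
#' @export
write_manifest <- function(path, config_path = NULL, observer_path = NULL,
                           outputs = character(0), seed = NA_integer_) {
  jsonlite::write_json(list(
    tool = "svopsim",
    version = as.character(utils::packageVersion("svopsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config_path, observer = observer_path,
    seed = seed, outputs = outputs
  ), path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Write a session event log as JSON lines
#'
#' @param session An `svop_session`.
#' @param path Output path (one event object per line).
#' @export
write_session_log <- function(session, path) {
  log <- session$log
  lines <- vapply(seq_len(nrow(log)), function(i) {
    rec <- as.list(log[i, ])
    rec <- rec[!vapply(rec, function(v) is.na(v) && !is.character(v), logical(1))]
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
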