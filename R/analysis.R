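# The validation statistics: exclusion bookkeeping, floor truncation,
# mean-sensitivity agreement, per-location Pearson correlation maps, and
# test-retest repeatability over the 54 test points.

#' Apply the exclusion rules to a set of test results
#'
#' Gaze-driven tests are excluded iff incomplete (the instrument's only
#' failure mode here); button-response tests are excluded iff their
#' false-positive rate exceeds `fp_cutoff` (manufacturer reliability
#' guideline).  Eyelid/lens-rim artefact grading requires a human reader
#' and is reported as a non-simulated category.
#'
#' @param results List of `svop_field` objects.
#' @param fp_cutoff False-positive exclusion bound, default 0.15.
#' @return `list(kept, excluded, reasons)`: `kept` and `excluded` are
#'   index vectors partitioning the input, `reasons` a character vector
#'   (one reason per excluded test).
#' @export
apply_exclusions <- function(results, fp_cutoff = 0.15) {
  reasons <- vapply(results, function(f) {
    if (identical(f$version, "sap_sim")) {
      if (!is.na(f$fp_rate) && f$fp_rate > fp_cutoff) {
        return(sprintf("false positives > %d%%", round(100 * fp_cutoff)))
      }
    } else if (!f$complete) {
      return("incomplete")
    }
    NA_character_
  }, character(1))
  excluded <- which(!is.na(reasons))
  list(kept = setdiff(seq_along(results), excluded),
       excluded = excluded,
       reasons = reasons[excluded])
}

#' Mean sensitivity of a field
#'
#' @param field An `svop_field` (complete).
#' @param exclude_blind_spot Drop the two blind-spot locations (52-point
#'   summary) or keep all 54.
#' @return Mean threshold in dB.
#' @export
mean_sensitivity <- function(field, exclude_blind_spot = TRUE) {
  p <- field$points
  keep <- if (exclude_blind_spot) !p$is_blind_spot else rep(TRUE, nrow(p))
  mean(p$threshold_db[keep])
}

#' Pair two fields for comparison
#'
#' @param field_a,field_b `svop_field` objects on the same eye and
#'   pattern; `field_a` is the instrument under test, `field_b` the
#'   comparison (floor-truncated) device.
#' @param subject_id Identifier carried into reports.
#' @param pair_kind `"cross_device"` or `"repeat"`.
#' @return An `svop_pair` list.
#' @export
comparison_pair <- function(field_a, field_b, subject_id = NA,
                            pair_kind = c("cross_device", "repeat")) {
  pair_kind <- match.arg(pair_kind)
  if (!identical(field_a$eye, field_b$eye) ||
      !identical(field_a$pattern_name, field_b$pattern_name)) {
    stop("paired fields must share eye and pattern")
  }
  structure(list(field_a = field_a, field_b = field_b,
                 subject_id = subject_id, pair_kind = pair_kind),
            class = "svop_pair")
}

# matrix of thresholds (pairs x locations) for one side of a pair list
pair_matrix <- function(pairs, side) {
  do.call(rbind, lapply(pairs, function(p) p[[side]]$points$threshold_db))
}

pointwise_report <- function(r, pattern_pts, n_pairs, truncation_floor,
                             exclude_blind_spot) {
  keep <- if (exclude_blind_spot) !pattern_pts$is_blind_spot else TRUE
  rk <- r[keep]
  structure(list(
    per_location = data.frame(x_deg = pattern_pts$x_deg,
                              y_deg = pattern_pts$y_deg,
                              is_blind_spot = pattern_pts$is_blind_spot,
                              r = r, n = n_pairs),
    summary = list(mean_r = mean(rk, na.rm = TRUE),
                   min_r = if (all(is.na(rk))) NA_real_ else min(rk, na.rm = TRUE),
                   max_r = if (all(is.na(rk))) NA_real_ else max(rk, na.rm = TRUE),
                   n_locations = length(rk),
                   n_above_0.70 = sum(rk > 0.70, na.rm = TRUE),
                   n_above_0.80 = sum(rk > 0.80, na.rm = TRUE)),
    truncation_floor_db = truncation_floor,
    exclude_blind_spot = exclude_blind_spot,
    n_pairs = n_pairs
  ), class = "svop_pointwise")
}

#' @export
print.svop_pointwise <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<svop_pointwise> %d pairs, %d locations%s\n",
                     "  r: mean %.2f, range %.2f-%.2f; >0.70: %d, >0.80: %d\n"),
              x$n_pairs, s$n_locations,
              if (x$exclude_blind_spot) " (blind spot excluded)" else "",
              s$mean_r, s$min_r, s$max_r, s$n_above_0.70, s$n_above_0.80))
  invisible(x)
}

#' Per-location correlation between two devices
#'
#' For every test location, the Pearson correlation across subjects
#' between the two devices' thresholds.  The comparison device's values
#' (`field_b`) are truncated at the display floor BEFORE correlating,
#' because the instrument under test cannot display stimuli brighter than
#' that floor.
#'
#' @param pairs List of `svop_pair` objects (`cross_device`).
#' @param truncation_floor Floor in dB applied to `field_b`, default 14.
#' @param exclude_blind_spot Drop blind-spot locations from the summary.
#' @return An `svop_pointwise` report: per-location `r` plus summary
#'   (mean, range, counts above 0.70 and 0.80).
#' @export
pointwise_correlation <- function(pairs, truncation_floor = SVOP_LEVEL_RANGE_DB[1],
                                  exclude_blind_spot = TRUE) {
  if (length(pairs) < 3) stop("need at least 3 pairs to correlate")
  a <- pair_matrix(pairs, "field_a")
  b <- truncate_for_comparison(pair_matrix(pairs, "field_b"),
                               truncation_floor)
  r <- vapply(seq_len(ncol(a)),
              function(j) suppressWarnings(stats::cor(a[, j], b[, j])),
              numeric(1))
  pointwise_report(r, pairs[[1]]$field_a$points, length(pairs),
                   truncation_floor, exclude_blind_spot)
}

#' Test-retest repeatability
#'
#' Per-location Pearson correlation between first and repeat tests on the
#' same eye with the same device, over all test locations.  No floor
#' truncation is applied: both sides come from the same instrument.
#'
#' @param repeat_pairs List of `svop_pair` objects (`repeat`).
#' @param exclude_blind_spot Drop blind-spot locations from the summary.
#' @return An `svop_pointwise` report.
#' @export
repeatability <- function(repeat_pairs, exclude_blind_spot = TRUE) {
  if (length(repeat_pairs) < 3) stop("need at least 3 repeat pairs")
  a <- pair_matrix(repeat_pairs, "field_a")
  b <- pair_matrix(repeat_pairs, "field_b")
  r <- vapply(seq_len(ncol(a)),
              function(j) suppressWarnings(stats::cor(a[, j], b[, j])),
              numeric(1))
  pointwise_report(r, repeat_pairs[[1]]$field_a$points, length(repeat_pairs),
                   NA_real_, exclude_blind_spot)
}

#' Specify a simulated cohort
#'
#' @param n_healthy,n_glaucoma Observer counts.
#' @param archetype_mix Character vector of glaucoma archetypes sampled
#'   uniformly for the glaucoma group.
#' @param repeat_fraction Fraction of observers who also perform repeat
#'   tests, default 0.5.
#' @param observer_args Named list of overrides passed to
#'   [observer_model()] (noise parameters etc.).
#' @param master_seed Master RNG seed; per-observer seeds derive from it.
#' @return An `svop_cohort_spec` list.
#' @export
cohort_spec <- function(n_healthy = 10, n_glaucoma = 10,
                        archetype_mix = c("early_glaucoma", "arcuate",
                                          "advanced"),
                        repeat_fraction = 0.5,
                        observer_args = list(),
                        master_seed = 1L) {
  structure(list(n_healthy = n_healthy, n_glaucoma = n_glaucoma,
                 archetype_mix = archetype_mix,
                 repeat_fraction = repeat_fraction,
                 observer_args = observer_args,
                 master_seed = master_seed),
            class = "svop_cohort_spec")
}

#' Simulate a validation cohort end-to-end
#'
#' Generates healthy and glaucomatous observers, runs a gaze-driven test
#' and a button-response (SAP-like) test on each (twice for the repeat
#' subset), applies the exclusion rules, and computes the agreement and
#' repeatability reports.
#'
#' @param spec An `svop_cohort_spec`.
#' @param config An `svop_config` used for every session (per-session
#'   seeds are derived from the master seed).
#' @return An `svop_cohort` list: `mean_sensitivity` (per-subject data
#'   frame with device means and the truth), `agreement_r` (Pearson r of
#'   the device mean sensitivities), `pointwise` / `repeatability_svop` /
#'   `repeatability_sap` (`svop_pointwise` reports), `exclusions`, and
#'   `durations_s`.
#' @export
cohort_experiment <- function(spec, config = session_config()) {
  set.seed(spec$master_seed)
  n <- spec$n_healthy + spec$n_glaucoma
  obs_seeds <- sample.int(2^30, n)
  sess_seeds <- matrix(sample.int(2^30, 4 * n), nrow = n)
  kinds <- c(rep("normal", spec$n_healthy),
             sample(spec$archetype_mix, spec$n_glaucoma, replace = TRUE))
  # repeat testing spans both groups (stratified), as in a validation study
  is_repeat <- c(seq_len(spec$n_healthy) <=
                   ceiling(spec$n_healthy * spec$repeat_fraction),
                 seq_len(spec$n_glaucoma) <=
                   ceiling(spec$n_glaucoma * spec$repeat_fraction))

  pattern <- generate_pattern(config$pattern_name, config$eye)
  observers <- lapply(seq_len(n), function(i) {
    set.seed(obs_seeds[i])
    tf <- make_glaucoma_field(pattern, field_archetype(kinds[i]))
    do.call(observer_model,
            c(list(true_field = tf, pattern = pattern,
                   rng_seed = obs_seeds[i]),
              spec$observer_args))
  })

  run_one <- function(i, k, sap = FALSE) {
    cfg <- config
    cfg$rng_seed <- sess_seeds[i, k]
    if (sap) run_sap_like_session(cfg, observers[[i]])
    else run_session(cfg, observers[[i]])
  }
  svop1 <- lapply(seq_len(n), run_one, k = 1)
  sap1 <- lapply(seq_len(n), run_one, k = 2, sap = TRUE)
  svop2 <- lapply(which(is_repeat), function(i) run_one(i, 3))
  sap2 <- lapply(which(is_repeat), function(i) run_one(i, 4, sap = TRUE))

  fields <- c(lapply(svop1, `[[`, "field"), lapply(sap1, `[[`, "field"))
  excl <- apply_exclusions(fields)
  keep_cross <- vapply(seq_len(n), function(i) {
    (i %in% excl$kept) && ((i + n) %in% excl$kept)
  }, logical(1))

  cross <- lapply(which(keep_cross), function(i) {
    comparison_pair(svop1[[i]]$field, sap1[[i]]$field, subject_id = i)
  })
  ms <- data.frame(
    subject = which(keep_cross),
    group = ifelse(kinds[keep_cross] == "normal", "healthy", "glaucoma"),
    truth = vapply(which(keep_cross), function(i) {
      p <- !pattern$is_blind_spot
      mean(truncate_for_comparison(observers[[i]]$true_field[p]))
    }, numeric(1)),
    svop = vapply(cross, function(p) mean_sensitivity(p$field_a), numeric(1)),
    sap = vapply(cross, function(p) mean_sensitivity(p$field_b), numeric(1))
  )

  rep_ok <- function(s1, s2) s1$complete && s2$complete
  ri <- which(is_repeat)
  svop_rep <- Filter(Negate(is.null), lapply(seq_along(ri), function(k) {
    i <- ri[k]
    if (!rep_ok(svop1[[i]], svop2[[k]])) return(NULL)
    comparison_pair(svop1[[i]]$field, svop2[[k]]$field, subject_id = i,
                    pair_kind = "repeat")
  }))
  sap_rep <- lapply(seq_along(ri), function(k) {
    i <- ri[k]
    comparison_pair(sap1[[i]]$field, sap2[[k]]$field, subject_id = i,
                    pair_kind = "repeat")
  })

  structure(list(
    mean_sensitivity = ms,
    agreement_r = if (nrow(ms) >= 3) stats::cor(ms$svop, ms$sap) else NA_real_,
    truth_r = if (nrow(ms) >= 3) stats::cor(ms$svop, ms$truth) else NA_real_,
    pointwise = if (length(cross) >= 3) pointwise_correlation(cross) else NULL,
    repeatability_svop = if (length(svop_rep) >= 3) repeatability(svop_rep) else NULL,
    repeatability_sap = if (length(sap_rep) >= 3) repeatability(sap_rep) else NULL,
    exclusions = excl,
    durations_s = data.frame(
      svop = vapply(svop1, `[[`, numeric(1), "duration_s"),
      sap = vapply(sap1, `[[`, numeric(1), "duration_s")
    ),
    kinds = kinds
  ), class = "svop_cohort")
}

#' @export
print.svop_cohort <- function(x, ...) {
  cat(sprintf("<svop_cohort> %d comparison pairs, agreement r = %.3f\n",
              nrow(x$mean_sensitivity), x$agreement_r))
  if (!is.null(x$repeatability_svop)) {
    cat(sprintf("  repeatability: gaze test mean r = %.2f, button test mean r = %.2f\n",
                x$repeatability_svop$summary$mean_r,
                x$repeatability_sap$summary$mean_r))
  }
  invisible(x)
}

#' Write a per-location report as CSV
#'
#' @param report An `svop_pointwise`.
#' @param path Output CSV (columns `x_deg`, `y_deg`, `is_blind_spot`,
#'   `r`, `n`).
#' @export
write_pointwise <- function(report, path) {
  utils::write.csv(report$per_location, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
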