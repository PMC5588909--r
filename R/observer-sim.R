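# Synthetic patient + eye tracker: ground-truth sensitivity fields,
# frequency-of-seeing responses, and gaze-stream synthesis with oculomotor
# and tracking noise.  The simulator is the closed-loop counterpart of the
# gaze classifier: with all noise at zero the classifier recovers the
# observer's intended decision for every presentation.

#' Construct a synthetic observer
#'
#' Bundles the ground-truth sensitivity field with the psychometric and
#' oculomotor noise parameters of the simulated patient and tracker.
#'
#' @param true_field Per-location true sensitivity (dB), aligned with
#'   `pattern`; values outside the displayable range are allowed (the
#'   display floor applies only at measurement time).
#' @param pattern The `svop_pattern` the field is defined on.
#' @param psychometric_slope_db Spread of the frequency-of-seeing curve
#'   (dB); 0 gives a deterministic step observer.
#' @param fp_rate,fn_rate False-positive / false-negative response rates.
#' @param saccade_latency_mean_ms,saccade_latency_sd_ms Latency of the
#'   refixation saccade (ms).
#' @param landing_noise_deg SD of the saccade endpoint error (degrees).
#' @param gaze_noise_deg SD of per-sample fixation jitter as reported by
#'   the tracker (degrees); the manufacturer figure for controlled
#'   conditions is below 0.5.
#' @param dropout_prob Probability a gaze sample is reported invalid.
#' @param head_drift_mm_per_s Slow head translation speed (mm/s).
#' @param rng_seed Seed attached to the observer for reproducible cohorts.
#' @return An `svop_observer` list.
#' @export
observer_model <- function(true_field, pattern,
                           psychometric_slope_db = 2,
                           fp_rate = 0.03, fn_rate = 0.03,
                           saccade_latency_mean_ms = 250,
                           saccade_latency_sd_ms = 50,
                           landing_noise_deg = 0.5,
                           gaze_noise_deg = 0.3,
                           dropout_prob = 0.02,
                           head_drift_mm_per_s = 0.5,
                           rng_seed = NULL) {
  stopifnot(length(true_field) == nrow(pattern),
            fp_rate >= 0, fp_rate <= 1, fn_rate >= 0, fn_rate <= 1,
            psychometric_slope_db >= 0)
  structure(list(true_field = true_field, pattern = pattern,
                 psychometric_slope_db = psychometric_slope_db,
                 fp_rate = fp_rate, fn_rate = fn_rate,
                 saccade_latency_mean_ms = saccade_latency_mean_ms,
                 saccade_latency_sd_ms = saccade_latency_sd_ms,
                 landing_noise_deg = landing_noise_deg,
                 gaze_noise_deg = gaze_noise_deg,
                 dropout_prob = dropout_prob,
                 head_drift_mm_per_s = head_drift_mm_per_s,
                 rng_seed = rng_seed),
            class = "svop_observer")
}

#' A noise-free deterministic observer
#'
#' Step psychometric (seen iff the stimulus is at least as bright as the
#' true sensitivity), no response errors, no oculomotor or tracking noise.
#' Useful as the ideal-subject reference in closed-loop checks.
#'
#' @inheritParams observer_model
#' @return An `svop_observer`.
#' @export
ideal_observer <- function(true_field, pattern, rng_seed = NULL) {
  observer_model(true_field, pattern,
                 psychometric_slope_db = 0, fp_rate = 0, fn_rate = 0,
                 saccade_latency_sd_ms = 0, landing_noise_deg = 0,
                 gaze_noise_deg = 0, dropout_prob = 0,
                 head_drift_mm_per_s = 0, rng_seed = rng_seed)
}

#' Generate a normal ("hill of vision") sensitivity field
#'
#' Sensitivity falls off linearly with eccentricity from a foveal peak,
#' with additive Gaussian between-location noise; the blind-spot pair is
#' set to 0 dB (no photoreceptors).
#'
#' @param pattern An `svop_pattern`.
#' @param peak_db Foveal peak sensitivity, default 31.5 dB.
#' @param slope_db_per_deg Eccentricity fall-off, default 0.08 dB/deg.
#' @param noise_sd_db Between-location noise SD, default 1 dB.
#' @return Numeric vector of true sensitivities aligned with `pattern`.
#' @export
make_normal_field <- function(pattern, peak_db = 31.5,
                              slope_db_per_deg = 0.08, noise_sd_db = 1) {
  ecc <- sqrt(pattern$x_deg^2 + pattern$y_deg^2)
  sens <- peak_db - slope_db_per_deg * ecc +
    stats::rnorm(nrow(pattern), 0, noise_sd_db)
  sens <- pmin(pmax(sens, 0), 40)
  sens[pattern$is_blind_spot] <- 0
  sens
}

#' Field archetype for glaucomatous damage
#'
#' @param kind One of `"normal"`, `"early_glaucoma"` (superior nasal-step
#'   defect), `"arcuate"` (superior Bjerrum-arc defect), `"advanced"`
#'   (widespread loss sparing a central island).
#' @param peak_db,slope_db_per_deg,noise_sd_db Normal-field parameters.
#' @param defect_depth_db Depression of the affected locations in dB
#'   (defaults per kind: 0, 10, 15, 25).
#' @return An `svop_archetype` list.
#' @export
field_archetype <- function(kind = c("normal", "early_glaucoma", "arcuate",
                                     "advanced"),
                            peak_db = 31.5, slope_db_per_deg = 0.08,
                            noise_sd_db = 1, defect_depth_db = NULL) {
  kind <- match.arg(kind)
  if (is.null(defect_depth_db)) {
    defect_depth_db <- switch(kind, normal = 0, early_glaucoma = 10,
                              arcuate = 15, advanced = 25)
  }
  structure(list(kind = kind, peak_db = peak_db,
                 slope_db_per_deg = slope_db_per_deg,
                 noise_sd_db = noise_sd_db,
                 defect_depth_db = defect_depth_db),
            class = "svop_archetype")
}

# location masks of the classic defect shapes (per-eye frame,
# temporal = +x, so nasal is -x for the right-eye frame and the stored
# left-eye frame alike after mirroring)
defect_mask <- function(pattern, kind) {
  ecc <- sqrt(pattern$x_deg^2 + pattern$y_deg^2)
  nasal <- if (identical(attr(pattern, "eye"), "left")) {
    pattern$x_deg > 0
  } else {
    pattern$x_deg < 0
  }
  switch(kind,
    normal = rep(FALSE, nrow(pattern)),
    # superior nasal step: the peripheral superior-nasal quadrant
    early_glaucoma = pattern$y_deg > 0 & nasal & ecc >= 15,
    # superior Bjerrum arc arching over fixation at mid eccentricity
    arcuate = pattern$y_deg > 0 & ecc >= 9 & ecc <= 21,
    # everything outside the central island
    advanced = ecc > 6
  )
}

#' Generate a glaucomatous sensitivity field
#'
#' A normal hill-of-vision field with a localized depression superimposed
#' according to the archetype.  Depressed sensitivities may fall below the
#' 14 dB display floor; truncation happens only at measurement time.
#'
#' @param pattern An `svop_pattern`.
#' @param archetype An `svop_archetype`.
#' @return Numeric vector of true sensitivities aligned with `pattern`.
#' @export
make_glaucoma_field <- function(pattern, archetype = field_archetype("arcuate")) {
  sens <- make_normal_field(pattern, archetype$peak_db,
                            archetype$slope_db_per_deg, archetype$noise_sd_db)
  mask <- defect_mask(pattern, archetype$kind) & !pattern$is_blind_spot
  sens[mask] <- sens[mask] - archetype$defect_depth_db
  sens <- pmax(sens, 0)
  sens[pattern$is_blind_spot] <- 0
  sens
}

#' Frequency-of-seeing response
#'
#' Draws a seen/unseen response from the observer's psychometric function:
#' `p(seen) = fp + (1 - fp - fn) * Phi((t - level) / slope)` with `t` the
#' true sensitivity at the location.  Since higher dB means a dimmer
#' stimulus, levels above threshold are unlikely to be seen.  With slope 0
#' the observer is a deterministic step (seen iff `level <= t`, subject to
#' the fp/fn lapses).
#'
#' @param observer An `svop_observer`.
#' @param location_index Row index into the observer's pattern.
#' @param level_db Presented level in dB.
#' @return `"seen"` or `"unseen"` (draws from the current RNG stream).
#' @export
respond <- function(observer, location_index, level_db) {
  t <- observer$true_field[location_index]
  s <- observer$psychometric_slope_db
  core <- if (s <= 0) as.numeric(level_db <= t) else stats::pnorm((t - level_db) / s)
  p <- observer$fp_rate + (1 - observer$fp_rate - observer$fn_rate) * core
  if (p >= 1 || (p > 0 && stats::runif(1) < p)) "seen" else "unseen"
}

#' Closed-form probability of seeing
#'
#' The analytic counterpart of [respond()], used to calibrate the
#' simulated frequency-of-seeing curve.
#'
#' @inheritParams respond
#' @return Probability in `[0, 1]`.
#' @export
p_seen <- function(observer, location_index, level_db) {
  t <- observer$true_field[location_index]
  s <- observer$psychometric_slope_db
  core <- if (s <= 0) as.numeric(level_db <= t) else stats::pnorm((t - level_db) / s)
  observer$fp_rate + (1 - observer$fp_rate - observer$fn_rate) * core
}

# place a point at given component angles on the screen for a pose
angles_to_screen <- function(angles_deg, pose) {
  a <- angles_deg * pi / 180
  c(pose$x_mm + pose$z_mm * tan(a[1]),
    pose$y_mm + pose$z_mm * tan(a[2]))
}

#' Synthesize the gaze stream for one presentation
#'
#' Produces a 60 Hz stream spanning the response window: fixation-holding
#' samples with angular jitter and slow head drift; if the intended
#' decision is "seen", a saccade at a sampled latency landing on the
#' stimulus plus endpoint noise.  Samples are flagged invalid with the
#' observer's dropout probability.
#'
#' @param observer An `svop_observer`.
#' @param decision Intended decision, `"seen"` or `"unseen"` (from
#'   [respond()]).
#' @param fixation_xy_mm,stimulus_xy_mm Screen points, mm.
#' @param onset_ms Stimulus onset time; samples cover
#'   `[onset_ms - lead_ms, onset_ms + window_ms]`.
#' @param window_ms Response window, default 1000 ms.
#' @param pose Starting `svop_eye_pose`.
#' @param lead_ms Pre-onset fixation segment, default 600 ms (covers a
#'   fixation-dwell check).
#' @param rate_hz Sampling rate, default 60 Hz.
#' @return An `svop_gaze` stream (draws from the current RNG stream).
#' @export
synthesize_gaze <- function(observer, decision, fixation_xy_mm,
                            stimulus_xy_mm, onset_ms = 0, window_ms = 1000,
                            pose = eye_pose(), lead_ms = 600, rate_hz = 60) {
  dt <- 1000 / rate_hz
  t <- seq(onset_ms - lead_ms, onset_ms + window_ms, by = dt)
  n <- length(t)

  # slow head translation in a random direction, continuous over the stream
  drift_dir <- if (observer$head_drift_mm_per_s > 0) {
    a <- stats::runif(1, 0, 2 * pi); c(cos(a), sin(a))
  } else c(0, 0)
  drift <- observer$head_drift_mm_per_s * (t - t[1]) / 1000
  px <- pose$x_mm + drift_dir[1] * drift
  py <- pose$y_mm + drift_dir[2] * drift
  pz <- rep(pose$z_mm, n)

  # intended gaze target per sample (fixation, then stimulus after latency)
  latency <- NA_real_
  on_stim <- rep(FALSE, n)
  if (identical(decision, "seen")) {
    latency <- stats::rnorm(1, observer$saccade_latency_mean_ms,
                            observer$saccade_latency_sd_ms)
    latency <- min(max(latency, 100), window_ms - 200)
    on_stim <- t >= onset_ms + latency
  }
  land <- stimulus_xy_mm
  if (observer$landing_noise_deg > 0) {
    err <- stats::rnorm(2, 0, observer$landing_noise_deg)
    # endpoint error applied in visual angle at the landing position
    ang <- c(atan((stimulus_xy_mm[1] - pose$x_mm) / pose$z_mm),
             atan((stimulus_xy_mm[2] - pose$y_mm) / pose$z_mm)) * 180 / pi
    land <- angles_to_screen(ang + err, pose)
  }

  gx <- ifelse(on_stim, land[1], fixation_xy_mm[1])
  gy <- ifelse(on_stim, land[2], fixation_xy_mm[2])
  if (observer$gaze_noise_deg > 0) {
    # per-sample angular jitter around the intended gaze point
    jx <- stats::rnorm(n, 0, observer$gaze_noise_deg) * pi / 180
    jy <- stats::rnorm(n, 0, observer$gaze_noise_deg) * pi / 180
    gx <- px + pz * tan(atan((gx - px) / pz) + jx)
    gy <- py + pz * tan(atan((gy - py) / pz) + jy)
  }
  valid <- if (observer$dropout_prob > 0) {
    stats::runif(n) >= observer$dropout_prob
  } else rep(TRUE, n)

  gaze_stream(t_ms = t, x_mm = gx, y_mm = gy, valid = valid,
              pose_x_mm = px, pose_y_mm = py, pose_z_mm = pz)
}

#' Read / write an observer parameter set as YAML
#'
#' All scalar observer parameters plus the true field and the pattern
#' identity round-trip losslessly.
#'
#' @param observer An `svop_observer`.
#' @param path File path.
#' @return `read_observer` returns an `svop_observer`.
#' @export
write_observer <- function(observer, path) {
  rec <- observer[setdiff(names(observer), c("pattern", "true_field"))]
  rec$pattern_name <- attr(observer$pattern, "pattern_name")
  rec$eye <- attr(observer$pattern, "eye")
  rec$true_field <- as.numeric(observer$true_field)
  yaml::write_yaml(rec, path)
  invisible(path)
}

#' @rdname write_observer
#' @export
read_observer <- function(path) {
  rec <- yaml::read_yaml(path)
  pattern <- generate_pattern(rec$pattern_name, rec$eye)
  observer_model(
    true_field = as.numeric(rec$true_field), pattern = pattern,
    psychometric_slope_db = rec$psychometric_slope_db,
    fp_rate = rec$fp_rate, fn_rate = rec$fn_rate,
    saccade_latency_mean_ms = rec$saccade_latency_mean_ms,
    saccade_latency_sd_ms = rec$saccade_latency_sd_ms,
    landing_noise_deg = rec$landing_noise_deg,
    gaze_noise_deg = rec$gaze_noise_deg,
    dropout_prob = rec$dropout_prob,
    head_drift_mm_per_s = rec$head_drift_mm_per_s,
    rng_seed = rec$rng_seed
  )
}
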