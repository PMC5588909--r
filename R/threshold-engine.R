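# The threshold test proper: 4-2 bracketing per location, four quadrant
# seed points whose results propagate starting levels to their neighbours,
# fixation-gated gaze-contingent scheduling, and the v1/v2 behavioural
# variants (v2 clamps propagated starting levels at 18 dB, uses a longer
# fixation dwell, and adds a waiting-time priority weight to scheduling).

#' Session configuration
#'
#' @param version `"v1"` or `"v2"`.  The version fixes the starting-level
#'   clamp (v2: never below 18 dB), the fixation dwell (v1 200 ms, v2
#'   500 ms) and the scheduling priority weight (v1 0, v2 0.05) unless
#'   these are overridden explicitly.
#' @param eye `"right"` or `"left"`.
#' @param pattern_name Test pattern, default `"24-2"`.
#' @param seed_start_db Starting level at the four seed locations,
#'   default 25 dB.
#' @param stimulus An `svop_stimulus` (level is set per presentation).
#' @param screen An `svop_screen`.
#' @param fixation_tol_deg Fixation tolerance (degrees), default 2.
#' @param dwell_ms Fixation dwell; `NULL` takes the version default.
#' @param direction_tol_deg,amplitude_tol_frac Gaze-vector tolerances.
#' @param window_ms Unseen-decision window, default 1000 ms.
#' @param priority_weight Scheduling weight per presentation waited;
#'   `NULL` takes the version default (0 reproduces v1 behaviour).
#' @param retry_budget Consecutive failed fixation checks or invalid
#'   presentations tolerated before the test is abandoned as incomplete.
#' @param rng_seed Seed for the session's scheduling and observer draws.
#' @return An `svop_config` list.
#' @export
session_config <- function(version = c("v2", "v1"),
                           eye = c("right", "left"),
                           pattern_name = "24-2",
                           seed_start_db = 25,
                           stimulus = stimulus_spec(),
                           screen = screen_model(),
                           fixation_tol_deg = 2,
                           dwell_ms = NULL,
                           direction_tol_deg = 20,
                           amplitude_tol_frac = 0.30,
                           window_ms = 1000,
                           priority_weight = NULL,
                           retry_budget = 40,
                           rng_seed = 1L) {
  version <- match.arg(version)
  eye <- match.arg(eye)
  if (is.null(dwell_ms)) dwell_ms <- if (version == "v1") 200 else 500
  if (is.null(priority_weight)) priority_weight <- if (version == "v1") 0 else 0.05
  structure(list(version = version, eye = eye, pattern_name = pattern_name,
                 seed_start_db = seed_start_db, stimulus = stimulus,
                 screen = screen, fixation_tol_deg = fixation_tol_deg,
                 dwell_ms = dwell_ms, direction_tol_deg = direction_tol_deg,
                 amplitude_tol_frac = amplitude_tol_frac,
                 window_ms = window_ms, priority_weight = priority_weight,
                 retry_budget = retry_budget, rng_seed = rng_seed),
            class = "svop_config")
}

#' Seed locations of the growth pattern
#'
#' The test starts by thresholding four "seed" locations, one per
#' quadrant, whose results set the starting levels of their neighbours.
#' The mid-eccentricity points at (+/-9, +/-9) are used; they are never
#' blind-spot points.
#'
#' @param pattern An `svop_pattern` (24-2).
#' @return Integer row indices of the four seed locations.
#' @export
seed_locations <- function(pattern) {
  idx <- which(abs(pattern$x_deg) == 9 & abs(pattern$y_deg) == 9)
  stopifnot(length(idx) == 4)
  idx
}

# indices of 4-neighbours (6 degrees along one axis) of location i
four_neighbours <- function(pattern, i) {
  dx <- pattern$x_deg - pattern$x_deg[i]
  dy <- pattern$y_deg - pattern$y_deg[i]
  which((abs(dx) == 6 & dy == 0) | (dx == 0 & abs(dy) == 6))
}

#' Starting level propagated from neighbouring thresholds
#'
#' Non-seed locations start at the rounded mean (half up) of their
#' completed neighbours' thresholds, clamped to the displayable range;
#' under v2 the starting level is additionally clamped to at least 18 dB
#' so that no threshold can ever be decided by a single stimulus
#' decision.  Seed locations use a fixed start.
#'
#' @param neighbor_thresholds Thresholds (dB) of completed neighbours;
#'   must be non-empty for non-seed locations.
#' @param version `"v1"` or `"v2"`.
#' @param is_seed If `TRUE`, returns `seed_start_db`.
#' @param seed_start_db Fixed seed starting level, default 25 dB.
#' @return Starting level in dB.
#' @export
starting_level <- function(neighbor_thresholds, version = c("v2", "v1"),
                           is_seed = FALSE, seed_start_db = 25) {
  version <- match.arg(version)
  if (is_seed) return(seed_start_db)
  if (length(neighbor_thresholds) == 0) {
    stop("no completed neighbour thresholds to propagate a starting level from")
  }
  lv <- floor(mean(neighbor_thresholds) + 0.5)    # round half up
  lv <- min(max(lv, SVOP_LEVEL_RANGE_DB[1]), SVOP_LEVEL_RANGE_DB[2])
  if (version == "v2") lv <- max(lv, 18)
  lv
}

#' Initialise a 4-2 staircase
#'
#' @param start_level_db Starting level (dB), clamped to the displayable
#'   range.
#' @return An `svop_staircase` state.
#' @export
staircase_new <- function(start_level_db) {
  lv <- min(max(start_level_db, SVOP_LEVEL_RANGE_DB[1]), SVOP_LEVEL_RANGE_DB[2])
  structure(list(current_level_db = lv, last_response = "none",
                 n_reversals = 0L, n_presentations = 0L,
                 last_seen_level = NA_real_, threshold_db = NA_real_,
                 floor_hits = 0L, ceiling_hits = 0L,
                 started = FALSE, finished = FALSE, unmeasurable = FALSE),
            class = "svop_staircase")
}

#' Advance a 4-2 staircase by one response
#'
#' The 4-2 bracketing rules: the level steps by 4 dB until the first
#' response reversal, then by 2 dB; a seen response makes the next
#' stimulus dimmer (+dB), an unseen response brighter (-dB).  The
#' staircase finishes at the second reversal with the threshold set to
#' the last level that was seen.  Levels clamp to the displayable
#' [14, 40] dB; two consecutive unseen responses at the 14 dB floor
#' finish the staircase at 14 dB (flagged unmeasurable if nothing was
#' ever seen), and two consecutive seen responses at the 40 dB ceiling
#' finish it at 40 dB.
#'
#' @param state An unfinished `svop_staircase`.
#' @param response `"seen"` or `"unseen"`.
#' @return The updated `svop_staircase`.
#' @export
staircase_update <- function(state, response) {
  if (state$finished) stop("staircase already finished")
  if (!response %in% c("seen", "unseen")) stop("response must be seen or unseen")
  lv <- state$current_level_db
  state$n_presentations <- state$n_presentations + 1L
  state$started <- TRUE
  if (response == "seen") state$last_seen_level <- lv
  if (state$last_response != "none" && response != state$last_response) {
    state$n_reversals <- state$n_reversals + 1L
  }
  if (state$n_reversals >= 2L) {
    state$finished <- TRUE
    state$threshold_db <- state$last_seen_level
    if (is.na(state$threshold_db)) {     # defensive; cannot occur with 2 reversals
      state$threshold_db <- SVOP_LEVEL_RANGE_DB[1]
      state$unmeasurable <- TRUE
    }
    state$last_response <- response
    return(state)
  }
  # saturation at the displayable bounds
  if (response == "unseen" && lv <= SVOP_LEVEL_RANGE_DB[1]) {
    state$floor_hits <- state$floor_hits + 1L
    if (state$floor_hits >= 2L) {
      state$finished <- TRUE
      state$threshold_db <- SVOP_LEVEL_RANGE_DB[1]
      state$unmeasurable <- is.na(state$last_seen_level)
      state$last_response <- response
      return(state)
    }
  } else state$floor_hits <- 0L
  if (response == "seen" && lv >= SVOP_LEVEL_RANGE_DB[2]) {
    state$ceiling_hits <- state$ceiling_hits + 1L
    if (state$ceiling_hits >= 2L) {
      state$finished <- TRUE
      state$threshold_db <- SVOP_LEVEL_RANGE_DB[2]
      state$last_response <- response
      return(state)
    }
  } else state$ceiling_hits <- 0L

  step <- if (state$n_reversals == 0L) 4 else 2
  dirn <- if (response == "seen") +1 else -1
  state$current_level_db <- min(max(lv + dirn * step, SVOP_LEVEL_RANGE_DB[1]),
                                SVOP_LEVEL_RANGE_DB[2])
  state$last_response <- response
  state
}

#' Locations currently eligible for presentation
#'
#' A location can be tested only if its stimulus, projected for the
#' current fixation point and eye pose, falls fully on the panel; this is
#' why, with fixation near the top of the screen, superior-field points
#' (drawn above fixation) become ineligible.  Non-seed locations
#' additionally require at least one completed 4-neighbour so a starting
#' level can be propagated; while any seed is unfinished only seeds are
#' offered.
#'
#' @param states List of `svop_staircase` states (one per location).
#' @param pattern The `svop_pattern`.
#' @param fixation_xy_mm Current fixation point on screen, mm.
#' @param pose Current `svop_eye_pose`.
#' @param screen An `svop_screen`.
#' @param radius_mm Stimulus radius for the on-screen check.
#' @param seeds Seed indices (from [seed_locations()]).
#' @return Integer indices of eligible locations (possibly empty).
#' @export
eligible_locations <- function(states, pattern, fixation_xy_mm, pose, screen,
                               radius_mm = 2.1, seeds = seed_locations(pattern)) {
  unfinished <- which(!vapply(states, `[[`, logical(1), "finished"))
  if (length(unfinished) == 0) return(integer(0))
  if (any(seeds %in% unfinished)) unfinished <- intersect(seeds, unfinished)
  ok <- vapply(unfinished, function(i) {
    if (!(i %in% seeds)) {
      nb <- four_neighbours(pattern, i)
      if (!any(vapply(states[nb], `[[`, logical(1), "finished"))) return(FALSE)
    }
    xy <- project_stimulus(c(pattern$x_deg[i], pattern$y_deg[i]), pose,
                           fixation_xy_mm, screen = screen,
                           radius_mm = radius_mm)
    !anyNA(xy)
  }, logical(1))
  unfinished[ok]
}

# fixation point (on a coarse grid) that maximises the number of eligible
# locations; used to recover from an empty eligible set
recenter_fixation <- function(states, pattern, pose, screen, radius_mm,
                              seeds) {
  gx <- seq(-0.35, 0.35, length.out = 5) * screen$width_mm
  gy <- seq(-0.35, 0.35, length.out = 5) * screen$height_mm
  best <- c(0, 0); best_n <- -1L
  for (x in gx) for (y in gy) {
    n <- length(eligible_locations(states, pattern, c(x, y), pose, screen,
                                   radius_mm, seeds))
    if (n > best_n) { best_n <- n; best <- c(x, y) }
  }
  best
}

# propagate a starting level to location i from finished neighbours,
# falling back to the nearest finished location if no 4-neighbour is
# done.  Locations whose staircase bottomed out without a seen response
# are censored at the display floor, not estimates, so they are used
# only when nothing measurable has finished.
propagated_start <- function(states, pattern, i, version, seed_start_db,
                             seeds) {
  if (i %in% seeds) {
    return(starting_level(numeric(0), version, is_seed = TRUE,
                          seed_start_db = seed_start_db))
  }
  fin <- which(vapply(states, `[[`, logical(1), "finished"))
  meas <- fin[!vapply(states[fin], `[[`, logical(1), "unmeasurable")]
  pool <- if (length(meas) > 0) meas else fin
  if (length(pool) == 0) stop("no completed location to propagate from")
  nb <- intersect(four_neighbours(pattern, i), pool)
  if (length(nb) == 0) {
    d <- (pattern$x_deg[pool] - pattern$x_deg[i])^2 +
         (pattern$y_deg[pool] - pattern$y_deg[i])^2
    nb <- pool[which.min(d)]
  }
  th <- vapply(states[nb], `[[`, numeric(1), "threshold_db")
  starting_level(th, version, seed_start_db = seed_start_db)
}

# shared bookkeeping for building the field result out of staircase states
states_to_field <- function(states, pattern, version, duration_s,
                            fp_rate = NA_real_) {
  th <- vapply(states, `[[`, numeric(1), "threshold_db")
  np <- vapply(states, `[[`, integer(1), "n_presentations")
  un <- vapply(states, `[[`, logical(1), "unmeasurable")
  visual_field(pattern, threshold_db = th, n_presentations = np,
               version = version, complete = !anyNA(th),
               duration_s = duration_s, fp_rate = fp_rate,
               unmeasurable = un)
}

#' Run a full simulated gaze-driven threshold test
#'
#' The closed test loop: verify fixation on the current target; pick an
#' eligible location (seeded RNG, waiting-time priority under v2);
#' project the stimulus for the current eye pose (gaze-contingent
#' compensation); synthesize the observer's gaze response; classify it
#' from the gaze vector; update that location's 4-2 staircase.  A seen
#' stimulus becomes the next fixation target; unseen stimuli leave the
#' target in place.  If no location is eligible from the current fixation
#' point, a re-centering fixation target is shown at the screen position
#' that maximises eligibility.  The session ends complete when every
#' staircase has finished, or incomplete when fixation checks or
#' presentations fail more than `retry_budget` times in a row (tracking
#' loss).
#'
#' @param config An `svop_config`.
#' @param observer An `svop_observer` on the same pattern.
#' @return An `svop_session`: `list(field, log, complete, duration_s)`
#'   where `log` is a data frame of timestamped events (fixation checks,
#'   presentations with level, screen position, eye pose and decision).
#' @export
run_session <- function(config, observer) {
  set.seed(config$rng_seed)
  pattern <- generate_pattern(config$pattern_name, config$eye)
  stopifnot(nrow(pattern) == nrow(observer$pattern))
  seeds <- seed_locations(pattern)
  states <- lapply(seq_len(nrow(pattern)), function(i) staircase_new(25))
  started <- rep(FALSE, nrow(pattern))
  waits <- rep(0, nrow(pattern))
  radius_mm <- project_size(config$stimulus$diameter_deg,
                            eye_pose(), c(0, 0)) / 2

  pose <- eye_pose()
  fixation <- c(0, 0)
  t_ms <- 0
  fail_streak <- 0L
  log <- list()
  ev <- function(type, ...) {
    log[[length(log) + 1L]] <<- data.frame(t_ms = t_ms, type = type, ...,
                                           stringsAsFactors = FALSE)
  }

  repeat {
    if (all(vapply(states, `[[`, logical(1), "finished"))) break
    if (fail_streak > config$retry_budget) break

    # head drift between events
    if (observer$head_drift_mm_per_s > 0) {
      a <- stats::runif(1, 0, 2 * pi)
      step_mm <- observer$head_drift_mm_per_s * 0.5
      pose <- eye_pose(min(max(pose$x_mm + cos(a) * step_mm, -60), 60),
                       min(max(pose$y_mm + sin(a) * step_mm, -40), 40),
                       pose$z_mm)
    }

    # fixation check over a dwell window
    hold <- synthesize_gaze(observer, "unseen", fixation, fixation,
                            onset_ms = t_ms, window_ms = 0, pose = pose,
                            lead_ms = config$dwell_ms + 100)
    fix_ok <- verify_fixation(hold, fixation, config$fixation_tol_deg,
                              config$dwell_ms)
    ev("fixation_check",
       outcome = if (is.na(fix_ok)) "tracking_failure"
                 else if (fix_ok) "pass" else "fail")
    t_ms <- t_ms + config$dwell_ms + 100
    if (!isTRUE(fix_ok)) { fail_streak <- fail_streak + 1L; next }

    elig <- eligible_locations(states, pattern, fixation, pose,
                               config$screen, radius_mm, seeds)
    if (length(elig) == 0) {
      fixation <- recenter_fixation(states, pattern, pose, config$screen,
                                    radius_mm, seeds)
      ev("recenter", x_mm = fixation[1], y_mm = fixation[2])
      t_ms <- t_ms + 500
      next
    }
    waits[elig] <- waits[elig] + 1
    w <- 1 + config$priority_weight * waits[elig]
    i <- if (length(elig) == 1) elig else sample(elig, 1, prob = w)
    waits[i] <- 0

    if (!started[i]) {
      states[[i]]$current_level_db <-
        propagated_start(states, pattern, i, config$version,
                         config$seed_start_db, seeds)
      started[i] <- TRUE
    }
    level <- states[[i]]$current_level_db
    xy <- project_stimulus(c(pattern$x_deg[i], pattern$y_deg[i]), pose,
                           fixation, screen = config$screen,
                           radius_mm = radius_mm)
    if (anyNA(xy)) { next }    # pose moved since eligibility; reschedule

    intended <- respond(observer, i, level)
    stream <- synthesize_gaze(observer, intended, fixation, xy,
                              onset_ms = t_ms, window_ms = config$window_ms,
                              pose = pose, lead_ms = 0)
    dec <- classify_response(stream, fixation, xy, onset_ms = t_ms,
                             window_ms = config$window_ms,
                             direction_tol_deg = config$direction_tol_deg,
                             amplitude_tol_frac = config$amplitude_tol_frac,
                             fixation_tol_deg = config$fixation_tol_deg)
    ev("presentation", location = i, level_db = level,
       x_mm = xy[1], y_mm = xy[2],
       pose_x_mm = pose$x_mm, pose_y_mm = pose$y_mm, pose_z_mm = pose$z_mm,
       fix_x_mm = fixation[1], fix_y_mm = fixation[2],
       outcome = dec$outcome)
    if (identical(dec$outcome, "seen")) {
      t_ms <- t_ms + dec$saccade_latency_ms + 200
    } else {
      t_ms <- t_ms + config$window_ms + 100
    }

    if (identical(dec$outcome, "invalid")) {
      fail_streak <- fail_streak + 1L
      next
    }
    fail_streak <- 0L
    states[[i]] <- staircase_update(states[[i]], dec$outcome)
    if (identical(dec$outcome, "seen")) fixation <- xy
  }

  complete <- all(vapply(states, `[[`, logical(1), "finished"))
  field <- states_to_field(states, pattern, config$version, t_ms / 1000)
  structure(list(field = field,
                 log = do.call(rbind_fill, log),
                 complete = complete, duration_s = t_ms / 1000),
            class = "svop_session")
}

#' Run a button-response (SAP-like) threshold test
#'
#' The same 4-2 bracketing engine, seed points and starting-level
#' propagation, but with the gaze layer removed: the observer's
#' frequency-of-seeing draw (including button false-positive and
#' false-negative lapses) is taken directly as the response.  Serves as
#' the comparison device in agreement analyses; the observer's
#' false-positive rate is recorded on the result for the exclusion rules.
#'
#' @param config An `svop_config` (gaze tolerances are ignored).
#' @param observer An `svop_observer`.
#' @return An `svop_session`.
#' @export
run_sap_like_session <- function(config, observer) {
  set.seed(config$rng_seed)
  pattern <- generate_pattern(config$pattern_name, config$eye)
  seeds <- seed_locations(pattern)
  states <- lapply(seq_len(nrow(pattern)), function(i) staircase_new(25))
  started <- rep(FALSE, nrow(pattern))
  t_ms <- 0
  log <- list()
  repeat {
    unfinished <- which(!vapply(states, `[[`, logical(1), "finished"))
    if (length(unfinished) == 0) break
    if (any(seeds %in% unfinished)) {
      cand <- intersect(seeds, unfinished)
    } else {
      has_nb <- vapply(unfinished, function(i) {
        nb <- four_neighbours(pattern, i)
        any(vapply(states[nb], `[[`, logical(1), "finished"))
      }, logical(1))
      cand <- unfinished[has_nb]
      if (length(cand) == 0) cand <- unfinished
    }
    i <- if (length(cand) == 1) cand else sample(cand, 1)
    if (!started[i]) {
      states[[i]]$current_level_db <-
        propagated_start(states, pattern, i, config$version,
                         config$seed_start_db, seeds)
      started[i] <- TRUE
    }
    level <- states[[i]]$current_level_db
    outcome <- respond(observer, i, level)
    log[[length(log) + 1L]] <- data.frame(
      t_ms = t_ms, type = "presentation", location = i, level_db = level,
      outcome = outcome, stringsAsFactors = FALSE)
    t_ms <- t_ms + 1500            # nominal presentation + response cycle
    states[[i]] <- staircase_update(states[[i]], outcome)
  }
  field <- states_to_field(states, pattern, "sap_sim", t_ms / 1000,
                           fp_rate = observer$fp_rate)
  structure(list(field = field, log = do.call(rbind_fill, log),
                 complete = TRUE, duration_s = t_ms / 1000),
            class = "svop_session")
}

#' @export
print.svop_session <- function(x, ...) {
  cat(sprintf("<svop_session> %s, %s, %d presentations, %.0f s\n",
              x$field$version,
              if (x$complete) "complete" else "incomplete",
              sum(x$log$type == "presentation", na.rm = TRUE),
              x$duration_s))
  invisible(x)
}

# rbind data frames that may differ in columns (log events carry
# event-specific fields)
rbind_fill <- function(...) {
  dfs <- list(...)
  dfs <- dfs[!vapply(dfs, is.null, logical(1))]
  if (length(dfs) == 0) return(NULL)
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (cl in setdiff(cols, names(d))) d[[cl]] <- NA
    d[cols]
  })
  do.call(rbind, dfs)
}
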