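# Independent brute-force replay of the 4-2 bracketing rules, written as
# a plain imperative transcription so it can serve as an oracle for the
# engine's staircase implementation.
#
# Given a starting level and a response sequence it returns the presented
# levels, where (if anywhere) the staircase finished, and the decided
# threshold.

oracle_42_replay <- function(start, responses, lo = 14, hi = 40) {
  level <- min(hi, max(lo, start))
  prev <- NULL
  reversals <- 0
  seen_at <- NA
  presented <- numeric(0)
  threshold <- NA
  unmeasurable <- FALSE
  finished_at <- NA
  floor_run <- 0
  ceil_run <- 0
  for (k in seq_along(responses)) {
    r <- responses[k]
    presented <- c(presented, level)
    if (r == "seen") seen_at <- level
    if (!is.null(prev) && r != prev) reversals <- reversals + 1
    if (reversals == 2) {
      threshold <- seen_at
      finished_at <- k
      break
    }
    if (r == "unseen" && level == lo) floor_run <- floor_run + 1 else floor_run <- 0
    if (r == "seen" && level == hi) ceil_run <- ceil_run + 1 else ceil_run <- 0
    if (floor_run == 2) {
      threshold <- lo
      unmeasurable <- is.na(seen_at)
      finished_at <- k
      break
    }
    if (ceil_run == 2) {
      threshold <- hi
      finished_at <- k
      break
    }
    delta <- if (reversals == 0) 4 else 2
    level <- if (r == "seen") level + delta else level - delta
    level <- min(hi, max(lo, level))
    prev <- r
  }
  list(presented = presented, threshold = threshold,
       finished_at = finished_at, unmeasurable = unmeasurable)
}

# drive the engine's staircase with a response sequence, recording the
# level presented before each update
engine_42_trace <- function(start, responses) {
  st <- staircase_new(start)
  presented <- numeric(0)
  finished_at <- NA
  for (k in seq_along(responses)) {
    presented <- c(presented, st$current_level_db)
    st <- staircase_update(st, responses[k])
    if (st$finished) { finished_at <- k; break }
  }
  list(presented = presented, threshold = st$threshold_db,
       finished_at = finished_at, unmeasurable = st$unmeasurable,
       state = st)
}

# deterministic step observer: seen iff the stimulus is at least as
# bright (numerically no dimmer) than the true sensitivity
step_response <- function(level, truth) if (level <= truth) "seen" else "unseen"

# run one staircase against a step observer until it finishes
run_step_staircase <- function(start, truth, max_steps = 50) {
  st <- staircase_new(start)
  for (k in seq_len(max_steps)) {
    st <- staircase_update(st, step_response(st$current_level_db, truth))
    if (st$finished) break
  }
  st
}

# flat field whose value the engine can represent exactly from its
# 25 dB seed start (integer, reachable by 4/2 steps along every path)
flat_field <- function(pattern, value = 29) {
  f <- rep(value, nrow(pattern))
  f[pattern$is_blind_spot] <- 0
  f
}
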