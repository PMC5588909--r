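test_that("seed locations are one per quadrant and off the blind spot", {
  p <- generate_pattern("24-2", "right")
  idx <- seed_locations(p)
  expect_length(idx, 4)
  signs <- paste(sign(p$x_deg[idx]), sign(p$y_deg[idx]))
  expect_setequal(signs, c("1 1", "1 -1", "-1 1", "-1 -1"))
  expect_false(any(p$is_blind_spot[idx]))
})

test_that("starting levels propagate as rounded neighbour means with the v2 clamp", {
  expect_equal(starting_level(c(30, 28), "v2"), 29)
  expect_equal(starting_level(c(14, 15), "v2"), 18)   # clamped
  expect_equal(starting_level(c(14, 15), "v1"), 15)   # 14.5 rounds up, no clamp
  expect_equal(starting_level(c(39, 40), "v1"), 40)
  expect_equal(starting_level(numeric(0), "v2", is_seed = TRUE), 25)
  expect_error(starting_level(numeric(0), "v2"), "neighbour")
})

test_that("staircase follows the 4-2 rules on hand-checked traces", {
  # start 25, unseen x2 then seen at 17 (reversal 1), unseen at 19
  # (reversal 2): threshold is the last seen level
  tr <- engine_42_trace(25, c("unseen", "unseen", "seen", "unseen"))
  expect_equal(tr$presented, c(25, 21, 17, 19))
  expect_equal(tr$threshold, 17)
  # all unseen saturates at the 14 dB floor, unmeasurable
  tr2 <- engine_42_trace(25, rep("unseen", 10))
  expect_equal(tr2$threshold, 14)
  expect_true(tr2$unmeasurable)
  expect_false(is.na(tr2$finished_at))
  # all seen saturates at the 40 dB ceiling
  tr3 <- engine_42_trace(25, rep("seen", 10))
  expect_equal(tr3$threshold, 40)
  expect_false(tr3$unmeasurable)
  # updating a finished staircase is an error
  st <- tr$state
  expect_error(staircase_update(st, "seen"), "finished")
})

test_that("staircase agrees with the brute-force 4-2 replay to depth 12", {
  # exhaustive: every response sequence of length 12, several starts
  seqs <- expand.grid(rep(list(c("seen", "unseen")), 12),
                      stringsAsFactors = FALSE)
  for (start in c(14, 18, 25, 40)) {
    mismatch <- 0L
    for (k in seq_len(nrow(seqs))) {
      resp <- unlist(seqs[k, ], use.names = FALSE)
      o <- oracle_42_replay(start, resp)
      e <- engine_42_trace(start, resp)
      same <- identical(e$presented, o$presented) &&
        identical(e$finished_at, o$finished_at) &&
        identical(as.numeric(e$threshold), as.numeric(o$threshold)) &&
        identical(e$unmeasurable, o$unmeasurable)
      if (!same) mismatch <- mismatch + 1L
    }
    expect_identical(mismatch, 0L)
  }
})

test_that("a step observer is bracketed within 2 dB for all truths and starts", {
  for (truth in 15:39) {
    for (start in 18:30) {
      st <- run_step_staircase(start, truth)
      expect_true(st$finished)
      expect_lte(abs(st$threshold_db - truth), 2)
    }
  }
})

test_that("eligibility honours screen bounds and the growth pattern", {
  p <- generate_pattern("24-2", "right")
  scr <- screen_model()
  pose <- eye_pose()
  states <- lapply(seq_len(nrow(p)), function(i) staircase_new(25))
  seeds <- seed_locations(p)
  # at the start only seeds are offered
  e0 <- eligible_locations(states, p, c(0, 0), pose, scr)
  expect_setequal(e0, seeds)
  # finish the seeds: neighbours of seeds open up
  for (i in seeds) {
    states[[i]]$finished <- TRUE
    states[[i]]$threshold_db <- 30
  }
  e1 <- eligible_locations(states, p, c(0, 0), pose, scr)
  expect_gt(length(e1), 0)
  nb_ok <- vapply(e1, function(i) {
    any(vapply(seq_len(nrow(p)), function(j) {
      states[[j]]$finished &&
        ((abs(p$x_deg[j] - p$x_deg[i]) == 6 && p$y_deg[j] == p$y_deg[i]) ||
         (p$x_deg[j] == p$x_deg[i] && abs(p$y_deg[j] - p$y_deg[i]) == 6))
    }, logical(1)))
  }, logical(1))
  expect_true(all(nb_ok))
  # fixation near the top edge: superior-field points largely ineligible
  top_fix <- c(0, scr$height_mm / 2 - 10)
  e_top <- eligible_locations(states, p, top_fix, pose, scr)
  sup <- p$y_deg[e_top] > 0
  expect_lt(sum(sup), length(e1[p$y_deg[e1] > 0]) + 1)
  proj_ok <- vapply(e_top, function(i) {
    !anyNA(project_stimulus(c(p$x_deg[i], p$y_deg[i]), pose, top_fix,
                            screen = scr, radius_mm = 2.1))
  }, logical(1))
  expect_true(all(proj_ok))
  # everything finished: nothing eligible
  for (i in seq_along(states)) {
    states[[i]]$finished <- TRUE
    states[[i]]$threshold_db <- 30
  }
  expect_length(eligible_locations(states, p, c(0, 0), pose, scr), 0)
})

test_that("an ideal observer yields a complete field within 2 dB of truth", {
  p <- generate_pattern("24-2", "right")
  set.seed(21)
  tf <- make_normal_field(p)
  obs <- ideal_observer(tf, p)
  sess <- run_session(session_config(version = "v2", rng_seed = 3), obs)
  expect_true(sess$complete)
  nb <- !p$is_blind_spot
  err <- abs(sess$field$points$threshold_db - truncate_for_comparison(tf))
  expect_lte(max(err[nb]), 2)
  # blind spot: truly blind, bottoms out at the display floor
  expect_equal(sess$field$points$threshold_db[!nb], c(14, 14))
  expect_true(all(sess$field$points$unmeasurable[!nb]))
})

test_that("fixation gating and gaze-contingency hold over the event log", {
  p <- generate_pattern("24-2", "right")
  set.seed(33)
  tf <- make_normal_field(p)
  obs <- observer_model(tf, p)   # realistic noise incl. head drift
  sess <- run_session(session_config(version = "v2", rng_seed = 8), obs)
  log <- sess$log
  pres <- which(log$type == "presentation")
  # every presentation immediately follows a passed fixation check
  expect_true(all(log$type[pres - 1] == "fixation_check" &
                  log$outcome[pres - 1] == "pass"))
  # every logged stimulus position re-projects to the location's angular
  # offset through the logged pose
  for (k in pres) {
    pose <- eye_pose(log$pose_x_mm[k], log$pose_y_mm[k], log$pose_z_mm[k])
    off <- subtended_offset(c(log$x_mm[k], log$y_mm[k]),
                            c(log$fix_x_mm[k], log$fix_y_mm[k]), pose)
    i <- log$location[k]
    expect_lt(max(abs(off - c(p$x_deg[i], p$y_deg[i]))), 1e-6)
  }
})

test_that("v2 never starts a location below 18 dB; v1 may", {
  p <- generate_pattern("24-2", "right")
  # deep advanced loss pushes propagated starts toward the floor
  set.seed(44)
  tf <- make_glaucoma_field(p, field_archetype("advanced"))
  obs <- ideal_observer(tf, p)
  first_levels <- function(version) {
    sess <- run_session(session_config(version = version, rng_seed = 5), obs)
    log <- sess$log[sess$log$type == "presentation", ]
    vapply(split(log, log$location), function(d) d$level_db[1], numeric(1))
  }
  expect_true(all(first_levels("v2") >= 18))
  expect_lt(min(first_levels("v1")), 18)
})

test_that("tracker dropout makes the session incomplete, not an error", {
  p <- generate_pattern("24-2", "right")
  set.seed(55)
  tf <- make_normal_field(p)
  obs <- observer_model(tf, p, dropout_prob = 1)
  sess <- run_session(session_config(rng_seed = 2, retry_budget = 5), obs)
  expect_false(sess$complete)
  expect_true(all(is.na(sess$field$points$threshold_db)))
})

test_that("sessions are deterministic given the seed", {
  p <- generate_pattern("24-2", "right")
  set.seed(66)
  tf <- make_normal_field(p)
  obs <- observer_model(tf, p)
  cfg <- session_config(version = "v2", rng_seed = 13)
  s1 <- run_session(cfg, obs)
  s2 <- run_session(cfg, obs)
  expect_identical(s1$field$points, s2$field$points)
  expect_identical(s1$log, s2$log)
  b1 <- run_sap_like_session(cfg, obs)
  b2 <- run_sap_like_session(cfg, obs)
  expect_identical(b1$field$points, b2$field$points)
})

test_that("the SAP-like comparator thresholds accurately and records fp rate", {
  p <- generate_pattern("24-2", "right")
  set.seed(77)
  tf <- make_normal_field(p)
  sess <- run_sap_like_session(session_config(rng_seed = 4),
                               ideal_observer(tf, p))
  expect_true(sess$complete)
  nb <- !p$is_blind_spot
  err <- abs(sess$field$points$threshold_db - truncate_for_comparison(tf))
  expect_lte(max(err[nb]), 2)
  # a trigger-happy observer is flagged above the 15% exclusion bound
  obs_fp <- observer_model(tf, p, fp_rate = 0.2)
  sess_fp <- run_sap_like_session(session_config(rng_seed = 4), obs_fp)
  expect_equal(sess_fp$field$fp_rate, 0.2)
  expect_gt(sess_fp$field$fp_rate, 0.15)
})
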