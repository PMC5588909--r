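make_field <- function(th, version = "v2", complete = !anyNA(th),
                       fp_rate = NA_real_, eye = "right") {
  p <- generate_pattern("24-2", eye)
  visual_field(p, th, version = version, complete = complete,
               fp_rate = fp_rate)
}

rand_field <- function(version = "v2", fp_rate = NA_real_) {
  make_field(round(runif(54, 16, 36)), version = version, fp_rate = fp_rate)
}

test_that("exclusion rules mirror the reliability criteria", {
  set.seed(1)
  complete_svop <- rand_field("v2")
  sap_ok <- rand_field("sap_sim", fp_rate = 0.10)
  sap_bad <- rand_field("sap_sim", fp_rate = 0.16)
  th <- complete_svop$points$threshold_db; th[3] <- NA
  incomplete_svop <- make_field(th, complete = FALSE)

  res <- apply_exclusions(list(complete_svop, sap_ok, sap_bad,
                               incomplete_svop))
  expect_setequal(res$kept, c(1, 2))
  expect_setequal(res$excluded, c(3, 4))
  expect_setequal(res$reasons, c("false positives > 15%", "incomplete"))
  # bookkeeping: partition with one reason per exclusion
  expect_equal(length(res$kept) + length(res$excluded), 4)
  expect_length(res$reasons, length(res$excluded))
})

test_that("mean sensitivity respects the blind-spot toggle", {
  th <- rep(30, 54)
  p <- generate_pattern("24-2", "right")
  th[p$is_blind_spot] <- 14
  f <- visual_field(p, th)
  expect_equal(mean_sensitivity(f, exclude_blind_spot = TRUE), 30)
  expect_equal(mean_sensitivity(f, exclude_blind_spot = FALSE),
               (52 * 30 + 2 * 14) / 54)
})

test_that("pointwise correlation recovers designed dependence", {
  set.seed(2)
  # identical fields: r = 1 everywhere
  pairs_id <- lapply(1:8, function(k) {
    f <- rand_field()
    comparison_pair(f, f, subject_id = k)
  })
  rep_id <- pointwise_correlation(pairs_id)
  expect_equal(rep_id$per_location$r, rep(1, 54), tolerance = 1e-12)
  # anti-correlated synthetic fields: r = -1 everywhere
  pairs_anti <- lapply(1:8, function(k) {
    f <- rand_field()
    g <- make_field(54 - f$points$threshold_db)
    comparison_pair(f, g, subject_id = k)
  })
  rep_anti <- pointwise_correlation(pairs_anti, truncation_floor = 0)
  expect_equal(rep_anti$per_location$r, rep(-1, 54), tolerance = 1e-12)
  # Gaussian-copula pairs with per-location correlation 0.8
  set.seed(3)
  rho <- 0.8
  n_pairs <- 60
  pairs_cop <- lapply(seq_len(n_pairs), function(k) {
    z1 <- rnorm(54)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(54)
    comparison_pair(make_field(pmin(pmax(26 + 4 * z1, 14), 40)),
                    make_field(pmin(pmax(26 + 4 * z2, 14), 40)),
                    subject_id = k)
  })
  rep_cop <- pointwise_correlation(pairs_cop, truncation_floor = 0)
  expect_lt(abs(rep_cop$summary$mean_r - rho), 0.1)
})

test_that("truncation is applied to the comparison device before correlating", {
  # construct comparison fields whose variation lies entirely below a
  # raised floor: truncating BEFORE correlating collapses that variation
  # (r undefined), truncating after would have left r = 1
  set.seed(4)
  pairs <- lapply(1:20, function(k) {
    b <- round(runif(54, 14, 19))
    comparison_pair(make_field(b + 10), make_field(b), subject_id = k)
  })
  rep_hi <- pointwise_correlation(pairs, truncation_floor = 20)
  expect_true(all(is.na(rep_hi$per_location$r)))
  rep_lo <- pointwise_correlation(pairs, truncation_floor = 14)
  expect_equal(rep_lo$per_location$r, rep(1, 54), tolerance = 1e-12)
})

test_that("repeatability reporting matches its contract", {
  set.seed(5)
  pairs_id <- lapply(1:10, function(k) {
    f <- rand_field()
    comparison_pair(f, f, subject_id = k, pair_kind = "repeat")
  })
  rep1 <- repeatability(pairs_id)
  expect_equal(rep1$per_location$r, rep(1, 54), tolerance = 1e-12)
  expect_equal(rep1$summary$n_above_0.80, 52)   # blind spot excluded
  expect_equal(rep1$summary$n_locations, 52)
  rep_all <- repeatability(pairs_id, exclude_blind_spot = FALSE)
  expect_equal(rep_all$summary$n_above_0.80, 54)
  # independent random fields: mean r near 0
  pairs_null <- lapply(1:50, function(k) {
    comparison_pair(rand_field(), rand_field(), subject_id = k,
                    pair_kind = "repeat")
  })
  rep0 <- repeatability(pairs_null)
  expect_lt(abs(rep0$summary$mean_r), 0.15)
})

test_that("pearson matches the textbook two-pass formula on fixtures", {
  two_pass <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  set.seed(6)
  pairs <- lapply(1:12, function(k) {
    comparison_pair(rand_field(), rand_field(), subject_id = k)
  })
  rep <- pointwise_correlation(pairs, truncation_floor = 0)
  a <- sapply(pairs, function(p) p$field_a$points$threshold_db)
  b <- sapply(pairs, function(p) p$field_b$points$threshold_db)
  for (j in c(1, 17, 36, 54)) {
    expect_equal(rep$per_location$r[j], two_pass(a[j, ], b[j, ]),
                 tolerance = 1e-12)
  }
})

test_that("a small noiseless cohort reproduces itself perfectly", {
  spec <- cohort_spec(n_healthy = 3, n_glaucoma = 2, repeat_fraction = 1,
                      observer_args = list(
                        psychometric_slope_db = 0, fp_rate = 0, fn_rate = 0,
                        saccade_latency_sd_ms = 0, landing_noise_deg = 0,
                        gaze_noise_deg = 0, dropout_prob = 0,
                        head_drift_mm_per_s = 0),
                      master_seed = 42L)
  res <- cohort_experiment(spec, session_config(version = "v2"))
  expect_equal(nrow(res$mean_sensitivity), 5)
  # gaze and button devices agree essentially perfectly on mean sensitivity
  expect_gt(res$agreement_r, 0.99)
  # deterministic observers: repeat thresholds agree within the 2 dB
  # bracketing quantisation at every point (the estimate may shift by one
  # final step when the propagated starting level differs between runs)
  svop1 <- sapply(res$repeatability_svop$per_location$r, identity)
  expect_true(all(is.na(svop1) | svop1 > 0.6))
  expect_gt(res$repeatability_svop$summary$mean_r, 0.9)
  # same master seed twice: identical reports
  res2 <- cohort_experiment(spec, session_config(version = "v2"))
  expect_identical(res$mean_sensitivity, res2$mean_sensitivity)
  expect_identical(res$repeatability_svop$per_location,
                   res2$repeatability_svop$per_location)
})
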