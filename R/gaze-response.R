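# Saccadic response classification: deciding from a gaze stream whether
# the subject was fixating, and whether a presented stimulus was perceived,
# from the direction and amplitude of the gaze-response vector.
#
# All tolerances are expressed in degrees of visual angle and evaluated
# through the per-sample eye pose (screen mm -> degrees), never in raw mm.

#' Construct a gaze stream
#'
#' A time-ordered set of gaze samples: the gaze intersection with the
#' screen plane plus the concurrent eye position.  Invalid samples
#' (tracking dropout) carry no position.
#'
#' @param t_ms Sample timestamps (ms), increasing.
#' @param x_mm,y_mm Gaze point on screen (mm); `NA` where invalid.
#' @param valid Logical vector.
#' @param pose_x_mm,pose_y_mm,pose_z_mm Eye position per sample (mm);
#'   scalars are recycled.
#' @return An `svop_gaze` data frame.
#' @export
gaze_stream <- function(t_ms, x_mm, y_mm, valid = TRUE,
                        pose_x_mm = 0, pose_y_mm = 0, pose_z_mm = 550) {
  n <- length(t_ms)
  if (is.unsorted(t_ms)) stop("gaze samples must be time-ordered")
  g <- data.frame(t_ms = t_ms,
                  x_mm = rep_len(x_mm, n), y_mm = rep_len(y_mm, n),
                  valid = rep_len(valid, n),
                  pose_x_mm = rep_len(pose_x_mm, n),
                  pose_y_mm = rep_len(pose_y_mm, n),
                  pose_z_mm = rep_len(pose_z_mm, n))
  g$x_mm[!g$valid] <- NA_real_
  g$y_mm[!g$valid] <- NA_real_
  structure(g, class = c("svop_gaze", "data.frame"))
}

# angular distance (deg) between two screen points through a sample's pose
sample_angular_dist <- function(x1, y1, x2, y2, px, py, pz) {
  ax <- (atan((x1 - px) / pz) - atan((x2 - px) / pz)) * 180 / pi
  ay <- (atan((y1 - py) / pz) - atan((y2 - py) / pz)) * 180 / pi
  sqrt(ax^2 + ay^2)
}

#' Verify steady fixation on a target
#'
#' Checks that over the trailing `dwell_ms` of the stream every valid
#' sample lies within `tolerance_deg` of the target.  If more than half of
#' the samples in the window are invalid the tracking quality is deemed
#' insufficient to decide and `NA` is returned; the caller must withhold
#' the presentation.
#'
#' @param stream An `svop_gaze`.
#' @param target_xy_mm Fixation target on screen, mm.
#' @param tolerance_deg Angular tolerance (degrees), default 2.
#' @param dwell_ms Dwell window, default 200 ms.
#' @return `TRUE`, `FALSE`, or `NA` on tracking-quality failure.
#' @export
verify_fixation <- function(stream, target_xy_mm, tolerance_deg = 2,
                            dwell_ms = 200) {
  stopifnot(tolerance_deg > 0, dwell_ms > 0)
  if (nrow(stream) == 0) return(NA)
  w <- stream[stream$t_ms >= max(stream$t_ms) - dwell_ms, , drop = FALSE]
  if (mean(!w$valid) > 0.5) return(NA)
  v <- w[w$valid, , drop = FALSE]
  if (nrow(v) == 0) return(NA)
  d <- sample_angular_dist(v$x_mm, v$y_mm,
                           target_xy_mm[1], target_xy_mm[2],
                           v$pose_x_mm, v$pose_y_mm, v$pose_z_mm)
  all(d <= tolerance_deg)
}

#' Detect the first saccade in a gaze stream
#'
#' Scans consecutive valid samples for inter-sample angular velocity above
#' `velocity_deg_s`.  A candidate movement counts as a saccade only if its
#' amplitude -- from the median pre-movement position to the median
#' post-movement position -- exceeds `min_amplitude_deg`; this rejects the
#' velocity spikes that per-sample tracker jitter produces.  The landing
#' point is the componentwise median of the post-movement steady samples.
#'
#' @param stream An `svop_gaze` with at least 2 valid samples.
#' @param velocity_deg_s Saccade velocity threshold, default 100 deg/s.
#' @param min_amplitude_deg Minimum movement amplitude, default 2 degrees
#'   (well below the smallest 24-2 stimulus offset of ~4.2 degrees).
#' @return `list(onset_ms, landing_xy_mm)` or `NULL` if no saccade.
#' @export
detect_saccade <- function(stream, velocity_deg_s = 100,
                           min_amplitude_deg = 2) {
  v <- stream[stream$valid, , drop = FALSE]
  n <- nrow(v)
  if (n < 2) return(NULL)
  d <- sample_angular_dist(v$x_mm[-1], v$y_mm[-1],
                           v$x_mm[-n], v$y_mm[-n],
                           v$pose_x_mm[-1], v$pose_y_mm[-1], v$pose_z_mm[-1])
  dt <- diff(v$t_ms) / 1000
  vel <- d / pmax(dt, 1e-9)
  hot <- vel > velocity_deg_s
  if (!any(hot)) return(NULL)
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in which(runs$values)) {
    s <- starts[k]; e <- ends[k]        # velocity k is between samples k, k+1
    pre <- seq.int(max(1L, s - 5L), s)
    post <- seq.int(min(e + 1L, n), min(e + 10L, n))
    pre_xy <- c(stats::median(v$x_mm[pre]), stats::median(v$y_mm[pre]))
    land <- c(stats::median(v$x_mm[post]), stats::median(v$y_mm[post]))
    j <- post[1]
    amp <- sample_angular_dist(land[1], land[2], pre_xy[1], pre_xy[2],
                               v$pose_x_mm[j], v$pose_y_mm[j], v$pose_z_mm[j])
    if (amp >= min_amplitude_deg) {
      return(list(onset_ms = v$t_ms[s + 1L], landing_xy_mm = land))
    }
  }
  NULL
}

#' Classify the gaze response to a stimulus presentation
#'
#' The decision rule of saccadic-vector perimetry: a stimulus counts as
#' seen only if the subject makes a saccade whose vector -- direction and
#' amplitude from the fixation point -- matches the fixation-to-stimulus
#' vector within tolerance, inside the response window.  If the window
#' elapses with gaze held on fixation the stimulus was unseen.  Anything
#' else (tracking loss, a saccade on a non-matching vector, gaze wandering
#' off fixation) is an invalid presentation that must be repeated.
#'
#' @param stream An `svop_gaze` covering the response window.
#' @param fixation_xy_mm,stimulus_xy_mm Screen points, mm.
#' @param onset_ms Stimulus onset time (ms, same clock as the stream).
#' @param window_ms Unseen-decision window; default 1000 ms.
#' @param direction_tol_deg Allowed angle between the response vector and
#'   the fixation-to-stimulus vector, default 20 degrees.
#' @param amplitude_tol_frac Allowed fractional amplitude mismatch,
#'   default 0.30.
#' @param fixation_tol_deg Tolerance for "gaze held at fixation" when
#'   deciding unseen, default 2 degrees.
#' @param velocity_deg_s Saccade detection threshold, default 100 deg/s.
#' @return An `svop_decision`: `list(outcome, saccade_latency_ms,
#'   landing_xy_mm)` with `outcome` one of `"seen"`, `"unseen"`,
#'   `"invalid"`.
#' @export
classify_response <- function(stream, fixation_xy_mm, stimulus_xy_mm,
                              onset_ms, window_ms = 1000,
                              direction_tol_deg = 20,
                              amplitude_tol_frac = 0.30,
                              fixation_tol_deg = 2,
                              velocity_deg_s = 100) {
  decision <- function(outcome, latency = NA_real_, landing = c(NA_real_, NA_real_)) {
    structure(list(outcome = outcome, saccade_latency_ms = latency,
                   landing_xy_mm = landing), class = "svop_decision")
  }
  w <- stream[stream$t_ms >= onset_ms & stream$t_ms <= onset_ms + window_ms, ,
              drop = FALSE]
  if (nrow(w) == 0 || mean(!w$valid) > 0.5) return(decision("invalid"))
  sac <- detect_saccade(w, velocity_deg_s)
  valid <- w[w$valid, , drop = FALSE]
  if (is.null(sac)) {
    d <- sample_angular_dist(valid$x_mm, valid$y_mm,
                             fixation_xy_mm[1], fixation_xy_mm[2],
                             valid$pose_x_mm, valid$pose_y_mm, valid$pose_z_mm)
    if (all(d <= fixation_tol_deg)) return(decision("unseen"))
    return(decision("invalid"))
  }
  # vectors in component-angle space through the pose at saccade time
  i <- which.min(abs(valid$t_ms - sac$onset_ms))
  pose <- eye_pose(valid$pose_x_mm[i], valid$pose_y_mm[i], valid$pose_z_mm[i])
  resp <- subtended_offset(sac$landing_xy_mm, fixation_xy_mm, pose)
  req <- subtended_offset(stimulus_xy_mm, fixation_xy_mm, pose)
  amp_resp <- sqrt(sum(resp^2)); amp_req <- sqrt(sum(req^2))
  if (amp_req <= 0 || amp_resp <= 0) return(decision("invalid"))
  cosang <- sum(resp * req) / (amp_resp * amp_req)
  dir_err <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  amp_err <- abs(amp_resp - amp_req) / amp_req
  if (dir_err <= direction_tol_deg && amp_err <= amplitude_tol_frac) {
    return(decision("seen", latency = sac$onset_ms - onset_ms,
                    landing = sac$landing_xy_mm))
  }
  decision("invalid")
}

#' @export
print.svop_decision <- function(x, ...) {
  cat("<svop_decision>", x$outcome)
  if (identical(x$outcome, "seen")) {
    cat(sprintf(" (latency %.0f ms)", x$saccade_latency_ms))
  }
  cat("\n")
  invisible(x)
}

#' Read / write gaze streams as JSON lines
#'
#' One sample per line: `t_ms`, `x_mm`, `y_mm`, `valid` and the eye pose.
#' Invalid samples are written without a position.
#'
#' @param stream An `svop_gaze`.
#' @param path File path.
#' @return `read_gaze_stream` returns an `svop_gaze`.
#' @export
write_gaze_stream <- function(stream, path) {
  lines <- vapply(seq_len(nrow(stream)), function(i) {
    s <- stream[i, ]
    rec <- list(t_ms = s$t_ms, valid = s$valid,
                pose = list(x_mm = s$pose_x_mm, y_mm = s$pose_y_mm,
                            z_mm = s$pose_z_mm))
    if (s$valid) { rec$x_mm <- s$x_mm; rec$y_mm <- s$y_mm }
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gaze_stream
#' @export
read_gaze_stream <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  gaze_stream(
    t_ms = vapply(recs, `[[`, numeric(1), "t_ms"),
    x_mm = vapply(recs, function(r) r$x_mm %||% NA_real_, numeric(1)),
    y_mm = vapply(recs, function(r) r$y_mm %||% NA_real_, numeric(1)),
    valid = vapply(recs, `[[`, logical(1), "valid"),
    pose_x_mm = vapply(recs, function(r) r$pose$x_mm, numeric(1)),
    pose_y_mm = vapply(recs, function(r) r$pose$y_mm, numeric(1)),
    pose_z_mm = vapply(recs, function(r) r$pose$z_mm, numeric(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
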