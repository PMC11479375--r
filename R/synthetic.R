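# Synthetic gait cohort simulator.
#
# Emulates a walkway protocol: subjects walk repeatedly across a
# pressure-sensitive mat at slow / preferred / fast instructed speeds while
# wearing an ear accelerometer. The generator first builds the footfall
# sequence (per-foot IC chains with stride-to-stride variability and
# left-right asymmetry, stance-fraction-derived FCs, heel x/y coordinates),
# then synthesizes ear acceleration on top of it: gravity, step- and
# stride-frequency harmonics whose local amplitude tracks the local stride
# length, a damped-oscillation impact transient at every IC, a smaller
# transient at every FC, a per-subject sensor-orientation rotation
# ("ear anatomy"), and Gaussian sensor noise. Ground-truth stride records
# are derived from the emitted events and coordinates with the same
# machinery the analysis side uses, so generator and metrics agree exactly.

#' Distribution hyperparameters for synthetic subjects
#'
#' Defaults are healthy-adult walking norms: cadence around 95 / 112 / 125
#' steps per minute and stride length around 110 / 128 / 145 cm at slow /
#' preferred / fast instructed speeds, stride-to-stride CVs of a few
#' percent, small (~1-2%) left-right asymmetries, stride width around 8 cm
#' with high relative variability, and stance fractions of 62/60/58% of the
#' gait cycle reflecting the shortening of double support with speed.
#'
#' @param ... overrides for individual fields; see the function body for
#'   the complete list, units are in the field names or documented above.
#' @return named list of hyperparameters.
#' @export
subject_hyper <- function(...) {
  h <- list(
    cadence_mean = c(slow = 95, preferred = 112, fast = 125),   # steps/min
    cadence_subject_sd = 6,
    cadence_speed_jitter_sd = 1.5,
    stride_length_mean = c(slow = 110, preferred = 128, fast = 145),  # cm
    stride_length_subject_sd = 8,
    stride_length_speed_jitter_sd = 2,
    stride_time_cv_mean = 2.5, stride_time_cv_sd = 0.8,          # %
    stride_length_cv_mean = 2.5, stride_length_cv_sd = 0.8,      # %
    temporal_asym_mean = 1.0, temporal_asym_sd = 0.5,            # %
    spatial_asym_mean = 1.5, spatial_asym_sd = 0.8,              # %
    stride_width_mean = 8, stride_width_sd = 1.5,                # cm
    stride_width_cv_mean = 20, stride_width_cv_sd = 5,           # %
    height_mean = 1.73, height_sd = 0.10,                        # m
    orientation_sd_deg = 8,                                      # per axis
    noise_sd_g = 0.03,
    stance_fraction = c(slow = 0.62, preferred = 0.60, fast = 0.58),
    harmonic_amp_g = 0.35,     # vertical amplitude at 130 cm stride length
    impact_amp_g = 0.8,        # IC transient amplitude at preferred cadence
    fc_amp_ratio = 0.35,       # FC transient relative to IC transient
    lead_in_s = 0.5)           # recording margin before/after the walk
  dots <- list(...)
  unknown <- setdiff(names(dots), names(h))
  if (length(unknown))
    stop_mear(paste("unknown hyperparameter(s):",
                    paste(unknown, collapse = ", ")), "mear_config_error")
  h[names(dots)] <- dots
  h
}

#' Configuration of a synthetic cohort
#'
#' @param n_subjects number of subjects (>= 2).
#' @param walks_per_speed named integer vector: repetitions per instructed
#'   speed; defaults to 6 slow, 8 preferred, 10 fast walks.
#' @param walkway_m walkway length in meters.
#' @param seed master seed; every subject and bout derives its own
#'   substream from it by counter, so cohorts are reproducible.
#' @param hyper subject-distribution hyperparameters ([subject_hyper()]).
#' @return a `cohort_config` object.
#' @export
cohort_config <- function(n_subjects, walks_per_speed = c(slow = 6,
                                                          preferred = 8,
                                                          fast = 10),
                          walkway_m = 6.7, seed = 1,
                          hyper = subject_hyper()) {
  if (n_subjects < 2) stop_mear("n_subjects must be >= 2", "mear_config_error")
  if (walkway_m <= 0) stop_mear("walkway_m must be > 0", "mear_config_error")
  if (!all(SPEED_LEVELS %in% names(walks_per_speed)))
    stop_mear("walks_per_speed must name slow, preferred and fast",
              "mear_config_error")
  structure(list(n_subjects = as.integer(n_subjects),
                 walks_per_speed = walks_per_speed[SPEED_LEVELS],
                 walkway_m = walkway_m, seed = as.integer(seed),
                 hyper = hyper),
            class = "cohort_config")
}

# counter-derived substreams below 2^31 so parallel generation reproduces
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in idx) s <- (s * 69069 + as.double(k) * 7919 + 1) %% 2147483647
  as.integer(s)
}

rot3 <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Draw one synthetic subject
#'
#' Deterministic given `(config$seed, index)`. Per-speed cadences and
#' stride lengths share a between-subject offset plus small per-speed
#' jitter and are sorted so that slow < preferred < fast always holds.
#'
#' @param config a [cohort_config()].
#' @param index subject index (1-based).
#' @return a `subject_params` object.
#' @export
draw_subject <- function(config, index) {
  stopifnot(inherits(config, "cohort_config"))
  h <- config$hyper
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 1L, index))
  cad <- sort(h$cadence_mean + stats::rnorm(1, 0, h$cadence_subject_sd) +
                stats::rnorm(3, 0, h$cadence_speed_jitter_sd))
  len <- sort(h$stride_length_mean +
                stats::rnorm(1, 0, h$stride_length_subject_sd) +
                stats::rnorm(3, 0, h$stride_length_speed_jitter_sd))
  names(cad) <- names(len) <- SPEED_LEVELS
  subject <- structure(list(
    subject_id = sprintf("S%03d", index),
    ear_side = if (index %% 2L == 1L) "left" else "right",
    height = stats::rnorm(1, h$height_mean, h$height_sd),
    cadence = cad,
    stride_length = len,
    stride_time_cv = abs(stats::rnorm(1, h$stride_time_cv_mean,
                                      h$stride_time_cv_sd)),
    stride_length_cv = abs(stats::rnorm(1, h$stride_length_cv_mean,
                                        h$stride_length_cv_sd)),
    temporal_asym = abs(stats::rnorm(1, h$temporal_asym_mean,
                                     h$temporal_asym_sd)),
    spatial_asym = abs(stats::rnorm(1, h$spatial_asym_mean,
                                    h$spatial_asym_sd)),
    asym_foot_time = sample(c("left", "right"), 1),
    asym_foot_len = sample(c("left", "right"), 1),
    stride_width = max(2, stats::rnorm(1, h$stride_width_mean,
                                       h$stride_width_sd)),
    stride_width_cv = abs(stats::rnorm(1, h$stride_width_cv_mean,
                                       h$stride_width_cv_sd)),
    rotation = rot3(stats::rnorm(3, 0, h$orientation_sd_deg)),
    phases = stats::runif(4, 0, 2 * pi),
    noise_sd = h$noise_sd_g,
    stance_fraction = h$stance_fraction,
    hyper = h), class = "subject_params")
  subject
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# split a mean value between feet so the asymmetry formula recovers asym_pct:
# the larger foot carries the configured mean, the smaller mean*(1-a/100)
asym_split <- function(mean_value, asym_pct, big_foot) {
  small <- mean_value * (1 - asym_pct / 100)
  if (big_foot == "left") c(left = mean_value, right = small)
  else c(left = small, right = mean_value)
}

truncated_jitter <- function(n, mean, cv_pct, floor_frac = 0.3) {
  pmax(floor_frac * mean, stats::rnorm(n, mean, mean * cv_pct / 100))
}

#' Generate one synthetic walking bout
#'
#' Builds the footfall sequence and stride geometry for one walk across
#' the walkway, then synthesizes the ear-acceleration signal on top of it
#' (see the file header for the signal model). Ground-truth stride records
#' are derived from the emitted events via [strides_from_events()] plus
#' the heel coordinates, so bout-internal consistency is exact.
#'
#' @param subject a [draw_subject()] result.
#' @param speed `"slow"`, `"preferred"` or `"fast"`.
#' @param seed integer seed for this bout's substream.
#' @param walkway_m walkway length in meters.
#' @return a [walk_bout()] with ground-truth `events` and `strides`.
#' @export
generate_bout <- function(subject, speed, seed, walkway_m = 6.7) {
  stopifnot(inherits(subject, "subject_params"))
  speed <- match.arg(speed, SPEED_LEVELS)
  h <- subject$hyper
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  cadence <- subject$cadence[[speed]]
  stride_t <- 120 / cadence                       # s, mean over feet
  stride_l <- subject$stride_length[[speed]]      # cm
  walkway_cm <- walkway_m * 100
  l_foot <- asym_split(stride_l, subject$spatial_asym, subject$asym_foot_len)
  if (walkway_cm < min(l_foot))
    stop_mear("walkway shorter than one stride", "mear_config_error")
  stance <- subject$stance_fraction[[speed]]

  n_str <- ceiling(walkway_cm / min(l_foot)) + 1L  # strides per foot
  feet <- c("left", "right")
  start_foot <- sample(feet, 1)
  other <- setdiff(feet, start_foot)

  # Timing: both feet share the common gait-cycle durations (stride time
  # is the sum of both step times, so it cannot differ between feet on a
  # straight walk); temporal asymmetry is the left-right step-time split,
  # a phase offset of the second foot inside each cycle. This keeps the
  # feet phase-locked instead of drifting apart.
  cycle_t <- truncated_jitter(n_str + 1, stride_t, subject$stride_time_cv)
  q <- 1 / (2 - subject$temporal_asym / 100)      # larger-step fraction
  step_frac <- if (subject$asym_foot_time == other) q else 1 - q
  step_frac_i <- pmin(0.8, pmax(0.2, step_frac *
    (1 + stats::rnorm(n_str + 1, 0, subject$stride_time_cv / 200))))
  lead <- h$lead_in_s
  ic <- list()
  ic[[start_foot]] <- lead + cumsum(c(0, cycle_t[seq_len(n_str)]))
  ic[[other]] <- ic[[start_foot]] + step_frac_i * cycle_t

  stride_lens <- list()
  for (ft in feet)
    stride_lens[[ft]] <- truncated_jitter(n_str, l_foot[[ft]],
                                          subject$stride_length_cv)
  x <- list(); y <- list()
  first_step_len <- truncated_jitter(1, stride_l / 2,
                                     subject$stride_length_cv)
  x[[start_foot]] <- cumsum(c(0, stride_lens[[start_foot]]))
  x[[other]] <- first_step_len + cumsum(c(0, stride_lens[[other]]))
  for (ft in feet) {
    side <- if (ft == "left") 1 else -1
    y[[ft]] <- side * (subject$stride_width / 2) *
      (1 + stats::rnorm(n_str + 1, 0, subject$stride_width_cv / 100))
  }

  # FCs at the stance fraction of each realized ipsilateral cycle; the
  # trailing IC takes the mean stride time
  fc <- list()
  for (ft in feet) {
    realized <- diff(ic[[ft]])
    fc[[ft]] <- ic[[ft]] + stance * c(realized, stride_t)
  }

  events <- gait_events(
    time = c(ic$left, fc$left, ic$right, fc$right),
    kind = c(rep("IC", n_str + 1), rep("FC", n_str + 1),
             rep("IC", n_str + 1), rep("FC", n_str + 1)),
    foot = rep(c("left", "right"), each = 2 * (n_str + 1)))

  strides <- strides_from_events(events)
  for (ft in feet) {
    rows <- which(strides$foot == ft)
    ord <- order(strides$ic_time[rows])
    idx_stride <- match(round(strides$ic_time[rows], 9),
                        round(ic[[ft]][seq_len(n_str)], 9))
    strides$stride_length_cm[rows] <- stride_lens[[ft]][idx_stride]
    # stride width: perpendicular distance of the contralateral contact to
    # the line through the two flanking ipsilateral contacts
    contra <- setdiff(feet, ft)
    for (r in seq_along(rows)) {
      i <- idx_stride[r]
      t0 <- ic[[ft]][i]; t1 <- ic[[ft]][i + 1]
      j <- which(ic[[contra]] > t0 & ic[[contra]] < t1)
      if (length(j) != 1) next
      p1 <- c(x[[ft]][i], y[[ft]][i])
      p2 <- c(x[[ft]][i + 1], y[[ft]][i + 1])
      q <- c(x[[contra]][j], y[[contra]][j])
      v <- p2 - p1
      strides$stride_width_cm[rows[r]] <-
        abs(v[1] * (q[2] - p1[2]) - v[2] * (q[1] - p1[1])) / sqrt(sum(v^2))
    }
  }

  rec <- synth_acceleration(subject, speed, events,
                            stride_lens_by_time = list(
                              ic = ic, lens = stride_lens))
  walk_bout(rec, speed, events, strides)
}

# acceleration synthesis on top of an event sequence (see file header)
synth_acceleration <- function(subject, speed, events, stride_lens_by_time) {
  h <- subject$hyper
  fs <- MEAR_SAMPLE_RATE
  t_end <- max(events$time) + h$lead_in_s
  n <- ceiling(t_end * fs) + 1L
  t <- (seq_len(n) - 1) / fs

  steps <- sort(events$time[events$kind == "IC"])
  phase <- 2 * pi * stats::approx(steps, seq_along(steps) - 1, t,
                                  rule = 2)$y

  # local amplitude envelope follows the local stride length (ratio to a
  # 130 cm reference), so the signal amplitude encodes stride length
  env_t <- c(); env_v <- c()
  for (ft in c("left", "right")) {
    ics <- stride_lens_by_time$ic[[ft]]
    lens <- stride_lens_by_time$lens[[ft]]
    env_t <- c(env_t, ics[seq_along(lens)])
    env_v <- c(env_v, lens / 130)
  }
  ord <- order(env_t)
  env <- stats::approx(env_t[ord], env_v[ord], t, rule = 2)$y
  amp <- h$harmonic_amp_g * env

  ph <- subject$phases
  is_ax <- 1 + amp * sin(phase + ph[1]) + 0.3 * amp * sin(2 * phase + ph[2])
  ap_ax <- 0.55 * amp * sin(phase + ph[3])
  ml_ax <- 0.30 * h$harmonic_amp_g * sin(phase / 2 + ph[4])

  speed_scale <- subject$cadence[[speed]] / 112
  add_transient <- function(sig, times, amp0, freq, decay, weight) {
    for (tau in times) {
      i0 <- floor(tau * fs) + 1L
      i1 <- min(n, i0 + 0.25 * fs)
      if (i0 > n) next
      dt <- t[i0:i1] - tau
      dt[dt < 0] <- 0
      sig[i0:i1] <- sig[i0:i1] +
        weight * amp0 * exp(-dt / decay) * sin(2 * pi * freq * dt)
    }
    sig
  }
  for (ft in c("left", "right")) {
    ics <- events$time[events$kind == "IC" & events$foot == ft]
    fcs <- events$time[events$kind == "FC" & events$foot == ft]
    amp_ic <- h$impact_amp_g * speed_scale *
      (1 + stats::rnorm(1, 0, 0.08))
    amp_fc <- h$fc_amp_ratio * amp_ic
    ml_sign <- if (ft == "left") 1 else -1
    is_ax <- add_transient(is_ax, ics, amp_ic, 13, 0.05, 1)
    ap_ax <- add_transient(ap_ax, ics, amp_ic, 13, 0.05, 0.6)
    ml_ax <- add_transient(ml_ax, ics, amp_ic, 13, 0.05, 0.3 * ml_sign)
    ap_ax <- add_transient(ap_ax, fcs, amp_fc, 8, 0.04, 1)
    is_ax <- add_transient(is_ax, fcs, amp_fc, 8, 0.04, 0.5)
    ml_ax <- add_transient(ml_ax, fcs, amp_fc, 8, 0.04, -0.2 * ml_sign)
  }

  S <- rbind(ml_ax, ap_ax, is_ax)            # sensor axes ml, ap, is
  S <- subject$rotation %*% S
  S <- S + stats::rnorm(length(S), 0, subject$noise_sd)
  S <- pmin(pmax(S, -MEAR_ACC_RANGE_G), MEAR_ACC_RANGE_G)
  accel_recording(t(S), subject_id = subject$subject_id,
                  ear_side = subject$ear_side, t0 = 0)
}

#' Generate a full synthetic cohort
#'
#' @param config a [cohort_config()].
#' @return list with `bouts` (list of [walk_bout()]s, one per subject x
#'   speed x repetition) and `manifest` (data.frame mapping `bout_id` to
#'   `subject_id`, `ear_side`, `speed_condition`, `walk_index`) -- the
#'   manifest is what group-aware splitting keys on.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  bouts <- list()
  manifest <- list()
  for (si in seq_len(config$n_subjects)) {
    subject <- draw_subject(config, si)
    for (sp_i in seq_along(SPEED_LEVELS)) {
      sp <- SPEED_LEVELS[sp_i]
      for (w in seq_len(config$walks_per_speed[[sp]])) {
        bout_seed <- derive_seed(config$seed, 2L, si, sp_i, w)
        bout <- generate_bout(subject, sp, bout_seed, config$walkway_m)
        id <- sprintf("%s_%s_%02d", subject$subject_id, sp, w)
        bouts[[id]] <- bout
        manifest[[length(manifest) + 1]] <-
          data.frame(bout_id = id, subject_id = subject$subject_id,
                     ear_side = subject$ear_side, speed_condition = sp,
                     walk_index = w, stringsAsFactors = FALSE)
      }
    }
  }
  list(bouts = bouts, manifest = do.call(rbind, manifest))
}
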