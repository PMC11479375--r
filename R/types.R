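#' @keywords internal
"_PACKAGE"

MEAR_SAMPLE_RATE <- 100    # Hz, sensor-native
MEAR_ACC_RANGE_G <- 16     # sensor full scale per axis
ACC_CHANNELS <- c("acc_ml", "acc_ap", "acc_is")

EAR_SIDES <- c("left", "right")
FOOT_LEVELS <- c("left", "right", "unknown")
EVENT_KINDS <- c("IC", "FC")
SPEED_LEVELS <- c("slow", "preferred", "fast")

stop_mear <- function(msg, class) {
  stop(structure(class = c(class, "mear_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Construct a triaxial ear-acceleration recording
#'
#' An `accel_recording` holds one continuous 100 Hz triaxial acceleration
#' time series from an ear-worn sensor, in units of g, with axes
#' medio-lateral (ML), anterior-posterior (AP) and inferior-superior (IS).
#' The time of sample `i` (1-based) is `t0 + (i - 1) / sample_rate`.
#'
#' @param samples numeric matrix with one row per sample and columns
#'   `acc_ml`, `acc_ap`, `acc_is` (order is enforced; names optional).
#' @param subject_id opaque subject identifier.
#' @param ear_side `"left"` or `"right"`: which ear carried the sensor.
#' @param t0 time of the first sample, seconds.
#' @param sample_rate sampling rate in Hz; must be 100 (sensor-native).
#' @return an object of class `accel_recording`.
#' @export
accel_recording <- function(samples, subject_id = "unknown",
                            ear_side = "left", t0 = 0,
                            sample_rate = MEAR_SAMPLE_RATE) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L)
    stop_mear("samples must have 3 columns (acc_ml, acc_ap, acc_is)",
              "mear_format_error")
  if (nrow(samples) < 1L)
    stop_mear("recording must contain at least one sample", "mear_format_error")
  storage.mode(samples) <- "double"
  colnames(samples) <- ACC_CHANNELS
  if (!all(is.finite(samples)))
    stop_mear("recording contains non-finite samples", "mear_format_error")
  if (max(abs(samples)) > MEAR_ACC_RANGE_G)
    stop_mear(sprintf("|acc| exceeds sensor range of +/-%d g", MEAR_ACC_RANGE_G),
              "mear_format_error")
  if (!identical(as.numeric(sample_rate), 100))
    stop_mear("sample_rate must be 100 Hz", "mear_format_error")
  ear_side <- match.arg(ear_side, EAR_SIDES)
  structure(list(samples = samples,
                 subject_id = as.character(subject_id),
                 ear_side = ear_side,
                 t0 = as.numeric(t0),
                 sample_rate = 100),
            class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> subject=%s ear=%s n=%d (%.2f s) t0=%.3f s\n",
              x$subject_id, x$ear_side, nrow(x$samples),
              nrow(x$samples) / x$sample_rate, x$t0))
  invisible(x)
}

#' Sample times of a recording
#' @param recording an `accel_recording`.
#' @return numeric vector of sample times in seconds.
#' @export
recording_times <- function(recording) {
  recording$t0 + (seq_len(nrow(recording$samples)) - 1) / recording$sample_rate
}

#' Construct a gait-event table
#'
#' Events are initial contacts (IC, heel strike) and final contacts
#' (FC, toe off), each with a foot side (`"unknown"` until sides are
#' assigned) and a time in seconds. The table is sorted by time.
#'
#' @param time numeric, seconds, all `>= 0`.
#' @param kind character, `"IC"` or `"FC"`.
#' @param foot character, `"left"`, `"right"` or `"unknown"`.
#' @return a `data.frame` with columns `time`, `kind`, `foot`, sorted by time.
#' @export
gait_events <- function(time = numeric(), kind = character(),
                        foot = rep("unknown", length(time))) {
  if (length(time) != length(kind) || length(time) != length(foot))
    stop_mear("time, kind and foot must have equal length", "mear_format_error")
  if (length(time) && any(!is.finite(time) | time < 0))
    stop_mear("event times must be finite and >= 0", "mear_format_error")
  if (length(kind) && !all(kind %in% EVENT_KINDS))
    stop_mear("event kind must be 'IC' or 'FC'", "mear_format_error")
  if (length(foot) && !all(foot %in% FOOT_LEVELS))
    stop_mear("event foot must be 'left', 'right' or 'unknown'",
              "mear_format_error")
  d <- data.frame(time = as.numeric(time), kind = as.character(kind),
                  foot = as.character(foot), stringsAsFactors = FALSE)
  d <- d[order(d$time, d$kind, d$foot), , drop = FALSE]
  rownames(d) <- NULL
  d
}

STRIDE_COLUMNS <- c("foot", "ic_time", "stride_time", "swing_time",
                    "dsupp_time", "stride_length_cm", "stride_width_cm")

#' Construct a stride table
#'
#' One row per gait cycle of one foot: temporal parameters in seconds
#' (stride time, swing time, double support time) and spatial parameters
#' in cm (stride length, stride width). `NA` marks parameters that could
#' not be derived for a cycle.
#'
#' @param foot,ic_time,stride_time,swing_time,dsupp_time vectors of equal
#'   length: foot side, cycle-start IC time (s) and temporal parameters (s).
#' @param stride_length_cm,stride_width_cm spatial parameters (cm), `NA`
#'   when unavailable.
#' @return a `data.frame` with the canonical stride columns.
#' @export
stride_table <- function(foot = character(), ic_time = numeric(),
                         stride_time = numeric(), swing_time = numeric(),
                         dsupp_time = numeric(),
                         stride_length_cm = rep(NA_real_, length(foot)),
                         stride_width_cm = rep(NA_real_, length(foot))) {
  d <- data.frame(foot = as.character(foot), ic_time = as.numeric(ic_time),
                  stride_time = as.numeric(stride_time),
                  swing_time = as.numeric(swing_time),
                  dsupp_time = as.numeric(dsupp_time),
                  stride_length_cm = as.numeric(stride_length_cm),
                  stride_width_cm = as.numeric(stride_width_cm),
                  stringsAsFactors = FALSE)
  if (nrow(d)) {
    if (!all(d$foot %in% c("left", "right")))
      stop_mear("stride foot must be 'left' or 'right'", "mear_format_error")
    bad <- !is.na(d$stride_time) & d$stride_time <= 0
    if (any(bad)) stop_mear("stride_time must be > 0", "mear_format_error")
    bad <- !is.na(d$swing_time) &
      (d$swing_time < 0 | d$swing_time >= ifelse(is.na(d$stride_time), Inf,
                                                 d$stride_time))
    if (any(bad)) stop_mear("swing_time must lie in [0, stride_time)",
                            "mear_format_error")
    bad <- !is.na(d$stride_length_cm) & d$stride_length_cm < 0
    if (any(bad)) stop_mear("stride_length_cm must be >= 0", "mear_format_error")
  }
  d
}

#' Construct a walking bout
#'
#' A bout is one continuous walk across the walkway at a single instructed
#' speed: the sensor recording plus (optionally) ground-truth events and
#' stride geometry.
#'
#' @param recording an [accel_recording()].
#' @param speed_condition `"slow"`, `"preferred"` or `"fast"`.
#' @param events ground-truth or predicted event table ([gait_events()]).
#' @param strides ground-truth stride table ([stride_table()]), optional.
#' @return an object of class `walk_bout`.
#' @export
walk_bout <- function(recording, speed_condition, events = gait_events(),
                      strides = stride_table()) {
  stopifnot(inherits(recording, "accel_recording"))
  speed_condition <- match.arg(speed_condition, SPEED_LEVELS)
  if (nrow(events) > 1 && is.unsorted(events$time))
    stop_mear("bout events must be sorted by time", "mear_format_error")
  structure(list(recording = recording, speed_condition = speed_condition,
                 events = events, strides = strides),
            class = "walk_bout")
}

#' @export
print.walk_bout <- function(x, ...) {
  cat(sprintf("<walk_bout> subject=%s speed=%s events=%d strides=%d\n",
              x$recording$subject_id, x$speed_condition,
              nrow(x$events), nrow(x$strides)))
  invisible(x)
}
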