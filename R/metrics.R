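# Stride-level gait parameters from sided event sequences, and bout-level
# mean / variability / asymmetry summaries.
#
# Definitions (standard gait-phase conventions, walkway instrumentation):
#   stride time   = time between successive ICs of the same foot
#   swing time    = from a foot's FC to its next IC (foot airborne)
#   double support= the two within-cycle intervals with both feet grounded:
#                   (contralateral FC - ipsilateral IC) at cycle start plus
#                   (ipsilateral FC - contralateral IC) before swing
#   CV            = 100 * sd / mean (sample sd, ddof = 1), in %
#   asymmetry     = 100 * (1 - mean(smaller foot) / mean(larger foot)), in %

GAIT_PARAMETERS <- c("stride_time", "swing_time", "dsupp_time",
                     "stride_length_cm", "stride_width_cm")

#' Derive temporal stride parameters from sided gait events
#'
#' For every pair of consecutive ipsilateral ICs one stride row is
#' produced. Swing and double-support require the FCs inside the cycle; if
#' an expected event is missing the affected fields are `NA` and the stride
#' carries a reason code (stride time itself only needs the two ICs).
#' Strides overlapping a detected step gap (see [assign_foot_side()]) are
#' flagged invalid with reason `"gap"`.
#'
#' @param events sided event table; a `"gap_intervals"` attribute (as set
#'   by [assign_foot_side()]) is honoured if present.
#' @return a stride table with additional columns `valid` (logical) and
#'   `reason` (`""` when valid).
#' @export
strides_from_events <- function(events) {
  gaps <- attr(events, "gap_intervals")
  rows <- list()
  for (ft in c("left", "right")) {
    contra <- other_foot(ft)
    ic <- sort(events$time[events$kind == "IC" & events$foot == ft])
    fc <- sort(events$time[events$kind == "FC" & events$foot == ft])
    cic <- sort(events$time[events$kind == "IC" & events$foot == contra])
    cfc <- sort(events$time[events$kind == "FC" & events$foot == contra])
    if (length(ic) < 2) next
    for (i in seq_len(length(ic) - 1)) {
      t0 <- ic[i]; t1 <- ic[i + 1]
      stride_time <- t1 - t0
      swing <- NA_real_; dsupp <- NA_real_
      valid <- TRUE; reason <- ""
      my_fc <- fc[fc > t0 & fc < t1]
      c_ic <- cic[cic > t0 & cic < t1]
      c_fc <- cfc[cfc > t0 & cfc < t1]
      if (length(my_fc) != 1 || length(c_ic) != 1 || length(c_fc) != 1) {
        valid <- FALSE
        reason <- "alternation"
      } else {
        if (!(c_fc < c_ic && c_ic < my_fc)) {
          valid <- FALSE
          reason <- "phase_order"
        } else {
          swing <- t1 - my_fc
          dsupp <- (c_fc - t0) + (my_fc - c_ic)
        }
      }
      if (valid && !is.null(gaps) && nrow(gaps)) {
        overlaps <- any(gaps[, 1] < t1 & gaps[, 2] > t0)
        if (overlaps) { valid <- FALSE; reason <- "gap" }
      }
      rows[[length(rows) + 1]] <-
        data.frame(foot = ft, ic_time = t0, stride_time = stride_time,
                   swing_time = swing, dsupp_time = dsupp,
                   stride_length_cm = NA_real_, stride_width_cm = NA_real_,
                   valid = valid, reason = reason, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- stride_table()
    out$valid <- logical(); out$reason <- character()
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$ic_time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize one gait parameter over the strides of a bout
#'
#' @param strides stride table (a `valid` column, if present, restricts the
#'   summary to valid strides with a non-`NA` value of the parameter).
#' @param parameter one of `"stride_time"`, `"swing_time"`, `"dsupp_time"`,
#'   `"stride_length_cm"`, `"stride_width_cm"`.
#' @return list with `mean` (native units), `cv` (%), `asymmetry` (%),
#'   stride counts, and a character vector `flags` naming any undefined
#'   summaries (`NA` values are flagged, never silently zero). CV needs at
#'   least 2 valid strides and a positive mean; asymmetry needs at least 2
#'   valid strides per foot; if both per-foot means are zero the asymmetry
#'   is 0 by convention, if only one is zero it is undefined.
#' @export
summarize_bout <- function(strides, parameter = GAIT_PARAMETERS) {
  parameter <- match.arg(parameter)
  ok <- if ("valid" %in% names(strides)) strides$valid else
    rep(TRUE, nrow(strides))
  ok <- ok & !is.na(strides[[parameter]])
  v <- strides[[parameter]][ok]
  ft <- strides$foot[ok]
  flags <- character()
  if (!length(v)) flags <- c(flags, "no_valid_strides")
  mean_v <- if (length(v)) mean(v) else NA_real_
  cv <- NA_real_
  if (length(v) >= 2) {
    if (mean_v > 0) cv <- 100 * stats::sd(v) / mean_v
    else flags <- c(flags, "cv_undefined_nonpositive_mean")
  } else flags <- c(flags, "cv_needs_2_strides")
  asym <- NA_real_
  nL <- sum(ft == "left"); nR <- sum(ft == "right")
  if (nL >= 2 && nR >= 2) {
    mL <- mean(v[ft == "left"]); mR <- mean(v[ft == "right"])
    lo <- min(mL, mR); hi <- max(mL, mR)
    if (hi == 0 && lo == 0) {
      asym <- 0                       # both feet zero: no asymmetry
    } else if (lo <= 0) {
      flags <- c(flags, "asymmetry_undefined")  # one-sided zero / negative
    } else {
      asym <- 100 * (1 - lo / hi)
    }
  } else flags <- c(flags, "asymmetry_needs_2_strides_per_foot")
  list(parameter = parameter, mean = mean_v, cv = cv, asymmetry = asym,
       n_strides = length(v), n_left = nL, n_right = nR, flags = flags)
}

#' Summarize all gait parameters of a bout into a tidy table
#'
#' @param strides stride table.
#' @return data.frame with one row per parameter: `parameter`, `mean`,
#'   `cv`, `asymmetry`, `n_strides`.
#' @export
summarize_all <- function(strides) {
  do.call(rbind, lapply(GAIT_PARAMETERS, function(p) {
    s <- summarize_bout(strides, p)
    data.frame(parameter = p, mean = s$mean, cv = s$cv,
               asymmetry = s$asymmetry, n_strides = s$n_strides,
               stringsAsFactors = FALSE)
  }))
}

#' Join spatial predictions onto a stride table
#'
#' Predictions are keyed by `(foot, ic_time)`; each key must be unique on
#' both sides. Strides without a prediction (e.g. cycles discarded by the
#' duration gate) keep `NA` spatial fields; predictions without a stride
#' are reported in the `"unmatched_predictions"` attribute.
#'
#' @param strides stride table.
#' @param predictions data.frame with columns `foot`, `ic_time` and one or
#'   both of `stride_length_cm`, `stride_width_cm`.
#' @return the stride table with spatial fields filled where matched.
#' @export
merge_spatial <- function(strides, predictions) {
  key <- function(f, t) paste(f, sprintf("%.6f", t))
  ks <- key(strides$foot, strides$ic_time)
  kp <- key(predictions$foot, predictions$ic_time)
  if (anyDuplicated(kp) || anyDuplicated(ks))
    stop_mear("duplicate (foot, ic_time) keys in spatial merge",
              "mear_format_error")
  idx <- match(ks, kp)
  for (col in intersect(c("stride_length_cm", "stride_width_cm"),
                        names(predictions)))
    strides[[col]] <- ifelse(is.na(idx), strides[[col]],
                             predictions[[col]][idx])
  attr(strides, "unmatched_predictions") <-
    predictions[!(kp %in% ks), , drop = FALSE]
  strides
}
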