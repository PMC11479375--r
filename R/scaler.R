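# Robust standardization of the acceleration channels: remove the per-channel
# median and divide by the per-channel interquartile range, fitted once on the
# pooled samples of the training recordings and frozen afterwards. Quartiles
# use linear interpolation between order statistics (quantile type 7).

#' Fit a robust scaler on pooled training recordings
#'
#' Computes the per-channel median and interquartile range (IQR) over all
#' samples of the supplied recordings pooled together. The scaler is meant
#' to be fitted on the training split only and then reused unchanged for
#' validation, test and inference.
#'
#' @param recordings a list of [accel_recording()] objects (a single
#'   recording is also accepted).
#' @return an object of class `scaler_params`: list with numeric length-3
#'   vectors `median` and `iqr` (one entry per channel, in g).
#' @export
fit_robust_scaler <- function(recordings) {
  if (inherits(recordings, "accel_recording")) recordings <- list(recordings)
  if (!length(recordings))
    stop_mear("need at least one recording to fit the scaler",
              "mear_degenerate_error")
  pooled <- do.call(rbind, lapply(recordings, function(r) {
    stopifnot(inherits(r, "accel_recording"))
    r$samples
  }))
  med <- apply(pooled, 2, stats::median)
  q <- apply(pooled, 2, stats::quantile, probs = c(0.25, 0.75), type = 7,
             names = FALSE)
  iqr <- q[2, ] - q[1, ]
  if (any(iqr <= 0))
    stop_mear(sprintf("degenerate data: zero IQR on channel(s) %s",
                      paste(ACC_CHANNELS[iqr <= 0], collapse = ", ")),
              "mear_degenerate_error")
  structure(list(median = stats::setNames(med, ACC_CHANNELS),
                 iqr = stats::setNames(iqr, ACC_CHANNELS)),
            class = "scaler_params")
}

#' Standardize acceleration samples with fitted scaler parameters
#'
#' Applies `(x - median) / IQR` per channel and returns the samples as a
#' 3 x n channel-by-time block, the orientation consumed by the networks.
#'
#' @param x an [accel_recording()] or an n x 3 sample matrix.
#' @param params a `scaler_params` object from [fit_robust_scaler()].
#' @return numeric matrix, 3 rows (`acc_ml`, `acc_ap`, `acc_is`) x n columns.
#' @export
apply_scaler <- function(x, params) {
  stopifnot(inherits(params, "scaler_params"))
  m <- if (inherits(x, "accel_recording")) x$samples else as.matrix(x)
  if (ncol(m) != 3L)
    stop_mear("expected 3 acceleration channels", "mear_format_error")
  (t(m) - params$median) / params$iqr    # 3 x n; recycling is per column
}

#' Invert a standardization
#'
#' Reconstructs raw samples from a standardized 3 x n block; exact inverse
#' of [apply_scaler()] up to float round-off.
#'
#' @param block 3 x n standardized block.
#' @param params the `scaler_params` used to standardize.
#' @return n x 3 sample matrix in g.
#' @export
invert_scaler <- function(block, params) {
  stopifnot(inherits(params, "scaler_params"), nrow(block) == 3L)
  t(block * params$iqr + params$median)
}
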