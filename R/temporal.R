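# Temporal gait-event network: a stack of dilated-convolution blocks (conv ->
# batch norm -> ReLU -> dropout, length-preserving "same" padding, dilation
# growing exponentially with depth) followed by a position-wise fully
# connected projection to two output channels (IC, FC). The network is
# trained on BCE-with-logits against smeared event labels; a sigmoid is
# applied at inference only.

#' Configuration of the temporal event-detection network
#'
#' @param n_blocks number of dilated convolution blocks.
#' @param channels feature channels per block.
#' @param kernel convolution kernel size; must be odd so that symmetric
#'   "same" padding preserves length.
#' @param dilation_growth dilation of block `i` is `dilation_growth^(i-1)`.
#' @param dropout dropout probability inside each block.
#' @param in_channels input channels (3 acceleration axes).
#' @param out_channels output channels (2: IC and FC).
#' @param window input window length in samples.
#' @return a `temporal_config` list.
#' @export
temporal_config <- function(n_blocks = 5L, channels = 32L, kernel = 3L,
                            dilation_growth = 2L, dropout = 0.2,
                            in_channels = 3L, out_channels = 2L,
                            window = 200L) {
  if (kernel %% 2L != 1L)
    stop_mear("kernel size must be odd for length-preserving padding",
              "mear_config_error")
  if (n_blocks < 1L || channels < 1L || dilation_growth < 1L)
    stop_mear("invalid temporal model configuration", "mear_config_error")
  if (dropout < 0 || dropout >= 1)
    stop_mear("dropout must lie in [0, 1)", "mear_config_error")
  structure(list(n_blocks = as.integer(n_blocks),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 dilation_growth = as.integer(dilation_growth),
                 dropout = dropout, in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 window = as.integer(window)),
            class = "temporal_config")
}

#' Receptive field of the temporal network, in samples
#'
#' Closed form: `1 + (kernel - 1) * sum(growth^(0:(n_blocks-1)))`.
#' The default configuration (kernel 3, growth 2, 5 blocks) spans 63
#' samples = 0.63 s at 100 Hz, at least half a typical gait cycle.
#'
#' @param config a [temporal_config()].
#' @return integer receptive field in samples.
#' @export
receptive_field <- function(config) {
  dil <- config$dilation_growth^(seq_len(config$n_blocks) - 1)
  as.integer(1 + (config$kernel - 1) * sum(dil))
}

#' Build the temporal event-detection network
#'
#' @param config a [temporal_config()]. Weights are initialized from the
#'   current RNG state (seed before calling for reproducibility).
#' @return a `temporal_model` object; forward passes yield logits, see
#'   [predict_traces()] for the probability-trace inference path.
#' @export
build_temporal_model <- function(config = temporal_config()) {
  stopifnot(inherits(config, "temporal_config"))
  layers <- list()
  in_ch <- config$in_channels
  for (i in seq_len(config$n_blocks)) {
    dil <- config$dilation_growth^(i - 1)
    pad <- (config$kernel - 1L) * dil / 2L
    layers <- c(layers, list(
      layer_conv1d(in_ch, config$channels, config$kernel, dil,
                   pad = c(pad, pad)),
      layer_batchnorm(config$channels),
      layer_relu(),
      layer_dropout(config$dropout)))
    in_ch <- config$channels
  }
  # position-wise fully connected projection to the IC/FC logit channels
  layers <- c(layers, list(layer_conv1d(in_ch, config$out_channels, 1L)))
  structure(list(config = config, layers = layers, scaler = NULL),
            class = "temporal_model")
}

temporal_forward <- function(model, x, training = FALSE) {
  seq_forward(model$layers, ctb(x), training)
}

#' Slice a recording into fixed-length analysis windows
#'
#' Windows of `window` samples are taken every `hop` samples; when the
#' length is not a multiple of the hop, a final right-aligned window is
#' appended so the whole recording is covered.
#'
#' @param x an [accel_recording()] or a 3 x n channel-by-time block.
#' @param window window length in samples.
#' @param hop hop between window starts in samples.
#' @return list with `blocks` (3 x window x n_windows array) and `offsets`
#'   (0-based sample offsets of each window).
#' @export
make_windows <- function(x, window = 200L, hop = 100L) {
  block <- if (inherits(x, "accel_recording")) t(x$samples) else as.matrix(x)
  n <- ncol(block)
  if (n < window)
    stop_mear(sprintf("recording too short: %d samples < window of %d",
                      n, window), "mear_length_error")
  offsets <- seq(0L, n - window, by = hop)
  if (offsets[length(offsets)] != n - window)
    offsets <- c(offsets, n - window)
  blocks <- array(0, c(nrow(block), window, length(offsets)))
  for (i in seq_along(offsets))
    blocks[, , i] <- block[, offsets[i] + seq_len(window)]
  list(blocks = blocks, offsets = as.integer(offsets), window = window)
}

#' Build per-sample training targets for one window
#'
#' Each event inside the window contributes a Gaussian bump (peak exactly 1
#' at the event sample, standard deviation `sigma` samples, truncated at
#' `truncate * sigma`) on its channel (row 1: IC, row 2: FC); overlapping
#' bumps are combined by the pointwise maximum, so targets stay in `[0, 1]`.
#'
#' @param events event table ([gait_events()]).
#' @param t0 time of the window's first sample, seconds.
#' @param window window length in samples.
#' @param fs sampling rate, Hz.
#' @param sigma bump standard deviation in samples.
#' @param truncate bump support half-width in multiples of `sigma`.
#' @return a 2 x `window` matrix of targets in `[0, 1]`.
#' @export
make_label_traces <- function(events, t0, window = 200L, fs = 100,
                              sigma = 5, truncate = 4) {
  y <- matrix(0, 2L, window)
  half <- ceiling(truncate * sigma)
  for (i in seq_len(nrow(events))) {
    s <- round((events$time[i] - t0) * fs)  # 0-based sample of the event
    if (s < -half || s > window - 1 + half) next
    ks <- max(0, s - half):min(window - 1, s + half)
    if (!length(ks)) next
    row <- if (events$kind[i] == "IC") 1L else 2L
    bump <- exp(-((ks - s)^2) / (2 * sigma^2))
    y[row, ks + 1] <- pmax(y[row, ks + 1], bump)
  }
  y
}

#' Score a recording into per-sample IC/FC probability traces
#'
#' The recording is standardized, cut into 50%-overlapping windows, each
#' window is scored by the network (evaluation mode: dropout off, batch
#' norm on running statistics), sigmoid probabilities of overlapping
#' windows are averaged per sample, and the result is aligned to the
#' recording time base.
#'
#' @param model a trained `temporal_model`.
#' @param recording an [accel_recording()] of at least `window` samples.
#' @param scaler `scaler_params`; defaults to the scaler stored in the model.
#' @param hop hop between windows in samples (default 50% overlap).
#' @return an `event_trace`: list with `t0`, `fs` and a 2 x n probability
#'   matrix `p` (row 1: IC, row 2: FC), values in `[0, 1]`.
#' @export
predict_traces <- function(model, recording, scaler = model$scaler,
                           hop = 100L) {
  stopifnot(inherits(model, "temporal_model"))
  if (is.null(scaler))
    stop_mear("no scaler: pass one or train the model first",
              "mear_config_error")
  block <- apply_scaler(recording, scaler)
  w <- make_windows(block, model$config$window, hop)
  nw <- dim(w$blocks)[3]
  logits <- temporal_forward(model, w$blocks, training = FALSE)$y
  probs <- sigmoid(logits)
  n <- ncol(block)
  acc <- matrix(0, 2L, n)
  cnt <- numeric(n)
  for (i in seq_len(nw)) {
    cols <- w$offsets[i] + seq_len(w$window)
    acc[, cols] <- acc[, cols] + probs[, , i]
    cnt[cols] <- cnt[cols] + 1
  }
  structure(list(t0 = recording$t0, fs = recording$sample_rate,
                 p = acc / rep(cnt, each = 2L)),
            class = "event_trace")
}

#' Extract discrete gait events from a probability trace
#'
#' Takes local maxima of each channel above `threshold`; within any
#' `refractory` span only the highest peak survives (ties broken toward
#' the earlier sample). Event times are `t0 + sample / fs`; the foot side
#' is left `"unknown"` (see [assign_foot_side()]).
#'
#' @param trace an `event_trace` from [predict_traces()].
#' @param threshold minimum peak probability.
#' @param refractory minimum spacing between retained events of one
#'   channel, seconds.
#' @return event table ([gait_events()]) with `foot = "unknown"`.
#' @export
extract_events <- function(trace, threshold = 0.5, refractory = 0.30) {
  stopifnot(inherits(trace, "event_trace"))
  refr <- round(refractory * trace$fs)
  one_channel <- function(p) {
    n <- length(p)
    if (n < 2) return(integer())
    is_peak <- logical(n)
    is_peak[1] <- p[1] > p[2]
    is_peak[n] <- p[n] > p[n - 1]
    if (n > 2) {
      i <- 2:(n - 1)
      is_peak[i] <- p[i] > p[i - 1] & p[i] >= p[i + 1]
    }
    cand <- which(is_peak & p > threshold)
    if (!length(cand)) return(integer())
    cand <- cand[order(-p[cand], cand)]  # tallest first, earlier wins ties
    kept <- integer()
    for (s in cand)
      if (!length(kept) || all(abs(kept - s) >= refr)) kept <- c(kept, s)
    sort(kept)
  }
  ic <- one_channel(trace$p[1, ])
  fc <- one_channel(trace$p[2, ])
  gait_events(time = trace$t0 + (c(ic, fc) - 1) / trace$fs,
              kind = c(rep("IC", length(ic)), rep("FC", length(fc))),
              foot = rep("unknown", length(ic) + length(fc)))
}

other_foot <- function(f) ifelse(f == "left", "right", "left")

#' Assign foot sides to side-agnostic detected events
#'
#' ICs are assigned alternately left/right in time order; the anchor side
#' of the first IC follows the configured convention (default: the foot
#' ipsilateral to the sensor ear). FCs alternate as well; their anchor is
#' the first FC, sided contralateral to its nearest preceding IC per
#' normal gait phasing (the FC of foot X falls between the contralateral
#' IC and the next ipsilateral IC). Alternation also sides trailing FCs
#' that no longer have a following IC for context.
#'
#' A step gap (an IC-to-IC interval exceeding `gap_factor` times the median
#' interval, i.e. a probable missed step) does not drop events; the gap
#' interval is recorded in the `"gap_intervals"` attribute so that
#' [strides_from_events()] can flag strides spanning it as invalid.
#'
#' @param events event table with `foot = "unknown"`.
#' @param ear_side which ear carried the sensor (`"left"`/`"right"`).
#' @param anchor `"ipsilateral"` (default) or `"contralateral"`: side
#'   assigned to the first IC relative to `ear_side`. Side-agnostic
#'   summaries are invariant under this choice; sided ones may be globally
#'   swapped.
#' @param gap_factor multiple of the median IC interval above which an
#'   interval is flagged as a gap.
#' @return sided event table with attribute `"gap_intervals"` (2-column
#'   matrix of gap start/end times, possibly 0 rows).
#' @export
assign_foot_side <- function(events, ear_side, anchor = c("ipsilateral",
                                                          "contralateral"),
                             gap_factor = 1.8) {
  anchor <- match.arg(anchor)
  ear_side <- match.arg(ear_side, EAR_SIDES)
  first_side <- if (anchor == "ipsilateral") ear_side else other_foot(ear_side)
  ic_idx <- which(events$kind == "IC")
  fc_idx <- which(events$kind == "FC")
  ic_t <- events$time[ic_idx]
  sides <- rep(c(first_side, other_foot(first_side)),
               length.out = length(ic_idx))
  out <- events
  out$foot[ic_idx] <- sides
  if (length(fc_idx)) {
    # anchor the first FC on its nearest preceding IC (normal phasing:
    # an FC follows the contralateral IC), then alternate -- FCs alternate
    # feet just as ICs do, and alternation also sides the trailing FCs
    # that have no later IC context
    fc_t <- events$time[fc_idx]
    prev <- which(ic_t < fc_t[1])
    first_fc_side <- if (length(prev)) other_foot(sides[max(prev)])
                     else first_side
    out$foot[fc_idx] <- rep(c(first_fc_side, other_foot(first_fc_side)),
                            length.out = length(fc_idx))
  }
  gaps <- matrix(numeric(), 0, 2, dimnames = list(NULL, c("start", "end")))
  if (length(ic_t) >= 3) {
    d <- diff(ic_t)
    bad <- which(d > gap_factor * stats::median(d))
    if (length(bad))
      gaps <- cbind(start = ic_t[bad], end = ic_t[bad + 1])
  }
  attr(out, "gap_intervals") <- gaps
  attr(out, "anchor") <- anchor
  out
}
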