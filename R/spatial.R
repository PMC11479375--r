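# Spatial stride-characteristic networks: causal residual TCNs that regress
# a single scalar (stride length or stride width, cm) from the acceleration
# spanning one gait cycle. Each residual block holds two dilated causal
# convolutions (padding followed by chomping, so no activation ever sees the
# future), each followed by ReLU and dropout, plus an additive bypass (a 1x1
# convolution where channel counts differ). The block stack feeds a temporal
# average-pooling layer and a final linear map to one output.

#' Configuration of a spatial stride-regression network
#'
#' @param n_blocks number of residual blocks.
#' @param channels feature channels per block.
#' @param kernel convolution kernel size.
#' @param dilation_growth dilation of block `i` is `dilation_growth^(i-1)`.
#' @param dropout dropout probability after each convolution.
#' @param in_channels input channels (3 acceleration axes).
#' @param use_duration if `TRUE`, the original (pre-resampling) cycle
#'   duration is appended as an auxiliary scalar input to the linear head.
#'   Off by default; the resampled waveform alone carries the signal.
#' @param window fixed input length after cycle resampling, samples.
#' @return a `spatial_config` list.
#' @export
spatial_config <- function(n_blocks = 3L, channels = 16L, kernel = 3L,
                           dilation_growth = 2L, dropout = 0.1,
                           in_channels = 3L, use_duration = FALSE,
                           window = 200L) {
  if (n_blocks < 1L || channels < 1L || kernel < 1L || dilation_growth < 1L)
    stop_mear("invalid spatial model configuration", "mear_config_error")
  if (dropout < 0 || dropout >= 1)
    stop_mear("dropout must lie in [0, 1)", "mear_config_error")
  structure(list(n_blocks = as.integer(n_blocks),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 dilation_growth = as.integer(dilation_growth),
                 dropout = dropout, in_channels = as.integer(in_channels),
                 use_duration = isTRUE(use_duration),
                 window = as.integer(window)),
            class = "spatial_config")
}

causal_conv_layers <- function(in_ch, out_ch, kernel, dilation, dropout) {
  overhang <- (kernel - 1L) * dilation
  list(layer_conv1d(in_ch, out_ch, kernel, dilation,
                    pad = c(overhang, overhang)),
       layer_chomp(overhang),     # drop the future-looking overhang
       layer_relu(),
       layer_dropout(dropout))
}

make_resblock <- function(in_ch, out_ch, kernel, dilation, dropout) {
  main <- c(causal_conv_layers(in_ch, out_ch, kernel, dilation, dropout),
            causal_conv_layers(out_ch, out_ch, kernel, dilation, dropout))
  down <- if (in_ch != out_ch) layer_conv1d(in_ch, out_ch, 1L) else NULL
  list(main = main, down = down)
}

# m is a (C x T*B) activation matrix with shape descriptor tb = c(T, B);
# causal blocks preserve T, so the skip path always shape-matches.
resblock_forward <- function(block, m, tb, training) {
  main <- seq_forward_mat(block$main, m, tb, training)
  if (is.null(block$down)) {
    skip <- m
    down_cache <- NULL
  } else {
    d <- conv1d_forward(block$down, m, tb)
    skip <- d$y
    down_cache <- d$cache
  }
  list(y = main$y + skip, tb = main$tb,
       cache = list(main = main$caches, down = down_cache))
}

resblock_backward <- function(block, dm, cache) {
  main <- seq_backward_mat(block$main, cache$main, dm)
  if (is.null(block$down)) {
    dx <- main$dx + dm
    down_grads <- NULL
  } else {
    d <- conv1d_backward(block$down, dm, cache$down)
    dx <- main$dx + d$dx
    down_grads <- d$grads
  }
  list(dx = dx, grads = list(main = main$grads, down = down_grads))
}

#' Build a spatial stride-regression network
#'
#' @param config a [spatial_config()]. Weights are initialized from the
#'   current RNG state.
#' @return a `spatial_model`. The target standardization slots
#'   (`target_mean`, `target_sd`) are filled by [train_spatial()]; until
#'   then predictions are on the standardized scale.
#' @export
build_spatial_model <- function(config = spatial_config()) {
  stopifnot(inherits(config, "spatial_config"))
  blocks <- list()
  in_ch <- config$in_channels
  for (i in seq_len(config$n_blocks)) {
    dil <- config$dilation_growth^(i - 1)
    blocks[[i]] <- make_resblock(in_ch, config$channels, config$kernel, dil,
                                 config$dropout)
    in_ch <- config$channels
  }
  n_aux <- 1L + as.integer(config$use_duration)  # foot side (+ duration)
  head_in <- config$channels + n_aux
  head <- list(W = matrix(stats::rnorm(head_in, sd = sqrt(1 / head_in)),
                          1, head_in),
               b = 0)
  structure(list(config = config, blocks = blocks, head = head,
                 target_mean = 0, target_sd = 1, scaler = NULL,
                 duration_scale = 1, calibration = c(0, 1)),
            class = "spatial_model")
}

spatial_params_get <- function(model) {
  list(blocks = lapply(model$blocks, function(b)
         list(main = params_get(b$main),
              down = if (!is.null(b$down)) b$down$params)),
       head = model$head)
}

spatial_params_set <- function(model, params) {
  for (i in seq_along(model$blocks)) {
    model$blocks[[i]]$main <- params_set(model$blocks[[i]]$main,
                                         params$blocks[[i]]$main)
    if (!is.null(model$blocks[[i]]$down))
      model$blocks[[i]]$down$params <- params$blocks[[i]]$down
  }
  model$head <- params$head
  model
}

# x: (3, T, B); aux: (n_aux, B) matrix. Returns standardized-scale outputs
# (length-B vector) plus caches for the backward pass.
spatial_forward <- function(model, x, aux, training = FALSE) {
  s <- as_mat(ctb(x))
  m <- s$m; tb <- s$tb
  caches <- vector("list", length(model$blocks))
  for (i in seq_along(model$blocks)) {
    out <- resblock_forward(model$blocks[[i]], m, tb, training)
    m <- out$y
    tb <- out$tb
    caches[[i]] <- out$cache
  }
  grp <- rep(seq_len(tb[2]), each = tb[1])
  pooled <- t(rowsum(t(m), grp)) / tb[1]                 # (C, B) temporal mean
  feats <- rbind(pooled, aux)
  z <- as.vector(model$head$W %*% feats + model$head$b)
  list(y = z, caches = caches, feats = feats, tb = tb)
}

spatial_backward <- function(model, fwd, dz) {
  # dz: length-B gradient on the scalar outputs
  B <- length(dz)
  dW <- matrix(dz, 1, B) %*% t(fwd$feats)
  db <- sum(dz)
  dfeats <- crossprod(model$head$W, matrix(dz, 1, B))   # (C + n_aux, B)
  C <- model$config$channels
  T_len <- fwd$tb[1]
  dpool <- dfeats[seq_len(C), , drop = FALSE] / T_len
  dm <- dpool[, rep(seq_len(B), each = T_len), drop = FALSE]
  grads_blocks <- vector("list", length(model$blocks))
  for (i in rev(seq_along(model$blocks))) {
    out <- resblock_backward(model$blocks[[i]], dm, fwd$caches[[i]])
    dm <- out$dx
    grads_blocks[[i]] <- out$grads
  }
  list(grads = list(blocks = grads_blocks, head = list(W = dW, b = db)),
       dx = dm)
}

spatial_update_buffers <- function(model, fwd) model  # no batch norm in sTCN

foot_code_num <- function(foot) ifelse(foot == "left", -0.5, 0.5)

segment_aux <- function(model, segments) {
  aux <- matrix(foot_code_num(vapply(segments, `[[`, character(1), "foot")),
                1, length(segments))
  if (model$config$use_duration)
    aux <- rbind(aux, vapply(segments, `[[`, numeric(1), "duration") /
                   model$duration_scale)
  aux
}

segments_block <- function(segments) {
  window <- ncol(segments[[1]]$x)
  x <- array(0, c(3L, window, length(segments)))
  for (i in seq_along(segments)) x[, , i] <- segments[[i]]$x
  x
}

#' Extract standardized, fixed-length gait-cycle segments
#'
#' For each pair of consecutive ipsilateral ICs, the raw acceleration
#' between them is standardized with `scaler` and linearly resampled to
#' `out_len` samples. Cycles whose duration falls outside
#' `[min_dur, max_dur]` (outside the human walking range; also protects the
#' resampler) are discarded and counted in the `"n_discarded"` attribute.
#'
#' @param recording an [accel_recording()].
#' @param events sided event table; only `IC` rows with a known foot are
#'   used.
#' @param scaler `scaler_params` fitted on the training split.
#' @param out_len fixed segment length after resampling.
#' @param min_dur,max_dur plausibility gate on cycle duration, seconds.
#' @return list of `gait_cycle_segment`s: each a list with `x` (3 x
#'   `out_len` standardized block), `foot`, `ic_time`, `duration`. Fewer
#'   than two ipsilateral ICs yields an empty list.
#' @export
extract_gait_cycles <- function(recording, events, scaler, out_len = 200L,
                                min_dur = 0.5, max_dur = 4) {
  block <- apply_scaler(recording, scaler)
  n <- ncol(block)
  fs <- recording$sample_rate
  segments <- list()
  n_discarded <- 0L
  for (ft in c("left", "right")) {
    ics <- sort(events$time[events$kind == "IC" & events$foot == ft])
    if (length(ics) < 2) next
    for (i in seq_len(length(ics) - 1)) {
      dur <- ics[i + 1] - ics[i]
      i0 <- round((ics[i] - recording$t0) * fs) + 1
      i1 <- round((ics[i + 1] - recording$t0) * fs)
      if (dur < min_dur || dur > max_dur || i0 < 1 || i1 > n || i1 <= i0) {
        n_discarded <- n_discarded + 1L
        next
      }
      seg <- block[, i0:i1, drop = FALSE]
      segments[[length(segments) + 1]] <-
        structure(list(x = resample_block(seg, out_len), foot = ft,
                       ic_time = ics[i], duration = dur),
                  class = "gait_cycle_segment")
    }
  }
  attr(segments, "n_discarded") <- n_discarded
  segments
}

# linear resampling of a (C x L) block to (C x out_len)
resample_block <- function(seg, out_len) {
  L <- ncol(seg)
  if (L == out_len) return(seg)
  x_in <- seq(0, 1, length.out = L)
  x_out <- seq(0, 1, length.out = out_len)
  t(apply(seg, 1, function(ch) stats::approx(x_in, ch, x_out)$y))
}

#' Predict a stride scalar (cm) for gait-cycle segments
#'
#' Runs the network in evaluation mode (deterministic) and de-standardizes
#' the output with the target scaling fitted during training.
#'
#' @param model a `spatial_model`.
#' @param segments a list of segments from [extract_gait_cycles()] (a
#'   single segment is also accepted).
#' @return numeric vector of predictions in cm (one per segment).
#' @export
predict_stride_scalar <- function(model, segments) {
  stopifnot(inherits(model, "spatial_model"))
  if (inherits(segments, "gait_cycle_segment")) segments <- list(segments)
  if (!length(segments)) return(numeric())
  x <- segments_block(segments)
  aux <- segment_aux(model, segments)
  z <- spatial_forward(model, x, aux, training = FALSE)$y
  raw <- z * model$target_sd + model$target_mean
  cal <- model$calibration %||% c(0, 1)
  cal[1] + cal[2] * raw
}
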