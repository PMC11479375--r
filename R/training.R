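# Training protocol: subject-level ("group") splitting so no individual
# contributes to more than one partition, k-fold cross-validation over the
# training subjects, grid search over batch size / learning rate / epochs,
# BCE-with-logits for the event network and MSE (on z-scored targets) for
# the stride regressors, both optimized with Adam. Within each run the
# epoch with the lowest validation loss supplies the returned weights.

#' Subject-level train/test/k-fold split plan
#'
#' Splits subjects (never bouts) into a test set and `k` cross-validation
#' folds of the remaining subjects, stratifying on each subject's
#' speed-condition bout counts as far as subject-level assignment allows.
#' Every non-test subject validates in exactly one fold.
#'
#' @param manifest cohort manifest (columns `bout_id`, `subject_id`,
#'   `speed_condition`).
#' @param test_fraction fraction of subjects held out for the test set.
#' @param k number of cross-validation folds.
#' @param seed RNG seed for the (stratified) shuffle.
#' @return a `split_plan`: list with `test` (subject ids) and `folds`
#'   (list of `k` lists with `train` / `val` subject ids).
#' @export
make_split_plan <- function(manifest, test_fraction = 0.2, k = 5, seed = 1) {
  subjects <- unique(manifest$subject_id)
  n <- length(subjects)
  n_test <- max(1L, round(test_fraction * n))
  if (n - n_test < k)
    stop_mear(sprintf(
      "too few subjects: %d leaves %d for %d folds after the test split",
      n, n - n_test, k), "mear_config_error")
  # stratum = the subject's speed-condition bout-count signature
  sig <- vapply(subjects, function(s) {
    paste(table(factor(manifest$speed_condition[manifest$subject_id == s],
                       levels = SPEED_LEVELS)), collapse = "/")
  }, character(1))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # interleave strata so test and folds draw evenly from each
  by_sig <- split(subjects[order(sig)], sort(sig))
  by_sig <- lapply(by_sig, sample)
  ordered <- character()
  while (any(lengths(by_sig) > 0)) {
    for (g in seq_along(by_sig)) {
      if (length(by_sig[[g]])) {
        ordered <- c(ordered, by_sig[[g]][1])
        by_sig[[g]] <- by_sig[[g]][-1]
      }
    }
  }
  test <- ordered[seq_len(n_test)]
  rest <- ordered[-seq_len(n_test)]
  fold_of <- rep(seq_len(k), length.out = length(rest))
  folds <- lapply(seq_len(k), function(f)
    list(train = rest[fold_of != f], val = rest[fold_of == f]))
  plan <- structure(list(test = test, folds = folds, k = k, seed = seed),
                    class = "split_plan")
  validate_split_plan(plan)
  plan
}

validate_split_plan <- function(plan) {
  all_val <- unlist(lapply(plan$folds, `[[`, "val"))
  if (anyDuplicated(all_val))
    stop_mear("a subject validates in more than one fold", "mear_config_error")
  for (f in plan$folds) {
    if (length(intersect(plan$test, c(f$train, f$val))))
      stop_mear("test subjects leak into a fold", "mear_config_error")
    if (length(intersect(f$train, f$val)))
      stop_mear("fold train and validation overlap", "mear_config_error")
  }
  invisible(plan)
}

#' Map each subject to its partition (leakage check helper)
#'
#' @param plan a `split_plan`.
#' @return named character vector: subject id -> `"test"` or `"fold<i>"`
#'   (the fold in which the subject validates).
#' @export
plan_partition <- function(plan) {
  out <- stats::setNames(rep("test", length(plan$test)), plan$test)
  for (i in seq_along(plan$folds))
    out[plan$folds[[i]]$val] <- sprintf("fold%d", i)
  out
}

## ---- dataset builders ------------------------------------------------------

#' Build windowed training data for the temporal network
#'
#' Slices each bout into standardized windows (see [make_windows()]) and
#' pairs every window with its smeared IC/FC label traces.
#'
#' @param bouts list of [walk_bout()]s with ground-truth events.
#' @param scaler `scaler_params` fitted on the training recordings.
#' @param window,hop windowing geometry in samples.
#' @param sigma label bump width in samples ([make_label_traces()]).
#' @return list with `x` (3 x window x N), `y` (2 x window x N), `subject`
#'   (length-N character).
#' @export
temporal_training_data <- function(bouts, scaler, window = 200L, hop = 100L,
                                   sigma = 5) {
  xs <- list(); ys <- list(); subj <- character()
  for (bout in bouts) {
    rec <- bout$recording
    block <- apply_scaler(rec, scaler)
    w <- make_windows(block, window, hop)
    nw <- length(w$offsets)
    lab <- array(0, c(2L, window, nw))
    for (i in seq_len(nw))
      lab[, , i] <- make_label_traces(bout$events,
                                      t0 = rec$t0 + w$offsets[i] / rec$sample_rate,
                                      window = window, fs = rec$sample_rate,
                                      sigma = sigma)
    xs[[length(xs) + 1]] <- w$blocks
    ys[[length(ys) + 1]] <- lab
    subj <- c(subj, rep(rec$subject_id, nw))
  }
  n_total <- length(subj)
  x <- array(0, c(3L, window, n_total))
  y <- array(0, c(2L, window, n_total))
  at <- 0L
  for (i in seq_along(xs)) {
    nw <- dim(xs[[i]])[3]
    x[, , at + seq_len(nw)] <- xs[[i]]
    y[, , at + seq_len(nw)] <- ys[[i]]
    at <- at + nw
  }
  list(x = x, y = y, subject = subj)
}

#' Build gait-cycle regression data for a spatial network
#'
#' Extracts ground-truth gait cycles from each bout and pairs each with
#' its stride target (length or width, cm); cycles without a target are
#' dropped.
#'
#' @param bouts list of [walk_bout()]s with ground-truth events/strides.
#' @param scaler `scaler_params`.
#' @param target `"stride_length_cm"` or `"stride_width_cm"`.
#' @param config [spatial_config()] (for the resampling length).
#' @return list with `segments` (list), `y` (cm), `subject`.
#' @export
spatial_training_data <- function(bouts, scaler,
                                  target = c("stride_length_cm",
                                             "stride_width_cm"),
                                  config = spatial_config()) {
  target <- match.arg(target)
  segments <- list(); y <- numeric(); subj <- character()
  for (bout in bouts) {
    segs <- extract_gait_cycles(bout$recording, bout$events, scaler,
                                out_len = config$window)
    if (!length(segs)) next
    key <- paste(bout$strides$foot, sprintf("%.6f", bout$strides$ic_time))
    for (s in segs) {
      i <- match(paste(s$foot, sprintf("%.6f", s$ic_time)), key)
      if (is.na(i) || is.na(bout$strides[[target]][i])) next
      segments[[length(segments) + 1]] <- s
      y <- c(y, bout$strides[[target]][i])
      subj <- c(subj, bout$recording$subject_id)
    }
  }
  list(segments = segments, y = y, subject = subj)
}

## ---- training loops --------------------------------------------------------

# standardized -> raw -> random 3D rotation -> standardized, folded into a
# single affine map on the channel dimension; one independent rotation per
# batch element for augmentation diversity
augment_rotation <- function(xb, scaler, deg) {
  d <- dim(xb)
  out <- xb
  for (i in seq_len(d[3])) {
    R <- rot3(stats::rnorm(3, 0, deg))
    A <- (1 / scaler$iqr) * R * rep(scaler$iqr, each = 3)
    b <- (R %*% scaler$median - scaler$median) / scaler$iqr
    out[, , i] <- A %*% xb[, , i] + as.vector(b)
  }
  out
}

check_finite_loss <- function(loss, where) {
  if (!is.finite(loss))
    stop_mear(sprintf("non-finite loss (%g) during %s: try a lower learning rate",
                      loss, where), "mear_training_error")
}

#' Train the temporal event-detection network
#'
#' Minimizes BCE-with-logits over the label traces with Adam; the weights
#' of the epoch with the lowest validation loss are returned. Fully
#' deterministic given `seed`.
#'
#' @param data from [temporal_training_data()].
#' @param train_subjects,val_subjects subject ids of the two partitions;
#'   with no validation subjects the training loss drives model selection.
#' @param config [temporal_config()].
#' @param epochs,batch_size,lr optimization hyperparameters.
#' @param seed RNG seed covering weight init, shuffling and dropout.
#' @param scaler optional `scaler_params` to embed in the trained model
#'   (required when `augment_rotation_deg > 0`).
#' @param augment_rotation_deg orientation augmentation as in
#'   [train_spatial()]: random raw-space 3D rotations per training batch
#'   so event detection generalizes across sensor orientations; 0
#'   disables.
#' @return list with `model` (a `temporal_model`) and `history`
#'   (data.frame: epoch, train_loss, val_loss).
#' @export
train_temporal <- function(data, train_subjects, val_subjects = character(),
                           config = temporal_config(), epochs = 30,
                           batch_size = 64, lr = 1e-3, seed = 1,
                           scaler = NULL, augment_rotation_deg = 10) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  model <- build_temporal_model(config)
  idx_tr <- which(data$subject %in% train_subjects)
  idx_val <- which(data$subject %in% val_subjects)
  if (!length(idx_tr))
    stop_mear("no training windows for the given subjects",
              "mear_config_error")
  if (augment_rotation_deg > 0 && is.null(scaler))
    stop_mear("rotation augmentation needs the scaler", "mear_config_error")
  params <- params_get(model$layers)
  state <- adam_init(params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = params, layers = model$layers)

  eval_loss <- function(idx) {
    if (!length(idx)) return(NA_real_)
    tot <- 0
    for (chunk in split(idx, ceiling(seq_along(idx) / 256))) {
      fw <- seq_forward(model$layers, data$x[, , chunk, drop = FALSE],
                        training = FALSE)
      tot <- tot + bce_with_logits(fw$y,
                                   data$y[, , chunk, drop = FALSE])$loss *
        length(chunk)
    }
    tot / length(idx)
  }

  for (ep in seq_len(epochs)) {
    perm <- sample(idx_tr)
    batch_losses <- numeric()
    for (batch in split(perm, ceiling(seq_along(perm) / batch_size))) {
      xb <- data$x[, , batch, drop = FALSE]
      if (augment_rotation_deg > 0)
        xb <- augment_rotation(xb, scaler, augment_rotation_deg)
      yb <- data$y[, , batch, drop = FALSE]
      fw <- seq_forward(model$layers, xb, training = TRUE)
      model$layers <- seq_update_buffers(model$layers, fw$caches)
      l <- bce_with_logits(fw$y, yb)
      check_finite_loss(l$loss, "temporal training")
      batch_losses <- c(batch_losses, l$loss)
      bw <- seq_backward(model$layers, fw$caches, l$dz)
      upd <- adam_step(params, bw$grads, state, lr)
      params <- upd$params
      state <- upd$state
      model$layers <- params_set(model$layers, params)
    }
    val <- eval_loss(idx_val)
    sel <- if (is.na(val)) mean(batch_losses) else val
    if (sel < best$loss)
      best <- list(loss = sel, params = params, layers = model$layers)
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = mean(batch_losses),
                                         val_loss = val))
  }
  model$layers <- best$layers
  model$scaler <- scaler
  list(model = model, history = history, best_val_loss = best$loss)
}

#' Train a spatial stride-regression network
#'
#' Minimizes MSE on z-scored targets (standardization fitted on the
#' training subjects, stored in the model and undone at prediction time).
#'
#' @param data from [spatial_training_data()].
#' @param train_subjects,val_subjects subject ids of the two partitions.
#' @param config [spatial_config()].
#' @param epochs,batch_size,lr optimization hyperparameters.
#' @param seed RNG seed.
#' @param scaler optional `scaler_params` to embed in the model (required
#'   when `augment_rotation_deg > 0`).
#' @param augment_rotation_deg orientation augmentation: per training
#'   batch, the raw-space acceleration is rotated by a random 3D rotation
#'   with per-axis angles drawn from N(0, this many degrees) before
#'   re-standardization. Teaches the regressor rotation-invariant features
#'   so it generalizes across sensor orientations ("ear anatomies") unseen
#'   during training; 0 disables.
#' @return list with `model` (a `spatial_model`), `history`,
#'   `best_val_loss` (standardized-scale MSE).
#' @export
train_spatial <- function(data, train_subjects, val_subjects = character(),
                          config = spatial_config(), epochs = 30,
                          batch_size = 64, lr = 1e-3, seed = 1,
                          scaler = NULL, augment_rotation_deg = 10) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  model <- build_spatial_model(config)
  idx_tr <- which(data$subject %in% train_subjects)
  idx_val <- which(data$subject %in% val_subjects)
  if (!length(idx_tr))
    stop_mear("no training cycles for the given subjects",
              "mear_config_error")
  model$target_mean <- mean(data$y[idx_tr])
  model$target_sd <- stats::sd(data$y[idx_tr])
  if (!is.finite(model$target_sd) || model$target_sd == 0)
    model$target_sd <- 1        # constant targets: plain centering
  ystd <- (data$y - model$target_mean) / model$target_sd
  x_all <- segments_block(data$segments)
  aux_all <- segment_aux(model, data$segments)
  if (augment_rotation_deg > 0 && is.null(scaler))
    stop_mear("rotation augmentation needs the scaler", "mear_config_error")

  params <- spatial_params_get(model)
  state <- adam_init(params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = params)

  eval_loss <- function(idx) {
    if (!length(idx)) return(NA_real_)
    tot <- 0
    for (chunk in split(idx, ceiling(seq_along(idx) / 512))) {
      z <- spatial_forward(model, x_all[, , chunk, drop = FALSE],
                           aux_all[, chunk, drop = FALSE],
                           training = FALSE)$y
      tot <- tot + mse_loss(z, ystd[chunk])$loss * length(chunk)
    }
    tot / length(idx)
  }

  for (ep in seq_len(epochs)) {
    perm <- sample(idx_tr)
    batch_losses <- numeric()
    for (batch in split(perm, ceiling(seq_along(perm) / batch_size))) {
      xb <- x_all[, , batch, drop = FALSE]
      if (augment_rotation_deg > 0)
        xb <- augment_rotation(xb, scaler, augment_rotation_deg)
      fw <- spatial_forward(model, xb,
                            aux_all[, batch, drop = FALSE], training = TRUE)
      l <- mse_loss(fw$y, ystd[batch])
      check_finite_loss(l$loss, "spatial training")
      batch_losses <- c(batch_losses, l$loss)
      bw <- spatial_backward(model, fw, l$dpred)
      upd <- adam_step(params, bw$grads, state, lr)
      params <- upd$params
      state <- upd$state
      model <- spatial_params_set(model, params)
    }
    val <- eval_loss(idx_val)
    sel <- if (is.na(val)) mean(batch_losses) else val
    if (sel < best$loss) best <- list(loss = sel, params = params)
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = mean(batch_losses),
                                         val_loss = val))
  }
  model <- spatial_params_set(model, best$params)
  model$scaler <- scaler
  list(model = model, history = history, best_val_loss = best$loss)
}

#' Cross-validated grid search over batch size, learning rate and epochs
#'
#' Trains every grid point on every fold of the plan, averages the
#' best-epoch validation losses, and returns the argmin; ties break toward
#' smaller batch, then lower learning rate, then fewer epochs.
#'
#' @param grid list with non-empty numeric vectors `batch_size`, `lr`,
#'   `epochs`.
#' @param data training data (passed through to `train_fn`).
#' @param plan a `split_plan` whose folds define the CV partitions.
#' @param train_fn function `(data, train_subjects, val_subjects,
#'   batch_size, lr, epochs, seed) -> list(best_val_loss = ...)`; wrap
#'   [train_temporal()] / [train_spatial()] or inject a stub.
#' @param seed base seed; each (grid point, fold) trains with a derived
#'   substream.
#' @return list with `best` (row of the grid), `cv_table` (one row per
#'   grid point x fold).
#' @export
grid_search <- function(grid, data, plan, train_fn, seed = 1) {
  for (nm in c("batch_size", "lr", "epochs"))
    if (!length(grid[[nm]]))
      stop_mear(sprintf("grid axis '%s' is empty", nm), "mear_config_error")
  points <- expand.grid(batch_size = grid$batch_size, lr = grid$lr,
                        epochs = grid$epochs, KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (gi in seq_len(nrow(points))) {
    for (f in seq_along(plan$folds)) {
      fold <- plan$folds[[f]]
      res <- train_fn(data, fold$train, fold$val,
                      batch_size = points$batch_size[gi], lr = points$lr[gi],
                      epochs = points$epochs[gi],
                      seed = derive_seed(seed, gi, f))
      rows[[length(rows) + 1]] <-
        data.frame(batch_size = points$batch_size[gi], lr = points$lr[gi],
                   epochs = points$epochs[gi], fold = f,
                   val_loss = res$best_val_loss)
    }
  }
  cv_table <- do.call(rbind, rows)
  agg <- stats::aggregate(val_loss ~ batch_size + lr + epochs, cv_table, mean)
  agg <- agg[order(agg$val_loss, agg$batch_size, agg$lr, agg$epochs), ]
  list(best = agg[1, c("batch_size", "lr", "epochs")], cv_table = cv_table,
       cv_means = agg)
}

#' Default hyperparameter grid
#'
#' Mirrors the three searched axes (batch size, learning rate, epochs).
#' @return list of candidate vectors.
#' @export
default_grid <- function() {
  list(batch_size = c(32, 64, 128), lr = c(1e-4, 1e-3, 1e-2),
       epochs = c(30, 50, 100))
}
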