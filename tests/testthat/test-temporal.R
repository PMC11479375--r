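test_that("windowing covers recordings with a right-aligned tail", {
  block <- matrix(rnorm(3 * 200), 3)
  w <- make_windows(block, 200, 100)
  expect_equal(w$offsets, 0L)
  expect_equal(dim(w$blocks), c(3, 200, 1))
  w <- make_windows(matrix(rnorm(3 * 300), 3), 200, 100)
  expect_equal(w$offsets, c(0L, 100L))
  w <- make_windows(matrix(rnorm(3 * 250), 3), 200, 100)
  expect_equal(w$offsets, c(0L, 50L))
  expect_error(make_windows(matrix(rnorm(3 * 150), 3), 200, 100),
               "too short")
})

test_that("label traces are unit-peak Gaussians combined by maximum", {
  none <- make_label_traces(gait_events(), t0 = 0)
  expect_true(all(none == 0))
  ev <- gait_events(time = 1.0, kind = "IC", foot = "unknown")
  y <- make_label_traces(ev, t0 = 0, window = 200, sigma = 5)
  expect_equal(y[1, 101], 1.0)               # sample 100 (0-based)
  expect_equal(y[1, 96], y[1, 106])          # symmetric decay
  expect_equal(y[1, 101 - 5], exp(-0.5), tolerance = 1e-12)
  expect_true(all(y[2, ] == 0))
  expect_true(all(y[1, c(1:75, 127:200)] == 0))  # truncated at 4 sigma
  # two close events: pointwise max keeps the trace within [0, 1]
  ev2 <- gait_events(time = c(1.0, 1.03), kind = c("IC", "IC"),
                     foot = c("unknown", "unknown"))
  y2 <- make_label_traces(ev2, t0 = 0)
  expect_lte(max(y2), 1)
  expect_equal(y2[1, 101], 1.0)
  expect_equal(y2[1, 104], 1.0)
  expect_gte(min(y2[1, 101:104]), exp(-(1.5^2) / 50))
})

test_that("peak extraction honours threshold and refractory period", {
  fs <- 100
  p <- matrix(0, 2, 400)
  trace <- structure(list(t0 = 0, fs = fs, p = p), class = "event_trace")
  expect_equal(nrow(extract_events(trace)), 0L)
  # single bump peaking at sample 150 (0-based) with p = 0.9
  p[1, ] <- 0.9 * exp(-((0:399 - 150)^2) / 50)
  trace$p <- p
  ev <- extract_events(trace, threshold = 0.5, refractory = 0.30)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$time, 1.50)
  expect_equal(ev$kind, "IC")
  # two bumps 10 samples apart with 30-sample refractory: taller survives
  p2 <- matrix(0, 2, 400)
  p2[2, ] <- pmax(0.7 * exp(-((0:399 - 200)^2) / 18),
                  0.9 * exp(-((0:399 - 210)^2) / 18))
  trace$p <- p2
  ev2 <- extract_events(trace, threshold = 0.5, refractory = 0.30)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$time, 2.10)
})

test_that("label-then-extract recovers event times exactly", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    times <- sort(sample(20:180, n)) / 100
    times <- times[c(TRUE, diff(times) > 0.35)]
    ev <- gait_events(time = times, kind = rep("IC", length(times)),
                      foot = rep("unknown", length(times)))
    y <- make_label_traces(ev, t0 = 0)
    trace <- structure(list(t0 = 0, fs = 100, p = y), class = "event_trace")
    got <- extract_events(trace, threshold = 0.5, refractory = 0.30)
    expect_equal(got$time, times)
  }
})

test_that("probability traces stay in [0,1] and average across window overlap", {
  set.seed(22)
  model <- build_temporal_model(temporal_config(n_blocks = 2, channels = 8))
  rec <- tiny_recording(350)
  scaler <- fit_robust_scaler(rec)
  trace <- predict_traces(model, rec, scaler)
  expect_s3_class(trace, "event_trace")
  expect_equal(ncol(trace$p), 350)
  expect_true(all(trace$p >= 0 & trace$p <= 1))
  # recompute by scoring the windows independently: a sample covered by two
  # windows must carry the mean of both probabilities
  block <- apply_scaler(rec, scaler)
  w <- make_windows(block, 200, 100)
  probs <- lapply(seq_along(w$offsets), function(i) {
    out <- mear:::seq_forward(model$layers,
                              array(w$blocks[, , i], c(3, 200, 1)))$y
    mear:::sigmoid(out[, , 1])
  })
  s <- 180  # 0-based sample inside windows 1 (offset 0) and 2 (offset 100)
  manual <- (probs[[1]][1, s + 1] + probs[[2]][1, s - 100 + 1]) / 2
  expect_equal(trace$p[1, s + 1], manual, tolerance = 1e-12)
  # recording of exactly window length: trace of equal length
  rec200 <- tiny_recording(200)
  expect_equal(ncol(predict_traces(model, rec200, scaler)$p), 200)
})

test_that("shifting a recording shifts extracted events by the same amount", {
  set.seed(23)
  model <- build_temporal_model(temporal_config(n_blocks = 2, channels = 8))
  bout <- one_bout()
  scaler <- fit_robust_scaler(bout$recording)
  n <- nrow(bout$recording$samples)
  shift <- 100L
  r1 <- accel_recording(bout$recording$samples[1:(n - shift), ],
                        ear_side = "left")
  r2 <- accel_recording(bout$recording$samples[(shift + 1):n, ],
                        ear_side = "left")
  e1 <- extract_events(predict_traces(model, r1, scaler), threshold = 0.2)
  e2 <- extract_events(predict_traces(model, r2, scaler), threshold = 0.2)
  # events in the interior common span must coincide after shifting
  t1 <- e1$time[e1$time > 3 & e1$time < 5] - shift / 100
  t2 <- e2$time[e2$time > 3 - shift / 100 & e2$time < 5 - shift / 100]
  expect_equal(t1, t2, tolerance = 1e-9)
})

test_that("foot sides alternate from the configured anchor", {
  ev <- gait_events(time = c(0.5, 1.05, 1.6, 2.15), kind = rep("IC", 4),
                    foot = rep("unknown", 4))
  sided <- assign_foot_side(ev, ear_side = "left")
  expect_equal(sided$foot, c("left", "right", "left", "right"))
  sided_r <- assign_foot_side(ev, ear_side = "left",
                              anchor = "contralateral")
  expect_equal(sided_r$foot, c("right", "left", "right", "left"))
  # FCs take the side contralateral to the nearest preceding IC
  ev2 <- gait_events(time = c(0.5, 0.62, 1.05, 1.17),
                     kind = c("IC", "FC", "IC", "FC"),
                     foot = rep("unknown", 4))
  sided2 <- assign_foot_side(ev2, "left")
  expect_equal(sided2$foot, c("left", "right", "right", "left"))
})

test_that("side re-assignment matches simulator truth up to a global swap", {
  bout <- one_bout()
  truth <- bout$events
  stripped <- gait_events(truth$time, truth$kind,
                          rep("unknown", nrow(truth)))
  agree <- function(anchor) {
    sided <- assign_foot_side(stripped, bout$recording$ear_side, anchor)
    mean(sided$foot == truth$foot)
  }
  accs <- c(agree("ipsilateral"), agree("contralateral"))
  expect_true(any(accs == 1))     # one anchor choice is exactly right
  expect_true(any(accs == 0))     # the other is the global swap
})

test_that("a missing step leaves a gap that invalidates spanning strides", {
  bout <- one_bout()
  truth <- bout$events
  ics <- which(truth$kind == "IC")
  drop <- ics[6]                   # remove one mid-walk IC
  broken <- gait_events(truth$time[-drop], truth$kind[-drop],
                        rep("unknown", nrow(truth) - 1))
  sided <- assign_foot_side(broken, bout$recording$ear_side)
  gaps <- attr(sided, "gap_intervals")
  expect_gte(nrow(gaps), 1)
  strides <- strides_from_events(sided)
  in_gap <- strides$ic_time < gaps[1, 2] &
    (strides$ic_time + strides$stride_time) > gaps[1, 1]
  expect_true(all(!strides$valid[in_gap]))
})
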