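test_that("cohort generation is deterministic and correctly sized", {
  cfg <- cohort_config(4, c(slow = 1, preferred = 2, fast = 1), seed = 31)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_equal(length(c1$bouts), 4 * 4)   # n_subjects * sum(walks)
  expect_equal(nrow(c1$manifest), 16)
  expect_identical(c1$bouts[[5]]$recording$samples,
                   c2$bouts[[5]]$recording$samples)
  expect_identical(c1$manifest, c2$manifest)
  # manifest groups: each bout id maps to exactly one subject
  expect_equal(anyDuplicated(c1$manifest$bout_id), 0L)
  per_subj <- table(c1$manifest$subject_id)
  expect_true(all(per_subj == 4))
})

test_that("subjects draw deterministically with ordered speed profiles", {
  cfg <- cohort_config(10, seed = 32)
  s1 <- draw_subject(cfg, 3)
  s2 <- draw_subject(cfg, 3)
  expect_identical(s1, s2)
  for (i in 1:10) {
    s <- draw_subject(cfg, i)
    expect_lt(s$cadence[["slow"]], s$cadence[["preferred"]])
    expect_lt(s$cadence[["preferred"]], s$cadence[["fast"]])
    expect_true(all(c(s$stride_time_cv, s$spatial_asym) >= 0))
    expect_equal(det(s$rotation), 1, tolerance = 1e-12)  # proper rotation
    expect_equal(crossprod(s$rotation), diag(3), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_equal(length(unique(vapply(1:10, function(i)
    draw_subject(cfg, i)$subject_id, character(1)))), 10)
})

test_that("zero-variability subjects walk perfectly periodically", {
  s <- degenerate_subject()
  b <- generate_bout(s, "preferred", seed = 55)
  st <- b$strides[b$strides$valid, ]
  expect_gt(nrow(st), 4)
  for (col in c("stride_time", "swing_time", "dsupp_time",
                "stride_length_cm", "stride_width_cm")) {
    expect_equal(diff(range(st[[col]])), 0, tolerance = 1e-9)
    s_sum <- summarize_bout(st, if (col %in% c("stride_length_cm",
                                               "stride_width_cm")) col
                            else col)
    expect_equal(s_sum$cv, 0, tolerance = 1e-9)
  }
  # per foot, FC - IC equals the stance duration used by the generator
  for (ft in c("left", "right")) {
    ic <- b$events$time[b$events$kind == "IC" & b$events$foot == ft]
    fc <- b$events$time[b$events$kind == "FC" & b$events$foot == ft]
    stance <- fc - ic
    expected <- s$stance_fraction[["preferred"]] * (120 / s$cadence[["preferred"]])
    expect_equal(stance, rep(expected, length(stance)), tolerance = 1e-9)
  }
})

test_that("configured spatial asymmetry is recovered from ground truth", {
  hyper <- subject_hyper(spatial_asym_mean = 20, spatial_asym_sd = 0,
                         stride_length_cv_mean = 0, stride_length_cv_sd = 0,
                         stride_length_subject_sd = 0,
                         stride_length_speed_jitter_sd = 0)
  cfg <- cohort_config(2, seed = 77, hyper = hyper)
  s <- draw_subject(cfg, 1)
  b <- generate_bout(s, "preferred", seed = 5)
  st <- b$strides[b$strides$valid & !is.na(b$strides$stride_length_cm), ]
  mL <- mean(st$stride_length_cm[st$foot == "left"])
  mR <- mean(st$stride_length_cm[st$foot == "right"])
  expect_equal(100 * (1 - min(mL, mR) / max(mL, mR)), 20, tolerance = 1e-9)
  asym <- summarize_bout(st, "stride_length_cm")$asymmetry
  expect_equal(asym, 20, tolerance = 1e-9)
})

test_that("stride records agree exactly with the emitted event sequence", {
  cohort <- small_cohort()
  for (b in cohort$bouts[1:6]) {
    derived <- strides_from_events(b$events)
    expect_equal(derived$ic_time, b$strides$ic_time, tolerance = 1e-12)
    expect_equal(derived$stride_time, b$strides$stride_time,
                 tolerance = 1e-12)
    expect_equal(derived$swing_time, b$strides$swing_time,
                 tolerance = 1e-12)
    expect_equal(derived$dsupp_time, b$strides$dsupp_time,
                 tolerance = 1e-12)
    # conservation: per foot, stride times sum to last IC - first IC
    for (ft in c("left", "right")) {
      ic <- b$events$time[b$events$kind == "IC" & b$events$foot == ft]
      rows <- derived$foot == ft
      expect_equal(sum(derived$stride_time[rows]),
                   max(ic) - min(ic), tolerance = 1e-9)
    }
  }
})

test_that("ground-truth stride time equals the ipsilateral IC difference", {
  b <- one_bout()
  for (ft in c("left", "right")) {
    ic <- sort(b$events$time[b$events$kind == "IC" & b$events$foot == ft])
    st <- b$strides[b$strides$foot == ft, ]
    expect_equal(st$stride_time, diff(ic), tolerance = 1e-12)
  }
})

test_that("generated cadence converges to the configured mean", {
  # many preferred bouts of one subject: observed cadence within 3 SE
  cfg <- cohort_config(2, seed = 88)
  s <- draw_subject(cfg, 1)
  per_bout <- vapply(1:40, function(i) {
    b <- generate_bout(s, "preferred", seed = 1000 + i)
    st <- b$strides$stride_time[b$strides$valid]
    120 / mean(st)            # steps/min from mean stride time
  }, numeric(1))
  se <- sd(per_bout) / sqrt(length(per_bout))
  expect_lt(abs(mean(per_bout) - s$cadence[["preferred"]]),
            3 * se + 0.5)
})

test_that("step-frequency signal energy clears the noise floor", {
  b <- one_bout()
  x <- b$recording$samples[, "acc_is"]
  spec <- stats::spec.pgram(stats::ts(x, frequency = 100), plot = FALSE,
                            taper = 0)
  steps <- sort(b$events$time[b$events$kind == "IC"])
  f_step <- 1 / mean(diff(steps))
  band <- spec$freq > f_step - 0.3 & spec$freq < f_step + 0.3
  noise_band <- spec$freq > 30    # far above gait dynamics: noise floor
  expect_gt(max(spec$spec[band]), 10 * stats::median(spec$spec[noise_band]))
})

test_that("impossible walkway configurations are refused", {
  cfg <- cohort_config(2, walkway_m = 0.8, seed = 3)
  s <- draw_subject(cfg, 1)
  expect_error(generate_bout(s, "fast", seed = 1, walkway_m = 0.8),
               "walkway shorter")
  expect_error(cohort_config(1), "n_subjects")
  expect_error(cohort_config(3, walkway_m = -1), "walkway_m")
  expect_error(subject_hyper(bogus = 1), "unknown hyperparameter")
})
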