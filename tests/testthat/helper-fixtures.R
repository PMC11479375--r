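# Shared fixtures, built in code. Expensive objects (small cohort, trained
# pipeline) are memoized so several test files can reuse one computation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a short deterministic recording with known values
tiny_recording <- function(n = 250, seed = 5, t0 = 0) {
  set.seed(seed)
  accel_recording(matrix(stats::rnorm(n * 3, sd = 0.5), n, 3),
                  subject_id = "T01", ear_side = "left", t0 = t0)
}

# small cohort shared across synthetic / training / metrics tests
small_cohort <- function() {
  memo("small_cohort", {
    cfg <- cohort_config(6, c(slow = 1, preferred = 2, fast = 1), seed = 404)
    generate_cohort(cfg)
  })
}

# a single preferred-speed bout with typical variability
one_bout <- function() {
  memo("one_bout", {
    cfg <- cohort_config(2, c(slow = 1, preferred = 1, fast = 1), seed = 11)
    generate_bout(draw_subject(cfg, 1), "preferred", 2024)
  })
}

# a zero-variability, zero-asymmetry subject (degenerate draws)
degenerate_subject <- function() {
  hyper <- subject_hyper(
    cadence_subject_sd = 0, cadence_speed_jitter_sd = 0,
    stride_length_subject_sd = 0, stride_length_speed_jitter_sd = 0,
    stride_time_cv_mean = 0, stride_time_cv_sd = 0,
    stride_length_cv_mean = 0, stride_length_cv_sd = 0,
    temporal_asym_mean = 0, temporal_asym_sd = 0,
    spatial_asym_mean = 0, spatial_asym_sd = 0,
    stride_width_cv_mean = 0, stride_width_cv_sd = 0,
    noise_sd_g = 0, orientation_sd_deg = 0)
  cfg <- cohort_config(2, c(slow = 1, preferred = 1, fast = 1),
                       seed = 7, hyper = hyper)
  draw_subject(cfg, 1)
}

# brute-force maximum matching under a tolerance (assignment oracle)
brute_force_tp <- function(predicted, annotated, tolerance = 0.25) {
  na <- length(annotated)
  np <- length(predicted)
  if (!na || !np) return(0L)
  allowed <- abs(outer(annotated, predicted, `-`)) < tolerance
  best <- 0L
  rec <- function(ia, used_p, count) {
    if (count + (na - ia + 1) <= best) return()
    if (ia > na) { best <<- max(best, count); return() }
    rec(ia + 1L, used_p, count)            # leave annotated ia unmatched
    for (ip in which(allowed[ia, ] & !used_p)) {
      used_p[ip] <- TRUE
      rec(ia + 1L, used_p, count + 1L)
      used_p[ip] <- FALSE
    }
  }
  rec(1L, logical(np), 0L)
  best
}

# gait-like random matching instance: sorted annotated events with step-like
# spacing, jittered predictions, random misses and spurious detections
random_match_instance <- function(max_events = 8, jitter_sd = 0.05,
                                  max_jitter = 0.12) {
  n <- sample.int(max_events, 1)
  annotated <- cumsum(stats::runif(n, 0.30, 0.9))
  jit <- pmax(pmin(stats::rnorm(n, 0, jitter_sd), max_jitter), -max_jitter)
  predicted <- annotated + jit
  keep <- stats::runif(n) > 0.15
  predicted <- predicted[keep]
  n_fp <- stats::rpois(1, 0.7)
  if (n_fp > 0)
    predicted <- c(predicted, stats::runif(n_fp, 0, max(annotated) + 0.5))
  list(annotated = annotated, predicted = sort(predicted))
}

# independent ICC oracle built on stats::aov mean squares
icc_oracle_aov <- function(true, pred) {
  n <- length(true)
  d <- data.frame(y = c(true, pred),
                  target = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ target + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  list(consistency = (msr - mse) / (msr + (k - 1) * mse),
       agreement = (msr - mse) /
         (msr + (k - 1) * mse + (k / n) * (msc - mse)))
}
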