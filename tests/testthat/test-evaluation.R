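test_that("event matching handles identity, tolerance edge and swaps", {
  t <- c(0.5, 1.0, 1.5)
  m <- match_events(t, t)
  expect_equal(m$tp, 3); expect_equal(m$fn, 0); expect_equal(m$fp, 0)
  expect_true(all(m$pairs$t_annotated == m$pairs$t_predicted))
  # 0.30 s apart with 0.25 s tolerance: no match (strict <)
  m2 <- match_events(0.80, 0.50)
  expect_equal(c(m2$tp, m2$fn, m2$fp), c(0, 1, 1))
  # exactly at tolerance: still no match
  m3 <- match_events(0.75, 0.50)
  expect_equal(m3$tp, 0)
  just_in <- match_events(0.7499, 0.50)
  expect_equal(just_in$tp, 1)
  # swapping roles swaps FN and FP, preserves TP
  p <- c(0.5, 1.02, 2.0); a <- c(0.5, 1.0, 1.4, 3.0)
  mf <- match_events(p, a); mr <- match_events(a, p)
  expect_equal(mf$tp, mr$tp)
  expect_equal(mf$fn, mr$fp)
  expect_equal(mf$fp, mr$fn)
})

test_that("greedy matching equals the brute-force optimum on gait-like instances", {
  set.seed(51)
  for (i in 1:300) {
    inst <- random_match_instance()
    m <- match_events(inst$predicted, inst$annotated, 0.25)
    expect_equal(m$tp, brute_force_tp(inst$predicted, inst$annotated, 0.25))
    expect_true(all(abs(m$pairs$t_annotated - m$pairs$t_predicted) < 0.25))
  }
})

test_that("detection scores implement the printed formulas and conventions", {
  s <- detection_scores(list(tp = 8, fn = 2, fp = 4))
  expect_equal(s$recall, 0.8)
  expect_equal(s$precision, 8 / 12)
  expect_equal(s$f1, 2 * s$precision * s$recall / (s$precision + s$recall))
  # degenerate: TP = 0 with both error kinds present -> all zero
  z <- detection_scores(list(tp = 0, fn = 3, fp = 2))
  expect_equal(c(z$recall, z$precision, z$f1), c(0, 0, 0))
  # undefined denominators are flagged NA, never silently 0
  u <- detection_scores(list(tp = 0, fn = 0, fp = 2))
  expect_true(is.na(u$recall))
  expect_match(u$flags, "recall_undefined", all = FALSE)
  # weighted aggregate
  w <- weighted_detection_scores(list(a = list(tp = 90, fn = 10, fp = 0),
                                      b = list(tp = 50, fn = 50, fp = 0)))
  expect_equal(w$recall, 0.5 * 0.9 + 0.5 * 0.5)
})

test_that("time errors use the annotated-minus-predicted sign convention", {
  a <- c(1.0, 2.0, 3.0)
  m <- match_events(a + 0.010, a)     # predictions uniformly 10 ms late
  te <- time_errors(m)
  expect_equal(te$mean, -0.010, tolerance = 1e-12)
  expect_true(all(abs(te$errors) < m$tolerance))
  m0 <- match_events(numeric(), a)
  expect_equal(time_errors(m0)$flags, "no_matches")
})

test_that("agreement statistics separate the two ICC variants", {
  x <- c(10, 12, 14, 16, 18, 25)
  a_id <- agreement(x, x)
  expect_equal(a_id$rmse_abs, 0)
  expect_equal(a_id$pearson_r, 1)
  expect_equal(a_id$icc, 1, tolerance = 1e-12)
  expect_equal(a_id$band, "excellent")
  # constant offset: consistency stays 1, absolute agreement drops
  a_off <- agreement(x + 5, x)
  expect_equal(a_off$icc_consistency, 1, tolerance = 1e-12)
  expect_lt(a_off$icc_agreement, 1)
  expect_equal(a_off$rmse_abs, 5)
  # zero variance flagged
  a_const <- agreement(rep(3, 5), c(1, 2, 3, 4, 5))
  expect_true("zero_variance" %in% a_const$flags)
  expect_true(is.na(a_const$pearson_r))
  expect_error(agreement(1:2, 1:2), "at least 3")
})

test_that("ICC matches an independent aov-based computation", {
  set.seed(52)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    true <- rnorm(n, 100, 10)
    pred <- true + rnorm(n, sample(c(0, 3), 1), 4)
    a <- agreement(pred, true)
    oracle <- icc_oracle_aov(true, pred)
    expect_equal(a$icc_consistency, oracle$consistency, tolerance = 1e-10)
    expect_equal(a$icc_agreement, oracle$agreement, tolerance = 1e-10)
    # and r agrees with stats::cor
    expect_equal(a$pearson_r, cor(pred, true), tolerance = 1e-12)
  }
})

test_that("agreement converges to perfect as noise vanishes", {
  set.seed(53)
  x <- runif(20, 50, 150)
  for (eps in c(1, 0.1, 0.001)) {
    a <- agreement(x + eps * rnorm(20), x)
    expect_gt(a$pearson_r, 1 - 10 * eps)
    expect_gt(a$icc, 1 - 10 * eps)
  }
})

test_that("ICC interpretation bands follow the published cut-offs", {
  expect_equal(interpret_icc(0.49), "poor")
  expect_equal(interpret_icc(0.5), "moderate")
  expect_equal(interpret_icc(0.76), "good")
  expect_equal(interpret_icc(0.95), "excellent")
  expect_true(is.na(interpret_icc(NA)))
})

test_that("repeated-measures ANOVA matches a from-scratch decomposition", {
  # hand-built 3 subjects x 3 conditions
  tab <- rbind(c(5, 6, 9), c(4, 5, 7), c(6, 7, 9))
  res <- rm_anova(tab)
  g <- mean(tab)
  ss_cond <- 3 * sum((colMeans(tab) - g)^2)
  ss_subj <- 3 * sum((rowMeans(tab) - g)^2)
  ss_err <- sum((tab - g)^2) - ss_cond - ss_subj
  f_manual <- (ss_cond / 2) / (ss_err / 4)
  expect_equal(res$F, f_manual, tolerance = 1e-12)
  expect_equal(res$df1, 2); expect_equal(res$df2, 4)
  # against stats::aov with an Error(subject) stratum
  d <- data.frame(y = as.vector(tab),
                  subj = factor(rep(1:3, 3)),
                  cond = factor(rep(1:3, each = 3)))
  aovres <- summary(stats::aov(y ~ cond + Error(subj), data = d))
  ftab <- aovres[["Error: Within"]][[1]]
  expect_equal(res$F, ftab[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$p, ftab[["Pr(>F)"]][1], tolerance = 1e-10)
  # identical values across conditions for every subject: F = 0, p = 1
  null_tab <- matrix(rep(c(3, 4, 5), 3), 3, byrow = FALSE)
  res0 <- rm_anova(null_tab)
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
})

test_that("randomized RM-ANOVA agrees with aov to near machine precision", {
  set.seed(54)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    tab <- matrix(rnorm(n * 3, 10, 2), n, 3)
    res <- rm_anova(tab)
    d <- data.frame(y = as.vector(tab), subj = factor(rep(seq_len(n), 3)),
                    cond = factor(rep(1:3, each = n)))
    ftab <- summary(stats::aov(y ~ cond + Error(subj), d))[["Error: Within"]][[1]]
    expect_equal(res$F, ftab[["F value"]][1], tolerance = 1e-10)
  }
})

test_that("speed-stratified RMSE builds per-cell tables and excludes incomplete subjects", {
  set.seed(55)
  d <- expand.grid(subject = paste0("S", 1:4), speed = c("slow", "preferred",
                                                         "fast"),
                   bout = 1:3, stringsAsFactors = FALSE)
  d$true <- runif(nrow(d), 100, 140)
  d$pred <- d$true + rnorm(nrow(d), 0, 5)
  res <- speed_stratified_rmse(d)
  expect_equal(dim(res$table), c(4L, 3L))
  # one manually recomputed cell
  rows <- d$subject == "S2" & d$speed == "fast"
  manual <- 100 * sqrt(mean((d$pred[rows] - d$true[rows])^2)) /
    mean(d$true[rows])
  expect_equal(res$table["S2", "fast"], manual, tolerance = 1e-12)
  expect_equal(res$anova$df1, 2)
  expect_equal(res$anova$df2, 2 * (4 - 1))
  # drop one subject's fast bouts: excluded with a warning
  d_inc <- d[!(d$subject == "S4" & d$speed == "fast"), ]
  expect_warning(res2 <- speed_stratified_rmse(d_inc), "excluding 1")
  expect_equal(res2$anova$df2, 2 * (3 - 1))
})
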