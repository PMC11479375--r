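# Agreement evaluation: event matching at a time tolerance, detection
# scores (precision / recall / F1), signed time errors, RMSE / Pearson /
# intraclass-correlation agreement statistics with interpretation bands,
# and a repeated-measures ANOVA of relative RMSE across walking speeds.

#' Match predicted against annotated events at a time tolerance
#'
#' Among all cross pairs with `|t_annotated - t_predicted| < tolerance`
#' (strict inequality), pairs are accepted greedily in order of ascending
#' absolute time difference (ties: earlier annotated, then earlier
#' predicted event); each event joins at most one pair. Matched pairs are
#' true positives, unmatched annotated events false negatives, unmatched
#' predicted events false positives.
#'
#' @param predicted,annotated numeric vectors of event times (seconds),
#'   each sorted ascending.
#' @param tolerance matching tolerance in seconds (default 250 ms).
#' @return a `match_result`: list with `tp`, `fn`, `fp`, `pairs`
#'   (data.frame `t_annotated`, `t_predicted`) and `tolerance`.
#' @export
match_events <- function(predicted, annotated, tolerance = 0.250) {
  predicted <- as.numeric(predicted)
  annotated <- as.numeric(annotated)
  if (is.unsorted(predicted) || is.unsorted(annotated))
    stop_mear("event lists must be sorted by time", "mear_format_error")
  np <- length(predicted); na <- length(annotated)
  pairs <- data.frame(t_annotated = numeric(), t_predicted = numeric())
  if (np && na) {
    dt <- abs(outer(annotated, predicted, `-`))
    cand <- which(dt < tolerance, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(dt[cand], annotated[cand[, 1]], predicted[cand[, 2]])
      cand <- cand[ord, , drop = FALSE]
      used_a <- logical(na); used_p <- logical(np)
      keep_a <- integer(); keep_p <- integer()
      for (r in seq_len(nrow(cand))) {
        ia <- cand[r, 1]; ip <- cand[r, 2]
        if (!used_a[ia] && !used_p[ip]) {
          used_a[ia] <- TRUE; used_p[ip] <- TRUE
          keep_a <- c(keep_a, ia); keep_p <- c(keep_p, ip)
        }
      }
      o <- order(annotated[keep_a])
      pairs <- data.frame(t_annotated = annotated[keep_a][o],
                          t_predicted = predicted[keep_p][o])
    }
  }
  structure(list(tp = nrow(pairs), fn = na - nrow(pairs),
                 fp = np - nrow(pairs), pairs = pairs,
                 tolerance = tolerance),
            class = "match_result")
}

#' Detection scores from a match result or raw counts
#'
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `F1 = 2 * precision * recall / (precision + recall)`. With `TP = 0` but
#' errors of both kinds present, all three are 0 by convention; a score
#' whose denominator is 0 is `NA` and named in `flags` (never silently 0).
#'
#' @param result a `match_result`, or a list/vector with elements `tp`,
#'   `fn`, `fp` (so printed confusion counts can be scored directly).
#' @return list with `recall`, `precision`, `f1`, the counts, and `flags`.
#' @export
detection_scores <- function(result) {
  tp <- result[["tp"]]; fn <- result[["fn"]]; fp <- result[["fp"]]
  flags <- character()
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  if (is.na(recall)) flags <- c(flags, "recall_undefined_no_annotated")
  if (is.na(precision)) flags <- c(flags, "precision_undefined_no_predicted")
  f1 <- if (!is.na(recall) && !is.na(precision)) {
    if (precision + recall > 0) 2 * precision * recall / (precision + recall)
    else 0
  } else NA_real_
  list(tp = tp, fn = fn, fp = fp, recall = recall, precision = precision,
       f1 = f1, flags = flags)
}

#' Support-weighted aggregate of per-class detection scores
#'
#' Weights each class's precision/recall/F1 by its support (`TP + FN`).
#'
#' @param results named list of `match_result`s or count lists (one per
#'   event class, e.g. IC and FC).
#' @return list with weighted `recall`, `precision`, `f1` and `support`.
#' @export
weighted_detection_scores <- function(results) {
  scores <- lapply(results, detection_scores)
  support <- vapply(scores, function(s) s$tp + s$fn, numeric(1))
  w <- support / sum(support)
  agg <- function(field) sum(w * vapply(scores, `[[`, numeric(1), field))
  list(recall = agg("recall"), precision = agg("precision"), f1 = agg("f1"),
       support = support)
}

#' Signed time errors of matched events
#'
#' Sign convention: `time error = t_annotated - t_predicted` (a late
#' prediction gives a negative error).
#'
#' @param result a `match_result`.
#' @return list with `errors` (seconds), `mean`, and `flags` (flagged
#'   empty when there are no matches).
#' @export
time_errors <- function(result) {
  stopifnot(inherits(result, "match_result"))
  if (result$tp == 0)
    return(list(errors = numeric(), mean = NA_real_, flags = "no_matches"))
  errors <- result$pairs$t_annotated - result$pairs$t_predicted
  list(errors = errors, mean = mean(errors), flags = character())
}

ICC_BANDS <- c(poor = 0.5, moderate = 0.75, good = 0.9)

#' Interpretation band for an intraclass correlation coefficient
#'
#' Cut-offs: poor (< 0.5), moderate (0.5-0.75), good (0.75-0.9),
#' excellent (> 0.9).
#'
#' @param icc a single ICC value (may be `NA`).
#' @return character band name or `NA`.
#' @export
interpret_icc <- function(icc) {
  if (is.na(icc)) return(NA_character_)
  if (icc < 0.5) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc <= 0.9) "good"
  else "excellent"
}

icc_from_mean_squares <- function(x) {
  # x: n x k matrix (targets x raters); two-way model mean squares
  n <- nrow(x); k <- ncol(x)
  g <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - g)^2)
  ssc <- n * sum((col_m - g)^2)
  sst <- sum((x - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse,
       consistency = (msr - mse) / (msr + (k - 1) * mse),
       agreement = (msr - mse) /
         (msr + (k - 1) * mse + (k / n) * (msc - mse)))
}

#' Agreement statistics between predicted and ground-truth values
#'
#' Computes `RMSE_abs = sqrt(mean((pred - true)^2))`, `RMSE_rel = 100 *
#' RMSE_abs / mean(true)` (%), Pearson's r with a two-sided significance
#' flag at `alpha = 0.05`, and the single-rater two-way intraclass
#' correlation from the paired-measurement ANOVA mean squares. Both ICC
#' variants are returned: `icc_consistency` ignores a systematic offset
#' between methods, `icc_agreement` (the default `icc`) penalizes it. An
#' interpretation band (poor / moderate / good / excellent) is attached.
#'
#' @param pred,true paired numeric vectors (same bouts/subjects), `n >= 3`.
#' @param variant which ICC fills the `icc` slot.
#' @param alpha two-sided significance level for Pearson's r.
#' @return an `agreement_stats` list.
#' @export
agreement <- function(pred, true, variant = c("agreement", "consistency"),
                      alpha = 0.05) {
  variant <- match.arg(variant)
  ok <- !is.na(pred) & !is.na(true)
  pred <- pred[ok]; true <- true[ok]
  n <- length(pred)
  if (n < 3)
    stop_mear("agreement statistics need at least 3 pairs", "mear_data_error")
  rmse_abs <- sqrt(mean((pred - true)^2))
  rmse_rel <- 100 * rmse_abs / mean(true)
  flags <- character()
  r <- r_p <- NA_real_
  icc_c <- icc_a <- NA_real_
  if (stats::sd(pred) == 0 || stats::sd(true) == 0) {
    flags <- c(flags, "zero_variance")
  } else {
    ct <- stats::cor.test(pred, true)
    r <- unname(ct$estimate); r_p <- ct$p.value
    ms <- icc_from_mean_squares(cbind(true, pred))
    icc_c <- ms$consistency; icc_a <- ms$agreement
  }
  icc <- if (variant == "agreement") icc_a else icc_c
  structure(list(n = n, rmse_abs = rmse_abs, rmse_rel = rmse_rel,
                 pearson_r = r, pearson_p = r_p,
                 significant = !is.na(r_p) && r_p < alpha,
                 icc = icc, icc_variant = variant,
                 icc_agreement = icc_a, icc_consistency = icc_c,
                 band = interpret_icc(icc), flags = flags),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "<agreement> n=%d RMSE=%.3g (%.1f%%) r=%.3f%s ICC(%s)=%.3f [%s]\n",
    x$n, x$rmse_abs, x$rmse_rel, x$pearson_r,
    if (isTRUE(x$significant)) "*" else "", x$icc_variant, x$icc, x$band))
  invisible(x)
}

#' One-way repeated-measures ANOVA across within-subject conditions
#'
#' Classic within-subject decomposition: `F = MS_condition / MS_error`
#' with `df = (c - 1, (c - 1) * (n - 1))` for `c` conditions and `n`
#' complete subjects.
#'
#' @param values n x c numeric matrix: one row per subject, one column per
#'   condition (no missing cells).
#' @return list with `F`, `df1`, `df2`, `p` and the mean squares.
#' @export
rm_anova <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); c <- ncol(values)
  if (n < 2 || c < 2)
    stop_mear("repeated-measures ANOVA needs >= 2 subjects and conditions",
              "mear_data_error")
  g <- mean(values)
  ss_cond <- n * sum((colMeans(values) - g)^2)
  ss_subj <- c * sum((rowMeans(values) - g)^2)
  ss_tot <- sum((values - g)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- c - 1; df2 <- (c - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f <- if (ms_err > 0) ms_cond / ms_err else if (ms_cond == 0) 0 else Inf
  p <- if (ms_err > 0) stats::pf(f, df1, df2, lower.tail = FALSE) else
    if (ms_cond == 0) 1 else 0
  if (ms_err == 0 && ms_cond == 0) { f <- 0; p <- 1 }
  list(F = f, df1 = df1, df2 = df2, p = p, ms_condition = ms_cond,
       ms_error = ms_err)
}

#' Speed-stratified relative RMSE with a repeated-measures ANOVA
#'
#' For each subject and speed condition, computes the relative RMSE (%)
#' between predicted and true per-bout values of one gait parameter, then
#' tests for a speed effect with a one-way repeated-measures ANOVA over
#' the three speeds. Subjects missing any speed are excluded with a
#' warning.
#'
#' @param d data.frame with columns `subject`, `speed`, `pred`, `true`
#'   (one row per bout).
#' @return list with `table` (subject x speed relative RMSE, wide) and
#'   `anova` (see [rm_anova()]).
#' @export
speed_stratified_rmse <- function(d) {
  stopifnot(all(c("subject", "speed", "pred", "true") %in% names(d)))
  cell <- function(sub, sp) {
    rows <- d$subject == sub & d$speed == sp
    if (!any(rows)) return(NA_real_)
    100 * sqrt(mean((d$pred[rows] - d$true[rows])^2)) / mean(d$true[rows])
  }
  subjects <- unique(d$subject)
  tab <- sapply(SPEED_LEVELS, function(sp)
    vapply(subjects, cell, numeric(1), sp = sp))
  tab <- matrix(tab, nrow = length(subjects),
                dimnames = list(subjects, SPEED_LEVELS))
  complete <- stats::complete.cases(tab)
  if (any(!complete))
    warning(sprintf("excluding %d subject(s) without all three speeds",
                    sum(!complete)))
  if (sum(complete) < 2)
    stop_mear("need >= 2 complete subjects for the speed ANOVA",
              "mear_data_error")
  list(table = tab, anova = rm_anova(tab[complete, , drop = FALSE]))
}
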