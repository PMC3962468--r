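#' Mean and standard error of the mean
#'
#' SEM is the sample standard deviation (n-1 denominator) divided by
#' the square root of n — the `mean +/- SEM` convention used for all
#' cohort summaries.
#'
#' @param values numeric vector, length >= 2.
#' @return A list with `mean` and `sem`.
#' @export
mean_sem <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop("mean_sem needs at least 2 non-missing values")
  }
  list(mean = mean(values), sem = sd(values) / sqrt(length(values)))
}

#' Paired one-tailed Student t-test
#'
#' The t statistic is computed on the per-eye differences
#' `observed - control`; the p-value is the one-tailed tail
#' probability of Student's t with `n - 1` degrees of freedom in the
#' stated direction (`greater`: observed exceeds control).
#'
#' @param observed,control numeric vectors of equal length >= 2
#'   (per-eye metric values).
#' @param direction `"greater"` or `"less"` — the a-priori alternative
#'   for `observed` relative to `control`.
#' @return A list: `t`, `df`, `p`, `mean_diff`, `sem_diff`,
#'   `direction`.
#' @export
paired_one_tailed_t <- function(observed, control,
                                direction = c("greater", "less")) {
  direction <- match.arg(direction)
  observed <- as.numeric(observed)
  control <- as.numeric(control)
  if (length(observed) != length(control)) {
    stop("observed and control must have equal length")
  }
  n <- length(observed)
  if (n < 2L) stop("need at least 2 pairs")
  d <- observed - control
  sdd <- sd(d)
  if (sdd < .Machine$double.eps * max(1, abs(mean(d)))) {
    stop("degenerate variance: all paired differences are identical")
  }
  sem <- sdd / sqrt(n)
  t <- mean(d) / sem
  df <- n - 1L
  p <- if (direction == "greater") pt(t, df, lower.tail = FALSE) else pt(t, df)
  list(t = t, df = df, p = p, mean_diff = mean(d), sem_diff = sem,
       direction = direction)
}

# Pull one metric (observed and control) out of a list of eye results.
extract_metric <- function(eyes, metric) {
  get1 <- function(side) {
    vapply(eyes, function(e) {
      s <- e[[side]]
      switch(metric,
             pct_vessel = s$pct_vessel,
             pct_near_1_3 = s$stroma_bins$pct[["near_1_3"]],
             pct_mid_4_6 = s$stroma_bins$pct[["mid_4_6"]],
             pct_far_ge7 = s$stroma_bins$pct[["far_ge7"]],
             stop("unknown metric"))
    }, numeric(1))
  }
  list(observed = get1("observed"), control = get1("control"))
}

# A-priori test directions: lesions are hypothesized to sit over and
# near vessels more than chance, and far from them less; the middle
# bin has no directional hypothesis and is reported two-sided.
METRIC_DIRECTIONS <- c(pct_vessel = "greater", pct_near_1_3 = "greater",
                       pct_mid_4_6 = "two_sided", pct_far_ge7 = "less")

#' Summarize a cohort of eyes
#'
#' Per metric (percent over vessels; stroma percents at 1-3, 4-6 and
#' >=7 pixels): observed and control mean +/- SEM and a paired Student
#' t-test on the per-eye differences. Directions are fixed a priori —
#' `pct_vessel` and `pct_near_1_3` one-tailed greater, `pct_far_ge7`
#' one-tailed less, `pct_mid_4_6` two-sided (smaller one-tailed p
#' doubled) — and echoed in the output.
#'
#' @param eyes list of `eye_result` objects (length >= 2).
#' @param alpha significance level, default 0.05.
#' @return A `cohort_summary`: list with `n_eyes`, `alpha`, and
#'   `metrics` (one entry per metric).
#' @export
summarize_cohort <- function(eyes, alpha = 0.05) {
  if (length(eyes) < 2L) stop("insufficient data: need at least 2 eyes")
  stopifnot(all(vapply(eyes, inherits, logical(1), "eye_result")))
  metrics <- lapply(names(METRIC_DIRECTIONS), function(metric) {
    v <- extract_metric(eyes, metric)
    dir <- METRIC_DIRECTIONS[[metric]]
    obs <- mean_sem(v$observed)
    ctl <- mean_sem(v$control)
    test <- tryCatch({
      if (dir == "two_sided") {
        t1 <- paired_one_tailed_t(v$observed, v$control, "greater")
        p <- 2 * min(t1$p, 1 - t1$p)
        c(t1[c("t", "df", "mean_diff", "sem_diff")],
          list(p = min(p, 1), direction = "two_sided"))
      } else {
        paired_one_tailed_t(v$observed, v$control, dir)
      }
    }, error = function(e) {
      list(t = NA_real_, df = length(v$observed) - 1L, p = NA_real_,
           mean_diff = mean(v$observed - v$control), sem_diff = NA_real_,
           direction = dir, degenerate = conditionMessage(e))
    })
    list(metric = metric,
         observed_mean = obs$mean, observed_sem = obs$sem,
         control_mean = ctl$mean, control_sem = ctl$sem,
         mean_diff = test$mean_diff, sem_diff = test$sem_diff,
         t_statistic = test$t, degrees_of_freedom = test$df,
         p = test$p, direction = test$direction,
         significant = !is.na(test$p) && test$p < alpha,
         degenerate = test$degenerate)
  })
  names(metrics) <- names(METRIC_DIRECTIONS)
  structure(list(n_eyes = length(eyes), alpha = alpha, metrics = metrics),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d eyes (alpha = %g)\n", x$n_eyes, x$alpha))
  for (m in x$metrics) {
    cat(sprintf(
      "  %-12s observed %5.1f +/- %4.1f%%  control %5.1f +/- %4.1f%%  diff %+5.1f  p = %s (%s)%s\n",
      m$metric, m$observed_mean, m$observed_sem, m$control_mean,
      m$control_sem, m$mean_diff,
      if (is.na(m$p)) "NA" else format.pval(m$p, digits = 3),
      m$direction, if (isTRUE(m$significant)) " *" else ""))
  }
  invisible(x)
}
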