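# Clock evaluation (MAE, Pearson R, R^2), the RR2 ratio quantifying a
# clock's stochastic component, the RR2 vs (1/R^2 - 1) diagnostic, and the
# cross-cohort meta-analysis.

#' Evaluate age predictions against known ages
#'
#' R^2 is defined as the squared Pearson correlation of predicted vs true
#' age (not a regression R^2): this is what cancels study-specific biases in
#' the RR2 ratio. MAE defaults to the mean absolute error, with a median
#' option.
#'
#' @param predicted,true numeric age vectors of equal length (>= 3); `true`
#'   must not be constant.
#' @param mae_type `"mean"` (default) or `"median"` absolute error.
#' @return object of class `clock_eval`: `mae`, `pearson_r`, `r2`,
#'   `p_value`, `n`. If `predicted` is constant the correlation is undefined
#'   and returned as `NA` with a warning (MAE is still reported).
#' @export
evaluate_clock <- function(predicted, true, mae_type = c("mean", "median")) {
  mae_type <- match.arg(mae_type)
  if (length(predicted) != length(true)) stopf("length mismatch")
  if (length(true) < 3) stopf("need >= 3 samples")
  if (anyNA(predicted) || anyNA(true)) stopf("missing values")
  if (sd(true) == 0) stopf("true ages are constant")
  err <- predicted - true
  mae <- if (mae_type == "mean") mean(abs(err)) else median(abs(err))
  if (sd(predicted) == 0) {
    warnf("constant predictions: correlation undefined")
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- cor.test(predicted, true, method = "pearson",
                   alternative = "two.sided")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(mae = mae, pearson_r = r, r2 = r^2, p_value = p,
                 n = length(true), mae_type = mae_type),
            class = "clock_eval")
}

#' @export
print.clock_eval <- function(x, ...) {
  cat(sprintf("clock_eval: MAE=%.3f R=%.3f R2=%.3f p=%.3g n=%d\n",
              x$mae, x$pearson_r, x$r2, x$p_value, x$n))
  invisible(x)
}

#' RR2: ratio of R-squared values of a stochastic clock to its original
#'
#' `RR2 = R^2(stochastic) / R^2(original)` on the same cohort quantifies the
#' fraction of the original clock's accuracy attributable to a pure
#' stochastic process; study-specific biases affect both clocks and cancel
#' in the ratio. Values above 1 are reported with a warning (empirically the
#' ratio is below 1).
#'
#' @param stoc,orig `clock_eval` results for the stochastic and original
#'   clock on the same cohort.
#' @param cohort optional cohort label.
#' @param n cohort size (defaults to `orig$n`).
#' @return object of class `rr2_record`: `cohort`, `rr2`, `r2_stoc`,
#'   `r2_orig`, `n`.
#' @export
rr2 <- function(stoc, orig, cohort = NA_character_, n = NULL) {
  stopifnot(inherits(stoc, "clock_eval"), inherits(orig, "clock_eval"))
  if (is.na(orig$r2) || orig$r2 == 0)
    stopf("original clock R^2 is zero/undefined: RR2 undefined")
  ratio <- stoc$r2 / orig$r2
  if (!is.na(ratio) && ratio > 1)
    warnf("RR2 = %.3f > 1: stochastic clock outperforms the original", ratio)
  structure(list(cohort = cohort, rr2 = ratio, r2_stoc = stoc$r2,
                 r2_orig = orig$r2, n = if (is.null(n)) orig$n else n),
            class = "rr2_record")
}

#' RR2 against unexplained variation: the alternative-hypothesis diagnostic
#'
#' Under the alternative reading that stochastic clocks capture the age
#' variation *not* explained by a clock, RR2 would track `1/R^2 - 1`. This
#' returns the transformed pairs and their Pearson correlation so that
#' clustering away from the line of proportionality can be checked.
#'
#' @param rr2_values numeric RR2 values per cohort.
#' @param r2_orig original-clock R^2 per cohort (same length, >= 3 usable).
#' @return list with `pairs` (data.frame `rr2`, `unexplained`) and
#'   `correlation`; cohorts with `r2_orig = 0` are excluded with a warning.
#' @export
rr2_vs_unexplained <- function(rr2_values, r2_orig) {
  if (length(rr2_values) != length(r2_orig)) stopf("length mismatch")
  drop_ <- r2_orig == 0 | is.na(r2_orig)
  if (any(drop_)) warnf("excluding %d record(s) with R^2 = 0", sum(drop_))
  rr2_values <- rr2_values[!drop_]
  r2_orig <- r2_orig[!drop_]
  if (length(rr2_values) < 3) stopf("need >= 3 usable records")
  x <- 1 / r2_orig - 1
  list(pairs = data.frame(rr2 = rr2_values, unexplained = x),
       correlation = cor(rr2_values, x))
}

#' Meta-analysis comparison of RR2 ratios between two clocks
#'
#' Two tests over cohort-paired ratios: a one-tailed paired Wilcoxon
#' (signed-rank) test, and the two-tailed t-test of the clock-indicator
#' coefficient in a weighted least-squares fit of
#' `ratio ~ clock + cohort` with cohort sample sizes as weights.
#'
#' @param rr2_a,rr2_b per-cohort RR2 ratios for clocks "a" and "b", paired
#'   by position; >= 5 cohorts for the Wilcoxon branch.
#' @param n per-cohort sample sizes (regression weights); default equal.
#' @param alternative direction of the one-tailed Wilcoxon test on `a`
#'   relative to `b` (`"less"`: a < b).
#' @return list with `wilcoxon_p`, `regression_p` and
#'   `regression_coef` (the clock-b minus clock-a adjusted difference).
#' @export
meta_compare <- function(rr2_a, rr2_b, n = NULL,
                         alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(rr2_a) != length(rr2_b)) stopf("cohorts are not paired")
  k <- length(rr2_a)
  if (k < 5) stopf("need >= 5 paired cohorts")
  if (is.null(n)) n <- rep(1, k)
  if (length(n) != k) stopf("`n` must have one weight per cohort")

  d <- rr2_a - rr2_b
  wilcoxon_p <- if (all(d == 0)) 1 else
    suppressWarnings(wilcox.test(rr2_a, rr2_b, paired = TRUE,
                                 alternative = alternative)$p.value)

  df <- data.frame(ratio = c(rr2_a, rr2_b),
                   clock = factor(rep(c("a", "b"), each = k)),
                   cohort = factor(rep(seq_len(k), 2)),
                   w = rep(n, 2))
  fitw <- lm(ratio ~ clock + cohort, data = df, weights = w)
  co <- summary(fitw)$coefficients["clockb", ]
  list(wilcoxon_p = wilcoxon_p,
       regression_p = unname(co["Pr(>|t|)"]),
       regression_coef = unname(co["Estimate"]))
}
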