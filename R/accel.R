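# Extrinsic and intrinsic epigenetic age acceleration (EAA/IAA) and their
# association tests with phenotypes.

#' Extrinsic age acceleration (EAA)
#'
#' Residuals of the ordinary least-squares regression of predicted DNAm-age
#' on chronological age. Positive values flag samples epigenetically older
#' than their age.
#'
#' @param dnam_age predicted DNAm-age (years).
#' @param age chronological age (years), not constant; n >= 3.
#' @return numeric residual vector (sums to ~0).
#' @export
eaa <- function(dnam_age, age) {
  if (length(dnam_age) != length(age)) stopf("length mismatch")
  if (length(age) < 3) stopf("need >= 3 samples")
  if (sd(age) == 0) stopf("chronological age is constant")
  unname(resid(lm(dnam_age ~ age)))
}

#' Intrinsic age acceleration (IAA)
#'
#' Residuals of DNAm-age regressed on chronological age plus 11 of the 12
#' immune-cell fractions (the fractions sum to 1, so only 11 are linearly
#' independent given an intercept; the dropped column is the one with the
#' largest mean, and because of the simplex collinearity the residuals do
#' not depend on which one is dropped). IAA is EAA purged of cell-type
#' composition signal.
#'
#' @inheritParams eaa
#' @param fractions samples x k matrix of cell-type fractions, rows summing
#'   to 1 (within 1e-6); `n > k + 1`.
#' @return numeric residual vector.
#' @export
iaa <- function(dnam_age, age, fractions) {
  fractions <- as.matrix(fractions)
  n <- length(age)
  if (length(dnam_age) != n || nrow(fractions) != n) stopf("length mismatch")
  if (any(abs(rowSums(fractions) - 1) > 1e-6))
    stopf("fraction rows must sum to 1")
  k <- ncol(fractions)
  if (n <= k + 1) stopf("need more samples (%d) than regressors (%d)", n, k + 1)
  if (sd(age) == 0) stopf("chronological age is constant")
  drop_col <- which.max(colMeans(fractions))
  X <- cbind(age = age, fractions[, -drop_col, drop = FALSE])
  fit <- lm(dnam_age ~ X)
  # aliased columns (e.g. constant fractions, absorbed by the intercept) are
  # dropped by lm; residuals remain the projection onto the design space
  if (anyNA(coef(fit)))
    warnf("rank-deficient design after drop: %d aliased column(s) ignored",
          sum(is.na(coef(fit))))
  unname(resid(fit))
}

#' Test association between age acceleration and a phenotype
#'
#' Rank-based group comparisons use an exact Wilcoxon rank-sum p-value for
#' small samples (combined n below 50, no ties) and the continuity-corrected
#' normal approximation otherwise. Ordinal phenotypes (e.g. smoking coded
#' 0/1/2) use the slope t-test of a linear regression of the acceleration
#' measure on the ordinal score.
#'
#' @param acc numeric residuals (EAA, IAA or relative mitotic age residuals).
#' @param phenotype two-level grouping (factor/character/logical) for the
#'   Wilcoxon kinds, or numeric ordinal scores for `"ordinal_regression"`.
#' @param kind `"wilcoxon_two_tailed"`, `"wilcoxon_one_tailed"` or
#'   `"ordinal_regression"`.
#' @param alternative for the one-tailed test: is the first factor level
#'   `"greater"` (default) or `"less"` than the second?
#' @return list with `statistic`, `p_value`, `kind`.
#' @export
test_association <- function(acc, phenotype,
                             kind = c("wilcoxon_two_tailed",
                                      "wilcoxon_one_tailed",
                                      "ordinal_regression"),
                             alternative = c("greater", "less")) {
  kind <- match.arg(kind)
  alternative <- match.arg(alternative)
  if (length(acc) != length(phenotype)) stopf("length mismatch")
  if (kind == "ordinal_regression") {
    score <- as.numeric(phenotype)
    if (anyNA(score)) stopf("ordinal phenotype must be numeric")
    if (sd(score) == 0) stopf("phenotype is constant")
    co <- summary(lm(acc ~ score))$coefficients["score", ]
    return(list(statistic = unname(co["t value"]),
                p_value = unname(co["Pr(>|t|)"]), kind = kind))
  }
  g <- factor(phenotype)
  if (nlevels(g) != 2) stopf("need exactly 2 groups, got %d", nlevels(g))
  x <- acc[g == levels(g)[1]]
  y <- acc[g == levels(g)[2]]
  if (length(x) < 2 || length(y) < 2) stopf("need >= 2 samples per group")
  exact <- (length(x) + length(y)) < 50
  alt <- if (kind == "wilcoxon_two_tailed") "two.sided" else alternative
  wt <- suppressWarnings(wilcox.test(x, y, alternative = alt, exact = exact,
                                     correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, kind = kind)
}
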