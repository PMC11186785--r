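# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

.check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1))
    stopf("`%s` must lie in [0, 1]", name)
  invisible(x)
}

.check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stopf("`%s` must be a single integer >= %s", name, format(min))
  as.integer(x)
}

.check_scalar <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    stopf("`%s` must be a single number >= %s", name, format(min))
  as.numeric(x)
}

# Seed for the i-th subtask of a master seed; stays below 2^31 - 1 so it is a
# valid R integer seed. Deterministic, so cohorts are reproducible and
# order-independent.
derive_seed <- function(master, index) {
  as.integer((abs(as.numeric(master)) %% 2147483 * 977 +
                (as.numeric(index) %% 1000003) * 9973 + 1) %% 2147483647)
}

.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Cheap deterministic content hash for provenance headers (no external digest
# dependency; collisions are harmless here).
.tiny_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Clip beta-values away from the boundaries
#'
#' Beta-values of exactly 0 or 1 map to infinite normal quantiles, so before
#' any quantile-space operation they are clipped to `[eps, 1 - eps]`. The
#' number of clipped entries is recorded in the `"n_clipped"` attribute so
#' clamping events can be reported.
#'
#' @param beta numeric vector or matrix of beta-values.
#' @param eps clipping margin, default `1e-6`.
#' @return `beta` clipped, with attribute `n_clipped`.
#' @export
clip_beta <- function(beta, eps = 1e-6) {
  if (!is.numeric(beta)) stopf("`beta` must be numeric")
  n_clipped <- sum(beta < eps | beta > 1 - eps, na.rm = TRUE)
  out <- pmin(pmax(beta, eps), 1 - eps)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Transform beta-values to standard-normal quantiles
#'
#' The simulator operates additively on `x = qnorm(beta)`; this transform is
#' what makes beta-value changes heteroscedastic (largest near beta = 0.5,
#' shrinking toward 0/1) and keeps simulated values inside (0, 1).
#'
#' @inheritParams clip_beta
#' @return numeric object of normal quantiles.
#' @export
beta_to_quantile <- function(beta, eps = 1e-6) {
  x <- qnorm(clip_beta(beta, eps))
  attr(x, "n_clipped") <- NULL
  x
}

#' Transform normal quantiles back to beta-values
#' @param x numeric quantiles.
#' @return beta-values in (0, 1).
#' @export
quantile_to_beta <- function(x) pnorm(x)
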