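# Population-level stochastic DNAm-accrual simulator.
#
# Each CpG c is altered per time step with probability
#   p_c = 1 - exp(-gamma * |EffSize_c|),
# and an alteration adds a half-normal deviate |N(0, sigma)|, signed by the
# effect direction, to the CpG's inverse-normal quantile x = qnorm(beta).
# Working in quantile space keeps betas strictly inside (0, 1) and gives the
# characteristic heteroscedasticity of beta-values (changes are largest near
# beta = 0.5 and shrink toward the boundaries).

#' Simulation parameters
#'
#' @param gamma global alteration rate (dimensionless, >= 0). Larger gamma
#'   pushes every CpG's per-step alteration probability toward 1; for small
#'   gamma the probability is ~ gamma * |effect size|.
#' @param sigma scale of the quantile-space half-normal deviate (>= 0).
#' @param steps_per_year time steps per year of aging; default 35, anchored
#'   to the approximate annual number of hematopoietic stem-cell divisions
#'   (the step unit is arbitrary, this anchor just aids interpretation).
#' @param base_age age (years) at which simulation starts; default 45, the
#'   reference young-group age.
#' @param eps beta clipping margin before the quantile transform.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(gamma, sigma, steps_per_year = 35, base_age = 45,
                       eps = 1e-6) {
  structure(list(
    gamma = .check_scalar(gamma, "gamma", min = 0),
    sigma = .check_scalar(sigma, "sigma", min = 0),
    steps_per_year = .check_count(steps_per_year, "steps_per_year", min = 1),
    base_age = .check_scalar(base_age, "base_age"),
    eps = .check_scalar(eps, "eps", min = 0)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("sim_params: gamma=%g sigma=%g steps_per_year=%d base_age=%g\n",
              x$gamma, x$sigma, x$steps_per_year, x$base_age))
  invisible(x)
}

#' Per-step alteration probability of a CpG
#'
#' `p_c = 1 - exp(-gamma * |effect_size|)`: zero iff gamma or the effect is
#' zero, strictly increasing in both, saturating at 1.
#'
#' @param effect_size signed effect size(s) in beta-units.
#' @param gamma global alteration rate, >= 0.
#' @return probability vector in [0, 1).
#' @export
alteration_probability <- function(effect_size, gamma) {
  gamma <- .check_scalar(gamma, "gamma", min = 0)
  1 - exp(-gamma * abs(effect_size))
}

#' Number of simulation steps for a target age
#' @param params a `sim_params`.
#' @param age target age in years, `>= base_age`. Fractional ages are
#'   supported; steps are rounded to the nearest integer.
#' @return integer step count.
#' @export
n_sim_steps <- function(params, age) {
  stopifnot(inherits(params, "sim_params"))
  if (any(age < params$base_age))
    stopf("`age` (%s) below base_age (%s)", format(min(age)),
          format(params$base_age))
  as.integer(round(params$steps_per_year * (age - params$base_age)))
}

# Align a per-CpG vector to the effect table's CpG order.
.align_profile <- function(x, effects, name) {
  effects <- .as_effect_table(effects)
  if (!is.null(names(x))) {
    miss <- setdiff(effects$cpg_id, names(x))
    if (length(miss))
      stopf("`%s` is missing CpGs: %s", name,
            paste(head(miss, 5), collapse = ", "))
    x <- x[effects$cpg_id]
  } else if (length(x) != nrow(effects)) {
    stopf("`%s` length %d does not match %d CpGs", name, length(x),
          nrow(effects))
  }
  setNames(as.numeric(x), effects$cpg_id)
}

# Total quantile-space drift per CpG after n_steps, for nsim independent
# simulations. Exploits that the update is purely additive in quantile space:
# the number of alterations is Binomial(n_steps, p_c) and each adds an
# independent half-normal deviate, so end states can be drawn without
# stepping through time. Returns an ncpg x nsim matrix of unsigned drifts.
.draw_drift <- function(p_c, n_steps, sigma, nsim = 1) {
  ncpg <- length(p_c)
  k <- rbinom(ncpg * nsim, n_steps, p_c)   # p_c recycles: CpG varies fastest
  K <- sum(k)
  if (K > 0 && sigma > 0) {
    # per-entry sums of k half-normal deviates via cumsum boundaries
    cs <- c(0, cumsum(abs(rnorm(K, 0, sigma))))
    ends <- cumsum(k)
    drift <- cs[ends + 1] - cs[ends - k + 1]
  } else {
    drift <- numeric(ncpg * nsim)
  }
  matrix(drift, nrow = ncpg, ncol = nsim)
}

#' Advance a quantile profile by one time step
#'
#' The literal per-step update: each CpG is independently altered with its
#' probability `p_c`, and altered CpGs receive a signed half-normal deviate.
#' `simulate_sample()` uses an exact additive shortcut instead; this function
#' is the definitional reference (and trajectory recorder).
#'
#' @param x named quantile profile (`beta_to_quantile` of betas), aligned to
#'   `effects`.
#' @param effects an `effect_table`.
#' @param params a `sim_params`.
#' @return updated quantile profile.
#' @export
sim_step <- function(x, effects, params) {
  stopifnot(inherits(params, "sim_params"))
  x <- .align_profile(x, effects, "x")
  p_c <- alteration_probability(effects$effect_size, params$gamma)
  hit <- runif(length(x)) < p_c
  if (any(hit) && params$sigma > 0)
    x[hit] <- x[hit] + sign(effects$effect_size[hit]) *
      abs(rnorm(sum(hit), 0, params$sigma))
  x
}

#' Simulate one sample's beta profile at a target age
#'
#' Starts from the (clipped, quantile-transformed) ground profile and runs
#' `steps_per_year * (age - base_age)` steps of stochastic accrual. Because
#' the quantile-space update is additive, the end state is drawn exactly in
#' one shot (Binomial alteration counts plus summed half-normal deviates)
#' rather than by looping over steps; `simulate_trajectory()` provides the
#' per-step path when needed.
#'
#' @param ground per-CpG beta profile at `base_age` (named by CpG, or in
#'   `effects` order).
#' @param effects an `effect_table` (signs fix drift direction, magnitudes
#'   the alteration probability).
#' @param params a `sim_params`.
#' @param age target age in years, `>= base_age`.
#' @param seed optional integer seed (local to this call).
#' @return named beta profile in (0, 1), with attribute `n_steps`.
#' @export
simulate_sample <- function(ground, effects, params, age, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  effects <- .as_effect_table(effects)
  ground <- .align_profile(ground, effects, "ground")
  n_steps <- n_sim_steps(params, age)
  x0 <- beta_to_quantile(ground, params$eps)
  if (n_steps == 0L || params$sigma == 0 || params$gamma == 0) {
    out <- quantile_to_beta(x0)
  } else {
    p_c <- alteration_probability(effects$effect_size, params$gamma)
    drift <- .with_seed(seed, .draw_drift(p_c, n_steps, params$sigma, 1L))
    out <- quantile_to_beta(x0 + sign(effects$effect_size) * drift[, 1])
  }
  names(out) <- effects$cpg_id
  attr(out, "n_steps") <- n_steps
  out
}

#' Record a per-step simulation trajectory
#'
#' Runs the literal per-step update and records the beta profile after every
#' step. Mainly for diagnostics/figures (e.g. checking that mean beta drifts
#' linearly with time away from the boundaries).
#'
#' @inheritParams simulate_sample
#' @param n_steps number of steps to run.
#' @return matrix of `(n_steps + 1)` rows (step 0 first) by CpG columns.
#' @export
simulate_trajectory <- function(ground, effects, params, n_steps,
                                seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  effects <- .as_effect_table(effects)
  ground <- .align_profile(ground, effects, "ground")
  n_steps <- .check_count(n_steps, "n_steps", min = 0)
  x <- beta_to_quantile(ground, params$eps)
  names(x) <- effects$cpg_id
  out <- matrix(NA_real_, nrow = n_steps + 1, ncol = length(x),
                dimnames = list(NULL, effects$cpg_id))
  out[1, ] <- quantile_to_beta(x)
  .with_seed(seed, {
    for (i in seq_len(n_steps)) {
      x <- sim_step(x, effects, params)
      out[i + 1, ] <- quantile_to_beta(x)
    }
  })
  out
}
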