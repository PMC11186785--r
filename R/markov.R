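# Two-state Markov model of single-cell CpG methylation dynamics.
#
# A CpG in a single cell is binary (0 unmethylated, 1 methylated). Switches
# happen per discrete time step with probability p (0 -> 1) and q (1 -> 0).
# Starting from the unmethylated state, the probability of being methylated
# after t steps has a closed form that is linear in t while far from the
# steady state pi1 = p / (p + q).

.check_rates <- function(p, q) {
  .check_prob(p, "p")
  .check_prob(q, "q")
  if (length(p) != 1L || length(q) != 1L)
    stopf("`p` and `q` must be single probabilities")
  invisible(NULL)
}

#' Transition matrix of the two-state methylation chain
#'
#' @param p probability of an unmethylated CpG becoming methylated per step.
#' @param q probability of a methylated CpG losing methylation per step.
#' @return 2 x 2 row-stochastic matrix `[[1-p, p], [q, 1-q]]`, with states
#'   ordered (unmethylated, methylated).
#' @examples
#' transition_matrix(0.3, 0.1)
#' @export
transition_matrix <- function(p, q) {
  .check_rates(p, q)
  matrix(c(1 - p, q, p, 1 - q), nrow = 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

#' Closed-form probability of being methylated after t steps
#'
#' For a CpG starting unmethylated, `P01(t) = p/(p+q) * (1 - (1-p-q)^t)`.
#' It is 0 at `t = 0` and converges to the steady state `p/(p+q)`; with
#' `p = q = 0` the start state is absorbing and 0 is returned for all t.
#'
#' @inheritParams transition_matrix
#' @param t nonnegative integer step count (vectorised).
#' @return probability (vector along `t`).
#' @examples
#' prob_methylated_closed_form(0.3, 0.1, 2) # 0.48
#' @export
prob_methylated_closed_form <- function(p, q, t) {
  .check_rates(p, q)
  if (any(t < 0) || any(t != round(t))) stopf("`t` must be nonnegative integers")
  if (p + q == 0) return(rep(0, length(t)))
  r <- 1 - p - q
  # exponent-log only for r > 0; direct integer power otherwise (oscillatory
  # regime r < 0 is supported but outside the biological regime).
  pow <- if (r > 0) exp(t * log(r)) else ifelse(t == 0, 1, r^t)
  (p / (p + q)) * (1 - pow)
}

#' Recurrence evaluation of the methylation probability
#'
#' Iterates `P01 <- p + (1 - p - q) * P01` from `P01(0) = 0`. Agrees with the
#' closed form to ~1e-12 for t up to 1e5; intended as the definitional
#' reference implementation.
#'
#' @inheritParams prob_methylated_closed_form
#' @param t single nonnegative integer step count.
#' @return probability.
#' @export
prob_methylated_recurrence <- function(p, q, t) {
  .check_rates(p, q)
  t <- .check_count(t, "t", min = 0)
  p01 <- 0
  r <- 1 - p - q
  for (i in seq_len(t)) p01 <- p + r * p01
  p01
}

#' Steady-state distribution of the two-state chain
#'
#' @inheritParams transition_matrix
#' @return named vector `c(pi0 = q/(p+q), pi1 = p/(p+q))`; errors if
#'   `p + q = 0` (no unique stationary distribution).
#' @export
steady_state <- function(p, q) {
  .check_rates(p, q)
  if (p + q == 0) stopf("steady state undefined for p = q = 0")
  c(pi0 = q / (p + q), pi1 = p / (p + q))
}

#' Linear-regime approximation P01(t) ~ p * t
#'
#' Valid while p, q are tiny and p*t is far from the steady state; the
#' returned absolute error against the closed form makes the domain of
#' validity explicit.
#'
#' @inheritParams prob_methylated_closed_form
#' @return list with `approx = p * t` and `abs_error` vs the closed form.
#' @export
linear_approximation <- function(p, q, t) {
  exact <- prob_methylated_closed_form(p, q, t)
  approx <- p * t
  list(approx = approx, abs_error = abs(exact - approx))
}
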