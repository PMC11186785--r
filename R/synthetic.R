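# Synthetic-data generators: young/old sorted-cell reference panels,
# "real-aging" cohorts mixing stochastic and nonstochastic signal, and
# immune-cell-fraction matrices. These stand in for the access-controlled
# cohorts (sorted-monocyte reference panels, whole-blood studies) so every
# stage is testable offline.

# Blood-like 12-cell-type composition used as the default simplex base.
.default_fraction_base <- c(
  Neu = 0.55, Mono = 0.08, NK = 0.05, Bnv = 0.03, Bmem = 0.02,
  CD4nv = 0.08, CD4mem = 0.08, CD8nv = 0.04, CD8mem = 0.04,
  Treg = 0.01, Eos = 0.015, Baso = 0.005)

# Truncated half-normal magnitudes in (0, max] via inverse-CDF sampling.
.rhalfnorm_trunc <- function(n, sd, max) {
  if (sd == 0) return(rep(0, n))
  u <- runif(n)
  sd * qnorm(0.5 + 0.5 * u * (2 * pnorm(max / sd) - 1))
}

#' Generate a young/old reference panel with known effect sizes
#'
#' Emulates a sorted-cell reference panel: per-CpG ground states are drawn
#' from a bimodal beta-like mixture (modes near 0.1 and 0.9 plus 20%
#' intermediate uniform mass, mirroring genome-wide DNAm bimodality), signed
#' true effects are small (|effect| <= `max_effect`, default 0.05, the scale
#' observed over ~4 decades in purified cells), and per-sample noise is added
#' in inverse-normal-quantile space so that beta-value variance shrinks near
#' 0/1. The generative truth is recorded for recovery tests.
#'
#' @param n_cpgs number of CpGs (>= 2).
#' @param n_young,n_old samples per group (>= 2); defaults 43/11 mirror the
#'   young/old monocyte pools the protocol is anchored on.
#' @param effect_sd scale of the half-normal effect-size magnitudes
#'   (beta-units, >= 0).
#' @param frac_hyper fraction of CpGs whose true effect is positive
#'   (hypermethylating).
#' @param noise_sd per-sample quantile-space noise SD.
#' @param max_effect cap on |true effect| (beta-units).
#' @param seed integer seed.
#' @return object of class `reference_panel`: matrices `young` and `old`
#'   (CpGs x samples), `true_effects` (an `effect_table` holding the
#'   generative truth), `young_ages`, `old_ages`, and `n_clamped` (count of
#'   old-state clamping events).
#' @export
make_reference_panel <- function(n_cpgs, n_young = 43, n_old = 11,
                                 effect_sd = 0.02, frac_hyper = 0.5,
                                 noise_sd = 0.1, max_effect = 0.05,
                                 seed = 1) {
  n_cpgs <- .check_count(n_cpgs, "n_cpgs", min = 2)
  n_young <- .check_count(n_young, "n_young", min = 2)
  n_old <- .check_count(n_old, "n_old", min = 2)
  effect_sd <- .check_scalar(effect_sd, "effect_sd", min = 0)
  .check_prob(frac_hyper, "frac_hyper")
  noise_sd <- .check_scalar(noise_sd, "noise_sd", min = 0)
  eps <- 1e-6

  .with_seed(seed, {
    cpgs <- sprintf("cg%07d", seq_len(n_cpgs))
    comp <- sample(c("lo", "hi", "mid"), n_cpgs, replace = TRUE,
                   prob = c(0.4, 0.4, 0.2))
    ground <- numeric(n_cpgs)
    ground[comp == "lo"] <- rbeta(sum(comp == "lo"), 5, 45)
    ground[comp == "hi"] <- rbeta(sum(comp == "hi"), 45, 5)
    ground[comp == "mid"] <- runif(sum(comp == "mid"), 0.1, 0.9)

    mag <- .rhalfnorm_trunc(n_cpgs, effect_sd, max_effect)
    sgn <- ifelse(runif(n_cpgs) < frac_hyper, 1, -1)
    effect <- sgn * mag

    proposed <- ground + effect
    n_clamped <- sum(proposed < 0 | proposed > 1)
    if (n_clamped > 0.10 * n_cpgs)
      stopf("`effect_sd` too large: clamping would censor %d/%d effects",
            n_clamped, n_cpgs)
    old_state <- pmin(pmax(proposed, eps), 1 - eps)
    effect <- old_state - ground

    draw_group <- function(means, n) {
      x <- beta_to_quantile(means, eps)
      m <- matrix(rnorm(length(means) * n, 0, noise_sd), ncol = n)
      out <- quantile_to_beta(x + m)
      dimnames(out) <- list(cpgs, NULL)
      out
    }
    young <- draw_group(ground, n_young)
    colnames(young) <- sprintf("young_%02d", seq_len(n_young))
    old <- draw_group(old_state, n_old)
    colnames(old) <- sprintf("old_%02d", seq_len(n_old))

    structure(list(
      young = young, old = old,
      true_effects = .as_effect_table(data.frame(
        cpg_id = cpgs, ground_state = ground, old_state = old_state,
        effect_size = effect, stringsAsFactors = FALSE)),
      young_ages = rep(45, n_young), old_ages = rep(82, n_old),
      n_clamped = n_clamped
    ), class = "reference_panel")
  })
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf(
    "reference_panel: %d CpGs, %d young / %d old samples, max |effect| %.4f\n",
    nrow(x$young), ncol(x$young), ncol(x$old),
    max(abs(x$true_effects$effect_size))))
  invisible(x)
}

#' Generate an aging cohort mixing stochastic and nonstochastic signal
#'
#' Each sample starts from a randomly drawn young-panel profile and is aged
#' by the stochastic simulator to a random age in `age_range`. On top of the
#' stochastic accrual, optional nonstochastic components can be layered:
#' covariate-scaled per-CpG offsets (specified in beta-units at the ground
#' state, applied additively in quantile space so betas stay bounded), and a
#' cell-composition shift that perturbs a 12-column fraction matrix per group
#' and, through a per-CpG signature, the beta-values themselves.
#'
#' @param panel a `reference_panel`.
#' @param n_samples cohort size.
#' @param age_range length-2 numeric, min/max age in years; the minimum must
#'   be at least `params$base_age`.
#' @param params a `sim_params` (the stochastic component).
#' @param nonstochastic list of components, each a list with `name`,
#'   `offset` (per-CpG beta-unit vector) and `values` (per-sample covariate,
#'   length `n_samples`; e.g. 0/1 for a binary covariate).
#' @param cell_shift optional list with `groups` (per-sample labels),
#'   `deltas` (named list: group -> length-k fraction delta), and optionally
#'   `base` (simplex base, default blood-like 12 types), `signature` (per-CpG
#'   beta-units per unit change of the first fraction) and `conc` (Dirichlet
#'   concentration, default 200).
#' @param seed integer seed.
#' @param ages optional explicit per-sample ages (length `n_samples`, inside
#'   `age_range`); by default ages are drawn uniformly over the range.
#'   Useful when a nonstochastic component must be a function of age.
#' @param age_jitter_sd SD (years, default 0) of a per-sample deviation
#'   between chronological and "biological" age: the stochastic simulation
#'   runs to `age + N(0, age_jitter_sd)` (floored at `base_age`) while the
#'   metadata records the chronological age. This is what keeps a clock's
#'   R-squared away from 1 in real cohorts; with the default 0 the mapping
#'   from age to expected methylation is exact.
#' @param noise_sd SD (default 0) of per-sample, per-CpG measurement noise
#'   added in quantile space after all other components.
#' @return list with `betas` (CpGs x samples) and `samples` (data.frame:
#'   sample_id, age, one column per covariate, group, and frac_* columns when
#'   `cell_shift` is given).
#' @export
make_aging_cohort <- function(panel, n_samples, age_range, params,
                              nonstochastic = list(), cell_shift = NULL,
                              seed = 1, ages = NULL, age_jitter_sd = 0,
                              noise_sd = 0) {
  stopifnot(inherits(panel, "reference_panel"), inherits(params, "sim_params"))
  n_samples <- .check_count(n_samples, "n_samples", min = 1)
  if (length(age_range) != 2 || age_range[1] > age_range[2])
    stopf("`age_range` must be c(min, max)")
  if (age_range[1] < params$base_age)
    stopf("`age_range` starts below base_age (%g)", params$base_age)
  effects <- panel$true_effects
  cpgs <- effects$cpg_id
  eps <- params$eps
  gq <- beta_to_quantile(effects$ground_state, eps)

  # beta-unit offset at ground state -> quantile-space offset
  offset_to_quantile <- function(v) {
    beta_to_quantile(pmin(pmax(effects$ground_state + v, eps), 1 - eps), eps) - gq
  }

  if (!is.null(ages)) {
    if (length(ages) != n_samples) stopf("`ages` must have length %d", n_samples)
    if (any(ages < age_range[1] | ages > age_range[2]))
      stopf("explicit `ages` fall outside `age_range`")
  }
  .with_seed(seed, {
    if (is.null(ages))
      ages <- round(runif(n_samples, age_range[1], age_range[2]), 1)
    draw_idx <- sample(ncol(panel$young), n_samples, replace = TRUE)
    bio_ages <- pmax(params$base_age,
                     ages + rnorm(n_samples, 0, age_jitter_sd))
    meta <- data.frame(sample_id = sprintf("s%04d", seq_len(n_samples)),
                       age = ages, stringsAsFactors = FALSE)

    betas <- matrix(NA_real_, nrow = length(cpgs), ncol = n_samples,
                    dimnames = list(cpgs, meta$sample_id))
    for (i in seq_len(n_samples)) {
      betas[, i] <- simulate_sample(panel$young[cpgs, draw_idx[i]], effects,
                                    params, bio_ages[i],
                                    seed = derive_seed(seed, i))
    }
    x <- beta_to_quantile(betas, eps)
    if (noise_sd > 0)
      x <- x + matrix(rnorm(length(x), 0, noise_sd), nrow = nrow(x))

    for (comp in nonstochastic) {
      stopifnot(is.list(comp), !is.null(comp$name), !is.null(comp$offset),
                !is.null(comp$values))
      if (length(comp$values) != n_samples)
        stopf("covariate `%s` must have %d values", comp$name, n_samples)
      dq <- offset_to_quantile(rep_len(comp$offset, length(cpgs)))
      x <- x + outer(dq, as.numeric(comp$values))
      meta[[comp$name]] <- comp$values
    }

    if (!is.null(cell_shift)) {
      groups <- rep_len(cell_shift$groups, n_samples)
      base <- cell_shift$base
      if (is.null(base)) base <- .default_fraction_base
      frac <- make_cell_fractions(n_samples, k = length(base), base = base,
                                  group_deltas = cell_shift$deltas,
                                  groups = groups,
                                  conc = cell_shift$conc %||% 200,
                                  seed = derive_seed(seed, 777001))
      meta$group <- groups
      if (!is.null(cell_shift$signature)) {
        sig <- rep_len(cell_shift$signature, length(cpgs))
        d1 <- frac[, 1] - base[1] / sum(base)
        x <- x + outer(offset_to_quantile(sig), d1)
      }
      colnames(frac) <- sprintf("frac_%d", seq_len(ncol(frac)))
      meta <- cbind(meta, as.data.frame(frac))
    }

    betas <- quantile_to_beta(x)
    dimnames(betas) <- list(cpgs, meta$sample_id)
    list(betas = betas, samples = meta)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a row-stochastic cell-fraction matrix
#'
#' Rows are Dirichlet draws around `base` (optionally shifted per group by
#' `group_deltas`) and renormalized, so every row is nonnegative and sums to
#' 1 exactly.
#'
#' @param n_samples number of rows.
#' @param k number of cell types (default 12).
#' @param base simplex base composition (length k, sums to 1); default is a
#'   blood-like 12-type composition.
#' @param group_deltas named list mapping group label to a length-k delta
#'   added to `base` (renormalized afterwards).
#' @param groups per-sample group labels (recycled); required when
#'   `group_deltas` is nonempty.
#' @param conc Dirichlet concentration (larger = tighter around the target).
#' @param seed integer seed.
#' @return `n_samples` x `k` matrix, rows summing to 1.
#' @export
make_cell_fractions <- function(n_samples, k = 12, base = NULL,
                                group_deltas = list(), groups = NULL,
                                conc = 200, seed = 1) {
  n_samples <- .check_count(n_samples, "n_samples", min = 1)
  k <- .check_count(k, "k", min = 2)
  if (is.null(base)) {
    if (k == 12) base <- unname(.default_fraction_base)
    else base <- rep(1 / k, k)
  }
  if (length(base) != k || any(base < 0) || abs(sum(base) - 1) > 1e-8)
    stopf("`base` must be a length-%d simplex vector", k)
  if (length(group_deltas) && is.null(groups))
    stopf("`groups` required when `group_deltas` is given")
  if (is.null(groups)) groups <- rep("all", n_samples)
  groups <- rep_len(as.character(groups), n_samples)

  .with_seed(seed, {
    out <- matrix(NA_real_, nrow = n_samples, ncol = k)
    for (g in unique(groups)) {
      idx <- which(groups == g)
      target <- base
      if (!is.null(group_deltas[[g]])) {
        d <- group_deltas[[g]]
        if (length(d) != k) stopf("delta for group `%s` must have length %d", g, k)
        target <- pmax(base + d, 1e-6)
        target <- target / sum(target)
      }
      draws <- matrix(rgamma(length(idx) * k, shape = conc * target),
                      ncol = k, byrow = TRUE)
      out[idx, ] <- draws / rowSums(draws)
    }
    rownames(out) <- sprintf("s%04d", seq_len(n_samples))
    out
  })
}
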