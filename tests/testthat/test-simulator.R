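# Population-level stochastic accrual engine.

test_that("alteration probability follows 1 - exp(-gamma |effect|)", {
  expect_equal(alteration_probability(0, 5), 0)
  expect_equal(alteration_probability(0.3, 0), 0)
  # direct evaluation at the reference fitted gamma
  expect_equal(alteration_probability(0.05, 9.25), 1 - exp(-0.4625),
               tolerance = 1e-12)
  expect_equal(alteration_probability(-0.05, 9.25),
               alteration_probability(0.05, 9.25))
  expect_gt(alteration_probability(0.01, 1e6), 1 - 1e-9)
  # strictly increasing in |effect| and gamma
  e <- seq(0.001, 0.05, by = 0.001)
  expect_true(all(diff(alteration_probability(e, 9.25)) > 0))
  expect_true(all(diff(sapply(c(1, 5, 20), alteration_probability,
                              effect_size = 0.02)) > 0))
  expect_error(alteration_probability(0.1, -1), ">=")
})

test_that("degenerate simulations return the input profile", {
  eff <- tiny_effects()
  g <- setNames(eff$ground_state, eff$cpg_id)
  for (p in list(sim_params(0, 0.01), sim_params(5, 0))) {
    out <- simulate_sample(g, eff, p, 80, seed = 1)
    expect_equal(unname(out), unname(pnorm(qnorm(g))), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # zero steps: clip/transform round trip only
  out <- simulate_sample(g, eff, sim_params(5, 0.001), 45, seed = 1)
  expect_lt(max(abs(out - g)), 1e-9)
  expect_identical(attr(out, "n_steps"), 0L)
})

test_that("step counts follow the steps-per-year anchor", {
  p <- sim_params(9.25, 5e-4)  # defaults: 35 steps/year from age 45
  expect_identical(n_sim_steps(p, 82), 1295L)
  expect_identical(n_sim_steps(p, 45), 0L)
  expect_identical(n_sim_steps(p, 45.5), 18L)  # fractional age rounds
  expect_error(n_sim_steps(p, 40), "below base_age")
  eff <- tiny_effects()
  s <- simulate_sample(setNames(eff$ground_state, eff$cpg_id), eff, p, 82,
                       seed = 3)
  expect_identical(attr(s, "n_steps"), 1295L)
})

test_that("expected quantile drift matches T * p_c * sigma * sqrt(2/pi)", {
  # one CpG, near-certain alteration, 1000 steps, 1000 replicates
  eff <- data.frame(cpg_id = "cg1", ground_state = 0.3, old_state = 0.9,
                    effect_size = 0.6)
  params <- sim_params(gamma = 50, sigma = 5e-4)  # p_c ~ 1
  p_c <- alteration_probability(0.6, 50)
  T_ <- 1000L; reps <- 1000L
  x0 <- qnorm(0.3)
  drifts <- withr::with_seed(77, {
    replicate(reps, {
      k <- rbinom(1, T_, p_c)
      sum(abs(rnorm(k, 0, 5e-4)))
    })
  })
  # direct-replication oracle agrees with the analytic mean
  expected <- T_ * p_c * 5e-4 * sqrt(2 / pi)
  expect_equal(expected, 0.399, tolerance = 0.01)
  expect_lt(abs(mean(drifts) - expected), 3 * sd(drifts) / sqrt(reps))

  # the packaged simulator reproduces it within 3 standard errors
  sims <- sapply(1:400, function(i) {
    s <- simulate_sample(c(cg1 = 0.3), eff, params, 45 + T_ / 35, seed = i)
    qnorm(s) - x0
  })
  n_steps <- attr(simulate_sample(c(cg1 = 0.3), eff, params, 45 + T_ / 35,
                                  seed = 1), "n_steps")
  expected_sim <- n_steps * p_c * 5e-4 * sqrt(2 / pi)
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - expected_sim), 3 * se)
})

test_that("per-CpG drift signs follow the effect directions", {
  eff <- data.frame(cpg_id = c("up", "dn"),
                    ground_state = c(0.3, 0.7),
                    old_state = c(0.35, 0.65),
                    effect_size = c(0.05, -0.05))
  params <- sim_params(9.25, 5e-4)
  sims <- sapply(1:500, function(i)
    simulate_sample(setNames(eff$ground_state, eff$cpg_id), eff, params, 80,
                    seed = i))
  expect_gt(mean(sims["up", ]), 0.3)
  expect_lt(mean(sims["dn", ]), 0.7)
  expect_true(all(sims > 0 & sims < 1))
})

test_that("beta changes are heteroscedastic across the beta range", {
  # equal quantile drift: |delta beta| largest at 0.5, shrinking toward 0/1
  d <- 0.2
  db <- abs(pnorm(qnorm(c(0.05, 0.5, 0.95)) + d) - c(0.05, 0.5, 0.95))
  expect_gt(db[2], db[1])
  expect_gt(db[2], db[3])
})

test_that("one-shot end state agrees with the per-step trajectory in law", {
  eff <- data.frame(cpg_id = "cg1", ground_state = 0.3, old_state = 0.35,
                    effect_size = 0.05)
  params <- sim_params(20, 0.01)
  T_ <- 200L
  traj_ends <- withr::with_seed(9, {
    replicate(300, simulate_trajectory(c(cg1 = 0.3), eff, params, T_)[T_ + 1, 1])
  })
  shot_ends <- sapply(1:300, function(i)
    simulate_sample(c(cg1 = 0.3), eff, params,
                    45 + as.numeric(T_) / params$steps_per_year, seed = i))
  # same law: compare means within combined Monte-Carlo error
  se <- sqrt(var(traj_ends) / 300 + var(shot_ends) / 300)
  expect_lt(abs(mean(traj_ends) - mean(shot_ends)), 4 * se)
})

test_that("mean beta drifts linearly far from the boundaries", {
  eff <- data.frame(cpg_id = "cg1", ground_state = 0.3, old_state = 0.35,
                    effect_size = 0.05)
  params <- sim_params(30, 0.002)
  traj <- withr::with_seed(123, {
    sapply(1:60, function(i)
      simulate_trajectory(c(cg1 = 0.3), eff, params, 400)[, 1])
  })
  mean_beta <- rowMeans(traj)
  t_ <- seq_along(mean_beta) - 1
  fit <- lm(mean_beta ~ t_)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("simulation is reproducible and seed-sensitive", {
  eff <- tiny_effects()
  g <- setNames(eff$ground_state, eff$cpg_id)
  params <- sim_params(9.25, 5e-4)
  a <- simulate_sample(g, eff, params, 80, seed = 7)
  b <- simulate_sample(g, eff, params, 80, seed = 7)
  c_ <- simulate_sample(g, eff, params, 80, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, c_))
})
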