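# Synthetic reference panels, aging cohorts and cell-fraction matrices.

test_that("reference panel honours its stated generative structure", {
  panel <- make_reference_panel(200, 30, 30, seed = 5)
  expect_true(all(panel$young >= 0 & panel$young <= 1))
  expect_true(all(panel$old >= 0 & panel$old <= 1))
  expect_identical(rownames(panel$young), rownames(panel$old))
  expect_lte(max(abs(panel$true_effects$effect_size)), 0.05)

  # zero effect size: old means equal young means up to sampling noise
  p0 <- make_reference_panel(100, 50, 50, effect_sd = 0, seed = 6)
  expect_equal(p0$true_effects$effect_size, rep(0, 100))
  expect_lt(max(abs(rowMeans(p0$old) - rowMeans(p0$young))), 0.1)

  # forced hypermethylation: all recorded effects positive
  ph <- make_reference_panel(100, 10, 10, frac_hyper = 1, seed = 7)
  expect_true(all(ph$true_effects$effect_size > 0))

  expect_error(make_reference_panel(1, 10, 10), ">=")
  expect_error(make_reference_panel(100, 10, 10, effect_sd = 0.5,
                                    max_effect = 0.9),
               "censor")
})

test_that("empirical group differences recover the recorded truth", {
  panel <- make_reference_panel(353, n_young = 50, n_old = 50, seed = 11)
  emp <- rowMeans(panel$old) - rowMeans(panel$young)
  expect_gt(cor(emp, panel$true_effects$effect_size), 0.9)
})

test_that("aging cohorts honour null dynamics and age bounds", {
  panel <- shared_panel()
  params0 <- sim_params(5, 0)  # sigma = 0: no stochastic change
  co <- make_aging_cohort(panel, 10, c(45, 80), params0, seed = 3)
  # every sample equals its drawn young profile (up to transform round trip)
  drawn <- apply(co$betas, 2, function(b)
    min(apply(panel$young, 2, function(y) max(abs(y - b)))))
  expect_lt(max(drawn), 1e-9)
  expect_true(all(co$samples$age >= 45 & co$samples$age <= 80))
  expect_error(make_aging_cohort(panel, 10, c(30, 80), params0),
               "base_age")
})

test_that("nonstochastic offsets shift group means by the stated amount", {
  panel <- shared_panel()
  params <- sim_params(0, 0)  # isolate the nonstochastic component
  n <- 200
  male <- rep(c(0, 1), each = n / 2)
  offs <- c(rep(0.02, 50), rep(0, nrow(panel$young) - 50))
  co <- make_aging_cohort(panel, n, c(45, 46), params,
                          nonstochastic = list(list(name = "male",
                                                    offset = offs,
                                                    values = male)),
                          seed = 8)
  diff_means <- rowMeans(co$betas[1:50, male == 1]) -
    rowMeans(co$betas[1:50, male == 0])
  expect_lt(abs(mean(diff_means) - 0.02), 0.005)
  expect_equal(co$samples$male, male)
})

test_that("age-slope signs track true effect directions under pure accrual", {
  panel <- shared_panel()
  params <- sim_params(8, 0.002)
  co <- make_aging_cohort(panel, 150, c(45, 83), params, seed = 21)
  eff <- panel$true_effects$effect_size
  slopes <- apply(co$betas, 1, function(b) coef(lm(b ~ co$samples$age))[2])
  strong <- abs(eff) > 0.015  # above the noise floor
  agree <- mean(sign(slopes[strong]) == sign(eff[strong]))
  expect_gte(agree, 0.95)
})

test_that("cell fractions are exactly row-stochastic with stated shifts", {
  f <- make_cell_fractions(50, seed = 2)
  expect_equal(dim(f), c(50, 12))
  expect_true(all(f >= 0))
  expect_equal(unname(rowSums(f)), rep(1, 50), tolerance = 1e-12)
  expect_lt(max(abs(colMeans(f) - stocclock:::.default_fraction_base)), 0.02)

  # forced two-type shift
  g <- rep(c("A", "B"), each = 100)
  f2 <- make_cell_fractions(200, k = 2, base = c(0.5, 0.5),
                            group_deltas = list(A = c(0.1, -0.1)),
                            groups = g, seed = 3)
  expect_equal(mean(f2[g == "A", 1]), 0.6, tolerance = 0.02)
  expect_equal(mean(f2[g == "B", 1]), 0.5, tolerance = 0.02)

  # zero deltas: groups indistinguishable in expectation
  f3 <- make_cell_fractions(200, k = 3, base = rep(1, 3) / 3,
                            group_deltas = list(A = rep(0, 3)),
                            groups = g, seed = 4)
  expect_equal(colMeans(f3[g == "A", ]), colMeans(f3[g == "B", ]),
               tolerance = 0.03)

  expect_error(make_cell_fractions(10, k = 3, base = c(0.5, 0.2, 0.2)),
               "simplex")
})

test_that("cell shifts propagate to metadata fractions and betas", {
  panel <- shared_panel()
  params <- sim_params(0, 0)
  sig <- rep(0.5, nrow(panel$young))  # strong composition signature
  co <- make_aging_cohort(
    panel, 100, c(45, 46), params,
    cell_shift = list(groups = rep(c("M", "F"), each = 50),
                      deltas = list(M = c(0.1, -0.1, rep(0, 10))),
                      signature = sig),
    seed = 12)
  fcols <- grep("^frac_", names(co$samples))
  expect_length(fcols, 12)
  expect_equal(unname(rowSums(co$samples[, fcols])), rep(1, 100),
               tolerance = 1e-9)
  m_frac1 <- co$samples$frac_1[co$samples$group == "M"]
  f_frac1 <- co$samples$frac_1[co$samples$group == "F"]
  expect_gt(mean(m_frac1), mean(f_frac1))
  # betas shifted for the group with the raised fraction
  expect_gt(mean(co$betas[, co$samples$group == "M"]) -
              mean(co$betas[, co$samples$group == "F"]), 0.01)
})
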