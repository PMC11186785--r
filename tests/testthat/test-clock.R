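# Cohort generation, elastic-net clock training, and prediction.

make_cohorts <- function(panel, params, n = 2, ages = seq(45, 83, by = 2),
                         spa = 2, seed0 = 100) {
  lapply(seq_len(n), function(i)
    generate_cohort(panel, panel$true_effects, params, ages = ages,
                    samples_per_age = spa, seed = seed0 + i))
}

test_that("generate_cohort reproduces the protocol geometry", {
  panel <- shared_panel(60, seed = 31)
  params <- sim_params(8, 0.002)
  co <- generate_cohort(panel, panel$true_effects, params, ages = 45:83,
                        samples_per_age = 5, seed = 1)
  expect_equal(ncol(co$betas), 195)
  expect_equal(length(unique(co$ages)), 39)
  expect_true(all(co$betas > 0 & co$betas < 1))

  # determinism
  co2 <- generate_cohort(panel, panel$true_effects, params, ages = 45:83,
                         samples_per_age = 5, seed = 1)
  expect_identical(co$betas, co2$betas)

  # single sample at base age: identical to its drawn ground profile
  co1 <- generate_cohort(panel, panel$true_effects, params, ages = 45,
                         samples_per_age = 1, seed = 2)
  match_err <- min(apply(panel$young, 2, function(y)
    max(abs(y - co1$betas[, 1]))))
  expect_lt(match_err, 1e-9)
})

test_that("train_clock recovers a noiseless linear signal exactly", {
  # ages linearly encoded in two CpGs, no noise: selection RMSE ~ 0 at
  # lambda = 0 and training R^2 ~ 1
  ages <- rep(seq(40, 80, by = 2), each = 2)
  mk <- function(a) {
    b <- rbind(0.2 + a / 400, 0.9 - a / 400, 0.5 + 0 * a)
    dimnames(b) <- list(c("cg1", "cg2", "cg3"), sprintf("s%02d", seq_along(a)))
    b
  }
  tr <- list(betas = mk(ages), ages = ages)
  sel_ages <- rev(ages)
  se <- list(betas = mk(sel_ages), ages = sel_ages)
  expect_warning(
    model <- train_clock(tr, se, lambda_grid = seq(0, 1, by = 0.1)),
    "zero-variance")
  expect_equal(model$lambda, 0)
  expect_lt(min(model$lambda_rmse$rmse), 1e-3)
  expect_equal(unname(model$weights["cg3"]), 0)
  pred <- predict_age(model, tr$betas, mode = "frozen")
  expect_equal(unname(pred), ages, tolerance = 1e-4)
  expect_gt(cor(pred, ages)^2, 0.999)
})

test_that("the full lambda grid is fitted and the RMSE minimizer selected", {
  panel <- shared_panel(60, seed = 31)
  params <- sim_params(8, 0.002)
  cos_ <- make_cohorts(panel, params, 2)
  model <- train_clock(cos_[[1]], cos_[[2]])
  expect_equal(nrow(model$lambda_rmse), 1001)
  expect_equal(sort(model$lambda_rmse$lambda), seq(0, 1, by = 0.001),
               tolerance = 1e-12)
  # the stored lambda is the selection-RMSE minimizer (smallest on ties)
  lr <- model$lambda_rmse
  best <- min(lr$rmse)
  expect_equal(model$lambda, min(lr$lambda[lr$rmse <= best + 1e-12]))
  # (near-zero optimal lambda on the full protocol geometry is asserted in
  # the acceptance suite; this scaled-down cohort legitimately regularizes)
})

test_that("stochastic clock predicts simulated age on a fresh cohort", {
  panel <- shared_panel(60, seed = 31)
  params <- sim_params(8, 0.002)
  cos_ <- make_cohorts(panel, params, 3)
  model <- train_clock(cos_[[1]], cos_[[2]],
                       lambda_grid = seq(0, 1, by = 0.01))
  pred <- predict_age(model, cos_[[3]]$betas)
  ev <- evaluate_clock(pred, cos_[[3]]$ages)
  expect_gt(ev$pearson_r, 0.9)
})

test_that("prediction honours both standardization modes", {
  panel <- shared_panel(60, seed = 31)
  params <- sim_params(8, 0.002)
  cos_ <- make_cohorts(panel, params, 2)
  model <- train_clock(cos_[[1]], cos_[[2]],
                       lambda_grid = seq(0, 1, by = 0.01))

  # frozen stats on the training set reproduce fitted values exactly
  pred_tr <- predict_age(model, cos_[[1]]$betas, mode = "frozen")
  Z <- scale(t(cos_[[1]]$betas), center = model$train_mean,
             scale = model$train_sd)
  manual <- drop(model$intercept + Z %*% model$weights)
  expect_equal(unname(pred_tr), unname(manual), tolerance = 1e-12)

  # within-dataset mode: invariant to per-CpG affine shifts
  b <- cos_[[2]]$betas
  b_shift <- b
  b_shift[1, ] <- pmin(b_shift[1, ] + 0.1, 1)  # constant shift on one CpG
  expect_equal(predict_age(model, b_shift),
               predict_age(model, b), tolerance = 1e-9)
  b_scale <- (b - 0.1) * 0.5 + 0.2  # positive affine on all CpGs
  expect_equal(predict_age(model, b_scale), predict_age(model, b),
               tolerance = 1e-9)

  # all-zero weights predict the intercept
  m0 <- model
  m0$weights[] <- 0
  expect_equal(unname(predict_age(m0, b)),
               rep(m0$intercept, ncol(b)))

  # missing CpGs are named
  expect_error(predict_age(model, b[-1, , drop = FALSE]),
               rownames(b)[1])
  expect_error(predict_age(model, b[, 1:2], mode = "within"), ">= 3")
})

test_that("clock models round-trip through serialization", {
  panel <- shared_panel(60, seed = 31)
  params <- sim_params(8, 0.002)
  cos_ <- make_cohorts(panel, params, 2)
  model <- train_clock(cos_[[1]], cos_[[2]],
                       lambda_grid = seq(0, 1, by = 0.01))
  path <- withr::local_tempfile(fileext = ".csv")
  write_clock_model(model, path)
  expect_warning(back <- read_clock_coefficients(path), "transform")
  expect_equal(back$cpg_ids, model$cpg_ids)
  expect_equal(back$weights, model$weights)
  expect_equal(back$intercept, model$intercept)
  expect_equal(back$mode, model$mode)
  pred_a <- predict_age(model, cos_[[2]]$betas)
  pred_b <- predict_age(back, cos_[[2]]$betas)
  expect_equal(pred_a, pred_b, tolerance = 1e-6)
})

test_that("read_clock_coefficients handles third-party tables", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cpg_id,weight,annotation", "cg1,2.5,promoter", "cg2,-1,body"),
             path)
  expect_warning(expect_warning(
    m <- read_clock_coefficients(path, intercept = 50),
    "extra column"), "transform")
  expect_equal(m$intercept, 50)
  expect_equal(unname(m$weights), c(2.5, -1))
  # missing intercept is an error
  expect_error(suppressWarnings(read_clock_coefficients(path)), "intercept")
  # duplicate CpGs rejected
  writeLines(c("cpg_id,weight", "cg1,1", "cg1,2"), path)
  expect_error(suppressWarnings(read_clock_coefficients(path, intercept = 0)),
               "duplicate")
})
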