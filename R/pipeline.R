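# End-to-end orchestration: synthetic panel -> effect sizes -> (gamma, sigma)
# fit -> three artificial cohorts -> stochastic clock -> original clock on a
# synthetic real-aging cohort -> RR2 -> EAA/IAA. Plus a thin command-line
# front end.

#' Default pipeline configuration
#'
#' Left untouched, the defaults reproduce the reference protocol: a 353-CpG
#' panel with 43 young / 11 old samples, 35 steps per year from base age 45
#' to target age 82 (1,295 steps), three cohorts of five samples per age
#' over ages 45-83 (195 samples, 39 distinct ages), elastic net alpha 0.5
#' with lambda from 0 to 1 in steps of 0.001 (1,001 candidates), and
#' within-dataset standardization at application time.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @return a named list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    n_cpgs = 353, n_young = 43, n_old = 11,
    effect_sd = 0.02, frac_hyper = 0.5, noise_sd = 0.1,
    steps_per_year = 35, base_age = 45, target_age = 82,
    ages = 45:83, samples_per_age = 5,
    alpha = 0.5, lambda_step = 0.001,
    fit = list(resolution = 11, depth = 3, n_sim = 50),
    real = list(n = 195, age_range = c(45, 83), offset = 0.02,
                n_offset_cpgs = 50),
    standardization = "within"
  )
}

#' Scaled-down configuration for quick runs and tests
#' @inheritParams default_config
#' @export
demo_config <- function(seed = 1) {
  cfg <- default_config(seed)
  cfg$n_cpgs <- 80
  cfg$ages <- seq(45, 83, by = 2)
  cfg$samples_per_age <- 3
  cfg$lambda_step <- 0.01
  cfg$fit <- list(resolution = 5, depth = 2, n_sim = 10)
  cfg$real$n <- 60
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("[stage %s] %s", name, conditionMessage(e)))
}

#' Run the full pipeline into an output directory
#'
#' Deterministic given `config$seed`; writes the reference panel, effect
#' table, fit JSON, three cohort TSVs, the stochastic and original clock
#' files, evaluation JSONs, an RR2 CSV, an EAA/IAA table and a log of stage
#' seeds.
#'
#' @param config list from [default_config()] or [demo_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a manifest list of the main artifacts.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, ...)
  log_lines <- c(sprintf("stocclock pipeline seed=%d hash=%s", config$seed,
                         .tiny_hash(config)))
  logit <- function(fmt, ...) log_lines <<- c(log_lines, sprintf(fmt, ...))

  panel <- .stage("synth", {
    s <- derive_seed(config$seed, 1)
    logit("synth seed=%d", s)
    make_reference_panel(config$n_cpgs, config$n_young, config$n_old,
                         effect_sd = config$effect_sd,
                         frac_hyper = config$frac_hyper,
                         noise_sd = config$noise_sd, seed = s)
  })
  write_beta_matrix(panel$young, pth("panel_young.tsv"), "synth",
                    config$seed, config)
  write_beta_matrix(panel$old, pth("panel_old.tsv"), "synth",
                    config$seed, config)

  effects <- .stage("effects", estimate_effects(panel$young, panel$old))
  write_effect_table(effects, pth("effects.csv"))

  fit <- .stage("fit-params", {
    s <- derive_seed(config$seed, 2)
    logit("fit-params seed=%d", s)
    fit_parameters(effects, panel$old,
                   fit_config(resolution = config$fit$resolution,
                              depth = config$fit$depth,
                              n_sim = config$fit$n_sim, seed = s),
                   steps_per_year = config$steps_per_year,
                   base_age = config$base_age,
                   target_age = config$target_age)
  })
  write_fit_result(fit, pth("fit.json"))
  params <- sim_params(fit$gamma, fit$sigma, config$steps_per_year,
                       config$base_age)

  cohorts <- .stage("simulate-cohort", {
    lapply(setNames(1:3, c("train", "select", "test")), function(i) {
      s <- derive_seed(config$seed, 10 + i)
      logit("simulate-cohort %d seed=%d", i, s)
      generate_cohort(panel, effects, params, ages = config$ages,
                      samples_per_age = config$samples_per_age, seed = s)
    })
  })
  for (nm in names(cohorts))
    write_beta_matrix(cohorts[[nm]]$betas,
                      pth(sprintf("cohort_%s.tsv", nm)), "simulate-cohort",
                      config$seed, config)

  lambda_grid <- seq(0, 1, by = config$lambda_step)
  stoc_clock <- .stage("train-clock", {
    train_clock(cohorts$train, cohorts$select, alpha = config$alpha,
                lambda_grid = lambda_grid, mode = config$standardization)
  })
  write_clock_model(stoc_clock, pth("clock_stochastic.csv"))

  # synthetic "real" aging cohorts: stochastic accrual plus a deterministic
  # age-correlated nonstochastic component on a subset of CpGs
  real <- .stage("synth-real", {
    offs <- numeric(config$n_cpgs)
    idx <- seq_len(min(config$real$n_offset_cpgs, config$n_cpgs))
    offs[idx] <- config$real$offset
    # deterministic nonstochastic component scaling with age
    lapply(setNames(1:3, c("train", "select", "test")), function(i) {
      s <- derive_seed(config$seed, 20 + i)
      logit("synth-real %s seed=%d", i, s)
      ages_i <- .with_seed(derive_seed(s, 1),
                           round(runif(config$real$n,
                                       config$real$age_range[1],
                                       config$real$age_range[2]), 1))
      scale01 <- (ages_i - config$base_age) /
        diff(range(config$real$age_range))
      make_aging_cohort(
        panel, config$real$n, config$real$age_range, params,
        nonstochastic = list(list(name = "age_scaled", offset = offs,
                                  values = scale01)),
        seed = s, ages = ages_i)
    })
  })
  for (nm in names(real)) {
    write_beta_matrix(real[[nm]]$betas,
                      pth(sprintf("real_%s.tsv", nm)), "synth-real",
                      config$seed, config)
    write_sample_sheet(real[[nm]]$samples,
                       pth(sprintf("real_%s_samples.csv", nm)), "synth-real",
                       config$seed, config)
  }

  orig_clock <- .stage("train-clock-original", {
    train_clock(list(betas = real$train$betas, ages = real$train$samples$age),
                list(betas = real$select$betas,
                     ages = real$select$samples$age),
                alpha = config$alpha, lambda_grid = lambda_grid,
                mode = config$standardization)
  })
  write_clock_model(orig_clock, pth("clock_original.csv"))

  evals <- .stage("apply-clock", {
    true_age <- real$test$samples$age
    pred_s <- predict_age(stoc_clock, real$test$betas)
    pred_o <- predict_age(orig_clock, real$test$betas)
    list(stoc = evaluate_clock(pred_s, true_age),
         orig = evaluate_clock(pred_o, true_age))
  })
  jsonlite::write_json(
    lapply(evals, function(e) e[c("mae", "pearson_r", "r2", "p_value", "n")]),
    pth("evaluation.json"), auto_unbox = TRUE, digits = NA)

  record <- .stage("rr2", rr2(evals$stoc, evals$orig, cohort = "synthetic"))
  write.csv(data.frame(cohort = record$cohort, rr2 = record$rr2,
                       r2_stoc = record$r2_stoc, r2_orig = record$r2_orig,
                       n = record$n),
            pth("rr2.csv"), row.names = FALSE)

  accel <- .stage("accel", {
    pred_o <- predict_age(orig_clock, real$test$betas)
    data.frame(sample_id = real$test$samples$sample_id,
               eaa = eaa(pred_o, real$test$samples$age))
  })
  write.csv(accel, pth("acceleration.csv"), row.names = FALSE)

  writeLines(log_lines, pth("pipeline.log"))
  invisible(list(out_dir = out_dir, fit = fit, stoc_clock = stoc_clock,
                 orig_clock = orig_clock, evals = evals, rr2 = record))
}

# ---------------------------------------------------------------------------
# Command-line front end

.cli_opts <- function(args) {
  # parse --key value / --key=value pairs
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stopf("unexpected argument `%s`", a)
    if (grepl("=", a, fixed = TRUE)) {
      kv <- sub("^--", "", a)
      k <- sub("=.*$", "", kv)
      out[[k]] <- sub("^[^=]*=", "", kv)
      i <- i + 1L
    } else {
      k <- sub("^--", "", a)
      if (i == length(args)) stopf("missing value for --%s", k)
      out[[k]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}

.cli_num <- function(opts, key, default = NULL) {
  if (is.null(opts[[key]])) {
    if (is.null(default)) stopf("missing required option --%s", key)
    return(default)
  }
  as.numeric(opts[[key]])
}

#' Command-line entry point
#'
#' Subcommands: `synth`, `fit-params`, `simulate-cohort`, `train-clock`,
#' `apply-clock`, `rr2`, `accel`, `meta`, `run`. Every subcommand accepts
#' `--seed`. Invoke via `Rscript -e 'stocclock::stoc_cli()' -- <cmd> ...`
#' or the `inst/cli/stocclock` script.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   trailing command line).
#' @return invisibly, the subcommand's main result.
#' @export
stoc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stopf("usage: stocclock <subcommand> [--options]")
  cmd <- args[1]
  opts <- .cli_opts(args[-1])
  seed <- as.integer(.cli_num(opts, "seed", 1))

  res <- switch(
    cmd,
    "synth" = {
      panel <- make_reference_panel(.cli_num(opts, "n-cpgs", 353),
                                    .cli_num(opts, "n-young", 43),
                                    .cli_num(opts, "n-old", 11),
                                    seed = seed)
      out <- opts[["out"]] %||% "."
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_beta_matrix(panel$young, file.path(out, "panel_young.tsv"),
                        "synth", seed)
      write_beta_matrix(panel$old, file.path(out, "panel_old.tsv"),
                        "synth", seed)
      write_effect_table(panel$true_effects,
                         file.path(out, "true_effects.csv"))
      panel
    },
    "fit-params" = {
      young <- read_beta_matrix(opts[["young"]])
      old <- read_beta_matrix(opts[["old"]])
      fit <- fit_parameters(estimate_effects(young, old), old,
                            fit_config(seed = seed))
      write_fit_result(fit, opts[["out"]] %||% "fit.json")
      fit
    },
    "simulate-cohort" = {
      young <- read_beta_matrix(opts[["young"]])
      old <- read_beta_matrix(opts[["old"]])
      effects <- estimate_effects(young, old)
      panel <- structure(list(young = young, old = old,
                              true_effects = effects),
                         class = "reference_panel")
      params <- sim_params(.cli_num(opts, "gamma"), .cli_num(opts, "sigma"))
      co <- generate_cohort(panel, effects, params,
                            samples_per_age = .cli_num(opts,
                                                       "samples-per-age", 5),
                            seed = seed)
      write_beta_matrix(co$betas, opts[["out"]] %||% "cohort.tsv",
                        "simulate-cohort", seed)
      write_sample_sheet(data.frame(sample_id = colnames(co$betas),
                                    age = co$ages),
                         opts[["ages-out"]] %||% "cohort_samples.csv",
                         "simulate-cohort", seed)
      co
    },
    "train-clock" = {
      tr <- read_beta_matrix(opts[["train"]])
      tr_ages <- read_sample_sheet(opts[["train-ages"]])$age
      se <- read_beta_matrix(opts[["select"]])
      se_ages <- read_sample_sheet(opts[["select-ages"]])$age
      model <- train_clock(list(betas = tr, ages = tr_ages),
                           list(betas = se, ages = se_ages),
                           alpha = .cli_num(opts, "alpha", 0.5))
      write_clock_model(model, opts[["out"]] %||% "clock.csv")
      model
    },
    "apply-clock" = {
      model <- read_clock_coefficients(opts[["clock"]])
      betas <- read_beta_matrix(opts[["betas"]])
      pred <- predict_age(model, betas)
      sheet <- read_sample_sheet(opts[["ages"]])
      df <- data.frame(sample_id = colnames(betas), predicted = pred,
                       true = sheet$age[match(colnames(betas),
                                              sheet$sample_id)])
      write.csv(df, opts[["out"]] %||% "predictions.csv", row.names = FALSE)
      df
    },
    "rr2" = {
      rd <- function(p) read.csv(p, comment.char = "#")
      a <- rd(opts[["stoc"]]); b <- rd(opts[["orig"]])
      ev_a <- evaluate_clock(a$predicted, a$true)
      ev_b <- evaluate_clock(b$predicted, b$true)
      rec <- rr2(ev_a, ev_b)
      jsonlite::write_json(list(stoc = unclass(ev_a), orig = unclass(ev_b),
                                rr2 = rec$rr2),
                           opts[["out"]] %||% "rr2.json",
                           auto_unbox = TRUE, digits = NA)
      rec
    },
    "accel" = {
      pred <- read.csv(opts[["predictions"]], comment.char = "#")
      sheet <- read_sample_sheet(opts[["samples"]])
      sheet <- sheet[match(pred$sample_id, sheet$sample_id), ]
      out <- data.frame(sample_id = pred$sample_id,
                        eaa = eaa(pred$predicted, sheet$age))
      fcols <- grep("^frac_", names(sheet), value = TRUE)
      if (length(fcols))
        out$iaa <- iaa(pred$predicted, sheet$age,
                       as.matrix(sheet[, fcols]))
      write.csv(out, opts[["out"]] %||% "acceleration.csv",
                row.names = FALSE)
      out
    },
    "meta" = {
      df <- read.csv(opts[["ratios"]], comment.char = "#")
      wide <- split(df, df$clock)
      if (length(wide) != 2) stopf("ratios file must contain 2 clocks")
      a <- wide[[1]][order(wide[[1]]$cohort), ]
      b <- wide[[2]][order(wide[[2]]$cohort), ]
      res <- meta_compare(a$rr2, b$rr2, n = a$n)
      jsonlite::write_json(res, opts[["out"]] %||% "meta.json",
                           auto_unbox = TRUE, digits = NA)
      res
    },
    "run" = {
      cfg <- if (identical(opts[["config"]], "demo")) demo_config(seed)
             else default_config(seed)
      run_pipeline(cfg, opts[["out"]] %||% "stocclock_run")
    },
    stopf("unknown subcommand `%s`", cmd)
  )
  invisible(res)
}
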