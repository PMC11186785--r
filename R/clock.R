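# Training elastic-net clocks on simulated (or real) cohorts, with
# RMSE-based model selection on an independent cohort, and applying clocks
# to new beta matrices under two standardization modes.

#' Generate an artificial cohort from the fitted simulator
#'
#' For every (age, replicate) pair, a starting profile is drawn uniformly
#' from the young pool and aged by the stochastic simulator. With the default
#' `ages = 45:83` and `samples_per_age = 5` this yields the protocol cohort
#' of 195 samples over 39 distinct age values.
#'
#' @param panel a `reference_panel` (its young samples form the start pool).
#' @param effects an `effect_table` driving the simulator.
#' @param params a `sim_params`.
#' @param ages vector of distinct ages (years), all `>= base_age`.
#' @param samples_per_age replicates per age value.
#' @param seed integer seed; per-sample seeds are derived from it, so the
#'   cohort is reproducible.
#' @return object of class `aging_cohort`: `betas` (CpGs x samples), `ages`,
#'   and `provenance` (seed and young-pool draw indices).
#' @export
generate_cohort <- function(panel, effects, params, ages = 45:83,
                            samples_per_age = 5, seed = 1) {
  stopifnot(inherits(panel, "reference_panel"), inherits(params, "sim_params"))
  effects <- .as_effect_table(effects)
  samples_per_age <- .check_count(samples_per_age, "samples_per_age", min = 1)
  if (!ncol(panel$young)) stopf("young pool is empty")
  if (any(ages < params$base_age)) stopf("ages below base_age")
  ages_all <- rep(sort(unique(ages)), each = samples_per_age)
  n <- length(ages_all)
  cpgs <- effects$cpg_id
  draw_idx <- .with_seed(seed, sample(ncol(panel$young), n, replace = TRUE))
  betas <- matrix(NA_real_, nrow = length(cpgs), ncol = n,
                  dimnames = list(cpgs, sprintf("sim_%03d", seq_len(n))))
  for (i in seq_len(n)) {
    betas[, i] <- simulate_sample(panel$young[cpgs, draw_idx[i]], effects,
                                  params, ages_all[i],
                                  seed = derive_seed(seed, i))
  }
  structure(list(betas = betas, ages = ages_all,
                 provenance = list(seed = seed, draw_idx = draw_idx,
                                   params = params)),
            class = "aging_cohort")
}

#' @export
print.aging_cohort <- function(x, ...) {
  cat(sprintf("aging_cohort: %d CpGs x %d samples, ages %g-%g (%d distinct)\n",
              nrow(x$betas), ncol(x$betas), min(x$ages), max(x$ages),
              length(unique(x$ages))))
  invisible(x)
}

.cohort_xy <- function(cohort, name) {
  if (inherits(cohort, "aging_cohort"))
    return(list(betas = cohort$betas, ages = cohort$ages))
  if (is.list(cohort) && !is.null(cohort$betas) && !is.null(cohort$ages))
    return(list(betas = cohort$betas, ages = cohort$ages))
  stopf("`%s` must be an aging_cohort or a list(betas, ages)", name)
}

#' Train an elastic-net clock with held-out model selection
#'
#' Per-CpG beta-values are standardized to mean 0, SD 1 on the training set
#' (this removes baseline DNAm differences between cell types), then one
#' elastic-net model is fitted per lambda on the grid (alpha fixed, default
#' 0.5). Every candidate is evaluated on the selection cohort by RMSE under
#' the chosen application-time standardization mode, and the minimizer is
#' returned, ties broken toward the smallest lambda. Zero-variance training
#' CpGs are excluded from the fit and carry weight 0 (with a warning).
#'
#' @param train,select cohorts (`aging_cohort` or `list(betas, ages)`)
#'   sharing the same CpGs.
#' @param alpha elastic-net mixing parameter, default 0.5.
#' @param lambda_grid penalty grid; default `seq(0, 1, by = 0.001)` (1,001
#'   values). Lambda values follow glmnet's parameterization and are
#'   comparable only within this package; selection is by RMSE, not by the
#'   lambda value itself.
#' @param mode application-time standardization stored in the model:
#'   `"within"` (default) z-scores each CpG inside the evaluation dataset,
#'   `"frozen"` reuses the training statistics.
#' @return object of class `clock_model`: `cpg_ids`, `weights` (named, zeros
#'   allowed), `intercept`, `alpha`, `lambda`, `lambda_rmse` (selection RMSE
#'   per candidate), `train_mean`, `train_sd`, `mode`.
#' @export
train_clock <- function(train, select, alpha = 0.5,
                        lambda_grid = seq(0, 1, by = 0.001),
                        mode = c("within", "frozen")) {
  mode <- match.arg(mode)
  tr <- .cohort_xy(train, "train")
  se <- .cohort_xy(select, "select")
  if (!identical(rownames(tr$betas), rownames(se$betas)))
    stopf("train and select cohorts must share the same CpGs (same order)")
  if (length(unique(tr$ages)) < 2) stopf("training ages are degenerate")
  if (any(lambda_grid < 0)) stopf("`lambda_grid` must be nonnegative")

  X <- t(tr$betas)
  y <- as.numeric(tr$ages)
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  keep <- sdev > 0
  if (!all(keep))
    warnf("%d zero-variance CpG(s) excluded from the fit (weight 0)",
          sum(!keep))
  if (sum(keep) < 2) stopf("fewer than 2 CpGs with variance in training data")
  Xs <- scale(X[, keep, drop = FALSE], center = mu[keep], scale = sdev[keep])

  grid <- sort(unique(as.numeric(lambda_grid)), decreasing = TRUE)
  fit <- glmnet::glmnet(Xs, y, alpha = alpha, lambda = grid,
                        standardize = FALSE)

  # selection-set predictors standardized under the stored application mode
  Zs <- .standardize_eval(se$betas[rownames(tr$betas), , drop = FALSE][keep, ,
                                                                      drop = FALSE],
                          mode, mu[keep], sdev[keep])
  preds <- predict(fit, newx = t(Zs))
  rmse <- sqrt(colMeans((preds - as.numeric(se$ages))^2))
  fitted_lambda <- fit$lambda
  # minimum RMSE, ties toward the smallest lambda
  best_rmse <- min(rmse)
  cand <- which(rmse <= best_rmse + 1e-12)
  j <- cand[which.min(fitted_lambda[cand])]

  beta <- as.numeric(coef(fit)[, j])
  weights <- setNames(rep(0, ncol(X)), colnames(X))
  weights[keep] <- beta[-1]

  structure(list(
    cpg_ids = rownames(tr$betas),
    weights = weights,
    intercept = beta[1],
    alpha = alpha,
    lambda = fitted_lambda[j],
    lambda_rmse = data.frame(lambda = fitted_lambda, rmse = as.numeric(rmse)),
    train_mean = setNames(mu, colnames(X)),
    train_sd = setNames(sdev, colnames(X)),
    mode = mode
  ), class = "clock_model")
}

.standardize_eval <- function(betas, mode, train_mean, train_sd) {
  if (mode == "frozen") {
    sdv <- ifelse(train_sd > 0, train_sd, 1)
    return((betas - train_mean) / sdv)
  }
  if (ncol(betas) < 3)
    stopf("within-dataset standardization needs >= 3 samples")
  mu <- rowMeans(betas)
  sdv <- apply(betas, 1, sd)
  sdv[sdv == 0] <- Inf  # constant CpGs contribute 0 after z-scoring
  (betas - mu) / sdv
}

#' Predict age with a clock model
#'
#' Standardizes each CpG's beta-values (within the evaluation dataset by
#' default, which makes predictions invariant to per-CpG location/scale
#' shifts such as cell-type baseline differences; or with frozen training
#' statistics) and applies the linear model.
#'
#' @param model a `clock_model`.
#' @param betas beta matrix (CpGs x samples) containing all model CpGs.
#' @param mode override of the model's standardization mode.
#' @return named numeric vector of predicted ages.
#' @export
predict_age <- function(model, betas, mode = NULL) {
  stopifnot(inherits(model, "clock_model"))
  if (is.null(mode)) mode <- model$mode
  mode <- match.arg(mode, c("within", "frozen"))
  if (!is.matrix(betas) || is.null(rownames(betas)))
    stopf("`betas` must be a matrix with CpG rownames")
  miss <- setdiff(model$cpg_ids, rownames(betas))
  if (length(miss))
    stopf("betas missing %d model CpG(s): %s", length(miss),
          paste(head(miss, 5), collapse = ", "))
  B <- betas[model$cpg_ids, , drop = FALSE]
  Z <- .standardize_eval(B, mode, model$train_mean[model$cpg_ids],
                         model$train_sd[model$cpg_ids])
  drop(model$intercept + crossprod(Z, model$weights[model$cpg_ids]))[colnames(betas)] ->
    out
  setNames(as.numeric(out), colnames(betas))
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf(
    "clock_model: %d CpGs (%d nonzero), alpha=%g, lambda=%g, mode=%s\n",
    length(x$weights), sum(x$weights != 0), x$alpha, x$lambda, x$mode))
  invisible(x)
}

#' Write a clock model to disk
#'
#' Single-file format: a `#json:` header line carrying intercept, alpha,
#' lambda and standardization mode, followed by a CSV of per-CpG weight and
#' training statistics.
#'
#' @param model a `clock_model`.
#' @param path output file.
#' @export
write_clock_model <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  hdr <- jsonlite::toJSON(list(intercept = model$intercept,
                               alpha = model$alpha, lambda = model$lambda,
                               mode = model$mode),
                          auto_unbox = TRUE, digits = NA)
  df <- data.frame(cpg_id = model$cpg_ids,
                   weight = as.numeric(model$weights[model$cpg_ids]),
                   train_mean = as.numeric(model$train_mean[model$cpg_ids]),
                   train_sd = as.numeric(model$train_sd[model$cpg_ids]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#json:", hdr), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read clock coefficients (own or third-party format)
#'
#' Reads the single-file format written by [write_clock_model()], or a plain
#' coefficient CSV with columns `cpg_id` and `weight` (plus optional
#' `train_mean`/`train_sd`, enabling frozen standardization) and an
#' `intercept` supplied as argument or as an extra column. Published clocks
#' that apply an age transform after the linear predictor (e.g. log-linear
#' under age 20) are not transformed here; a warning flags this on import.
#'
#' @param path input file.
#' @param intercept intercept value when the file does not carry one.
#' @param alpha,lambda metadata defaults when absent from the file.
#' @return a `clock_model`.
#' @export
read_clock_coefficients <- function(path, intercept = NULL, alpha = NA_real_,
                                    lambda = NA_real_) {
  first <- readLines(path, n = 1)
  meta <- list(intercept = intercept, alpha = alpha, lambda = lambda,
               mode = "within")
  if (startsWith(first, "#json:")) {
    meta <- utils::modifyList(meta,
                              jsonlite::fromJSON(sub("^#json:", "", first)))
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("cpg_id", "weight") %in% names(df)))
    stopf("coefficient file needs columns cpg_id, weight")
  if (anyDuplicated(df$cpg_id)) stopf("duplicate CpGs in coefficient file")
  if ("intercept" %in% names(df) && is.null(meta$intercept))
    meta$intercept <- df$intercept[1]
  if (is.null(meta$intercept))
    stopf("no intercept in file or argument")
  extra <- setdiff(names(df),
                   c("cpg_id", "weight", "train_mean", "train_sd", "intercept"))
  if (length(extra))
    warnf("ignoring extra column(s): %s", paste(extra, collapse = ", "))
  has_stats <- all(c("train_mean", "train_sd") %in% names(df))
  if (!has_stats && identical(meta$mode, "frozen"))
    stopf("frozen mode requires train_mean/train_sd columns")
  warnf(paste("imported coefficients are applied as a raw linear model;",
              "any published age transform is NOT applied"))
  structure(list(
    cpg_ids = as.character(df$cpg_id),
    weights = setNames(as.numeric(df$weight), df$cpg_id),
    intercept = as.numeric(meta$intercept),
    alpha = as.numeric(meta$alpha),
    lambda = as.numeric(meta$lambda),
    lambda_rmse = NULL,
    train_mean = if (has_stats) setNames(as.numeric(df$train_mean), df$cpg_id)
                 else setNames(rep(NA_real_, nrow(df)), df$cpg_id),
    train_sd = if (has_stats) setNames(as.numeric(df$train_sd), df$cpg_id)
               else setNames(rep(NA_real_, nrow(df)), df$cpg_id),
    mode = if (has_stats) meta$mode else "within"
  ), class = "clock_model")
}
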