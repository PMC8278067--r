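#' Sampler configuration for the hierarchical RL models
#'
#' Defaults: 4 chains of 2000 iterations, half warm-up (the heavier 6 x
#' 10,000 configuration is reserved for the diffusion model, see
#' [ddm_sampler_config()]). All chains derive their RNG stream from `seed`.
#'
#' @param chains,iter,warmup MCMC settings.
#' @param seed Integer seed.
#' @param prior_mu_sd,prior_sigma_sd Standard-normal-style prior scales for
#'   the population locations and (half-normal) scales on the
#'   unconstrained scale.
#' @param save_loglik Keep pointwise log likelihoods (needed for
#'   [compare_models()]).
#' @return A list of class `rl_sampler_config`.
#' @export
rl_sampler_config <- function(chains = 4L, iter = 2000L, warmup = iter %/% 2L,
                              seed = 1L, prior_mu_sd = 1, prior_sigma_sd = 1,
                              save_loglik = TRUE) {
  stopifnot(chains >= 1L, iter > warmup, warmup >= 1L)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 prior_mu_sd = prior_mu_sd, prior_sigma_sd = prior_sigma_sd,
                 save_loglik = isTRUE(save_loglik)),
            class = "rl_sampler_config")
}

# records -> integer arrays for the C++ backend; subjects sorted and
# 0-indexed, trials ordered within subject.
rl_prepare_data <- function(records) {
  need <- c("participant_id", "trial", "interactant", "target_expression",
            "response", "correct")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  if (any(is.na(records$response))) stop("no-response trials must be filtered out")
  records <- records[order(records$participant_id, records$trial), , drop = FALSE]
  ids <- unique(records$participant_id)
  list(subj = as.integer(factor(records$participant_id, levels = ids)) - 1L,
       inter = as.integer(records$interactant) - 1L,
       expr = as.integer(records$target_expression == "frown"),
       choice = as.integer(records$response == records$target_expression),
       r = ifelse(records$correct == 1L, 1, -1),
       ids = ids, n_subjects = length(ids), records = records)
}

rl_transform_pop <- function(mu, type) {
  switch(type,
         unit = stats::plogis(mu),
         temp = 2 * stats::plogis(mu),
         mu)
}

#' Fit an RL model hierarchically by MCMC
#'
#' Subject-level parameters are modelled non-centrally as deviations from a
#' population average on an unconstrained scale (logistic transform to
#' \[0,1\] for learning rates, doubled logistic to (0,2) for temperatures,
#' identity for bias terms), with standard normal priors throughout and
#' half-normal priors on the population scales. Sampling is componentwise
#' slice sampling within Gibbs (compiled); chains are independent and
#' seeded. Population parameters with split R-hat above 1.05 are flagged in
#' `$converged`, never silently accepted.
#'
#' @param records Filtered multi-subject records (>= 2 participants).
#' @param model An [rl_model_spec()].
#' @param config An [rl_sampler_config()].
#' @return An object of class `rl_fit` with elements `draws` (iterations x
#'   chains x parameters array; includes natural-scale population locations
#'   `pop_*`), `summary`, `loglik` (draws x trials matrix or `NULL`),
#'   `model`, `data`, `config`, `converged`.
#' @export
fit_rl_hierarchical <- function(records, model = rl_model_spec("copy_bias"),
                                config = rl_sampler_config()) {
  dat <- rl_prepare_data(records)
  if (dat$n_subjects < 2L) stop("need at least 2 participants")
  P <- length(model$params)
  n_keep <- config$iter - config$warmup
  par_names <- c(paste0("mu_", model$params),
                 paste0("sigma_", model$params),
                 paste0(rep(model$params, dat$n_subjects), "[",
                        rep(seq_len(dat$n_subjects), each = P), "]"))
  chains <- vector("list", config$chains)
  loglik <- NULL
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + 1000L * ch)
    res <- rl_sampler_cpp(dat$subj, dat$inter, dat$expr, dat$choice, dat$r,
                          dat$n_subjects, model$code,
                          config$iter, config$warmup, config$save_loglik,
                          rep(config$prior_mu_sd, P),
                          rep(config$prior_sigma_sd, P),
                          1.0, 20L)
    chains[[ch]] <- res$draws
    if (config$save_loglik)
      loglik <- rbind(loglik, res$loglik)
  }
  draws <- array(NA_real_, dim = c(n_keep, config$chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  for (ch in seq_len(config$chains)) draws[, ch, ] <- chains[[ch]]
  # derived: population locations on the natural scale
  pop <- array(NA_real_, dim = c(n_keep, config$chains, P),
               dimnames = list(NULL, NULL, paste0("pop_", model$params)))
  for (p in seq_len(P))
    pop[, , p] <- rl_transform_pop(draws[, , p, drop = FALSE], model$types[p])
  all_draws <- array(c(draws, pop),
                     dim = c(n_keep, config$chains, length(par_names) + P),
                     dimnames = list(NULL, NULL,
                                     c(par_names, dimnames(pop)[[3]])))
  summ <- summarize_draws(all_draws)
  pop_rows <- grepl("^(mu_|sigma_|pop_)", summ$parameter)
  converged <- all(summ$rhat[pop_rows] < 1.05, na.rm = TRUE)
  if (!converged)
    warning("population-level R-hat above 1.05; treat estimates with caution")
  structure(list(draws = all_draws, summary = summ, loglik = loglik,
                 model = model, data = dat, config = config,
                 converged = converged),
            class = "rl_fit")
}

#' @export
print.rl_fit <- function(x, ...) {
  cat(sprintf("Hierarchical RL fit: model '%s', %d subjects, %d x %d draws%s\n",
              x$model$name, x$data$n_subjects, dim(x$draws)[1],
              dim(x$draws)[2],
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$summary[grepl("^pop_|^sigma_", x$summary$parameter), ], digits = 3)
  invisible(x)
}

# flat (draws*chains) x P matrix of one subject's natural parameters
rl_subject_draws <- function(fit, s) {
  P <- length(fit$model$params)
  cols <- paste0(fit$model$params, "[", s, "]")
  m <- sapply(cols, function(cn) as.vector(fit$draws[, , cn]))
  matrix(m, ncol = P, dimnames = list(NULL, fit$model$params))
}

#' Compare RL models by PSIS-LOO
#'
#' Fits each model to the same data and ranks them by approximate
#' leave-one-out expected log predictive density ([psis_loo()]). Ties
#' (criterion differences within one standard error of the difference) are
#' reported, not broken silently; observations with unreliable importance
#' weights are counted per model.
#'
#' @param records Filtered multi-subject records.
#' @param models List of [rl_model_spec()] objects (or names).
#' @param config An [rl_sampler_config()]; `save_loglik` is forced on.
#' @return A `rl_model_comparison`: data frame `table` (one row per model,
#'   best first, with `elpd_loo`, `se`, `elpd_diff`, `se_diff`, `tied`),
#'   plus the fitted objects in `$fits`.
#' @export
compare_models <- function(records, models, config = rl_sampler_config()) {
  config$save_loglik <- TRUE
  models <- lapply(models, function(m)
    if (inherits(m, "rl_model_spec")) m else rl_model_spec(m))
  fits <- lapply(models, function(m) fit_rl_hierarchical(records, m, config))
  loos <- lapply(fits, function(f) psis_loo(f$loglik))
  elpd <- vapply(loos, `[[`, numeric(1), "elpd_loo")
  ord <- order(elpd, decreasing = TRUE)
  best <- ord[1]
  tab <- do.call(rbind, lapply(ord, function(i) {
    diff_i <- loos[[i]]$pointwise - loos[[best]]$pointwise
    se_diff <- sqrt(length(diff_i) * stats::var(diff_i))
    data.frame(model = models[[i]]$name,
               elpd_loo = loos[[i]]$elpd_loo, se = loos[[i]]$se,
               p_loo = loos[[i]]$p_loo,
               elpd_diff = sum(diff_i), se_diff = se_diff,
               n_flagged = loos[[i]]$n_flagged,
               tied = i != best & abs(sum(diff_i)) <= se_diff,
               stringsAsFactors = FALSE)
  }))
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, loos = loos),
            class = "rl_model_comparison")
}

#' @export
print.rl_model_comparison <- function(x, ...) {
  cat("Model comparison (PSIS-LOO, best first):\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Posterior-predictive learning curves
#'
#' Simulates each participant's schedule forward from their posterior
#' parameter draws (`n_sims_per_draw` runs per draw) and aggregates
#' predicted correct-response rates by condition role and relative trial
#' number: `CI` is the interactant requiring congruent responses before the
#' reversal and incongruent after, `IC` the reverse. The two clips of an
#' interactant share relative trial numbers 1..2*reps (reps+1 = first trial
#' after reversal). The intervals are the average across participants of
#' each participant's central 80 percent predictive interval.
#'
#' @param fit An `rl_fit`.
#' @param n_sims_per_draw Simulations per retained posterior draw.
#' @param n_draws Number of posterior draws used (subsampled evenly).
#' @param seed Integer seed for the simulations.
#' @return Data frame with columns `condition` ("CI"/"IC"), `cond_trial`,
#'   `mean_cr`, `lo80`, `hi80`.
#' @export
posterior_predict <- function(fit, n_sims_per_draw = 100L, n_draws = 200L,
                              seed = 1L) {
  records <- fit$data$records
  records <- add_condition_trial(records)
  n_rel <- max(records$cond_trial)
  ncell <- 2L * n_rel
  total <- dim(fit$draws)[1] * dim(fit$draws)[2]
  use <- unique(round(seq(1, total, length.out = min(n_draws, total))))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed)
  mean_mat <- matrix(0, length(fit$data$ids), ncell)
  lo_mat <- hi_mat <- matrix(NA_real_, length(fit$data$ids), ncell)
  for (s in seq_along(fit$data$ids)) {
    rec <- records[records$participant_id == fit$data$ids[s], , drop = FALSE]
    # role of each trial's interactant: CI if congruent in block 1
    b1 <- rec[rec$block == 1, ]
    ci_inter <- unique(b1$interactant[b1$condition == "congruent"])
    role_ci <- rec$interactant %in% ci_inter
    cellid <- as.integer(ifelse(role_ci, 0L, n_rel) + rec$cond_trial - 1L)
    theta <- rl_subject_draws(fit, s)[use, , drop = FALSE]
    cr <- rl_predict_cpp(theta, fit$model$code,
                         as.integer(rec$interactant) - 1L,
                         as.integer(rec$target_expression == "frown"),
                         as.integer(rec$condition == "congruent"),
                         cellid, ncell, as.integer(n_sims_per_draw))
    q_safe <- function(v, p)
      if (all(is.na(v))) NA_real_ else unname(stats::quantile(v, p, na.rm = TRUE))
    mean_mat[s, ] <- colMeans(cr, na.rm = TRUE)
    lo_mat[s, ] <- apply(cr, 2, q_safe, 0.1)
    hi_mat[s, ] <- apply(cr, 2, q_safe, 0.9)
  }
  data.frame(condition = rep(c("CI", "IC"), each = n_rel),
             cond_trial = rep(seq_len(n_rel), 2L),
             mean_cr = colMeans(mean_mat, na.rm = TRUE),
             lo80 = colMeans(lo_mat, na.rm = TRUE),
             hi80 = colMeans(hi_mat, na.rm = TRUE),
             stringsAsFactors = FALSE)
}
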