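#' Sampler configuration for the hierarchical DDM
#'
#' The default mirrors the full-scale analysis (6 chains of 10,000
#' iterations, 1000 warm-up); `fast = TRUE` gives a reduced desk-scale
#' configuration suitable for tests and smoke runs.
#'
#' @param chains,iter,warmup MCMC settings.
#' @param seed Integer seed.
#' @param prior_mu_sd Prior sd for the 11 population locations (v cells,
#'   log-a cells, logit-z, logit-t0), on the unconstrained scale.
#' @param prior_sigma_sd Half-normal prior sd for the population scales.
#' @param fast Use the reduced configuration (2 chains x 1500, 500 warmup).
#' @return List of class `ddm_sampler_config`.
#' @export
ddm_sampler_config <- function(chains = 6L, iter = 10000L, warmup = 1000L,
                               seed = 1L,
                               prior_mu_sd = c(rep(2, 4), rep(1, 7)),
                               prior_sigma_sd = rep(1, 11),
                               fast = FALSE) {
  if (fast) { chains <- 2L; iter <- 1500L; warmup <- 500L }
  stopifnot(chains >= 1L, iter > warmup)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 prior_mu_sd = prior_mu_sd, prior_sigma_sd = prior_sigma_sd),
            class = "ddm_sampler_config")
}

DDM_CELLS <- c("ss", "sf", "fs", "ff")
ddm_slot_names <- c(paste0("v_", DDM_CELLS), paste0("a_", DDM_CELLS),
                    "z_s", "z_f", "t0")

ddm_prepare_data <- function(records) {
  need <- c("participant_id", "response", "rt_ms", "target_expression",
            "correct_response")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  if (any(is.na(records$response))) stop("no-response trials must be filtered out")
  records <- records[order(records$participant_id, records$trial), , drop = FALSE]
  ids <- unique(records$participant_id)
  cell <- ddm_cell(records$target_expression, records$correct_response)
  list(subj = as.integer(factor(records$participant_id, levels = ids)) - 1L,
       cell = match(cell, DDM_CELLS) - 1L,
       expr = as.integer(records$target_expression == "frown"),
       upper = as.integer(records$response == "smile"),
       rt = records$rt_ms / 1000,
       ids = ids, n_subjects = length(ids), records = records)
}

#' Fit the response-coded hierarchical Wiener diffusion model
#'
#' Cell-means parameterization over the 2 x 2 target-expression by
#' required-response design: drift and boundary separation per cell, start
#' bias per target expression, one non-decision time per subject. All
#' parameters vary by participant as non-centered deviations from
#' population averages (identity scale for v, log for a, logit for z;
#' t0 is a logit fraction of 95 percent of the subject's fastest RT, which
#' guarantees rt > t0 in every draw). Fitting is componentwise slice
#' sampling within Gibbs; unconverged population parameters (split R-hat >
#' 1.05) are flagged.
#'
#' @param records Filtered records (RT in ms, >= 2 participants).
#' @param config A [ddm_sampler_config()].
#' @return Object of class `ddm_fit` with `draws` (iterations x chains x
#'   parameters, including natural-scale population cell means `pop_*`),
#'   `summary`, `data`, `config`, `converged`.
#' @export
fit_ddm_hierarchical <- function(records,
                                 config = ddm_sampler_config(fast = TRUE)) {
  dat <- ddm_prepare_data(records)
  if (dat$n_subjects < 2L) stop("need at least 2 participants")
  P <- 11L
  n_keep <- config$iter - config$warmup
  par_names <- c(paste0("mu_", ddm_slot_names),
                 paste0("sigma_", ddm_slot_names),
                 paste0(rep(ddm_slot_names, dat$n_subjects), "[",
                        rep(seq_len(dat$n_subjects), each = P), "]"))
  mu_init <- c(rep(0, 4), rep(log(1.5), 4), 0, 0, -1)
  sigma_init <- rep(0.3, P)
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + 1000L * ch)
    res <- ddm_sampler_cpp(dat$subj, dat$cell, dat$expr, dat$upper, dat$rt,
                           dat$n_subjects, config$iter, config$warmup,
                           config$prior_mu_sd, config$prior_sigma_sd,
                           mu_init, sigma_init, 1e-7, 1.0, 20L)
    chains[[ch]] <- res$draws
    if (ch == 1L) t0_max <- res$t0_max
  }
  draws <- array(NA_real_, dim = c(n_keep, config$chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  for (ch in seq_len(config$chains)) draws[, ch, ] <- chains[[ch]]
  # natural-scale population cell means
  pop_names <- paste0("pop_", ddm_slot_names[1:10])
  pop <- array(NA_real_, dim = c(n_keep, config$chains, 10L),
               dimnames = list(NULL, NULL, pop_names))
  for (p in 1:4)  pop[, , p] <- draws[, , p, drop = FALSE]
  for (p in 5:8)  pop[, , p] <- exp(draws[, , p, drop = FALSE])
  for (p in 9:10) pop[, , p] <- stats::plogis(draws[, , p, drop = FALSE])
  all_draws <- array(c(draws, pop),
                     dim = c(n_keep, config$chains, length(par_names) + 10L),
                     dimnames = list(NULL, NULL, c(par_names, pop_names)))
  summ <- summarize_draws(all_draws)
  pop_rows <- grepl("^(mu_|sigma_|pop_)", summ$parameter)
  converged <- all(summ$rhat[pop_rows] < 1.05, na.rm = TRUE)
  if (!converged)
    warning("population-level R-hat above 1.05; treat estimates with caution")
  structure(list(draws = all_draws, summary = summ, data = dat,
                 config = config, t0_max = t0_max, converged = converged),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("Hierarchical DDM fit: %d subjects, %d x %d draws%s\n",
              x$data$n_subjects, dim(x$draws)[1], dim(x$draws)[2],
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$summary[grepl("^pop_", x$summary$parameter), ], digits = 3)
  invisible(x)
}

#' Flat matrix of population-level DDM draws
#'
#' @param fit A `ddm_fit`.
#' @return (draws x 10) matrix with columns `v_ss..v_ff`, `a_ss..a_ff`,
#'   `z_s`, `z_f` on the natural scale; the input format expected by the
#'   contrast functions.
#' @export
ddm_population_draws <- function(fit) {
  cols <- paste0("pop_", ddm_slot_names[1:10])
  m <- sapply(cols, function(cn) as.vector(fit$draws[, , cn]))
  colnames(m) <- ddm_slot_names[1:10]
  m
}

#' Posterior contrast summary
#'
#' @param x Numeric vector of per-draw contrast values.
#' @return List of class `contrast_summary`: `mean`, `cri_95` (2.5 and
#'   97.5 percent quantiles), `fraction_positive`.
#' @export
contrast_summary <- function(x) {
  cri <- unname(stats::quantile(x, c(0.025, 0.975)))
  structure(list(mean = mean(x), cri_95 = cri,
                 fraction_positive = mean(x > 0)),
            class = "contrast_summary")
}

#' @export
print.contrast_summary <- function(x, ...) {
  cat(sprintf("%.2f, 95%% CrI = [%.2f, %.2f], %.1f%% of posterior mass positive\n",
              x$mean, x$cri_95[1], x$cri_95[2], 100 * x$fraction_positive))
  invisible(x)
}

#' Congruency contrast on absolute drift rates
#'
#' Per posterior draw, takes the absolute drift in each design cell and
#' contrasts congruent against incongruent cells:
#' `(|v_ss| + |v_ff|) - (|v_sf| + |v_fs|)` (sum variant) and its half (the
#' per-condition-mean variant). Both are reported because the sum of two
#' cell differences is sometimes described as an "average difference".
#'
#' @param draws A `ddm_fit` or a draws matrix as from
#'   [ddm_population_draws()] (columns `v_ss`, `v_sf`, `v_fs`, `v_ff`).
#' @return List with `contrast_summary` elements `sum` and `mean`.
#' @export
contrast_drift_congruency <- function(draws) {
  m <- if (inherits(draws, "ddm_fit")) ddm_population_draws(draws) else draws
  d <- (abs(m[, "v_ss"]) + abs(m[, "v_ff"])) -
       (abs(m[, "v_sf"]) + abs(m[, "v_fs"]))
  list(sum = contrast_summary(d), mean = contrast_summary(d / 2))
}

#' Target-expression contrasts (smile minus frown)
#'
#' Marginalizes over congruency for the drift magnitude (`v_abs`) and
#' boundary (`a`) contrasts; the bias contrast is directly `z_s - z_f`.
#'
#' @param draws A `ddm_fit` or a [ddm_population_draws()] matrix.
#' @param parameter One of `"v_abs"`, `"a"`, `"z"`.
#' @return A `contrast_summary`.
#' @export
contrast_expression <- function(draws, parameter = c("v_abs", "a", "z")) {
  parameter <- match.arg(parameter)
  m <- if (inherits(draws, "ddm_fit")) ddm_population_draws(draws) else draws
  d <- switch(parameter,
    v_abs = (abs(m[, "v_ss"]) + abs(m[, "v_sf"])) / 2 -
            (abs(m[, "v_fs"]) + abs(m[, "v_ff"])) / 2,
    a = (m[, "a_ss"] + m[, "a_sf"]) / 2 - (m[, "a_fs"] + m[, "a_ff"]) / 2,
    z = m[, "z_s"] - m[, "z_f"])
  contrast_summary(d)
}

#' Congruency contrast on boundary separation
#'
#' `(a_ss + a_ff)/2 - (a_sf + a_fs)/2`, marginalizing over target
#' expression.
#'
#' @inheritParams contrast_expression
#' @return A `contrast_summary`.
#' @export
contrast_boundary_congruency <- function(draws) {
  m <- if (inherits(draws, "ddm_fit")) ddm_population_draws(draws) else draws
  d <- (m[, "a_ss"] + m[, "a_ff"]) / 2 - (m[, "a_sf"] + m[, "a_fs"]) / 2
  contrast_summary(d)
}
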