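#' Configuration for the synthetic dataset generator
#'
#' The defaults state the emulated study design: 58 participants, 4 clips x
#' 12 repetitions x 2 blocks (5568 trials in total), a copy-bias RL
#' population with natural-scale locations alpha = 0.3, beta = 0.5,
#' zeta = 0.5, condition-indexed Wiener RT parameters with larger drift
#' magnitude and boundary separation in congruent cells and a small
#' smile-ward start bias, and artifact rates chosen so injected counts are
#' of the same order as the emulated study's exclusions (about 10 percent
#' fast non-compliance, 1 percent no-response).
#'
#' @param n_participants Number of synthetic participants.
#' @param reps_per_clip Clip repetitions per block.
#' @param rl_population Named list: natural-scale locations `alpha`,
#'   `beta`, `zeta` and between-subject sds on the unconstrained scale
#'   `sd_alpha`, `sd_beta` (logit scales), `sd_zeta`.
#' @param ddm_population Named list: cell vectors `v`, `a` (names `ss`,
#'   `sf`, `fs`, `ff`), `z` (names `s`, `f`), scalar `t0`, and
#'   between-subject sds `sd_v`, `sd_log_a`, `sd_logit_z`, `sd_log_t0`.
#' @param p_fast_noncompliance Probability a trial's RT is replaced by a
#'   uniform draw below the 626 ms cutoff.
#' @param p_no_response Probability a trial's response is erased.
#' @param counterbalance Alternate the block-1 copy interactant across
#'   participants.
#' @param seed Integer seed; the whole dataset is a function of it.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_participants = 58L, reps_per_clip = 12L,
                             rl_population = list(alpha = 0.3, beta = 0.5,
                                                  zeta = 0.5, sd_alpha = 0.5,
                                                  sd_beta = 0.5, sd_zeta = 0.3),
                             ddm_population = list(
                               v = c(ss = 1.2, sf = -0.7, fs = 0.7, ff = -1.2),
                               a = c(ss = 2.1, sf = 1.8, fs = 2.0, ff = 2.3),
                               z = c(s = 0.53, f = 0.50), t0 = 0.45,
                               sd_v = 0.25, sd_log_a = 0.12,
                               sd_logit_z = 0.15, sd_log_t0 = 0.15),
                             p_fast_noncompliance = 0.10,
                             p_no_response = 0.01,
                             counterbalance = TRUE, seed = 1L) {
  stopifnot(n_participants >= 1L, reps_per_clip >= 1L,
            p_fast_noncompliance >= 0, p_fast_noncompliance <= 1,
            p_no_response >= 0, p_no_response <= 1,
            p_fast_noncompliance + p_no_response <= 1)
  structure(list(n_participants = as.integer(n_participants),
                 reps_per_clip = as.integer(reps_per_clip),
                 rl_population = rl_population,
                 ddm_population = ddm_population,
                 p_fast_noncompliance = p_fast_noncompliance,
                 p_no_response = p_no_response,
                 counterbalance = isTRUE(counterbalance),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Inverse-CDF sample from the Wiener first-passage distribution conditional
# on absorbing at `boundary`, on a fixed decision-time grid.
sample_wiener_conditional <- function(n, v, a, z, t0, boundary,
                                      horizon = 12) {
  grid <- c(seq(5e-4, 2, by = 2e-3), seq(2.005, horizon, by = 5e-3))
  dens <- dwiener(grid, v, a, z, boundary = boundary)
  cdf <- cumsum(dens * c(grid[1], diff(grid)))
  tot <- cdf[length(cdf)]
  if (tot <= 0) return(rep(t0 + stats::runif(n, 0.3, 1), length.out = n))
  u <- stats::runif(n) * tot
  idx <- findInterval(u, cdf) + 1L
  idx[idx > length(grid)] <- length(grid)
  t0 + grid[idx]
}

#' Generate a ground-truthed synthetic dataset
#'
#' Builds trial-level records with known per-subject parameters so that
#' preprocessing, model fitting and recovery can be tested without any real
#' data. Two generator modes match the two fitted model families:
#'
#' * `rl_choices`: choices come from the copy-bias RL agent
#'   ([simulate_agent()]); RTs are then drawn from the subject's
#'   condition-matched Wiener first-passage distribution conditional on the
#'   chosen boundary, so choice statistics follow the RL model exactly
#'   while RT marginals stay realistic.
#' * `ddm_joint`: choice and RT are drawn jointly from the subject's
#'   condition-indexed Wiener process; correctness and shock follow from
#'   the task contingencies.
#'
#' Artifacts are injected afterwards: with `p_fast_noncompliance` a trial's
#' RT is resampled uniformly in \[0, 626) ms, with `p_no_response` the
#' response is erased. The `artifact` column records the ground-truth
#' exclusion reason of the final record (injected artifacts plus any
#' naturally out-of-window RT), so filter reports can be checked exactly.
#'
#' @param config A [generator_config()].
#' @param mode `"rl_choices"` or `"ddm_joint"`.
#' @param rts In `rl_choices` mode, set `FALSE` to skip RT generation
#'   (choice-only experiments run faster; rt_ms is then fixed at 1000).
#' @return Object of class `synthetic_dataset`: `records` (tidy data
#'   frame), `truth` (list with per-subject `rl` and `ddm` parameter data
#'   frames), `config`, `mode`.
#' @export
generate_dataset <- function(config = generator_config(),
                             mode = c("rl_choices", "ddm_joint"),
                             rts = TRUE) {
  mode <- match.arg(mode)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(config$seed)
  rl <- config$rl_population
  dp <- config$ddm_population
  fast_cut <- rt_cutoff_ms()
  rec_list <- truth_rl <- truth_ddm <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    copy_first <- if (config$counterbalance) 1L + (p - 1L) %% 2L else 1L
    cmap <- contingency_map(copy_first)
    sch <- generate_schedule(reps_per_clip = config$reps_per_clip,
                             participant_id = p, contingencies = cmap)
    # subject parameters (non-centered draws around the population truth)
    alpha <- stats::plogis(stats::qlogis(rl$alpha) + rl$sd_alpha * stats::rnorm(1))
    beta <- 2 * stats::plogis(stats::qlogis(rl$beta / 2) + rl$sd_beta * stats::rnorm(1))
    zeta <- rl$zeta + rl$sd_zeta * stats::rnorm(1)
    v_s <- dp$v + dp$sd_v * stats::rnorm(4)
    a_s <- exp(log(dp$a) + dp$sd_log_a * stats::rnorm(4))
    z_s <- stats::plogis(stats::qlogis(dp$z) + dp$sd_logit_z * stats::rnorm(2))
    t0_s <- exp(log(dp$t0) + dp$sd_log_t0 * stats::rnorm(1))
    names(v_s) <- names(a_s) <- c("ss", "sf", "fs", "ff")
    names(z_s) <- c("s", "f")
    cell <- ddm_cell(sch$target_expression, sch$correct_response)
    zc <- substr(sch$target_expression, 1, 1)
    if (mode == "rl_choices") {
      sim <- simulate_agent(list(alpha = alpha, beta = beta, zeta = zeta), sch)
      response <- sim$response
      correct <- sim$correct
      rt_s <- rep(1, nrow(sch))
      if (rts) {
        key <- paste(cell, response)
        for (k in unique(key)) {
          idx <- which(key == k)
          b <- if (response[idx[1]] == "smile") "upper" else "lower"
          c1 <- cell[idx[1]]
          rt_s[idx] <- sample_wiener_conditional(
            length(idx), v_s[[c1]], a_s[[c1]], z_s[[substr(c1, 1, 1)]],
            t0_s, b)
        }
      }
    } else {
      response <- character(nrow(sch)); rt_s <- numeric(nrow(sch))
      for (i in seq_len(nrow(sch))) {
        repeat {
          s1 <- rwiener_cpp(1L, v_s[[cell[i]]], a_s[[cell[i]]],
                            z_s[[zc[i]]], t0_s, 1e-3, 20)
          if (!is.na(s1$boundary)) break
        }
        response[i] <- if (s1$boundary == 1L) "smile" else "frown"
        rt_s[i] <- s1$rt
      }
      correct <- as.integer(response == sch$correct_response)
    }
    rt_ms <- rt_s * 1000
    # artifact injection
    u <- stats::runif(nrow(sch))
    fast_inj <- u < config$p_fast_noncompliance
    none_inj <- !fast_inj &
      u < config$p_fast_noncompliance + config$p_no_response
    rt_ms[fast_inj] <- stats::runif(sum(fast_inj), 0, fast_cut)
    response[none_inj] <- NA_character_
    rt_ms[none_inj] <- NA_real_
    correct[none_inj] <- 0L
    rec <- data.frame(sch,
                      response = response, rt_ms = rt_ms,
                      correct = correct, shock = 1L - correct,
                      stringsAsFactors = FALSE)
    rec$artifact <- ifelse(is.na(rec$response), "none",
                    ifelse(rec$rt_ms < fast_cut, "fast",
                    ifelse(rec$rt_ms > 5000, "slow", NA_character_)))
    rec_list[[p]] <- rec
    truth_rl[[p]] <- data.frame(participant_id = p, copy_first = copy_first,
                                alpha = alpha, beta = beta, zeta = zeta)
    truth_ddm[[p]] <- data.frame(participant_id = p,
                                 t(c(v = v_s, a = a_s, z = z_s)),
                                 t0 = t0_s)
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL
  structure(list(records = add_condition_trial(records),
                 truth = list(rl = do.call(rbind, truth_rl),
                              ddm = do.call(rbind, truth_ddm)),
                 config = config, mode = mode),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset (%s mode): %d participants, %d trials, seed %d\n",
              x$mode, x$config$n_participants, nrow(x$records),
              x$config$seed))
  invisible(x)
}

#' Serialize / load the generator's ground truth
#'
#' Machine-readable truth tables keyed by participant, for recovery
#' scoring. Round-trips losslessly through JSON.
#'
#' @param dataset A `synthetic_dataset`.
#' @param path Optional file path; when supplied the truth is written as
#'   JSON.
#' @return The truth list (invisibly when written).
#' @export
truth_report <- function(dataset, path = NULL) {
  truth <- list(
    population = list(rl = dataset$config$rl_population,
                      ddm = dataset$config$ddm_population),
    subjects = list(rl = dataset$truth$rl, ddm = dataset$truth$ddm),
    seed = dataset$config$seed, mode = dataset$mode)
  if (!is.null(path)) {
    jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    return(invisible(truth))
  }
  truth
}

#' @rdname truth_report
#' @export
read_truth_report <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth$subjects$rl <- as.data.frame(truth$subjects$rl)
  truth$subjects$ddm <- as.data.frame(truth$subjects$ddm)
  truth
}

#' Score a fit against known generating values
#'
#' @param fit_summary Summary data frame with columns `parameter`, `mean`,
#'   `q2.5`, `q97.5` (as produced by the fit objects).
#' @param truth Named numeric vector of generating values, names matching
#'   `parameter`.
#' @return Data frame with absolute error and 95 percent interval coverage
#'   per parameter.
#' @export
score_recovery <- function(fit_summary, truth) {
  idx <- match(names(truth), fit_summary$parameter)
  if (anyNA(idx)) stop("parameters missing from summary: ",
                       paste(names(truth)[is.na(idx)], collapse = ", "))
  data.frame(parameter = names(truth),
             truth = unname(truth),
             estimate = fit_summary$mean[idx],
             abs_error = abs(fit_summary$mean[idx] - unname(truth)),
             covered = fit_summary$q2.5[idx] <= unname(truth) &
               unname(truth) <= fit_summary$q97.5[idx],
             stringsAsFactors = FALSE)
}
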