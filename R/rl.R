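#' Reinforcement-learning model specifications
#'
#' The model family shares a Rescorla-Wagner core: per interactant the
#' learner tracks action values Q over \{copy, not copy\}, chooses by
#' SoftMax with temperature beta, and updates the chosen action's value by
#' alpha times the prediction error (reinforcement minus current value).
#' Variants differ in how the copy bias enters:
#'
#' * `baseline_no_bias` - alpha, beta only.
#' * `copy_bias` (winning model) - a static bias zeta added to the value of
#'   copying inside the SoftMax.
#' * `prior_bias_only` - zeta fixed at 0 but Q_copy starts at a learnable
#'   offset `q0` that later learning can wash out.
#' * `expr_dep_alpha` - learning rate indexed by the target expression.
#' * `expr_dep_zeta` - copy bias indexed by the target expression.
#'
#' Constraints: alpha in \[0, 1\], beta in (0, 2), zeta/q0 unconstrained.
#'
#' @param name One of the model names above.
#' @return An `rl_model_spec` list with the model `name`, internal `code`,
#'   parameter `params` and constraint `types`.
#' @examples
#' rl_model_spec("copy_bias")$params
#' @export
rl_model_spec <- function(name = c("copy_bias", "baseline_no_bias",
                                   "prior_bias_only", "expr_dep_alpha",
                                   "expr_dep_zeta")) {
  name <- match.arg(name)
  info <- switch(name,
    baseline_no_bias = list(code = 0L, params = c("alpha", "beta")),
    copy_bias        = list(code = 1L, params = c("alpha", "beta", "zeta")),
    prior_bias_only  = list(code = 2L, params = c("alpha", "beta", "q0")),
    expr_dep_alpha   = list(code = 3L,
                            params = c("alpha_smile", "alpha_frown", "beta", "zeta")),
    expr_dep_zeta    = list(code = 4L,
                            params = c("alpha", "beta", "zeta_smile", "zeta_frown")))
  types <- ifelse(grepl("^alpha", info$params), "unit",
                  ifelse(info$params == "beta", "temp", "real"))
  structure(list(name = name, code = info$code, params = info$params,
                 types = types),
            class = "rl_model_spec")
}

#' Subject-level RL parameters
#'
#' Validating constructor for a single agent's parameters of the winning
#' copy-bias model.
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param beta SoftMax temperature in (0, 2); below 1 the value difference
#'   between actions is amplified, above 1 it is attenuated.
#' @param zeta Copy bias (unconstrained); positive values favour copying.
#' @return Named list of class `rl_params`.
#' @export
rl_params <- function(alpha, beta, zeta = 0) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (beta <= 0 || beta >= 2) stop("beta must be in (0, 2)")
  structure(list(alpha = alpha, beta = beta, zeta = zeta),
            class = "rl_params")
}

#' SoftMax probability of copying
#'
#' `P(copy) = exp((Q_copy + zeta) / beta) / (exp((Q_copy + zeta) / beta) +
#' exp(Q_notcopy / beta))`, evaluated in an overflow-safe way.
#'
#' @param q_copy,q_not_copy Current action values.
#' @param zeta Copy bias added to the value of copying.
#' @param beta Temperature, must be positive.
#' @return Probability in (0, 1); `P(copy) + P(not copy) = 1` by
#'   construction.
#' @examples
#' copy_probability(0, 0, 0, 1)    # 0.5
#' copy_probability(0, 0, 0.5, 1)  # plogis(0.5)
#' @export
copy_probability <- function(q_copy, q_not_copy, zeta, beta) {
  if (any(beta <= 0)) stop("beta must be positive")
  stats::plogis((q_copy + zeta - q_not_copy) / beta)
}

#' Rescorla-Wagner value update
#'
#' `Q <- Q + alpha * (r - Q)` for the chosen action only (the caller
#' updates nothing else).
#'
#' @param q Current value of the chosen action.
#' @param r Reinforcement, -1 (shock) or +1 (no shock).
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated value; stays in \[-1, 1\] when `q` starts there.
#' @examples
#' update_q(0, 1, 0.3)  # 0.3
#' @export
update_q <- function(q, r, alpha) {
  if (any(alpha < 0 | alpha > 1)) stop("alpha must be in [0, 1]")
  q + alpha * (r - q)
}

#' Simulate an RL agent on a trial schedule
#'
#' Runs the generative model forward: on each trial the agent samples
#' copy/not-copy from the SoftMax for the current interactant, responds with
#' the target expression (copy) or its opposite, receives +1/-1
#' reinforcement from the task contingencies, and updates the chosen
#' action's value.
#'
#' @param params Named list of natural-scale parameters matching
#'   `model$params` (e.g. from [rl_params()]).
#' @param schedule A `trial_schedule`.
#' @param model An [rl_model_spec()].
#' @param seed Optional integer seed.
#' @return Data frame with one row per trial: `choice`, `p_copy`,
#'   `response`, `correct`, `reinforcement`.
#' @export
simulate_agent <- function(params, schedule,
                           model = rl_model_spec("copy_bias"), seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  p <- params[model$params]
  if (any(vapply(p, is.null, logical(1))))
    stop("params must contain: ", paste(model$params, collapse = ", "))
  n <- nrow(schedule)
  q <- matrix(0, 2, 2)  # [interactant, action]; action 1 = not copy, 2 = copy
  if (model$name == "prior_bias_only") q[, 2] <- p$q0
  choice <- integer(n); p_copy <- numeric(n)
  for (i in seq_len(n)) {
    tp <- rl_trial_params(p, model, schedule$target_expression[i])
    it <- schedule$interactant[i]
    p_copy[i] <- copy_probability(q[it, 2], q[it, 1], tp$zeta, tp$beta)
    choice[i] <- as.integer(stats::runif(1) < p_copy[i])
    response <- if (choice[i] == 1L) schedule$target_expression[i] else
      opposite_expression(schedule$target_expression[i])
    r <- reinforcement(response, schedule$correct_response[i])
    a <- choice[i] + 1L
    q[it, a] <- update_q(q[it, a], r, tp$alpha)
    if (i == 1L) { resp <- character(n); rein <- integer(n) }
    resp[i] <- response; rein[i] <- r
  }
  data.frame(trial = schedule$trial,
             choice = ifelse(choice == 1L, "copy", "not_copy"),
             p_copy = p_copy, response = resp,
             correct = as.integer(rein == 1L), reinforcement = rein,
             stringsAsFactors = FALSE)
}

# per-trial effective (alpha, beta, zeta) under a model variant
rl_trial_params <- function(p, model, target_expression) {
  switch(model$name,
    baseline_no_bias = list(alpha = p$alpha, beta = p$beta, zeta = 0),
    copy_bias        = list(alpha = p$alpha, beta = p$beta, zeta = p$zeta),
    prior_bias_only  = list(alpha = p$alpha, beta = p$beta, zeta = 0),
    expr_dep_alpha   = list(
      alpha = if (target_expression == "smile") p$alpha_smile else p$alpha_frown,
      beta = p$beta, zeta = p$zeta),
    expr_dep_zeta    = list(alpha = p$alpha, beta = p$beta,
      zeta = if (target_expression == "smile") p$zeta_smile else p$zeta_frown))
}

#' RL log likelihood of an observed choice sequence
#'
#' Sums the log SoftMax probability of each observed copy/not-copy choice
#' while evolving the Q state with the observed reinforcements. Records
#' must be in trial order (the update is order-dependent); out-of-order
#' input is an error. Trials excluded in preprocessing are simply absent
#' from both the likelihood and the value updates.
#'
#' @param params Named list of natural-scale parameters for `model`.
#' @param records Single-subject records with columns `trial`,
#'   `interactant`, `target_expression`, `response`, `correct`.
#' @param model An [rl_model_spec()].
#' @param pointwise If `TRUE` return the per-trial log probabilities as an
#'   attribute `"pointwise"`.
#' @return Log likelihood (scalar).
#' @export
rl_log_likelihood <- function(params, records,
                              model = rl_model_spec("copy_bias"),
                              pointwise = FALSE) {
  if (is.unsorted(records$trial, strictly = TRUE))
    stop("records must be strictly ordered by trial")
  p <- params[model$params]
  if (any(vapply(p, is.null, logical(1))))
    stop("params must contain: ", paste(model$params, collapse = ", "))
  q <- matrix(0, 2, 2)
  if (model$name == "prior_bias_only") q[, 2] <- p$q0
  copy <- as.integer(records$response == records$target_expression)
  r <- ifelse(records$correct == 1L, 1, -1)
  n <- nrow(records)
  lp <- numeric(n)
  for (i in seq_len(n)) {
    tp <- rl_trial_params(p, model, records$target_expression[i])
    it <- records$interactant[i]
    pc <- copy_probability(q[it, 2], q[it, 1], tp$zeta, tp$beta)
    lp[i] <- if (copy[i] == 1L) log(pc) else log1p(-pc)
    a <- copy[i] + 1L
    q[it, a] <- update_q(q[it, a], r[i], tp$alpha)
  }
  out <- sum(lp)
  if (pointwise) attr(out, "pointwise") <- lp
  out
}
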