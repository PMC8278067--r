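test_that("copy_probability matches the SoftMax formula", {
  expect_equal(copy_probability(0, 0, 0, 1), 0.5)
  expect_equal(copy_probability(0, 0, 0, 0.17), 0.5)
  # direct evaluation of the stated formula at the copy-bias scale reported
  # for the population (zeta = 0.50, beta = 1)
  expect_equal(copy_probability(0, 0, 0.5, 1), 0.6224593, tolerance = 1e-6)
  # low temperature amplifies the value difference
  expect_equal(copy_probability(1, -1, 0, 0.01), 1, tolerance = 1e-10)
  expect_error(copy_probability(0, 0, 0, 0), "beta")
  expect_error(copy_probability(0, 0, 0, -1), "beta")
  # normalization: P(copy) + P(not copy) = 1, with P(not copy) evaluated
  # through the same SoftMax with the roles of the two actions swapped
  set.seed(1)
  for (i in 1:50) {
    q <- rnorm(2); z <- rnorm(1); b <- runif(1, 0.05, 2)
    expect_equal(copy_probability(q[1], q[2], z, b) +
                   copy_probability(q[2], q[1], -z, b), 1, tolerance = 1e-12)
  }
})

test_that("update_q implements the Rescorla-Wagner rule", {
  expect_equal(update_q(0, 1, 0.3), 0.3)
  expect_equal(update_q(0.7, -1, 0), 0.7)
  expect_error(update_q(0, 1, 1.2), "alpha")
  # closed form after k identical rewards from zero: 1 - (1 - alpha)^k
  for (alpha in c(0.1, 0.3, 0.9)) {
    q <- 0
    for (k in 1:12) {
      q <- update_q(q, 1, alpha)
      expect_equal(q, 1 - (1 - alpha)^k, tolerance = 1e-12)
    }
  }
  # Q stays in [-1, 1] under random +/-1 reinforcement
  set.seed(2)
  q <- 0
  for (i in 1:500) {
    q <- update_q(q, sample(c(-1, 1), 1), runif(1))
    expect_true(q >= -1 && q <= 1)
  }
})

test_that("simulate_agent respects limiting cases", {
  sch <- generate_schedule(seed = 10)
  # huge copy bias: agent copies essentially always
  sim <- simulate_agent(list(alpha = 0.3, beta = 0.5, zeta = 50), sch, seed = 1)
  expect_true(all(sim$choice == "copy"))
  expect_identical(sim$response, sch$target_expression)
  # no learning, no bias: probability 0.5 on every trial
  sim0 <- simulate_agent(list(alpha = 0, beta = 0.5, zeta = 0), sch, seed = 2)
  expect_true(all(sim0$p_copy == 0.5))
  # determinism given seed
  expect_identical(simulate_agent(rl_params(0.3, 0.5, 0.5), sch, seed = 7),
                   simulate_agent(rl_params(0.3, 0.5, 0.5), sch, seed = 7))
})

test_that("first-trial copy rate matches the SoftMax prediction", {
  sch <- generate_schedule(seed = 4, reps_per_clip = 1L)[1, , drop = FALSE]
  set.seed(99)
  n <- 4000
  copies <- vapply(seq_len(n), function(i)
    simulate_agent(list(alpha = 0.3, beta = 0.5, zeta = 0.5),
                   sch)$choice == "copy", logical(1))
  p_hat <- mean(copies)
  p_theo <- copy_probability(0, 0, 0.5, 0.5)
  expect_lt(abs(p_hat - p_theo), 3 * sqrt(p_theo * (1 - p_theo) / n))
})

test_that("rl_log_likelihood matches hand values and the compiled backend", {
  sch <- make_tiny_schedule()
  rec <- sch[1, , drop = FALSE]
  rec$response <- rec$target_expression       # copy on a single trial
  rec$correct <- as.integer(rec$response == rec$correct_response)
  expect_equal(rl_log_likelihood(list(alpha = 0.3, beta = 0.5, zeta = 0), rec),
               log(0.5))
  # R implementation agrees with the C++ likelihood used by the sampler
  ds <- small_rl_dataset()
  for (mname in c("copy_bias", "baseline_no_bias", "prior_bias_only",
                  "expr_dep_alpha", "expr_dep_zeta")) {
    model <- rl_model_spec(mname)
    set.seed(5)
    theta <- lapply(model$types, function(ty)
      switch(ty, unit = runif(1), temp = runif(1, 0.1, 1.9), rnorm(1)))
    names(theta) <- model$params
    r1 <- ds$records[ds$records$participant_id == 1, ]
    llR <- rl_log_likelihood(theta, r1, model)
    dat <- mimicrl:::rl_prepare_data(r1)
    llC <- mimicrl:::rl_loglik_cpp(dat$subj, dat$inter, dat$expr, dat$choice,
                                   dat$r, matrix(unlist(theta), 1), model$code,
                                   FALSE)$total
    expect_equal(llR, llC, tolerance = 1e-10, label = mname)
  }
})

test_that("sequence probabilities sum to one (exhaustive oracle)", {
  sch <- make_tiny_schedule()
  params <- list(alpha = 0.4, beta = 0.7, zeta = 0.3)
  total <- 0
  for (mask in 0:15) {
    copy <- as.integer(intToBits(mask)[1:4])
    rec <- sch
    rec$response <- ifelse(copy == 1L, rec$target_expression,
                           opposite_expression(rec$target_expression))
    rec$correct <- as.integer(rec$response == rec$correct_response)
    total <- total + exp(rl_log_likelihood(params, rec))
  }
  expect_equal(total, 1, tolerance = 1e-12)
  # same property for the expression-dependent variants
  for (mname in c("expr_dep_alpha", "expr_dep_zeta", "prior_bias_only")) {
    model <- rl_model_spec(mname)
    params <- as.list(setNames(c(0.2, 0.5, 0.8, 0.3)[seq_along(model$params)],
                               model$params))
    params[["beta"]] <- 0.7
    total <- 0
    for (mask in 0:15) {
      copy <- as.integer(intToBits(mask)[1:4])
      rec <- sch
      rec$response <- ifelse(copy == 1L, rec$target_expression,
                             opposite_expression(rec$target_expression))
      rec$correct <- as.integer(rec$response == rec$correct_response)
      total <- total + exp(rl_log_likelihood(params, rec, model))
    }
    expect_equal(total, 1, tolerance = 1e-12, label = mname)
  }
})

test_that("likelihood is invariant to interactant relabeling and needs ordered trials", {
  ds <- small_rl_dataset()
  r1 <- ds$records[ds$records$participant_id == 2, ]
  params <- list(alpha = 0.3, beta = 0.5, zeta = 0.5)
  ll <- rl_log_likelihood(params, r1)
  r2 <- r1
  r2$interactant <- 3L - r1$interactant
  expect_equal(rl_log_likelihood(params, r2), ll)
  r3 <- r1[rev(seq_len(nrow(r1))), ]
  expect_error(rl_log_likelihood(params, r3), "ordered")
})

test_that("likelihood is on average highest near the generating parameters", {
  # Monte-Carlo sanity: across datasets, ll at truth >= ll at a perturbation
  sch <- generate_schedule(seed = 21)
  truth <- list(alpha = 0.3, beta = 0.5, zeta = 0.5)
  worse <- list(alpha = 0.9, beta = 1.5, zeta = -0.5)
  set.seed(77)
  diffs <- replicate(60, {
    sim <- simulate_agent(truth, sch)
    rec <- data.frame(sch, response = sim$response, correct = sim$correct)
    rl_log_likelihood(truth, rec) - rl_log_likelihood(worse, rec)
  })
  expect_gt(mean(diffs), 0)
})
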