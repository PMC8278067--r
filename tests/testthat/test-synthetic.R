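test_that("generated datasets have the stated trial structure", {
  cfg <- generator_config(n_participants = 5L, seed = 91L)
  ds <- generate_dataset(cfg, mode = "rl_choices", rts = FALSE)
  expect_identical(nrow(ds$records), 5L * 96L)
  expect_identical(nrow(ds$truth$rl), 5L)
  expect_identical(nrow(ds$truth$ddm), 5L)
  # counterbalancing alternates the block-1 copy interactant
  expect_identical(ds$truth$rl$copy_first, c(1L, 2L, 1L, 2L, 1L))
  # per participant the schedule satisfies the design invariants
  for (p in 1:5) {
    rp <- ds$records[ds$records$participant_id == p, ]
    expect_true(all(table(rp$interactant, rp$target_expression, rp$block) == 12L))
  }
  # determinism
  ds2 <- generate_dataset(cfg, mode = "rl_choices", rts = FALSE)
  expect_identical(ds$records, ds2$records)
  expect_identical(ds$truth, ds2$truth)
})

test_that("artifact labels match the filtering rules exactly", {
  cfg <- generator_config(n_participants = 6L, seed = 92L)
  for (mode in c("rl_choices", "ddm_joint")) {
    ds <- generate_dataset(cfg, mode = mode)
    out <- filter_trials(ds$records)
    lab <- table(factor(ds$records$artifact, levels = c("fast", "slow", "none")))
    expect_identical(out$report$n_fast_excluded, unname(lab[["fast"]]))
    expect_identical(out$report$n_slow_excluded, unname(lab[["slow"]]))
    expect_identical(out$report$n_no_response_excluded, unname(lab[["none"]]))
    expect_identical(out$report$n_retained,
                     sum(is.na(ds$records$artifact)))
  }
})

test_that("zero artifact rates retain every trial", {
  cfg <- generator_config(n_participants = 3L, p_fast_noncompliance = 0,
                          p_no_response = 0, seed = 93L)
  ds <- generate_dataset(cfg, mode = "rl_choices", rts = FALSE)
  out <- filter_trials(ds$records)
  expect_identical(out$report$n_retained, out$report$n_input)
})

test_that("an unbiased non-learning population performs at chance", {
  cfg <- generator_config(n_participants = 30L,
                          rl_population = list(alpha = 0, beta = 1, zeta = 0,
                                               sd_alpha = 0, sd_beta = 0,
                                               sd_zeta = 0),
                          p_fast_noncompliance = 0, p_no_response = 0,
                          seed = 94L)
  ds <- generate_dataset(cfg, mode = "rl_choices", rts = FALSE)
  n <- nrow(ds$records)
  expect_lt(abs(mean(ds$records$correct) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("first-trial copy rate matches the population-averaged SoftMax", {
  cfg <- generator_config(n_participants = 300L, reps_per_clip = 1L,
                          p_fast_noncompliance = 0, p_no_response = 0,
                          seed = 95L)
  ds <- generate_dataset(cfg, mode = "rl_choices", rts = FALSE)
  first <- ds$records[ds$records$trial == 1L, ]
  copied <- first$response == first$target_expression
  p_theo <- mean(plogis(ds$truth$rl$zeta / ds$truth$rl$beta))
  expect_lt(abs(mean(copied) - p_theo), 3 * sqrt(0.25 / nrow(first)))
})

test_that("learning curves rise within blocks and dip at the reversal", {
  ds <- generate_dataset(generator_config(n_participants = 40L,
                                          p_fast_noncompliance = 0,
                                          p_no_response = 0, seed = 96L),
                         mode = "rl_choices", rts = FALSE)
  curves <- summarize_behaviour(ds$records)$curves
  pooled <- aggregate(mean_cr ~ cond_trial, curves, mean)
  expect_gt(pooled$mean_cr[12] - pooled$mean_cr[1], 0.05)  # block-1 learning
  expect_lt(pooled$mean_cr[13] - pooled$mean_cr[12], -0.2) # reversal dip
  expect_gt(pooled$mean_cr[24] - pooled$mean_cr[13], 0.05) # relearning
})

test_that("rl_choices RT marginals respect the conditional Wiener draw", {
  # RTs are strictly above the subject's non-decision time and finite
  ds <- generate_dataset(generator_config(n_participants = 4L,
                                          p_fast_noncompliance = 0,
                                          p_no_response = 0, seed = 97L),
                         mode = "rl_choices")
  for (p in 1:4) {
    rp <- ds$records[ds$records$participant_id == p, ]
    expect_true(all(rp$rt_ms / 1000 > ds$truth$ddm$t0[p]))
  }
})

test_that("truth report round-trips through JSON and scores recoveries", {
  ds <- generate_dataset(generator_config(n_participants = 3L, seed = 98L),
                         mode = "rl_choices", rts = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  truth_report(ds, path)
  back <- read_truth_report(path)
  expect_equal(back$subjects$rl$zeta, ds$truth$rl$zeta, tolerance = 1e-12)
  expect_equal(back$population$rl$alpha, 0.3)
  expect_identical(back$seed, 98L)
  # recovery scoring returns per-parameter coverage in {TRUE, FALSE}
  fake_summary <- data.frame(parameter = c("pop_alpha", "pop_zeta"),
                             mean = c(0.32, 0.4), q2.5 = c(0.2, 0.1),
                             q97.5 = c(0.45, 0.6))
  sc <- score_recovery(fake_summary, c(pop_alpha = 0.3, pop_zeta = 0.9))
  expect_identical(sc$covered, c(TRUE, FALSE))
  expect_equal(sc$abs_error, c(0.02, 0.5))
  expect_error(score_recovery(fake_summary, c(nope = 1)), "missing")
})
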