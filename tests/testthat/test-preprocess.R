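test_that("rt_cutoff_ms sums its components", {
  expect_identical(rt_cutoff_ms(500, 126), 626)
  expect_identical(rt_cutoff_ms(0, 0), 0)
  expect_identical(rt_cutoff_ms(500, 200), 700)
  expect_error(rt_cutoff_ms(-1, 126), "non-negative")
})

test_that("filter_trials applies fast/slow/no-response rules with strict boundaries", {
  rec <- make_filter_fixture()
  out <- filter_trials(rec)
  expect_identical(out$report$n_input, 6L)
  expect_identical(out$report$n_fast_excluded, 1L)   # 600
  expect_identical(out$report$n_slow_excluded, 1L)   # 5100
  expect_identical(out$report$n_no_response_excluded, 1L)
  expect_identical(out$report$n_retained, 3L)
  expect_setequal(out$records$rt_ms, c(626, 700, 4999))  # boundary retained

  # empty input
  empty <- filter_trials(rec[0, ])
  expect_identical(empty$report$n_input, 0L)
  expect_identical(empty$report$n_retained, 0L)

  # all in range
  allok <- filter_trials(data.frame(response = "smile", rt_ms = rep(1000, 5)))
  expect_identical(allok$report$n_retained, 5L)

  # inconsistent rt/response definition is an error
  expect_error(filter_trials(data.frame(response = "smile", rt_ms = NA_real_)),
               "rt_ms")
})

test_that("filter_trials is idempotent and the report partitions the input", {
  ds <- generate_dataset(generator_config(n_participants = 4L, seed = 17L),
                         mode = "rl_choices")
  out1 <- filter_trials(ds$records)
  rep1 <- out1$report
  expect_identical(rep1$n_input - rep1$n_fast_excluded - rep1$n_slow_excluded -
                     rep1$n_no_response_excluded, rep1$n_retained)
  out2 <- filter_trials(out1$records)
  expect_identical(out2$records, out1$records)
  expect_identical(out2$report$n_retained, out2$report$n_input)
})

test_that("filter report serializes to JSON", {
  out <- filter_trials(make_filter_fixture())
  path <- withr::local_tempfile(fileext = ".json")
  write_filter_report(out$report, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$n_retained, 3L)
})

test_that("summarize_behaviour computes cell means and flags empty cells", {
  rec <- data.frame(
    participant_id = 1L, trial = 1:8,
    condition = rep(c("congruent", "incongruent"), each = 4),
    target_expression = rep(c("smile", "smile", "frown", "frown"), 2),
    correct = c(1L, 1L, 1L, 1L, 0L, 1L, 0L, 1L),
    rt_ms = rep(1000, 8), stringsAsFactors = FALSE)
  s <- summarize_behaviour(rec)
  cells <- s$cells
  expect_identical(sum(cells$n), nrow(rec))
  expect_equal(cells$mean_cr[cells$condition == "congruent" &
                               cells$target_expression == "smile"], 1.0)
  expect_equal(cells$mean_cr[cells$condition == "incongruent" &
                               cells$target_expression == "smile"], 0.5)
  # empty cell marked unavailable, not zero
  s2 <- summarize_behaviour(rec[rec$condition == "congruent", ])
  empty <- s2$cells[s2$cells$condition == "incongruent", ]
  expect_true(all(!empty$available))
  expect_true(all(is.na(empty$mean_cr)))
})

test_that("a copy-biased population is more accurate on congruent trials", {
  ds <- small_rl_dataset()
  s <- summarize_behaviour(ds$records)
  cc <- with(s$cells, weighted.mean(mean_cr[condition == "congruent"],
                                    n[condition == "congruent"]))
  ic <- with(s$cells, weighted.mean(mean_cr[condition == "incongruent"],
                                    n[condition == "incongruent"]))
  expect_gt(cc, ic)
})

test_that("reversal_early_late handles degenerate and extreme fixtures", {
  # identical blocks: difference 0, p = 1, flagged zero variance
  base <- expand.grid(participant_id = 1:6, interactant = 1:2,
                      target_expression = c("smile", "frown"),
                      cond_trial_block = 1:4, block = 1:2)
  base$condition <- ifelse(base$interactant == 1, "congruent", "incongruent")
  base$correct <- 1L
  r <- reversal_early_late(base, window = 3L)
  expect_equal(r$mean_diff, rep(0, 4))
  expect_equal(r$p, rep(1, 4))
  expect_true(all(r$zero_variance))

  # block 1 perfect, block 2 all wrong in the first window
  base$correct <- ifelse(base$block == 2L & base$cond_trial_block <= 3L, 0L, 1L)
  r2 <- reversal_early_late(base, window = 3L)
  first <- r2[r2$window == "first", ]
  expect_equal(first$mean_diff, rep(1, 2))
})

test_that("paired t statistic matches the textbook formula", {
  # 5 participants, one congruency cell, hand-computable difference
  b1 <- c(1, 1, 2/3, 1, 2/3)
  b2 <- c(1/3, 2/3, 1/3, 1, 0)
  rec <- do.call(rbind, lapply(1:5, function(p) {
    data.frame(participant_id = p, interactant = 1L,
               target_expression = rep(c("smile", "frown"), each = 12),
               condition = "congruent", block = rep(rep(1:2, each = 6), 2),
               cond_trial_block = rep(rep(1:6, 2), 2),
               correct = 0L)
  }))
  # fill first-3 windows with means b1/b2 (multiples of 1/3 over 6 trials
  # per window: 2 clips x 3)
  for (p in 1:5) for (b in 1:2) {
    sel <- which(rec$participant_id == p & rec$block == b &
                   rec$cond_trial_block <= 3)
    val <- if (b == 1) b1[p] else b2[p]
    rec$correct[sel] <- rep(c(1L, 0L), times = c(round(val * 6), 6 - round(val * 6)))
  }
  r <- reversal_early_late(rec, window = 3L)
  row <- r[r$condition == "congruent" & r$window == "first", ]
  d <- b1 - b2
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(row$t, t_oracle, tolerance = 1e-10)
  expect_identical(row$n_pairs, 5L)
  expect_identical(row$df, 4)
})

test_that("add_condition_trial numbers clip presentations within and across blocks", {
  sch <- generate_schedule(seed = 8)
  sch$participant_id <- 1L
  rec <- add_condition_trial(as.data.frame(sch))
  key <- paste(rec$interactant, rec$target_expression)
  for (k in unique(key)) {
    expect_identical(sort(rec$cond_trial[key == k]), 1:24)
    expect_identical(sort(rec$cond_trial_block[key == k & rec$block == 1]), 1:12)
  }
  # first trial after reversal has cond_trial = 13
  expect_true(all(rec$cond_trial[rec$block == 2 & rec$cond_trial_block == 1] == 13L))
})

test_that("records CSV round-trips including NA responses", {
  ds <- generate_dataset(generator_config(n_participants = 2L, seed = 23L),
                         mode = "rl_choices")
  path <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(ds$records, path)
  back <- read_records_csv(path)
  expect_identical(back$response, ds$records$response)
  expect_equal(back$rt_ms, ds$records$rt_ms)
  expect_identical(back$artifact, ds$records$artifact)
})
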