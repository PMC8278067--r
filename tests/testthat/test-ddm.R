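test_that("Wiener density: symmetry, reflection and domain errors", {
  tt <- c(0.05, 0.2, 0.5, 1, 2, 5)
  # driftless symmetric process: both boundaries equally likely at all times
  expect_equal(dwiener(tt, 0, 1.5, 0.5, "upper"),
               dwiener(tt, 0, 1.5, 0.5, "lower"), tolerance = 1e-12)
  # reflection identity across a parameter grid
  for (v in c(-1.5, 0.4, 2)) for (z in c(0.3, 0.5, 0.7)) {
    expect_equal(dwiener(tt, v, 2, z, "lower"),
                 dwiener(tt, -v, 2, 1 - z, "upper"), tolerance = 1e-10)
  }
  expect_error(dwiener(-0.1, 1, 1, 0.5), "positive")
  expect_error(dwiener(0, 1, 1, 0.5), "positive")
  expect_error(dwiener(1, 1, -1, 0.5), "drift/boundary")
  expect_error(dwiener(1, 1, 1, 1.2), "z must be")
})

test_that("small-time and large-time series agree where both apply", {
  # forcing extreme tolerances pushes the adaptive switch to either branch;
  # results must agree in the mid-time region
  for (v in c(-1, 0.5)) for (z in c(0.35, 0.6)) {
    t_mid <- seq(0.3, 3, by = 0.3)
    d_tight <- dwiener(t_mid, v, 1.8, z, "upper", eps = 1e-12)
    d_loose <- dwiener(t_mid, v, 1.8, z, "upper", eps = 1e-7)
    expect_equal(d_tight, d_loose, tolerance = 1e-6)
  }
})

test_that("density integrates to one and matches the closed-form choice probability", {
  for (v in c(-2, -1, 0, 1, 2)) for (a in c(0.5, 1.5, 3)) {
    for (z in c(0.2, 0.5, 0.8)) {
      up <- stats::integrate(function(t) dwiener(t, v, a, z, "upper"),
                             0, Inf, rel.tol = 1e-9)$value
      lo <- stats::integrate(function(t) dwiener(t, v, a, z, "lower"),
                             0, Inf, rel.tol = 1e-9)$value
      expect_equal(up + lo, 1, tolerance = 1e-4)
      expect_equal(up, pwiener_upper(v, a, z), tolerance = 1e-3)
    }
  }
})

test_that("simulator matches the closed-form choice probabilities", {
  n <- 20000
  sim0 <- rwiener(n, 0, 2, 0.5, dt = 1e-3, seed = 41)
  p0 <- mean(sim0$boundary == "upper")
  expect_lt(abs(p0 - 0.5), 3 * sqrt(0.25 / n))
  sim1 <- rwiener(n, 1, 2, 0.5, dt = 2e-4, seed = 42)
  p_theo <- pwiener_upper(1, 2, 0.5)
  expect_lt(abs(mean(sim1$boundary == "upper") - p_theo),
            3 * sqrt(p_theo * (1 - p_theo) / n) + 0.01)  # + Euler bias margin
  # t0 shifts RTs, timeouts are excluded and counted
  sim2 <- rwiener(500, 0, 1, 0.5, t0 = 0.4, dt = 1e-3, seed = 43, horizon = 0.05)
  expect_true(all(sim2$rt >= 0.4))
  expect_gt(attr(sim2, "n_timeout"), 0)
  expect_identical(nrow(sim2) + attr(sim2, "n_timeout"), 500L)
})

test_that("ddm_log_likelihood composes densities by design cell", {
  params <- ddm_params(v = c(ss = 1, sf = -1, fs = 1, ff = -1),
                       a = c(ss = 2, sf = 2, fs = 2, ff = 2),
                       z = c(s = 0.5, f = 0.5), t0 = 0.3)
  obs <- data.frame(rt = c(1, 1), response = c("smile", "frown"),
                    target_expression = c("smile", "smile"),
                    required_response = c("smile", "smile"),
                    stringsAsFactors = FALSE)
  # symmetric parameters: upper and lower responses at equal t, mirrored
  # drift cells give equal density
  l1 <- dwiener(0.7, 1, 2, 0.5, "upper", log = TRUE)
  l2 <- dwiener(0.7, 1, 2, 0.5, "lower", log = TRUE)
  ll <- ddm_log_likelihood(obs, params)
  expect_equal(as.numeric(ll), l1 + l2)
  # rt <= t0 is a reported conflict
  obs_bad <- obs; obs_bad$rt <- c(0.2, 1)
  ll_bad <- ddm_log_likelihood(obs_bad, params)
  expect_identical(attr(ll_bad, "n_conflict"), 1L)
  expect_identical(as.numeric(ll_bad), -Inf)
})

test_that("dataset reflection (swap responses, negate v, mirror z) preserves likelihood", {
  set.seed(44)
  cfg <- generator_config(n_participants = 1L, reps_per_clip = 3L,
                          p_fast_noncompliance = 0, p_no_response = 0,
                          seed = 45L)
  ds <- generate_dataset(cfg, mode = "ddm_joint")
  obs <- data.frame(rt = ds$records$rt_ms / 1000,
                    response = ds$records$response,
                    target_expression = ds$records$target_expression,
                    required_response = ds$records$correct_response,
                    stringsAsFactors = FALSE)
  params <- ddm_params(v = c(ss = 1.1, sf = -0.6, fs = 0.7, ff = -1.3),
                       a = c(ss = 2, sf = 1.8, fs = 2.1, ff = 2.2),
                       z = c(s = 0.55, f = 0.48), t0 = 0.35)
  ll <- ddm_log_likelihood(obs, params)
  flip <- function(x) ifelse(x == "smile", "frown", "smile")
  obs2 <- obs
  obs2$response <- flip(obs$response)
  obs2$target_expression <- flip(obs$target_expression)
  obs2$required_response <- flip(obs$required_response)
  # relabeling smile<->frown everywhere maps cell ss<->ff, sf<->fs and
  # mirrors drift and bias
  params2 <- ddm_params(
    v = c(ss = -params$v[["ff"]], sf = -params$v[["fs"]],
          fs = -params$v[["sf"]], ff = -params$v[["ss"]]),
    a = c(ss = params$a[["ff"]], sf = params$a[["fs"]],
          fs = params$a[["sf"]], ff = params$a[["ss"]]),
    z = c(s = 1 - params$z[["f"]], f = 1 - params$z[["s"]]),
    t0 = params$t0)
  expect_equal(as.numeric(ddm_log_likelihood(obs2, params2)),
               as.numeric(ll), tolerance = 1e-8)
})

test_that("likelihood is maximized near the generating drift (grid oracle)", {
  set.seed(46)
  v_true <- 1.2
  sim <- rwiener(3000, v_true, 2, 0.5, t0 = 0.3, dt = 1e-3, seed = 47)
  obs <- data.frame(rt = sim$rt, response = ifelse(sim$boundary == "upper",
                                                   "smile", "frown"),
                    target_expression = "smile", required_response = "smile",
                    stringsAsFactors = FALSE)
  grid <- seq(0.4, 2.0, by = 0.1)
  lls <- vapply(grid, function(v) {
    p <- ddm_params(v = c(ss = v, sf = 0, fs = 0, ff = 0),
                    a = c(ss = 2, sf = 2, fs = 2, ff = 2),
                    z = c(s = 0.5, f = 0.5), t0 = 0.3)
    as.numeric(ddm_log_likelihood(obs, p))
  }, numeric(1))
  expect_lt(abs(grid[which.max(lls)] - v_true), 0.2)
})

test_that("contrast operations recover constructed shifts", {
  set.seed(48)
  n <- 5000
  base <- abs(rnorm(n, 1.5, 0.2))
  draws <- cbind(v_ss = base + rnorm(n, 0, 0.01),
                 v_sf = -(base + rnorm(n, 0, 0.01)),
                 v_fs = base + rnorm(n, 0, 0.01),
                 v_ff = -(base + rnorm(n, 0, 0.01)),
                 a_ss = 2 + rnorm(n, 0, 0.05), a_sf = 2 + rnorm(n, 0, 0.05),
                 a_fs = 2 + rnorm(n, 0, 0.05), a_ff = 2 + rnorm(n, 0, 0.05),
                 z_s = 0.5 + rnorm(n, 0, 0.01), z_f = 0.5 + rnorm(n, 0, 0.01))
  # identical |v| across cells: congruency contrast centred at 0
  dc <- contrast_drift_congruency(draws)
  expect_lt(abs(dc$sum$mean), 0.02)
  expect_lt(abs(dc$mean$mean), 0.02)
  expect_equal(contrast_expression(draws, "z")$fraction_positive, 0.5,
               tolerance = 0.05)
  # inject |v| + delta in both congruent cells: sum contrast ~ 2 delta
  delta <- 0.4
  draws2 <- draws
  draws2[, "v_ss"] <- draws[, "v_ss"] + delta
  draws2[, "v_ff"] <- draws[, "v_ff"] - delta
  dc2 <- contrast_drift_congruency(draws2)
  expect_equal(dc2$sum$mean, 2 * delta, tolerance = 0.05)
  expect_equal(dc2$mean$mean, delta, tolerance = 0.05)
  expect_gt(dc2$sum$fraction_positive, 0.999)
  # bias shifted by +0.03 for smiles
  draws3 <- draws; draws3[, "z_s"] <- draws[, "z_s"] + 0.03
  cz <- contrast_expression(draws3, "z")
  expect_equal(cz$mean, 0.03, tolerance = 0.005)
  # boundary shifted +0.22 for frown targets: smile - frown contrast -0.22
  draws4 <- draws
  draws4[, "a_fs"] <- draws[, "a_fs"] + 0.22
  draws4[, "a_ff"] <- draws[, "a_ff"] + 0.22
  ca <- contrast_expression(draws4, "a")
  expect_equal(ca$mean, -0.22, tolerance = 0.02)
  # congruency contrast is invariant to relabeling smile<->frown
  relab <- draws2[, c("v_ff", "v_fs", "v_sf", "v_ss",
                      "a_ff", "a_fs", "a_sf", "a_ss", "z_f", "z_s")]
  relab[, 1:4] <- -relab[, 1:4]
  relab[, 9:10] <- 1 - relab[, 9:10]
  colnames(relab) <- colnames(draws2)
  dc_rel <- contrast_drift_congruency(relab)
  expect_equal(dc_rel$sum$mean, dc2$sum$mean, tolerance = 1e-10)
})
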