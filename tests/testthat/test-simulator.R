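test_that("the same seed reproduces the dataset exactly", {
  cfg <- scenario_config(1, n_subjects = 60)
  s1 <- simulate_scenario(cfg, seed = 5)
  s2 <- simulate_scenario(cfg, seed = 5)
  expect_identical(s1$dataset$longitudinal, s2$dataset$longitudinal)
  expect_identical(s1$dataset$survival, s2$dataset$survival)
  expect_identical(s1$latent, s2$latent)
  s3 <- simulate_scenario(cfg, seed = 6)
  expect_false(identical(s1$dataset$survival$time,
                         s3$dataset$survival$time))
})

test_that("without trial heterogeneity the latent trial effects are zero", {
  s <- simulate_scenario(scenario_config(1, n_subjects = 40), seed = 2)
  expect_equal(s$latent$nu, matrix(0, 1, 2))
  s2 <- simulate_scenario(
    scenario_config(2, n_subjects = 40,
                    sigma_nu = list(var_M = 0, var_T = 0, cov = 0)),
    seed = 2)
  expect_true(all(s2$latent$nu == 0))
})

test_that("trial-effect draws reproduce the generating covariance", {
  cfg <- scenario_config(3, n_subjects = 50, n_trials = 5000)
  s <- simulate_scenario(cfg, seed = 3)
  emp <- stats::cov(s$latent$nu)
  expect_lt(abs(emp[1, 1] - 0.400) / 0.400, 0.05)
  expect_lt(abs(emp[2, 2] - 0.400) / 0.400, 0.05)
  expect_lt(abs(emp[1, 2] - 0.280) / 0.280, 0.05)
})

test_that("event-time draws invert the cumulative hazard exactly", {
  cons <- list(family = "exponential", rate = 0.7)
  # b = 0: exponential closed form
  expect_equal(draw_event_time(0.4, 0, cons, 0.3),
               -log(0.3) / (0.7 * exp(0.4)), tolerance = 1e-10)
  # b != 0: closed-form inversion of lambda e^a (e^{bt}-1)/b
  a <- -0.2; b <- 0.5; u <- 0.15
  closed <- log(1 + b * (-log(u)) * exp(-a) / 0.7) / b
  expect_equal(draw_event_time(a, b, cons, u), closed, tolerance = 1e-8)
  # u near 1 gives a tiny event time (inverse-CDF monotonicity)
  expect_lt(draw_event_time(0, 0, cons, 1 - 1e-9), 1e-6)
  expect_error(draw_event_time(0, 0, cons, 0), "in \\(0, 1\\)")
  expect_error(draw_event_time(0, 0, cons, 1), "in \\(0, 1\\)")
  # insufficient total hazard -> survives past the horizon
  expect_true(is.infinite(draw_event_time(-30, 0, cons, 0.5, t_max = 10)))
  # the vectorized sampler agrees with the root-finder
  set.seed(17)
  av <- rnorm(30); bv <- rnorm(30, 0, 0.4); uv <- runif(30)
  tv <- surromed:::.draw_event_times_vec(av, bv, cons, uv, t_max = 100)
  tr <- vapply(1:30, function(i)
    draw_event_time(av[i], bv[i], cons, uv[i], t_max = 100), 0)
  expect_equal(tv[is.finite(tr)], tr[is.finite(tr)], tolerance = 1e-8)
})

test_that("baseline calibration solves the null-effect case in closed form", {
  cfg0 <- scenario_config(1, eta = 0, beta_ZT = 0, beta_T = 0,
                          calibrate = FALSE)
  b <- calibrate_baseline("exponential", cfg0,
                          data.frame(time = 1, survival = 0.5))
  expect_equal(b$rate, log(2), tolerance = 1e-6)
})

test_that("Weibull calibration hits two anchors, verified by Monte Carlo", {
  cfg <- scenario_config(1, calibrate = FALSE)
  b <- calibrate_baseline("weibull", cfg,
                          data.frame(time = c(1, 3),
                                     survival = c(0.5, 0.2)))
  expect_equal(attr(b, "achieved"), c(0.5, 0.2), tolerance = 0.01)
  # independent Monte-Carlo check: draw subjects and event times, compare
  # the empirical survival at the anchors
  set.seed(99)
  n <- 20000
  z <- rbinom(n, 1, .5); x <- rbinom(n, 1, .5)
  om <- matrix(rnorm(2 * n), n, 2) %*% chol(cfg$Sigma_omega)
  a <- cfg$beta_ZT * z + cfg$beta_T * x +
    cfg$eta * (cfg$beta0 + om[, 1] + cfg$beta_ZM * z + cfg$beta_M * x)
  bb <- cfg$eta * (cfg$beta1 + om[, 2] + cfg$beta2 * z)
  u <- runif(n)
  tt <- surromed:::.draw_event_times_vec(a, bb, b, u, t_max = 200)
  expect_equal(mean(tt > 1), 0.5, tolerance = 0.02)
  expect_equal(mean(tt > 3), 0.2, tolerance = 0.02)
})

test_that("infeasible calibration targets are rejected", {
  cfg <- scenario_config(1, calibrate = FALSE)
  expect_error(calibrate_baseline("exponential", cfg,
                                  data.frame(time = c(1, 3),
                                             survival = c(0.9, 0.95))),
               "increasing survival")
})

test_that("with no marker-event link, arms have exchangeable event times", {
  skip_if_not_installed("survival")
  chis <- vapply(1:6, function(s) {
    cfg <- scenario_config(1, n_subjects = 400, eta = 0, beta_ZT = 0,
                           beta_T = 0)
    sv <- simulate_scenario(cfg, seed = s)$dataset$survival
    survival::survdiff(survival::Surv(time, event) ~ treatment,
                       data = sv)$chisq
  }, 0)
  # chi-squared(1) under the null: mean 1, individual values rarely > 10
  expect_lt(mean(chis), 3)
  expect_true(all(chis < 12))
})

test_that("generated datasets always satisfy the container invariants", {
  for (sc in 1:3) {
    s <- simulate_scenario(scenario_config(sc, n_subjects = 80), seed = sc)
    ds <- s$dataset
    expect_s3_class(ds, "joint_dataset")    # constructor validates
    fup <- ds$survival$time[match(ds$longitudinal$id, ds$survival$id)]
    expect_true(all(ds$longitudinal$time <= fup))
    expect_true(all(ds$survival$event %in% c(0, 1)))
    expect_equal(length(ds$trials), length(unique(ds$survival$trial)))
  }
})
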