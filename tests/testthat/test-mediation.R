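# Counterfactual survival and the natural-effect decomposition.

.med_params <- function(basis, eps = NULL) {
  p <- scenario1_params(basis)
  if (!is.null(eps)) p$Sigma_omega <- diag(eps, 2)
  p
}

test_that("counterfactual survival is one at t = 0 and matches the closed form", {
  basis <- mspline_basis(4, tau = 3)
  lam <- 0.5
  pars <- .med_params(basis, eps = 1e-14)
  pars$hazard_raw <- surromed:::.const_hazard_raw(basis, lam)
  spec <- scenario_model_spec()
  for (zz in list(c(1, 1), c(1, 0), c(0, 0)))
    expect_equal(counterfactual_survival(0, zz[1], zz[2], c(x = 1), pars,
                                         spec, basis = basis), 1)
  # degenerate random effects: S = exp(-lambda e^a (e^{bt}-1)/b)
  for (t in c(0.5, 1.5, 3)) for (z in 0:1) for (zp in 0:1) for (x in 0:1) {
    a <- 1 * z - 0.3 * x + 0.3 * (0.2 + 1 * zp + 0.1 * x)
    b <- 0.3 * (1.2 + 0.3 * zp)
    Sref <- exp(-lam * exp(a) * (exp(b * t) - 1) / b)
    expect_equal(counterfactual_survival(t, z, zp, c(x = x), pars, spec,
                                         basis = basis, gh_nodes = 5),
                 Sref, tolerance = 1e-8)
  }
})

test_that("without an association the marker pathway is closed", {
  basis <- mspline_basis(7, tau = 3)
  pars <- .med_params(basis)
  pars$eta <- 0
  spec <- scenario_model_spec()
  covtab <- data.frame(x = c(0, 1), .weight = c(.5, .5))
  eff <- natural_effects(c(0.5, 1, 2, 3), pars, spec, covtab,
                         basis = basis)
  expect_equal(eff$nie, rep(0, 4), tolerance = 1e-14)
  expect_true(all(abs(eff$tte) > 0))   # direct pathway still open
})

test_that("the shared-random-effects link never mediates", {
  basis <- mspline_basis(7, tau = 3)
  spec <- model_spec(link = "shared_random_effects",
                     covariates_longitudinal = "x",
                     covariates_survival = "x")
  pars <- parameter_set(
    hazard_raw = surromed:::.const_hazard_raw(basis, 0.4),
    eta = c(0.2, 0.1), sigma_eps = 0.3,
    Sigma_omega = matrix(c(0.562, -0.112, -0.112, 0.450), 2, 2),
    beta_long = c(intercept = 0.2, time = 1.2, treatment = 1,
                  treatment_g = 0.3, x = 0.1),
    beta_surv = c(treatment = 1, x = -0.3))
  eff <- natural_effects(1:3, pars, spec,
                         data.frame(x = c(0, 1), .weight = c(.5, .5)),
                         basis = basis)
  expect_equal(eff$nie, rep(0, 3), tolerance = 1e-14)
})

test_that("TTE = NIE + NDE holds to machine precision and survival decays", {
  basis <- mspline_basis(7, tau = 3)
  pars <- .med_params(basis)
  spec <- scenario_model_spec()
  covtab <- data.frame(x = c(0, 1), .weight = c(.5, .5))
  tg <- seq(0.2, 3, by = 0.2)
  eff <- natural_effects(tg, pars, spec, covtab, basis = basis)
  expect_equal(eff$tte, eff$nie + eff$nde)  # exact by construction
  for (cl in c("S11", "S10", "S00")) {
    expect_true(all(diff(eff[[cl]]) <= 1e-12))
    expect_true(all(eff[[cl]] >= 0 & eff[[cl]] <= 1))
  }
})

test_that("the weighted-category shortcut equals per-row averaging exactly", {
  basis <- mspline_basis(7, tau = 3)
  pars <- .med_params(basis)
  spec <- scenario_model_spec()
  short <- natural_effects(1:2, pars, spec,
                           data.frame(x = c(0, 1), .weight = c(.25, .75)),
                           basis = basis)
  rows <- natural_effects(1:2, pars, spec,
                          data.frame(x = c(0, 1, 1, 1)), basis = basis)
  expect_equal(short$pte, rows$pte)
  expect_equal(short$S10, rows$S10)
})

test_that("doubling the effect-integral resolution barely moves the PTE", {
  basis <- mspline_basis(7, tau = 3)
  pars <- .med_params(basis)
  spec <- scenario_model_spec()
  covtab <- data.frame(x = c(0, 1), .weight = c(.5, .5))
  e1 <- natural_effects(1:3, pars, spec, covtab, basis = basis,
                        gh_nodes = 20)
  e2 <- natural_effects(1:3, pars, spec, covtab, basis = basis,
                        gh_nodes = 40)
  expect_lt(max(abs(e1$pte - e2$pte)), 0.005)
})

test_that("PTE is flagged, never clipped, when the total effect vanishes", {
  basis <- mspline_basis(7, tau = 3)
  pars <- .med_params(basis)
  pars$beta_surv[["treatment"]] <- 0
  pars$beta_long[["treatment"]] <- 0
  pars$beta_long[["treatment_g"]] <- 0
  spec <- scenario_model_spec()
  eff <- natural_effects(1:2, pars, spec,
                         data.frame(x = c(0, 1), .weight = c(.5, .5)),
                         basis = basis)
  expect_true(all(eff$pte_unreliable))
  # opposing direct and indirect effects can push PTE outside [0, 1]
  pars$beta_long[["treatment"]] <- 1
  pars$beta_surv[["treatment"]] <- -0.32
  eff2 <- natural_effects(1, pars, spec,
                          data.frame(x = c(0, 1), .weight = c(.5, .5)),
                          basis = basis)
  expect_false(eff2$pte >= 0 && eff2$pte <= 1)
})

test_that("R2_trial follows its definition on the printed matrices", {
  expect_equal(r2_trial(matrix(c(.086, 0, 0, .086), 2, 2)), 0)
  expect_equal(r2_trial(matrix(c(.1, sqrt(.1 * .4), sqrt(.1 * .4), .4),
                               2, 2)), 1)
  expect_equal(r2_trial(matrix(c(.086, .056, .056, .086), 2, 2)),
               0.056^2 / (0.086 * 0.086), tolerance = 1e-12)
  expect_equal(r2_trial(matrix(c(.4, .28, .28, .4), 2, 2)),
               0.28^2 / (0.4 * 0.4), tolerance = 1e-12)
  expect_warning(r2 <- r2_trial(matrix(c(0, 0, 0, .1), 2, 2)), "undefined")
  expect_true(is.na(r2))
})

test_that("degenerate parameter uncertainty collapses the bootstrap bands", {
  fit <- small_fit(n = 200, seed = 42)
  fit0 <- fit
  fit0$vcov_theta <- matrix(0, length(fit$theta), length(fit$theta))
  b <- bootstrap_bands(fit0, 1:2, n_boot = 25, seed = 3)
  m <- mediate(fit, 1:2)
  expect_equal(b$pte$lower, m$pte, tolerance = 1e-12)
  expect_equal(b$pte$upper, m$pte, tolerance = 1e-12)
})

test_that("the point estimate lies inside its own 95% band", {
  fit <- small_fit(n = 200, seed = 42)
  m <- mediate(fit, c(1, 2), n_boot = 200)
  b <- attr(m, "bands")
  for (k in c("nie", "nde", "tte", "pte")) {
    expect_true(all(m[[k]] >= b[[k]]$lower - 1e-12))
    expect_true(all(m[[k]] <= b[[k]]$upper + 1e-12))
  }
})

test_that("bands are deterministic given the seed", {
  fit <- small_fit(n = 200, seed = 42)
  b1 <- bootstrap_bands(fit, 1, n_boot = 50, seed = 11)
  b2 <- bootstrap_bands(fit, 1, n_boot = 50, seed = 11)
  expect_identical(b1$pte, b2$pte)
})
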