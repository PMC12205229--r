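# Penalized joint likelihood: closed-form oracles, quadrature behavior,
# parameter packing, and the optimizer contract.

test_that("with no association the likelihood factorizes exactly", {
  sim <- small_sim(n = 60, seed = 7)
  ds <- sim$dataset
  spec <- scenario_model_spec()
  basis <- mspline_basis(7, tau = ds$tau,
                         event_times = ds$survival$time[ds$survival$event == 1])
  pars <- scenario1_params(basis)
  pars$eta <- 0
  pll <- penalized_loglik(ds, pars, spec, kappa = 0, basis = basis)
  sv <- ds$survival
  lp <- pars$beta_surv[["treatment"]] * sv$treatment +
    pars$beta_surv[["x"]] * sv$x
  surv_ll <- sum(sv$event * (log(baseline_hazard(pars$hazard_raw, basis,
                                                 sv$time)) + lp) -
                   cumulative_baseline(pars$hazard_raw, basis, sv$time) *
                   exp(lp))
  dat <- surromed:::.prepare_fit_data(ds, spec, basis,
                                      integration_config(), 0)
  lmm_ll <- surromed:::sjm_lmm_ll(c(log(pars$sigma_eps),
                                    surromed:::.lchol_pack(pars$Sigma_omega),
                                    pars$beta_long), dat)
  expect_equal(as.numeric(pll), lmm_ll + surv_ll, tolerance = 1e-10)
})

test_that("with degenerate random effects the survival term is closed form", {
  # one subject, constant baseline, current-level link: the cumulative
  # hazard is lambda e^a (e^{bT}-1)/b
  long <- data.frame(id = 1, trial = 1, time = c(0, 0.4, 0.9),
                     value = c(0.5, 1.0, 1.6))
  surv <- data.frame(id = 1, trial = 1, time = 1.4, event = 1,
                     treatment = 1, x = 1)
  ds <- joint_dataset(long, surv, tau = 2)
  basis <- mspline_basis(4, tau = 2)
  lam <- 0.6
  eps <- 1e-12
  pars <- parameter_set(
    hazard_raw = surromed:::.const_hazard_raw(basis, lam),
    eta = 0.3, sigma_eps = 0.4,
    Sigma_omega = diag(eps, 2),
    beta_long = c(intercept = 0.2, time = 1.2, treatment = 1,
                  treatment_g = 0.3, x = 0.1),
    beta_surv = c(treatment = 1, x = -0.3))
  ll <- subject_loglik(ds, 1, pars, scenario_model_spec(), basis = basis)
  # closed-form pieces at omega = 0
  mu <- 0.2 + 1.2 * long$time + 1 + 0.3 * long$time + 0.1
  gauss <- sum(dnorm(long$value, mu, 0.4, log = TRUE))
  a <- 1 - 0.3 + 0.3 * (0.2 + 1 + 0.1)
  b <- 0.3 * (1.2 + 0.3)
  Tst <- 1.4
  Lam <- lam * exp(a) * (exp(b * Tst) - 1) / b
  surv_ll <- log(lam) + a + b * Tst - Lam
  expect_equal(ll, gauss + surv_ll, tolerance = 1e-6)
})

test_that("raising the quadrature order barely moves the likelihood", {
  sim <- small_sim(n = 60, seed = 7)
  ds <- sim$dataset
  spec <- scenario_model_spec()
  basis <- mspline_basis(7, tau = ds$tau)
  pars <- scenario1_params(basis)
  l9 <- subject_loglik(ds, 5, pars, spec, integration_config(gh_nodes = 9),
                       basis = basis)
  l15 <- subject_loglik(ds, 5, pars, spec,
                        integration_config(gh_nodes = 15), basis = basis)
  expect_lt(abs(l9 - l15), 1e-4)
})

test_that("kappa = 0 is unpenalized and positive kappa can only lower it", {
  sim <- small_sim(n = 40, seed = 3)
  ds <- sim$dataset
  spec <- scenario_model_spec()
  basis <- mspline_basis(7, tau = ds$tau)
  set.seed(4)
  pars <- scenario1_params(basis)
  pars$hazard_raw <- abs(rnorm(basis$n_basis, 0.4, 0.15))  # curved hazard
  p0 <- penalized_loglik(ds, pars, spec, kappa = 0, basis = basis)
  expect_equal(as.numeric(p0), attr(p0, "loglik"))
  p5 <- penalized_loglik(ds, pars, spec, kappa = 5, basis = basis)
  expect_gt(attr(p5, "penalty"), 0)
  expect_lt(as.numeric(p5), as.numeric(p0))
  expect_equal(as.numeric(p5),
               attr(p5, "loglik") - 5 * attr(p5, "penalty"))
})

test_that("vanishing trial-level variance recovers the no-trial-effect value", {
  sim <- small_sim(n = 40, seed = 3)
  ds <- sim$dataset
  basis <- mspline_basis(7, tau = ds$tau)
  pars <- scenario1_params(basis)
  p_none <- penalized_loglik(ds, pars, scenario_model_spec(), kappa = 0,
                             basis = basis)
  pars$Sigma_nu <- diag(1e-10, 2)
  spec_r <- scenario_model_spec(trial_mode = "random")
  p_rand <- penalized_loglik(ds, pars, spec_r,
                             integration_config(mc_trial_draws = 200),
                             kappa = 0, basis = basis)
  expect_equal(as.numeric(p_rand), as.numeric(p_none), tolerance = 1e-4)
})

test_that("packing the parameter vector is a bijection", {
  set.seed(8)
  spec <- scenario_model_spec(trial_mode = "random")
  nb <- 9
  ps <- parameter_set(
    hazard_raw = rnorm(nb), eta = 0.42, sigma_eps = 0.77,
    Sigma_omega = crossprod(matrix(rnorm(4), 2, 2)) + diag(0.1, 2),
    beta_long = setNames(rnorm(5), c("intercept", "time", "treatment",
                                     "treatment_g", "x")),
    beta_surv = setNames(rnorm(2), c("treatment", "x")),
    Sigma_nu = crossprod(matrix(rnorm(4), 2, 2)) + diag(0.05, 2))
  th <- surromed:::.theta_pack(ps, spec)
  ps2 <- surromed:::.theta_unpack(th, spec, nb, 5, 2,
                                  names(ps$beta_long), names(ps$beta_surv))
  expect_equal(ps2$hazard_raw, ps$hazard_raw)
  expect_equal(ps2$eta, ps$eta)
  expect_equal(ps2$sigma_eps, ps$sigma_eps)
  expect_equal(ps2$Sigma_omega, ps$Sigma_omega)
  expect_equal(ps2$Sigma_nu, ps$Sigma_nu)
  expect_equal(surromed:::.theta_pack(ps2, spec), th)
})

test_that("model-spec guards warn on structurally zero mediation pathways", {
  expect_warning(model_spec(link = "current_slope", interaction = FALSE),
                 "structurally zero")
  sp <- model_spec(link = "shared_random_effects")
  expect_false(sp$mediation_possible)
  expect_error(model_spec(random_components = c(2L, 2L)),
               "exactly two distinct")
})

test_that("refitting from the optimum is a fixed point", {
  fit <- small_fit(n = 200, seed = 42)
  refit <- fit_joint_model(small_sim(200, 42)$dataset,
                           scenario_model_spec(), se = FALSE,
                           init = fit$params)
  expect_true(refit$converged)
  expect_lt(abs(refit$pll - fit$pll), 1e-6 * (1 + abs(fit$pll)))
  expect_lt(max(abs(refit$theta - fit$theta)), 1e-3)
})

test_that("estimates are stable under richer integration rules", {
  fit <- small_fit(n = 200, seed = 42)
  se <- standard_errors(fit)
  fit2 <- fit_joint_model(small_sim(200, 42)$dataset,
                          scenario_model_spec(),
                          intcfg = integration_config(gh_nodes = 15,
                                                      time_quadrature = 31),
                          se = FALSE)
  common <- intersect(names(fit$natural), names(fit2$natural))
  expect_true(all(abs(fit$natural[common] - fit2$natural[common]) <
                    0.5 * se[common]))
})

test_that("the variance matrix is symmetric with positive diagonal", {
  fit <- small_fit(n = 200, seed = 42)
  expect_true(fit$se_available)
  V <- fit$vcov_natural
  expect_lt(max(abs(V - t(V))), 1e-10)
  se <- standard_errors(fit)
  expect_true(all(is.finite(se)) && all(se > 0))
})

test_that("the association SE at n = 800 is on the reported scale", {
  fit <- cached("fit_full_1",
                fit_joint_model(cached("sim_full_1",
                                       simulate_scenario(scenario_config(1),
                                                         seed = 1))$dataset,
                                scenario_model_spec(), se = TRUE))
  se <- standard_errors(fit)
  expect_gt(se[["association"]], 0.01)
  expect_lt(se[["association"]], 0.08)
})
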