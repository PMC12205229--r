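# Shared fixtures: a session-level cache so expensive fits are built once
# and reused across test files.

.sjm_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sjm_cache[[key]])) assign(key, force(expr), .sjm_cache)
  .sjm_cache[[key]]
}

toy_tables <- function() {
  long <- data.frame(
    id = rep(c("a", "b"), each = 3),
    trial = "t1",
    time = c(0, 0.5, 1.0, 0, 0.4, 0.8),
    value = c(1.0, 1.2, 1.5, 0.3, 0.2, 0.4))
  surv <- data.frame(
    id = c("a", "b"),
    trial = "t1",
    time = c(1.0, 1.1),
    event = c(1, 0),
    treatment = c(1, 0),
    x = c(0, 1))
  list(long = long, surv = surv)
}

scenario1_params <- function(basis, rate = 0.3) {
  parameter_set(
    hazard_raw = surromed:::.const_hazard_raw(basis, rate),
    eta = 0.3, sigma_eps = 0.3,
    Sigma_omega = matrix(c(0.562, -0.112, -0.112, 0.450), 2, 2),
    beta_long = c(intercept = 0.2, time = 1.2, treatment = 1,
                  treatment_g = 0.3, x = 0.1),
    beta_surv = c(treatment = 1, x = -0.3))
}

small_sim <- function(n = 150, seed = 42, scenario = 1, ...) {
  cached(sprintf("sim_%d_%d_%d_%s", scenario, n, seed,
                 paste(c(...), collapse = "_")),
         simulate_scenario(scenario_config(scenario, n_subjects = n, ...),
                           seed = seed))
}

small_fit <- function(n = 200, seed = 42, se = TRUE) {
  cached(sprintf("fit_%d_%d_%s", n, seed, se),
         fit_joint_model(small_sim(n, seed)$dataset, scenario_model_spec(),
                         se = se))
}
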