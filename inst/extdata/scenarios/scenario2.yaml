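# Scenario 2: 100 centers, small treatment-effect heterogeneity.
name: scenario2
n_subjects: 800
n_trials: 100
sigma_nu:
  var_M: 0.086
  var_T: 0.086
  cov: 0.056
sigma_omega:
  var_intercept: 0.562
  var_slope: 0.450
  cov: -0.112
residual_sd: 0.300
beta0: 0.200
beta1: 1.200
beta2: 0.300          # treatment-by-time interaction
beta_ZM: 1.000        # treatment effect, longitudinal
beta_ZT: 1.000        # treatment effect, survival (log-hazard)
beta_M: 0.100         # binary covariate, longitudinal
beta_T: -0.300        # binary covariate, survival
eta: 0.300            # current-level association
tau: 3.0
baseline:
  family: exponential
  rate: null          # calibrated to the survival anchor below
survival_targets:
  - time: 1.0
    survival: 0.50
censoring_target: 0.20
censor_upper_mult: 3.5   # uniform censoring on [0, mult * tau], capped at tau
visit_spacing: 0.20      # years between scheduled visits (~6.2 per subject)
visit_jitter: 0.2        # +/- fraction of the spacing
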