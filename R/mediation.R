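#' Counterfactual survival under separated treatment assignments
#'
#' Computes \eqn{S_{zz'}(t \mid x)}: the survival probability at `t` when
#' treatment is set to `z` in the event process while the biomarker follows
#' its trajectory under treatment `z'`, for covariate values `x`. The
#' conditional survival given the random effects is
#' \deqn{\exp\left(-\int_0^t \lambda_0(u) e^{(\beta_{Z,T}+\nu_T) z +
#'   \beta_T' x + \eta\, h(M_{z'}(u))} du\right)}
#' with the error-free marker in the link (measurement error never enters
#' the hazard), and the individual random effects are integrated out by
#' two-dimensional Gauss-Hermite quadrature over their prior; trial-level
#' effects, when present, by Monte Carlo.
#'
#' @param t Evaluation times in `[0, tau]`.
#' @param z,zprime Treatment assignments (0/1) for the event process and
#'   the biomarker process.
#' @param x Named covariate values (vector or one-row data frame).
#' @param params A [parameter_set()].
#' @param spec A [model_spec()].
#' @param intcfg An [integration_config()]; `time_quadrature` drives the
#'   time integral (the same rule as the likelihood), `n_mc_effects` the
#'   trial-effect draws.
#' @param basis [mspline_basis()] carrying the fitted baseline hazard; not
#'   needed when `baseline` is given.
#' @param baseline Optional parametric baseline override: a spec list
#'   (`family` plus parameters, as in [calibrate_baseline()]) or a
#'   vectorized hazard function of time.
#' @param gh_nodes Gauss-Hermite nodes per dimension for the effect
#'   integral (default 20).
#' @param trial_shift Optional `c(dM, dT)` treatment-effect deviations of a
#'   specific trial (fixed trial mode), applied times `zprime` to the
#'   marker and times `z` to the hazard.
#' @param nu_draws Optional matrix of trial-effect draws (random trial
#'   mode); generated from `intcfg$seed` when needed.
#' @return Vector of survival probabilities, one per time.
#' @export
counterfactual_survival <- function(t, z, zprime, x, params, spec,
                                    intcfg = integration_config(),
                                    basis = NULL, baseline = NULL,
                                    gh_nodes = 20, trial_shift = c(0, 0),
                                    nu_draws = NULL) {
  stopifnot(z %in% c(0, 1), zprime %in% c(0, 1))
  t <- as.numeric(t)
  if (any(t < 0)) stop("t must be nonnegative")
  lam0 <- .resolve_baseline(params, basis, baseline)
  if (!is.null(basis) && any(t > basis$tau))
    stop(sprintf("t must lie in [0, %g]", basis$tau))

  traj <- spec$trajectory
  rc <- spec$random_components
  pn_long <- names(params$beta_long)
  pn_surv <- names(params$beta_surv)
  xv <- if (is.data.frame(x)) x[1, , drop = FALSE] else as.list(x)

  # survival linear predictor without the marker term
  bS <- params$beta_surv
  lp_surv <- bS[["treatment"]] * z + trial_shift[2] * z
  for (cv in spec$covariates_survival)
    lp_surv <- lp_surv + bS[[cv]] * as.numeric(xv[[cv]])

  # Gauss-Hermite grid over the random-effect prior
  gh <- pracma::gaussHermite(gh_nodes)
  Lw <- t(chol(params$Sigma_omega))
  gi <- rep(seq_len(gh_nodes), each = gh_nodes)
  gj <- rep(seq_len(gh_nodes), gh_nodes)
  om <- sqrt(2) * cbind(gh$x[gi], gh$x[gj]) %*% t(Lw)    # ngrid x 2
  wts <- gh$w[gi] * gh$w[gj] / pi

  # trial-level draws (random mode): common draws across (z, zprime)
  use_nu <- spec$trial_mode == "random" && !is.null(params$Sigma_nu)
  if (use_nu && is.null(nu_draws)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(.substream_seed(intcfg$seed, "effects_nu"))
    nu_draws <- matrix(rnorm(2 * intcfg$n_mc_effects),
                       intcfg$n_mc_effects, 2) %*% t(t(chol(params$Sigma_nu)))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }

  use_deriv <- spec$link == "current_slope"
  shared <- spec$link == "shared_random_effects"
  eta <- params$eta

  vapply(t, function(tt) {
    if (tt == 0) return(1)
    gl <- pracma::gaussLegendre(max(intcfg$time_quadrature, 15), 0, tt)
    lam <- lam0(gl$x)
    if (shared) {
      Lam0 <- sum(gl$w * lam)
      lp <- lp_surv + om %*% eta
      if (use_nu) {
        ch <- outer(exp(drop(lp)), exp(nu_draws[, 2] * z)) * Lam0
        return(sum(wts * rowMeans(exp(-ch))))
      }
      return(sum(wts * exp(-Lam0 * exp(lp))))
    }
    ev <- trajectory_eval(traj, gl$x)
    f <- if (use_deriv) ev$df else ev$f
    g <- if (use_deriv) ev$dg else ev$g
    # fixed part of h at nodes (marker under treatment zprime)
    mfix <- drop(f %*% params$beta_long[seq_len(traj$n_components)])
    mfix <- mfix + (if (use_deriv) 0 else
      (params$beta_long[["treatment"]] + trial_shift[1]) * zprime)
    if (spec$interaction)
      mfix <- mfix + params$beta_long[["treatment_g"]] * zprime * g
    if (!use_deriv)
      for (cv in spec$covariates_longitudinal)
        mfix <- mfix + params$beta_long[[cv]] * as.numeric(xv[[cv]])
    hr <- f[, rc, drop = FALSE]                           # nq x 2
    # Lambda(omega) = sum_q w_q lam_q exp(lp + eta (mfix_q + hr_q . omega))
    A <- exp(eta * om %*% t(hr))                          # ngrid x nq
    base <- gl$w * lam * exp(lp_surv + eta * mfix)        # nq
    ch <- drop(A %*% base)                                # ngrid
    if (use_nu) {
      # nu_M shifts the marker under zprime; nu_T shifts the hazard under z
      fac <- exp(eta * nu_draws[, 1] * zprime * (!use_deriv) +
                   nu_draws[, 2] * z)
      S <- rowMeans(exp(-outer(ch, fac)))
      sum(wts * S)
    } else {
      sum(wts * exp(-ch))
    }
  }, 0)
}

.resolve_baseline <- function(params, basis, baseline) {
  if (is.function(baseline)) return(baseline)
  if (is.list(baseline)) return(.baseline_fun(baseline))
  if (is.null(basis))
    stop("either a spline basis (fitted hazard) or a parametric baseline ",
         "must be supplied")
  raw <- params$hazard_raw
  if (!length(raw)) stop("parameter set carries no baseline coefficients")
  function(u) baseline_hazard(raw, basis, u)
}

#' Natural direct, indirect and total effects on the survival scale
#'
#' Computes population-averaged counterfactual survival S11, S10, S00 on a
#' time grid and derives NIE = S11 - S10, NDE = S10 - S00, TTE = NIE + NDE
#' and PTE = NIE / TTE. Covariates are averaged over the rows of
#' `covariate_table` (with optional `.weight` column: the weighted-category
#' shortcut, identical to per-row averaging for categorical covariates);
#' with fixed trial effects the empirical trial distribution is averaged
#' alongside.
#'
#' PTE is reported at every time but flagged unreliable where
#' `|TTE| < tte_floor` (survival curves too close for the ratio to mean
#' anything); it is never clipped, since opposing direct and indirect
#' effects can legitimately push it outside `[0, 1]`.
#'
#' @inheritParams counterfactual_survival
#' @param times Evaluation times, strictly positive.
#' @param covariate_table Data frame of covariate rows (empirical
#'   distribution of X), optional `.weight` column.
#' @param trial_table Optional data frame (fixed trial mode) with columns
#'   `dM`, `dT` (per-trial treatment-effect deviations) and `.weight`.
#' @param tte_floor Reliability floor for the PTE flag (default 0.01).
#' @return An object of class `"mediation_result"`: a data frame with
#'   columns `time`, `S11`, `S10`, `S00`, `nie`, `nde`, `tte`, `pte`,
#'   `pte_unreliable`.
#' @export
natural_effects <- function(times, params, spec, covariate_table,
                            intcfg = integration_config(), basis = NULL,
                            baseline = NULL, gh_nodes = 20,
                            trial_table = NULL, tte_floor = 0.01) {
  times <- as.numeric(times)
  if (!length(times) || any(times <= 0))
    stop("times must be strictly positive")
  covariate_table <- as.data.frame(covariate_table)
  if (!nrow(covariate_table)) stop("covariate table is empty")
  w <- covariate_table$.weight
  if (is.null(w)) w <- rep(1 / nrow(covariate_table), nrow(covariate_table))
  w <- w / sum(w)

  if (is.null(trial_table)) {
    trial_table <- data.frame(dM = 0, dT = 0, .weight = 1)
  }
  tw <- trial_table$.weight / sum(trial_table$.weight)

  # common trial-effect draws shared across the three curves
  nu_draws <- NULL
  if (spec$trial_mode == "random" && !is.null(params$Sigma_nu)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(.substream_seed(intcfg$seed, "effects_nu"))
    nu_draws <- matrix(rnorm(2 * intcfg$n_mc_effects),
                       intcfg$n_mc_effects, 2) %*% t(t(chol(params$Sigma_nu)))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }

  Scurve <- function(z, zp) {
    out <- numeric(length(times))
    for (r in seq_len(nrow(covariate_table)))
      for (s in seq_len(nrow(trial_table)))
        out <- out + w[r] * tw[s] *
          counterfactual_survival(times, z, zp,
                                  covariate_table[r, , drop = FALSE],
                                  params, spec, intcfg, basis, baseline,
                                  gh_nodes,
                                  trial_shift = c(trial_table$dM[s],
                                                  trial_table$dT[s]),
                                  nu_draws = nu_draws)
    out
  }
  S11 <- Scurve(1, 1); S10 <- Scurve(1, 0); S00 <- Scurve(0, 0)
  nie <- S11 - S10
  nde <- S10 - S00
  tte <- nie + nde
  pte <- nie / tte
  res <- data.frame(time = times, S11 = S11, S10 = S10, S00 = S00,
                    nie = nie, nde = nde, tte = tte, pte = pte,
                    pte_unreliable = abs(tte) < tte_floor)
  structure(res, class = c("mediation_result", "data.frame"),
            n_mc_effects = if (is.null(nu_draws)) 0L else nrow(nu_draws),
            gh_nodes = gh_nodes)
}

#' Mediation analysis of a fitted joint model
#'
#' Convenience wrapper deriving the natural effects and PTE from an
#' [sjm_fit][fit_joint_model()], averaging over the empirical covariate
#' distribution of the fitted dataset (and the empirical trial distribution
#' under fixed trial effects), with optional parametric-bootstrap bands.
#'
#' @param fit An `sjm_fit`.
#' @param times Evaluation times.
#' @param n_boot Bootstrap draws for 95% bands (0 = none).
#' @param seed Seed for the bootstrap.
#' @param ... Passed to [natural_effects()].
#' @return A [natural_effects()] result, with percentile bands attached
#'   when `n_boot > 0`.
#' @export
mediate <- function(fit, times, n_boot = 0, seed = fit$intcfg$seed, ...) {
  stopifnot(inherits(fit, "sjm_fit"))
  if (!fit$spec$mediation_possible)
    warning("shared-random-effects link: the mediated effect is ",
            "structurally zero (random effects are independent of ",
            "treatment)")
  res <- natural_effects(times, fit$params, fit$spec, fit$covariate_table,
                         fit$intcfg, basis = fit$basis,
                         trial_table = .trial_table_from_fit(fit), ...)
  if (n_boot > 0) {
    bands <- bootstrap_bands(fit, times, n_boot = n_boot, seed = seed, ...)
    attr(res, "bands") <- bands
  }
  res
}

.trial_table_from_fit <- function(fit) {
  if (fit$spec$trial_mode != "fixed") return(NULL)
  nl <- names(fit$params$beta_long)
  tf <- grep("^treatment_trial", nl, value = TRUE)
  # reference trial has zero deviation; empirical trial weights
  data.frame(dM = c(0, unname(fit$params$beta_long[tf])),
             dT = c(0, unname(fit$params$beta_surv[tf])),
             .weight = fit$trial_weights)
}

#' Parametric-bootstrap confidence bands for the mediation curves
#'
#' Draws parameter vectors from the asymptotic Gaussian distribution of the
#' maximum penalized-likelihood estimator — on the unconstrained scale, so
#' every draw yields valid covariance matrices — recomputes the natural
#' effects for each draw, and returns pointwise 2.5th/97.5th percentile
#' bands.
#'
#' @param fit A converged `sjm_fit` with an available variance matrix.
#' @param times Evaluation times.
#' @param n_boot Number of draws (>= 100 recommended; 1000 by default).
#' @param seed RNG seed (deterministic bands).
#' @param ... Passed to [natural_effects()].
#' @return List of data frames `nie`, `nde`, `tte`, `pte`, each with
#'   columns `time`, `lower`, `upper`, plus the draw array as attribute
#'   `"draws"`.
#' @export
bootstrap_bands <- function(fit, times, n_boot = 1000,
                            seed = fit$intcfg$seed, ...) {
  stopifnot(inherits(fit, "sjm_fit"), n_boot >= 1)
  if (is.null(fit$vcov_theta))
    stop("variance matrix unavailable; refit with se = TRUE")
  p <- length(fit$theta)
  V <- (fit$vcov_theta + t(fit$vcov_theta)) / 2
  ev <- eigen(V, symmetric = TRUE)
  R <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p)
  set.seed(.substream_seed(seed, "bootstrap"))
  Z <- matrix(rnorm(n_boot * p), n_boot, p)
  TH <- sweep(Z %*% t(R), 2, fit$theta, `+`)
  nb <- fit$basis$n_basis
  pL <- length(fit$params$beta_long)
  pS <- length(fit$params$beta_surv)
  draws <- array(NA_real_, c(n_boot, length(times), 4),
                 dimnames = list(NULL, NULL, c("nie", "nde", "tte", "pte")))
  for (b in seq_len(n_boot)) {
    pb <- .theta_unpack(TH[b, ], fit$spec, nb, pL, pS,
                        names(fit$params$beta_long),
                        names(fit$params$beta_surv))
    eb <- natural_effects(times, pb, fit$spec, fit$covariate_table,
                          fit$intcfg, basis = fit$basis,
                          trial_table = .trial_table_from_fit(fit), ...)
    draws[b, , ] <- cbind(eb$nie, eb$nde, eb$tte, eb$pte)
  }
  qs <- function(k) data.frame(
    time = times,
    lower = apply(draws[, , k, drop = FALSE], 2, quantile, 0.025),
    upper = apply(draws[, , k, drop = FALSE], 2, quantile, 0.975))
  structure(list(nie = qs("nie"), nde = qs("nde"), tte = qs("tte"),
                 pte = qs("pte")),
            draws = draws, n_boot = n_boot)
}

#' Trial-level coefficient of determination
#'
#' Squared trial-level correlation between the treatment effects on the
#' marker and on the event time,
#' \eqn{R^2_{trial} = \sigma_{\nu_{M,T}}^2 / (\sigma_{\nu_M}^2
#' \sigma_{\nu_T}^2)}, computed from the trial-level covariance matrix.
#'
#' @param Sigma_nu 2x2 trial-level covariance matrix (or an `sjm_fit` whose
#'   parameter set carries one).
#' @return Value in `[0, 1]`, or `NA` (with a warning) when a variance
#'   component is zero.
#' @export
r2_trial <- function(Sigma_nu) {
  if (inherits(Sigma_nu, "sjm_fit")) Sigma_nu <- Sigma_nu$params$Sigma_nu
  if (is.null(Sigma_nu)) stop("no trial-level covariance available")
  stopifnot(all(dim(Sigma_nu) == c(2, 2)))
  if (Sigma_nu[1, 1] <= 0 || Sigma_nu[2, 2] <= 0) {
    warning("zero trial-level variance component; R2_trial undefined")
    return(NA_real_)
  }
  Sigma_nu[1, 2]^2 / (Sigma_nu[1, 1] * Sigma_nu[2, 2])
}

#' True mediation measures of a simulation scenario
#'
#' Plugs the generating parameters of a [scenario_config()] into the
#' counterfactual-survival formula (calibrated parametric baseline,
#' Gauss-Hermite integration over the individual random effects, covariate
#' averaged over its two levels) and returns the implied NIE, NDE, TTE and
#' PTE.
#'
#' @param cfg A [scenario_config()].
#' @param times Evaluation times.
#' @param intcfg An [integration_config()].
#' @param gh_nodes Nodes per dimension for the effect integral.
#' @return A [natural_effects()] result.
#' @export
scenario_true_effects <- function(cfg, times = 1:3,
                                  intcfg = integration_config(),
                                  gh_nodes = 20) {
  stopifnot(inherits(cfg, "scenario_config"))
  spec <- scenario_model_spec()
  params <- parameter_set(
    hazard_raw = numeric(0), eta = cfg$eta, sigma_eps = cfg$residual_sd,
    Sigma_omega = cfg$Sigma_omega,
    beta_long = c(intercept = cfg$beta0, time = cfg$beta1,
                  treatment = cfg$beta_ZM, treatment_g = cfg$beta2,
                  x = cfg$beta_M),
    beta_surv = c(treatment = cfg$beta_ZT, x = cfg$beta_T))
  covtab <- data.frame(x = c(0, 1), .weight = c(0.5, 0.5))
  natural_effects(times, params, spec, covtab, intcfg,
                  baseline = cfg$baseline, gh_nodes = gh_nodes)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("mediation measures (survival-difference scale)\n")
  df <- as.data.frame(x)
  df[] <- lapply(df, function(v) if (is.numeric(v)) signif(v, 4) else v)
  print(df, row.names = FALSE)
  if (!is.null(attr(x, "bands")))
    cat("95% parametric-bootstrap bands attached (",
        attr(attr(x, "bands"), "n_boot"), " draws)\n", sep = "")
  invisible(x)
}

#' Plot mediation curves
#'
#' Two panels: PTE over time, and the natural effect curves (NIE, NDE,
#' TTE), with dashed 95% bands when present.
#'
#' @param x A [natural_effects()] / [mediate()] result.
#' @param ... Unused.
#' @export
plot.mediation_result <- function(x, ...) {
  bands <- attr(x, "bands")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ylim <- range(x$pte, if (!is.null(bands)) unlist(bands$pte[-1]), 0, 1)
  plot(x$time, x$pte, type = "b", pch = 19, xlab = "time", ylab = "PTE(t)",
       main = "proportion of treatment effect", ylim = ylim)
  if (!is.null(bands)) {
    graphics::lines(bands$pte$time, bands$pte$lower, lty = 2)
    graphics::lines(bands$pte$time, bands$pte$upper, lty = 2)
  }
  ylim <- range(x$nie, x$nde, x$tte, 0,
                if (!is.null(bands)) unlist(lapply(bands[c("nie", "nde",
                                                           "tte")],
                                                   function(b) b[-1])))
  plot(x$time, x$tte, type = "b", pch = 19, xlab = "time",
       ylab = "effect on survival", main = "natural effects", ylim = ylim)
  graphics::lines(x$time, x$nie, type = "b", pch = 1, col = 2)
  graphics::lines(x$time, x$nde, type = "b", pch = 2, col = 4)
  if (!is.null(bands))
    for (k in c("nie", "nde", "tte")) {
      graphics::lines(bands[[k]]$time, bands[[k]]$lower, lty = 2,
                      col = switch(k, nie = 2, nde = 4, tte = 1))
      graphics::lines(bands[[k]]$time, bands[[k]]$upper, lty = 2,
                      col = switch(k, nie = 2, nde = 4, tte = 1))
    }
  graphics::legend("bottomleft", c("TTE", "NIE", "NDE"), col = c(1, 2, 4),
                   pch = c(19, 1, 2), bty = "n")
  invisible(x)
}
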