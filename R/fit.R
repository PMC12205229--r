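#' Penalized joint log-likelihood
#'
#' Evaluates the penalized log-likelihood of a [joint_dataset()] at a given
#' [parameter_set()]: the sum of subject contributions (longitudinal
#' Gaussian terms and the survival term, with individual random effects
#' integrated by (pseudo-)adaptive Gauss-Hermite quadrature, and trial-level
#' random effects, if present, by Monte Carlo with common random numbers)
#' minus `kappa` times the integrated squared curvature of the baseline
#' hazard.
#'
#' @param dataset A [joint_dataset()].
#' @param params A [parameter_set()].
#' @param spec A [model_spec()].
#' @param intcfg An [integration_config()].
#' @param kappa Smoothing parameter (>= 0); `kappa = 0` gives the
#'   unpenalized log-likelihood.
#' @param basis An [mspline_basis()]; defaults to `n_knots` knots on
#'   `[0, tau]` with quantile placement on observed event times.
#' @param n_knots Knot count used when `basis` is not supplied.
#' @return The penalized log-likelihood, with attributes `loglik` and
#'   `penalty`.
#' @export
penalized_loglik <- function(dataset, params, spec, intcfg =
                               integration_config(), kappa = 5,
                             basis = NULL, n_knots = 7) {
  stopifnot(inherits(dataset, "joint_dataset"),
            inherits(params, "parameter_set"), kappa >= 0)
  if (is.null(basis))
    basis <- mspline_basis(n_knots, tau = dataset$tau,
                           event_times =
                             dataset$survival$time[dataset$survival$event == 1])
  dat <- .prepare_fit_data(dataset, spec, basis, intcfg, kappa)
  if (intcfg$pseudo_adaptive)
    dat <- .attach_pseudo_nodes(dat, .theta_lmm_from(params, spec))
  th <- .theta_pack(params, spec)
  if (length(params$hazard_raw) != basis$n_basis)
    stop("hazard_raw length does not match the spline basis (",
         basis$n_basis, " functions)")
  r <- sjm_pll(th, dat)
  structure(r$pll, loglik = r$loglik, penalty = r$penalty)
}

#' Log-likelihood contribution of a single subject
#'
#' @inheritParams penalized_loglik
#' @param subject Subject identifier.
#' @param trial_effect Trial-level deviations `c(nu_M, nu_T)` applied (times
#'   the subject's treatment indicator) to the marker mean and the
#'   log-hazard.
#' @return The subject's marginal log-likelihood contribution.
#' @export
subject_loglik <- function(dataset, subject, params, spec,
                           intcfg = integration_config(),
                           trial_effect = c(0, 0), basis = NULL,
                           n_knots = 7) {
  stopifnot(inherits(dataset, "joint_dataset"))
  i <- match(subject, dataset$survival$id)
  if (is.na(i)) stop("unknown subject '", subject, "'")
  if (is.null(basis))
    basis <- mspline_basis(n_knots, tau = dataset$tau,
                           event_times =
                             dataset$survival$time[dataset$survival$event == 1])
  spec_eval <- spec
  spec_eval$trial_mode <- "none"      # shifts supplied explicitly
  dat <- .prepare_fit_data(dataset, spec_eval, basis, intcfg, kappa = 0)
  if (intcfg$pseudo_adaptive)
    dat <- .attach_pseudo_nodes(dat, .theta_lmm_from(params, spec_eval))
  pe <- params; pe$Sigma_nu <- NULL
  th <- .theta_pack(pe, spec_eval)
  z <- dataset$survival$treatment[i]
  val <- sjm_subject_ll(th, dat, i, trial_effect[1] * z, trial_effect[2] * z)
  if (!is.finite(val))
    stop("non-finite likelihood contribution for subject '", subject, "'")
  val
}

# longitudinal-only parameter vector (log sige, lchol Sigma_omega, beta_long)
.theta_lmm_from <- function(params, spec) {
  c(log(params$sigma_eps), .lchol_pack(params$Sigma_omega), params$beta_long)
}

# raw coefficients giving a constant hazard `rate` (partition of unity)
.const_hazard_raw <- function(basis, rate) {
  ord <- basis$order
  k <- basis$knots
  span <- k[seq_len(basis$n_basis) + ord] - k[seq_len(basis$n_basis)]
  sqrt(rate * span / ord)
}

#' Fit the joint model by penalized maximum likelihood
#'
#' Two-stage warm start followed by joint maximization: the longitudinal
#' mixed model is fitted alone (closed-form marginal likelihood), its
#' random-effect posteriors fix the pseudo-adaptive Gauss-Hermite grid, the
#' survival block (baseline hazard, association, survival fixed effects) is
#' then optimized with the longitudinal block held, and finally all
#' parameters are maximized jointly with a quasi-Newton ascent. When
#' standard errors are requested the fit is polished with damped Newton
#' (Levenberg-Marquardt) steps using the finite-difference Hessian, which is
#' then reused as the curvature estimate: the variance matrix is the inverse
#' Hessian of the penalized log-likelihood at the maximizer.
#'
#' Convergence requires the relative objective change, relative parameter
#' change and gradient norm to fall below `control$tol_obj`,
#' `control$tol_par` and `control$tol_grad` (defaults 1e-5, 1e-5, 1e-3).
#'
#' @inheritParams penalized_loglik
#' @param init Optional [parameter_set()] used as starting value.
#' @param se Compute the variance matrix (finite-difference Hessian)?
#' @param control List of optimizer settings: `tol_obj`, `tol_par`,
#'   `tol_grad`, `max_polish`, `maxit`.
#' @return An object of class `"sjm_fit"`.
#' @export
fit_joint_model <- function(dataset, spec, intcfg = integration_config(),
                            kappa = 5, basis = NULL, n_knots = 7,
                            init = NULL, se = TRUE, control = list()) {
  stopifnot(inherits(dataset, "joint_dataset"), inherits(spec, "model_spec"))
  ctl <- modifyList(list(tol_obj = 1e-5, tol_par = 1e-5, tol_grad = 1e-3,
                         max_polish = 8, maxit = 400, rel_tol = 1e-8),
                    control)
  sv <- dataset$survival
  if (is.null(basis))
    basis <- mspline_basis(n_knots, tau = dataset$tau,
                           event_times = sv$time[sv$event == 1])
  dat <- .prepare_fit_data(dataset, spec, basis, intcfg, kappa)
  nb <- dat$nb; pL <- dat$pL; pS <- dat$pS
  neta <- dat$neta
  trial_random <- spec$trial_mode == "random"

  # ---- stage 1: longitudinal mixed model alone -------------------------
  bL0 <- coef(lm.fit(dat$X, dat$y))
  bL0[is.na(bL0)] <- 0
  res0 <- dat$y - dat$X %*% bL0
  th_lmm0 <- c(log(max(sd(res0), 1e-3)), log(0.7), 0, log(0.7), bL0)
  o1 <- nlminb(th_lmm0, function(p) -sjm_lmm_ll(p, dat),
               control = list(iter.max = 300, eval.max = 600))
  th_lmm <- o1$par

  if (intcfg$pseudo_adaptive) dat <- .attach_pseudo_nodes(dat, th_lmm)

  # ---- assemble starting vector ---------------------------------------
  if (!is.null(init)) {
    theta <- .theta_pack(init, spec)
    if (length(theta) != nb + neta + 4 + pL + pS + 3 * trial_random)
      stop("init parameter set does not match the model layout")
  } else {
    rate0 <- sum(sv$event) / sum(sv$time)
    theta <- c(.const_hazard_raw(basis, rate0), rep(0, neta),
               th_lmm[1], th_lmm[2:4], th_lmm[-(1:4)], rep(0, pS))
    if (trial_random) theta <- c(theta, log(0.1), 0, log(0.1))
  }

  negf <- function(th) -sjm_pll_value(th, dat)
  grad_free <- function(th, idx, central = FALSE)
    -sjm_pll_grad(th, dat, idx, central = central)

  evals <- 0L
  run_block <- function(theta, idx, maxit) {
    fn <- function(v) { th <- theta; th[idx] <- v; evals <<- evals + 1L
      negf(th) }
    gr <- function(v) { th <- theta; th[idx] <- v
      evals <<- evals + length(idx); grad_free(th, idx) }
    o <- nlminb(theta[idx], fn, gr,
                control = list(iter.max = maxit, eval.max = 3 * maxit,
                               rel.tol = ctl$rel_tol))
    theta[idx] <- o$par
    list(theta = theta, obj = o$objective, conv = o$convergence,
         iter = o$iterations)
  }

  # ---- stage 2: survival block ----------------------------------------
  if (is.null(init)) {
    idx_surv <- c(seq_len(nb), nb + seq_len(neta),
                  nb + neta + 4 + pL + seq_len(pS))
    if (trial_random) idx_surv <- c(idx_surv, nb + neta + 4 + pL + pS + 1:3)
    b2 <- run_block(theta, idx_surv, ctl$maxit)
    theta <- b2$theta
  }

  # ---- stage 3: joint maximization ------------------------------------
  idx_all <- seq_along(theta)
  b3 <- run_block(theta, idx_all, ctl$maxit)
  obj_prev <- b3$obj
  theta_prev <- theta
  theta <- b3$theta
  n_iter <- b3$iter

  g <- grad_free(theta, idx_all, central = TRUE)
  gnorm <- max(abs(g))

  # ---- optional damped-Newton (Levenberg-Marquardt) polish + Hessian ---
  H <- NULL
  if (se || gnorm > ctl$tol_grad) {
    H <- sjm_pll_hess(theta, dat)
    lam <- 1e-3
    for (it in seq_len(ctl$max_polish)) {
      if (gnorm <= ctl$tol_grad) break
      A <- -(H) + diag(lam, length(theta))
      step <- tryCatch(solve(A, -g), error = function(e) NULL)
      if (is.null(step)) { lam <- lam * 10; next }
      cand <- theta + step
      f_cand <- negf(cand)
      if (is.finite(f_cand) && f_cand < obj_prev) {
        theta_prev <- theta
        theta <- cand
        obj_prev <- f_cand
        lam <- max(lam / 4, 1e-8)
        g <- grad_free(theta, idx_all, central = TRUE)
        gnorm <- max(abs(g))
        n_iter <- n_iter + 1L
        if (it %% 3 == 0) H <- sjm_pll_hess(theta, dat)
      } else {
        lam <- lam * 10
        if (lam > 1e8) break
      }
    }
    if (se && max(abs(theta - theta_prev)) > 0) H <- sjm_pll_hess(theta, dat)
  }

  rel_par <- max(abs(theta - theta_prev)) / max(1, max(abs(theta)))
  converged <- gnorm <= max(ctl$tol_grad, 1e-3 * (1 + abs(obj_prev))) &&
    b3$conv %in% c(0L, 1L)

  params <- .theta_unpack(theta, spec, nb, pL, pS,
                          dat$names_long, dat$names_surv)
  natural <- .natural_from_theta(theta, spec, nb, pL, pS,
                                 dat$names_long, dat$names_surv)

  vcov_theta <- vcov_natural <- NULL
  se_available <- FALSE
  if (se && !is.null(H)) {
    vcov_theta <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(vcov_theta) && all(diag(vcov_theta) > 0)) {
      J <- .natural_jacobian(theta, spec, nb, pL, pS,
                             dat$names_long, dat$names_surv)
      vcov_natural <- J %*% vcov_theta %*% t(J)
      dimnames(vcov_natural) <- list(names(natural), names(natural))
      se_available <- TRUE
    } else {
      warning("Hessian not invertible or not negative definite; ",
              "standard errors unavailable")
      vcov_theta <- NULL
    }
  }

  ll <- sjm_pll(theta, dat)
  structure(list(theta = theta, params = params, natural = natural,
                 loglik = ll$loglik, penalty = ll$penalty, pll = ll$pll,
                 converged = converged, n_iter = n_iter,
                 n_evals = evals, gradient_norm = gnorm,
                 rel_par_change = rel_par,
                 kappa = kappa, basis = basis, spec = spec, intcfg = intcfg,
                 vcov_theta = vcov_theta, vcov_natural = vcov_natural,
                 se_available = se_available,
                 theta_lmm = th_lmm,
                 covariate_table = .covariate_table(dataset, spec),
                 trials = dataset$trials,
                 trial_weights = as.numeric(prop.table(table(
                   factor(dataset$survival$trial,
                          levels = dataset$trials)))),
                 dataset_summary = summarize_dataset(dataset)),
            class = "sjm_fit")
}

# unique covariate rows with empirical weights (for population averaging)
.covariate_table <- function(dataset, spec) {
  covs <- union(spec$covariates_longitudinal, spec$covariates_survival)
  sv <- dataset$survival
  if (!length(covs))
    return(data.frame(.weight = 1))
  tab <- sv[, covs, drop = FALSE]
  key <- do.call(paste, c(tab, sep = "\r"))
  agg <- tapply(rep(1, nrow(tab)), key, sum)
  uk <- names(agg)
  out <- tab[match(uk, key), , drop = FALSE]
  out$.weight <- as.numeric(agg) / nrow(tab)
  rownames(out) <- NULL
  out
}

# natural-scale parameter vector (variance components on the variance scale)
.natural_from_theta <- function(theta, spec, nb, pL, pS, nl, ns) {
  p <- .theta_unpack(theta, spec, nb, pL, pS, nl, ns)
  out <- c(setNames(p$eta, if (length(p$eta) == 1) "association" else
                      paste0("association_", seq_along(p$eta))),
           setNames(p$beta_surv, paste0("surv_", ns)),
           setNames(p$beta_long, paste0("long_", nl)),
           sigma_eps = p$sigma_eps,
           sigma_w0_sq = p$Sigma_omega[1, 1],
           sigma_w01 = p$Sigma_omega[1, 2],
           sigma_w1_sq = p$Sigma_omega[2, 2])
  if (!is.null(p$Sigma_nu))
    out <- c(out, sigma_nuM_sq = p$Sigma_nu[1, 1],
             sigma_nuMT = p$Sigma_nu[1, 2],
             sigma_nuT_sq = p$Sigma_nu[2, 2])
  out
}

.natural_jacobian <- function(theta, spec, nb, pL, pS, nl, ns, h = 1e-6) {
  f0 <- .natural_from_theta(theta, spec, nb, pL, pS, nl, ns)
  J <- matrix(0, length(f0), length(theta))
  for (j in seq_along(theta)) {
    hp <- h * max(1, abs(theta[j]))
    tp <- tm <- theta
    tp[j] <- tp[j] + hp; tm[j] <- tm[j] - hp
    J[, j] <- (.natural_from_theta(tp, spec, nb, pL, pS, nl, ns) -
                 .natural_from_theta(tm, spec, nb, pL, pS, nl, ns)) / (2 * hp)
  }
  rownames(J) <- names(f0)
  J
}

#' Standard errors of a fitted joint model
#'
#' Natural-scale standard errors from the inverse Hessian of the penalized
#' log-likelihood, with delta-method transforms for the residual standard
#' deviation and the covariance components (estimated through their
#' Cholesky factors).
#'
#' @param fit An [sjm_fit][fit_joint_model()] object.
#' @return Named vector of standard errors.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "sjm_fit"))
  if (!fit$se_available)
    stop("standard errors unavailable (fit without se, or singular Hessian)")
  sqrt(pmax(diag(fit$vcov_natural), 0))
}

#' @export
print.sjm_fit <- function(x, ...) {
  cat("joint longitudinal-survival model fit\n")
  cat(sprintf("  link: %s, trial mode: %s, kappa = %g\n",
              x$spec$link, x$spec$trial_mode, x$kappa))
  cat(sprintf("  penalized log-likelihood: %.3f (log-likelihood %.3f)\n",
              x$pll, x$loglik))
  cat(sprintf("  converged: %s (max |grad| %.2e, %d iterations)\n",
              x$converged, x$gradient_norm, x$n_iter))
  est <- x$natural
  if (x$se_available) {
    se <- standard_errors(x)
    tab <- data.frame(estimate = est, se = se)
  } else tab <- data.frame(estimate = est)
  print(signif(tab, 4))
  invisible(x)
}

#' @export
summary.sjm_fit <- function(object, ...) {
  est <- object$natural
  if (object$se_available) {
    se <- standard_errors(object)
    z <- est / se
    tab <- data.frame(estimate = est, se = se, z = z,
                      p = 2 * pnorm(-abs(z)))
  } else tab <- data.frame(estimate = est)
  structure(list(table = tab, fit = object), class = "summary.sjm_fit")
}

#' @export
print.summary.sjm_fit <- function(x, ...) {
  print.sjm_fit(x$fit)
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' Writes estimates, the variance matrix and the model layout so mediation
#' can be recomputed without refitting.
#'
#' @param fit An `sjm_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(theta = fit$theta, natural = as.list(fit$natural),
              vcov_theta = fit$vcov_theta,
              loglik = fit$loglik, penalty = fit$penalty, pll = fit$pll,
              converged = fit$converged, kappa = fit$kappa,
              link = fit$spec$link, trial_mode = fit$spec$trial_mode,
              interior_knots = fit$basis$interior_knots,
              tau = fit$basis$tau)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
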