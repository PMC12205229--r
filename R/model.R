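#' Joint model specification
#'
#' Declares both submodels: the trajectory basis `f(t)` of the longitudinal
#' mean, which components carry individual random effects, the
#' treatment-by-time interaction `g(t)`, covariates of each submodel, the
#' link between the marker process and the hazard, and how trial-level
#' treatment-effect heterogeneity is handled.
#'
#' Links: `"current_level"` puts the error-free marker value \eqn{M(t)} in
#' the hazard, `"current_slope"` its time derivative, and
#' `"shared_random_effects"` the individual random effects themselves. A
#' mediated treatment effect requires the linked quantity to depend on
#' treatment: with the slope link this needs the treatment-by-time
#' interaction (otherwise the mediated effect is structurally zero — a
#' warning is issued), and the shared-random-effects link never allows
#' mediation since random effects are independent of treatment.
#'
#' @param link Link function between marker and hazard.
#' @param trajectory A [trajectory_basis()].
#' @param random_components Indices of the trajectory components carrying
#'   individual random effects; exactly two (intercept plus one time-varying
#'   component), the first of which must be the constant component.
#' @param covariates_longitudinal,covariates_survival Covariate column
#'   names entering each submodel.
#' @param interaction Include the treatment-by-`g(t)` interaction?
#' @param trial_mode `"none"`, `"fixed"` (treatment-by-trial fixed effects in
#'   both submodels, `2(K-1)` extra parameters), or `"random"` (bivariate
#'   Gaussian trial-level deviations of the two treatment effects).
#' @return An object of class `"model_spec"`.
#' @export
model_spec <- function(link = c("current_level", "current_slope",
                                "shared_random_effects"),
                       trajectory = trajectory_basis("intercept_linear"),
                       random_components = c(1L, 2L),
                       covariates_longitudinal = character(),
                       covariates_survival = character(),
                       interaction = TRUE,
                       trial_mode = c("none", "fixed", "random")) {
  link <- match.arg(link)
  trial_mode <- match.arg(trial_mode)
  stopifnot(inherits(trajectory, "trajectory_basis"))
  random_components <- as.integer(random_components)
  if (length(random_components) != 2 ||
      anyDuplicated(random_components) ||
      any(random_components < 1) ||
      any(random_components > trajectory$n_components))
    stop("random_components must name exactly two distinct trajectory ",
         "components")
  # the hazard-side factorization requires the first random component to be
  # time-constant (an intercept)
  tchk <- seq(0.05, 1, length.out = 7)
  ev <- trajectory_eval(trajectory, tchk)
  if (stats::sd(ev$f[, random_components[1]]) > 1e-12)
    stop("the first random component must be the constant (intercept) term")
  if (link == "current_slope" && !interaction)
    warning("current-slope link without a treatment-by-time interaction: ",
            "the linked slope does not depend on treatment, so the mediated ",
            "effect is structurally zero")
  mediation_possible <- link != "shared_random_effects"
  structure(list(link = link, trajectory = trajectory,
                 random_components = random_components,
                 covariates_longitudinal = covariates_longitudinal,
                 covariates_survival = covariates_survival,
                 interaction = interaction, trial_mode = trial_mode,
                 mediation_possible = mediation_possible),
            class = "model_spec")
}

#' Integration settings for likelihood and mediation integrals
#'
#' @param gh_nodes Gauss-Hermite nodes per random-effect dimension
#'   (default 9).
#' @param pseudo_adaptive Center and scale the Gauss-Hermite grid at each
#'   subject's random-effect posterior from the longitudinal submodel,
#'   computed once at initialization (default); otherwise the grid follows
#'   the random-effect prior.
#' @param mc_trial_draws Monte-Carlo draws for trial-level random effects
#'   (default 1000); one fixed draw set is shared by all subjects of a trial
#'   and across optimizer iterations (common random numbers keep the
#'   objective deterministic).
#' @param time_quadrature Gauss-Legendre order for the cumulative-hazard
#'   time integral on each subject interval (default 15).
#' @param n_mc_effects Monte-Carlo draws for the mediation effect integrals
#'   when sampling is required (default 5000); individual random effects in
#'   the effect integrals use deterministic Gauss-Hermite quadrature.
#' @param seed Seed controlling every Monte-Carlo component.
#' @return An object of class `"integration_config"`.
#' @export
integration_config <- function(gh_nodes = 9, pseudo_adaptive = TRUE,
                               mc_trial_draws = 1000, time_quadrature = 15,
                               n_mc_effects = 5000, seed = 1L) {
  stopifnot(gh_nodes >= 3, mc_trial_draws >= 100, time_quadrature >= 3)
  structure(list(gh_nodes = as.integer(gh_nodes),
                 pseudo_adaptive = isTRUE(pseudo_adaptive),
                 mc_trial_draws = as.integer(mc_trial_draws),
                 time_quadrature = as.integer(time_quadrature),
                 n_mc_effects = as.integer(n_mc_effects),
                 seed = as.integer(seed)),
            class = "integration_config")
}

# ---- parameter set -------------------------------------------------------

.chol2 <- function(S) t(chol(S))  # lower factor

.lchol_pack <- function(S) {
  L <- .chol2(S)
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
}

.lchol_unpack <- function(v) {
  L <- matrix(c(exp(v[1]), v[2], 0, exp(v[3])), 2, 2)
  L %*% t(L)
}

#' Construct a full parameter set
#'
#' Holds every parameter of the joint model: raw baseline-hazard
#' coefficients (squared to give the hazard), association parameter(s)
#' `eta`, residual standard deviation, random-effect covariances, and the
#' fixed effects of both submodels. Packing to and from the unconstrained
#' optimization vector is a bijection (covariances via their Cholesky
#' factors with log-diagonal).
#'
#' @param hazard_raw Raw (square-root scale) baseline hazard coefficients.
#' @param eta Association parameter (length 2 for the shared-random-effects
#'   link).
#' @param sigma_eps Residual standard deviation (> 0).
#' @param Sigma_omega 2x2 covariance of the individual random effects.
#' @param beta_long Named fixed effects of the longitudinal submodel, in the
#'   design order given by [parameter_names()].
#' @param beta_surv Named fixed effects of the survival submodel.
#' @param Sigma_nu Optional 2x2 trial-level covariance (random trial mode).
#' @return An object of class `"parameter_set"`.
#' @export
parameter_set <- function(hazard_raw, eta, sigma_eps, Sigma_omega,
                          beta_long, beta_surv, Sigma_nu = NULL) {
  stopifnot(sigma_eps > 0, all(dim(Sigma_omega) == c(2, 2)))
  if (min(eigen(Sigma_omega, symmetric = TRUE, only.values = TRUE)$values)
      <= 0)
    stop("Sigma_omega must be positive definite")
  if (!is.null(Sigma_nu) &&
      min(eigen(Sigma_nu, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("Sigma_nu must be positive definite")
  structure(list(hazard_raw = as.numeric(hazard_raw),
                 eta = as.numeric(eta),
                 sigma_eps = sigma_eps,
                 Sigma_omega = Sigma_omega,
                 beta_long = beta_long, beta_surv = beta_surv,
                 Sigma_nu = Sigma_nu),
            class = "parameter_set")
}

#' Fixed-effect design layout implied by a model specification
#'
#' @param spec A [model_spec()].
#' @param trials Trial labels of the dataset (needed for fixed trial mode).
#' @return List with the longitudinal and survival coefficient names.
#' @export
parameter_names <- function(spec, trials = NULL) {
  bl <- spec$trajectory$labels
  bl <- c(bl, "treatment")
  if (spec$interaction) bl <- c(bl, "treatment_g")
  bl <- c(bl, spec$covariates_longitudinal)
  bs <- c("treatment", spec$covariates_survival)
  if (spec$trial_mode == "fixed") {
    if (is.null(trials) || length(trials) < 2)
      stop("fixed trial mode needs the dataset trial labels (K >= 2)")
    tf <- paste0("treatment_trial", trials[-1])
    bl <- c(bl, tf)
    bs <- c(bs, tf)
  }
  list(beta_long = bl, beta_surv = bs)
}

# theta layout: [hazard_raw (nb)] [eta (neta)] [log sigma_eps]
# [lchol Sigma_omega (3)] [beta_long (pL)] [beta_surv (pS)]
# [lchol Sigma_nu (3), random trial mode only]
.theta_pack <- function(params, spec) {
  neta <- if (spec$link == "shared_random_effects") 2L else 1L
  stopifnot(length(params$eta) == neta)
  th <- c(params$hazard_raw, params$eta, log(params$sigma_eps),
          .lchol_pack(params$Sigma_omega),
          params$beta_long, params$beta_surv)
  if (spec$trial_mode == "random") {
    if (is.null(params$Sigma_nu))
      stop("random trial mode requires Sigma_nu in the parameter set")
    th <- c(th, .lchol_pack(params$Sigma_nu))
  }
  unname(th)
}

.theta_unpack <- function(theta, spec, nb, pL, pS,
                          names_long = NULL, names_surv = NULL) {
  neta <- if (spec$link == "shared_random_effects") 2L else 1L
  k <- 0
  gr <- function(n) { v <- theta[(k + 1):(k + n)]; k <<- k + n; v }
  hz <- gr(nb); eta <- gr(neta); ls <- gr(1); lw <- gr(3)
  bL <- gr(pL); bS <- gr(pS)
  Snu <- NULL
  if (spec$trial_mode == "random") Snu <- .lchol_unpack(gr(3))
  if (!is.null(names_long)) names(bL) <- names_long
  if (!is.null(names_surv)) names(bS) <- names_surv
  parameter_set(hazard_raw = hz, eta = eta, sigma_eps = exp(ls),
                Sigma_omega = .lchol_unpack(lw),
                beta_long = bL, beta_surv = bS, Sigma_nu = Snu)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("joint model parameter set\n")
  cat("  association eta:", signif(x$eta, 4), "\n")
  cat("  residual sd:", signif(x$sigma_eps, 4), "\n")
  cat("  longitudinal fixed effects:\n")
  print(signif(x$beta_long, 4))
  cat("  survival fixed effects:\n")
  print(signif(x$beta_surv, 4))
  cat("  Sigma_omega:\n"); print(signif(x$Sigma_omega, 4))
  if (!is.null(x$Sigma_nu)) { cat("  Sigma_nu:\n"); print(signif(x$Sigma_nu, 4)) }
  cat("  baseline hazard raw coefficients:", signif(x$hazard_raw, 3), "\n")
  invisible(x)
}

# ---- prepared fit data (C++ contract) ------------------------------------

# Build the per-subject design matrices, quadrature layout and Gauss-Hermite
# geometry consumed by the compiled likelihood.
.prepare_fit_data <- function(dataset, spec, basis, intcfg, kappa,
                              eps_draws = NULL) {
  sv <- dataset$survival
  lg <- dataset$longitudinal
  n <- nrow(sv)
  traj <- spec$trajectory
  rc <- spec$random_components
  trials <- dataset$trials
  pn <- parameter_names(spec, trials)

  covL <- spec$covariates_longitudinal
  covS <- spec$covariates_survival
  miss <- setdiff(union(covL, covS), names(sv))
  if (length(miss))
    stop("covariate(s) not in the survival table: ",
         paste(miss, collapse = ", "))

  # subject-level fixed design builder at arbitrary times
  make_design <- function(i, t, deriv = FALSE) {
    ev <- trajectory_eval(traj, t)
    f <- if (deriv) ev$df else ev$f
    g <- if (deriv) ev$dg else ev$g
    z <- sv$treatment[i]
    out <- f
    out <- cbind(out, if (deriv) 0 else z)
    if (spec$interaction) out <- cbind(out, z * g)
    for (cv in covL)
      out <- cbind(out, if (deriv) 0 else sv[[cv]][i])
    if (spec$trial_mode == "fixed")
      for (tr in trials[-1])
        out <- cbind(out, if (deriv) 0 else z * (sv$trial[i] == tr))
    out
  }

  idx <- split(seq_len(nrow(lg)), factor(lg$id, levels = sv$id))
  nij <- lengths(idx)
  if (any(nij == 0))
    stop("subject '", sv$id[which(nij == 0)[1]], "' has no measurements")
  off <- c(0L, cumsum(nij))
  ord <- unlist(idx, use.names = FALSE)
  y <- lg$value[ord]
  tl <- lg$time[ord]
  sid <- rep(seq_len(n), nij)

  X <- matrix(0, length(y), length(pn$beta_long))
  Zr <- matrix(0, length(y), 2)
  for (i in seq_len(n)) {
    rows <- (off[i] + 1):off[i + 1]
    X[rows, ] <- make_design(i, tl[rows])
    Zr[rows, ] <- trajectory_eval(traj, tl[rows])$f[, rc, drop = FALSE]
  }

  nq <- intcfg$time_quadrature
  gl <- pracma::gaussLegendre(nq, 0, 1)  # map per subject to [0, T*]
  Tst <- sv$time
  pL <- length(pn$beta_long)
  QWt <- t(outer(Tst, gl$w))             # weights scaled to [0, T*]
  QBt <- matrix(0, basis$n_basis, n * nq)
  QAt <- matrix(0, pL, n * nq)
  Qz1t <- matrix(0, nq, n)
  qz0 <- numeric(n)
  ATt <- matrix(0, pL, n)
  zTt <- matrix(0, 2, n)
  BTt <- t(mspline_eval(basis, pmin(Tst, basis$tau)))
  use_deriv <- spec$link == "current_slope"
  for (i in seq_len(n)) {
    cols <- ((i - 1) * nq + 1):(i * nq)
    tq <- Tst[i] * gl$x
    QBt[, cols] <- t(mspline_eval(basis, pmin(tq, basis$tau)))
    QAt[, cols] <- t(make_design(i, tq, deriv = use_deriv))
    ev <- trajectory_eval(traj, tq)
    fr <- if (use_deriv) ev$df else ev$f
    qz0[i] <- fr[1, rc[1]]
    Qz1t[, i] <- fr[, rc[2]]
    ATt[, i] <- make_design(i, Tst[i], deriv = use_deriv)
    evT <- trajectory_eval(traj, Tst[i])
    frT <- if (use_deriv) evT$df else evT$f
    zTt[, i] <- frT[1, rc]
  }

  Xs <- matrix(0, n, length(pn$beta_surv))
  Xs[, 1] <- sv$treatment
  j <- 1
  for (cv in covS) { j <- j + 1; Xs[, j] <- sv[[cv]] }
  if (spec$trial_mode == "fixed")
    for (tr in trials[-1]) {
      j <- j + 1
      Xs[, j] <- sv$treatment * (sv$trial == tr)
    }

  # parameter-independent longitudinal cross-products, one column/subject
  yty <- sy <- numeric(n)
  Xty <- sX <- matrix(0, pL, n)
  XtX <- matrix(0, pL * pL, n)
  XtZ <- matrix(0, pL * 2, n)
  Zty <- sZ <- matrix(0, 2, n)
  ZtZ <- matrix(0, 3, n)
  for (i in seq_len(n)) {
    rows <- (off[i] + 1):off[i + 1]
    Xi <- X[rows, , drop = FALSE]
    Zi <- Zr[rows, , drop = FALSE]
    yi <- y[rows]
    yty[i] <- sum(yi * yi); sy[i] <- sum(yi)
    Xty[, i] <- crossprod(Xi, yi)
    sX[, i] <- colSums(Xi)
    XtX[, i] <- crossprod(Xi)
    XtZ[, i] <- crossprod(Xi, Zi)
    Zty[, i] <- crossprod(Zi, yi)
    sZ[, i] <- colSums(Zi)
    zz <- crossprod(Zi)
    ZtZ[, i] <- c(zz[1, 1], zz[1, 2], zz[2, 2])
  }

  gh <- pracma::gaussHermite(intcfg$gh_nodes)
  trial_random <- spec$trial_mode == "random"
  dat <- list(
    n = n, nb = basis$n_basis, pL = pL,
    pS = length(pn$beta_surv), nq = nq, ngh = intcfg$gh_nodes,
    link = match(spec$link, c("current_level", "current_slope",
                              "shared_random_effects")) - 1L,
    neta = if (spec$link == "shared_random_effects") 2L else 1L,
    fixed_nodes = FALSE, trial_random = trial_random,
    y = y, X = X, Zr = Zr, off = off, delta = sv$event, Tstar = Tst,
    Xst = t(Xs), BTt = BTt, ATt = ATt, zTt = zTt, QWt = QWt,
    QBt = QBt, QAt = QAt, Qz1t = Qz1t, qz0 = qz0,
    yty = yty, sy = sy, nij = as.numeric(diff(off)),
    Xty = Xty, sX = sX, XtX = XtX, XtZ = XtZ, Zty = Zty, sZ = sZ,
    ZtZ = ZtZ,
    MUt = matrix(0, 2, n), UFt = matrix(0, 3, n),
    ghx = gh$x, ghlw = log(gh$w) + gh$x^2,
    P = penalty_matrix(basis), kappa = kappa,
    names_long = pn$beta_long, names_surv = pn$beta_surv)
  if (trial_random) {
    dat$itrial <- match(sv$trial, trials) - 1L
    dat$ntrial <- length(trials)
    dat$nmc <- intcfg$mc_trial_draws
    if (is.null(eps_draws)) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      set.seed(.substream_seed(intcfg$seed, "trial_mc"))
      eps_draws <- matrix(rnorm(2 * intcfg$mc_trial_draws),
                          intcfg$mc_trial_draws, 2)
      if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    }
    dat$EPS <- eps_draws
    dat$treat <- sv$treatment
  }
  dat
}

# attach pseudo-adaptive node geometry from a longitudinal-only parameter set
.attach_pseudo_nodes <- function(dat, theta_lmm) {
  post <- sjm_lmm_posterior(theta_lmm, dat)
  dat$MUt <- post$MUt
  dat$UFt <- post$UFt
  dat$fixed_nodes <- TRUE
  dat
}
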