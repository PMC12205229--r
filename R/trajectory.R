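#' Trajectory bases for the longitudinal submodel
#'
#' The marker mean trajectory is \eqn{\theta' f(t)} plus covariate and
#' treatment terms, where `f(t)` is a vector of time functions with analytic
#' first derivatives (required by the current-slope link), and `g(t)` carries
#' the treatment-by-time interaction.
#'
#' Three kinds are provided:
#' \describe{
#'   \item{`"intercept_linear"`}{\eqn{f(t) = (1, t)}, \eqn{g(t) = t} — the
#'     random intercept/slope model used throughout the simulation study.}
#'   \item{`"psa"`}{\eqn{f(t) = (1, f_1(t), f_2(t))} with
#'     \eqn{f_1(t) = (1+t)^\alpha - 1} capturing a sharp post-baseline drop
#'     (decreasing toward −1 for \eqn{\alpha < 0}) and a long-term rise
#'     \eqn{f_2}; \eqn{g(t) = f_2(t)}. The \eqn{f_2} form admits two
#'     algebraic readings; the default is
#'     \eqn{f_2(t) = t^{\lambda+1} (1+t)^\lambda} (`f2_form = "product"`),
#'     with \eqn{f_2(t) = t^{\lambda+1} / (1+t)^\lambda}
#'     (`f2_form = "ratio"`) available. Both satisfy \eqn{f_2(0) = 0} and
#'     increase from 0 for \eqn{\lambda > -1}.}
#'   \item{`"custom"`}{user-supplied component list; each component is a
#'     `list(f = , df = )` pair of vectorized functions.}
#' }
#'
#' @param kind One of `"intercept_linear"`, `"psa"`, `"custom"`.
#' @param alpha,lambda Shape parameters of the `"psa"` kind.
#' @param f2_form `"product"` (default) or `"ratio"`; see Details.
#' @param components For `"custom"`: list of `list(f, df)` pairs.
#' @param g,dg For `"custom"`: interaction function and its derivative;
#'   defaults to the last trajectory component.
#' @return An object of class `"trajectory_basis"`.
#' @export
trajectory_basis <- function(kind = c("intercept_linear", "psa", "custom"),
                             alpha = -11.4, lambda = -0.3,
                             f2_form = c("product", "ratio"),
                             components = NULL, g = NULL, dg = NULL) {
  kind <- match.arg(kind)
  f2_form <- match.arg(f2_form)
  if (kind == "intercept_linear") {
    comps <- list(
      list(f = function(t) rep(1, length(t)), df = function(t) rep(0, length(t))),
      list(f = function(t) t, df = function(t) rep(1, length(t))))
    gf <- function(t) t; dgf <- function(t) rep(1, length(t))
    labels <- c("intercept", "time")
  } else if (kind == "psa") {
    f1 <- function(t) (1 + t)^alpha - 1
    df1 <- function(t) alpha * (1 + t)^(alpha - 1)
    if (f2_form == "product") {
      f2 <- function(t) t^(lambda + 1) * (1 + t)^lambda
      df2 <- function(t) (lambda + 1) * t^lambda * (1 + t)^lambda +
        t^(lambda + 1) * lambda * (1 + t)^(lambda - 1)
    } else {
      f2 <- function(t) t^(lambda + 1) / (1 + t)^lambda
      df2 <- function(t) (lambda + 1) * t^lambda / (1 + t)^lambda -
        t^(lambda + 1) * lambda / (1 + t)^(lambda + 1)
    }
    comps <- list(
      list(f = function(t) rep(1, length(t)), df = function(t) rep(0, length(t))),
      list(f = f1, df = df1),
      list(f = f2, df = df2))
    gf <- f2; dgf <- df2
    labels <- c("intercept", "f1", "f2")
  } else {
    if (is.null(components) || !length(components))
      stop("custom trajectory requires a non-empty component list")
    comps <- components
    if (is.null(g)) {
      gf <- comps[[length(comps)]]$f; dgf <- comps[[length(comps)]]$df
    } else {
      if (is.null(dg)) stop("custom g requires its derivative dg")
      gf <- g; dgf <- dg
    }
    labels <- paste0("f", seq_along(comps) - 1)
  }
  structure(list(kind = kind, components = comps, g = gf, dg = dgf,
                 labels = labels, alpha = alpha, lambda = lambda,
                 f2_form = f2_form, n_components = length(comps)),
            class = "trajectory_basis")
}

#' Evaluate a trajectory basis and its derivatives
#'
#' @param basis A [trajectory_basis()].
#' @param t Nonnegative evaluation times.
#' @param tau Optional horizon; times beyond it are rejected.
#' @return List with matrices `f`, `df` (`length(t)` rows, one column per
#'   component) and vectors `g`, `dg`.
#' @export
trajectory_eval <- function(basis, t, tau = NULL) {
  stopifnot(inherits(basis, "trajectory_basis"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0))
    stop("trajectory times must be finite and nonnegative")
  if (!is.null(tau) && any(t > tau))
    stop(sprintf("trajectory times must lie in [0, %g]", tau))
  f <- vapply(basis$components, function(cmp) cmp$f(t), numeric(length(t)))
  df <- vapply(basis$components, function(cmp) cmp$df(t), numeric(length(t)))
  if (length(t) == 1) { f <- matrix(f, 1); df <- matrix(df, 1) }
  colnames(f) <- colnames(df) <- basis$labels
  list(f = f, df = df, g = basis$g(t), dg = basis$dg(t))
}

#' @export
print.trajectory_basis <- function(x, ...) {
  cat(sprintf("trajectory basis '%s' with %d components (%s)\n",
              x$kind, x$n_components, paste(x$labels, collapse = ", ")))
  if (x$kind == "psa")
    cat(sprintf("  alpha = %g, lambda = %g, f2 form = %s\n",
                x$alpha, x$lambda, x$f2_form))
  invisible(x)
}
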