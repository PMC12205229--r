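#' M-spline basis for the baseline hazard
#'
#' Constructs an M-spline basis of a given order on `[0, tau]` with interior
#' knots either supplied directly or placed at quantiles of observed event
#' times (the usual penalized-hazard convention), with an equidistant
#' fallback when no event times are given.
#'
#' The basis underlies the baseline hazard \eqn{\lambda_0(t) = \sum_i c_i
#' M_i(t)} where nonnegativity of the hazard is guaranteed by parameterizing
#' \eqn{c_i = r_i^2} in terms of unconstrained raw coefficients \eqn{r_i}.
#' With the knot convention used here (`n_knots` counts the two boundary
#' knots), a basis of order `ord` has `n_knots + ord - 2` functions.
#'
#' @param n_knots Total number of knots including the two boundary knots
#'   (default 7, i.e. 5 interior knots for a cubic basis).
#' @param tau Upper boundary of the time domain (study horizon).
#' @param order Spline order (4 = cubic, the default).
#' @param interior_knots Optional strictly increasing vector of interior
#'   knots in `(0, tau)`; overrides `n_knots`.
#' @param event_times Optional event times used to place interior knots at
#'   quantiles; ignored when `interior_knots` is given.
#' @return An object of class `"mspline_basis"`.
#' @export
mspline_basis <- function(n_knots = 7, tau, order = 4, interior_knots = NULL,
                          event_times = NULL) {
  stopifnot(is.numeric(tau), length(tau) == 1, tau > 0, order >= 1)
  if (is.null(interior_knots)) {
    n_int <- n_knots - 2
    if (n_int < 0) stop("n_knots must be at least 2 (the two boundary knots)")
    if (n_int == 0) {
      interior_knots <- numeric(0)
    } else if (!is.null(event_times) && length(event_times) >= n_int + 1) {
      p <- seq_len(n_int) / (n_int + 1)
      interior_knots <- unname(stats::quantile(event_times, p, type = 7))
      # quantile knots can tie on discrete data; fall back to equidistant
      interior_knots <- interior_knots[interior_knots > 0 & interior_knots < tau]
      if (anyDuplicated(interior_knots) || length(interior_knots) < n_int)
        interior_knots <- tau * seq_len(n_int) / (n_int + 1)
    } else {
      interior_knots <- tau * seq_len(n_int) / (n_int + 1)
    }
  }
  interior_knots <- as.numeric(interior_knots)
  if (length(interior_knots) > 0) {
    if (any(diff(interior_knots) <= 0))
      stop("interior knots must be strictly increasing")
    if (any(interior_knots <= 0) || any(interior_knots >= tau))
      stop("interior knots must lie strictly inside (0, tau)")
  }
  knots <- c(rep(0, order), interior_knots, rep(tau, order))
  structure(list(order = order, tau = tau,
                 interior_knots = interior_knots,
                 knots = knots,
                 n_basis = length(interior_knots) + order),
            class = "mspline_basis")
}

#' @export
print.mspline_basis <- function(x, ...) {
  cat(sprintf("M-spline basis: order %d, %d basis functions on [0, %g]\n",
              x$order, x$n_basis, x$tau))
  cat("interior knots:", if (length(x$interior_knots))
    paste(signif(x$interior_knots, 4), collapse = " ") else "(none)", "\n")
  invisible(x)
}

# B-spline design matrix on the basis' knot sequence, with boundary handling:
# splineDesign is right-open at the last knot, so clamp t = tau to the
# half-open convention by evaluating at tau via derivs of the limit.
.bspline_design <- function(basis, t, deriv = 0) {
  t <- as.numeric(t)
  ord <- basis$order
  # splineDesign excludes x == last knot; evaluate tau as left limit
  eps_idx <- t >= basis$tau
  tt <- t
  tt[eps_idx] <- basis$tau * (1 - 1e-12) + 0 # left limit at the boundary
  splines::splineDesign(basis$knots, tt, ord = ord,
                        derivs = rep(deriv, length(tt)))
}

# scale factors turning B-splines into M-splines (unit-integral density form)
.mspline_scale <- function(basis) {
  ord <- basis$order
  k <- basis$knots
  ord / (k[seq_len(basis$n_basis) + ord] - k[seq_len(basis$n_basis)])
}

#' Evaluate M-spline basis functions
#'
#' Each M-spline is a nonnegative spline normalized to integrate to one over
#' its support, obtained by rescaling the corresponding B-spline.
#'
#' @param basis An [mspline_basis()].
#' @param t Evaluation times in `[0, tau]`.
#' @param deriv Derivative order (0, 1 or 2).
#' @return Matrix with `length(t)` rows and `n_basis` columns.
#' @export
mspline_eval <- function(basis, t, deriv = 0) {
  stopifnot(inherits(basis, "mspline_basis"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0) || any(t > basis$tau))
    stop(sprintf("evaluation times must lie in [0, %g]", basis$tau))
  B <- .bspline_design(basis, t, deriv = deriv)
  sweep(B, 2, .mspline_scale(basis), `*`)
}

# Gauss-Legendre nodes on [a,b]; exact for polynomials of degree <= 2n-1
.gl_nodes <- function(n, a, b) {
  q <- pracma::gaussLegendre(n, a, b)
  list(x = q$x, w = q$w)
}

# distinct knot intervals of the basis (piecewise-polynomial segments)
.knot_intervals <- function(basis) {
  brk <- unique(c(0, basis$interior_knots, basis$tau))
  cbind(lower = brk[-length(brk)], upper = brk[-1])
}

#' Integrated M-splines (I-splines)
#'
#' Computes \eqn{I_i(t) = \int_0^t M_i(u)\,du} exactly by piecewise
#' Gauss-Legendre quadrature (exact for the piecewise-polynomial integrand).
#' Each I-spline is nondecreasing from 0 to 1.
#'
#' @inheritParams mspline_eval
#' @return Matrix with `length(t)` rows and `n_basis` columns.
#' @export
ispline_eval <- function(basis, t) {
  stopifnot(inherits(basis, "mspline_basis"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0) || any(t > basis$tau))
    stop(sprintf("evaluation times must lie in [0, %g]", basis$tau))
  iv <- .knot_intervals(basis)
  ngl <- max(3, ceiling((basis$order + 1) / 2))  # exact for degree order-1
  # cumulative integrals over whole intervals
  cum <- matrix(0, nrow(iv) + 1, basis$n_basis)
  for (j in seq_len(nrow(iv))) {
    q <- .gl_nodes(ngl, iv[j, 1], iv[j, 2])
    cum[j + 1, ] <- cum[j, ] + crossprod(q$w, mspline_eval(basis, q$x))
  }
  out <- matrix(0, length(t), basis$n_basis)
  brk <- c(iv[, 1], basis$tau)
  for (m in seq_along(t)) {
    j <- findInterval(t[m], brk, rightmost.closed = TRUE)
    j <- max(1L, min(j, nrow(iv)))
    val <- cum[j, ]
    if (t[m] > iv[j, 1]) {
      q <- .gl_nodes(ngl, iv[j, 1], t[m])
      val <- val + as.numeric(crossprod(q$w, mspline_eval(basis, q$x)))
    }
    out[m, ] <- val
  }
  out
}

#' Baseline hazard and cumulative baseline hazard
#'
#' The baseline hazard is \eqn{\lambda_0(t) = \sum_i r_i^2 M_i(t)} with raw
#' coefficients `raw_coefficients` squared to enforce nonnegativity; the
#' cumulative hazard \eqn{\Lambda_0(t)} uses the exact integrated basis
#' (I-splines), so \eqn{\Lambda_0(0)=0} and \eqn{\Lambda_0} is nondecreasing.
#'
#' @param raw_coefficients Unconstrained coefficient vector (length
#'   `n_basis`); the hazard uses their squares.
#' @inheritParams mspline_eval
#' @return Numeric vector of hazard (or cumulative hazard) values.
#' @export
baseline_hazard <- function(raw_coefficients, basis, t) {
  stopifnot(length(raw_coefficients) == basis$n_basis)
  drop(mspline_eval(basis, t) %*% raw_coefficients^2)
}

#' @rdname baseline_hazard
#' @export
cumulative_baseline <- function(raw_coefficients, basis, t) {
  stopifnot(length(raw_coefficients) == basis$n_basis)
  drop(ispline_eval(basis, t) %*% raw_coefficients^2)
}

#' Curvature penalty matrix and smoothness penalty
#'
#' `penalty_matrix` returns \eqn{P_{ij} = \int_0^\tau M_i''(u) M_j''(u) du},
#' computed exactly by piecewise Gauss-Legendre quadrature; the smoothness
#' penalty of a hazard with squared coefficients \eqn{c = r^2} is then the
#' quadratic form \eqn{\int \lambda_0''(u)^2 du = c' P c}.
#'
#' @inheritParams baseline_hazard
#' @return `penalty_matrix`: symmetric positive semidefinite matrix;
#'   `smoothness_penalty`: a nonnegative scalar.
#' @export
penalty_matrix <- function(basis) {
  if (basis$order < 3)
    stop("curvature penalty requires order >= 3 (second derivative)")
  iv <- .knot_intervals(basis)
  ngl <- basis$order  # integrand degree 2*(order-3) <= 2*ngl-1
  P <- matrix(0, basis$n_basis, basis$n_basis)
  for (j in seq_len(nrow(iv))) {
    q <- .gl_nodes(ngl, iv[j, 1], iv[j, 2])
    D2 <- mspline_eval(basis, q$x, deriv = 2)
    P <- P + crossprod(D2, D2 * q$w)
  }
  (P + t(P)) / 2
}

#' @rdname penalty_matrix
#' @export
smoothness_penalty <- function(raw_coefficients, basis) {
  stopifnot(length(raw_coefficients) == basis$n_basis)
  cc <- raw_coefficients^2
  as.numeric(cc %*% penalty_matrix(basis) %*% cc)
}

#' Raw coefficients representing a given positive function
#'
#' Least-squares projection of a positive target function onto the M-spline
#' span, returned on the raw (square-root) scale. For targets inside the
#' nonnegative-coefficient cone (e.g. positive affine functions) the
#' representation is exact up to the spline approximation error.
#'
#' @param basis An [mspline_basis()].
#' @param f Vectorized positive function of time.
#' @return Raw coefficient vector of length `n_basis`.
#' @export
mspline_project <- function(basis, f) {
  # interpolation at Greville-type sites gives exact coefficients for
  # functions inside the spline span (affine functions in particular)
  ord <- basis$order
  k <- basis$knots
  grev <- vapply(seq_len(basis$n_basis), function(i)
    mean(k[(i + 1):(i + ord - 1)]), 0)
  grev <- pmin(pmax(grev, 0), basis$tau)
  # oversample to stabilize least squares
  ts <- sort(unique(c(grev, seq(0, basis$tau, length.out = 4 * basis$n_basis))))
  M <- mspline_eval(basis, ts)
  cc <- stats::coef(stats::lm.fit(M, f(ts)))
  cc[is.na(cc)] <- 0
  if (any(cc < -1e-8))
    warning("target function leaves the nonnegative-coefficient cone; ",
            "hazard representation is approximate")
  sqrt(pmax(cc, 0))
}
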