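# Spline machinery for the baseline hazard: nonnegativity, unit integrals,
# exact cumulative hazards and the curvature penalty.

test_that("an order-1 basis with no interior knots is the uniform density", {
  b <- mspline_basis(n_knots = 2, tau = 4, order = 1)
  expect_equal(b$n_basis, 1)
  expect_equal(drop(mspline_eval(b, c(0.5, 2, 3.9))), rep(1 / 4, 3))
})

test_that("M-splines are nonnegative and integrate to one on varied layouts", {
  layouts <- list(
    mspline_basis(7, tau = 3),
    mspline_basis(4, tau = 1),
    mspline_basis(tau = 2, interior_knots = c(0.1, 0.15, 1.9)),
    mspline_basis(5, tau = 3, order = 3))
  for (b in layouts) {
    tg <- seq(0, b$tau, length.out = 2001)
    M <- mspline_eval(b, tg)
    expect_true(all(M >= 0))
    for (i in seq_len(b$n_basis)) {
      num <- stats::integrate(function(u) mspline_eval(b, u)[, i], 0, b$tau,
                              rel.tol = 1e-10, subdivisions = 400L)$value
      expect_equal(num, 1, tolerance = 1e-6)
    }
    # I-splines reach exactly 1 at tau
    expect_equal(drop(ispline_eval(b, b$tau)), rep(1, b$n_basis),
                 tolerance = 1e-10)
  }
})

test_that("evaluation outside [0, tau] is a domain error", {
  b <- mspline_basis(7, tau = 3)
  expect_error(mspline_eval(b, 3.01), "\\[0, 3\\]")
  expect_error(mspline_eval(b, -0.001), "\\[0, 3\\]")
  expect_error(ispline_eval(b, 3.5), "\\[0, 3\\]")
})

test_that("cumulative baseline equals numeric integration and is monotone", {
  set.seed(31)
  for (rep in 1:3) {
    b <- mspline_basis(sample(4:8, 1), tau = runif(1, 1, 5))
    raw <- rnorm(b$n_basis)
    for (t in runif(4, 0, b$tau)) {
      num <- stats::integrate(function(u) baseline_hazard(raw, b, u), 0, t,
                              rel.tol = 1e-12, subdivisions = 500L)$value
      expect_equal(cumulative_baseline(raw, b, t), num, tolerance = 1e-8)
    }
    tg <- sort(runif(30, 0, b$tau))
    expect_true(all(diff(cumulative_baseline(raw, b, tg)) >= -1e-12))
    expect_equal(cumulative_baseline(raw, b, 0), 0)
  }
})

test_that("zero coefficients give a zero hazard everywhere", {
  b <- mspline_basis(7, tau = 3)
  raw <- rep(0, b$n_basis)
  tg <- seq(0, 3, 0.25)
  expect_equal(baseline_hazard(raw, b, tg), rep(0, length(tg)))
  expect_equal(cumulative_baseline(raw, b, tg), rep(0, length(tg)))
  expect_equal(smoothness_penalty(raw, b), 0)
})

test_that("the curvature penalty vanishes for representable affine hazards", {
  b <- mspline_basis(6, tau = 2)
  raw <- mspline_project(b, function(t) 0.5 + 0.2 * t)
  tg <- seq(0, 2, length.out = 101)
  expect_equal(baseline_hazard(raw, b, tg), 0.5 + 0.2 * tg,
               tolerance = 1e-8)
  expect_lt(smoothness_penalty(raw, b), 1e-12)
})

test_that("scaling the hazard by c scales the penalty by c^2", {
  set.seed(7)
  b <- mspline_basis(7, tau = 3)
  raw <- abs(rnorm(b$n_basis))
  p1 <- smoothness_penalty(raw, b)
  cc <- 2.7
  p2 <- smoothness_penalty(sqrt(cc) * raw, b)
  expect_equal(p2, cc^2 * p1, tolerance = 1e-12)
})

test_that("the penalty matches numeric integration of the squared curvature", {
  set.seed(11)
  b <- mspline_basis(7, tau = 3)
  raw <- rnorm(b$n_basis)
  f <- function(u) {
    d2 <- mspline_eval(b, u, deriv = 2) %*% raw^2
    drop(d2)^2
  }
  # integrate piecewise between knots (the curvature is only piecewise smooth)
  brk <- c(0, b$interior_knots, 3)
  num <- sum(vapply(seq_len(length(brk) - 1), function(j)
    stats::integrate(f, brk[j], brk[j + 1], rel.tol = 1e-10)$value, 0))
  expect_equal(smoothness_penalty(raw, b), num, tolerance = 1e-6)
})

test_that("adding a representable affine component leaves the penalty unchanged", {
  set.seed(13)
  b <- mspline_basis(6, tau = 2)
  c_rand <- abs(rnorm(b$n_basis))
  c_aff <- mspline_project(b, function(t) 0.3 + 0.1 * t)^2
  p1 <- smoothness_penalty(sqrt(c_rand), b)
  p2 <- smoothness_penalty(sqrt(c_rand + c_aff), b)
  # cross term: integral of lambda'' * affine'' is zero since affine'' = 0
  expect_equal(p2, p1, tolerance = 1e-10)
})

test_that("quantile knot placement stays inside (0, tau) and falls back", {
  ev <- c(rexp(40, 1), 2.9)
  b <- mspline_basis(7, tau = 3, event_times = ev)
  expect_true(all(b$interior_knots > 0 & b$interior_knots < 3))
  expect_equal(b$n_basis, 9)
  b2 <- mspline_basis(7, tau = 3, event_times = rep(1, 50))  # ties
  expect_equal(b2$interior_knots, 3 * (1:5) / 6)
  expect_error(mspline_basis(tau = 3, interior_knots = c(2, 1)),
               "increasing")
})
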