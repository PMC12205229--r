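// Penalized joint log-likelihood for a longitudinal marker and a
// time-to-event endpoint.
//
// Conditional on the individual random effects omega (and trial effects nu),
// the longitudinal records are independent Gaussians around the error-free
// marker and the survival contribution is lambda(T*)^delta * exp(-Lambda(T*)).
// omega is integrated out on a (pseudo-)adaptive Gauss-Hermite grid whose
// per-subject centers/scales are fixed at initialization; trial-level effects
// are integrated by Monte Carlo with common random numbers shared by all
// subjects of a trial.
//
// All design/basis evaluations and the parameter-independent longitudinal
// cross-products are precomputed in R (transposed for column contiguity), so
// one likelihood evaluation is a pure flop loop; gradients and Hessians are
// finite differences taken inside C++ against a single no-copy data view.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

mat view(const Rcpp::List& d, const char* nm) {
  Rcpp::NumericMatrix m = d[nm];
  return mat(m.begin(), m.nrow(), m.ncol(), false, true);
}
vec viewv(const Rcpp::List& d, const char* nm) {
  Rcpp::NumericVector v = d[nm];
  return vec(v.begin(), v.size(), false, true);
}

struct FitData {
  int n, nb, pL, pS, nq, ngh, link, neta;
  bool fixed_nodes, trial_random;
  vec y; mat X; mat Zr; uvec off;          // raw longitudinal blocks (lmm)
  vec del, Tst;
  mat Xst;        // pS x n
  mat BTt;        // nb x n
  mat ATt;        // pL x n
  mat zTt;        // 2 x n
  mat QWt, Qz1t;  // nq x n
  vec qz0;        // n
  mat QBt;        // nb x (n*nq)
  mat QAt;        // pL x (n*nq)
  // parameter-independent longitudinal cross-products
  vec yty, sy, nij;
  mat Xty, sX;    // pL x n
  mat XtX;        // (pL*pL) x n
  mat XtZ;        // (pL*2) x n
  mat Zty, sZ;    // 2 x n
  mat ZtZ;        // 3 x n (z11, z12, z22)
  mat MUt;        // 2 x n
  mat UFt;        // 3 x n (u11, u12, u22)
  vec ghx, ghlw;
  mat P;
  double kappa;
  uvec itrial; int ntrial, nmc;
  mat EPS; vec treat;
};

FitData unpack_data(const Rcpp::List& d) {
  FitData D;
  D.n  = Rcpp::as<int>(d["n"]);   D.nb = Rcpp::as<int>(d["nb"]);
  D.pL = Rcpp::as<int>(d["pL"]);  D.pS = Rcpp::as<int>(d["pS"]);
  D.nq = Rcpp::as<int>(d["nq"]);  D.ngh = Rcpp::as<int>(d["ngh"]);
  D.link = Rcpp::as<int>(d["link"]);
  D.neta = Rcpp::as<int>(d["neta"]);
  D.fixed_nodes = Rcpp::as<bool>(d["fixed_nodes"]);
  D.trial_random = Rcpp::as<bool>(d["trial_random"]);
  D.y = viewv(d, "y"); D.X = view(d, "X"); D.Zr = view(d, "Zr");
  D.off = Rcpp::as<uvec>(d["off"]);
  D.del = viewv(d, "delta"); D.Tst = viewv(d, "Tstar");
  D.Xst = view(d, "Xst"); D.BTt = view(d, "BTt"); D.ATt = view(d, "ATt");
  D.zTt = view(d, "zTt");
  D.QWt = view(d, "QWt"); D.Qz1t = view(d, "Qz1t");
  D.qz0 = viewv(d, "qz0");
  D.QBt = view(d, "QBt"); D.QAt = view(d, "QAt");
  D.yty = viewv(d, "yty"); D.sy = viewv(d, "sy"); D.nij = viewv(d, "nij");
  D.Xty = view(d, "Xty"); D.sX = view(d, "sX");
  D.XtX = view(d, "XtX"); D.XtZ = view(d, "XtZ");
  D.Zty = view(d, "Zty"); D.sZ = view(d, "sZ"); D.ZtZ = view(d, "ZtZ");
  D.MUt = view(d, "MUt"); D.UFt = view(d, "UFt");
  D.ghx = viewv(d, "ghx"); D.ghlw = viewv(d, "ghlw");
  D.P = view(d, "P");
  D.kappa = Rcpp::as<double>(d["kappa"]);
  if (D.trial_random) {
    D.itrial = Rcpp::as<uvec>(d["itrial"]);
    D.ntrial = Rcpp::as<int>(d["ntrial"]);
    D.nmc = Rcpp::as<int>(d["nmc"]);
    D.EPS = view(d, "EPS");
    D.treat = viewv(d, "treat");
  } else { D.ntrial = 0; D.nmc = 0; }
  return D;
}

struct Params {
  vec raw, chaz, eta;
  double sige;
  double Lw11, Lw21, Lw22, ldetLw, Li11, Li21, Li22;
  vec bL, bS;
  double lnu11, lnu21, lnu22;
  double ls_const;
};

Params unpack_theta(const vec& th, const FitData& D) {
  Params P;
  int k = 0;
  P.raw = th.subvec(k, k + D.nb - 1); k += D.nb;
  P.chaz = square(P.raw);
  P.eta = th.subvec(k, k + D.neta - 1); k += D.neta;
  P.sige = std::exp(th(k)); k += 1;
  const double l11 = th(k), l21 = th(k + 1), l22 = th(k + 2); k += 3;
  P.Lw11 = std::exp(l11); P.Lw21 = l21; P.Lw22 = std::exp(l22);
  P.ldetLw = l11 + l22;
  P.Li11 = std::exp(-l11);
  P.Li21 = -l21 * std::exp(-l11 - l22);
  P.Li22 = std::exp(-l22);
  P.bL = th.subvec(k, k + D.pL - 1); k += D.pL;
  P.bS = th.subvec(k, k + D.pS - 1); k += D.pS;
  if (D.trial_random) {
    P.lnu11 = th(k); P.lnu21 = th(k + 1); P.lnu22 = th(k + 2); k += 3;
  }
  P.ls_const = -0.5 * std::log(2.0 * M_PI) - std::log(P.sige);
  return P;
}

// log-likelihood of one subject with optional trial-effect shifts dM
// (marker mean) and dT (log-hazard)
double subject_ll(int i, double dM, double dT,
                  const FitData& D, const Params& P) {
  const int nq = D.nq, ngh = D.ngh, pL = D.pL;

  // GH geometry: omega = mu + sqrt(2) U z, U upper-triangular so omega1
  // varies along one coordinate only
  double mu0, mu1, u11, u12, u22;
  if (D.fixed_nodes) {
    const double* uf = D.UFt.colptr(i);
    mu0 = D.MUt(0, i); mu1 = D.MUt(1, i);
    u11 = uf[0]; u12 = uf[1]; u22 = uf[2];
  } else {
    const double S11 = P.Lw11 * P.Lw11;
    const double S12 = P.Lw11 * P.Lw21;
    const double S22 = P.Lw21 * P.Lw21 + P.Lw22 * P.Lw22;
    mu0 = 0.0; mu1 = 0.0;
    u22 = std::sqrt(S22); u12 = S12 / u22;
    const double dd = S11 - u12 * u12;
    u11 = std::sqrt(dd > 1e-300 ? dd : 1e-300);
  }
  const double lognorm = std::log(2.0 * u11 * u22);

  // survival fixed pieces
  const double* xs = D.Xst.colptr(i);
  double fs = dT;
  for (int j = 0; j < D.pS; ++j) fs += xs[j] * P.bS(j);
  double lamT = 0.0;
  {
    const double* bt = D.BTt.colptr(i);
    for (int j = 0; j < D.nb; ++j) lamT += bt[j] * P.chaz(j);
    if (lamT < 1e-300) lamT = 1e-300;
  }
  const double delta = D.del(i);

  // longitudinal sufficient statistics at current beta (with shift dM):
  // rr = y'y - 2 b'X'y + b'X'Xb  (then shift), rZ = Z'y - (X'Z)'b
  double rr, rZ0, rZ1;
  {
    const double* xty = D.Xty.colptr(i);
    const double* xtx = D.XtX.colptr(i);
    const double* xtz = D.XtZ.colptr(i);
    double bXty = 0.0, bXXb = 0.0;
    for (int a = 0; a < pL; ++a) {
      bXty += P.bL(a) * xty[a];
      double s = 0.0;
      for (int b = 0; b < pL; ++b) s += xtx[a * pL + b] * P.bL(b);
      bXXb += P.bL(a) * s;
    }
    rr = D.yty(i) - 2.0 * bXty + bXXb;
    rZ0 = D.Zty(0, i); rZ1 = D.Zty(1, i);
    for (int a = 0; a < pL; ++a) {
      rZ0 -= xtz[a] * P.bL(a);
      rZ1 -= xtz[pL + a] * P.bL(a);
    }
    if (dM != 0.0) {
      double sr = D.sy(i);
      const double* sx = D.sX.colptr(i);
      for (int a = 0; a < pL; ++a) sr -= sx[a] * P.bL(a);
      rr += -2.0 * dM * sr + D.nij(i) * dM * dM;
      rZ0 -= dM * D.sZ(0, i);
      rZ1 -= dM * D.sZ(1, i);
    }
  }
  const double z11 = D.ZtZ(0, i), z12 = D.ZtZ(1, i), z22 = D.ZtZ(2, i);
  const double inv2s2 = 1.0 / (2.0 * P.sige * P.sige);
  const double nconst = D.nij(i) * P.ls_const;

  // survival integrand pieces at quadrature nodes
  double G[64];
  double mfixT = 0.0, e0 = 0.0, zT1 = 0.0, eta1 = 0.0;
  const double* qw = D.QWt.colptr(i);
  const double* qz1 = D.Qz1t.colptr(i);
  if (D.link <= 1) {
    eta1 = P.eta(0);
    for (int q = 0; q < nq; ++q) {
      const double* qb = D.QBt.colptr((uword)i * nq + q);
      const double* qa = D.QAt.colptr((uword)i * nq + q);
      double lam = 0.0;
      for (int j = 0; j < D.nb; ++j) lam += qb[j] * P.chaz(j);
      double mf = 0.0;
      for (int j = 0; j < pL; ++j) mf += qa[j] * P.bL(j);
      if (dM != 0.0 && D.link == 0) mf += dM;
      G[q] = qw[q] * lam * std::exp(fs + eta1 * mf);
    }
    const double* at = D.ATt.colptr(i);
    for (int j = 0; j < pL; ++j) mfixT += at[j] * P.bL(j);
    if (D.link == 0) mfixT += dM;
    e0 = eta1 * D.qz0(i);
    zT1 = D.zTt(1, i);
  } else {
    for (int q = 0; q < nq; ++q) {
      const double* qb = D.QBt.colptr((uword)i * nq + q);
      double lam = 0.0;
      for (int j = 0; j < D.nb; ++j) lam += qb[j] * P.chaz(j);
      G[q] = qw[q] * lam;
    }
  }
  const double loglamT = std::log(lamT);
  const double zT0 = D.zTt(0, i);

  // factor exp(e0 * w0) over the two grid coordinates
  double E0a[32], E0b[32];
  if (D.link <= 1) {
    for (int j = 0; j < ngh; ++j) {
      E0a[j] = std::exp(e0 * (mu0 + M_SQRT2 * u11 * D.ghx(j)));
      E0b[j] = std::exp(e0 * M_SQRT2 * u12 * D.ghx(j));
    }
  }

  // streaming log-sum-exp over the GH grid
  double m_best = -datum::inf, acc = 0.0;
  for (int j2 = 0; j2 < ngh; ++j2) {
    const double w1 = mu1 + M_SQRT2 * u22 * D.ghx(j2);
    double inner = 0.0, hT1 = 0.0;
    if (D.link <= 1) {
      for (int q = 0; q < nq; ++q)
        inner += G[q] * std::exp(eta1 * w1 * qz1[q]);
      inner *= E0b[j2];
      hT1 = eta1 * zT1 * w1;
    } else {
      for (int q = 0; q < nq; ++q) inner += G[q];
    }
    const double lw2 = D.ghlw(j2);
    for (int j1 = 0; j1 < ngh; ++j1) {
      const double w0 = mu0 + M_SQRT2 * (u11 * D.ghx(j1) + u12 * D.ghx(j2));
      double lsurv;
      if (D.link <= 1) {
        const double Lam = E0a[j1] * inner;
        lsurv = delta * (loglamT + fs + eta1 * (mfixT + zT0 * w0) + hT1)
          - Lam;
      } else {
        const double lp = fs + P.eta(0) * w0 + P.eta(1) * w1;
        lsurv = delta * (loglamT + lp) - std::exp(lp) * inner;
      }
      const double ssr = rr - 2.0 * (rZ0 * w0 + rZ1 * w1)
        + z11 * w0 * w0 + 2.0 * z12 * w0 * w1 + z22 * w1 * w1;
      const double llong = nconst - ssr * inv2s2;
      const double q0 = P.Li11 * w0;
      const double q1 = P.Li21 * w0 + P.Li22 * w1;
      const double lprior = -std::log(2.0 * M_PI) - P.ldetLw
        - 0.5 * (q0 * q0 + q1 * q1);
      const double v = llong + lsurv + lprior + D.ghlw(j1) + lw2;
      if (v > m_best) {
        acc = acc * std::exp(m_best - v) + 1.0;
        m_best = v;
      } else {
        acc += std::exp(v - m_best);
      }
    }
  }
  return m_best + std::log(acc) + lognorm;
}

double full_ll(const vec& th, const FitData& D, vec* per_subj) {
  Params P = unpack_theta(th, D);
  double ll = 0.0;
  if (!D.trial_random) {
    for (int i = 0; i < D.n; ++i) {
      const double li = subject_ll(i, 0.0, 0.0, D, P);
      if (per_subj) (*per_subj)(i) = li;
      ll += li;
    }
  } else {
    const double ln11 = std::exp(P.lnu11), ln22 = std::exp(P.lnu22);
    for (int g = 0; g < D.ntrial; ++g) {
      uvec idx = find(D.itrial == (uword)g);
      vec smc(D.nmc);
      for (int m = 0; m < D.nmc; ++m) {
        const double nuM = ln11 * D.EPS(m, 0);
        const double nuT = P.lnu21 * D.EPS(m, 0) + ln22 * D.EPS(m, 1);
        double s = 0.0;
        for (uword k = 0; k < idx.n_elem; ++k) {
          const int i = (int)idx(k);
          s += subject_ll(i, nuM * D.treat(i), nuT * D.treat(i), D, P);
        }
        smc(m) = s;
      }
      const double mb = smc.max();
      ll += mb + std::log(accu(exp(smc - mb))) - std::log((double)D.nmc);
    }
  }
  return ll;
}

double penalty_val(const vec& th, const FitData& D) {
  Params P = unpack_theta(th, D);
  return as_scalar(P.chaz.t() * D.P * P.chaz);
}

} // namespace

// [[Rcpp::export]]
Rcpp::List sjm_pll(const arma::vec& theta, const Rcpp::List& dat,
                   bool per_subject = false) {
  FitData D = unpack_data(dat);
  if (D.nq > 64) Rcpp::stop("time_quadrature order is limited to 64");
  if (D.ngh > 32) Rcpp::stop("gh_nodes is limited to 32");
  vec ps;
  if (per_subject) ps.set_size(D.n);
  double ll = full_ll(theta, D, per_subject ? &ps : nullptr);
  double pen = penalty_val(theta, D);
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("penalty") = pen,
    Rcpp::Named("pll") = ll - D.kappa * pen);
  if (per_subject) out["per_subject"] = ps;
  return out;
}

// [[Rcpp::export]]
double sjm_pll_value(const arma::vec& theta, const Rcpp::List& dat) {
  FitData D = unpack_data(dat);
  if (D.nq > 64) Rcpp::stop("time_quadrature order is limited to 64");
  if (D.ngh > 32) Rcpp::stop("gh_nodes is limited to 32");
  return full_ll(theta, D, nullptr) - D.kappa * penalty_val(theta, D);
}

// Finite-difference gradient of the penalized log-likelihood over the
// free indices (1-based); central differences when central = true.
// [[Rcpp::export]]
arma::vec sjm_pll_grad(const arma::vec& theta, const Rcpp::List& dat,
                       const arma::uvec& free_idx, bool central = false,
                       double rel_step = 1e-6) {
  FitData D = unpack_data(dat);
  vec th = theta;
  auto f = [&](const vec& x) {
    return full_ll(x, D, nullptr) - D.kappa * penalty_val(x, D);
  };
  const double f0 = central ? 0.0 : f(th);
  vec g(free_idx.n_elem, fill::zeros);
  for (uword k = 0; k < free_idx.n_elem; ++k) {
    const uword j = free_idx(k) - 1;
    const double h = rel_step * std::max(1.0, std::abs(th(j)));
    const double old = th(j);
    th(j) = old + h;
    const double fp = f(th);
    if (central) {
      th(j) = old - h;
      g(k) = (fp - f(th)) / (2.0 * h);
    } else {
      g(k) = (fp - f0) / h;
    }
    th(j) = old;
  }
  return g;
}

// Finite-difference Hessian (second differences, symmetric).
// [[Rcpp::export]]
arma::mat sjm_pll_hess(const arma::vec& theta, const Rcpp::List& dat,
                       double rel_step = 1e-4) {
  FitData D = unpack_data(dat);
  const int p = theta.n_elem;
  vec th = theta;
  mat H(p, p);
  auto f = [&](const vec& x) {
    return full_ll(x, D, nullptr) - D.kappa * penalty_val(x, D);
  };
  vec hs(p);
  for (int j = 0; j < p; ++j)
    hs(j) = rel_step * std::max(1.0, std::abs(theta(j)));
  const double f00 = f(th);
  vec fp(p), fm(p);
  for (int j = 0; j < p; ++j) {
    th = theta; th(j) += hs(j); fp(j) = f(th);
    th = theta; th(j) -= hs(j); fm(j) = f(th);
  }
  for (int j = 0; j < p; ++j) {
    H(j, j) = (fp(j) - 2.0 * f00 + fm(j)) / (hs(j) * hs(j));
    for (int k = j + 1; k < p; ++k) {
      th = theta; th(j) += hs(j); th(k) += hs(k);
      const double fpp = f(th);
      th(k) = theta(k) - hs(k);
      const double fpm = f(th);
      th = theta; th(j) -= hs(j); th(k) += hs(k);
      const double fmp = f(th);
      th(k) = theta(k) - hs(k);
      const double fmm = f(th);
      H(j, k) = H(k, j) = (fpp - fpm - fmp + fmm) / (4.0 * hs(j) * hs(k));
    }
  }
  return (H + H.t()) / 2.0;
}

// Log-likelihood contribution of one subject (1-based index), given fixed
// trial-effect shifts dM (marker scale) and dT (log-hazard scale).
// [[Rcpp::export]]
double sjm_subject_ll(const arma::vec& theta, const Rcpp::List& dat,
                      int subject, double dM = 0.0, double dT = 0.0) {
  FitData D = unpack_data(dat);
  Params P = unpack_theta(theta, D);
  if (subject < 1 || subject > D.n) Rcpp::stop("subject index out of range");
  return subject_ll(subject - 1, dM, dT, D, P);
}

// Marginal log-likelihood of the longitudinal submodel alone (closed form):
// y_i ~ N(X_i bL, Zr_i Sigma_w Zr_i' + sige^2 I). theta_lmm packs
// (log sige, l11, l21, l22, bL).
// [[Rcpp::export]]
double sjm_lmm_ll(const arma::vec& theta_lmm, const Rcpp::List& dat) {
  FitData D = unpack_data(dat);
  const double sige = std::exp(theta_lmm(0));
  const double l11 = theta_lmm(1), l21 = theta_lmm(2), l22 = theta_lmm(3);
  mat Lw = { {std::exp(l11), 0.0}, {l21, std::exp(l22)} };
  mat Sw = Lw * Lw.t();
  vec bL = theta_lmm.subvec(4, 3 + D.pL);
  double ll = 0.0;
  for (int i = 0; i < D.n; ++i) {
    const uword a = D.off(i), b = D.off(i + 1);
    const mat Z = D.Zr.rows(a, b - 1);
    vec r = D.y.subvec(a, b - 1) - D.X.rows(a, b - 1) * bL;
    mat V = Z * Sw * Z.t();
    V.diag() += sige * sige;
    mat C = chol(V, "lower");
    vec u = solve(trimatl(C), r);
    ll += -0.5 * (double)(b - a) * std::log(2.0 * M_PI)
      - accu(log(C.diag())) - 0.5 * dot(u, u);
  }
  return ll;
}

// Per-subject posterior mean and upper-factor scale of the random effects
// given the longitudinal data alone (used for the pseudo-adaptive rule).
// [[Rcpp::export]]
Rcpp::List sjm_lmm_posterior(const arma::vec& theta_lmm,
                             const Rcpp::List& dat) {
  FitData D = unpack_data(dat);
  const double sige = std::exp(theta_lmm(0));
  const double l11 = theta_lmm(1), l21 = theta_lmm(2), l22 = theta_lmm(3);
  mat Lw = { {std::exp(l11), 0.0}, {l21, std::exp(l22)} };
  mat Swinv = inv_sympd(Lw * Lw.t());
  vec bL = theta_lmm.subvec(4, 3 + D.pL);
  mat MU(2, D.n), UF(3, D.n);
  const double is2 = 1.0 / (sige * sige);
  for (int i = 0; i < D.n; ++i) {
    const uword a = D.off(i), b = D.off(i + 1);
    const mat Z = D.Zr.rows(a, b - 1);
    vec r = D.y.subvec(a, b - 1) - D.X.rows(a, b - 1) * bL;
    mat Prec = Swinv + Z.t() * Z * is2;
    mat V = inv_sympd(Prec);
    vec mu = V * (Z.t() * r * is2);
    MU(0, i) = mu(0); MU(1, i) = mu(1);
    const double u22 = std::sqrt(V(1, 1));
    const double u12 = V(0, 1) / u22;
    const double dd = V(0, 0) - u12 * u12;
    UF(0, i) = std::sqrt(dd > 1e-300 ? dd : 1e-300);
    UF(1, i) = u12;
    UF(2, i) = u22;
  }
  return Rcpp::List::create(Rcpp::Named("MUt") = MU,
                            Rcpp::Named("UFt") = UF);
}
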