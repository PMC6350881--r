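#include <Rcpp.h>
using namespace Rcpp;

// Auxiliaries of the adhesive (Baxter) hard-sphere direct correlation
// function for one parameter set.  eta is the well-width-rescaled packing
// fraction; lambda is the physical (minus) root of the Baxter quadratic.
struct ShsAux {
  double eta, lambda, mu, alpha, beta;
  bool ok;
};

static ShsAux shs_aux(double R_HS, double nu, double tau, double delta) {
  ShsAux a;
  a.ok = false;
  a.eta = a.lambda = a.mu = a.alpha = a.beta = NA_REAL;
  if (!(R_HS > 0.0) || !(delta > 0.0) || nu < 0.0) return a;
  const double ratio = (2.0 * R_HS + delta) / (2.0 * R_HS);
  const double eta = nu * ratio * ratio * ratio;
  if (eta >= 1.0) return a;
  const double om = 1.0 - eta;
  const double eps = tau + eta / om;
  const double gam = nu * (1.0 + eta / 2.0) / (3.0 * om * om);
  const double disc = eps * eps - gam;
  if (disc < 0.0) return a;
  const double lambda = (6.0 / eta) * (eps - std::sqrt(disc));
  const double mu = lambda * eta * om;
  const double om4 = om * om * om * om;
  const double opm = 1.0 + 2.0 * eta - mu;
  a.eta = eta;
  a.lambda = lambda;
  a.mu = mu;
  a.alpha = opm * opm / om4;
  a.beta = -(3.0 * eta * (2.0 + eta) * (2.0 + eta)
             - 2.0 * mu * (1.0 + 7.0 * eta + eta * eta)
             + mu * mu * (2.0 + eta)) / (2.0 * om4);
  a.ok = true;
  return a;
}

static inline double shs_one_q(double q, double R_HS, const ShsAux& a) {
  const double k = 2.0 * q * R_HS;
  const double k2 = k * k, k3 = k2 * k, k4 = k2 * k2, k6 = k3 * k3;
  const double sk = std::sin(k), ck = std::cos(k);
  const double eta = a.eta, lam = a.lambda;
  double C = 2.0 * eta * lam * sk / k
           - 2.0 * eta * eta * lam * lam * (1.0 - ck) / k2
           - 24.0 * eta / k6 *
             (a.alpha * k3 * (sk - k * ck)
              + a.beta * k2 * (2.0 * k * sk - (k2 - 2.0) * ck - 2.0)
              + 0.5 * eta * a.alpha *
                ((4.0 * k3 - 24.0 * k) * sk - (k4 - 12.0 * k2 + 24.0) * ck + 24.0));
  return 1.0 / (1.0 - C);
}

// Structure factor for every q (rows) at every hard-sphere radius node
// (columns).  tau and delta are supplied per node because the well-width
// rule ties them to the node's R_HS.  Invalid nodes give NaN columns; the
// R wrapper pre-screens and raises informative errors.
// [[Rcpp::export(name = ".shs_matrix_cpp")]]
NumericMatrix shs_matrix_cpp(NumericVector q, NumericVector R_HS, double nu,
                             NumericVector tau, NumericVector delta) {
  const int nq = q.size(), nn = R_HS.size();
  NumericMatrix S(nq, nn);
  for (int j = 0; j < nn; ++j) {
    ShsAux a = shs_aux(R_HS[j], nu, tau[j], delta[j]);
    if (!a.ok || nu == 0.0) {
      const double fill = (nu == 0.0) ? 1.0 : NA_REAL;
      for (int i = 0; i < nq; ++i) S(i, j) = fill;
      continue;
    }
    for (int i = 0; i < nq; ++i) S(i, j) = shs_one_q(q[i], R_HS[j], a);
  }
  return S;
}

static inline double sphere_P(double x) {
  // [3 (sin x - x cos x) / x^3]^2, stable near x = 0
  if (x < 1e-4) {
    const double x2 = x * x;
    const double f = 1.0 - x2 / 10.0;
    return f * f;
  }
  const double f = 3.0 * (std::sin(x) - x * std::cos(x)) / (x * x * x);
  return f * f;
}

// Accept/reject Monte Carlo inversion of a 1D curve into sphere radii.
// Model: I(q) = s * sum_k V(r_k) P(q r_k) with the scale s re-derived at
// every step by weighted linear least squares; a move is accepted iff the
// reduced chi^2 decreases.  Uses R's RNG stream.
// [[Rcpp::export(name = ".mcsas_kernel_cpp")]]
List mcsas_kernel_cpp(NumericVector q, NumericVector I, NumericVector w,
                      NumericVector r_init, double r_min, double r_max,
                      int max_iter, double chi2_target) {
  const int nq = q.size(), n = r_init.size();
  NumericMatrix cols(nq, n);
  NumericVector r = clone(r_init);
  std::vector<double> m(nq, 0.0);

  auto fill_col = [&](int k, double rk, double* out) {
    const double V = 4.0 / 3.0 * M_PI * rk * rk * rk;
    for (int i = 0; i < nq; ++i) out[i] = V * sphere_P(q[i] * rk);
  };
  for (int k = 0; k < n; ++k) {
    fill_col(k, r[k], &cols(0, k));
    for (int i = 0; i < nq; ++i) m[i] += cols(i, k);
  }

  const double dof = std::max(1, nq - 1);
  auto chi2_of = [&](const std::vector<double>& mm, double* scale_out) {
    double smi = 0.0, smm = 0.0;
    for (int i = 0; i < nq; ++i) {
      smi += w[i] * mm[i] * I[i];
      smm += w[i] * mm[i] * mm[i];
    }
    const double s = (smm > 0.0) ? smi / smm : 0.0;
    double c = 0.0;
    for (int i = 0; i < nq; ++i) {
      const double d = s * mm[i] - I[i];
      c += w[i] * d * d;
    }
    if (scale_out) *scale_out = s;
    return c / dof;
  };

  double scale = 0.0;
  double chi2 = chi2_of(m, &scale);
  std::vector<double> m_new(nq);
  int iter = 0, accepted = 0;
  for (iter = 0; iter < max_iter && chi2 > chi2_target; ++iter) {
    const int j = std::min(n - 1, (int)(unif_rand() * n));
    const double r_new = r_min + unif_rand() * (r_max - r_min);
    std::vector<double> newcol(nq);
    fill_col(j, r_new, newcol.data());
    for (int i = 0; i < nq; ++i) m_new[i] = m[i] - cols(i, j) + newcol[i];
    double s_new;
    const double c_new = chi2_of(m_new, &s_new);
    if (c_new < chi2) {
      chi2 = c_new;
      scale = s_new;
      r[j] = r_new;
      for (int i = 0; i < nq; ++i) {
        cols(i, j) = newcol[i];
        m[i] = m_new[i];
      }
      ++accepted;
      if (accepted % 1024 == 0) {  // refresh running sum against FP drift
        std::fill(m.begin(), m.end(), 0.0);
        for (int k = 0; k < n; ++k)
          for (int i = 0; i < nq; ++i) m[i] += cols(i, k);
        chi2 = chi2_of(m, &scale);
      }
    }
  }

  return List::create(_["r"] = r, _["scale"] = scale, _["chi2_red"] = chi2,
                      _["iterations"] = iter, _["accepted"] = accepted,
                      _["converged"] = chi2 <= chi2_target);
}
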