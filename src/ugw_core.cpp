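// Entropic unbalanced Gromov-Wasserstein solver core.
//
// Minimizes, over nonnegative couplings pi restricted to a feasibility mask,
//   L(pi) = sum_ijkl (Dx[i,k] - Dy[j,l])^2 pi[i,j] pi[k,l]
//         + rho * KL(pi_1 (x) pi_1 | a (x) a)
//         + rho * KL(pi_2 (x) pi_2 | b (x) b)
//         + eps * KL(pi (x) pi | (a (x) b)^(x)2)
// through the bi-convex relaxation L(pi, gamma) (replace one factor of each
// product by gamma). Alternating exact minimization in pi and gamma is a
// descent method for the relaxed objective: each half step is an entropic
// unbalanced optimal-transport problem solved by a log-stabilized Sinkhorn
// scaling loop. At convergence the two factors coincide and the relaxed
// objective equals L on the diagonal; the returned coupling is the average
// of the two factors.
//
// Reference marginals a, b are assumed to carry total mass 1 each; when the
// caller removes structurally infeasible rows/columns it must keep the
// original 1/p weights so that objectives reported here remain those of the
// full problem.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static const double ABSORB_THRESHOLD = 30.0;

// KL(mu | nu) = sum mu log(mu/nu) - m(mu) + m(nu), with 0 log 0 := 0 and
// the reference total fixed at 1 (see header note).
static double kl_vec(const vec &mu, const vec &nu) {
  double s = 0.0;
  for (uword i = 0; i < mu.n_elem; ++i) {
    if (mu(i) > 0.0) s += mu(i) * std::log(mu(i) / nu(i));
  }
  return s - accu(mu) + 1.0;
}

static double kl_mat(const mat &pi, const vec &a, const vec &b) {
  double s = 0.0;
  for (uword j = 0; j < pi.n_cols; ++j) {
    for (uword i = 0; i < pi.n_rows; ++i) {
      double x = pi(i, j);
      if (x > 0.0) s += x * std::log(x / (a(i) * b(j)));
    }
  }
  return s - accu(pi) + 1.0;
}

// Bi-convex relaxed objective L(pi, gamma); equals the diagonal objective
// when pi == gamma. Uses the tensorized-KL identity
// KL(mu (x) mu' | nu (x) nu) = m(mu') KL(mu|nu) + m(mu) KL(mu'|nu)
//                              + (m(mu) - 1)(m(mu') - 1).
static double bi_objective(const mat &pi, const mat &gam, const mat &Dx2,
                           const mat &Dy2, const mat &Dx, const mat &Dy,
                           const vec &a, const vec &b, double rho,
                           double eps) {
  const vec mu_p = sum(pi, 1), nu_p = sum(pi, 0).t();
  const vec mu_g = sum(gam, 1), nu_g = sum(gam, 0).t();
  const double mp = accu(pi), mg = accu(gam);
  double e = dot(mu_p, Dx2 * mu_g) + dot(nu_p, Dy2 * nu_g) -
             2.0 * accu(gam % (Dx * pi * Dy));
  const double cross = (mp - 1.0) * (mg - 1.0);
  double obj = e;
  obj += rho * (mg * kl_vec(mu_p, a) + mp * kl_vec(mu_g, a) + cross);
  obj += rho * (mg * kl_vec(nu_p, b) + mp * kl_vec(nu_g, b) + cross);
  obj += eps * (mg * kl_mat(pi, a, b) + mp * kl_mat(gam, a, b) + cross);
  return obj;
}

// One-sided log-sum-exp fallback for a line of the scaling update, used
// when the stabilized kernel line has underflowed to zero.
static double line_softmin(const mat &C, const vec &pot, const vec &lref,
                           const umat &mask, double epsp, uword i,
                           bool by_row) {
  double mx = -datum::inf;
  uword n = by_row ? C.n_cols : C.n_rows;
  for (uword k = 0; k < n; ++k) {
    bool ok = by_row ? (mask(i, k) != 0) : (mask(k, i) != 0);
    if (!ok) continue;
    double val = lref(k) + (pot(k) - (by_row ? C(i, k) : C(k, i))) / epsp;
    if (val > mx) mx = val;
  }
  if (!std::isfinite(mx)) return datum::nan;  // fully masked line
  double s = 0.0;
  for (uword k = 0; k < n; ++k) {
    bool ok = by_row ? (mask(i, k) != 0) : (mask(k, i) != 0);
    if (!ok) continue;
    double val = lref(k) + (pot(k) - (by_row ? C(i, k) : C(k, i))) / epsp;
    s += std::exp(val - mx);
  }
  return mx + std::log(s);
}

// Exactly minimize the relaxed objective in one factor given the other:
// an entropic unbalanced OT problem with cost induced by `ref`, solved by
// stabilized Sinkhorn scaling with warm-started potentials u, v.
static mat half_update(const mat &ref, const mat &Dx2, const mat &Dy2,
                       const mat &Dx, const mat &Dy, const umat &mask,
                       const uvec &masked_idx, const vec &a, const vec &b,
                       const vec &la, const vec &lb, double rho, double eps,
                       int max_inner, vec &u, vec &v) {
  const uword p1 = Dx2.n_rows, p2 = Dy2.n_rows;
  const double m = accu(ref);
  const vec mu = sum(ref, 1), nu = sum(ref, 0).t();
  const double kconst = rho * kl_vec(mu, a) + rho * kl_vec(nu, b) +
                        eps * kl_mat(ref, a, b) +
                        (2.0 * rho + eps) * (m - 1.0);
  mat C = repmat(Dx2 * mu, 1, p2) + repmat((Dy2 * nu).t(), p1, 1) -
          2.0 * (Dx * ref * Dy);
  C += kconst;
  if (!C.is_finite()) {
    Rcpp::stop("non-finite values in the transport cost; increasing eps "
               "usually restores numerical stability");
  }

  const double epsp = eps * m, rhop = rho * m;
  const double kappa = rhop / (rhop + epsp);

  vec uhat = u, vhat = v;
  mat K = (repmat(uhat, 1, p2) + repmat(vhat.t(), p1, 1) - C) / epsp +
          repmat(la, 1, p2) + repmat(lb.t(), p1, 1);
  K.elem(masked_idx).fill(-datum::inf);
  K = exp(K);
  vec alpha(p1, fill::ones), beta(p2, fill::ones);

  // Rebuild the stabilized kernel around the current absorbed potentials.
  auto absorb = [&]() {
    K = (repmat(uhat, 1, p2) + repmat(vhat.t(), p1, 1) - C) / epsp +
        repmat(la, 1, p2) + repmat(lb.t(), p1, 1);
    K.elem(masked_idx).fill(-datum::inf);
    K = exp(K);
  };

  for (int inner = 0; inner < max_inner; ++inner) {
    const vec u_old = u;
    vec kb = K * beta;
    for (uword i = 0; i < p1; ++i) {
      double lkb;
      if (kb(i) > 0.0) {
        lkb = std::log(kb(i));
      } else {
        lkb = line_softmin(C, v, lb, mask, epsp, i, true) - la(i) -
              uhat(i) / epsp;
        if (!std::isfinite(lkb)) { u(i) = 0.0; continue; }
      }
      u(i) = kappa * (uhat(i) + epsp * la(i) - epsp * lkb);
    }
    // absorb on the log scale before exponentiating, so a large first
    // step cannot overflow the scaling vector
    if (abs((u - uhat) / epsp).max() > ABSORB_THRESHOLD) {
      uhat = u;
      absorb();
      alpha.ones();
    } else {
      alpha = exp((u - uhat) / epsp);
    }

    vec ka = K.t() * alpha;
    for (uword j = 0; j < p2; ++j) {
      double lka;
      if (ka(j) > 0.0) {
        lka = std::log(ka(j));
      } else {
        lka = line_softmin(C, u, la, mask, epsp, j, false) - lb(j) -
              vhat(j) / epsp;
        if (!std::isfinite(lka)) { v(j) = 0.0; continue; }
      }
      v(j) = kappa * (vhat(j) + epsp * lb(j) - epsp * lka);
    }
    if (abs((v - vhat) / epsp).max() > ABSORB_THRESHOLD) {
      vhat = v;
      absorb();
      beta.ones();
      alpha = exp((u - uhat) / epsp);
    } else {
      beta = exp((v - vhat) / epsp);
    }

    if (abs(u - u_old).max() < 1e-10 + 1e-7 * std::max(1.0, abs(u).max()))
      break;
  }

  mat out = (alpha * beta.t()) % K;
  out.elem(masked_idx).zeros();
  if (!out.is_finite()) {
    Rcpp::stop("non-finite coupling during Sinkhorn iterations; "
               "increasing eps usually restores numerical stability");
  }
  return out;
}

// [[Rcpp::export(name = ".ugw_core")]]
Rcpp::List ugw_core(const arma::mat &Dx, const arma::mat &Dy,
                    const arma::umat &mask, const arma::vec &a,
                    const arma::vec &b, double rho, double eps, int max_outer,
                    int max_inner, double tol) {
  const uword p1 = Dx.n_rows, p2 = Dy.n_rows;
  const mat Dx2 = Dx % Dx, Dy2 = Dy % Dy;
  const vec la = log(a), lb = log(b);
  const uvec masked_idx = find(mask == 0);

  // Product-measure initialization restricted to the mask, for both
  // factors of the relaxation.
  mat pi = a * b.t();
  pi.elem(masked_idx).zeros();
  mat gam = pi;

  vec u_pi(p1, fill::zeros), v_pi(p2, fill::zeros);
  vec u_g(p1, fill::zeros), v_g(p2, fill::zeros);
  std::vector<double> trace;
  trace.push_back(bi_objective(pi, gam, Dx2, Dy2, Dx, Dy, a, b, rho, eps));

  bool converged = false;
  int outer = 0;
  for (outer = 1; outer <= max_outer; ++outer) {
    const mat pi_prev = pi, gam_prev = gam;
    if (!(accu(gam) > 0.0) || !(accu(pi) > 0.0)) { converged = true; break; }

    pi = half_update(gam, Dx2, Dy2, Dx, Dy, mask, masked_idx, a, b, la, lb,
                     rho, eps, max_inner, u_pi, v_pi);
    gam = half_update(pi, Dx2, Dy2, Dx, Dy, mask, masked_idx, a, b, la, lb,
                      rho, eps, max_inner, u_g, v_g);

    // Equal-mass projection along the (s pi, gam / s) direction, which
    // leaves the distortion term invariant; the alternation alone does not
    // control this direction and the factor masses can drift apart for
    // small rho. Applied with a descent safeguard.
    const double mp = accu(pi), mg = accu(gam);
    if (mp > 0.0 && mg > 0.0 &&
        (mp / mg > 1.0 + 1e-12 || mg / mp > 1.0 + 1e-12)) {
      const double before =
          bi_objective(pi, gam, Dx2, Dy2, Dx, Dy, a, b, rho, eps);
      const double s = std::sqrt(mg / mp);
      const mat pi_s = s * pi, gam_s = gam / s;
      const double after =
          bi_objective(pi_s, gam_s, Dx2, Dy2, Dx, Dy, a, b, rho, eps);
      if (after <= before + 1e-12 * (1.0 + std::abs(before))) {
        pi = pi_s;
        gam = gam_s;
      }
    }

    trace.push_back(bi_objective(pi, gam, Dx2, Dy2, Dx, Dy, a, b, rho, eps));
    const double mx = std::max(pi.max(), gam.max());
    const double delta = std::max(abs(pi - pi_prev).max(),
                                  abs(gam - gam_prev).max());
    if (delta < tol * std::max(1.0, mx)) { converged = true; break; }
  }

  mat out = 0.5 * (pi + gam);
  out.elem(masked_idx).zeros();
  const double final_objective =
      bi_objective(out, out, Dx2, Dy2, Dx, Dy, a, b, rho, eps);
  const double factor_gap = abs(pi - gam).max();

  return Rcpp::List::create(
      Rcpp::Named("pi") = out, Rcpp::Named("objective_trace") = trace,
      Rcpp::Named("n_outer_iterations") = std::min(outer, max_outer),
      Rcpp::Named("converged") = converged,
      Rcpp::Named("final_mass") = accu(out),
      Rcpp::Named("final_objective") = final_objective,
      Rcpp::Named("factor_gap") = factor_gap);
}
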