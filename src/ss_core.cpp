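// Steady-state core for the NAD salvage network.
//
// The network is small (8 species, 18 reactions) but the optimizer needs
// ~10^6 steady-state solves per study, so the rate laws, Jacobian and the
// pseudo-transient/Newton solver live here. Strategy:
//   1. pseudo-transient continuation (implicit Euler with growing step),
//      robust from any non-negative start, run on the full 8-d system;
//   2. Newton refinement on the reduced 7-d system with Nam eliminated
//      via the pyridine conservation relation (the full Jacobian is
//      singular along the conserved direction).
// Concentrations are mM, enzymes nM, time s, temperature K, Ea kJ/mol.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double RGAS = 8.314;

struct Net {
  arma::mat N;          // species x reactions
  arma::ivec sub;       // substrate species index per reaction
  arma::ivec enz;       // enzyme index per reaction, -1 = none
  arma::ivec mm;        // 1 = Michaelis-Menten, 0 = first order
  arma::vec kT;         // rate constant at requested temperature
  arma::vec Km;
  double total;
};

static Net unpack(const List& m, const arma::vec& E_nM, double T) {
  Net net;
  net.N = as<arma::mat>(m["N"]);
  net.sub = as<arma::ivec>(m["sub"]);
  net.enz = as<arma::ivec>(m["enz"]);
  net.mm = as<arma::ivec>(m["mm"]);
  arma::vec k0 = as<arma::vec>(m["k0"]);
  arma::vec Ea = as<arma::vec>(m["Ea"]);
  double T0 = as<double>(m["T0"]);
  net.Km = as<arma::vec>(m["Km"]);
  net.total = as<double>(m["total"]);
  net.kT = k0 % arma::exp(-(Ea * 1000.0 / RGAS) * (1.0 / T - 1.0 / T0));
  // fold the enzyme abundance (nM -> mM) into the effective constant
  for (arma::uword j = 0; j < net.kT.n_elem; ++j) {
    if (net.mm[j] == 1) {
      int e = net.enz[j];
      net.kT[j] *= (e >= 0 ? E_nM[e] * 1e-6 : 0.0);
    }
  }
  return net;
}

static arma::vec fluxes(const Net& net, const arma::vec& C) {
  arma::vec v(net.kT.n_elem);
  for (arma::uword j = 0; j < v.n_elem; ++j) {
    double S = C[net.sub[j]];
    v[j] = net.mm[j] == 1 ? net.kT[j] * S / (net.Km[j] + S) : net.kT[j] * S;
  }
  return v;
}

static arma::vec rhs(const Net& net, const arma::vec& C) {
  return net.N * fluxes(net, C);
}

// dv_j/dS on the reaction's substrate; assembled into the full Jacobian
static arma::mat jac(const Net& net, const arma::vec& C) {
  arma::uword ns = net.N.n_rows;
  arma::mat J(ns, ns, arma::fill::zeros);
  for (arma::uword j = 0; j < net.kT.n_elem; ++j) {
    double S = C[net.sub[j]];
    double dv = net.mm[j] == 1
      ? net.kT[j] * net.Km[j] / ((net.Km[j] + S) * (net.Km[j] + S))
      : net.kT[j];
    J.col(net.sub[j]) += net.N.col(j) * dv;
  }
  return J;
}

// [[Rcpp::export(name = ".cpp_fluxes")]]
NumericVector cpp_fluxes(List model, NumericVector E, double T, NumericVector C) {
  Net net = unpack(model, as<arma::vec>(E), T);
  return wrap(fluxes(net, as<arma::vec>(C)));
}

// [[Rcpp::export(name = ".cpp_rhs")]]
NumericVector cpp_rhs(List model, NumericVector E, double T, NumericVector C) {
  Net net = unpack(model, as<arma::vec>(E), T);
  return wrap(rhs(net, as<arma::vec>(C)));
}

// [[Rcpp::export(name = ".cpp_solve_ss")]]
List cpp_solve_ss(List model, NumericVector E, double T, NumericVector C0,
                  double tol_rel = 1e-10, double tol_newton = 1e-12,
                  int max_transient = 1500, int max_newton = 60) {
  Net net = unpack(model, as<arma::vec>(E), T);
  arma::uword ns = net.N.n_rows;
  arma::vec C = as<arma::vec>(C0);
  arma::mat Nabs = arma::abs(net.N);
  arma::mat I = arma::eye(ns, ns);
  int it_trans = 0, it_newton = 0;

  // residuals are judged relative to the gross turnover at the state:
  // ||N v|| small compared with ||(|N|) v||. A state with zero turnover is
  // genuinely stationary.
  auto gross = [&](const arma::vec& C_) {
    return arma::norm(Nabs * fluxes(net, C_));
  };

  arma::vec f = rhs(net, C);
  double rel0 = 1e-6;  // transient hand-off point; tightened on retry

  for (int attempt = 0; attempt < 3; ++attempt) {
    // pseudo-transient continuation: one Newton-like solve of the implicit
    // Euler step, (I/h - J) d = f; step h grows on acceptance. Moderate
    // residual growth is tolerated (the residual need not fall
    // monotonically on the way to the attractor).
    double h = 1e-2;
    while (arma::norm(f) > rel0 * gross(C) + 1e-300 && it_trans < max_transient) {
      ++it_trans;
      arma::mat A = I / h - jac(net, C);
      arma::vec d;
      if (!arma::solve(d, A, f, arma::solve_opts::no_approx)) { h *= 0.25; continue; }
      double lam = 1.0;
      arma::vec Cn = C + d;
      int back = 0;
      while (Cn.min() < -1e-12 && back < 60) { lam *= 0.5; Cn = C + lam * d; ++back; }
      Cn.transform([](double x) { return x < 0 ? 0.0 : x; });
      arma::vec fn = rhs(net, Cn);
      if (arma::norm(fn) <= arma::norm(f) * 1.5 + 1e-300 || h <= 1e-6) {
        C = Cn; f = fn; h = std::min(h * 2.0, 1e12);
      } else {
        h *= 0.25;
      }
    }

    // project onto the conservation plane before refining
    double others = arma::accu(C) - C[0];
    C[0] = std::max(net.total - others, 0.0);

    // Newton on the reduced system (Nam = total - sum of the rest)
    for (int k = 0; k < max_newton; ++k) {
      ++it_newton;
      f = rhs(net, C);
      arma::vec fr = f.subvec(1, ns - 1);
      if (arma::norm(fr) < 1e-300) break;
      arma::mat J = jac(net, C);
      arma::mat Jr(ns - 1, ns - 1);
      for (arma::uword i = 1; i < ns; ++i)
        for (arma::uword j2 = 1; j2 < ns; ++j2)
          Jr(i - 1, j2 - 1) = J(i, j2) - J(i, 0);
      arma::vec d;
      if (!arma::solve(d, Jr, -fr, arma::solve_opts::no_approx)) break;
      double lam = 1.0;
      bool accepted = false;
      for (int back = 0; back < 60; ++back) {
        arma::vec Cr = C.subvec(1, ns - 1) + lam * d;
        double nam = net.total - arma::accu(Cr);
        if (Cr.min() >= -1e-15 && nam >= -1e-15) {
          arma::vec Cn(ns);
          Cn[0] = std::max(nam, 0.0);
          for (arma::uword i = 1; i < ns; ++i) Cn[i] = std::max(Cr[i - 1], 0.0);
          arma::vec fn = rhs(net, Cn);
          if (arma::norm(fn.subvec(1, ns - 1)) <= arma::norm(fr) * (1.0 - 1e-4 * lam) ||
              arma::norm(fn.subvec(1, ns - 1)) < tol_newton * gross(Cn)) {
            C = Cn;
            accepted = true;
            break;
          }
        }
        lam *= 0.5;
      }
      if (!accepted) break;
      if (arma::norm(lam * d) < tol_newton * std::max(1.0, arma::norm(C))) break;
    }

    f = rhs(net, C);
    if (arma::norm(f) <= tol_rel * gross(C) + 1e-300) break;
    rel0 *= 1e-3;  // Newton stalled: integrate further before retrying
  }

  double resid = arma::norm(f);
  bool converged = resid <= tol_rel * gross(C) + 1e-300;
  return List::create(
    _["C"] = wrap(C),
    _["fluxes"] = wrap(fluxes(net, C)),
    _["residual"] = resid,
    _["converged"] = converged,
    _["iterations"] = IntegerVector::create(_["transient"] = it_trans, _["newton"] = it_newton)
  );
}
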