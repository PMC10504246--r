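// Prior force field: harmonic bonds V = k (r - r0)^2 + V0, power-law
// repulsion V = 4 eps r^-6 + V0 over non-excluded pairs, and a global
// two-term cosine dihedral V = sum_n k_n (1 + cos(n phi - gamma_n)).
// Also evaluates the smooth Gaussian pair-distance perturbation used by the
// synthetic toy-polymer fixtures.  Forces are exact negative gradients.
#include "cgfold_core.h"
using namespace arma;

namespace cgfold {

PriorTerms parse_prior_terms(const Rcpp::List& terms) {
  PriorTerms pt;
  pt.bonds = Rcpp::as<umat>(terms["bonds"]);
  pt.bond_k = Rcpp::as<vec>(terms["bond_k"]);
  pt.bond_r0 = Rcpp::as<vec>(terms["bond_r0"]);
  pt.bond_v0 = Rcpp::as<vec>(terms["bond_v0"]);
  pt.pairs = Rcpp::as<umat>(terms["pairs"]);
  pt.pair_eps = Rcpp::as<vec>(terms["pair_eps"]);
  pt.pair_v0 = Rcpp::as<vec>(terms["pair_v0"]);
  pt.quads = Rcpp::as<umat>(terms["quads"]);
  pt.dih_k = Rcpp::as<vec>(terms["dih_k"]);
  pt.dih_gamma = Rcpp::as<vec>(terms["dih_gamma"]);
  pt.dih_n = Rcpp::as<vec>(terms["dih_n"]);
  return pt;
}

Perturbation parse_perturbation(const Rcpp::List& pert) {
  Perturbation pe;
  pe.pairs = Rcpp::as<umat>(pert["pairs"]);
  pe.amp = Rcpp::as<vec>(pert["amp"]);
  pe.center = Rcpp::as<vec>(pert["center"]);
  pe.width = Rcpp::as<vec>(pert["width"]);
  return pe;
}

double dihedral_phi(const vec& x1, const vec& x2, const vec& x3,
                    const vec& x4, mat* dphi) {
  vec b1 = x2 - x1, b2 = x3 - x2, b3 = x4 - x3;
  vec A = cross(b1, b2), B = cross(b2, b3);
  double nb2 = norm(b2);
  double a2 = dot(A, A), b2n = dot(B, B);
  if (a2 < 1e-18 || b2n < 1e-18)
    Rcpp::stop("dihedral undefined: collinear triple of beads");
  double sinp = dot(cross(A, B), b2) / nb2;
  double cosp = dot(A, B);
  double phi = std::atan2(sinp, cosp);
  if (dphi != nullptr) {
    // Blondel & Karplus form; signs fixed to the atan2 convention above
    vec t1 = -(nb2 / a2) * A;
    vec t4 = (nb2 / b2n) * B;
    double ca = dot(b1, b2) / (nb2 * nb2);
    double cb = dot(b3, b2) / (nb2 * nb2);
    vec t2 = (-1.0 - ca) * t1 + cb * t4;
    vec t3 = ca * t1 + (-1.0 - cb) * t4;
    dphi->set_size(3, 4);
    dphi->col(0) = t1; dphi->col(1) = t2; dphi->col(2) = t3; dphi->col(3) = t4;
  }
  return phi;
}

double prior_eval(const mat& X3, const PriorTerms& pt, mat& F3) {
  double V = 0.0;
  for (uword b = 0; b < pt.bonds.n_rows; ++b) {
    uword i = pt.bonds(b, 0), j = pt.bonds(b, 1);
    vec dr = X3.col(i) - X3.col(j);
    double r = norm(dr);
    double dv = r - pt.bond_r0[b];
    V += pt.bond_k[b] * dv * dv + pt.bond_v0[b];
    vec g = (2.0 * pt.bond_k[b] * dv / r) * dr;   // dV/dx_i
    F3.col(i) -= g;
    F3.col(j) += g;
  }
  for (uword p = 0; p < pt.pairs.n_rows; ++p) {
    uword i = pt.pairs(p, 0), j = pt.pairs(p, 1);
    vec dr = X3.col(i) - X3.col(j);
    double r2 = dot(dr, dr);
    double r6 = r2 * r2 * r2;
    V += 4.0 * pt.pair_eps[p] / r6 + pt.pair_v0[p];
    // dV/dr = -24 eps r^-7 ; dV/dx_i = dV/dr * dr_hat
    vec g = (-24.0 * pt.pair_eps[p] / (r6 * r2)) * dr;
    F3.col(i) -= g;
    F3.col(j) += g;
  }
  for (uword q = 0; q < pt.quads.n_rows; ++q) {
    mat dphi;
    double phi = dihedral_phi(X3.col(pt.quads(q, 0)), X3.col(pt.quads(q, 1)),
                              X3.col(pt.quads(q, 2)), X3.col(pt.quads(q, 3)),
                              &dphi);
    double dVdphi = 0.0;
    for (uword t = 0; t < pt.dih_k.n_elem; ++t) {
      double n = pt.dih_n[t];
      V += pt.dih_k[t] * (1.0 + std::cos(n * phi - pt.dih_gamma[t]));
      dVdphi += -n * pt.dih_k[t] * std::sin(n * phi - pt.dih_gamma[t]);
    }
    for (int c = 0; c < 4; ++c)
      F3.col(pt.quads(q, c)) -= dVdphi * dphi.col(c);
  }
  return V;
}

double perturbation_eval(const mat& X3, const Perturbation& pe, mat& F3) {
  double V = 0.0;
  for (uword p = 0; p < pe.pairs.n_rows; ++p) {
    uword i = pe.pairs(p, 0), j = pe.pairs(p, 1);
    vec dr = X3.col(i) - X3.col(j);
    double r = norm(dr);
    double t = (r - pe.center[p]) / pe.width[p];
    double g = pe.amp[p] * std::exp(-0.5 * t * t);
    V += g;
    double dVdr = -g * t / pe.width[p];
    vec gr = (dVdr / r) * dr;
    F3.col(i) -= gr;
    F3.col(j) += gr;
  }
  return V;
}

}  // namespace cgfold

// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::List prior_eval_cpp(const arma::mat& coords, const Rcpp::List& terms) {
  using namespace cgfold;
  PriorTerms pt = parse_prior_terms(terms);
  arma::mat X3 = coords.t();
  arma::mat F3 = arma::zeros<arma::mat>(3, X3.n_cols);
  double V = prior_eval(X3, pt, F3);
  return Rcpp::List::create(Rcpp::Named("energy") = V,
                            Rcpp::Named("forces") = arma::mat(F3.t()));
}

// [[Rcpp::export]]
Rcpp::List perturbation_eval_cpp(const arma::mat& coords,
                                 const Rcpp::List& pert) {
  using namespace cgfold;
  Perturbation pe = parse_perturbation(pert);
  arma::mat X3 = coords.t();
  arma::mat F3 = arma::zeros<arma::mat>(3, X3.n_cols);
  double V = perturbation_eval(X3, pe, F3);
  return Rcpp::List::create(Rcpp::Named("energy") = V,
                            Rcpp::Named("forces") = arma::mat(F3.t()));
}

// [[Rcpp::export]]
double dihedral_angle_cpp(const arma::mat& four) {
  using namespace cgfold;
  arma::mat X = four.t();
  return dihedral_phi(X.col(0), X.col(1), X.col(2), X.col(3), nullptr);
}
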