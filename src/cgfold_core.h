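#pragma once
#include <RcppArmadillo.h>
#include <vector>

// Internal double-precision core shared by the network evaluator, the prior
// force field and the Langevin integrator.  Node features are stored
// column-per-bead (F x n) so that per-edge gathers/scatters touch contiguous
// memory; the R-facing layout is row-per-bead and is transposed on entry.

namespace cgfold {

constexpr double KB_KCAL = 0.0019872041;   // kcal/mol/K
constexpr double FORCE2ACC = 4.184e-4;     // (kcal/mol/A)/amu -> A/fs^2

struct GnnConfig {
  double rlow, rhigh;
  int K, F, N, slots, H;
  bool train_basis;
};

struct GnnBlock {
  // stored "transposed": out_col = W * in_col + b
  arma::mat W1, W2, Wpre, Wpost, Wout;
  arma::vec b1, b2, bpost, bout;
};

struct GnnParams {
  arma::mat emb;        // F x slots
  arma::vec mu, beta;   // K
  std::vector<GnnBlock> blocks;
  arma::mat Wh1;        // H x F
  arma::vec bh1;        // H
  arma::vec Wh2;        // H
  double bh2;
};

struct GnnGrads {
  arma::mat emb;
  arma::vec mu, beta;
  std::vector<GnnBlock> blocks;
  arma::mat Wh1;
  arma::vec bh1;
  arma::vec Wh2;
  double bh2;
};

GnnConfig parse_gnn_config(const Rcpp::List& config);
GnnParams parse_gnn_params(const Rcpp::List& params, const GnnConfig& cfg);

// Batched evaluation over frames stacked along columns of X3 (3 x ntot).
// offsets has length nframes+1 (0-based node offsets of each frame).
void gnn_eval_core(const arma::mat& X3, const arma::uvec& z,
                   const arma::uvec& offsets,
                   const GnnConfig& cfg, const GnnParams& P,
                   bool want_forces, bool want_pgrad,
                   arma::vec& energy, arma::mat& forces, GnnGrads* G);

struct PriorTerms {
  arma::umat bonds;   // m x 2 (0-based)
  arma::vec bond_k, bond_r0, bond_v0;
  arma::umat pairs;   // p x 2 non-excluded repulsive pairs
  arma::vec pair_eps, pair_v0;
  arma::umat quads;   // q x 4
  arma::vec dih_k, dih_gamma, dih_n;
};

struct Perturbation {
  arma::umat pairs;   // g x 2
  arma::vec amp, center, width;
};

PriorTerms parse_prior_terms(const Rcpp::List& terms);
Perturbation parse_perturbation(const Rcpp::List& pert);

// X3 is 3 x n; forces accumulated (3 x n); returns potential energy.
double prior_eval(const arma::mat& X3, const PriorTerms& pt, arma::mat& F3);
double perturbation_eval(const arma::mat& X3, const Perturbation& pe, arma::mat& F3);

// signed dihedral angle and (optionally) its gradient wrt the four points
double dihedral_phi(const arma::vec& x1, const arma::vec& x2,
                    const arma::vec& x3, const arma::vec& x4,
                    arma::mat* dphi /* 3 x 4 or nullptr */);

}  // namespace cgfold
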