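// Multi-replica BAOAB Langevin dynamics over a combined potential:
// prior terms + optional Gaussian perturbation (toy ground truth) +
// optional graph-network potential (batched across replicas each step).
// Units: coordinates A, energies kcal/mol, masses amu, time fs,
// friction ps^-1.  Each replica carries an independent RNG stream derived
// from the master seed, so results do not depend on execution order.
#include "cgfold_core.h"
#include <random>
using namespace arma;

namespace cgfold {

struct ForceModel {
  bool has_prior = false, has_pert = false, has_gnn = false;
  PriorTerms prior;
  Perturbation pert;
  GnnConfig gcfg;
  GnnParams gpar;
  uvec z;
};

// Evaluate combined forces for all live replicas; returns per-replica energy.
static void eval_forces(const std::vector<mat>& X, const std::vector<bool>& ok,
                        ForceModel& fm, std::vector<mat>& F, vec& U) {
  const int R = X.size();
  const uword n = X[0].n_cols;
  for (int r = 0; r < R; ++r) {
    F[r].zeros();
    U[r] = 0.0;
    if (!ok[r]) continue;
    if (fm.has_prior) U[r] += prior_eval(X[r], fm.prior, F[r]);
    if (fm.has_pert) U[r] += perturbation_eval(X[r], fm.pert, F[r]);
  }
  if (fm.has_gnn) {
    std::vector<int> live;
    for (int r = 0; r < R; ++r) if (ok[r]) live.push_back(r);
    if (!live.empty()) {
      const int L = live.size();
      mat Xb(3, n * L);
      uvec zb(n * L), offsets(L + 1);
      for (int l = 0; l < L; ++l) {
        Xb.cols(l * n, (l + 1) * n - 1) = X[live[l]];
        zb.subvec(l * n, (l + 1) * n - 1) = fm.z;
        offsets[l] = l * n;
      }
      offsets[L] = L * n;
      vec eb;
      mat fb;
      gnn_eval_core(Xb, zb, offsets, fm.gcfg, fm.gpar, true, false, eb, fb,
                    nullptr);
      for (int l = 0; l < L; ++l) {
        U[live[l]] += eb[l];
        F[live[l]] += fb.cols(l * n, (l + 1) * n - 1);
      }
    }
  }
}

}  // namespace cgfold

// [[Rcpp::depends(RcppArmadillo)]]

// starts: list of (n x 3) matrices, one per replica.
// model: list with optional elements `prior`, `perturbation`, `gnn`
//        (gnn = list(params, config, z)).
// Returns saved coordinates (nsave x n x 3 per replica), potential and
// kinetic energies, final state, and per-replica stability flags.
// [[Rcpp::export]]
Rcpp::List run_langevin_cpp(const Rcpp::List& starts,
                            const arma::vec& masses, const Rcpp::List& model,
                            double temperature, double dt_fs, double gamma_ps,
                            int n_steps, int save_every, int seed,
                            bool init_velocities) {
  using namespace cgfold;
  const int R = starts.size();
  const uword n = masses.n_elem;

  ForceModel fm;
  if (model.containsElementNamed("prior") &&
      !Rf_isNull(model["prior"])) {
    fm.has_prior = true;
    fm.prior = parse_prior_terms(model["prior"]);
  }
  if (model.containsElementNamed("perturbation") &&
      !Rf_isNull(model["perturbation"])) {
    fm.has_pert = true;
    fm.pert = parse_perturbation(model["perturbation"]);
  }
  if (model.containsElementNamed("gnn") && !Rf_isNull(model["gnn"])) {
    fm.has_gnn = true;
    Rcpp::List g = model["gnn"];
    fm.gcfg = parse_gnn_config(g["config"]);
    fm.gpar = parse_gnn_params(g["params"], fm.gcfg);
    fm.z = Rcpp::as<uvec>(g["z"]);
  }

  const double gamma_fs = gamma_ps / 1000.0;
  const double kT = KB_KCAL * temperature;
  const double c1 = std::exp(-gamma_fs * dt_fs);
  vec sd_v(n);  // thermal velocity scale per bead, A/fs
  for (uword i = 0; i < n; ++i)
    sd_v[i] = std::sqrt(kT * FORCE2ACC / masses[i]);

  std::vector<mat> X(R), V(R), F(R, zeros<mat>(3, n));
  std::vector<bool> ok(R, true);
  std::vector<std::mt19937_64> rng;
  std::normal_distribution<double> gauss(0.0, 1.0);
  for (int r = 0; r < R; ++r) {
    X[r] = trans(Rcpp::as<mat>(starts[r]));
    rng.emplace_back(static_cast<uint64_t>(seed) + 1000003ULL * (r + 1));
    V[r] = zeros<mat>(3, n);
    if (init_velocities && temperature > 0) {
      for (uword i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) V[r](d, i) = sd_v[i] * gauss(rng[r]);
    }
  }

  const int nsave = n_steps / save_every;
  std::vector<Rcpp::NumericVector> saved;
  for (int r = 0; r < R; ++r) {
    Rcpp::NumericVector a(static_cast<R_xlen_t>(nsave) * n * 3);
    a.attr("dim") = Rcpp::IntegerVector::create(nsave, n, 3);
    saved.push_back(a);
  }
  mat Upot(nsave, R), Ukin(nsave, R);

  vec U(R);
  eval_forces(X, ok, fm, F, U);

  for (int step = 1; step <= n_steps; ++step) {
    for (int r = 0; r < R; ++r) {
      if (!ok[r]) continue;
      mat& x = X[r];
      mat& v = V[r];
      for (uword i = 0; i < n; ++i) {
        double a = 0.5 * dt_fs * FORCE2ACC / masses[i];
        double c2 = sd_v[i] * std::sqrt(1.0 - c1 * c1);
        for (int d = 0; d < 3; ++d) {
          v(d, i) += a * F[r](d, i);                      // B
          x(d, i) += 0.5 * dt_fs * v(d, i);               // A
          v(d, i) = c1 * v(d, i) + c2 * gauss(rng[r]);    // O
          x(d, i) += 0.5 * dt_fs * v(d, i);               // A
        }
      }
      if (!x.is_finite() || abs(x).max() > 1e4) {
        ok[r] = false;  // freeze diverged replica, keep the rest running
        Rcpp::warning("replica %d became unstable at step %d", r + 1, step);
      }
    }
    eval_forces(X, ok, fm, F, U);
    for (int r = 0; r < R; ++r) {
      if (!ok[r]) continue;
      for (uword i = 0; i < n; ++i) {
        double a = 0.5 * dt_fs * FORCE2ACC / masses[i];
        for (int d = 0; d < 3; ++d) V[r](d, i) += a * F[r](d, i);  // B
      }
    }
    if (step % save_every == 0) {
      int s = step / save_every - 1;
      for (int r = 0; r < R; ++r) {
        for (uword i = 0; i < n; ++i)
          for (int d = 0; d < 3; ++d)
            saved[r][s + nsave * (i + n * d)] = X[r](d, i);
        Upot(s, r) = U[r];
        double ke = 0.0;
        for (uword i = 0; i < n; ++i)
          ke += 0.5 * masses[i] * dot(V[r].col(i), V[r].col(i));
        Ukin(s, r) = ke / FORCE2ACC;
      }
    }
  }

  Rcpp::List coords(R), final_x(R), final_v(R);
  for (int r = 0; r < R; ++r) {
    coords[r] = saved[r];
    final_x[r] = arma::mat(X[r].t());
    final_v[r] = arma::mat(V[r].t());
  }
  return Rcpp::List::create(
      Rcpp::Named("coords") = coords, Rcpp::Named("potential") = Upot,
      Rcpp::Named("kinetic") = Ukin,
      Rcpp::Named("ok") = Rcpp::LogicalVector(ok.begin(), ok.end()),
      Rcpp::Named("final_coords") = final_x,
      Rcpp::Named("final_velocities") = final_v);
}
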