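// Graph neural-network potential: typed-bead embedding, expnorm radial basis
// with a cosine switching function, stacked continuous-filter-convolution
// interaction blocks with residual connections and a scalar energy head.
// Forces are the exact analytic negative coordinate gradient obtained by a
// hand-written reverse pass; the same pass also yields exact parameter
// gradients of the total energy, which the trainer turns into loss gradients.
#include "cgfold_core.h"
using namespace arma;

namespace cgfold {

GnnConfig parse_gnn_config(const Rcpp::List& config) {
  GnnConfig c;
  c.rlow = Rcpp::as<double>(config["cutoff_lower"]);
  c.rhigh = Rcpp::as<double>(config["cutoff_upper"]);
  c.K = Rcpp::as<int>(config["n_basis"]);
  c.F = Rcpp::as<int>(config["feature_width"]);
  c.N = Rcpp::as<int>(config["n_blocks"]);
  c.slots = Rcpp::as<int>(config["embedding_slots"]);
  c.H = Rcpp::as<int>(config["head_width"]);
  c.train_basis = Rcpp::as<bool>(config["trainable_basis"]);
  return c;
}

GnnParams parse_gnn_params(const Rcpp::List& params, const GnnConfig& cfg) {
  GnnParams P;
  P.emb = trans(Rcpp::as<mat>(params["embedding"]));     // F x slots
  P.mu = Rcpp::as<vec>(params["mu"]);
  P.beta = Rcpp::as<vec>(params["beta"]);
  Rcpp::List blocks = params["blocks"];
  for (int b = 0; b < cfg.N; ++b) {
    Rcpp::List bl = blocks[b];
    GnnBlock B;
    B.W1 = trans(Rcpp::as<mat>(bl["W1"]));     // F x K
    B.b1 = Rcpp::as<vec>(bl["b1"]);
    B.W2 = trans(Rcpp::as<mat>(bl["W2"]));     // F x F
    B.b2 = Rcpp::as<vec>(bl["b2"]);
    B.Wpre = trans(Rcpp::as<mat>(bl["Wpre"]));
    B.Wpost = trans(Rcpp::as<mat>(bl["Wpost"]));
    B.bpost = Rcpp::as<vec>(bl["bpost"]);
    B.Wout = trans(Rcpp::as<mat>(bl["Wout"]));
    B.bout = Rcpp::as<vec>(bl["bout"]);
    P.blocks.push_back(B);
  }
  Rcpp::List head = params["head"];
  P.Wh1 = trans(Rcpp::as<mat>(head["W1"]));    // H x F
  P.bh1 = Rcpp::as<vec>(head["b1"]);
  P.Wh2 = Rcpp::as<vec>(head["W2"]);           // H
  P.bh2 = Rcpp::as<double>(head["b2"]);
  return P;
}

static GnnGrads zero_grads(const GnnConfig& cfg, const GnnParams& P) {
  GnnGrads G;
  G.emb = zeros<mat>(P.emb.n_rows, P.emb.n_cols);
  G.mu = zeros<vec>(cfg.K);
  G.beta = zeros<vec>(cfg.K);
  for (int b = 0; b < cfg.N; ++b) {
    GnnBlock Z;
    Z.W1 = zeros<mat>(cfg.F, cfg.K); Z.b1 = zeros<vec>(cfg.F);
    Z.W2 = zeros<mat>(cfg.F, cfg.F); Z.b2 = zeros<vec>(cfg.F);
    Z.Wpre = zeros<mat>(cfg.F, cfg.F);
    Z.Wpost = zeros<mat>(cfg.F, cfg.F); Z.bpost = zeros<vec>(cfg.F);
    Z.Wout = zeros<mat>(cfg.F, cfg.F); Z.bout = zeros<vec>(cfg.F);
    G.blocks.push_back(Z);
  }
  G.Wh1 = zeros<mat>(cfg.H, cfg.F);
  G.bh1 = zeros<vec>(cfg.H);
  G.Wh2 = zeros<vec>(cfg.H);
  G.bh2 = 0.0;
  return G;
}

// cosine switch: 0 at both cutoffs, 1 at the midpoint
static inline double fcut(double d, double rlow, double rhigh) {
  if (d <= rlow || d >= rhigh) return 0.0;
  return 0.5 * (std::cos(M_PI * (2.0 * (d - rlow) / (rhigh - rlow) + 1.0)) + 1.0);
}
static inline double fcut_deriv(double d, double rlow, double rhigh) {
  if (d <= rlow || d >= rhigh) return 0.0;
  double w = 2.0 * M_PI / (rhigh - rlow);
  return -0.5 * w * std::sin(M_PI * (2.0 * (d - rlow) / (rhigh - rlow) + 1.0));
}

void gnn_eval_core(const mat& X3, const uvec& z, const uvec& offsets,
                   const GnnConfig& cfg, const GnnParams& P,
                   bool want_forces, bool want_pgrad,
                   vec& energy, mat& forces, GnnGrads* G) {
  const int nframes = offsets.n_elem - 1;
  const uword ntot = X3.n_cols;
  const int K = cfg.K, F = cfg.F, N = cfg.N;
  const double alpha = 5.0 / (cfg.rhigh - cfg.rlow);

  // ---- edges (within-frame pairs with d <= cutoff_upper, both directions)
  std::vector<uword> esrc_v, edst_v;
  std::vector<double> ed_v;
  for (int f = 0; f < nframes; ++f) {
    for (uword i = offsets[f]; i < offsets[f + 1]; ++i) {
      for (uword j = i + 1; j < offsets[f + 1]; ++j) {
        double dx = X3(0, i) - X3(0, j), dy = X3(1, i) - X3(1, j),
               dz = X3(2, i) - X3(2, j);
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d <= cfg.rhigh) {
          edst_v.push_back(i); esrc_v.push_back(j); ed_v.push_back(d);
          edst_v.push_back(j); esrc_v.push_back(i); ed_v.push_back(d);
        }
      }
    }
  }
  const uword E = ed_v.size();
  uvec esrc(esrc_v), edst(edst_v);
  vec ed(ed_v);

  // ---- radial basis: Phi (K x E)
  vec xe(E), cutv(E);
  for (uword e = 0; e < E; ++e) {
    xe[e] = std::exp(alpha * (cfg.rlow - ed[e]));
    cutv[e] = fcut(ed[e], cfg.rlow, cfg.rhigh);
  }
  mat Gbas(K, E), Phi(K, E);
  if (E > 0) {
    for (uword e = 0; e < E; ++e)
      for (int k = 0; k < K; ++k) {
        double t = xe[e] - P.mu[k];
        Gbas(k, e) = std::exp(-P.beta[k] * t * t);
        Phi(k, e) = cutv[e] * Gbas(k, e);
      }
  }

  // ---- forward
  mat xi = P.emb.cols(z);                       // F x ntot
  std::vector<mat> sv_xi(N), sv_H1(N), sv_WC(N), sv_Pre(N), sv_Y(N), sv_A(N);
  for (int b = 0; b < N; ++b) {
    const GnnBlock& B = P.blocks[b];
    sv_xi[b] = xi;
    mat Pre = B.Wpre * xi;                      // F x ntot
    mat Y = zeros<mat>(F, ntot);
    mat H1, WC;
    if (E > 0) {
      H1 = tanh(B.W1 * Phi + repmat(B.b1, 1, E));
      WC = B.W2 * H1;  WC.each_col() += B.b2;   // F x E
      mat Msg = WC % Pre.cols(esrc);
      for (uword e = 0; e < E; ++e) Y.col(edst[e]) += Msg.col(e);
    }
    mat A = tanh(B.Wpost * Y + repmat(B.bpost, 1, ntot));
    xi += B.Wout * A;  xi.each_col() += B.bout;
    sv_H1[b] = std::move(H1); sv_WC[b] = std::move(WC);
    sv_Pre[b] = std::move(Pre); sv_Y[b] = std::move(Y); sv_A[b] = std::move(A);
  }
  mat Hh = tanh(P.Wh1 * xi + repmat(P.bh1, 1, ntot));   // H x ntot
  rowvec u = P.Wh2.t() * Hh + P.bh2;                     // 1 x ntot

  energy.set_size(nframes);
  for (int f = 0; f < nframes; ++f) {
    double s = 0.0;
    for (uword i = offsets[f]; i < offsets[f + 1]; ++i) s += u[i];
    energy[f] = s;
  }

  if (!want_forces && !want_pgrad) return;

  // ---- reverse pass: dU/dxi with U = sum of all node scalars
  GnnGrads GG = zero_grads(cfg, P);
  mat dHh = repmat(P.Wh2, 1, ntot);             // H x ntot
  mat dZh = dHh % (1.0 - Hh % Hh);
  if (want_pgrad) {
    GG.Wh2 = sum(Hh, 1);
    GG.bh2 = static_cast<double>(ntot);
    GG.Wh1 = dZh * xi.t();
    GG.bh1 = sum(dZh, 1);
  }
  mat dxi = P.Wh1.t() * dZh;                    // F x ntot
  mat dPhi = zeros<mat>(K, E);
  vec dd = zeros<vec>(E);

  for (int b = N - 1; b >= 0; --b) {
    const GnnBlock& B = P.blocks[b];
    const mat& A = sv_A[b];
    mat dA = B.Wout.t() * dxi;
    if (want_pgrad) {
      GG.blocks[b].Wout = dxi * A.t();
      GG.blocks[b].bout = sum(dxi, 1);
    }
    mat dh1 = dA % (1.0 - A % A);
    if (want_pgrad) {
      GG.blocks[b].Wpost = dh1 * sv_Y[b].t();
      GG.blocks[b].bpost = sum(dh1, 1);
    }
    mat dY = B.Wpost.t() * dh1;                 // F x ntot
    mat dPre = zeros<mat>(F, ntot);
    if (E > 0) {
      mat dMsg(F, E), dWC(F, E);
      for (uword e = 0; e < E; ++e) {
        dMsg.col(e) = dY.col(edst[e]);
        dWC.col(e) = dMsg.col(e) % sv_Pre[b].col(esrc[e]);
        dPre.col(esrc[e]) += dMsg.col(e) % sv_WC[b].col(e);
      }
      mat dH1 = B.W2.t() * dWC;
      if (want_pgrad) {
        GG.blocks[b].W2 = dWC * sv_H1[b].t();
        GG.blocks[b].b2 = sum(dWC, 1);
      }
      mat dZ1 = dH1 % (1.0 - sv_H1[b] % sv_H1[b]);
      if (want_pgrad) {
        GG.blocks[b].W1 = dZ1 * Phi.t();
        GG.blocks[b].b1 = sum(dZ1, 1);
      }
      dPhi += B.W1.t() * dZ1;
    }
    if (want_pgrad) GG.blocks[b].Wpre = dPre * sv_xi[b].t();
    dxi += B.Wpre.t() * dPre;
  }
  if (want_pgrad) {
    for (uword i = 0; i < ntot; ++i) GG.emb.col(z[i]) += dxi.col(i);
  }

  // ---- basis backward: Phi(k,e) = C(e) * exp(-beta_k (xe_e - mu_k)^2)
  for (uword e = 0; e < E; ++e) {
    double dCe = 0.0, dxe = 0.0;
    for (int k = 0; k < K; ++k) {
      double t = xe[e] - P.mu[k];
      double dG = dPhi(k, e) * cutv[e];
      dCe += dPhi(k, e) * Gbas(k, e);
      double common = dG * Gbas(k, e);
      dxe += common * (-2.0 * P.beta[k] * t);
      if (want_pgrad) {
        GG.mu[k] += common * (2.0 * P.beta[k] * t);
        GG.beta[k] += common * (-t * t);
      }
    }
    dd[e] = dCe * fcut_deriv(ed[e], cfg.rlow, cfg.rhigh) + dxe * (-alpha * xe[e]);
  }

  if (want_forces) {
    forces = zeros<mat>(3, ntot);
    for (uword e = 0; e < E; ++e) {
      uword i = edst[e], j = esrc[e];
      if (ed[e] > 0) {
        vec g = (X3.col(i) - X3.col(j)) * (dd[e] / ed[e]);
        // F = -dU/dx; each directed edge carries d's dependence on both ends
        forces.col(i) -= g;
        forces.col(j) += g;
      }
    }
  }
  if (want_pgrad && G != nullptr) *G = std::move(GG);
}

static Rcpp::List grads_to_list(const GnnGrads& G, const GnnConfig& cfg) {
  Rcpp::List blocks(cfg.N);
  for (int b = 0; b < cfg.N; ++b) {
    blocks[b] = Rcpp::List::create(
        Rcpp::Named("W1") = trans(G.blocks[b].W1),
        Rcpp::Named("b1") = G.blocks[b].b1,
        Rcpp::Named("W2") = trans(G.blocks[b].W2),
        Rcpp::Named("b2") = G.blocks[b].b2,
        Rcpp::Named("Wpre") = trans(G.blocks[b].Wpre),
        Rcpp::Named("Wpost") = trans(G.blocks[b].Wpost),
        Rcpp::Named("bpost") = G.blocks[b].bpost,
        Rcpp::Named("Wout") = trans(G.blocks[b].Wout),
        Rcpp::Named("bout") = G.blocks[b].bout);
  }
  return Rcpp::List::create(
      Rcpp::Named("embedding") = trans(G.emb),
      Rcpp::Named("mu") = G.mu,
      Rcpp::Named("beta") = G.beta,
      Rcpp::Named("blocks") = blocks,
      Rcpp::Named("head") = Rcpp::List::create(
          Rcpp::Named("W1") = trans(G.Wh1), Rcpp::Named("b1") = G.bh1,
          Rcpp::Named("W2") = G.Wh2, Rcpp::Named("b2") = G.bh2));
}

}  // namespace cgfold

// [[Rcpp::depends(RcppArmadillo)]]

// Batched network evaluation.  `coords` is an (ntot x 3) stack of frames,
// `offsets` the 0-based node offset of each frame (length nframes+1),
// `z` 0-based bead type ids per node.
// [[Rcpp::export]]
Rcpp::List gnn_eval_cpp(const arma::mat& coords, const arma::uvec& z,
                        const arma::uvec& offsets, const Rcpp::List& params,
                        const Rcpp::List& config, bool want_forces,
                        bool want_pgrad) {
  using namespace cgfold;
  if (!coords.is_finite()) Rcpp::stop("non-finite coordinates");
  GnnConfig cfg = parse_gnn_config(config);
  GnnParams P = parse_gnn_params(params, cfg);
  arma::vec energy;
  arma::mat forces;
  GnnGrads G;
  gnn_eval_core(coords.t(), z, offsets, cfg, P, want_forces, want_pgrad,
                energy, forces, want_pgrad ? &G : nullptr);
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("energy") = energy,
      Rcpp::Named("forces") = R_NilValue,
      Rcpp::Named("pgrad") = R_NilValue);
  if (want_forces) out["forces"] = arma::mat(forces.t());
  if (want_pgrad) out["pgrad"] = grads_to_list(G, cfg);
  return out;
}
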