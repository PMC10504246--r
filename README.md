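# cgfold

Machine-learned coarse-grained (CG) force fields for protein
thermodynamics, in R.

## What this is for

All-atom molecular dynamics resolves protein conformational equilibria at
femtosecond resolution but milli­second cost.  A thermodynamically
consistent coarse-grained model — one bead per residue, placed on the
alpha carbon — can sample the same equilibrium distribution orders of
magnitude faster, if its potential approximates the many-body potential of
mean force over the CG coordinates.  `cgfold` is for computational
structural biologists and method developers who want to build, train and
validate such models end to end:

1. **Mapping** (`map_frames`, `assign_bead_types`): linear selection of
   Cα coordinates and forces from all-atom data; 21 bead types (20
   canonical amino acids + norleucine), protonation variants merged,
   terminal residues typed like internal ones.
2. **Prior potentials** (`fit_priors`, `prior_energy_forces`): harmonic
   bonds `k (r − r₀)² + V₀`, pairwise repulsion `4 ε r⁻⁶ + V₀`, and a
   global chirality-breaking dihedral
   `Σₙ kₙ (1 + cos(n φ − γₙ))`, fitted by Boltzmann inversion with the
   dihedral amplitudes halved to give a soft prior.
3. **Graph network potential** (`gn_potential`, `gnn_forces`): stacked
   continuous-filter convolutions over the bead graph with an expnorm
   radial basis on 3–12 Å, tanh activations and sum aggregation; the
   default architecture (4 blocks, 128 features, 18 basis functions) has
   exactly **294,565** trainable parameters.  Forces are the exact
   analytic negative gradient (hand-written reverse pass in compiled
   code).
4. **Force matching** (`train_potential`): minimizes
   `L = 1/(3nM) Σ‖Ξ F(r) + ∇U(Ξ r; θ)‖²` over the *residual* between
   mapped forces and prior forces (delta-learning), with an 85/5/10
   frame split, Adam, plateau learning-rate decay and
   validation-minimum checkpointing.
5. **Langevin simulation** (`run_simulation`): BAOAB integrator, 350 K,
   1 fs step, 32 isolated replicas saved every 100 fs by default.
6. **MSM validation** (`fit_tica`, `estimate_msm`, `pcca_macrostates`,
   `free_energy_surface`, `bootstrap_report`): pairwise-distance
   features, TICA (with frozen reference covariances for CG data),
   k-means, reversible MSM, PCCA+ macrostates, 80×80 free-energy grids,
   Kabsch RMSD and bootstrapped native-macrostate statistics.
7. **Synthetic ground truth** (`make_toy_polymer`, `sample_reference`):
   toy polymers governed by a fully known analytic potential with exact
   recorded forces, so the entire pipeline is testable on one CPU with no
   external data.

A thin command-line interface over these functions is installed at
`inst/cli/cgfold` (`cgfold map | fit-priors | train | simulate | analyze |
fixtures | inspect-model`).

## Worked example

```r
library(cgfold)

# 1. a synthetic ground-truth system with exact forces
spec <- make_toy_polymer(n_beads = 10, seed = 1)
ref  <- sample_reference(spec, n_frames = 8000, seed = 7)

# 2. fit prior potentials by Boltzmann inversion
priors <- fit_priors(ref, spec$topology)

# 3. train the network on the residual forces (delta-learning)
fit <- train_potential(
  ref, spec$topology, spec$forcefield,
  net_config = network_config(n_blocks = 2, feature_width = 32,
                              n_basis = 8, embedding_slots = 22),
  config = training_config(batch_size = 128, learning_rate = 2e-3,
                           max_epochs = 4, seed = 1))

# 4. simulate the learned potential and compare marginals
prot <- simulation_protocol(n_steps = 4000, n_replicas = 16, friction = 1,
                            save_interval = 10, seed = 2)
set.seed(2)
starts <- lapply(sample(8000, 16), function(i) ref$systems$toy$coords[i, , ])
sim <- run_simulation(spec$topology, spec$forcefield, starts, prot,
                      potential = fit$potential)
mad <- compare_marginals(ref$systems$toy$coords, ensemble_frames(sim),
                         spec$topology)
```

Output (about 80 s on one CPU):

```
Toy polymer: 10 beads, 15 perturbation Gaussians, 350 K
fitted bond: k = 10.12 kcal/mol/A^2, r0 = 3.816 A
  epoch  train_mse    val_mse    lr
4     4 0.01910327 0.01948576 0.002
test force MAE: 0.074 kcal/mol/A
Trajectory ensemble: 16 replicas x 400 saved frames (10 beads), 16 stable
marginal difference vs ground truth: bonds 0.004, dihedrals 0.011
```

Reading the numbers: the inversion recovers the generating bond constants
(true k = 10, r₀ = 3.8); after four epochs the network's validation MSE
(0.019 (kcal/mol/Å)²) is far below the residual-force variance of the
zero model (≈ 0.085), i.e. it has learned most of the perturbation the
priors cannot express; the 16 CG replicas driven by priors + network stay
stable and reproduce the ground-truth bond and dihedral marginals to
within 0.4% / 1.1% mean absolute histogram difference.

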