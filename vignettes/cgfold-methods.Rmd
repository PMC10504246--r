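---
title: "Machine-learned coarse-grained force fields with cgfold: models, priors, training and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cgfold methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem and the model

Proteins live in an equilibrium of conformational states, and sampling that
equilibrium with all-atom molecular dynamics is expensive.  `cgfold`
implements a bottom-up coarse-graining workflow that seeks *thermodynamic
consistency*: the coarse model's Boltzmann distribution should match the
mapped distribution of the all-atom system, even though individual atomic
degrees of freedom are integrated out.

The resolution is one bead per residue, placed on the alpha carbon.  The
mapping `x = Xi r` is a pure linear selection of the Calpha rows of the
all-atom coordinate and force arrays (`map_frames()`); no averaging is
involved, so mapped forces are exactly the atomistic Calpha forces.  Each
bead carries a type from a 21-letter vocabulary: the 20 canonical amino
acids plus norleucine, with protonation variants merged into their parent
type and terminal residues typed like internal ones
(`bead_vocabulary()`, `assign_bead_types()`).

## Variational force matching

Given `M` mapped coordinate/force pairs, the CG potential `U(x; theta)` is
trained to minimize the mean squared difference between its negative
gradient and the mapped forces,

```
L(theta) = 1/(3 n M) * sum_c || Xi F(r_c) + grad U(Xi r_c; theta) ||^2 ,
```

the standard variational estimator of the many-body potential of mean
force.  With frames of different bead counts batched together the
normalization is the total component count (`force_matching_loss()`),
which reduces to `1/(3 n M)` for fixed `n`.  Because the mapped force at a
CG configuration is a *stochastic* function of the configuration (the
solvent and side-chain degrees of freedom are gone), the loss has an
irreducible variance floor: even a perfect potential of mean force cannot
drive it to zero on real data.  On the synthetic fixtures the recorded
forces are exact gradients of a known potential, so there the loss can and
does go far below the zero-model variance.

## Prior potential and delta-learning

A neural network alone extrapolates poorly to configurations never seen in
training, assigning them spuriously low energies.  `cgfold` therefore
places simple physics *priors* beneath the network and trains the network
on the residual forces only (`delta_targets()`), so the total CG force is
`F_prior + F_network`:

* bonded, per consecutive pair: `V(r) = k (r - r0)^2 + V0`;
* repulsive, per non-excluded pair: `V(r) = 4 eps r^-6 + V0`;
* dihedral, per four consecutive beads:
  `V(phi) = sum_{n=1,2} k_n (1 + cos(n phi - gamma_n))`, one global
  parameter set for all quadruples.

The dihedral term exists to break mirror symmetry.  Pairwise distances are
achiral: reflecting a conformation leaves every distance (hence the
network energy and the other two priors) unchanged while negating every
dihedral.  A phase offset `gamma_n` not equal to 0 or pi makes
`V(phi) != V(-phi)` and penalizes mirror images of the chirally sampled
training data.

Prior parameters are fitted by Boltzmann inversion (`fit_priors()`):
histograms (64 bins) of bond lengths per type pair (range mean +/- 4 sd),
non-excluded pair distances, and pooled dihedral angles are converted to
free-energy profiles `-kB T log p` and least-squares fitted to the three
functional forms.  Numerical conventions: the repulsion is fitted only on
the rising shoulder below the distance mode (the region the power law is
meant to describe); the dihedral series is fitted linearly in the
`(k cos gamma, k sin gamma)` basis and converted to amplitude/phase; the
fitted dihedral amplitudes are then *halved*, giving a soft prior that
orients chirality without dominating the potential; `V0` is fixed at 0
(it shifts energies, never forces); norleucine parameters are adapted from
leucine; type pairs with insufficient data fall back to a pooled default
entry.  `kB = 0.0019872041 kcal/mol/K` everywhere.

Repulsion exclusions default to bonded `(i, i+1)` pairs and are
configurable to offsets 2 and 3, mirroring the force-field file's
`exclusions` parameter.

## The graph network potential

The network (`gn_potential()`) is a continuous-filter convolution graph
network over the bead graph.  Edges are all directed pairs within an upper
cutoff (12 A by default); each distance is expanded in `K = 18` *expnorm*
radial basis functions on 3.0-12.0 A,

```
phi_k(d) = f_cut(d) * exp(-beta_k (exp(alpha (r_low - d)) - mu_k)^2),
alpha = 5 / (r_high - r_low),
```

with a cosine switch `f_cut` that vanishes at both cutoffs and equals 1 at
their midpoint.  The exponential warping elongates the basis towards long
distances, which suits the soft, long-ranged statistics of CG beads; basis
centers and widths are trainable (centers uniform on `[exp(-5), 1]`,
widths constant `(2 (1 - exp(-5)) / K)^-2` at initialization).

Each of the `N = 4` interaction blocks updates node features
`xi` (width 128) as

```
xi <- xi + W_out tanh(W_post Aggr_j[ W_C(d_ij) * (W_pre xi_j) ] + biases)
W_C(d)  = W2 tanh(W1 phi(d) + b1) + b2
```

with sum aggregation (preserves extensivity) and tanh activations (keeps
the learned free-energy surface smooth).  After the last block a two-layer
head (128 -> 64 -> 1, tanh) produces per-bead scalars that sum to the
energy; forces are the exact negative gradient computed by a hand-written
reverse pass in compiled code -- no finite differences anywhere in the
force path.

The exact per-block layout -- biases on the filter network, the
post-aggregation linear and the block-output linear, a bias-free
pre-convolution linear, a 100-slot embedding table of which 21 rows are
used, and the 128 -> 64 -> 1 head -- is pinned by the requirement that the
default configuration counts exactly **294,565** trainable parameters
(`count_parameters()`); the unused embedding rows are inert.  One
consequence of the biased filter network is a small energy discontinuity
when a pair crosses the upper cutoff (the filter of a vanishing basis
vector is the bias path, not zero); with the 12 A cutoff and the priors
bounding the sampled space this has no observable effect in the tests, and
it is the price of reproducing the printed parameter count with the stated
layout.

## Training

`train_potential()` minimizes the force-matching loss with Adam.  Frames
are split 85/5/10 into train/validation/test uniformly at random per
frame, reproducibly from one master seed that also governs weight
initialization and shuffling.  (Splitting per frame rather than per
trajectory means neighboring, correlated frames can land on both sides of
the split; for the synthetic exact-force data this is immaterial, but on
real trajectory data it would make validation loss slightly optimistic.)

The gradient of the loss with respect to the parameters is a second-order
quantity: it differentiates through the force, which is itself a
gradient.  The reverse pass returns the exact parameter gradient of the
*energy*; the loss gradient `-grad_theta (v . grad_x U)` (with `v` the
force residual direction) is then formed as a Pearlmutter-style
Hessian-vector product, evaluated by a central finite difference of the
exact parameter-gradient pass along `v` with step `1e-3` A on the maximal
coordinate component.  The unit tests verify this against dense finite
differences of the loss itself to 1e-4.

Training/validation losses are recorded as mean squared error per epoch;
the checkpoint at the validation minimum is selected, with a plateau rule
(learning-rate decay x0.8 after 5 stagnant epochs, stop after 30); the
test loss is reported as mean absolute error and plays no role in
selection.

## Langevin simulation

`run_simulation()` integrates the combined potential with the BAOAB
splitting of Langevin dynamics -- chosen over other splittings for its
superior configurational sampling accuracy at finite step size.  Protocol
defaults follow the CG validation protocol: 350 K, 1 fs step, output every
100 fs, 32 parallel isolated replicas, Maxwell-Boltzmann initial
velocities, one child RNG stream per replica (results are independent of
replica execution order).  The friction coefficient defaults to
0.1 ps^-1; friction shapes kinetics, not the stationary distribution, and
the thermodynamics is the quantity being validated.  Masses are residue
masses; equilibrium distributions are mass-independent, which the tests
verify directly.  A replica whose coordinates leave a 1e4 A box is flagged
and frozen while the others continue; there is no force clipping, since
bounding the sampled space is the priors' job.

Starting conformations are selected evenly across the free-energy surface
of reference data by grid-stratified sampling over a 2-D projection (at
most one frame per occupied cell, farthest-point fallback for degenerate
projections; `select_starting_points()`).

## MSM validation pipeline

The thermodynamic comparison between reference and CG ensembles runs
through `featurize_pairwise_distances()` (all Calpha pairs -- the one
featurization transferable between resolutions), TICA
(`fit_tica()`/`project_tica()`: symmetrized lagged-covariance eigenproblem;
reference-covariance mode projects CG data with the model fitted on
reference data, 4 components for the reference fit and 3 for CG
projection), seeded k-means discretization, reversible maximum-likelihood
MSM estimation on the largest strongly connected set (`estimate_msm()`,
the standard detailed-balance fixed point, tolerance 1e-12), PCCA+
macrostates (`pcca_macrostates()`; reversibility guarantees the real
spectrum PCCA+ needs; memberships are stored, reporting uses the crisp
argmax), and an 80 x 80 free-energy grid over the first two components
with per-frame weights `pi(microstate) / count(microstate)` and
`F = -kB T log(sum w)` shifted to zero at the occupied minimum
(`free_energy_surface()`).

`rmsd_kabsch()` implements least-squares superposition via the SVD
construction with a reflection guard (RMSD is still defined, if
degenerate, for collinear inputs).  The native macrostate is the one
containing the global minimum-RMSD frame, ties broken towards the lower
macrostate index; `rank_macrostates_by_energy()` implements the
complementary minimum-mean-energy criterion.  `bootstrap_report()` wraps
the whole pipeline: the first 10% of each trajectory is discarded, 10
models are estimated from resamples of 90% of the trajectories, bootstrap
macrostates are matched to the full-data partition by stationary-weighted
microstate overlap, and 10 conformations per macrostate are sampled
proportionally to within-state weights.  MSM lag, microstate count and
macrostate count have no canonical values at this scale; the defaults
(lag 10 saved frames, `k = max(20, frames/500)` capped at 200, `m` by
argument) are package choices and are reported as such.  Macrostate RMSD
statistics are unweighted over sampled frames.

# The synthetic ground truth, and what the tests do and do not show

`make_toy_polymer()` builds a 10-bead chain governed by exactly the three
prior terms (bond k = 10 kcal/mol/A^2 at 3.8 A, repulsion eps = 1, chiral
dihedral k = (0.8, 0.4), gamma = (0.7, -0.5)) plus a smooth many-body
perturbation: Gaussians (amplitude +/- [0.5, 1] kcal/mol, centers
5.5-7.5 A, widths 0.8-1.2 A, drawn once per seed) on the (i, i+2) and
(i, i+3) pair distances -- deliberately expressible by a small
distance-based network.  `sample_reference()` draws decorrelated frames
from long BAOAB runs (stride 100 steps, friction 1 ps^-1 for faster
decorrelation, 20000 burn-in steps) and records *exact analytic* forces.

This emulates the statistical structure of CG training data -- Boltzmann
configurations with matching forces for 21-type bead chains at a stated
temperature -- but not real protein energetics: forces are deterministic
(no variance floor), the perturbation is mild (about 1.4 kB T), and the
chain has no secondary structure.  Passing the end-to-end test therefore
demonstrates that the machinery is correct (mapping, priors, network,
gradients, integrator, analysis), not that a 10-bead toy predicts protein
folding.  Two further honest caveats: the perturbation's equilibrium
effect on bond/dihedral marginals is small (its signature lives mostly in
force space, where the trained network must explain at least 90% of the
residual variance), and the CG validation runs start from conformations
spread over the reference ensemble, so the marginal comparison primarily
checks that the learned potential *holds* the correct distribution rather
than finds it from far away.  Marginals are compared per degree of
freedom (each bond, each dihedral; 24-bin normalized histograms, mean
absolute bin difference averaged over dofs) because the perturbation's
sign alternates along the chain and pooling would cancel real
discrepancies.

Problem sizes used by the test suite and the acceptance script -- 5 x 10^4
training frames, a 2-block/32-feature/8-basis network, 8 training epochs,
32 replicas of 6 ps for the CG validation runs, 10^5 saved frames for the
sampler fidelity check, 10^6 steps for the Markov chain oracles -- are the
package's chosen desk-scale study conditions: large enough that every
statistical tolerance is meaningful, small enough to run on one CPU.

# Numerical choices and degenerate inputs

* Double precision throughout (R's native numeric); the compiled core is
  dense Armadillo linear algebra.
* Dihedral angles follow the IUPAC sign convention (cis = 0); gradients
  use the Blondel-Karplus form; a collinear bead triple is an error for
  the geometry function, and the dihedral prior's force grows near
  collinearity but remains integrable under the sampled measure.
* Energy unit conversion in the integrator:
  1 (kcal/mol/A)/amu = 4.184e-4 A/fs^2.
* TICA regularizes the instantaneous covariance with a trace-scaled ridge
  (1e-10) before whitening and drops numerically null directions.
* k-means restarts with a shifted seed (up to 10 times) if a clustering
  degenerates; the restart count is deterministic.
* Ties: native-macrostate ties break to the lower index; equal-mean energy
  ranking is a stable index-ordered sort; the minimum-RMSD frame is the
  first minimizer.
* Frame archives are a versioned native R serialization (RDS) with
  per-system groups of `[M, n, 3]` arrays and a temperature attribute --
  an exact round trip.  Force-field files, topologies and run
  configurations are YAML.

# Known limitations

* The trainer is CPU-bound and single-threaded beyond BLAS; it is sized
  for desk-scale fixtures, not multi-millisecond protein datasets.
* Bonded/repulsive prior parameter *values* for real proteins are not
  shipped: they are reproducible from data via `fit_priors()` but no
  published table exists to copy.
* Kinetics are out of scope by construction: force matching preserves
  thermodynamics, and the reported MSMs are used only for equilibrium
  quantities.
* The per-frame data split leaks temporal correlation on trajectory data
  (see above); a per-trajectory split is the conservative alternative.
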