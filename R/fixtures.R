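#' Synthetic toy-polymer fixture
#'
#' A desk-scale ground-truth system: a bead chain governed by a fully known
#' analytic potential with the same structure as the CG model's -- the
#' three prior terms plus a smooth many-body-expressible perturbation (sums
#' of Gaussians on the (i, i+2) and (i, i+3) pair distances, which a small
#' network can represent).  Exact analytic forces make every downstream
#' module testable without external data.
#'
#' Ground-truth parameters: bonds k = 10 kcal/mol/A^2 at r0 = 3.8 A;
#' repulsion epsilon = 1 kcal/mol A^6 (bonded pairs excluded); dihedral
#' amplitudes k1 = 0.8, k2 = 0.4 kcal/mol with phases 0.7 and -0.5 rad
#' (chiral: not 0 or pi).  Perturbation amplitudes are drawn in
#' `+/- [0.5, 1] * perturbation_amplitude`, centers in 5.5-7.5 A, widths in
#' 0.8-1.2 A, reproducibly from the seed.
#'
#' @param n_beads chain length (>= 4 so dihedrals exist).
#' @param seed RNG seed for the perturbation draw.
#' @param perturbation_amplitude Gaussian amplitude scale, kcal/mol
#'   (0 makes the potential equal the priors exactly).
#' @param temperature K the fixture is meant to be sampled at.
#' @return Object of class `toy_polymer`: `topology`, `forcefield`,
#'   `perturbation` (pairs/amp/center/width), `temperature`, `seed`.
#' @export
make_toy_polymer <- function(n_beads = 10L, seed = 1L,
                             perturbation_amplitude = 1,
                             temperature = 350) {
  if (n_beads < 4)
    stop("toy polymer needs at least 4 beads (dihedral term undefined)",
         call. = FALSE)
  vocab <- bead_vocabulary()
  residues <- names(vocab)[(seq_len(n_beads) - 1L) %% length(vocab) + 1L]
  topology <- build_cg_topology(residues, vocab, chain = "TOY")
  ff <- prior_forcefield(
    bonds = list(default = list(k = 10, r0 = 3.8, v0 = 0)),
    repulsion = list(default = list(epsilon = 1, v0 = 0)),
    dihedral = list(terms = list(list(n = 1, k = 0.8, gamma = 0.7),
                                 list(n = 2, k = 0.4, gamma = -0.5))),
    exclusions = 1L)
  pairs <- rbind(
    cbind(seq_len(n_beads - 2), seq_len(n_beads - 2) + 2L),
    cbind(seq_len(n_beads - 3), seq_len(n_beads - 3) + 3L))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  g <- nrow(pairs)
  pert <- list(pairs = pairs,
               amp = perturbation_amplitude *
                 sample(c(-1, 1), g, replace = TRUE) * runif(g, 0.5, 1),
               center = runif(g, 5.5, 7.5), width = runif(g, 0.8, 1.2))
  structure(list(topology = topology, forcefield = ff, perturbation = pert,
                 temperature = temperature, seed = seed,
                 n_beads = as.integer(n_beads)), class = "toy_polymer")
}

#' @export
print.toy_polymer <- function(x, ...) {
  cat(sprintf("Toy polymer: %d beads, %d perturbation Gaussians, %g K\n",
              x$n_beads, nrow(x$perturbation$pairs), x$temperature))
  invisible(x)
}

#' Analytic ground-truth energy and forces of a toy polymer
#'
#' Priors plus perturbation; forces are exact negative gradients.
#'
#' @param spec a [make_toy_polymer()] spec.
#' @param coords n x 3 matrix (A).
#' @return List with `energy` (kcal/mol) and `forces` (n x 3).
#' @export
toy_energy_forces <- function(spec, coords) {
  pr <- prior_energy_forces(coords, spec$topology, spec$forcefield)
  pe <- perturbation_eval_cpp(coords, list(
    pairs = spec$perturbation$pairs - 1L, amp = spec$perturbation$amp,
    center = spec$perturbation$center, width = spec$perturbation$width))
  list(energy = pr$energy + pe$energy, forces = pr$forces + pe$forces)
}

# loose helical starting chain with ~3.8 A spacing
toy_start_coords <- function(n_beads) {
  i <- seq_len(n_beads) - 1
  cbind(3.4 * i, 1.6 * sin(2.1 * i), 1.6 * cos(2.1 * i))
}

#' Sample a reference ensemble from the toy ground truth
#'
#' Long Langevin runs under the analytic potential, burnt in and thinned by
#' `stride` integrator steps so frames are decorrelated, with exact
#' analytic forces recorded at every saved frame.  This emulates the
#' statistical structure of CG training data: Boltzmann-distributed
#' configurations with matching forces at a stated temperature.
#'
#' @param spec a [make_toy_polymer()] spec.
#' @param n_frames total frames to collect (split over replicas).
#' @param n_replicas parallel replicas.
#' @param stride integrator steps between saved frames.
#' @param burn_steps equilibration steps discarded per replica.
#' @param friction ps^-1 (sampling efficiency only; does not affect the
#'   equilibrium distribution).
#' @param timestep fs.
#' @param seed RNG seed.
#' @return A [frame_dataset()] with system tag `"toy"`; forces are exact.
#' @export
sample_reference <- function(spec, n_frames, n_replicas = 8L, stride = 100L,
                             burn_steps = 20000L, friction = 1,
                             timestep = 1, seed = 1L) {
  per_rep <- ceiling(n_frames / n_replicas)
  protocol <- simulation_protocol(
    n_steps = burn_steps + per_rep * stride, temperature = spec$temperature,
    timestep = timestep, friction = friction,
    save_interval = stride * timestep, n_replicas = n_replicas, seed = seed)
  sim <- run_simulation(spec$topology, spec$forcefield,
                        starts = toy_start_coords(spec$n_beads),
                        protocol = protocol,
                        perturbation = spec$perturbation)
  if (!all(sim$ok)) stop("reference sampling unstable; reduce timestep",
                         call. = FALSE)
  skip <- burn_steps %/% stride
  frames <- do.call(rbind, lapply(sim$coords, function(x)
    matrix(x[(skip + 1):dim(x)[1], , ], ncol = prod(dim(x)[-1]))))
  frames <- frames[seq_len(n_frames), , drop = FALSE]
  n <- spec$n_beads
  coords <- array(frames, c(n_frames, n, 3))
  forces <- array(0, c(n_frames, n, 3))
  for (f in seq_len(n_frames))
    forces[f, , ] <- toy_energy_forces(spec, coords[f, , ])$forces
  frame_dataset(coords, forces, temperature = spec$temperature,
                system = "toy")
}

#' Reflect coordinates through the yz-plane
#'
#' Negates the x coordinate: pair distances are unchanged but every
#' dihedral angle is negated, which is the mechanism by which a chiral
#' dihedral prior penalizes mirror images.
#'
#' @param coords n x 3 matrix or `[S, n, 3]` array.
#' @return Mirrored coordinates of the same shape.
#' @export
mirror_coords <- function(coords) {
  if (is.matrix(coords)) {
    coords[, 1] <- -coords[, 1]
  } else {
    coords[, , 1] <- -coords[, , 1]
  }
  coords
}

#' Sample a discrete Markov chain
#'
#' Exact Markov-chain sampling from a row-stochastic transition matrix;
#' oracle data for the MSM estimator.
#'
#' @param transition row-stochastic matrix.
#' @param n_steps chain length.
#' @param seed RNG seed.
#' @param start initial state (default 1).
#' @return Integer state trajectory of length `n_steps`.
#' @export
make_markov_fixture <- function(transition, n_steps, seed = 1L, start = 1L) {
  transition <- as.matrix(transition)
  if (any(transition < 0) || max(abs(rowSums(transition) - 1)) > 1e-10)
    stop("transition matrix must be row-stochastic", call. = FALSE)
  S <- nrow(transition)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cum <- t(apply(transition, 1, cumsum))
  u <- runif(n_steps - 1)
  out <- integer(n_steps)
  out[1] <- start
  for (t in 2:n_steps)
    out[t] <- sum(u[t - 1] > cum[out[t - 1], ]) + 1L
  out
}

#' Per-frame bond-length and dihedral series of a trajectory
#'
#' Vectorized internal-coordinate extraction used for marginal comparisons.
#'
#' @param traj `[S, n, 3]` coordinate array.
#' @param topology a [build_cg_topology()] object.
#' @return Matrix of S rows: one column per bond / per dihedral.
#' @export
bond_length_series <- function(traj, topology) {
  b <- topology$bonds
  out <- sapply(seq_len(nrow(b)), function(q)
    sqrt(rowSums((traj[, b[q, 1], , drop = FALSE] -
                    traj[, b[q, 2], , drop = FALSE])^2, dims = 1)))
  matrix(out, ncol = nrow(b))
}

#' @rdname bond_length_series
#' @export
dihedral_series <- function(traj, topology) {
  q <- topology$dihedrals
  S <- dim(traj)[1]
  vcross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  out <- sapply(seq_len(nrow(q)), function(j) {
    x1 <- matrix(traj[, q[j, 1], ], S, 3); x2 <- matrix(traj[, q[j, 2], ], S, 3)
    x3 <- matrix(traj[, q[j, 3], ], S, 3); x4 <- matrix(traj[, q[j, 4], ], S, 3)
    b1 <- x2 - x1; b2 <- x3 - x2; b3 <- x4 - x3
    A <- vcross(b1, b2); B <- vcross(b2, b3)
    atan2(rowSums(vcross(A, B) * b2) / sqrt(rowSums(b2^2)), rowSums(A * B))
  })
  matrix(out, ncol = nrow(q))
}

#' Mean absolute histogram difference between two samples
#'
#' Both samples are binned on a common range into `bins` equal bins
#' (values outside the range fall in the edge bins); the difference is the
#' mean over bins of the absolute difference of the normalized bin
#' probabilities.
#'
#' @param a,b numeric samples.
#' @param bins bin count.
#' @param range common range (defaults to the joint data range).
#' @return Scalar in `[0, 2/bins * bins]`.
#' @export
histogram_difference <- function(a, b, bins = 24L, range = NULL) {
  if (is.null(range)) range <- base::range(c(a, b))
  br <- seq(range[1], range[2], length.out = bins + 1)
  ha <- graphics::hist(pmin(pmax(a, range[1]), range[2]), breaks = br,
                       plot = FALSE)$counts
  hb <- graphics::hist(pmin(pmax(b, range[1]), range[2]), breaks = br,
                       plot = FALSE)$counts
  mean(abs(ha / sum(ha) - hb / sum(hb)))
}

#' Compare bond and dihedral marginals of two trajectories
#'
#' Per-degree-of-freedom comparison: for every bond and every dihedral the
#' normalized histograms of the two trajectories are compared with
#' [histogram_difference()] and the differences are averaged over the
#' degrees of freedom.  Comparing per dof (rather than pooling) keeps the
#' check sensitive to effects that differ in sign along the chain.
#'
#' @param traj_a,traj_b `[S, n, 3]` coordinate arrays (matched frame counts
#'   recommended; subsample the larger one).
#' @param topology a [build_cg_topology()] object.
#' @param bins histogram bins.
#' @return List with `bond` and `dihedral` mean absolute histogram
#'   differences.
#' @export
compare_marginals <- function(traj_a, traj_b, topology, bins = 24L) {
  ba <- bond_length_series(traj_a, topology)
  bb <- bond_length_series(traj_b, topology)
  bond <- mean(vapply(seq_len(ncol(ba)), function(j)
    histogram_difference(ba[, j], bb[, j], bins), numeric(1)))
  da <- dihedral_series(traj_a, topology)
  db <- dihedral_series(traj_b, topology)
  dihedral <- mean(vapply(seq_len(ncol(da)), function(j)
    histogram_difference(da[, j], db[, j], bins, range = c(-pi, pi)),
    numeric(1)))
  list(bond = bond, dihedral = dihedral)
}

#' Flatten a trajectory ensemble into one coordinate array
#'
#' Concatenates the saved frames of the (stable) replicas, optionally
#' discarding the first fraction of each replica.
#'
#' @param sim a `trajectory_ensemble`.
#' @param drop_frac initial fraction of frames discarded per replica.
#' @return `[S_total, n, 3]` array.
#' @export
ensemble_frames <- function(sim, drop_frac = 0.1) {
  keep <- which(sim$ok)
  mats <- lapply(sim$coords[keep], function(x) {
    d <- floor(dim(x)[1] * drop_frac)
    matrix(x[(d + 1):dim(x)[1], , , drop = FALSE],
           ncol = prod(dim(x)[-1]))
  })
  flat <- do.call(rbind, mats)
  array(flat, c(nrow(flat), dim(sim$coords[[1]])[2], 3))
}
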