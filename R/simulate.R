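#' Simulation protocol
#'
#' CG Langevin protocol defaults: 350 K, 1 fs timestep, output saved every
#' 100 fs, 32 parallel isolated replicas.  The friction coefficient
#' defaults to 0.1 ps^-1; friction affects kinetics but not the sampled
#' equilibrium distribution, which is the quantity of interest here.
#'
#' @param n_steps integration steps per replica.
#' @param temperature K.
#' @param timestep fs.
#' @param friction ps^-1.
#' @param save_interval fs between saved frames.
#' @param n_replicas number of independent replicas.
#' @param seed master seed; each replica derives a child stream.
#' @return Object of class `simulation_protocol`.
#' @export
simulation_protocol <- function(n_steps, temperature = 350, timestep = 1,
                                friction = 0.1, save_interval = 100,
                                n_replicas = 32L, seed = 1L) {
  stopifnot(timestep > 0, friction >= 0, temperature >= 0, n_steps >= 1)
  if (save_interval %% timestep != 0)
    stop("save_interval must be a multiple of the timestep", call. = FALSE)
  structure(list(n_steps = as.integer(n_steps), temperature = temperature,
                 timestep = timestep, friction = friction,
                 save_interval = save_interval,
                 n_replicas = as.integer(n_replicas), seed = as.integer(seed)),
            class = "simulation_protocol")
}

#' One BAOAB Langevin step (reference implementation)
#'
#' Splitting: half kick (B), half drift (A), Ornstein-Uhlenbeck velocity
#' update (O), half drift (A), half kick (B) with re-evaluated forces.
#' Deterministic given the supplied noise matrix.  The production path is
#' the compiled loop inside [run_simulation()]; this single-step version
#' defines the update and backs the integrator tests.
#'
#' @param x n x 3 coordinates (A).
#' @param v n x 3 velocities (A/fs).
#' @param force_fn function(x) returning `list(energy, forces)`.
#' @param masses amu per bead.
#' @param dt timestep, fs.
#' @param friction ps^-1.
#' @param temperature K.
#' @param noise optional n x 3 standard-normal matrix (drawn if NULL).
#' @return List with updated `x`, `v`, `force`, `potential`.
#' @export
langevin_step <- function(x, v, force_fn, masses, dt, friction, temperature,
                          noise = NULL) {
  conv <- 4.184e-4  # (kcal/mol/A)/amu -> A/fs^2
  f <- force_fn(x)
  v <- v + 0.5 * dt * conv * f$forces / masses
  x <- x + 0.5 * dt * v
  c1 <- exp(-friction / 1000 * dt)
  sd_v <- sqrt(kB * temperature * conv / masses)
  if (is.null(noise)) noise <- matrix(rnorm(length(x)), nrow(x), 3)
  v <- c1 * v + sqrt(1 - c1^2) * sd_v * noise
  x <- x + 0.5 * dt * v
  f <- force_fn(x)
  v <- v + 0.5 * dt * conv * f$forces / masses
  list(x = x, v = v, force = f$forces, potential = f$energy)
}

#' Run Langevin CG simulations
#'
#' Integrates `n_replicas` independent, isolated replicas of the combined
#' potential (priors + optional network + optional fixture perturbation)
#' with the BAOAB scheme, saving coordinates and energies every
#' `save_interval`.  Initial velocities are Maxwell-Boltzmann at the
#' protocol temperature.  A replica whose coordinates diverge (beyond
#' 1e4 A) is flagged and frozen while the others continue.
#'
#' @param topology a [build_cg_topology()] object.
#' @param priors a [prior_forcefield()] (or NULL for no prior terms).
#' @param starts list of n x 3 start coordinates, one per replica (a single
#'   matrix is recycled).
#' @param protocol a [simulation_protocol()].
#' @param potential optional trained [gn_potential()] added to the priors.
#' @param perturbation optional fixture perturbation (see
#'   [make_toy_polymer()]).
#' @return Object of class `trajectory_ensemble`: per-replica coordinate
#'   arrays `[n_saved, n, 3]`, potential/kinetic energy matrices
#'   `[n_saved, n_replicas]`, stability flags, final state and the
#'   protocol.
#' @export
run_simulation <- function(topology, priors, starts, protocol,
                           potential = NULL, perturbation = NULL) {
  if (is.matrix(starts))
    starts <- rep(list(starts), protocol$n_replicas)
  if (length(starts) != protocol$n_replicas)
    stop("need one start per replica", call. = FALSE)
  model <- list(
    prior = if (!is.null(priors))
      prior_terms_for_topology(topology, priors) else NULL,
    perturbation = if (!is.null(perturbation)) list(
      pairs = perturbation$pairs - 1L, amp = perturbation$amp,
      center = perturbation$center, width = perturbation$width) else NULL,
    gnn = if (!is.null(potential)) list(
      params = potential$params, config = potential$config,
      z = topology$type_ids) else NULL)
  save_every <- as.integer(round(protocol$save_interval / protocol$timestep))
  out <- run_langevin_cpp(starts, topology$masses, model,
                          protocol$temperature, protocol$timestep,
                          protocol$friction, protocol$n_steps, save_every,
                          protocol$seed, init_velocities = TRUE)
  structure(list(coords = out$coords, potential = out$potential,
                 kinetic = out$kinetic, ok = out$ok,
                 final_coords = out$final_coords,
                 final_velocities = out$final_velocities,
                 protocol = protocol, topology = topology),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory ensemble: %d replicas x %d saved frames (%d beads), %d stable\n",
              length(x$coords), dim(x$coords[[1]])[1], dim(x$coords[[1]])[2],
              sum(x$ok)))
  invisible(x)
}

#' Select starting conformations spread over a 2-D projection
#'
#' Grid-stratified sampling over the projection's bounding box: the box is
#' divided into cells and at most one frame is drawn per occupied cell
#' until `n` are chosen.  If fewer cells are occupied than `n`, the
#' remainder is filled by farthest-point sampling in projection space.
#' Deterministic for a given seed.
#'
#' @param projections m x 2 matrix (e.g. the first two TICs of reference
#'   data).
#' @param n number of starting frames.
#' @param seed RNG seed.
#' @param grid cells per axis (default `ceiling(sqrt(2 n))`).
#' @return Integer vector of `n` distinct frame indices.
#' @export
select_starting_points <- function(projections, n, seed = 1L, grid = NULL) {
  stopifnot(ncol(projections) >= 2, n >= 1, nrow(projections) >= n)
  pr <- projections[, 1:2, drop = FALSE]
  if (is.null(grid)) grid <- ceiling(sqrt(2 * n))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cut2 <- function(x) pmin(pmax(findInterval(
    x, seq(min(x), max(x), length.out = grid + 1), all.inside = TRUE), 1), grid)
  cell <- (cut2(pr[, 1]) - 1L) * grid + cut2(pr[, 2])
  picks <- integer(0)
  occupied <- split(seq_len(nrow(pr)), cell)
  occupied <- occupied[sample(length(occupied))]
  for (cl in occupied) {
    if (length(picks) >= n) break
    picks <- c(picks, if (length(cl) == 1) cl else sample(cl, 1))
  }
  while (length(picks) < n) {  # farthest-point fallback
    rest <- setdiff(seq_len(nrow(pr)), picks)
    dmin <- vapply(rest, function(i)
      min(sqrt(rowSums((pr[picks, , drop = FALSE] -
                          matrix(pr[i, ], length(picks), 2,
                                 byrow = TRUE))^2))), numeric(1))
    picks <- c(picks, rest[which.max(dmin)])
  }
  picks[seq_len(n)]
}
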