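#' Prior energy terms
#'
#' The prior potential bounds the configuration space accessible to the CG
#' model and carries basic physics, so the network only needs to learn the
#' residual (delta-learning).  Three terms are used: a harmonic bond
#' `V(r) = k (r - r0)^2 + V0` between consecutive beads, a pairwise
#' repulsion `V(r) = 4 eps r^-6 + V0` over non-excluded pairs, and a global
#' cosine dihedral `V(phi) = sum_n k_n (1 + cos(n phi - gamma_n))` over
#' every four consecutive beads, whose phase offsets break mirror symmetry
#' and so enforce chirality.
#'
#' @param r distance(s), A (must be > 0).
#' @param k spring constant, kcal/mol/A^2.
#' @param r0 equilibrium distance, A.
#' @param v0 base potential, kcal/mol.
#' @return A list with `energy` (kcal/mol) and `deriv` (dV/dr, kcal/mol/A),
#'   vectorized over `r` (or `phi`).
#' @name prior_terms
NULL

#' @rdname prior_terms
#' @export
bonded_energy_force <- function(r, k, r0, v0 = 0) {
  if (any(r <= 0)) stop("bond distance must be positive", call. = FALSE)
  list(energy = k * (r - r0)^2 + v0, deriv = 2 * k * (r - r0))
}

#' @rdname prior_terms
#' @param epsilon repulsion strength, kcal/mol A^6.
#' @export
repulsive_energy_force <- function(r, epsilon, v0 = 0) {
  if (any(r <= 0)) stop("pair distance must be positive", call. = FALSE)
  list(energy = 4 * epsilon * r^-6 + v0, deriv = -24 * epsilon * r^-7)
}

#' @rdname prior_terms
#' @param phi dihedral angle(s), rad; wrapped into (-pi, pi].
#' @param gamma phase offsets, rad (one per periodicity).
#' @param n periodicities matching `k` (default 1, 2).
#' @export
dihedral_energy_force <- function(phi, k, gamma, n = seq_along(k)) {
  stopifnot(length(k) == length(gamma), length(k) == length(n))
  phi <- wrap_angle(phi)
  energy <- deriv <- numeric(length(phi))
  for (t in seq_along(k)) {
    energy <- energy + k[t] * (1 + cos(n[t] * phi - gamma[t]))
    deriv <- deriv - n[t] * k[t] * sin(n[t] * phi - gamma[t])
  }
  list(energy = energy, deriv = deriv)
}

wrap_angle <- function(phi) {
  w <- (phi + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: 0 for a planar cis arrangement, pi for trans;
#' mirror-image coordinates give the negated angle.
#'
#' @param x1,x2,x3,x4 numeric 3-vectors.
#' @return Angle in (-pi, pi].
#' @export
dihedral_angle <- function(x1, x2, x3, x4) {
  b1 <- x2 - x1; b2 <- x3 - x2; b3 <- x4 - x3
  A <- cross3(b1, b2); B <- cross3(b2, b3)
  if (sum(A^2) < 1e-18 || sum(B^2) < 1e-18)
    stop("dihedral undefined: collinear triple of beads", call. = FALSE)
  atan2(sum(cross3(A, B) * b2) / sqrt(sum(b2^2)), sum(A * B))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angles of consecutive-bead quadruples
#'
#' @param coords n x 3 coordinate matrix.
#' @param quads q x 4 matrix of 1-based bead indices.
#' @return Numeric vector of signed angles, rad.
#' @export
dihedral_angles <- function(coords, quads) {
  apply(quads, 1, function(q)
    dihedral_angle(coords[q[1], ], coords[q[2], ], coords[q[3], ],
                   coords[q[4], ]))
}

#' Prior force field container
#'
#' @param bonds named list: per bead-type pair key `"TYP1-TYP2"` a list with
#'   `k` (kcal/mol/A^2), `r0` (A), `v0` (kcal/mol).  A `default` entry is
#'   used for pairs without explicit parameters.
#' @param repulsion named list: per unordered type-pair key (or `default`) a
#'   list with `epsilon` (kcal/mol A^6) and `v0`.
#' @param dihedral list with element `terms`: a list of
#'   `list(n = , k = , gamma = )`; one global parameter set shared by all
#'   quadruples.
#' @param exclusions integer vector of neighbor offsets excluded from the
#'   repulsive term (default 1: bonded pairs).
#' @return Object of class `prior_forcefield`.
#' @export
prior_forcefield <- function(bonds = list(default = list(k = 10, r0 = 3.8, v0 = 0)),
                             repulsion = list(default = list(epsilon = 1, v0 = 0)),
                             dihedral = list(terms = list(
                               list(n = 1, k = 0, gamma = 0),
                               list(n = 2, k = 0, gamma = 0))),
                             exclusions = 1L) {
  for (b in bonds) stopifnot(b$k >= 0, b$r0 > 0)
  for (p in repulsion) stopifnot(p$epsilon >= 0)
  structure(list(bonds = bonds, repulsion = repulsion, dihedral = dihedral,
                 exclusions = as.integer(exclusions)),
            class = "prior_forcefield")
}

#' @export
print.prior_forcefield <- function(x, ...) {
  cat(sprintf("Prior force field: %d bond entries, %d repulsion entries, %d dihedral terms; exclusions: offsets %s\n",
              length(x$bonds), length(x$repulsion),
              length(x$dihedral$terms),
              paste(x$exclusions, collapse = ",")))
  invisible(x)
}

pair_key <- function(a, b) paste(a, b, sep = "-")

lookup_pair <- function(table, a, b, what) {
  for (key in c(pair_key(a, b), pair_key(b, a))) {
    if (!is.null(table[[key]])) return(table[[key]])
  }
  # norleucine parameters are adapted from leucine when not fitted directly
  if (a == "NLE" || b == "NLE") {
    a2 <- if (a == "NLE") "LEU" else a
    b2 <- if (b == "NLE") "LEU" else b
    for (key in c(pair_key(a2, b2), pair_key(b2, a2))) {
      if (!is.null(table[[key]])) return(table[[key]])
    }
  }
  if (!is.null(table[["default"]])) return(table[["default"]])
  stop(sprintf("no %s parameters for type pair %s-%s", what, a, b),
       call. = FALSE)
}

# Assemble flat per-term parameter arrays for the C++ evaluator.
prior_terms_for_topology <- function(topology, ff) {
  stopifnot(inherits(topology, "cg_topology"), inherits(ff, "prior_forcefield"))
  rn <- topology$residue_names
  rn[rn %in% names(attr(bead_vocabulary(), "aliases"))] <-
    attr(bead_vocabulary(), "aliases")[rn[rn %in% names(attr(bead_vocabulary(), "aliases"))]]
  bonds <- topology$bonds
  bk <- br0 <- bv0 <- numeric(nrow(bonds))
  for (i in seq_len(nrow(bonds))) {
    p <- lookup_pair(ff$bonds, rn[bonds[i, 1]], rn[bonds[i, 2]], "bond")
    bk[i] <- p$k; br0[i] <- p$r0; bv0[i] <- p$v0 %||% 0
  }
  # repulsion acts on all pairs not excluded by the force field's offsets
  # or the topology's explicit exclusion pairs
  top2 <- topology
  offs <- unique(c(topology$exclusion_offsets, ff$exclusions))
  n <- topology$n_beads
  excl <- do.call(rbind, c(list(matrix(integer(0), ncol = 2)),
                           lapply(offs[offs >= 1 & offs < n], function(o)
                             cbind(seq_len(n - o), seq_len(n - o) + o))))
  top2$exclusion_pairs <- rbind(topology$exclusion_pairs, excl)
  pairs <- repulsion_pairs(top2)
  pe <- pv0 <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    p <- lookup_pair(ff$repulsion, rn[pairs[i, 1]], rn[pairs[i, 2]],
                     "repulsion")
    pe[i] <- p$epsilon; pv0[i] <- p$v0 %||% 0
  }
  terms <- ff$dihedral$terms
  list(bonds = bonds - 1L, bond_k = bk, bond_r0 = br0, bond_v0 = bv0,
       pairs = pairs - 1L, pair_eps = pe, pair_v0 = pv0,
       quads = topology$dihedrals - 1L,
       dih_k = vapply(terms, `[[`, numeric(1), "k"),
       dih_gamma = vapply(terms, `[[`, numeric(1), "gamma"),
       dih_n = vapply(terms, `[[`, numeric(1), "n"))
}

#' Total prior energy and forces of a configuration
#'
#' Sums the bonded term over bonds, the repulsive term over all non-excluded
#' pairs and the dihedral term over consecutive quadruples; forces are the
#' exact negative gradient of the implemented sum.
#'
#' @param coords n x 3 coordinate matrix (A).
#' @param topology a [build_cg_topology()] object.
#' @param ff a [prior_forcefield()].
#' @return List with `energy` (kcal/mol) and `forces` (n x 3, kcal/mol/A).
#' @export
prior_energy_forces <- function(coords, topology, ff) {
  stopifnot(nrow(coords) == topology$n_beads, ncol(coords) == 3)
  prior_eval_cpp(coords, prior_terms_for_topology(topology, ff))
}

# ---- Boltzmann inversion ---------------------------------------------------

inversion_profile <- function(samples, bins, range = NULL) {
  if (length(samples) == 0) stop("empty histogram", call. = FALSE)
  if (is.null(range)) range <- c(min(samples), max(samples))
  h <- graphics::hist(samples[samples >= range[1] & samples <= range[2]],
                      breaks = seq(range[1], range[2], length.out = bins + 1),
                      plot = FALSE)
  keep <- h$counts > 0
  if (!any(keep)) stop("empty histogram", call. = FALSE)
  list(x = h$mids[keep], p = h$density[keep], counts = h$counts[keep])
}

#' Boltzmann inversion of bond-length samples
#'
#' Fits the harmonic bond form to `-kB T log p(r)` by least squares on a
#' 64-bin histogram over mean +/- 4 sd.
#'
#' @param samples bond-length samples (A).
#' @param temperature K.
#' @param bins histogram bin count.
#' @return List with `k`, `r0`, `v0 = 0`.
#' @export
fit_bond_inversion <- function(samples, temperature, bins = 64) {
  m <- mean(samples); s <- stats::sd(samples)
  pr <- inversion_profile(samples, bins, c(m - 4 * s, m + 4 * s))
  y <- -kB * temperature * log(pr$p)
  fit <- stats::lm(y ~ x + I(x^2), data = data.frame(x = pr$x),
                   weights = pr$counts)
  k <- coef(fit)[[3]]
  if (!is.finite(k) || k <= 0)
    stop("bond histogram is not convex; cannot invert", call. = FALSE)
  list(k = k, r0 = -coef(fit)[[2]] / (2 * k), v0 = 0)
}

#' Boltzmann inversion of nonbonded short-range distances
#'
#' Fits `4 eps r^-6` to `-kB T log p(r)` on the rising left shoulder of the
#' distance distribution (bins strictly below the mode).
#'
#' @inheritParams fit_bond_inversion
#' @return List with `epsilon`, `v0 = 0`.
#' @export
fit_repulsion_inversion <- function(samples, temperature, bins = 64) {
  pr <- inversion_profile(samples, bins)
  mode_i <- which.max(pr$p)
  if (mode_i < 3) stop("no rising shoulder below the distance mode",
                       call. = FALSE)
  x <- pr$x[seq_len(mode_i - 1)]
  y <- -kB * temperature * log(pr$p[seq_len(mode_i - 1)])
  fit <- stats::lm(y ~ I(x^-6), weights = pr$counts[seq_len(mode_i - 1)])
  list(epsilon = max(coef(fit)[[2]] / 4, 0), v0 = 0)
}

#' Boltzmann inversion of pooled dihedral angles
#'
#' Fits the two-term cosine series to `-kB T log p(phi)` by linear least
#' squares in the `(k_n cos gamma_n, k_n sin gamma_n)` basis, then converts
#' to amplitude/phase.  The returned amplitudes are the fitted values
#' multiplied by 0.5 (a soft prior that breaks mirror symmetry without
#' dominating the potential); the unhalved fit is kept in the
#' `unhalved` attribute.
#'
#' @param angles dihedral samples, rad.
#' @inheritParams fit_bond_inversion
#' @return List with element `terms` (two `list(n, k, gamma)` entries).
#' @export
fit_dihedral_inversion <- function(angles, temperature, bins = 64) {
  pr <- inversion_profile(angles, bins, c(-pi, pi))
  y <- -kB * temperature * log(pr$p)
  X <- cbind(cos(pr$x), sin(pr$x), cos(2 * pr$x), sin(2 * pr$x))
  fit <- stats::lm(y ~ X, weights = pr$counts)
  cf <- coef(fit)[-1]
  # V = sum k_n (1 + cos(n phi - gamma_n))
  #   = const + k_n cos(gamma_n) cos(n phi) + k_n sin(gamma_n) sin(n phi)
  terms <- lapply(1:2, function(n) {
    a <- cf[[2 * n - 1]]; b <- cf[[2 * n]]
    list(n = n, k = sqrt(a^2 + b^2), gamma = atan2(b, a))
  })
  halved <- lapply(terms, function(t) { t$k <- 0.5 * t$k; t })
  structure(list(terms = halved), unhalved = list(terms = terms))
}

#' Fit prior parameters from a frame dataset by Boltzmann inversion
#'
#' Builds histograms of bond lengths per bead-type pair, non-excluded pair
#' distances per type pair, and pooled dihedral angles from the mapped
#' frames, and inverts each against its prior functional form at the dataset
#' temperature.  Dihedral amplitudes are halved (soft prior); norleucine
#' repulsion parameters are adapted from leucine.  Type pairs with fewer
#' than `min_samples` distance observations fall back to a pooled fit stored
#' under the `default` key.
#'
#' @param frames a [frame_dataset()]; all systems are pooled.
#' @param topologies a `cg_topology` or named list of them (one per system).
#' @param temperature K; defaults to the dataset temperature.
#' @param bins histogram bin count.
#' @param min_samples minimum per-pair sample count before falling back to
#'   the pooled default.
#' @return A [prior_forcefield()].
#' @export
fit_priors <- function(frames, topologies, temperature = frames$temperature,
                       bins = 64, min_samples = 200) {
  stopifnot(inherits(frames, "frame_dataset"))
  if (inherits(topologies, "cg_topology"))
    topologies <- stats::setNames(rep(list(topologies), length(frames$systems)),
                                  names(frames$systems))
  bond_samples <- list(); rep_samples <- list(); dihedrals <- numeric(0)
  excl_offsets <- 1L
  for (nm in names(frames$systems)) {
    top <- topologies[[nm]]
    excl_offsets <- union(excl_offsets, top$exclusion_offsets)
    X <- frames$systems[[nm]]$coords
    rn <- top$residue_names
    for (b in seq_len(nrow(top$bonds))) {
      i <- top$bonds[b, 1]; j <- top$bonds[b, 2]
      key <- pair_key(sort(c(rn[i], rn[j]))[1], sort(c(rn[i], rn[j]))[2])
      d <- sqrt(rowSums((X[, i, , drop = FALSE] - X[, j, , drop = FALSE])^2,
                        dims = 1))
      bond_samples[[key]] <- c(bond_samples[[key]], d)
    }
    rp <- repulsion_pairs(top)
    for (p in seq_len(nrow(rp))) {
      i <- rp[p, 1]; j <- rp[p, 2]
      key <- pair_key(sort(c(rn[i], rn[j]))[1], sort(c(rn[i], rn[j]))[2])
      d <- sqrt(rowSums((X[, i, , drop = FALSE] - X[, j, , drop = FALSE])^2,
                        dims = 1))
      rep_samples[[key]] <- c(rep_samples[[key]], d)
    }
    if (nrow(top$dihedrals) > 0) {
      for (f in seq_len(dim(X)[1]))
        dihedrals <- c(dihedrals, dihedral_angles(X[f, , ], top$dihedrals))
    }
  }
  if (length(bond_samples) == 0) stop("empty histogram", call. = FALSE)
  bonds <- lapply(bond_samples, fit_bond_inversion, temperature = temperature,
                  bins = bins)
  bonds$default <- fit_bond_inversion(unlist(bond_samples), temperature, bins)
  repulsion <- list(default =
    fit_repulsion_inversion(unlist(rep_samples), temperature, bins))
  for (key in names(rep_samples)) {
    if (length(rep_samples[[key]]) >= min_samples)
      repulsion[[key]] <- tryCatch(
        fit_repulsion_inversion(rep_samples[[key]], temperature, bins),
        error = function(e) repulsion$default)
  }
  dihedral <- if (length(dihedrals) > 0)
    fit_dihedral_inversion(dihedrals, temperature, bins)
  else list(terms = list(list(n = 1, k = 0, gamma = 0),
                         list(n = 2, k = 0, gamma = 0)))
  prior_forcefield(bonds = bonds, repulsion = repulsion, dihedral = dihedral,
                   exclusions = sort(excl_offsets))
}

#' Write or read a prior force field as YAML
#'
#' Top-level keys: `bonds` (per `"TYP1-TYP2"` pair: k, r0, V0), `repulsion`
#' (per pair: epsilon, V0), `dihedrals` (`terms` list), `exclusions`
#' (neighbor offsets), and a `units` block.
#'
#' @param ff a [prior_forcefield()].
#' @param path file path.
#' @return `read_forcefield` returns a [prior_forcefield()].
#' @export
write_forcefield <- function(ff, path) {
  yaml::write_yaml(list(
    units = list(length = "angstrom", energy = "kcal/mol"),
    bonds = lapply(ff$bonds, function(b)
      list(k = b$k, r0 = b$r0, V0 = b$v0 %||% 0)),
    repulsion = lapply(ff$repulsion, function(p)
      list(epsilon = p$epsilon, V0 = p$v0 %||% 0)),
    dihedrals = list(terms = lapply(ff$dihedral$terms, function(t)
      list(n = t$n, k = t$k, gamma = t$gamma))),
    exclusions = as.list(ff$exclusions)), path)
  invisible(path)
}

#' @rdname write_forcefield
#' @export
read_forcefield <- function(path) {
  y <- yaml::read_yaml(path)
  prior_forcefield(
    bonds = lapply(y$bonds, function(b) list(k = b$k, r0 = b$r0, v0 = b$V0)),
    repulsion = lapply(y$repulsion, function(p)
      list(epsilon = p$epsilon, v0 = p$V0)),
    dihedral = list(terms = y$dihedrals$terms),
    exclusions = unlist(y$exclusions))
}
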