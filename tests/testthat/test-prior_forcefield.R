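test_that("analytic prior terms match their closed forms and derivatives", {
  b <- bonded_energy_force(3.8, k = 10, r0 = 3.8)
  expect_equal(b$energy, 0)
  expect_equal(b$deriv, 0)
  expect_equal(bonded_energy_force(4.0, 10, 3.8)$energy, 0.4)
  expect_equal(repulsive_energy_force(1, epsilon = 1)$energy, 4)
  expect_equal(repulsive_energy_force(2, epsilon = 1)$energy, 0.0625)
  d <- dihedral_energy_force(0, k = c(1, 0), gamma = c(0, 0))
  expect_equal(d$energy, 2)
  expect_equal(dihedral_energy_force(pi, c(1, 0), c(0, 0))$energy, 0,
               tolerance = 1e-12)
  expect_equal(dihedral_energy_force(pi, c(0, 1), c(0, 0), n = c(1, 2))$energy,
               2)
  # phase offset breaks mirror symmetry (the chirality mechanism)
  expect_false(isTRUE(all.equal(
    dihedral_energy_force(1, k = c(1, 0), gamma = c(0.7, 0))$energy,
    dihedral_energy_force(-1, k = c(1, 0), gamma = c(0.7, 0))$energy)))
  expect_error(bonded_energy_force(-1, 10, 3.8), "positive")
  expect_error(repulsive_energy_force(0, 1), "positive")

  # every analytic derivative matches the central finite difference
  h <- 1e-4
  for (r in c(2.5, 3.8, 5.1)) {
    fd <- (bonded_energy_force(r + h, 7, 3.6, 0.2)$energy -
             bonded_energy_force(r - h, 7, 3.6, 0.2)$energy) / (2 * h)
    expect_equal(bonded_energy_force(r, 7, 3.6, 0.2)$deriv, fd,
                 tolerance = 1e-6)
    fd <- (repulsive_energy_force(r + h, 2)$energy -
             repulsive_energy_force(r - h, 2)$energy) / (2 * h)
    expect_equal(repulsive_energy_force(r, 2)$deriv, fd, tolerance = 1e-6)
  }
  for (phi in c(-2.1, 0.3, 2.9)) {
    fd <- (dihedral_energy_force(phi + h, c(0.8, 0.4), c(0.7, -0.5))$energy -
             dihedral_energy_force(phi - h, c(0.8, 0.4), c(0.7, -0.5))$energy) /
      (2 * h)
    expect_equal(dihedral_energy_force(phi, c(0.8, 0.4), c(0.7, -0.5))$deriv,
                 fd, tolerance = 1e-6)
  }
})

test_that("dihedral geometry follows the IUPAC sign convention", {
  cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(dihedral_angle(cis[1, ], cis[2, ], cis[3, ], cis[4, ]), 0)
  expect_equal(abs(dihedral_angle(trans[1, ], trans[2, ], trans[3, ],
                                  trans[4, ])), pi)
  for (s in 1:5) {
    set.seed(s)
    Q <- matrix(rnorm(12), 4, 3)
    phi <- dihedral_angle(Q[1, ], Q[2, ], Q[3, ], Q[4, ])
    Qm <- mirror_coords(Q)
    expect_equal(dihedral_angle(Qm[1, ], Qm[2, ], Qm[3, ], Qm[4, ]), -phi)
  }
  col <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(dihedral_angle(col[1, ], col[2, ], col[3, ], col[4, ]),
               "collinear")
})

test_that("total prior energy/forces match an independent double-loop oracle", {
  top <- build_cg_topology(rep(c("ALA", "GLY", "LEU", "SER"), 2))
  ff <- prior_forcefield(
    bonds = list(default = list(k = 10, r0 = 3.8, v0 = 0)),
    repulsion = list(default = list(epsilon = 1, v0 = 0)),
    dihedral = list(terms = list(list(n = 1, k = 0.8, gamma = 0.7),
                                 list(n = 2, k = 0.4, gamma = -0.5))))
  X <- chain_coords(8, seed = 2)
  out <- prior_energy_forces(X, top, ff)
  expect_equal(out$energy, prior_energy_oracle(X, top, ff), tolerance = 1e-10)
  # forces are the exact negative gradient
  num <- fd_forces(function(x) prior_energy_forces(x, top, ff)$energy, X)
  expect_lt(max(abs(num - out$forces)) / max(abs(out$forces)), 1e-6)
  # internal forces: zero net force and torque
  expect_lt(max(abs(colSums(out$forces))), 1e-8)
  torque <- colSums(t(vapply(seq_len(8), function(i)
    cgfold:::cross3(X[i, ], out$forces[i, ]), numeric(3))))
  expect_lt(max(abs(torque)), 1e-8)
  # rigid-motion invariance of the energy
  R <- random_rotation(3)
  expect_equal(prior_energy_forces(X %*% R + matrix(c(1, -2, 3), 8, 3,
                                                    byrow = TRUE),
                                   top, ff)$energy, out$energy,
               tolerance = 1e-10)
})

test_that("two bonded beads at r0 have zero energy and force", {
  top <- build_cg_topology(c("ALA", "ALA"))
  ff <- prior_forcefield(bonds = list(default = list(k = 10, r0 = 3.8, v0 = 0)),
                         repulsion = list(default = list(epsilon = 1, v0 = 0)))
  out <- prior_energy_forces(rbind(c(0, 0, 0), c(3.8, 0, 0)), top, ff)
  expect_equal(out$energy, 0)
  expect_equal(max(abs(out$forces)), 0)
})

test_that("excluded pairs contribute zero repulsive energy", {
  res <- rep(c("ALA", "GLY", "LEU"), 2)
  ff <- prior_forcefield(repulsion = list(default = list(epsilon = 2, v0 = 0)),
                         dihedral = list(terms = list(list(n = 1, k = 0,
                                                           gamma = 0))))
  top1 <- build_cg_topology(res, exclusion_offsets = 1L)
  top13 <- build_cg_topology(res, exclusion_offsets = c(1L, 3L))
  X <- chain_coords(6, seed = 5)
  v1 <- prior_energy_forces(X, top1, ff)$energy
  v13 <- prior_energy_forces(X, top13, ff)$energy
  # unexcluded sum minus the explicit pair terms
  off3 <- sum(vapply(seq_len(3), function(i)
    repulsive_energy_force(sqrt(sum((X[i, ] - X[i + 3, ])^2)), 2)$energy,
    numeric(1)))
  expect_equal(v13, v1 - off3, tolerance = 1e-12)
})

test_that("missing pair parameters raise a named error", {
  top <- build_cg_topology(c("ALA", "TRP", "GLY"))
  ff <- prior_forcefield(bonds = list(`ALA-TRP` = list(k = 1, r0 = 3.8,
                                                       v0 = 0)))
  ff$bonds$default <- NULL
  expect_error(prior_energy_forces(chain_coords(3), top, ff), "TRP-GLY")
})

test_that("Boltzmann inversion recovers known parameters", {
  set.seed(10)
  # harmonic bond at 350 K: p(r) ~ exp(-k (r-r0)^2 / kBT)
  kT <- boltzmann_kcal() * 350
  r <- rnorm(50000, mean = 3.8, sd = sqrt(kT / (2 * 10)))
  fit <- fit_bond_inversion(r, temperature = 350)
  expect_lt(abs(fit$k - 10) / 10, 0.1)
  expect_lt(abs(fit$r0 - 3.8), 0.05)
  # uniform dihedral samples give near-zero amplitudes
  ang <- runif(50000, -pi, pi)
  flat <- fit_dihedral_inversion(ang, temperature = 350)
  expect_true(all(vapply(flat$terms, `[[`, numeric(1), "k") < 0.05))
  # returned amplitudes are exactly half the unhalved least-squares fit
  spec <- toy_spec()
  ref <- toy_reference_small()
  ffit <- fit_priors(ref, spec$topology)
  un <- attr(ffit$dihedral, "unhalved")
  expect_equal(vapply(ffit$dihedral$terms, `[[`, numeric(1), "k"),
               0.5 * vapply(un$terms, `[[`, numeric(1), "k"))
  # fitted bond parameters near the generating values
  expect_lt(abs(ffit$bonds$default$k - 10) / 10, 0.15)
  expect_lt(abs(ffit$bonds$default$r0 - 3.8), 0.05)
  expect_error(fit_bond_inversion(numeric(0), 350), "empty histogram")
})

test_that("force-field YAML round-trips", {
  ff <- prior_forcefield(
    bonds = list(`ALA-GLY` = list(k = 9.5, r0 = 3.79, v0 = 0),
                 default = list(k = 10, r0 = 3.8, v0 = 0)),
    repulsion = list(default = list(epsilon = 1.2, v0 = 0)),
    dihedral = list(terms = list(list(n = 1, k = 0.4, gamma = 0.65),
                                 list(n = 2, k = 0.2, gamma = -0.5))),
    exclusions = c(1L, 2L))
  path <- tempfile(fileext = ".yaml")
  write_forcefield(ff, path)
  back <- read_forcefield(path)
  expect_equal(back$bonds$`ALA-GLY`$k, 9.5)
  expect_equal(back$repulsion$default$epsilon, 1.2)
  expect_equal(back$dihedral$terms[[2]]$gamma, -0.5)
  expect_identical(back$exclusions, c(1L, 2L))
})
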