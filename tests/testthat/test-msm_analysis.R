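test_that("pairwise-distance features match the all-pairs oracle", {
  x <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  f <- featurize_pairwise_distances(x)
  expect_equal(dim(f), c(1L, 3L))
  expect_equal(as.numeric(f), c(3, 4, 5))  # (1,2), (1,3), (2,3)
  set.seed(31)
  arr <- array(rnorm(5 * 6 * 3), c(5, 6, 3))
  ff <- featurize_pairwise_distances(arr)
  expect_equal(ncol(ff), 15)
  for (fr in 1:5) {
    k <- 0
    for (i in 1:5) for (j in (i + 1):6) {
      k <- k + 1
      expect_equal(ff[fr, k], sqrt(sum((arr[fr, i, ] - arr[fr, j, ])^2)))
    }
  }
  # rigid-motion invariance
  R <- random_rotation(32)
  xr <- x %*% R + matrix(c(5, -1, 2), 3, 3, byrow = TRUE)
  expect_equal(featurize_pairwise_distances(xr), f, tolerance = 1e-12)
})

test_that("TICA extracts the slow component of AR(1) mixtures", {
  set.seed(33)
  n <- 1e5
  ar1 <- function(phi) {
    x <- numeric(n)
    for (t in 2:n) x[t] <- phi * x[t - 1] + rnorm(1)
    x
  }
  X <- cbind(ar1(0.9), ar1(0.1))
  m <- fit_tica(X, lag = 5, dim = 2)
  v <- m$components[, 1]
  expect_gt(abs(v[1]) / sqrt(sum(v^2)), 0.99)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))       # sorted descending
  expect_true(all(m$eigenvalues <= 1 + 1e-6))          # autocorrelation bound
  # components orthonormal in the C0 metric
  G <- t(m$components) %*% m$C0 %*% m$components
  expect_equal(G, diag(nrow(G)), tolerance = 1e-6)
  # frozen-model projection of the training data equals direct output
  pr <- project_tica(m, X)
  m2 <- fit_tica(X, lag = 5, dim = 2)
  expect_lt(max(abs(pr - project_tica(m2, X))), 1e-8)
})

test_that("k-means discretization is seeded and sensible", {
  set.seed(34)
  blobs <- rbind(matrix(rnorm(200, -5), 100, 2), matrix(rnorm(200, 5), 100, 2))
  cl <- cluster_microstates(blobs, k = 2, seed = 1)
  lab <- cl$dtrajs[[1]]
  expect_length(unique(lab[1:100]), 1)
  expect_length(unique(lab[101:200]), 1)
  expect_false(lab[1] == lab[101])
  expect_identical(cl$dtrajs, cluster_microstates(blobs, k = 2, seed = 1)$dtrajs)
  # inertia no worse than a random assignment
  rand_inertia <- sum((blobs - colMeans(blobs)[col(blobs)])^2) / 2
  expect_lt(cl$inertia, rand_inertia)
})

test_that("reversible MSM recovers the two-state stationary vector", {
  Tm <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  d <- make_markov_fixture(Tm, 1e6, seed = 1)
  m <- estimate_msm(d, lag = 1)
  expect_lt(max(abs(rowSums(m$transition) - 1)), 1e-12)
  expect_true(all(m$transition >= 0))
  expect_lt(max(abs(m$pi - c(2 / 3, 1 / 3))), 0.01)
  expect_lt(max(abs(m$pi %*% m$transition - m$pi)), 1e-10)
})

test_that("three-state chain stationary vector is recovered end to end", {
  T3 <- rbind(c(0.90, 0.05, 0.05),
              c(0.10, 0.85, 0.05),
              c(0.05, 0.10, 0.85))
  pi_true <- Re(eigen(t(T3))$vectors[, 1])
  pi_true <- pi_true / sum(pi_true)
  d <- make_markov_fixture(T3, 1e6, seed = 2)
  m <- estimate_msm(d, lag = 1)
  expect_lt(max(abs(m$pi - pi_true)), 0.02)
})

test_that("disconnected states are dropped to the largest component", {
  d <- c(rep(c(1L, 2L), 500), rep(3L, 3))   # state 3 nearly unvisited
  d[length(d)] <- 3L
  m <- estimate_msm(list(rep(c(1L, 2L), 500), rep(3L, 5)), lag = 1)
  expect_identical(m$states, c(1L, 2L))
  expect_identical(m$dropped, 3L)
})

test_that("PCCA+ recovers planted block structure", {
  Tb <- rbind(c(0.45, 0.45, 0.05, 0.05),
              c(0.45, 0.45, 0.05, 0.05),
              c(0.05, 0.05, 0.45, 0.45),
              c(0.05, 0.05, 0.45, 0.45))
  d <- make_markov_fixture(Tb, 2e5, seed = 3)
  m <- estimate_msm(d, lag = 1)
  p <- pcca_macrostates(m, 2)
  expect_identical(p$labels[1], p$labels[2])
  expect_identical(p$labels[3], p$labels[4])
  expect_false(p$labels[1] == p$labels[3])
  expect_equal(sum(p$probabilities), 100, tolerance = 1e-6)
  # m equal to microstate count gives the identity partition
  pid <- pcca_macrostates(m, 4)
  expect_length(unique(pid$labels), 4)
})

test_that("free-energy differences follow bin weight ratios exactly", {
  mm <- structure(list(states = c(1L, 2L), pi = c(2 / 3, 1 / 3)),
                  class = "markov_model")
  proj <- cbind(c(rep(0.1, 20), rep(0.9, 10)), 0.5)
  dtr <- c(rep(1L, 20), rep(2L, 10))
  fes <- free_energy_surface(proj, dtr, mm, temperature = 350, bins = 2)
  occ <- fes$free_energy[!is.na(fes$free_energy)]
  expect_equal(min(occ), 0)
  expect_equal(max(occ) - min(occ), boltzmann_kcal() * 350 * log(2),
               tolerance = 1e-10)
  # single occupied bin sits at zero; default grid is 80 x 80
  one <- free_energy_surface(cbind(rep(0, 5), 0), rep(1L, 5),
                             structure(list(states = 1L, pi = 1),
                                       class = "markov_model"), 350)
  expect_equal(dim(one$free_energy), c(80L, 80L))
  expect_equal(sum(!is.na(one$free_energy)), 1)
  expect_equal(min(one$free_energy, na.rm = TRUE), 0)
})

test_that("Kabsch RMSD is a superposition pseudometric", {
  set.seed(36)
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd_kabsch(X, X), 0)
  R <- random_rotation(37)
  expect_lt(rmsd_kabsch(X, X %*% R + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)),
            1e-10)
  # independent oracle: bio3d's fitted RMSD
  Y <- X + matrix(rnorm(30, sd = 0.5), 10, 3)
  ref <- bio3d::rmsd(as.vector(t(X)), as.vector(t(Y)), fit = TRUE)
  expect_equal(rmsd_kabsch(X, Y), ref, tolerance = 1e-3)
  # symmetry and triangle inequality on random triples
  for (s in 1:5) {
    set.seed(400 + s)
    A <- matrix(rnorm(30), 10, 3); B <- matrix(rnorm(30), 10, 3)
    C <- matrix(rnorm(30), 10, 3)
    expect_equal(rmsd_kabsch(A, B), rmsd_kabsch(B, A), tolerance = 1e-10)
    expect_lte(rmsd_kabsch(A, C), rmsd_kabsch(A, B) + rmsd_kabsch(B, C) + 1e-10)
  }
})

test_that("native macrostate follows the minimum-RMSD frame with tie rule", {
  macro <- c(1L, 2L, 2L, 3L, 1L)
  rmsd <- c(2.0, 1.5, 0.4, 1.0, 3.0)
  expect_identical(identify_native_macrostate(macro, rmsd), 2L)
  expect_identical(identify_native_macrostate(rep(4L, 3), c(1, 2, 3)), 4L)
  # ties broken towards the lower macrostate index
  expect_identical(identify_native_macrostate(c(3L, 1L), c(0.5, 0.5)), 1L)
})

test_that("energy ranking of macrostates is stable and shift-invariant", {
  macro <- c(1L, 1L, 2L, 2L, 3L)
  en <- c(-5, -5, -1, -1, -3)
  r <- rank_macrostates_by_energy(macro, en)
  expect_identical(as.integer(r), c(1L, 3L, 2L))
  expect_identical(as.integer(rank_macrostates_by_energy(macro, en + 100)),
                   c(1L, 3L, 2L))
  # equal means: stable order by index
  expect_identical(as.integer(rank_macrostates_by_energy(c(1L, 2L), c(1, 1))),
                   c(1L, 2L))
  r2 <- rank_macrostates_by_energy(c(1L, 1L, 3L), c(1, 2, 0), m = 3)
  expect_identical(attr(r2, "excluded"), 2L)
})

test_that("bootstrap report aggregates a full pipeline", {
  # synthetic two-well trajectories of a 4-bead chain: bistable dihedral
  top <- build_cg_topology(c("ALA", "GLY", "LEU", "SER"),
                           exclusion_offsets = c(1L, 3L))
  ff <- prior_forcefield(
    bonds = list(default = list(k = 10, r0 = 3.8, v0 = 0)),
    repulsion = list(default = list(epsilon = 1, v0 = 0)),
    dihedral = list(terms = list(list(n = 2, k = 1.2, gamma = 0),
                                 list(n = 1, k = 0.15, gamma = 0.5))),
    exclusions = c(1L, 3L))
  prot <- simulation_protocol(n_steps = 60000, temperature = 350,
                              timestep = 1, friction = 2, save_interval = 60,
                              n_replicas = 6, seed = 21)
  sim <- run_simulation(top, ff, chain_coords(4, seed = 2, jitter = 0.1),
                        prot)
  reference <- chain_coords(4, seed = 2, jitter = 0.1)
  rep_ <- bootstrap_report(sim, reference, lag = 2, k = 20, m = 2,
                           n_boot = 10, seed = 4)
  expect_s3_class(rep_, "macrostate_report")
  expect_equal(nrow(rep_$table), 2)
  expect_equal(sum(rep_$table$native), 1)
  expect_true(all(rep_$table$prob_mean >= 0, na.rm = TRUE))
  expect_equal(nrow(rep_$table), 2)
  # 10 bootstrap models; truncation removed the first 10% of each replica
  expect_equal(rep_$n_boot, 10)
  expect_true(all(dim(rep_$samples[[rep_$native]])[1] <= 10))
  # identical trajectories give zero spread
  same <- rep(list(sim$coords[[1]]), 4)
  rep2 <- bootstrap_report(same, reference, lag = 2, k = 10, m = 2,
                           n_boot = 5, seed = 5)
  expect_lt(max(rep2$table$prob_sd, na.rm = TRUE), 1e-8)
})
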