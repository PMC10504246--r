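small_cfg <- function() network_config(n_blocks = 2L, feature_width = 16L,
                                       n_basis = 6L, embedding_slots = 22L,
                                       head_width = 8L)

test_that("parameter counts reproduce the architecture layout", {
  expect_identical(count_parameters(network_config()), 294565L)
  expect_identical(count_parameters(
    network_config(n_blocks = 1L, feature_width = 8L, n_basis = 4L,
                   embedding_slots = 10L, head_width = 4L)), 449L)
  expect_identical(count_parameters(network_config(trainable_basis = FALSE)),
                   294565L - 36L)
  # the count describes the actual weight arrays
  pot <- gn_potential(small_cfg(), seed = 1)
  expect_identical(length(cgfold:::flatten_params(pot$params)),
                   count_parameters(small_cfg()))
})

test_that("edge lists contain exactly the within-cutoff pairs", {
  x2 <- rbind(c(0, 0, 0), c(5, 0, 0))
  expect_equal(nrow(build_edges(x2, 12)), 2)
  expect_equal(nrow(build_edges(rbind(c(0, 0, 0), c(13, 0, 0)), 12)), 0)
  set.seed(20)
  X <- matrix(runif(60, 0, 15), 20, 3)
  e <- build_edges(X, 8)
  # brute-force all-pairs oracle
  ref <- 0
  for (i in 1:19) for (j in (i + 1):20)
    if (sqrt(sum((X[i, ] - X[j, ])^2)) <= 8) ref <- ref + 2
  expect_equal(nrow(e), ref)
  expect_true(all(e$i != e$j))
  # symmetric: both directions present
  expect_setequal(paste(e$i, e$j), paste(e$j, e$i))
})

test_that("radial basis vanishes at both cutoffs and has K values", {
  cfg <- network_config()
  expect_equal(ncol(rbf_expand(5, cfg)), 18)
  expect_equal(max(abs(rbf_expand(cfg$cutoff_upper, cfg))), 0)
  expect_equal(max(abs(rbf_expand(cfg$cutoff_lower, cfg))), 0)
  expect_gt(max(rbf_expand((cfg$cutoff_lower + cfg$cutoff_upper) / 2, cfg)), 0)
})

test_that("embedding is a deterministic typed lookup", {
  pot <- gn_potential(small_cfg(), seed = 2)
  z <- c(3L, 7L, 3L)
  E <- embed_types(pot, z)
  expect_identical(E[1, ], E[3, ])
  perm <- c(2L, 3L, 1L)
  expect_identical(embed_types(pot, z[perm]), E[perm, ])
  pot$params$embedding[4, ] <- 1  # row for type id 3
  expect_true(all(embed_types(pot, 3L) == 1))
  expect_error(embed_types(pot, 25L), "range")
})

test_that("interaction block matches hand computation and edge-order freedom", {
  pot <- gn_potential(small_cfg(), seed = 3)
  blk <- pot$params$blocks[[1]]
  feat <- embed_types(pot, c(0L, 1L, 2L))
  # no edges: aggregation is empty, but offsets still propagate through the
  # pinned bias path (linear -> tanh -> linear of the zero aggregate)
  no_edges <- data.frame(i = integer(0), j = integer(0), d = numeric(0))
  phi0 <- matrix(numeric(0), 0, small_cfg()$n_basis)
  out <- interaction_block(feat, no_edges, phi0, blk)
  bias_path <- matrix(tanh(blk$bpost), 3, 16, byrow = TRUE) %*% blk$Wout +
    matrix(blk$bout, 3, 16, byrow = TRUE)
  expect_equal(out, feat + bias_path, tolerance = 1e-12)
  # single-edge hand computation
  e1 <- data.frame(i = 1L, j = 2L, d = 5)
  phi <- rbf_expand(5, small_cfg(), pot$params$mu, pot$params$beta)
  out1 <- interaction_block(feat, e1, phi, blk)
  wc <- tanh(phi %*% blk$W1 + matrix(blk$b1, 1)) %*% blk$W2 + matrix(blk$b2, 1)
  msg <- as.numeric(wc) * as.numeric(feat[2, ] %*% blk$Wpre)
  Y <- matrix(0, 3, 16); Y[1, ] <- msg
  expect_equal(out1, feat + sweep(tanh(sweep(Y %*% blk$Wpost, 2, blk$bpost,
                                             `+`)) %*% blk$Wout, 2,
                                  blk$bout, `+`), tolerance = 1e-12)
  # output invariant to edge listing order
  X <- chain_coords(5, seed = 4)
  ed <- build_edges(X, 12)
  phiE <- rbf_expand(ed$d, small_cfg(), pot$params$mu, pot$params$beta)
  ord <- sample(nrow(ed))
  feat5 <- embed_types(pot, 0:4)
  expect_equal(interaction_block(feat5, ed[ord, ], phiE[ord, , drop = FALSE],
                                 blk),
               interaction_block(feat5, ed, phiE, blk), tolerance = 1e-12)
})

test_that("fast path equals the composed reference implementation", {
  cfg <- small_cfg()
  pot <- gn_potential(cfg, seed = 5)
  X <- chain_coords(8, seed = 6)
  z <- c(0L, 4L, 9L, 20L, 2L, 2L, 7L, 11L)
  edges <- build_edges(X, cfg$cutoff_upper)
  phi <- rbf_expand(edges$d, cfg, pot$params$mu, pot$params$beta)
  feat <- embed_types(pot, z)
  for (b in pot$params$blocks) feat <- interaction_block(feat, edges, phi, b)
  hh <- tanh(sweep(feat %*% pot$params$head$W1, 2, pot$params$head$b1, `+`))
  U_ref <- sum(hh %*% pot$params$head$W2 + pot$params$head$b2)
  expect_equal(gnn_energy(pot, X, z), U_ref, tolerance = 1e-12)
})

test_that("network energy respects rigid-motion and permutation symmetry", {
  pot <- gn_potential(network_config(), seed = 7)  # full default architecture
  X <- chain_coords(10, seed = 8)
  z <- assign_bead_types(c("ALA", "GLY", "SER", "LEU", "VAL", "PHE", "ALA",
                           "TRP", "GLU", "LYS"))
  U <- gnn_energy(pot, X, z)
  expect_lt(abs(gnn_energy(pot, X + matrix(c(1, 2, 3), 10, 3, byrow = TRUE),
                           z) - U), 1e-9)
  R <- random_rotation(9)
  expect_lt(abs(gnn_energy(pot, X %*% R, z) - U), 1e-7)
  # swapping two identically typed beads leaves U unchanged
  swap <- seq_len(10); swap[c(1, 7)] <- c(7, 1)  # both ALA
  expect_equal(gnn_energy(pot, X[swap, ], z[swap]), U, tolerance = 1e-12)
  expect_error(gnn_energy(pot, X * NA, z), "non-finite")
})

test_that("forces are the exact negative gradient and equivariant", {
  cfg <- small_cfg()
  pot <- gn_potential(cfg, seed = 10)
  X <- chain_coords(10, seed = 11)
  z <- rep(0:4, 2)
  Fm <- gnn_forces(pot, X, z)
  num <- fd_forces(function(x) gnn_energy(pot, x, z), X, h = 1e-3)
  expect_lt(max(abs(num - Fm)) / max(abs(Fm)), 1e-4)
  expect_lt(max(abs(colSums(Fm))), 1e-6)
  R <- random_rotation(12)
  expect_lt(max(abs(gnn_forces(pot, X %*% R, z) - Fm %*% R)), 1e-6)
  # permutation equivariance
  perm <- sample(10)
  expect_equal(gnn_forces(pot, X[perm, ], z[perm]), Fm[perm, ],
               tolerance = 1e-10)
})

test_that("a bead beyond the cutoff is an inert isolated node", {
  cfg <- small_cfg()
  pot <- gn_potential(cfg, seed = 13)
  X <- chain_coords(5, seed = 14)
  z <- c(0L, 1L, 2L, 3L, 4L)
  far <- rbind(X, c(500, 500, 500))
  U_far <- gnn_energy(pot, far, c(z, 5L))
  # its contribution is the isolated-node energy (independent of position)
  farther <- rbind(X, c(900, -800, 100))
  expect_equal(gnn_energy(pot, farther, c(z, 5L)), U_far, tolerance = 1e-10)
  Ff <- gnn_forces(pot, far, c(z, 5L))
  expect_equal(max(abs(Ff[6, ])), 0)
  expect_equal(Ff[1:5, ], gnn_forces(pot, X, z), tolerance = 1e-10)
})

test_that("parameter gradients match dense finite differences", {
  cfg <- network_config(n_blocks = 1L, feature_width = 8L, n_basis = 4L,
                        embedding_slots = 22L, head_width = 4L)
  pot <- gn_potential(cfg, seed = 15)
  X <- chain_coords(6, seed = 16)
  z <- c(0L, 5L, 10L, 15L, 20L, 3L)
  g <- cgfold:::flatten_params(
    gnn_evaluate(pot, X, z, forces = FALSE, param_grad = TRUE)$pgrad)
  theta <- cgfold:::flatten_params(pot$params)
  set.seed(17)
  idx <- sample(length(theta), 40)
  h <- 1e-5
  for (i in idx) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    pp <- pot; pp$params <- cgfold:::unflatten_params(tp, pot$params)
    pm <- pot; pm$params <- cgfold:::unflatten_params(tm, pot$params)
    fd <- (gnn_energy(pp, X, z) - gnn_energy(pm, X, z)) / (2 * h)
    expect_equal(g[i], fd, tolerance = 1e-5)
  }
})

test_that("checkpoints round-trip the full model", {
  pot <- gn_potential(small_cfg(), seed = 18)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(pot, path, meta = list(epoch = 3L))
  back <- load_checkpoint(path)
  expect_identical(back$potential$params, pot$params)
  expect_identical(back$meta$epoch, 3L)
  expect_output(inspect_model(path), "294,565|parameters")
})
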