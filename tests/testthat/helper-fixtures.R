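# Shared fixtures, memoized so expensive objects are built once per test run.
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

toy_spec <- function() memo("toy_spec", make_toy_polymer(10, seed = 1))

# 20k-frame reference ensemble of the standard toy polymer (exact forces)
toy_reference <- function() memo("toy_reference",
  sample_reference(toy_spec(), 20000, n_replicas = 8, seed = 11))

# a small decorrelated subset for cheap distribution checks
toy_reference_small <- function() memo("toy_reference_small", {
  ref <- toy_reference()
  idx <- seq(1, 20000, by = 4)
  frame_dataset(ref$systems$toy$coords[idx, , ],
                ref$systems$toy$forces[idx, , ],
                temperature = ref$temperature, system = "toy")
})

# trained small potential on the shared reference (cached across test files)
toy_training <- function() memo("toy_training",
  train_potential(
    toy_reference(), toy_spec()$topology, toy_spec()$forcefield,
    net_config = network_config(n_blocks = 2L, feature_width = 32L,
                                n_basis = 8L, embedding_slots = 22L),
    config = training_config(batch_size = 128L, learning_rate = 2e-3,
                             max_epochs = 6L, seed = 1L)))

# independent double-loop prior energy in plain R (oracle)
prior_energy_oracle <- function(coords, topology, ff) {
  terms <- cgfold:::prior_terms_for_topology(topology, ff)
  V <- 0
  for (b in seq_len(nrow(terms$bonds))) {
    r <- sqrt(sum((coords[terms$bonds[b, 1] + 1, ] -
                     coords[terms$bonds[b, 2] + 1, ])^2))
    V <- V + terms$bond_k[b] * (r - terms$bond_r0[b])^2 + terms$bond_v0[b]
  }
  for (p in seq_len(nrow(terms$pairs))) {
    r <- sqrt(sum((coords[terms$pairs[p, 1] + 1, ] -
                     coords[terms$pairs[p, 2] + 1, ])^2))
    V <- V + 4 * terms$pair_eps[p] * r^-6 + terms$pair_v0[p]
  }
  for (q in seq_len(nrow(terms$quads))) {
    phi <- dihedral_angle(coords[terms$quads[q, 1] + 1, ],
                          coords[terms$quads[q, 2] + 1, ],
                          coords[terms$quads[q, 3] + 1, ],
                          coords[terms$quads[q, 4] + 1, ])
    for (t in seq_along(terms$dih_k))
      V <- V + terms$dih_k[t] *
        (1 + cos(terms$dih_n[t] * phi - terms$dih_gamma[t]))
  }
  V
}

# small random-ish but reproducible chain configuration
chain_coords <- function(n, seed = 1, jitter = 0.4) {
  set.seed(seed)
  cgfold:::toy_start_coords(n) + matrix(rnorm(3 * n, sd = jitter), n, 3)
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# finite-difference force check helper
fd_forces <- function(energy_fn, coords, h = 1e-5) {
  out <- matrix(0, nrow(coords), 3)
  for (i in seq_len(nrow(coords))) for (d in 1:3) {
    xp <- coords; xp[i, d] <- xp[i, d] + h
    xm <- coords; xm[i, d] <- xm[i, d] - h
    out[i, d] <- -(energy_fn(xp) - energy_fn(xm)) / (2 * h)
  }
  out
}

# tiny 3-residue PDB written at test time
write_test_pdb <- function(path, drop_ca_of = NULL) {
  res <- c("ALA", "GLY", "SER")
  lines <- character(0)
  serial <- 0
  for (i in seq_along(res)) {
    for (atom in c("N", "CA", "C")) {
      if (i %in% drop_ca_of && atom == "CA") next
      serial <- serial + 1
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, atom, res[i], i, 3.8 * i + 0.5 * serial %% 2, 1.0 * i, 0.0,
        substr(atom, 1, 1)))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}
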