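#' Network architecture configuration
#'
#' Hyperparameters of the graph network potential: stacked continuous-filter
#' convolution blocks over a bead graph whose edges are pairwise distances
#' within an upper cutoff, with an exponential-normal radial basis and a
#' scalar energy head.  Defaults follow the architecture used for protein
#' CG potentials: 4 interaction blocks, 128 features, 128 filters, 18
#' expnorm basis functions spanning 3.0-12.0 A, tanh activation, sum
#' aggregation.  The default configuration has exactly 294,565 trainable
#' parameters.
#'
#' @param n_blocks number of interaction blocks.
#' @param feature_width node feature dimension.
#' @param filter_width continuous-filter dimension (must equal
#'   `feature_width` for the elementwise filter product).
#' @param n_basis number of radial basis functions.
#' @param cutoff_lower,cutoff_upper radial basis range, A.
#' @param activation nonlinearity; only `"tanh"` is supported (it keeps the
#'   learned free-energy surface smooth).
#' @param aggregation message pooling; only `"sum"` is supported (preserves
#'   extensivity).
#' @param embedding_slots rows of the embedding table (21 are used by the
#'   bead vocabulary; the remaining slots are inert).
#' @param head_width hidden width of the energy head
#'   (feature -> head -> 1).
#' @param trainable_basis whether basis centers/widths are trainable.
#' @return Object of class `network_config`.
#' @export
network_config <- function(n_blocks = 4L, feature_width = 128L,
                           filter_width = feature_width, n_basis = 18L,
                           cutoff_lower = 3.0, cutoff_upper = 12.0,
                           activation = "tanh", aggregation = "sum",
                           embedding_slots = 100L,
                           head_width = feature_width %/% 2L,
                           trainable_basis = TRUE) {
  if (cutoff_lower >= cutoff_upper)
    stop("cutoff_lower must be below cutoff_upper", call. = FALSE)
  stopifnot(n_blocks >= 1, n_basis >= 1, feature_width >= 1, head_width >= 1)
  if (filter_width != feature_width)
    stop("filter_width must equal feature_width", call. = FALSE)
  if (activation != "tanh") stop("only tanh activation is supported")
  if (aggregation != "sum") stop("only sum aggregation is supported")
  structure(list(n_blocks = as.integer(n_blocks),
                 feature_width = as.integer(feature_width),
                 filter_width = as.integer(filter_width),
                 n_basis = as.integer(n_basis),
                 cutoff_lower = cutoff_lower, cutoff_upper = cutoff_upper,
                 activation = activation, aggregation = aggregation,
                 embedding_slots = as.integer(embedding_slots),
                 head_width = as.integer(head_width),
                 trainable_basis = trainable_basis),
            class = "network_config")
}

#' Count trainable parameters of a network configuration
#'
#' Embedding table + (optionally trainable) basis centers/widths + per block
#' the filter-generating network, the bias-free pre-convolution linear, the
#' post-aggregation linear and the block-output linear + the two-layer
#' energy head.
#'
#' @param config a [network_config()] or `gn_potential`.
#' @return Integer parameter count.
#' @examples
#' count_parameters(network_config())  # 294565
#' @export
count_parameters <- function(config) {
  if (inherits(config, "gn_potential")) config <- config$config
  Fw <- config$feature_width; Ff <- config$filter_width
  K <- config$n_basis; H <- config$head_width
  block <- (K * Ff + Ff) + (Ff * Ff + Ff) + Fw * Fw + (Fw * Fw + Fw) +
    (Fw * Fw + Fw)
  config$embedding_slots * Fw +
    (if (config$trainable_basis) 2L * K else 0L) +
    config$n_blocks * block +
    (Fw * H + H) + (H + 1L)
}

default_basis <- function(config) {
  K <- config$n_basis
  list(mu = seq(exp(-5), 1, length.out = K),
       beta = rep((2 * (1 - exp(-5)) / K)^-2, K))
}

xavier <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -s, s), n_in, n_out)
}

#' Initialize a graph network potential
#'
#' Weights are Glorot-uniform initialized, biases zero; basis centers are
#' uniformly spaced on `[exp(-5), 1]` in the warped coordinate and widths
#' are constant `(2 (1 - exp(-5)) / K)^-2`.
#'
#' @param config a [network_config()].
#' @param seed RNG seed for weight initialization.
#' @return Object of class `gn_potential` with elements `config` and
#'   `params`.
#' @export
gn_potential <- function(config = network_config(), seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  Fw <- config$feature_width; K <- config$n_basis; H <- config$head_width
  basis <- default_basis(config)
  blocks <- lapply(seq_len(config$n_blocks), function(b) list(
    W1 = xavier(K, Fw), b1 = numeric(Fw),
    W2 = xavier(Fw, Fw), b2 = numeric(Fw),
    Wpre = xavier(Fw, Fw),
    Wpost = xavier(Fw, Fw), bpost = numeric(Fw),
    Wout = xavier(Fw, Fw), bout = numeric(Fw)))
  params <- list(
    embedding = matrix(rnorm(config$embedding_slots * Fw),
                       config$embedding_slots, Fw),
    mu = basis$mu, beta = basis$beta, blocks = blocks,
    head = list(W1 = xavier(Fw, H), b1 = numeric(H),
                W2 = matrix(xavier(H, 1), H, 1), b2 = 0))
  structure(list(config = config, params = params), class = "gn_potential")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.gn_potential <- function(x, ...) {
  c <- x$config
  cat(sprintf(
    "Graph network potential: %d blocks, %d features, %d basis (%.1f-%.1f A), %s parameters\n",
    c$n_blocks, c$feature_width, c$n_basis, c$cutoff_lower, c$cutoff_upper,
    format(count_parameters(c), big.mark = ",")))
  invisible(x)
}

#' Build the edge list of a configuration
#'
#' All directed bead pairs (i, j), i != j, with Euclidean distance at or
#' below the upper cutoff; both directions are present and there are no
#' self edges.
#'
#' @param coords n x 3 matrix (A).
#' @param cutoff_upper A.
#' @return data.frame with columns `i` (receiving bead), `j` (neighbor) and
#'   `d` (distance, A).
#' @export
build_edges <- function(coords, cutoff_upper) {
  n <- nrow(coords)
  stopifnot(n >= 2)
  D <- as.matrix(stats::dist(coords))
  idx <- which(D <= cutoff_upper & upper.tri(D), arr.ind = TRUE)
  data.frame(i = c(idx[, 1], idx[, 2]), j = c(idx[, 2], idx[, 1]),
             d = rep(D[idx], 2))
}

#' Expand distances in the exponential-normal radial basis
#'
#' `phi_k(d) = f_cut(d) exp(-beta_k (exp(alpha (r_low - d)) - mu_k)^2)` with
#' `alpha = 5 / (r_high - r_low)` and a cosine switch `f_cut` that vanishes
#' at both cutoffs and is 1 at their midpoint.  The exponential warping
#' elongates the basis towards longer distances, which suits CG bead
#' interactions.
#'
#' @param d distances, A.
#' @param config a [network_config()].
#' @param mu,beta basis centers/widths; defaults to the initialization
#'   values.
#' @return length(d) x K matrix of basis values.
#' @export
rbf_expand <- function(d, config, mu = NULL, beta = NULL) {
  if (is.null(mu) || is.null(beta)) {
    basis <- default_basis(config)
    mu <- mu %||% basis$mu; beta <- beta %||% basis$beta
  }
  rl <- config$cutoff_lower; rh <- config$cutoff_upper
  alpha <- 5 / (rh - rl)
  fc <- ifelse(d > rl & d < rh,
               0.5 * (cos(pi * (2 * (d - rl) / (rh - rl) + 1)) + 1), 0)
  x <- exp(alpha * (rl - d))
  out <- outer(x, mu, function(xx, m) (xx - m)^2)
  out <- exp(-sweep(out, 2, beta, `*`)) * fc
  out
}

#' Embed bead types into initial node features
#'
#' Row i of the result is the z_i-th row of the embedding table (0-based
#' lookup); beads of equal type get identical features.
#'
#' @param potential a [gn_potential()].
#' @param z integer vector of 0-based bead type ids.
#' @return n x feature_width matrix.
#' @export
embed_types <- function(potential, z) {
  if (any(z < 0 | z >= potential$config$embedding_slots))
    stop("bead type id out of embedding range", call. = FALSE)
  potential$params$embedding[z + 1L, , drop = FALSE]
}

#' One interaction block (reference implementation)
#'
#' Per edge the filter-generating network maps the basis expansion to a
#' continuous filter, which multiplies the pre-convolution linear of the
#' neighbor features; messages are sum-aggregated per receiving bead,
#' passed through linear-tanh-linear, and added residually.  This plain-R
#' implementation defines the block semantics; the fast path in
#' [gnn_energy()] is checked against compositions of it.
#'
#' @param features n x F node feature matrix.
#' @param edges edge data.frame from [build_edges()].
#' @param phi E x K basis matrix for the edge distances.
#' @param block one element of `potential$params$blocks`.
#' @return Updated n x F feature matrix.
#' @export
interaction_block <- function(features, edges, phi, block) {
  n <- nrow(features)
  pre <- features %*% block$Wpre
  Y <- matrix(0, n, ncol(features))
  if (nrow(edges) > 0) {
    H1 <- tanh(sweep(phi %*% block$W1, 2, block$b1, `+`))
    WC <- sweep(H1 %*% block$W2, 2, block$b2, `+`)
    msg <- WC * pre[edges$j, , drop = FALSE]
    agg <- rowsum(msg, group = edges$i)
    Y[as.integer(rownames(agg)), ] <- agg
  }
  A <- tanh(sweep(Y %*% block$Wpost, 2, block$bpost, `+`))
  features + sweep(A %*% block$Wout, 2, block$bout, `+`)
}

stack_frames <- function(coords, z) {
  if (!is.list(coords)) { coords <- list(coords); z <- list(z) }
  if (!is.list(z)) z <- rep(list(z), length(coords))
  ns <- vapply(coords, nrow, integer(1))
  list(X = do.call(rbind, coords),
       z = unlist(z),
       offsets = cumsum(c(0L, ns)),
       ns = ns)
}

#' Evaluate the network potential on one or more configurations
#'
#' @param potential a [gn_potential()].
#' @param coords n x 3 matrix or list of matrices (frames are batched as a
#'   disjoint union of graphs).
#' @param z 0-based type ids (vector, or list matching `coords`).
#' @param forces also return forces (exact negative coordinate gradient).
#' @param param_grad also return the gradient of the summed energy with
#'   respect to every parameter array.
#' @return List with `energy` (kcal/mol per frame), `forces` (list of n x 3
#'   matrices, kcal/mol/A) and `pgrad` (parameter-shaped list) as requested.
#' @export
gnn_evaluate <- function(potential, coords, z, forces = TRUE,
                         param_grad = FALSE) {
  st <- stack_frames(coords, z)
  if (any(st$z < 0 | st$z >= potential$config$embedding_slots))
    stop("bead type id out of embedding range", call. = FALSE)
  if (!all(is.finite(st$X))) stop("non-finite coordinates", call. = FALSE)
  out <- gnn_eval_cpp(st$X, st$z, st$offsets, potential$params,
                      potential$config, forces, param_grad)
  res <- list(energy = as.numeric(out$energy))
  if (forces) {
    splits <- rep(seq_along(st$ns), st$ns)
    res$forces <- lapply(seq_along(st$ns), function(i)
      out$forces[splits == i, , drop = FALSE])
  }
  if (param_grad) res$pgrad <- out$pgrad
  res
}

#' Network energy of a configuration
#'
#' The scalar CG potential: per-node energies from the head network summed
#' over beads.  Depends on coordinates only through pairwise distances, so
#' it is invariant under rigid motions and permutations of identically
#' typed beads.
#'
#' @inheritParams gnn_evaluate
#' @return Energy in kcal/mol (vector if `coords` is a list).
#' @export
gnn_energy <- function(potential, coords, z) {
  gnn_evaluate(potential, coords, z, forces = FALSE)$energy
}

#' Network forces of a configuration
#'
#' Exact negative gradient of [gnn_energy()] obtained by a hand-written
#' reverse pass (no finite differences).
#'
#' @inheritParams gnn_evaluate
#' @return n x 3 force matrix (kcal/mol/A), or a list if `coords` is a list.
#' @export
gnn_forces <- function(potential, coords, z) {
  f <- gnn_evaluate(potential, coords, z, forces = TRUE)$forces
  if (is.list(coords)) f else f[[1]]
}

#' Save or load a model checkpoint
#'
#' A self-describing archive with the network configuration, all weight
#' arrays, the bead-vocabulary fingerprint and optional training metadata.
#'
#' @param potential a [gn_potential()].
#' @param path file path.
#' @param meta optional list (epoch, losses, ...).
#' @return `load_checkpoint` returns a list with `potential` and `meta`.
#' @export
save_checkpoint <- function(potential, path, meta = list()) {
  saveRDS(list(format = "cgfold-checkpoint", version = 1L,
               config = potential$config, params = potential$params,
               vocabulary = names(bead_vocabulary()), meta = meta), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "cgfold-checkpoint"))
    stop("not a cgfold checkpoint: ", path, call. = FALSE)
  list(potential = structure(list(config = x$config, params = x$params),
                             class = "gn_potential"),
       meta = x$meta)
}

#' Print a checkpoint or potential summary
#'
#' @param x path to a checkpoint or a `gn_potential`.
#' @return The potential, invisibly.
#' @export
inspect_model <- function(x) {
  if (is.character(x)) x <- load_checkpoint(x)$potential
  print(x)
  invisible(x)
}
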