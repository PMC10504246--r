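#' Training configuration for force matching
#'
#' @param fractions train/validation/test split fractions (must sum to 1).
#' @param batch_size frames per batch (graphs are batched as a disjoint
#'   union).
#' @param learning_rate initial Adam learning rate.
#' @param max_epochs maximum epochs.
#' @param seed master seed governing split, weight initialization and
#'   shuffling.
#' @param plateau_patience epochs without validation improvement before the
#'   learning rate is decayed.
#' @param lr_decay decay factor applied on a plateau.
#' @param stop_patience epochs without improvement before stopping.
#' @param plateau_tol minimum relative improvement that resets patience.
#' @param fd_step step (A) of the directional finite difference used for
#'   the loss parameter gradient (a Hessian-vector product through the
#'   exact parameter-gradient pass).
#' @return Object of class `training_config`.
#' @export
training_config <- function(fractions = c(train = 0.85, val = 0.05, test = 0.10),
                            batch_size = 64L, learning_rate = 1e-4,
                            max_epochs = 30L, seed = 1L,
                            plateau_patience = 5L, lr_decay = 0.8,
                            stop_patience = 30L, plateau_tol = 1e-4,
                            fd_step = 1e-3) {
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("split fractions must be positive and sum to 1", call. = FALSE)
  structure(list(fractions = fractions, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 plateau_patience = as.integer(plateau_patience),
                 lr_decay = lr_decay, stop_patience = as.integer(stop_patience),
                 plateau_tol = plateau_tol, fd_step = fd_step),
            class = "training_config")
}

#' Random train/validation/test split
#'
#' `round(f_train n)` frames to training, `round(f_val n)` to validation,
#' the remainder to test; uniform without replacement, reproducible from
#' the seed.
#'
#' @param n_frames total frame count (>= 20).
#' @param fractions length-3 split fractions.
#' @param seed RNG seed.
#' @return Factor of length `n_frames` with levels train/val/test.
#' @export
split_dataset <- function(n_frames, fractions = c(0.85, 0.05, 0.10),
                          seed = 1L) {
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("split fractions must be positive and sum to 1", call. = FALSE)
  stopifnot(n_frames >= 20)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample.int(n_frames)
  n_train <- round(fractions[1] * n_frames)
  n_val <- round(fractions[2] * n_frames)
  lab <- rep("test", n_frames)
  lab[perm[seq_len(n_train)]] <- "train"
  lab[perm[n_train + seq_len(n_val)]] <- "val"
  factor(lab, levels = c("train", "val", "test"))
}

#' Residual force targets for delta-learning
#'
#' Subtracts the prior forces (evaluated at the mapped coordinates) from the
#' mapped all-atom forces; the network is trained on the residual so that
#' the total CG force at inference is prior + network.
#'
#' @param frames a [frame_dataset()] of mapped coordinate/force pairs.
#' @param topologies a `cg_topology` or named list per system.
#' @param priors a [prior_forcefield()].
#' @return A [frame_dataset()] whose forces are the residual targets.
#' @export
delta_targets <- function(frames, topologies, priors) {
  stopifnot(inherits(frames, "frame_dataset"))
  if (inherits(topologies, "cg_topology"))
    topologies <- stats::setNames(rep(list(topologies), length(frames$systems)),
                                  names(frames$systems))
  systems <- frames$systems
  for (nm in names(systems)) {
    terms <- prior_terms_for_topology(topologies[[nm]], priors)
    X <- systems[[nm]]$coords
    Fm <- systems[[nm]]$forces
    for (f in seq_len(dim(X)[1])) {
      pf <- prior_eval_cpp(X[f, , ], terms)$forces
      Fm[f, , ] <- Fm[f, , ] - pf
    }
    systems[[nm]]$forces <- Fm
  }
  structure(list(systems = systems, temperature = frames$temperature),
            class = "frame_dataset")
}

#' Force-matching loss
#'
#' Mean squared error over every force component in the batch:
#' `L = sum ||target - predicted||^2 / (3 n_total)`, which reduces to the
#' `1/(3 n M)` normalization for fixed bead count.
#'
#' @param predicted,target matching numeric structures (matrices, arrays or
#'   lists of matrices).
#' @return Scalar loss (kcal/mol/A)^2.
#' @export
force_matching_loss <- function(predicted, target) {
  p <- unlist(predicted); t <- unlist(target)
  if (length(p) == 0) stop("empty batch", call. = FALSE)
  stopifnot(length(p) == length(t))
  sum((t - p)^2) / length(p)
}

#' Generic Adam minimizer
#'
#' Adaptive-moment gradient descent on a flat parameter vector; used by the
#' trainer and directly testable on problems with closed-form solutions.
#'
#' @param par initial parameter vector.
#' @param grad_fn function(par) returning the gradient (an attribute
#'   `value` may carry the objective).
#' @param steps iteration count.
#' @param lr learning rate (may be a vector per step).
#' @param beta1,beta2,eps Adam moment parameters.
#' @return Final parameter vector.
#' @export
adam_minimize <- function(par, grad_fn, steps, lr = 1e-2, beta1 = 0.9,
                          beta2 = 0.999, eps = 1e-8) {
  m <- v <- numeric(length(par))
  lr <- rep(lr, length.out = steps)
  for (t in seq_len(steps)) {
    g <- grad_fn(par)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    par <- par - lr[t] * mhat / (sqrt(vhat) + eps)
  }
  par
}

# flatten parameter-shaped lists to a single vector and back
flatten_params <- function(p) {
  unlist(list(p$embedding, p$mu, p$beta,
              lapply(p$blocks, function(b)
                list(b$W1, b$b1, b$W2, b$b2, b$Wpre, b$Wpost, b$bpost,
                     b$Wout, b$bout)),
              p$head$W1, p$head$b1, p$head$W2, p$head$b2), use.names = FALSE)
}

unflatten_params <- function(vec, template) {
  i <- 0L
  take <- function(proto) {
    n <- length(proto)
    out <- vec[(i + 1L):(i + n)]
    i <<- i + n
    if (is.matrix(proto)) matrix(out, nrow(proto), ncol(proto)) else out
  }
  p <- template
  p$embedding <- take(template$embedding)
  p$mu <- take(template$mu); p$beta <- take(template$beta)
  p$blocks <- lapply(template$blocks, function(b) {
    for (nm in c("W1", "b1", "W2", "b2", "Wpre", "Wpost", "bpost", "Wout",
                 "bout")) b[[nm]] <- take(b[[nm]])
    b
  })
  p$head$W1 <- take(template$head$W1); p$head$b1 <- take(template$head$b1)
  p$head$W2 <- take(template$head$W2); p$head$b2 <- take(template$head$b2)
  p
}

# mask that freezes the basis when it is not trainable
basis_mask <- function(template, trainable_basis) {
  m <- lapply(template, function(x) x)  # same shapes
  v <- rep(1, length(flatten_params(template)))
  if (!trainable_basis) {
    nK <- length(template$mu)
    off <- length(template$embedding)
    v[(off + 1):(off + 2 * nK)] <- 0
  }
  v
}

# gradient of the batch loss wrt all parameters via a central directional
# finite difference of the exact parameter-gradient pass (Pearlmutter HVP)
loss_and_grad <- function(params, config, Xb, zb, offsets, targets, fd_step) {
  base <- gnn_eval_cpp(Xb, zb, offsets, params, config, TRUE, FALSE)
  resid <- base$forces - targets
  loss <- sum(resid^2) / length(resid)
  v <- 2 * resid / length(resid)           # dL/dF
  m <- max(abs(v))
  if (m == 0)
    return(list(loss = loss, grad = NULL))
  dir <- v / m
  h <- fd_step
  gp <- gnn_eval_cpp(Xb + h * dir, zb, offsets, params, config, FALSE, TRUE)$pgrad
  gm <- gnn_eval_cpp(Xb - h * dir, zb, offsets, params, config, FALSE, TRUE)$pgrad
  # dL/dtheta = -grad_theta (v . grad_x U)
  grad <- -m * (flatten_params(gp) - flatten_params(gm)) / (2 * h)
  list(loss = loss, grad = grad)
}

# collect per-frame (coords, target, z) triples across systems
collect_frames <- function(frames, topologies) {
  if (inherits(topologies, "cg_topology"))
    topologies <- stats::setNames(rep(list(topologies), length(frames$systems)),
                                  names(frames$systems))
  out <- list()
  for (nm in names(frames$systems)) {
    X <- frames$systems[[nm]]$coords
    Fm <- frames$systems[[nm]]$forces
    z <- topologies[[nm]]$type_ids
    for (f in seq_len(dim(X)[1]))
      out[[length(out) + 1L]] <- list(coords = X[f, , ], target = Fm[f, , ],
                                      z = z)
  }
  out
}

batch_eval_loss <- function(params, config, items, idx, batch_size) {
  tot_sq <- tot_abs <- 0; tot_n <- 0
  for (b in split(idx, ceiling(seq_along(idx) / batch_size))) {
    st <- stack_frames(lapply(items[b], `[[`, "coords"),
                       lapply(items[b], `[[`, "z"))
    tg <- do.call(rbind, lapply(items[b], `[[`, "target"))
    out <- gnn_eval_cpp(st$X, st$z, st$offsets, params, config, TRUE, FALSE)
    r <- out$forces - tg
    tot_sq <- tot_sq + sum(r^2); tot_abs <- tot_abs + sum(abs(r))
    tot_n <- tot_n + length(r)
  }
  list(mse = tot_sq / tot_n, mae = tot_abs / tot_n)
}

#' Train a network potential by variational force matching
#'
#' Forms residual targets (mapped forces minus prior forces), splits frames
#' into train/validation/test, and minimizes the mean-squared force error
#' with Adam.  The learning rate decays on validation plateaus and the
#' checkpoint with the lowest validation loss is returned.  Training and
#' validation losses are squared-error; the test loss is reported as mean
#' absolute error and is not used for selection.
#'
#' @param frames a [frame_dataset()] of mapped coordinate/force pairs.
#' @param topologies a `cg_topology` or named list per system.
#' @param priors a [prior_forcefield()]; residual targets are computed
#'   against it.
#' @param net_config a [network_config()].
#' @param config a [training_config()].
#' @param potential optional starting [gn_potential()] (defaults to a fresh
#'   initialization from the master seed).
#' @param verbose print per-epoch losses.
#' @return List with `potential` (best checkpoint), `history` (per-epoch
#'   data.frame), `test_mae`, `split` and `best_epoch`.
#' @export
train_potential <- function(frames, topologies, priors,
                            net_config = network_config(n_blocks = 2L,
                                                        feature_width = 32L,
                                                        n_basis = 8L),
                            config = training_config(), potential = NULL,
                            verbose = FALSE) {
  residual <- delta_targets(frames, topologies, priors)
  items <- collect_frames(residual, topologies)
  M <- length(items)
  split <- split_dataset(M, config$fractions, seed = config$seed)
  idx_train <- which(split == "train")
  idx_val <- which(split == "val")
  idx_test <- which(split == "test")
  if (length(idx_train) == 0) stop("empty training split", call. = FALSE)

  if (is.null(potential)) potential <- gn_potential(net_config,
                                                    seed = config$seed)
  params <- potential$params
  ncfg <- potential$config
  template <- params
  theta <- flatten_params(params)
  mask <- basis_mask(template, ncfg$trainable_basis)
  mom <- vel <- numeric(length(theta))
  lr <- config$learning_rate
  best <- list(val = Inf, theta = theta, epoch = 0L)
  history <- NULL
  plateau <- 0L; t_adam <- 0L

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(idx_train)
    ep_loss <- 0; ep_n <- 0
    for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      st <- stack_frames(lapply(items[b], `[[`, "coords"),
                         lapply(items[b], `[[`, "z"))
      tg <- do.call(rbind, lapply(items[b], `[[`, "target"))
      lg <- loss_and_grad(params, ncfg, st$X, st$z, st$offsets, tg,
                          config$fd_step)
      if (!is.finite(lg$loss))
        stop("training diverged: non-finite loss at epoch ", epoch,
             call. = FALSE)
      ep_loss <- ep_loss + lg$loss * length(tg); ep_n <- ep_n + length(tg)
      if (is.null(lg$grad)) next
      g <- lg$grad * mask
      t_adam <- t_adam + 1L
      mom <- 0.9 * mom + 0.1 * g
      vel <- 0.999 * vel + 0.001 * g^2
      theta <- theta - lr * (mom / (1 - 0.9^t_adam)) /
        (sqrt(vel / (1 - 0.999^t_adam)) + 1e-8)
      params <- unflatten_params(theta, template)
    }
    val <- if (length(idx_val) > 0)
      batch_eval_loss(params, ncfg, items, idx_val, config$batch_size)$mse
    else ep_loss / ep_n
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_mse = ep_loss / ep_n,
                                         val_mse = val, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.5g  val %.5g  lr %.3g", epoch,
                      ep_loss / ep_n, val, lr))
    if (val < best$val * (1 - config$plateau_tol)) {
      best <- list(val = val, theta = theta, epoch = epoch)
      plateau <- 0L
    } else {
      plateau <- plateau + 1L
      if (plateau %% config$plateau_patience == 0) lr <- lr * config$lr_decay
      if (plateau >= config$stop_patience) break
    }
  }
  params <- unflatten_params(best$theta, template)
  best_potential <- structure(list(config = ncfg, params = params),
                              class = "gn_potential")
  test_mae <- if (length(idx_test) > 0)
    batch_eval_loss(params, ncfg, items, idx_test, config$batch_size)$mae
  else NA_real_
  list(potential = best_potential, history = history, test_mae = test_mae,
       split = split, best_epoch = best$epoch)
}
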