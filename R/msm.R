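#' Pairwise-distance featurization
#'
#' Featurizes bead trajectories into all pairwise distances (i < j,
#' lexicographic order), the transferable representation used both for
#' reference and CG simulations.
#'
#' @param traj `[S, n, 3]` coordinate array or a single n x 3 matrix.
#' @return S x (n(n-1)/2) feature matrix.
#' @export
featurize_pairwise_distances <- function(traj) {
  if (is.matrix(traj)) traj <- array(traj, c(1, dim(traj)))
  n <- dim(traj)[2]
  stopifnot(n >= 2)
  pairs <- t(utils::combn(n, 2))
  out <- matrix(0, dim(traj)[1], nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    d <- traj[, pairs[p, 1], , drop = FALSE] - traj[, pairs[p, 2], ,
                                                    drop = FALSE]
    out[, p] <- sqrt(rowSums(array(d, c(dim(traj)[1], 3))^2))
  }
  out
}

#' Time-lagged independent component analysis
#'
#' Projects feature trajectories onto their slowest linear components by
#' solving the symmetrized generalized eigenproblem of the time-lagged
#' versus instantaneous covariance matrices at the given lag.  Components
#' are orthonormal in the instantaneous-covariance metric and eigenvalues
#' are sorted descending.  A fitted model can be applied to new data with
#' [project_tica()] without refitting, which is how CG simulations are
#' projected with reference (all-atom) covariances.
#'
#' @param features feature matrix or list of matrices (one per trajectory).
#' @param lag lag time in frames.
#' @param dim number of components kept.
#' @param ridge diagonal regularization added to the instantaneous
#'   covariance (scaled by its trace) to handle singular features.
#' @return Object of class `tica_model` with `mean`, `components`,
#'   `eigenvalues`, `lag`, `dim`, and the covariance summaries `C0`, `Ct`.
#' @export
fit_tica <- function(features, lag, dim = 2L, ridge = 1e-10) {
  trajs <- if (is.list(features)) features else list(features)
  trajs <- trajs[vapply(trajs, nrow, integer(1)) > lag]
  if (length(trajs) == 0) stop("no trajectory longer than the lag",
                               call. = FALSE)
  p <- ncol(trajs[[1]])
  sum_x <- numeric(p); count <- 0
  for (X in trajs) {
    a <- X[seq_len(nrow(X) - lag), , drop = FALSE]
    b <- X[lag + seq_len(nrow(X) - lag), , drop = FALSE]
    sum_x <- sum_x + colSums(a) + colSums(b)
    count <- count + 2 * (nrow(X) - lag)
  }
  mu <- sum_x / count
  C0 <- Ct <- matrix(0, p, p)
  for (X in trajs) {
    a <- sweep(X[seq_len(nrow(X) - lag), , drop = FALSE], 2, mu)
    b <- sweep(X[lag + seq_len(nrow(X) - lag), , drop = FALSE], 2, mu)
    C0 <- C0 + crossprod(a) + crossprod(b)
    Ct <- Ct + crossprod(a, b) + crossprod(b, a)
  }
  C0 <- C0 / count; Ct <- Ct / count
  C0r <- C0 + diag(ridge * max(sum(diag(C0)), 1), p)
  e0 <- eigen(C0r, symmetric = TRUE)
  keep <- e0$values > max(e0$values) * 1e-12
  W <- e0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep]), sum(keep))
  M <- t(W) %*% Ct %*% W
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- W %*% es$vectors
  structure(list(mean = mu, components = V, eigenvalues = es$values,
                 lag = lag, dim = as.integer(min(dim, ncol(V))),
                 C0 = C0, Ct = Ct), class = "tica_model")
}

#' Project features with a fitted TICA model
#'
#' @param model a [fit_tica()] model (e.g. fitted on reference data).
#' @param features matrix or list of matrices.
#' @param dim number of components (defaults to the model's).
#' @return Projection matrix, or list of matrices matching the input.
#' @export
project_tica <- function(model, features, dim = model$dim) {
  proj1 <- function(X)
    sweep(X, 2, model$mean) %*% model$components[, seq_len(dim), drop = FALSE]
  if (is.list(features)) lapply(features, proj1) else proj1(features)
}

#' Discretize projections with seeded k-means
#'
#' @param projections matrix or list of matrices (one per trajectory).
#' @param k number of microstates.
#' @param seed RNG seed.
#' @param max_restarts re-seeded restarts if clustering degenerates.
#' @return List with `dtrajs` (list of 1-based integer label vectors),
#'   `centers`, and `inertia`.
#' @export
cluster_microstates <- function(projections, k, seed = 1L, max_restarts = 10L) {
  prlist <- if (is.list(projections)) projections else list(projections)
  X <- do.call(rbind, prlist)
  stopifnot(k <= nrow(X))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  km <- NULL
  for (r in seq_len(max_restarts)) {
    set.seed(seed + r - 1L)
    km <- tryCatch(stats::kmeans(X, centers = k, iter.max = 100, nstart = 3),
                   error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(km) && length(unique(km$cluster)) == k) break
  }
  if (is.null(km)) stop("k-means failed after restarts", call. = FALSE)
  ns <- vapply(prlist, nrow, integer(1))
  idx <- split(km$cluster, rep(seq_along(ns), ns))
  list(dtrajs = unname(idx), centers = km$centers,
       inertia = km$tot.withinss)
}

#' Estimate a reversible Markov state model
#'
#' Counts transitions at the given lag (sliding window), restricts to the
#' largest strongly connected set of the count graph, and computes the
#' detailed-balance-constrained maximum-likelihood transition matrix by the
#' standard fixed-point iteration.  The stationary distribution is read off
#' the reversible weights.
#'
#' @param dtrajs integer label vector or list of them.
#' @param lag lag in frames (>= 1).
#' @param tol fixed-point convergence tolerance.
#' @return Object of class `markov_model` with `transition`, `pi`,
#'   `counts`, `states` (original labels of the connected set) and
#'   `dropped`.
#' @export
estimate_msm <- function(dtrajs, lag = 1L, tol = 1e-12) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  stopifnot(lag >= 1)
  states <- sort(unique(unlist(dtrajs)))
  S <- length(states)
  C <- matrix(0, S, S)
  for (d in dtrajs) {
    d <- match(d, states)
    if (length(d) > lag) {
      a <- d[seq_len(length(d) - lag)]
      b <- d[lag + seq_len(length(d) - lag)]
      for (t in seq_along(a)) C[a[t], b[t]] <- C[a[t], b[t]] + 1
    }
  }
  comp <- strongly_connected(C > 0)
  weight <- vapply(split(rowSums(C), comp), sum, numeric(1))
  keep <- which(comp == as.integer(names(weight)[which.max(weight)]))
  dropped <- states[setdiff(seq_len(S), keep)]
  C <- C[keep, keep, drop = FALSE]
  X <- C + t(C)
  ci <- rowSums(C)
  for (iter in seq_len(20000)) {
    xi <- rowSums(X)
    denom <- outer(ci / xi, ci / xi, `+`)
    Xn <- (C + t(C)) / denom
    delta <- max(abs(Xn - X)) / max(X)
    X <- Xn
    if (delta < tol) break
  }
  xi <- rowSums(X)
  T_ <- X / xi
  structure(list(transition = T_, pi = xi / sum(xi), counts = C,
                 states = states[keep], dropped = dropped, lag = lag),
            class = "markov_model")
}

# Kosaraju strongly connected components on a logical adjacency matrix
strongly_connected <- function(adj) {
  n <- nrow(adj)
  # iterative DFS with explicit finish order
  order <- integer(0); visited <- rep(FALSE, n)
  for (s in seq_len(n)) {
    if (visited[s]) next
    stack <- list(c(s, 0L))
    visited[s] <- TRUE
    while (length(stack) > 0) {
      fr <- stack[[length(stack)]]
      u <- fr[1]
      nxt <- which(adj[u, ] & !visited)
      if (length(nxt) == 0) {
        order <- c(order, u)
        stack[[length(stack)]] <- NULL
      } else {
        visited[nxt[1]] <- TRUE
        stack[[length(stack) + 1L]] <- c(nxt[1], 0L)
      }
    }
  }
  comp <- integer(n); cur <- 0L
  visited <- rep(FALSE, n)
  tadj <- t(adj)
  for (s in rev(order)) {
    if (visited[s]) next
    cur <- cur + 1L
    stack <- s; visited[s] <- TRUE
    while (length(stack) > 0) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      comp[u] <- cur
      nxt <- which(tadj[u, ] & !visited)
      visited[nxt] <- TRUE
      stack <- c(stack, nxt)
    }
  }
  comp
}

#' PCCA+ macrostate partition
#'
#' Spectral clustering of MSM microstates into `m` metastable macrostates
#' using the top `m` right eigenvectors of the reversible transition
#' matrix (PCCA+ with the inner-simplex vertex search).  Memberships are
#' stored; reporting uses the crisp argmax assignment.  Macrostate
#' equilibrium probabilities are sums of stationary weights.
#'
#' @param model a [estimate_msm()] model.
#' @param m number of macrostates.
#' @return Object of class `macrostate_partition` with `labels` (macrostate
#'   per microstate), `memberships`, `probabilities` (percent, sums to
#'   100).
#' @export
pcca_macrostates <- function(model, m) {
  S <- nrow(model$transition)
  stopifnot(m >= 1, m <= S)
  pi_ <- model$pi
  D <- sqrt(pi_)
  Sym <- model$transition * outer(D, 1 / D)
  es <- eigen((Sym + t(Sym)) / 2, symmetric = TRUE)
  ord <- order(es$values, decreasing = TRUE)[seq_len(m)]
  X <- es$vectors[, ord, drop = FALSE] / D
  X[, 1] <- 1
  if (m == 1) {
    labels <- rep(1L, S)
    chi <- matrix(1, S, 1)
  } else {
    idx <- integer(m)
    ortho <- X
    idx[1] <- which.max(rowSums(ortho^2))
    ortho <- sweep(ortho, 2, ortho[idx[1], ])
    for (j in 2:m) {
      d <- sqrt(rowSums(ortho^2))
      idx[j] <- which.max(d)
      vj <- ortho[idx[j], ] / d[idx[j]]
      ortho <- ortho - (ortho %*% vj) %*% t(vj)
    }
    A <- solve(X[idx, , drop = FALSE])
    chi <- X %*% A
    labels <- max.col(chi, ties.method = "first")
  }
  probs <- vapply(seq_len(m), function(g) sum(pi_[labels == g]), numeric(1))
  structure(list(labels = labels, memberships = chi,
                 probabilities = 100 * probs / sum(probs), model = model),
            class = "macrostate_partition")
}

#' @export
print.macrostate_partition <- function(x, ...) {
  cat("PCCA+ partition:", length(x$probabilities), "macrostates;",
      "probabilities (%):", paste(sprintf("%.1f", x$probabilities),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Free-energy surface over two TICA components
#'
#' Bins the projection onto an 80 x 80 grid and assigns each frame the
#' equilibrium weight of its microstate (stationary probability divided by
#' the microstate's frame count), then `F = -kB T log(sum of weights)` per
#' bin, shifted so the occupied minimum is zero.  Unoccupied bins are NA.
#'
#' @param projections m x 2 projection matrix (frames of all trajectories).
#' @param dtrajs integer microstate labels matching the rows.
#' @param model a [estimate_msm()] model estimated from `dtrajs`.
#' @param temperature K.
#' @param bins grid size per axis.
#' @return Object of class `fes_grid`: `free_energy` (bins x bins,
#'   kcal/mol), `xedges`, `yedges`, `temperature`.
#' @export
free_energy_surface <- function(projections, dtrajs, model, temperature = 350,
                                bins = 80L) {
  stopifnot(ncol(projections) >= 2)
  labels <- unlist(dtrajs)
  stopifnot(length(labels) == nrow(projections))
  w <- rep(0, length(labels))
  counts <- table(factor(labels, levels = model$states))
  for (s in seq_along(model$states)) {
    sel <- labels == model$states[s]
    if (counts[s] > 0) w[sel] <- model$pi[s] / counts[s]
  }
  xe <- seq(min(projections[, 1]), max(projections[, 1]), length.out = bins + 1)
  ye <- seq(min(projections[, 2]), max(projections[, 2]), length.out = bins + 1)
  ix <- pmin(pmax(findInterval(projections[, 1], xe, all.inside = TRUE), 1), bins)
  iy <- pmin(pmax(findInterval(projections[, 2], ye, all.inside = TRUE), 1), bins)
  W <- matrix(0, bins, bins)
  for (f in seq_along(w)) W[ix[f], iy[f]] <- W[ix[f], iy[f]] + w[f]
  Fmat <- matrix(NA_real_, bins, bins)
  occ <- W > 0
  Fmat[occ] <- -kB * temperature * log(W[occ])
  Fmat <- Fmat - min(Fmat[occ])
  structure(list(free_energy = Fmat, xedges = xe, yedges = ye,
                 temperature = temperature), class = "fes_grid")
}

#' RMSD after optimal superposition (Kabsch)
#'
#' Least-squares rigid superposition via the SVD construction with a
#' reflection guard, then root-mean-square deviation.
#'
#' @param X,Y n x 3 coordinate matrices (n >= 3).
#' @return RMSD in A.
#' @export
rmsd_kabsch <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 3, ncol(X) == 3)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  s <- svd(crossprod(Yc, Xc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
}

#' RMSD of every frame of a trajectory to a reference structure
#'
#' @param traj `[S, n, 3]` array.
#' @param reference n x 3 matrix.
#' @return Numeric vector of RMSDs (A).
#' @export
rmsd_series <- function(traj, reference) {
  vapply(seq_len(dim(traj)[1]), function(f)
    rmsd_kabsch(traj[f, , ], reference), numeric(1))
}

#' Identify the native macrostate
#'
#' The macrostate containing the frame with the global minimum RMSD to the
#' experimental (reference) structure; ties are broken towards the lower
#' macrostate index.
#'
#' @param macro_per_frame integer macrostate label per analyzed frame.
#' @param rmsd RMSD per analyzed frame (A).
#' @return Macrostate id (integer).
#' @export
identify_native_macrostate <- function(macro_per_frame, rmsd) {
  stopifnot(length(macro_per_frame) == length(rmsd))
  cand <- which(rmsd == min(rmsd, na.rm = TRUE))
  min(macro_per_frame[cand])
}

#' Rank macrostates by mean network energy
#'
#' Macrostates sorted by ascending mean potential energy of their sampled
#' frames; a minimal-energy criterion that identifies native macrostates.
#' Equal means keep index order (stable); macrostates with no sampled
#' frames are excluded and reported in the `excluded` attribute.
#'
#' @param macro_per_frame integer macrostate label per frame.
#' @param energies potential energy per frame (kcal/mol).
#' @param m total number of macrostates (default: max label).
#' @return Integer vector of macrostate ids, lowest mean energy first.
#' @export
rank_macrostates_by_energy <- function(macro_per_frame, energies,
                                       m = max(macro_per_frame)) {
  stopifnot(length(macro_per_frame) == length(energies))
  means <- vapply(seq_len(m), function(g) {
    e <- energies[macro_per_frame == g]
    if (length(e) == 0) NA_real_ else mean(e)
  }, numeric(1))
  present <- which(!is.na(means))
  ranking <- present[order(means[present], present)]
  structure(ranking, excluded = setdiff(seq_len(m), present))
}

#' Bootstrapped native-macrostate report
#'
#' Full validation pipeline on a set of CG trajectories: drop the first
#' `truncate_frac` of each trajectory, featurize into pairwise distances,
#' project with TICA (optionally a frozen reference model), discretize with
#' k-means, estimate a reversible MSM, partition with PCCA+, and identify
#' the native macrostate by minimum RMSD to the reference structure.
#' Statistics (macrostate equilibrium probability and RMSD mean/sd/min)
#' are reported as mean +/- sd over `n_boot` models estimated from
#' resamples of 90% of the trajectories; bootstrap macrostates are matched
#' to the full-data macrostates by stationary-weighted microstate overlap.
#'
#' @param trajs list of `[S, n, 3]` arrays or a `trajectory_ensemble`.
#' @param reference n x 3 reference structure (A).
#' @param lag MSM lag (saved frames).
#' @param k microstate count (default scales with data size).
#' @param m macrostate count.
#' @param tica_model optional frozen [fit_tica()] model (reference
#'   covariances); fitted on the trajectories when NULL.
#' @param tica_dim projection dimension.
#' @param n_boot bootstrap model count.
#' @param boot_frac fraction of trajectories per resample.
#' @param truncate_frac initial fraction of each trajectory discarded.
#' @param n_samples conformations sampled per macrostate.
#' @param seed RNG seed.
#' @return Object of class `macrostate_report`: `table` (per-macrostate
#'   statistics with the native flag), `native`, `partition`, `samples`
#'   (list of `[n_samples, n, 3]` arrays), `tica`, `msm`.
#' @export
bootstrap_report <- function(trajs, reference, lag = 10L, k = NULL, m = 4L,
                             tica_model = NULL, tica_dim = 2L, n_boot = 10L,
                             boot_frac = 0.9, truncate_frac = 0.1,
                             n_samples = 10L, seed = 1L) {
  if (inherits(trajs, "trajectory_ensemble")) trajs <- trajs$coords
  stopifnot(length(trajs) >= 2)
  trajs <- lapply(trajs, function(x) {
    drop_n <- floor(dim(x)[1] * truncate_frac)
    x[(drop_n + 1):dim(x)[1], , , drop = FALSE]
  })
  feats <- lapply(trajs, featurize_pairwise_distances)
  if (is.null(tica_model)) tica_model <- fit_tica(feats, lag = lag,
                                                  dim = tica_dim)
  projs <- project_tica(tica_model, feats, dim = tica_dim)
  total_frames <- sum(vapply(projs, nrow, integer(1)))
  if (is.null(k)) k <- max(20L, min(200L, total_frames %/% 500L))
  cl <- cluster_microstates(projs, k = k, seed = seed)
  msm <- estimate_msm(cl$dtrajs, lag = lag)
  part <- pcca_macrostates(msm, m)
  micro_all <- unlist(cl$dtrajs)
  macro_of_micro <- rep(NA_integer_, k)
  macro_of_micro[msm$states] <- part$labels
  macro_all <- macro_of_micro[micro_all]
  rmsd_all <- unlist(lapply(trajs, rmsd_series, reference = reference))
  keep <- !is.na(macro_all)
  native <- identify_native_macrostate(macro_all[keep], rmsd_all[keep])

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  boot_prob <- matrix(NA_real_, n_boot, m)
  boot_rmsd_mean <- boot_rmsd_min <- matrix(NA_real_, n_boot, m)
  missing_native <- 0L
  for (b in seq_len(n_boot)) {
    pick <- sort(sample(length(trajs), max(2, round(boot_frac * length(trajs)))))
    bm <- tryCatch(estimate_msm(cl$dtrajs[pick], lag = lag),
                   error = function(e) NULL)
    if (is.null(bm)) next
    bp <- tryCatch(pcca_macrostates(bm, min(m, nrow(bm$transition))),
                   error = function(e) NULL)
    if (is.null(bp)) next
    # match bootstrap macrostates to full-model macrostates by pi overlap
    bmac_of_micro <- rep(NA_integer_, k)
    bmac_of_micro[bm$states] <- bp$labels
    map <- vapply(seq_len(m), function(g) {
      micro_g <- msm$states[part$labels == g]
      micro_g <- micro_g[micro_g %in% bm$states]
      if (length(micro_g) == 0) return(NA_integer_)
      wt <- tapply(bm$pi[match(micro_g, bm$states)], bmac_of_micro[micro_g],
                   sum)
      as.integer(names(wt)[which.max(wt)])
    }, integer(1))
    bmicro <- unlist(cl$dtrajs[pick])
    bmacro <- bmac_of_micro[bmicro]
    brmsd <- unlist(lapply(trajs[pick], rmsd_series, reference = reference))
    for (g in seq_len(m)) {
      if (is.na(map[g])) next
      boot_prob[b, g] <- sum(bp$probabilities[map[g]])
      sel <- !is.na(bmacro) & bmacro == map[g]
      if (any(sel)) {
        boot_rmsd_mean[b, g] <- mean(brmsd[sel])
        boot_rmsd_min[b, g] <- min(brmsd[sel])
      }
    }
    if (is.na(map[native])) missing_native <- missing_native + 1L
  }
  tab <- data.frame(
    macrostate = seq_len(m),
    prob_mean = colMeans(boot_prob, na.rm = TRUE),
    prob_sd = apply(boot_prob, 2, stats::sd, na.rm = TRUE),
    rmsd_mean = vapply(seq_len(m), function(g) {
      sel <- keep & macro_all == g
      if (any(sel)) mean(rmsd_all[sel]) else NA_real_
    }, numeric(1)),
    rmsd_sd = vapply(seq_len(m), function(g) {
      sel <- keep & macro_all == g
      if (sum(sel) > 1) stats::sd(rmsd_all[sel]) else NA_real_
    }, numeric(1)),
    rmsd_min = vapply(seq_len(m), function(g) {
      sel <- keep & macro_all == g
      if (any(sel)) min(rmsd_all[sel]) else NA_real_
    }, numeric(1)),
    native = seq_len(m) == native)
  # sample conformations per macrostate, proportional to equilibrium weights
  all_coords <- do.call(rbind, lapply(trajs, function(x)
    matrix(x, dim(x)[1], prod(dim(x)[-1]))))
  samples <- lapply(seq_len(m), function(g) {
    sel <- which(keep & macro_all == g)
    if (length(sel) == 0) return(NULL)
    wsel <- msm$pi[match(micro_all[sel], msm$states)]
    pick <- sample(sel, min(n_samples, length(sel)),
                   prob = wsel / sum(wsel),
                   replace = length(sel) < n_samples)
    array(all_coords[pick, ], c(length(pick), dim(trajs[[1]])[2], 3))
  })
  structure(list(table = tab, native = native, partition = part,
                 samples = samples, tica = tica_model, msm = msm,
                 n_boot = n_boot, missing_native = missing_native),
            class = "macrostate_report")
}

#' @export
print.macrostate_report <- function(x, ...) {
  cat("Macrostate report (native =", x$native, "):\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
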