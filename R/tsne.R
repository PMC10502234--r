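# t-SNE optimization core.
#
# The embedding minimizes KL(P || Q) where Q is the Student-t kernel over
# embedding distances. The per-point KL gradient is
#   grad_i = 4 sum_{j != i} (p_ij - q_ij) phi_ij,
#   phi_ij = (y_i - y_j) / (1 + ||y_i - y_j||^2),
# and points descend it with momentum. The tracked mode additionally
# advances the per-sample Jacobian blocks G_i = dy_i/dx_i through the very
# same update arithmetic (see attribution.R for the dense reference ops).

#' Optimizer configuration for t-SNE
#'
#' @param n_iter total number of iterations.
#' @param learning_rate positive step size.
#' @param momentum,final_momentum momentum before / after the switch.
#' @param momentum_switch iteration at which momentum changes.
#' @param exaggeration_factor early-exaggeration multiplier applied to P
#'   (and, in tracked runs, to dP/dX) during the first
#'   \code{exaggeration_iters} iterations.
#' @param exaggeration_iters length of the exaggeration phase; must be
#'   smaller than \code{n_iter}.
#' @param use_gains adaptive per-coordinate gains (van der Maaten style).
#'   Off by default: the gain update is sign-based and non-differentiable,
#'   so tracked runs treat gains as per-iteration constants when enabled.
#' @param bh_theta Barnes-Hut opening angle in [0, 1), or NULL for the
#'   exact O(n^2) mode.
#' @param d_out embedding dimensionality (2 or 3; Barnes-Hut requires 2).
#' @param store_every record the embedding every so many iterations
#'   (0 = final only).
#' @param kl_every evaluate KL(P||Q) every so many iterations (0 = never).
#' @return list of class \code{tsne_config}.
#' @export
tsne_config <- function(n_iter = 1000L, learning_rate = 200,
                        momentum = 0.5, final_momentum = 0.8,
                        momentum_switch = 250L,
                        exaggeration_factor = 12, exaggeration_iters = 250L,
                        use_gains = FALSE, bh_theta = NULL,
                        d_out = 2L, store_every = 0L, kl_every = 50L) {
  stopifnot(n_iter >= 1, learning_rate > 0, exaggeration_factor > 0,
            d_out %in% c(2L, 3L))
  if (exaggeration_iters >= n_iter)
    stop("exaggeration_iters must be smaller than n_iter")
  if (!is.null(bh_theta)) {
    if (bh_theta < 0 || bh_theta >= 1) stop("bh_theta must lie in [0, 1)")
    if (d_out != 2L) stop("Barnes-Hut mode supports 2-D embeddings only")
  }
  structure(list(n_iter = as.integer(n_iter), learning_rate = learning_rate,
                 momentum = momentum, final_momentum = final_momentum,
                 momentum_switch = as.integer(momentum_switch),
                 exaggeration_factor = exaggeration_factor,
                 exaggeration_iters = as.integer(exaggeration_iters),
                 use_gains = use_gains, bh_theta = bh_theta,
                 d_out = as.integer(d_out),
                 store_every = as.integer(store_every),
                 kl_every = as.integer(kl_every)),
            class = "tsne_config")
}

# Student-t kernel matrix E_ij = 1/(1+||y_i-y_j||^2), zero diagonal
tsne_kernel <- function(Y) {
  E <- 1 / (1 + sq_dists(Y))
  diag(E) <- 0
  E
}

#' Per-iteration t-SNE quantities
#'
#' Computes the Student-t affinities Q, the pairwise displacement kernels
#' \eqn{\phi_{ij}}, the normalizer Z and the KL gradient for an embedding.
#'
#' @param Y n-by-d' embedding matrix.
#' @param P an \code{affinity_model} or a joint affinity matrix.
#' @param exaggeration multiplier applied to P (early exaggeration).
#' @return list of class \code{step_quantities}: \code{Q}, \code{Z},
#'   \code{E} (unnormalized kernel), \code{Phi} (n x n x d' array with
#'   \code{Phi[i,j,] = phi_ij}), and \code{grad}, the n-by-d' matrix of
#'   KL gradients \eqn{4\sum_j (p_{ij}-q_{ij})\phi_{ij}}.
#' @export
compute_step_quantities <- function(Y, P, exaggeration = 1) {
  Y <- as.matrix(Y)
  if (!all(is.finite(Y))) stop("embedding contains non-finite coordinates")
  Pm <- if (inherits(P, "affinity_model")) P$P else as.matrix(P)
  n <- nrow(Y)
  d_out <- ncol(Y)
  E <- tsne_kernel(Y)
  Z <- sum(E)
  Q <- E / Z
  Phi <- array(0, dim = c(n, n, d_out))
  for (a in seq_len(d_out)) Phi[, , a] <- E * outer(Y[, a], Y[, a], "-")
  W <- (exaggeration * Pm - Q) * E
  grad <- 4 * (rowSums(W) * Y - W %*% Y)
  structure(list(Q = Q, Z = Z, E = E, Phi = Phi, grad = grad,
                 exaggeration = exaggeration),
            class = "step_quantities")
}

# The one place where the optimizer arithmetic lives; the tracked update in
# the engine mirrors exactly this (momentum, then position).
apply_update <- function(Y, velocity, gains, grad, learning_rate, momentum,
                         use_gains) {
  if (use_gains) {
    agree <- sign(grad) == sign(velocity)
    gains <- ifelse(agree, gains * 0.8, gains + 0.2)
    gains[gains < 0.01] <- 0.01
    velocity <- momentum * velocity - learning_rate * gains * grad
  } else {
    velocity <- momentum * velocity - learning_rate * grad
  }
  list(Y = Y + velocity, velocity = velocity, gains = gains)
}

#' One optimizer step
#'
#' Applies momentum gradient descent on KL(P||Q) to an embedding state.
#'
#' @param state list of class \code{embedding_state}: \code{Y},
#'   \code{velocity}, \code{gains}, \code{iteration}.
#' @param quantities output of \code{\link{compute_step_quantities}} for
#'   \code{state$Y}.
#' @param config a \code{\link{tsne_config}}.
#' @return the advanced \code{embedding_state}.
#' @export
tsne_step <- function(state, quantities, config) {
  mom <- if (state$iteration + 1L <= config$momentum_switch)
    config$momentum else config$final_momentum
  upd <- apply_update(state$Y, state$velocity, state$gains, quantities$grad,
                      config$learning_rate, mom, config$use_gains)
  it <- state$iteration + 1L
  if (any(abs(upd$Y) > 1e8))
    stop("optimization diverged at iteration ", it)
  structure(list(Y = upd$Y, velocity = upd$velocity, gains = upd$gains,
                 iteration = it),
            class = "embedding_state")
}

#' Initial embedding state
#'
#' Draws the initial embedding from an isotropic Gaussian (sd 1e-4),
#' independent of the data, so that \eqn{\partial y^0 / \partial x = 0}
#' holds exactly.
#'
#' @param n number of points.
#' @param d_out embedding dimensionality.
#' @param seed RNG seed for the draw.
#' @return an \code{embedding_state} at iteration 0.
#' @export
init_embedding <- function(n, d_out = 2L, seed = 0L) {
  Y0 <- with_seed(seed, matrix(stats::rnorm(n * d_out, sd = 1e-4), n, d_out))
  structure(list(Y = Y0, velocity = matrix(0, n, d_out),
                 gains = matrix(1, n, d_out), iteration = 0L),
            class = "embedding_state")
}

kl_divergence <- function(P, Q) {
  keep <- P > 0
  sum(P[keep] * log(P[keep] / pmax(Q[keep], 1e-300)))
}

#' Fit a t-SNE embedding, optionally tracking input gradients
#'
#' Runs the full optimization loop. With \code{track = TRUE} the per-sample
#' Jacobian blocks \eqn{G_i = \partial y_i / \partial x_i} are advanced at
#' every iteration by the dynamic-programming recursion
#' \deqn{\partial dy_i/\partial x_i = 4\sum_{j\neq i}
#'   [(\partial p_{ij}/\partial x_i - \partial q_{ij}/\partial x_i)\,
#'    \phi_{ij}^\top + (p_{ij}-q_{ij})\,\partial\phi_{ij}/\partial x_i],}
#' with \eqn{\partial q/\partial x} and \eqn{\partial\phi/\partial x}
#' obtained by chaining through \eqn{y_i} only (cross-sample blocks
#' \eqn{\partial y_i/\partial x_j} are assumed zero). A velocity-derivative
#' tensor mirrors the momentum update so the tracked map is exactly the map
#' the optimizer applies.
#'
#' @param X numeric samples-by-features matrix.
#' @param config a \code{\link{tsne_config}}.
#' @param perplexity perplexity for affinity calibration.
#' @param seed seed for the random initialization.
#' @param track logical; track \eqn{\partial y_i/\partial x_i}.
#' @param affinity optional pre-computed \code{affinity_model} (e.g. with
#'   frozen betas); calibrated from X when NULL.
#' @param Y_init optional explicit initial embedding (overrides the seeded
#'   Gaussian draw).
#' @param V_init,G_init,Gv_init optional restart state: velocity, tracked
#'   gradient tensor and its velocity counterpart (each in engine form, a
#'   list of d' n-by-d matrices), allowing a tracked run to be continued
#'   from a checkpoint.
#' @return object of class \code{tsne_fit}: final \code{Y}; \code{G}
#'   (tracked runs: list of d' matrices, \code{G[[a]][i, f]} =
#'   \eqn{\partial y_{ia}/\partial x_{if}}); the \code{affinity} model;
#'   \code{kl} checkpoints; stored \code{trajectory}; \code{config};
#'   \code{seed}.
#' @export
tsne_fit <- function(X, config = tsne_config(), perplexity = 30, seed = 0L,
                     track = FALSE, affinity = NULL, Y_init = NULL,
                     V_init = NULL, G_init = NULL, Gv_init = NULL) {
  X <- as_data_matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  d_out <- config$d_out
  model <- if (is.null(affinity)) calibrate_affinities(X, perplexity) else affinity
  P <- model$P
  dPdX <- if (track) affinity_input_gradient(X, model)$dPdX else NULL

  if (is.null(Y_init)) {
    Y <- with_seed(seed, matrix(stats::rnorm(n * d_out, sd = 1e-4), n, d_out))
  } else {
    Y <- as.matrix(Y_init)
    stopifnot(nrow(Y) == n, ncol(Y) == d_out)
  }
  V <- if (is.null(V_init)) matrix(0, n, d_out) else as.matrix(V_init)
  gains <- matrix(1, n, d_out)
  if (track) {
    G <- if (is.null(G_init)) rep(list(matrix(0, n, d)), d_out) else G_init
    Gv <- if (is.null(Gv_init)) rep(list(matrix(0, n, d)), d_out) else Gv_init
  }
  use_bh <- !is.null(config$bh_theta)
  kl_log <- list()
  traj <- list()

  for (t in seq_len(config$n_iter)) {
    alpha <- if (t <= config$exaggeration_iters) config$exaggeration_factor else 1
    mom <- if (t <= config$momentum_switch) config$momentum else config$final_momentum

    E <- tsne_kernel(Y)
    Da <- lapply(seq_len(d_out), function(a) outer(Y[, a], Y[, a], "-"))
    if (use_bh) {
      bm <- .bh_moments(Y, config$bh_theta)
      Z <- sum(bm$Zi)
      S <- bm$S
      sumE2 <- bm$sumE2
      Tm <- bm$T
    } else {
      Z <- sum(E)
      E2 <- E * E
      S <- vapply(seq_len(d_out), function(a) rowSums(E2 * Da[[a]]), numeric(n))
      sumE2 <- rowSums(E2)
      if (track) {
        E3 <- E2 * E
        Tm <- cbind(rowSums(E3 * Da[[1]] * Da[[1]]),
                    rowSums(E3 * Da[[1]] * Da[[2]]),
                    rowSums(E3 * Da[[2]] * Da[[2]]))
        if (d_out == 3L)
          Tm <- cbind(Tm, rowSums(E3 * Da[[1]] * Da[[3]]),
                      rowSums(E3 * Da[[2]] * Da[[3]]),
                      rowSums(E3 * Da[[3]] * Da[[3]]))
      }
    }
    # KL gradient: attractive (exact, dense P) minus repulsive (S/Z)
    PE <- (alpha * P) * E
    attr_force <- vapply(seq_len(d_out),
                         function(a) rowSums(PE * Da[[a]]), numeric(n))
    grad <- 4 * (attr_force - S / Z)

    if (track) {
      # C_i = B_i - A_i, the d'xd' matrix multiplying G_i in d(grad_i)/dx_i
      pe_sum <- rowSums(PE)
      Cm <- tracked_coefficient(d_out, n, Z, S, sumE2, Tm, PE, E, Da, pe_sum)
      EDa <- lapply(Da, function(D) E * D)     # phi components
      dgrad <- vector("list", d_out)
      for (a in seq_len(d_out)) {
        Ra <- vapply(seq_len(d), function(f) rowSums(EDa[[a]] * dPdX[[f]]),
                     numeric(n)) * alpha
        acc <- Ra
        for (b in seq_len(d_out)) acc <- acc + Cm[[a]][[b]] * G[[b]]
        dgrad[[a]] <- 4 * acc
      }
      eff_lr <- if (config$use_gains) config$learning_rate * gains else
        matrix(config$learning_rate, n, d_out)
      for (a in seq_len(d_out)) {
        Gv[[a]] <- mom * Gv[[a]] - eff_lr[, a] * dgrad[[a]]
        G[[a]] <- G[[a]] + Gv[[a]]
      }
    }

    upd <- apply_update(Y, V, gains, grad, config$learning_rate, mom,
                        config$use_gains)
    Y <- upd$Y; V <- upd$velocity; gains <- upd$gains
    if (any(abs(Y) > 1e8)) stop("optimization diverged at iteration ", t)
    if (config$kl_every > 0 && (t %% config$kl_every == 0 || t == config$n_iter)) {
      Ecur <- tsne_kernel(Y)
      kl_log[[length(kl_log) + 1L]] <-
        data.frame(iteration = t, kl = kl_divergence(P, Ecur / sum(Ecur)))
    }
    if (config$store_every > 0 && t %% config$store_every == 0)
      traj[[length(traj) + 1L]] <- list(iteration = t, Y = Y)
  }

  rownames(Y) <- rownames(X)
  out <- list(Y = Y, velocity = V,
              G = if (track) G else NULL,
              Gv = if (track) Gv else NULL,
              affinity = model,
              kl = if (length(kl_log)) do.call(rbind, kl_log) else NULL,
              trajectory = traj, config = config, seed = seed,
              feature_names = colnames(X), sample_ids = rownames(X),
              tracked = track)
  class(out) <- "tsne_fit"
  out
}

# Per-sample d'xd' coefficient C_i = B_i - A_i where
#   A_i = sum_j phi_ij (dq_ij/dy_i)^T   (the chained -dq/dx term)
#   B_i = sum_j (alpha p_ij - q_ij) dphi_ij/dy_i
# Returned as Cm[[a]][[b]]: n-vectors such that the tracked update is
# dgrad_a = 4 (R_a + sum_b Cm[[a]][[b]] * G_b).
tracked_coefficient <- function(d_out, n, Z, S, sumE2, Tm, PE, E, Da, pe_sum) {
  Tidx <- if (d_out == 2L)
    matrix(c(1L, 2L, 2L, 3L), 2, 2)
  else
    matrix(c(1L, 2L, 4L, 2L, 3L, 5L, 4L, 5L, 6L), 3, 3)
  E2 <- E * E
  Cm <- vector("list", d_out)
  for (a in seq_len(d_out)) {
    Cm[[a]] <- vector("list", d_out)
    for (b in seq_len(d_out)) {
      Tab <- Tm[, Tidx[a, b]]
      Aab <- (-2 / Z) * Tab + (4 / Z^2) * S[, a] * S[, b]
      Bp <- (if (a == b) pe_sum else 0) - 2 * rowSums(PE * E * Da[[a]] * Da[[b]])
      Brep <- ((if (a == b) sumE2 else 0) - 2 * Tab) / Z
      Cm[[a]][[b]] <- (Bp - Brep) - Aab
    }
  }
  Cm
}

#' Barnes-Hut repulsive forces and normalizer
#'
#' Approximates the repulsive part of the t-SNE gradient with a quadtree:
#' returns the per-point numerator \eqn{S_i = \sum_j E_{ij}^2 (y_i - y_j)},
#' the normalizer estimate \eqn{Z = \sum_{ij} E_{ij}}, the repulsive force
#' \eqn{F_i = S_i / Z}, and the higher moments used by tracked runs.
#' \code{theta = 0} opens every cell and reproduces the exact sums.
#'
#' @param Y n-by-2 embedding.
#' @param theta opening angle in [0, 1).
#' @return list with \code{S}, \code{Z}, \code{force} (= S/Z),
#'   \code{sumE2}, \code{T} (n x 3: xx, xy, yy moments), \code{Zi}.
#' @export
bh_forces <- function(Y, theta) {
  Y <- as.matrix(Y)
  if (ncol(Y) != 2L) stop("Barnes-Hut mode supports 2-D embeddings only")
  m <- .bh_moments(Y, theta)
  Z <- sum(m$Zi)
  list(S = m$S, Z = Z, force = m$S / Z, sumE2 = m$sumE2, T = m$T, Zi = m$Zi)
}
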