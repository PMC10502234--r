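# Gradient tracking through the optimizer and the attributions derived
# from the final Jacobian blocks.

test_that("embedding-space partials match finite differences", {
  set.seed(21)
  n <- 6
  Y <- matrix(rnorm(n * 2), n, 2)
  P <- matrix(1 / (n * (n - 1)), n, n); diag(P) <- 0
  sq <- compute_step_quantities(Y, P)
  sp <- step_partials(sq, Y)
  h <- 1e-6
  for (i in seq_len(n)) for (a in 1:2) {
    Yp <- Y; Yp[i, a] <- Yp[i, a] + h
    Ym <- Y; Ym[i, a] <- Ym[i, a] - h
    sqp <- compute_step_quantities(Yp, P)
    sqm <- compute_step_quantities(Ym, P)
    for (j in seq_len(n)) {
      if (i == j) next
      expect_equal(sp$dq_dy[i, j, a],
                   (sqp$Q[i, j] - sqm$Q[i, j]) / (2 * h), tolerance = 1e-5)
      expect_equal(sp$dphi_dy[i, j, , a],
                   (sqp$Phi[i, j, ] - sqm$Phi[i, j, ]) / (2 * h),
                   tolerance = 1e-5)
    }
  }
})

test_that("dphi/dy is the identity at zero displacement", {
  Y <- rbind(c(1, 2), c(1, 2), c(0, 0), c(3, 1))
  sq <- compute_step_quantities(Y, matrix(1 / 12, 4, 4))
  sp <- step_partials(sq, Y)
  expect_equal(sp$dphi_dy[1, 2, , ], diag(2))
})

test_that("q-derivatives conserve total probability mass", {
  # sum over all ordered pairs of dq_ij/dy_k must vanish because
  # sum q = 1 identically; assembled from the i-role, j-role, and the
  # normalizer-only role of third parties
  set.seed(22)
  n <- 7
  Y <- matrix(rnorm(n * 2), n, 2)
  sq <- compute_step_quantities(Y, matrix(1 / (n * (n - 1)), n, n))
  sp <- step_partials(sq, Y)
  for (k in c(1, 4)) for (a in 1:2) {
    i_role <- sum(sp$dq_dy[k, , a])
    j_role <- sum(sp$dq_dy[k, , a])       # by symmetry q_ij = q_ji
    others <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || i == k || j == k) next
      others <- others + 4 * sp$Q[i, j] * sp$S[k, a] / sp$Z
    }
    expect_equal(i_role + j_role + others, 0, tolerance = 1e-12)
  }
})

test_that("chaining to input space is the stated matrix product", {
  # hand example: dq/dy = (1, 2), G_i = [[3, 0], [0, 5]] -> dq/dx = (3, 10)
  n <- 2; d_out <- 2; d <- 2
  partials <- structure(list(
    dq_dy = array(0, dim = c(n, n, d_out)),
    dphi_dy = array(0, dim = c(n, n, d_out, d_out))), class = "step_partials")
  partials$dq_dy[1, 2, ] <- c(1, 2)
  partials$dphi_dy[1, 2, , ] <- diag(2)
  G <- gradient_tensor(list(rbind(c(3, 0), c(0, 5)), matrix(0, 2, 2)))
  ch <- chain_to_input(partials, G)
  expect_equal(ch$dq_dx[1, 2, ], c(3, 10))
  expect_equal(ch$dphi_dx[1, 2, , ], rbind(c(3, 0), c(0, 5)))
  # zero tensor propagates zeros
  ch0 <- chain_to_input(partials, zero_gradient_tensor(n, d_out, d))
  expect_true(all(ch0$dq_dx == 0) && all(ch0$dphi_dx == 0))
  # shape mismatch is a contract violation
  expect_error(chain_to_input(partials, zero_gradient_tensor(3, 2, 2)),
               "shape")
})

test_that("the first tracked step reduces to the dP/dX outer products", {
  # from x-independent initialization G0 = 0, so at t = 1
  # G1 = -lr * 4 * sum_j (alpha dp_ij/dx_i) phi_ij^T
  set.seed(23)
  n <- 6; d <- 3
  X <- matrix(rnorm(n * d), n, d)
  model <- calibrate_affinities(X, perplexity = 3)
  dP <- affinity_input_gradient(X, model)$dPdX
  cfg <- tsne_config(n_iter = 1, learning_rate = 10, exaggeration_factor = 4,
                     exaggeration_iters = 0, kl_every = 0)
  cfgEx <- tsne_config(n_iter = 2, learning_rate = 10, exaggeration_factor = 4,
                       exaggeration_iters = 1, kl_every = 0)
  cfgEx$n_iter <- 1L   # one exaggerated step
  fit <- tsne_fit(X, cfgEx, seed = 5, track = TRUE, affinity = model)
  Y0 <- init_embedding(n, 2, 5)$Y
  sq <- compute_step_quantities(Y0, model, exaggeration = 4)
  for (i in seq_len(n)) {
    expected <- matrix(0, 2, d)
    for (j in seq_len(n)) {
      if (j == i) next
      dp <- 4 * vapply(dP, function(M) M[i, j], numeric(1))  # alpha = 4
      expected <- expected + sq$Phi[i, j, ] %o% dp
    }
    expected <- -10 * 4 * expected
    got <- rbind(fit$G[[1]][i, ], fit$G[[2]][i, ])
    expect_equal(got, expected, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("P = Q with zero dP/dX is a fixed point of the recursion", {
  set.seed(24)
  n <- 5; d <- 3
  Y <- matrix(rnorm(n * 2), n, 2)
  sq <- compute_step_quantities(Y, matrix(0, n, n))
  sq2 <- compute_step_quantities(Y, sq$Q)
  sp <- step_partials(sq2, Y)
  G <- zero_gradient_tensor(n, 2, d)
  Gv <- zero_gradient_tensor(n, 2, d)
  dP0 <- rep(list(matrix(0, n, n)), d)
  ch <- chain_to_input(sp, G)
  upd <- update_gradient_tensor(G, Gv, dP0, sq2, ch, learning_rate = 100,
                                momentum = 0.8, exaggeration = 1, P = sq$Q)
  expect_true(all(vapply(upd$G$blocks, function(B) all(B == 0), logical(1))))
})

test_that("optimized tracking equals the literal dense-loop implementation", {
  set.seed(25)
  n <- 10; d <- 4
  X <- matrix(rnorm(n * d), n, d)
  cfg <- tsne_config(n_iter = 20, learning_rate = 30,
                     exaggeration_factor = 6, exaggeration_iters = 8,
                     momentum_switch = 12, kl_every = 0)
  fit <- tsne_fit(X, cfg, perplexity = 4, seed = 3, track = TRUE)
  ref <- track_gradients_dense(X, cfg, perplexity = 4, seed = 3)
  expect_equal(fit$Y, ref$Y, tolerance = 1e-12, ignore_attr = TRUE)
  for (i in seq_len(n)) {
    got <- rbind(fit$G[[1]][i, ], fit$G[[2]][i, ])
    expect_equal(got, ref$G$blocks[[i]], tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("tracked gradients equal finite differences of the tracked map", {
  # central FD of the conditional rollout (other samples frozen at the
  # reference trajectory) -- the map the diagonal-block recursion
  # differentiates; run through both an exaggerated and a plain phase
  set.seed(26)
  n <- 10; d <- 3
  X <- matrix(rnorm(n * d), n, d)
  model <- calibrate_affinities(X, perplexity = 4)
  cfg <- tsne_config(n_iter = 30, learning_rate = 100,
                     exaggeration_factor = 12, exaggeration_iters = 12,
                     momentum_switch = 15, kl_every = 0)
  fit <- tsne_fit(X, cfg, seed = 4, track = TRUE, affinity = model)
  FD <- rollout_fd_gradient(X, model, cfg, seed = 4, h = 1e-7)
  G <- array(0, dim = c(n, 2, d))
  for (a in 1:2) G[, a, ] <- fit$G[[a]]
  expect_lt(max(abs(G - FD)) / max(abs(FD)), 1e-4)
})

test_that("attribution variants follow their definitions", {
  G <- list(rbind(c(3, 0), c(1, -2)), rbind(c(0, 5), c(2, 4)))
  fit <- list(Y = rbind(c(1, 0), c(0, 0)), G = G,
              sample_ids = c("s1", "s2"), feature_names = c("f1", "f2"))
  A <- attributions(fit, center = FALSE)
  # y = (1, 0): A = 2 * y^T G = 2 * G[1, ] of the first component block
  expect_equal(unname(A$A[1, ]), c(6, 0))
  # y = (0, 0): zero attribution regardless of G
  expect_equal(unname(A$A[2, ]), c(0, 0))
  Apos <- attributions(list(Y = rbind(c(-1, 0), c(0, 0)), G = G), center = FALSE,
                       variant = "positive_only")
  expect_equal(unname(Apos$A[1, ]), c(0, 0))   # raw (-6, 0) clipped
  Agi <- attributions(c(fit, list(X = rbind(c(-2, 7), c(1, 1)))),
                      center = FALSE, variant = "grad_times_input")
  expect_equal(unname(Agi$A[1, ]), c(12, 0))
  expect_error(attributions(fit, variant = "nope"))
  expect_error(attributions(list(Y = fit$Y, G = NULL)), "track")
})

test_that("PCA back-projection multiplies by the loadings", {
  A <- structure(list(A = matrix(5, 1, 1), variant = "raw", space = "native",
                      centering = "centroid"), class = "attribution_matrix")
  out <- project_attributions(A, matrix(c(0.6, 0.8), 1, 2))
  expect_equal(unname(out$A), matrix(c(3, 4), 1, 2))
  expect_equal(out$space, "pca_backprojected")
  # identity loadings change nothing
  A2 <- structure(list(A = matrix(rnorm(6), 2, 3), variant = "raw",
                       space = "native", centering = "centroid"),
                  class = "attribution_matrix")
  expect_equal(project_attributions(A2, diag(3))$A, A2$A)
  # orthonormal loadings preserve per-sample norms
  Qm <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  out2 <- project_attributions(A2, Qm)
  expect_equal(sqrt(rowSums(out2$A^2)), sqrt(rowSums(A2$A^2)))
  expect_error(project_attributions(out2, diag(3)), "back-projected")
  expect_error(project_attributions(A2, diag(4)), "loadings")
})

test_that("group aggregation is |mean|, not mean of |.|", {
  A <- rbind(c(1, -3), c(-1, -3), c(2, 2))
  labels <- c("g1", "g1", "g2")
  M <- aggregate_by_group(A, labels)
  expect_equal(unname(M["g1", ]), c(0, 3))     # cancellation then abs
  expect_equal(unname(M["g2", ]), c(2, 2))     # single member: |A_i|
  # loop oracle on a random instance
  set.seed(27)
  A2 <- matrix(rnorm(40), 10, 4)
  lab2 <- sample(c("a", "b", "c"), 10, replace = TRUE)
  M2 <- aggregate_by_group(A2, lab2)
  for (g in unique(lab2)) for (f in 1:4) {
    vals <- A2[lab2 == g, f]
    expect_equal(unname(M2[g, f]), abs(mean(vals)))
  }
  expect_warning(aggregate_by_group(A, factor(labels, levels = c("g1", "g2", "g3"))),
                 "empty")
  expect_error(aggregate_by_group(A, c("g1", "g2")), "label")
})
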