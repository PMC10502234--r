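# Attribution tracking: the per-sample Jacobian blocks G_i = dy_i/dx_i and
# the feature attributions derived from them.
#
# Two implementations coexist on purpose. tsne_fit(track = TRUE) advances G
# with fully vectorized arithmetic; the exported granular operations below
# (step_partials, chain_to_input, update_gradient_tensor) are a literal
# dense-loop transcription of the recursion, and track_gradients_dense()
# runs the whole pipeline through them. The two must agree to within
# floating-point accumulation error, which the test-suite enforces.

#' Construct a gradient tensor
#'
#' @param blocks list of n matrices, each d'-by-d, holding
#'   \eqn{\partial y_i / \partial x_i}. Off-diagonal blocks
#'   \eqn{\partial y_i/\partial x_j} are identically zero by assumption and
#'   never stored.
#' @param iteration iteration the tensor belongs to.
#' @return object of class \code{gradient_tensor}.
#' @export
gradient_tensor <- function(blocks, iteration = 0L) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  structure(list(blocks = blocks, iteration = as.integer(iteration)),
            class = "gradient_tensor")
}

#' Zero-initialized gradient tensor
#' @param n,d_out,d dimensions.
#' @export
#' @rdname gradient_tensor
zero_gradient_tensor <- function(n, d_out, d) {
  gradient_tensor(rep(list(matrix(0, d_out, d)), n), iteration = 0L)
}

# engine representation (list over embedding components of n-by-d matrices)
# <-> block representation (list over samples of d'-by-d matrices)
blocks_from_components <- function(Gcomp) {
  d_out <- length(Gcomp)
  n <- nrow(Gcomp[[1]])
  lapply(seq_len(n), function(i)
    do.call(rbind, lapply(seq_len(d_out), function(a) Gcomp[[a]][i, ])))
}

components_from_blocks <- function(blocks) {
  d_out <- nrow(blocks[[1]])
  lapply(seq_len(d_out), function(a)
    t(vapply(blocks, function(B) B[a, ], numeric(ncol(blocks[[1]])))))
}

#' Embedding-space partials of q and phi
#'
#' Computes, for every ordered pair (i, j), the exact partial derivatives
#' \eqn{\partial q_{ij}/\partial y_i} (including the dependence through the
#' global normalizer Z) and \eqn{\partial \phi_{ij}/\partial y_i}.
#'
#' @param quantities a \code{\link{compute_step_quantities}} result.
#' @param Y the embedding it was computed from.
#' @return list of class \code{step_partials}: \code{dq_dy}
#'   (n x n x d'), \code{dphi_dy} (n x n x d' x d'), plus the moments
#'   \code{S} (\eqn{\sum_j E^2 \Delta}) and \code{Z} needed to assemble
#'   third-party roles \eqn{\partial q_{ij}/\partial y_k}, k not in (i,j).
#' @export
step_partials <- function(quantities, Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  d_out <- ncol(Y)
  E <- quantities$E
  Z <- quantities$Z
  Q <- quantities$Q
  Da <- lapply(seq_len(d_out), function(a) outer(Y[, a], Y[, a], "-"))
  S <- vapply(seq_len(d_out), function(a) rowSums(E^2 * Da[[a]]), numeric(n))
  dq_dy <- array(0, dim = c(n, n, d_out))
  for (a in seq_len(d_out)) {
    M <- (-2 * E^2 * Da[[a]] + 4 * Q * S[, a]) / Z
    diag(M) <- 0
    dq_dy[, , a] <- M
  }
  dphi_dy <- array(0, dim = c(n, n, d_out, d_out))
  for (a in seq_len(d_out)) for (b in seq_len(d_out)) {
    M <- (if (a == b) E else 0) - 2 * E^2 * Da[[a]] * Da[[b]]
    diag(M) <- 0
    dphi_dy[, , a, b] <- M
  }
  structure(list(dq_dy = dq_dy, dphi_dy = dphi_dy, S = S, Z = Z, Q = Q, E = E),
            class = "step_partials")
}

#' Chain embedding-space partials to input space
#'
#' Matrix products \eqn{\partial q_{ij}/\partial x_i =
#' (\partial q_{ij}/\partial y_i)\,G_i} and likewise for \eqn{\phi},
#' using only the stored diagonal block \eqn{G_i = \partial y_i/\partial x_i}
#' (cross-sample blocks are zero by assumption).
#'
#' @param partials a \code{\link{step_partials}} result.
#' @param G a \code{\link{gradient_tensor}} at the previous iteration.
#' @return list with \code{dq_dx} (n x n x d) and \code{dphi_dx}
#'   (n x n x d' x d).
#' @export
chain_to_input <- function(partials, G) {
  stopifnot(inherits(G, "gradient_tensor"))
  n <- dim(partials$dq_dy)[1]
  d_out <- dim(partials$dq_dy)[3]
  d <- ncol(G$blocks[[1]])
  if (length(G$blocks) != n || nrow(G$blocks[[1]]) != d_out)
    stop("gradient tensor shape does not match the step partials")
  dq_dx <- array(0, dim = c(n, n, d))
  dphi_dx <- array(0, dim = c(n, n, d_out, d))
  for (i in seq_len(n)) {
    Gi <- G$blocks[[i]]
    for (j in seq_len(n)) {
      if (i == j) next
      dq_dx[i, j, ] <- as.numeric(partials$dq_dy[i, j, ] %*% Gi)
      dphi_dx[i, j, , ] <- matrix(partials$dphi_dy[i, j, , ], d_out, d_out) %*% Gi
    }
  }
  list(dq_dx = dq_dx, dphi_dx = dphi_dx)
}

#' Advance the gradient tensor through one optimizer step
#'
#' Literal dense-loop implementation of the dynamic-programming recursion:
#' \deqn{\partial dy_i/\partial x_i = 4\sum_{j\neq i}
#'   [(\partial p_{ij}/\partial x_i - \partial q_{ij}/\partial x_i)\,
#'    \phi_{ij}^{\top} + (p_{ij} - q_{ij})\,\partial\phi_{ij}/\partial x_i]}
#' followed by the same momentum arithmetic the optimizer applies to the
#' embedding (a velocity-derivative tensor Gv mirrors the velocity).
#'
#' @param G,Gv gradient tensor and its velocity counterpart at t-1.
#' @param dPdX the \code{dPdX} list from
#'   \code{\link{affinity_input_gradient}}.
#' @param quantities step quantities at t-1 (with exaggeration applied via
#'   the \code{exaggeration} argument, not baked into P).
#' @param chained output of \code{\link{chain_to_input}}.
#' @param learning_rate,momentum optimizer constants for this step.
#' @param exaggeration early-exaggeration factor for this step; multiplies
#'   both P and dP/dX.
#' @param P joint affinity matrix (unexaggerated).
#' @return list with advanced \code{G}, \code{Gv} and the per-sample
#'   \code{dgrad} blocks.
#' @export
update_gradient_tensor <- function(G, Gv, dPdX, quantities, chained,
                                   learning_rate, momentum, exaggeration = 1,
                                   P) {
  stopifnot(inherits(G, "gradient_tensor"), inherits(Gv, "gradient_tensor"))
  if (G$iteration != Gv$iteration)
    stop("gradient tensor and velocity tensor are at different iterations")
  n <- length(G$blocks)
  d_out <- nrow(G$blocks[[1]])
  d <- ncol(G$blocks[[1]])
  Q <- quantities$Q
  Phi <- quantities$Phi
  newG <- G$blocks
  newGv <- Gv$blocks
  dgrad <- vector("list", n)
  for (i in seq_len(n)) {
    acc <- matrix(0, d_out, d)
    for (j in seq_len(n)) {
      if (i == j) next
      dp_ij <- exaggeration * vapply(dPdX, function(M) M[i, j], numeric(1))
      term1 <- Phi[i, j, ] %o% (dp_ij - chained$dq_dx[i, j, ])
      term2 <- (exaggeration * P[i, j] - Q[i, j]) *
        matrix(chained$dphi_dx[i, j, , ], d_out, d)
      acc <- acc + term1 + term2
    }
    dgrad[[i]] <- 4 * acc
    newGv[[i]] <- momentum * newGv[[i]] - learning_rate * dgrad[[i]]
    newG[[i]] <- newG[[i]] + newGv[[i]]
  }
  list(G = gradient_tensor(newG, G$iteration + 1L),
       Gv = gradient_tensor(newGv, Gv$iteration + 1L),
       dgrad = dgrad)
}

#' Dense-loop reference tracker
#'
#' Runs the full t-SNE optimization while advancing the gradient tensor
#' through the exported granular operations only. Slow by construction;
#' serves as the reference the optimized tracker in
#' \code{\link{tsne_fit}} is checked against.
#'
#' @inheritParams tsne_fit
#' @return list with \code{Y}, \code{G} (a \code{gradient_tensor}),
#'   \code{affinity}.
#' @export
track_gradients_dense <- function(X, config = tsne_config(), perplexity = 30,
                                  seed = 0L, affinity = NULL, Y_init = NULL) {
  X <- as_data_matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  d_out <- config$d_out
  model <- if (is.null(affinity)) calibrate_affinities(X, perplexity) else affinity
  P <- model$P
  dPdX <- affinity_input_gradient(X, model)$dPdX
  state <- init_embedding(n, d_out, seed)
  if (!is.null(Y_init)) state$Y <- as.matrix(Y_init)
  G <- zero_gradient_tensor(n, d_out, d)
  Gv <- zero_gradient_tensor(n, d_out, d)
  for (t in seq_len(config$n_iter)) {
    alpha <- if (t <= config$exaggeration_iters) config$exaggeration_factor else 1
    mom <- if (t <= config$momentum_switch) config$momentum else config$final_momentum
    sq <- compute_step_quantities(state$Y, P, exaggeration = alpha)
    partials <- step_partials(sq, state$Y)
    chained <- chain_to_input(partials, G)
    upd <- update_gradient_tensor(G, Gv, dPdX, sq, chained,
                                  config$learning_rate, mom,
                                  exaggeration = alpha, P = P)
    G <- upd$G
    Gv <- upd$Gv
    state <- tsne_step(state, sq, config)
  }
  list(Y = state$Y, G = G, Gv = Gv, affinity = model)
}

#' Per-sample feature attributions from a tracked fit
#'
#' The raw attribution of sample i is the gradient of its squared distance
#' from the embedding centroid: \eqn{A_i = 2\,(y_i - \bar y)^\top G_i}, a
#' length-d row vector. The centroid is treated as the (fixed) origin; this
#' makes the score translation-consistent and is recorded in the output.
#'
#' @param fit a \code{\link{tsne_fit}} run with \code{track = TRUE}, or a
#'   list with elements \code{Y}, \code{G} (engine or block form) and
#'   \code{X}.
#' @param X the input matrix (required for the \code{grad_times_input}
#'   variant when not stored in \code{fit}).
#' @param variant \code{"raw"} (signed gradients), \code{"positive_only"}
#'   (negative entries zeroed), or \code{"grad_times_input"}
#'   (\eqn{|A \circ x|}).
#' @param center subtract the embedding centroid before taking
#'   \eqn{\|y\|^2} (default TRUE).
#' @return object of class \code{attribution_matrix}: list with the n-by-d
#'   matrix \code{A}, \code{variant}, \code{space = "native"} and the
#'   centering convention.
#' @export
attributions <- function(fit, X = NULL,
                         variant = c("raw", "positive_only", "grad_times_input"),
                         center = TRUE) {
  variant <- match.arg(variant)
  Y <- as.matrix(fit$Y)
  G <- fit$G
  if (is.null(G)) stop("fit has no tracked gradients; rerun with track = TRUE")
  if (inherits(G, "gradient_tensor")) G <- components_from_blocks(G$blocks)
  d_out <- length(G)
  Yc <- if (center) sweep(Y, 2, colMeans(Y)) else Y
  A <- 2 * Reduce(`+`, lapply(seq_len(d_out), function(a) Yc[, a] * G[[a]]))
  if (variant == "positive_only") {
    A[A < 0] <- 0
  } else if (variant == "grad_times_input") {
    if (is.null(X)) X <- fit$X
    if (is.null(X)) stop("grad_times_input needs the input matrix X")
    A <- abs(A * as.matrix(X))
  }
  rownames(A) <- fit$sample_ids %||% rownames(Y)
  colnames(A) <- fit$feature_names %||% colnames(A)
  structure(list(A = A, variant = variant, space = "native",
                 centering = if (center) "centroid" else "origin"),
            class = "attribution_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Back-project attributions through PCA loadings
#'
#' When t-SNE was fit on principal-component scores, attributions live in
#' PC space; multiplying by the loadings maps them back to the original
#' features.
#'
#' @param A an \code{attribution_matrix} in native (PC) space.
#' @param loadings d_pc-by-d_orig matrix (rows = components the fit used).
#' @return an \code{attribution_matrix} with \code{space =
#'   "pca_backprojected"}.
#' @export
project_attributions <- function(A, loadings) {
  stopifnot(inherits(A, "attribution_matrix"))
  if (A$space != "native")
    stop("attributions are already back-projected")
  loadings <- as.matrix(loadings)
  if (ncol(A$A) != nrow(loadings))
    stop("loadings have ", nrow(loadings), " rows but attributions have ",
         ncol(A$A), " features")
  Ap <- A$A %*% loadings
  rownames(Ap) <- rownames(A$A)
  structure(list(A = Ap, variant = A$variant, space = "pca_backprojected",
                 centering = A$centering),
            class = "attribution_matrix")
}

#' Group-averaged absolute attributions
#'
#' Per group, the absolute value of the mean attribution over member
#' samples (not the mean of absolute values), the aggregation used both
#' for cluster-level summaries and lineage-level marker scores.
#'
#' @param A an \code{attribution_matrix} or a plain n-by-d matrix.
#' @param labels group id per sample.
#' @return groups-by-d matrix, rownames = group ids (sorted).
#' @export
aggregate_by_group <- function(A, labels) {
  M <- if (inherits(A, "attribution_matrix")) A$A else as.matrix(A)
  if (length(labels) != nrow(M))
    stop("need one label per sample (", nrow(M), " samples, ",
         length(labels), " labels)")
  labels <- as.factor(labels)
  empty <- setdiff(levels(labels), unique(as.character(labels)))
  if (length(empty))
    warning("excluding empty group(s): ", paste(empty, collapse = ", "))
  labels <- droplevels(labels)
  counts <- as.vector(table(labels))
  abs(rowsum(M, labels) / counts)
}
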