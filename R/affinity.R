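# Input-space affinities and their input gradients.
#
# The affinity model is the standard perplexity-calibrated Gaussian kernel:
# conditionals p_{j|i} with per-point precision beta_i = 1/(2 sigma_i^2)
# found by bisection so that 2^H(p_{.|i}) equals the requested perplexity,
# then symmetrized to p_ij = (p_{j|i} + p_{i|j}) / (2n).

#' Validate a samples-by-features data matrix
#'
#' @param X numeric matrix, samples in rows, features in columns. Row and
#'   column names are used as sample ids / feature names; defaults are
#'   generated when absent.
#' @param min_n minimum number of rows required.
#' @return the validated matrix with dimnames filled in.
#' @keywords internal
as_data_matrix <- function(X, min_n = 4L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < min_n)
    stop("data matrix needs at least ", min_n, " samples, got ", nrow(X))
  if (ncol(X) < 1L) stop("data matrix needs at least one feature")
  if (!all(is.finite(X))) stop("data matrix contains missing or non-finite values")
  if (is.null(rownames(X))) rownames(X) <- paste0("s", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X))) stop("feature names must be unique")
  X
}

# squared Euclidean distance matrix (zero diagonal, symmetric)
sq_dists <- function(X) {
  s <- rowSums(X^2)
  D <- outer(s, s, "+") - 2 * tcrossprod(X)
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

# Shannon entropy (bits) and conditional row for one point at precision beta.
# d2 excludes the self distance.
row_conditional <- function(d2, beta) {
  w <- exp(-beta * (d2 - min(d2)))   # shift for numerical stability
  p <- w / sum(w)
  p
}

row_entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Calibrate perplexity-matched input affinities
#'
#' Finds per-point precisions \eqn{\beta_i} by bisection so that the
#' conditional distribution over neighbours of each point has
#' \eqn{2^{H} = } \code{perplexity}, then symmetrizes to the joint
#' matrix \eqn{p_{ij} = (p_{j|i} + p_{i|j})/(2n)}.
#'
#' @param X numeric samples-by-features matrix.
#' @param perplexity target perplexity, in (1, n-1].
#' @param tol tolerance on the entropy match, |2^H - perplexity| < tol.
#' @param max_iter maximum bisection iterations per point.
#' @return an object of class \code{affinity_model}: list with the joint
#'   matrix \code{P} (symmetric, zero diagonal, off-diagonal sum 1), the
#'   conditional matrix \code{P_cond} (row i = p_{.|i}), \code{betas},
#'   and the calibration settings.
#' @export
calibrate_affinities <- function(X, perplexity = 30, tol = 1e-5, max_iter = 200L) {
  X <- as_data_matrix(X, min_n = 3L)
  n <- nrow(X)
  if (!is.finite(perplexity) || perplexity <= 1 || perplexity > n - 1)
    stop("perplexity must lie in (1, n-1]; got ", perplexity, " with n = ", n)

  D <- sq_dists(X)
  P_cond <- matrix(0, n, n)
  betas <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- D[i, -i]
    beta <- 1
    beta_lo <- 0
    beta_hi <- Inf
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      p <- row_conditional(d2, beta)
      gap <- 2^row_entropy_bits(p) - perplexity
      if (abs(gap) < tol) { ok <- TRUE; break }
      if (gap > 0) {        # too smooth: increase precision
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta_lo + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- (beta_lo + beta_hi) / 2
      }
    }
    if (!ok)
      stop("perplexity calibration did not converge for sample ", i,
           " (row '", rownames(X)[i], "'): duplicate or degenerate neighbourhood?")
    betas[i] <- beta
    P_cond[i, -i] <- p
  }
  P_cond[P_cond < 1e-12 & P_cond > 0] <- 1e-12
  P_cond[row(P_cond) != col(P_cond) & P_cond == 0] <- 1e-12
  P_cond <- P_cond / rowSums(P_cond)    # renormalize after flooring
  diag(P_cond) <- 0
  P <- (P_cond + t(P_cond)) / (2 * n)
  structure(list(P = P, P_cond = P_cond, betas = betas,
                 perplexity = perplexity, tol = tol,
                 sample_ids = rownames(X)),
            class = "affinity_model")
}

#' Recompute joint affinities with frozen precisions
#'
#' Evaluates the conditional and joint affinities on (possibly perturbed)
#' data while holding the per-point precisions fixed. This is the map that
#' the analytic input gradient differentiates, and the map finite-difference
#' oracles must perturb.
#'
#' @param X numeric samples-by-features matrix.
#' @param betas per-point precisions (from \code{calibrate_affinities}).
#' @return an \code{affinity_model} with the supplied betas.
#' @export
affinities_from_betas <- function(X, betas) {
  X <- as_data_matrix(X, min_n = 3L)
  n <- nrow(X)
  stopifnot(length(betas) == n)
  D <- sq_dists(X)
  Doff <- D
  diag(Doff) <- Inf
  shift <- apply(Doff, 1, min)         # per-row shift; cancels in normalization
  W <- exp(-betas * (D - shift))       # beta_i, shift_i recycle down rows
  diag(W) <- 0
  P_cond <- W / rowSums(W)
  P <- (P_cond + t(P_cond)) / (2 * n)
  structure(list(P = P, P_cond = P_cond, betas = betas,
                 perplexity = NA_real_, tol = NA_real_,
                 sample_ids = rownames(X)),
            class = "affinity_model")
}

#' Analytic gradient of the joint affinities with respect to the inputs
#'
#' Computes, for every ordered pair (i, j), the row vector
#' \eqn{\partial p_{ij} / \partial x_i} with the precisions \eqn{\beta}
#' held constant (the calibration root-find is not differentiated).
#' Both appearances of \eqn{x_i} are accounted for: the numerator and
#' normalizer of its own conditional row \eqn{p_{j|i}} and the numerator
#' and normalizer of row j's conditional \eqn{p_{i|j}}.
#'
#' @param X the matrix the model was calibrated on.
#' @param model an \code{affinity_model}.
#' @return object of class \code{affinity_gradient}: list with
#'   \code{dPdX}, a list of length d of n-by-n matrices
#'   (\code{dPdX[[f]][i, j]} is \eqn{\partial p_{ij} / \partial x_{if}}),
#'   and \code{betas_frozen = TRUE}.
#' @export
affinity_input_gradient <- function(X, model) {
  X <- as_data_matrix(X, min_n = 3L)
  n <- nrow(X)
  d <- ncol(X)
  if (n < 3) stop("input gradient undefined for n < 3 (degenerate normalizer)")
  stopifnot(inherits(model, "affinity_model"), nrow(model$P) == n)
  Pc <- model$P_cond
  betas <- model$betas
  Mu <- Pc %*% X                       # mu_i = sum_k p_{k|i} x_k
  A1 <- (2 * betas) * Pc               # 2 beta_i p_{j|i}
  Qj <- t(Pc)                          # Qj[i,j] = p_{i|j}
  A2 <- Qj * (1 - Qj) * matrix(2 * betas, n, n, byrow = TRUE)  # 2 beta_j p_{i|j}(1-p_{i|j})
  dPdX <- vector("list", d)
  for (f in seq_len(d)) {
    xf <- X[, f]
    Xj <- matrix(xf, n, n, byrow = TRUE)           # x_j[f]
    term1 <- A1 * (Xj - Mu[, f])                   # 2 b_i p_{j|i} (x_j - mu_i)
    term2 <- A2 * (xf - Xj)                        # 2 b_j p_{i|j}(1-p_{i|j})(x_i - x_j)
    Df <- (term1 - term2) / (2 * n)
    diag(Df) <- 0
    dPdX[[f]] <- Df
  }
  names(dPdX) <- colnames(X)
  structure(list(dPdX = dPdX, betas_frozen = TRUE,
                 feature_names = colnames(X), sample_ids = rownames(X)),
            class = "affinity_gradient")
}
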