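# Synthetic cluster data with known ground-truth feature dependencies.
#
# Clusters are defined purely by translation: every sample is isotropic
# Gaussian noise, and each non-null cluster has a small, disjoint subset of
# features shifted by a fixed amount. One cluster is left untranslated (the
# null cluster), so any structure t-SNE finds for it comes from the other
# clusters' defining features.

#' Specification of a synthetic cluster dataset
#'
#' Defaults correspond to the reference study conditions used throughout
#' the test-suite: 4 clusters of 75 samples, 30 features, 5 defining
#' features per non-null cluster, translation 6, unit noise.
#'
#' @param n_per_cluster samples per cluster.
#' @param n_clusters number of clusters (first cluster is the null cluster
#'   with no translated features).
#' @param d number of features.
#' @param features_per_cluster defining features per non-null cluster.
#' @param shift translation applied to defining features.
#' @param noise_sd standard deviation of the Gaussian base noise.
#' @param seed RNG seed.
#' @param hierarchical if TRUE, consecutive non-null clusters additionally
#'   share one translated feature, inducing super-cluster structure. Note
#'   this relaxes the disjointness of the defining subsets; default FALSE.
#' @return list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_per_cluster = 75L, n_clusters = 4L, d = 30L,
                           features_per_cluster = 5L, shift = 6,
                           noise_sd = 1, seed = 0L, hierarchical = FALSE) {
  stopifnot(n_per_cluster >= 1, n_clusters >= 2, d >= 1,
            features_per_cluster >= 1, shift >= 0, noise_sd > 0)
  if (features_per_cluster * (n_clusters - 1) > d)
    stop("not enough features: need features_per_cluster * (n_clusters - 1) <= d")
  structure(list(n_per_cluster = as.integer(n_per_cluster),
                 n_clusters = as.integer(n_clusters), d = as.integer(d),
                 features_per_cluster = as.integer(features_per_cluster),
                 shift = shift, noise_sd = noise_sd, seed = as.integer(seed),
                 hierarchical = isTRUE(hierarchical)),
            class = "synthetic_spec")
}

#' Generate a synthetic cluster dataset
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list of class \code{synthetic_dataset}: \code{X} (n-by-d matrix),
#'   \code{labels} (integer cluster ids, 1 = null cluster), \code{truth}
#'   (list mapping cluster to its defining feature indices), \code{spec}.
#' @export
generate_clusters <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  K <- spec$n_clusters
  npc <- spec$n_per_cluster
  n <- K * npc
  d <- spec$d
  fpc <- spec$features_per_cluster
  labels <- rep(seq_len(K), each = npc)
  truth <- vector("list", K)
  truth[[1]] <- integer(0)                     # null cluster
  for (k in seq_len(K - 1))
    truth[[k + 1]] <- ((k - 1) * fpc + 1):(k * fpc)
  if (spec$hierarchical && K >= 4) {
    # consecutive non-null clusters share the first feature of the pair
    for (k in seq(2, K - 1, by = 2)) {
      if (k + 1 <= K) truth[[k + 1]] <- union(truth[[k + 1]], truth[[k]][1])
    }
  }
  X <- with_seed(spec$seed, matrix(stats::rnorm(n * d, 0, spec$noise_sd), n, d))
  for (k in seq_len(K)) {
    if (length(truth[[k]]))
      X[labels == k, truth[[k]]] <- X[labels == k, truth[[k]]] + spec$shift
  }
  rownames(X) <- paste0("s", seq_len(n))
  colnames(X) <- paste0("f", seq_len(d))
  names(truth) <- paste0("cluster", seq_len(K))
  structure(list(X = X, labels = labels, truth = truth, spec = spec),
            class = "synthetic_dataset")
}

# Mann-Whitney AUROC of `scores` as a classifier of `positive` membership
auroc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Score attribution recovery of ground-truth features
#'
#' Aggregates attributions per cluster (absolute value of the mean) and
#' asks how well the aggregated scores separate each cluster's defining
#' features from the rest: Wilcoxon rank-sum p-value, AUROC, and the
#' fraction of defining features found in the top decile. The null cluster
#' has no defining features of its own and is tested against the union of
#' all clusters' defining features.
#'
#' @param A an \code{attribution_matrix} computed on \code{data$X}.
#' @param data a \code{\link{generate_clusters}} result.
#' @return data.frame of class \code{recovery_summary} with one row per
#'   cluster: \code{cluster}, \code{n_truth}, \code{auroc},
#'   \code{p_value}, \code{top_decile_frac}.
#' @export
score_recovery <- function(A, data) {
  stopifnot(inherits(data, "synthetic_dataset"))
  M <- aggregate_by_group(A, data$labels)
  d <- ncol(M)
  truth_union <- sort(unique(unlist(data$truth)))
  k_top <- ceiling(0.1 * d)
  rows <- lapply(seq_len(nrow(M)), function(k) {
    scores <- M[k, ]
    tf <- data$truth[[k]]
    if (!length(tf)) tf <- truth_union   # null cluster vs all defining features
    pos <- seq_len(d) %in% tf
    top <- order(-scores, seq_len(d))[seq_len(k_top)]
    pv <- tryCatch(
      stats::wilcox.test(scores[pos], scores[!pos],
                         alternative = "greater", exact = FALSE)$p.value,
      error = function(e) NA_real_)
    data.frame(cluster = k, n_truth = length(data$truth[[k]]),
               auroc = auroc(scores, pos), p_value = pv,
               top_decile_frac = mean(tf %in% top))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("recovery_summary", "data.frame")
  out
}
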