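# Corruption-based validation of feature attributions.
#
# The logic: if an attribution method finds the features that drive an
# embedding, corrupting those features should degrade a refit embedding
# more than corrupting a random subset of the same size. Degradation is
# measured against the uncorrupted reference embedding with three metrics
# (pairwise-distance Spearman, K-means ARI, 10-NN preservation), each equal
# to 1 when nothing changed.

round_count <- function(fraction, d) {
  k <- round(fraction * d)
  if (k < 1)
    stop("fraction ", fraction, " selects no features (d = ", d, ")")
  as.integer(min(k, d))
}

top_k <- function(scores, k) sort(order(-abs(scores), seq_along(scores))[seq_len(k)])

#' Select features to corrupt
#'
#' Local level: per sample, the top \code{round(fraction * d)} features by
#' absolute score. Class/global level: features are ranked by how often
#' they appear in member samples' top sets, and the most frequent
#' \code{round(fraction * d)} are kept (ties broken by ascending feature
#' index). When \code{scores} is a single importance vector (a global
#' baseline), the top features are taken directly.
#'
#' @param scores an \code{attribution_matrix}, an n-by-d matrix of
#'   per-sample scores, or a length-d importance vector (larger = more
#'   important).
#' @param level one of \code{"local"}, \code{"class"}, \code{"global"}.
#' @param fraction fraction of features to corrupt, in (0, 1].
#' @param labels class labels (required for \code{level = "class"}).
#' @param method corruption method recorded in the plan: \code{"mean"},
#'   \code{"permute"}, or \code{"remove"} (global only).
#' @return list of class \code{corruption_plan}: \code{level},
#'   \code{method}, \code{fraction}, \code{selected} (per-sample list /
#'   per-class list / single integer vector), \code{labels}, \code{d}.
#' @export
select_features <- function(scores, level = c("local", "class", "global"),
                            fraction, labels = NULL,
                            method = c("mean", "permute", "remove")) {
  level <- match.arg(level)
  method <- match.arg(method)
  if (method == "remove" && level != "global")
    stop("'remove' corruption is only defined at the global level")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  M <- if (inherits(scores, "attribution_matrix")) scores$A else scores
  if (is.null(dim(M))) {                     # plain importance vector
    d <- length(M)
    k <- round_count(fraction, d)
    if (level == "class") {
      if (is.null(labels)) stop("class-level selection requires labels")
      sel <- lapply(split(seq_along(labels), labels), function(ignored) top_k(M, k))
    } else {
      sel <- top_k(M, k)
      if (level == "local") stop("local-level selection needs per-sample scores")
    }
  } else {
    M <- as.matrix(M)
    d <- ncol(M)
    k <- round_count(fraction, d)
    per_sample <- lapply(seq_len(nrow(M)), function(i) top_k(M[i, ], k))
    if (level == "local") {
      sel <- per_sample
    } else if (level == "class") {
      if (is.null(labels)) stop("class-level selection requires labels")
      if (length(labels) != nrow(M)) stop("need one label per sample")
      sel <- lapply(split(per_sample, labels), function(sets) {
        freq <- tabulate(unlist(sets), nbins = d)
        sort(order(-freq, seq_len(d))[seq_len(k)])
      })
    } else {
      freq <- tabulate(unlist(per_sample), nbins = d)
      sel <- sort(order(-freq, seq_len(d))[seq_len(k)])
    }
  }
  structure(list(level = level, method = method, fraction = fraction,
                 selected = sel, labels = labels, d = d),
            class = "corruption_plan")
}

# n-by-d logical matrix of cells to corrupt, plus the unit id per sample
plan_cells <- function(plan, n) {
  sel <- matrix(FALSE, n, plan$d)
  if (plan$level == "local") {
    if (length(plan$selected) != n) stop("plan does not match the matrix")
    for (i in seq_len(n)) sel[i, plan$selected[[i]]] <- TRUE
    unit <- rep("all", n)
  } else if (plan$level == "class") {
    labs <- as.character(plan$labels)
    if (length(labs) != n) stop("plan does not match the matrix")
    for (g in names(plan$selected)) sel[labs == g, plan$selected[[g]]] <- TRUE
    unit <- labs
  } else {
    sel[, plan$selected] <- TRUE
    unit <- rep("all", n)
  }
  list(sel = sel, unit = unit)
}

#' Apply a corruption plan to a data matrix
#'
#' \code{mean}: each selected cell is replaced by the mean of the selected
#' cells of that feature within the corruption unit (the class at class
#' level, the whole dataset otherwise). \code{permute}: the selected cells
#' of each feature are shuffled among themselves within the unit (seeded).
#' \code{remove}: the selected feature columns are dropped (global level
#' only).
#'
#' @param X data matrix the plan was built for.
#' @param plan a \code{\link{select_features}} plan.
#' @param seed seed for the permutation method.
#' @return the corrupted matrix (fewer columns under \code{remove}).
#' @export
corrupt <- function(X, plan, seed = 0L) {
  stopifnot(inherits(plan, "corruption_plan"))
  X <- as.matrix(X)
  if (ncol(X) != plan$d) stop("plan was built for ", plan$d, " features")
  n <- nrow(X)
  if (plan$method == "remove")
    return(X[, -plan$selected, drop = FALSE])
  pc <- plan_cells(plan, n)
  out <- X
  if (plan$method == "mean") {
    for (u in unique(pc$unit)) {
      rows <- which(pc$unit == u)
      for (f in seq_len(ncol(X))) {
        cells <- rows[pc$sel[rows, f]]
        if (length(cells)) out[cells, f] <- mean(X[cells, f])
      }
    }
  } else {  # permute
    with_seed(seed, {
      for (u in unique(pc$unit)) {
        rows <- which(pc$unit == u)
        for (f in seq_len(ncol(X))) {
          cells <- rows[pc$sel[rows, f]]
          if (length(cells) > 1) out[cells, f] <- X[sample(cells), f]
        }
      }
    })
  }
  out
}

#' Spearman correlation of pairwise embedding distances
#'
#' Rank correlation over all n(n-1)/2 pairwise Euclidean distances before
#' and after corruption; 1 when the (rank) geometry is unchanged. Beyond
#' \code{max_pairs} pairs a seeded subsample is used.
#'
#' @param Y_before,Y_after embeddings with matching rows.
#' @param max_pairs pair budget before subsampling (default 10^6 pairs,
#'   reached around n = 1415).
#' @param seed subsampling seed.
#' @return Spearman rho in [-1, 1].
#' @export
metric_spearman <- function(Y_before, Y_after, max_pairs = 1e6, seed = 0L) {
  n <- nrow(Y_before)
  if (n != nrow(Y_after)) stop("embeddings differ in size")
  if (n < 3) stop("pairwise-distance correlation undefined for n < 3")
  db <- as.vector(stats::dist(Y_before))
  da <- as.vector(stats::dist(Y_after))
  if (length(db) > max_pairs) {
    keep <- with_seed(seed, sample.int(length(db), max_pairs))
    db <- db[keep]; da <- da[keep]
  }
  stats::cor(db, da, method = "spearman")
}

# k nearest neighbour indices per row, ties broken by ascending index
knn_indices <- function(Y, k) {
  D <- as.matrix(stats::dist(Y))
  diag(D) <- Inf
  n <- nrow(D)
  lapply(seq_len(n), function(i) order(D[i, ], seq_len(n))[seq_len(k)])
}

#' k-nearest-neighbour preservation
#'
#' Mean over points of the fraction of each point's k nearest neighbours
#' (self excluded, distance ties broken by index) retained after
#' corruption.
#'
#' @param Y_before,Y_after embeddings with matching rows.
#' @param k neighbourhood size (default 10).
#' @return preservation in [0, 1].
#' @export
metric_knn10 <- function(Y_before, Y_after, k = 10L) {
  n <- nrow(Y_before)
  if (n != nrow(Y_after)) stop("embeddings differ in size")
  if (n <= k) stop("need more than k = ", k, " points")
  nb <- knn_indices(Y_before, k)
  na_ <- knn_indices(Y_after, k)
  mean(vapply(seq_len(n),
              function(i) length(intersect(nb[[i]], na_[[i]])) / k,
              numeric(1)))
}

#' Adjusted Rand index between K-means clusterings of two embeddings
#'
#' K-means (seeded, multiple restarts) is fit independently on each
#' embedding and the two labelings are compared with the adjusted Rand
#' index.
#'
#' @param Y_before,Y_after embeddings with matching rows.
#' @param K number of clusters (default 10).
#' @param seed seed for both K-means fits.
#' @param nstart random restarts per fit.
#' @return ARI (1 = identical partitions up to relabeling).
#' @export
metric_ari_kmeans <- function(Y_before, Y_after, K = 10L, seed = 0L,
                              nstart = 10L) {
  n <- nrow(Y_before)
  if (n != nrow(Y_after)) stop("embeddings differ in size")
  if (n < K) stop("need at least K = ", K, " points")
  cb <- with_seed(substream_seed(seed, "kmeans-before"),
                  stats::kmeans(Y_before, centers = K, nstart = nstart,
                                iter.max = 100)$cluster)
  ca <- with_seed(substream_seed(seed, "kmeans-after"),
                  stats::kmeans(Y_after, centers = K, nstart = nstart,
                                iter.max = 100)$cluster)
  mclust::adjustedRandIndex(cb, ca)
}

#' Laplacian score of each feature on an affinity graph
#'
#' He et al.'s locality-preservation score with a supplied affinity matrix
#' S (here the t-SNE P matrix, or Q from an embedding): smaller = more
#' important. Features constant over the graph get \code{Inf} (least
#' informative).
#'
#' @param X data matrix.
#' @param S symmetric nonnegative affinity matrix.
#' @return length-d vector of raw Laplacian scores.
#' @export
laplacian_score <- function(X, S) {
  X <- as.matrix(X)
  S <- as.matrix(S)
  stopifnot(nrow(S) == nrow(X), ncol(S) == nrow(X))
  dg <- rowSums(S)
  D1 <- sum(dg)
  vapply(seq_len(ncol(X)), function(r) {
    f <- X[, r]
    ft <- f - sum(f * dg) / D1
    den <- sum(ft^2 * dg)
    if (den <= 0) return(Inf)
    num <- sum(ft * (dg * ft - as.vector(S %*% ft)))   # f' L f, L = D - S
    num / den
  }, numeric(1))
}

#' Fisher score of each feature
#'
#' Ratio of between-class to within-class variance; larger = more
#' important.
#'
#' @param X data matrix.
#' @param labels class labels.
#' @return length-d vector of Fisher scores.
#' @export
fisher_score <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.factor(labels)
  if (length(labels) != nrow(X)) stop("need one label per sample")
  mu <- colMeans(X)
  groups <- split(seq_len(nrow(X)), labels)
  num <- den <- numeric(ncol(X))
  for (g in groups) {
    nc <- length(g)
    mg <- colMeans(X[g, , drop = FALSE])
    num <- num + nc * (mg - mu)^2
    vg <- colMeans(sweep(X[g, , drop = FALSE], 2, mg)^2)
    den <- den + nc * vg
  }
  ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
}

#' Baseline feature-importance scores
#'
#' All scores are returned oriented so that larger means more important
#' (the Laplacian score is negated accordingly; its raw value is available
#' via \code{\link{laplacian_score}}).
#'
#' @param X data matrix.
#' @param kind one of \code{"laplace_P"}, \code{"laplace_Q"},
#'   \code{"fisher"}, \code{"pca_variance"}, \code{"abs_feature"}.
#' @param labels class labels (\code{fisher}; also switches
#'   \code{laplace_*} to the class-based variant, recomputing the affinity
#'   on each class subset).
#' @param affinity an \code{affinity_model} (for \code{laplace_P}).
#' @param embedding an embedding matrix (for \code{laplace_Q}; the
#'   Student-t Q matrix is computed from it).
#' @param n_components number of leading principal components for
#'   \code{pca_variance}, whose score is the variance-weighted squared
#'   loading of each feature.
#' @param perplexity perplexity used when a class-based Laplacian score
#'   recalibrates affinities per class subset.
#' @return a length-d importance vector; for \code{abs_feature} an n-by-d
#'   matrix of |x| cell scores (local use), or use \code{colMeans} of it
#'   for class/global levels; for class-based \code{laplace_*} or
#'   \code{fisher} with per-class output, a class-by-d matrix.
#' @export
baseline_scores <- function(X, kind = c("laplace_P", "laplace_Q", "fisher",
                                        "pca_variance", "abs_feature"),
                            labels = NULL, affinity = NULL, embedding = NULL,
                            n_components = NULL, perplexity = 30) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  d <- ncol(X)
  if (kind == "abs_feature") return(abs(X))
  if (kind == "fisher") {
    if (is.null(labels)) stop("fisher score requires labels")
    return(fisher_score(X, labels))
  }
  if (kind == "pca_variance") {
    if (is.null(n_components)) n_components <- min(10L, d, nrow(X) - 1L)
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    m <- min(n_components, ncol(pc$rotation))
    return(as.vector(pc$rotation[, seq_len(m), drop = FALSE]^2 %*%
                       pc$sdev[seq_len(m)]^2))
  }
  # Laplacian scores
  graph_for <- function(rows) {
    if (kind == "laplace_P") {
      if (is.null(affinity)) stop("laplace_P requires an affinity model")
      if (length(rows) == nrow(X)) affinity$P
      else calibrate_affinities(X[rows, , drop = FALSE],
                                min(perplexity, length(rows) - 1))$P
    } else {
      if (is.null(embedding)) stop("laplace_Q requires an embedding")
      E <- tsne_kernel(as.matrix(embedding)[rows, , drop = FALSE])
      E / sum(E)
    }
  }
  if (is.null(labels)) {
    -laplacian_score(X, graph_for(seq_len(nrow(X))))
  } else {
    groups <- split(seq_len(nrow(X)), as.factor(labels))
    out <- t(vapply(groups, function(rows)
      -laplacian_score(X[rows, , drop = FALSE], graph_for(rows)),
      numeric(d)))
    rownames(out) <- names(groups)
    out
  }
}

percentile_ci <- function(x, n_boot = 1000L, seed = 0L, level = 0.95) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(c(lo = NA_real_, hi = NA_real_))
  means <- with_seed(seed, vapply(seq_len(n_boot), function(b)
    mean(x[sample.int(length(x), replace = TRUE)]), numeric(1)))
  q <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Run the corruption validation experiment
#'
#' For every combination of selector, level, corruption method, corruption
#' fraction and t-SNE seed: fit a reference t-SNE (tracked when attribution
#' selectors are present), select features, corrupt, refit on the corrupted
#' data with a fresh perplexity calibration but the same initialization
#' seed, and compare the refit embedding to the reference with the three
#' degradation metrics. Random-selection cells are averaged over
#' \code{n_random_subsets} seeded subsets.
#'
#' @param X data matrix.
#' @param labels optional class labels (required for class level and the
#'   fisher selector; also sets the K-means K to the number of classes).
#' @param selectors subset of \code{"attribution"}, \code{"positive"},
#'   \code{"grad_times_input"}, \code{"abs_feature"}, \code{"random"},
#'   \code{"laplace_P"}, \code{"laplace_Q"}, \code{"fisher"},
#'   \code{"pca_variance"}.
#' @param levels subset of \code{"local"}, \code{"class"}, \code{"global"}.
#' @param methods subset of \code{"mean"}, \code{"permute"},
#'   \code{"remove"} (remove runs only at global level).
#' @param fractions corruption fractions (default 2\% to 18\% in 2\% steps).
#' @param tsne_seeds integer vector of reference-fit seeds.
#' @param perplexity,config t-SNE settings for the reference and refits.
#' @param n_random_subsets random subsets per cell for the random baseline.
#' @param kmeans_k K for the ARI metric; defaults to the number of classes
#'   when labels are given, else 10.
#' @param n_boot bootstrap resamples for the 95\% CIs.
#' @param seed global seed fanned out to permutation/bootstrap substreams.
#' @param checkpoint optional path to a TSV; completed cells are appended
#'   as they finish and are skipped on rerun (resume support).
#' @param verbose print progress.
#' @return list of class \code{validation_report}: \code{cells} (one row
#'   per selector/level/method/fraction/seed/subset), \code{summary}
#'   (aggregated over seeds with bootstrap CIs), \code{metadata}.
#' @export
run_corruption_experiment <- function(X, labels = NULL,
                                      selectors = c("attribution", "random"),
                                      levels = "local", methods = "mean",
                                      fractions = seq(0.02, 0.18, by = 0.02),
                                      tsne_seeds = 0:9, perplexity = 30,
                                      config = tsne_config(),
                                      n_random_subsets = 10L,
                                      kmeans_k = NULL, n_boot = 1000L,
                                      seed = 0L, checkpoint = NULL,
                                      verbose = FALSE) {
  X <- as_data_matrix(X)
  n <- nrow(X); d <- ncol(X)
  attr_selectors <- c("attribution", "positive", "grad_times_input")
  need_track <- any(selectors %in% attr_selectors)
  if (is.null(kmeans_k)) kmeans_k <- if (!is.null(labels))
    length(unique(labels)) else 10L
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint))
    done <- utils::read.table(checkpoint, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  cells <- list()
  log_msg <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "), ...)

  for (ts in tsne_seeds) {
    log_msg("reference fit, seed ", ts)
    ref <- tsne_fit(X, config, perplexity, seed = ts, track = need_track)
    scores <- list()
    if (need_track) {
      A_raw <- attributions(ref, X = X, variant = "raw")
      scores$attribution <- A_raw
      if ("positive" %in% selectors)
        scores$positive <- attributions(ref, X = X, variant = "positive_only")
      if ("grad_times_input" %in% selectors)
        scores$grad_times_input <- attributions(ref, X = X,
                                                variant = "grad_times_input")
    }
    if ("abs_feature" %in% selectors) scores$abs_feature <- abs(X)
    if ("laplace_P" %in% selectors)
      scores$laplace_P <- baseline_scores(X, "laplace_P",
                                          labels = if ("class" %in% levels) labels,
                                          affinity = ref$affinity,
                                          perplexity = perplexity)
    if ("laplace_Q" %in% selectors)
      scores$laplace_Q <- baseline_scores(X, "laplace_Q",
                                          labels = if ("class" %in% levels) labels,
                                          embedding = ref$Y)
    if ("fisher" %in% selectors)
      scores$fisher <- baseline_scores(X, "fisher", labels = labels)
    if ("pca_variance" %in% selectors)
      scores$pca_variance <- baseline_scores(X, "pca_variance")

    refit_metrics <- function(Xc, cell_seed) {
      re <- tsne_fit(Xc, config, min(perplexity, nrow(Xc) - 1), seed = ts,
                     track = FALSE)
      c(spearman = metric_spearman(ref$Y, re$Y,
                                   seed = substream_seed(seed, "spearman", cell_seed)),
        ari = metric_ari_kmeans(ref$Y, re$Y, K = kmeans_k,
                                seed = substream_seed(seed, "ari", cell_seed)),
        knn10 = metric_knn10(ref$Y, re$Y))
    }

    for (lv in levels) for (me in methods) {
      if (me == "remove" && lv != "global") next
      for (fr in fractions) {
        for (sl in selectors) {
          if (lv == "class" && is.null(labels)) stop("class level requires labels")
          subsets <- if (sl == "random") seq_len(n_random_subsets) else 0L
          for (sb in subsets) {
            if (!is.null(done) &&
                nrow(done[done$selector == sl & done$level == lv &
                          done$method == me &
                          abs(done$fraction - fr) < 1e-12 &
                          done$seed == ts & done$subset == sb, ]) > 0) {
              cells[[length(cells) + 1L]] <-
                done[done$selector == sl & done$level == lv & done$method == me &
                     abs(done$fraction - fr) < 1e-12 & done$seed == ts &
                     done$subset == sb, ][1, ]
              next
            }
            plan <- if (sl == "random") {
              random_plan(d, n, lv, fr, labels, me,
                          seed = substream_seed(seed, "random-subset",
                                                1e4 * ts + 100 * sb + round(1e3 * fr)))
            } else {
              sc <- scores[[sl]]
              if (is.null(sc)) stop("no scores available for selector ", sl)
              select_features(sc, lv, fr, labels = labels, method = me)
            }
            cell_id <- 1e5 * ts + 1e3 * match(sl, selectors) + 10 * sb +
              round(100 * fr)
            Xc <- corrupt(X, plan, seed = substream_seed(seed, "permute", cell_id))
            m <- refit_metrics(Xc, cell_id)
            row <- data.frame(selector = sl, level = lv, method = me,
                              fraction = fr, seed = ts, subset = sb,
                              spearman = m["spearman"], ari = m["ari"],
                              knn10 = m["knn10"], row.names = NULL)
            cells[[length(cells) + 1L]] <- row
            if (!is.null(checkpoint))
              utils::write.table(row, checkpoint, sep = "\t", append =
                                   file.exists(checkpoint),
                                 col.names = !file.exists(checkpoint),
                                 row.names = FALSE, quote = FALSE)
            log_msg(sl, "/", lv, "/", me, " fr=", fr, " seed=", ts,
                    if (sl == "random") paste0(" subset=", sb),
                    "  rho=", round(m["spearman"], 3))
          }
        }
      }
    }
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  groups <- split(cells, list(cells$selector, cells$level, cells$method,
                              cells$fraction), drop = TRUE)
  summary <- do.call(rbind, lapply(groups, function(g) {
    out <- data.frame(selector = g$selector[1], level = g$level[1],
                      method = g$method[1], fraction = g$fraction[1],
                      n_runs = nrow(g))
    for (mt in c("spearman", "ari", "knn10")) {
      ci <- percentile_ci(g[[mt]], n_boot,
                          seed = substream_seed(seed, paste0("boot-", mt)))
      out[[paste0(mt, "_mean")]] <- mean(g[[mt]])
      out[[paste0(mt, "_lo")]] <- ci["lo"]
      out[[paste0(mt, "_hi")]] <- ci["hi"]
    }
    out
  }))
  rownames(summary) <- NULL
  structure(list(cells = cells, summary = summary,
                 metadata = list(selectors = selectors, levels = levels,
                                 methods = methods, fractions = fractions,
                                 tsne_seeds = tsne_seeds,
                                 perplexity = perplexity,
                                 kmeans_k = kmeans_k, seed = seed,
                                 n_random_subsets = n_random_subsets,
                                 config = unclass(config))),
            class = "validation_report")
}

# a corruption plan with uniformly random feature subsets of matched size
random_plan <- function(d, n, level, fraction, labels, method, seed) {
  k <- round_count(fraction, d)
  sel <- with_seed(seed, {
    if (level == "local") lapply(seq_len(n), function(i) sort(sample.int(d, k)))
    else if (level == "class")
      lapply(split(seq_len(n), labels), function(g) sort(sample.int(d, k)))
    else sort(sample.int(d, k))
  })
  structure(list(level = level, method = method, fraction = fraction,
                 selected = sel, labels = labels, d = d),
            class = "corruption_plan")
}
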