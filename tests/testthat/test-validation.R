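# Feature selection, corruption, degradation metrics, and baselines.

test_that("local selection takes the top fraction by absolute score", {
  A <- matrix(c(0.1, 0.9, 0.5), 1, 3)
  plan <- select_features(A, "local", fraction = 1 / 3)
  expect_equal(plan$selected[[1]], 2L)
  # fraction 1 selects everything
  plan_all <- select_features(A, "local", fraction = 1)
  expect_equal(plan_all$selected[[1]], 1:3)
  # negative scores count by magnitude
  plan_neg <- select_features(matrix(c(0.1, -0.9, 0.5), 1, 3), "local", 1 / 3)
  expect_equal(plan_neg$selected[[1]], 2L)
  expect_error(select_features(A, "local", fraction = 0.05), "selects no")
})

test_that("global selection counts top-set membership across samples", {
  A <- rbind(c(3, 1, 0), c(2, 1, 0), c(0, 1, 4))
  plan <- select_features(A, "global", fraction = 1 / 3)
  expect_equal(plan$selected, 1L)    # top-1 twice, beats the others
  # class level: per-class counting
  planc <- select_features(A, "class", fraction = 1 / 3,
                           labels = c("u", "u", "v"))
  expect_equal(planc$selected$u, 1L)
  expect_equal(planc$selected$v, 3L)
  expect_error(select_features(A, "class", 1 / 3), "labels")
  expect_error(select_features(A, "local", 1 / 3, method = "remove"),
               "global")
})

test_that("selection ties break by ascending feature index", {
  A <- matrix(c(1, 1, 1, 1), 1, 4)
  plan <- select_features(A, "local", fraction = 0.5)
  expect_equal(plan$selected[[1]], 1:2)
})

test_that("mean corruption replaces cells by the unit-feature mean", {
  X <- cbind(c(1, 2, 3), c(5, 5, 5))
  rownames(X) <- paste0("s", 1:3); colnames(X) <- c("f1", "f2")
  plan <- select_features(rbind(c(1, 0), c(1, 0), c(1, 0)), "global", 0.5)
  Xc <- corrupt(X, plan)
  expect_equal(unname(Xc[, 1]), c(2, 2, 2))
  expect_equal(unname(Xc[, 2]), c(5, 5, 5))
  # constant column unchanged under mean corruption
  plan2 <- select_features(rbind(c(0, 1), c(0, 1), c(0, 1)), "global", 0.5)
  expect_equal(corrupt(X, plan2), X)
})

test_that("permutation corruption is seeded and preserves the multiset", {
  set.seed(31)
  X <- matrix(rnorm(60), 12, 5)
  A <- matrix(rnorm(60), 12, 5)
  plan <- select_features(A, "local", 0.4, method = "permute")
  X1 <- corrupt(X, plan, seed = 5)
  X2 <- corrupt(X, plan, seed = 5)
  expect_identical(X1, X2)
  X3 <- corrupt(X, plan, seed = 6)
  expect_false(identical(X1, X3))
  for (f in 1:5) expect_equal(sort(X1[, f]), sort(X[, f]))
})

test_that("remove corruption drops columns at the global level only", {
  X <- matrix(rnorm(40), 10, 4)
  v <- c(4, 1, 3, 2)
  plan <- select_features(v, "global", 0.25, method = "remove")
  expect_equal(ncol(corrupt(X, plan)), 3)
  expect_equal(plan$selected, 1L)
  plan$level <- "local"
  expect_error(select_features(matrix(v, 1), "local", 0.25, method = "remove"))
})

test_that("distance-rank correlation behaves as a similarity invariant", {
  set.seed(32)
  Y <- matrix(rnorm(20), 10, 2)
  expect_equal(metric_spearman(Y, Y), 1)
  # similarity transform: rotation + scale + shift keeps all ranks
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_equal(metric_spearman(Y, 3 * Y %*% R + 5), 1)
  # hand-built full rank reversal (3 points)
  Yb <- rbind(c(0, 0), c(1, 0), c(3, 0))          # d = (1, 3, 2)
  Ya <- rbind(c(0, 0), c(5, 0), c(1, 1))          # d = (5, 1.41, 4.12)
  expect_equal(metric_spearman(Yb, Ya), -1)
  expect_error(metric_spearman(Y[1:2, ], Y[1:2, ]), "n < 3")
  # brute-force agreement on a random instance
  Ya2 <- matrix(rnorm(20), 10, 2)
  expect_equal(metric_spearman(Y, Ya2), brute_spearman_dist(Y, Ya2))
})

test_that("knn preservation matches a brute-force count", {
  set.seed(33)
  Y <- matrix(rnorm(30), 15, 2)
  expect_equal(metric_knn10(Y, Y), 1)
  Ya <- matrix(rnorm(30), 15, 2)
  expect_equal(metric_knn10(Y, Ya, k = 3), brute_knn_preservation(Y, Ya, 3))
  # two far blobs shuffled internally, k = 1: hand-checkable
  Yb <- rbind(c(0, 0), c(0, 1), c(100, 0), c(100, 1), c(50, 50))
  Yc <- rbind(c(0, 1), c(0, 0), c(100, 1), c(100, 0), c(50, 50))
  expect_equal(metric_knn10(Yb, Yc, k = 1), brute_knn_preservation(Yb, Yc, 1))
  expect_error(metric_knn10(Y, Ya, k = 20), "more than")
})

test_that("kmeans ARI metric is seeded and exact on identical input", {
  set.seed(34)
  Y <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20, 6), 10, 2))
  expect_equal(metric_ari_kmeans(Y, Y, K = 2, seed = 1), 1)
  Yn <- Y + rnorm(40, sd = 2)
  r1 <- metric_ari_kmeans(Y, Yn, K = 2, seed = 1)
  r2 <- metric_ari_kmeans(Y, Yn, K = 2, seed = 1)
  expect_identical(r1, r2)
  expect_error(metric_ari_kmeans(Y[1:3, ], Y[1:3, ], K = 10), "at least")
})

test_that("ARI agrees with the hand contingency formula", {
  # permutation invariance and the classic -0.5 case
  expect_equal(ari_contingency(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  expect_equal(ari_contingency(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_equal(mclust::adjustedRandIndex(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  set.seed(35)
  for (rep in 1:5) {
    a <- sample(1:3, 20, replace = TRUE)
    b <- sample(1:4, 20, replace = TRUE)
    expect_equal(mclust::adjustedRandIndex(a, b), ari_contingency(a, b))
  }
})

test_that("identity corruption leaves all metrics at 1 with matched seeds", {
  set.seed(36)
  X <- rbind(matrix(rnorm(60), 20, 3), matrix(rnorm(60, 5), 20, 3))
  cfg <- tsne_config(n_iter = 60, exaggeration_iters = 10,
                     momentum_switch = 30, kl_every = 0)
  f1 <- tsne_fit(X, cfg, perplexity = 8, seed = 2)
  f2 <- tsne_fit(X, cfg, perplexity = 8, seed = 2)
  expect_equal(metric_spearman(f1$Y, f2$Y), 1)
  expect_equal(metric_knn10(f1$Y, f2$Y), 1)
  expect_equal(metric_ari_kmeans(f1$Y, f2$Y, K = 2, seed = 0), 1)
})

test_that("Laplacian score flags constant features as least informative", {
  set.seed(37)
  X <- cbind(rnorm(10), rep(1, 10))
  S <- matrix(1 / 90, 10, 10); diag(S) <- 0
  ls <- laplacian_score(X, S)
  expect_true(is.infinite(ls[2]))
  expect_true(is.finite(ls[1]))
})

test_that("Fisher score ranks a separating feature above pure noise", {
  set.seed(38)
  labels <- rep(c("a", "b"), each = 20)
  X <- cbind(c(rnorm(20, 0), rnorm(20, 5)), rnorm(40))
  fs <- fisher_score(X, labels)
  expect_gt(fs[1], fs[2])
  # hand evaluation on a tiny case: two classes, exact means/variances
  Xt <- cbind(c(0, 2, 4, 6), c(1, 1, 1, 1) + c(-1, 1, -1, 1) * 1e-8)
  ft <- fisher_score(Xt, c("a", "a", "b", "b"))
  # feature 1: between = 2*(2-3)^2 + 2*(5-3)^2 = 2+... within = 2*1+2*1
  num <- 2 * (1 - 3)^2 + 2 * (5 - 3)^2
  den <- 2 * 1 + 2 * 1
  expect_equal(ft[1], num / den)
})

test_that("pca variance control prefers high-variance directions", {
  set.seed(39)
  X <- cbind(rnorm(50, sd = 5), rnorm(50, sd = 1), rnorm(50, sd = 0.2))
  sc <- baseline_scores(X, "pca_variance", n_components = 2)
  expect_equal(order(-sc), 1:3)
})

test_that("baseline orientation makes larger always more important", {
  set.seed(40)
  X <- cbind(rnorm(30), rep(1, 30), rnorm(30))
  S <- matrix(1, 30, 30); diag(S) <- 0
  af <- structure(list(P = S / sum(S), P_cond = S / rowSums(S),
                       betas = rep(1, 30)), class = "affinity_model")
  sc <- baseline_scores(X, "laplace_P", affinity = af)
  expect_true(sc[2] == -Inf)   # constant feature least important
})

test_that("the experiment driver aggregates cells with bootstrap CIs", {
  set.seed(41)
  X <- rbind(matrix(rnorm(100), 20, 5), matrix(rnorm(100, 4), 20, 5))
  labels <- rep(1:2, each = 20)
  cfg <- tsne_config(n_iter = 40, exaggeration_factor = 1,
                     exaggeration_iters = 0, momentum_switch = 20,
                     kl_every = 0, learning_rate = 50)
  rep_ <- run_corruption_experiment(
    X, labels = labels, selectors = c("abs_feature", "random"),
    levels = "local", methods = "mean", fractions = c(0.2, 0.4),
    tsne_seeds = 0:1, perplexity = 5, config = cfg,
    n_random_subsets = 3, kmeans_k = 2, n_boot = 50, seed = 3)
  cells <- rep_$cells
  expect_equal(nrow(cells), 2 * 2 * (1 + 3))    # seeds x fractions x subsets
  expect_true(all(cells$spearman >= -1 & cells$spearman <= 1))
  expect_true(all(cells$knn10 >= 0 & cells$knn10 <= 1))
  s <- rep_$summary
  expect_equal(nrow(s), 4)                      # 2 selectors x 2 fractions
  expect_true(all(s$spearman_lo <= s$spearman_mean + 1e-9))
  expect_true(all(s$spearman_hi >= s$spearman_mean - 1e-9))
  # checkpoint resume reproduces the same cells without recomputation
  ckpt <- tempfile(fileext = ".tsv")
  rep2 <- run_corruption_experiment(
    X, labels = labels, selectors = c("abs_feature", "random"),
    levels = "local", methods = "mean", fractions = c(0.2, 0.4),
    tsne_seeds = 0:1, perplexity = 5, config = cfg,
    n_random_subsets = 3, kmeans_k = 2, n_boot = 50, seed = 3,
    checkpoint = ckpt)
  rep3 <- run_corruption_experiment(
    X, labels = labels, selectors = c("abs_feature", "random"),
    levels = "local", methods = "mean", fractions = c(0.2, 0.4),
    tsne_seeds = 0:1, perplexity = 5, config = cfg,
    n_random_subsets = 3, kmeans_k = 2, n_boot = 50, seed = 3,
    checkpoint = ckpt)
  expect_equal(rep3$summary, rep2$summary)
  expect_equal(rep2$cells$spearman, rep_$cells$spearman)
})

test_that("random plans are reproducible and of matched size", {
  p1 <- tsnegrad:::random_plan(10, 5, "local", 0.3, NULL, "mean", seed = 9)
  p2 <- tsnegrad:::random_plan(10, 5, "local", 0.3, NULL, "mean", seed = 9)
  expect_identical(p1$selected, p2$selected)
  expect_true(all(lengths(p1$selected) == 3))
})
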