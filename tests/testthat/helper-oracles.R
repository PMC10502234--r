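# Independent oracles and fixture builders used across the test files.
# These deliberately avoid the package's optimized code paths: dense loops,
# closed-form hand evaluation, and finite differences only.

## conditional rollout: re-run sample i's trajectory against the frozen
## per-iteration reference positions of all other samples. This is the map
## whose derivative the diagonal-block recursion tracks; central finite
## differences of it are the system-level oracle.
rollout_sample <- function(X, i, model, cfg, seed, ref_traj) {
  n <- nrow(X)
  P <- affinities_from_betas(X, model$betas)$P
  st <- init_embedding(n, cfg$d_out, seed)
  yi <- st$Y[i, ]
  vi <- rep(0, cfg$d_out)
  for (t in seq_len(cfg$n_iter)) {
    alpha <- if (t <= cfg$exaggeration_iters) cfg$exaggeration_factor else 1
    mom <- if (t <= cfg$momentum_switch) cfg$momentum else cfg$final_momentum
    Ycur <- ref_traj[[t]]              # embedding entering step t (1 = init)
    Ycur[i, ] <- yi
    E <- 1 / (1 + as.matrix(stats::dist(Ycur))^2)
    diag(E) <- 0
    Z <- sum(E)
    Delta <- sweep(-Ycur, 2, -yi)      # rows y_i - y_j
    gi <- 4 * colSums((alpha * P[i, ] - E[i, ] / Z) * E[i, ] * Delta)
    vi <- mom * vi - cfg$learning_rate * gi
    yi <- yi + vi
  }
  yi
}

# reference trajectory (list of embeddings entering each step) for a fit
# run with store_every = 1
reference_trajectory <- function(fit, n, d_out, seed) {
  c(list(init_embedding(n, d_out, seed)$Y),
    lapply(fit$trajectory[-length(fit$trajectory)], `[[`, "Y"))
}

# central FD of the conditional rollout for every (i, feature)
rollout_fd_gradient <- function(X, model, cfg, seed, h = 1e-6) {
  n <- nrow(X); d <- ncol(X)
  cfg$store_every <- 1L
  fit <- tsne_fit(X, cfg, seed = seed, track = FALSE, affinity = model)
  traj <- reference_trajectory(fit, n, cfg$d_out, seed)
  FD <- array(0, dim = c(n, cfg$d_out, d))
  for (i in seq_len(n)) for (f in seq_len(d)) {
    Xp <- X; Xp[i, f] <- Xp[i, f] + h
    Xm <- X; Xm[i, f] <- Xm[i, f] - h
    yp <- rollout_sample(Xp, i, model, cfg, seed, traj)
    ym <- rollout_sample(Xm, i, model, cfg, seed, traj)
    FD[i, , f] <- (yp - ym) / (2 * h)
  }
  FD
}

## hand contingency-table ARI (Hubert & Arabie)
ari_contingency <- function(a, b) {
  tab <- table(a, b)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(length(a), 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

## brute-force metrics (loops, no shared code with the implementation)
brute_spearman_dist <- function(Ya, Yb) {
  n <- nrow(Ya)
  da <- db <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    da <- c(da, sqrt(sum((Ya[i, ] - Ya[j, ])^2)))
    db <- c(db, sqrt(sum((Yb[i, ] - Yb[j, ])^2)))
  }
  stats::cor(rank(da), rank(db))
}

brute_knn_preservation <- function(Ya, Yb, k) {
  n <- nrow(Ya)
  nn_of <- function(Y, i) {
    d <- sapply(seq_len(n), function(j)
      if (j == i) Inf else sqrt(sum((Y[i, ] - Y[j, ])^2)))
    order(d, seq_len(n))[seq_len(k)]
  }
  mean(sapply(seq_len(n), function(i)
    length(intersect(nn_of(Ya, i), nn_of(Yb, i))) / k))
}

## toy aligned sequences for the mutation encoder; built in code, ~300 nt
make_toy_msa <- function() {
  L <- 300
  base <- strsplit(paste(rep("ACGT", L / 4), collapse = ""), "")[[1]]
  ref <- base
  s <- list(s1 = base, s2 = base, s3 = base, s4 = base)
  # shared substitution at 150 (ref 'C' -> 'G') in s1, s2: kept feature
  stopifnot(ref[150] == "C")
  s$s1[150] <- "G"; s$s2[150] <- "G"
  # singleton substitution at 160 in s3 only: dropped
  s$s3[160] <- "A"
  # substitution at 50 in s1, s2: inside 100-nt flank, dropped
  s$s1[50] <- "T"; s$s2[50] <- "T"
  # short deletion (3 nt) at 190-192 in s1, s2: kept as del features
  s$s1[190:192] <- "-"; s$s2[190:192] <- "-"
  # long deletion (15 nt > 12) at 120-134 in s3: recoded missing
  s$s3[120:134] <- "-"
  # ambiguity at 170 in s4: missing
  s$s4[170] <- "N"
  # substitution at 170 in s1, s2 (s4 missing there): kept, s4 NA
  s$s1[170] <- "T"; s$s2[170] <- "T"
  c(ref = paste(ref, collapse = ""),
    vapply(s, paste, character(1), collapse = ""))
}
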