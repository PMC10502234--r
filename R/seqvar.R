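# Binary mutation presence/absence encoding of a multiple sequence
# alignment against a reference, plus the attribution-driven QC and
# marker-identification procedures used downstream.

read_alignment <- function(msa) {
  if (inherits(msa, "XStringSet")) {
    seqs <- as.character(msa)
  } else if (is.character(msa) && length(msa) == 1 && file.exists(msa)) {
    seqs <- as.character(Biostrings::readBStringSet(msa))
  } else if (is.character(msa) && !is.null(names(msa))) {
    seqs <- msa
  } else {
    stop("msa must be an XStringSet, a FASTA path, or a named character vector")
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences need names")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1)
    stop("ragged alignment: sequence lengths ", paste(unique(widths), collapse = ", "))
  toupper(seqs)
}

#' Encode an aligned set of sequences as a binary mutation matrix
#'
#' Each alignment column where a sample differs from the reference yields
#' one binary feature per observed alternate state (substitution base, or a
#' deletion token); a cell is 1 when the sample carries that state.
#' Positions are 1-based reference coordinates after dropping reference gap
#' columns (insertions relative to the reference are not encoded).
#' Filters: runs of deletion longer than \code{long_deletion_nt} are
#' recoded as missing across their span (assembly-gap semantics, not true
#' deletions); ambiguity characters (N etc.) are missing; features
#' observed in fewer than two samples are dropped; features within the
#' first or last \code{flank_trim} reference positions are dropped (poorly
#' covered sequence ends).
#'
#' @param msa aligned sequences: a \code{Biostrings} XStringSet, a path to
#'   an aligned FASTA, or a named character vector.
#' @param reference_id name of the reference sequence within \code{msa}
#'   (excluded from the sample rows).
#' @param flank_trim number of reference positions trimmed at each end.
#' @param long_deletion_nt deletions strictly longer than this are recoded
#'   as missing.
#' @return object of class \code{mutation_matrix}: \code{values} (n-by-m
#'   0/1 matrix, NA = missing), \code{features} (data.frame with
#'   \code{position}, \code{alt} -- a base or \code{"del"} -- and carrier
#'   \code{count}), \code{reference_id}, \code{missing_freq} (per-feature
#'   NA frequency).
#' @export
encode_mutations <- function(msa, reference_id, flank_trim = 100L,
                             long_deletion_nt = 12L) {
  seqs <- read_alignment(msa)
  if (!reference_id %in% names(seqs))
    stop("reference '", reference_id, "' not found in the alignment")
  ref <- seqs[[reference_id]]
  samples <- seqs[setdiff(names(seqs), reference_id)]
  n <- length(samples)
  if (n < 1) stop("no sample sequences besides the reference")

  ref_chars <- strsplit(ref, "")[[1]]
  keep_cols <- ref_chars != "-"              # drop insertion columns
  ref_chars <- ref_chars[keep_cols]
  L <- length(ref_chars)
  C <- matrix("", n, L)
  for (i in seq_len(n))
    C[i, ] <- strsplit(samples[[i]], "")[[1]][keep_cols]
  rownames(C) <- names(samples)

  missing <- !(C %in% c("A", "C", "G", "T", "-"))
  dim(missing) <- dim(C)
  # long deletion runs -> missing across their span
  for (i in seq_len(n)) {
    r <- rle(C[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    long <- which(r$values & r$lengths > long_deletion_nt)
    for (k in long) missing[i, starts[k]:ends[k]] <- TRUE
  }

  feats <- list()
  cols <- list()
  for (p in seq_len(L)) {
    obs <- C[, p]
    states <- setdiff(unique(obs[!missing[, p]]), ref_chars[p])
    states <- states[states %in% c("A", "C", "G", "T", "-")]
    for (s in sort(states)) {
      v <- as.numeric(obs == s)
      v[missing[, p]] <- NA
      cnt <- sum(v == 1, na.rm = TRUE)
      if (cnt < 2) next                                  # singleton filter
      if (p <= flank_trim || p > L - flank_trim) next    # flank trim
      alt <- if (s == "-") "del" else s
      feats[[length(feats) + 1L]] <-
        data.frame(position = p, alt = alt, count = cnt)
      cols[[length(cols) + 1L]] <- v
    }
  }
  if (!length(feats)) {
    values <- matrix(numeric(0), n, 0)
    features <- data.frame(position = integer(0), alt = character(0),
                           count = integer(0))
  } else {
    values <- do.call(cbind, cols)
    features <- do.call(rbind, feats)
    colnames(values) <- paste0(features$position, ":", features$alt)
    rownames(values) <- names(samples)
  }
  structure(list(values = values, features = features,
                 reference_id = reference_id,
                 missing_freq = if (ncol(values)) colMeans(is.na(values)) else
                   numeric(0),
                 flank_trim = flank_trim, long_deletion_nt = long_deletion_nt),
            class = "mutation_matrix")
}

#' Impute missing mutation calls as the reference state
#'
#' Masked cells are set to 0 (reference genotype) and the mask is cleared;
#' the pre-imputation missingness frequencies are retained for QC, and
#' features that become all-zero (fully missing or carried only by masked
#' cells) are flagged.
#'
#' @param M a \code{\link{encode_mutations}} result.
#' @param strategy currently only \code{"reference"}.
#' @return the imputed \code{mutation_matrix} with \code{missing_freq}
#'   preserved and a \code{degenerate} vector naming all-zero features.
#' @export
impute_missing <- function(M, strategy = "reference") {
  stopifnot(inherits(M, "mutation_matrix"))
  strategy <- match.arg(strategy, "reference")
  V <- M$values
  V[is.na(V)] <- 0
  M$values <- V
  M$degenerate <- colnames(V)[colSums(V) == 0]
  M$imputed <- strategy
  M
}

#' Per-cluster missingness frequency of each feature
#'
#' @param M a \code{mutation_matrix} (pre-imputation, i.e. with NAs).
#' @param labels cluster id per sample.
#' @return clusters-by-features matrix of NA frequencies.
#' @export
missingness_by_cluster <- function(M, labels) {
  stopifnot(inherits(M, "mutation_matrix"))
  V <- is.na(M$values) + 0
  counts <- as.vector(table(as.factor(labels)))
  rowsum(V, as.factor(labels)) / counts
}

# correlation of a permuted score vector against y, over all permutations
# (exact) or a seeded sample
perm_pvalue_spearman <- function(x, y, n_perm = 1000L, seed = 0L) {
  rho_obs <- stats::cor(x, y, method = "spearman")
  m <- length(x)
  if (factorial(m) <= n_perm) {
    perms <- all_permutations(m)
    rhos <- apply(perms, 1, function(p) stats::cor(x[p], y, method = "spearman"))
    p <- mean(rhos >= rho_obs - 1e-12)
  } else {
    rhos <- with_seed(seed, vapply(seq_len(n_perm), function(b)
      stats::cor(x[sample.int(m)], y, method = "spearman"), numeric(1)))
    p <- (1 + sum(rhos >= rho_obs - 1e-12)) / (n_perm + 1)
  }
  list(rho = rho_obs, p_value = p)
}

all_permutations <- function(m) {
  if (m == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(m - 1L)
  do.call(rbind, lapply(seq_len(m), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

#' Correlate cluster-averaged attributions with missingness
#'
#' Quality-control check: a positive correlation between a cluster's
#' averaged attribution scores and the per-feature missingness frequency
#' indicates that the cluster is driven by missing-data patterns rather
#' than biology. Significance via a (one-sided, positive) permutation test
#' of the Spearman correlation, exact when the number of features permits.
#'
#' @param A an \code{attribution_matrix} on the samples.
#' @param cluster_labels cluster id per sample (e.g. from density-based
#'   clustering of the embedding).
#' @param missingness clusters-by-features missingness frequencies
#'   (\code{\link{missingness_by_cluster}}); row order must match the
#'   sorted cluster ids.
#' @param n_perm permutations when exhaustive enumeration is infeasible.
#' @param seed permutation seed.
#' @param min_size clusters smaller than this are skipped with a warning.
#' @return data.frame with one row per cluster: \code{cluster}, \code{n},
#'   \code{rho} (NA when attributions are constant), \code{p_value}.
#' @export
qc_missingness_correlation <- function(A, cluster_labels, missingness,
                                       n_perm = 1000L, seed = 0L,
                                       min_size = 3L) {
  Ag <- aggregate_by_group(A, cluster_labels)
  missingness <- as.matrix(missingness)
  if (!all(dim(Ag) == dim(missingness)))
    stop("missingness matrix does not match aggregated attributions")
  sizes <- table(as.factor(cluster_labels))
  rows <- lapply(seq_len(nrow(Ag)), function(k) {
    cl <- rownames(Ag)[k]
    if (sizes[[cl]] < min_size) {
      warning("skipping cluster ", cl, " (fewer than ", min_size, " samples)")
      return(NULL)
    }
    x <- Ag[k, ]
    y <- missingness[k, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(cluster = cl, n = sizes[[cl]], rho = NA_real_,
                        p_value = NA_real_))
    pt <- perm_pvalue_spearman(x, y, n_perm,
                               seed = substream_seed(seed, "qc-perm", k))
    data.frame(cluster = cl, n = sizes[[cl]], rho = pt$rho,
               p_value = pt$p_value)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(cluster = character(0), n = integer(0),
                      rho = numeric(0), p_value = numeric(0)))
  do.call(rbind, rows)
}

#' Identify candidate lineage markers by attribution and frequency
#'
#' Per group, features are flagged when they lie at or above the group's
#' \code{percentile} threshold of the attribution score and/or of the
#' feature frequency; thresholds are computed within each group. The four
#' quadrants partition each group's feature set.
#'
#' @param group_attr groups-by-features attribution matrix
#'   (\code{\link{aggregate_by_group}}).
#' @param freqs groups-by-features frequency matrix (for binary mutation
#'   features, the group-wise feature mean).
#' @param percentile threshold percentile in (0, 100).
#' @return named list per group, each with \code{by_attribution},
#'   \code{by_frequency}, \code{both}, \code{attribution_only},
#'   \code{frequency_only}, \code{neither} (character feature names).
#' @export
identify_markers <- function(group_attr, freqs, percentile = 90) {
  group_attr <- as.matrix(group_attr)
  freqs <- as.matrix(freqs)
  if (!all(dim(group_attr) == dim(freqs)))
    stop("attribution and frequency matrices must have matching shape")
  if (percentile < 0 || percentile >= 100) stop("percentile must lie in [0, 100)")
  feats <- colnames(group_attr) %||% paste0("f", seq_len(ncol(group_attr)))
  out <- lapply(seq_len(nrow(group_attr)), function(g) {
    a <- group_attr[g, ]
    f <- freqs[g, ]
    ta <- stats::quantile(a, percentile / 100, names = FALSE)
    tf <- stats::quantile(f, percentile / 100, names = FALSE)
    by_a <- feats[a >= ta]
    by_f <- feats[f >= tf]
    list(by_attribution = by_a, by_frequency = by_f,
         both = intersect(by_a, by_f),
         attribution_only = setdiff(by_a, by_f),
         frequency_only = setdiff(by_f, by_a),
         neither = setdiff(feats, union(by_a, by_f)))
  })
  names(out) <- rownames(group_attr) %||% paste0("g", seq_len(nrow(group_attr)))
  out
}
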