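# tsnegrad

Per-sample, per-feature attributions for t-SNE embeddings, computed by
propagating the derivative of each embedded point with respect to its own
input features through every step of the optimizer.

## The problem

t-SNE is a workhorse for visualizing high-dimensional biological data —
expression profiles, mutation matrices, image features — but it gives no
native answer to the question practitioners actually ask of the plot:
*which features put this sample (or this cluster) where it is?* The usual
recourse is post-hoc enrichment over hand-picked groups, which is ad hoc
and biased toward what one already expects to find.

`tsnegrad` ports the vanilla-gradient attribution idea from supervised
learning to t-SNE. The attribution of feature *f* for sample *i* is

```
A[i, f] = d ||y_i - ȳ||² / d x[i, f] = 2 (y_i - ȳ)ᵀ G_i[, f]
```

where `G_i = ∂y_i/∂x_i` is the Jacobian block of the final embedding
position with respect to the sample's own inputs. Because `y_i` is the
end point of an optimization rather than an explicit function, `G_i` is
advanced alongside the optimizer by a dynamic-programming recursion: at
each iteration the derivative of the KL gradient,

```
∂(grad_i)/∂x_i = 4 Σ_j [ (∂p_ij/∂x_i − ∂q_ij/∂x_i) φ_ijᵀ + (p_ij − q_ij) ∂φ_ij/∂x_i ],
φ_ij = (y_i − y_j) / (1 + ||y_i − y_j||²),
```

is chained through `y_i` (cross-sample blocks `∂y_i/∂x_j` are zeroed, the
standard tractability assumption) and pushed through exactly the same
momentum arithmetic the optimizer applies to the positions. Everything is
validated against finite-difference and dense-loop oracles; see the
methods vignette (`vignettes/methods.Rmd`) for the model, its
assumptions, and the regimes in which attributions are — and are not —
feature-selective.

The package also provides:

* exact and Barnes–Hut (quadtree, 2-D) gradient modes;
* a corruption-based validation framework (distance-rank Spearman,
  K-means ARI, 10-NN preservation; local/class/global selection; mean,
  permutation and removal corruption; Laplacian, Fisher, PCA-variance,
  feature-value and random baselines with bootstrap CIs);
* a synthetic generator with known ground-truth feature dependencies and
  recovery scoring (AUROC, rank-sum tests);
* encoding of an aligned FASTA into a binary mutation presence/absence
  matrix with QC filters (singleton removal, flank trimming, long
  deletions as missing), reference imputation, attribution–missingness
  QC, and percentile-threshold marker identification;
* a command-line interface (`inst/cli/tsnegrad`) with subcommands
  `simulate`, `fit`, `attribute`, `validate`, `encode`, `qc`, `markers`.

## Worked example

Four Gaussian clusters in 30 dimensions, each defined by translating five
known features (translation 2, so clusters overlap in affinity space —
the regime in which gradient attributions are feature-selective; see the
vignette); one cluster carries no translated features. Fit a tracked
t-SNE, attribute, and score recovery of the defining features:

```r
library(tsnegrad)

ds  <- generate_clusters(synthetic_spec(shift = 2, seed = 1))
cfg <- tsne_config(n_iter = 500, learning_rate = 100,
                   exaggeration_factor = 1, exaggeration_iters = 0,
                   momentum_switch = 250)
fit <- tsne_fit(ds$X, cfg, perplexity = 30, seed = 0, track = TRUE)
A   <- attributions(fit, X = ds$X)
score_recovery(A, ds)
#>   cluster n_truth     auroc      p_value top_decile_frac
#> 1       1       0 0.7644444 0.0071984264             0.2
#> 2       2       5 0.9680000 0.0006241174             0.6
#> 3       3       5 0.9200000 0.0019034725             0.4
#> 4       4       5 0.9520000 0.0009156005             0.4
```

Each row is one cluster: `auroc` is how well the class-averaged
|attribution| ranks that cluster's five defining features above the other
25 (cluster 1 is the null cluster, scored against the union of all
defining features), and `p_value` is the one-sided rank-sum test of the
same contrast. Here every translated cluster's defining features are
recovered with AUROC ≥ 0.92 at p < 0.002.

The corruption-based check of the same claim, against a matched random
baseline:

```r
rep <- run_corruption_experiment(
  ds$X, labels = ds$labels,
  selectors = c("attribution", "random"),
  levels = "local", methods = "mean",
  fractions = seq(0.02, 0.18, by = 0.02),
  tsne_seeds = 0:4, config = cfg, seed = 7)
rep$summary   # per selector x fraction: metric means with bootstrap CIs
```

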