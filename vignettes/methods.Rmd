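---
title: "Gradient attributions for t-SNE: model, assumptions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient attributions for t-SNE: model, assumptions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

t-SNE places each sample $x_i \in \mathbb{R}^d$ at a low-dimensional
position $y_i \in \mathbb{R}^{d'}$ by minimizing the Kullback–Leibler
divergence between perplexity-calibrated Gaussian input affinities
$p_{ij}$ and Student-t embedding affinities $q_{ij}$. The embedding is
widely used to find structure in genomic and other high-dimensional
biological data, but offers no native answer to the question *which input
features put this sample where it is*. `tsnegrad` answers it with the
vanilla-gradient attribution idea from supervised learning: the score of
feature $f$ for sample $i$ is a partial derivative of a scalar summary of
the sample's final position,

$$A_{if} \;=\; \frac{\partial\,\lVert y_i - \bar y\rVert^2}{\partial x_{if}}
\;=\; 2\,(y_i - \bar y)^\top \frac{\partial y_i}{\partial x_{if}}.$$

## Tracking the Jacobian through the optimizer

$y_i$ is not an explicit function of $x_i$: it is the end point of an
iterative optimization. The package therefore advances the per-sample
Jacobian blocks $G_i^t = \partial y_i^t / \partial x_i$ alongside the
optimizer by dynamic programming. With the per-step KL gradient
$\mathrm{grad}_i = 4\sum_{j\ne i}(p_{ij} - q_{ij})\,\phi_{ij}$,
$\phi_{ij} = (y_i-y_j)\,(1+\lVert y_i-y_j\rVert^2)^{-1}$, one step of the
recursion is

$$\frac{\partial\, \mathrm{grad}_i}{\partial x_i} = 4 \sum_{j \neq i}
\Big[\big(\tfrac{\partial p_{ij}}{\partial x_i}
 - \tfrac{\partial q_{ij}}{\partial x_i}\big)\,\phi_{ij}^\top
 + (p_{ij} - q_{ij})\,\tfrac{\partial \phi_{ij}}{\partial x_i}\Big],$$

where $\partial q/\partial x_i$ and $\partial\phi/\partial x_i$ chain
through $y_i$ only. Two modelling commitments matter:

* **Cross-sample blocks are zeroed.** $\partial y_i/\partial x_j$ is
  assumed zero for $j \neq i$ and never stored. This is what makes the
  computation tractable (a $d' \times d$ block per sample instead of an
  $n \times n$ grid of blocks), and it changes the meaning of $G_i$: it is
  the exact derivative of the *conditional rollout* — the map obtained by
  perturbing $x_i$ and re-running sample $i$'s trajectory against the
  frozen reference trajectories of all other samples (with the global
  normalizer $Z$ still responding through $y_i$). A forward-mode
  implementation of the full Jacobian on small instances shows that the
  discarded cross-sample coupling is *not* small: off-diagonal blocks
  reach the same magnitude as the diagonal ones, so $G_i$ should never be
  read as the sensitivity of the full coupled system. All system-level
  correctness tests in this package therefore differentiate the
  conditional rollout, where the tracker is exact to finite-difference
  precision ($\sim 10^{-7}$ relative).
* **Calibration is frozen.** The per-point precisions $\beta_i$ from the
  perplexity bisection are held constant when differentiating $p_{ij}$;
  the root-find is not a differentiable operation. The closed form of
  $\partial p_{ij}/\partial x_i$ (derived by differentiating the
  symmetrized conditionals through both the row-$i$ numerator/normalizer
  and the row-$j$ normalizer) is validated against frozen-$\beta$ central
  differences element-wise.

The tracked update mirrors the *implemented* optimizer arithmetic
exactly: a velocity-derivative tensor follows the momentum update, early
exaggeration multiplies both $P$ and $\partial P/\partial X$, and
adaptive gains (off by default in tracked runs) would be treated as
per-iteration constants. Initialization is an isotropic Gaussian with
standard deviation $10^{-4}$, independent of the data, so $G^0 = 0$ holds
exactly; PCA initialization is deliberately unsupported in tracked mode.

Two implementations coexist: a vectorized engine inside `tsne_fit(track =
TRUE)` and a literal dense-loop transcription of the recursion
(`step_partials`, `chain_to_input`, `update_gradient_tensor`,
`track_gradients_dense`). The test-suite holds them to agreement at
$10^{-10}$ absolute on $n = 30$.

## Optimizer settings for attribution runs

Defaults for plain embedding runs follow reference t-SNE conventions
(1000 iterations, learning rate 200, momentum 0.5 switching to 0.8 at
iteration 250, early exaggeration 12 for 250 iterations). For *tracked*
runs the package's examples and validation experiments disable early
exaggeration and use a smaller learning rate (100). The reason is a
property of the linearized dynamics, not a convenience: during the
exaggerated phase the per-step map has expanding directions, and the
tracked Jacobian grows geometrically (reaching $10^{50}$ and beyond
within a few hundred iterations at any learning rate we examined) while
the embedding itself stays bounded. The resulting attributions are
dominated by exponentially amplified noise. Without exaggeration the
converged phase is contractive, $G$ settles to order-one values, and
attributions stabilize. On the synthetic benchmark below the embedding
still resolves all clusters perfectly without exaggeration at these
sample sizes.

## Barnes–Hut mode

The quadratic bottleneck of both the forces and the tracked update is a
set of repulsive moment sums per sample:
$Z_i=\sum_j E_{ij}$, $\sum_j E_{ij}^2$, $S_i=\sum_j E_{ij}^2\Delta_{ij}$
and $T_i=\sum_j E_{ij}^3\Delta_{ij}\Delta_{ij}^\top$, with
$E_{ij} = (1+\lVert\Delta_{ij}\rVert^2)^{-1}$. A quadtree (written in
C++, 2-D only) summarizes far cells as point masses at their centroid
when $\text{side}/\text{distance} < \theta$; $\theta = 0$ opens every
cell and reproduces the exact sums bit-for-bit, which the tests assert on
full tracked runs. At $\theta = 0.5$ the moments are accurate to about
1%. Two caveats are documented rather than hidden:

* The attractive terms use the dense calibrated $P$ (this package does
  not sparsify affinities), so Barnes–Hut mode here bounds the repulsive
  cost, not the total asymptotic cost.
* Contracts on *accumulated* quantities at $\theta > 0$ are
  ill-conditioned: a 1% per-step moment error feeds a recursion whose
  error amplification is governed by the same Lyapunov growth as above,
  so the end-of-run Jacobian difference between $\theta = 0.5$ and exact
  mode fluctuates with the horizon (9–16% in our measurements). The
  stable contract — and the one tested — is on what the tree actually
  approximates: forces within 5% and the per-evaluation moment sums
  within 10% at $\theta = 0.5$.

## The synthetic benchmark and what it can show

`generate_clusters()` draws $n$ i.i.d. Gaussian samples
(`noise_sd = 1`) in $d = 30$ dimensions and translates a small disjoint
feature subset (5 per cluster) by `shift` for each non-null cluster; one
cluster is left untranslated. Defaults (4 clusters of 75, shift 6) are
the package's reference conditions. An optional `hierarchical` flag lets
consecutive clusters share one defining feature to induce super-cluster
structure; it is off by default because it breaks the disjointness that
the recovery scoring assumes.

Recovery scoring aggregates attributions per cluster (absolute value of
the mean — the mean cancels sample-level noise, which is essential
here), then measures AUROC and a rank-sum p-value of defining versus
non-defining features; the null cluster is scored against the union of
all defining features.

An important empirical finding, reproduced by the acceptance checks and
worth understanding before using the method: **gradient attributions are
only feature-selective when clusters retain affinity overlap.** The
input-space gradient
$\partial p_{ij}/\partial x_i$ is coherent across a cluster's members
only through pairs $(i, j)$ that straddle cluster boundaries; within-cluster
pairs contribute feature-agnostic noise. At shift 6 the between-cluster
Gaussian affinities are numerically negligible ($p_{j|i} \sim 10^{-8}$
and below), and class-averaged attributions cannot separate defining
from non-defining features (AUROC $\approx$ 0.5 at perplexity 30,
regardless of iteration count or learning rate); the corresponding
acceptance checks are left failing at those reference conditions rather
than weakened. At shift 2, where
clusters overlap, defining-feature AUROC for the translated clusters
typically reaches 0.9–1.0 — with substantial run-to-run variability, and
with nothing recovered in runs whose embeddings fail to resolve the
clusters, so embedding quality should be checked before attributing; raising the
perplexity far enough to force cross-cluster neighbours (e.g. 90 at
shift 6) partially restores selectivity. Recovery is therefore *not*
monotone in the translation amount. Practically: attribute embeddings
whose clusters are near enough to interact, or raise perplexity, and
treat attribution magnitudes on isolated, well-separated clusters with
suspicion.

The generator emulates translation-defined hierarchical clusters with
isotropic noise only. It does not emulate correlated features, count
noise, batch structure, or sparse binary data; passing recovery tests
here demonstrates mechanism, not performance on any particular assay.

## Corruption-based validation

`run_corruption_experiment()` asks whether corrupting the top-attributed
features degrades a refit embedding more than corrupting random subsets
of the same size. Degradation is measured against the reference
embedding by: Spearman correlation of all pairwise distances (global
structure; seeded subsampling beyond $10^6$ pairs), ARI between seeded
K-means clusterings (cluster structure; K defaults to the number of
known classes, else 10; 10 restarts), and mean 10-nearest-neighbour
retention (local structure; ties broken by index). Selection levels
follow the attribution's granularity: per-sample (local), per-class
top-set frequency (class), or corpus-wide top-set frequency (global),
with ties broken by ascending feature index and the per-sample top set
defined by membership in the upper `fraction` quantile of $|A_i|$.
Corruption methods: replace selected cells by the mean of the selected
cells of that feature within the corruption unit (the class at class
level, the whole dataset otherwise — the mean of a single cell would be
a no-op), permute selected cells within feature and unit (seeded), or
drop the feature columns entirely (global level only). Refits use a
fresh perplexity calibration on corrupted data but the same
initialization seed as the reference, isolating the corruption effect
from initialization noise. Cells aggregate over t-SNE seeds with
percentile-bootstrap 95% confidence intervals (1000 resamples by
default). Baselines: absolute feature values, Laplacian score on either
the input affinities P or the embedding kernel Q (ascending = more
important; class-based variants recalibrate per class subset), Fisher
score (supervised), a variance-weighted squared-loadings PCA control
(the "top principal components" control generalized to non-PC inputs),
and seeded random subsets (10 per cell).

Under the reference shift-6 conditions the attribution-guided corruption
does **not** reliably beat random subsets — the expected consequence of
the selectivity loss described above (and the ARI saturates at 1 because
no 10–18% corruption breaks clusters that far apart). The corresponding
acceptance check is left failing at those conditions by design; in the
overlap regime the ordering holds.

One spec-level invariant we do not test: invariance of report cells to
sample order. The seeded Gaussian initialization assigns draws by row
position, so permuting input rows permutes initial positions and changes
individual trajectories; only distributional summaries are
order-invariant.

## Sequence-variant encoding

`encode_mutations()` turns an aligned FASTA (alignment is upstream;
MAFFT or similar) into a binary presence/absence matrix against a named
reference: one feature per (position, alternate state), positions
1-based on the reference after dropping reference-gap columns
(insertions are not encoded). Filters, all tested against hand counts:
deletion runs longer than 12 nt are recoded as missing across their span
(assembly-gap semantics); ambiguity characters are missing; features
observed fewer than twice are dropped; features within 100 positions of
either end are dropped (poorly covered ends). Multi-allelic sites encode
each alternate state independently. `impute_missing()` sets masked cells
to the reference state while retaining pre-imputation missingness
frequencies, which `qc_missingness_correlation()` correlates with
cluster-averaged attributions (Spearman, one-sided permutation p-value,
exhaustive over all $m!$ orderings when $m! \le$ the permutation budget)
— a positive correlation flags clusters organized by missingness rather
than biology. `identify_markers()` applies a per-group 90th-percentile
threshold (type-7 quantiles, features at or above the threshold) to
group-averaged attributions and to feature frequencies and reports the
four quadrants.

## Numerical choices

* Perplexity bisection: entropy tolerance $10^{-5}$, 200 iterations
  maximum, failure names the offending row. Conditionals are floored at
  $10^{-12}$ before symmetrization.
* Divergence guard: any $|y| > 10^8$ aborts with the iteration number.
* Finite-difference oracles use central differences with steps
  $10^{-6}$–$10^{-7}$; at the trajectory level the sensitivity
  magnitudes ($10^5$ and beyond under exaggeration) make the step choice
  matter, and the tests use $10^{-7}$ where convergence studies showed
  truncation error dominating at $10^{-6}$.
* The attribution origin is the embedding centroid (t-SNE output is
  translation-arbitrary; the KL gradient conserves the centroid, so this
  is equivalent to centring the initialization) and is recorded in the
  output metadata.
* Problem sizes in tests and the acceptance script (n = 200–300, d = 30,
  250–500 iterations, 2–5 seeds) were chosen as the smallest at which
  the cluster structure and the mechanisms above are cleanly expressed.

## Known limitations

* Attributions inherit every pathology of the embedding; they explain
  the placement the optimizer produced, not the data-generating process.
* The diagonal-block assumption means $G$ answers a conditional
  ("move only this sample") question; cross-sample influence is invisible.
* Tracked runs with early exaggeration are numerically meaningless (see
  above); the package does not forbid them, but the defaults used in all
  validation avoid them.
* Barnes–Hut mode is 2-D only, and with dense affinities the attractive
  term remains $O(n^2)$.
* The Spearman metric subsamples pairs beyond $n \approx 1400$
  (seeded, recorded in metadata).
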