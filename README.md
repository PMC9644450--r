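# sparsemil

Multiple-instance classification of immune repertoires with sparse
attention pooling.

## The problem

In T-cell receptor (TCR) repertoire studies, one tissue sample yields a
*set* of TCR sequences — a few in some samples, hundreds in others — and a
single label (tumor vs normal). Classical classifiers expect one feature
vector per sample, so this data falls under multiple instance learning
(MIL): each sample is a **bag** with label $y_i \in \{0, 1\}$, each TCR an
**instance** $x_{ij} \in \mathbb{R}^p$ (here $p = 30$, a fixed-length
numeric embedding of the CDR3 amino-acid sequence). Under the *primary
instance assumption*, only a subset of instances — e.g. the TCRs that
recognize tumor antigens — explains the bag label; the rest are noise.

`sparsemil` implements a permutation-invariant neural network that both
classifies bags and *selects* their primary instances:

1. **Instance encoder** — locally fully-connected residual blocks: every
   instance passes through the same $p \times p$ affine map + ReLU (+
   dropout in training), with an identity skip connection, so instances are
   transformed independently with shared weights.
2. **Sparse attention pooling** — each encoded instance $z_j$ gets a score
   $e_j$; the scores are mapped to attention weights by **sparsemax**,

   $$\mathrm{sparsemax}(e) = \arg\min_{\alpha \in \Delta^{K-1}}
     \|\alpha - e\|^2,$$

   the Euclidean projection onto the probability simplex. Unlike softmax,
   the projection sets weights of low-scoring instances to **exactly
   zero**: the support of $\alpha$ is a hard, adaptively thresholded
   selection of primary instances. The bag feature is
   $\tilde z = \sum_j \alpha_j z_j$.
3. **Head** — batch normalization of $\tilde z$, one linear unit, sigmoid
   probability; binary cross-entropy training with Adam.

Variable bag sizes are handled by zero-padding to a capacity $m^*$ with a
validity mask (oversized bags keep their first $m^*$ instances); masked
slots provably receive zero attention and zero gradient, so predictions
are independent of padding and of instance order.

The package also ships the surrounding experimental machinery: a synthetic
bag generator under the primary-instance assumption, stratified 10-fold
cross-validation with AUC, the 2×2 skip/sparsemax ablation grid, capacity
($m^*$) sensitivity sweeps, attention/feature heatmap matrices, selection
against ground truth, mean-distance comparison to reference embedding
sets, rank-based method comparison with an exact Wilcoxon signed-rank
test, an Atchley-factor amino-acid featurizer, and a CLI.

## Worked example

```r
library(sparsemil)

spec <- synthetic_spec(n_bags = 200, positive_fraction = 0.5, p = 30,
                       signal_shift = 1, seed = 42)
bags <- generate_synthetic(spec)

cv <- cross_validate(bags, minn_config(),
                     train_config(epochs = 40, seed = 42), k = 5)
cv
#> <minn_cv> 5 folds: mean AUC 0.9350 (sd 0.0298)

model <- train_minn(bags, minn_config(), train_config(epochs = 40, seed = 42))
selection_recall(model, bags)
#> [1] 0.78

b <- bags[[11]]                       # a positive bag with 4 instances
round(bag_attention(model, list(b))$alpha[1, 1:4], 3)
#> 0 0.271 0.729 0
which(label_primary_instances(model, b))
#> [1] 2 3
```

The CV AUC says the model separates tumor-like from normal-like bags
almost perfectly on this strongly signalled synthetic benchmark; the
recall says 78% of ground-truth signal instances fall inside the sparse
attention support. In the example bag, sparsemax put exactly zero weight
on two instances and concentrated on the two it found most informative —
the zeros are exact, not small.

The same protocols are available from the command line:

```sh
sparsemil simulate --seed 1 --n-bags 400 --out-dir data/
sparsemil cv --bags data/synthetic_bags.tsv --seed 1 --out-dir results/
sparsemil ablation --bags data/synthetic_bags.tsv --seed 1 --out-dir results/
```

## Vignette

`vignettes/sparse-attention-mil.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, and the numerical
choices (tie-breaking at the sparsemax support boundary, masking by
subvector projection, batch-norm conventions, model selection).
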