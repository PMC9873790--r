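---
title: "Mosaic multi-omics integration with trimosaic: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mosaic multi-omics integration with trimosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`trimosaic` treats every single-cell data matrix as a relation between two
entities: a cell batch and a feature modality. Each observed matrix
`X[b,m]` is tri-factorized,

$$
X_{bm} \approx \alpha_{bm}\, C_b\, (\Sigma + \Sigma_{bm})\, C_m^\top
       + b^{cell}_{bm} \mathbf{1}^\top + \mathbf{1}\, {b^{feat}_{bm}}^\top ,
$$

and all matrices are fitted jointly: the cell factor $C_b$ is shared by
every matrix of batch $b$, the feature factor $C_m$ by every matrix of
modality $m$. This sharing is what integrates the mosaic: two batches that
never share a modality still communicate through chains of shared factors,
provided the bipartite graph of batches and modalities (one edge per
matrix) is connected.

Rows of $C_b$ and $C_m$ live on the probability simplex: each latent
dimension is read as a biological program, and a row gives the proportions
with which programs make up a cell or feature. $\Sigma$ is a shared
non-negative $d \times d$ matrix coupling cell programs to feature
programs; $\Sigma_{bm}$ are matrix-specific deviations kept small by the
penalty $\lambda \sum \lVert \Sigma_{bm}\rVert_F^2$, so that per-matrix
technical structure does not contaminate the shared geometry. The scalar
$\alpha_{bm}$ and the two bias vectors absorb per-matrix scale, per-cell
offsets (e.g. depth) and per-feature offsets (e.g. mean level); they have
closed-form minimizers.

### Why the model cannot score down-regulation

Because factors and associations are non-negative and biases absorb
baselines, the low-rank term can only add signal *above* a feature's
baseline. Feature scores produced after retraining (below) therefore rank
features by cluster-specific elevation; a gene that defines a cluster by
absence ranks low, not high. This matters when validating marker rankings
(see "Simulator ground truth" below).

## Training

Mini-batch alternating gradient descent: each iteration resamples 10% of
the rows and columns of every matrix, then updates all cell factors, all
feature factors, the shared $\Sigma$ and each $\Sigma_{bm}$ in that fixed
order with Adam-style adaptive steps, and finally refreshes biases by their
closed-form means on the current mini-batch. The simplex constraint is
enforced by reparameterization — raw parameters pass through a row softmax,
which also satisfies the strict-positivity reading of the constraint — and
$\Sigma$s are clipped to the non-negative orthant after every update.

Numerical choices that experience forced:

* **$\Sigma$ starts at the identity, not 0.** A zero $\Sigma$ is a
  degenerate saddle: the reconstruction is identically zero, the
  trace-ratio update for $\alpha$ divides by zero, and once $\alpha$ jumps
  the factor gradients reverse sign and $\Sigma$ stays clipped at zero.
  $\Sigma_{bm}$, the biases (0) and $\alpha$ (1) keep their natural starts.
* **$\alpha$ is refreshed from the full matrix only** (at checkpoints).
  The closed form is a ratio of inner products; on a 10% x 10% mini-batch
  its denominator is small and noisy and we observed excursions of
  $\alpha$ to $\pm 10^3$ that destroyed training. The bias vectors, whose
  closed forms are plain means, are refreshed per mini-batch without
  trouble.
* **Checkpoints** (every `checkpoint_every` iterations) evaluate the
  full-data loss, fully refresh biases and scales (sequential coordinate
  minimization, which can never increase the loss), record the simplex and
  non-negativity invariants, and abort with diagnostics if the loss is not
  finite.
* Defaults: `d = 30` (20 is ample for simulated data), `lambda = 0.001`,
  `n_iters = 4000`, `batch_frac = 0.1`, `learning_rate = 0.01` (0.02 is a
  good choice for the simulated scales in this package); all are
  `run_config()` fields.

`closed_form_updates()` exposes the bias/scale minimizers. By default each
returned quantity is the minimizer holding the *current* other parameters
fixed (simultaneous semantics, which is what the closed forms define);
`sequential = TRUE` gives the in-training variant where each update sees
the previous one. Only the sequential form guarantees descent, which is
what the corresponding regression test asserts.

## Pseudo-counts and normalization

Missing grid slots declared as `pseudo_slots` are filled from observed
matrices of the same batch: gene activity = binarized row-sums of the
regions within the 2 kb upstream window or the body of each gene
(binarization deliberately discards the region-count/expression scale,
which is not linearly related); protein = the cognate gene's expression
column, composed with gene activity when only accessibility is present.

Per-modality normalization before fitting: gene expression is quantile
normalized per matrix (every cell is forced onto the matrix's mean sorted
profile; ties get the mean of the tied reference values, preserving within-
cell rank order and equalizing row sums); protein abundance is
log(1+x)-then-quantile normalized; accessibility and pseudo-gene-activity
are binarized. Pseudo-protein is normalized like observed protein, so both
enter the loss on the same scale. The quantile reference is per matrix —
nothing in the procedure requires a cross-matrix reference, and a
per-matrix reference leaves each matrix's bias terms to do the cross-matrix
work. Motif-deviation matrices (signed, already normalized by their
producer) pass through untouched; the bias terms absorb their offsets.

Region-gene association reads "lies within" as *any overlap* with the gene
body or the strand-adjusted upstream window `[TSS - 2000, TSS)` —
containment would drop regions straddling a boundary for no biological
reason. Coordinates are 0-based half-open (BED) throughout.

## Graph post-processing

Distances are Euclidean between cell-factor rows (the d-simplex embeds in
Euclidean space; no evidence favors a fancier metric). Each cell receives
`k` neighbors split across batches proportionally to batch size
(floor + largest remainder, minimum 1 per batch, so quotas sum to `k`
exactly); this proportional split is what lets batches with very different
sizes mix. With radius `r < 1`, only the fraction `r` of shortest
cross-batch edges per ordered batch pair is kept — recommended when
batches are known to differ in composition — and within-batch edges are
never pruned. Cross-batch distances are then rescaled per cell by
$\bar d_{ii} / \bar d_{ij}$ (means over the *post-pruning* neighbor sets —
normalization is defined on the graph that survives pruning), which
equalizes each cell's mean within- and cross-batch neighbor distance and is
idempotent. Leiden clustering runs on shared-neighbor (Jaccard) affinities
of the normalized graph: Jaccard weights are scale-free, so clustering is
insensitive to the absolute distance scale the normalization leaves behind.

## Retraining and feature scores

Given cluster labels, the cell factors are replaced by frozen one-hot
indicator matrices (used as-is, no softmax), the latent dimension becomes
the cluster count, and feature factors, associations, biases and scales are
re-learned from fresh initialization — warm starts would leak pre-cluster
structure into per-cluster scores, and biases/scales are cheap to re-learn.
Extra matrices (e.g. chromVAR-style motif deviations) attach to existing
batches as new modalities and receive factors of their own. The score
matrix of modality $m$ is $M = C_m \Sigma^\top$; column $c$ ranks every
feature for cluster $c$, and `top_features()` reports the top-n with ties
broken by feature index.

## The simulator and its ground truth

`simulate_mosaic()` replaces a kinetic-model transcription simulator with a
hierarchical generative model that keeps exactly the structures the method
exploits: shared cell types across batches, a linear region-to-gene
coupling, a one-to-one gene-to-protein coupling, additive per-batch latent
offsets, and a rare type.

Per type $t$: every region $r$ has accessibility logit
$\ell_{tr} = \ell_0 + \beta\,[r\text{ private to a marker gene of }t]
+ u_r + \theta_{tr}$, with baseline $\ell_0 = -2$, marker boost
$\beta = 2.5$, per-region offset $u_r \sim N(0, 0.2)$ and type-specific
offsets $\theta_{tr} \sim N(0, 1)$ — accessibility differs between cell
types genome-wide, not only at marker loci. Gene means are proportional to
the mean activity of the gene's 1-5 private regions times a log-normal
type effect (sd 0.2); expression is negative binomial (size 10),
accessibility Bernoulli, and protein log-normal (sd 0.3) around
1 + the cognate-gene mean. Batch effects are additive $N(0, 0.3)$ offsets
on the logit/log scale per batch and feature. Defaults: 6 batches, 16
types, 50 cells per type, 100 genes with 5 disjoint marker genes per type,
20 proteins mapped onto marker genes, rare type = the last type at 15% of
a normal type's size. Values the source design fixes (16 types, 4 dropped
per batch, tenth-size batches 1/4/6, the 15% rare rule, 8 benchmark seeds)
are defaults; the remaining magnitudes were chosen once as realistic for a
"strong separation, mild batch effect" regime and are not tuned.

What the simulator does **not** emulate: sequencing-depth variation per
cell, trajectory/continuous populations, doublets, zero inflation beyond
the NB/Bernoulli sampling, or peak-set mismatch between accessibility
batches. A green end-to-end test therefore establishes that the machinery
recovers planted cluster structure under the stated noise — not
performance on any real dataset.

**Ground-truth marker rankings** order genes by the *signed* log2 fold
change of noiseless type means (type vs mean of the rest), most
over-expressed first. The signed choice is deliberate: marker genes are
genes elevated in a type, and the model's non-negative scores cannot (by
design, see above) rank absence-markers high. With each gene the exclusive
marker of one type, ranking by |LFC| would put mostly down-regulated genes
on top and no elevation-based score could correlate with it;
`ground_truth_ranking(..., direction = "absolute")` preserves the
symmetric-DE variant for users who want it.

Scenario constructors reshape the paired simulation into the benchmark
layouts (4-of-16 type removal per batch; tenth-size batches 1, 4, 6;
accessibility-only/expression-only splits with or without a bridging
paired batch; a three-modality layout with protein-only batches in the
middle third). The rare type is sized before type removal.

## Metrics

Graph connectivity builds a fresh k = 15 kNN graph from the embedding
(method-agnostic, rather than reusing the method's own normalized graph)
and averages, over types, the largest-connected-component fraction of each
type's induced subgraph. ARI and NMI are computed against truth labels at
every Leiden resolution from 0.1 to 10 in steps of 0.5, and the maxima are
reported independently. NMI normalizes mutual information by the
arithmetic mean of the entropies; Kendall is the tie-corrected tau-b; both
conventions are stated because the source leaves them open. kNN agreement
reduces each pre-integration matrix (PCA-30, or LSI-30 for accessibility)
and averages the fraction of same-label neighbors. Rare-type F1 takes the
cluster with the largest overlap with the true rare set and returns the
harmonic mean of its precision and recall.

## Known limitations

* The optimizer is plain R; fits in the low minutes for ~10^3-10^4 cells
  and would need compiled kernels beyond ~10^5.
* Distance matrices are dense (`stats::dist`), so graph construction is
  O(n^2) memory.
* `d` is not selected automatically; the fit is robust for d above the
  number of latent programs, and too-small d merges types.
* Exact zero entries in $\Sigma$ rows can make individual latent
  dimensions inert after aggressive clipping; the identity start makes
  this rare but a restart with a different seed is the remedy.
* Pseudo-counts assume the region-gene window heuristic; distal regulation
  is invisible to the bridge.
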