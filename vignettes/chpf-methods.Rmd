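---
title: "Classifying cellular hypoxia status: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cellular hypoxia status: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tumor tissue is unevenly oxygenated, and a cell's oxygen state shapes its
transcriptome, its invasiveness and its response to therapy. Bulk hypoxia
signatures smear this heterogeneity out; at single-cell resolution, however,
no one signature can be trusted on its own, because published hypoxia gene
sets come from different experimental systems and disagree on the margins.
`chpf` classifies every cell of an scRNA-seq dataset as *hypoxic* or
*normoxic* by trusting only the cells on which several signatures agree, and
learning the rest.

The framework has three stages:

1. **Signature activity.** Each hypoxia gene set is scored in each cell by
   single-sample gene set enrichment (ssGSEA). For a cell with `G` genes
   ranked by expression in descending order, the score is the accumulated
   difference between the in-set weighted empirical distribution (weights
   `(G - i + 1)^alpha` at ranking position `i`, normalized to one) and the
   uniform out-of-set distribution. Only ranks enter the statistic, so any
   strictly monotone transform of a cell's expression leaves its scores
   unchanged.
2. **High-confidence consensus.** Per signature, a two-component Gaussian
   mixture fitted by EM splits cells into a high- and a low-score group
   (the component with the larger mean is "high"). A cell is
   *high-confidence hypoxic* only if every signature puts it in the high
   group, *high-confidence normoxic* only if every signature puts it in the
   low group; all other cells are left unclassified. The conjunction is
   deliberately strict — with seven signatures, 126 of the 128 possible
   agreement patterns yield "unclassified".
3. **Recall-weighted ensemble.** The top differentially expressed genes
   between the two high-confidence classes (two-sided Wilcoxon rank-sum,
   ranked by raw p-value, default panel 500) become features for a committee
   of gradient-boosted tree classifiers. High-confidence cells are split
   into 5 stratified folds; each of the 100 members trains on all hypoxic
   cells of its training folds plus an equal-size random undersample of
   normoxic cells (hypoxic cells are typically the minority, and an
   unbalanced committee would inherit the imbalance). A member's weight is
   its recall for the hypoxic class on its held-out fold, so members that
   miss true hypoxic cells lose influence. The decision statistic for cell
   `i` is the voting rate

   `v_i = sum_t w_t I_t(i) / sum_t w_t`

   with `I_t(i) = 1` when member `t` predicts hypoxic; `v_i >= 0.5` calls
   the cell hypoxic. High-confidence cells keep their consensus labels; the
   ensemble only decides the cells the consensus could not.

Downstream, genes used by more than 90% of members (positive split gain)
are "stable features", and per cell type a Wilcoxon test with
Benjamini–Hochberg correction retains signature genes at FDR < 0.05 and
log2FC > 1.5 (both strict; log2FC is computed on `mean(expm1(lognorm)) + 1`).

## Critical regulators of status-specific networks

Given a directed TF→target regulatory network per cell status (construction
is external; the package consumes edge lists), each node is scored by five
centralities: total degree, betweenness and harmonic closeness on the
undirected view, eigenvector centrality on the largest connected component,
and PageRank (damping 0.85) on the directed graph. Edge weights are ignored
here: regulatory confidence weights are not shortest-path distances, and
treating them as such would invert their meaning.

The five per-node ranks are scaled to rank ratios `r = rank/N` and
integrated with a Q statistic: the joint probability that the order
statistics of five independent Uniform(0,1) draws fall below the sorted
observed ratios, evaluated with the classical recursion
`Q = k! v_k`, `v_j = sum_i (-1)^(i-1) v_(j-i) r_(k-j+1)^i / i!`. Smaller Q
means jointly more central. The recursion is validated in the test suite
against a Monte-Carlo estimate of the same probability. One property worth
stating plainly: this joint probability is *not* uniformly distributed when
the five ranks are independent and uninformative — it concentrates near
small values (its median under the null is ≈ 0.1 for five metrics). It is a
rank-aggregation score, not a calibrated p-value, and the package documents
it as such; selection uses only its ordering. The top `ceil(0.01 N)` genes
by Q (boundary ties included) are the network's critical genes, and the
critical TFs of the hypoxic network absent from the reference network's
critical set are the status-specific regulators.

## Small scores

* **Hypoxia score**: mean of per-gene z-scored log-normalized expression
  over a signature; the paper-scale alternative formulations (sum,
  enrichment) order cells nearly identically, and the z-mean keeps the
  score comparable across signatures of different sizes. Genes constant
  across cells contribute 0.
* **CNA score**: per cell, the sum of squared inferred copy-number region
  values — zero only for a flat profile.
* **Risk score**: `sum_i coef_i * expr_i` with externally fitted survival
  coefficients; patients split at the median score (a score exactly at the
  median goes to the low-risk group; with an even number of distinct
  scores the split is exactly half/half).
* **WTCS**: weighted-KS enrichment of an up- and a down-set against a
  ranked signature, `(ES_up - ES_down)/2` when the two enrichments have
  opposite signs and 0 otherwise — the connectivity-map convention. Bounded
  by [-1, 1] and antisymmetric under swapping the sets.
* **Drug–TF filter**: Spearman correlation of TF expression against drug
  AUC over shared cell lines, BH-corrected, retained at `|rho| > 0.3` and
  `FDR < 0.05` (both strict); negative rho means sensitivity under the
  lower-AUC-is-sensitive convention.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_cell_fraction` | 0.001 | genes expressed (count > 0) in less than this fraction of cells are removed; the boundary fraction is retained |
| `scale_factor` | 10⁴ | library-size target before `log1p` |
| `alpha` | 0.25 | ssGSEA rank-weight exponent (0 = unweighted KS walk) |
| `n_features` | 500 | DEG panel size, by ascending raw p-value |
| `n_members` | 100 | ensemble size; must be divisible by `k_folds` |
| `k_folds` | 5 | stratified folds; 100/5 = 20 members per fold |
| `nrounds`, `max_depth`, `eta` | 100, 6, 0.1 | per-member boosting configuration |
| `stable_fraction` | 0.9 | member-usage fraction (strictly exceeded) for stable features |
| `sig_fdr`, `sig_lfc` | 0.05, 1.5 | cell-type signature thresholds, both strict |
| `top_frac` | 0.01 | critical-gene fraction of network nodes |

Decisions that were genuinely open, and the choices made:

* "Expressed" means raw count strictly greater than zero.
* ssGSEA consumes log-normalized (not z-scaled) expression by default;
  since the statistic is rank-based within each cell, per-gene scaling
  would only matter through rank changes.
* Ties in expression are broken by lexicographic gene identifier, making
  every score deterministic across runs and platforms.
* A mixture-posterior of exactly 0.5 assigns the cell to the high group,
  and a voting rate of exactly 0.5 calls the cell hypoxic; both boundary
  rules are tested.
* Member recall is computed per member on its own held-out fold (not
  pooled), so each weight reflects exactly the data its member never saw.
* DEG ranking uses raw p-values; the panel is a fixed-size selection, not
  an inference, so multiplicity correction would only reorder ties.
* Gene matching between matrices and signatures is exact string match
  after uppercasing; unmatched signature genes are dropped with a message.

## The synthetic generator

`generate_dataset()` emulates the features the pipeline's statistics rely
on, and nothing more: negative-binomial counts (dispersion 0.5) with
log-normal per-cell library sizes (mean 5,000), a designated fraction of
hypoxic cells (default 20%, a typical order for hypoxic compartments in
solid-tumor cores) whose 200 program genes gain a log2 fold change of 2
with compositional renormalization, cell types assigned independently of
status, hypoxic cells confined to the "core" region, and 7 signatures of
50 genes drawing 80% from the program. It does not emulate real gene
names, chromosomal structure, doublets, ambient RNA or batch effects —
passing tests therefore demonstrate the framework's statistical machinery,
not robustness to those artifacts. `generate_network()` plants hub TFs by
preferential attachment with boosted attractiveness;
`generate_ranked_signature()` plants extremal up/down blocks for WTCS.

All generators are pure functions of their configuration; every random
draw derives from the config seed.

## Problem sizes and numerical choices

The test suite exercises the full pipeline at the default generator scale
(2,000 cells × 2,000 genes, 100 members) for the planted-truth recovery
check across three seeds, and at a reduced scale (500 cells × 600 genes,
20 members) for byte-level determinism and integration checks, chosen so
the whole suite completes in well under half an hour on one CPU. EM uses a
log-likelihood tolerance of 1e-6 with at most 500 iterations, a variance
floor of `1e-8 * var(x)` against component collapse, and k-means
initialization from the caller's seed. Boosting runs single-threaded with
explicit per-member seeds, which makes trained ensembles — and every file
the pipeline writes — bit-reproducible for a fixed configuration. The
ensemble holds members as serialized boosters rather than live handles,
keeping the resident memory of a 100-member committee in the tens of
megabytes.

## Known limitations

* The consensus stage assumes each signature's score distribution is
  reasonably bimodal; on tissues with little genuine hypoxia the mixture
  split is arbitrary and the consensus (correctly) leaves most cells
  unclassified, but the downstream classifier then has little to learn
  from.
* Signatures are user input. The package ships only synthetic ones; real
  analyses should supply curated hypoxia gene sets.
* The Q statistic orders nodes; it is not a p-value and no significance
  threshold is attached to the critical-gene cut.
* GRN construction, CNV inference and survival model fitting are consumed
  as inputs, never performed.
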