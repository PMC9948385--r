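---
title: "Double clustering of cells and patients with LDA"
author: "phenotopics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double clustering of cells and patients with LDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotopics)
```

## The problem and the model

Cytometry-like data arrive as one matrix per patient — thousands of cells
in rows, a handful of fluorescence markers in columns — and the cells are
not comparable across patients until a shared notion of "cell type" has
been established. `phenotopics` solves the two problems jointly (*double
clustering*): it first learns a cell-type vocabulary shared by the whole
cohort, then stratifies patients by modelling their cell-type composition.

**Stage 1 — cell typing.** All patients' cells are concatenated, each
marker is standardized with a pooled Z-score (mean and standard deviation
of the concatenated column), and K-means partitions the standardized cells
into a fixed number `W` of clusters. For an N-marker panel where each
marker is a low/high mixture, the natural choice is `W = 2^N`, one cluster
per binary marker pattern. The pooled (rather than per-patient) Z-score is
what makes the vocabulary transferable: the same standardization and the
same centroids are reused whenever new cells are assigned.

**Stage 2 — patient clustering.** Counting each patient's cells per
cluster gives a patients × cell-types count matrix, which is exactly a
document–word matrix: patients are documents, cell types are words. A
Latent Dirichlet Allocation with `K` topics is fitted to it, with
symmetric Dirichlet priors

$$\theta_d \sim \mathrm{Dirichlet}(\alpha), \qquad
  \phi_k \sim \mathrm{Dirichlet}(\beta),$$

where $\theta_d$ is patient *d*'s distribution over latent phenotypes and
$\phi_k$ is phenotype *k*'s distribution over cell types. Inference is by
collapsed Gibbs sampling: with $\theta$ and $\phi$ integrated out, each
cell token's phenotype assignment $z_i$ is resampled from

$$\mathbb{P}(z_i = k \mid z_{-i}, w_i = w, d_i = d) \;\propto\;
  \frac{C^{WK}_{wk} + \beta}{\sum_{w'} C^{WK}_{w'k} + W\beta}
  \cdot
  \frac{C^{DK}_{dk} + \alpha}{\sum_{k'} C^{DK}_{dk'} + K\alpha},$$

where $C^{WK}$ and $C^{DK}$ are the word–topic and document–topic count
matrices with token *i* removed. Patients are assigned to
$\arg\max_k \theta_{dk}$ (ties to the lowest index), and each cell type
gets a posterior over phenotypes by Bayes inversion,
$\mathbb{P}(k \mid w) \propto \phi_{kw} m_k$ with $m_k$ the
length-weighted empirical topic mass. Both directions are reported:
$\phi$ answers "what does this phenotype look like", the inversion answers
"which phenotype does this cell population point to".

Count tables that already exist — microbial genus abundances, for
instance — enter directly at stage 2.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `W` | `2^N` | vocabulary size (cell types); fixed, never auto-selected |
| `K_topics` | user | number of patient clusters; 2 for a case/control split |
| `alpha` | 1.0 | document–topic concentration; 1 is mild smoothing suited to cohorts of ~100 patients |
| `beta` | 0.1 | topic–word concentration; < 1 favours crisp cell-type signatures per phenotype |
| `n_iterations` | 500 | Gibbs sweeps; the log-likelihood trace lets you check convergence |
| `n_burnin`, `thin` | 200, 10 | retained post-burn-in samples are averaged into θ and φ |
| `sigma` (simulator) | 0.25 | marker noise; the robustness knob — larger values blur the low/high states |
| `distance` (simulator) | — | exact pairwise Euclidean distance between class probability vectors |

No stopping rule is imposed: the chain always runs `n_iterations` sweeps
and the collapsed joint log-likelihood
$\log \mathbb{P}(\mathbf{w}, \mathbf{z} \mid \alpha, \beta)$ is recorded
per sweep as a convergence monitor.

Averaging the smoothed estimates over retained samples (rather than using
the final state) reduces single-sample Monte Carlo noise. No label-switch
correction is applied *within* a chain — for a single converged chain at
this corpus scale the topic labelling is stable — and alignment to ground
truth happens downstream via the majority vote.

## What the simulator emulates — and what it does not

The generator mimics an idealized cytometry cohort. Each marker is a
two-component Gaussian mixture (`mu_low = 0`, `mu_high = 1`, common
`sigma`); a cell's type is the N-bit pattern of its low/high states (bit
*j* of the type code is marker *j*'s state, marker order = column order);
each patient draws `cells_per_patient` types i.i.d. from its class's
probability vector.

Class vectors are built as a blend of the uniform background with a
class-specific one-hot signature,
$v_c = (1-t)\,u + t\,e_c$, $t = \text{distance}/\sqrt{2}$, so that every
pair of classes is *exactly* `distance` apart for any distance up to
$\sqrt{2}$, with no clipping or renormalization. We chose this over
spreading the difference across all coordinates (e.g. orthogonal ±1
signature patterns): diffuse constructions cannot exceed a pairwise
distance of $\sqrt{2/W}$ without clipping — at `W = 16` that caps the knob
at 0.35, too small to express a well-separated regime — whereas the blend
keeps one interpretable knob over its full range and matches the biology
of a disease class being enriched for a characteristic population.
Signature types are drawn by seed; `distance = 0` collapses every class to
the uniform vector.

Reproducibility is structural: each patient's RNG stream is derived from
the root seed and the patient's index, so patient 7 has identical cells
whether the cohort holds 10 patients or 500, and the whole cohort is a
pure function of its `cohort_spec`.

Deliberately **not** simulated: doublets, spillover/compensation, batch
effects, non-Gaussian marker noise, per-patient variability of the class
vector, or real marker panels. Passing tests on this generator show the
pipeline recovers structure *of this idealized form*; they say nothing
about robustness to gating artefacts or batch structure in real FCS data,
whose preprocessing is assumed done upstream.

One property of these conditions is worth stating plainly, because the
test suite measures it: with `cells_per_patient` around $10^3$–$10^4$, the
per-patient multinomial noise on a cell-type frequency is of order
$\sqrt{v_w(1 - v_w)/n} \approx 0.01$, so even a class separation of 0.1 is
several standard errors wide and a converged sampler recovers the classes
almost perfectly. Chance-level behaviour requires separations at or below
the multinomial noise scale (or `sigma` large enough to destroy the
cell-typing stage). The acceptance checks report the accuracy the pipeline
actually attains in the `distance = 0.1` regime rather than assuming it is
at chance.

## Numerical and design choices

* **K-means**: `stats::kmeans`, MacQueen update, 10 random restarts,
  300-iteration cap, seeded. MacQueen avoids both the Quick-TRANSfer
  non-convergence of Hartigan–Wong on $10^5$-cell pooled matrices and
  Lloyd's empty-cluster restarts on nearly noiseless blobs. Nearest-
  centroid assignment breaks ties toward the lowest cluster index.
* **Empty counts** are legitimate: a cell type absent from a patient is a
  word with zero occurrences, and `W` never shrinks.
* **Gibbs initialization**: $z_i \sim \mathrm{Uniform}\{1..K\}$ i.i.d.
  from the seed; sweeps visit tokens in deterministic document-major
  order. The sampler is compiled (Rcpp) and uses R's RNG, so
  `set.seed()`-style reproducibility holds end to end; a pure-R sweep with
  identical semantics is exported for small corpora and for testing.
* **Evaluation**: each predicted cluster maps to the most frequent true
  label among its members (ties toward the label that sorts first); two
  clusters may map to one label, which floors balanced two-class accuracy
  at 0.5. The "cross-validation" is literally repeated balanced
  subsampling: clustering has no train/test split, so each of the
  `n_folds` repetitions draws minority-class-many patients per class,
  re-clusters the subsample and scores it.
* **Consensus networks**: co-assignment frequencies over `n_runs` repeated
  fits (consecutive derived seeds; both the K-means and LDA seeds vary
  unless cell typing is frozen), edges kept when frequency ≥ threshold
  (the boundary is kept, matching "remove below 30%"), self-edges excluded
  and the diagonal fixed at 1.
* **K selection** is the user's: no automatic criterion is implemented;
  use the number of conditions (2 for case/control) or explore a small
  grid.

## Scale of the shipped checks

The test suite and acceptance script run cohorts of 20 patients per
phenotype with 1000 cells each (10 seeds per condition), corpora of 100
documents × 200 tokens for parameter recovery, and exact-posterior
comparisons on ≤ 10-token corpora enumerated over all $2^{10}$
assignments — sizes chosen so the full suite completes in minutes while
keeping every estimate's Monte Carlo error well inside the asserted
tolerances.

## Worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_markers = 2, n_phenotypes = 2,
                    patients_per_phenotype = 20, cells_per_patient = 1000,
                    sigma = 0.25, distance = 1, seed = 1)
cohort <- simulate_cohort(spec)
res <- double_cluster(cohort, K_topics = 2, seed = 2)
majority_vote_accuracy(res$assignments, cohort$labels)$accuracy
round(res$celltype_topic, 2)   # which phenotype each cell type points to

net <- run_consensus(cohort, K_topics = 2, n_runs = 40, base_seed = 10)
table(network_components(net), cohort$labels)
```

## Known limitations

* The vocabulary is a hard partition: soft or hierarchical cell typing
  (mixture models, tree-structured topics) is out of scope.
* A single chain is used; multi-chain convergence diagnostics are left to
  the user via the log-likelihood trace.
* Real FCS ingestion expects pre-processed, compensated, transformed
  matrices; no gating or transform is applied.
* Highly unbalanced cohorts should be evaluated through the balanced
  resampling protocol, not raw accuracy.
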