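---
title: "Condition-specific co-expression networks and gene-set biomarker screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-specific co-expression networks and gene-set biomarker screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Bulk RNA-seq cohorts that span many conditions — tissue regions, disease
states, developmental stages — hide *condition-specific* co-expression:
two genes may be tightly correlated in the samples of one condition and
uncorrelated everywhere else.  A conventional co-expression network
computed over all samples dilutes such relationships below any sensible
threshold.  `csgcn` implements a pipeline that recovers them:

1. **Preprocessing** — log2 transform, a Kolmogorov–Smirnov outlier
   screen on samples, quantile normalization.
2. **Condition-specific network construction** — for every unordered
   gene pair, the samples are clustered in the pair's 2-D expression
   space with full-covariance Gaussian mixture models; Spearman
   correlation is computed *within* each sufficiently large cluster, so
   an edge carries the subset of samples that supports it (its sample
   mask).  The network threshold is chosen by random-matrix theory
   (RMT) on the nearest-neighbor spacing distribution (NNSD) of the
   thresholded correlation matrix's eigenvalues.
3. **Link-community modules** — edges are clustered into modules by
   the standard link-community procedure (edge Jaccard similarity on
   inclusive neighbor sets, single-linkage, partition-density cut).
4. **Label enrichment** — every edge and module is tested for
   enrichment of a sample label (one-sided Fisher exact test, Hochberg
   correction), yielding region-specific sub-networks, unique edges and
   anatomically merged mini-network gene sets.
5. **Biomarker screening (phase I)** — a gene set's expression is used
   to classify samples into regions with a feedforward network (input →
   512 → 256 → 128 ReLU units → softmax) under stratified 10-fold CV;
   the set's fold accuracies are compared by Student's t-test against
   the mean accuracies of 50 random gene sets whose genes are
   length-matched within 10%.  Significance requires p < 0.001 and a
   positive direction.
6. **Combinatorial decomposition (phase II)** — a significant set is
   broken into candidate genes by scoring gene subsets of growing size
   (exhaustively up to size 3, then by beam search), accumulating
   per-gene appearance frequencies, and calling candidates at
   mean + 0.5·SD of the aggregate frequency.  A Random-Forest
   importance ranking provides an independent comparison.
7. **Mutation enrichment** — a gene set's somatic-mutation burden in a
   tumor cohort (distinct mutated genes, tumors with ≥1 mutation, total
   mutations) is compared against 100 size-controlled random gene sets
   with an add-one empirical p-value, called at p < 0.01.
8. **Embedding** — PCA followed by exact t-SNE (perplexity 30)
   visualizes how well a gene set separates the sample regions; the
   mean silhouette width over region labels quantifies it.

Everything is driven by two tabular inputs: a genes × samples
expression matrix (TPM-like) with a sample → region label table and
optional gene lengths, and a simplified mutation table
(`tumor_id`, `tumor_type`, `gene`, one row per mutation event).

## The synthetic study

Because the pipeline's correctness claims are about *recovering planted
structure*, the package ships a first-class generator
(`sim_config()`, `simulate_gem()`, `simulate_mutations()`).  The
reference study is 6 regions × 60 samples, 300 genes, one 10-gene
module planted per region, and a 2-type tumor cohort of 100 tumors per
type with background per-gene mutation probability 0.01 and one 50-gene
set mutated at 5× that rate.

On the log2 scale every gene has a baseline `mu_g`; for a sample of
region `r`, a gene of the module planted in `r` follows

    x = mu_g + noise_sd * (lambda * f + sqrt(1 - lambda^2) * e)

with one shared latent factor `f ~ N(0,1)` per module per sample
(default loading `lambda = 0.95`), while outside `r` the same gene is
downregulated by `region_shift` (default 3 log2 units) with independent
noise.  Background genes are independent noise everywhere.  The emitted
matrix is `2^x`, with a small fraction of zeros injected to exercise
the missing-value path (zeros become missing at the log2 step, and
negative normalized values are excluded from pair clustering).

Two design points deserve emphasis:

* **Module genes are modeled as regional markers.**  Their baselines
  are drawn from N(4.5, 1) on the log2 scale — clearly expressed,
  mirroring the empirical observation that enriched network nodes sit
  well above the all-gene expression average — and they are *down*
  regulated outside their region rather than upregulated inside it.
  The distinction matters because of quantile normalization: if a
  fifth of a 300-gene transcriptome is co-shifted into the extreme
  upper tail of every in-region sample, the module genes occupy the
  same top ranks in every sample, the shared factor cancels out of the
  within-sample ranks, and normalization erases the planted
  correlation.  Keeping in-region values interleaved with the
  background preserves the factor's rank signal.  (At realistic
  transcriptome sizes — tens of thousands of genes with a handful
  planted — both formulations behave identically; the choice is a
  small-transcriptome correction, not a biological claim.)
* **What the generator does not emulate:** library-size artifacts,
  batch effects, count noise (values are log-normal, not NB counts),
  correlated background modules, or realistic mutation spectra
  (trinucleotide context, CNVs).  Passing tests therefore demonstrate
  the machinery recovers the planted generative structure, not that it
  is robust to every artifact of real cohorts.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `ks_threshold` | 0.15 | KS D above which a sample is an outlier (strict >) |
| `min_cluster` | 30 | smallest sample cluster eligible for a correlation |
| `max_components` | 5 | largest per-pair mixture size tried (BIC-selected) |
| `chi2_crit` | 99.607 | NNSD transition critical value; the 99.9% chi-square quantile at 60 histogram bins |
| `edge_alpha` | 1e-10 | adjusted-p threshold for region-enriched edges (strict <) |
| `module_alpha` | 1e-3 | adjusted-p threshold for enriched modules |
| `min_edges` | 3 | smallest link-community module retained |
| `perplexity` | 30 | t-SNE perplexity (requires n > 3 × perplexity) |
| `n_random` | 50 | random gene sets per screened set |
| `size_tolerance` | 0.10 | gene-length matching tolerance for random sets |
| `n_rand` | 100 | randomizations in the mutation test (p < 0.01) |

## Numerical choices

* **Per-pair mixtures.**  EM on full-covariance 2-D Gaussians,
  k-means++ initialization with a few Lloyd steps, 2 restarts,
  tolerance 1e-5 (relative log-likelihood), covariance ridge 1e-6.
  Component count by BIC over 1..5 with early stopping after two
  consecutive non-improvements.  Each pair draws its RNG stream from
  the scan seed and the two *gene names*, so results are independent of
  gene order and chunked scans reproduce the full scan exactly.
* **RMT threshold.**  Scanning thresholds downward, each thresholded
  matrix (max |rho| per pair, zero-degree genes dropped) is
  eigendecomposed; near-duplicate eigenvalues are collapsed and the
  spectrum unfolded through a monotone (Hyman) spline through every
  10th eigenvalue.  The NNSD chi-square uses 60 bins on [0, 3] with
  exponential expected counts; spacings beyond 3 are excluded from
  both observed and expected counts.  Disconnected module blocks have
  independent spectra (superposed point processes → Poisson-like
  spacings); background edges glue the graph into one matrix and push
  the spacings toward the Gaussian-orthogonal-ensemble law.  Because
  the raw statistic is noisy for small matrices, the transition is
  located on a running median (window 5 over distinct edge sets): tau
  is the last threshold whose smoothed statistic is Poisson-consistent
  before the scan ends in sustained exceedance.  A published threshold
  can be supplied verbatim via `tau_override`.
* **Quantile normalization.**  Reference = across-sample mean of
  sorted vectors; ties receive the mean of their tied target
  quantiles; missing entries keep their positions, with the reference
  interpolated for samples with fewer observed values.  Idempotent on
  tie-free data.
* **Enrichment.**  One-sided Fisher p-values are computed as upper
  hypergeometric tails, vectorized across all edge × label tests.
  The Hochberg family is, by default, *all* edge × label tests of one
  labeling variable together — the most conservative reading
  consistent with a single adjusted-p threshold spanning all edges; a
  per-edge family is available (`family = "per_target"`).  Module
  sample sets default to the union of member edges' in-cluster
  samples (`sample_set = "intersection"` available).
* **Classifier.**  Single-precision mini-batch Adam on the
  cross-entropy loss; defaults lr 3e-3, batch 128, 15 epochs (the
  accuracy plateaus well before this on the package's data scale), He
  initialization, per-fold feature standardization by training-set
  statistics.  Deterministic given the seed.
* **Phase-II scoring.**  Every subset is scored with a deterministic
  seed derived from its gene content, so a full-width beam reproduces
  exhaustive enumeration exactly.  The default subset scorer is a
  Random-Forest CV (`ranger`, reduced folds): scoring thousands of
  subsets with the 512/256/128 network is out of proportion at desk
  scale, and the search only needs a consistent relative ranking.  Set
  `scorer = "mlp"` to mirror phase I exactly.  The candidate threshold
  uses the sample (n−1) standard deviation.
* **Random forests.** `ranger` with 100 fully-grown trees; a
  1e-7 impurity-decrease stopping threshold is numerically equivalent
  to growing trees fully, which is the default behavior.
* **Mutation p-values.**  Add-one empirical p `(1 + r) / (1 + n)`
  with ties counted as exceedances, so p is never zero at n = 100; the
  plain `r / n` is also reported.
* **t-SNE.**  Exact (dense) implementation: per-point bandwidth by
  binary search to the target perplexity, early exaggeration 4 for 100
  iterations, learning rate 200, momentum 0.5 → 0.8, random normal
  initialization from the seed.  Adequate for cohort-scale sample
  counts; no Barnes–Hut approximation.

## Worked sizes

The test-suite and the acceptance script run the full pipeline on the
reference study above (44,850 gene pairs, 360 samples), screen the
60-gene planted union against 50 size-controlled random sets, decompose
10-gene sets, and run 100-randomization mutation tests — sizes chosen
so a complete run finishes comfortably on a single core.  Validation
loops (type-I control of the screen, decomposition recall) run their
screens at reduced cost (fewer folds/epochs, smaller forests); the
contracts under test are fold-count robust.

## Known limitations

* The per-pair GMM stage can carve spuriously elongated sub-clusters
  out of pure noise, producing occasional high-|rho| background edge
  clusters; the RMT threshold and the enrichment filter control but do
  not eliminate them (the reference study shows ~2–3% background pair
  false positives at the selected tau).
* RMT thresholding needs enough eigenvalues to be meaningful; on very
  small networks the scan reports "no threshold" and the caller must
  supply one.
* The label-enrichment test conditions on the observed masks; samples
  excluded as missing/negative in a pair reduce its table and can make
  a genuinely specific edge untestable when a marker gene is absent
  almost everywhere else.
* Exact t-SNE is O(n²) per iteration; for cohorts beyond a few
  thousand samples a Barnes–Hut implementation would be required.
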