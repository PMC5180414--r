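---
title: "Methods: three-layer somatic driver and drug prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-layer somatic driver and drug prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, its numerical
choices, and what its synthetic-data tests do and do not establish. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## The three-layer model

A patient's somatic mutation profile is interpreted in three stages, each
producing a ranked table.

### Layer 1: one driver-potential score per variant

Every variant is scored on [0, 1] by category:

* **Point coding mutations** are scored by a support vector machine with
  Gaussian radial kernel $k(u,v) = e^{-\gamma \lVert u-v \rVert^2}$ over
  eleven pathogenicity predictors. Six predictors (SIFT, PolyPhen-2
  HumDiv, LRT, MutationTaster, MutationAssessor, FATHMM) arrive already
  transformed to a 0–1 deleteriousness scale; the other five (GERP++,
  PhyloP, CADD, VEST, SiPhy) live on heterogeneous native scales and are
  min–max scaled with ranges learned from the training table, clamped at
  inference so unseen extremes cannot leave [0, 1]. The scaler is
  persisted inside the model archive, which keeps scoring deterministic
  across sessions. Decision values are mapped to probabilities with a
  Platt sigmoid fitted on *out-of-fold* decision values, so the
  calibration never sees predictions on its own training points.
* **Point non-coding mutations** take a precomputed functional score
  looked up by position; an absent site scores 0. The router between the
  two point categories is the predictor database itself: an exact
  (chrom, pos, ref, alt) hit means coding, anything else flows to the
  non-coding scorer. A position hit with an allele mismatch warns and is
  treated as a miss.
* **Structural variants** take the recurrent focal copy-number signal of
  the regions they overlap, conditional on role: deletion signal counts
  only over tumor-suppressor genes (a loss-of-function reading),
  duplication signal only over oncogenes (gain of function). Any overlap
  of at least one base qualifies; multiple overlaps take the maximum
  signal; no qualifying overlap scores 0 (a value, not an error).
  **Indels**, whose mode of action is unknown a priori, are scored under
  both readings and keep the larger value.

### Layer 2: the logistic gene model

Variants are assigned to their closest gene by genomic distance (0 inside
a span, otherwise the gap to the nearest boundary; ties break
lexicographically for determinism). Per gene, the maxima of the three
layer-1 categories plus a phenotype-driven prior form the feature vector
$x \in [0,1]^4$, and the driver probability is the sigmoid
$h(x) = (1 + e^{-(w^\top x + b)})^{-1}$ of a non-regularized logistic
model fitted by minimizing the mean binary cross-entropy. Genes with
$h(x) \ge 0.11$ are called drivers; the boundary is inclusive (a choice —
the recommended cutoff is stated without a side).

The phenotype prior is deliberately pluggable: a (gene, subtype) score
table on [0, 1]. Genes absent from the table get prior 0, and an unknown
subtype falls back to the default subtype's table with a warning.
Re-deriving the prior from literature mining is out of scope.

### Layer 3: drug ranking

Driver-called genes are expanded to themselves (self-relatedness exactly
1.0) plus their top-4 pathway neighbors by normalized relatedness.
Interaction records are filtered by the direct target's role with fixed
controlled vocabularies: five positively-influencing terms for tumor
suppressors, fifteen negatively-influencing terms for oncogenes, no
filter for other genes; records sourced from the curated FDA list bypass
the term filter. The vocabularies are implemented verbatim as published —
including "agonist"/"partial agonist" among the *negative* oncogene
terms, which is pharmacologically surprising but is the stated contract,
so it is not corrected here. Each drug scores
$\text{gene score} \times \text{relatedness} \times \text{activity}$,
where activity is the per-drug mean assay score (values beyond 1.5 IQR of
the drug's own assays dropped first) min–max normalized across drugs.
Tier 1 means FDA approved (regardless of trial status), tier 2 in active
trials only, tier 3 otherwise; a tumor-type repurposing flag is metadata
only and never changes a score.

Open design points resolved here: both the direct gene and its neighbors
are always queried (neighbor expansion is not conditional on the direct
gene lacking drugs); a drug reachable through several paths keeps only
its best-scoring path; a gene listed as both suppressor and oncogene is
queried broadly as "other" with a warning.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| SVM cost $c$ | 10 | — | published operating point of the tuned model |
| kernel width $\gamma$ | 0.001 | — | idem; larger $\gamma$ = smaller kernel |
| tuning grid | $c \in \{0.1,1,10,100\} \times \gamma \in \{10^{-4..-1}\}$ | — | the published point plus one decade either side; ties within 0.001 AUC break toward smaller $c$ then smaller $\gamma$ (the least overfitting-prone corner) |
| CV folds | 5 | — | published evaluation protocol |
| bootstrap replicates | 2000 | — | published CI protocol (tests use fewer for speed; the parameter is exposed) |
| gene cutoff | 0.11 | probability | recommended binary cutoff, inclusive |
| neighbors $k$ | 4 | genes | published neighbor expansion |
| TDS bin size $X$ | 10 | lines | published default |
| MMAF thresholds | ≤ 0.01 (TP), ≥ 0.20 (TN) | allele freq. | published training/testing filters |
| missing activity | 0.5 | probability | neutral value, flagged `no_activity_data`; the sources are silent on missing assays |
| logistic tolerance | 1e-8 | gradient norm | convergence criterion of the mean-CE Newton fit |

## Numerical choices

* **SMO solver.** The C-SVC dual is solved by sequential minimal
  optimization with maximal-violating-pair working-set selection,
  stopping tolerance 1e-3, full kernel matrix in memory. This is
  appropriate for the package's problem sizes (hundreds to a few thousand
  training vectors) and is fully deterministic — no random working-set
  choices — so fixed-seed training is bit-reproducible.
* **Platt calibration** uses the standard regularized Newton fit with
  step halving on out-of-fold decision values.
* **Logistic fit.** Newton–Raphson with step halving on the mean
  cross-entropy; convergence at gradient norm ≤ 1e-8. Perfect separation
  is reported as an error (with the normalized divergence direction) when
  the fit reaches vanishing loss with every case pinned to its own class;
  a pure gradient criterion cannot make this distinction because the
  mean-CE gradient decays exponentially in the margin. Collinearity
  (pairwise $R^2 \ge 0.90$) aborts the fit up front.
* **AUC** is computed from mid-ranks (Mann–Whitney), so ties credit 0.5
  exactly; the bootstrap CI resamples positives and negatives separately
  (stratified percentile).
* **TDS boundary semantics.** A range query locates the last bin whose
  first coordinate is ≤ start and scans forward until the coordinate
  exceeds the range end; because coordinates are sorted within a key, a
  bin whose first coordinate exceeds the end can be skipped safely, which
  also resolves duplicate coordinates split across bin boundaries.
  Degenerate inputs: an empty database builds an empty index; an unknown
  key returns an empty result (not an error); unsorted input fails with
  the offending line number.
* **Coordinates** are 1-based inclusive internally; BED input is
  converted on ingest; the dash-allele convention marks indels in the
  5-column dialect.

## The synthetic world

The fixture generators emulate every external resource at desk scale,
with defaults of 200 genes, 129-variant patients and 1000 + 1000 labeled
training mutations (tests use smaller sizes where a criterion does not
pin them, to keep the suite fast on one CPU).

* **Predictor scores** load on a single shared latent deleteriousness
  factor plus independent noise — the simplest generator that reproduces
  the mutually positively correlated structure of real pathogenicity
  predictors. The class separation (default 2 latent SD) controls
  difficulty: separation 0 yields chance-level trained models,
  separation 6 near-perfect ones, and both ends are asserted in tests.
* **Gene resources** place non-overlapping spans per chromosome, draw
  disjoint suppressor/oncogene subsets, and put deletion-signal regions
  strictly inside suppressor spans and duplication regions inside
  oncogene spans.
* **The "planted driver" scenario** mirrors the in-paper worked case
  qualitatively: one gene among 129 carries a maximally deleterious
  coding mutation, a 0.9 phenotype prior, and one FDA-approved
  maximum-activity drug targeting it directly; competing priors are
  capped at 0.3 and competing CNV signals at 0.6 so the planted
  configuration dominates by construction.

What a green test establishes: contract correctness (routing,
aggregation, ranking, tie-breaks, serialization), formula correctness
against independent oracles, and qualitative behavior (radial beats
linear on radially separable data; higher separation yields higher AUC).
What it does not establish: real-world discrimination (the published
benchmark AUCs require external curated datasets that are out of scope),
realistic predictor marginals or linkage structure, or calibration
quality on real tumors.

## Known limitations

* Mutation context and protein context columns are emitted as missing:
  HGVS-style annotation needs a transcript database that is out of scope.
* The per-parameter ±10% logistic-recovery acceptance check at n = 5000
  is statistically tight for the two unit-weight parameters (their
  standard errors are ≈ 0.11 against an absolute tolerance of 0.1); it
  passes at the suite's fixed seed, but readers should treat it as a
  marginal criterion by construction, not as evidence of a tighter
  estimator.
* Non-default genome builds require user-supplied databases in matching
  coordinates; coordinate lift-over is out of scope.
* The TDS speed comparison against compressed-index tools is
  hardware-dependent and deliberately not an acceptance gate; only
  correctness (oracle equivalence with a linear scan) is asserted.
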