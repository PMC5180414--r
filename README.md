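# oncotriad

Three-layer interpretation of a single patient's somatic cancer genome:
score every mutation, rank candidate driver genes, and rank candidate
targeted drugs. The package is aimed at method developers and
computational oncologists who need a self-contained, fully testable
implementation of this pipeline — every annotation resource it consumes
can be emulated at miniature scale by the built-in fixture generators, so
the whole system installs, runs and validates offline.

## The model

**Layer 1 — variant scores.** Each somatic mutation receives one
driver-potential score in [0, 1] according to its category:

- *Point coding mutations:* a support vector machine with Gaussian radial
  kernel `k(u, v) = exp(-γ‖u−v‖²)` over eleven normalized pathogenicity
  predictors (SIFT, PolyPhen-2 HumDiv, LRT, MutationTaster,
  MutationAssessor, FATHMM, GERP++, PhyloP, CADD, VEST, SiPhy), with
  default hyperparameters `c = 10`, `γ = 0.001` and Platt-calibrated
  probability output. A point mutation is "coding" exactly when the
  predictor database holds its exact (chrom, pos, ref, alt) row; otherwise
  it is routed to the non-coding scorer.
- *Point non-coding mutations:* a precomputed functional score looked up
  by position (0 when absent).
- *Structural variants and indels:* the recurrent focal copy-number
  signal of overlapping regions — deletions count over tumor-suppressor
  genes (loss of function), duplications over oncogenes (gain of
  function); indels take the more deleterious of the two readings;
  multiple overlaps take the maximum signal.

**Layer 2 — gene scores.** Variants map to their closest gene by genomic
distance. Per gene, the maxima of the three layer-1 score categories plus
a phenotype-driven prior form `x = (svm, funseq, cnv, prior)`, and a
non-regularized logistic model gives the driver probability

```
h(x) = 1 / (1 + exp(−(wᵀx + b)))
```

fitted by minimizing the mean cross-entropy
`(1/m) Σ −yₙ log h(xₙ) − (1−yₙ) log(1−h(xₙ))`. Genes with `h(x) ≥ 0.11`
are called drivers.

**Layer 3 — drug scores.** Each driver-called gene (the *final target*)
is expanded to itself (relatedness 1.0) plus its top-4 pathway neighbors
(*direct targets*). Interaction records are filtered by the target's
cancer role — activating terms for tumor suppressors, inhibiting terms
for oncogenes, anything for other genes — and every reachable drug is
scored by the joint probability

```
drug score = gene score × relatedness × activity
```

with activity the outlier-trimmed, min-max-normalized mean assay score.
Drugs are tiered: 1 = FDA approved, 2 = in active clinical trials,
3 = otherwise.

A by-product is a generic **two-step dictionary index** (`tds_build()` /
`tds_query()`): a binary sidecar index over any sorted key-coordinate
text database, splitting each key's lines into bins of X lines (default
10) so a query costs two random accesses plus at most X sequential line
reads per touched bin.

## Worked example

The bundled fixture world plants one driver gene (maximally deleterious
coding mutation, high phenotype prior) among 129 mutated genes, plus one
FDA-approved drug targeting it:

```r
library(oncotriad)
cli_main(c("demo-run", "--seed", "1", "--out-prefix", "demo/P1"))
#> top gene: GEN0001 (score 0.917)
#> top drug: TARGETINIB (score 0.917, tier 1)
```

`demo/P1.genes.csv` then begins (scores printed to three decimals):

```
Gene name,Gene category,Maximum radial SVM score,Maximum FunSeq2 score,Maximum normalized CNV signal score,Phenolyzer score,Driver gene score
GEN0001,KEGG cancer pathway,0.991,0.000,0.000,0.900,0.917
GEN0193,Other,0.805,0.000,0.000,0.203,0.558
```

Read: the planted gene's best coding mutation scored 0.991 under the
calibrated radial SVM, its phenotype prior is 0.900, and the logistic
layer turns the four features into a 0.917 driver probability — rank 1 of
129. The drug table's first row multiplies that 0.917 by the
self-relatedness 1.000 and the planted drug's normalized activity 1.000
into a drug score of 0.917, tier 1:

```
Drug name,Final target gene,Direct target gene,Driver gene score,BioSystems normalized relatedness probability,PubChem normalized drug active probability,Driver drug score,Tier,...
TARGETINIB,GEN0001,GEN0001,0.917,1.000,1.000,0.917,1,...
```

A JSON mirror (`demo/P1.json`) carries the same three tables.

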