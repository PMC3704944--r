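---
title: "Drug repositioning from integrated similarity layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug repositioning from integrated similarity layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugrepo)
```

## The idea

Most computational repositioning methods look for drug-disease
relationships. `drugrepo` takes a drug-centered route instead: build a
classifier that predicts each drug's therapeutic class (its WHO ATC
level-2 code, e.g. `L01` for antineoplastic agents) from the drug's own
characteristics, and then read its *stable misclassifications* as
repositioning hypotheses. A drug whose chemistry, targets and induced
expression response all resemble antineoplastic agents — yet which is
labelled as an anthelmintic — is not a classifier failure; it is a
candidate for reuse in oncology. The classifier is therefore built to
extract knowledge about known drugs, not to predict classes for unseen
ones, and its cross-validated accuracy serves as the credibility budget
for the misclassifications it produces.

## The three dissimilarity layers

All three layers are pairwise drug-drug *dissimilarities* in $[0, 1]$,
which makes heterogeneous data directly fusable.

**Chemical structure.** Each drug is a fixed-length binary substructure
fingerprint $\mathcal{B}_i$ (any fixed-length fingerprint works; the
SMILES reader uses ChemmineR atom-pair fingerprints, 1024 bits by
default). With the Jaccard index $JI$, cosine similarity $CS$ and Dice
coefficient $DC$ of the corresponding bit sets,

$$K^{CHEM}_{ij} = 1 - \frac{JI(\mathcal{B}_i,\mathcal{B}_j) +
CS(\mathcal{B}_i,\mathcal{B}_j) + DC(\mathcal{B}_i,\mathcal{B}_j)}{3}.$$

Averaging three overlap measures rather than picking one damps the
idiosyncrasies of each (Jaccard punishes size imbalance hardest, Dice
least). The formula is undefined on empty sets, so drugs without a
fingerprint (or, below, without targets) are excluded before matrices
are built.

**Molecular targets.** Two components are averaged. $K^{TAR\prime}$
applies the same three-measure formula to the drugs' target protein
sets. Because target sets are small, that measure is coarse
(many pairs tie at 1), so it is complemented by $K^{TAR\prime\prime}$:
the length of the shortest path in the protein-protein interaction
network between any target of drug $i$ and any target of drug $j$
(0 when they share a target), range-normalized to $[0, 1]$ over all
drug pairs. Targets absent from the network are ignored for the path
search; a pair with no finite connecting path is assigned the longest
finite distance observed in the cohort plus one *before* normalization,
which keeps unreachable pairs maximally dissimilar without infinities.

**Gene expression.** Each drug's differential-expression table
(per-gene p-value and fold-change sign, produced upstream by a
limma-style contrast against controls) is turned into a signed rank
profile: genes are sorted by the key $-\mathrm{sign}(\Delta)(1 - p)$,
so significantly up-regulated genes rank first, significantly
down-regulated genes last, and non-significant genes drift to the
middle; ties get average ranks. Two profiles are compared with a
weighted Spearman's Footrule,

$$K^{GEX}_{ij} = N\!\left[\sum_g |R_i(g) - R_j(g)| \,
\frac{W_i(g) + W_j(g)}{2}\right], \qquad W_D(g) = 1 - p_D(g),$$

with $N$ denoting the same range normalization. The weights make the
footrule care most about genes that are confidently differential in at
least one of the two profiles.

A note on the rank key: a literal reading of "rank by signed p-value"
(key $-\mathrm{sign}(\Delta)\,p$) would place *high*-p up-regulated
genes ahead of low-p ones, contradicting the intended ordering stated
above. The package therefore uses $-\mathrm{sign}(\Delta)(1 - p)$ by
default and keeps the literal key available as
`rank_key = "literal"` so both conventions remain testable.

## Fusion, filtering, embedding, classification

The joint matrix is the elementwise mean
$\hat{K} = (K^{GEX} + K^{TAR} + K^{CHEM})/3$ over the drugs present in
all three layers. Drugs in ATC level-2 classes with fewer than
`min_class_size` members (default 8) are then removed: tiny classes
cannot be learned and sabotage stratified cross-validation. Multiple
ATC codes per drug are resolved by keeping the first listed (or
dropping the drug, `multi_atc = "drop"`).

$\hat{K}$ is a biologically-weighted kernel but a poor input for
kernel classifiers directly. Classical multidimensional scaling
(principal coordinates analysis) converts it to Euclidean coordinates:
$B = -\tfrac12 J \hat{K}^{(2)} J$ is eigendecomposed and coordinates
are kept for eigenvalues above $10^{-9} \lambda_{\max}$ (numerical
guard for "positive"); negative eigenvalues — the non-Euclidean part of
the fused dissimilarity — are dropped rather than corrected by additive
constants.

The embedding dimension is a denoising knob: too few dimensions discard
class signal, too many re-admit noise. `select_dimension()` evaluates a
Gaussian-kernel multiclass SVM (`e1071::svm`, one-against-one) by
stratified 6-fold cross-validation on the first $i$ principal
coordinates for every candidate $i$ and takes the error-minimizing
dimension, breaking ties toward the smaller one. The fold assignment is
drawn once per call (stratified, so no fold loses a class) and reused
across all candidate dimensions; the raw argmin is used without curve
smoothing. The SVM hyperparameter *rule* is fixed throughout:
$\gamma = 1/(d \cdot \mathrm{var}(\text{coords}))$ — a scale-free
default recomputed on each candidate subspace, since a single absolute
$\gamma$ cannot fit both a 1-D and a 100-D projection — and $C = 1$.
Both can be overridden.

## From misclassifications to repositioning scores

`bootstrap_predict()` repeats, for a configurable number of iterations
(10,000 in the reference protocol; hundreds suffice for the synthetic
cohorts here): draw a random 90% of the drugs *without replacement*,
train the SVM on them, predict the held-out 10%, and increment each
held-out drug's count for its predicted class. Sampling without
replacement — rather than with-replacement resampling — is what "90% of
the drugs" requires; predictions are accumulated for held-out drugs
only, so the same counts consistently yield an out-of-sample accuracy
estimate (`accumulate = "all"` reproduces the alternative reading).
Drugs never held out by chance receive forced extra iterations, so
every drug ends with at least one prediction.

The frequency of class $c$ among drug $j$'s predictions is the
repositioning score $S_{c,j} \in [0,1]$; per drug the scores form a
probability distribution. The most frequent class is the final
prediction (ties broken lexicographically and flagged), and the
fraction of drugs whose final prediction matches their label is the
mode accuracy. Every other predicted class is a repositioning
suggestion with reliability $S_{c,j}$; `repositioning_report()` lists
them sorted by score and `class_flow_summary()` aggregates them into
class-to-class flow edges. The package reports both the mode accuracy
and the mean per-iteration held-out accuracy, which need not coincide.

## The synthetic cohort generator

Real inputs at the original scale (thousands of expression arrays,
a full drug-structure database, a genome-wide interaction network and
curated ATC assignments) are external resources; the generator builds
self-contained cohorts that carry the same *statistical* structure, so
the whole pipeline is testable offline:

- **Fingerprints**: one random prototype per class (bits set with
  density 0.3 over 256 bits), members flip each bit independently with
  probability 0.02. Within-class Hamming distances then follow the
  binomial expectation $2 L \rho (1-\rho)$.
- **Targets/network**: an Erdős–Rényi graph (400 proteins, edge
  probability 0.015, mean degree 6; a Barabási–Albert option exists
  because real interaction networks are heavy-tailed), one disjoint
  connected 6-protein module per class found by seeded breadth-first
  search, each drug drawing 2-6 module proteins.
- **Expression**: 1000 genes; 40 per class are differential for that
  class's drugs with $p = 0.01\,u$, $u \sim U(0,1]$, and a
  class-coherent sign; all other p-values uniform on $(0,1]$ with
  random signs.
- **Mislabelling**: a chosen fraction of drugs keep their
  feature-generating class but receive another class's label; the truth
  table records each planted event. These are the ground truth against
  which repositioning recovery is measured.

Defaults (10 classes × 12 drugs, 1000 genes) mirror the reference
cohort class-wise — every class comfortably clears the min-8 filter —
at desk scale; the gene universe is kept small since the footrule is
linear in it. The end-to-end checks in the test suite run this
generator at exactly these settings with 500 subsampling iterations.
What passing them shows is that the machinery — layers, fusion,
embedding, dimension search, scoring — correctly recovers structure it
is able to represent; it does not show that real chemistry, real
interaction networks (the generator's graph is not scale-free by
default, its modules are disjoint) or real expression noise (no
correlation between genes, no batch structure) are as benign.

## Numerical choices and degenerate inputs

- Range normalization is $(x - \min)/(\max - \min)$ over all
  off-diagonal entries of the matrix at hand; a degenerate range (all
  raw values equal) maps to all-zero rather than erroring.
- Symmetry is enforced to $10^{-12}$ on construction and on matrix
  read; matrix TSVs carry 17 significant digits so round trips are
  bit-exact.
- A p-value of exactly 0 is rejected (weights would saturate and the
  upstream test cannot produce it); a log fold change of exactly 0 is
  assigned sign $+1$, an arbitrary but fixed convention.
- An all-zero dissimilarity matrix has no positive eigenvalues and
  raises a "degenerate embedding" error instead of returning an empty
  coordinate matrix.
- Training subsets that lose all but one class are redrawn (counted,
  capped at 100 per iteration).

## A short example

```{r example, eval = FALSE}
co <- generate_cohort(cohort_spec(mislabel_fraction = 0.05, seed = 42))
res <- run_repositioning(co, iterations = 500, seed = 7)
res
#> repositioning_result: 120 drugs, 10 classes
#>   positive eigenvalues: 63; selected dimension: 3 (CV error 0.050)
#>   mode-prediction accuracy: 0.950; heldout accuracy: 0.945
#>   repositioning records: 11 (6 with score 1)
subset(res$report, score == 1)
co$truth     # the six planted mislabellings, all recovered above
```

## Limitations

The method ranks hypotheses; it attaches no significance test to a
repositioning score, and a score of 1 means "the classifier never
wavered", not "the repositioning is correct". Accuracy and scores are
in-cohort quantities: drugs outside the training cohort cannot be
scored. Layers are fused with equal weights; drugs missing any layer
are dropped rather than imputed. ATC level 2 is the only label
granularity supported.
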