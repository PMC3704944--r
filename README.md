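# drugrepo

Drug repositioning by re-reading a classifier's mistakes.

`drugrepo` predicts the WHO ATC level-2 therapeutic class of each drug
in a cohort from three integrated layers of drug-drug dissimilarity,
and then interprets the drugs it *systematically misclassifies* as
repositioning candidates: if everything measurable about an
anthelmintic — its chemical substructures, where its targets sit in the
protein-protein interaction network, the expression response it
induces — says "antineoplastic agent", that disagreement with the label
is the finding.

The three layers, each a pairwise dissimilarity in [0, 1]:

- **K<sup>CHEM</sup>** — binary fingerprints compared by
  `1 − (JI + CS + DC)/3` (Jaccard index, cosine similarity, Dice
  coefficient of the bit sets);
- **K<sup>TAR</sup>** — the mean of the same set measure on target
  protein sets and the range-normalized shortest-path distance between
  target sets on a PPI network;
- **K<sup>GEX</sup>** — a weighted Spearman's Footrule
  `N[ Σ_g |R_i(g) − R_j(g)| · (W_i(g)+W_j(g))/2 ]` on signed p-value
  rank profiles, with weights `W = 1 − p`.

The fused matrix `K̂ = (K^GEX + K^TAR + K^CHEM)/3`, restricted to ATC
classes with ≥ 8 members, is embedded by classical multidimensional
scaling; the embedding dimension is chosen by stratified 6-fold
cross-validated error of a Gaussian-kernel multiclass SVM; repeated
90/10 subsampling then turns each drug's prediction frequencies into
repositioning scores `S ∈ [0, 1]`.

A synthetic cohort generator (`cohort_spec()` / `generate_cohort()`)
produces all five inputs with planted class structure and an optional
fraction of deliberately mislabelled drugs, so the whole pipeline is
testable end to end with no external data.

## Worked example

Generate a 120-drug cohort (10 classes × 12 drugs) in which 6 drugs
carry the data of one class but the label of another, and run the full
pipeline:

```r
library(drugrepo)
co  <- generate_cohort(cohort_spec(mislabel_fraction = 0.05, seed = 42))
res <- run_repositioning(co, iterations = 500, seed = 7)
res
#> repositioning_result: 120 drugs, 10 classes
#>   positive eigenvalues: 63; selected dimension: 3 (CV error 0.050)
#>   mode-prediction accuracy: 0.950; heldout accuracy: 0.945
#>   repositioning records: 11 (6 with score 1)
```

The accuracy of 0.950 is exactly the ceiling for this cohort: the 114
correctly labelled drugs are all recovered, and the 6 planted
mislabellings are — by design — "misclassified". Those six are the
score-1 repositioning records, and each one points to the drug's true
feature class:

```r
subset(res$report, score == 1)
#>   drug_id original_atc2 predicted_atc2 score n_eval is_confirmation
#> 1    D016           C03            B02     1     45           FALSE
#> 2    D024           J10            B02     1     53           FALSE
#> 3    D029           I09            C03     1     47           FALSE
#> 4    D061           D04            F06     1     50           FALSE
#> 5    D064           J10            F06     1     60           FALSE
#> 6    D082           D04            G07     1     48           FALSE
co$truth
#>   drug_id label_class feature_class
#> 1    D016         C03           B02
#> ...                                  # identical six rows
```

`score = 1` means the held-out SVM assigned that class in every one of
the drug's `n_eval` evaluations; `res$flows` aggregates the records
into class-to-class flow edges for network drawing.

Real cohorts enter through the readers — `read_fingerprints()` (bit
tables or SMILES), `read_targets()`, `read_ppi()`,
`read_expression_stats()`, `read_atc()` — and a thin command-line front
end (`inst/cli/drugrepo.R`) exposes each stage
(`simulate`, `layers`, `integrate`, `embed`, `select-dim`,
`reposition`) for shell pipelines.

See `vignettes/repositioning-method.Rmd` for the model, its
assumptions, parameter defaults and known limitations.

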