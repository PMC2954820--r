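# hipred

Predicting haploinsufficiency from gene properties, and scoring the
pathogenicity of genic deletions.

## What it does, and for whom

Most genes tolerate the loss of one copy; a few hundred do not, and those
haploinsufficient (HI) genes account for much of the pathogenicity of the
large heterozygous deletions seen in clinical microarray practice. hipred
is for statistical geneticists and clinical-genomics analysts who need to
move from "this patient carries a 2 Mb deletion" to "this deletion is more
damaging than anything seen in 99% of healthy controls". It provides:

* **Loss-of-function (LOF) annotation** of deletion CNVs against
  transcript models, by five explicit criteria applied in a fixed order
  (deletion of over half the CDS; of the start codon; of the entire first
  exon; of a 2-bp splice signal; a frameshifting partial CDS loss). Genes
  whose every coding transcript is disrupted in `>= 2` distinct healthy
  individuals form a *haplosufficient* (HS) training catalog.
* **A linear discriminant classifier** trained on HI-vs-HS labels over
  gene properties (dN/dS, summed promoter conservation over the
  `[-100, 100)` TSS window, an 8-fold embryonic over-expression flag, and
  weighted network proximity to known HI genes), with variance scaling so
  the coefficient magnitudes read as per-feature contributions. Every
  predictable gene gets a posterior probability of haploinsufficiency,
  `p(HI)`, evaluated by repeated stratified 10-fold cross-validation (AUC,
  MCC), with constrained feature selection, predictive-mean-matching
  imputation, and enrichment validation utilities.
* **Deletion LOD scores.** For a deletion covering genes with
  probabilities `p_i`, with `q = prod(1 - p_i)`,

  ```
  LOD = log10((1 - q) / q)
  ```

  the log-odds that at least one deleted gene causes haploinsufficiency
  versus none. A deletion is judged by the fraction of healthy controls
  whose own most-pathogenic deletion scores at least as high, using raw
  control cohorts or packaged percentile tables; the same score pooled
  over a genome's unique deleted genes gives a genome-wide
  haploinsufficiency burden.
* **A synthetic-data module** that generates every input — toy gene
  models with planted LOF deletions, two-class Gaussian features with a
  known optimal AUC, networks with planted seed proximity, control LOD
  cohorts — with ground truth, so the whole pipeline is testable without
  any external data.

## Worked example

```r
library(hipred)

## 1. haplosufficient catalog from deletion CNVs
sim <- simulate_genome_and_cnvs(n_genes = 80, n_lof_recurrent = 15,
                                n_lof_single = 8, n_benign = 8,
                                n_individuals = 40, seed = 1)
catalog <- build_hs_catalog(sim$cnvs, sim$models, min_individuals = 2)
catalog
#> hs_catalog: 15 genes at >= 2 individuals (23 putative at >= 1)
#> LOF events by criterion: over_half_cds=31, start_codon=12, first_exon=24,
#>   splice_signal=28, frameshift=18
```

The 15 genes recurrently lost in distinct individuals are exactly the 15
planted recurrent-LOF genes; the 8 single-carrier genes appear only in the
putative set, and the 8 benign intronic deletions disrupt nothing.

```r
## 2. train the LDA model and cross-validate
feats <- simulate_feature_classes(n_hi = 1000, n_hs = 1000,
                                  target_auc = 0.81, seed = 1)
model <- fit_lda(feats$features, feats$labels)
model
#> lda_model: 4 features, trained on 1000 HI / 1000 HS (0 rows dropped)
#>     f1     f2     f3     f4
#> 0.4476 0.4425 0.4525 0.6154
cv <- cross_validate(feats$features, feats$labels, repeats = 30, seed = 1)
cv
#> cv_result: 10-fold x 30 repeats  mean AUC 0.789, mean MCC 0.414
```

The printed coefficients are the absolute discriminant weights after
variance scaling — the per-feature contributions. The generator drew the
two classes at an analytically optimal AUC of 0.81, and cross-validation
recovers that ceiling up to dataset-level sampling noise.

```r
## 3. score every gene, then a deletion
phi <- predict_phi(model, feats$features)
head(phi, 3)
#>   gene_id       phi        provenance
#> 1  G00001 0.8641402 observed_features
#> 2  G00002 0.7007969 observed_features
#> 3  G00003 0.7185322 observed_features

lod <- lod_score(c(0.92, 0.15, 0.40))
lod
#> [1] 1.371249
empirical_p(lod, load_control_percentiles("AA"))
#> [1] 0.03530003
```

A deletion removing three genes with `p(HI)` of 0.92, 0.15 and 0.40 has
LOD 1.37: odds of about 23:1 that at least one of the three causes
haploinsufficiency. Roughly 3.5% of African-American healthy controls
carry a deletion scoring at least as high, so this deletion is suspicious
but not exceptional.

A thin command-line wrapper over the same functions ships in
`inst/scripts/hipred.R` (`call-lof`, `train`, `predict`, `score-deletion`,
`simulate`).

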