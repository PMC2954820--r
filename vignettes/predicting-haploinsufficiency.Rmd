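---
title: "Predicting haploinsufficiency and scoring deletion pathogenicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting haploinsufficiency and scoring deletion pathogenicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Haploinsufficiency (HI) — a single functional gene copy being insufficient
for normal function — is the most direct pathogenic mechanism for the large
heterozygous deletions seen in clinical array-CGH practice. Whether a given
deletion is pathogenic therefore depends mostly on *which* genes it
disrupts, not on how long it is. hipred implements a complete framework for
that judgement: it learns what distinguishes known HI genes from genes that
demonstrably tolerate heterozygous loss, assigns every predictable gene a
probability `p(HI)`, and aggregates those probabilities into a per-deletion
log-odds (LOD) score that can be compared against the distribution of
scores carried by healthy individuals.

The training signal on the "tolerant" side comes from deletion CNVs in
healthy cohorts: genes repeatedly and unambiguously lost in people who
enrolled as controls are operationally *haplosufficient* (HS).

## Loss-of-function calling

A deletion disrupts a transcript if it satisfies any of five criteria,
evaluated in a fixed order with the first hit reported:

1. **over_half_cds** — strictly more than 50% of the coding bases removed.
   Exactly half does not qualify ("over half" is read literally).
2. **start_codon** — any of the three 5'-most CDS bases removed
   (strand-aware; the codon may straddle a CDS junction).
3. **first_exon** — the 5'-most exon *fully contained* in the deletion.
   Partial 5' overlaps are not counted here; when they matter they are
   captured by the start-codon rule. This avoids double-counting ambiguous
   partial hits.
4. **splice_signal** — overlap with any 2-bp intronic window flanking an
   exon boundary (donor and acceptor, every intron). The windows are
   positional only; no sequence is read, which keeps the pipeline
   annotation-only.
5. **frameshift** — a partial CDS hit whose deleted coding length is not a
   multiple of 3. This is only reachable when the deletion neither misses
   the CDS nor contains it (a whole-CDS deletion is already caught by rule
   1).

A *gene* is LOF in an individual only when **every** coding transcript has
at least one disrupting deletion from that individual (different
transcripts may be hit by different deletions). Genes LOF in at least
`min_individuals` distinct individuals (default 2 — recurrence guards
against call artifacts and undiagnosed carriers) form the HS catalog;
the `>= 1` set is kept as "putative". A per-criterion tally of
transcript-level events is reported so the contribution of each rule is
auditable.

## Predictor variables

* **dN/dS** — coding constraint; consumed as a per-gene column.
* **Promoter conservation** — a per-base conservation score summed over
  the `[-100, 100)` window about each transcript's TSS (the 5' end;
  reflected on the minus strand so offset −100 is always upstream in
  transcription direction) and summarized per gene by the **median** over
  transcripts, the same reduction used for all per-transcript quantities.
  Computing the conservation track itself is out of scope; it is read as
  a plain (chrom, pos, score) TSV.
* **Embryonic expression** — binary; 1 when the gene is at least 8-fold
  over-expressed in any embryonic dataset relative to its reference level
  (union across datasets; an embryonic signal over a zero reference counts
  as passing, two zeros do not).
* **Network proximity to known HI genes** — the sum of log-likelihood edge
  weights from the gene to the seed (known-HI) set in a probabilistic
  functional network. Of the two proximity measures exposed (weighted
  direct-edge sum and unweighted shortest-path hops) the weighted sum is
  the shipped predictor, because it uses the network's likelihood weights
  directly; hops are kept as an alternative column. For genes that are
  themselves seeds, leave-one-out removal from the seed set (the default)
  prevents label leakage into training.
* **Tissue specificity** — SD of expression across tissues after each
  gene's profile is normalized to sum 1. Row normalization is an
  interpretation choice: the SD of an unnormalized profile confounds
  expression magnitude with specificity.

Descriptive properties (transcript length, 3'UTR length, paralog identity,
interaction-partner counts) are carried for the HI-vs-HS comparison report
but are not part of the shipped 4-feature model.

Group comparisons use a two-tailed Mann–Whitney U test for continuous
properties and a two-sided Fisher's exact test for binary ones, with group
means reported as z-scores against the genome average (error bars of
2 × SEM). The Mann–Whitney kernel enumerates all group assignments exactly
for combined sizes ≤ 16 without ties, and otherwise uses the normal
approximation with tie correction; when every value is tied the p-value
is 1.

Feature-subset selection enumerates candidate subsets and requires
(i) joint non-missing coverage of at least half the genes and (ii) all
pairwise |Spearman| < 0.3 (average ranks for ties, computed on jointly
non-missing genes), then ranks the survivors by cross-validated AUC.
Candidates are processed in sorted name order so the outcome cannot depend
on column order.

## The classifier

Linear discriminant analysis with a pooled within-class covariance. Each
feature is divided by its training SD before entering the model, so the
absolute discriminant coefficients are directly comparable as per-feature
contributions; this also makes `p(HI)` invariant to any positive rescaling
of a raw feature. The discriminant is `w = S⁻¹(μ_HI − μ_HS)` and the
posterior is logistic in the discriminant score with an intercept from the
class means and priors.

Choices the data do not dictate, surfaced as options:

* **Priors** default to the empirical training frequencies
  (`priors = "equal"` is available). The shape of the genome-wide `p(HI)`
  distribution — in particular how bimodal it looks — depends on this
  choice, so it is recorded in the model object.
* **MCC threshold** is a posterior of 0.5, configurable.
* **Cross-validation** is stratified 10-fold, repeated 30 times by
  default with a mandatory seed; AUC and MCC are pooled over folds within
  a repeat and averaged over repeats (pooled-per-repeat rather than
  per-fold averaging — the alternative convention would differ only in
  fold-level noise).
* **Training is complete-case** by default; predictive mean matching
  (PMM) imputation is opt-in. PMM regresses each incomplete feature on the
  others over complete cases, and each missing cell receives the observed
  value of one of the 5 nearest complete cases by predicted value
  (uniformly at random). Features are processed in order of increasing
  missingness; recipients whose predictors are themselves missing use
  donor-pool means for the prediction step only. Imputed cells are flagged
  so scored genes carry an `imputed_features` provenance.

Degenerate inputs are handled explicitly: a singular pooled covariance
raises a collinearity error; identical class means fit with a warning and
a zero discriminant; constant features are rejected at scaling.

Predicted-HI enrichment tests label the top 10% of scored genes as
predicted HI. Two fold-enrichment definitions coexist and are always
labeled, because both appear in published validation arithmetic: the
sample **odds ratio** of a 2×2 table (set A vs set B), and the
**proportion ratio** of a set's predicted-HI fraction against the 10%
baseline.

## Deletion scoring

For a deletion covering genes with probabilities `p_i`, with
`q = Π(1 − p_i)` (independence between genes assumed):

```
LOD = log10((1 − q) / q)
```

Base 10 matches the magnitudes of the tabulated control percentiles and
the term "LOD". Probabilities are clamped into `[1e-6, 1 − 1e-6]` before
the product — several training genes saturate at `p(HI) = 1`, and an
unclamped score would be infinite; the epsilon is configurable and small
enough that no realistic score is affected. A gene without `p(HI)` is
skipped and counted, never treated as `p = 0`. By default a deletion's
gene set is the genes it renders LOF under the rules above;
`overlap_mode` widens this to any overlapped gene (how published
pathogenic-deletion sets were mapped to genes is not stated, so both
modes exist).

Each individual is summarized by their maximal deletion LOD; the
pathogenicity of a query deletion is the fraction of control individuals
whose maximal LOD is **at least** the query's (ties counted in, reading
"same or greater" literally). With raw control values this is exact with
resolution 1/N; with a packaged percentile table (50/90/95/99th
percentiles for an African-American and a European-American control
cohort) the survival probability is linearly interpolated between
tabulated points and clamped to the outermost tabulated percentile beyond
them — the table simply carries no resolution past its tails, so queries
below the 50th percentile report 0.5 and above the 99th report 0.01.

The same machinery pools the unique LOF genes across all deletions of one
genome into a single genome-wide haploinsufficiency burden LOD.
`roc_compare` benchmarks LOD against deletion length and gene count,
taking the most extreme control deletion per individual as the control
representative for each metric.

## What the synthetic module emulates — and what it does not

Every input has a generator with planted ground truth:

* `simulate_genome_and_cnvs` builds three-exon toy transcripts whose
  5'-most exon is untranslated, so that *every* criterion — including
  first-exon deletion — can be planted without an earlier rule firing
  first. Deletions are engineered per criterion and verified at
  construction; infeasible requests (a splice deletion on a single-exon
  transcript) fail with an error naming the conflict. Defaults: 200
  genes, 100 individuals, 40 recurrent-LOF genes (2–4 carriers), 20
  single-carrier genes, 20 benign intronic deletions.
* `simulate_feature_classes` is the generative twin of the classifier:
  two multivariate-Gaussian classes with shared covariance (default: unit
  variances, 0.2 correlation), class separation set so the analytic
  optimal AUC `Φ(Δ/√2)` equals a target (default 0.81, 1000 genes per
  class, 4 features — the operating point of the real-data model), plus
  optional MCAR missingness.
* `simulate_network` plants extra seed-adjacent edges (default 3 per
  class-1 gene, Gamma(2,1) weights) on an Erdős–Rényi background.
* `simulate_control_lods` draws per-individual maximal LODs from a
  shifted Gamma whose median sits just below 0 with a right tail into the
  low single digits, the shape of real control maxima.

Generators derive their RNG stream from the master seed plus a fixed
per-generator offset, so adding a generator never perturbs existing
fixtures, and identical seeds give byte-identical files.

These simulations validate the *machinery*, not the biology: real gene
properties are not Gaussian (the embryonic flag is binary, dN/dS is
bounded and skewed), missingness in real annotation is informative rather
than MCAR, real CNV breakpoints do not respect gene territories, and real
networks are modular rather than Erdős–Rényi. A passing suite therefore
shows that the rules, estimator, scores and their numerics are correct —
not that 0.81 AUC is attainable on any particular new data source.

## Problem sizes and runtime

The test suite and the acceptance script are sized for interactive use:
LOF recovery on 200 genes × 100 individuals, classifier checks at up to
2000 genes per class, 10-fold × 30-repeat cross-validation at 1000 genes
per class, exact-enumeration cross-checks at group sizes ≤ 7 (Mann–
Whitney), margins ≤ 30 (Fisher) and 1000 random vectors (LOD). The full
suite runs in well under a minute.

## Known limitations

* The HS catalog inherits any systematic miscalling in the input CNVs;
  recurrence (`min_individuals = 2`) mitigates but cannot eliminate this.
* `p(HI)` is a posterior under the model, not a calibrated genome-wide
  HI rate — the true fraction of HI genes is unknown, so calibration
  cannot be assessed, only relative enrichment.
* The LOD score assumes no interaction between co-deleted genes.
* Percentile-table mode cannot distinguish scores beyond the tabulated
  99th percentile; use raw control values where available.
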