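---
title: "svforest: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{svforest: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Rare exon-altering deletions and duplications are a recurrent cause of
undiagnosed Mendelian disease, but most of the rare structural variants
(SVs) in any genome are benign. `svforest` produces a per-variant
pathogenicity score so that the handful of compelling variants can be
prioritized for manual review. The score is produced by a random forest
over 17 annotation features; it equals the fraction of trees that vote
"pathogenic" and therefore lives in [0, 1]. It is a ranking statistic, not
a calibrated probability, and we recommend ranking over hard thresholds
wherever the downstream workflow permits.

Two modelling commitments shape everything else:

* **Rare versus rare.** The clinically relevant contrast is rare pathogenic
  against *rare* benign variants. Classifiers trained against common
  variation tend to learn allele-frequency surrogates instead. The curation
  pipeline therefore retains only records with minor allele frequency
  (MAF) below 1% — computed for catalog records as
  `observed_events / (2 × samplesize)` — and distinguishes rare records with
  at least one homozygous carrier (putatively benign) from rare records with
  none (unlabeled, but overwhelmingly benign).
* **Size must not be a label surrogate.** Pathogenic and benign catalogs are
  acquired by different detection technologies with different size
  sensitivities. Each pathogenic SV of size `N` is therefore paired with an
  unused benign SV of the same type (DEL/DUP) whose size falls inside
  `[N/α − s, N·α + s]`, walking an ordered list of benign tiers (most to
  least trusted) and dropping pathogenic records that match nowhere.

## The 17 features

Coordinates are 0-based half-open throughout (BED arithmetic); VCF POS
converts on read and write. A variant is scoreable when it overlaps at
least one exon of an APPRIS principal transcript by ≥ 1 bp; abutting
intervals do not overlap. Intronic and intergenic variants are refused
rather than scored.

* **CDS disruption** (per gene; aggregated min / min / max across genes):
  with `L` the principal-transcript CDS length, the fraction of coding
  sequence 5′ of the first disrupted coding base (1 when undisrupted), the
  fraction 3′ of the last disrupted base, and the fraction of CDS
  overlapped. All three are computed in transcript orientation, so the
  "start" side of a minus-strand gene is the genomic right end.
* **Gene importance**: minimum LOEUF and maximum pLI over overlapped genes,
  plus *highly impacted* variants restricted to genes whose principal start
  codon (pLI) or stop codon (LOEUF) is contained in the variant, or with
  CDS overlap fraction > 0.5. "Contains the codon" is implemented as
  containing the first/last coding base, the simplest strand-aware reading.
* **Conservation and expression**: the track value of interest is averaged
  over the 400 highest-valued run-length units of the variant ∩ exon space;
  with fewer than 400 covered units, all covered units are averaged. Exon
  expression at a nucleotide is the sum of the TPMs of transcripts covering
  it; exon inclusion divides that sum by the total TPM of the containing
  gene (undefined — not zero — for zero-TPM genes; where exons of two genes
  overlap, expression sums across both and the larger per-gene inclusion is
  kept).
* **TAD boundary strength**: maximum strength among boundaries intersecting
  the variant.
* **Exon structure**: minimum exon transcript order (the number of exons
  preceding an overlapped exon in its principal transcript), minimum exon
  count among hit genes, maximum number of exons overlapped in one gene,
  whether any overlapped exon is constitutive, and whether all overlapped
  exons could be skipped in frame.
* **Type**: deletion versus duplication.

Missing values (no CDS in a hit gene, unscored gene, no trigger met, empty
track, no boundary) are imputed with training medians; boolean features use
the training majority, ties resolved to `FALSE`. Medians are computed
before imputation and stored inside the trained model so that inference
reproduces training-time behavior exactly.

### Design choices where the definitions were genuinely open

* **Top-400 unit.** The track conventions can count either nucleotides or
  merged equal-valued intervals. We default to *run-length intervals*,
  unweighted by width, for both conservation and expression, because the
  interval reading is the one that generalizes to the fewer-than-400 case;
  a per-nucleotide mode is available via `unit = "nucleotide"`.
* **Conservation support.** Conservation is restricted to variant ∩ exon
  space (like expression), not the whole variant span, keeping every track
  feature on the same support.
* **Size-match window.** The window is multiplicative with additive slack,
  `[N/α − 20, N·α + 20]`, with α = 1.06101 and 20 bp slack as defaults;
  both are `match_config()` parameters. Within a tier the size-closest
  candidate is consumed, ties to the smaller, which preserves the size
  distribution best; pathogenic records are processed in input order
  (configurable to size-ascending) for determinism.
* **Duplicate calls.** Reciprocal overlap at or above 0.9 counts as a
  duplicate (`dup_cmp = ">="`, configurable), and the greedy sweep keeps
  either the first appearance or the smallest record depending on the
  dataset convention being reproduced.
* **Constitutive exon** means coordinate-identical presence in every
  annotated transcript of the gene — an annotation-level definition that is
  deterministic and directly testable, rather than an inclusion-ratio
  estimate.
* **In-frame skippability** is evaluated per overlapped exon (internal exon,
  length ≡ 0 mod 3), reading "all overlapped exons can be skipped"
  distributively; joint (summed-length) skippability is a plausible
  alternative we did not adopt.
* **Boolean aggregation across genes** follows the semantics of the names:
  `any_exon_constitutive` is an OR, `all_exons_inframe_skippable` an AND.
* **Principal transcript** selection takes the best (lowest) APPRIS rank,
  breaking ties by transcript length and then lexicographic id, making the
  choice permutation-invariant over annotation row order. Genes without
  APPRIS annotation are dropped with a logged count. Exon indices and
  eligibility use principal-transcript exons only; alternative transcripts
  enter only the constitutive-exon test and the expression formulas.
* **Imprecise breakpoints** (CIPOS/CIEND) are ignored; point estimates are
  used.

## The classifier

`forest_config()` defaults to the selected hyperparameters: 1,000 trees,
maximum depth 10, **one feature considered per split**, minimum 2 samples
per leaf, minimum 4 to split, no out-of-bag estimation. One feature per
split is unusual but deliberate: with strongly correlated features it
decorrelates the trees. The backing implementation is `ranger` with
`num.threads = 1` and a fixed seed, which makes training bit-reproducible;
`min.bucket` maps to the per-leaf minimum and `min.node.size` to the
per-split minimum. The full 576-point hyperparameter grid (depths 5/10/15/∞
× 1–4 features × leaf 1/2/4 × split 2/4 × 500/1,000/3,000 trees × OOB
on/off) is exposed by `default_param_grid()` and searched with
leave-one-chromosome-out validation, optionally restricted to
high-confidence sources.

Records above 3 Mb are excluded from training and scored 1.0 at inference:
the model never sees that size regime, and observed benign SVs that large
are rare enough that the rule dominates any feature-based estimate.
Class weights are not used because size matching brings the classes to
roughly 1:1 by construction.

## Evaluation

ROC curves are built by a threshold sweep with tied scores grouped;
`score ≥ t` counts as positive so that the 3 Mb score of exactly 1.0 is
always called pathogenic. The trapezoid AUC equals the Mann–Whitney
statistic with half-credit for ties (asserted to 1e-9 in the tests). The
AUC standard error follows Hanley & McNeil,

$$SE^2 = \frac{A(1-A) + (n_1-1)(Q_1 - A^2) + (n_2-1)(Q_2 - A^2)}{n_1 n_2},
\quad Q_1 = \frac{A}{2-A},\ Q_2 = \frac{2A^2}{1+A},$$

with a 95% interval `A ± 1.96·SE` clipped to [0, 1]; we use the
untransformed interval. The sensitivity threshold is the largest score cut
reaching the target sensitivity. Leave-one-chromosome-out folds and the
chromosome 1/3/5/7 held-out split prevent positional leakage; a
one-SV-per-gene subsample (greedy, in seeded random order) measures
performance without gene-level clustering.

## What the synthetic generator emulates — and what it does not

`fixture_spec()` defines the study conditions under which the package is
tested: 2,000 genes on eight 30-Mb chromosomes; 3–12 exons per gene with an
optional alternate transcript skipping one internal exon; a bimodal gene
population (25% constrained: pLI ∈ [0.9, 1], LOEUF ∈ [0.05, 0.35]; the rest
unconstrained) with 5% of genes missing from the score table;
piecewise-constant phyloP-like conservation (blocks of 3–20 bp, baseline
mean 0.5, sd 1) elevated by +2.0 on constrained genes' exons; log-normal
transcript TPMs over five tissues, pooled by summation; and log-uniform SV
sizes over 50 bp–3 Mb for *both* classes, so no size signal separates them.

The planted class contrast mirrors the real contrasts the features exploit:
pathogenic SVs fall in constrained genes with probability 0.9 (clinical
catalogs are dominated by established disease genes), anchor on the start
codon half the time, and ablate their whole gene when large enough with
probability 0.4 (whole-gene loss is a hallmark of reported pathogenic
CNVs). Benign SVs anchor uniformly over exonic space except that they enter
constrained genes with probability only 0.05, emulating the depletion of
standing structural variation in constrained genes under purifying
selection. Both classes share one placement sampler, so setting the effect
probabilities equal (and the boost to zero) makes the class distributions
identical by construction — the null fixture used in testing.

What the generator does **not** emulate: linkage structure, realistic gene
density or exon-length distributions, sequence content, caller artifacts
(imprecise breakpoints, genotyping error), database-specific duplication
patterns, or the gene-level clustering of clinical catalogs beyond the
constrained-gene preference. Passing tests on these fixtures demonstrate
that the implementation computes its definitions correctly and that the
training machinery recovers a planted, realistic signal — not that any
particular accuracy will be achieved on real data.

A note on the label-shuffled control used in the tests: a forest refit to
shuffled labels amplifies whatever accidental correlation the shuffle has
with the dominant feature axis, so a *single* shuffled-control AUC has high
variance even when the expected value is exactly 0.5. The test suite
therefore averages the control over five shuffle replicates per seed and
five seeds.

## Numerical and degenerate-input conventions

* Track construction unions overlapping equal-valued intervals and rejects
  overlaps with conflicting values; adjacent equal values merge, so the
  run-length representation is canonical regardless of input order.
* Uncovered bases yield "no value", which propagates to a missing feature
  (never silently zero).
* Spearman correlations of constant features are reported as 0 with a
  warning; the correlation matrix is ordered by average-linkage clustering
  on 1 − ρ, with a configurable list of sign-flipped features (the LOEUF
  and CDS-adjacency features, which run opposite to pLI) to keep the
  clustered blocks positive.
* Wilcoxon paired tests drop zero differences; fully tied input returns
  p = 1 with a warning; single pairs are an error.
* `dgv_maf` caps computed MAF at 1 with a warning; zero sample sizes are an
  error.
* Model files embed a format version; loading any other version is an error
  naming both versions.

## Problem sizes used by the test suite

Unit tests run on a 60-gene, four-chromosome bundle. The feature oracle
check compares 200 random variants (≤ 100 kb) against an independent
per-base implementation at 1e-9. The recovery experiment trains on 2,000
and tests on 500 variants for each of five seeds, with five label-shuffled
refits per seed; deduplication is cross-checked against an O(n²) oracle on
twenty 500-record instances. These sizes were chosen so the full suite
exercises every pipeline stage at statistically meaningful scale while
remaining comfortable to run on a laptop.

## Known limitations

* Inversions, insertions, breakends and multi-sample genotypes are out of
  scope; only DEL/DUP records are read, and others are dropped with a
  count.
* Scores are not probabilities and are not calibrated; thresholds derived
  on one dataset (e.g. a 90%-sensitivity cut) will not transfer exactly to
  cohorts with different benign/pathogenic composition.
* A single MAF per record is assumed; multi-allelic frequency bookkeeping
  is not modelled.
* The feature set is gene-centric: fully non-coding variants are refused,
  and regulatory effects beyond TAD-boundary strength are not represented.
* Trained models serialize the fitted forest via RDS; models are portable
  across machines but tied to the package's model-format version.
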