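# svforest

Random-forest pathogenicity scoring of exon-altering structural variants
(SVs).

Clinical genome sequencing surfaces thousands of deletions and duplications
per proband, and most of the rare exon-altering ones are benign. `svforest`
helps clinicians and researchers rank these variants: it annotates each
DEL/DUP with **17 features** spanning gene importance (pLI, LOEUF, and their
"highly impacted gene" variants), coding-sequence disruption (fraction of
CDS overlapped, and the undisrupted fractions adjacent to the start and stop
codons), conservation (mean phyloP of the 400 most conserved overlapped
units), expression (per-nucleotide exon expression and exon inclusion
derived from transcript TPMs), TAD-boundary strength, and exon structure
(constitutive exons, in-frame skippability, exon order and counts) — then
scores the variant with a random forest. The score is the **fraction of
decision trees voting pathogenic**, in [0, 1]; it is a ranking statistic,
not a probability. Variants larger than 3 Mb are scored 1.0 by rule, since
benign SVs that large are vanishingly rare.

The package also implements the full training-set curation pipeline for
building a **rare, size-matched** case/control set — reciprocal-overlap
deduplication (`min(shared/|a|, shared/|b|)`), allele-frequency rarity
classes (MAF < 1%, split by homozygote carriers), common-variant removal,
and tiered size matching in the multiplicative window
`[N/α − 20, N·α + 20]` (α = 1.06101) — plus leave-one-chromosome-out
evaluation utilities with Hanley–McNeil AUC standard errors:

SE² = [A(1−A) + (n₁−1)(Q₁−A²) + (n₂−1)(Q₂−A²)] / (n₁n₂),
Q₁ = A/(2−A), Q₂ = 2A²/(1+A).

Everything runs end-to-end on synthetic annotation bundles generated by the
package itself; no external genomic resources are required to use, test, or
benchmark the code. With real resources (Ensembl gene models with APPRIS
tags, a phyloP track, GTEx transcript TPMs, gnomAD constraint scores, TAD
boundaries) the same functions annotate and score real variant calls.

## Worked example

```r
library(svforest)

# 1. synthetic annotation bundle + labeled SV sets (seed-deterministic)
spec <- fixture_spec(seed = 42, n_pathogenic = 400,
                     n_benign_tiers = c(clinvar_likely_benign = 120,
                                        clinvar_benign = 120, apes = 80,
                                        gnomad_rare_benign = 80,
                                        gnomad_rare_unlabeled = 100))
generate_annotation_bundle(spec, "bundle")
bundle <- load_annotation_bundle("bundle")
svs <- generate_labeled_svs(spec, bundle)

# 2. curation: size filter + tiered size-and-type matching
matched <- size_match(filter_by_size(svs$pathogenic),
                      lapply(svs$benign_tiers, filter_by_size),
                      match_config())
pairs <- attr(matched, "pairs")
table(matched$tier)
#>                  apes        clinvar_benign clinvar_likely_benign
#>                    56                    95                   103
#>    gnomad_rare_benign gnomad_rare_unlabeled
#>                    42                    36

# 3. features + held-out chromosome split + training
train_svs <- rbind(pairs$pathogenic, pairs$benign)
labels <- rep(c("pathogenic", "benign"), each = nrow(pairs$pathogenic))
fm <- sv_features(train_svs, bundle)
test <- normalize_chrom(train_svs$chrom) %in% c("1", "3", "5", "7")
model <- train_forest(fm[!test, ], labels[!test], forest_config(seed = 42))
model
#> sv_model: 1000 trees over 17 features; trained on 155 benign, 168 pathogenic

# 4. evaluation on the held-out chromosomes
scores <- predict_scores(model, fm[test, ], sizes = sv_size(train_svs)[test])
roc_auc(scores, labels[test])
#> AUC 0.889 (95% CI 0.853-0.925; Hanley-McNeil SE 0.0184; n+=164 n-=177)
sensitivity_threshold(scores, labels[test], target = 0.9)
#> $threshold
#> [1] 0.673
#> $sensitivity
#> [1] 0.902439
#> $fpr
#> [1] 0.220339

round(sort(gini_importances(model), decreasing = TRUE)[1:5], 3)
#>         phylop_top400             loeuf_min               pli_max
#>                 0.215                 0.176                 0.169
#>   pli_high_impact_max loeuf_high_impact_min
#>                 0.082                 0.080
```

Each tier-matched benign SV lies within the size window of its pathogenic
partner, so the two size distributions coincide and the forest cannot learn
acquisition-driven size bias. On the held-out chromosomes the model
separates planted pathogenic from benign variants (AUC 0.89), reaches 90%
sensitivity at a score threshold of 0.67 with a 22% false-positive rate, and
attributes the most importance to the conservation and gene-constraint
features that carry the planted signal.

## Command-line interface

A thin Rscript front end is installed at
`system.file("scripts", "svforest", package = "svforest")`:

```sh
svforest fixtures --out bundle/ --seed 3 --pathogenic 120 --benign 60,60,60
svforest train    --features features.tsv --out model.rds --seed 7
svforest score    --vcf in.vcf --annotations bundle/ --model model.rds --out scored.tsv
svforest evaluate --scores scored.tsv --labels labels.tsv --target-sensitivity 0.9
svforest importance --model model.rds
```

`score` accepts VCF (SVTYPE with END or SVLEN in INFO) or a headered TSV,
drops non-exonic records with a message, and writes
`chrom,start,end,svtype,id,score` (or an annotated VCF with `--format vcf`).

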