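# Hand-built single-gene bundle used by several blocks: + strand, CDS
# [100,400) across three exons.
plus_gene_bundle <- function() {
  df <- gene_rows("G1", "T1", 1, "+", "1",
                  iv(c(50, 150, 250), c(120, 220, 420)),
                  cds = iv(c(100, 150, 250), c(120, 220, 400)))
  annotation_bundle(build_gene_models(df),
                    scores = data.frame(gene_id = "G1", pli = 0.99,
                                        loeuf = 0.3))
}

test_that("CDS triple matches the disruption definitions on the + strand", {
  # CDS pieces [100,120) [150,220) [250,400): L = 240. SV hitting the last
  # CDS piece exactly: first disrupted coding base is CDS coordinate 90.
  b <- plus_gene_bundle()
  f <- cds_features(sv_records("1", 250, 420, "DEL"), b)
  expect_equal(unname(f), c(90 / 240, 0, 150 / 240))
})

test_that("an SV missing the CDS but hitting a non-coding exon scores (1,1,0)", {
  b <- plus_gene_bundle()
  f <- cds_features(sv_records("1", 50, 90, "DEL"), b)  # 5' UTR only
  expect_equal(unname(f), c(1, 1, 0))
})

test_that("minus-strand CDS features agree with the per-base oracle", {
  df <- gene_rows("G1", "T1", 1, "-", "1",
                  iv(c(50, 150, 250), c(120, 220, 420)),
                  cds = iv(c(100, 150, 250), c(120, 220, 400)))
  b <- annotation_bundle(build_gene_models(df))
  # 3' of the minus-strand transcript is the genomic left end
  f <- cds_features(sv_records("1", 90, 130, "DEL"), b)
  # disrupted genomic [100,120) = transcript-space tail (coords 220-239 of
  # L = 240): 5' of the first disrupted base keeps 220/240, 3' nothing
  expect_equal(unname(f), c(220 / 240, 0, 20 / 240))
})

test_that("multi-gene aggregation is min/min/max for the CDS triple", {
  df <- rbind(
    gene_rows("A", "TA", 1, "+", "1", iv(100, 400), cds = iv(100, 400)),
    gene_rows("B", "TB", 1, "+", "1", iv(300, 700), cds = iv(300, 700)))
  b <- annotation_bundle(build_gene_models(df))
  # SV [340,400): A overlapped (240-300)/300, B (40-100)/400
  f <- cds_features(sv_records("1", 340, 400, "DEL"), b)
  expect_equal(unname(f), c(min(240 / 300, 40 / 400),
                            min(0, 300 / 400),
                            max(60 / 300, 60 / 400)))
})

test_that("top-400 averages all units when fewer than 400 are covered", {
  tr <- pb_track(data.frame(chrom = "1", start = seq(0, 90, 10),
                            end = seq(10, 100, 10), value = 1:10))
  sv <- sv_records("1", 0, 100, "DEL")
  space <- iv(0, 100)
  expect_equal(top400_track_mean(sv, tr, space), mean(1:10))
})

test_that("top-400 per-nucleotide mode averages the 400 best bases", {
  # 1000 bases: 400 at 2.0, 600 at 0.0
  tr <- pb_track(data.frame(chrom = "1", start = c(0, 400), end = c(400, 1000),
                            value = c(2, 0)))
  sv <- sv_records("1", 0, 1000, "DEL")
  expect_equal(top400_track_mean(sv, tr, iv(0, 1000), unit = "nucleotide"), 2)
  # interval mode sees two run-length units
  expect_equal(top400_track_mean(sv, tr, iv(0, 1000), unit = "interval"), 1)
  # empty track over the space -> missing
  expect_true(is.na(top400_track_mean(sv, pb_track(), iv(0, 1000))))
})

test_that("top-400 interval mode takes the 400 highest of many units", {
  with_seed(9, {
    v <- round(rnorm(1000), 6)
    v <- v + c(0, cumsum(abs(diff(v)) < 1e-12))  # ensure no equal neighbors
    tr <- pb_track(data.frame(chrom = "1", start = 0:999, end = 1:1000,
                              value = v))
    sv <- sv_records("1", 0, 1000, "DEL")
    expect_equal(top400_track_mean(sv, tr, iv(0, 1000)),
                 mean(sort(v, decreasing = TRUE)[1:400]))
  })
})

test_that("high-impact gene scores require the start/stop or >50% CDS trigger", {
  b <- plus_gene_bundle()
  # covers ~40% of CDS, no start codon (CDS starts at 100)
  f1 <- gene_importance_features(sv_records("1", 280, 400, "DEL"), b)
  expect_true(is.na(f1["pli_high_impact_max"]))
  expect_equal(unname(f1["pli_max"]), 0.99)
  # covers the start codon
  f2 <- gene_importance_features(sv_records("1", 90, 130, "DEL"), b)
  expect_equal(unname(f2["pli_high_impact_max"]), 0.99)
  expect_true(is.na(f2["loeuf_high_impact_min"]))  # stop codon untouched
  # covers > 50% of CDS
  f3 <- gene_importance_features(sv_records("1", 150, 420, "DEL"), b)
  expect_equal(unname(f3["pli_high_impact_max"]), 0.99)
  expect_equal(unname(f3["loeuf_high_impact_min"]), 0.3)
  # unscored gene -> all importance features missing
  df <- gene_rows("G1", "T1", 1, "+", "1", iv(50, 120), cds = iv(100, 120))
  b2 <- annotation_bundle(build_gene_models(df))
  f4 <- gene_importance_features(sv_records("1", 90, 130, "DEL"), b2)
  expect_true(all(is.na(f4)))
})

test_that("exon structure features follow the transcript-order footnote", {
  ex <- iv(seq(0, 9000, 1000), seq(0, 9000, 1000) + 100)
  df <- gene_rows("G1", "T1", 1, "+", "1", ex, cds = ex)
  b <- annotation_bundle(build_gene_models(df))
  # overlap exons 3-5 (1-based): genomic [2000,4100)
  f <- exon_structure_features(sv_records("1", 2050, 4050, "DEL"), b)
  expect_equal(unname(f["min_exon_order"]), 2)
  expect_equal(unname(f["max_exons_overlapped"]), 3)
  expect_equal(unname(f["min_exons_in_gene"]), 10)
  expect_equal(unname(f["any_exon_constitutive"]), 1)  # single transcript

  # minus strand: same overlap counts from the other end
  dfm <- gene_rows("G1", "T1", 1, "-", "1", ex, cds = ex)
  bm <- annotation_bundle(build_gene_models(dfm))
  fm <- exon_structure_features(sv_records("1", 2050, 4050, "DEL"), bm)
  expect_equal(unname(fm["min_exon_order"]), 10 - 5)
})

test_that("in-frame skippability needs internal exons with length % 3 == 0", {
  mk <- function(len2, len3) {
    ex <- iv(c(0, 1000, 2000, 3000), c(100, 1000 + len2, 2000 + len3, 3100))
    annotation_bundle(build_gene_models(
      gene_rows("G1", "T1", 1, "+", "1", ex, cds = ex)))
  }
  sv <- sv_records("1", 1000, 2500, "DEL")  # hits exons 2 and 3
  expect_equal(unname(exon_structure_features(
    sv, mk(81, 120))["all_exons_inframe_skippable"]), 1)
  expect_equal(unname(exon_structure_features(
    sv, mk(81, 100))["all_exons_inframe_skippable"]), 0)
  # first/last exons can never be skipped in frame
  expect_equal(unname(exon_structure_features(
    sv_records("1", 0, 50, "DEL"), mk(81, 120))["all_exons_inframe_skippable"]), 0)
})

test_that("constitutive means identical coordinates in every transcript", {
  ex <- iv(c(0, 1000, 2000), c(90, 1090, 2090))
  df <- rbind(
    gene_rows("G1", "T1", 1, "+", "1", ex),
    gene_rows("G1", "T2", 2, "+", "1", iv(c(0, 2000), c(90, 2090))))
  b <- annotation_bundle(build_gene_models(df))
  f_mid <- exon_structure_features(sv_records("1", 1000, 1050, "DEL"), b)
  expect_equal(unname(f_mid["any_exon_constitutive"]), 0)  # skipped by T2
  f_first <- exon_structure_features(sv_records("1", 0, 50, "DEL"), b)
  expect_equal(unname(f_first["any_exon_constitutive"]), 1)
})

test_that("TAD strength takes the maximum and respects half-open abutment", {
  tads <- data.frame(chrom = "1", start = c(100, 300), end = c(200, 400),
                     strength = c(0.3, 0.9))
  expect_equal(tad_feature(sv_records("1", 150, 350, "DEL"), tads), 0.9)
  expect_true(is.na(tad_feature(sv_records("1", 500, 600, "DEL"), tads)))
  expect_true(is.na(tad_feature(sv_records("1", 0, 100, "DEL"), tads)))
})

test_that("golden worked case reproduces its closed-form feature vector", {
  wc <- worked_feature_case()
  got <- assemble_features(wc$sv, wc$bundle)
  expect_identical(unname(is.na(got)), unname(is.na(wc$expected)))
  nn <- !is.na(wc$expected)
  expect_equal(unname(got[nn]), unname(wc$expected[nn]), tolerance = 1e-12)
  # DUP twin: identical except is_deletion
  dup <- wc$sv; dup$svtype <- "DUP"
  got_dup <- assemble_features(dup, wc$bundle)
  expect_equal(got_dup[setdiff(names(got_dup), "is_deletion")][nn[-17]],
               got[setdiff(names(got), "is_deletion")][nn[-17]])
  expect_equal(unname(got_dup["is_deletion"]), 0)
})

test_that("intronic-only SVs are refused as not scoreable", {
  b <- plus_gene_bundle()
  expect_error(assemble_features(sv_records("1", 230, 240, "DEL"), b),
               "exon-altering")
  fm <- sv_features(sv_records("1", 230, 240, "DEL"), b, on_no_exon = "keep")
  expect_true(all(is.na(fm[, sv_feature_names])))
})

test_that("missing values are imputed from supplied medians", {
  wc <- worked_feature_case()
  med <- setNames(rep(0.42, 17), sv_feature_names)
  got <- assemble_features(wc$sv, wc$bundle, medians = med)
  expect_equal(unname(got["loeuf_high_impact_min"]), 0.42)
  expect_true(attr(got, "missing")["loeuf_high_impact_min"])
  expect_false(attr(got, "missing")["pli_max"])
})

test_that("feature medians use the majority for booleans, median otherwise", {
  fm <- data.frame(id = letters[1:5])
  for (nm in sv_feature_names) fm[[nm]] <- c(1, 2, 3, 4, NA)
  fm$is_deletion <- c(1, 1, 1, 0, 0)
  fm$any_exon_constitutive <- c(0, 0, 1, NA, NA)
  med <- feature_medians(fm)
  expect_equal(unname(med["tad_strength_max"]), 2.5)
  expect_equal(unname(med["is_deletion"]), 1)
  expect_equal(unname(med["any_exon_constitutive"]), 0)  # ties/minority -> 0
  imp <- impute_features(fm, med)
  expect_false(any(is.na(imp[, sv_feature_names])))
})

test_that("feature extraction is independent of annotation row order", {
  fx <- small_fixture()
  svs <- random_exonic_svs(25, fx$bundle, max_size = 5e4, seed = 31)
  df <- read.delim(file.path(fx$dir, "genes.tsv"),
                   colClasses = c(chrom = "character"))
  perm <- with_seed(8, df[sample(nrow(df)), ])
  b2 <- annotation_bundle(
    build_gene_models(perm),
    scores = load_gene_scores(file.path(fx$dir, "gene_scores.tsv")),
    conservation = fx$bundle$conservation,
    expression = fx$bundle$expression,
    inclusion = fx$bundle$inclusion,
    tad = fx$bundle$tad)
  f1 <- sv_features(svs, fx$bundle, on_no_exon = "keep")
  f2 <- sv_features(svs, b2, on_no_exon = "keep")
  expect_equal(f1, f2)
})

test_that("deleting an entire gene maximizes the CDS and exon features", {
  fx <- small_fixture()
  et <- fx$bundle$models$exon_table
  g <- et$gene_id[1]
  rows <- et[et$gene_id == g, ]
  sv <- sv_records(rows$chrom[1], min(rows$start) - 10, max(rows$end) + 10,
                   "DEL")
  f <- assemble_features(sv, fx$bundle)
  expect_equal(unname(f["cds_frac_overlapped"]), 1)
  expect_equal(unname(f["cds_frac_from_start"]), 0)
  expect_equal(unname(f["cds_frac_from_stop"]), 0)
  expect_equal(unname(f["max_exons_overlapped"]), rows$n_exons[1])
})

test_that("correlation matrix is Spearman, clustered, and flip-aware", {
  with_seed(14, {
    n <- 500
    fm <- data.frame(id = sprintf("s%03d", 1:n))
    for (nm in sv_feature_names) fm[[nm]] <- rnorm(n)
    # plant a rank-identical pair (LOEUF runs opposite to pLI)
    fm$pli_high_impact_max <- runif(n)
    fm$loeuf_high_impact_min <- -fm$pli_high_impact_max + 5
    rho <- feature_correlation_matrix(fm)
    expect_equal(unname(diag(rho)), rep(1, 17))
    # after the sign flip the pair correlates +1
    expect_equal(rho["pli_high_impact_max", "loeuf_high_impact_min"], 1)
    # independent features stay near zero at n = 500
    sub <- rho[c("phylop_top400", "tad_strength_max", "exon_expression_top400"),
               c("min_exon_order", "is_deletion", "exon_inclusion_top400")]
    expect_true(all(abs(sub) < 0.15))
    expect_setequal(attr(rho, "order"), sv_feature_names)
  })
  # constant feature: correlations undefined -> 0 with a warning
  fm2 <- data.frame(id = letters[1:5])
  for (nm in sv_feature_names) fm2[[nm]] <- rnorm(5)
  fm2$is_deletion <- 1
  expect_warning(rho2 <- feature_correlation_matrix(fm2), "constant")
  expect_equal(sum(abs(rho2["is_deletion", ]) > 0), 1)  # only the diagonal
  expect_error(feature_correlation_matrix(fm2[1:2, ]), "at least 3")
})
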