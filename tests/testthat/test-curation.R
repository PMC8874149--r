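test_that("reciprocal overlap is min(shared/size_a, shared/size_b)", {
  a <- sv_records("1", 0, 100, "DEL")
  expect_equal(reciprocal_overlap(a, sv_records("1", 10, 110, "DEL")), 0.9)
  expect_equal(reciprocal_overlap(a, a), 1)
  expect_equal(reciprocal_overlap(a, sv_records("1", 0, 1000, "DEL")), 0.1)
  expect_equal(reciprocal_overlap(a, sv_records("2", 0, 100, "DEL")), 0)
})

test_that("greedy dedup keeps the smallest of nested duplicates", {
  svs <- sv_records("1", c(0, 5, 2), c(1000, 960, 990), "DEL",
                    id = c("big", "small", "mid"))
  kept <- dedup_by_overlap(svs, 0.9, keep = "smallest")
  expect_equal(kept$id, "small")
  # disjoint records are all retained
  far <- sv_records("1", c(0, 5000), c(100, 5100), "DEL", id = c("a", "b"))
  expect_equal(nrow(dedup_by_overlap(far, 0.9)), 2)
  # keep = "first" retains the first appearance in input order
  expect_equal(dedup_by_overlap(svs, 0.9, keep = "first")$id, "big")
  expect_error(dedup_by_overlap(
    sv_records("1", c(0, 0), c(100, 100), c("DEL", "DUP")), 0.9),
    "single svtype")
})

test_that("dedup matches the O(n^2) greedy oracle on random instances", {
  for (seed in 1:3) {
    svs <- with_seed(seed, {
      n <- 200
      start <- floor(runif(n, 0, 5e4))
      sv_records(sample(c("1", "2"), n, TRUE), start,
                 start + floor(exp(runif(n, log(50), log(5e3)))), "DEL",
                 id = sprintf("d%03d", 1:n))
    })
    for (keep in c("first", "smallest")) {
      got <- dedup_by_overlap(svs, 0.9, keep = keep)
      exp <- oracle_dedup(svs, 0.9, keep = keep)
      expect_identical(got$id, exp$id)
    }
  }
})

test_that("catalog MAF is events over twice the sample size", {
  expect_equal(dgv_maf(10, 100), 0.05)
  expect_equal(dgv_maf(0, 100), 0)
  expect_warning(m <- dgv_maf(300, 100), "capping")
  expect_equal(m, 1)
  expect_error(dgv_maf(1, 0), "samplesize")
})

test_that("rarity classes split on MAF and homozygote count", {
  svs <- sv_records("1", c(0, 0, 0), c(100, 100, 100), "DEL",
                    maf = c(0.02, 0.005, 0.005), n_homalt = c(5, 1, 0))
  expect_equal(classify_rarity(svs),
               c("common", "rare_benign", "rare_unlabeled"))
  svs$maf[1] <- NA
  expect_error(classify_rarity(svs), "missing maf")
})

test_that("common-SV removal uses exact matches and reciprocal overlap", {
  svs <- sv_records("1", c(100, 5000, 9000), c(200, 6000, 9100), "DEL",
                    id = c("exact", "ro", "kept"))
  dgv <- sv_records("1", 100, 200, "DEL")
  gnomad <- sv_records("1", 5000, 5960, "DEL")  # RO 0.96
  out <- remove_common(svs, exact_sources = list(dgv),
                       ro_sources = list(gnomad))
  expect_equal(out$id, "kept")
  # RO 0.5 is not close enough to remove
  weak <- sv_records("1", 9000, 9200, "DEL")
  expect_equal(nrow(remove_common(svs[3, ], ro_sources = list(weak))), 1)
  # exact match requires the same svtype
  dup <- sv_records("1", 100, 200, "DUP")
  expect_equal(nrow(remove_common(svs[1, ], exact_sources = list(dup))), 1)
})

test_that("size matching uses the multiplicative window and consumes benign SVs", {
  cfg <- match_config(alpha = 1.06101, slack_bp = 20)
  p <- sv_records("1", 0, 1000, "DEL", id = "p1")
  tier1 <- sv_records("2", c(0, 0), c(940, 5000), "DEL", id = c("b940", "b5000"))
  m <- size_match(p, list(tier1), cfg)
  expect_equal(m$benign_id, "b940")  # window ~ [922.5, 1081.0]

  # out-of-window benign SV in tier 1 -> falls through to tier 2
  p2 <- sv_records("1", c(0, 0), c(1000, 1000), "DEL", id = c("p1", "p2"))
  tier1b <- sv_records("2", 0, 1005, "DEL", id = "only")
  tier2 <- sv_records("3", 0, 990, "DEL", id = "backup")
  m2 <- size_match(p2, list(t1 = tier1b, t2 = tier2), cfg)
  expect_equal(m2$benign_id, c("only", "backup"))
  expect_equal(m2$tier, c("t1", "t2"))

  # no reuse: a single benign SV matches at most one pathogenic SV
  m3 <- size_match(p2, list(t1 = tier1b), cfg)
  expect_equal(nrow(m3), 1)
  expect_equal(attr(m3, "dropped"), "p2")

  # type mismatch never matches
  dup_tier <- sv_records("2", 0, 1000, "DUP", id = "dup")
  m4 <- size_match(p, list(dup_tier), cfg)
  expect_equal(nrow(m4), 0)
  expect_error(size_match(p, list(), cfg), "empty tier")
})

test_that("within a tier the size-closest benign SV is chosen, ties smaller", {
  cfg <- match_config()
  p <- sv_records("1", 0, 1000, "DEL")
  tier <- sv_records("2", c(0, 0, 0), c(990, 1009, 1011), "DEL",
                     id = c("b990", "b1009", "b1011"))
  expect_equal(size_match(p, list(tier), cfg)$benign_id, "b1009")
  tie <- sv_records("2", c(0, 0), c(990, 1010), "DEL", id = c("lo", "hi"))
  expect_equal(size_match(p, list(tie), cfg)$benign_id, "lo")
})

test_that("matched pairs share type, stay in-window, and match distributions", {
  fx <- small_fixture()
  spec <- small_spec()
  spec$n_pathogenic <- 500
  spec$n_benign_tiers <- c(t1 = 300, t2 = 300, t3 = 300)
  svs <- generate_labeled_svs(spec, fx$bundle)
  cfg <- match_config()
  m <- size_match(svs$pathogenic, svs$benign_tiers, cfg)
  pairs <- attr(m, "pairs")
  expect_gt(nrow(m), 400)
  expect_identical(pairs$pathogenic$svtype, pairs$benign$svtype)
  N <- sv_size(pairs$pathogenic); B <- sv_size(pairs$benign)
  expect_true(all(B >= N / cfg$alpha - cfg$slack_bp &
                    B <= N * cfg$alpha + cfg$slack_bp))
  expect_false(any(duplicated(paste(m$tier, m$benign_id))))
  ks <- suppressWarnings(ks.test(N, B)$statistic)
  expect_lt(ks, 0.1)
})

test_that("feature-identical records collapse within and vanish across labels", {
  fm <- data.frame(id = sprintf("v%d", 1:7))
  for (nm in sv_feature_names) fm[[nm]] <- c(1, 1, 1, 2, 3, 3, 4)
  labels <- c("benign", "benign", "benign", "benign",
              "pathogenic", "benign", "pathogenic")
  out <- dedup_feature_identical(fm, labels)
  # group 1 (benign x3) -> one representative; group 3 in both labels -> gone
  expect_equal(out$fm$id, c("v1", "v4", "v7"))
  expect_equal(out$labels, c("benign", "benign", "pathogenic"))
  # all-distinct input is untouched
  fm2 <- fm; for (nm in sv_feature_names) fm2[[nm]] <- 1:7
  out2 <- dedup_feature_identical(fm2, labels)
  expect_equal(out2$fm$id, fm2$id)
})

test_that("chromosome splits and LOCO folds never leak chromosomes", {
  svs <- sv_records(rep(c("chr1", "chr2", "chr3", "chr5", "chr7"), each = 4),
                    1:20 * 1000, 1:20 * 1000 + 100, "DEL")
  sp <- chromosome_split(svs, held_out = c("1", "3", "5", "7"))
  expect_false(any(normalize_chrom(sp$train$chrom) %in% c("1", "3", "5", "7")))
  expect_true(all(normalize_chrom(sp$test$chrom) %in% c("1", "3", "5", "7")))
  expect_error(chromosome_split(svs, c("1", "2", "3", "5", "7")),
               "empty training")

  folds <- loco_folds(svs)
  expect_length(folds, 5)
  for (ch in names(folds)) {
    expect_false(ch %in% normalize_chrom(svs$chrom[folds[[ch]]$train]))
    expect_true(all(normalize_chrom(svs$chrom[folds[[ch]]$test]) == ch))
  }
  expect_error(loco_folds(svs[svs$chrom == "chr1", ]), ">= 2 chromosomes")
})

test_that("one-SV-per-gene subsampling is disjoint and seed-deterministic", {
  fx <- small_fixture()
  svs <- random_exonic_svs(60, fx$bundle, max_size = 2e4, seed = 17)
  out <- one_sv_per_gene_subsample(svs, fx$bundle, seed = 5)
  genes <- unlist(lapply(exon_overlap(out, fx$bundle), names))
  expect_false(any(duplicated(genes)))
  out2 <- one_sv_per_gene_subsample(svs, fx$bundle, seed = 5)
  expect_identical(out, out2)
  # two SVs in the same gene: exactly one survives
  et <- fx$bundle$models$exon_table
  r <- et[1, ]
  two <- sv_records(r$chrom, c(r$start, r$start + 1), c(r$end, r$end + 1),
                    "DEL", id = c("s1", "s2"))
  expect_equal(nrow(one_sv_per_gene_subsample(two, fx$bundle, seed = 1)), 1)
})
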