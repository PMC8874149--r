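# Shared test fixtures. Bundles are generated in code at test time and
# memoized per session.

.fixture_cache <- new.env(parent = emptyenv())

# Compact generator settings used by most tests: small genome, SVs capped
# well under the chromosome length.
small_spec <- function(seed = 11, ...) {
  fixture_spec(
    n_genes = 60, n_chrom = 4, chrom_length = 2e6,
    intergenic_len = c(5e3, 2e4),
    n_pathogenic = 40,
    n_benign_tiers = c(tier1 = 20, tier2 = 20, tier3 = 20),
    size_range = c(50, 2e4),
    seed = seed, ...)
}

cached_bundle <- function(key, spec) {
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  dir <- file.path(tempdir(), paste0("svforest_", key))
  generate_annotation_bundle(spec, dir)
  obj <- list(dir = dir, bundle = load_annotation_bundle(dir), spec = spec)
  .fixture_cache[[key]] <- obj
  obj
}

small_fixture <- function() cached_bundle("small", small_spec())

# Flat gene-model rows for hand-built genes.
gene_rows <- function(gene_id, transcript_id, appris_rank, strand, chrom,
                      exons, cds = NULL) {
  rows <- data.frame(
    gene_id = gene_id, symbol = gene_id, transcript_id = transcript_id,
    appris_rank = appris_rank, strand = strand, feature = "exon",
    chrom = chrom, start = exons$start, end = exons$end)
  if (!is.null(cds) && nrow(cds))
    rows <- rbind(rows, data.frame(
      gene_id = gene_id, symbol = gene_id, transcript_id = transcript_id,
      appris_rank = appris_rank, strand = strand, feature = "cds",
      chrom = chrom, start = cds$start, end = cds$end))
  rows
}

iv <- function(start, end) data.frame(start = start, end = end)

# Random SVs guaranteed to overlap a principal exon of the bundle, with
# spans bounded by max_size.
random_exonic_svs <- function(n, bundle, max_size = 1e5, seed = 1) {
  et <- bundle$models$exon_table
  with_seed(seed, {
    r <- sample.int(nrow(et), n, replace = TRUE)
    anchor <- floor(runif(n, et$start[r], et$end[r]))
    size <- pmax(50, floor(exp(runif(n, log(50), log(max_size)))))
    start <- pmax(0, anchor - floor(runif(n) * (size - 1)))
    sv_records(chrom = et$chrom[r], start = start, end = start + size,
               svtype = sample(c("DEL", "DUP"), n, replace = TRUE),
               id = sprintf("rx%04d", seq_len(n)))
  })
}

with_seed <- svforest:::with_seed
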