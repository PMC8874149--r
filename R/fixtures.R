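# fixtures: seed-deterministic synthetic annotation bundles and labeled SV
# sets with planted signal, so every stage of the pipeline runs end-to-end
# without external genomic resources. All emitted data are synthetic.

#' Specification for a synthetic annotation bundle and SV set
#'
#' Defaults describe the study conditions the test-suite fixtures use: a
#' compact multi-chromosome genome whose genes split into a constrained
#' (disease-relevant) and an unconstrained class, phyloP-like conservation
#' that is elevated on constrained genes' exons, log-uniform SV sizes over
#' the 50 bp - 3 Mb scoring range, and pathogenic SVs planted preferentially
#' in constrained genes and over start codons.
#'
#' @param n_genes Number of genes.
#' @param n_chrom,chrom_length Chromosome count and common length (bp).
#' @param exons_per_gene,exon_len,intron_len,intergenic_len Integer ranges
#'   (min, max) in bp for the gene layout.
#' @param p_alt_transcripts Probability a gene carries an alternate
#'   transcript skipping one internal exon.
#' @param p_constrained Fraction of genes that are constrained.
#' @param p_score_missing Probability a gene is absent from the score table.
#' @param cons_mean,cons_sd,cons_block,cons_boost Conservation model: exonic
#'   baseline mean/sd, block-length range of the piecewise-constant signal,
#'   and the additive boost on constrained genes' exons.
#' @param n_tissues,tpm_meanlog,tpm_sdlog Expression model: tissues and the
#'   per-transcript log-normal TPM distribution.
#' @param n_tad,tad_width TAD-boundary count and width.
#' @param n_pathogenic Number of pathogenic SVs.
#' @param n_benign_tiers Named integer vector: benign SVs per tier, in tier
#'   order (most to least trusted).
#' @param size_range SV size range (log-uniform), bp.
#' @param p_dup Probability an SV is a duplication.
#' @param p_hit_constrained Probability a pathogenic SV targets a
#'   constrained gene.
#' @param p_benign_hit_constrained Probability a benign SV is anchored in a
#'   constrained gene: purifying selection depletes standing benign variation
#'   in constrained genes, so this is well below the constrained gene
#'   fraction.
#' @param p_cover_start Probability a pathogenic SV is anchored on its
#'   target gene's start codon (otherwise on a random exon).
#' @param p_ablate Probability a pathogenic SV large enough to span its
#'   target gene is placed to ablate it entirely (whole-gene loss/gain, a
#'   hallmark of clinically reported SVs).
#' @param seed Seed; the same spec yields byte-identical bundles.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 2000,
                         n_chrom = 8, chrom_length = 3e7,
                         exons_per_gene = c(3, 12),
                         exon_len = c(60, 300),
                         intron_len = c(300, 3000),
                         intergenic_len = c(3e4, 1e5),
                         p_alt_transcripts = 0.6,
                         p_constrained = 0.25,
                         p_score_missing = 0.05,
                         cons_mean = 0.5, cons_sd = 1, cons_block = c(3, 20),
                         cons_boost = 2,
                         n_tissues = 5, tpm_meanlog = 1, tpm_sdlog = 1,
                         n_tad = 40, tad_width = 1e4,
                         n_pathogenic = 500,
                         n_benign_tiers = c(clinvar_likely_benign = 150,
                                            clinvar_benign = 150,
                                            apes = 100,
                                            gnomad_rare_benign = 100,
                                            gnomad_rare_unlabeled = 250),
                         size_range = c(50, 3e6),
                         p_dup = 0.35,
                         p_hit_constrained = 0.9,
                         p_benign_hit_constrained = 0.05,
                         p_cover_start = 0.5,
                         p_ablate = 0.4,
                         seed = 1) {
  spec <- as.list(environment())
  stopifnot(n_genes > 0, n_chrom > 0, chrom_length > 0,
            all(n_benign_tiers > 0), n_pathogenic > 0,
            p_constrained >= 0, p_constrained <= 1,
            p_hit_constrained >= 0, p_hit_constrained <= 1,
            p_cover_start >= 0, p_cover_start <= 1,
            size_range[1] >= 1, size_range[2] >= size_range[1])
  structure(spec, class = "fixture_spec")
}

.runif_int <- function(n, range) {
  floor(stats::runif(n, range[1], range[2] + 1))
}

# Lay out genes, transcripts, scores, tracks; pure function of the RNG state.
.gen_annotation <- function(spec) {
  chroms <- paste0("chr", seq_len(spec$n_chrom))
  ge_acc <- vector("list", spec$n_genes)
  sc_acc <- vector("list", spec$n_genes)
  tp_acc <- vector("list", spec$n_genes)
  cn_acc <- vector("list", spec$n_genes)
  truth <- logical(spec$n_genes)
  cursor <- stats::setNames(rep(10e3, spec$n_chrom), chroms)
  for (gi in seq_len(spec$n_genes)) {
    gid <- sprintf("G%04d", gi)
    ch <- chroms[(gi - 1) %% spec$n_chrom + 1]
    strand <- sample(c("+", "-"), 1)
    n_ex <- .runif_int(1, spec$exons_per_gene)
    ex_len <- .runif_int(n_ex, spec$exon_len)
    in_len <- .runif_int(max(n_ex - 1, 1), spec$intron_len)
    start <- cursor[ch] + .runif_int(1, spec$intergenic_len)
    ex_start <- start + c(0, cumsum(ex_len[-n_ex] + in_len[seq_len(n_ex - 1)]))
    ex_end <- ex_start + ex_len
    if (ex_end[n_ex] >= spec$chrom_length)
      stopf("fixture geometry infeasible: gene %s exceeds chromosome %s", gid, ch)
    cursor[ch] <- ex_end[n_ex]
    # CDS from inside the first exon to inside the last (transcript-agnostic
    # genomic span; per-transcript CDS is this span clipped to its exons)
    cds_lo <- ex_start[1] + floor(ex_len[1] / 2)
    cds_hi <- ex_end[n_ex] - floor(ex_len[n_ex] / 2)
    constrained <- stats::runif(1) < spec$p_constrained
    truth[gi] <- constrained

    tx_sets <- list(T1 = seq_len(n_ex))
    if (n_ex >= 3 && stats::runif(1) < spec$p_alt_transcripts) {
      skip <- sample(2:(n_ex - 1), 1)
      tx_sets$T2 <- setdiff(seq_len(n_ex), skip)
    }
    g_rows <- vector("list", length(tx_sets))
    t_rows <- vector("list", length(tx_sets))
    for (ti in seq_along(tx_sets)) {
      tid <- sprintf("%s.%s", gid, names(tx_sets)[ti])
      idx <- tx_sets[[ti]]
      cs <- pmax(ex_start[idx], cds_lo); ce <- pmin(ex_end[idx], cds_hi)
      sel <- ce > cs
      n_rows <- length(idx) + sum(sel)
      g_rows[[ti]] <- list(
        gene_id = rep(gid, n_rows), symbol = rep(paste0("SYM", gi), n_rows),
        transcript_id = rep(tid, n_rows), appris_rank = rep(ti, n_rows),
        strand = rep(strand, n_rows),
        feature = rep(c("exon", "cds"), c(length(idx), sum(sel))),
        chrom = rep(ch, n_rows),
        start = c(ex_start[idx], cs[sel]), end = c(ex_end[idx], ce[sel]))
      t_rows[[ti]] <- list(
        transcript_id = rep(tid, spec$n_tissues),
        tissue = paste0("tissue", seq_len(spec$n_tissues)),
        tpm = stats::rlnorm(spec$n_tissues, spec$tpm_meanlog, spec$tpm_sdlog))
    }
    ge_acc[[gi]] <- g_rows
    tp_acc[[gi]] <- t_rows
    if (stats::runif(1) >= spec$p_score_missing) {
      sc_acc[[gi]] <- list(gene_id = gid,
        pli = if (constrained) stats::runif(1, 0.9, 1)
              else stats::runif(1, 0, 0.2),
        loeuf = if (constrained) stats::runif(1, 0.05, 0.35)
                else stats::runif(1, 0.7, 1.6))
    }
    # piecewise-constant conservation over this gene's exons
    boost <- if (constrained) spec$cons_boost else 0
    c_rows <- vector("list", n_ex)
    for (e in seq_len(n_ex)) {
      len <- ex_len[e]
      w <- .runif_int(ceiling(len / spec$cons_block[1]) + 1L, spec$cons_block)
      cw <- pmin(cumsum(w), len)
      k <- which(cw >= len)[1]
      c_rows[[e]] <- list(chrom = rep(ch, k),
                          start = ex_start[e] + c(0, cw[seq_len(k - 1)]),
                          end = ex_start[e] + cw[seq_len(k)],
                          value = round(stats::rnorm(k, spec$cons_mean + boost,
                                                     spec$cons_sd), 3))
    }
    cn_acc[[gi]] <- c_rows
  }
  tad <- data.frame(
    chrom = sample(chroms, spec$n_tad, replace = TRUE),
    start = floor(stats::runif(spec$n_tad, 0, spec$chrom_length - spec$tad_width)))
  tad$end <- tad$start + spec$tad_width
  tad$strength <- round(stats::runif(spec$n_tad), 3)
  tad <- tad[order(tad$chrom, tad$start), ]
  flat <- function(acc, fields, nested = TRUE) {
    if (nested) acc <- unlist(acc, recursive = FALSE)
    acc <- acc[!vapply(acc, is.null, logical(1))]
    out <- lapply(fields, function(f)
      unlist(lapply(acc, `[[`, f), use.names = FALSE))
    names(out) <- fields
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  list(genes = flat(ge_acc, c("gene_id", "symbol", "transcript_id",
                              "appris_rank", "strand", "feature", "chrom",
                              "start", "end")),
       scores = flat(sc_acc, c("gene_id", "pli", "loeuf"), nested = FALSE),
       tpm = flat(tp_acc, c("transcript_id", "tissue", "tpm")),
       cons = flat(cn_acc, c("chrom", "start", "end", "value")),
       tad = tad, constrained = stats::setNames(truth, sprintf("G%04d", seq_len(spec$n_genes))))
}

#' Generate a synthetic annotation bundle on disk
#'
#' Writes `genes.tsv`, `gene_scores.tsv`, `conservation.bedgraph`,
#' `transcript_tpm.tsv` and `tad_boundaries.bed` (the layout read by
#' [load_annotation_bundle()]) plus `constrained_genes_synthetic.tsv`, the
#' generator's ground truth about which genes are constrained. The bundle is
#' internally consistent (CDS within exons, tracks covering exon space) and
#' byte-identical for identical specs.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
generate_annotation_bundle <- function(spec, dir) {
  ann <- with_seed(spec$seed, .gen_annotation(spec))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  w(ann$genes, "genes.tsv")
  w(ann$scores, "gene_scores.tsv")
  w(ann$tpm, "transcript_tpm.tsv")
  utils::write.table(ann$cons, file.path(dir, "conservation.bedgraph"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(ann$tad, file.path(dir, "tad_boundaries.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  w(data.frame(gene_id = names(ann$constrained),
               constrained = unname(ann$constrained)),
    "constrained_genes_synthetic.tsv")
  invisible(dir)
}

# Sample one anchored SV; anchor must end up covered, interval inside the
# chromosome, so every emitted SV overlaps >= 1 exonic base.
.place_sv <- function(anchor, size, chrom_length) {
  size <- min(size, chrom_length)
  lo <- max(0, anchor - size + 1)
  hi <- min(anchor, chrom_length - size)
  s <- floor(stats::runif(1, lo, hi + 1))
  c(s, s + size)
}

#' Generate labeled pathogenic and tiered benign SV sets
#'
#' Pathogenic SVs target constrained genes with probability
#' `p_hit_constrained` (anchored on the start codon with probability
#' `p_cover_start`, otherwise on a random exonic base of the target gene);
#' benign SVs are anchored uniformly over exonic space, except that they
#' fall in constrained genes only with probability
#' `p_benign_hit_constrained`, emulating the depletion of standing benign
#' structural variation in constrained genes under purifying selection.
#' Sizes are log-uniform over `size_range` for both classes, so class
#' separation comes from the planted annotation signal, not size. Every SV
#' overlaps at least one exon.
#'
#' Constrained targets are identified from the bundle's score table
#' (pLI >= 0.5 or LOEUF <= 0.5).
#'
#' @param spec A [fixture_spec()].
#' @param bundle The loaded `annotation_bundle` generated from `spec`.
#' @return List `pathogenic` (an `sv_tbl`) and `benign_tiers` (named list of
#'   `sv_tbl`s in tier order).
#' @export
generate_labeled_svs <- function(spec, bundle) {
  with_seed(spec$seed + 1L, .gen_labeled_svs(spec, bundle))
}

.gen_labeled_svs <- function(spec, bundle) {
  et <- bundle$models$exon_table
  genes <- bundle$models$genes
  gene_ids <- names(genes)
  constrained <- gene_ids[
    (!is.na(bundle$pli[gene_ids]) & bundle$pli[gene_ids] >= 0.5) |
      (!is.na(bundle$loeuf[gene_ids]) & bundle$loeuf[gene_ids] <= 0.5)]
  if (!length(constrained)) constrained <- gene_ids
  exon_w <- et$end - et$start
  rows_con <- which(et$gene_id %in% constrained)
  rows_unc <- setdiff(seq_len(nrow(et)), rows_con)
  if (!length(rows_unc)) rows_unc <- seq_len(nrow(et))
  rsize <- function(n) floor(exp(stats::runif(
    n, log(spec$size_range[1]), log(spec$size_range[2]))))

  rows_by_gene <- split(seq_len(nrow(et)), et$gene_id)

  # One sampler for both classes: anchor exon drawn width-weighted within the
  # chosen constraint class, so zeroed effect sizes make the two classes
  # identically distributed by construction.
  sample_one <- function(p_class_constrained, p_cover_start, p_ablate) {
    rows <- if (stats::runif(1) < p_class_constrained) rows_con else rows_unc
    if (!length(rows)) rows <- rows_unc
    r <- rows[sample.int(length(rows), 1, prob = exon_w[rows])]
    gid <- et$gene_id[r]
    g <- genes[[gid]]
    ch <- et$chrom[r]
    svtype <- if (stats::runif(1) < spec$p_dup) "DUP" else "DEL"
    size <- rsize(1)
    grows <- rows_by_gene[[gid]]
    span <- c(min(et$start[grows]), max(et$end[grows]))
    if (size >= span[2] - span[1] && stats::runif(1) < p_ablate) {
      # whole-gene ablation: place the SV to contain the gene span
      lo <- max(0, span[2] - size)
      hi <- min(span[1], spec$chrom_length - size)
      st <- floor(stats::runif(1, lo, hi + 1))
      return(list(chrom = ch, start = st, end = st + size, svtype = svtype))
    }
    anchor <- if (g$cds_map$L > 0 && stats::runif(1) < p_cover_start)
      g$cds_map$start_codon
    else floor(stats::runif(1, et$start[r], et$end[r]))
    se <- .place_sv(anchor, size, spec$chrom_length)
    list(chrom = ch, start = se[1], end = se[2], svtype = svtype)
  }

  mk_set <- function(n, pathogenic, source, prefix) {
    recs <- if (pathogenic)
      lapply(seq_len(n), function(i) sample_one(
        spec$p_hit_constrained, spec$p_cover_start, spec$p_ablate))
    else
      lapply(seq_len(n), function(i) sample_one(
        spec$p_benign_hit_constrained, 0, 0))
    sv_records(
      chrom = vapply(recs, `[[`, character(1), "chrom"),
      start = vapply(recs, `[[`, numeric(1), "start"),
      end = vapply(recs, `[[`, numeric(1), "end"),
      svtype = vapply(recs, `[[`, character(1), "svtype"),
      id = sprintf("%s%05d", prefix, seq_len(n)),
      maf = stats::runif(n, 0, 0.009),
      n_homalt = if (pathogenic) 0 else stats::rpois(n, 0.5),
      label = if (pathogenic) "pathogenic" else "benign",
      source = source)
  }

  pathogenic <- mk_set(spec$n_pathogenic, TRUE, "clinvar_pathogenic", "P")
  tiers <- lapply(seq_along(spec$n_benign_tiers), function(ti)
    mk_set(spec$n_benign_tiers[ti], FALSE, names(spec$n_benign_tiers)[ti],
           sprintf("B%d_", ti)))
  names(tiers) <- names(spec$n_benign_tiers)
  list(pathogenic = pathogenic, benign_tiers = tiers)
}

#' A hand-constructed feature-extraction golden case
#'
#' A single five-exon gene on the + strand with an alternate transcript
#' skipping exon 3, one-interval-per-exon conservation, two transcripts with
#' TPM 6 and 2, one TAD boundary, and a deletion covering exons 2-3. Every
#' feature has a closed-form expected value, documented below.
#'
#' Geometry (0-based half-open): exons `[1000,1100) [1300,1390) [1600,1720)
#' [2000,2150) [2400,2500)`; CDS from 1050 to 2450 clipped to exons, total
#' CDS length L = 460; deletion `[1290, 1730)` removes exons 2 (90 bp,
#' in-frame, constitutive) and 3 (120 bp, in-frame, skipped by the alternate
#' transcript). Expected values: CDS overlapped 210/460; CDS 5' of the first
#' disrupted coding base 50/460; 3' of the last 200/460; conservation mean
#' of units {2, 3} = 2.5; expression mean of {8, 6} = 7 (TPM 6+2 on exon 2,
#' 6 on exon 3); inclusion mean of {1, 0.75}; TAD strength 0.8; pLI 0.95,
#' LOEUF 0.2, high-impact variants missing (start/stop untouched, CDS
#' fraction < 0.5); exon orders 1-2 so minimum order 1; 5 exons in gene;
#' 2 exons overlapped.
#'
#' @return List `bundle` (an `annotation_bundle`), `sv` (one-row `sv_tbl`),
#'   and `expected` (named feature vector with `NA` for missing values).
#' @export
worked_feature_case <- function() {
  ex <- data.frame(start = c(1000, 1300, 1600, 2000, 2400),
                   end = c(1100, 1390, 1720, 2150, 2500))
  cds_lo <- 1050; cds_hi <- 2450
  mk_tx <- function(tid, rank, idx) {
    cs <- pmax(ex$start[idx], cds_lo); ce <- pmin(ex$end[idx], cds_hi)
    rbind(
      data.frame(gene_id = "G1", symbol = "SYM1", transcript_id = tid,
                 appris_rank = rank, strand = "+", feature = "exon",
                 chrom = "chr1", start = ex$start[idx], end = ex$end[idx]),
      data.frame(gene_id = "G1", symbol = "SYM1", transcript_id = tid,
                 appris_rank = rank, strand = "+", feature = "cds",
                 chrom = "chr1", start = cs, end = ce))
  }
  models <- build_gene_models(rbind(mk_tx("G1.T1", 1, 1:5),
                                    mk_tx("G1.T2", 2, c(1, 2, 4, 5))))
  cons <- pb_track(data.frame(chrom = "chr1", start = ex$start, end = ex$end,
                              value = c(1, 2, 3, 1.5, 1.2)))
  tpm <- data.frame(transcript_id = c("G1.T1", "G1.T2"),
                    tissue = "tissue1", tpm = c(6, 2))
  tracks <- build_expression_tracks(tpm, models)
  bundle <- annotation_bundle(
    models = models,
    scores = data.frame(gene_id = "G1", pli = 0.95, loeuf = 0.2),
    conservation = cons,
    expression = tracks$expression,
    inclusion = tracks$inclusion,
    tad = data.frame(chrom = "chr1", start = 1500, end = 1550, strength = 0.8))
  sv <- sv_records("chr1", 1290, 1730, "DEL", id = "golden_del")
  expected <- c(
    cds_frac_from_start = 50 / 460,
    cds_frac_from_stop = 200 / 460,
    cds_frac_overlapped = 210 / 460,
    phylop_top400 = 2.5,
    exon_expression_top400 = 7,
    exon_inclusion_top400 = 0.875,
    tad_strength_max = 0.8,
    loeuf_min = 0.2,
    loeuf_high_impact_min = NA_real_,
    pli_max = 0.95,
    pli_high_impact_max = NA_real_,
    all_exons_inframe_skippable = 1,
    any_exon_constitutive = 1,
    min_exon_order = 1,
    min_exons_in_gene = 5,
    max_exons_overlapped = 2,
    is_deletion = 1
  )
  list(bundle = bundle, sv = sv, expected = expected)
}
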