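# annotation_store: gene/transcript/exon models with APPRIS principal
# transcript selection, run-length per-base tracks (conservation,
# expression, exon inclusion), gene constraint scores and TAD boundaries,
# assembled into one queryable bundle. All coordinates 0-based half-open.

# ---- gene models -----------------------------------------------------------

#' Load gene models from a flat TSV or an Ensembl-style GTF
#'
#' The flat dialect is a headered TSV with columns `gene_id`, `symbol`,
#' `transcript_id`, `appris_rank` (small integer, lower is more principal),
#' `strand` (+/-), `feature` (`exon` or `cds`), `chrom`, `start`, `end`
#' (0-based half-open). GTF input (`.gtf`/`.gff` extension, read with
#' rtracklayer) uses `exon`/`CDS` rows and an `appris` attribute or
#' `appris_principal_N` / `appris_alternative_N` tags.
#'
#' For each gene one APPRIS principal transcript is selected: best (lowest)
#' APPRIS rank, ties broken by greatest exonic length, remaining ties by
#' transcript id. Genes with no APPRIS-annotated transcript are dropped with
#' a logged count.
#'
#' @param path Path to the gene-model file.
#' @return A `gene_models` object: per-gene transcript structures plus a
#'   precomputed principal-exon table used by interval queries.
#' @export
load_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("gtf", "gff")) .gtf_to_flat(path)
        else utils::read.delim(path, stringsAsFactors = FALSE,
                               colClasses = c(chrom = "character"))
  build_gene_models(df)
}

.gtf_to_flat <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("reading GTF requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  keep <- as.character(gr$type) %in% c("exon", "CDS")
  gr <- gr[keep]
  rank <- rep(NA_real_, length(gr))
  if (!is.null(gr$appris)) rank <- suppressWarnings(as.numeric(gr$appris))
  if (!is.null(gr$tag)) {
    tag <- as.character(gr$tag)
    pr_n <- suppressWarnings(as.numeric(sub(".*_", "", tag)))
    rank[grepl("appris_principal_[0-9]+", tag)] <-
      pr_n[grepl("appris_principal_[0-9]+", tag)]
    rank[grepl("appris_alternative_[0-9]+", tag)] <-
      100 + pr_n[grepl("appris_alternative_[0-9]+", tag)]
  }
  data.frame(
    gene_id = as.character(gr$gene_id),
    symbol = as.character(gr$gene_name %||% gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    appris_rank = rank,
    strand = as.character(GenomicRanges::strand(gr)),
    feature = ifelse(as.character(gr$type) == "CDS", "cds", "exon"),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Build gene models from a flat annotation table
#'
#' Programmatic entry point behind [load_gene_models()]; accepts the flat
#' dialect as an in-memory data frame (used heavily by tests and fixtures).
#'
#' @param df Data frame with the flat gene-model columns.
#' @return A `gene_models` object.
#' @export
build_gene_models <- function(df) {
  need <- c("gene_id", "transcript_id", "appris_rank", "strand", "feature",
            "chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("gene model table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (is.null(df$symbol)) df$symbol <- df$gene_id
  df$feature <- tolower(df$feature)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)

  genes <- list()
  dropped <- 0L
  rows_by_gene <- split(seq_len(nrow(df)), df$gene_id)
  for (gid in sort(names(rows_by_gene))) {
    gdf <- df[rows_by_gene[[gid]], , drop = FALSE]
    txs <- list()
    rows_by_tx <- split(seq_len(nrow(gdf)), gdf$transcript_id)
    for (tid in sort(names(rows_by_tx))) {
      tdf <- gdf[rows_by_tx[[tid]], , drop = FALSE]
      is_ex <- tdf$feature == "exon"
      ex <- data.frame(start = tdf$start[is_ex], end = tdf$end[is_ex])
      cds <- data.frame(start = tdf$start[!is_ex], end = tdf$end[!is_ex])
      ex <- ex[order(ex$start), , drop = FALSE]
      cds <- cds[order(cds$start), , drop = FALSE]
      if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)]))
        stopf("transcript %s has overlapping exons", tid)
      if (nrow(cds)) {
        inside <- vapply(seq_len(nrow(cds)), function(i) {
          any(cds$start[i] >= ex$start & cds$end[i] <= ex$end)
        }, logical(1))
        if (!all(inside))
          stopf("transcript %s: CDS interval outside every exon", tid)
      }
      txs[[tid]] <- list(
        transcript_id = tid,
        appris_rank = tdf$appris_rank[1],
        strand = tdf$strand[1],
        exons = as.matrix(ex),
        cds = as.matrix(cds),
        length = sum(ex$end - ex$start)
      )
    }
    ranks <- vapply(txs, function(t) as.numeric(t$appris_rank), numeric(1))
    if (all(is.na(ranks))) {
      dropped <- dropped + 1L
      next
    }
    cand <- which(ranks == min(ranks, na.rm = TRUE))
    if (length(cand) > 1) {
      lens <- vapply(txs[cand], function(t) t$length, numeric(1))
      cand <- cand[lens == max(lens)]
    }
    principal_id <- names(txs)[cand[1]]  # remaining ties: lexicographic id
    genes[[gid]] <- list(
      gene_id = gid,
      symbol = gdf$symbol[1],
      chrom = gdf$chrom[1],
      strand = gdf$strand[1],
      transcripts = txs,
      principal_id = principal_id,
      principal = txs[[principal_id]],
      cds_map = .cds_map(txs[[principal_id]])
    )
  }
  if (dropped > 0)
    message(sprintf("build_gene_models: dropped %d gene(s) without APPRIS annotation",
                    dropped))
  models <- structure(
    list(genes = genes, exon_table = .principal_exon_table(genes)),
    class = "gene_models", dropped_no_appris = dropped)
  models
}

# Transcript-orientation map of the principal CDS: for each genomic CDS
# interval (ascending), its offset in CDS coordinates (0 = first coding base
# 5' of the transcript), plus start/stop codon first-base genomic positions.
.cds_map <- function(tx) {
  cds <- tx$cds
  if (!nrow(cds)) {
    return(list(L = 0, n = 0L))
  }
  w <- cds[, "end"] - cds[, "start"]
  n <- nrow(cds)
  tx_order <- if (tx$strand == "-") rev(seq_len(n)) else seq_len(n)
  off <- numeric(n)
  off[tx_order] <- cumsum(c(0, w[tx_order][-n]))
  list(
    L = sum(w), n = n,
    start = cds[, "start"], end = cds[, "end"], offset = off,
    strand = tx$strand,
    # genomic position (0-based) of the first and last coding base in
    # transcript orientation
    start_codon = if (tx$strand == "-") cds[n, "end"] - 1 else cds[1, "start"],
    stop_codon = if (tx$strand == "-") cds[1, "start"] else cds[n, "end"] - 1
  )
}

# One row per principal-transcript exon with the per-exon quantities used by
# the exon-structure features.
.principal_exon_table <- function(genes) {
  rows <- lapply(genes, function(g) {
    tx <- g$principal
    ex <- tx$exons
    n <- nrow(ex)
    genomic_idx <- seq_len(n)
    order0 <- if (tx$strand == "-") rev(genomic_idx) - 1L else genomic_idx - 1L
    len <- ex[, "end"] - ex[, "start"]
    internal <- order0 > 0 & order0 < n - 1
    const <- vapply(genomic_idx, function(i) {
      all(vapply(g$transcripts, function(t) {
        any(t$exons[, "start"] == ex[i, "start"] &
              t$exons[, "end"] == ex[i, "end"])
      }, logical(1)))
    }, logical(1))
    data.frame(
      gene_id = g$gene_id, chrom = g$chrom,
      start = ex[, "start"], end = ex[, "end"],
      order0 = order0, len = len,
      internal = internal,
      inframe_ok = internal & len %% 3 == 0,
      constitutive = const,
      n_exons = n,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), order0 = integer(),
                      len = numeric(), internal = logical(),
                      inframe_ok = logical(), constitutive = logical(),
                      n_exons = integer())
  rownames(out) <- NULL
  out
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d gene(s), %d principal exon(s)\n",
              length(x$genes), nrow(x$exon_table)))
  invisible(x)
}

# ---- per-base tracks -------------------------------------------------------

#' Construct a run-length per-base track
#'
#' A track stores, per chromosome, sorted non-overlapping `(interval, value)`
#' pairs in which adjacent equal-valued intervals are merged; querying an
#' uncovered base yields no value.
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open). Rows may be unsorted; duplicated/overlapping rows
#'   with equal values are unioned, overlaps with differing values are an
#'   error.
#' @return A `pb_track` object.
#' @export
pb_track <- function(df = data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), value = numeric())) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  by_chrom <- list()
  for (ch in sort(unique(df$chrom))) {
    d <- df[df$chrom == ch, c("start", "end", "value"), drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    n <- nrow(d)
    if (n > 1) {
      # union overlapping rows (cummax handles containment); only
      # equal-valued overlaps are legal
      cume <- cummax(c(-Inf, d$end[-n]))
      new_run <- c(TRUE, d$start[-1] > cume[-1] |
                     (d$start[-1] == cume[-1] & d$value[-1] != d$value[-n]))
      # rows in one run must share one value (overlap or equal-valued abut)
      grp <- cumsum(new_run)
      chk <- tapply(d$value, grp, function(v) length(unique(v)))
      if (any(chk > 1)) {
        g <- as.integer(names(chk)[chk > 1][1])
        stopf("track: overlapping intervals with different values on %s near %g",
              ch, d$start[which(grp == g)[1]])
      }
      run_last <- c(which(new_run)[-1] - 1L, n)
      d <- data.frame(start = d$start[new_run],
                      end = cummax(d$end)[run_last],
                      value = d$value[new_run])
      # a second equal-adjacent pass catches runs split only by value ties
      d <- merge_equal_runs(d)
    }
    by_chrom[[ch]] <- d
    rownames(by_chrom[[ch]]) <- NULL
  }
  structure(list(by_chrom = by_chrom), class = "pb_track")
}

#' Load a bedGraph-style track
#'
#' @param path Path to a bedGraph file (`chrom start end value`, no header;
#'   `track`/`#` lines are skipped). Rows may be unsorted.
#' @return A `pb_track`.
#' @export
load_track <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  if (!length(lines)) return(pb_track())
  df <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  pb_track(df)
}

#' Write a track as bedGraph
#' @param track A `pb_track`.
#' @param path Output path.
#' @export
write_track <- function(track, path) {
  df <- as.data.frame(track)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @exportS3Method base::as.data.frame
as.data.frame.pb_track <- function(x, ...) {
  rows <- lapply(names(x$by_chrom), function(ch)
    cbind(chrom = ch, x$by_chrom[[ch]]))
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric())
  out
}

#' Query a track over one interval
#'
#' @param track A `pb_track`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open query interval.
#' @return Data frame `start,end,value` of the covered sub-intervals, clipped
#'   to the query; zero rows where the track has no value.
#' @export
track_query <- function(track, chrom, start, end) {
  d <- track$by_chrom[[chrom]]
  if (is.null(d))
    return(data.frame(start = numeric(), end = numeric(), value = numeric()))
  keep <- d$end > start & d$start < end
  d <- d[keep, , drop = FALSE]
  d$start <- pmax(d$start, start)
  d$end <- pmin(d$end, end)
  rownames(d) <- NULL
  d
}

# ---- expression tracks -----------------------------------------------------

#' Build exon-expression and exon-inclusion tracks from transcript TPMs
#'
#' For every nucleotide covered by an exon of any transcript, exon expression
#' is the sum of the TPM of transcripts whose exons cover that nucleotide
#' (TPMs pooled over tissues by `reduction` first). Exon inclusion is that
#' sum divided by the total TPM of all transcripts of the containing gene —
#' the estimated proportion of the gene's transcripts that include the
#' nucleotide. Bases whose containing gene has zero total TPM have no
#' inclusion value; where exons of two genes overlap, expression sums across
#' both and the per-gene maximum inclusion is kept. Adjacent equal-valued
#' bases are merged into run-length intervals.
#'
#' @param tpm Long data frame with columns `transcript_id`, `tissue`, `tpm`.
#' @param models A `gene_models` object containing every transcript in `tpm`.
#' @param reduction How to pool a transcript's TPM across tissues.
#' @return List with `pb_track` elements `expression` and `inclusion`.
#' @export
build_expression_tracks <- function(tpm, models,
                                    reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  stopifnot(all(c("transcript_id", "tpm") %in% names(tpm)))
  red <- if (reduction == "sum") sum else mean
  tx_tpm <- tapply(tpm$tpm, tpm$transcript_id, red)

  all_tx <- unlist(lapply(models$genes, function(g) names(g$transcripts)))
  unknown <- setdiff(names(tx_tpm), all_tx)
  if (length(unknown))
    stopf("TPM table contains transcript(s) absent from the gene models: %s",
          paste(utils::head(unknown, 5), collapse = ", "))

  # one record per (transcript, exon) across all transcripts of all genes
  rows <- list()
  for (g in models$genes) {
    for (t in g$transcripts) {
      v <- tx_tpm[t$transcript_id]
      v <- if (is.na(v)) 0 else as.numeric(v)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = t$exons[, "start"], end = t$exons[, "end"],
        gene_id = g$gene_id, tpm = v, row.names = NULL)
    }
  }
  exdf <- do.call(rbind, rows)
  if (is.null(exdf) || !nrow(exdf))
    return(list(expression = pb_track(), inclusion = pb_track()))
  gene_total <- vapply(models$genes, function(g)
    sum(vapply(g$transcripts, function(t) {
      v <- tx_tpm[t$transcript_id]; if (is.na(v)) 0 else as.numeric(v)
    }, numeric(1))), numeric(1))

  ex_gr <- granges_0h(exdf$chrom, exdf$start, exdf$end)
  pieces <- GenomicRanges::disjoin(ex_gr)
  hit <- GenomicRanges::findOverlaps(pieces, ex_gr)
  qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)

  expr_val <- as.numeric(tapply(exdf$tpm[sh], qh, sum))
  piece_idx <- as.integer(names(tapply(exdf$tpm[sh], qh, sum)))

  # inclusion: per (piece, gene) sum of covering-transcript TPM / gene total,
  # undefined for zero-TPM genes, max across genes
  key <- paste(qh, exdf$gene_id[sh])
  pg_sum <- tapply(exdf$tpm[sh], key, sum)
  pg_piece <- as.integer(sub(" .*", "", names(pg_sum)))
  pg_gene <- sub("^[0-9]+ ", "", names(pg_sum))
  denom <- gene_total[pg_gene]
  ok <- denom > 0
  incl_ratio <- pg_sum[ok] / denom[ok]
  incl_val <- tapply(incl_ratio, pg_piece[ok], max)
  incl_idx <- as.integer(names(incl_val))

  pc <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(pieces)),
    start = GenomicRanges::start(pieces) - 1,
    end = GenomicRanges::end(pieces))

  mk <- function(idx, val) {
    df <- cbind(pc[idx, , drop = FALSE], value = as.numeric(val))
    pb_track(df)
  }
  list(expression = mk(piece_idx, expr_val), inclusion = mk(incl_idx, incl_val))
}

# ---- other resources -------------------------------------------------------

#' Load a gene constraint-score table
#' @param path TSV with header `gene_id`, `pli`, `loeuf`; genes may be absent.
#' @return Data frame with those columns.
#' @export
load_gene_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "pli", "loeuf") %in% names(df)))
  df
}

#' Load TAD boundaries from a BED4 file
#' @param path BED file whose 4th column is the boundary strength.
#' @return Data frame `chrom`, `start`, `end`, `strength`.
#' @export
load_tad_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "strength"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  if (any(!is.finite(df$strength))) stopf("TAD boundary strength must be finite")
  df
}

# ---- bundle ----------------------------------------------------------------

#' Assemble an annotation bundle
#'
#' Combines gene models, constraint scores, per-base tracks and TAD
#' boundaries, and precomputes the interval indexes used by feature
#' extraction.
#'
#' @param models A `gene_models` object.
#' @param scores Data frame `gene_id`, `pli`, `loeuf` (may omit genes).
#' @param conservation,expression,inclusion `pb_track` objects.
#' @param tad Data frame `chrom`, `start`, `end`, `strength`.
#' @return An `annotation_bundle`.
#' @export
annotation_bundle <- function(models, scores = NULL,
                              conservation = pb_track(),
                              expression = pb_track(),
                              inclusion = pb_track(),
                              tad = NULL) {
  if (is.null(scores))
    scores <- data.frame(gene_id = character(), pli = numeric(),
                         loeuf = numeric())
  if (is.null(tad))
    tad <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strength = numeric())
  et <- models$exon_table
  exon_gr <- granges_0h(et$chrom, et$start, et$end)
  union_gr <- GenomicRanges::reduce(exon_gr)
  structure(list(
    models = models,
    pli = stats::setNames(scores$pli, scores$gene_id),
    loeuf = stats::setNames(scores$loeuf, scores$gene_id),
    conservation = conservation, expression = expression,
    inclusion = inclusion, tad = tad,
    exon_gr = exon_gr, union_gr = union_gr,
    track_gr = lapply(
      list(conservation = conservation, expression = expression,
           inclusion = inclusion),
      function(tr) {
        df <- as.data.frame(tr)
        gr <- granges_0h(df$chrom, df$start, df$end)
        S4Vectors::mcols(gr)$value <- df$value
        gr
      }),
    tad_gr = granges_0h(tad$chrom, tad$start, tad$end)
  ), class = "annotation_bundle")
}

#' Load an annotation bundle from a directory
#'
#' Expects `genes.tsv` (or `genes.gtf`), `gene_scores.tsv`,
#' `conservation.bedgraph`, `transcript_tpm.tsv` and `tad_boundaries.bed`,
#' the layout written by [generate_annotation_bundle()]. Expression and
#' inclusion tracks are built from the TPM table at load time.
#'
#' @param dir Bundle directory.
#' @param tissue_reduction Passed to [build_expression_tracks()].
#' @return An `annotation_bundle`.
#' @export
load_annotation_bundle <- function(dir, tissue_reduction = "sum") {
  gene_path <- file.path(dir, "genes.tsv")
  if (!file.exists(gene_path)) gene_path <- file.path(dir, "genes.gtf")
  models <- load_gene_models(gene_path)
  tpm <- utils::read.delim(file.path(dir, "transcript_tpm.tsv"),
                           stringsAsFactors = FALSE)
  tracks <- build_expression_tracks(tpm, models, reduction = tissue_reduction)
  annotation_bundle(
    models = models,
    scores = load_gene_scores(file.path(dir, "gene_scores.tsv")),
    conservation = load_track(file.path(dir, "conservation.bedgraph")),
    expression = tracks$expression,
    inclusion = tracks$inclusion,
    tad = load_tad_bed(file.path(dir, "tad_boundaries.bed"))
  )
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat(sprintf(
    "annotation_bundle: %d gene(s), %d scored, tracks: cons=%d expr=%d incl=%d intervals, %d TAD boundaries\n",
    length(x$models$genes), sum(!is.na(x$pli)),
    length(x$track_gr$conservation), length(x$track_gr$expression),
    length(x$track_gr$inclusion), nrow(x$tad)))
  invisible(x)
}

#' Genes whose principal-transcript exons overlap an SV
#'
#' Eligibility ("exon-altering") requires at least 1 bp overlap between the
#' SV and a principal-transcript exon; half-open abutment does not count.
#'
#' @param svs An `sv_tbl` (one or more records).
#' @param bundle An `annotation_bundle`.
#' @return A list, one element per SV, each a list with per-gene entries
#'   `gene_id` and `exon_indices` (0-based transcript-order positions of the
#'   overlapped principal exons).
#' @export
exon_overlap <- function(svs, bundle) {
  et <- bundle$models$exon_table
  sv_gr <- granges_0h(svs$chrom, svs$start, svs$end)
  hit <- GenomicRanges::findOverlaps(sv_gr, bundle$exon_gr)
  qh <- S4Vectors::queryHits(hit); sh <- S4Vectors::subjectHits(hit)
  out <- rep(list(list()), nrow(svs))
  for (q in unique(qh)) {
    rows <- sh[qh == q]
    gl <- split(et$order0[rows], et$gene_id[rows])
    out[[q]] <- lapply(names(gl), function(g)
      list(gene_id = g, exon_indices = sort(unname(gl[[g]]))))
    names(out[[q]]) <- names(gl)
  }
  out
}
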