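# Independent brute-force oracles. These deliberately work per nucleotide
# (expanding intervals to base vectors) and re-derive principal transcripts,
# CDS coordinates and track values from the raw bundle files, sharing no
# interval algebra with the package implementation.

# Raw bundle files as plain data frames.
read_raw_bundle <- function(dir) {
  list(
    genes = read.delim(file.path(dir, "genes.tsv"),
                       colClasses = c(chrom = "character")),
    scores = read.delim(file.path(dir, "gene_scores.tsv")),
    tpm = read.delim(file.path(dir, "transcript_tpm.tsv")),
    cons = read.table(file.path(dir, "conservation.bedgraph"), sep = "\t",
                      col.names = c("chrom", "start", "end", "value"),
                      colClasses = c("character", "numeric", "numeric",
                                     "numeric")),
    tad = read.table(file.path(dir, "tad_boundaries.bed"), sep = "\t",
                     col.names = c("chrom", "start", "end", "strength"),
                     colClasses = c("character", "numeric", "numeric",
                                    "numeric"))
  )
}

# Principal transcript id per gene: best APPRIS rank, then longest, then
# lexicographically smallest id.
oracle_principal <- function(genes) {
  out <- list()
  for (gid in unique(genes$gene_id)) {
    g <- genes[genes$gene_id == gid, ]
    tids <- sort(unique(g$transcript_id))
    rank <- sapply(tids, function(t) g$appris_rank[g$transcript_id == t][1])
    len <- sapply(tids, function(t) {
      e <- g[g$transcript_id == t & g$feature == "exon", ]
      sum(e$end - e$start)
    })
    if (all(is.na(rank))) next
    cand <- tids[!is.na(rank) & rank == min(rank, na.rm = TRUE)]
    cand <- cand[len[cand] == max(len[cand])]
    out[[gid]] <- sort(cand)[1]
  }
  out
}

# All bases (0-based positions) of the intervals in df rows.
.bases <- function(df) {
  if (!nrow(df)) return(numeric())
  unlist(lapply(seq_len(nrow(df)), function(i) seq(df$start[i], df$end[i] - 1)))
}

# Mean of the top-k run-length units over a per-base value vector aligned to
# sorted base positions `pos`; NA values are uncovered bases.
.oracle_top_units <- function(pos, val, unit, k = 400) {
  keep <- !is.na(val)
  pos <- pos[keep]; val <- val[keep]
  if (!length(pos)) return(NA_real_)
  o <- order(pos); pos <- pos[o]; val <- val[o]
  run <- cumsum(c(TRUE, diff(pos) != 1 | val[-1] != val[-length(val)]))
  if (unit == "interval") {
    uv <- tapply(val, run, function(v) v[1])
    uv <- as.numeric(uv)
    if (length(uv) >= k) mean(sort(uv, decreasing = TRUE)[seq_len(k)])
    else mean(uv)
  } else {
    if (length(val) <= k) mean(val)
    else mean(sort(val, decreasing = TRUE)[seq_len(k)])
  }
}

# The full 17-feature oracle for one SV (one-row data frame with chrom,
# start, end, svtype). Returns a named vector with NA for missing values.
oracle_features <- function(sv, raw, unit = "interval") {
  genes <- raw$genes
  principal <- oracle_principal(genes)
  S <- sv$start; E <- sv$end; CH <- sv$chrom
  in_sv <- function(p) p >= S & p < E

  tx_tpm <- tapply(raw$tpm$tpm, raw$tpm$transcript_id, sum)

  per_gene <- list()
  for (gid in names(principal)) {
    pex <- genes[genes$transcript_id == principal[[gid]] &
                   genes$feature == "exon", ]
    if (pex$chrom[1] != CH) next
    pex <- pex[order(pex$start), ]
    hit <- any(pex$start < E & pex$end > S)
    if (!hit) next
    strand <- pex$strand[1]
    n_ex <- nrow(pex)
    order0 <- if (strand == "-") rev(seq_len(n_ex)) - 1 else seq_len(n_ex) - 1

    cdsr <- genes[genes$transcript_id == principal[[gid]] &
                    genes$feature == "cds", ]
    cdsr <- cdsr[order(cdsr$start), ]
    cds_bases <- .bases(cdsr)
    if (strand == "-") cds_bases <- rev(cds_bases)
    L <- length(cds_bases)
    if (L > 0) {
      disrupted <- in_sv(cds_bases)
      frac <- mean(disrupted)
      if (!any(disrupted)) {
        fs <- 1; fe <- 1
      } else {
        fs <- (min(which(disrupted)) - 1) / L
        fe <- (L - max(which(disrupted))) / L
      }
      start_cov <- in_sv(cds_bases[1])
      stop_cov <- in_sv(cds_bases[L])
    } else {
      frac <- NA; fs <- NA; fe <- NA; start_cov <- FALSE; stop_cov <- FALSE
    }

    srow <- raw$scores[raw$scores$gene_id == gid, ]
    pli <- if (nrow(srow)) srow$pli[1] else NA
    loeuf <- if (nrow(srow)) srow$loeuf[1] else NA

    ex_hit <- which(pex$start < E & pex$end > S)
    # constitutive: identical coordinates in every transcript of the gene
    g_all <- genes[genes$gene_id == gid & genes$feature == "exon", ]
    tids <- unique(g_all$transcript_id)
    const <- sapply(ex_hit, function(i) all(sapply(tids, function(t) {
      te <- g_all[g_all$transcript_id == t, ]
      any(te$start == pex$start[i] & te$end == pex$end[i])
    })))
    lens <- pex$end - pex$start
    internal <- order0 > 0 & order0 < n_ex - 1
    inframe <- all(lens[ex_hit] %% 3 == 0 & internal[ex_hit])

    hi <- !is.na(frac) && frac > 0.5
    per_gene[[gid]] <- list(
      fs = fs, fe = fe, frac = frac,
      pli = pli, loeuf = loeuf,
      pli_hi = if (start_cov || hi) pli else NA,
      loeuf_hi = if (stop_cov || hi) loeuf else NA,
      min_order = min(order0[ex_hit]), n_ex = n_ex,
      n_overlap = length(ex_hit),
      any_const = any(const), all_inframe = inframe)
  }
  if (!length(per_gene)) return(NULL)

  # exon-space bases: union of principal exons of all genes on the
  # chromosome, restricted to the SV
  all_pex <- do.call(rbind, lapply(names(principal), function(gid) {
    p <- genes[genes$transcript_id == principal[[gid]] &
                 genes$feature == "exon", ]
    p[p$chrom == CH, ]
  }))
  space <- sort(unique(.bases(all_pex)))
  space <- space[in_sv(space)]

  # conservation per base
  cons <- raw$cons[raw$cons$chrom == CH & raw$cons$end > S &
                     raw$cons$start < E, ]
  cons_val <- rep(NA_real_, length(space))
  for (i in seq_len(nrow(cons))) {
    sel <- space >= cons$start[i] & space < cons$end[i]
    cons_val[sel] <- cons$value[i]
  }

  # expression / inclusion per base from TPM and all transcripts' exons
  allex <- genes[genes$feature == "exon" & genes$chrom == CH &
                   genes$end > S & genes$start < E, ]
  expr_val <- rep(0, length(space))
  covered <- rep(FALSE, length(space))
  for (i in seq_len(nrow(allex))) {
    sel <- space >= allex$start[i] & space < allex$end[i]
    expr_val[sel] <- expr_val[sel] + tx_tpm[[allex$transcript_id[i]]]
    covered <- covered | sel
  }
  expr_val[!covered] <- NA
  incl_val <- rep(NA_real_, length(space))
  for (gid in unique(allex$gene_id)) {
    gx <- allex[allex$gene_id == gid, ]
    gtids <- unique(genes$transcript_id[genes$gene_id == gid])
    total <- sum(sapply(gtids, function(t) tx_tpm[[t]]))
    if (total <= 0) next
    gcov <- rep(0, length(space))
    for (i in seq_len(nrow(gx))) {
      sel <- space >= gx$start[i] & space < gx$end[i]
      gcov[sel] <- gcov[sel] + tx_tpm[[gx$transcript_id[i]]]
    }
    seen <- rowSums(matrix(vapply(seq_len(nrow(gx)), function(i)
      space >= gx$start[i] & space < gx$end[i], logical(length(space))),
      nrow = length(space))) > 0
    ratio <- gcov / total
    upd <- seen & (is.na(incl_val) | ratio > incl_val)
    incl_val[upd] <- ratio[upd]
  }

  tad <- raw$tad[raw$tad$chrom == CH & raw$tad$end > S & raw$tad$start < E, ]

  agg <- function(x, f) {
    x <- unlist(x)
    if (all(is.na(x))) NA_real_ else f(x, na.rm = TRUE)
  }
  pg <- per_gene
  c(
    cds_frac_from_start = agg(lapply(pg, `[[`, "fs"), min),
    cds_frac_from_stop = agg(lapply(pg, `[[`, "fe"), min),
    cds_frac_overlapped = agg(lapply(pg, `[[`, "frac"), max),
    phylop_top400 = .oracle_top_units(space, cons_val, unit),
    exon_expression_top400 = .oracle_top_units(space, expr_val, unit),
    exon_inclusion_top400 = .oracle_top_units(space, incl_val, unit),
    tad_strength_max = if (nrow(tad)) max(tad$strength) else NA_real_,
    loeuf_min = agg(lapply(pg, `[[`, "loeuf"), min),
    loeuf_high_impact_min = agg(lapply(pg, `[[`, "loeuf_hi"), min),
    pli_max = agg(lapply(pg, `[[`, "pli"), max),
    pli_high_impact_max = agg(lapply(pg, `[[`, "pli_hi"), max),
    all_exons_inframe_skippable = as.numeric(all(sapply(pg, `[[`, "all_inframe"))),
    any_exon_constitutive = as.numeric(any(sapply(pg, `[[`, "any_const"))),
    min_exon_order = min(sapply(pg, `[[`, "min_order")),
    min_exons_in_gene = min(sapply(pg, `[[`, "n_ex")),
    max_exons_overlapped = max(sapply(pg, `[[`, "n_overlap")),
    is_deletion = as.numeric(sv$svtype == "DEL")
  )
}

# O(n^2) greedy reciprocal-overlap dedup oracle.
oracle_dedup <- function(svs, threshold = 0.9, keep = "first",
                         dup_cmp = ">=") {
  ord <- if (keep == "smallest") order(svs$end - svs$start)
         else seq_len(nrow(svs))
  d <- svs[ord, ]
  kept <- integer()
  for (i in seq_len(nrow(d))) {
    dup <- FALSE
    for (j in kept) {
      if (d$chrom[i] != d$chrom[j]) next
      ov <- max(0, min(d$end[i], d$end[j]) - max(d$start[i], d$start[j]))
      ro <- min(ov / (d$end[i] - d$start[i]), ov / (d$end[j] - d$start[j]))
      hit <- if (dup_cmp == ">=") ro >= threshold else ro > threshold
      if (hit) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, i)
  }
  d[kept, ]
}

# Mann-Whitney AUC with tie correction (rank formulation).
mw_auc <- function(scores, labels) {
  pos <- labels == "pathogenic"
  n1 <- sum(pos); n2 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
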