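# feature_extraction: the 17 per-SV annotation features, with the multi-gene
# aggregation rules (min/max/any/all), top-400 conventions for conservation
# and expression, and training-median imputation.

#' Names of the 17 SV features, in the fixed model order
#'
#' @format Character vector of length 17. Boolean features are coded 0/1.
#' @export
sv_feature_names <- c(
  "cds_frac_from_start", "cds_frac_from_stop", "cds_frac_overlapped",
  "phylop_top400", "exon_expression_top400", "exon_inclusion_top400",
  "tad_strength_max",
  "loeuf_min", "loeuf_high_impact_min", "pli_max", "pli_high_impact_max",
  "all_exons_inframe_skippable", "any_exon_constitutive",
  "min_exon_order", "min_exons_in_gene", "max_exons_overlapped",
  "is_deletion"
)

.sv_boolean_features <- c("all_exons_inframe_skippable",
                          "any_exon_constitutive", "is_deletion")

.min_na <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
.max_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)

# Per-gene CDS summary for one SV: disrupted-fraction triple in transcript
# orientation plus start/stop-codon coverage. `m` is a gene's cds_map.
.gene_cds_summary <- function(m, S, E) {
  if (m$L == 0) {
    return(list(from_start = NA_real_, from_stop = NA_real_,
                frac = NA_real_, start_cov = FALSE, stop_cov = FALSE))
  }
  ov_s <- pmax(m$start, S); ov_e <- pmin(m$end, E)
  w <- ov_e - ov_s
  sel <- w > 0
  tot <- sum(w[sel])
  if (tot == 0) {
    from_start <- 1; from_stop <- 1
  } else {
    cs <- if (m$strand == "-") m$offset + (m$end - ov_e)
          else m$offset + (ov_s - m$start)
    ce <- cs + w
    from_start <- min(cs[sel]) / m$L
    from_stop <- (m$L - max(ce[sel])) / m$L
  }
  list(from_start = from_start, from_stop = from_stop, frac = tot / m$L,
       start_cov = S <= m$start_codon && m$start_codon < E,
       stop_cov = S <= m$stop_codon && m$stop_codon < E)
}

# Intersect clipped track pieces (ts,te,tv) with exon-space intervals
# (ss,se); both sorted and non-overlapping. Returns run-length units
# (list of start/end/value vectors) with abutting equal values merged.
.clip_track_to_space <- function(ts, te, tv, ss, se) {
  empty <- list(start = numeric(), end = numeric(), value = numeric())
  if (!length(ts) || !length(ss)) return(empty)
  # for track piece i, space intervals j1..j2 overlap it (integer coords)
  j1 <- findInterval(ts + 0.5, se) + 1L   # first j with se[j] > ts[i]
  j2 <- findInterval(te - 0.5, ss)        # last j with ss[j] < te[i]
  k <- pmax(0L, j2 - j1 + 1L)
  if (!any(k > 0)) return(empty)
  qh <- rep.int(seq_along(ts), k)
  sh <- sequence(k, from = j1)
  s <- pmax(ts[qh], ss[sh]); e <- pmin(te[qh], se[sh]); v <- tv[qh]
  # merge abutting equal-valued units (already sorted by construction)
  n <- length(s)
  if (n > 1) {
    new_run <- c(TRUE, s[-1] != e[-n] | v[-1] != v[-n])
    run_end <- c(which(new_run)[-1] - 1L, n)
    e <- e[run_end]
    s <- s[new_run]; v <- v[new_run]
  }
  list(start = s, end = e, value = v)
}

.top400_from_units <- function(units, unit = c("interval", "nucleotide"),
                               k = 400) {
  unit <- match.arg(unit)
  v <- units$value
  if (!length(v)) return(NA_real_)
  if (unit == "interval") {
    if (length(v) >= k) mean(sort(v, decreasing = TRUE)[seq_len(k)])
    else mean(v)
  } else {
    w <- units$end - units$start
    if (sum(w) <= k) return(sum(v * w) / sum(w))
    o <- order(v, decreasing = TRUE)
    v <- v[o]; w <- w[o]
    cw <- cumsum(w)
    j <- which(cw >= k)[1]
    full <- if (j > 1) sum(v[seq_len(j - 1)] * w[seq_len(j - 1)]) else 0
    rem <- k - if (j > 1) cw[j - 1] else 0
    (full + v[j] * rem) / k
  }
}

# Batch feature engine. Returns a data frame: id + 17 numeric columns with
# NA marking missing (pre-imputation) values, attribute "n_overlap_genes".
.sv_feature_matrix <- function(svs, bundle, unit = "interval") {
  n <- nrow(svs)
  et <- bundle$models$exon_table
  sv_gr <- granges_0h(svs$chrom, svs$start, svs$end)
  sp <- function(gr) {
    h <- GenomicRanges::findOverlaps(sv_gr, gr)
    split(S4Vectors::subjectHits(h),
          factor(S4Vectors::queryHits(h), levels = seq_len(n)))
  }
  ex_sp <- sp(bundle$exon_gr)
  un_sp <- sp(bundle$union_gr)
  tr_sp <- lapply(bundle$track_gr, sp)
  tad_sp <- sp(bundle$tad_gr)
  un_start <- GenomicRanges::start(bundle$union_gr) - 1
  un_end <- GenomicRanges::end(bundle$union_gr)
  tr_dat <- lapply(bundle$track_gr, function(gr) list(
    start = GenomicRanges::start(gr) - 1, end = GenomicRanges::end(gr),
    value = S4Vectors::mcols(gr)$value))

  out <- matrix(NA_real_, nrow = n, ncol = length(sv_feature_names),
                dimnames = list(NULL, sv_feature_names))
  n_genes <- integer(n)

  et_gene <- et$gene_id; et_order0 <- et$order0; et_inframe <- et$inframe_ok
  et_const <- et$constitutive; et_nex <- et$n_exons

  for (i in seq_len(n)) {
    rows <- ex_sp[[i]]
    if (!length(rows)) next
    S <- svs$start[i]; E <- svs$end[i]
    gene_ids <- sort(unique(et_gene[rows]))
    n_genes[i] <- length(gene_ids)

    g_from_start <- g_from_stop <- g_frac <- numeric(0)
    g_loeuf <- g_pli <- g_loeuf_hi <- g_pli_hi <- numeric(0)
    g_all_inframe <- g_any_const <- logical(0)
    g_n_exons <- g_n_overlap <- numeric(0)

    for (g in gene_ids) {
      gm <- bundle$models$genes[[g]]
      cs <- .gene_cds_summary(gm$cds_map, S, E)
      g_from_start <- c(g_from_start, cs$from_start)
      g_from_stop <- c(g_from_stop, cs$from_stop)
      g_frac <- c(g_frac, cs$frac)
      pli <- unname(bundle$pli[g]); loeuf <- unname(bundle$loeuf[g])
      if (!length(pli)) pli <- NA_real_
      if (!length(loeuf)) loeuf <- NA_real_
      g_pli <- c(g_pli, pli); g_loeuf <- c(g_loeuf, loeuf)
      hi_cds <- !is.na(cs$frac) && cs$frac > 0.5
      g_pli_hi <- c(g_pli_hi, if (cs$start_cov || hi_cds) pli else NA_real_)
      g_loeuf_hi <- c(g_loeuf_hi, if (cs$stop_cov || hi_cds) loeuf else NA_real_)
      gr_rows <- rows[et_gene[rows] == g]
      g_all_inframe <- c(g_all_inframe, all(et_inframe[gr_rows]))
      g_any_const <- c(g_any_const, any(et_const[gr_rows]))
      g_n_exons <- c(g_n_exons, et_nex[gr_rows[1]])
      g_n_overlap <- c(g_n_overlap, length(gr_rows))
    }

    # SV ∩ exon space (principal-exon union), for track features
    ur <- un_sp[[i]]
    ss <- pmax(un_start[ur], S); se <- pmin(un_end[ur], E)
    tr_vals <- vapply(names(tr_dat), function(tn) {
      td <- tr_dat[[tn]]; r <- tr_sp[[tn]][[i]]
      units <- .clip_track_to_space(pmax(td$start[r], S), pmin(td$end[r], E),
                                    td$value[r], ss, se)
      .top400_from_units(units, unit)
    }, numeric(1))

    tad_rows <- tad_sp[[i]]
    out[i, ] <- c(
      cds_frac_from_start = .min_na(g_from_start),
      cds_frac_from_stop = .min_na(g_from_stop),
      cds_frac_overlapped = .max_na(g_frac),
      phylop_top400 = unname(tr_vals["conservation"]),
      exon_expression_top400 = unname(tr_vals["expression"]),
      exon_inclusion_top400 = unname(tr_vals["inclusion"]),
      tad_strength_max = .max_na(
        if (length(tad_rows)) bundle$tad$strength[tad_rows] else NA_real_),
      loeuf_min = .min_na(g_loeuf),
      loeuf_high_impact_min = .min_na(g_loeuf_hi),
      pli_max = .max_na(g_pli),
      pli_high_impact_max = .max_na(g_pli_hi),
      all_exons_inframe_skippable = as.numeric(all(g_all_inframe)),
      any_exon_constitutive = as.numeric(any(g_any_const)),
      min_exon_order = min(et_order0[rows]),
      min_exons_in_gene = min(g_n_exons),
      max_exons_overlapped = max(g_n_overlap),
      is_deletion = as.numeric(svs$svtype[i] == "DEL")
    )
  }
  fm <- data.frame(id = svs$id, out, stringsAsFactors = FALSE)
  attr(fm, "n_overlap_genes") <- n_genes
  fm
}

#' Compute the 17 features for a table of SVs
#'
#' @param svs An `sv_tbl`.
#' @param bundle An `annotation_bundle`.
#' @param unit Unit for the top-400 conservation/expression convention:
#'   `"interval"` averages the 400 highest-valued run-length intervals
#'   (default), `"nucleotide"` the 400 highest-valued bases.
#' @param on_no_exon What to do with SVs that overlap no principal-transcript
#'   exon: `"error"` (default, they are not scoreable), `"drop"` them with a
#'   message, or `"keep"` them as all-`NA` rows.
#' @param medians Optional named vector of training medians; when supplied,
#'   missing values are imputed with [impute_features()].
#' @return Data frame with column `id` and the 17 feature columns
#'   (booleans coded 0/1); `NA` marks missing (unimputed) values.
#' @export
sv_features <- function(svs, bundle, unit = c("interval", "nucleotide"),
                        on_no_exon = c("error", "drop", "keep"),
                        medians = NULL) {
  unit <- match.arg(unit)
  on_no_exon <- match.arg(on_no_exon)
  fm <- .sv_feature_matrix(svs, bundle, unit)
  ng <- attr(fm, "n_overlap_genes")
  if (any(ng == 0)) {
    if (on_no_exon == "error")
      stopf("%d SV(s) not scoreable; exon-altering SVs only (e.g. id %s)",
            sum(ng == 0), fm$id[ng == 0][1])
    if (on_no_exon == "drop") {
      message(sprintf("sv_features: dropped %d SV(s) with no exon overlap",
                      sum(ng == 0)))
      fm <- fm[ng > 0, , drop = FALSE]
      attr(fm, "n_overlap_genes") <- ng[ng > 0]
    }
  }
  if (!is.null(medians)) fm <- impute_features(fm, medians)
  fm
}

#' Assemble the feature vector for a single SV
#'
#' @param sv A one-row `sv_tbl`.
#' @inheritParams sv_features
#' @return Named numeric vector of the 17 features (with attribute
#'   `missing`, the pre-imputation missingness mask).
#' @export
assemble_features <- function(sv, bundle, medians = NULL,
                              unit = c("interval", "nucleotide")) {
  stopifnot(nrow(sv) == 1)
  fm <- sv_features(sv, bundle, unit = match.arg(unit), on_no_exon = "error")
  miss <- is.na(as.numeric(fm[1, sv_feature_names]))
  names(miss) <- sv_feature_names
  if (!is.null(medians)) fm <- impute_features(fm, medians)
  out <- as.numeric(fm[1, sv_feature_names])
  names(out) <- sv_feature_names
  attr(out, "missing") <- miss
  out
}

# ---- spec'd per-family operations (thin views over the engine) -------------

#' CDS disruption features for one SV
#'
#' Per gene, with `L` the principal-transcript CDS length: the fraction of
#' CDS 5' of the first disrupted coding base (1 if undisrupted), the fraction
#' 3' of the last disrupted base, and the fraction of CDS overlapped;
#' aggregated min/min/max across genes. Strand-aware.
#'
#' @param sv A one-row `sv_tbl`.
#' @param bundle An `annotation_bundle`.
#' @return Named numeric vector `cds_frac_from_start`, `cds_frac_from_stop`,
#'   `cds_frac_overlapped` (`NA` when no overlapped gene has a CDS).
#' @export
cds_features <- function(sv, bundle) {
  fm <- .sv_feature_matrix(sv, bundle)
  v <- as.numeric(fm[1, c("cds_frac_from_start", "cds_frac_from_stop",
                          "cds_frac_overlapped")])
  stats::setNames(v, c("cds_frac_from_start", "cds_frac_from_stop",
                       "cds_frac_overlapped"))
}

#' Mean of the top-400 track units overlapped by an SV
#'
#' Restricts `track` to the SV's exon-overlap space, decomposes the result
#' into run-length units, and averages the 400 highest-valued units; when
#' fewer than 400 units are covered, all covered units are averaged.
#'
#' @param sv A one-row `sv_tbl`.
#' @param track A `pb_track`.
#' @param exon_space Data frame `start`,`end` of SV-intersected exon
#'   intervals (0-based half-open) on the SV's chromosome.
#' @param unit `"interval"` (unweighted run-length units, default) or
#'   `"nucleotide"`.
#' @return Mean value, or `NA` if the track has no value over `exon_space`.
#' @export
top400_track_mean <- function(sv, track, exon_space,
                              unit = c("interval", "nucleotide")) {
  unit <- match.arg(unit)
  tq <- track_query(track, sv$chrom[1], sv$start[1], sv$end[1])
  units <- .clip_track_to_space(tq$start, tq$end, tq$value,
                                pmax(exon_space$start, sv$start[1]),
                                pmin(exon_space$end, sv$end[1]))
  .top400_from_units(units, unit)
}

#' Gene-importance features for one SV
#'
#' `loeuf_min`/`pli_max` aggregate over all exon-overlapped genes. The
#' high-impact variants restrict to genes whose principal start codon (pLI)
#' or stop codon (LOEUF) is covered by the SV, or with CDS-overlap
#' fraction > 0.5; `NA` when no gene qualifies or none is scored.
#'
#' @inheritParams cds_features
#' @return Named numeric vector of the four gene-importance features.
#' @export
gene_importance_features <- function(sv, bundle) {
  fm <- .sv_feature_matrix(sv, bundle)
  nm <- c("loeuf_min", "loeuf_high_impact_min", "pli_max",
          "pli_high_impact_max")
  stats::setNames(as.numeric(fm[1, nm]), nm)
}

#' Exon-structure features for one SV
#'
#' Exon transcript order counts the exons preceding an exon in its principal
#' transcript (0-based); constitutive means coordinate-identical presence in
#' every transcript of the gene; in-frame skippable means an internal exon
#' whose length is a multiple of 3.
#'
#' @inheritParams cds_features
#' @return Named numeric vector of the five exon-structure features
#'   (booleans coded 0/1).
#' @export
exon_structure_features <- function(sv, bundle) {
  fm <- .sv_feature_matrix(sv, bundle)
  nm <- c("all_exons_inframe_skippable", "any_exon_constitutive",
          "min_exon_order", "min_exons_in_gene", "max_exons_overlapped")
  stats::setNames(as.numeric(fm[1, nm]), nm)
}

#' Maximum TAD-boundary strength overlapped by an SV
#'
#' @param sv A one-row `sv_tbl`.
#' @param boundaries Data frame `chrom`, `start`, `end`, `strength`.
#' @return Maximum strength among boundaries intersecting the SV, `NA` when
#'   none intersects.
#' @export
tad_feature <- function(sv, boundaries) {
  keep <- boundaries$chrom == sv$chrom[1] &
    boundaries$end > sv$start[1] & boundaries$start < sv$end[1]
  .max_na(if (any(keep)) boundaries$strength[keep] else NA_real_)
}

# ---- imputation ------------------------------------------------------------

#' Per-feature imputation values from a training feature matrix
#'
#' Numeric features use the median of the non-missing values; boolean (0/1)
#' features use the training majority value (ties toward 0/FALSE).
#'
#' @param fm Feature matrix from [sv_features()].
#' @return Named numeric vector over the 17 features.
#' @export
feature_medians <- function(fm) {
  vapply(sv_feature_names, function(nm) {
    x <- fm[[nm]]
    x <- x[!is.na(x)]
    if (!length(x)) return(if (nm %in% .sv_boolean_features) 0 else NA_real_)
    if (nm %in% .sv_boolean_features) as.numeric(mean(x) > 0.5)
    else stats::median(x)
  }, numeric(1))
}

#' Impute missing feature values
#'
#' @param fm Feature matrix from [sv_features()].
#' @param medians Named vector from [feature_medians()].
#' @return `fm` with `NA` entries replaced by the supplied values.
#' @export
impute_features <- function(fm, medians) {
  for (nm in sv_feature_names) {
    nas <- is.na(fm[[nm]])
    if (any(nas)) fm[[nm]][nas] <- medians[[nm]]
  }
  fm
}

# ---- correlation -----------------------------------------------------------

#' Spearman correlation matrix of features, ordered by clustering
#'
#' Computes the 17 x 17 Spearman rank correlation over a feature matrix and
#' orders rows/columns by average-linkage hierarchical clustering on the
#' correlation distance (1 - rho). Selected features can be sign-flipped
#' first to reduce negative correlation blocks (LOEUF runs opposite to pLI).
#'
#' @param fm Feature matrix from [sv_features()] (>= 3 rows).
#' @param flip Character vector of feature names to negate before
#'   correlating.
#' @return Ordered correlation matrix with attribute `order`.
#' @export
feature_correlation_matrix <- function(fm,
                                       flip = c("loeuf_min",
                                                "loeuf_high_impact_min",
                                                "cds_frac_from_start",
                                                "cds_frac_from_stop")) {
  m <- as.matrix(fm[, sv_feature_names])
  if (nrow(m) < 3) stopf("need at least 3 feature vectors")
  for (nm in intersect(flip, colnames(m))) m[, nm] <- -m[, nm]
  rho <- suppressWarnings(
    stats::cor(m, method = "spearman", use = "pairwise.complete.obs"))
  if (any(is.na(rho))) {
    warnf("constant feature(s): undefined correlations reported as 0")
    rho[is.na(rho)] <- 0
  }
  diag(rho) <- 1
  hc <- stats::hclust(stats::as.dist(1 - rho), method = "average")
  ord <- hc$order
  out <- rho[ord, ord]
  attr(out, "order") <- colnames(rho)[ord]
  out
}
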