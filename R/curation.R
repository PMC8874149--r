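# curation: training/test-set construction — reciprocal-overlap
# deduplication, allele-frequency rarity classes, common-SV removal, tiered
# size matching, feature-identical dedup, chromosome splits.

#' Reciprocal overlap between two SVs
#'
#' `min(overlap / size_a, overlap / size_b)`; 0 across chromosomes.
#'
#' @param a,b One-row `sv_tbl` records (or vectors recycled elementwise).
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' a <- sv_records("1", 0, 100, "DEL"); b <- sv_records("1", 10, 110, "DEL")
#' reciprocal_overlap(a, b)  # 0.9
reciprocal_overlap <- function(a, b) {
  ov <- ifelse(a$chrom == b$chrom,
               overlap_bp(a$start, a$end, b$start, b$end), 0)
  pmin(ov / (a$end - a$start), ov / (b$end - b$start))
}

# RO of record i against all records in table `tbl` (vectorized).
.ro_vs <- function(start, end, chrom, tbl) {
  ov <- ifelse(tbl$chrom == chrom, overlap_bp(tbl$start, tbl$end, start, end), 0)
  pmin(ov / (end - start), ov / (tbl$end - tbl$start))
}

#' Greedy reciprocal-overlap deduplication
#'
#' Sweeps the records in the stated order (size-ascending for
#' `keep = "smallest"`, input order for `keep = "first"`) and retains a
#' record iff it is not a duplicate of any previously retained record.
#' Duplicates are pairs whose reciprocal overlap meets `threshold` under
#' `dup_cmp` (default: RO >= threshold). Deletions and duplications should be
#' deduplicated separately by the caller.
#'
#' @param svs A svtype-homogeneous `sv_tbl`.
#' @param threshold Reciprocal-overlap duplicate threshold in (0, 1].
#' @param keep `"first"` (input order) or `"smallest"` (size-ascending sweep).
#' @param dup_cmp `">="` (default) or `">"`: comparison that makes a pair a
#'   duplicate.
#' @return The retained `sv_tbl` (in sweep order).
#' @export
dedup_by_overlap <- function(svs, threshold = 0.9,
                             keep = c("first", "smallest"),
                             dup_cmp = c(">=", ">")) {
  keep <- match.arg(keep)
  dup_cmp <- match.arg(dup_cmp)
  stopifnot(threshold > 0, threshold <= 1)
  if (length(unique(svs$svtype)) > 1)
    stopf("dedup_by_overlap expects a single svtype; split DEL/DUP first")
  ord <- if (keep == "smallest") order(sv_size(svs)) else seq_len(nrow(svs))
  d <- svs[ord, , drop = FALSE]
  is_dup <- if (dup_cmp == ">=") function(ro) any(ro >= threshold)
            else function(ro) any(ro > threshold)
  kept <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    prev <- d[kept, , drop = FALSE]
    ro <- if (nrow(prev)) .ro_vs(d$start[i], d$end[i], d$chrom[i], prev) else numeric()
    kept[i] <- !length(ro) || !is_dup(ro)
  }
  validate_sv_records(d[kept, , drop = FALSE])
}

#' Minor allele frequency from event counts
#'
#' `observed_events / (2 * samplesize)`, the diploid-population MAF used for
#' copy-number catalog records (observed losses or gains over allele count).
#'
#' @param observed_events Non-negative event count.
#' @param samplesize Number of sampled individuals (> 0).
#' @return MAF; values above 1 are capped at 1 with a warning.
#' @export
dgv_maf <- function(observed_events, samplesize) {
  if (any(samplesize <= 0)) stopf("samplesize must be > 0")
  maf <- observed_events / (2 * samplesize)
  if (any(maf > 1)) {
    warnf("MAF > 1 computed; capping at 1")
    maf <- pmin(maf, 1)
  }
  maf
}

#' Rarity class of an SV
#'
#' Common if MAF exceeds the threshold; otherwise rare-benign when at least
#' one individual is homozygous for the minor allele, rare-unlabeled when
#' none is.
#'
#' @param svs An `sv_tbl` with `maf` and `n_homalt` present.
#' @param maf_threshold MAF cut-off for "common" (default 1%).
#' @return Character vector: `"common"`, `"rare_benign"`, `"rare_unlabeled"`.
#' @export
classify_rarity <- function(svs, maf_threshold = 0.01) {
  if (any(is.na(svs$maf))) stopf("classify_rarity: missing maf")
  if (any(is.na(svs$n_homalt))) stopf("classify_rarity: missing n_homalt")
  ifelse(svs$maf > maf_threshold, "common",
         ifelse(svs$n_homalt >= 1, "rare_benign", "rare_unlabeled"))
}

#' Remove SVs matching common-SV catalogs
#'
#' Removes records exactly matching (chrom, start, end, svtype) any record in
#' `exact_sources`, and records with reciprocal overlap above `ro_threshold`
#' to any record of the same type in `ro_sources`.
#'
#' @param svs An `sv_tbl`.
#' @param exact_sources List of `sv_tbl`s matched exactly.
#' @param ro_sources List of `sv_tbl`s matched by reciprocal overlap.
#' @param ro_threshold RO above which a record is removed (default 0.9).
#' @return The filtered `sv_tbl`.
#' @export
remove_common <- function(svs, exact_sources = list(), ro_sources = list(),
                          ro_threshold = 0.9) {
  drop <- logical(nrow(svs))
  for (src in exact_sources) {
    key_src <- paste(src$chrom, src$start, src$end, src$svtype)
    drop <- drop | paste(svs$chrom, svs$start, svs$end, svs$svtype) %in% key_src
  }
  for (src in ro_sources) {
    for (i in which(!drop)) {
      same <- src[src$svtype == svs$svtype[i], , drop = FALSE]
      if (nrow(same) &&
          any(.ro_vs(svs$start[i], svs$end[i], svs$chrom[i], same) > ro_threshold))
        drop[i] <- TRUE
    }
  }
  validate_sv_records(svs[!drop, , drop = FALSE])
}

#' Size-matching configuration
#'
#' A pathogenic SV of size `N` seeks a benign SV of the same type whose size
#' lies in the multiplicative window
#' `[N / alpha - slack_bp, N * alpha + slack_bp]`.
#'
#' @param alpha Multiplicative window factor (> 1), default 1.06101.
#' @param slack_bp Additive window in bp, default 20.
#' @param order Order in which pathogenic SVs are processed.
#' @return A `match_config` list.
#' @export
match_config <- function(alpha = 1.06101, slack_bp = 20,
                         order = c("input", "size")) {
  stopifnot(alpha > 1, slack_bp >= 0)
  structure(list(alpha = alpha, slack_bp = slack_bp,
                 order = match.arg(order)), class = "match_config")
}

#' Tiered size-and-type matching of pathogenic to benign SVs
#'
#' Walks the pathogenic SVs (input order by default); each seeks an unused
#' benign SV of the same type within the size window of `cfg`, trying the
#' benign tiers in order and falling through to the next tier only when the
#' current one offers no candidate. Among in-window candidates the
#' size-closest is consumed (ties to the smaller). Pathogenic SVs that match
#' in no tier are dropped.
#'
#' @param pathogenic An `sv_tbl`.
#' @param benign_tiers Ordered (most to least trusted) list of `sv_tbl`s.
#' @param cfg A [match_config()].
#' @return Data frame of matched pairs: pathogenic `id`/`size`, benign
#'   `id`/`size`, `tier`, plus attribute `dropped` (unmatched pathogenic ids)
#'   and attribute `pairs` (list with the matched `sv_tbl`s `pathogenic`
#'   and `benign`, row-aligned).
#' @export
size_match <- function(pathogenic, benign_tiers, cfg = match_config()) {
  if (!length(benign_tiers)) stopf("size_match: empty tier list")
  if (is.null(names(benign_tiers)))
    names(benign_tiers) <- paste0("tier", seq_along(benign_tiers))
  ord <- if (cfg$order == "size") order(sv_size(pathogenic))
         else seq_len(nrow(pathogenic))
  tier_size <- lapply(benign_tiers, sv_size)
  used <- lapply(benign_tiers, function(t) logical(nrow(t)))
  res <- vector("list", nrow(pathogenic))
  dropped <- character()
  for (i in ord) {
    N <- pathogenic$end[i] - pathogenic$start[i]
    lo <- N / cfg$alpha - cfg$slack_bp
    hi <- N * cfg$alpha + cfg$slack_bp
    matched <- FALSE
    for (ti in seq_along(benign_tiers)) {
      bt <- benign_tiers[[ti]]
      cand <- which(!used[[ti]] & bt$svtype == pathogenic$svtype[i] &
                      tier_size[[ti]] >= lo & tier_size[[ti]] <= hi)
      if (length(cand)) {
        dist <- abs(tier_size[[ti]][cand] - N)
        best <- cand[dist == min(dist)]
        if (length(best) > 1)  # ties to the smaller benign SV
          best <- best[which.min(tier_size[[ti]][best])]
        best <- best[1]
        used[[ti]][best] <- TRUE
        res[[i]] <- data.frame(
          pathogenic_id = pathogenic$id[i], pathogenic_size = N,
          benign_id = bt$id[best], benign_size = tier_size[[ti]][best],
          tier = names(benign_tiers)[ti],
          .p = i, .t = ti, .b = best, stringsAsFactors = FALSE)
        matched <- TRUE
        break
      }
    }
    if (!matched) dropped <- c(dropped, pathogenic$id[i])
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(pathogenic_id = character(), pathogenic_size = numeric(),
                      benign_id = character(), benign_size = numeric(),
                      tier = character(), .p = integer(), .t = integer(),
                      .b = integer())
  pairs <- list(
    pathogenic = validate_sv_records(pathogenic[out$.p, , drop = FALSE]),
    benign = validate_sv_records(do.call(rbind, c(
      list(sv_records(character(), numeric(), numeric(), character())),
      lapply(seq_len(nrow(out)), function(k)
        benign_tiers[[out$.t[k]]][out$.b[k], , drop = FALSE]))))
  )
  out$.p <- out$.t <- out$.b <- NULL
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "pairs") <- pairs
  out
}

#' Remove feature-identical SVs within and across labels
#'
#' Within each label, groups of SVs with identical feature vectors keep one
#' representative (the first). Feature vectors occurring under both labels
#' are removed entirely from both.
#'
#' @param fm Feature matrix from [sv_features()].
#' @param labels Character vector (`"pathogenic"`/`"benign"`), one per row.
#' @return List `fm`, `labels` after deduplication, plus `removed_ids`.
#' @export
dedup_feature_identical <- function(fm, labels) {
  stopifnot(length(labels) == nrow(fm))
  key <- apply(fm[, sv_feature_names], 1, paste, collapse = "\r")
  keep <- !duplicated(paste(labels, key))
  both <- intersect(key[labels == "pathogenic"], key[labels == "benign"])
  keep <- keep & !key %in% both
  list(fm = fm[keep, , drop = FALSE], labels = labels[keep],
       removed_ids = fm$id[!keep])
}

#' Held-out chromosome split
#'
#' @param svs An `sv_tbl`.
#' @param held_out Chromosomes (chr prefix optional) forming the test set;
#'   defaults to chromosomes 1, 3, 5 and 7.
#' @return List of `sv_tbl`s `train` and `test`.
#' @export
chromosome_split <- function(svs, held_out = c("1", "3", "5", "7")) {
  chrom <- normalize_chrom(svs$chrom)
  held_out <- normalize_chrom(held_out)
  test <- chrom %in% held_out
  if (all(test)) stopf("held_out covers every chromosome: empty training set")
  list(train = validate_sv_records(svs[!test, , drop = FALSE]),
       test = validate_sv_records(svs[test, , drop = FALSE]))
}

#' Leave-one-chromosome-out folds
#'
#' @param svs An `sv_tbl`.
#' @return Named list with one fold per chromosome, each containing the
#'   integer row indices `train` and `test`.
#' @export
loco_folds <- function(svs) {
  chrom <- normalize_chrom(svs$chrom)
  chroms <- unique(chrom)
  if (length(chroms) < 2) stopf("leave-one-chromosome-out needs >= 2 chromosomes")
  folds <- lapply(chroms, function(ch)
    list(train = which(chrom != ch), test = which(chrom == ch)))
  names(folds) <- chroms
  folds
}

#' Subsample SVs so no gene is overlapped twice
#'
#' Visits the SVs in seeded random order and retains each iff its set of
#' exon-overlapped genes is disjoint from the genes of all previously
#' retained SVs; afterwards every gene overlaps at most one retained SV.
#'
#' @param svs An `sv_tbl`.
#' @param bundle An `annotation_bundle` (defines gene overlap).
#' @param seed Integer seed for the sampling order.
#' @return The retained `sv_tbl`.
#' @export
one_sv_per_gene_subsample <- function(svs, bundle, seed = 1) {
  genes_per_sv <- lapply(exon_overlap(svs, bundle), names)
  ord <- with_seed(seed, sample.int(nrow(svs)))
  seen <- character()
  kept <- integer()
  for (i in ord) {
    g <- genes_per_sv[[i]]
    if (!any(g %in% seen)) {
      kept <- c(kept, i)
      seen <- c(seen, g)
    }
  }
  validate_sv_records(svs[sort(kept), , drop = FALSE])
}
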