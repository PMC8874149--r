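# sv_io: read, normalize, filter, and write DEL/DUP structural-variant
# records. Internal convention is 0-based half-open coordinates everywhere;
# VCF POS (1-based) is converted on read and write.

SV_TYPES <- c("DEL", "DUP")
SV_LABELS <- c("pathogenic", "benign", "unlabeled")

# VCF SVTYPE / record-type spellings accepted for the two classes we handle.
.svtype_map <- c(
  DEL = "DEL", DUP = "DUP",
  deletion = "DEL", duplication = "DUP",
  `copy_number_loss` = "DEL", `copy_number_gain` = "DUP"
)

#' Construct a table of structural-variant records
#'
#' The package represents SVs as a plain data frame with one row per variant
#' and 0-based half-open coordinates, the convention used by BED arithmetic.
#'
#' @param chrom Chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions (`end > start`).
#' @param svtype `"DEL"` or `"DUP"`.
#' @param id Record identifiers (generated when missing).
#' @param maf Minor allele frequency in `[0, 1]`, or `NA`.
#' @param n_homalt Count of individuals homozygous for the minor allele, or `NA`.
#' @param label `"pathogenic"`, `"benign"`, or `"unlabeled"`.
#' @param source Free-text provenance tag.
#' @return A data frame of class `sv_tbl` with the columns above.
#' @export
#' @examples
#' sv_records("1", 100, 200, "DEL")
sv_records <- function(chrom, start, end, svtype,
                       id = NULL, maf = NA_real_, n_homalt = NA_real_,
                       label = "unlabeled", source = NA_character_) {
  n <- length(start)
  if (is.null(id)) id <- if (n) sprintf("sv%05d", seq_len(n)) else character()
  df <- data.frame(
    id = as.character(id),
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    svtype = as.character(svtype),
    maf = rep_len(as.numeric(maf), n),
    n_homalt = rep_len(as.numeric(n_homalt), n),
    label = rep_len(as.character(label), n),
    source = rep_len(as.character(source), n),
    stringsAsFactors = FALSE
  )
  validate_sv_records(df)
}

validate_sv_records <- function(df) {
  if (nrow(df)) {
    if (any(df$end <= df$start))
      stopf("invalid SV record(s): end <= start for id(s) %s",
            paste(df$id[df$end <= df$start], collapse = ", "))
    bad_type <- !df$svtype %in% SV_TYPES
    if (any(bad_type))
      stopf("svtype must be DEL or DUP (got: %s)",
            paste(unique(df$svtype[bad_type]), collapse = ", "))
    bad_maf <- !is.na(df$maf) & (df$maf < 0 | df$maf > 1)
    if (any(bad_maf)) stopf("maf outside [0, 1] for id(s) %s",
                            paste(df$id[bad_maf], collapse = ", "))
    if (any(!is.na(df$n_homalt) & df$n_homalt < 0))
      stopf("n_homalt must be non-negative")
    if (any(!df$label %in% SV_LABELS))
      stopf("label must be one of %s", paste(SV_LABELS, collapse = ", "))
  }
  class(df) <- c("sv_tbl", "data.frame")
  df
}

#' Sizes of SV records
#' @param svs An `sv_tbl`.
#' @return Numeric vector of sizes in bp (`end - start`).
#' @export
sv_size <- function(svs) svs$end - svs$start

.parse_info <- function(info) {
  if (info == "." || info == "") return(list())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  has_eq <- grepl("=", parts, fixed = TRUE)
  keys <- ifelse(has_eq, sub("=.*$", "", parts), parts)
  vals <- ifelse(has_eq, sub("^[^=]*=", "", parts), "")
  as.list(stats::setNames(vals, keys))
}

.num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read structural variants from a VCF file
#'
#' Parses a VCF 4.x file with symbolic SV records (SVTYPE plus END or SVLEN
#' in INFO) into the internal 0-based half-open representation
#' (`start = POS - 1`, `end = END`). Records whose SVTYPE does not map to
#' DEL/DUP (inversions, insertions, breakends, ...) are dropped and counted.
#' AF and N_HOMALT INFO values are captured when present.
#'
#' @param path Path to an uncompressed VCF file.
#' @param chrom_style Chromosome-name normalization applied on read
#'   (see [normalize_chrom()]), or `"asis"` to keep names untouched.
#' @return An `sv_tbl`. Attribute `dropped_svtype` counts records dropped for
#'   unsupported SVTYPE; attribute `record_errors` is a data frame describing
#'   records skipped with a record-level problem (e.g. neither END nor SVLEN,
#'   or END before POS), also raised as a warning.
#' @export
read_sv_vcf <- function(path, chrom_style = c("strip", "chr", "asis")) {
  chrom_style <- match.arg(chrom_style)
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  body_idx <- which(!is_meta & nzchar(lines))
  recs <- vector("list", length(body_idx))
  errs <- list()
  dropped <- 0L
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8)
      stopf("malformed VCF line %d: expected >= 8 tab-separated fields, got %d",
            i, length(f))
    pos <- suppressWarnings(as.numeric(f[2]))
    if (is.na(pos))
      stopf("malformed VCF line %d: POS '%s' is not numeric", i, f[2])
    info <- .parse_info(f[8])
    svtype_raw <- info[["SVTYPE"]] %||% NA_character_
    if (is.na(svtype_raw)) {
      # fall back to symbolic ALT, e.g. <DEL>
      alt <- f[5]
      if (grepl("^<.+>$", alt)) svtype_raw <- gsub("[<>]", "", alt)
    }
    svtype <- unname(.svtype_map[svtype_raw])
    if (is.na(svtype) || is.null(svtype)) {
      dropped <- dropped + 1L
      next
    }
    end <- .num_or_na(info[["END"]] %||% NA)
    svlen <- .num_or_na(sub(",.*$", "", info[["SVLEN"]] %||% NA))
    if (is.na(end) && is.na(svlen)) {
      errs[[length(errs) + 1L]] <- data.frame(
        line = i, id = f[3], message = "neither END nor SVLEN present")
      next
    }
    start0 <- pos - 1
    end0 <- if (!is.na(end)) end else start0 + abs(svlen)
    if (end0 <= start0) {
      errs[[length(errs) + 1L]] <- data.frame(
        line = i, id = f[3],
        message = sprintf("non-positive size (start=%g, end=%g)", start0, end0))
      next
    }
    af <- .num_or_na(sub(",.*$", "", info[["AF"]] %||% info[["MAF"]] %||% NA))
    nha <- .num_or_na(info[["N_HOMALT"]] %||% NA)
    recs[[k]] <- data.frame(
      id = if (f[3] == ".") sprintf("line%d", i) else f[3],
      chrom = f[1], start = start0, end = end0, svtype = svtype,
      maf = af, n_homalt = nha, label = "unlabeled",
      source = NA_character_, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(out))
    out <- sv_records(character(), numeric(), numeric(), character())
  if (chrom_style != "asis") out$chrom <- normalize_chrom(out$chrom, chrom_style)
  out <- validate_sv_records(out)
  if (dropped > 0)
    message(sprintf("read_sv_vcf: dropped %d record(s) with unsupported SVTYPE",
                    dropped))
  attr(out, "dropped_svtype") <- dropped
  if (length(errs)) {
    err_df <- do.call(rbind, errs)
    warnf("read_sv_vcf: %d record(s) skipped with errors (lines %s)",
          nrow(err_df), paste(err_df$line, collapse = ", "))
    attr(out, "record_errors") <- err_df
  }
  out
}

#' Read structural variants from a headered TSV/BED-like table
#'
#' Requires columns `chrom`, `start`, `end`, `svtype` (0-based half-open);
#' `id`, `maf`, `n_homalt`, `label`, and `source` are used when present and
#' extra columns are ignored.
#'
#' @param path Path to a tab-separated file with a header row.
#' @inheritParams read_sv_vcf
#' @return An `sv_tbl`.
#' @export
read_sv_tsv <- function(path, chrom_style = c("asis", "strip", "chr")) {
  chrom_style <- match.arg(chrom_style)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  need <- c("chrom", "start", "end", "svtype")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("SV table %s lacks column(s): %s", path,
                          paste(miss, collapse = ", "))
  if (chrom_style != "asis") df$chrom <- normalize_chrom(df$chrom, chrom_style)
  sv_records(
    chrom = df$chrom, start = df$start, end = df$end, svtype = df$svtype,
    id = if ("id" %in% names(df)) df$id else NULL,
    maf = if ("maf" %in% names(df)) df$maf else NA_real_,
    n_homalt = if ("n_homalt" %in% names(df)) df$n_homalt else NA_real_,
    label = if ("label" %in% names(df)) df$label else "unlabeled",
    source = if ("source" %in% names(df)) df$source else NA_character_
  )
}

#' Write SV records to a TSV file
#' @param svs An `sv_tbl`.
#' @param path Output path.
#' @export
write_sv_tsv <- function(svs, path) {
  utils::write.table(as.data.frame(svs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Retain SVs within a size range
#'
#' The training pipeline retains SVs between 50 bp and 3 Mb; both bounds are
#' inclusive and input order is preserved.
#'
#' @param svs An `sv_tbl`.
#' @param min_bp,max_bp Inclusive size bounds in bp.
#' @return The filtered `sv_tbl`.
#' @export
filter_by_size <- function(svs, min_bp = 50, max_bp = 3e6) {
  stopifnot(min_bp >= 1, max_bp >= min_bp)
  sz <- sv_size(svs)
  validate_sv_records(svs[sz >= min_bp & sz <= max_bp, , drop = FALSE])
}

#' Write scored SVs
#'
#' TSV mode writes `chrom,start,end,svtype,id,score` (0-based half-open).
#' VCF mode emits one VCF 4.2 record per SV with the score in the
#' `SVFOREST` INFO field (`POS = start + 1`, `END = end`).
#'
#' @param svs An `sv_tbl`.
#' @param scores Numeric scores in `[0, 1]`, one per record.
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @export
write_scored_output <- function(svs, scores, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (length(scores) != nrow(svs))
    stopf("length mismatch: %d records but %d scores", nrow(svs),
          length(scores))
  if (format == "tsv") {
    out <- data.frame(chrom = svs$chrom, start = svs$start, end = svs$end,
                      svtype = svs$svtype, id = svs$id, score = scores)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    hdr <- c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
      "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
      "##INFO=<ID=SVFOREST,Number=1,Type=Float,Description=\"svforest pathogenicity score\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
    )
    body <- sprintf("%s\t%d\t%s\tN\t<%s>\t.\t.\tSVTYPE=%s;END=%d;SVFOREST=%s",
                    svs$chrom, as.integer(svs$start + 1), svs$id, svs$svtype,
                    svs$svtype, as.integer(svs$end),
                    format(scores, trim = TRUE, digits = 6))
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}
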