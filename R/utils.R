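# Internal helpers shared across modules.

#' Normalize chromosome names
#'
#' Strips or adds a `"chr"` prefix so that structural variants and annotation
#' resources from mixed sources can be compared on one naming scheme.
#'
#' @param x Character vector of chromosome names.
#' @param style `"strip"` removes a leading `"chr"`, `"chr"` ensures one.
#' @return Character vector of normalized names.
#' @export
#' @examples
#' normalize_chrom(c("chr1", "2", "chrX"))
#' normalize_chrom(c("1", "chr2"), style = "chr")
normalize_chrom <- function(x, style = c("strip", "chr")) {
  style <- match.arg(style)
  bare <- sub("^chr", "", as.character(x))
  if (style == "strip") bare else paste0("chr", bare)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# bp shared between [s1,e1) and [s2,e2); vectorized.
overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# GRanges from 0-based half-open columns.
granges_0h <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1, end = end))
}

# Merge adjacent intervals with equal values within one chromosome.
# df has columns start, end, value, sorted by start, non-overlapping.
merge_equal_runs <- function(df) {
  n <- nrow(df)
  if (n <= 1L) return(df)
  new_run <- c(TRUE, df$start[-1] != df$end[-n] | df$value[-1] != df$value[-n])
  run_end <- c(which(new_run)[-1] - 1L, n)
  data.frame(
    start = df$start[new_run],
    end = df$end[run_end],
    value = df$value[new_run],
    row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
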