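# evaluation: ROC/AUC with Hanley-McNeil standard errors, sensitivity
# thresholds, per-genome benign-elimination summaries, paired comparisons.
# Pathogenic is the positive class throughout; a score tied with a threshold
# counts as positive (score >= t), so the 3 Mb score of exactly 1.0 is
# always called pathogenic.

.as_positive <- function(labels) {
  labels <- as.character(labels)
  ok <- labels %in% c("pathogenic", "benign")
  if (!all(ok)) stopf("labels must be 'pathogenic' or 'benign'")
  labels == "pathogenic"
}

#' Hanley-McNeil standard error of an AUC
#'
#' `SE^2 = [A(1-A) + (n1-1)(Q1-A^2) + (n2-1)(Q2-A^2)] / (n1 n2)` with
#' `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#'
#' @param auc The AUC estimate `A`.
#' @param n1,n2 Numbers of positive and negative examples.
#' @return The standard error.
#' @export
hanley_mcneil_se <- function(auc, n1, n2) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
}

#' ROC curve and AUC with a Hanley-McNeil confidence interval
#'
#' Builds the ROC by a threshold sweep with tied scores grouped, computes
#' the AUC by the trapezoid rule (equal to the Mann-Whitney statistic with
#' 1/2 credit for ties), and a 95% CI as `A +/- 1.96 SE` clipped to `[0,1]`.
#'
#' @param scores Numeric scores (higher = more pathogenic).
#' @param labels `"pathogenic"`/`"benign"` per score; both must occur.
#' @return An `sv_eval` list: `roc` (data frame `threshold`, `fpr`, `tpr`),
#'   `auc`, `se`, `ci95`, `n1`, `n2`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- .as_positive(labels)
  if (!any(pos) || all(pos))
    stopf("roc_auc requires both pathogenic and benign labels")
  n1 <- sum(pos); n2 <- sum(!pos)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & pos), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & !pos), numeric(1))
  roc <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, fp / n2), tpr = c(0, tp / n1))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  se <- hanley_mcneil_se(auc, n1, n2)
  structure(list(roc = roc, auc = auc, se = se,
                 ci95 = c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se)),
                 n1 = n1, n2 = n2),
            class = "sv_eval")
}

#' @export
print.sv_eval <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f; Hanley-McNeil SE %.4f; n+=%d n-=%d)\n",
              x$auc, x$ci95[1], x$ci95[2], x$se, x$n1, x$n2))
  invisible(x)
}

#' Score threshold achieving a target sensitivity
#'
#' Returns the largest threshold `t` such that calling `score >= t`
#' pathogenic reaches at least the target sensitivity, along with the
#' achieved sensitivity and the resulting false-positive rate.
#'
#' @param scores Numeric scores.
#' @param labels `"pathogenic"`/`"benign"` per score.
#' @param target Target sensitivity in (0, 1], e.g. 0.9.
#' @return List `threshold`, `sensitivity`, `fpr`.
#' @export
sensitivity_threshold <- function(scores, labels, target = 0.9) {
  stopifnot(target > 0, target <= 1)
  pos <- .as_positive(labels)
  if (!any(pos)) stopf("no pathogenic records")
  cand <- sort(unique(scores[pos]), decreasing = TRUE)
  sens <- vapply(cand, function(t) mean(scores[pos] >= t), numeric(1))
  ok <- sens >= target
  if (!any(ok)) {
    warnf("target sensitivity %.2f unattainable; returning minimum score", target)
    t <- min(scores)
  } else {
    t <- cand[which(ok)[1]]  # largest threshold reaching the target
  }
  list(threshold = t,
       sensitivity = mean(scores[pos] >= t),
       fpr = if (any(!pos)) mean(scores[!pos] >= t) else NA_real_)
}

#' Per-genome fraction of SVs called benign
#'
#' For each genome, the fraction of its (putatively benign) SVs scoring
#' below the threshold — the fraction eliminated from consideration.
#'
#' @param genomes Named list: one numeric score vector per genome.
#' @param threshold Classification threshold (score >= threshold is called
#'   pathogenic).
#' @return List `fractions` (per genome) and `mean`; empty genomes are
#'   excluded with a warning.
#' @export
per_genome_elimination <- function(genomes, threshold) {
  empty <- vapply(genomes, function(g) length(g) == 0, logical(1))
  if (any(empty)) {
    warnf("excluding %d empty genome(s)", sum(empty))
    genomes <- genomes[!empty]
  }
  if (!length(genomes)) stopf("no non-empty genomes")
  fr <- vapply(genomes, function(g) mean(g < threshold), numeric(1))
  list(fractions = fr, mean = mean(fr))
}

#' Two-sided Wilcoxon signed-rank test on paired fractions
#'
#' Zero differences are dropped (the signed-rank convention); fully tied
#' input returns p = 1 with a warning.
#'
#' @param a,b Equal-length paired numeric vectors.
#' @return Two-sided p-value.
#' @export
paired_rank_test <- function(a, b) {
  if (length(a) != length(b)) stopf("paired samples must have equal length")
  if (length(a) < 2) stopf("paired test undefined for n < 2")
  if (all(a == b)) {
    warnf("all pairs tied; p = 1")
    return(1)
  }
  stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
}
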