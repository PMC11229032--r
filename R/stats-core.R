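#' Median fold change between two sample groups
#'
#' The toolkit's headline effect size: the median TPM of the tumor group
#' divided by the median TPM of the control group. A symmetric pseudocount
#' of 0.01 TPM is added to both medians so the ratio is defined and finite
#' when a group median is zero, and so that
#' \code{fold_change(a, b) * fold_change(b, a) == 1} holds.
#'
#' @param tumor_values,control_values Non-empty numeric vectors of TPM
#'   values (>= 0).
#' @param pseudocount Pseudocount added to both medians; default 0.01 TPM.
#' @return Strictly positive finite ratio.
#' @export
fold_change <- function(tumor_values, control_values, pseudocount = 0.01) {
  check_group(tumor_values, "tumor")
  check_group(control_values, "control")
  (stats::median(tumor_values) + pseudocount) /
    (stats::median(control_values) + pseudocount)
}

#' Log2 fold change as a difference of log-scale medians
#'
#' Computed as \eqn{median(\log_2(T+1)) - median(\log_2(C+1))}. Note this is
#' the difference of medians taken on the log scale, not the log of the
#' median ratio; the two differ for skewed distributions because the median
#' commutes with the monotone log transform per group but the pseudocount
#' ratio does not.
#'
#' @inheritParams fold_change
#' @return Signed difference; antisymmetric under swapping the groups.
#' @export
log2_fold_change <- function(tumor_values, control_values) {
  check_group(tumor_values, "tumor")
  check_group(control_values, "control")
  stats::median(log2(tumor_values + 1)) - stats::median(log2(control_values + 1))
}

check_group <- function(x, label) {
  if (length(x) == 0L)
    stop(label, " group is empty", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop(label, " group must contain finite non-negative values", call. = FALSE)
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups, the test behind every
#' differential call in the toolkit. Uses the exact null distribution when
#' the smaller group has at most \code{exact_limit} observations and the
#' pooled values are tie-free; otherwise the tie-corrected normal
#' approximation with continuity correction. Because the statistic depends
#' only on ranks, the p-value is invariant under any strictly increasing
#' transform of the pooled values (in particular, TPM vs log2(TPM+1)).
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact_limit Largest \code{min(length(a), length(b))} for which the
#'   exact distribution is used (tie-free data only). Default 8.
#' @return Two-sided p-value in (0, 1]. All pooled values identical gives 1.
#' @export
mwu_test <- function(a, b, exact_limit = 8L) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  if (any(!is.finite(pooled)))
    stop("groups must contain finite values", call. = FALSE)
  if (length(unique(pooled)) == 1L) return(1)
  has_ties <- anyDuplicated(pooled) > 0L
  use_exact <- !has_ties && min(length(a), length(b)) <= exact_limit
  res <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  min(res$p.value, 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, clipped at 1 and returned in the
#' input order. Differential calls throughout the package use the
#' conventional threshold of 0.05 on these adjusted values.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
adjust_pvalues <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0L))
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Summarise one sample group's expression of a gene
#'
#' @param label Group label.
#' @param tpm_values Numeric TPM vector (may be empty; then \code{n = 0} and
#'   medians are \code{NA}).
#' @return One-row data.frame: \code{group}, \code{n}, \code{median_tpm}
#'   and \code{median_log} (median of log2(TPM+1), computed on the log
#'   scale, not the log of the TPM median).
#' @export
group_summary <- function(label, tpm_values) {
  n <- length(tpm_values)
  data.frame(group = label, n = n,
             median_tpm = if (n) stats::median(tpm_values) else NA_real_,
             median_log = if (n) stats::median(log2(tpm_values + 1)) else NA_real_,
             stringsAsFactors = FALSE)
}
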