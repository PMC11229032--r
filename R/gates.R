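#' Configuration for logic-gate feasibility calls
#'
#' Thresholds for the expression-level classifier of dual-antigen CAR
#' gates. A gene counts as "on" in a sample at \code{tau_on} TPM or above,
#' and as "absent" below \code{tau_off} TPM. A gate needs at least
#' \code{c_min} tumor coverage, and any normal tissue may carry at most
#' \code{s_max} co-coverage before it is flagged unsafe. The defaults are
#' deliberately conservative and every threshold is exposed, because the
#' decision of when a gate "can be applied" is otherwise made by eye.
#'
#' @param tau_on Activation threshold in TPM (default 10).
#' @param tau_off Absence threshold in TPM (default 1); must be < tau_on.
#' @param c_min Minimum tumor coverage fraction (default 0.8).
#' @param s_max Maximum normal-tissue co-coverage fraction (default 0.05);
#'   must be < c_min.
#' @return An object of class \code{gate_config}.
#' @export
gate_config <- function(tau_on = 10, tau_off = 1, c_min = 0.8, s_max = 0.05) {
  if (!(tau_off < tau_on))
    stop("tau_off must be smaller than tau_on", call. = FALSE)
  if (!(c_min > 0 && c_min <= 1))
    stop("c_min must lie in (0, 1]", call. = FALSE)
  if (!(s_max >= 0 && s_max < c_min))
    stop("s_max must lie in [0, c_min)", call. = FALSE)
  structure(list(tau_on = tau_on, tau_off = tau_off,
                 c_min = c_min, s_max = s_max), class = "gate_config")
}

#' Paired expression and correlation of two genes in a cohort
#'
#' Collects per-sample expression of two candidate antigens in the primary
#' tumor and control groups and computes Pearson and Spearman correlations
#' per group on the log2(TPM+1) scale (Pearson on raw TPM is dominated by
#' high-expression outliers; Spearman is rank-based either way). A gene
#' that is constant within a group has no defined correlation there; it is
#' reported as \code{NA}, never coerced to a number.
#'
#' @param gene_a,gene_b Gene symbols.
#' @param cohort A [build_cohort()] result.
#' @return List of class \code{gate_pair_profile}: \code{$pairs} (columns
#'   \code{sample_id}, \code{group}, \code{a_tpm}, \code{b_tpm},
#'   \code{a_log}, \code{b_log}) and \code{$correlations} (per group,
#'   \code{pearson_r} and \code{spearman_r}).
#' @export
pair_correlation <- function(gene_a, gene_b, cohort) {
  stopifnot(inherits(cohort, "cohort"))
  groups <- c("primary_tumor", "control")
  pairs <- do.call(rbind, lapply(groups, function(g) {
    ids <- cohort$samples[[g]]
    if (length(ids) == 0L)
      stop("cohort has no ", g, " samples", call. = FALSE)
    a <- cohort_values(cohort, gene_a, g)
    b <- cohort_values(cohort, gene_b, g)
    data.frame(sample_id = ids, group = g, a_tpm = unname(a),
               b_tpm = unname(b), a_log = log2(unname(a) + 1),
               b_log = log2(unname(b) + 1), stringsAsFactors = FALSE)
  }))
  cors <- do.call(rbind, lapply(groups, function(g) {
    sub <- pairs[pairs$group == g, ]
    safe_cor <- function(method) {
      if (stats::sd(sub$a_log) == 0 || stats::sd(sub$b_log) == 0)
        return(NA_real_)
      stats::cor(sub$a_log, sub$b_log, method = method)
    }
    data.frame(group = g, pearson_r = safe_cor("pearson"),
               spearman_r = safe_cor("spearman"), stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- rownames(cors) <- NULL
  structure(list(gene_a = gene_a, gene_b = gene_b,
                 pairs = pairs, correlations = cors),
            class = "gate_pair_profile")
}

#' @export
print.gate_pair_profile <- function(x, ...) {
  cat(sprintf("paired expression %s / %s (%d samples)\n",
              x$gene_a, x$gene_b, nrow(x$pairs)))
  print(x$correlations)
  invisible(x)
}

frac_at_least <- function(x, tau) mean(x >= tau)

#' Expression-level feasibility of dual-antigen logic gates
#'
#' Classifies the four dual-antigen gating strategies for a gene pair by
#' expression coverage. All fractions are per-sample counts on linear TPM
#' against the [gate_config()] thresholds:
#' \itemize{
#'   \item \strong{AND} (kill only when both antigens present): tumor
#'     fraction with both genes >= tau_on must reach c_min, and in every
#'     normal tissue the both-on fraction must stay <= s_max.
#'   \item \strong{OR} (either antigen suffices): tumor either-on fraction
#'     >= c_min, and every tissue's either-on fraction <= s_max.
#'   \item \strong{NOT} (gene_a activates, gene_b vetoes): tumor fraction
#'     with gene_a on and gene_b below tau_off >= c_min; any tissue where
#'     gene_a's on-fraction exceeds s_max must be protected by the veto,
#'     i.e. its gene_b >= tau_off fraction must reach 1 - s_max.
#'   \item \strong{IF-BETTER} (gene_a primary, gene_b co-stimulation):
#'     applies when AND failed only for lack of tumor co-coverage — the
#'     tissue-safety half of AND holds, gene_a alone covers >= c_min of
#'     tumor samples, and gene_b still co-occurs in at least c_min/2.
#' }
#' AND and OR verdicts are symmetric in the gene pair; NOT and IF-BETTER
#' read gene_a as the activating antigen.
#'
#' @param gene_a,gene_b Gene symbols.
#' @param cohort A [build_cohort()] result (tumor group = primary tumor).
#' @param gtex_m Healthy-tissue [expr_matrix()] containing both genes.
#' @param annotations Annotation data.frame with the \code{gtex_normal}
#'   samples of \code{gtex_m}.
#' @param config A [gate_config()].
#' @return List of class \code{gate_verdicts}: \code{$verdicts} (per gate,
#'   \code{viable} plus its supporting fractions), \code{$tumor} (tumor
#'   coverage fractions), \code{$tissues} (per-tissue fractions) and
#'   \code{$config}.
#' @export
gate_feasibility <- function(gene_a, gene_b, cohort, gtex_m, annotations,
                             config = gate_config()) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "gate_config"))
  gtex_m <- convert_scale(gtex_m, "tpm")
  for (g in c(gene_a, gene_b))
    if (!g %in% genes(gtex_m))
      stop("no tissue expression table for gene '", g, "'", call. = FALSE)
  a_t <- cohort_values(cohort, gene_a, "primary_tumor")
  b_t <- cohort_values(cohort, gene_b, "primary_tumor")
  cfg <- config

  tumor <- data.frame(
    both_on = mean(a_t >= cfg$tau_on & b_t >= cfg$tau_on),
    either_on = mean(a_t >= cfg$tau_on | b_t >= cfg$tau_on),
    a_on = frac_at_least(a_t, cfg$tau_on),
    b_on = frac_at_least(b_t, cfg$tau_on),
    a_on_b_absent = mean(a_t >= cfg$tau_on & b_t < cfg$tau_off))

  ann <- annotations[annotations$sample_class == "gtex_normal" &
                       annotations$sample_id %in% samples(gtex_m), ]
  if (nrow(ann) == 0L)
    stop("no annotated healthy-tissue samples found", call. = FALSE)
  tissues <- sort(unique(ann$cohort_code))
  tissue_tab <- do.call(rbind, lapply(tissues, function(ts) {
    ids <- ann$sample_id[ann$cohort_code == ts]
    a <- gtex_m$values[gene_a, ids]
    b <- gtex_m$values[gene_b, ids]
    data.frame(tissue = ts, n = length(ids),
               both_on = mean(a >= cfg$tau_on & b >= cfg$tau_on),
               either_on = mean(a >= cfg$tau_on | b >= cfg$tau_on),
               a_on = frac_at_least(a, cfg$tau_on),
               b_on = frac_at_least(b, cfg$tau_on),
               b_above_off = frac_at_least(b, cfg$tau_off),
               stringsAsFactors = FALSE)
  }))
  rownames(tissue_tab) <- NULL

  and_tumor_ok <- tumor$both_on >= cfg$c_min
  and_tissue_ok <- all(tissue_tab$both_on <= cfg$s_max)
  or_tumor_ok <- tumor$either_on >= cfg$c_min
  or_tissue_ok <- all(tissue_tab$either_on <= cfg$s_max)
  not_tumor_ok <- tumor$a_on_b_absent >= cfg$c_min
  exposed <- tissue_tab$a_on > cfg$s_max
  not_tissue_ok <- all(tissue_tab$b_above_off[exposed] >= 1 - cfg$s_max)
  ifb_ok <- !and_tumor_ok && and_tissue_ok &&
    tumor$a_on >= cfg$c_min && tumor$both_on >= cfg$c_min / 2

  verdicts <- data.frame(
    gate = c("AND", "OR", "NOT", "IF_BETTER"),
    viable = c(and_tumor_ok && and_tissue_ok,
               or_tumor_ok && or_tissue_ok,
               not_tumor_ok && not_tissue_ok,
               ifb_ok),
    tumor_coverage = c(tumor$both_on, tumor$either_on,
                       tumor$a_on_b_absent, tumor$a_on),
    worst_tissue_fraction = c(max(tissue_tab$both_on),
                              max(tissue_tab$either_on),
                              if (any(exposed))
                                min(tissue_tab$b_above_off[exposed]) else NA_real_,
                              max(tissue_tab$both_on)),
    stringsAsFactors = FALSE)

  structure(list(gene_a = gene_a, gene_b = gene_b, verdicts = verdicts,
                 tumor = tumor, tissues = tissue_tab, config = cfg),
            class = "gate_verdicts")
}

#' @export
print.gate_verdicts <- function(x, ...) {
  cat(sprintf("logic-gate feasibility %s (activating) / %s\n",
              x$gene_a, x$gene_b))
  print(x$verdicts)
  invisible(x)
}
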