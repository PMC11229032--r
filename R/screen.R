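#' Screen a cohort for tumor-associated antigens
#'
#' The primary discovery tool: for every gene of the tested universe
#' (typically the plasma-membrane surfaceome), computes the median fold
#' change, the log2 fold change, and a two-sided Mann-Whitney p-value of
#' primary tumor versus control samples, adjusts the p-values by
#' Benjamini-Hochberg over the \emph{whole} tested universe, and reports
#' the genes that are significant (adjusted p < 0.05) and pass the fold
#' change threshold in the requested direction. \code{direction = "over"}
#' keeps FC >= \code{fc_threshold} (CAR target candidates);
#' \code{direction = "under"} keeps FC <= 1/\code{fc_threshold} (candidates
#' for NOT-gate veto antigens), so a single threshold slider serves both.
#'
#' @param cohort A [build_cohort()] result.
#' @param gene_universe Optional [gene_set()] (or character vector)
#'   restricting the tested universe; default tests every gene in the
#'   cohort matrix.
#' @param fc_threshold Fold-change threshold, > 1.
#' @param direction \code{"over"} or \code{"under"}.
#' @return A data.frame sorted by decreasing |log2fc| (ties broken by gene
#'   symbol) with columns \code{gene}, group sizes and medians, \code{fc},
#'   \code{log2fc}, \code{p_value}, \code{adj_p}, \code{significant}, and
#'   volcano coordinates \code{volcano_x} (= log2fc) and \code{volcano_y}
#'   (= -log10 adjusted p, with adj_p floored at 1e-300). Attribute
#'   \code{"n_tested"} records the adjustment-universe size.
#' @export
screen_taa <- function(cohort, gene_universe = NULL, fc_threshold = 2,
                       direction = c("over", "under")) {
  direction <- match.arg(direction)
  stopifnot(inherits(cohort, "cohort"))
  if (!is.numeric(fc_threshold) || fc_threshold <= 1)
    stop("fc_threshold must be > 1", call. = FALSE)
  if (length(cohort$samples$primary_tumor) < 2L ||
      length(cohort$samples$control) < 2L)
    stop("screen requires at least 2 samples in each group", call. = FALSE)
  expr <- cohort$expr
  if (!is.null(gene_universe)) expr <- filter_gene_set(expr, gene_universe)
  tab <- differential_table(expr,
                            cohort$samples$primary_tumor,
                            cohort$samples$control)
  tab$adj_p <- adjust_pvalues(tab$p_value)
  tab$significant <- tab$adj_p < 0.05
  keep <- tab$significant & (if (direction == "over") tab$fc >= fc_threshold
                             else tab$fc <= 1 / fc_threshold)
  out <- tab[keep, , drop = FALSE]
  out$volcano_x <- out$log2fc
  out$volcano_y <- -log10(pmax(out$adj_p, 1e-300))
  out <- out[order(-abs(out$log2fc), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- nrow(tab)
  out
}

# Per-gene medians, fold changes and Mann-Whitney p-values of group A
# (tumor) versus group B (control) over every gene of a TPM matrix.
differential_table <- function(expr, ids_a, ids_b) {
  stopifnot(inherits(expr, "expr_matrix"), expr$scale == "tpm")
  A <- expr$values[, ids_a, drop = FALSE]
  B <- expr$values[, ids_b, drop = FALSE]
  med_a <- apply(A, 1L, stats::median)
  med_b <- apply(B, 1L, stats::median)
  medlog_a <- apply(log2(A + 1), 1L, stats::median)
  medlog_b <- apply(log2(B + 1), 1L, stats::median)
  p <- vapply(seq_len(nrow(A)), function(i) mwu_test(A[i, ], B[i, ]),
              numeric(1L))
  data.frame(gene = rownames(A),
             n_tumor = ncol(A), n_control = ncol(B),
             median_tpm_tumor = med_a, median_tpm_control = med_b,
             median_log_tumor = medlog_a, median_log_control = medlog_b,
             fc = (med_a + 0.01) / (med_b + 0.01),
             log2fc = medlog_a - medlog_b,
             p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fold change of candidate genes across tumors
#'
#' Tabulates, for each requested gene, its tumor-versus-control fold change
#' in every requested cohort, for judging whether a candidate is selective
#' for one tumor type or usable across several.
#'
#' @param genes_wanted Character vector of gene symbols.
#' @param cohorts Named list of [build_cohort()] results (names = tumor
#'   codes).
#' @param scale \code{"fc"} for the median TPM ratio, \code{"log2fc"} for
#'   the difference of log-scale medians.
#' @return data.frame, one row per gene, one column per tumor code.
#' @export
fc_table <- function(genes_wanted, cohorts, scale = c("fc", "log2fc")) {
  scale <- match.arg(scale)
  stopifnot(is.list(cohorts), length(cohorts) > 0L)
  if (is.null(names(cohorts)))
    names(cohorts) <- vapply(cohorts, `[[`, character(1L), "tumor_code")
  missing_genes <- unique(unlist(lapply(cohorts, function(co)
    setdiff(genes_wanted, genes(co$expr)))))
  if (length(missing_genes))
    stop("gene(s) absent from cohort matrices: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  cells <- sapply(names(cohorts), function(code) {
    co <- cohorts[[code]]
    vapply(genes_wanted, function(g) {
      tv <- cohort_values(co, g, "primary_tumor")
      cv <- cohort_values(co, g, "control")
      if (scale == "fc") fold_change(tv, cv) else log2_fold_change(tv, cv)
    }, numeric(1L))
  })
  cells <- matrix(cells, nrow = length(genes_wanted),
                  dimnames = list(NULL, names(cohorts)))
  cbind(data.frame(gene = genes_wanted, stringsAsFactors = FALSE),
        as.data.frame(cells))
}

#' Median expression profile of a gene across cohorts
#'
#' For each cohort, reports sample count and median expression (TPM and
#' log2(TPM+1)) of the gene in primary tumor, metastatic (omitted when the
#' cohort has none) and control samples — the at-a-glance view of which
#' tumors overexpress a candidate and how much expression the pooled
#' control tissue carries.
#'
#' @param gene Gene symbol.
#' @param cohorts Named list of [build_cohort()] results.
#' @return data.frame with columns \code{tumor_code}, \code{group},
#'   \code{n}, \code{median_tpm}, \code{median_log}.
#' @export
median_profile <- function(gene, cohorts) {
  stopifnot(is.list(cohorts), length(cohorts) > 0L)
  if (is.null(names(cohorts)))
    names(cohorts) <- vapply(cohorts, `[[`, character(1L), "tumor_code")
  rows <- lapply(names(cohorts), function(code) {
    co <- cohorts[[code]]
    classes <- c("primary_tumor", "metastatic", "control")
    part <- lapply(classes, function(cl) {
      ids <- co$samples[[cl]]
      if (length(ids) == 0L) return(NULL)
      group_summary(cl, cohort_values(co, gene, cl))
    })
    out <- do.call(rbind, part)
    cbind(data.frame(tumor_code = code, stringsAsFactors = FALSE), out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expression of a gene across healthy tissues, with optional tumor contrast
#'
#' Summarises a gene's expression in every tissue of a healthy-tissue
#' (GTEx-shaped) matrix. When a tumor cohort is supplied, each tissue is
#' additionally tested against the cohort's primary tumor samples
#' (Mann-Whitney, Benjamini-Hochberg across the tissues of this call) and
#' the log2 fold change is reported as tumor minus tissue — the off-tumor
#' toxicity check: tissues where a candidate target is high flag organs a
#' CAR against it would attack.
#'
#' @param gene Gene symbol.
#' @param gtex_m Healthy-tissue [expr_matrix()] (any scale; converted to
#'   TPM internally).
#' @param annotations Annotation data.frame containing the
#'   \code{gtex_normal} samples of \code{gtex_m}.
#' @param cohort Optional [build_cohort()] result providing the tumor group.
#' @return data.frame with one row per tissue (tumor row first when a
#'   cohort is given): \code{group}, \code{n}, \code{median_tpm},
#'   \code{median_log}, and — only with a cohort — \code{log2fc},
#'   \code{p_value}, \code{adj_p}, \code{significant}.
#' @export
tissue_expression <- function(gene, gtex_m, annotations, cohort = NULL) {
  stopifnot(inherits(gtex_m, "expr_matrix"))
  gtex_m <- convert_scale(gtex_m, "tpm")
  if (!gene %in% genes(gtex_m))
    stop("gene '", gene, "' not present in tissue matrix", call. = FALSE)
  ann <- annotations[annotations$sample_class == "gtex_normal" &
                       annotations$sample_id %in% samples(gtex_m), ]
  if (nrow(ann) == 0L)
    stop("no annotated healthy-tissue samples found", call. = FALSE)
  tissues <- sort(unique(ann$cohort_code))
  per_tissue <- lapply(tissues, function(ts) {
    ids <- ann$sample_id[ann$cohort_code == ts]
    list(summary = group_summary(ts, gtex_m$values[gene, ids]),
         values = gtex_m$values[gene, ids])
  })
  tab <- do.call(rbind, lapply(per_tissue, `[[`, "summary"))
  if (is.null(cohort)) {
    rownames(tab) <- NULL
    return(tab)
  }
  tumor_vals <- cohort_values(cohort, gene, "primary_tumor")
  tab$log2fc <- vapply(per_tissue, function(pt)
    log2_fold_change(tumor_vals, pt$values), numeric(1L))
  tab$p_value <- vapply(per_tissue, function(pt)
    mwu_test(tumor_vals, pt$values), numeric(1L))
  tab$adj_p <- adjust_pvalues(tab$p_value)
  tab$significant <- tab$adj_p < 0.05
  tumor_row <- group_summary(paste0(cohort$tumor_code, "_primary_tumor"),
                             tumor_vals)
  tumor_row$log2fc <- NA_real_
  tumor_row$p_value <- NA_real_
  tumor_row$adj_p <- NA_real_
  tumor_row$significant <- NA
  out <- rbind(tumor_row, tab)
  rownames(out) <- NULL
  out
}

#' Three-group comparison for cohorts with metastatic samples
#'
#' Melanoma (SKCM) is the one TCGA cohort with enough metastatic samples
#' for inference, and this tool serves it: all three pairwise Mann-Whitney
#' tests between metastatic, primary tumor and control samples of a gene,
#' Benjamini-Hochberg adjusted over the three p-values, alongside per-group
#' summaries.
#'
#' @param gene Gene symbol.
#' @param cohort A [build_cohort()] result whose three classes are all
#'   non-empty.
#' @return List of class \code{three_group_comparison}: \code{$summary}
#'   (one row per class) and \code{$tests} (one row per pair with
#'   \code{log2fc} = first group minus second, \code{p_value},
#'   \code{adj_p}, \code{significant}).
#' @export
skcm_compare <- function(gene, cohort) {
  stopifnot(inherits(cohort, "cohort"))
  classes <- c("metastatic", "primary_tumor", "control")
  for (cl in classes)
    if (length(cohort$samples[[cl]]) == 0L)
      stop("cohort ", cohort$tumor_code, " has no ", cl, " samples",
           call. = FALSE)
  vals <- lapply(classes, function(cl) cohort_values(cohort, gene, cl))
  names(vals) <- classes
  summary <- do.call(rbind, lapply(classes, function(cl)
    group_summary(cl, vals[[cl]])))
  pairs <- list(c("metastatic", "primary_tumor"),
                c("metastatic", "control"),
                c("primary_tumor", "control"))
  tests <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(group_a = p[1L], group_b = p[2L],
               log2fc = log2_fold_change(vals[[p[1L]]], vals[[p[2L]]]),
               p_value = mwu_test(vals[[p[1L]]], vals[[p[2L]]]),
               stringsAsFactors = FALSE)
  }))
  tests$adj_p <- adjust_pvalues(tests$p_value)
  tests$significant <- tests$adj_p < 0.05
  rownames(summary) <- rownames(tests) <- NULL
  structure(list(gene = gene, summary = summary, tests = tests),
            class = "three_group_comparison")
}

#' @export
print.three_group_comparison <- function(x, ...) {
  cat("three-group comparison for", x$gene, "\n")
  print(x$summary)
  print(x$tests)
  invisible(x)
}
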