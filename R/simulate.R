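#' Specify a synthetic tumor/control cohort
#'
#' Describes one TCGA/GTEx-shaped cohort for the synthetic generator:
#' group sizes, number of genes, within-group noise, and a set of planted
#' signals. Expression is drawn on the log2(TPM+1) scale — each gene gets a
#' baseline drawn uniformly from \code{baseline_range} (the default 0-8
#' spans roughly 0-255 TPM, the dynamic range the screening tools
#' exercise), each planted (gene, group) pair is shifted by log2 of its
#' fold change, Gaussian noise of standard deviation \code{sigma} is added
#' per sample, and the result is decoded to TPM (clamped at zero).
#'
#' @param tumor_code Cohort label, default \code{"SIM"}.
#' @param n_primary,n_metastatic,n_adjacent_normal Group sizes.
#' @param tissues Named integer vector: control tissue name -> sample count.
#' @param n_genes Number of genes (named \code{G0001}, \code{G0002}, ...).
#' @param planted Optional data.frame with columns \code{gene} (name or
#'   index), \code{target} (\code{"primary_tumor"}, \code{"metastatic"} or
#'   a tissue name) and \code{fc} (> 0); each entry multiplies the gene's
#'   TPM+1 level in that group by \code{fc}.
#' @param sigma Log2-scale noise standard deviation, default 0.25.
#' @param baseline_range Range of per-gene baseline log2(TPM+1) means.
#' @param seed RNG seed (mandatory; generation is reproducible).
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(tumor_code = "SIM", n_primary = 40L,
                        n_metastatic = 0L, n_adjacent_normal = 10L,
                        tissues = c(TissueA = 30L), n_genes = 200L,
                        planted = NULL, sigma = 0.25,
                        baseline_range = c(0, 8), seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("a numeric seed is mandatory", call. = FALSE)
  sizes <- c(n_primary, n_metastatic, n_adjacent_normal, tissues)
  if (any(sizes < 0L)) stop("group sizes must be >= 0", call. = FALSE)
  if (n_primary < 1L) stop("need at least one primary tumor sample", call. = FALSE)
  if (length(tissues) && is.null(names(tissues)))
    stop("tissues must be a named vector", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  gene_names <- sprintf("G%04d", seq_len(n_genes))
  if (!is.null(planted)) {
    planted <- as.data.frame(planted, stringsAsFactors = FALSE)
    stopifnot(all(c("gene", "target", "fc") %in% colnames(planted)))
    if (is.numeric(planted$gene)) {
      if (any(planted$gene < 1L | planted$gene > n_genes))
        stop("planted gene index out of range", call. = FALSE)
      planted$gene <- gene_names[planted$gene]
    }
    if (!all(planted$gene %in% gene_names))
      stop("planted gene name outside the generated genes", call. = FALSE)
    valid_targets <- c("primary_tumor", "metastatic", names(tissues))
    if (!all(planted$target %in% valid_targets))
      stop("planted target must be a sample class or a declared tissue",
           call. = FALSE)
    if (any(planted$fc <= 0)) stop("planted fold changes must be > 0",
                                   call. = FALSE)
  }
  structure(list(tumor_code = tumor_code, n_primary = as.integer(n_primary),
                 n_metastatic = as.integer(n_metastatic),
                 n_adjacent_normal = as.integer(n_adjacent_normal),
                 tissues = tissues, n_genes = as.integer(n_genes),
                 gene_names = gene_names, planted = planted, sigma = sigma,
                 baseline_range = baseline_range, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic tumor/control cohort
#'
#' Draws the cohort described by a [cohort_spec()] and returns everything
#' the analysis stack consumes: the TPM expression matrix over all samples,
#' per-sample annotations in the TCGA/GTEx shape, a one-entry cohort map,
#' a gene set covering all genes (standing in for the surfaceome
#' restriction), and the ground-truth table of planted effects. The same
#' seed always yields identical output.
#'
#' @param spec A [cohort_spec()].
#' @return List with elements \code{expr} ([expr_matrix()], TPM),
#'   \code{annotations}, \code{cmap}, \code{gene_set} and \code{truth}
#'   (columns \code{gene}, \code{target}, \code{fc},
#'   \code{baseline_log2}).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c(list(primary_tumor = spec$n_primary,
                   metastatic = spec$n_metastatic,
                   adjacent_normal = spec$n_adjacent_normal),
              as.list(spec$tissues))
  group_is_tissue <- c(rep(FALSE, 3L), rep(TRUE, length(spec$tissues)))
  names(group_is_tissue) <- names(groups)

  with_seed(spec$seed, {
    baseline <- stats::runif(spec$n_genes, spec$baseline_range[1L],
                             spec$baseline_range[2L])
    shift <- matrix(0, nrow = spec$n_genes, ncol = length(groups),
                    dimnames = list(spec$gene_names, names(groups)))
    if (!is.null(spec$planted))
      for (k in seq_len(nrow(spec$planted)))
        shift[spec$planted$gene[k], spec$planted$target[k]] <-
          shift[spec$planted$gene[k], spec$planted$target[k]] +
          log2(spec$planted$fc[k])

    blocks <- list()
    ann <- list()
    for (g in names(groups)) {
      n <- groups[[g]]
      if (n == 0L) next
      ids <- if (group_is_tissue[[g]])
        sprintf("GTEX-%s-%04d", gsub("[^A-Za-z0-9]", "", g), seq_len(n))
      else
        sprintf("%s-%s-%04d", spec$tumor_code,
                c(primary_tumor = "T", metastatic = "M",
                  adjacent_normal = "N")[[g]], seq_len(n))
      noise <- matrix(stats::rnorm(spec$n_genes * n, 0, spec$sigma),
                      nrow = spec$n_genes)
      vals <- pmax(2^(baseline + shift[, g] + noise) - 1, 0)
      dimnames(vals) <- list(spec$gene_names, ids)
      blocks[[g]] <- vals
      ann[[g]] <- data.frame(
        sample_id = ids,
        source_project = if (group_is_tissue[[g]]) "GTEX" else "TCGA",
        cohort_code = if (group_is_tissue[[g]]) g else spec$tumor_code,
        sample_class = if (group_is_tissue[[g]]) "gtex_normal" else g,
        stringsAsFactors = FALSE)
    }
    expr <- expr_matrix(do.call(cbind, blocks), "tpm")
    annotations <- do.call(rbind, ann)
    rownames(annotations) <- NULL
    truth <- if (is.null(spec$planted))
      data.frame(gene = character(0L), target = character(0L),
                 fc = numeric(0L), baseline_log2 = numeric(0L),
                 stringsAsFactors = FALSE)
    else
      data.frame(gene = spec$planted$gene, target = spec$planted$target,
                 fc = spec$planted$fc,
                 baseline_log2 = baseline[match(spec$planted$gene,
                                                spec$gene_names)],
                 stringsAsFactors = FALSE)
    list(expr = expr,
         annotations = annotations,
         cmap = cohort_map(stats::setNames(list(names(spec$tissues)),
                                           spec$tumor_code)),
         gene_set = gene_set(spec$gene_names, name = "simulated_surfaceome"),
         truth = truth)
  })
}

#' Assemble the analysis cohort of a simulated dataset
#'
#' Convenience wrapper: splits a [simulate_cohort()] result into its TCGA
#' and GTEx matrices and runs [build_cohort()] on them.
#'
#' @param sim A [simulate_cohort()] result.
#' @return A [build_cohort()] cohort.
#' @export
simulated_cohort <- function(sim) {
  tcga_ids <- sim$annotations$sample_id[sim$annotations$source_project == "TCGA"]
  gtex_ids <- sim$annotations$sample_id[sim$annotations$source_project == "GTEX"]
  tcga_m <- expr_matrix(sim$expr$values[, tcga_ids, drop = FALSE], "tpm")
  gtex_m <- expr_matrix(sim$expr$values[, gtex_ids, drop = FALSE], "tpm")
  build_cohort(names(sim$cmap)[1L], tcga_m, gtex_m, sim$annotations, sim$cmap)
}

#' Generate a synthetic cancer cell line panel
#'
#' Produces a cell line expression matrix plus metadata table in the DepMap
#' model-table shape. Unplanted (gene, line) values follow the same
#' log-normal model as [simulate_cohort()]; planted entries set the exact
#' TPM level of one gene in one cell line, for building validation panels
#' with known high/medium/low expressors.
#'
#' @param n_lines Number of cell lines.
#' @param lineages Character vector of lineages, recycled across lines.
#' @param n_genes Number of background genes (named \code{G0001}, ...).
#' @param planted Optional data.frame with columns \code{gene},
#'   \code{line} (cell line name) and \code{tpm}; planted genes not among
#'   the background genes are appended to the matrix.
#' @param sigma,baseline_range As in [cohort_spec()].
#' @param seed RNG seed (mandatory).
#' @param line_names Optional explicit cell line names (default
#'   \code{CL001}, ...); duplicates are an error.
#' @return List with \code{expr} ([expr_matrix()], TPM, columns = model
#'   ids) and \code{models} (data.frame as [load_cellline_models()]).
#' @export
simulate_celllines <- function(n_lines, lineages = "Bowel", n_genes = 25L,
                               planted = NULL, sigma = 0.25,
                               baseline_range = c(0, 8), seed,
                               line_names = NULL) {
  if (missing(seed) || !is.numeric(seed))
    stop("a numeric seed is mandatory", call. = FALSE)
  if (n_lines < 0L) stop("n_lines must be >= 0", call. = FALSE)
  if (is.null(line_names)) line_names <- sprintf("CL%03d", seq_len(n_lines))
  if (length(line_names) != n_lines)
    stop("line_names length must equal n_lines", call. = FALSE)
  if (anyDuplicated(line_names))
    stop("duplicate cell line names", call. = FALSE)
  gene_names <- sprintf("G%04d", seq_len(n_genes))
  if (!is.null(planted)) {
    planted <- as.data.frame(planted, stringsAsFactors = FALSE)
    stopifnot(all(c("gene", "line", "tpm") %in% colnames(planted)))
    if (!all(planted$line %in% line_names))
      stop("planted cell line not among the generated lines", call. = FALSE)
    if (any(planted$tpm < 0)) stop("planted TPM must be >= 0", call. = FALSE)
    gene_names <- union(gene_names, planted$gene)
  }
  model_ids <- sprintf("ACH-%06d", seq_len(n_lines))
  lineage_col <- if (n_lines) rep_len(lineages, n_lines) else character(0L)
  models <- data.frame(model_id = model_ids, cell_line_name = line_names,
                       lineage = lineage_col,
                       primary_disease = if (n_lines)
                         paste(lineage_col, "Cancer") else character(0L),
                       subtype = rep_len("Adenocarcinoma", n_lines),
                       catalog_number = sprintf("CAT-%04d", seq_len(n_lines)),
                       stringsAsFactors = FALSE)
  with_seed(seed, {
    baseline <- stats::runif(length(gene_names), baseline_range[1L],
                             baseline_range[2L])
    vals <- matrix(0, nrow = length(gene_names), ncol = n_lines,
                   dimnames = list(gene_names, model_ids))
    if (n_lines > 0L) {
      noise <- matrix(stats::rnorm(length(gene_names) * n_lines, 0, sigma),
                      nrow = length(gene_names))
      vals[] <- pmax(2^(baseline + noise) - 1, 0)
    }
    if (!is.null(planted))
      for (k in seq_len(nrow(planted)))
        vals[planted$gene[k],
             model_ids[match(planted$line[k], line_names)]] <- planted$tpm[k]
    list(expr = expr_matrix(vals, "tpm"), models = models)
  })
}

#' Write a simulated cohort as the TSV dialects the loaders read
#'
#' Emits \code{tcga_expression.tsv}, \code{gtex_expression.tsv},
#' \code{tcga_phenotype.tsv}, \code{gtex_phenotype.tsv},
#' \code{cohort_map.tsv}, \code{gene_set.txt} and \code{truth.tsv} into a
#' directory, exactly as [load_expression()], [load_phenotype()],
#' [load_cohort_map()] and [load_gene_set()] expect them.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ann <- sim$annotations
  tcga <- ann[ann$source_project == "TCGA", ]
  gtex <- ann[ann$source_project == "GTEX", ]
  paths <- c(
    tcga_expr = file.path(dir, "tcga_expression.tsv"),
    gtex_expr = file.path(dir, "gtex_expression.tsv"),
    tcga_pheno = file.path(dir, "tcga_phenotype.tsv"),
    gtex_pheno = file.path(dir, "gtex_phenotype.tsv"),
    cmap = file.path(dir, "cohort_map.tsv"),
    gene_set = file.path(dir, "gene_set.txt"),
    truth = file.path(dir, "truth.tsv"))
  write_expression(expr_matrix(sim$expr$values[, tcga$sample_id, drop = FALSE],
                               "tpm"), paths[["tcga_expr"]])
  write_expression(expr_matrix(sim$expr$values[, gtex$sample_id, drop = FALSE],
                               "tpm"), paths[["gtex_expr"]])
  type_of <- c(primary_tumor = "Primary Tumor", metastatic = "Metastatic",
               adjacent_normal = "Solid Tissue Normal")
  write_result_tsv(data.frame(sample = tcga$sample_id,
                              sample_type = unname(type_of[tcga$sample_class]),
                              cohort = tcga$cohort_code,
                              stringsAsFactors = FALSE),
                   paths[["tcga_pheno"]])
  write_result_tsv(data.frame(sample = gtex$sample_id,
                              tissue = gtex$cohort_code,
                              stringsAsFactors = FALSE),
                   paths[["gtex_pheno"]])
  map_lines <- vapply(names(sim$cmap), function(code)
    paste0(code, "\t", paste(sim$cmap[[code]], collapse = ",")),
    character(1L))
  writeLines(map_lines, paths[["cmap"]])
  writeLines(sim$gene_set$symbols, paths[["gene_set"]])
  write_result_tsv(sim$truth, paths[["truth"]])
  invisible(paths)
}

#' Write a simulated cell line panel as loader-ready TSVs
#'
#' Emits \code{cellline_expression.tsv} and \code{cellline_models.tsv}.
#'
#' @param sim A [simulate_celllines()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cellline_fixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expr = file.path(dir, "cellline_expression.tsv"),
             models = file.path(dir, "cellline_models.tsv"))
  write_expression(sim$expr, paths[["expr"]])
  write_result_tsv(sim$models, paths[["models"]])
  invisible(paths)
}
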