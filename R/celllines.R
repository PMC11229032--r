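#' Load a cancer cell line model table
#'
#' Reads tab-separated cell line metadata in the DepMap model-table shape.
#' Columns \code{model_id}, \code{cell_line_name}, \code{lineage},
#' \code{primary_disease}, \code{subtype} and \code{catalog_number} are
#' expected; the DepMap release headers (\code{ModelID},
#' \code{CellLineName}, \code{OncotreeLineage}, \code{OncotreePrimaryDisease},
#' \code{OncotreeSubtype}, \code{CatalogNumber}) are accepted as aliases.
#'
#' @param path Path to the TSV file.
#' @return data.frame with the six canonical columns.
#' @export
load_cellline_models <- function(path) {
  if (!file.exists(path)) stop("model table not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = "character")
  aliases <- list(model_id = c("model_id", "ModelID"),
                  cell_line_name = c("cell_line_name", "CellLineName"),
                  lineage = c("lineage", "OncotreeLineage"),
                  primary_disease = c("primary_disease",
                                      "OncotreePrimaryDisease"),
                  subtype = c("subtype", "OncotreeSubtype"),
                  catalog_number = c("catalog_number", "CatalogNumber"))
  out <- lapply(names(aliases), function(canon) {
    hit <- intersect(aliases[[canon]], colnames(dt))
    if (length(hit) == 0L)
      stop("model table ", path, " lacks required column '", canon, "'",
           call. = FALSE)
    dt[[hit[1L]]]
  })
  names(out) <- names(aliases)
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (anyDuplicated(out$model_id))
    stop("duplicate model ids in ", path, call. = FALSE)
  out
}

#' Select cancer cell lines by target expression
#'
#' Filters a cell line expression matrix to the lines whose expression of a
#' candidate gene passes a TPM threshold, optionally within one lineage —
#' the step that turns a candidate target into a wet-lab validation panel
#' (high/medium/low expressors for CAR activation and cytotoxicity assays,
#' or low expressors as negative controls). \code{direction = "above"}
#' keeps expression >= threshold and \code{"below"} keeps expression <
#' threshold, so the two directions partition the considered lines.
#'
#' @param gene Gene symbol.
#' @param expr [expr_matrix()] of cell line expression, columns = model ids
#'   (any scale; DepMap expression ships as log2(TPM+1) — declare it and it
#'   is converted).
#' @param models Model table from [load_cellline_models()].
#' @param lineage Optional lineage restriction (must exist in the table).
#' @param threshold TPM threshold, >= 0.
#' @param direction \code{"above"} or \code{"below"}.
#' @return data.frame sorted by decreasing \code{expression_tpm} (ties by
#'   cell line name): \code{cell_line_name}, \code{lineage},
#'   \code{primary_disease}, \code{subtype}, \code{catalog_number},
#'   \code{expression_tpm}, \code{gene}.
#' @export
select_cell_lines <- function(gene, expr, models, lineage = NULL,
                              threshold = 0, direction = c("above", "below")) {
  direction <- match.arg(direction)
  stopifnot(inherits(expr, "expr_matrix"), is.data.frame(models))
  if (!is.numeric(threshold) || threshold < 0)
    stop("threshold must be a non-negative TPM value", call. = FALSE)
  expr <- convert_scale(expr, "tpm")
  if (!gene %in% genes(expr))
    stop("gene '", gene, "' not present in the cell line matrix",
         call. = FALSE)
  tab <- models[models$model_id %in% samples(expr), , drop = FALSE]
  if (!is.null(lineage)) {
    if (!lineage %in% models$lineage)
      stop("unknown lineage '", lineage, "'", call. = FALSE)
    tab <- tab[tab$lineage == lineage, , drop = FALSE]
  }
  tab$expression_tpm <- unname(expr$values[gene, tab$model_id])
  keep <- if (direction == "above") tab$expression_tpm >= threshold
          else tab$expression_tpm < threshold
  out <- tab[keep, , drop = FALSE]
  out <- out[order(-out$expression_tpm, out$cell_line_name), , drop = FALSE]
  out$gene <- rep_len(gene, nrow(out))
  out <- out[, c("cell_line_name", "lineage", "primary_disease", "subtype",
                 "catalog_number", "expression_tpm", "gene")]
  rownames(out) <- NULL
  out
}
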