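#' Supported expression scales
#'
#' Expression matrices carry a scale tag so that every downstream statistic
#' can insist on the scale it needs. Three encodings occur in the supported
#' file dialects:
#' \describe{
#'   \item{\code{"tpm"}}{linear transcripts per million, values >= 0.}
#'   \item{\code{"log2_tpm_plus1"}}{\eqn{\log_2(TPM + 1)}, the display scale
#'     used throughout the toolkit.}
#'   \item{\code{"xena_log2_tpm"}}{\eqn{\log_2(TPM + 0.001)}, the encoding of
#'     the UCSC Xena RSEM expression files (\code{tcga_RSEM_gene_tpm},
#'     \code{gtex_RSEM_gene_tpm}).}
#' }
#'
#' @return Character vector of valid scale tags.
#' @export
expr_scales <- function() c("tpm", "log2_tpm_plus1", "xena_log2_tpm")

norm_scale <- function(scale) {
  if (length(scale) != 1L || !is.character(scale))
    stop("scale tag must be a single string", call. = FALSE)
  aliases <- c(tpm = "tpm", log = "log2_tpm_plus1", xena = "xena_log2_tpm")
  s <- if (scale %in% names(aliases)) unname(aliases[[scale]]) else scale
  if (!s %in% expr_scales())
    stop("unknown expression scale tag: '", scale, "' (expected one of ",
         paste(expr_scales(), collapse = ", "), ")", call. = FALSE)
  s
}

#' Construct an expression matrix
#'
#' A thin container for a gene-by-sample numeric matrix plus its scale tag.
#' Row names are gene identifiers (Ensembl IDs or symbols), column names are
#' sample identifiers; both must be unique and all values finite. Values on
#' the TPM scale must be non-negative.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique dimnames.
#' @param scale One of [expr_scales()] (aliases: \code{"log"}, \code{"xena"}).
#' @return An object of class \code{expr_matrix}.
#' @export
expr_matrix <- function(values, scale = "tpm") {
  scale <- norm_scale(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(samples) && ncol(values) == 0L) samples <- character(0L)
  if (is.null(genes) && nrow(values) == 0L) genes <- character(0L)
  if (is.null(genes) || is.null(samples))
    stop("values must carry gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must all be finite", call. = FALSE)
  if (scale == "tpm" && any(values < 0))
    stop("TPM values must be non-negative", call. = FALSE)
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [scale: %s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene identifiers of an expression matrix
#' @param m An \code{expr_matrix}.
#' @return Character vector of gene identifiers.
#' @export
genes <- function(m) rownames(m$values)

#' Sample identifiers of an expression matrix
#' @param m An \code{expr_matrix}.
#' @return Character vector of sample identifiers.
#' @export
samples <- function(m) colnames(m$values)

#' Load a gene-by-sample expression matrix from TSV
#'
#' Reads a tab-separated expression table in the Xena RSEM layout: the first
#' column holds gene identifiers and every remaining column is one sample.
#' The caller declares the encoding of the stored numbers via \code{scale};
#' the loader performs no transformation (see [convert_scale()]).
#'
#' Duplicate sample columns are rejected. Duplicate gene rows are resolved
#' by keeping the row with the highest total expression across samples (the
#' dominant-transcript rule, applied on the linear TPM scale); the number of
#' rows dropped this way is recorded in attribute \code{"dropped_duplicates"}.
#'
#' @param path Path to the TSV file.
#' @param scale Declared scale of the stored values, one of [expr_scales()].
#' @return An [expr_matrix()].
#' @export
load_expression <- function(path, scale = "tpm") {
  scale <- norm_scale(scale)
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE,
                          colClasses = list(character = 1L))
  if (ncol(dt) < 2L)
    stop("malformed header in ", path,
         ": need a gene column plus at least one sample column", call. = FALSE)
  sample_ids <- colnames(dt)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample columns in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  gene_ids <- dt[[1L]]
  val_cols <- dt[, -1L, with = FALSE]
  for (j in seq_along(val_cols)) {
    col <- val_cols[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop("non-numeric expression value in ", path, " at row ", bad[1L],
             ", column '", sample_ids[j], "': '", col[bad[1L]], "'",
             call. = FALSE)
      val_cols[[j]] <- num
    }
  }
  m <- as.matrix(val_cols)
  rownames(m) <- gene_ids
  dropped <- 0L
  if (anyDuplicated(gene_ids)) {
    keep <- resolve_duplicate_genes(m, scale)
    dropped <- nrow(m) - length(keep)
    m <- m[keep, , drop = FALSE]
  }
  out <- expr_matrix(m, scale)
  attr(out, "dropped_duplicates") <- dropped
  out
}

# Pick, for each duplicated gene id, the row with the highest total
# expression on the linear scale. Returns row indices in original order.
resolve_duplicate_genes <- function(m, scale) {
  lin <- switch(scale,
                tpm = m,
                log2_tpm_plus1 = 2^m - 1,
                xena_log2_tpm = pmax(2^m - 0.001, 0))
  totals <- rowSums(lin)
  ids <- rownames(m)
  keep <- vapply(split(seq_along(ids), ids), function(idx) {
    idx[which.max(totals[idx])]
  }, integer(1L))
  sort(unname(keep))
}

#' Convert an expression matrix between scales
#'
#' Elementwise re-encoding between linear TPM, \eqn{\log_2(TPM+1)} and the
#' Xena \eqn{\log_2(TPM+0.001)} encoding. Decoding from the Xena scale clamps
#' at zero, since \eqn{2^x - 0.001} can fall slightly below zero for the
#' sentinel value that encodes zero expression. Round-tripping TPM through
#' the log scale recovers the input to within floating-point accuracy.
#'
#' @param m An [expr_matrix()].
#' @param target Target scale, one of [expr_scales()].
#' @return An [expr_matrix()] on the target scale.
#' @export
convert_scale <- function(m, target) {
  stopifnot(inherits(m, "expr_matrix"))
  target <- norm_scale(target)
  if (m$scale == target) return(m)
  tpm <- switch(m$scale,
                tpm = m$values,
                log2_tpm_plus1 = 2^m$values - 1,
                xena_log2_tpm = pmax(2^m$values - 0.001, 0))
  # guard against tiny negatives from floating point on the log2(x+1) path
  tpm[tpm < 0 & tpm > -1e-12] <- 0
  out <- switch(target,
                tpm = tpm,
                log2_tpm_plus1 = log2(tpm + 1),
                xena_log2_tpm = log2(tpm + 0.001))
  expr_matrix(out, target)
}

#' Re-key gene identifiers to symbols
#'
#' Replaces the gene axis of a matrix (typically Ensembl IDs) with gene
#' symbols via a caller-supplied mapping. Genes without a mapping are
#' dropped; the count is recorded in attribute \code{"dropped_unmapped"}.
#' When several input genes map to one symbol, the row with the highest
#' total linear expression is kept (attribute \code{"dropped_collisions"}).
#'
#' @param m An [expr_matrix()].
#' @param mapping Named character vector, names = current gene ids,
#'   values = symbols.
#' @return An [expr_matrix()] keyed by symbols.
#' @export
map_gene_ids <- function(m, mapping) {
  stopifnot(inherits(m, "expr_matrix"))
  if (length(mapping) == 0L || is.null(names(mapping)))
    stop("gene id mapping is empty", call. = FALSE)
  ids <- genes(m)
  hit <- ids %in% names(mapping)
  if (!any(hit))
    stop("gene id mapping covers none of the matrix genes", call. = FALSE)
  vals <- m$values[hit, , drop = FALSE]
  rownames(vals) <- unname(mapping[ids[hit]])
  collisions <- 0L
  if (anyDuplicated(rownames(vals))) {
    keep <- resolve_duplicate_genes(vals, m$scale)
    collisions <- nrow(vals) - length(keep)
    vals <- vals[keep, , drop = FALSE]
  }
  out <- expr_matrix(vals, m$scale)
  attr(out, "dropped_unmapped") <- sum(!hit)
  attr(out, "dropped_collisions") <- collisions
  out
}

#' Restrict an expression matrix to a gene set
#'
#' Keeps only the rows whose symbol belongs to the gene set (for CAR work,
#' the plasma-membrane surfaceome), preserving the matrix's row order. An
#' empty intersection is an error: a screen over zero genes is vacuous.
#'
#' @param m An [expr_matrix()] keyed by gene symbols.
#' @param gene_set A [gene_set()] or character vector of symbols.
#' @return The restricted [expr_matrix()].
#' @export
filter_gene_set <- function(m, gene_set) {
  stopifnot(inherits(m, "expr_matrix"))
  symbols <- if (inherits(gene_set, "gene_set")) gene_set$symbols else
    as.character(gene_set)
  keep <- genes(m) %in% symbols
  if (!any(keep))
    stop("gene set shares no genes with the expression matrix", call. = FALSE)
  expr_matrix(m$values[keep, , drop = FALSE], m$scale)
}

#' Construct a named gene set
#'
#' @param symbols Character vector of gene symbols (must be non-empty;
#'   duplicates are removed).
#' @param name Label for the set, e.g. \code{"plasma_membrane_GO_0005886"}.
#' @return An object of class \code{gene_set}.
#' @export
gene_set <- function(symbols, name = "gene_set") {
  symbols <- unique(as.character(symbols))
  symbols <- symbols[nzchar(symbols)]
  if (length(symbols) == 0L) stop("gene set is empty", call. = FALSE)
  structure(list(name = name, symbols = symbols), class = "gene_set")
}

#' Read a gene set from a one-symbol-per-line file
#'
#' Lines starting with \code{#} are comments; blank lines are ignored.
#'
#' @param path File path.
#' @param name Label for the set; defaults to the file name.
#' @return A [gene_set()].
#' @export
load_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) stop("gene set file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_set(lines, name = name)
}
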