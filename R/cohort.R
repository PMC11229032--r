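#' Sample classes recognised by the toolkit
#'
#' @return Character vector of the sample-class labels used in annotations.
#' @export
sample_classes <- function()
  c("primary_tumor", "metastatic", "adjacent_normal", "gtex_normal", "cell_line")

# TCGA sample_type strings -> sample_class. Anything else is skipped.
tcga_sample_type_class <- function(sample_type) {
  out <- rep(NA_character_, length(sample_type))
  out[startsWith(sample_type, "Primary")] <- "primary_tumor"
  out[sample_type == "Metastatic"] <- "metastatic"
  out[sample_type == "Solid Tissue Normal"] <- "adjacent_normal"
  out
}

#' Load a sample phenotype table
#'
#' Parses a tab-separated phenotype file in one of two dialects and returns
#' one annotation row per usable sample.
#'
#' \strong{TCGA dialect}: columns \code{sample}, \code{sample_type} and a
#' cohort column (\code{cohort}, \code{primary_disease} or
#' \code{_primary_disease}). Sample types are mapped to classes as:
#' \code{"Primary *"} (including primary blood-derived cancers) to
#' \code{primary_tumor}, \code{"Metastatic"} to \code{metastatic},
#' \code{"Solid Tissue Normal"} to \code{adjacent_normal}. Rows with any
#' other sample type (recurrent tumors, ...) are skipped; the skipped count
#' is recorded in attribute \code{"skipped"}.
#'
#' \strong{GTEX dialect}: columns \code{sample} and \code{tissue} (or
#' \code{_primary_site}); every row becomes class \code{gtex_normal} with
#' the tissue as its cohort code.
#'
#' @param path Path to the TSV file.
#' @param dialect \code{"TCGA"} or \code{"GTEX"}.
#' @return A data.frame with columns \code{sample_id},
#'   \code{source_project}, \code{cohort_code}, \code{sample_class}.
#' @export
load_phenotype <- function(path, dialect = c("TCGA", "GTEX")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("phenotype file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = "character")
  need_col <- function(options) {
    hit <- intersect(options, colnames(dt))
    if (length(hit) == 0L)
      stop("phenotype file ", path, " lacks required column '", options[1L],
           "'", call. = FALSE)
    hit[1L]
  }
  if (dialect == "TCGA") {
    s_col <- need_col("sample")
    t_col <- need_col("sample_type")
    c_col <- need_col(c("cohort", "primary_disease", "_primary_disease"))
    cls <- tcga_sample_type_class(dt[[t_col]])
    skipped <- sum(is.na(cls))
    keep <- !is.na(cls)
    ann <- data.frame(sample_id = dt[[s_col]][keep],
                      source_project = "TCGA",
                      cohort_code = dt[[c_col]][keep],
                      sample_class = cls[keep],
                      stringsAsFactors = FALSE)
  } else {
    s_col <- need_col("sample")
    t_col <- need_col(c("tissue", "_primary_site"))
    skipped <- 0L
    ann <- data.frame(sample_id = dt[[s_col]],
                      source_project = "GTEX",
                      cohort_code = dt[[t_col]],
                      sample_class = "gtex_normal",
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample ids in phenotype file ", path, call. = FALSE)
  attr(ann, "skipped") <- skipped
  ann
}

#' Construct a tumor-to-control-tissue map
#'
#' Assigns, for each tumor cohort code, the set of healthy-tissue names
#' whose samples are pooled with the tumor's adjacent normals to form the
#' control group. An empty tissue set is allowed and means adjacent normals
#' only.
#'
#' @param entries Named list; names are tumor codes, values character
#'   vectors of tissue names (possibly empty).
#' @return An object of class \code{cohort_map}.
#' @export
cohort_map <- function(entries) {
  if (!is.list(entries) || is.null(names(entries)) ||
      any(!nzchar(names(entries))))
    stop("cohort map must be a named list of tissue vectors", call. = FALSE)
  if (anyDuplicated(names(entries)))
    stop("duplicate tumor codes in cohort map", call. = FALSE)
  entries <- lapply(entries, as.character)
  structure(entries, class = "cohort_map")
}

#' Read a tumor-to-tissue map from TSV
#'
#' Two tab-separated columns: tumor code and a comma-separated tissue list
#' (second column may be empty). Lines starting with \code{#} are comments.
#' A default map covering the 33 TCGA tumor codes ships with the package:
#' \code{system.file("extdata", "cohort_map_default.tsv", package =
#' "cartarget")}. That file is an editable transcription of the usual
#' TCGA-to-GTEx tissue pairing and should be reviewed before production use.
#'
#' @param path File path.
#' @return A [cohort_map()].
#' @export
load_cohort_map <- function(path) {
  if (!file.exists(path)) stop("cohort map file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  codes <- vapply(parts, `[`, character(1L), 1L)
  tissues <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(trimws(p[2L]))) return(character(0L))
    trimws(strsplit(p[2L], ",", fixed = TRUE)[[1L]])
  })
  names(tissues) <- codes
  cohort_map(tissues)
}

#' Assemble an analysis cohort for one tumor
#'
#' Pools, for the requested tumor code, the TCGA primary-tumor samples, any
#' metastatic samples, and the control group (TCGA adjacent normals plus
#' the GTEx samples of the tissues the cohort map assigns to this tumor)
#' into one merged expression matrix restricted to the genes shared by both
#' sources. The merged matrix is always converted to linear TPM so every
#' downstream statistic starts from the same scale.
#'
#' @param tumor_code Tumor cohort code, e.g. \code{"COAD"}.
#' @param tcga_m,gtex_m [expr_matrix()] objects on the same scale, keyed by
#'   gene symbols.
#' @param annotations Annotation data.frame covering both sources (rows as
#'   returned by [load_phenotype()], concatenated).
#' @param cmap A [cohort_map()].
#' @return An object of class \code{cohort}: list with \code{tumor_code},
#'   \code{expr} (merged TPM matrix) and \code{samples}, a list of sample id
#'   vectors \code{primary_tumor}, \code{metastatic}, \code{control} (plus
#'   the control breakdown \code{adjacent_normal}, \code{gtex_normal}).
#' @export
build_cohort <- function(tumor_code, tcga_m, gtex_m, annotations, cmap) {
  stopifnot(inherits(tcga_m, "expr_matrix"), inherits(gtex_m, "expr_matrix"),
            inherits(cmap, "cohort_map"))
  if (tcga_m$scale != gtex_m$scale)
    stop("TCGA and GTEx matrices are on different scales (",
         tcga_m$scale, " vs ", gtex_m$scale, ")", call. = FALSE)
  if (!tumor_code %in% names(cmap))
    stop("tumor code '", tumor_code, "' absent from cohort map", call. = FALSE)
  tissues <- cmap[[tumor_code]]
  gtex_ann <- annotations[annotations$sample_class == "gtex_normal", ]
  missing_tissue <- setdiff(tissues, unique(gtex_ann$cohort_code))
  if (length(missing_tissue))
    stop("cohort map tissue(s) not present in GTEx annotation: ",
         paste(missing_tissue, collapse = ", "), call. = FALSE)

  in_tcga <- annotations$sample_id %in% samples(tcga_m)
  pick <- function(class) {
    annotations$sample_id[in_tcga &
                            annotations$cohort_code == tumor_code &
                            annotations$sample_class == class]
  }
  primary <- pick("primary_tumor")
  metastatic <- pick("metastatic")
  adjacent <- pick("adjacent_normal")
  gtex_ctrl <- gtex_ann$sample_id[gtex_ann$cohort_code %in% tissues &
                                    gtex_ann$sample_id %in% samples(gtex_m)]
  control <- c(adjacent, gtex_ctrl)
  if (length(primary) == 0L)
    stop("no primary tumor samples found for ", tumor_code, call. = FALSE)
  if (length(control) == 0L)
    stop("no control samples found for ", tumor_code,
         " (no adjacent normals and no mapped GTEx tissue samples)",
         call. = FALSE)

  shared <- intersect(genes(tcga_m), genes(gtex_m))
  if (length(shared) == 0L)
    stop("TCGA and GTEx matrices share no genes", call. = FALSE)
  tcga_cols <- c(primary, metastatic, adjacent)
  merged <- cbind(tcga_m$values[shared, tcga_cols, drop = FALSE],
                  gtex_m$values[shared, gtex_ctrl, drop = FALSE])
  expr <- convert_scale(expr_matrix(merged, tcga_m$scale), "tpm")
  structure(list(tumor_code = tumor_code,
                 expr = expr,
                 samples = list(primary_tumor = primary,
                                metastatic = metastatic,
                                control = control,
                                adjacent_normal = adjacent,
                                gtex_normal = gtex_ctrl)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort %s: %d genes; %d primary / %d metastatic / %d control\n",
              x$tumor_code, nrow(x$expr$values),
              length(x$samples$primary_tumor), length(x$samples$metastatic),
              length(x$samples$control)))
  invisible(x)
}

# TPM values of one gene for one sample group of a cohort.
cohort_values <- function(cohort, gene, group) {
  stopifnot(inherits(cohort, "cohort"))
  if (!gene %in% genes(cohort$expr))
    stop("gene '", gene, "' not present in cohort matrix", call. = FALSE)
  ids <- cohort$samples[[group]]
  cohort$expr$values[gene, ids]
}
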