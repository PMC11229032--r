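# Shared fixture builders; everything is generated in code at test time.

# Build a cohort from an explicit gene x sample TPM matrix. Sample ids
# prefixed T* are primary tumors, M* metastatic, N* adjacent normals and
# X* GTEx samples of `tissue`.
toy_cohort <- function(tpm, tissue = "Colon", code = "COAD") {
  ids <- colnames(tpm)
  cls <- ifelse(startsWith(ids, "T"), "primary_tumor",
         ifelse(startsWith(ids, "M"), "metastatic",
         ifelse(startsWith(ids, "N"), "adjacent_normal", "gtex_normal")))
  ann <- data.frame(
    sample_id = ids,
    source_project = ifelse(cls == "gtex_normal", "GTEX", "TCGA"),
    cohort_code = ifelse(cls == "gtex_normal", tissue, code),
    sample_class = cls, stringsAsFactors = FALSE)
  is_gtex <- cls == "gtex_normal"
  tcga_m <- expr_matrix(tpm[, !is_gtex, drop = FALSE], "tpm")
  gtex_m <- expr_matrix(tpm[, is_gtex, drop = FALSE], "tpm")
  cmap <- cohort_map(stats::setNames(list(tissue), code))
  list(cohort = build_cohort(code, tcga_m, gtex_m, ann, cmap),
       ann = ann, tcga_m = tcga_m, gtex_m = gtex_m, cmap = cmap)
}

# Random non-negative TPM matrix with dimnames.
random_tpm <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(round(rexp(n_genes * n_samples, rate = 0.02), 3),
              nrow = n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%03d", seq_len(n_samples))))
  m
}

# Build one simulated dataset on disk for exercising the CLI subcommands.
cli_fixture <- function(dir, seed = 101) {
  spec <- cohort_spec(n_genes = 60L, n_primary = 20L, n_metastatic = 15L,
                      n_adjacent_normal = 5L, tissues = c(TissueA = 15L),
                      planted = data.frame(gene = 1:2,
                                           target = "primary_tumor", fc = 16),
                      seed = seed)
  sim <- simulate_cohort(spec)
  paths <- write_cohort_fixture(sim, dir)
  cl <- simulate_celllines(4, n_genes = 8L,
                           planted = data.frame(gene = "G0001",
                                                line = c("CL001", "CL002"),
                                                tpm = c(900, 50)),
                           seed = seed + 1)
  c(paths, write_cellline_fixture(cl, dir), sim = list(sim))
}

common_flags <- function(fx) {
  c("--expr", fx[["tcga_expr"]], "--pheno", fx[["tcga_pheno"]],
    "--gtex-expr", fx[["gtex_expr"]], "--gtex-pheno", fx[["gtex_pheno"]],
    "--map", fx[["cmap"]])
}

# Standard planted-signal study conditions used across screen tests.
planted_spec <- function(seed, n_genes = 6000L, n_planted = 3L, fc = 16) {
  cohort_spec(n_genes = n_genes,
              n_primary = 40L, n_adjacent_normal = 10L,
              tissues = c(TissueA = 30L),
              planted = data.frame(gene = seq_len(n_planted),
                                   target = "primary_tumor", fc = fc),
              sigma = 0.25, seed = seed)
}
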