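test_that("load_expression round-trips a small TSV and tags the scale", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "A\t0\t1", "B\t2\t0", "C\t1\t2"), path)
  m <- load_expression(path, "tpm")
  expect_s3_class(m, "expr_matrix")
  expect_identical(m$scale, "tpm")
  expect_identical(genes(m), c("A", "B", "C"))
  expect_identical(samples(m), c("S1", "S2"))
  expect_equal(m$values["B", "S1"], 2)
})

test_that("loader rejects duplicate sample columns and bad cells", {
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS1", "A\t1\t2"), dup)
  expect_error(load_expression(dup, "tpm"), "duplicate sample")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "A\t1\toops"), bad)
  expect_error(load_expression(bad, "tpm"), "non-numeric.*S2")
})

test_that("duplicate gene rows resolve to the highest-expression row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "A\t1\t1", "A\t5\t5", "B\t3\t3"), path)
  m <- load_expression(path, "tpm")
  expect_identical(genes(m), c("A", "B"))
  expect_equal(unname(m$values["A", ]), c(5, 5))
  expect_identical(attr(m, "dropped_duplicates"), 1L)
})

test_that("Xena-encoded values decode to TPM, clamped at zero", {
  vals <- matrix(c(-9.9658, 3, 0), nrow = 3,
                 dimnames = list(c("A", "B", "C"), "S1"))
  m <- convert_scale(expr_matrix(vals, "xena"), "tpm")
  expect_equal(m$values["A", "S1"], 0, tolerance = 1e-3)
  expect_gte(m$values["A", "S1"], 0)
  expect_equal(m$values["B", "S1"], 2^3 - 0.001)
})

test_that("TPM to log2(TPM+1) hits the textbook anchor points", {
  vals <- matrix(c(0, 1, 7), nrow = 3,
                 dimnames = list(c("A", "B", "C"), "S1"))
  m <- convert_scale(expr_matrix(vals, "tpm"), "log")
  expect_equal(unname(m$values[, "S1"]), c(0, 1, 3))
  expect_error(convert_scale(m, "parts_per_billion"), "unknown")
})

test_that("scale conversion round-trips random matrices", {
  for (seed in 1:5) {
    tpm <- random_tpm(30, 8, seed = seed)
    m <- expr_matrix(tpm, "tpm")
    back <- convert_scale(convert_scale(m, "log"), "tpm")
    expect_equal(back$values, tpm, tolerance = 1e-9)
    via_xena <- convert_scale(convert_scale(m, "xena"), "tpm")
    expect_equal(via_xena$values, tpm, tolerance = 1e-9)
  }
})

test_that("phenotype dialects map sample types to classes", {
  tcga <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tsample_type\tcohort",
               "S1\tPrimary Tumor\tCOAD",
               "S2\tSolid Tissue Normal\tCOAD",
               "S3\tMetastatic\tSKCM",
               "S4\tPrimary Blood Derived Cancer - Peripheral Blood\tLAML",
               "S5\tRecurrent Tumor\tCOAD"), tcga)
  ann <- load_phenotype(tcga, "TCGA")
  expect_identical(ann$sample_class,
                   c("primary_tumor", "adjacent_normal", "metastatic",
                     "primary_tumor"))
  expect_identical(attr(ann, "skipped"), 1L)
  expect_true(all(ann$source_project == "TCGA"))

  gtex <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\ttissue", "G1\tColon", "G2\tLung"), gtex)
  gann <- load_phenotype(gtex, "GTEX")
  expect_identical(gann$sample_class, c("gtex_normal", "gtex_normal"))
  expect_identical(gann$cohort_code, c("Colon", "Lung"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tfoo", "S1\tx"), bad)
  expect_error(load_phenotype(bad, "TCGA"), "sample_type")
})

test_that("map_gene_ids relabels, resolves collisions, drops unmapped", {
  tpm <- matrix(c(1, 1, 10, 10, 3, 3), nrow = 3, byrow = TRUE,
                dimnames = list(c("ENSG1", "ENSG2", "ENSG3"), c("S1", "S2")))
  m <- expr_matrix(tpm, "tpm")
  one <- map_gene_ids(m, c(ENSG1 = "CEACAM6", ENSG2 = "CEACAM6",
                           ENSG3 = "DPEP1"))
  expect_identical(genes(one), c("CEACAM6", "DPEP1"))
  expect_equal(unname(one$values["CEACAM6", ]), c(10, 10))
  expect_identical(attr(one, "dropped_collisions"), 1L)

  partial <- map_gene_ids(m, c(ENSG1 = "A"))
  expect_identical(attr(partial, "dropped_unmapped"), 2L)
  expect_error(map_gene_ids(m, c(ENSGX = "A")), "covers none")
  expect_error(map_gene_ids(m, character(0)), "empty")
})

test_that("filter_gene_set restricts rows, preserves order, rejects empties", {
  tpm <- random_tpm(5, 2)
  m <- expr_matrix(tpm, "tpm")
  sub <- filter_gene_set(m, gene_set(c("G004", "G002")))
  expect_identical(genes(sub), c("G002", "G004"))
  expect_identical(filter_gene_set(m, gene_set(genes(m)))$values, m$values)
  expect_error(filter_gene_set(m, gene_set("ZZZ")), "no genes")
})

test_that("gene-set filter and symbol mapping commute", {
  tpm <- random_tpm(6, 3)
  m <- expr_matrix(tpm, "tpm")
  mapping <- stats::setNames(paste0("SYM", 1:6), genes(m))
  gs <- gene_set(c("SYM2", "SYM5"))
  a <- filter_gene_set(map_gene_ids(m, mapping), gs)
  b <- map_gene_ids(filter_gene_set(m, names(mapping)[c(2, 5)]), mapping)
  expect_identical(a$values, b$values)
})

test_that("build_cohort pools adjacent normals with mapped GTEx tissue", {
  tpm <- random_tpm(4, 6, seed = 3)
  colnames(tpm) <- c("T1", "T2", "T3", "N1", "X1", "X2")
  fx <- toy_cohort(tpm)
  co <- fx$cohort
  expect_length(co$samples$control, 3L)
  expect_setequal(co$samples$control, c("N1", "X1", "X2"))
  expect_length(co$samples$primary_tumor, 3L)

  # sample sets partition the merged matrix columns
  all_ids <- unlist(co$samples[c("primary_tumor", "metastatic", "control")])
  expect_setequal(all_ids, samples(co$expr))
  expect_identical(anyDuplicated(all_ids), 0L)
})

test_that("cohort with an empty tissue set uses adjacent normals only", {
  tpm <- random_tpm(3, 4, seed = 4)
  colnames(tpm) <- c("T1", "T2", "N1", "X1")
  ids <- colnames(tpm)
  ann <- data.frame(sample_id = ids,
                    source_project = c("TCGA", "TCGA", "TCGA", "GTEX"),
                    cohort_code = c("COAD", "COAD", "COAD", "Colon"),
                    sample_class = c("primary_tumor", "primary_tumor",
                                     "adjacent_normal", "gtex_normal"),
                    stringsAsFactors = FALSE)
  tcga_m <- expr_matrix(tpm[, 1:3], "tpm")
  gtex_m <- expr_matrix(tpm[, 4, drop = FALSE], "tpm")
  co <- build_cohort("COAD", tcga_m, gtex_m, ann,
                     cohort_map(list(COAD = character(0))))
  expect_identical(co$samples$control, "N1")
  expect_error(build_cohort("LUAD", tcga_m, gtex_m, ann,
                            cohort_map(list(COAD = character(0)))),
               "absent from cohort map")
  expect_error(build_cohort("COAD", tcga_m, gtex_m, ann,
                            cohort_map(list(COAD = "Lung"))),
               "not present in GTEx annotation")
})

test_that("cohort map and gene set files parse with comments", {
  mapf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "COAD\tColon,Small Intestine", "HNSC\t"), mapf)
  cmap <- load_cohort_map(mapf)
  expect_identical(cmap$COAD, c("Colon", "Small Intestine"))
  expect_identical(cmap$HNSC, character(0))

  default <- load_cohort_map(system.file("extdata", "cohort_map_default.tsv",
                                         package = "cartarget"))
  expect_identical(default$COAD, "Colon")
  expect_length(default, 33L)

  gsf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# surfaceome", "CEACAM6", "", "DPEP1"), gsf)
  gs <- load_gene_set(gsf)
  expect_identical(gs$symbols, c("CEACAM6", "DPEP1"))
})
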