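test_that("screen recovers exactly the planted genes on a 200-gene cohort", {
  spec <- planted_spec(seed = 7, n_genes = 200L)
  sim <- simulate_cohort(spec)
  co <- simulated_cohort(sim)
  tab <- screen_taa(co, sim$gene_set, fc_threshold = 15, direction = "over")
  expect_setequal(tab$gene, sim$truth$gene)
  expect_true(all(tab$significant))
  expect_true(all(tab$fc >= 15))
  expect_identical(attr(tab, "n_tested"), 200L)
  # sorted by decreasing |log2fc|
  expect_identical(order(-abs(tab$log2fc), tab$gene), seq_len(nrow(tab)))
})

test_that("screen output equals a brute-force per-gene recomputation", {
  spec <- planted_spec(seed = 9, n_genes = 100L, n_planted = 4L, fc = 8)
  sim <- simulate_cohort(spec)
  co <- simulated_cohort(sim)
  tab <- screen_taa(co, fc_threshold = 4, direction = "over")

  tv <- co$expr$values[, co$samples$primary_tumor, drop = FALSE]
  cv <- co$expr$values[, co$samples$control, drop = FALSE]
  g_all <- genes(co$expr)
  fc <- vapply(g_all, function(g) fold_change(tv[g, ], cv[g, ]), numeric(1))
  lfc <- vapply(g_all, function(g) log2_fold_change(tv[g, ], cv[g, ]),
                numeric(1))
  p <- vapply(g_all, function(g) mwu_test(tv[g, ], cv[g, ]), numeric(1))
  adj <- adjust_pvalues(p)
  keep <- adj < 0.05 & fc >= 4
  ord <- order(-abs(lfc[keep]), g_all[keep])
  expect_identical(tab$gene, g_all[keep][ord])
  expect_equal(tab$fc, unname(fc[keep][ord]))
  expect_equal(tab$log2fc, unname(lfc[keep][ord]))
  expect_equal(tab$p_value, unname(p[keep][ord]))
  expect_equal(tab$adj_p, unname(adj[keep][ord]))
})

test_that("adjustment universe is the full filtered gene set", {
  spec <- planted_spec(seed = 13, n_genes = 120L)
  sim <- simulate_cohort(spec)
  co <- simulated_cohort(sim)
  full <- screen_taa(co, fc_threshold = 15)
  expect_identical(attr(full, "n_tested"), 120L)
  sub <- gene_set(sprintf("G%04d", 1:50))
  part <- screen_taa(co, sub, fc_threshold = 15)
  expect_identical(attr(part, "n_tested"), 50L)
  # shrinking the adjustment universe changes the adjusted p-values
  shared <- intersect(full$gene, part$gene)
  expect_true(length(shared) > 0)
  ratio <- part$adj_p[match(shared, part$gene)] /
    full$adj_p[match(shared, full$gene)]
  expect_equal(ratio, rep(50 / 120, length(shared)), tolerance = 1e-9)
  expect_error(screen_taa(co, gene_set("NOPE"), fc_threshold = 2), "no genes")
  expect_error(screen_taa(co, fc_threshold = 1), "> 1")
})

test_that("over and under screens are dual under label swapping", {
  spec <- planted_spec(seed = 17, n_genes = 150L)
  sim <- simulate_cohort(spec)
  co <- simulated_cohort(sim)
  swapped <- co
  swapped$samples[c("primary_tumor", "control")] <-
    co$samples[c("control", "primary_tumor")]
  over <- screen_taa(co, fc_threshold = 15, direction = "over")
  under <- screen_taa(swapped, fc_threshold = 15, direction = "under")
  expect_setequal(over$gene, under$gene)
  idx <- match(over$gene, under$gene)
  expect_equal(over$fc * under$fc[idx], rep(1, nrow(over)), tolerance = 1e-9)
  expect_equal(over$log2fc, -under$log2fc[idx])
  expect_equal(over$p_value, under$p_value[idx])
})

test_that("fc_table reports per-cohort fold changes on both scales", {
  tpm <- matrix(c(0, 0, 100, 1, 1, 1,
                  8, 8, 8, 1, 1, 1), nrow = 2, byrow = TRUE,
                dimnames = list(c("GA", "GB"),
                                c("T1", "T2", "T3", "N1", "X1", "X2")))
  fx <- toy_cohort(tpm)
  cohorts <- list(COAD = fx$cohort)
  one <- fc_table("GB", cohorts, scale = "fc")
  expect_equal(one$COAD,
               fold_change(c(8, 8, 8), c(1, 1, 1)))
  # median-difference log2FC differs from log2 of the FC ratio when skewed
  skew <- fc_table("GA", cohorts, scale = "log2fc")
  expect_equal(skew$COAD, log2_fold_change(c(0, 0, 100), c(1, 1, 1)))
  expect_false(isTRUE(all.equal(skew$COAD,
                                log2(fc_table("GA", cohorts, "fc")$COAD))))
  expect_error(fc_table(c("GA", "NOPE"), cohorts), "NOPE")
})

test_that("fc_table flags planted tumor-restricted overexpression", {
  spec_a <- planted_spec(seed = 19, n_genes = 50L, n_planted = 1L, fc = 16)
  sim_a <- simulate_cohort(spec_a)
  spec_b <- cohort_spec(tumor_code = "OTHER", n_genes = 50L,
                        tissues = c(TissueA = 30L), seed = 20)
  sim_b <- simulate_cohort(spec_b)
  cohorts <- list(SIM = simulated_cohort(sim_a),
                  OTHER = simulated_cohort(sim_b))
  tab <- fc_table("G0001", cohorts, scale = "fc")
  expect_gte(tab$SIM, 8)
  expect_lt(abs(log2(tab$OTHER)), 1)
})

test_that("median_profile emits one row per non-empty class", {
  tpm <- matrix(5, nrow = 2, ncol = 6,
                dimnames = list(c("GA", "GB"),
                                c("T1", "T2", "T3", "N1", "X1", "X2")))
  fx <- toy_cohort(tpm)
  prof <- median_profile("GA", list(COAD = fx$cohort))
  expect_identical(nrow(prof), 2L)            # no metastatic row
  expect_setequal(prof$group, c("primary_tumor", "control"))
  expect_true(all(prof$median_tpm == 5))

  with_met <- toy_cohort(cbind(tpm, M1 = c(5, 5), M2 = c(5, 5)))
  prof2 <- median_profile("GA", list(COAD = with_met$cohort))
  expect_identical(nrow(prof2), 3L)
  expect_identical(prof2$n[prof2$group == "metastatic"], 2L)
  expect_error(median_profile("NOPE", list(COAD = fx$cohort)), "NOPE")
})

test_that("median_profile recovers generator medians within tolerance", {
  spec <- planted_spec(seed = 23, n_genes = 40L, n_planted = 1L, fc = 16)
  sim <- simulate_cohort(spec)
  prof <- median_profile("G0001", list(SIM = simulated_cohort(sim)))
  b <- sim$truth$baseline_log2[1]
  expected_t <- 2^(b + 4) - 1
  expected_c <- 2^b - 1
  got_t <- prof$median_tpm[prof$group == "primary_tumor"]
  got_c <- prof$median_tpm[prof$group == "control"]
  expect_equal(log2(got_t + 1), log2(expected_t + 1), tolerance = 0.1)
  expect_equal(log2(got_c + 1), log2(expected_c + 1), tolerance = 0.1)
})

test_that("tissue_expression contrasts each tissue against the tumor", {
  spec <- cohort_spec(n_genes = 30L, tissues = c(TissueA = 25L, TissueB = 25L),
                      planted = data.frame(gene = "G0001",
                                           target = c("primary_tumor",
                                                      "TissueB"),
                                           fc = c(32, 32)),
                      seed = 29)
  sim <- simulate_cohort(spec)
  co <- simulated_cohort(sim)
  gtex_ids <- sim$annotations$sample_id[
    sim$annotations$source_project == "GTEX"]
  gtex_m <- expr_matrix(sim$expr$values[, gtex_ids, drop = FALSE], "tpm")

  plain <- tissue_expression("G0001", gtex_m, sim$annotations)
  expect_identical(nrow(plain), 2L)
  expect_false("p_value" %in% colnames(plain))

  tab <- tissue_expression("G0001", gtex_m, sim$annotations, co)
  expect_identical(nrow(tab), 3L)            # tumor row + 2 tissues
  a_row <- tab[tab$group == "TissueA", ]
  b_row <- tab[tab$group == "TissueB", ]
  # tumor is planted 32x over TissueA: log2fc near 5 and significant
  expect_equal(a_row$log2fc, 5, tolerance = 0.35)
  expect_true(a_row$significant)
  # TissueB carries the same planted level as the tumor: null contrast
  expect_lt(abs(b_row$log2fc), 0.5)
  expect_false(b_row$significant)
  expect_error(tissue_expression("NOPE", gtex_m, sim$annotations), "NOPE")
})

test_that("three-group comparison separates a shifted metastatic class", {
  spec <- cohort_spec(n_genes = 20L, n_metastatic = 30L,
                      tissues = c(TissueA = 30L),
                      planted = data.frame(gene = "G0001",
                                           target = "metastatic", fc = 8),
                      seed = 31)
  sim <- simulate_cohort(spec)
  co <- simulated_cohort(sim)
  res <- skcm_compare("G0001", co)
  expect_identical(nrow(res$summary), 3L)
  expect_identical(res$summary$n,
                   lengths(co$samples[c("metastatic", "primary_tumor",
                                        "control")], use.names = FALSE))
  met <- res$tests$group_a == "metastatic"
  expect_true(all(res$tests$significant[met]))
  expect_false(res$tests$significant[!met])
  expect_equal(res$tests$log2fc[res$tests$group_b == "primary_tumor"], 3,
               tolerance = 0.35)
})

test_that("three-group comparison is null-calibrated and guards empties", {
  spec <- cohort_spec(n_genes = 10L, n_metastatic = 25L,
                      tissues = c(TissueA = 30L), seed = 37)
  sim <- simulate_cohort(spec)
  co <- simulated_cohort(sim)
  hits <- vapply(sprintf("G%04d", 1:10), function(g)
    sum(skcm_compare(g, co)$tests$significant), numeric(1))
  expect_lte(mean(hits) / 3, 0.2)

  no_met <- simulated_cohort(simulate_cohort(
    cohort_spec(n_genes = 5L, tissues = c(TissueA = 10L), seed = 38)))
  expect_error(skcm_compare("G0001", no_met), "metastatic")
})
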