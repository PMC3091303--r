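test_that("papilloma pairs are averaged per animal", {
  mat <- matrix(c(4, 6, 4.2, 1, 3, 5), nrow = 1,
                dimnames = list("P1", paste0("s", 1:6)))
  mat <- rbind(P1 = mat[1, ], P2 = c(0, 2, 7, 1, 1, 1))
  se <- quickSE(mat, animals = c("A1", "A1", "A2", "A3", "A3", "A4"),
                tissue = "PAPILLOMA")
  comb <- combinePapillomaPairs(se)
  expect_equal(ncol(comb), 4)
  vals <- SummarizedExperiment::assay(comb, 1)
  expect_equal(unname(vals["P1", "A1_P"]), 5)    # pair mean
  expect_equal(unname(vals["P1", "A2_P"]), 4.2)  # singleton unchanged
  expect_equal(unname(vals["P2", "A1_P"]), 1)

  se3 <- quickSE(mat[, c(1, 1, 2, 3, 4, 5)], tissue = "PAPILLOMA",
                 animals = c("A1", "A1", "A1", "A2", "A2", "A3"))
  expect_error(combinePapillomaPairs(se3), "more than 2")
})

test_that("cis/trans classification uses a closed 30 Mb same-chromosome window", {
  ## published-table-shaped cases
  expect_identical(classifyCisTrans("14", 56.7, "14", 41), "CIS")
  expect_identical(classifyCisTrans("9", 50.4, "9", 34), "CIS")
  expect_identical(classifyCisTrans("4", 148.0, "1", 187), "TRANS")
  ## boundary and degenerate behavior
  expect_identical(classifyCisTrans("2", 50, "2", 80), "CIS")    # exactly 30
  expect_identical(classifyCisTrans("2", 50, "2", 80.01), "TRANS")
  expect_identical(classifyCisTrans("2", 50, "3", 50), "TRANS")
  expect_identical(classifyCisTrans("2", 50, "2", 50, window = 1e-9), "CIS")
  expect_identical(classifyCisTrans(NA, NA, "2", 50), "UNPLACED")
})

test_that("cis/trans ratio counts significant autosomal records", {
  rec <- data.frame(probe = sprintf("P%d", 1:12),
                    gene_chr = c(rep("1", 10), "X", "X"),
                    cis_trans = c(rep("CIS", 5), rep("TRANS", 4), "CIS",
                                  "CIS", "TRANS"),
                    significant = c(rep(TRUE, 9), FALSE, TRUE, TRUE))
  ctr <- cisTransRatio(rec)
  expect_equal(ctr$n_cis, 5)
  expect_equal(ctr$n_trans, 4)
  expect_equal(ctr$ratio, 1.25)
  ## X-linked genes enter only on request
  expect_equal(cisTransRatio(rec, include_x = TRUE)$n_cis, 6)
  ## no trans records: infinite ratio with counts intact
  only_cis <- rec[rec$cis_trans == "CIS" & rec$gene_chr != "X", ]
  expect_equal(cisTransRatio(only_cis)$ratio, Inf)
})

test_that("mapping recovers planted architecture and respects FDR monotonicity", {
  coh <- tinyCohort()
  rec <- tinyRecords("SKIN")
  pl <- coh$truth$planted
  skin_active <- pl$probe[pl$kind == "steady" & pl$in_skin]
  recovered <- rec$significant[match(skin_active, rec$probe)]
  expect_gte(mean(recovered), 0.9)
  ## false-discovery proportion within control
  false_sig <- sum(rec$significant & !(rec$probe %in% pl$probe))
  expect_lte(false_sig / max(1, sum(rec$significant)), 0.2)
  ## planted cis eQTL classified CIS at their true locus
  cis_probes <- pl$probe[pl$mode == "CIS" & pl$in_skin & pl$kind == "steady"]
  ## the peak may wander to a linked neighbor marker, so a planted cis
  ## effect occasionally classifies trans on a sparse marker panel
  got <- rec[rec$probe %in% cis_probes & rec$significant, ]
  expect_gte(mean(got$cis_trans == "CIS"), 0.75)
  ## and the peak itself stays close to the true causal marker
  map <- markerMap(coh$genotypes)
  true_mk <- pl$marker[match(got$probe, pl$probe)]
  expect_gte(mean(got$peak_chr == map$chr[match(true_mk, map$marker)]), 0.9)

  ## lowering the FDR threshold never adds records
  sig10 <- rec$probe[rec$q <= 0.10]
  sig05 <- rec$probe[rec$q <= 0.05]
  expect_true(all(sig05 %in% sig10))

  ## mapping rejects un-combined papilloma samples
  expect_error(mapEqtl(coh$papilloma, coh$genotypes, tinyConfig()),
               "combine papilloma pairs")
})

test_that("conservation summary compares tissues through fold-change stability", {
  rec_a <- tinyRecords("SKIN")
  fc_se <- suppressMessages(matchedFoldChange(tinyCohort()$carcinoma,
                                              tinyCohort()$skin))
  fc <- rowMeans(SummarizedExperiment::assay(fc_se, 1))

  ## B = A: full conservation on every chromosome with any eQTL
  cons_same <- compareConservation(rec_a, rec_a, fc)
  expect_equal(cons_same$fraction_conserved, 1)
  pc <- cons_same$per_chromosome
  expect_true(all(pc$frac_conserved[pc$n_eqtl > 0] == 1))
  expect_equal(sum(cons_same$table), sum(rec_a$significant))

  ## against carcinoma: attenuated and masked effects drop out
  rec_c <- tinyRecords("CARCINOMA")
  cons <- compareConservation(rec_a, rec_c, fc)
  expect_lt(cons$fraction_conserved, 1)
  ## the amplified chromosome has the planted masking
  masked <- tinyCohort()$truth$planted
  masked <- masked$probe[masked$masked]
  expect_true(all(!cons$conserved[masked[masked %in%
                                           names(cons$conserved)]]))
})

test_that("tumor-specific sets and the expression gate behave on edge cases", {
  rec_t <- data.frame(probe = c("P1", "P2", "P3"), significant = TRUE)
  rec_s <- data.frame(probe = c("P4", "P5"), significant = TRUE)
  ## disjoint significant sets: the full tumor set returns
  expect_equal(tumorSpecificEqtl(rec_t, rec_s)$tumor_specific$probe,
               c("P1", "P2", "P3"))
  ## identical sets: empty
  expect_equal(nrow(tumorSpecificEqtl(rec_t, rec_t)$tumor_specific), 0)

  ## planted carcinoma-only eQTL are found tumor-specific in the cohort
  coh <- tinyCohort()
  ts <- tumorSpecificEqtl(tinyRecords("CARCINOMA"), tinyRecords("SKIN"),
                          coh$skin)
  pl <- coh$truth$planted
  tumor_only <- pl$probe[pl$kind == "steady" & !pl$in_skin]
  expect_gte(mean(tumor_only %in% ts$tumor_specific$probe), 0.7)
  ## the low-baseline planted genes drive the expression-gated subset
  expect_true(nrow(ts$expressed_only_in_tumor) >= 1)
  expect_true(all(ts$expressed_only_in_tumor$probe %in%
                    ts$tumor_specific$probe))
})

test_that("confirmation retests records at their discovery peak only", {
  coh <- tinyCohort()
  rec <- tinyRecords("SKIN")
  sig <- rec[rec$significant, ][1:5, ]
  conf <- confirmEqtl(sig, coh$skin, coh$genotypes, tinyConfig())
  ## same cohort: regression p at the peak equals a direct recomputation
  mat <- log2Values(coh$skin)
  meta <- sampleMeta(coh$skin)
  g <- genotypeCalls(coh$genotypes)[meta$animal, sig$peak_marker[1]]
  expect_equal(conf$confirm_p[1],
               markerRegressionP(mat[sig$probe[1], ], g)$p)

  ## missing probe: untestable, excluded from the q-value set
  sig2 <- sig
  sig2$probe[2] <- "NOT_A_PROBE"
  conf2 <- confirmEqtl(sig2, coh$skin, coh$genotypes, tinyConfig())
  expect_true(conf2$untestable[2])
  expect_true(is.na(conf2$confirm_q[2]))
  expect_false(conf2$confirmed[2])
})

test_that("papilloma count QTL rejects constant phenotypes", {
  coh <- tinyCohort()
  ph <- coh$phenotype
  ph$papilloma_count_wk20 <- 3L
  expect_error(papillomaCountQtl(ph, coh$genotypes, n_perm = 100),
               "equal")
})
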