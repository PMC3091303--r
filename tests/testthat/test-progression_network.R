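test_that("matched fold-changes subtract genotype-matched skin per animal", {
  set.seed(50)
  skin <- matrix(rnorm(20 * 6), 20, 6,
                 dimnames = list(sprintf("P%02d", 1:20), sprintf("s%d", 1:6)))
  tumor <- skin + 1
  colnames(tumor) <- sprintf("t%d", 1:6)
  se_s <- quickSE(skin, animals = sprintf("A%d", 1:6), tissue = "SKIN")
  se_t <- quickSE(tumor, animals = sprintf("A%d", c(1:4, 7, 8)),
                  tissue = "CARCINOMA")
  fc <- suppressMessages(matchedFoldChange(se_t, se_s))
  expect_equal(ncol(fc), 4)  # only matched animals
  vals <- SummarizedExperiment::assay(fc, 1)
  expect_equal(unname(vals), matrix(1, 20, 4), tolerance = 1e-12)

  ## hand-averaged oracle on random data
  tumor2 <- matrix(rnorm(20 * 6), 20, 6,
                   dimnames = dimnames(tumor))
  se_t2 <- quickSE(tumor2, animals = sprintf("A%d", 1:6),
                   tissue = "CARCINOMA")
  fc2 <- matchedFoldChange(se_t2, se_s)
  expect_equal(rowMeans(SummarizedExperiment::assay(fc2, 1)),
               rowMeans(tumor2 - skin))
  expect_error(matchedFoldChange(se_t2, quickSE(skin,
    animals = sprintf("B%d", 1:6))), "no matched animals")
})

test_that("extreme-change selection matches the normal tail", {
  set.seed(51)
  fc_mat <- matrix(rnorm(2000 * 10), 2000, 10)
  rownames(fc_mat) <- sprintf("P%04d", 1:2000)
  se <- quickSE(fc_mat, tissue = "SKIN")
  ext <- extremeChangeProbes(se, sd_multiplier = 2)
  ## selected fraction ~ 2 * Phi(-2) = 4.55%, binomial band
  frac <- nrow(ext) / 2000
  p0 <- 2 * pnorm(-2)
  expect_lt(abs(frac - p0), 3 * sqrt(p0 * (1 - p0) / 2000) + 0.005)

  ## an outlying probe is selected with direction UP
  fc_mat2 <- fc_mat
  fc_mat2[7, ] <- fc_mat2[7, ] + 5 * sd(rowMeans(fc_mat))
  ext2 <- extremeChangeProbes(quickSE(fc_mat2))
  expect_true("P0007" %in% ext2$probe)
  expect_identical(ext2$direction[ext2$probe == "P0007"], "UP")

  ## identical mean fold-changes: empty selection
  flat <- quickSE(matrix(rep(c(1, -1), 50), 25, 4, byrow = FALSE) * 0 + 2)
  expect_warning(ext0 <- extremeChangeProbes(flat), "zero|unstable")
  expect_equal(nrow(ext0), 0)
})

test_that("progression network keeps a planted module and filters singleton edges", {
  set.seed(52)
  n <- 50
  f <- rnorm(n)
  module <- t(vapply(1:10, function(i) 0.9 * f + sqrt(0.19) * rnorm(n),
                     numeric(n)))
  anti <- t(vapply(1:5, function(i) -0.9 * f + sqrt(0.19) * rnorm(n),
                   numeric(n)))
  noise <- matrix(rnorm(60 * n), 60, n)
  X <- rbind(module, anti, noise)
  rownames(X) <- sprintf("P%03d", seq_len(nrow(X)))
  se <- quickSE(X, tissue = "SKIN")
  ext <- data.frame(probe = rownames(X), gene = rownames(X),
                    mean_fc = rowMeans(X), direction = "UP")
  net <- buildProgressionNetwork(se, extreme = ext, alpha = 0.05,
                                 n_perm = 150, seed = 53)
  mod_ids <- sprintf("P%03d", 1:10)
  anti_ids <- sprintf("P%03d", 11:15)
  expect_true(all(mod_ids %in% net$nodes$probe))
  ## anti-correlated module connects with INVERSE edges to the main one
  cross <- net$edges[(net$edges$from %in% mod_ids &
                        net$edges$to %in% anti_ids) |
                       (net$edges$from %in% anti_ids &
                          net$edges$to %in% mod_ids), ]
  expect_true(nrow(cross) > 0)
  expect_true(all(cross$sign == "INVERSE"))
  within <- net$edges[net$edges$from %in% mod_ids &
                        net$edges$to %in% mod_ids, ]
  expect_true(all(within$sign == "DIRECT"))
  ## every edge respects the threshold; noise rarely survives
  expect_true(all(abs(net$edges$r) >= net$r_star))
  expect_lte(sum(!(net$nodes$probe %in% c(mod_ids, anti_ids))), 1)

  ## triangle filtering is idempotent
  keep1 <- rewireQTL:::cliqueFilterNodes(net$edges, net$nodes$probe, 3)
  edges1 <- net$edges[net$edges$from %in% keep1 & net$edges$to %in% keep1, ]
  keep2 <- rewireQTL:::cliqueFilterNodes(edges1, keep1, 3)
  expect_setequal(keep1, keep2)

  ## clique_min = 2 keeps all endpoints of significant edges
  net2 <- buildProgressionNetwork(se, extreme = ext, alpha = 0.05,
                                  n_perm = 150, clique_min = 2, seed = 53)
  expect_setequal(net2$nodes$probe,
                  unique(c(net2$edges$from, net2$edges$to)))
})

test_that("locus networks collect a trans band and flag its cis driver", {
  coh <- tinyCohort()
  truth <- coh$truth
  resp <- truth$planted[truth$planted$kind == "response", ]
  ## build a synthetic trans band instead: use the susceptibility locus in
  ## papillomas, where several planted genes share one peak
  rec <- tinyRecords("PAPILLOMA")
  locus <- truth$susceptibility$marker
  se <- combinePapillomaPairs(coh$papilloma)
  net <- buildLocusNetwork(locus, rec, se, coh$genotypes,
                           tolerance_mb = 5, n_perm = 150, seed = 54)
  expect_gte(nrow(net$nodes), 2)
  expect_true(all(net$edges$to[net$edges$type == "locus"] %in%
                    net$nodes$node))
  expect_gte(length(net$cis_genes), 1)

  ## no linked records: error
  far <- markerMap(coh$genotypes)
  lonely <- far$marker[far$chr == "19"][1]
  rec_none <- rec
  rec_none$significant <- FALSE
  expect_error(buildLocusNetwork(lonely, rec_none, se, coh$genotypes),
               "no significant eQTL")

  ## zero tolerance keeps only exact peak positions
  net0 <- buildLocusNetwork(locus, rec, se, coh$genotypes,
                            tolerance_mb = 0, n_perm = 150, seed = 54)
  mb <- far$mb[far$marker == locus]
  sig <- rec[rec$significant, ]
  expect_equal(nrow(net0$nodes) - 1,
               sum(sig$peak_chr == "14" & sig$peak_mb == mb))
})
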