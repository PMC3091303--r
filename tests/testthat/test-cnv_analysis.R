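test_that("copy-number calls use inclusive log2 cutoffs", {
  x <- c(-0.5, -0.3, -0.29, 0, 0.29, 0.3, 0.5, NA)
  calls <- callCopyNumber(x, 0.3)
  expect_identical(calls,
                   c("DEL", "DEL", "NEUTRAL", "NEUTRAL", "NEUTRAL",
                     "AMP", "AMP", NA))
  expect_error(callCopyNumber(c(0.1, Inf)), "finite")
})

test_that("fraction of genome altered follows the nearest-probe rule", {
  lens <- data.frame(chr = c("1", "2"), length_mb = c(100, 100))
  probes <- data.frame(probe = c("c1a", "c1b", "c2a"),
                       chr = c("1", "1", "2"), mb = c(25, 75, 50))
  mk <- function(r) AcghSet(matrix(r, 3, 1,
                                   dimnames = list(probes$probe, "T1")),
                            probes)
  ## all neutral: 0% altered
  res0 <- fractionGenomeAltered(mk(c(0, 0, 0)), chromosome_lengths = lens,
                                bins_per_chromosome = 1000)
  expect_equal(res0$per_tumor$pct_amplified, 0)
  expect_equal(res0$per_tumor$pct_deleted, 0)

  ## chromosome 2 fully amplified, chromosome 1 neutral: 50% amplified
  res1 <- fractionGenomeAltered(mk(c(0, 0, 1)), chromosome_lengths = lens,
                                bins_per_chromosome = 1000)
  expect_equal(res1$per_tumor$pct_amplified, 50)

  ## probes at 25 (AMP) and 75 (NEUTRAL) on a 100 Mb chromosome: bins left
  ## of the 50 Mb midpoint belong to the first probe
  probes2 <- probes[1:2, ]
  acgh2 <- AcghSet(matrix(c(0.5, 0), 2, 1,
                          dimnames = list(probes2$probe, "T1")), probes2)
  res2 <- fractionGenomeAltered(acgh2, chromosome_lengths = lens[1, ],
                                bins_per_chromosome = 1000000)
  expect_equal(res2$per_tumor$pct_amplified, 50)
})

test_that("analytic segment counting equals explicit bin enumeration", {
  set.seed(60)
  lens <- data.frame(chr = c("1", "2", "3"), length_mb = c(90, 60, 40))
  for (rep in 1:10) {
    probes <- do.call(rbind, lapply(1:3, function(ci) {
      k <- sample(2:8, 1)
      data.frame(chr = lens$chr[ci],
                 mb = sort(runif(k, 0, lens$length_mb[ci])))
    }))
    probes$probe <- sprintf("cg%02d", seq_len(nrow(probes)))
    ratios <- matrix(sample(c(-0.5, 0, 0.5), nrow(probes) * 2,
                            replace = TRUE),
                     nrow(probes), 2,
                     dimnames = list(probes$probe, c("T1", "T2")))
    acgh <- AcghSet(ratios, probes)
    a <- fractionGenomeAltered(acgh, chromosome_lengths = lens,
                               bins_per_chromosome = 10000,
                               mode = "analytic")
    b <- fractionGenomeAltered(acgh, chromosome_lengths = lens,
                               bins_per_chromosome = 10000, mode = "bins")
    expect_identical(a$per_tumor, b$per_tumor)
  }
})

test_that("redundant probes sharing their neighbors' calls leave fractions unchanged", {
  set.seed(61)
  lens <- data.frame(chr = "1", length_mb = 80)
  probes <- data.frame(probe = c("a", "b", "c"), chr = "1",
                       mb = c(10, 40, 70))
  ratios <- matrix(c(0.5, 0.5, -0.5), 3, 1,
                   dimnames = list(probes$probe, "T1"))
  base <- fractionGenomeAltered(AcghSet(ratios, probes),
                                chromosome_lengths = lens,
                                bins_per_chromosome = 100000)
  ## a2 sits between two AMP probes; c2 beyond the last (DEL) probe
  probes2 <- rbind(probes, data.frame(probe = c("a2", "c2"), chr = "1",
                                      mb = c(25, 78)))
  ratios2 <- rbind(ratios, matrix(c(0.5, -0.5), 2, 1,
                                  dimnames = list(c("a2", "c2"), "T1")))
  aug <- fractionGenomeAltered(AcghSet(ratios2, probes2),
                               chromosome_lengths = lens,
                               bins_per_chromosome = 100000)
  expect_equal(aug$per_tumor$pct_amplified, base$per_tumor$pct_amplified)
  expect_equal(aug$per_tumor$pct_deleted, base$per_tumor$pct_deleted)
})

test_that("alteration frequency tracks and chromosome gains summarize the panel", {
  coh <- tinyCohort()
  freq <- alterationFrequencyTrack(coh$acgh)
  tr <- freq$track
  expect_true(all(tr$amp_freq >= 0 & tr$amp_freq <= 1))
  ev <- coh$truth$cnv_event
  in_reg <- tr$chr == ev$chr & tr$mb >= ev$start_mb
  expected <- mean(coh$amp_tumors)
  if (any(in_reg)) {
    band <- 3 * sqrt(0.25 / length(coh$amp_tumors))
    expect_true(all(abs(tr$amp_freq[in_reg] - expected) < band + 0.05))
  }
  gains <- freq$chromosome_gain
  expect_gte(gains$gain_freq[gains$chr == ev$chr],
             expected)  # "any AMP probe" mode includes the event tumors

  ## flat profiles give a zero track
  flat <- AcghSet(matrix(0, 4, 2,
                         dimnames = list(paste0("p", 1:4), c("T1", "T2"))),
                  data.frame(probe = paste0("p", 1:4), chr = "1",
                             mb = 1:4))
  f0 <- alterationFrequencyTrack(flat)
  expect_true(all(f0$track$amp_freq == 0 & f0$track$del_freq == 0))
})

test_that("amplification-expression association detects the planted boost", {
  coh <- tinyCohort()
  fc_se <- suppressMessages(matchedFoldChange(coh$carcinoma, coh$skin))
  masked <- coh$truth$planted$probe[coh$truth$planted$masked][1]
  fc <- SummarizedExperiment::assay(fc_se, 1)[masked, ]
  amp <- coh$amp_tumors[colnames(fc_se)]
  res <- amplificationExpressionTest(amp, fc)
  expect_lt(res$p, 1e-4)
  expect_gt(res$r, 0)
  expect_gt(res$mean_fold_difference, 2)

  ## identical groups: statistic near zero, p near 1
  set.seed(62)
  y <- rnorm(40)
  amp2 <- rep(c(TRUE, FALSE), 20)
  res2 <- amplificationExpressionTest(amp2, y)
  expect_gt(res2$p, 0.01)
  expect_lt(abs(res2$r), 0.4)
  expect_error(amplificationExpressionTest(rep(TRUE, 10), rnorm(10)),
               "empty")
})
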