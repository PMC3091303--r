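test_that("marker regression equals the two-sample t-test and flags degenerate input", {
  ## worked example: {1,2} vs {3,4}
  res <- markerRegressionP(c(1, 2, 3, 4), c(0L, 0L, 1L, 1L))
  oracle <- t.test(c(1, 2), c(3, 4), var.equal = TRUE)$p.value
  expect_equal(res$p, oracle, tolerance = 1e-12)
  expect_false(res$degenerate)

  ## random instances against the closed-form oracle
  set.seed(20)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    g <- rbinom(n, 1, 0.5)
    if (sum(g) < 3 || sum(1 - g) < 3) next
    y <- rnorm(n, mean = g * rnorm(1))
    expect_equal(markerRegressionP(y, g)$p,
                 t.test(y[g == 1], y[g == 0], var.equal = TRUE)$p.value,
                 tolerance = 1e-10)
  }

  ## degenerate cases return p = 1 with the flag set
  const <- markerRegressionP(rep(2, 8), rep(c(0L, 1L), 4))
  expect_equal(const$p, 1)
  expect_true(const$degenerate)
  onegrp <- markerRegressionP(rnorm(8), rep(1L, 8))
  expect_equal(onegrp$p, 1)
  expect_true(onegrp$degenerate)

  ## genotype codes accepted
  expect_equal(markerRegressionP(c(1, 2, 3, 4),
                                 c("HOM_FVB", "HOM_FVB", "HET", "HET"))$p,
               oracle, tolerance = 1e-12)
  expect_error(markerRegressionP(1:4, c("A", "A", "H", "H")),
               "unknown genotype code")
})

test_that("minimal-p scan picks the argmin with a deterministic genomic tie-break", {
  set.seed(21)
  map <- data.frame(marker = c("m1", "m2", "m3"), chr = "1",
                    mb = c(1, 2, 3))
  calls <- cbind(m1 = rbinom(20, 1, 0.5), m2 = rbinom(20, 1, 0.5),
                 m3 = rbinom(20, 1, 0.5))
  calls[, 3] <- calls[, 1]  # identical genotype columns -> tied p
  rownames(calls) <- sprintf("A%02d", 1:20)
  gs <- GenotypeSet(calls, map)
  y <- rnorm(20) + calls[, 1]
  scan <- minPScan(y, gs)
  expect_equal(scan$per_marker_p[["m1"]], scan$per_marker_p[["m3"]])
  expect_identical(scan$peak_marker, "m1")  # earliest position wins
  expect_equal(scan$p_minimal_obs, min(scan$per_marker_p))

  single <- minPScan(y, GenotypeSet(calls[, 1, drop = FALSE], map[1, ]))
  expect_equal(single$p_minimal_obs, single$per_marker_p[[1]])
})

test_that("permutation correction is exact for deterministic signal and uniform under the null", {
  map <- defaultMarkerMap(40)
  gt <- simulateBackcross(30, map, seed = 22)
  calls <- genotypeCalls(gt)
  ## noise-free function of one marker: corrected p = 0, shown as <1/n_perm
  y <- as.numeric(calls[, 10])
  res <- permutationCorrectedP(y, gt, n_perm = 100, seed = 23)
  expect_equal(res$corrected_p[1], 0)
  expect_identical(formatPermP(res$corrected_p[1], 100), "<0.01")

  ## null probes: corrected p uniform on the permutation grid
  set.seed(24)
  Y <- matrix(rnorm(30 * 150), 30, 150)
  null <- permutationCorrectedP(Y, gt, n_perm = 100, seed = 25)
  expect_gt(suppressWarnings(ks.test(null$corrected_p, "punif"))$p.value,
            0.01)
  expect_true(all(abs(null$corrected_p * 100 -
                        round(null$corrected_p * 100)) < 1e-9))
  expect_error(permutationCorrectedP(Y[1:4, ], calls[1:4, ], n_perm = 100),
               "6 animals")
  expect_error(permutationCorrectedP(Y, gt, n_perm = 50), "at least 100")
})

test_that("Storey q-values estimate pi0 and stay monotone and clipped", {
  expect_equal(storeyQvalues(rep(1, 30))$q_out, rep(1, 30))

  set.seed(26)
  unif <- storeyQvalues(runif(2000))
  expect_gte(unif$pi0_hat, 0.85)
  expect_lte(unif$pi0_hat, 1)

  ## property: q monotone in sorted p, within [0, 1]
  for (i in 1:20) {
    p <- switch(1 + i %% 3, runif(200), rbeta(200, 0.3, 1),
                round(runif(200), 2))
    q <- storeyQvalues(p)
    expect_true(all(q$q_out >= 0 & q$q_out <= 1))
    o <- order(p)
    expect_true(all(diff(q$q_out[o]) >= -1e-12))
  }
  expect_error(storeyQvalues(c(0.5, 1.2)), "0, 1")
})

test_that("SAM statistic behaves like a moderated t and its FDR finds a planted shift", {
  set.seed(27)
  X <- matrix(rnorm(300 * 16), 300, 16,
              dimnames = list(sprintf("P%03d", 1:300), NULL))
  labels <- rep(c("A", "B"), each = 8)

  ## equal means: d centred at zero
  sam0 <- samScan(X, labels, n_perm = 100, seed = 28)
  expect_lt(abs(median(sam0$table$d)), 0.1)

  ## s0 = 0 with equal group sizes reproduces t-statistic ordering
  samt <- samScan(X, labels, n_perm = 100, seed = 28, s0 = 0)
  tstat <- apply(X, 1, function(y)
    t.test(y[1:8], y[9:16], var.equal = TRUE)$statistic)
  expect_identical(order(samt$table$d), order(tstat))

  ## a 5-SD shifted probe attains the max |d| and a q below all nulls
  X2 <- X
  X2["P001", 1:8] <- X2["P001", 1:8] + 5
  sam2 <- samScan(X2, labels, n_perm = 100, seed = 29)
  expect_identical(sam2$table$probe[which.max(abs(sam2$table$d))], "P001")
  expect_lt(sam2$table$q_sam[1], min(sam2$table$q_sam[-1]) + 1e-12)

  ## label swap flips every d
  rev_lab <- factor(labels, levels = c("B", "A"))
  sam_rev <- samScan(X, rev_lab, n_perm = 100, seed = 28,
                     s0 = sam0$s0)
  expect_equal(sam_rev$table$d, -sam0$table$d)
  expect_error(samScan(X[, 1:5], rep(c("A", "B"), c(2, 3)), n_perm = 100),
               "at least 3")
})

test_that("GWER correlation threshold tracks the null maximum distribution", {
  set.seed(30)
  X <- matrix(rnorm(12 * 40), 12, 40,
              dimnames = list(sprintf("P%02d", 1:12), NULL))
  thr <- gwerCorrelationThreshold(X, alpha = 0.05, n_perm = 200, seed = 31)
  expect_true(thr$r_star > 0 && thr$r_star < 1)

  ## alpha = 1: the threshold is the minimum of the null maxima
  thr1 <- gwerCorrelationThreshold(X, alpha = 1, n_perm = 200, seed = 31)
  expect_equal(thr1$r_star, min(thr$null_max))

  ## duplicated probe row exceeds the threshold in the observed data
  X2 <- rbind(X, dup = X[1, ])
  cc <- cor(t(X2))
  expect_gt(abs(cc["P01", "dup"]), thr$r_star)

  ## threshold shrinks with sample size (two independent probes)
  set.seed(32)
  small <- gwerCorrelationThreshold(matrix(rnorm(2 * 20), 2, 20),
                                    alpha = 0.05, n_perm = 300, seed = 33)
  big <- gwerCorrelationThreshold(matrix(rnorm(2 * 200), 2, 200),
                                  alpha = 0.05, n_perm = 300, seed = 33)
  expect_lt(big$r_star, small$r_star)
  ## and is close to the Fisher-z two-sided null quantile for one pair
  fisher_q <- tanh(qnorm(0.975) / sqrt(200 - 3))
  expect_lt(abs(big$r_star - fisher_q), 0.05)

  expect_warning(gwerCorrelationThreshold(rbind(X, 0), n_perm = 100,
                                          seed = 34), "zero-variance")
})
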