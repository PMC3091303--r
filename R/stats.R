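## ---------------------------------------------------------------------------
## Single-marker regression scan
##
## For a binary backcross genotype the slope test of y ~ I(HET) is identical
## to the equal-variance two-sample t-test, so the whole scan reduces to
## cross-products and is computed for all probes x markers at once.
## ---------------------------------------------------------------------------

## Y: animals x probes (numeric). G: animals x markers (0/1 integer, NA ok).
## Returns probes x markers matrix of two-sided p-values. Degenerate cells
## (a genotype class absent, < 1 residual df, or zero within-group variance
## with equal means) get p = 1; exact separation (zero variance, unequal
## means) gets p = 0.
scanPvalues <- function(Y, G) {
  stopIfNot(nrow(Y) == nrow(G), "Y and G must have the same number of rows")
  n <- nrow(Y)
  P <- ncol(Y)
  m <- ncol(G)
  Gd <- G
  storage.mode(Gd) <- "double"
  hasNA <- anyNA(Gd)
  if (hasNA) {
    Md <- 1 * !is.na(Gd)
    G0 <- Gd
    G0[is.na(G0)] <- 0
    nk <- colSums(Md)
    SY <- crossprod(Y, Md)
    SYY <- crossprod(Y * Y, Md)
  } else {
    G0 <- Gd
    nk <- rep.int(n, m)
    SY <- matrix(colSums(Y), P, m)
    SYY <- matrix(colSums(Y * Y), P, m)
  }
  n1 <- colSums(G0)
  n0 <- nk - n1
  S1 <- crossprod(Y, G0)
  S0 <- SY - S1
  rep1 <- rep(pmax(n1, 1), each = P)
  rep0 <- rep(pmax(n0, 1), each = P)
  mean1 <- S1 / rep1
  mean0 <- S0 / rep0
  ss <- SYY - mean1 * S1 - mean0 * S0   # pooled within-group SS
  df <- rep(nk - 2, each = P)
  sp2 <- ss / df
  se2 <- sp2 * (1 / rep1 + 1 / rep0)
  diff <- mean1 - mean0
  tt <- diff / sqrt(se2)
  p <- 2 * pt(-abs(tt), df)
  ## degenerate cells: settle deterministically rather than abort the scan
  zero <- is.finite(ss) & ss <= 1e-12 & df >= 1
  if (any(zero)) p[zero] <- ifelse(abs(diff[zero]) > 1e-8, 0, 1)
  badcol <- n1 < 1 | n0 < 1 | nk < 3
  if (any(badcol)) p[, badcol] <- 1
  p[!is.finite(p)] <- 1
  dimnames(p) <- list(colnames(Y), colnames(G))
  p
}

## Coerce genotype input (GenotypeSet / matrix / vector of 0-1 or code
## strings) to a 0/1 integer matrix.
asCallMatrix <- function(g) {
  if (is(g, "GenotypeSet")) return(genotypeCalls(g))
  if (is.character(g) || is.factor(g)) {
    g <- as.character(g)
    bad <- setdiff(unique(g[!is.na(g)]), c("HOM_FVB", "HET"))
    stopIfNot(length(bad) == 0,
              paste("unknown genotype code:", paste(bad, collapse = ", ")))
    g <- ifelse(g == "HET", 1L, 0L)
  }
  if (!is.matrix(g)) g <- matrix(as.integer(g), ncol = 1)
  storage.mode(g) <- "integer"
  g
}

#' Single-marker regression p-value
#'
#' P-value for the association between an expression (or phenotype) vector
#' and one binary backcross genotype, from the slope test of
#' `y ~ I(HET)` -- numerically identical to the equal-variance two-sample
#' t-test. Degenerate inputs (a genotype class absent, constant `y`) return
#' p = 1 with a degenerate flag instead of aborting, so genome scans never
#' stop mid-way.
#'
#' @param y numeric vector over animals.
#' @param g genotype vector: 0/1 integers (1 = HET) or codes
#'   `"HOM_FVB"`/`"HET"`; `NA` drops the animal from this regression.
#' @return list with elements `p` and `degenerate`.
#' @export
markerRegressionP <- function(y, g) {
  g <- asCallMatrix(g)
  stopIfNot(length(y) == nrow(g), "y and g lengths differ")
  ok <- !is.na(y) & !is.na(g[, 1])
  yv <- y[ok]
  gv <- g[ok, 1]
  n1 <- sum(gv == 1L)
  n0 <- sum(gv == 0L)
  degenerate <- n1 < 1 || n0 < 1 || length(yv) < 3 ||
    sd(yv) < 1e-12
  p <- scanPvalues(matrix(yv, ncol = 1), matrix(gv, ncol = 1))[1, 1]
  list(p = unname(p), degenerate = degenerate)
}

#' Genome scan for the minimal p-value
#'
#' Runs the single-marker regression at every marker and records the lowest
#' observed p-value and its peak marker. Ties are broken deterministically
#' by genomic order (lowest chromosome, then lowest Mb), which is the order
#' markers are stored in a [GenotypeSet()].
#'
#' @param y numeric vector over animals.
#' @param genotypes a [GenotypeSet()] (or 0/1 matrix in genomic column
#'   order).
#' @return list with `per_marker_p`, `p_minimal_obs`, `peak_index`, and
#'   `peak_marker` (marker id, when column names are present).
#' @export
minPScan <- function(y, genotypes) {
  G <- asCallMatrix(genotypes)
  stopIfNot(ncol(G) >= 1, "at least one marker required")
  p <- scanPvalues(matrix(y, ncol = 1), G)[1, ]
  k <- which.min(p)  # first minimum = genomic-order tie break
  list(per_marker_p = p, p_minimal_obs = unname(p[k]),
       peak_index = unname(k),
       peak_marker = if (!is.null(colnames(G))) colnames(G)[k] else k)
}

## Matrix version: rows of `pmat` are probes.
minPFromMatrix <- function(pmat) {
  peak <- max.col(-pmat, ties.method = "first")
  list(p_min = pmat[cbind(seq_len(nrow(pmat)), peak)], peak_index = peak)
}

#' Minimal-p permutation correction
#'
#' Family-wise corrected p-values for genome scans: the animal rows of the
#' genotype matrix are shuffled as whole rows (preserving inter-marker
#' linkage) `n_perm` times, the minimal scan p-value is recomputed for each
#' shuffle, and the corrected p-value is the fraction of shuffles whose
#' minimal p-value is at or below the observed one. The same shuffles are
#' shared by all probes. A count of zero is reported as corrected p = 0
#' (displayed as `<1/n_perm`); it is substituted by `1/(2 n_perm)` before
#' q-value estimation downstream.
#'
#' @param Y numeric matrix animals x probes (a vector is treated as one
#'   probe).
#' @param genotypes a [GenotypeSet()] or 0/1 call matrix.
#' @param n_perm number of genotype shuffles (>= 100).
#' @param seed RNG seed for the shuffles.
#' @param return_null also return the `n_perm` x probes matrix of null
#'   minimal p-values.
#' @return list with `corrected_p`, `p_minimal_obs`, `peak_index`,
#'   `per_marker_p` (probes x markers), and optionally `null_min_p`.
#' @export
permutationCorrectedP <- function(Y, genotypes, n_perm = 1000L, seed = NULL,
                                  return_null = FALSE) {
  G <- asCallMatrix(genotypes)
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1)
  stopIfNot(nrow(Y) >= 6, "at least 6 animals required")
  stopIfNot(n_perm >= 100, "n_perm must be at least 100")
  n <- nrow(Y)
  obs <- scanPvalues(Y, G)
  mp <- minPFromMatrix(obs)
  counts <- numeric(ncol(Y))
  null_min <- if (return_null) matrix(NA_real_, n_perm, ncol(Y)) else NULL
  withSeed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      pb <- minPFromMatrix(scanPvalues(Y, G[idx, , drop = FALSE]))$p_min
      counts <- counts + (pb <= mp$p_min)
      if (return_null) null_min[b, ] <- pb
    }
  })
  out <- list(corrected_p = counts / n_perm, p_minimal_obs = mp$p_min,
              peak_index = mp$peak_index, per_marker_p = obs)
  if (return_null) out$null_min_p <- null_min
  out
}

#' Format a permutation p-value for display
#'
#' Zero permutation counts are shown as `"<1/n_perm"` rather than 0, since
#' the permutation scheme cannot resolve p-values below its granularity.
#'
#' @param p corrected p-value(s) on the `1/n_perm` grid.
#' @param n_perm number of permutations used.
#' @return character vector.
#' @export
formatPermP <- function(p, n_perm) {
  ifelse(p <= 0, sprintf("<%g", 1 / n_perm), format(p, digits = 4))
}

## ---------------------------------------------------------------------------
## Storey q-values
## ---------------------------------------------------------------------------

#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0, 0.05, ..., 0.90
#' with a cubic smoothing spline evaluated at the grid maximum, then
#' computes step-up q-values `q(i) = min_{j>=i} pi0 * m * p(j) / j` on the
#' sorted p-values, clipped to [0, 1].
#'
#' @param p vector of p-values in [0, 1].
#' @param lambda tuning grid for pi0 estimation.
#' @return list of class `qvalue_result` with `p_in`, `q_out`, `pi0_hat`.
#' @export
storeyQvalues <- function(p, lambda = seq(0, 0.90, by = 0.05)) {
  stopIfNot(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  m <- length(p)
  if (m < 20) {
    ## too few tests for stable pi0 smoothing; fall back to pi0 = 1 (BH)
    pi0 <- 1
  } else {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- predict(fit, x = max(lambda))$y
    pi0 <- min(1, max(pi0, 1e-8))
  }
  o <- order(p)
  ps <- p[o]
  q_sorted <- pi0 * m * ps / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  structure(list(p_in = p, q_out = q, pi0_hat = pi0),
            class = "qvalue_result")
}

## ---------------------------------------------------------------------------
## SAM two-class statistic
## ---------------------------------------------------------------------------

## Tusher-style relative difference and its denominator for all probes.
## X: probes x samples, cls: logical (TRUE = class A).
samStats <- function(X, cls) {
  nA <- sum(cls)
  nB <- sum(!cls)
  mA <- rowMeans(X[, cls, drop = FALSE])
  mB <- rowMeans(X[, !cls, drop = FALSE])
  ssA <- rowSums((X[, cls, drop = FALSE] - mA)^2)
  ssB <- rowSums((X[, !cls, drop = FALSE] - mB)^2)
  a <- (1 / nA + 1 / nB) / (nA + nB - 2)
  s <- sqrt(a * (ssA + ssB))
  list(r = mA - mB, s = s)
}

## Tusher percentile search for the exchangeability constant s0: the
## percentile of s (grid 0, 5, ..., 100) minimizing the coefficient of
## variation of the MAD of d across s-quantile windows.
chooseS0 <- function(r, s) {
  qs <- quantile(s, probs = seq(0, 1, by = 0.05), names = FALSE, type = 7)
  nbin <- min(100L, max(5L, floor(length(s) / 10)))
  bins <- cut(rank(s, ties.method = "first"), breaks = nbin, labels = FALSE)
  cvs <- vapply(qs, function(s0) {
    d <- r / (s + s0)
    mads <- tapply(d, bins, mad)
    mu <- mean(mads)
    if (!is.finite(mu) || mu <= 0) return(Inf)
    sd(mads) / mu
  }, numeric(1))
  qs[which.min(cvs)]
}

#' SAM-style two-class differential expression
#'
#' Moderated two-class statistic `d = (mean_A - mean_B) / (s + s0)` where
#' `s` is the pooled standard error of the difference and `s0` is the
#' exchangeability constant chosen by the percentile search of the original
#' algorithm (minimizing the coefficient of variation of `d` across
#' `s`-quantile windows). Per-probe FDR (`q_sam`) is estimated from label
#' permutations as the median count of permuted `|d|` values exceeding each
#' observed `|d|`, divided by the observed count at that threshold, made
#' monotone and clipped to [0, 1].
#'
#' @param X numeric matrix probes x samples.
#' @param labels two-class factor/character vector over samples; `d > 0`
#'   means higher in the first class (first factor level or first unique
#'   value).
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @param s0 optional fixed exchangeability constant (bypasses the search).
#' @return list of class `sam_result` with a per-probe `table`
#'   (probe, d, s, q_sam), plus `s0` and `n_perm`.
#' @export
samScan <- function(X, labels, n_perm = 200L, seed = NULL, s0 = NULL) {
  lev <- if (is.factor(labels)) levels(droplevels(labels)) else
    unique(as.character(labels))
  labels <- as.character(labels)
  stopIfNot(length(lev) == 2, "labels must have exactly two classes")
  cls <- labels == lev[1]
  stopIfNot(sum(cls) >= 3 && sum(!cls) >= 3,
            "each class needs at least 3 samples")
  st <- samStats(X, cls)
  if (is.null(s0)) s0 <- chooseS0(st$r, st$s)
  d <- st$r / (st$s + s0)
  P <- length(d)
  thr <- sort(abs(d))  # ascending thresholds
  cnt <- matrix(NA_real_, n_perm, P)
  withSeed(seed, {
    for (b in seq_len(n_perm)) {
      lb <- sample(labels)
      stb <- samStats(X, lb == lev[1])
      db <- abs(stb$r / (stb$s + s0))
      ## #{|d*| >= thr_i} for every threshold at once
      cnt[b, ] <- P - findInterval(thr - 1e-12, sort(db))
    }
  })
  med_cnt <- apply(cnt, 2, median)
  n_ge <- P - seq_len(P) + 1  # observed #{|d| >= thr_i}
  fdr <- pmin(med_cnt / n_ge, 1)
  ## step-up: each probe gets the best achievable FDR at any threshold at
  ## or below its own |d| (monotone: larger |d| -> smaller or equal q)
  fdr <- cummin(fdr)
  q <- numeric(P)
  q[order(abs(d))] <- fdr
  tab <- data.frame(probe = if (!is.null(rownames(X))) rownames(X)
                            else as.character(seq_len(P)),
                    d = d, s = st$s, mean_diff = st$r, q_sam = q,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, s0 = s0, n_perm = n_perm,
                 classes = lev), class = "sam_result")
}

## ---------------------------------------------------------------------------
## Genome-wide error-rate correlation threshold
## ---------------------------------------------------------------------------

#' Genome-wide error-rate correlation threshold
#'
#' Permutation threshold for calling pairwise Pearson correlations
#' significant at family-wise level `alpha`: in each permutation every
#' probe's sample order is shuffled independently, the maximum absolute
#' correlation over all probe pairs is recorded, and the threshold is the
#' `1 - alpha` empirical quantile of that maximum distribution.
#'
#' @param X numeric matrix probes x samples (>= 2 probes, >= 4 samples).
#'   Zero-variance rows are excluded with a warning.
#' @param alpha family-wise error rate.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list of class `gwer_threshold` with `r_star`, `null_max`,
#'   `alpha`, `n_perm`.
#' @export
gwerCorrelationThreshold <- function(X, alpha = 0.05, n_perm = 1000L,
                                     seed = NULL) {
  stopIfNot(ncol(X) >= 4, "at least 4 samples required")
  v <- apply(X, 1, sd)
  if (any(v < 1e-12)) {
    warning(sum(v < 1e-12), " zero-variance probe row(s) excluded")
    X <- X[v >= 1e-12, , drop = FALSE]
  }
  stopIfNot(nrow(X) >= 2, "at least 2 variable probes required")
  nS <- ncol(X)
  maxes <- numeric(n_perm)
  withSeed(seed, {
    for (b in seq_len(n_perm)) {
      Xp <- X
      for (i in seq_len(nrow(X))) Xp[i, ] <- X[i, sample.int(nS)]
      cc <- cor(t(Xp))
      diag(cc) <- 0
      maxes[b] <- max(abs(cc))
    }
  })
  r_star <- unname(quantile(maxes, probs = 1 - alpha, type = 1))
  structure(list(r_star = r_star, null_max = maxes, alpha = alpha,
                 n_perm = n_perm), class = "gwer_threshold")
}
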