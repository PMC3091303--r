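## ---------------------------------------------------------------------------
## Same-host papilloma similarity analysis
## ---------------------------------------------------------------------------

#' Expression distance matrix between samples
#'
#' @param se expression `SummarizedExperiment` (or plain probes x samples
#'   matrix).
#' @param metric `"correlation"` (1 - Pearson r over probes, bounded in
#'   [0, 2]) or `"euclidean"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
expressionDistance <- function(se, metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  mat <- if (is.matrix(se)) se else log2Values(se)
  stopIfNot(ncol(mat) >= 3, "at least 3 samples required")
  if (metric == "correlation") {
    v <- apply(mat, 2, sd)
    stopIfNot(all(v > 1e-12),
              "zero-variance sample under the correlation metric")
    d <- 1 - cor(mat)
  } else {
    d <- as.matrix(dist(t(mat)))
  }
  diag(d) <- 0
  d
}

## Index of each sample's nearest other sample; ties broken by sample
## order (first minimum).
nearestNeighbors <- function(d) {
  dd <- d
  diag(dd) <- Inf
  max.col(-dd, ties.method = "first")
}

#' Same-host nearest-neighbor count
#'
#' Counts samples whose nearest other sample (by the supplied distance
#' matrix) comes from the same host animal. Distance ties are broken by
#' sample order.
#'
#' @param d distance matrix.
#' @param hosts host (animal) label per sample.
#' @return integer count.
#' @export
sameHostNNCount <- function(d, hosts) {
  stopIfNot(length(unique(hosts)) >= 2, "at least 2 hosts required")
  nn <- nearestNeighbors(d)
  sum(hosts == hosts[nn])
}

#' Mutual nearest-neighbor pair count
#'
#' Counts host pairs in which each member's nearest neighbor is the other
#' member. Hosts without exactly 2 samples are excluded with a warning.
#'
#' @param d distance matrix.
#' @param hosts host label per sample.
#' @return integer count of mutual pairs.
#' @export
mutualNearestPairCount <- function(d, hosts) {
  tab <- table(hosts)
  bad <- names(tab)[tab != 2]
  if (length(bad) > 0)
    warning("host(s) without exactly 2 samples excluded: ",
            paste(bad, collapse = ", "))
  keep <- hosts %in% names(tab)[tab == 2]
  nn <- nearestNeighbors(d)
  n_mutual <- 0L
  for (h in names(tab)[tab == 2]) {
    i <- which(hosts == h)
    if (nn[i[1]] == i[2] && nn[i[2]] == i[1]) n_mutual <- n_mutual + 1L
  }
  n_mutual
}

#' Same-host clustering permutation test
#'
#' Tests whether expression profiles from the same host are more similar
#' than expected: the distance matrix is computed once, the observed
#' same-host nearest-neighbor count `N_observed` is compared to its null
#' distribution under `n_perm` random permutations of the host labels, and
#' `p = #{N_perm >= N_observed} / n_perm`. A zero count is displayed as
#' `<1/n_perm`. Only the host partition matters, so shuffling labels is
#' equivalent to shuffling samples.
#'
#' @param se expression `SummarizedExperiment` or matrix.
#' @param hosts host label per sample (default: the `animal` column of the
#'   sample metadata).
#' @param n_perm number of label permutations (default 10,000).
#' @param seed RNG seed.
#' @param metric distance metric, see [expressionDistance()].
#' @param return_null also return the permutation null counts `N_perm`.
#' @return list of class `cluster_test` with `n_observed`,
#'   `n_pairs_mutual`, `p_perm`, `p_display`, `n_perm`, `metric`, and
#'   optionally `null_counts`.
#' @export
sameHostPermutationTest <- function(se, hosts = NULL, n_perm = 10000L,
                                    seed = NULL,
                                    metric = c("correlation", "euclidean"),
                                    return_null = FALSE) {
  metric <- match.arg(metric)
  if (is.null(hosts)) hosts <- sampleMeta(se)$animal
  stopIfNot(any(table(hosts) >= 2),
            "at least one host needs 2 or more samples")
  d <- expressionDistance(se, metric)
  nn <- nearestNeighbors(d)
  n_obs <- sum(hosts == hosts[nn])
  n <- length(hosts)
  null_counts <- withSeed(seed, {
    vapply(seq_len(n_perm), function(b) {
      hp <- hosts[sample.int(n)]
      sum(hp == hp[nn])
    }, integer(1))
  })
  p <- sum(null_counts >= n_obs) / n_perm
  tab <- table(hosts)
  n_mutual <- if (all(tab == 2)) mutualNearestPairCount(d, hosts)
              else suppressWarnings(mutualNearestPairCount(d, hosts))
  out <- list(n_observed = n_obs, n_pairs_mutual = n_mutual,
              p_perm = p, p_display = formatPermP(p, n_perm),
              n_perm = n_perm, metric = metric)
  if (return_null) out$null_counts <- null_counts
  structure(out, class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("Same-host clustering permutation test (", x$metric, " distance)\n",
      sep = "")
  cat("  N_observed =", x$n_observed, " mutual pairs =", x$n_pairs_mutual,
      "\n  p =", x$p_display, "(", x$n_perm, "permutations )\n")
  invisible(x)
}
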