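#' Pipeline configuration
#'
#' Collects the tunable constants of the analysis in one validated object.
#' Defaults follow the study design the package models: a 30 Mb cis window,
#' 10% eQTL FDR, 5% confirmation and differential-expression FDR, 1,000
#' genotype shuffles for eQTL family-wise correction, 10,000 label shuffles
#' for the same-host clustering test, log2 +/- 0.3 aCGH call cutoffs, a
#' 2-standard-deviation fold-change cutoff with clique size 3 for progression
#' networks, and 1,000,000 bins per chromosome for genome-altered fractions.
#'
#' @param cis_window_mb half-width (Mb) of the cis window around a gene.
#' @param fdr_eqtl q-value cutoff for steady-state eQTL significance.
#' @param fdr_confirm q-value cutoff in the confirmation cohort.
#' @param fdr_de SAM q cutoff for susceptibility differential expression.
#' @param n_perm_eqtl genotype shuffles for the minimal-p correction.
#' @param n_perm_cluster label shuffles for the same-host test.
#' @param n_perm_gwer permutations for the genome-wide error-rate
#'   correlation threshold.
#' @param cnv_cutoff_log2 aCGH amplification/deletion cutoff (inclusive).
#' @param sd_multiplier fold-change SD multiplier for extreme-change probes.
#' @param clique_min minimum clique size for progression-network nodes.
#' @param bins_per_chromosome bins used for fraction-genome-altered.
#' @param seed master seed for all permutation machinery.
#' @return A validated list of class `rewire_config`.
#' @export
rewireConfig <- function(cis_window_mb = 30, fdr_eqtl = 0.10,
                         fdr_confirm = 0.05, fdr_de = 0.05,
                         n_perm_eqtl = 1000L, n_perm_cluster = 10000L,
                         n_perm_gwer = 1000L, cnv_cutoff_log2 = 0.3,
                         sd_multiplier = 2, clique_min = 3L,
                         bins_per_chromosome = 1000000L, seed = 1L) {
  cfg <- list(cis_window_mb = cis_window_mb, fdr_eqtl = fdr_eqtl,
              fdr_confirm = fdr_confirm, fdr_de = fdr_de,
              n_perm_eqtl = as.integer(n_perm_eqtl),
              n_perm_cluster = as.integer(n_perm_cluster),
              n_perm_gwer = as.integer(n_perm_gwer),
              cnv_cutoff_log2 = cnv_cutoff_log2,
              sd_multiplier = sd_multiplier,
              clique_min = as.integer(clique_min),
              bins_per_chromosome = as.integer(bins_per_chromosome),
              seed = as.integer(seed))
  for (f in c("fdr_eqtl", "fdr_confirm", "fdr_de"))
    stopIfNot(cfg[[f]] > 0 && cfg[[f]] < 1,
              paste(f, "must be in (0, 1)"))
  for (f in c("n_perm_eqtl", "n_perm_cluster", "n_perm_gwer"))
    stopIfNot(cfg[[f]] >= 100L, paste(f, "must be at least 100"))
  stopIfNot(cfg$cis_window_mb > 0, "cis_window_mb must be positive")
  stopIfNot(cfg$cnv_cutoff_log2 > 0, "cnv_cutoff_log2 must be positive")
  stopIfNot(cfg$sd_multiplier > 0, "sd_multiplier must be positive")
  stopIfNot(cfg$clique_min >= 1L, "clique_min must be >= 1")
  stopIfNot(cfg$bins_per_chromosome >= 1L, "bins_per_chromosome must be >= 1")
  class(cfg) <- "rewire_config"
  cfg
}

#' @export
print.rewire_config <- function(x, ...) {
  cat("rewire_config:\n")
  for (f in names(x)) cat(sprintf("  %-20s %s\n", f, format(x[[f]])))
  invisible(x)
}
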