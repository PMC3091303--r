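## ---------------------------------------------------------------------------
## Tissue-level eQTL mapping and cross-tissue architecture analyses
## ---------------------------------------------------------------------------

#' Combine papilloma pairs by averaging
#'
#' Pairs of papillomas from the same animal are combined for eQTL analysis
#' using the mean expression of each probe; singleton papillomas pass
#' through unchanged.
#'
#' @param se papilloma expression `SummarizedExperiment`.
#' @return `SummarizedExperiment` with one column per animal.
#' @export
combinePapillomaPairs <- function(se) {
  meta <- sampleMeta(se)
  stopIfNot(all(meta$tissue == "PAPILLOMA"),
            "combinePapillomaPairs expects papilloma samples")
  tab <- table(meta$animal)
  stopIfNot(all(tab <= 2),
            paste("more than 2 papillomas for animal(s):",
                  paste(names(tab)[tab > 2], collapse = ", ")))
  mat <- log2Values(se)
  animals <- unique(meta$animal)
  out <- vapply(animals, function(a) {
    rowMeans(mat[, meta$animal == a, drop = FALSE])
  }, numeric(nrow(mat)))
  colnames(out) <- paste0(animals, "_P")
  expressionExperiment(out, probeAnnotation(se),
                       data.frame(animal = animals, tissue = "PAPILLOMA",
                                  cohort = meta$cohort[match(animals,
                                                             meta$animal)],
                                  stringsAsFactors = FALSE))
}

#' Classify eQTL as cis or trans
#'
#' An eQTL is cis when its peak marker lies on the same chromosome as the
#' gene and within `window` Mb of it (closed interval: a distance exactly
#' equal to the window is cis); otherwise trans. Genes without a genomic
#' position are `UNPLACED`.
#'
#' @param gene_chr,gene_mb gene position (vectors allowed).
#' @param marker_chr,marker_mb peak marker position.
#' @param window cis window half-width in Mb (default 30).
#' @return character vector in `{CIS, TRANS, UNPLACED}`.
#' @export
classifyCisTrans <- function(gene_chr, gene_mb, marker_chr, marker_mb,
                             window = 30) {
  out <- ifelse(is.na(gene_chr) | is.na(gene_mb), "UNPLACED",
                ifelse(as.character(gene_chr) == as.character(marker_chr) &
                         abs(gene_mb - marker_mb) <= window, "CIS", "TRANS"))
  out
}

## Core mapping on a plain matrix (probes x animals). Column names must be
## animal ids present in the genotypes.
mapMatrix <- function(values, annotation, genotypes, config, tissue) {
  animals <- colnames(values)
  calls <- genotypeCalls(genotypes)
  stopIfNot(all(animals %in% rownames(calls)),
            "every sample animal must be genotyped")
  map <- markerMap(genotypes)
  G <- calls[animals, , drop = FALSE]
  Y <- t(values)
  res <- permutationCorrectedP(Y, G, n_perm = config$n_perm_eqtl,
                               seed = config$seed)
  ann <- annotation[match(rownames(values), annotation$probe), , drop = FALSE]
  peak <- res$peak_index
  corrected <- res$corrected_p
  ## zero permutation ranks go into the q-value machinery as 1/(2 n_perm)
  q_in <- ifelse(corrected <= 0, 1 / (2 * config$n_perm_eqtl), corrected)
  qres <- storeyQvalues(q_in)
  records <- data.frame(
    probe = rownames(values),
    gene = ann$gene,
    gene_chr = ann$chr,
    gene_mb = ann$mb,
    peak_marker = map$marker[peak],
    peak_chr = map$chr[peak],
    peak_mb = map$mb[peak],
    p_raw = res$p_minimal_obs,
    p_perm = corrected,
    q = qres$q_out,
    cis_trans = classifyCisTrans(ann$chr, ann$mb, map$chr[peak],
                                 map$mb[peak], config$cis_window_mb),
    tissue = tissue,
    stringsAsFactors = FALSE)
  records$significant <- records$q <= config$fdr_eqtl
  attr(records, "pi0_hat") <- qres$pi0_hat
  attr(records, "n_perm") <- config$n_perm_eqtl
  records
}

#' Map eQTL in one tissue
#'
#' Per probe: a single-marker regression scan over all markers, minimal-p
#' permutation correction with shared genotype shuffles, Storey q-values
#' over the corrected p-values of all probes, significance at
#' `config$fdr_eqtl`, and cis/trans classification of the peak.
#' Papilloma matrices must be pair-combined first
#' ([combinePapillomaPairs()]): samples must map 1:1 to genotyped animals.
#'
#' @param se expression `SummarizedExperiment`.
#' @param genotypes a [GenotypeSet()].
#' @param config a [rewireConfig()].
#' @param tissue tissue label stored in the records (default: from the
#'   sample metadata).
#' @return data.frame of eQTL records (one per probe) with columns probe,
#'   gene, gene_chr, gene_mb, peak_marker, peak_chr, peak_mb, p_raw,
#'   p_perm, q, cis_trans, tissue, significant; attributes `pi0_hat` and
#'   `n_perm`.
#' @export
mapEqtl <- function(se, genotypes, config = rewireConfig(), tissue = NULL) {
  meta <- sampleMeta(se)
  stopIfNot(!anyDuplicated(meta$animal),
            "samples must map 1:1 to animals (combine papilloma pairs first)")
  if (is.null(tissue)) tissue <- meta$tissue[1]
  values <- log2Values(se)
  colnames(values) <- meta$animal
  mapMatrix(values, probeAnnotation(se), genotypes, config, tissue)
}

#' Cis/trans ratio of significant eQTL
#'
#' @param records eQTL record data.frame.
#' @param include_x include X-linked genes (default FALSE: ratio summaries
#'   are restricted to autosomes).
#' @return list with `n_cis`, `n_trans`, `ratio` (Inf when no trans).
#' @export
cisTransRatio <- function(records, include_x = FALSE) {
  r <- records[records$significant & records$cis_trans != "UNPLACED", ,
               drop = FALSE]
  if (!include_x) r <- r[r$gene_chr != "X", , drop = FALSE]
  n_cis <- sum(r$cis_trans == "CIS")
  n_trans <- sum(r$cis_trans == "TRANS")
  list(n_cis = n_cis, n_trans = n_trans,
       ratio = if (n_trans == 0) Inf else n_cis / n_trans)
}

#' Cross-tissue eQTL conservation
#'
#' An eQTL of tissue A is conserved when its probe also has a significant
#' eQTL in tissue B (the peak may move; `strict_peak = TRUE` additionally
#' requires the same peak chromosome). Tests whether conservation is
#' associated with expression stability (|fold-change - mean| within
#' `sd_multiplier` SDs; Fisher exact test on the 2x2 table) and whether
#' conserved eQTL were stronger in tissue A (Wilcoxon rank-sum on -log10
#' corrected p). Per-chromosome conserved fractions are reported for
#' autosomes.
#'
#' @param records_a,records_b eQTL records of the two tissues (same probe
#'   universe).
#' @param fold_change named per-probe mean fold-change vector.
#' @param sd_multiplier stability cutoff in SDs of the mean fold-change.
#' @param strict_peak require the conserved eQTL to peak on the same
#'   chromosome.
#' @return list of class `conservation_summary`.
#' @export
compareConservation <- function(records_a, records_b, fold_change,
                                sd_multiplier = 2, strict_peak = FALSE) {
  sig_a <- records_a[records_a$significant, , drop = FALSE]
  stopIfNot(nrow(sig_a) > 0, "no significant eQTL in tissue A")
  sig_b <- records_b[records_b$significant, , drop = FALSE]
  conserved <- sig_a$probe %in% sig_b$probe
  if (strict_peak) {
    bchr <- sig_b$peak_chr[match(sig_a$probe, sig_b$probe)]
    conserved <- conserved & !is.na(bchr) & bchr == sig_a$peak_chr
  }
  fc <- fold_change[sig_a$probe]
  stable <- abs(fc - mean(fold_change, na.rm = TRUE)) <=
    sd_multiplier * sd(fold_change, na.rm = TRUE)
  tab <- table(factor(conserved, c(FALSE, TRUE)),
               factor(stable, c(FALSE, TRUE)),
               dnn = c("conserved", "stable"))
  fish <- fisher.test(tab)
  n_perm <- attr(records_a, "n_perm")
  floor_p <- if (is.null(n_perm)) 1e-6 else 1 / (2 * n_perm)
  strength <- -log10(pmax(sig_a$p_perm, floor_p))
  wil <- if (any(conserved) && any(!conserved))
    wilcox.test(strength[conserved], strength[!conserved],
                alternative = "greater", exact = FALSE)$p.value
  else NA_real_
  auto <- sig_a$gene_chr != "X"
  per_chrom <- do.call(rbind, lapply(as.character(1:19), function(ch) {
    i <- which(auto & sig_a$gene_chr == ch)
    data.frame(chr = ch, n_eqtl = length(i),
               frac_conserved = if (length(i)) mean(conserved[i]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(conserved = setNames(conserved, sig_a$probe),
                 fraction_conserved = mean(conserved),
                 table = tab, fisher_odds_ratio = unname(fish$estimate),
                 fisher_p = fish$p.value, wilcox_p = wil,
                 per_chromosome = per_chrom),
            class = "conservation_summary")
}

#' Probes expressed above background
#'
#' A probe is above background in a tissue when its median log2 value
#' exceeds a threshold; the default threshold is the 25th percentile of
#' the distribution of all-probe medians of that matrix.
#'
#' @param se expression `SummarizedExperiment`.
#' @param threshold optional fixed log2 threshold.
#' @return list with `above` (named logical) and `threshold`.
#' @export
aboveBackground <- function(se, threshold = NULL) {
  med <- apply(log2Values(se), 1, median)
  if (is.null(threshold)) threshold <- unname(quantile(med, 0.25))
  list(above = med > threshold, threshold = threshold)
}

#' Tumor-specific eQTL
#'
#' Records significant in the tumor tissue whose probe has no significant
#' eQTL in normal skin; a second subset flags those whose transcript is
#' not expressed above background in skin at all ("expressed only in
#' tumors").
#'
#' @param tumor_records,skin_records eQTL records of the two tissues.
#' @param skin_se optional skin expression matrix for the expression gate.
#' @param background_threshold optional fixed background threshold.
#' @return list with `tumor_specific` (record subset),
#'   `expressed_only_in_tumor` (subset of those), `background_threshold`.
#' @export
tumorSpecificEqtl <- function(tumor_records, skin_records, skin_se = NULL,
                              background_threshold = NULL) {
  sig_t <- tumor_records[tumor_records$significant, , drop = FALSE]
  sig_s <- skin_records$probe[skin_records$significant]
  specific <- sig_t[!(sig_t$probe %in% sig_s), , drop = FALSE]
  gated <- specific[0, , drop = FALSE]
  thr <- background_threshold
  if (!is.null(skin_se)) {
    bg <- aboveBackground(skin_se, background_threshold)
    thr <- bg$threshold
    low <- names(bg$above)[!bg$above]
    gated <- specific[specific$probe %in% low, , drop = FALSE]
  }
  list(tumor_specific = specific, expressed_only_in_tumor = gated,
       background_threshold = thr)
}

#' Perturbation eQTL scan
#'
#' Maps eQTL whose phenotype is the per-animal change in expression
#' between matched normal skin and carcinoma rather than a steady-state
#' level. Only probes expressed above background in both tissues and
#' without a significant steady-state eQTL in either tissue are scanned;
#' the trans fraction of the significant records is reported.
#'
#' @param skin_se,carcinoma_se matched expression matrices.
#' @param genotypes a [GenotypeSet()].
#' @param skin_records,carcinoma_records steady-state eQTL records used
#'   for the exclusion filter.
#' @param config a [rewireConfig()].
#' @param background_threshold optional fixed background threshold.
#' @return list with `records`, `n_tested`, `n_significant`,
#'   `trans_fraction`, and `matched_animals`.
#' @export
perturbationEqtlScan <- function(skin_se, carcinoma_se, genotypes,
                                 skin_records, carcinoma_records,
                                 config = rewireConfig(),
                                 background_threshold = NULL) {
  ms <- sampleMeta(skin_se)
  mc <- sampleMeta(carcinoma_se)
  matched <- intersect(ms$animal, mc$animal)
  stopIfNot(length(matched) > 0, "no matched animals")
  skin_m <- log2Values(skin_se)[, match(matched, ms$animal), drop = FALSE]
  carc_m <- log2Values(carcinoma_se)[, match(matched, mc$animal),
                                     drop = FALSE]
  common <- intersect(rownames(skin_m), rownames(carc_m))
  fc <- carc_m[common, , drop = FALSE] - skin_m[common, , drop = FALSE]
  colnames(fc) <- matched
  bg_s <- aboveBackground(skin_se, background_threshold)
  bg_c <- aboveBackground(carcinoma_se, background_threshold)
  steady <- union(skin_records$probe[skin_records$significant],
                  carcinoma_records$probe[carcinoma_records$significant])
  keep <- common[bg_s$above[common] & bg_c$above[common] &
                   !(common %in% steady)]
  stopIfNot(length(keep) > 0, "no probes pass the perturbation filter")
  records <- mapMatrix(fc[keep, , drop = FALSE],
                       probeAnnotation(skin_se), genotypes, config,
                       tissue = "PERTURBATION")
  sig <- records[records$significant & records$cis_trans != "UNPLACED", ,
                 drop = FALSE]
  list(records = records, n_tested = length(keep), n_significant = nrow(sig),
       trans_fraction = if (nrow(sig)) mean(sig$cis_trans == "TRANS")
                        else NA_real_,
       matched_animals = matched)
}

#' Confirm discovery eQTL in an independent cohort
#'
#' Each discovery record is re-tested by one regression of the probe's
#' expression on its discovery peak marker in the confirmation cohort (no
#' re-scan, so no multiplicity over markers); q-values are computed on
#' exactly this set of p-values and records confirm at
#' `config$fdr_confirm`. Probes absent from the confirmation matrix are
#' marked untestable and excluded from the q-value set.
#'
#' @param records discovery eQTL records (typically the significant ones).
#' @param conf_se confirmation expression `SummarizedExperiment` (one
#'   sample per animal).
#' @param conf_genotypes confirmation [GenotypeSet()].
#' @param config a [rewireConfig()].
#' @return `records` with added columns `confirm_p`, `confirm_q`,
#'   `confirmed`, `untestable`; attribute `pi0_hat`.
#' @export
confirmEqtl <- function(records, conf_se, conf_genotypes,
                        config = rewireConfig()) {
  meta <- sampleMeta(conf_se)
  stopIfNot(!anyDuplicated(meta$animal),
            "confirmation samples must map 1:1 to animals")
  calls <- genotypeCalls(conf_genotypes)
  stopIfNot(all(records$peak_marker %in% colnames(calls)),
            "discovery peak markers must be genotyped in the confirmation cohort")
  stopIfNot(all(meta$animal %in% rownames(calls)),
            "confirmation animals must be genotyped")
  mat <- log2Values(conf_se)
  colnames(mat) <- meta$animal
  g_all <- calls[meta$animal, , drop = FALSE]
  records$untestable <- !(records$probe %in% rownames(mat))
  records$confirm_p <- NA_real_
  testable <- which(!records$untestable)
  for (i in testable) {
    records$confirm_p[i] <- markerRegressionP(
      mat[records$probe[i], ], g_all[, records$peak_marker[i]])$p
  }
  records$confirm_q <- NA_real_
  if (length(testable)) {
    qres <- storeyQvalues(records$confirm_p[testable])
    records$confirm_q[testable] <- qres$q_out
    attr(records, "pi0_hat") <- qres$pi0_hat
  }
  records$confirmed <- !records$untestable &
    records$confirm_q <= config$fdr_confirm
  records
}

#' QTL scan of papilloma counts
#'
#' Classical QTL analysis of the papilloma burden phenotype: per-marker
#' regression of `log(count + 1)` on genotype, with the same minimal-p
#' permutation family-wise correction as the eQTL scans.
#'
#' @param phenotype data.frame with columns `animal` and
#'   `papilloma_count_wk20`.
#' @param genotypes a [GenotypeSet()].
#' @param n_perm permutations for the family-wise correction.
#' @param seed RNG seed.
#' @return list with `per_marker_p`, `peak_marker`, `peak_chr`, `peak_mb`,
#'   `p_minimal_obs`, `corrected_p`.
#' @export
papillomaCountQtl <- function(phenotype, genotypes, n_perm = 1000L,
                              seed = NULL) {
  counts <- phenotype$papilloma_count_wk20
  stopIfNot(all(counts >= 0), "papilloma counts must be nonnegative")
  stopIfNot(length(unique(counts)) > 1, "all papilloma counts are equal")
  calls <- genotypeCalls(genotypes)
  stopIfNot(all(phenotype$animal %in% rownames(calls)),
            "phenotyped animals must be genotyped")
  y <- log(counts + 1)
  G <- calls[phenotype$animal, , drop = FALSE]
  res <- permutationCorrectedP(matrix(y, ncol = 1), G, n_perm = n_perm,
                               seed = seed)
  map <- markerMap(genotypes)
  k <- res$peak_index[1]
  list(per_marker_p = res$per_marker_p[1, ], peak_marker = map$marker[k],
       peak_chr = map$chr[k], peak_mb = map$mb[k],
       p_minimal_obs = res$p_minimal_obs[1],
       corrected_p = res$corrected_p[1])
}
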