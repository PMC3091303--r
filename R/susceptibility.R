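## ---------------------------------------------------------------------------
## Susceptibility classification, differential expression, candidate table
## ---------------------------------------------------------------------------

#' Classify animals by papilloma burden
#'
#' SUSCEPTIBLE for more than 7 papillomas at week 20, RESISTANT for fewer
#' than 2, INTERMEDIATE otherwise (2-7 inclusive; excluded from
#' differential expression).
#'
#' @param counts nonnegative integer vector of week-20 papilloma counts
#'   (or a phenotype data.frame with column `papilloma_count_wk20`).
#' @return character vector of classes.
#' @export
classifySusceptibility <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$papilloma_count_wk20
  stopIfNot(all(counts >= 0), "counts must be nonnegative")
  ifelse(counts > 7, "SUSCEPTIBLE",
         ifelse(counts < 2, "RESISTANT", "INTERMEDIATE"))
}

#' Susceptibility differential expression (SAM)
#'
#' SAM contrast of papilloma expression between resistant and susceptible
#' animals (intermediate animals excluded). Papilloma pairs are averaged
#' per animal first (disable with `combine_pairs = FALSE`). The signed
#' fold-change follows the candidate-table convention: negative means
#' higher in resistant animals.
#'
#' @param papilloma_se papilloma expression `SummarizedExperiment`.
#' @param phenotype data.frame with `animal` and `papilloma_count_wk20`
#'   (or a precomputed `susceptibility_class` column).
#' @param config a [rewireConfig()]; `fdr_de` is the SAM q cutoff and
#'   `seed` drives the label permutations.
#' @param n_perm SAM label permutations.
#' @param combine_pairs average papilloma pairs per animal first.
#' @return data.frame per probe: probe, gene, d, q_sam, fold_change
#'   (signed linear scale), higher_in, significant; attribute `s0`.
#' @export
susceptibilityDe <- function(papilloma_se, phenotype,
                             config = rewireConfig(), n_perm = 200L,
                             combine_pairs = TRUE) {
  se <- if (combine_pairs) combinePapillomaPairs(papilloma_se) else
    papilloma_se
  meta <- sampleMeta(se)
  cls <- if (!is.null(phenotype$susceptibility_class))
    phenotype$susceptibility_class else
    classifySusceptibility(phenotype)
  cls <- cls[match(meta$animal, phenotype$animal)]
  keep <- !is.na(cls) & cls != "INTERMEDIATE"
  stopIfNot(sum(cls[keep] == "RESISTANT") >= 3 &&
              sum(cls[keep] == "SUSCEPTIBLE") >= 3,
            "need at least 3 animals per susceptibility class")
  mat <- log2Values(se)[, keep, drop = FALSE]
  labels <- factor(cls[keep], levels = c("SUSCEPTIBLE", "RESISTANT"))
  sam <- samScan(mat, labels, n_perm = n_perm, seed = config$seed)
  tab <- sam$table
  ## d > 0 means higher in susceptible; Table-1 sign convention:
  ## negative fold-change = higher in resistant
  lfc <- tab$mean_diff
  out <- data.frame(probe = tab$probe,
                    gene = probeAnnotation(se)$gene[match(tab$probe,
                                                          rownames(mat))],
                    d = tab$d, q_sam = tab$q_sam,
                    fold_change = ifelse(lfc >= 0, 2^lfc, -(2^(-lfc))),
                    higher_in = ifelse(lfc >= 0, "SUSCEPTIBLE",
                                       "RESISTANT"),
                    stringsAsFactors = FALSE)
  out$significant <- out$q_sam <= config$fdr_de
  attr(out, "s0") <- sam$s0
  out
}

#' Candidate susceptibility gene table
#'
#' Intersects the susceptibility-associated probes (SAM significant) with
#' the tumor-specific eQTL set and emits a candidate table: gene position,
#' signed fold-change (negative = higher in resistant), SAM q (percent),
#' which class and which genotype the gene is higher in (mean papilloma
#' expression of HET versus HOM_FVB animals at the record's peak marker),
#' and the eQTL locus position. Rows are sorted most resistant-elevated
#' first.
#'
#' @param de_results output of [susceptibilityDe()].
#' @param tumor_specific_records tumor-specific eQTL record subset (see
#'   [tumorSpecificEqtl()]).
#' @param genotypes a [GenotypeSet()].
#' @param papilloma_se papilloma expression used for the genotype-mean
#'   comparison (pairs are averaged per animal).
#' @return data.frame shaped like the published candidate table: columns
#'   gene, probe, chr, mb, fold_change, q_pct, higher_in,
#'   higher_genotype, eqtl_chr, eqtl_mb.
#' @export
candidateGeneTable <- function(de_results, tumor_specific_records,
                               genotypes, papilloma_se) {
  sig_de <- de_results[de_results$significant, , drop = FALSE]
  recs <- tumor_specific_records
  common <- intersect(sig_de$probe, recs$probe)
  if (length(common) == 0) {
    return(data.frame(gene = character(), probe = character(),
                      chr = character(), mb = numeric(),
                      fold_change = numeric(), q_pct = numeric(),
                      higher_in = character(), higher_genotype = character(),
                      eqtl_chr = character(), eqtl_mb = numeric(),
                      stringsAsFactors = FALSE))
  }
  se <- combinePapillomaPairs(papilloma_se)
  meta <- sampleMeta(se)
  calls <- genotypeCalls(genotypes)
  mat <- log2Values(se)
  de_i <- match(common, de_results$probe)
  rec_i <- match(common, recs$probe)
  higher_geno <- vapply(seq_along(common), function(k) {
    g <- calls[meta$animal, recs$peak_marker[rec_i[k]]]
    y <- mat[common[k], ]
    ok <- !is.na(g)
    m_het <- mean(y[ok & g == 1L])
    m_hom <- mean(y[ok & g == 0L])
    if (is.nan(m_het) || is.nan(m_hom)) NA_character_
    else if (m_het >= m_hom) "HET" else "HOM"
  }, character(1))
  out <- data.frame(gene = recs$gene[rec_i], probe = common,
                    chr = recs$gene_chr[rec_i], mb = recs$gene_mb[rec_i],
                    fold_change = de_results$fold_change[de_i],
                    q_pct = 100 * de_results$q_sam[de_i],
                    higher_in = de_results$higher_in[de_i],
                    higher_genotype = higher_geno,
                    eqtl_chr = recs$peak_chr[rec_i],
                    eqtl_mb = recs$peak_mb[rec_i],
                    stringsAsFactors = FALSE)
  out <- out[order(out$fold_change), , drop = FALSE]
  rownames(out) <- NULL
  out
}
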