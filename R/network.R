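## ---------------------------------------------------------------------------
## Skin -> tumor progression networks
## ---------------------------------------------------------------------------

#' Matched tumor - skin fold changes
#'
#' Per-animal, per-probe log2 difference between tumor and matched normal
#' skin expression. Animals without both tissues are dropped (and
#' reported). Papilloma matrices should be pair-combined first.
#'
#' @param tumor_se,skin_se expression `SummarizedExperiment`s with one
#'   sample per animal.
#' @param center_samples optionally median-center each sample first (for
#'   inputs not normalized together).
#' @return `SummarizedExperiment` with assay `fc` (probes x matched
#'   animals).
#' @export
matchedFoldChange <- function(tumor_se, skin_se, center_samples = FALSE) {
  mt <- sampleMeta(tumor_se)
  ms <- sampleMeta(skin_se)
  matched <- intersect(mt$animal, ms$animal)
  stopIfNot(length(matched) > 0, "no matched animals")
  if (length(matched) < 4)
    warning("fewer than 4 matched animals")
  dropped <- length(union(mt$animal, ms$animal)) - length(matched)
  if (dropped > 0)
    message(dropped, " animal(s) without both tissues dropped")
  tm <- log2Values(tumor_se)[, match(matched, mt$animal), drop = FALSE]
  sm <- log2Values(skin_se)[, match(matched, ms$animal), drop = FALSE]
  if (center_samples) {
    tm <- sweep(tm, 2, apply(tm, 2, median))
    sm <- sweep(sm, 2, apply(sm, 2, median))
  }
  common <- intersect(rownames(tm), rownames(sm))
  fc <- tm[common, , drop = FALSE] - sm[common, , drop = FALSE]
  colnames(fc) <- matched
  ann <- probeAnnotation(tumor_se)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fc = fc),
    rowData = S4Vectors::DataFrame(
      ann[match(common, ann$probe), c("gene", "chr", "mb")],
      row.names = common),
    colData = S4Vectors::DataFrame(animal = matched, tissue = "FOLD_CHANGE",
                                   cohort = mt$cohort[match(matched,
                                                            mt$animal)],
                                   row.names = matched))
  se
}

#' Probes with extreme mean fold-change
#'
#' Selects probes whose mean fold-change deviates from the global mean of
#' mean fold-changes by more than `sd_multiplier` global standard
#' deviations, with an UP/DOWN direction relative to the global mean.
#'
#' @param fc_se fold-change `SummarizedExperiment` from
#'   [matchedFoldChange()].
#' @param sd_multiplier cutoff in global SDs (default 2).
#' @return data.frame with columns `probe`, `gene`, `mean_fc`,
#'   `direction`; attributes `global_mean`, `global_sd`.
#' @export
extremeChangeProbes <- function(fc_se, sd_multiplier = 2) {
  fc <- SummarizedExperiment::assay(fc_se, 1L)
  if (nrow(fc) < 20)
    warning("fewer than 20 probes: global SD may be unstable")
  mean_fc <- rowMeans(fc)
  gm <- mean(mean_fc)
  gsd <- sd(mean_fc)
  if (!is.finite(gsd) || gsd <= 0) {
    warning("zero global fold-change SD: no probe is extreme")
    gsd <- Inf
  }
  sel <- abs(mean_fc - gm) > sd_multiplier * gsd
  rd <- SummarizedExperiment::rowData(fc_se)
  out <- data.frame(probe = rownames(fc)[sel],
                    gene = rd$gene[sel],
                    mean_fc = mean_fc[sel],
                    direction = ifelse(mean_fc[sel] > gm, "UP", "DOWN"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "global_mean") <- gm
  attr(out, "global_sd") <- gsd
  out
}

## Keep only nodes belonging to a clique of size >= clique_min in the
## thresholded graph. For clique_min = 3 this is exactly triangle
## membership (any node of a k-clique, k >= 3, is in a triangle).
cliqueFilterNodes <- function(edges, nodes, clique_min) {
  if (clique_min <= 2 || nrow(edges) == 0) {
    keep <- if (clique_min <= 1) nodes else
      nodes[nodes %in% c(edges$from, edges$to)]
    return(keep)
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE, vertices = nodes)
  if (clique_min == 3) {
    keep <- nodes[igraph::count_triangles(g) > 0]
  } else {
    cl <- igraph::cliques(g, min = clique_min)
    keep <- unique(names(unlist(cl)))
  }
  keep
}

#' Build the progression co-expression network
#'
#' Over the extreme-fold-change probes: pairwise Pearson correlations of
#' per-animal fold-changes, an edge wherever |r| meets the genome-wide
#' error-rate threshold at level `alpha` (sign DIRECT/INVERSE), and nodes
#' filtered to membership in a clique of size >= `clique_min` (triangle
#' membership for the default 3). Edge signs survive the filtering.
#'
#' @param fc_se fold-change `SummarizedExperiment`.
#' @param extreme optional precomputed [extremeChangeProbes()] table.
#' @param alpha family-wise level of the correlation threshold.
#' @param n_perm permutations for the threshold.
#' @param clique_min minimum clique size for retained nodes.
#' @param sd_multiplier forwarded to [extremeChangeProbes()] when
#'   `extreme` is NULL.
#' @param seed RNG seed.
#' @return list of class `progression_network` with `nodes` (probe, gene,
#'   mean_fc, direction), `edges` (from, to, r, sign), `r_star`,
#'   `clique_min`.
#' @export
buildProgressionNetwork <- function(fc_se, extreme = NULL, alpha = 0.05,
                                    n_perm = 1000L, clique_min = 3L,
                                    sd_multiplier = 2, seed = NULL) {
  if (is.null(extreme))
    extreme <- extremeChangeProbes(fc_se, sd_multiplier)
  stopIfNot(nrow(extreme) > 0, "extreme probe set is empty")
  fc <- SummarizedExperiment::assay(fc_se, 1L)[extreme$probe, , drop = FALSE]
  thr <- gwerCorrelationThreshold(fc, alpha = alpha, n_perm = n_perm,
                                  seed = seed)
  cc <- cor(t(fc))
  diag(cc) <- 0
  idx <- which(abs(cc) >= thr$r_star & upper.tri(cc), arr.ind = TRUE)
  edges <- data.frame(from = rownames(cc)[idx[, 1]],
                      to = colnames(cc)[idx[, 2]],
                      r = cc[idx],
                      sign = ifelse(cc[idx] >= 0, "DIRECT", "INVERSE"),
                      stringsAsFactors = FALSE)
  keep <- cliqueFilterNodes(edges, extreme$probe, clique_min)
  nodes <- extreme[extreme$probe %in% keep, , drop = FALSE]
  edges <- edges[edges$from %in% keep & edges$to %in% keep, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, r_star = thr$r_star,
                 clique_min = clique_min, alpha = alpha),
            class = "progression_network")
}

#' @export
print.progression_network <- function(x, ...) {
  cat("progression_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (|r| >=", signif(x$r_star, 3), ", clique >=", x$clique_min,
      ")\n")
  invisible(x)
}

#' Build a locus-anchored eQTL network
#'
#' The network of genes whose significant eQTL peak at a shared locus:
#' gene nodes are the probes whose peak marker lies within
#' `tolerance_mb` of the locus marker on its chromosome, each with a
#' locus -> gene edge; gene-gene edges use the genome-wide error-rate
#' correlation criterion on the expression of those probes. The cis genes
#' at the locus are flagged as candidate drivers.
#'
#' @param locus_marker marker id anchoring the network.
#' @param records significant eQTL records of the tissue.
#' @param se expression matrix of the same tissue (pair-combined for
#'   papillomas).
#' @param genotypes [GenotypeSet()] holding the marker map.
#' @param tolerance_mb how far (Mb) a peak may sit from the locus marker
#'   (default 5).
#' @param alpha,n_perm,seed correlation-threshold parameters.
#' @return list of class `locus_network` with `nodes`, `edges` (locus and
#'   correlation edges), `cis_genes`, `r_star`.
#' @export
buildLocusNetwork <- function(locus_marker, records, se, genotypes,
                              tolerance_mb = 5, alpha = 0.05,
                              n_perm = 1000L, seed = NULL) {
  map <- markerMap(genotypes)
  stopIfNot(locus_marker %in% map$marker, "locus marker not in marker map")
  lchr <- map$chr[map$marker == locus_marker]
  lmb <- map$mb[map$marker == locus_marker]
  sig <- records[records$significant, , drop = FALSE]
  hit <- sig$peak_chr == lchr & abs(sig$peak_mb - lmb) <= tolerance_mb
  stopIfNot(any(hit), "no significant eQTL linked to this locus")
  genes <- sig[hit, , drop = FALSE]
  cis_genes <- genes$probe[genes$cis_trans == "CIS"]
  locus_edges <- data.frame(from = locus_marker, to = genes$probe,
                            r = NA_real_, sign = "EQTL", type = "locus",
                            stringsAsFactors = FALSE)
  corr_edges <- data.frame(from = character(), to = character(),
                           r = numeric(), sign = character(),
                           type = character(), stringsAsFactors = FALSE)
  r_star <- NA_real_
  if (nrow(genes) >= 2) {
    mat <- log2Values(se)[genes$probe, , drop = FALSE]
    thr <- gwerCorrelationThreshold(mat, alpha = alpha, n_perm = n_perm,
                                    seed = seed)
    r_star <- thr$r_star
    cc <- cor(t(mat))
    diag(cc) <- 0
    idx <- which(abs(cc) >= r_star & upper.tri(cc), arr.ind = TRUE)
    if (nrow(idx)) {
      corr_edges <- data.frame(from = rownames(cc)[idx[, 1]],
                               to = colnames(cc)[idx[, 2]],
                               r = cc[idx],
                               sign = ifelse(cc[idx] >= 0, "DIRECT",
                                             "INVERSE"),
                               type = "correlation",
                               stringsAsFactors = FALSE)
    }
  }
  nodes <- data.frame(node = c(locus_marker, genes$probe),
                      kind = c("locus", ifelse(genes$probe %in% cis_genes,
                                               "cis_gene", "trans_gene")),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes,
                 edges = rbind(locus_edges, corr_edges),
                 cis_genes = cis_genes, locus_marker = locus_marker,
                 r_star = r_star),
            class = "locus_network")
}
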