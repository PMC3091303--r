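## ---------------------------------------------------------------------------
## Tab-delimited readers/writers. Dialect: UTF-8 TSV, "NA" for missing,
## first column is the row identifier.
## ---------------------------------------------------------------------------

#' Read an expression matrix with probe annotation
#'
#' Reads a probes x samples log2 expression TSV (first column `probe`,
#' header names the samples) and a probe annotation TSV (`probe`, `gene`,
#' `chr`, `mb`). Probes whose gene mapping is missing or `UNANNOTATED` are
#' dropped before analysis (the count is reported), mirroring the removal
#' of probesets not mapped to an annotated RefSeq gene.
#'
#' @param path expression TSV.
#' @param annotation_path probe annotation TSV.
#' @param meta_path optional sample metadata TSV (`sample`, `animal`,
#'   `tissue`, `cohort`). When absent, samples are treated as one SKIN
#'   sample per animal named by the column header.
#' @return A `SummarizedExperiment` (see [expressionExperiment()]).
#' @export
readExpression <- function(path, annotation_path, meta_path = NULL) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopIfNot(ncol(raw) >= 2, "expression file needs probe + sample columns")
  probes <- as.character(raw[[1]])
  dup <- probes[duplicated(probes)]
  stopIfNot(length(dup) == 0,
            paste("duplicate probe_id:", paste(unique(dup), collapse = ", ")))
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppress <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(suppress) & !is.na(col) & col != "NA")
      stopIfNot(length(bad) == 0,
                sprintf("non-numeric expression value at row %d, column '%s'",
                        bad[1], names(vals)[j]))
      vals[[j]] <- suppress
    }
  }
  mat <- as.matrix(vals)
  rownames(mat) <- probes
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE)
  ann$chr <- as.character(ann$chr)
  annotated <- ann[!is.na(ann$gene) & ann$gene != "UNANNOTATED" &
                     !is.na(ann$chr) & !is.na(ann$mb), , drop = FALSE]
  stopIfNot(nrow(annotated) > 0, "no annotated probes")
  keep <- probes %in% annotated$probe
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " probe(s) without RefSeq annotation dropped")
  mat <- mat[keep, , drop = FALSE]
  if (is.null(meta_path)) {
    meta <- data.frame(animal = colnames(mat), tissue = "SKIN",
                       cohort = "DISCOVERY", stringsAsFactors = FALSE)
  } else {
    meta <- read.delim(meta_path, stringsAsFactors = FALSE)
    meta <- meta[match(colnames(mat), meta$sample), , drop = FALSE]
    stopIfNot(!anyNA(meta$animal), "metadata must cover every sample")
  }
  expressionExperiment(mat, annotated, meta)
}

## Full-precision numeric formatting so write -> read round trips are
## bit-exact.
fmtNum <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Write an expression SummarizedExperiment as TSV
#'
#' Values are written at full precision so a write/read round trip
#' reproduces the matrix bit-exactly.
#'
#' @param se expression `SummarizedExperiment`.
#' @param path output TSV for the matrix.
#' @param annotation_path optional TSV for the probe annotation.
#' @param meta_path optional TSV for the sample metadata.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(se, path, annotation_path = NULL,
                            meta_path = NULL) {
  mat <- log2Values(se)
  out <- data.frame(probe = rownames(mat),
                    apply(mat, 2, fmtNum),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("probe", colnames(mat))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path))
    write.table(probeAnnotation(se), annotation_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    write.table(sampleMeta(se), meta_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Read backcross genotypes with a marker map
#'
#' Reads an animals x markers genotype TSV (first column `animal`) and a
#' marker map TSV (`marker`, `chr`, `mb`). Columns are reordered to the
#' genomic order of the map; the per-marker missing rate is reported.
#'
#' @param path genotype TSV.
#' @param marker_map_path marker map TSV.
#' @param codes two-token genotype alphabet,
#'   `c(HOM_FVB = "A", HET = "H")` by default. `"NA"` and `""` are missing.
#' @return A [GenotypeSet()].
#' @export
readGenotypes <- function(path, marker_map_path,
                          codes = c(HOM_FVB = "A", HET = "H")) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  animals <- raw[[1]]
  gm <- as.matrix(raw[, -1, drop = FALSE])
  rownames(gm) <- animals
  map <- read.delim(marker_map_path, stringsAsFactors = FALSE)
  extra <- setdiff(colnames(gm), as.character(map$marker))
  stopIfNot(length(extra) == 0,
            paste("marker(s) absent from map:", paste(extra, collapse = ", ")))
  tokens <- unique(gm[!is.na(gm) & gm != "NA" & gm != ""])
  bad <- setdiff(tokens, unname(codes))
  stopIfNot(length(bad) == 0,
            paste("unknown genotype token:", paste(bad, collapse = ", ")))
  calls <- matrix(NA_integer_, nrow(gm), ncol(gm), dimnames = dimnames(gm))
  calls[gm == codes[["HOM_FVB"]]] <- 0L
  calls[gm == codes[["HET"]]] <- 1L
  gs <- GenotypeSet(calls, map)
  miss <- colMeans(is.na(genotypeCalls(gs)))
  if (any(miss > 0))
    message("markers with missing calls: ", sum(miss > 0),
            " (max rate ", signif(max(miss), 3), ")")
  gs
}

#' Write a GenotypeSet as TSV
#'
#' @param gs a [GenotypeSet()].
#' @param path output genotype TSV.
#' @param marker_map_path optional TSV for the marker map.
#' @param codes genotype alphabet used for encoding.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(gs, path, marker_map_path = NULL,
                           codes = c(HOM_FVB = "A", HET = "H")) {
  calls <- genotypeCalls(gs)
  enc <- matrix("NA", nrow(calls), ncol(calls), dimnames = dimnames(calls))
  enc[!is.na(calls) & calls == 0L] <- codes[["HOM_FVB"]]
  enc[!is.na(calls) & calls == 1L] <- codes[["HET"]]
  out <- data.frame(animal = rownames(calls), enc, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(marker_map_path))
    write.table(markerMap(gs), marker_map_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Write eQTL records as TSV
#'
#' @param records eQTL record data.frame (see [mapEqtl()]).
#' @param path output TSV.
#' @return `path`, invisibly. The permutation p column is accompanied by a
#'   display column where zero counts read `<1/n_perm`.
#' @export
writeEqtlRecords <- function(records, path) {
  out <- records
  n_perm <- attr(records, "n_perm")
  if (!is.null(n_perm))
    out$p_perm_display <- formatPermP(out$p_perm, n_perm)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Network export (Cytoscape-readable)
## ---------------------------------------------------------------------------

## Build an igraph object from nodes/edges data frames.
networkGraph <- function(nodes, edges) {
  stopIfNot(all(c(edges$from, edges$to) %in% nodes$node),
            "edge endpoints must exist in the node set")
  vattr <- nodes
  names(vattr)[names(vattr) == "node"] <- "name"
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vattr)
}

#' Export a network for Cytoscape
#'
#' Writes a correlation network in SIF (interaction labels `pos`/`neg` for
#' direct/inverse correlation), GraphML (node fold-change stored as a
#' numeric attribute), or plain edge-list TSV.
#'
#' @param nodes data.frame with a `node` column plus any node attributes
#'   (e.g. `gene`, `fold_change`, `direction`).
#' @param edges data.frame with columns `from`, `to`, `sign`
#'   (`DIRECT`/`INVERSE`) and optionally `r`.
#' @param path output file.
#' @param format one of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(nodes, edges, path,
                          format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (nrow(edges) > 0)
    stopIfNot(all(c(edges$from, edges$to) %in% nodes$node),
              "edge endpoints must exist in the node set")
  if (format == "sif") {
    if (nrow(edges) == 0) {
      writeLines(character(0), path)
    } else {
      lab <- ifelse(edges$sign == "INVERSE", "neg", "pos")
      writeLines(paste(edges$from, lab, edges$to), path)
    }
  } else if (format == "tsv") {
    write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- if (nrow(nodes) == 0) igraph::make_empty_graph(directed = FALSE)
         else networkGraph(nodes, edges)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
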