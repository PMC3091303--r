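#' @import methods
NULL

## ---------------------------------------------------------------------------
## GenotypeSet: backcross genotypes plus the marker map
## ---------------------------------------------------------------------------

#' GenotypeSet: backcross genotype calls with a marker map
#'
#' Holds the animals x markers genotype matrix of a backcross
#' ((A x B) x B design), coded 0 = homozygous recurrent strain (HOM_FVB),
#' 1 = heterozygous (HET), `NA` = missing, together with the marker map
#' (marker, chromosome, Mb). Markers are kept in genomic order
#' (chromosome 1..19 then X, ascending Mb), which fixes the deterministic
#' tie-break used by peak-marker selection.
#'
#' @slot calls integer matrix, animals in rows, markers in columns.
#' @slot map data.frame with columns `marker`, `chr`, `mb`.
#' @export
setClass("GenotypeSet", representation(calls = "matrix", map = "data.frame"))

setValidity("GenotypeSet", function(object) {
  m <- object@map
  if (!all(c("marker", "chr", "mb") %in% names(m)))
    return("map must have columns marker, chr, mb")
  if (anyDuplicated(m$marker)) return("duplicate marker ids in map")
  if (!all(as.character(m$chr) %in% chromLevels()))
    return("marker chromosomes must be in 1..19, X")
  if (any(m$mb < 0)) return("marker positions must be nonnegative")
  if (!identical(seq_len(nrow(m)), chromOrder(m$chr, m$mb)))
    return("markers must be sorted by chromosome then position")
  cl <- object@calls
  if (ncol(cl) != nrow(m)) return("call columns must match marker map rows")
  if (!identical(colnames(cl), as.character(m$marker)))
    return("call column names must equal map marker ids, in map order")
  v <- cl[!is.na(cl)]
  if (length(v) && !all(v %in% c(0L, 1L)))
    return("genotype calls must be 0 (HOM_FVB), 1 (HET) or NA")
  TRUE
})

#' Construct a GenotypeSet
#'
#' @param calls integer (or 0/1 numeric) matrix, animals x markers; values
#'   0 = HOM_FVB, 1 = HET, NA = missing. Column names must name markers.
#' @param map data.frame with columns `marker`, `chr`, `mb`. Rows are
#'   re-sorted into genomic order and `calls` columns are aligned to them.
#' @return A [GenotypeSet-class] object.
#' @export
GenotypeSet <- function(calls, map) {
  map <- map[chromOrder(map$chr, map$mb), , drop = FALSE]
  rownames(map) <- NULL
  map$chr <- as.character(map$chr)
  map$marker <- as.character(map$marker)
  storage.mode(calls) <- "integer"
  missing_cols <- setdiff(map$marker, colnames(calls))
  stopIfNot(length(missing_cols) == 0,
            paste("markers absent from call matrix:",
                  paste(head(missing_cols, 5), collapse = ", ")))
  calls <- calls[, map$marker, drop = FALSE]
  new("GenotypeSet", calls = calls, map = map)
}

#' @describeIn GenotypeSet-class genotype call matrix (0/1/NA integers).
#' @param x,object a `GenotypeSet`.
#' @export
genotypeCalls <- function(x) {
  stopIfNot(is(x, "GenotypeSet"), "x must be a GenotypeSet")
  x@calls
}

#' @describeIn GenotypeSet-class marker map data.frame (marker, chr, mb).
#' @export
markerMap <- function(x) {
  stopIfNot(is(x, "GenotypeSet"), "x must be a GenotypeSet")
  x@map
}

#' @describeIn GenotypeSet-class number of animals.
#' @export
nAnimals <- function(x) nrow(genotypeCalls(x))

#' @describeIn GenotypeSet-class number of markers.
#' @export
nMarkers <- function(x) ncol(genotypeCalls(x))

setMethod("show", "GenotypeSet", function(object) {
  cl <- object@calls
  cat("GenotypeSet:", nrow(cl), "animals x", ncol(cl), "markers\n")
  cat("  chromosomes:", length(unique(object@map$chr)),
      " missing rate:", signif(mean(is.na(cl)), 3), "\n")
})

## ---------------------------------------------------------------------------
## Expression containers are SummarizedExperiment objects
## ---------------------------------------------------------------------------

#' Build an expression SummarizedExperiment
#'
#' Wraps a probes x samples log2 expression matrix into a
#' [SummarizedExperiment::SummarizedExperiment] with probe annotation as
#' `rowData` (gene, chr, mb) and per-sample metadata as `colData`
#' (animal, tissue, cohort).
#'
#' @param values numeric matrix, probes x samples, log2 scale; finite.
#' @param annotation data.frame with columns `probe`, `gene`, `chr`, `mb`
#'   covering the rows of `values`.
#' @param sampleMeta data.frame with columns `animal`, `tissue`
#'   (SKIN/PAPILLOMA/CARCINOMA) and optionally `cohort`
#'   (DISCOVERY/CONFIRMATION, default DISCOVERY); one row per column.
#' @return A `SummarizedExperiment` with assay `"log2"`.
#' @export
expressionExperiment <- function(values, annotation, sampleMeta) {
  stopIfNot(is.matrix(values) && is.numeric(values),
            "values must be a numeric matrix")
  stopIfNot(all(is.finite(values)), "expression values must all be finite")
  stopIfNot(!anyDuplicated(annotation$probe), "duplicate probe ids")
  ann <- annotation[match(rownames(values), annotation$probe), , drop = FALSE]
  stopIfNot(!anyNA(ann$probe), "annotation must cover every probe row")
  if (is.null(sampleMeta$cohort)) sampleMeta$cohort <- "DISCOVERY"
  stopIfNot(all(sampleMeta$tissue %in% c("SKIN", "PAPILLOMA", "CARCINOMA")),
            "tissue must be SKIN, PAPILLOMA or CARCINOMA")
  stopIfNot(nrow(sampleMeta) == ncol(values),
            "sampleMeta must have one row per sample column")
  nonpap <- sampleMeta$tissue != "PAPILLOMA"
  dup <- duplicated(paste(sampleMeta$animal, sampleMeta$tissue,
                          sampleMeta$cohort)[nonpap])
  stopIfNot(!any(dup), "at most one skin/carcinoma sample per animal")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = values),
    rowData = S4Vectors::DataFrame(gene = ann$gene, chr = as.character(ann$chr),
                                   mb = ann$mb, row.names = rownames(values)),
    colData = S4Vectors::DataFrame(animal = as.character(sampleMeta$animal),
                                   tissue = sampleMeta$tissue,
                                   cohort = sampleMeta$cohort,
                                   row.names = colnames(values))
  )
}

## Convenience accessors used throughout the package.
log2Values <- function(se) SummarizedExperiment::assay(se, 1L)

probeAnnotation <- function(se) {
  rd <- SummarizedExperiment::rowData(se)
  data.frame(probe = rownames(se), gene = rd$gene, chr = rd$chr, mb = rd$mb,
             stringsAsFactors = FALSE)
}

sampleMeta <- function(se) {
  cd <- SummarizedExperiment::colData(se)
  data.frame(sample = colnames(se), animal = cd$animal, tissue = cd$tissue,
             cohort = cd$cohort, stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## AcghSet: aCGH log2 ratio profiles
## ---------------------------------------------------------------------------

#' AcghSet: array-CGH log2 ratio profiles for a tumor panel
#'
#' @slot ratios numeric matrix, aCGH probes x tumors, log2 tumor/reference.
#' @slot probes data.frame with columns `probe`, `chr`, `mb`, sorted
#'   genomically.
#' @export
setClass("AcghSet", representation(ratios = "matrix", probes = "data.frame"))

setValidity("AcghSet", function(object) {
  p <- object@probes
  if (!all(c("probe", "chr", "mb") %in% names(p)))
    return("probes must have columns probe, chr, mb")
  if (anyDuplicated(p$probe)) return("duplicate aCGH probe ids")
  if (nrow(p) != nrow(object@ratios))
    return("ratio rows must match probe table")
  if (!identical(seq_len(nrow(p)), chromOrder(p$chr, p$mb)))
    return("aCGH probes must be sorted genomically")
  TRUE
})

#' Construct an AcghSet
#'
#' @param ratios numeric matrix of log2 ratios, probes x tumors.
#' @param probes data.frame with columns `probe`, `chr`, `mb`; rows are
#'   re-sorted genomically and `ratios` follows.
#' @return An [AcghSet-class].
#' @export
AcghSet <- function(ratios, probes) {
  probes$chr <- as.character(probes$chr)
  probes$probe <- as.character(probes$probe)
  o <- chromOrder(probes$chr, probes$mb)
  probes <- probes[o, , drop = FALSE]
  rownames(probes) <- NULL
  ratios <- ratios[o, , drop = FALSE]
  rownames(ratios) <- probes$probe
  new("AcghSet", ratios = ratios, probes = probes)
}

#' @describeIn AcghSet-class log2 ratio matrix.
#' @param x,object an `AcghSet`.
#' @export
acghRatios <- function(x) {
  stopIfNot(is(x, "AcghSet"), "x must be an AcghSet")
  x@ratios
}

#' @describeIn AcghSet-class probe position table.
#' @export
acghProbes <- function(x) {
  stopIfNot(is(x, "AcghSet"), "x must be an AcghSet")
  x@probes
}

setMethod("show", "AcghSet", function(object) {
  cat("AcghSet:", nrow(object@ratios), "probes x", ncol(object@ratios),
      "tumors\n")
})
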