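## Shared small synthetic cohort, built once per test run.
.fixtures <- new.env(parent = emptyenv())

tinyCohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- simulateTumorCohort(
      n_animals = 60, n_probes = 200, n_markers = 120, n_carcinomas = 50,
      n_acgh_probes = 200, seed = 101,
      n_cis = 15, n_trans = 5, n_masked = 3, n_susceptibility = 5,
      n_carcinoma_only = 3, n_response = 8)
  }
  .fixtures$cohort
}

tinyConfig <- function(...) {
  rewireConfig(n_perm_eqtl = 300, n_perm_gwer = 150, seed = 101, ...)
}

## Memoized eQTL records on the tiny cohort.
tinyRecords <- function(tissue) {
  key <- paste0("rec_", tissue)
  if (is.null(.fixtures[[key]])) {
    coh <- tinyCohort()
    se <- switch(tissue,
                 SKIN = coh$skin,
                 PAPILLOMA = combinePapillomaPairs(coh$papilloma),
                 CARCINOMA = coh$carcinoma)
    .fixtures[[key]] <- mapEqtl(se, coh$genotypes, tinyConfig())
  }
  .fixtures[[key]]
}

## A bare expression SummarizedExperiment from a matrix (one tissue).
quickSE <- function(mat, animals = colnames(mat), tissue = "SKIN") {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("P%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("S%03d", seq_len(ncol(mat)))
  if (is.null(animals)) animals <- colnames(mat)
  ann <- data.frame(probe = rownames(mat), gene = rownames(mat),
                    chr = "1", mb = seq_len(nrow(mat)),
                    stringsAsFactors = FALSE)
  expressionExperiment(mat, ann,
                       data.frame(animal = animals, tissue = tissue,
                                  stringsAsFactors = FALSE))
}
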