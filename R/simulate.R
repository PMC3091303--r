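## ---------------------------------------------------------------------------
## Synthetic FVBBX-like cohort with recoverable ground truth
## ---------------------------------------------------------------------------

#' Default SNP marker panel
#'
#' Deterministic marker map emulating a genome-wide backcross SNP panel:
#' markers are allocated to chromosomes proportionally to physical length
#' (at least 2 per chromosome) and spaced evenly.
#'
#' @param n_markers total marker count (default 230).
#' @param chromosomes data.frame (`chr`, `length_mb`); defaults to
#'   [mouseChromosomes()].
#' @return data.frame with columns `marker`, `chr`, `mb` in genomic order.
#' @export
defaultMarkerMap <- function(n_markers = 230L, chromosomes = mouseChromosomes()) {
  L <- chromosomes$length_mb
  alloc <- pmax(2L, floor(n_markers * L / sum(L)))
  ## trim/extend to the requested total, adjusting the largest chromosomes
  while (sum(alloc) > n_markers) {
    i <- which.max(alloc)
    alloc[i] <- alloc[i] - 1L
  }
  while (sum(alloc) < n_markers) {
    i <- which.min(alloc / L)
    alloc[i] <- alloc[i] + 1L
  }
  maps <- lapply(seq_len(nrow(chromosomes)), function(i) {
    k <- alloc[i]
    data.frame(chr = chromosomes$chr[i],
               mb = seq(3, L[i] - 3, length.out = k),
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  map <- data.frame(marker = sprintf("M%03d", seq_len(nrow(map))),
                    chr = map$chr, mb = map$mb, stringsAsFactors = FALSE)
  map[chromOrder(map$chr, map$mb), , drop = FALSE]
}

#' Simulate backcross genotypes
#'
#' Genotypes for an (A x B) x B backcross: along each chromosome the 0/1
#' (HOM_FVB/HET) state follows a two-state Markov chain whose switch
#' probability between adjacent markers is the Haldane recombination
#' fraction `r = (1 - exp(-2 d / 100)) / 2`, with `d` the inter-marker
#' distance in centimorgan (`distance_mb * cm_per_mb`). Chromosomes are
#' independent and each chain starts HET or HOM_FVB with probability 1/2.
#'
#' @param n_animals number of animals (>= 2).
#' @param marker_map data.frame (`marker`, `chr`, `mb`).
#' @param cm_per_mb genetic-to-physical scale (default 0.5 cM/Mb).
#' @param seed RNG seed.
#' @return A [GenotypeSet()]; animal ids `A001`, `A002`, ...
#' @export
simulateBackcross <- function(n_animals, marker_map, cm_per_mb = 0.5,
                              seed = NULL) {
  stopIfNot(n_animals >= 2, "n_animals must be at least 2")
  stopIfNot(cm_per_mb > 0, "cm_per_mb must be positive")
  map <- marker_map[chromOrder(marker_map$chr, marker_map$mb), , drop = FALSE]
  calls <- withSeed(seed, {
    cols <- vector("list", nrow(map))
    for (chr in unique(map$chr)) {
      idx <- which(map$chr == chr)
      d_cm <- diff(map$mb[idx]) * cm_per_mb
      r <- (1 - exp(-2 * d_cm / 100)) / 2
      state <- rbinom(n_animals, 1L, 0.5)
      cols[[idx[1]]] <- state
      for (j in seq_along(r)) {
        flip <- rbinom(n_animals, 1L, r[j])
        state <- ifelse(flip == 1L, 1L - state, state)
        cols[[idx[j + 1]]] <- state
      }
    }
    do.call(cbind, cols)
  })
  dimnames(calls) <- list(sprintf("A%03d", seq_len(n_animals)),
                          as.character(map$marker))
  GenotypeSet(calls, map)
}

#' Define the planted ground truth of a synthetic cohort
#'
#' Builds a probe annotation and a planted eQTL architecture with known
#' truth: `n_cis` cis and `n_trans` trans eQTL active in all tissues whose
#' effects attenuate multiplicatively with progression stage; a subset of
#' the cis eQTL placed inside a recurrent distal amplification region
#' (whose expression boost masks them in carcinomas); tumor-specific eQTL
#' tied to a protective susceptibility locus; carcinoma-only eQTL; and
#' response-only ("perturbation") loci that control the normal-to-tumor
#' expression change but not steady-state levels.
#'
#' @param marker_map marker map data.frame.
#' @param n_probes total probe count.
#' @param n_cis,n_trans planted steady-state eQTL active in every tissue
#'   (effect size `beta`, attenuated by `attenuation` per stage).
#' @param beta planted effect in expression-SD units added to HET animals.
#' @param attenuation multiplier applied per progression step
#'   (skin -> papilloma -> carcinoma).
#' @param n_masked how many of the cis eQTL to place inside the
#'   amplification region (must be <= `n_cis`).
#' @param n_susceptibility tumor-only (papilloma + carcinoma) eQTL at the
#'   susceptibility locus, effect `beta_tumor`, HET-high.
#' @param n_carcinoma_only eQTL active only in carcinomas.
#' @param n_response probes of the response-only trans band: one shared
#'   trans locus of effect `beta_response` acting on the skin-to-carcinoma
#'   expression change; its probes carry an animal-level deviation of SD
#'   `pert_shared_sd` shared between skin and carcinoma, which masks the
#'   effect in both steady states but cancels in the fold-change.
#' @param beta_tumor,beta_response effect sizes of the tumor-specific and
#'   response-only eQTL (not attenuated).
#' @param noise_sd residual expression SD.
#' @param host_effect_sd SD of the per-animal deviation shared by a
#'   papilloma pair.
#' @param pert_shared_sd SD of the animal-level deviation shared between
#'   skin and carcinoma for response probes.
#' @param cnv_event list: `chr`, `start_mb`, `gain_prob` (per carcinoma),
#'   `boost` (log2 expression added to in-region genes of amplified
#'   tumors).
#' @param susc_base_mu mean papilloma count of HOM_FVB animals.
#' @param susc_ratio multiplicative effect of the protective HET genotype
#'   on the count mean (< 1 is protective).
#' @param nb_size negative-binomial dispersion of the counts.
#' @param seed RNG seed.
#' @return list of class `cohort_truth`.
#' @export
simulateTruth <- function(marker_map, n_probes = 2000L, n_cis = 50L,
                          n_trans = 20L, beta = 1.5, attenuation = 0.6,
                          n_masked = 5L, n_susceptibility = 5L,
                          n_carcinoma_only = 5L, n_response = 12L,
                          beta_tumor = 2, beta_response = 2, noise_sd = 1,
                          host_effect_sd = 1, pert_shared_sd = 4,
                          cnv_event = list(chr = "7", start_mb = 125,
                                           gain_prob = 0.45, boost = 3),
                          susc_base_mu = 9, susc_ratio = 0.3, nb_size = 3,
                          seed = NULL) {
  stopIfNot(n_masked <= n_cis, "n_masked must not exceed n_cis")
  stopIfNot(cnv_event$gain_prob >= 0 && cnv_event$gain_prob <= 1,
            "gain_prob must be in [0, 1]")
  stopIfNot(noise_sd > 0, "noise_sd must be positive")
  chroms <- mouseChromosomes()
  lenOf <- setNames(chroms$length_mb, chroms$chr)
  map <- marker_map
  n_planted <- n_cis + n_trans + n_susceptibility + n_carcinoma_only +
    n_response
  stopIfNot(n_probes >= n_planted, "n_probes too small for planted truth")
  withSeed(seed, {
    ann <- data.frame(
      probe = sprintf("P%04d", seq_len(n_probes)),
      gene = sprintf("Gene%04d", seq_len(n_probes)),
      chr = sample(chroms$chr, n_probes, replace = TRUE,
                   prob = chroms$length_mb),
      mb = NA_real_, stringsAsFactors = FALSE)
    ann$mb <- runif(n_probes, 1, lenOf[ann$chr] - 1)
    idx <- sample.int(n_probes, n_planted)
    take <- function(k) {
      out <- idx[seq_len(k)]
      idx <<- idx[-seq_len(k)]
      out
    }
    planted <- list()
    placeCis <- function(i, mk, jitter = 10) {
      ann$chr[i] <<- map$chr[mk]
      ann$mb[i] <<- pmin(pmax(map$mb[mk] + runif(1, -jitter, jitter), 0.5),
                         lenOf[map$chr[mk]] - 0.5)
    }
    ## cis eQTL inside the amplification event region (masked in carcinoma)
    if (n_masked > 0) {
      ev_markers <- which(map$chr == cnv_event$chr &
                            map$mb >= cnv_event$start_mb)
      stopIfNot(length(ev_markers) > 0,
                "no markers inside the cnv event region")
      pid <- take(n_masked)
      mk <- sample(ev_markers, n_masked, replace = TRUE)
      for (k in seq_len(n_masked)) {
        ann$chr[pid[k]] <- cnv_event$chr
        ann$mb[pid[k]] <- runif(1, cnv_event$start_mb + 0.5,
                                lenOf[cnv_event$chr] - 0.5)
      }
      planted$masked <- data.frame(probe = ann$probe[pid],
                                   marker = map$marker[mk], beta = beta,
                                   mode = "CIS", kind = "steady",
                                   in_skin = TRUE, in_papilloma = TRUE,
                                   in_carcinoma = TRUE,
                                   attenuation = attenuation, masked = TRUE,
                                   stringsAsFactors = FALSE)
    }
    ## remaining genome-wide cis eQTL
    if (n_cis - n_masked > 0) {
      k <- n_cis - n_masked
      pid <- take(k)
      mk <- sample.int(nrow(map), k, replace = TRUE)
      for (j in seq_len(k)) placeCis(pid[j], mk[j])
      planted$cis <- data.frame(probe = ann$probe[pid],
                                marker = map$marker[mk], beta = beta,
                                mode = "CIS", kind = "steady",
                                in_skin = TRUE, in_papilloma = TRUE,
                                in_carcinoma = TRUE,
                                attenuation = attenuation, masked = FALSE,
                                stringsAsFactors = FALSE)
    }
    ## trans eQTL: causal marker on a different chromosome from the gene
    if (n_trans > 0) {
      pid <- take(n_trans)
      mk <- integer(n_trans)
      for (j in seq_len(n_trans)) {
        mk[j] <- sample(which(map$chr != ann$chr[pid[j]]), 1)
      }
      planted$trans <- data.frame(probe = ann$probe[pid],
                                  marker = map$marker[mk], beta = beta,
                                  mode = "TRANS", kind = "steady",
                                  in_skin = TRUE, in_papilloma = TRUE,
                                  in_carcinoma = TRUE,
                                  attenuation = attenuation, masked = FALSE,
                                  stringsAsFactors = FALSE)
    }
    ## protective-locus tumor eQTL (HET-high, papilloma + carcinoma only)
    susc14 <- which(map$chr == "14")
    susc_marker <- map$marker[susc14[which.min(abs(map$mb[susc14] - 62))]]
    if (n_susceptibility > 0) {
      pid <- take(n_susceptibility)
      mki <- match(susc_marker, map$marker)
      for (j in seq_len(n_susceptibility)) placeCis(pid[j], mki, jitter = 15)
      planted$susc <- data.frame(probe = ann$probe[pid],
                                 marker = susc_marker, beta = beta_tumor,
                                 mode = "CIS", kind = "steady",
                                 in_skin = FALSE, in_papilloma = TRUE,
                                 in_carcinoma = TRUE, attenuation = 1,
                                 masked = FALSE, stringsAsFactors = FALSE)
    }
    ## carcinoma-only eQTL
    if (n_carcinoma_only > 0) {
      pid <- take(n_carcinoma_only)
      mk <- sample.int(nrow(map), n_carcinoma_only, replace = TRUE)
      for (j in seq_len(n_carcinoma_only)) placeCis(pid[j], mk[j])
      planted$carc <- data.frame(probe = ann$probe[pid],
                                 marker = map$marker[mk], beta = beta_tumor,
                                 mode = "CIS", kind = "steady",
                                 in_skin = FALSE, in_papilloma = FALSE,
                                 in_carcinoma = TRUE, attenuation = 1,
                                 masked = FALSE, stringsAsFactors = FALSE)
    }
    ## response-only (perturbation) probes: one shared trans locus (a
    ## response trans-band), acting on the fold-change only
    if (n_response > 0) {
      pid <- take(n_response)
      mk <- sample.int(nrow(map), 1)
      for (j in seq_len(n_response)) {
        if (ann$chr[pid[j]] == map$chr[mk]) {
          ann$chr[pid[j]] <- sample(setdiff(chroms$chr, map$chr[mk]), 1)
          ann$mb[pid[j]] <- runif(1, 1, lenOf[ann$chr[pid[j]]] - 1)
        }
      }
      planted$resp <- data.frame(probe = ann$probe[pid],
                                 marker = map$marker[mk],
                                 beta = beta_response, mode = "TRANS",
                                 kind = "response", in_skin = FALSE,
                                 in_papilloma = FALSE, in_carcinoma = TRUE,
                                 attenuation = 1, masked = FALSE,
                                 stringsAsFactors = FALSE)
    }
    planted <- if (length(planted)) do.call(rbind, planted) else
      data.frame(probe = character(), marker = character(), beta = numeric(),
                 mode = character(), kind = character(), in_skin = logical(),
                 in_papilloma = logical(), in_carcinoma = logical(),
                 attenuation = numeric(), masked = logical(),
                 stringsAsFactors = FALSE)
    rownames(planted) <- NULL
    ## baselines: some tumor-specific probes sit below skin background;
    ## response-band probes are constitutively well expressed so the
    ## above-background filter never removes them despite their wide
    ## animal-level deviation
    baseline <- rnorm(n_probes, 7, 0.5)
    names(baseline) <- ann$probe
    if (n_response > 0)
      baseline[planted$probe[planted$kind == "response"]] <- 9
    if (n_susceptibility > 0) {
      low <- planted$probe[planted$kind == "steady" & !planted$in_skin &
                             planted$in_papilloma]
      low <- head(low, max(1, ceiling(length(low) * 0.6)))
      baseline[low] <- 4.0
    }
    structure(list(annotation = ann, planted = planted, baseline = baseline,
                   noise_sd = noise_sd, host_effect_sd = host_effect_sd,
                   pert_shared_sd = pert_shared_sd, cnv_event = cnv_event,
                   susceptibility = list(marker = susc_marker,
                                         base_mu = susc_base_mu,
                                         ratio = susc_ratio,
                                         nb_size = nb_size),
                   attenuation = attenuation, marker_map = map,
                   seed = seed),
              class = "cohort_truth")
  })
}

## Progression stage index used by the attenuation model.
stageIndex <- function(tissue) {
  c(SKIN = 0, PAPILLOMA = 1, CARCINOMA = 2)[[tissue]]
}

#' Simulate a tissue expression matrix from planted truth
#'
#' Expression = per-probe baseline + sum of active planted effects
#' (`beta * attenuation^stage` added to HET animals at the causal marker) +
#' a per-animal host deviation shared by a papilloma pair (papilloma only) +
#' Gaussian noise. Response-kind loci contribute `-beta/2` in skin and
#' `+beta/2` in carcinoma (so the skin-to-carcinoma change carries the
#' full effect while each steady state carries only half), on top of an
#' animal-level deviation shared between skin and carcinoma (supplied via
#' `shared_effects`) that masks the steady-state halves but cancels in
#' the fold-change.
#'
#' @param genotypes a [GenotypeSet()].
#' @param truth a `cohort_truth` from [simulateTruth()].
#' @param tissue `"SKIN"`, `"PAPILLOMA"` or `"CARCINOMA"`.
#' @param seed RNG seed.
#' @param animals subset of animal ids to emit (default: all genotyped).
#' @param n_singletons for papilloma, how many animals get a single tumor
#'   instead of a pair (the last ones in `animals`).
#' @param shared_effects optional matrix (response probes x animals) of
#'   animal-level deviations added in both skin and carcinoma.
#' @param cohort cohort label stored in the sample metadata.
#' @return expression `SummarizedExperiment`.
#' @export
simulateExpression <- function(genotypes, truth, tissue, seed = NULL,
                               animals = NULL, n_singletons = 0L,
                               shared_effects = NULL, cohort = "DISCOVERY") {
  stopIfNot(tissue %in% c("SKIN", "PAPILLOMA", "CARCINOMA"),
            paste("unknown tissue:", tissue))
  calls <- genotypeCalls(genotypes)
  if (is.null(animals)) animals <- rownames(calls)
  stopIfNot(all(animals %in% rownames(calls)),
            "animals must be genotyped")
  ann <- truth$annotation
  nP <- nrow(ann)
  nA <- length(animals)
  st <- stageIndex(tissue)
  tiscol <- paste0("in_", tolower(tissue))
  ## per-animal genetic signal (probes x animals)
  signal <- matrix(truth$baseline[ann$probe], nP, nA,
                   dimnames = list(ann$probe, animals))
  pl <- truth$planted
  active <- pl[pl$kind == "steady" & pl[[tiscol]], , drop = FALSE]
  if (nrow(active)) {
    for (k in seq_len(nrow(active))) {
      het <- calls[animals, active$marker[k]]
      het[is.na(het)] <- 0L
      eff <- active$beta[k] * active$attenuation[k]^st
      signal[active$probe[k], ] <- signal[active$probe[k], ] + eff * het
    }
  }
  ## response-only loci: the skin -> carcinoma change carries the full
  ## effect (split -beta/2 / +beta/2) so neither steady state shows it
  if (tissue %in% c("SKIN", "CARCINOMA")) {
    resp <- pl[pl$kind == "response", , drop = FALSE]
    half <- if (tissue == "SKIN") -0.5 else 0.5
    if (nrow(resp)) {
      for (k in seq_len(nrow(resp))) {
        het <- calls[animals, resp$marker[k]]
        het[is.na(het)] <- 0L
        signal[resp$probe[k], ] <- signal[resp$probe[k], ] +
          half * resp$beta[k] * het
      }
    }
  }
  if (!is.null(shared_effects) && tissue %in% c("SKIN", "CARCINOMA")) {
    common <- intersect(rownames(shared_effects), ann$probe)
    signal[common, ] <- signal[common, ] +
      shared_effects[common, animals, drop = FALSE]
  }
  withSeed(seed, {
    if (tissue == "PAPILLOMA") {
      stopIfNot(n_singletons <= nA, "too many singleton animals")
      host <- matrix(rnorm(nP * nA, 0, truth$host_effect_sd), nP, nA,
                     dimnames = list(ann$probe, animals))
      paired <- animals[seq_len(nA - n_singletons)]
      single <- setdiff(animals, paired)
      cols_animal <- c(rep(paired, each = 2), single)
      suffix <- c(rep(c("P1", "P2"), length(paired)),
                  rep("P1", length(single)))
      vals <- signal[, cols_animal, drop = FALSE] +
        host[, cols_animal, drop = FALSE] +
        matrix(rnorm(nP * length(cols_animal), 0, truth$noise_sd), nP)
      colnames(vals) <- paste(cols_animal, suffix, sep = "_")
      meta <- data.frame(animal = cols_animal, tissue = "PAPILLOMA",
                         cohort = cohort, stringsAsFactors = FALSE)
    } else {
      vals <- signal + matrix(rnorm(nP * nA, 0, truth$noise_sd), nP, nA)
      colnames(vals) <- paste(animals, substr(tissue, 1, 1), sep = "_")
      meta <- data.frame(animal = animals, tissue = tissue, cohort = cohort,
                         stringsAsFactors = FALSE)
    }
    expressionExperiment(vals, ann, meta)
  })
}

#' Simulate a full tumor-progression cohort
#'
#' Generates the complete study material for one backcross cohort: marker
#' map, genotypes, skin / paired-papilloma / carcinoma expression with the
#' planted eQTL architecture of [simulateTruth()], aCGH profiles with a
#' recurrent distal amplification that boosts local gene expression in
#' amplified tumors (masking their cis eQTL), and overdispersed papilloma
#' counts shifted by the protective susceptibility locus.
#'
#' @param n_animals cohort size (default 100).
#' @param n_probes expression probes (default 2,000).
#' @param n_markers SNP markers (default 230).
#' @param n_carcinomas animals that develop a carcinoma (default 60).
#' @param n_singleton_papillomas animals contributing a single papilloma
#'   instead of a pair (default 6).
#' @param n_acgh_probes aCGH panel size (default 2,504).
#' @param truth optional `cohort_truth` to reuse (e.g. for a confirmation
#'   cohort); a default one is built otherwise.
#' @param marker_map optional marker map (must match `truth` if both
#'   given).
#' @param cohort cohort label (`"DISCOVERY"` or `"CONFIRMATION"`).
#' @param seed master RNG seed.
#' @param ... forwarded to [simulateTruth()] when `truth` is NULL.
#' @return list of class `rewire_cohort` with elements `genotypes`, `skin`,
#'   `papilloma`, `carcinoma`, `acgh`, `phenotype`, `amp_tumors`, `truth`.
#' @export
simulateTumorCohort <- function(n_animals = 100L, n_probes = 2000L,
                                n_markers = 230L, n_carcinomas = 60L,
                                n_singleton_papillomas = 6L,
                                n_acgh_probes = 2504L, truth = NULL,
                                marker_map = NULL, cohort = "DISCOVERY",
                                seed = 1L, ...) {
  stopIfNot(n_carcinomas <= n_animals, "n_carcinomas must be <= n_animals")
  seeds <- childSeeds(seed, 10)
  if (is.null(marker_map))
    marker_map <- if (!is.null(truth)) truth$marker_map
                  else defaultMarkerMap(n_markers)
  if (is.null(truth))
    truth <- simulateTruth(marker_map, n_probes = n_probes,
                           seed = seeds[[1]], ...)
  gt <- simulateBackcross(n_animals, marker_map, seed = seeds[[2]])
  animals <- rownames(genotypeCalls(gt))
  ## animal-level deviation for response probes, shared skin <-> carcinoma
  resp_probes <- truth$planted$probe[truth$planted$kind == "response"]
  shared <- NULL
  if (length(resp_probes) > 0) {
    shared <- withSeed(seeds[[3]], {
      matrix(rnorm(length(resp_probes) * n_animals, 0, truth$pert_shared_sd),
             length(resp_probes), n_animals,
             dimnames = list(resp_probes, animals))
    })
  }
  skin <- simulateExpression(gt, truth, "SKIN", seed = seeds[[4]],
                             shared_effects = shared, cohort = cohort)
  papilloma <- simulateExpression(gt, truth, "PAPILLOMA", seed = seeds[[5]],
                                  n_singletons = n_singleton_papillomas,
                                  cohort = cohort)
  carc_animals <- withSeed(seeds[[6]], sort(sample(animals, n_carcinomas)))
  carcinoma <- simulateExpression(gt, truth, "CARCINOMA", seed = seeds[[7]],
                                  animals = carc_animals,
                                  shared_effects = shared, cohort = cohort)
  ## amplification event: which carcinomas carry the gain, expression boost
  ev <- truth$cnv_event
  chroms <- mouseChromosomes()
  lenOf <- setNames(chroms$length_mb, chroms$chr)
  amp <- withSeed(seeds[[8]], {
    setNames(rbinom(n_carcinomas, 1L, ev$gain_prob) == 1L, carc_animals)
  })
  ann <- truth$annotation
  in_region <- ann$chr == ev$chr & ann$mb >= ev$start_mb
  if (any(in_region) && any(amp)) {
    vals <- SummarizedExperiment::assay(carcinoma, 1L)
    amp_cols <- which(amp[SummarizedExperiment::colData(carcinoma)$animal])
    vals[in_region, amp_cols] <- vals[in_region, amp_cols] + ev$boost
    SummarizedExperiment::assay(carcinoma, 1L) <- vals
  }
  ## aCGH profiles for the carcinomas
  acgh <- withSeed(seeds[[9]], {
    probes <- data.frame(
      probe = sprintf("CGH%04d", seq_len(n_acgh_probes)),
      chr = sample(chroms$chr, n_acgh_probes, replace = TRUE,
                   prob = chroms$length_mb),
      mb = NA_real_, stringsAsFactors = FALSE)
    probes$mb <- runif(n_acgh_probes, 0.5, lenOf[probes$chr] - 0.5)
    ratios <- matrix(rnorm(n_acgh_probes * n_carcinomas, 0, 0.05),
                     n_acgh_probes, n_carcinomas,
                     dimnames = list(probes$probe, carc_animals))
    ev_rows <- probes$chr == ev$chr & probes$mb >= ev$start_mb
    if (any(ev_rows) && any(amp)) {
      k <- sum(ev_rows) * sum(amp)
      ratios[ev_rows, amp] <- pmax(0.4, rnorm(k, 0.8, 0.1))
    }
    AcghSet(ratios, probes)
  })
  ## papilloma counts: negative binomial, HET protective at the locus
  su <- truth$susceptibility
  het <- genotypeCalls(gt)[, su$marker]
  het[is.na(het)] <- 0L
  counts <- withSeed(seeds[[10]], {
    mu <- su$base_mu * su$ratio^het
    rnbinom(n_animals, size = su$nb_size, mu = mu)
  })
  phenotype <- data.frame(animal = animals, papilloma_count_wk20 = counts,
                          stringsAsFactors = FALSE)
  phenotype$susceptibility_class <- classifySusceptibility(counts)
  structure(list(genotypes = gt, skin = skin, papilloma = papilloma,
                 carcinoma = carcinoma, acgh = acgh, phenotype = phenotype,
                 amp_tumors = amp, truth = truth, marker_map = marker_map,
                 cohort = cohort, seed = seed),
            class = "rewire_cohort")
}

#' @export
print.rewire_cohort <- function(x, ...) {
  cat("rewire_cohort (", x$cohort, "): ", nAnimals(x$genotypes),
      " animals, ", nMarkers(x$genotypes), " markers, ",
      nrow(x$truth$annotation), " probes\n", sep = "")
  cat("  samples: skin ", ncol(x$skin), ", papilloma ", ncol(x$papilloma),
      ", carcinoma ", ncol(x$carcinoma), "\n", sep = "")
  cat("  planted eQTL:", nrow(x$truth$planted), "\n")
  invisible(x)
}
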