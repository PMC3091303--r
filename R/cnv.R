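## ---------------------------------------------------------------------------
## aCGH copy-number calling and genome alteration summaries
## ---------------------------------------------------------------------------

#' Call copy-number state from log2 ratios
#'
#' AMP when the ratio is at or above `+cutoff`, DEL at or below `-cutoff`
#' (boundary inclusive), otherwise NEUTRAL.
#'
#' @param x an [AcghSet()], numeric matrix, or numeric vector of log2
#'   ratios.
#' @param cutoff call cutoff (default 0.3).
#' @return character object of the same shape with values AMP/DEL/NEUTRAL.
#' @export
callCopyNumber <- function(x, cutoff = 0.3) {
  r <- if (is(x, "AcghSet")) acghRatios(x) else x
  stopIfNot(all(is.finite(r[!is.na(r)])), "log2 ratios must be finite")
  calls <- ifelse(is.na(r), NA_character_,
                  ifelse(r >= cutoff, "AMP",
                         ifelse(r <= -cutoff, "DEL", "NEUTRAL")))
  if (is.matrix(r)) dimnames(calls) <- dimnames(r)
  calls
}

## Number of the B equally spaced bins of a chromosome of length L whose
## center lies at or left of position `m` (bin centers at (j - 1/2) L / B).
binsLeftOf <- function(m, L, B) pmin(B, pmax(0, floor(m * B / L + 0.5)))

## Per-probe bin counts on one chromosome: each bin inherits the call of
## its nearest probe; exact-midpoint ties go to the left (lower-Mb) probe.
## `mode = "analytic"` counts bins per nearest-probe segment in closed
## form; `mode = "bins"` enumerates every bin explicitly.
chromBinCounts <- function(pos, L, B, mode = c("analytic", "bins")) {
  mode <- match.arg(mode)
  k <- length(pos)
  if (k == 1) return(B)
  mids <- (pos[-k] + pos[-1]) / 2
  if (mode == "analytic") {
    cuts <- c(0, binsLeftOf(mids, L, B), B)
    return(diff(cuts))
  }
  centers <- (seq_len(B) - 0.5) * L / B
  idx <- findInterval(centers, pos)
  idx[idx == 0] <- 1L
  inner <- idx < k
  right_closer <- inner &
    (centers - pos[pmin(idx, k)]) > (pos[pmin(idx + 1L, k)] - centers)
  idx[right_closer] <- idx[right_closer] + 1L
  tabulate(idx, nbins = k)
}

#' Fraction of the genome altered per tumor
#'
#' Each chromosome is divided into `bins_per_chromosome` equally spaced
#' bins; every bin inherits the AMP/DEL/NEUTRAL call of its most
#' physically proximal probe with data (exact-midpoint ties to the
#' lower-Mb probe). The amplified and deleted percentages are the altered
#' bin fractions over all covered chromosomes. The default analytic mode
#' counts bins per nearest-probe segment in closed form and equals the
#' explicit bin enumeration exactly; `mode = "bins"` is retained for
#' audit. Chromosomes without any measured probe are excluded (with a
#' message).
#'
#' @param acgh an [AcghSet()].
#' @param cutoff call cutoff, see [callCopyNumber()].
#' @param chromosome_lengths data.frame (`chr`, `length_mb`); defaults to
#'   [mouseChromosomes()].
#' @param bins_per_chromosome bins per chromosome (default 1,000,000).
#' @param mode `"analytic"` or `"bins"`.
#' @return list with `per_tumor` (data.frame: tumor, pct_amplified,
#'   pct_deleted), `per_chromosome` (chr x tumor amplified-fraction
#'   matrix), and `calls`.
#' @export
fractionGenomeAltered <- function(acgh, cutoff = 0.3,
                                  chromosome_lengths = mouseChromosomes(),
                                  bins_per_chromosome = 1000000L,
                                  mode = c("analytic", "bins")) {
  mode <- match.arg(mode)
  B <- bins_per_chromosome
  calls <- callCopyNumber(acgh, cutoff)
  probes <- acghProbes(acgh)
  tumors <- colnames(calls)
  lenOf <- setNames(chromosome_lengths$length_mb,
                    as.character(chromosome_lengths$chr))
  chrs <- intersect(chromosome_lengths$chr, unique(probes$chr))
  skipped <- setdiff(chromosome_lengths$chr, chrs)
  if (length(skipped))
    message("chromosome(s) without probes excluded: ",
            paste(skipped, collapse = ", "))
  amp_bins <- del_bins <- matrix(0, length(chrs), length(tumors),
                                 dimnames = list(chrs, tumors))
  covered <- matrix(FALSE, length(chrs), length(tumors),
                    dimnames = list(chrs, tumors))
  for (ci in seq_along(chrs)) {
    ch <- chrs[ci]
    rows <- which(probes$chr == ch)
    pos_all <- probes$mb[rows]
    for (tj in seq_along(tumors)) {
      has <- !is.na(calls[rows, tj])
      if (!any(has)) next
      covered[ci, tj] <- TRUE
      cnt <- chromBinCounts(pos_all[has], lenOf[[ch]], B, mode)
      cl <- calls[rows[has], tj]
      amp_bins[ci, tj] <- sum(cnt[cl == "AMP"])
      del_bins[ci, tj] <- sum(cnt[cl == "DEL"])
    }
  }
  tot <- colSums(covered) * B
  per_tumor <- data.frame(tumor = tumors,
                          pct_amplified = 100 * colSums(amp_bins) / tot,
                          pct_deleted = 100 * colSums(del_bins) / tot,
                          stringsAsFactors = FALSE)
  rownames(per_tumor) <- NULL
  list(per_tumor = per_tumor,
       per_chromosome = amp_bins / B,
       calls = calls)
}

#' Per-probe alteration frequencies across tumors
#'
#' For each aCGH probe, the fraction of tumors called AMP and DEL
#' (plotted above/below zero in genome tracks), plus the per-chromosome
#' gain frequency: the fraction of tumors with at least one AMP probe on
#' the chromosome (mode `"any"`), or with at least `frac_cutoff` of its
#' probes AMP (mode `"fraction"`).
#'
#' @param acgh an [AcghSet()].
#' @param cutoff call cutoff.
#' @param gain_mode `"any"` or `"fraction"`.
#' @param frac_cutoff probe fraction for `gain_mode = "fraction"`
#'   (default 0.25).
#' @return list with `track` (probe, chr, mb, amp_freq, del_freq) and
#'   `chromosome_gain` (chr, gain_freq).
#' @export
alterationFrequencyTrack <- function(acgh, cutoff = 0.3,
                                     gain_mode = c("any", "fraction"),
                                     frac_cutoff = 0.25) {
  gain_mode <- match.arg(gain_mode)
  calls <- callCopyNumber(acgh, cutoff)
  stopIfNot(ncol(calls) >= 2, "at least 2 tumors required")
  probes <- acghProbes(acgh)
  track <- data.frame(probe = probes$probe, chr = probes$chr,
                      mb = probes$mb,
                      amp_freq = rowMeans(calls == "AMP", na.rm = TRUE),
                      del_freq = rowMeans(calls == "DEL", na.rm = TRUE),
                      stringsAsFactors = FALSE)
  chrs <- unique(probes$chr)
  gain <- vapply(chrs, function(ch) {
    sub <- calls[probes$chr == ch, , drop = FALSE]
    per_tumor <- if (gain_mode == "any") {
      colSums(sub == "AMP", na.rm = TRUE) >= 1
    } else {
      colMeans(sub == "AMP", na.rm = TRUE) >= frac_cutoff
    }
    mean(per_tumor)
  }, numeric(1))
  list(track = track,
       chromosome_gain = data.frame(chr = chrs, gain_freq = unname(gain),
                                    stringsAsFactors = FALSE))
}

#' Amplification versus expression fold-change association
#'
#' Tests whether tumors carrying an amplification at an aCGH probe show a
#' larger expression fold-change for a nearby gene: point-biserial
#' correlation between the AMP indicator and the per-tumor fold-change,
#' with the p-value of the equivalent equal-variance two-sample t-test.
#'
#' @param amp_calls per-tumor call vector (from [callCopyNumber()]) or
#'   logical AMP indicator.
#' @param fold_change per-tumor fold-change vector of the gene, aligned
#'   with `amp_calls`.
#' @return list with `r` (point-biserial), `p`, `mean_amp`, `mean_other`,
#'   `mean_fold_difference` (linear scale), `n_amp`, `n_other`.
#' @export
amplificationExpressionTest <- function(amp_calls, fold_change) {
  amp <- if (is.logical(amp_calls)) amp_calls else amp_calls == "AMP"
  stopIfNot(length(amp) == length(fold_change),
            "amp_calls and fold_change lengths differ")
  ok <- !is.na(amp) & !is.na(fold_change)
  amp <- amp[ok]
  y <- fold_change[ok]
  stopIfNot(sum(amp) >= 1 && sum(!amp) >= 1, "one group is empty")
  if (sum(amp) < 3 || sum(!amp) < 3)
    warning("fewer than 3 tumors in a group")
  res <- markerRegressionP(y, as.integer(amp))
  r <- suppressWarnings(cor(y, as.numeric(amp)))
  m1 <- mean(y[amp])
  m0 <- mean(y[!amp])
  list(r = r, p = res$p, mean_amp = m1, mean_other = m0,
       mean_fold_difference = 2^(m1 - m0), n_amp = sum(amp),
       n_other = sum(!amp))
}
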