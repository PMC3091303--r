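---
title: "Methods: eQTL rewiring analysis during skin tumor progression"
author: "rewireQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eQTL rewiring analysis during skin tumor progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewireQTL)
```

## The scientific setting

rewireQTL analyzes how germline genetic control of gene expression changes
as tumors progress from normal tissue through benign to malignant stages in
a genetically heterogeneous mouse backcross. In an interspecific backcross
such as (SPRET/Ei x FVB/N) x FVB/N, every autosomal locus is either
heterozygous (HET) or homozygous for the recurrent strain (HOM_FVB) with
expected 1:1 frequency, which makes single-marker regression a natural eQTL
engine: for a binary genotype the slope test of `expression ~ I(HET)` is
exactly the equal-variance two-sample t-test.

The package covers, end to end:

* eQTL mapping per tissue (skin, papilloma, carcinoma) with family-wise
  permutation correction and Storey q-value FDR;
* cis/trans classification and architecture comparison across tissues,
  including conservation tests, tumor-specific eQTL, and "perturbation"
  eQTL mapped on matched normal-to-tumor expression changes;
* the same-host papilloma similarity permutation test;
* skin-to-tumor progression co-expression networks with a genome-wide
  error-rate (GWER) correlation threshold and clique filtering;
* aCGH copy-number calling, fraction-of-genome-altered summaries, and
  amplification-versus-expression association;
* susceptibility analysis: papilloma-burden classes, SAM differential
  expression, and the candidate gene table.

A synthetic cohort generator with planted, fully-known ground truth
exercises every stage; all quantitative claims made by the test suite and
the acceptance script are computed against that truth or against
independent oracles (closed forms, explicit enumeration, calibration
simulations).

## eQTL mapping

For each probe the scan records the lowest p-value across all markers
(`minPScan`). Family-wise correction (`permutationCorrectedP`) shuffles the
*rows* of the genotype matrix — whole animals — so that inter-marker
linkage is preserved under the null, recomputes the minimal p-value per
shuffle, and reports the fraction of shuffles at or below the observed
minimum. All probes share the same shuffles, which both matches the
"shuffled genotypes" design and lets the whole scan run as a handful of
matrix cross-products. With `n_perm` shuffles the corrected p-value has
granularity `1/n_perm`; a count of zero is displayed as `<1/n_perm` and is
substituted by `1/(2 n_perm)` before q-value estimation to avoid zeros.

Storey q-values (`storeyQvalues`) estimate the null proportion pi0 on the
lambda grid 0, 0.05, ..., 0.90 with a df-3 smoothing spline evaluated at
the grid maximum, then apply the step-up rule
`q(i) = min_{j >= i} pi0 m p(j) / j`. Below 20 p-values the estimator
falls back to pi0 = 1 (Benjamini-Hochberg behavior) because the smoother is
unstable there.

A consequence of the permutation granularity worth knowing: with `m`
probes and `n_perm` shuffles, the smallest achievable q is about
`pi0 * m / (2 n_perm k)` where `k` probes sit at the corrected-p floor. A
tissue needs roughly `k >= pi0 * m / (2 n_perm fdr)` floor probes before
*anything* is significant. This is faithful to the published design (1,000
shuffles, thousands of probes) but matters when choosing reduced test
scales; the test suite uses 150-400 shuffles with 150-300 probes
accordingly.

**Cis/trans.** A record is CIS when the peak marker is on the gene's
chromosome within a closed 30 Mb window (a distance of exactly 30 Mb is
cis), TRANS otherwise, UNPLACED without a gene position. Peak ties are
broken by genomic order for reproducibility. On sparse marker panels the
peak occasionally wanders to a linked neighbor far enough to flip a planted
cis effect to TRANS; this is expected scan behavior, not an error, and the
tests allow for it. X-linked genes are scanned but excluded from cis/trans
ratio summaries and per-chromosome conservation (restricted to autosomes).

**Degenerate regressions** (a genotype class absent, constant expression)
return p = 1 with a flag rather than aborting a genome scan.

**Missing genotypes** drop an animal from that marker's regression only,
never listwise.

## Perturbation eQTL

The perturbation scan regresses the per-animal difference (carcinoma minus
matched skin) on genotype. Probes enter only if they are expressed above
background in both tissues and have no significant steady-state eQTL in
either — so the perturbation and steady-state significant sets are disjoint
by construction. "Above background" is not defined in terms of the array
platform here: a probe is above background when its median log2 value
exceeds the 25th percentile of all probe medians (configurable), and the
threshold used is returned with the result.

## Same-host clustering test

Distances between papilloma profiles use 1 − Pearson correlation by
default (euclidean available). The statistic is the number of samples whose
nearest neighbor comes from the same animal; significance comes from
10,000 host-label permutations with the distance matrix computed once
(permuting labels is equivalent to permuting samples and much cheaper).
Because the statistic is a small integer, the reported permutation p-value
is conservative and discrete; the calibration tests therefore check exact
uniformity of the tie-randomized permutation p-value and super-uniformity
of the reported one, rather than pretending the reported p is continuous.

## Progression networks

Per-animal fold-changes (tumor minus genotype-matched skin) give each probe
a mean fold-change; probes beyond `sd_multiplier` (default 2) global SDs
are "extreme" with an UP/DOWN direction. Edges connect extreme probes whose
fold-change correlation reaches the GWER threshold: the 1 − alpha quantile
of the permutation distribution of the *maximum* absolute pairwise
correlation, with every probe's sample order shuffled independently. Nodes
are then filtered to membership in a clique of size >= 3, implemented as
triangle membership — every node of a k-clique (k >= 3) lies in a
triangle, so this is exact while avoiding maximal-clique enumeration — and
the filter is idempotent. Mixed-sign triangles are retained; edge signs
(DIRECT/INVERSE) survive filtering. Locus-anchored networks collect the
significant records peaking within 5 Mb (configurable) of a marker, draw
locus-to-gene edges plus GWER-thresholded gene-gene edges, and flag the cis
genes at the locus as candidate drivers.

## aCGH analysis

Calls use inclusive log2 cutoffs: ratio >= +0.3 is AMP, <= −0.3 is DEL.
Fraction of genome altered divides each chromosome into 1,000,000 equally
spaced bins (bin centers at `(j - 1/2) L / B`), each bin inheriting the
call of its nearest measured probe, exact-midpoint ties going to the
lower-Mb probe. The default implementation counts bins per nearest-probe
segment in closed form (`floor(mid B / L + 1/2)` differences) and equals
the explicit enumeration exactly; the enumeration mode is retained for
audit. Chromosome-level "gained" status uses >= 1 AMP probe by default,
with a fraction-of-probes mode (default 25%) behind a flag, since a
chromosome-level gain is not otherwise defined. Chromosomes without probes
are excluded from the denominator, with a message.

## Susceptibility analysis

Animals with more than 7 papillomas at week 20 are SUSCEPTIBLE, fewer than
2 RESISTANT; 2-7 inclusive form an INTERMEDIATE class excluded from
differential expression (both published thresholds are strict
inequalities). SAM uses the Tusher relative difference
`d = (mean_A - mean_B)/(s + s0)` with `s` the pooled standard error and
`s0` chosen by the percentile search (grid 0, 5, ..., 100) minimizing the
coefficient of variation of the MAD of `d` across s-quantile windows; with
`s0 = 0` and equal group sizes, `d` is exactly the t statistic. Per-probe
FDR comes from label permutations (median exceedance count over the
observed count, step-up monotone, clipped to [0, 1]). Papilloma pairs are
averaged per animal before SAM by default (consistent with the eQTL
analysis; disable with `combine_pairs = FALSE`). The candidate table is
the exact intersection of the SAM-significant set with the tumor-specific
eQTL set, with the published sign convention (negative fold-change =
higher in resistant animals), the higher-expressing genotype read off the
HET/HOM means at the record's peak marker, and rows ordered most
resistant-elevated first.

## The synthetic cohort

`simulateTumorCohort` generates one backcross cohort: genotypes, three
tissue expression matrices, aCGH profiles, and papilloma counts, all with
recoverable truth. Key design choices:

* **Genotypes** follow a per-chromosome two-state Markov chain with the
  Haldane map function `r = (1 - exp(-2d/100))/2`, `d` in cM at a fixed
  0.5 cM/Mb (mouse-genome scale; the study gives only Mb positions).
* **Default scale**: 100 animals, 230 markers, 2,000 probes, 2,504 aCGH
  probes, 60 carcinomas, papilloma pairs for all but 6 animals — matching
  the study's panel shapes at desk-scale runtime.
* **Steady-state eQTL**: 50 cis + 20 trans, effect 1.5 expression-SD on
  HET animals, attenuated by 0.6 per progression stage (skin 1.0,
  papilloma 0.6, carcinoma 0.36) — the mechanism behind the declining
  counts.
* **Host effect**: papilloma pairs share a per-animal, per-probe Gaussian
  deviation (SD 1) — the minimal mechanism that makes same-host tumors
  most similar under a correlation metric (a scalar per-sample intercept
  would be invisible to correlation distances).
* **Amplification event**: distal chromosome 7 (>= 125 Mb) gains in 45%
  of carcinomas; in-region aCGH probes of amplified tumors get log2
  ratios >= 0.4, and in-region genes get a +3 log2 expression boost that
  masks their planted cis eQTL in carcinomas — the Ccnd1/Hras1-style
  mechanism.
* **Tumor-specific eQTL**: five genes at the chromosome 14 protective
  locus active only in papillomas/carcinomas (HET-high, effect 2), some
  with low skin baselines so they read out as "expressed only in tumors";
  five more carcinoma-only eQTL elsewhere.
* **Response-only trans band**: twelve constitutively expressed probes
  driven by one shared trans locus whose effect is carried by the
  skin-to-carcinoma *change* (−beta/2 in skin, +beta/2 in carcinoma,
  beta = 2) underneath an animal-level deviation (SD 4) shared between
  the tissues; the deviation hides the steady-state halves and cancels in
  the fold-change, so the locus is only discoverable by the perturbation
  scan.
* **Papilloma counts** are negative binomial (size 3), mean 9 for
  HOM_FVB animals, multiplied by 0.3 for carriers of the protective HET
  allele — giving class sizes (about 11 resistant, 25 susceptible per 100
  animals) close to the study's 11/22 out of 71, with overdispersion so
  the count-QTL scan is exercised on a realistic surface.

What the generator does **not** emulate: microarray intensity
distributions and probe-level effects, batch structure, allele-specific
hybridization bias on an FVB-designed array, aCGH segmentation noise, and
linkage between the susceptibility locus and unrelated planted eQTL.
Passing tests therefore demonstrate correctness of the statistical
machinery and recoverability of planted mechanisms, not performance on
real microarray data.

## Numerical and testing choices

* Scan p-values come from closed-form cross-products; degenerate cells are
  settled deterministically (p = 1, or p = 0 under exact separation).
* All permutation machinery takes explicit seeds; identical seed and
  inputs give identical output, and seeded calls restore the caller's RNG
  stream.
* Matrices round-trip through TSV at full precision (`%.17g`).
* The acceptance checks run at the scales their statements fix (500 null
  probes with 200 shuffles; the default cohort; 100-replicate network and
  monotonicity panels; 10^6-bin enumeration on 20 random profiles; 200
  null cluster replicates). Where a check calls for a "reduced scale" the
  replicates use 60-100 animals, 150-300 probes, 100-230 markers and
  150-400 shuffles — chosen so that expected counts under the planted
  truth separate cleanly at the q-value granularity discussed above.
* The monotonicity panel plants only the attenuating architecture, since
  the claim it verifies is that attenuation alone shrinks significant
  counts stage by stage.

## Known limitations

* Single-marker scans only; interval mapping between markers is out of
  scope, so peak positions inherit the marker grid resolution.
* Probes need a single (chromosome, Mb) position; multi-mapping probes
  are not modeled.
* The GWER threshold permutes probes independently, which destroys
  inter-probe correlation under the null — the standard, slightly
  conservative choice for co-expression screens.
* SAM's permutation FDR uses the median-exceedance estimator without a
  pi0 correction; it is conservative for strongly non-null panels.
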