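# rewireQTL

Tools for asking how the germline control of gene expression is rewired as
tumors develop in a genetically heterogeneous mouse backcross. In an
interspecific backcross such as (SPRET/Ei x FVB/N) x FVB/N every autosomal
locus is HET or HOM_FVB with expected 1:1 ratio, so an expression
quantitative trait locus (eQTL) scan reduces to single-marker regression:
for probe *g* and marker *m*,

```
p_gm  from the slope test of  y_g ~ I(HET at m)        (= equal-variance t-test)
p_minimal-obs(g) = min_m p_gm
corrected p(g)   = #{ shuffles b : p_minimal-perm(g, b) <= p_minimal-obs(g) } / n_perm
```

where each shuffle permutes whole animal rows of the genotype matrix
(preserving marker linkage). Storey q-values over the corrected p-values
give the FDR; records are cis when the peak marker lies within 30 Mb of
the gene on the same chromosome, trans otherwise. Around this core the
package provides the downstream analyses of a tumor-progression study:
cross-tissue eQTL conservation, tumor-specific and perturbation
(normal-to-tumor fold-change) eQTL, a same-host tumor-similarity
permutation test, progression co-expression networks with a genome-wide
error-rate correlation threshold and clique filtering, aCGH copy-number
calling with fraction-of-genome-altered summaries, and SAM-based
susceptibility candidate tables. A synthetic backcross cohort generator
with planted truth makes every stage testable.

Audience: systems-genetics and cancer-genomics analysts working with
cross-based eQTL designs, and anyone needing a tested reference
implementation of minimal-p permutation eQTL mapping, Storey q-values,
SAM, or GWER correlation thresholds.

## Worked example

```r
library(rewireQTL)

## one synthetic discovery cohort: genotypes, skin/papilloma/carcinoma
## expression, aCGH, papilloma counts, with planted eQTL architecture
coh <- simulateTumorCohort(n_animals = 100, n_probes = 400,
                           n_markers = 230, seed = 7)
cfg <- rewireConfig(n_perm_eqtl = 200, seed = 7)

rec <- mapEqtl(coh$skin, coh$genotypes, cfg)
sum(rec$significant)
#> [1] 84
head(rec[order(rec$q, rec$p_raw), c("probe", "peak_marker", "p_raw",
                                    "p_perm", "q", "cis_trans")], 4)
#>     probe peak_marker        p_raw p_perm          q cis_trans
#> 355 P0355        M063 3.668526e-18      0 0.01158283     TRANS
#> 320 P0320        M203 3.794602e-17      0 0.01158283       CIS
#> 64  P0064        M051 6.155440e-17      0 0.01158283     TRANS
#> 330 P0330        M211 1.163901e-16      0 0.01158283     CIS

cisTransRatio(rec)[c("n_cis", "n_trans", "ratio")]
#> $n_cis   [1] 48
#> $n_trans [1] 32
#> $ratio   [1] 1.5

sameHostPermutationTest(coh$papilloma, n_perm = 10000, seed = 8)
#> Same-host clustering permutation test (correlation distance)
#>   N_observed = 188  mutual pairs = 94
#>   p = <0.0001 ( 10000 permutations )
```

84 of 400 probes have a significant eQTL at 10% FDR (the cohort plants 70
active skin eQTL of effect 1.5 SD, all recovered here, plus the usual
FDR-level complement of false positives); `p_perm = 0` means no genotype
shuffle beat the observed scan minimum, displayed as `<1/n_perm`. The
clustering test shows papilloma pairs from the same animal are far more
similar than label permutations allow (p below the 1/10,000 resolution),
the planted host-sharing effect.

Downstream: `tumorSpecificEqtl()` and `perturbationEqtlScan()` contrast
tissues, `buildProgressionNetwork()` builds the fold-change network
(export with `exportNetwork()` as SIF/GraphML for Cytoscape),
`fractionGenomeAltered()` and `amplificationExpressionTest()` summarize
the aCGH panel, and `susceptibilityDe()` + `candidateGeneTable()` produce
the susceptibility candidate table. See the methods vignette
(`vignettes/eqtl-rewiring-methods.Rmd`) for the models, defaults, and
their rationale.

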