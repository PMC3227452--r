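# senemeth

Analysis toolkit for studying how cultured human mesenchymal stromal cells
(MSC) change as they approach replicative senescence, along two axes:

1. **Growth kinetics.** Serial-passage cultures are summarized as population
   doublings per passage, `PDP_i = log2(h_i / s_i)` (cells harvested over
   cells seeded), and their cumulative sum CPD. Because only a shrinking
   subset of MSC — the fibroblastoid colony-forming units (CFU-f) — actually
   proliferates, the package also computes CFU-f-adjusted doublings
   `log2(h_i / (s_i · f_i))`, where the CFU-f frequency `f_i` is estimated
   from limiting-dilution assays under the single-hit Poisson model
   `P(well positive) = 1 − exp(−dose · f)` by pooled maximum likelihood with
   profile-likelihood confidence intervals.

2. **DNA methylation.** Beta-value matrices from promoter CpG arrays are
   quantile normalized, explored by PCA, filtered by absolute group-mean
   difference (|Δβ| > 0.15), and tested for consistent early-vs-late-passage
   differences with a from-scratch implementation of Significance Analysis
   of Microarrays (SAM): moderated statistic `d = r / (s + s0)` with a
   variance-stabilizing fudge factor `s0`, permutation null (exhaustive
   label shuffles or within-donor sign flips when feasible), asymmetric
   delta cut-points and permutation-estimated false discovery rates. The
   selected senescence-associated (SA) CpG sites are then mapped onto
   published chromatin-mark target sets (H3K4me3, H3K9me3, H3K27me3, EZH2)
   by RefSeq ID and by genomic position (±100 bp), and their
   over-representation is quantified with exact hypergeometric and Fisher
   tests.

A synthetic-data module generates array-scale beta matrices with planted
tissue and senescence signatures, mark categories biased toward the
high-methylation stratum, limiting-dilution well counts and multi-passage
growth series — all with known ground truth, so every pipeline stage has a
quantitative acceptance surface without any external download.

## Worked example

```r
library(senemeth)

cfg <- synth_config(n_cpg = 2000, n_sa_planted = 100, sa_delta = 0.25,
                    n_tissue_planted = 150,
                    marks = tibble::tibble(
                      name = c("H3K4me3", "H3K27me3"), size = c(600L, 400L),
                      high_frac = c(0.05, 0.85), sa_enrichment = c(1, 5)),
                    rng_seed = 2026)
sim <- simulate_methylation(cfg)
report <- run_senescence_analysis(sim$beta, sim$samples,
                                  annotation = sim$annotation,
                                  marks = sim$marks, seed = 1)
report
#> Senescence analysis report
#>   CpGs: 2000 in, 2000 complete
#>   delta-beta filter: 51 hyper / 49 hypo
#>   paired SAM: 141 SA CpGs (66 hyper, 75 hypo) at FDR 0.0284
#>   PCA: tissue separates on PC1, passage class on PC2
#>   top enrichment: H3K27me3 (p=1.9e-16), H3K4me3 (p=1)
```

Reading the report: the Δβ filter flags CpGs whose mean methylation moves by
more than 15 percentage points between early and late passage in the adipose
samples; paired SAM (late minus early within each donor) selects 141 SA
CpGs at an achieved FDR of 2.8%; the large planted tissue signature
dominates PC1 while the passage signature appears on a later component; and
the SA set is strongly over-represented among H3K27me3 targets
(hypergeometric `p_over = 1.9e-16`, fold 2.5) but not among H3K4me3 targets —
the planted enrichment recovered end to end.

```r
report$enrichment
#> # A tibble: 2 × 8
#>   category     N     K     n     k  fold   p_over p_under
#> 1 H3K4me3   2000   600   141    27 0.638 9.99e- 1 0.00176
#> 2 H3K27me3  2000   400   141    70 2.48  1.94e-16 1
```

Growth kinetics on a simulated culture whose CFU-f frequency decays from
20% to below 1% over ten passages:

```r
growth <- simulate_growth(seed = 1)
tail(growth_table(growth)[, c("passage", "f", "pdp", "cpd", "cpd_cfu")], 3)
#>   passage       f    pdp   cpd cpd_cfu
#> 1       8 0.0173  -0.805  7.35    40.1
#> 2       9 0.0122  -1.32   6.03    45.1
#> 3      10 0.00857 -1.89   4.14    50.1

estimate_cfu_frequency(simulate_dilution(0.2, seed = 1))
#>   f_hat ci_low ci_high loglik method status
#> 1 0.175  0.137   0.221  -78.5 ml     ok
```

Late passages lose cells (`pdp < 0`) so the conventional curve plateaus
near 4–7 doublings, while the CFU-f-adjusted curve keeps rising past 50 —
the proliferative subset is dividing far more than the bulk numbers
suggest. The limiting-dilution fit (4 doses × 48 wells) recovers the true
frequency 0.2 inside its 95% interval.

A thin command-line front end over the same functions is included at
`inst/cli/senemeth.R` (`simulate`, `growth`, `normalize`, `filter-delta`,
`sam`, `run-senescence` subcommands).

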