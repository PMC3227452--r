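---
title: "Models and methods behind senemeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind senemeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(senemeth)
```

senemeth analyses two facets of replicative senescence in cultured
mesenchymal stromal cells (MSC): the kinetics of long-term expansion, and
the DNA-methylation changes that accompany it. This vignette explains the
models, the parameters that matter, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Growth kinetics

### Population doublings

A passage that seeds $s_i$ cells and harvests $h_i$ represents
$\mathrm{PDP}_i = \log_2(h_i/s_i)$ population doublings;
$\mathrm{CPD}_n = \sum_{i \le n} \mathrm{PDP}_i$. Bulk doublings understate
the division history of the proliferative compartment, because only a
fraction $f_i$ of MSC — the fibroblastoid colony-forming units (CFU-f) —
found new colonies. The CFU-f-adjusted doubling counts divisions of that
compartment:
$$\mathrm{PDP}^{\mathrm{CFU\text{-}f}}_i = \log_2\!\frac{h_i}{s_i f_i}.$$
A ratio of counts ($h_i / (s_i f_i)$) is only a number of doublings after
taking $\log_2$; we therefore define the adjusted quantity with the
logarithm throughout, which also makes it commensurate with
$\mathrm{PDP}_i$ and reproduces the qualitative behaviour expected of such
curves (they dominate the conventional curve whenever $f_i \le 1$, with
equality exactly at $f_i \equiv 1$; a property test asserts this).

Terminal passages ($h_i = 0$) end a curve: the doubling is reported as
missing and the cumulative curve stops, rather than propagating $-\infty$.

### CFU-f frequency from limiting dilution

Wells seeded with $d$ cells are scored positive or negative for colony
growth. Under the single-hit Poisson model each seeded cell founds a colony
independently with probability $f$, so
$P(\text{negative}) = e^{-df}$. The estimator pools all doses through the
binomial likelihood
$$L(f) = \prod_d \binom{N_d}{k_d} p_d^{k_d} (1-p_d)^{N_d-k_d},
  \qquad p_d = 1 - e^{-df},$$
maximized by solving the score equation with `uniroot` (tolerance
$10^{-14}$; the score is strictly decreasing in $f$, so the root is
unique). With a single informative dose this reproduces the closed form
$\hat f = -\ln(1-k/N)/d$ to $10^{-9}$, which a test asserts against a grid
oracle. The 95% interval comes from profile likelihood at the
$\chi^2_1(0.95)/2$ drop. Assays with all wells positive (or all negative)
identify only a lower (upper) bound; they are flagged
(`status = "all_positive"` / `"all_negative"`) instead of being forced to
an interior estimate. A naive estimator (positives divided by cells seeded
at the lowest dose) is available via `method = "proportion"` for
sensitivity analysis only. Frequencies are fractions of cells; doses are
cells per well; the default design is 1/3/10/30 cells per well with 48
replicate wells, the layout used in MSC practice.

Because a well at dose $>1$ can be founded by several clones, "frequency"
here means the single-hit-model parameter, not a direct colony count; the
model is the standard one for such assays and its parameter recovery and
interval coverage are verified by simulation in the test suite.

## Methylation pipeline

### Normalization, PCA, Δβ filter

Beta values (methylation fractions in $[0,1]$) are quantile normalized so
that every sample shares the reference distribution formed by the mean of
the order statistics across samples; ties receive the mean of the
reference values at the tied ranks. We delegate to
`limma::normalizeQuantiles(ties = TRUE)`, the canonical implementation of
exactly this rule. On tie-free data the transform leaves all columns with
an identical sorted vector and is idempotent to $10^{-12}$ (both asserted);
with ties the averaged outputs deliberately depart from the pure
order-statistic reference, so exact idempotence holds only up to tie
groups.

PCA treats samples as observations and CpGs as centred, unscaled
variables (`prcomp`); beta values already share a scale, so variable
scaling would only amplify noise at invariant sites. Component signs are
fixed by making each component's largest-magnitude loading positive, for
run-to-run reproducibility. Missing beta values must be resolved first;
the package's policy is complete-case (drop CpGs missing anywhere, report
the count), the least surprising choice for the low missingness of
promoter arrays. `pc_association()` summarizes how strongly each component
separates a grouping factor by the between-group $R^2$ of its scores.

The Δβ filter selects CpGs whose group-mean difference exceeds a
threshold, default 0.15 — an **absolute** difference of methylation
fraction (15 percentage points), applied with strict inequality; a site at
exactly 0.15 is excluded. It is deliberately simple and resistant to
chip-level confounding.

Heatmap display uses row-mean scaling (each CpG divided by its mean,
leaving unit row means) and agglomerative hierarchical clustering with
Euclidean distance. The linkage is average by default — the common default
of interactive expression viewers — and exposed as an argument; merge
heights are verified against a brute-force agglomeration oracle.

### Significance Analysis of Microarrays

SAM is implemented from scratch in its two-class and paired forms:
$$d_i = \frac{r_i}{s_i + s_0},$$
with $r_i$ the group-mean difference (unpaired; orientation is second
factor level minus first) or the mean within-donor late-minus-early
difference (paired), $s_i$ the corresponding pooled or paired standard
error, and $s_0$ the fudge factor. With $s_0 = 0$ the unpaired $d$ equals
the classical pooled-variance $t$ statistic to $10^{-10}$ (asserted).

$s_0$ is chosen on the original recipe: candidates are the 0, 5, …, 100
percentiles of the $s_i$ distribution; features are split into quantile
bins of $s_i$ (up to 100, at least 20 features per bin); each candidate is
scored by the coefficient of variation across bins of the median absolute
deviation of $d$ (scaled by $1/0.64$); the minimizer wins. Two degenerate
cases are handled explicitly: an all-equal $s$ distribution returns that
value with a warning, and when zero-variance features exist (quantile
normalization can create exactly constant rows) the candidate $s_0 = 0$
is excluded, since $0/0$ statistics are undefined there.

The permutation null uses label shuffles (unpaired; $\binom{n}{n_1}$
distinct assignments) or within-donor sign flips (paired; $2^{n_d}$
patterns). When the distinct count is within the budget `B` (default
1000) the null is enumerated exhaustively and is seed-independent;
otherwise `B` distinct permutations are sampled without replacement under
the mandatory seed. Expected order statistics $\bar d_{(i)}$ are means of
the sorted null statistics.

For a threshold $\delta$, cut-points are asymmetric: walking outward from
the centre of $\bar d$ (defined tie-robustly by the sign of $\bar d$,
which is non-decreasing), the first sorted observed $d$ departing from
$\bar d$ by at least $\delta$ on each side sets the cut, and everything
beyond it is called. The estimated false discovery rate is
$$\widehat{\mathrm{FDR}}(\delta) = \pi_0 \cdot
  \frac{\mathrm{median}_b\,\#\{d^{*b} \text{ beyond the cuts}\}}
       {\#\{\text{called}\}},$$
capped at 1, defined as 0 when nothing is called. $\pi_0 = 1$ by default
(conservative); a quantile-based estimate from the central half of the
null is available. `select_significant()` takes the smallest tabulated
$\delta$ achieving the target FDR and splits calls by the sign of $d$
(positive = methylation gained in the second condition, reported as
hyper-methylated). The default $\delta$ grid combines a percentile ladder
of the observed departures $|d_{(i)} - \bar d_{(i)}|$ with the exact top
100 departures, so thresholds inside a gap between null-like and strongly
shifted features remain reachable.

Every quantity — $d$, $\bar d$, cut-points, false-call medians, FDR — is
checked against an independent brute-force enumeration on a small fixture,
and FDR calibration and planted-effect recovery are verified by
simulation.

### Chromatin-mark overlap and enrichment

Published ChIP target sets enter either as RefSeq accession lists or as
BED intervals (0-based half-open). A CpG belongs to a category if its
RefSeq accession (version suffix stripped) is listed, or if its coordinate
extended by ±`window` (default 100 bp, strand-agnostic — no strand rule is
defensible for a symmetric promoter window) touches an interval. The
boundary convention is pinned by tests: the closed probe window
$[p-w,\,p+w]$ is compared against the raw BED coordinates treated as a
closed interval, so an interval starting at coordinate $p+w$ matches and
$p+w+1$ does not; on the upstream side an interval ending at $p-w$
matches. Mixing a 1-based point with 0-based intervals is off-by-one on
one side under any convention; we fix the convention once, test it at the
exact boundaries, and keep it.

Per-category methylation summaries report the median, quartiles and
5th/95th percentiles of CpG-wise mean beta. Enrichment of a CpG subset in
a category uses the exact hypergeometric tails
($p_{\mathrm{over}} = P(X \ge k)$, $p_{\mathrm{under}} = P(X \le k)$, both
always reported, with fold $= (k/n)/(K/N)$); generic gene-set
over-representation uses Fisher's exact test with optional
Benjamini–Hochberg adjustment. The one-sided Fisher p equals the
hypergeometric upper tail on the same table (asserted). Raw per-category
p-values are the primary output (only a handful of mark categories are
ever tested at once); mutually exclusive variants such as "H3K27me3 only"
are built by set algebra on the computed membership maps
(`exclusive_membership()`), which is equivalent to interval-level algebra
for every analysis the package performs and far easier to verify. The
default enrichment universe is all CpGs passing the missingness filter;
restricting to platform-mappable CpGs is possible by passing that set as
`universe`.

## The synthetic-data generator

`simulate_methylation()` draws per-CpG baselines from a two-stratum beta
mixture: a low-methylation promoter mass (75% of sites, mean 0.05,
precision 15) and a high-methylation stratum (mean 0.5, precision 6).
These values were calibrated once so that the array-wide median of
CpG-wise mean beta lands near 5%, the typical promoter-array figure, and
are exposed as parameters rather than hard-coded. Senescence-associated
(SA) sites are planted as additive shifts (default 0.25) between passage
classes, tissue-specific sites (default shift 0.25) between adipose and
bone-marrow samples, with group means and draws clipped to
$[0.001, 0.999]$; per-sample noise is beta-distributed around the group
mean with precision 200 (roughly a 0.03 standard deviation mid-scale).
Additive shifts on the beta scale are a documented simplification — real
effects are likely multiplicative near the boundaries — chosen because the
entire analysis operates on beta values.

Three couplings give the generator its acceptance surface:

* mark categories draw a configured fraction of members (`high_frac`)
  from the high-methylation stratum, so repressive-mark categories sit
  above the array-wide median and active-mark categories at or below it;
* SA sites are sampled with weight `sa_enrichment` inside each category,
  so the realized inside/outside odds ratio approaches the configured
  factor (a Monte-Carlo test asserts this);
* planted directions respect feasibility: hyper-methylating sites need
  headroom above, hypo-methylating sites below. Tissue signatures are
  planted with balanced direction (half up, half down, each drawn from
  the feasible pool), mirroring the roughly balanced hyper/hypo counts
  seen in real cross-tissue comparisons; the SA hyper fraction (default
  0.30) is honoured up to feasibility — since SA sites concentrate in the
  high-methylation stratum, the hypo direction dominates, as it does in
  real senescence data.

The generator does **not** emulate array chemistry, probe types, detection
p-values, batch effects beyond an optional per-sample monotone distortion
(which quantile normalization must and does remove), donor effects, or
gender signatures. Passing tests therefore demonstrate the correctness of
the statistical machinery under the stated model, not robustness to every
artefact of real arrays.

`simulate_dilution()` draws well counts from the exact single-hit
binomial; `simulate_growth()` declines the CFU-f frequency exponentially
from 20% to below 1% over ten passages (rate 0.35 per passage) with five
doublings per proliferative cell per passage and a 5% lognormal counting
error — the canonical trajectory of MSC cultures approaching senescence.

Seeding: one master seed, deterministic child streams per component; the
same configuration and seed reproduce output bit-for-bit.

## Design choices and limitations

* **Paired vs unpaired senescence contrast.** The early-vs-late analysis
  is paired by donor (each donor contributes both passages), which
  cancels sample-level distortions; the tissue contrast is unpaired.
* **Joint normalization smears dense unbalanced signal.** When a large
  fraction of sites differs between groups, quantile normalization
  redistributes part of that signal into null features of the unpaired
  contrast. This is a property of the normalization, visible in the test
  suite, and a reason the pipeline's headline senescence analysis relies
  on the paired statistic.
* **Unstated upstream settings.** Published set sizes from comparable
  analyses depend on permutation counts, $\pi_0$, and cut-point details
  that are rarely reported; `replicate_published()` therefore prints a
  side-by-side comparison with the published counts without asserting
  equality.
* **Discrete p-values.** Hypergeometric p-values are discrete; on null
  configurations they are only approximately uniform, which the
  Kolmogorov–Smirnov size check accounts for with a loose level.
* **Problem sizes.** The test suite exercises the full 27,578-CpG scale
  where the property under test needs it (enrichment size/power, figure
  structure) and 1,000–2,000 CpGs elsewhere; simulation replicate counts
  (50 null calibrations, 100 enrichment seeds per arm, 1,000 coverage
  assays per frequency) were chosen to keep Monte-Carlo error comfortably
  inside the asserted tolerances.
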