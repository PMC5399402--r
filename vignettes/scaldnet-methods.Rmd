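---
title: "Models and methods behind scaldnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scaldnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaldnet)
```

scaldnet analyzes two-block (metabolome + transcriptome) time-course data
from cold-stored fruit to dissect delayed chilling injuries such as
superficial scald. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic-data generator
does and does not emulate.

## The multi-block PLS-DA model

The supervised core is a NIPALS multi-block PLS with a super-score layer.
Blocks are autoscaled (per variable: mean-centered, divided by the n−1
standard deviation) and then divided by the square root of their variable
count, so a 36,000-gene block cannot overshadow a 600-metabolite block at
the super level. For each component:

1. per block, weights `w_b ∝ X_b' u` (unit norm) and scores
   `t_b = X_b w_b` are computed against the current Y-residual score `u`;
2. the super score is `T = [t_1 … t_B] w_T` with unit-norm super weights
   `w_T`, whose entries measure each block's importance on that component;
3. Y-weights come from regressing the Y-residual on `T`, and both the
   blocks and Y are deflated by `T`.

Deflating every block by the shared super score makes successive super
scores mutually orthogonal and, with a single block, collapses the model
onto ordinary PLS2 — the test suite verifies both against an independent
textbook NIPALS implementation. The sign of each component is fixed by
requiring the Y-weight of a designated response (default: the last one;
the pipeline designates scald severity) to be non-negative.

The response matrix couples a categorical treatment factor (dummy-coded,
one indicator per treatment) with continuous storage day and scald
severity, all autoscaled with the same convention as X so that the
per-response explained-variance shares `SSY_ar` are comparable.

## VIP scoring, normalization, and selection

VIPs are computed per response (the pipeline uses scald severity). For
variable j in block b the raw Wold VIP is

VIP_j = sqrt( p_b · Σ_a SSY_ar w_ja² / Σ_a SSY_ar ),

with block weights unit-normed within their block, so Σ_{j∈b} VIP_j² =
p_b — the single-block convention under which the average VIP is one by
definition. In a multi-block model this leaves each block's VIPs on its
own scale, so a second, block-level rescaling multiplies each block by a
constant making every block's VIP **sum** equal to P_total/B. Two printed
facts pin this convention down: the grand mean of rescaled VIPs is exactly
one, and blocks of 610 and 36,253 variables give the narrow block a
~60-fold higher block-average VIP (36,253/610 ≈ 59.4). An alternative
normalization (equal Σ VIP² per block) exists but does not reproduce the
60-fold block-mean ratio together with the unit grand mean, which is why
the equal-sum convention was adopted; the raw VIP is reported alongside
for transparency.

Because the classic "VIP > 1" rule is meaningless after block rescaling,
selection is per block by the upper-tail rule `VIP > μ + t_{p,∞} σ`, with
`t_{p,∞}` the standard-normal upper-p quantile (0.4399 at the default
p = 0.33) and μ, σ the block's VIP mean and n−1 standard deviation.
Selected variables are split into positive and negative lists by the sign
of their Pearson correlation with the response; an exactly zero
correlation goes to the positive list (logged), and a constant response is
an error.

## Filtering, smoothing, clustering

The detection filter keeps a gene iff (a) some (treatment, day) cell has a
replicate sum strictly above 5 RPKM and (b) the gene is detected
(replicate sum > 0) in at least two cells. "Detected" is defined as a
positive replicate sum — zero is the only unambiguous non-detection in
RPKM units. The filter is idempotent and order-invariant; metabolites are
never filtered, only autoscaled (optionally log2-transformed first,
default off since relative-abundance platforms are already
quasi-logarithmic in dynamic range).

Gene summarization clusters PCA-smoothed profiles: the scaled expression
matrix (genes as points, all 72 observations as dimensions) is
reconstructed from its first 10 principal components, and Lloyd's k-means
runs once from 100 centroids drawn uniformly from the gene points without
replacement. Ties in assignment go to the lowest cluster index; empty
clusters are deleted after convergence (assignments unchanged, or 300
iterations); the within-cluster SSE is asserted non-increasing at every
iteration. Cluster mean profiles are averages of the *scaled, unsmoothed*
expression — smoothing only stabilizes the centroids, while the summary
profiles stay faithful to the data. Clustering uses all observations
rather than treatment-averaged profiles, which keeps replicate-level
variation available to the correlation stage.

## Correlation networks, anchors, refinement

Networks are built over the union of cluster means and individual
metabolites, restricted to replicate-level observations within a day
window: days {0, 7, 14, 28, 61} for the pre-symptomatic ("2-month")
network and all days for the symptomatic ("6-month") one. Replicate-level
observations (rather than per-time means) are used because more
observations stabilize r; at low noise the two choices agree. An edge is
added whenever r² ≥ 0.700 regardless of sign (the signed r is stored),
with weight 1 − r²; profiles constant within the window are excluded from
pairing and logged. Metabolite–metabolite, cluster–cluster and
cluster–metabolite edges are all eligible.

Anchor analysis takes the induced subgraph on an anchor metabolite and its
first neighbors (CTOL in the 2-month network, methanol in the 6-month
network, both configurable), then refines the member genes of any
neighboring clusters by keeping only genes whose own r² against the
anchor trace reaches 0.700 over the window. Node metrics are degree,
neighborhood connectivity (mean neighbor degree; 0 for isolated nodes)
and the local clustering coefficient (0 by convention below degree 2).
Graphs are exported as GraphML; layout is left to downstream viewers.

## Over-representation analysis

Functional bins are hierarchical dot-separated paths; a gene annotated to
`wall.pectin.PME` is counted in `wall`, `wall.pectin` and
`wall.pectin.PME`. Each bin with at least one background member gets two
one-sided hypergeometric tests (upper tail for over-, lower tail for
under-representation — reported separately rather than as one two-sided
Fisher test, matching how over- and under-expressed categories are
interpreted), Bonferroni-corrected by the number of bins actually tested.
Direction is called from the smaller adjusted tail at α = 0.05. Exact p
values with a standard α replace display-oriented score cutoffs used by
some ORA front-ends, whose meaning is tool-specific. The pipeline runs
ORA of the positive and negative VIP gene lists and of both refined
anchor lists, always against the full filtered gene set as background —
the conservative choice when no explicit background is stated.

## The synthetic-data generator

The generator emulates the study design: 3 treatments × 8 storage days
(0–183 d) × 3 replicates = 72 observations, with day-0 generated once and
shared across treatments (treatments are applied at harvest, so the
pre-treatment state is common). Scald severity follows the observed
phenotype on the 1–4 ordinal scale: control fruit pass score 2 after 61 d
and reach 4 by 183 d, DPA fruit reach only 2 at 183 d, 1-MCP fruit stay
at 1.

Planted signals act additively on log2 abundances:

* **CTOL-like** biphasic marker: zero until onset 14 d, linear rise to a
  92 d peak, linear decline to 25% of peak by 183 d — rising between 2
  and 4 weeks, peaking mid-storage, declining as symptoms appear;
  strongly damped under DPA (×0.15) and 1-MCP (×0.10).
* **methanol-like** late marker: exactly zero through 61 d, then a
  clamped logistic rise (midpoint halfway between onset and the final
  day, slope (183 − onset)/8) normalized to 1 at 183 d — mirroring
  symptom development, control-specific (DPA ×0.10, 1-MCP ×0.05), shared
  by six methyl-ester metabolites.
* **ripening background**: linear over the whole course, equal in control
  and DPA, damped under 1-MCP (×0.3).

Defaults: amplitude 2 log2-units per signal, noise sd 0.3 log2-units
(typical replicate-level RNA-seq variability), baselines log2-uniform on
[0, 10], 2,000 genes (40 CTOL-linked, 60 methanol-linked, 100 ripening,
rest noise) and 120 metabolites. A signal's genes and metabolites share
its amplitude, which makes a linked gene *exactly* proportional to the
signal's metabolites on the raw scale — so at vanishing noise their
correlation is identically 1, giving the zero-noise invariants their
analytic ground truth. Each planted gene set carries a distinct
`planted.<signal>` annotation bin; noise genes rotate through 15
background bins.

What the generator does **not** emulate: count-based sampling noise,
metabolite platform artifacts (drift, censoring, missing values),
regulatory cascades or autocorrelated residuals, and any gene–metabolite
relationship other than shared latent curves. Passing recovery tests
therefore demonstrates that the pipeline's inference machinery is correct
and well-calibrated under the planted model, not that real fruit data
would yield equally clean recovery.

## Numerical choices and degenerate inputs

* 3 model components by default (the interpreted structure lives in the
  first three latent-variable planes); configurable.
* NIPALS converges on the super score at relative tolerance 1e−10 (cap
  500 iterations); an exhausted Y-residual or a block with no Y-covariance
  is an error rather than a silent zero component.
* Zero-variance variables are dropped (and reported) at autoscaling;
  constant in-window profiles are excluded from networks; a single-variable
  block yields no VIP selection (σ undefined) with a warning.
* PCA components are sign-fixed by making the largest-magnitude loading
  positive; PCA smoothing errors when the requested components exceed the
  numerical rank.
* The VIP selection inequality is strict, so an all-equal VIP block
  selects nothing.

## Problem sizes and verification

The test suite runs entirely on synthetic data generated at test time:
recovery checks use the full 72-observation design with 2,000 genes
(five seeds), oracle checks use instances small enough for brute-force
enumeration (graphs ≤ 30 nodes, exhaustive 2-partitions, hypergeometric
tail sums), and the block-ratio computation uses the full 610 + 36,253
variable widths over 63 observations, where the NIPALS fit takes on the
order of a second. The acceptance script (`scripts/acceptance.R`) refits
both models from scratch at run time.

## Known limitations

* The number of components is fixed, not cross-validated; no permutation
  validation of the MBPLS-DA model is included.
* k-means uses a single initialization by design (matching the
  100-random-centroid protocol); it deliberately over-partitions and
  relies on the correlation stage to regroup clusters around anchors.
* ORA ignores bin overlap induced by the hierarchy when correcting for
  multiple testing (Bonferroni over all tested bins is conservative).
* The pipeline assumes complete data; missing-value imputation and
  RPKM computation from reads are out of scope.
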