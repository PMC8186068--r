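---
title: "Bias-aware gene set testing for methylation arrays"
author: "methylORA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias-aware gene set testing for methylation arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylORA)
```

# The problem

Gene set over-representation analysis of methylation-array results starts
from a list of significant CpG probes, maps them to genes through the array
manifest, and asks whether a gene set contains more "hit" genes than chance
would allow.  Two properties of array annotation break the central
hypergeometric model behind that question:

* **Probe-number bias.**  The number of CpGs measured per gene spans three
  orders of magnitude (a median around 20 on modern arrays, with a tail
  into the hundreds).  Under any significance rule applied per probe, a
  gene with 200 probes is far more likely to contain at least one
  significant probe than a gene with one.  Gene sets whose members are
  probe-rich are then enriched for composition reasons alone.
* **Multi-gene bias.**  Roughly one gene-annotated CpG in ten is annotated
  to two or more overlapping genes.  A single significant probe shared by a
  cluster of related genes — which tend to sit in the same gene set — can
  raise the naive overlap by the whole cluster size at once.

`methylORA` corrects both.  It is built around three ideas: reciprocal
multi-gene weights, an empirical probability weighting function (PWF), and
a one-sided Wallenius noncentral hypergeometric test.

# The model

Let CpG $i$ annotated to gene $j$ receive the weight
$w_{ij} = 1 / \#\{\text{genes annotated to CpG}_{ij}\}$, so each probe
distributes a total mass of 1 over its genes.  The *equivalent CpG count*
of gene $j$ is $N_j = \sum_i w_{ij}$; with no shared probes it is simply
the probe count.  Given the significant set $A$, the per-gene score is

$$S_j = \min\left(\textstyle\sum_{i} 1[\mathrm{CpG}_{ij} \in A]\, w_{ij},\; 1\right),$$

so a gene contributes at most one count no matter how many of its probes
are significant, and a probe shared by $k$ genes contributes $1/k$ to each.
The enrichment statistic of set $g$ is $ES_g = \sum_{j \in g} S_j$.

The PWF is the empirical probability that a gene is differentially
methylated as a function of its probe count: the binary indicator
$1[S_j > 0]$, ordered by ascending $N_j$, smoothed with a tricube moving
average (`limma::tricubeMovingAverage`).  A set's expected enrichment odds
are

$$ODDS_g = \frac{\mathrm{mean}\,PWF(\text{genes in } g)}
               {\mathrm{mean}\,PWF(\text{genes not in } g)},$$

and the p-value is the inclusive upper tail $P(X \ge \lfloor ES_g \rfloor)$
of Wallenius' noncentral hypergeometric distribution with $m_1 = J_g$
(genes of $g$ on the array), $m_2$ the rest of the universe, $n$ the number
of genes with any significant probe, and odds $ODDS_g$.  Three variants are
exposed: `GOmeth` (both corrections), `HGT-mod` (probe-number bias only:
integer counts, PWF ordered by raw probe counts) and `HGT` (plain
hypergeometric, odds 1) as the uncorrected baseline.

Region-based analysis (`goregion()`) reduces to the same machinery: DMRs
are overlapped with the single-basepair CpG coordinates, and the CpGs under
the regions become the significant set.  Region detection is itself driven
by probe density, so the same PWF correction applies unchanged.

# Parameters that matter

* `span` (default 0.5): fraction of the gene universe covered by the
  tricube window.  The smoother uses a centred odd window, truncated and
  weight-renormalised at the edges, so constant inputs are reproduced
  exactly.  0.5 is the long-standing default of the smoother's reference
  implementation; smaller values track the bias trend more locally at the
  price of noise.
* `method`: `GOmeth` unless you deliberately want a partially corrected or
  uncorrected comparator.
* `adjust`: BH by default; Holm available where family-wise control is
  wanted.
* Region filters (`filterRegions`): keep regions with at least 3
  underlying CpGs and mean $|\Delta\beta| \ge 0.1$ by default, both
  boundary-inclusive (a region is removed only when strictly below a
  threshold).  Either filter can be disabled; some data sets are
  deliberately tested unfiltered.
* Gene set size filtering (`filterBySize`, 5–5000) is available but off by
  default: the Wallenius tests do not need it, it exists to mirror the
  protocols of methods that do.

# Numerical choices

* **Wallenius tail.**  No suitable evaluator ships with base R, so the
  package computes the probability mass from the integral representation
  $P(X=x) = \binom{m_1}{x}\binom{m_2}{n-x} D \int_0^1 (1-s^\omega)^x
  (1-s)^{n-x} s^{D-1}\,ds$ with $D = \omega(m_1-x) + m_2-(n-x)$, in log
  space, using level-refined tanh–sinh quadrature around the analytically
  located mode.  Tails are summed over the shorter side of the support.
  Agreement is machine-level against the central hypergeometric at
  $\omega = 1$ and within $10^{-8}$ of an exhaustive draw-sequence
  enumeration on small urns; the suite asserts both.  The statistic is
  floored ($x = \lfloor ES_g \rfloor$), which makes the test slightly
  conservative when scores are fractional; rounding instead would trade
  that conservatism for anti-conservatism on half-counts, and flooring is
  the behaviour the score definition implies.
* **Draws are integers.**  $n$ counts genes with $S_j > 0$, unweighted;
  fractional information enters through $x$ and the odds, not the number
  of draws.  Significant CpGs with no gene annotation are ignored for the
  urn and reported separately.
* **The PWF indicator is $S_j > 0$**, not $S_j = 1$: a gene whose only
  significant probe is shared is still differentially methylated.
* **Tie-breaking.**  Genes with equal ordering counts are sorted by gene
  id before smoothing, and result rows with equal p-values are ordered by
  set id, so every run is exactly reproducible.
* **Degenerate cases.**  An all-zero out-of-set PWF mean caps the odds at
  $10^6$ with a warning; sets that do not intersect the universe are
  reported with $p = 1$; an empty significant set warns and returns all
  $p = 1$; a universe smaller than two genes refuses to run.
* **Feature restriction recomputes weights.**  After restricting to, say,
  promoter features, a CpG that kept only one of its genes gets weight 1.
  Reusing full-annotation weights would under-count restricted links; the
  restricted table is treated as the array the analysis sees.
* **Coordinates.**  Regions live in `GRanges` (1-based closed) —
  BED input is shifted on import, CSV input declares its convention — and
  a CpG overlaps a region when its single basepair lies inside it.  Strand
  is ignored.

# What the synthetic generator emulates

`syntheticAnnotation()` reproduces the composition statistics that drive
both biases, calibrated to a modern array: ~70% of CpGs annotated to at
least one gene, ~9% of gene-annotated CpGs shared between (adjacent) genes,
and a heavy-tailed CpGs-per-gene distribution.  The per-gene counts are
1 + negative binomial with dispersion (size) 1.2 and mean solved
numerically so the median is 20; draws of 10,000 genes then span 1 to a few
hundred CpGs per gene.  Sharing is placed between genomically adjacent
genes, and `syntheticGeneSets()` builds 30% of its sets around a contiguous
genomic block (half of the set's members), so shared CpGs concentrate
within sets the way clustered gene families do on real arrays — the
mechanism that turns a single shared probe into a spurious enrichment for
an uncorrected test.  Set sizes are log-uniform on 10–500.

What it does *not* emulate: beta-value distributions, correlated
methylation along the genome, cell-type mixtures, array noise, or a
realistic gene-set ontology with nested terms.  Calibration results on this
generator therefore demonstrate that the corrections remove the biases the
generator contains — the composition biases — not that every property of
real data is covered.

The null harnesses mirror two designs: `sampleNullCpGs()` draws uniform
random "significant" sets of 50–10,000 CpGs, and `simulateNullTwoGroup()`
assigns samples from one shared per-CpG normal model to two artificial
groups of $n = 10$, ranks CpGs by the two-sample $t$ magnitude and takes
the top 1000 — the ranked-input workflow used when nothing is truly
significant.  An ordinary $t$ replaces moderated statistics deliberately:
under an exact null the ranking is uniform either way, and the harness
needs no variance shrinkage machinery.

# Problem sizes used by the shipped experiments

The packaged acceptance experiments run the full null design at 10,000
genes (≈340,000 CpGs), 300 gene sets, 50 replicates per significant-set
size for sizes {50, 100, 500, 1000, 5000, 10000}, and 50 two-group seeds —
a few minutes on one core.  The published design of this kind of study uses
100 replicates; medians over 50 are already stable to well within the
margin the calibration claims need.

# Known limitations

* The Wallenius urn treats genes as exchangeable given the PWF; residual
  correlation between genes beyond probe count (e.g. co-methylation of
  neighbouring genes among *significant* probes) is not modelled.
* With very large significant sets (tens of thousands of probes) the gene
  universe saturates and all tests lose resolution; restricting input to
  the top-ranked probes or moving to a region-based analysis is the
  supported route.
* `walleniusOracle()` is an exhaustive enumerator for verification only;
  it refuses urns above 12 balls.
* The uncorrected `HGT` variant is provided as a comparator, not as a
  recommended analysis.
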