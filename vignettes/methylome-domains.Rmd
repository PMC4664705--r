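---
title: "Window-based DMR calling and megabase domain analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based DMR calling and megabase domain analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(badscan)
```

## The statistical model

badscan compares two WGBS methylomes (control vs treatment, two replicates
each) at the level of 300 bp tiling windows. The data model per CpG site is
a binomial read count: of `total` reads covering the site, `meth` report a
methylated cytosine, and the methylation level is `100 * meth / total`.
Sites on the two strands are independent observations — strand collapsing
into dinucleotide units is deliberately **not** performed, because per-C
counting is the conservative reading when the upstream processing is not
known to have collapsed strands; a user who wants dinucleotide units can
collapse positions before constructing the `methylome`.

Counts are pooled across the CpG sites of a window before testing: the
inference target is the regional methylation difference across the window,
not site-level differences. Each treatment replicate is tested against the
**pooled control** (pooling both control replicates maximizes control
coverage per window) with Fisher's exact test on the 2x2 window table. The
two-sided p-value is the sum of the probabilities of all tables with the
same margins whose hypergeometric probability does not exceed the observed
table's. The Benjamini-Hochberg step-up adjustment is applied genome-wide
within each replicate comparison — autosomes and the X-like chromosome
together, since per-chromosome adjustment is a different (and here
unmotivated) error-rate target.

A window is a DMR iff in *both* replicate comparisons:

* BH-adjusted value `q < alpha` (default 0.1),
* absolute pooled methylation difference `|diff| >= min_diff` (default
  0.25, with a tie at exactly 0.25 included), and
* the sign of the difference agrees.

Requiring the effect size per replicate comparison (rather than on a
pooled treatment) is the stricter of the two readings of a
"reproducible" difference, and it makes the DMR set invariant under
swapping replicate labels, which the test suite asserts.

### Assumptions

* Read counts within a window are exchangeable across sites — the Fisher
  test treats the pooled window as one binomial sample per condition.
  Correlated coverage (PCR duplicates, mappability) would make p-values
  anti-conservative; upstream deduplication/filters are assumed.
* No smoothing is applied by default. A centered running-mean smoother
  over `smooth_k = 5` windows exists behind the `smooth` flag of
  `call_dmrs()` (applied to window fractions only; p-values always use raw
  counts), but it is off because defensible smoothing parameters depend on
  data the package does not see.
* Windows with pooled coverage below `min_total_reads = 5` in any compared
  sample are skipped — a guard against near-empty windows whose Fisher
  test is uninformative.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `window_size` | 300 | bp | the regional scale of the test; ~3 CpGs per window at 100 bp spacing |
| `min_diff` | 0.25 | fraction | separates biologically meaningful regional shifts from coverage noise at ~25x |
| `alpha` | 0.1 | FDR | step-up control per replicate comparison |
| `min_total_reads` | 5 | reads | coverage floor per sample per window |
| `bin_size` | 5e5 | bp | megabase-scale clustering unit for domains |
| `quantile` | 0.75 | — | top-quartile rule for domain-qualifying bins |
| `flank` | 1e4 | bp | gene association window extension, symmetric and strand-agnostic |
| `n_perm` | 1000 | — | permutation resolution; the smallest attainable p is 1/(n_perm+1) |

## Numerical choices

* **Quantile convention.** The domain threshold is the empirical-CDF
  linear-interpolation quantile (`stats::quantile(..., type = 4)`) of the
  counts over bins containing at least one feature. On the counts
  {1, 5, 6, 7, 1} this gives 5.75, so bins with 6 and 7 qualify under the
  strictly-greater rule — the behaviour the domain caller is specified
  and tested against. The R default (type 7) would give 6 and drop one
  of the two bins.
* **Nonzero bins only.** The quantile is computed over occupied bins. With
  genome-wide sparsity the all-bins quantile degenerates to 0 and
  "more than the quantile" would qualify *every* occupied bin; restricting
  to occupied bins keeps the rule selective (a genuine "top quartile").
* **Strict inequality, one degenerate exception.** Qualifying bins must
  exceed the threshold strictly. If all occupied bins share one count the
  threshold equals it and no domain is called (warning). The one
  degenerate case where the strict rule is self-defeating — a single
  occupied bin genome-wide, which *is* the whole top quantile — is called
  as one domain.
* **Domain trimming.** A domain's interval runs from the first feature in
  its first bin to the last feature in its last bin, which is why a
  single-bin domain can be shorter than one bin — consistent with domain
  catalogues whose minimum domain size is below the binning unit.
* **Fisher ties.** Table probabilities within a relative 1e-7 of the
  observed probability count as ties (they are mathematically equal
  probabilities computed along different floating-point paths). Tables
  with a zero margin have a single attainable configuration and get p = 1
  by convention, reported via `message()`.
* **Level clipping.** Planted shifts that would push a true level outside
  [0.01, 0.99] are clipped (and counted in a `message()`); levels of
  exactly 0 or 1 would make replicate jitter meaningless and create
  degenerate binomials.
* **Band bucketing.** Control-level bands are `[0, 25]`, `(25, 75]`,
  `(75, 100]` percent, a partition of covered element instances; an
  instance is the intersection of an element with one 300 bp grid cell
  (kept per-cell — adjacent cells are *not* merged), so band statistics
  are on the same footing as window statistics.
* **Permutation p-values** use the add-one estimator
  `(1 + #{perm >= obs}) / (n_perm + 1)`, which is never zero and is valid
  under the null.

## What the synthetic generator emulates — and what it does not

`simulate_methylomes()` draws CpG positions as a geometric point process
(mean spacing 100 bp), coverage as Poisson(25) truncated at >= 1, and reads
as Binomial(coverage, level). True levels are 0.8 background / 0.1 in
island-like regions; planted domains (3 per chromosome, 0.3–2 Mb) shift
the treatment level by +0.4 on autosome-like and −0.4 on X-like
chromosomes. Planted hyper-domains sit on a partially methylated (0.45)
pre-shift background in **both** conditions: a +0.4 shift from the 0.8
background would saturate and clip everywhere, destroying the very
contrast the domain plants; biologically this mirrors partially methylated
domains being the substrate of methylation gain. Replicate-level true
levels get independent uniform ±0.02 jitter per site, a minimal stand-in
for biological replicate variability.

`simulate_tracks()` builds satellite-like elements preferentially inside
hyper-domains, enhancer-like elements inside X-like hypo-domains,
uniform LINE-like elements, islands/shores from the methylome ground
truth, peaks placed away from X-like hypo-domains (producing the negative
occupancy/methylation rank correlation on the X-like chromosome), genes
with repressed labels preferentially inside domains, and a LAD track in
which a randomized-rounding fraction (expectation = the configured 0.6) of
planted autosomal domains each receive a covering LAD clipped against
neighbouring domains, with background LADs kept away from all planted
domains — so the realized domain/LAD overlap is controlled by
construction.

Not emulated: read-level artefacts (bisulfite conversion failure, mapping
bias, PCR duplicates), CpG density heterogeneity beyond the island model,
distance-decaying methylation autocorrelation, copy-number variation, and
mixed Xi/Xa cell populations. Passing recovery tests therefore
demonstrates the correctness and calibration of the *inference machinery*
under the stated noise model, not robustness to every artefact of real
WGBS data.

## Problem sizes

The default generator uses a 40 Mb genome (three 10 Mb autosome-like
chromosomes, one 10 Mb X-like), ~400,000 CpG sites and four samples —
large enough for ~130,000 testable windows and stable recovery statistics,
small enough that the full pipeline runs in well under five minutes on one
CPU. Unit tests use 0.3–6 Mb genomes; the LAD-geometry checks across 20
seeds use a sparse 3 kb CpG spacing because domain/LAD geometry does not
depend on the methylomes at all.

## Resolved design questions

* *Pooled vs per-replicate treatment testing*: each replicate is tested
  separately and reproducibility across both is required; the alternative
  (one test on pooled treatment) has no replicate-reproducibility notion.
* *Hyper and hypo DMRs are binned jointly* before domain calling, with
  domain direction assigned by majority of member DMRs (ties labelled
  hyper with a warning); the X-like and autosome-like chromosomes then
  compete in one genome-wide threshold, matching a "genome-wide DMR
  distribution" reading. Direction-split binning is available by simply
  subsetting the DMR set before `bin_features()`.
* *Domain-overlap significance* uses bin units (all genome bins as the
  population, LAD-containing bins as successes, domain bins as draws)
  because domains vary in length; the descriptive whole-domain overlap
  fraction is reported alongside.
* *Element enrichment significance* is an unnamed test upstream; a
  width- and chromosome-preserving permutation test was chosen because it
  respects the chromosome-scale composition differences that are central
  to the autosome-vs-X contrast.

## Known limitations

* The Fisher/BH/threshold procedure is the specified inference; no
  beta-binomial dispersion modelling or smoothing-based shrinkage
  (DSS/methylKit-style) is provided, so overdispersed real data may show
  more false positives than the binomial model predicts.
* The BH step-up adjustment is monotone and sort-stable, but re-applying
  it to its own output is not an identity in general; adjusted values are
  reported once and must not be re-adjusted.
* Enrichment ratios depend on the merged element footprint; for heavily
  fragmented tracks the per-feature overlap count (also reported) is the
  more interpretable number.
* The chromosome summary reports a chromosome with no covered CpG as
  missing (`NA`), never as 0 % methylation.
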