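---
title: "Methods: a gene-level scan of SNP array signal intensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a gene-level scan of SNP array signal intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpsignal)
```

## The problem and the model

A biallelic genotyping array reports two fluorescence intensities per SNP
and sample, one per allele probe (A and B). Genotype calling collapses
this pair into one of three discrete classes and discards the magnitudes.
`snpsignal` works on the magnitudes instead: in a case/control design
(here motivated by cattle with ovarian pathologies versus healthy
controls), it asks, gene by gene, whether the distribution of normalized
total intensity differs between the two groups.

The normalized quantity is a per-SNP log ratio. For SNP $s$ and sample
$j$, with $T_{js} = A_{js} + B_{js}$ and the per-SNP across-sample median
$M_s = \mathrm{median}(T_{1s}, \dots, T_{Ns})$,
$$v_{js} = \log_2\!\left(\frac{T_{js}}{M_s}\right).$$
Using the median of *all* samples as the reference (not a per-group
median) means $v$ measures each sample's deviation from the cohort-typical
intensity at that SNP. For an odd number of samples the per-SNP median of
$v$ is exactly zero (the median commutes with the monotone $\log_2$); for
an even number it is $\le 0$, with equality only when the two middle
totals tie, because the median averages the two central order statistics
arithmetically while the log-scale midpoint is their geometric mean. Cells
with $T = 0$ are masked rather than floored or imputed: any pseudo-count
would bias the log ratio by an arbitrary amount, and downstream code
simply drops masked cells.

## The gene scan

SNPs map to genes by position, inclusive of both gene ends; a SNP inside
two overlapping genes counts for both. Genes with at least 15 SNPs
(`scan_config(min_snps = 15)`) are eligible — a precision filter: with 6
samples per group, a 15-SNP gene yields vectors of 90 observations per
group. For each eligible gene the case and control vectors concatenate
$v_{js}$ over the gene's SNPs (positional order) and the group's samples;
this (SNP × sample)-cell layout is the only reading under which the
per-gene two-sample tests have meaningful sample sizes.

Two tests are run per gene:

* **variance**: $F = s^2_{\text{case}} / s^2_{\text{control}}$ with
  $(n_1 - 1, n_2 - 1)$ degrees of freedom, two-sided by doubling the
  smaller tail probability and capping at 1;
* **mean**: the Welch unequal-variance $t$-test. Welch is chosen because
  variance equality is itself under test; pooling would condition one
  test on the other.

The Benjamini–Hochberg step-up rule is applied at $\alpha = 0.05$,
implemented literally: sort the $m$ p-values ascending, let $k$ be the
largest $i$ with $P_{(i)} \le \alpha i / m$, reject the $k$ smallest.
Ties cannot split across the boundary (an equal p-value that passes at
rank $i$ passes at every larger rank). The correction is applied
**separately** to the mean-test and the variance-test families; the
headline significant set (`bh_significant`) is the mean family. A joint
correction over both families ($m = 2 \times$ genes) would also be
defensible; separate families were chosen so each test's FDR is
interpretable on its own.

The observations within a gene are treated as exchangeable: the tests
ignore SNP-level correlation and the weak cross-sample dependence that
median-centering introduces. This reproduces the procedure as a
practitioner would run it rather than correcting it; the measured
consequence (see the acceptance suite) is a mild inflation of the
empirical FDR above the nominal level — about 0.052 rather than
$\pi_0 \alpha = 0.045$ in the synthetic regime below — which still sits
inside the two-Monte-Carlo-standard-error band around 0.05.

Degenerate genes — fewer than two usable values in a group, or zero
variance in both groups — are excluded from testing but recorded in a
skip log attached to the result, never silently dropped.

## PCA differentiation

The genome-wide view is a samples-by-genes feature matrix: cell
$(j, g)$ is the mean of sample $j$'s unmasked normalized values over gene
$g$'s SNPs, computed over the significant genes. Concatenating raw
per-gene vectors instead would give a ragged object; the per-gene mean is
the minimal rectangular reduction. The matrix is column-centered and
decomposed by covariance PCA (sample covariance, divisor $n-1$, via the
SVD of the centered matrix); eigenvalues are reported non-increasing and
sum to the trace of the covariance matrix. Eigenvector sign is inherently
arbitrary, so PC1's sign is fixed by requiring the case-group mean score
to be non-negative (other components: largest-magnitude loading
positive), making score plots reproducible run to run. The per-gene view
(`gene_pc1_profile`) applies the same decomposition to one gene's
samples-by-SNPs matrix and rescales PC1 scores to unit maximum absolute
value, the layout of a per-sample loading bar chart.

## The synthetic-data generator

No public equivalent of the study's raw array data is assumed, so the
generator emulates its design: 6 cases vs 6 controls by default, genes
laid out as non-overlapping intervals whose SNP counts straddle the
15-SNP eligibility threshold (default 10–20), intergenic markers between
them. Per SNP, a baseline level $b_s \sim N(\mu_0, \sigma_b^2)$ is drawn
once ($\mu_0 = 10$ log₂ units, i.e. totals around $2^{10}$ fluorescence
units — a realistic array scale; $\sigma_b = 0.5$); per cell,
$t_{js} = b_s + e_{js}$ with $e_{js} \sim N(0, \sigma^2)$,
$\sigma = 0.3$ log₂ units by default. Effect genes (a configurable
fraction, default 10%) add a mean shift $\delta$ (default 1.0 log₂ units)
and multiply $\sigma$ by a variance-inflation factor for case samples
only. The emitted total is $T = 2^t$, split as $A = uT$, $B = (1-u)T$
with $u \sim U(0.05, 0.95)$ per cell — positivity and $A + B = T$ hold by
construction, and the split is irrelevant downstream since only $T$ is
analyzed. One seed drives a single random stream in fixed draw order, so
equal seeds give bit-identical files.

What the generator does **not** model: genotype cluster structure (the
three-cloud A/B geometry), probe GC bias, batch and plate effects, linkage
disequilibrium between markers, and B-allele-frequency structure. Tests
passing on this generator therefore demonstrate the pipeline's statistical
operating characteristics under clean additive noise, not robustness to
real array artifacts.

## Numerical choices and edge cases

* Even-count medians use the arithmetic mean of the two central order
  statistics (the 12-sample design forces a convention).
* The two-sided F-test p-value is $\min(1, 2\min(\Pr(F \le f),
  \Pr(F \ge f)))$; p-values are clamped into $(0, 1]$.
* Region length is `end - start` (coordinate difference), matching the
  arithmetic used for the arbitrary-region control; SNP containment stays
  inclusive of both endpoints.
* Interval overlap is strict (`max(starts) < min(ends)`): touching
  intervals do not overlap.
* Pathway coverage percentages are truncated, not rounded, at two
  decimals — the convention that reproduces the printed reference rows.
* Haplotype group-consistency uses the strongest reading: a pattern must
  occur in every sample of one group and no sample of the other.
* BH ties are broken by the stable order of the sorted sequence (and, as
  noted, cannot straddle the rejection boundary).

## Problem sizes

The acceptance study runs 50 replicates of 1000 eligible genes (15–20
SNPs each, ~22,000 markers, 12 samples) — about 4 minutes on one CPU.
Unit and property tests use 20–700 genes per dataset; the analysis
scripts use 500 genes. These sizes give stable Monte-Carlo estimates
(FDR standard error ≈ 0.003) while staying interactive; the generator
scales linearly in markers × samples if a full 648k-marker emulation is
wanted.

## Known limitations

* The scan treats within-gene observations as independent; on real data
  with linkage disequilibrium the effective sample size per gene is
  smaller than the vector length and p-values are anticonservative.
* The variance-test family is sensitive to non-normality of the log
  ratios (the F-test has no robustness to kurtosis).
* The eligibility filter conditions the tested set on marker density, so
  gene-level results are not comparable across arrays with different SNP
  panels.
* `evaluate_recovery` scores only eligible effect genes; effects planted
  in sub-threshold genes are invisible to the scan by design.
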