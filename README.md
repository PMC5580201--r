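# snpsignal

Genome-wide scan of SNP genotyping-array **signal intensities** for
differentiating two groups of samples — e.g. diseased versus healthy
animals — gene by gene, without using the called genotypes.

Genotyping arrays measure two fluorescence intensities per SNP and sample,
one per allele probe (A and B). Beyond the base-pair genotype they encode,
these intensities carry quantitative information (copy number, probe
chemistry, regulatory signal) that a two-group comparison can exploit.
`snpsignal` implements that comparison end to end for a case/control
design, together with a seeded synthetic-data generator so every stage can
be exercised and calibrated without access to proprietary array data.

## The method

1. **Normalization.** Per SNP *s* and sample *j*, the total intensity is
   *T<sub>js</sub> = A<sub>js</sub> + B<sub>js</sub>*; the per-SNP
   reference is the across-sample median
   *M<sub>s</sub> = median(T<sub>1s</sub>, …, T<sub>Ns</sub>)*; the
   normalized value is *log₂(T<sub>js</sub>/M<sub>s</sub>)*. Cells with
   *T = 0* are masked, never floored.
2. **Gene scan.** SNPs are mapped to genes by position (inclusive of both
   gene ends); genes with at least 15 SNPs are eligible. For each eligible
   gene, case and control vectors concatenate the normalized values over
   (SNP × sample) cells. A two-sided F-test
   (*F = s²_case / s²_control*, p = 2·min(tail probabilities) capped at 1)
   tests equality of variance; a two-sided Welch t-test tests equality of
   means.
3. **Multiple testing.** The Benjamini–Hochberg step-up rule at α = 0.05:
   order the p-values ascending, find the largest *i* with
   *P(i) ≤ α·i/m*, and declare the *i* smallest significant — applied
   separately to the mean-test and variance-test families.
4. **Differentiation.** A samples-by-genes feature matrix (per-sample mean
   of normalized values over each significant gene's SNPs) is decomposed
   by covariance PCA; PC1 scores should separate the two groups. A
   per-gene PC1 loading profile gives the single-gene view.
5. **Region controls.** Arbitrary-region and flanking-SNP tests (the
   signal should live in the gene, not its surroundings), a CNV
   declaration filter (≥ 3 adjacent SNPs spanning ≥ 1 kb), interval
   overlap, pathway coverage arithmetic, and a haplotype
   group-consistency check.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (500 genes, 6 cases vs 6 controls, 10% of genes carrying a +1.0 log₂
mean shift):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_normalize.R
Rscript analysis/03_scan.R
Rscript analysis/04_pca.R
Rscript analysis/05_regions.R
```

which prints, among other things:

```
simulated 9946 SNPs x 12 samples; 500 genes (272 eligible), 50 with planted effects
tested 272 eligible genes; 29 BH-significant (mean family), 0 (variance family)
recovery vs planted truth: TP 26, FP 3, FN 0 -> empirical FDR 0.103, power 1.000
PC1 explains 98.0% of variance (PC2 0.4%)
PC1 linearly separates cases from controls: TRUE
top gene G0336: span 1750 bp, 18 SNPs, mean-test p = 6.22e-74
average mean-test p of its two 5-SNP flanks: 0.442
null region chr1:43501-45151 (17 SNPs): mean-test p = 0.682
```

Read: all 50 planted genes that passed the eligibility filter were
recovered (plus 3 false positives among 272 tests, a single-replicate
empirical FDR of 0.10); the group separation is carried by PC1; the
flanking SNPs and a random null region show no signal, so the effect is
localized to the genes it was planted in.

The same pipeline runs as one call:

```r
library(snpsignal)
run_pipeline(pipeline_config(mode = "simulate", out_dir = "out", seed = 42))
```

which writes `results.tsv`, `scores.tsv`, `skipped.tsv` and a
`manifest.json` recording the seed, a config hash and per-stage timings.

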