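# crosstrait

Integrative analysis of the shared genetic basis of complex traits from
GWAS **summary statistics** alone. `crosstrait` is written for statistical
geneticists who have per-SNP Z-scores for two or more traits, a
block-partitioned LD reference, and (optionally) cis-eQTL expression
weight models — and who want, in one tidyverse-native package:

* **TWAS** — the association between cis-predicted expression and a trait,
  `Z = w'z / sqrt(w'Vw)` for weight vector `w`, GWAS Z-scores `z` and
  reference LD `V`, with Bonferroni families, a weight-permutation
  robustness test, conditional GWAS traces and novelty classification
  against known risk regions;
* **Genome-wide genetic correlation** — LD score regression of `z²` (and
  cross-trait `z₁z₂`) on LD scores with free intercepts, `ĥ² = slope·M/N`,
  `r̂_g = ĝcov / sqrt(ĥ²₁ ĥ²₂)`, block-jackknife standard errors;
* **Local genetic correlation** — per-LD-block heritability
  `(z'V⁺z − k)/(n − k)` and covariance `z₁'V⁺z₂ / sqrt(n₁n₂)` under a
  rank-k truncated pseudo-inverse, with Wald p-values and Bonferroni
  assessment over blocks, optionally anchored on the LDSC heritability;
* **Putative causality** — summed local correlations over trait-specific
  risk regions with jackknife confidence intervals: if trait 1 causally
  influences trait 2, trait-1-specific regions correlate strongly with
  trait 2 while trait-2-specific regions do not.

A synthetic-data generator (LD blocks, two-trait architectures including
an oligogenic mode, GWAS summary statistics, sparse weight models) makes
the whole pipeline runnable and testable without any external dataset.

## Worked example

A desk-scale two-trait study: an oligogenic "disease" trait (signal in 24
LD blocks, h² = 0.5) and a polygenic "BMI-like" trait (h² = 0.25), genetic
correlation −0.2, both at N = 50,000 over M = 10,000 SNPs:

```r
library(crosstrait)

blocks <- simulate_ld_blocks(n_blocks = 200, block_size = 50,
                             rho = seq(0.1, 0.9, length.out = 8), seed = 42)
truth  <- simulate_effects(blocks, h2 = c(0.5, 0.25), rg = -0.2,
                           architecture = "oligogenic", seed = 43)
dd  <- simulate_sumstats(truth, blocks, n = 50000, trait = 1, seed = 44)
bmi <- simulate_sumstats(truth, blocks, n = 50000, trait = 2, seed = 45)

rg <- ldsc_rg(dd, bmi, ld_scores(blocks))
rg
#> Cross-trait genetic correlation (LD score regression)
#>   rg = -0.3195 (SE 0.1806), p = 0.0769
#>   h2_1 = 0.8814 (SE 0.4957); h2_2 = 0.3141 (SE 0.0497); M = 10000

scan <- local_scan(dd, bmi, blocks, anchor_h2 = c(rg$h2_1$h2, rg$h2_2$h2))
glance(scan)
#> # A tibble: 1 × 8
#>   h2_1_total h2_2_total gcov_total rg_total n_blocks n_significant threshold
#> 1      0.881      0.314    -0.0649   -0.123      200            14   0.00025

causality_contrast(scan, partition_blocks(dd, bmi, blocks))
#> Putative-causality contrast
#>   label           count estimate     se   ci_lo   ci_hi
#> 1 trait1_specific    19  -0.350  0.0358 -0.421  -0.280
#> 2 trait2_specific    32  -0.0136 0.0750 -0.161   0.133
#> 3 both                5  -0.454  0.0758 -0.602  -0.305
#> 4 neither           144   0.0188 0.0399 -0.0595  0.0971
#> verdict: consistent_T1_causes_T2
```

Reading the output: at this problem size a single replicate's `rg` is
noisy (−0.32 ± 0.18 around a truth of −0.2; the recovery tests average 100
replicates at M = 20,000). The oligogenic trait's heritability estimate is
wide — exactly why `local_scan` accepts the steadier LDSC estimate as an
anchor, after which the per-block heritabilities sum to it by
construction. In the contrast, the 19 trait-1-specific regions carry a
strong correlation with trait 2 (CI excludes 0) while the 32
trait-2-specific regions do not (CI includes 0): with the generator's
shared signal concentrated in trait 1's causal loci this is the expected
readout, and it illustrates the verdict logic rather than any discovery.

Every fitted object has `tidy()`/`glance()` methods and the scan/contrast
objects have `autoplot()` methods; `run_pipeline(pipeline_config(seed = 1),
"out/")` executes simulate → QC → clump → TWAS → rg → local-rg → causality
end to end and writes per-stage TSVs, a config echo and a run report. A
thin CLI over the same functions lives at
`inst/scripts/crosstrait.R` (subcommands `simulate`, `qc`, `clump`, `rg`,
`local-rg`, `causality`, `run-all`).

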