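---
title: "Methods: cross-trait genetic architecture from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-trait genetic architecture from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`crosstrait` studies the shared genetic basis of two complex traits using
nothing but GWAS summary statistics (per-SNP Z-scores with sample sizes),
an LD reference organised as approximately independent blocks, and
prepackaged cis-eQTL expression weight models. Four statistical components
sit on top of a synthetic-data generator:

1. a transcriptome-wide association scan (TWAS),
2. genome-wide SNP-heritability and cross-trait genetic correlation by LD
   score regression,
3. local SNP-heritability and local genetic correlation per LD block via
   truncated quadratic forms, and
4. a putative-causality contrast over trait-specific risk regions.

The generator is first-class, tested code: it defines the study conditions
under which every statistical claim in the test suite is evaluated.

# The generative model

Genotypes are standardized implicitly and allele frequencies are never
modelled; the LD correlation matrix $V$ of each block is the primitive,
because every downstream statistic consumes only $(z, n, V)$. Per block,

$$ z \;=\; \sqrt{n}\, V \beta \;+\; \varepsilon, \qquad
   \varepsilon \sim \mathcal{N}(0, V), $$

where $\beta$ holds per-SNP causal effects on the standardized scale. The
residual covariance is fixed at $V$ rather than $(1 - h^2_{\mathrm{local}})V$:
per-block heritabilities in realistic architectures are of order $10^{-3}$
or less, so the distinction is far below the resolution of any test here;
this is a documented simplification.

Effect pairs for two traits are drawn with per-SNP cross-trait covariance
$r_g \sqrt{h^2_1 h^2_2} / M_{\text{shared}}$, so the genome-wide genetic
correlation equals $r_g$ in expectation. Two architectures are supported:
*polygenic* (every SNP causal) and *oligogenic*, which confines the trait-1
causal SNPs to a configurable number of blocks — 24 by default, the number
of risk regions of a strongly oligogenic fibrotic disease of the palmar
fascia, the motivating use case. With `exact_scaling = TRUE` (default) each
trait's effect vector is rescaled so $\sum_j \beta_j^2 = h^2$ exactly.

Two LD models are provided. The AR(1) model $V_{ij} = \rho^{|i-j|}$ has a
closed form used by exact tests. The default simulation conditions recycle
$\rho$ over a grid from 0.1 to 0.9 across blocks: heterogeneous LD is what
gives LD scores their spread, and with a single $\rho$ the LD-score
regressor is nearly constant and the regression slope barely identified —
just as a real LDSC analysis would be uninformative if every locus had
identical LD. A `random_psd` model (random orthogonal mixing of positive
eigenvalues) serves as an unstructured stress test.

# TWAS

For a gene's weight vector $w$ over its cis SNPs, GWAS Z-scores $z$ and
reference LD $V$,

$$ Z_{\mathrm{TWAS}} = \frac{w' z}{\sqrt{w' V w}}, $$

with a two-tailed standard-normal p-value. The statistic is invariant to
positive rescaling of $w$ and flips sign under negation; models with
$w'Vw < 10^{-8}$ are rejected as degenerate rather than silently inflated.
A scan over $m$ tissue-specific models uses the Bonferroni threshold
$\alpha/m$ with a `<=` boundary convention everywhere.

**Permutation test.** The weight *values* are shuffled across the model's
SNP positions, holding the GWAS statistics and LD fixed, and the add-one
estimator $p = (1 + \#\{|z_{\mathrm{perm}}| \ge |z_{\mathrm{obs}}|\})/(B+1)$
keeps p in $(0, 1]$. The number of permutations is a configuration knob;
with one SNP every permutation is the identity and $p = 1$ by construction.

**Conditional GWAS.** With $r_j = (Vw)_j / \sqrt{w'Vw}$ the correlation
between SNP $j$ and the predicted expression, the conditioned score is
$(z_j - r_j Z_{\mathrm{TWAS}}) / \sqrt{1 - r_j^2}$, zeroed where
$r_j^2 \ge 1 - 10^{-10}$. Note the standardization can *amplify* a
conditioned score whose numerator shrank when $r_j$ is large; the honest
qualitative statement, which the tests assert, is that conditioning
residualizes signal-dominated loci toward zero at the model's
top-correlated SNP.

**Novelty.** A significant model marks a novel region at window $W$ when
the best GWAS p in the gene's cis region (TSS $\pm$ 0.5 Mb by default; the
same window used to report the best local GWAS SNP) is not genome-wide
significant, and the TSS is at least $W$ from every known risk region;
$W \in \{0.5, 1, 2\}$ Mb are reported.

# LD score regression

The LD score $\ell_j = \sum_k V_{jk}^2$ is summed within a SNP's block
(cross-block LD is zero by construction). Heritability comes from a
weighted regression of $z_j^2$ on $\ell_j$ with a free intercept:
$\hat h^2 = \text{slope} \cdot M / N$, with $N$ the median sample size and
$M$ the number of regression SNPs. Design choices:

* **Weights** are $1 / \max(\ell_j, 1)$ in a single step, not the original
  two-step iterated heteroskedasticity weighting. The acceptance standard
  here is parameter recovery under the generative model, not numeric
  equality with any particular implementation, and the single-step version
  recovers the truth well within the tolerance of the tests.
* **The intercept is always free**, absorbing confounding or sample
  overlap; there is no constrained-intercept mode.
* **Standard errors** are a delete-one-block jackknife over 200 contiguous
  SNP blocks (reduced with a warning when SNPs are scarce).

Cross-trait genetic correlation regresses $z_{1j} z_{2j}$ on $\ell_j$ over
the SNP intersection, converts the slope to a genetic covariance
$\text{slope} \cdot M / \sqrt{N_1 N_2}$, and normalizes by the geometric
mean of the two heritabilities. The jackknife resamples the *full ratio
statistic* so numerator and denominator noise are propagated together, and
the p-value is the two-tailed Wald test of $\hat r_g / \mathrm{se}$. A
trait paired with itself yields $r_g = 1$ exactly (the three regressions
coincide; the ratio is short-circuited rather than computed as
$x/\sqrt{x^2}$). Non-positive heritability estimates make the correlation
undefined and are reported as `NA` with a diagnostic instead of a complex
number or a crash.

# Local heritability and local correlation

Within one block, let $V^{+}$ be the rank-$k$ truncated pseudo-inverse of
$V$. With $q = z' V^{+} z$,

$$ \hat h^2_{\mathrm{local}} = \frac{q - k}{n - k}, \qquad
   \hat\rho = \frac{z_1' V^{+} z_2}{\sqrt{n_1 n_2}}, $$

and the null variance of $\hat\rho$ is
$(k + n_1 \hat h^{2+}_1 + n_2 \hat h^{2+}_2) / (n_1 n_2)$ with
$\hat h^{2+} = \max(\hat h^2, 0)$, giving a two-tailed Wald p per block.
Negative local heritabilities are *retained* in outputs (truncation happens
only inside the variance and the correlation normalization) so that sums
across blocks stay unbiased. The local correlation
$\hat\rho / \sqrt{\hat h^2_1 \hat h^2_2}$ is `NA` when either
heritability is non-positive.

**Eigen-truncation rule.** $k$ retains the top eigenvalues reaching 99.5%
of cumulative LD variance, capped at $\min(n_{\mathrm{snps}}, 50)$. The cap
bounds the per-block noise ($\mathrm{var}(q) \approx 2k$ under the null) at
the problem sizes this package targets; the 0.5% discarded variance biases
local heritability down by the same fraction, far inside every tolerance
used.

**Calibration regime.** The Wald variance above is the exact marginal
variance of $\hat\rho$ under zero local covariance *with real per-trait
signal* (the two mean-shift terms are genuine variance contributions from
the other trait's signal). Under a pure noise null the plug-in
$\hat h^{2+}$ terms are upward-biased by truncation of estimation noise
and make the test mildly conservative. The calibration suite therefore
evaluates type-I error in the regime the statistic is designed for: blocks
harboring a single-trait association of realistic locus strength (local
$h^2 = 5\times10^{-4}$ at $n = 10^5$, i.e. a genome heritability of 0.5
spread over 1,000 causal blocks per trait, disjoint between traits so every
cross-trait covariance is exactly null). Measured over 2,000 such blocks
the rejection rate at 0.05 and the Kolmogorov-Smirnov uniformity of p both
calibrate.

**Genome scans and anchoring.** Per-block estimates are summed into genome
totals; blocks containing no analyzed SNP are dropped and counted. Because
the quadratic-form estimator is noisy at modest GWAS sample sizes, the scan
can rescale local heritabilities so their total matches an external anchor
(typically the more stable LD-score-regression estimate); anchored totals
match the anchor to machine precision by construction. Per-block
significance uses $0.05 / n_{\mathrm{blocks}}$.

# Putative causality

Blocks are partitioned by GWAS significance ($p \le 5\times10^{-8}$) into
trait-1-specific, trait-2-specific, both, and neither. For a set $S$,

$$ \hat r_S = \frac{\sum_S \hat\rho}
   {\sqrt{\left(\sum_S \hat h^{2+}_1\right)\left(\sum_S \hat h^{2+}_2\right)}}, $$

with a delete-one-region jackknife and $\pm 1.96\,\mathrm{se}$ intervals.
If trait 1 causally drives trait 2, trait-1-specific regions carry a strong
correlation with trait 2 while trait-2-specific regions do not. The verdict
is `consistent_T1_causes_T2` when both trait-specific sets contain more
than 10 regions, the T1-specific interval excludes zero, the T2-specific
interval includes zero (the "near zero" narrative made operational, since
no numeric rule exists for it), and the two intervals do not overlap;
mirrored for the other direction; `not_tested` when either count is at or
below 10; otherwise `inconclusive`. The "both" and "neither" partitions are
reported but never affect the verdict. Swapping trait labels provably
mirrors the verdict because every ingredient is symmetric.

A caution on aggregation: the set-level correlation of a union of two
disjoint sets is *not* always between the two set estimates — with
non-proportional per-trait denominators Cauchy–Schwarz can push the union
below both. The tests assert the property only in the proportional regime
where the union is a weighted mean, and pin the counterexample as such.

# Study conditions of the statistical test suite

All simulation settings were fixed at design time from the considerations
above, and state what passing shows about real data:

| check | conditions |
|---|---|
| heritability recovery | $M = 20{,}000$ (200 blocks × 100 SNPs), $N = 50{,}000$, $h^2 = 0.5$, 100 replicates |
| rg recovery | same genome, $h^2 = 0.5/0.25$, $r_g = -0.2$ (the sign of the motivating disease–BMI pair), 100 replicates |
| local type-I | 2,000 single-trait-signal blocks as above |
| conservation | 100 blocks × 50 SNPs, $h^2 = 0.5$, 50 replicates |
| causality | 300 blocks × 25 SNPs, $n = 5\times10^4$; causal scenario: trait 1 oligogenic in 24 blocks ($h^2 = 0.1$), transmission $\beta_2 = 0.3\,\beta_1 + \gamma$ with $\gamma$ oligogenic in 24 disjoint blocks; pleiotropy scenario: identical shared effects in 200 blocks at fixed per-block strength $1.5\times10^{-3}$, chosen so block significance probability is mid-range and both trait-specific partitions exceed 10 regions |

The generator emulates block LD, two-trait architectures and sparse
cis-eQTL weights. It does **not** emulate allele-frequency spectra,
imputation quality, population structure, sample overlap between cohorts,
in-sample versus reference LD mismatch, or the X chromosome. Passing tests
demonstrate correctness of the estimators under their own assumptions, not
robustness to those real-data complications; in particular the local
covariance carries no sample-overlap correction and must only be applied to
non-overlapping cohorts (declared in configuration).

# Numerical choices and degenerate inputs

* Ties in clumping are broken by (p, chromosome, position, rsID) ascending,
  making region output invariant to input row order. The distance window
  defaults to 1 Mb. The published description of the clumping thresholds is
  ambiguous about direction; here 0.25 governs SNP-to-clump assignment and
  0.3 governs clump-to-region merging, and the implementation is validated
  against an exhaustive transcription of that greedy specification, not
  against any external tool.
* "Multi-allelic" is operationalized as an rsID occurring with more than
  one distinct allele pair, or any allele longer than one base; "has an
  rsID" as matching `rs` + digits. QC rule masks are evaluated against the
  input table and the union of violations is removed, each record counted
  under the first rule it matches — which makes a second application the
  identity.
* Empty inputs: QC of an empty table returns an empty table and a zeroed
  report; an empty clump input returns an empty region set; an interval
  with no SNPs reports $+\infty$ as its minimum p; empty causality
  partitions are reported with count 0 and `NA` estimates.
* Seeds are mandatory for every stochastic generator, flow from one root
  seed in the pipeline, and restore the RNG state on exit.

# Limitations

Beyond the generator's non-goals above: the LDSC implementation is the
single-step-weighted, free-intercept variant and does not implement
partitioned heritability; the local estimators assume the block partition
is given (synthetic genomes define their own blocks; real analyses consume
a block BED); and the causality contrast stops at "consistent with"
language — it is not Mendelian randomization and makes no pleiotropy-robust
causal claim.
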