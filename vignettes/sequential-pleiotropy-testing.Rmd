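---
title: "Methods: sequential Wald testing for pleiotropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequential Wald testing for pleiotropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Model

For each SNP, `pleioscan` fits the single-marker multi-trait regression

$$y_{j} = x\,\beta_j + \varepsilon_j, \qquad j = 1,\dots,p,$$

where $x$ is the mean-centered genotype (dosage of the A1 allele), $y_j$
the centered, covariate-adjusted phenotype for trait $j$, and the stacked
errors follow $\mathrm{MVN}(0, R \otimes I_n)$ with $R$ the $p \times p$
within-subject error covariance. With identical per-trait designs the
GLS/SUR estimator and its sampling covariance reduce, in the balanced case,
to

$$\hat\beta_j = \frac{x'y_j}{x'x}, \qquad
  \mathrm{cov}(\hat\beta) = \frac{R}{x'x}.$$

Key modelling assumptions: multivariate-normal errors (for quantitative
traits, transformation plus large-sample normality of linear-model
estimates make this mild), non-informative phenotype missingness, and
unrelated samples — the package performs no kinship correction, so related
samples should be pruned upstream.

### The error-covariance approximation

$R$ is unknown. Re-estimating it from per-SNP residuals doubles the work of
a scan, so `estimate_error_covariance()` instead computes, once, the
covariance $S$ of the adjusted phenotypes,

$$S_{jj'} = \frac{1}{n_{jj'} - 1} \sum_{i} y_{ij}\, y_{ij'},$$

summing over samples where both traits are observed. Because an individual
SNP explains only a small fraction of trait variance (a large effect is
~1–3%), $S$ is close to the residual covariance $\hat R$, and $S - \hat R$
is positive semi-definite (it equals the rank-one outer-product contribution
of the fitted SNP effect), so substituting $S$ for $R$ can only make
inference slightly conservative — and only in the regime where power is
essentially 1 anyway. The test suite verifies both the PSD property and the
calibration consequences by simulation.

Under missingness the paper-level definition of $S$ is open; we use
pairwise-complete products (maximizing data use and preserving the
compute-once property) and repair non-positive-definite results by clipping
eigenvalues at $10^{-8}$ of the largest. Covariate adjustment is likewise
per trait over each trait's own observed rows.

## Sequential intersection-union testing

Stage $s$ tests "the SNP affects at least $s$ traits" against the composite
null that at most $s-1$ effects are non-zero. Each way of zeroing a subset
$K$ of $p - s + 1$ effects is one component null with Wald statistic

$$w_K = \hat\beta_K' \left[\mathrm{cov}(\hat\beta)_{KK}\right]^{-1}
  \hat\beta_K \;\sim\; \chi^2_{p-s+1} \text{ under that null},$$

and the intersection-union p-value is the upper tail at
$\min_K w_K$. Stage 1 is the global test $\beta = 0$ (df $= p$); stage 2's
component nulls correspond to deleting one row of the identity contrast;
stage $s$ generalizes this to all $\binom{p}{s-1}$ subsets, which is why
the implementation caps $p \le 15$. For $p = 2$, the stage-2 p-value equals
the maximum of the two marginal Wald p-values exactly — a closed form the
tests exploit.

Reported p-values are raw per-stage IU p-values; *declared pleiotropy order*
at level $\alpha$ requires all of stages $1..s$ below $\alpha$ (gating).
Whether to monotonize p-values across stages was an open design point; we
report raw values because gating already enforces the sequential logic and
raw values remain interpretable per stage. An `early_stop_p` threshold
(e.g. 0.01) skips later stages once a stage fails it; skipped stages are
reported as absent rather than 1, so downstream code can distinguish
"not significant" from "not computed". p-values are floored at $10^{-300}$
before $-\log_{10}$ reporting.

## Unbalanced data

Samples are grouped by missing-value pattern (`find_missing_patterns()`).
Writing $E_g$ for the selection matrix of the traits observed in group $g$
and $S_g = S[{\rm mask}_g, {\rm mask}_g]$, the grouped normal equations are

$$A = \sum_g (x'x)_g \, E_g' S_g^{-1} E_g, \qquad
  b = \sum_g E_g' S_g^{-1} (x'Y)_g, \qquad
  \hat\beta = A^{-1} b,\; \mathrm{cov}(\hat\beta) = A^{-1}.$$

This is the unique GLS solution under a block-diagonal error covariance
with per-pattern blocks $S_g$; the test suite checks it against a
brute-force observation-level GLS that assembles the full
$\Omega^{-1}$-weighted system, on hundreds of random unbalanced instances,
to relative error below $10^{-9}$. The estimator is a
precision-weighted combination of unbiased group-specific estimators and is
therefore unbiased under non-informative missingness (verified by
simulation with the true covariance supplied).

Two deliberate choices where the original behavior is unstated:

* **Genotype centering is global** (over all analyzed samples), not
  per group — one consistent $x$ per SNP.
* **Missing genotypes are mean-imputed** before centering (imputed entries
  become exactly 0, contributing nothing to $x'x$ or $x'y$) rather than
  spawning extra patterns; with the 95% call-rate filter this touches at
  most 5% of entries per SNP.

Groups smaller than `min_group_size` can be dropped (off by default;
values like 50 are useful when completely-random missingness fragments the
data), trading a little information for bounded cost.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `maf_min` | 0.001 | minimum minor-allele frequency (inclusive) |
| `call_rate_min` | 0.95 | minimum per-variant call rate (inclusive) |
| `min_group_size` | 1 | smallest missing-pattern group retained |
| `early_stop_p` | 1 | stage p-value above which later stages are skipped |
| `alpha` (regions) | 1e-8 | genome-wide significance, strict inequality |
| `gap_bp` | 1e6 | merge distance for region grouping (bp) |
| `transforms` | identity | per-trait `log` option for skewed traits |

Boundary conventions: filters are inclusive at the printed thresholds;
significance is strict (`p < alpha`); region merging is strict
(`distance < gap_bp`), so two regions may be separated by exactly `gap_bp`.
`.bim` positions are treated as 1-based and regions are closed intervals.

## The synthetic-data generator

`simulate_dataset()`/`write_fixture()` emulate the validation study's
conditions: allele frequency $f \sim \mathrm{Uniform}(0.01, 0.5)$ (the
empirical biobank MAF distribution is not available, so a pluggable uniform
law stands in), dosages $\mathrm{Binomial}(2, f)$, and errors MVN with unit
total phenotypic variance per trait: the error variance is $1 - h^2_j$ and
homogeneous correlation $\rho$ applies to the error scale, so
$\beta_1 = \sqrt{h^2_1 / (2f(1-f))}$ makes "percent variance explained"
exact. Other affected traits get $\beta_j = \text{effect\_ratio}\cdot
\beta_1$. Missing-value patterns are injected by sampling a pattern per
sample from a user-given distribution.

What the generator does *not* emulate: linkage disequilibrium between
variants (fixture SNPs are independent, so region grouping on fixtures
exercises the distance logic, not LD structure), relatedness, informative
missingness, non-normal traits, and population stratification. Passing
tests therefore demonstrate correctness of the estimator, test calibration
and plumbing under the stated model — not robustness to those real-data
features.

## The Monte Carlo engine

The calibration studies need $5\times10^5$–$10^6$ replicates. The compiled
batch engine samples the *sufficient statistics* of the test directly from
their exact joint distribution instead of materializing $n \times p$ data
per replicate. With $u = x_c / \lVert x_c \rVert$ and centered errors
$E_c$:

* genotype class counts $(n_0, n_1, n_2)$ are multinomial, which fixes
  $x'x$ exactly;
* $z = u'E_c \sim \mathrm{MVN}(0, \Sigma)$, independent of
  $M = E_c'E_c - zz' \sim \mathrm{Wishart}(\Sigma, n-2)$ (Bartlett
  decomposition);
* $(n-1)S = x'x\,\beta\beta' + \sqrt{x'x}(\beta z' + z\beta') + zz' + M$
  and $\hat\beta = \beta + z/\sqrt{x'x}$.

This identity is verified on raw data to $10^{-10}$ in the test suite, and
the batch and full-pipeline engines are compared on rejection rates. All
draws use R's RNG, so studies are reproducible under `set.seed()`. The
replicate cost is independent of $n$, which is what makes million-replicate
calibration runs take seconds. The full raw-data engine (`engine = "full"`)
remains the reference path and is required for settings with missing-value
patterns.

Study sizes used in the shipped tests and acceptance script: $5\times10^5$
replicates for the $\alpha = 0.01$ type-I rates, $10^6$ for
$\alpha = 10^{-3}$, $10^5$ for the conservativeness bound, and $10^4$ per
cell for power comparisons; at these sizes the Monte Carlo standard error
is a few percent of each reported quantity. The power study's rejection
rule (which stage, which $\alpha$) is configurable because the original
definition is not fixed; the defaults are stage 2 at $\alpha = 0.05$.

## Numerical choices

* Linear solves use symmetric-PD Cholesky factorizations; explicit inverses
  appear only in the returned $p \times p$ covariance.
* A singular normal-equations matrix (e.g. a trait observed in no retained
  group) raises a classed condition; `run_scan()` records the SNP in the
  skip log and continues.
* Monomorphic or all-missing SNPs are skipped with a logged reason;
  the batch engine redraws the (probability $\approx 0$) monomorphic
  replicate.
* Ties in the minimum Wald statistic do not affect the p-value; the
  reported driving null is the first argmin in enumeration order.
* Dosage counts the A1 allele; flipping alleles negates $\hat\beta$ and
  leaves every p-value unchanged (sign symmetry of quadratic forms).

## Limitations

* No mixed-model or kinship adjustment; intended for (distantly) unrelated
  samples.
* Apparent pleiotropy can arise from LD between distinct causal variants
  affecting different traits; the test cannot distinguish this from true
  pleiotropy.
* The sequential test covers quantitative traits under the linear model;
  generalized-linear outcomes would need adjusted residuals upstream.
* Summary-statistic input (no individual-level data) is out of scope.
* $S$ under missingness is pairwise-complete by design choice; with highly
  structured missingness and strong effects this could differ from the
  (unstated) original behavior.
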