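---
title: "Hierarchical growth-trajectory GWAS: models and methods"
author: "hirrm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical growth-trajectory GWAS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hirrm)
```

## The two-hierarchy model

Longitudinal traits such as body weight are measured repeatedly across age.
Rather than mapping each age separately or carrying all time points through
a multivariate mixed model, `hirrm` stratifies the analysis into two
hierarchies.

**First hierarchy — individual trajectories.** Each individual's
measurements $y_i(t)$ are summarized by a biologically meaningful growth
curve. The flexible four-parameter family is

$$y(t) = a\,(1 + b e^{-rt})^{1/(1-k)},$$

with $a$ the mature (asymptotic) size, $b$ an integration constant tied to
the initial condition, $r$ the intrinsic growth rate and $k$ a shape
parameter moving the inflection point. Fixing $k$ recovers the familiar
three-parameter curves: $k=0$ the Bertalanffy form (implemented as
$a(1-b e^{-rt})$ with $b>0$ for growth, so the $k=0$ member equals it with
the sign of $b$ flipped), $k \to 1$ the Gompertz curve
$a\exp(-b e^{-rt})$ (implemented as its own family because the exponent is
undefined at $k=1$), and $k=2$ the logistic curve. A normalized Legendre
polynomial basis (orthonormal on $[-1,1]$ after an affine map of the age
range, the random-regression convention) is available as a linear
alternative.

Fitting is non-linear least squares (Levenberg–Marquardt) for the
biological families and ordinary least squares for the Legendre family.
Because the curve is linear in $(a, ab)$ once $r$ is fixed, the fitter
profiles $r$ over a coarse grid with exact linear solves to locate the
global basin, then polishes with a small multi-start; for the
four-parameter family both sides of the $k=1$ singularity are attempted
(with an exclusion band $|k-1| > 10^{-4}$) and the domain constraint
$1 + b e^{-rt} > 0$ is enforced on the data grid. Non-convergence is
reported as `converged = FALSE` with the best parameters found, never
silently. Each fit reports $RSS/(n-d)$ as the residual variance, $R^2$,
and Gaussian AIC/BIC with $d+1$ parameters (the residual variance counts);
model selection ranks by BIC, breaking ties toward fewer parameters.

**Second hierarchy — the fitted coefficients as traits.** The $d$ fitted
coefficients $p_i$ of individual $i$ are treated as correlated quantitative
traits in a genomic multivariate linear mixed model,

$$P = XB + Z\alpha + G + E, \qquad
  G \sim MN(0, V_g, K), \quad E \sim MN(0, V_{pe}, I_n),$$

with $K$ the genomic relationship matrix, $V_g$ the genetic covariance of
the regressions and $V_{pe}$ the permanent-environmental covariance (the
non-genetic individual effect persisting across the repeated measurements).
The fixed effects are per-trait intercepts plus optional covariates.

## Null REML and the measurement correction

Under the no-QTL null, $(V_g, V_{pe})$ are estimated by REML. After
rotating by the eigenvectors of $K = U_k S_k U_k^T$ the rows become
independent with covariance $s_{k,i} V_g + V_{pe}$, and for any candidate
pair the two matrices are simultaneously diagonalized, reducing each
likelihood evaluation to $d$ univariate weighted regressions — evaluation
is $O(nd)$ after one $d \times d$ eigendecomposition. The maximizer is
found by quasi-Newton iteration on an unconstrained log-Cholesky
parameterization (positive semi-definiteness holds by construction),
warm-started with a few EM sweeps. Convergence requires a relative
log-likelihood change below $10^{-8}$ and a small gradient; the gradient is
measured by central differences, so its max-norm is compared against
$10^{-5}$ *relative to the criterion magnitude* — an absolute $10^{-5}$ is
below the resolution of numerical differentiation at cohort-scale
likelihood values. Standard deviations of all components come from the
central-difference observed information (relative step $10^{-4}$), and
Wald tests compare each component with its standard deviation (one-sided
for variances, two-sided for covariances).

The first hierarchy is itself an estimation step: the fitted coefficients
carry sampling error with known covariance
$\hat\sigma^2 (J^T J)^{-1}$ per individual ($J$ the Jacobian of the curve
at the estimate), which the second-hierarchy model represents as an extra
independent residual on the regressions. Since this component is *known*,
`estimate_null_mvlmm(meas_cov = ...)` fits the total independent
covariance and reports $V_{pe}$ with the mean measurement covariance
subtracted (floored to positive semi-definite); the uncorrected total is
retained as `Vpe_total`. Association scans whiten against the total — the
measurement noise is genuinely part of the marker-test residual — while
variance-component inference about the biology uses the corrected
$V_{pe}$. Individuals whose trajectories leave a coefficient essentially
unidentified (sampling-covariance trace far above the cohort median; 10x
by default) are treated as failing fits and dropped, as are unconverged
fits.

## Canonical transformation and the marker tests

With $V_{pe} = U_{pe} S_{pe} U_{pe}^T$ and
$A = S_{pe}^{-1/2} U_{pe}^T$, eigen-decomposing
$A V_g A^T = U_\lambda S_\lambda U_\lambda^T$ yields $L = U_\lambda^T A$
with $L V_{pe} L^T = I$ and $L V_g L^T = S_\lambda$. The transformed
phenotypes $P^* = P L^T$ split the multivariate model into $d$ independent
univariate models; pseudo-trait $l$ has covariance
$s_{\lambda l} K + I_n$. Canonical values are ordered descending and each
row of $L$ is sign-fixed (largest-magnitude entry positive) so output is
reproducible.

Each pseudo-trait is whitened once by
$V^{-1/2} = (s_{\lambda l} S_k + I)^{-1/2} U_k^T$, fixing the variance
ratio at its null estimate (the EMMAX approximation). Markers are centered
at twice their allele frequency (mean-imputed first, effects stay
per-allele) and, like the phenotype, residualized on the whitened fixed
effects; the per-trait statistic is then ordinary least squares with unit
residual variance, $\chi^2_l = \hat a_l^{*2} (z'^T z')$. The pleiotropy
statistic sums the $d$ per-trait chi-squares and is referred to the
chi-square distribution with $d$ degrees of freedom; $-\log_{10} p$ is
computed on the log scale and capped at 320. Effects and standard errors
are mapped back to the curve-parameter scale through $(L^T)^{-1}$.
Genome-wide significance uses the Bonferroni bound $-\log_{10}(\alpha/m)$,
and calibration is monitored by the genomic-control value
$\mathrm{median}(\chi^2)/\mathrm{median}(\chi^2_d)$.

Fixing the variance ratios can cost power at strong QTLs, so an optional
second round re-estimates the per-trait ratio by univariate REML with the
candidate marker as a fixed covariate (started from the genomic value) and
re-tests it exactly, with the residual variance re-estimated. Markers are
flagged for refinement when their first-pass $p$ falls below $10^{-4}$ or
they are in the top 0.1% (both configurable); at most one refinement pass
is run, i.e. two rounds in total. Identical marker columns share a cached
refinement result.

## The synthetic-data generator

The generator emulates the data-generating design the method targets: a SNP panel
with local LD, QTLs placed at random, correlated regression deviations,
and 16-point trajectories with Gaussian measurement error.

* **Genotypes.** Haplotypes follow a first-order Markov copying model:
  within blocks of 20 markers each allele copies its left neighbour with
  probability 0.8, otherwise it is drawn fresh at the marker's allele
  frequency (Uniform(0.05, 0.5)); blocks and chromosomes are independent.
  This reproduces monotonically decaying local LD without shipping a real
  panel.
* **Deviations.** All pairwise correlations among genetic and among
  permanent-environmental regressions are 0.5, permanent-environmental
  regression variances are 4.0, regression heritability is 0.5, and the
  trajectory measurement-error variance is 4.0, at 16 time points —
  the design's default conditions. 500 QTLs jointly carry
  30% of the genetic variance by default, with effects drawn multivariate
  normal at the same 0.5 correlation and rescaled to the target fraction;
  the remaining genetic variance is polygenic, drawn matrix-normal against
  the realized genomic relationship matrix.
* **Deviation basis.** By default the deviations enter the trajectory
  through an order-2 normalized Legendre basis (`deviation_basis =
  "legendre"`), the random-regression convention under which coefficient
  variances are on the phenotype scale — a variance of 4.0 is then
  commensurate with the error variance of 4.0 and the trajectories stay
  biologically plausible. The alternative `"curve"` basis perturbs the
  growth-curve parameters themselves; because the raw parameters differ by
  orders of magnitude (an asymptote near 21 against a rate near 0.23), a
  common variance is only meaningful in trajectory-normalized units (one
  unit = one phenotype-unit RMS perturbation of the curve), and deviations
  that would push a curve out of its domain or beyond ten times the
  population curve's magnitude are halved until valid. The curve basis is
  the right choice when the fitted family must match the generative family
  (e.g. studying the residual-variance estimator of the four-parameter
  fits); the Legendre basis is the default for covariance-recovery and
  calibration studies.
* **What the generator does not emulate:** genotyping error and missing
  calls, population structure beyond what the copying model induces,
  selection, age-dependent (heteroscedastic) measurement error, and
  non-Gaussian trait distributions. Passing recovery and calibration tests
  on these simulations therefore demonstrates correctness of the machinery
  under the stated generative conditions, not robustness to every feature
  of real data.

QTL calling follows the neighbourhood rule: a marker is a QTL if it
exceeds the significance threshold and carries the largest summed
statistic among its 20 closest positional neighbours (10 each side,
truncated at chromosome ends; ties go to the leftmost marker). Power is
the fraction of simulated QTLs whose window contains a called marker; the
type-I error is the fraction of markers outside all QTL windows that are
called.

## Numerical choices and degenerate inputs

* GRM: standardized (VanRaden) $K = WW^T/m$ after per-marker mean
  imputation; eigenvalues are floored at zero, and a ridge can be added
  when the null REML struggles. Monomorphic markers are an error — filter
  first (defaults MAF $\ge$ 0.01, missingness $\le$ 0.1).
* A kinship eigenvalue spread below 0.05 triggers a warning: $V_g$ and
  $V_{pe}$ are then nearly confounded.
* Near-singular $V_{pe}$ in the canonical step is repaired by a ridge of
  $10^{-8}$ times its mean diagonal with a warning, refused only if the
  condition number still exceeds $10^{12}$ (a zero matrix is refused
  outright, naming the offending eigenvalue).
* Markers monomorphic after whitening score $\chi^2 = 0$ with a
  degenerate flag rather than dividing by zero.
* Information criteria remain finite on interpolating fits by flooring
  RSS at the smallest positive double.

## Problem sizes used in the shipped simulation studies

The recovery and calibration studies run at n = 500 individuals,
m = 2,000 markers, d = 3 regression coefficients and 16 time points, with
20 replicates in the acceptance script and 10 in the test suite; the
residual-variance study fits 500 four-parameter trajectories per cohort;
the power grid uses n = 200, m = 250 with 20 paired replicates per effect
size. These sizes were chosen so that Monte-Carlo standard errors are
small against the tolerance bands while a full run stays in the minutes
range on a single core.

## Known limitations

* Individuals with too few records for their family are dropped rather
  than predicted from the cohort distribution; shrinkage prediction of
  sparse individuals is out of scope.
* The measurement correction is homoscedastic (mean covariance): with
  strongly heterogeneous per-individual identifiability the corrected
  $V_{pe}$ is a plug-in approximation, which is why clearly unidentifiable
  fits are dropped instead of corrected.
* The EMMAX approximation is exact only under the null components;
  refinement mitigates, but does not eliminate, its conservatism at very
  large QTL effects.
* Genomic control with few, strong QTLs concentrated on a small panel can
  dip below one at non-QTL markers because the polygenic term absorbs QTL
  variance; with the default QTL count spread over the panel the value
  stays near one.
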