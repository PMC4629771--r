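---
title: "Twin variance-component models in twinkin: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin variance-component models in twinkin: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinkin)
```

## The classical twin model

The observation unit throughout the package is the twin pair. Monozygotic
(MZ) pairs share all segregating genes and dizygotic (DZ) pairs on
average half; both are assumed to share trait-relevant rearing
environment to the same degree (the equal-environments assumption).
Decomposing a phenotype P into additive genetic (A), non-additive genetic
(D), shared environmental (C) and non-shared environmental (E) latent
sources, with variances summing to the phenotypic variance, the expected
cross-twin covariances are

$$\mathrm{Cov}_{MZ} = \sigma^2_A + \sigma^2_D + \sigma^2_C, \qquad
  \mathrm{Cov}_{DZ} = \tfrac12\,\sigma^2_A + \tfrac14\,\sigma^2_D +
  \sigma^2_C ,$$

implemented in `expected_pair_covariance()`. C and D are not jointly
identified from twins reared together, so model families never contain
both: the saturated family is ACE when the MZ correlation is at most
twice the DZ correlation, ADE when it exceeds it
(`select_saturated()`; an exact tie goes to ACE, the more conservative
choice for familial aggregation). Narrow-sense heritability is the
standardized A share; broad-sense adds D.

Binary traits use the liability-threshold model: a standard-normal latent
liability with a single threshold \(t = \Phi^{-1}(1-K)\) for population
prevalence \(K\). Twin similarity is then summarized either by the
probandwise concordance \(2C/(2C+D)\) over concordant-affected (C) and
discordant (D) pair counts — the probability that a co-twin of an
affected index twin is affected — or by the tetrachoric correlation of
the latent liabilities.

## Likelihoods

**Continuous traits.** `fit_continuous()` maximizes the per-pair
bivariate-normal log-likelihood with a common mean and the
zygosity-specific expected covariance. Parameters are unconstrained path
loadings whose squares are the variance components, so nonnegativity
requires no constrained optimization; the sign of a loading is not
identified and magnitudes are reported. Pairs in which exactly one twin
is measured contribute their univariate marginal density
(full-information maximum likelihood). The likelihood depends on the data
only through per-zygosity sufficient statistics that are symmetrized over
twin order, which makes twin-relabeling invariance exact rather than
approximate.

**Binary traits.** `fit_binary()` maximizes the multinomial likelihood of
the concordance-cell counts; cell probabilities are orthant probabilities
of a standard bivariate normal whose correlation is the model-implied
liability correlation \(r_z a^2 + q_z d^2 + c^2\). One threshold is
shared by both twins (exchangeability) and across zygosity groups; the
total liability variance is fixed at 1, so the standardized shares are
the parameters. The alternative of zygosity-specific thresholds is not
offered: it absorbs prevalence differences that the classical design
assumes away, and stratified questions are better answered by splitting
the cohort.

**Bivariate Cholesky.** `fit_bivariate()` parameterizes each component's
two-trait covariance block as \(\Lambda \Lambda'\) with lower-triangular
\(\Lambda\), guaranteeing positive semidefiniteness. Derived quantities
are the factor-level correlations (e.g. \(r_G = (\Lambda_A
\Lambda_A')_{12} / \sqrt{(\Lambda_A \Lambda_A')_{11} (\Lambda_A
\Lambda_A')_{22}}\)), the phenotypic correlation, and the share of the
phenotypic covariance carried by each source
(`phenotypic_decomposition()`). Three likelihood routes cover the trait
kinds:

* continuous–continuous: 4-variate normal on symmetrized sufficient
  statistics;
* binary–binary: multinomial over the 16 joint outcome cells per
  zygosity, so the cost is independent of the number of pairs;
* mixed: the continuous margins enter as a bivariate-normal density and
  the binary orthants are evaluated on the conditional bivariate normal
  given the continuous values, avoiding 4-dimensional integration per
  pair. Internally the continuous trait is conditioned on first; all
  derived correlations are order-invariant (tested).

Unit liability variances for binary traits are enforced by construction:
the non-shared loading of a constrained row is fixed to 1 before the row
is rescaled to unit total variance, a smooth surjective parameterization
that needs no explicit constraints. Families ACE, ADE and AE are
supported; AE matters in practice because published bivariate liability
analyses that report only genetic and non-shared environmental
correlations correspond to an AE structure, and freeing near-zero C paths
mainly adds variance to \(\hat r_G\).

**Direction of causation.** `fit_direction_of_causation()` compares the
model in which X causes Y (cross-twin cross-trait covariance constrained
to \(\beta\) times X's own cross-twin covariance pattern) with the
reverse, each with trait-specific A and E residuals only — richer
residual structure destroys the identification that makes the comparison
meaningful. Both causal models are restrictions of the AE Cholesky, so
their log-likelihoods can never exceed it (tested). The AIC difference
decides; below a margin (default 2, the conventional
indistinguishability band for AIC) the result is "indistinguishable".
The comparison is implemented for continuous trait pairs; it is only
informative when the two traits have clearly different variance
structures, and a warning is issued when the fitted structures are
near-identical.

## Numerical kernels

All liability computations route through two deterministic kernels,
validated in the test suite against `mvtnorm::pmvnorm` and a
double-integration oracle built on `stats::integrate`:

* `pbvn()`, a vectorized bivariate-normal CDF using Gauss–Legendre
  quadrature on the arcsine-transformed correlation (machine precision at
  48 nodes, stable as \(|\rho| \to 1\)). Vectorization matters because
  the mixed likelihood evaluates one rectangle probability per pair per
  optimizer step.
* 4-variate rectangle probabilities assembled by inclusion–exclusion over
  *upper-orthant* terms: dimensions one and two are exact
  (`pnorm`/`pbvn`), dimensions three and four use sequential-conditioning
  quadrature over the sharpest tails. Integrating only small, sharp tail
  regions keeps the absolute error near 1e-8 — integrating large cells
  directly converges much more slowly — and the 16 cell probabilities sum
  to 1 exactly by construction.

Optimization is multi-start quasi-Newton (BFGS, relative tolerance
1e-12): five seeded starts for univariate fits, three for bivariate fits,
the first from Falconer-style moment estimates
(\(a^2 \approx 2(r_{MZ}-r_{DZ})\), \(c^2 \approx 2r_{DZ}-r_{MZ}\)) and
the rest jittered. A fit is flagged `converged` only when the best
log-likelihood is reproduced within 1e-6 (1e-4 for bivariate fits) by a
second start. Tetrachoric correlations are optimized on the Fisher-z
scale so the estimate stays inside (−1, 1), with \(|\rho| > 0.999\)
flagged as a boundary solution; degenerate margins (no affected, or all
affected) are refused with an error that names the implied boundary
value.

Confidence intervals: univariate standardized shares carry
profile-likelihood intervals at the \(\chi^2_1\) 0.95 cutoff, found by
root-finding on the profile deviance with the remaining shares
re-optimized at each candidate value and clipped at the [0, 1]
boundaries. Descriptive statistics use a seeded percentile bootstrap over
pairs (default 1,000 replicates) rather than delta-method variances,
which are fragile near boundaries. Likelihood-ratio tests that drop a
variance component sit on the boundary of the parameter space; the
package reports the standard \(\chi^2\) p-value and labels it
conservative rather than applying the 50:50 mixture correction, keeping
the degrees-of-freedom bookkeeping transparent (the test suite confirms
the empirical type-I rate stays at or below nominal).

## The synthetic-cohort generator

`simulate_continuous()`, `simulate_binary()` and `simulate_bivariate()`
draw latent factors with the exact cross-twin correlations of the
classical model: additive factors correlate 1 (MZ) / 0.5 (DZ), dominance
factors 1 / 0.25, shared environment 1 / 1, non-shared environment 0.
The DZ correlations are realized as
\(\sqrt{r}\,Z_{\text{common}} + \sqrt{1-r}\,Z_{\text{unique}}\), which
hits the target correlation exactly without multivariate sampling
machinery. Thresholds for binary traits are deterministic quantiles of
the generating prevalence, never refit per replicate, so generative truth
stays separate from estimation. One master seed drives everything;
stage-specific sub-streams are derived deterministically *through the
generator itself* (`set.seed` plus `sample.int`), because arithmetic maps
of the form \(a\cdot\text{seed}+b\cdot k\) produce structured seed
sequences whose Mersenne–Twister streams are visibly correlated.

`apply_misclassification()` flips each observed binary value
independently with the complement of sensitivity (for true positives) or
specificity (for true negatives); the defaults in the recovery
experiments, 0.88 and 0.89, are the reported operating characteristics of
the Danish asthma screening question against clinical examination.
`ascertain_probands()` keeps pairs with at least one affected member.
Probandwise concordance is by construction unchanged by this selection,
but naive variance-component fits on ascertained cohorts are biased; the
package deliberately provides no ascertainment-corrected likelihood
(published analyses do not specify the correction used) and instead lets
the generator quantify the bias empirically.

What the generator emulates: zygosity-specific latent correlation
structure, liability thresholds, questionnaire noise, proband
ascertainment, causal and confounded exposure–outcome wiring
(`simulate_cotwin()`). What it does not: age and sex moderation of the
variance components, opposite-sex-specific DZ structure, chorionicity,
assortative mating, violations of the equal-environments assumption, and
longitudinal dependence. Passing recovery tests therefore demonstrates
correctness of the estimators under the classical model's assumptions,
not robustness of the twin design itself to their violation.

## The recovery-experiment catalogue

Each catalogued experiment (`list_experiments()`) simulates cohorts whose
generating parameters are published twin-study estimates and checks that
the package recovers them: the 1994 adolescent asthma scenario
(a² = 0.79, c² = 0.11, prevalence 7.1%; 50,000 pairs per zygosity), an
IgE-like continuous trait (a² = 0.81; 5,000 pairs per zygosity), an
FEV₁/FVC-like continuous pair (heritabilities 0.68/0.58, genetic
correlation 0.90), a rare/common binary pair with a negative genetic and
positive non-shared environmental correlation (−0.30 and 0.52,
prevalences 0.5% and 9.9%, per-trait heritabilities 0.85/0.75 with an AE
generating structure, as implied by a report of genetic and non-shared
correlations only), a pleiotropy scenario in which the additive-genetic
cross-covariance constitutes 81% of a phenotypic correlation of 0.50, and
a low-heritability/high-shared-environment binary scenario
(a² = 0.14, c² = 0.60, prevalence 3%). Where the source material does not
state a nuisance value, it was fixed once from typical values in the twin
literature — the per-trait heritabilities just mentioned, a non-shared
environmental correlation of 0.30 for the lung-function pair — and not
revisited.

Tolerances are pre-registered as roughly three Monte-Carlo standard
errors of the reported estimate. At several of the catalogued sample
sizes a single simulated cohort is noisier than a third of the tolerance
(for example, the Fisher-information standard error of the estimated
heritability in the 1994 scenario is about 2.2 percentage points at
50,000 pairs per zygosity, and about 3.2 points in the low-heritability
scenario, where the small MZ–DZ contrast carries little information);
those experiments therefore report the mean of the smallest number of
independent replicates that brings three standard errors inside the
tolerance (11, 10, 6 and 3 replicates for the scenarios concerned, 1
elsewhere). Replicate counts were derived from the Fisher/pilot standard
errors, not from observed pass/fail at any seed. The whole catalogue runs
in a few minutes on one CPU; `scripts/acceptance.R` re-executes it for an
arbitrary seed.

## Data-model conventions

Cohorts are wide data frames, one row per pair, because the pair is the
sampling unit and every likelihood factorizes over pairs. Binary traits
are stored as 0/1 integers, missing values as empty CSV fields. Zygosity
carries only MZ/DZ — the published models pool same- and opposite-sex DZ
pairs — and per-twin sex is retained for stratified analyses only
(stratification is done by splitting the cohort, not by moderation
parameters). Twin order within a pair is arbitrary, and every statistic
in the package is tested for exact invariance under relabeling; the
descriptive correlations achieve this by double entry (each pair
contributes both orderings), which matches the cross-twin covariance
definition used by the likelihoods, rather than by an ANOVA-style
intraclass estimator.

## Known limitations

* Bivariate fits report no confidence intervals; profile intervals for
  the factor correlations would require many constrained refits of a
  9–11-parameter model and published significance markers could not be
  reproduced without knowing how they were computed.
* Bivariate fits use pairs complete on both traits; full-information
  handling of partially missing pairs is univariate-only.
* The direction-of-causation comparison is continuous-only and, like all
  such models, uninformative when the two traits have similar variance
  structures.
* Matched odds ratios are unadjusted; covariate-adjusted conditional
  models are out of scope.
* Fits on proband-ascertained cohorts are biased and are not corrected;
  the generator exists to measure that bias.
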