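---
title: "Two-sample Mendelian randomization of chronic hepatitis B on stroke: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization of chronic hepatitis B on stroke: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chbstroke)
```

## The question and the design

Chronic hepatitis B (CHB) and stroke are both heavily concentrated in
East Asia, and observational studies disagree on whether CHB raises or
lowers stroke risk. Two-sample Mendelian randomization (MR) addresses the
question with genetics: variants robustly associated with CHB
susceptibility serve as instrumental variables, and their effects on
stroke — read off an independent stroke GWAS — identify the causal effect
of CHB liability on stroke risk, provided three assumptions hold:

1. the variants are associated with the exposure (relevance);
2. they are independent of confounders of the exposure–outcome relation;
3. they affect the outcome only through the exposure (exclusion
   restriction; violations are *horizontal pleiotropy*).

The package implements the full analysis as reusable, tested functions:
summary-statistics I/O, allele harmonization, instrument screening and LD
clumping, five causal estimators, heterogeneity/pleiotropy diagnostics,
Bonferroni control, and a synthetic-data generator with known ground
truth so that every stage can be validated at desk scale. The exposure
side ships with the package: the 12 genome-wide-significant CHB variants
of a Chinese case-control GWAS (9114 cases, 9257 controls, N = 18,371),
eleven of which sit in the HLA region on chromosome 6.

## Harmonization

Outcome effects are aligned per variant to the exposure's effect allele.
Swapped allele labels negate the outcome effect and complement its
frequency; strand-complement matches (A↔T, C↔G per base) are resolved
before the same swap logic; standard errors are never touched. Every
input variant receives exactly one audit tag (`kept`, `flipped`,
`complemented`, `dropped_missing`, `dropped_palindromic`,
`dropped_mismatch`), so the accounting identity — aligned plus dropped
equals input — is testable and the pipeline's choices are inspectable
after the fact.

Palindromic variants (A/T, C/G) are strand-ambiguous from labels alone.
The default policy infers orientation by comparing both allele
frequencies to 0.5 and drops the variant when either frequency lies
within 0.08 of 0.5 (`eaf_ambiguity_band`), the common practice in
two-sample MR software; `drop` and `keep` are available. None of the 12
packaged instruments is palindromic, so the default cannot affect the
reproduction of the shipped study; the band matters only for user data.

Variants absent from the outcome are dropped with an audit record and
never proxied: the analysis this package reproduces did exactly that
with rs2853953, leaving 11 usable variants, and LD-proxy lookup would
require external reference data the package deliberately does not touch.

## Instrument screening and clumping

Instrument strength is screened with
\(F = R^2 (N-2) / (1 - R^2)\), flagging \(F \le 10\) as weak. Two
\(R^2\) approximations are exposed: `eaf`
(\(R^2 = 2f(1-f)\beta^2\)) and `zscore`
(\(R^2 = z^2/(z^2+N-2)\), \(z=\beta/SE\)). The default is `zscore`
because recomputing the published instrument F-values from their printed
betas and SEs reproduces them to within a few percent under `zscore`
(rs12614: 144.45 versus the printed 144.35) but differs several-fold
under `eaf`, which assumes a standardized quantitative trait. No exact
equality with the printed F column is claimed anywhere: the printed
values are not exactly recoverable under any standard formula from the
rounded table entries, so tests assert the scientifically meaningful
statements (all F > 10; rs12614 within 5%).

Clumping is the standard greedy procedure: rank by exposure p-value
(ties broken by chromosome, then position, for determinism), keep the
best remaining variant, remove all same-chromosome variants within the
distance cutoff whose squared correlation with it reaches the threshold,
repeat. Defaults are \(r^2 < 0.01\) within 10,000 kb — the published
parameters. The distance rule is interpreted as a pairwise index-to-
candidate distance, matching the stated "distance cutoff"; variants on
different chromosomes are never pruned against each other, and variants
missing from the LD matrix are treated as uncorrelated but flagged in
the clump report. The package consumes a user-supplied signed LD matrix
(r, not r²) and never computes LD from genotype panels. The shipped
`ld_eas_synthetic.tsv` is a synthetic block matrix — nine HLA variants
in one high-LD block, three variants independent — whose structure makes
greedy clumping retain exactly the four variants the published analysis
retained (rs1883832, rs7453920, rs9277535, rs1419881); real-panel
replication requires a user-supplied matrix.

## The five estimators

All effects are log odds; odds ratios are exponentials. With aligned
exposure effects \(\beta_{Xj}\) (SE \(SE_{Xj}\)) and outcome effects
\(\beta_{Yj}\) (SE \(SE_{Yj}\)), the per-variant Wald ratio is
\(\hat\theta_j = \beta_{Yj}/\beta_{Xj}\) with first-order SE
\(SE_{Yj}/|\beta_{Xj}|\).

**IVW (canonical).** Inverse-variance weighting of the ratios with
\(w_j = \beta_{Xj}^2/SE_{Yj}^2\), identically weighted through-origin
regression of \(\beta_Y\) on \(\beta_X\). Fixed-effects SE is
\((\sum w_j)^{-1/2}\).

**IVW (all SNPs).** Generalized least squares through the origin under
\(\Omega_{jk} = SE_{Yj}\,SE_{Yk}\,\rho_{jk}\), with \(\rho\) the signed
LD correlation: \(\hat\theta = (\beta_X'\Omega^{-1}\beta_X)^{-1}
\beta_X'\Omega^{-1}\beta_Y\). This lets all variants of a gene region
contribute without overcounting. It reduces to the canonical IVW under
identity LD (asserted to 1e-12 in the tests).

**MR-Egger (canonical and all SNPs).** The same regressions with a free
intercept, after orienting every variant so \(\beta_{Xj} > 0\) (the
orientation that makes the intercept interpretable; estimates are
invariant to joint sign flips). The slope is a pleiotropy-robust causal
estimate under the InSIDE assumption; the intercept estimates the mean
directional pleiotropic effect. Inference is t-based with \(J-2\)
degrees of freedom. In the correlated form, reorienting variant \(j\)
also flips the sign of its error correlations, so the GLS covariance is
\(S\Omega S\) with \(S\) the orientation sign matrix — omitting this is
a subtle error that the test suite's Cholesky-whitening oracle catches.

**Weighted median.** The 0.5-quantile of the ratio distribution weighted
by the IVW weights, linearly interpolated between the cumulative-weight
midpoints; consistent when valid instruments carry at least half the
weight. The penalized and simple variants are not implemented. Its SE
comes from a parametric bootstrap (default 1000 replicates) resampling
both effect vectors from their reported normal sampling distributions;
the seed is a required argument so no global RNG state is consumed
silently.

### Variance models and numerics

Every estimator offers `fixed` and `multiplicative_random` (default)
variance models; the latter inflates SEs by
\(\max(1, \sqrt{Q/(J-1)})\) (IVW; generalized residual form in the
correlated case) or \(\max(1, \sqrt{RSS_w/(J-2)})\) (Egger), the
prevailing default in two-sample MR software. The inflation floor at 1
means the model never rewards underdispersion. The 95% CI multiplier is
1.96 for IVW and the weighted median and the \(t_{J-2}\) quantile for
Egger.

\(\Omega\) is inverted by dense solves after a condition check: when the
eigenvalue ratio exceeds 1e10 (near-collinear instruments, plausible for
11 HLA variants under real LD) the fit aborts with advice to add ridge
regularization (\(\Omega + \epsilon\,\mathrm{diag}\,\Omega\), default
\(\epsilon = 0\)) or drop instruments, rather than returning a fragile
estimate.

Degenerate inputs are rejected early: zero exposure effects before Wald
ratios, fewer than 3 instruments for Egger and the median, fewer than 2
for Q, non-positive SEs at construction.

## Sensitivity analyses and multiple testing

Cochran's Q is always computed about the **fixed-effects** IVW estimate
(the standard definition) even when the reported estimate uses random
effects, with a \(\chi^2_{J-1}\) reference. For correlated instrument
sets the generalized residual form
\((\beta_Y-\hat\theta\beta_X)'\Omega^{-1}(\beta_Y-\hat\theta\beta_X)\)
is used: the naive Q over correlated instruments would double-count
shared variation. Both forms coincide under identity LD (tested).

The Egger intercept test reports the intercept, its SE, and the
\(t_{J-2}\) p-value from whichever Egger fit matches the instrument set.

Bonferroni control uses threshold \(\alpha/m\); for the five stroke
outcomes at \(\alpha = 0.05\) this is 0.01. The comparison is
deliberately non-strict (\(p \le\) threshold): the published analysis
declares p = 0.010 significant at threshold 0.01, which forces this
convention.

## The synthetic-data generator

`simulate_two_sample()` draws, per variant: frequency
\(f_j \sim U(\texttt{maf\_range})\), true instrument effect
\(\gamma_j \sim U(\texttt{gamma\_range})\), pleiotropic effect
\(\alpha_j\) (zero; \(N(0,\sigma^2)\) balanced; \(N(\mu,\sigma^2)\)
directional), and SEs from the standard GWAS approximation
\(SE \approx 1/\sqrt{2f(1-f)N}\) with configurable effective sample
sizes. Estimation errors for the two sides are independent multivariate
normals whose correlation follows the configured block LD structure
(blocks `ar1` or `compound`), scaled by the SEs. Observed effects are
\(\hat\beta_{Xj} = \gamma_j + \epsilon_{Xj}\) and
\(\hat\beta_{Yj} = \theta\gamma_j + \alpha_j + \epsilon_{Yj}\).

Defaults are the study's conditions: \(J = 12\), exposure \(N = 18371\),
outcome at the any-stroke effective size
(\(4/(1/27413+1/237242) \approx 98{,}287\)); `gamma_range = (0.09,
0.20)` was chosen once so that simulated F-statistics span roughly
25–320, the span of the published instrument table. Binary-trait SEs use
the effective-sample-size device because only case/control counts are
published for either trait. `reference_study()` instead anchors the
exposure side to the packaged instrument table verbatim and scales the
outcome noise to the large-artery stroke arm (1735 cases, 237,242
controls, effective \(n \approx 6890\)), omitting rs2853953.

A single RNG stream seeded once per study generates all draws in a fixed
order, which makes studies bit-identical under a repeated seed — the
reproducibility property the tests and the pipeline rely on.

What the generator does **not** emulate: winner's-curse bias in the
exposure estimates, sample overlap between the two GWASs, allele-label
or strand errors (alleles are always non-palindromic and consistent
unless a test perturbs them deliberately), frequency differences between
the two cohorts, and real HLA LD (blocks are stylized `ar1`/`compound`
structures). Passing calibration tests on these simulations therefore
validates the estimators' arithmetic and their behavior under the
modelled violations (pleiotropy, LD, weak noise), not robustness to
those unmodelled artefacts of real data.

## Validation strategy and problem sizes

Every estimator is checked against an independent brute-force oracle
that shares no code with the implementation: written-out normal
equations for IVW and Egger, Cholesky-whitening followed by ordinary
least squares for the GLS forms, an exhaustive crossing-interval scan
for the weighted median, and a literal re-transcription of the greedy
rule for clumping. Monte-Carlo checks use fixed seeds and sizes chosen
to keep the suite fast while leaving comfortable statistical margins:
type-I error of the fixed-effects IVW and calibration of the Egger
intercept under balanced pleiotropy at 2000 replicates (±3 Monte-Carlo
SDs around 0.05), effect recovery at 200 large-cohort replicates
(tolerance 0.01 on \(\theta = \log 0.872 \approx -0.137\)), power
monotonicity at 200 replicates per pleiotropy level, and LD-structure
recovery of the simulated errors at 800 replicates.

One algebraic note: with a dominant-weight instrument the interpolated
weighted median equals that instrument's ratio exactly only when the
cumulative-weight midpoint lands on 0.5; in general it lies in the
adjacent interval. The tests therefore assert the exact case via a
symmetric weight configuration and leave the general dominant-weight
behavior to the oracle comparison.

## Known limitations

- Exact reproduction of the published stroke estimates requires the
  real outcome summary statistics and a real East Asian LD panel; see
  `inst/recipes/headline_reproduction.md`. The shipped LD matrix is a
  synthetic structural stand-in, adequate for exercising the pipeline
  and reproducing the clumping retention pattern, not for real
  inference.
- The published phrase "odds ratio per unit decrease in log odds" of
  the exposure conflicts with the conventional per-unit-increase
  reading; this package reports effects per unit *increase* of exposure
  log-odds and leaves the interpretation to the analyst.
- Which variance model (fixed vs multiplicative random effects) the
  original analysis used is not stated; both are implemented and the
  default is the random-effects model, so third-decimal differences
  against the published intervals are expected under the default.
- Only biallelic variants are handled; multi-allelic records and
  LD-proxy substitution are out of scope.
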