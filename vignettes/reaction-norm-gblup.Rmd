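---
title: "Multi-environment genomic prediction with reaction-norm GBLUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-environment genomic prediction with reaction-norm GBLUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Breeding programs that select for a micronutrient trait such as kernel zinc
concentration evaluate inbred lines in a handful of environments
(site-by-year combinations) and want to predict, from genome-wide markers,
the performance of lines that were never phenotyped (new candidates) or
that were phenotyped in some environments but not others (sparse testing).
Genotype-by-environment interaction (G×E) makes the two problems different:
information can be borrowed across correlated environments only if the
model represents how genomic effects change between them.

`gxeblup` implements the reaction-norm family of GBLUP models for this
setting, together with the surrounding workflow: marker quality control,
genomic relationship matrices, adjusted line means, heritability,
cross-validated prediction ability, and selection-response projections.
A synthetic-data generator produces inbred panels and bi-parental
doubled-haploid (DH) populations with exactly the covariance structure the
models assume, so the entire pipeline is testable without external data.

## Models

For line $j$ in environment $i$ the observed trait value is modelled as

$$y_{ij} = \mu + E_i + L_j + g_j + gE_{ij} + e_{ij}$$

with independent normal terms: environment main effect
$E_i \sim N(0, \sigma^2_E)$, line effect $L_j \sim N(0, \sigma^2_L)$,
genomic effect $g = (g_1,\dots,g_J)' \sim N(0, G\sigma^2_g)$ with
$G = XX'/p$ over $p$ column-centred marker dosages, the interaction
$gE \sim N(0, (Z_g G Z_g')\#(Z_E Z_E')\,\sigma^2_{gE})$ where $\#$ is the
Hadamard (element-wise) product of the genomic and environment incidence
structures, and residual $e_{ij} \sim N(0, \sigma^2_e)$. Dropping terms
gives the nested models: M1 (environment + line), M2 (+ genomic), M3
(+ genomic-by-environment). The line effect is retained alongside the
genomic effect to absorb genetic signal that imperfect marker–QTL linkage
leaves uncaptured.

Because the environment incidence kernel is a same-environment indicator,
the interaction covariance is block-diagonal by environment with blocks
$G\sigma^2_{gE}$: interaction effects are independent draws from the
genomic covariance in each environment. With a single environment the
interaction kernel collapses onto the genomic kernel, which is asserted in
the tests.

### Centring and scaling of G

`compute_grm()` centres marker columns by their mean before the
cross-product (an uncentred Gram matrix conflates allele frequency with
relatedness); `center = FALSE` is available. The division is by the marker
count $p$ only; VanRaden-style $2\sum p_kq_k$ scaling is provided as an
option but off by default, matching the plain $XX'/p$ convention. For
homozygous inbreds coded 0/2 the mean diagonal of $G$ is about
$E[4pq] \approx 0.7$, not 1; all variance components attached to $G$ are
therefore *coefficients of that kernel*, and moment checks in the tests
use the realized kernel scale rather than assuming a unit diagonal.

## Estimation

`fit_gibbs()` draws from the posterior of
$\{\mu, E, L, g, gE, \sigma^2_\cdot\}$ by Gibbs sampling. Each
record-level kernel $K_k$ is eigen-decomposed once
($K_k = U_k D_k U_k'$, diagonal jitter $10^{-8}$); writing
$u_k = U_k D_k^{1/2}\delta_k$ makes the full-conditional precision of
$\delta_k$ diagonal, so each block is sampled jointly at $O(n \cdot r_k)$
cost per iteration in compiled code. Variances get scaled-inverse-$\chi^2$
updates; masked records are imputed by data augmentation, which is what
makes cross-validation cheap: the eigen-decompositions depend only on the
design, not the mask. The overall mean has a flat prior; the environment
main effect is a random effect with its own variance, which is why an
environment variance is reported alongside the others.

### Priors

Each variance has a scaled-inverse-$\chi^2(\nu_0, S_0)$ prior. Scales
follow the partition convention of Bayesian GBLUP software: the residual
scale corresponds to $(1-R^2)$ of the phenotypic variance and each of the
$K$ random terms to $R^2/K$ of it, divided by the mean diagonal of its
kernel ($R^2 = 0.5$ by default). The default degrees of freedom are
$\nu_0 = 2$, deliberately weak: in this design the line/genomic and
interaction/residual pairs are separated only by the off-diagonal
structure of $G$ (with one replicate per cell the interaction is
confounded with the residual up to that structure), and simulation
experiments showed that moderately informative priors ($\nu_0 = 5$)
visibly drag the posterior means of the weakly identified components
toward their prior modes, while maximum likelihood on the same data sits
near the truth. With $\nu_0 = 2$ the posterior means of a
300-line × 1,000-marker × 3-environment recovery experiment are unbiased
to within one posterior SD. Both $\nu_0$ and $R^2$ are arguments.

### Oracle

`closed_form_blup()` solves the same mixed model exactly at fixed
variances (GLS mean, conditional means of every random term, predictions
for masked cells). It is used three ways: to validate the sampler at fixed
components (agreement within Monte-Carlo error), to prove the
ridge-regression equivalence of genomic BLUP
($\lambda = p\,\sigma^2_e/\sigma^2_g$), and as a fast deterministic engine
for cross-validation property tests.

## Cross-validation

`cv_plan()` + `run_cross_validation()` implement the two standard schemes
with fivefold splits repeated (default 20 times, 100 runs): CV1 masks
*all* environments of each validation line (new-line prediction); CV2
masks exactly one environment per validation line, allocated round-robin
so each environment is missing for about a third of them (sparse
testing). Prediction ability $r_{MP}$ is the Pearson correlation between
observed cell values and predicted genetic values, computed within each
environment over a run's masked cells and then averaged over runs; the
summary's `Average` row averages the per-run environment means. Inside CV
the sampler runs at a reduced budget (4,000 iterations, 1,000 burn-in) by
default; the deterministic BLUP engine at fixed components is available
and is what the scheme-level property tests use, since the properties
under test (CV2 ≥ CV1, noiseless limit, monotonicity in genomic variance)
concern the masking schemes, not the sampler.

## The synthetic-data generator

The generator emulates the two population types of a zinc biofortification
program at desk scale, and is itself first-class, tested code.

* **Panel** (`simulate_panel_genotypes()`): Balding–Nichols-style model —
  per-marker ancestral frequency Uniform(0.05, 0.5), subpopulation
  frequencies Beta-perturbed with divergence parameter `fst`, each inbred a
  single haplotype doubled (dosages 0/2). Defaults: 5 subpopulations,
  `fst = 0.2`. At 300 lines × 1,000 markers this reproduces the diffuse
  spectrum of a real diverse panel (roughly half the principal components
  are needed for 80% of the genomic variance; the first two explain a few
  percent) while keeping enough relatedness structure for the variance
  components to be separable.
* **DH populations** (`simulate_dh_genotypes()`): each line is a doubled
  F1 gamete over a configurable genetic map (default 10 chromosomes ×
  1.5 Morgans, uniform marker spacing), with crossovers Poisson in the
  chromosome length (Haldane, no interference). Lines are fully homozygous
  by construction; defaults are sized to bi-parental populations of
  around 112–143 lines.
* **Phenotypes** (`simulate_phenotypes()`): records drawn from the full
  M3 decomposition. Marker effects are i.i.d. $N(0, \sigma^2_g/p)$ so the
  genomic values have covariance exactly $G\sigma^2_g$; the interaction is
  drawn per environment from an eigen factor of $G$ (so its covariance is
  exactly the M3 Hadamard structure); replicates share every term except
  the residual. Default variance scale: mean 26.94 μg/g with components
  (E 8.11, L 2.47, g 10.03, gE 2.13, e 4.92) (μg/g)², the full-data
  estimates for a diverse tropical panel. With these defaults the implied
  between-environment correlation of line means,
  $(\sigma^2_L + c\,\sigma^2_g) / (\sigma^2_L + c\,\sigma^2_g +
  c\,\sigma^2_{gE} + \sigma^2_e)$ with $c$ the mean diagonal of $G$, is
  about 0.6, inside the 0.3–0.7 range typical of multi-environment zinc
  trials.

What the generator does **not** emulate: linkage disequilibrium calibrated
to real maize, selection or drift across generations, spatial field trends,
non-normal residuals. Passing tests on synthetic data therefore validate
the estimation machinery and the scheme logic, not the field realism of
any particular dataset.

## Numerical choices

* Eigen jitter $10^{-8}$ on every kernel; null directions (relative
  eigenvalue < $10^{-10}$) dropped.
* Balanced phenotype designs bypass the mixed model in `compute_blues()`
  (the BLUE equals the cell mean exactly); unbalanced multi-replicate
  environments are fitted with `lme4`.
* Reported percentages of within-environment variance are rounded to
  integers, variances to 2 decimals in rendered tables; unrounded values
  are always retained and round-trip within display precision.
* Correlations in CV are skipped (with a message) when a run leaves fewer
  than 3 masked cells in an environment.
* Heterozygosity above 5% in a marker matrix triggers a warning, since the
  intended material is inbred.

## Problem sizes used in the shipped analyses

The test-suite recovery experiment uses 300 lines × 1,000 markers × 3
environments with 15,000 iterations (5,000 burn-in, thinning 5); the
acceptance script runs the same design for 30,000 iterations (8,000
burn-in); scheme-level cross-validation properties use
100–150-line panels with fivefold plans and 1–2 repeats. These sizes give
posterior SDs around 1–2 (μg/g)² for the genomic variance and make the
whole suite run in minutes on one core; they are scaled-down analogues of
a 923-line panel with ~180k markers, not reproductions of it.

## Known limitations

* Bayesian path only; no REML/frequentist fitting.
* The line/genomic and interaction/residual splits are intrinsically
  weakly identified in single-replicate three-environment designs; expect
  wide posteriors for those components at these sizes, whatever the
  sampler settings.
* The DH selection-response projections of the source breeding context are
  not derivable from the plain truncation-selection formula; the formula's
  output is reported as-is.
* No CV0 / leave-one-environment-out scheme, no LD pruning, no marker
  phasing or SNP calling.
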