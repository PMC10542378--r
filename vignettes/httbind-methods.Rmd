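---
title: "Modelling genetic contributions to regional 5-HTT binding"
author: "httbind maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling genetic contributions to regional 5-HTT binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(httbind)
```

## The scientific problem

The serotonin transporter (5-HTT) regulates extracellular serotonin by
reuptake, and its regional availability in the living human brain can be
quantified with [11C]DASB PET as the non-displaceable binding potential
(BP~ND~), one unitless value per region per participant. `httbind`
implements a two-arm analysis of whether common serotonin-related genetic
variants shape regional 5-HTT availability in healthy adults:

1. an **association arm** — a Gaussian latent-variable model (LVM)
   relating five carrier-coded variants (*BDNF* rs6265, the triallelic
   *SLC6A4* 5-HTTLPR system, *HTR1A* rs6295, *HTR2A* rs7333412, *MAOA*
   rs1137070) and nuisance covariates (age, sex, PET and MRI scanner
   type) to seven intercorrelated regional BP~ND~ values, with an
   FDR-controlled search for additional model paths and a genotype-block
   likelihood-ratio test; and
2. a **prediction arm** — a permutation-calibrated, repeatedly
   cross-validated random-forest framework asking whether genotype alone
   predicts covariate-adjusted regional binding at the individual level.

Because suitable cohort data are access-restricted, the package ships a
calibrated synthetic-cohort generator that reproduces the generative
structure both arms assume, so every stage is testable end to end.

## Genotype coding

All variants are dichotomized under a carrier model (1 = at least one
copy of the carrier allele, 0 = homozygote reference): rs6265 met(A)-
carriers vs val/val, rs6295 G-carriers vs CC, rs7333412 G-carriers vs AA,
and rs1137070 T-carriers vs CC. The 5-HTTLPR insertion/deletion (L/S) is
combined with the adjacent A/G SNP (known under the aliases rs25531 and
rs23351; treated here as a single A/G locus) into the functional S'
grouping: the G allele occurs only on L backgrounds and makes that allele
(L~G~) functionally S-like, so S'-carriers have at least one S or L~G~
allele and the reference group is L~A~/L~A~. A G allele reported on an
S/S background is rejected as an inconsistent haplotype. Missing
genotypes are rejected rather than imputed, matching a complete-
genotyping inclusion design.

Genotype-level QC uses a plain Pearson 1-df chi-square against
Hardy-Weinberg expectations (no continuity correction or exact test; the
minimal defensible default in the absence of stated mechanics) and, for
the X-linked rs1137070, a 2x2 chi-square comparing hemizygous male allele
frequencies (one allele each) with female frequencies (two each).

## The latent-variable model

For participant $i$ with covariate row $x_i$ (five carrier indicators,
mean-centered age, sex, PET scanner, MRI scanner) and regional outcomes
$y_{ir}$, $r = 1, \dots, 7$:

$$\eta_i = \gamma^\top x_i + \zeta_i, \qquad \zeta_i \sim N(0, \tau^2)$$
$$y_{ir} = \nu_r + \lambda_r \eta_i + \delta_r^\top x_i + \varepsilon_{ir},
  \qquad \varepsilon_i \sim N(0, \Psi)$$

The shared factor $\eta$ captures the strong inter-regional correlation
of 5-HTT binding; $\Psi$ is diagonal plus residual covariances for the
anatomically adjacent pairs caudate:putamen, amygdala:hippocampus and
thalamus:midbrain; and two direct paths (sex to caudate, rs6265 to
neocortex) act beside the factor. Identification fixes the caudate
loading $\lambda_{\text{caudate}} = 1$ and the latent intercept to 0, so
every $\gamma$ is read in caudate BP~ND~ units (the reference scale);
with a single region the latent variance is not separable from the
residual and is fixed to zero, making the model collapse to ordinary
regression (a property the tests exploit as an oracle).

Estimation is full-information Gaussian maximum likelihood. The implied
moments are $\mu_i = \nu + \lambda (\gamma^\top x_i) + \Delta x_i$ and
$\Sigma = \lambda\lambda^\top \tau^2 + \Psi$, shared across participants.
The optimizer is BFGS with analytic gradients on a log-variance
parameterization (residual pair covariances enter untransformed; a
non-positive-definite $\Sigma$ returns a finite barrier value, which the
line search backs away from). Starting values come from a principal-axis
heuristic on the covariance of per-region OLS residuals; convergence
requires a vanishing gradient, with up to five jittered restarts.
Standard errors are taken from the inverse of the numerically
differentiated observed information at the optimum, on the natural scale;
intervals are Wald 95% and p-values two-sided normal — also for variance
parameters, whose intervals should be read descriptively.

### Path search and block test

Candidates are every absent direct covariate-to-region path (61 under
the default spec) and every absent residual covariance (18). The exact
candidate universe of such searches is a design choice; this one covers
all single-edge extensions of the default graph. The default screening
statistic is the Rao score test at the null fit — no refit per candidate;
the candidate's score component is combined with the observed information
of the extended model, so 79 candidates cost two gradient evaluations
each plus one information matrix. A Wald confirmation mode (refit each
candidate, test the added parameter) is exposed as `method = "wald"`;
score screening is the default because it is the established screening
device for modification searches and is two orders of magnitude cheaper.
Raw p-values are Benjamini-Hochberg adjusted across the entire candidate
set and additions flagged at adjusted p < 0.05.

The genotype-block likelihood-ratio test removes all genotype-bearing
parameters (five latent effects plus the rs6265-to-neocortex direct
path, hence 6 df by default) and refers twice the log-likelihood
difference to a chi-square.

## Per-region regressions and percent differences

Each region is also fit by OLS on all five carrier indicators plus the
nuisance covariates. Percent differences divide a carrier coefficient by
the covariate-adjusted reference mean: the fitted value with all carrier
indicators at zero, age at its mean, and the binary nuisance covariates
at their sample proportions (not their modes). The denominator choice is
deliberate — it makes the statistic independent of covariate imbalance
and of any positive rescaling of BP~ND~ — since group-mean denominators
are ambiguous in this design.

## The prediction harness

For each region the outcome is the OLS residual of BP~ND~ on age, sex
and the two scanner indicators; the null model's error is the root mean
square of those residuals, RMSE~residual~. The genotype model is a
random-forest regressor on the five carrier indicators only: 500 trees,
bootstrap per tree, `max(1, floor(p/3)) = 1` candidate feature per split,
minimum terminal-node size 5. Performance is repeated five-fold
cross-validation: squared errors are pooled across the five held-out
folds before the root (one RMSE per fold assignment; the alternative
mean-of-fold-RMSEs reading is exposed as `pooling = "fold"`), then
averaged over ten fold-assignment resamples. Improvement is
$\Delta\text{RMSE} = 100(\text{RMSE}_{\text{residual}} -
\text{RMSE}_{\text{genotype}}) / \text{RMSE}_{\text{residual}}$.

Significance comes from an empirical null: each permutation shuffles the
residual vector and re-runs the complete cross-validation procedure
(all folds and resamples), the default being 10,000 permutations. The
p-value is one-sided (improvement means lower RMSE) with add-one
smoothing, $p = (1 + \#\{\text{null} \le \text{observed}\})/(B+1)$,
which keeps p strictly positive; the smoothing convention is ours, as is
the one-sidedness, both standard for empirical nulls asking "better than
chance?". The seven per-region p-values are Holm-adjusted into
family-wise p~FWE~.

The forest itself is an in-package C++ implementation specialised to
binary features, fixed by the contract above (trees, bootstrap,
split-sampling rule, node size); the test suite cross-checks its
cross-validated RMSE against the independent `randomForest`
implementation on identical data. The in-package engine exists because
the permutation arm multiplies forest fits by the permutation count and
the simulation replicates, and a specialised engine keeps full
calibration studies computable. All randomness (fold assignment,
bootstraps, split sampling, permutations) flows through R's RNG, so a
single `set.seed()` makes every result, including the permutation null,
bit-for-bit reproducible.

With `mtry = 1` a forest learns even a noiseless single-variant signal
only partially (each split has one chance in five of sampling the
informative feature), which the cross-check against `randomForest`
reproduces; `mtry = p` recovers such signals essentially exactly. The
default stays at the `p/3` rule because that is the harness contract.

## The synthetic-cohort generator

`cohortConfig()` encodes the study conditions as defaults:

* **marginals** — n = 140 (84 F / 56 M), PET A/H 42/98, MRI T/V 81/59,
  carrier counts 99 (5-HTTLPR S'), 107 (rs6295 G), 53 (rs7333412 G),
  65 (rs1137070 T), 50 (rs6265 met); ages truncated-normal 26.7 ± 7.2 on
  [18, 51]. Counts are realised exactly by shuffled fixed-count
  assignment (not binomial sampling), independently across variants —
  the joint genotype distribution is unavailable, so independence is the
  neutral choice.
* **effects** — latent effects planted at the association estimates:
  rs1137070 +0.07, rs6265 −0.06, age −0.009 per year; direct sex-to-
  caudate +0.14; all other covariate effects zero. The rs6265 direct
  neocortex path defaults to $+0.06\,\lambda_{\text{neocortex}}$ so that
  the total rs6265 effect on neocortex is approximately null (direct and
  latent-mediated contributions cancel).
* **calibration closure** — with the caudate loading fixed at 1, a
  planted caudate percent difference of 11% for the MAOA contrast forces
  the caudate reference mean $0.07 / 0.11 \approx 0.636$; remaining
  region means are configurable plausible DASB-scale values (putamen
  0.75, midbrain 1.10, thalamus 1.15, hippocampus 0.50, amygdala 0.75,
  neocortex 0.25), and loadings derive as $\lambda_r = (\text{pct}_r /
  100)\,\mu_r / \gamma_{\text{MAOA}}$ so the latent pathway reproduces
  the planted percent profile (caudate 11, putamen 9, amygdala 2, other
  regions 6 — the midpoint of the 2–11 range, an invented default).
  This closure makes the effect-size targets and the percent-difference
  targets mutually consistent inside one generator; whether the printed
  11% and 0.07 are exactly consistent in the source cohort depends on an
  unprinted caudate mean, so the closure is this package's resolution.
* **dispersion** — total covariate-adjusted regional SDs set to the
  residual-RMSE profile (0.266, 0.301, 0.251, 0.305, 0.121, 0.272,
  0.056); latent residual SD $\tau = 0.15$ (a configurable choice);
  region residual variances derived by subtraction, $\psi_r =
  \text{sd}_r^2 - \lambda_r^2\tau^2$, and the configuration is rejected
  if any is non-positive. Residual correlations for the three linked
  pairs default to 0.3, a plausible adjacent-region value. Because the
  subtraction closure ignores the (small) genotype-effect variance, the
  covariate-only caudate residual SD comes out near 0.270 rather than
  0.266 — a deliberate, documented property of the closure, about 1.5%.

Nuisance covariates enter the generator mean-centered, so the regional
means are exactly the reference-genotype means at covariate means;
carrier indicators enter as 0/1, so percent differences relative to the
reference group equal the planted profile in expectation.

The generator emulates the statistical structure the analysis assumes —
it does not simulate PET physics, kinetic-model noise, non-Gaussian
tails, genotype linkage, or lifestyle covariates. Passing recovery tests
on generated cohorts therefore demonstrates correctness of the
estimators under the assumed model, not robustness to real-data
violations of it. The generator emits carrier indicators only, so
Hardy-Weinberg QC applies when users supply raw genotypes.

## Numerical choices and degenerate inputs

* Optimizer tolerance: relative log-likelihood change below 1e-10 with
  a gradient-norm check; restarts jitter the start by N(0, 0.1·attempt).
* Monomorphic samples make the Hardy-Weinberg test undefined; it returns
  p = 1 with a warning rather than NaN.
* Constant carrier indicators make the corresponding regional
  coefficient inestimable; it is reported as NA with a warning.
* Score-test variances that are non-positive after partialling (numerical
  degeneracy) yield NA candidates rather than fabricated p-values.
* A negative likelihood-ratio statistic beyond 1e-6 triggers a refit
  with more restarts, then an error.
* Percent differences require a positive reference mean; BP~ND~ scales
  satisfy this in practice and violations are errors.

## Problem sizes used by the test suite

Simulation-based checks use sizes chosen to balance Monte-Carlo
resolution against runtime on one CPU: 200 cohorts of n = 140 for
estimator recovery (Monte-Carlo SE of the mean MAOA effect about 0.0026),
100 cohorts for the dispersion calibration, n = 10,000 single cohorts
for consistency checks, and a 500-simulation type-I study of the
permutation test at B = 199 permutations with reduced forests (15 trees,
one resample, n = 40) — the calibration of a permutation test is
invariant to the statistic's configuration, which is what makes the
reduced setting informative.

## Known limitations

* Wald inference for variance parameters is crude near boundaries; no
  profile or robust (sandwich) intervals are provided.
* The likelihood assumes complete data; missing values are rejected, not
  modelled.
* The path search considers single-edge extensions only and score and
  Wald screening can disagree in small samples.
* The forest engine is specialised to binary features; continuous
  features would need the general split search it deliberately omits.
* Holm and Benjamini-Hochberg are the only multiplicity procedures
  offered, mirroring the two families (seven prediction models; all
  search candidates) they serve.
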