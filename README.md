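# httbind

Genetic contributions to regional brain serotonin transporter (5-HTT)
availability: latent-variable association modelling and permutation-
calibrated genotype prediction for [11C]DASB PET binding potentials.

## What this package is for

Regional 5-HTT availability, measured by PET as the non-displaceable
binding potential BP_ND, is strongly intercorrelated across brain
regions and plausibly shaped by common serotonin-related genetic
variants. `httbind` implements, as tested reusable code, a two-arm
analysis of this question for cohorts carrying five carrier-coded
variants (*BDNF* rs6265, the triallelic *SLC6A4* 5-HTTLPR system,
*HTR1A* rs6295, *HTR2A* rs7333412, *MAOA* rs1137070), nuisance
covariates (age, sex, PET and MRI scanner type) and seven regional
BP_ND values (caudate, putamen, midbrain, thalamus, hippocampus,
amygdala, neocortex):

* **Association.** A Gaussian latent-variable model in which the seven
  regions load on one shared factor,

      eta_i  = gamma' x_i + zeta_i,          zeta ~ N(0, tau^2)
      y_ir   = nu_r + lambda_r eta_i + delta paths + eps_ir,  eps ~ N(0, Psi)

  with the caudate loading fixed to 1 so covariate effects `gamma` are
  read in caudate BP_ND units, residual covariance links for
  caudate:putamen, amygdala:hippocampus and thalamus:midbrain, and
  direct sex-to-caudate and rs6265-to-neocortex paths. Fitted by full
  maximum likelihood with analytic gradients; includes a score-test
  search over all absent paths with Benjamini-Hochberg FDR control, a
  6-df genotype-block likelihood-ratio test, and per-region regressions
  reporting covariate-adjusted percent differences between genotype
  groups.
* **Prediction.** Per region, BP_ND is residualized against the
  nuisance covariates and a random forest on the five carrier
  indicators alone (500 trees, bootstrap per tree, `max(1, floor(p/3))`
  features per split) is evaluated by five-fold cross-validation
  repeated ten times; significance of the RMSE improvement
  `deltaRMSE = 100 (RMSE_residual - RMSE_genotype) / RMSE_residual`
  comes from an empirical null of (by default) 10,000 outcome
  permutations, each re-running the complete cross-validation, with
  Holm control across the seven regions.

Because suitable cohort data are access-restricted, a calibrated
synthetic-cohort generator (`cohortConfig()` / `simulateCohort()`)
reproduces the marginals, effect sizes and dispersion profile the
analysis assumes, making every stage testable. Genotype utilities
(triallelic 5-HTTLPR S' recoding, carrier dichotomization,
Hardy-Weinberg and X-linked allele-frequency chi-square tests) and
cohort CSV input/output round out the pipeline.

## Worked example

```r
library(httbind)

coh <- simulateCohort(cohortConfig(), seed = 11)  # 140 participants
fit <- fitLvm(coh)
fit
#> LvmFit: 140 participants, logLik = 362.471, converged
#>                      term estimate      se    lower     upper       p
#>             latent.httlpr  0.04910 0.03380 -0.01720  0.115000 0.14600
#>             latent.rs6295  0.01810 0.03660 -0.05360  0.089900 0.62100
#>          latent.rs7333412  0.02550 0.03180 -0.03690  0.087900 0.42300
#>          latent.rs1137070  0.06900 0.03190  0.00652  0.132000 0.03040
#>             latent.rs6265 -0.03350 0.03380 -0.09980  0.032800 0.32200
#>                latent.age -0.00601 0.00266 -0.01120 -0.000794 0.02390
#>                latent.sex -0.00457 0.03100 -0.06530  0.056200 0.88300
#>                latent.pet  0.01470 0.03410 -0.05210  0.081500 0.66600
#>                latent.mri -0.02170 0.03110 -0.08260  0.039300 0.48600
#>       direct.sex->caudate  0.13000 0.03720  0.05740  0.203000 0.00046
#>  direct.rs6265->neocortex  0.00156 0.00893 -0.01590  0.019100 0.86100

percentDifference(fitRegional(coh, "caudate"), "rs1137070")
#> [1] 15.28561

lrt <- lrtGenotypes(coh)
lrt[c("statistic", "df", "p")]
#> $statistic  10.58...   $df  6   $p  0.102...
```

This simulated cohort plants a latent MAOA rs1137070 carrier effect of
+0.07 caudate BP_ND units and a direct sex effect of +0.14; the fit
recovers 0.069 (p = 0.030) and 0.130 (p < 0.001) — estimates are noisy
at n = 140, which is exactly what the simulation arm of the test suite
quantifies across hundreds of cohorts. The percent difference (15.3%
here, 11% in expectation) is the carrier coefficient relative to the
covariate-adjusted reference-group mean. The genotype-block LRT
aggregates all genotype parameters (6 df).

The prediction arm runs the same way (reduce the permutation count for
interactive use):

```r
pr <- predictRegions(coh, predictionConfig(nPermutations = 199), seed = 1)
pr@results   # region, rmseResidual, rmseGenotype, deltaRmse, pUnc, pFwe
```

`runFullAnalysis()` chains QC, model fit, path search, LRT, regional
regressions and prediction into one report; `writeReport()` serialises
it to JSON; `readCohort()`/`writeCohort()` handle cohort CSVs (raw
genotypes such as `L/S` + `A/G` or `C/T` are recoded to carrier
indicators on read).

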