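#' Cohort of regional 5-HTT binding with genotypes and covariates
#'
#' `BindingCohort` extends [SummarizedExperiment::SummarizedExperiment] with
#' a single assay `"bpnd"` holding the seven regional BP_ND values (rows =
#' regions in the canonical order of [regionNames()], columns = participants)
#' and `colData` columns `age` (years), `sex` (0 = female, 1 = male), `pet`
#' (0 = GE-Advance "A", 1 = HRRT "H"), `mri` (0 = Trio "T", 1 = Verio "V")
#' and the five carrier indicators named as in [genotypeNames()] (1 =
#' carrier group, 0 = homozygote reference).
#'
#' @aliases BindingCohort
#' @seealso [BindingCohort()], [readCohort()], [simulateCohort()]
#' @exportClass BindingCohort
setClass("BindingCohort", contains = "SummarizedExperiment")

setValidity("BindingCohort", function(object) {
  msg <- character()
  if (!"bpnd" %in% assayNames(object))
    msg <- c(msg, "assay 'bpnd' is required")
  if (!identical(rownames(object), regionNames()))
    msg <- c(msg, sprintf("rows must be exactly the regions %s, in order",
                          paste(regionNames(), collapse = ", ")))
  needed <- c("age", "sex", "pet", "mri", genotypeNames())
  missing <- setdiff(needed, colnames(colData(object)))
  if (length(missing))
    msg <- c(msg, paste0("missing colData column(s): ",
                         paste(missing, collapse = ", ")))
  if (!length(msg) && ncol(object) > 0L) {
    bp <- assay(object, "bpnd")
    if (!is.numeric(bp) || anyNA(bp) || any(!is.finite(bp)))
      msg <- c(msg, "BP_ND values must be finite and non-missing")
    cd <- colData(object)
    for (v in c("sex", "pet", "mri", genotypeNames())) {
      if (anyNA(cd[[v]]) || !all(cd[[v]] %in% c(0, 1)))
        msg <- c(msg, sprintf("colData column '%s' must be 0/1", v))
    }
    if (anyNA(cd$age) || !is.numeric(cd$age))
      msg <- c(msg, "age must be numeric and non-missing")
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "duplicate participant ids")
  }
  if (length(msg)) msg else TRUE
})

#' Specification of the latent-variable model graph
#'
#' Describes the model fitted by [fitLvm()]: which regions load on the latent
#' factor (the `referenceRegion` loading is fixed to 1 for identification),
#' which covariates act on the factor, which direct covariate-to-region paths
#' are included in addition, and which region pairs carry residual
#' covariances.
#'
#' @slot regions character, ordered subset of [regionNames()].
#' @slot covariates character, subset of [covariateNames()].
#' @slot referenceRegion single region whose loading is fixed to 1.
#' @slot directPaths data.frame with columns `covariate`, `region`.
#' @slot residualPairs data.frame with columns `region1`, `region2`.
#' @aliases LvmSpec
#' @seealso [lvmSpec()], [fitLvm()]
#' @exportClass LvmSpec
setClass("LvmSpec", representation(
  regions = "character",
  covariates = "character",
  referenceRegion = "character",
  directPaths = "data.frame",
  residualPairs = "data.frame"
))

setValidity("LvmSpec", function(object) {
  msg <- character()
  if (!all(object@regions %in% regionNames()) || !length(object@regions))
    msg <- c(msg, "regions must be a non-empty subset of regionNames()")
  if (anyDuplicated(object@regions))
    msg <- c(msg, "duplicated regions")
  if (!all(object@covariates %in% covariateNames()))
    msg <- c(msg, "covariates must be drawn from covariateNames()")
  if (length(object@referenceRegion) != 1L ||
      !object@referenceRegion %in% object@regions)
    msg <- c(msg, "referenceRegion must be one of the model regions")
  dp <- object@directPaths
  if (nrow(dp)) {
    if (!all(dp$covariate %in% object@covariates) ||
        !all(dp$region %in% object@regions))
      msg <- c(msg, "direct paths must connect model covariates to model regions")
    if (anyDuplicated(dp[c("covariate", "region")]))
      msg <- c(msg, "duplicated direct paths")
  }
  rp <- object@residualPairs
  if (nrow(rp)) {
    if (!all(unlist(rp[c("region1", "region2")]) %in% object@regions))
      msg <- c(msg, "residual pairs must be model regions")
    if (any(rp$region1 == rp$region2))
      msg <- c(msg, "residual pairs must be distinct regions")
    key <- apply(rp[c("region1", "region2")], 1L,
                 function(z) paste(sort(z), collapse = "|"))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicated residual pairs")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted latent-variable model
#'
#' Maximum-likelihood fit of an [LvmSpec-class] to a [BindingCohort-class]:
#' parameter estimates on the natural scale, standard errors from the inverse
#' observed information, Wald 95% confidence intervals and two-sided normal
#' p-values, the maximised log-likelihood and convergence metadata.
#'
#' @slot spec the fitted [LvmSpec-class].
#' @slot coefficients data.frame (term, type, estimate, se, lower, upper, p).
#' @slot loglik maximised log-likelihood.
#' @slot nobs number of participants.
#' @slot converged logical.
#' @slot details list with optimizer diagnostics and the raw parameter vector.
#' @aliases LvmFit
#' @exportClass LvmFit
setClass("LvmFit", representation(
  spec = "LvmSpec",
  coefficients = "data.frame",
  loglik = "numeric",
  nobs = "integer",
  converged = "logical",
  details = "list"
))

#' Result of the model-path search
#'
#' All candidate direct paths and residual covariances absent from a fitted
#' model, each with its score statistic, raw p-value and Benjamini-Hochberg
#' adjusted p-value; `added` marks candidates with adjusted p < 0.05.
#'
#' @slot candidates data.frame (type, from, to, statistic, p, pFdr, added).
#' @slot method "score" or "wald".
#' @aliases PathSearchResult
#' @exportClass PathSearchResult
setClass("PathSearchResult", representation(
  candidates = "data.frame",
  method = "character"
))

#' Per-region genotype prediction results
#'
#' One row per region: the covariate-only null RMSE, the mean cross-validated
#' RMSE of the genotype random forest, the percent RMSE change, the
#' uncorrected permutation p-value and the Holm family-wise adjusted p-value,
#' plus summaries of the permutation null distribution.
#'
#' @slot results data.frame (region, rmseResidual, rmseGenotype, deltaRmse,
#'   pUnc, pFwe).
#' @slot nullSummary data.frame of null-distribution quantiles per region.
#' @slot config the [predictionConfig()] list used.
#' @aliases PredictionResult
#' @exportClass PredictionResult
setClass("PredictionResult", representation(
  results = "data.frame",
  nullSummary = "data.frame",
  config = "list"
))

#' Configuration of the synthetic-cohort generator
#'
#' Marginals and generative parameters for [simulateCohort()]; see
#' [cohortConfig()] for the calibrated defaults and the meaning of each slot.
#'
#' @slot n cohort size.
#' @slot sexCounts,petCounts,mriCounts integer pairs (reference, other).
#' @slot ageMean,ageSd,ageRange age distribution (years), truncated normal.
#' @slot carrierCounts named integer vector, carriers per variant.
#' @slot gamma named numeric, covariate effects on the latent factor
#'   (reference-region BP_ND units).
#' @slot delta data.frame of direct covariate-to-region effects.
#' @slot regionalMeans named numeric, reference-group region means at
#'   covariate means.
#' @slot regionalPct named numeric, planted percent difference per region for
#'   the MAOA carrier contrast (drives the loadings).
#' @slot lambda named numeric, factor loadings (reference region = 1).
#' @slot tau latent residual SD.
#' @slot adjustedSd named numeric, total covariate-adjusted SD per region.
#' @slot residCor named numeric, residual correlations for the three region
#'   pairs `caudate:putamen`, `amygdala:hippocampus`, `thalamus:midbrain`.
#' @aliases GeneratorConfig
#' @exportClass GeneratorConfig
setClass("GeneratorConfig", representation(
  n = "integer",
  sexCounts = "integer",
  petCounts = "integer",
  mriCounts = "integer",
  ageMean = "numeric",
  ageSd = "numeric",
  ageRange = "numeric",
  carrierCounts = "integer",
  gamma = "numeric",
  delta = "data.frame",
  regionalMeans = "numeric",
  regionalPct = "numeric",
  lambda = "numeric",
  tau = "numeric",
  adjustedSd = "numeric",
  residCor = "numeric"
))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  n <- object@n
  if (length(n) != 1L || n < 0L) msg <- c(msg, "n must be a single count >= 0")
  for (nm in c("sexCounts", "petCounts", "mriCounts")) {
    ct <- slot(object, nm)
    if (length(ct) != 2L || any(ct < 0L) || sum(ct) != n)
      msg <- c(msg, sprintf("%s must be two non-negative counts summing to n", nm))
  }
  if (!identical(sort(names(object@carrierCounts)), sort(genotypeNames())))
    msg <- c(msg, "carrierCounts must be named by the five variants")
  else if (any(object@carrierCounts < 0L) || any(object@carrierCounts > n))
    msg <- c(msg, "carrier counts must lie in [0, n]")
  if (object@ageSd <= 0) msg <- c(msg, "ageSd must be > 0")
  if (length(object@ageRange) != 2L || diff(object@ageRange) <= 0)
    msg <- c(msg, "ageRange must be an increasing pair")
  for (nm in c("regionalMeans", "regionalPct", "lambda", "adjustedSd")) {
    if (!identical(names(slot(object, nm)), regionNames()))
      msg <- c(msg, sprintf("%s must be named by the seven regions in order", nm))
  }
  if (!identical(sort(names(object@gamma)), sort(covariateNames())))
    msg <- c(msg, "gamma must be named by covariateNames()")
  if (any(object@adjustedSd <= 0)) msg <- c(msg, "adjustedSd must be > 0")
  if (object@tau < 0) msg <- c(msg, "tau must be >= 0")
  if (!length(msg)) {
    psi <- object@adjustedSd^2 - object@lambda^2 * object@tau^2
    if (any(psi <= 0))
      msg <- c(msg, paste0("implied residual variance non-positive for: ",
                           paste(names(psi)[psi <= 0], collapse = ", ")))
  }
  if (any(abs(object@residCor) >= 1))
    msg <- c(msg, "residual correlations must lie in (-1, 1)")
  if (length(msg)) msg else TRUE
})
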