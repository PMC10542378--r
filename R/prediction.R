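## Genotype prediction harness: residualization, repeated five-fold
## cross-validated random-forest RMSE, and permutation calibration.

#' Prediction harness configuration
#'
#' Defaults follow the harness contract: five folds, ten fold-assignment
#' resamples, forests of 500 trees with `max(1, floor(p/3))` candidate
#' features per split (1 for the five carrier features) and minimum
#' terminal-node size 5, and 10,000 permutations for the empirical null
#' (configure down for exploratory runs and tests). RMSE is pooled: squared
#' errors from the five held-out folds are combined before the root, giving
#' one RMSE per fold assignment, then averaged over resamples (`pooling =
#' "fold"` instead averages per-fold RMSEs).
#'
#' @param kFolds number of cross-validation folds.
#' @param nResamples fold-assignment resamples.
#' @param nTrees trees per forest.
#' @param mtry candidate features per split; `NULL` = `max(1, floor(p/3))`.
#' @param nodeSize minimum terminal-node size.
#' @param nPermutations permutations for the null distribution.
#' @param pooling `"pooled"` (default) or `"fold"`.
#' @return A named list used by [rfCvRmse()], [permutationTest()] and
#'   [predictRegions()].
#' @export
predictionConfig <- function(kFolds = 5L, nResamples = 10L, nTrees = 500L,
                             mtry = NULL, nodeSize = 5L,
                             nPermutations = 10000L,
                             pooling = c("pooled", "fold")) {
  pooling <- match.arg(pooling)
  stopifnot(kFolds >= 2L, nTrees >= 1L, nResamples >= 1L,
            nPermutations >= 1L, nodeSize >= 1L)
  list(kFolds = as.integer(kFolds), nResamples = as.integer(nResamples),
       nTrees = as.integer(nTrees), mtry = mtry,
       nodeSize = as.integer(nodeSize),
       nPermutations = as.integer(nPermutations), pooling = pooling)
}

.resolveMtry <- function(config, p) {
  if (!is.null(config$mtry)) as.integer(config$mtry)
  else max(1L, as.integer(floor(p / 3)))
}

#' Residualize a region against nuisance covariates
#'
#' OLS residuals of one region's BP_ND on centered age, sex and the two
#' scanner indicators: the covariate-adjusted outcome used by the
#' prediction models, and the null predictor whose RMSE the genotype
#' forests must beat.
#'
#' @param cohort a [BindingCohort-class].
#' @param region one of [regionNames()].
#' @return Numeric residual vector (mean zero, orthogonal to the design).
#' @export
residualizeRegion <- function(cohort, region) {
  stopifnot(is(cohort, "BindingCohort"))
  region <- match.arg(region, regionNames())
  X <- designMatrix(cohort)[, c("age", "sex", "pet", "mri"), drop = FALSE]
  y <- as.numeric(bpnd(cohort)[region, ])
  fit <- lm(y ~ X)
  if (anyNA(coef(fit))) stop("rank-deficient nuisance design")
  unname(resid(fit))
}

#' Root-mean-square of a residual vector
#'
#' The RMSE of the covariate-only null model, i.e. the root of the mean
#' squared residual.
#'
#' @param residuals numeric vector.
#' @return Scalar RMSE.
#' @examples
#' rmseResidual(c(3, -4))  # sqrt(12.5)
#' @export
rmseResidual <- function(residuals) {
  if (!length(residuals)) stop("empty residual vector")
  sqrt(mean(residuals^2))
}

.featureMatrix <- function(features) {
  X <- as.matrix(features)
  if (anyNA(X) || !all(X %in% c(0, 1)))
    stop("features must be binary 0/1 indicators")
  storage.mode(X) <- "integer"
  X
}

#' Cross-validated random-forest RMSE
#'
#' For each of `nResamples` random fold assignments, partitions the cohort
#' into `kFolds` folds, fits a random-forest regressor on the training
#' folds (bootstrap per tree, `mtry` candidate features per split) and
#' predicts the held-out fold; squared errors are pooled across folds into
#' one RMSE per assignment, and the mean over assignments is returned.
#'
#' @param features binary feature matrix (participants by carriers).
#' @param outcome numeric outcome (covariate-adjusted residuals).
#' @param config a [predictionConfig()].
#' @param seed optional integer seed.
#' @return List with `mean` (mean RMSE over resamples) and `perResample`.
#' @export
rfCvRmse <- function(features, outcome, config = predictionConfig(),
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- .featureMatrix(features)
  stopifnot(nrow(X) == length(outcome))
  mtry <- .resolveMtry(config, ncol(X))
  if (config$pooling == "pooled") {
    per <- .forestCvRmse(X, as.numeric(outcome), config$kFolds,
                         config$nResamples, config$nTrees, mtry,
                         config$nodeSize)
  } else {
    per <- vapply(seq_len(config$nResamples), function(r) {
      n <- length(outcome)
      perm <- sample.int(n)
      folds <- cut(seq_len(n), config$kFolds, labels = FALSE)
      mean(vapply(seq_len(config$kFolds), function(f) {
        test <- perm[folds == f]
        train <- perm[folds != f]
        pr <- .forestFitPredict(X[train, , drop = FALSE], outcome[train],
                                X[test, , drop = FALSE], config$nTrees,
                                mtry, config$nodeSize)
        sqrt(mean((outcome[test] - pr)^2))
      }, numeric(1)))
    }, numeric(1))
  }
  list(mean = mean(per), perResample = per)
}

#' Permutation test of genotype prediction performance
#'
#' Builds an empirical null by permuting the outcome vector and re-running
#' the complete cross-validation procedure (all folds and resamples) for
#' each permutation. The one-sided p-value asks whether the observed mean
#' RMSE is smaller (better) than expected by chance, with add-one
#' smoothing: `p = (1 + #\{null <= observed\}) / (B + 1)`.
#'
#' @inheritParams rfCvRmse
#' @return List with `pUnc`, `observed`, `null` (vector of B null mean
#'   RMSEs) and `nullSummary` (quantiles).
#' @export
permutationTest <- function(features, outcome, config = predictionConfig(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- .featureMatrix(features)
  stopifnot(nrow(X) == length(outcome))
  mtry <- .resolveMtry(config, ncol(X))
  observed <- rfCvRmse(X, outcome, config)$mean
  nullDist <- .forestPermNull(X, as.numeric(outcome),
                              config$nPermutations, config$kFolds,
                              config$nResamples, config$nTrees, mtry,
                              config$nodeSize)
  pUnc <- (1 + sum(nullDist <= observed)) / (config$nPermutations + 1)
  list(pUnc = pUnc, observed = observed, null = nullDist,
       nullSummary = c(mean = mean(nullDist), sd = sd(nullDist),
                       quantile(nullDist, c(0.025, 0.25, 0.5, 0.75, 0.975))))
}

#' Percent change in prediction RMSE
#'
#' `100 * (rmseResidual - rmseGenotype) / rmseResidual`: positive when the
#' genotype model improves on the covariate-only null.
#'
#' @param rmseResidual RMSE of the covariate-only null (must be > 0).
#' @param rmseGenotype cross-validated RMSE of the genotype model.
#' @return Percent change (scalar).
#' @examples
#' deltaRmse(0.266, 0.263)
#' deltaRmse(1.0, 1.1)  # degradation is negative
#' @export
deltaRmse <- function(rmseResidual, rmseGenotype) {
  if (rmseResidual <= 0) stop("rmseResidual must be positive")
  100 * (rmseResidual - rmseGenotype) / rmseResidual
}

#' Genotype prediction across all regions
#'
#' Runs the full prediction pipeline for each of the seven regions:
#' residualize against nuisance covariates, cross-validated genotype
#' random-forest RMSE, permutation p-value, and Holm adjustment of the
#' seven uncorrected p-values into family-wise `pFwe`.
#'
#' @param cohort a [BindingCohort-class].
#' @param config a [predictionConfig()].
#' @param seed optional integer seed governing folds, trees and
#'   permutations.
#' @return A [PredictionResult-class].
#' @examples
#' coh <- simulateCohort(cohortConfig(), seed = 4)
#' cfg <- predictionConfig(nResamples = 2, nTrees = 50, nPermutations = 39)
#' pr <- predictRegions(coh, cfg, seed = 1)
#' pr
#' @export
predictRegions <- function(cohort, config = predictionConfig(),
                           seed = NULL) {
  stopifnot(is(cohort, "BindingCohort"))
  if (!is.null(seed)) set.seed(seed)
  cd <- cohortCovariates(cohort)
  X <- .featureMatrix(cd[, genotypeNames(), drop = FALSE])
  rows <- lapply(regionNames(), function(r) {
    res <- residualizeRegion(cohort, r)
    rr <- rmseResidual(res)
    pt <- permutationTest(X, res, config)
    list(row = data.frame(region = r, rmseResidual = rr,
                          rmseGenotype = pt$observed,
                          deltaRmse = deltaRmse(rr, pt$observed),
                          pUnc = pt$pUnc, stringsAsFactors = FALSE),
         nullSummary = pt$nullSummary)
  })
  results <- do.call(rbind, lapply(rows, `[[`, "row"))
  results$pFwe <- holmAdjust(results$pUnc)
  nullSummary <- data.frame(region = regionNames(),
                            do.call(rbind, lapply(rows, `[[`, "nullSummary")),
                            check.names = FALSE, stringsAsFactors = FALSE)
  new("PredictionResult", results = results, nullSummary = nullSummary,
      config = config)
}

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf(
    "PredictionResult: %d regions, %d-fold CV x %d resamples, %d trees, %d permutations\n",
    nrow(object@results), object@config$kFolds, object@config$nResamples,
    object@config$nTrees, object@config$nPermutations))
  tab <- object@results
  tab[-1] <- lapply(tab[-1], signif, 3)
  print(tab, row.names = FALSE)
  invisible(NULL)
})
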