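## Per-region multiple regressions and percent differences.

#' Per-region regression of binding on genotypes and covariates
#'
#' Ordinary least squares of one region's BP_ND on the five carrier
#' indicators plus centered age, sex and the two scanner indicators, with
#' Wald 95% intervals. The covariate-adjusted reference mean is the fitted
#' value with all carrier indicators at 0, age at its sample mean and the
#' binary nuisance covariates at their sample proportions; percent
#' differences relate each carrier coefficient to that mean.
#'
#' @param cohort a [BindingCohort-class].
#' @param region one of [regionNames()].
#' @return List of class data (region, `model` (the `lm` fit),
#'   `coefficients` data.frame, `referenceMean`, `pctDiff` named by
#'   genotype).
#' @examples
#' coh <- simulateCohort(cohortConfig(), seed = 2)
#' fr <- fitRegional(coh, "caudate")
#' fr$pctDiff
#' @export
fitRegional <- function(cohort, region) {
  stopifnot(is(cohort, "BindingCohort"))
  region <- match.arg(region, regionNames())
  X <- designMatrix(cohort)
  y <- bpnd(cohort)[region, ]
  df <- data.frame(y = as.numeric(y), X, check.names = FALSE)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    keep <- covariateNames()[apply(X, 2L, function(v) length(unique(v)) > 1L)]
    dropped <- setdiff(covariateNames(), keep)
    warning("inestimable (constant) term(s): ", paste(dropped, collapse = ", "))
  }
  fit <- lm(stats::reformulate(covariateNames(), response = "y"), data = df)
  cf <- summary(fit)$coefficients
  z <- qnorm(0.975)
  coefs <- data.frame(
    term = rownames(cf),
    estimate = cf[, 1],
    se = cf[, 2],
    lower = cf[, 1] - z * cf[, 2],
    upper = cf[, 1] + z * cf[, 2],
    p = cf[, 4],
    row.names = NULL, stringsAsFactors = FALSE
  )
  beta <- coef(fit)
  ref <- c(1, rep(0, length(genotypeNames())),  # intercept, carriers at 0
           0,                                   # centered age at its mean
           mean(X[, "sex"]), mean(X[, "pet"]), mean(X[, "mri"]))
  names(ref) <- c("(Intercept)", covariateNames())
  b <- beta[names(ref)]
  b[is.na(b)] <- 0
  referenceMean <- sum(b * ref)
  pct <- vapply(genotypeNames(), function(g) {
    bg <- beta[[g]]
    if (is.na(bg)) return(NA_real_)
    if (referenceMean <= 0)
      stop("reference mean is non-positive; percent difference undefined")
    100 * bg / referenceMean
  }, numeric(1))
  list(region = region, model = fit, coefficients = coefs,
       referenceMean = referenceMean, pctDiff = pct)
}

#' Percent difference between genotype groups
#'
#' `100 * beta_genotype / referenceMean` from a [fitRegional()] fit: the
#' model-adjusted percent difference in regional BP_ND between the carrier
#' group and the homozygote reference group.
#'
#' @param fit result of [fitRegional()].
#' @param genotype one of [genotypeNames()].
#' @return Percent difference (scalar).
#' @examples
#' coh <- simulateCohort(cohortConfig(), seed = 2)
#' percentDifference(fitRegional(coh, "caudate"), "rs1137070")
#' @export
percentDifference <- function(fit, genotype) {
  genotype <- match.arg(genotype, genotypeNames())
  unname(fit$pctDiff[genotype])
}

#' @describeIn fitRegional fit every region; returns a data.frame with one
#'   row per region and genotype (estimate, CI, p, percent difference).
#' @export
fitAllRegions <- function(cohort) {
  out <- lapply(regionNames(), function(r) {
    fr <- fitRegional(cohort, r)
    co <- fr$coefficients
    co <- co[co$term %in% genotypeNames(), ]
    data.frame(region = r, genotype = co$term, estimate = co$estimate,
               se = co$se, lower = co$lower, upper = co$upper, p = co$p,
               referenceMean = fr$referenceMean,
               pctDiff = unname(fr$pctDiff[co$term]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
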