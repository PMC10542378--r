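threeRegionParams <- function() {
  list(nu = c(0.6, 0.8, 1.0), lambda = c(1, 0.8, 0.5),
       gamma = c(0.07, -0.01), delta = 0.1,
       psi = c(0.05, 0.06, 0.04), tau2 = 0.02, pairs = 0.01)
}

threeRegionSpec <- function() {
  lvmSpec(regions = c("caudate", "putamen", "midbrain"),
          covariates = c("rs1137070", "age"),
          directPaths = data.frame(covariate = "rs1137070",
                                   region = "putamen"),
          residualPairs = data.frame(region1 = "caudate",
                                     region2 = "putamen"))
}

test_that("implied moments follow the factor-model algebra", {
  spec <- lvmSpec(regions = c("caudate", "putamen"),
                  covariates = "rs1137070",
                  directPaths = data.frame(covariate = character(),
                                           region = character()),
                  residualPairs = data.frame(region1 = character(),
                                             region2 = character()))
  # no shared factor: diagonal covariance
  p0 <- list(nu = c(1, 2), lambda = c(1, 0.5), gamma = 0.1, delta = numeric(),
             psi = c(0.3, 0.4), tau2 = 0, pairs = numeric())
  m0 <- impliedMoments(spec, p0, c(rs1137070 = 1))
  expect_equal(unname(m0$Sigma), diag(c(0.3, 0.4)))
  expect_equal(unname(m0$mean), c(1.1, 2.05))

  # unit loadings, unit latent variance, no residuals: all-ones matrix
  p1 <- list(nu = c(0, 0), lambda = c(1, 1), gamma = 0, delta = numeric(),
             psi = c(0, 0), tau2 = 1, pairs = numeric())
  expect_equal(unname(impliedMoments(spec, p1, c(rs1137070 = 0))$Sigma),
               matrix(1, 2, 2))

  # arbitrary parameters against direct matrix arithmetic
  p2 <- list(nu = c(0.5, 0.7), lambda = c(1, 0.6), gamma = 0.2,
             delta = numeric(), psi = c(0.11, 0.07), tau2 = 0.09,
             pairs = numeric())
  m2 <- impliedMoments(spec, p2, c(rs1137070 = 1))
  oracle <- tcrossprod(c(1, 0.6)) * 0.09 + diag(c(0.11, 0.07))
  expect_equal(unname(m2$Sigma), oracle, tolerance = 1e-12)
  expect_equal(unname(m2$mean), c(0.5, 0.7) + c(1, 0.6) * 0.2,
               tolerance = 1e-12)
})

test_that("model log-likelihood equals a multivariate-normal density oracle", {
  coh <- makeTestCohort(5)
  spec <- threeRegionSpec()
  par <- threeRegionParams()
  ll <- lvmLogLik(coh, spec, par)
  X <- designMatrix(coh)
  Sigma <- impliedMoments(spec, par, c(rs1137070 = 0, age = 0))$Sigma
  oracle <- 0
  for (i in 1:5) {
    x <- X[i, c("rs1137070", "age")]
    mu <- impliedMoments(spec, par, x)$mean
    y <- bpnd(coh)[c("caudate", "putamen", "midbrain"), i]
    oracle <- oracle + dmvnormOracle(y, mu, Sigma)
  }
  expect_equal(ll, oracle, tolerance = 1e-9)
})

test_that("log-likelihood is exchangeable over participants and rejects non-PD covariance", {
  coh <- makeTestCohort(9)
  spec <- threeRegionSpec()
  par <- threeRegionParams()
  perm <- c(4, 1, 9, 2, 8, 3, 7, 5, 6)
  cohP <- BindingCohort(bpnd(coh)[, perm],
                        cbind(id = colnames(coh)[perm],
                              cohortCovariates(coh)[perm, ]))
  expect_equal(lvmLogLik(coh, spec, par), lvmLogLik(cohP, spec, par),
               tolerance = 1e-9)
  bad <- par
  bad$pairs <- 10  # far exceeds the component variances
  expect_error(lvmLogLik(coh, spec, bad), "positive definite")
})

test_that("analytic gradient matches central finite differences", {
  coh <- makeTestCohort(25)
  spec <- lvmSpec()
  idx <- httbind:::.lvmIndex(spec)
  dat <- httbind:::.lvmData(coh, spec)
  theta <- httbind:::.lvmStart(dat, spec, idx)
  ev <- httbind:::.lvmEval(theta, dat, idx)
  num <- vapply(seq_along(theta), function(k) {
    h <- 1e-6 * max(1, abs(theta[k]))
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    (httbind:::.lvmEval(tp, dat, idx, grad = FALSE)$f -
       httbind:::.lvmEval(tm, dat, idx, grad = FALSE)$f) / (2 * h)
  }, numeric(1))
  expect_equal(ev$g, num, tolerance = 1e-5)
})

test_that("single-region model reproduces ordinary least squares", {
  coh <- makeTestCohort(40, seed = 4)
  spec <- lvmSpec(regions = "caudate")
  fit <- fitLvm(coh, spec)
  X <- cbind(1, designMatrix(coh))
  beta <- olsOracle(X, as.numeric(bpnd(coh)["caudate", ]))
  est <- coef(fit)
  expect_equal(unname(est["nu.caudate"]), beta[1], tolerance = 1e-6)
  expect_equal(unname(est[paste0("latent.", covariateNames())]),
               beta[-1], tolerance = 1e-6)
  # ML residual variance is RSS / n
  res <- as.numeric(bpnd(coh)["caudate", ]) - X %*% beta
  expect_equal(unname(est["psi.caudate"]), sum(res^2) / 40, tolerance = 1e-6)
})

test_that("Wald intervals are estimate +/- z * se and p two-sided normal", {
  coh <- simulateCohort(cohortConfig(), seed = 41)
  fit <- fitLvm(coh)
  co <- fit@coefficients
  ok <- is.finite(co$se)
  z <- qnorm(0.975)
  expect_equal(co$lower[ok], co$estimate[ok] - z * co$se[ok], tolerance = 1e-12)
  expect_equal(co$upper[ok], co$estimate[ok] + z * co$se[ok], tolerance = 1e-12)
  expect_equal(co$p[ok], 2 * pnorm(-abs(co$estimate[ok] / co$se[ok])),
               tolerance = 1e-12)
})

test_that("planted effects are recovered at large n", {
  coh <- simulateCohort(scaledConfig(10000), seed = 51)
  fit <- fitLvm(coh)
  est <- coef(fit)
  expect_true(fit@converged)
  # absolute bounds of ~3 Monte-Carlo SEs at n = 10,000
  expect_lt(abs(est[["latent.rs1137070"]] - 0.07), 0.012)
  expect_lt(abs(est[["latent.age"]] + 0.009), 0.001)
  expect_lt(abs(est[["direct.sex->caudate"]] - 0.14), 0.014)
  expect_lt(abs(est[["latent.rs6265"]] + 0.06), 0.012)
  # loadings close to the generator calibration
  lam <- lvmParameters(fit)$lambda
  expect_lt(max(abs(lam - cohortConfig()@lambda)), 0.06)
})

test_that("an under-determined fit is rejected", {
  coh <- simulateCohort(scaledConfig(20), seed = 6)
  expect_error(fitLvm(coh), "cannot identify")
})

test_that("genotype-block LRT has 6 df, is zero under self-comparison, and matches the regression oracle", {
  coh <- simulateCohort(cohortConfig(), seed = 61)
  lrt <- lrtGenotypes(coh)
  expect_identical(lrt$df, 6L)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$p, pchisq(lrt$statistic, 6, lower.tail = FALSE),
               tolerance = 1e-12)

  # degenerate single-region case: the LRT equals the closed-form nested
  # Gaussian regression likelihood-ratio n * log(RSS0 / RSS1)
  spec1 <- lvmSpec(regions = "caudate")
  lrt1 <- lrtGenotypes(coh, spec1)
  X <- designMatrix(coh)
  y <- as.numeric(bpnd(coh)["caudate", ])
  rss <- function(M) {
    b <- olsOracle(M, y)
    sum((y - M %*% b)^2)
  }
  oracle <- 140 * log(rss(cbind(1, X[, c("age", "sex", "pet", "mri")])) /
                        rss(cbind(1, X)))
  expect_equal(lrt1$statistic, oracle, tolerance = 1e-4)
  expect_identical(lrt1$df, 5L)

  # identical models: statistic 0, p 1 (fit the reduced model both ways)
  red <- lvmSpec(covariates = c("age", "sex", "pet", "mri"),
                 directPaths = data.frame(covariate = "sex",
                                          region = "caudate"))
  f1 <- fitLvm(coh, red)
  f2 <- fitLvm(coh, red, restarts = 2L)
  expect_equal(2 * (f1@loglik - f2@loglik), 0, tolerance = 1e-4)
})
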