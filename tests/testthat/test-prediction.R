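featureFixture <- function(n, seed = 1) {
  set.seed(seed)
  matrix(rbinom(n * 5, 1, c(0.7, 0.75, 0.4, 0.45, 0.35)), n, 5,
         byrow = TRUE)
}

test_that("residualization is orthogonal to the nuisance design", {
  coh <- makeTestCohort(30, seed = 23)
  r <- residualizeRegion(coh, "caudate")
  X <- cbind(1, designMatrix(coh)[, c("age", "sex", "pet", "mri")])
  expect_lt(max(abs(crossprod(X, r))), 1e-10)
  expect_lt(abs(mean(r)), 1e-12)
  # oracle on a small instance
  y <- as.numeric(bpnd(coh)["caudate", ])
  expect_equal(r, as.numeric(y - X %*% olsOracle(X, y)), tolerance = 1e-9)
  # an outcome exactly linear in the covariates leaves zero residuals
  lin <- BindingCohort(
    matrix(rep(2 + 0.1 * cohortCovariates(coh)$age, each = 7), 7,
           dimnames = list(regionNames(), colnames(coh))),
    cbind(id = colnames(coh), cohortCovariates(coh)))
  expect_lt(max(abs(residualizeRegion(lin, "midbrain"))), 1e-10)
})

test_that("rmseResidual is the root mean square", {
  expect_identical(rmseResidual(rep(0, 5)), 0)
  expect_equal(rmseResidual(c(3, -4)), sqrt(12.5), tolerance = 1e-12)
  expect_error(rmseResidual(numeric()), "empty")
})

test_that("deltaRmse follows its defining formula", {
  expect_identical(deltaRmse(0.5, 0.5), 0)
  expect_equal(deltaRmse(0.266, 0.263), 100 * (0.266 - 0.263) / 0.266,
               tolerance = 1e-12)
  expect_equal(deltaRmse(1.0, 1.1), -10, tolerance = 1e-12)
  expect_error(deltaRmse(0, 1), "positive")
})

test_that("cross-validated RMSE is deterministic under seeding", {
  X <- featureFixture(60)
  y <- rnorm(60)
  cfg <- predictionConfig(nResamples = 3, nTrees = 60, nPermutations = 19)
  a <- rfCvRmse(X, y, cfg, seed = 9)
  b <- rfCvRmse(X, y, cfg, seed = 9)
  c <- rfCvRmse(X, y, cfg, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a$mean, c$mean))
  expect_equal(a$mean, mean(a$perResample), tolerance = 1e-12)
})

test_that("a noiseless single-feature signal is learned almost perfectly", {
  X <- featureFixture(80, seed = 3)
  y <- 2 * X[, 1]
  cfg <- predictionConfig(nResamples = 2, nTrees = 100, mtry = 5)
  out <- rfCvRmse(X, y, cfg, seed = 4)
  expect_lt(out$mean, 0.05 * sd(y))
})

test_that("pure-noise outcomes show no cross-validated improvement on average", {
  X <- featureFixture(50, seed = 5)
  cfg <- predictionConfig(nResamples = 1, nTrees = 30)
  set.seed(6)
  gap <- replicate(60, {
    y <- rnorm(50)
    rfCvRmse(X, y, cfg)$mean - rmseResidual(y - mean(y))
  })
  expect_gt(mean(gap), 0)
})

test_that("the in-repo forest agrees with the randomForest reference", {
  skip_if_not_installed("randomForest")
  set.seed(8)
  n <- 120
  X <- featureFixture(n, seed = 8)
  y <- 0.5 * X[, 1] - 0.3 * X[, 4] + rnorm(n, 0, 0.5)
  folds <- sample(rep(1:5, length.out = n))
  sse <- 0
  df <- data.frame(X)
  for (f in 1:5) {
    tr <- folds != f
    rf <- randomForest::randomForest(df[tr, ], y[tr], ntree = 500,
                                     mtry = 1, nodesize = 5)
    pr <- predict(rf, df[!tr, ])
    sse <- sse + sum((y[!tr] - pr)^2)
  }
  reference <- sqrt(sse / n)
  own <- rfCvRmse(X, y, predictionConfig(nResamples = 5, nTrees = 500),
                  seed = 9)$mean
  expect_equal(own, reference, tolerance = 0.06)
})

test_that("permutation p-value follows the add-one rank convention", {
  X <- featureFixture(50, seed = 11)
  y <- rnorm(50)
  cfg <- predictionConfig(nResamples = 1, nTrees = 25, nPermutations = 99)
  pt <- permutationTest(X, y, cfg, seed = 12)
  expect_equal(pt$pUnc, (1 + sum(pt$null <= pt$observed)) / 100,
               tolerance = 1e-12)
  expect_gt(pt$pUnc, 0)
  expect_lte(pt$pUnc, 1)
  expect_identical(length(pt$null), 99L)
})

test_that("a strong planted signal attains the minimum attainable p-value", {
  X <- featureFixture(100, seed = 13)
  y <- 2 * X[, 2] + rnorm(100, 0, 0.1)
  cfg <- predictionConfig(nResamples = 2, nTrees = 50, mtry = 5,
                          nPermutations = 199)
  pt <- permutationTest(X, y, cfg, seed = 14)
  expect_equal(pt$pUnc, 1 / 200, tolerance = 1e-12)
})

test_that("predictRegions reports all regions with Holm-adjusted p-values", {
  coh <- simulateCohort(cohortConfig(), seed = 15)
  cfg <- predictionConfig(nResamples = 2, nTrees = 40, nPermutations = 39)
  pr <- predictRegions(coh, cfg, seed = 16)
  res <- pr@results
  expect_identical(res$region, regionNames())
  expect_equal(res$pFwe, unname(holmAdjust(res$pUnc)), tolerance = 1e-12)
  # delta identity holds exactly on the stored unrounded values
  expect_equal(res$deltaRmse,
               100 * (res$rmseResidual - res$rmseGenotype) / res$rmseResidual,
               tolerance = 1e-12)
  # full determinism of the report under an identical invocation
  pr2 <- predictRegions(coh, cfg, seed = 16)
  expect_identical(pr@results, pr2@results)
})
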