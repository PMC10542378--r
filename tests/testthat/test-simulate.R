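test_that("marginal counts match the configuration exactly, every run", {
  cfg <- cohortConfig()
  for (s in 1:4) {
    coh <- simulateCohort(cfg, seed = s)
    cd <- cohortCovariates(coh)
    expect_identical(ncol(coh), 140L)
    expect_identical(sum(cd$sex == 0), 84L)
    expect_identical(sum(cd$sex == 1), 56L)
    expect_identical(sum(cd$pet == 1), 98L)
    expect_identical(sum(cd$mri == 1), 59L)
    expect_identical(sum(cd$rs1137070), 65L)
    expect_identical(sum(cd$rs6265), 50L)
    expect_identical(sum(cd$httlpr), 99L)
    expect_identical(sum(cd$rs6295), 107L)
    expect_identical(sum(cd$rs7333412), 53L)
    expect_true(all(cd$age >= 18 & cd$age <= 51))
  }
})

test_that("generation is deterministic under a fixed seed and varies across seeds", {
  a <- simulateCohort(cohortConfig(), seed = 12)
  b <- simulateCohort(cohortConfig(), seed = 12)
  c <- simulateCohort(cohortConfig(), seed = 13)
  expect_identical(bpnd(a), bpnd(b))
  expect_identical(cohortCovariates(a), cohortCovariates(b))
  expect_false(identical(bpnd(a), bpnd(c)))
})

test_that("degenerate configurations behave sensibly", {
  empty <- cohortConfig(n = 0, sexCounts = c(0, 0), petCounts = c(0, 0),
                        mriCounts = c(0, 0),
                        carrierCounts = c(httlpr = 0, rs6295 = 0,
                                          rs7333412 = 0, rs1137070 = 0,
                                          rs6265 = 0))
  coh <- simulateCohort(empty, seed = 1)
  expect_identical(ncol(coh), 0L)
  expect_identical(rownames(coh), regionNames())

  zeroCarrier <- scaledConfig(20)
  zeroCarrier@carrierCounts["rs6265"] <- 0L
  coh2 <- simulateCohort(zeroCarrier, seed = 2)
  expect_identical(sum(cohortCovariates(coh2)$rs6265), 0L)

  # mismatched counts and non-positive implied residual variances rejected
  expect_error(cohortConfig(n = 10, sexCounts = c(8, 4)), "summing to n")
  expect_error(cohortConfig(tau = 5), "non-positive")
})

test_that("noiseless null config returns the regional means exactly", {
  cfg <- scaledConfig(20, gamma = setNames(rep(0, 9), covariateNames()),
                      tau = 1e-8,
                      adjustedSd = setNames(rep(1e-6, 7), regionNames()),
                      delta = data.frame(covariate = character(),
                                         region = character(),
                                         value = numeric()))
  coh <- simulateCohort(cfg, seed = 3)
  mu <- cohortConfig()@regionalMeans
  expect_equal(as.numeric(bpnd(coh)), rep(mu, 20), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("implied covariance matches the empirical covariate-adjusted covariance at large n", {
  cfg <- scaledConfig(10000)
  coh <- simulateCohort(cfg, seed = 21)
  X <- cbind(1, designMatrix(coh))
  Y <- t(bpnd(coh))
  # regress out all covariates (genotypes included); remaining covariance
  # should approach lambda lambda' tau^2 + Psi (plus the direct paths'
  # contributions, removed by the regression since the paths are covariates)
  R <- Y - X %*% solve(crossprod(X), crossprod(X, Y))
  empCov <- crossprod(R) / (nrow(R) - 1)
  Sigma <- generatorParams(cfg)$Sigma
  expect_lt(max(abs(empCov - Sigma)), 0.012)
  # configured residual correlation for the caudate-putamen link
  par <- generatorParams(cfg)
  latentPart <- tcrossprod(par$lambda)[1, 2] * par$tau^2
  empResid <- empCov[1, 2] - latentPart
  rho <- empResid / sqrt(par$psi[1] * par$psi[2])
  expect_lt(abs(rho - 0.3), 0.035)  # ~3 Monte-Carlo SEs at n = 10,000
})

test_that("planted percent differences are recovered on a large cohort", {
  coh <- simulateCohort(scaledConfig(10000), seed = 31)
  fr <- fitRegional(coh, "caudate")
  expect_equal(percentDifference(fr, "rs1137070"), 11, tolerance = 2.5)
  frA <- fitRegional(coh, "amygdala")
  expect_equal(percentDifference(frA, "rs1137070"), 2, tolerance = 1.5)
})
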