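test_that("a saturated candidate universe yields an empty result", {
  spec <- lvmSpec(regions = c("caudate", "putamen"),
                  covariates = "rs1137070",
                  directPaths = data.frame(
                    covariate = c("rs1137070", "rs1137070"),
                    region = c("caudate", "putamen")),
                  residualPairs = data.frame(region1 = "caudate",
                                             region2 = "putamen"))
  expect_identical(nrow(httbind:::.candidatePaths(spec)), 0L)
})

test_that("the default candidate universe covers absent paths and covariances", {
  cand <- httbind:::.candidatePaths(lvmSpec())
  expect_identical(sum(cand$type == "direct"), 61L)
  expect_identical(sum(cand$type == "covariance"), 18L)
})

test_that("a planted extra direct path is found and BH-adjusted", {
  cfg <- scaledConfig(2000)
  cfg@delta <- rbind(cfg@delta,
                     data.frame(covariate = "age", region = "amygdala",
                                value = 0.02))
  coh <- simulateCohort(cfg, seed = 71)
  fit <- fitLvm(coh)
  sr <- pathSearch(fit, coh)
  cand <- sr@candidates
  hit <- cand[cand$type == "direct" & cand$from == "age" &
                cand$to == "amygdala", ]
  expect_identical(nrow(hit), 1L)
  expect_true(hit$added)
  expect_true(all(cand$pFdr >= cand$p - 1e-15, na.rm = TRUE))
  expect_equal(cand$pFdr[!is.na(cand$p)], bhAdjust(cand$p[!is.na(cand$p)]),
               tolerance = 1e-12)
})

test_that("score and Wald screening agree on the strongest candidate", {
  cfg <- scaledConfig(1000)
  cfg@delta <- rbind(cfg@delta,
                     data.frame(covariate = "mri", region = "thalamus",
                                value = 0.15))
  coh <- simulateCohort(cfg, seed = 72)
  fit <- fitLvm(coh)
  top <- function(sr) {
    cand <- sr@candidates
    cand[which.min(cand$p), c("type", "from", "to")]
  }
  sc <- pathSearch(fit, coh, method = "score")
  expect_identical(as.character(top(sc)), c("direct", "mri", "thalamus"))
  # Wald confirmation on the reduced universe is expensive; confirm the
  # score winner directly by refitting with the candidate added
  specE <- httbind:::.extendSpec(fit@spec, "direct", "mri", "thalamus")
  fitE <- fitLvm(coh, specE)
  co <- fitE@coefficients
  row <- co[co$term == "direct.mri->thalamus", ]
  expect_lt(row$p, 1e-4)
  expect_lt(abs(row$estimate - 0.15), 0.06)  # ~3.5 SEs at n = 1,000
})

test_that("null cohorts rarely add paths at FDR 0.05", {
  cfg <- cohortConfig(gamma = setNames(rep(0, 9), covariateNames()),
                      delta = data.frame(covariate = character(),
                                         region = character(),
                                         value = numeric()))
  set.seed(81)
  anyAdded <- vapply(1:25, function(i) {
    coh <- simulateCohort(cfg)
    fit <- fitLvm(coh)
    any(pathSearch(fit, coh)@candidates$added, na.rm = TRUE)
  }, logical(1))
  # under FDR control the per-replicate family-wise addition rate is near
  # 0.05; 10/25 would be a wild excursion (binomial P < 1e-4)
  expect_lte(sum(anyAdded), 9)
})
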