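test_that("triallelic 5-HTTLPR recoding follows the S' carrier definition", {
  expect_identical(recodeHttlpr(c("L", "L"), c("A", "A")), 0L)  # L_A L_A
  expect_identical(recodeHttlpr(c("L", "L"), c("A", "G")), 1L)  # carries L_G
  expect_identical(recodeHttlpr(c("L", "L"), c("G", "G")), 1L)
  expect_identical(recodeHttlpr(c("L", "S"), c("A", "A")), 1L)
  expect_identical(recodeHttlpr(c("S", "S"), c("A", "A")), 1L)
  expect_error(recodeHttlpr(c("S", "S"), c("A", "G")), "inconsistent")
  expect_error(recodeHttlpr(c("L", "X"), c("A", "A")), "illegal")
  expect_error(recodeHttlpr(c("L", NA), c("A", "A")), "missing")
})

test_that("carrier dichotomization is total on legal inputs and rejects the rest", {
  expect_identical(carrierIndicator("rs1137070", c("C", "T")), 1L)
  expect_identical(carrierIndicator("rs1137070", c("T", "T")), 1L)
  expect_identical(carrierIndicator("rs1137070", c("C", "C")), 0L)
  expect_identical(carrierIndicator("rs1137070", "T"), 1L)  # hemizygous male
  expect_identical(carrierIndicator("rs1137070", "C"), 0L)
  expect_identical(carrierIndicator("rs6265", c("G", "A")), 1L)  # met-carrier
  expect_identical(carrierIndicator("rs6265", c("G", "G")), 0L)
  expect_identical(carrierIndicator("rs6295", c("C", "G")), 1L)
  expect_identical(carrierIndicator("rs6295", c("C", "C")), 0L)
  expect_identical(carrierIndicator("rs7333412", c("A", "G")), 1L)
  expect_identical(carrierIndicator("rs7333412", c("A", "A")), 0L)
  expect_error(carrierIndicator("rs9999", c("A", "A")), "unknown variant")
  expect_error(carrierIndicator("rs6265", "A"), "autosomal")
  expect_error(carrierIndicator("rs6265", c("G", NA)), "missing")
  expect_error(carrierIndicator("rs6295", c("A", "G")), "illegal")
})

test_that("Hardy-Weinberg test matches the Pearson statistic and chi-square tail", {
  exact <- hweTest(81, 18, 1)  # exact HWE proportions at q = 0.1
  expect_equal(exact$statistic, 0, tolerance = 1e-12)
  expect_equal(exact$p, 1)

  extreme <- hweTest(50, 0, 50)  # total heterozygote deficit
  expect_equal(extreme$statistic, 100, tolerance = 1e-10)
  expect_lt(extreme$p, 1e-20)

  mid <- hweTest(30, 60, 10)  # expected 36/48/16 at q = 0.4
  expect_equal(mid$statistic, 6.25, tolerance = 1e-10)
  expect_equal(mid$p, chisqPOracle(6.25), tolerance = 1e-8)
  expect_equal(mid$p, 0.0124, tolerance = 1e-2)

  expect_warning(mono <- hweTest(70, 0, 0), "monomorphic")
  expect_equal(mono$p, 1)
  expect_error(hweTest(0, 0, 0), "no genotyped")
})

test_that("hweTest p equals the chi-square survival function (integration oracle)", {
  cases <- list(c(40, 45, 15), c(12, 30, 8), c(90, 9, 1))
  for (cc in cases) {
    res <- hweTest(cc[1], cc[2], cc[3])
    expect_equal(res$p, chisqPOracle(res$statistic), tolerance = 1e-7)
  }
})

test_that("X-linked allele test matches a hand-computed 2x2 Pearson chi-square", {
  eq <- xLinkedFreqTest(c(10, 10), c(50, 50))
  expect_equal(eq$statistic, 0, tolerance = 1e-12)
  expect_equal(eq$p, 1)

  res <- xLinkedFreqTest(c(40, 16), c(100, 62))
  stat <- pearson2x2Oracle(rbind(c(40, 16), c(100, 62)))
  expect_equal(res$statistic, stat, tolerance = 1e-10)
  expect_equal(res$p, chisqPOracle(stat), tolerance = 1e-8)

  expect_lt(xLinkedFreqTest(c(20, 0), c(0, 40))$p, 1e-10)
  expect_error(xLinkedFreqTest(c(0, 0), c(10, 10)), "zero alleles")
})

test_that("X-linked test is symmetric in sexes and allele labels", {
  m <- c(31, 12); f <- c(80, 55)
  a <- xLinkedFreqTest(m, f)
  expect_equal(a$p, xLinkedFreqTest(f, m)$p, tolerance = 1e-12)
  expect_equal(a$p, xLinkedFreqTest(rev(m), rev(f))$p, tolerance = 1e-12)
})
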