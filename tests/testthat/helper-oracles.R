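# Independent oracles: deliberately different code paths from the package
# (determinant/mahalanobis instead of Cholesky, explicit normal equations,
# numeric integration instead of pchisq, hand-written Pearson formula).

dmvnormOracle <- function(x, mu, Sigma) {
  d <- length(mu)
  md <- stats::mahalanobis(matrix(x, nrow = 1), mu, Sigma)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  -0.5 * (d * log(2 * pi) + ld + md)
}

olsOracle <- function(X, y) {
  as.numeric(solve(crossprod(X), crossprod(X, y)))
}

chisqPOracle <- function(stat, df = 1) {
  stats::integrate(function(z) stats::dchisq(z, df), lower = stat,
                   upper = Inf, rel.tol = 1e-10)$value
}

pearson2x2Oracle <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - e)^2 / e)
}

# deterministic hand-built cohort, independent of the package generator
makeTestCohort <- function(n = 12, seed = 99) {
  set.seed(seed)
  cov <- data.frame(
    id = paste0("p", seq_len(n)),
    age = round(runif(n, 20, 45), 1),
    sex = rep_len(c(0L, 1L), n),
    pet = rep_len(c(0L, 0L, 1L), n),
    mri = rbinom(n, 1, 0.45),
    httlpr = rbinom(n, 1, 0.7),
    rs6295 = rbinom(n, 1, 0.75),
    rs7333412 = rbinom(n, 1, 0.4),
    rs1137070 = rbinom(n, 1, 0.45),
    rs6265 = rbinom(n, 1, 0.35)
  )
  bp <- matrix(rnorm(7 * n, mean = rep(c(0.6, 0.8, 1.1, 1.1, 0.5, 0.8, 0.25),
                                       n), sd = 0.2),
               nrow = 7, dimnames = list(regionNames(), cov$id))
  BindingCohort(bp, cov)
}

# small-but-identifiable simulated cohorts for model tests
scaledConfig <- function(n, ...) {
  frac <- n / 140
  cohortConfig(
    n = n,
    sexCounts = c(n - round(56 * frac), round(56 * frac)),
    petCounts = c(round(42 * frac), n - round(42 * frac)),
    mriCounts = c(round(81 * frac), n - round(81 * frac)),
    carrierCounts = round(c(httlpr = 99, rs6295 = 107, rs7333412 = 53,
                            rs1137070 = 65, rs6265 = 50) * frac),
    ...
  )
}
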