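## Carrier-model recoding and genotype-level QC.
##
## Grouping conventions (indicator 1 = carrier group, 0 = homozygote
## reference):
##   5-HTTLPR + triallelic SNP: S'-carriers (>=1 S or >=1 L_G) vs L_A/L_A
##   rs6295:    G-carriers vs CC;   rs7333412: G-carriers vs AA
##   rs1137070: T-carriers vs CC (X-linked; hemizygous males carry one allele)
##   rs6265:    met(A)-carriers vs val/val (G/G)
## The triallelic SNP adjacent to 5-HTTLPR is known under the aliases rs25531
## and rs23351; it is treated as a single A/G locus whose G allele occurs
## only on L backgrounds (L_G).

.carrierAllele <- c(rs6265 = "A", rs6295 = "G", rs7333412 = "G",
                    rs1137070 = "T")
.alphabet <- list(rs6265 = c("G", "A"), rs6295 = c("C", "G"),
                  rs7333412 = c("A", "G"), rs1137070 = c("C", "T"),
                  httlpr = c("L", "S"), httlpr_snp = c("A", "G"))

.checkAlleles <- function(variant, alleles) {
  ok <- .alphabet[[variant]]
  if (is.null(ok)) stop("unknown variant: ", variant)
  bad <- setdiff(alleles, ok)
  if (length(bad))
    stop(sprintf("illegal allele(s) %s for %s (expected %s)",
                 paste(bad, collapse = ","), variant,
                 paste(ok, collapse = "/")))
  invisible(TRUE)
}

#' Triallelic 5-HTTLPR carrier recoding
#'
#' Collapses the biallelic 5-HTTLPR insertion/deletion (L/S) together with
#' the adjacent A/G SNP into the functional S' grouping: the G allele occurs
#' only on L backgrounds and renders that L allele (L_G) functionally
#' S-like, so a participant is an S'-carrier iff the diplotype contains at
#' least one S or one L_G allele. The homozygote reference group is
#' L_A/L_A.
#'
#' @param lpr character vector of two L/S alleles (e.g. `c("L","S")`).
#' @param snp character vector of two A/G alleles of the triallelic SNP.
#' @return Integer 1 (S'-carrier) or 0 (L_A/L_A).
#' @examples
#' recodeHttlpr(c("L", "L"), c("A", "A"))  # 0: L_A L_A
#' recodeHttlpr(c("L", "L"), c("A", "G"))  # 1: carries L_G
#' recodeHttlpr(c("S", "S"), c("A", "A"))  # 1: two S alleles
#' @export
recodeHttlpr <- function(lpr, snp) {
  if (length(lpr) != 2L || length(snp) != 2L)
    stop("lpr and snp must each supply two alleles")
  if (anyNA(lpr) || anyNA(snp)) stop("missing 5-HTTLPR alleles are rejected")
  .checkAlleles("httlpr", lpr)
  .checkAlleles("httlpr_snp", snp)
  nL <- sum(lpr == "L")
  nG <- sum(snp == "G")
  if (nG > nL)
    stop("inconsistent haplotype: triallelic G allele on an S background")
  as.integer(any(lpr == "S") || nG > 0L)
}

#' Carrier-model dichotomization of a biallelic variant
#'
#' Returns 1 if the genotype carries at least one copy of the variant's
#' carrier allele (rs6265: A/met; rs6295: G; rs7333412: G; rs1137070: T),
#' else 0. rs1137070 is X-linked: hemizygous males supply a single allele
#' and are carriers iff that allele is T.
#'
#' @param variant one of `"rs6265"`, `"rs6295"`, `"rs7333412"`,
#'   `"rs1137070"`.
#' @param alleles character vector of two alleles, or a single allele for a
#'   hemizygous male at rs1137070.
#' @return Integer carrier indicator.
#' @examples
#' carrierIndicator("rs1137070", c("C", "T"))  # 1: T-carrier
#' carrierIndicator("rs1137070", c("C", "C"))  # 0
#' carrierIndicator("rs1137070", "T")          # 1: hemizygous carrier
#' @export
carrierIndicator <- function(variant, alleles) {
  if (!variant %in% names(.carrierAllele))
    stop("unknown variant: ", variant)
  if (anyNA(alleles) || !length(alleles))
    stop("missing genotype for ", variant, " is rejected")
  if (length(alleles) == 1L && variant != "rs1137070")
    stop(variant, " is autosomal: two alleles required")
  if (length(alleles) > 2L) stop("at most two alleles")
  .checkAlleles(variant, alleles)
  as.integer(any(alleles == .carrierAllele[[variant]]))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson one-degree-of-freedom goodness-of-fit test of the observed
#' genotype counts against Hardy-Weinberg expectations at the sample allele
#' frequency, without continuity correction. For the X-linked rs1137070 use
#' female genotypes only.
#'
#' @param nHomRef,nHet,nHomAlt non-negative genotype counts.
#' @return List with `statistic`, `df` (= 1) and `p`. A monomorphic sample
#'   yields p = 1 with a warning.
#' @examples
#' hweTest(81, 18, 1)    # exact HWE proportions: p = 1
#' hweTest(30, 60, 10)   # chi-square 6.25
#' @export
hweTest <- function(nHomRef, nHet, nHomAlt) {
  counts <- c(nHomRef, nHet, nHomAlt)
  if (length(counts) != 3L || anyNA(counts) || any(counts < 0))
    stop("three non-negative genotype counts required")
  n <- sum(counts)
  if (n == 0) stop("no genotyped individuals")
  q <- (nHet + 2 * nHomAlt) / (2 * n)  # alt allele frequency
  if (q == 0 || q == 1) {
    warning("monomorphic sample: Hardy-Weinberg test undefined, p set to 1")
    return(list(statistic = 0, df = 1L, p = 1))
  }
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat, df = 1L,
       p = pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' X-linked male-versus-female allele-frequency test
#'
#' 2x2 Pearson chi-square test (no continuity correction) of allele-frequency
#' homogeneity between hemizygous males (one allele each) and females (two
#' alleles each), as used for the X-linked MAOA rs1137070.
#'
#' @param maleAlleles,femaleAlleles length-2 vectors of allele counts
#'   (reference, alternative).
#' @return List with `statistic`, `df` (= 1) and `p`.
#' @examples
#' xLinkedFreqTest(c(10, 10), c(50, 50))  # identical frequencies: p = 1
#' xLinkedFreqTest(c(40, 16), c(100, 62))
#' @export
xLinkedFreqTest <- function(maleAlleles, femaleAlleles) {
  if (length(maleAlleles) != 2L || length(femaleAlleles) != 2L)
    stop("allele counts must be length-2 (reference, alternative)")
  if (sum(maleAlleles) == 0 || sum(femaleAlleles) == 0)
    stop("zero alleles in one sex")
  tab <- rbind(male = maleAlleles, female = femaleAlleles)
  if (any(colSums(tab) == 0)) {
    warning("monomorphic across both sexes: p set to 1")
    return(list(statistic = 0, df = 1L, p = 1))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = 1L, p = unname(ct$p.value))
}
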