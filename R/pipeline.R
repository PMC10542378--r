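## One-command reproduction of the full two-arm analysis on a cohort.

#' Run the complete analysis
#'
#' Executes, in order: genotype QC (Hardy-Weinberg per autosomal variant and
#' the X-linked male-versus-female allele comparison, when raw genotypes are
#' supplied), the latent-variable model fit, the FDR-controlled path
#' search, the genotype-block likelihood-ratio test, the per-region
#' regressions with percent differences, and the seven-region genotype
#' prediction harness. All randomness flows from `seed`.
#'
#' QC needs genotype counts, which carrier indicators alone cannot provide;
#' pass `rawGenotypes` (a data.frame with columns `variant`, `nHomRef`,
#' `nHet`, `nHomAlt`, plus optionally `maleRef`/`maleAlt` for rs1137070) to
#' include it, otherwise the QC block is `NULL`.
#'
#' @param cohort a [BindingCohort-class].
#' @param seed integer root seed recorded in the provenance block.
#' @param spec an [LvmSpec-class].
#' @param predConfig a [predictionConfig()].
#' @param rawGenotypes optional genotype-count table for QC (see above).
#' @return List of class `AnalysisReport` with components `qc`, `lvm`,
#'   `pathSearch`, `lrt`, `regional`, `prediction`, `provenance`.
#' @examples
#' coh <- simulateCohort(cohortConfig(), seed = 9)
#' rep <- runFullAnalysis(coh, seed = 9,
#'                        predConfig = predictionConfig(nResamples = 2,
#'                                                      nTrees = 50,
#'                                                      nPermutations = 19))
#' rep$lrt[c("statistic", "df", "p")]
#' @export
runFullAnalysis <- function(cohort, seed = 1L, spec = lvmSpec(),
                            predConfig = predictionConfig(),
                            rawGenotypes = NULL) {
  stopifnot(is(cohort, "BindingCohort"))
  set.seed(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  qc <- NULL
  if (!is.null(rawGenotypes)) {
    qc <- stage("qc", {
      rows <- lapply(seq_len(nrow(rawGenotypes)), function(i) {
        g <- rawGenotypes[i, ]
        hw <- hweTest(g$nHomRef, g$nHet, g$nHomAlt)
        data.frame(variant = g$variant, hweStatistic = hw$statistic,
                   hweP = hw$p, stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, rows)
      xrow <- rawGenotypes[rawGenotypes$variant == "rs1137070", ]
      if (nrow(xrow) == 1L && !is.null(xrow$maleRef) &&
          !is.na(xrow$maleRef)) {
        xt <- xLinkedFreqTest(
          c(xrow$maleRef, xrow$maleAlt),
          c(2 * xrow$nHomRef + xrow$nHet, 2 * xrow$nHomAlt + xrow$nHet))
        attr(out, "xLinked") <- xt
      }
      out
    })
  }
  fit <- stage("lvm", fitLvm(cohort, spec))
  search <- stage("pathSearch", pathSearch(fit, cohort))
  lrt <- stage("lrt", lrtGenotypes(cohort, spec))
  regional <- stage("regional", fitAllRegions(cohort))
  prediction <- stage("prediction", predictRegions(cohort, predConfig))
  report <- list(
    qc = qc,
    lvm = fit,
    pathSearch = search,
    lrt = lrt[c("statistic", "df", "p")],
    regional = regional,
    prediction = prediction,
    provenance = list(
      seed = seed,
      n = ncol(cohort),
      package = as.character(utils::packageVersion("httbind")),
      rVersion = R.version.string
    )
  )
  class(report) <- "AnalysisReport"
  report
}

#' @export
print.AnalysisReport <- function(x, ...) {
  cat("== Analysis report (n =", x$provenance$n, ", seed =",
      x$provenance$seed, ") ==\n")
  if (!is.null(x$qc)) {
    cat("-- Genotype QC --\n")
    print(x$qc, row.names = FALSE)
  }
  cat("-- Latent-variable model --\n")
  show(x$lvm)
  cat("-- Path search --\n")
  show(x$pathSearch)
  cat(sprintf("-- Genotype-block LRT: chi2 = %.3f, df = %d, p = %.4g --\n",
              x$lrt$statistic, x$lrt$df, x$lrt$p))
  cat("-- Regional percent differences (MAOA rs1137070 carriers) --\n")
  maoa <- x$regional[x$regional$genotype == "rs1137070",
                     c("region", "estimate", "pctDiff", "p")]
  maoa[-1] <- lapply(maoa[-1], signif, 3)
  print(maoa, row.names = FALSE)
  cat("-- Genotype prediction --\n")
  show(x$prediction)
  invisible(x)
}

#' Write an analysis report to JSON
#'
#' Serialises the numerical content of [runFullAnalysis()] output (QC,
#' model coefficients, path-search candidates, LRT, regional table,
#' prediction table and provenance) to a JSON file.
#'
#' @param report an `AnalysisReport`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeReport <- function(report, path) {
  stopifnot(inherits(report, "AnalysisReport"))
  out <- list(
    qc = report$qc,
    lvm = list(coefficients = report$lvm@coefficients,
               loglik = report$lvm@loglik,
               nobs = report$lvm@nobs,
               converged = report$lvm@converged),
    pathSearch = report$pathSearch@candidates,
    lrt = report$lrt,
    regional = report$regional,
    prediction = list(results = report$prediction@results,
                      nullSummary = report$prediction@nullSummary),
    provenance = report$provenance
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
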