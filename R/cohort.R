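#' Construct a BindingCohort
#'
#' Builds a [BindingCohort-class] from a region-by-participant matrix of
#' BP_ND values and a per-participant covariate table. Sex, scanner and
#' carrier columns may be given either as 0/1 integers or as the file codes
#' (`F`/`M`, `A`/`H`, `T`/`V`); they are stored internally as 0/1 with
#' female, GE-Advance ("A") and Trio ("T") as the zero level. Age is stored
#' in raw years; model-fitting functions mean-center it.
#'
#' @param bpnd numeric matrix, 7 regions (rows, named as [regionNames()]) by
#'   n participants.
#' @param covariates data.frame with columns `age`, `sex`, `pet`, `mri` and
#'   the five carrier indicators; optional column `id` supplies participant
#'   names.
#' @return A validated [BindingCohort-class].
#' @examples
#' cfg <- cohortConfig(n = 12, sexCounts = c(8, 4), petCounts = c(4, 8),
#'                     mriCounts = c(7, 5),
#'                     carrierCounts = c(httlpr = 8, rs6295 = 9,
#'                                       rs7333412 = 5, rs1137070 = 6,
#'                                       rs6265 = 4))
#' coh <- simulateCohort(cfg, seed = 1)
#' coh
#' @export
BindingCohort <- function(bpnd, covariates) {
  bpnd <- as.matrix(bpnd)
  covariates <- as.data.frame(covariates)
  if (nrow(bpnd) != length(regionNames()))
    stop("bpnd must have one row per region (", length(regionNames()), ")")
  if (is.null(rownames(bpnd))) rownames(bpnd) <- regionNames()
  if (!identical(sort(rownames(bpnd)), sort(regionNames())))
    stop("bpnd rownames must be the seven canonical regions")
  bpnd <- bpnd[regionNames(), , drop = FALSE]
  if (ncol(bpnd) != nrow(covariates))
    stop("bpnd columns and covariate rows disagree")
  ids <- if ("id" %in% names(covariates)) as.character(covariates$id)
         else colnames(bpnd)
  if (is.null(ids)) ids <- if (nrow(covariates)) paste0("s", seq_len(nrow(covariates))) else character()
  if (anyDuplicated(ids)) stop("duplicate participant ids")
  covariates$id <- NULL
  covariates$sex <- .recodeBinary(covariates$sex, "F", "M", "sex")
  covariates$pet <- .recodeBinary(covariates$pet, "A", "H", "pet")
  covariates$mri <- .recodeBinary(covariates$mri, "T", "V", "mri")
  for (g in genotypeNames()) {
    if (is.null(covariates[[g]])) stop("missing covariate column: ", g)
    covariates[[g]] <- .recodeBinary(covariates[[g]], "0", "1", g)
  }
  colnames(bpnd) <- ids
  cd <- S4Vectors::DataFrame(covariates, row.names = ids)
  se <- SummarizedExperiment(assays = list(bpnd = bpnd), colData = cd)
  new("BindingCohort", se)
}

.recodeBinary <- function(x, zero, one, what) {
  if (is.null(x)) stop("missing covariate column: ", what)
  if (is.numeric(x)) {
    if (anyNA(x) || !all(x %in% c(0, 1)))
      stop("column '", what, "' must be 0/1 (or coded ",
           zero, "/", one, ")")
    return(as.integer(x))
  }
  x <- as.character(x)
  if (anyNA(x) || !all(x %in% c(zero, one)))
    stop("column '", what, "' must be coded ", zero, "/", one)
  as.integer(x == one)
}

#' @describeIn BindingCohort the region-by-participant BP_ND matrix.
#' @param x a `BindingCohort`.
#' @export
bpnd <- function(x) assay(x, "bpnd")

#' @describeIn BindingCohort participant-by-covariate data.frame (internal
#'   0/1 coding, age in years).
#' @export
cohortCovariates <- function(x) as.data.frame(colData(x))

#' Model design matrix for a cohort
#'
#' Participant-by-covariate numeric matrix in the order of
#' [covariateNames()], with age mean-centered (the coding used by all model
#' fits).
#'
#' @param cohort a [BindingCohort-class].
#' @return Numeric matrix with one column per covariate.
#' @export
designMatrix <- function(cohort) {
  cd <- cohortCovariates(cohort)
  X <- cbind(
    vapply(genotypeNames(), function(g) as.numeric(cd[[g]]), numeric(nrow(cd))),
    age = cd$age - mean(cd$age),
    sex = as.numeric(cd$sex),
    pet = as.numeric(cd$pet),
    mri = as.numeric(cd$mri)
  )
  colnames(X) <- covariateNames()
  rownames(X) <- rownames(cd)
  X
}

setMethod("show", "BindingCohort", function(object) {
  cat(sprintf("BindingCohort: %d participants, %d regions\n",
              ncol(object), nrow(object)))
  if (ncol(object)) {
    cd <- colData(object)
    cat(sprintf("  sex F/M: %d/%d | PET A/H: %d/%d | MRI T/V: %d/%d\n",
                sum(cd$sex == 0), sum(cd$sex == 1),
                sum(cd$pet == 0), sum(cd$pet == 1),
                sum(cd$mri == 0), sum(cd$mri == 1)))
    carr <- vapply(genotypeNames(), function(g) sum(cd[[g]]), integer(1))
    cat("  carriers:", paste(sprintf("%s=%d", names(carr), carr),
                             collapse = " "), "\n")
    cat(sprintf("  age: mean %.1f, range %.0f-%.0f\n",
                mean(cd$age), min(cd$age), max(cd$age)))
  }
  invisible(NULL)
})

#' Read or write a cohort file
#'
#' The cohort file is a CSV (or TSV) with one row per participant and
#' columns `id`, `age`, `sex` (F/M), `pet` (A/H), `mri` (T/V), the five
#' genotype columns and the seven region columns in canonical order.
#' Genotype columns may hold either carrier indicators (0/1) or raw
#' genotypes as slash-separated alleles (e.g. `G/A`; a single allele for
#' hemizygous males at rs1137070), with the 5-HTTLPR raw form using the two
#' columns `httlpr` (L/S alleles) and `httlpr_snp` (A/G alleles of the
#' triallelic SNP). Raw genotypes are recoded to carrier indicators on read
#' via [recodeHttlpr()] and [carrierIndicator()].
#'
#' @param path file path.
#' @param sep field separator (`","` for CSV, `"\t"` for TSV).
#' @return `readCohort` returns a [BindingCohort-class]; `writeCohort`
#'   invisibly returns `path`.
#' @export
readCohort <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  required <- c("id", "age", "sex", "pet", "mri", regionNames())
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cohort file missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$id)) stop("duplicate participant ids")
  for (r in regionNames()) {
    if (anyNA(df[[r]]) || !is.numeric(df[[r]]))
      stop("region column '", r, "' must be numeric and complete")
  }
  geno <- .recodeGenotypeColumns(df)
  cov <- data.frame(id = as.character(df$id), age = as.numeric(df$age),
                    sex = df$sex, pet = df$pet, mri = df$mri, geno,
                    check.names = FALSE)
  bp <- t(as.matrix(df[, regionNames(), drop = FALSE]))
  colnames(bp) <- as.character(df$id)
  BindingCohort(bp, cov)
}

.recodeGenotypeColumns <- function(df) {
  n <- nrow(df)
  isRaw <- function(col) is.character(df[[col]]) &&
    any(grepl("/", df[[col]], fixed = TRUE) | nchar(df[[col]]) == 1L &
          !df[[col]] %in% c("0", "1"))
  split2 <- function(x) strsplit(as.character(x), "/", fixed = TRUE)
  out <- list()
  for (g in genotypeNames()) {
    if (is.null(df[[g]])) stop("cohort file missing column(s): ", g)
    if (g == "httlpr" && isRaw("httlpr")) {
      if (is.null(df$httlpr_snp))
        stop("raw 5-HTTLPR genotypes require the 'httlpr_snp' column")
      lpr <- split2(df$httlpr); snp <- split2(df$httlpr_snp)
      out[[g]] <- vapply(seq_len(n), function(i)
        recodeHttlpr(lpr[[i]], snp[[i]]), integer(1))
    } else if (g != "httlpr" && isRaw(g)) {
      al <- split2(df[[g]])
      out[[g]] <- vapply(seq_len(n), function(i)
        carrierIndicator(g, al[[i]]), integer(1))
    } else {
      out[[g]] <- .recodeBinary(df[[g]], "0", "1", g)
    }
  }
  out <- lapply(out, as.integer)
  structure(as.data.frame(out, check.names = FALSE),
            names = genotypeNames())
}

#' @rdname readCohort
#' @param cohort a [BindingCohort-class].
#' @export
writeCohort <- function(cohort, path, sep = ",") {
  stopifnot(is(cohort, "BindingCohort"))
  cd <- cohortCovariates(cohort)
  df <- data.frame(
    id = colnames(cohort),
    age = cd$age,
    sex = c("F", "M")[cd$sex + 1L],
    pet = c("A", "H")[cd$pet + 1L],
    mri = c("T", "V")[cd$mri + 1L],
    check.names = FALSE
  )
  for (g in genotypeNames()) df[[g]] <- cd[[g]]
  bp <- t(bpnd(cohort))
  for (r in regionNames()) df[[r]] <- unname(bp[, r])
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
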