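## Model-path search and genotype-block likelihood-ratio test.

.extendSpec <- function(spec, type, from, to) {
  if (type == "direct") {
    dp <- rbind(spec@directPaths,
                data.frame(covariate = from, region = to,
                           stringsAsFactors = FALSE))
    new("LvmSpec", regions = spec@regions, covariates = spec@covariates,
        referenceRegion = spec@referenceRegion, directPaths = dp,
        residualPairs = spec@residualPairs)
  } else {
    rp <- rbind(spec@residualPairs,
                data.frame(region1 = from, region2 = to,
                           stringsAsFactors = FALSE))
    new("LvmSpec", regions = spec@regions, covariates = spec@covariates,
        referenceRegion = spec@referenceRegion,
        directPaths = spec@directPaths, residualPairs = rp)
  }
}

.candidatePaths <- function(spec) {
  have <- paste(spec@directPaths$covariate, spec@directPaths$region)
  direct <- expand.grid(from = spec@covariates, to = spec@regions,
                        stringsAsFactors = FALSE)
  direct <- direct[!paste(direct$from, direct$to) %in% have, , drop = FALSE]
  out <- if (nrow(direct))
    data.frame(type = "direct", direct, stringsAsFactors = FALSE)
  else
    data.frame(type = character(), from = character(), to = character(),
               stringsAsFactors = FALSE)
  if (length(spec@regions) >= 2L) {
    pairs <- t(utils::combn(spec@regions, 2L))
    haveP <- c(paste(spec@residualPairs$region1, spec@residualPairs$region2),
               paste(spec@residualPairs$region2, spec@residualPairs$region1))
    keep <- !paste(pairs[, 1], pairs[, 2]) %in% haveP
    if (any(keep))
      out <- rbind(out, data.frame(type = "covariance",
                                   from = pairs[keep, 1],
                                   to = pairs[keep, 2],
                                   stringsAsFactors = FALSE))
  }
  out
}

## observed information of the null fit (natural scale), via central
## differences of the analytic gradient
.observedInfo <- function(theta, dat, idx, h = 1e-5) {
  p <- idx$npar
  H <- matrix(0, p, p)
  for (k in seq_len(p)) {
    hk <- h * max(1, abs(theta[k]))
    tp <- theta; tp[k] <- tp[k] + hk
    tm <- theta; tm[k] <- tm[k] - hk
    gp <- .lvmEval(tp, dat, idx)$g
    gm <- .lvmEval(tm, dat, idx)$g
    if (is.null(gp) || is.null(gm)) stop("information evaluation failed")
    H[, k] <- (gp - gm) / (2 * hk)
  }
  0.5 * (H + t(H))
}

#' Search for additional model paths
#'
#' Enumerates every direct covariate-to-region path and every residual
#' covariance absent from the fitted specification, scores each candidate,
#' and adjusts the raw p-values by Benjamini-Hochberg across the whole
#' candidate set; candidates with adjusted p < 0.05 are flagged as `added`.
#'
#' The default scoring is the Rao score (Lagrange multiplier) test of the
#' candidate parameter evaluated at the null fit, i.e. no refit per
#' candidate: the statistic is `U^2 / (I_tt - I_tq I_qq^{-1} I_qt)` with
#' `U` the candidate component of the score and `I` the observed
#' information of the extended model at the null estimate. `method =
#' "wald"` instead refits the model with each candidate added and uses the
#' Wald test of the added parameter (slower; useful for confirmation).
#'
#' @param fit a converged [LvmFit-class].
#' @param cohort the [BindingCohort-class] the model was fitted to.
#' @param method `"score"` (default) or `"wald"`.
#' @param fdrLevel adjusted-p threshold for flagging additions.
#' @return A [PathSearchResult-class].
#' @examples
#' coh <- simulateCohort(cohortConfig(), seed = 3)
#' fit <- fitLvm(coh)
#' sr <- pathSearch(fit, coh)
#' sr
#' @export
pathSearch <- function(fit, cohort, method = c("score", "wald"),
                       fdrLevel = 0.05) {
  stopifnot(is(fit, "LvmFit"), is(cohort, "BindingCohort"))
  method <- match.arg(method)
  if (!fit@converged) stop("path search requires a converged fit")
  spec <- fit@spec
  cand <- .candidatePaths(spec)
  if (!nrow(cand)) {
    return(new("PathSearchResult", method = method,
               candidates = data.frame(type = character(), from = character(),
                                       to = character(), statistic = numeric(),
                                       p = numeric(), pFdr = numeric(),
                                       added = logical())))
  }
  stat <- p <- rep(NA_real_, nrow(cand))
  if (method == "score") {
    idx0 <- .lvmIndex(spec)
    dat0 <- .lvmData(cohort, spec)
    theta0 <- fit@details$theta
    par0 <- .unflatten(theta0, idx0)
    I0 <- .observedInfo(theta0, dat0, idx0)
    I0inv <- tryCatch(solve(I0), error = function(e) NULL)
    if (is.null(I0inv)) stop("singular observed information at the null fit")
    for (k in seq_len(nrow(cand))) {
      specE <- .extendSpec(spec, cand$type[k], cand$from[k], cand$to[k])
      idxE <- .lvmIndex(specE)
      datE <- .lvmData(cohort, specE)
      parE <- par0
      if (cand$type[k] == "direct") {
        parE$delta <- c(par0$delta, 0)
        newPos <- idxE$iDelta[idxE$nd]
      } else {
        parE$pairs <- c(par0$pairs, 0)
        newPos <- idxE$iPairs[idxE$np]
      }
      thetaE <- .flatten(parE, idxE)
      oldPos <- setdiff(seq_len(idxE$npar), newPos)
      g0 <- .lvmEval(thetaE, datE, idxE)$g
      if (is.null(g0)) next
      U <- -g0[newPos]
      h <- 1e-5
      tp <- thetaE; tp[newPos] <- h
      tm <- thetaE; tm[newPos] <- -h
      gp <- .lvmEval(tp, datE, idxE)$g
      gm <- .lvmEval(tm, datE, idxE)$g
      if (is.null(gp) || is.null(gm)) next
      col <- (gp - gm) / (2 * h)
      Itt <- col[newPos]
      Itq <- col[oldPos]
      v <- Itt - as.numeric(crossprod(Itq, I0inv %*% Itq))
      if (!is.finite(v) || v <= 0) next
      stat[k] <- U^2 / v
      p[k] <- pchisq(stat[k], df = 1L, lower.tail = FALSE)
    }
  } else {
    for (k in seq_len(nrow(cand))) {
      specE <- .extendSpec(spec, cand$type[k], cand$from[k], cand$to[k])
      fitE <- tryCatch(fitLvm(cohort, specE), error = function(e) NULL)
      if (is.null(fitE)) next
      co <- fitE@coefficients
      term <- if (cand$type[k] == "direct")
        paste0("direct.", cand$from[k], "->", cand$to[k])
      else paste0("cov.", cand$from[k], ":", cand$to[k])
      row <- co[co$term == term, ]
      if (nrow(row) == 1L && is.finite(row$se)) {
        stat[k] <- (row$estimate / row$se)^2
        p[k] <- row$p
      }
    }
  }
  pFdr <- rep(NA_real_, length(p))
  ok <- is.finite(p)
  if (any(ok)) pFdr[ok] <- bhAdjust(p[ok])
  res <- data.frame(cand, statistic = stat, p = p, pFdr = pFdr,
                    added = !is.na(pFdr) & pFdr < fdrLevel,
                    stringsAsFactors = FALSE)
  new("PathSearchResult", candidates = res, method = method)
}

setMethod("show", "PathSearchResult", function(object) {
  cand <- object@candidates
  cat(sprintf("PathSearchResult (%s tests): %d candidates, %d added at FDR 0.05\n",
              object@method, nrow(cand), sum(cand$added, na.rm = TRUE)))
  if (any(cand$added, na.rm = TRUE)) {
    tab <- cand[cand$added, ]
    tab[c("statistic", "p", "pFdr")] <- lapply(tab[c("statistic", "p", "pFdr")],
                                               signif, 3)
    print(tab, row.names = FALSE)
  } else if (nrow(cand)) {
    best <- cand[order(cand$p), ][1, ]
    cat(sprintf("  smallest adjusted p: %s %s->%s (p = %.3g, pFdr = %.3g)\n",
                best$type, best$from, best$to, best$p, best$pFdr))
  }
  invisible(NULL)
})

#' Genotype-block likelihood-ratio test
#'
#' Compares the full model against the model with every genotype-bearing
#' parameter removed (the five latent carrier effects and any direct path
#' from a carrier indicator, six parameters under the default
#' specification): `statistic = 2 (loglik_full - loglik_reduced)`, with a
#' chi-square reference on the number of removed parameters.
#'
#' @param cohort a [BindingCohort-class].
#' @param spec the full [LvmSpec-class]; default [lvmSpec()].
#' @param ... passed to [fitLvm()].
#' @return List with `statistic`, `df`, `p`, and both fits (`full`,
#'   `reduced`).
#' @examples
#' coh <- simulateCohort(cohortConfig(), seed = 5)
#' lrtGenotypes(coh)[c("statistic", "df", "p")]
#' @export
lrtGenotypes <- function(cohort, spec = lvmSpec(), ...) {
  stopifnot(is(cohort, "BindingCohort"), is(spec, "LvmSpec"))
  genos <- intersect(spec@covariates, genotypeNames())
  if (!length(genos)) stop("spec contains no genotype covariates")
  keepDp <- !(spec@directPaths$covariate %in% genos)
  reducedSpec <- new("LvmSpec",
                     regions = spec@regions,
                     covariates = setdiff(spec@covariates, genos),
                     referenceRegion = spec@referenceRegion,
                     directPaths = spec@directPaths[keepDp, , drop = FALSE],
                     residualPairs = spec@residualPairs)
  full <- fitLvm(cohort, spec, ...)
  reduced <- fitLvm(cohort, reducedSpec, ...)
  df <- .lvmIndex(spec)$npar - .lvmIndex(reducedSpec)$npar
  stat <- 2 * (full@loglik - reduced@loglik)
  if (stat < -1e-6) {
    full <- fitLvm(cohort, spec, restarts = 10L)
    stat <- 2 * (full@loglik - reduced@loglik)
    if (stat < -1e-6)
      stop("negative likelihood-ratio statistic: fits did not converge")
  }
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE),
       full = full, reduced = reduced)
}
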