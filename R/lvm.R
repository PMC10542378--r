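## Gaussian latent-variable model for regional binding.
##
## Model: for participant i with covariate row x_i,
##   eta_i = gamma' x_i + zeta_i,            zeta ~ N(0, tau^2)
##   y_ir  = nu_r + lambda_r eta_i + delta paths + eps_ir,  eps ~ N(0, Psi)
## Identification: the reference-region loading is fixed to 1 and the latent
## intercept to 0, so covariate effects on the factor are read in
## reference-region BP_ND units. Psi is diagonal plus the residual
## covariances named in the model specification. Estimation is ML
## (quasi-Newton on log-variance scale, analytic gradients); standard
## errors come from the inverse of the numerically differentiated observed
## information on the natural scale.

#' Specify the latent-variable model graph
#'
#' Default specification: all seven regions load on one factor (caudate as
#' reference), all nine covariates act on the factor, direct paths
#' sex-to-caudate and rs6265-to-neocortex, residual covariances for
#' caudate:putamen, amygdala:hippocampus and thalamus:midbrain.
#'
#' With a single region the latent residual variance is not identifiable
#' and is fixed to zero, so the model degenerates to an ordinary linear
#' regression of that region on the covariates.
#'
#' @param regions ordered subset of [regionNames()].
#' @param covariates subset of [covariateNames()].
#' @param referenceRegion region whose loading is fixed to 1.
#' @param directPaths data.frame (`covariate`, `region`).
#' @param residualPairs data.frame (`region1`, `region2`).
#' @return An [LvmSpec-class].
#' @examples
#' lvmSpec()
#' @export
lvmSpec <- function(regions = regionNames(),
                    covariates = covariateNames(),
                    referenceRegion = "caudate",
                    directPaths = NULL,
                    residualPairs = NULL) {
  if (is.null(directPaths)) {
    directPaths <- data.frame(covariate = c("sex", "rs6265"),
                              region = c("caudate", "neocortex"),
                              stringsAsFactors = FALSE)
    directPaths <- directPaths[directPaths$covariate %in% covariates &
                                 directPaths$region %in% regions, ,
                               drop = FALSE]
    # with one region a direct path is indistinguishable from the latent
    # effect of the same covariate
    if (length(regions) == 1L) directPaths <- directPaths[0, , drop = FALSE]
  }
  if (is.null(residualPairs)) {
    residualPairs <- data.frame(
      region1 = c("caudate", "amygdala", "thalamus"),
      region2 = c("putamen", "hippocampus", "midbrain"),
      stringsAsFactors = FALSE)
    keep <- residualPairs$region1 %in% regions &
      residualPairs$region2 %in% regions
    residualPairs <- residualPairs[keep, , drop = FALSE]
  }
  if (!referenceRegion %in% regions) referenceRegion <- regions[1]
  obj <- new("LvmSpec", regions = regions, covariates = covariates,
             referenceRegion = referenceRegion,
             directPaths = directPaths, residualPairs = residualPairs)
  validObject(obj)
  obj
}

setMethod("show", "LvmSpec", function(object) {
  cat(sprintf("LvmSpec: %d region(s) on one latent factor (reference: %s)\n",
              length(object@regions), object@referenceRegion))
  cat("  covariates:", paste(object@covariates, collapse = ", "), "\n")
  if (nrow(object@directPaths))
    cat("  direct paths:",
        paste(sprintf("%s->%s", object@directPaths$covariate,
                      object@directPaths$region), collapse = ", "), "\n")
  if (nrow(object@residualPairs))
    cat("  residual covariances:",
        paste(sprintf("%s:%s", object@residualPairs$region1,
                      object@residualPairs$region2), collapse = ", "), "\n")
  invisible(NULL)
})

## ---- internal parameter bookkeeping ------------------------------------

.lvmIndex <- function(spec) {
  r <- length(spec@regions)
  refIdx <- match(spec@referenceRegion, spec@regions)
  freeLambda <- setdiff(seq_len(r), refIdx)
  hasLatent <- r >= 2L
  nc <- length(spec@covariates)
  nd <- nrow(spec@directPaths)
  np <- nrow(spec@residualPairs)
  sizes <- c(nu = r, lambda = length(freeLambda), gamma = nc, delta = nd,
             psi = r, tau2 = as.integer(hasLatent), pairs = np)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  block <- function(nm) if (sizes[[nm]] > 0L) starts[[nm]]:ends[[nm]] else integer()
  list(
    r = r, nc = nc, nd = nd, np = np,
    refIdx = refIdx, freeLambda = freeLambda, hasLatent = hasLatent,
    iNu = block("nu"), iLambda = block("lambda"), iGamma = block("gamma"),
    iDelta = block("delta"), iPsi = block("psi"), iTau2 = block("tau2"),
    iPairs = block("pairs"), npar = unname(ends[length(ends)]),
    pair1 = match(spec@residualPairs$region1, spec@regions),
    pair2 = match(spec@residualPairs$region2, spec@regions)
  )
}

.lvmData <- function(cohort, spec) {
  Y <- t(bpnd(cohort))[, spec@regions, drop = FALSE]
  Xall <- designMatrix(cohort)
  X <- Xall[, spec@covariates, drop = FALSE]
  nd <- nrow(spec@directPaths)
  D <- matrix(0, nrow(Y), nd)
  dRegion <- integer(nd)
  if (nd) {
    for (k in seq_len(nd)) {
      D[, k] <- Xall[, spec@directPaths$covariate[k]]
      dRegion[k] <- match(spec@directPaths$region[k], spec@regions)
    }
  }
  list(Y = Y, X = X, D = D, dRegion = dRegion, n = nrow(Y))
}

## flat natural-scale parameter vector <-> named list
.unflatten <- function(theta, idx) {
  lambda <- rep(1, idx$r)
  lambda[idx$freeLambda] <- theta[idx$iLambda]
  list(nu = theta[idx$iNu], lambda = lambda,
       gamma = theta[idx$iGamma], delta = theta[idx$iDelta],
       psi = theta[idx$iPsi],
       tau2 = if (idx$hasLatent) theta[idx$iTau2] else 0,
       pairs = theta[idx$iPairs])
}

.flatten <- function(par, idx) {
  theta <- numeric(idx$npar)
  theta[idx$iNu] <- par$nu
  theta[idx$iLambda] <- par$lambda[idx$freeLambda]
  theta[idx$iGamma] <- par$gamma
  theta[idx$iDelta] <- par$delta
  theta[idx$iPsi] <- par$psi
  if (idx$hasLatent) theta[idx$iTau2] <- par$tau2
  theta[idx$iPairs] <- par$pairs
  theta
}

.lvmSigma <- function(par, idx) {
  Sigma <- tcrossprod(par$lambda) * par$tau2 + diag(par$psi, idx$r)
  if (idx$np) {
    for (k in seq_len(idx$np)) {
      i <- idx$pair1[k]; j <- idx$pair2[k]
      Sigma[i, j] <- Sigma[i, j] + par$pairs[k]
      Sigma[j, i] <- Sigma[j, i] + par$pairs[k]
    }
  }
  Sigma
}

## negative log-likelihood and its natural-scale analytic gradient
.lvmEval <- function(theta, dat, idx, grad = TRUE) {
  par <- .unflatten(theta, idx)
  Sigma <- .lvmSigma(par, idx)
  U <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(U)) return(list(f = 1e12, g = NULL, ok = FALSE))
  n <- dat$n; r <- idx$r
  u <- as.vector(dat$X %*% par$gamma)
  M <- matrix(par$nu, n, r, byrow = TRUE) + outer(u, par$lambda)
  if (idx$nd) {
    for (k in seq_len(idx$nd))
      M[, dat$dRegion[k]] <- M[, dat$dRegion[k]] + par$delta[k] * dat$D[, k]
  }
  E <- dat$Y - M
  W <- chol2inv(U)
  logdet <- 2 * sum(log(diag(U)))
  P <- E %*% W
  quad <- sum(E * P)
  f <- 0.5 * (n * r * log(2 * pi) + n * logdet + quad)
  if (!grad) return(list(f = f, g = NULL, ok = TRUE))
  S <- crossprod(E)
  A <- 0.5 * (n * W - W %*% S %*% W)
  g <- numeric(idx$npar)
  g[idx$iNu] <- -colSums(P)
  Wl <- as.vector(A %*% par$lambda)
  gLambdaFull <- -colSums(u * P) + 2 * par$tau2 * Wl
  g[idx$iLambda] <- gLambdaFull[idx$freeLambda]
  g[idx$iGamma] <- -as.vector(crossprod(dat$X, P %*% par$lambda))
  if (idx$nd) {
    for (k in seq_len(idx$nd))
      g[idx$iDelta[k]] <- -sum(dat$D[, k] * P[, dat$dRegion[k]])
  }
  g[idx$iPsi] <- diag(A)
  if (idx$hasLatent) g[idx$iTau2] <- sum(par$lambda * Wl)
  if (idx$np) {
    for (k in seq_len(idx$np))
      g[idx$iPairs[k]] <- 2 * A[idx$pair1[k], idx$pair2[k]]
  }
  list(f = f, g = g, ok = TRUE)
}

## optimization scale: log for psi and tau2, identity elsewhere
.toOpt <- function(theta, idx) {
  out <- theta
  out[idx$iPsi] <- log(theta[idx$iPsi])
  if (idx$hasLatent) out[idx$iTau2] <- log(theta[idx$iTau2])
  out
}

.toNat <- function(thetaOpt, idx) {
  out <- thetaOpt
  out[idx$iPsi] <- exp(thetaOpt[idx$iPsi])
  if (idx$hasLatent) out[idx$iTau2] <- exp(thetaOpt[idx$iTau2])
  out
}

.lvmStart <- function(dat, spec, idx) {
  n <- dat$n
  Xf <- cbind(1, dat$X)  # direct effects start at 0
  B <- tryCatch(solve(crossprod(Xf), crossprod(Xf, dat$Y)),
                error = function(e) stop("rank-deficient design"))
  R <- dat$Y - Xf %*% B
  Cres <- crossprod(R) / max(n, 1L)
  nu0 <- B[1, ]
  gamma0 <- if (idx$nc) B[1 + seq_len(idx$nc), idx$refIdx] else numeric()
  par <- list(nu = as.numeric(nu0), gamma = as.numeric(gamma0),
              delta = rep(0, idx$nd))
  if (idx$hasLatent) {
    ei <- eigen(Cres, symmetric = TRUE)
    v <- ei$vectors[, 1]
    s <- v[idx$refIdx]
    if (abs(s) < 1e-8) { v <- rep(1 / sqrt(idx$r), idx$r); s <- v[idx$refIdx] }
    lambda0 <- v / s
    tau20 <- max(ei$values[1] * s^2, 1e-4)
    psi0 <- pmax(diag(Cres) - lambda0^2 * tau20, 0.25 * pmax(diag(Cres), 1e-6))
    pairs0 <- numeric(idx$np)
    if (idx$np) {
      for (k in seq_len(idx$np)) {
        i <- idx$pair1[k]; j <- idx$pair2[k]
        raw <- Cres[i, j] - lambda0[i] * lambda0[j] * tau20
        cap <- 0.6 * sqrt(psi0[i] * psi0[j])
        pairs0[k] <- sign(raw) * min(abs(raw), cap)
      }
    }
    par$lambda <- lambda0; par$tau2 <- tau20; par$psi <- as.numeric(psi0)
    par$pairs <- pairs0
  } else {
    par$lambda <- 1
    par$tau2 <- 0
    par$psi <- max(diag(Cres), 1e-6)
    par$pairs <- numeric()
  }
  .flatten(par, idx)
}

#' Fit the latent-variable model by maximum likelihood
#'
#' Fits the Gaussian latent-variable model described by `spec` to a cohort.
#' Optimization is quasi-Newton (BFGS) with analytic gradients on a
#' log-variance parameterization, starting from a principal-axis heuristic
#' on the covariate-residual covariance, with up to `restarts` jittered
#' restarts on non-convergence. Standard errors are obtained from the
#' inverse of the numerically differentiated observed information at the
#' optimum; Wald 95% intervals and two-sided normal p-values accompany
#' every free parameter.
#'
#' @param cohort a [BindingCohort-class].
#' @param spec an [LvmSpec-class]; default [lvmSpec()].
#' @param restarts maximum number of jittered restarts.
#' @param control passed to [stats::optim()] (sensible defaults supplied).
#' @return An [LvmFit-class].
#' @examples
#' coh <- simulateCohort(cohortConfig(), seed = 11)
#' fit <- fitLvm(coh)
#' fit
#' @export
fitLvm <- function(cohort, spec = lvmSpec(), restarts = 5L,
                   control = list()) {
  stopifnot(is(cohort, "BindingCohort"), is(spec, "LvmSpec"))
  validObject(spec)
  idx <- .lvmIndex(spec)
  dat <- .lvmData(cohort, spec)
  if (dat$n <= idx$npar)
    stop(sprintf("n = %d participants cannot identify %d parameters",
                 dat$n, idx$npar))
  ctrl <- modifyList(list(maxit = 1000L, reltol = 1e-10), control)
  fn <- function(to) .lvmEval(.toNat(to, idx), dat, idx, grad = FALSE)$f
  gr <- function(to) {
    ev <- .lvmEval(.toNat(to, idx), dat, idx)
    if (!ev$ok) return(numeric(idx$npar))
    g <- ev$g
    g[idx$iPsi] <- g[idx$iPsi] * exp(to[idx$iPsi])
    if (idx$hasLatent) g[idx$iTau2] <- g[idx$iTau2] * exp(to[idx$iTau2])
    g
  }
  start <- .toOpt(.lvmStart(dat, spec, idx), idx)
  best <- NULL
  for (attempt in 0:restarts) {
    s <- if (attempt == 0) start else start + rnorm(idx$npar, 0, 0.1 * attempt)
    opt <- tryCatch(optim(s, fn, gr, method = "BFGS", control = ctrl),
                    error = function(e) NULL)
    if (is.null(opt)) next
    gnorm <- max(abs(gr(opt$par)))
    ok <- opt$convergence == 0 && opt$value < 1e11 && gnorm < 1e-3 * (1 + abs(opt$value))
    if (is.null(best) || opt$value < best$value - 1e-8) {
      best <- opt; best$ok <- ok
    }
    if (!is.null(best) && best$ok) break
  }
  if (is.null(best)) stop("latent-variable model optimization failed")
  thetaNat <- .toNat(best$par, idx)
  loglik <- -.lvmEval(thetaNat, dat, idx, grad = FALSE)$f
  H <- tryCatch(
    optimHess(thetaNat, function(tn) .lvmEval(tn, dat, idx, grad = FALSE)$f,
              function(tn) {
                ev <- .lvmEval(tn, dat, idx)
                if (ev$ok) ev$g else numeric(idx$npar)
              }),
    error = function(e) NULL)
  vc <- if (!is.null(H))
    tryCatch(solve(0.5 * (H + t(H))), error = function(e) NULL) else NULL
  se <- rep(NA_real_, idx$npar)
  if (!is.null(vc)) {
    dv <- diag(vc)
    se[dv > 0] <- sqrt(dv[dv > 0])
  } else {
    warning("singular observed information: standard errors unavailable")
  }
  coefs <- .lvmCoefTable(thetaNat, se, spec, idx)
  new("LvmFit", spec = spec, coefficients = coefs, loglik = loglik,
      nobs = dat$n, converged = isTRUE(best$ok),
      details = list(theta = thetaNat, se = se, vcov = vc, index = idx,
                     optim = best[c("value", "convergence", "counts")]))
}

.lvmTermNames <- function(spec, idx) {
  nm <- character(idx$npar)
  nm[idx$iNu] <- paste0("nu.", spec@regions)
  nm[idx$iLambda] <- paste0("lambda.", spec@regions[idx$freeLambda])
  nm[idx$iGamma] <- paste0("latent.", spec@covariates)
  if (idx$nd)
    nm[idx$iDelta] <- paste0("direct.", spec@directPaths$covariate, "->",
                             spec@directPaths$region)
  nm[idx$iPsi] <- paste0("psi.", spec@regions)
  if (idx$hasLatent) nm[idx$iTau2] <- "tau2"
  if (idx$np)
    nm[idx$iPairs] <- paste0("cov.", spec@residualPairs$region1, ":",
                             spec@residualPairs$region2)
  nm
}

.lvmCoefTable <- function(thetaNat, se, spec, idx) {
  type <- character(idx$npar)
  type[idx$iNu] <- "intercept"
  type[idx$iLambda] <- "loading"
  type[idx$iGamma] <- "latent"
  type[idx$iDelta] <- "direct"
  type[idx$iPsi] <- "variance"
  if (idx$hasLatent) type[idx$iTau2] <- "variance"
  type[idx$iPairs] <- "covariance"
  z <- qnorm(0.975)
  est <- thetaNat
  data.frame(
    term = .lvmTermNames(spec, idx),
    type = type,
    estimate = est,
    se = se,
    lower = est - z * se,
    upper = est + z * se,
    p = 2 * pnorm(-abs(est / se)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' @describeIn fitLvm the estimated parameters as a named list (`nu`,
#'   `lambda`, `gamma`, `delta`, `psi`, `tau2`, `pairs`).
#' @param fit an [LvmFit-class].
#' @export
lvmParameters <- function(fit) {
  stopifnot(is(fit, "LvmFit"))
  idx <- fit@details$index
  par <- .unflatten(fit@details$theta, idx)
  names(par$nu) <- fit@spec@regions
  names(par$lambda) <- fit@spec@regions
  names(par$gamma) <- fit@spec@covariates
  if (idx$nd)
    names(par$delta) <- paste0(fit@spec@directPaths$covariate, "->",
                               fit@spec@directPaths$region)
  names(par$psi) <- fit@spec@regions
  if (idx$np)
    names(par$pairs) <- paste0(fit@spec@residualPairs$region1, ":",
                               fit@spec@residualPairs$region2)
  par
}

setMethod("show", "LvmFit", function(object) {
  cat(sprintf("LvmFit: %d participants, logLik = %.3f, %s\n", object@nobs,
              object@loglik,
              if (object@converged) "converged" else "NOT converged"))
  keep <- object@coefficients$type %in% c("latent", "direct")
  tab <- object@coefficients[keep, c("term", "estimate", "se", "lower",
                                     "upper", "p")]
  tab[-1] <- lapply(tab[-1], signif, 3)
  print(tab, row.names = FALSE)
  invisible(NULL)
})

#' @export
setMethod("coef", "LvmFit", function(object, ...) {
  setNames(object@coefficients$estimate, object@coefficients$term)
})

#' @export
setMethod("logLik", "LvmFit", function(object, ...) {
  structure(object@loglik, df = object@details$index$npar,
            nobs = object@nobs, class = "logLik")
})

#' Implied moments of the latent-variable model
#'
#' Mean vector and covariance matrix of the regional binding values implied
#' by a parameter set at one covariate row: `mean_r = nu_r + lambda_r
#' (gamma' x) + direct paths`, `Sigma = lambda lambda' tau^2 + Psi` (the
#' covariance does not depend on x).
#'
#' @param spec an [LvmSpec-class].
#' @param params named parameter list as returned by [lvmParameters()].
#' @param x named numeric vector of covariate values (model coding).
#' @return List with `mean` and `Sigma`.
#' @export
impliedMoments <- function(spec, params, x) {
  stopifnot(is(spec, "LvmSpec"))
  idx <- .lvmIndex(spec)
  if (!all(spec@covariates %in% names(x)))
    stop("x must name every model covariate")
  xv <- as.numeric(x[spec@covariates])
  eta <- sum(params$gamma * xv)
  mu <- params$nu + params$lambda * eta
  if (idx$nd) {
    for (k in seq_len(idx$nd)) {
      r <- match(spec@directPaths$region[k], spec@regions)
      mu[r] <- mu[r] + params$delta[k] * x[[spec@directPaths$covariate[k]]]
    }
  }
  Sigma <- .lvmSigma(params, idx)
  dimnames(Sigma) <- list(spec@regions, spec@regions)
  list(mean = setNames(as.numeric(mu), spec@regions), Sigma = Sigma)
}

#' Log-likelihood of a parameter set on a cohort
#'
#' Sum over participants of the multivariate normal log-density of the
#' regional values at the implied subject-specific mean and shared
#' covariance. A non-positive-definite implied covariance is an error.
#'
#' @param cohort a [BindingCohort-class].
#' @param spec an [LvmSpec-class].
#' @param params named parameter list (see [lvmParameters()]).
#' @return The log-likelihood (scalar).
#' @export
lvmLogLik <- function(cohort, spec, params) {
  idx <- .lvmIndex(spec)
  dat <- .lvmData(cohort, spec)
  ev <- .lvmEval(.flatten(params, idx), dat, idx, grad = FALSE)
  if (!ev$ok) stop("implied covariance matrix is not positive definite")
  -ev$f
}
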