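## Single-trait Bayesian whole-genome regression by Gibbs sampling.
##
## Two equivalent forms are provided: the marker-effect form (Bayesian ridge
## regression, one normal prior with common variance over all marker
## effects) and the G-BLUP form on the realized relationship matrix, which
## is preferred when m >> n. Variance components carry scaled
## inverse-chi-square priors chi^-2(df, S) read in the "sum"
## parameterisation sigma2 = (S + SS)/chisq(df + n); defaults follow the
## convention df = 5 and S = var(y) * 0.5.

#' Single-trait sampler configuration
#'
#' @param nIter total Gibbs iterations (default 3000).
#' @param burnIn burn-in iterations discarded from posterior summaries
#'   (default 1500).
#' @param df0 prior degrees of freedom for both variance components
#'   (default 5).
#' @param scaleFrac scale rule: `S = var(y) * scaleFrac` (default 0.5).
#' @param thin keep every `thin`-th post-burn-in draw (default 1, i.e.
#'   unthinned).
#' @param fixSigma2U,fixSigma2E optional fixed values for the genetic
#'   (or marker-effect) and residual variances; when supplied the
#'   corresponding update is skipped. Intended for sampler verification
#'   against the closed-form ridge solution.
#' @param seed chain seed.
#' @return list of class `"STConfig"`.
#' @export
stConfig <- function(nIter = 3000L, burnIn = 1500L, df0 = 5, scaleFrac = 0.5,
                     thin = 1L, fixSigma2U = NULL, fixSigma2E = NULL,
                     seed = 1L) {
  stopifnot(nIter > burnIn, burnIn >= 0, thin >= 1)
  structure(list(nIter = as.integer(nIter), burnIn = as.integer(burnIn),
                 df0 = df0, scaleFrac = scaleFrac, thin = as.integer(thin),
                 fixSigma2U = fixSigma2U, fixSigma2E = fixSigma2E,
                 seed = as.integer(seed)),
            class = "STConfig")
}

#' Bayesian ridge regression on marker effects
#'
#' Gibbs sampler for `y = 1 mu + X beta + e` with `beta_j ~ N(0, sigma2_b)`,
#' `sigma2_b ~ chi^-2(df0, S)`, `e ~ N(0, sigma2_e I)`,
#' `sigma2_e ~ chi^-2(df0, S)`, `S = var(y) * scaleFrac`. Updates are
#' single-site normal for `beta`, normal for `mu`, scaled inverse-chi-square
#' for the variances. Individuals with missing `y` contribute no likelihood
#' and receive predictions `g = X beta`.
#'
#' @param y phenotype vector (NA = unobserved).
#' @param X n x m genotype dosage matrix (complete).
#' @param config an [stConfig()].
#' @return an [STPosterior-class]; slot `g` satisfies `g = X betaMean`.
#' @export
fitBRR <- function(y, X, config = stConfig()) {
  stopifnot(inherits(config, "STConfig"))
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must be complete")
  obs <- which(!is.na(y))
  if (length(obs) < 2L) stop("need at least 2 observed phenotypes")
  yo <- y[obs]
  vy <- stats::var(yo)
  if (vy == 0) stop("var(y) is zero: scale rule S = var(y) * scaleFrac undefined")
  S0 <- vy * config$scaleFrac
  Xo <- X[obs, , drop = FALSE]
  n <- length(obs); m <- ncol(X)
  xtx <- colSums(Xo^2)
  set.seed(config$seed)
  beta <- rep(0, m)
  mu <- mean(yo)
  s2b <- if (is.null(config$fixSigma2U)) vy / 2 else config$fixSigma2U
  s2e <- if (is.null(config$fixSigma2E)) vy / 2 else config$fixSigma2E
  resid <- yo - mu                      # running residual y - mu - X beta
  nKeep <- 0L
  betaSum <- rep(0, m); muSum <- 0; s2bSum <- 0; s2eSum <- 0
  for (it in seq_len(config$nIter)) {
    ## mu
    rfull <- resid + mu
    mu <- stats::rnorm(1L, mean(rfull), sqrt(s2e / n))
    resid <- rfull - mu
    ## beta, single site
    z <- stats::rnorm(m)
    for (j in seq_len(m)) {
      if (xtx[j] == 0) { beta[j] <- stats::rnorm(1L, 0, sqrt(s2b)); next }
      rj <- resid + Xo[, j] * beta[j]
      prec <- xtx[j] / s2e + 1 / s2b
      bmean <- (sum(Xo[, j] * rj) / s2e) / prec
      bnew <- bmean + z[j] / sqrt(prec)
      resid <- rj - Xo[, j] * bnew
      beta[j] <- bnew
    }
    ## variances
    if (is.null(config$fixSigma2U))
      s2b <- .rScaledInvChisq(config$df0, S0, m, sum(beta^2))
    if (is.null(config$fixSigma2E))
      s2e <- .rScaledInvChisq(config$df0, S0, n, sum(resid^2))
    if (it > config$burnIn && (it - config$burnIn) %% config$thin == 0L) {
      nKeep <- nKeep + 1L
      betaSum <- betaSum + beta; muSum <- muSum + mu
      s2bSum <- s2bSum + s2b; s2eSum <- s2eSum + s2e
    }
  }
  betaMean <- betaSum / nKeep
  names(betaMean) <- colnames(X)
  g <- drop(X %*% betaMean)
  names(g) <- rownames(X)
  new("STPosterior", method = "BRR", g = g, betaMean = betaMean,
      muMean = muSum / nKeep, sigma2U = s2bSum / nKeep,
      sigma2E = s2eSum / nKeep, seed = config$seed)
}

#' Single-trait G-BLUP by Gibbs sampling
#'
#' Equivalent-model form of Bayesian ridge regression: `y = 1 mu + u + e`
#' with `u ~ N(0, sigma2_u K)`. The sampler works in the eigenbasis of the
#' training-subset kinship (individuals with missing `y` are excluded from
#' the likelihood); their genetic values are recovered afterwards by the
#' scale-free projection `u_new = K_no K_oo^-1 u_obs`, which is exact for
#' posterior means.
#'
#' @param y phenotype vector aligned with `K` (NA = predict only).
#' @param K a [KinshipMatrix-class] or plain symmetric matrix.
#' @param config an [stConfig()].
#' @return an [STPosterior-class] with `g` of length `n` (all individuals).
#' @export
fitGBLUP <- function(y, K, config = stConfig()) {
  stopifnot(inherits(config, "STConfig"))
  Km <- if (is(K, "KinshipMatrix")) kinship(K) else as.matrix(K)
  n <- length(y)
  stopifnot(nrow(Km) == n)
  obs <- which(!is.na(y))
  if (length(obs) < 2L) stop("need at least 2 observed phenotypes")
  yo <- y[obs]
  vy <- stats::var(yo)
  if (vy == 0) stop("var(y) is zero: scale rule undefined")
  S0 <- vy * config$scaleFrac
  no <- length(obs)
  Koo <- Km[obs, obs, drop = FALSE]
  eig <- .kinshipEigen(Koo)
  V <- eig$vectors; d <- eig$values; r <- length(d)
  set.seed(config$seed)
  mu <- mean(yo)
  s2u <- if (is.null(config$fixSigma2U)) vy / 2 else config$fixSigma2U
  s2e <- if (is.null(config$fixSigma2E)) vy / 2 else config$fixSigma2E
  a <- rep(0, r)                        # u_obs = V a
  nKeep <- 0L; uSum <- rep(0, no); muSum <- 0; s2uSum <- 0; s2eSum <- 0
  yt <- drop(crossprod(V, yo))
  for (it in seq_len(config$nIter)) {
    ## rotated genetic coordinates: independent scalar posteriors
    et <- yt - drop(crossprod(V, rep(mu, no)))
    pv <- 1 / (1 / (s2u * d) + 1 / s2e)
    a <- pv * et / s2e + sqrt(pv) * stats::rnorm(r)
    u <- drop(V %*% a)
    mu <- stats::rnorm(1L, mean(yo - u), sqrt(s2e / no))
    if (is.null(config$fixSigma2U))
      s2u <- .rScaledInvChisq(config$df0, S0, r, sum(a^2 / d))
    if (is.null(config$fixSigma2E))
      s2e <- .rScaledInvChisq(config$df0, S0, no, sum((yo - mu - u)^2))
    if (it > config$burnIn && (it - config$burnIn) %% config$thin == 0L) {
      nKeep <- nKeep + 1L
      uSum <- uSum + u; muSum <- muSum + mu; s2uSum <- s2uSum + s2u; s2eSum <- s2eSum + s2e
    }
  }
  uObs <- uSum / nKeep
  g <- rep(NA_real_, n)
  g[obs] <- uObs
  mis <- setdiff(seq_len(n), obs)
  if (length(mis)) {
    sol <- solve(Koo + diag(1e-8, no), uObs)
    g[mis] <- drop(Km[mis, obs, drop = FALSE] %*% sol)
  }
  names(g) <- rownames(Km)
  new("STPosterior", method = "GBLUP", g = g, betaMean = numeric(0),
      muMean = muSum / nKeep, sigma2U = s2uSum / nKeep,
      sigma2E = s2eSum / nKeep, seed = config$seed)
}

#' Predict genetic values from a fitted single-trait model
#'
#' @param object an [STPosterior-class] from [fitBRR()].
#' @param Xnew genotype dosages with marker columns aligned to the training
#'   panel (checked by name when both carry names).
#' @param includeMu add the intercept for a phenotype-scale prediction
#'   (default `FALSE`: genomic value only).
#' @return numeric vector `Xnew %*% betaMean` (+ `muMean` if requested).
#' @export
predictST <- function(object, Xnew, includeMu = FALSE) {
  stopifnot(is(object, "STPosterior"))
  if (object@method != "BRR")
    stop("predictST() needs marker effects; fit with fitBRR(), or read g from the GBLUP fit")
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != length(object@betaMean))
    stop("marker mismatch: ", ncol(Xnew), " columns vs ",
         length(object@betaMean), " training markers")
  if (!is.null(colnames(Xnew)) && !is.null(names(object@betaMean)) &&
      !identical(colnames(Xnew), names(object@betaMean)))
    stop("marker ids do not match the training panel: ",
         paste(utils::head(setdiff(colnames(Xnew), names(object@betaMean))), collapse = ", "))
  drop(Xnew %*% object@betaMean) + if (includeMu) object@muMean else 0
}
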