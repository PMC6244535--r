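## Synthetic study generator: genotypes, genetic values with a structured
## trait covariance, and multi-environment trial phenotypes. Defaults emulate
## a wheat advanced-line panel evaluated for eight baking-quality traits in a
## sparse multi-environment trial network linked by check lines.

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic study. The defaults
#' describe the emulated study conditions: 495 inbred lines genotyped at
#' 6,655 SNPs, eight traits with heritabilities spanning 0.36-0.64, two
#' groups of four traits with within-group genetic correlation 0.7 and no
#' cross-group correlation, and a trial network of 82 trials in nine
#' environments linked by five check lines.
#'
#' @param nIndividuals,nMarkers,nTraits panel dimensions.
#' @param mafRange range of per-marker allele frequencies, within (0, 0.5].
#' @param h2 per-trait narrow-sense heritability at the line-mean level,
#'   strictly inside (0, 1); recycled to `nTraits`.
#' @param geneticCorr t x t genetic correlation matrix (symmetric, unit
#'   diagonal, PSD). Default: block structure with two equal groups,
#'   within-group correlation `withinCorr`, zero across groups.
#' @param withinCorr within-group correlation used to build the default
#'   `geneticCorr`.
#' @param nEnvironments number of location-year combinations.
#' @param nTrials total number of trials, distributed round-robin over
#'   environments.
#' @param trialVar variance of the random trial-within-environment effect.
#' @param envVar variance of the fixed environment effects (drawn once).
#' @param nChecks number of check lines replicated in every trial (they link
#'   the trials; must be < `nIndividuals`).
#' @param missingGenoRate fraction of genotype calls set missing, in \[0, 1).
#' @param nQTL optional number of markers with nonzero effect; default `NULL`
#'   means all markers contribute (infinitesimal architecture).
#' @param seed master integer seed; every stochastic operation draws a
#'   sub-seed from this via [subSeeds()].
#' @return validated list of class `"SimConfig"`.
#' @export
simConfig <- function(nIndividuals = 495L, nMarkers = 6655L, nTraits = 8L,
                      mafRange = c(0.05, 0.5),
                      h2 = seq(0.36, 0.64, length.out = nTraits),
                      geneticCorr = NULL, withinCorr = 0.7,
                      nEnvironments = 9L, nTrials = 82L,
                      trialVar = 0.5, envVar = 1,
                      nChecks = 5L, missingGenoRate = 0,
                      nQTL = NULL, seed = 1L) {
  stopifnot(nIndividuals >= 2, nMarkers >= 1, nTraits >= 1,
            nEnvironments >= 1, nTrials >= nEnvironments,
            trialVar >= 0, envVar >= 0,
            missingGenoRate >= 0, missingGenoRate < 1)
  if (length(mafRange) != 2 || mafRange[1] <= 0 || mafRange[2] > 0.5 ||
      mafRange[1] > mafRange[2])
    stop("mafRange must be an increasing pair within (0, 0.5]")
  h2 <- rep_len(h2, nTraits)
  if (any(h2 <= 0) || any(h2 >= 1)) stop("h2 entries must be strictly inside (0, 1)")
  if (nChecks >= nIndividuals) stop("nChecks must be < nIndividuals")
  if (is.null(geneticCorr)) {
    g1 <- seq_len(ceiling(nTraits / 2))
    geneticCorr <- diag(nTraits)
    for (grp in list(g1, setdiff(seq_len(nTraits), g1)))
      geneticCorr[grp, grp] <- withinCorr
    diag(geneticCorr) <- 1
  }
  geneticCorr <- as.matrix(geneticCorr)
  if (nrow(geneticCorr) != nTraits || max(abs(geneticCorr - t(geneticCorr))) > 1e-8 ||
      max(abs(diag(geneticCorr) - 1)) > 1e-8)
    stop("geneticCorr must be a symmetric nTraits x nTraits matrix with unit diagonal")
  geneticCorr <- .clipCorr(geneticCorr)
  structure(list(nIndividuals = as.integer(nIndividuals),
                 nMarkers = as.integer(nMarkers), nTraits = as.integer(nTraits),
                 mafRange = mafRange, h2 = h2, geneticCorr = geneticCorr,
                 nEnvironments = as.integer(nEnvironments),
                 nTrials = as.integer(nTrials), trialVar = trialVar,
                 envVar = envVar, nChecks = as.integer(nChecks),
                 missingGenoRate = missingGenoRate,
                 nQTL = if (is.null(nQTL)) NULL else as.integer(nQTL),
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate biallelic SNP genotypes
#'
#' Per marker, an allele frequency `p_m` is drawn uniformly on
#' `config$mafRange`; genotypes are drawn as Binomial(2, p_m) and recoded to
#' \{-1, 0, 1\} (Hardy-Weinberg sampling, markers independent — no linkage
#' disequilibrium is simulated). A fraction `missingGenoRate` of entries is
#' then set missing uniformly at random.
#'
#' @param config a [simConfig()] object.
#' @return a [GenotypeMatrix-class]; realized allele frequencies are
#'   recomputed from the non-missing calls.
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(subSeeds(config$seed, 3L)[1L])
  n <- config$nIndividuals; m <- config$nMarkers
  p <- stats::runif(m, config$mafRange[1], config$mafRange[2])
  X <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)) - 1, n, m)
  if (config$missingGenoRate > 0) {
    nmiss <- stats::rbinom(1L, n * m, config$missingGenoRate)
    X[sample.int(n * m, nmiss)] <- NA
  }
  rownames(X) <- sprintf("L%03d", seq_len(n))
  colnames(X) <- sprintf("M%05d", seq_len(m))
  GenotypeMatrix(X)
}

#' Simulate genetic values and line-level trait records
#'
#' Marker effects are drawn i.i.d. across markers from a multivariate normal
#' over traits with covariance `Sigma / (2 sum p q)`, where
#' `Sigma = geneticCorr` (unit genetic variances); genetic values are
#' `u = W B` with `W` the centered genotype matrix, so the genetic covariance
#' of `u` converges to `Sigma`. Per-trait residual variances are chosen from
#' the *realized* genetic variance so that `Var(u_t) / (Var(u_t) + R_t)`
#' equals `h2[t]`.
#'
#' @param geno a complete [GenotypeMatrix-class] (no missing calls; impute
#'   first or simulate with `missingGenoRate = 0`).
#' @param config a [simConfig()] object.
#' @return list with `traits` (n x t matrix `y = u + e`) and `truth`, a list
#'   holding `u`, `Sigma` (generating genetic covariance), `R` (residual
#'   variances) and `markerEffects`.
#' @export
simulateTraits <- function(geno, config) {
  stopifnot(is(geno, "GenotypeMatrix"), inherits(config, "SimConfig"))
  X <- genoCalls(geno)
  if (anyNA(X)) stop("genotypes must be complete (impute first)")
  set.seed(subSeeds(config$seed, 3L)[2L])
  t <- config$nTraits
  Sigma <- config$geneticCorr  # unit genetic variances: Sigma == correlation
  p <- colMeans(X + 1) / 2
  W <- sweep(X, 2L, 2 * p - 1)  # X + (1 - 2p)
  denom <- 2 * sum(p * (1 - p))
  m <- ncol(X)
  active <- seq_len(m)
  if (!is.null(config$nQTL)) active <- sort(sample.int(m, min(config$nQTL, m)))
  B <- matrix(0, m, t)
  Z <- matrix(stats::rnorm(length(active) * t), length(active), t)
  scl <- denom * length(active) / m  # keep Var(u) ~ Sigma under sparse architecture
  B[active, ] <- Z %*% chol(Sigma / scl)
  u <- W %*% B
  vu <- apply(u, 2L, stats::var)
  R <- vu * (1 - config$h2) / config$h2
  e <- matrix(stats::rnorm(nrow(X) * t), nrow(X), t) %*% diag(sqrt(R), t)
  y <- u + e
  tn <- sprintf("T%d", seq_len(t))
  dimnames(y) <- dimnames(u) <- list(rownames(X), tn)
  names(R) <- tn
  dimnames(Sigma) <- list(tn, tn)
  list(traits = y,
       truth = list(u = u, Sigma = Sigma, R = R, markerEffects = B, h2 = config$h2))
}

#' Simulate a multi-environment trial layout
#'
#' Each non-check line is assigned to a home trial (trials are distributed
#' round-robin over environments); a fraction `replicatedFrac` of the
#' non-check lines — the "promising" lines a breeding program advances — is
#' additionally evaluated in trials of other environments, and check lines
#' appear in every trial and link the network. Records receive a fixed
#' environment effect, a random trial effect with variance `trialVar`, and
#' per-record residual noise.
#'
#' @param values n x t matrix of line-level trait values (typically the true
#'   genetic values `truth$u`, so that the per-record residual carries all
#'   non-genetic noise).
#' @param config a [simConfig()] object.
#' @param residVar per-trait variance of the per-record residual; defaults to
#'   `(1 - h2)/h2` times the column variances of `values`, reproducing the
#'   target line-level heritability for a line observed once.
#' @param replicatedFrac fraction of non-check lines evaluated in additional
#'   environments (default 1/3, emulating the multi-location evaluation of
#'   advanced lines).
#' @param nExtraEnvs number of additional environments for a replicated line
#'   (default 2).
#' @return long-format `data.frame` with columns
#'   `line, env, trial, trait, value`.
#' @export
simulateTrials <- function(values, config, residVar = NULL,
                           replicatedFrac = 1 / 3, nExtraEnvs = 2L) {
  stopifnot(inherits(config, "SimConfig"), is.matrix(values))
  n <- nrow(values); t <- ncol(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("L%03d", seq_len(n))
  if (is.null(colnames(values))) colnames(values) <- sprintf("T%d", seq_len(t))
  if (is.null(residVar))
    residVar <- apply(values, 2L, stats::var) * (1 - config$h2) / config$h2
  residVar <- rep_len(residVar, t)
  if (config$nChecks == 0L && config$nEnvironments > 1L)
    warning("no check lines with multiple environments: the trial network is weakly connected")
  set.seed(subSeeds(config$seed, 3L)[3L])
  envOfTrial <- rep(seq_len(config$nEnvironments), length.out = config$nTrials)
  envEff <- stats::rnorm(config$nEnvironments, 0, sqrt(config$envVar))
  trialEff <- stats::rnorm(config$nTrials, 0, sqrt(config$trialVar))
  checks <- seq_len(config$nChecks)
  others <- setdiff(seq_len(n), checks)
  trialOf <- sample(rep(seq_len(config$nTrials), length.out = length(others)))
  lineIdx <- c(rep(checks, each = config$nTrials), others)
  trialIdx <- c(rep(seq_len(config$nTrials), times = config$nChecks), trialOf)
  ## multi-environment evaluation of a subset of lines
  nRep <- round(replicatedFrac * length(others))
  if (nRep > 0L && config$nEnvironments > 1L && nExtraEnvs > 0L) {
    repLines <- sample(others, nRep)
    homeEnv <- envOfTrial[trialOf[match(repLines, others)]]
    for (k in seq_along(repLines)) {
      cand <- setdiff(seq_len(config$nEnvironments), homeEnv[k])
      extraEnvs <- cand[sample.int(length(cand), min(nExtraEnvs, length(cand)))]
      extraTrials <- vapply(extraEnvs, function(ev) {
        cand <- which(envOfTrial == ev)
        cand[sample.int(length(cand), 1L)]
      }, integer(1))
      lineIdx <- c(lineIdx, rep(repLines[k], length(extraTrials)))
      trialIdx <- c(trialIdx, extraTrials)
    }
  }
  nrec <- length(lineIdx)
  recs <- do.call(rbind, lapply(seq_len(t), function(k) {
    data.frame(line = rownames(values)[lineIdx],
               env = sprintf("E%02d", envOfTrial[trialIdx]),
               trial = sprintf("E%02d.T%03d", envOfTrial[trialIdx], trialIdx),
               trait = colnames(values)[k],
               value = values[lineIdx, k] + envEff[envOfTrial[trialIdx]] +
                 trialEff[trialIdx] + stats::rnorm(nrec, 0, sqrt(residVar[k])),
               stringsAsFactors = FALSE)
  }))
  rownames(recs) <- NULL
  recs
}

#' Run the full synthetic study
#'
#' Generates complete genotypes, genetic values and traits from them, applies
#' genotype missingness afterwards (so the truth is defined on the complete
#' panel), and lays the genetic values out on the trial network.
#'
#' @param config a [simConfig()] object.
#' @return list with `geno` (with missingness as configured), `genoComplete`,
#'   `traits` (line-level y = u + e), `truth`, and `pheno` (trial records
#'   generated from the true genetic values with per-record residual variance
#'   `truth$R`).
#' @export
simulateStudy <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cfgComplete <- config; cfgComplete$missingGenoRate <- 0
  geno <- simulateGenotypes(cfgComplete)
  sim <- simulateTraits(geno, config)
  pheno <- simulateTrials(sim$truth$u, config, residVar = sim$truth$R)
  genoObs <- geno
  if (config$missingGenoRate > 0) {
    X <- genoCalls(geno)
    set.seed(subSeeds(config$seed, 4L)[4L])
    nmiss <- stats::rbinom(1L, length(X), config$missingGenoRate)
    X[sample.int(length(X), nmiss)] <- NA
    genoObs <- GenotypeMatrix(X)
  }
  list(geno = genoObs, genoComplete = geno, traits = sim$traits,
       truth = sim$truth, pheno = pheno, config = config)
}
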