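## Adjustment of raw multi-trial phenotypes to per-line BLUEs, heritability
## on an adjusted-mean basis, and environment/trait correlation summaries.
##
## The trial model per trait is
##   y_ijk = mu + g_i + e_j + t_k(j) + eps_ijk
## with genotype and environment fixed and trial-within-environment random.
## Heritability follows the adjusted-means formulation
##   H2 = sigma2_g / (sigma2_g + vbar/2)
## where vbar is the mean variance of a difference of two adjusted means and
## sigma2_g comes from a companion fit with genotype random (the fixed-
## genotype model itself carries no genotypic variance).

.checkPhenoTable <- function(pheno) {
  need <- c("line", "env", "trial", "trait", "value")
  if (!all(need %in% names(pheno)))
    stop("phenotype table must have columns ", paste(need, collapse = ", "))
  et <- unique(pheno[, c("env", "trial")])
  if (anyDuplicated(et$trial))
    stop("trial ids must be nested within environments (a trial in two environments)")
  if (anyDuplicated(pheno[, c("line", "trial", "trait")]))
    stop("duplicate (line, trial, trait) records")
  invisible(pheno)
}

## One-trait REML fit. Returns the pieces fitBlues assembles.
.fitBluesOne <- function(dat) {
  dat$line <- factor(dat$line)
  dat$env <- factor(dat$env)
  dat$trial <- factor(dat$trial)
  n <- nlevels(dat$line)
  comp <- .lineComponents(dat$line, dat$trial)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop("trial network is not connected: ", length(sizes),
         " disconnected line groups of sizes ", paste(sizes, collapse = ", "))
  }
  oneEnv <- nlevels(dat$env) == 1L
  oneTrialPerEnv <- all(tapply(dat$trial, dat$env, function(x) length(unique(x))) == 1L)
  satDesign <- oneTrialPerEnv && !anyDuplicated(dat[, c("line", "trial")])

  if (oneEnv && satDesign) {
    ## saturated single-trial design: BLUEs are the raw values
    fit <- stats::lm(value ~ 0 + line, data = dat)
    b <- stats::coef(fit)
    C <- stats::vcov(fit)
    s2e <- summary(fit)$sigma^2
    if (!is.finite(s2e)) { s2e <- 0; C[] <- 0 }
    s2t <- 0
    est <- b; names(est) <- levels(dat$line)
    se <- sqrt(pmax(diag(C), 0))
    C <- as.matrix(C)
  } else {
    form <- if (oneEnv) value ~ 0 + line else value ~ 0 + line + env
    ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                              check.nobs.vs.rankZ = "ignore",
                              check.nobs.vs.nRE = "ignore",
                              calc.derivs = FALSE)
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(stats::update(form, . ~ . + (1 | trial)), data = dat,
                 REML = TRUE, control = ctrl)))
    fe <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2t <- vc$vcov[vc$grp == "trial"]
    s2e <- vc$vcov[vc$grp == "Residual"]
    lix <- grep("^line", names(fe))
    if (length(lix) < n)
      warning("rank-deficient fixed effects: ", n - length(lix), " line(s) not estimable")
    ## adjusted mean = line coefficient + average environment adjustment
    eix <- grep("^env", names(fe))
    envAdj <- if (length(eix)) mean(c(0, fe[eix])) else 0
    est <- fe[lix] + envAdj
    names(est) <- sub("^line", "", names(fe)[lix])
    C <- V[lix, lix, drop = FALSE]
    if (length(eix)) {
      ## se of the adjusted mean includes the env-average term
      a <- rep(1 / (length(eix) + 1), length(eix))
      Vee <- V[eix, eix, drop = FALSE]
      Vle <- V[lix, eix, drop = FALSE]
      se <- sqrt(pmax(diag(C) + drop(a %*% Vee %*% a) + 2 * drop(Vle %*% a), 0))
    } else se <- sqrt(pmax(diag(C), 0))
  }

  ## vbar: exact mean over all line pairs of Var(BLUE_i - BLUE_j); environment
  ## terms cancel in differences so only the line-coefficient block enters.
  nb <- length(est)
  vbar <- if (nb > 1) 2 * (nb * sum(diag(C)) - sum(C)) / (nb * (nb - 1)) else NA_real_

  ## companion fit, genotype random, for sigma2_g
  s2g <- tryCatch({
    if (satDesign && oneEnv) {
      max(stats::var(dat$value) - s2e, 0)
    } else {
      formR <- if (oneEnv) value ~ 1 + (1 | line) + (1 | trial)
               else value ~ env + (1 | line) + (1 | trial)
      fitR <- suppressMessages(suppressWarnings(
        lme4::lmer(formR, data = dat, REML = TRUE,
                   control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                               check.nobs.vs.nRE = "ignore",
                                               calc.derivs = FALSE))))
      vcR <- as.data.frame(lme4::VarCorr(fitR))
      vcR$vcov[vcR$grp == "line"]
    }
  }, error = function(e) NA_real_)

  list(blues = est, se = se, sigma2Trial = s2t, sigma2Resid = s2e,
       sigma2Geno = s2g, vbar = vbar)
}

#' Fit per-line adjusted means (BLUEs) for each trait
#'
#' Fits, per trait, the linear mixed model with fixed genotype and (when
#' present) environment effects and a random trial-within-environment effect
#' by REML, and a companion fit with genotype random that supplies the
#' genotypic variance for [heritability()]. Errors if the trial network is
#' disconnected (no check lines linking trials), listing the group sizes.
#'
#' @param pheno long-format phenotype table with columns
#'   `line, env, trial, trait, value`.
#' @param traits traits to fit; default all present.
#' @return a [BLUEResult-class].
#' @export
fitBlues <- function(pheno, traits = NULL) {
  .checkPhenoTable(pheno)
  if (is.null(traits)) traits <- unique(as.character(pheno$trait))
  lines <- sort(unique(as.character(pheno$line)))
  t <- length(traits)
  B <- SE <- matrix(NA_real_, length(lines), t, dimnames = list(lines, traits))
  s2t <- s2e <- s2g <- vb <- H2 <- stats::setNames(rep(NA_real_, t), traits)
  for (k in seq_len(t)) {
    dat <- pheno[pheno$trait == traits[k] & !is.na(pheno$value), ]
    if (!nrow(dat)) next
    r <- .fitBluesOne(dat)
    B[names(r$blues), k] <- r$blues
    SE[names(r$blues), k] <- r$se
    s2t[k] <- r$sigma2Trial; s2e[k] <- r$sigma2Resid
    s2g[k] <- r$sigma2Geno; vb[k] <- r$vbar
    H2[k] <- if (is.finite(r$sigma2Geno) && is.finite(r$vbar) && r$vbar > 0)
      heritability(r$sigma2Geno, r$vbar) else NA_real_
  }
  new("BLUEResult", blues = B, se = SE, sigma2Trial = s2t, sigma2Resid = s2e,
      sigma2Geno = s2g, vbar = vb, H2 = H2)
}

#' Heritability on an adjusted-mean basis
#'
#' `H2 = sigma2_g / (sigma2_g + vbar/2)` with `vbar` the mean variance of a
#' difference of two adjusted means.
#'
#' @param sigma2g genotypic variance (>= 0).
#' @param vbar mean variance of a difference of two adjusted means (> 0).
#' @return heritability in \[0, 1\].
#' @examples
#' heritability(1, 2)   # 0.5
#' heritability(3, 2)   # 0.75
#' @export
heritability <- function(sigma2g, vbar) {
  if (any(sigma2g < 0)) stop("sigma2g must be non-negative")
  if (any(vbar <= 0)) stop("vbar must be positive")
  sigma2g / (sigma2g + vbar / 2)
}

#' Pearson correlations between environments, per trait
#'
#' BLUEs are computed separately inside each environment (the trial model
#' without the environment term) and correlated pairwise over the lines the
#' two environments share; cells backed by fewer than `minShared` shared
#' lines are set to `NA`.
#'
#' @param pheno long-format phenotype table.
#' @param traits traits to process; default all.
#' @param minShared minimum number of shared lines per cell (default 3).
#' @return named list of environment x environment correlation matrices.
#' @export
envCorrelations <- function(pheno, traits = NULL, minShared = 3L) {
  .checkPhenoTable(pheno)
  if (is.null(traits)) traits <- unique(as.character(pheno$trait))
  envs <- sort(unique(as.character(pheno$env)))
  out <- list()
  for (tr in traits) {
    perEnv <- lapply(envs, function(ev) {
      dat <- pheno[pheno$trait == tr & pheno$env == ev & !is.na(pheno$value), ]
      if (!nrow(dat)) return(stats::setNames(numeric(0), character(0)))
      tryCatch(.fitBluesOne(dat)$blues,
               error = function(e) stats::setNames(numeric(0), character(0)))
    })
    names(perEnv) <- envs
    M <- matrix(NA_real_, length(envs), length(envs), dimnames = list(envs, envs))
    diag(M) <- 1
    for (i in seq_along(envs)) for (j in seq_len(i - 1L)) {
      shared <- intersect(names(perEnv[[i]]), names(perEnv[[j]]))
      if (length(shared) >= minShared)
        M[i, j] <- M[j, i] <- stats::cor(perEnv[[i]][shared], perEnv[[j]][shared])
    }
    out[[tr]] <- M
  }
  out
}

#' Trait correlation matrix and PCA of standardized traits
#'
#' @param bluesMat lines x traits matrix of adjusted means (e.g.
#'   `blues(fitBlues(...))`).
#' @return list with `correlation` (pairwise-complete Pearson; constant
#'   columns give `NA` cells), `loadings`, and `explained` — the fractions of
#'   variance per principal component (summing to 1).
#' @export
traitSummary <- function(bluesMat) {
  bluesMat <- as.matrix(bluesMat)
  if (nrow(bluesMat) < 3) stop("need at least 3 lines")
  cc <- suppressWarnings(stats::cor(bluesMat, use = "pairwise.complete.obs"))
  complete <- stats::complete.cases(bluesMat)
  keep <- apply(bluesMat[complete, , drop = FALSE], 2L, stats::sd) > 0
  pca <- stats::prcomp(bluesMat[complete, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  expl <- pca$sdev^2 / sum(pca$sdev^2)
  list(correlation = cc, loadings = pca$rotation, explained = expl)
}
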