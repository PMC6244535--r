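## Phenotyping-budget cross-validation designs and sweeps.
##
## Schemes:
##   ST-CV1      single-trait model; test lines have no phenotypes.
##   MT-CV1      multi-trait model; test lines unphenotyped for every trait.
##   MT-CV2      test lines phenotyped for the correlated traits only.
##   MT-CV2-50b  correlated traits phenotyped on the same half of train and
##               test lines (balanced).
##   MT-CV2-50u  correlated traits phenotyped on different halves per trait
##               (unbalanced): train and test sets are each split into four
##               quarters and every correlated trait masks a distinct pair
##               of train quarters and of test quarters.
## Predictive ability is the Pearson correlation between adjusted means and
## predicted genetic values on the lines not phenotyped for the target.

.splitQuarters <- function(ids) {
  ## seeded random assignment to 4 quarters; remainders round-robin
  q <- rep_len(1:4, length(ids))
  split(ids, q[sample.int(length(ids))])
}

.newMask <- function(observed, scheme, targetTrait, seed) {
  new("MaskPlan", observed = observed, scheme = scheme,
      targetTrait = targetTrait, seed = as.integer(seed))
}

#' CV1 mask: test lines unphenotyped for every trait
#'
#' @param lineNames line identifiers (or an integer n).
#' @param trainCount number of training lines, 0 < trainCount < n.
#' @param traits trait names entering the model.
#' @param targetTrait the predicted trait (defaults to the first).
#' @param seed plan seed.
#' @return a [MaskPlan-class].
#' @export
makeMaskCV1 <- function(lineNames, trainCount, traits, targetTrait = traits[1], seed = 1L) {
  if (is.numeric(lineNames) && length(lineNames) == 1L)
    lineNames <- sprintf("L%03d", seq_len(lineNames))
  n <- length(lineNames)
  stopifnot(trainCount > 0, trainCount < n)
  set.seed(seed)
  train <- sample.int(n, trainCount)
  obs <- matrix(FALSE, n, length(traits), dimnames = list(lineNames, traits))
  obs[train, ] <- TRUE
  .newMask(obs, "CV1", targetTrait, seed)
}

#' CV2 mask: target trait on the train set, correlated traits everywhere
#'
#' Traits outside `{targetTrait} U correlatedTraits` are excluded from the
#' model entirely (the plan's columns are exactly the modelled traits).
#'
#' @inheritParams makeMaskCV1
#' @param correlatedTraits non-empty set of traits observed on all lines
#'   (1 to 3 of them give the 2T/3T/4T designs).
#' @return a [MaskPlan-class].
#' @export
makeMaskCV2 <- function(lineNames, trainCount, targetTrait, correlatedTraits, seed = 1L) {
  if (is.numeric(lineNames) && length(lineNames) == 1L)
    lineNames <- sprintf("L%03d", seq_len(lineNames))
  n <- length(lineNames)
  stopifnot(trainCount > 0, trainCount < n)
  if (length(correlatedTraits) == 0)
    stop("CV2 needs at least one correlated trait (with none it is CV1)")
  if (targetTrait %in% correlatedTraits)
    stop("target trait cannot be one of the correlated traits")
  set.seed(seed)
  train <- sample.int(n, trainCount)
  traits <- c(targetTrait, correlatedTraits)
  obs <- matrix(TRUE, n, length(traits), dimnames = list(lineNames, traits))
  obs[, targetTrait] <- FALSE
  obs[train, targetTrait] <- TRUE
  .newMask(obs, "CV2", targetTrait, seed)
}

#' CV2 mask with 50% phenotyping of the correlated traits
#'
#' Train and test sets are each divided into four quarters (random, with
#' remainders assigned round-robin). Every correlated trait is observed on
#' exactly two train quarters and two test quarters (about half of each).
#' In `balanced` mode all correlated traits share the same observed halves;
#' in `unbalanced` mode each correlated trait is assigned a distinct pair of
#' quarters (cycling through the six possible pairs in seeded random order,
#' separately for train and test), so different lines are phenotyped for
#' different traits.
#'
#' @inheritParams makeMaskCV2
#' @param mode `"balanced"` or `"unbalanced"`.
#' @return a [MaskPlan-class].
#' @export
makeMaskCV2Partial <- function(lineNames, trainCount, targetTrait,
                               correlatedTraits, mode = c("balanced", "unbalanced"),
                               seed = 1L) {
  mode <- match.arg(mode)
  if (is.numeric(lineNames) && length(lineNames) == 1L)
    lineNames <- sprintf("L%03d", seq_len(lineNames))
  n <- length(lineNames)
  stopifnot(trainCount > 0, trainCount < n)
  if (length(correlatedTraits) == 0) stop("need at least one correlated trait")
  if (trainCount < 4L || (n - trainCount) < 4L)
    stop("train and test sets must each have at least 4 lines to form quarters")
  set.seed(seed)
  train <- sample.int(n, trainCount)
  test <- setdiff(seq_len(n), train)
  qTrain <- .splitQuarters(train)
  qTest <- .splitQuarters(test)
  pairs <- utils::combn(4L, 2L, simplify = FALSE)   # 6 candidate quarter-pairs
  nc <- length(correlatedTraits)
  if (mode == "balanced") {
    trainPair <- rep(list(pairs[[sample.int(6L, 1L)]]), nc)
    testPair <- rep(list(pairs[[sample.int(6L, 1L)]]), nc)
  } else {
    trainPair <- pairs[sample.int(6L)][seq_len(nc)]
    testPair <- pairs[sample.int(6L)][seq_len(nc)]
  }
  traits <- c(targetTrait, correlatedTraits)
  obs <- matrix(FALSE, n, length(traits), dimnames = list(lineNames, traits))
  obs[train, targetTrait] <- TRUE
  for (k in seq_len(nc)) {
    maskedTrain <- unlist(qTrain[trainPair[[k]]])
    maskedTest <- unlist(qTest[testPair[[k]]])
    obs[, correlatedTraits[k]] <- TRUE
    obs[c(maskedTrain, maskedTest), correlatedTraits[k]] <- FALSE
  }
  .newMask(obs, if (mode == "balanced") "CV2-50b" else "CV2-50u", targetTrait, seed)
}

## Build a mask for one CV iteration of a given scheme.
.maskForScheme <- function(scheme, lineNames, trainCount, targetTrait,
                           correlatedTraits, seed) {
  switch(scheme,
    "ST-CV1" = makeMaskCV1(lineNames, trainCount, targetTrait, targetTrait, seed),
    "MT-CV1" = makeMaskCV1(lineNames, trainCount,
                           c(targetTrait, correlatedTraits), targetTrait, seed),
    "MT-CV2" = makeMaskCV2(lineNames, trainCount, targetTrait, correlatedTraits, seed),
    "MT-CV2-50b" = makeMaskCV2Partial(lineNames, trainCount, targetTrait,
                                      correlatedTraits, "balanced", seed),
    "MT-CV2-50u" = makeMaskCV2Partial(lineNames, trainCount, targetTrait,
                                      correlatedTraits, "unbalanced", seed),
    stop("unknown scheme: ", scheme))
}

#' Run a cross-validation design
#'
#' For each iteration a fresh mask is drawn with an iteration-specific
#' sub-seed, the designated model is fitted on the masked phenotypes
#' ([fitGBLUP()] for ST-CV1, [fitMT()] otherwise, with the identity kernel
#' when `useMarkers = FALSE`), and the Pearson correlation between adjusted
#' means and predicted genetic values is computed on the lines not
#' phenotyped for the target trait. Iterations whose model fit fails are
#' skipped with a warning; more than 10\% failures abort the run.
#'
#' @param bluesMat lines x traits matrix of adjusted means.
#' @param K a [KinshipMatrix-class] or matrix aligned with `bluesMat` rows
#'   (ignored when `useMarkers = FALSE`).
#' @param scheme one of `"ST-CV1"`, `"MT-CV1"`, `"MT-CV2"`, `"MT-CV2-50b"`,
#'   `"MT-CV2-50u"`.
#' @param targetTrait predicted trait.
#' @param correlatedTraits 1-3 correlated traits (the 2T/3T/4T sets);
#'   ignored for `"ST-CV1"`.
#' @param trainCount training-set size (50 to n-1); alternatively give
#'   `trainFraction`.
#' @param trainFraction training fraction of n, used when `trainCount` is
#'   missing.
#' @param nIterations CV iterations (default 100).
#' @param seed master seed; per-iteration sub-seeds come from [subSeeds()].
#' @param useMarkers use the kinship kernel (`TRUE`) or the identity
#'   (`FALSE`, the no-marker variant).
#' @param stCfg,mtCfg sampler configurations (chain seeds are overridden per
#'   iteration).
#' @param fitter optional override `function(Ymasked, K, mask)` returning a
#'   full prediction vector for the target trait (testing hook).
#' @return a [CVResult-class].
#' @export
runCV <- function(bluesMat, K, scheme, targetTrait, correlatedTraits = NULL,
                  trainCount = NULL, trainFraction = 0.6, nIterations = 100L,
                  seed = 1L, useMarkers = TRUE,
                  stCfg = stConfig(), mtCfg = mtConfig(), fitter = NULL) {
  bluesMat <- as.matrix(bluesMat)
  n <- nrow(bluesMat)
  if (is.null(rownames(bluesMat))) rownames(bluesMat) <- sprintf("L%03d", seq_len(n))
  if (is.null(trainCount)) trainCount <- round(trainFraction * n)
  if (scheme != "ST-CV1") {
    if (is.null(correlatedTraits) || !length(correlatedTraits))
      stop("multi-trait schemes need correlatedTraits")
    if (length(correlatedTraits) > 3L)
      stop("at most 3 correlated traits (2T/3T/4T designs)")
  }
  stopifnot(targetTrait %in% colnames(bluesMat))
  KK <- if (is(K, "KinshipMatrix")) kinship(K) else if (is.null(K)) NULL else as.matrix(K)
  Keig <- if (!is.null(KK) && useMarkers && scheme != "ST-CV1") .kinshipEigen(KK) else NULL
  seeds <- subSeeds(seed, nIterations)
  rows <- vector("list", nIterations)
  nFail <- 0L
  for (i in seq_len(nIterations)) {
    mask <- .maskForScheme(scheme, rownames(bluesMat), trainCount,
                           targetTrait, correlatedTraits, seeds[i])
    obs <- observedCells(mask)
    Ym <- bluesMat[, colnames(obs), drop = FALSE]
    Ym[!obs] <- NA
    test <- testLines(mask)
    pred <- tryCatch({
      if (!is.null(fitter)) {
        fitter(Ym, KK, mask)
      } else if (scheme == "ST-CV1") {
        fit <- fitGBLUP(Ym[, targetTrait],
                        if (useMarkers) KK else diag(n),
                        stConfig(nIter = stCfg$nIter, burnIn = stCfg$burnIn,
                                 df0 = stCfg$df0, scaleFrac = stCfg$scaleFrac,
                                 seed = seeds[i]))
        fit@g
      } else {
        cfg <- mtConfig(nIter = mtCfg$nIter, burnIn = mtCfg$burnIn,
                        dfSigma = mtCfg$dfSigma, SSigma = mtCfg$SSigma,
                        dfR = mtCfg$dfR, SR = mtCfg$SR, seed = seeds[i])
        fit <- fitMT(Ym, K = if (useMarkers) KK else NULL, config = cfg,
                     Keig = if (useMarkers) Keig else NULL)
        predictMT(fit, targetTrait)
      }
    }, error = function(e) e)
    if (inherits(pred, "error")) {
      nFail <- nFail + 1L
      warning("iteration ", i, " failed: ", conditionMessage(pred))
      rows[[i]] <- data.frame(iteration = i, cor = NA_real_, nTest = length(test))
      next
    }
    rows[[i]] <- data.frame(
      iteration = i,
      cor = stats::cor(bluesMat[test, targetTrait], pred[test],
                       use = "complete.obs"),
      nTest = length(test))
  }
  if (nFail > 0.1 * nIterations)
    stop("more than 10% of CV iterations failed (", nFail, "/", nIterations, ")")
  new("CVResult", results = do.call(rbind, rows), scheme = scheme,
      targetTrait = targetTrait,
      design = list(trainCount = trainCount, nIterations = nIterations,
                    correlatedTraits = correlatedTraits, seed = seed,
                    useMarkers = useMarkers))
}

#' Sweep the training-population size
#'
#' Runs [runCV()] at each size for each scheme and returns a tidy table
#' suitable for plotting predictive-ability curves against phenotyping
#' budget.
#'
#' @inheritParams runCV
#' @param sizes vector of training-set sizes.
#' @param schemes schemes to run at every size.
#' @return data.frame with columns
#'   `size, scheme, nTraits, mean, sd, nIterations`.
#' @export
sweepTrainingSize <- function(bluesMat, K, sizes, schemes, targetTrait,
                              correlatedTraits = NULL, nIterations = 100L,
                              seed = 1L, useMarkers = TRUE,
                              stCfg = stConfig(), mtCfg = mtConfig()) {
  grid <- expand.grid(size = sizes, scheme = schemes, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(k) {
    res <- runCV(bluesMat, K, grid$scheme[k], targetTrait, correlatedTraits,
                 trainCount = grid$size[k], nIterations = nIterations,
                 seed = seed, useMarkers = useMarkers, stCfg = stCfg, mtCfg = mtCfg)
    s <- cvSummary(res)
    data.frame(size = grid$size[k], scheme = grid$scheme[k],
               nTraits = if (grid$scheme[k] == "ST-CV1") 1L else length(correlatedTraits) + 1L,
               mean = unname(s["mean"]), sd = unname(s["sd"]),
               nIterations = nIterations)
  })
  do.call(rbind, out)
}

#' Plot a training-size sweep
#'
#' Predictive-ability curves with a shaded +-SD band, one colour per scheme.
#'
#' @param sweep output of [sweepTrainingSize()].
#' @return a ggplot object.
#' @export
plotSweep <- function(sweep) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotSweep() needs the ggplot2 package")
  ggplot2::ggplot(sweep, ggplot2::aes(x = size, y = mean,
                                      colour = scheme, fill = scheme)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - sd, ymax = mean + sd),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "training-population size",
                  y = "predictive ability r(y, y-hat)") +
    ggplot2::theme_minimal()
}
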