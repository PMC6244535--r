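## Exact combinatorial constraints of every masking scheme, then behaviour
## of the cross-validation driver itself.

test_that("CV1 masks a clean train/test split for all traits", {
  m <- makeMaskCV1(495, 297, c("W", "SV", "MH"), "W", seed = 2)
  obs <- observedCells(m)
  expect_equal(sum(obs), 297 * 3)
  expect_equal(sum(!obs), 198 * 3)
  ## test lines observed for nothing
  expect_true(all(rowSums(obs) %in% c(0L, 3L)))
  ## n-1 training lines leaves a single test line
  m1 <- makeMaskCV1(10, 9, "y", seed = 3)
  expect_equal(length(testLines(m1)), 1L)
  ## determinism
  expect_identical(observedCells(makeMaskCV1(50, 30, "y", seed = 5)),
                   observedCells(makeMaskCV1(50, 30, "y", seed = 5)))
})

test_that("CV2 masks observe correlated traits everywhere and the target on train only", {
  m <- makeMaskCV2(495, 297, "W", c("SV", "MH", "TW"), seed = 4)
  obs <- observedCells(m)
  expect_equal(sum(obs), 297 + 3 * 495)
  expect_true(all(obs[, c("SV", "MH", "TW")]))
  expect_equal(sum(obs[, "W"]), 297)
  expect_equal(length(testLines(m)), 198)
  expect_error(makeMaskCV2(100, 60, "W", character(0)), "CV1")
  expect_error(makeMaskCV2(100, 60, "W", c("W", "SV")), "cannot")
})

test_that("50% masking plans satisfy their exact quarter constraints", {
  for (n in c(16L, 100L, 495L)) {
    trainCount <- round(0.6 * n)
    testCount <- n - trainCount
    for (seed in 1:5) {
      for (mode in c("balanced", "unbalanced")) {
        m <- makeMaskCV2Partial(n, trainCount, "W", c("SV", "MH", "TW"),
                                mode = mode, seed = seed)
        obs <- observedCells(m)
        trainSet <- rownames(obs)[obs[, "W"]]
        testSet <- testLines(m)
        expect_equal(length(trainSet), trainCount)
        ## each correlated trait observed on ~half of train and half of test:
        ## exactly the sum of two quarters, quarters differing by at most 1
        for (tr in c("SV", "MH", "TW")) {
          oTr <- sum(obs[trainSet, tr])
          oTe <- sum(obs[testSet, tr])
          expect_gte(oTr, 2 * floor(trainCount / 4))
          expect_lte(oTr, 2 * ceiling(trainCount / 4))
          expect_gte(oTe, 2 * floor(testCount / 4))
          expect_lte(oTe, 2 * ceiling(testCount / 4))
        }
        cols <- lapply(c("SV", "MH", "TW"), function(tr) obs[, tr])
        if (mode == "balanced") {
          ## same lines phenotyped in every correlated trait
          expect_identical(cols[[1]], cols[[2]])
          expect_identical(cols[[1]], cols[[3]])
        } else {
          ## distinct quarter-pairs: no two traits share their observed set,
          ## and the union of observed test lines exceeds any single trait's
          expect_false(identical(cols[[1]], cols[[2]]))
          expect_false(identical(cols[[1]], cols[[3]]))
          expect_false(identical(cols[[2]], cols[[3]]))
          uni <- Reduce(`|`, lapply(cols, function(cl) cl[testSet]))
          expect_gt(sum(uni), max(vapply(cols, function(cl) sum(cl[testSet]), numeric(1))))
        }
      }
    }
  }
  expect_error(makeMaskCV2Partial(10, 7, "W", "SV"), "at least 4")
})

test_that("an oracle predictor scores predictive ability 1", {
  p <- makePanel(n = 60, m = 100, t = 2, rg = 0.5, seed = 31)
  oracle <- function(Y, K, mask) p$traits[, "T1"]
  res <- runCV(p$traits, p$K, "MT-CV2", "T1", "T2", trainCount = 36,
               nIterations = 3, seed = 7, fitter = oracle)
  expect_equal(cvIterations(res)$cor, rep(1, 3))
})

test_that("test sets never include lines phenotyped for the target trait", {
  p <- makePanel(n = 40, m = 80, t = 2, rg = 0.5, seed = 32)
  seen <- list()
  spy <- function(Y, K, mask) {
    obs <- observedCells(mask)
    seen[[length(seen) + 1L]] <<- list(test = testLines(mask), obs = obs)
    p$traits[, "T1"]
  }
  for (sch in c("ST-CV1", "MT-CV1", "MT-CV2", "MT-CV2-50b", "MT-CV2-50u")) {
    seen <- list()
    runCV(p$traits, p$K, sch, "T1", "T2", trainCount = 24,
          nIterations = 2, seed = 3, fitter = spy)
    for (s in seen)
      expect_false(any(s$obs[s$test, "T1"]))
  }
})

test_that("runCV is reproducible and a pure-noise trait predicts at zero", {
  set.seed(40)
  n <- 80
  Y <- matrix(rnorm(n), n, 1, dimnames = list(sprintf("L%03d", 1:n), "T1"))
  p <- makePanel(n = n, m = 150, t = 1, rg = 0, seed = 33)
  r1 <- runCV(Y, p$K, "ST-CV1", "T1", trainCount = 48, nIterations = 10,
              seed = 5, stCfg = fastST())
  r2 <- runCV(Y, p$K, "ST-CV1", "T1", trainCount = 48, nIterations = 10,
              seed = 5, stCfg = fastST())
  expect_identical(cvIterations(r1)$cor, cvIterations(r2)$cor)
  s <- cvSummary(r1)
  expect_lt(abs(s["mean"]), 2 * s["sd"] / sqrt(s["n"]) + 0.15)
})

test_that("the training-size sweep emits one row per size and scheme with a rising trend", {
  p <- makePanel(n = 100, m = 200, t = 2, rg = 0.8, h2 = 0.6, seed = 34)
  sizes <- c(20, 40, 60, 80)
  sw <- sweepTrainingSize(p$traits, p$K, sizes, c("ST-CV1", "MT-CV2"), "T1",
                          correlatedTraits = "T2", nIterations = 4, seed = 6,
                          stCfg = fastST(), mtCfg = fastMT())
  expect_equal(nrow(sw), length(sizes) * 2)
  expect_equal(sort(unique(sw$size)), sizes)
  st <- sw[sw$scheme == "ST-CV1", ]
  expect_gt(cor(st$size, st$mean, method = "spearman"), 0)
})

test_that("phenotyping depth orders the schemes: full CV2, half CV2, CV1", {
  ## reduced-scale version of the central design comparison: deeper
  ## phenotyping of correlated traits on the prediction targets never hurts
  cfg <- simConfig(nIndividuals = 160, nMarkers = 400, nTraits = 4,
                   h2 = rep(0.5, 4), geneticCorr = equiCorr(4, 0.8), seed = 61)
  g <- simulateGenotypes(cfg)
  sim <- simulateTraits(g, cfg)
  K <- additiveK(g)
  stC <- stConfig(nIter = 1000, burnIn = 400)
  mtC <- mtConfig(nIter = 1000, burnIn = 400)
  m <- vapply(c("ST-CV1", "MT-CV1", "MT-CV2-50b", "MT-CV2-50u", "MT-CV2"),
              function(sch) cvSummary(runCV(sim$traits, K, sch, "T1",
                                            c("T2", "T3", "T4"),
                                            trainCount = 96, nIterations = 10,
                                            seed = 3, stCfg = stC,
                                            mtCfg = mtC))["mean"],
              numeric(1))
  expect_gt(m[["MT-CV2"]], m[["MT-CV2-50u"]])
  expect_gt(m[["MT-CV2-50u"]], m[["MT-CV1"]])
  expect_lt(abs(m[["MT-CV2-50u"]] - m[["MT-CV2-50b"]]), 0.1)
  expect_gt(m[["MT-CV1"]], m[["ST-CV1"]] - 0.05)
})
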