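test_that("multi-trait posterior summaries are reproducible and well-formed", {
  p <- makePanel(n = 80, m = 150, t = 3, rg = 0.5, seed = 21)
  f1 <- fitMT(p$traits, p$K, fastMT(seed = 7))
  f2 <- fitMT(p$traits, p$K, fastMT(seed = 7))
  expect_identical(geneticValues(f1), geneticValues(f2))
  expect_identical(geneticCovariance(f1), geneticCovariance(f2))
  S <- geneticCovariance(f1)
  expect_lt(max(abs(S - t(S))), 1e-10)
  expect_gt(min(eigen(S, only.values = TRUE)$values), 0)
  expect_true(all(residualVariances(f1) > 0))
  expect_equal(unname(diag(geneticCorrelation(f1))), rep(1, 3))
})

test_that("a single-trait multi-trait fit agrees with the G-BLUP fit", {
  p <- makePanel(n = 200, m = 400, t = 1, rg = 0, h2 = 0.5, seed = 22)
  Y <- p$traits
  fmt <- fitMT(Y, p$K, mtConfig(seed = 5))
  fst <- fitGBLUP(Y[, 1], p$K, stConfig(seed = 5))
  expect_gt(cor(geneticValues(fmt)[, 1], fst@g), 0.98)
})

test_that("genetic correlations are recovered and a diagonal truth stays diagonal", {
  ## diagonal Sigma: posterior off-diagonal correlations centred on zero
  ## (averaged over datasets; a single posterior has sd ~ 0.1 at n = 300)
  off0 <- unlist(lapply(1:4, function(s) {
    p0 <- makePanel(n = 300, m = 600, t = 3, rg = 0, seed = 22 + s)
    f0 <- fitMT(p0$traits, p0$K, mtConfig(seed = 3))
    geneticCorrelation(f0)[upper.tri(diag(3))]
  }))
  expect_lt(mean(abs(off0)), 0.15)
  expect_lt(abs(mean(off0)), 0.1)
  ## strong correlation: posterior lands in a sensible band
  p8 <- makePanel(n = 300, m = 400, t = 2, rg = 0.8, seed = 24)
  f8 <- fitMT(p8$traits, p8$K, mtConfig(seed = 3))
  expect_gt(geneticCorrelation(f8)[1, 2], 0.6)
  expect_lt(geneticCorrelation(f8)[1, 2], 0.95)
})

test_that("permuting trait order permutes the posterior covariance consistently", {
  p <- makePanel(n = 150, m = 300, t = 3, rg = 0.6, seed = 25)
  perm <- c(2, 3, 1)
  f1 <- fitMT(p$traits, p$K, mtConfig(seed = 9))
  f2 <- fitMT(p$traits[, perm], p$K, mtConfig(seed = 9))
  ## same posterior up to MCMC error, with rows/columns permuted
  expect_equal(unname(geneticCovariance(f2)),
               unname(geneticCovariance(f1)[perm, perm]), tolerance = 0.12)
  expect_equal(unname(geneticValues(f2)), unname(geneticValues(f1)[, perm]),
               tolerance = 0.15)
})

test_that("predictMT returns masked-line predictions driven by kinship and correlated traits", {
  p <- makePanel(n = 150, m = 300, t = 2, rg = 0.8, seed = 26)
  test <- sprintf("L%03d", 101:150)
  Y <- p$traits
  Y[test, "T1"] <- NA
  fit <- fitMT(Y, p$K, fastMT(seed = 2))
  pr <- predictMT(fit, "T1", test)
  expect_named(pr, test)
  ## observed lines track their own phenotype more tightly than masked lines
  rObs <- cor(p$traits[1:100, "T1"], predictMT(fit, "T1")[1:100])
  rMask <- cor(p$traits[test, "T1"], pr)
  expect_gt(rObs, rMask)
  expect_error(predictMT(fit, "T9"), "unknown trait")
  expect_error(predictMT(fit, "T1", "nope"), "unknown line")
})

test_that("with diagonal truth and identity kernel, unphenotyped lines shrink to the prior mean", {
  set.seed(30)
  n <- 120
  Y <- matrix(rnorm(2 * n), n, 2, dimnames = list(sprintf("L%03d", 1:n), c("T1", "T2")))
  Y[1:30, "T1"] <- NA   # no own-trait data, no kinship, uncorrelated traits
  fit <- fitMTNoMarker(Y, fastMT(seed = 8))
  expect_lt(max(abs(predictMT(fit, "T1", sprintf("L%03d", 1:30)))), 0.35)
  ## identity passed explicitly is the same computation
  fit2 <- fitMT(Y, K = diag(n), config = fastMT(seed = 8))
  expect_identical(geneticValues(fit), geneticValues(fit2))
  expect_identical(geneticCovariance(fit), geneticCovariance(fit2))
})

test_that("correlated traits observed on target lines raise predictive ability without markers", {
  p <- makePanel(n = 200, m = 400, t = 2, rg = 0.8, seed = 27)
  test <- sprintf("L%03d", 141:200)
  ## CV2-style: correlated trait observed on everyone, target masked on test
  Ycv2 <- p$traits; Ycv2[test, "T1"] <- NA
  fcv2 <- fitMTNoMarker(Ycv2, fastMT(seed = 4))
  rcv2 <- cor(p$traits[test, "T1"], predictMT(fcv2, "T1", test))
  ## CV1-style without markers: nothing to learn from for test lines
  Ycv1 <- p$traits; Ycv1[test, ] <- NA
  fcv1 <- fitMTNoMarker(Ycv1, fastMT(seed = 4))
  rcv1 <- cor(p$traits[test, "T1"], predictMT(fcv1, "T1", test))
  expect_gt(rcv2, rcv1 + 0.2)
})

test_that("ill-posed multi-trait inputs are rejected", {
  Y <- matrix(rnorm(20), 10, 2, dimnames = list(sprintf("L%03d", 1:10), c("T1", "T2")))
  Y[2:10, 2] <- NA
  expect_error(fitMT(Y, NULL, fastMT()), "fewer than 2")
  expect_error(fitMT(Y[, 1, drop = FALSE], K = diag(5)), "nrow")
})
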