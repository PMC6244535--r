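test_that("heritability formula matches its closed form and is monotone", {
  expect_equal(heritability(1, 2), 0.5)
  expect_equal(heritability(0, 2), 0)
  expect_equal(heritability(3, 2), 0.75)
  expect_error(heritability(-1, 2), "non-negative")
  expect_error(heritability(1, 0), "positive")
  ## increasing in sigma2_g, decreasing in vbar
  sg <- seq(0.1, 5, length.out = 20)
  expect_true(all(diff(heritability(sg, 2)) > 0))
  vb <- seq(0.1, 5, length.out = 20)
  expect_true(all(diff(vapply(vb, function(v) heritability(1, v), numeric(1))) < 0))
})

test_that("saturated single-trial design returns raw values as BLUEs", {
  ph <- data.frame(line = sprintf("L%02d", 1:8), env = "E1", trial = "T1",
                   trait = "y", value = rnorm(8))
  bl <- fitBlues(ph)
  expect_equal(unname(blues(bl)[ph$line, "y"]), ph$value)
  expect_equal(unname(bl@sigma2Trial["y"]), 0)
})

test_that("balanced trial effects cancel in the adjusted means", {
  ph <- balancedTwoTrial(nLines = 6, trialEff = c(1, -1))
  bl <- suppressWarnings(fitBlues(ph))
  ## per-line mean across the two trials is the line value itself
  lineMeans <- tapply(ph$value, ph$line, mean)
  expect_equal(unname(blues(bl)[sprintf("L%02d", 1:6), "y"]),
               as.numeric(lineMeans[sprintf("L%02d", 1:6)]), tolerance = 0.02)
  ## invariance to adding a constant to one trial (absorbed by trial effect)
  ph2 <- ph
  ph2$value[ph2$trial == "T1"] <- ph2$value[ph2$trial == "T1"] + 10
  bl2 <- suppressWarnings(fitBlues(ph2))
  d <- blues(bl2)[, "y"] - blues(bl)[, "y"]
  expect_lt(diff(range(d)), 1e-6)
})

test_that("REML matches the ANOVA moment estimator on a balanced design", {
  set.seed(42)
  nl <- 12; nt <- 6
  trialEff <- rnorm(nt, 0, 2)
  ph <- do.call(rbind, lapply(seq_len(nt), function(k)
    data.frame(line = sprintf("L%02d", 1:nl), env = "E1",
               trial = sprintf("T%d", k), trait = "y",
               value = rep(0, nl) + trialEff[k] + rnorm(nl, 0, 1))))
  bl <- fitBlues(ph)
  ## two-way balanced ANOVA (lines and trials): method-of-moments estimator
  fit <- aov(value ~ line + trial, data = ph)
  ms <- summary(fit)[[1]]$`Mean Sq`
  mom <- (ms[2] - ms[3]) / nl
  expect_equal(unname(bl@sigma2Trial["y"]), mom, tolerance = 1e-4)
  expect_equal(unname(bl@sigma2Resid["y"]), ms[3], tolerance = 1e-4)
})

test_that("trial variance is recovered from the simulated network", {
  cfg <- simConfig(nIndividuals = 495, nMarkers = 100, nTraits = 1, h2 = 0.5,
                   trialVar = 4, seed = 31)
  st <- simulateStudy(cfg)
  bl <- fitBlues(st$pheno)
  expect_gt(unname(bl@sigma2Trial["T1"]), 2.5)
  expect_lt(unname(bl@sigma2Trial["T1"]), 5.5)
})

test_that("a disconnected trial network is reported with its groups", {
  ph <- data.frame(line = c("A", "B", "C", "D"), env = c("E1", "E1", "E2", "E2"),
                   trial = c("T1", "T1", "T2", "T2"), trait = "y",
                   value = rnorm(4))
  expect_error(fitBlues(ph), "not connected")
})

test_that("environment correlations use shared lines and respect the minimum", {
  ## duplicated environment -> correlation 1
  base <- data.frame(line = sprintf("L%02d", 1:10), env = "E1", trial = "T1",
                     trait = "y", value = rnorm(10))
  dup <- transform(base, env = "E2", trial = "T2")
  ec <- envCorrelations(rbind(base, dup))
  expect_equal(ec$y["E1", "E2"], 1)
  ## fewer than 3 shared lines -> NA cell
  small <- rbind(base, transform(base[1:2, ], env = "E3", trial = "T3"))
  ec2 <- envCorrelations(small)
  expect_true(is.na(ec2$y["E1", "E3"]))
  ## independent noise -> correlation near 0 on average over seeds
  rs <- vapply(1:6, function(s) {
    set.seed(s)
    a <- transform(base, value = rnorm(10))
    b <- transform(base, env = "E2", trial = "T2", value = rnorm(10))
    envCorrelations(rbind(a, b))$y["E1", "E2"]
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.4)
})

test_that("trait summary obeys PCA identities and separates trait groups", {
  set.seed(8)
  ## two collinear traits
  x <- rnorm(30)
  ts2 <- traitSummary(cbind(a = x, b = 2 * x + 1))
  expect_equal(ts2$correlation["a", "b"], 1)
  expect_equal(ts2$explained[1], 1, tolerance = 1e-9)
  ## explained fractions always sum to 1
  Y <- matrix(rnorm(200), 40, 5)
  expect_equal(sum(traitSummary(Y)$explained), 1, tolerance = 1e-9)
  ## constant column -> NA correlation cell
  tsc <- traitSummary(cbind(a = rnorm(20), b = rep(1, 20)))
  expect_true(is.na(tsc$correlation["a", "b"]))
  ## two-group covariance shows up as a sign-coherent PC structure
  p <- makePanel(n = 300, m = 300, t = 4, rg = 0, seed = 13)
  cfgG <- simConfig(nIndividuals = 300, nMarkers = 300, nTraits = 8,
                    h2 = rep(0.6, 8), withinCorr = 0.7, seed = 14)
  simG <- simulateTraits(simulateGenotypes(cfgG), cfgG)
  tsG <- traitSummary(simG$traits)
  l1 <- tsG$loadings[, 1]; l2 <- tsG$loadings[, 2]
  grp1 <- 1:4; grp2 <- 5:8
  ## on one of the first two PCs the groups load with opposite signs
  sep <- function(l) abs(mean(sign(l[grp1])) - mean(sign(l[grp2]))) == 2
  expect_true(sep(l1) || sep(l2))
})
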