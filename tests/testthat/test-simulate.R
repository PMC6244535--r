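test_that("genotype simulation is deterministic and respects Hardy-Weinberg at p = 0.5", {
  cfg <- simConfig(nIndividuals = 500, nMarkers = 40, nTraits = 2,
                   mafRange = c(0.5, 0.5), h2 = c(0.5, 0.5), seed = 7)
  g1 <- simulateGenotypes(cfg)
  g2 <- simulateGenotypes(cfg)
  expect_identical(genoCalls(g1), genoCalls(g2))
  ## genotype class frequencies near 1/4, 1/2, 1/4
  tab <- table(genoCalls(g1)) / length(genoCalls(g1))
  expect_equal(unname(tab[c("-1", "0", "1")]), c(0.25, 0.5, 0.25),
               tolerance = 0.05, ignore_attr = TRUE)
  expect_equal(unname(alleleFreq(g1)), rep(0.5, 40), tolerance = 0.08)
})

test_that("genotype missingness count is binomial around n*m*rate", {
  counts <- vapply(1:8, function(s) {
    cfg <- simConfig(nIndividuals = 50, nMarkers = 20, nTraits = 2,
                     h2 = c(0.5, 0.5), missingGenoRate = 0.2, seed = s)
    sum(is.na(genoCalls(simulateGenotypes(cfg))))
  }, numeric(1))
  ## n*m = 1000, expectation 200, sd ~ sqrt(1000*0.2*0.8) ~ 12.6
  expect_true(all(abs(counts - 200) < 5 * sqrt(1000 * 0.2 * 0.8)))
  expect_lt(abs(mean(counts) - 200), 15)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(mafRange = c(0, 0.5)), "mafRange")
  expect_error(simConfig(mafRange = c(0.1, 0.6)), "mafRange")
  expect_error(simConfig(nTraits = 2, h2 = c(0.5, 1)), "h2")
  expect_error(simConfig(nIndividuals = 10, nChecks = 10), "nChecks")
  expect_error(simConfig(nTraits = 2, h2 = c(0.5, 0.5),
                         geneticCorr = matrix(c(1, 2, 0.5, 1), 2, 2)),
               "symmetric")
})

test_that("simulated genetic values reproduce the target heritability and correlations", {
  cfg <- simConfig(nIndividuals = 2000, nMarkers = 1500, nTraits = 3,
                   h2 = c(0.5, 0.5, 0.5),
                   geneticCorr = matrix(c(1, 0.9, 0, 0.9, 1, 0, 0, 0, 1), 3, 3),
                   seed = 11)
  sim <- simulateTraits(simulateGenotypes(cfg), cfg)
  u <- sim$truth$u
  h2hat <- apply(u, 2, var) / apply(sim$traits, 2, var)
  expect_true(all(abs(h2hat - 0.5) < 0.05))
  cu <- cor(u)
  expect_gt(cu[1, 2], 0.85); expect_lt(cu[1, 2], 0.95)
  expect_lt(abs(cu[1, 3]), 0.1)
  expect_lt(abs(cu[2, 3]), 0.1)
  ## realized genetic covariance close to the generating one (Frobenius)
  relF <- norm(cov(u) - sim$truth$Sigma, "F") / norm(sim$truth$Sigma, "F")
  expect_lt(relF, 0.1)
})

test_that("trial layout replicates checks everywhere and degenerates cleanly", {
  cfg <- simConfig(nIndividuals = 40, nMarkers = 50, nTraits = 1, h2 = 0.5,
                   nEnvironments = 9, nTrials = 9, nChecks = 5, trialVar = 0.5,
                   seed = 3)
  vals <- matrix(rnorm(40), 40, 1, dimnames = list(sprintf("L%03d", 1:40), "T1"))
  ph <- simulateTrials(vals, cfg, residVar = 0.1, replicatedFrac = 0)
  counts <- table(ph$line)
  expect_true(all(counts[sprintf("L%03d", 1:5)] == 9))
  expect_true(all(counts[sprintf("L%03d", 6:40)] == 1))
  ## trials nested in environments
  expect_false(anyDuplicated(unique(ph[, c("env", "trial")])$trial) > 0)

  ## single environment, single trial, zero trial variance: value + noise only
  cfg1 <- simConfig(nIndividuals = 30, nMarkers = 50, nTraits = 1, h2 = 0.5,
                    nEnvironments = 1, nTrials = 1, trialVar = 0, envVar = 0,
                    nChecks = 2, seed = 5)
  ph1 <- simulateTrials(vals[1:30, , drop = FALSE], cfg1, residVar = 0.04)
  v <- ph1$value[match(rownames(vals)[1:30], ph1$line)]
  expect_lt(max(abs(v - vals[1:30, 1])), 4 * sqrt(0.04))
  expect_gt(sd(v - vals[1:30, 1]), 0)

  ## no checks across environments: weak connectivity warning
  cfg0 <- simConfig(nIndividuals = 30, nMarkers = 50, nTraits = 1, h2 = 0.5,
                    nEnvironments = 2, nTrials = 2, nChecks = 0, seed = 6)
  expect_warning(simulateTrials(vals[1:30, , drop = FALSE], cfg0, residVar = 0.1),
                 "connected")
})

test_that("the whole study is reproducible from one seed", {
  cfg <- simConfig(nIndividuals = 50, nMarkers = 60, nTraits = 2,
                   h2 = c(0.4, 0.6), nEnvironments = 3, nTrials = 6,
                   nChecks = 3, missingGenoRate = 0.1, seed = 99)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(genoCalls(s1$geno), genoCalls(s2$geno))
  expect_identical(s1$pheno, s2$pheno)
  expect_identical(s1$truth$u, s2$truth$u)
})
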