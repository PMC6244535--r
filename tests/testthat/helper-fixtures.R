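## Fixtures shared across test files. Everything is generated in code under
## fixed seeds; no stored data.

## Equicorrelated genetic correlation matrix.
equiCorr <- function(t, r) { M <- matrix(r, t, t); diag(M) <- 1; M }

## Small correlated-trait panel: genotypes, traits, kinship.
makePanel <- function(n = 120, m = 400, t = 4, rg = 0.8, h2 = 0.5, seed = 4) {
  cfg <- simConfig(nIndividuals = n, nMarkers = m, nTraits = t,
                   h2 = rep(h2, t), geneticCorr = equiCorr(t, rg),
                   missingGenoRate = 0, seed = seed)
  geno <- simulateGenotypes(cfg)
  sim <- simulateTraits(geno, cfg)
  list(cfg = cfg, geno = geno, traits = sim$traits, truth = sim$truth,
       K = additiveK(geno))
}

## A tiny balanced two-trial phenotype table with known trial effects and a
## whisper of noise (REML is degenerate at exactly zero residual variance).
balancedTwoTrial <- function(nLines = 6, trialEff = c(1, -1), noiseSd = 0.01,
                             seed = 1) {
  set.seed(seed)
  vals <- stats::setNames(seq_len(nLines), sprintf("L%02d", seq_len(nLines)))
  do.call(rbind, lapply(seq_along(trialEff), function(k) {
    data.frame(line = names(vals), env = "E1", trial = sprintf("T%d", k),
               trait = "y",
               value = unname(vals) + trialEff[k] + rnorm(nLines, 0, noiseSd))
  }))
}

fastST <- function(seed = 1L) stConfig(nIter = 1200L, burnIn = 400L, seed = seed)
fastMT <- function(seed = 1L) mtConfig(nIter = 1200L, burnIn = 400L, seed = seed)
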