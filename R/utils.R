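#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

utils::globalVariables(c("size", "scheme", "sd"))

#' Derive reproducible sub-seeds from a master seed
#'
#' All stochastic stages draw their own seed from a single stream keyed by the
#' master seed, so adding a stage never perturbs the draws of existing ones.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each usable with [set.seed()].
#' @export
subSeeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

## Clip the spectrum of a correlation matrix at `floor` and rescale to unit
## diagonal; used when a user-supplied genetic correlation is singular.
.clipCorr <- function(C, floor = 1e-8) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) >= floor) return(C)
  message("genetic correlation matrix not positive definite; eigenvalues clipped at ", floor)
  v <- pmax(e$values, floor)
  C2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(C2))
  C2 <- C2 / tcrossprod(d)
  (C2 + t(C2)) / 2
}

## Connected components of the bipartite line/trial incidence, by union-find.
## Returns an integer component label per line.
.lineComponents <- function(line, trial) {
  line <- as.character(line); trial <- as.character(trial)
  ids <- c(unique(line), paste0("\r", unique(trial)))
  parent <- seq_along(ids)
  names(parent) <- ids
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  li <- match(line, ids); ti <- match(paste0("\r", trial), ids)
  for (k in seq_along(li)) {
    a <- find(li[k]); b <- find(ti[k])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(match(unique(line), ids), find, integer(1))
  comp <- as.integer(factor(roots))
  names(comp) <- unique(line)
  comp
}

.symmetrize <- function(M) (M + t(M)) / 2

## Draw one matrix from the inverse-Wishart with density
## |S|^{nu/2} |Sigma|^{-(nu+t+1)/2} exp(-tr(S Sigma^{-1})/2):
## Sigma^{-1} ~ Wishart(nu, S^{-1}).
.rInvWishart <- function(nu, S) {
  Sinv <- chol2inv(chol(.symmetrize(S)))
  W <- stats::rWishart(1L, df = nu, Sigma = .symmetrize(Sinv))[, , 1L]
  .symmetrize(chol2inv(chol(W)))
}

## Scaled inverse-chi-square draw in the "sum" parameterisation:
## sigma2 = (S + SS) / chisq(df + n).
.rScaledInvChisq <- function(df0, S0, n, SS) (S0 + SS) / stats::rchisq(1L, df = df0 + n)
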