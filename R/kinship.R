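## SNP quality control, imputation and the realized additive relationship
## matrix K = WW' / (2 sum p q) with W the centered genotype matrix,
## W_im = X_im + (1 - 2 p_m).

#' Genotype quality control
#'
#' Applies, in order: (1) removal of markers with missingness above
#' `maxMarkerMissing`; (2) removal of individuals with missingness above
#' `maxIndMissing`; (3) removal of markers whose minor allele frequency,
#' recomputed on the retained individuals, falls below `minMAF`. The order
#' matters: MAF is always recomputed last.
#'
#' @param geno a [GenotypeMatrix-class].
#' @param maxMarkerMissing,maxIndMissing,minMAF thresholds (defaults 0.20,
#'   0.50, 0.05).
#' @return the filtered [GenotypeMatrix-class] with attribute `"qc"`, a list
#'   of counts removed per rule.
#' @export
qcFilter <- function(geno, maxMarkerMissing = 0.20, maxIndMissing = 0.50,
                     minMAF = 0.05) {
  stopifnot(is(geno, "GenotypeMatrix"))
  X <- genoCalls(geno)
  mm <- colMeans(is.na(X))
  dropMarkerMiss <- mm > maxMarkerMissing
  X <- X[, !dropMarkerMiss, drop = FALSE]
  im <- rowMeans(is.na(X))
  dropInd <- im > maxIndMissing
  X <- X[!dropInd, , drop = FALSE]
  p <- colMeans(X + 1, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  dropMAF <- !is.finite(maf) | maf < minMAF
  X <- X[, !dropMAF, drop = FALSE]
  if (ncol(X) == 0L) stop("all markers removed by QC: empty panel")
  out <- GenotypeMatrix(X, dosage = geno@dosage)
  attr(out, "qc") <- list(markersMissing = sum(dropMarkerMiss),
                          individuals = sum(dropInd),
                          markersMAF = sum(dropMAF),
                          markersKept = ncol(X), linesKept = nrow(X))
  out
}

#' Impute missing genotype calls by per-marker means
#'
#' @param geno a [GenotypeMatrix-class].
#' @return complete [GenotypeMatrix-class] with real-valued dosages.
#' @export
imputeMean <- function(geno) {
  stopifnot(is(geno, "GenotypeMatrix"))
  X <- genoCalls(geno)
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2L]]
  GenotypeMatrix(X, dosage = TRUE)
}

#' Impute missing genotype calls under a multivariate-normal model
#'
#' Iterative expectation-maximisation treating the marker profile of each
#' line as a draw from a multivariate normal with a low-rank covariance:
#' missing entries are initialised at the marker means and repeatedly
#' replaced by their conditional expectation under the current rank-`rank`
#' truncated-SVD reconstruction of the centered matrix, until the largest
#' change falls below `tol` or `maxIter` sweeps. Imputed values are
#' real-valued dosages, clamped to \[-1, 1\]; rounding to the nearest call is
#' available via `round`.
#'
#' @param geno a [GenotypeMatrix-class] (typically post-QC).
#' @param rank rank of the covariance model; default
#'   `min(n - 1, m - 1, 20)`.
#' @param maxIter,tol convergence controls (defaults 100, 1e-3 on the
#'   largest imputed-value change, which is ample for the dosage precision
#'   the relationship matrix needs).
#' @param round round imputations back to \{-1, 0, 1\}.
#' @return complete [GenotypeMatrix-class]; attribute `"converged"` records
#'   whether `tol` was met (a warning is raised otherwise).
#' @export
imputeEM <- function(geno, rank = NULL, maxIter = 100L, tol = 1e-3, round = FALSE) {
  stopifnot(is(geno, "GenotypeMatrix"))
  X <- genoCalls(geno)
  idx <- which(is.na(X))
  if (!length(idx)) return(geno)
  n <- nrow(X); m <- ncol(X)
  if (is.null(rank)) rank <- max(1L, min(n - 1L, m - 1L, 20L))
  mu <- colMeans(X, na.rm = TRUE)
  Xc <- X
  Xc[idx] <- mu[((idx - 1L) %/% n) + 1L]
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    mu <- colMeans(Xc)
    Z <- sweep(Xc, 2L, mu)
    sv <- svd(Z, nu = rank, nv = rank)
    r <- min(rank, sum(sv$d > 1e-10))
    fit <- sv$u[, seq_len(r), drop = FALSE] %*%
      (sv$d[seq_len(r)] * t(sv$v[, seq_len(r), drop = FALSE]))
    newv <- pmin(pmax(fit[idx] + mu[((idx - 1L) %/% n) + 1L], -1), 1)
    delta <- max(abs(newv - Xc[idx]))
    Xc[idx] <- newv
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM imputation did not converge in ", maxIter,
            " iterations (last change ", signif(delta, 3), ")")
  if (round) Xc[idx] <- pmin(pmax(round(Xc[idx]), -1), 1)
  out <- GenotypeMatrix(Xc, dosage = !round)
  attr(out, "converged") <- converged
  out
}

#' Realized additive relationship matrix
#'
#' `K = WW' / (2 sum p_m q_m)` with `W_im = X_im + (1 - 2 p_m)`, allele
#' frequencies `p_m` recomputed from the current (complete) matrix and
#' `q_m = 1 - p_m`. The same `p` is used for centering and for the
#' denominator.
#'
#' @param geno complete [GenotypeMatrix-class] (no missing entries; impute
#'   first).
#' @return a [KinshipMatrix-class].
#' @examples
#' g <- GenotypeMatrix(matrix(c(1, -1), 2, 1))
#' kinship(additiveK(g))  # [[2, -2], [-2, 2]]
#' @export
additiveK <- function(geno) {
  stopifnot(is(geno, "GenotypeMatrix"))
  X <- genoCalls(geno)
  if (anyNA(X)) stop("genotypes must be complete; run imputeEM() or imputeMean() first")
  p <- colMeans(X + 1) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: VanRaden denominator is zero")
  W <- sweep(X, 2L, 2 * p - 1)  # X + (1 - 2p)
  K <- tcrossprod(W) / denom
  KinshipMatrix(K, denom = denom)
}

## Spectral decomposition of K with small eigenvalues dropped; shared by the
## samplers. Jitter is applied only implicitly through the clipping floor.
.kinshipEigen <- function(K, floor = 1e-8) {
  e <- eigen(.symmetrize(K), symmetric = TRUE)
  keep <- e$values > floor
  if (!any(keep)) stop("kinship matrix has no eigenvalue above the floor; not usable")
  list(vectors = e$vectors[, keep, drop = FALSE], values = e$values[keep])
}
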