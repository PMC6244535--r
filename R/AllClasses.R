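#' @import methods
NULL

## ---------------------------------------------------------------------------
## GenotypeMatrix
## ---------------------------------------------------------------------------

#' Biallelic SNP genotypes for a panel of inbred lines
#'
#' Stores an individuals-by-markers matrix of biallelic SNP calls coded
#' \{-1, 0, 1\} (homozygous reference / heterozygous / homozygous alternate),
#' with `NA` for missing calls, together with per-marker allele frequencies.
#' After EM imputation entries may be real-valued dosages in \[-1, 1\]
#' (`dosage = TRUE`).
#'
#' @slot X numeric matrix, lines x markers, dimnames required.
#' @slot alleleFreq per-marker frequency of the "+1" allele, computed from
#'   non-missing calls.
#' @slot dosage logical; `TRUE` once entries may be real-valued imputations.
#' @export
setClass("GenotypeMatrix",
  representation(X = "matrix", alleleFreq = "numeric", dosage = "logical"))

setValidity("GenotypeMatrix", function(object) {
  X <- object@X
  if (!is.numeric(X)) return("X must be a numeric matrix")
  if (is.null(rownames(X)) || is.null(colnames(X)))
    return("X must carry line ids (rownames) and marker ids (colnames)")
  if (anyDuplicated(rownames(X))) return("duplicate line ids")
  if (anyDuplicated(colnames(X))) return("duplicate marker ids")
  if (length(object@alleleFreq) != ncol(X))
    return("alleleFreq must have one entry per marker")
  v <- X[!is.na(X)]
  if (!object@dosage && length(v) && !all(v %in% c(-1, 0, 1)))
    return("genotype calls must be in {-1, 0, 1} or NA")
  if (object@dosage && length(v) && (min(v) < -1 - 1e-6 || max(v) > 1 + 1e-6))
    return("dosages must lie in [-1, 1]")
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param X lines x markers numeric matrix coded \{-1,0,1\} (or dosages),
#'   `NA` for missing. Dimnames are required; generic ids are supplied when
#'   absent.
#' @param dosage set `TRUE` when `X` holds real-valued imputed dosages.
#' @return a [GenotypeMatrix-class] object; allele frequencies are computed
#'   from the non-missing calls of each marker.
#' @examples
#' g <- GenotypeMatrix(matrix(c(1, -1, 0, 1), 2, 2))
#' alleleFreq(g)
#' @export
GenotypeMatrix <- function(X, dosage = FALSE) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- sprintf("L%03d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("M%05d", seq_len(ncol(X)))
  p <- colMeans(X + 1, na.rm = TRUE) / 2
  new("GenotypeMatrix", X = X, alleleFreq = p, dosage = isTRUE(dosage))
}

#' @describeIn GenotypeMatrix raw call matrix
#' @param object,x a `GenotypeMatrix`
#' @export
genoCalls <- function(x) x@X

#' @describeIn GenotypeMatrix per-marker frequency of the "+1" allele
#' @export
alleleFreq <- function(x) x@alleleFreq

#' @describeIn GenotypeMatrix line identifiers
#' @export
lineIds <- function(x) rownames(x@X)

#' @describeIn GenotypeMatrix marker identifiers
#' @export
markerIds <- function(x) colnames(x@X)

#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@X))

setMethod("show", "GenotypeMatrix", function(object) {
  miss <- mean(is.na(object@X))
  cat(sprintf("GenotypeMatrix: %d lines x %d markers (%s; %.1f%% missing)\n",
              nrow(object@X), ncol(object@X),
              if (object@dosage) "dosages" else "calls {-1,0,1}", 100 * miss))
  maf <- pmin(object@alleleFreq, 1 - object@alleleFreq)
  cat(sprintf("  MAF: min %.3f, median %.3f\n",
              suppressWarnings(min(maf, na.rm = TRUE)),
              stats::median(maf, na.rm = TRUE)))
})

## ---------------------------------------------------------------------------
## KinshipMatrix
## ---------------------------------------------------------------------------

#' Realized additive relationship matrix
#'
#' Symmetric positive semi-definite matrix `K = WW' / (2 sum p q)` built from
#' centered genotypes (VanRaden scaling). The denominator used is retained
#' for inspection.
#'
#' @slot K symmetric n x n matrix with line-id dimnames.
#' @slot denom the scaling `2 sum p_m q_m`.
#' @export
setClass("KinshipMatrix", representation(K = "matrix", denom = "numeric"))

setValidity("KinshipMatrix", function(object) {
  K <- object@K
  if (nrow(K) != ncol(K)) return("K must be square")
  if (is.null(rownames(K))) return("K must carry line ids")
  if (max(abs(K - t(K))) > 1e-10) return("K must be symmetric (tol 1e-10)")
  TRUE
})

#' Construct a KinshipMatrix from a plain symmetric matrix
#' @param K symmetric numeric matrix; symmetrized exactly via (K + K')/2.
#' @param denom optional VanRaden denominator used to build `K`.
#' @export
KinshipMatrix <- function(K, denom = NA_real_) {
  K <- as.matrix(K)
  if (is.null(rownames(K))) rownames(K) <- colnames(K) <- sprintf("L%03d", seq_len(nrow(K)))
  if (is.null(colnames(K))) colnames(K) <- rownames(K)
  new("KinshipMatrix", K = .symmetrize(K), denom = denom)
}

#' @describeIn KinshipMatrix the matrix itself
#' @param x a `KinshipMatrix`
#' @export
kinship <- function(x) x@K

#' @export
setMethod("dim", "KinshipMatrix", function(x) dim(x@K))

setMethod("show", "KinshipMatrix", function(object) {
  cat(sprintf("KinshipMatrix: %d lines; mean diagonal %.3f; denom %.3f\n",
              nrow(object@K), mean(diag(object@K)), object@denom))
})

## ---------------------------------------------------------------------------
## MaskPlan
## ---------------------------------------------------------------------------

#' Phenotype availability plan for a cross-validation scheme
#'
#' Boolean lines x traits matrix: `TRUE` where the model sees the phenotype.
#' The trait columns are exactly the traits entering the model for that
#' scheme (target first, then correlated traits).
#'
#' @slot observed logical matrix with line/trait dimnames.
#' @slot scheme scheme label, e.g. `"MT-CV2"`.
#' @slot targetTrait name of the trait being predicted.
#' @slot seed the seed that generated the plan.
#' @export
setClass("MaskPlan",
  representation(observed = "matrix", scheme = "character",
                 targetTrait = "character", seed = "integer"))

setValidity("MaskPlan", function(object) {
  if (!is.logical(object@observed)) return("observed must be logical")
  if (is.null(rownames(object@observed)) || is.null(colnames(object@observed)))
    return("observed must carry line and trait ids")
  if (!object@targetTrait %in% colnames(object@observed))
    return("targetTrait must be a column of observed")
  TRUE
})

#' @describeIn MaskPlan the boolean availability matrix
#' @param x a `MaskPlan`
#' @export
observedCells <- function(x) x@observed

#' @describeIn MaskPlan lines with no observation of the target trait
#' @export
testLines <- function(x) rownames(x@observed)[!x@observed[, x@targetTrait]]

setMethod("show", "MaskPlan", function(object) {
  cs <- colSums(object@observed)
  cat(sprintf("MaskPlan [%s] target=%s, %d lines\n  observed per trait: %s\n",
              object@scheme, object@targetTrait, nrow(object@observed),
              paste(sprintf("%s=%d", names(cs), cs), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## BLUEResult
## ---------------------------------------------------------------------------

#' Adjusted means and variance components from the trial model
#'
#' Result of fitting, per trait, the mixed model with fixed genotype and
#' environment effects and a random trial-within-environment effect, plus the
#' companion fit with genotype random (which provides the genotypic variance
#' entering the heritability formula).
#'
#' @slot blues lines x traits matrix of adjusted means.
#' @slot se matching standard errors.
#' @slot sigma2Trial,sigma2Resid,sigma2Geno per-trait variance components.
#' @slot vbar per-trait mean variance of a difference of two adjusted means.
#' @slot H2 per-trait broad-sense heritability on an adjusted-mean basis.
#' @export
setClass("BLUEResult",
  representation(blues = "matrix", se = "matrix", sigma2Trial = "numeric",
                 sigma2Resid = "numeric", sigma2Geno = "numeric",
                 vbar = "numeric", H2 = "numeric"))

setValidity("BLUEResult", function(object) {
  if (!identical(dim(object@blues), dim(object@se))) return("blues/se dims differ")
  h <- object@H2[is.finite(object@H2)]
  if (length(h) && (min(h) < 0 || max(h) > 1)) return("H2 must lie in [0, 1]")
  TRUE
})

#' @describeIn BLUEResult adjusted means (lines x traits)
#' @param x a `BLUEResult`
#' @export
blues <- function(x) x@blues

#' @describeIn BLUEResult per-trait heritability
#' @export
traitH2 <- function(x) x@H2

setMethod("show", "BLUEResult", function(object) {
  cat(sprintf("BLUEResult: %d lines x %d traits\n", nrow(object@blues), ncol(object@blues)))
  cat("  H2:", paste(sprintf("%s=%.2f", names(object@H2), object@H2), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## Posteriors
## ---------------------------------------------------------------------------

#' Posterior summaries of the single-trait sampler
#'
#' @slot method `"GBLUP"` or `"BRR"`.
#' @slot g posterior-mean genetic value per line (all lines, including those
#'   without phenotype).
#' @slot betaMean posterior-mean marker effects (BRR form; length 0 for GBLUP).
#' @slot muMean posterior-mean intercept.
#' @slot sigma2U,sigma2E posterior-mean genetic and residual variances.
#' @slot seed chain seed.
#' @export
setClass("STPosterior",
  representation(method = "character", g = "numeric", betaMean = "numeric",
                 muMean = "numeric", sigma2U = "numeric", sigma2E = "numeric",
                 seed = "integer"))

setMethod("show", "STPosterior", function(object) {
  cat(sprintf("STPosterior [%s]: %d lines; mu=%.3f, sigma2_u=%.3f, sigma2_e=%.3f\n",
              object@method, length(object@g), object@muMean,
              object@sigma2U, object@sigma2E))
})

#' Posterior summaries of the multi-trait sampler
#'
#' @slot uMean n x t posterior-mean genetic values.
#' @slot SigmaMean t x t posterior-mean genetic covariance.
#' @slot RMean posterior-mean residual variance per trait.
#' @slot muMean posterior-mean intercept per trait.
#' @slot geneticCorr correlation version of `SigmaMean`.
#' @slot seed chain seed.
#' @export
setClass("MTPosterior",
  representation(uMean = "matrix", SigmaMean = "matrix", RMean = "numeric",
                 muMean = "numeric", geneticCorr = "matrix", seed = "integer"))

setValidity("MTPosterior", function(object) {
  if (max(abs(object@SigmaMean - t(object@SigmaMean))) > 1e-8)
    return("SigmaMean must be symmetric")
  if (any(object@RMean <= 0)) return("residual variances must be positive")
  if (max(abs(diag(object@geneticCorr) - 1)) > 1e-8)
    return("geneticCorr must have unit diagonal")
  TRUE
})

#' @describeIn MTPosterior posterior-mean genetic values
#' @param x an `MTPosterior`
#' @export
geneticValues <- function(x) x@uMean

#' @describeIn MTPosterior posterior-mean genetic covariance
#' @export
geneticCovariance <- function(x) x@SigmaMean

#' @describeIn MTPosterior posterior genetic correlation matrix
#' @export
geneticCorrelation <- function(x) x@geneticCorr

#' @describeIn MTPosterior posterior-mean residual variances
#' @export
residualVariances <- function(x) x@RMean

setMethod("show", "MTPosterior", function(object) {
  t <- ncol(object@uMean)
  cat(sprintf("MTPosterior: %d lines x %d traits\n", nrow(object@uMean), t))
  cat("  genetic correlations (upper triangle):",
      paste(sprintf("%.2f", object@geneticCorr[upper.tri(object@geneticCorr)]), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## CVResult
## ---------------------------------------------------------------------------

#' Cross-validation predictive-ability result
#'
#' @slot results data.frame with one row per iteration: `iteration`, `cor`
#'   (Pearson predictive ability on the test set), `nTest`.
#' @slot scheme,targetTrait design labels.
#' @slot design echo of the design parameters.
#' @export
setClass("CVResult",
  representation(results = "data.frame", scheme = "character",
                 targetTrait = "character", design = "list"))

#' @describeIn CVResult mean and SD of predictive ability across iterations
#' @param x a `CVResult`
#' @return named numeric: `mean`, `sd`, `n`.
#' @export
cvSummary <- function(x) {
  r <- x@results$cor
  c(mean = mean(r, na.rm = TRUE), sd = stats::sd(r, na.rm = TRUE), n = sum(!is.na(r)))
}

#' @describeIn CVResult per-iteration results table
#' @export
cvIterations <- function(x) x@results

setMethod("show", "CVResult", function(object) {
  s <- cvSummary(object)
  cat(sprintf("CVResult [%s] target=%s: predictive ability %.3f +- %.3f (%d iterations)\n",
              object@scheme, object@targetTrait, s["mean"], s["sd"], s["n"]))
})
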