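## Readers/writers for the package's plain-text formats and the top-level
## pipeline runner.
##
## Genotype TSV dialect (fixed so round-trips are bit-exact): tab-separated,
## header row of marker ids, first column `line`, calls in {-1,0,1} or real
## dosages, missing written "NA".

#' Read genotypes from TSV or VCF
#'
#' VCF records are mapped as `0/0 -> -1`, `0/1` (or `1/0`) `-> 0`,
#' `1/1 -> 1`, `./. -> NA`; non-biallelic records are skipped with a
#' message. The VCF path requires the `vcfR` package.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return a [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "vcf") return(.readGenotypesVCF(path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "line") stop("malformed genotype TSV: first column must be 'line'")
  if (anyDuplicated(df$line)) stop("duplicate line ids in ", path)
  X <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(X)) {
    bad <- which(!apply(df[, -1, drop = FALSE], 1L, function(r) all(is.na(r) | grepl("^-?[0-9.]+$", r))))
    stop("malformed genotype rows at line(s): ", paste(utils::head(bad + 1L), collapse = ", "))
  }
  storage.mode(X) <- "double"
  rownames(X) <- df$line
  GenotypeMatrix(X, dosage = !all(X[!is.na(X)] %in% c(-1, 0, 1)))
}

.readGenotypesVCF <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  biallelic <- vcfR::is.biallelic(v)
  if (any(!biallelic)) {
    message(sum(!biallelic), " non-biallelic VCF record(s) skipped")
    v <- v[biallelic, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("\\|", "/", gt)
  map <- c("0/0" = -1, "0/1" = 0, "1/0" = 0, "1/1" = 1)
  X <- matrix(unname(map[gt]), nrow = nrow(gt), dimnames = dimnames(gt))
  X <- t(X)   # lines x markers
  if (anyDuplicated(rownames(X))) stop("duplicate sample ids in ", path)
  GenotypeMatrix(X)
}

#' Write genotypes as TSV
#'
#' @param geno a [GenotypeMatrix-class].
#' @param path output path.
#' @export
writeGenotypes <- function(geno, path) {
  stopifnot(is(geno, "GenotypeMatrix"))
  df <- data.frame(line = lineIds(geno), genoCalls(geno), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the long-format phenotype table (CSV)
#'
#' Columns `line, env, trial, trait, value`.
#'
#' @param path file path.
#' @return data.frame (validated).
#' @export
readPhenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  .checkPhenoTable(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname readPhenotypes
#' @param pheno phenotype table.
#' @export
writePhenotypes <- function(pheno, path) {
  .checkPhenoTable(pheno)
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a kinship matrix (TSV with line-id header)
#'
#' @param path file path.
#' @return a [KinshipMatrix-class].
#' @export
readKinship <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1]]
  KinshipMatrix(K)
}

#' @rdname readKinship
#' @param K a [KinshipMatrix-class].
#' @export
writeKinship <- function(K, path) {
  stopifnot(is(K, "KinshipMatrix"))
  df <- data.frame(line = rownames(kinship(K)), kinship(K), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline: simulate, adjust, kinship, cross-validate
#'
#' Executes the requested stages in order under one output directory and
#' writes a run manifest (seeds, configuration echo, md5 checksums of every
#' output, timestamps). Re-running with an identical configuration
#' reproduces identical outputs.
#'
#' @param config either a YAML file path or a list with components:
#'   `seed`; `sim` (arguments for [simConfig()]); `cv` (list with `schemes`,
#'   `targetTrait`, `correlatedTraits`, `trainCount`, `nIterations`,
#'   optional `nIter`/`burnIn` chain lengths); optional logical flags
#'   `doBlues`, `doKinship`, `doCV`.
#' @param outDir output directory (created).
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  manifest <- list(package = as.character(utils::packageVersion("mtgp")),
                   seed = seed, config = config, started = format(Sys.time()),
                   stages = list(), files = list())
  writeOut <- function(obj, name, writer) {
    path <- file.path(outDir, name)
    writer(obj, path)
    manifest$files[[name]] <<- unname(tools::md5sum(path))
    path
  }

  simArgs <- config$sim
  simArgs$seed <- seed
  cfg <- do.call(simConfig, simArgs)
  study <- simulateStudy(cfg)
  writeOut(study$geno, "genotypes.tsv", writeGenotypes)
  writeOut(study$pheno, "phenotypes.csv", writePhenotypes)
  manifest$stages$simulate <- list(nLines = cfg$nIndividuals, nMarkers = cfg$nMarkers,
                                   nTraits = cfg$nTraits)

  bl <- NULL
  if (!isFALSE(config$doBlues)) {
    bl <- fitBlues(study$pheno)
    blDf <- data.frame(line = rownames(blues(bl)), blues(bl), check.names = FALSE)
    writeOut(blDf, "blues.csv",
             function(o, p) utils::write.csv(o, p, row.names = FALSE, quote = FALSE))
    rep <- list(H2 = as.list(traitH2(bl)), sigma2Trial = as.list(bl@sigma2Trial),
                sigma2Resid = as.list(bl@sigma2Resid), vbar = as.list(bl@vbar))
    writeOut(rep, "variance_components.json",
             function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA))
    manifest$stages$blues <- list(traits = colnames(blues(bl)))
  }

  Kobj <- NULL
  if (!isFALSE(config$doKinship)) {
    g <- qcFilter(study$geno)
    if (anyNA(genoCalls(g))) g <- imputeEM(g)
    Kobj <- additiveK(g)
    writeOut(Kobj, "K.tsv", writeKinship)
    writeOut(attr(g, "qc"), "qc_report.json",
             function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE))
    manifest$stages$kinship <- attr(g, "qc")
  }

  if (!isFALSE(config$doCV) && !is.null(config$cv) && !is.null(bl) && !is.null(Kobj)) {
    cv <- config$cv
    Y <- blues(bl)[rownames(kinship(Kobj)), , drop = FALSE]
    mtCfg <- mtConfig(nIter = if (is.null(cv$nIter)) 3000L else cv$nIter,
                      burnIn = if (is.null(cv$burnIn)) 1500L else cv$burnIn)
    stCfg <- stConfig(nIter = mtCfg$nIter, burnIn = mtCfg$burnIn)
    rows <- lapply(cv$schemes, function(sch) {
      res <- runCV(Y, Kobj, sch, cv$targetTrait,
                   correlatedTraits = unlist(cv$correlatedTraits),
                   trainCount = cv$trainCount,
                   nIterations = if (is.null(cv$nIterations)) 100L else cv$nIterations,
                   seed = seed, stCfg = stCfg, mtCfg = mtCfg)
      s <- cvSummary(res)
      data.frame(scheme = sch, target = cv$targetTrait, mean = unname(s["mean"]),
                 sd = unname(s["sd"]), nIterations = unname(s["n"]))
    })
    cvTab <- do.call(rbind, rows)
    writeOut(cvTab, "cv_results.csv",
             function(o, p) utils::write.csv(o, p, row.names = FALSE, quote = FALSE))
    manifest$stages$cv <- list(schemes = cv$schemes, trainCount = cv$trainCount)
  }

  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
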