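# File I/O, run configuration and pipeline orchestration.

#' Read a genotype matrix
#'
#' Supported formats:
#' \describe{
#'   \item{tsv}{samples x SNPs table; first column holds sample ids, header
#'     holds SNP labels.}
#'   \item{vcf}{VCF with GT fields; genotypes become the alternate-allele
#'     count (0/0 -> 0, 0/1 -> 1, 1/1 -> 2, ./. -> NA). Coordinates are
#'     1-based per the VCF standard; SNP identity is the ID column.}
#'   \item{plink_raw}{plink .raw dialect: columns FID IID PAT MAT SEX
#'     PHENOTYPE then one 0/1/2/NA column per SNP.}
#' }
#'
#' @param path input file.
#' @param format one of `"tsv"`, `"vcf"`, `"plink_raw"`.
#' @return samples x SNPs matrix, additive 0/1/2 coding, NA for missing.
#' @export
readGenotypes <- function(path, format = c("tsv", "vcf", "plink_raw")) {
    format <- match.arg(format)
    stopIfNot(file.exists(path), paste("file not found:", path))
    switch(format,
        tsv = {
            df <- utils::read.delim(path, check.names = FALSE,
                                    stringsAsFactors = FALSE)
            m <- as.matrix(df[, -1L, drop = FALSE])
            if (!is.numeric(m))
                stop("parse error: non-numeric genotype entries in ", path,
                     call. = FALSE)
            rownames(m) <- as.character(df[[1L]])
            storage.mode(m) <- "integer"
            m
        },
        vcf = {
            v <- vcfR::read.vcfR(path, verbose = FALSE)
            gt <- vcfR::extract.gt(v, element = "GT")
            count <- function(g) {
                if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
                alleles <- strsplit(g, "[/|]")[[1L]]
                if (any(alleles == ".")) return(NA_integer_)
                sum(alleles != "0")
            }
            m <- t(apply(gt, c(1L, 2L), count))
            ids <- vcfR::getID(v)
            colnames(m) <- ids
            storage.mode(m) <- "integer"
            m
        },
        plink_raw = {
            df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                                    stringsAsFactors = FALSE, na.strings = "NA")
            meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
            stopIfNot(all(meta %in% names(df)),
                      "parse error: not a plink .raw file (missing meta columns)")
            m <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
            rownames(m) <- as.character(df$IID)
            # plink suffixes the counted allele (snp_A); strip it
            colnames(m) <- sub("_[ACGT]$", "", colnames(m))
            storage.mode(m) <- "integer"
            m
        })
}

#' Full run configuration
#'
#' Aggregates every tunable of the pipeline: the synthetic-data config (used
#' when no input data are supplied), the per-layer FDR selection thresholds
#' (0.1 isoforms, 0.05 markers and phenotypes), the nominal-p cutoff zeroing
#' weak edges before masking (0.05), the per-layer keep fraction (0.35), the
#' training hyperparameters, the screening thresholds (precision 0.6,
#' p 0.05), the mediator-module weight fraction (0.10), the number of
#' top-impact SNPs screened (5), and the global seed.
#'
#' @param synth a [SynthConfig-class].
#' @param qThresholds named FDR cutoffs (isoform, marker, phenotype).
#' @param pCutoff pre-mask nominal significance cutoff.
#' @param keepFraction per-layer top-fraction of edges kept.
#' @param train a [TrainConfig-class].
#' @param precisionThreshold,pThreshold screening cutoffs.
#' @param moduleFraction mediator-module weight fraction.
#' @param topK high-impact SNPs fed to the screen.
#' @param seed global seed (propagated to stages).
#' @return a named list (serializes losslessly to JSON).
#' @export
runConfig <- function(synth = synthConfig(),
                      qThresholds = c(isoform = 0.1, marker = 0.05,
                                      phenotype = 0.05),
                      pCutoff = 0.05, keepFraction = 0.35,
                      train = trainConfig(),
                      precisionThreshold = 0.6, pThreshold = 0.05,
                      moduleFraction = 0.10, topK = 5L, seed = 1L) {
    thr <- c(qThresholds, pCutoff, keepFraction, precisionThreshold,
             pThreshold, moduleFraction)
    stopIfNot(all(thr > 0 & thr <= 1), "all thresholds must lie in (0, 1]")
    list(synth = synth, qThresholds = qThresholds, pCutoff = pCutoff,
         keepFraction = keepFraction, train = train,
         precisionThreshold = precisionThreshold, pThreshold = pThreshold,
         moduleFraction = moduleFraction, topK = as.integer(topK),
         seed = as.integer(seed))
}

# Stable md5 of a run configuration (base-R; serialized to a temp file).
configHash <- function(config) {
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(config, f, version = 2L)
    unname(tools::md5sum(f))
}

pipelineStage <- function(name, expr) {
    message("[slem] stage: ", name)
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full two-step pipeline
#'
#' Executes association analysis on the multilevel data, architecture
#' construction, training (with optional cross-validation), impact scoring,
#' combination screening on the end-to-end data, and holdout re-evaluation.
#' When datasets are not supplied they are generated from `config$synth`
#' (train and holdout cohorts from independent seeds). Idempotent under a
#' fixed seed; every artifact records the config hash and seed.
#'
#' @param config a [runConfig()] list.
#' @param multilevel optional [MultilevelDataset-class].
#' @param train optional training [EndToEndDataset-class].
#' @param holdout optional holdout [EndToEndDataset-class].
#' @param outDir optional directory for artifacts (model JSON, association /
#'   impact / screen TSVs, run report JSON).
#' @param withCV run k-fold CV and record the AUROC summary (default TRUE).
#' @return list: model (trained), associations, impact, topSnps, screen,
#'   holdout, cv (or NULL), report.
#' @export
runPipeline <- function(config = runConfig(), multilevel = NULL, train = NULL,
                        holdout = NULL, outDir = NULL, withCV = TRUE) {
    hash <- configHash(config)
    if (is.null(multilevel))
        multilevel <- pipelineStage("simulate-multilevel",
                                    genMultilevel(config$synth))
    if (is.null(train))
        train <- pipelineStage("simulate-train",
                               genEndToEnd(config$synth, seedOffset = 100L))
    if (is.null(holdout))
        holdout <- pipelineStage("simulate-holdout",
                                 genEndToEnd(config$synth, seedOffset = 200L))
    tabs <- pipelineStage("assoc", list(
        snpIsoform = batchAssoc(multilevel, "snp->isoform"),
        snpMarker = batchAssoc(multilevel, "snp->marker"),
        snpPhenotype = batchAssoc(multilevel, "snp->phenotype"),
        isoformMarker = batchAssoc(multilevel, "isoform->marker"),
        markerPhenotype = batchAssoc(multilevel, "marker->phenotype")))
    model0 <- pipelineStage("init", buildModel(
        tabs, qThresholds = config$qThresholds, pCutoff = config$pCutoff,
        keepFraction = config$keepFraction, seed = config$seed))
    cv <- NULL
    if (withCV)
        cv <- pipelineStage("cross-validate",
                            crossValidate(model0, train, config$train))
    model <- pipelineStage("train", trainSlem(model0, train, config$train))
    impact <- pipelineStage("impact", impactScoresMatrix(model))
    top <- topSnps(impact, min(config$topK, nrow(impact)))
    screen <- pipelineStage("screen", screenCombinations(
        train, top, config$precisionThreshold, config$pThreshold))
    hold <- pipelineStage("evaluate", evaluateHoldout(screen, holdout))
    report <- list(
        package = as.character(utils::packageVersion("slem")),
        rVersion = R.version.string,
        configHash = hash, seed = config$seed,
        nMultilevel = nrow(genotypes(multilevel)),
        nTrain = nrow(genotypes(train)), nHoldout = nrow(genotypes(holdout)),
        layerSizes = vapply(model@layers, length, integer(1)),
        unmaskedEdges = edgeCount(model),
        cvAuroc = if (is.null(cv)) NULL else cv$mean,
        trainLoss = model@trainState$finalLoss,
        topSnps = top,
        nScreened = nrow(screen), nPassed = sum(screen$passed))
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeSlemModel(model, file.path(outDir, "model.json"))
        for (nm in names(tabs))
            writeAssociationTsv(tabs[[nm]],
                                file.path(outDir, paste0("assoc_", nm, ".tsv")))
        writeImpactTsv(impact, file.path(outDir, "impact.tsv"))
        writeScreenTsv(screen, file.path(outDir, "screen.tsv"))
        writeScreenTsv(hold, file.path(outDir, "holdout.tsv"))
        if (!is.null(cv)) writeMetricsTsv(cv, file.path(outDir, "cv.tsv"))
        jsonlite::write_json(report, file.path(outDir, "report.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    list(model = model, associations = tabs, impact = impact, topSnps = top,
         screen = screen, holdout = hold, cv = cv, report = report)
}
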