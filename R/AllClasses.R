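#' @import methods
NULL

#' Configuration for the synthetic multilevel / end-to-end generator
#'
#' Holds the study conditions the generator emulates: sample sizes for the
#' small precise multilevel cohort and the large end-to-end cohort, layer
#' widths (SNPs, transcript isoforms, protein markers, cellular phenotypes),
#' per-SNP minor-allele frequencies, the planted layer-to-layer effect
#' matrices, per-layer Gaussian noise scale, and the liability intercept that
#' controls case prevalence.
#'
#' @slot nSamplesMultilevel integer, samples in the multilevel cohort.
#' @slot nSamplesE2E integer, samples in an end-to-end cohort.
#' @slot nSnps,nIsoforms,nMarkers,nPhenotypes integer layer widths.
#' @slot maf numeric vector of minor-allele frequencies in (0, 0.5], one per SNP.
#' @slot effectIsoform numeric matrix (nSnps x nIsoforms) of planted per-allele
#'   effects in noise-SD units.
#' @slot effectMarker numeric matrix (nIsoforms x nMarkers).
#' @slot effectPhenotype numeric matrix (nMarkers x nPhenotypes).
#' @slot effectDisease numeric vector (nPhenotypes) of liability loadings.
#' @slot noiseSd non-negative per-layer Gaussian noise scale.
#' @slot latentSd scale of a sample-level latent factor loading on every
#'   feature (shared biological/technical variation producing the pervasive
#'   feature-feature correlation seen in expression and neuropathology data);
#'   0 disables it.
#' @slot liabilityIntercept real; `NA` means auto-calibrate to
#'   `targetPrevalence` at generation time.
#' @slot targetPrevalence case fraction aimed for when auto-calibrating.
#' @slot seed integer seed; identical configs generate bit-identical data.
#' @exportClass SynthConfig
setClass("SynthConfig", representation(
    nSamplesMultilevel = "integer",
    nSamplesE2E = "integer",
    nSnps = "integer",
    nIsoforms = "integer",
    nMarkers = "integer",
    nPhenotypes = "integer",
    maf = "numeric",
    effectIsoform = "matrix",
    effectMarker = "matrix",
    effectPhenotype = "matrix",
    effectDisease = "numeric",
    noiseSd = "numeric",
    latentSd = "numeric",
    liabilityIntercept = "numeric",
    targetPrevalence = "numeric",
    seed = "integer"
))

setValidity("SynthConfig", function(object) {
    msg <- character()
    cnt <- c(object@nSamplesMultilevel, object@nSamplesE2E, object@nSnps,
             object@nIsoforms, object@nMarkers, object@nPhenotypes)
    if (any(is.na(cnt)) || any(cnt < 1L))
        msg <- c(msg, "all counts must be >= 1")
    if (length(object@maf) != object@nSnps)
        msg <- c(msg, "maf must have one entry per SNP")
    if (any(object@maf <= 0 | object@maf > 0.5))
        msg <- c(msg, "maf entries must lie in (0, 0.5]")
    if (!identical(dim(object@effectIsoform), c(object@nSnps, object@nIsoforms)))
        msg <- c(msg, "effectIsoform must be nSnps x nIsoforms")
    if (!identical(dim(object@effectMarker), c(object@nIsoforms, object@nMarkers)))
        msg <- c(msg, "effectMarker must be nIsoforms x nMarkers")
    if (!identical(dim(object@effectPhenotype), c(object@nMarkers, object@nPhenotypes)))
        msg <- c(msg, "effectPhenotype must be nMarkers x nPhenotypes")
    if (length(object@effectDisease) != object@nPhenotypes)
        msg <- c(msg, "effectDisease must have one loading per phenotype")
    if (is.na(object@noiseSd) || object@noiseSd < 0)
        msg <- c(msg, "noiseSd must be >= 0")
    if (is.na(object@latentSd) || object@latentSd < 0)
        msg <- c(msg, "latentSd must be >= 0")
    if (!is.na(object@liabilityIntercept) && !is.finite(object@liabilityIntercept))
        msg <- c(msg, "liabilityIntercept must be finite or NA")
    if (length(msg)) msg else TRUE
})

#' Multilevel dataset: genotypes plus three molecular/cellular layers
#'
#' All tables share the same sample index (rownames). The covariate table
#' carries age, sex and diagnosis; diagnosis equals the generated (or
#' observed) binary label.
#'
#' @slot genotypes samples x SNPs matrix, additive 0/1/2 coding.
#' @slot isoforms samples x isoforms real matrix.
#' @slot markers samples x markers real matrix.
#' @slot phenotypes samples x phenotypes real matrix.
#' @slot covariates data.frame with columns age, sex, diagnosis.
#' @slot diagnosis integer vector of 0/1 labels.
#' @slot truth list of planted effect matrices (ground truth) or empty list.
#' @exportClass MultilevelDataset
setClass("MultilevelDataset", representation(
    genotypes = "matrix",
    isoforms = "matrix",
    markers = "matrix",
    phenotypes = "matrix",
    covariates = "data.frame",
    diagnosis = "integer",
    truth = "list"
))

setValidity("MultilevelDataset", function(object) {
    msg <- character()
    n <- nrow(object@genotypes)
    ids <- rownames(object@genotypes)
    for (nm in c("isoforms", "markers", "phenotypes")) {
        tab <- slot(object, nm)
        if (nrow(tab) != n) msg <- c(msg, paste0(nm, ": sample count mismatch"))
        if (ncol(tab) < 1L) msg <- c(msg, paste0(nm, ": layer table is empty"))
        if (!identical(rownames(tab), ids))
            msg <- c(msg, paste0(nm, ": sample index differs from genotypes"))
    }
    if (nrow(object@covariates) != n)
        msg <- c(msg, "covariates: sample count mismatch")
    if (length(object@diagnosis) != n)
        msg <- c(msg, "diagnosis length mismatch")
    if (!all(object@diagnosis %in% c(0L, 1L)))
        msg <- c(msg, "diagnosis must be 0/1")
    if (length(msg)) msg else TRUE
})

#' End-to-end dataset: genotypes and a binary diagnosis label
#'
#' @slot genotypes samples x SNPs additive-coded matrix.
#' @slot labels integer 0/1 diagnosis per sample.
#' @exportClass EndToEndDataset
setClass("EndToEndDataset", representation(
    genotypes = "matrix",
    labels = "integer"
))

setValidity("EndToEndDataset", function(object) {
    msg <- character()
    if (length(object@labels) != nrow(object@genotypes))
        msg <- c(msg, "labels length must equal sample count")
    if (!all(object@labels %in% c(0L, 1L)))
        msg <- c(msg, "labels must be 0/1")
    if (length(msg)) msg else TRUE
})

#' Table of pairwise association records between two adjacent layers
#'
#' One record per (source, target) pair with the test statistic (OLS slope or
#' Kendall tau-b), its sign, the two-sided p-value and the
#' Benjamini-Hochberg q-value computed within the table.
#'
#' @slot records data.frame with columns source, target, statistic, sign, p, q.
#' @slot layerPair label such as "snp->isoform".
#' @exportClass AssociationTable
setClass("AssociationTable", representation(
    records = "data.frame",
    layerPair = "character"
))

setValidity("AssociationTable", function(object) {
    msg <- character()
    need <- c("source", "target", "statistic", "sign", "p", "q")
    if (!all(need %in% names(object@records)))
        msg <- c(msg, paste("records must have columns:", paste(need, collapse = ", ")))
    else {
        r <- object@records
        if (anyDuplicated(paste(r$source, r$target, sep = "\r")))
            msg <- c(msg, "(source, target) pairs must be unique")
        if (nrow(r) && any(r$p <= 0 | r$p > 1, na.rm = TRUE))
            msg <- c(msg, "p-values must lie in (0, 1]")
        if (nrow(r) && any(r$q <= 0 | r$q > 1, na.rm = TRUE))
            msg <- c(msg, "q-values must lie in (0, 1]")
        if (nrow(r) && !all(r$sign %in% c(-1, 1)))
            msg <- c(msg, "sign must be +1 or -1")
    }
    if (length(msg)) msg else TRUE
})

#' Sparse five-layer network model
#'
#' The central artifact: node labels for the five layers (SNPs, isoforms,
#' markers, phenotypes, disease), four weight matrices with binary masks,
#' fixed activations (tanh on the three hidden layers, sigmoid on the
#' single-node output), and the training state. Masked entries are exactly
#' zero and stay zero through training.
#'
#' @slot layers list of 5 character vectors of node labels.
#' @slot weights list of 4 numeric matrices (fan_in x fan_out).
#' @slot masks list of 4 binary matrices, same shapes as weights.
#' @slot activations character(4), "tanh" x3 then "sigmoid".
#' @slot seed integer seed used for the Xavier draws.
#' @slot trainState list: optimizer hyperparameters and epoch counter.
#' @exportClass SlemModel
setClass("SlemModel", representation(
    layers = "list",
    weights = "list",
    masks = "list",
    activations = "character",
    seed = "integer",
    trainState = "list"
))

setValidity("SlemModel", function(object) {
    msg <- character()
    if (length(object@layers) != 5L)
        msg <- c(msg, "exactly 5 layers required")
    if (length(object@layers) == 5L && length(object@layers[[5L]]) != 1L)
        msg <- c(msg, "output layer must have exactly 1 node")
    for (l in object@layers)
        if (anyDuplicated(l)) msg <- c(msg, "duplicate node labels within a layer")
    if (length(object@weights) != 4L || length(object@masks) != 4L)
        msg <- c(msg, "4 weight and 4 mask matrices required")
    else for (i in seq_len(4L)) {
        W <- object@weights[[i]]; M <- object@masks[[i]]
        want <- c(length(object@layers[[i]]), length(object@layers[[i + 1L]]))
        if (!identical(dim(W), as.integer(want)))
            msg <- c(msg, sprintf("weight matrix %d has wrong shape", i))
        if (!identical(dim(M), dim(W)))
            msg <- c(msg, sprintf("mask %d shape differs from weights", i))
        if (!all(M %in% c(0, 1)))
            msg <- c(msg, sprintf("mask %d must be binary", i))
        if (any(W[M == 0] != 0))
            msg <- c(msg, sprintf("masked entries of weight matrix %d must be exactly 0", i))
    }
    if (!identical(object@activations, c("tanh", "tanh", "tanh", "sigmoid")))
        msg <- c(msg, "activations must be tanh, tanh, tanh, sigmoid")
    if (length(msg)) msg else TRUE
})

#' Training hyperparameters
#'
#' Defaults are the tuned values used throughout: learning rate 0.005, batch
#' size 250, 750 epochs, 10-fold cross-validation, 100 repeated models.
#'
#' @slot learningRate,batchSize,epochs,folds,repeats,seed see [trainConfig()].
#' @exportClass TrainConfig
setClass("TrainConfig", representation(
    learningRate = "numeric",
    batchSize = "integer",
    epochs = "integer",
    folds = "integer",
    repeats = "integer",
    seed = "integer"
))

setValidity("TrainConfig", function(object) {
    msg <- character()
    if (object@learningRate < 0) msg <- c(msg, "learningRate must be >= 0")
    if (any(c(object@batchSize, object@epochs, object@folds, object@repeats) < 1L))
        msg <- c(msg, "batchSize, epochs, folds and repeats must be positive")
    if (length(msg)) msg else TRUE
})

#' Mediator module: strong-edge subnetwork feeding chosen phenotype nodes
#'
#' @slot nodes list of retained node labels per layer (snp, isoform, marker,
#'   phenotype).
#' @slot edges data.frame with columns from, to, layer, weight.
#' @slot anchors anchor phenotype node labels.
#' @exportClass MediatorModule
setClass("MediatorModule", representation(
    nodes = "list",
    edges = "data.frame",
    anchors = "character"
))

setValidity("MediatorModule", function(object) {
    msg <- character()
    if (!all(c("from", "to", "layer", "weight") %in% names(object@edges)))
        msg <- c(msg, "edges must have columns from, to, layer, weight")
    if (!all(object@anchors %in% object@nodes[["phenotype"]]))
        msg <- c(msg, "anchors must be retained phenotype nodes")
    if (length(msg)) msg else TRUE
})
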