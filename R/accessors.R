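# Accessors and show methods for the package's S4 classes.

#' @rdname accessors
#' @param object an object of one of the package's S4 classes.
#' @export
setGeneric("genotypes", function(object) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("isoforms", function(object) standardGeneric("isoforms"))
#' @rdname accessors
#' @export
setGeneric("markers", function(object) standardGeneric("markers"))
#' @rdname accessors
#' @export
setGeneric("phenotypes", function(object) standardGeneric("phenotypes"))
#' @rdname accessors
#' @export
setGeneric("covariates", function(object) standardGeneric("covariates"))
#' @rdname accessors
#' @export
setGeneric("diagnosisLabels", function(object) standardGeneric("diagnosisLabels"))
#' @rdname accessors
#' @export
setGeneric("plantedTruth", function(object) standardGeneric("plantedTruth"))
#' @rdname accessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("layerPair", function(object) standardGeneric("layerPair"))
#' @rdname accessors
#' @export
setGeneric("layerNodes", function(object) standardGeneric("layerNodes"))
#' @rdname accessors
#' @export
setGeneric("edgeWeights", function(object) standardGeneric("edgeWeights"))
#' @rdname accessors
#' @export
setGeneric("edgeMasks", function(object) standardGeneric("edgeMasks"))
#' @rdname accessors
#' @export
setGeneric("edgeCount", function(object) standardGeneric("edgeCount"))
#' @rdname accessors
#' @export
setGeneric("moduleNodes", function(object) standardGeneric("moduleNodes"))
#' @rdname accessors
#' @export
setGeneric("moduleEdges", function(object) standardGeneric("moduleEdges"))

#' Accessors for slem S4 objects
#'
#' `genotypes()`, `isoforms()`, `markers()`, `phenotypes()`, `covariates()`,
#' `diagnosisLabels()` and `plantedTruth()` read the layer tables of datasets;
#' `records()` and `layerPair()` read association tables; `layerNodes()`,
#' `edgeWeights()`, `edgeMasks()` and `edgeCount()` read models (edgeCount is
#' the number of unmasked edges); `moduleNodes()`/`moduleEdges()` read
#' mediator modules.
#'
#' @name accessors
#' @return the corresponding slot contents.
NULL

#' @rdname accessors
setMethod("genotypes", "MultilevelDataset", function(object) object@genotypes)
#' @rdname accessors
setMethod("genotypes", "EndToEndDataset", function(object) object@genotypes)
#' @rdname accessors
setMethod("isoforms", "MultilevelDataset", function(object) object@isoforms)
#' @rdname accessors
setMethod("markers", "MultilevelDataset", function(object) object@markers)
#' @rdname accessors
setMethod("phenotypes", "MultilevelDataset", function(object) object@phenotypes)
#' @rdname accessors
setMethod("covariates", "MultilevelDataset", function(object) object@covariates)
#' @rdname accessors
setMethod("diagnosisLabels", "MultilevelDataset", function(object) object@diagnosis)
#' @rdname accessors
setMethod("diagnosisLabels", "EndToEndDataset", function(object) object@labels)
#' @rdname accessors
setMethod("plantedTruth", "MultilevelDataset", function(object) object@truth)
#' @rdname accessors
setMethod("records", "AssociationTable", function(object) object@records)
#' @rdname accessors
setMethod("layerPair", "AssociationTable", function(object) object@layerPair)
#' @rdname accessors
setMethod("layerNodes", "SlemModel", function(object) object@layers)
#' @rdname accessors
setMethod("edgeWeights", "SlemModel", function(object) object@weights)
#' @rdname accessors
setMethod("edgeMasks", "SlemModel", function(object) object@masks)
#' @rdname accessors
setMethod("edgeCount", "SlemModel",
          function(object) sum(vapply(object@masks, sum, numeric(1))))
#' @rdname accessors
setMethod("moduleNodes", "MediatorModule", function(object) object@nodes)
#' @rdname accessors
setMethod("moduleEdges", "MediatorModule", function(object) object@edges)

setMethod("show", "SynthConfig", function(object) {
    cat("SynthConfig:", object@nSamplesMultilevel, "multilevel /",
        object@nSamplesE2E, "end-to-end samples\n")
    cat("  layers:", object@nSnps, "SNPs ->", object@nIsoforms, "isoforms ->",
        object@nMarkers, "markers ->", object@nPhenotypes, "phenotypes -> disease\n")
    cat("  planted edges:", sum(object@effectIsoform != 0), "/",
        sum(object@effectMarker != 0), "/", sum(object@effectPhenotype != 0),
        "; noise SD", object@noiseSd, "; seed", object@seed, "\n")
})

setMethod("show", "MultilevelDataset", function(object) {
    cat("MultilevelDataset:", nrow(object@genotypes), "samples\n")
    cat("  genotypes:", ncol(object@genotypes), "SNPs; isoforms:",
        ncol(object@isoforms), "; markers:", ncol(object@markers),
        "; phenotypes:", ncol(object@phenotypes), "\n")
    cat("  cases:", sum(object@diagnosis), "/", length(object@diagnosis), "\n")
})

setMethod("show", "EndToEndDataset", function(object) {
    cat("EndToEndDataset:", nrow(object@genotypes), "samples x",
        ncol(object@genotypes), "SNPs;", sum(object@labels), "cases\n")
})

setMethod("show", "AssociationTable", function(object) {
    cat("AssociationTable [", object@layerPair, "]: ",
        nrow(object@records), " records, ",
        sum(object@records$q < 0.05, na.rm = TRUE), " with q < 0.05\n", sep = "")
})

setMethod("show", "SlemModel", function(object) {
    sizes <- vapply(object@layers, length, integer(1))
    cat("SlemModel: layers", paste(sizes, collapse = "/"),
        "|", edgeCount(object), "unmasked edges\n")
    cat("  activations:", paste(object@activations, collapse = ", "),
        "| epochs trained:",
        if (is.null(object@trainState$epochsTrained)) 0
        else object@trainState$epochsTrained, "\n")
})

setMethod("show", "TrainConfig", function(object) {
    cat("TrainConfig: lr", object@learningRate, "| batch", object@batchSize,
        "| epochs", object@epochs, "| folds", object@folds,
        "| repeats", object@repeats, "| seed", object@seed, "\n")
})

setMethod("show", "MediatorModule", function(object) {
    cat("MediatorModule anchored at:", paste(object@anchors, collapse = ", "), "\n")
    cat("  nodes:", paste(vapply(object@nodes, length, integer(1)),
                          collapse = "/"),
        "| edges:", nrow(object@edges), "\n")
})
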