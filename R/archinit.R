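#' Select layer nodes from an association table
#'
#' A target node is selected when its minimum q-value over all sources falls
#' strictly below the threshold; labels are returned deduplicated in stable
#' order of first appearance in the table.
#'
#' @param table an [AssociationTable-class].
#' @param qThreshold FDR cutoff in (0, 1).
#' @return character vector of selected target labels.
#' @export
selectNodes <- function(table, qThreshold) {
    stopIfNot(qThreshold > 0 && qThreshold < 1, "qThreshold must lie in (0, 1)")
    rec <- records(table)
    if (nrow(rec) == 0L) {
        warning("empty association table: no nodes selected")
        return(character(0))
    }
    targets <- unique(rec$target)
    minq <- vapply(split(rec$q, factor(rec$target, levels = targets)),
                   min, numeric(1))
    targets[minq < qThreshold]
}

#' Xavier (Glorot) normal standard deviation
#'
#' @param fanIn,fanOut positive fan counts.
#' @return `sqrt(2 / (fanIn + fanOut))`.
#' @export
xavierSigma <- function(fanIn, fanOut) {
    stopIfNot(fanIn >= 1 && fanOut >= 1, "fanIn and fanOut must be >= 1")
    sqrt(2 / (fanIn + fanOut))
}

#' Convert a two-sided p-value into a signed Xavier-scale weight
#'
#' Inverse-transform initialization: `sign * sigma * qnorm(1 - p/2)`. Smaller
#' p-values map to larger absolute weights; a population of uniform p-values
#' yields |weights| following the half-normal with scale `sigma`, i.e. the
#' absolute values of a Xavier normal draw.
#'
#' @param p two-sided p-value(s) in (0, 1].
#' @param sign +1 or -1, from the association direction.
#' @param sigma Xavier scale, see [xavierSigma()].
#' @return numeric weight(s).
#' @export
pvalueToWeight <- function(p, sign, sigma) {
    stopIfNot(all(p > 0 & p <= 1), "p must lie in (0, 1]")
    stopIfNot(all(sign %in% c(-1, 1)), "sign must be +1 or -1")
    sign * sigma * stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Keep the top fraction of nonzero weights by absolute value
#'
#' Among the E entries with nonzero initial weight, the `ceiling(keepFraction
#' * E)` largest |weights| are kept (mask 1); everything else is masked 0.
#' Ties in |weight| are broken by (row, column) lexicographic order.
#'
#' @param weights numeric matrix.
#' @param keepFraction fraction in (0, 1].
#' @return binary mask matrix of the same shape.
#' @export
maskTopFraction <- function(weights, keepFraction) {
    stopIfNot(keepFraction > 0 && keepFraction <= 1,
              "keepFraction must lie in (0, 1]")
    mask <- array(0, dim = dim(weights), dimnames = dimnames(weights))
    nz <- which(weights != 0)
    if (length(nz) == 0L) {
        warning("all-zero weight matrix: mask is all zero")
        return(mask)
    }
    keep <- as.integer(ceiling(keepFraction * length(nz)))
    rows <- (nz - 1L) %% nrow(weights) + 1L
    cols <- (nz - 1L) %/% nrow(weights) + 1L
    ord <- order(-abs(weights[nz]), rows, cols)
    mask[nz[ord[seq_len(keep)]]] <- 1
    mask
}

# Dense (fanIn x fanOut) weight matrix from an association table restricted to
# selected node labels, via the p-value -> Xavier inverse transform; pairs
# with nominal p >= pCutoff are zeroed before masking.
#
# transform = "rank" (default) maps the layer's p-values through their
# empirical ranks onto Xavier-normal quantiles, so the initialized weight
# population is exactly Xavier-distributed (|w| bounded near 3 sigma) while
# preserving the smaller-p => larger-|w| ordering. transform = "direct"
# applies the closed form sign * sigma * qnorm(1 - p/2) per edge, which can
# produce weights of many sigma when p-values underflow at large sample
# sizes, saturating the tanh units downstream.
edgeInitMatrix <- function(table, sources, targets, pCutoff,
                           transform = c("rank", "direct")) {
    transform <- match.arg(transform)
    rec <- records(table)
    rec <- rec[rec$source %in% sources & rec$target %in% targets, , drop = FALSE]
    sigma <- xavierSigma(length(sources), length(targets))
    W <- matrix(0, length(sources), length(targets),
                dimnames = list(sources, targets))
    if (nrow(rec)) {
        if (transform == "rank") {
            u <- (rank(rec$p, ties.method = "average") - 0.5) / nrow(rec)
            w <- pvalueToWeight(u, rec$sign, sigma)
        } else {
            w <- pvalueToWeight(rec$p, rec$sign, sigma)
        }
        w[rec$p >= pCutoff] <- 0
        W[cbind(match(rec$source, sources), match(rec$target, targets))] <- w
    }
    W
}

#' Assemble the sparse initialized five-layer model
#'
#' Node selection and edge initialization in one step:
#' \enumerate{
#'   \item isoform, marker and phenotype nodes are selected from the SNP-side
#'     association tables at per-layer FDR thresholds (defaults 0.1 / 0.05 /
#'     0.05);
#'   \item edges between adjacent selected layers are initialized from the
#'     nominal association p-values (SNP->isoform from the linear table, the
#'     two upper layers from the Kendall tables) by an inverse transform onto
#'     the Xavier normal. By default (`weightTransform = "rank"`) each
#'     layer's p-values are mapped through their empirical ranks onto Xavier
#'     quantiles, so the initialized weights are Xavier-distributed and
#'     bounded near 3 sigma regardless of how extreme the p-values are;
#'     `"direct"` applies [pvalueToWeight()] per edge instead. Non-significant
#'     pairs (nominal p >= `pCutoff`) are zeroed;
#'   \item per layer, only the top `keepFraction` of the surviving edges (by
#'     absolute weight) are unmasked;
#'   \item the phenotype->disease edges carry no association information and
#'     are drawn fresh from the Xavier normal under `seed`.
#' }
#'
#' @param tables named list of [AssociationTable-class] objects with elements
#'   `snpIsoform`, `isoformMarker`, `markerPhenotype` and (for marker /
#'   phenotype node selection) `snpMarker`, `snpPhenotype`. If the latter two
#'   are missing, markers and phenotypes are selected from the corresponding
#'   edge tables instead.
#' @param qThresholds FDR cutoffs for the isoform, marker, phenotype layers.
#' @param pCutoff nominal-p significance cutoff applied before masking.
#' @param keepFraction per-layer keep fraction (default 0.35).
#' @param weightTransform `"rank"` (default) or `"direct"`; see Details.
#' @param diseaseLabel label of the single output node.
#' @param seed seed for the output-layer Xavier draw.
#' @return a [SlemModel-class].
#' @export
buildModel <- function(tables,
                       qThresholds = c(isoform = 0.1, marker = 0.05,
                                       phenotype = 0.05),
                       pCutoff = 0.05, keepFraction = 0.35,
                       weightTransform = c("rank", "direct"),
                       diseaseLabel = "disease", seed = 1L) {
    weightTransform <- match.arg(weightTransform)
    need <- c("snpIsoform", "isoformMarker", "markerPhenotype")
    stopIfNot(all(need %in% names(tables)),
              paste("tables must include:", paste(need, collapse = ", ")))
    snps <- unique(records(tables$snpIsoform)$source)
    isoSel <- selectNodes(tables$snpIsoform, qThresholds[["isoform"]])
    mrkSel <- selectNodes(
        if (!is.null(tables$snpMarker)) tables$snpMarker else tables$isoformMarker,
        qThresholds[["marker"]])
    pheSel <- selectNodes(
        if (!is.null(tables$snpPhenotype)) tables$snpPhenotype
        else tables$markerPhenotype,
        qThresholds[["phenotype"]])
    for (lay in list(c("isoform", length(isoSel)), c("marker", length(mrkSel)),
                     c("phenotype", length(pheSel))))
        if (as.integer(lay[2L]) == 0L)
            stop("architecture error: no nodes selected for the ", lay[1L],
                 " layer", call. = FALSE)

    W1 <- edgeInitMatrix(tables$snpIsoform, snps, isoSel, pCutoff, weightTransform)
    W2 <- edgeInitMatrix(tables$isoformMarker, isoSel, mrkSel, pCutoff, weightTransform)
    W3 <- edgeInitMatrix(tables$markerPhenotype, mrkSel, pheSel, pCutoff, weightTransform)
    M1 <- maskTopFraction(W1, keepFraction)
    M2 <- maskTopFraction(W2, keepFraction)
    M3 <- maskTopFraction(W3, keepFraction)
    w4 <- withSeed(seed, matrix(
        stats::rnorm(length(pheSel), 0, xavierSigma(length(pheSel), 1L)),
        ncol = 1L, dimnames = list(pheSel, diseaseLabel)))
    M4 <- array(1, dim = dim(w4), dimnames = dimnames(w4))
    new("SlemModel",
        layers = list(snp = snps, isoform = isoSel, marker = mrkSel,
                      phenotype = pheSel, disease = diseaseLabel),
        weights = list(W1 * M1, W2 * M2, W3 * M3, w4),
        masks = list(M1, M2, M3, M4),
        activations = c("tanh", "tanh", "tanh", "sigmoid"),
        seed = as.integer(seed),
        trainState = list(optimizer = "adam", epochsTrained = 0L))
}

#' Serialize a model to JSON (lossless round trip)
#' @param model a [SlemModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSlemModel <- function(model, path) {
    packMat <- function(W)
        list(dim = dim(W), dimnames = dimnames(W), values = as.numeric(W))
    obj <- list(
        layers = model@layers,
        weights = stats::setNames(lapply(model@weights, packMat),
                                  paste0("w", 1:4)),
        masks = stats::setNames(lapply(model@masks, packMat),
                                paste0("m", 1:4)),
        activations = model@activations,
        seed = model@seed,
        trainState = model@trainState)
    # I(17) significant digits: doubles survive the text round trip bit-exactly
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
    invisible(path)
}

#' Read a model back from JSON
#' @param path file written by [writeSlemModel()].
#' @return a [SlemModel-class].
#' @export
readSlemModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    remat <- function(m)
        matrix(as.numeric(m$values), m$dim[1L], m$dim[2L],
               dimnames = lapply(m$dimnames, as.character))
    ts <- as.list(obj$trainState)
    if (!is.null(ts$epochsTrained)) ts$epochsTrained <- as.integer(ts$epochsTrained)
    new("SlemModel",
        layers = lapply(obj$layers, as.character),
        weights = unname(lapply(obj$weights, remat)),
        masks = unname(lapply(obj$masks, remat)),
        activations = as.character(obj$activations),
        seed = as.integer(obj$seed),
        trainState = ts)
}
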