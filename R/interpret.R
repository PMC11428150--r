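#' Per-SNP impact scores by explicit path enumeration
#'
#' Treats each node as a linear combiner (activation functions deliberately
#' ignored): the impact of a SNP is the absolute value of the sum, over every
#' unmasked path SNP -> isoform -> marker -> phenotype -> disease, of the
#' product of edge weights along the path. A SNP with no surviving path
#' scores 0. This is the reference implementation; [impactScoresMatrix()]
#' computes the same quantity as a matrix product.
#'
#' @param model a trained or initialized [SlemModel-class].
#' @param useTrained ignored placeholder for API symmetry; scores always use
#'   the model's current (masked) weights.
#' @return data.frame with columns `snp`, `score`, `rank`, sorted by
#'   descending score, ties broken lexicographically by label.
#' @export
impactScoresPaths <- function(model, useTrained = TRUE) {
    W <- mapply(function(w, m) w * m, model@weights, model@masks,
                SIMPLIFY = FALSE)
    snps <- model@layers[[1L]]
    score <- vapply(seq_along(snps), function(s) {
        total <- 0
        e1 <- which(W[[1L]][s, ] != 0)
        for (i in e1) {
            e2 <- which(W[[2L]][i, ] != 0)
            for (j in e2) {
                e3 <- which(W[[3L]][j, ] != 0)
                for (k in e3) {
                    if (W[[4L]][k, 1L] != 0)
                        total <- total + W[[1L]][s, i] * W[[2L]][i, j] *
                            W[[3L]][j, k] * W[[4L]][k, 1L]
                }
            }
        }
        abs(total)
    }, numeric(1))
    impactTable(snps, score)
}

#' Per-SNP impact scores via the weight-matrix product
#'
#' `|(W1 o M1)(W2 o M2)(W3 o M3) w4|` per SNP row; algebraically identical to
#' [impactScoresPaths()] because the per-node combination rule is linear.
#'
#' @inheritParams impactScoresPaths
#' @return data.frame as in [impactScoresPaths()].
#' @export
impactScoresMatrix <- function(model, useTrained = TRUE) {
    W <- mapply(function(w, m) w * m, model@weights, model@masks,
                SIMPLIFY = FALSE)
    v <- abs(as.numeric(W[[1L]] %*% W[[2L]] %*% W[[3L]] %*% W[[4L]]))
    impactTable(model@layers[[1L]], v)
}

impactTable <- function(snps, score) {
    ord <- order(-score, snps)
    out <- data.frame(snp = snps[ord], score = score[ord],
                      rank = seq_along(snps), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Top-k SNPs by impact score
#'
#' @param table impact table from [impactScoresMatrix()] /
#'   [impactScoresPaths()].
#' @param k number of SNPs (default 5); ties are already lexicographic in the
#'   table.
#' @return character vector of SNP labels.
#' @export
topSnps <- function(table, k = 5L) {
    stopIfNot(k >= 1, "k must be a positive count")
    stopIfNot(k <= nrow(table), "k must not exceed the number of SNPs")
    table$snp[seq_len(as.integer(k))]
}

#' Extract the mediator module around anchor phenotype nodes
#'
#' Keeps the top `weightFraction` of |weights| globally over the unmasked
#' edges of the three inter-layer matrices (SNP->isoform, isoform->marker,
#' marker->phenotype), then retains exactly the nodes and edges that lie on a
#' surviving directed path into one of the anchor phenotype nodes.
#'
#' @param model a (typically trained) [SlemModel-class].
#' @param anchorPhenotypes phenotype node labels to project onto.
#' @param weightFraction fraction of strong edges kept globally (default 0.10).
#' @return a [MediatorModule-class].
#' @export
extractModule <- function(model, anchorPhenotypes, weightFraction = 0.10) {
    stopIfNot(weightFraction > 0 && weightFraction <= 1,
              "weightFraction must lie in (0, 1]")
    unknown <- setdiff(anchorPhenotypes, model@layers[[4L]])
    if (length(unknown))
        stop("unknown anchor label(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    W <- mapply(function(w, m) w * m, model@weights[1:3], model@masks[1:3],
                SIMPLIFY = FALSE)
    absw <- unlist(lapply(W, function(w) abs(w[w != 0])))
    if (length(absw) == 0L)
        stop("model has no unmasked edges in the first three layers",
             call. = FALSE)
    keep <- ceiling(weightFraction * length(absw))
    thr <- sort(absw, decreasing = TRUE)[keep]
    strong <- lapply(W, function(w) (abs(w) >= thr) & (w != 0))
    # backward reachability from the anchors (indices into each layer)
    pheIdx <- match(anchorPhenotypes, model@layers[[4L]])
    mrkIdx <- which(rowSums(strong[[3L]][, pheIdx, drop = FALSE]) > 0)
    isoIdx <- which(rowSums(strong[[2L]][, mrkIdx, drop = FALSE]) > 0)
    snpIdx <- which(rowSums(strong[[1L]][, isoIdx, drop = FALSE]) > 0)
    edgeDf <- function(w, s, fromIdx, toIdx, fromLab, toLab, layer) {
        idx <- which(s[fromIdx, toIdx, drop = FALSE], arr.ind = TRUE)
        if (nrow(idx) == 0L)
            return(data.frame(from = character(0), to = character(0),
                              layer = character(0), weight = numeric(0),
                              stringsAsFactors = FALSE))
        data.frame(from = fromLab[fromIdx][idx[, 1L]],
                   to = toLab[toIdx][idx[, 2L]],
                   layer = layer,
                   weight = w[fromIdx, toIdx, drop = FALSE][idx],
                   stringsAsFactors = FALSE)
    }
    L <- model@layers
    edges <- rbind(
        edgeDf(W[[1L]], strong[[1L]], snpIdx, isoIdx, L[[1L]], L[[2L]],
               "snp->isoform"),
        edgeDf(W[[2L]], strong[[2L]], isoIdx, mrkIdx, L[[2L]], L[[3L]],
               "isoform->marker"),
        edgeDf(W[[3L]], strong[[3L]], mrkIdx, pheIdx, L[[3L]], L[[4L]],
               "marker->phenotype"))
    rownames(edges) <- NULL
    new("MediatorModule",
        nodes = list(snp = L[[1L]][snpIdx], isoform = L[[2L]][isoIdx],
                     marker = L[[3L]][mrkIdx], phenotype = anchorPhenotypes),
        edges = edges, anchors = anchorPhenotypes)
}

#' Write an impact table as TSV (snp, score, rank)
#' @param table impact table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeImpactTsv <- function(table, path) {
    utils::write.table(table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a mediator module as JSON plus a plain edge list
#'
#' @param module a [MediatorModule-class].
#' @param path JSON output file; an edge-list TSV (`from`, `to`, `weight`) is
#'   written next to it with extension `.edges.tsv` for graph tools.
#' @return `path`, invisibly.
#' @export
writeModuleJson <- function(module, path) {
    jsonlite::write_json(list(nodes = module@nodes,
                              anchors = module@anchors,
                              edges = module@edges),
                         path, auto_unbox = TRUE, digits = NA)
    edgePath <- sub("\\.json$", "", path)
    utils::write.table(module@edges, paste0(edgePath, ".edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
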