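#' Covariate-adjusted linear association between one predictor and one response
#'
#' Ordinary least squares of `y` on `[1, x, covariates]` after listwise
#' deletion; the reported statistic is the slope of `x`, with its two-sided
#' t-test p-value. Mirrors per-pair eQTL / GLM association testing.
#'
#' @param x numeric predictor (e.g. one SNP, additive-coded).
#' @param y numeric response (e.g. one isoform's expression).
#' @param covariates optional numeric matrix/data.frame of adjustment
#'   covariates.
#' @param source,target optional labels stored in the record.
#' @return one-row data.frame: source, target, statistic (slope), sign, p, q
#'   (q is `NA` here; it is filled in per-table by [batchAssoc()]).
#' @export
linearAssoc <- function(x, y, covariates = NULL, source = "x", target = "y") {
    x <- as.numeric(x); y <- as.numeric(y)
    stopIfNot(length(x) == length(y), "x and y must have equal length")
    C <- if (is.null(covariates)) NULL else as.matrix(covariates)
    keep <- stats::complete.cases(x, y, if (is.null(C)) rep(0, length(x)) else C)
    x <- x[keep]; y <- y[keep]
    if (!is.null(C)) C <- C[keep, , drop = FALSE]
    n <- length(x)
    ncov <- if (is.null(C)) 0L else ncol(C)
    stopIfNot(n > ncov + 2L, "too few complete observations for the design")
    if (stats::sd(x) == 0)
        stop("degenerate predictor: x is constant after listwise deletion",
             call. = FALSE)
    X <- cbind(`(Intercept)` = 1, x = x, C)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
        stop("singular design: covariates are collinear with the predictor",
             call. = FALSE)
    fit <- qr.coef(qrX, y)
    res <- y - X %*% fit
    df <- n - ncol(X)
    sigma2 <- sum(res^2) / df
    XtXinv <- chol2inv(qr.R(qrX))
    se <- sqrt(sigma2 * XtXinv[2L, 2L])
    slope <- fit[["x"]]
    tval <- if (se == 0) sign(slope) * Inf else slope / se
    p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    p <- max(p, .Machine$double.xmin)   # keep p in (0, 1]
    data.frame(source = source, target = target, statistic = slope,
               sign = if (slope >= 0) 1 else -1, p = p, q = NA_real_,
               stringsAsFactors = FALSE)
}

#' Kendall rank association (tau-b) between two vectors
#'
#' Tie-corrected Kendall tau-b with a two-sided p-value: exact for n <= 10
#' without ties, continuity-corrected normal approximation otherwise. Used
#' for the upper layer pairs, whose neuropathology-style features need not be
#' normally distributed.
#'
#' @param x,y numeric vectors (n >= 3 after listwise deletion).
#' @param source,target optional labels.
#' @return one-row data.frame as in [linearAssoc()] with statistic = tau-b.
#' @export
kendallAssoc <- function(x, y, source = "x", target = "y") {
    keep <- stats::complete.cases(x, y)
    x <- as.numeric(x)[keep]; y <- as.numeric(y)[keep]
    n <- length(x)
    stopIfNot(n >= 3L, "kendallAssoc needs n >= 3")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("degenerate predictor: constant vector", call. = FALSE)
    exact <- n <= 10L && !anyDuplicated(x) && !anyDuplicated(y)
    ct <- suppressWarnings(
        stats::cor.test(x, y, method = "kendall", exact = exact,
                        continuity = !exact))
    tau <- unname(ct$estimate)
    p <- max(min(ct$p.value, 1), .Machine$double.xmin)
    data.frame(source = source, target = target, statistic = tau,
               sign = if (tau >= 0) 1 else -1, p = p, q = NA_real_,
               stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, clipped at 1, monotone in rank and invariant to
#' input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted q-values, same order as input.
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0L) return(numeric(0))
    stopIfNot(all(p > 0 & p <= 1), "p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

# Frisch-Waugh-Lovell batch OLS: project the covariate design out of both
# sides once, then every (x, y) pair reduces to a simple regression on the
# residuals; identical to the full OLS per pair. Returns slope, t, p matrices.
fwlBatch <- function(X, Y, C) {
    n <- nrow(X)
    D <- cbind(1, C)
    qrD <- qr(D)
    RX <- X - qr.fitted(qrD, X)
    RY <- Y - qr.fitted(qrD, Y)
    xx <- colSums(RX^2)
    yy <- colSums(RY^2)
    XtY <- crossprod(RX, RY)                     # p x q
    degenerate <- xx < n * 1e-24
    xxSafe <- ifelse(degenerate, 1, xx)
    slope <- XtY / xxSafe
    df <- n - ncol(D) - 1L
    rss <- pmax(outer(rep(1, nrow(XtY)), yy) - slope * XtY, 0)
    se <- sqrt(rss / df / xxSafe)
    tval <- ifelse(se == 0, sign(slope) * Inf, slope / se)
    p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    p <- pmax(pmin(p, 1), .Machine$double.xmin)
    if (any(degenerate)) {
        slope[degenerate, ] <- 0
        p[degenerate, ] <- 1
    }
    list(slope = slope, p = p, degenerate = degenerate, df = df)
}

validLayerPairs <- c("snp->isoform", "snp->marker", "snp->phenotype",
                     "isoform->marker", "marker->phenotype")

layerMatrix <- function(dataset, layer) {
    switch(layer,
           snp = dataset@genotypes,
           isoform = dataset@isoforms,
           marker = dataset@markers,
           phenotype = dataset@phenotypes,
           stop("unknown layer: ", layer, call. = FALSE))
}

#' Batch pairwise associations between two adjacent layers
#'
#' Computes one association record per (source, target) pair. SNP-sourced
#' pairs use covariate-adjusted linear associations ([linearAssoc()]
#' semantics, vectorised); isoform->marker and marker->phenotype pairs use the
#' Kendall rank test ([kendallAssoc()]). q-values are Benjamini-Hochberg
#' adjusted within the table.
#'
#' For `snp->isoform` the adjustment follows the eQTL protocol: age, sex and
#' diagnosis, optionally plus the top `nPCs` principal components of the
#' isoform matrix as surrogates for hidden expression confounders. The PC
#' term defaults to 0 because it is only meaningful when the isoform pool is
#' much larger than the number of components: with a desk-scale pool (tens of
#' isoforms) the top PCs coincide with the strongest genotype-driven
#' expression directions and residualising against them removes the very
#' associations being tested. Set `nPCs` (e.g. `min(15, n - 10)`) when
#' analysing transcriptome-scale isoform tables. SNP->marker and
#' SNP->phenotype adjust for age, sex and diagnosis only.
#'
#' @param dataset a [MultilevelDataset-class].
#' @param layerPair one of `"snp->isoform"`, `"snp->marker"`,
#'   `"snp->phenotype"`, `"isoform->marker"`, `"marker->phenotype"`.
#' @param covariates covariate column labels from the dataset's covariate
#'   table (ignored for the Kendall pairs).
#' @param nPCs number of expression principal components added for
#'   `snp->isoform` (default 0; see Details).
#' @return an [AssociationTable-class].
#' @export
batchAssoc <- function(dataset, layerPair,
                       covariates = c("age", "sex", "diagnosis"),
                       nPCs = 0L) {
    stopIfNot(layerPair %in% validLayerPairs,
              paste("layerPair must be one of:",
                    paste(validLayerPairs, collapse = ", ")))
    parts <- strsplit(layerPair, "->", fixed = TRUE)[[1L]]
    X <- layerMatrix(dataset, parts[1L])
    Y <- layerMatrix(dataset, parts[2L])
    if (parts[1L] == "snp") {
        bad <- setdiff(covariates, colnames(dataset@covariates))
        if (length(bad))
            stop("unknown covariate label(s): ", paste(bad, collapse = ", "),
                 call. = FALSE)
        C <- as.matrix(dataset@covariates[, covariates, drop = FALSE])
        if (layerPair == "snp->isoform") {
            n <- nrow(X)
            nPCs <- min(as.integer(nPCs), max(n - 10L, 0L),
                        ncol(dataset@isoforms) - 1L)
            if (nPCs > 0L) {
                pcs <- stats::prcomp(dataset@isoforms, center = TRUE,
                                     scale. = FALSE)$x[, seq_len(nPCs), drop = FALSE]
                C <- cbind(C, pcs)
            }
        }
        if (anyNA(X) || anyNA(Y) || anyNA(C)) {
            # listwise deletion per pair: fall back to the pairwise engine
            rec <- do.call(rbind, lapply(seq_len(ncol(X)), function(j) {
                do.call(rbind, lapply(seq_len(ncol(Y)), function(k) {
                    tryCatch(linearAssoc(X[, j], Y[, k], C,
                                         source = colnames(X)[j],
                                         target = colnames(Y)[k]),
                             error = function(e)
                                 data.frame(source = colnames(X)[j],
                                            target = colnames(Y)[k],
                                            statistic = 0, sign = 1, p = 1,
                                            q = NA_real_))
                }))
            }))
        } else {
            fb <- fwlBatch(X, Y, C)
            rec <- data.frame(
                source = rep(colnames(X), times = ncol(Y)),
                target = rep(colnames(Y), each = ncol(X)),
                statistic = as.numeric(fb$slope),
                sign = ifelse(as.numeric(fb$slope) >= 0, 1, -1),
                p = as.numeric(fb$p), q = NA_real_,
                stringsAsFactors = FALSE)
        }
    } else {
        rec <- do.call(rbind, lapply(seq_len(ncol(X)), function(j) {
            do.call(rbind, lapply(seq_len(ncol(Y)), function(k) {
                tryCatch(kendallAssoc(X[, j], Y[, k],
                                      source = colnames(X)[j],
                                      target = colnames(Y)[k]),
                         error = function(e)
                             data.frame(source = colnames(X)[j],
                                        target = colnames(Y)[k],
                                        statistic = 0, sign = 1, p = 1,
                                        q = NA_real_))
            }))
        }))
    }
    rec$q <- bhAdjust(rec$p)
    rownames(rec) <- NULL
    new("AssociationTable", records = rec, layerPair = layerPair)
}

#' Write an association table as TSV
#' @param table an [AssociationTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAssociationTsv <- function(table, path) {
    utils::write.table(records(table), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
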