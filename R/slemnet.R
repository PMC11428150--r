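#' Create a training configuration
#'
#' Defaults are the tuned hyperparameters: learning rate 0.005, batch size
#' 250, 750 epochs, 10-fold cross-validation, 100 repeated models, ADAM
#' optimizer (beta1 = 0.9, beta2 = 0.999, eps = 1e-8), binary cross-entropy
#' loss, no bias terms.
#'
#' @param learningRate ADAM step size.
#' @param batchSize mini-batch size.
#' @param epochs passes over the training data.
#' @param folds cross-validation folds.
#' @param repeats number of repeated trained models for averaged evaluation.
#' @param seed integer seed controlling shuffling and fold assignment.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(learningRate = 0.005, batchSize = 250L, epochs = 750L,
                        folds = 10L, repeats = 100L, seed = 1L) {
    new("TrainConfig", learningRate = as.numeric(learningRate),
        batchSize = as.integer(batchSize), epochs = as.integer(epochs),
        folds = as.integer(folds), repeats = as.integer(repeats),
        seed = as.integer(seed))
}

checkGenotypeSchema <- function(model, X) {
    want <- model@layers[[1L]]
    missing <- setdiff(want, colnames(X))
    if (length(missing))
        stop("genotype columns do not match the SNP layer; missing: ",
             paste(utils::head(missing, 10L), collapse = ", "),
             if (length(missing) > 10L) ", ..." else "", call. = FALSE)
    X[, want, drop = FALSE]
}

#' Forward pass through the masked network
#'
#' `h1 = tanh(X (W1 o M1))`, `h2 = tanh(h1 (W2 o M2))`,
#' `h3 = tanh(h2 (W3 o M3))`, `yhat = sigmoid(h3 w4)`; no bias terms. The
#' sign of an intermediate activation is the node's predicted on-off status.
#'
#' @param model a [SlemModel-class].
#' @param X genotype batch (samples x SNPs); columns are matched to the SNP
#'   layer by name.
#' @return list with elements `h1`, `h2`, `h3`, `yhat`.
#' @export
slemForward <- function(model, X) {
    X <- checkGenotypeSchema(model, as.matrix(X))
    W <- model@weights; M <- model@masks
    h1 <- tanh(X %*% (W[[1L]] * M[[1L]]))
    h2 <- tanh(h1 %*% (W[[2L]] * M[[2L]]))
    h3 <- tanh(h2 %*% (W[[3L]] * M[[3L]]))
    yhat <- sigmoid(h3 %*% (W[[4L]] * M[[4L]]))
    list(h1 = h1, h2 = h2, h3 = h3, yhat = yhat)
}

# Mean binary cross-entropy with probability clipping.
bceLoss <- function(p, y, eps = 1e-12) {
    p <- pmin(pmax(p, eps), 1 - eps)
    -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Current mean binary cross-entropy of a model on a dataset
#' @param model a [SlemModel-class].
#' @param data an [EndToEndDataset-class].
#' @return scalar loss.
#' @export
modelLoss <- function(model, data) {
    fw <- slemForward(model, genotypes(data))
    bceLoss(as.numeric(fw$yhat), data@labels)
}

#' Train the masked network with ADAM and gradient masking
#'
#' Minimizes binary cross-entropy by mini-batch backpropagation. Every
#' gradient is multiplied elementwise by the layer's binary mask before the
#' ADAM update, and weights are re-masked after each step, so masked edges
#' remain exactly zero throughout training. Deterministic under the config
#' seed (single-threaded).
#'
#' @param model a [SlemModel-class].
#' @param data an [EndToEndDataset-class] containing both classes.
#' @param config a [TrainConfig-class]; `folds`/`repeats` are ignored here.
#' @return the trained [SlemModel-class] (trainState records epochs and the
#'   final training loss).
#' @export
trainSlem <- function(model, data, config = trainConfig()) {
    X <- checkGenotypeSchema(model, genotypes(data))
    y <- data@labels
    if (length(unique(y)) < 2L)
        stop("training error: data contain a single class", call. = FALSE)
    W <- model@weights; M <- model@masks
    mState <- lapply(W, function(w) array(0, dim = dim(w)))
    vState <- lapply(W, function(w) array(0, dim = dim(w)))
    lr <- config@learningRate
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    n <- nrow(X); step <- 0L
    withSeed(config@seed, {
        for (epoch in seq_len(config@epochs)) {
            idx <- sample.int(n)
            starts <- seq(1L, n, by = config@batchSize)
            for (s in starts) {
                b <- idx[s:min(s + config@batchSize - 1L, n)]
                Xb <- X[b, , drop = FALSE]; yb <- y[b]
                W1 <- W[[1L]] * M[[1L]]; W2 <- W[[2L]] * M[[2L]]
                W3 <- W[[3L]] * M[[3L]]; W4 <- W[[4L]] * M[[4L]]
                h1 <- tanh(Xb %*% W1)
                h2 <- tanh(h1 %*% W2)
                h3 <- tanh(h2 %*% W3)
                p <- sigmoid(h3 %*% W4)
                # dL/dz4 for BCE+sigmoid, averaged over the batch
                dz4 <- (p - yb) / length(yb)
                g4 <- crossprod(h3, dz4)
                dh3 <- dz4 %*% t(W4)
                dz3 <- dh3 * (1 - h3^2)
                g3 <- crossprod(h2, dz3)
                dh2 <- dz3 %*% t(W3)
                dz2 <- dh2 * (1 - h2^2)
                g2 <- crossprod(h1, dz2)
                dh1 <- dz2 %*% t(W2)
                dz1 <- dh1 * (1 - h1^2)
                g1 <- crossprod(Xb, dz1)
                grads <- list(g1, g2, g3, g4)
                step <- step + 1L
                for (l in seq_len(4L)) {
                    g <- grads[[l]] * M[[l]]
                    mState[[l]] <- b1 * mState[[l]] + (1 - b1) * g
                    vState[[l]] <- b2 * vState[[l]] + (1 - b2) * g * g
                    mhat <- mState[[l]] / (1 - b1^step)
                    vhat <- vState[[l]] / (1 - b2^step)
                    W[[l]] <- (W[[l]] - lr * mhat / (sqrt(vhat) + eps)) * M[[l]]
                }
            }
        }
    })
    out <- model
    out@weights <- W
    out@trainState <- utils::modifyList(model@trainState, list(
        optimizer = "adam", learningRate = lr, batchSize = config@batchSize,
        epochsTrained = (if (is.null(model@trainState$epochsTrained)) 0L
                         else model@trainState$epochsTrained) + config@epochs))
    out@trainState$finalLoss <- modelLoss(out, data)
    out
}

#' Area under the ROC curve
#'
#' The probability that a random positive outscores a random negative, ties
#' counted one half (Mann-Whitney U normalization).
#'
#' @param scores real-valued predictions.
#' @param labels binary 0/1 labels; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
aurocScore <- function(scores, labels) {
    labels <- as.integer(labels)
    n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
    if (n1 == 0L || n0 == 0L)
        stop("undefined metric: both classes must be present", call. = FALSE)
    r <- rank(scores)
    (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: cases and controls are split separately so each
# fold keeps the class balance.
stratifiedFolds <- function(labels, folds, seed) {
    withSeed(seed, {
        f <- integer(length(labels))
        for (cls in unique(labels)) {
            i <- which(labels == cls)
            f[i] <- sample(rep_len(seq_len(folds), length(i)))
        }
        f
    })
}

#' Stratified k-fold cross-validation of a model template
#'
#' For each fold a fresh copy of the (initialized) template is trained on the
#' remaining folds and scored by AUROC on the held-out fold.
#'
#' @param model the initialized [SlemModel-class] template.
#' @param data an [EndToEndDataset-class] with `n >= folds`.
#' @param config a [TrainConfig-class].
#' @return list with `mean`, `sd` and `perFold` (data.frame fold / auroc).
#' @export
crossValidate <- function(model, data, config = trainConfig()) {
    y <- data@labels
    stopIfNot(config@folds <= length(y), "folds must not exceed sample count")
    fold <- stratifiedFolds(y, config@folds, config@seed)
    res <- vapply(seq_len(config@folds), function(k) {
        tr <- which(fold != k); te <- which(fold == k)
        dtr <- new("EndToEndDataset",
                   genotypes = data@genotypes[tr, , drop = FALSE],
                   labels = y[tr])
        cfg <- config; cfg@seed <- config@seed + k
        fit <- trainSlem(model, dtr, cfg)
        sc <- as.numeric(slemForward(fit, data@genotypes[te, , drop = FALSE])$yhat)
        aurocScore(sc, y[te])
    }, numeric(1))
    list(mean = mean(res), sd = stats::sd(res),
         perFold = data.frame(fold = seq_len(config@folds), auroc = res))
}

#' Fully connected comparator model
#'
#' Same layers and nodes as a sparse model, but with all-ones masks and
#' Xavier-normal weights throughout; the conventional (biologically
#' unlabelled) baseline. For layers 138/67/42/19/1 this model has
#' 138*67 + 67*42 + 42*19 + 19 = 12877 edges.
#'
#' @param layers either a [SlemModel-class] (its layer labels are reused), a
#'   named list of 5 label vectors, or an integer vector of 5 layer sizes.
#' @param seed seed for the Xavier draws.
#' @return a [SlemModel-class] with all edges unmasked.
#' @export
fullyConnectedBaseline <- function(layers, seed = 1L) {
    if (is(layers, "SlemModel")) layers <- layers@layers
    if (is.numeric(layers)) {
        stopIfNot(length(layers) == 5L, "5 layer sizes required")
        pref <- c("snp", "iso", "mrk", "phe", "dis")
        layers <- stats::setNames(
            lapply(seq_len(5L), function(i) makeLabels(pref[i], layers[i])),
            c("snp", "isoform", "marker", "phenotype", "disease"))
    }
    W <- withSeed(seed, lapply(seq_len(4L), function(i) {
        fi <- length(layers[[i]]); fo <- length(layers[[i + 1L]])
        matrix(stats::rnorm(fi * fo, 0, xavierSigma(fi, fo)), fi, fo,
               dimnames = list(layers[[i]], layers[[i + 1L]]))
    }))
    M <- lapply(W, function(w) array(1, dim = dim(w), dimnames = dimnames(w)))
    new("SlemModel", layers = layers, weights = W, masks = M,
        activations = c("tanh", "tanh", "tanh", "sigmoid"),
        seed = as.integer(seed),
        trainState = list(optimizer = "adam", epochsTrained = 0L))
}

#' Write cross-validation metrics as TSV (fold, auroc)
#' @param cv result of [crossValidate()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMetricsTsv <- function(cv, path) {
    utils::write.table(cv$perFold, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
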