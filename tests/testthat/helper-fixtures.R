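# Shared fixtures and independent oracles used across the test files.

# Random small five-layer model with the given layer sizes and mask density.
randomModel <- function(sizes = c(6, 4, 3, 2, 1), density = 0.7, seed = 1) {
    pref <- c("snp", "iso", "mrk", "phe", "dis")
    layers <- stats::setNames(
        lapply(seq_len(5), function(i) sprintf("%s%03d", pref[i], seq_len(sizes[i]))),
        c("snp", "isoform", "marker", "phenotype", "disease"))
    withr::with_seed(seed, {
        W <- lapply(seq_len(4), function(i) {
            m <- matrix(rnorm(sizes[i] * sizes[i + 1]), sizes[i], sizes[i + 1],
                        dimnames = list(layers[[i]], layers[[i + 1]]))
            m
        })
        M <- lapply(W, function(w) {
            m <- array(rbinom(length(w), 1, density), dim = dim(w),
                       dimnames = dimnames(w))
            m[1, 1] <- 1   # keep a spine so the network stays connected
            m
        })
        W <- mapply(function(w, m) w * m, W, M, SIMPLIFY = FALSE)
        new("SlemModel", layers = layers, weights = W, masks = M,
            activations = c("tanh", "tanh", "tanh", "sigmoid"), seed = 1L,
            trainState = list(optimizer = "adam", epochsTrained = 0L))
    })
}

# Single-path chain model with one node per layer and the given edge weights.
chainModel <- function(w = c(2, 0.5, -1, 3)) {
    layers <- list(snp = "A", isoform = "I", marker = "M",
                   phenotype = "P", disease = "D")
    W <- lapply(w, function(x) matrix(x, 1, 1))
    for (i in 1:4) dimnames(W[[i]]) <- list(layers[[i]], layers[[i + 1]])
    M <- lapply(W, function(x) array(1, dim = c(1, 1), dimnames = dimnames(x)))
    new("SlemModel", layers = layers, weights = W, masks = M,
        activations = c("tanh", "tanh", "tanh", "sigmoid"), seed = 1L,
        trainState = list(optimizer = "adam", epochsTrained = 0L))
}

# Independent OLS oracle: explicit normal-equation solve for the slope of x
# and its two-sided t-test p-value in the model y ~ 1 + x + covariates.
olsOracle <- function(x, y, C = NULL) {
    X <- cbind(1, x, C)
    XtX <- t(X) %*% X
    beta <- solve(XtX, t(X) %*% y)
    res <- y - X %*% beta
    df <- length(y) - ncol(X)
    se <- sqrt((sum(res^2) / df) * solve(XtX)[2, 2])
    tval <- beta[2] / se
    list(slope = beta[2], p = 2 * pt(abs(tval), df, lower.tail = FALSE))
}

# Brute-force Kendall tau-b via O(n^2) pair enumeration with tie correction.
kendallOracle <- function(x, y) {
    n <- length(x)
    conc <- disc <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
        if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
    n0 <- n * (n - 1) / 2
    tx <- sum(sapply(table(x), function(t) t * (t - 1) / 2))
    ty <- sum(sapply(table(y), function(t) t * (t - 1) / 2))
    (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Exhaustive hypergeometric upper tail: enumerate all C(N, n) carrier subsets
# of a population with K patients and count those with >= k patients.
hyperOracle <- function(N, K, n, k) {
    subsets <- combn(N, n)
    hits <- colSums(subsets <= K)  # patients are individuals 1..K
    mean(hits >= k)
}

# Forward-pass oracle written independently of the package internals.
forwardOracle <- function(model, X) {
    w <- mapply(function(a, b) a * b, slem::edgeWeights(model),
                slem::edgeMasks(model), SIMPLIFY = FALSE)
    a <- X
    for (i in 1:3) a <- tanh(a %*% w[[i]])
    1 / (1 + exp(-(a %*% w[[4]])))
}

# Small end-to-end dataset with an exactly penetrant planted combination:
# carriers of the combo are always cases, everyone else is a case with
# probability baseRate.
penetrantData <- function(n = 2000, baseRate = 0.3, seed = 1) {
    withr::with_seed(seed, {
        G <- cbind(A = rbinom(n, 2, 0.4), B = rbinom(n, 2, 0.4),
                   C = rbinom(n, 2, 0.4))
        rownames(G) <- sprintf("S%04d", seq_len(n))
        combo <- c(A = 1L, B = 0L)
        carrier <- G[, "A"] == 1 & G[, "B"] == 0
        y <- ifelse(carrier, 1L, rbinom(n, 1, baseRate))
        list(data = new("EndToEndDataset", genotypes = G,
                        labels = as.integer(y)),
             combo = combo, carrier = carrier)
    })
}

# Compact synthetic config for fast pipeline-level tests.
smallConfig <- function(seed = 1, ...) {
    synthConfig(nSamplesMultilevel = 200, nSamplesE2E = 800, nSnps = 25,
                nIsoforms = 12, nMarkers = 6, nPhenotypes = 4, seed = seed, ...)
}
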