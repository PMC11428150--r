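test_that("all-zero genotypes give zero activations and output one half", {
    m <- randomModel(seed = 2)
    X <- matrix(0, 3, 6, dimnames = list(NULL, layerNodes(m)$snp))
    fw <- slemForward(m, X)
    expect_true(all(fw$h1 == 0) && all(fw$h2 == 0) && all(fw$h3 == 0))
    expect_true(all(fw$yhat == 0.5))
})

test_that("a single-path chain composes activations as expected", {
    m <- chainModel(c(2, 0.5, -1, 3))
    X <- matrix(1, 1, 1, dimnames = list(NULL, "A"))
    fw <- slemForward(m, X)
    want <- 1 / (1 + exp(-3 * tanh(-tanh(tanh(2) * 0.5))))
    expect_equal(as.numeric(fw$yhat), want, tolerance = 1e-12)
})

test_that("perturbing a masked weight never changes the output", {
    m <- randomModel(sizes = c(5, 4, 3, 2, 1), density = 0.5, seed = 3)
    X <- withr::with_seed(4, matrix(rbinom(20 * 5, 2, 0.3), 20, 5,
                                    dimnames = list(NULL, layerNodes(m)$snp)))
    base <- slemForward(m, X)$yhat
    mask1 <- edgeMasks(m)[[2]]
    off <- which(mask1 == 0)
    expect_gt(length(off), 0)
    m2 <- m
    m2@weights[[2]][off[1]] <- 99        # dead edge; mask zeroes it in forward
    expect_equal(slemForward(m2, X)$yhat, base)
})

test_that("forward pass matches an independent matrix-chain oracle", {
    for (s in 1:10) {
        m <- randomModel(sizes = c(7, 5, 4, 3, 1), density = 0.6, seed = s)
        X <- withr::with_seed(100 + s,
            matrix(rbinom(15 * 7, 2, 0.4), 15, 7,
                   dimnames = list(NULL, layerNodes(m)$snp)))
        expect_equal(as.numeric(slemForward(m, X)$yhat),
                     as.numeric(forwardOracle(m, X)), tolerance = 1e-6)
    }
})

test_that("schema mismatches name the missing SNPs", {
    m <- randomModel(seed = 5)
    X <- matrix(0, 2, 3, dimnames = list(NULL, c("snp001", "snp002", "snp003")))
    expect_error(slemForward(m, X), "snp004")
})

trainingFixture <- function(seed = 6, n = 300) {
    m <- randomModel(sizes = c(6, 4, 3, 2, 1), density = 0.6, seed = seed)
    # plant the label signal on a SNP that actually has an unmasked path
    sig <- topSnps(impactScoresMatrix(m), 1)
    withr::with_seed(seed + 1, {
        X <- matrix(rbinom(n * 6, 2, 0.4), n, 6,
                    dimnames = list(NULL, layerNodes(m)$snp))
        y <- as.integer(runif(n) < plogis(1.5 * (X[, sig] - 1)))
    })
    list(model = m, data = new("EndToEndDataset", genotypes = X, labels = y))
}

test_that("training respects masks, reduces loss and is seed-deterministic", {
    fx <- trainingFixture()
    cfg <- trainConfig(epochs = 40, batchSize = 64, seed = 11)
    fit <- trainSlem(fx$model, fx$data, cfg)
    for (l in 1:4)
        expect_true(all(fit@weights[[l]][edgeMasks(fit)[[l]] == 0] == 0))
    expect_lt(fit@trainState$finalLoss, modelLoss(fx$model, fx$data))
    fit2 <- trainSlem(fx$model, fx$data, cfg)
    expect_identical(fit@weights, fit2@weights)
    expect_false(identical(
        fit@weights,
        trainSlem(fx$model, fx$data, trainConfig(epochs = 40, batchSize = 64,
                                                 seed = 12))@weights))
})

test_that("a zero learning rate leaves the weights untouched", {
    fx <- trainingFixture(seed = 8)
    fit <- trainSlem(fx$model, fx$data,
                     trainConfig(learningRate = 0, epochs = 3,
                                 batchSize = 64, seed = 1))
    expect_identical(fit@weights, fx$model@weights)
})

test_that("single-class data abort training", {
    fx <- trainingFixture(seed = 9)
    bad <- new("EndToEndDataset", genotypes = genotypes(fx$data),
               labels = rep(0L, nrow(genotypes(fx$data))))
    expect_error(trainSlem(fx$model, bad, trainConfig(epochs = 1)),
                 "single class")
})

test_that("AUROC equals pairwise concordance with ties at one half", {
    expect_equal(aurocScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
    expect_equal(aurocScore(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
    expect_equal(aurocScore(c(0.5, 0.5), c(1, 0)), 0.5)
    s <- withr::with_seed(10, rnorm(50)); y <- withr::with_seed(11, rbinom(50, 1, 0.5))
    expect_equal(aurocScore(s, y) + aurocScore(-s, y), 1)
    expect_error(aurocScore(s, rep(1, 50)), "both classes")
})

test_that("cross-validation is stratified, reproducible and validates folds", {
    fx <- trainingFixture(seed = 12, n = 200)
    cfg <- trainConfig(epochs = 40, batchSize = 64, folds = 4, seed = 21)
    cv1 <- crossValidate(fx$model, fx$data, cfg)
    cv2 <- crossValidate(fx$model, fx$data, cfg)
    expect_equal(cv1$perFold, cv2$perFold)
    expect_equal(nrow(cv1$perFold), 4)
    expect_true(cv1$mean > 0.5)   # planted signal is recoverable
    expect_error(crossValidate(fx$model, fx$data,
                               trainConfig(folds = 500)), "folds")
})

test_that("the fully connected comparator has the closed-form edge count", {
    fc <- fullyConnectedBaseline(c(138, 67, 42, 19, 1), seed = 1)
    expect_equal(edgeCount(fc), 12877)
    expect_equal(edgeCount(fullyConnectedBaseline(c(1, 1, 1, 1, 1))), 4)
    for (s in 1:5) {
        sizes <- withr::with_seed(s, sample(2:9, 4))
        fc2 <- fullyConnectedBaseline(c(sizes, 1), seed = s)
        # count oracle: brute-force mask sum
        expect_equal(edgeCount(fc2),
                     sum(vapply(edgeMasks(fc2), sum, numeric(1))))
        expect_equal(edgeCount(fc2),
                     sum(sizes * c(sizes[-1], 1)))
    }
    # reusing a sparse model's layers keeps its labels
    sp <- randomModel(seed = 30)
    fc3 <- fullyConnectedBaseline(sp)
    expect_identical(layerNodes(fc3), layerNodes(sp))
    expect_true(all(edgeMasks(fc3)[[1]] == 1))
})
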