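makeTable <- function(df, pair = "snp->isoform") {
    df$statistic <- if (is.null(df$statistic)) rep(1, nrow(df)) else df$statistic
    df$sign <- if (is.null(df$sign)) rep(1, nrow(df)) else df$sign
    new("AssociationTable",
        records = data.frame(source = df$source, target = df$target,
                             statistic = df$statistic, sign = df$sign,
                             p = df$p, q = df$q, stringsAsFactors = FALSE),
        layerPair = pair)
}

test_that("node selection filters on min q with stable order", {
    tab <- makeTable(data.frame(source = c("s1", "s1", "s1"),
                                target = c("A", "B", "C"),
                                p = c(0.01, 0.02, 0.1),
                                q = c(0.04, 0.09, 0.2)))
    expect_equal(selectNodes(tab, 0.05), "A")
    expect_equal(selectNodes(tab, 0.1), c("A", "B"))
    allOne <- makeTable(data.frame(source = "s1", target = c("A", "B"),
                                   p = c(1, 1), q = c(1, 1)))
    expect_length(selectNodes(allOne, 0.5), 0)
    empty <- makeTable(data.frame(source = character(0), target = character(0),
                                  p = numeric(0), q = numeric(0)))
    expect_warning(res <- selectNodes(empty, 0.1), "empty")
    expect_length(res, 0)
    expect_error(selectNodes(tab, 0), "0, 1")
})

test_that("Xavier sigma follows the closed form and is symmetric", {
    expect_equal(xavierSigma(1, 1), 1)
    expect_equal(xavierSigma(138, 67), sqrt(2 / 205))
    expect_equal(xavierSigma(138, 67), 0.09877, tolerance = 1e-4)
    expect_equal(xavierSigma(7, 3), xavierSigma(3, 7))
    expect_error(xavierSigma(0, 5), ">= 1")
})

test_that("p-value to weight transform matches the normal quantile", {
    expect_equal(pvalueToWeight(1, 1, 0.5), 0)
    expect_equal(pvalueToWeight(0.05, 1, 0.1), 0.1 * qnorm(0.975))
    expect_equal(pvalueToWeight(0.05, 1, 0.1), 0.19600, tolerance = 1e-4)
    expect_equal(pvalueToWeight(0.05, -1, 0.1), -0.1 * qnorm(0.975))
    expect_error(pvalueToWeight(0, 1, 0.1), "0, 1")
    # strictly decreasing in p
    p <- seq(0.01, 1, by = 0.01)
    expect_true(all(diff(pvalueToWeight(p, 1, 0.3)) < 0))
})

test_that("uniform p-values give half-normal weight magnitudes", {
    sigma <- 0.2
    w <- withr::with_seed(4, pvalueToWeight(runif(10000), 1, sigma))
    ks <- stats::ks.test(abs(w) / sigma, function(q) 2 * pnorm(q) - 1)
    expect_gt(ks$p.value, 0.01)
})

test_that("weight -> p -> weight round-trips through a two-sided z-test", {
    sigma <- 0.15
    w <- withr::with_seed(5, rnorm(200, 0, sigma))
    p <- 2 * pnorm(abs(w) / sigma, lower.tail = FALSE)
    back <- pvalueToWeight(p, ifelse(w >= 0, 1, -1), sigma)
    expect_equal(back, w, tolerance = 1e-9)
})

test_that("top-fraction masking keeps the ceiling count with tie rules", {
    w <- matrix(0, 5, 6)
    w[1:20] <- seq(0.1, 2, by = 0.1)
    m <- maskTopFraction(w, 0.35)
    expect_equal(sum(m), 7)                    # ceiling(0.35 * 20)
    w10 <- matrix(c(1:10, rep(0, 2)), 3, 4)
    expect_equal(sum(maskTopFraction(w10, 0.35)), 4)  # ceiling(3.5)
    # kept set equals a brute-force sort of |weights|
    W <- withr::with_seed(6, matrix(rnorm(40), 8, 5))
    m2 <- maskTopFraction(W, 0.4)
    keep <- ceiling(0.4 * sum(W != 0))
    thr <- sort(abs(W[W != 0]), decreasing = TRUE)[keep]
    expect_setequal(which(m2 == 1), which(abs(W) >= thr & W != 0))
    expect_warning(maskTopFraction(matrix(0, 2, 2), 0.5), "all-zero")
})

test_that("masking is idempotent and equivariant to storage order", {
    W <- withr::with_seed(7, matrix(rnorm(48), 6, 8))
    m <- maskTopFraction(W, 0.3)
    expect_equal(maskTopFraction(W * m, 1), m)  # idempotent on the kept set
    pr <- withr::with_seed(8, sample(6)); pc <- withr::with_seed(9, sample(8))
    expect_equal(maskTopFraction(W[pr, pc], 0.3), m[pr, pc])
    # ties broken by (row, column) lexicographic order: (1,1) then (1,2)
    Wt <- matrix(1, 2, 2)
    expect_equal(maskTopFraction(Wt, 0.5), matrix(c(1, 0, 1, 0), 2, 2))
})

buildSmallTables <- function(seed = 10) {
    cfg <- smallConfig(seed = seed)
    ml <- genMultilevel(cfg)
    list(
        tabs = list(snpIsoform = batchAssoc(ml, "snp->isoform"),
                    snpMarker = batchAssoc(ml, "snp->marker"),
                    snpPhenotype = batchAssoc(ml, "snp->phenotype"),
                    isoformMarker = batchAssoc(ml, "isoform->marker"),
                    markerPhenotype = batchAssoc(ml, "marker->phenotype")),
        ml = ml)
}

test_that("model assembly selects nodes, masks per layer and seeds output", {
    st <- buildSmallTables()
    m1 <- buildModel(st$tabs, seed = 1)
    expect_s4_class(m1, "SlemModel")
    expect_true(validObject(m1))
    # edge count identity: sum of per-layer ceilings plus output edges
    counts <- vapply(1:3, function(i) {
        W <- edgeWeights(m1)[[i]]
        sum(edgeMasks(m1)[[i]])
    }, numeric(1))
    nz <- vapply(1:3, function(i) {
        tab <- st$tabs[[c("snpIsoform", "isoformMarker", "markerPhenotype")[i]]]
        sel <- layerNodes(m1)[c(i, i + 1)]
        rec <- records(tab)
        rec <- rec[rec$source %in% sel[[1]] & rec$target %in% sel[[2]], ]
        sum(rec$p < 0.05)
    }, numeric(1))
    expect_equal(counts, ceiling(0.35 * nz))
    expect_equal(edgeCount(m1), sum(counts) + length(layerNodes(m1)$phenotype))
    # disease-layer weights differ across seeds, everything else identical
    m2 <- buildModel(st$tabs, seed = 2)
    expect_identical(edgeWeights(m1)[1:3], edgeWeights(m2)[1:3])
    expect_identical(edgeMasks(m1), edgeMasks(m2))
    expect_false(identical(edgeWeights(m1)[[4]], edgeWeights(m2)[[4]]))
})

test_that("an empty intermediate layer aborts with the layer name", {
    st <- buildSmallTables()
    tabs <- st$tabs
    rec <- records(tabs$snpIsoform); rec$q <- rep(1, nrow(rec))
    tabs$snpIsoform <- new("AssociationTable", records = rec,
                           layerPair = "snp->isoform")
    expect_error(buildModel(tabs), "isoform layer")
})

test_that("planted edges survive masking above the background rate", {
    cfg <- synthConfig(nSamplesMultilevel = 500, nSnps = 40, nIsoforms = 20,
                       nMarkers = 10, nPhenotypes = 6, nSamplesE2E = 100,
                       effectSize = 1.5, seed = 23)
    ml <- genMultilevel(cfg)
    tabs <- list(snpIsoform = batchAssoc(ml, "snp->isoform"),
                 snpMarker = batchAssoc(ml, "snp->marker"),
                 snpPhenotype = batchAssoc(ml, "snp->phenotype"),
                 isoformMarker = batchAssoc(ml, "isoform->marker"),
                 markerPhenotype = batchAssoc(ml, "marker->phenotype"))
    m <- buildModel(tabs, seed = 23)
    truth <- plantedTruth(ml)$effectIsoform
    M1 <- edgeMasks(m)[[1]]
    iso <- layerNodes(m)$isoform
    plantedKept <- plantedTotal <- bgKept <- bgTotal <- 0
    for (s in rownames(truth)) for (t in intersect(colnames(truth), iso)) {
        kept <- M1[s, t] == 1
        if (truth[s, t] != 0) {
            plantedTotal <- plantedTotal + 1
            plantedKept <- plantedKept + kept
        } else {
            bgTotal <- bgTotal + 1
            bgKept <- bgKept + kept
        }
    }
    bgRate <- bgKept / bgTotal
    bt <- stats::binom.test(plantedKept, plantedTotal, p = max(bgRate, 1e-6),
                            alternative = "greater")
    expect_lt(bt$p.value, 0.01)
})

test_that("model JSON serialization round-trips losslessly", {
    st <- buildSmallTables(seed = 12)
    m <- buildModel(st$tabs, seed = 3)
    f <- tempfile(fileext = ".json")
    writeSlemModel(m, f)
    back <- readSlemModel(f)
    expect_equal(back@weights, m@weights, tolerance = 0)
    expect_equal(back@masks, m@masks, tolerance = 0)
    expect_identical(back@layers, m@layers)
    expect_identical(back@activations, m@activations)
    expect_identical(back@seed, m@seed)
})
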