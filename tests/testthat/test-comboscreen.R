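test_that("combination enumeration covers the state space exactly once", {
    expect_length(enumerateCombinations("A", 1, 1), 3)
    all5 <- enumerateCombinations(LETTERS[1:5], 1, 5)
    expect_length(all5, 1023)                         # 4^5 - 1
    keys <- vapply(all5, formatCombination, "")
    expect_equal(anyDuplicated(keys), 0L)
    # brute-force count oracle: sum over k of C(5,k) * 3^k
    expect_equal(length(all5), sum(choose(5, 1:5) * 3^(1:5)))
    two <- enumerateCombinations(c("A", "B"), 2, 2)
    expect_length(two, 9)
    expect_error(enumerateCombinations(character(0)), "non-empty")
    expect_error(enumerateCombinations("A", 2, 1), "minOrder")
})

test_that("combination strings round-trip through format and parse", {
    cmb <- c(A = 0L, B = 1L, C = 2L)
    expect_equal(formatCombination(cmb), "A0B1C2")
    expect_identical(parseCombination("A0B1C2"), cmb)
    long <- c(snp001 = 2L, snp007 = 0L)
    expect_identical(parseCombination(formatCombination(long)), long)
})

test_that("carrier matching is exact on assigned SNPs and skips missing", {
    G <- rbind(c(2, 1, 0, 0, 1),
               c(2, 0, 1, 0, 2),
               c(1, 1, 1, 0, 0),
               c(2, 2, 2, 0, 1),
               c(0, 1, 0, 2, 1))
    colnames(G) <- LETTERS[1:5]
    idx <- carrierIndices(G, c(A = 2L, D = 0L))
    expect_equal(as.integer(idx), c(1L, 2L, 4L))
    idx2 <- carrierIndices(G, c(A = 2L, B = 1L, D = 0L))
    expect_equal(as.integer(idx2), 1L)
    Gna <- G; Gna[1, "A"] <- NA
    idx3 <- carrierIndices(Gna, c(A = 2L, D = 0L))
    expect_equal(as.integer(idx3), c(2L, 4L))
    expect_equal(attr(idx3, "nExcluded"), 1L)
    expect_error(carrierIndices(G, c(Z = 1L)), "absent")
})

test_that("carrier counts equal a brute-force row scan on random data", {
    withr::with_seed(51, {
        G <- matrix(rbinom(200 * 4, 2, 0.4), 200, 4,
                    dimnames = list(NULL, c("A", "B", "C", "D")))
    })
    for (cmb in list(c(A = 1L), c(B = 0L, D = 2L), c(A = 2L, C = 1L, D = 0L))) {
        scan <- which(vapply(seq_len(200), function(i)
            all(G[i, names(cmb)] == cmb), logical(1)))
        expect_equal(as.integer(carrierIndices(G, cmb)), scan)
    }
})

test_that("carrier counts are anti-monotone in added constraints", {
    withr::with_seed(52, {
        G <- matrix(rbinom(300 * 5, 2, 0.3), 300, 5,
                    dimnames = list(NULL, LETTERS[1:5]))
    })
    for (s in 1:20) {
        withr::with_seed(60 + s, {
            k <- sample(1:4, 1)
            base <- sort(sample(LETTERS[1:5], k))
            states <- sample(0:2, k, replace = TRUE)
            extra <- sample(setdiff(LETTERS[1:5], base), 1)
        })
        cmb <- stats::setNames(as.integer(states), base)
        bigger <- c(cmb, stats::setNames(1L, extra))
        expect_lte(length(carrierIndices(G, bigger)),
                   length(carrierIndices(G, cmb)))
    }
})

test_that("precision reproduces the published worked examples", {
    expect_equal(round(precisionScore(10, 13), 3), 0.769)
    expect_equal(precisionScore(6, 6), 1)
    expect_equal(round(precisionScore(761, 1407), 3), 0.541)
    expect_equal(round(precisionScore(19, 28), 3), 0.679)
    # 30/104 = 0.28846, printed as 0.289 (rounded up); agree to 1e-3
    expect_equal(precisionScore(30, 104), 0.289, tolerance = 2e-3)
    expect_equal(precisionScore(0, 5), 0)
    flagged <- precisionScore(0, 0)
    expect_true(is.na(flagged))
    expect_true(attr(flagged, "noCarriers"))
    expect_error(precisionScore(5, 3), "positives")
})

test_that("precision of a union of disjoint carrier sets is a weighted mean", {
    for (s in 1:10) {
        withr::with_seed(70 + s, {
            tp1 <- sample(0:20, 1); n1 <- tp1 + sample(0:20, 1)
            tp2 <- sample(0:20, 1); n2 <- tp2 + sample(0:20, 1)
        })
        if (n1 == 0 || n2 == 0) next
        pu <- precisionScore(tp1 + tp2, n1 + n2)
        lo <- min(tp1 / n1, tp2 / n2); hi <- max(tp1 / n1, tp2 / n2)
        expect_gte(pu, lo - 1e-12)
        expect_lte(pu, hi + 1e-12)
    }
})

test_that("hypergeometric upper tail is exact", {
    expect_equal(hypergeomUpper(10, 5, 4, 0), 1)
    expect_equal(hypergeomUpper(10, 5, 4, 4), 5 / 210)
    expect_error(hypergeomUpper(10, 12, 4, 2), "inconsistent")
    for (N in c(8, 10, 12)) {
        K <- N %/% 2
        for (n in c(2, 4)) for (k in 0:min(K, n)) {
            expect_equal(hypergeomUpper(N, K, n, k), hyperOracle(N, K, n, k),
                         tolerance = 1e-12)
        }
    }
})

test_that("a fully penetrant planted combination passes the screen", {
    fx <- penetrantData(n = 2000, baseRate = 0.3, seed = 5)
    res <- screenCombinations(fx$data, c("A", "B"), 0.6, 0.05)
    expect_equal(nrow(res), 15)                       # 2*3 + 9
    row <- res[res$combination == "A1B0", ]
    expect_equal(row$precision, 1)
    expect_true(row$passed)
    expect_equal(row$positives, sum(fx$carrier))
    # thresholds are strict: a tie fails
    expect_false(isTRUE(res$precision[1] == 0.6 && res$passed[1]))
    bad <- new("EndToEndDataset", genotypes = genotypes(fx$data),
               labels = rep(0L, 2000))
    expect_error(screenCombinations(bad, c("A", "B")), "no patients")
})

test_that("single-SNP control screen covers every genotype state", {
    fx <- penetrantData(n = 500, seed = 6)
    res <- screenSingleSnps(fx$data)
    expect_equal(nrow(res), 3 * 3)
    expect_true(all(res$order == 1))
})

test_that("holdout evaluation pairs precisions and flags degenerate rows", {
    fx <- penetrantData(n = 1000, seed = 7)
    res <- screenCombinations(fx$data, c("A", "B"), 0.6, 0.05)
    hold <- evaluateHoldout(res, fx$data)       # identical data
    expect_equal(hold$holdoutPrecision, hold$trainPrecision)
    # a 2-sample holdout where the combo matches 1 patient of 1 carrier
    G2 <- rbind(c(1, 0, 2), c(0, 0, 1))
    colnames(G2) <- c("A", "B", "C")
    d2 <- new("EndToEndDataset", genotypes = G2, labels = c(1L, 0L))
    h2 <- evaluateHoldout(res, d2)
    row <- h2[h2$combination == "A1B0", ]
    expect_equal(row$holdoutPrecision, 1)
    expect_equal(row$holdoutPositives, 1)
    # combination with no holdout carriers is flagged, not scored
    G3 <- rbind(c(2, 2, 2), c(2, 2, 2))
    colnames(G3) <- c("A", "B", "C")
    d3 <- new("EndToEndDataset", genotypes = G3, labels = c(1L, 0L))
    h3 <- evaluateHoldout(res, d3)
    expect_true(all(h3$noCarriers))
    expect_true(all(is.na(h3$holdoutPrecision)))
})

test_that("holdout marks de-enriched combinations below the base rate", {
    G <- cbind(A = c(1L, 1L, 1L, 0L, 0L, 0L))
    rownames(G) <- sprintf("S%d", 1:6)
    train <- new("EndToEndDataset", genotypes = G,
                 labels = c(1L, 1L, 1L, 0L, 0L, 0L))
    res <- screenCombinations(train, "A", 0.6, 0.5)
    # holdout where carriers of A=1 are mostly controls
    hold <- new("EndToEndDataset", genotypes = G,
                labels = c(0L, 0L, 1L, 1L, 1L, 0L))
    h <- evaluateHoldout(res, hold, onlyPassed = FALSE)
    row <- h[h$combination == "A1", ]
    expect_lt(row$holdoutPrecision, 0.5)
    expect_true(row$deEnriched)
})
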