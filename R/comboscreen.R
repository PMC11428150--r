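# Genotype-combination screening: enumerate joint genotype-state assignments
# of candidate SNPs, score each by precision and hypergeometric enrichment on
# a labelled cohort, and re-evaluate passers on an independent holdout.

#' Format / parse genotype combinations
#'
#' A combination assigns a state in \{0, 1, 2\} (homozygous reference /
#' heterozygous / homozygous alternative) to a subset of SNPs. Single-letter
#' SNP aliases render compactly ("A0B1C2"); longer labels are joined with
#' commas ("snp001=0,snp007=2").
#'
#' @param combo named integer vector (names = SNP labels, values = states).
#' @return `formatCombination`: a single string; `parseCombination`: the named
#'   integer vector.
#' @export
formatCombination <- function(combo) {
    lab <- names(combo)
    if (all(nchar(lab) == 1L))
        paste0(lab, combo, collapse = "")
    else
        paste0(lab, "=", combo, collapse = ",")
}

#' @rdname formatCombination
#' @param x a string produced by `formatCombination`.
#' @export
parseCombination <- function(x) {
    if (grepl("=", x, fixed = TRUE)) {
        parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1L]], "=", fixed = TRUE)
        stats::setNames(as.integer(vapply(parts, `[`, "", 2L)),
                        vapply(parts, `[`, "", 1L))
    } else {
        ch <- strsplit(x, "")[[1L]]
        stopIfNot(length(ch) %% 2L == 0L, "malformed combination string")
        lab <- ch[seq(1L, length(ch), 2L)]
        stats::setNames(as.integer(ch[seq(2L, length(ch), 2L)]), lab)
    }
}

#' Enumerate all genotype-state combinations of candidate SNPs
#'
#' All subsets of the SNP list with sizes in \[minOrder, maxOrder\], crossed
#' with all 3^size state assignments, in deterministic order: subset size
#' ascending, subsets in lexicographic (index) order, then states as an
#' odometer with the last SNP fastest. For 5 SNPs and orders 1-5 this yields
#' sum C(5,k) 3^k = 4^5 - 1 = 1023 combinations.
#'
#' @param snps candidate SNP labels.
#' @param minOrder,maxOrder subset size bounds.
#' @return list of named integer vectors.
#' @export
enumerateCombinations <- function(snps, minOrder = 1L,
                                  maxOrder = length(snps)) {
    stopIfNot(length(snps) >= 1L, "snps must be non-empty")
    stopIfNot(minOrder >= 1L && minOrder <= maxOrder &&
              maxOrder <= length(snps),
              "need 1 <= minOrder <= maxOrder <= length(snps)")
    out <- list()
    for (k in seq(minOrder, maxOrder)) {
        subsets <- utils::combn(seq_along(snps), k, simplify = FALSE)
        states <- as.matrix(expand.grid(rep(list(0:2), k))[, k:1, drop = FALSE])
        # expand.grid varies the first column fastest; reversing the columns
        # gives an odometer with the last SNP fastest
        states <- states[do.call(order, as.data.frame(states)), , drop = FALSE]
        for (sub in subsets)
            for (r in seq_len(nrow(states)))
                out[[length(out) + 1L]] <-
                    stats::setNames(as.integer(states[r, ]), snps[sub])
    }
    out
}

#' Samples carrying a genotype combination
#'
#' A sample carries the combination when its genotype equals the assigned
#' state at every assigned SNP; unassigned SNPs are unconstrained. Samples
#' with a missing genotype at an assigned SNP are excluded (carrier status
#' undefined); their count is returned as the `nExcluded` attribute.
#'
#' @param genotypes samples x SNPs 0/1/2 matrix.
#' @param combo named integer vector (see [parseCombination()]).
#' @return integer vector of carrier row indices.
#' @export
carrierIndices <- function(genotypes, combo) {
    missingSnps <- setdiff(names(combo), colnames(genotypes))
    stopIfNot(length(missingSnps) == 0L,
              paste("combination SNP(s) absent from genotypes:",
                    paste(missingSnps, collapse = ", ")))
    sub <- genotypes[, names(combo), drop = FALSE]
    hasNA <- rowSums(is.na(sub)) > 0L
    match <- !hasNA & rowSums(sub == rep(combo, each = nrow(sub))) == length(combo)
    out <- which(match)
    attr(out, "nExcluded") <- sum(hasNA)
    out
}

#' Precision of a marker
#'
#' Patients carrying the marker divided by all carriers of the marker.
#'
#' @param truePositives carriers who are patients.
#' @param positives all carriers.
#' @return `truePositives / positives`; `NA` with a "no carriers" attribute
#'   when `positives` is 0 (flagged, not an error).
#' @export
precisionScore <- function(truePositives, positives) {
    stopIfNot(positives >= truePositives && truePositives >= 0,
              "need positives >= truePositives >= 0")
    if (positives == 0) {
        out <- NA_real_
        attr(out, "noCarriers") <- TRUE
        return(out)
    }
    truePositives / positives
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at least
#' k patients among n carriers sampled from a population of N samples
#' containing K patients. Exact.
#'
#' @param N population size.
#' @param K patients in the population.
#' @param n carriers drawn.
#' @param k patients among the carriers.
#' @return upper-tail probability.
#' @export
hypergeomUpper <- function(N, K, n, k) {
    stopIfNot(K <= N && n <= N && k <= min(K, n) && k >= max(0, n - (N - K)),
              "inconsistent hypergeometric counts")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Screen genotype combinations by precision and enrichment
#'
#' Enumerates all combinations of the candidate SNPs
#' ([enumerateCombinations()]), counts carriers and carrier patients, and
#' computes precision and the hypergeometric upper-tail p-value with
#' N = all samples and K = all patients. A combination passes when
#' precision > `precisionThreshold` AND p < `pThreshold` (both strict).
#' The full table is returned with passers flagged.
#'
#' @param data an [EndToEndDataset-class] (must contain patients).
#' @param snps candidate SNP labels (typically [topSnps()] output).
#' @param precisionThreshold precision cutoff (default 0.6).
#' @param pThreshold p-value cutoff (default 0.05).
#' @param minOrder,maxOrder combination size bounds.
#' @param aliases optional single-letter aliases for the SNPs (names = SNP
#'   labels) used for compact combination strings.
#' @return data.frame: combination, order, positives, truePositives,
#'   precision, p, passed.
#' @export
screenCombinations <- function(data, snps, precisionThreshold = 0.6,
                               pThreshold = 0.05, minOrder = 1L,
                               maxOrder = length(snps), aliases = NULL) {
    stopIfNot(precisionThreshold > 0 && precisionThreshold < 1 &&
              pThreshold > 0 && pThreshold < 1, "thresholds must lie in (0, 1)")
    y <- data@labels
    N <- length(y); K <- sum(y == 1L)
    if (K == 0L)
        stop("screening error: dataset contains no patients", call. = FALSE)
    combos <- enumerateCombinations(snps, minOrder, maxOrder)
    rows <- lapply(combos, function(cmb) {
        car <- carrierIndices(genotypes(data), cmb)
        pos <- length(car)
        tp <- sum(y[car] == 1L)
        prec <- precisionScore(tp, pos)
        p <- if (pos == 0L) NA_real_ else hypergeomUpper(N, K, pos, tp)
        disp <- cmb
        if (!is.null(aliases)) names(disp) <- aliases[names(cmb)]
        data.frame(combination = formatCombination(disp), order = length(cmb),
                   positives = pos, truePositives = tp,
                   precision = as.numeric(prec), p = p,
                   passed = !is.na(prec) && prec > precisionThreshold &&
                       !is.na(p) && p < pThreshold,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "population") <- c(N = N, K = K)
    attr(out, "snps") <- snps
    attr(out, "aliases") <- aliases
    out
}

#' Screen every single-SNP genotype-state marker (control comparison)
#'
#' Order-1 screening over all SNP columns of the dataset with the same
#' statistics as [screenCombinations()]; the single-SNP baseline against
#' which combination markers are compared.
#'
#' @inheritParams screenCombinations
#' @return data.frame as in [screenCombinations()].
#' @export
screenSingleSnps <- function(data, precisionThreshold = 0.6,
                             pThreshold = 0.05) {
    screenCombinations(data, colnames(genotypes(data)),
                       precisionThreshold, pThreshold,
                       minOrder = 1L, maxOrder = 1L)
}

#' Re-evaluate screened combinations on an independent holdout
#'
#' For each record (by default only the passers), recomputes precision and
#' hypergeometric p on the holdout cohort and pairs them with the training
#' values (the data behind a train-vs-holdout precision scatter). A
#' combination with no holdout carriers is flagged `noCarriers` with
#' precision omitted; one whose holdout precision falls below the holdout
#' base rate is labelled `deEnriched`.
#'
#' @param records output of [screenCombinations()].
#' @param data holdout [EndToEndDataset-class] sharing the SNP columns.
#' @param onlyPassed evaluate only the passing combinations (default TRUE).
#' @return data.frame: combination, trainPrecision, holdoutPrecision,
#'   holdoutP, holdoutPositives, holdoutTruePositives, noCarriers, deEnriched.
#' @export
evaluateHoldout <- function(records, data, onlyPassed = TRUE) {
    aliases <- attr(records, "aliases")
    if (onlyPassed) records <- records[records$passed, , drop = FALSE]
    y <- data@labels
    N <- length(y); K <- sum(y == 1L)
    baseRate <- K / N
    rows <- lapply(seq_len(nrow(records)), function(i) {
        cmb <- parseCombination(records$combination[i])
        if (!is.null(aliases))
            names(cmb) <- names(aliases)[match(names(cmb), aliases)]
        car <- carrierIndices(genotypes(data), cmb)
        pos <- length(car)
        tp <- sum(y[car] == 1L)
        prec <- if (pos == 0L) NA_real_ else tp / pos
        p <- if (pos == 0L) NA_real_ else hypergeomUpper(N, K, pos, tp)
        data.frame(combination = records$combination[i],
                   trainPrecision = records$precision[i],
                   holdoutPrecision = prec, holdoutP = p,
                   holdoutPositives = pos, holdoutTruePositives = tp,
                   noCarriers = pos == 0L,
                   deEnriched = !is.na(prec) && prec < baseRate,
                   stringsAsFactors = FALSE)
    })
    out <- if (length(rows)) do.call(rbind, rows)
        else data.frame(combination = character(0), trainPrecision = numeric(0),
                        holdoutPrecision = numeric(0), holdoutP = numeric(0),
                        holdoutPositives = integer(0),
                        holdoutTruePositives = integer(0),
                        noCarriers = logical(0), deEnriched = logical(0))
    attr(out, "holdoutBaseRate") <- baseRate
    out
}

#' Write a screening table as TSV
#' @param records output of [screenCombinations()] or [evaluateHoldout()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeScreenTsv <- function(records, path) {
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
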