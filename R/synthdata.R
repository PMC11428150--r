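#' Build a synthetic-data configuration with planted multilevel structure
#'
#' Creates a [SynthConfig-class] describing a small, precise multilevel cohort
#' (genotypes, transcript isoforms, protein markers, cellular phenotypes,
#' covariates) and a large end-to-end genotype/diagnosis cohort sharing the
#' same planted generative chain. Defaults mirror a desk-scale version of the
#' study conditions: 57 multilevel samples, 138 risk SNPs, 67/42/19
#' intermediate features and 7300 end-to-end samples.
#'
#' Planted structure: `nPlantedSnps` SNPs carry per-allele effects of
#' `effectSize` noise-SD units on planted isoforms; the first planted SNP is
#' "dominant" (it feeds two isoforms). Planted isoforms feed a small set of
#' markers, markers feed two phenotypes, and those phenotypes load on the
#' disease liability. All planted coefficients share the sign `+` so paths do
#' not cancel. `effectSize = 0` gives a pure-null generator.
#'
#' @param nSamplesMultilevel,nSamplesE2E cohort sizes.
#' @param nSnps,nIsoforms,nMarkers,nPhenotypes layer widths.
#' @param maf minor-allele frequencies, recycled to `nSnps`; `NULL` draws them
#'   uniformly from \[0.05, 0.5\] under `seed`.
#' @param effectSize planted per-allele effect in noise-SD units (default 2).
#' @param nPlantedSnps number of causal SNPs (default 5).
#' @param noiseSd per-layer Gaussian noise SD (default 1).
#' @param latentSd scale of a shared sample-level latent factor loading on
#'   every isoform/marker/phenotype (default 0.5), emulating the pervasive
#'   co-expression / shared technical variation of real assay data; it is
#'   independent of genotype. Set 0 for mutually independent null features.
#' @param liabilityIntercept liability intercept; `NA` auto-calibrates to
#'   `targetPrevalence` when a dataset is generated.
#' @param targetPrevalence target case fraction for auto-calibration.
#' @param effectIsoform,effectMarker,effectPhenotype,effectDisease explicit
#'   planted effect matrices/vector, overriding the built-in planting.
#' @param seed integer seed; identical configs yield bit-identical datasets.
#' @return A validated [SynthConfig-class] object.
#' @examples
#' cfg <- synthConfig(nSamplesMultilevel = 40, nSnps = 20, nIsoforms = 10,
#'                    nMarkers = 6, nPhenotypes = 3, nSamplesE2E = 500, seed = 1)
#' ml <- genMultilevel(cfg)
#' dim(genotypes(ml))
#' @export
synthConfig <- function(nSamplesMultilevel = 57L, nSamplesE2E = 7300L,
                        nSnps = 138L, nIsoforms = 67L, nMarkers = 42L,
                        nPhenotypes = 19L, maf = NULL,
                        effectSize = 2, nPlantedSnps = 5L, noiseSd = 1,
                        latentSd = 0.5,
                        liabilityIntercept = NA_real_, targetPrevalence = 0.5,
                        effectIsoform = NULL, effectMarker = NULL,
                        effectPhenotype = NULL, effectDisease = NULL,
                        seed = 1L) {
    nSnps <- as.integer(nSnps); nIsoforms <- as.integer(nIsoforms)
    nMarkers <- as.integer(nMarkers); nPhenotypes <- as.integer(nPhenotypes)
    if (is.null(maf)) {
        # GWAS risk SNPs are common variants; draw allele frequencies
        # uniformly over [0.1, 0.5]
        maf <- withSeed(seed, stats::runif(nSnps, 0.1, 0.5))
    } else {
        maf <- rep_len(as.numeric(maf), nSnps)
    }
    planted <- plantedEffects(nSnps, nIsoforms, nMarkers, nPhenotypes,
                              effectSize, as.integer(nPlantedSnps))
    if (is.null(effectIsoform)) effectIsoform <- planted$E1
    if (is.null(effectMarker)) effectMarker <- planted$E2
    if (is.null(effectPhenotype)) effectPhenotype <- planted$E3
    if (is.null(effectDisease)) effectDisease <- planted$wD
    new("SynthConfig",
        nSamplesMultilevel = as.integer(nSamplesMultilevel),
        nSamplesE2E = as.integer(nSamplesE2E),
        nSnps = nSnps, nIsoforms = nIsoforms, nMarkers = nMarkers,
        nPhenotypes = nPhenotypes, maf = maf,
        effectIsoform = effectIsoform, effectMarker = effectMarker,
        effectPhenotype = effectPhenotype, effectDisease = effectDisease,
        noiseSd = as.numeric(noiseSd),
        latentSd = as.numeric(latentSd),
        liabilityIntercept = as.numeric(liabilityIntercept),
        targetPrevalence = as.numeric(targetPrevalence),
        seed = as.integer(seed))
}

# Fixed deterministic planting: SNP1 is dominant (feeds isoforms 1 and 2),
# SNPs 2..k feed isoforms 2..k+? one each; isoforms map pairwise onto markers,
# markers onto the first two phenotypes, which load 1 each on liability.
plantedEffects <- function(nSnps, nIsoforms, nMarkers, nPhenotypes,
                           effectSize, nPlanted) {
    E1 <- matrix(0, nSnps, nIsoforms,
                 dimnames = list(makeLabels("snp", nSnps), makeLabels("iso", nIsoforms)))
    E2 <- matrix(0, nIsoforms, nMarkers,
                 dimnames = list(makeLabels("iso", nIsoforms), makeLabels("mrk", nMarkers)))
    E3 <- matrix(0, nMarkers, nPhenotypes,
                 dimnames = list(makeLabels("mrk", nMarkers), makeLabels("phe", nPhenotypes)))
    wD <- stats::setNames(numeric(nPhenotypes), makeLabels("phe", nPhenotypes))
    if (effectSize != 0 && nPlanted > 0) {
        nPlanted <- min(nPlanted, nSnps)
        nIsoUsed <- min(nPlanted, nIsoforms)
        for (s in seq_len(nPlanted))
            E1[s, min(s, nIsoUsed)] <- effectSize
        if (nIsoforms >= 2L) E1[1L, 2L] <- effectSize  # dominant SNP, second path
        # dense planted blocks upstream of the liability: every planted
        # isoform feeds every planted marker and so on, emulating redundant
        # multilevel readouts of the same underlying processes (signal adds
        # coherently across readouts, per-feature noise does not)
        nMrkUsed <- min(max(1L, ceiling(nIsoUsed / 2)), nMarkers)
        E2[seq_len(nIsoUsed), seq_len(nMrkUsed)] <- effectSize
        nPheUsed <- min(4L, nPhenotypes)
        E3[seq_len(nMrkUsed), seq_len(nPheUsed)] <- effectSize
        wD[seq_len(nPheUsed)] <- 1
    }
    list(E1 = E1, E2 = E2, E3 = E3, wD = wD)
}

#' Generate an additive-coded genotype matrix
#'
#' Each genotype is drawn as Binomial(2, maf), i.e. Hardy-Weinberg
#' equilibrium, and coded 0 (homozygous reference), 1 (heterozygous),
#' 2 (homozygous alternative).
#'
#' @param nSamples number of samples (rows).
#' @param mafs minor-allele frequencies in (0, 0.5], one per SNP; names become
#'   the SNP labels (default `snp001`, ...).
#' @param seed integer seed.
#' @return integer matrix with sample rownames and SNP colnames.
#' @export
genGenotypes <- function(nSamples, mafs, seed = 1L) {
    stopIfNot(is.numeric(nSamples) && length(nSamples) == 1L && nSamples >= 1,
              "nSamples must be a positive count")
    stopIfNot(length(mafs) >= 1L && all(mafs > 0 & mafs <= 0.5),
              "mafs must lie in (0, 0.5]")
    n <- as.integer(nSamples); p <- length(mafs)
    lab <- names(mafs)
    if (is.null(lab)) lab <- makeLabels("snp", p)
    G <- withSeed(seed, {
        vapply(seq_len(p), function(j) stats::rbinom(n, 2L, mafs[j]),
               integer(n))
    })
    G <- matrix(as.integer(G), nrow = n, ncol = p,
                dimnames = list(sprintf("S%05d", seq_len(n)), lab))
    G
}

# Push genotypes through the planted chain. Each layer is a linear mix of the
# (standardised) previous layer plus N(0, noiseSd) noise and a shared
# sample-level latent factor (loadings of scale latentSd, random sign); the
# marker layer additionally applies tanh to the standardised isoform signal so
# that rank-based edge detection is exercised on a non-Gaussian dependency.
propagateLayers <- function(G, config, seed) {
    withSeed(seed, {
        n <- nrow(G)
        noise <- function(nc) matrix(stats::rnorm(n * nc, 0, config@noiseSd), n, nc)
        u <- stats::rnorm(n)
        latent <- function(nc) {
            if (config@latentSd == 0) return(0)
            load <- config@latentSd * stats::runif(nc, 0.5, 1.5) *
                sample(c(-1, 1), nc, replace = TRUE)
            outer(u, load)
        }
        iso <- G %*% config@effectIsoform + latent(config@nIsoforms) +
            noise(config@nIsoforms)
        mrk <- tanh(zscore(iso)) %*% config@effectMarker +
            latent(config@nMarkers) + noise(config@nMarkers)
        phe <- zscore(mrk) %*% config@effectPhenotype +
            latent(config@nPhenotypes) + noise(config@nPhenotypes)
        lin <- as.numeric(zscore(phe) %*% config@effectDisease)
        colnames(iso) <- colnames(config@effectIsoform)
        colnames(mrk) <- colnames(config@effectMarker)
        colnames(phe) <- colnames(config@effectPhenotype)
        rownames(iso) <- rownames(mrk) <- rownames(phe) <- rownames(G)
        list(isoforms = iso, markers = mrk, phenotypes = phe, liability = lin)
    })
}

#' Calibrate the liability intercept for a target case prevalence
#'
#' Simulates a calibration cohort under the config seed and returns the
#' intercept c such that mean(sigmoid(liability + c)) equals the target.
#'
#' @param config a [SynthConfig-class].
#' @param target case fraction; default the config's `targetPrevalence`.
#' @param nCalib calibration cohort size.
#' @return the intercept (numeric scalar).
#' @export
calibrateIntercept <- function(config, target = config@targetPrevalence,
                               nCalib = 5000L) {
    G <- genGenotypes(nCalib, stats::setNames(config@maf, rownames(config@effectIsoform)),
                      seed = config@seed + 903L)
    lin <- propagateLayers(G, config, seed = config@seed + 904L)$liability
    f <- function(c0) mean(sigmoid(lin + c0)) - target
    stats::uniroot(f, lower = -50, upper = 50, tol = 1e-8)$root
}

resolveIntercept <- function(config) {
    if (is.na(config@liabilityIntercept)) calibrateIntercept(config)
    else config@liabilityIntercept
}

#' Generate a multilevel dataset (genotype, isoform, marker, phenotype layers)
#'
#' Applies the planted chain: isoforms are a linear function of genotypes plus
#' small age/sex covariate effects and noise; markers mix a tanh-transformed
#' isoform signal; phenotypes mix markers; the binary diagnosis is drawn from
#' a sigmoid liability on the phenotypes. Planted effect matrices are recorded
#' in the `truth` slot.
#'
#' @param config a [SynthConfig-class].
#' @return a [MultilevelDataset-class].
#' @export
genMultilevel <- function(config) {
    validObject(config)
    n <- config@nSamplesMultilevel
    G <- genGenotypes(n, stats::setNames(config@maf, rownames(config@effectIsoform)),
                      seed = config@seed)
    lay <- propagateLayers(G, config, seed = config@seed + 1L)
    cov <- withSeed(config@seed + 2L, data.frame(
        age = round(stats::rnorm(n, 45, 9)),
        sex = stats::rbinom(n, 1L, 0.5),
        row.names = rownames(G)))
    # mild covariate effects on expression (age/sex enter the isoform layer)
    isoCov <- lay$isoforms +
        outer(0.02 * (cov$age - 45), rep(1, config@nIsoforms)) +
        outer(0.2 * (cov$sex - 0.5), rep(1, config@nIsoforms))
    intercept <- resolveIntercept(config)
    diag01 <- withSeed(config@seed + 3L,
        stats::rbinom(n, 1L, sigmoid(lay$liability + intercept)))
    cov$diagnosis <- diag01
    new("MultilevelDataset",
        genotypes = G, isoforms = isoCov, markers = lay$markers,
        phenotypes = lay$phenotypes, covariates = cov,
        diagnosis = as.integer(diag01),
        truth = list(effectIsoform = config@effectIsoform,
                     effectMarker = config@effectMarker,
                     effectPhenotype = config@effectPhenotype,
                     effectDisease = config@effectDisease,
                     liabilityIntercept = intercept))
}

#' Generate an end-to-end genotype/diagnosis dataset
#'
#' Shares the planted chain with [genMultilevel()]: genotypes are pushed
#' through the layer effects (with fresh per-layer noise) to a liability, and
#' labels are Bernoulli(sigmoid(liability + intercept)).
#'
#' @param config a [SynthConfig-class].
#' @param n sample count; default `config@nSamplesE2E`.
#' @param seedOffset added to the config seed so independent train/holdout
#'   cohorts can be drawn from one config.
#' @return an [EndToEndDataset-class].
#' @export
genEndToEnd <- function(config, n = config@nSamplesE2E, seedOffset = 100L) {
    validObject(config)
    G <- genGenotypes(n, stats::setNames(config@maf, rownames(config@effectIsoform)),
                      seed = config@seed + seedOffset)
    lay <- propagateLayers(G, config, seed = config@seed + seedOffset + 1L)
    intercept <- resolveIntercept(config)
    y <- withSeed(config@seed + seedOffset + 2L,
                  stats::rbinom(n, 1L, sigmoid(lay$liability + intercept)))
    new("EndToEndDataset", genotypes = G, labels = as.integer(y))
}

#' Write a genotype matrix as TSV (samples x SNPs)
#' @param genotypes additive 0/1/2 matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypesTsv <- function(genotypes, path) {
    df <- data.frame(sample = rownames(genotypes), genotypes,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a real-valued layer table as TSV with a node-label header
#' @param m samples x nodes matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeLayerTsv <- function(m, path) {
    df <- data.frame(sample = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write genotypes as a minimal VCF
#'
#' Emits a VCFv4.2 file with synthetic chromosome/position fields (one SNP per
#' record, GT-only FORMAT) so standard VCF tooling can read the matrix back.
#' Missing genotypes become `./.`.
#'
#' @param genotypes samples x SNPs 0/1/2 matrix (NA allowed).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenotypesVcf <- function(genotypes, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", rownames(genotypes)), collapse = "\t")),
               con)
    gtmap <- c("0/0", "0/1", "1/1")
    for (j in seq_len(ncol(genotypes))) {
        g <- genotypes[, j]
        gt <- ifelse(is.na(g), "./.", gtmap[g + 1L])
        writeLines(paste(c("1", as.character(j), colnames(genotypes)[j], "A",
                           "G", ".", "PASS", ".", "GT", gt), collapse = "\t"),
                   con)
    }
    invisible(path)
}

#' Write the planted ground-truth network as JSON
#' @param truth the `truth` list of a generated [MultilevelDataset-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTruthJson <- function(truth, path) {
    jsonlite::write_json(lapply(truth, function(x) {
        if (is.matrix(x)) list(dimnames = dimnames(x), values = unname(x))
        else x
    }), path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
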