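# in-code fixtures shared across test files

colData <- SummarizedExperiment::colData

makePE <- function(e, l, scaleHint = "log") {
    np <- ncol(e)
    if (is.null(rownames(e))) {
        rownames(e) <- rownames(l) <- paste0("f", seq_len(nrow(e)))
    }
    if (is.null(colnames(e))) {
        colnames(e) <- colnames(l) <- paste0("P", seq_len(np))
    }
    PairedExperiment(e, l,
                     ageEarly = seq(40, by = 1, length.out = np),
                     ageLate = seq(55, by = 1, length.out = np),
                     scaleHint = scaleHint)
}

randomPE <- function(nFeatures, nPairs, seed, scaleHint = "log") {
    withr::with_seed(seed, {
        e <- matrix(rnorm(nFeatures * nPairs, 5, 2), nFeatures, nPairs)
        l <- e + matrix(rnorm(nFeatures * nPairs, 0, 1), nFeatures, nPairs)
        if (scaleHint == "linear") { e <- 2^e; l <- 2^l }
        makePE(e, l, scaleHint)
    })
}

# probe GRanges with given 0-based midpoints (50 bp probes)
probesAt <- function(mid, ratio, chrom = "chr1") {
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = mid - 25 + 1, width = 50))
    S4Vectors::mcols(gr)$log2_ratio <- ratio
    gr
}

referenceSimConfig <- function(seed = 1L, interSdScale = 0.5, ...) {
    simulationConfig(nGenes = 5000L, nPairs = 10L,
                     plantedSets = list(list(name = "translation",
                                             nGenes = 100L, effect = -1)),
                     noiseSd = 0.25, interSdScale = interSdScale,
                     seed = seed, ...)
}
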