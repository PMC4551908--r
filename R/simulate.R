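#' Configuration for the paired-design simulator
#'
#' Defines the generative model for synthetic paired longitudinal expression
#' data with known ground truth. On the log2 scale, gene `g` in subject `i`
#' has baseline `b_gi = baseline_g + u_gi` with a gene-specific
#' inter-individual effect `u_gi ~ N(0, interSd_g)`; the early sample is
#' `b_gi + noise`, the late sample `b_gi + effect_g + noise`, and values are
#' emitted on the linear scale as `2^log2value`. The default design mirrors a
#' small longitudinal cohort: 10 subject pairs sampled 12-19 years apart,
#' first samples taken between 35 and 75 minus the gap years of age,
#' lognormal-scale intensities, and gene-specific inter-individual spread.
#'
#' @param nGenes number of genes.
#' @param nPairs number of subject pairs (>= 2).
#' @param gapRange sampling-gap range in years (uniform draw per subject).
#' @param ageRange overall age span in years; the early age is uniform on
#'   `[ageRange[1], ageRange[2] - gap]`.
#' @param baselineMean,baselineSd mean and SD of per-gene baseline log2
#'   intensity.
#' @param interSdScale scale of the per-gene inter-individual SD, drawn as
#'   `|N(0, interSdScale)|`.
#' @param plantedSets list of planted coordinated effects, each a list with
#'   `name`, `nGenes`, `effect` (signed log2 fold change) and optional
#'   `effectSd` (gene-to-gene spread of the effect, default 0). Planted gene
#'   sets are disjoint.
#' @param noiseSd per-sample measurement noise SD (log2 scale).
#' @param pairedBaseline when `TRUE` (default) the subject effect `u_gi` is
#'   shared between the early and late sample — the longitudinal design's
#'   strength, inter-individual baseline variation cancels in the change.
#'   When `FALSE`, `u_gi` is drawn independently at each time point,
#'   emulating subject-by-time trajectory heterogeneity: inter-individual
#'   variance then contaminates the temporal change, the regime in which
#'   variance-bounded selection matters most.
#' @param intensityVarianceCoupling when `TRUE`, low-intensity genes get
#'   proportionally larger inter-individual SD (factor
#'   `2^((baselineMean - baseline_g) / (2 * baselineSd))`), emulating the
#'   higher relative uncertainty of weak signals.
#' @param seed integer seed; everything downstream is deterministic given it.
#'
#' @return A validated `SimulationConfig` (a classed list).
#' @export
simulationConfig <- function(nGenes = 5000L, nPairs = 10L,
                             gapRange = c(12, 19), ageRange = c(35, 75),
                             baselineMean = 5, baselineSd = 2,
                             interSdScale = 0.5,
                             plantedSets = list(),
                             noiseSd = 0.25,
                             pairedBaseline = TRUE,
                             intensityVarianceCoupling = FALSE,
                             seed = 1L) {
    cfg <- list(nGenes = as.integer(nGenes), nPairs = as.integer(nPairs),
                gapRange = as.numeric(gapRange), ageRange = as.numeric(ageRange),
                baselineMean = baselineMean, baselineSd = baselineSd,
                interSdScale = interSdScale, plantedSets = plantedSets,
                noiseSd = noiseSd, pairedBaseline = isTRUE(pairedBaseline),
                intensityVarianceCoupling = isTRUE(intensityVarianceCoupling),
                seed = as.integer(seed))
    if (cfg$nPairs < 2L) stop("nPairs must be at least 2")
    if (cfg$nGenes < 1L) stop("nGenes must be positive")
    if (any(c(cfg$baselineSd, cfg$interSdScale, cfg$noiseSd) < 0)) {
        stop("all standard deviations must be nonnegative")
    }
    if (length(cfg$gapRange) != 2L || diff(cfg$gapRange) < 0) {
        stop("gapRange must be (min, max) with min <= max")
    }
    for (ps in cfg$plantedSets) {
        if (!all(c("name", "nGenes", "effect") %in% names(ps))) {
            stop("each planted set needs fields: name, nGenes, effect")
        }
        if (!is.null(ps$effectSd) && ps$effectSd < 0) stop("effectSd must be nonnegative")
    }
    totPlanted <- sum(vapply(cfg$plantedSets, function(p) as.integer(p$nGenes), 1L))
    if (totPlanted > cfg$nGenes) {
        stop("planted sets exceed the total number of genes")
    }
    nm <- vapply(cfg$plantedSets, `[[`, character(1), "name")
    if (anyDuplicated(nm)) stop("planted set names must be unique")
    structure(cfg, class = "SimulationConfig")
}

#' Simulate a paired longitudinal expression matrix with known truth
#'
#' @param cfg a [simulationConfig()].
#'
#' @return A list with `pe` (a [PairedExperiment-class], linear scale) and
#'   `truth` (a `DataFrame` aligned with the features: `set` — planted set
#'   name or `NA` —, `effect`, `baseline`, `inter_sd`).
#' @export
simulatePairedExpression <- function(cfg) {
    stopifnot(inherits(cfg, "SimulationConfig"))
    withr::with_seed(cfg$seed, {
        G <- cfg$nGenes; P <- cfg$nPairs
        genes <- sprintf("gene%05d", seq_len(G))
        subjects <- sprintf("S%02d", seq_len(P))

        gap <- stats::runif(P, cfg$gapRange[1], cfg$gapRange[2])
        age_early <- stats::runif(P, cfg$ageRange[1], cfg$ageRange[2] - gap)
        age_late <- age_early + gap

        baseline <- stats::rnorm(G, cfg$baselineMean, cfg$baselineSd)
        interSd <- abs(stats::rnorm(G, 0, cfg$interSdScale))
        if (cfg$intensityVarianceCoupling) {
            interSd <- interSd * 2^((cfg$baselineMean - baseline) /
                                    (2 * max(cfg$baselineSd, 1e-8)))
        }

        setLab <- rep(NA_character_, G)
        effect <- rep(0, G)
        if (length(cfg$plantedSets)) {
            pool <- sample.int(G)
            ofs <- 0L
            for (ps in cfg$plantedSets) {
                idx <- pool[ofs + seq_len(ps$nGenes)]
                ofs <- ofs + as.integer(ps$nGenes)
                setLab[idx] <- ps$name
                esd <- if (is.null(ps$effectSd)) 0 else ps$effectSd
                effect[idx] <- ps$effect + stats::rnorm(ps$nGenes, 0, esd)
            }
        }

        u <- matrix(stats::rnorm(G * P, 0, 1), G, P) * interSd
        uLate <- if (cfg$pairedBaseline) u else
            matrix(stats::rnorm(G * P, 0, 1), G, P) * interSd
        earlyLog <- baseline + u +
            matrix(stats::rnorm(G * P, 0, cfg$noiseSd), G, P)
        lateLog <- baseline + uLate + effect +
            matrix(stats::rnorm(G * P, 0, cfg$noiseSd), G, P)

        e <- 2^earlyLog
        l <- 2^lateLog
        dimnames(e) <- dimnames(l) <- list(genes, subjects)
        pe <- PairedExperiment(e, l, subject = subjects,
                               ageEarly = age_early, ageLate = age_late,
                               scaleHint = "linear")
        truth <- DataFrame(set = setLab, effect = effect, baseline = baseline,
                           inter_sd = interSd, row.names = genes)
        list(pe = pe, truth = truth)
    })
}

#' Extract the planted gene sets from a truth table
#'
#' @param truth the `truth` component of [simulatePairedExpression()].
#' @return A named list of gene-id vectors, one per planted set.
#' @export
plantedSets <- function(truth) {
    lab <- truth$set
    split(rownames(truth)[!is.na(lab)], lab[!is.na(lab)])
}

#' Simulate matched early/late tiling-array probe tracks
#'
#' Probes of fixed length are placed uniformly over a single region; each
#' probe's log2 ratio is the regional truth plus Gaussian noise, with planted
#' temporal effects added to the late tracks inside designated truth
#' intervals. Emits one track per subject per time point, ready for the
#' binning-then-components path.
#'
#' @param nProbes probes per track.
#' @param regionLength region span in bp (single chromosome `"chrS"`,
#'   positions 0-based within `[0, regionLength)`).
#' @param truthWindows data.frame with columns `start`, `end` (0-based
#'   half-open), `baseline` (log2 ratio) and `effect` (added to late tracks);
#'   regions outside any truth window default to baseline 0, effect 0.
#' @param nPairs subject pairs.
#' @param noiseSd per-probe noise SD.
#' @param probeLength probe length in bp.
#' @param seed integer seed.
#'
#' @return A list with `early` and `late` (lists of `GRanges` with
#'   `log2_ratio`, one per subject) and `truth` (the truth window table).
#' @export
simulateProbeTrack <- function(nProbes = 2000L, regionLength = 100000L,
                               truthWindows = data.frame(start = integer(),
                                                         end = integer(),
                                                         baseline = numeric(),
                                                         effect = numeric()),
                               nPairs = 10L, noiseSd = 0.2,
                               probeLength = 50L, seed = 1L) {
    stopifnot(nProbes >= 1L, regionLength > probeLength, nPairs >= 1L)
    expected <- nProbes * 500 / regionLength
    if (stats::pbinom(3, size = as.integer(nProbes), prob = min(1, 500 / regionLength)) > 0.99) {
        warning("probe density is too low for 500 bp windows to ever satisfy a 4-probe minimum")
    }
    withr::with_seed(as.integer(seed), {
        s0 <- sort(sample.int(regionLength - probeLength, nProbes, replace = TRUE)) - 1L
        gr0 <- GRanges("chrS", IRanges::IRanges(start = s0 + 1L, width = probeLength))
        mid <- s0 + probeLength / 2
        base <- rep(0, nProbes)
        eff <- rep(0, nProbes)
        if (nrow(truthWindows)) {
            for (i in seq_len(nrow(truthWindows))) {
                inWin <- mid >= truthWindows$start[i] & mid < truthWindows$end[i]
                base[inWin] <- truthWindows$baseline[i]
                eff[inWin] <- truthWindows$effect[i]
            }
        }
        mk <- function(mu) {
            g <- gr0
            mcols(g)$log2_ratio <- mu + stats::rnorm(nProbes, 0, noiseSd)
            g
        }
        list(early = lapply(seq_len(nPairs), function(i) mk(base)),
             late = lapply(seq_len(nPairs), function(i) mk(base + eff)),
             truth = truthWindows)
    })
}
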