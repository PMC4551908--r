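#' Build a ranked list from a gene-level score table
#'
#' The signed temporal distance `t` is used directly as the ranking metric
#' (RNK semantics): genes are ordered by metric, descending, with metric ties
#' broken by lexicographic gene symbol so the order — and hence every
#' enrichment score — is deterministic. Optionally restricts to the features
#' that passed the SD selection, the pre-filtering step that bounds temporal
#' changes by an upper limit on the variance before enrichment testing.
#'
#' @param st gene-level score table (after [collapseToGenes()] if the input
#'   was transcript-level); rownames are gene symbols.
#' @param selectedOnly restrict to rows with `selected == TRUE` (requires
#'   [sdSelect()] to have been run).
#'
#' @return A named numeric vector sorted in decreasing metric order; names
#'   are unique gene symbols.
#' @export
buildRankedList <- function(st, selectedOnly = FALSE) {
    stopifnot("t" %in% colnames(st))
    if (selectedOnly) {
        if (!"selected" %in% colnames(st)) {
            stop("selectedOnly = TRUE requires a 'selected' column (run sdSelect() first)")
        }
        st <- st[st$selected, , drop = FALSE]
        if (nrow(st) == 0L) stop("no features are selected; cannot build a ranked list")
    }
    if (nrow(st) == 0L) stop("empty score table; cannot build a ranked list")
    if (anyDuplicated(rownames(st))) stop("duplicate gene symbols in the score table")
    metric <- as.numeric(st$t)
    names(metric) <- rownames(st)
    metric[order(-metric, names(metric), method = "radix")]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The classic running-sum statistic on a ranked list: walking down the list,
#' the sum increases by \eqn{|m_i|^p / N_R} at each set member (with
#' \eqn{N_R = \sum_{hits} |m|^p}) and decreases by \eqn{1/(N - N_{hits})}
#' otherwise. The enrichment score is the signed maximum deviation from zero.
#'
#' @param rankedList named numeric vector from [buildRankedList()] (sorted
#'   decreasing, unique names).
#' @param geneSet character vector of gene symbols; must intersect the list
#'   but not cover it entirely.
#' @param exponentP weighting exponent (1 = the standard weighted statistic;
#'   0 = classic unweighted KS).
#'
#' @return A list with `ES`, the full `running` sum (length of the list), and
#'   `leadingEdge` (set members at or before the extremum for positive ES, at
#'   or after it for negative ES).
#' @export
enrichmentScore <- function(rankedList, geneSet, exponentP = 1) {
    .checkRankedList(rankedList)
    hits <- names(rankedList) %in% geneSet
    nh <- sum(hits)
    N <- length(rankedList)
    if (nh == 0L) stop("gene set has no overlap with the ranked universe")
    if (nh == N) stop("gene set covers the entire universe; the miss decrement is undefined")
    w <- abs(rankedList)^exponentP
    NR <- sum(w[hits])
    inc <- if (NR > 0) w / NR else rep(1 / nh, N)  # all-zero hit metrics: equal mass
    step <- ifelse(hits, inc, -1 / (N - nh))
    running <- cumsum(step)
    maxP <- max(running)
    minP <- min(running)
    # signed maximum deviation; a magnitude tie yields 0 (the only rule
    # antisymmetric under list negation+reversal). Ties are detected with a
    # small relative tolerance so the outcome does not depend on summation
    # order.
    cmp <- .tieCompare(maxP, minP)
    if (cmp > 0) {
        peak <- which.max(running)
        ES <- maxP
        le <- names(rankedList)[seq_len(peak)][hits[seq_len(peak)]]
    } else if (cmp < 0) {
        peak <- which.min(running)
        ES <- minP
        le <- names(rankedList)[peak:N][hits[peak:N]]
    } else {
        ES <- 0
        le <- character(0)
    }
    list(ES = ES, running = unname(running), leadingEdge = le)
}

# compare |maxP| vs |minP| with 1e-12 relative tolerance; 0 means tie
.tieCompare <- function(maxP, minP) {
    d <- maxP + minP
    if (abs(d) <= 1e-12 * max(abs(maxP), abs(minP), 1e-300)) 0L
    else if (d > 0) 1L else -1L
}

.checkRankedList <- function(rl) {
    if (is.null(names(rl)) || anyDuplicated(names(rl))) {
        stop("ranked list must have unique gene symbols as names")
    }
    if (is.unsorted(rev(rl))) stop("ranked list must be sorted in decreasing metric order")
    invisible(TRUE)
}

# ES from sorted hit positions only: the running sum is linear between hits,
# so its extrema occur immediately after or immediately before a hit.
.esFromPositions <- function(pos, w, N) {
    nh <- length(pos)
    wh <- w[pos]
    NR <- sum(wh)
    hitCum <- if (NR > 0) cumsum(wh) / NR else seq_len(nh) / nh
    missRate <- 1 / (N - nh)
    after <- hitCum - (pos - seq_len(nh)) * missRate
    before <- c(0, hitCum[-nh]) - (pos - 1 - (seq_len(nh) - 1)) * missRate
    maxP <- max(after, before, 0)
    minP <- min(after, before, 0)
    cmp <- .tieCompare(maxP, minP)
    if (cmp > 0) maxP else if (cmp < 0) minP else 0
}

#' Pre-ranked GSEA with a gene-permutation null
#'
#' Computes the weighted KS enrichment score for each gene set against a
#' ranked list, and calibrates it by gene-label permutation: for each set
#' size, `nPerm` random same-size subsets of the universe are drawn and
#' scored. Normalised enrichment scores divide the observed ES by the mean
#' magnitude of same-sign permutation scores; nominal p-values are the
#' same-sign permutation tail with a +1 correction (never exactly zero,
#' floored at 1/(nPerm + 1)); the FDR q-value follows the NES-pooling
#' procedure of the reference GSEA implementation (set `fdrMethod = "BH"` for
#' Benjamini-Hochberg on the nominal p-values instead). Results are
#' deterministic given `seed`.
#'
#' @inheritParams enrichmentScore
#' @param geneSets named list of character vectors (see [readGmt()]).
#' @param nPerm number of gene-label permutations (>= 1).
#' @param minSize,maxSize set-size filters applied after intersection with
#'   the ranked universe.
#' @param seed integer seed for the permutation stream.
#' @param fdrMethod `"gsea"` (NES-pooling) or `"BH"`.
#'
#' @return A [S4Vectors::DataFrame] with one row per retained set: `name`,
#'   `size`, `ES`, `NES`, `pval`, `padj`, `leadingEdge` (a `CharacterList`),
#'   sorted by `NES` decreasing. Sets filtered out (no overlap or size out of
#'   bounds) are reported via messages.
#' @export
gseaPreranked <- function(rankedList, geneSets, nPerm = 1000L, minSize = 15L,
                          maxSize = 500L, exponentP = 1, seed = 1L,
                          fdrMethod = c("gsea", "BH")) {
    fdrMethod <- match.arg(fdrMethod)
    .checkRankedList(rankedList)
    if (nPerm < 1L) stop("nPerm must be at least 1")
    if (is.null(names(geneSets)) || anyDuplicated(names(geneSets))) {
        stop("gene sets must have unique names")
    }
    universe <- names(rankedList)
    N <- length(universe)
    trimmed <- lapply(geneSets, intersect, universe)
    nDropped <- vapply(geneSets, length, 1L) - vapply(trimmed, length, 1L)
    if (any(nDropped > 0)) {
        message(sprintf("%d gene(s) outside the ranked universe dropped across %d set(s)",
                        sum(nDropped), sum(nDropped > 0)))
    }
    sizes <- vapply(trimmed, length, 1L)
    keep <- sizes >= minSize & sizes <= pmin(maxSize, N - 1L)
    if (!any(keep)) {
        warning("all gene sets were filtered out by the size bounds")
        return(DataFrame(name = character(), size = integer(), ES = numeric(),
                         NES = numeric(), pval = numeric(), padj = numeric(),
                         leadingEdge = IRanges::CharacterList()))
    }
    trimmed <- trimmed[keep]
    sizes <- sizes[keep]

    w <- abs(rankedList)^exponentP
    obs <- lapply(trimmed, function(g) enrichmentScore(rankedList, g, exponentP))
    es <- vapply(obs, `[[`, numeric(1), "ES")

    # one permutation-ES matrix per distinct set size (statistically identical
    # to per-set sampling; the null depends on the set only through its size)
    uSizes <- sort(unique(sizes))
    permBySize <- withr::with_seed(as.integer(seed), {
        stats::setNames(lapply(uSizes, function(k) {
            vapply(seq_len(nPerm), function(b) {
                .esFromPositions(sort.int(sample.int(N, k)), w, N)
            }, numeric(1))
        }), as.character(uSizes))
    })

    nes <- pval <- padj <- rep(NA_real_, length(es))
    nesPermAll <- vector("list", length(es))
    for (i in seq_along(es)) {
        perm <- permBySize[[as.character(sizes[i])]]
        posMean <- mean(perm[perm > 0])
        negMean <- mean(abs(perm[perm < 0]))
        nes[i] <- if (es[i] >= 0) es[i] / posMean else es[i] / negMean
        nesPerm <- ifelse(perm >= 0, perm / posMean, perm / negMean)
        nesPermAll[[i]] <- nesPerm
        if (es[i] >= 0) {
            same <- perm[perm >= 0]
            pval[i] <- (1 + sum(same >= es[i])) / (1 + length(same))
        } else {
            same <- perm[perm < 0]
            pval[i] <- (1 + sum(same <= es[i])) / (1 + length(same))
        }
    }

    if (fdrMethod == "BH") {
        padj <- stats::p.adjust(pval, method = "BH")
    } else {
        pool <- unlist(nesPermAll, use.names = FALSE)
        nPosPool <- sum(pool >= 0)
        nNegPool <- sum(pool < 0)
        nPosObs <- sum(nes >= 0)
        nNegObs <- sum(nes < 0)
        for (i in seq_along(nes)) {
            if (nes[i] >= 0) {
                num <- if (nPosPool) sum(pool >= nes[i]) / nPosPool else 0
                den <- sum(nes >= nes[i]) / max(nPosObs, 1L)
            } else {
                num <- if (nNegPool) sum(pool <= nes[i]) / nNegPool else 0
                den <- sum(nes <= nes[i]) / max(nNegObs, 1L)
            }
            padj[i] <- min(1, if (den > 0) num / den else 1)
        }
    }

    out <- DataFrame(
        name = names(trimmed), size = sizes, ES = es, NES = nes,
        pval = pval, padj = padj,
        leadingEdge = IRanges::CharacterList(lapply(obs, `[[`, "leadingEdge")))
    rownames(out) <- NULL
    out[order(-out$NES), , drop = FALSE]
}

#' Wilcoxon rank-sum test of a set's score shift against background
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test comparing a gene set's
#' per-gene values (e.g. combined scores or z-scores) with a background set.
#' The exact null distribution is used for combined sample sizes up to 25
#' when no ties are present; otherwise the normal approximation with tie and
#' continuity correction is used. If every value is tied across both groups
#' the test is uninformative and p = 1 is returned.
#'
#' @param setScores,backgroundScores nonempty numeric vectors.
#' @return A list with `statistic` (the rank-sum W) and `p.value`.
#' @export
wilcoxonSetShift <- function(setScores, backgroundScores) {
    x <- as.numeric(setScores)
    y <- as.numeric(backgroundScores)
    if (!length(x) || !length(y)) stop("both score vectors must be nonempty")
    if (length(unique(c(x, y))) == 1L) {
        return(list(statistic = length(x) * length(y) / 2, p.value = 1))
    }
    exact <- (length(x) + length(y)) <= 25L && !anyDuplicated(c(x, y))
    ht <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = exact, correct = TRUE))
    list(statistic = unname(ht$statistic), p.value = ht$p.value)
}
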