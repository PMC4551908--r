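#' Bin tiling-array probe ratios into sliding windows
#'
#' Probe-level log2 ratios are averaged in fixed-size sliding windows (500 bp
#' window, 250 bp step by default), anchored at position 0 of each
#' chromosome. A probe belongs to a window when its midpoint lies in
#' `[start, end)` (0-based half-open), so each probe contributes to at most
#' `ceiling(window/step)` windows. Windows holding fewer than `minProbes`
#' probes are emitted with `kept = FALSE`; windows with no probes at all are
#' not emitted.
#'
#' @param probes a `GRanges` with a numeric `log2_ratio` metadata column (one
#'   track per sample contrast), e.g. from [readProbeTrack()].
#' @param window,step window size and step in bp; `step > window` is an
#'   error since it would leave unintended gaps.
#' @param minProbes minimum member probes for a window to be kept.
#'
#' @return A [WindowTrack-class].
#' @export
binProbes <- function(probes, window = 500L, step = 250L, minProbes = 4L) {
    stopifnot(is(probes, "GRanges"))
    if (!"log2_ratio" %in% colnames(mcols(probes))) {
        stop("probes must carry a 'log2_ratio' metadata column")
    }
    if (step > window) stop("step size must not exceed window size (gaps would be left uncovered)")
    if (!all(is.finite(probes$log2_ratio))) stop("non-finite probe log2 ratios")
    window <- as.integer(window); step <- as.integer(step)
    minProbes <- as.integer(minProbes)

    chrom <- as.character(seqnames(probes))
    # midpoint on the 0-based half-open scale [start-1, end)
    mid <- (start(probes) - 1 + end(probes)) / 2
    val <- probes$log2_ratio

    outChrom <- character(); outStart <- integer(); outVals <- list()
    for (ch in unique(chrom)) {
        sel <- which(chrom == ch)
        m <- mid[sel]
        # window index range containing each midpoint: j*step <= m < j*step+window
        jLo <- pmax(0L, as.integer(ceiling((m - window) / step + 1e-9)))
        jHi <- as.integer(floor(m / step + 1e-9))
        # drop exact upper-boundary cases (half-open windows)
        onEdge <- (m - jHi * step) >= window
        jHi[onEdge] <- jHi[onEdge]  # cannot happen when step <= window, kept for clarity
        reps <- pmax(0L, jHi - jLo + 1L)
        probeIdx <- rep(sel, reps)
        winIdx <- unlist(lapply(seq_along(sel), function(i) {
            if (reps[i] <= 0L) integer() else seq.int(jLo[i], jHi[i])
        }), use.names = FALSE)
        # enforce half-open membership explicitly
        ok <- mid[probeIdx] >= winIdx * step & mid[probeIdx] < winIdx * step + window
        probeIdx <- probeIdx[ok]; winIdx <- winIdx[ok]
        if (!length(winIdx)) next
        byWin <- split(val[probeIdx], winIdx)
        js <- as.integer(names(byWin))
        outChrom <- c(outChrom, rep(ch, length(js)))
        outStart <- c(outStart, js * step)
        outVals <- c(outVals, unname(byWin))
    }
    n <- lengths(outVals)
    gr <- GRanges(outChrom,
                  IRanges::IRanges(start = outStart + 1L, width = window))
    mcols(gr)$mean_log2 <- vapply(outVals, mean, numeric(1))
    mcols(gr)$n_probes <- as.integer(n)
    mcols(gr)$n_above <- rep(NA_integer_, length(gr))
    mcols(gr)$kept <- n >= minProbes
    ord <- order(as.character(seqnames(gr)), start(gr), method = "radix")
    new("WindowTrack", windows = gr[ord], probeValues = outVals[ord],
        trackValues = val, windowSize = window, stepSize = step,
        minProbes = minProbes, floorValue = NA_real_)
}

#' Quantile floor rule for binned windows
#'
#' Low log2 ratios are uninformative after normalisation (they include cases
#' where the input signal exceeds the enrichment signal), so member probe
#' ratios below the track-wide `floorQ` quantile (default the median) are
#' reset to that quantile before window means are computed, and windows with
#' none or one member probe strictly above the floor are discarded
#' (`kept = FALSE`). Ties at the floor count as not above. The operation is
#' idempotent: re-applying the same floor leaves the track unchanged.
#'
#' @param wt a [WindowTrack-class] from [binProbes()].
#' @param floorQ quantile in `[0, 1]` computed over all probe ratios of the
#'   source track.
#'
#' @return The floored `WindowTrack`, with `mean_log2`, `n_above` and `kept`
#'   updated and `floorValue()` set.
#' @export
quantileFloor <- function(wt, floorQ = 0.5) {
    stopifnot(is(wt, "WindowTrack"), floorQ >= 0, floorQ <= 1)
    if (!length(wt@windows)) stop("empty window track")
    # inverse-CDF (type 1) quantile: an order statistic, so re-applying the
    # floor recovers the same value and the operation is idempotent
    floor <- stats::quantile(wt@trackValues, floorQ, names = FALSE, type = 1)
    vals <- lapply(wt@probeValues, pmax, floor)
    gr <- wt@windows
    mcols(gr)$mean_log2 <- vapply(vals, mean, numeric(1))
    nAbove <- vapply(vals, function(x) sum(x > floor), integer(1))
    mcols(gr)$n_above <- nAbove
    mcols(gr)$kept <- mcols(gr)$n_probes >= wt@minProbes & nAbove >= 2L
    new("WindowTrack", windows = gr, probeValues = vals,
        trackValues = pmax(wt@trackValues, floor),
        windowSize = wt@windowSize, stepSize = wt@stepSize,
        minProbes = wt@minProbes, floorValue = floor)
}

#' Stratify window-level values by distance to the nearest CpG island
#'
#' Assigns each window a distance to the closest CpG-island boundary, using
#' whichever window edge is closer to the nearest island (windows overlapping
#' an island get the distance-0 stratum, labelled `"CGI"`). Shore distances
#' are binned in fixed increments starting at the island boundary, and the
#' per-window values (e.g. the three components v, s, t computed on binned
#' ratios) are summarised per stratum.
#'
#' @param windowValues a `GRanges` whose numeric metadata columns hold the
#'   per-window quantities to summarise.
#' @param cgis a `GRanges` of CpG islands (merged; see [readCgiBed()]).
#' @param maxDist maximum shore distance in bp; windows further away are
#'   dropped (count reported).
#' @param bin shore bin width in bp.
#'
#' @return A list with `assignment` (the retained windows with `distance` and
#'   `bin` columns added) and `summary` (a `DataFrame` per stratum: `bin`,
#'   `dist_lo`, `dist_hi`, `n_windows`, then mean/median/sd per value
#'   column).
#' @export
cgiDistancePartition <- function(windowValues, cgis, maxDist = 3000L, bin = 250L) {
    stopifnot(is(windowValues, "GRanges"), is(cgis, "GRanges"))
    if (!length(cgis)) stop("no CpG islands supplied")
    numCols <- colnames(mcols(windowValues))[vapply(mcols(windowValues),
                                                    is.numeric, logical(1))]
    if (!length(numCols)) stop("windowValues must carry numeric metadata columns to summarise")
    hasCgi <- as.character(seqnames(windowValues)) %in%
        unique(as.character(seqnames(cgis)))
    if (any(!hasCgi)) {
        message(sprintf("excluding %d window(s) on chromosome(s) without CpG islands",
                        sum(!hasCgi)))
    }
    w <- windowValues[hasCgi]
    if (!length(w)) stop("no windows share a chromosome with the CpG islands")
    dtn <- GenomicRanges::distanceToNearest(w, cgis)
    d <- rep(NA_integer_, length(w))
    d[S4Vectors::queryHits(dtn)] <- mcols(dtn)$distance
    overlap <- IRanges::overlapsAny(w, cgis)
    keep <- !is.na(d) & (overlap | d < maxDist)
    dropped <- sum(!keep)
    if (dropped) message(sprintf("dropping %d window(s) beyond %d bp from any island",
                                 dropped, as.integer(maxDist)))
    w <- w[keep]; d <- d[keep]; overlap <- overlap[keep]
    binIdx <- ifelse(overlap, -1L, as.integer(d %/% bin))
    mcols(w)$distance <- ifelse(overlap, 0L, d)
    mcols(w)$bin <- ifelse(binIdx < 0L, "CGI",
                           sprintf("[%d,%d)", binIdx * bin, (binIdx + 1L) * bin))

    levs <- sort(unique(binIdx))
    rows <- lapply(levs, function(b) {
        sel <- binIdx == b
        stats <- unlist(lapply(numCols, function(cn) {
            x <- mcols(w)[[cn]][sel]
            stats::setNames(c(mean(x), stats::median(x), stats::sd(x)),
                            paste0(cn, c("_mean", "_median", "_sd")))
        }))
        c(dist_lo = if (b < 0L) 0L else b * bin,
          dist_hi = if (b < 0L) 0L else (b + 1L) * bin,
          n_windows = sum(sel), stats)
    })
    m <- as.data.frame(do.call(rbind, rows))
    m$dist_lo <- as.integer(m$dist_lo)
    m$dist_hi <- as.integer(m$dist_hi)
    m$n_windows <- as.integer(m$n_windows)
    summary <- DataFrame(
        bin = ifelse(levs < 0L, "CGI",
                     sprintf("[%d,%d)", levs * bin, (levs + 1L) * bin)),
        m)
    list(assignment = w, summary = summary)
}

#' Quantile normalisation utility
#'
#' Plumbing for multi-array inputs: equalises the value distributions of the
#' columns of a matrix (via [limma::normalizeQuantiles()]). Inputs to
#' [binProbes()] are otherwise assumed normalised upstream.
#'
#' @param mat numeric matrix (probes x arrays).
#' @return The quantile-normalised matrix.
#' @export
quantileNormalize <- function(mat) {
    stopifnot(is.matrix(mat), is.numeric(mat))
    out <- limma::normalizeQuantiles(mat)
    dimnames(out) <- dimnames(mat)
    out
}
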