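#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<- mcols mcols<-
#'   queryHits
#' @importFrom BiocGenerics start end width sort
#' @importFrom GenomeInfoDb seqnames
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData
#' @importFrom GenomicRanges GRanges
NULL

#' Paired longitudinal experiment
#'
#' Container for a paired before/after design: the same subject assayed at an
#' early and a late time point. Extends
#' [SummarizedExperiment::SummarizedExperiment] with two aligned assays,
#' `"early"` and `"late"` (features x subject pairs), per-pair metadata
#' (`subject`, `age_early`, `age_late` in years) in `colData`, and a
#' `scale_hint` (`"linear"` or `"log"`) in `metadata()` describing the stored
#' values.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#'
#' @section Validity:
#' Both assays must be present with identical dimensions; all values must be
#' finite; on the linear scale all values must be nonnegative; `age_late`
#' must exceed `age_early` for every pair; feature and pair identifiers must
#' be unique.
#'
#' @seealso [PairedExperiment()] for construction, [computeComponents()] for
#'   the three-component decomposition.
#' @export
setClass("PairedExperiment", contains = "SummarizedExperiment")

.validPairedExperiment <- function(object) {
    msg <- character()
    an <- assayNames(object)
    if (!all(c("early", "late") %in% an)) {
        return("assays 'early' and 'late' are both required")
    }
    e <- assay(object, "early")
    l <- assay(object, "late")
    if (!identical(dim(e), dim(l))) {
        msg <- c(msg, "'early' and 'late' assays must have identical dimensions")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
        msg <- c(msg, "feature ids (rownames) must be present and unique")
    }
    if (is.null(colnames(object)) || anyDuplicated(colnames(object))) {
        msg <- c(msg, "pair ids (colnames) must be present and unique")
    }
    sh <- S4Vectors::metadata(object)$scale_hint
    if (is.null(sh) || !sh %in% c("linear", "log")) {
        msg <- c(msg, "metadata()$scale_hint must be 'linear' or 'log'")
    }
    if (!all(is.finite(e)) || !all(is.finite(l))) {
        bad <- .firstNonFinite(e, l)
        msg <- c(msg, sprintf("non-finite value at feature '%s', pair '%s' (%s)",
                              bad$feature, bad$pair, bad$assay))
    } else if (identical(sh, "linear") && (any(e < 0) || any(l < 0))) {
        msg <- c(msg, "linear-scale intensities must be nonnegative")
    }
    cd <- colData(object)
    need <- c("subject", "age_early", "age_late")
    if (!all(need %in% colnames(cd))) {
        msg <- c(msg, sprintf("colData must contain columns: %s",
                              paste(need, collapse = ", ")))
    } else if (any(cd$age_late <= cd$age_early)) {
        bad <- colnames(object)[which(cd$age_late <= cd$age_early)[1L]]
        msg <- c(msg, sprintf("age_late must exceed age_early (violated for pair '%s')", bad))
    }
    if (length(msg)) msg else TRUE
}

setValidity("PairedExperiment", .validPairedExperiment)

.firstNonFinite <- function(e, l) {
    for (nm in c("early", "late")) {
        m <- if (nm == "early") e else l
        idx <- which(!is.finite(m))
        if (length(idx)) {
            i <- arrayInd(idx[1L], dim(m))
            return(list(assay = nm,
                        feature = rownames(m)[i[1L]] %||% as.character(i[1L]),
                        pair = colnames(m)[i[2L]] %||% as.character(i[2L])))
        }
    }
    list(assay = NA_character_, feature = NA_character_, pair = NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a PairedExperiment
#'
#' @param early,late numeric matrices (features x pairs) of nonnegative
#'   intensities (linear scale) or log-scale values, with identical dimnames.
#'   Rownames are feature ids; colnames are pair ids.
#' @param subject character vector of subject identifiers, one per pair
#'   (defaults to the column names).
#' @param ageEarly,ageLate numeric vectors of ages in years at the two
#'   sampling time points; `ageLate > ageEarly` is required pairwise.
#' @param scaleHint `"linear"` (RPKM-like intensities) or `"log"` (e.g. binned
#'   log2 ratios).
#'
#' @return A [PairedExperiment-class] object.
#' @examples
#' e <- matrix(2^rnorm(20, 5), 5, 4,
#'             dimnames = list(paste0("g", 1:5), paste0("P", 1:4)))
#' l <- e * 2^rnorm(20, 0, 0.1)
#' pe <- PairedExperiment(e, l, ageEarly = c(40, 42, 45, 50),
#'                        ageLate = c(55, 56, 60, 63))
#' pe
#' @export
PairedExperiment <- function(early, late,
                             subject = colnames(early),
                             ageEarly, ageLate,
                             scaleHint = c("linear", "log")) {
    scaleHint <- match.arg(scaleHint)
    early <- as.matrix(early)
    late <- as.matrix(late)
    if (is.null(colnames(early)) && !is.null(subject)) {
        colnames(early) <- colnames(late) <- subject
    }
    if (ncol(early) == 0L) stop("at least one subject pair is required")
    cd <- DataFrame(subject = as.character(subject),
                    age_early = as.numeric(ageEarly),
                    age_late = as.numeric(ageLate),
                    row.names = colnames(early))
    se <- SummarizedExperiment(
        assays = SimpleList(early = early, late = late),
        colData = cd)
    S4Vectors::metadata(se)$scale_hint <- scaleHint
    new("PairedExperiment", se)
}

#' Sliding-window summary of a tiling-array probe track
#'
#' Result of [binProbes()]: fixed-size sliding windows over a probe-level
#' log2-ratio track, each with its member-probe mean, probe count and a
#' `kept` flag. Retains the member probe ratios so that the quantile floor
#' rule ([quantileFloor()]) can be applied and re-applied consistently.
#'
#' @slot windows a `GRanges` with metadata columns `mean_log2`, `n_probes`,
#'   `n_above` (probes strictly above the floor; `NA` until a floor is
#'   applied) and `kept`.
#' @slot probeValues list of numeric vectors, member probe log2 ratios per
#'   window (floored values after [quantileFloor()]).
#' @slot trackValues numeric, all probe ratios of the source track (used for
#'   the track-wide floor quantile).
#' @slot windowSize,stepSize,minProbes integer tiling parameters (bp, bp,
#'   probes).
#' @slot floorValue numeric floor applied to probe ratios (`NA_real_` before
#'   [quantileFloor()]).
#' @export
setClass("WindowTrack",
         slots = c(windows = "GRanges",
                   probeValues = "list",
                   trackValues = "numeric",
                   windowSize = "integer",
                   stepSize = "integer",
                   minProbes = "integer",
                   floorValue = "numeric"))

setValidity("WindowTrack", function(object) {
    msg <- character()
    mc <- colnames(mcols(object@windows))
    need <- c("mean_log2", "n_probes", "n_above", "kept")
    if (!all(need %in% mc)) {
        msg <- c(msg, sprintf("window metadata columns required: %s",
                              paste(need, collapse = ", ")))
    }
    if (length(object@probeValues) != length(object@windows)) {
        msg <- c(msg, "one probe-value vector per window is required")
    }
    if (object@stepSize > object@windowSize) {
        msg <- c(msg, "step size must not exceed window size (gaps would be left uncovered)")
    }
    if (length(msg)) msg else TRUE
})
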