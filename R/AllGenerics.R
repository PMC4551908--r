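#' @rdname PairedExperiment
#' @param x,object a `PairedExperiment` (or `WindowTrack` where noted).
#' @export
setGeneric("earlyAssay", function(x) standardGeneric("earlyAssay"))

#' @rdname PairedExperiment
#' @export
setGeneric("lateAssay", function(x) standardGeneric("lateAssay"))

#' @rdname PairedExperiment
#' @export
setGeneric("scaleHint", function(x) standardGeneric("scaleHint"))

#' @rdname PairedExperiment
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname PairedExperiment
#' @export
setGeneric("ageEarly", function(x) standardGeneric("ageEarly"))

#' @rdname PairedExperiment
#' @export
setGeneric("ageLate", function(x) standardGeneric("ageLate"))

#' @rdname WindowTrack-class
#' @param x a `WindowTrack`.
#' @export
setGeneric("windows", function(x) standardGeneric("windows"))

#' @rdname WindowTrack-class
#' @export
setGeneric("keptWindows", function(x) standardGeneric("keptWindows"))

#' @rdname WindowTrack-class
#' @export
setGeneric("floorValue", function(x) standardGeneric("floorValue"))

setMethod("earlyAssay", "PairedExperiment",
          function(x) assay(x, "early"))

setMethod("lateAssay", "PairedExperiment",
          function(x) assay(x, "late"))

setMethod("scaleHint", "PairedExperiment",
          function(x) S4Vectors::metadata(x)$scale_hint)

setMethod("subjectIds", "PairedExperiment",
          function(x) colData(x)$subject)

setMethod("ageEarly", "PairedExperiment",
          function(x) colData(x)$age_early)

setMethod("ageLate", "PairedExperiment",
          function(x) colData(x)$age_late)

setMethod("show", "PairedExperiment", function(object) {
    callNextMethod()
    gaps <- ageLate(object) - ageEarly(object)
    cat(sprintf("scale_hint: %s | sampling gap: %.0f-%.0f years\n",
                scaleHint(object), min(gaps), max(gaps)))
})

setMethod("windows", "WindowTrack", function(x) x@windows)

setMethod("keptWindows", "WindowTrack", function(x) {
    x@windows[x@windows$kept]
})

setMethod("floorValue", "WindowTrack", function(x) x@floorValue)

setMethod("show", "WindowTrack", function(object) {
    w <- object@windows
    cat(sprintf("WindowTrack: %d windows (%d kept), window %d bp / step %d bp, min %d probes\n",
                length(w), sum(w$kept), object@windowSize, object@stepSize,
                object@minProbes))
    if (!is.na(object@floorValue)) {
        cat(sprintf("  quantile floor applied at %.4g\n", object@floorValue))
    }
})
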