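#' Pipeline configuration
#'
#' Validated configuration for [runPipeline()]. Unknown keys are rejected so
#' typos fail before any computation starts.
#'
#' @param matrixPath,metadataPath input TSVs (see [readPairedMatrix()]).
#' @param gmtPath gene-set collection (GMT).
#' @param outDir output directory (created if missing).
#' @param scaleHint stored-value scale of the matrix.
#' @param logTransform,pseudocount working-scale control.
#' @param weights component weights for [combineScores()].
#' @param kSd SD cutoff for [sdSelect()].
#' @param mappingPath optional transcript-to-gene TSV (columns `transcript`,
#'   `gene`); when given, scores are collapsed per gene.
#' @param collapseMode collapse rule (see [collapseToGenes()]); the ranked
#'   list always uses the `max_abs_t` representative, the selection the
#'   `min_score` one, so this sets the score-table artifact's rule.
#' @param selectedOnly build the ranked list from selected features only (the
#'   pre-filtering coupling).
#' @param nPerm,minSize,maxSize,exponentP GSEA parameters.
#' @param fdrMethod GSEA FDR procedure.
#' @param seed integer seed used for every stochastic step.
#'
#' @return A classed list (`PipelineConfig`).
#' @export
pipelineConfig <- function(matrixPath, metadataPath, gmtPath, outDir,
                           scaleHint = "linear", logTransform = TRUE,
                           pseudocount = 1, weights = c(1, 1, 1) / 3,
                           kSd = 1.0, mappingPath = NULL,
                           collapseMode = "min_score", selectedOnly = TRUE,
                           nPerm = 1000L, minSize = 15L, maxSize = 500L,
                           exponentP = 1, fdrMethod = "gsea", seed = 1L) {
    cfg <- as.list(environment())
    known <- names(formals(pipelineConfig))
    extra <- setdiff(names(cfg), known)
    if (length(extra)) stop(sprintf("unknown configuration key(s): %s",
                                    paste(extra, collapse = ", ")))
    stopifnot(is.character(cfg$matrixPath), is.character(cfg$metadataPath),
              is.character(cfg$gmtPath), is.character(cfg$outDir))
    structure(cfg, class = "PipelineConfig")
}

#' Run the end-to-end analysis pipeline
#'
#' Chains the full flow: read the paired matrix, compute the three
#' components, combine and select, optionally collapse transcripts to genes,
#' build the signed-t ranked list, run pre-ranked GSEA, and write a
#' deterministic artifact set (`score_table.tsv`, `ranked_list.rnk`,
#' `gsea_results.tsv`, `manifest.json`). Identical inputs and configuration
#' yield byte-identical numeric outputs; the manifest records the package
#' version, seed, configuration and MD5 checksums of every artifact. All
#' input paths are validated before any computation starts, and any stage
#' failure aborts with the stage name.
#'
#' @param cfg a [pipelineConfig()].
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(cfg) {
    stopifnot(inherits(cfg, "PipelineConfig"))
    inputs <- c(matrix = cfg$matrixPath, metadata = cfg$metadataPath,
                gmt = cfg$gmtPath)
    if (!is.null(cfg$mappingPath)) inputs <- c(inputs, mapping = cfg$mappingPath)
    missing <- inputs[!file.exists(inputs)]
    if (length(missing)) {
        stop(sprintf("input file(s) not found before starting: %s",
                     paste(sprintf("%s (%s)", missing, names(missing)), collapse = "; ")))
    }
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)

    stage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
                 call. = FALSE)
        })
    }

    pe <- stage("read", readPairedMatrix(cfg$matrixPath, cfg$metadataPath,
                                         scaleHint = cfg$scaleHint))
    cs <- stage("components", computeComponents(pe, cfg$logTransform, cfg$pseudocount))
    st <- stage("score", combineScores(cs, weights = cfg$weights))
    st <- stage("select", sdSelect(st, kSd = cfg$kSd))

    if (!is.null(cfg$mappingPath)) {
        mapping <- stage("mapping", .readTsv(cfg$mappingPath))
        stScore <- stage("collapse", collapseToGenes(st, mapping, mode = cfg$collapseMode))
        stRank <- stage("collapse", collapseToGenes(st, mapping, mode = "max_abs_t"))
        # selection flags live on the score-collapsed table; carry them onto
        # the ranking representative per gene
        stRank$selected <- stScore[rownames(stRank), "selected"]
    } else {
        stScore <- stRank <- st
    }
    rl <- stage("rank", buildRankedList(stRank, selectedOnly = cfg$selectedOnly))
    sets <- stage("gmt", readGmt(cfg$gmtPath))
    res <- stage("gsea", gseaPreranked(rl, sets, nPerm = cfg$nPerm,
                                       minSize = cfg$minSize, maxSize = cfg$maxSize,
                                       exponentP = cfg$exponentP, seed = cfg$seed,
                                       fdrMethod = cfg$fdrMethod))

    paths <- c(score_table = file.path(cfg$outDir, "score_table.tsv"),
               ranked_list = file.path(cfg$outDir, "ranked_list.rnk"),
               gsea_results = file.path(cfg$outDir, "gsea_results.tsv"))
    stage("write", {
        writeScoreTable(stScore, paths["score_table"])
        writeRnk(rl, paths["ranked_list"])
        writeGseaResults(res, paths["gsea_results"])
    })

    manifest <- list(
        package = "threeCA",
        version = as.character(utils::packageVersion("threeCA")),
        seed = cfg$seed,
        config = unclass(cfg),
        n_features = nrow(pe),
        n_pairs = ncol(pe),
        n_selected = sum(st$selected),
        artifacts = as.list(tools::md5sum(paths)))
    jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(manifest)
}
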