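#' Read a paired expression matrix and its pair metadata
#'
#' The matrix is a TSV whose first column holds feature ids and whose
#' remaining columns are named `<subject>_<early|late>`; the sidecar metadata
#' TSV has columns `subject`, `age_early`, `age_late`. Malformed headers,
#' duplicate feature ids, ragged rows and non-numeric cells are hard errors
#' naming the offending column or line.
#'
#' @param path matrix TSV path.
#' @param metadataPath pair-metadata TSV path.
#' @param scaleHint `"linear"` or `"log"`, describing the stored values.
#'
#' @return A [PairedExperiment-class].
#' @export
readPairedMatrix <- function(path, metadataPath, scaleHint = c("linear", "log")) {
    scaleHint <- match.arg(scaleHint)
    df <- .readTsv(path)
    if (ncol(df) < 3L) stop("matrix must have a feature column plus early/late sample columns")
    feat <- as.character(df[[1L]])
    if (anyDuplicated(feat)) {
        stop(sprintf("duplicate feature id(s): %s",
                     paste(utils::head(unique(feat[duplicated(feat)]), 3L), collapse = ", ")))
    }
    cols <- colnames(df)[-1L]
    bad <- cols[!grepl("^.+_(early|late)$", cols)]
    if (length(bad)) {
        stop(sprintf("malformed sample column name(s): %s (expected <subject>_<early|late>)",
                     paste(bad, collapse = ", ")))
    }
    subj <- sub("_(early|late)$", "", cols)
    tp <- sub("^.*_", "", cols)
    subjects <- unique(subj)
    for (s in subjects) {
        if (sum(subj == s & tp == "early") != 1L || sum(subj == s & tp == "late") != 1L) {
            stop(sprintf("subject '%s' must have exactly one early and one late column", s))
        }
    }
    num <- lapply(cols, function(cn) {
        x <- df[[cn]]
        xs <- suppressWarnings(as.numeric(x))
        if (anyNA(xs)) {
            line <- which(is.na(xs))[1L]
            stop(sprintf("non-numeric cell in column '%s', data line %d ('%s')",
                         cn, line, as.character(x[line])))
        }
        xs
    })
    mat <- do.call(cbind, num)
    colnames(mat) <- cols
    rownames(mat) <- feat
    md <- .readTsv(metadataPath)
    need <- c("subject", "age_early", "age_late")
    if (!all(need %in% colnames(md))) {
        stop(sprintf("metadata must contain columns: %s", paste(need, collapse = ", ")))
    }
    if (!setequal(md$subject, subjects)) {
        stop("metadata subjects do not match the matrix sample columns")
    }
    md <- md[match(subjects, md$subject), ]
    e <- mat[, paste0(subjects, "_early"), drop = FALSE]
    l <- mat[, paste0(subjects, "_late"), drop = FALSE]
    colnames(e) <- colnames(l) <- subjects
    PairedExperiment(e, l, subject = subjects,
                     ageEarly = md$age_early, ageLate = md$age_late,
                     scaleHint = scaleHint)
}

#' @rdname readPairedMatrix
#' @param pe a `PairedExperiment` to write.
#' @param matrixPath,metadataPath output TSV paths.
#' @export
writePairedMatrix <- function(pe, matrixPath, metadataPath) {
    e <- earlyAssay(pe); l <- lateAssay(pe)
    subj <- subjectIds(pe)
    out <- data.frame(feature = rownames(pe), check.names = FALSE)
    for (i in seq_along(subj)) {
        out[[paste0(subj[i], "_early")]] <- .fmtNum(e[, i])
        out[[paste0(subj[i], "_late")]] <- .fmtNum(l[, i])
    }
    utils::write.table(out, matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
    md <- data.frame(subject = subj,
                     age_early = .fmtNum(ageEarly(pe)),
                     age_late = .fmtNum(ageLate(pe)))
    utils::write.table(md, metadataPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(matrixPath, metadataPath))
}

.readTsv <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
    df <- tryCatch(
        utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = ""),
        error = function(e) stop(sprintf("failed to parse %s: %s", path, conditionMessage(e))))
    if (ncol(df) != length(first)) {
        stop(sprintf("ragged rows in %s: header has %d fields", path, length(first)))
    }
    df
}

.fmtNum <- function(x) {
    # 15 significant digits: round-trips doubles to ~1e-15 relative precision
    ifelse(is.na(x), "NA", sprintf("%.15g", x))
}

#' Write / read a score table TSV
#'
#' Columns: `feature`, `v`, `s`, `t`, `rank_v`, `rank_s`, `rank_t`, `score`,
#' and when present `z_sd`, `selected`, `direction`.
#'
#' @param st score table (`DataFrame` from [combineScores()]/[sdSelect()]).
#' @param path output TSV path.
#' @export
writeScoreTable <- function(st, path) {
    cols <- intersect(c("v", "s", "t", "rank_v", "rank_s", "rank_t",
                        "score", "z_sd", "selected", "direction", "transcript"),
                      colnames(st))
    out <- data.frame(feature = rownames(st), stringsAsFactors = FALSE)
    for (cn in cols) {
        x <- st[[cn]]
        out[[cn]] <- if (is.numeric(x)) .fmtNum(x) else x
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeScoreTable
#' @export
readScoreTable <- function(path) {
    df <- .readTsv(path)
    stopifnot("feature" %in% colnames(df))
    if (anyDuplicated(df$feature)) stop("duplicate feature ids in score table")
    out <- DataFrame(df[, setdiff(colnames(df), "feature"), drop = FALSE],
                     row.names = df$feature)
    out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`. Lines with fewer than
#' three fields are an error naming the line; duplicate set names are an
#' error.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; per-set descriptions in
#'   `attr(, "description")`.
#' @export
readGmt <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 3L)
    if (length(short)) {
        stop(sprintf("GMT line %d has fewer than 3 fields (name, description, members...)",
                     short[1L]))
    }
    nm <- vapply(parts, `[[`, character(1), 1L)
    if (anyDuplicated(nm)) stop("duplicate gene set names in GMT")
    sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
    names(sets) <- nm
    attr(sets, "description") <- stats::setNames(
        vapply(parts, `[[`, character(1), 2L), nm)
    sets
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
    lines <- vapply(seq_along(sets), function(i) {
        paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read / write a ranked list in RNK format
#'
#' Two-column headerless TSV: gene symbol, signed metric. Duplicate symbols
#' are an error. The file is written in decreasing metric order (byte-stable:
#' metric ties broken by symbol).
#'
#' @param rankedList named numeric vector (see [buildRankedList()]).
#' @param path RNK file path.
#' @export
writeRnk <- function(rankedList, path) {
    .checkRankedList(rankedList)
    utils::write.table(
        data.frame(names(rankedList), .fmtNum(unname(rankedList))),
        path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeRnk
#' @export
readRnk <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, quote = "",
                            col.names = c("gene", "metric"))
    if (anyDuplicated(df$gene)) {
        stop(sprintf("duplicate symbol(s) in RNK: %s",
                     paste(utils::head(unique(df$gene[duplicated(df$gene)]), 3L),
                           collapse = ", ")))
    }
    if (!is.numeric(df$metric)) stop("RNK metric column must be numeric")
    rl <- stats::setNames(df$metric, df$gene)
    rl[order(-rl, names(rl), method = "radix")]
}

#' Read a probe-level log2-ratio track
#'
#' BED4-like TSV without header: `chrom`, `start`, `end` (0-based half-open,
#' BED convention), `log2_ratio`. Probes are validated (start < end, finite
#' ratios) and sorted by position.
#'
#' @param path track file path.
#' @return A `GRanges` with a `log2_ratio` metadata column.
#' @export
readProbeTrack <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "log2_ratio"))
    if (any(df$start >= df$end)) {
        stop(sprintf("probe with start >= end at line %d", which(df$start >= df$end)[1L]))
    }
    if (!all(is.finite(df$log2_ratio))) {
        stop(sprintf("non-finite log2 ratio at line %d", which(!is.finite(df$log2_ratio))[1L]))
    }
    gr <- GRanges(df$chrom, IRanges::IRanges(start = df$start + 1L, end = df$end))
    mcols(gr)$log2_ratio <- df$log2_ratio
    sort(gr)
}

#' Read a CpG-island BED3 file
#'
#' Islands are imported (via [rtracklayer::import()]), merged where they
#' overlap, and length-filtered.
#'
#' @param path BED3 file path.
#' @param minLength minimum island length in bp after merging.
#' @return A `GRanges` of non-overlapping islands.
#' @export
readCgiBed <- function(path, minLength = 500L) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    gr <- rtracklayer::import(path, format = "BED")
    gr <- GenomicRanges::reduce(gr)
    gr[width(gr) >= minLength]
}

#' Write a window track as BED-like TSV
#'
#' Columns: `chrom`, `start`, `end` (0-based half-open), `mean_log2`,
#' `n_probes`, `kept`.
#'
#' @param wt a [WindowTrack-class].
#' @param path output path.
#' @export
writeWindowTrack <- function(wt, path) {
    w <- windows(wt)
    utils::write.table(
        data.frame(chrom = as.character(seqnames(w)), start = start(w) - 1L,
                   end = end(w), mean_log2 = .fmtNum(w$mean_log2),
                   n_probes = w$n_probes, kept = w$kept),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write GSEA results as TSV
#'
#' Mirrors the conventional result layout: `NAME`, `SIZE`, `ES`, `NES`,
#' `P-val`, `FDR`, `LEADING_EDGE` (comma-separated).
#'
#' @param res result `DataFrame` from [gseaPreranked()].
#' @param path output path.
#' @export
writeGseaResults <- function(res, path) {
    utils::write.table(
        data.frame(NAME = res$name, SIZE = res$size, ES = .fmtNum(res$ES),
                   NES = .fmtNum(res$NES), `P-val` = .fmtNum(res$pval),
                   FDR = .fmtNum(res$padj),
                   LEADING_EDGE = vapply(res$leadingEdge, paste,
                                         character(1), collapse = ","),
                   check.names = FALSE),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
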