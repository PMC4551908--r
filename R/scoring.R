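#' Three-component decomposition of a paired design
#'
#' For each feature, the subject pairs are plotted as points
#' \eqn{p_i = (x_i, y_i)} in the early-vs-late plane. Three components
#' summarise the point cloud:
#' \describe{
#'   \item{v (variance radius)}{root-mean-square Euclidean distance of the
#'     pair points from their centroid: the inter-individual variability of
#'     the paired signal.}
#'   \item{s (signal strength)}{length of the vector from the origin to the
#'     centroid, guarding against low-intensity artifacts.}
#'   \item{t (temporal distance)}{signed perpendicular distance of the
#'     centroid from the 45-degree identity line,
#'     \eqn{t = (c_y - c_x)/\sqrt{2}}; positive means an increase with age.}
#' }
#'
#' @param pe a [PairedExperiment-class].
#' @param logTransform compute components on `log2(x + pseudocount)` when the
#'   stored scale is linear (the default working scale; log-scale inputs are
#'   used as stored).
#' @param pseudocount nonnegative value added before the log transform; must
#'   be positive when a log transform of linear data is requested.
#'
#' @return A [S4Vectors::DataFrame] with one row per feature and columns
#'   `cx`, `cy` (centroid), `v`, `s`, `t`.
#'
#' @examples
#' e <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", c("a", "b", "c")))
#' l <- matrix(c(3, 4, 5), 1, 3, dimnames = list("g1", c("a", "b", "c")))
#' pe <- PairedExperiment(e, l, ageEarly = c(40, 41, 42),
#'                        ageLate = c(55, 56, 57), scaleHint = "log")
#' computeComponents(pe, logTransform = FALSE)  # t = 2/sqrt(2), s = sqrt(20)
#' @export
computeComponents <- function(pe, logTransform = TRUE, pseudocount = 1) {
    stopifnot(is(pe, "PairedExperiment"))
    if (ncol(pe) == 0L) stop("zero pairs: at least one subject pair is required")
    ws <- .workingScale(pe, logTransform, pseudocount)
    e <- ws$early
    l <- ws$late
    cx <- unname(rowMeans(e))
    cy <- unname(rowMeans(l))
    s <- sqrt(cx^2 + cy^2)
    t <- (cy - cx) / sqrt(2)
    v <- sqrt(unname(rowMeans((e - cx)^2 + (l - cy)^2)))
    DataFrame(cx = cx, cy = cy, v = v, s = s, t = t,
              row.names = rownames(pe))
}

.workingScale <- function(pe, logTransform, pseudocount) {
    e <- earlyAssay(pe)
    l <- lateAssay(pe)
    if (logTransform && identical(scaleHint(pe), "linear")) {
        if (!is.numeric(pseudocount) || pseudocount <= 0) {
            stop("a positive pseudocount is required to log-transform linear intensities")
        }
        e <- log2(e + pseudocount)
        l <- log2(l + pseudocount)
    }
    list(early = e, late = l)
}

#' Combine the three components into a single ranking score
#'
#' Each component is ranked over all features (average ranks on ties): the
#' variance radius `v` ascending (lowest variance gets rank 1), the signal
#' strength `s` descending, and the temporal magnitude `|t|` descending. The
#' combined score is the weighted mean of the three ranks; lower scores are
#' more significant. With the default equal weights, no component is
#' privileged: when two features tie on temporal change and signal, the one
#' with lower variance scores better.
#'
#' @param cs component table from [computeComponents()].
#' @param weights nonnegative weights for (v, s, t), summing to 1.
#'
#' @return A `DataFrame` with columns `v`, `s`, `t`, `rank_v`, `rank_s`,
#'   `rank_t`, `score` and `direction` (`"up"`, `"down"`, or `"flat"` when
#'   `t` is exactly zero).
#' @export
combineScores <- function(cs, weights = c(1, 1, 1) / 3) {
    stopifnot(all(c("v", "s", "t") %in% colnames(cs)))
    if (nrow(cs) < 2L) stop("at least 2 features are required for ranking")
    if (length(weights) != 3L || any(weights < 0) ||
        abs(sum(weights) - 1) > 1e-8) {
        stop("weights must be three nonnegative values summing to 1")
    }
    rank_v <- rank(cs$v, ties.method = "average")
    rank_s <- rank(-cs$s, ties.method = "average")
    rank_t <- rank(-abs(cs$t), ties.method = "average")
    score <- weights[1L] * rank_v + weights[2L] * rank_s + weights[3L] * rank_t
    if (length(unique(score)) == 1L && nrow(cs) > 1L &&
        all(rank_v == rank_v[1L]) && all(rank_s == rank_s[1L]) &&
        all(rank_t == rank_t[1L])) {
        warning("all features are identical in all three components; scores are uninformative")
    }
    direction <- ifelse(cs$t > 0, "up", ifelse(cs$t < 0, "down", "flat"))
    DataFrame(v = cs$v, s = cs$s, t = cs$t,
              rank_v = rank_v, rank_s = rank_s, rank_t = rank_t,
              score = score, direction = direction,
              row.names = rownames(cs))
}

#' Standard-deviation selection rule
#'
#' Transforms scores into the distance from the best (minimum) score in
#' standard-deviation units, \eqn{z = (score - min) / SD}, and selects every
#' feature within `kSd` (default 1 SD; the sample SD with the n-1 denominator
#' is used). The returned table's `metadata()` carries two diagnostics: the
#' fraction of features selected, and whether the lowest-scoring 2% of
#' features fall entirely within the selection (the expected behaviour of a
#' 1-SD cutoff on genome-scale score distributions).
#'
#' @param st score table from [combineScores()].
#' @param kSd positive cutoff in SD units.
#'
#' @return `st` with columns `z_sd` and `selected` added; diagnostics in
#'   `S4Vectors::metadata()`: `fraction_selected`, `top2pct_within_cutoff`,
#'   `sd_zero`.
#' @export
sdSelect <- function(st, kSd = 1.0) {
    stopifnot("score" %in% colnames(st), kSd >= 0)
    sc <- st$score
    if (length(sc) < 2L || !all(is.finite(sc))) {
        stop("at least 2 finite scores are required")
    }
    sdev <- stats::sd(sc)
    if (sdev == 0) {
        warning("all scores identical (SD = 0): selecting every feature")
        z <- rep(0, length(sc))
    } else {
        z <- (sc - min(sc)) / sdev
    }
    out <- st
    out$z_sd <- z
    out$selected <- z <= kSd
    top2 <- sc <= stats::quantile(sc, 0.02, names = FALSE)
    S4Vectors::metadata(out) <- c(S4Vectors::metadata(st), list(
        k_sd = kSd,
        fraction_selected = mean(out$selected),
        top2pct_within_cutoff = all(out$selected[top2]),
        sd_zero = sdev == 0))
    out
}

#' Per-component contribution diagnostic
#'
#' Diagnoses which component drives a feature's combined score: ranks are
#' computed over all features (same conventions as [combineScores()]),
#' inverted (`invrank = N + 1 - rank`, so that a top-ranked component has the
#' largest inverse rank) and expressed as percentages
#' `pct_k = invrank_k / sum(invranks)`. A feature ranked identically on all
#' three components contributes exactly (1/3, 1/3, 1/3).
#'
#' @param cs component table from [computeComponents()] (or a score table;
#'   only `v`, `s`, `t` are used). Ranks are always computed over all rows.
#' @param subset feature ids to report (default all). Every id must be
#'   present in `cs`.
#' @param group optional label (e.g. `"top"`, `"random"`, `"shuffled"`)
#'   attached to the output rows for plotting grouped comparisons.
#'
#' @return A `DataFrame` with columns `pct_v`, `pct_s`, `pct_t` (rows sum to
#'   1) and `group`.
#' @export
componentContribution <- function(cs, subset = rownames(cs), group = NA_character_) {
    stopifnot(all(c("v", "s", "t") %in% colnames(cs)))
    n <- nrow(cs)
    if (n == 0L) stop("no features: contributions are undefined")
    missing <- setdiff(subset, rownames(cs))
    if (length(missing)) {
        stop(sprintf("subset feature(s) not present in the component table: %s",
                     paste(utils::head(missing, 5L), collapse = ", ")))
    }
    if (!length(subset)) stop("subset must be nonempty")
    inv_v <- n + 1 - rank(cs$v, ties.method = "average")
    inv_s <- n + 1 - rank(-cs$s, ties.method = "average")
    inv_t <- n + 1 - rank(-abs(cs$t), ties.method = "average")
    tot <- inv_v + inv_s + inv_t
    out <- DataFrame(pct_v = inv_v / tot, pct_s = inv_s / tot,
                     pct_t = inv_t / tot,
                     group = rep(group, n),
                     row.names = rownames(cs))
    out[subset, , drop = FALSE]
}

#' Shuffled control: destroy the intra-subject pairing
#'
#' Randomly permutes the 2n sample columns (n early + n late) and reassigns
#' them to n pseudo-pairs. Marginal value distributions are preserved exactly
#' (the output holds the same sample columns), but the longitudinal pairing
#' is destroyed, so consistent temporal effects vanish in expectation. Used
#' as the negative control when assessing component contributions of
#' top-scored features.
#'
#' @param pe a [PairedExperiment-class] with at least 2 pairs.
#' @param seed integer seed; the permutation is deterministic given the seed.
#'
#' @return A `PairedExperiment` of the same dimensions with permuted
#'   early/late assignments; `metadata()$shuffled` is set to `TRUE`.
#' @export
shuffledControl <- function(pe, seed) {
    stopifnot(is(pe, "PairedExperiment"))
    n <- ncol(pe)
    if (n < 2L) stop("at least 2 pairs are required to shuffle")
    pool <- cbind(earlyAssay(pe), lateAssay(pe))
    perm <- withr::with_seed(as.integer(seed), sample.int(2L * n))
    e <- pool[, perm[seq_len(n)], drop = FALSE]
    l <- pool[, perm[n + seq_len(n)], drop = FALSE]
    colnames(e) <- colnames(l) <- colnames(pe)
    out <- PairedExperiment(e, l, subject = subjectIds(pe),
                            ageEarly = ageEarly(pe), ageLate = ageLate(pe),
                            scaleHint = scaleHint(pe))
    S4Vectors::metadata(out)$shuffled <- TRUE
    out
}

#' Collapse transcript-level scores to gene symbols
#'
#' When several transcripts map to one gene symbol, a single representative is
#' kept: the transcript with the minimal combined score (`mode =
#' "min_score"`, for score-based selection) or with the largest temporal
#' magnitude `|t|` (`mode = "max_abs_t"`, for building ranked lists).
#' Criterion ties are broken by lexicographic transcript id, so the collapse
#' is deterministic. Transcripts without a mapping entry are dropped; their
#' count is reported via a message and the `"n_unmapped"` metadata entry.
#'
#' @param st score table (rownames are transcript ids) from
#'   [combineScores()] or [sdSelect()].
#' @param mapping data.frame with columns `transcript` and `gene`.
#' @param mode `"min_score"` or `"max_abs_t"`.
#'
#' @return The collapsed `DataFrame`, one row per gene symbol (rownames are
#'   gene symbols; column `transcript` records the representative).
#' @export
collapseToGenes <- function(st, mapping, mode = c("min_score", "max_abs_t")) {
    mode <- match.arg(mode)
    if (!is.data.frame(mapping) && !is(mapping, "DataFrame")) {
        stop("mapping must be a data.frame with columns 'transcript' and 'gene'")
    }
    if (nrow(mapping) == 0L) stop("empty transcript-to-gene mapping")
    stopifnot(all(c("transcript", "gene") %in% colnames(mapping)))
    tx <- rownames(st)
    idx <- match(tx, mapping$transcript)
    unmapped <- sum(is.na(idx))
    if (unmapped) {
        message(sprintf("dropping %d unmapped transcript(s)", unmapped))
    }
    keep <- !is.na(idx)
    st2 <- st[keep, , drop = FALSE]
    gene <- as.character(mapping$gene)[idx[keep]]
    crit <- switch(mode,
                   min_score = st2$score,
                   max_abs_t = -abs(st2$t))
    ord <- order(gene, crit, rownames(st2), method = "radix")
    st2 <- st2[ord, , drop = FALSE]
    gene <- gene[ord]
    first <- !duplicated(gene)
    out <- st2[first, , drop = FALSE]
    out$transcript <- rownames(out)
    rownames(out) <- gene[first]
    S4Vectors::metadata(out)$n_unmapped <- unmapped
    out
}

#' One-call scoring convenience
#'
#' Runs [computeComponents()], [combineScores()] and [sdSelect()] in
#' sequence, returning the selected score table.
#'
#' @inheritParams computeComponents
#' @inheritParams combineScores
#' @inheritParams sdSelect
#' @return see [sdSelect()].
#' @export
scorePairedExperiment <- function(pe, logTransform = TRUE, pseudocount = 1,
                                  weights = c(1, 1, 1) / 3, kSd = 1.0) {
    sdSelect(combineScores(computeComponents(pe, logTransform, pseudocount),
                           weights = weights),
             kSd = kSd)
}
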