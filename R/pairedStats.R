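#' Build the intra- vs inter-individual pairing plan
#'
#' The baseline comparison for a paired design: intra-individual changes (the
#' longitudinal pairs themselves) against a background of inter-individual
#' contrasts between different subjects of similar age. All unordered subject
#' pairs whose ages at the chosen time point differ by at most `maxAgeDiff`
#' years qualify; each inter pair is oriented older-minus-younger by exact
#' age, falling back to lexicographic subject order on exact-age ties.
#'
#' @param metadata data.frame-like with columns `subject`, `age_early`,
#'   `age_late` (one row per subject pair; `colData()` of a
#'   [PairedExperiment-class] works directly).
#' @param maxAgeDiff maximum age difference in years for an inter pair.
#' @param timepoint which samples form the inter-individual background:
#'   `"early"` (default; the cross-section uncontaminated by the second
#'   sampling), `"late"`, or `"both"` (the union of pairs qualifying at
#'   either time point, each compared at its qualifying time point).
#'
#' @return An object of class `PairingPlan`: a list with `intra` (data.frame
#'   subject/age_early/age_late) and `inter` (data.frame subject_a/subject_b/
#'   timepoint/age_a/age_b/age_diff, oriented so subject_a is the older).
#' @export
buildPairing <- function(metadata, maxAgeDiff = 2, timepoint = c("early", "late", "both")) {
    timepoint <- match.arg(timepoint)
    md <- as.data.frame(metadata)
    stopifnot(all(c("subject", "age_early", "age_late") %in% colnames(md)))
    if (nrow(md) < 2L) stop("at least 2 subjects are required")
    if (anyDuplicated(md$subject)) stop("duplicate subject ids in metadata")

    enumerate <- function(tp) {
        age <- if (tp == "early") md$age_early else md$age_late
        cmb <- utils::combn(seq_len(nrow(md)), 2L)
        keep <- abs(age[cmb[1L, ]] - age[cmb[2L, ]]) <= maxAgeDiff
        if (!any(keep)) return(NULL)
        cmb <- cmb[, keep, drop = FALSE]
        a <- cmb[1L, ]; b <- cmb[2L, ]
        # orient older minus younger; lexicographic subject order on age ties
        swap <- age[a] < age[b] |
            (age[a] == age[b] & md$subject[a] > md$subject[b])
        tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
        data.frame(subject_a = md$subject[a], subject_b = md$subject[b],
                   timepoint = tp, age_a = age[a], age_b = age[b],
                   age_diff = age[a] - age[b], stringsAsFactors = FALSE)
    }
    inter <- if (timepoint == "both") {
        rbind(enumerate("early"), enumerate("late"))
    } else {
        enumerate(timepoint)
    }
    if (is.null(inter) || nrow(inter) == 0L) {
        stop(sprintf("no inter-individual pairs within %.3g years; increase maxAgeDiff",
                     maxAgeDiff))
    }
    structure(list(intra = md[, c("subject", "age_early", "age_late")],
                   inter = inter),
              class = "PairingPlan")
}

#' @export
print.PairingPlan <- function(x, ...) {
    cat(sprintf("PairingPlan: %d intra-individual pairs, %d inter-individual pairs (%s)\n",
                nrow(x$intra), nrow(x$inter),
                paste(unique(x$inter$timepoint), collapse = "+")))
    invisible(x)
}

#' Per-feature intra- vs inter-individual change test
#'
#' For every feature, the intra-individual changes (late minus early per
#' subject, on the log scale) are compared with the inter-individual changes
#' (older minus younger between age-matched subjects at the plan's time
#' point) by a two-sample test, and Benjamini-Hochberg q-values are computed
#' across features. Features constant across all contrasts are flagged and
#' assigned p = 1 by convention.
#'
#' @param pe a [PairedExperiment-class].
#' @param plan a `PairingPlan` from [buildPairing()].
#' @param test `"wilcoxon"` (rank-sum, default) or `"welch"` (Welch t).
#' @param logTransform,pseudocount working-scale control as in
#'   [computeComponents()].
#'
#' @return A `DataFrame` with columns `statistic`, `p`, `q`, `constant`.
#' @export
intraVsInterTest <- function(pe, plan, test = c("wilcoxon", "welch"),
                             logTransform = TRUE, pseudocount = 1) {
    test <- match.arg(test)
    stopifnot(is(pe, "PairedExperiment"), inherits(plan, "PairingPlan"))
    if (nrow(plan$intra) < 2L || nrow(plan$inter) < 2L) {
        stop("the plan must contain at least 2 intra and 2 inter pairs")
    }
    ws <- .workingScale(pe, logTransform, pseudocount)
    subj <- subjectIds(pe)
    intraIdx <- match(plan$intra$subject, subj)
    if (anyNA(intraIdx)) stop("plan subjects missing from the experiment")
    intra <- ws$late[, intraIdx, drop = FALSE] - ws$early[, intraIdx, drop = FALSE]

    ia <- match(plan$inter$subject_a, subj)
    ib <- match(plan$inter$subject_b, subj)
    if (anyNA(ia) || anyNA(ib)) stop("plan subjects missing from the experiment")
    tp <- plan$inter$timepoint
    pick <- function(idx, tps) {
        m <- matrix(NA_real_, nrow(pe), length(idx))
        for (j in seq_along(idx)) {
            m[, j] <- if (tps[j] == "early") ws$early[, idx[j]] else ws$late[, idx[j]]
        }
        m
    }
    inter <- pick(ia, tp) - pick(ib, tp)

    n <- nrow(pe)
    p <- stat <- rep(NA_real_, n)
    constant <- rep(FALSE, n)
    for (i in seq_len(n)) {
        xi <- intra[i, ]; yi <- inter[i, ]
        if (length(unique(c(xi, yi))) == 1L) {
            constant[i] <- TRUE
            p[i] <- 1
            stat[i] <- NA_real_
            next
        }
        ht <- if (test == "wilcoxon") {
            suppressWarnings(stats::wilcox.test(xi, yi, exact = !anyDuplicated(c(xi, yi)) &&
                                                    (length(xi) + length(yi)) <= 25L))
        } else {
            stats::t.test(xi, yi, var.equal = FALSE)
        }
        p[i] <- ht$p.value
        stat[i] <- unname(ht$statistic)
    }
    DataFrame(statistic = stat, p = p, q = benjaminiHochberg(p),
              constant = constant, row.names = rownames(pe))
}

#' Benjamini-Hochberg step-up false discovery rate
#'
#' Validates the inputs and applies the standard step-up procedure (with
#' monotonicity enforcement) via [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return q-values in `[0, 1]`, same length and order as `pvals`.
#' @export
benjaminiHochberg <- function(pvals) {
    p <- as.numeric(pvals)
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
        stop("p-values must be finite and within [0, 1]")
    }
    stats::p.adjust(p, method = "BH")
}

#' Fisher over-representation test across annotation sets
#'
#' One-sided Fisher's exact (hypergeometric) test of whether each annotation
#' set is over-represented among the selected genes relative to the universe,
#' with Benjamini-Hochberg correction across sets. Generic plumbing for
#' set-level summaries of a selection.
#'
#' @param selected character vector of selected gene ids (must be a subset of
#'   `universe`).
#' @param universe character vector of all tested gene ids.
#' @param annotations named list of character vectors; each set is
#'   intersected with the universe before testing.
#'
#' @return A `DataFrame` with one row per set: `k` (selected in set), `K`
#'   (selected), `n` (set size in universe), `N` (universe size),
#'   `odds_ratio` (sample odds ratio), `p` (one-sided), `q` (BH).
#' @export
fisherEnrichment <- function(selected, universe, annotations) {
    universe <- unique(as.character(universe))
    selected <- unique(as.character(selected))
    if (!length(universe)) stop("empty universe")
    extra <- setdiff(selected, universe)
    if (length(extra)) {
        stop(sprintf("selected genes outside the universe: %s",
                     paste(utils::head(extra, 5L), collapse = ", ")))
    }
    if (is.null(names(annotations))) stop("annotations must be a named list")
    N <- length(universe)
    K <- length(selected)
    res <- lapply(annotations, function(set) {
        setU <- intersect(unique(as.character(set)), universe)
        n <- length(setU)
        k <- length(intersect(setU, selected))
        p <- stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE)
        or <- (k * (N - n - K + k)) / ((K - k) * (n - k))
        c(k = k, n = n, odds_ratio = or, p = p)
    })
    m <- do.call(rbind, res)
    DataFrame(k = as.integer(m[, "k"]), K = K, n = as.integer(m[, "n"]), N = N,
              odds_ratio = m[, "odds_ratio"], p = m[, "p"],
              q = benjaminiHochberg(m[, "p"]),
              row.names = names(annotations))
}
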