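test_that("window binning matches hand enumeration", {
    # midpoints 100,200,300,400,600: [0,500) holds 4 probes, [250,750) holds 3
    gr <- probesAt(c(100, 200, 300, 400, 600), c(1, 2, 3, 4, 10))
    wt <- binProbes(gr, window = 500, step = 250, minProbes = 4)
    w <- windows(wt)
    expect_identical(BiocGenerics::start(w)[1:2] - 1L, c(0L, 250L))
    expect_equal(w$mean_log2[1], 2.5, tolerance = 1e-15)
    expect_equal(w$mean_log2[2], mean(c(3, 4, 10)), tolerance = 1e-15)
    expect_identical(w$n_probes[1:2], c(4L, 3L))
    expect_identical(w$kept[1:2], c(TRUE, FALSE))

    # a 3-probe window is below the 4-probe minimum
    wt3 <- binProbes(probesAt(c(100, 200, 300), c(1, 1, 1)), 500, 250, 4)
    expect_false(windows(wt3)$kept[1])

    # 4 probes of ratio 1: mean 1, kept
    wt4 <- binProbes(probesAt(c(50, 150, 250, 350), rep(1, 4)), 500, 250, 4)
    expect_identical(windows(wt4)$mean_log2[1], 1)
    expect_true(windows(wt4)$kept[1])

    expect_error(binProbes(gr, window = 200, step = 300), "step size")
})

test_that("probe-window membership matches a brute-force scan", {
    for (seed in 1:20) {
        dat <- withr::with_seed(seed, {
            n <- sample(20:80, 1)
            list(mid = sort(sample(seq(25, 6000, by = 5), n)),
                 val = rnorm(n))
        })
        wt <- binProbes(probesAt(dat$mid, dat$val), 500, 250, 4)
        ora <- oracleBinScan(dat$mid, dat$val, 500, 250)
        w <- windows(wt)
        expect_identical(length(w), length(ora))
        expect_identical(BiocGenerics::start(w) - 1L,
                         vapply(ora, function(x) as.integer(x$start), 1L))
        expect_identical(w$n_probes, vapply(ora, function(x) as.integer(x$n), 1L))
        expect_equal(w$mean_log2, vapply(ora, `[[`, numeric(1), "mean"),
                     tolerance = 1e-12)
        # each probe joins at most ceiling(window/step) windows
        expect_lte(sum(w$n_probes), length(dat$mid) * ceiling(500 / 250))
    }
})

test_that("window means ignore probe input order", {
    mid <- c(100, 200, 300, 400, 600, 700)
    val <- c(0.3, -1, 2, 0.1, 5, -2)
    perm <- withr::with_seed(8, sample(6))
    a <- binProbes(probesAt(mid, val), 500, 250, 4)
    b <- binProbes(probesAt(mid[perm], val[perm]), 500, 250, 4)
    expect_equal(windows(a)$mean_log2, windows(b)$mean_log2, tolerance = 1e-15)
    expect_identical(windows(a)$n_probes, windows(b)$n_probes)
})

test_that("the quantile floor resets, discards and is idempotent", {
    # ratios {-2,-1,0,1,2} in one window of 5: floor 0, floored mean 0.6, kept
    wt <- binProbes(probesAt(c(50, 150, 250, 350, 450), c(-2, -1, 0, 1, 2)),
                    500, 500, 4)
    fl <- quantileFloor(wt, 0.5)
    expect_identical(floorValue(fl), 0)
    expect_equal(windows(fl)$mean_log2[1], 0.6, tolerance = 1e-15)
    expect_identical(windows(fl)$n_above[1], 2L)
    expect_true(windows(fl)$kept[1])

    # all ratios equal: floor equals them, nothing strictly above, all discarded
    wtEq <- binProbes(probesAt(c(50, 150, 250, 350), rep(1.5, 4)), 500, 500, 4)
    expect_false(any(windows(quantileFloor(wtEq))$kept))

    # exactly one probe above the floor: discarded
    wt1 <- binProbes(probesAt(c(50, 150, 250, 350, 450), c(-1, -1, -1, -1, 9)),
                     500, 500, 4)
    fl1 <- quantileFloor(wt1)
    expect_identical(windows(fl1)$n_above[1], 1L)
    expect_false(windows(fl1)$kept[1])

    # idempotence on a random track
    rnd <- withr::with_seed(21, binProbes(
        probesAt(sort(sample(seq(25, 8000, 10), 60)), rnorm(60)), 500, 250, 4))
    once <- quantileFloor(rnd, 0.5)
    twice <- quantileFloor(once, 0.5)
    expect_identical(floorValue(twice), floorValue(once))
    expect_equal(windows(twice)$mean_log2, windows(once)$mean_log2,
                 tolerance = 1e-15)
    expect_identical(windows(twice)$kept, windows(once)$kept)
})

test_that("CGI distance partition assigns strata by the closer boundary", {
    cgis <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        start = c(101, 5001), end = c(900, 6000)))   # 0-based [100,900), [5000,6000)

    mk <- function(start0, end0, v) {
        g <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(start = start0 + 1, end = end0))
        S4Vectors::mcols(g)$v <- v
        g
    }
    # window inside a CGI -> stratum "CGI"
    res <- cgiDistancePartition(mk(200, 700, 1), cgis, maxDist = 3000, bin = 250)
    expect_identical(res$assignment$bin, "CGI")
    expect_identical(res$assignment$distance, 0L)

    # window [1000,1500) with nearest CGI ending at 900 -> distance 100, [0,250)
    res <- cgiDistancePartition(mk(1000, 1500, 1), cgis, 3000, 250)
    expect_identical(res$assignment$distance, 100L)
    expect_identical(res$assignment$bin, "[0,250)")

    # flanking CGIs 400 bp left / 300 bp right -> the closer (right) wins: 300
    # left CGI ends at 900 (0-based); window [1300,1700); right CGI at [2000,...)
    cgis2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        start = c(101, 2001), end = c(900, 2600)))
    res <- cgiDistancePartition(mk(1300, 1700, 1), cgis2, 3000, 250)
    expect_identical(res$assignment$distance, 300L)
    expect_identical(res$assignment$bin, "[250,500)")

    # chromosome without CGIs is excluded with a message
    far <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 500))
    S4Vectors::mcols(far)$v <- 2
    expect_message(
        expect_error(cgiDistancePartition(far, cgis, 3000, 250), "no windows"),
        "without CpG islands")
})

test_that("distance strata tile without overlap and cover every kept window", {
    cgis <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = 10001, end = 12000))
    starts0 <- seq(0, 30000, by = 500)
    g <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = starts0 + 1, width = 500))
    S4Vectors::mcols(g)$v <- withr::with_seed(4, runif(length(g)))
    res <- suppressMessages(cgiDistancePartition(g, cgis, maxDist = 3000, bin = 250))
    # each retained window lands in exactly one stratum
    expect_false(anyNA(res$assignment$bin))
    shore <- res$summary[res$summary$bin != "CGI", ]
    lo <- shore$dist_lo; hi <- shore$dist_hi
    expect_true(all(hi - lo == 250))
    expect_true(all(lo == sort(lo)))
    expect_identical(anyDuplicated(lo), 0L)
    expect_true(all(hi <= 3000))
    # stratum counts add up to the retained windows
    expect_identical(sum(res$summary$n_windows), length(res$assignment))
})

test_that("quantile normalisation equalises column distributions", {
    m <- withr::with_seed(9, cbind(rnorm(200, 0, 1), rnorm(200, 3, 2)))
    qn <- quantileNormalize(m)
    expect_equal(sort(qn[, 1]), sort(qn[, 2]), tolerance = 1e-12)
})
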