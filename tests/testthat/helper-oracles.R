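# Independent brute-force oracles: explicit loops, no shared code with R/.

# average rank (ties) without rank()
oracleRank <- function(x) {
    vapply(seq_along(x), function(i) {
        sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
    }, numeric(1))
}

oracleComponents <- function(e, l) {
    out <- data.frame(cx = numeric(nrow(e)), cy = 0, v = 0, s = 0, t = 0)
    for (i in seq_len(nrow(e))) {
        xs <- e[i, ]; ys <- l[i, ]
        cx <- sum(xs) / length(xs)
        cy <- sum(ys) / length(ys)
        d2 <- 0
        for (j in seq_along(xs)) d2 <- d2 + (xs[j] - cx)^2 + (ys[j] - cy)^2
        out$cx[i] <- cx; out$cy[i] <- cy
        out$v[i] <- sqrt(d2 / length(xs))
        out$s[i] <- sqrt(cx^2 + cy^2)
        out$t[i] <- (cy - cx) / sqrt(2)
    }
    out
}

oracleCombine <- function(v, s, t, w = c(1, 1, 1) / 3) {
    rv <- oracleRank(v)
    rs <- oracleRank(-s)
    rt <- oracleRank(-abs(t))
    w[1] * rv + w[2] * rs + w[3] * rt
}

oracleES <- function(metrics, isHit, p = 1) {
    N <- length(metrics)
    nh <- sum(isHit)
    NR <- 0
    for (i in seq_len(N)) if (isHit[i]) NR <- NR + abs(metrics[i])^p
    run <- 0; hi <- 0; lo <- 0
    for (i in seq_len(N)) {
        run <- if (isHit[i]) run + abs(metrics[i])^p / NR else run - 1 / (N - nh)
        if (run > hi) hi <- run
        if (run < lo) lo <- run
    }
    if (abs(hi + lo) <= 1e-12 * max(abs(hi), abs(lo), 1e-300)) 0
    else if (hi > -lo) hi else lo
}

oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    prev <- 1
    for (i in m:1) {
        val <- min(prev, p[o[i]] * m / i)
        q[o[i]] <- val
        prev <- val
    }
    q
}

# one-sided upper hypergeometric tail by explicit summation
oracleHyperP <- function(k, K, n, N) {
    tot <- 0
    for (x in k:min(n, K)) {
        tot <- tot + choose(n, x) * choose(N - n, K - x) / choose(N, K)
    }
    tot
}

# brute-force sliding-window scan over probe midpoints (0-based half-open)
oracleBinScan <- function(mid, val, window, step) {
    maxJ <- floor(max(mid) / step)
    res <- list()
    for (j in 0:maxJ) {
        lo <- j * step; hi <- lo + window
        inWin <- mid >= lo & mid < hi
        if (any(inWin)) {
            res[[length(res) + 1]] <- list(start = lo, n = sum(inWin),
                                           mean = mean(val[inWin]))
        }
    }
    res
}
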