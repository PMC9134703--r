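# Independent reference implementations used to cross-check the package.
# Each is a direct transcription of the defining formula, kept deliberately
# naive (loops, grids, enumeration).

# weight-by-dosage score, one individual at a time
oraclePhs <- function(dosages, weights) {
    ids <- names(weights)
    out <- numeric(ncol(dosages))
    for (i in seq_len(ncol(dosages))) {
        s <- 0
        for (id in ids) s <- s + weights[[id]] * dosages[id, i]
        out[i] <- s
    }
    names(out) <- colnames(dosages)
    out
}

# normal-equations least squares
oracleOls <- function(X, y) drop(solve(t(X) %*% X, t(X) %*% y))

# Benjamini-Hochberg by hand: p(i) * m / i then cumulative minimum
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
}

# Cox partial log-likelihood, no ties assumed
oracleCoxLoglik <- function(beta, X, time, event) {
    X <- as.matrix(X)
    eta <- drop(X %*% beta)
    ll <- 0
    for (i in which(event == 1)) {
        atRisk <- time >= time[i]
        ll <- ll + eta[i] - log(sum(exp(eta[atRisk])))
    }
    ll
}

# one-covariate partial-likelihood maximiser by grid search
oracleCoxGrid <- function(x, time, event, lo = -5, hi = 5, step = 1e-4) {
    grid <- seq(lo, hi, by = step)
    ll <- vapply(grid, function(b)
        oracleCoxLoglik(b, matrix(x, ncol = 1), time, event), 0)
    grid[which.max(ll)]
}

# greedy forward selection scored by brute-force partial likelihood
# (each candidate model maximised with optim), mirroring the defined
# selection rule but sharing no code with the implementation
oracleForwardStep <- function(candidates, dosages, time, event,
                              forced, alphaEntry, maxSnps) {
    fitLl <- function(vars) {
        X <- t(dosages[vars, , drop = FALSE])
        op <- stats::optim(rep(0, length(vars)),
                           function(b) -oracleCoxLoglik(b, X, time, event),
                           method = "BFGS")
        -op$value
    }
    selected <- character()
    llCur <- fitLl(forced)
    remaining <- candidates
    while (length(selected) < maxSnps && length(remaining)) {
        lls <- vapply(remaining, function(cd)
            fitLl(c(forced, selected, cd)), 0)
        best <- which.max(lls)
        p <- pchisq(2 * (lls[best] - llCur), 1, lower.tail = FALSE)
        if (!(p < alphaEntry)) break
        selected <- c(selected, remaining[best])
        remaining <- remaining[-best]
        llCur <- lls[best]
    }
    selected
}

# empirical survival function (no censoring)
oracleEmpiricalSurv <- function(times, at) {
    vapply(at, function(a) mean(times > a), 0)
}

# logistic scan series at common scan ages: individuals differ in onset,
# so mean levels spread across the whole Centiloid range
makeLogisticSeries <- function(onsets, scanAges, k = 0.15, thr = 20,
                               ceiling = 100, noiseSd = 0) {
    shift <- log(ceiling / thr - 1) / k
    do.call(rbind, lapply(seq_along(onsets), function(i) {
        cl <- ceiling * plogis(k * (scanAges - onsets[i] - shift)) +
            rnorm(length(scanAges), 0, noiseSd)
        data.frame(participant_id = sprintf("S%03d", i),
                   scan_age = scanAges,
                   centiloid = cl, stringsAsFactors = FALSE)
    }))
}
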