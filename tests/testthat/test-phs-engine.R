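test_that("candidate filtering is a strict p-value screen", {
    ss <- data.frame(snp_id = sprintf("rs%d", 1:10),
                     effect_allele = "A",
                     or = 1.1,
                     p = c(rep(1e-6, 4), rep(0.5, 6)))
    expect_identical(filterCandidateSnps(ss), sprintf("rs%d", 1:4))
    ss$p <- 0.5
    expect_identical(filterCandidateSnps(ss), character(0))
    # boundary: p exactly at the threshold is excluded
    ss$p[1] <- 1e-5
    expect_identical(filterCandidateSnps(ss, 1e-5), character(0))
    expect_identical(filterCandidateSnps(ss[0, ]), character(0))
    ss$p[3] <- -1
    expect_error(filterCandidateSnps(ss), "row.*3")
})

test_that("the score is the weight-by-dosage sum", {
    pan <- new("SnpPanel", panel = S4Vectors::DataFrame(
        id = c("a", "b", "c"), effectAllele = c("A", "C", "G"),
        weight = c(0.1, -0.2, 5.0), forced = rep(FALSE, 3)))
    d <- rbind(a = c(1, 0), b = c(2, 0), c = c(0, 0))
    colnames(d) <- c("s1", "s2")
    sc <- phsScores(computePhs(d, pan))
    expect_equal(unname(sc["s1"]), -0.3)
    expect_equal(unname(sc["s2"]), 0)
    # permuting variant rows leaves scores unchanged
    expect_equal(phsScores(computePhs(d[c(3, 1, 2), ], pan)), sc)
    # oracle: per-individual loop, machine precision
    set.seed(41)
    D <- matrix(sample(0:2, 50 * 3, TRUE), nrow = 3,
                dimnames = list(c("a", "b", "c"), sprintf("i%02d", 1:50)))
    expect_equal(phsScores(computePhs(D, pan)),
                 oraclePhs(D, panelWeights(pan)), tolerance = 1e-15)
    expect_error(computePhs(d[1:2, ], pan), "missing.*c")
    d[1, 1] <- NA
    expect_error(computePhs(d, pan), "missing dosage")
})

test_that("stratification uses mean +/- 1 SD or explicit cutpoints", {
    r <- stratifyPhs(c(1.2, -1.0, 0), thresholds = c(-0.67, 1.04))
    expect_equal(as.character(phsStrata(r)), c("high", "low", "mid"))
    set.seed(42)
    g <- stratifyPhs(rnorm(100000))
    frac <- mean(phsStrata(g) == "high") * 100
    expect_lt(abs(frac - 15.87), 0.5)
    allEq <- stratifyPhs(rep(2, 5), thresholds = c(-1, 3))
    expect_true(all(phsStrata(allEq) == "mid"))
    expect_error(stratifyPhs(rep(2, 5)), "distinct")
})

test_that("dosages are flipped to the panel's effect allele, strand never
           inferred", {
    pan <- new("SnpPanel", panel = S4Vectors::DataFrame(
        id = c("a", "b"), effectAllele = c("A", "C"),
        weight = c(1, 1), forced = c(FALSE, FALSE)))
    d <- rbind(a = c(0, 1, 2), b = c(2, 2, 0))
    colnames(d) <- paste0("s", 1:3)
    al <- data.frame(id = c("a", "b"), countedAllele = c("G", "C"),
                     otherAllele = c("A", "T"))
    flipped <- alignDosages(d, al, pan)
    expect_equal(unname(flipped["a", ]), c(2, 1, 0))
    expect_equal(unname(flipped["b", ]), c(2, 2, 0))
    alPalin <- data.frame(id = c("a", "b"), countedAllele = c("T", "C"),
                          otherAllele = c("A", "T"))
    expect_error(alignDosages(d, alPalin, pan), "palindromic")
    alBad <- data.frame(id = c("a", "b"), countedAllele = c("G", "C"),
                        otherAllele = c("C", "T"))
    expect_error(alignDosages(d, alBad, pan), "neither")
})

test_that("forward stepwise selection favours the truly associated variant
           and matches a brute-force oracle on tiny problems", {
    bh <- c(rate = 3e-6, shape = 0.14)
    # power: a single real effect enters first
    set.seed(51)
    hits <- replicate(25, {
        n <- 1000
        D <- matrix(rbinom(5 * n, 2, 0.3), nrow = 5,
                    dimnames = list(c(sprintf("rs%d", 1:4), "APOE_e4"),
                                    sprintf("i%04d", 1:n)))
        sc <- 1.0 * D["rs1", ] + 0.8 * D["APOE_e4", ]
        on <- generateOnsets(sc - mean(sc), bh)
        surv <- data.frame(time = on, event = 1L)
        pan <- suppressWarnings(forwardStepwiseCox(
            sprintf("rs%d", 1:4), D, surv, forced = "APOE_e4",
            alphaEntry = 0.05, maxSnps = 2))
        setdiff(snpIds(pan), "APOE_e4")[1]
    })
    expect_gte(mean(hits == "rs1"), 0.9)
    # null candidates at a stringent entry threshold: nothing selected
    set.seed(52)
    D <- matrix(rbinom(6 * 500, 2, 0.3), nrow = 6,
                dimnames = list(c(sprintf("rs%d", 1:5), "APOE_e4"),
                                sprintf("i%03d", 1:500)))
    on <- generateOnsets(0.5 * D["APOE_e4", ] - 0.3, bh)
    surv <- data.frame(time = on, event = 1L)
    panNull <- suppressWarnings(forwardStepwiseCox(
        sprintf("rs%d", 1:5), D, surv, forced = "APOE_e4",
        alphaEntry = 1e-4, maxSnps = 31))
    expect_identical(snpIds(panNull), "APOE_e4")
    # cap: maxSnps = 0 keeps only the forced variants
    pan0 <- forwardStepwiseCox(sprintf("rs%d", 1:5), D, surv,
                               forced = "APOE_e4", maxSnps = 0)
    expect_identical(snpIds(pan0), "APOE_e4")
    expect_true(all(panelTable(pan0)$forced))
    # oracle: greedy selection by brute-force partial likelihood agrees
    # on tiny problems (8 subjects, 3 candidates); draws where the
    # forced model itself separates are regenerated
    compared <- 0
    for (sd in 531:560) {
        set.seed(sd)
        n <- 8
        D8 <- matrix(rbinom(4 * n, 2, 0.5), nrow = 4,
                     dimnames = list(c("c1", "c2", "c3", "apoe"),
                                     sprintf("i%d", 1:n)))
        tm <- sort(rexp(n, 0.1) + 1) + runif(n, 0, 1e-3)  # no ties
        ev <- c(rep(1L, 6), rbinom(2, 1, 0.5))  # some censoring
        surv8 <- data.frame(time = tm, event = ev)
        # draws where any tiny Cox fit separates are regenerated: the
        # brute-force oracle has no notion of a diverging fit
        notes <- character()
        pan8 <- tryCatch(
            withCallingHandlers(
                forwardStepwiseCox(c("c1", "c2", "c3"), D8, surv8,
                                   forced = "apoe", alphaEntry = 0.25,
                                   maxSnps = 3),
                warning = function(w) {
                    notes <<- c(notes, conditionMessage(w))
                    invokeRestart("muffleWarning")
                }),
            error = function(e) NULL)
        if (is.null(pan8) || length(notes)) next
        if (any(abs(panelTable(pan8)$weight) > 5)) next
        sel <- setdiff(snpIds(pan8), "apoe")
        ref <- oracleForwardStep(c("c1", "c2", "c3"), D8, tm, ev,
                                 "apoe", 0.25, 3)
        expect_identical(sel, ref)
        compared <- compared + 1
        if (compared >= 5) break
    }
    expect_gte(compared, 3)
})

test_that("panel weights reproduce the generative log-hazard scale", {
    # Cox regression of simulated onsets on the computed score has
    # coefficient 1 (the score is a log relative hazard)
    set.seed(55)
    n <- 1500
    covered <- replicate(10, {
        D <- matrix(rbinom(3 * n, 2, 0.3), nrow = 3,
                    dimnames = list(c("a", "b", "c"), sprintf("i%04d", 1:n)))
        pan <- new("SnpPanel", panel = S4Vectors::DataFrame(
            id = c("a", "b", "c"), effectAllele = NA_character_,
            weight = c(0.4, -0.3, 0.6), forced = rep(FALSE, 3)))
        sc <- phsScores(computePhs(D, pan))
        on <- generateOnsets(sc - mean(sc), c(rate = 3e-6, shape = 0.14))
        ci <- confint(survival::coxph(
            survival::Surv(on, rep(1, n)) ~ sc))
        ci[1] < 1 && 1 < ci[2]
    })
    expect_gte(sum(covered), 8)
})

test_that("the hazard curve is proportional in the score", {
    bh <- c(rate = 1e-4, shape = 0.1)
    h0 <- hazardCurve(0, bh)
    ages <- seq(50, 95, by = 0.5)
    expect_equal(h0(ages), bh[["rate"]] * exp(bh[["shape"]] * ages))
    h2 <- hazardCurve(log(2), bh)
    expect_equal(h2(ages) / h0(ages), rep(2, length(ages)))
    H <- cumsum(h0(ages)) * 0.5
    expect_true(all(diff(H) >= 0))
})
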