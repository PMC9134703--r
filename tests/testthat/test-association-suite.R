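test_that("cross-sectional OLS recovers exact and noisy effects", {
    set.seed(81)
    n <- 120
    d <- data.frame(phs = rnorm(n), age = rnorm(n, 73, 6),
                    sex = rbinom(n, 1, 0.5),
                    education = rnorm(n, 13, 3), apoe = rbinom(n, 1, 0.35))
    d$cl_neocortex <- 2 * d$phs + 0.5 * d$age  # zero noise
    res <- suppressWarnings(fitCrossSectional(d, "cl_neocortex"))
    expect_equal(res$beta[res$term == "phs"], 2, tolerance = 1e-12)
    # 12-row fixture against the normal equations
    set.seed(82)
    f <- data.frame(phs = rnorm(12), age = rnorm(12, 70, 5),
                    sex = rbinom(12, 1, 0.5), education = rnorm(12, 12, 2),
                    apoe = rbinom(12, 1, 0.4))
    f$cl_neocortex <- 5 + 3 * f$phs + rnorm(12, 0, 4)
    res12 <- fitCrossSectional(f, "cl_neocortex")
    X <- cbind(1, f$phs, f$age, f$sex, f$education, f$apoe)
    ref <- oracleOls(X, f$cl_neocortex)
    expect_equal(res12$beta, unname(ref), tolerance = 1e-8)
    # collinear design is refused by name
    d$age2 <- d$age
    expect_error(suppressWarnings(
        fitCrossSectional(d, "cl_neocortex",
                          covariates = c("age", "age2"))),
        "collinear.*age2")
    # carrier subgroup drops the APOE covariate
    resC <- suppressWarnings(
        fitCrossSectional(d, "cl_neocortex", subgroup = "e4_carriers"))
    expect_false("apoe" %in% resC$term)
    expect_equal(unique(resC$n), sum(d$apoe == 1))
})

test_that("FDR adjustment matches the step-up definition", {
    expect_equal(fdrAdjust(0.03), 0.03)
    expect_equal(fdrAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(fdrAdjust(rep(1, 5)), rep(1, 5))
    set.seed(83)
    p <- runif(20)
    expect_equal(fdrAdjust(p), oracleBH(p))
    expect_true(all(fdrAdjust(p) >= p))
    o <- sample(20)
    expect_equal(fdrAdjust(p[o]), fdrAdjust(p)[o])
    expect_error(fdrAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("likelihood-ratio tests compare nested maximum-likelihood fits", {
    set.seed(84)
    d <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
    d$y <- 1 + d$x1 + rnorm(40)
    full <- lm(y ~ x1 + x2, d)
    same <- likelihoodRatioTest(full, full)
    expect_equal(same$statistic, 0)
    expect_equal(same$p, 1)
    red <- lm(y ~ x1, d)
    out <- likelihoodRatioTest(full, red)
    expect_equal(out$df, 1)
    expect_equal(out$statistic,
                 2 * (as.numeric(logLik(full)) - as.numeric(logLik(red))))
    expect_error(likelihoodRatioTest(red, full), "more parameters")
    expect_error(likelihoodRatioTest(full, lm(y ~ x1, d[1:30, ])),
                 "different numbers of rows")
})

test_that("the longitudinal mixed model is exact in the noiseless limit
           and matches OLS when the random intercept vanishes", {
    # deterministic data: every beta recovered to numerical precision
    n <- 30
    d <- expand.grid(participant_id = sprintf("p%02d", 1:n),
                     time = c(0, 1.5, 3), KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
    set.seed(85)
    cov1 <- data.frame(participant_id = sprintf("p%02d", 1:n),
                       phs = rnorm(n), apoe = rbinom(n, 1, 0.4))
    d <- merge(d, cov1)
    d$value <- 2 + 0.5 * d$phs * d$time - 0.3 * d$apoe * d$time
    fit <- suppressWarnings(fitLongitudinal(d, terms = c("phs", "apoe"),
                                            scaleVars = character(0)))
    b <- setNames(fit$table$beta, fit$table$term)
    expect_equal(unname(b["phs:time"]), 0.5, tolerance = 1e-8)
    expect_equal(unname(b["time:apoe"]), -0.3, tolerance = 1e-8)
    expect_equal(unname(b["(Intercept)"]), 2, tolerance = 1e-8)
    expect_equal(fit$n, nrow(d))
    # boundary (zero) random-intercept variance degenerates to OLS:
    # residuals with negative within-participant correlation force the
    # variance estimate to the boundary
    nB <- 40
    e <- rnorm(nB)
    dB <- data.frame(participant_id = rep(sprintf("q%02d", 1:nB),
                                          each = 2),
                     time = rep(c(0, 1.5), nB),
                     phs = rep(rnorm(nB), each = 2))
    dB$value <- 0.2 * dB$phs * dB$time + as.vector(rbind(e, -e))
    expect_warning(
        fitB <- fitLongitudinal(dB, terms = "phs",
                                scaleVars = character(0)),
        "degenerating to OLS")
    expect_true(fitB$olsFallback)
    olsB <- lm(value ~ phs:time, dB)
    expect_equal(fitB$table$beta[fitB$table$term == "phs:time"],
                 unname(coef(olsB)["phs:time"]), tolerance = 1e-8)
    expect_error(fitLongitudinal(d[, c("participant_id", "value")],
                                 terms = "phs"), "lacks column")
})

test_that("standardised betas are invariant to affine covariate changes", {
    set.seed(86)
    n <- 60
    d <- expand.grid(participant_id = sprintf("p%02d", 1:n),
                     time = c(0, 1.5, 3), stringsAsFactors = FALSE)
    cov1 <- data.frame(participant_id = sprintf("p%02d", 1:n),
                       phs = rnorm(n))
    d <- merge(d, cov1)
    d$value <- 0.2 * d$phs * d$time + rnorm(n)[match(d$participant_id,
                                                     cov1$participant_id)] +
        rnorm(nrow(d), 0, 0.2)
    f1 <- fitLongitudinal(d, terms = "phs", scaleVars = "phs")
    d2 <- d
    d2$phs <- 10 * d2$phs + 3
    f2 <- fitLongitudinal(d2, terms = "phs", scaleVars = "phs")
    expect_equal(f1$table$beta, f2$table$beta, tolerance = 1e-6)
})

test_that("simple-effect slopes are linear in the interaction", {
    set.seed(87)
    n <- 50
    d <- expand.grid(participant_id = sprintf("p%02d", 1:n),
                     time = c(0, 1.5, 3), stringsAsFactors = FALSE)
    cov1 <- data.frame(participant_id = sprintf("p%02d", 1:n),
                       phs = rnorm(n))
    d <- merge(d, cov1)
    d$value <- -0.1 * d$phs * d$time +
        rnorm(n, 0, 0.5)[match(d$participant_id, cov1$participant_id)] +
        rnorm(nrow(d), 0, 0.2)
    fit <- fitLongitudinal(d, terms = "phs", scaleVars = character(0))
    sl <- simpleEffectSlopes(fit)
    b1 <- fit$table$beta[fit$table$term == "phs:time"]
    expect_equal(sl$slope[sl$contrast == "difference"], 2 * b1)
    expect_equal(sl$slope[1], -b1)
    expect_equal(sl$slope[2], b1)
    # beta1 = 0 gives identical slopes at both levels
    d0 <- d
    d0$value <- rnorm(nrow(d0))
    fit0 <- suppressWarnings(fitLongitudinal(d0, terms = "phs",
                                             scaleVars = character(0)))
    sl0 <- simpleEffectSlopes(fit0)
    expect_equal(sl0$slope[1], -sl0$slope[2])
    # stratified-refit oracle: slopes at fixed score levels match models
    # refitted on noiseless strata generated at those levels
    dS <- expand.grid(participant_id = sprintf("q%02d", 1:40),
                      time = c(0, 1.5, 3), stringsAsFactors = FALSE)
    covS <- data.frame(participant_id = sprintf("q%02d", 1:40),
                       phs = rep(c(-1, 1), each = 20))
    dS <- merge(dS, covS)
    dS$value <- (0.05 - 0.1 * dS$phs) * dS$time
    fitS <- suppressWarnings(fitLongitudinal(dS, terms = "phs",
                                             timeMainEffect = TRUE,
                                             scaleVars = character(0)))
    slS <- simpleEffectSlopes(fitS)
    for (lv in c(-1, 1)) {
        ref <- coef(lm(value ~ time, dS[dS$phs == lv, ]))["time"]
        expect_equal(slS$slope[which(slS$level == lv)], unname(ref),
                     tolerance = 1e-8)
    }
    dS$other <- rbinom(nrow(dS), 1, 0.5)
    noPhs <- suppressWarnings(fitLongitudinal(dS, terms = "other",
                                              scaleVars = character(0)))
    expect_error(simpleEffectSlopes(noPhs), "PHS-by-time")
})

test_that("backward AIC selection is deterministic and keeps real effects", {
    set.seed(88)
    n <- 120
    mk <- function() {
        d <- expand.grid(participant_id = sprintf("p%03d", 1:n),
                         time = c(0, 1.5, 3, 4.5), stringsAsFactors = FALSE)
        cov1 <- data.frame(participant_id = sprintf("p%03d", 1:n),
                           phs = rnorm(n), sex = rbinom(n, 1, 0.5),
                           apoe = rbinom(n, 1, 0.35))
        d <- merge(d, cov1)
        u <- rnorm(n, 0, 0.3)
        d$value <- 0.4 * d$phs * d$time +
            u[match(d$participant_id, cov1$participant_id)] +
            rnorm(nrow(d), 0, 0.3)
        d
    }
    keep <- replicate(10, {
        d <- mk()
        sel <- suppressWarnings(backwardSelectAic(
            d, terms = c("phs", "sex", "apoe")))
        "phs" %in% sel$terms
    })
    expect_gte(mean(keep), 0.9)
    d <- mk()
    s1 <- suppressWarnings(backwardSelectAic(d, terms = c("phs", "sex",
                                                          "apoe")))
    s2 <- suppressWarnings(backwardSelectAic(d, terms = c("phs", "sex",
                                                          "apoe")))
    expect_identical(s1$terms, s2$terms)
})

test_that("the atrophy panel fits one model per ROI with family FDR", {
    set.seed(89)
    n <- 80
    vis <- expand.grid(participant_id = sprintf("p%03d", 1:n),
                       visit_age = c(70, 71.5, 73), stringsAsFactors = FALSE)
    covd <- data.frame(participant_id = sprintf("p%03d", 1:n),
                       phs = rnorm(n), sex = rbinom(n, 1, 0.5),
                       education = rnorm(n, 13, 3),
                       apoe = rbinom(n, 1, 0.35))
    mkRoi <- function(roi, slope) {
        u <- rnorm(n, 0, 0.02)
        i <- match(vis$participant_id, covd$participant_id)
        data.frame(participant_id = vis$participant_id,
                   visit_age = vis$visit_age, roi = roi,
                   volume = 1 + u[i] + slope * covd$phs[i] *
                       (vis$visit_age - 70) +
                       rnorm(nrow(vis), 0, 0.01))
    }
    vols <- rbind(mkRoi("entorhinal", -0.01), mkRoi("precuneus", 0))
    res <- suppressWarnings(runAtrophyPanel(vols, covd))
    expect_equal(nrow(res), 2)
    expect_true(all(res$p_fdr >= res$p))
    expect_lt(res$p[res$roi == "entorhinal"], 0.01)
    # identical data in two ROIs give identical results
    vols2 <- rbind(mkRoi("a", -0.005), vols[vols$roi == "entorhinal", ])
    vols2$roi[vols2$roi == "a"] <- "copy"
    dup <- vols[vols$roi == "entorhinal", ]
    dup$roi <- "dup"
    vols3 <- rbind(vols[vols$roi == "entorhinal", ], dup)
    res3 <- suppressWarnings(runAtrophyPanel(vols3, covd))
    expect_equal(res3$beta[1], res3$beta[2])
    expect_equal(res3$p[1], res3$p[2])
    expect_warning(runAtrophyPanel(vols, covd, rois = c("entorhinal",
                                                        "missing_roi")),
                   "skipped.*missing_roi")
})
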