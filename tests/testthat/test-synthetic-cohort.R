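test_that("genotype generator respects binomial moments and determinism", {
    cfg <- simulationConfig(nParticipants = 10000, nSnps = 4,
                            alleleFreqRange = c(0.3, 0.3),
                            trueBetas = rep(0, 4), seed = 5)
    se <- generateGenotypes(cfg)
    dos <- SummarizedExperiment::assay(se, "dosage")
    expect_true(all(dos %in% 0:2))
    # mean dosage of a Binomial(2, 0.3) variant is 0.6
    sem <- sqrt(2 * 0.3 * 0.7 / 10000)
    for (i in 1:4)
        expect_lt(abs(mean(dos[i, ]) - 0.6), 3 * sem)
    se2 <- generateGenotypes(cfg)
    expect_identical(dos, SummarizedExperiment::assay(se2, "dosage"))
    expect_error(simulationConfig(nParticipants = 0), "positive")
    expect_error(simulationConfig(alleleFreqRange = c(0, 0.5)), "0, 1")
})

test_that("onset ages follow the Gompertz proportional-hazards model", {
    bh <- c(rate = 3e-6, shape = 0.14)
    on0 <- generateOnsets(rep(0, 5000), bh, seed = 21)
    # closed-form Gompertz CDF
    cdf <- function(t) 1 - exp(-bh[["rate"]] / bh[["shape"]] *
                               expm1(bh[["shape"]] * t))
    ks <- suppressWarnings(ks.test(on0, cdf))
    expect_gt(ks$p.value, 0.01)
    # two strata differing by log(4) in score give a hazard ratio near 4;
    # the 95% CI covers it in nearly all replicates
    sc <- rep(c(0, 1.386), each = 1000)
    hi <- as.integer(sc > 0)
    covered <- vapply(1:10, function(s) {
        on <- generateOnsets(sc, bh, seed = 220 + s)
        ci <- exp(confint(survival::coxph(
            survival::Surv(on, rep(1, 2000)) ~ hi)))
        # exp(1.386) is 4.0: the stratum hazard ratio by construction
        ci[1] < 4.0 && 4.0 < ci[2]
    }, TRUE)
    expect_gte(sum(covered), 8)
    # higher score brings onset forward
    onHigh <- generateOnsets(rep(3, 1000), bh, seed = 23)
    expect_lt(median(onHigh), median(on0))
    expect_error(generateOnsets(c(0, NA), bh), "finite")
})

test_that("amyloid trajectories anchor at the threshold and carry the
           configured noise", {
    cfg <- simulationConfig(nParticipants = 3, nSnps = 0,
                            trueBetas = numeric(0), clNoiseSd = 0, seed = 2)
    visits <- data.frame(participant_id = rep(c("P1", "P2", "P3"), each = 4),
                         visit_age = c(70, 71.5, 73, 74.5,
                                       65, 70, 75, 80,
                                       60, 62, 64, 66))
    onsets <- c(71.5, 70, 80)
    am <- generateAmyloidTrajectories(onsets, visits, cfg,
                                      regions = "neocortex")
    # scan exactly at onset reads exactly the threshold
    expect_equal(am$centiloid[am$participant_id == "P1" &
                              am$scan_age == 71.5], 20)
    # noiseless trajectories increase strictly across visits
    for (id in unique(am$participant_id))
        expect_true(all(diff(am$centiloid[am$participant_id == id]) > 0))
    # never-converter sits at the floor
    am2 <- generateAmyloidTrajectories(c(71.5, NA, 80), visits, cfg,
                                       regions = "neocortex")
    expect_true(all(am2$centiloid[am2$participant_id == "P2"] < 1e-6))
    # measurement noise has the configured SD
    cfgN <- simulationConfig(nParticipants = 1, nSnps = 0,
                             trueBetas = numeric(0), clNoiseSd = 5, seed = 3)
    v1 <- data.frame(participant_id = "P1", visit_age = seq(69, 71,
                                                            length.out = 10000))
    amN <- generateAmyloidTrajectories(70, v1, cfgN, regions = "neocortex",
                                       seed = 9)
    am0 <- generateAmyloidTrajectories(70, v1, cfg, regions = "neocortex")
    expect_lt(abs(sd(amN$centiloid - am0$centiloid) - 5), 0.1)
    # ceiling at or below the threshold is a configuration error
    expect_error(simulationConfig(clCeiling = 15), "ceiling")
})

test_that("longitudinal outcomes have the generative score-by-time slope", {
    cfg <- simulationConfig(nParticipants = 2, nSnps = 0,
                            trueBetas = numeric(0), nRois = 2,
                            randomInterceptSd = 0, outcomeNoiseSd = 0,
                            atrophySlopePerPhs = -0.02, seed = 4)
    visits <- data.frame(participant_id = rep(c("P1", "P2"), each = 3),
                         visit_age = c(70, 71.5, 73, 68, 69.5, 71))
    out <- generateLongitudinalOutcomes(c(0, 1), visits, cfg, seed = 6)
    slopes <- vapply(split(out$volumes[out$volumes$roi == "entorhinal", ],
                           out$volumes$participant_id[
                               out$volumes$roi == "entorhinal"]),
                     function(d) unname(coef(lm(volume ~ visit_age, d))[2]),
                     0)
    # noiseless construction: slope difference is exactly the per-score slope
    expect_equal(unname(slopes["P2"] - slopes["P1"]), -0.02,
                 tolerance = 1e-10)
    # null score effect: fitted interaction centred on zero across replicates
    cfg0 <- simulationConfig(nParticipants = 40, nSnps = 0,
                             trueBetas = numeric(0), nRois = 1,
                             atrophySlopePerPhs = 0, seed = 8)
    set.seed(31)
    betas <- replicate(60, {
        sc <- rnorm(40)
        vis <- generateVisitSchedule(runif(40, 65, 80), cfg0)
        vol <- generateLongitudinalOutcomes(sc, vis, cfg0)$volumes
        base <- ave(vol$visit_age, vol$participant_id, FUN = min)
        d <- data.frame(participant_id = vol$participant_id,
                        time = vol$visit_age - base, value = vol$volume,
                        phs = sc[match(vol$participant_id,
                                       unique(vol$participant_id))])
        f <- suppressWarnings(fitLongitudinal(d, terms = "phs",
                                              scaleVars = character(0)))
        f$table$beta[f$table$term == "phs:time"]
    })
    expect_lt(abs(mean(betas)), 3 * sd(betas) / sqrt(60))
})

test_that("cohort summary reports within-diagnosis percentages", {
    pt <- data.frame(
        diagnosis = c(rep("CN", 573), rep("AD", 83)),
        sex = c(rep(c("female", "male"), c(318, 255)),
                rep(c("female", "male"), c(48, 35))),
        apoeE4Count = c(rep(c(0, 1), c(412, 161)), rep(c(0, 1), c(24, 59))))
    sm <- suppressWarnings(summarizeCohort(pt))
    expect_equal(sm$percent[sm$diagnosis == "AD" & sm$variable == "apoeE4" &
                            sm$level == "present"], 71.1)
    expect_equal(sm$percent[sm$diagnosis == "CN" & sm$variable == "sex" &
                            sm$level == "female"], 55.5)
    one <- data.frame(diagnosis = "MCI", sex = "female", apoeE4Count = 2)
    smOne <- suppressWarnings(summarizeCohort(one))
    expect_equal(smOne$percent[smOne$variable == "sex"], 100.0)
    expect_warning(summarizeCohort(pt), "omitted")
    expect_error(summarizeCohort(data.frame(diagnosis = "XX")), "unknown")
})

test_that("the full cohort simulation is deterministic in its seed", {
    cfg <- simulationConfig(nParticipants = 60, seed = 12)
    c1 <- simulateCohort(cfg)
    c2 <- simulateCohort(cfg)
    expect_identical(dosages(c1), dosages(c2))
    expect_identical(amyloidScans(c1), amyloidScans(c2))
    expect_identical(participants(c1), participants(c2))
    # visit ages strictly increasing per participant
    am <- amyloidScans(c1)
    am <- am[am$region == "neocortex", ]
    for (d in split(am$scan_age, am$participant_id))
        expect_true(all(diff(d) > 0) || length(d) == 1)
    # with zero noise, abnormality first turns true at the first scan
    # after the true onset age
    cfg0 <- simulationConfig(nParticipants = 60, clNoiseSd = 0, seed = 12)
    c0 <- simulateCohort(cfg0)
    am0 <- amyloidScans(c0)
    am0 <- am0[am0$region == "neocortex", ]
    pt <- participants(c0)
    for (id in rownames(pt)) {
        d <- am0[am0$participant_id == id, ]
        ab <- classifyAbnormal(d$centiloid)
        onset <- pt[id, "trueOnsetAge"]
        expect_identical(ab, !is.na(onset) & d$scan_age >= onset)
    }
})
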