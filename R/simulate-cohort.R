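#' Build a simulation configuration
#'
#' Defaults emulate the structure of a longitudinal ageing cohort with
#' amyloid PET imaging and genotyping: roughly 780 participants, a panel of
#' 31 risk SNPs plus two forced APOE pseudo-variants with dominant weights,
#' a Gompertz baseline hazard for the age at which amyloid becomes abnormal
#' (incidence doubling about every five years, median onset near 75 years at
#' the average genetic risk), sigmoidal Centiloid trajectories crossing
#' 20 CL at onset, and visits every 18 months with per-visit dropout tuned
#' to a mean follow-up near 4.8 years.
#'
#' @param nParticipants cohort size.
#' @param nSnps number of non-APOE panel variants.
#' @param alleleFreqRange range for effect-allele frequencies.
#' @param trueBetas per-SNP log-hazard effects; default a fixed alternating
#'   pattern of modest effects (|beta| 0.05-0.18).
#' @param apoeWeights log-hazard weights of the APOE epsilon-4 and
#'   epsilon-2 pseudo-variants (per allele copy).
#' @param apoeFreqs allele frequencies of the two APOE variants.
#' @param baselineHazard Gompertz `rate` (1/year) and `shape` (1/year).
#' @param baselineAgeMean,baselineAgeSd age at entry (years).
#' @param visitInterval years between visits.
#' @param maxVisits maximum visits per participant.
#' @param dropoutProb per-visit Bernoulli dropout probability; once dropped
#'   a participant has no further visits.
#' @param clThreshold Centiloid abnormality threshold.
#' @param clFloor,clCeiling asymptotes of the Centiloid trajectory
#'   (0 = typical young control, 100 = typical mild AD).
#' @param clRate logistic rate constant (1/year) of amyloid accumulation.
#' @param clNoiseSd per-scan Centiloid measurement noise SD.
#' @param nRois number of cortical ROIs in the atrophy tables.
#' @param atrophyBaseSlope,atrophySlopePerPhs volume slope (fraction/year)
#'   at score zero and its change per score unit.
#' @param cognitionBaseSlope,cognitionSlopePerPhs cognitive slope
#'   (composite SD/year) at score zero and its change per score unit.
#' @param randomInterceptSd,outcomeNoiseSd between-individual intercept SD
#'   and residual SD of the longitudinal outcomes (outcome units).
#' @param horizonAge onsets drawn beyond this age are never-converters.
#' @param seed integer seed; identical configuration implies an identical
#'   cohort.
#' @return a [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nParticipants = 50, seed = 1)
#' cfg
#' @export
simulationConfig <- function(nParticipants = 780L,
                             nSnps = 31L,
                             alleleFreqRange = c(0.05, 0.5),
                             trueBetas = defaultTrueBetas(nSnps),
                             apoeWeights = c(e4 = 1.0, e2 = -0.45),
                             apoeFreqs = c(e4 = 0.20, e2 = 0.07),
                             baselineHazard = c(rate = 3e-6, shape = 0.14),
                             baselineAgeMean = 73,
                             baselineAgeSd = 6.5,
                             visitInterval = 1.5,
                             maxVisits = 8L,
                             dropoutProb = 0.18,
                             clThreshold = 20,
                             clFloor = 0,
                             clCeiling = 100,
                             clRate = 0.15,
                             clNoiseSd = 5,
                             nRois = 33L,
                             atrophyBaseSlope = -0.005,
                             atrophySlopePerPhs = -0.002,
                             cognitionBaseSlope = -0.02,
                             cognitionSlopePerPhs = -0.03,
                             randomInterceptSd = 0.25,
                             outcomeNoiseSd = 0.15,
                             horizonAge = 110,
                             seed = 1L) {
    if (!is.numeric(nParticipants) || nParticipants < 1)
        stopf("nParticipants must be a positive count")
    if (!is.numeric(nSnps) || nSnps < 0)
        stopf("nSnps must be a non-negative count")
    bh <- baselineHazard
    if (is.null(names(bh))) names(bh) <- c("rate", "shape")
    new("SimulationConfig",
        nParticipants = as.integer(nParticipants),
        nSnps = as.integer(nSnps),
        alleleFreqRange = as.numeric(alleleFreqRange),
        trueBetas = as.numeric(trueBetas),
        apoeWeights = apoeWeights,
        apoeFreqs = apoeFreqs,
        baselineHazard = bh,
        baselineAgeMean = baselineAgeMean,
        baselineAgeSd = baselineAgeSd,
        visitInterval = visitInterval,
        maxVisits = as.integer(maxVisits),
        dropoutProb = dropoutProb,
        clThreshold = clThreshold,
        clFloor = clFloor,
        clCeiling = clCeiling,
        clRate = clRate,
        clNoiseSd = clNoiseSd,
        nRois = as.integer(nRois),
        atrophyBaseSlope = atrophyBaseSlope,
        atrophySlopePerPhs = atrophySlopePerPhs,
        cognitionBaseSlope = cognitionBaseSlope,
        cognitionSlopePerPhs = cognitionSlopePerPhs,
        randomInterceptSd = randomInterceptSd,
        outcomeNoiseSd = outcomeNoiseSd,
        horizonAge = horizonAge,
        seed = as.integer(seed))
}

#' @rdname simulationConfig
#' @param n number of effects to generate.
#' @export
defaultTrueBetas <- function(n)
    rep_len(c(0.12, -0.08, 0.15, 0.1, -0.05, 0.18, 0.07, -0.1), n)

#' Cortical regions of interest used by the synthetic atrophy tables
#'
#' Names follow the Desikan-Killiany cortical parcellation; the first `n`
#' are returned, with `entorhinal` always first so it is available as the
#' neurodegeneration covariate of the longitudinal model.
#'
#' @param n number of ROI names (at most 33).
#' @export
desikanRois <- function(n = 33L) {
    rois <- c("entorhinal", "precuneus", "posterior_cingulate",
        "inferior_temporal", "middle_temporal", "superior_temporal",
        "fusiform", "parahippocampal", "inferior_parietal",
        "superior_parietal", "supramarginal", "lateral_occipital",
        "lingual", "pericalcarine", "cuneus", "isthmus_cingulate",
        "caudal_anterior_cingulate", "rostral_anterior_cingulate",
        "medial_orbitofrontal", "lateral_orbitofrontal", "pars_opercularis",
        "pars_orbitalis", "pars_triangularis", "rostral_middle_frontal",
        "caudal_middle_frontal", "superior_frontal", "frontal_pole",
        "temporal_pole", "transverse_temporal", "banks_sts",
        "postcentral", "precentral", "paracentral")
    rois[seq_len(min(n, length(rois)))]
}

# Default raw scales of the synthetic neuropsychological battery
cognitiveTestScales <- function() {
    data.frame(
        test = c("cvlt", "rcft", "cowat", "category_switching", "lmii"),
        mean = c(45, 20, 40, 13, 12),
        sd = c(10, 6, 11, 3.5, 4),
        stringsAsFactors = FALSE)
}

#' Simulate biallelic genotype dosages under Hardy-Weinberg equilibrium
#'
#' Draws `nSnps` independent variants with effect-allele frequencies
#' uniform on `alleleFreqRange`, each dosage Binomial(2, f), plus the two
#' APOE pseudo-variants (`APOE_e4`, `APOE_e2`) whose dosages are the allele
#' counts. Variant metadata carries the effect allele, frequency, the
#' generative log-hazard weight, and synthetic GWAS summary statistics
#' (odds ratio and p-value) so that candidate filtering and stepwise
#' selection can be exercised end to end.
#'
#' @param config a [SimulationConfig-class].
#' @param seed optional seed overriding `config@seed`.
#' @return a `SummarizedExperiment` with a `dosage` assay (variants x
#'   individuals) and rowData columns `effectAllele`, `otherAllele`,
#'   `freq`, `trueBeta`, `forced`, `or`, `p`.
#' @export
generateGenotypes <- function(config, seed = config@seed) {
    validObject(config)
    n <- config@nParticipants
    m <- config@nSnps
    withSeed(seed, {
        freqs <- stats::runif(m, config@alleleFreqRange[1],
                              config@alleleFreqRange[2])
        dos <- matrix(stats::rbinom(n * m, 2L, rep(freqs, each = n)),
                      nrow = m, ncol = n, byrow = TRUE)
        e4 <- stats::rbinom(n, 2L, config@apoeFreqs[["e4"]])
        e2 <- stats::rbinom(n, 2L, config@apoeFreqs[["e2"]])
        alleles <- c("A", "C", "G", "T")
        eff <- sample(alleles, m, replace = TRUE)
        oth <- vapply(eff, function(a) sample(setdiff(alleles, a), 1L), "")
        # synthetic genome-wide summary statistics: every panel SNP passes
        # the candidate threshold; APOE variants are overwhelmingly strong
        pval <- 10^-stats::runif(m, 5.2, 12)
        or <- exp(config@trueBetas + stats::rnorm(m, 0, 0.02))
        mat <- rbind(dos, e4, e2)
        ids <- c(sprintf("rs%06d", seq_len(m)), "APOE_e4", "APOE_e2")
        rownames(mat) <- ids
        colnames(mat) <- sprintf("P%04d", seq_len(n))
        rd <- S4Vectors::DataFrame(
            effectAllele = c(eff, "C", "T"),
            otherAllele = c(oth, "T", "C"),
            freq = c(freqs, config@apoeFreqs[["e4"]],
                     config@apoeFreqs[["e2"]]),
            trueBeta = c(config@trueBetas, config@apoeWeights[["e4"]],
                         config@apoeWeights[["e2"]]),
            forced = c(rep(FALSE, m), TRUE, TRUE),
            or = c(or, exp(config@apoeWeights[["e4"]]),
                   exp(config@apoeWeights[["e2"]])),
            p = c(pval, 1e-50, 1e-30),
            row.names = ids)
        SummarizedExperiment::SummarizedExperiment(
            assays = list(dosage = mat), rowData = rd)
    })
}

# Gompertz baseline cumulative hazard H0(t) = rate/shape * (exp(shape t) - 1)
gompertzCumHaz <- function(t, rate, shape) rate / shape * (expm1(shape * t))

# Inverse of the cumulative hazard
gompertzInvCumHaz <- function(H, rate, shape) log1p(shape * H / rate) / shape

#' Draw ages of amyloid onset from a proportional-hazards Gompertz model
#'
#' The hazard for an individual with score `s` is
#' `h(t) = rate * exp(shape * t) * exp(s)`; onset ages are drawn by inverse
#' transform of the cumulative hazard, so the generative hazard ratio
#' between two individuals is exactly `exp(s1 - s2)` at every age.
#'
#' @param trueScores numeric vector of log relative hazards.
#' @param baselineHazard named numeric, Gompertz `rate` and `shape`.
#' @param seed optional integer seed.
#' @return numeric vector of onset ages in years (always finite; compare
#'   against a horizon age to classify never-converters).
#' @export
generateOnsets <- function(trueScores, baselineHazard, seed = NULL) {
    if (any(!is.finite(trueScores)))
        stopf("trueScores must be finite")
    rate <- baselineHazard[["rate"]]
    shape <- baselineHazard[["shape"]]
    if (rate <= 0 || shape <= 0)
        stopf("Gompertz rate and shape must be positive")
    withSeed(seed, {
        e <- stats::rexp(length(trueScores))
        gompertzInvCumHaz(e * exp(-trueScores), rate, shape)
    })
}

# Noiseless logistic Centiloid value at a given age, anchored so the curve
# crosses the threshold exactly at the onset age. Infinite onset -> floor.
logisticCL <- function(age, onsetAge, config) {
    fl <- config@clFloor; ce <- config@clCeiling
    k <- config@clRate; thr <- config@clThreshold
    shift <- log((ce - fl) / (thr - fl) - 1) / k
    x <- ifelse(is.finite(onsetAge), k * (age - onsetAge - shift), -Inf)
    fl + (ce - fl) * stats::plogis(x)
}

#' Generate longitudinal Centiloid trajectories
#'
#' Noiseless trajectories are logistic in age with floor and ceiling from
#' the configuration, anchored to cross the abnormality threshold exactly
#' at the onset age; independent Gaussian measurement noise with SD
#' `clNoiseSd` is added per scan. Participants without an onset age (`NA`,
#' never-converters) sit at the floor.
#'
#' @param onsetAges numeric vector (years), `NA` for never-converters.
#' @param visits data.frame with `participant_id` and `visit_age`; the
#'   participant index is matched by position in `onsetAges` via the
#'   factor order of `participant_id`.
#' @param config a [SimulationConfig-class].
#' @param regions character vector of region labels to emit.
#' @param seed optional seed.
#' @return data.frame `participant_id`, `region`, `scan_age`, `centiloid`.
#' @export
generateAmyloidTrajectories <- function(onsetAges, visits, config,
                                        regions = amyloidRegions(),
                                        seed = NULL) {
    if (config@clCeiling <= config@clThreshold)
        stopf("Centiloid ceiling must exceed the threshold")
    ids <- unique(visits$participant_id)
    if (length(onsetAges) != length(ids))
        stopf("onsetAges must have one value per participant")
    onset <- onsetAges[match(visits$participant_id, ids)]
    withSeed(seed, {
        out <- do.call(rbind, lapply(regions, function(rg) {
            cl0 <- logisticCL(visits$visit_age,
                              ifelse(is.na(onset), Inf, onset), config)
            data.frame(participant_id = visits$participant_id,
                       region = rg,
                       scan_age = visits$visit_age,
                       centiloid = cl0 + stats::rnorm(length(cl0), 0,
                                                      config@clNoiseSd),
                       stringsAsFactors = FALSE)
        }))
        rownames(out) <- NULL
        out
    })
}

#' Generate the visit schedule
#'
#' Visits are spaced `visitInterval` years apart starting at the baseline
#' age; after each visit the participant drops out with probability
#' `dropoutProb` and has no further visits, up to `maxVisits`.
#'
#' @param baselineAges numeric vector of entry ages.
#' @param config a [SimulationConfig-class].
#' @param seed optional seed.
#' @return data.frame `participant_id`, `visit`, `visit_age`.
#' @export
generateVisitSchedule <- function(baselineAges, config, seed = NULL) {
    n <- length(baselineAges)
    ids <- sprintf("P%04d", seq_len(n))
    withSeed(seed, {
        extra <- pmin(stats::rgeom(n, config@dropoutProb),
                      config@maxVisits - 1L)
        do.call(rbind, lapply(seq_len(n), function(i) {
            k <- 0:extra[i]
            data.frame(participant_id = ids[i], visit = k + 1L,
                       visit_age = baselineAges[i] + k * config@visitInterval,
                       stringsAsFactors = FALSE)
        }))
    })
}

#' Generate longitudinal atrophy and cognition tables
#'
#' Each outcome follows a random-intercept linear growth model:
#' `value = intercept + (baseSlope + slopePerPhs * score) * time +
#' u_individual + noise`, with time in years since the first visit.
#' Volumes are emitted as fractions of a reference volume for `nRois`
#' cortical ROIs; cognition as raw scores of a five-test battery plus a
#' CDR sum-of-boxes column that increases over time.
#'
#' @param trueScores numeric, one score per participant.
#' @param visits data.frame from [generateVisitSchedule()].
#' @param config a [SimulationConfig-class].
#' @param roiSlopePerPhs optional per-ROI score-by-time slopes overriding
#'   `config@atrophySlopePerPhs` (recycled across ROIs).
#' @param seed optional seed.
#' @return list with data.frames `volumes` (`participant_id`, `visit_age`,
#'   `roi`, `volume`) and `cognition` (`participant_id`, `visit_age`,
#'   `test`, `score`).
#' @export
generateLongitudinalOutcomes <- function(trueScores, visits, config,
                                         roiSlopePerPhs = NULL,
                                         seed = NULL) {
    ids <- unique(visits$participant_id)
    if (length(trueScores) != length(ids))
        stopf("trueScores must have one value per participant")
    idx <- match(visits$participant_id, ids)
    score <- trueScores[idx]
    base <- stats::ave(visits$visit_age, visits$participant_id, FUN = min)
    tm <- visits$visit_age - base
    rois <- desikanRois(config@nRois)
    slopes <- if (is.null(roiSlopePerPhs)) rep(config@atrophySlopePerPhs,
                                               length(rois))
              else rep_len(roiSlopePerPhs, length(rois))
    withSeed(seed, {
        volumes <- do.call(rbind, lapply(seq_along(rois), function(r) {
            u <- stats::rnorm(length(ids), 0, config@randomInterceptSd * 0.2)
            mu <- 1 + u[idx] +
                (config@atrophyBaseSlope + slopes[r] * score) * tm
            data.frame(participant_id = visits$participant_id,
                       visit_age = visits$visit_age, roi = rois[r],
                       volume = mu + stats::rnorm(length(mu), 0,
                                         config@outcomeNoiseSd * 0.1),
                       stringsAsFactors = FALSE)
        }))
        scales <- cognitiveTestScales()
        cognition <- do.call(rbind, lapply(seq_len(nrow(scales)), function(s) {
            u <- stats::rnorm(length(ids), 0, config@randomInterceptSd)
            z <- u[idx] + (config@cognitionBaseSlope +
                           config@cognitionSlopePerPhs * score) * tm +
                stats::rnorm(length(tm), 0, config@outcomeNoiseSd)
            data.frame(participant_id = visits$participant_id,
                       visit_age = visits$visit_age, test = scales$test[s],
                       score = scales$mean[s] + scales$sd[s] * z,
                       stringsAsFactors = FALSE)
        }))
        uc <- stats::rnorm(length(ids), 0, 0.2)
        cdr <- data.frame(participant_id = visits$participant_id,
                          visit_age = visits$visit_age, test = "cdr_sb",
                          score = pmax(0, uc[idx] +
                              (0.08 + 0.06 * score) * tm +
                              stats::rnorm(length(tm), 0, 0.15)),
                          stringsAsFactors = FALSE)
        rownames(volumes) <- rownames(cognition) <- NULL
        list(volumes = volumes, cognition = rbind(cognition, cdr))
    })
}

#' Simulate a complete synthetic cohort
#'
#' Runs every generator under a single seed: genotypes (including the APOE
#' pseudo-variants), the true polygenic score (centred weight-by-dosage
#' sum), onset ages from the Gompertz proportional-hazards model, the visit
#' schedule with dropout, Centiloid trajectories per region, ROI volumes
#' and cognitive scores, and a clinical diagnosis label. Diagnosis is a
#' stand-in obtained by ranking a noisy latent severity (baseline age minus
#' onset age) and labelling the top fractions AD and MCI so group sizes
#' mirror a memory-clinic-free ageing cohort (about 73% CN, 16% MCI,
#' 11% AD).
#'
#' @param config a [SimulationConfig-class].
#' @return an [AmyloidCohort-class] object. Ground truth lives in
#'   `colData` (`trueScore`, `trueOnsetAge`, `NA` for never-converters).
#' @examples
#' coh <- simulateCohort(simulationConfig(nParticipants = 40, seed = 7))
#' coh
#' @export
simulateCohort <- function(config) {
    validObject(config)
    se <- generateGenotypes(config)
    dos <- SummarizedExperiment::assay(se, "dosage")
    rd <- SummarizedExperiment::rowData(se)
    # centred so the average individual sits at the baseline hazard
    w <- rd$trueBeta
    trueScore <- as.numeric(crossprod(dos, w)) - sum(w * 2 * rd$freq)
    n <- config@nParticipants
    withSeed(config@seed + 1L, {
        onsetRaw <- generateOnsets(trueScore, config@baselineHazard)
        baselineAge <- pmin(pmax(stats::rnorm(n, config@baselineAgeMean,
                                              config@baselineAgeSd), 55), 95)
        sex <- ifelse(stats::runif(n) < 0.54, "female", "male")
        education <- pmin(pmax(round(stats::rnorm(n, 13, 3)), 6), 20)
        visits <- generateVisitSchedule(baselineAge, config)
        amyloid <- generateAmyloidTrajectories(onsetRaw, visits, config)
        outcomes <- generateLongitudinalOutcomes(trueScore, visits, config)
        severity <- baselineAge - onsetRaw + stats::rnorm(n, 0, 2)
        qs <- stats::quantile(severity, c(1 - 0.106, 1 - 0.106 - 0.159))
        diagnosis <- ifelse(severity > qs[1], "AD",
                     ifelse(severity > qs[2], "MCI", "CN"))
    })
    cd <- S4Vectors::DataFrame(
        sex = sex,
        baselineAge = baselineAge,
        educationYears = education,
        apoeE4Count = as.integer(dos["APOE_e4", ]),
        apoeE2Count = as.integer(dos["APOE_e2", ]),
        diagnosis = diagnosis,
        trueScore = trueScore,
        trueOnsetAge = ifelse(onsetRaw > config@horizonAge, NA_real_,
                              onsetRaw),
        row.names = colnames(dos))
    obj <- new("AmyloidCohort",
               SummarizedExperiment::SummarizedExperiment(
                   assays = list(dosage = dos),
                   rowData = rd, colData = cd),
               amyloid = amyloid, volumes = outcomes$volumes,
               cognition = outcomes$cognition)
    S4Vectors::metadata(obj)$config <- config
    validObject(obj)
    obj
}

#' Cohort characteristics table by clinical diagnosis
#'
#' Summarises a participant table the way population-characteristics tables
#' are reported: counts with within-diagnosis percentages for categorical
#' variables, mean and SD for continuous ones, percentages rounded to one
#' decimal place.
#'
#' @param participants data.frame with a `diagnosis` column (levels among
#'   CN, MCI, AD) plus any of `sex`, `apoeE4Count`, `baselineAge`,
#'   `educationYears`, `trueScore`/`phs`.
#' @return data.frame in long form: `diagnosis`, `n_group`, `variable`,
#'   `level`, `n`, `percent`, `mean`, `sd`.
#' @export
summarizeCohort <- function(participants) {
    if (!"diagnosis" %in% names(participants))
        stopf("participants must have a 'diagnosis' column")
    bad <- setdiff(unique(participants$diagnosis), c("CN", "MCI", "AD"))
    if (length(bad))
        stopf("unknown diagnosis label(s): %s", paste(bad, collapse = ", "))
    groups <- intersect(c("CN", "MCI", "AD"), unique(participants$diagnosis))
    empty <- setdiff(c("CN", "MCI", "AD"), groups)
    if (length(empty))
        warnf("empty diagnosis group(s) omitted: %s",
              paste(empty, collapse = ", "))
    catVars <- list()
    if ("sex" %in% names(participants))
        catVars$sex <- participants$sex
    if ("apoeE4Count" %in% names(participants))
        catVars$apoeE4 <- ifelse(participants$apoeE4Count > 0,
                                 "present", "absent")
    contVars <- intersect(c("baselineAge", "educationYears", "trueScore",
                            "phs"), names(participants))
    rows <- list()
    for (g in groups) {
        sel <- participants$diagnosis == g
        ng <- sum(sel)
        for (v in names(catVars)) {
            tab <- table(catVars[[v]][sel])
            for (lv in names(tab)) {
                rows[[length(rows) + 1L]] <- data.frame(
                    diagnosis = g, n_group = ng, variable = v, level = lv,
                    n = as.integer(tab[[lv]]),
                    percent = round(100 * tab[[lv]] / ng, 1),
                    mean = NA_real_, sd = NA_real_,
                    stringsAsFactors = FALSE)
            }
        }
        for (v in contVars) {
            x <- participants[[v]][sel]
            rows[[length(rows) + 1L]] <- data.frame(
                diagnosis = g, n_group = ng, variable = v, level = NA,
                n = sum(!is.na(x)), percent = NA_real_,
                mean = mean(x, na.rm = TRUE),
                sd = stats::sd(x, na.rm = TRUE),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
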