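#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' Simulation configuration for a synthetic amyloid-imaging cohort
#'
#' Holds every parameter of the synthetic cohort generator: cohort size,
#' variant panel, APOE pseudo-variant weights, the Gompertz baseline hazard
#' for amyloid onset, the logistic Centiloid trajectory, the visit schedule
#' and the outcome slopes. Construct with [simulationConfig()].
#'
#' @slot nParticipants integer, cohort size.
#' @slot nSnps integer, number of non-APOE panel variants.
#' @slot alleleFreqRange numeric(2), range for effect-allele frequencies.
#' @slot trueBetas numeric, per-variant log-hazard effects (length `nSnps`).
#' @slot apoeWeights named numeric(2), log-hazard weights for the APOE
#'   epsilon-4 and epsilon-2 pseudo-variants.
#' @slot apoeFreqs named numeric(2), allele frequencies of the two APOE
#'   pseudo-variants.
#' @slot baselineHazard named numeric(2), Gompertz parameters `rate`
#'   (1/year) and `shape` (1/year).
#' @slot baselineAgeMean,baselineAgeSd numeric, distribution of age at
#'   study entry (years).
#' @slot visitInterval numeric, years between visits.
#' @slot maxVisits integer, maximum number of visits per participant.
#' @slot dropoutProb numeric, per-visit Bernoulli dropout probability.
#' @slot clThreshold numeric, Centiloid abnormality threshold (default 20).
#' @slot clFloor,clCeiling numeric, asymptotes of the Centiloid trajectory.
#' @slot clRate numeric, logistic rate constant of amyloid accumulation
#'   (1/year).
#' @slot clNoiseSd numeric, per-scan Centiloid measurement noise SD.
#' @slot nRois integer, number of cortical regions of interest for the
#'   atrophy tables.
#' @slot atrophyBaseSlope,atrophySlopePerPhs numeric, volume-fraction/year
#'   slope components.
#' @slot cognitionBaseSlope,cognitionSlopePerPhs numeric, composite-SD/year
#'   slope components.
#' @slot randomInterceptSd,outcomeNoiseSd numeric, between-individual and
#'   residual SDs of the longitudinal outcome model (outcome units).
#' @slot horizonAge numeric, onset ages beyond this are treated as
#'   never-converting.
#' @slot seed integer, random seed keying the whole cohort.
#' @seealso [simulateCohort()]
#' @export
setClass("SimulationConfig", representation(
    nParticipants = "integer",
    nSnps = "integer",
    alleleFreqRange = "numeric",
    trueBetas = "numeric",
    apoeWeights = "numeric",
    apoeFreqs = "numeric",
    baselineHazard = "numeric",
    baselineAgeMean = "numeric",
    baselineAgeSd = "numeric",
    visitInterval = "numeric",
    maxVisits = "integer",
    dropoutProb = "numeric",
    clThreshold = "numeric",
    clFloor = "numeric",
    clCeiling = "numeric",
    clRate = "numeric",
    clNoiseSd = "numeric",
    nRois = "integer",
    atrophyBaseSlope = "numeric",
    atrophySlopePerPhs = "numeric",
    cognitionBaseSlope = "numeric",
    cognitionSlopePerPhs = "numeric",
    randomInterceptSd = "numeric",
    outcomeNoiseSd = "numeric",
    horizonAge = "numeric",
    seed = "integer"
))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nParticipants < 1L) msg <- c(msg, "nParticipants must be positive")
    if (object@nSnps < 0L) msg <- c(msg, "nSnps must be non-negative")
    fr <- object@alleleFreqRange
    if (length(fr) != 2L || any(fr <= 0) || any(fr >= 1) || fr[1] > fr[2])
        msg <- c(msg, "alleleFreqRange must be an increasing pair in (0, 1)")
    if (length(object@trueBetas) != object@nSnps)
        msg <- c(msg, "trueBetas must have length nSnps")
    if (any(!is.finite(object@trueBetas)))
        msg <- c(msg, "trueBetas must be finite")
    if (any(object@baselineHazard <= 0))
        msg <- c(msg, "Gompertz rate and shape must be positive")
    if (object@visitInterval <= 0) msg <- c(msg, "visitInterval must be > 0")
    if (object@dropoutProb < 0 || object@dropoutProb > 1)
        msg <- c(msg, "dropoutProb must be in [0, 1]")
    if (object@clNoiseSd < 0) msg <- c(msg, "clNoiseSd must be >= 0")
    if (object@clCeiling <= object@clThreshold)
        msg <- c(msg, "Centiloid ceiling must exceed the abnormality threshold")
    if (object@clFloor >= object@clThreshold)
        msg <- c(msg, "Centiloid floor must lie below the abnormality threshold")
    if (object@clRate <= 0) msg <- c(msg, "clRate must be positive")
    if (length(msg)) msg else TRUE
})

#' A panel of scoring variants with Cox log-hazard weights
#'
#' Ordered set of variants making up a polygenic hazard score: the forced
#' APOE variants plus the SNPs retained by forward stepwise Cox selection,
#' each with its effect allele and the per-allele log-hazard weight from the
#' final joint Cox refit.
#'
#' @slot panel a `DataFrame` with columns `id`, `effectAllele`, `weight`
#'   and logical `forced`.
#' @seealso [forwardStepwiseCox()], [computePhs()]
#' @export
setClass("SnpPanel", representation(panel = "DataFrame"))

setValidity("SnpPanel", function(object) {
    p <- object@panel
    need <- c("id", "effectAllele", "weight", "forced")
    if (!all(need %in% colnames(p)))
        return(paste("panel must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(p$id)) return("duplicated variant ids in panel")
    if (any(!is.finite(p$weight))) return("panel weights must be finite")
    TRUE
})

#' Per-individual polygenic hazard scores and strata
#'
#' @slot score named numeric, the continuous score per individual
#'   (weight-by-dosage sum, a log relative hazard).
#' @slot stratum factor with levels `low`, `mid`, `high`.
#' @slot thresholds numeric(2), the low/high cutpoints used.
#' @seealso [computePhs()], [stratifyPhs()]
#' @export
setClass("PhsResult", representation(
    score = "numeric", stratum = "factor", thresholds = "numeric"))

setValidity("PhsResult", function(object) {
    if (length(object@stratum) &&
        length(object@stratum) != length(object@score))
        return("score and stratum lengths differ")
    if (length(object@stratum) &&
        !identical(levels(object@stratum), c("low", "mid", "high")))
        return("stratum levels must be low, mid, high")
    TRUE
})

#' Amyloid disease-progression curve
#'
#' Monotone map between Centiloid level and disease time tau (years),
#' anchored so that `CL(0) == threshold`. Stored as a dense sampled grid;
#' [predictCL()] and [diseaseTime()] interpolate it in either direction.
#'
#' @slot tau numeric, disease-time grid (years, increasing).
#' @slot cl numeric, Centiloid values on the grid (strictly increasing).
#' @slot threshold numeric, the anchoring Centiloid threshold.
#' @slot floor,ceiling numeric, valid Centiloid range of the curve.
#' @seealso [fitProgressionCurve()], [estimateOnsetAge()]
#' @export
setClass("ProgressionCurve", representation(
    tau = "numeric", cl = "numeric", threshold = "numeric",
    floor = "numeric", ceiling = "numeric"))

setValidity("ProgressionCurve", function(object) {
    if (length(object@tau) != length(object@cl))
        return("tau and cl grids must have equal length")
    if (any(diff(object@cl) <= 0))
        return("Centiloid grid must be strictly increasing")
    if (any(diff(object@tau) <= 0))
        return("disease-time grid must be strictly increasing")
    TRUE
})

#' Synthetic cohort with genotypes, phenotypes and longitudinal tables
#'
#' A `SummarizedExperiment` whose `dosage` assay holds variant-by-individual
#' allele dosages (0/1/2), with variant metadata in `rowData` (effect
#' allele, frequency, generative log-hazard weight, synthetic summary-stats
#' odds ratio and p-value) and the participant table in `colData` (sex,
#' baseline age, education, APOE counts, diagnosis, plus ground truth:
#' `trueScore` and `trueOnsetAge`). Longitudinal tables ride in extra
#' slots in long format keyed by participant and visit age.
#'
#' @slot amyloid data.frame: `participant_id`, `region`, `scan_age`,
#'   `centiloid`.
#' @slot volumes data.frame: `participant_id`, `visit_age`, `roi`, `volume`
#'   (fraction of baseline reference volume).
#' @slot cognition data.frame: `participant_id`, `visit_age`, `test`,
#'   `score` (raw test units; `cdr_sb` rides along untransformed).
#' @seealso [simulateCohort()]
#' @export
setClass("AmyloidCohort", contains = "SummarizedExperiment",
    representation(amyloid = "data.frame", volumes = "data.frame",
                   cognition = "data.frame"))

setValidity("AmyloidCohort", function(object) {
    ids <- colnames(object)
    for (nm in c("amyloid", "volumes", "cognition")) {
        tab <- slot(object, nm)
        if (nrow(tab) && !all(tab$participant_id %in% ids))
            return(sprintf("%s table refers to unknown participant ids", nm))
    }
    if (nrow(object@amyloid) &&
        !all(object@amyloid$region %in% amyloidRegions()))
        return("unknown amyloid region label")
    TRUE
})

#' Fixed set of amyloid-PET regions of interest
#'
#' @return character vector of the three Centiloid reporting regions.
#' @export
amyloidRegions <- function()
    c("neocortex", "frontal", "posterior_cingulate")
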