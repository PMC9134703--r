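#' Configure a pipeline run
#'
#' Exactly one input branch must be active: either a synthetic
#' [SimulationConfig-class] or the paths of the real input files
#' (summary statistics TSV, genotype dosage TSV or VCF, participant CSV
#' and long-format phenotype CSVs).
#'
#' @param synthetic a [SimulationConfig-class], or `NULL` for file input.
#' @param paths named list with `summaryStats`, `dosages`, `participants`,
#'   `amyloid`, `volumes`, `cognition` when `synthetic` is `NULL`.
#' @param outputDir directory for stage outputs.
#' @param clThreshold Centiloid abnormality threshold.
#' @param phsThresholds optional explicit low/high score cutpoints
#'   (default: cohort mean plus/minus one SD).
#' @param alphaEntry,maxSnps stepwise-selection controls.
#' @param pThreshold candidate screen on the summary statistics.
#' @param subgroups run the APOE carrier / non-carrier cross-sectional
#'   subgroup models.
#' @param e3e3Only restrict the onset analysis to epsilon-3 homozygotes.
#' @param truncate left-truncate the survival analysis at study entry.
#' @param timeMainEffect add a Time main effect to the longitudinal
#'   models.
#' @param seed integer seed for the synthetic branch.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(synthetic = NULL, paths = NULL,
                      outputDir = tempfile("phsrun"),
                      clThreshold = 20, phsThresholds = NULL,
                      alphaEntry = 0.05, maxSnps = 31L, pThreshold = 1e-5,
                      subgroups = TRUE, e3e3Only = FALSE, truncate = FALSE,
                      timeMainEffect = FALSE, seed = 1L) {
    if (is.null(synthetic) == is.null(paths))
        stopf("exactly one of 'synthetic' or 'paths' must be supplied")
    if (!is.null(synthetic) && !is(synthetic, "SimulationConfig"))
        stopf("'synthetic' must be a SimulationConfig")
    if (!is.null(paths)) {
        need <- c("summaryStats", "dosages", "participants", "amyloid",
                  "volumes", "cognition")
        missing <- setdiff(need, names(paths))
        if (length(missing))
            stopf("paths lack entries: %s", paste(missing, collapse = ", "))
    }
    stopifnot(is.finite(clThreshold), is.finite(alphaEntry))
    structure(list(synthetic = synthetic, paths = paths,
                   outputDir = outputDir, clThreshold = clThreshold,
                   phsThresholds = phsThresholds, alphaEntry = alphaEntry,
                   maxSnps = as.integer(maxSnps), pThreshold = pThreshold,
                   subgroups = subgroups, e3e3Only = e3e3Only,
                   truncate = truncate, timeMainEffect = timeMainEffect,
                   seed = as.integer(seed)),
              class = "RunConfig")
}

# stable md5 of the configuration (thresholds, paths, seed)
configHash <- function(config) {
    x <- config
    x$synthetic <- if (is.null(x$synthetic)) NULL else {
        sl <- slotNames(x$synthetic)
        stats::setNames(lapply(sl, function(s) slot(x$synthetic, s)), sl)
    }
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(paste(utils::capture.output(utils::str(x)), collapse = "\n"),
               f)
    unname(tools::md5sum(f))
}

#' Load and validate the pipeline inputs
#'
#' Synthetic branch: generates the cohort from the embedded
#' [SimulationConfig-class] (same configuration and seed, same cohort).
#' File branch: reads and validates every input, aligning genotype
#' dosages by variant id.
#'
#' @param config a [runConfig()].
#' @return list with `cohort` (an [AmyloidCohort-class]) and
#'   `summaryStats`.
#' @export
loadInputs <- function(config) {
    if (!is.null(config$synthetic)) {
        cfg <- config$synthetic
        cfg@seed <- config$seed
        cohort <- simulateCohort(cfg)
        rd <- SummarizedExperiment::rowData(cohort)
        ss <- data.frame(snp_id = rownames(cohort),
                         effect_allele = rd$effectAllele,
                         or = rd$or, p = rd$p, stringsAsFactors = FALSE)
        return(list(cohort = cohort, summaryStats = ss))
    }
    p <- config$paths
    ss <- readSummaryStats(p$summaryStats)
    dos <- if (grepl("\\.vcf(\\.gz)?$", p$dosages))
        readVcfDosages(p$dosages)$dosages else readDosageTsv(p$dosages)
    pt <- utils::read.csv(p$participants, stringsAsFactors = FALSE)
    if (!"participant_id" %in% names(pt))
        stopf("participant table lacks 'participant_id'")
    amyLong <- readPhenotypeCsv(p$amyloid, regions = amyloidRegions())
    volLong <- readPhenotypeCsv(p$volumes)
    cogLong <- readPhenotypeCsv(p$cognition)
    ids <- pt$participant_id
    dos <- dos[, ids, drop = FALSE]
    amyloid <- data.frame(participant_id = amyLong$participant_id,
                          region = amyLong$variable,
                          scan_age = amyLong$visit_age,
                          centiloid = amyLong$value,
                          stringsAsFactors = FALSE)
    volumes <- data.frame(participant_id = volLong$participant_id,
                          visit_age = volLong$visit_age,
                          roi = volLong$variable, volume = volLong$value,
                          stringsAsFactors = FALSE)
    cognition <- data.frame(participant_id = cogLong$participant_id,
                            visit_age = cogLong$visit_age,
                            test = cogLong$variable, score = cogLong$value,
                            stringsAsFactors = FALSE)
    cd <- S4Vectors::DataFrame(pt[, setdiff(names(pt), "participant_id")],
                               row.names = ids)
    cohort <- new("AmyloidCohort",
                  SummarizedExperiment::SummarizedExperiment(
                      assays = list(dosage = dos), colData = cd),
                  amyloid = amyloid, volumes = volumes,
                  cognition = cognition)
    validObject(cohort)
    list(cohort = cohort, summaryStats = ss)
}

# survival table used for panel derivation: imputed onset ages as events,
# last scan age as the censoring time
.stepwiseSurvival <- function(cohort, onsets) {
    am <- amyloidScans(cohort)
    lastScan <- vapply(split(am$scan_age, am$participant_id), max, 0)
    ids <- colnames(cohort)
    i <- match(ids, onsets$participant_id)
    ev <- onsets$status[i] == "event"
    data.frame(time = ifelse(ev, onsets$onset_age[i], lastScan[ids]),
               event = as.integer(ev), row.names = NULL)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — input loading, onset imputation
#' (progression curve, then per-participant onset ages, which the score
#' stage needs as its survival outcome), score derivation (candidate
#' screen, forward stepwise Cox with forced APOE variants, scoring,
#' stratification), cognitive composites, association models
#' (cross-sectional amyloid regressions with FDR and subgroups,
#' longitudinal mixed models with likelihood-ratio tests, AIC backward
#' selection, simple-effect slopes, the ROI atrophy panel) and the
#' onset survival analysis (Cox and Kaplan-Meier). Each stage's outputs
#' are written to `config$outputDir` before the next begins; a failure
#' aborts the run with the stage name, recorded in the report.
#'
#' @param config a [runConfig()].
#' @return invisibly, the run state: every intermediate result plus the
#'   report written by [writeReport()].
#' @export
runPipeline <- function(config) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    state <- list(config = config, warnings = character(),
                  stageRows = list(), outputs = character(),
                  formulas = list(), stage = "load", failed = NULL)
    emit <- function(obj, name) {
        f <- file.path(config$outputDir, name)
        utils::write.csv(obj, f, row.names = FALSE)
        state$outputs <<- c(state$outputs, f)
        f
    }
    collect <- function(expr) withCallingHandlers(expr,
        warning = function(w) {
            state$warnings <<- c(state$warnings, conditionMessage(w))
            invokeRestart("muffleWarning")
        })
    runStage <- function(name, expr) {
        state$stage <<- name
        tryCatch(collect(expr), error = function(e) {
            state$failed <<- name
            writeReport(state)
            stopf("pipeline failed at stage '%s': %s", name,
                  conditionMessage(e))
        })
    }
    runStage("load", {
        inputs <- loadInputs(config)
        state$cohort <- inputs$cohort
        state$summaryStats <- inputs$summaryStats
        pt <- participants(state$cohort)
        pt <- cbind(participant_id = rownames(pt), pt)
        state$participants <- pt
        emit(pt, "participants.csv")
        writeDosageTsv(dosages(state$cohort),
                       file.path(config$outputDir, "dosages.tsv"))
        state$outputs <- c(state$outputs,
                           file.path(config$outputDir, "dosages.tsv"))
        state$stageRows$load <- c(participants = nrow(pt),
                                  variants = nrow(state$cohort))
    })
    runStage("onset", {
        am <- amyloidScans(state$cohort)
        state$curve <- fitProgressionCurve(am,
                                           threshold = config$clThreshold)
        state$onsets <- estimateOnsetAge(am, state$curve)
        emit(data.frame(tau = state$curve@tau, cl = state$curve@cl),
             "progression_curve.csv")
        emit(state$onsets, "onsets.csv")
        state$stageRows$onset <- c(events = sum(state$onsets$status ==
                                                "event"),
                                   censored = sum(state$onsets$status ==
                                                  "censored"))
    })
    runStage("score", {
        cands <- filterCandidateSnps(state$summaryStats, config$pThreshold)
        cands <- setdiff(cands, c("APOE_e4", "APOE_e2"))
        surv <- .stepwiseSurvival(state$cohort, state$onsets)
        vi <- data.frame(id = state$summaryStats$snp_id,
                         effectAllele = state$summaryStats$effect_allele)
        state$panel <- forwardStepwiseCox(
            cands, dosages(state$cohort), surv,
            alphaEntry = config$alphaEntry, maxSnps = config$maxSnps,
            summaryStats = state$summaryStats, variantInfo = vi)
        phs <- computePhs(dosages(state$cohort), state$panel)
        state$phs <- stratifyPhs(phs, config$phsThresholds)
        writePanelTsv(state$panel,
                      file.path(config$outputDir, "panel.tsv"))
        state$outputs <- c(state$outputs,
                           file.path(config$outputDir, "panel.tsv"))
        emit(data.frame(participant_id = names(phsScores(state$phs)),
                        phs = phsScores(state$phs),
                        stratum = as.character(phsStrata(state$phs))),
             "phs.csv")
        state$stageRows$score <- c(candidates = length(cands),
                                   selected = sum(!panelTable(
                                       state$panel)$forced))
    })
    runStage("composites", {
        cog <- cognitionScores(state$cohort)
        tests <- cog[cog$test != "cdr_sb", , drop = FALSE]
        firstAge <- stats::ave(tests$visit_age, tests$participant_id,
                               FUN = min)
        baseline <- tests[tests$visit_age == firstAge, , drop = FALSE]
        pt <- state$participants
        cnIds <- pt$participant_id[pt$diagnosis == "CN"]
        state$normRef <- buildNormReference(baseline, cnIds)
        state$composites <- do.call(rbind, lapply(
            defaultCompositeSpecs(), function(sp)
                computeComposite(tests, sp, state$normRef)))
        cdr <- cog[cog$test == "cdr_sb", , drop = FALSE]
        state$composites <- rbind(state$composites,
            data.frame(participant_id = cdr$participant_id,
                       visit_age = cdr$visit_age, composite = "cdr_sb",
                       value = cdr$score, n_tests = 1L))
        emit(state$composites, "composites.csv")
        state$stageRows$composites <- c(rows = nrow(state$composites))
    })
    runStage("associations", {
        am <- amyloidScans(state$cohort)
        firstAge <- stats::ave(am$scan_age, am$participant_id, am$region,
                               FUN = min)
        base <- am[am$scan_age == firstAge, , drop = FALSE]
        pt <- state$participants
        wide <- data.frame(participant_id = pt$participant_id,
                           phs = phsScores(state$phs)[pt$participant_id],
                           age = pt$baselineAge,
                           sex = as.integer(pt$sex == "male"),
                           education = pt$educationYears,
                           apoe = as.integer(pt$apoeE4Count > 0))
        for (rg in amyloidRegions()) {
            b <- base[base$region == rg, ]
            wide[[paste0("cl_", rg)]] <-
                b$centiloid[match(wide$participant_id, b$participant_id)]
        }
        ocs <- paste0("cl_", amyloidRegions())
        xs <- fitCrossSectional(wide, ocs)
        xs$population <- "all"
        if (config$subgroups) {
            for (sg in c("e4_carriers", "e4_noncarriers")) {
                x <- fitCrossSectional(wide, ocs, subgroup = sg)
                x$population <- sg
                xs <- rbind(xs, x)
            }
        }
        state$crossSectional <- xs
        emit(xs, "cross_sectional.csv")
        long <- list()
        for (dom in unique(state$composites$composite)) {
            oc <- state$composites[state$composites$composite == dom,
                                   c("participant_id", "visit_age",
                                     "value")]
            d <- assembleLongitudinalData(state$cohort, state$phs, oc)
            fit <- fitLongitudinal(d,
                                   timeMainEffect = config$timeMainEffect)
            red <- fitLongitudinal(d, terms = setdiff(fit$terms, "phs"),
                                   timeMainEffect = config$timeMainEffect)
            lrt <- likelihoodRatioTest(fit, red)
            sel <- backwardSelectAic(d,
                                     timeMainEffect = config$timeMainEffect)
            slopes <- simpleEffectSlopes(fit)
            tab <- fit$table
            tab$domain <- dom
            tab$lrt_p_phs <- lrt$p
            tab$retained_after_aic <- paste(sel$terms, collapse = "+")
            long[[dom]] <- list(fit = fit, lrt = lrt, selection = sel,
                                slopes = slopes)
            state$formulas[[dom]] <- deparse(fit$formula)
            state$longitudinalTable <- rbind(state$longitudinalTable, tab)
        }
        state$longitudinal <- long
        emit(state$longitudinalTable, "longitudinal.csv")
        vol <- roiVolumes(state$cohort)
        nonAd <- pt$participant_id[pt$diagnosis != "AD"]
        state$atrophy <- runAtrophyPanel(
            vol[vol$participant_id %in% nonAd, ],
            wide[, c("participant_id", "phs", "sex", "education", "apoe")])
        emit(state$atrophy, "atrophy_panel.csv")
        state$stageRows$associations <-
            c(cross_sectional = nrow(xs),
              longitudinal_models = length(long),
              atrophy_rois = nrow(state$atrophy))
    })
    runStage("onset_survival", {
        am <- amyloidScans(state$cohort)
        lastScan <- vapply(split(am$scan_age, am$participant_id), max, 0)
        followup <- data.frame(participant_id = names(lastScan),
                               censor_age = unname(lastScan),
                               censor_reason = "end_of_followup")
        state$survivalTable <- buildSurvivalTable(
            state$participants, state$onsets, followup, state$phs,
            e3e3Only = config$e3e3Only)
        state$cox <- fitCoxPh(state$survivalTable,
                              truncate = config$truncate)
        state$km <- kmCompare(state$survivalTable,
                              truncate = config$truncate)
        emit(state$survivalTable, "survival_table.csv")
        emit(kmCurvePoints(state$km), "km_curves.csv")
        emit(state$km$medians, "km_medians.csv")
        state$stageRows$onset_survival <-
            c(n = nrow(state$survivalTable),
              events = sum(state$survivalTable$event))
    })
    state$stage <- "report"
    state$report <- writeReport(state)
    invisible(state)
}

#' Write the run report
#'
#' JSON report with the package version, the configuration hash,
#' per-stage row counts, the fitted model formulas, accumulated
#' warnings and a manifest of every output file with its MD5 checksum.
#' Aborted runs report the failing stage.
#'
#' @param state pipeline state (see [runPipeline()]).
#' @param path report path; defaults to `run_report.json` in the output
#'   directory.
#' @return invisibly, the report list.
#' @export
writeReport <- function(state,
                        path = file.path(state$config$outputDir,
                                         "run_report.json")) {
    manifest <- lapply(state$outputs, function(f)
        list(file = basename(f), md5 = unname(tools::md5sum(f))))
    report <- list(
        package = "PolygenicHazard",
        version = as.character(utils::packageVersion("PolygenicHazard")),
        config_hash = configHash(state$config),
        seed = state$config$seed,
        failed_stage = state$failed,
        stage_rows = state$stageRows,
        model_formulas = state$formulas,
        warnings = state$warnings,
        manifest = manifest)
    jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                         null = "null")
    invisible(report)
}
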