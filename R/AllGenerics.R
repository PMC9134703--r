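#' @rdname SnpPanel-class
#' @param object,x an object.
#' @export
setGeneric("panelTable", function(x) standardGeneric("panelTable"))

#' @rdname SnpPanel-class
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname SnpPanel-class
#' @export
setGeneric("panelWeights", function(x) standardGeneric("panelWeights"))

#' @rdname PhsResult-class
#' @export
setGeneric("phsScores", function(x) standardGeneric("phsScores"))

#' @rdname PhsResult-class
#' @export
setGeneric("phsStrata", function(x) standardGeneric("phsStrata"))

#' @rdname PhsResult-class
#' @export
setGeneric("phsThresholds", function(x) standardGeneric("phsThresholds"))

#' @rdname ProgressionCurve-class
#' @param curve a [ProgressionCurve-class] object.
#' @param tau disease time(s) in years.
#' @export
setGeneric("predictCL", function(curve, tau) standardGeneric("predictCL"))

#' @rdname ProgressionCurve-class
#' @param cl Centiloid value(s).
#' @export
setGeneric("diseaseTime", function(curve, cl) standardGeneric("diseaseTime"))

#' @rdname AmyloidCohort-class
#' @export
setGeneric("amyloidScans", function(x) standardGeneric("amyloidScans"))

#' @rdname AmyloidCohort-class
#' @export
setGeneric("roiVolumes", function(x) standardGeneric("roiVolumes"))

#' @rdname AmyloidCohort-class
#' @export
setGeneric("cognitionScores", function(x) standardGeneric("cognitionScores"))

#' @rdname AmyloidCohort-class
#' @export
setGeneric("participants", function(x) standardGeneric("participants"))

#' @rdname AmyloidCohort-class
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

setMethod("panelTable", "SnpPanel", function(x) x@panel)
setMethod("snpIds", "SnpPanel", function(x) as.character(x@panel$id))
setMethod("panelWeights", "SnpPanel", function(x) {
    w <- x@panel$weight
    names(w) <- x@panel$id
    w
})

setMethod("phsScores", "PhsResult", function(x) x@score)
setMethod("phsStrata", "PhsResult", function(x) x@stratum)
setMethod("phsThresholds", "PhsResult", function(x) x@thresholds)

setMethod("amyloidScans", "AmyloidCohort", function(x) x@amyloid)
setMethod("roiVolumes", "AmyloidCohort", function(x) x@volumes)
setMethod("cognitionScores", "AmyloidCohort", function(x) x@cognition)
setMethod("participants", "AmyloidCohort",
    function(x) as.data.frame(SummarizedExperiment::colData(x)))
setMethod("dosages", "AmyloidCohort",
    function(x) SummarizedExperiment::assay(x, "dosage"))

setMethod("show", "SnpPanel", function(object) {
    p <- object@panel
    cat(sprintf("SnpPanel with %d variants (%d forced)\n",
                nrow(p), sum(p$forced)))
    if (nrow(p)) {
        show(utils::head(as.data.frame(p), 5L))
        if (nrow(p) > 5L) cat("...\n")
    }
})

setMethod("show", "PhsResult", function(object) {
    cat(sprintf("PhsResult for %d individuals\n", length(object@score)))
    cat(sprintf("  score: mean %.3f, sd %.3f\n",
                mean(object@score), stats::sd(object@score)))
    if (length(object@stratum))
        cat("  strata:", paste(sprintf("%s=%d", levels(object@stratum),
            tabulate(object@stratum, 3L)), collapse = " "), "\n")
})

setMethod("show", "ProgressionCurve", function(object) {
    cat(sprintf(paste0("ProgressionCurve: CL(0) = %.1f, range [%.1f, %.1f] CL",
                       " over tau [%.1f, %.1f] years\n"),
        object@threshold, min(object@cl), max(object@cl),
        min(object@tau), max(object@tau)))
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0("SimulationConfig: %d participants, %d SNPs + 2 APOE",
                       " variants, seed %d\n"),
        object@nParticipants, object@nSnps, object@seed))
    cat(sprintf("  Gompertz baseline: rate %.3g/y, shape %.3g/y; horizon %g y\n",
        object@baselineHazard[["rate"]], object@baselineHazard[["shape"]],
        object@horizonAge))
    cat(sprintf("  visits every %.2g y (max %d, dropout %.2g); CL noise sd %.2g\n",
        object@visitInterval, object@maxVisits, object@dropoutProb,
        object@clNoiseSd))
})
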