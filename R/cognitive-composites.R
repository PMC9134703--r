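#' Specify a cognitive composite
#'
#' A composite averages z-standardised constituent tests; the direction
#' flips tests where higher raw scores mean worse performance (timed
#' tasks, error counts).
#'
#' @param name composite name.
#' @param tests character vector of constituent test names.
#' @param directions +1 (higher is better) or -1 per test; recycled.
#' @return list of class `CompositeSpec`.
#' @export
compositeSpec <- function(name, tests, directions = 1) {
    if (!length(tests)) stopf("composite needs at least one constituent")
    directions <- rep_len(directions, length(tests))
    if (!all(directions %in% c(-1, 1)))
        stopf("directions must be +1 or -1")
    structure(list(name = name, tests = tests, directions = directions),
              class = "CompositeSpec")
}

#' Default composite definitions for the synthetic battery
#'
#' Recognition memory (list-learning and complex-figure recognition),
#' executive function (verbal fluency and category switching) and episodic
#' recall (list learning, story recall, figure recall) composites over the
#' synthetic test names emitted by [generateLongitudinalOutcomes()].
#'
#' @return named list of `CompositeSpec`s.
#' @export
defaultCompositeSpecs <- function() {
    list(recognition = compositeSpec("recognition", c("cvlt", "rcft")),
         executive_function = compositeSpec("executive_function",
                                            c("cowat", "category_switching")),
         episodic_recall = compositeSpec("episodic_recall",
                                         c("cvlt", "lmii", "rcft")))
}

#' Build a normative reference from cognitively normal baselines
#'
#' Per-test mean and standard deviation over the baseline visit of the
#' cognitively normal participants only.
#'
#' @param baseline data.frame `participant_id`, `test`, `score` (one row
#'   per participant and test; baseline visit only).
#' @param cnIds participant ids classified as cognitively normal.
#' @return data.frame `test`, `mean`, `sd`, `n` of class `NormReference`.
#' @export
buildNormReference <- function(baseline, cnIds) {
    b <- baseline[baseline$participant_id %in% cnIds &
                  !is.na(baseline$score), , drop = FALSE]
    if (!nrow(b)) stopf("no cognitively normal baseline scores")
    sp <- split(b$score, b$test)
    ns <- vapply(sp, length, 0L)
    if (any(ns < 2L))
        stopf("fewer than 2 CN baseline scores for test(s): %s",
              paste(names(sp)[ns < 2L], collapse = ", "))
    sds <- vapply(sp, stats::sd, 0)
    if (any(sds == 0))
        stopf("zero CN baseline SD for test(s): %s",
              paste(names(sp)[sds == 0], collapse = ", "))
    out <- data.frame(test = names(sp),
                      mean = vapply(sp, mean, 0),
                      sd = sds, n = ns, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    class(out) <- c("NormReference", "data.frame")
    out
}

#' Compute a cognitive composite per participant-visit
#'
#' Each constituent is standardised against the normative reference,
#' `z = direction * (score - mean) / sd`, and the composite is the mean of
#' the available standardised constituents. By default a visit missing
#' some (but not all) constituents averages over what is available; in
#' strict mode any missing constituent yields a missing composite. Visits
#' missing every constituent always propagate `NA`.
#'
#' @param scores long data.frame `participant_id`, `visit_age`, `test`,
#'   `score`.
#' @param spec a [compositeSpec()].
#' @param reference a [buildNormReference()] result covering all
#'   constituents.
#' @param strict require all constituents present at a visit.
#' @return data.frame `participant_id`, `visit_age`, `composite`, `value`,
#'   `n_tests`.
#' @export
computeComposite <- function(scores, spec, reference, strict = FALSE) {
    missingRef <- setdiff(spec$tests, reference$test)
    if (length(missingRef))
        stopf("reference lacks test(s): %s",
              paste(missingRef, collapse = ", "))
    s <- scores[scores$test %in% spec$tests, , drop = FALSE]
    j <- match(s$test, reference$test)
    dir <- spec$directions[match(s$test, spec$tests)]
    s$z <- dir * (s$score - reference$mean[j]) / reference$sd[j]
    key <- interaction(s$participant_id, s$visit_age, drop = TRUE)
    agg <- lapply(split(s, key), function(d) {
        z <- d$z[!is.na(d$z)]
        nAvail <- length(z)
        val <- if (nAvail == 0L || (strict && nAvail < length(spec$tests)))
            NA_real_ else mean(z)
        data.frame(participant_id = d$participant_id[1L],
                   visit_age = d$visit_age[1L], composite = spec$name,
                   value = val, n_tests = nAvail, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, agg)
    out <- out[order(out$participant_id, out$visit_age), , drop = FALSE]
    rownames(out) <- NULL
    out
}
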