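#' Build the birth-to-onset survival table
#'
#' One row per high- or low-PHS participant (the mid stratum is excluded
#' from the onset analysis). Survival time is the number of years from
#' birth to (a) the imputed age of amyloid onset (an event), (b) the age
#' of withdrawal from the study (censored), or (c) the age at the last
#' completed follow-up without an event (censored).
#'
#' @param participantTable data.frame, one row per participant:
#'   `participant_id`, `baselineAge`, `sex`, `educationYears`, and
#'   optionally `apoeE4Count`/`apoeE2Count` (for the epsilon-3/3
#'   subgroup filter).
#' @param onsetEstimates output of [estimateOnsetAge()].
#' @param followup data.frame `participant_id`, `censor_age` (withdrawal
#'   or last-exam age), optional `censor_reason` in `withdrew`,
#'   `end_of_followup`.
#' @param strata a [PhsResult-class] with strata, or a factor/character
#'   vector named by participant id.
#' @param e3e3Only restrict to APOE epsilon-3 homozygotes (no e4, no e2
#'   pseudo-allele).
#' @return data.frame `participant_id`, `entry` (study-entry age), `time`,
#'   `event`, `stratum`, `baseline_age`, `sex`, `education`.
#' @export
buildSurvivalTable <- function(participantTable, onsetEstimates, followup,
                               strata, e3e3Only = FALSE) {
    st <- if (is(strata, "PhsResult")) {
        s <- phsStrata(strata)
        stats::setNames(as.character(s), names(phsScores(strata)))
    } else stats::setNames(as.character(strata), names(strata))
    pt <- participantTable
    if (e3e3Only) {
        if (!all(c("apoeE4Count", "apoeE2Count") %in% names(pt)))
            stopf("e3e3Only requires apoeE4Count and apoeE2Count columns")
        pt <- pt[pt$apoeE4Count == 0 & pt$apoeE2Count == 0, , drop = FALSE]
    }
    pt <- pt[st[pt$participant_id] %in% c("low", "high"), , drop = FALSE]
    i <- match(pt$participant_id, onsetEstimates$participant_id)
    j <- match(pt$participant_id, followup$participant_id)
    if (anyNA(i) || anyNA(j))
        stopf("every participant needs an onset estimate and a %s",
              "follow-up record")
    isEvent <- onsetEstimates$status[i] == "event"
    onset <- onsetEstimates$onset_age[i]
    censorAge <- followup$censor_age[j]
    if (any(!isEvent & !is.na(onset)))
        stopf("censored onset record(s) carry an onset age; inconsistent")
    if (any(isEvent & is.na(onset)))
        stopf("event record(s) without an onset age; inconsistent")
    time <- ifelse(isEvent, onset, censorAge)
    if (any(time <= 0)) stopf("non-positive survival times")
    out <- data.frame(participant_id = pt$participant_id,
                      entry = pt$baselineAge,
                      time = time,
                      event = as.integer(isEvent),
                      stratum = factor(st[pt$participant_id],
                                       levels = c("low", "high")),
                      baseline_age = pt$baselineAge,
                      sex = as.integer(pt$sex == "male"),
                      education = pt$educationYears,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

# drop records incompatible with delayed entry (event imputed before the
# study-entry age); returns the table plus how many rows went
.applyTruncation <- function(table) {
    bad <- table$time <= table$entry
    if (any(bad))
        warnf("%d record(s) with onset at or before study entry dropped %s",
              sum(bad), "under left truncation")
    table[!bad, , drop = FALSE]
}

#' Cox proportional-hazards comparison of high versus low PHS
#'
#' Hazard of reaching abnormal amyloid, high versus low stratum, adjusted
#' for baseline age, sex and years of education; ties handled by the
#' Efron approximation. The default uses the literal from-birth time
#' scale; `truncate = TRUE` adds delayed entry at the study-entry age
#' (records whose imputed onset precedes entry are dropped, since they
#' are observable only because imputation reaches before entry).
#'
#' @param table a [buildSurvivalTable()] result.
#' @param covariates adjustment columns of `table`.
#' @param truncate use left truncation at study entry.
#' @return list with `hr`, `ci` (95%), `p` (Wald), `coefTable`, `n`,
#'   `nEvents`, `fit`.
#' @export
fitCoxPh <- function(table, covariates = c("baseline_age", "sex",
                                           "education"),
                     truncate = FALSE) {
    if (truncate) table <- .applyTruncation(table)
    counts <- table(table$stratum, table$event)
    if (any(rowSums(counts[, "1", drop = FALSE]) < 1))
        stopf("each stratum needs at least one event")
    resp <- if (truncate) "survival::Surv(entry, time, event)"
            else "survival::Surv(time, event)"
    fml <- stats::as.formula(paste(resp, "~",
        paste(c("stratum", covariates), collapse = " + ")))
    msg <- NULL
    fit <- withCallingHandlers(
        survival::coxph(fml, data = table, ties = "efron"),
        warning = function(w) {
            msg <<- conditionMessage(w); invokeRestart("muffleWarning")
        })
    co <- stats::coef(fit)
    if ((!is.null(msg) && grepl("infinite", msg)) ||
        any(abs(co) > 15, na.rm = TRUE))
        stopf("monotone partial likelihood (complete separation); %s",
              "consider penalized Cox regression")
    sm <- summary(fit)
    k <- "stratumhigh"
    list(hr = unname(sm$conf.int[k, "exp(coef)"]),
         ci = unname(sm$conf.int[k, c("lower .95", "upper .95")]),
         p = unname(sm$coefficients[k, "Pr(>|z|)"]),
         coefTable = sm$coefficients,
         n = nrow(table), nEvents = sum(table$event), fit = fit)
}

#' Kaplan-Meier comparison of onset age between PHS strata
#'
#' Product-limit survival per stratum with complementary log-log
#' confidence intervals; the median onset age is the first age at which
#' the survival curve drops to 0.5 or below (absent when the curve never
#' reaches it), and strata are compared by the log-rank test.
#'
#' @param table a [buildSurvivalTable()] result.
#' @param truncate use left truncation at study entry.
#' @param riskAges optional age grid for numbers at risk.
#' @return list with `medians` (data.frame per stratum: median and 95%
#'   CI), `logrank` (`statistic`, `p`), `atRisk`, `fit`.
#' @export
kmCompare <- function(table, truncate = FALSE, riskAges = NULL) {
    if (truncate) table <- .applyTruncation(table)
    if (sum(table$event) == 0)
        stopf("no events in the survival table; log-rank undefined")
    resp <- if (truncate) "survival::Surv(entry, time, event)"
            else "survival::Surv(time, event)"
    fit <- survival::survfit(
        stats::as.formula(paste(resp, "~ stratum")), data = table,
        conf.type = "log-log")
    tb <- summary(fit)$table
    medians <- data.frame(
        stratum = sub("stratum=", "", rownames(tb)),
        n = tb[, "records"], events = tb[, "events"],
        median = tb[, "median"], ci_lower = tb[, "0.95LCL"],
        ci_upper = tb[, "0.95UCL"], stringsAsFactors = FALSE)
    rownames(medians) <- NULL
    sd <- survival::survdiff(
        stats::as.formula(paste(resp, "~ stratum")), data = table)
    p <- stats::pchisq(sd$chisq, length(sd$n) - 1, lower.tail = FALSE)
    atRisk <- NULL
    if (!is.null(riskAges)) {
        sm <- summary(fit, times = riskAges, extend = TRUE)
        atRisk <- data.frame(stratum = sub("stratum=", "",
                                           as.character(sm$strata)),
                             age = sm$time, n_risk = sm$n.risk,
                             survival = sm$surv)
    }
    list(medians = medians,
         logrank = list(statistic = sd$chisq, p = p),
         atRisk = atRisk, fit = fit)
}

#' Kaplan-Meier curve points for plotting
#'
#' @param km a [kmCompare()] result.
#' @return data.frame `stratum`, `age`, `survival`, `ci_lower`,
#'   `ci_upper`.
#' @export
kmCurvePoints <- function(km) {
    fit <- km$fit
    strata <- rep(sub("stratum=", "", names(fit$strata)), fit$strata)
    data.frame(stratum = strata, age = fit$time, survival = fit$surv,
               ci_lower = fit$lower, ci_upper = fit$upper,
               stringsAsFactors = FALSE)
}
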