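#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement, order-preserving with
#' the input vector. Adjusted p-values are never smaller than the raw
#' ones.
#'
#' @param p numeric vector of p-values in [0, 1] (NAs propagate).
#' @return adjusted p-values in input order.
#' @export
fdrAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stopf("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Cross-sectional regression of baseline amyloid on the PHS
#'
#' Ordinary least squares of baseline Centiloid on the polygenic hazard
#' score per region, controlling for age, sex, years of education and
#' binary APOE epsilon-4 status. In the carrier and non-carrier subgroups
#' the APOE covariate is dropped automatically (no variation). FDR
#' adjustment is applied to the predictor's p-values across the region
#' family.
#'
#' @param data data.frame with one row per participant: the outcome
#'   columns, the predictor, and covariate columns `age`, `sex`,
#'   `education`, `apoe` (0/1).
#' @param outcomes names of the outcome columns (one per region).
#' @param predictor name of the score column.
#' @param covariates adjustment covariates.
#' @param subgroup one of `all`, `e4_carriers`, `e4_noncarriers`.
#' @return data.frame, one row per outcome and term, with `beta`, `se`,
#'   `ci_lower`, `ci_upper`, `p`, and `p_fdr` on the predictor rows.
#' @export
fitCrossSectional <- function(data, outcomes, predictor = "phs",
                              covariates = c("age", "sex", "education",
                                             "apoe"),
                              subgroup = c("all", "e4_carriers",
                                           "e4_noncarriers")) {
    subgroup <- match.arg(subgroup)
    if (subgroup != "all") {
        keep <- if (subgroup == "e4_carriers") data$apoe == 1
                else data$apoe == 0
        data <- data[keep, , drop = FALSE]
        covariates <- setdiff(covariates, "apoe")
    }
    res <- lapply(outcomes, function(oc) {
        vars <- c(oc, predictor, covariates)
        cc <- stats::complete.cases(data[, vars])
        d <- data[cc, vars, drop = FALSE]
        fml <- stats::reformulate(c(predictor, covariates), response = oc)
        mm <- stats::model.matrix(fml, d)
        qrm <- qr(mm)
        if (qrm$rank < ncol(mm))
            stopf("rank-deficient design for %s; collinear column(s): %s",
                  oc, paste(colnames(mm)[qrm$pivot[-seq_len(qrm$rank)]],
                            collapse = ", "))
        fit <- stats::lm(fml, data = d)
        sm <- summary(fit)$coefficients
        ci <- waldCI(sm[, 1], sm[, 2])
        data.frame(outcome = oc, term = rownames(sm), beta = sm[, 1],
                   se = sm[, 2], ci_lower = ci[, 1], ci_upper = ci[, 2],
                   p = sm[, 4], n = nrow(d), stringsAsFactors = FALSE,
                   row.names = NULL)
    })
    out <- do.call(rbind, res)
    out$p_fdr <- NA_real_
    isPred <- out$term == predictor
    out$p_fdr[isPred] <- fdrAdjust(out$p[isPred])
    out
}

#' Likelihood-ratio test between nested model fits
#'
#' `statistic = 2 (logLik_full - logLik_reduced)` referred to a chi-square
#' distribution with degrees of freedom equal to the parameter-count
#' difference. Both fits must be maximum-likelihood fits on the same rows.
#'
#' @param full,reduced fitted models (`lm`, `lmerMod`, or a
#'   [fitLongitudinal()] result).
#' @return list with `statistic`, `df`, `p`.
#' @export
likelihoodRatioTest <- function(full, reduced) {
    getFit <- function(x) if (inherits(x, "LongitudinalFit")) x$fit else x
    full <- getFit(full); reduced <- getFit(reduced)
    llF <- stats::logLik(full); llR <- stats::logLik(reduced)
    nF <- stats::nobs(full); nR <- stats::nobs(reduced)
    if (nF != nR)
        stopf("models were fitted on different numbers of rows (%d vs %d)",
              nF, nR)
    df <- attr(llF, "df") - attr(llR, "df")
    if (df < 0)
        stopf("the reduced model has more parameters than the full model")
    stat <- max(0, 2 * (as.numeric(llF) - as.numeric(llR)))
    p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
    list(statistic = stat, df = df, p = p)
}

# centre and scale the continuous covariates of a longitudinal model frame
.scaleContinuous <- function(d, vars) {
    info <- list()
    for (v in intersect(vars, names(d))) {
        mu <- mean(d[[v]], na.rm = TRUE)
        sdv <- stats::sd(d[[v]], na.rm = TRUE)
        if (!is.finite(sdv) || sdv == 0) sdv <- 1
        d[[v]] <- (d[[v]] - mu) / sdv
        info[[v]] <- c(mean = mu, sd = sdv)
    }
    attr(d, "scaling") <- info
    d
}

.longitudinalFormula <- function(terms, timeMainEffect, random = TRUE) {
    rhs <- paste(sprintf("%s:time", terms), collapse = " + ")
    if (timeMainEffect) rhs <- paste("time", rhs, sep = " + ")
    if (random) rhs <- paste(rhs, "+ (1 | participant_id)")
    stats::as.formula(paste("value ~", rhs))
}

#' Fit the longitudinal interaction-with-time mixed model
#'
#' The change model for an outcome c is
#' `c = b0 + b1 PHS*Time + b2 Centiloid(frontal)*Time +
#' b3 entorhinal volume*Time + b4 baseline age*Time + b5 Sex*Time +
#' b6 Education*Time + b7 APOE*Time + (1 | participant)`,
#' with Time in years since the baseline visit and continuous covariates
#' centred and scaled. The model is interaction-only (no Time main
#' effect) as printed; `timeMainEffect = TRUE` adds one. Fitting is by
#' maximum likelihood by default so likelihood-ratio tests on fixed
#' effects are valid; p-values use Satterthwaite degrees of freedom. A
#' singular random-intercept fit falls back to ordinary least squares
#' with a flag.
#'
#' @param data model frame with columns `value`, `time`,
#'   `participant_id`, and the covariate columns named in `terms`.
#' @param terms covariates interacting with time, in the order of the
#'   model's coefficients.
#' @param timeMainEffect add a Time main effect.
#' @param reml use restricted maximum likelihood instead of ML.
#' @param scaleVars continuous covariates to centre and scale.
#' @return object of class `LongitudinalFit`: list with `fit`, `table`
#'   (term, beta, se, ci, p), `formula`, `n`, `nParticipants`,
#'   `singular`, `olsFallback`, `scaling`.
#' @export
fitLongitudinal <- function(data,
                            terms = c("phs", "cl_frontal", "entorhinal",
                                      "baseline_age", "sex", "education",
                                      "apoe"),
                            timeMainEffect = FALSE, reml = FALSE,
                            scaleVars = c("phs", "cl_frontal", "entorhinal",
                                          "baseline_age", "education")) {
    need <- c("value", "time", "participant_id", terms)
    missingCols <- setdiff(need, names(data))
    if (length(missingCols))
        stopf("model frame lacks column(s): %s",
              paste(missingCols, collapse = ", "))
    data <- data[stats::complete.cases(data[, need]), need, drop = FALSE]
    nPerId <- table(data$participant_id)
    if (mean(nPerId >= 2) < 0.5)
        warnf("fewer than half the participants have >= 2 visits")
    data <- .scaleContinuous(data, scaleVars)
    fml <- .longitudinalFormula(terms, timeMainEffect)
    fit <- suppressMessages(lmerTest::lmer(fml, data = data, REML = reml))
    singular <- lme4::isSingular(fit)
    olsFallback <- FALSE
    if (singular) {
        warnf("random-intercept variance is zero; degenerating to OLS")
        fit <- stats::lm(.longitudinalFormula(terms, timeMainEffect,
                                              random = FALSE), data = data)
        olsFallback <- TRUE
    }
    sm <- summary(fit)$coefficients
    pcol <- ncol(sm)  # lmerTest: Pr(>|t|) in col 5; lm: col 4
    ci <- waldCI(sm[, 1], sm[, 2])
    tab <- data.frame(term = rownames(sm), beta = sm[, 1], se = sm[, 2],
                      ci_lower = ci[, 1], ci_upper = ci[, 2], p = sm[, pcol],
                      stringsAsFactors = FALSE, row.names = NULL)
    structure(list(fit = fit, table = tab, formula = fml, n = nrow(data),
                   nParticipants = length(nPerId), terms = terms,
                   timeMainEffect = timeMainEffect,
                   singular = singular, olsFallback = olsFallback,
                   reml = reml, scaling = attr(data, "scaling"),
                   data = data),
              class = "LongitudinalFit")
}

#' @export
print.LongitudinalFit <- function(x, ...) {
    cat("Longitudinal mixed model (", if (x$olsFallback) "OLS fallback"
        else if (x$reml) "REML" else "ML", ")\n", sep = "")
    cat("  ", deparse(x$formula), "\n", sep = "")
    cat(sprintf("  %d observations, %d participants\n", x$n,
                x$nParticipants))
    print(x$table, digits = 3)
    invisible(x)
}

#' Backward AIC selection over the interaction terms
#'
#' Starting from the full interaction-with-time model, repeatedly drops
#' the covariate-by-time term whose removal lowers the AIC the most,
#' stopping when no removal lowers it. The intercept and the random
#' intercept are never dropped. Fits use maximum likelihood so AICs are
#' comparable.
#'
#' @param data model frame as for [fitLongitudinal()].
#' @param terms interaction covariates of the full model.
#' @param timeMainEffect add a Time main effect throughout.
#' @return list with `terms` (retained), `fit` (the reduced
#'   `LongitudinalFit`), and `trace` (data.frame of steps).
#' @export
backwardSelectAic <- function(data,
                              terms = c("phs", "cl_frontal", "entorhinal",
                                        "baseline_age", "sex", "education",
                                        "apoe"),
                              timeMainEffect = FALSE) {
    current <- terms
    fit <- fitLongitudinal(data, terms = current,
                           timeMainEffect = timeMainEffect)
    aicCur <- stats::AIC(fit$fit)
    trace <- data.frame(dropped = NA_character_, aic = aicCur,
                        stringsAsFactors = FALSE)
    while (length(current) > 1L) {
        aics <- vapply(current, function(tm) {
            f <- suppressWarnings(
                fitLongitudinal(data, terms = setdiff(current, tm),
                                timeMainEffect = timeMainEffect))
            stats::AIC(f$fit)
        }, 0)
        if (min(aics) >= aicCur) break
        drop <- names(which.min(aics))
        current <- setdiff(current, drop)
        fit <- suppressWarnings(
            fitLongitudinal(data, terms = current,
                            timeMainEffect = timeMainEffect))
        aicCur <- stats::AIC(fit$fit)
        trace <- rbind(trace, data.frame(dropped = drop, aic = aicCur))
    }
    list(terms = current, fit = fit, trace = trace)
}

#' Simple-effect slopes at high and low PHS
#'
#' Annual outcome change implied by the fitted model at fixed PHS levels
#' (default plus and minus one SD on the centred/scaled score, other
#' covariates at their centred zero): `slope(level) = b_Time + level *
#' b_PHSxTime` (`b_Time = 0` for the interaction-only model). The
#' difference between the two slopes and its delta-method standard error
#' are reported.
#'
#' @param fit a [fitLongitudinal()] result containing a PHS-by-time term.
#' @param levels numeric(2), PHS levels on the standardized scale.
#' @return data.frame with one row per level plus a `difference` row.
#' @export
simpleEffectSlopes <- function(fit, levels = c(-1, 1)) {
    stopifnot(inherits(fit, "LongitudinalFit"))
    V <- as.matrix(stats::vcov(fit$fit))
    beta <- if (inherits(fit$fit, "lm")) stats::coef(fit$fit)
            else lme4::fixef(fit$fit)
    nm <- names(beta)
    iInt <- which(nm %in% c("phs:time", "time:phs"))
    if (!length(iInt))
        stopf("model does not contain a PHS-by-time interaction")
    iTime <- which(nm == "time")
    contrast <- function(level) {
        k <- numeric(length(beta))
        k[iInt] <- level
        if (length(iTime)) k[iTime] <- 1
        k
    }
    rows <- lapply(levels, function(lv) {
        k <- contrast(lv)
        est <- sum(k * beta)
        se <- sqrt(drop(t(k) %*% V %*% k))
        data.frame(level = lv, slope = est, se = se,
                   ci_lower = est - 1.96 * se, ci_upper = est + 1.96 * se)
    })
    kd <- contrast(levels[2]) - contrast(levels[1])
    est <- sum(kd * beta)
    se <- sqrt(drop(t(kd) %*% V %*% kd))
    out <- rbind(do.call(rbind, rows),
                 data.frame(level = NA, slope = est, se = se,
                            ci_lower = est - 1.96 * se,
                            ci_upper = est + 1.96 * se))
    out$contrast <- c(sprintf("PHS = %+g SD", levels), "difference")
    rownames(out) <- NULL
    out
}

#' Longitudinal atrophy panel over cortical ROIs
#'
#' Fits the interaction-with-time mixed model of [fitLongitudinal()] to
#' each region-of-interest volume, by default controlling only for sex,
#' education and APOE status beside the PHS (volumes are assumed
#' pre-adjusted for age and intracranial volume upstream), then adjusts
#' the PHS-by-time p-values across the ROI family by FDR.
#'
#' @param volumes long data.frame `participant_id`, `visit_age`, `roi`,
#'   `volume`.
#' @param covariateData data.frame, one row per participant:
#'   `participant_id`, `phs`, `sex`, `education`, `apoe`.
#' @param rois ROIs to analyse; defaults to those present.
#' @param terms interaction covariates of the per-ROI model.
#' @return data.frame, one row per ROI: the PHS-by-time estimate with
#'   `p_fdr`, plus `singular`. Skipped ROIs are dropped with a warning.
#' @export
runAtrophyPanel <- function(volumes, covariateData,
                            rois = unique(volumes$roi),
                            terms = c("phs", "sex", "education", "apoe")) {
    absent <- setdiff(rois, unique(volumes$roi))
    if (length(absent)) {
        warnf("ROI(s) missing from the volume table, skipped: %s",
              paste(absent, collapse = ", "))
        rois <- setdiff(rois, absent)
    }
    rows <- lapply(rois, function(r) {
        v <- volumes[volumes$roi == r, , drop = FALSE]
        base <- stats::ave(v$visit_age, v$participant_id, FUN = min)
        d <- data.frame(participant_id = v$participant_id,
                        time = v$visit_age - base, value = v$volume,
                        stringsAsFactors = FALSE)
        d <- merge(d, covariateData, by = "participant_id")
        f <- suppressWarnings(
            fitLongitudinal(d, terms = terms,
                            scaleVars = c("phs", "education")))
        est <- f$table[f$table$term %in% c("phs:time", "time:phs"), ]
        data.frame(roi = r, beta = est$beta, se = est$se,
                   ci_lower = est$ci_lower, ci_upper = est$ci_upper,
                   p = est$p, singular = f$singular,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_fdr <- fdrAdjust(out$p)
    rownames(out) <- NULL
    out
}

#' Assemble the longitudinal model frame from a cohort
#'
#' Joins an outcome table to the participant covariates, the baseline
#' frontal Centiloid value and the baseline entorhinal-cortex volume, and
#' computes Time as years since each participant's first visit.
#'
#' @param cohort an [AmyloidCohort-class].
#' @param phs a [PhsResult-class] aligned to the cohort.
#' @param outcome data.frame `participant_id`, `visit_age`, `value`.
#' @param baselineDiagnosis restrict to participants whose baseline
#'   diagnosis is among these labels (default CN and MCI, i.e. non-AD).
#' @return data.frame ready for [fitLongitudinal()].
#' @export
assembleLongitudinalData <- function(cohort, phs, outcome,
                                     baselineDiagnosis = c("CN", "MCI")) {
    pt <- participants(cohort)
    pt$participant_id <- rownames(pt)
    keep <- pt$diagnosis %in% baselineDiagnosis
    pt <- pt[keep, , drop = FALSE]
    am <- amyloidScans(cohort)
    am <- am[am$region == "frontal", , drop = FALSE]
    clf <- vapply(split(am, am$participant_id),
                  function(d) d$centiloid[which.min(d$scan_age)], 0)
    vol <- roiVolumes(cohort)
    vol <- vol[vol$roi == "entorhinal", , drop = FALSE]
    ent <- vapply(split(vol, vol$participant_id),
                  function(d) d$volume[which.min(d$visit_age)], 0)
    d <- outcome[outcome$participant_id %in% pt$participant_id, ,
                 drop = FALSE]
    base <- stats::ave(d$visit_age, d$participant_id, FUN = min)
    i <- match(d$participant_id, pt$participant_id)
    s <- phsScores(phs)
    data.frame(participant_id = d$participant_id,
               time = d$visit_age - base,
               value = d$value,
               phs = as.numeric(s[d$participant_id]),
               cl_frontal = as.numeric(clf[d$participant_id]),
               entorhinal = as.numeric(ent[d$participant_id]),
               baseline_age = pt$baselineAge[i],
               sex = as.integer(pt$sex[i] == "male"),
               education = pt$educationYears[i],
               apoe = as.integer(pt$apoeE4Count[i] > 0),
               stringsAsFactors = FALSE)
}
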