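#' Classify a Centiloid value as abnormal
#'
#' Values equal to or above the threshold (20 CL by convention) indicate
#' abnormal amyloid deposition.
#'
#' @param cl numeric Centiloid value(s).
#' @param threshold abnormality threshold (inclusive).
#' @return logical vector.
#' @export
classifyAbnormal <- function(cl, threshold = 20) {
    if (any(!is.finite(cl)))
        stopf("non-finite Centiloid value")
    checkScalarNumeric(threshold, "threshold")
    cl >= threshold
}

#' Fit an amyloid disease-progression curve
#'
#' Reconstructs the population trajectory of Centiloid accumulation as a
#' function of disease time from short individual scan series, by the
#' slope-versus-level approach used in the natural-history trajectory
#' literature: (a) each individual's accumulation rate is the least-squares
#' slope of Centiloid against age, and their level the mean Centiloid over
#' scans; (b) the rate is modelled as a quadratic function `f(CL)` of the
#' level, clipped to be positive; (c) integrating `dCL/dtau = f(CL)` from
#' the abnormality threshold in both directions yields the curve, anchored
#' so `CL(0) = threshold`.
#'
#' @param amyloid long data.frame `participant_id`, `scan_age`,
#'   `centiloid`, optionally `region`.
#' @param threshold Centiloid abnormality threshold.
#' @param region region to use when a `region` column is present.
#' @param floor,ceiling Centiloid asymptotes delimiting the curve's valid
#'   range.
#' @param nGrid size of the sampled grid held in the returned object.
#' @return a [ProgressionCurve-class].
#' @export
fitProgressionCurve <- function(amyloid, threshold = 20,
                                region = "neocortex",
                                floor = 0, ceiling = 100,
                                nGrid = 2001L) {
    if ("region" %in% names(amyloid))
        amyloid <- amyloid[amyloid$region == region, , drop = FALSE]
    if (ceiling <= threshold || floor >= threshold)
        stopf("threshold must lie strictly between floor and ceiling")
    sp <- split(amyloid, amyloid$participant_id)
    sp <- sp[vapply(sp, nrow, 0L) >= 2L]
    if (length(sp) < 5L)
        stopf("need scan series (>= 2 scans) from at least 5 individuals")
    if (length(sp) < 20L)
        warnf("only %d usable individuals; the progression curve %s",
              length(sp), "is recommended with >= 20")
    level <- vapply(sp, function(d) mean(d$centiloid), 0)
    rate <- vapply(sp, function(d)
        stats::cov(d$scan_age, d$centiloid) / stats::var(d$scan_age), 0)
    if (max(abs(rate)) < 1e-8 || stats::median(abs(rate)) < 1e-10)
        stopf("no progression signal: all individual rates are ~ 0")
    fit <- stats::lm(rate ~ level + I(level^2))
    span <- ceiling - floor
    clGrid <- seq(floor + 0.005 * span, ceiling - 0.005 * span,
                  length.out = nGrid)
    f <- stats::predict(fit, newdata = data.frame(level = clGrid))
    fmin <- max(1e-4, 0.02 * max(f))
    if (any(f < fmin)) {
        warnf("fitted accumulation rate non-positive or near zero over %s",
              "part of the Centiloid range; clipped")
        f <- pmax(f, fmin)
    }
    # tau(CL) = integral from threshold of dCL / f(CL), trapezoid rule
    g <- 1 / f
    dcl <- diff(clGrid)
    tRaw <- c(0, cumsum(dcl * (g[-length(g)] + g[-1]) / 2))
    t0 <- stats::approx(clGrid, tRaw, xout = threshold)$y
    new("ProgressionCurve", tau = tRaw - t0, cl = clGrid,
        threshold = threshold, floor = floor, ceiling = ceiling)
}

# linear interpolation with terminal-slope extrapolation
.interpExtrap <- function(x, y, xout) {
    n <- length(x)
    yo <- stats::approx(x, y, xout = xout, rule = 2)$y
    lo <- xout < x[1L]
    hi <- xout > x[n]
    if (any(lo)) {
        s <- (y[2L] - y[1L]) / (x[2L] - x[1L])
        yo[lo] <- y[1L] + s * (xout[lo] - x[1L])
    }
    if (any(hi)) {
        s <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
        yo[hi] <- y[n] + s * (xout[hi] - x[n])
    }
    yo
}

#' @rdname ProgressionCurve-class
#' @export
setMethod("predictCL", "ProgressionCurve", function(curve, tau)
    .interpExtrap(curve@tau, curve@cl, tau))

#' @rdname ProgressionCurve-class
#' @export
setMethod("diseaseTime", "ProgressionCurve", function(curve, cl)
    .interpExtrap(curve@cl, curve@tau, cl))

#' Impute each participant's age of amyloid onset
#'
#' For a participant whose mean longitudinal Centiloid level is at or above
#' the threshold, the progression curve gives the elapsed disease time
#' between crossing the threshold and reaching that mean level; subtracting
#' this elapsed time from the mean scan age yields the imputed age of
#' onset. Participants whose mean level stays below the threshold are
#' censored with reason `never_abnormal`. Mean levels above the curve's
#' ceiling are clamped just below it, with a warning.
#'
#' @param amyloid long data.frame `participant_id`, `scan_age`,
#'   `centiloid`, optionally `region`.
#' @param curve a [ProgressionCurve-class].
#' @param threshold abnormality threshold; defaults to the curve's anchor.
#' @param region region used when a `region` column is present.
#' @return data.frame `participant_id`, `onset_age` (`NA` when censored),
#'   `status` (`event`/`censored`), `censor_reason`, `mean_cl`,
#'   `mean_age`.
#' @export
estimateOnsetAge <- function(amyloid, curve, threshold = curve@threshold,
                             region = "neocortex") {
    if ("region" %in% names(amyloid))
        amyloid <- amyloid[amyloid$region == region, , drop = FALSE]
    if (!nrow(amyloid)) stopf("no scans to estimate onset from")
    sp <- split(amyloid, amyloid$participant_id)
    meanCl <- vapply(sp, function(d) mean(d$centiloid), 0)
    meanAge <- vapply(sp, function(d) mean(d$scan_age), 0)
    # near the ceiling the trajectory is flat and disease time diverges;
    # saturated mean levels are clamped to a high interior level where
    # the curve is still informative
    cap <- curve@ceiling - 0.025 * (curve@ceiling - curve@floor)
    clamped <- meanCl > cap
    if (any(clamped & meanCl >= threshold))
        warnf("%d participant(s) with mean Centiloid at or above the %s",
              sum(clamped), "curve ceiling; clamped below it")
    clUse <- pmin(meanCl, cap)
    isEvent <- meanCl >= threshold
    elapsed <- diseaseTime(curve, clUse) - diseaseTime(curve, threshold)
    out <- data.frame(
        participant_id = names(sp),
        onset_age = ifelse(isEvent, meanAge - elapsed, NA_real_),
        status = ifelse(isEvent, "event", "censored"),
        censor_reason = ifelse(isEvent, NA_character_, "never_abnormal"),
        mean_cl = meanCl, mean_age = meanAge,
        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
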