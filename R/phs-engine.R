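#' Filter candidate variants by GWAS p-value
#'
#' Keeps exactly the variants whose association p-value is strictly below
#' the threshold (the conventional candidate screen is `p < 1e-5`),
#' preserving the input order.
#'
#' @param summaryStats data.frame with columns `snp_id`, `effect_allele`,
#'   `or`, `p` (see [readSummaryStats()]).
#' @param pThreshold strict upper bound on the p-value, in (0, 1).
#' @return character vector of candidate variant ids.
#' @export
filterCandidateSnps <- function(summaryStats, pThreshold = 1e-5) {
    if (!all(c("snp_id", "p") %in% names(summaryStats)))
        stopf("summaryStats must have columns 'snp_id' and 'p'")
    if (!is.numeric(pThreshold) || pThreshold <= 0 || pThreshold >= 1)
        stopf("pThreshold must lie in (0, 1)")
    if (nrow(summaryStats) == 0L) return(character())
    p <- summaryStats$p
    bad <- which(!is.finite(p) | p <= 0 | p > 1)
    if (length(bad))
        stopf("malformed p-value in summary statistics row(s): %s",
              paste(bad, collapse = ", "))
    if (anyDuplicated(summaryStats$snp_id))
        stopf("duplicated variant ids in summary statistics")
    as.character(summaryStats$snp_id[p < pThreshold])
}

# Fit a Cox model on a set of dosage covariates; returns list(fit, ok, msg).
# Convergence problems are reported, not thrown, so stepwise can skip.
.coxOnVariants <- function(vars, survivalTable, dosages) {
    df <- as.data.frame(t(dosages[vars, , drop = FALSE]))
    names(df) <- vars
    df$.time <- survivalTable$time
    df$.event <- survivalTable$event
    useEntry <- "entry" %in% names(survivalTable) &&
        any(survivalTable$entry > 0)
    if (useEntry) df$.entry <- survivalTable$entry
    resp <- if (useEntry) "survival::Surv(.entry, .time, .event)"
            else "survival::Surv(.time, .event)"
    rhs <- if (length(vars)) paste(sprintf("`%s`", vars), collapse = " + ")
           else "1"
    fml <- stats::as.formula(paste(resp, "~", rhs))
    msg <- NULL
    fit <- withCallingHandlers(
        tryCatch(survival::coxph(fml, data = df, ties = "efron",
                                 control = survival::coxph.control(
                                     iter.max = 50)),
                 error = function(e) {msg <<- conditionMessage(e); NULL}),
        warning = function(w) {
            msg <<- conditionMessage(w)
            invokeRestart("muffleWarning")
        })
    ok <- !is.null(fit) && is.null(msg) && all(is.finite(stats::coef(fit)))
    list(fit = fit, ok = ok, msg = msg)
}

#' Forward stepwise Cox selection of scoring variants
#'
#' Starting from a Cox proportional-hazards model containing only the
#' forced covariates (the two APOE variants), candidates are added one at a
#' time: at each step the candidate giving the largest partial-likelihood
#' improvement enters, provided its one-degree likelihood-ratio p-value is
#' below `alphaEntry`; selection stops when no candidate qualifies or
#' `maxSnps` SNPs have entered. The returned panel carries the
#' coefficients of the final joint Cox refit as per-allele log-hazard
#' weights, so the score reproduces the joint model's linear predictor.
#'
#' Ties in likelihood improvement are broken by the smaller summary-stats
#' p-value (when `summaryStats` is supplied), then by lexicographic id,
#' making the selection reproducible.
#'
#' @param candidates character vector of candidate variant ids (rows of
#'   `dosages`).
#' @param dosages numeric matrix, variants x individuals, values 0/1/2.
#' @param survivalTable data.frame with `time` (years), `event` (0/1) and
#'   optionally `entry` (delayed-entry age) aligned to the columns of
#'   `dosages`.
#' @param forced ids of covariates forced into the model before any step.
#' @param alphaEntry likelihood-ratio entry threshold.
#' @param maxSnps maximum number of selected (non-forced) SNPs.
#' @param summaryStats optional data.frame (`snp_id`, `p`) used only for
#'   tie-breaking.
#' @param variantInfo optional data.frame (`id`, `effectAllele`) copied
#'   into the panel metadata.
#' @return a [SnpPanel-class]; forced variants first.
#' @export
forwardStepwiseCox <- function(candidates, dosages, survivalTable,
                               forced = c("APOE_e4", "APOE_e2"),
                               alphaEntry = 0.05, maxSnps = 31L,
                               summaryStats = NULL, variantInfo = NULL) {
    if (sum(survivalTable$event) < 1L)
        stopf("survival table has no events")
    missing <- setdiff(c(forced, candidates), rownames(dosages))
    if (length(missing))
        stopf("variants absent from dosage matrix: %s",
              paste(missing, collapse = ", "))
    if (ncol(dosages) != nrow(survivalTable))
        stopf("dosage columns and survival rows differ")
    base <- .coxOnVariants(forced, survivalTable, dosages)
    if (!base$ok)
        stopf("forced-covariate Cox model failed (%s); check for separation",
              base$msg %||% "no fit")
    llCur <- base$fit$loglik[2L]
    fitCur <- base$fit
    selected <- character()
    remaining <- setdiff(candidates, forced)
    ssP <- if (!is.null(summaryStats))
        stats::setNames(summaryStats$p, summaryStats$snp_id) else NULL
    while (length(selected) < maxSnps && length(remaining)) {
        ll <- rep(NA_real_, length(remaining))
        for (i in seq_along(remaining)) {
            f <- .coxOnVariants(c(forced, selected, remaining[i]),
                                survivalTable, dosages)
            if (!f$ok) {
                warnf("candidate %s skipped (Cox fit: %s)", remaining[i],
                      f$msg %||% "failed")
                next
            }
            ll[i] <- f$fit$loglik[2L]
        }
        if (all(is.na(ll))) break
        imp <- ll - llCur
        best <- max(imp, na.rm = TRUE)
        tied <- which(!is.na(imp) & imp >= best - 1e-10)
        if (length(tied) > 1L) {
            ord <- order(if (is.null(ssP)) rep(0, length(tied))
                         else ssP[remaining[tied]], remaining[tied])
            tied <- tied[ord]
        }
        pick <- remaining[tied[1L]]
        pEnter <- stats::pchisq(2 * imp[tied[1L]], df = 1, lower.tail = FALSE)
        if (!(pEnter < alphaEntry)) break
        selected <- c(selected, pick)
        remaining <- setdiff(remaining, pick)
        refit <- .coxOnVariants(c(forced, selected), survivalTable, dosages)
        llCur <- refit$fit$loglik[2L]
        fitCur <- refit$fit
    }
    ids <- c(forced, selected)
    wt <- stats::coef(fitCur)
    names(wt) <- gsub("`", "", names(wt))
    ea <- rep(NA_character_, length(ids))
    if (!is.null(variantInfo))
        ea <- as.character(variantInfo$effectAllele[
            match(ids, variantInfo$id)])
    new("SnpPanel", panel = S4Vectors::DataFrame(
        id = ids, effectAllele = ea, weight = as.numeric(wt[ids]),
        forced = ids %in% forced))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Align a dosage matrix to a panel's effect alleles
#'
#' When the counted allele of a genotype file differs from the panel's
#' effect allele, the dosage is flipped (`2 - d`). Strand is never
#' inferred: a mismatch at a palindromic variant (A/T or C/G) is
#' ambiguous and raises an error, as does an allele not present in the
#' variant's allele pair.
#'
#' @param dosages variants x individuals matrix with rownames.
#' @param alleles data.frame `id`, `countedAllele`, `otherAllele`
#'   describing the file's coding.
#' @param panel a [SnpPanel-class] with known effect alleles.
#' @return the dosage matrix, flipped where required.
#' @export
alignDosages <- function(dosages, alleles, panel) {
    tab <- panelTable(panel)
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    for (i in seq_len(nrow(tab))) {
        id <- tab$id[i]
        ea <- tab$effectAllele[i]
        if (is.na(ea) || !id %in% alleles$id) next
        j <- match(id, alleles$id)
        counted <- alleles$countedAllele[j]
        other <- alleles$otherAllele[j]
        if (counted == ea) next
        if (!is.na(other) && other == ea) {
            if (comp[[counted]] == other)
                stopf("palindromic allele mismatch at %s (%s/%s): strand %s",
                      id, counted, other, "cannot be resolved")
            dosages[id, ] <- 2 - dosages[id, ]
        } else {
            stopf("effect allele %s of %s matches neither file allele (%s/%s)",
                  ea, id, counted, other)
        }
    }
    dosages
}

#' Compute polygenic hazard scores
#'
#' The score is the weight-by-dosage sum over the panel,
#' `score_i = sum_j w_j d_ij`, interpretable as a log relative hazard.
#' Dosages must already be aligned to the panel's effect alleles (see
#' [alignDosages()]); missing variants or missing dosage values are
#' errors — nothing is silently imputed.
#'
#' @param dosages variants x individuals numeric matrix.
#' @param panel a [SnpPanel-class].
#' @param center,scale optional post-summation normalisation of the score
#'   (off by default; the raw sum is the canonical score).
#' @return a [PhsResult-class] with scores and empty strata (see
#'   [stratifyPhs()]).
#' @examples
#' pan <- new("SnpPanel", panel = S4Vectors::DataFrame(
#'     id = c("a", "b"), effectAllele = c("A", "G"),
#'     weight = c(0.5, -1), forced = c(FALSE, FALSE)))
#' d <- rbind(a = c(0, 2), b = c(1, 1))
#' colnames(d) <- c("s1", "s2")
#' phsScores(computePhs(d, pan))
#' @export
computePhs <- function(dosages, panel, center = FALSE, scale = FALSE) {
    tab <- panelTable(panel)
    missing <- setdiff(tab$id, rownames(dosages))
    if (length(missing))
        stopf("panel variants missing from dosage matrix: %s",
              paste(missing, collapse = ", "))
    d <- dosages[tab$id, , drop = FALSE]
    if (anyNA(d))
        stopf("missing dosage values for %d entries; no silent imputation",
              sum(is.na(d)))
    s <- as.numeric(crossprod(d, tab$weight))
    names(s) <- colnames(dosages)
    if (center) s <- s - mean(s)
    if (scale) {
        if (stats::sd(s) == 0) stopf("cannot scale constant scores")
        s <- s / stats::sd(s)
    }
    new("PhsResult", score = s,
        stratum = factor(character(), levels = c("low", "mid", "high")),
        thresholds = c(low = NA_real_, high = NA_real_))
}

#' Stratify scores into low / mid / high groups
#'
#' Default cutpoints are the cohort mean plus and minus one standard
#' deviation: `high` is strictly above the upper cutpoint (about the 84th
#' percentile for Gaussian scores), `low` strictly below the lower one.
#' Explicit cutpoints override the cohort-derived ones.
#'
#' @param scores a [PhsResult-class] or numeric vector.
#' @param thresholds optional numeric(2) `(low, high)` cutpoints.
#' @return a [PhsResult-class] with the `stratum` slot filled.
#' @export
stratifyPhs <- function(scores, thresholds = NULL) {
    s <- if (is(scores, "PhsResult")) phsScores(scores) else scores
    if (is.null(thresholds)) {
        if (length(unique(s)) < 2L)
            stopf("need >= 2 distinct scores to derive cutpoints")
        sd <- stats::sd(s)
        if (sd == 0) stopf("zero score SD; supply explicit thresholds")
        thresholds <- c(mean(s) - sd, mean(s) + sd)
    }
    thresholds <- sort(as.numeric(thresholds))
    st <- factor(ifelse(s > thresholds[2], "high",
                 ifelse(s < thresholds[1], "low", "mid")),
                 levels = c("low", "mid", "high"))
    new("PhsResult", score = s, stratum = st,
        thresholds = c(low = thresholds[1], high = thresholds[2]))
}

#' Age-specific hazard function for a given score
#'
#' Under the proportional-hazards model the hazard of an individual with
#' score `s` is `h(t) = h0(t) exp(s)`; the relative hazard between two
#' individuals is `exp(s1 - s2)` at every age.
#'
#' @param score log relative hazard.
#' @param baselineHazard either a function of age returning the baseline
#'   hazard, or named Gompertz parameters `rate` and `shape`.
#' @return a function of age (years) returning the hazard (1/year).
#' @export
hazardCurve <- function(score, baselineHazard) {
    checkScalarNumeric(score, "score")
    h0 <- if (is.function(baselineHazard)) baselineHazard
          else function(t) baselineHazard[["rate"]] *
                   exp(baselineHazard[["shape"]] * t)
    force(h0)
    function(t) h0(t) * exp(score)
}
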