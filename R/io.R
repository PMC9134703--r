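#' Read GWAS summary statistics
#'
#' Tab-separated with header columns `snp_id`, `effect_allele`, `or`,
#' `p` (odds ratio and association p-value per variant).
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
readSummaryStats <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("snp_id", "effect_allele", "or", "p")
    missing <- setdiff(need, names(d))
    if (length(missing))
        stopf("summary statistics lack column(s): %s",
              paste(missing, collapse = ", "))
    bad <- which(!is.finite(d$p) | d$p <= 0 | d$p > 1)
    if (length(bad))
        stopf("malformed p-value in row(s): %s", paste(bad, collapse = ", "))
    if (anyDuplicated(d$snp_id))
        stopf("duplicated snp_id values")
    d
}

#' Write / read a dosage matrix as TSV
#'
#' Rows are variants, columns individuals; the first column holds the
#' variant id.
#'
#' @param dosages variants x individuals numeric matrix with dimnames.
#' @param path file path.
#' @return `readDosageTsv` returns the matrix.
#' @export
writeDosageTsv <- function(dosages, path) {
    df <- data.frame(snp_id = rownames(dosages), dosages,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeDosageTsv
#' @export
readDosageTsv <- function(path) {
    d <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    m
}

#' Read allele dosages from a VCF
#'
#' Dosage is the count of ALT alleles in the GT field; missing genotypes
#' (`./.`) become `NA` (downstream scoring refuses missing dosages rather
#' than imputing).
#'
#' @param path VCF file path.
#' @return list with `dosages` (variants x individuals matrix) and
#'   `alleles` (data.frame `id`, `countedAllele`, `otherAllele`; the
#'   counted allele is ALT).
#' @export
readVcfDosages <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    count <- function(g) {
        if (is.na(g) || grepl("\\.", g)) return(NA_real_)
        sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
    }
    dos <- apply(gt, c(1, 2), count)
    fix <- vcfR::getFIX(v)
    ids <- fix[, "ID"]
    rownames(dos) <- ids
    list(dosages = dos,
         alleles = data.frame(id = ids,
                              countedAllele = fix[, "ALT"],
                              otherAllele = fix[, "REF"],
                              stringsAsFactors = FALSE))
}

#' Serialize / read a scoring panel as TSV
#'
#' @param panel a [SnpPanel-class].
#' @param path file path.
#' @return `readPanelTsv` returns a [SnpPanel-class].
#' @export
writePanelTsv <- function(panel, path) {
    utils::write.table(as.data.frame(panelTable(panel)), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writePanelTsv
#' @export
readPanelTsv <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    new("SnpPanel", panel = S4Vectors::DataFrame(
        id = d$id, effectAllele = d$effectAllele,
        weight = d$weight, forced = as.logical(d$forced)))
}

#' Read a long-format phenotype CSV
#'
#' Columns `participant_id`, `visit_age`, `variable`, `value`. Validation
#' names the offending keys: duplicate participant-visit-variable rows
#' and non-increasing visit ages per participant-variable are errors.
#'
#' @param path file path.
#' @param regions when supplied, `variable` labels must come from this
#'   set (used for Centiloid tables).
#' @return the validated data.frame.
#' @export
readPhenotypeCsv <- function(path, regions = NULL) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("participant_id", "visit_age", "variable", "value")
    missing <- setdiff(need, names(d))
    if (length(missing))
        stopf("phenotype file lacks column(s): %s",
              paste(missing, collapse = ", "))
    key <- paste(d$participant_id, d$visit_age, d$variable)
    if (anyDuplicated(key))
        stopf("duplicate participant-visit keys: %s",
              paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
    if (!is.null(regions)) {
        bad <- setdiff(unique(d$variable), regions)
        if (length(bad))
            stopf("unknown region label(s): %s", paste(bad, collapse = ", "))
    }
    byPv <- split(d$visit_age, paste(d$participant_id, d$variable))
    nonInc <- names(byPv)[vapply(byPv, function(a) any(diff(a) <= 0), TRUE)]
    if (length(nonInc))
        stopf("non-increasing visit ages for: %s",
              paste(utils::head(nonInc, 3), collapse = "; "))
    rownames(d) <- NULL
    d
}

# wide (one column per variable) -> long interchange format
#' Convert a wide phenotype table to the long interchange format
#'
#' @param wide data.frame with `participant_id`, `visit_age` and one
#'   column per variable.
#' @return long data.frame `participant_id`, `visit_age`, `variable`,
#'   `value`.
#' @export
wideToLongPhenotypes <- function(wide) {
    vars <- setdiff(names(wide), c("participant_id", "visit_age"))
    out <- do.call(rbind, lapply(vars, function(v)
        data.frame(participant_id = wide$participant_id,
                   visit_age = wide$visit_age, variable = v,
                   value = wide[[v]], stringsAsFactors = FALSE)))
    rownames(out) <- NULL
    out
}
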