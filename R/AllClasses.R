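#' @import methods
NULL

.emptySamples <- function() {
    data.frame(sample_id = character(), project = character(),
               status = character(), inheritance_mode = character(),
               family_id = character(), proband_flag = logical(),
               confirmation_seq = character(),
               confirmation_segregation = character(),
               diagnosis = character(), stringsAsFactors = FALSE)
}

.emptyObservations <- function() {
    data.frame(sample_id = character(), key = character(),
               contig = character(), start = integer(), end = integer(),
               ref = character(), alt = character(),
               zygosity = character(), gt = character(),
               filter = character(), stringsAsFactors = FALSE)
}

.emptyRegistry <- function() {
    data.frame(key = character(), contig = character(), start = integer(),
               end = integer(), ref = character(), alt = character(),
               stringsAsFactors = FALSE)
}

.predictionTools <- c("sift", "polyphen", "lrt", "mutation_taster", "fathmm")

.populationSlots <- c("kg1000", "esp6500", "exac", "hgvd", "jpn2k",
                      "inhouse_control")

.emptyAnnotations <- function() {
    df <- data.frame(key = character(), gene = character(),
                     region_class = character(), function_class = character(),
                     hgvs = character(), stringsAsFactors = FALSE)
    for (p in .populationSlots) df[[p]] <- numeric()
    for (t in .predictionTools) df[[paste0("pred_", t)]] <- character()
    df$splice_score <- numeric()
    df$clinvar_significance <- character()
    df$prior_category <- character()
    df
}

.emptyImportLog <- function() {
    data.frame(path = character(), sample_id = character(),
               records_read = integer(), observations_stored = integer(),
               records_rejected = integer(), stringsAsFactors = FALSE)
}

#' VariantWarehouse: registry of samples, genotype observations and
#' deduplicated variants
#'
#' The central container of the package. It holds the sample sheet (one row
#' per sequenced individual, with case/control status and inheritance mode),
#' the genotype observations parsed from per-sample VCF files (one row per
#' sample x variant), the deduplicated variant registry in ANNOVAR 1-based
#' inclusive coordinates, the joined annotation table, and the per-sample
#' clinical profiles (numeric, categorical and series-valued fields).
#'
#' @slot samples data.frame sample sheet.
#' @slot observations data.frame of genotype observations.
#' @slot registry data.frame of unique variant keys.
#' @slot annotations data.frame of per-variant annotations.
#' @slot clinicalNumeric long data.frame (sample_id, field, value).
#' @slot clinicalCategorical long data.frame (sample_id, field, value).
#' @slot clinicalSeries long data.frame (sample_id, field, x, y, interpolated).
#' @slot seriesGrids named list of declared x-grids per series field.
#' @slot config list of store-wide configuration (chromosome naming,
#'   VCF FILTER policy).
#' @slot importLog data.frame log of completed VCF imports.
#'
#' @exportClass VariantWarehouse
setClass("VariantWarehouse",
    representation(samples = "data.frame", observations = "data.frame",
                   registry = "data.frame", annotations = "data.frame",
                   clinicalNumeric = "data.frame",
                   clinicalCategorical = "data.frame",
                   clinicalSeries = "data.frame", seriesGrids = "list",
                   config = "list", importLog = "data.frame"))

setValidity("VariantWarehouse", function(object) {
    msg <- character()
    s <- object@samples
    if (anyDuplicated(s$sample_id))
        msg <- c(msg, "duplicated sample_id in sample sheet")
    o <- object@observations
    if (nrow(o) && anyDuplicated(o[c("sample_id", "key")]))
        msg <- c(msg, "duplicated (sample_id, key) observation")
    if (anyDuplicated(object@registry$key))
        msg <- c(msg, "duplicated key in variant registry")
    if (nrow(object@annotations) && anyDuplicated(object@annotations$key))
        msg <- c(msg, "more than one annotation record for a variant key")
    bad <- setdiff(unique(s$status), c("case", "control"))
    if (length(bad))
        msg <- c(msg, paste("unknown sample status:", paste(bad, collapse = ", ")))
    # one designated proband per family among cases
    cs <- s[s$status == "case" & s$proband_flag, , drop = FALSE]
    if (nrow(cs) && anyDuplicated(cs$family_id))
        msg <- c(msg, "family with more than one designated proband")
    if (length(msg)) msg else TRUE
})

#' FilterFunnel: stage-by-stage record of a filtering cascade
#'
#' @slot stages data.frame with columns stage, n_in, n_out.
#' @slot removed named list of removed variant keys per stage.
#' @slot survivors character vector of surviving variant keys.
#' @slot scope label ("cohort" or the sample id of a case funnel).
#'
#' @exportClass FilterFunnel
setClass("FilterFunnel",
    representation(stages = "data.frame", removed = "list",
                   survivors = "character", scope = "character"))

setValidity("FilterFunnel", function(object) {
    st <- object@stages
    msg <- character()
    if (nrow(st)) {
        if (any(st$n_out > st$n_in))
            msg <- c(msg, "stage with n_out > n_in")
        if (nrow(st) > 1 && any(st$n_in[-1] != st$n_out[-nrow(st)]))
            msg <- c(msg, "stage k+1 n_in does not equal stage k n_out")
        nrem <- vapply(object@removed, length, integer(1))
        if (any(st$n_in - st$n_out != nrem))
            msg <- c(msg, "removed-key list inconsistent with stage counts")
    }
    if (length(msg)) msg else TRUE
})

#' AssociationResult: stratified 2x2 case-control statistics for a variant
#'
#' Cells follow the usual carrier layout: a = carriers among stratum
#' probands, b = non-carriers among stratum probands, c = carriers among
#' controls, d = non-carriers among controls.
#'
#' @slot a,b,c,d numeric contingency cells (counts).
#' @slot stratum "AD_or_mitochondrial" or "AR_or_sporadic".
#' @slot countingUnit "proband_carrier" or "allele".
#' @slot orPoint odds ratio point estimate.
#' @slot ciLow,ciHigh 95 percent confidence bounds.
#' @slot pValue two-sided Fisher exact P.
#' @slot correctionApplied TRUE when the Haldane-Anscombe +0.5 was used.
#' @slot smallCountWarning TRUE when total carriers (a + c) < 10.
#' @slot ps4Support TRUE when the odds-ratio evidence rule fires.
#'
#' @exportClass AssociationResult
setClass("AssociationResult",
    representation(a = "numeric", b = "numeric", c = "numeric", d = "numeric",
                   stratum = "character", countingUnit = "character",
                   orPoint = "numeric", ciLow = "numeric", ciHigh = "numeric",
                   pValue = "numeric", correctionApplied = "logical",
                   smallCountWarning = "logical", ps4Support = "logical"))

setValidity("AssociationResult", function(object) {
    msg <- character()
    cells <- c(object@a, object@b, object@c, object@d)
    if (any(cells < 0)) msg <- c(msg, "negative contingency cell")
    if (object@pValue < 0 || object@pValue > 1)
        msg <- c(msg, "p-value outside [0, 1]")
    if (length(msg)) msg else TRUE
})

#' AggregatePhenotype: averaged phenotype of the carriers of a variant or gene
#'
#' @slot scope description of the carrier set (variant key, gene symbol or
#'   variant set).
#' @slot numeric data.frame (field, mean, sd, n); sd is NA when n < 2.
#' @slot categorical named list of frequency tables.
#' @slot series data.frame (field, x, mean, sd, n) pointwise on the shared grid.
#' @slot nCarriers number of carriers contributing.
#' @slot interpolatedSamples sample ids whose series were interpolated onto
#'   the declared grid.
#'
#' @exportClass AggregatePhenotype
setClass("AggregatePhenotype",
    representation(scope = "character", numeric = "data.frame",
                   categorical = "list", series = "data.frame",
                   nCarriers = "integer", interpolatedSamples = "character"))

#' Classification: combined ACMG/AMP pathogenicity verdict
#'
#' @slot verdict one of pathogenic, likely_pathogenic, uncertain,
#'   likely_benign, benign.
#' @slot firedRule identifier of the combining rule satisfied.
#' @slot evidence data.frame of evidence codes (code, polarity, strength,
#'   source).
#'
#' @exportClass Classification
setClass("Classification",
    representation(verdict = "character", firedRule = "character",
                   evidence = "data.frame"))
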