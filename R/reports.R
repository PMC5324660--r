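#' Round half away from zero
#'
#' Commercial (half-up) rounding, used for the report percentages so that
#' e.g. 1.25 renders as 1.3 at one decimal.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return numeric.
#' @export
roundHalfUp <- function(x, digits = 1) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cohort summary: region and functional breakdown of the registry
#'
#' Counts the unique registry variants by region class, and the exonic
#' variants by functional class, with percentages (of the unique-variant
#' total, respectively of the exonic count) rounded half-up to one
#' decimal. Registry variants without an annotation are reported in an
#' explicit "unannotated" bucket so region counts always sum to the
#' unique-variant total.
#'
#' @param wh a \linkS4class{VariantWarehouse}.
#' @return list with n_samples, n_observations, n_unique, region
#'   (data.frame class/count/percent), exonic_function (data.frame
#'   class/count/percent, within exonic), and protein_affecting
#'   (count + percent of exonic).
#' @export
cohortSummary <- function(wh) {
    nUnique <- nrow(wh@registry)
    ann <- wh@annotations[match(wh@registry$key, wh@annotations$key), ,
                          drop = FALSE]
    region <- ann$region_class
    region[is.na(region)] <- "unannotated"
    regionLevels <- c(.regionEnum, "unannotated")
    regCount <- table(factor(region, levels = regionLevels))
    regDf <- data.frame(class = regionLevels,
                        count = as.integer(regCount),
                        percent = if (nUnique)
                            roundHalfUp(100 * as.integer(regCount) / nUnique)
                        else rep(0, length(regionLevels)),
                        stringsAsFactors = FALSE)
    exonic <- ann[!is.na(ann$region_class) &
                  ann$region_class == "exonic", , drop = FALSE]
    nExonic <- nrow(exonic)
    funCount <- table(factor(exonic$function_class, levels = .functionEnum))
    funDf <- data.frame(class = .functionEnum,
                        count = as.integer(funCount),
                        percent = if (nExonic)
                            roundHalfUp(100 * as.integer(funCount) / nExonic)
                        else rep(0, length(.functionEnum)),
                        stringsAsFactors = FALSE)
    nAffect <- sum(funDf$count[funDf$class %in% .proteinAffecting])
    list(n_samples = nrow(wh@samples),
         n_observations = nrow(wh@observations),
         n_unique = nUnique,
         region = regDf,
         exonic_function = funDf,
         protein_affecting = list(
             count = nAffect,
             percent = if (nExonic) roundHalfUp(100 * nAffect / nExonic)
                       else 0))
}

.annotatedSurvivorBlock <- function(wh, keys) {
    ann <- wh@annotations[match(keys, wh@annotations$key), , drop = FALSE]
    ann$key <- keys
    ann <- ann[order(ann$gene, ann$key), , drop = FALSE]
    rownames(ann) <- NULL
    ann
}

#' Case view: one patient's diagnostic report
#'
#' The per-patient report: sample and pedigree fields, clinical profile,
#' filter funnel, surviving variants with their annotations (gene, HGVS,
#' population frequencies, prediction calls, prior labels), and the
#' confirmation fields. For control samples filtering is not applicable
#' and the report says so.
#'
#' @param wh an annotated \linkS4class{VariantWarehouse}.
#' @param sampleId a registered sample.
#' @param config a [filterConfig()] for the funnel.
#' @return list report; render with [renderReport()].
#' @export
caseView <- function(wh, sampleId, config = filterConfig()) {
    s <- wh@samples[wh@samples$sample_id == sampleId, , drop = FALSE]
    if (!nrow(s)) stop("unknown sample: ", sampleId)
    clin <- list(
        numeric = wh@clinicalNumeric[
            wh@clinicalNumeric$sample_id == sampleId,
            c("field", "value"), drop = FALSE],
        categorical = wh@clinicalCategorical[
            wh@clinicalCategorical$sample_id == sampleId,
            c("field", "value"), drop = FALSE],
        series = wh@clinicalSeries[
            wh@clinicalSeries$sample_id == sampleId,
            c("field", "x", "y"), drop = FALSE])
    if (s$status == "control") {
        return(list(sample = as.list(s), clinical = clin,
                    filtering = "not applicable (control sample)",
                    survivors = NULL))
    }
    funnel <- caseFunnel(wh, sampleId, config)
    surv <- sort(funnel@survivors)
    list(sample = as.list(s), clinical = clin,
         funnel = funnelStages(funnel),
         survivors = .annotatedSurvivorBlock(wh, surv),
         confirmation = as.list(s[c("confirmation_seq",
                                    "confirmation_segregation",
                                    "diagnosis")]))
}

#' Variant view: one variant's evidence report
#'
#' The per-variant report: carriers with their inheritance modes, the
#' annotation block, the association statistics in both inheritance
#' strata (with the PS4 flag), and the aggregated carrier phenotype when
#' clinical data exist.
#'
#' @param wh an annotated \linkS4class{VariantWarehouse}.
#' @param keys a variant key or a variant set.
#' @return list report; render with [renderReport()].
#' @export
variantView <- function(wh, keys) {
    if (!all(keys %in% wh@registry$key))
        stop("variant(s) absent from registry: ",
             paste(setdiff(keys, wh@registry$key), collapse = ", "))
    carriers <- carriersOf(wh, variant = keys, includeControls = TRUE)
    carriers <- merge(carriers,
                      wh@samples[c("sample_id", "status",
                                   "inheritance_mode")],
                      by = "sample_id", sort = TRUE)
    assoc <- lapply(c(AD = "AD_or_mitochondrial", AR = "AR_or_sporadic"),
        function(st) {
            res <- tryCatch(suppressMessages(associationStats(
                buildContingency(wh, keys, st))), error = function(e) NULL)
            if (is.null(res)) return(NULL)
            list(stratum = st, a = res@a, b = res@b, c = res@c, d = res@d,
                 odds_ratio = res@orPoint, ci_low = res@ciLow,
                 ci_high = res@ciHigh, p_value = res@pValue,
                 ps4 = res@ps4Support,
                 small_count_warning = res@smallCountWarning)
        })
    pheno <- tryCatch(aggregatePhenotype(wh, variant = keys),
                      error = function(e) NULL)
    hasClinical <- !is.null(pheno) &&
        (nrow(pheno@numeric) > 0 || length(pheno@categorical) > 0 ||
         nrow(pheno@series) > 0)
    list(variants = .annotatedSurvivorBlock(wh, sort(keys)),
         carriers = carriers,
         association = assoc,
         phenotype = if (hasClinical) list(
             scope = pheno@scope, n_carriers = pheno@nCarriers,
             numeric = pheno@numeric,
             categorical = lapply(pheno@categorical,
                                  function(t) as.list(stats::setNames(
                                      as.integer(t), names(t)))),
             series = pheno@series)
         else "unavailable (no clinical data for carriers)")
}

#' Render a report list as canonical JSON or aligned text
#'
#' JSON is the canonical machine-readable form (deterministic for a fixed
#' store); the text rendering carries the same field values for human
#' reading.
#'
#' @param report a list from [caseView()], [variantView()] or
#'   [cohortSummary()].
#' @param format "json" or "text".
#' @return character scalar.
#' @export
renderReport <- function(report, format = c("json", "text")) {
    format <- match.arg(format)
    if (format == "json")
        return(as.character(jsonlite::toJSON(report, auto_unbox = TRUE,
                                             digits = 10, pretty = TRUE,
                                             dataframe = "rows",
                                             na = "null")))
    .renderText(report, indent = 0)
}

.renderText <- function(x, indent) {
    pad <- strrep("  ", indent)
    if (is.data.frame(x)) {
        if (!nrow(x)) return(paste0(pad, "(none)"))
        txt <- utils::capture.output(print(x, row.names = FALSE))
        return(paste(paste0(pad, txt), collapse = "\n"))
    }
    if (is.list(x)) {
        parts <- vapply(seq_along(x), function(i) {
            nm <- names(x)[i]
            body <- .renderText(x[[i]], indent + 1)
            paste0(pad, if (!is.null(nm) && nzchar(nm)) paste0(nm, ":")
                   else "-", "\n", body)
        }, "")
        return(paste(parts, collapse = "\n"))
    }
    if (is.null(x)) return(paste0(pad, "(none)"))
    paste0(pad, paste(format(x), collapse = " "))
}
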