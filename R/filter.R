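#' Filtering configuration
#'
#' Thresholds and switches of the rare-variant filtering cascade. All
#' values can be tightened or relaxed per disorder.
#'
#' @param mafThreshold population allele-frequency threshold (default 0.01:
#'   variants above 1 percent in any checked panel are removed).
#' @param spliceThreshold dbscSNV splice-score rescue threshold (default
#'   0.6): intronic and synonymous variants scoring below it are removed.
#' @param populationsChecked population slots consulted by the cohort MAF
#'   rule.
#' @param publicPanels the public panels consulted by the per-case funnel
#'   before the in-house stage.
#' @param retainPriorPathogenic exempt variants previously reported
#'   pathogenic / likely pathogenic from the frequency and effect rules.
#' @param dropControlOnly remove variants observed only in controls.
#' @param spliceRescueRegions region/effect classes eligible for the
#'   splice-score rescue.
#' @param minTools minimum non-missing in-silico calls for a unanimous
#'   consensus (used downstream by the evidence assignment).
#' @return A list of class "FilterConfig".
#' @export
filterConfig <- function(mafThreshold = 0.01, spliceThreshold = 0.6,
                         populationsChecked = .populationSlots,
                         publicPanels = c("kg1000", "esp6500", "exac"),
                         retainPriorPathogenic = TRUE,
                         dropControlOnly = TRUE,
                         spliceRescueRegions = c("intronic", "synonymous"),
                         minTools = 3) {
    stopifnot(mafThreshold > 0, mafThreshold < 1,
              spliceThreshold > 0, spliceThreshold < 1,
              length(populationsChecked) > 0)
    structure(list(mafThreshold = mafThreshold,
                   spliceThreshold = spliceThreshold,
                   populationsChecked = populationsChecked,
                   publicPanels = publicPanels,
                   retainPriorPathogenic = retainPriorPathogenic,
                   dropControlOnly = dropControlOnly,
                   spliceRescueRegions = spliceRescueRegions,
                   minTools = minTools),
              class = "FilterConfig")
}

.newFunnel <- function(scope) {
    new("FilterFunnel",
        stages = data.frame(stage = character(), n_in = integer(),
                            n_out = integer(), stringsAsFactors = FALSE),
        removed = list(), survivors = character(), scope = scope)
}

.pushStage <- function(funnel, name, keysIn, keysOut) {
    funnel@stages <- rbind(funnel@stages,
        data.frame(stage = name, n_in = length(keysIn),
                   n_out = length(keysOut), stringsAsFactors = FALSE))
    funnel@removed[[name]] <- setdiff(keysIn, keysOut)
    funnel@survivors <- keysOut
    funnel
}

# any non-missing frequency above threshold? (missing is treated as rare)
.mafAbove <- function(ann, pops, threshold) {
    above <- rep(FALSE, nrow(ann))
    for (p in pops) {
        v <- ann[[p]]
        above <- above | (!is.na(v) & v > threshold)
    }
    above
}

.priorPathogenic <- function(ann) {
    ann$prior_category %in% c("pathogenic", "likely_pathogenic")
}

.proteinAffecting <- c("missense", "nonsense", "stoploss",
                       "frameshift_insertion", "frameshift_deletion",
                       "frameshift_block_substitution",
                       "nonframeshift_insertion", "nonframeshift_deletion",
                       "nonframeshift_block_substitution")

#' Apply the cohort-level four-rule filter
#'
#' The cascade applied to the whole unique-variant registry:
#' \enumerate{
#'   \item variants previously reported pathogenic or likely pathogenic are
#'     exempt from the frequency and effect rules, regardless of MAF;
#'   \item variants exceeding the MAF threshold in any checked population
#'     are removed;
#'   \item intronic and synonymous variants whose splice score is below the
#'     threshold (or missing) are removed;
#'   \item variants observed only in controls are removed (this rule also
#'     applies to the exempt set: a control-only record has no case
#'     carrier to interpret).
#' }
#'
#' @param wh an annotated \linkS4class{VariantWarehouse}.
#' @param config a [filterConfig()].
#' @return A \linkS4class{FilterFunnel}; `survivors(funnel)` gives the
#'   surviving keys.
#' @export
applyCohortFilter <- function(wh, config = filterConfig()) {
    if (!nrow(wh@annotations))
        stop("registry has no annotations; run joinAnnotations() (annotate) first")
    ann <- wh@annotations[wh@annotations$key %in% wh@registry$key, ,
                          drop = FALSE]
    funnel <- .newFunnel("cohort")
    keys <- ann$key
    exempt <- if (config$retainPriorPathogenic) .priorPathogenic(ann)
              else rep(FALSE, nrow(ann))

    # rule 2: population frequency
    drop2 <- .mafAbove(ann, config$populationsChecked, config$mafThreshold) &
        !exempt
    keys2 <- keys[!drop2]
    funnel <- .pushStage(funnel, "maf", keys, keys2)
    ann2 <- ann[!drop2, , drop = FALSE]
    exempt2 <- exempt[!drop2]

    # rule 3: intronic/synonymous without splice rescue
    spliceCandidate <- rep(FALSE, nrow(ann2))
    if ("intronic" %in% config$spliceRescueRegions)
        spliceCandidate <- spliceCandidate | ann2$region_class == "intronic"
    if ("synonymous" %in% config$spliceRescueRegions)
        spliceCandidate <- spliceCandidate |
            (ann2$region_class %in% c("exonic", "exonic_splicing") &
             ann2$function_class == "synonymous")
    if ("UTR" %in% config$spliceRescueRegions)
        spliceCandidate <- spliceCandidate |
            ann2$region_class %in% c("UTR3", "UTR5")
    rescued <- !is.na(ann2$splice_score) &
        ann2$splice_score >= config$spliceThreshold
    drop3 <- spliceCandidate & !rescued & !exempt2
    keys3 <- keys2[!drop3]
    funnel <- .pushStage(funnel, "splice", keys2, keys3)

    # rule 4: control-only variants (exemption does not apply)
    if (config$dropControlOnly) {
        caseIds <- wh@samples$sample_id[wh@samples$status == "case"]
        caseKeys <- unique(
            wh@observations$key[wh@observations$sample_id %in% caseIds])
        keys4 <- keys3[keys3 %in% caseKeys]
    } else keys4 <- keys3
    funnel <- .pushStage(funnel, "control_only", keys3, keys4)
    validObject(funnel)
    funnel
}

#' Per-case filtering funnel
#'
#' The diagnostic funnel applied to one case's observed variants, with
#' stage-by-stage counts:
#' \enumerate{
#'   \item all variants observed in the sample;
#'   \item MAF below threshold in the public panels (1000 Genomes,
#'     ESP6500, ExAC by default; missing frequencies pass as rare);
#'   \item exonic / exonic-splicing region;
#'   \item protein-affecting (synonymous variants are dropped unless their
#'     splice score reaches the rescue threshold);
#'   \item MAF below threshold among the in-house controls.
#' }
#' Variants previously reported pathogenic or likely pathogenic bypass
#' stages 2-5 and are appended to the survivor set.
#'
#' @param wh an annotated \linkS4class{VariantWarehouse}.
#' @param sampleId a registered case sample.
#' @param config a [filterConfig()].
#' @return A \linkS4class{FilterFunnel} scoped to the sample.
#' @export
caseFunnel <- function(wh, sampleId, config = filterConfig()) {
    if (!(sampleId %in% wh@samples$sample_id))
        stop("unknown sample: ", sampleId)
    if (!nrow(wh@annotations))
        stop("registry has no annotations; run joinAnnotations() (annotate) first")
    obsKeys <- wh@observations$key[wh@observations$sample_id == sampleId]
    funnel <- .newFunnel(sampleId)
    ann <- wh@annotations[match(obsKeys, wh@annotations$key), , drop = FALSE]
    ann$key <- obsKeys              # unannotated keys keep NA attributes
    exempt <- !is.na(ann$region_class) & .priorPathogenic(ann) &
        config$retainPriorPathogenic

    keysA <- obsKeys
    funnel <- .pushStage(funnel, "observed", keysA, keysA)

    keepB <- !.mafAbove(ann, config$publicPanels, config$mafThreshold)
    keysB <- keysA[keepB]
    funnel <- .pushStage(funnel, "public_maf", keysA, keysB)
    annB <- ann[keepB, , drop = FALSE]

    keepC <- !is.na(annB$region_class) &
        annB$region_class %in% c("exonic", "exonic_splicing")
    keysC <- keysB[keepC]
    funnel <- .pushStage(funnel, "coding_region", keysB, keysC)
    annC <- annB[keepC, , drop = FALSE]

    rescued <- !is.na(annC$splice_score) &
        annC$splice_score >= config$spliceThreshold
    keepD <- annC$function_class %in% .proteinAffecting |
        (annC$function_class == "synonymous" & rescued) |
        (annC$region_class == "exonic_splicing" &
         annC$function_class == "none")
    keysD <- keysC[keepD]
    funnel <- .pushStage(funnel, "protein_affecting", keysC, keysD)
    annD <- annC[keepD, , drop = FALSE]

    keepE <- !.mafAbove(annD, "inhouse_control", config$mafThreshold)
    keysE <- keysD[keepE]
    funnel <- .pushStage(funnel, "inhouse_maf", keysD, keysE)

    funnel@survivors <- union(keysE, obsKeys[exempt])
    validObject(funnel)
    funnel
}

#' Funnel accessors and rendering
#'
#' @param funnel a \linkS4class{FilterFunnel}.
#' @return \code{funnelCounts}: integer vector of per-stage output counts
#'   (named by stage); \code{survivors}: character vector of surviving
#'   keys; \code{funnelStages}: the stage data.frame.
#' @export
funnelCounts <- function(funnel) {
    stats::setNames(as.integer(funnel@stages$n_out), funnel@stages$stage)
}

#' @rdname funnelCounts
#' @export
survivors <- function(funnel) funnel@survivors

#' @rdname funnelCounts
#' @export
funnelStages <- function(funnel) funnel@stages

#' Render a funnel as JSON or aligned text
#'
#' @param funnel a \linkS4class{FilterFunnel}.
#' @param format "json" (machine-readable, lists removed keys per stage)
#'   or "text".
#' @return A character scalar.
#' @export
funnelReport <- function(funnel, format = c("json", "text")) {
    format <- match.arg(format)
    st <- funnel@stages
    if (format == "json") {
        stages <- lapply(seq_len(nrow(st)), function(i) {
            list(stage = st$stage[i], n_in = st$n_in[i], n_out = st$n_out[i],
                 removed_keys = as.list(funnel@removed[[st$stage[i]]]))
        })
        return(as.character(jsonlite::toJSON(
            list(scope = funnel@scope, stages = stages,
                 survivors = as.list(funnel@survivors)),
            auto_unbox = TRUE, pretty = TRUE)))
    }
    lines <- c(sprintf("Filter funnel [%s]", funnel@scope),
               sprintf("  %-18s %6s %6s %8s", "stage", "in", "out", "removed"))
    for (i in seq_len(nrow(st)))
        lines <- c(lines, sprintf("  %-18s %6d %6d %8d", st$stage[i],
                                  st$n_in[i], st$n_out[i],
                                  st$n_in[i] - st$n_out[i]))
    lines <- c(lines, sprintf("  survivors: %d", length(funnel@survivors)))
    paste(lines, collapse = "\n")
}

setMethod("show", "FilterFunnel", function(object) {
    cat(funnelReport(object, format = "text"), "\n")
})
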