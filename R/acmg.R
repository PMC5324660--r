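.strengthFromCode <- function(code) {
    if (grepl("^PVS", code)) return(c("pathogenic", "very_strong"))
    if (grepl("^PS", code)) return(c("pathogenic", "strong"))
    if (grepl("^PM", code)) return(c("pathogenic", "moderate"))
    if (grepl("^PP", code)) return(c("pathogenic", "supporting"))
    if (grepl("^BA", code)) return(c("benign", "stand_alone"))
    if (grepl("^BS", code)) return(c("benign", "strong"))
    if (grepl("^BP", code)) return(c("benign", "supporting"))
    stop("unknown evidence code label without explicit strength: ", code)
}

#' Build an evidence-code table
#'
#' Evidence codes are (label, polarity, strength) triples so nonstandard
#' labels are representable; polarity and strength default from the label
#' prefix (PVS/PS/PM/PP, BA/BS/BP). The cosegregation code PM7 carries
#' moderate strength by its prefix (it is the supporting cosegregation
#' code PP1 upgraded to moderate).
#'
#' @param codes character vector of code labels.
#' @param strengths optional explicit strengths (recycled), overriding the
#'   prefix defaults.
#' @param source "automatic" or "manual".
#' @return data.frame (code, polarity, strength, source).
#' @export
evidenceSet <- function(codes, strengths = NULL, source = "manual") {
    if (!length(codes))
        return(data.frame(code = character(), polarity = character(),
                          strength = character(), source = character(),
                          stringsAsFactors = FALSE))
    ps <- t(vapply(codes, .strengthFromCode, character(2)))
    df <- data.frame(code = codes, polarity = ps[, 1], strength = ps[, 2],
                     source = source, stringsAsFactors = FALSE)
    if (!is.null(strengths)) df$strength <- strengths
    rownames(df) <- NULL
    df
}

#' Assign automatic ACMG evidence codes from store context
#'
#' Derives the automatically assessable codes for a variant (or a
#' variant set treated as one unit, e.g. two cis variants):
#' \itemize{
#'   \item PM2: absent (missing or zero frequency) from every configured
#'     population panel;
#'   \item PP3: unanimous damaging in-silico consensus over at least
#'     \code{minTools} called tools;
#'   \item PS4: the odds-ratio evidence flag of the supplied association
#'     result;
#'   \item PM3: a recorded in-trans partner variant with a prior
#'     pathogenic-side label (trans phase cannot be derived from unphased
#'     VCFs, so it is accepted only as a recorded family-segregation
#'     assertion);
#'   \item PP1, upgraded to PM7 (moderate) from \code{upgradeFamilies}
#'     co-segregating families on: cosegregation with disease.
#' }
#'
#' @param wh an annotated \linkS4class{VariantWarehouse}.
#' @param keys variant key(s).
#' @param association an \linkS4class{AssociationResult} for the variant
#'   (set) in the relevant stratum; required, because PS4 cannot be
#'   assessed without the association run.
#' @param segregatingFamilies number of families in which the variant
#'   co-segregates with disease (recorded assertion; 0 = none).
#' @param transPartnerLabel clinical-significance label of a recorded
#'   in-trans partner variant, or NULL.
#' @param populations population slots consulted for PM2.
#' @param minTools minimum called tools for PP3.
#' @param upgradeFamilies cosegregating-family count at which PP1 is
#'   upgraded to PM7 (default 3).
#' @param orThreshold odds-ratio threshold handed to [ps4Assess()].
#' @return Evidence data.frame as from [evidenceSet()], source
#'   "automatic".
#' @export
assignAutoEvidence <- function(wh, keys, association,
                               segregatingFamilies = 0,
                               transPartnerLabel = NULL,
                               populations = .populationSlots,
                               minTools = 3, upgradeFamilies = 3,
                               orThreshold = 5.0) {
    if (missing(association) || is.null(association))
        stop("PS4 assessment requires an association result; ",
             "run buildContingency()/associationStats() first")
    ann <- wh@annotations[wh@annotations$key %in% keys, , drop = FALSE]
    if (!nrow(ann)) stop("no annotation for key(s): ",
                         paste(keys, collapse = ", "))
    codes <- character()
    # PM2: absent from all configured panels (every variant of the set)
    freqs <- unlist(ann[populations], use.names = FALSE)
    if (all(is.na(freqs) | freqs == 0))
        codes <- c(codes, "PM2")
    # PP3: unanimous in-silico consensus (weakest member of a set governs)
    predCols <- paste0("pred_", .predictionTools)
    unanimous <- vapply(seq_len(nrow(ann)), function(i) {
        calls <- unlist(ann[i, predCols], use.names = FALSE)
        if (all(is.na(calls))) return(FALSE)
        predictionConsensus(calls, minTools = minTools)$unanimous
    }, logical(1))
    if (length(unanimous) && all(unanimous))
        codes <- c(codes, "PP3")
    # PS4
    if (suppressMessages(ps4Assess(association, orThreshold = orThreshold)))
        codes <- c(codes, "PS4")
    # PM3
    if (!is.null(transPartnerLabel) &&
        parseSignificance(transPartnerLabel) %in%
            c("pathogenic", "likely_pathogenic"))
        codes <- c(codes, "PM3")
    # PP1 / PM7
    if (segregatingFamilies >= upgradeFamilies) codes <- c(codes, "PM7")
    else if (segregatingFamilies >= 1) codes <- c(codes, "PP1")
    evidenceSet(codes, source = "automatic")
}

.countStrength <- function(ev, polarity, strength) {
    sum(ev$polarity == polarity & ev$strength == strength)
}

#' Combine ACMG evidence codes into a pathogenicity classification
#'
#' Implements the published ACMG/AMP combining rules over strength counts.
#' With nVS/nS/nM/nP the pathogenic-side very-strong/strong/moderate/
#' supporting counts:
#' \itemize{
#'   \item Pathogenic: 1 very strong with (>=1 strong | >=2 moderate |
#'     1 moderate + 1 supporting | >=2 supporting); or >=2 strong; or
#'     1 strong with (>=3 moderate | 2 moderate + >=2 supporting |
#'     1 moderate + >=4 supporting).
#'   \item Likely pathogenic: 1 very strong + 1 moderate; 1 strong +
#'     1-2 moderate; 1 strong + >=2 supporting; >=3 moderate;
#'     2 moderate + >=2 supporting; 1 moderate + >=4 supporting.
#'   \item Benign: 1 stand-alone, or >=2 benign-strong.
#'   \item Likely benign: 1 benign-strong + 1 benign-supporting, or
#'     >=2 benign-supporting.
#' }
#' When both a pathogenic-side and a benign-side combination fire, the
#' evidence is conflicting and the verdict is uncertain; so is any
#' evidence set matching no combination.
#'
#' @param evidence data.frame from [evidenceSet()] /
#'   [assignAutoEvidence()], or a character vector of code labels.
#' @return A \linkS4class{Classification}.
#' @examples
#' combineEvidence(c("PS4", "PM7", "PP3"))   # likely_pathogenic
#' combineEvidence(c("PM2", "PM3", "PM7"))   # likely_pathogenic
#' @export
combineEvidence <- function(evidence) {
    if (is.character(evidence)) evidence <- evidenceSet(evidence)
    ev <- evidence
    nVS <- .countStrength(ev, "pathogenic", "very_strong")
    nS <- .countStrength(ev, "pathogenic", "strong")
    nM <- .countStrength(ev, "pathogenic", "moderate")
    nP <- .countStrength(ev, "pathogenic", "supporting")
    nBA <- .countStrength(ev, "benign", "stand_alone")
    nBS <- .countStrength(ev, "benign", "strong")
    nBP <- .countStrength(ev, "benign", "supporting")

    pathRule <- NULL
    if (nVS >= 2)
        pathRule <- c("pathogenic", "P-i (>=2 very strong)")
    else if (nVS >= 1 && (nS >= 1 || nM >= 2 || (nM == 1 && nP == 1) ||
                          nP >= 2))
        pathRule <- c("pathogenic", "P-i (very strong + corroboration)")
    else if (nS >= 2)
        pathRule <- c("pathogenic", "P-ii (>=2 strong)")
    else if (nS == 1 && (nM >= 3 || (nM == 2 && nP >= 2) ||
                         (nM == 1 && nP >= 4)))
        pathRule <- c("pathogenic", "P-iii (strong + moderates/supportings)")
    else if (nVS >= 1 && nM >= 1)
        pathRule <- c("likely_pathogenic", "LP-i (very strong + moderate)")
    else if (nS == 1 && nM >= 1 && nM <= 2)
        pathRule <- c("likely_pathogenic", "LP-ii (strong + 1-2 moderate)")
    else if (nS == 1 && nP >= 2)
        pathRule <- c("likely_pathogenic", "LP-iii (strong + >=2 supporting)")
    else if (nM >= 3)
        pathRule <- c("likely_pathogenic", "LP-iv (>=3 moderate)")
    else if (nM == 2 && nP >= 2)
        pathRule <- c("likely_pathogenic",
                      "LP-v (2 moderate + >=2 supporting)")
    else if (nM == 1 && nP >= 4)
        pathRule <- c("likely_pathogenic",
                      "LP-vi (moderate + >=4 supporting)")

    benRule <- NULL
    if (nBA >= 1)
        benRule <- c("benign", "B-i (stand-alone)")
    else if (nBS >= 2)
        benRule <- c("benign", "B-ii (>=2 benign strong)")
    else if (nBS == 1 && nBP >= 1)
        benRule <- c("likely_benign", "LB-i (benign strong + supporting)")
    else if (nBP >= 2)
        benRule <- c("likely_benign", "LB-ii (>=2 benign supporting)")

    if (!is.null(pathRule) && !is.null(benRule)) {
        verdict <- "uncertain"; rule <- "conflicting evidence"
    } else if (!is.null(pathRule)) {
        verdict <- pathRule[1]; rule <- pathRule[2]
    } else if (!is.null(benRule)) {
        verdict <- benRule[1]; rule <- benRule[2]
    } else {
        verdict <- "uncertain"; rule <- "no combination satisfied"
    }
    new("Classification", verdict = verdict, firedRule = rule,
        evidence = ev)
}

#' Classification accessors
#'
#' @param x a \linkS4class{Classification}.
#' @return character scalar / evidence data.frame.
#' @export
verdict <- function(x) x@verdict

#' @rdname verdict
#' @export
firedRule <- function(x) x@firedRule

setMethod("show", "Classification", function(object) {
    cat(sprintf("Classification: %s\n", object@verdict))
    cat(sprintf("  rule: %s\n", object@firedRule))
    if (nrow(object@evidence))
        cat(sprintf("  evidence: %s\n",
                    paste(object@evidence$code, collapse = " + ")))
})
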