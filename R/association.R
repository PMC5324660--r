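#' Build a stratified carrier contingency table
#'
#' Counts carriers of a variant (or of any variant in a set, e.g. two cis
#' variants) among the probands of one inheritance stratum versus the
#' control pool. Each family contributes exactly one proband;
#' unknown-inheritance cases are excluded from both strata.
#'
#' @param wh a \linkS4class{VariantWarehouse}.
#' @param keys character vector of variant keys (a carrier is a sample
#'   with at least one alt allele at any key in the set).
#' @param stratum "AD_or_mitochondrial" or "AR_or_sporadic" (abbreviations
#'   "ad" / "ar" accepted).
#' @param unit "proband_carrier" (default: cells count individuals) or
#'   "allele" (cells count chromosomes; het = 1, hom_alt = 2,
#'   hemizygous = 1 alt allele, denominators 2N).
#' @param panelAf,panelN optional frequency-only control panel folded into
#'   the control cells as carrier counts round(af * 2 * n) under a
#'   no-homozygote assumption for rare variants.
#' @return list(a, b, c, d, stratum, unit) with the cell counts.
#' @export
buildContingency <- function(wh, keys, stratum, unit = c("proband_carrier",
                             "allele"), panelAf = NULL, panelN = NULL) {
    unit <- match.arg(unit)
    stratum <- .normalizeInheritance(stratum, "case")
    if (stratum %in% c("unknown", "not_applicable"))
        stop("stratum must be an inheritance mode, got: ", stratum)
    missingKeys <- setdiff(keys, wh@registry$key)
    if (length(missingKeys))
        stop("variant(s) absent from registry: ",
             paste(missingKeys, collapse = ", "))
    s <- wh@samples
    probands <- s[s$status == "case" & s$proband_flag &
                  s$inheritance_mode == stratum, , drop = FALSE]
    if (!nrow(probands)) stop("empty stratum: ", stratum)
    controls <- s[s$status == "control", , drop = FALSE]
    obs <- wh@observations[wh@observations$key %in% keys, , drop = FALSE]
    alleleCount <- function(ids) {
        o <- obs[obs$sample_id %in% ids, , drop = FALSE]
        if (!nrow(o)) return(0L)
        per <- tapply(ifelse(o$zygosity == "hom_alt", 2L, 1L), o$sample_id,
                      sum)
        sum(per)
    }
    carrierCount <- function(ids) length(intersect(unique(obs$sample_id), ids))
    if (unit == "proband_carrier") {
        a <- carrierCount(probands$sample_id)
        b <- nrow(probands) - a
        cc <- carrierCount(controls$sample_id)
        d <- nrow(controls) - cc
    } else {
        a <- alleleCount(probands$sample_id)
        b <- 2L * nrow(probands) - a
        cc <- alleleCount(controls$sample_id)
        d <- 2L * nrow(controls) - cc
    }
    if (!is.null(panelAf)) {
        stopifnot(!is.null(panelN))
        extra <- round(panelAf * 2 * panelN)
        cc <- cc + extra
        d <- d + (if (unit == "allele") 2L * panelN else panelN) - extra
    }
    list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(cc),
         d = as.numeric(d), stratum = stratum, unit = unit)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums the hypergeometric probabilities, over all tables with the same
#' margins, of every table whose probability does not exceed that of the
#' observed table (with a relative tolerance of 1e-7 on the comparison,
#' so ties at the observed probability are included).
#'
#' @param a,b,c,d cell counts (carriers/non-carriers by group).
#' @return The two-sided P value.
#' @export
fisherExactTwoSided <- function(a, b, c, d) {
    stopifnot(a >= 0, b >= 0, c >= 0, d >= 0,
              a == round(a), b == round(b), c == round(c), d == round(d))
    m <- a + b                       # group-1 total
    n <- c + d                       # group-2 total
    k <- a + c                       # carrier margin
    if (k == 0 || k == m + n || m == 0 || n == 0) return(1)
    support <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(support, m, n, k)
    pObs <- stats::dhyper(a, m, n, k)
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Odds ratio, Woolf confidence interval and Fisher exact P for a 2x2 table
#'
#' The odds ratio is ad/(bc); when any cell is zero the Haldane-Anscombe
#' correction (+0.5 on all four cells) is applied to both the point
#' estimate and the interval, and flagged. The confidence interval is the
#' Woolf log-normal interval exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))
#' on the (corrected) cells; the exact conditional interval from the
#' Fisher test is available as an alternative. Tables where both b and d
#' are zero (no non-carriers anywhere) are degenerate.
#'
#' @param table list(a, b, c, d, ...) as from [buildContingency()], or a
#'   numeric vector c(a, b, c, d).
#' @param alpha two-sided significance level for the interval.
#' @param ciMethod "woolf" (default) or "exact" (conditional maximum
#'   likelihood interval via [stats::fisher.test()]).
#' @param orThreshold odds-ratio threshold for the PS4-style flag.
#' @return An \linkS4class{AssociationResult}.
#' @export
associationStats <- function(table, alpha = 0.05,
                             ciMethod = c("woolf", "exact"),
                             orThreshold = 5.0) {
    ciMethod <- match.arg(ciMethod)
    if (is.numeric(table)) table <- list(a = table[1], b = table[2],
                                         c = table[3], d = table[4])
    a <- table$a; b <- table$b; cc <- table$c; d <- table$d
    stopifnot(all(c(a, b, cc, d) >= 0))
    if (b == 0 && d == 0)
        stop("degenerate table: no non-carriers in either group")
    correction <- any(c(a, b, cc, d) == 0)
    cells <- c(a, b, cc, d) + if (correction) 0.5 else 0
    orPoint <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    z <- stats::qnorm(1 - alpha / 2)
    if (ciMethod == "woolf") {
        se <- sqrt(sum(1 / cells))
        ciLow <- exp(log(orPoint) - z * se)
        ciHigh <- exp(log(orPoint) + z * se)
    } else {
        ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                                 conf.level = 1 - alpha)
        ciLow <- ft$conf.int[1]
        ciHigh <- ft$conf.int[2]
    }
    p <- fisherExactTwoSided(a, b, cc, d)
    res <- new("AssociationResult", a = a, b = b, c = cc, d = d,
               stratum = if (!is.null(table$stratum)) table$stratum else "",
               countingUnit = if (!is.null(table$unit)) table$unit else
                   "proband_carrier",
               orPoint = orPoint, ciLow = ciLow, ciHigh = ciHigh,
               pValue = p, correctionApplied = correction,
               smallCountWarning = (a + cc) < 10, ps4Support = FALSE)
    res@ps4Support <- ps4Assess(res, orThreshold = orThreshold)
    validObject(res)
    res
}

#' PS4-style odds-ratio evidence flag
#'
#' The variant prevalence among affected probands counts as strong
#' evidence when the odds ratio reaches the threshold (fivefold by
#' default) and the 95 percent confidence interval excludes 1.0. Odds
#' ratios computed from single-digit carrier counts additionally carry a
#' small-count warning.
#'
#' @param result an \linkS4class{AssociationResult}, or a list with
#'   elements \code{orPoint}, \code{ciLow} (and optionally
#'   \code{smallCountWarning}) when assessing externally reported
#'   statistics.
#' @param orThreshold minimum odds ratio (default 5.0).
#' @return logical.
#' @export
ps4Assess <- function(result, orThreshold = 5.0) {
    if (is(result, "AssociationResult"))
        result <- list(orPoint = result@orPoint, ciLow = result@ciLow,
                       smallCountWarning = result@smallCountWarning)
    if (isTRUE(result$smallCountWarning))
        message("odds ratio computed from fewer than 10 carriers; ",
                "interpret with caution")
    isTRUE(result$orPoint >= orThreshold && result$ciLow > 1.0)
}

#' Association scan over a set of variants
#'
#' Computes the stratified association statistics for every key in both
#' inheritance strata and returns them as one table sorted by descending
#' odds ratio, optionally written as a tab-separated report.
#'
#' @param wh a \linkS4class{VariantWarehouse}.
#' @param keys variant keys to scan (typically cohort-filter survivors).
#' @param strata strata to scan (both by default).
#' @param unit counting unit, see [buildContingency()].
#' @param out optional path for a tab-separated report.
#' @param orThreshold odds-ratio threshold for the PS4 flag.
#' @return data.frame with columns key, gene, stratum, a, b, c, d,
#'   odds_ratio, ci_low, ci_high, p_value, ps4, small_count_warning.
#' @export
associationScan <- function(wh, keys, strata = c("AD_or_mitochondrial",
                            "AR_or_sporadic"), unit = "proband_carrier",
                            out = NULL, orThreshold = 5.0) {
    geneOf <- wh@annotations$gene[match(keys, wh@annotations$key)]
    geneOf[is.na(geneOf)] <- ""
    rows <- list()
    for (i in seq_along(keys)) {
        for (st in strata) {
            tab <- buildContingency(wh, keys[i], st, unit = unit)
            res <- suppressMessages(
                associationStats(tab, orThreshold = orThreshold))
            rows[[length(rows) + 1L]] <- data.frame(
                key = keys[i], gene = geneOf[i], stratum = st,
                a = tab$a, b = tab$b, c = tab$c, d = tab$d,
                odds_ratio = res@orPoint, ci_low = res@ciLow,
                ci_high = res@ciHigh, p_value = res@pValue,
                ps4 = res@ps4Support,
                small_count_warning = res@smallCountWarning,
                stringsAsFactors = FALSE)
        }
    }
    df <- do.call(rbind, rows)
    df <- df[order(-df$odds_ratio, df$key, df$stratum), , drop = FALSE]
    rownames(df) <- NULL
    if (!is.null(out))
        utils::write.table(format(df, digits = 15, scientific = FALSE,
                                  trim = TRUE),
                           out, sep = "\t", quote = FALSE, row.names = FALSE)
    df
}

setMethod("show", "AssociationResult", function(object) {
    cat(sprintf("AssociationResult [%s, %s]\n",
                if (nzchar(object@stratum)) object@stratum else "unstratified",
                object@countingUnit))
    cat(sprintf("  table: a=%g b=%g c=%g d=%g%s\n", object@a, object@b,
                object@c, object@d,
                if (object@correctionApplied) "  (Haldane-Anscombe +0.5)"
                else ""))
    cat(sprintf("  OR = %.3f  95%% CI (%.3f, %.3f)  P = %.4g\n",
                object@orPoint, object@ciLow, object@ciHigh, object@pValue))
    cat(sprintf("  PS4 support: %s%s\n", object@ps4Support,
                if (object@smallCountWarning) "  [small-count warning]"
                else ""))
})

#' Association-result accessors
#'
#' @param x an \linkS4class{AssociationResult}.
#' @return numeric scalars / logical flags.
#' @name association-accessors
NULL

#' @rdname association-accessors
#' @export
orPoint <- function(x) x@orPoint

#' @rdname association-accessors
#' @export
ciBounds <- function(x) c(low = x@ciLow, high = x@ciHigh)

#' @rdname association-accessors
#' @export
pValue <- function(x) x@pValue
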