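#' Default column binding for refGene-style ANNOVAR tables
#'
#' ANNOVAR output headers differ between versions and between table_annovar
#' and wANNOVAR exports, so the binding from header names to semantic slots
#' is configuration. The shipped default covers refGene-style headers.
#'
#' @return Named list mapping semantic slots to header names. Prediction
#'   tools are a named character vector under \code{predictions}.
#' @export
annovarColumnMap <- function() {
    list(contig = "Chr", start = "Start", end = "End", ref = "Ref",
         alt = "Alt", gene = "Gene.refGene", region = "Func.refGene",
         func = "ExonicFunc.refGene", hgvs = "AAChange.refGene",
         kg1000 = "1000g2015aug_all", esp6500 = "esp6500siv2_all",
         exac = "ExAC_ALL", hgvd = "HGVD", jpn2k = "2KJPN",
         inhouse_control = "InHouse",
         ada = "dbscSNV_ADA_SCORE", rf = "dbscSNV_RF_SCORE",
         clinvar = "CLNSIG",
         predictions = c(sift = "SIFT_pred",
                         polyphen = "Polyphen2_HDIV_pred",
                         lrt = "LRT_pred",
                         mutation_taster = "MutationTaster_pred",
                         fathmm = "FATHMM_pred"))
}

.regionEnum <- c("exonic", "exonic_splicing", "splicing", "intronic",
                 "UTR3", "UTR5", "ncRNA", "intergenic",
                 "upstream_downstream")

# map ANNOVAR Func labels (possibly compound, ";"-separated) to one enum
.mapRegion <- function(x) {
    x <- tolower(trimws(x))
    out <- rep(NA_character_, length(x))
    out[grepl("^exonic;splicing", x)] <- "exonic_splicing"
    out[is.na(out) & grepl("^exonic", x)] <- "exonic"
    out[is.na(out) & grepl("^splicing", x)] <- "splicing"
    out[is.na(out) & grepl("^intronic", x)] <- "intronic"
    out[is.na(out) & grepl("^utr3", x)] <- "UTR3"
    out[is.na(out) & grepl("^utr5", x)] <- "UTR5"
    out[is.na(out) & grepl("^ncrna", x)] <- "ncRNA"
    out[is.na(out) & grepl("^intergenic", x)] <- "intergenic"
    out[is.na(out) & grepl("^(upstream|downstream)", x)] <-
        "upstream_downstream"
    out
}

.functionEnum <- c("synonymous", "missense", "nonsense", "stoploss",
                   "frameshift_insertion", "frameshift_deletion",
                   "frameshift_block_substitution",
                   "nonframeshift_insertion", "nonframeshift_deletion",
                   "nonframeshift_block_substitution", "none")

.mapFunction <- function(x) {
    x <- tolower(trimws(x))
    out <- rep("none", length(x))
    out[grepl("^synonymous", x)] <- "synonymous"
    out[grepl("^nonsynonymous", x) | grepl("^missense", x)] <- "missense"
    out[grepl("^stopgain", x) | grepl("^nonsense", x)] <- "nonsense"
    out[grepl("^stoploss", x)] <- "stoploss"
    out[grepl("^frameshift insertion", x)] <- "frameshift_insertion"
    out[grepl("^frameshift deletion", x)] <- "frameshift_deletion"
    out[grepl("^frameshift (block )?substitution", x)] <-
        "frameshift_block_substitution"
    out[grepl("^nonframeshift insertion", x)] <- "nonframeshift_insertion"
    out[grepl("^nonframeshift deletion", x)] <- "nonframeshift_deletion"
    out[grepl("^nonframeshift (block )?substitution", x)] <-
        "nonframeshift_block_substitution"
    out
}

.parseMaf <- function(x) {
    x[is.na(x) | x %in% c(".", "", "NA")] <- NA
    suppressWarnings(as.numeric(x))
}

.mapPrediction <- function(x) {
    x <- toupper(trimws(as.character(x)))
    out <- rep(NA_character_, length(x))
    out[x %in% c("D", "A", "DAMAGING", "DELETERIOUS")] <- "damaging"
    out[x %in% c("T", "B", "N", "P", "TOLERATED", "TOLERANT", "BENIGN",
                 "NEUTRAL", "POLYMORPHISM")] <- "tolerated"
    out
}

#' Parse an ANNOVAR/wANNOVAR-style annotation table
#'
#' Reads a tab-separated annotation table with a header and converts each
#' row into an annotation record carrying a normalized variant key, the
#' region and functional class, population allele frequencies (missing
#' values stay missing, never zero), in-silico prediction calls, the
#' dbscSNV splice score (max of the ada and rf scores) and the parsed
#' clinical-significance label.
#'
#' @param path tab-separated file with header.
#' @param columnMap binding of semantic slots to header names; see
#'   [annovarColumnMap()].
#' @return list with \code{records} (data.frame, one row per parsed
#'   variant) and \code{rejects} (data.frame of unparseable rows with a
#'   reason).
#' @export
parseAnnotationTable <- function(path, columnMap = annovarColumnMap()) {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("contig", "start", "end", "ref", "alt", "region")
    for (slot in need) {
        colname <- columnMap[[slot]]
        if (is.null(colname) || !(colname %in% names(df)))
            stop("annotation table is missing mandatory column: ",
                 if (is.null(colname)) slot else colname)
    }
    gc <- function(slot) {
        colname <- columnMap[[slot]]
        if (!is.null(colname) && colname %in% names(df)) df[[colname]]
        else rep(NA_character_, nrow(df))
    }
    start <- suppressWarnings(as.integer(gc("start")))
    end <- suppressWarnings(as.integer(gc("end")))
    region <- .mapRegion(gc("region"))
    bad <- is.na(start) | is.na(end) | is.na(region) |
        !nzchar(gc("ref")) | !nzchar(gc("alt"))
    rejects <- data.frame(row = which(bad),
                          reason = ifelse(is.na(region[bad]),
                                          "unrecognized region class",
                                          "malformed coordinates/alleles")[
                                              seq_len(sum(bad))],
                          stringsAsFactors = FALSE)
    keep <- !bad
    contig <- normalizeContig(gc("contig")[keep])
    rec <- data.frame(
        key = variantKeyString(contig, start[keep], end[keep],
                               toupper(gc("ref")[keep]),
                               toupper(gc("alt")[keep])),
        gene = ifelse(is.na(gc("gene")[keep]), "", gc("gene")[keep]),
        region_class = region[keep],
        function_class = .mapFunction(gc("func")[keep]),
        hgvs = ifelse(is.na(gc("hgvs")[keep]), "", gc("hgvs")[keep]),
        stringsAsFactors = FALSE)
    # exonic function classes only exist on the exonic surface
    rec$function_class[!(rec$region_class %in%
                         c("exonic", "exonic_splicing"))] <- "none"
    for (p in .populationSlots)
        rec[[p]] <- .parseMaf(gc(p)[keep])
    preds <- columnMap$predictions
    for (t in .predictionTools) {
        colname <- preds[[t]]
        rec[[paste0("pred_", t)]] <-
            if (!is.null(colname) && colname %in% names(df))
                .mapPrediction(df[[colname]][keep])
            else NA_character_
    }
    ada <- .parseMaf(gc("ada")[keep])
    rf <- .parseMaf(gc("rf")[keep])
    rec$splice_score <- pmax(ada, rf, na.rm = TRUE)
    rec$splice_score[is.na(ada) & is.na(rf)] <- NA_real_
    raw <- gc("clinvar")[keep]
    raw[is.na(raw)] <- ""
    rec$clinvar_significance <- raw
    sig <- vapply(raw, parseSignificance, "", USE.NAMES = FALSE)
    rec$prior_category <- ifelse(!nzchar(raw) | raw == ".", "novel",
        c(pathogenic = "pathogenic", likely_pathogenic = "likely_pathogenic",
          benign = "benign", likely_benign = "likely_benign",
          uncertain = "unknown_significance",
          other = "unknown_significance")[sig])
    list(records = rec, rejects = rejects)
}

#' Attach annotation records to the variant registry
#'
#' Joins annotation records to registry variants by exact variant-key
#' equality. Duplicate records for one key keep the first occurrence (a
#' conflict message is emitted); records whose key is absent from the
#' registry are returned as unmatched.
#'
#' @param wh a \linkS4class{VariantWarehouse} with a populated registry.
#' @param records annotation data.frame from [parseAnnotationTable()].
#' @return The updated warehouse; the join summary is available as
#'   \code{attr(, "joinSummary")}: list(n_joined, unmatched_keys).
#' @export
joinAnnotations <- function(wh, records) {
    if (!nrow(wh@registry))
        stop("registry is empty; import VCFs and run updateRegistry() first")
    if (is.list(records) && !is.data.frame(records) &&
        !is.null(records$records))
        records <- records$records
    dup <- duplicated(records$key)
    if (any(dup)) {
        message(sum(dup),
                " duplicate annotation row(s) for already-seen keys; ",
                "keeping first occurrence")
        records <- records[!dup, , drop = FALSE]
    }
    matched <- records$key %in% wh@registry$key
    unmatched <- records$key[!matched]
    newAnn <- records[matched, , drop = FALSE]
    keep <- !(wh@annotations$key %in% newAnn$key)
    ann <- rbind(wh@annotations[keep, , drop = FALSE],
                 newAnn[names(.emptyAnnotations())])
    rownames(ann) <- NULL
    wh@annotations <- ann
    validObject(wh)
    attr(wh, "joinSummary") <- list(n_joined = sum(matched),
                                    unmatched_keys = unmatched)
    wh
}

#' Parse a clinical-significance label
#'
#' Case-insensitive containment parsing of free-text ClinVar-style labels.
#' Labels combining a same-polarity pair (e.g. "Pathogenic/Likely_pathogenic")
#' map to the more conservative of the two; labels mixing pathogenic- and
#' benign-side assertions, and explicit conflict labels, map to "other".
#'
#' @param label free-text significance string.
#' @return One of "pathogenic", "likely_pathogenic", "benign",
#'   "likely_benign", "uncertain", "other".
#' @export
parseSignificance <- function(label) {
    s <- tolower(gsub("_", " ", as.character(label)))
    if (is.na(s) || !nzchar(trimws(s))) return("other")
    if (grepl("conflicting", s)) return("other")
    hasLP <- grepl("likely[ /]?pathogenic", s)
    hasP <- grepl("pathogenic", gsub("likely[ /]?pathogenic", "", s))
    hasLB <- grepl("likely[ /]?benign", s)
    hasB <- grepl("benign", gsub("likely[ /]?benign", "", s))
    hasU <- grepl("uncertain|unknown significance|\\bvus\\b", s)
    pathSide <- hasLP || hasP
    benSide <- hasLB || hasB
    if (pathSide && benSide) return("other")
    if (pathSide) return(if (hasLP && hasP) "likely_pathogenic"
                         else if (hasP) "pathogenic" else "likely_pathogenic")
    if (benSide) return(if (hasLB && hasB) "likely_benign"
                        else if (hasB) "benign" else "likely_benign")
    if (hasU) return("uncertain")
    "other"
}

#' Consensus over in-silico prediction calls
#'
#' @param calls character vector of per-tool calls in
#'   \{"damaging", "tolerated", NA\}.
#' @param minTools minimum number of non-missing calls for a unanimous
#'   consensus to count.
#' @return list(n_damaging, n_called, unanimous).
#' @export
predictionConsensus <- function(calls, minTools = 3) {
    calls <- unlist(calls, use.names = FALSE)
    nCalled <- sum(!is.na(calls))
    if (nCalled == 0) stop("no predictions: all calls are missing")
    nDamaging <- sum(calls == "damaging", na.rm = TRUE)
    list(n_damaging = nDamaging, n_called = nCalled,
         unanimous = nDamaging == nCalled && nCalled >= minTools)
}
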