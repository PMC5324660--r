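#' Construct a VariantWarehouse
#'
#' Creates an empty warehouse, or one populated directly from sample and
#' observation tables (useful for programmatic construction and testing;
#' the usual route into a warehouse is [importVcf()]).
#'
#' @param samples optional data.frame with at least sample_id, status,
#'   inheritance_mode; missing columns are filled with defaults.
#' @param observations optional data.frame with at least sample_id, key
#'   or the key fields (contig, start, end, ref, alt) plus zygosity.
#' @param config list of store configuration: \code{chr_prefix} (default
#'   TRUE), \code{filter_pass_only} (default TRUE: only PASS/"." VCF
#'   records are ingested).
#' @return A \linkS4class{VariantWarehouse}.
#' @export
VariantWarehouse <- function(samples = NULL, observations = NULL,
                             config = list()) {
    cfg <- list(chr_prefix = TRUE, filter_pass_only = TRUE)
    cfg[names(config)] <- config
    wh <- new("VariantWarehouse", samples = .emptySamples(),
              observations = .emptyObservations(),
              registry = .emptyRegistry(), annotations = .emptyAnnotations(),
              clinicalNumeric = data.frame(sample_id = character(),
                  field = character(), value = numeric(),
                  stringsAsFactors = FALSE),
              clinicalCategorical = data.frame(sample_id = character(),
                  field = character(), value = character(),
                  stringsAsFactors = FALSE),
              clinicalSeries = data.frame(sample_id = character(),
                  field = character(), x = numeric(), y = numeric(),
                  interpolated = logical(), stringsAsFactors = FALSE),
              seriesGrids = list(), config = cfg,
              importLog = .emptyImportLog())
    if (!is.null(samples))
        wh <- addSamples(wh, samples)
    if (!is.null(observations)) {
        obs <- as.data.frame(observations, stringsAsFactors = FALSE)
        if (is.null(obs$key))
            obs$key <- variantKeyString(obs$contig, obs$start, obs$end,
                                        obs$ref, obs$alt)
        if (is.null(obs$contig)) {
            kf <- parseKeyString(obs$key)
            obs$contig <- kf$contig; obs$start <- kf$start
            obs$end <- kf$end; obs$ref <- kf$ref; obs$alt <- kf$alt
        }
        if (is.null(obs$zygosity)) obs$zygosity <- "het"
        if (is.null(obs$gt)) obs$gt <- "0/1"
        if (is.null(obs$filter)) obs$filter <- "PASS"
        wh@observations <- rbind(.emptyObservations(),
                                 obs[names(.emptyObservations())])
        wh <- updateRegistry(wh)
    }
    validObject(wh)
    wh
}

# Fill sample-sheet defaults and designate probands (first affected sample
# of each family unless a proband_flag is supplied).
addSamples <- function(wh, samples) {
    s <- as.data.frame(samples, stringsAsFactors = FALSE)
    if (is.null(s$sample_id)) stop("samples require a sample_id column")
    if (is.null(s$status)) stop("samples require a status column")
    if (is.null(s$project)) s$project <- "default"
    if (is.null(s$inheritance_mode))
        s$inheritance_mode <- ifelse(s$status == "control",
                                     "not_applicable", "unknown")
    s$inheritance_mode[s$status == "control"] <- "not_applicable"
    if (is.null(s$family_id) )
        s$family_id <- s$sample_id
    s$family_id[is.na(s$family_id) | !nzchar(s$family_id)] <-
        s$sample_id[is.na(s$family_id) | !nzchar(s$family_id)]
    for (col in c("confirmation_seq", "confirmation_segregation", "diagnosis"))
        if (is.null(s[[col]])) s[[col]] <- ""
    explicit <- !is.null(samples$proband_flag)
    if (!explicit) s$proband_flag <- FALSE
    combined <- rbind(wh@samples, s[names(.emptySamples())])
    # proband designation: keep explicit flags; otherwise first case per family
    for (fam in unique(combined$family_id[combined$status == "case"])) {
        idx <- which(combined$family_id == fam & combined$status == "case")
        if (!any(combined$proband_flag[idx]))
            combined$proband_flag[idx[1]] <- TRUE
    }
    combined$proband_flag[combined$status == "control"] <- FALSE
    wh@samples <- combined
    validObject(wh)
    wh
}

.zygosityFromAlleles <- function(alleles, altIndex) {
    hits <- sum(alleles == altIndex)
    if (length(alleles) == 1L) return("hemizygous")
    if (hits == length(alleles)) "hom_alt" else "het"
}

#' Import a single-sample VCF file into the warehouse
#'
#' Each passing variant record becomes one genotype observation per alt
#' allele referenced by the genotype, keyed by [normalizeVariant()].
#' Re-importing the same file for the same sample is idempotent. By default
#' only records whose FILTER is PASS or "." are ingested, and genotypes
#' with missing alleles ("./.", "0/.") are not stored.
#'
#' @param wh a \linkS4class{VariantWarehouse}.
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @param sampleId unique sample identifier.
#' @param status "case" or "control".
#' @param inheritance "AD_or_mitochondrial", "AR_or_sporadic", "unknown"
#'   (cases) or "not_applicable" (controls).
#' @param project free-text project label.
#' @param familyId family identifier (defaults to the sample id).
#' @param probandFlag optional logical; when NA the first affected sample
#'   of a family is designated proband.
#' @return The updated warehouse. The per-file import summary (records
#'   read, observations stored, records rejected) is appended to
#'   [importLog()].
#' @export
importVcf <- function(wh, path, sampleId, status = c("case", "control"),
                      inheritance = NULL, project = "default",
                      familyId = NULL, probandFlag = NA) {
    status <- match.arg(status)
    if (is.null(inheritance))
        inheritance <- if (status == "control") "not_applicable" else "unknown"
    inheritance <- .normalizeInheritance(inheritance, status)
    meta <- data.frame(sample_id = sampleId, project = project,
                       status = status, inheritance_mode = inheritance,
                       family_id = if (is.null(familyId)) sampleId else familyId,
                       stringsAsFactors = FALSE)
    existing <- wh@samples[wh@samples$sample_id == sampleId, , drop = FALSE]
    if (nrow(existing)) {
        same <- all(existing$project == meta$project,
                    existing$status == meta$status,
                    existing$inheritance_mode == meta$inheritance_mode,
                    existing$family_id == meta$family_id)
        if (!same)
            stop("sample_id ", sampleId,
                 " already registered with different metadata")
    } else {
        if (!is.na(probandFlag)) meta$proband_flag <- probandFlag
        wh <- addSamples(wh, meta)
    }

    v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    nRead <- nrow(fix)
    gtMat <- if (ncol(v@gt) >= 2)
        vcfR::extract.gt(v, element = "GT") else NULL
    rows <- vector("list", nRead)
    nRejected <- 0L
    for (i in seq_len(nRead)) {
        filt <- fix[i, "FILTER"]
        if (is.na(filt)) filt <- "."
        if (isTRUE(wh@config$filter_pass_only) &&
            !(filt %in% c("PASS", "."))) {
            nRejected <- nRejected + 1L
            next
        }
        alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
        gt <- if (!is.null(gtMat)) gtMat[i, 1] else NA_character_
        if (is.na(gt) || !nzchar(gt) || gt == ".") {
            nRejected <- nRejected + 1L
            next
        }
        alleles <- suppressWarnings(
            as.integer(strsplit(gt, "[/|]")[[1]]))
        if (anyNA(alleles)) {           # half-called / missing genotype
            nRejected <- nRejected + 1L
            next
        }
        used <- sort(unique(alleles[alleles > 0L]))
        if (!length(used)) {            # hom-ref record
            nRejected <- nRejected + 1L
            next
        }
        recRows <- list()
        ok <- TRUE
        for (ai in used) {
            if (ai > length(alts)) { ok <- FALSE; break }
            key <- tryCatch(
                normalizeVariant(fix[i, "CHROM"], as.integer(fix[i, "POS"]),
                                 fix[i, "REF"], alts[ai],
                                 chrPrefix = isTRUE(wh@config$chr_prefix)),
                error = function(e) NULL)
            if (is.null(key)) { ok <- FALSE; break }
            key$sample_id <- sampleId
            key$zygosity <- .zygosityFromAlleles(alleles, ai)
            key$gt <- gt
            key$filter <- filt
            recRows[[length(recRows) + 1L]] <- key
        }
        if (!ok) {
            nRejected <- nRejected + 1L
            next
        }
        rows[[i]] <- do.call(rbind, recRows)
    }
    newObs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    nStored <- 0L
    if (!is.null(newObs) && nrow(newObs)) {
        newObs <- newObs[names(.emptyObservations())]
        dupInFile <- duplicated(newObs[c("sample_id", "key")])
        newObs <- newObs[!dupInFile, , drop = FALSE]
        have <- paste(wh@observations$sample_id, wh@observations$key)
        fresh <- !(paste(newObs$sample_id, newObs$key) %in% have)
        nStored <- sum(fresh)
        wh@observations <- rbind(wh@observations,
                                 newObs[fresh, , drop = FALSE])
    }
    wh@importLog <- rbind(wh@importLog,
        data.frame(path = path, sample_id = sampleId,
                   records_read = nRead, observations_stored = nStored,
                   records_rejected = nRejected, stringsAsFactors = FALSE))
    validObject(wh)
    wh
}

.normalizeInheritance <- function(x, status) {
    x <- tolower(x)
    mode <- switch(x,
        "ad" = , "ad_or_mitochondrial" = , "mitochondrial" =
            "AD_or_mitochondrial",
        "ar" = , "ar_or_sporadic" = , "sporadic" = "AR_or_sporadic",
        "unknown" = "unknown",
        "not_applicable" = , "na" = "not_applicable",
        stop("unknown inheritance mode: ", x))
    if (status == "control") "not_applicable" else mode
}

#' Rebuild the deduplicated variant registry
#'
#' Scans all stored genotype observations and rebuilds the unique-variant
#' registry (the "database update" step). Reproducible on re-run.
#'
#' @param wh a \linkS4class{VariantWarehouse}.
#' @return The warehouse with an up-to-date registry.
#' @seealso [registryCounts()]
#' @export
updateRegistry <- function(wh) {
    obs <- wh@observations
    if (!nrow(obs)) {
        wh@registry <- .emptyRegistry()
        return(wh)
    }
    reg <- unique(obs[c("key", "contig", "start", "end", "ref", "alt")])
    reg <- reg[order(reg$contig, reg$start, reg$end, reg$ref, reg$alt), ,
               drop = FALSE]
    rownames(reg) <- NULL
    wh@registry <- reg
    validObject(wh)
    wh
}

#' Registry size: unique variants and total observations
#'
#' @param wh a \linkS4class{VariantWarehouse}.
#' @return Named integer vector c(n_unique_variants, n_observations).
#' @export
registryCounts <- function(wh) {
    c(n_unique_variants = nrow(wh@registry),
      n_observations = nrow(wh@observations))
}

#' Export the unique-variant list in ANNOVAR format
#'
#' Writes one tab-separated row per registry variant: contig, start, end,
#' ref, alt (1-based inclusive, "-" for absent indel alleles), suitable as
#' input to table_annovar / wANNOVAR. No header line.
#'
#' @param wh a \linkS4class{VariantWarehouse}.
#' @param path output file path.
#' @return Invisibly, the number of rows written.
#' @export
exportAnnovarList <- function(wh, path) {
    if (!nrow(wh@registry)) stop("registry is empty; run updateRegistry()")
    reg <- wh@registry[c("contig", "start", "end", "ref", "alt")]
    utils::write.table(reg, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(nrow(reg))
}

#' Read an ANNOVAR-format variant list
#'
#' @param path a file written by [exportAnnovarList()] (or any headerless
#'   5-column ANNOVAR variant list).
#' @return data.frame with key, contig, start, end, ref, alt.
#' @export
readAnnovarList <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("contig", "start", "end",
                                          "ref", "alt"),
                            colClasses = c("character", "integer", "integer",
                                           "character", "character"))
    df$key <- variantKeyString(df$contig, df$start, df$end, df$ref, df$alt)
    df[c("key", "contig", "start", "end", "ref", "alt")]
}

#' Warehouse accessors
#'
#' @param wh a \linkS4class{VariantWarehouse}.
#' @return The corresponding data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
sampleTable <- function(wh) wh@samples

#' @rdname accessors
#' @export
observationTable <- function(wh) wh@observations

#' @rdname accessors
#' @export
variantRegistry <- function(wh) wh@registry

#' @rdname accessors
#' @export
annotationTable <- function(wh) wh@annotations

#' @rdname accessors
#' @export
importLog <- function(wh) wh@importLog

setMethod("show", "VariantWarehouse", function(object) {
    s <- object@samples
    cat("VariantWarehouse\n")
    cat(sprintf("  samples:      %d (%d case, %d control)\n", nrow(s),
                sum(s$status == "case"), sum(s$status == "control")))
    cat(sprintf("  observations: %d\n", nrow(object@observations)))
    cat(sprintf("  registry:     %d unique variants (%d annotated)\n",
                nrow(object@registry), nrow(object@annotations)))
})

#' Save / load a warehouse as a plain-text snapshot directory
#'
#' Persistence is a directory of TSV/CSV/JSON files so a store can be
#' inspected, versioned and reloaded without any database server.
#'
#' @param wh a \linkS4class{VariantWarehouse}.
#' @param dir snapshot directory (created if absent).
#' @return \code{saveWarehouse}: invisibly, \code{dir};
#'   \code{loadWarehouse}: the reconstructed warehouse.
#' @export
saveWarehouse <- function(wh, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, f) utils::write.table(df, file.path(dir, f),
        sep = "\t", quote = FALSE, row.names = FALSE)
    wt(wh@samples, "samples.tsv")
    wt(wh@observations, "observations.tsv")
    wt(wh@registry, "registry.tsv")
    wt(wh@annotations, "annotations.tsv")
    wt(wh@clinicalNumeric, "clinical_numeric.tsv")
    wt(wh@clinicalCategorical, "clinical_categorical.tsv")
    wt(wh@clinicalSeries, "clinical_series.tsv")
    wt(wh@importLog, "import_log.tsv")
    jsonlite::write_json(list(config = wh@config,
                              seriesGrids = wh@seriesGrids),
                         file.path(dir, "config.json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(dir)
}

#' @rdname saveWarehouse
#' @export
loadWarehouse <- function(dir) {
    rd <- function(f, template) {
        p <- file.path(dir, f)
        df <- utils::read.table(p, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE,
                                colClasses = vapply(template, class, ""))
        if (!nrow(df)) template else df
    }
    meta <- jsonlite::read_json(file.path(dir, "config.json"),
                                simplifyVector = TRUE)
    wh <- VariantWarehouse(config = as.list(meta$config))
    wh@samples <- rd("samples.tsv", .emptySamples())
    wh@observations <- rd("observations.tsv", .emptyObservations())
    wh@registry <- rd("registry.tsv", .emptyRegistry())
    wh@annotations <- rd("annotations.tsv", .emptyAnnotations())
    wh@clinicalNumeric <- rd("clinical_numeric.tsv", wh@clinicalNumeric)
    wh@clinicalCategorical <- rd("clinical_categorical.tsv",
                                 wh@clinicalCategorical)
    wh@clinicalSeries <- rd("clinical_series.tsv", wh@clinicalSeries)
    wh@importLog <- rd("import_log.tsv", .emptyImportLog())
    grids <- meta$seriesGrids
    wh@seriesGrids <- if (length(grids)) lapply(grids, as.numeric) else list()
    validObject(wh)
    wh
}
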