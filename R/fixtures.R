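#' Specify a synthetic cohort
#'
#' Defines the generative model of a synthetic case-control cohort: the
#' number of autosomal-dominant-type families, autosomal-recessive /
#' sporadic families (one sequenced proband each) and controls, a table
#' of variants with per-stratum carrier probabilities and annotation
#' attributes, an optional clinical model, and the seed that fully
#' determines the generated bytes.
#'
#' @param nAdFamilies,nArFamilies,nControls cohort sizes.
#' @param variants data.frame with columns contig, pos, ref, alt (VCF
#'   dialect) plus optional gene, region (ANNOVAR Func label), func
#'   (ANNOVAR ExonicFunc label), kg1000, esp6500, exac, hgvd, jpn2k,
#'   inhouse, ada, rf, clnsig, pAd, pAr, pCtrl (carrier probabilities,
#'   default 0).
#' @param clinicalModel optional list(effectVariant = row index,
#'   numeric = data.frame(field, mean_carrier, sd_carrier,
#'   mean_noncarrier, sd_noncarrier)): carriers of the effect variant
#'   draw their numeric fields from the shifted normal.
#' @param seed integer seed.
#' @return list of class "CohortSpec".
#' @export
cohortSpec <- function(nAdFamilies, nArFamilies, nControls, variants,
                       clinicalModel = NULL, seed = 1L) {
    v <- as.data.frame(variants, stringsAsFactors = FALSE)
    stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(v)))
    defaults <- list(gene = "GENE", region = "exonic",
                     func = "nonsynonymous SNV", kg1000 = NA_real_,
                     esp6500 = NA_real_, exac = NA_real_, hgvd = NA_real_,
                     jpn2k = NA_real_, inhouse = NA_real_, ada = NA_real_,
                     rf = NA_real_, clnsig = "", pAd = 0, pAr = 0, pCtrl = 0)
    for (nm in names(defaults))
        if (is.null(v[[nm]])) v[[nm]] <- defaults[[nm]]
    probs <- c(v$pAd, v$pAr, v$pCtrl)
    stopifnot(all(probs >= 0 & probs <= 1))
    structure(list(nAdFamilies = nAdFamilies, nArFamilies = nArFamilies,
                   nControls = nControls, variants = v,
                   clinicalModel = clinicalModel, seed = as.integer(seed)),
              class = "CohortSpec")
}

.writeSampleVcf <- function(path, sampleId, records) {
    header <- c("##fileformat=VCFv4.1",
                "##source=varwarden synthetic cohort generator",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                       sampleId))
    body <- if (nrow(records))
        sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s", records$contig,
                as.integer(records$pos), records$ref, records$alt,
                records$gt)
    else character()
    writeLines(c(header, body), path)
}

.annovarHeader <- c("Chr", "Start", "End", "Ref", "Alt", "Func.refGene",
                    "Gene.refGene", "ExonicFunc.refGene", "AAChange.refGene",
                    "1000g2015aug_all", "esp6500siv2_all", "ExAC_ALL",
                    "HGVD", "2KJPN", "InHouse", "dbscSNV_ADA_SCORE",
                    "dbscSNV_RF_SCORE", "CLNSIG", "SIFT_pred",
                    "Polyphen2_HDIV_pred", "LRT_pred",
                    "MutationTaster_pred", "FATHMM_pred")

.writeAnnotationTable <- function(path, v, predictions = NULL) {
    norm <- do.call(rbind, lapply(seq_len(nrow(v)), function(i)
        normalizeVariant(v$contig[i], v$pos[i], v$ref[i], v$alt[i])))
    dot <- function(x) ifelse(is.na(x), ".", as.character(x))
    if (is.null(predictions))
        predictions <- matrix(".", nrow(v), 5)
    out <- data.frame(norm$contig, norm$start, norm$end, norm$ref, norm$alt,
                      v$region, v$gene, dot(ifelse(v$func == "", ".",
                                                   v$func)),
                      ".", dot(v$kg1000), dot(v$esp6500), dot(v$exac),
                      dot(v$hgvd), dot(v$jpn2k), dot(v$inhouse),
                      dot(v$ada), dot(v$rf),
                      ifelse(nzchar(v$clnsig), v$clnsig, "."),
                      predictions[, 1], predictions[, 2], predictions[, 3],
                      predictions[, 4], predictions[, 5],
                      stringsAsFactors = FALSE)
    names(out) <- .annovarHeader
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(norm$key)
}

#' Generate a synthetic cohort on disk
#'
#' Draws carrier status as independent Bernoulli trials per sample and
#' variant (with the stratum-specific probability), writes one VCF per
#' sample, the ANNOVAR-style annotation table, the sample sheet, the
#' clinical table, and a truth table recording every draw. Identical
#' seeds yield identical bytes.
#'
#' @param spec a [cohortSpec()].
#' @param dir output directory (created).
#' @return list(dir, samples, truth, annotation, vcfs) with the file
#'   paths and the truth data.frame (sample_id, variant row, carrier,
#'   zygosity).
#' @export
generateCohort <- function(spec, dir) {
    stopifnot(inherits(spec, "CohortSpec"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    oldSeed <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(oldSeed))
        assign(".Random.seed", oldSeed, globalenv()))
    set.seed(spec$seed)
    samples <- data.frame(
        sample_id = c(sprintf("AD%04d", seq_len(spec$nAdFamilies)),
                      sprintf("AR%04d", seq_len(spec$nArFamilies)),
                      sprintf("CT%04d", seq_len(spec$nControls))),
        status = c(rep("case", spec$nAdFamilies + spec$nArFamilies),
                   rep("control", spec$nControls)),
        inheritance = c(rep("ad", spec$nAdFamilies),
                        rep("ar", spec$nArFamilies),
                        rep("not_applicable", spec$nControls)),
        stringsAsFactors = FALSE)
    samples$family_id <- samples$sample_id
    v <- spec$variants
    nV <- nrow(v)
    probFor <- function(group)
        switch(group, ad = v$pAd, ar = v$pAr, v$pCtrl)
    truth <- vector("list", nrow(samples))
    vcfs <- character(nrow(samples))
    for (i in seq_len(nrow(samples))) {
        p <- probFor(samples$inheritance[i])
        carrier <- stats::rbinom(nV, 1L, p) == 1L
        truth[[i]] <- data.frame(sample_id = samples$sample_id[i],
                                 variant_row = seq_len(nV),
                                 carrier = carrier,
                                 zygosity = ifelse(carrier, "het", ""),
                                 stringsAsFactors = FALSE)
        rec <- v[carrier, c("contig", "pos", "ref", "alt"), drop = FALSE]
        rec$gt <- rep("0/1", nrow(rec))
        vcfs[i] <- file.path(dir, paste0(samples$sample_id[i], ".vcf"))
        .writeSampleVcf(vcfs[i], samples$sample_id[i], rec)
    }
    truth <- do.call(rbind, truth)
    annPath <- file.path(dir, "annotation.tsv")
    keys <- .writeAnnotationTable(annPath, v)
    truth$key <- keys[truth$variant_row]
    utils::write.csv(samples, file.path(dir, "samples.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    clinPath <- NULL
    cm <- spec$clinicalModel
    if (!is.null(cm)) {
        effKey <- keys[cm$effectVariant]
        isCarrier <- truth$carrier[truth$key == effKey][
            match(samples$sample_id,
                  truth$sample_id[truth$key == effKey])]
        clin <- data.frame(sample_id = samples$sample_id,
                           stringsAsFactors = FALSE, check.names = FALSE)
        for (j in seq_len(nrow(cm$numeric))) {
            f <- cm$numeric[j, ]
            vals <- ifelse(isCarrier,
                stats::rnorm(nrow(samples), f$mean_carrier, f$sd_carrier),
                stats::rnorm(nrow(samples), f$mean_noncarrier,
                             f$sd_noncarrier))
            clin[[paste0("numeric:", f$field)]] <- round(vals, 3)
        }
        clinPath <- file.path(dir, "clinical.csv")
        utils::write.csv(clin, clinPath, row.names = FALSE, quote = FALSE)
    }
    list(dir = dir, samples = samples, truth = truth,
         annotation = annPath, clinical = clinPath, vcfs = vcfs,
         keys = keys)
}

#' Load a generated cohort directory into a warehouse
#'
#' Convenience wrapper running the full import, update and annotate path
#' over the files written by [generateCohort()].
#'
#' @param gen the list returned by [generateCohort()].
#' @return An annotated \linkS4class{VariantWarehouse}.
#' @export
loadCohort <- function(gen) {
    wh <- VariantWarehouse()
    for (i in seq_len(nrow(gen$samples)))
        wh <- importVcf(wh, gen$vcfs[i], gen$samples$sample_id[i],
                        status = gen$samples$status[i],
                        inheritance = gen$samples$inheritance[i],
                        familyId = gen$samples$family_id[i])
    wh <- updateRegistry(wh)
    parsed <- parseAnnotationTable(gen$annotation)
    wh <- joinAnnotations(wh, parsed$records)
    if (!is.null(gen$clinical)) wh <- importClinical(wh, gen$clinical)
    wh
}

# shared scaffolding of the two worked-example case fixtures
.caseProfileSpec <- function(nCommon, nNoncoding, nSynonymous, nInhouseHigh,
                             nSurvivor, survivorGene, contig, seed) {
    n <- nCommon + nNoncoding + nSynonymous + nInhouseHigh + nSurvivor
    pos <- 10000L + 10L * seq_len(n)
    v <- data.frame(contig = contig, pos = pos, ref = "A", alt = "G",
                    gene = sprintf("GENE%03d", seq_len(n)),
                    region = "exonic", func = "nonsynonymous SNV",
                    kg1000 = NA_real_, esp6500 = NA_real_, exac = NA_real_,
                    hgvd = NA_real_, jpn2k = NA_real_, inhouse = NA_real_,
                    ada = NA_real_, rf = NA_real_, clnsig = "",
                    pAd = 0, pAr = 0, pCtrl = 0, stringsAsFactors = FALSE)
    i <- 0L
    common <- i + seq_len(nCommon); i <- i + nCommon
    v$kg1000[common] <- 0.05            # fails the public-MAF stage
    noncod <- i + seq_len(nNoncoding); i <- i + nNoncoding
    v$region[noncod] <- rep(c("intronic", "UTR3", "UTR5"),
                            length.out = nNoncoding)
    v$func[noncod] <- ""
    syn <- i + seq_len(nSynonymous); i <- i + nSynonymous
    v$func[syn] <- "synonymous SNV"     # no splice rescue: score missing
    inh <- i + seq_len(nInhouseHigh); i <- i + nInhouseHigh
    v$inhouse[inh] <- 0.02              # fails the in-house stage
    surv <- i + seq_len(nSurvivor)
    v$gene[surv] <- survivorGene
    list(variants = v, survivorRows = surv, seed = seed)
}

.writeCaseProfile <- function(profile, dir, indexId, inheritance,
                              nExtraCarriers, extraPrefix) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    v <- profile$variants
    # all in-silico tools call the survivor variants damaging
    preds <- matrix(".", nrow(v), 5)
    preds[profile$survivorRows, ] <- "D"
    annPath <- file.path(dir, "annotation.tsv")
    keys <- .writeAnnotationTable(annPath, v, predictions = preds)
    indexVcf <- file.path(dir, paste0(indexId, ".vcf"))
    rec <- v[c("contig", "pos", "ref", "alt")]
    rec$gt <- "0/1"
    .writeSampleVcf(indexVcf, indexId, rec)
    samples <- data.frame(sample_id = indexId, status = "case",
                          inheritance = inheritance, vcf = indexVcf,
                          stringsAsFactors = FALSE)
    # further families carrying (only) the survivor variants
    for (j in seq_len(nExtraCarriers)) {
        sid <- sprintf("%s%02d", extraPrefix, j)
        p <- file.path(dir, paste0(sid, ".vcf"))
        recj <- v[profile$survivorRows, c("contig", "pos", "ref", "alt"),
                  drop = FALSE]
        recj$gt <- "0/1"
        .writeSampleVcf(p, sid, recj)
        samples <- rbind(samples,
            data.frame(sample_id = sid, status = "case",
                       inheritance = inheritance, vcf = p,
                       stringsAsFactors = FALSE))
    }
    list(dir = dir, samples = samples, annotation = annPath,
         indexId = indexId, survivorKeys = keys[profile$survivorRows],
         keys = keys)
}

#' Worked-example case fixtures
#'
#' Two on-disk fixtures whose index sample's annotation profile drives the
#' per-case funnel through a fixed stage sequence:
#' \itemize{
#'   \item \code{case1Profile()}: an autosomal-dominant index case
#'     observing 333 variants, of which 15 pass the public-MAF stage, 6
#'     are exonic, 5 protein-affecting and 2 survive the in-house stage
#'     (both in the same gene), plus four further carrier families of the
#'     two surviving variants.
#'   \item \code{case2Profile()}: a sporadic index case observing 392
#'     variants with stage counts 24, 10, 8 and finally 5, plus three
#'     further carrier families.
#' }
#' Both load through the full import, annotate and filter path.
#'
#' @param dir output directory (a fresh temporary directory by default).
#' @return list(dir, samples, annotation, indexId, survivorKeys, keys);
#'   feed to [loadCaseProfile()].
#' @export
case1Profile <- function(dir = tempfile("case1_")) {
    prof <- .caseProfileSpec(nCommon = 318, nNoncoding = 9,
                             nSynonymous = 1, nInhouseHigh = 3,
                             nSurvivor = 2, survivorGene = "GENE_A",
                             contig = "chr11", seed = 11L)
    .writeCaseProfile(prof, dir, indexId = "CASE1_INDEX",
                      inheritance = "ad", nExtraCarriers = 4,
                      extraPrefix = "C1FAM")
}

#' @rdname case1Profile
#' @export
case2Profile <- function(dir = tempfile("case2_")) {
    prof <- .caseProfileSpec(nCommon = 368, nNoncoding = 14,
                             nSynonymous = 2, nInhouseHigh = 3,
                             nSurvivor = 5, survivorGene = "GENE_B",
                             contig = "chr10", seed = 12L)
    .writeCaseProfile(prof, dir, indexId = "CASE2_INDEX",
                      inheritance = "ar", nExtraCarriers = 3,
                      extraPrefix = "C2FAM")
}

#' @rdname case1Profile
#' @param profile the list returned by \code{case1Profile()} /
#'   \code{case2Profile()}.
#' @export
loadCaseProfile <- function(profile) {
    wh <- VariantWarehouse()
    for (i in seq_len(nrow(profile$samples)))
        wh <- importVcf(wh, profile$samples$vcf[i],
                        profile$samples$sample_id[i],
                        status = profile$samples$status[i],
                        inheritance = profile$samples$inheritance[i])
    wh <- updateRegistry(wh)
    parsed <- parseAnnotationTable(profile$annotation)
    joinAnnotations(wh, parsed$records)
}

#' Simulate stratified carrier counts
#'
#' Replicated Bernoulli-cohort draws for the parameter-recovery check:
#' each replicate draws the carrier count among probands and controls
#' from the respective binomials and returns the 2x2 cells.
#'
#' @param nCase,nControl cohort sizes.
#' @param pCase,pControl carrier probabilities.
#' @param reps number of replicates.
#' @return data.frame (a, b, c, d), one row per replicate.
#' @export
simulateCarrierCounts <- function(nCase, nControl, pCase, pControl,
                                  reps = 200) {
    a <- stats::rbinom(reps, nCase, pCase)
    cc <- stats::rbinom(reps, nControl, pControl)
    data.frame(a = a, b = nCase - a, c = cc, d = nControl - cc)
}
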