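# Local VCF writer, independent of the package's generator, so import
# tests do not depend on the code under test.
writeTestVcf <- function(path, sampleId, chrom, pos, ref, alt, gt,
                         filter = rep("PASS", length(pos))) {
    header <- c("##fileformat=VCFv4.1",
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                       sampleId))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\tGT\t%s",
                    chrom, as.integer(pos), ref, alt, filter, gt)
    writeLines(c(header, body), path)
    path
}

# Annotation-record builder with the full column set expected by
# joinAnnotations(), defaulting every optional attribute to missing.
makeAnnRecords <- function(key, gene = "GENE", region_class = "exonic",
                           function_class = "missense", hgvs = "",
                           kg1000 = NA_real_, esp6500 = NA_real_,
                           exac = NA_real_, hgvd = NA_real_,
                           jpn2k = NA_real_, inhouse_control = NA_real_,
                           splice_score = NA_real_,
                           clinvar_significance = "",
                           prior_category = "novel",
                           pred = NA_character_) {
    n <- length(key)
    df <- data.frame(key = key, gene = rep_len(gene, n),
                     region_class = rep_len(region_class, n),
                     function_class = rep_len(function_class, n),
                     hgvs = rep_len(hgvs, n),
                     kg1000 = rep_len(kg1000, n),
                     esp6500 = rep_len(esp6500, n),
                     exac = rep_len(exac, n),
                     hgvd = rep_len(hgvd, n),
                     jpn2k = rep_len(jpn2k, n),
                     inhouse_control = rep_len(inhouse_control, n),
                     stringsAsFactors = FALSE)
    for (t in c("sift", "polyphen", "lrt", "mutation_taster", "fathmm"))
        df[[paste0("pred_", t)]] <- rep_len(pred, n)
    df$splice_score <- rep_len(splice_score, n)
    df$clinvar_significance <- rep_len(clinvar_significance, n)
    df$prior_category <- rep_len(prior_category, n)
    df
}

# Small annotated warehouse: 4 AD probands (2 carriers of v1),
# 3 controls (1 carrier of v1, 2 carriers of v3 only), 2 AR probands.
tinyWarehouse <- function() {
    keys <- variantKeyString("chr1", c(100, 200, 300), c(100, 200, 300),
                             "A", c("G", "T", "C"))
    obs <- function(id, k) data.frame(sample_id = id, key = k,
                                      stringsAsFactors = FALSE)
    samples <- data.frame(
        sample_id = c("AD1", "AD2", "AD3", "AD4", "AR1", "AR2",
                      "CT1", "CT2", "CT3"),
        status = c(rep("case", 6), rep("control", 3)),
        inheritance_mode = c(rep("AD_or_mitochondrial", 4),
                             rep("AR_or_sporadic", 2),
                             rep("not_applicable", 3)),
        stringsAsFactors = FALSE)
    observations <- rbind(
        obs("AD1", keys[1]), obs("AD2", keys[1]), obs("AD1", keys[2]),
        obs("AR1", keys[2]), obs("CT1", keys[1]),
        obs("CT2", keys[3]), obs("CT3", keys[3]))
    wh <- VariantWarehouse(samples = samples, observations = observations)
    ann <- makeAnnRecords(keys, gene = c("GENE_A", "GENE_A", "GENE_B"))
    wh <- joinAnnotations(wh, ann)
    attr(wh, "keys") <- keys
    wh
}

# From-scratch two-sided Fisher oracle by full hypergeometric
# enumeration (lchoose arithmetic, per-table).
fisherOracle <- function(a, b, c, d) {
    m <- a + b; n2 <- c + d; k <- a + c
    if (k == 0 || k == m + n2 || m == 0 || n2 == 0) return(1)
    support <- max(0, k - n2):min(k, m)
    probs <- exp(lchoose(m, support) + lchoose(n2, k - support) -
                 lchoose(m + n2, k))
    pObs <- probs[support == a]
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

# register an extra empty case sample on an existing warehouse
addSamplesForTest <- function(wh, id) {
    varwarden:::addSamples(wh, data.frame(
        sample_id = id, status = "case",
        inheritance_mode = "AD_or_mitochondrial", stringsAsFactors = FALSE))
}
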