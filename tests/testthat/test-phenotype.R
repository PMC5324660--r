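# clinical CSV for the tinyWarehouse samples
writeClinical <- function(path,
                          ids = c("AD1", "AD2", "AR1"),
                          onset = c(10, 20, 35),
                          progression = c("progressive", "progressive",
                                          "stable"),
                          audiograms = c("125=30;250=40;500=55",
                                         "125=40;250=50;500=65",
                                         "125=20;500=45")) {
    lines <- c("sample_id,numeric:onset_age,cat:progression,series:audiogram",
               sprintf("%s,%s,%s,%s", ids, onset, progression, audiograms))
    writeLines(lines, path)
    path
}

test_that("carrier lookup is sorted, gene-scoped, and control-aware", {
    wh <- tinyWarehouse()
    keys <- attr(wh, "keys")
    ca <- carriersOf(wh, variant = keys[1])
    expect_equal(ca$sample_id, c("AD1", "AD2"))   # sorted, cases only
    ca2 <- carriersOf(wh, variant = keys[1], includeControls = TRUE)
    expect_equal(ca2$sample_id, c("AD1", "AD2", "CT1"))
    # gene scope = union over the gene's variants (brute force)
    byGene <- carriersOf(wh, gene = "GENE_A")
    obs <- observationTable(wh)
    ann <- annotationTable(wh)
    expected <- sort(unique(obs$sample_id[
        obs$key %in% ann$key[ann$gene == "GENE_A"] &
        obs$sample_id %in% sampleTable(wh)$sample_id[
            sampleTable(wh)$status == "case"]]))
    expect_equal(byGene$sample_id, expected)
    # unknown scope is an empty list, not an error
    expect_equal(nrow(carriersOf(wh, gene = "NO_SUCH_GENE")), 0)
    expect_error(carriersOf(wh), "exactly one")
})

test_that("numeric aggregation gives mean and sample SD over non-missing carriers", {
    wh <- importClinical(tinyWarehouse(), writeClinical(tempfile()))
    keys <- attr(tinyWarehouse(), "keys")
    agg <- aggregatePhenotype(wh, variant = keys[1])   # carriers AD1, AD2
    num <- agg@numeric
    expect_equal(num$mean[num$field == "onset_age"], 15)
    expect_equal(num$sd[num$field == "onset_age"], sqrt(50),
                 tolerance = 1e-12)
    expect_equal(num$n[num$field == "onset_age"], 2)
    # single carrier: mean identity, sd undefined
    agg1 <- aggregatePhenotype(wh, variant = keys[2])  # AD1, AR1 carry v2
    expect_equal(agg1@numeric$n, 2)
    aggSolo <- aggregatePhenotype(wh,
        variant = c(keys[2]), fields = "onset_age")
    wh2 <- wh
    # restrict to one carrier by removing AR1's observation of v2
    wh2@observations <- wh2@observations[
        !(wh2@observations$sample_id == "AR1" &
          wh2@observations$key == keys[2]), ]
    solo <- aggregatePhenotype(wh2, variant = keys[2])
    expect_equal(solo@numeric$mean, 10)
    expect_true(is.na(solo@numeric$sd))
    expect_error(aggregatePhenotype(wh, variant = "chr9:1-1:A>G"),
                 "no carriers")
})

test_that("categorical fields aggregate to frequency tables", {
    wh <- importClinical(tinyWarehouse(), writeClinical(tempfile()))
    agg <- aggregatePhenotype(wh, gene = "GENE_A")  # AD1, AD2, AR1
    tab <- agg@categorical$progression
    expect_equal(as.integer(tab[c("progressive", "stable")]), c(2L, 1L))
    expect_equal(sum(tab), agg@nCarriers)
})

test_that("series fields aggregate pointwise with interpolation onto the declared grid", {
    wh <- importClinical(tinyWarehouse(), writeClinical(tempfile()))
    agg <- aggregatePhenotype(wh, gene = "GENE_A")
    ser <- agg@series
    expect_equal(sort(unique(ser$x)), c(125, 250, 500))
    # AR1 was on a different grid and got interpolated
    expect_equal(agg@interpolatedSamples, "AR1")
    # pointwise mean at x = 125 over the three carriers: (30+40+20)/3
    expect_equal(ser$mean[ser$x == 125], 30)
    expect_equal(ser$n[ser$x == 125], 3)
    # AR1's value at 250 interpolates (125, 20)-(500, 45) linearly:
    # 20 + 25 * (250 - 125) / (500 - 125)
    expect_equal(ser$mean[ser$x == 250], mean(c(40, 50, 20 + 25 * 125 / 375)),
                 tolerance = 1e-12)
})

test_that("aggregation is permutation-invariant and matches brute force", {
    v <- data.frame(contig = "chr6", pos = c(100, 200), ref = "A", alt = "G",
                    pAd = c(0.5, 0.2), pAr = c(0.5, 0.2),
                    pCtrl = c(0.1, 0.1))
    cm <- list(effectVariant = 1,
               numeric = data.frame(field = "onset_age", mean_carrier = 12,
                                    sd_carrier = 4, mean_noncarrier = 45,
                                    sd_noncarrier = 10))
    g <- generateCohort(cohortSpec(30, 30, 30, v, clinicalModel = cm,
                                   seed = 17), tempfile())
    wh <- loadCohort(g)
    agg <- aggregatePhenotype(wh, variant = g$keys[1])
    ids <- carriersOf(wh, variant = g$keys[1])$sample_id
    raw <- wh@clinicalNumeric
    vals <- raw$value[raw$sample_id %in% ids & raw$field == "onset_age"]
    expect_equal(agg@numeric$mean, mean(vals), tolerance = 1e-12)
    expect_equal(agg@numeric$sd, stats::sd(vals), tolerance = 1e-12)
    # permuting stored clinical rows does not change the aggregate
    wh2 <- wh
    wh2@clinicalNumeric <- wh2@clinicalNumeric[
        rev(seq_len(nrow(wh2@clinicalNumeric))), ]
    agg2 <- aggregatePhenotype(wh2, variant = g$keys[1])
    expect_equal(agg2@numeric, agg@numeric)
})

test_that("case-vs-aggregate comparison reports z-scores where sd is defined", {
    wh <- importClinical(tinyWarehouse(), writeClinical(tempfile()))
    keys <- attr(tinyWarehouse(), "keys")
    agg <- aggregatePhenotype(wh, variant = keys[1])   # mean 15, sd 7.071
    cmp <- compareCase(wh, "AD2", agg)
    z <- cmp$z[cmp$field == "onset_age"]
    expect_equal(z, (20 - 15) / sqrt(50), tolerance = 1e-12)
    expect_equal(z, 0.7071068, tolerance = 1e-6)
    # value equal to the carrier mean gives z = 0
    whEq <- wh
    i <- which(whEq@clinicalNumeric$sample_id == "AD2")
    whEq@clinicalNumeric$value[i] <- 22.5      # mean of {10, 22.5, 35}
    aggEq <- aggregatePhenotype(whEq, gene = "GENE_A")
    cmpEq <- compareCase(whEq, "AD2", aggEq)
    expect_equal(cmpEq$z[cmpEq$field == "onset_age"], 0)
    # a sample with no clinical values yields an empty report
    expect_equal(nrow(compareCase(wh, "AD3", agg)), 0)
    expect_error(compareCase(wh, "NOPE", agg), "unknown sample")
})

test_that("clinical capacities (9 series / 40 numeric / 20 categorical) are enforced", {
    p <- tempfile()
    hdr <- c("sample_id", paste0("numeric:f", 1:41))
    writeLines(c(paste(hdr, collapse = ","),
                 paste(c("S1", rep("1", 41)), collapse = ",")), p)
    expect_error(importClinical(tinyWarehouse(), p), "40 numeric")
    hdr <- c("sample_id", paste0("cat:f", 1:21))
    writeLines(c(paste(hdr, collapse = ","),
                 paste(c("S1", rep("x", 21)), collapse = ",")), p)
    expect_error(importClinical(tinyWarehouse(), p), "20 categorical")
    hdr <- c("sample_id", paste0("series:f", 1:10))
    writeLines(c(paste(hdr, collapse = ","),
                 paste(c("S1", rep("1=2", 10)), collapse = ",")), p)
    expect_error(importClinical(tinyWarehouse(), p), "9 series")
    # missing cells are excluded from denominators, not stored as zero
    writeLines(c("sample_id,numeric:a", "S1,", "S2,5"), p)
    wh <- importClinical(tinyWarehouse(), p)
    expect_equal(nrow(wh@clinicalNumeric), 1)
    expect_equal(wh@clinicalNumeric$value, 5)
})
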