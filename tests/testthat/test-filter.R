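# annotated warehouse exercising each cohort rule:
#   v1 prior pathogenic + common      -> retained by exemption
#   v2 missense, ExAC 2%              -> removed at the MAF rule
#   v3 synonymous, splice 0.7         -> retained (rescued)
#   v4 synonymous, splice 0.2         -> removed at the splice rule
#   v5 intronic, no score             -> removed at the splice rule
#   v6 missense, rare, control-only   -> removed at the control rule
#   v7 missense, rare, in cases       -> survives
ruleWarehouse <- function() {
    keys <- variantKeyString("chr2", 1:7 * 100, 1:7 * 100, "A", "G")
    samples <- data.frame(sample_id = c("P1", "P2", "C1", "C2"),
                          status = c("case", "case", "control", "control"),
                          inheritance_mode = c("AD_or_mitochondrial",
                                               "AR_or_sporadic",
                                               "not_applicable",
                                               "not_applicable"),
                          stringsAsFactors = FALSE)
    observations <- data.frame(
        sample_id = c("P1", "P1", "P1", "P1", "P2", "P2", "C1", "C2"),
        key = c(keys[1], keys[2], keys[3], keys[4], keys[5], keys[7],
                keys[6], keys[7]),
        stringsAsFactors = FALSE)
    wh <- VariantWarehouse(samples = samples, observations = observations)
    ann <- makeAnnRecords(keys)
    ann$kg1000 <- c(0.05, NA, NA, NA, NA, NA, NA)
    ann$exac <- c(NA, 0.02, NA, NA, NA, NA, NA)
    ann$function_class <- c("missense", "missense", "synonymous",
                            "synonymous", "none", "missense", "missense")
    ann$region_class <- c("exonic", "exonic", "exonic", "exonic",
                          "intronic", "exonic", "exonic")
    ann$splice_score <- c(NA, NA, 0.7, 0.2, NA, NA, NA)
    ann$clinvar_significance <- c("Pathogenic", rep("", 6))
    ann$prior_category <- c("pathogenic", rep("novel", 6))
    wh <- joinAnnotations(wh, ann)
    attr(wh, "keys") <- keys
    wh
}

test_that("the four cohort rules remove and retain the right variants", {
    wh <- ruleWarehouse()
    keys <- attr(wh, "keys")
    fun <- applyCohortFilter(wh)
    surv <- survivors(fun)
    expect_true(keys[1] %in% surv)    # prior pathogenic, despite MAF 5%
    expect_false(keys[2] %in% surv)   # MAF above threshold
    expect_true(keys[3] %in% surv)    # splice-rescued synonymous
    expect_false(keys[4] %in% surv)   # synonymous below splice threshold
    expect_false(keys[5] %in% surv)   # intronic without score
    expect_false(keys[6] %in% surv)   # control-only
    expect_true(keys[7] %in% surv)
    st <- funnelStages(fun)
    expect_equal(st$stage, c("maf", "splice", "control_only"))
    expect_equal(st$n_in[1], 7)
    expect_equal(st$n_out, c(6, 4, 3))
})

test_that("an unannotated registry directs the user to annotate", {
    wh <- tinyWarehouse()
    bare <- VariantWarehouse(samples = sampleTable(wh),
                             observations = observationTable(wh))
    expect_error(applyCohortFilter(bare), "annotate")
    expect_error(caseFunnel(bare, "AD1"), "annotate")
})

test_that("survivor sets are monotone in both thresholds", {
    wh <- ruleWarehouse()
    mafGrid <- c(0.05, 0.01, 0.005, 0.001)
    prev <- NULL
    for (m in mafGrid) {
        s <- survivors(applyCohortFilter(wh, filterConfig(mafThreshold = m)))
        if (!is.null(prev)) expect_true(all(s %in% prev))
        prev <- s
    }
    prev <- NULL
    for (sp in c(0.1, 0.3, 0.6, 0.9)) {
        s <- survivors(applyCohortFilter(wh,
            filterConfig(spliceThreshold = sp)))
        if (!is.null(prev)) expect_true(all(s %in% prev))
        prev <- s
    }
})

test_that("marking a removed variant prior-pathogenic restores it (rules 2-3)", {
    wh <- ruleWarehouse()
    keys <- attr(wh, "keys")
    base <- survivors(applyCohortFilter(wh))
    for (k in setdiff(keys[2:5], base)) {
        wh2 <- wh
        i <- which(wh2@annotations$key == k)
        wh2@annotations$prior_category[i] <- "pathogenic"
        expect_true(k %in% survivors(applyCohortFilter(wh2)), label = k)
    }
    # the exemption does not extend to control-only removal
    wh3 <- wh
    i <- which(wh3@annotations$key == keys[6])
    wh3@annotations$prior_category[i] <- "pathogenic"
    expect_false(keys[6] %in% survivors(applyCohortFilter(wh3)))
})

test_that("stage counts conserve and match a single-pass predicate oracle", {
    wh <- ruleWarehouse()
    cfg <- filterConfig()
    fun <- applyCohortFilter(wh, cfg)
    st <- funnelStages(fun)
    for (i in seq_len(nrow(st)))
        expect_equal(st$n_in[i] - st$n_out[i],
                     length(fun@removed[[st$stage[i]]]))
    # brute-force single-pass evaluation of the combined predicate
    ann <- annotationTable(wh)
    obs <- observationTable(wh)
    caseIds <- sampleTable(wh)$sample_id[sampleTable(wh)$status == "case"]
    oracle <- vapply(seq_len(nrow(ann)), function(i) {
        r <- ann[i, ]
        exempt <- r$prior_category %in% c("pathogenic", "likely_pathogenic")
        mafHigh <- any(!is.na(unlist(r[cfg$populationsChecked])) &
                       unlist(r[cfg$populationsChecked]) > cfg$mafThreshold)
        spliceCand <- r$region_class == "intronic" ||
            (r$region_class %in% c("exonic", "exonic_splicing") &&
             r$function_class == "synonymous")
        rescued <- !is.na(r$splice_score) &&
            r$splice_score >= cfg$spliceThreshold
        inCases <- r$key %in% obs$key[obs$sample_id %in% caseIds]
        keep <- exempt || (!mafHigh && !(spliceCand && !rescued))
        keep && inCases
    }, logical(1))
    expect_setequal(survivors(fun), ann$key[oracle])
})

test_that("case funnels report the stage sequence and handle empty samples", {
    wh <- ruleWarehouse()
    fun <- caseFunnel(wh, "P1")
    expect_equal(unname(funnelCounts(fun)[1]), 4)
    # sample with zero observations
    wh2 <- addSamplesForTest(wh, "P9")
    fun0 <- caseFunnel(wh2, "P9")
    expect_equal(unname(funnelCounts(fun0)), rep(0L, 5))
    expect_error(caseFunnel(wh, "NOPE"), "unknown sample")
})

test_that("funnel reports render to JSON with per-stage removed keys", {
    wh <- ruleWarehouse()
    fun <- applyCohortFilter(wh)
    js <- jsonlite::fromJSON(funnelReport(fun, "json"),
                             simplifyVector = FALSE)
    expect_length(js$stages, 3)
    for (i in seq_along(js$stages)) {
        stg <- js$stages[[i]]
        expect_equal(stg$n_in - stg$n_out, length(stg$removed_keys))
    }
    # round-trip: counts reproduce
    expect_equal(vapply(js$stages, function(s) s$n_out, 1),
                 unname(as.numeric(funnelCounts(fun))))
    # empty funnel renders an empty stage list
    empty <- varwarden:::.newFunnel("none")
    expect_length(jsonlite::fromJSON(funnelReport(empty, "json"),
                                     simplifyVector = FALSE)$stages, 0)
})
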