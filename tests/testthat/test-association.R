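test_that("contingency tables count carrier probands per stratum", {
    wh <- tinyWarehouse()
    keys <- attr(wh, "keys")
    # AD probands {AD1, AD2 carriers; AD3, AD4 non}, controls {CT1 carrier}
    tab <- buildContingency(wh, keys[1], "ad")
    expect_equal(unlist(tab[c("a", "b", "c", "d")]),
                 c(a = 2, b = 2, c = 1, d = 2))
    # unknown-inheritance stratum names are rejected
    expect_error(buildContingency(wh, keys[1], "unknown"), "stratum")
    expect_error(buildContingency(wh, "chr9:1-1:A>G", "ad"), "absent")
})

test_that("allele counting tallies alt alleles against 2N denominators", {
    wh <- tinyWarehouse()
    keys <- attr(wh, "keys")
    # make AD2 homozygous for v1
    i <- which(wh@observations$sample_id == "AD2" &
               wh@observations$key == keys[1])
    wh@observations$zygosity[i] <- "hom_alt"
    tab <- buildContingency(wh, keys[1], "ad", unit = "allele")
    # brute-force tally: AD1 het (1) + AD2 hom (2) = 3 of 2*4 alleles
    expect_equal(unlist(tab[c("a", "b")]), c(a = 3, b = 5))
    expect_equal(unlist(tab[c("c", "d")]), c(c = 1, d = 5))
})

test_that("a variant set with identical carriers equals the single variant", {
    wh <- tinyWarehouse()
    keys <- attr(wh, "keys")
    # duplicate v1's carriers onto a new cis partner
    obs <- observationTable(wh)
    cis <- obs[obs$key == keys[1], ]
    cis$key <- "chr1:150-150:G>A"
    wh2 <- VariantWarehouse(samples = sampleTable(wh),
                            observations = rbind(obs, cis))
    t1 <- buildContingency(wh2, keys[1], "ad")
    t2 <- buildContingency(wh2, c(keys[1], "chr1:150-150:G>A"), "ad")
    expect_equal(t1[c("a", "b", "c", "d")], t2[c("a", "b", "c", "d")])
})

test_that("odds ratio, Woolf CI and Haldane correction match hand values", {
    r <- associationStats(list(a = 1, b = 1, c = 1, d = 1))
    expect_equal(orPoint(r), 1.0)
    expect_lt(ciBounds(r)["low"], 1.0)
    expect_gt(ciBounds(r)["high"], 1.0)
    expect_equal(pValue(r), 1.0)

    r <- associationStats(list(a = 10, b = 90, c = 5, d = 95))
    expect_equal(orPoint(r), 19 / 9, tolerance = 1e-12)
    # exp(ln OR +/- z * sqrt(1/10 + 1/90 + 1/5 + 1/95))
    expect_equal(unname(ciBounds(r)), c(0.6946538, 6.4158444),
                 tolerance = 1e-6)
    expect_false(r@correctionApplied)

    r <- suppressMessages(associationStats(list(a = 5, b = 827, c = 0,
                                                d = 3533)))
    expect_true(r@correctionApplied)
    # (5.5 * 3533.5) / (827.5 * 0.5)
    expect_equal(orPoint(r), 5.5 * 3533.5 / (827.5 * 0.5),
                 tolerance = 1e-12)
    expect_equal(orPoint(r), 46.97, tolerance = 1e-3)

    expect_error(associationStats(list(a = 2, b = 0, c = 3, d = 0)),
                 "degenerate")
})

test_that("the exact-CI option delegates to the conditional interval", {
    r <- associationStats(list(a = 10, b = 90, c = 5, d = 95),
                          ciMethod = "exact")
    ft <- stats::fisher.test(matrix(c(10, 90, 5, 95), 2, byrow = TRUE))
    expect_equal(unname(ciBounds(r)), ft$conf.int[1:2], tolerance = 1e-10)
})

test_that("Fisher P matches enumeration and fisher.test on small tables", {
    expect_equal(fisherExactTwoSided(1, 1, 1, 1), 1)
    expect_equal(fisherExactTwoSided(3, 0, 0, 3), 0.1)  # 2/20 by enumeration
    # exhaustive sweep over all tables with total <= 25
    maxDiff <- 0
    for (m in 0:25) for (n2 in 0:(25 - m)) {
        if (m + n2 == 0) next
        for (k in 0:(m + n2)) {
            for (a in max(0, k - n2):min(k, m)) {
                b <- m - a; cc <- k - a; d <- n2 - cc
                maxDiff <- max(maxDiff,
                               abs(fisherExactTwoSided(a, b, cc, d) -
                                   fisherOracle(a, b, cc, d)))
            }
        }
    }
    expect_lt(maxDiff, 1e-10)
    # spot agreement with the reference implementation on larger tables
    set.seed(42)
    for (i in 1:50) {
        cells <- rpois(4, 8)
        if (sum(cells[c(2, 4)]) == 0) next
        p <- fisherExactTwoSided(cells[1], cells[2], cells[3], cells[4])
        pref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
        expect_equal(p, pref, tolerance = 1e-9)
    }
})

test_that("swapping case and control rows inverts the OR and keeps P", {
    set.seed(11)
    for (i in 1:25) {
        cells <- rpois(4, 6) + 1
        r1 <- associationStats(list(a = cells[1], b = cells[2],
                                    c = cells[3], d = cells[4]))
        r2 <- associationStats(list(a = cells[3], b = cells[4],
                                    c = cells[1], d = cells[2]))
        expect_equal(orPoint(r2), 1 / orPoint(r1), tolerance = 1e-12)
        expect_equal(pValue(r2), pValue(r1), tolerance = 1e-12)
    }
})

test_that("increasing the case-carrier cell never decreases the OR", {
    set.seed(13)
    for (i in 1:25) {
        b <- sample(5:50, 1); cc <- sample(1:10, 1); d <- sample(20:80, 1)
        ors <- vapply(1:10, function(a)
            orPoint(suppressMessages(associationStats(
                list(a = a, b = b, c = cc, d = d)))), 1)
        expect_true(all(diff(ors) >= 0))
    }
})

test_that("the odds-ratio evidence flag follows the fivefold + CI rule", {
    expect_true(ps4Assess(list(orPoint = 14.1, ciLow = 1.78)))
    expect_false(ps4Assess(list(orPoint = 4.3, ciLow = 0.5)))
    expect_false(ps4Assess(list(orPoint = 6.0, ciLow = 0.9)))   # CI spans 1
    expect_false(ps4Assess(list(orPoint = 4.9, ciLow = 1.2)))   # below 5x
    expect_message(ps4Assess(list(orPoint = 10, ciLow = 2,
                                  smallCountWarning = TRUE)), "caution")
})

test_that("association scans emit one row per variant and stratum, deterministically", {
    wh <- tinyWarehouse()
    keys <- attr(wh, "keys")
    scan <- associationScan(wh, keys[1:2])
    expect_equal(nrow(scan), 4)
    expect_equal(sort(unique(scan$stratum)),
                 c("AD_or_mitochondrial", "AR_or_sporadic"))
    expect_true(all(diff(scan$odds_ratio) <= 0))
    f1 <- tempfile(); f2 <- tempfile()
    associationScan(wh, keys[1:2], out = f1)
    associationScan(wh, keys[1:2], out = f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("a variant enriched in one stratum ranks higher there", {
    v <- data.frame(contig = "chr4", pos = c(100, 200), ref = "A", alt = "G",
                    pAd = c(0.3, 0.01), pAr = c(0.01, 0.3),
                    pCtrl = c(0.01, 0.01))
    g <- generateCohort(cohortSpec(80, 80, 150, v, seed = 5), tempfile())
    wh <- loadCohort(g)
    scan <- associationScan(wh, g$keys)
    orOf <- function(k, st) scan$odds_ratio[scan$key == k &
                                            scan$stratum == st]
    expect_gt(orOf(g$keys[1], "AD_or_mitochondrial"),
              orOf(g$keys[1], "AR_or_sporadic"))
    expect_gt(orOf(g$keys[2], "AR_or_sporadic"),
              orOf(g$keys[2], "AD_or_mitochondrial"))
    # truth-table round trip: registry counts equal brute-force truth counts
    tab <- buildContingency(wh, g$keys[1], "ad")
    tr <- g$truth[g$truth$key == g$keys[1] & g$truth$carrier, ]
    adIds <- g$samples$sample_id[g$samples$inheritance == "ad"]
    ctIds <- g$samples$sample_id[g$samples$status == "control"]
    expect_equal(tab$a, sum(tr$sample_id %in% adIds))
    expect_equal(tab$c, sum(tr$sample_id %in% ctIds))
})

test_that("frequency-only panels fold into the control cells", {
    wh <- tinyWarehouse()
    keys <- attr(wh, "keys")
    t0 <- buildContingency(wh, keys[1], "ad")
    t1 <- buildContingency(wh, keys[1], "ad", panelAf = 0.01, panelN = 1000)
    expect_equal(t1$c, t0$c + round(0.01 * 2000))
    expect_equal(t1$c + t1$d, t0$c + t0$d + 1000)
})
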