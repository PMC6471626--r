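mkTable <- function(vals, varClass = "OTU") {
    if (is.null(rownames(vals)))
        rownames(vals) <- paste0("V", seq_len(nrow(vals)))
    GrangerTimeSeries(vals, varClass = varClass)
}

test_that("the abundance filter applies mean and zero-fraction rules", {
    keepMe <- rep(2, 10)                       # mean 2, zero fraction 0
    dropMe <- c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1)  # mean 0.4, zero frac 0.6
    tab <- mkTable(rbind(A = keepMe, B = dropMe))
    out <- filterAbundance(tab)
    expect_identical(out$kept, "A")
    expect_identical(out$report$var_id, "B")
    expect_identical(out$report$reason, "low_mean+high_zero_fraction")
})

test_that("the and/or combiner changes the verdict as designed", {
    dropMe <- c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1)  # mean 0.4, zero frac 0.6
    tab <- mkTable(rbind(A = rep(2, 10), B = dropMe))
    # meanThresh 0.3: mean condition fails (0.4 >= 0.3), zero-frac holds
    kept_and <- filterAbundance(tab, meanThresh = 0.3, combine = "and")$kept
    kept_or <- filterAbundance(tab, meanThresh = 0.3, combine = "or")$kept
    expect_true("B" %in% kept_and)
    expect_false("B" %in% kept_or)
})

test_that("environmental variables are exempt from the abundance filter", {
    zeros <- rep(0, 10)
    tab <- mkTable(rbind(env = zeros, otu = zeros),
                   varClass = c("environmental", "OTU"))
    out <- filterAbundance(tab)
    expect_identical(out$kept, "env")
})

test_that("the abundance filter is idempotent and order-invariant", {
    set.seed(61)
    vals <- matrix(rpois(60, 0.7), 6, 10,
                   dimnames = list(paste0("V", 1:6), NULL))
    tab <- mkTable(vals)
    once <- filterAbundance(tab)
    twice <- filterAbundance(once$table)
    expect_identical(rownames(once$table), rownames(twice$table))
    expect_equal(nrow(twice$report), 0L)
    shuffled <- filterAbundance(tab[sample(6), ])
    expect_setequal(once$kept, shuffled$kept)
})

test_that("filter input validation: empty table and bad thresholds", {
    tab <- mkTable(matrix(1, 1, 10, dimnames = list("A", NULL)))
    expect_error(filterAbundance(tab, zeroFracThresh = 1.5), "\\[0, 1\\]")
    expect_error(filterAbundance(tab[0, ]), "empty")
})

test_that("listwise deletion removes exactly the affected time points", {
    set.seed(62)
    vals <- matrix(rnorm(5 * 20), 5, 20,
                   dimnames = list(paste0("V", 1:5), paste0("t", 1:20)))
    tab <- mkTable(vals)
    # no missing: identity
    out0 <- dropMissing(tab)
    expect_equal(tsValues(out0$table), vals)

    # one missing cell: T decreases by one
    v1 <- vals; v1[2, 3] <- NA
    out1 <- dropMissing(mkTable(v1))
    expect_equal(nTimePoints(out1$table), 19L)
    expect_identical(out1$report$time_label, "t3")

    # several variables missing at 4 distinct time points: T drops by 4
    v2 <- vals
    v2[1, 2] <- NA; v2[3, 2] <- NA; v2[2, 7] <- NA
    v2[4, 11] <- NA; v2[5, 19] <- NA
    out2 <- dropMissing(mkTable(v2))
    expect_equal(nTimePoints(out2$table), 16L)
    # temporal order of the remainder is preserved
    expect_identical(timeLabels(out2$table),
                     setdiff(paste0("t", 1:20),
                             c("t2", "t7", "t11", "t19")))
})

test_that("too few complete time points is an error", {
    vals <- matrix(rnorm(24), 2, 12,
                   dimnames = list(c("A", "B"), paste0("t", 1:12)))
    vals[1, 1:5] <- NA
    expect_error(dropMissing(mkTable(vals)), "min_T")
})

test_that("the ADF statistic matches an independent lm() implementation", {
    set.seed(63)
    rw <- cumsum(rnorm(200))
    ar <- simAR1(200, 0.4)
    for (s in list(rw, ar)) {
        for (k in c(0, 2)) {
            got <- adfTest(s, maxLags = k)
            expect_equal(got$statistic, oracleADFStat(s, k),
                         tolerance = 1e-8)
        }
        gotCT <- adfTest(s, regression = "constant_trend", maxLags = 1)
        expect_equal(gotCT$statistic,
                     oracleADFStat(s, 1, "constant_trend"),
                     tolerance = 1e-8)
    }
})

test_that("unit roots are retained and stationary series rejected", {
    set.seed(64)
    rw <- cumsum(rnorm(200))      # unit root by construction
    wn <- rnorm(200)
    expect_gte(adfTest(rw)$p_value, 0.05 / 5)  # clearly not small
    expect_lt(adfTest(wn)$p_value, 0.01)
})

test_that("the screen removes non-stationary series and logs verdicts", {
    set.seed(65)
    vals <- rbind(stat1 = simAR1(120, 0.3),
                  walk = cumsum(rnorm(120)),
                  stat2 = simAR1(120, 0.2))
    tab <- mkTable(vals)
    out <- adfScreen(tab)
    expect_identical(sort(rownames(out$table)), c("stat1", "stat2"))
    expect_equal(nrow(out$results), 3L)
    expect_identical(out$results$verdict[out$results$var_id == "walk"],
                     "nonstationary")
    expect_identical(out$report$reason, "nonstationary")
    # verdict is consistent with the configured alpha
    expect_true(all((out$results$p_value < 0.05) ==
                    (out$results$verdict == "stationary")))
})

test_that("a constant series is removed with a warning, not a crash", {
    set.seed(66)
    tab <- mkTable(rbind(flat = rep(2, 60), ok = simAR1(60, 0.3)))
    expect_warning(out <- adfScreen(tab), "constant")
    expect_identical(rownames(out$table), "ok")
})

test_that("ADF has power against a moderately persistent AR(1)", {
    rejected <- vapply(1:100, function(seed) {
        set.seed(seed + 6000)
        adfTest(simAR1(500, 0.3))$p_value < 0.05
    }, logical(1))
    expect_gte(mean(rejected), 0.95)
})
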