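test_that("an empty conditioning set reduces to the bivariate statistic", {
    set.seed(41)
    for (i in 1:10) {
        x <- simAR1(80, 0.3); y <- simAR1(80, 0.3)
        p <- sample(1:3, 1)
        cond <- conditionalGC(x, y, list(), p = p)
        rssR <- arRSS(fitLagged(x, list(x = x), p = p))
        rssF <- arRSS(fitLagged(x, list(x = x, y = y), p = p))
        expect_equal(cond$cond_gc, gcStatistic(rssR, rssF),
                     tolerance = 1e-12)
    }
})

test_that("a mediated chain edge loses significance when conditioned", {
    sim <- simulateVAR(makeMotif("chain", T = 500, seed = 42))
    v <- tsValues(sim$table)
    # premise: the spurious Y -> X association is bivariate-significant
    rssR <- arRSS(fitLagged(v["X", ], list(x = v["X", ]), p = 1))
    rssF <- arRSS(fitLagged(v["X", ], list(x = v["X", ], y = v["Y", ]),
                            p = 1))
    biv <- gcFTest(rssR, rssF, T = 500, p = 1)
    expect_lt(biv$p_value, 0.05)
    cond <- conditionalGC(v["X", ], v["Y", ], list(Z = v["Z", ]), p = 1)
    expect_gt(cond$p_value, 0.05)
    expect_identical(cond$verdict, "indirect")
    # and conditioning cannot add information: cond gc below bivariate gc
    expect_lt(cond$cond_gc, gcStatistic(rssR, rssF) + 1e-10)
})

test_that("a genuinely direct edge survives conditioning on a bystander", {
    set.seed(43)
    n <- 500
    y <- simAR1(n, 0.3); z <- simAR1(n, 0.3)
    x <- numeric(n)
    for (t in 2:n) x[t] <- 0.3 * x[t - 1] + 0.6 * y[t - 1] + rnorm(1)
    cond <- conditionalGC(x, y, list(Z = z), p = 1)
    expect_lt(cond$p_value, 0.05)
    expect_identical(cond$verdict, "direct")
})

test_that("conditional degrees of freedom account for the full model", {
    set.seed(44)
    x <- simAR1(100, 0.3); y <- simAR1(100, 0.3); z <- simAR1(100, 0.3)
    cond <- conditionalGC(x, y, list(Z = z), p = 2)
    # (T - p) observations minus 3 series x 2 lags + intercept
    expect_equal(cond$df2, (100 - 2) - (3 * 2 + 1))
})

test_that("a mediator collinear with the source is refused by name", {
    set.seed(45)
    x <- simAR1(60, 0.3); y <- simAR1(60, 0.3)
    expect_error(conditionalGC(x, y, list(Zdup = y), p = 1,
                               sourceId = "Y"),
                 "collinear.*Zdup|Zdup.*collinear")
})

test_that("edge classification follows the any-spurious-mediator rule", {
    one <- data.frame(source = "A", target = "B", mediators = "M1",
                      cond_gc = 0.4, f_stat = 11, p_value = 0.001,
                      verdict = "direct")
    expect_identical(classifyEdge(one)$verdict, "direct")

    two <- rbind(one,
                 data.frame(source = "A", target = "B", mediators = "M2",
                            cond_gc = 0.01, f_stat = 1.1, p_value = 0.30,
                            verdict = "indirect"))
    cls <- classifyEdge(two)
    expect_identical(cls$verdict, "indirect")
    expect_identical(cls$mediators, "M2")
})

test_that("the raw-threshold rule separates published conditional values", {
    # conditional causality values 0.2009 (kept) and 0.0102 (removed)
    tests <- data.frame(source = c("A", "C"), target = c("B", "D"),
                        mediators = c("M1", "M2"),
                        cond_gc = c(0.2009, 0.0102),
                        f_stat = NA, p_value = NA, verdict = NA)
    c1 <- classifyEdge(tests[1, ], rule = "gc_threshold", threshold = 0.05)
    c2 <- classifyEdge(tests[2, ], rule = "gc_threshold", threshold = 0.05)
    expect_identical(c1$verdict, "direct")
    expect_identical(c2$verdict, "indirect")
    expect_error(classifyEdge(tests, rule = "gc_threshold"), "threshold")
})
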