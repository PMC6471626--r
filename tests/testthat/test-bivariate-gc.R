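test_that("the causality statistic is a log variance ratio", {
    expect_equal(gcStatistic(2.5, 2.5), 0)
    expect_equal(gcStatistic(exp(1) * 1.7, 1.7), 1, tolerance = 1e-12)
    expect_error(gcStatistic(1, 0), "degenerate")
})

test_that("the F-test matches its definition and the F upper tail", {
    eq <- gcFTest(3, 3, T = 50, p = 2)
    expect_equal(eq$f_stat, 0)
    expect_equal(eq$p_value, 1)

    # p-value for F = 4 on (1, 40) df against numerical integration
    ft <- gcFTest(3 * (1 + 4 * 1 / 40), 3, T = 43, p = 1)
    expect_equal(ft$f_stat, 4, tolerance = 1e-10)
    tail <- stats::integrate(function(u) stats::df(u, 1, 40), 4, Inf,
                             rel.tol = 1e-10)$value
    expect_equal(ft$p_value, tail, tolerance = 1e-6)

    expect_error(gcFTest(3, 2, T = 7, p = 3), "too short")
})

test_that("pipeline statistics equal the normal-equations oracle", {
    set.seed(21)
    x1 <- simAR1(300, 0.3)
    x2 <- numeric(300)
    for (t in 2:300) x2[t] <- 0.3 * x2[t - 1] + 0.6 * x1[t - 1] + rnorm(1)
    tab <- GrangerTimeSeries(rbind(A = x1, B = x2))
    scan <- gcScan(tab, selection = "fixed", p = 1)
    fwd <- scan[scan$source == "A" & scan$target == "B", ]
    orc <- oracleGC(x2, x1, p = 1)
    expect_equal(fwd$gc, orc$gc, tolerance = 1e-8)
    expect_equal(fwd$f_stat, orc$f_stat, tolerance = 1e-8)
    expect_equal(fwd$p_value, orc$p_value, tolerance = 1e-8)
})

test_that("a scan enumerates all ordered pairs in lexicographic order", {
    tab <- nullTable(3, 60, seed = 31)
    scan <- gcScan(tab, selection = "fixed", p = 1)
    expect_equal(nrow(scan), 6L)
    expect_equal(scan$source, sort(scan$source))
    expect_error(gcScan(tab[1, ], selection = "fixed", p = 1),
                 "at least 2")
})

test_that("per-pair statistics are invariant to variable ordering", {
    tab <- nullTable(4, 80, seed = 32)
    scan1 <- gcScan(tab, selection = "fixed", p = 2)
    scan2 <- gcScan(tab[c(3, 1, 4, 2), ], selection = "fixed", p = 2)
    expect_equal(scan1, scan2)
})

test_that("gc and f_stat obey the monotone identity on every pair", {
    tab <- nullTable(5, 70, seed = 33)
    scan <- gcScan(tab, selection = "bic")
    ok <- scan$status == "ok"
    lhs <- scan$gc[ok]
    rhs <- log(1 + scan$f_stat[ok] * scan$p[ok] / scan$df2[ok])
    expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("statistics are invariant under positive rescaling of a series", {
    tab <- nullTable(3, 90, seed = 34)
    vals <- tsValues(tab)
    vals["V02", ] <- vals["V02", ] * 137.5
    tab2 <- GrangerTimeSeries(vals)
    s1 <- gcScan(tab, selection = "fixed", p = 1)
    s2 <- gcScan(tab2, selection = "fixed", p = 1)
    expect_equal(s1$gc, s2$gc, tolerance = 1e-8)
    expect_equal(s1$f_stat, s2$f_stat, tolerance = 1e-8)
    expect_equal(s1$p_value, s2$p_value, tolerance = 1e-8)
})

test_that("perfect fits are reported as degenerate, not significant", {
    t <- 1:40
    y <- numeric(40); y[1] <- 2
    for (k in 2:40) y[k] <- 0.9 * y[k - 1]   # deterministic decay
    x <- simAR1(40, 0.3)
    tab <- GrangerTimeSeries(rbind(A = x, B = y))
    scan <- gcScan(tab, selection = "fixed", p = 1)
    degRow <- scan[scan$target == "B", ]
    expect_true(all(degRow$status == "degenerate"))
    expect_true(all(is.na(degRow$p_value)))
})

test_that("null p-values are roughly uniform (small replicate check)", {
    pv <- vapply(1:200, function(seed) {
        set.seed(seed + 4000)
        a <- simAR1(60, 0.3); b <- simAR1(60, 0.3)
        rssR <- arRSS(fitLagged(b, list(y = b), p = 1))
        rssF <- arRSS(fitLagged(b, list(y = b, x = a), p = 1))
        gcFTest(rssR, rssF, T = 60, p = 1)$p_value
    }, numeric(1))
    expect_gt(mean(pv), 0.4)
    expect_lt(mean(pv), 0.6)
})
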