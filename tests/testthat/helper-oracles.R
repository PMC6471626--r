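# Independent oracles used to check the package's fitting and testing
# routines. They deliberately avoid the package's own design-matrix and
# fitting code paths: explicit normal equations instead of QR, lm() with
# a model formula for the Dickey-Fuller regression.

# OLS of y[t] on lags 1..p of each series in `regs` (plus intercept),
# solved from the normal equations (X'X)^-1 X'y on the window t = p+1..T.
oracleLagFit <- function(y, regs, p, intercept = TRUE) {
    T <- length(y)
    idx <- (p + 1L):T
    X <- if (intercept) matrix(1, length(idx), 1L) else
        matrix(numeric(0), length(idx), 0L)
    for (r in regs)
        for (k in seq_len(p))
            X <- cbind(X, r[idx - k])
    beta <- solve(crossprod(X), crossprod(X, y[idx]))
    res <- y[idx] - X %*% beta
    list(coef = drop(beta), rss = sum(res^2))
}

# Bivariate Granger statistics straight from the oracle fits.
oracleGC <- function(target, source, p, intercept = TRUE) {
    T <- length(target)
    r <- oracleLagFit(target, list(target), p, intercept)$rss
    f <- oracleLagFit(target, list(target, source), p, intercept)$rss
    df2 <- T - 2 * p - 1
    fstat <- (df2 / p) * (r - f) / f
    list(gc = log(r / f), f_stat = fstat,
         p_value = stats::pf(fstat, p, df2, lower.tail = FALSE))
}

# Dickey-Fuller tau statistic via lm() and a model formula.
oracleADFStat <- function(y, k, regression = "constant") {
    dy <- diff(y)
    n <- length(dy)
    idx <- (k + 1L):n
    d <- data.frame(dy = dy[idx], ylag = y[idx])
    rhs <- "ylag"
    if (regression == "constant_trend") {
        d$trend <- idx + 1
        rhs <- c(rhs, "trend")
    }
    if (k > 0)
        for (j in seq_len(k)) {
            d[[paste0("d", j)]] <- dy[idx - j]
            rhs <- c(rhs, paste0("d", j))
        }
    fit <- stats::lm(stats::reformulate(rhs, "dy"), data = d)
    unname(summary(fit)$coefficients["ylag", "t value"])
}

# Independent AR(1) series via the recursive filter (burn-in dropped).
simAR1 <- function(T, phi, sd = 1, burn = 100L) {
    as.numeric(stats::filter(stats::rnorm(T + burn, sd = sd), phi,
                             method = "recursive"))[burn + seq_len(T)]
}

# A tiny table fixture: n independent AR(1) variables.
nullTable <- function(n, T, phi = 0.3, seed) {
    set.seed(seed)
    vals <- t(vapply(seq_len(n), function(i) simAR1(T, phi), numeric(T)))
    rownames(vals) <- sprintf("V%02d", seq_len(n))
    GrangerTimeSeries(vals)
}

writeTsvFixture <- function(df, path = tempfile(fileext = ".tsv")) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}
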