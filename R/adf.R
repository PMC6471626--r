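#' @importFrom stats pnorm sd var
NULL

## MacKinnon (1994) response-surface coefficients for the asymptotic
## p-value of the Dickey-Fuller tau statistic, single-series case.
## p = pnorm(polynomial(tau)); small-tau and large-tau branches split at
## tau_star, with hard clamps outside [tau_min, tau_max].
.mackinnon <- list(
    constant = list(
        star = -1.61, min = -18.83, max = 2.74,
        smallp = c(2.1659, 1.4412, 0.038269),
        largep = c(1.7339, 0.93202, -0.12745, -0.010368)),
    constant_trend = list(
        star = -2.89, min = -16.18, max = 0.7,
        smallp = c(3.2512, 1.6047, 0.049588),
        largep = c(2.5261, 0.61654, -0.37956, -0.060285)))

mackinnonPValue <- function(stat, regression = c("constant",
                                                 "constant_trend")) {
    regression <- match.arg(regression)
    tab <- .mackinnon[[regression]]
    if (stat > tab$max) return(1)
    if (stat < tab$min) return(0)
    cf <- if (stat <= tab$star) tab$smallp else tab$largep
    pnorm(sum(cf * stat^(seq_along(cf) - 1)))
}

## Dickey-Fuller auxiliary regression at a fixed augmentation lag k:
## diff(y)[t] = c (+ b*t) + gamma*y[t-1] + sum_j d_j diff(y)[t-j] + e.
## Returns the t statistic of gamma plus the pieces needed for AIC.
dfAuxiliary <- function(y, k, regression, offset = k) {
    T <- length(y)
    dy <- diff(y)
    n <- length(dy) - offset                 # usable rows
    idx <- (offset + 1L):length(dy)          # rows of dy used as response
    X <- cbind(`(Intercept)` = rep(1, n), ylag1 = y[idx])
    if (regression == "constant_trend")
        X <- cbind(X, trend = idx + 1)
    if (k > 0)
        for (j in seq_len(k))
            X <- cbind(X, dy[idx - j])
    fit <- lm.fit(X, dy[idx])
    if (fit$rank < ncol(X))
        stop("singular Dickey-Fuller regression (constant or collinear series)")
    res <- fit$residuals
    rss <- sum(res^2)
    ## t statistic for the level coefficient (column 2)
    s2 <- rss / (n - ncol(X))
    dInv <- diag(chol2inv(qr.R(fit$qr)))    # (X'X)^-1 diag, pivoted order
    seAll <- numeric(ncol(X))
    seAll[fit$qr$pivot] <- sqrt(s2 * dInv)
    list(tstat = fit$coefficients[2L] / seAll[2L], rss = rss, n = n,
         ncoef = ncol(X))
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Tests the null of a unit root (non-stationarity) against stationarity
#' around a constant (optionally a linear trend). The auxiliary regression
#' of the differenced series on the lagged level, deterministic terms and
#' \code{k} lagged differences yields the tau statistic of the level
#' coefficient; its p-value uses the MacKinnon response-surface
#' approximation. A small p-value rejects the unit root, i.e. supports
#' stationarity.
#'
#' @param y numeric series, length >= 10, no NAs.
#' @param regression \code{"constant"} (default) or
#'   \code{"constant_trend"}.
#' @param maxLags \code{"auto_aic"} (default: augmentation order chosen by
#'   AIC over 0..\code{floor((T-1)^(1/3))} on a common sample, then refit
#'   on the full usable sample) or a fixed non-negative integer.
#'
#' @return list: \code{statistic} (tau), \code{p_value}, \code{lags}
#'   (augmentation order used), \code{regression}. A constant series
#'   returns \code{statistic = NA}, \code{p_value = 1} with a warning.
#' @examples
#' set.seed(1)
#' adfTest(cumsum(rnorm(100)))$p_value   # random walk: large
#' adfTest(rnorm(100))$p_value           # white noise: small
#' @export
adfTest <- function(y, regression = c("constant", "constant_trend"),
                    maxLags = "auto_aic") {
    regression <- match.arg(regression)
    T <- length(y)
    if (T < 10L) stop("ADF test requires at least 10 observations")
    if (anyNA(y)) stop("series contains NAs; clean the table first")
    if (sd(y) == 0) {
        warning("constant (zero-variance) series; treated as non-stationary")
        return(list(statistic = NA_real_, p_value = 1, lags = 0L,
                    regression = regression))
    }
    if (identical(maxLags, "auto_aic")) {
        kmax <- max(0L, as.integer(floor((T - 1)^(1 / 3))))
        ## score every k on the common sample defined by kmax
        aics <- vapply(0:kmax, function(k) {
            aux <- dfAuxiliary(y, k, regression, offset = kmax)
            aux$n * log(aux$rss / aux$n) + 2 * aux$ncoef
        }, numeric(1))
        k <- (0:kmax)[which.min(aics)]
    } else {
        k <- as.integer(maxLags)
        if (k < 0) stop("'maxLags' must be a non-negative integer or 'auto_aic'")
    }
    aux <- dfAuxiliary(y, k, regression, offset = k)
    list(statistic = unname(aux$tstat),
         p_value = mackinnonPValue(unname(aux$tstat), regression),
         lags = k, regression = regression)
}
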