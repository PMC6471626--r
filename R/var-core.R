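#' @importFrom stats lm.fit setNames coef residuals
NULL

## Build the lagged design matrix for OLS on the window t = p+1..T.
## Each regressor series contributes columns lag1..lagp; an optional
## intercept column comes first. `window` lets callers shrink the sample
## (e.g. common-window lag selection); it indexes t, not rows.
lagDesign <- function(regressors, p, T, intercept = TRUE,
                      window = (p + 1L):T) {
    stopifnot(p >= 1L, all(window > p), all(window <= T))
    cols <- list()
    if (intercept) cols[["(Intercept)"]] <- rep(1, length(window))
    for (nm in names(regressors)) {
        r <- regressors[[nm]]
        for (k in seq_len(p))
            cols[[sprintf("%s.l%d", nm, k)]] <- r[window - k]
    }
    do.call(cbind, cols)
}

#' Fit a lagged regression by ordinary least squares
#'
#' Regresses \code{y[t]} on lags 1..p of each series in
#' \code{regressors} (plus an intercept by default), using observations
#' t = p+1..T. All models fit with the same \code{p} share this window,
#' so residual sums of squares of nested models are directly comparable --
#' the basis of every Granger-causality statistic in the package.
#'
#' @param y numeric target series of length T.
#' @param regressors named list of numeric series, each of length T. Lags
#'   1..p of every series enter the design. Include \code{y} itself to get
#'   an autoregressive term.
#' @param p integer lag order (>= 1).
#' @param intercept logical; include an intercept column (default TRUE).
#'   The lagged-regression equations of the underlying model omit it, but
#'   abundance series are not mean-zero, so it is on by default.
#' @param targetId character label for the fit.
#' @param window integer vector of time indices to fit on; default
#'   \code{(p+1):T}. Must satisfy \code{window > p}.
#'
#' @return An \linkS4class{ARFit}.
#' @examples
#' set.seed(1)
#' y <- as.numeric(stats::arima.sim(list(ar = 0.5), 100))
#' fit <- fitLagged(y, list(y = y), p = 1)
#' coef(fit)
#' @export
fitLagged <- function(y, regressors, p, intercept = TRUE,
                      targetId = "y", window = NULL) {
    p <- as.integer(p)
    T <- length(y)
    if (!is.list(regressors) || length(regressors) == 0L)
        stop("'regressors' must be a non-empty named list of series")
    if (is.null(names(regressors)) || any(!nzchar(names(regressors))))
        names(regressors) <- paste0("x", seq_along(regressors))
    lens <- vapply(regressors, length, 1L)
    if (any(lens != T))
        stop("all regressor series must have the same length as 'y'")
    if (is.null(window)) window <- (p + 1L):T
    ncoef <- length(regressors) * p + as.integer(intercept)
    if (length(window) <= ncoef)
        stop(sprintf("series too short: %d usable observations for %d coefficients",
                     length(window), ncoef))
    if (!all(is.finite(y[window])) ||
        !all(vapply(regressors, function(r) all(is.finite(r)), TRUE)))
        stop("series contain non-finite values; clean the table first")
    X <- lagDesign(regressors, p, T, intercept, window)
    fit <- lm.fit(X, y[window])
    if (fit$rank < ncol(X)) {
        dropped <- colnames(X)[fit$qr$pivot[(fit$rank + 1L):ncol(X)]]
        stop("rank-deficient design; collinear regressors: ",
             paste(dropped, collapse = ", "))
    }
    res <- as.numeric(fit$residuals)
    rss <- sum(res^2)
    new("ARFit",
        targetId = targetId,
        regressorIds = names(regressors),
        p = p,
        coefficients = setNames(as.numeric(fit$coefficients), colnames(X)),
        residuals = res,
        rss = rss,
        nEff = length(window),
        sigma2 = rss / length(window))
}

#' @export
setMethod("coef", "ARFit", function(object, ...) object@coefficients)

#' @export
setMethod("residuals", "ARFit", function(object, ...) object@residuals)

#' Residual sum of squares of an ARFit
#' @param fit an \linkS4class{ARFit}
#' @return non-negative numeric
#' @export
arRSS <- function(fit) fit@rss

setMethod("show", "ARFit", function(object) {
    cat(sprintf("ARFit: %s ~ lags 1..%d of {%s}%s\n",
                object@targetId, object@p,
                paste(object@regressorIds, collapse = ", "),
                if ("(Intercept)" %in% names(object@coefficients))
                    " + intercept" else ""))
    cat(sprintf("  n_eff = %d, RSS = %.6g, sigma2 = %.6g\n",
                object@nEff, object@rss, object@sigma2))
    invisible(NULL)
})

#' Select a lag order by information criterion
#'
#' For a univariate model (\code{x = NULL}) scores the AR(p) fit of
#' \code{y}; for a bivariate model scores the two-equation system in
#' (\code{y}, \code{x}), each equation regressed on lags of both series.
#' Candidates p = 1..pMax are compared on the common window
#' t = pMax+1..T so criteria are computed on identical samples; ties break
#' toward the smaller order.
#'
#' @param y numeric series.
#' @param x optional second numeric series (bivariate selection).
#' @param selection \code{"bic"} (default), \code{"aic"}, or
#'   \code{"fixed"}.
#' @param p lag order returned when \code{selection = "fixed"}.
#' @param pMax largest candidate order; default
#'   \code{min(4, floor(T/10))}.
#' @param intercept include intercepts in the scored fits.
#'
#' @return integer lag order.
#' @export
selectOrder <- function(y, x = NULL, selection = c("bic", "aic", "fixed"),
                        p = NULL, pMax = NULL, intercept = TRUE) {
    selection <- match.arg(selection)
    T <- length(y)
    if (selection == "fixed") {
        if (is.null(p)) stop("selection 'fixed' requires 'p'")
        return(as.integer(p))
    }
    if (is.null(pMax)) pMax <- max(1L, min(4L, T %/% 10L))
    pMax <- as.integer(pMax)
    nSeries <- if (is.null(x)) 1L else 2L
    n <- T - pMax
    if (n <= nSeries * pMax + as.integer(intercept) + 1L)
        stop(sprintf("pMax = %d infeasible for T = %d", pMax, T))
    window <- (pMax + 1L):T
    crit <- vapply(seq_len(pMax), function(pp) {
        kPerEq <- nSeries * pp + as.integer(intercept)
        regs <- if (is.null(x)) list(y = y) else list(y = y, x = x)
        ll <- 0
        k <- 0
        for (target in if (is.null(x)) list(y) else list(y, x)) {
            ## a candidate order whose design is collinear (e.g. a
            ## deterministic series) is infeasible, not an error here
            f <- tryCatch(fitLagged(target, regs, pp, intercept,
                                    window = window),
                          error = function(e) NULL)
            if (is.null(f)) return(Inf)
            s2 <- f@rss / n
            ll <- ll + (if (s2 <= 0) -Inf else n * log(s2))
            k <- k + kPerEq
        }
        penalty <- if (selection == "bic") k * log(n) else 2 * k
        ll + penalty
    }, numeric(1))
    if (all(!is.finite(crit) & crit > 0))
        stop("no feasible lag order: every candidate design is collinear")
    as.integer(which.min(crit))  # which.min takes the first (smallest p) on ties
}
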