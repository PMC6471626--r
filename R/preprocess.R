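#' Delete time points with missing observations
#'
#' Listwise deletion on a shared time grid: every time point at which any
#' variable is missing is dropped for all variables, preserving the
#' temporal order of the remainder. A shared grid is required because the
#' downstream lagged regressions need aligned lags across variables.
#'
#' @param x a \linkS4class{GrangerTimeSeries}.
#' @param minT smallest acceptable number of remaining time points
#'   (default 10); fewer is an error.
#'
#' @return list: \code{table} (cleaned \linkS4class{GrangerTimeSeries}),
#'   \code{report} (data.frame of removed time labels, reason
#'   \code{"missing_policy"}).
#' @export
dropMissing <- function(x, minT = 10L) {
    stopifnot(is(x, "GrangerTimeSeries"))
    vals <- tsValues(x)
    bad <- apply(vals, 2L, anyNA)
    if (sum(!bad) < minT)
        stop(sprintf("only %d complete time points remain (min_T = %d)",
                     sum(!bad), minT))
    report <- data.frame(time_label = colnames(vals)[bad],
                         reason = rep("missing_policy", sum(bad)),
                         stringsAsFactors = FALSE)
    list(table = x[, !bad], report = report)
}

#' Filter low-abundance, zero-inflated OTUs
#'
#' Removes OTU rows whose mean abundance is below \code{meanThresh}
#' and/or whose fraction of zero observations exceeds
#' \code{zeroFracThresh} -- a guard against dropout-driven artefacts in
#' the causality network. Environmental variables are never filtered
#' (the criterion is defined for taxa). The default combiner is
#' \code{"and"} (remove only when both conditions hold); \code{"or"}
#' removes when either holds.
#'
#' @param x a \linkS4class{GrangerTimeSeries} with no missing values (run
#'   \code{\link{dropMissing}} first).
#' @param meanThresh mean-abundance cutoff (default 1).
#' @param zeroFracThresh zero-fraction cutoff in [0, 1] (default 0.5).
#' @param combine \code{"and"} (default) or \code{"or"}.
#'
#' @return list: \code{table} (filtered), \code{report} (data.frame of
#'   removed variables with reason \code{"low_mean"},
#'   \code{"high_zero_fraction"} or \code{"low_mean+high_zero_fraction"}),
#'   \code{kept} (character ids), \code{thresholds} (list).
#' @examples
#' sim <- simulateVAR(makeMotif("null", nExtraNoiseVars = 3,
#'                              T = 60, seed = 1))
#' filterAbundance(sim$table)$kept
#' @export
filterAbundance <- function(x, meanThresh = 1, zeroFracThresh = 0.5,
                            combine = c("and", "or")) {
    combine <- match.arg(combine)
    stopifnot(is(x, "GrangerTimeSeries"))
    vals <- tsValues(x)
    if (nrow(vals) == 0L || ncol(vals) == 0L) stop("empty table")
    if (anyNA(vals)) stop("table has missing values; run dropMissing() first")
    if (!is.finite(meanThresh))
        stop("'meanThresh' must be finite")
    if (zeroFracThresh < 0 || zeroFracThresh > 1)
        stop("'zeroFracThresh' must lie in [0, 1]")
    isOTU <- varClass(x) == "OTU"
    lowMean <- rowMeans(vals) < meanThresh
    highZero <- rowMeans(vals == 0) > zeroFracThresh
    remove <- isOTU & switch(combine,
                             "and" = lowMean & highZero,
                             "or" = lowMean | highZero)
    reason <- ifelse(lowMean & highZero, "low_mean+high_zero_fraction",
                     ifelse(lowMean, "low_mean", "high_zero_fraction"))
    report <- data.frame(var_id = rownames(vals)[remove],
                         reason = reason[remove],
                         stringsAsFactors = FALSE)
    list(table = x[!remove, ],
         report = report,
         kept = rownames(vals)[!remove],
         thresholds = list(meanThresh = meanThresh,
                           zeroFracThresh = zeroFracThresh,
                           combine = combine))
}

#' Stationarity screen with the augmented Dickey-Fuller test
#'
#' Applies \code{\link{adfTest}} to every variable and removes those for
#' which the unit-root null is not rejected at \code{alpha} (p-value >=
#' alpha), since the autoregressive causality model is only valid for
#' stationary series. Constant series are removed (with a warning) rather
#' than crashing the screen.
#'
#' @param x a \linkS4class{GrangerTimeSeries} with no missing values and
#'   at least 10 time points.
#' @param alpha significance level (default 0.05); a variable is kept
#'   (verdict \code{"stationary"}) iff its ADF p-value < alpha.
#' @param regression,maxLags passed to \code{\link{adfTest}}.
#'
#' @return list: \code{table} (stationary variables only),
#'   \code{results} (data.frame: \code{var_id}, \code{adf_statistic},
#'   \code{p_value}, \code{n_lags}, \code{verdict}), \code{report}
#'   (removed variables, reason \code{"nonstationary"}).
#' @export
adfScreen <- function(x, alpha = 0.05,
                      regression = c("constant", "constant_trend"),
                      maxLags = "auto_aic") {
    regression <- match.arg(regression)
    stopifnot(is(x, "GrangerTimeSeries"))
    vals <- tsValues(x)
    if (anyNA(vals)) stop("table has missing values; run dropMissing() first")
    if (ncol(vals) < 10L) stop("ADF screen requires at least 10 time points")
    res <- lapply(rownames(vals), function(id) {
        a <- adfTest(vals[id, ], regression = regression, maxLags = maxLags)
        data.frame(var_id = id, adf_statistic = a$statistic,
                   p_value = a$p_value, n_lags = a$lags,
                   verdict = if (a$p_value < alpha) "stationary"
                             else "nonstationary",
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    keep <- res$verdict == "stationary"
    report <- data.frame(var_id = res$var_id[!keep],
                         reason = rep("nonstationary", sum(!keep)),
                         stringsAsFactors = FALSE)
    list(table = x[keep, ], results = res, report = report)
}
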