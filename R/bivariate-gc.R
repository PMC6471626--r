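#' @importFrom stats pf
NULL

#' Granger-causality statistic from nested residual sums of squares
#'
#' The causality of a source on a target is the log ratio of the
#' maximum-likelihood residual variances of the restricted model (target's
#' own lags only) and the full model (target's plus source's lags):
#' \code{ln(var(u)/var(w))}. On a shared fitting window the sample-size
#' normalisations cancel, so this equals \code{ln(rssRestricted/rssFull)}.
#' Zero when the source adds nothing; positive otherwise (up to rounding,
#' since the models are nested).
#'
#' @param rssRestricted,rssFull residual sums of squares of the restricted
#'   and full models, fit on the same window.
#' @return non-negative numeric (tiny negatives from rounding are possible).
#' @export
gcStatistic <- function(rssRestricted, rssFull) {
    if (rssFull <= 0)
        stop("degenerate pair: full model fits perfectly (rss == 0); ",
             "the statistic is undefined")
    log(rssRestricted / rssFull)
}

#' F-test for the significance of a Granger-causality statistic
#'
#' Tests the null of no causality (all cross-lag coefficients zero) with
#' \deqn{F = \frac{T - 2p - 1}{p} \cdot
#'       \frac{RSS_{restricted} - RSS_{full}}{RSS_{full}},}
#' referred to an F distribution with (p, T - 2p - 1) degrees of freedom,
#' where T is the full series length and p the lag order.
#'
#' @param rssRestricted,rssFull nested residual sums of squares (shared
#'   window).
#' @param T integer, full series length.
#' @param p integer lag order.
#' @return list with \code{f_stat}, \code{df1}, \code{df2}, \code{p_value}.
#' @export
gcFTest <- function(rssRestricted, rssFull, T, p) {
    p <- as.integer(p)
    df2 <- T - 2L * p - 1L
    if (df2 <= 0L)
        stop(sprintf("series too short for lag %d (T = %d)", p, T))
    if (rssFull <= 0)
        stop("degenerate pair: full model fits perfectly (rss == 0)")
    f <- (df2 / p) * (rssRestricted - rssFull) / rssFull
    f <- max(f, 0)  # nested OLS; clamp rounding noise
    list(f_stat = f, df1 = p, df2 = df2,
         p_value = pf(f, p, df2, lower.tail = FALSE))
}

## One directed test: does `source` Granger-cause `target`?
## Returns the row of statistics; restricted fits are cached by caller.
gcPairTest <- function(target, source, p, intercept = TRUE,
                       rssRestricted = NULL) {
    T <- length(target)
    if (is.null(rssRestricted))
        rssRestricted <- fitLagged(target, list(y = target), p,
                                   intercept)@rss
    full <- fitLagged(target, list(y = target, x = source), p, intercept)
    if (full@rss <= .Machine$double.eps * max(1, rssRestricted)) {
        return(list(p = p, gc = NA_real_, f_stat = NA_real_,
                    df1 = p, df2 = T - 2L * p - 1L,
                    p_value = NA_real_, status = "degenerate"))
    }
    ft <- gcFTest(rssRestricted, full@rss, T, p)
    list(p = p, gc = gcStatistic(rssRestricted, full@rss),
         f_stat = ft$f_stat, df1 = ft$df1, df2 = ft$df2,
         p_value = ft$p_value, status = "ok")
}

#' Bivariate Granger-causality scan over all ordered pairs
#'
#' Runs the directed Granger-causality test for every ordered pair
#' (source, target) of variables in a cleaned, stationarity-screened
#' table: n(n-1) tests. For each pair the restricted model (target's own
#' lags) and the full model (plus the source's lags) are fit on the shared
#' window t = p+1..T, and the statistic and F-test computed from their
#' residual sums of squares. Results are in deterministic lexicographic
#' order (source, then target).
#'
#' @param x a \linkS4class{GrangerTimeSeries} without missing values.
#' @param selection lag-order policy: \code{"bic"} (default), \code{"aic"}
#'   (per-pair selection on the bivariate system), or \code{"fixed"}.
#' @param p lag order when \code{selection = "fixed"}.
#' @param pMax largest candidate order for bic/aic; default
#'   \code{min(4, floor(T/10))}.
#' @param globalP logical; when TRUE and selection is bic/aic, a single
#'   order (the minimum over per-pair selections) is applied to every pair
#'   for comparability.
#' @param intercept include intercepts (default TRUE).
#'
#' @return data.frame with one row per ordered pair: \code{source},
#'   \code{target}, \code{p}, \code{gc}, \code{f_stat}, \code{df1},
#'   \code{df2}, \code{p_value}, \code{q_value} (NA until
#'   \code{\link{storeyQValues}} is applied via \code{\link{addQValues}}),
#'   \code{status} (\code{"ok"} or \code{"degenerate"}; degenerate pairs
#'   carry NA statistics and are excluded from FDR correction).
#' @examples
#' sim <- simulateVAR(makeMotif("pair", T = 120, seed = 1))
#' head(gcScan(sim$table, selection = "fixed", p = 1))
#' @export
gcScan <- function(x, selection = c("bic", "aic", "fixed"), p = NULL,
                   pMax = NULL, globalP = FALSE, intercept = TRUE) {
    selection <- match.arg(selection)
    stopifnot(is(x, "GrangerTimeSeries"))
    vals <- tsValues(x)
    if (anyNA(vals))
        stop("table has missing values; run dropMissing() first")
    n <- nrow(vals)
    if (n < 2L) stop("at least 2 variables are required")
    ids <- sort(rownames(vals))
    T <- ncol(vals)

    pairs <- expand.grid(target = ids, source = ids,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, c("source", "target")]
    pairs <- pairs[order(pairs$source, pairs$target), ]

    pickP <- function(src, tgt) {
        if (selection == "fixed") {
            if (is.null(p)) stop("selection 'fixed' requires 'p'")
            as.integer(p)
        } else {
            selectOrder(vals[tgt, ], vals[src, ], selection = selection,
                        pMax = pMax, intercept = intercept)
        }
    }
    pVec <- mapply(pickP, pairs$source, pairs$target)
    if (globalP) pVec <- rep(min(pVec), length(pVec))

    restrCache <- new.env(parent = emptyenv())
    rows <- vector("list", nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
        tgt <- pairs$target[i]; src <- pairs$source[i]; pp <- pVec[i]
        key <- paste(tgt, pp, sep = "|")
        if (is.null(restrCache[[key]]))
            restrCache[[key]] <- fitLagged(vals[tgt, ],
                                           list(y = vals[tgt, ]),
                                           pp, intercept)@rss
        rows[[i]] <- gcPairTest(vals[tgt, ], vals[src, ], pp, intercept,
                                rssRestricted = restrCache[[key]])
    }
    res <- do.call(rbind, lapply(rows, as.data.frame))
    out <- cbind(pairs, res, q_value = NA_real_)
    rownames(out) <- NULL
    out[c("source", "target", "p", "gc", "f_stat", "df1", "df2",
          "p_value", "q_value", "status")]
}
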