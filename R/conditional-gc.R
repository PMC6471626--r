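#' Conditional Granger causality of a source on a target given mediators
#'
#' Decides whether the causality of \code{y} (source) on \code{x} (target)
#' survives conditioning on candidate mediators \code{z}. Both models
#' include the target's own lags and the mediators' lags; the full model
#' adds the source's lags. The conditional statistic is the log ratio of
#' the two residual variances, zero when the source adds nothing once the
#' mediators are accounted for. Significance uses an F-test with
#' df1 = p and df2 = (T - p) minus the number of coefficients in the full
#' model (intercept included).
#'
#' With an empty mediator set this reduces exactly to the bivariate
#' statistic for y -> x.
#'
#' @param x numeric target series (the effect).
#' @param y numeric source series (the putative cause).
#' @param z list of numeric mediator series (possibly empty), or a single
#'   numeric vector.
#' @param p integer lag order.
#' @param intercept include intercepts (default TRUE).
#' @param alpha significance level for the direct/indirect verdict.
#' @param sourceId,targetId,mediatorIds labels for the report.
#'
#' @return one-row data.frame: \code{source}, \code{target},
#'   \code{mediators} (comma-separated), \code{p}, \code{cond_gc},
#'   \code{f_stat}, \code{df1}, \code{df2}, \code{p_value},
#'   \code{verdict} (\code{"direct"} if p_value < alpha else
#'   \code{"indirect"}).
#' @examples
#' sim <- simulateVAR(makeMotif("chain", T = 300, seed = 2))
#' v <- tsValues(sim$table)
#' conditionalGC(v["X", ], v["Y", ], list(Z = v["Z", ]), p = 1)
#' @export
conditionalGC <- function(x, y, z = list(), p, intercept = TRUE,
                          alpha = 0.05, sourceId = "Y", targetId = "X",
                          mediatorIds = NULL) {
    if (is.numeric(z)) z <- list(z)
    p <- as.integer(p)
    T <- length(x)
    if (is.null(mediatorIds))
        mediatorIds <- if (length(z)) {
            if (is.null(names(z))) paste0("Z", seq_along(z)) else names(z)
        } else character()
    names(z) <- if (length(z)) mediatorIds else NULL

    reduced <- c(list(x), z)
    names(reduced) <- c(targetId, mediatorIds)
    full <- c(list(x), setNames(list(y), sourceId), z)
    names(full) <- c(targetId, sourceId, mediatorIds)

    fitR <- fitLagged(x, reduced, p, intercept, targetId = targetId)
    fitF <- fitLagged(x, full, p, intercept, targetId = targetId)

    nCoefFull <- length(full) * p + as.integer(intercept)
    df2 <- (T - p) - nCoefFull
    if (df2 <= 0L)
        stop(sprintf("too many mediators for T = %d at lag %d", T, p))
    if (fitF@rss <= 0)
        stop("degenerate conditional model: full fit is perfect")
    gc <- log(fitR@rss / fitF@rss)
    f <- max((df2 / p) * (fitR@rss - fitF@rss) / fitF@rss, 0)
    pv <- pf(f, p, df2, lower.tail = FALSE)
    data.frame(source = sourceId, target = targetId,
               mediators = paste(mediatorIds, collapse = ","),
               p = p, cond_gc = gc, f_stat = f, df1 = p, df2 = df2,
               p_value = pv,
               verdict = if (pv < alpha) "direct" else "indirect",
               stringsAsFactors = FALSE)
}

#' Classify a directed edge as direct or indirect
#'
#' An edge is kept as direct only if it survives conditioning on every
#' candidate mediator: under the default \code{"ftest_alpha"} rule each
#' conditional test must retain \code{p_value < alpha}; under the
#' \code{"gc_threshold"} rule each conditional statistic must exceed
#' \code{threshold}. A single failing mediator makes the edge indirect
#' (the "any spurious indirect causality" rule), and that mediator set is
#' recorded.
#'
#' @param condResults data.frame of conditional test rows (as returned by
#'   \code{\link{conditionalGC}}), non-empty.
#' @param rule \code{"ftest_alpha"} (default) or \code{"gc_threshold"}.
#' @param alpha significance level for the F-test rule.
#' @param threshold cutoff on \code{cond_gc} for the threshold rule.
#'
#' @return list with \code{verdict} (\code{"direct"}/\code{"indirect"})
#'   and \code{mediators} (character vector of mediator sets that failed;
#'   empty for a direct edge).
#' @export
classifyEdge <- function(condResults, rule = c("ftest_alpha", "gc_threshold"),
                         alpha = 0.05, threshold = NULL) {
    rule <- match.arg(rule)
    if (!is.data.frame(condResults) || nrow(condResults) == 0L)
        stop("'condResults' must be a non-empty data.frame")
    fails <- switch(rule,
        ftest_alpha = condResults$p_value >= alpha,
        gc_threshold = {
            if (is.null(threshold))
                stop("rule 'gc_threshold' requires 'threshold'")
            condResults$cond_gc <= threshold
        })
    list(verdict = if (any(fails)) "indirect" else "direct",
         mediators = condResults$mediators[fails])
}
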