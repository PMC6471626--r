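#' @importFrom stats smooth.spline predict p.adjust
NULL

#' Storey q-values with smoother pi0 estimation
#'
#' Converts a family of p-values into q-values (the minimum false
#' discovery rate at which each test is called significant). The
#' proportion of true nulls, pi0, is estimated by default with the
#' natural-cubic-spline smoother of Storey & Tibshirani: the tail
#' proportions \code{mean(p > lambda)/(1 - lambda)} over a lambda grid
#' are smoothed (df = 3) and evaluated at the largest lambda. Then
#' \deqn{q_{(i)} = \min_{j \ge i} \; \pi_0 \, m \, p_{(j)} / j,}
#' capped at 1. With \code{pi0Method = "bh"} pi0 is fixed at 1 and the
#' q-values equal Benjamini-Hochberg adjusted p-values exactly.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param lambda grid in [0, 1) for pi0 estimation; default
#'   \code{seq(0.05, 0.95, 0.05)}.
#' @param pi0Method \code{"smoother"} (default), \code{"fixed_lambda"}
#'   (tail estimate at \code{fixedLambda}), or \code{"bh"}.
#' @param fixedLambda single lambda for \code{"fixed_lambda"}.
#'
#' @return list of class \code{"QValueSet"}: \code{pValues},
#'   \code{qValues} (same order as input), \code{pi0}, \code{lambda},
#'   \code{pi0Method}.
#' @examples
#' set.seed(1)
#' qs <- storeyQValues(runif(200))
#' qs$pi0
#' @export
storeyQValues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                          pi0Method = c("smoother", "fixed_lambda", "bh"),
                          fixedLambda = 0.5) {
    pi0Method <- match.arg(pi0Method)
    if (length(p) < 1L) stop("'p' must be non-empty")
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1] with no NAs")
    m <- length(p)
    pi0 <- switch(pi0Method,
        bh = 1,
        fixed_lambda = mean(p > fixedLambda) / (1 - fixedLambda),
        smoother = {
            if (any(lambda < 0 | lambda >= 1))
                stop("'lambda' must lie in [0, 1)")
            lambda <- sort(unique(lambda))
            pi0l <- vapply(lambda,
                           function(l) mean(p > l) / (1 - l), numeric(1))
            if (length(lambda) >= 4L) {
                sp <- smooth.spline(lambda, pi0l, df = 3)
                predict(sp, x = max(lambda))$y
            } else pi0l[length(pi0l)]  # grid too short to smooth
        })
    if (pi0 <= 0) {
        warning("pi0 estimate <= 0; clamped to 1/m")
        pi0 <- 1 / m
    }
    pi0 <- min(pi0, 1)

    ## step-up from the largest p; arithmetic arranged so that pi0 = 1
    ## reproduces Benjamini-Hochberg exactly, bit for bit
    o <- order(p, decreasing = TRUE)
    qo <- cummin(pi0 * ((m / (m:1)) * p[o]))
    q <- numeric(m)
    q[o] <- pmin(1, qo)

    structure(list(pValues = p, qValues = q, pi0 = pi0,
                   lambda = if (pi0Method == "smoother") lambda else NULL,
                   pi0Method = pi0Method),
              class = "QValueSet")
}

#' @export
print.QValueSet <- function(x, ...) {
    cat(sprintf("QValueSet: %d tests, pi0 = %.4f (%s)\n",
                length(x$pValues), x$pi0, x$pi0Method))
    cat(sprintf("  significant at q < 0.05: %d\n", sum(x$qValues < 0.05)))
    invisible(x)
}

#' Attach q-values to a Granger-causality scan
#'
#' Applies \code{\link{storeyQValues}} to the p-values of all
#' non-degenerate rows of a \code{\link{gcScan}} result, treating the
#' complete set of ordered-pair tests as one FDR family. Degenerate rows
#' keep \code{NA}.
#'
#' @param results data.frame from \code{\link{gcScan}}.
#' @param ... passed to \code{\link{storeyQValues}}.
#' @return the data.frame with its \code{q_value} column filled in;
#'   the pi0 estimate is attached as \code{attr(, "pi0")}.
#' @export
addQValues <- function(results, ...) {
    ok <- results$status == "ok"
    if (!any(ok)) stop("no testable pairs in 'results'")
    qs <- storeyQValues(results$p_value[ok], ...)
    results$q_value[ok] <- qs$qValues
    attr(results, "pi0") <- qs$pi0
    results
}
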