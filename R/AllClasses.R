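#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

VAR_CLASSES <- c("OTU", "environmental")

#' GrangerTimeSeries: a variables-by-time abundance table
#'
#' Thin extension of \link[SummarizedExperiment]{SummarizedExperiment} holding
#' one assay, \code{"values"}: a numeric matrix with variables (OTUs and
#' environmental factors) as rows and time points as columns. Per-variable
#' metadata lives in \code{rowData}: at least \code{varClass} (one of
#' \code{"OTU"} or \code{"environmental"}) and optionally \code{displayName}
#' (e.g. a taxonomy string). Missing observations are \code{NA}, never zero:
#' a zero is a measured absence and participates in the zero-inflation
#' filter, while \code{NA} marks an unsampled time point and is handled by
#' listwise deletion (\code{\link{dropMissing}}).
#'
#' @slot ... see \link[SummarizedExperiment]{SummarizedExperiment}
#' @seealso \code{\link{GrangerTimeSeries}} (constructor),
#'   \code{\link{varClass}}, \code{\link{timeLabels}}, \code{\link{tsValues}}
#' @export
setClass("GrangerTimeSeries", contains = "SummarizedExperiment")

setValidity("GrangerTimeSeries", function(object) {
    msg <- character()
    if (!("values" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'values' is required")
    else if (!is.numeric(assay(object, "values")))
        msg <- c(msg, "assay 'values' must be numeric")
    rn <- rownames(object)
    if (is.null(rn) || anyDuplicated(rn) || any(!nzchar(rn)))
        msg <- c(msg, "variable ids (rownames) must be unique non-empty strings")
    cn <- colnames(object)
    if (!is.null(cn) && anyDuplicated(cn))
        msg <- c(msg, "time labels (colnames) must be unique")
    if (!("varClass" %in% colnames(rowData(object))))
        msg <- c(msg, "rowData must contain a 'varClass' column")
    else {
        vc <- rowData(object)$varClass
        if (!all(vc %in% VAR_CLASSES))
            msg <- c(msg, sprintf("varClass values must be in {%s}",
                                  paste(VAR_CLASSES, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' CausalityGraph: a directed Granger-causality network
#'
#' Holds the vertex set (variable ids with their class), the directed edge
#' set with the full per-edge statistics (lag order, Granger-causality value,
#' F statistic, p- and q-value), an optional undirected edge set, and an
#' audit log of edges removed by conditional-Granger-causality pruning.
#'
#' @slot vertices data.frame with columns \code{id}, \code{class} and logical
#'   \code{isolated}.
#' @slot edges data.frame of retained directed edges: \code{source},
#'   \code{target}, \code{p}, \code{gc}, \code{f_stat}, \code{df1},
#'   \code{df2}, \code{p_value}, \code{q_value}, \code{status}.
#' @slot undirected data.frame of unordered pairs (empty by default).
#' @slot pruned data.frame logging removed edges and the conditional tests
#'   behind each removal: \code{source}, \code{target}, \code{mediator},
#'   \code{cond_gc}, \code{f_stat}, \code{p_value}, \code{verdict}.
#' @slot params list of the thresholds and options the graph was built with.
#' @seealso \code{\link{buildGraph}}, \code{\link{pruneGraph}},
#'   \code{\link{writeNetwork}}
#' @export
setClass("CausalityGraph",
    representation(vertices = "data.frame",
                   edges = "data.frame",
                   undirected = "data.frame",
                   pruned = "data.frame",
                   params = "list"))

setValidity("CausalityGraph", function(object) {
    msg <- character()
    v <- object@vertices
    e <- object@edges
    if (!all(c("id", "class") %in% colnames(v)))
        msg <- c(msg, "vertices must have 'id' and 'class' columns")
    if (nrow(e)) {
        need <- c("source", "target")
        if (!all(need %in% colnames(e)))
            msg <- c(msg, "edges must have 'source' and 'target' columns")
        else {
            if (!all(c(e$source, e$target) %in% v$id))
                msg <- c(msg, "every edge endpoint must be a vertex")
            if (any(e$source == e$target))
                msg <- c(msg, "self-loops are not allowed")
        }
    }
    if (anyDuplicated(v$id))
        msg <- c(msg, "vertex ids must be unique")
    if (length(msg)) msg else TRUE
})

#' ARFit: a least-squares fit of a lagged regression
#'
#' Result of regressing a target series on lags 1..p of one or more
#' regressor series (plus an optional intercept), by ordinary least squares
#' on the window t = p+1..T.
#'
#' @slot targetId character, name of the dependent series.
#' @slot regressorIds character, names of the series whose lags enter the
#'   design (the target's own lags are listed when present).
#' @slot p integer lag order.
#' @slot coefficients named numeric vector (intercept first when included).
#' @slot residuals numeric vector of length T - p.
#' @slot rss non-negative residual sum of squares.
#' @slot nEff integer, T - p.
#' @slot sigma2 rss / nEff (maximum-likelihood residual variance).
#' @seealso \code{\link{fitLagged}}
#' @export
setClass("ARFit",
    representation(targetId = "character",
                   regressorIds = "character",
                   p = "integer",
                   coefficients = "numeric",
                   residuals = "numeric",
                   rss = "numeric",
                   nEff = "integer",
                   sigma2 = "numeric"))

setValidity("ARFit", function(object) {
    msg <- character()
    if (object@rss < -1e-10) msg <- c(msg, "rss must be non-negative")
    if (length(object@residuals) != object@nEff)
        msg <- c(msg, "residuals must have length nEff")
    if (abs(object@rss - sum(object@residuals^2)) >
        1e-10 * max(1, object@rss))
        msg <- c(msg, "rss must equal the sum of squared residuals")
    if (length(msg)) msg else TRUE
})
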