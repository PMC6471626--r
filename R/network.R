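#' @importFrom igraph graph_from_data_frame components make_empty_graph
NULL

emptyEdgeFrame <- function() {
    data.frame(source = character(), target = character(),
               p = integer(), gc = numeric(), f_stat = numeric(),
               df1 = integer(), df2 = integer(), p_value = numeric(),
               q_value = numeric(), status = character(),
               stringsAsFactors = FALSE)
}

emptyPrunedFrame <- function() {
    data.frame(source = character(), target = character(),
               mediator = character(), p = integer(), cond_gc = numeric(),
               f_stat = numeric(), p_value = numeric(),
               verdict = character(), stringsAsFactors = FALSE)
}

#' Build the directed causality graph from a corrected scan
#'
#' Keeps exactly the ordered pairs whose q-value is below
#' \code{qThreshold} as directed edges. All variables stay in the vertex
#' set (isolated vertices are flagged, not dropped). The undirected edge
#' set is empty by default. Cycles are permitted; when present, a warning
#' lists the non-trivial strongly connected components.
#'
#' @param results data.frame from \code{\link{gcScan}} with q-values
#'   filled in (\code{\link{addQValues}}); missing q-values on testable
#'   rows are an error.
#' @param qThreshold q-value cutoff for edge inclusion (default 0.05).
#' @param vertices optional data.frame (\code{id}, \code{class}) giving
#'   the vertex set and classes; defaults to all ids in \code{results}
#'   with class \code{"OTU"}. A \linkS4class{GrangerTimeSeries} may also
#'   be given.
#'
#' @return a \linkS4class{CausalityGraph} (unpruned; every retained edge
#'   has status \code{"direct"}).
#' @export
buildGraph <- function(results, qThreshold = 0.05, vertices = NULL) {
    ok <- results$status == "ok"
    if (any(is.na(results$q_value[ok])))
        stop("q_values missing; run addQValues() on the scan first")
    if (is(vertices, "GrangerTimeSeries"))
        vertices <- data.frame(id = rownames(vertices),
                               class = unname(varClass(vertices)),
                               stringsAsFactors = FALSE)
    if (is.null(vertices)) {
        ids <- sort(unique(c(results$source, results$target)))
        vertices <- data.frame(id = ids, class = "OTU",
                               stringsAsFactors = FALSE)
    }
    keep <- ok & results$q_value < qThreshold
    edges <- results[keep, c("source", "target", "p", "gc", "f_stat",
                             "df1", "df2", "p_value", "q_value")]
    edges <- edges[order(edges$source, edges$target), ]
    edges$status <- rep("direct", nrow(edges))
    rownames(edges) <- NULL
    if (nrow(edges) == 0L) edges <- emptyEdgeFrame()
    vertices <- vertices[order(vertices$id), ]
    vertices$isolated <- !(vertices$id %in% c(edges$source, edges$target))
    rownames(vertices) <- NULL
    g <- new("CausalityGraph", vertices = vertices, edges = edges,
             undirected = data.frame(), pruned = emptyPrunedFrame(),
             params = list(qThreshold = qThreshold))
    warnCycles(g)
    g
}

warnCycles <- function(graph) {
    e <- graph@edges
    if (nrow(e) == 0L) return(invisible(NULL))
    ig <- graph_from_data_frame(e[, c("source", "target")], directed = TRUE)
    sc <- components(ig, mode = "strong")
    big <- which(sc$csize > 1L)
    if (length(big)) {
        members <- vapply(big, function(k)
            paste(names(sc$membership)[sc$membership == k],
                  collapse = ","), character(1))
        warning("graph contains cycles; strongly connected components: ",
                paste(sprintf("{%s}", members), collapse = " "))
    }
    invisible(NULL)
}

#' Prune spurious (mediated) edges with conditional Granger causality
#'
#' Single pass over the directed edges of the unpruned graph. For each
#' edge i -> j the candidate mediators are, by default, the variables z
#' with both i -> z and z -> j in the (unpruned) edge set -- the two-path
#' configuration in which a mediated effect can masquerade as a direct
#' one; \code{mediators = "all"} widens the candidates to every other
#' vertex. Each mediator is tested separately with
#' \code{\link{conditionalGC}} at the edge's own lag order; the edge is
#' kept only if it stays significant against every mediator
#' (\code{\link{classifyEdge}}). Removed edges move to the pruning audit
#' log. All decisions are made against the original edge set, so pruning
#' is deterministic and idempotent.
#'
#' @param graph a \linkS4class{CausalityGraph} from
#'   \code{\link{buildGraph}}.
#' @param x the \linkS4class{GrangerTimeSeries} the graph was built from.
#' @param rule,alpha,threshold passed to \code{\link{classifyEdge}}.
#' @param mediators \code{"two_path"} (default) or \code{"all"}.
#' @param intercept include intercepts in the conditional fits.
#'
#' @return the pruned \linkS4class{CausalityGraph}; the audit log of all
#'   conditional tests is in \code{prunedEdges(graph)} (rows with verdict
#'   \code{"indirect"} are the removals).
#' @export
pruneGraph <- function(graph, x, rule = c("ftest_alpha", "gc_threshold"),
                       alpha = 0.05, threshold = NULL,
                       mediators = c("two_path", "all"),
                       intercept = TRUE) {
    rule <- match.arg(rule)
    mediators <- match.arg(mediators)
    stopifnot(is(graph, "CausalityGraph"), is(x, "GrangerTimeSeries"))
    e <- graph@edges
    if (!all(graph@vertices$id %in% rownames(x)))
        stop("graph vertices missing from the table: ",
             paste(setdiff(graph@vertices$id, rownames(x)), collapse = ", "))
    if (nrow(e) == 0L) return(graph)
    vals <- tsValues(x)

    hasEdge <- paste(e$source, e$target)
    keepRow <- rep(TRUE, nrow(e))
    audit <- vector("list", nrow(e))
    for (i in seq_len(nrow(e))) {
        src <- e$source[i]; tgt <- e$target[i]
        zCand <- switch(mediators,
            two_path = {
                zs <- e$target[e$source == src]      # src -> z
                zs[paste(zs, tgt) %in% hasEdge & zs != tgt]  # z -> tgt
            },
            all = setdiff(graph@vertices$id, c(src, tgt)))
        if (length(zCand) == 0L) next
        tests <- do.call(rbind, lapply(zCand, function(z)
            conditionalGC(vals[tgt, ], vals[src, ],
                          list(vals[z, ]), p = e$p[i],
                          intercept = intercept, alpha = alpha,
                          sourceId = src, targetId = tgt,
                          mediatorIds = z)))
        cls <- classifyEdge(tests, rule = rule, alpha = alpha,
                            threshold = threshold)
        tests$verdict <- ifelse(tests$mediators %in% cls$mediators,
                                "indirect", "direct")
        audit[[i]] <- tests
        if (cls$verdict == "indirect") keepRow[i] <- FALSE
    }
    audit <- do.call(rbind, audit[!vapply(audit, is.null, TRUE)])
    prunedLog <- if (is.null(audit)) emptyPrunedFrame() else
        data.frame(source = audit$source, target = audit$target,
                   mediator = audit$mediators, p = audit$p,
                   cond_gc = audit$cond_gc, f_stat = audit$f_stat,
                   p_value = audit$p_value, verdict = audit$verdict,
                   stringsAsFactors = FALSE)

    out <- graph
    out@edges <- e[keepRow, ]
    rownames(out@edges) <- NULL
    out@pruned <- prunedLog
    removed <- e[!keepRow, , drop = FALSE]
    removed$status <- rep("pruned", nrow(removed))
    rownames(removed) <- NULL
    out@vertices$isolated <- !(out@vertices$id %in%
                               c(out@edges$source, out@edges$target))
    out@params <- c(graph@params,
                    list(pruneRule = rule, pruneAlpha = alpha,
                         pruneThreshold = threshold,
                         mediatorPolicy = mediators,
                         removedEdges = removed))
    out
}

#' Run the full network-inference pipeline on a cleaned table
#'
#' Convenience wrapper: pairwise Granger-causality scan
#' (\code{\link{gcScan}}), Storey q-value correction over the whole
#' family (\code{\link{addQValues}}), edge selection at the q-threshold
#' (\code{\link{buildGraph}}), and conditional-Granger-causality pruning
#' (\code{\link{pruneGraph}}). The input must already be cleaned
#' (no missing values) and stationarity-screened.
#'
#' @param x a \linkS4class{GrangerTimeSeries}.
#' @param qThreshold edge-inclusion q-value cutoff (default 0.05).
#' @param prune logical; run the conditional pruning pass (default TRUE).
#' @param pi0Method passed to \code{\link{storeyQValues}}.
#' @param alpha significance level for conditional tests.
#' @param ... passed to \code{\link{gcScan}} (lag-order policy etc.).
#'
#' @return list: \code{graph} (the final \linkS4class{CausalityGraph}),
#'   \code{scan} (the corrected scan table), \code{pi0}.
#' @examples
#' sim <- simulateVAR(makeMotif("chain", T = 200, seed = 3))
#' net <- grangerNetwork(sim$table, selection = "fixed", p = 1)
#' net$graph
#' @export
grangerNetwork <- function(x, ..., qThreshold = 0.05, prune = TRUE,
                           pi0Method = "smoother", alpha = 0.05) {
    scan <- gcScan(x, ...)
    scan <- addQValues(scan, pi0Method = pi0Method)
    graph <- buildGraph(scan, qThreshold = qThreshold, vertices = x)
    if (prune)
        graph <- pruneGraph(graph, x, alpha = alpha)
    list(graph = graph, scan = scan, pi0 = attr(scan, "pi0"))
}

#' @rdname CausalityGraph-accessors
#' @export
setGeneric("gcEdges", function(x) standardGeneric("gcEdges"))

#' @rdname CausalityGraph-accessors
#' @export
setGeneric("gcVertices", function(x) standardGeneric("gcVertices"))

#' @rdname CausalityGraph-accessors
#' @export
setGeneric("prunedEdges", function(x) standardGeneric("prunedEdges"))

#' Accessors for CausalityGraph
#'
#' \code{gcEdges} returns the retained directed edges with their
#' statistics; \code{gcVertices} the vertex table (id, class, isolated);
#' \code{prunedEdges} the conditional-test audit log (rows with verdict
#' \code{"indirect"} are the pruned edges).
#'
#' @param x a \linkS4class{CausalityGraph}
#' @name CausalityGraph-accessors
#' @aliases gcEdges gcVertices prunedEdges
NULL

#' @rdname CausalityGraph-accessors
#' @export
setMethod("gcEdges", "CausalityGraph", function(x) x@edges)

#' @rdname CausalityGraph-accessors
#' @export
setMethod("gcVertices", "CausalityGraph", function(x) x@vertices)

#' @rdname CausalityGraph-accessors
#' @export
setMethod("prunedEdges", "CausalityGraph", function(x) x@pruned)

setMethod("show", "CausalityGraph", function(object) {
    npr <- sum(object@pruned$verdict == "indirect")
    cat(sprintf("CausalityGraph: %d vertices (%d isolated), %d directed edges\n",
                nrow(object@vertices), sum(object@vertices$isolated),
                nrow(object@edges)))
    if (npr > 0)
        cat(sprintf("  %d edge(s) pruned as mediated (indirect)\n", npr))
    if (!is.null(object@params$qThreshold))
        cat(sprintf("  q-threshold: %g\n", object@params$qThreshold))
    invisible(NULL)
})
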