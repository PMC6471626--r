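#' @importFrom utils read.delim write.table
#' @importFrom igraph graph_from_data_frame write_graph read_graph
#'   as_data_frame vertex_attr
NULL

sepForPath <- function(path) {
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a time-series abundance table
#'
#' Reads a delimited text table (TSV or CSV, chosen by file extension)
#' with one header row and one label column, into a
#' \linkS4class{GrangerTimeSeries}. Empty cells and \code{"NA"} are
#' missing observations; zeros are data, never missing. Either layout is
#' accepted and normalised to variables-in-rows.
#'
#' @param path file path.
#' @param orientation \code{"vars_in_rows"} (default) or
#'   \code{"vars_in_cols"}.
#' @param meta optional variable metadata: a data.frame with columns
#'   \code{var_id}, \code{display_name}, \code{class}, or a path to such
#'   a TSV/CSV (see \code{\link{readVariableMeta}}). Variables absent
#'   from the metadata default to class \code{"OTU"}.
#'
#' @return a \linkS4class{GrangerTimeSeries} (possibly with missing
#'   values; run \code{\link{dropMissing}} before analysis).
#' @export
readTimeSeriesTable <- function(path,
                                orientation = c("vars_in_rows",
                                                "vars_in_cols"),
                                meta = NULL) {
    orientation <- match.arg(orientation)
    raw <- read.delim(path, sep = sepForPath(path), header = TRUE,
                      row.names = NULL, check.names = FALSE,
                      colClasses = "character", strip.white = TRUE)
    labels <- raw[[1]]
    m <- as.matrix(raw[, -1, drop = FALSE])
    rownames(m) <- labels
    if (orientation == "vars_in_cols") m <- t(m)
    if (anyDuplicated(rownames(m)))
        stop("duplicate variable ids: ",
             paste(unique(rownames(m)[duplicated(rownames(m))]),
                   collapse = ", "))
    vals <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
    isMissing <- is.na(m) | m == "" | toupper(m) == "NA"
    parsed <- suppressWarnings(as.numeric(m[!isMissing]))
    if (anyNA(parsed)) {
        bad <- which(!isMissing, arr.ind = TRUE)[which(is.na(parsed))[1], ]
        stop(sprintf("non-numeric cell '%s' at variable '%s', time '%s'",
                     m[bad[1], bad[2]], rownames(m)[bad[1]],
                     colnames(m)[bad[2]]))
    }
    vals[!isMissing] <- parsed

    varClass <- rep("OTU", nrow(vals))
    displayName <- rownames(vals)
    if (!is.null(meta)) {
        if (is.character(meta)) meta <- readVariableMeta(meta)
        hit <- match(rownames(vals), meta$var_id)
        varClass[!is.na(hit)] <- meta$class[hit[!is.na(hit)]]
        dn <- meta$display_name[hit[!is.na(hit)]]
        displayName[!is.na(hit)][!is.na(dn)] <- dn[!is.na(dn)]
    }
    GrangerTimeSeries(vals, varClass = varClass, displayName = displayName)
}

#' Read a variable metadata table
#'
#' Expects delimited text with columns \code{var_id},
#' \code{display_name}, \code{class} (\code{"OTU"} or
#' \code{"environmental"}).
#'
#' @param path file path (TSV or CSV by extension).
#' @return data.frame.
#' @export
readVariableMeta <- function(path) {
    meta <- read.delim(path, sep = sepForPath(path), header = TRUE,
                       check.names = FALSE, colClasses = "character",
                       strip.white = TRUE)
    need <- c("var_id", "class")
    if (!all(need %in% colnames(meta)))
        stop("metadata must have columns 'var_id' and 'class'")
    if (!("display_name" %in% colnames(meta)))
        meta$display_name <- meta$var_id
    if (!all(meta$class %in% VAR_CLASSES))
        stop(sprintf("metadata 'class' values must be in {%s}",
                     paste(VAR_CLASSES, collapse = ", ")))
    meta
}

## Edges (direct + pruned) in the deterministic writer order.
edgeExportFrame <- function(graph) {
    e <- gcEdges(graph)
    direct <- if (nrow(e)) e[, c("source", "target", "gc", "f_stat",
                                 "p_value", "q_value", "status")] else
        data.frame(source = character(), target = character(),
                   gc = numeric(), f_stat = numeric(),
                   p_value = numeric(), q_value = numeric(),
                   status = character(), stringsAsFactors = FALSE)
    removed <- graph@params$removedEdges
    if (!is.null(removed) && nrow(removed)) {
        ## pruned edges keep their bivariate statistics in the export
        direct <- rbind(direct,
                        removed[, c("source", "target", "gc", "f_stat",
                                    "p_value", "q_value", "status")])
    } else {
        pr <- prunedEdges(graph)
        pr <- pr[pr$verdict == "indirect", , drop = FALSE]
        if (nrow(pr)) {
            key <- !duplicated(paste(pr$source, pr$target))
            direct <- rbind(direct,
                data.frame(source = pr$source[key], target = pr$target[key],
                           gc = NA_real_, f_stat = NA_real_,
                           p_value = NA_real_, q_value = NA_real_,
                           status = "pruned", stringsAsFactors = FALSE))
        }
    }
    out <- direct[order(direct$source, direct$target), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Write a causality graph for Cytoscape and downstream tools
#'
#' Three formats: \describe{
#'   \item{edge_tsv}{tab-delimited edge table with columns source,
#'     target, gc, f_stat, p_value, q_value, status (\code{"direct"} for
#'     retained edges, \code{"pruned"} for edges removed by conditional
#'     pruning).}
#'   \item{sif}{Cytoscape simple-interaction format, interaction type
#'     \code{"gc"}; only retained edges, plus lone lines for isolated
#'     vertices.}
#'   \item{graphml}{GraphML with vertex class and all edge statistics as
#'     attributes (Cytoscape-importable; round-trips through
#'     \code{\link{readNetwork}}).}
#' }
#' Edge ordering is lexicographic by source then target in every format,
#' so outputs are deterministic and diffable.
#'
#' @param graph a \linkS4class{CausalityGraph}.
#' @param path output file path.
#' @param format \code{"edge_tsv"}, \code{"sif"}, or \code{"graphml"}.
#' @return the path, invisibly.
#' @export
writeNetwork <- function(graph, path,
                         format = c("edge_tsv", "sif", "graphml")) {
    format <- match.arg(format)
    stopifnot(is(graph, "CausalityGraph"))
    switch(format,
        edge_tsv = {
            tab <- edgeExportFrame(graph)
            num <- vapply(tab, is.numeric, TRUE)
            tab[num] <- lapply(tab[num], function(z)
                ifelse(is.na(z), "NA", sprintf("%.17g", z)))
            write.table(tab, path, sep = "\t", quote = FALSE,
                        row.names = FALSE)
        },
        sif = {
            e <- gcEdges(graph)
            e <- e[order(e$source, e$target), , drop = FALSE]
            lines <- if (nrow(e))
                sprintf("%s\tgc\t%s", e$source, e$target) else character()
            iso <- sort(gcVertices(graph)$id[gcVertices(graph)$isolated])
            writeLines(c(lines, iso), path)
        },
        graphml = {
            e <- gcEdges(graph)
            v <- gcVertices(graph)
            ig <- graph_from_data_frame(
                if (nrow(e)) e[order(e$source, e$target), ] else
                    data.frame(source = character(), target = character()),
                directed = TRUE,
                vertices = data.frame(name = v$id, class = v$class,
                                      stringsAsFactors = FALSE))
            write_graph(ig, path, format = "graphml")
        })
    invisible(path)
}

#' Read a causality graph written by writeNetwork
#'
#' Reconstructs a \linkS4class{CausalityGraph} from an edge table TSV or
#' a GraphML file. Edge statistics and (for GraphML) vertex classes are
#' restored; rows with status \code{"pruned"} in an edge table go to the
#' pruning log.
#'
#' @param path file path.
#' @param format \code{"edge_tsv"} or \code{"graphml"}.
#' @return a \linkS4class{CausalityGraph}.
#' @export
readNetwork <- function(path, format = c("edge_tsv", "graphml")) {
    format <- match.arg(format)
    if (format == "edge_tsv") {
        tab <- read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
        direct <- tab[tab$status == "direct", , drop = FALSE]
        prunedTab <- tab[tab$status == "pruned", , drop = FALSE]
        ids <- sort(unique(c(tab$source, tab$target)))
        edges <- emptyEdgeFrame()
        if (nrow(direct)) {
            edges <- data.frame(source = direct$source,
                                target = direct$target,
                                p = NA_integer_, gc = direct$gc,
                                f_stat = direct$f_stat,
                                df1 = NA_integer_, df2 = NA_integer_,
                                p_value = direct$p_value,
                                q_value = direct$q_value,
                                status = "direct",
                                stringsAsFactors = FALSE)
            edges <- edges[order(edges$source, edges$target), ]
            rownames(edges) <- NULL
        }
        pruned <- emptyPrunedFrame()
        if (nrow(prunedTab))
            pruned <- data.frame(source = prunedTab$source,
                                 target = prunedTab$target,
                                 mediator = NA_character_,
                                 p = NA_integer_, cond_gc = NA_real_,
                                 f_stat = NA_real_, p_value = NA_real_,
                                 verdict = "indirect",
                                 stringsAsFactors = FALSE)
        vertices <- data.frame(id = ids, class = "OTU",
                               stringsAsFactors = FALSE)
    } else {
        ig <- read_graph(path, format = "graphml")
        ed <- igraph::as_data_frame(ig, what = "edges")
        vd <- igraph::as_data_frame(ig, what = "vertices")
        vertices <- data.frame(id = vd$name,
                               class = if ("class" %in% colnames(vd))
                                   vd$class else "OTU",
                               stringsAsFactors = FALSE)
        vertices <- vertices[order(vertices$id), ]
        rownames(vertices) <- NULL
        edges <- emptyEdgeFrame()
        if (nrow(ed)) {
            getcol <- function(nm, default) if (nm %in% colnames(ed))
                ed[[nm]] else rep(default, nrow(ed))
            edges <- data.frame(source = ed$from, target = ed$to,
                                p = as.integer(getcol("p", NA_integer_)),
                                gc = getcol("gc", NA_real_),
                                f_stat = getcol("f_stat", NA_real_),
                                df1 = as.integer(getcol("df1", NA_integer_)),
                                df2 = as.integer(getcol("df2", NA_integer_)),
                                p_value = getcol("p_value", NA_real_),
                                q_value = getcol("q_value", NA_real_),
                                status = getcol("status", "direct"),
                                stringsAsFactors = FALSE)
            edges <- edges[order(edges$source, edges$target), ]
            rownames(edges) <- NULL
        }
        pruned <- emptyPrunedFrame()
    }
    vertices$isolated <- !(vertices$id %in% c(edges$source, edges$target))
    new("CausalityGraph", vertices = vertices, edges = edges,
        undirected = data.frame(), pruned = pruned, params = list())
}
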