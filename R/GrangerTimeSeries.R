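#' Construct a GrangerTimeSeries
#'
#' @param values numeric matrix, variables in rows and time points in
#'   columns. Rownames are the variable ids (required, unique). Colnames are
#'   the time labels; when absent, \code{"t1".."tT"} is used.
#' @param varClass character vector, per-variable class, each \code{"OTU"}
#'   or \code{"environmental"}. Recycled if length 1. Default \code{"OTU"}.
#' @param displayName optional character vector of human-readable names
#'   (e.g. taxonomy strings); defaults to the variable ids.
#'
#' @return A \linkS4class{GrangerTimeSeries}.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("OTU", 1:4), NULL))
#' gts <- GrangerTimeSeries(m)
#' nVars(gts)
#' @export
GrangerTimeSeries <- function(values, varClass = "OTU", displayName = NULL) {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        stop("'values' must have rownames (variable ids)")
    if (is.null(colnames(values)))
        colnames(values) <- paste0("t", seq_len(ncol(values)))
    varClass <- rep_len(as.character(varClass), nrow(values))
    if (is.null(displayName)) displayName <- rownames(values)
    rd <- DataFrame(varClass = varClass,
                    displayName = rep_len(as.character(displayName),
                                          nrow(values)),
                    row.names = rownames(values))
    se <- SummarizedExperiment(assays = list(values = values), rowData = rd)
    new("GrangerTimeSeries", se)
}

#' @rdname GrangerTimeSeries-accessors
#' @export
setGeneric("tsValues", function(x) standardGeneric("tsValues"))

#' @rdname GrangerTimeSeries-accessors
#' @export
setGeneric("varClass", function(x) standardGeneric("varClass"))

#' @rdname GrangerTimeSeries-accessors
#' @export
setGeneric("timeLabels", function(x) standardGeneric("timeLabels"))

#' @rdname GrangerTimeSeries-accessors
#' @export
setGeneric("nVars", function(x) standardGeneric("nVars"))

#' @rdname GrangerTimeSeries-accessors
#' @export
setGeneric("nTimePoints", function(x) standardGeneric("nTimePoints"))

#' Accessors for GrangerTimeSeries
#'
#' \code{tsValues} returns the variables-by-time numeric matrix;
#' \code{varClass} the per-variable class vector (named by variable id);
#' \code{timeLabels} the ordered time labels; \code{nVars} and
#' \code{nTimePoints} the two dimensions.
#'
#' @param x a \linkS4class{GrangerTimeSeries}
#' @name GrangerTimeSeries-accessors
#' @aliases tsValues varClass timeLabels nVars nTimePoints
NULL

#' @rdname GrangerTimeSeries-accessors
#' @export
setMethod("tsValues", "GrangerTimeSeries", function(x) assay(x, "values"))

#' @rdname GrangerTimeSeries-accessors
#' @export
setMethod("varClass", "GrangerTimeSeries", function(x) {
    stats::setNames(rowData(x)$varClass, rownames(x))
})

#' @rdname GrangerTimeSeries-accessors
#' @export
setMethod("timeLabels", "GrangerTimeSeries", function(x) colnames(x))

#' @rdname GrangerTimeSeries-accessors
#' @export
setMethod("nVars", "GrangerTimeSeries", function(x) nrow(x))

#' @rdname GrangerTimeSeries-accessors
#' @export
setMethod("nTimePoints", "GrangerTimeSeries", function(x) ncol(x))

setMethod("show", "GrangerTimeSeries", function(object) {
    vc <- table(factor(rowData(object)$varClass, levels = VAR_CLASSES))
    nmiss <- sum(is.na(assay(object, "values")))
    cat(sprintf(
        "GrangerTimeSeries: %d variables (%d OTU, %d environmental) x %d time points\n",
        nrow(object), vc[["OTU"]], vc[["environmental"]], ncol(object)))
    if (nmiss > 0)
        cat(sprintf("  %d missing observations (run dropMissing())\n", nmiss))
    invisible(NULL)
})
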