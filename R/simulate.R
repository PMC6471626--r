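#' @importFrom stats rnorm runif rpois
NULL

#' Specify a vector-autoregressive simulation
#'
#' Describes a VAR(p) data-generating process with known causal
#' structure: \code{coef[i, j, k]} is the effect of variable j's lag k on
#' variable i, so a nonzero off-diagonal entry is a true directed edge
#' j -> i. The spectral radius of the companion matrix must be below 1
#' (stationarity); otherwise construction fails, naming the radius.
#'
#' @param coef numeric array n x n x p (a matrix is taken as p = 1), with
#'   dimnames on the first margin giving variable ids (defaults
#'   \code{V1..Vn}).
#' @param noiseSd innovation standard deviation, scalar or per-variable
#'   (default 1).
#' @param intercepts per-variable intercepts (default 0).
#' @param T number of retained time points.
#' @param seed integer seed; mandatory, so every draw is reproducible
#'   without touching global RNG state.
#' @param postTransform \code{"none"} (default), \code{"shift_to_nonnegative"}
#'   (adds a constant per variable so minima are 0, mimicking abundances),
#'   or \code{"poisson_round"} (Poisson draws around the shifted values,
#'   mimicking counts).
#' @param missingRate fraction of cells set missing after transform
#'   (default 0).
#' @param burnIn initialization steps discarded (default 200).
#' @param varClass per-variable class for the generated table.
#'
#' @return list of class \code{"SimSpec"}.
#' @export
simSpec <- function(coef, noiseSd = 1, intercepts = 0, T, seed,
                    postTransform = c("none", "shift_to_nonnegative",
                                      "poisson_round"),
                    missingRate = 0, burnIn = 200L, varClass = "OTU") {
    postTransform <- match.arg(postTransform)
    if (is.matrix(coef)) coef <- array(coef, dim = c(dim(coef), 1L),
                                       dimnames = c(dimnames(coef), list(NULL)))
    stopifnot(length(dim(coef)) == 3L, dim(coef)[1] == dim(coef)[2])
    n <- dim(coef)[1]; p <- dim(coef)[3]
    ids <- dimnames(coef)[[1]]
    if (is.null(ids)) ids <- paste0("V", seq_len(n))
    if (missing(seed)) stop("'seed' is mandatory in a SimSpec")
    if (missingRate < 0 || missingRate >= 1)
        stop("'missingRate' must lie in [0, 1)")
    ## companion-matrix stationarity check
    comp <- matrix(0, n * p, n * p)
    for (k in seq_len(p))
        comp[seq_len(n), (k - 1) * n + seq_len(n)] <- coef[, , k]
    if (p > 1)
        comp[(n + 1):(n * p), seq_len(n * (p - 1))] <- diag(n * (p - 1))
    rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
    if (rho >= 1)
        stop(sprintf("non-stationary specification: spectral radius %.4f >= 1",
                     rho))
    structure(list(coef = coef, ids = ids, n = n, p = p,
                   noiseSd = rep_len(noiseSd, n),
                   intercepts = rep_len(intercepts, n),
                   T = as.integer(T), seed = as.integer(seed),
                   postTransform = postTransform,
                   missingRate = missingRate,
                   burnIn = as.integer(burnIn),
                   varClass = rep_len(varClass, n),
                   spectralRadius = rho),
              class = "SimSpec")
}

withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old))
                rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

#' Simulate a VAR time series with known causal structure
#'
#' Iterates \code{x(t) = intercept + sum_k B_k x(t-k) + noise} with
#' Gaussian innovations, discards the burn-in, applies the post
#' transform, and injects missing values at the configured rate. The true
#' graph (one directed edge per nonzero cross coefficient) is returned
#' alongside the table so recovery can be benchmarked. Identical specs
#' (including seed) give bitwise-identical output.
#'
#' @param spec a \code{\link{simSpec}}.
#' @return list: \code{table} (\linkS4class{GrangerTimeSeries}),
#'   \code{trueGraph} (\linkS4class{CausalityGraph} with statistic
#'   columns NA).
#' @examples
#' sim <- simulateVAR(makeMotif("chain", T = 100, seed = 1))
#' gcEdges(sim$trueGraph)[, c("source", "target")]
#' @export
simulateVAR <- function(spec) {
    stopifnot(inherits(spec, "SimSpec"))
    n <- spec$n; p <- spec$p
    total <- spec$burnIn + spec$T
    vals <- withSeed(spec$seed, {
        X <- matrix(0, n, total + p)
        X[, seq_len(p)] <- rnorm(n * p, sd = spec$noiseSd)
        eps <- matrix(rnorm(n * total, sd = spec$noiseSd), n, total)
        for (t in seq_len(total)) {
            acc <- spec$intercepts + eps[, t]
            for (k in seq_len(p))
                acc <- acc + spec$coef[, , k] %*% X[, p + t - k]
            X[, p + t] <- acc
        }
        out <- X[, p + spec$burnIn + seq_len(spec$T), drop = FALSE]
        if (spec$postTransform != "none") {
            shift <- pmin(apply(out, 1, min), 0)
            out <- out - shift
            if (spec$postTransform == "poisson_round")
                out <- matrix(rpois(length(out), lambda = out),
                              n, spec$T)
        }
        if (spec$missingRate > 0) {
            miss <- runif(length(out)) < spec$missingRate
            out[miss] <- NA_real_
        }
        out
    })
    rownames(vals) <- spec$ids
    colnames(vals) <- paste0("t", seq_len(spec$T))
    table <- GrangerTimeSeries(vals, varClass = spec$varClass)

    idx <- which(apply(spec$coef != 0, c(1, 2), any) &
                 !diag(TRUE, n), arr.ind = TRUE)
    edges <- emptyEdgeFrame()
    if (nrow(idx)) {
        edges <- data.frame(source = spec$ids[idx[, 2]],
                            target = spec$ids[idx[, 1]],
                            p = spec$p, gc = NA_real_, f_stat = NA_real_,
                            df1 = NA_integer_, df2 = NA_integer_,
                            p_value = NA_real_, q_value = NA_real_,
                            status = "direct", stringsAsFactors = FALSE)
        edges <- edges[order(edges$source, edges$target), ]
        rownames(edges) <- NULL
    }
    vertices <- data.frame(id = sort(spec$ids),
                           class = spec$varClass[order(spec$ids)],
                           stringsAsFactors = FALSE)
    vertices$isolated <- !(vertices$id %in% c(edges$source, edges$target))
    trueGraph <- new("CausalityGraph", vertices = vertices, edges = edges,
                     undirected = data.frame(),
                     pruned = emptyPrunedFrame(),
                     params = list(source = "simulateVAR", seed = spec$seed))
    list(table = table, trueGraph = trueGraph)
}

#' Canonical causal motifs for benchmarking
#'
#' Builds a \code{\link{simSpec}} for the small directed structures the
#' pipeline must handle: \describe{
#'   \item{null}{independent AR(1) series (no causal edges).}
#'   \item{pair}{X1 -> X2.}
#'   \item{chain}{Y -> Z -> X with no direct Y -> X: the scenario in
#'     which a bivariate scan reports a spurious Y -> X edge that
#'     conditional pruning must remove.}
#'   \item{fork}{common driver Z -> X and Z -> Y (confounding).}
#'   \item{collider}{X -> Z <- Y.}
#' }
#' Every series keeps a self-lag coefficient of 0.3 so each variable is a
#' persistent, stationary AR(1) on its own.
#'
#' @param name motif name.
#' @param strength cross-lag coefficient (default 0.6); must keep the
#'   spec stationary.
#' @param nExtraNoiseVars independent AR(1) nuisance variables appended
#'   (default 0).
#' @param T,seed passed to \code{\link{simSpec}}.
#' @param noiseSd innovation standard deviation (default 1).
#' @param selfCoef self-lag coefficient (default 0.3).
#'
#' @return a \code{\link{simSpec}}.
#' @export
makeMotif <- function(name = c("null", "pair", "chain", "fork", "collider"),
                      strength = 0.6, nExtraNoiseVars = 0L, T, seed,
                      noiseSd = 1, selfCoef = 0.3) {
    name <- match.arg(name)
    core <- switch(name,
        null = list(ids = c("X1", "X2"), edges = NULL),
        pair = list(ids = c("X1", "X2"), edges = rbind(c("X1", "X2"))),
        chain = list(ids = c("Y", "Z", "X"),
                     edges = rbind(c("Y", "Z"), c("Z", "X"))),
        fork = list(ids = c("Z", "X", "Y"),
                    edges = rbind(c("Z", "X"), c("Z", "Y"))),
        collider = list(ids = c("X", "Y", "Z"),
                        edges = rbind(c("X", "Z"), c("Y", "Z"))))
    ids <- core$ids
    if (nExtraNoiseVars > 0)
        ids <- c(ids, paste0("N", seq_len(nExtraNoiseVars)))
    n <- length(ids)
    B <- matrix(0, n, n, dimnames = list(ids, ids))
    diag(B) <- selfCoef
    if (!is.null(core$edges))
        for (r in seq_len(nrow(core$edges)))
            B[core$edges[r, 2], core$edges[r, 1]] <- strength
    simSpec(B, noiseSd = noiseSd, T = T, seed = seed)
}
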