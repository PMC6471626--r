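scanFixture <- function(q) {
    n <- length(q)
    data.frame(source = LETTERS[seq_len(n)],
               target = LETTERS[seq_len(n) + 1L],
               p = 1L, gc = 0.2, f_stat = 5, df1 = 1L, df2 = 40L,
               p_value = q / 2, q_value = q, status = "ok",
               stringsAsFactors = FALSE)
}

test_that("edges are exactly the pairs below the q-threshold", {
    empty <- buildGraph(scanFixture(c(0.6, 0.9)))
    expect_equal(nrow(gcEdges(empty)), 0L)
    expect_true(all(gcVertices(empty)$isolated))

    one <- buildGraph(scanFixture(c(0.04, 0.9)))
    expect_equal(gcEdges(one)$source, "A")
    expect_equal(gcEdges(one)$target, "B")
    expect_equal(nrow(one@undirected), 0L)
    expect_false(gcVertices(one)$isolated[gcVertices(one)$id == "A"])
})

test_that("a scan without q-values is refused", {
    s <- scanFixture(0.04)
    s$q_value <- NA_real_
    expect_error(buildGraph(s), "q_values")
})

test_that("cycles are allowed but announced", {
    s <- rbind(scanFixture(0.01),
               data.frame(source = "B", target = "A", p = 1L, gc = 0.2,
                          f_stat = 5, df1 = 1L, df2 = 40L,
                          p_value = 0.005, q_value = 0.01, status = "ok"))
    expect_warning(g <- buildGraph(s), "cycles")
    expect_equal(nrow(gcEdges(g)), 2L)
})

test_that("self-loops and dangling endpoints violate graph validity", {
    v <- data.frame(id = c("A", "B"), class = "OTU", isolated = FALSE)
    e <- data.frame(source = "A", target = "A", stringsAsFactors = FALSE)
    expect_error(new("CausalityGraph", vertices = v, edges = e,
                     undirected = data.frame(), pruned = data.frame(),
                     params = list()),
                 "self-loops")
})

test_that("a graph with no two-paths is returned unchanged by pruning", {
    sim <- simulateVAR(makeMotif("pair", T = 200, seed = 71))
    scan <- addQValues(gcScan(sim$table, selection = "fixed", p = 1),
                       pi0Method = "bh")
    g <- buildGraph(scan, vertices = sim$table)
    pruned <- pruneGraph(g, sim$table)
    expect_equal(gcEdges(pruned), gcEdges(g))
})

test_that("pruning removes the mediated chain edge in most replicates", {
    # the spurious Y -> X edge shows up in a subset of chain replicates;
    # among those, conditioning on Z should remove it most of the time,
    # true edges should always survive, and pruning must be idempotent
    spurious <- 0L; removedN <- 0L
    for (seed in 1:40) {
        sim <- simulateVAR(makeMotif("chain", T = 300, seed = seed))
        scan <- addQValues(gcScan(sim$table, selection = "fixed", p = 1),
                           pi0Method = "bh")
        g <- suppressWarnings(buildGraph(scan, vertices = sim$table))
        e <- gcEdges(g)
        if (!any(e$source == "Y" & e$target == "X")) next
        spurious <- spurious + 1L
        pg <- pruneGraph(g, sim$table)
        pe <- gcEdges(pg)
        removed <- !any(pe$source == "Y" & pe$target == "X")
        removedN <- removedN + removed
        expect_true(any(pe$source == "Y" & pe$target == "Z"))
        expect_true(any(pe$source == "Z" & pe$target == "X"))
        if (removed) {
            log <- prunedEdges(pg)
            expect_true(any(log$source == "Y" & log$target == "X" &
                            log$verdict == "indirect"))
        }
        pg2 <- pruneGraph(pg, sim$table)
        expect_equal(gcEdges(pg2), gcEdges(pg))
    }
    expect_gte(spurious, 3L)
    expect_gt(removedN / spurious, 0.5)
})

test_that("graph/table variable mismatch is an error", {
    sim <- simulateVAR(makeMotif("pair", T = 120, seed = 72))
    scan <- addQValues(gcScan(sim$table, selection = "fixed", p = 1),
                       pi0Method = "bh")
    g <- suppressWarnings(buildGraph(scan, vertices = sim$table))
    other <- simulateVAR(makeMotif("chain", T = 120, seed = 1))$table
    expect_error(pruneGraph(g, other[c("Y", "Z"), ]), "missing")
})

test_that("BH-mode edge selection matches p.adjust selection", {
    tab <- nullTable(6, 80, seed = 73)
    scan <- gcScan(tab, selection = "fixed", p = 1)
    scan <- addQValues(scan, pi0Method = "bh")
    g <- suppressWarnings(buildGraph(scan, qThreshold = 0.05))
    manual <- stats::p.adjust(scan$p_value, "BH") < 0.05
    expect_equal(nrow(gcEdges(g)), sum(manual))
})

test_that("the FDR family covers every ordered pair", {
    tab <- nullTable(5, 70, seed = 74)
    scan <- addQValues(gcScan(tab, selection = "fixed", p = 1),
                       pi0Method = "bh")
    g <- suppressWarnings(buildGraph(scan, vertices = tab))
    nOk <- sum(scan$status == "ok")
    nDeg <- sum(scan$status == "degenerate")
    nSig <- nrow(gcEdges(g))
    expect_equal(nOk + nDeg, 5 * 4)
    expect_equal(nSig + sum(scan$status == "ok" & scan$q_value >= 0.05) +
                 nDeg, 5 * 4)
})

test_that("the end-to-end wrapper threads its pieces together", {
    sim <- simulateVAR(makeMotif("pair", T = 300, seed = 75))
    net <- suppressWarnings(grangerNetwork(sim$table, selection = "fixed",
                                           p = 1, pi0Method = "bh"))
    expect_s4_class(net$graph, "CausalityGraph")
    e <- gcEdges(net$graph)
    expect_true(any(e$source == "X1" & e$target == "X2"))
    expect_equal(nrow(net$scan), 2L)
    expect_true(net$pi0 > 0 && net$pi0 <= 1)
})
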