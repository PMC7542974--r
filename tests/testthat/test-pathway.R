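chain3 <- function() PathwayGraph("chain", nodes = c("A", "B", "C"),
  edges = data.frame(from = c("A", "B"), to = c("B", "C"),
                     reversible = FALSE))

test_that("degree centralities count directed connections", {
  g <- chain3()
  expect_equal(nodeCentrality(g, "out_degree"), c(A = 1, B = 1, C = 0))
  expect_equal(nodeCentrality(g, "in_degree"), c(A = 0, B = 1, C = 1))
  expect_equal(nodeCentrality(g, "total_degree"), c(A = 1, B = 2, C = 1))
})

test_that("relative betweenness and eigenvector behave on canonical graphs", {
  g <- chain3()
  b <- nodeCentrality(g, "relative_betweenness")
  expect_equal(b, c(A = 0, B = 1, C = 0))  # (n-1)(n-2)/2 = 1
  star <- PathwayGraph("star", nodes = c("H", "L1", "L2", "L3", "L4"),
    edges = data.frame(from = "H", to = c("L1", "L2", "L3", "L4"),
                       reversible = FALSE))
  ev <- nodeCentrality(star, "eigenvector")
  expect_equal(unname(ev["H"]), 1)
  expect_true(all(ev[paste0("L", 1:4)] < 1))
  expect_equal(length(unique(round(ev[paste0("L", 1:4)], 12))), 1L)
})

test_that("closeness uses reachable nodes only and zeros isolated ones", {
  g <- PathwayGraph("p", nodes = c("A", "B", "X"),
    edges = data.frame(from = "A", to = "B", reversible = FALSE))
  oc <- nodeCentrality(g, "out_closeness")
  expect_equal(oc, c(A = 1, B = 0, X = 0))
  ic <- nodeCentrality(g, "in_closeness")
  expect_equal(ic, c(A = 0, B = 1, X = 0))
})

test_that("all seven centralities match brute-force oracles on the graph battery", {
  battery <- centrality_battery()
  for (nm in names(battery)) {
    g <- battery[[nm]]
    expect_equal(nodeCentrality(g, "out_degree"), oracle_degree(g, "out"),
                 tolerance = 1e-10, info = nm)
    expect_equal(nodeCentrality(g, "in_degree"), oracle_degree(g, "in"),
                 tolerance = 1e-10, info = nm)
    expect_equal(nodeCentrality(g, "total_degree"), oracle_degree(g, "all"),
                 tolerance = 1e-10, info = nm)
    expect_equal(nodeCentrality(g, "relative_betweenness"),
                 oracle_betweenness_relative(g), tolerance = 1e-10, info = nm)
    expect_equal(nodeCentrality(g, "out_closeness"),
                 oracle_closeness(g, "out"), tolerance = 1e-10, info = nm)
    expect_equal(nodeCentrality(g, "in_closeness"),
                 oracle_closeness(g, "in"), tolerance = 1e-10, info = nm)
    expect_equal(nodeCentrality(g, "total_closeness"),
                 oracle_closeness(g, "all"), tolerance = 1e-10, info = nm)
    expect_equal(nodeCentrality(g, "eigenvector"), oracle_eigenvector(g),
                 tolerance = 1e-9, info = nm)
  }
})

test_that("making every edge reversible equalizes in- and out-degree", {
  set.seed(61)
  pl <- simulatePathwayLibrary(3, c(5, 9), seed = 61)
  for (p in pl$library@pathways) {
    e <- p@edges; e$reversible <- TRUE
    rev_g <- PathwayGraph(p@pathway_id, nodes = p@nodes, edges = e)
    expect_equal(nodeCentrality(rev_g, "in_degree"),
                 nodeCentrality(rev_g, "out_degree"))
  }
})

test_that("hypergeometric enrichment matches exact combinatorial sums", {
  lib <- PathwayLibrary("synthetic", list(
    PathwayGraph("P1", nodes = sprintf("C%02d", 1:5)),
    PathwayGraph("P2", nodes = sprintf("C%02d", 6:20))))
  # universe 20, pathway 5, draws 10, overlap 4
  hits <- c(sprintf("C%02d", 1:4), sprintf("C%02d", 11:16))
  res <- enrichPathways(hits, lib)
  p1 <- res$enrichment_p[res$pathway_id == "P1"]
  expect_equal(p1, oracle_hyper_upper(4, 5, 20, 10), tolerance = 1e-12)
  # hand value: [C(5,4)C(15,6) + C(5,5)C(15,5)] / C(20,10)
  hand <- (choose(5, 4) * choose(15, 6) + choose(5, 5) * choose(15, 5)) /
    choose(20, 10)
  expect_equal(p1, hand, tolerance = 1e-12)
  # zero overlap -> p = 1
  res0 <- enrichPathways(sprintf("C%02d", 6:10), lib)
  expect_equal(res0$enrichment_p[res0$pathway_id == "P1"], 1.0)
  # hits = pathway = universe -> p = 1
  uni_lib <- PathwayLibrary("s", list(PathwayGraph("P", nodes = c("a", "b"))))
  expect_equal(enrichPathways(c("a", "b"), uni_lib)$enrichment_p, 1.0)
  expect_error(enrichPathways("zzz", lib), "map")
})

test_that("hypergeometric masses sum to one over the support", {
  for (case in list(c(20, 5, 10), c(30, 12, 7), c(9, 3, 4))) {
    N <- case[1]; K <- case[2]; n <- case[3]
    ks <- max(0, n + K - N):min(K, n)
    total <- sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
    expect_equal(total, 1, tolerance = 1e-12)
    # and the implementation's tail at the minimum support value is 1
    expect_equal(stats::phyper(min(ks) - 1, K, N - K, n, lower.tail = FALSE),
                 1, tolerance = 1e-12)
  }
})

test_that("impact is the hit-centrality share with documented edge cases", {
  g <- chain3()
  expect_equal(pathwayImpact(character(0), g, "relative_betweenness"), 0)
  expect_equal(pathwayImpact(c("A", "B", "C"), g, "eigenvector"), 1)
  # B carries all betweenness on a path
  expect_equal(pathwayImpact("B", g, "relative_betweenness"), 1)
  expect_equal(pathwayImpact("A", g, "relative_betweenness"), 0)
  # edgeless graph: hit fraction with a warning
  bare <- PathwayGraph("bare", nodes = c("A", "B"))
  expect_warning(i <- pathwayImpact("A", bare), "zero total centrality")
  expect_equal(i, 0.5)
})

test_that("impact is monotone in the hit set", {
  set.seed(91)
  pl <- simulatePathwayLibrary(2, c(6, 10), seed = 91)
  g <- pl$library@pathways[[1]]
  hits <- character(0)
  last <- 0
  for (node in sample(g@nodes)) {
    hits <- c(hits, node)
    cur <- pathwayImpact(hits, g, "eigenvector")
    expect_gte(cur, last - 1e-12)
    last <- cur
  }
})

test_that("switching the topology algorithm never touches enrichment p", {
  pl <- simulatePathwayLibrary(6, c(5, 10), seed = 17)
  set.seed(17)
  hits <- sample(pathwayUniverse(pl$library), 10)
  a <- pathwayAnalysis(hits, pl$library, "eigenvector")
  b <- pathwayAnalysis(hits, pl$library, "relative_betweenness")
  expect_identical(a$enrichment_p, b$enrichment_p)
  expect_false(isTRUE(all.equal(a$impact, b$impact)))
  # single-pathway library: q = p
  solo <- PathwayLibrary("s", pl$library@pathways[1])
  r1 <- pathwayAnalysis(intersect(hits, pl$library@pathways[[1]]@nodes), solo)
  expect_equal(r1$enrichment_q, r1$enrichment_p)
  expect_error(pathwayAnalysis(character(0), pl$library), "empty")
})

test_that("pathway libraries round-trip through the text format", {
  pl <- simulatePathwayLibrary(4, c(4, 8), seed = 23)
  f <- withr::local_tempfile(fileext = ".txt")
  writePathwayLibrary(pl$library, f)
  back <- readPathwayLibrary(f, "synthetic")
  expect_equal(length(back@pathways), 4L)
  for (i in 1:4) {
    expect_equal(back@pathways[[i]]@nodes, pl$library@pathways[[i]]@nodes)
    expect_equal(back@pathways[[i]]@edges$from,
                 pl$library@pathways[[i]]@edges$from)
    expect_equal(back@pathways[[i]]@edges$reversible,
                 pl$library@pathways[[i]]@edges$reversible)
  }
  expect_equal(pathwayUniverse(back), pathwayUniverse(pl$library))
})
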