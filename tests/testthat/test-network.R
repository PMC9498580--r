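twoTriangles <- function() {
  InteractionGraph(data.frame(
    from = c("A", "B", "C", "D", "E", "F"),
    to = c("B", "C", "A", "E", "F", "D"),
    confidence = 0.9, stringsAsFactors = FALSE))
}

test_that("MCL resolves toy graphs deterministically", {
  p <- mcl(twoTriangles())
  expect_identical(nClusters(p), 2L)
  m <- clusterMembership(p)
  expect_identical(unname(m["A"]), unname(m["B"]))
  expect_identical(unname(m["A"]), unname(m["C"]))
  expect_false(m["A"] == m["D"])
  expect_true(converged(p))

  single <- InteractionGraph(data.frame(from = "A", to = "B",
                                        confidence = 0.5))
  ps <- mcl(single)
  expect_identical(nClusters(ps), 1L)
  expect_length(clusterMembership(ps), 2L)

  ## parameter validation
  expect_error(mcl(single, inflation = 1), "inflation")
  expect_error(mcl(single, expansion = 1), "expansion")
  expect_error(mcl(InteractionGraph(NULL)), "empty")
})

test_that("MCL partitions are exhaustive, disjoint and respect components", {
  sg <- simulateGraph(3, 8, 0.8, 0.1, seed = 42)
  p <- mcl(sg$graph)
  m <- clusterMembership(p)
  expect_setequal(names(m), graphNodes(sg$graph))
  expect_setequal(unique(m), seq_len(nClusters(p)))
  ## nodes in different connected components never share a cluster
  comp <- igraph::components(asIgraph(sg$graph))$membership
  tab <- table(m, comp[names(m)])
  expect_true(all(rowSums(tab > 0) == 1L))
})

test_that("MCL recovers a planted 3-block partition (ARI >= 0.9)", {
  sg <- simulateGraph(3, 10, 0.9, 0.05, seed = 7)
  p <- mcl(sg$graph, inflation = 2.0)
  ari <- mclust::adjustedRandIndex(clusterMembership(p)[names(sg$truth)],
                                   sg$truth)
  expect_gte(ari, 0.9)
})

test_that("raising inflation does not coarsen the fixture partitions", {
  sg <- simulateGraph(3, 8, 0.8, 0.08, seed = 19)
  ks <- vapply(c(1.5, 2.0, 3.0, 5.0), function(infl)
    nClusters(mcl(sg$graph, inflation = infl)), integer(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("patient subnetworks keep threshold edges and singleton genes", {
  g <- tgaStudyNetwork()
  sub <- patientSubnetwork(g, c("DNAH9", "HYDIN"), minConfidence = 0.4)
  expect_equal(nrow(edgeTable(sub)), 1L)
  expect_equal(edgeTable(sub)$confidence, 0.9)

  sub2 <- patientSubnetwork(g, c("DNAI1", "SPAG17"), minConfidence = 0.7)
  expect_equal(nrow(edgeTable(sub2)), 1L)

  ## the weak OFD1-DNAH11 tie survives only at the lowest tier
  expect_equal(nrow(edgeTable(
    patientSubnetwork(g, c("OFD1", "DNAH11"), 0.15))), 1L)
  expect_equal(nrow(edgeTable(
    patientSubnetwork(g, c("OFD1", "DNAH11"), 0.4))), 0L)

  ## genes absent from the background graph appear as singletons
  sub3 <- patientSubnetwork(g, c("DNAH9", "NOSUCHGENE"), 0.4)
  expect_setequal(graphNodes(sub3), c("DNAH9", "NOSUCHGENE"))
  expect_equal(nrow(edgeTable(sub3)), 0L)

  expect_identical(graphNodes(patientSubnetwork(g, character(0))),
                   character(0))
})

test_that("degree-preserving null keeps every vertex degree", {
  sg <- simulateGraph(2, 10, 0.6, 0.2, seed = 5)
  g <- asIgraph(sg$graph)
  deg <- igraph::degree(g)
  set.seed(1)
  for (b in 1:25) {
    null <- VariantTriage:::.degreePreservingNull(g)
    expect_identical(igraph::degree(null), deg)
    expect_identical(igraph::ecount(null), igraph::ecount(g))
  }
})

test_that("interaction enrichment flags planted cliques and is seeded", {
  ## planted clique of 6 in a sparse 60-node background
  set.seed(33)
  n <- 60
  pairs <- utils::combn(n, 2)
  present <- runif(ncol(pairs)) < 0.04
  nodes <- sprintf("N%02d", 1:n)
  edges <- data.frame(from = nodes[pairs[1, present]],
                      to = nodes[pairs[2, present]],
                      confidence = 0.5, stringsAsFactors = FALSE)
  clique <- t(utils::combn(nodes[1:6], 2))
  edges <- rbind(edges, data.frame(from = clique[, 1], to = clique[, 2],
                                   confidence = 0.9))
  g <- InteractionGraph(edges, nodes = nodes)
  enr <- interactionEnrichment(g, nodes[1:6], nPermutations = 1000,
                               seed = 99)
  expect_lte(pValue(enr), 0.01)
  expect_identical(observedEdges(enr), 15L)

  ## identical seed, identical result
  enr2 <- interactionEnrichment(g, nodes[1:6], nPermutations = 1000,
                                seed = 99)
  expect_identical(pValue(enr2), pValue(enr))
  expect_identical(enr2@nullMean, enr@nullMean)

  ## a set with no internal edges can never be enriched
  empty <- interactionEnrichment(g, c(nodes[7], nodes[50]),
                                 nPermutations = 100, seed = 1)
  expect_identical(pValue(empty), 1)

  expect_error(interactionEnrichment(g, nodes[1], seed = 1), "at least 2")
  expect_error(interactionEnrichment(g, c("X", "Y"), seed = 1),
               "not in graph")
  expect_gte(pValue(enr), 1 / 1001)
})

test_that("simulated graphs honour their planted structure", {
  ## no between-block edges -> components are exactly the blocks
  sg <- simulateGraph(3, 6, 0.9, 0, seed = 3)
  comp <- igraph::components(asIgraph(sg$graph))$membership
  expect_equal(length(unique(comp)), 3L)
  tab <- table(comp[names(sg$truth)], sg$truth)
  expect_true(all(rowSums(tab > 0) == 1L))

  ## no structure -> recovery near chance
  sg0 <- simulateGraph(3, 10, 0.25, 0.25, seed = 13)
  p0 <- mcl(sg0$graph)
  ari0 <- mclust::adjustedRandIndex(
    clusterMembership(p0)[names(sg0$truth)], sg0$truth)
  expect_lt(abs(ari0), 0.2)
})
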