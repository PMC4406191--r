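## a -> b -> c chain used by several examples
chain <- makeGraph(c("a", "b", "c"),
                   rbind(edgeRow("a", "b"), edgeRow("b", "c")))

test_that("merge is idempotent and unions by id", {
  g <- chain
  expect_true(graphIdentical(mergeNetworks(list(g, g)), g))
  g2 <- makeGraph(c("x", "y", "z"), rbind(edgeRow("x", "y")))
  m <- mergeNetworks(list(g, g2))
  expect_identical(nrow(graphNodes(m)), 6L)
  expect_identical(nrow(graphEdges(m)), 3L)
  ## sharing one node: |V1| + |V2| - 1
  g3 <- makeGraph(c("c", "d"), rbind(edgeRow("c", "d")))
  expect_identical(nrow(graphNodes(mergeNetworks(list(g, g3)))), 4L)
  ## conflicting classes for one id
  g4 <- makeGraph("a", classes = "SmallMolecule")
  expect_error(mergeNetworks(list(g, g4)), class = "conflictError")
  expect_error(mergeNetworks(list()), class = "preconditionError")
})

test_that("merge is associative and commutative up to graph equality", {
  gs <- lapply(c(101, 102, 103), function(s) randomDigraph(8, s))
  m1 <- mergeNetworks(list(mergeNetworks(gs[1:2]), gs[[3]]))
  m2 <- mergeNetworks(list(gs[[1]], mergeNetworks(gs[2:3])))
  m3 <- mergeNetworks(rev(gs))
  expect_true(graphIdentical(m1, m2))
  expect_true(graphIdentical(m1, m3))
})

test_that("neighborhood respects direction and hop limit", {
  expect_setequal(nodeIds(queryNeighborhood(chain, "b", "both")),
                  c("a", "b", "c"))
  expect_setequal(nodeIds(queryNeighborhood(chain, "b", "downstream")),
                  c("b", "c"))
  expect_setequal(nodeIds(queryNeighborhood(chain, "b", "upstream")),
                  c("a", "b"))
  whole <- queryNeighborhood(chain, c("a", "b", "c"))
  expect_true(graphIdentical(whole, chain))
  expect_error(queryNeighborhood(chain, "nope"), class = "missingNodeError")
})

test_that("common stream finds the reachability intersection", {
  ## diamond: s1 -> x, s2 -> x, x -> y
  dia <- makeGraph(c("s1", "s2", "x", "y"),
                   rbind(edgeRow("s1", "x"), edgeRow("s2", "x"),
                         edgeRow("x", "y")))
  core <- queryCommonStream(dia, c("s1", "s2"), "downstream",
                            includePaths = FALSE)
  expect_setequal(nodeIds(core), c("x", "y"))
  withPaths <- queryCommonStream(dia, c("s1", "s2"), "downstream")
  expect_setequal(nodeIds(withPaths), c("s1", "s2", "x", "y"))
  ## disjoint reach: empty result
  two <- makeGraph(c("p", "q", "r", "s"),
                   rbind(edgeRow("p", "q"), edgeRow("r", "s")))
  expect_identical(nrow(graphNodes(queryCommonStream(two, c("p", "r")))), 0L)
  ## upstream variant on the reversed diamond mirrors the downstream case
  rev_ <- makeGraph(c("s1", "s2", "x", "y"),
                    rbind(edgeRow("x", "s1"), edgeRow("x", "s2"),
                          edgeRow("y", "x")))
  up <- queryCommonStream(rev_, c("s1", "s2"), "upstream",
                          includePaths = FALSE)
  expect_setequal(nodeIds(up), c("x", "y"))
  expect_error(queryCommonStream(dia, "s1"), class = "preconditionError")
})

test_that("paths between seeds honour the length limit", {
  g <- makeGraph(c("a", "m", "b"),
                 rbind(edgeRow("a", "m"), edgeRow("m", "b")))
  r2 <- queryPathsBetween(g, c("a", "b"), limit = 2)
  expect_setequal(nodeIds(r2), c("a", "m", "b"))
  expect_identical(nrow(graphEdges(r2)), 2L)
  r1 <- queryPathsBetween(g, c("a", "b"), limit = 1)
  expect_identical(nrow(graphNodes(r1)), 0L)
  ## adjacent both ways: both edges included
  ab <- makeGraph(c("a", "b"), rbind(edgeRow("a", "b"), edgeRow("b", "a")))
  rb <- queryPathsBetween(ab, c("a", "b"), limit = 1)
  expect_identical(nrow(graphEdges(rb)), 2L)
})

test_that("paths from-to is directed and validates its inputs", {
  g <- makeGraph(c("a", "m", "b"),
                 rbind(edgeRow("a", "m"), edgeRow("m", "b")))
  fwd <- queryPathsFromTo(g, "a", "b", limit = 2)
  expect_setequal(nodeIds(fwd), c("a", "m", "b"))
  expect_identical(nrow(graphNodes(queryPathsFromTo(g, "b", "a", limit = 2))),
                   0L)
  ## source with no outgoing edges
  expect_identical(nrow(graphNodes(queryPathsFromTo(g, "b", "m", limit = 3))),
                   0L)
  expect_error(queryPathsFromTo(g, c("a", "b"), c("b", "m")),
               class = "preconditionError")
  expect_error(queryPathsFromTo(g, character(), "b"),
               class = "preconditionError")
})

test_that("queries agree with independent igraph oracles on random graphs", {
  skip_if_not_installed("igraph")
  for (seed in 1:12) {
    g <- randomDigraph(sample(6:16, 1, prob = rep(1, 11)), seed = 1000 + seed)
    ids <- nodeIds(g)
    set.seed(seed)
    seeds <- sample(ids, 2)
    for (dir in c("both", "upstream", "downstream")) {
      lim <- sample(1:3, 1)
      got <- queryNeighborhood(g, seeds, dir, limit = lim)
      expect_setequal(nodeIds(got),
                      oracleNeighborhoodIds(g, seeds, dir, lim))
    }
    for (dir in c("downstream", "upstream")) {
      common <- Reduce(intersect,
                       lapply(seeds, function(s) oracleReach(g, s, dir)))
      got <- queryCommonStream(g, seeds, dir, includePaths = FALSE)
      expect_setequal(nodeIds(got), common)
    }
    lim <- sample(2:3, 1)
    exp_ <- oraclePathSubgraph(g, c(
      oraclePaths(g, seeds[1], seeds[2], lim),
      oraclePaths(g, seeds[2], seeds[1], lim)))
    got <- queryPathsBetween(g, seeds, limit = lim)
    expect_setequal(nodeIds(got), exp_$ids)
    expect_identical(edgeKeys(got),
                     edgeKeys(.subgraphFromEdges(g, exp_$ids, exp_$edgeIdx)))
  }
})

test_that("query results are subgraphs and grow with the limit", {
  g <- randomDigraph(14, seed = 77)
  ids <- nodeIds(g)
  seeds <- ids[1:2]
  prevN <- -1L
  for (lim in 1:4) {
    r <- queryNeighborhood(g, seeds, "both", limit = lim)
    expect_true(all(nodeIds(r) %in% ids))
    expect_true(all(edgeKeys(r) %in% edgeKeys(g)))
    expect_gte(nrow(graphNodes(r)), prevN)
    prevN <- nrow(graphNodes(r))
  }
  prevN <- -1L
  for (lim in 1:4) {
    r <- queryPathsBetween(g, seeds, limit = lim)
    expect_true(all(nodeIds(r) %in% ids))
    expect_true(all(edgeKeys(r) %in% edgeKeys(g)))
    expect_gte(nrow(graphNodes(r)), prevN)
    prevN <- nrow(graphNodes(r))
  }
})
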