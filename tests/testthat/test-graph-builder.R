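toys <- toyDocuments()

test_that("a complex yields one component edge per member", {
  m <- biopaxModel(list(
    biopaxElement("urn:t:cx", "Complex",
                  refs = list(component = c("urn:t:p1", "urn:t:p2", "urn:t:p3"))),
    biopaxElement("urn:t:p1", "Protein"),
    biopaxElement("urn:t:p2", "Protein"),
    biopaxElement("urn:t:p3", "Protein")))
  g <- buildGraph(m)
  expect_identical(nrow(graphNodes(g)), 4L)
  ed <- graphEdges(g)
  expect_identical(nrow(ed), 3L)
  expect_true(all(ed$kind == "complex-component"))
  expect_true(all(ed$directed))
  cs <- classSets(g)$BioPAX
  expect_identical(lengths(cs@classes), c(Complex = 1L, Protein = 3L))
})

test_that("pathway with two reactions gives 7 nodes and 6 edges", {
  mk <- function(r, l, rgt) biopaxElement(r, "BiochemicalReaction",
                                          refs = list(left = l, right = rgt))
  m <- biopaxModel(c(
    list(biopaxElement("urn:t:pw", "Pathway",
                       refs = list(pathwayComponent = c("urn:t:r1", "urn:t:r2"))),
         mk("urn:t:r1", "urn:t:a", "urn:t:b"),
         mk("urn:t:r2", "urn:t:c", "urn:t:d")),
    lapply(c("urn:t:a", "urn:t:b", "urn:t:c", "urn:t:d"),
           biopaxElement, biopaxType = "Protein")))
  g <- buildGraph(m)
  expect_identical(nrow(graphNodes(g)), 7L)
  ed <- graphEdges(g)
  expect_identical(nrow(ed), 6L)
  expect_identical(sum(ed$kind == "pathway-component"), 2L)
  expect_identical(sum(ed$kind == "participant-left"), 2L)
  expect_identical(sum(ed$kind == "participant-right"), 2L)
  ## conversion orientation: left -> reaction -> right
  expect_true(all(ed$target[ed$kind == "participant-left"] %in% c("r1", "r2")))
  expect_true(all(ed$source[ed$kind == "participant-right"] %in% c("r1", "r2")))
})

test_that("empty and non-Level-3 models are handled", {
  expect_identical(nrow(graphNodes(buildGraph(biopaxModel()))), 0L)
  raw <- readBiopax(toys[["toy_l2"]], upgrade = FALSE)
  expect_error(buildGraph(raw), class = "levelPreconditionError")
})

test_that("entity references decorate but never become nodes", {
  m <- readBiopax(toys[["toy_l3"]])
  g <- buildGraph(m)
  expect_identical(nrow(graphNodes(g)), 8L)   # 11 elements - 3 ProteinReferences
  expect_false(any(graphNodes(g)$biopaxClass == "ProteinReference"))
})

test_that("control interactions orient controller -> control -> controlled", {
  g <- buildGraph(readBiopax(toys[["diamond"]]))
  ed <- graphEdges(g)
  expect_identical(ed[ed$kind == "controller", "source"], "C")
  expect_identical(ed[ed$kind == "controller", "target"], "cat1")
  expect_identical(ed[ed$kind == "controlled", "source"], "cat1")
  expect_identical(ed[ed$kind == "controlled", "target"], "r3")
})

test_that("pathway steps link the processes of consecutive steps", {
  m <- biopaxModel(list(
    biopaxElement("urn:t:pw", "Pathway",
                  refs = list(pathwayComponent = c("urn:t:r1", "urn:t:r2"),
                              pathwayOrder = c("urn:t:s1", "urn:t:s2"))),
    biopaxElement("urn:t:s1", "PathwayStep",
                  refs = list(stepProcess = "urn:t:r1",
                              nextStep = "urn:t:s2")),
    biopaxElement("urn:t:s2", "PathwayStep",
                  refs = list(stepProcess = "urn:t:r2")),
    biopaxElement("urn:t:r1", "BiochemicalReaction"),
    biopaxElement("urn:t:r2", "BiochemicalReaction")))
  g <- buildGraph(m)
  ## steps contribute edges only, not nodes
  expect_identical(nrow(graphNodes(g)), 3L)
  st <- graphEdges(g)[graphEdges(g)$kind == "pathway-step", ]
  expect_identical(nrow(st), 1L)
  expect_identical(st$source, "r1")
  expect_identical(st$target, "r2")
})

test_that("member edges and duplicate left/right participation", {
  m <- biopaxModel(list(
    biopaxElement("urn:t:fam", "Protein",
                  refs = list(memberPhysicalEntity = "urn:t:p1")),
    biopaxElement("urn:t:p1", "Protein"),
    biopaxElement("urn:t:rx", "BiochemicalReaction",
                  refs = list(left = "urn:t:p1", right = "urn:t:p1"))))
  ed <- graphEdges(buildGraph(m))
  expect_identical(sum(ed$kind == "member"), 1L)
  ## same entity on both sides: two edges of different kinds
  expect_identical(sum(ed$kind == "participant-left"), 1L)
  expect_identical(sum(ed$kind == "participant-right"), 1L)
})

test_that("node ids deduplicate URI fragment collisions", {
  m <- biopaxModel(list(
    biopaxElement("http://a.org/x#p1", "Protein"),
    biopaxElement("http://b.org/y#p1", "Protein")))
  ids <- graphNodes(buildGraph(m))$id
  expect_setequal(ids, c("p1", "p1.2"))
})

test_that("graph construction is deterministic", {
  gm <- generateModel(generatorSpec(nPathways = 2, nReactions = 8,
                                    nProteins = 10, nSmallMolecules = 3,
                                    nComplexes = 2, seed = 13))
  g1 <- buildGraph(gm$model)
  g2 <- buildGraph(gm$model)
  expect_identical(graphNodes(g1), graphNodes(g2))
  expect_identical(graphEdges(g1), graphEdges(g2))
})

test_that("class set is a true partition by concrete type", {
  g <- buildGraph(readBiopax(toys[["diamond"]]))
  cs <- buildClassSet(g)
  ids <- unlist(cs@classes, use.names = FALSE)
  expect_setequal(ids, nodeIds(g))
  expect_identical(anyDuplicated(ids), 0L)
  ## Catalysis is classed as Catalysis, not merged under Control/Interaction
  expect_identical(cs@classes$Catalysis, "cat1")
  nd <- graphNodes(g)
  for (cl in names(cs@classes))
    expect_true(all(nd$biopaxClass[match(cs@classes[[cl]], nd$id)] == cl))
})

test_that("interaction counting recurses through sub-pathways", {
  m <- readBiopax(toys[["nested"]])
  expect_identical(countInteractions(m, "http://example.org/nested#P"), 3L)
  expect_identical(countInteractions(m, "http://example.org/nested#Q"), 2L)
  flat <- readBiopax(toys[["toy_l3"]])
  expect_identical(countInteractions(flat, "http://example.org/toy#pw1"), 2L)
  mEmpty <- biopaxModel(list(biopaxElement("urn:t:pw", "Pathway")))
  expect_identical(countInteractions(mEmpty, "urn:t:pw"), 0L)
  expect_error(countInteractions(flat, "http://example.org/toy#p1"),
               class = "typeError")
})
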