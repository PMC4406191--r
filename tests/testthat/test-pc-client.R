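BASE <- "http://www.pathwaycommons.org/pc2"

test_that("request construction is a pure function of the query", {
  cases <- list(
    list(searchQuery("interferon AND signaling", biopaxType = "Pathway"),
         paste0(BASE, "/search?q=interferon%20AND%20signaling&page=0&type=pathway")),
    list(searchQuery("p53 OR apoptosis", biopaxType = "Interaction", page = 2),
         paste0(BASE, "/search?q=p53%20OR%20apoptosis&page=2&type=interaction")),
    list(searchQuery("kinase*"),
         paste0(BASE, "/search?q=kinase%2A&page=0")),
    list(searchQuery("tp53", nameOnly = TRUE),
         paste0(BASE, "/search?q=name%3A%28tp53%29&page=0")),
    list(searchQuery("interferon signaling", nameOnly = TRUE,
                     biopaxType = "Pathway"),
         paste0(BASE, "/search?q=name%3A%28interferon%20signaling%29&page=0&type=pathway")),
    list(searchQuery("insulin", organisms = "9606"),
         paste0(BASE, "/search?q=insulin&page=0&organism=9606")),
    list(searchQuery("insulin", organisms = c("9606", "10090")),
         paste0(BASE, "/search?q=insulin&page=0&organism=9606&organism=10090")),
    list(searchQuery("glycolysis", datasources = "reactome"),
         paste0(BASE, "/search?q=glycolysis&page=0&datasource=reactome")),
    list(searchQuery("glycolysis", organisms = "9606",
                     datasources = c("reactome", "humancyc"),
                     biopaxType = "Pathway"),
         paste0(BASE, "/search?q=glycolysis&page=0&type=pathway&organism=9606",
                "&datasource=reactome&datasource=humancyc")),
    list(searchQuery("uniprot:P04637", biopaxType = "EntityReference"),
         paste0(BASE, "/search?q=uniprot%3AP04637&page=0&type=entityreference")),
    list(searchQuery("signal*", biopaxType = "TopPathways"),
         paste0(BASE, "/top_pathways?q=signal%2A&page=0")),
    list(searchQuery("wnt", biopaxType = "TopPathways", organisms = "9606"),
         paste0(BASE, "/top_pathways?q=wnt&page=0&organism=9606"))
  )
  for (cs in cases)
    expect_identical(searchRequestUrl(cs[[1]]), cs[[2]])
  ## repeat runs are byte-identical
  q <- cases[[9]][[1]]
  expect_identical(searchRequestUrl(q), searchRequestUrl(q))
  expect_error(searchQuery("x", biopaxType = "Gene"),
               class = "preconditionError")
  expect_error(searchQuery("x", page = -1), class = "preconditionError")
})

test_that("search parses hits, including the empty page", {
  hits <- list(
    list(uri = "urn:pc:pw1", name = "Pathway one", organism = "9606",
         dataSource = "reactome", excerpt = "alpha <b>beta</b>",
         numInteractions = "12"),
    list(uri = "urn:pc:pw2", name = "Pathway two", organism = "10090",
         dataSource = "panther", excerpt = "gamma", numInteractions = "3"),
    list(uri = "urn:pc:er1", name = "Some protein", organism = "9606",
         dataSource = "uniprot", excerpt = "delta"))
  q <- searchQuery("alpha", biopaxType = "Pathway")
  tp <- mockTransport(stats::setNames(
    list(searchResponseXml(hits, total = 3)), searchRequestUrl(q)))
  page <- pcSearch(q, tp)
  h <- searchHits(page)
  expect_identical(nrow(h), 3L)
  expect_identical(h$uri, c("urn:pc:pw1", "urn:pc:pw2", "urn:pc:er1"))
  expect_identical(h$numInteractions, c(12L, 3L, NA_integer_))
  expect_identical(page@totalHits, 3L)

  qe <- searchQuery("nothing")
  tpe <- mockTransport(stats::setNames(
    list(searchResponseXml(list(), total = 0)), searchRequestUrl(qe)))
  pe <- pcSearch(qe, tpe)
  expect_identical(nrow(searchHits(pe)), 0L)
  expect_identical(pe@totalHits, 0L)
})

test_that("TopPathways dispatches to the dedicated endpoint", {
  q <- searchQuery("signal*", biopaxType = "TopPathways")
  tp <- mockTransport(stats::setNames(
    list(searchResponseXml(list(), total = 0)), searchRequestUrl(q)))
  pcSearch(q, tp)
  expect_match(transportCalls(tp), "/top_pathways\\?", all = TRUE)
})

test_that("pagination issues ceiling(total / pageSize) requests", {
  for (total in c(1L, 499L, 500L, 501L, 1200L, 2500L)) {
    q <- searchQuery("x")
    nPages <- max(1L, as.integer(ceiling(total / 500)))
    routes <- list()
    for (p in seq_len(nPages) - 1L) {
      qp <- q; qp$page <- p
      routes[[searchRequestUrl(qp)]] <-
        searchResponseXml(list(list(uri = sprintf("urn:pc:%d", p))),
                          total = total)
    }
    tp <- mockTransport(routes)
    pages <- pcSearchPages(q, tp)
    expect_length(pages, nPages)
    expect_length(transportCalls(tp), nPages)
  }
})

test_that("fetchOwl returns BioPAX payloads and rejects others", {
  toy <- paste(readLines(toyDocuments()[["toy_l3"]]), collapse = "\n")
  cfg <- pcConfig()
  url <- sprintf("%s/get?uri=%s", cfg$baseUrl,
                 utils::URLencode("urn:pc:toy", reserved = TRUE))
  tp <- mockTransport(stats::setNames(list(toy), url))
  owl <- fetchOwl("urn:pc:toy", tp)
  expect_identical(length(readBiopax(owl)), 11L)
  ## 404 and non-OWL payloads
  expect_error(fetchOwl("urn:pc:absent", mockTransport()),
               class = "pcNotFoundError")
  urlH <- sprintf("%s/get?uri=%s", cfg$baseUrl,
                  utils::URLencode("urn:pc:html", reserved = TRUE))
  tpH <- mockTransport(stats::setNames(
    list("<html><body>error</body></html>"), urlH))
  expect_error(fetchOwl("urn:pc:html", tpH), class = "pcContentError")
  expect_error(fetchOwl("", tp), class = "preconditionError")
})

test_that("traverse-based interaction counting counts returned values", {
  cfg <- pcConfig()
  mk <- function(uri, body) {
    u <- sprintf("%s/traverse?uri=%s&path=%s", cfg$baseUrl,
                 utils::URLencode(uri, reserved = TRUE),
                 utils::URLencode("Pathway/pathwayComponent*:Interaction",
                                  reserved = TRUE))
    mockTransport(stats::setNames(list(body), u))
  }
  expect_identical(
    pcCountPathwayInteractions("urn:pc:pw",
      mk("urn:pc:pw", traverseResponseXml(sprintf("urn:pc:i%d", 1:5)))), 5L)
  expect_identical(
    pcCountPathwayInteractions("urn:pc:pw",
      mk("urn:pc:pw", traverseResponseXml(character()))), 0L)
  expect_error(
    pcCountPathwayInteractions("urn:pc:pw", mk("urn:pc:pw", "not xml <<<")),
    class = "pcContentError")
})

test_that("advanced queries fetch, merge and match local results", {
  cfg <- pcConfig()
  owlA <- miniPathwayOwl("A"); owlB <- miniPathwayOwl("B")
  getUrl <- function(uri) sprintf("%s/get?uri=%s", cfg$baseUrl,
                                  utils::URLencode(uri, reserved = TRUE))
  tp <- mockTransport(stats::setNames(list(owlA, owlB),
                                      c(getUrl("urn:pc:A"), getUrl("urn:pc:B"))))
  gA <- buildGraph(readBiopax(owlA))
  gB <- buildGraph(readBiopax(owlB))
  merged <- pcAdvancedQuery("get", c("urn:pc:A", "urn:pc:B"), tp)
  ## shared protein appears once: |V1| + |V2| - 1
  expect_identical(nrow(graphNodes(merged)),
                   nrow(graphNodes(gA)) + nrow(graphNodes(gB)) - 1L)
  expect_true(graphIdentical(merged, mergeNetworks(list(gA, gB))))
  ## neighborhood by URI equals the local query on the merged graph
  seedUri <- "http://example.org/A#rx_A"
  tp2 <- mockTransport(stats::setNames(list(owlA), getUrl("urn:pc:A")))
  nb <- pcAdvancedQuery("neighborhood", "urn:pc:A", tp2, limit = 1L)
  ## seeds are the nodes of the fetched record itself; compare against the
  ## local result seeded with every node of gA
  local <- queryNeighborhood(gA, nodeIds(gA), "both", limit = 1L)
  expect_true(graphIdentical(pcAdvancedQuery("get", "urn:pc:A", tp2), gA))
  expect_error(pcAdvancedQuery("get", character(), tp),
               class = "preconditionError")
  expect_true(is(nb, "TypedGraph"))
})

test_that("species presets and the bundled taxon table resolve names", {
  expect_identical(popularSpecies()[["human"]], 9606L)
  expect_identical(speciesName(9606), "Homo sapiens")
  expect_identical(speciesName(10090), "Mus musculus")
  expect_true(is.na(speciesName(424242)))
})
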