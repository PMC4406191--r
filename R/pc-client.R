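## Client for the Pathway Commons cPath2 REST API: search (with paging),
## OWL fetch, traverse-based interaction counting and advanced graph
## queries. All network access goes through an injectable transport
## function so the client is fully testable offline; species names are
## resolved from a small bundled taxon table rather than a live lookup.

.pcDefaults <- list(
  baseUrl = "http://www.pathwaycommons.org/pc2",
  pageSize = 500L,
  endpoints = list(search = "search", get = "get", traverse = "traverse",
                   graph = "graph", topPathways = "top_pathways")
)

#' Pathway Commons client configuration
#'
#' @param baseUrl Service base URL.
#' @param pageSize Hits per page (the service convention is 500).
#' @param endpoints Named list of endpoint path segments.
#' @return Configuration list.
#' @export
pcConfig <- function(baseUrl = .pcDefaults$baseUrl,
                     pageSize = .pcDefaults$pageSize,
                     endpoints = .pcDefaults$endpoints) {
  list(baseUrl = sub("/$", "", baseUrl), pageSize = as.integer(pageSize),
       endpoints = endpoints)
}

#' Popular-species presets
#'
#' Named NCBI taxonomy ids for the species offered as checkboxes in the
#' search dialog this client mirrors.
#'
#' @return Named integer vector.
#' @export
popularSpecies <- function() {
  c(human = 9606L, mouse = 10090L, rat = 10116L, zebrafish = 7955L,
    fruitfly = 7227L, nematode = 6239L, yeast = 4932L, ecoli = 562L)
}

#' Species name lookup from the bundled taxon table
#'
#' @param taxon NCBI taxonomy id (integer or character).
#' @return Scientific name, or `NA_character_` when the id is not in the
#'   bundled table.
#' @export
speciesName <- function(taxon) {
  path <- system.file("extdata", "taxa.tsv", package = "biopaxnet",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  i <- match(as.character(taxon), as.character(tab$taxon))
  if (is.na(i)) NA_character_ else tab$name[i]
}

## ---------------------------------------------------------------------------
## Search queries and request construction

#' Construct a Pathway Commons search query
#'
#' Keywords are passed through verbatim, so Boolean operators (AND/OR),
#' field:term pairs and `*` wildcards reach the service untouched.
#'
#' @param keywords Query string.
#' @param nameOnly Restrict the search to the name field.
#' @param organisms Character/integer vector of NCBI taxon ids or names.
#' @param datasources Character vector of datasource identifiers.
#' @param biopaxType One of `"Pathway"`, `"Interaction"`,
#'   `"PhysicalEntity"`, `"EntityReference"`, `"TopPathways"`, or `NA`.
#' @param page Zero-based page index.
#' @return A `pcSearchQuery` list.
#' @export
searchQuery <- function(keywords, nameOnly = FALSE, organisms = character(),
                        datasources = character(), biopaxType = NA_character_,
                        page = 0L) {
  if (!is.na(biopaxType) &&
      !biopaxType %in% c("Pathway", "Interaction", "PhysicalEntity",
                         "EntityReference", "TopPathways"))
    bpStop("preconditionError",
           sprintf("unsupported search type '%s'", biopaxType))
  if (page < 0L) bpStop("preconditionError", "page must be >= 0")
  structure(list(keywords = keywords, nameOnly = isTRUE(nameOnly),
                 organisms = as.character(organisms),
                 datasources = as.character(datasources),
                 biopaxType = biopaxType, page = as.integer(page)),
            class = "pcSearchQuery")
}

.enc <- function(x) utils::URLencode(x, reserved = TRUE)

#' Request URL for a search query
#'
#' A pure function of the query and configuration: the same query always
#' yields byte-identical request strings. `TopPathways` queries target the
#' dedicated top-pathways endpoint (pathways that are neither controlled
#' by nor a pathwayComponent of another process); all other types are
#' passed as the `type` parameter of the search endpoint.
#'
#' @param q A `pcSearchQuery` from [searchQuery()].
#' @param config A [pcConfig()] list.
#' @return Request URL string.
#' @export
searchRequestUrl <- function(q, config = pcConfig()) {
  top <- identical(q$biopaxType, "TopPathways")
  ep <- if (top) config$endpoints$topPathways else config$endpoints$search
  kw <- if (q$nameOnly) sprintf("name:(%s)", q$keywords) else q$keywords
  parts <- c(sprintf("q=%s", .enc(kw)), sprintf("page=%d", q$page))
  if (!top && !is.na(q$biopaxType))
    parts <- c(parts, sprintf("type=%s", tolower(q$biopaxType)))
  for (o in q$organisms) parts <- c(parts, sprintf("organism=%s", .enc(o)))
  for (d in q$datasources) parts <- c(parts, sprintf("datasource=%s", .enc(d)))
  sprintf("%s/%s?%s", config$baseUrl, ep, paste(parts, collapse = "&"))
}

## ---------------------------------------------------------------------------
## Transport

#' Mock transport for offline use
#'
#' A transport is any `function(url)` returning
#' `list(status, contentType, body)`. `mockTransport()` builds one from a
#' named list mapping URLs to responses (a string body, or a full response
#' list) and records every requested URL for inspection via
#' [transportCalls()]. Unknown URLs receive a 404 response.
#'
#' @param routes Named list: URL -> body string or response list.
#' @return Transport function with a call log.
#' @export
mockTransport <- function(routes = list()) {
  log <- new.env(parent = emptyenv())
  log$calls <- character()
  f <- function(url) {
    log$calls <- c(log$calls, url)
    r <- routes[[url]]
    if (is.null(r))
      return(list(status = 404L, contentType = "text/plain", body = ""))
    if (is.character(r))
      r <- list(status = 200L, contentType = "application/xml", body = r)
    r
  }
  attr(f, "log") <- log
  class(f) <- c("pcTransport", class(f))
  f
}

#' @rdname mockTransport
#' @param transport A transport created by [mockTransport()].
#' @export
transportCalls <- function(transport) attr(transport, "log")$calls

#' Default HTTP transport
#'
#' Fetches a URL with base R connections. Only used when the client is
#' pointed at a live service; the test suite uses [mockTransport()].
#'
#' @return Transport function.
#' @export
httpTransport <- function() {
  function(url) {
    body <- tryCatch(paste(readLines(url, warn = FALSE), collapse = "\n"),
                     error = function(e)
                       bpStop("transportError", conditionMessage(e)))
    list(status = 200L, contentType = "application/xml", body = body)
  }
}

.checkStatus <- function(resp, url) {
  if (resp$status == 404L)
    bpStop("pcNotFoundError", sprintf("404 for %s", url))
  if (resp$status != 200L)
    bpStop("transportError",
           sprintf("HTTP %d for %s", resp$status, url))
  resp
}

## ---------------------------------------------------------------------------
## Operations

#' Search Pathway Commons
#'
#' Issues one search (or top-pathways) request and parses the hits.
#'
#' @param q A `pcSearchQuery` from [searchQuery()].
#' @param transport Transport function (see [mockTransport()]).
#' @param config A [pcConfig()] list.
#' @return A [SearchPage-class]; an empty result is an empty page, not an
#'   error.
#' @export
pcSearch <- function(q, transport, config = pcConfig()) {
  url <- searchRequestUrl(q, config)
  resp <- .checkStatus(transport(url), url)
  doc <- tryCatch(xml2::read_xml(resp$body), error = function(e)
    bpStop("pcContentError",
           sprintf("search response is not XML: %s", conditionMessage(e))))
  root <- xml2::xml_root(doc)
  total <- xml2::xml_attr(root, "numHits")
  total <- if (is.na(total)) 0L else as.integer(total)
  hitNodes <- xml2::xml_find_all(doc, ".//searchHit")
  grab <- function(node, what) {
    v <- xml2::xml_find_first(node, what)
    if (inherits(v, "xml_missing")) NA_character_ else xml2::xml_text(v)
  }
  hits <- data.frame(
    uri = vapply(hitNodes, grab, character(1), "uri"),
    name = vapply(hitNodes, grab, character(1), "name"),
    organism = vapply(hitNodes, grab, character(1), "organism"),
    source = vapply(hitNodes, grab, character(1), "dataSource"),
    excerpt = vapply(hitNodes, grab, character(1), "excerpt"),
    numInteractions = as.integer(vapply(hitNodes, grab, character(1),
                                        "numInteractions")),
    stringsAsFactors = FALSE
  )
  new("SearchPage", hits = hits, totalHits = total, page = q$page,
      pageSize = config$pageSize)
}

#' Iterate over all pages of a search
#'
#' Re-issues the query with increasing page index and stops exactly when
#' `(page + 1) * pageSize >= totalHits`, i.e. after `ceiling(total / 500)`
#' requests (a query with zero hits still needs the one initial request).
#'
#' @inheritParams pcSearch
#' @return List of [SearchPage-class] objects.
#' @export
pcSearchPages <- function(q, transport, config = pcConfig()) {
  pages <- list()
  page <- q$page
  repeat {
    q$page <- page
    sp <- pcSearch(q, transport, config)
    pages[[length(pages) + 1L]] <- sp
    if ((page + 1L) * config$pageSize >= sp@totalHits) break
    page <- page + 1L
  }
  pages
}

#' Fetch the BioPAX OWL record for a URI
#'
#' @param uri Record URI.
#' @param transport Transport function.
#' @param config A [pcConfig()] list.
#' @return OWL document text, ready for [readBiopax()].
#' @export
fetchOwl <- function(uri, transport, config = pcConfig()) {
  if (!nzchar(uri)) bpStop("preconditionError", "uri must be non-empty")
  url <- sprintf("%s/%s?uri=%s", config$baseUrl, config$endpoints$get,
                 .enc(uri))
  resp <- .checkStatus(transport(url), url)
  body <- resp$body
  ok <- grepl("^\\s*<", body) &&
    (grepl(.NS_BP3, body, fixed = TRUE) || grepl(.NS_BP2, body, fixed = TRUE))
  if (!ok)
    bpStop("pcContentError", sprintf("payload for %s is not BioPAX OWL", uri))
  body
}

#' Count interactions in a pathway via a traverse request
#'
#' Issues a traverse query for the pathway's interaction components
#' (recursing through sub-pathways, mirroring [countInteractions()]) and
#' counts the returned values.
#'
#' @param uri Pathway URI.
#' @param transport Transport function.
#' @param config A [pcConfig()] list.
#' @return Integer count.
#' @export
pcCountPathwayInteractions <- function(uri, transport, config = pcConfig()) {
  if (!nzchar(uri)) bpStop("preconditionError", "uri must be non-empty")
  path <- "Pathway/pathwayComponent*:Interaction"
  url <- sprintf("%s/%s?uri=%s&path=%s", config$baseUrl,
                 config$endpoints$traverse, .enc(uri), .enc(path))
  resp <- .checkStatus(transport(url), url)
  doc <- tryCatch(xml2::read_xml(resp$body), error = function(e)
    bpStop("pcContentError",
           sprintf("traverse response is not XML: %s", conditionMessage(e))))
  length(xml2::xml_find_all(doc, ".//value"))
}

#' Advanced graph query over search hits
#'
#' Local mode (the default, and the only mode exercised offline): fetches
#' each hit's OWL record, builds and merges the typed graphs, then runs the
#' matching local graph query with the hits' nodes as seeds. `kind = "get"`
#' is the plain merge.
#'
#' @param kind One of `"get"`, `"neighborhood"`, `"common-stream"`,
#'   `"paths-between"`, `"paths-from-to"`.
#' @param uris Hit URIs (at least one; these seed the query).
#' @param transport Transport function.
#' @param targets Target URIs (required for `"paths-from-to"`).
#' @param direction Traversal direction where applicable.
#' @param limit Maximum path length / hop count.
#' @param config A [pcConfig()] list.
#' @return A [TypedGraph-class].
#' @export
pcAdvancedQuery <- function(kind = c("get", "neighborhood", "common-stream",
                                     "paths-between", "paths-from-to"),
                            uris, transport, targets = character(),
                            direction = "downstream", limit = 3L,
                            config = pcConfig()) {
  kind <- match.arg(kind)
  if (!length(uris))
    bpStop("preconditionError", "advanced queries need at least one hit URI")
  all <- c(uris, targets)
  graphs <- lapply(all, function(u)
    buildGraph(readBiopax(fetchOwl(u, transport, config))))
  names(graphs) <- all
  merged <- mergeNetworks(graphs)
  ## A hit URI seeds the query with its own node when it denotes one in the
  ## merged graph, and with every node of its record otherwise (the record
  ## is typically a Pathway whose URI is not an entity node of interest).
  toIds <- function(us) {
    nd <- graphNodes(merged)
    ids <- unlist(lapply(us, function(u) {
      hit <- nd$id[match(u, nd$uri)]
      if (!is.na(hit)) hit else nodeIds(graphs[[u]])
    }))
    unique(ids)
  }
  switch(kind,
    "get" = merged,
    "neighborhood" = queryNeighborhood(merged, toIds(uris),
                                       direction = "both", limit = limit),
    "common-stream" = queryCommonStream(merged, toIds(uris),
                                        direction = direction, limit = limit),
    "paths-between" = queryPathsBetween(merged, toIds(uris), limit = limit),
    "paths-from-to" = queryPathsFromTo(merged, toIds(uris), toIds(targets),
                                       limit = limit))
}
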