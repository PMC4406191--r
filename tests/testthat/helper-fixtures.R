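## Shared test fixtures: quick graph constructors, a seeded random digraph
## generator, and independent igraph-based oracles for the query
## operations (BFS reachability and exhaustive simple-path enumeration).

## Build a TypedGraph from node ids and an edge table
## (source, target, kind, directed). All nodes are Proteins unless classes
## are given.
makeGraph <- function(ids, edges = NULL, classes = NULL) {
  nodes <- data.frame(id = ids,
                      biopaxClass = classes %||% rep("Protein", length(ids)),
                      label = ids,
                      uri = if (length(ids)) paste0("urn:test:", ids)
                            else character(0),
                      stringsAsFactors = FALSE)
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        kind = character(), directed = logical(),
                        stringsAsFactors = FALSE)
  g <- typedGraph(nodes, edges)
  g@classSets <- list(BioPAX = buildClassSet(g))
  g
}

edgeRow <- function(source, target, kind = "controlled", directed = TRUE) {
  data.frame(source = source, target = target, kind = kind,
             directed = directed, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Random typed digraph with a mix of directed and undirected edges.
randomDigraph <- function(n, seed, pEdge = 2 / max(n - 1, 1)) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(s = ids, t = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$s != pairs$t, ]
  keep <- stats::runif(nrow(pairs)) < pEdge / 2
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs)) {
    undirected <- stats::runif(nrow(pairs)) < 0.25
    edges <- data.frame(source = pairs$s, target = pairs$t,
                        kind = ifelse(undirected, "participant", "controlled"),
                        directed = !undirected, stringsAsFactors = FALSE)
    ## undirected edges are stored once; drop duplicates
    key <- ifelse(edges$directed,
                  paste(edges$source, edges$target, sep = ">"),
                  paste(pmin(edges$source, edges$target),
                        pmax(edges$source, edges$target), sep = "-"))
    edges <- edges[!duplicated(key), , drop = FALSE]
  } else {
    edges <- NULL
  }
  makeGraph(ids, edges)
}

## igraph view of a TypedGraph: every undirected edge becomes two arcs.
asIgraph <- function(g) {
  ed <- graphEdges(g)
  arcs <- rbind(ed[c("source", "target")],
                with(ed[!ed$directed, , drop = FALSE],
                     data.frame(source = target, target = source)))
  igraph::graph_from_data_frame(arcs, directed = TRUE,
                                vertices = graphNodes(g)$id)
}

igMode <- function(direction)
  switch(direction, downstream = "out", upstream = "in", both = "all")

## Oracle: node set within `limit` hops of the seeds (BFS via igraph::ego).
oracleNeighborhoodIds <- function(g, seeds, direction, limit) {
  ig <- asIgraph(g)
  nb <- igraph::ego(ig, order = limit, nodes = seeds, mode = igMode(direction))
  sort(unique(unlist(lapply(nb, names))))
}

## Oracle: nodes reachable from `seed` by a path of length >= 1.
oracleReach <- function(g, seed, direction) {
  ig <- asIgraph(g)
  mode <- igMode(direction)
  nbrs <- names(igraph::neighbors(ig, seed, mode = mode))
  if (!length(nbrs)) return(character(0))
  sort(unique(unlist(lapply(nbrs, function(v)
    names(igraph::subcomponent(ig, v, mode = mode))))))
}

## Oracle: all simple directed paths (node id sequences) from `from` to any
## node in `targets`, of length <= limit.
oraclePaths <- function(g, from, targets, limit) {
  ig <- asIgraph(g)
  targets <- setdiff(targets, from)
  if (!length(targets)) return(list())
  ps <- igraph::all_simple_paths(ig, from = from, to = targets,
                                 mode = "out", cutoff = limit)
  lapply(ps, names)
}

## Node/edge identity keys for subgraph comparisons.
edgeKeys <- function(g) {
  ed <- graphEdges(g)
  sort(sprintf("%s|%s|%s|%d", ed$source, ed$kind, ed$target, ed$directed))
}

## Expected result of a paths-style query, from enumerated oracle paths:
## the node union and the edge rows realizing each hop.
oraclePathSubgraph <- function(g, pathList) {
  ids <- as.character(sort(unique(unlist(pathList))))
  ed <- graphEdges(g)
  idx <- integer()
  for (p in pathList)
    for (i in seq_len(length(p) - 1L)) {
      u <- p[[i]]; v <- p[[i + 1L]]
      idx <- c(idx, which((ed$directed & ed$source == u & ed$target == v) |
                            (!ed$directed &
                               ((ed$source == u & ed$target == v) |
                                  (ed$source == v & ed$target == u)))))
    }
  list(ids = ids, edgeIdx = sort(unique(idx)))
}

## cPath2-style canned responses --------------------------------------------

searchResponseXml <- function(hits, total = length(hits)) {
  hitXml <- vapply(hits, function(h) {
    fields <- vapply(names(h), function(f)
      sprintf("<%s>%s</%s>", f, h[[f]], f), character(1))
    sprintf("<searchHit>%s</searchHit>", paste(fields, collapse = ""))
  }, character(1))
  sprintf('<?xml version="1.0"?><searchResponse numHits="%d">%s</searchResponse>',
          total, paste(hitXml, collapse = ""))
}

traverseResponseXml <- function(values) {
  sprintf('<?xml version="1.0"?><traverseResponse>%s</traverseResponse>',
          paste(sprintf("<traverseEntry><value>%s</value></traverseEntry>",
                        values), collapse = ""))
}

## A tiny single-reaction pathway OWL document sharing protein `shared`.
miniPathwayOwl <- function(tag, shared = "pShared") {
  base <- sprintf("http://example.org/%s", tag)
  sprintf('<?xml version="1.0" encoding="UTF-8"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:bp="http://www.biopax.org/release/biopax-level3.owl#">
  <bp:Pathway rdf:about="%s#pw_%s">
    <bp:pathwayComponent rdf:resource="%s#rx_%s"/>
  </bp:Pathway>
  <bp:BiochemicalReaction rdf:about="%s#rx_%s">
    <bp:left rdf:resource="urn:shared:%s"/>
    <bp:right rdf:resource="%s#prod_%s"/>
  </bp:BiochemicalReaction>
  <bp:Protein rdf:about="urn:shared:%s"/>
  <bp:Protein rdf:about="%s#prod_%s"/>
</rdf:RDF>', base, tag, base, tag, base, tag, shared, base, tag, shared,
   base, tag)
}
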