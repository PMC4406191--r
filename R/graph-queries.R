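## Local implementations of the advanced graph queries (the Import Network
## dialog's Get / Nearest Neighborhood / Common Stream / Paths Between /
## Paths From To), defined over the directed edge conventions of
## buildGraph(). Directed edges traverse source -> target downstream and
## target -> source upstream; undirected participant edges traverse both
## ways in every direction mode.

## Adjacency list for one traversal direction.
.adjacency <- function(graph, direction = c("downstream", "upstream", "both")) {
  direction <- match.arg(direction)
  nd <- graphNodes(graph)$id
  ed <- graphEdges(graph)
  adj <- stats::setNames(vector("list", length(nd)), nd)
  add <- function(a, b) adj[[a]] <<- c(adj[[a]], b)
  for (i in seq_len(nrow(ed))) {
    s <- ed$source[i]; t <- ed$target[i]
    if (!ed$directed[i]) { add(s, t); add(t, s) }
    else if (direction == "downstream") add(s, t)
    else if (direction == "upstream") add(t, s)
    else { add(s, t); add(t, s) }
  }
  lapply(adj, unique)
}

.checkSeeds <- function(graph, seeds) {
  missing <- setdiff(seeds, graphNodes(graph)$id)
  if (length(missing))
    bpStop("missingNodeError",
           sprintf("unknown node id(s): %s", paste(missing, collapse = ", ")))
  invisible(seeds)
}

## Breadth-first search; returns all nodes within `limit` hops of `from`
## (including `from` itself).
.bfs <- function(adj, from, limit = Inf) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[from] <- 0
  queue <- from
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    if (dist[[u]] >= limit) next
    for (v in adj[[u]]) {
      if (is.infinite(dist[[v]])) {
        dist[[v]] <- dist[[u]] + 1
        queue <- c(queue, v)
      }
    }
  }
  names(dist)[is.finite(dist)]
}

## Nodes reachable from `seed` by a path of length >= 1 (seed included only
## if it lies on a cycle through itself).
.reachFrom <- function(adj, seed) {
  nb <- adj[[seed]]
  if (!length(nb)) return(character(0))
  .bfs(adj, nb, Inf)
}

## All simple paths (node sequences) from `from` ending in `targets`, of
## length (edge count) <= limit. Depth-bounded DFS.
.boundedPaths <- function(adj, from, targets, limit) {
  paths <- list()
  walk <- function(path) {
    u <- path[[length(path)]]
    if (length(path) > 1L && u %in% targets)
      paths[[length(paths) + 1L]] <<- path
    if (length(path) - 1L >= limit) return(invisible())
    for (v in adj[[u]])
      if (!v %in% path) walk(c(path, v))
  }
  walk(from)
  paths
}

## Edge row indices realizing a hop u -> v (directed forward, or undirected).
.hopEdges <- function(edges, u, v) {
  which((edges$directed & edges$source == u & edges$target == v) |
        (!edges$directed &
           ((edges$source == u & edges$target == v) |
            (edges$source == v & edges$target == u))))
}

.subgraphFromEdges <- function(graph, ids, edgeIdx) {
  nd <- graphNodes(graph)
  nodes <- nd[nd$id %in% ids, , drop = FALSE]
  edges <- graphEdges(graph)[sort(unique(edgeIdx)), , drop = FALSE]
  sets <- lapply(classSets(graph), function(cs) {
    cls <- lapply(cs@classes, function(v) v[v %in% ids])
    classSet(cs@name, cls[lengths(cls) > 0])
  })
  typedGraph(nodes, edges, sets)
}

#' Merge typed graphs into one network
#'
#' Nodes are unified by id and edges by (source, target, kind); the
#' `"BioPAX"` class set is re-derived and any other class sets are merged by
#' name. The Get query over several search hits reduces to this merge.
#'
#' @param graphs List of [TypedGraph-class] objects (at least one).
#' @return A [TypedGraph-class].
#' @export
mergeNetworks <- function(graphs) {
  if (!length(graphs))
    bpStop("preconditionError", "mergeNetworks() needs at least one graph")
  nodes <- do.call(rbind, lapply(graphs, graphNodes))
  cls <- tapply(nodes$biopaxClass, nodes$id, function(x) length(unique(x)))
  bad <- names(cls)[cls > 1]
  if (length(bad))
    bpStop("conflictError",
           sprintf("node id(s) with conflicting BioPAX classes: %s",
                   paste(bad, collapse = ", ")))
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  edges <- do.call(rbind, lapply(graphs, graphEdges))
  if (nrow(edges)) {
    key <- sprintf("%s|%s|%s", edges$source, edges$kind, edges$target)
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  extra <- list()
  for (g in graphs) {
    for (cs in classSets(g)) {
      if (cs@name == "BioPAX") next
      if (is.null(extra[[cs@name]])) extra[[cs@name]] <- cs@classes
      else for (k in names(cs@classes))
        extra[[cs@name]][[k]] <- unique(c(extra[[cs@name]][[k]], cs@classes[[k]]))
    }
  }
  g <- typedGraph(nodes, edges)
  sets <- c(list(BioPAX = buildClassSet(g)),
            lapply(names(extra), function(n) classSet(n, extra[[n]])))
  names(sets) <- c("BioPAX", names(extra))
  g@classSets <- sets
  g
}

#' Neighborhood query
#'
#' Induced subgraph on the seed nodes together with every node within
#' `limit` hops, in the requested direction (default: first-order
#' neighborhood in both directions).
#'
#' @param graph A [TypedGraph-class].
#' @param seeds Character vector of node ids.
#' @param direction `"both"` (default), `"upstream"` or `"downstream"`.
#' @param limit Maximum number of hops (default 1).
#' @return A [TypedGraph-class] subgraph.
#' @export
queryNeighborhood <- function(graph, seeds,
                              direction = c("both", "upstream", "downstream"),
                              limit = 1L) {
  direction <- match.arg(direction)
  .checkSeeds(graph, seeds)
  adj <- .adjacency(graph, direction)
  inducedSubgraph(graph, .bfs(adj, seeds, limit))
}

#' Common Stream query
#'
#' Finds the nodes reachable from *every* seed in the given direction (the
#' common downstream or upstream set) and, by default, the simple connecting
#' paths (length at most `limit`) from each seed to that common set; the
#' result is the induced subgraph on the union.
#'
#' @param graph A [TypedGraph-class].
#' @param seeds At least two node ids.
#' @param direction `"downstream"` (default) or `"upstream"`.
#' @param limit Maximum connecting-path length (default 3).
#' @param includePaths If `FALSE`, return only the induced subgraph on the
#'   common set.
#' @return A [TypedGraph-class] subgraph (empty when the seeds share no
#'   common stream).
#' @export
queryCommonStream <- function(graph, seeds,
                              direction = c("downstream", "upstream"),
                              limit = 3L, includePaths = TRUE) {
  direction <- match.arg(direction)
  if (length(seeds) < 2L)
    bpStop("preconditionError", "Common Stream needs at least two seeds")
  .checkSeeds(graph, seeds)
  adj <- .adjacency(graph, direction)
  common <- Reduce(intersect, lapply(seeds, function(s) .reachFrom(adj, s)))
  if (!length(common)) return(inducedSubgraph(graph, character(0)))
  if (!includePaths) return(inducedSubgraph(graph, common))
  ids <- common
  for (s in seeds)
    for (p in .boundedPaths(adj, s, common, limit))
      ids <- c(ids, p)
  inducedSubgraph(graph, unique(ids))
}

#' Paths Between query
#'
#' Union of all nodes and edges lying on some directed simple path of
#' length at most `limit` between any ordered pair of distinct seeds.
#' Undirected participant edges are traversable both ways.
#'
#' @param graph A [TypedGraph-class].
#' @param seeds At least two node ids.
#' @param limit Maximum path length in edges (default 3).
#' @return A [TypedGraph-class] subgraph containing exactly the path nodes
#'   and path edges.
#' @export
queryPathsBetween <- function(graph, seeds, limit = 3L) {
  if (length(seeds) < 2L)
    bpStop("preconditionError", "Paths Between needs at least two seeds")
  .checkSeeds(graph, seeds)
  if (limit < 1L) bpStop("preconditionError", "limit must be >= 1")
  adj <- .adjacency(graph, "downstream")
  edges <- graphEdges(graph)
  ids <- character(); eidx <- integer()
  for (s in seeds) {
    for (p in .boundedPaths(adj, s, setdiff(seeds, s), limit)) {
      ids <- c(ids, p)
      for (i in seq_len(length(p) - 1L))
        eidx <- c(eidx, .hopEdges(edges, p[[i]], p[[i + 1L]]))
    }
  }
  .subgraphFromEdges(graph, unique(ids), eidx)
}

#' Paths From To query
#'
#' Union of all nodes and edges on directed simple paths from any source to
#' any target, of length at most `limit`.
#'
#' @param graph A [TypedGraph-class].
#' @param sources,targets Non-empty, disjoint sets of node ids.
#' @param limit Maximum path length in edges (default 3).
#' @return A [TypedGraph-class] subgraph.
#' @export
queryPathsFromTo <- function(graph, sources, targets, limit = 3L) {
  if (!length(sources) || !length(targets))
    bpStop("preconditionError", "sources and targets must be non-empty")
  if (length(intersect(sources, targets)))
    bpStop("preconditionError", "sources and targets must be disjoint")
  .checkSeeds(graph, c(sources, targets))
  adj <- .adjacency(graph, "downstream")
  edges <- graphEdges(graph)
  ids <- character(); eidx <- integer()
  for (s in sources) {
    for (p in .boundedPaths(adj, s, targets, limit)) {
      ids <- c(ids, p)
      for (i in seq_len(length(p) - 1L))
        eidx <- c(eidx, .hopEdges(edges, p[[i]], p[[i + 1L]]))
    }
  }
  .subgraphFromEdges(graph, unique(ids), eidx)
}
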