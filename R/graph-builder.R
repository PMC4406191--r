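## Conversion of a Level-3 BioPAX model into a typed, styled network graph.
##
## Node rule: one node per Pathway, Interaction (incl. subtypes),
## PhysicalEntity (incl. subtypes) and Gene element. EntityReference,
## PathwayStep and utility elements do not become nodes.
##
## Edge rules:
##   Complex --component--> member            kind "complex-component" (directed)
##   entity --memberPhysicalEntity--> member  kind "member"            (directed)
##   Pathway --pathwayComponent--> process    kind "pathway-component" (directed)
##   stepProcess(step) --> stepProcess(nextStep)  kind "pathway-step"  (directed)
##   left --> Conversion, Conversion --> right    kinds "participant-left"/"-right"
##   controller --> Control, Control --> controlled  kinds "controller"/"controlled"
##   Interaction -- participant                kind "participant"      (undirected)

.EDGE_DIRECTED <- c(
  "complex-component" = TRUE, "pathway-component" = TRUE,
  "pathway-step" = TRUE, "participant-left" = TRUE,
  "participant-right" = TRUE, "participant" = FALSE,
  "controller" = TRUE, "controlled" = TRUE, "member" = TRUE
)

## Local part of an IRI: text after '#', else after the last '/', else
## after the last ':' (urn-style identifiers).
.uriFragment <- function(uri) {
  frag <- sub("^.*#", "", uri)
  if (identical(frag, uri)) frag <- sub("^.*/", "", uri)
  if (identical(frag, uri)) frag <- sub("^.*:", "", uri)
  if (!nzchar(frag)) frag <- uri
  frag
}

## Generic participant-like properties on interactions outside the
## Conversion/Control branches.
.PARTICIPANT_PROPS <- c("participant", "product", "template", "cofactor")

#' Build a typed graph from a Level-3 BioPAX model
#'
#' Applies the node and edge construction rules documented above, assigns
#' every node its mEPN-derived glyph, and attaches the `"BioPAX"` class set
#' partitioning nodes by their concrete BioPAX type.
#'
#' @param model A [BioPaxModel-class] at level 3.
#' @return A [TypedGraph-class].
#' @export
#' @examples
#' owl <- system.file("extdata", "toy_l3.owl", package = "biopaxnet")
#' g <- buildGraph(readBiopax(owl))
#' nrow(graphNodes(g))  # 8
buildGraph <- function(model) {
  if (model@level != 3L)
    bpStop("levelPreconditionError", "graphs are built from Level-3 models only")
  els <- model@elements[order(names(model@elements), method = "radix")]
  eligible <- vapply(els, function(e) .isNodeType(e@biopaxType), logical(1))
  nodeEls <- els[eligible]

  ## Stable ids: URI local fragment, numeric suffix on collision.
  ids <- character(length(nodeEls))
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(nodeEls)) {
    frag <- .uriFragment(nodeEls[[i]]@uri)
    if (is.null(seen[[frag]])) {
      seen[[frag]] <- 1L
      ids[i] <- frag
    } else {
      seen[[frag]] <- seen[[frag]] + 1L
      ids[i] <- sprintf("%s.%d", frag, seen[[frag]])
    }
  }
  uri2id <- structure(ids, names = names(nodeEls))

  labels <- vapply(nodeEls, function(e)
    if (!is.na(e@displayName)) e@displayName else .uriFragment(e@uri),
    character(1))
  classes <- vapply(nodeEls, function(e) e@biopaxType, character(1))
  styles <- lapply(classes, glyphForType)
  nodes <- data.frame(
    id = unname(ids), biopaxClass = unname(classes), label = unname(labels),
    uri = names(nodeEls),
    shape2d = vapply(styles, `[[`, character(1), "shape2d"),
    shape3d = vapply(styles, `[[`, character(1), "shape3d"),
    colour = vapply(styles, `[[`, character(1), "colour"),
    stringsAsFactors = FALSE
  )

  src <- character(); tgt <- character(); kind <- character()
  addEdge <- function(fromUri, toUri, k) {
    a <- uri2id[fromUri]; b <- uri2id[toUri]
    if (is.na(a) || is.na(b) || a == b) return(invisible())
    src <<- c(src, unname(a)); tgt <<- c(tgt, unname(b)); kind <<- c(kind, k)
  }

  for (uri in names(els)) {
    e <- els[[uri]]
    t <- e@biopaxType
    if (isA(t, "PhysicalEntity")) {
      for (m in bpRefs(e, "memberPhysicalEntity")) addEdge(uri, m, "member")
      if (isA(t, "Complex"))
        for (m in bpRefs(e, "component")) addEdge(uri, m, "complex-component")
    } else if (isA(t, "Pathway")) {
      for (m in bpRefs(e, "pathwayComponent"))
        addEdge(uri, m, "pathway-component")
      for (stepUri in bpRefs(e, "pathwayOrder")) {
        step <- els[[stepUri]]
        if (is.null(step)) next
        for (nextUri in bpRefs(step, "nextStep")) {
          nxt <- els[[nextUri]]
          if (is.null(nxt)) next
          for (x in bpRefs(step, "stepProcess"))
            for (y in bpRefs(nxt, "stepProcess"))
              addEdge(x, y, "pathway-step")
        }
      }
    } else if (isA(t, "Control")) {
      for (m in bpRefs(e, "controller")) addEdge(m, uri, "controller")
      for (m in bpRefs(e, "controlled")) addEdge(uri, m, "controlled")
    } else if (isA(t, "Conversion")) {
      for (m in bpRefs(e, "left")) addEdge(m, uri, "participant-left")
      for (m in bpRefs(e, "right")) addEdge(uri, m, "participant-right")
      for (m in bpRefs(e, "participant")) addEdge(uri, m, "participant")
    } else if (isA(t, "Interaction")) {
      for (p in .PARTICIPANT_PROPS)
        for (m in bpRefs(e, p)) addEdge(uri, m, "participant")
    }
  }

  edges <- data.frame(source = src, target = tgt, kind = kind,
                      directed = unname(.EDGE_DIRECTED[kind]),
                      stringsAsFactors = FALSE)
  g <- typedGraph(nodes, edges)
  g@classSets <- list(BioPAX = buildClassSet(g))
  g
}

#' Derive the per-type class set of a graph
#'
#' Partitions node ids by their concrete (most specific) BioPAX class; the
#' result is the `"BioPAX"` class set attached by [buildGraph()].
#'
#' @param graph A [TypedGraph-class].
#' @param name Class-set name (default `"BioPAX"`).
#' @return A [ClassSet-class]; every node appears in exactly one class.
#' @export
buildClassSet <- function(graph, name = "BioPAX") {
  nd <- graphNodes(graph)
  if (!nrow(nd)) return(classSet(name))
  classSet(name, split(nd$id, nd$biopaxClass))
}

#' Count interactions within a pathway
#'
#' Counts the distinct Interaction-typed elements reachable from a pathway
#' through `pathwayComponent` links, recursing through sub-pathways; each
#' interaction is counted once. This mirrors the traverse-based interaction
#' count shown for pathway search hits.
#'
#' @param model A [BioPaxModel-class].
#' @param pathway_uri URI of a Pathway element in `model`.
#' @return Integer count.
#' @export
countInteractions <- function(model, pathway_uri) {
  el <- model@elements[[pathway_uri]]
  if (is.null(el) || !isA(el@biopaxType, "Pathway"))
    bpStop("typeError", sprintf("'%s' is not a Pathway in this model", pathway_uri))
  seenP <- character(); found <- character()
  queue <- pathway_uri
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    if (u %in% seenP) next
    seenP <- c(seenP, u)
    e <- model@elements[[u]]
    if (is.null(e)) next
    for (comp in bpRefs(e, "pathwayComponent")) {
      ce <- model@elements[[comp]]
      if (is.null(ce)) next
      if (isA(ce@biopaxType, "Interaction")) found <- c(found, comp)
      else if (isA(ce@biopaxType, "Pathway")) queue <- c(queue, comp)
    }
  }
  length(unique(found))
}

#' Test two typed graphs for equality
#'
#' Graphs are equal when they have the same node ids with the same BioPAX
#' classes and the same multiset of (source, kind, target, directed) edges.
#' Class sets, labels and styles are not compared.
#'
#' @param g1,g2 [TypedGraph-class] objects.
#' @return Logical scalar.
#' @export
graphIdentical <- function(g1, g2) {
  n1 <- graphNodes(g1)[c("id", "biopaxClass")]
  n2 <- graphNodes(g2)[c("id", "biopaxClass")]
  n1 <- n1[order(n1$id), , drop = FALSE]; rownames(n1) <- NULL
  n2 <- n2[order(n2$id), , drop = FALSE]; rownames(n2) <- NULL
  if (!identical(n1, n2)) return(FALSE)
  key <- function(g) {
    e <- graphEdges(g)
    sort(sprintf("%s|%s|%s|%d", e$source, e$kind, e$target, e$directed))
  }
  identical(key(g1), key(g2))
}

#' Induced subgraph on a node id set
#'
#' Keeps the given nodes and every edge whose two endpoints are both kept;
#' class sets are filtered to the remaining ids.
#'
#' @param graph A [TypedGraph-class].
#' @param ids Character vector of node ids (must exist in the graph).
#' @return A [TypedGraph-class].
#' @export
inducedSubgraph <- function(graph, ids) {
  nd <- graphNodes(graph)
  missing <- setdiff(ids, nd$id)
  if (length(missing))
    bpStop("missingNodeError",
           sprintf("unknown node id(s): %s", paste(missing, collapse = ", ")))
  nodes <- nd[nd$id %in% ids, , drop = FALSE]
  ed <- graphEdges(graph)
  edges <- ed[ed$source %in% ids & ed$target %in% ids, , drop = FALSE]
  sets <- lapply(classSets(graph), function(cs) {
    cls <- lapply(cs@classes, function(v) v[v %in% ids])
    classSet(cs@name, cls[lengths(cls) > 0])
  })
  typedGraph(nodes, edges, sets)
}
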