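#' Accessors for biopaxnet objects
#'
#' `elements()` returns the URI-keyed element list of a model;
#' `biopaxLevel()` its BioPAX level. `graphNodes()`, `graphEdges()` and
#' `classSets()` return the node table, edge table and class sets of a
#' [TypedGraph-class]. `nodeIds()` returns the node id vector.
#' `layoutCoords()` returns the coordinate matrix of a
#' [LayoutResult-class]. `searchHits()` returns the hit table of a
#' [SearchPage-class].
#'
#' @param x The object.
#' @return See details above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))
#' @rdname accessors
#' @export
setGeneric("biopaxLevel", function(x) standardGeneric("biopaxLevel"))
#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setGeneric("classSets", function(x) standardGeneric("classSets"))
#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
#' @rdname accessors
#' @export
setGeneric("layoutCoords", function(x) standardGeneric("layoutCoords"))
#' @rdname accessors
#' @export
setGeneric("searchHits", function(x) standardGeneric("searchHits"))

#' @rdname accessors
#' @export
setMethod("elements", "BioPaxModel", function(x) x@elements)
#' @rdname accessors
#' @export
setMethod("biopaxLevel", "BioPaxModel", function(x) x@level)
#' @rdname accessors
#' @export
setMethod("graphNodes", "TypedGraph", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("graphEdges", "TypedGraph", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("classSets", "TypedGraph", function(x) x@classSets)
#' @rdname accessors
#' @export
setMethod("nodeIds", "TypedGraph", function(x) x@nodes$id)
#' @rdname accessors
#' @export
setMethod("layoutCoords", "LayoutResult", function(x) x@coordinates)
#' @rdname accessors
#' @export
setMethod("searchHits", "SearchPage", function(x) x@hits)

#' Number of elements in a model
#' @param x A [BioPaxModel-class].
#' @return Integer.
#' @export
setMethod("length", "BioPaxModel", function(x) length(x@elements))

setMethod("show", "BioPaxElement", function(object) {
  cat(sprintf("BioPaxElement <%s> %s\n", object@biopaxType, object@uri))
  if (!is.na(object@displayName))
    cat("  displayName:", object@displayName, "\n")
  for (p in names(object@refs))
    cat(sprintf("  %s -> %s\n", p, paste(object@refs[[p]], collapse = ", ")))
})

setMethod("show", "BioPaxModel", function(object) {
  tab <- table(vapply(object@elements, function(e) e@biopaxType, character(1)))
  cat(sprintf("BioPaxModel (Level %d) with %d elements\n",
              object@level, length(object@elements)))
  if (length(tab)) {
    for (t in names(sort(tab, decreasing = TRUE)))
      cat(sprintf("  %-24s %d\n", t, tab[[t]]))
  }
})

setMethod("show", "TypedGraph", function(object) {
  cat(sprintf("TypedGraph with %d nodes, %d edges, %d class set(s)\n",
              nrow(object@nodes), nrow(object@edges), length(object@classSets)))
  if (nrow(object@edges)) {
    tab <- table(object@edges$kind)
    for (k in names(tab)) cat(sprintf("  %-20s %d\n", k, tab[[k]]))
  }
})

setMethod("show", "ClassSet", function(object) {
  cat(sprintf("ClassSet '%s': %d class(es), %d node(s)\n", object@name,
              length(object@classes),
              length(unlist(object@classes, use.names = FALSE))))
})

setMethod("show", "LayoutResult", function(object) {
  cat(sprintf("LayoutResult: %d node(s) in %dD, seed %d, %d sweep(s)\n",
              nrow(object@coordinates), object@dims, object@seed,
              object@iterationsUsed))
})

setMethod("show", "SearchPage", function(object) {
  cat(sprintf("SearchPage %d: %d hit(s) of %d total (page size %d)\n",
              object@page, nrow(object@hits), object@totalHits,
              object@pageSize))
})
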