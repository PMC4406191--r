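#' @import methods
NULL

## ---------------------------------------------------------------------------
## BioPaxElement

#' BioPaxElement: one typed element of a BioPAX document
#'
#' An element is identified by an absolute IRI and carries a supported BioPAX
#' type, optional display name, literal-valued properties and
#' reference-valued properties (values are URIs of other elements in the
#' same model).
#'
#' @slot uri Absolute IRI; unique key within a model.
#' @slot biopaxType One of [supportedBiopaxTypes()].
#' @slot displayName Display name, or `NA_character_`.
#' @slot literals Named list; each entry a character vector of literal values.
#' @slot refs Named list; each entry a character vector of target URIs.
#' @export
setClass("BioPaxElement",
  representation(
    uri = "character",
    biopaxType = "character",
    displayName = "character",
    literals = "list",
    refs = "list"
  ),
  prototype(displayName = NA_character_, literals = list(), refs = list())
)

setValidity("BioPaxElement", function(object) {
  msgs <- character()
  if (length(object@uri) != 1L || !nzchar(object@uri))
    msgs <- c(msgs, "uri must be a single non-empty string")
  if (length(object@biopaxType) != 1L ||
      !object@biopaxType %in% supportedBiopaxTypes())
    msgs <- c(msgs, sprintf("biopaxType '%s' is not supported",
                            paste(object@biopaxType, collapse = ",")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a BioPaxElement
#'
#' @param uri Absolute IRI.
#' @param biopaxType Supported type name.
#' @param displayName Optional display name.
#' @param literals Named list of character vectors (literal properties).
#' @param refs Named list of character vectors of URIs (reference properties).
#' @return A [BioPaxElement-class] object.
#' @export
biopaxElement <- function(uri, biopaxType, displayName = NA_character_,
                          literals = list(), refs = list()) {
  new("BioPaxElement", uri = uri, biopaxType = biopaxType,
      displayName = as.character(displayName), literals = literals, refs = refs)
}

## ---------------------------------------------------------------------------
## BioPaxModel

#' BioPaxModel: URI-keyed store of BioPAX elements
#'
#' @slot level BioPAX level, 2 or 3. Models produced by [readBiopax()] are
#'   always at level 3 (level-2 input is upgraded).
#' @slot elements Named list of [BioPaxElement-class], keyed by URI.
#' @slot provenance Free-text source description.
#' @export
setClass("BioPaxModel",
  representation(level = "integer", elements = "list", provenance = "character"),
  prototype(level = 3L, elements = list(), provenance = NA_character_)
)

setValidity("BioPaxModel", function(object) {
  msgs <- character()
  if (!object@level %in% c(2L, 3L))
    msgs <- c(msgs, "level must be 2 or 3")
  uris <- vapply(object@elements, function(e) e@uri, character(1))
  if (length(uris)) {
    if (anyDuplicated(uris))
      msgs <- c(msgs, "duplicate element URIs")
    if (!identical(unname(names(object@elements)), unname(uris)))
      msgs <- c(msgs, "elements must be keyed by their own URI")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a BioPaxModel
#'
#' @param elements List of [BioPaxElement-class] objects.
#' @param level BioPAX level (2 or 3).
#' @param provenance Optional source description.
#' @return A [BioPaxModel-class].
#' @export
biopaxModel <- function(elements = list(), level = 3L,
                        provenance = NA_character_) {
  uris <- vapply(elements, function(e) e@uri, character(1))
  names(elements) <- uris
  elements <- elements[order(uris, method = "radix")]
  new("BioPaxModel", level = as.integer(level), elements = elements,
      provenance = as.character(provenance))
}

## ---------------------------------------------------------------------------
## ClassSet

#' ClassSet: a named partition of graph node ids
#'
#' @slot name Class-set name (for example `"BioPAX"`).
#' @slot classes Named list; each entry the character vector of node ids
#'   assigned to that class. Classes are disjoint.
#' @export
setClass("ClassSet",
  representation(name = "character", classes = "list"),
  prototype(classes = list())
)

setValidity("ClassSet", function(object) {
  msgs <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "name must be a single non-empty string")
  ids <- unlist(object@classes, use.names = FALSE)
  if (length(ids) && anyDuplicated(ids))
    msgs <- c(msgs, "classes must be disjoint (duplicate node ids found)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ClassSet
#' @param name Set name.
#' @param classes Named list of character id vectors.
#' @return A [ClassSet-class].
#' @export
classSet <- function(name, classes = list()) {
  classes <- lapply(classes, function(x)
    sort(unique(as.character(x)), method = "radix"))
  if (length(classes))
    classes <- classes[order(names(classes), method = "radix")]
  new("ClassSet", name = name, classes = classes)
}

## ---------------------------------------------------------------------------
## TypedGraph

.emptyNodes <- function() {
  data.frame(id = character(), biopaxClass = character(),
             label = character(), uri = character(),
             shape2d = character(), shape3d = character(),
             colour = character(), stringsAsFactors = FALSE)
}

.emptyEdges <- function() {
  data.frame(source = character(), target = character(), kind = character(),
             directed = logical(), stringsAsFactors = FALSE)
}

#' TypedGraph: a typed, styled pathway network
#'
#' Nodes carry their concrete BioPAX class, a display label, the originating
#' element URI and the mEPN-derived glyph (2D shape, 3D shape, colour).
#' Edges carry a kind (complex-component, pathway-component, pathway-step,
#' participant-left, participant-right, participant, controller, controlled,
#' member) and a per-edge directedness flag.
#'
#' @slot nodes data.frame with columns id, biopaxClass, label, uri, shape2d,
#'   shape3d, colour.
#' @slot edges data.frame with columns source, target, kind, directed.
#' @slot classSets Named list of [ClassSet-class] objects.
#' @export
setClass("TypedGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 classSets = "list"),
  prototype(nodes = .emptyNodes(), edges = .emptyEdges(), classSets = list())
)

setValidity("TypedGraph", function(object) {
  msgs <- character()
  nd <- object@nodes; ed <- object@edges
  need <- c("id", "biopaxClass", "label", "uri")
  if (!all(need %in% names(nd)))
    msgs <- c(msgs, "nodes must have columns id, biopaxClass, label, uri")
  if (anyDuplicated(nd$id))
    msgs <- c(msgs, "duplicate node ids")
  if (!all(c("source", "target", "kind", "directed") %in% names(ed)))
    msgs <- c(msgs, "edges must have columns source, target, kind, directed")
  else if (nrow(ed) &&
           !all(c(ed$source, ed$target) %in% nd$id))
    msgs <- c(msgs, "edge endpoints must be node ids")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TypedGraph
#'
#' @param nodes,edges Data frames as documented for [TypedGraph-class];
#'   missing style columns are filled from the glyph table.
#' @param classSets Named list of [ClassSet-class] objects.
#' @return A [TypedGraph-class].
#' @export
typedGraph <- function(nodes = .emptyNodes(), edges = .emptyEdges(),
                       classSets = list()) {
  for (col in c("shape2d", "shape3d", "colour")) {
    if (!col %in% names(nodes)) {
      nodes[[col]] <- if (nrow(nodes))
        vapply(nodes$biopaxClass, function(t) glyphForType(t)[[col]], character(1))
      else character()
    }
  }
  if (!"uri" %in% names(nodes))
    nodes$uri <- if (nrow(nodes)) nodes$id else character()
  if (!"label" %in% names(nodes))
    nodes$label <- if (nrow(nodes)) nodes$id else character()
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  edges$directed <- as.logical(edges$directed)
  new("TypedGraph", nodes = nodes, edges = edges, classSets = classSets)
}

## ---------------------------------------------------------------------------
## Layout

#' LayoutParams: parameters of the multilevel force-directed layout
#'
#' @slot edgeLength Natural edge length (arbitrary units, > 0).
#' @slot repulsion Repulsion constant (> 0).
#' @slot maxIter Maximum refinement sweeps per level.
#' @slot tol Convergence threshold on maximum node displacement.
#' @slot stopSize Coarsening stops when a level has at most this many nodes.
#' @export
setClass("LayoutParams",
  representation(edgeLength = "numeric", repulsion = "numeric",
                 maxIter = "integer", tol = "numeric", stopSize = "integer"))

setValidity("LayoutParams", function(object) {
  ok <- object@edgeLength > 0 && object@repulsion > 0 && object@maxIter > 0 &&
    object@tol > 0 && object@stopSize >= 2
  if (ok) TRUE else "all layout parameters must be positive (stopSize >= 2)"
})

#' @param edgeLength,repulsion,maxIter,tol,stopSize See slots of
#'   [LayoutParams-class].
#' @return A [LayoutParams-class].
#' @rdname LayoutParams-class
#' @export
layoutParams <- function(edgeLength = 1, repulsion = 1, maxIter = 60L,
                         tol = 1e-3, stopSize = 10L) {
  new("LayoutParams", edgeLength = edgeLength, repulsion = repulsion,
      maxIter = as.integer(maxIter), tol = tol, stopSize = as.integer(stopSize))
}

#' LayoutResult: node coordinates produced by the layout engine
#'
#' @slot coordinates Numeric matrix, one row per node (rownames are node
#'   ids), 2 or 3 columns; centred at the origin.
#' @slot dims 2 or 3.
#' @slot seed Random seed used.
#' @slot iterationsUsed Total refinement sweeps across all levels.
#' @slot energyTrace List (one numeric vector per level, coarsest first) of
#'   the total layout energy after each accepted sweep.
#' @export
setClass("LayoutResult",
  representation(coordinates = "matrix", dims = "integer", seed = "integer",
                 iterationsUsed = "integer", energyTrace = "list"))

setValidity("LayoutResult", function(object) {
  msgs <- character()
  if (!object@dims %in% c(2L, 3L)) msgs <- c(msgs, "dims must be 2 or 3")
  if (ncol(object@coordinates) != object@dims)
    msgs <- c(msgs, "coordinate columns must equal dims")
  if (nrow(object@coordinates) && !all(is.finite(object@coordinates)))
    msgs <- c(msgs, "all coordinates must be finite")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Search (Pathway Commons client)

#' SearchPage: one page of Pathway Commons search hits
#'
#' @slot hits data.frame with columns uri, name, organism, source, excerpt,
#'   numInteractions (NA for non-pathway hits).
#' @slot totalHits Total number of hits for the query.
#' @slot page Zero-based page index.
#' @slot pageSize Service page size (500).
#' @export
setClass("SearchPage",
  representation(hits = "data.frame", totalHits = "integer", page = "integer",
                 pageSize = "integer"),
  prototype(totalHits = 0L, page = 0L, pageSize = 500L))

setValidity("SearchPage", function(object) {
  if (nrow(object@hits) > object@pageSize)
    "a page may not hold more hits than pageSize" else TRUE
})

## ---------------------------------------------------------------------------
## Generator

#' GeneratorSpec: parameters of the synthetic pathway-model generator
#'
#' @slot nPathways,nReactions,nProteins,nSmallMolecules,nComplexes
#'   Non-negative element counts.
#' @slot meanComplexSize Mean number of components per complex.
#' @slot controlFraction Share of reactions receiving a Catalysis, in [0,1].
#' @slot nestingDepth Maximum sub-pathway nesting depth.
#' @slot seed Integer random seed.
#' @export
setClass("GeneratorSpec",
  representation(nPathways = "integer", nReactions = "integer",
                 nProteins = "integer", nSmallMolecules = "integer",
                 nComplexes = "integer", meanComplexSize = "numeric",
                 controlFraction = "numeric", nestingDepth = "integer",
                 seed = "integer"))

setValidity("GeneratorSpec", function(object) {
  msgs <- character()
  cnts <- c(object@nPathways, object@nReactions, object@nProteins,
            object@nSmallMolecules, object@nComplexes, object@nestingDepth)
  if (any(cnts < 0)) msgs <- c(msgs, "all counts must be >= 0")
  if (object@controlFraction < 0 || object@controlFraction > 1)
    msgs <- c(msgs, "controlFraction must lie in [0, 1]")
  if (object@meanComplexSize < 1) msgs <- c(msgs, "meanComplexSize must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' @param nPathways,nReactions,nProteins,nSmallMolecules,nComplexes,meanComplexSize,controlFraction,nestingDepth,seed
#'   See slots of [GeneratorSpec-class].
#' @return A [GeneratorSpec-class].
#' @rdname GeneratorSpec-class
#' @export
generatorSpec <- function(nPathways = 1L, nReactions = 4L, nProteins = 8L,
                          nSmallMolecules = 2L, nComplexes = 1L,
                          meanComplexSize = 3, controlFraction = 0.5,
                          nestingDepth = 0L, seed = 1L) {
  new("GeneratorSpec", nPathways = as.integer(nPathways),
      nReactions = as.integer(nReactions), nProteins = as.integer(nProteins),
      nSmallMolecules = as.integer(nSmallMolecules),
      nComplexes = as.integer(nComplexes),
      meanComplexSize = meanComplexSize, controlFraction = controlFraction,
      nestingDepth = as.integer(nestingDepth), seed = as.integer(seed))
}
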