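## GraphML interchange. Declared keys: node class/label/uri/shape2d/shape3d/
## colour (strings), x/y/z (doubles, when a layout is given), edge kind
## (string); per-edge directedness is expressed with the standard GraphML
## `directed` edge attribute.

.GRAPHML_NS <- "http://graphml.graphdrawing.org/xmlns"

.NODE_KEYS <- c(class = "biopaxClass", label = "label", uri = "uri",
                shape2d = "shape2d", shape3d = "shape3d", colour = "colour")

#' Write a typed graph as GraphML
#'
#' @param graph A [TypedGraph-class].
#' @param path Output file path.
#' @param layout Optional [LayoutResult-class]; its coordinates are written
#'   as x/y (and z for 3D layouts) node attributes.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(graph, path, layout = NULL) {
  doc <- xml2::xml_new_root("graphml", xmlns = .GRAPHML_NS)
  addKey <- function(id, dom, type) {
    xml2::xml_add_child(doc, "key", id = id, `for` = dom,
                        `attr.name` = id, `attr.type` = type)
  }
  for (k in names(.NODE_KEYS)) addKey(k, "node", "string")
  coordCols <- character()
  if (!is.null(layout)) {
    coordCols <- c("x", "y", if (layout@dims == 3L) "z")
    for (k in coordCols) addKey(k, "node", "double")
  }
  addKey("kind", "edge", "string")
  gnode <- xml2::xml_add_child(doc, "graph", id = "G",
                               edgedefault = "directed")
  nd <- graphNodes(graph)
  coords <- if (!is.null(layout)) layout@coordinates else NULL
  for (i in seq_len(nrow(nd))) {
    n <- xml2::xml_add_child(gnode, "node", id = nd$id[i])
    for (k in names(.NODE_KEYS)) {
      d <- xml2::xml_add_child(n, "data", key = k)
      xml2::xml_text(d) <- as.character(nd[[.NODE_KEYS[[k]]]][i])
    }
    if (!is.null(coords)) {
      xy <- coords[nd$id[i], ]
      for (j in seq_along(coordCols)) {
        d <- xml2::xml_add_child(n, "data", key = coordCols[j])
        xml2::xml_text(d) <- sprintf("%.17g", xy[[j]])
      }
    }
  }
  ed <- graphEdges(graph)
  for (i in seq_len(nrow(ed))) {
    e <- xml2::xml_add_child(gnode, "edge", source = ed$source[i],
                             target = ed$target[i],
                             directed = if (ed$directed[i]) "true" else "false")
    d <- xml2::xml_add_child(e, "data", key = "kind")
    xml2::xml_text(d) <- ed$kind[i]
  }
  tryCatch(xml2::write_xml(doc, path),
           error = function(e) bpStop("ioError", conditionMessage(e)))
  invisible(path)
}

#' Read GraphML into a typed graph
#'
#' Inverse of [writeGraphML()] on its own output. Foreign GraphML without
#' this package's keys loads with default class `"PhysicalEntity"`, edge
#' kind `"participant"` and a warning. Coordinates, when present, are
#' returned as a [LayoutResult-class].
#'
#' @param path GraphML file path.
#' @return List with elements `graph` ([TypedGraph-class]) and `layout`
#'   ([LayoutResult-class] or `NULL`).
#' @export
readGraphML <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    bpStop("parseError", sprintf("not well-formed GraphML: %s",
                                 conditionMessage(e))))
  xml2::xml_ns_strip(doc)
  gnode <- xml2::xml_find_first(doc, ".//graph")
  if (inherits(gnode, "xml_missing"))
    bpStop("parseError", "no <graph> element found")
  edgeDefault <- identical(xml2::xml_attr(gnode, "edgedefault"), "directed")
  keys <- xml2::xml_find_all(doc, ".//key")
  keyIds <- xml2::xml_attr(keys, "id")
  foreign <- !all(c("class", "kind") %in% keyIds)
  if (foreign)
    bpWarn("foreignGraphmlWarning",
           "GraphML lacks biopaxnet keys; defaulting classes and edge kinds")

  nodeEls <- xml2::xml_find_all(gnode, "./node")
  getData <- function(el, key) {
    d <- xml2::xml_find_first(el, sprintf("./data[@key='%s']", key))
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  ids <- xml2::xml_attr(nodeEls, "id")
  col <- function(key) vapply(nodeEls, getData, character(1), key)
  cls <- col("class"); cls[is.na(cls)] <- "PhysicalEntity"
  lab <- col("label"); lab[is.na(lab)] <- ids[is.na(lab)]
  uri <- col("uri"); uri[is.na(uri)] <- ids[is.na(uri)]
  nodes <- data.frame(id = ids, biopaxClass = cls, label = lab, uri = uri,
                      stringsAsFactors = FALSE)
  for (sc in c("shape2d", "shape3d", "colour")) {
    v <- col(sc)
    if (!all(is.na(v))) nodes[[sc]] <- v
  }
  xs <- suppressWarnings(as.numeric(col("x")))
  ys <- suppressWarnings(as.numeric(col("y")))
  zs <- suppressWarnings(as.numeric(col("z")))
  layout <- NULL
  if (length(ids) && !anyNA(xs) && !anyNA(ys)) {
    dims <- if (!anyNA(zs)) 3L else 2L
    coords <- cbind(x = xs, y = ys, if (dims == 3L) zs)
    rownames(coords) <- ids
    layout <- new("LayoutResult", coordinates = coords, dims = dims,
                  seed = NA_integer_, iterationsUsed = 0L,
                  energyTrace = list())
  }

  edgeEls <- xml2::xml_find_all(gnode, "./edge")
  kind <- vapply(edgeEls, getData, character(1), "kind")
  kind[is.na(kind)] <- "participant"
  dirAttr <- xml2::xml_attr(edgeEls, "directed")
  directed <- ifelse(is.na(dirAttr), edgeDefault, dirAttr == "true")
  edges <- data.frame(source = xml2::xml_attr(edgeEls, "source"),
                      target = xml2::xml_attr(edgeEls, "target"),
                      kind = kind, directed = directed,
                      stringsAsFactors = FALSE)
  g <- typedGraph(nodes, edges)
  g@classSets <- list(BioPAX = buildClassSet(g))
  list(graph = g, layout = layout)
}
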