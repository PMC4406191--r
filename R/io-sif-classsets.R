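## SIF and class-set file exchange.
##
## SIF: one line per edge, "source<TAB>kind<TAB>target", sorted
## lexicographically so output is byte-identical across runs.
##
## Class-set file: tab-separated (node id, class set name, class name), one
## assignment per line, '#' comments, UTF-8. The format enables
## cross-network highlighting: class sets exported from one network can be
## imported onto another that shares node identifiers.

#' Write a graph in SIF format
#'
#' @param graph A [TypedGraph-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeSIF <- function(graph, path) {
  ed <- graphEdges(graph)
  lines <- sprintf("%s\t%s\t%s", ed$source, ed$kind, ed$target)
  con <- tryCatch(file(path, "w", encoding = "UTF-8"), error = function(e)
    bpStop("ioError", conditionMessage(e)))
  on.exit(close(con))
  writeLines(sort(lines, method = "radix"), con)
  invisible(path)
}

#' Export the class sets of a graph
#'
#' @param graph A [TypedGraph-class] with at least one class set.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
exportClassSets <- function(graph, path) {
  sets <- classSets(graph)
  lines <- character()
  for (cs in sets)
    for (cl in names(cs@classes))
      lines <- c(lines, sprintf("%s\t%s\t%s", cs@classes[[cl]], cs@name, cl))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"), error = function(e)
    bpStop("ioError", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c("# node_id\tclass_set\tclass", sort(lines, method = "radix")),
             con)
  invisible(path)
}

#' Import class sets onto a graph
#'
#' Reads a class-set file and attaches its sets to the graph. Node ids in
#' the file that do not exist in the graph are skipped; the number of
#' skipped assignments is reported in a warning and in the `"skipped"`
#' attribute of the result.
#'
#' @param graph A [TypedGraph-class].
#' @param path Class-set file path.
#' @return The graph with the imported class sets attached (replacing sets
#'   of the same name).
#' @export
importClassSets <- function(graph, path) {
  raw <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", raw)
  lineNo <- which(keep)
  rows <- strsplit(raw[keep], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 3L |
                 vapply(rows, function(r) any(!nzchar(r)), logical(1)))
  if (length(bad))
    bpStop("parseError",
           sprintf("malformed class-set line %d: '%s'",
                   lineNo[bad[1L]], raw[lineNo[bad[1L]]]))
  ids <- vapply(rows, `[[`, character(1), 1L)
  setNames_ <- vapply(rows, `[[`, character(1), 2L)
  classes <- vapply(rows, `[[`, character(1), 3L)
  known <- ids %in% graphNodes(graph)$id
  skipped <- sum(!known)
  if (skipped)
    bpWarn("unknownNodeWarning",
           sprintf("skipped %d assignment(s) for node id(s) absent from the graph",
                   skipped))
  sets <- classSets(graph)
  for (sn in unique(setNames_)) {
    sel <- setNames_ == sn & known
    sets[[sn]] <- classSet(sn, split(ids[sel], classes[sel]))
  }
  graph@classSets <- sets
  attr(graph, "skipped") <- skipped
  graph
}
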