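## Operations on the in-memory BioPAX object model.

#' Query model elements by BioPAX type
#'
#' @param model A [BioPaxModel-class].
#' @param type_name Supported type name.
#' @param includeSubtypes If `TRUE` (default), elements whose type descends
#'   from `type_name` are returned as well; otherwise strict type equality.
#' @return List of [BioPaxElement-class], sorted by URI.
#' @export
#' @examples
#' m <- biopaxModel(list(biopaxElement("http://x/cat1", "Catalysis")))
#' length(getElementsOfType(m, "Control"))                         # 1
#' length(getElementsOfType(m, "Control", includeSubtypes = FALSE)) # 0
getElementsOfType <- function(model, type_name, includeSubtypes = TRUE) {
  .checkType(type_name)
  wanted <- if (includeSubtypes) biopaxSubtypes(type_name) else type_name
  els <- model@elements
  keep <- vapply(els, function(e) e@biopaxType %in% wanted, logical(1))
  els <- els[keep]
  els[order(names(els), method = "radix")]
}

## Reference-property values of an element (character(0) when absent).
bpRefs <- function(el, prop) {
  v <- el@refs[[prop]]
  if (is.null(v)) character(0) else v
}

## First literal value of a property, or NA.
bpLiteral <- function(el, prop) {
  v <- el@literals[[prop]]
  if (is.null(v) || !length(v)) NA_character_ else v[[1L]]
}

#' Unresolved cross-references of a model
#'
#' @param model A [BioPaxModel-class].
#' @return Character vector of referenced URIs with no matching element.
#' @export
danglingRefs <- function(model) {
  uris <- names(model@elements)
  refs <- unlist(lapply(model@elements, function(e)
    unlist(e@refs, use.names = FALSE)), use.names = FALSE)
  sort(unique(refs[!refs %in% uris]))
}

## Resolve dangling references: strict -> error; otherwise insert root-typed
## placeholder elements (marked with literal placeholder = "true") + warning.
resolveModel <- function(model, strict = FALSE) {
  dang <- danglingRefs(model)
  if (!length(dang)) return(model)
  if (strict)
    bpStop("danglingReferenceError",
           sprintf("unresolved references: %s", paste(dang, collapse = ", ")))
  bpWarn("danglingReferenceWarning",
         sprintf("%d unresolved reference(s) replaced by placeholder elements: %s",
                 length(dang), paste(dang, collapse = ", ")))
  ph <- lapply(dang, function(u)
    biopaxElement(u, "BioPaxElement",
                  literals = list(placeholder = "true")))
  biopaxModel(c(unname(model@elements), ph), level = model@level,
              provenance = model@provenance)
}

## TRUE for placeholder elements inserted for dangling references.
isPlaceholder <- function(el) {
  identical(bpLiteral(el, "placeholder"), "true")
}
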