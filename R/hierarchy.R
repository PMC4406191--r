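## Supported subset of the BioPAX Level 3 class hierarchy, kept as a rooted
## tree (child -> parent). "BioPaxElement" is the artificial root; utility
## classes outside the subset are retained at the root when encountered.

.BIOPAX_PARENT <- c(
  Entity                           = "BioPaxElement",
  Pathway                          = "Entity",
  Interaction                      = "Entity",
  Control                          = "Interaction",
  Catalysis                        = "Control",
  Modulation                       = "Control",
  TemplateReactionRegulation       = "Control",
  Conversion                       = "Interaction",
  BiochemicalReaction              = "Conversion",
  TransportWithBiochemicalReaction = "BiochemicalReaction",
  ComplexAssembly                  = "Conversion",
  Degradation                      = "Conversion",
  Transport                        = "Conversion",
  TemplateReaction                 = "Interaction",
  MolecularInteraction             = "Interaction",
  GeneticInteraction               = "Interaction",
  PhysicalEntity                   = "Entity",
  Protein                          = "PhysicalEntity",
  SmallMolecule                    = "PhysicalEntity",
  Dna                              = "PhysicalEntity",
  DnaRegion                        = "PhysicalEntity",
  Rna                              = "PhysicalEntity",
  RnaRegion                        = "PhysicalEntity",
  Complex                          = "PhysicalEntity",
  Gene                             = "Entity",
  EntityReference                  = "BioPaxElement",
  ProteinReference                 = "EntityReference",
  SmallMoleculeReference           = "EntityReference",
  DnaReference                     = "EntityReference",
  RnaReference                     = "EntityReference",
  PathwayStep                      = "BioPaxElement",
  BiochemicalPathwayStep           = "PathwayStep"
)

#' Supported BioPAX type names
#'
#' The package models a fixed subset of the BioPAX Level 3 ontology as a
#' rooted tree. `supportedBiopaxTypes()` lists every supported type name,
#' including the artificial root `"BioPaxElement"`.
#'
#' @return Character vector of type names, sorted.
#' @export
#' @examples
#' "Catalysis" %in% supportedBiopaxTypes()
supportedBiopaxTypes <- function() {
  sort(c("BioPaxElement", names(.BIOPAX_PARENT)))
}

.checkType <- function(type_name) {
  if (length(type_name) != 1L || !type_name %in% supportedBiopaxTypes())
    bpStop("unsupportedTypeError",
           sprintf("unsupported BioPAX type: '%s'", paste(type_name, collapse = ",")))
  invisible(type_name)
}

#' Ancestor chain of a supported BioPAX type
#'
#' @param type_name A supported type name.
#' @return Character vector from `type_name` up to the root (inclusive).
#' @export
biopaxAncestors <- function(type_name) {
  .checkType(type_name)
  chain <- type_name
  while (type_name != "BioPaxElement") {
    type_name <- unname(.BIOPAX_PARENT[[type_name]])
    chain <- c(chain, type_name)
  }
  chain
}

#' Subtype test on the supported BioPAX hierarchy
#'
#' `isA(x, ancestor)` is `TRUE` iff `ancestor` lies on the parent chain of
#' `x`, inclusively (so `isA(t, t)` is always `TRUE`).
#'
#' @param type_name,ancestor Supported type names.
#' @return Logical scalar.
#' @export
#' @examples
#' isA("BiochemicalReaction", "Conversion")  # TRUE
#' isA("Protein", "Interaction")             # FALSE
isA <- function(type_name, ancestor) {
  .checkType(ancestor)
  ancestor %in% biopaxAncestors(type_name)
}

#' Descendants of a supported BioPAX type
#'
#' @param type_name A supported type name.
#' @return Character vector of all types `t` with `isA(t, type_name)`,
#'   including `type_name` itself; sorted.
#' @export
biopaxSubtypes <- function(type_name) {
  .checkType(type_name)
  all <- supportedBiopaxTypes()
  sort(all[vapply(all, function(t) type_name %in% biopaxAncestors(t), logical(1))])
}

## Types whose instances become graph nodes.
.NODE_ROOTS <- c("Pathway", "Interaction", "PhysicalEntity", "Gene")

.isNodeType <- function(type_name) {
  any(vapply(.NODE_ROOTS, function(r) isA(type_name, r), logical(1)))
}
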