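## BioPAX OWL (RDF/XML) reading and writing, level detection, and the
## Level-2 -> Level-3 upgrade applied before graph construction.

.NS_RDF <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
.NS_BP3 <- "http://www.biopax.org/release/biopax-level3.owl#"
.NS_BP2 <- "http://www.biopax.org/release/biopax-level2.owl#"
.NS_BP1 <- "http://www.biopax.org/release/biopax-level1.owl#"
.NS_OWL <- "http://www.w3.org/2002/07/owl#"

## Level-3 class names outside the supported subset are retained at the
## nearest supported ancestor. Known utility classes sit at the root.
.L3_FALLBACK <- c(
  UtilityClass = "BioPaxElement", Stoichiometry = "BioPaxElement",
  BioSource = "BioPaxElement", Provenance = "BioPaxElement",
  Evidence = "BioPaxElement", Score = "BioPaxElement",
  SequenceSite = "BioPaxElement", SequenceInterval = "BioPaxElement",
  SequenceLocation = "BioPaxElement", ExperimentalForm = "BioPaxElement",
  DeltaG = "BioPaxElement", KPrime = "BioPaxElement",
  ChemicalStructure = "BioPaxElement"
)

.L2_CLASS_MAP <- c(
  protein = "Protein", smallMolecule = "SmallMolecule", complex = "Complex",
  pathway = "Pathway", biochemicalReaction = "BiochemicalReaction",
  catalysis = "Catalysis", control = "Control", modulation = "Modulation",
  transport = "Transport",
  transportWithBiochemicalReaction = "TransportWithBiochemicalReaction",
  complexAssembly = "ComplexAssembly", conversion = "Conversion",
  interaction = "Interaction", physicalInteraction = "MolecularInteraction",
  physicalEntity = "PhysicalEntity", dna = "Dna", rna = "Rna",
  pathwayStep = "PathwayStep"
)
.L2_WRAPPERS <- c("physicalEntityParticipant", "sequenceParticipant")

.L2_PROP_MAP <- c(
  "LEFT" = "left", "RIGHT" = "right", "CONTROLLER" = "controller",
  "CONTROLLED" = "controlled", "COMPONENTS" = "component",
  "PATHWAY-COMPONENTS" = "pathwayComponent", "PARTICIPANTS" = "participant",
  "STEP-INTERACTIONS" = "stepProcess", "NEXT-STEP" = "nextStep",
  "NAME" = "displayName", "SHORT-NAME" = "displayName",
  "SYNONYMS" = "name", "COMMENT" = "comment", "ORGANISM" = "organism",
  "CELLULAR-LOCATION" = "cellularLocation"
)

## Map an input class name to a supported type; unknown names fall back to
## the root with a warning (graceful degradation).
.normaliseL3Type <- function(name) {
  if (name %in% supportedBiopaxTypes()) return(name)
  if (name %in% names(.L3_FALLBACK)) return(unname(.L3_FALLBACK[[name]]))
  if (grepl("Xref$", name) || grepl("Vocabulary$", name)) return("BioPaxElement")
  if (grepl("Reference$", name)) return("EntityReference")
  bpWarn("unsupportedClassWarning",
         sprintf("unsupported BioPAX class '%s' retained as root type", name))
  "BioPaxElement"
}

.asXmlDoc <- function(source) {
  if (inherits(source, "xml_document")) return(source)
  tryCatch({
    if (is.character(source) && length(source) == 1L &&
        grepl("^\\s*<", source)) {
      xml2::read_xml(source)
    } else {
      xml2::read_xml(source)
    }
  }, error = function(e) {
    bpStop("parseError", sprintf("not well-formed XML: %s", conditionMessage(e)))
  })
}

#' Detect the BioPAX level of an OWL document
#'
#' @param source File path, XML text, or an `xml_document`.
#' @return Integer 3 or 2, per the declared BioPAX namespace.
#' @export
detectLevel <- function(source) {
  doc <- .asXmlDoc(source)
  uris <- as.character(xml2::xml_ns(doc))
  if (.NS_BP3 %in% uris) return(3L)
  if (.NS_BP2 %in% uris) return(2L)
  if (.NS_BP1 %in% uris || any(grepl("biopax", uris, fixed = TRUE)))
    bpStop("unsupportedLevelError",
           "document declares an unsupported BioPAX level (only Levels 2 and 3 are read)")
  bpStop("notBiopaxError", "document declares no BioPAX namespace")
}

.baseIri <- function(doc) {
  root <- xml2::xml_root(doc)
  at <- xml2::xml_attrs(root)
  b <- at[names(at) %in% c("xml:base", "base")]
  if (length(b)) unname(b[[1L]]) else ""
}

.resolveIri <- function(ref, base) {
  if (startsWith(ref, "#")) paste0(base, ref) else ref
}

## Parse one RDF node element (typed resource). Nested typed elements are
## hoisted into their own records; the parent keeps a reference.
.parseNode <- function(node, base, bpUri, sink) {
  local <- xml2::xml_name(node)
  uri <- xml2::xml_attr(node, "about")
  if (is.na(uri)) {
    id <- xml2::xml_attr(node, "ID")
    uri <- if (!is.na(id)) paste0(base, "#", id) else {
      sink$anon <- sink$anon + 1L
      sprintf("urn:anon:%d", sink$anon)
    }
  } else {
    uri <- .resolveIri(uri, base)
  }
  literals <- list(); refs <- list()
  for (child in xml2::xml_children(node)) {
    pname <- xml2::xml_name(child)
    res <- xml2::xml_attr(child, "resource")
    kids <- xml2::xml_children(child)
    if (!is.na(res)) {
      refs[[pname]] <- c(refs[[pname]], .resolveIri(res, base))
    } else if (length(kids)) {
      for (k in kids) {
        kuri <- .parseNode(k, base, bpUri, sink)
        refs[[pname]] <- c(refs[[pname]], kuri)
      }
    } else {
      literals[[pname]] <- c(literals[[pname]], xml2::xml_text(child))
    }
  }
  sink$records[[length(sink$records) + 1L]] <-
    list(uri = uri, class = local, literals = literals, refs = refs)
  uri
}

#' Read a BioPAX OWL document
#'
#' Parses BioPAX Level 2 or Level 3 RDF/XML into a [BioPaxModel-class].
#' Level-2 documents are upgraded to Level 3 before being returned (set
#' `upgrade = FALSE` to obtain the raw Level-2 model). Dangling
#' `rdf:resource` references are replaced by placeholder elements with a
#' warning; with `strict = TRUE` they raise an error instead.
#'
#' @param source File path, XML text, or an `xml_document`.
#' @param strict Raise an error on unresolved references (default `FALSE`).
#' @param upgrade Upgrade Level-2 models to Level 3 (default `TRUE`).
#' @return A resolved [BioPaxModel-class] (at Level 3 unless
#'   `upgrade = FALSE` on Level-2 input).
#' @export
#' @examples
#' owl <- system.file("extdata", "toy_l3.owl", package = "biopaxnet")
#' m <- readBiopax(owl)
#' length(m)  # 11
readBiopax <- function(source, strict = FALSE, upgrade = TRUE) {
  doc <- .asXmlDoc(source)
  level <- detectLevel(doc)
  base <- .baseIri(doc)
  sink <- new.env(parent = emptyenv())
  sink$records <- list(); sink$anon <- 0L
  for (node in xml2::xml_children(xml2::xml_root(doc))) {
    local <- xml2::xml_name(node)
    if (local %in% c("Ontology", "imports")) next  # owl:imports ignored
    .parseNode(node, base, .NS_BP3, sink)
  }
  els <- lapply(sink$records, function(r) {
    if (level == 3L) {
      type <- .normaliseL3Type(r$class)
      dn <- if (!is.null(r$literals$displayName)) r$literals$displayName[[1L]]
            else if (!is.null(r$literals$standardName)) r$literals$standardName[[1L]]
            else if (!is.null(r$literals$name)) r$literals$name[[1L]]
            else NA_character_
      biopaxElement(r$uri, type, displayName = dn,
                    literals = r$literals, refs = r$refs)
    } else {
      ## Level 2: keep raw class/property names for the upgrade step.
      lits <- r$literals
      lits[["_l2Class"]] <- r$class
      provisional <- if (r$class %in% .L2_WRAPPERS) "PhysicalEntity"
                     else if (r$class %in% names(.L2_CLASS_MAP))
                       unname(.L2_CLASS_MAP[[r$class]])
                     else "BioPaxElement"
      dn <- if (!is.null(r$literals$NAME)) r$literals$NAME[[1L]]
            else if (!is.null(r$literals$`SHORT-NAME`)) r$literals$`SHORT-NAME`[[1L]]
            else NA_character_
      biopaxElement(r$uri, provisional, displayName = dn,
                    literals = lits, refs = r$refs)
    }
  })
  ## Duplicate rdf:about entries: keep the first occurrence.
  uris <- vapply(els, function(e) e@uri, character(1))
  els <- els[!duplicated(uris)]
  model <- biopaxModel(els, level = level)
  model <- resolveModel(model, strict = strict)
  if (level == 2L && upgrade) model <- upgradeToL3(model)
  model
}

#' Upgrade a Level-2 model to Level 3
#'
#' Maps Level-2 classes to their Level-3 equivalents, translates the
#' Level-2 ALL-CAPS property names, and collapses the Level-2
#' `physicalEntityParticipant` indirection so that interactions and
#' complexes reference the physical entities directly. The participant
#' wrappers are removed, so the upgraded model has `n - w` elements where
#' `w` is the number of wrappers.
#'
#' @param model A [BioPaxModel-class] at level 2.
#' @return The upgraded [BioPaxModel-class] at level 3.
#' @export
upgradeToL3 <- function(model) {
  if (model@level != 2L)
    bpStop("alreadyLevel3Error", "model is already at BioPAX Level 3")
  els <- model@elements
  l2class <- vapply(els, function(e) {
    c <- bpLiteral(e, "_l2Class"); if (is.na(c)) "" else c
  }, character(1))
  isWrap <- l2class %in% .L2_WRAPPERS
  ## wrapper URI -> wrapped physical entity URI
  wmap <- vapply(els[isWrap], function(e) {
    tgt <- bpRefs(e, "PHYSICAL-ENTITY")
    if (!length(tgt)) e@uri else tgt[[1L]]
  }, character(1))
  subst <- function(uris) {
    hit <- uris %in% names(wmap)
    uris[hit] <- unname(wmap[uris[hit]])
    uris
  }
  out <- lapply(els[!isWrap], function(e) {
    cls <- bpLiteral(e, "_l2Class")
    newType <- if (!is.na(cls) && cls %in% names(.L2_CLASS_MAP)) {
      unname(.L2_CLASS_MAP[[cls]])
    } else if (is.na(cls)) {
      e@biopaxType   # placeholder inserted during resolution
    } else {
      bpWarn("unsupportedClassWarning",
             sprintf("unmapped Level-2 class '%s' retained as root type", cls))
      "BioPaxElement"
    }
    refs <- e@refs
    if (length(refs)) {
      names(refs) <- vapply(names(refs), function(p) {
        if (p %in% names(.L2_PROP_MAP)) unname(.L2_PROP_MAP[[p]]) else p
      }, character(1))
      refs <- lapply(refs, subst)
      ## merge duplicate property names produced by the renaming
      refs <- tapply(unlist(refs, use.names = FALSE),
                     rep(names(refs), lengths(refs)), c, simplify = FALSE)
      refs <- lapply(refs, unname)
    }
    lits <- e@literals
    lits[["_l2Class"]] <- NULL
    if (length(lits)) {
      names(lits) <- vapply(names(lits), function(p) {
        if (p %in% names(.L2_PROP_MAP)) unname(.L2_PROP_MAP[[p]]) else p
      }, character(1))
      lits <- tapply(unlist(lits, use.names = FALSE),
                     rep(names(lits), lengths(lits)), c, simplify = FALSE)
      lits <- lapply(lits, unname)
    }
    biopaxElement(e@uri, newType, displayName = e@displayName,
                  literals = lits, refs = refs)
  })
  biopaxModel(unname(out), level = 3L, provenance = model@provenance)
}

#' Write a Level-3 model as BioPAX OWL (RDF/XML)
#'
#' Emits the conventional abbreviated RDF/XML form, one typed element per
#' top-level node, deterministically ordered (elements by URI, properties by
#' name), so identical models serialize byte-identically. Placeholder
#' elements inserted for dangling references are not written (they are
#' regenerated on re-read); with `strict = TRUE` their presence is an error.
#'
#' @param model A [BioPaxModel-class] at level 3.
#' @param path Output file path.
#' @param strict Refuse to write models containing placeholder elements.
#' @return `path`, invisibly.
#' @export
writeBiopax <- function(model, path, strict = FALSE) {
  if (model@level != 3L)
    bpStop("levelPreconditionError", "only Level-3 models are written")
  ph <- vapply(model@elements, isPlaceholder, logical(1))
  if (strict && any(ph))
    bpStop("placeholderWriteError",
           "model contains placeholder elements for unresolved references")
  doc <- xml2::xml_new_root(
    "rdf:RDF",
    "xmlns:rdf" = .NS_RDF, "xmlns:bp" = .NS_BP3, "xmlns:owl" = .NS_OWL
  )
  els <- model@elements[!ph]
  for (uri in sort(names(els), method = "radix")) {
    e <- els[[uri]]
    tname <- if (e@biopaxType == "BioPaxElement") "UtilityClass" else e@biopaxType
    node <- xml2::xml_add_child(doc, paste0("bp:", tname), "rdf:about" = e@uri)
    lits <- e@literals
    if (!is.na(e@displayName) && is.null(lits[["displayName"]]))
      lits[["displayName"]] <- e@displayName
    for (p in sort(as.character(names(lits)), method = "radix")) {
      if (startsWith(p, "_")) next
      for (v in lits[[p]])
        xml2::xml_add_child(node, paste0("bp:", p), v)
    }
    for (p in sort(as.character(names(e@refs)), method = "radix")) {
      for (v in e@refs[[p]])
        xml2::xml_add_child(node, paste0("bp:", p), "rdf:resource" = v)
    }
  }
  tryCatch(xml2::write_xml(doc, path),
           error = function(e) bpStop("ioError", conditionMessage(e)))
  invisible(path)
}
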