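## Synthetic fixtures: hand-authored toy BioPAX documents shipped under
## extdata/, and a seeded random generator of Level-3 pathway models whose
## exact expected graph composition is recorded during generation. The
## recorded expectations serve as the central cross-module oracle: a graph
## built from a generated model must reproduce them exactly.

#' Shipped toy BioPAX documents
#'
#' * `toy_l3` — one pathway with two biochemical reactions over four
#'   proteins plus a two-component complex (Level 3; 11 elements counting
#'   the entity references).
#' * `toy_l2` — the same pathway authored in Level 2 with
#'   `physicalEntityParticipant` wrappers.
#' * `diamond` — a conversion/control diamond used by the Common Stream
#'   examples (two reactions producing one protein that feeds a third,
#'   catalysed reaction).
#' * `nested` — a pathway with a sub-pathway, for recursive interaction
#'   counting (3 interactions in the outer pathway, 2 in the inner).
#'
#' @return Named character vector of file paths.
#' @export
toyDocuments <- function() {
  f <- function(name) system.file("extdata", name, package = "biopaxnet",
                                  mustWork = TRUE)
  c(toy_l3 = f("toy_l3.owl"), toy_l2 = f("toy_l2.owl"),
    diamond = f("diamond.owl"), nested = f("nested.owl"))
}

.GEN_BASE <- "http://example.org/gen#"

## Run `expr` under a fixed seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Generate a random Level-3 pathway model with known composition
#'
#' Emits proteins and small molecules (proteins carry entity references),
#' complexes with components drawn from the entity pool, biochemical
#' reactions with 1-2 left and 1-2 right participants, catalyses on a
#' `controlFraction` share of reactions, and pathways partitioning the
#' reactions, optionally nested up to `nestingDepth`. Alongside the model
#' it returns the exact expected node and edge counts per kind and the
#' per-pathway recursive interaction counts, recorded during generation
#' (not recomputed), so graph-construction bugs cannot cancel out.
#'
#' @param spec A [GeneratorSpec-class] from [generatorSpec()].
#' @return List with elements `model` ([BioPaxModel-class]) and `expected`
#'   (list with `nNodes`, `nEdges`, `nodesByClass`, `edgesByKind`,
#'   `perPathwayInteractions`).
#' @export
#' @examples
#' gm <- generateModel(generatorSpec(nPathways = 1, nReactions = 2,
#'                                   nProteins = 4, nSmallMolecules = 0,
#'                                   nComplexes = 0, controlFraction = 0,
#'                                   seed = 7))
#' gm$expected$nNodes
generateModel <- function(spec) {
  validObject(spec)
  poolSize <- spec@nProteins + spec@nSmallMolecules
  cxSize <- max(1L, round(spec@meanComplexSize))
  if (spec@nComplexes > 0L && cxSize > poolSize)
    bpStop("specError", "complex size exceeds the entity pool")
  if (spec@nReactions > 0L && poolSize + spec@nComplexes < 2L)
    bpStop("specError", "reactions need at least two candidate participants")
  nCat <- round(spec@controlFraction * spec@nReactions)
  if (nCat > 0L && spec@nProteins < 1L)
    bpStop("specError", "catalyses need at least one protein controller")

  .withSeed(spec@seed, {
    els <- list()
    add <- function(e) els[[length(els) + 1L]] <<- e
    uriOf <- function(id) paste0(.GEN_BASE, id)

    proteins <- sprintf("p%03d", seq_len(spec@nProteins))
    smols <- sprintf("sm%03d", seq_len(spec@nSmallMolecules))
    for (id in proteins) {
      add(biopaxElement(uriOf(paste0("ref_", id)), "ProteinReference"))
      add(biopaxElement(uriOf(id), "Protein", displayName = id,
                        refs = list(entityReference = uriOf(paste0("ref_", id)))))
    }
    for (id in smols)
      add(biopaxElement(uriOf(id), "SmallMolecule", displayName = id))

    edgeKinds <- c("complex-component" = 0L, "pathway-component" = 0L,
                   "pathway-step" = 0L, "participant-left" = 0L,
                   "participant-right" = 0L, "participant" = 0L,
                   "controller" = 0L, "controlled" = 0L, "member" = 0L)

    pool <- c(proteins, smols)
    complexes <- sprintf("cx%03d", seq_len(spec@nComplexes))
    for (id in complexes) {
      comps <- sample(pool, cxSize)
      add(biopaxElement(uriOf(id), "Complex",
                        refs = list(component = uriOf(comps))))
      edgeKinds[["complex-component"]] <-
        edgeKinds[["complex-component"]] + length(comps)
    }

    rpool <- c(pool, complexes)
    reactions <- sprintf("rx%03d", seq_len(spec@nReactions))
    for (id in reactions) {
      nLeft <- sample(1:2, 1L); nRight <- sample(1:2, 1L)
      while (nLeft + nRight > length(rpool))
        if (nRight > 1L) nRight <- nRight - 1L else nLeft <- nLeft - 1L
      parts <- sample(rpool, nLeft + nRight)
      add(biopaxElement(uriOf(id), "BiochemicalReaction",
                        refs = list(left = uriOf(parts[seq_len(nLeft)]),
                                    right = uriOf(parts[nLeft + seq_len(nRight)]))))
      edgeKinds[["participant-left"]] <- edgeKinds[["participant-left"]] + nLeft
      edgeKinds[["participant-right"]] <- edgeKinds[["participant-right"]] + nRight
    }

    catalysed <- if (nCat > 0L) sample(reactions, nCat) else character()
    cats <- sprintf("cat%03d", seq_along(catalysed))
    for (i in seq_along(catalysed)) {
      add(biopaxElement(uriOf(cats[i]), "Catalysis",
                        refs = list(controller = uriOf(sample(proteins, 1L)),
                                    controlled = uriOf(catalysed[i]))))
      edgeKinds[["controller"]] <- edgeKinds[["controller"]] + 1L
      edgeKinds[["controlled"]] <- edgeKinds[["controlled"]] + 1L
    }

    pathways <- sprintf("pw%02d", seq_len(spec@nPathways))
    ownReactions <- stats::setNames(vector("list", length(pathways)), pathways)
    children <- stats::setNames(vector("list", length(pathways)), pathways)
    depth <- stats::setNames(integer(length(pathways)), pathways)
    if (spec@nPathways > 0L) {
      assign_ <- if (length(reactions))
        sample(pathways, length(reactions), replace = TRUE) else character()
      for (i in seq_along(reactions))
        ownReactions[[assign_[i]]] <- c(ownReactions[[assign_[i]]], reactions[i])
      if (spec@nestingDepth > 0L && spec@nPathways > 1L) {
        for (j in 2:spec@nPathways) {
          cand <- pathways[seq_len(j - 1L)][depth[seq_len(j - 1L)] <
                                              spec@nestingDepth]
          if (length(cand) && stats::runif(1) < 0.5) {
            parent <- if (length(cand) == 1L) cand else sample(cand, 1L)
            children[[parent]] <- c(children[[parent]], pathways[j])
            depth[[pathways[j]]] <- depth[[parent]] + 1L
          }
        }
      }
      for (p in pathways) {
        comps <- c(ownReactions[[p]], children[[p]])
        refs <- if (length(comps)) list(pathwayComponent = uriOf(comps))
                else list()
        add(biopaxElement(uriOf(p), "Pathway", displayName = p, refs = refs))
        edgeKinds[["pathway-component"]] <-
          edgeKinds[["pathway-component"]] + length(comps)
      }
    }

    ## recursive interaction counts (reactions are partitioned, so sums are
    ## exact distinct counts)
    perPathway <- stats::setNames(
      integer(length(pathways)),
      if (length(pathways)) paste0(.GEN_BASE, pathways) else character(0))
    countRec <- function(p) {
      n <- length(ownReactions[[p]])
      for (ch in children[[p]]) n <- n + countRec(ch)
      n
    }
    for (p in pathways) perPathway[[paste0(.GEN_BASE, p)]] <- countRec(p)

    nodesByClass <- c(
      Protein = spec@nProteins, SmallMolecule = spec@nSmallMolecules,
      Complex = spec@nComplexes, BiochemicalReaction = spec@nReactions,
      Catalysis = length(cats), Pathway = spec@nPathways
    )
    nodesByClass <- nodesByClass[nodesByClass > 0L]
    expected <- list(
      nNodes = sum(nodesByClass),
      nEdges = sum(edgeKinds),
      nodesByClass = nodesByClass,
      edgesByKind = edgeKinds[edgeKinds > 0L],
      perPathwayInteractions = perPathway
    )
    list(model = biopaxModel(els, level = 3L,
                             provenance = sprintf("generated (seed %d)", spec@seed)),
         expected = expected)
  })
}
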