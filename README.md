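# biopaxnet

Pathway and molecular-interaction databases increasingly exchange their
content as **BioPAX** — a community OWL ontology serialized as RDF/XML —
and aggregate it through **Pathway Commons** and its **cPath2** REST
service. Working with those documents as *networks* (for layout, querying
and interchange with graph tools) requires a pipeline: parse the OWL into a
typed object model, convert pathway semantics into nodes and edges, and lay
the result out in 2D or 3D. `biopaxnet` provides that pipeline as an R
package for systems biologists and bioinformaticians who want to go from a
BioPAX Level 2/3 document (local file or Pathway Commons record) to a
styled, queryable, exportable network without a GUI tool.

## What it does

* **Parse / write BioPAX OWL.** `readBiopax()` builds a URI-keyed
  `BioPaxModel` from Level 3 RDF/XML; Level 2 documents are detected and
  upgraded (class/property renaming, collapse of the
  `physicalEntityParticipant` indirection) before use. `writeBiopax()`
  round-trips models deterministically.
* **Graph construction.** `buildGraph()` creates one node per Pathway,
  Interaction, PhysicalEntity and Gene element and typed edges for complex
  components, pathway components and step order, conversion left/right
  participants, control relations and entity membership. Conversions are
  oriented `left → reaction → right` and controls
  `controller → control → controlled`; generic participation is
  undirected. Every node carries an mEPN-derived glyph (2D shape, 3D
  solid, colour) from a versioned style table, and a `"BioPAX"` class set
  partitions nodes by their concrete entity type.
* **Advanced queries, locally.** `mergeNetworks()`, `queryNeighborhood()`,
  `queryCommonStream()`, `queryPathsBetween()` and `queryPathsFromTo()`
  reproduce the cPath2 graph-query semantics as offline graph algorithms
  over those edge conventions.
* **Layout.** `layoutGraph()` computes seeded, deterministic 2D/3D
  multilevel force-directed layouts (matching-based coarsening plus
  Fruchterman–Reingold forces with locally truncated repulsion; an isolated
  edge settles at distance `d* = C^(1/3)·ℓ` from the force balance
  `d²/ℓ = C·ℓ²/d`).
* **Interchange.** GraphML (with class/style/coordinate keys), SIF, and
  tab-separated class-set files, all with exact round trips.
* **Pathway Commons client.** `pcSearch()` / `pcSearchPages()` /
  `fetchOwl()` / `pcCountPathwayInteractions()` / `pcAdvancedQuery()`
  compose cPath2 requests (keywords with AND/OR and `*` wildcards,
  organism and datasource filters, Top Pathways, 500-hit pages) through an
  injectable transport, so everything is testable offline with
  `mockTransport()`.
* **Synthetic models.** `generateModel()` emits seeded random Level-3
  models together with their exact expected graph composition;
  `toyDocuments()` ships four hand-authored fixtures.

## Worked example

```r
library(biopaxnet)
owl <- toyDocuments()[["toy_l3"]]
model <- readBiopax(owl)
model
#> BioPaxModel (Level 3) with 11 elements
#>   Protein                  4
#>   ProteinReference         3
#>   BiochemicalReaction      2
#>   Complex                  1
#>   Pathway                  1
```

Eleven elements, but only eight become nodes — the three
`ProteinReference` elements annotate their proteins rather than appearing
in the network:

```r
g <- buildGraph(model)
g
#> TypedGraph with 8 nodes, 8 edges, 1 class set(s)
#>   complex-component    2
#>   participant-left     2
#>   participant-right    2
#>   pathway-component    2

countInteractions(model, "http://example.org/toy#pw1")
#> [1] 2
```

The edge-kind breakdown reads directly off the document: a two-component
complex, two reactions each with one substrate and one product, and a
pathway containing both reactions; the pathway holds 2 interactions. A
deterministic 2D layout and export:

```r
lay <- layoutGraph(g, dims = 2, seed = 42)
lay
#> LayoutResult: 8 node(s) in 2D, seed 42, 60 sweep(s)
head(round(layoutCoords(lay), 2))
#>      [,1]  [,2]
#> cx1  2.24 -1.36
#> p1   1.80 -0.33
#> p2   1.19 -1.77
#> p3  -0.93  2.16
#> p4  -2.74  0.91
#> pw1 -0.62  0.00

writeGraphML(g, "toy.graphml", layout = lay)
writeSIF(g, "toy.sif")
```

Coordinates are origin-centred in units of the natural edge length
(default 1); the same seed always reproduces them bit-for-bit.

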