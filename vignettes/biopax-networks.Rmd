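---
title: "From BioPAX documents to typed networks: models, rules and numerics"
author: "biopaxnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From BioPAX documents to typed networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biopaxnet)
```

# The problem

BioPAX encodes pathway knowledge — entities (proteins, small molecules,
nucleic acids, complexes), interactions (conversions, controls, template
reactions) and pathways that organise them — as an OWL ontology serialized
in RDF/XML. The representation is a graph of typed, cross-referencing
resources, but it is not directly a *network*: pathway semantics
(membership, participation, regulation) must be translated into nodes and
edges before layout, neighbourhood exploration or interchange with graph
tools are possible. `biopaxnet` implements that translation together with
the surrounding machinery: parsing and level upgrade, glyph styling, local
graph queries, multilevel force-directed layout, and file interchange.

# The object model and the supported hierarchy

A `BioPaxModel` is a URI-keyed store of `BioPaxElement` objects, each with
a concrete type from a fixed supported subset of the BioPAX Level 3 class
hierarchy (see `supportedBiopaxTypes()`), literal properties and
reference properties. The subset covers the classes that carry network
semantics: the `Pathway`/`Interaction`/`PhysicalEntity`/`Gene` branches,
entity references, and pathway steps. Classes outside the subset are
retained at their nearest supported ancestor (utility classes at the
artificial root) with a warning; this graceful degradation means a
document full of `Stoichiometry` or vocabulary resources still parses and
still yields the network of its entities.

Property names are normalised to Level-3 camelCase. Level-2 documents are
recognised by their namespace and upgraded before graph construction:
classes are renamed (`protein` → `Protein`, …), the ALL-CAPS Level-2
property names are translated, and the `physicalEntityParticipant`
indirection is collapsed so interactions reference physical entities
directly. The upgrade removes exactly the wrapper elements, and upgrading
an already-Level-3 model is an explicit error rather than a silent no-op,
so accidental double upgrades surface immediately.

Unresolved `rdf:resource` targets default to *warn and insert a
placeholder element* rather than failing: aggregated exports are commonly
truncated, and a user who has downloaded one pathway from a large source
should still get its network. A `strict = TRUE` mode turns the same
condition into an error for pipelines that need guarantees. Placeholders
are never written back to OWL; they are regenerated on re-read.

# Graph construction rules

One node is created per `Pathway`, `Interaction` (including subtypes),
`PhysicalEntity` (including subtypes) and `Gene` element. Entity
references, pathway steps and utility elements do not become nodes —
entity references annotate their entities, and a step is an ordering
construct, not a biological object.

Edges, with their direction conventions:

| kind | from → to | directed |
|---|---|---|
| `complex-component` | complex → component | yes |
| `member` | entity → member entity | yes |
| `pathway-component` | pathway → component process | yes |
| `pathway-step` | process of step → process of next step | yes |
| `participant-left` | left entity → conversion | yes |
| `participant-right` | conversion → right entity | yes |
| `controller` | controller entity → control | yes |
| `controlled` | control → controlled process | yes |
| `participant` | interaction — participant | no |

The ontology itself is silent on direction; these conventions are chosen
so that "downstream" traversal follows biochemical flow (substrate →
reaction → product, controller → control → target), which is what gives
the Common Stream query its meaning. Generic participation (molecular and
genetic interactions, template-reaction products and templates, cofactors)
carries no inherent orientation and is traversable both ways.

Two interpretation points were genuinely open and are fixed here. First,
"steps of a pathway": both `pathwayComponent` membership and
`PathwayStep` order links are emitted, with distinct kinds, so either view
can be filtered later. Because steps are not nodes, a step's order link is
realised as an edge between the *processes* of consecutive steps
(`stepProcess` of a step → `stepProcess` of its `nextStep`). Second, an
entity occurring on both sides of a reaction produces two edges of
different kinds, not one — the two roles are distinct facts.

Self-loops cannot arise from well-formed input under these rules; if a
malformed document implies one (a complex containing itself), the edge is
dropped.

Node identifiers are the URI local part (after `#`, else after the last
`/` or `:`), deduplicated with a numeric suffix in deterministic URI
order. Construction is fully deterministic: elements are iterated sorted
by URI, so the same model always yields byte-identical node and edge
tables.

## Glyphs and class sets

Every node carries a 2D glyph, a 3D solid and a colour from a versioned
style table (`inst/extdata/glyph-styles.tsv`) mapping BioPAX types onto
mEPN-style shapes. Three mappings are fixed by the visual scheme the table
reproduces: the dumbbell for `RnaRegion`, the Ion/Simple Molecule glyph
for `SmallMolecule`, and a dedicated generic glyph for `Control` (for data
where only the generic regulation type is available). Types without an
explicit entry inherit the nearest listed ancestor's style, so extending
the table is optional; the remaining entries are package choices that can
be replaced wholesale by editing the TSV, since only shape *names* are
stored — no geometry is rendered here.

Class assignment uses the concrete, most specific type — `Catalysis`
nodes class as `Catalysis`, not `Control` — so a per-type breakdown of a
mixed network distinguishes regulation flavours. The `"BioPAX"` class set
is a true partition of the node set, and class sets round-trip through a
tab-separated exchange file, which also lets externally derived
partitions (e.g. co-expression clusters) be imported onto a pathway
network that shares identifiers.

# Query semantics

The advanced queries are defined as local algorithms over the edge
conventions above; directed edges traverse forward when going downstream
and backward when going upstream, undirected edges both ways always.

* **Merge** unions nodes by id and edges by (source, target, kind);
  conflicting classes for one id are an error, not a silent overwrite.
* **Neighborhood** is the induced subgraph on the seeds plus every node
  within `limit` hops (default 1 — "first order").
* **Common Stream** intersects the reach sets of all seeds (a node counts
  as reachable from a seed only via a path of length ≥ 1). By default the
  result also includes the simple connecting paths (length ≤ `limit`)
  from each seed to the common set, because a common stream without the
  routes to it is hard to interpret; `includePaths = FALSE` restricts to
  the common set itself.
* **Paths Between / Paths From To** return the union of nodes and edges on
  simple directed paths up to `limit` between seed pairs (respectively
  from sources to targets). Paths are simple — cycles contribute only
  their simple sub-paths — and the default `limit` is 3, a pragmatic
  radius that keeps enumeration tractable while spanning
  substrate→reaction→product→reaction chains.

Every query result is a subgraph of the input, and results grow
monotonically with `limit`. The test suite checks all four queries against
independent oracles (igraph breadth-first search, reachability
intersection, exhaustive simple-path enumeration) on seeded random
digraphs.

# Layout

The layout engine follows the multilevel force-directed recipe: coarsen by
maximal edge matching until at most `stopSize` nodes remain, place the
coarsest level uniformly at random (seeded) in a cube of side
`ℓ·√n`, refine level by level, prolongating coarse positions to their
children with a small seeded jitter.

Forces are the Fruchterman–Reingold pair with natural edge length `ℓ` and
repulsion constant `C`:

* attraction along each edge: `F_a(d) = d²/ℓ`,
* repulsion between node pairs: `F_r(d) = C·ℓ²/d`, truncated to zero
  beyond a cutoff of `3ℓ`.

The truncation replaces the far-field approximation of multipole-based
layouts: beyond a few natural lengths the aggregate repulsion mostly
rescales the picture, and a local cutoff preserves the O(n log n) cost
(pairs are found on a spatial grid for larger levels, by brute force below
200 nodes) while keeping edge lengths near `ℓ`. This is an approximation
in the same spirit as, not a reimplementation of, the fast multipole
multilevel method; no bit-compatibility with any existing implementation
is claimed.

The corresponding potential,

```
E = Σ_edges d³/(3ℓ) + Σ_{pairs, d<3ℓ} C·ℓ²·(log 3ℓ − log d),
```

is what refinement minimises. Each sweep computes forces, caps
displacements at a temperature that cools by 0.95 per accepted sweep, and
*accepts the sweep only if the energy does not increase*, halving the step
on rejection (up to 12 backtracks, after which the level is declared
converged). Energy monotonicity within a level is therefore guaranteed by
construction, not hoped for; the accepted energies are recorded in the
result's `energyTrace`. Refinement also stops when the maximum
displacement falls below `tol`.

For an isolated dyad the force balance `d²/ℓ = C·ℓ²/d` gives the
closed-form equilibrium `d* = C^(1/3)·ℓ`, which the tests verify to
within 5% (observed error is ~10⁻⁴). Parameters and defaults:
`edgeLength` ℓ = 1 (the coordinate unit), `repulsion` C = 1 (so `d* = ℓ`),
`maxIter` 60 sweeps per level, `tol` 10⁻³, `stopSize` 10, seed 42. The
seed is a required, recorded part of the result: identical graph,
parameters and seed give bit-identical coordinates; different seeds give
different but energy-comparable layouts.

Degenerate inputs: an empty graph is an error; a single node sits at the
origin; an edgeless graph cannot be coarsened and is simply refined at one
level (pure repulsion, capped by `maxIter`); coincident points are guarded
by a 10⁻⁹ distance floor. All layouts are re-centred at the origin.

# The Pathway Commons client

Requests to the cPath2-style service are pure functions of the query
object — the same `searchQuery()` always produces byte-identical URLs —
which makes request construction snapshot-testable. Keywords pass through
verbatim (Boolean AND/OR, `field:term`, `*` wildcards); `nameOnly` wraps
the query as `name:(…)`; the `TopPathways` type dispatches to the
dedicated top-pathways endpoint; organism and datasource filters become
repeated parameters. Pages hold 500 hits and the pagination iterator stops
exactly when `(page+1)·500 ≥ totalHits`.

All network access goes through an injectable transport function;
`mockTransport()` supplies canned responses and records every requested
URL, so the entire client is exercised offline. Species names are
resolved from a small bundled taxon table (`speciesName()`,
`popularSpecies()`) instead of a live taxonomy lookup — a deliberate
trade of live coverage for offline determinism, with a pluggable path for
anyone who needs more. Advanced queries in local mode fetch each hit's
OWL, build and merge the graphs, and run the local query with the hits'
nodes as seeds; a hit URI that denotes a node seeds that node, otherwise
its whole record.

# The synthetic generator

`generateModel()` emulates the composition of desk-scale pathway
downloads: tens of entities, 1–2 substrates and products per reaction,
complexes of 2–4 components drawn from the entity pool, a configurable
fraction of catalysed reactions, and reactions partitioned among pathways
with optional sub-pathway nesting. Defaults (one pathway, four reactions,
eight proteins, two small molecules, one complex, 50% catalysis) mirror a
small curated pathway record. The generator records its exact expected
node and edge composition *during* generation rather than recomputing it
afterwards, so a bug shared between generator and builder cannot cancel
out; the independent anchors are the hand-authored fixtures whose counts
were derived manually.

What the generator does **not** emulate: realistic degree distributions or
pathway topology (no scale-free structure), cross-references to real
databases, multiple entity states/locations, or malformed input beyond
what the dedicated error-path tests construct. Passing tests on generated
models therefore demonstrate correctness of the construction rules and
bookkeeping, not robustness to every artefact of real Pathway Commons
exports — the fixtures and the placeholder machinery cover the common
truncation case, nothing more.

Validation problem sizes, chosen to exercise the code well past the
fixture scale while keeping the suite quick: 200 generated models of up to
roughly 300 elements for the construction oracle, and 100 random digraphs
of up to 40 nodes for the query-oracle comparison.

# Interchange formats

GraphML is the canonical interchange: declared keys for class, label, URI,
glyph fields and optional x/y/z coordinates, with per-edge directedness in
the standard `directed` attribute. Reading is the exact inverse of
writing on the package's own output; foreign GraphML without these keys
loads with defaulted classes and a warning rather than failing, so
hand-drawn networks can still be imported. SIF output is one
`source TAB kind TAB target` line per edge, sorted, hence byte-identical
across runs. The class-set file is defined here (tab-separated id / set /
class triples with `#` comments) since the feature it supports names no
syntax of its own.

# Known limitations

* The BioPAX subset is deliberately partial: ~30 classes with network
  semantics, not the full ontology; no OWL reasoning; Turtle/N-Triples
  are not read.
* Level-2 upgrade covers the mapped class list; exotic Level-2 classes
  degrade to the root type with a warning.
* The layout approximates long-range repulsion by truncation; very dense
  graphs may cluster differently than a full multipole implementation
  would place them.
* Path queries enumerate simple paths and are exponential in `limit`;
  they are intended for the small `limit` values (≤ 4) that make
  biological sense.
* The live HTTP transport is minimal (no retries, no authentication); the
  client is designed around injected transports.
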