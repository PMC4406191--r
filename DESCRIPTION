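Package: biopaxnet
Title: BioPAX Pathway Networks: Parsing, Graph Construction, Queries and
    Layout
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reads BioPAX Level 2/3 OWL (RDF/XML) pathway documents into an
    in-memory object model (upgrading Level 2 to Level 3), converts them to
    typed network graphs with an mEPN-derived glyph scheme and a per-type
    class set, runs advanced graph queries locally (neighborhood, common
    stream, paths between, paths from-to, merge), computes 2D/3D multilevel
    force-directed layouts, and exchanges results as GraphML, SIF and
    class-set files. Includes a mockable client for the Pathway Commons
    cPath2 REST API and a seeded generator of synthetic pathway models for
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
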