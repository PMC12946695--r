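Package: netcanvas
Title: Backend-Agnostic Visualisation Middleware for Networks and Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A universal middleware layer between network or tree analysis
    libraries and graphical rendering. Foreign graph objects are normalised
    through a provider plug-in registry into a single internal data model, so
    the rendered output is identical regardless of which analysis library
    produced the graph. A declarative cascading style grammar covers vertices,
    edges, arrows, self-loops, labels, clustering hulls and subtree patches; a
    computational-geometry engine routes edges as straight lines, circular
    arcs, cubic Beziers, port-constrained curves, waypoint polylines, and tree
    elbows; rectangular and radial phylogenetic tree layouts and tanglegrams
    are computed internally. Scenes keep vertex positions in data units and
    sizes in figure units, so marker sizes are invariant under zoom, and
    serialise deterministically to JSON and SVG.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    grDevices,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
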