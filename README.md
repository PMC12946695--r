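# netcanvas

Backend-agnostic visualisation middleware for networks and trees in R.

Network drawing usually lives inside whichever analysis library produced the
graph, so the same network plotted from two different stacks looks different,
and features such as curved edges, clustering hulls or tanglegrams exist in
some stacks but not others. netcanvas sits between analysis and rendering:

* **one internal model** — every input object is normalised by a *provider*
  plug-in into the same vertex/edge (or rooted-tree) structure, so the
  rendered scene depends only on the abstract graph, never on the library
  that produced it;
* **one declarative style grammar** — a cascading nested mapping covering
  vertices, edges, arrows, self-loops, labels, clustering hulls and subtree
  patches, with global scalars, positional sequences (recycled by
  `index mod length`) and per-element mappings;
* **one geometry engine** — straight, circular-arc (tension = bulge as a
  fraction of the chord, positive to the left of travel), cubic Bezier,
  port-constrained (prescribed incidence angles), waypoint, self-loop and
  tree-elbow edges, plus marker clipping, arrowheads and arc-length path
  splitting;
* **internally computed tree layouts** — rectangular and radial embeddings
  from cumulative branch lengths with unit leaf spacing, subtree cascade
  patches, and a tanglegram function for facing tree pairs;
* **a dual coordinate contract** — positions are data units, sizes are figure
  units (points), so marker sizes and line widths are invariant under zoom;
* **deterministic output** — scenes serialise to byte-stable JSON and SVG;
  PNG rasterisation goes through base graphics.

Scene assembly is O(n + m): graphs with a hundred thousand vertices and two
hundred thousand edges assemble in well under a second.

## Worked example

A small directed signalling loop, styled with arcs and labels:

```r
library(netcanvas)

h <- plot_network(
  list(edges = list(c("ERK", "MEK"), c("MEK", "RAF"), c("RAF", "RAS"),
                    c("RAS", "ERK"), c("ERK", "ERK")),
       directed = TRUE),
  layout = list(ERK = c(0, 0), MEK = c(1, 0), RAF = c(1.2, 1), RAS = c(0, 1)),
  style = list(edge = list(geometry = "arc", tension = 0.25),
               vertex = list(facecolor = "teal", size = 14),
               vertex_label = list(text = "id", voffset = 12)))
h
#> <netcanvas render: 5 edge, 5 arrow, 4 vertex, 4 label>

scene_counts(h$scene)
#> grouping  cascade     edge    arrow   vertex    label
#>        0        0        5        5        4        4

export_figure(h, "signalling.svg")   # byte-deterministic SVG
export_figure(h, "signalling.json")  # scene as deterministic JSON
```

Five edges (the `ERK` self-edge is drawn as a loop lobe), five arrowheads,
four markers, four labels — exactly the primitive counts the scene contract
promises. Edges sit below arrows, arrows below markers, markers below labels.

A tree goes through the same pipeline, with the layout computed internally:

```r
tr <- plot_tree("((human:0.006,chimp:0.007):0.02,macaque:0.03);",
                kind = "rectangular")
tr
#> <netcanvas render: 4 edge, 5 vertex, 3 label>

round(tr$layout$coords, 4)
#>             x    y
#> .n1     0.000 1.25
#> .n2     0.020 0.50
#> human   0.026 0.00
#> chimp   0.027 1.00
#> macaque 0.030 2.00
```

The x coordinates are cumulative branch lengths from the root (human at
0.02 + 0.006), the y coordinates place the leaves at unit spacing with each
internal node at the mean of its children. `plot_tree_pair(t1, t2, links)`
draws two facing trees with leaf-to-leaf links (a tanglegram);
`grouping_spec()` adds padded convex hulls behind vertex clusters or covers;
`cascade_nodes` shades whole subtrees.

Foreign graph objects plug in through the provider registry:

```r
register_provider(provider_descriptor(
  name = "my-lib", kind = "network",
  matcher   = function(obj) inherits(obj, "my_graph"),
  converter = function(obj) build_network(obj$edges),
  layout_extractor = function(obj) obj$coords))
```

After registration, `plot_network(obj)` accepts `my_graph` objects directly,
and the resulting scene is identical to one assembled from any other
representation of the same graph.

A thin command line sits over the same functions:

```sh
inst/cli/netcanvas network --edges edges.tsv --layout layout.tsv \
    --style style.json --out out.svg
inst/cli/netcanvas tree --newick tree.nwk --kind radial --out out.svg
```

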