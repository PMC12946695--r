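---
title: "netcanvas: how the middleware models, styles and lays out networks and trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netcanvas: how the middleware models, styles and lays out networks and trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcanvas)
```

## The problem netcanvas addresses

Network visualisation sits between two well-served stages: analysis libraries
that compute graph statistics and layouts, and graphics backends that put ink
on a canvas. Each analysis library tends to ship its own plotting code, so the
same network drawn from two different libraries looks different, and features
(curved edges, clustering hulls, tanglegrams) exist in some stacks but not
others. netcanvas is the middleware in between: every input is normalised into
one internal model, one declarative style grammar covers every visual element,
and one geometry engine produces the scene — so the rendered output depends
only on the abstract graph, never on where it came from.

## The internal model

A network is a vertex label sequence, an *ordered* edge list (self-loops and
parallel edges kept, in order), a directedness flag and optional per-element
attributes (`build_network()`). Edge endpoint indices are resolved once at
construction, so no downstream stage repeats label lookups. A rooted tree is a
child-to-parent map with branch lengths (missing lengths default to 1 so
topology-only trees still lay out); `leaf_order` is the depth-first traversal
respecting child order, and is the backbone of both tree layouts
(`build_tree()`). Layouts are consumed, not computed, for general networks:
`validate_layout()` only enforces the contract — every vertex covered, one
common dimension (2 or 3), finite values.

Element identity is by label; *positional* per-element styling addresses
elements by insertion order. Parallel edges are therefore distinct styleable
elements. This is a deliberate choice: order is deterministic and
provider-independent, whereas any keying scheme for multi-edges would not be.

## Providers

Input objects are recognised by a registry of providers, each a matcher
predicate plus a converter into the internal model (and an optional layout
extractor). User-registered providers are matched before the built-ins
(`internal`, `edgelist`, `newick`), first match by registration order — a
deterministic stand-in for run-time library discovery: an adapter for a real
analysis library is simply a provider registered at load time. Because every
provider funnels into the same model, scenes assembled from different
providers serialise to identical bytes; the test suite checks this
element-wise on seeded random graphs.

## The style grammar

A style is a nested mapping: element type (`vertex`, `edge`, `arrow`, `loop`,
`vertex_label`, `edge_label`, `cascade`, `grouping`) to property to value.
Values come in three shapes:

* a scalar — applies to every element;
* an unnamed sequence — positional, recycled by `index mod length` (the
  grammar-of-graphics recycling rule; the short-list behaviour is our
  convention);
* a named mapping — per element by id, falling back to the built-in default.

Fragments cascade by deep merge, later layers overriding earlier ones key by
key at the leaf level; sequences and mappings replace rather than merge. The
built-in styles (`default`, `minimal`, `tree`) are complete — every property
has a value — so any stack based on one of them resolves with no missing
property. Resolution is a pure function; `flatten_style()` additionally
pre-analyses the cascade (which element types are fully scalar, and their
resolved exemplars) so scene assembly pays no per-call analysis cost.

Two grammar notes. The property vocabulary is a documented minimum that
covers every feature the package draws, not a clone of any other system's
option list. And bezier geometry reads its 1–2 control points from the
`waypoints` property — the vocabulary deliberately has no separate
control-point key.

Quantitative colouring maps a numeric vector linearly onto a built-in colour
map (`viridis`, `gray`, `coolwarm`), defaulting the normalisation to the data
range; constant data with no explicit range is an error rather than a guess.
The normalisation record is kept on the result so a backend can draw a colour
bar.

## Edge geometry

All conventions are fixed once: angles in radians, counterclockwise from +x,
in data space; tension is dimensionless (fraction of the chord length),
positive bulging to the left of travel. The geometry kinds are:

* **straight** — the chord;
* **arc** — the circle through the endpoints whose midpoint is offset
  `tension * |chord|` perpendicular-left of the chord midpoint. Arcs are
  carried as polylines sampled *exactly on the circle*, with the true arc
  midpoint always a sample (64 segments), so downstream stages need only two
  segment kinds (line, cubic) and the semicircle fixed point is exact;
* **bezier** — a cubic; a single (quadratic) control point is elevated
  exactly (`c1 = p1 + 2/3 (q - p1)`, symmetric for `c2`);
* **ports** — a cubic whose control arms have prescribed incidence angles
  and length `strength * |chord|` (default 1/3, the standard cubic
  heuristic), so the departure tangent equals the out-port angle exactly;
* **waypoints** — a polyline through the given intermediate points;
* **elbow** — tree edges: cross-axis move to the corner `(parent main,
  child cross)` then main-axis move (rectangular), or a sweep at the parent
  radius followed by a radial segment (radial);
* **loop** — a closed cubic lobe on a self-edge. The control arms open 30
  degrees either side of the loop direction with length `4/(3 cos 30) * size`,
  which places the curve's farthest point exactly at distance `size` in the
  loop direction (the distance profile `|B(t) - p|` is maximal at `t = 1/2`
  for any half-angle below 54.7 degrees, where `sin^2 w = 2 cos^2 w`). The
  default direction points away from the centroid of the vertex's
  neighbours, straight up for isolated vertices.

Supporting operations: `path_length()` uses 32-node Gauss–Legendre quadrature
of the cubic speed (spectrally accurate, far beyond the 1e-9 conservation
tolerance); `split_path()` cuts by arc length with exact de Casteljau
subdivision, so concatenation reproduces the geometry and an elbow can be
split at its corner for split-edge styling; `clip_at_marker()` trims a path at
a circle or axis-aligned square boundary (analytic on line segments,
root-bracketing to 1e-12 on cubics) — the marker centre can be passed
explicitly, which is what makes re-clipping an already-clipped path a no-op;
`arrowhead()` builds the isoceles tip triangle on the terminal tangent and
shortens the path to abut its base.

## Scene assembly and the dual coordinate contract

`assemble_scene()` resolves data + layout + style into an ordered set of draw
primitives: one marker per vertex, one path per edge (loops as lobes), one
arrow polygon per directed edge, one hull polygon per group, one patch per
requested cascade node, one text per requested label. Stacking is fixed:
grouping < cascade < edge < arrow < vertex < label, element order within a
class. In 3D, primitives are painter-sorted far-to-near first (our choice; no
occlusion rule is implied by the feature itself), and marker/edge colours are
dimmed by `depth_shade()`: `f = floor + (1 - floor)(z - zmin)/(zmax - zmin)`,
clamped, with floor 0.3.

Positions live in data units; every size-like attribute (marker size, line
width, arrow dimensions, font size) lives in figure units (points at export).
That is the dual coordinate contract — marker sizes survive zoom — and
`zoom_transform_check()` is its testable form: rescaling all data-space
coordinates leaves every figure-space attribute bit-identical.

Grouping hulls dilate the convex hull of the member coordinates outward by
`padding` data units (arc-rounded or mitred corners; a single point becomes a
disc), so every member is strictly inside for positive padding. Cascade
patches span the subtree's contiguous leaf segment plus half a leaf spacing
each side, from the node's main-axis coordinate out to the leaf extent or the
subtree's own maximum — an axis-aligned band in rectangular layouts, an
annular sector in radial ones.

**Representation.** Scenes whose style resolves to one scalar per property
(no grouping, cascades, labels, loops, 2D) are stored column-wise: packed
coordinate vectors per element class plus one shared resolved-attribute list.
Everything is still computed eagerly at assembly — geometry, resolved styles,
order — only the per-element list view is materialised on demand by
`scene_primitives()`, byte-identical (via `scene_json()`) to what the general
element-wise path produces. This is the vectorised container design R calls
for: a hundred-thousand-edge scene is a handful of numeric vectors rather
than hundreds of thousands of small heap objects, which keeps assembly O(n+m)
with a small constant. Any styled, grouped, labelled, looped or 3D scene uses
the general element-wise representation.

## Tree layouts

Only tree layouts are computed internally. Leaf `i` (in `leaf_order`) sits at
cross coordinate `i` — unit spacing, exactly uniform; each internal node at
the plain arithmetic mean of its children's cross coordinates (no
subtree-size weighting — a declared convention, since plain means are the
simplest rule consistent with standard drawings); the main-axis coordinate is
the cumulative branch length from the root, or integer depth on request. The
rectangular orientation maps (main, cross) onto (x, y) as right/left/up/down.
The radial layout assigns leaf `i` the angle `start + i * span / L`, dividing
by `L` rather than `L - 1` so a full-circle span reserves one leaf gap and
the first and last leaves never collide; radius is cumulative branch length.
Both layouts are linear in a global branch-length scaling and induce the same
leaf order.

The tanglegram (`plot_tree_pair()`) lays the first tree out facing right and
the second facing left at a horizontal offset (`gap` data units between the
leaf columns), then draws one straight link per leaf pair, endpoints exactly
at the leaf coordinates. For identical trees with identity links, mirror
symmetry makes every link exactly horizontal — which the tests assert as
equality, not a tolerance.

## Determinism and serialisation

`scene_json()` is the equality surface: fixed field order, sorted attribute
keys, floats at 9 significant digits, so two scenes are element-wise equal
exactly when their JSON bytes are equal. SVG is likewise hand-emitted
deterministic text, one `<g>` per zorder class; the data-to-pixel transform
is fixed from the scene's bounding box, figure units map to pixels
one-to-one, and it is here — where the two coordinate systems meet — that
edges are clipped at their end markers and arrowheads realised. PNG export
rasterises through base graphics and is not byte-deterministic (raster
encoders are not), which is why the determinism guarantee names svg and json.

## Synthetic data

`erdos_renyi(n, m, seed)` samples exactly `m` distinct undirected edges
uniformly without replacement — the G(n, m) model, matching the (n, m)
parameterisation used in the scalability checks, with `m = 2n` as the
reference family. `random_tree(L, seed)` grows a rooted binary tree by
sequential leaf attachment (each new leaf splits a uniformly chosen existing
branch), with branch lengths uniform on (0.5, 1.5) — bounded away from zero
so layouts never degenerate; the distribution itself is a package convention.
`random_layout()` is uniform on the unit square, a stand-in for the layouts
real analysis libraries would supply. Seeds fully determine every output, and
the generators restore the caller's RNG state.

What these fixtures emulate is the *shape* of real inputs — sparse graphs
with a known edge budget, binary phylogenies with positive branch lengths —
not their statistics: real networks have degree heterogeneity, communities
and weighted edges, and real phylogenies are not uniform-attachment trees.
Passing tests on these fixtures therefore demonstrates correctness of the
model, grammar, geometry and contracts, not anything about the visual quality
of layouts on real data (layout quality is upstream of this package by
design).

## Numerical choices and test problem sizes

Tolerances in the tests follow the quantity: exact equality where the
computation is exact (leaf spacing, tension-0 arcs, tanglegram link
horizontality), 1e-12 for closed-form coordinate arithmetic, 1e-9 for
root-finding and quadrature (clipping, arc-length conservation,
equivariance). Degenerate inputs fail loudly: coincident endpoints for
non-loop geometry, markers that swallow a path, constant data without an
explicit colour normalisation, cycles or multiple roots in parent maps.

The scalability check assembles G(n, 2n) scenes at n = 10^3, 10^4, 10^5 and
requires the per-call runtime ratio between successive decades to stay in
[5, 20] (nominal 10 for O(n+m)). Measurement cycles over several distinct
seeded inputs per size so every call runs cache-cold — repeatedly assembling
one resident graph flatters mid sizes whose working set fits in CPU cache and
skews both ratios outward — and takes the best of several batched passes to
suppress timer quantisation and scheduler noise. Fixture counts elsewhere
(100 seeded graphs for provider equivalence, 100 random trees for the layout
oracle, 1000 random port edges) were chosen to exercise the properties
densely while keeping the full suite fast.

## Known limitations

* General network layouts are consumed, never computed; there is no fallback
  force-directed layout.
* Adapters for real analysis libraries are extension points (the provider
  protocol), not shipped bindings.
* The 3D contract covers depth shading and painter ordering; projection is
  the backend's business, and the SVG writer draws 3D scenes by class, not by
  depth.
* Edge bundling, collision-avoiding routing, unrooted/equal-angle tree
  layouts and ladderisation are out of scope.
* The toy Newick reader handles the plain subset (labels, lengths, nesting);
  no quoting or comments.
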