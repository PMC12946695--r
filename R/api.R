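# High-level entry points: plot_network() and plot_tree() mirror the two main
# user-facing calls of the middleware; plot_tree_pair() is the tanglegram
# specialty function. Each returns a render handle wrapping the assembled
# scene; export_figure() writes svg (deterministic text), json (deterministic
# text) or png (raster via base graphics).

new_render_handle <- function(scene, data, layout, style) {
  structure(list(scene = scene, data = data, layout = layout, style = style),
            class = "netcanvas_render")
}

#' @export
print.netcanvas_render <- function(x, ...) {
  cnt <- scene_counts(x$scene)
  cat("<netcanvas render: ",
      paste(sprintf("%d %s", as.integer(cnt), names(cnt))[cnt > 0],
            collapse = ", "), ">\n", sep = "")
  invisible(x)
}

#' Plot a network from any supported input object
#'
#' Detects a provider for `obj`, normalises it into the internal model,
#' cascades the style fragments over the `"default"` style, assembles the
#' scene and wraps it in a render handle. The layout may be passed explicitly
#' or extracted by the provider; there is no fallback layout computation.
#'
#' @param obj an opaque network object some registered provider understands
#'   (e.g. a `netcanvas_network`, or an edge-list mapping with an `edges`
#'   key).
#' @param layout optional raw layout mapping or `netcanvas_layout`.
#' @param style optional style fragment or list of fragments.
#' @param grouping optional [grouping_spec()].
#' @return a `netcanvas_render` handle.
#' @examples
#' h <- plot_network(list(edges = list(c("A", "B"), c("B", "C"))),
#'                   layout = list(A = c(0, 0), B = c(1, 0), C = c(1, 1)))
#' scene_counts(h$scene)
#' @export
plot_network <- function(obj, layout = NULL, style = NULL, grouping = NULL) {
  norm <- normalise_input(obj)
  if (is.null(layout)) layout <- norm$layout
  if (is.null(layout)) {
    stop("missing-layout error: no layout argument and provider '",
         norm$provider, "' exposes none", call. = FALSE)
  }
  layout <- validate_layout(layout, norm$data)
  flat <- flatten_style(style)
  scene <- assemble_scene(norm$data, layout, flat, grouping = grouping)
  new_render_handle(scene, norm$data, layout, flat)
}

#' Plot a tree with an internally computed layout
#'
#' Unlike general networks, tree layouts (rectangular or radial) are computed
#' here. Styles cascade over the `"tree"` default (elbow edges, leaf labels).
#' Leaf labels are placed at the leaf coordinates, offset along the main axis
#' in figure units.
#'
#' @param obj an opaque tree object (a `netcanvas_tree` or a Newick string
#'   for the built-in providers).
#' @param kind `"rectangular"` or `"radial"`.
#' @param opts optional [tree_layout_options()]; `kind` must agree.
#' @param style optional style fragment or list of fragments.
#' @param cascade_nodes optional node ids to shade with cascade patches.
#' @return a `netcanvas_render` handle.
#' @export
plot_tree <- function(obj, kind = c("rectangular", "radial"), opts = NULL,
                      style = NULL, cascade_nodes = NULL) {
  kind <- match.arg(kind)
  norm <- normalise_input(obj)
  tree <- norm$data
  if (!inherits(tree, "netcanvas_tree")) {
    stop("unsupported-input error: provider '", norm$provider,
         "' did not yield a tree", call. = FALSE)
  }
  if (is.null(opts)) opts <- tree_layout_options(kind = kind)
  if (opts$kind != kind) {
    stop("grammar error: opts$kind is '", opts$kind, "' but kind is '",
         kind, "'", call. = FALSE)
  }
  layout <- if (kind == "rectangular") layout_rectangular(tree, opts)
            else layout_radial(tree, opts)
  leaf_labels <- stats::setNames(as.list(tree$leaf_order), tree$leaf_order)
  flat <- flatten_style(c(list(list(vertex_label = list(text = leaf_labels))),
                          if (is.null(style)) list()
                          else if (is_style_fragment(style)) list(style)
                          else style),
                        base = "tree")
  scene <- assemble_scene(tree, layout, flat, cascade_nodes = cascade_nodes)
  new_render_handle(scene, tree, layout, flat)
}

is_style_fragment <- function(style) {
  inherits(style, "netcanvas_style") ||
    (is.list(style) && length(style) &&
     any(names(style) %in% .style_element_types))
}

#' Tanglegram: two trees facing each other with leaf links
#'
#' The first tree is laid out rectangular facing right, the second mirrored
#' (facing left) at a horizontal offset, and one link path is drawn per leaf
#' pair, connecting the two leaf coordinates exactly. With `tree2 = tree1` and
#' identity links every link is horizontal, by mirror symmetry.
#'
#' @param tree1,tree2 opaque tree objects.
#' @param links list of `c(leaf_in_tree1, leaf_in_tree2)` pairs (may be
#'   empty).
#' @param style optional style fragment or list of fragments.
#' @param gap horizontal clearance between the two leaf columns (data units).
#' @return a `netcanvas_render` handle; the scene contains both trees (vertex
#'   ids prefixed `L:` and `R:`) and the link paths.
#' @export
plot_tree_pair <- function(tree1, tree2, links = list(), style = NULL,
                           gap = 1) {
  t1 <- normalise_input(tree1)$data
  t2 <- normalise_input(tree2)$data
  if (!inherits(t1, "netcanvas_tree") || !inherits(t2, "netcanvas_tree")) {
    stop("unsupported-input error: tanglegram needs two trees", call. = FALSE)
  }
  lay1 <- layout_rectangular(t1, tree_layout_options(orientation = "right"))
  lay2 <- layout_rectangular(t2, tree_layout_options(orientation = "left"))
  d1 <- max(lay1$coords[, 1])
  d2 <- max(-lay2$coords[, 1])
  shift <- d1 + gap + d2
  lay2$coords[, 1] <- lay2$coords[, 1] + shift

  pt1 <- prefix_tree(t1, "L:")
  pt2 <- prefix_tree(t2, "R:")
  c1 <- lay1$coords; rownames(c1) <- paste0("L:", rownames(c1))
  c2 <- lay2$coords; rownames(c2) <- paste0("R:", rownames(c2))
  lay1p <- structure(list(coords = c1, ndim = 2L),
                     class = "netcanvas_layout")
  attr(lay1p, "tree_kind") <- "rectangular"
  attr(lay1p, "orientation") <- "right"
  lay2p <- structure(list(coords = c2, ndim = 2L),
                     class = "netcanvas_layout")
  attr(lay2p, "tree_kind") <- "rectangular"
  attr(lay2p, "orientation") <- "left"

  flat <- flatten_style(style, base = "tree")
  label1 <- stats::setNames(as.list(t1$leaf_order),
                            paste0("L:", t1$leaf_order))
  label2 <- stats::setNames(as.list(t2$leaf_order),
                            paste0("R:", t2$leaf_order))
  flat1 <- flatten_style(list(unclass(flat),
                              list(vertex_label = list(text = label1))),
                         base = NULL)
  flat2 <- flatten_style(list(unclass(flat),
                              list(vertex_label = list(text = label2))),
                         base = NULL)
  s1 <- assemble_scene(pt1, lay1p, flat1)
  s2 <- assemble_scene(pt2, lay2p, flat2)

  link_prims <- vector("list", length(links))
  for (k in seq_along(links)) {
    lk <- links[[k]]
    a <- lk[[1]]; b <- lk[[2]]
    if (!a %in% t1$leaf_order) {
      stop("lookup error: link endpoint '", a, "' is not a leaf of tree 1",
           call. = FALSE)
    }
    if (!b %in% t2$leaf_order) {
      stop("lookup error: link endpoint '", b, "' is not a leaf of tree 2",
           call. = FALSE)
    }
    p1 <- c1[paste0("L:", a), ]
    p2 <- c2[paste0("R:", b), ]
    link_prims[[k]] <- new_primitive(
      "path", "edge", length(scene_primitives(s1)) + k - 1L,
      paste0("L:", a, "~R:", b), rbind(p1, p2),
      list(color = "#808080", linewidth = 1, linestyle = "solid"),
      segments = "line")
  }

  prims <- c(scene_primitives(s1), scene_primitives(s2), link_prims)
  rk <- .zclass_rank[vapply(prims, function(p) p$zclass, "")]
  prims <- prims[order(rk)]   # stable: preserves within-class order
  scene <- structure(list(primitives = prims, ndim = 2L, colourbar = NULL),
                     class = "netcanvas_scene")
  data <- list(tree1 = t1, tree2 = t2, links = links)
  new_render_handle(scene, data, list(lay1p, lay2p), flat)
}

prefix_tree <- function(tree, prefix) {
  px <- function(x) stats::setNames(paste0(prefix, x),
                                    if (is.null(names(x))) NULL
                                    else paste0(prefix, names(x)))
  structure(list(
    nodes = paste0(prefix, tree$nodes),
    root = paste0(prefix, tree$root),
    parent = px(tree$parent),
    children = stats::setNames(lapply(tree$children,
                                      function(ch) paste0(prefix, ch)),
                               paste0(prefix, names(tree$children))),
    branch_length = stats::setNames(tree$branch_length,
                                    paste0(prefix, names(tree$branch_length))),
    leaf_order = paste0(prefix, tree$leaf_order)
  ), class = "netcanvas_tree")
}

#' Export a render handle to a file
#'
#' `svg` and `json` are deterministic text: exporting the same scene twice
#' yields identical bytes. `png` rasterises through the base-graphics
#' backend.
#'
#' @param handle a `netcanvas_render`.
#' @param format `"svg"`, `"json"` or `"png"`; inferred from the path
#'   extension when omitted.
#' @param path output file path.
#' @param width image width in pixels (svg/png).
#' @return `path`, invisibly.
#' @export
export_figure <- function(handle, path, format = NULL, width = 600) {
  scene <- if (inherits(handle, "netcanvas_scene")) handle else handle$scene
  if (is.null(format)) {
    format <- tolower(sub("^.*\\.", "", path))
  }
  if (!format %in% c("svg", "json", "png")) {
    stop("format error: unsupported format '", format,
         "' (svg, json, png)", call. = FALSE)
  }
  if (format == "json") {
    writeLines(scene_json(scene), path, useBytes = TRUE)
  } else if (format == "svg") {
    writeLines(scene_svg(scene, width = width), path, useBytes = TRUE)
  } else {
    grDevices::png(path, width = width, height = width)
    on.exit(grDevices::dev.off())
    draw_scene_base(scene)
  }
  invisible(path)
}

# raster backend: base graphics walk of the primitives, same stacking as SVG
draw_scene_base <- function(scene) {
  bb <- scene_bbox(scene)
  graphics::plot.new()
  graphics::plot.window(xlim = bb[1:2], ylim = bb[3:4], asp = 1)
  prims <- scene_primitives(scene)
  by_class <- split(prims,
                    factor(vapply(prims, function(p) p$zclass, ""),
                           levels = names(.zclass_rank)))
  for (cls in names(.zclass_rank)) {
    for (p in by_class[[cls]]) {
      if (p$kind == "polygon" && cls != "arrow") {
        col <- grDevices::adjustcolor(p$attrs$facecolor,
                                      alpha.f = p$attrs$alpha %||% 1)
        graphics::polygon(p$coords[, 1], p$coords[, 2], col = col,
                          border = NA)
      } else if (p$kind == "path") {
        pts <- sample_path(new_path(p$coords, p$segments), 17L)
        graphics::lines(pts[, 1], pts[, 2], col = p$attrs$color,
                        lwd = p$attrs$linewidth,
                        lty = switch(p$attrs$linestyle %||% "solid",
                                     dashed = 2, dotted = 3, 1))
      } else if (p$kind == "marker") {
        if ((p$attrs$size %||% 0) > 0) {
          graphics::points(p$coords[1, 1], p$coords[1, 2],
                           pch = if (identical(p$attrs$shape, "square")) 22
                                 else 21,
                           bg = p$attrs$facecolor, col = p$attrs$edgecolor,
                           cex = p$attrs$size / 7)
        }
      } else if (p$kind == "text") {
        graphics::text(p$coords[1, 1], p$coords[1, 2], p$attrs$text,
                       col = p$attrs$color %||% "black",
                       cex = (p$attrs$size %||% 9) / 11, adj = c(0, 0.5))
      }
    }
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Command line: netcanvas network --edges edges.tsv [--layout layout.tsv]
#                                 [--style style.json] --out out.svg
#               netcanvas tree --newick tree.nwk [--kind radial] --out out.svg

parse_cli_flags <- function(args) {
  out <- list(positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (grepl("^--", a)) {
      key <- sub("^--", "", a)
      if (i == length(args) || grepl("^--", args[[i + 1L]])) {
        out[[key]] <- TRUE
        i <- i + 1L
      } else {
        out[[key]] <- args[[i + 1L]]
        i <- i + 2L
      }
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1L
    }
  }
  out
}

read_edge_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  edges <- as.matrix(df[, 1:2, drop = FALSE])
  attrs <- if (ncol(df) >= 3L) list(weight = as.numeric(df[, 3])) else NULL
  build_network(edges = edges, edge_attrs = attrs)
}

read_layout_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  coords <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(coords) <- "double"
  rownames(coords) <- as.character(df[, 1])
  coords
}

read_style_json <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Command-line entry point
#'
#' A thin wrapper over [plot_network()] and [plot_tree()]:
#' `netcanvas network --edges edges.tsv --layout layout.tsv
#' [--style style.json] [--directed] --out out.svg` or
#' `netcanvas tree --newick tree.nwk [--kind radial] [--style style.json]
#' --out out.svg`. Edge lists are two tab-separated id columns (optional
#' third weight column); layouts are `id <tab> x <tab> y [<tab> z]` rows.
#'
#' @param args character vector of command-line arguments.
#' @return the output path, invisibly.
#' @export
netcanvas_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || !args[[1]] %in% c("network", "tree")) {
    stop("usage: netcanvas <network|tree> [flags] --out <file>",
         call. = FALSE)
  }
  cmd <- args[[1]]
  fl <- parse_cli_flags(args[-1])
  if (is.null(fl$out)) stop("missing --out", call. = FALSE)
  style <- if (!is.null(fl$style)) read_style_json(fl$style) else NULL
  handle <- if (cmd == "network") {
    if (is.null(fl$edges)) stop("missing --edges", call. = FALSE)
    net <- read_edge_tsv(fl$edges)
    if (isTRUE(fl$directed) || identical(fl$directed, "true")) {
      net$directed <- TRUE
    }
    if (is.null(fl$layout)) stop("missing --layout", call. = FALSE)
    plot_network(net, layout = read_layout_tsv(fl$layout), style = style)
  } else {
    if (is.null(fl$newick)) stop("missing --newick", call. = FALSE)
    txt <- paste(readLines(fl$newick, warn = FALSE), collapse = "")
    kind <- if (is.null(fl$kind)) "rectangular" else fl$kind
    plot_tree(txt, kind = kind, style = style)
  }
  export_figure(handle, fl$out, format = fl$format)
  invisible(fl$out)
}
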