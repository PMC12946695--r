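# Scene assembly: network/tree + layout + style -> ordered list of draw
# primitives. This is the renderer-facing contract. Positions live in data
# units (they scale with zoom); marker sizes, line widths, arrow dimensions
# and font sizes live in figure units (points; invariant under zoom). Each
# primitive carries explicit space tags for its attributes.
#
# Stacking: grouping < cascade < edge < arrow < vertex < label; within a
# class, element index order. In 3D, primitives are painter-sorted far to
# near before the class order applies among equal depths.

.zclass_rank <- c(grouping = 1, cascade = 2, edge = 3, arrow = 4,
                  vertex = 5, label = 6)

.attr_spaces <- list(
  marker = c(size = "figure", shape = "none", facecolor = "none",
             edgecolor = "none", linewidth = "figure"),
  path = c(color = "none", linewidth = "figure", linestyle = "none"),
  arrow = c(color = "none", width = "figure", length = "figure",
            angle = "none"),
  text = c(text = "none", size = "figure", color = "none",
           hoffset = "figure", voffset = "figure"),
  patch = c(facecolor = "none", alpha = "none")
)

new_primitive <- function(kind, zclass, index, id, coords, attrs,
                          segments = NULL, z = NA_real_) {
  list(kind = kind, zclass = zclass, index = index, id = id,
       coords = coords, segments = segments, attrs = attrs, z = z)
}

#' Describe a vertex grouping (clustering or cover)
#'
#' @param groups named list: group id -> vector of member vertex ids.
#' @param mode `"partition"` (groups must be disjoint and cover all vertices)
#'   or `"cover"` (overlaps allowed).
#' @return a `netcanvas_grouping`.
#' @export
grouping_spec <- function(groups, mode = c("partition", "cover")) {
  mode <- match.arg(mode)
  stopifnot(is.list(groups), !is.null(names(groups)))
  structure(list(groups = groups, mode = mode),
            class = "netcanvas_grouping")
}

check_grouping <- function(grouping, vertex_ids) {
  members <- unlist(grouping$groups, use.names = FALSE)
  unknown <- setdiff(members, vertex_ids)
  if (length(unknown)) {
    stop("lookup error: grouping references unknown vertex: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (grouping$mode == "partition") {
    if (anyDuplicated(members)) {
      stop("structural error: partition groups must be disjoint",
           call. = FALSE)
    }
    if (length(setdiff(vertex_ids, members))) {
      stop("structural error: partition must cover every vertex",
           call. = FALSE)
    }
  }
  invisible(NULL)
}

# hex colour per element from a list of resolved style values, computed once
# per distinct value so the common all-equal case stays O(n)
resolve_colours <- function(values, shade = NULL) {
  if (is.null(shade) && isTRUE(attr(values, "nc_scalar")) &&
      length(values)) {
    c0 <- resolve_colour(values[[1]])
    return(rep(grDevices::rgb(c0[1], c0[2], c0[3]), length(values)))
  }
  keys <- vapply(values, function(v) paste(v, collapse = ","), "")
  ukeys <- unique(keys)
  urgb <- lapply(values[match(ukeys, keys)], resolve_colour)
  idx <- match(keys, ukeys)
  if (is.null(shade)) {
    uhex <- vapply(urgb, function(c) grDevices::rgb(c[1], c[2], c[3]), "")
    return(uhex[idx])
  }
  rgb <- do.call(rbind, urgb)[idx, , drop = FALSE] * shade
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3])
}

#' Dim a colour by depth
#'
#' Scales each RGB channel by `f = floor + (1 - floor) (z - zmin) / (zmax -
#' zmin)`: the nearest element (`z = zmax`) keeps its colour, the farthest is
#' dimmed to `floor`. `z` outside `[zmin, zmax]` is clamped, not an error.
#'
#' @param base_colour RGB triple in [0, 1] (or anything [resolve_colour()]
#'   accepts).
#' @param z,zmin,zmax depth and depth range (data units), `zmin < zmax`.
#' @param floor dimming factor at `zmax` distance, in (0, 1].
#' @return RGB triple in [0, 1] (or matrix if `z` is a vector).
#' @export
depth_shade <- function(base_colour, z, zmin, zmax, floor = 0.3) {
  stopifnot(zmin < zmax, floor > 0, floor <= 1)
  rgb <- resolve_colour(base_colour)
  f <- depth_factor(z, zmin, zmax, floor)
  if (length(z) == 1L) return(rgb * f)
  outer(f, rgb)
}

depth_factor <- function(z, zmin, zmax, floor = 0.3) {
  zc <- pmin(pmax(z, zmin), zmax)
  floor + (1 - floor) * (zc - zmin) / (zmax - zmin)
}

#' Padded convex hull around a point set
#'
#' The convex hull of the points dilated outward by `padding` (a Minkowski sum
#' with a disc when `rounding` is `TRUE`, mitred corners otherwise). With
#' positive padding every input point is strictly inside. A single point
#' dilates to a disc of radius `padding`.
#'
#' @param points numeric matrix (k x 2) of member coordinates, k >= 1.
#' @param padding outward margin in data units, >= 0.
#' @param rounding round the corners?
#' @return closed polygon as an (m x 2) matrix (last vertex != first; the
#'   polygon is implicitly closed).
#' @export
group_hull <- function(points, padding = 0, rounding = TRUE) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) {
    stop("structural error: empty point set", call. = FALSE)
  }
  stopifnot(padding >= 0)
  hidx <- grDevices::chull(points[, 1], points[, 2])
  hull <- points[hidx, , drop = FALSE]
  # ensure counterclockwise orientation
  if (nrow(hull) >= 3L) {
    a <- sum(hull[, 1] * hull[c(2:nrow(hull), 1), 2] -
             hull[c(2:nrow(hull), 1), 1] * hull[, 2]) / 2
    if (a < 0) hull <- hull[nrow(hull):1, , drop = FALSE]
  }
  if (padding == 0) {
    if (nrow(hull) < 3L) {
      stop("structural error: zero-padding hull needs 3 non-collinear points",
           call. = FALSE)
    }
    return(unname(hull))
  }
  if (nrow(hull) == 1L) {
    th <- seq(0, 2 * pi, length.out = 65L)[-65L]
    return(unname(cbind(hull[1, 1] + padding * cos(th),
                        hull[1, 2] + padding * sin(th))))
  }
  if (nrow(hull) == 2L || polygon_area(hull) < 1e-12) {
    return(capsule_polygon(hull, padding))
  }
  dilate_polygon(hull, padding, rounding)
}

polygon_area <- function(p) {
  nxt <- c(2:nrow(p), 1)
  abs(sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2]) / 2)
}

# stadium around the two extreme points of a (nearly) collinear set
capsule_polygon <- function(hull, padding) {
  d2 <- as.matrix(stats::dist(hull))
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  a <- hull[ij[1], ]; b <- hull[ij[2], ]
  v <- b - a
  L <- sqrt(sum(v^2))
  base <- if (L < 1e-12) 0 else atan2(v[2], v[1])
  th1 <- base + pi / 2 + seq(0, pi, length.out = 33L)
  th2 <- base - pi / 2 + seq(0, pi, length.out = 33L)
  unname(rbind(
    cbind(b[1] + padding * cos(th2), b[2] + padding * sin(th2)),
    cbind(a[1] + padding * cos(th1), a[2] + padding * sin(th1))
  ))
}

# Minkowski dilation of a ccw convex polygon by a disc of radius `padding`
dilate_polygon <- function(hull, padding, rounding) {
  k <- nrow(hull)
  nxt <- c(2:k, 1)
  prv <- c(k, 1:(k - 1))
  ev <- hull[nxt, , drop = FALSE] - hull  # edge vectors
  elen <- sqrt(rowSums(ev^2))
  en <- cbind(ev[, 2], -ev[, 1]) / elen   # outward normal (ccw polygon)
  out <- NULL
  for (i in seq_len(k)) {
    n_in <- en[prv[i], ]   # normal of the incoming edge
    n_out <- en[i, ]       # normal of the outgoing edge
    if (rounding) {
      a1 <- atan2(n_in[2], n_in[1])
      a2 <- atan2(n_out[2], n_out[1])
      sweep <- (a2 - a1) %% (2 * pi)
      th <- a1 + sweep * seq(0, 1, length.out = 9L)
      arc <- cbind(hull[i, 1] + padding * cos(th),
                   hull[i, 2] + padding * sin(th))
      out <- rbind(out, arc)
    } else {
      # mitre: intersection of the two offset edge lines
      bis <- n_in + n_out
      bl <- sqrt(sum(bis^2))
      if (bl < 1e-12) {
        out <- rbind(out, hull[i, ] + padding * n_in,
                     hull[i, ] + padding * n_out)
      } else {
        bis <- bis / bl
        scale <- padding / sqrt((1 + sum(n_in * n_out)) / 2)
        out <- rbind(out, hull[i, ] + scale * bis)
      }
    }
  }
  unname(out)
}

#' Shaded patch behind a subtree
#'
#' Rectangular layouts: an axis-aligned band over the subtree's cross-axis
#' range (its leaf segment plus half a leaf spacing each side), running from
#' the node's main-axis coordinate to the maximum leaf extent
#' (`extent_to = "leaves"`) or the subtree's own maximum
#' (`extent_to = "subtree"`). Radial layouts: the corresponding annular
#' sector.
#'
#' @param tree a `netcanvas_tree`.
#' @param node id of the subtree root.
#' @param layout the `netcanvas_layout` produced by [layout_rectangular()] or
#'   [layout_radial()] for this tree.
#' @param extent_to `"leaves"` or `"subtree"`.
#' @return closed polygon as an (m x 2) matrix.
#' @export
cascade_patch <- function(tree, node, layout,
                          extent_to = c("leaves", "subtree")) {
  extent_to <- match.arg(extent_to)
  if (!node %in% tree$nodes) {
    stop("lookup error: unknown node '", node, "'", call. = FALSE)
  }
  kind <- attr(layout, "tree_kind")
  if (is.null(kind)) {
    stop("structural error: layout was not produced by a tree layout",
         call. = FALSE)
  }
  seg <- leaf_segment(tree, node)
  sub_nodes <- tree_subtree_nodes(tree, node)
  if (kind == "rectangular") {
    orientation <- attr(layout, "orientation")
    mc <- rect_main_cross(layout$coords, orientation)
    m0 <- mc$main[[match(node, tree$nodes)]]
    m1 <- if (extent_to == "leaves") {
      max(mc$main[match(tree$leaf_order, tree$nodes)])
    } else {
      max(mc$main[match(sub_nodes, tree$nodes)])
    }
    cr <- c(seg[[1]] - 0.5, seg[[2]] + 0.5)
    rect <- cbind(main = c(m0, m1, m1, m0), cross = cr[c(1, 1, 2, 2)])
    return(unname(main_cross_to_xy(rect, orientation)))
  }
  angles <- attr(layout, "angles")
  radii <- attr(layout, "radii")
  gap <- attr(layout, "angular_span") / length(tree$leaf_order)
  th_leaves <- angles[tree$leaf_order]
  th1 <- th_leaves[[seg[[1]] + 1L]] - gap / 2
  th2 <- th_leaves[[seg[[2]] + 1L]] + gap / 2
  r0 <- radii[[node]]
  r1 <- if (extent_to == "leaves") max(radii[tree$leaf_order])
        else max(radii[sub_nodes])
  th <- seq(th1, th2, length.out = 49L)
  unname(rbind(cbind(r1 * cos(th), r1 * sin(th)),
               cbind(r0 * cos(rev(th)), r0 * sin(rev(th)))))
}

tree_subtree_nodes <- function(tree, node) {
  out <- character(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, cur)
    stack <- c(stack, tree$children[[cur]])
  }
  out
}

rect_main_cross <- function(coords, orientation) {
  switch(orientation,
    right = list(main = coords[, 1], cross = coords[, 2]),
    left  = list(main = -coords[, 1], cross = coords[, 2]),
    up    = list(main = coords[, 2], cross = coords[, 1]),
    down  = list(main = -coords[, 2], cross = coords[, 1])
  )
}

main_cross_to_xy <- function(mc, orientation) {
  switch(orientation,
    right = cbind(mc[, 1], mc[, 2]),
    left  = cbind(-mc[, 1], mc[, 2]),
    up    = cbind(mc[, 2], mc[, 1]),
    down  = cbind(mc[, 2], -mc[, 1])
  )
}

#' Assemble a scene from data, layout and style
#'
#' Produces exactly one marker per vertex, one path per edge (self-loops as
#' loop lobes), one arrow polygon per directed edge, one polygon per group,
#' one patch per requested cascade node, and one text per requested label, in
#' deterministic order. Scenes assembled from the same abstract graph are
#' element-wise identical regardless of the provider that supplied it.
#'
#' @param data a `netcanvas_network` or `netcanvas_tree`.
#' @param layout a `netcanvas_layout` (or raw mapping) covering the data.
#' @param style a `netcanvas_style` (flattened) or style fragments.
#' @param grouping optional [grouping_spec()].
#' @param cascade_nodes optional node ids (trees only) behind which cascade
#'   patches are drawn.
#' @return a `netcanvas_scene`.
#' @export
assemble_scene <- function(data, layout, style = get_default_style(),
                           grouping = NULL, cascade_nodes = NULL) {
  is_tree <- inherits(data, "netcanvas_tree")
  ids <- if (is_tree) data$nodes else data$vertex_ids
  edges <- if (is_tree) tree_edges(data) else data$edges
  directed <- if (is_tree) FALSE else data$directed
  if (!inherits(layout, "netcanvas_layout")) {
    layout <- validate_layout(layout, data)
  } else if (!identical(rownames(layout$coords), ids) &&
             !all(ids %in% rownames(layout$coords))) {
    layout <- validate_layout(layout$coords, data)
  }
  if (!inherits(style, "netcanvas_style")) style <- flatten_style(style)
  n <- length(ids)
  m <- nrow(edges)
  coords <- if (identical(rownames(layout$coords), ids)) layout$coords
            else layout$coords[ids, , drop = FALSE]
  ndim <- layout$ndim
  zr <- if (ndim == 3L) range(coords[, 3]) else c(0, 1)
  if (ndim == 3L && zr[1] == zr[2]) zr <- zr + c(-0.5, 0.5)

  # Fully scalar styles on a plain 2D graph (no groups, cascades, labels or
  # self-loops) are stored column-wise: one packed coordinate block per
  # element class plus one shared resolved-attribute list. This is the
  # vectorised representation a large graph deserves -- assembly stays O(n+m)
  # with a tiny constant -- while scene_primitives() materialises the
  # per-element view on demand, byte-identical to the general path.
  fi <- attr(style, "nc_fast")
  if (is.null(fi)) fi <- style_fast_info(style)
  if (ndim == 2L && is.null(grouping) && is.null(cascade_nodes) &&
      fi$all_scalar[["edge"]] && fi$all_scalar[["vertex"]] &&
      fi$straight && (!directed || fi$all_scalar[["arrow"]]) &&
      fi$no_vertex_label && fi$no_edge_label) {
    if (!is_tree && !is.null(data$edge_index)) {
      si <- data$edge_index[, 1]
      ti <- data$edge_index[, 2]
    } else {
      si <- match(edges[, 1], ids)
      ti <- match(edges[, 2], ids)
    }
    if (!any(si == ti)) {
      ex <- fi$edge_exemplar
      ec <- resolve_colour(ex$color)
      eattrs <- list(color = grDevices::rgb(ec[1], ec[2], ec[3]),
                     linewidth = ex$linewidth, linestyle = ex$linestyle)
      vx <- fi$vertex_exemplar
      fc <- resolve_colour(vx$facecolor)
      oc <- resolve_colour(vx$edgecolor)
      vattrs <- list(size = vx$size, shape = vx$shape,
                     facecolor = grDevices::rgb(fc[1], fc[2], fc[3]),
                     edgecolor = grDevices::rgb(oc[1], oc[2], oc[3]),
                     linewidth = vx$linewidth)
      x1 <- coords[si, 1]; y1 <- coords[si, 2]
      x2 <- coords[ti, 1]; y2 <- coords[ti, 2]
      blocks <- list(
        edges = list(src = edges[, 1], tgt = edges[, 2],
                     x1 = x1, y1 = y1, x2 = x2, y2 = y2, attrs = eattrs),
        arrows = if (directed) {
          ax <- fi$arrow_exemplar
          list(angle = atan2(y2 - y1, x2 - x1),
               attrs = list(color = eattrs$color, width = ax$width,
                            length = ax$length))
        } else NULL,
        vertices = list(ids = ids, x = coords[, 1], y = coords[, 2],
                        attrs = vattrs))
      return(structure(
        list(primitives = NULL, ndim = 2L,
             colourbar = attr(style, "colourbar"), blocks = blocks,
             cache = new.env(parent = emptyenv())),
        class = "netcanvas_scene"))
    }
  }

  prims <- list()

  # --- grouping hulls ------------------------------------------------------
  if (!is.null(grouping)) {
    check_grouping(grouping, ids)
    gids <- names(grouping$groups)
    gres <- resolve_all(style, "grouping", length(gids), gids)
    gcol <- resolve_colours(gres$facecolor)
    for (gi in seq_along(gids)) {
      members <- match(grouping$groups[[gi]], ids)
      poly <- group_hull(coords[members, 1:2, drop = FALSE],
                         padding = gres$padding[[gi]],
                         rounding = isTRUE(gres$rounding[[gi]]))
      prims[[length(prims) + 1L]] <- new_primitive(
        "polygon", "grouping", gi - 1L, gids[[gi]], poly,
        list(facecolor = gcol[[gi]], alpha = gres$alpha[[gi]]))
    }
  }

  # --- cascade patches (trees) --------------------------------------------
  if (!is.null(cascade_nodes)) {
    if (!is_tree) {
      stop("structural error: cascade patches require a tree", call. = FALSE)
    }
    cres <- resolve_all(style, "cascade", length(cascade_nodes),
                        cascade_nodes)
    ccol <- resolve_colours(cres$facecolor)
    for (k in seq_along(cascade_nodes)) {
      poly <- cascade_patch(data, cascade_nodes[[k]], layout,
                            extent_to = cres$extent[[k]])
      prims[[length(prims) + 1L]] <- new_primitive(
        "polygon", "cascade", k - 1L, cascade_nodes[[k]], poly,
        list(facecolor = ccol[[k]], alpha = cres$alpha[[k]]))
    }
  }

  # --- edges ---------------------------------------------------------------
  edge_prims <- vector("list", m)
  arrow_prims <- if (directed) vector("list", m) else list()
  eids <- character(0)
  si <- ti <- integer(0)
  if (m > 0L) {
    eids <- paste0(edges[, 1], "~", edges[, 2])
    si <- match(edges[, 1], ids)
    ti <- match(edges[, 2], ids)
    is_loop <- si == ti
    # a fully scalar straight-edge style (the dominant case) skips
    # per-element style resolution entirely: one resolved exemplar serves
    # every edge and arrow, so assembling very large graphs allocates little
    # beyond the geometry itself and stays O(n + m) with a small constant
    if (ndim == 2L && !any(is_loop) &&
        style_all_scalar(style, "edge") &&
        style_is_scalar(style, "edge", "geometry", "straight") &&
        (!directed || style_all_scalar(style, "arrow"))) {
      sep <- scalar_edge_primitives(style, coords, si, ti, eids, directed)
      edge_prims <- sep$edges
      if (directed) arrow_prims <- sep$arrows
    } else {
      eres <- resolve_all(style, "edge", m, eids)
      lres <- if (any(is_loop)) resolve_all(style, "loop", m, eids) else NULL
      ares <- if (directed) resolve_all(style, "arrow", m, eids) else NULL
      eshade <- if (ndim == 3L) {
        depth_factor((coords[si, 3] + coords[ti, 3]) / 2, zr[1], zr[2])
      } else NULL
      ecol <- resolve_colours(eres$color, eshade)
      tree_kind <- attr(layout, "tree_kind")
      orientation <- attr(layout, "orientation")
      nbr_centroid <- if (any(is_loop)) loop_neighbour_centroids(
        edges, ids, coords, is_loop) else NULL
      ez <- if (ndim == 3L) (coords[si, 3] + coords[ti, 3]) / 2
            else rep(NA_real_, m)
      fast <- style_is_scalar(style, "edge", "geometry", "straight") &&
        style_is_scalar(style, "edge", "offset", 0)
      x1 <- coords[si, 1]; y1 <- coords[si, 2]
      x2 <- coords[ti, 1]; y2 <- coords[ti, 2]
      lw <- eres$linewidth; lst <- eres$linestyle
      aw <- ares$width; al <- ares$length
      # when every edge resolves to the same attributes, share one list
      # (copy-on-write) instead of allocating m of them
      shared_eattrs <- if (is.null(eshade) &&
                           all_equal_scalars(eres$color) &&
                           all_equal_scalars(lw) && all_equal_scalars(lst)) {
        list(color = ecol[[1]], linewidth = lw[[1]], linestyle = lst[[1]])
      } else NULL
      na_z <- NA_real_
      seg_line <- "line"
      dim22 <- c(2L, 2L)
      dim12 <- c(1L, 2L)
      for (i in seq_len(m)) {
        if (fast && !is_loop[[i]]) {
          pm <- c(x1[[i]], x2[[i]], y1[[i]], y2[[i]])
          dim(pm) <- dim22
          edge_prims[[i]] <- list(
            kind = "path", zclass = "edge", index = i - 1L, id = eids[[i]],
            coords = pm, segments = seg_line,
            attrs = if (is.null(shared_eattrs)) {
              list(color = ecol[[i]], linewidth = lw[[i]],
                   linestyle = lst[[i]])
            } else shared_eattrs,
            z = if (ndim == 3L) ez[[i]] else na_z)
          if (directed) {
            ang <- atan2(y2[[i]] - y1[[i]], x2[[i]] - x1[[i]])
            am <- c(x2[[i]], y2[[i]])
            dim(am) <- dim12
            arrow_prims[[i]] <- list(
              kind = "polygon", zclass = "arrow", index = i - 1L,
              id = eids[[i]], coords = am, segments = NULL,
              attrs = list(color = ecol[[i]], width = aw[[i]],
                           length = al[[i]], angle = ang),
              z = if (ndim == 3L) coords[ti[[i]], 3] else NA_real_)
          }
          next
        }
        p1 <- coords[si[[i]], ]
        p2 <- coords[ti[[i]], ]
        path <- if (is_loop[[i]]) {
          ang <- lres$angle[[i]]
          if (is.null(ang)) ang <- loop_auto_angle(nbr_centroid, eids[[i]],
                                                   edges[i, 1], p1, ids)
          loop_path(p1[1:2], lres$size[[i]], ang)
        } else {
          edge_path_dispatch(eres$geometry[[i]], p1[1:2], p2[1:2], eres, i,
                             tree_kind, orientation)
        }
        off <- eres$offset[[i]]
        if (!is.null(off) && off != 0 && !is_loop[[i]]) {
          path <- offset_path(path, p1[1:2], p2[1:2], off)
        }
        edge_prims[[i]] <- new_primitive(
          "path", "edge", i - 1L, eids[[i]], unname(path$points),
          list(color = ecol[[i]], linewidth = lw[[i]], linestyle = lst[[i]]),
          segments = path$segments, z = ez[[i]])
        if (directed) {
          tangent <- path_terminal_tangent(path)[1:2]
          arrow_prims[[i]] <- new_primitive(
            "polygon", "arrow", i - 1L, eids[[i]],
            matrix(path_end(path)[1:2], 1L),
            list(color = ecol[[i]], width = aw[[i]], length = al[[i]],
                 angle = atan2(tangent[[2]], tangent[[1]])),
            z = if (ndim == 3L) coords[ti[[i]], 3] else NA_real_)
        }
      }
    }
  }
  prims <- c(prims, edge_prims, arrow_prims)

  # --- vertices ------------------------------------------------------------
  vres <- resolve_all(style, "vertex", n, ids)
  vshade <- if (ndim == 3L) depth_factor(coords[, 3], zr[1], zr[2]) else NULL
  vface <- resolve_colours(vres$facecolor, vshade)
  vedge <- resolve_colours(vres$edgecolor, vshade)
  vertex_prims <- vector("list", n)
  vsize <- vres$size; vshape <- vres$shape; vlw <- vres$linewidth
  vz <- if (ndim == 3L) coords[, 3] else rep(NA_real_, n)
  shared_vattrs <- if (n > 0L && is.null(vshade) &&
                       all_equal_scalars(vres$facecolor) &&
                       all_equal_scalars(vres$edgecolor) &&
                       all_equal_scalars(vsize) && all_equal_scalars(vshape) &&
                       all_equal_scalars(vlw)) {
    list(size = vsize[[1]], shape = vshape[[1]], facecolor = vface[[1]],
         edgecolor = vedge[[1]], linewidth = vlw[[1]])
  } else NULL
  na_zv <- NA_real_
  dim1d <- c(1L, as.integer(ndim))
  xs <- coords[, 1]; ys <- coords[, 2]
  for (i in seq_len(n)) {
    cm <- if (ndim == 2L) c(xs[[i]], ys[[i]]) else coords[i, ]
    dim(cm) <- dim1d
    vertex_prims[[i]] <- list(
      kind = "marker", zclass = "vertex", index = i - 1L, id = ids[[i]],
      coords = cm, segments = NULL,
      attrs = if (is.null(shared_vattrs)) {
        list(size = vsize[[i]], shape = vshape[[i]], facecolor = vface[[i]],
             edgecolor = vedge[[i]], linewidth = vlw[[i]])
      } else shared_vattrs,
      z = if (ndim == 3L) vz[[i]] else na_zv)
  }
  prims <- c(prims, vertex_prims)

  # --- labels --------------------------------------------------------------
  vlres <- if (is.null(style_raw_prop(style, "vertex_label", "text"))) NULL
           else resolve_all(style, "vertex_label", n, ids)
  want <- if (is.null(vlres)) logical(0)
          else !vapply(vlres$text, is.null, TRUE)
  if (any(want)) {
    lcol <- resolve_colours(vlres$color[want])
    widx <- which(want)
    for (k in seq_along(widx)) {
      i <- widx[[k]]
      txt <- vlres$text[[i]]
      if (identical(txt, "id")) txt <- ids[[i]]
      prims[[length(prims) + 1L]] <- new_primitive(
        "text", "label", i - 1L, ids[[i]], matrix(coords[i, ], 1L),
        list(text = as.character(txt), size = vlres$size[[i]],
             color = lcol[[k]], hoffset = vlres$hoffset[[i]],
             voffset = vlres$voffset[[i]]),
        z = if (ndim == 3L) coords[i, 3] else NA_real_)
    }
  }
  elres <- if (is.null(style_raw_prop(style, "edge_label", "text"))) NULL
           else resolve_all(style, "edge_label", m,
                            if (m) eids else character(0))
  ewant <- if (is.null(elres)) logical(0)
          else !vapply(elres$text, is.null, TRUE)
  if (any(ewant)) {
    lcol <- resolve_colours(elres$color[ewant])
    widx <- which(ewant)
    for (k in seq_along(widx)) {
      i <- widx[[k]]
      txt <- elres$text[[i]]
      if (identical(txt, "id")) txt <- eids[[i]]
      mid <- (coords[si[[i]], ] + coords[ti[[i]], ]) / 2
      prims[[length(prims) + 1L]] <- new_primitive(
        "text", "label", n + i - 1L, eids[[i]], matrix(mid, 1L),
        list(text = as.character(txt), size = elres$size[[i]],
             color = lcol[[k]], hoffset = elres$hoffset[[i]],
             voffset = elres$voffset[[i]]),
        z = if (ndim == 3L) mid[[3]] else NA_real_)
    }
  }

  if (ndim == 3L) {
    # painter's algorithm: far to near, then zorder class, then index
    zs <- vapply(prims, function(p) p$z, 1)
    zs[is.na(zs)] <- -Inf
    rk <- .zclass_rank[vapply(prims, function(p) p$zclass, "")]
    ix <- vapply(prims, function(p) p$index, 1L)
    prims <- prims[order(zs, rk, ix)]
  }

  structure(list(primitives = prims, ndim = ndim,
                 colourbar = attr(style, "colourbar")),
            class = "netcanvas_scene")
}

# was this resolved value list produced from one scalar style value?
all_equal_scalars <- function(vl) {
  isTRUE(attr(vl, "nc_scalar"))
}

# raw (unresolved) value of one style property, falling back to the defaults
style_raw_prop <- function(style, etype, prop) {
  props <- style[[etype]]
  if (!is.null(props) && prop %in% names(props)) props[[prop]]
  else .style_defaults$default[[etype]][[prop]]
}

# is this style property a plain scalar equal to `value`?
style_is_scalar <- function(style, etype, prop, value) {
  v <- style_raw_prop(style, etype, prop)
  style_value_kind(v, prop) == "scalar" && length(v) == 1L &&
    isTRUE(v == value)
}

# does every property of this element type resolve to one scalar?
style_all_scalar <- function(style, etype) {
  for (p in .style_vocabulary[[etype]]) {
    v <- style_raw_prop(style, etype, p)
    if (style_value_kind(v, p) != "scalar") return(FALSE)
  }
  TRUE
}

# tight constructor for the all-scalar straight-edge case: one shared attrs
# list, line segments only, minimal allocations per edge
scalar_edge_primitives <- function(style, coords, si, ti, eids, directed) {
  m <- length(si)
  ex <- resolve_element(style, "edge", 0L, NULL)
  c0 <- resolve_colour(ex$color)
  shared_attrs <- list(color = grDevices::rgb(c0[1], c0[2], c0[3]),
                       linewidth = ex$linewidth, linestyle = ex$linestyle)
  shared_arrow <- if (directed) resolve_element(style, "arrow", 0L, NULL)
                  else NULL
  edge_prims <- vector("list", m)
  arrow_prims <- if (directed) vector("list", m) else list()
  x1 <- coords[si, 1]; y1 <- coords[si, 2]
  x2 <- coords[ti, 1]; y2 <- coords[ti, 2]
  na_z <- NA_real_
  seg_line <- "line"
  dim22 <- c(2L, 2L)
  dim12 <- c(1L, 2L)
  for (i in seq_len(m)) {
    pm <- c(x1[[i]], x2[[i]], y1[[i]], y2[[i]])
    dim(pm) <- dim22
    edge_prims[[i]] <- list(
      kind = "path", zclass = "edge", index = i - 1L, id = eids[[i]],
      coords = pm, segments = seg_line, attrs = shared_attrs, z = na_z)
    if (directed) {
      am <- c(x2[[i]], y2[[i]])
      dim(am) <- dim12
      arrow_prims[[i]] <- list(
        kind = "polygon", zclass = "arrow", index = i - 1L, id = eids[[i]],
        coords = am, segments = NULL,
        attrs = list(color = shared_attrs$color,
                     width = shared_arrow$width,
                     length = shared_arrow$length,
                     angle = atan2(y2[[i]] - y1[[i]], x2[[i]] - x1[[i]])),
        z = na_z)
    }
  }
  list(edges = edge_prims, arrows = arrow_prims)
}

edge_path_dispatch <- function(kind, p1, p2, eres, i, tree_kind,
                               orientation) {
  switch(kind,
    straight = straight_path(p1, p2),
    arc = arc_path(p1, p2, eres$tension[[i]]),
    bezier = {
      wp <- eres$waypoints[[i]]
      if (is.null(wp)) {
        stop("grammar error: bezier geometry needs control points in the ",
             "'waypoints' property (edge ", i - 1L, ")", call. = FALSE)
      }
      bezier_path(p1, p2, wp)
    },
    ports = {
      pr <- eres$ports[[i]]
      if (is.null(pr) || length(pr) < 2L) {
        stop("grammar error: ports geometry needs a (theta_out, theta_in) ",
             "pair in the 'ports' property (edge ", i - 1L, ")",
             call. = FALSE)
      }
      ports_path(p1, p2, pr[[1]], pr[[2]])
    },
    waypoints = {
      wp <- eres$waypoints[[i]]
      if (is.null(wp)) {
        stop("grammar error: waypoints geometry needs the 'waypoints' ",
             "property (edge ", i - 1L, ")", call. = FALSE)
      }
      waypoint_path(p1, p2, wp)
    },
    elbow = elbow_path(p1, p2,
                       kind = if (identical(tree_kind, "radial")) "radial"
                              else "rectangular",
                       orientation = if (is.null(orientation)) "right"
                                     else orientation),
    stop("grammar error: unknown edge geometry '", kind, "'", call. = FALSE)
  )
}

# rigid perpendicular-left translation of a path, used to separate parallel
# edges; the offset is in data units
offset_path <- function(path, p1, p2, off) {
  v <- p2 - p1
  L <- sqrt(sum(v^2))
  if (L == 0) return(path)
  nl <- c(-v[2L], v[1L]) / L
  pts <- path$points
  pts[, 1] <- pts[, 1] + off * nl[1L]
  pts[, 2] <- pts[, 2] + off * nl[2L]
  new_path(pts, path$segments, path$closed)
}

# mean position of each looping vertex's neighbours (loop placement aid)
loop_neighbour_centroids <- function(edges, ids, coords, is_loop) {
  loops <- unique(edges[is_loop, 1])
  out <- vector("list", length(loops))
  names(out) <- loops
  for (v in loops) {
    nb <- unique(c(edges[edges[, 1] == v & !is_loop_row(edges), 2],
                   edges[edges[, 2] == v & !is_loop_row(edges), 1]))
    nb <- setdiff(nb, v)
    out[[v]] <- if (length(nb)) {
      colMeans(coords[match(nb, ids), 1:2, drop = FALSE])
    } else NULL
  }
  out
}

is_loop_row <- function(edges) edges[, 1] == edges[, 2]

# loop direction: away from the neighbour centroid; straight up when isolated
loop_auto_angle <- function(centroids, eid, vertex, p, ids) {
  ctr <- centroids[[vertex]]
  if (is.null(ctr)) return(pi / 2)
  d <- p[1:2] - ctr
  if (sum(d^2) < 1e-24) return(pi / 2)
  atan2(d[[2]], d[[1]])
}

#' The ordered primitive list of a scene
#'
#' Scenes built from fully scalar styles store their geometry column-wise;
#' this accessor materialises (and caches) the per-element primitive view,
#' identical to what a generally-styled assembly produces.
#' @param scene a `netcanvas_scene`.
#' @return list of primitives in draw order.
#' @export
scene_primitives <- function(scene) {
  if (!is.null(scene$primitives)) return(scene$primitives)
  if (is.null(scene$cache$prims)) {
    scene$cache$prims <- materialise_blocks(scene$blocks)
  }
  scene$cache$prims
}

materialise_blocks <- function(blocks) {
  eb <- blocks$edges; ab <- blocks$arrows; vb <- blocks$vertices
  m <- length(eb$src)
  eb$ids <- if (m) paste0(eb$src, "~", eb$tgt) else character(0)
  n <- length(vb$ids)
  prims <- vector("list", m + (if (is.null(ab)) 0L else m) + n)
  dim22 <- c(2L, 2L)
  dim12 <- c(1L, 2L)
  tpl_e <- list(kind = "path", zclass = "edge", index = 0L, id = "",
                coords = NULL, segments = "line", attrs = eb$attrs,
                z = NA_real_)
  for (i in seq_len(m)) {
    p <- tpl_e
    p[[3L]] <- i - 1L
    p[[4L]] <- eb$ids[[i]]
    pm <- c(eb$x1[[i]], eb$x2[[i]], eb$y1[[i]], eb$y2[[i]])
    dim(pm) <- dim22
    p[[5L]] <- pm
    prims[[i]] <- p
  }
  k <- m
  if (!is.null(ab)) {
    aa <- ab$attrs
    tpl_a <- list(kind = "polygon", zclass = "arrow", index = 0L, id = "",
                  coords = NULL, segments = NULL, attrs = NULL, z = NA_real_)
    for (i in seq_len(m)) {
      p <- tpl_a
      p[[3L]] <- i - 1L
      p[[4L]] <- eb$ids[[i]]
      am <- c(eb$x2[[i]], eb$y2[[i]])
      dim(am) <- dim12
      p[[5L]] <- am
      p[[7L]] <- list(color = aa$color, width = aa$width, length = aa$length,
                      angle = ab$angle[[i]])
      prims[[k + i]] <- p
    }
    k <- k + m
  }
  tpl_v <- list(kind = "marker", zclass = "vertex", index = 0L, id = "",
                coords = NULL, segments = NULL, attrs = vb$attrs,
                z = NA_real_)
  for (i in seq_len(n)) {
    p <- tpl_v
    p[[3L]] <- i - 1L
    p[[4L]] <- vb$ids[[i]]
    cm <- c(vb$x[[i]], vb$y[[i]])
    dim(cm) <- dim12
    p[[5L]] <- cm
    prims[[k + i]] <- p
  }
  prims
}

#' Rescale the data-space coordinates of a scene
#'
#' Multiplies every data-space coordinate by `scale`; figure-space attributes
#' are untouched by construction.
#' @param scene a `netcanvas_scene`.
#' @param scale positive factor.
#' @export
scale_scene <- function(scene, scale) {
  stopifnot(scale > 0)
  if (!is.null(scene$blocks)) {
    b <- scene$blocks
    b$edges$x1 <- b$edges$x1 * scale; b$edges$y1 <- b$edges$y1 * scale
    b$edges$x2 <- b$edges$x2 * scale; b$edges$y2 <- b$edges$y2 * scale
    b$vertices$x <- b$vertices$x * scale
    b$vertices$y <- b$vertices$y * scale
    scene$blocks <- b
    scene$cache <- new.env(parent = emptyenv())
    return(scene)
  }
  scene$primitives <- lapply(scene$primitives, function(p) {
    p$coords <- p$coords * scale
    if (!is.na(p$z)) p$z <- p$z * scale
    p
  })
  scene
}

#' Check the dual coordinate contract under zoom
#'
#' Rescales all data-space coordinates by `scale` and verifies that every
#' figure-space attribute of every primitive is unchanged while every
#' coordinate scaled exactly -- the testable form of "marker size is
#' maintained upon zoom".
#'
#' @param scene a `netcanvas_scene`.
#' @param scale positive zoom factor.
#' @return `TRUE` if the contract holds.
#' @export
zoom_transform_check <- function(scene, scale) {
  stopifnot(scale > 0)
  before <- scene_primitives(scene)
  after <- scene_primitives(scale_scene(scene, scale))
  for (k in seq_along(before)) {
    a <- before[[k]]; b <- after[[k]]
    if (!identical(a$attrs, b$attrs)) return(FALSE)  # figure space untouched
    if (!isTRUE(all(b$coords == a$coords * scale))) return(FALSE)
  }
  TRUE
}

#' Count primitives per zorder class
#' @param scene a `netcanvas_scene`.
#' @return named integer vector.
#' @export
scene_counts <- function(scene) {
  if (!is.null(scene$blocks)) {
    b <- scene$blocks
    m <- length(b$edges$src)
    return(stats::setNames(
      as.integer(c(0, 0, m, if (is.null(b$arrows)) 0 else m,
                   length(b$vertices$ids), 0)),
      names(.zclass_rank)))
  }
  z <- vapply(scene$primitives, function(p) p$zclass, "")
  tab <- table(factor(z, levels = names(.zclass_rank)))
  stats::setNames(as.integer(tab), names(tab))
}
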