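# Rectangular and radial tree embeddings -- the only layouts computed
# internally. General network layouts come from upstream providers.
#
# Conventions (used everywhere, including edge ports and loops): angles in
# radians, counterclockwise from the positive x axis; leaf spacing fixed at
# one data unit; internal nodes sit at the plain arithmetic mean of their
# children's cross coordinates / angles (no subtree-size weighting).

#' Options for tree layouts
#'
#' @param kind `"rectangular"` or `"radial"`.
#' @param use_branch_lengths if `FALSE`, the main-axis coordinate is integer
#'   depth instead of cumulative branch length.
#' @param orientation direction of growth for rectangular layouts:
#'   `"right"` (main axis = +x), `"left"` (-x), `"up"` (+y), `"down"` (-y).
#' @param angular_span total angle (radians) spanned by the leaves of a radial
#'   layout; must be in (0, 2*pi]. One leaf-gap is reserved at the end of the
#'   span (angles step by span/L, not span/(L-1)) so that with a full-circle
#'   span the first and last leaf do not collide.
#' @param start_angle angle of leaf 0 in a radial layout.
#' @return a `netcanvas_tree_layout_options` list.
#' @export
tree_layout_options <- function(kind = c("rectangular", "radial"),
                                use_branch_lengths = TRUE,
                                orientation = c("right", "left", "up", "down"),
                                angular_span = 2 * pi,
                                start_angle = 0) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  if (!(angular_span > 0 && angular_span <= 2 * pi + 1e-12)) {
    stop("grammar error: angular_span must be in (0, 2*pi]", call. = FALSE)
  }
  structure(list(kind = kind, use_branch_lengths = isTRUE(use_branch_lengths),
                 orientation = orientation, angular_span = angular_span,
                 start_angle = start_angle),
            class = "netcanvas_tree_layout_options")
}

# main-axis coordinate: cumulative branch length (or depth) from the root,
# computed parent-before-child by walking nodes in build order (root first,
# children always appear after their parent in `nodes`? not guaranteed --
# so walk the tree explicitly).
tree_main_coord <- function(tree, use_branch_lengths) {
  main <- stats::setNames(rep(NA_real_, length(tree$nodes)), tree$nodes)
  main[[tree$root]] <- 0
  stack <- tree$root
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (ch in tree$children[[cur]]) {
      step <- if (use_branch_lengths) tree$branch_length[[ch]] else 1
      main[[ch]] <- main[[cur]] + step
      stack <- c(stack, ch)
    }
  }
  main
}

# cross coordinate: leaf i (0-based, in leaf_order) at i; internal = mean of
# children's cross, computed children-before-parent (post-order).
tree_cross_coord <- function(tree, leaf_value) {
  cross <- stats::setNames(rep(NA_real_, length(tree$nodes)), tree$nodes)
  cross[tree$leaf_order] <- leaf_value
  post <- tree_postorder(tree)
  for (nd in post) {
    ch <- tree$children[[nd]]
    if (!is.null(ch) && length(ch)) cross[[nd]] <- mean(cross[ch])
  }
  cross
}

tree_postorder <- function(tree) {
  out <- character(0)
  stack <- tree$root
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(cur, out)
    stack <- c(stack, tree$children[[cur]])
  }
  out
}

#' Rectangular tree layout
#'
#' Leaf i (in `leaf_order`) sits at cross-axis coordinate i with unit spacing;
#' each internal node's cross coordinate is the arithmetic mean of its
#' children's; the main-axis coordinate is the cumulative branch length from
#' the root (or integer depth when `use_branch_lengths` is `FALSE`). The
#' orientation maps (main, cross) onto (x, y).
#'
#' @param tree a `netcanvas_tree`.
#' @param opts a [tree_layout_options()] with `kind = "rectangular"`.
#' @return a `netcanvas_layout` covering all nodes, tagged with the layout
#'   kind and orientation so elbow edges and cascade patches can match it.
#' @export
layout_rectangular <- function(tree, opts = tree_layout_options()) {
  stopifnot(inherits(tree, "netcanvas_tree"))
  if (opts$kind != "rectangular") {
    stop("grammar error: options are for kind '", opts$kind, "'",
         call. = FALSE)
  }
  if (length(tree$leaf_order) == 0L) {
    stop("structural error: tree has no leaves", call. = FALSE)
  }
  main <- tree_main_coord(tree, opts$use_branch_lengths)
  cross <- tree_cross_coord(tree, seq_along(tree$leaf_order) - 1)
  xy <- switch(opts$orientation,
    right = cbind(main, cross),
    left  = cbind(-main, cross),
    up    = cbind(cross, main),
    down  = cbind(cross, -main)
  )
  colnames(xy) <- c("x", "y")
  rownames(xy) <- tree$nodes
  out <- structure(list(coords = xy, ndim = 2L), class = "netcanvas_layout")
  attr(out, "tree_kind") <- "rectangular"
  attr(out, "orientation") <- opts$orientation
  out
}

#' Radial tree layout
#'
#' Leaf i gets angle `start_angle + i * angular_span / L` (L = number of
#' leaves; one leaf-gap is reserved so a full 2*pi span does not collide the
#' first and last leaf); internal node angles are the mean of their children's
#' angles; the radius is the cumulative branch length from the root. Cartesian
#' coordinates are `(r cos(theta), r sin(theta))`, counterclockwise.
#'
#' @inheritParams layout_rectangular
#' @export
layout_radial <- function(tree,
                          opts = tree_layout_options(kind = "radial")) {
  stopifnot(inherits(tree, "netcanvas_tree"))
  if (opts$kind != "radial") {
    stop("grammar error: options are for kind '", opts$kind, "'",
         call. = FALSE)
  }
  L <- length(tree$leaf_order)
  if (L == 0L) stop("structural error: tree has no leaves", call. = FALSE)
  r <- tree_main_coord(tree, opts$use_branch_lengths)
  theta <- tree_cross_coord(
    tree, opts$start_angle + (seq_len(L) - 1) * opts$angular_span / L)
  xy <- cbind(x = r * cos(theta), y = r * sin(theta))
  rownames(xy) <- tree$nodes
  out <- structure(list(coords = xy, ndim = 2L), class = "netcanvas_layout")
  attr(out, "tree_kind") <- "radial"
  attr(out, "angles") <- theta
  attr(out, "radii") <- r
  attr(out, "angular_span") <- opts$angular_span
  attr(out, "start_angle") <- opts$start_angle
  out
}

#' Contiguous leaf-index range under a node
#'
#' Because `leaf_order` is a depth-first traversal, the leaves under any node
#' occupy a contiguous block of indices; cascade patches span exactly that
#' block.
#'
#' @param tree a `netcanvas_tree`.
#' @param node a node id.
#' @return integer vector `(first, last)` of 0-based leaf indices.
#' @export
leaf_segment <- function(tree, node) {
  if (!node %in% tree$nodes) {
    stop("lookup error: unknown node '", node, "'", call. = FALSE)
  }
  leaves <- tree_dfs_leaves(tree, node)
  idx <- match(leaves, tree$leaf_order) - 1L
  c(first = min(idx), last = max(idx))
}
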