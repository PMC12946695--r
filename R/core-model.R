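#' Build the canonical internal network representation
#'
#' Every input provider normalises into this structure and every downstream
#' stage (styling, geometry, scene assembly) consumes it, so the rendered
#' output depends only on the abstract graph, never on which analysis library
#' produced it.
#'
#' Vertex identity is by label; per-element style sequences map by element
#' *order* (insertion order). Edge order is preserved verbatim: parallel edges
#' are distinct styleable elements and self-loops are kept.
#'
#' @param edges a two-column matrix / data.frame of (source, target) labels,
#'   or a list of length-2 vectors. May be empty.
#' @param vertex_ids optional vector of unique vertex labels. Defaults to the
#'   edge endpoints in first-appearance order.
#' @param directed logical; are edges directed?
#' @param vertex_attrs named list of per-vertex attribute vectors (each of
#'   length `n_vertices`).
#' @param edge_attrs named list of per-edge attribute vectors (each of length
#'   `nrow(edges)`).
#' @return an object of class `netcanvas_network` with fields `n_vertices`,
#'   `vertex_ids`, `edges` (two-column character matrix), `directed`,
#'   `vertex_attrs`, `edge_attrs`.
#' @examples
#' g <- build_network(list(c("A", "B"), c("B", "C")))
#' g$vertex_ids
#' @export
build_network <- function(edges = NULL, vertex_ids = NULL, directed = FALSE,
                          vertex_attrs = NULL, edge_attrs = NULL) {
  em <- as_edge_matrix(edges)
  if (is.null(vertex_ids)) {
    # first-appearance order: interleave source/target per edge
    seen <- as.character(t(em))
    vertex_ids <- unique(seen)
  } else {
    vertex_ids <- as.character(vertex_ids)
    if (anyDuplicated(vertex_ids)) {
      stop("structural error: duplicated vertex ids", call. = FALSE)
    }
    if (nrow(em) > 0L && !all(c(em) %in% vertex_ids)) {
      bad <- setdiff(unique(c(em)), vertex_ids)
      stop("structural error: edge references unknown vertex: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  n <- length(vertex_ids)
  check_attr_lengths(vertex_attrs, n, "vertex")
  check_attr_lengths(edge_attrs, nrow(em), "edge")
  structure(
    list(
      n_vertices = n,
      vertex_ids = vertex_ids,
      edges = em,
      # endpoint indices resolved once here, so downstream per-edge work
      # never repeats the label lookup
      edge_index = cbind(match(em[, 1], vertex_ids),
                         match(em[, 2], vertex_ids)),
      directed = isTRUE(directed),
      vertex_attrs = if (is.null(vertex_attrs)) list() else vertex_attrs,
      edge_attrs = if (is.null(edge_attrs)) list() else edge_attrs
    ),
    class = "netcanvas_network"
  )
}

as_edge_matrix <- function(edges) {
  if (is.null(edges) || length(edges) == 0L) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("source", "target"))))
  }
  if (is.list(edges) && !is.data.frame(edges)) {
    if (!all(vapply(edges, length, 1L) == 2L)) {
      stop("structural error: each edge must be a (source, target) pair",
           call. = FALSE)
    }
    em <- matrix(as.character(unlist(lapply(edges, as.character))),
                 ncol = 2, byrow = TRUE)
  } else {
    em <- as.matrix(edges)
    if (ncol(em) < 2L) {
      stop("structural error: edges need two columns", call. = FALSE)
    }
    em <- matrix(as.character(em[, 1:2, drop = FALSE]), ncol = 2)
  }
  dimnames(em) <- list(NULL, c("source", "target"))
  em
}

check_attr_lengths <- function(attrs, n, what) {
  if (is.null(attrs)) return(invisible(NULL))
  if (!is.list(attrs) || (length(attrs) > 0L && is.null(names(attrs)))) {
    stop("length error: ", what, "_attrs must be a named list", call. = FALSE)
  }
  for (nm in names(attrs)) {
    if (length(attrs[[nm]]) != n) {
      stop("length error: ", what, " attribute '", nm, "' has length ",
           length(attrs[[nm]]), ", expected ", n, call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Build the canonical rooted-tree representation
#'
#' The tree is encoded by a child-to-parent map. Children of each node are
#' ordered by the first appearance of the child in `parent_map`, and
#' `leaf_order` is the depth-first traversal order of the leaves respecting
#' that child order -- the order used by the rectangular and radial layouts.
#'
#' @param parent_map named vector or list mapping each non-root node id to its
#'   parent id. The root is the unique id that appears as a parent but never
#'   as a child.
#' @param branch_lengths optional named numeric vector: length of the edge
#'   above each node. Missing entries default to 1 so topology-only trees
#'   still lay out; the root's length is 0.
#' @return an object of class `netcanvas_tree` with fields `nodes`, `root`,
#'   `parent`, `children`, `branch_length`, `leaf_order`.
#' @examples
#' tr <- build_tree(c(A = "i", B = "i", i = "r", C = "r"))
#' tr$leaf_order
#' @export
build_tree <- function(parent_map, branch_lengths = NULL) {
  if (length(parent_map) == 0L) {
    stop("structural error: empty parent map", call. = FALSE)
  }
  kids <- names(parent_map)
  pars <- as.character(unlist(parent_map, use.names = FALSE))
  if (is.null(kids) || any(kids == "")) {
    stop("structural error: parent_map must be named child -> parent",
         call. = FALSE)
  }
  if (anyDuplicated(kids)) {
    stop("structural error: node listed with two parents", call. = FALSE)
  }
  roots <- setdiff(unique(pars), kids)
  if (length(roots) != 1L) {
    stop("structural error: expected exactly one root, found ",
         length(roots), call. = FALSE)
  }
  root <- roots
  nodes <- c(root, kids)
  parent <- stats::setNames(c(NA_character_, pars), nodes)
  # children ordered by first appearance of the child in parent_map
  children <- split(kids, factor(pars, levels = unique(pars)))
  children <- lapply(children, as.character)
  # cycle / connectivity check: walk up from every node, must reach root
  for (nd in kids) {
    cur <- nd
    steps <- 0L
    while (!is.na(parent[[cur]])) {
      cur <- parent[[cur]]
      steps <- steps + 1L
      if (steps > length(nodes)) {
        stop("structural error: cycle detected in parent map", call. = FALSE)
      }
    }
    if (cur != root) {
      stop("structural error: disconnected node '", nd, "'", call. = FALSE)
    }
  }
  bl <- stats::setNames(rep(1, length(nodes)), nodes)
  if (!is.null(branch_lengths)) {
    bln <- names(branch_lengths)
    unknown <- setdiff(bln, nodes)
    if (length(unknown)) {
      stop("structural error: branch length for unknown node: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    bl[bln] <- as.numeric(unlist(branch_lengths, use.names = FALSE))
    if (any(bl < 0)) {
      stop("structural error: negative branch length", call. = FALSE)
    }
  }
  bl[[root]] <- 0
  tr <- structure(
    list(nodes = nodes, root = root, parent = parent, children = children,
         branch_length = bl, leaf_order = character(0)),
    class = "netcanvas_tree"
  )
  tr$leaf_order <- tree_dfs_leaves(tr, root)
  tr
}

# depth-first leaf order under `node`, respecting children order
tree_dfs_leaves <- function(tree, node) {
  out <- character(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    ch <- tree$children[[cur]]
    if (is.null(ch) || length(ch) == 0L) {
      out <- c(out, cur)
    } else {
      stack <- c(stack, rev(ch))
    }
  }
  out
}

tree_is_leaf <- function(tree, node) {
  ch <- tree$children[[node]]
  is.null(ch) || length(ch) == 0L
}

#' List edges of a tree as (parent, child) pairs
#'
#' One edge per non-root node, in node order. This is the edge sequence scene
#' assembly styles positionally.
#' @param tree a `netcanvas_tree`
#' @return two-column character matrix
#' @export
tree_edges <- function(tree) {
  kids <- tree$nodes[tree$nodes != tree$root]
  cbind(source = unname(tree$parent[kids]), target = kids)
}

#' Validate a raw vertex-coordinate mapping against a network or tree
#'
#' Layouts for general networks are consumed from upstream analysis libraries,
#' not computed here; this checks the contract: every vertex covered, all
#' coordinate tuples of one common dimension (2 or 3), all values finite.
#'
#' @param layout a named list of coordinate vectors, or a numeric matrix with
#'   row names, mapping vertex id to its coordinates (data units).
#' @param network a `netcanvas_network` or `netcanvas_tree` whose vertices
#'   must all be covered.
#' @param ndim_hint optional 2 or 3; checked against the inferred dimension.
#' @return an object of class `netcanvas_layout`: list with `coords` (numeric
#'   matrix, rownames = vertex ids) and `ndim`.
#' @export
validate_layout <- function(layout, network, ndim_hint = NULL) {
  ids <- if (inherits(network, "netcanvas_tree")) network$nodes
         else network$vertex_ids
  if (inherits(layout, "netcanvas_layout")) {
    coords <- layout$coords
  } else if (is.matrix(layout)) {
    coords <- layout
  } else {
    lens <- vapply(layout, length, 1L)
    if (length(unique(lens)) > 1L) {
      stop("dimension error: mixed coordinate dimensions", call. = FALSE)
    }
    coords <- do.call(rbind, lapply(layout, as.numeric))
    rownames(coords) <- names(layout)
  }
  if (is.null(rownames(coords))) {
    stop("coverage error: layout has no vertex ids", call. = FALSE)
  }
  missing <- setdiff(ids, rownames(coords))
  if (length(missing)) {
    stop("coverage error: no coordinates for vertex: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  coords <- coords[ids, , drop = FALSE]
  ndim <- ncol(coords)
  if (!ndim %in% c(2L, 3L)) {
    stop("dimension error: coordinates must be 2D or 3D, got ", ndim,
         call. = FALSE)
  }
  if (!is.null(ndim_hint) && ndim != ndim_hint) {
    stop("dimension error: layout is ", ndim, "D but ", ndim_hint,
         "D was requested", call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("value error: non-finite coordinate in layout", call. = FALSE)
  }
  storage.mode(coords) <- "double"
  structure(list(coords = coords, ndim = ndim), class = "netcanvas_layout")
}

#' @export
print.netcanvas_network <- function(x, ...) {
  cat(sprintf("<netcanvas network: %d vertices, %d edges, %s>\n",
              x$n_vertices, nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' @export
print.netcanvas_tree <- function(x, ...) {
  cat(sprintf("<netcanvas tree: %d nodes, %d leaves, root '%s'>\n",
              length(x$nodes), length(x$leaf_order), x$root))
  invisible(x)
}
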