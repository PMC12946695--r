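# Synthetic data generators and a toy Newick reader/writer, so every stage is
# testable without downloads. The seed fully determines each output.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Random graph with a fixed number of edges (G(n, m))
#'
#' Samples `m` distinct undirected edges uniformly without replacement among
#' the `n (n - 1) / 2` possible pairs (no self-loops). Matches the (n, m)
#' parameterisation used for scalability benchmarking, where graphs with
#' `m = 2 n` are the reference points.
#'
#' @param n number of vertices.
#' @param m number of edges, `0 <= m <= n (n - 1) / 2`.
#' @param seed integer; equal seeds give identical edge lists.
#' @return a `netcanvas_network` with vertices `v1 ... vn`.
#' @export
erdos_renyi <- function(n, m, seed = 1L) {
  n <- as.integer(n)
  max_m <- n * (n - 1) / 2
  if (m < 0 || m > max_m) {
    stop("range error: m must be in [0, ", max_m, "] for n = ", n,
         call. = FALSE)
  }
  ids <- paste0("v", seq_len(n))
  if (m == 0) return(build_network(vertex_ids = ids))
  with_seed(seed, {
    if (max_m <= 4 * m || n <= 64) {
      # dense regime: enumerate all pairs and sample without replacement
      pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      pick <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
      i <- pick[, 1]; j <- pick[, 2]
    } else {
      # sparse regime: rejection sampling with exact dedup on the pair key
      i <- integer(0); j <- integer(0); keys <- numeric(0)
      while (length(i) < m) {
        need <- m - length(i)
        a <- sample.int(n, ceiling(need * 1.3), replace = TRUE)
        b <- sample.int(n, ceiling(need * 1.3), replace = TRUE)
        lo <- pmin(a, b); hi <- pmax(a, b)
        ok <- lo != hi
        lo <- lo[ok]; hi <- hi[ok]
        k <- (lo - 1) * n + (hi - 1)   # exact in doubles for n <= 2^26
        fresh <- !(k %in% keys) & !duplicated(k)
        i <- c(i, lo[fresh]); j <- c(j, hi[fresh])
        keys <- c(keys, k[fresh])
        if (length(i) > m) {
          i <- i[seq_len(m)]; j <- j[seq_len(m)]; keys <- keys[seq_len(m)]
        }
      }
    }
    build_network(edges = cbind(ids[i], ids[j]), vertex_ids = ids)
  })
}

#' Random uniform 2D layout for a network
#'
#' Coordinates uniform on the unit square; a stand-in for layouts that real
#' analysis libraries would supply.
#' @param network a `netcanvas_network`.
#' @param seed integer seed.
#' @param ndim 2 or 3.
#' @return a `netcanvas_layout`.
#' @export
random_layout <- function(network, seed = 1L, ndim = 2L) {
  ids <- network$vertex_ids
  with_seed(seed, {
    coords <- matrix(stats::runif(length(ids) * ndim), ncol = ndim)
    rownames(coords) <- ids
    validate_layout(coords, network)
  })
}

#' Random rooted binary tree
#'
#' Grown by sequential leaf attachment: starting from a two-leaf cherry, each
#' new leaf splits a uniformly chosen existing branch with a fresh internal
#' node. Branch lengths are uniform(0.5, 1.5) (bounded away from zero so
#' layouts never degenerate). A binary tree with L >= 2 leaves has exactly
#' L - 1 internal nodes.
#'
#' @param n_leaves number of leaves, >= 1.
#' @param seed integer seed.
#' @return a `netcanvas_tree` with leaves `t1 ... tL`.
#' @export
random_tree <- function(n_leaves, seed = 1L) {
  if (n_leaves < 1) {
    stop("range error: n_leaves must be >= 1", call. = FALSE)
  }
  with_seed(seed, {
    if (n_leaves == 1L) {
      return(build_tree(c(t1 = "n1"),
                        branch_lengths = c(t1 = stats::runif(1, 0.5, 1.5))))
    }
    children <- list(n1 = c("t1", "t2"))
    parent <- c(t1 = "n1", t2 = "n1")
    for (k in seq_len(n_leaves - 2L) + 2L) {
      attach_at <- sample(names(parent), 1L)    # any node with a branch above
      new_int <- paste0("n", k - 1L)
      new_leaf <- paste0("t", k)
      old_parent <- parent[[attach_at]]
      ch <- children[[old_parent]]
      ch[ch == attach_at] <- new_int
      children[[old_parent]] <- ch
      children[[new_int]] <- c(attach_at, new_leaf)
      parent[[attach_at]] <- new_int
      parent[[new_int]] <- old_parent
      parent[[new_leaf]] <- new_int
    }
    # emit the parent map in depth-first preorder so children order in the
    # built tree matches the grown children lists
    pm <- character(0)
    stack <- "n1"
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      ch <- children[[cur]]
      if (!is.null(ch)) {
        for (c_ in ch) pm[c_] <- cur
        stack <- c(stack, rev(ch))
      }
    }
    bl <- stats::setNames(stats::runif(length(pm), 0.5, 1.5), names(pm))
    build_tree(pm, branch_lengths = bl)
  })
}

#' Parse a toy Newick string
#'
#' Accepts the subset: nested parentheses, plain labels, `:length` suffixes
#' and a terminating `;` -- no comments, no quoted labels. Unlabelled internal
#' nodes are auto-named `.n1`, `.n2`, ... deterministically. Missing branch
#' lengths default to 1. This reader exists for fixtures and the command
#' line; live tree objects normally enter through providers.
#'
#' @param text a Newick string.
#' @return a `netcanvas_tree`.
#' @export
parse_newick_toy <- function(text) {
  text <- trimws(text)
  depth <- 0L
  for (i in seq_len(nchar(text))) {
    ch <- substr(text, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("parse error at position ", i, ": unbalanced ')'", call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop("parse error at end of input: ", depth, " unclosed '('",
         call. = FALSE)
  }
  if (!grepl(";$", text)) {
    stop("parse error at end of input: missing ';'", call. = FALSE)
  }
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) {
    stop("parse error: not a valid Newick tree", call. = FALSE)
  }
  phylo_to_tree(phy)
}

# convert an ape phylo (cladewise order, which preserves the written child
# order) into the internal tree structure
phylo_to_tree <- function(phy) {
  ntip <- length(phy$tip.label)
  labels <- c(phy$tip.label, character(phy$Nnode))
  if (!is.null(phy$node.label)) {
    nl <- phy$node.label
    labels[ntip + seq_along(nl)] <- nl
  }
  auto <- which(labels == "" | is.na(labels))
  labels[auto] <- paste0(".n", seq_along(auto))
  if (anyDuplicated(labels)) {
    stop("parse error: duplicated node labels", call. = FALSE)
  }
  pm <- stats::setNames(labels[phy$edge[, 1]], labels[phy$edge[, 2]])
  bl <- if (!is.null(phy$edge.length)) {
    stats::setNames(phy$edge.length, labels[phy$edge[, 2]])
  } else NULL
  build_tree(pm, branch_lengths = bl)
}

#' Write a tree as a toy Newick string
#'
#' Inverse of [parse_newick_toy()]: branch lengths are printed with 17
#' significant digits so a write/parse round trip reproduces topology and
#' lengths exactly.
#' @param tree a `netcanvas_tree`.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 17L) {
  fmt <- paste0("%.", digits, "g")
  node_str <- function(node) {
    ch <- tree$children[[node]]
    lab <- node
    body <- if (is.null(ch) || !length(ch)) lab else {
      paste0("(", paste(vapply(ch, node_str, ""), collapse = ","), ")", lab)
    }
    if (node == tree$root) body
    else paste0(body, ":", sprintf(fmt, tree$branch_length[[node]]))
  }
  paste0(node_str(tree$root), ";")
}
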