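# Independent brute-force oracles, deliberately written as plain recursions so
# they share no code with the package's iterative implementations.

# recursive rectangular layout: returns data.frame(node, main, cross)
oracle_rect <- function(tree, use_branch_lengths = TRUE) {
  counter <- new.env()
  counter$next_leaf <- 0
  rec <- function(node, depth) {
    ch <- tree$children[[node]]
    if (is.null(ch) || !length(ch)) {
      cross <- counter$next_leaf
      counter$next_leaf <- counter$next_leaf + 1
      return(data.frame(node = node, main = depth, cross = cross))
    }
    rows <- do.call(rbind, lapply(ch, function(c_) {
      step <- if (use_branch_lengths) tree$branch_length[[c_]] else 1
      rec(c_, depth + step)
    }))
    own_cross <- mean(rows$cross[match(ch, rows$node)])
    rbind(rows, data.frame(node = node, main = depth, cross = own_cross))
  }
  rec(tree$root, 0)
}

# recursive radial layout oracle: angle per leaf counter, radius cumulative
oracle_radial <- function(tree, span = 2 * pi, start = 0) {
  L <- length(tree$leaf_order)
  counter <- new.env()
  counter$next_leaf <- 0
  rec <- function(node, r) {
    ch <- tree$children[[node]]
    if (is.null(ch) || !length(ch)) {
      th <- start + counter$next_leaf * span / L
      counter$next_leaf <- counter$next_leaf + 1
      return(data.frame(node = node, r = r, theta = th))
    }
    rows <- do.call(rbind, lapply(ch, function(c_) {
      rec(c_, r + tree$branch_length[[c_]])
    }))
    own <- mean(rows$theta[match(ch, rows$node)])
    rbind(rows, data.frame(node = node, r = r, theta = own))
  }
  rec(tree$root, 0)
}

# rotate 2D points by `angle` around the origin, then translate
transform_pts <- function(m, angle = 0, shift = c(0, 0)) {
  R <- rbind(c(cos(angle), -sin(angle)), c(sin(angle), cos(angle)))
  sweep(m[, 1:2, drop = FALSE] %*% t(R), 2, shift, "+")
}

# a small fixed tree used across files: ((A,B),C) with unit branch lengths
fixture_tree <- function() {
  build_tree(c(A = "i", B = "i", i = "r", C = "r"))
}

# ray-casting point-in-polygon for hull containment checks
point_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((poly[i, 2] > p[2]) != (poly[j, 2] > p[2])) {
      xint <- (poly[j, 1] - poly[i, 1]) * (p[2] - poly[i, 2]) /
        (poly[j, 2] - poly[i, 2]) + poly[i, 1]
      if (p[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

max_pointset_dist <- function(a, b) {
  # directed Hausdorff-ish: max over rows of a of min distance to rows of b
  max(apply(a, 1, function(p) {
    min(sqrt((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2))
  }))
}
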