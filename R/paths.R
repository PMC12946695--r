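# Path primitive: an ordered point matrix plus segment tags. A "line" tag
# consumes one point after the current position, a "cubic" tag consumes three
# (two control points and the segment endpoint). All coordinates are data
# units. Circular arcs are carried as exact-on-circle polylines sampled at the
# arc constructors, so every downstream operation needs only lines and cubics.

new_path <- function(points, segments, closed = FALSE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  expected <- 1L + sum(ifelse(segments == "cubic", 3L, 1L))
  if (nrow(points) != expected) {
    stop("structural error: path has ", nrow(points), " points, segment tags",
         " require ", expected, call. = FALSE)
  }
  structure(list(points = points, segments = segments, closed = closed),
            class = "netcanvas_path")
}

path_start <- function(path) path$points[1L, ]
path_end <- function(path) path$points[nrow(path$points), ]

# per-segment views: list of point blocks (line: 2 x d, cubic: 4 x d)
path_segment_blocks <- function(path) {
  out <- vector("list", length(path$segments))
  i <- 1L
  for (k in seq_along(path$segments)) {
    take <- if (path$segments[[k]] == "cubic") 3L else 1L
    out[[k]] <- path$points[i:(i + take), , drop = FALSE]
    i <- i + take
  }
  out
}

blocks_to_path <- function(blocks, tags, closed = FALSE) {
  pts <- blocks[[1L]]
  if (length(blocks) > 1L) {
    for (k in 2:length(blocks)) {
      pts <- rbind(pts, blocks[[k]][-1L, , drop = FALSE])
    }
  }
  new_path(pts, tags, closed)
}

bezier_point <- function(P, t) {
  # P: 4 x d control matrix, t: vector of parameters
  b0 <- (1 - t)^3; b1 <- 3 * t * (1 - t)^2; b2 <- 3 * t^2 * (1 - t); b3 <- t^3
  outer(b0, P[1L, ]) + outer(b1, P[2L, ]) + outer(b2, P[3L, ]) +
    outer(b3, P[4L, ])
}

bezier_deriv <- function(P, t) {
  d0 <- 3 * (1 - t)^2; d1 <- 6 * t * (1 - t); d2 <- 3 * t^2
  outer(d0, P[2L, ] - P[1L, ]) + outer(d1, P[3L, ] - P[2L, ]) +
    outer(d2, P[4L, ] - P[3L, ])
}

# 32-node Gauss-Legendre rule on [0, 1], computed once
.gl_cache <- new.env(parent = emptyenv())
gl_rule <- function() {
  if (is.null(.gl_cache$rule)) {
    .gl_cache$rule <- pracma::gaussLegendre(32L, 0, 1)
  }
  .gl_cache$rule
}

# arc length of a cubic from parameter 0 to tmax (spectral-accuracy quadrature)
cubic_arclen <- function(P, tmax = 1) {
  if (tmax <= 0) return(0)
  gl <- gl_rule()
  t <- gl$x * tmax
  d <- bezier_deriv(P, t)
  sum(gl$w * sqrt(rowSums(d^2))) * tmax
}

segment_length <- function(block, tag) {
  if (tag == "cubic") cubic_arclen(block)
  else sqrt(sum((block[2L, ] - block[1L, ])^2))
}

#' Arc length of a path
#'
#' Line segments are exact; cubic segments use 32-node Gauss-Legendre
#' quadrature of the speed, accurate far beyond 1e-9 for non-degenerate
#' curves.
#' @param path a `netcanvas_path`.
#' @return total length in data units.
#' @export
path_length <- function(path) {
  blocks <- path_segment_blocks(path)
  sum(mapply(segment_length, blocks, path$segments))
}

#' Sample points along a path
#'
#' @param path a `netcanvas_path`.
#' @param n_per_segment samples per segment (endpoints included once).
#' @return matrix of sampled coordinates in path order.
#' @export
sample_path <- function(path, n_per_segment = 33L) {
  blocks <- path_segment_blocks(path)
  t <- seq(0, 1, length.out = n_per_segment)
  out <- path$points[1L, , drop = FALSE]
  for (k in seq_along(blocks)) {
    B <- blocks[[k]]
    pts <- if (path$segments[[k]] == "cubic") bezier_point(B, t)
           else outer(1 - t, B[1L, ]) + outer(t, B[2L, ])
    out <- rbind(out, pts[-1L, , drop = FALSE])
  }
  unname(out)
}

# de Casteljau subdivision of a cubic at local parameter t -> left/right 4 x d
split_cubic <- function(P, t) {
  A <- (1 - t) * P[1L, ] + t * P[2L, ]
  B <- (1 - t) * P[2L, ] + t * P[3L, ]
  C <- (1 - t) * P[3L, ] + t * P[4L, ]
  D <- (1 - t) * A + t * B
  E <- (1 - t) * B + t * C
  F <- (1 - t) * D + t * E
  list(left = rbind(P[1L, ], A, D, F), right = rbind(F, E, C, P[4L, ]))
}

# local parameter on a segment at which arc length from its start equals `s`
segment_param_at_length <- function(block, tag, s) {
  len <- segment_length(block, tag)
  if (s <= 0) return(0)
  if (s >= len) return(1)
  if (tag == "line") return(s / len)
  stats::uniroot(function(t) cubic_arclen(block, t) - s,
                 c(0, 1), tol = 1e-13)$root
}

split_segment <- function(block, tag, t) {
  if (tag == "cubic") {
    sc <- split_cubic(block, t)
    list(left = sc$left, right = sc$right, tags = c("cubic", "cubic"))
  } else {
    m <- (1 - t) * block[1L, ] + t * block[2L, ]
    list(left = rbind(block[1L, ], m), right = rbind(m, block[2L, ]),
         tags = c("line", "line"))
  }
}

#' Partition a path by arc length
#'
#' Cut points are given as strictly increasing fractions of the total arc
#' length in (0, 1); cubic segments are cut exactly by de Casteljau
#' subdivision, so the concatenated subpaths reproduce the original geometry.
#' For an elbow edge the natural split is at its corner (see
#' [elbow_corner_fraction()]); styling the subpaths independently gives
#' split-edge styling.
#'
#' @param path a `netcanvas_path`.
#' @param fractions strictly increasing numeric vector in (0, 1); empty for
#'   the identity split.
#' @return list of `netcanvas_path` subpaths, in order.
#' @export
split_path <- function(path, fractions = numeric(0)) {
  if (length(fractions)) {
    if (any(fractions <= 0 | fractions >= 1)) {
      stop("range error: split fractions must lie strictly in (0, 1)",
           call. = FALSE)
    }
    if (any(diff(fractions) <= 0)) {
      stop("range error: split fractions must be strictly increasing",
           call. = FALSE)
    }
  }
  if (!length(fractions)) return(list(path))
  blocks <- path_segment_blocks(path)
  tags <- path$segments
  seg_len <- mapply(segment_length, blocks, tags)
  total <- sum(seg_len)
  cuts <- fractions * total
  out <- list()
  cur_blocks <- list(); cur_tags <- character(0)
  consumed <- 0  # arc length of fully processed original segments
  ci <- 1L
  for (k in seq_along(blocks)) {
    block <- blocks[[k]]; tag <- tags[[k]]
    len <- seg_len[[k]]
    while (!is.null(block) && ci <= length(cuts) &&
           cuts[[ci]] <= consumed + len + 1e-12) {
      # cut position measured into the residual block (earlier cuts may have
      # already emitted part of this segment)
      rem_len <- segment_length(block, tag)
      s_into <- cuts[[ci]] - consumed - (len - rem_len)
      if (s_into >= rem_len - 1e-12) {
        # cut exactly at the segment end: finish the subpath cleanly
        cur_blocks <- c(cur_blocks, list(block)); cur_tags <- c(cur_tags, tag)
        out <- c(out, list(blocks_to_path(cur_blocks, cur_tags)))
        cur_blocks <- list(); cur_tags <- character(0)
        block <- NULL
      } else if (s_into <= 1e-12) {
        # cut at the segment start: previous subpath already ends here
        out <- c(out, list(blocks_to_path(cur_blocks, cur_tags)))
        cur_blocks <- list(); cur_tags <- character(0)
      } else {
        t <- segment_param_at_length(block, tag, s_into)
        sp <- split_segment(block, tag, t)
        cur_blocks <- c(cur_blocks, list(sp$left))
        cur_tags <- c(cur_tags, tag)
        out <- c(out, list(blocks_to_path(cur_blocks, cur_tags)))
        cur_blocks <- list(); cur_tags <- character(0)
        block <- sp$right
      }
      ci <- ci + 1L
    }
    if (!is.null(block)) {
      cur_blocks <- c(cur_blocks, list(block))
      cur_tags <- c(cur_tags, tag)
    }
    consumed <- consumed + len
  }
  c(out, list(blocks_to_path(cur_blocks, cur_tags)))
}

reverse_path <- function(path) {
  blocks <- rev(lapply(path_segment_blocks(path),
                       function(b) b[nrow(b):1, , drop = FALSE]))
  blocks_to_path(blocks, rev(path$segments), path$closed)
}

marker_signed_dist <- function(p, centre, shape, size) {
  d <- p - centre
  if (shape == "square") max(abs(d[1:2])) - size
  else sqrt(sum(d^2)) - size
}

#' Clip a path at a marker boundary
#'
#' Trims the path at its last (or first) intersection with the boundary of a
#' marker centred on the corresponding endpoint, so that arrowheads sit on the
#' marker edge rather than under it. The trimmed endpoint lies on the boundary
#' to within 1e-9; clipping an already-clipped path is a no-op.
#'
#' @param path a `netcanvas_path`.
#' @param marker_shape `"circle"` (size = radius) or `"square"` (size =
#'   half-width, axis-aligned).
#' @param marker_size marker extent in data units.
#' @param end `"target"` (clip at the path end) or `"start"`.
#' @param centre marker centre; defaults to the corresponding path endpoint
#'   (the vertex position of an unclipped edge). Pass it explicitly to
#'   re-clip a path whose endpoint already sits on the boundary -- a no-op.
#' @return the trimmed `netcanvas_path`.
#' @export
clip_at_marker <- function(path, marker_shape = c("circle", "square"),
                           marker_size, end = c("target", "start"),
                           centre = NULL) {
  marker_shape <- match.arg(marker_shape)
  end <- match.arg(end)
  if (marker_size <= 0) return(path)
  if (end == "start") {
    return(reverse_path(clip_at_marker(reverse_path(path), marker_shape,
                                       marker_size, "target", centre)))
  }
  if (is.null(centre)) centre <- path_end(path)
  dist_at <- function(p) marker_signed_dist(p, centre, marker_shape,
                                            marker_size)
  if (dist_at(path_end(path)) >= -1e-9) return(path)  # already clipped
  blocks <- path_segment_blocks(path)
  tags <- path$segments
  for (k in rev(seq_along(blocks))) {
    B <- blocks[[k]]; tag <- tags[[k]]
    pt_at <- if (tag == "cubic") function(t) drop(bezier_point(B, t))
             else function(t) (1 - t) * B[1L, ] + t * B[2L, ]
    # walk backwards through this segment for the crossing nearest the end
    ts <- seq(1, 0, length.out = 65L)
    d <- vapply(ts, function(t) dist_at(pt_at(t)), 1)
    cross <- which(d >= 0)[1L]
    if (is.na(cross)) next
    t_star <- if (d[[cross]] == 0) ts[[cross]] else
      stats::uniroot(function(t) dist_at(pt_at(t)),
                     c(ts[[cross]], ts[[cross - 1L]]), tol = 1e-12)$root
    sp <- split_segment(B, tag, t_star)
    keep <- blocks[seq_len(k - 1L)]
    keep_tags <- tags[seq_len(k - 1L)]
    if (t_star > 0) {
      keep <- c(keep, list(sp$left))
      keep_tags <- c(keep_tags, tag)
    }
    if (!length(keep)) {
      stop("fully-clipped error: marker swallows the entire path",
           call. = FALSE)
    }
    return(blocks_to_path(keep, keep_tags))
  }
  stop("fully-clipped error: marker swallows the entire path", call. = FALSE)
}

path_terminal_tangent <- function(path) {
  blocks <- path_segment_blocks(path)
  k <- length(blocks)
  B <- blocks[[k]]
  v <- if (path$segments[[k]] == "cubic") {
    d <- drop(bezier_deriv(B, 1))
    if (sqrt(sum(d^2)) < 1e-12) B[4L, ] - B[1L, ] else d
  } else B[2L, ] - B[1L, ]
  v / sqrt(sum(v^2))
}

#' Arrowhead triangle at the end of a path
#'
#' Builds an isoceles triangle whose tip is the path's terminal point and
#' whose axis is the terminal tangent, and shortens the path by `length` so it
#' abuts the triangle base. For directed edges only; dimensions are in the
#' caller's units (figure units at render time).
#'
#' @param path a clipped `netcanvas_path`.
#' @param width base width of the triangle.
#' @param length tip-to-base length of the triangle.
#' @return list with `triangle` (3 x 2 matrix: tip, base corners) and `path`
#'   (the shortened path).
#' @export
arrowhead <- function(path, width, length) {
  total <- path_length(path)
  if (length >= total) {
    stop("fully-clipped error: arrow length ", length,
         " exceeds path length ", signif(total, 6), call. = FALSE)
  }
  tip <- path_end(path)[1:2]
  tangent <- path_terminal_tangent(path)[1:2]
  normal <- c(-tangent[2L], tangent[1L])
  base_centre <- tip - length * tangent
  triangle <- rbind(tip, base_centre + (width / 2) * normal,
                    base_centre - (width / 2) * normal)
  rownames(triangle) <- NULL
  shortened <- split_path(path, (total - length) / total)[[1L]]
  list(triangle = triangle, path = shortened)
}
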