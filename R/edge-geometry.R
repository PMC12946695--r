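# Edge geometry grammar: straight lines, circular arcs, cubic Beziers,
# port-constrained curves, waypoint polylines, self-loops, and tree elbows.
#
# Conventions: tension is dimensionless (fraction of the chord length),
# positive bulging to the left of the direction of travel; port angles are
# radians counterclockwise from +x in data space; arcs use an exact circular
# parameterisation sampled onto a polyline whose midpoint is the true arc
# midpoint.

.arc_samples <- 64L  # even, so the exact arc midpoint is always a sample

#' Straight edge path
#' @param p1,p2 endpoint coordinates (data units).
#' @return a `netcanvas_path`.
#' @export
straight_path <- function(p1, p2) {
  if (isTRUE(all(p1 == p2))) {
    stop("degenerate-edge error: coincident endpoints (route self-loops via ",
         "loop_path)", call. = FALSE)
  }
  new_path(rbind(p1, p2), "line")
}

#' Circular-arc edge path
#'
#' The arc passes through both endpoints; its midpoint is offset
#' `tension * |p2 - p1|` perpendicular-left of the chord midpoint. Tension 0
#' degenerates to the straight path.
#'
#' @param p1,p2 endpoint coordinates.
#' @param tension dimensionless bulge, |tension| <= 10.
#' @export
arc_path <- function(p1, p2, tension = 0) {
  if (abs(tension) > 10) {
    stop("range error: |tension| must be <= 10", call. = FALSE)
  }
  if (tension == 0) return(straight_path(p1, p2))
  if (isTRUE(all(p1 == p2))) {
    stop("degenerate-edge error: coincident endpoints", call. = FALSE)
  }
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  v <- p2 - p1
  L <- sqrt(sum(v^2))
  nl <- c(-v[2L], v[1L]) / L          # unit left normal of travel
  mid <- (p1 + p2) / 2
  h <- tension * L                    # signed sagitta
  apex <- mid + h * nl
  # centre on the perpendicular bisector: |c-p1| = |c-apex|
  d <- (h^2 - L^2 / 4) / (2 * h)
  centre <- mid + d * nl
  r <- sqrt(sum((p1 - centre)^2))
  th1 <- atan2(p1[2L] - centre[2L], p1[1L] - centre[1L])
  th2 <- atan2(p2[2L] - centre[2L], p2[1L] - centre[1L])
  thm <- atan2(apex[2L] - centre[2L], apex[1L] - centre[1L])
  sweep_ccw <- (th2 - th1) %% (2 * pi)
  mid_ccw <- (thm - th1) %% (2 * pi)
  sweep <- if (mid_ccw <= sweep_ccw) sweep_ccw else sweep_ccw - 2 * pi
  th <- th1 + sweep * seq(0, 1, length.out = .arc_samples + 1L)
  pts <- cbind(centre[1L] + r * cos(th), centre[2L] + r * sin(th))
  pts[1L, ] <- p1
  pts[nrow(pts), ] <- p2
  new_path(pts, rep("line", .arc_samples))
}

#' Cubic Bezier edge path
#'
#' One control point (quadratic) is elevated exactly to a cubic:
#' `c1 = p1 + 2/3 (q - p1)`, `c2 = p2 + 2/3 (q - p2)`.
#'
#' @param p1,p2 endpoint coordinates.
#' @param controls list (or matrix rows) of 1 or 2 control points.
#' @export
bezier_path <- function(p1, p2, controls) {
  if (is.matrix(controls)) {
    controls <- lapply(seq_len(nrow(controls)), function(i) controls[i, ])
  }
  if (is.numeric(controls) && !is.list(controls)) controls <- list(controls)
  if (!length(controls) %in% c(1L, 2L)) {
    stop("arity error: bezier needs 1 or 2 control points, got ",
         length(controls), call. = FALSE)
  }
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (length(controls) == 1L) {
    q <- as.numeric(controls[[1L]])
    c1 <- p1 + (2 / 3) * (q - p1)
    c2 <- p2 + (2 / 3) * (q - p2)
  } else {
    c1 <- as.numeric(controls[[1L]])
    c2 <- as.numeric(controls[[2L]])
  }
  new_path(rbind(p1, c1, c2, p2), "cubic")
}

#' Port-constrained edge path
#'
#' A cubic Bezier whose departure tangent at `p1` has direction `theta_out`
#' and whose arrival tangent at `p2` points opposite `theta_in`:
#' `c1 = p1 + strength |p2-p1| (cos, sin)(theta_out)` and symmetrically for
#' `c2`.
#'
#' @param p1,p2 endpoint coordinates.
#' @param theta_out,theta_in incidence angles in radians (ccw from +x).
#' @param strength control-arm length as a fraction of the chord (default
#'   1/3, the standard cubic heuristic).
#' @export
ports_path <- function(p1, p2, theta_out, theta_in, strength = 1 / 3) {
  stopifnot(strength > 0)
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  L <- sqrt(sum((p2 - p1)^2))
  if (L == 0) {
    stop("degenerate-edge error: coincident endpoints", call. = FALSE)
  }
  c1 <- p1 + strength * L * c(cos(theta_out), sin(theta_out))
  c2 <- p2 + strength * L * c(cos(theta_in), sin(theta_in))
  new_path(rbind(p1, c1, c2, p2), "cubic")
}

#' Waypoint polyline edge path
#' @param p1,p2 endpoint coordinates.
#' @param waypoints list (or matrix rows) of intermediate coordinates, >= 1.
#' @export
waypoint_path <- function(p1, p2, waypoints) {
  if (is.matrix(waypoints)) {
    waypoints <- lapply(seq_len(nrow(waypoints)), function(i) waypoints[i, ])
  }
  if (is.numeric(waypoints) && !is.list(waypoints)) {
    waypoints <- list(waypoints)
  }
  if (!length(waypoints)) {
    stop("arity error: waypoint edge needs at least one waypoint ",
         "(use straight geometry instead)", call. = FALSE)
  }
  pts <- do.call(rbind, c(list(as.numeric(p1)),
                          lapply(waypoints, as.numeric),
                          list(as.numeric(p2))))
  new_path(pts, rep("line", nrow(pts) - 1L))
}

#' Self-loop path
#'
#' A cubic lobe leaving and re-entering the vertex; its farthest point (the
#' apex) lies exactly at distance `loop_size` from the vertex in direction
#' `loop_angle`. The two control arms open half an angle of 30 degrees either
#' side of the loop direction.
#'
#' @param p vertex coordinate.
#' @param loop_size apex distance in data units, > 0.
#' @param loop_angle apex direction in radians (ccw from +x).
#' @export
loop_path <- function(p, loop_size, loop_angle = pi / 2) {
  if (loop_size <= 0) {
    stop("range error: loop_size must be positive", call. = FALSE)
  }
  p <- as.numeric(p)
  w <- pi / 6
  k <- 4 / (3 * cos(w))  # puts the t = 1/2 apex exactly at loop_size
  c1 <- p + k * loop_size * c(cos(loop_angle + w), sin(loop_angle + w))
  c2 <- p + k * loop_size * c(cos(loop_angle - w), sin(loop_angle - w))
  new_path(rbind(p, c1, c2, p), "cubic", closed = TRUE)
}

#' Elbow edge for tree drawings
#'
#' Rectangular trees: two segments, a cross-axis move at the parent's
#' main-axis coordinate to the corner `(parent main, child cross)`, then a
#' main-axis move to the child. Radial trees: a circular sweep at the parent's
#' radius from the parent's angle to the child's, then a radial segment
#' outward to the child.
#'
#' @param parent_coord,child_coord coordinates from a tree layout.
#' @param kind `"rectangular"` or `"radial"` (must match the layout).
#' @param orientation rectangular orientation the layout was computed with.
#' @export
elbow_path <- function(parent_coord, child_coord,
                       kind = c("rectangular", "radial"),
                       orientation = "right") {
  kind <- match.arg(kind)
  p <- as.numeric(parent_coord); q <- as.numeric(child_coord)
  if (kind == "rectangular") {
    corner <- if (orientation %in% c("right", "left")) c(p[1L], q[2L])
              else c(q[1L], p[2L])
    if (isTRUE(all(corner == p)) || isTRUE(all(corner == q))) {
      return(new_path(rbind(p, q), "line"))  # shared cross coordinate
    }
    return(new_path(rbind(p, corner, q), c("line", "line")))
  }
  rp <- sqrt(sum(p^2))
  ap <- atan2(p[2L], p[1L])
  ac <- atan2(q[2L], q[1L])
  sweep <- (ac - ap + pi) %% (2 * pi) - pi  # shorter way around
  if (rp < 1e-12 || abs(sweep) < 1e-12) {
    return(new_path(rbind(p, q), "line"))  # pure radial move
  }
  th <- ap + sweep * seq(0, 1, length.out = .arc_samples + 1L)
  pts <- cbind(rp * cos(th), rp * sin(th))
  pts[1L, ] <- p
  pts <- rbind(pts, q)
  new_path(pts, rep("line", nrow(pts) - 1L))
}

#' Arc-length fraction of an elbow's corner
#'
#' The natural place to split an elbow for split-edge styling.
#' @param path an elbow `netcanvas_path`.
#' @return fraction in (0, 1), or `NA` for single-segment elbows.
#' @export
elbow_corner_fraction <- function(path) {
  if (length(path$segments) < 2L) return(NA_real_)
  blocks <- path_segment_blocks(path)
  lens <- mapply(segment_length, blocks, path$segments)
  # the radial elbow's corner is at the end of its arc polyline
  k <- length(lens) - 1L
  sum(lens[seq_len(k)]) / sum(lens)
}
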