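test_that("straight paths join their endpoints and reject coincident ones", {
  p <- straight_path(c(0, 0), c(2, 0))
  expect_equal(nrow(p$points), 2)
  expect_equal(path_length(p), 2)
  expect_error(straight_path(c(0, 0), c(0, 0)), "degenerate-edge")
})

test_that("arcs pass through the tension-offset midpoint", {
  # tension 0.5 on a chord of length 2: semicircle through (1, 1)
  p <- arc_path(c(0, 0), c(2, 0), 0.5)
  mid <- p$points[nrow(p$points) %/% 2 + 1, ]
  expect_lt(max(abs(mid - c(1, 1))), 1e-9)
  # every sampled point at distance 1 from the centre (1, 0)
  r <- sqrt((p$points[, 1] - 1)^2 + p$points[, 2]^2)
  expect_lt(max(abs(r - 1)), 1e-9)

  # tension 0 degenerates to the straight path
  p0 <- arc_path(c(0, 0), c(2, 0), 0)
  expect_equal(p0$points, straight_path(c(0, 0), c(2, 0))$points)

  # the reversed arc, reflected across the chord, traces the same point set
  fwd <- sample_path(arc_path(c(0, 1), c(3, 2), 0.4), 9)
  rev_ <- sample_path(arc_path(c(3, 2), c(0, 1), 0.4), 9)
  u <- c(3, 1) / sqrt(10)  # chord direction
  reflect <- function(m) {
    rel <- sweep(m, 2, c(0, 1))
    along <- rel %*% u
    t(vapply(seq_len(nrow(m)), function(i) {
      proj <- along[i] * u
      c(0, 1) + 2 * proj - rel[i, ]
    }, numeric(2)))
  }
  expect_lt(max_pointset_dist(fwd, reflect(rev_)), 1e-9)

  expect_error(arc_path(c(0, 0), c(1, 0), 11), "range error")
})

test_that("arc deviation from the chord vanishes with tension", {
  for (t in c(1e-3, 1e-6)) {
    p <- arc_path(c(0, 0), c(2, 0), t)
    expect_lt(max(abs(p$points[, 2])), 3 * t)
  }
})

test_that("bezier paths honour de Casteljau and quadratic elevation", {
  # degenerate cubic with controls on the chord is the chord
  p <- bezier_path(c(0, 0), c(3, 0), list(c(1, 0), c(2, 0)))
  expect_lt(max(abs(sample_path(p, 33)[, 2])), 1e-15)

  # midpoint of ((0,0),(0,1),(2,1),(2,0)) is (p1 + 3c1 + 3c2 + p2) / 8
  p2 <- bezier_path(c(0, 0), c(2, 0), list(c(0, 1), c(2, 1)))
  mid <- netcanvas:::bezier_point(p2$points, 0.5)
  expect_lt(max(abs(mid - c(1, 0.75))), 1e-12)

  # quadratic control elevates exactly
  q <- c(1, 1)
  pq <- bezier_path(c(0, 0), c(2, 0), list(q))
  c1 <- c(0, 0) + 2 / 3 * (q - c(0, 0))
  c2 <- c(2, 0) + 2 / 3 * (q - c(2, 0))
  pc <- bezier_path(c(0, 0), c(2, 0), list(c1, c2))
  expect_lt(max(abs(sample_path(pq, 65) - sample_path(pc, 65))), 1e-12)

  expect_error(bezier_path(c(0, 0), c(1, 0), list()), "arity error")
  expect_error(bezier_path(c(0, 0), c(1, 0),
                           list(c(0, 1), c(1, 1), c(2, 1))), "arity error")
})

test_that("port curves depart and arrive at the prescribed angles", {
  p <- ports_path(c(0, 0), c(2, 0), pi / 2, pi / 2)
  expect_equal(unname(p$points[2, ]), c(0, 2 / 3))
  expect_equal(unname(p$points[3, ]), c(2, 2 / 3))

  # collinear ports give a straight-looking cubic
  ps <- ports_path(c(0, 0), c(2, 0), 0, pi)
  expect_lt(max(abs(sample_path(ps, 33)[, 2])), 1e-15)

  set.seed(7)
  for (k in 1:200) {
    p1 <- stats::runif(2, -5, 5)
    p2 <- stats::runif(2, -5, 5)
    if (all(p1 == p2)) next
    th_out <- stats::runif(1, -pi, pi)
    th_in <- stats::runif(1, -pi, pi)
    pp <- ports_path(p1, p2, th_out, th_in)
    d0 <- drop(netcanvas:::bezier_deriv(pp$points, 0))
    dd <- abs(atan2(d0[2], d0[1]) - th_out) %% (2 * pi)
    expect_lt(min(dd, 2 * pi - dd), 1e-9)
    d1 <- drop(netcanvas:::bezier_deriv(pp$points, 1))
    arrive <- atan2(-d1[2], -d1[1])   # arrival tangent opposes theta_in
    diff <- abs(arrive - th_in) %% (2 * pi)
    expect_lt(min(diff, 2 * pi - diff), 1e-9)
  }
})

test_that("waypoint polylines visit each waypoint in order", {
  p <- waypoint_path(c(0, 0), c(2, 0), list(c(1, 1)))
  expect_equal(nrow(p$points), 3)
  expect_equal(unname(p$points[2, ]), c(1, 1))
  # collinear waypoints keep chord length
  pc <- waypoint_path(c(0, 0), c(2, 0), list(c(0.5, 0), c(1.5, 0)))
  expect_equal(path_length(pc), 2)
  expect_error(waypoint_path(c(0, 0), c(1, 0), list()), "arity error")
})

test_that("loops start and end at the vertex with the apex where asked", {
  p <- loop_path(c(1, 2), 0.8, pi / 2)
  expect_equal(unname(netcanvas:::path_start(p)), c(1, 2))
  expect_equal(unname(netcanvas:::path_end(p)), c(1, 2))
  apex <- drop(netcanvas:::bezier_point(p$points, 0.5))
  expect_lt(max(abs(apex - c(1, 2.8))), 1e-9)
  # apex is the farthest point
  d <- sqrt(rowSums(sweep(sample_path(p, 201), 2, c(1, 2))^2))
  expect_lt(max(d), 0.8 + 1e-9)

  # opposite loops share only the vertex
  a <- sample_path(loop_path(c(0, 0), 1, 0), 101)
  b <- sample_path(loop_path(c(0, 0), 1, pi), 101)
  keep <- sqrt(rowSums(a^2)) > 1e-6
  expect_gt(min(apply(a[keep, ], 1, function(q) {
    min(sqrt((b[, 1] - q[1])^2 + (b[, 2] - q[2])^2))
  })), 0.01)

  expect_error(loop_path(c(0, 0), -1), "range error")
})

test_that("rectangular elbows corner at (parent main, child cross)", {
  p <- elbow_path(c(0, 1.25), c(1, 2), "rectangular", "right")
  expect_equal(unname(p$points[2, ]), c(0, 2))
  # shared cross coordinate: single straight segment
  ps <- elbow_path(c(0, 1), c(2, 1), "rectangular", "right")
  expect_equal(length(ps$segments), 1)
})

test_that("radial elbows sweep at the parent radius then move radially", {
  parent <- c(sqrt(2) / 2, sqrt(2) / 2)      # r = 1, 45 degrees
  child <- c(0, 2.5)                          # r = 2.5, 90 degrees
  p <- elbow_path(parent, child, "radial")
  arc_pts <- p$points[seq_len(nrow(p$points) - 1L), ]
  expect_lt(max(abs(sqrt(rowSums(arc_pts^2)) - 1)), 1e-9)
  expect_equal(unname(p$points[nrow(p$points), ]), child)
})

test_that("marker clipping lands on the boundary and is idempotent", {
  p <- straight_path(c(0, 0), c(2, 0))
  pc <- clip_at_marker(p, "circle", 0.5, "target")
  expect_lt(max(abs(netcanvas:::path_end(pc) - c(1.5, 0))), 1e-9)
  ps <- clip_at_marker(p, "square", 0.5, "target")
  expect_lt(max(abs(netcanvas:::path_end(ps) - c(1.5, 0))), 1e-9)
  # start end
  pst <- clip_at_marker(p, "circle", 0.25, "start")
  expect_lt(max(abs(netcanvas:::path_start(pst) - c(0.25, 0))), 1e-9)
  # idempotence against the same marker
  pc2 <- clip_at_marker(pc, "circle", 0.5, "target", centre = c(2, 0))
  expect_equal(pc2$points, pc$points)
  # clipping a curved path also lands on the boundary
  cb <- clip_at_marker(bezier_path(c(0, 0), c(4, 0), list(c(1, 2), c(3, 2))),
                       "circle", 0.5, "target")
  expect_lt(abs(sqrt(sum((netcanvas:::path_end(cb) - c(4, 0))^2)) - 0.5),
            1e-9)
  expect_error(clip_at_marker(p, "circle", 3, "target"), "fully-clipped")
})

test_that("arrowheads sit on the terminal tangent and shorten the path", {
  p <- straight_path(c(0, 0), c(1.5, 0))
  ah <- arrowhead(p, width = 0.2, length = 0.2)
  expect_equal(unname(ah$triangle[1, ]), c(1.5, 0))
  expect_equal(unname((ah$triangle[2, ] + ah$triangle[3, ]) / 2), c(1.3, 0))
  expect_lt(abs(path_length(ah$path) - 1.3), 1e-12)
  # triangle area = width * length / 2
  tr <- ah$triangle
  area <- abs((tr[2, 1] - tr[1, 1]) * (tr[3, 2] - tr[1, 2]) -
              (tr[3, 1] - tr[1, 1]) * (tr[2, 2] - tr[1, 2])) / 2
  expect_equal(area, 0.02)
  expect_error(arrowhead(p, 0.2, 2), "fully-clipped")
})

test_that("splitting partitions arc length and conserves geometry", {
  p <- straight_path(c(0, 0), c(2, 0))
  halves <- split_path(p, 0.5)
  expect_equal(vapply(halves, path_length, 1), c(1, 1))

  # elbow corner split
  e <- elbow_path(c(0, 1.25), c(1, 2), "rectangular", "right")
  parts <- split_path(e, elbow_corner_fraction(e))
  expect_equal(vapply(parts, path_length, 1), c(0.75, 1))

  # identity split
  expect_identical(split_path(p), list(p))

  # arc-length conservation on a curved path
  cb <- ports_path(c(0, 0), c(3, 1), pi / 2, pi / 3)
  parts2 <- split_path(cb, c(0.2, 0.5, 0.9))
  expect_lt(abs(path_length(cb) - sum(vapply(parts2, path_length, 1))), 1e-9)
  # concatenation reproduces the endpoints chain
  expect_equal(netcanvas:::path_start(parts2[[1]]),
               netcanvas:::path_start(cb))
  for (k in 1:3) {
    expect_equal(netcanvas:::path_end(parts2[[k]]),
                 netcanvas:::path_start(parts2[[k + 1]]))
  }
  expect_equal(netcanvas:::path_end(parts2[[4]]), netcanvas:::path_end(cb))

  expect_error(split_path(p, c(0.5, 0.5)), "range error")
  expect_error(split_path(p, 1.5), "range error")
})

test_that("every geometry honours the endpoint contract", {
  p1 <- c(0.3, -1.2); p2 <- c(2.5, 0.7)
  paths <- list(
    straight_path(p1, p2),
    arc_path(p1, p2, 0.7),
    bezier_path(p1, p2, list(c(1, 3))),
    ports_path(p1, p2, 1, 2),
    waypoint_path(p1, p2, list(c(1, 1), c(2, -1)))
  )
  for (p in paths) {
    expect_lt(max(abs(netcanvas:::path_start(p) - p1)), 1e-12)
    expect_lt(max(abs(netcanvas:::path_end(p) - p2)), 1e-12)
  }
})

test_that("constructions are translation- and rotation-equivariant", {
  set.seed(11)
  for (k in 1:25) {
    p1 <- stats::runif(2, -3, 3); p2 <- stats::runif(2, -3, 3)
    ang <- stats::runif(1, 0, 2 * pi); sh <- stats::runif(2, -5, 5)
    q1 <- drop(transform_pts(rbind(p1), ang, sh))
    q2 <- drop(transform_pts(rbind(p2), ang, sh))
    t <- stats::runif(1, -1, 1)
    base <- transform_pts(sample_path(arc_path(p1, p2, t), 17), ang, sh)
    moved <- sample_path(arc_path(q1, q2, t), 17)
    expect_lt(max(abs(base - moved)), 1e-9)

    th <- stats::runif(2, -pi, pi)
    base_b <- transform_pts(
      sample_path(ports_path(p1, p2, th[1], th[2]), 17), ang, sh)
    moved_b <- sample_path(ports_path(q1, q2, th[1] + ang, th[2] + ang), 17)
    expect_lt(max(abs(base_b - moved_b)), 1e-9)
  }
})
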