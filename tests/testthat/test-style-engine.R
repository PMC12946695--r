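test_that("built-in styles are complete and unknown names are rejected", {
  for (nm in c("default", "minimal", "tree")) {
    st <- get_default_style(nm)
    for (etype in c("vertex", "edge", "arrow", "loop", "vertex_label",
                    "edge_label", "cascade", "grouping")) {
      res <- resolve_element(flatten_style(base = nm), etype, 0, "x")
      expect_true(all(c("netcanvas_style") %in% class(flatten_style(st))))
      expect_gt(length(res), 0)
    }
  }
  expect_error(get_default_style("fancy"), "lookup error")
  expect_identical(get_default_style("tree")$edge$geometry, "elbow")
})

test_that("cascading merge overrides later-over-earlier at leaf level", {
  st <- flatten_style(list(list(vertex = list(color = "red")),
                           list(vertex = list(color = "blue"))), base = NULL)
  expect_identical(st$vertex$color, "blue")

  st2 <- flatten_style(list(list(vertex = list(size = 10)),
                            list(vertex = list(color = "blue"))),
                       base = NULL)
  expect_equal(st2$vertex$size, 10)
  expect_identical(st2$vertex$color, "blue")

  # per-element sequence replaces a scalar wholesale
  st3 <- flatten_style(list(list(edge = list(tension = 0.2)),
                            list(edge = list(tension = c(0, 0.5)))),
                       base = NULL)
  expect_equal(st3$edge$tension, c(0, 0.5))
})

test_that("unknown element-type keys fail with a suggestion", {
  expect_error(flatten_style(list(list(vertx = list(size = 1)))),
               "vertex")
})

test_that("flattening is associative over fragment triples", {
  set.seed(99)
  frag <- function() {
    types <- sample(c("vertex", "edge", "loop"), 2)
    out <- list()
    for (tp in types) {
      out[[tp]] <- stats::setNames(
        as.list(stats::runif(2)),
        sample(c("size", "color", "linewidth", "tension"), 2))
    }
    out
  }
  for (rep in 1:20) {
    a <- frag(); b <- frag(); c_ <- frag()
    direct <- flatten_style(list(a, b, c_))
    nested <- flatten_style(list(unclass(flatten_style(list(a, b),
                                                       base = NULL)), c_))
    expect_equal(unclass(direct), unclass(nested))
  }
})

test_that("per-element resolution rotates sequences and falls back on maps", {
  st <- flatten_style(list(edge = list(color = c("red", "blue"),
                                       tension = list(`A~B` = 0.5))))
  # rotation: index 2 of 3 edges -> 2 mod 2 = 0 -> "red"
  expect_identical(resolve_element(st, "edge", 2, "C~A")$color, "red")
  expect_identical(resolve_element(st, "edge", 1, "B~C")$color, "blue")
  # scalar applies everywhere
  st2 <- flatten_style(list(vertex = list(size = 30)))
  expect_equal(resolve_element(st2, "vertex", 7, "q")$size, 30)
  # mapping: hit by id, default-style fallback otherwise
  expect_equal(resolve_element(st, "edge", 0, "A~B")$tension, 0.5)
  expect_equal(resolve_element(st, "edge", 1, "B~C")$tension, 0)
})

test_that("resolution is pure and returns exactly the vocabulary keys", {
  st <- flatten_style(list(vertex = list(size = c(5, 10, 15))))
  r1 <- resolve_element(st, "vertex", 4, "v5")
  r2 <- resolve_element(st, "vertex", 4, "v5")
  expect_identical(r1, r2)
  expect_identical(sort(names(r1)),
                   sort(c("size", "shape", "facecolor", "edgecolor",
                          "linewidth", "zorder")))
  r3 <- resolve_element(st, "edge", 0, "e")
  expect_identical(sort(names(r3)),
                   sort(c("color", "linewidth", "linestyle", "geometry",
                          "tension", "ports", "waypoints", "offset")))
})

test_that("vectorised resolution agrees with per-element resolution", {
  st <- flatten_style(list(edge = list(color = c("red", "blue", "lime"),
                                       linewidth = list(`B~C` = 4))))
  ids <- c("A~B", "B~C", "C~D", "D~E")
  all_res <- netcanvas:::resolve_all(st, "edge", 4, ids)
  for (i in seq_along(ids)) {
    one <- resolve_element(st, "edge", i - 1, ids[[i]])
    expect_identical(all_res$color[[i]], one$color)
    expect_identical(all_res$linewidth[[i]], one$linewidth)
  }
})

test_that("quantitative colouring normalises linearly and keeps the record", {
  r <- map_quantity_to_colour(c(0, 5, 10), "viridis")
  expect_equal(r$normalised, c(0, 0.5, 1))
  expect_equal(r$norm$vmin, 0)
  expect_equal(r$norm$vmax, 10)

  r2 <- map_quantity_to_colour(c(2, 4), "gray", norm = c(0, 8))
  expect_equal(r2$normalised, c(0.25, 0.5))
  expect_identical(r2$colors, c("#404040", "#808080"))

  expect_error(map_quantity_to_colour(c(3, 3, 3)), "degenerate-range")
  expect_error(map_quantity_to_colour(c(1, Inf)), "value error")
  expect_error(map_quantity_to_colour(1:3, "nope"), "lookup error")
  # constant values are fine with an explicit norm
  r3 <- map_quantity_to_colour(c(3, 3), "gray", norm = c(0, 6))
  expect_equal(r3$normalised, c(0.5, 0.5))
})

test_that("named colours resolve through the built-in table", {
  expect_equal(resolve_colour("red"), c(1, 0, 0))
  expect_equal(resolve_colour("#00ff00"), c(0, 1, 0))
  expect_equal(resolve_colour(c(0.2, 0.4, 0.6)), c(0.2, 0.4, 0.6))
  expect_error(resolve_colour("puce"), "lookup error")
})
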