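test_that("plot_network wires providers, layout and style together", {
  h <- plot_network(list(edges = list(c("A", "B"), c("B", "C"))),
                    layout = list(A = c(0, 0), B = c(1, 0), C = c(1, 1)))
  expect_s3_class(h, "netcanvas_render")
  expect_equal(unname(scene_counts(h$scene)[c("edge", "vertex")]),
               as.integer(c(2, 3)))

  # provider-extracted layout when the argument is omitted
  desc <- provider_descriptor(
    "with-layout", "network",
    matcher = function(obj) inherits(obj, "laid_out"),
    converter = function(obj) build_network(obj$edges),
    layout_extractor = function(obj) obj$xy)
  register_provider(desc)
  on.exit(unregister_provider("with-layout"))
  obj <- structure(list(edges = list(c("A", "B")),
                        xy = list(A = c(0, 0), B = c(1, 0))),
                   class = "laid_out")
  h2 <- plot_network(obj)
  expect_equal(unname(scene_counts(h2$scene)[["vertex"]]), 2L)

  expect_error(plot_network(list(edges = list(c("A", "B")))),
               "missing-layout")
  expect_error(plot_network(1:5), "unsupported-input")
})

test_that("plot_tree computes cumulative branch-length layouts", {
  h <- plot_tree("((A:1,B:2):0.5,C:3);", kind = "rectangular")
  coords <- h$layout$coords
  expect_equal(unname(coords[c("A", "B", "C"), 1]), c(1.5, 2.5, 3))

  hr <- plot_tree("((A:1,B:2):0.5,C:3);", kind = "radial")
  th <- attr(hr$layout, "angles")
  expect_equal(unname(th[c("A", "B", "C")]), c(0, 2 * pi / 3, 4 * pi / 3))
  expect_identical(
    names(th[c("A", "B", "C")]),
    names(attr(hr$layout, "angles")[c("A", "B", "C")]))

  expect_error(plot_tree("(A,B);", kind = "hyperbolic"), "arg")
  # leaf labels only (internal nodes unlabelled by default)
  labels <- Filter(function(p) p$kind == "text", scene_primitives(h$scene))
  expect_setequal(vapply(labels, function(p) p$attrs$text, ""),
                  c("A", "B", "C"))
})

test_that("tree scenes use elbow edges by default", {
  h <- plot_tree("((A,B),C);")
  edges <- Filter(function(p) p$zclass == "edge", scene_primitives(h$scene))
  n_seg <- vapply(edges, function(p) length(p$segments), 1L)
  expect_true(any(n_seg == 2))  # at least one true corner elbow
})

test_that("tanglegrams mirror, link leaves exactly, and reject non-leaves", {
  nwk <- "((A:1,B:2):0.5,C:3);"
  h <- plot_tree_pair(nwk, nwk,
                      links = list(c("A", "A"), c("B", "B"), c("C", "C")))
  links <- Filter(function(p) grepl("^L:.*~R:", p$id), scene_primitives(h$scene))
  expect_length(links, 3)
  for (lk in links) {
    expect_equal(lk$coords[1, 2], lk$coords[2, 2])  # exactly horizontal
  }
  # endpoints coincide with the leaf layout coordinates
  c1 <- h$layout[[1]]$coords
  c2 <- h$layout[[2]]$coords
  for (lk in links) {
    ids <- strsplit(lk$id, "~", fixed = TRUE)[[1]]
    expect_lt(max(abs(lk$coords[1, ] - c1[ids[1], ])), 1e-12)
    expect_lt(max(abs(lk$coords[2, ] - c2[ids[2], ])), 1e-12)
  }

  h0 <- plot_tree_pair(nwk, nwk)
  expect_length(Filter(function(p) grepl("^L:.*~R:", p$id),
                       scene_primitives(h0$scene)), 0)

  expect_error(plot_tree_pair(nwk, nwk, links = list(c("A", ".n1"))),
               "lookup error")
})

test_that("svg and json exports are byte-deterministic; json round-trips", {
  h <- plot_network(
    list(edges = list(c("A", "B"), c("B", "C")), directed = TRUE),
    layout = list(A = c(0, 0), B = c(1, 0), C = c(1, 1)),
    style = list(edge = list(geometry = "arc", tension = 0.3)))
  f1 <- tempfile(fileext = ".svg"); f2 <- tempfile(fileext = ".svg")
  export_figure(h, f1); export_figure(h, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  j <- tempfile(fileext = ".json")
  export_figure(h, j)
  reloaded <- scene_from_json(paste(readLines(j), collapse = "\n"))
  expect_identical(scene_json(reloaded), scene_json(h$scene))

  expect_error(export_figure(h, tempfile(fileext = ".pdf")), "format error")

  p <- tempfile(fileext = ".png")
  export_figure(h, p)
  expect_gt(file.size(p), 0)
  unlink(c(f1, f2, j, p))
})

test_that("svg output groups primitives by zorder class", {
  h <- plot_network(list(edges = list(c("A", "B")), directed = TRUE),
                    layout = list(A = c(0, 0), B = c(2, 0)))
  svg <- scene_svg(h$scene)
  expect_equal(sum(grepl("^<g class=", svg)), 6)
  g_order <- sub("^<g class=\"(.*)\">$", "\\1", grep("^<g class=",
                                                     svg, value = TRUE))
  expect_identical(g_order, c("grouping", "cascade", "edge", "arrow",
                              "vertex", "label"))
  # the directed edge got an arrow triangle
  expect_true(any(grepl("<polygon", svg)))
})

test_that("the null backend receives one call per primitive, in order", {
  h <- plot_tree("((A,B),C);", cascade_nodes = ".n2")
  be <- null_backend()
  render_scene(h$scene, be)
  expect_length(be$calls, length(scene_primitives(h$scene)))
  whats <- vapply(be$calls, function(c_) c_$what, "")
  kinds <- vapply(scene_primitives(h$scene), function(p) p$kind, "")
  expect_identical(whats, unname(c(marker = "marker", path = "path",
                                   polygon = "polygon", text = "text")[kinds]))
})

test_that("the CLI renders networks and trees end to end", {
  tmp <- tempfile("cli"); dir.create(tmp)
  edges <- file.path(tmp, "edges.tsv")
  writeLines(c("A\tB\t1.0", "B\tC\t2.0"), edges)
  layout <- file.path(tmp, "layout.tsv")
  writeLines(c("A\t0\t0", "B\t1\t0", "C\t1\t1"), layout)
  style <- file.path(tmp, "style.json")
  writeLines('{"vertex": {"facecolor": "teal", "size": 14}}', style)
  out <- file.path(tmp, "net.svg")
  netcanvas_cli(c("network", "--edges", edges, "--layout", layout,
                  "--style", style, "--out", out))
  svg <- readLines(out)
  expect_true(any(grepl("#008080", svg)))   # teal markers made it through

  nwk <- file.path(tmp, "tree.nwk")
  writeLines("((A:1,B:2):0.5,C:3);", nwk)
  out2 <- file.path(tmp, "tree.json")
  netcanvas_cli(c("tree", "--newick", nwk, "--kind", "radial",
                  "--out", out2))
  sc <- scene_from_json(paste(readLines(out2), collapse = "\n"))
  expect_equal(unname(table(factor(
    vapply(scene_primitives(sc), function(p) p$zclass, ""),
    levels = c("edge", "vertex", "label")))[["label"]]), 3L)

  expect_error(netcanvas_cli(c("network", "--edges", edges, "--out", out)),
               "--layout")
  expect_error(netcanvas_cli("volcano"), "usage")
  unlink(tmp, recursive = TRUE)
})
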