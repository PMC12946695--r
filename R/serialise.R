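# Deterministic scene serialisation. JSON is the equality surface for the
# provider-equivalence and determinism guarantees: sorted attribute keys,
# fixed float formatting at 9 significant digits, fixed field order. SVG is
# likewise emitted as plain deterministic text, one <g> per zorder class.

fmt_num <- function(x) {
  if (is.null(x) || length(x) == 0L) return("null")
  x <- as.numeric(x)
  out <- character(length(x))
  for (k in seq_along(x)) {
    v <- x[[k]]
    if (is.na(v)) { out[[k]] <- "null"; next }
    if (v == 0) v <- 0  # normalise -0
    out[[k]] <- sprintf("%.9g", v)
  }
  out
}

json_str <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  paste0("\"", s, "\"")
}

json_value <- function(v) {
  if (is.null(v)) return("null")
  if (is.logical(v)) return(ifelse(is.na(v), "null",
                                   ifelse(v, "true", "false"))[[1]])
  if (is.numeric(v)) {
    if (length(v) == 1L) return(fmt_num(v))
    return(paste0("[", paste(fmt_num(v), collapse = ","), "]"))
  }
  if (is.character(v)) {
    if (length(v) == 1L) return(json_str(v))
    return(paste0("[", paste(vapply(v, json_str, ""), collapse = ","), "]"))
  }
  if (is.matrix(v)) {
    rows <- apply(v, 1L, function(r) paste0("[", paste(fmt_num(r),
                                                       collapse = ","), "]"))
    return(paste0("[", paste(rows, collapse = ","), "]"))
  }
  if (is.list(v)) {
    if (is.null(names(v))) {
      return(paste0("[", paste(vapply(v, json_value, ""), collapse = ","),
                    "]"))
    }
    nm <- sort(names(v))
    return(paste0("{", paste0(vapply(nm, json_str, ""), ":",
                              vapply(v[nm], json_value, ""),
                              collapse = ","), "}"))
  }
  stop("cannot serialise value of class ", class(v)[[1]], call. = FALSE)
}

coords_json <- function(m) {
  if (!is.matrix(m)) m <- matrix(m, 1L)
  rows <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    rows[[i]] <- paste0("[", paste(fmt_num(m[i, ]), collapse = ","), "]")
  }
  paste0("[", paste(rows, collapse = ","), "]")
}

prim_space_tags <- function(p) {
  key <- if (p$kind == "marker") "marker"
         else if (p$kind == "path") "path"
         else if (p$kind == "text") "text"
         else if (identical(p$zclass, "arrow")) "arrow" else "patch"
  sp <- .attr_spaces[[key]]
  fig <- names(sp)[sp == "figure"]
  c("coords:data", if (length(fig)) paste0(fig, ":figure"))
}

prim_json <- function(p) {
  attrs <- p$attrs
  nm <- sort(names(attrs))
  attr_str <- paste0("{", paste0(vapply(nm, json_str, ""), ":",
                                 vapply(attrs[nm], json_value, ""),
                                 collapse = ","), "}")
  seg_str <- if (is.null(p$segments)) "null" else
    paste0("[", paste(vapply(p$segments, json_str, ""), collapse = ","), "]")
  spaces <- paste0("[", paste(vapply(prim_space_tags(p), json_str, ""),
                              collapse = ","), "]")
  paste0("{\"kind\":", json_str(p$kind),
         ",\"zclass\":", json_str(p$zclass),
         ",\"index\":", fmt_num(p$index),
         ",\"id\":", json_str(p$id),
         ",\"coords\":", coords_json(p$coords),
         ",\"segments\":", seg_str,
         ",\"z\":", if (is.na(p$z)) "null" else fmt_num(p$z),
         ",\"attrs\":", attr_str,
         ",\"spaces\":", spaces, "}")
}

#' Serialise a scene to deterministic JSON
#'
#' Fixed field order, sorted attribute keys, floats at 9 significant digits:
#' two scenes are element-wise equal exactly when their JSON bytes are equal.
#' @param scene a `netcanvas_scene`.
#' @return a single JSON string.
#' @export
scene_json <- function(scene) {
  prims <- vapply(scene_primitives(scene), prim_json, "")
  cb <- if (is.null(scene$colourbar)) "null" else json_value(scene$colourbar)
  paste0("{\"type\":\"netcanvas_scene\",\"ndim\":", fmt_num(scene$ndim),
         ",\"colourbar\":", cb,
         ",\"primitives\":[", paste(prims, collapse = ","), "]}")
}

#' Rebuild a scene from its JSON serialisation
#' @param txt JSON string produced by [scene_json()].
#' @return a `netcanvas_scene` equal (as serialised) to the original.
#' @export
scene_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (!identical(obj$type, "netcanvas_scene")) {
    stop("format error: not a netcanvas scene document", call. = FALSE)
  }
  prims <- lapply(obj$primitives, function(p) {
    coords <- do.call(rbind, lapply(p$coords, function(r) as.numeric(r)))
    attrs <- lapply(p$attrs, function(v) {
      if (is.list(v)) unlist(v) else v
    })
    new_primitive(p$kind, p$zclass, as.integer(p$index), p$id, coords, attrs,
                  segments = if (is.null(p$segments)) NULL
                             else as.character(unlist(p$segments)),
                  z = if (is.null(p$z)) NA_real_ else as.numeric(p$z))
  })
  cb <- obj$colourbar
  structure(list(primitives = prims, ndim = as.integer(obj$ndim),
                 colourbar = cb),
            class = "netcanvas_scene")
}

# ---------------------------------------------------------------------------
# Backend bridge: the renderer-facing contract is four draw calls with
# space-tagged attributes. The null backend records calls for testing; the
# SVG writer and the base-graphics raster backend implement the same walk.

#' A backend that records draw calls instead of drawing
#'
#' @return an environment with a `calls` list and the four draw functions
#'   `draw_marker`, `draw_path`, `draw_polygon`, `draw_text`.
#' @export
null_backend <- function() {
  env <- new.env(parent = emptyenv())
  env$calls <- list()
  rec <- function(what) {
    force(what)
    function(coords, attrs, ...) {
      env$calls[[length(env$calls) + 1L]] <-
        list(what = what, coords = coords, attrs = attrs)
      invisible(NULL)
    }
  }
  env$draw_marker <- rec("marker")
  env$draw_path <- rec("path")
  env$draw_polygon <- rec("polygon")
  env$draw_text <- rec("text")
  env
}

#' Walk a scene through a backend's draw calls
#'
#' @param scene a `netcanvas_scene`.
#' @param backend an object exposing `draw_marker`, `draw_path`,
#'   `draw_polygon`, `draw_text` (see [null_backend()]).
#' @export
render_scene <- function(scene, backend) {
  for (p in scene_primitives(scene)) {
    fn <- switch(p$kind, marker = backend$draw_marker,
                 path = backend$draw_path, polygon = backend$draw_polygon,
                 text = backend$draw_text)
    fn(p$coords, p$attrs, segments = p$segments, zclass = p$zclass)
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# SVG writer

svg_num <- function(x) sprintf("%.6g", round(x, 6) + 0)

scene_bbox <- function(scene) {
  xs <- ys <- numeric(0)
  for (p in scene_primitives(scene)) {
    xs <- range(xs, p$coords[, 1])
    ys <- range(ys, p$coords[, 2])
  }
  if (!length(xs)) return(c(0, 1, 0, 1))
  if (xs[1] == xs[2]) xs <- xs + c(-0.5, 0.5)
  if (ys[1] == ys[2]) ys <- ys + c(-0.5, 0.5)
  c(xs, ys)
}

# map data coords to pixel space (y axis flipped); returns closure + scale
svg_transform <- function(scene, width = 600, margin = 40) {
  bb <- scene_bbox(scene)
  s <- (width - 2 * margin) / max(bb[2] - bb[1], bb[4] - bb[3])
  height <- 2 * margin + s * (bb[4] - bb[3])
  list(
    fn = function(m) {
      cbind(margin + s * (m[, 1, drop = TRUE] - bb[1]),
            height - margin - s * (m[, 2, drop = TRUE] - bb[3]))
    },
    scale = s, width = width, height = height
  )
}

path_d <- function(points, segments) {
  d <- sprintf("M %s %s", svg_num(points[1, 1]), svg_num(points[1, 2]))
  i <- 2L
  for (tag in segments) {
    if (tag == "cubic") {
      d <- paste0(d, sprintf(" C %s %s, %s %s, %s %s",
                             svg_num(points[i, 1]), svg_num(points[i, 2]),
                             svg_num(points[i + 1, 1]),
                             svg_num(points[i + 1, 2]),
                             svg_num(points[i + 2, 1]),
                             svg_num(points[i + 2, 2])))
      i <- i + 3L
    } else {
      d <- paste0(d, sprintf(" L %s %s", svg_num(points[i, 1]),
                             svg_num(points[i, 2])))
      i <- i + 1L
    }
  }
  d
}

.linestyles <- c(solid = "", dashed = "6,4", dotted = "1.5,3")

svg_edge_elements <- function(p, tr, marker_info, arrow_attrs) {
  # pixel-space path; clip at the end markers and realise the arrowhead here,
  # where figure units (points ~ px) and data units meet
  pts <- tr$fn(p$coords)
  path <- new_path(pts, p$segments, FALSE)
  tgt <- sub("^.*~", "", p$id)
  src <- sub("~.*$", "", p$id)
  clip_one <- function(path, vid, end, centre) {
    mi <- marker_info[[vid]]
    if (is.null(mi) || mi$size <= 0) return(path)
    tryCatch(
      clip_at_marker(path, mi$shape, mi$size / 2, end, centre = centre),
      error = function(e) path)
  }
  if (src != tgt) {  # loops stay attached to their vertex
    tgt_centre <- path_end(path)
    src_centre <- path_start(path)
    path <- clip_one(path, tgt, "target", tgt_centre)
    path <- clip_one(path, src, "start", src_centre)
  }
  tri <- NULL
  if (!is.null(arrow_attrs)) {
    ah <- tryCatch(arrowhead(path, arrow_attrs$width, arrow_attrs$length),
                   error = function(e) NULL)
    if (!is.null(ah)) {
      path <- ah$path
      tri <- sprintf(
        "<polygon points=\"%s\" fill=\"%s\" stroke=\"none\"/>",
        paste(sprintf("%s,%s", svg_num(ah$triangle[, 1]),
                      svg_num(ah$triangle[, 2])), collapse = " "),
        arrow_attrs$color)
    }
  }
  dash <- unname(.linestyles[p$attrs$linestyle %||% "solid"])
  if (length(dash) != 1L || is.na(dash)) dash <- ""
  line <- sprintf(
    "<path d=\"%s\" fill=\"none\" stroke=\"%s\" stroke-width=\"%s\"%s/>",
    path_d(path$points, path$segments), p$attrs$color,
    svg_num(p$attrs$linewidth),
    if (nzchar(dash)) sprintf(" stroke-dasharray=\"%s\"", dash) else "")
  list(line = line, triangle = tri)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scene as deterministic SVG text
#'
#' One `<g>` element per zorder class; edges are clipped at their end markers
#' and arrowheads realised here, where the data-to-pixel transform is fixed.
#' Figure units map to pixels one-to-one.
#'
#' @param scene a `netcanvas_scene`.
#' @param width image width in pixels.
#' @return a character vector of SVG lines.
#' @export
scene_svg <- function(scene, width = 600) {
  tr <- svg_transform(scene, width)
  prims <- scene_primitives(scene)
  marker_info <- list()
  arrow_map <- list()
  for (p in prims) {
    if (p$kind == "marker") {
      marker_info[[p$id]] <- list(shape = p$attrs$shape %||% "circle",
                                  size = p$attrs$size %||% 0)
    } else if (identical(p$zclass, "arrow")) {
      arrow_map[[as.character(p$index)]] <- p$attrs
    }
  }
  by_class <- split(prims,
                    factor(vapply(prims, function(p) p$zclass, ""),
                           levels = names(.zclass_rank)))
  out <- sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                        "width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\">"),
                 svg_num(tr$width), svg_num(tr$height),
                 svg_num(tr$width), svg_num(tr$height))
  arrow_triangles <- character(0)
  for (cls in names(.zclass_rank)) {
    prims <- by_class[[cls]]
    out <- c(out, sprintf("<g class=\"%s\">", cls))
    if (cls == "edge") {
      for (p in prims) {
        el <- svg_edge_elements(p, tr, marker_info,
                                arrow_map[[as.character(p$index)]])
        out <- c(out, el$line)
        if (!is.null(el$triangle)) {
          arrow_triangles <- c(arrow_triangles, el$triangle)
        }
      }
    } else if (cls == "arrow") {
      out <- c(out, arrow_triangles)
    } else {
      for (p in prims) out <- c(out, svg_element(p, cls, tr))
    }
    out <- c(out, "</g>")
  }
  c(out, "</svg>")
}

svg_element <- function(p, cls, tr) {
  if (p$kind == "polygon" && cls != "arrow") {
    pts <- tr$fn(p$coords)
    return(sprintf(
      "<polygon points=\"%s\" fill=\"%s\" fill-opacity=\"%s\" stroke=\"none\"/>",
      paste(sprintf("%s,%s", svg_num(pts[, 1]), svg_num(pts[, 2])),
            collapse = " "),
      p$attrs$facecolor, svg_num(p$attrs$alpha %||% 1)))
  }
  if (p$kind == "marker") {
    if ((p$attrs$size %||% 0) <= 0) return(character(0))
    c0 <- tr$fn(p$coords)
    r <- p$attrs$size / 2
    if (identical(p$attrs$shape, "square")) {
      return(sprintf(
        paste0("<rect x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" ",
               "fill=\"%s\" stroke=\"%s\" stroke-width=\"%s\"/>"),
        svg_num(c0[1] - r), svg_num(c0[2] - r), svg_num(2 * r),
        svg_num(2 * r), p$attrs$facecolor, p$attrs$edgecolor,
        svg_num(p$attrs$linewidth %||% 1)))
    }
    return(sprintf(
      paste0("<circle cx=\"%s\" cy=\"%s\" r=\"%s\" fill=\"%s\" ",
             "stroke=\"%s\" stroke-width=\"%s\"/>"),
      svg_num(c0[1]), svg_num(c0[2]), svg_num(r), p$attrs$facecolor,
      p$attrs$edgecolor, svg_num(p$attrs$linewidth %||% 1)))
  }
  if (p$kind == "text") {
    c0 <- tr$fn(p$coords)
    return(sprintf(
      paste0("<text x=\"%s\" y=\"%s\" font-size=\"%s\" fill=\"%s\" ",
             "font-family=\"sans-serif\">%s</text>"),
      svg_num(c0[1] + (p$attrs$hoffset %||% 0)),
      svg_num(c0[2] - (p$attrs$voffset %||% 0)),
      svg_num(p$attrs$size %||% 9), p$attrs$color %||% "#000000",
      xml_escape(p$attrs$text)))
  }
  character(0)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}
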