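# Declarative cascading style grammar.
#
# A style document is a nested mapping: element type -> property -> value.
# A value is a scalar (applies to every element), an unnamed sequence
# (positional per element, recycled by index mod length), or a named mapping
# (per element by id, falling back to the built-in default). Fragments merge
# in cascade order: later layers override earlier ones key by key; the
# built-in defaults sit at the bottom so resolution is always complete.

.style_element_types <- c("vertex", "edge", "arrow", "loop",
                          "vertex_label", "edge_label", "cascade", "grouping")

# Documented property vocabulary: resolution returns exactly these keys.
.style_vocabulary <- list(
  vertex = c("size", "shape", "facecolor", "edgecolor", "linewidth", "zorder"),
  edge = c("color", "linewidth", "linestyle", "geometry", "tension", "ports",
           "waypoints", "offset"),
  arrow = c("marker", "width", "length"),
  loop = c("size", "angle"),
  vertex_label = c("text", "size", "color", "hoffset", "voffset"),
  edge_label = c("text", "size", "color", "hoffset", "voffset"),
  cascade = c("facecolor", "alpha", "extent"),
  grouping = c("facecolor", "alpha", "padding", "rounding")
)

# Properties whose single value is itself a numeric vector / coordinate list;
# for these, an unnamed *list* is positional per element and a bare numeric
# vector or matrix is one spec shared by all elements.
.structured_props <- c("ports", "waypoints")

.style_defaults <- list(
  default = list(
    vertex = list(size = 10, shape = "circle", facecolor = "gray",
                  edgecolor = "black", linewidth = 1, zorder = 2),
    edge = list(color = "black", linewidth = 1.5, linestyle = "solid",
                geometry = "straight", tension = 0, ports = NULL,
                waypoints = NULL, offset = 0),
    arrow = list(marker = "triangle", width = 5, length = 8),
    loop = list(size = 0.2, angle = NULL),
    vertex_label = list(text = NULL, size = 9, color = "black",
                        hoffset = 0, voffset = 0),
    edge_label = list(text = NULL, size = 8, color = "black",
                      hoffset = 0, voffset = 0),
    cascade = list(facecolor = "silver", alpha = 0.3, extent = "leaves"),
    grouping = list(facecolor = "silver", alpha = 0.3, padding = 0.1,
                    rounding = TRUE)
  )
)
.style_defaults$minimal <- utils::modifyList(.style_defaults$default, list(
  vertex = list(size = 5, facecolor = "black", linewidth = 0),
  edge = list(linewidth = 0.8, color = "gray")
))
.style_defaults$tree <- utils::modifyList(.style_defaults$default, list(
  vertex = list(size = 0, linewidth = 0),
  edge = list(geometry = "elbow", linewidth = 1.2),
  vertex_label = list(text = "id", hoffset = 4)
))

#' Built-in default styles
#'
#' A small library of complete styles for rapid prototyping: every property in
#' the vocabulary has a value, so any fragment stack based on one of these
#' resolves with no missing properties. `"tree"` draws edges as elbows and
#' labels leaves by id; `"minimal"` is a quiet small-marker look.
#'
#' @param name one of `"default"`, `"minimal"`, `"tree"`.
#' @return a complete `netcanvas_style`.
#' @export
get_default_style <- function(name = "default") {
  spec <- .style_defaults[[name]]
  if (is.null(spec)) {
    stop("lookup error: unknown style '", name, "' (available: ",
         paste(names(.style_defaults), collapse = ", "), ")", call. = FALSE)
  }
  structure(spec, class = "netcanvas_style")
}

#' Merge style fragments into one cascaded style
#'
#' Deep merge at the leaf level: later layers override earlier ones key by
#' key; a sequence or mapping value replaces (never merges element-wise with)
#' whatever came before. Unknown element-type keys are rejected here, with the
#' nearest valid key suggested.
#'
#' @param layers list of style fragments (nested lists), earliest first.
#'   A single fragment may be passed directly.
#' @param base name of the built-in default style placed under the stack, or
#'   `NULL` for a bare merge of the fragments only.
#' @return a `netcanvas_style` (complete if `base` is not `NULL`).
#' @export
flatten_style <- function(layers = list(), base = "default") {
  if (inherits(layers, "netcanvas_style") ||
      (is.list(layers) && length(layers) &&
       any(names(layers) %in% .style_element_types))) {
    layers <- list(layers)
  }
  out <- if (is.null(base)) list() else unclass(get_default_style(base))
  for (layer in layers) {
    if (is.null(layer)) next
    check_style_fragment(layer)
    for (etype in names(layer)) {
      props <- layer[[etype]]
      if (is.null(out[[etype]])) out[[etype]] <- list()
      for (p in names(props)) {
        out[[etype]][p] <- list(props[[p]])   # replace, never merge
      }
    }
  }
  out <- structure(out, class = "netcanvas_style")
  # pre-analyse the cascade once so scene assembly pays no per-call cost:
  # scalar-ness per element type plus resolved exemplars for shared attrs
  attr(out, "nc_fast") <- style_fast_info(out)
  out
}

style_fast_info <- function(style) {
  info <- list(
    all_scalar = vapply(c("edge", "vertex", "arrow"),
                        function(et) style_all_scalar(style, et), TRUE),
    straight = style_is_scalar(style, "edge", "geometry", "straight"),
    no_vertex_label = is.null(style_raw_prop(style, "vertex_label", "text")),
    no_edge_label = is.null(style_raw_prop(style, "edge_label", "text"))
  )
  if (info$all_scalar[["edge"]]) {
    info$edge_exemplar <- resolve_element(style, "edge", 0L, NULL)
  }
  if (info$all_scalar[["vertex"]]) {
    info$vertex_exemplar <- resolve_element(style, "vertex", 0L, NULL)
  }
  if (info$all_scalar[["arrow"]]) {
    info$arrow_exemplar <- resolve_element(style, "arrow", 0L, NULL)
  }
  info
}

check_style_fragment <- function(frag) {
  if (!is.list(frag)) {
    stop("grammar error: style fragment must be a nested list", call. = FALSE)
  }
  bad <- setdiff(names(frag), .style_element_types)
  if (length(bad)) {
    d <- utils::adist(bad[[1]], .style_element_types)
    stop("grammar error: unknown element type '", bad[[1]], "'; nearest is '",
         .style_element_types[which.min(d)], "'", call. = FALSE)
  }
  invisible(NULL)
}

# classify a property value: "scalar", "sequence" (positional) or "mapping"
style_value_kind <- function(value, prop) {
  if (is.null(value)) return("scalar")
  nm <- names(value)
  if (!is.null(nm) && all(nm != "")) return("mapping")
  if (prop %in% .structured_props) {
    # a bare numeric vector/matrix is one structured spec for all elements;
    # an unnamed list is positional per element
    if (is.list(value)) return("sequence")
    return("scalar")
  }
  if (is.list(value) || length(value) > 1L) return("sequence")
  "scalar"
}

#' Resolve the style of one concrete element
#'
#' Scalars are used as-is; unnamed sequences are indexed positionally with
#' rotation (index mod length); named mappings are looked up by element id and
#' fall back to the built-in default value.
#'
#' @param style a complete (flattened) `netcanvas_style`.
#' @param element_type one of the grammar's element types.
#' @param index 0-based element index (edge/vertex insertion order).
#' @param element_id element label, used for mapping-valued properties.
#' @return named list: property -> resolved value, keys exactly the
#'   vocabulary for `element_type`.
#' @export
resolve_element <- function(style, element_type, index = 0L,
                            element_id = NULL) {
  vocab <- .style_vocabulary[[element_type]]
  if (is.null(vocab)) {
    stop("grammar error: unknown element type '", element_type, "'",
         call. = FALSE)
  }
  props <- style[[element_type]]
  fallback <- .style_defaults$default[[element_type]]
  out <- vector("list", length(vocab))
  names(out) <- vocab
  for (p in vocab) {
    v <- if (!is.null(props) && p %in% names(props)) props[[p]]
         else fallback[[p]]
    out[p] <- list(resolve_style_value(v, p, index, element_id,
                                       fallback[[p]]))
  }
  out
}

resolve_style_value <- function(v, prop, index, element_id, fallback) {
  kind <- style_value_kind(v, prop)
  if (kind == "scalar") return(v)
  if (kind == "sequence") {
    i <- (as.integer(index) %% length(v)) + 1L
    return(if (is.list(v)) v[[i]] else v[[i]])
  }
  # mapping by id, default-style value when absent
  if (!is.null(element_id) && element_id %in% names(v)) {
    return(if (is.list(v)) v[[element_id]] else v[[element_id]])
  }
  fallback
}

# Vectorised resolution used by scene assembly: one list of per-element value
# vectors/lists for all n elements at once (same semantics as resolve_element,
# kept O(n) over elements).
resolve_all <- function(style, element_type, n, ids) {
  vocab <- .style_vocabulary[[element_type]]
  props <- style[[element_type]]
  fallback <- .style_defaults$default[[element_type]]
  out <- vector("list", length(vocab))
  names(out) <- vocab
  for (p in vocab) {
    v <- if (!is.null(props) && p %in% names(props)) props[[p]]
         else fallback[[p]]
    kind <- style_value_kind(v, p)
    out[[p]] <- switch(kind,
      scalar = structure(rep(list(v), length.out = n), nc_scalar = TRUE),
      sequence = {
        vl <- if (is.list(v)) v else as.list(v)
        vl[((seq_len(n) - 1L) %% length(vl)) + 1L]
      },
      mapping = {
        vl <- if (is.list(v)) v else as.list(v)
        res <- rep(list(fallback[[p]]), n)
        hit <- ids %in% names(vl)
        res[hit] <- vl[ids[hit]]
        res
      })
  }
  out
}

#' Map a quantitative variable to colours through a colour map
#'
#' Values are normalised linearly to [0, 1] (defaulting to their own range)
#' and looked up in a built-in colour map. The normalisation record is
#' retained on the result so a colour bar can be drawn by the backend.
#'
#' @param values finite numeric vector.
#' @param colourmap name of a built-in map: `"viridis"`, `"gray"`,
#'   `"coolwarm"`.
#' @param norm optional `c(vmin, vmax)` with `vmin < vmax`; required when all
#'   values are equal.
#' @return list with `colors` (hex strings), `rgb` (n x 3 matrix in [0, 1]),
#'   and `norm` (list with `vmin`, `vmax`, `colourmap`).
#' @export
map_quantity_to_colour <- function(values, colourmap = "viridis",
                                   norm = NULL) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) {
    stop("value error: values must be finite", call. = FALSE)
  }
  if (is.null(norm)) {
    vmin <- min(values); vmax <- max(values)
    if (vmax <= vmin) {
      stop("degenerate-range error: constant values need an explicit norm",
           call. = FALSE)
    }
  } else {
    vmin <- norm[[1]]; vmax <- norm[[2]]
    if (!(vmin < vmax)) {
      stop("value error: need vmin < vmax", call. = FALSE)
    }
  }
  t <- (values - vmin) / (vmax - vmin)
  rgb <- colourmap_lookup(colourmap, t)
  list(colors = rgb_to_hex(rgb), rgb = rgb, normalised = t,
       norm = list(vmin = vmin, vmax = vmax, colourmap = colourmap))
}
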