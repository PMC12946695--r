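# Provider plug-in registry.
#
# Rendering must be identical regardless of which analysis library produced
# the graph, so every input object passes through a provider that normalises
# it into the internal model. Providers are matched in order: user-registered
# providers first (in registration order), then the built-ins. Discovery of
# installed libraries is expressed through this registry precedence: a binding
# to a real third-party library is just a provider registered at load time.

.registry <- new.env(parent = emptyenv())

#' Describe an input provider
#'
#' @param name unique provider name.
#' @param kind `"network"` or `"tree"`.
#' @param matcher side-effect-free predicate: does this provider understand
#'   the object?
#' @param converter function turning the object into a `netcanvas_network` or
#'   `netcanvas_tree`.
#' @param layout_extractor optional function returning a raw layout mapping
#'   (or `NULL`) extracted from the object.
#' @return a `netcanvas_provider` descriptor.
#' @export
provider_descriptor <- function(name, kind, matcher, converter,
                                layout_extractor = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            kind %in% c("network", "tree"),
            is.function(matcher), is.function(converter))
  structure(list(name = name, kind = kind, matcher = matcher,
                 converter = converter, layout_extractor = layout_extractor),
            class = "netcanvas_provider")
}

builtin_providers <- function() {
  list(
    provider_descriptor(
      "internal", "network",
      matcher = function(obj) inherits(obj, c("netcanvas_network",
                                              "netcanvas_tree")),
      converter = function(obj) obj
    ),
    provider_descriptor(
      "edgelist", "network",
      matcher = function(obj) is.list(obj) && !is.null(obj$edges) &&
        !inherits(obj, c("netcanvas_network", "netcanvas_tree")),
      converter = function(obj) {
        build_network(edges = obj$edges, vertex_ids = obj$vertices,
                      directed = isTRUE(obj$directed),
                      vertex_attrs = obj$vertex_attrs,
                      edge_attrs = obj$edge_attrs)
      },
      layout_extractor = function(obj) obj$layout
    ),
    provider_descriptor(
      "newick", "tree",
      matcher = function(obj) is.character(obj) && length(obj) == 1L &&
        grepl(";\\s*$", obj),
      converter = function(obj) parse_newick_toy(obj)
    )
  )
}

reset_registry <- function() {
  assign("user", list(), envir = .registry)
  assign("builtin", builtin_providers(), envir = .registry)
  invisible(NULL)
}

all_providers <- function() {
  if (!exists("builtin", envir = .registry)) reset_registry()
  c(get("user", envir = .registry), get("builtin", envir = .registry))
}

#' Register an input provider
#'
#' User-registered providers are matched before the built-ins (`internal`,
#' `edgelist`, `newick`); among user providers, first match by registration
#' order wins.
#'
#' @param descriptor a [provider_descriptor()].
#' @return the provider name, invisibly.
#' @export
register_provider <- function(descriptor) {
  stopifnot(inherits(descriptor, "netcanvas_provider"))
  existing <- vapply(all_providers(), `[[`, "", "name")
  if (descriptor$name %in% existing) {
    stop("registration error: provider '", descriptor$name,
         "' already registered", call. = FALSE)
  }
  user <- get("user", envir = .registry)
  assign("user", c(user, list(descriptor)), envir = .registry)
  invisible(descriptor$name)
}

#' Remove a user-registered provider (built-ins cannot be removed)
#' @param name provider name.
#' @export
unregister_provider <- function(name) {
  user <- get("user", envir = .registry)
  keep <- vapply(user, `[[`, "", "name") != name
  assign("user", user[keep], envir = .registry)
  invisible(NULL)
}

#' Find the provider that understands an object
#'
#' @param obj an opaque network or tree object.
#' @return the name of the first matching provider.
#' @export
detect_provider <- function(obj) {
  for (p in all_providers()) {
    ok <- tryCatch(isTRUE(p$matcher(obj)), error = function(e) FALSE)
    if (ok) return(p$name)
  }
  stop("unsupported-input error: no provider matches object of class <",
       paste(class(obj), collapse = "/"), ">", call. = FALSE)
}

#' Normalise an opaque object into the internal model
#'
#' The output depends only on the abstract graph (vertices, ordered edges,
#' attributes), never on provider internals; this is what guarantees
#' identical rendering independent of the input stream.
#'
#' @param obj an opaque network or tree object.
#' @return a list with `data` (`netcanvas_network` or `netcanvas_tree`),
#'   `layout` (raw layout mapping or `NULL`) and `provider` (name).
#' @export
normalise_input <- function(obj) {
  name <- detect_provider(obj)
  prov <- NULL
  for (p in all_providers()) if (p$name == name) { prov <- p; break }
  data <- tryCatch(prov$converter(obj), error = function(e) {
    stop("conversion error in provider '", name, "': ", conditionMessage(e),
         call. = FALSE)
  })
  layout <- NULL
  if (!is.null(prov$layout_extractor)) {
    layout <- tryCatch(prov$layout_extractor(obj), error = function(e) NULL)
  }
  list(data = data, layout = layout, provider = name)
}
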