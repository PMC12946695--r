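# Backend-independent colour model: RGB triples in [0, 1]. Named colours are
# resolved through a fixed built-in table (the CSS basic set plus orange) so
# serialised scenes do not depend on any plotting backend's colour database.

.css_colours <- list(
  black = c(0, 0, 0), silver = c(0.75, 0.75, 0.75), gray = c(0.5, 0.5, 0.5),
  grey = c(0.5, 0.5, 0.5), white = c(1, 1, 1), maroon = c(0.5, 0, 0),
  red = c(1, 0, 0), purple = c(0.5, 0, 0.5), fuchsia = c(1, 0, 1),
  magenta = c(1, 0, 1), green = c(0, 0.5, 0), lime = c(0, 1, 0),
  olive = c(0.5, 0.5, 0), yellow = c(1, 1, 0), navy = c(0, 0, 0.5),
  blue = c(0, 0, 1), teal = c(0, 0.5, 0.5), aqua = c(0, 1, 1),
  cyan = c(0, 1, 1), orange = c(1, 0.647, 0)
)

#' Resolve a colour to an RGB triple in [0, 1]
#'
#' Accepts a name from the built-in table (CSS basic set), a `#RRGGBB` hex
#' string, or a numeric RGB(A) vector already in [0, 1].
#' @param x colour specification.
#' @return numeric length-3 vector in [0, 1].
#' @export
resolve_colour <- function(x) {
  if (is.numeric(x)) {
    if (!length(x) %in% c(3L, 4L) || any(x < 0) || any(x > 1)) {
      stop("value error: numeric colours must be RGB(A) in [0, 1]",
           call. = FALSE)
    }
    return(unname(x[1:3]))
  }
  x <- tolower(as.character(x))
  if (grepl("^#[0-9a-f]{6}$", x)) {
    return(strtoi(c(substr(x, 2, 3), substr(x, 4, 5), substr(x, 6, 7)),
                  base = 16L) / 255)
  }
  if (!is.null(.css_colours[[x]])) return(.css_colours[[x]])
  stop("lookup error: unknown colour '", x, "' (known: ",
       paste(names(.css_colours), collapse = ", "), ", or #RRGGBB)",
       call. = FALSE)
}

# Built-in colour maps as RGB anchor rows interpolated linearly in [0, 1].
.colourmaps <- list(
  viridis = rbind(
    c(0.267004, 0.004874, 0.329415), c(0.282623, 0.140926, 0.457517),
    c(0.253935, 0.265254, 0.529983), c(0.206756, 0.371758, 0.553117),
    c(0.163625, 0.471133, 0.558148), c(0.127568, 0.566949, 0.550556),
    c(0.134692, 0.658636, 0.517649), c(0.266941, 0.748751, 0.440573),
    c(0.477504, 0.821444, 0.318195), c(0.741388, 0.873449, 0.149561),
    c(0.993248, 0.906157, 0.143936)),
  gray = rbind(c(0, 0, 0), c(1, 1, 1)),
  coolwarm = rbind(c(0.230, 0.299, 0.754), c(0.865, 0.865, 0.865),
                   c(0.706, 0.016, 0.150))
)

colourmap_lookup <- function(name, t) {
  anchors <- .colourmaps[[name]]
  if (is.null(anchors)) {
    stop("lookup error: unknown colourmap '", name, "' (available: ",
         paste(names(.colourmaps), collapse = ", "), ")", call. = FALSE)
  }
  t <- pmin(pmax(t, 0), 1)
  k <- nrow(anchors)
  pos <- t * (k - 1)
  lo <- pmin(floor(pos), k - 2) + 1
  frac <- pos - (lo - 1)
  anchors[lo, , drop = FALSE] * (1 - frac) +
    anchors[lo + 1, , drop = FALSE] * frac
}

rgb_to_hex <- function(rgb) {
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3])
}
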