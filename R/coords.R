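#' Coordinate axes and coordinate systems
#'
#' Data frames in this package are arrays organised along explicit coordinate
#' axes. An axis is either a *scalar* axis (a strictly increasing numeric
#' vector, e.g. time in seconds or pixel x-positions in metres) or a *vector*
#' axis (an integer-indexed list of fixed-length position tuples, e.g. the
#' (x, y) position of each transducer). A coordinate system is an ordered
#' collection of axes; the total number of elements it addresses is the
#' product of the axis lengths.
#'
#' @param name axis name (character scalar).
#' @param units physical units (character scalar, e.g. `"m"`, `"s"`).
#' @param values strictly increasing numeric vector (scalar axis).
#' @param positions numeric matrix, one row per element (vector axis); all
#'   rows share the same dimensionality.
#' @return An object of class `scalar_axis` or `vector_axis`.
#' @export
scalar_axis <- function(name, units, values) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values) || any(!is.finite(values)))
    stop("scalar axis '", name, "': values must be finite")
  if (length(values) > 1L && any(diff(values) <= 0))
    stop("scalar axis '", name, "': values must be strictly increasing")
  structure(list(name = name, units = units, values = values),
            class = "scalar_axis")
}

#' @rdname scalar_axis
#' @export
vector_axis <- function(name, units, positions) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (nrow(positions) < 1L || anyNA(positions))
    stop("vector axis '", name, "': positions must be a finite matrix")
  structure(list(name = name, units = units, positions = positions),
            class = "vector_axis")
}

axis_length <- function(ax) {
  if (inherits(ax, "scalar_axis")) length(ax$values) else nrow(ax$positions)
}

#' @param ... axes (in order) making up the coordinate system.
#' @rdname scalar_axis
#' @export
coordinate_system <- function(...) {
  axes <- list(...)
  if (length(axes) == 1L && is.list(axes[[1L]]) &&
      !inherits(axes[[1L]], c("scalar_axis", "vector_axis")))
    axes <- axes[[1L]]
  ok <- vapply(axes, inherits, logical(1), c("scalar_axis", "vector_axis"))
  if (!all(ok)) stop("coordinate_system: all arguments must be axes")
  names(axes) <- vapply(axes, `[[`, character(1), "name")
  structure(list(axes = axes), class = "coordinate_system")
}

#' @export
length.coordinate_system <- function(x) {
  prod(vapply(x$axes, axis_length, numeric(1)))
}

#' @export
print.coordinate_system <- function(x, ...) {
  cat("<coordinate_system> ", length(x$axes), " axes, ",
      length(x), " elements\n", sep = "")
  for (ax in x$axes) {
    kind <- if (inherits(ax, "scalar_axis")) "scalar" else "vector"
    cat("  ", ax$name, " [", kind, ", n=", axis_length(ax), ", ",
        ax$units, "]\n", sep = "")
  }
  invisible(x)
}

#' Square image-pixel coordinate system
#'
#' Builds the n-by-n pixel-center grid for a square field of view centred on
#' the transducer array centre (the origin). Pixel centres are spaced
#' `fov / n` apart and the grid is symmetric about 0 on both axes; for odd n
#' the middle centre is exactly 0.
#'
#' @param n pixels per axis (>= 2).
#' @param fov field-of-view width/height in metres.
#' @return A `coordinate_system` with scalar axes `x` and `y` (metres), plus
#'   attributes `n`, `fov` and `pixel_size` used by the model builders.
#' @export
make_image_coords <- function(n, fov) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("make_image_coords: n must be >= 2")
  if (!is.numeric(fov) || fov <= 0) stop("make_image_coords: fov must be > 0")
  h <- fov / n
  centers <- (seq_len(n) - (n + 1) / 2) * h
  cs <- coordinate_system(scalar_axis("x", "m", centers),
                          scalar_axis("y", "m", centers))
  attr(cs, "n") <- n
  attr(cs, "fov") <- fov
  attr(cs, "pixel_size") <- h
  cs
}

image_coord_info <- function(coords) {
  stopifnot(inherits(coords, "coordinate_system"))
  x <- coords$axes$x$values
  y <- coords$axes$y$values
  list(x = x, y = y, nx = length(x), ny = length(y),
       hx = if (length(x) > 1) x[2] - x[1] else attr(coords, "pixel_size"),
       hy = if (length(y) > 1) y[2] - y[1] else attr(coords, "pixel_size"),
       fov = attr(coords, "fov"))
}
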