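#' Paraboloid absorber
#'
#' The analytical phantom primitive: a radially parabolic absorption profile
#' `p0(r) = A * (1 - |r - center|^2 / R^2)` for `|r - center| <= R`, zero
#' outside. Its circular line integrals (and hence its ideal point-detector
#' signal) have a closed form, which is what makes these phantoms useful as
#' exact oracles for discretized forward models.
#'
#' @param center numeric (x, y) in metres.
#' @param radius paraboloid span radius R in metres (> 0).
#' @param amplitude peak amplitude A (> 0, arbitrary units).
#' @return A `paraboloid_source`.
#' @export
paraboloid_source <- function(center, radius, amplitude = 1) {
  center <- as.numeric(center)
  if (length(center) != 2L || anyNA(center)) stop("center must be (x, y)")
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  if (!is.numeric(amplitude) || amplitude <= 0) stop("amplitude must be > 0")
  structure(list(center = center, radius = as.numeric(radius),
                 amplitude = as.numeric(amplitude)),
            class = "paraboloid_source")
}

#' Phantom specification
#'
#' A set of pairwise non-overlapping paraboloid sources wholly inside a
#' square field of view. Non-overlap makes the total signal the plain sum of
#' per-source closed forms.
#'
#' @param sources list of [paraboloid_source]s.
#' @param fov field-of-view width in metres.
#' @param seed integer seed recorded for provenance (may be NA).
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(sources, fov, seed = NA_integer_) {
  stopifnot(is.list(sources))
  half <- fov / 2
  ns <- length(sources)
  for (s in sources) {
    stopifnot(inherits(s, "paraboloid_source"))
    if (any(abs(s$center) + s$radius > half + 1e-12))
      stop("source disc extends outside the field of view")
  }
  if (ns > 1L) for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    d <- sqrt(sum((sources[[i]]$center - sources[[j]]$center)^2))
    if (d <= sources[[i]]$radius + sources[[j]]$radius)
      stop("sources overlap")
  }
  structure(list(sources = sources, fov = as.numeric(fov),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Draw a random paraboloid phantom
#'
#' Source count, radii, amplitudes and centres are drawn uniformly over the
#' given ranges; candidate sources violating the in-FOV or non-overlap
#' constraints are rejection-sampled. Deterministic for a fixed seed.
#'
#' @param n_sources_range integer (min, max) source count; default 1-8.
#' @param radius_range (min, max) radius as a fraction of the FOV width;
#'   default c(0.02, 0.15).
#' @param amplitude_range (min, max) amplitude; default c(0.5, 2).
#' @param fov field-of-view width in metres.
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget per source.
#' @return A [phantom_spec].
#' @export
sample_phantom <- function(n_sources_range = c(1L, 8L),
                           radius_range = c(0.02, 0.15),
                           amplitude_range = c(0.5, 2),
                           fov = 0.025, seed = 1L, max_tries = 1000L) {
  stopifnot(all(n_sources_range >= 1L), all(radius_range > 0),
            all(amplitude_range > 0), fov > 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(restore_rng(old_seed))
  set.seed(as.integer(seed))
  n <- if (n_sources_range[1L] == n_sources_range[2L]) n_sources_range[1L]
       else sample(seq(n_sources_range[1L], n_sources_range[2L]), 1L)
  sources <- list()
  half <- fov / 2
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      R <- stats::runif(1, radius_range[1L], radius_range[2L]) * fov
      if (R >= half) next
      cx <- stats::runif(1, -half + R, half - R)
      cy <- stats::runif(1, -half + R, half - R)
      ok <- TRUE
      for (s in sources) {
        if (sqrt((cx - s$center[1])^2 + (cy - s$center[2])^2) <=
            R + s$radius) { ok <- FALSE; break }
      }
      if (ok) {
        A <- stats::runif(1, amplitude_range[1L], amplitude_range[2L])
        sources[[length(sources) + 1L]] <-
          paraboloid_source(c(cx, cy), R, A)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("sample_phantom: could not place source ", i, " after ",
           max_tries, " tries; relax the ranges")
  }
  phantom_spec(sources, fov, seed)
}

restore_rng <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old_seed, envir = globalenv())
  invisible(NULL)
}

#' Rasterize a phantom onto an image grid
#'
#' Evaluates the summed paraboloid profiles at each pixel centre.
#'
#' @param spec a [phantom_spec].
#' @param coords an image coordinate system from [make_image_coords()].
#' @return An [image_frame] (non-negative everywhere).
#' @export
rasterize <- function(spec, coords) {
  stopifnot(inherits(spec, "phantom_spec"))
  ci <- image_coord_info(coords)
  px <- matrix(0, nrow = ci$ny, ncol = ci$nx)
  X <- matrix(ci$x, nrow = ci$ny, ncol = ci$nx, byrow = TRUE)
  Y <- matrix(ci$y, nrow = ci$ny, ncol = ci$nx)
  for (s in spec$sources) {
    r2 <- (X - s$center[1])^2 + (Y - s$center[2])^2
    v <- s$amplitude * (1 - r2 / s$radius^2)
    px <- px + pmax(v, 0)
  }
  image_frame(px, spec$fov)
}

#' Exact circular line integral of a paraboloid absorber
#'
#' Integrates the paraboloid profile along the circle of radius `rho`
#' centred on a detector position: the building block of the analytical
#' point-detector signal. Closed form; zero when the circle misses the
#' source disc, full-circle value when the circle lies inside it.
#'
#' @param source a [paraboloid_source].
#' @param detector_pos numeric (x, y) detector position in metres.
#' @param rho circle radius (m, >= 0); vectorised.
#' @return Numeric vector of integrals (amplitude x metres).
#' @export
arc_integral <- function(source, detector_pos, rho) {
  stopifnot(inherits(source, "paraboloid_source"))
  rho <- as.numeric(rho)
  if (any(rho < 0)) stop("rho must be >= 0")
  A <- source$amplitude; R <- source$radius
  D <- sqrt(sum((source$center - as.numeric(detector_pos))^2))
  out <- numeric(length(rho))
  pos <- rho > 0
  if (D == 0) {
    inside <- pos & rho <= R
    out[inside] <- 2 * pi * rho[inside] * A * (1 - rho[inside]^2 / R^2)
    return(out)
  }
  r <- rho[pos]
  u <- pmin(pmax((D^2 + r^2 - R^2) / (2 * D * r), -1), 1)
  phi <- acos(u)
  out[pos] <- A * r * (2 * phi * (1 - (D^2 + r^2) / R^2) +
                         (4 * D * r / R^2) * sin(phi))
  out
}

# d/drho of arc_integral. The terms multiplying d(phi_max)/drho vanish
# because the integrand is zero at the arc end points, so this closed form
# holds at every radius, including the tangency radii |D - R| and D + R
# (where it tends continuously to 0 from inside).
arc_integral_deriv <- function(source, detector_pos, rho) {
  A <- source$amplitude; R <- source$radius
  D <- sqrt(sum((source$center - as.numeric(detector_pos))^2))
  rho <- as.numeric(rho)
  out <- numeric(length(rho))
  if (D == 0) {
    inside <- rho <= R
    out[inside] <- 2 * pi * A * (1 - 3 * rho[inside]^2 / R^2)
    return(out)
  }
  pos <- rho > 0
  r <- rho[pos]
  u <- pmin(pmax((D^2 + r^2 - R^2) / (2 * D * r), -1), 1)
  phi <- acos(u)
  out[pos] <- A * (2 * phi * (1 - (D^2 + 3 * r^2) / R^2) +
                     (8 * D * r / R^2) * sin(phi))
  # rho -> 0 limit: 2 pi * p0 at the detector location
  if (any(!pos) && D < R) out[!pos] <- 2 * pi * A * (1 - D^2 / R^2)
  out
}

#' Analytical point-detector signal of a phantom
#'
#' The ideal pressure trace at each detector,
#' `s_d(t) = 1/(2 pi v_s) * d/dt [ sum_sources arc_integral(., r_d, v_s t) ]`,
#' evaluated by exact differentiation of the closed-form arc integrals.
#' Linear in the source amplitudes; an empty phantom yields zeros.
#'
#' @param spec a [phantom_spec].
#' @param geometry a [detector_geometry].
#' @param time_axis uniform numeric time axis (s).
#' @param wavelength,laser_energy,timestamp,frame_index frame metadata.
#' @return An [acoustic_frame].
#' @export
analytical_signal <- function(spec, geometry, time_axis,
                              wavelength = NA_real_, laser_energy = 1,
                              timestamp = 0, frame_index = 0L) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(geometry, "detector_geometry"))
  check_uniform_time(time_axis)
  vs <- geometry$speed_of_sound
  rho <- vs * time_axis
  nd <- nrow(geometry$positions)
  S <- matrix(0, nrow = nd, ncol = length(time_axis))
  for (d in seq_len(nd)) {
    pd <- geometry$positions[d, ]
    acc <- numeric(length(rho))
    for (src in spec$sources)
      acc <- acc + arc_integral_deriv(src, pd, pmax(rho, 0))
    # d/dt = v_s d/drho; overall scale 1/(2 pi v_s)
    S[d, ] <- acc / (2 * pi)
  }
  acoustic_frame(S, time_axis, wavelength = wavelength,
                 laser_energy = laser_energy, timestamp = timestamp,
                 frame_index = frame_index)
}

#' Default uniform time axis covering the field of view
#'
#' Chooses sample times so the wavefront radius `v_s * t` sweeps from just
#' inside the closest FOV corner to just beyond the farthest one, for a
#' centred square FOV.
#'
#' @param geometry a [detector_geometry].
#' @param fov field-of-view width (m).
#' @param n number of samples.
#' @param margin fractional radial margin beyond the FOV corners.
#' @return Numeric time axis (s).
#' @export
default_time_axis <- function(geometry, fov, n = 512L, margin = 0.05) {
  vs <- geometry$speed_of_sound
  rdet <- sqrt(rowSums(geometry$positions^2))
  rcorner <- fov * sqrt(2) / 2
  r0 <- max(min(rdet) - rcorner, 0) * (1 - margin)
  r1 <- (max(rdet) + rcorner) * (1 + margin)
  seq(r0, r1, length.out = n) / vs
}
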