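#' Detector geometry
#'
#' Positions and weights of the (point) transducers of a tomographic array,
#' together with the assumed homogeneous speed of sound.
#'
#' @param positions numeric matrix [n_detectors x 2] of (x, y) positions in
#'   metres; at least 3 distinct rows.
#' @param speed_of_sound speed of sound in m/s (> 0).
#' @param weights per-detector non-negative weights (solid-angle analogue);
#'   default 1 for all.
#' @return A `detector_geometry` object.
#' @export
detector_geometry <- function(positions, speed_of_sound = 1500,
                              weights = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 2L) stop("detector positions must be n x 2")
  if (nrow(positions) < 3L) stop("at least 3 detectors are required")
  if (anyNA(positions) || any(!is.finite(positions)))
    stop("detector positions must be finite")
  if (anyDuplicated(as.data.frame(positions)))
    stop("detector positions must be distinct")
  if (!is.numeric(speed_of_sound) || speed_of_sound <= 0)
    stop("speed_of_sound must be > 0")
  if (is.null(weights)) weights <- rep(1, nrow(positions))
  weights <- as.numeric(weights)
  if (length(weights) != nrow(positions) || any(weights < 0))
    stop("weights must be non-negative, one per detector")
  structure(list(positions = positions, weights = weights,
                 speed_of_sound = as.numeric(speed_of_sound)),
            class = "detector_geometry")
}

#' Circular-arc detector array
#'
#' Convenience constructor placing `n` point detectors uniformly on a circular
#' arc centred on the origin. The package default (128 detectors on a 270
#' degree arc of radius 40 mm, 1500 m/s) is a generic small-animal tomograph
#' layout; every parameter is configurable.
#'
#' @param n number of detectors.
#' @param radius arc radius in metres.
#' @param arc_deg angular coverage of the arc in degrees (360 = full ring).
#' @param speed_of_sound m/s.
#' @return A `detector_geometry`.
#' @export
arc_detector_geometry <- function(n = 128, radius = 0.040, arc_deg = 270,
                                  speed_of_sound = 1500) {
  arc <- arc_deg * pi / 180
  # symmetric about the +y axis; full ring avoids duplicating the seam point
  if (arc_deg >= 360) {
    th <- pi / 2 + seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  } else {
    th <- pi / 2 + seq(-arc / 2, arc / 2, length.out = n)
  }
  detector_geometry(cbind(radius * cos(th), radius * sin(th)),
                    speed_of_sound = speed_of_sound)
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat("<detector_geometry> ", nrow(x$positions), " detectors, v_s = ",
      x$speed_of_sound, " m/s\n", sep = "")
  invisible(x)
}

#' Acoustic data frame
#'
#' One laser shot's pressure record: a transducer-by-time sample matrix with
#' its (uniform) time axis and acquisition metadata.
#'
#' @param samples numeric matrix [n_transducers x n_times] (arbitrary
#'   pressure units).
#' @param time_axis numeric vector of sample times in seconds, uniformly
#'   spaced with dt > 0.
#' @param wavelength illumination wavelength in nm (or NA).
#' @param laser_energy per-shot laser energy, arbitrary units > 0.
#' @param timestamp acquisition time in seconds.
#' @param frame_index 0-based frame index within its dataset.
#' @return An `acoustic_frame`.
#' @export
acoustic_frame <- function(samples, time_axis, wavelength = NA_real_,
                           laser_energy = 1, timestamp = 0,
                           frame_index = 0L) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  time_axis <- as.numeric(time_axis)
  if (ncol(samples) != length(time_axis))
    stop("samples must have one column per time sample")
  check_uniform_time(time_axis)
  if (!is.na(laser_energy) && laser_energy <= 0)
    stop("laser_energy must be > 0")
  structure(list(samples = samples, time_axis = time_axis,
                 wavelength = as.numeric(wavelength),
                 laser_energy = as.numeric(laser_energy),
                 timestamp = as.numeric(timestamp),
                 frame_index = as.integer(frame_index)),
            class = "acoustic_frame")
}

check_uniform_time <- function(time_axis) {
  if (length(time_axis) < 2L) stop("time axis needs >= 2 samples")
  dt <- diff(time_axis)
  if (any(dt <= 0)) stop("time axis must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9 * mean(dt))
    stop("time axis must be uniformly spaced")
  invisible(mean(dt))
}

frame_dt <- function(frame) {
  (frame$time_axis[length(frame$time_axis)] - frame$time_axis[1L]) /
    (length(frame$time_axis) - 1L)
}

#' @export
print.acoustic_frame <- function(x, ...) {
  cat("<acoustic_frame> ", nrow(x$samples), " x ", ncol(x$samples),
      " samples, lambda = ", x$wavelength, " nm, t = ", x$timestamp,
      " s\n", sep = "")
  invisible(x)
}

#' Reconstructed image frame
#'
#' A single-wavelength reconstructed image on a uniform pixel-center grid
#' centred on the array centre. `pixels` is stored `[ny x nx]` with row index
#' increasing along +y and column index along +x.
#'
#' @param pixels numeric matrix [ny x nx].
#' @param fov field-of-view (width, height) in metres; a scalar is recycled.
#' @param wavelength nm (optional).
#' @param timestamp seconds.
#' @return An `image_frame`.
#' @export
image_frame <- function(pixels, fov, wavelength = NA_real_, timestamp = 0) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("image must be at least 2 x 2")
  fov <- as.numeric(fov)
  if (length(fov) == 1L) fov <- c(fov, fov)
  if (any(fov <= 0)) stop("fov must be > 0")
  structure(list(pixels = pixels, fov = fov,
                 wavelength = as.numeric(wavelength),
                 timestamp = as.numeric(timestamp)),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat("<image_frame> ", nrow(x$pixels), " x ", ncol(x$pixels),
      " px, fov = ", x$fov[1], " m\n", sep = "")
  invisible(x)
}

#' Multispectral image frame
#'
#' A per-time estimate of the full spectral image stack.
#'
#' @param stack numeric array [n_lambda x ny x nx].
#' @param wavelengths strictly increasing nm vector of length n_lambda.
#' @param timestamp seconds.
#' @return A `multispectral_frame`.
#' @export
multispectral_frame <- function(stack, wavelengths, timestamp = 0) {
  stack <- as.array(stack)
  if (length(dim(stack)) != 3L) stop("stack must be [n_lambda x ny x nx]")
  wavelengths <- as.numeric(wavelengths)
  if (dim(stack)[1L] != length(wavelengths))
    stop("stack first dimension must match wavelengths")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(stack = stack, wavelengths = wavelengths,
                 timestamp = as.numeric(timestamp)),
            class = "multispectral_frame")
}

#' Unmixed endmember-concentration frame
#'
#' Per-endmember concentration maps plus (optionally) an oxygen-saturation
#' map. Concentrations from the constrained path are non-negative and the
#' SO2 map lies in [0, 1] wherever total hemoglobin is positive; the
#' unconstrained (pseudoinverse) path may violate both, which downstream
#' metrics flag rather than hide.
#'
#' @param concentrations numeric array [n_endmembers x ny x nx].
#' @param endmember_names character vector of endmember names.
#' @param so2 optional [ny x nx] oxygen-saturation matrix (NA where
#'   undefined).
#' @param timestamp seconds.
#' @return An `unmixed_frame`.
#' @export
unmixed_frame <- function(concentrations, endmember_names, so2 = NULL,
                          timestamp = 0) {
  concentrations <- as.array(concentrations)
  if (length(dim(concentrations)) != 3L)
    stop("concentrations must be [n_endmembers x ny x nx]")
  if (dim(concentrations)[1L] != length(endmember_names))
    stop("one name per endmember is required")
  structure(list(concentrations = concentrations,
                 endmember_names = as.character(endmember_names),
                 so2 = so2, timestamp = as.numeric(timestamp)),
            class = "unmixed_frame")
}
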