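#' Dynamic multispectral gas-challenge specification
#'
#' Describes a synthetic dynamic acquisition emulating a small-animal gas
#' challenge: a tissue map of total hemoglobin whose oxygen saturation
#' relaxes mono-exponentially toward the plateau dictated by a rectangular
#' inhaled-O2 waveform, imaged by cycling through a wavelength set (with
#' optional per-wavelength oversampling) at a fixed frame period.
#'
#' The defaults define the package's reference synthetic study: 6
#' wavelengths (715-850 nm) cycled 6 times at one frame per 30 s
#' (36 frames, 18 min), oxygen on over the middle third of the record
#' (6 min air / 6 min O2 / 6 min air), a 20 s transition time constant --
#' so each phase spans many transition constants and the saturation
#' plateaus, as in a real breathing challenge -- saturation plateaus 0.6
#' (air) and 0.9 (O2), and additive white noise at a sinogram SNR of 10.
#' Only the frame cadence is compressed relative to a real acquisition;
#' the physiological time constants are not.
#'
#' @param hb_tot_map [ny x nx] non-negative total-hemoglobin map (a.u.);
#'   NULL for the built-in two-blob tissue phantom.
#' @param so2_air,so2_o2 saturation plateaus while breathing air / oxygen.
#' @param o2_window (t_on, t_off) seconds of the oxygen phase.
#' @param transition_rate mono-exponential relaxation rate k (1/s).
#' @param spectra an [endmember_spectra]; default the shipped hemoglobin
#'   pair at the acquisition wavelengths.
#' @param wavelength_cycle wavelengths visited per cycle (nm).
#' @param oversampling consecutive repeats of each wavelength (not
#'   averaged).
#' @param frame_period seconds between laser shots.
#' @param n_cycles number of full wavelength cycles.
#' @param snr sinogram signal-to-noise ratio (RMS of the first clean frame
#'   over the noise SD); ignored when `noise_sd` is given.
#' @param noise_sd absolute noise SD; NULL to derive from `snr`.
#' @param seed RNG seed for the noise.
#' @return A `dynamic_spectral_spec`.
#' @export
dynamic_spectral_spec <- function(hb_tot_map = NULL, so2_air = 0.6,
                                  so2_o2 = 0.9, o2_window = c(360, 720),
                                  transition_rate = 0.05,
                                  spectra = NULL,
                                  wavelength_cycle = c(715, 730, 760, 800,
                                                       830, 850),
                                  oversampling = 1L, frame_period = 30,
                                  n_cycles = 6L, snr = 10,
                                  noise_sd = NULL, seed = 1L) {
  if (is.null(spectra)) spectra <- hemoglobin_spectra(wavelength_cycle)
  if (!all(wavelength_cycle %in% spectra$wavelengths))
    stop("wavelength cycle contains wavelengths missing from the spectra")
  if (!is.null(hb_tot_map) && any(hb_tot_map < 0))
    stop("hb_tot_map must be non-negative")
  stopifnot(so2_air >= 0, so2_air <= 1, so2_o2 >= 0, so2_o2 <= 1,
            transition_rate > 0, frame_period > 0,
            oversampling >= 1L, n_cycles >= 1L)
  structure(list(hb_tot_map = hb_tot_map, so2_air = so2_air,
                 so2_o2 = so2_o2, o2_window = as.numeric(o2_window),
                 transition_rate = transition_rate, spectra = spectra,
                 wavelength_cycle = as.numeric(wavelength_cycle),
                 oversampling = as.integer(oversampling),
                 frame_period = frame_period,
                 n_cycles = as.integer(n_cycles),
                 snr = snr, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "dynamic_spectral_spec")
}

#' Rectangular inhaled-O2 reference waveform
#'
#' @param times sample times (s).
#' @param o2_window (t_on, t_off) of the oxygen phase.
#' @return 0/1 vector.
#' @export
gas_waveform <- function(times, o2_window = c(360, 720)) {
  as.numeric(times >= o2_window[1L] & times < o2_window[2L])
}

#' Analytic saturation time course under a rectangular O2 waveform
#'
#' The saturation relaxes as `dS/dt = k (S_target(t) - S)` with
#' `S_target` switching between the air and oxygen plateaus; the closed
#' form is evaluated phase by phase assuming equilibration at the air
#' plateau before the record starts.
#'
#' @param times sample times (s, non-negative, increasing).
#' @param o2_window (t_on, t_off).
#' @param rate relaxation rate k (1/s).
#' @param so2_air,so2_o2 plateaus.
#' @return Numeric saturation values in [0, 1].
#' @export
so2_profile <- function(times, o2_window = c(360, 720), rate = 0.05,
                        so2_air = 0.6, so2_o2 = 0.9) {
  t_on <- o2_window[1L]; t_off <- o2_window[2L]
  s_on <- so2_air  # value entering the O2 phase
  s_off <- so2_o2 + (s_on - so2_o2) * exp(-rate * (t_off - t_on))
  out <- numeric(length(times))
  for (i in seq_along(times)) {
    t <- times[i]
    out[i] <- if (t < t_on) {
      so2_air
    } else if (t < t_off) {
      so2_o2 + (s_on - so2_o2) * exp(-rate * (t - t_on))
    } else {
      so2_air + (s_off - so2_air) * exp(-rate * (t - t_off))
    }
  }
  out
}

# Built-in tissue map: a broad background disc plus two brighter blobs,
# all smooth (parabolic profiles) so rasterization is resolution-stable.
default_tissue_map <- function(coords) {
  ci <- image_coord_info(coords)
  X <- matrix(ci$x, ci$ny, ci$nx, byrow = TRUE)
  Y <- matrix(ci$y, ci$ny, ci$nx)
  fov <- ci$fov
  blob <- function(cx, cy, R, A) {
    v <- A * (1 - ((X - cx)^2 + (Y - cy)^2) / R^2)
    pmax(v, 0)
  }
  blob(0, 0, 0.38 * fov, 1) +
    blob(0.12 * fov, 0.10 * fov, 0.10 * fov, 1.5) +
    blob(-0.15 * fov, -0.08 * fov, 0.08 * fov, 1.0)
}

#' Simulate a dynamic multispectral dataset
#'
#' For each laser shot, the absorption image
#' `mu_a(r, lambda) = sum_i C_i(r, t) eps_i(lambda)` is forward-projected
#' through an exact arc-length (CDMMI) model and i.i.d. Gaussian noise is
#' added. Ground truth (tissue map, per-frame saturation, reference
#' waveform, frame times) is stored alongside the data.
#'
#' @param dyn a [dynamic_spectral_spec()].
#' @param geometry a [detector_geometry].
#' @param coords image grid from [make_image_coords()].
#' @param path output dataset directory.
#' @param time_axis acoustic time axis; NULL for
#'   [default_time_axis()] with 512 samples.
#' @return The opened `dataset_store`.
#' @export
simulate_dynamic_dataset <- function(dyn, geometry, coords, path,
                                     time_axis = NULL) {
  stopifnot(inherits(dyn, "dynamic_spectral_spec"))
  ci <- image_coord_info(coords)
  if (is.null(time_axis))
    time_axis <- default_time_axis(geometry, ci$fov, n = 512L)
  hb_tot <- if (is.null(dyn$hb_tot_map)) default_tissue_map(coords)
            else as.matrix(dyn$hb_tot_map)
  if (!all(dim(hb_tot) == c(ci$ny, ci$nx)))
    stop("hb_tot_map does not match the image grid")

  wl_seq <- rep(rep(dyn$wavelength_cycle, each = dyn$oversampling),
                dyn$n_cycles)
  n_frames <- length(wl_seq)
  times <- (seq_len(n_frames) - 1L) * dyn$frame_period
  s_t <- so2_profile(times, dyn$o2_window, dyn$transition_rate,
                     dyn$so2_air, dyn$so2_o2)
  w_t <- gas_waveform(times, dyn$o2_window)

  model <- cached_model("cdmmi", coords, geometry, time_axis)
  E <- dyn$spectra$E
  wl_idx <- match(wl_seq, dyn$spectra$wavelengths)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(restore_rng(old_seed))
  set.seed(dyn$seed)

  frames <- vector("list", n_frames)
  noise_sd <- dyn$noise_sd
  for (k in seq_len(n_frames)) {
    conc <- c(s_t[k], 1 - s_t[k])   # (HbO2, Hb) fractions of hb_tot
    names(conc) <- c("HbO2", "Hb")
    conc <- conc[dyn$spectra$names]
    mua <- hb_tot * sum(conc * E[wl_idx[k], ])
    sino <- model_apply(model, mua)
    if (is.null(noise_sd))
      noise_sd <- sqrt(mean(sino^2)) / dyn$snr
    if (noise_sd > 0)
      sino <- sino + matrix(stats::rnorm(length(sino), sd = noise_sd),
                            nrow(sino), ncol(sino))
    frames[[k]] <- acoustic_frame(sino, time_axis, wavelength = wl_seq[k],
                                  laser_energy = 1, timestamp = times[k],
                                  frame_index = k - 1L)
  }
  truth <- list(hb_tot = hb_tot, so2 = s_t, waveform = w_t, times = times)
  write_dataset(frames, geometry, path, truth = truth)
  open_dataset(path)
}
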