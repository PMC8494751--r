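#' Pipeline configuration
#'
#' Pipelines are driven by a YAML (or JSON) configuration; every field has
#' a default so an empty file is a valid configuration, and the resolved
#' configuration (all defaults materialized) is recorded in the provenance
#' file of each run. Unknown keys are rejected rather than ignored so that
#' typos cannot silently change an analysis.
#'
#' @name pipeline-config
NULL

default_config <- function() {
  list(
    input = NULL,
    output = NULL,
    n_workers = 1L,
    seed = 1L,
    precondition = list(
      energy = TRUE, energy_ref = 1, mean = TRUE,
      wiener = NULL,
      bandpass = list(f_lo_hz = 5e4, f_hi_hz = 7e6, order = 4L),
      water = NULL),
    recon = list(method = "lsqr", model_kind = "dimmi",
                 resolution = 50L, fov = 0.025,
                 max_iterations = 30L, tolerance = 1e-6, lambda = 0),
    spectral = list(filter = "sliding", tracking_index = 2),
    unmix = list(method = "pinv", spectra = NULL),
    metrics = list(negative_indicator = TRUE, correlation = TRUE))
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user))
    stop("config: '", path, "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("config: unknown key(s) ",
         paste0("'", path, if (nzchar(path)) ".", unknown, "'",
                collapse = ", "))
  for (k in names(user)) {
    kp <- if (nzchar(path)) paste0(path, ".", k) else k
    if (is.list(defaults[[k]]) && !is.null(user[[k]]) &&
        is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], kp)
    } else {
      defaults[k] <- user[k]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!is.null(cfg$precondition$bandpass)) {
      bp <- cfg$precondition$bandpass
      if (bp$f_hi_hz <= bp$f_lo_hz)
        stop("config: 'precondition.bandpass.f_hi_hz' must exceed ",
             "'precondition.bandpass.f_lo_hz'")
    }
    if (!cfg$recon$method %in% c("lsqr", "nnapcg", "bp"))
      stop("config: 'recon.method' must be lsqr, nnapcg or bp")
    if (!cfg$recon$model_kind %in% c("dimmi", "cdmmi"))
      stop("config: 'recon.model_kind' must be dimmi or cdmmi")
    if (!cfg$spectral$filter %in% c("sliding", "alpha", "alphabeta"))
      stop("config: 'spectral.filter' must be sliding, alpha or alphabeta")
    if (!cfg$unmix$method %in% c("pinv", "nonneg"))
      stop("config: 'unmix.method' must be pinv or nonneg")
    if (cfg$recon$resolution < 2)
      stop("config: 'recon.resolution' must be >= 2")
    if (cfg$n_workers < 1) stop("config: 'n_workers' must be >= 1")
  })
  cfg
}

#' Load and resolve a pipeline configuration
#'
#' @param path YAML/JSON file; an empty file yields the full default
#'   configuration.
#' @return A validated `pipeline_config` with every default materialized.
#' @export
load_config <- function(path) {
  user <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- validate_config(merge_config(default_config(), user))
  structure(cfg, class = "pipeline_config")
}

#' Extract the pipeline context from a dataset store
#'
#' Loads geometry, time axis, wavelength set and frame schedule into the
#' single metadata object every stage consumes.
#'
#' @param store a `dataset_store`.
#' @return A `pipeline_context`.
#' @export
populate_metadata <- function(store) {
  stopifnot(inherits(store, "dataset_store"))
  wls <- sort(unique(store$acquisition$wavelength_nm))
  tax <- store$t0 + store$dt * (seq_len(store$n_samples) - 1L)
  structure(list(geometry = store$geometry, time_axis = tax,
                 wavelengths = wls,
                 n_wavelengths = length(wls),
                 schedule = store$acquisition,
                 n_frames = store$n_frames),
            class = "pipeline_context")
}

config_precondition_settings <- function(pc) {
  wiener <- NULL
  if (!is.null(pc$wiener)) {
    ker <- pc$wiener$kernel
    if (!is.null(ker))
      wiener <- list(ir = impulse_response(as.numeric(ker)),
                     nsr = if (is.null(pc$wiener$nsr)) 0.1 else pc$wiener$nsr)
  }
  bandpass <- NULL
  if (!is.null(pc$bandpass))
    bandpass <- list(f_lo = pc$bandpass$f_lo_hz, f_hi = pc$bandpass$f_hi_hz,
                     order = if (is.null(pc$bandpass$order)) 4L
                             else pc$bandpass$order)
  water <- if (is.null(pc$water)) NULL else list(path_cm = pc$water$path_cm)
  precondition_settings(energy = isTRUE(pc$energy),
                        energy_ref = pc$energy_ref,
                        mean = isTRUE(pc$mean),
                        wiener = wiener, bandpass = bandpass, water = water)
}

write_array_bin <- function(a, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(as.array(a)), con, size = 8L, endian = "little")
  invisible(path)
}

#' Run the full processing pipeline
#'
#' Executes load, precondition, reconstruct, multispectral filter, unmix
#' and metrics on a dataset store. Stateless stages (precondition +
#' reconstruction, unmixing) are parallelized by static frame partitioning
#' and are bit-identical for any worker count; the state-carrying Kalata
#' filter always runs single-threaded in timestamp order. A provenance
#' record (resolved config, package version, input content hash, per-stage
#' wall clock, seeds) is written before the output arrays.
#'
#' @param config a `pipeline_config`, or a path to one.
#' @param store optional already-open `dataset_store` (otherwise
#'   `config$input` is opened).
#' @return Invisibly, a list with `images`, `multispectral`, `unmixed`,
#'   `metrics`, `provenance` and `output_dir`.
#' @export
run_pipeline <- function(config, store = NULL) {
  if (!inherits(config, "pipeline_config")) config <- load_config(config)
  if (is.null(store)) {
    if (is.null(config$input)) stop("config: 'input' path is required")
    store <- open_dataset(config$input)
  }
  ctx <- populate_metadata(store)
  if (ctx$n_wavelengths < 2L &&
      (config$spectral$filter != "sliding" ||
         !is.null(config$unmix$spectra)))
    stop("spectral stages require a multispectral dataset ",
         "(single wavelength found)")
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]

  coords <- make_image_coords(config$recon$resolution, config$recon$fov)
  pre <- config_precondition_settings(config$precondition)

  t0 <- tic()
  method <- config$recon$method
  opts <- solver_options(
    max_iterations = if (method == "nnapcg")
      max(config$recon$max_iterations, 100L)
    else config$recon$max_iterations,
    tolerance = config$recon$tolerance,
    lambda = config$recon$lambda,
    regularizer = if (config$recon$lambda > 0) "tikhonov" else "none")
  model <- if (method == "bp") ctx$geometry
           else cached_model(config$recon$model_kind, coords,
                              ctx$geometry, ctx$time_axis)
  timings$model_build <- tic() - t0

  t0 <- tic()
  images <- reconstruct_dataset(store, model, method = method, opts = opts,
                                image_coords = coords,
                                n_workers = config$n_workers,
                                precondition = pre)
  timings$reconstruction <- tic() - t0

  ms <- NULL; unmixed <- NULL
  if (ctx$n_wavelengths >= 2L) {
    t0 <- tic()
    ms <- if (config$spectral$filter == "sliding") {
      sliding_window_assemble(images, ctx$wavelengths)
    } else {
      kalata_filter(images, ctx$wavelengths,
                    order = config$spectral$filter,
                    tracking_index = config$spectral$tracking_index)
    }
    timings$spectral_filter <- tic() - t0

    t0 <- tic()
    spectra <- if (is.null(config$unmix$spectra))
      hemoglobin_spectra(ctx$wavelengths)
    else hemoglobin_spectra(ctx$wavelengths, path = config$unmix$spectra)
    unmixed <- lapply(ms, unmix, spectra = spectra,
                      method = config$unmix$method)
    timings$unmix <- tic() - t0
  }

  t0 <- tic()
  metr <- list()
  if (isTRUE(config$metrics$negative_indicator) && !is.null(unmixed)) {
    for (i in seq_along(unmixed[[1L]]$endmember_names)) {
      nm <- unmixed[[1L]]$endmember_names[i]
      metr[[paste0("negative_", nm)]] <- negative_indicator_map(
        lapply(unmixed, function(u) u$concentrations[i, , ]))
    }
  }
  truth <- get_truth(store)
  if (isTRUE(config$metrics$correlation) && !is.null(unmixed) &&
      !is.null(truth$waveform)) {
    t_emit <- vapply(ms, `[[`, numeric(1), "timestamp")
    w <- stats::approx(truth$times, truth$waveform, xout = t_emit,
                       method = "constant", rule = 2)$y
    so2 <- as_stack(lapply(unmixed, `[[`, "so2"))
    so2[!is.finite(so2)] <- 0
    metr$so2_correlation <- correlation_map(so2, w)
  }
  timings$metrics <- tic() - t0

  prov <- list(
    package_version = as.character(utils::packageVersion("msotr")),
    resolved_config = unclass(config),
    input_path = store$path,
    input_hash = unname(tools::md5sum(file.path(store$path, "data.bin"))),
    seed = config$seed,
    n_workers = config$n_workers,
    stage_wall_clock_s = timings)

  out <- list(images = images, multispectral = ms, unmixed = unmixed,
              metrics = metr, provenance = prov,
              output_dir = config$output)
  if (!is.null(config$output)) {
    dir.create(config$output, recursive = TRUE, showWarnings = FALSE)
    # provenance first: the record must exist before outputs are finalized
    write_json_file(prov, file.path(config$output, "provenance.json"))
    write_array_bin(as_stack(images),
                    file.path(config$output, "images.bin"))
    if (!is.null(unmixed)) {
      write_array_bin(as_stack(lapply(unmixed, `[[`, "so2")),
                      file.path(config$output, "so2.bin"))
      conc <- lapply(seq_along(unmixed[[1L]]$endmember_names), function(i)
        as_stack(lapply(unmixed, function(u) u$concentrations[i, , ])))
      for (i in seq_along(conc))
        write_array_bin(conc[[i]],
                        file.path(config$output,
                                  paste0("conc_",
                                         unmixed[[1L]]$endmember_names[i],
                                         ".bin")))
    }
    if (length(metr)) {
      for (nm in names(metr))
        utils::write.csv(metr[[nm]],
                         file.path(config$output, paste0(nm, ".csv")),
                         row.names = FALSE)
    }
  }
  invisible(out)
}

#' Re-run a pipeline from its provenance record
#'
#' @param provenance_path path to a `provenance.json` written by
#'   [run_pipeline()].
#' @param store optional dataset store override.
#' @return As [run_pipeline()].
#' @export
run_pipeline_from_provenance <- function(provenance_path, store = NULL) {
  prov <- jsonlite::read_json(provenance_path, simplifyVector = TRUE)
  cfg <- prov$resolved_config
  # jsonlite reads empty lists/NULLs; normalise then re-validate
  run_pipeline(load_config(cfg), store = store)
}
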