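#' On-disk acoustic dataset store
#'
#' Datasets (many acoustic frames sharing one geometry and time axis) are
#' kept in a simple directory layout designed for lazy, seekable per-frame
#' access so that arbitrarily long acquisitions never need to be resident in
#' memory:
#'
#' \preformatted{
#'   store/
#'     meta.json         format_version, n_frames, n_transducers,
#'                       n_samples, dt_s, t0_s
#'     geometry.json     detector positions (m), weights, speed_of_sound
#'     acquisition.tsv   per-frame wavelength_nm, energy, timestamp_s
#'     data.bin          float64 little-endian, one frame after another,
#'                       each frame column-major [n_transducers x n_samples]
#'     truth/            optional ground-truth arrays (synthetic data only)
#' }
#'
#' `write_dataset()` followed by `open_dataset()` round-trips every field
#' bit-exactly, and `get_frame()` is pure: repeated reads of the same index
#' return identical arrays.
#'
#' @param frames non-empty list of [acoustic_frame]s sharing n_transducers
#'   and time axis.
#' @param geometry a [detector_geometry] consistent with the frames.
#' @param path directory to create (overwritten if it exists).
#' @param truth optional named list of numeric arrays of ground truth to
#'   store alongside the data (used by the synthetic generators).
#' @return `write_dataset()` returns `path` invisibly; `open_dataset()`
#'   returns a `dataset_store` with fields `n_frames`, `geometry`,
#'   `acquisition` (data.frame) and methods below.
#' @export
write_dataset <- function(frames, geometry, path, truth = NULL) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("frames must be a non-empty list of acoustic frames")
  ok <- vapply(frames, inherits, logical(1), "acoustic_frame")
  if (!all(ok)) stop("all frames must be acoustic_frame objects")
  nt <- nrow(frames[[1L]]$samples)
  ns <- ncol(frames[[1L]]$samples)
  tax <- frames[[1L]]$time_axis
  for (f in frames) {
    if (nrow(f$samples) != nt || ncol(f$samples) != ns)
      stop("inconsistent frame shapes: all frames must share dimensions")
    if (max(abs(f$time_axis - tax)) > 1e-12 * max(abs(tax), 1e-30))
      stop("inconsistent frame time axes")
  }
  if (nt != nrow(geometry$positions))
    stop("frame transducer count does not match geometry")
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  dir.create(path, recursive = TRUE)

  meta <- list(format_version = 1L, n_frames = length(frames),
               n_transducers = nt, n_samples = ns,
               dt_s = (tax[ns] - tax[1L]) / (ns - 1L), t0_s = tax[1L])
  write_json_file(meta, file.path(path, "meta.json"))
  geo <- list(positions = unname(geometry$positions),
              weights = geometry$weights,
              speed_of_sound = geometry$speed_of_sound)
  write_json_file(geo, file.path(path, "geometry.json"))

  acq <- data.frame(
    frame_index = seq_along(frames) - 1L,
    wavelength_nm = vapply(frames, `[[`, numeric(1), "wavelength"),
    energy = vapply(frames, `[[`, numeric(1), "laser_energy"),
    timestamp_s = vapply(frames, `[[`, numeric(1), "timestamp"))
  utils::write.table(acq, file.path(path, "acquisition.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  for (f in frames)
    writeBin(as.vector(f$samples), con, size = 8L, endian = "little")

  if (!is.null(truth)) {
    tdir <- file.path(path, "truth")
    dir.create(tdir)
    tmeta <- lapply(truth, function(a) dim(as.array(a)))
    write_json_file(tmeta, file.path(tdir, "truth.json"))
    for (nm in names(truth)) {
      tcon <- file(file.path(tdir, paste0(nm, ".bin")), "wb")
      writeBin(as.vector(as.array(truth[[nm]])), tcon, size = 8L,
               endian = "little")
      close(tcon)
    }
  }
  invisible(path)
}

write_json_file <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(txt, path)
}

#' @param path path to a dataset store directory.
#' @rdname write_dataset
#' @export
open_dataset <- function(path) {
  if (!dir.exists(path)) stop("dataset store not found: ", path)
  need <- c("meta.json", "geometry.json", "acquisition.tsv", "data.bin")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stop("dataset store format error: missing ", f)
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  for (k in c("n_frames", "n_transducers", "n_samples", "dt_s", "t0_s"))
    if (is.null(meta[[k]]))
      stop("dataset store format error: meta.json lacks '", k, "'")
  if (meta$dt_s <= 0)
    stop("dataset store validation error: non-positive dt")
  geo <- jsonlite::read_json(file.path(path, "geometry.json"),
                             simplifyVector = TRUE)
  if (is.null(geo$positions) || is.null(geo$speed_of_sound))
    stop("dataset store format error: geometry.json incomplete")
  geometry <- detector_geometry(geo$positions,
                                speed_of_sound = geo$speed_of_sound,
                                weights = geo$weights)
  acq <- utils::read.table(file.path(path, "acquisition.tsv"),
                           header = TRUE, sep = "\t")
  if (nrow(acq) != meta$n_frames)
    stop("dataset store validation error: acquisition table length")
  expect_bytes <- as.numeric(meta$n_frames) * meta$n_transducers *
    meta$n_samples * 8
  if (file.info(file.path(path, "data.bin"))$size != expect_bytes)
    stop("dataset store validation error: data.bin size mismatch")
  structure(list(path = path, n_frames = as.integer(meta$n_frames),
                 n_transducers = as.integer(meta$n_transducers),
                 n_samples = as.integer(meta$n_samples),
                 dt = meta$dt_s, t0 = meta$t0_s,
                 geometry = geometry, acquisition = acq),
            class = "dataset_store")
}

#' Read one frame from a dataset store
#'
#' Seeks directly to the frame's byte range; nothing else in the file is
#' touched, so access cost is independent of dataset length.
#'
#' @param store a `dataset_store` from [open_dataset()].
#' @param k 0-based frame index.
#' @return An [acoustic_frame].
#' @export
get_frame <- function(store, k) {
  stopifnot(inherits(store, "dataset_store"))
  k <- as.integer(k)
  if (is.na(k) || k < 0L || k >= store$n_frames)
    stop("frame index out of range: ", k)
  n <- store$n_transducers * store$n_samples
  con <- file(file.path(store$path, "data.bin"), "rb")
  on.exit(close(con))
  seek(con, where = as.numeric(k) * n * 8, origin = "start")
  v <- readBin(con, "double", n = n, size = 8L, endian = "little")
  tax <- store$t0 + store$dt * (seq_len(store$n_samples) - 1L)
  row <- store$acquisition[k + 1L, ]
  acoustic_frame(matrix(v, nrow = store$n_transducers), tax,
                 wavelength = row$wavelength_nm, laser_energy = row$energy,
                 timestamp = row$timestamp_s, frame_index = k)
}

#' Read stored ground-truth arrays from a synthetic dataset store
#'
#' @param store a `dataset_store`.
#' @return Named list of arrays, or NULL when the store carries no truth.
#' @export
get_truth <- function(store) {
  tdir <- file.path(store$path, "truth")
  if (!dir.exists(tdir)) return(NULL)
  dims <- jsonlite::read_json(file.path(tdir, "truth.json"),
                              simplifyVector = TRUE)
  out <- list()
  for (nm in names(dims)) {
    con <- file(file.path(tdir, paste0(nm, ".bin")), "rb")
    v <- readBin(con, "double", n = prod(dims[[nm]]), size = 8L,
                 endian = "little")
    close(con)
    out[[nm]] <- if (length(dims[[nm]]) > 1L) array(v, dim = dims[[nm]])
                 else v
  }
  out
}

#' @export
print.dataset_store <- function(x, ...) {
  cat("<dataset_store> ", x$n_frames, " frames, ", x$n_transducers,
      " transducers x ", x$n_samples, " samples, dt = ", x$dt, " s\n",
      sep = "")
  invisible(x)
}
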