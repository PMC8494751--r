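#' Endmember absorption spectra
#'
#' The mixing matrix of linear spectral unmixing: molar absorption
#' coefficients of each endmember at each acquisition wavelength. Columns
#' must be linearly independent (full column rank) for the mixing system to
#' be invertible.
#'
#' @param wavelengths nm vector (strictly increasing).
#' @param E numeric matrix [n_lambda x n_endmembers], non-negative.
#' @param names endmember names; default `c("HbO2", "Hb")`.
#' @return An `endmember_spectra`.
#' @export
endmember_spectra <- function(wavelengths, E, names = colnames(E)) {
  wavelengths <- as.numeric(wavelengths)
  E <- as.matrix(E)
  storage.mode(E) <- "double"
  if (nrow(E) != length(wavelengths))
    stop("one spectrum row per wavelength is required")
  if (any(E < 0)) stop("absorption coefficients must be >= 0")
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (is.null(names)) names <- paste0("endmember", seq_len(ncol(E)))
  if (qr(E)$rank < ncol(E))
    stop("endmember spectra are rank deficient (columns proportional)")
  structure(list(wavelengths = wavelengths, E = E,
                 names = as.character(names)),
            class = "endmember_spectra")
}

#' Shipped oxy-/deoxy-hemoglobin spectra
#'
#' Molar absorption coefficients of HbO2 and Hb over 700-900 nm at a 10-nm
#' grid, after the standard literature compilation of tabulated hemoglobin
#' extinction values (Prahl, Oregon Medical Laser Center); linearly
#' interpolated to the requested wavelengths. Users may override with their
#' own CSV (columns `wavelength_nm`, then one column per endmember).
#'
#' @param wavelengths nm vector to evaluate at (within 700-900 nm).
#' @param path optional CSV overriding the shipped table.
#' @return An [endmember_spectra] at the requested wavelengths.
#' @export
hemoglobin_spectra <- function(wavelengths = c(715, 730, 760, 800, 830, 850),
                               path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hemoglobin_spectra.csv",
                        package = "msotr", mustWork = TRUE)
  tab <- utils::read.csv(path)
  if (names(tab)[1L] != "wavelength_nm")
    stop("spectra CSV must start with a wavelength_nm column")
  wl <- tab$wavelength_nm
  if (min(wavelengths) < min(wl) || max(wavelengths) > max(wl))
    stop("requested wavelength outside the tabulated range")
  ems <- names(tab)[-1L]
  E <- vapply(ems, function(nm)
    stats::approx(wl, tab[[nm]], xout = sort(wavelengths))$y,
    numeric(length(wavelengths)))
  endmember_spectra(sort(wavelengths), E, names = ems)
}

#' Sliding-window multispectral assembly
#'
#' Turns a stream of single-wavelength image frames into full-spectrum
#' estimates: at each incoming frame, emit the stack formed by the most
#' recent frame of every wavelength. Nothing is emitted until every
#' wavelength has been seen once (warm-up); oversampled wavelengths always
#' contribute their latest repetition.
#'
#' @param stream list of [image_frame]s with `wavelength` set, in time order.
#' @param wavelengths the full wavelength set (nm).
#' @return List of [multispectral_frame]s, one per input frame after
#'   warm-up, timestamped by the incoming frame.
#' @export
sliding_window_assemble <- function(stream, wavelengths) {
  wavelengths <- sort(as.numeric(wavelengths))
  latest <- vector("list", length(wavelengths))
  out <- list()
  for (fr in stream) {
    k <- match(fr$wavelength, wavelengths)
    if (is.na(k))
      stop("frame wavelength ", fr$wavelength,
           " nm not in the declared set")
    latest[[k]] <- fr
    if (any(vapply(latest, is.null, logical(1)))) next
    ny <- nrow(fr$pixels); nx <- ncol(fr$pixels)
    stack <- array(0, dim = c(length(wavelengths), ny, nx))
    for (j in seq_along(wavelengths))
      stack[j, , ] <- latest[[j]]$pixels
    out[[length(out) + 1L]] <-
      multispectral_frame(stack, wavelengths, timestamp = fr$timestamp)
  }
  out
}

#' Kalata filter gains from the tracking index
#'
#' The tracking index `Lambda` is the ratio of process to measurement noise
#' scales over one sample period. For the alpha-beta filter the gains follow
#' Kalata's closed forms `r = (4 + Lambda - sqrt(8 Lambda + Lambda^2)) / 4`,
#' `alpha = 1 - r^2`, `beta = 2 (2 - alpha) - 4 sqrt(1 - alpha)`. For the
#' first-order (alpha) filter the steady-state Riccati relation
#' `alpha^2 / (1 - alpha) = Lambda` gives
#' `alpha = (-Lambda + sqrt(Lambda^2 + 4 Lambda)) / 2`.
#'
#' @param tracking_index Lambda > 0.
#' @param order `"alpha"` or `"alphabeta"`.
#' @return List with `alpha` (and `beta` for the alpha-beta filter).
#' @export
kalata_gains <- function(tracking_index, order = c("alpha", "alphabeta")) {
  order <- match.arg(order)
  L <- tracking_index
  if (!is.numeric(L) || L <= 0) stop("tracking_index must be > 0")
  if (order == "alpha") {
    alpha <- (-L + sqrt(L^2 + 4 * L)) / 2
    list(alpha = min(alpha, 1), beta = 0)
  } else {
    r <- (4 + L - sqrt(8 * L + L^2)) / 4
    alpha <- 1 - r^2
    beta <- 2 * (2 - alpha) - 4 * sqrt(1 - alpha)
    list(alpha = alpha, beta = beta)
  }
}

#' Kalata alpha / alpha-beta multispectral state filter
#'
#' Tracks a per-pixel, per-wavelength level (and, for the alpha-beta
#' variant, trend) through a stream of single-wavelength frames. Every
#' incoming frame advances the whole state by the frame interval (identity
#' for the alpha filter, `x <- x + v dt` for alpha-beta), then applies the
#' measurement update to the incoming frame's channel only. A full-stack
#' estimate is emitted for every frame once all wavelengths have been seen.
#'
#' The alpha filter assumes a static level, so it smooths strongly
#' (steady-state white-noise variance gain `alpha / (2 - alpha)`) but lags a
#' moving signal by `slope * dt * (1 - alpha) / alpha`; the alpha-beta
#' filter tracks ramps with vanishing steady-state lag at the cost of less
#' noise suppression.
#'
#' @param stream list of [image_frame]s with wavelength and non-decreasing
#'   timestamps.
#' @param wavelengths full wavelength set (nm).
#' @param order `"alpha"` or `"alphabeta"`.
#' @param tracking_index Kalata tracking index (> 0).
#' @return List of [multispectral_frame] estimates, one per frame after
#'   warm-up.
#' @export
kalata_filter <- function(stream, wavelengths,
                          order = c("alpha", "alphabeta"),
                          tracking_index = 2) {
  order <- match.arg(order)
  g <- kalata_gains(tracking_index, order)
  wavelengths <- sort(as.numeric(wavelengths))
  nw <- length(wavelengths)
  seen <- logical(nw)
  x <- NULL; v <- NULL
  last_t <- -Inf
  out <- list()
  for (fr in stream) {
    k <- match(fr$wavelength, wavelengths)
    if (is.na(k))
      stop("frame wavelength ", fr$wavelength,
           " nm not in the declared set")
    if (fr$timestamp < last_t)
      stop("kalata_filter: timestamps must be non-decreasing")
    if (is.null(x)) {
      ny <- nrow(fr$pixels); nx <- ncol(fr$pixels)
      x <- array(0, dim = c(nw, ny, nx))
      v <- array(0, dim = c(nw, ny, nx))
    }
    dt <- if (is.finite(last_t)) fr$timestamp - last_t else 0
    last_t <- fr$timestamp
    # time update (all channels predicted every frame)
    if (order == "alphabeta" && dt > 0) x <- x + v * dt
    # measurement update on the incoming channel
    if (!seen[k]) {
      x[k, , ] <- fr$pixels         # initialise from the first observation
      seen[k] <- TRUE
    } else {
      resid <- fr$pixels - x[k, , ]
      x[k, , ] <- x[k, , ] + g$alpha * resid
      if (order == "alphabeta" && dt > 0)
        v[k, , ] <- v[k, , ] + (g$beta / dt) * resid
    }
    if (all(seen))
      out[[length(out) + 1L]] <-
        multispectral_frame(x, wavelengths, timestamp = fr$timestamp)
  }
  out
}

# Vectorised non-negative least squares for the mixing system: minimises
# ||E C - Y||_F^2 over C >= 0 for all pixels at once (the problem is
# separable per pixel), by the same accelerated projected gradient scheme
# as the image solver.
nnls_mixing <- function(E, Y, max_iterations = 500L, tol = 1e-12) {
  L <- max(svd(E, nu = 0, nv = 0)$d)^2 * 1.01
  EtY <- crossprod(E, Y)
  EtE <- crossprod(E)
  C <- matrix(0, ncol(E), ncol(Y))
  Z <- C
  tk <- 1
  fv <- function(C) {
    R <- E %*% C - Y
    0.5 * sum(R * R)
  }
  fC <- fv(C)
  for (k in seq_len(max_iterations)) {
    G <- EtE %*% Z - EtY
    Cn <- pmax(Z - G / L, 0)
    fn <- fv(Cn)
    if (fn > fC) {
      G <- EtE %*% C - EtY
      Cn <- pmax(C - G / L, 0)
      fn <- fv(Cn)
      tk <- 1
      if (fn > fC) { Cn <- C; fn <- fC }
    }
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Z <- Cn + ((tk - 1) / tn) * (Cn - C)
    delta <- max(abs(Cn - C))
    C <- Cn; fC <- fn; tk <- tn
    if (delta <= tol * max(1, max(abs(C)))) break
  }
  C
}

#' Linear spectral unmixing
#'
#' Inverts the mixing model `I = E C` per pixel: either the unconstrained
#' pseudoinverse solution `C = E^+ I`, or non-negative least squares
#' (accelerated projected gradient, the same solver contract as the image
#' reconstruction) which guarantees `C >= 0`.
#'
#' @param ms a [multispectral_frame] whose wavelengths equal the spectra's.
#' @param spectra an [endmember_spectra].
#' @param method `"pinv"` or `"nonneg"`.
#' @return An [unmixed_frame] with an SO2 map attached when the endmembers
#'   include HbO2 and Hb.
#' @export
unmix <- function(ms, spectra, method = c("pinv", "nonneg")) {
  method <- match.arg(method)
  stopifnot(inherits(ms, "multispectral_frame"),
            inherits(spectra, "endmember_spectra"))
  if (length(ms$wavelengths) != length(spectra$wavelengths) ||
      max(abs(ms$wavelengths - spectra$wavelengths)) > 1e-9)
    stop("frame wavelengths do not match the endmember spectra")
  E <- spectra$E
  d <- dim(ms$stack)
  Y <- matrix(ms$stack, nrow = d[1L])   # [n_lambda x n_pixels]
  C <- if (method == "pinv") {
    sv <- svd(E)
    pos <- sv$d > max(sv$d) * 1e-12
    Einv <- sv$v[, pos, drop = FALSE] %*%
      ((1 / sv$d[pos]) * t(sv$u[, pos, drop = FALSE]))
    Einv %*% Y
  } else {
    nnls_mixing(E, Y)
  }
  conc <- array(C, dim = c(ncol(E), d[2L], d[3L]))
  uf <- unmixed_frame(conc, spectra$names, timestamp = ms$timestamp)
  if (all(c("HbO2", "Hb") %in% spectra$names)) uf <- compute_so2(uf)
  uf
}

#' Hemoglobin oxygen saturation map
#'
#' `SO2 = HbO2 / (HbO2 + Hb)`, NA-flagged wherever total hemoglobin is
#' zero. With non-negative inputs the result lies in [0, 1]; unconstrained
#' (pseudoinverse) concentrations may push it outside that range, which is
#' reported as attribute `n_out_of_range` rather than clipped.
#'
#' @param unmixed an [unmixed_frame] whose endmembers include `HbO2` and
#'   `Hb`.
#' @return The frame with its `so2` field filled in.
#' @export
compute_so2 <- function(unmixed) {
  stopifnot(inherits(unmixed, "unmixed_frame"))
  i_o <- match("HbO2", unmixed$endmember_names)
  i_d <- match("Hb", unmixed$endmember_names)
  if (is.na(i_o) || is.na(i_d))
    stop("endmembers must include HbO2 and Hb")
  hbo2 <- unmixed$concentrations[i_o, , ]
  hb <- unmixed$concentrations[i_d, , ]
  tot <- hbo2 + hb
  so2 <- hbo2 / tot
  so2[tot == 0] <- NA_real_
  unmixed$so2 <- so2
  attr(unmixed$so2, "n_out_of_range") <-
    sum(so2 < 0 | so2 > 1, na.rm = TRUE)
  unmixed
}
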