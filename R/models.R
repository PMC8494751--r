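#' Sparse forward models for 2D photoacoustic tomography
#'
#' A forward model maps a vectorised image to the stack of detector time
#' samples. In the 2D geometry used throughout this package the ideal
#' point-detector signal is the time derivative of the circular line
#' integral of the initial pressure, so each model is assembled as
#' `M = 1/(2 pi v_s) * D_t %*% W` where `W` approximates the arc integrals
#' (one row per detector/time pair, detector-major then time) and `D_t` is a
#' per-detector temporal finite-difference stencil.
#'
#' Two discretizations of `W` are provided:
#' \describe{
#'   \item{dIMMI}{curve-sampling: points are placed uniformly in angle along
#'     the in-FOV portion of each integration circle and spread onto the four
#'     surrounding pixel centres by bilinear interpolation. The extra
#'     sampling acts as an anti-aliasing filter at low image resolutions.}
#'   \item{CDMMI}{exact arc length: each matrix entry is the exact length of
#'     the integration circle inside one pixel cell, treating the image as
#'     piecewise constant per cell. Row sums equal the in-FOV arc length to
#'     machine precision.}
#' }
#'
#' @name forward-models
NULL

# Angles (sorted, in [0, 2pi)) at which the circle of radius rho centred at
# (cx, cy) crosses any of the vertical lines `xs` or horizontal lines `ys`.
circle_line_angles <- function(cx, cy, rho, xs, ys) {
  ux <- (xs - cx) / rho
  ux <- ux[abs(ux) < 1]
  uy <- (ys - cy) / rho
  uy <- uy[abs(uy) < 1]
  a <- acos(ux)           # in (0, pi)
  b <- asin(uy)           # in (-pi/2, pi/2)
  th <- c(a, -a, b, pi - b)
  th <- th %% (2 * pi)
  sort(unique(th))
}

point_in_rect <- function(px, py, xmin, xmax, ymin, ymax) {
  px >= xmin & px <= xmax & py >= ymin & py <= ymax
}

# Quick radial reject: range of distances from a detector to the FOV square.
detector_rho_range <- function(cx, cy, xmin, xmax, ymin, ymax) {
  dx <- pmax(c(xmin - cx, cx - xmax), 0)
  dy <- pmax(c(ymin - cy, cy - ymax), 0)
  dmin <- sqrt(max(dx)^2 + max(dy)^2)
  cxs <- c(xmin, xmax); cys <- c(ymin, ymax)
  dmax <- 0
  for (x in cxs) for (y in cys)
    dmax <- max(dmax, sqrt((x - cx)^2 + (y - cy)^2))
  c(dmin, dmax)
}

#' Curve-sampling (dIMMI) arc-weight matrix
#'
#' @param image_coords image grid from [make_image_coords()].
#' @param geometry a [detector_geometry].
#' @param time_axis uniform time axis (s).
#' @param n_curve_samples points sampled along each in-FOV arc (>= 8);
#'   default `2 * max(nx, ny)`.
#' @return A `dgCMatrix` [n_detectors*n_times x nx*ny]; row r = (d-1)*n_times + t.
#' @export
build_arc_weights_dimmi <- function(image_coords, geometry, time_axis,
                                    n_curve_samples = NULL) {
  ci <- image_coord_info(image_coords)
  if (is.null(n_curve_samples)) n_curve_samples <- 2L * max(ci$nx, ci$ny)
  if (n_curve_samples < 8L) stop("n_curve_samples must be >= 8")
  vs <- geometry$speed_of_sound
  nt <- length(time_axis)
  nd <- nrow(geometry$positions)
  xmin <- ci$x[1] - ci$hx / 2; xmax <- ci$x[ci$nx] + ci$hx / 2
  ymin <- ci$y[1] - ci$hy / 2; ymax <- ci$y[ci$ny] + ci$hy / 2
  rho_all <- vs * time_axis

  ti <- vector("list", nd * nt); tj <- ti; tx <- ti
  for (d in seq_len(nd)) {
    cx <- geometry$positions[d, 1]; cy <- geometry$positions[d, 2]
    rr <- detector_rho_range(cx, cy, xmin, xmax, ymin, ymax)
    for (t in seq_len(nt)) {
      rho <- rho_all[t]
      if (rho <= 0 || rho < rr[1] || rho > rr[2]) next
      th <- circle_line_angles(cx, cy, rho, c(xmin, xmax), c(ymin, ymax))
      if (length(th) == 0L) {
        if (!point_in_rect(cx + rho, cy, xmin, xmax, ymin, ymax)) next
        segs <- cbind(0, 2 * pi)
      } else {
        a0 <- th
        a1 <- c(th[-1L], th[1L] + 2 * pi)
        mid <- (a0 + a1) / 2
        keep <- point_in_rect(cx + rho * cos(mid), cy + rho * sin(mid),
                              xmin, xmax, ymin, ymax)
        if (!any(keep)) next
        segs <- cbind(a0[keep], a1[keep])
      }
      dth <- segs[, 2L] - segs[, 1L]
      total <- sum(dth)
      nk <- pmax(1L, round(n_curve_samples * dth / total))
      step <- dth / nk
      ang <- rep(segs[, 1L], nk) + (sequence(nk) - 0.5) * rep(step, nk)
      wts <- rep(rho * step, nk)
      px <- cx + rho * cos(ang); py <- cy + rho * sin(ang)
      # bilinear onto pixel centres, clamped to the centre hull
      gx <- pmin(pmax((px - ci$x[1]) / ci$hx + 1, 1), ci$nx)
      gy <- pmin(pmax((py - ci$y[1]) / ci$hy + 1, 1), ci$ny)
      i0 <- pmin(floor(gx), ci$nx - 1L); fx <- gx - i0
      j0 <- pmin(floor(gy), ci$ny - 1L); fy <- gy - j0
      cols <- c((i0 - 1L) * ci$ny + j0,
                (i0 - 1L) * ci$ny + j0 + 1L,
                i0 * ci$ny + j0,
                i0 * ci$ny + j0 + 1L)
      vals <- c(wts * (1 - fx) * (1 - fy),
                wts * (1 - fx) * fy,
                wts * fx * (1 - fy),
                wts * fx * fy)
      r <- (d - 1L) * nt + t
      ti[[r]] <- rep.int(r, length(cols))
      tj[[r]] <- cols
      tx[[r]] <- vals
    }
  }
  Matrix::sparseMatrix(i = unlist(ti, use.names = FALSE),
                       j = unlist(tj, use.names = FALSE),
                       x = unlist(tx, use.names = FALSE),
                       dims = c(nd * nt, ci$nx * ci$ny))
}

#' Exact arc-length (CDMMI) weight matrix
#'
#' @inheritParams build_arc_weights_dimmi
#' @return A `dgCMatrix` [n_detectors*n_times x nx*ny]; entry (r, p) is the
#'   exact length of the integration circle inside pixel p's cell.
#' @export
build_arc_weights_cdmmi <- function(image_coords, geometry, time_axis) {
  ci <- image_coord_info(image_coords)
  vs <- geometry$speed_of_sound
  nt <- length(time_axis)
  nd <- nrow(geometry$positions)
  xe <- c(ci$x - ci$hx / 2, ci$x[ci$nx] + ci$hx / 2)  # cell edges
  ye <- c(ci$y - ci$hy / 2, ci$y[ci$ny] + ci$hy / 2)
  xmin <- xe[1L]; xmax <- xe[length(xe)]
  ymin <- ye[1L]; ymax <- ye[length(ye)]
  rho_all <- vs * time_axis

  ti <- vector("list", nd * nt); tj <- ti; tx <- ti
  for (d in seq_len(nd)) {
    cx <- geometry$positions[d, 1]; cy <- geometry$positions[d, 2]
    rr <- detector_rho_range(cx, cy, xmin, xmax, ymin, ymax)
    for (t in seq_len(nt)) {
      rho <- rho_all[t]
      if (rho <= 0 || rho < rr[1] || rho > rr[2]) next
      th <- circle_line_angles(cx, cy, rho, xe, ye)
      if (length(th) == 0L) {
        # circle entirely within one cell (or entirely outside the FOV)
        px <- cx + rho; py <- cy
        if (!point_in_rect(px, py, xmin, xmax, ymin, ymax)) next
        ix <- min(ci$nx, 1L + floor((px - xmin) / ci$hx))
        iy <- min(ci$ny, 1L + floor((py - ymin) / ci$hy))
        r <- (d - 1L) * nt + t
        ti[[r]] <- r; tj[[r]] <- (ix - 1L) * ci$ny + iy
        tx[[r]] <- 2 * pi * rho
        next
      }
      a0 <- th
      a1 <- c(th[-1L], th[1L] + 2 * pi)
      mid <- (a0 + a1) / 2
      px <- cx + rho * cos(mid); py <- cy + rho * sin(mid)
      keep <- point_in_rect(px, py, xmin, xmax, ymin, ymax)
      if (!any(keep)) next
      ix <- pmin(ci$nx, 1L + floor((px[keep] - xmin) / ci$hx))
      iy <- pmin(ci$ny, 1L + floor((py[keep] - ymin) / ci$hy))
      lens <- rho * (a1[keep] - a0[keep])
      r <- (d - 1L) * nt + t
      ti[[r]] <- rep.int(r, length(lens))
      tj[[r]] <- (ix - 1L) * ci$ny + iy
      tx[[r]] <- lens
    }
  }
  Matrix::sparseMatrix(i = unlist(ti, use.names = FALSE),
                       j = unlist(tj, use.names = FALSE),
                       x = unlist(tx, use.names = FALSE),
                       dims = c(nd * nt, ci$nx * ci$ny))
}

# Sparse per-detector temporal derivative stencil (central differences in
# the interior, one-sided at the record ends), acting on detector-major
# stacked rows.
temporal_derivative_stencil <- function(n_detectors, n_times, dt) {
  if (n_times < 2L) stop("need >= 2 time samples")
  i <- integer(0); j <- integer(0); x <- numeric(0)
  # one detector block
  ii <- c(1L, 1L, rep(2:(n_times - 1L), each = 2L), n_times, n_times)
  jj <- c(1L, 2L,
          as.vector(rbind(1:(n_times - 2L), 3:n_times)),
          n_times - 1L, n_times)
  xx <- c(-1 / dt, 1 / dt,
          rep(c(-1 / (2 * dt), 1 / (2 * dt)), n_times - 2L),
          -1 / dt, 1 / dt)
  off <- rep((seq_len(n_detectors) - 1L) * n_times, each = length(ii))
  Matrix::sparseMatrix(i = rep(ii, n_detectors) + off,
                       j = rep(jj, n_detectors) + off,
                       x = rep(xx, n_detectors),
                       dims = c(n_detectors * n_times,
                                n_detectors * n_times))
}

#' Assemble a forward model
#'
#' Builds `M = 1/(2 pi v_s) * D_t %*% W` for the requested discretization.
#' Deterministic for fixed inputs.
#'
#' @param kind `"dimmi"` or `"cdmmi"`.
#' @inheritParams build_arc_weights_dimmi
#' @param params optional list; `n_curve_samples` (dIMMI only).
#' @return A `forward_model` with fields `matrix` (dgCMatrix), `kind`,
#'   `image_coords`, `geometry`, `time_axis`, `params`.
#' @export
assemble_model <- function(kind, image_coords, geometry, time_axis,
                           params = list()) {
  kind <- match.arg(kind, c("dimmi", "cdmmi"))
  dt <- check_uniform_time(time_axis)
  W <- if (kind == "dimmi") {
    build_arc_weights_dimmi(image_coords, geometry, time_axis,
                            n_curve_samples = params$n_curve_samples)
  } else {
    build_arc_weights_cdmmi(image_coords, geometry, time_axis)
  }
  nd <- nrow(geometry$positions)
  nt <- length(time_axis)
  D <- temporal_derivative_stencil(nd, nt, dt)
  M <- (D %*% W) / (2 * pi * geometry$speed_of_sound)
  structure(list(matrix = methods::as(M, "CsparseMatrix"), kind = kind,
                 image_coords = image_coords, geometry = geometry,
                 time_axis = time_axis,
                 params = utils::modifyList(
                   list(derivative_stencil = "central-1st-order-ends"),
                   params)),
            class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat("<forward_model:", x$kind, "> ", nrow(x$matrix), " x ",
      ncol(x$matrix), ", nnz = ", length(x$matrix@x), "\n", sep = "")
  invisible(x)
}

# sinogram matrix [nd x nt] <-> detector-major stacked vector
sino_to_vec <- function(samples) as.vector(t(samples))
vec_to_sino <- function(v, n_detectors, n_times) t(matrix(v, nrow = n_times))

image_to_vec <- function(pixels) as.vector(pixels)   # [ny x nx], y fastest
vec_to_image <- function(v, ny, nx) matrix(v, nrow = ny, ncol = nx)

#' Apply a forward model or its adjoint
#'
#' `model_apply()` maps an image to its sinogram; `model_adjoint()` maps a
#' sinogram back to image space with the exact transpose, so the discrete
#' inner-product identity `<Mx, y> == <x, M'y>` holds to round-off.
#'
#' @param model a `forward_model`.
#' @param image an [image_frame] or [ny x nx] matrix.
#' @param sinogram an [acoustic_frame] or [n_detectors x n_times] matrix.
#' @return `model_apply()`: numeric [n_detectors x n_times] matrix;
#'   `model_adjoint()`: numeric [ny x nx] matrix.
#' @export
model_apply <- function(model, image) {
  px <- if (inherits(image, "image_frame")) image$pixels else as.matrix(image)
  v <- image_to_vec(px)
  if (length(v) != ncol(model$matrix))
    stop("image size does not match model: expected ", ncol(model$matrix),
         " pixels, got ", length(v))
  out <- as.numeric(model$matrix %*% v)
  vec_to_sino(out, nrow(model$geometry$positions), length(model$time_axis))
}

.model_cache <- new.env(parent = emptyenv())

#' Session-cached model assembly
#'
#' Model matrices depend only on (kind, grid, geometry, time axis, params),
#' so repeated analyses over one acquisition geometry can share them; this
#' wrapper memoizes [assemble_model()] within the R session.
#'
#' @inheritParams assemble_model
#' @return A `forward_model` (possibly shared; treat as read-only).
#' @export
cached_model <- function(kind, image_coords, geometry, time_axis,
                         params = list()) {
  ci <- image_coord_info(image_coords)
  key <- paste(kind, ci$nx, ci$ny, signif(ci$fov, 12),
               nrow(geometry$positions),
               signif(geometry$speed_of_sound, 12),
               signif(sum(geometry$positions^2), 12),
               length(time_axis), signif(time_axis[1L], 12),
               signif(time_axis[length(time_axis)], 12),
               paste(names(params), unlist(params), collapse = "_"),
               sep = "|")
  if (is.null(.model_cache[[key]]))
    .model_cache[[key]] <- assemble_model(kind, image_coords, geometry,
                                          time_axis, params)
  .model_cache[[key]]
}

#' @rdname model_apply
#' @export
model_adjoint <- function(model, sinogram) {
  s <- if (inherits(sinogram, "acoustic_frame")) sinogram$samples
       else as.matrix(sinogram)
  v <- sino_to_vec(s)
  if (length(v) != nrow(model$matrix))
    stop("sinogram size does not match model: expected ", nrow(model$matrix),
         " samples, got ", length(v))
  ci <- image_coord_info(model$image_coords)
  out <- as.numeric(Matrix::crossprod(model$matrix, v))
  vec_to_image(out, ci$ny, ci$nx)
}
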