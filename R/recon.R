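#' Solver options
#'
#' @param max_iterations iteration cap (>= 0).
#' @param tolerance stopping tolerance on the relative residual.
#' @param lambda Tikhonov regularization weight (>= 0); 0 means pure least
#'   squares.
#' @param regularizer `"none"` or `"tikhonov"`.
#' @return A `solver_options` list.
#' @export
solver_options <- function(max_iterations = 50L, tolerance = 1e-6,
                           lambda = 0, regularizer = c("none", "tikhonov")) {
  regularizer <- match.arg(regularizer)
  if (max_iterations < 0) stop("max_iterations must be >= 0")
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (lambda < 0) stop("lambda must be >= 0")
  if (regularizer == "none") lambda <- 0
  list(max_iterations = as.integer(max_iterations),
       tolerance = tolerance, lambda = lambda, regularizer = regularizer)
}

recon_result <- function(model, x, residuals, converged) {
  ci <- image_coord_info(model$image_coords)
  structure(list(image = image_frame(vec_to_image(x, ci$ny, ci$nx),
                                     fov = ci$fov),
                 iterations = length(residuals),
                 relative_residual = residuals,
                 converged = converged),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  rr <- x$relative_residual
  cat("<recon_result> ", x$iterations, " iterations, r_rel = ",
      if (length(rr)) signif(rr[length(rr)], 4) else NA,
      ", converged = ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Unconstrained least-squares reconstruction (LSQR)
#'
#' Solves `min ||M I - d||_2` (optionally with Tikhonov damping
#' `sqrt(lambda) * ||I||`) by the Golub-Kahan bidiagonalization recurrence.
#' The tracked residual norm is non-increasing by construction; iteration
#' stops at `tolerance` on the relative residual or at `max_iterations`.
#'
#' @param model a `forward_model` from [assemble_model()].
#' @param sinogram an [acoustic_frame] or [n_detectors x n_times] matrix.
#' @param opts a [solver_options()] list.
#' @return A `recon_result` (image, iteration count, relative-residual
#'   trace, convergence flag).
#' @export
lsqr_solve <- function(model, sinogram, opts = solver_options()) {
  A <- model$matrix
  s <- if (inherits(sinogram, "acoustic_frame")) sinogram$samples
       else as.matrix(sinogram)
  b <- sino_to_vec(s)
  if (length(b) != nrow(A)) stop("sinogram does not match model dimensions")
  n <- ncol(A)
  damp <- sqrt(opts$lambda)

  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0)
    return(recon_result(model, numeric(n), numeric(0), TRUE))
  if (opts$max_iterations == 0L)
    return(recon_result(model, numeric(n), 1, FALSE))

  u <- b / bnorm
  v <- as.numeric(Matrix::crossprod(A, u))
  alpha <- sqrt(sum(v^2))
  if (alpha == 0)
    return(recon_result(model, numeric(n), 1, FALSE))
  v <- v / alpha
  w <- v
  x <- numeric(n)
  phibar <- bnorm
  rhobar <- alpha
  res2 <- 0        # accumulated damping residual (psi^2 terms)
  res <- numeric(0)
  converged <- FALSE
  for (k in seq_len(opts$max_iterations)) {
    u <- as.numeric(A %*% v) - alpha * u
    beta <- sqrt(sum(u^2))
    if (beta > 0) {
      u <- u / beta
      v <- as.numeric(Matrix::crossprod(A, u)) - beta * v
      alpha <- sqrt(sum(v^2))
      if (alpha > 0) v <- v / alpha
    }
    # damping rotation (identity when lambda = 0)
    rhobar1 <- sqrt(rhobar^2 + damp^2)
    c1 <- rhobar / rhobar1
    s1 <- damp / rhobar1
    psi <- s1 * phibar
    phibar <- c1 * phibar
    # main plane rotation
    rho <- sqrt(rhobar1^2 + beta^2)
    cs <- rhobar1 / rho
    sn <- beta / rho
    theta <- sn * alpha
    rhobar <- -cs * alpha
    phi <- cs * phibar
    phibar <- sn * phibar
    x <- x + (phi / rho) * w
    w <- v - (theta / rho) * w
    res2 <- res2 + psi^2
    res <- c(res, sqrt(phibar^2 + res2) / bnorm)
    if (res[k] <= opts$tolerance) { converged <- TRUE; break }
  }
  recon_result(model, x, res, converged)
}

# Largest squared singular value of A by power iteration on A'A
#' @keywords internal
estimate_lipschitz <- function(A, n_iter = 30L) {
  v <- rep(1, ncol(A))
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (k in seq_len(n_iter)) {
    w <- as.numeric(Matrix::crossprod(A, A %*% v))
    lam <- sqrt(sum(w^2))
    if (lam == 0) return(1)
    v <- w / lam
  }
  lam
}

#' Non-negative reconstruction by accelerated projected gradient
#'
#' Minimizes `||M I - d||_2^2` (plus optional Tikhonov damping) subject to
#' `I >= 0` by Nesterov-accelerated projected gradient descent with a
#' function-value (monotone) restart and a Lipschitz step size from a power
#' iteration estimate of `||M'M||`. The projection guarantees the output is
#' element-wise non-negative at every iterate, and the restart rule makes
#' the objective non-increasing throughout.
#'
#' @inheritParams lsqr_solve
#' @param max_iterations optional override of `opts$max_iterations` (the
#'   constrained solver typically needs more iterations than LSQR).
#' @return A `recon_result` with `min(image) >= 0`.
#' @export
nnapcg_solve <- function(model, sinogram, opts = solver_options(
                           max_iterations = 200L, tolerance = 1e-6),
                         max_iterations = NULL) {
  A <- model$matrix
  s <- if (inherits(sinogram, "acoustic_frame")) sinogram$samples
       else as.matrix(sinogram)
  b <- sino_to_vec(s)
  if (length(b) != nrow(A)) stop("sinogram does not match model dimensions")
  n <- ncol(A)
  maxit <- if (is.null(max_iterations)) opts$max_iterations
           else as.integer(max_iterations)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0 || maxit == 0L)
    return(recon_result(model, numeric(n),
                        if (bnorm == 0) numeric(0) else 1, bnorm == 0))
  damp2 <- opts$lambda
  L <- estimate_lipschitz(A) + damp2
  L <- L * 1.01

  fval <- function(x) {
    r <- as.numeric(A %*% x) - b
    0.5 * sum(r^2) + 0.5 * damp2 * sum(x^2)
  }
  grad <- function(x) {
    as.numeric(Matrix::crossprod(A, as.numeric(A %*% x) - b)) + damp2 * x
  }
  x <- numeric(n)
  y <- x
  tk <- 1
  fx <- fval(x)
  res <- numeric(0)
  converged <- FALSE
  for (k in seq_len(maxit)) {
    xn <- pmax(y - grad(y) / L, 0)
    fn <- fval(xn)
    if (fn > fx) {
      # monotone restart: plain projected gradient step from x
      xn <- pmax(x - grad(x) / L, 0)
      fn <- fval(xn)
      tk <- 1
      if (fn > fx) { xn <- x; fn <- fx }  # stationary: keep x
    }
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- xn + ((tk - 1) / tn) * (xn - x)
    rr <- sqrt(sum((as.numeric(A %*% xn) - b)^2)) / bnorm
    res <- c(res, rr)
    moved <- sqrt(sum((xn - x)^2))
    x <- xn; fx <- fn; tk <- tn
    if (rr <= opts$tolerance ||
        (k > 1 && moved <= 1e-12 * max(sqrt(sum(x^2)), 1))) {
      converged <- rr <= opts$tolerance
      break
    }
  }
  recon_result(model, x, res, converged)
}

#' Universal backprojection (2D)
#'
#' Direct inversion: each pixel accumulates, over detectors,
#' `w_d * (2 p_d(t) - 2 t dp_d/dt)` evaluated at the time of flight
#' `t = |r - r_d| / v_s` by linear interpolation in time. Weights default to
#' `1/n_detectors`; the absolute scale of the output is arbitrary (images
#' are in arbitrary units). Pixels whose time of flight falls outside the
#' record contribute nothing; their count is returned as attribute
#' `n_out_of_record`.
#'
#' @param sinogram an [acoustic_frame] (uniform time axis required).
#' @param geometry a [detector_geometry].
#' @param image_coords image grid from [make_image_coords()].
#' @return An [image_frame].
#' @export
backproject <- function(sinogram, geometry, image_coords) {
  stopifnot(inherits(sinogram, "acoustic_frame"))
  tax <- sinogram$time_axis
  dt <- check_uniform_time(tax)
  P <- sinogram$samples
  nd <- nrow(P); nt <- ncol(P)
  if (nd != nrow(geometry$positions))
    stop("sinogram does not match geometry")
  ci <- image_coord_info(image_coords)
  X <- matrix(ci$x, nrow = ci$ny, ncol = ci$nx, byrow = TRUE)
  Y <- matrix(ci$y, nrow = ci$ny, ncol = ci$nx)
  vs <- geometry$speed_of_sound
  wd <- geometry$weights / sum(geometry$weights)
  acc <- matrix(0, ci$ny, ci$nx)
  n_out <- 0L
  for (d in seq_len(nd)) {
    p <- P[d, ]
    dp <- if (nt >= 3) {
      c(p[2] - p[1], (p[3:nt] - p[1:(nt - 2)]) / 2, p[nt] - p[nt - 1]) / dt
    } else (p[2] - p[1]) / dt + numeric(nt)
    q <- 2 * p - 2 * tax * dp
    tq <- sqrt((X - geometry$positions[d, 1])^2 +
                 (Y - geometry$positions[d, 2])^2) / vs
    idx <- (tq - tax[1]) / dt + 1
    inside <- idx >= 1 & idx <= nt
    n_out <- n_out + sum(!inside)
    i0 <- pmin(floor(idx[inside]), nt - 1L)
    f <- idx[inside] - i0
    val <- q[i0] * (1 - f) + q[i0 + 1L] * f
    acc[inside] <- acc[inside] + wd[d] * val
  }
  if (n_out > 0L)
    message("backproject: ", n_out,
            " pixel/detector pairs beyond the recorded time range")
  out <- image_frame(acc, fov = ci$fov, wavelength = sinogram$wavelength,
                     timestamp = sinogram$timestamp)
  attr(out, "n_out_of_record") <- n_out
  out
}

#' Reconstruct every frame of a dataset
#'
#' Frames are independent, so reconstruction is parallelized by statically
#' partitioning the frame range among workers; the output is bit-identical
#' for any worker count and preserves frame order. Frames whose
#' reconstruction fails are returned as NULL and listed in attribute
#' `failed_indices` (0-based).
#'
#' @param store a `dataset_store` from [open_dataset()].
#' @param model a `forward_model` (for `"lsqr"`/`"nnapcg"`) or a
#'   [detector_geometry] (for `"bp"`).
#' @param method `"lsqr"`, `"nnapcg"` or `"bp"`.
#' @param opts a [solver_options()] list.
#' @param image_coords image grid (required for `"bp"`; otherwise taken
#'   from the model).
#' @param n_workers number of parallel workers (forked; 1 = serial).
#' @param precondition optional [precondition_settings()] applied to each
#'   frame before reconstruction.
#' @return List of [image_frame]s, one per frame in order.
#' @export
reconstruct_dataset <- function(store, model, method = c("lsqr", "nnapcg",
                                                         "bp"),
                                opts = solver_options(),
                                image_coords = NULL, n_workers = 1L,
                                precondition = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(store, "dataset_store"))
  if (store$n_frames == 0L) return(list())
  if (method == "bp") {
    if (is.null(image_coords))
      stop("backprojection requires image_coords")
    geometry <- if (inherits(model, "detector_geometry")) model
                else model$geometry
  } else {
    if (!inherits(model, "forward_model"))
      stop("model-based reconstruction requires a forward_model")
    image_coords <- model$image_coords
  }
  one <- function(k) {
    fr <- get_frame(store, k)
    if (!is.null(precondition)) fr <- precondition_frame(fr, precondition)
    img <- switch(method,
      lsqr = lsqr_solve(model, fr, opts)$image,
      nnapcg = nnapcg_solve(model, fr, opts)$image,
      bp = backproject(fr, geometry, image_coords))
    img$wavelength <- fr$wavelength
    img$timestamp <- fr$timestamp
    img
  }
  idx <- 0:(store$n_frames - 1L)
  results <- parallel_frame_map(idx, one, n_workers)
  bad <- vapply(results, inherits, logical(1), "frame_error")
  if (all(bad))
    stop("reconstruction failed for every frame; first error: ",
         results[[1L]]$message)
  if (any(bad)) {
    attr(results, "failed_indices") <- idx[bad]
    attr(results, "failure_messages") <-
      vapply(results[bad], `[[`, character(1), "message")
    results[bad] <- list(NULL)
  }
  results
}

# Static, order-preserving parallel map over frame indices. Chunks are
# contiguous and assigned deterministically, so results are identical for
# any worker count.
parallel_frame_map <- function(idx, fn, n_workers) {
  safe <- function(k) tryCatch(fn(k), error = function(e)
    structure(list(message = conditionMessage(e)), class = "frame_error"))
  n_workers <- max(1L, as.integer(n_workers))
  if (n_workers == 1L || length(idx) < 2L ||
      .Platform$OS.type != "unix") {
    return(lapply(idx, safe))
  }
  chunks <- split(idx, ceiling(seq_along(idx) /
                                 ceiling(length(idx) / n_workers)))
  parts <- parallel::mclapply(chunks, function(ch) lapply(ch, safe),
                              mc.cores = n_workers, mc.preschedule = FALSE)
  unlist(parts, recursive = FALSE, use.names = FALSE)
}
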