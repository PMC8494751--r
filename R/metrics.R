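#' Reconstruction-quality and downstream statistical metrics
#'
#' Error metrics compare a reconstruction against the known source image on
#' a per-pixel error image `e = known - recon`; all sums are scaled by the
#' pixel count (note the L2 norm therefore carries an extra `1/sqrt(N)`
#' relative to a root-mean-square). Downstream statistics mirror the
#' analyses used on dynamic in vivo-style series: negative-pixel indicator
#' maps, binned Bland-Altman comparisons, per-pixel Welch t-score maps,
#' relative Cohen's d maps, correlation maps against a reference stimulus
#' waveform, Fisher-Z comparison of correlations, and a 7-parameter
#' piecewise mono-exponential fit of gas-challenge time courses.
#'
#' @name metrics
NULL

as_pixel_matrix <- function(x) {
  if (inherits(x, "image_frame")) x$pixels else as.matrix(x)
}

# list of image_frames / matrices, or [n, ny, nx] array -> array
as_stack <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (is.list(x)) {
    mats <- lapply(x, as_pixel_matrix)
    d <- dim(mats[[1L]])
    out <- array(0, dim = c(length(mats), d[1L], d[2L]))
    for (i in seq_along(mats)) out[i, , ] <- mats[[i]]
    return(out)
  }
  stop("expected a list of images or an [n x ny x nx] array")
}

#' Per-image error metrics
#'
#' @param known ground-truth [image_frame] or matrix.
#' @param recon reconstructed [image_frame] or matrix (same shape).
#' @return List: `bias`, `l1`, `l2` (pixel-count-scaled norms of the error
#'   image), `n_negative` (negative pixels in the reconstruction).
#' @export
error_metrics <- function(known, recon) {
  a <- as_pixel_matrix(known)
  b <- as_pixel_matrix(recon)
  if (!all(dim(a) == dim(b))) stop("image shapes differ")
  e <- a - b
  n <- length(e)
  list(bias = sum(e) / n,
       l1 = sum(abs(e)) / n,
       l2 = sqrt(sum(e^2)) / n,
       n_negative = sum(b < 0))
}

# Exact box mean with truncated border windows, via integral images.
box_mean <- function(m, w) {
  r <- (w - 1L) %/% 2L
  ny <- nrow(m); nx <- ncol(m)
  cs <- rbind(0, apply(m, 2L, cumsum))
  cs <- cbind(0, t(apply(cs, 1L, cumsum)))
  i1 <- pmax(seq_len(ny) - r, 1L); i2 <- pmin(seq_len(ny) + r, ny)
  j1 <- pmax(seq_len(nx) - r, 1L); j2 <- pmin(seq_len(nx) + r, nx)
  S <- cs[i2 + 1L, j2 + 1L, drop = FALSE] -
    cs[i1, j2 + 1L, drop = FALSE] -
    cs[i2 + 1L, j1, drop = FALSE] + cs[i1, j1, drop = FALSE]
  cnt <- outer(i2 - i1 + 1L, j2 - j1 + 1L)
  S / cnt
}

#' Structural similarity index
#'
#' Mean over local windows of the SSIM formula
#' `(2 mu_x mu_y + C1)(2 sigma_xy + C2) /
#'  ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`
#' with uniform `window x window` local statistics. The stabilizers default
#' to `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with `L` the dynamic range of the
#' pair.
#'
#' @param x,y images of the same shape.
#' @param C1,C2 stabilizing constants; NULL for the defaults above.
#' @param window odd window width (default 7).
#' @return SSIM in [-1, 1]; identical images give exactly 1.
#' @export
ssim <- function(x, y, C1 = NULL, C2 = NULL, window = 7L) {
  a <- as_pixel_matrix(x)
  b <- as_pixel_matrix(y)
  if (!all(dim(a) == dim(b))) stop("image shapes differ")
  if (is.null(C1) || is.null(C2)) {
    L <- diff(range(c(a, b)))
    if (L == 0) L <- 1
    if (is.null(C1)) C1 <- (0.01 * L)^2
    if (is.null(C2)) C2 <- (0.03 * L)^2
  }
  mu_a <- box_mean(a, window)
  mu_b <- box_mean(b, window)
  va <- box_mean(a * a, window) - mu_a^2
  vb <- box_mean(b * b, window) - mu_b^2
  cab <- box_mean(a * b, window) - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(s)
}

#' Relative residual of a reconstruction
#'
#' `||M I - d|| / ||d||`. For zero data it is 0 when the predicted
#' sinogram is also zero and +Inf otherwise.
#'
#' @param model a `forward_model`.
#' @param image an [image_frame] or matrix.
#' @param data the measured sinogram ([acoustic_frame] or matrix).
#' @return Non-negative scalar.
#' @export
relative_residual <- function(model, image, data) {
  d <- sino_to_vec(if (inherits(data, "acoustic_frame")) data$samples
                   else as.matrix(data))
  pred <- sino_to_vec(model_apply(model, image))
  dn <- sqrt(sum(d^2))
  rn <- sqrt(sum((pred - d)^2))
  if (dn == 0) return(if (sqrt(sum(pred^2)) == 0) 0 else Inf)
  rn / dn
}

#' Per-pixel negative-value counts over a series
#'
#' @param image_series list of images or [n x ny x nx] array.
#' @return Integer matrix: per pixel, the number of frames with value < 0.
#' @export
negative_indicator_map <- function(image_series) {
  s <- as_stack(image_series)
  apply(s < 0, c(2L, 3L), sum)
}

#' Binned Bland-Altman comparison
#'
#' Randomly samples a fraction of paired pixel values (without replacement,
#' seeded), then bins `((a+b)/2, a-b)` on an `n_bins x n_bins` grid spanning
#' the sampled ranges.
#'
#' @param a,b numeric arrays of identical shape (e.g. pixel time courses of
#'   two processing chains).
#' @param n_bins bins per axis (default 100).
#' @param sample_frac fraction of points to sample, in (0, 1].
#' @param seed RNG seed for the subsample.
#' @return List: `counts` (n_bins x n_bins), `mean_edges`, `diff_edges`,
#'   `mean_difference`, `loa` (limits of agreement, +-1.96 SD), `n`.
#' @export
bland_altman_binned <- function(a, b, n_bins = 100L, sample_frac = 0.1,
                                seed = 1L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("inputs differ in length")
  if (sample_frac <= 0 || sample_frac > 1)
    stop("sample_frac must be in (0, 1]")
  n <- floor(sample_frac * length(a))
  if (n < 1L) stop("empty sample")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(restore_rng(old_seed))
  set.seed(as.integer(seed))
  idx <- if (n == length(a)) seq_along(a) else sample.int(length(a), n)
  m <- (a[idx] + b[idx]) / 2
  d <- a[idx] - b[idx]
  rng_m <- range(m); rng_d <- range(d)
  if (diff(rng_m) == 0) rng_m <- rng_m + c(-0.5, 0.5)
  if (diff(rng_d) == 0) rng_d <- rng_d + c(-0.5, 0.5)
  me <- seq(rng_m[1L], rng_m[2L], length.out = n_bins + 1L)
  de <- seq(rng_d[1L], rng_d[2L], length.out = n_bins + 1L)
  bi <- pmin(pmax(findInterval(m, me, all.inside = TRUE), 1L), n_bins)
  bj <- pmin(pmax(findInterval(d, de, all.inside = TRUE), 1L), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  tab <- table(factor(bi, levels = seq_len(n_bins)),
               factor(bj, levels = seq_len(n_bins)))
  counts[] <- as.integer(tab)
  sd_d <- stats::sd(d)
  list(counts = counts, mean_edges = me, diff_edges = de,
       mean_difference = mean(d),
       loa = mean(d) + c(-1.96, 1.96) * (if (is.na(sd_d)) 0 else sd_d),
       n = n)
}

stack_mean_var <- function(s) {
  n <- dim(s)[1L]
  m <- apply(s, c(2L, 3L), mean)
  v <- apply(s, c(2L, 3L), stats::var)
  list(n = n, mean = m, var = v)
}

#' Per-pixel Welch t-score map
#'
#' Welch (unequal-variance) two-sample t statistic of `after` vs `before`
#' at each pixel. Zero-variance pixels with a nonzero mean difference give
#' +-Inf (flagged, not dropped).
#'
#' @param before,after frame stacks (lists of images or [n x ny x nx]
#'   arrays) with >= 2 frames each.
#' @return Numeric t-score matrix.
#' @export
tscore_map <- function(before, after) {
  b <- stack_mean_var(as_stack(before))
  a <- stack_mean_var(as_stack(after))
  if (b$n < 2L || a$n < 2L)
    stop("each stack needs at least 2 frames")
  se <- sqrt(a$var / a$n + b$var / b$n)
  t <- (a$mean - b$mean) / se
  t[se == 0 & a$mean == b$mean] <- 0
  t
}

cohens_d_map <- function(s1, s2) {
  a <- stack_mean_var(s1); b <- stack_mean_var(s2)
  sp <- sqrt(((a$n - 1) * a$var + (b$n - 1) * b$var) / (a$n + b$n - 2))
  (b$mean - a$mean) / sp
}

#' Relative Cohen's d map
#'
#' Scales a treatment effect by a physiological reference effect: per
#' pixel, `d_drug / d_gas` with `d = (mean2 - mean1) / pooled SD`. Pixels
#' with a negligible reference effect (|d_gas| < eps) are NA-flagged.
#'
#' @param drug_before,drug_after stacks around the treatment.
#' @param gas_before,gas_after stacks around the reference (gas) transition.
#' @param eps threshold on |d_gas| below which the ratio is undefined.
#' @return Numeric ratio matrix with NA where undefined.
#' @export
relative_cohens_d <- function(drug_before, drug_after, gas_before,
                              gas_after, eps = 1e-12) {
  dd <- cohens_d_map(as_stack(drug_before), as_stack(drug_after))
  dg <- cohens_d_map(as_stack(gas_before), as_stack(gas_after))
  out <- dd / dg
  out[!is.finite(dg) | abs(dg) < eps] <- NA_real_
  out
}

#' Per-pixel correlation with a reference waveform
#'
#' Pearson correlation of each pixel's mean-centred time course with the
#' centred reference (e.g. the known inhaled-O2 schedule). Constant pixels
#' are NA-flagged.
#'
#' @param series [n_t x ny x nx] array or list of images, in time order.
#' @param reference_waveform numeric vector of length n_t.
#' @return Correlation matrix in [-1, 1] with NA where undefined.
#' @export
correlation_map <- function(series, reference_waveform) {
  s <- as_stack(series)
  w <- as.numeric(reference_waveform)
  if (dim(s)[1L] != length(w)) stop("series and waveform lengths differ")
  wc <- w - mean(w)
  wn <- sqrt(sum(wc^2))
  if (wn == 0) stop("reference waveform is constant")
  d <- dim(s)
  m <- matrix(s, nrow = d[1L])
  mc <- m - matrix(colMeans(m), d[1L], ncol(m), byrow = TRUE)
  denom <- sqrt(colSums(mc^2)) * wn
  rho <- colSums(mc * wc) / denom
  rho[denom == 0] <- NA_real_
  matrix(rho, d[2L], d[3L])
}

#' Fisher-Z comparison of two correlations
#'
#' `z = (atanh(rho1) - atanh(rho2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p-value. Conventional significance labels at
#' alpha = 0.01 ("significant") and 0.0001 ("strong") are attached.
#'
#' @param rho1,rho2 correlation coefficients with |rho| < 1.
#' @param n1,n2 sample sizes (> 3).
#' @return List: `z`, `p`, `significant`, `strongly_significant`.
#' @export
fisher_z_compare <- function(rho1, n1, rho2, n2) {
  if (any(abs(c(rho1, rho2)) >= 1))
    stop("correlations must satisfy |rho| < 1")
  if (any(c(n1, n2) <= 3)) stop("sample sizes must exceed 3")
  z <- (atanh(rho1) - atanh(rho2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = p, significant = p < 0.01,
       strongly_significant = p < 1e-4)
}

gas_model_eval <- function(p, t) {
  # p = (b, A1, k1, tau1, A2, k2, tau2)
  r1 <- ifelse(t >= p[4], 1 - exp(-p[3] * (t - p[4])), 0)
  r2 <- ifelse(t >= p[7], 1 - exp(-p[6] * (t - p[7])), 0)
  p[1] + p[2] * r1 - p[5] * r2
}

#' Fit the 7-parameter gas-challenge response model
#'
#' Least-squares fit (Levenberg-Marquardt, bounded) of a piecewise
#' mono-exponential response
#' `y(t) = b + A1 (1 - exp(-k1 (t - tau1))) H(t - tau1)
#'           - A2 (1 - exp(-k2 (t - tau2))) H(t - tau2)`
#' with baseline `b`, rise amplitude/rate/switching time `A1, k1, tau1`
#' and fall amplitude/rate/switching time `A2, k2, tau2`; switching times
#' are constrained to the record. Non-convergent or constant series are
#' flagged, not raised.
#'
#' @param timecourse numeric response values.
#' @param times sample times (s), >= 50 samples spanning both transitions.
#' @param stimulus_onsets optional known (rise, fall) stimulus times; when
#'   given, a fitted switching time preceding its stimulus is flagged
#'   `noncausal`.
#' @return List: `parameters` (named length-7 vector), `residual_norm`,
#'   `converged`, `degenerate`, `noncausal`.
#' @export
fit_gas_model <- function(timecourse, times, stimulus_onsets = NULL) {
  y <- as.numeric(timecourse)
  t <- as.numeric(times)
  if (length(y) != length(t)) stop("timecourse and times differ in length")
  if (length(y) < 50L) stop("need >= 50 samples")
  out_names <- c("b", "A1", "k1", "tau1", "A2", "k2", "tau2")
  if (stats::sd(y) == 0) {
    p <- c(mean(y), 0, 1, t[1], 0, 1, t[1])
    names(p) <- out_names
    return(list(parameters = p, residual_norm = 0, converged = TRUE,
                degenerate = TRUE, noncausal = FALSE))
  }
  span <- t[length(t)] - t[1]
  # initial guesses from the smoothed derivative
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  dy <- diff(ys)
  i_up <- which.max(dy)
  i_dn <- which.min(dy)
  tau1_0 <- t[i_up]; tau2_0 <- t[i_dn]
  if (tau2_0 <= tau1_0) { tau1_0 <- t[1] + 0.3 * span
                          tau2_0 <- t[1] + 0.7 * span }
  b0 <- mean(y[t <= tau1_0])
  a1_0 <- max(ys) - b0
  a2_0 <- max(ys) - mean(y[t >= tau2_0 + 0.5 * (t[length(t)] - tau2_0)])
  p0 <- c(b0, max(a1_0, 1e-6), 5 / span, tau1_0,
          max(a2_0, 1e-6), 5 / span, tau2_0)
  lower <- c(-Inf, 0, 1e-8, t[1], 0, 1e-8, t[1])
  upper <- c(Inf, Inf, Inf, t[length(t)], Inf, Inf, t[length(t)])
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0,
                       fn = function(p) gas_model_eval(p, t) - y,
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    p <- p0
    names(p) <- out_names
    return(list(parameters = p, residual_norm = NA_real_,
                converged = FALSE, degenerate = FALSE, noncausal = FALSE))
  }
  p <- fit$par
  names(p) <- out_names
  noncausal <- FALSE
  if (!is.null(stimulus_onsets) && length(stimulus_onsets) >= 2L)
    noncausal <- p["tau1"] < stimulus_onsets[1L] - 1e-9 ||
      p["tau2"] < stimulus_onsets[2L] - 1e-9
  list(parameters = p,
       residual_norm = sqrt(sum(fit$fvec^2)),
       converged = fit$info %in% 1:4,
       degenerate = FALSE,
       noncausal = unname(noncausal))
}
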