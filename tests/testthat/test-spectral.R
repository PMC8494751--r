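mk_img <- function(m, wl, t) image_frame(m, fov = 0.01, wavelength = wl,
                                         timestamp = t)

test_that("sliding-window assembly warms up and keeps the latest repetition", {
  wls <- c(715, 730, 760)
  set.seed(1)
  mats <- replicate(9, matrix(runif(4), 2, 2), simplify = FALSE)
  stream <- lapply(1:9, function(k)
    mk_img(mats[[k]], wls[(k - 1L) %% 3L + 1L], k))
  out <- sliding_window_assemble(stream, wls)
  expect_length(out, 7L)               # first emission at frame 3
  expect_equal(out[[1L]]$timestamp, 3)
  # the stack always holds the latest frame per wavelength
  expect_equal(out[[5L]]$stack[1L, , ], mats[[7L]])  # 715 seen at frame 7
  expect_equal(out[[5L]]$stack[2L, , ], mats[[5L]])
  expect_equal(out[[5L]]$stack[3L, , ], mats[[6L]])

  # oversampled wavelengths: latest repetition wins
  st2 <- list(mk_img(mats[[1L]], 715, 1), mk_img(mats[[2L]], 715, 2),
              mk_img(mats[[3L]], 730, 3), mk_img(mats[[4L]], 760, 4))
  o2 <- sliding_window_assemble(st2, wls)
  expect_equal(o2[[1L]]$stack[1L, , ], mats[[2L]])

  # static input: constant emissions after warm-up
  st3 <- lapply(1:6, function(k)
    mk_img(mats[[(k - 1L) %% 3L + 1L]], wls[(k - 1L) %% 3L + 1L], k))
  o3 <- sliding_window_assemble(st3, wls)
  expect_equal(o3[[1L]]$stack, o3[[4L]]$stack)
  expect_error(sliding_window_assemble(list(mk_img(mats[[1]], 999, 1)),
                                       wls), "not in the declared set")
})

test_that("Kalata gains follow the tracking-index closed forms", {
  for (L in c(0.01, 0.1, 1, 10)) {
    g <- kalata_gains(L, "alpha")
    expect_equal(g$alpha^2 / (1 - g$alpha), L, tolerance = 1e-10)
    gb <- kalata_gains(L, "alphabeta")
    r <- (4 + L - sqrt(8 * L + L^2)) / 4
    expect_equal(gb$alpha, 1 - r^2)
    expect_equal(gb$beta, 2 * (2 - gb$alpha) - 4 * sqrt(1 - gb$alpha))
    expect_true(gb$alpha > 0 && gb$alpha <= 1 && gb$beta >= 0)
  }
  expect_error(kalata_gains(-1), "tracking_index")
})

ramp_stream <- function(n, slope, dt = 1, wl = 800) {
  lapply(seq_len(n), function(k)
    mk_img(matrix(slope * k * dt, 2, 2), wl, k * dt))
}

test_that("Kalata filters converge on constants and show the closed-form ramp lag", {
  wl <- 800
  const <- lapply(1:120, function(k) mk_img(matrix(3.7, 2, 2), wl, k))
  for (ord in c("alpha", "alphabeta")) {
    out <- kalata_filter(const, wl, order = ord, tracking_index = 0.5)
    expect_lt(max(abs(out[[110L]]$stack - 3.7)), 1e-9)
  }

  slope <- 0.8; dt <- 2
  stream <- ramp_stream(600, slope, dt)
  g <- kalata_gains(0.5, "alpha")
  oa <- kalata_filter(stream, wl, "alpha", 0.5)
  z_end <- slope * 600 * dt
  lag <- z_end - oa[[600L]]$stack[1, 1, 1]
  expect_equal(lag, slope * dt * (1 - g$alpha) / g$alpha,
               tolerance = 1e-6)

  ob <- kalata_filter(stream, wl, "alphabeta", 0.5)
  expect_lt(abs(z_end - ob[[600L]]$stack[1, 1, 1]), 1e-6 * slope * dt)

  bad <- list(mk_img(matrix(1, 2, 2), wl, 2), mk_img(matrix(1, 2, 2), wl, 1))
  expect_error(kalata_filter(bad, wl), "non-decreasing")
})

test_that("the alpha filter attains its steady-state noise variance", {
  set.seed(99)
  n <- 25000L
  g <- kalata_gains(0.5, "alpha")
  stream <- lapply(seq_len(n), function(k)
    mk_img(matrix(rnorm(4), 2, 2), 800, k))
  out <- kalata_filter(stream, 800, "alpha", 0.5)
  est <- t(vapply(out[2000:n], function(f) as.vector(f$stack),
                  numeric(4)))
  ratio <- mean(apply(est, 2L, stats::var))     # input variance is 1
  expect_equal(ratio, g$alpha / (2 - g$alpha), tolerance = 0.1)

  # alpha suppresses more noise than alpha-beta at equal tracking index
  outb <- kalata_filter(stream, 800, "alphabeta", 0.5)
  estb <- t(vapply(outb[2000:n], function(f) as.vector(f$stack),
                   numeric(4)))
  expect_lt(ratio, mean(apply(estb, 2L, stats::var)))
})

test_that("unmixing inverts the mixing model and enforces non-negativity", {
  spectra <- hemoglobin_spectra(c(715, 730, 760, 800, 830, 850))
  E <- spectra$E
  set.seed(3)
  ny <- 6L; nx <- 5L
  C <- array(runif(2 * ny * nx), dim = c(2, ny, nx))
  stack <- array(0, dim = c(6, ny, nx))
  for (i in 1:ny) for (j in 1:nx)
    stack[, i, j] <- E %*% C[, i, j]
  ms <- multispectral_frame(stack, spectra$wavelengths)

  for (m in c("pinv", "nonneg")) {
    u <- unmix(ms, spectra, method = m)
    expect_lt(max(abs(u$concentrations - C)), 1e-8 * max(C))
  }
  z <- unmix(multispectral_frame(stack * 0, spectra$wavelengths), spectra)
  expect_true(all(z$concentrations == 0))

  # noise pushing the pseudoinverse negative: nonneg matches the
  # active-set oracle per pixel and stays feasible
  noisy <- stack + array(rnorm(length(stack), sd = 0.3 * max(stack)),
                         dim = dim(stack))
  msn <- multispectral_frame(noisy, spectra$wavelengths)
  up <- unmix(msn, spectra, "pinv")
  expect_gt(sum(up$concentrations < 0), 0)
  un <- unmix(msn, spectra, "nonneg")
  expect_gte(min(un$concentrations), 0)
  for (i in c(1L, 4L)) for (j in c(2L, 5L)) {
    oracle <- nnls_active_set(E, noisy[, i, j])
    expect_equal(un$concentrations[, i, j], oracle, tolerance = 1e-6)
  }
  # SO2 of the constrained result lies in [0, 1]
  expect_true(all(un$so2 >= 0 & un$so2 <= 1, na.rm = TRUE))

  expect_error(endmember_spectra(c(700, 750), cbind(c(1, 2), c(2, 4))),
               "rank deficient")
})

test_that("oxygen saturation is the HbO2 fraction with flagged exceptions", {
  conc <- array(0, dim = c(2, 2, 2))
  conc[1, , ] <- matrix(c(0, 1, 2, 0.5), 2, 2)   # HbO2
  conc[2, , ] <- matrix(c(1, 1, 2, 0.0), 2, 2)   # Hb
  u <- compute_so2(unmixed_frame(conc, c("HbO2", "Hb")))
  expect_equal(u$so2[1, 1], 0)
  expect_equal(u$so2[2, 1], 0.5)
  expect_equal(u$so2[2, 2], 1)
  conc0 <- conc; conc0[, 1, 2] <- 0
  u0 <- compute_so2(unmixed_frame(conc0, c("HbO2", "Hb")))
  expect_true(is.na(u0$so2[1, 2]))
  # negative (unconstrained) inputs may leave [0, 1] and are flagged
  concn <- conc; concn[2, 2, 1] <- -0.5   # HbO2 = 1, Hb = -0.5 -> SO2 = 2
  un <- compute_so2(unmixed_frame(concn, c("HbO2", "Hb")))
  expect_gt(attr(un$so2, "n_out_of_range"), 0)
})
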