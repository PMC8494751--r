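make_frame <- function(samples, dt = 2.5e-8, wavelength = 800,
                       energy = 1) {
  acoustic_frame(samples, seq(0, by = dt, length.out = ncol(samples)),
                 wavelength = wavelength, laser_energy = energy)
}

test_that("energy calibration normalises shots to the reference energy", {
  s <- matrix(rnorm(4 * 64), 4, 64)
  f1 <- make_frame(s, energy = 1)
  expect_equal(energy_calibrate(f1, 1)$samples, s)
  f2 <- make_frame(s, energy = 2)
  expect_equal(energy_calibrate(f2, 1)$samples, s / 2)
  # two frames differing only in energy calibrate to the same signal
  fa <- make_frame(2.5 * s, energy = 2.5)
  fb <- make_frame(0.3 * s, energy = 0.3)
  expect_equal(energy_calibrate(fa, 1)$samples,
               energy_calibrate(fb, 1)$samples, tolerance = 1e-14)
  f2$laser_energy <- -1
  expect_error(energy_calibrate(f2), "laser_energy")
})

test_that("mean subtraction zeroes each transducer and is idempotent", {
  s <- matrix(rnorm(4 * 64), 4, 64) + 1:4
  f <- subtract_mean(make_frame(s))
  expect_true(all(abs(rowMeans(f$samples)) <
                    1e-12 * apply(f$samples, 1, sd)))
  expect_equal(subtract_mean(f)$samples, f$samples)
  const <- subtract_mean(make_frame(matrix(3, 4, 64)))
  expect_true(all(const$samples == 0))
})

test_that("Wiener deconvolution inverts known circular convolutions", {
  set.seed(8)
  n <- 128L
  x <- matrix(rnorm(3 * n), 3, n)
  f <- make_frame(x)
  delta <- impulse_response(1)
  expect_equal(wiener_deconvolve(f, delta, nsr = 0)$samples, x,
               tolerance = 1e-10)

  h <- 0.6^(0:7)                       # |H| > 0 everywhere
  H <- stats::fft(c(h, numeric(n - 8L)))
  y <- t(apply(x, 1, function(r)
    Re(stats::fft(stats::fft(r) * H, inverse = TRUE)) / n))
  rec <- wiener_deconvolve(make_frame(y), impulse_response(h), nsr = 0)
  expect_equal(rec$samples, x, tolerance = 1e-8)

  # nsr -> Inf drives the output to zero
  big <- wiener_deconvolve(f, impulse_response(h), nsr = 1e12)
  expect_lt(max(abs(big$samples)), 1e-9 * max(abs(x)))
  expect_error(impulse_response(c(0, 0)), "all zero")
})

test_that("band-pass keeps in-band tones and rejects out-of-band energy", {
  fs <- 4e7
  n <- 4096L
  tt <- seq(0, by = 1 / fs, length.out = n)
  tone <- function(f) matrix(sin(2 * pi * f * tt), 1, n,
                             byrow = TRUE)[c(1, 1, 1), ]
  mk <- function(s) make_frame(s, dt = 1 / fs)

  dc <- bandpass(mk(matrix(1, 3, n)), 5e4, 7e6)
  expect_lt(max(abs(dc$samples)), 1e-3)

  f0 <- sqrt(5e4 * 7e6)                 # geometric band centre
  mid <- bandpass(mk(tone(f0)), 5e4, 7e6)
  core <- 1000:3000                     # avoid filter edge transients
  amp <- max(abs(mid$samples[1, core]))
  expect_lt(abs(amp - 1), 0.05)
  # zero phase: filtered tone stays aligned with the input
  expect_gt(cor(mid$samples[1, core], tone(f0)[1, core]), 0.999)

  att <- function(f) {
    out <- bandpass(mk(tone(f)), 5e4, 7e6)
    20 * log10(max(abs(out$samples[1, core])))
  }
  expect_lt(att(5e3), -20)              # f_lo / 10
  expect_lt(att(min(7e7, 0.99 * fs / 2)), -20)
  expect_error(bandpass(mk(tone(1e6)), 7e6, 5e4), "invalid band")
})

test_that("water correction compensates Beer's-law attenuation", {
  tab <- water_absorption_table()
  expect_true(all(tab$mu_a_cm > 0))
  s <- matrix(rnorm(3 * 32), 3, 32)
  f <- make_frame(s, wavelength = 800)
  expect_equal(water_correction(f, tab, path_length_cm = 0)$samples, s)
  out <- water_correction(f, tab, path_length_cm = 3)
  ratio <- out$samples / s
  expect_true(all(ratio > 1))
  expect_equal(max(ratio), min(ratio), tolerance = 1e-12)
  f$wavelength <- 650
  expect_error(water_correction(f, tab), "outside")
})

test_that("time regridding is linear-exact and refuses extrapolation", {
  dt <- 2.5e-8
  n <- 128L
  tax <- seq(0, by = dt, length.out = n)
  s <- matrix(rnorm(2 * n), 2, n)
  f <- make_frame(s, dt = dt)
  expect_identical(regrid_time(f, tax)$samples, s)

  lin <- make_frame(rbind(3 * tax + 1, -2 * tax), dt = dt)
  sub <- seq(tax[10], tax[100], length.out = 37L)
  rg <- regrid_time(lin, sub)
  expect_equal(rg$samples[1, ], 3 * sub + 1, tolerance = 1e-12)

  sine <- make_frame(rbind(sin(2 * pi * 3e6 * tax),
                           cos(2 * pi * 2e6 * tax)), dt = dt)
  up <- regrid_time(sine, seq(tax[1], tax[n], length.out = 2 * n - 1L))
  back <- regrid_time(up, tax)
  expect_lt(rel_l2(back$samples, sine$samples), 1e-3)
  expect_error(regrid_time(f, tax + dt), "extrapolation")
})

test_that("the composite chain equals its stages in fixed order and is linear", {
  set.seed(12)
  n <- 256L
  s <- matrix(rnorm(4 * n), 4, n)
  f <- make_frame(s, dt = 2.5e-8, wavelength = 800, energy = 2)
  ir <- impulse_response(c(1, 0.4, 0.1))
  settings <- precondition_settings(
    energy = TRUE, energy_ref = 1, mean = TRUE,
    wiener = list(ir = ir, nsr = 0.05),
    bandpass = list(f_lo = 1e5, f_hi = 8e6),
    water = list(path_cm = 3))
  manual <- water_correction(
    bandpass(wiener_deconvolve(subtract_mean(energy_calibrate(f, 1)),
                               ir, nsr = 0.05), 1e5, 8e6),
    path_length_cm = 3)
  expect_equal(precondition_frame(f, settings)$samples, manual$samples,
               tolerance = 1e-12)

  off <- precondition_settings(energy = FALSE, mean = FALSE,
                               bandpass = NULL)
  expect_identical(precondition_frame(f, off)$samples, f$samples)
  expect_error(precondition_settings(order = c("bandpass", "wiener")),
               "order is fixed")

  # composite linearity (all stages are linear maps)
  g <- make_frame(matrix(rnorm(4 * n), 4, n), dt = 2.5e-8,
                  wavelength = 800, energy = 2)
  lin_set <- precondition_settings(energy = FALSE, mean = TRUE,
                                   wiener = list(ir = ir, nsr = 0.05),
                                   bandpass = list(f_lo = 1e5, f_hi = 8e6))
  P <- function(fr) precondition_frame(fr, lin_set)$samples
  comb <- f
  comb$samples <- 2 * f$samples - 0.7 * g$samples
  expect_equal(P(comb), 2 * P(f) - 0.7 * P(g), tolerance = 1e-10)
})
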