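test_that("error metrics follow their closed forms and a brute-force oracle", {
  set.seed(14)
  a <- matrix(rnorm(25), 5, 5)
  same <- error_metrics(a, a)
  expect_equal(same$bias, 0)
  expect_equal(same$l1, 0)
  expect_equal(same$l2, 0)
  expect_equal(same$n_negative, sum(a < 0))

  c0 <- 0.42
  shifted <- error_metrics(a, a - c0)
  expect_equal(shifted$bias, c0, tolerance = 1e-12)
  expect_equal(shifted$l1, c0, tolerance = 1e-12)
  expect_equal(shifted$l2, c0 / sqrt(25), tolerance = 1e-12)

  b <- matrix(rnorm(25), 5, 5)
  em <- error_metrics(a, b)
  e <- a - b
  expect_equal(em$bias, sum(e) / 25, tolerance = 1e-14)
  expect_equal(em$l1, sum(abs(e)) / 25, tolerance = 1e-14)
  expect_equal(em$l2, sqrt(sum(e^2)) / 25, tolerance = 1e-14)
  expect_error(error_metrics(a, matrix(0, 4, 5)), "shapes differ")
})

test_that("SSIM is 1 on identity, symmetric, and exact for flat images", {
  set.seed(15)
  x <- matrix(rnorm(100), 10, 10)
  y <- matrix(rnorm(100), 10, 10)
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-14)
  expect_true(abs(ssim(x, y)) <= 1)

  # constant images: zero variances reduce the formula to the luminance term
  mx <- 2; my <- 3; C1 <- 0.01; C2 <- 0.02
  got <- ssim(matrix(mx, 8, 8), matrix(my, 8, 8), C1 = C1, C2 = C2)
  expect_equal(got, (2 * mx * my + C1) / (mx^2 + my^2 + C1),
               tolerance = 1e-12)

  # brute-force windowed oracle (truncated 7x7 windows, same stabilizers)
  C1 <- 0.03; C2 <- 0.09
  oracle <- local({
    vals <- matrix(0, 10, 10)
    for (i in 1:10) for (j in 1:10) {
      ii <- max(1, i - 3):min(10, i + 3)
      jj <- max(1, j - 3):min(10, j + 3)
      xa <- x[ii, jj]; ya <- y[ii, jj]
      n <- length(xa)
      mx <- mean(xa); my <- mean(ya)
      vx <- mean(xa^2) - mx^2; vy <- mean(ya^2) - my^2
      cxy <- mean(xa * ya) - mx * my
      vals[i, j] <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
        ((mx^2 + my^2 + C1) * (vx + vy + C2))
    }
    mean(vals)
  })
  expect_equal(ssim(x, y, C1 = C1, C2 = C2), oracle, tolerance = 1e-10)
})

test_that("relative residuals match direct norm computation", {
  ts <- tiny_setup(n_pixels = 10L, n_times = 48L)
  M <- cached_model("cdmmi", ts$coords, ts$geometry, ts$time_axis)
  set.seed(16)
  x <- matrix(runif(100), 10, 10)
  d <- model_apply(M, x)
  expect_lt(relative_residual(M, x, d), 1e-12)
  expect_equal(relative_residual(M, matrix(0, 10, 10), d), 1)
  x2 <- matrix(runif(100), 10, 10)
  direct <- sqrt(sum((model_apply(M, x2) - d)^2)) / sqrt(sum(d^2))
  expect_equal(relative_residual(M, x2, d), direct, tolerance = 1e-14)
  zero <- matrix(0, nrow(d), ncol(d))
  expect_equal(relative_residual(M, matrix(0, 10, 10), zero), 0)
  expect_true(is.infinite(relative_residual(M, x, zero)))
})

test_that("negative indicator maps count per-pixel negative frames", {
  s <- array(1, dim = c(4, 3, 3))
  expect_true(all(negative_indicator_map(s) == 0))
  s[2, 1, 2] <- -1
  s[4, 1, 2] <- -5
  m <- negative_indicator_map(s)
  expect_equal(m[1, 2], 2)
  expect_equal(sum(m), 2)
})

test_that("binned Bland-Altman summaries match their definitions", {
  set.seed(17)
  a <- rnorm(5000)
  same <- bland_altman_binned(a, a, n_bins = 50L, sample_frac = 0.5)
  expect_equal(same$mean_difference, 0)
  nz <- which(same$counts > 0, arr.ind = TRUE)
  mid <- (same$diff_edges[nz[, 2]] + same$diff_edges[nz[, 2] + 1L]) / 2
  expect_true(all(abs(mid) < 1))       # all mass on the zero-difference row

  cshift <- bland_altman_binned(a + 2, a, n_bins = 10L, sample_frac = 1,
                                seed = 4)
  expect_equal(cshift$mean_difference, 2, tolerance = 1e-12)
  expect_equal(cshift$loa, c(2, 2), tolerance = 1e-12)

  b <- a + rnorm(5000, sd = 0.1)
  r1 <- bland_altman_binned(a, b, sample_frac = 0.1, seed = 9)
  r2 <- bland_altman_binned(a, b, sample_frac = 0.1, seed = 9)
  expect_identical(r1$counts, r2$counts)
  expect_equal(r1$n, 500L)
  # direct oracle on the full sample
  full <- bland_altman_binned(a, b, sample_frac = 1)
  expect_equal(full$mean_difference, mean(a - b), tolerance = 1e-14)
  expect_equal(full$loa,
               mean(a - b) + c(-1.96, 1.96) * sd(a - b),
               tolerance = 1e-12)
  expect_equal(sum(full$counts), 5000L)
  expect_error(bland_altman_binned(a, b, sample_frac = 0), "sample_frac")
})

test_that("t-score maps equal the Welch statistic", {
  set.seed(18)
  before <- array(rnorm(20 * 4 * 4), dim = c(20, 4, 4))
  after <- array(rnorm(15 * 4 * 4, mean = 0.5, sd = 2), dim = c(15, 4, 4))
  tm <- tscore_map(before, after)
  for (i in c(1L, 3L)) for (j in c(2L, 4L)) {
    oracle <- t.test(after[, i, j], before[, i, j],
                     var.equal = FALSE)$statistic
    expect_equal(tm[i, j], unname(oracle), tolerance = 1e-10)
  }
  expect_true(all(tscore_map(before, before) == 0))
  # degenerate zero-variance difference gives +-Inf
  z1 <- array(1, dim = c(5, 2, 2)); z2 <- array(2, dim = c(5, 2, 2))
  expect_true(all(is.infinite(tscore_map(z1, z2))))
  expect_error(tscore_map(before[1, , , drop = FALSE], after),
               "at least 2")
})

test_that("relative Cohen's d ratios match the formula oracle", {
  set.seed(19)
  gb <- array(rnorm(30 * 3 * 3), dim = c(30, 3, 3))
  ga <- gb + 1
  db <- array(rnorm(30 * 3 * 3), dim = c(30, 3, 3))
  da <- db + 0.5
  # drug transition identical to gas transition: ratio 1
  expect_equal(relative_cohens_d(gb, ga, gb, ga),
               matrix(1, 3, 3), tolerance = 1e-12)
  # no drug effect at all: ratio 0
  expect_equal(relative_cohens_d(db, db, gb, ga),
               matrix(0, 3, 3), tolerance = 1e-12)
  rd <- relative_cohens_d(db, da, gb, ga)
  cd <- function(x1, x2) {
    sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x2) - 1) * var(x2)) /
                 (length(x1) + length(x2) - 2))
    (mean(x2) - mean(x1)) / sp
  }
  for (i in 1:3) for (j in 1:3)
    expect_equal(rd[i, j],
                 cd(db[, i, j], da[, i, j]) / cd(gb[, i, j], ga[, i, j]),
                 tolerance = 1e-10)
})

test_that("correlation maps equal centred Pearson correlation", {
  w <- rep(c(0, 1, 0), each = 10)
  s <- array(0, dim = c(30, 2, 2))
  s[, 1, 1] <- 3 * w + 2
  s[, 1, 2] <- -w
  set.seed(20)
  s[, 2, 1] <- w + rnorm(30, sd = 0.5)
  s[, 2, 2] <- 5
  cm <- correlation_map(s, w)
  expect_equal(cm[1, 1], 1, tolerance = 1e-12)
  expect_equal(cm[1, 2], -1, tolerance = 1e-12)
  expect_equal(cm[2, 1], cor(s[, 2, 1], w), tolerance = 1e-12)
  expect_true(is.na(cm[2, 2]))
  expect_error(correlation_map(s, w[1:10]), "lengths differ")
})

test_that("Fisher-Z comparison matches the formula and its symmetries", {
  eq <- fisher_z_compare(0.4, 50, 0.4, 80)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  a <- fisher_z_compare(0.5, 103, 0.3, 103)
  b <- fisher_z_compare(0.3, 103, 0.5, 103)
  expect_equal(a$z, -b$z, tolerance = 1e-14)
  want <- (atanh(0.5) - atanh(0.3)) / sqrt(2 / 100)
  expect_equal(a$z, want, tolerance = 1e-12)
  expect_equal(a$p, 2 * pnorm(-abs(want)), tolerance = 1e-12)
  expect_error(fisher_z_compare(1, 50, 0.2, 50), "rho")
  expect_error(fisher_z_compare(0.5, 3, 0.2, 50), "sample sizes")
})

test_that("the 7-parameter gas model is recovered from its own output", {
  t <- seq(0, 216, by = 2)
  p_true <- c(b = 1.2, A1 = 0.9, k1 = 0.08, tau1 = 70,
              A2 = 0.8, k2 = 0.06, tau2 = 140)
  clean <- msotr:::gas_model_eval(p_true, t)
  fit <- fit_gas_model(clean, t)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$parameters - p_true) /
                  pmax(abs(p_true), 1e-6)), 1e-4)

  flat <- fit_gas_model(rep(2.5, length(t)), t)
  expect_true(flat$degenerate)
  expect_equal(unname(flat$parameters["b"]), 2.5)
  expect_equal(unname(flat$parameters["A1"]), 0)
  expect_equal(unname(flat$parameters["A2"]), 0)

  # switching-time shift recovered at SNR 10 (seeded)
  set.seed(23)
  p_shift <- p_true; p_shift["tau1"] <- p_true[["tau1"]] + 30
  sig <- msotr:::gas_model_eval(p_shift, t)
  noisy <- sig + rnorm(length(t), sd = sd(sig) / 10)
  fshift <- fit_gas_model(noisy, t, stimulus_onsets = c(70, 140))
  expect_lt(abs(fshift$parameters[["tau1"]] -
                  (fit$parameters[["tau1"]] + 30)), 2 * 2)
  expect_false(fshift$noncausal)
  expect_error(fit_gas_model(1:10, 1:10), ">= 50")
})
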