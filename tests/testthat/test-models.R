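test_that("curve-sampling weights reproduce in-FOV arc lengths", {
  ts <- tiny_setup()
  # include t = 0 to check the zero-radius row
  tax <- seq(0, max(ts$time_axis), length.out = 96L)
  W <- build_arc_weights_dimmi(ts$coords, ts$geometry, tax,
                               n_curve_samples = 256L)
  nt <- length(tax)
  expect_true(all(W[seq(1, nrow(W), by = nt), ] == 0))  # t = 0 rows

  # uniform image of ones: W 1 = arc length inside the FOV
  ones <- rep(1, ncol(W))
  got <- as.numeric(W %*% ones)
  vs <- ts$geometry$speed_of_sound
  half <- ts$fov / 2
  for (d in c(1L, 7L, 16L)) {
    for (t in seq(8L, nt, by = 7L)) {
      want <- arc_length_in_square(ts$geometry$positions[d, 1],
                                   ts$geometry$positions[d, 2],
                                   vs * tax[t], half)
      if (want > 1e-4 * half)
        expect_equal(got[(d - 1L) * nt + t], want,
                     tolerance = 0.01)
    }
  }

  # Cauchy refinement: doubling the sampling shrinks the change
  set.seed(4)
  img <- matrix(stats::runif(ncol(W)), 20, 20)
  y1 <- as.numeric(build_arc_weights_dimmi(ts$coords, ts$geometry, tax,
                                           64L) %*% as.vector(img))
  y2 <- as.numeric(build_arc_weights_dimmi(ts$coords, ts$geometry, tax,
                                           128L) %*% as.vector(img))
  y4 <- as.numeric(build_arc_weights_dimmi(ts$coords, ts$geometry, tax,
                                           256L) %*% as.vector(img))
  expect_lt(sqrt(sum((y4 - y2)^2)), sqrt(sum((y2 - y1)^2)))
})

test_that("exact arc-length weights partition each circle by pixel cell", {
  ts <- tiny_setup()
  W <- build_arc_weights_cdmmi(ts$coords, ts$geometry, ts$time_axis)
  rs <- Matrix::rowSums(W)
  vs <- ts$geometry$speed_of_sound
  nt <- length(ts$time_axis)
  half <- ts$fov / 2
  scale <- 2 * pi * vs * max(ts$time_axis)
  for (d in seq_len(16L)) for (t in seq(1L, nt, by = 5L)) {
    want <- arc_length_in_square(ts$geometry$positions[d, 1],
                                 ts$geometry$positions[d, 2],
                                 vs * ts$time_axis[t], half)
    expect_equal(rs[(d - 1L) * nt + t], want, tolerance = 1e-10 * scale)
  }

  # circle entirely inside one cell: single entry equal to 2 pi rho
  # (detector at a cell centre so the small circle crosses no cell edge)
  geom0 <- detector_geometry(rbind(c(0.0125, 0.0125), c(0.05, 0),
                                   c(0, 0.05)),
                             speed_of_sound = 1500)
  coords4 <- make_image_coords(4, 0.1)     # 25 mm cells
  tax0 <- c(1e-6, 2e-6)                    # rho = 1.5, 3 mm
  W0 <- build_arc_weights_cdmmi(coords4, geom0, tax0)
  row <- W0[1L, ]
  expect_equal(sum(row != 0), 1)
  expect_equal(sum(row), 2 * pi * 1500 * 1e-6, tolerance = 1e-12)

  # agreement with heavily-refined curve sampling. The two discretizations
  # model the image differently (piecewise-constant cells vs bilinear
  # interpolation), so they coincide only up to the O(h) interpolation gap
  # on smooth images -- a few percent at a 20-pixel grid -- and converge
  # jointly to the analytical signal as resolution grows (see the
  # forward-model benchmark).
  spec <- sample_phantom(n_sources_range = c(1L, 1L),
                         radius_range = c(0.25, 0.25), fov = ts$fov,
                         seed = 31)
  img <- rasterize(spec, ts$coords)$pixels
  Wd <- build_arc_weights_dimmi(ts$coords, ts$geometry, ts$time_axis,
                                n_curve_samples = 4096L)
  yc <- as.numeric(W %*% as.vector(img))
  yd <- as.numeric(Wd %*% as.vector(img))
  expect_lt(rel_l2(yd, yc), 0.05)
})

test_that("assembled models are deterministic linear operators with exact adjoints", {
  ts <- tiny_setup()
  M1 <- assemble_model("cdmmi", ts$coords, ts$geometry, ts$time_axis)
  M2 <- assemble_model("cdmmi", ts$coords, ts$geometry, ts$time_axis)
  expect_identical(M1$matrix, M2$matrix)
  expect_error(assemble_model("other", ts$coords, ts$geometry,
                              ts$time_axis))

  expect_true(all(model_apply(M1, matrix(0, 20, 20)) == 0))

  set.seed(2)
  for (i in 1:5) {
    x <- matrix(rnorm(400), 20, 20)
    y <- matrix(rnorm(16 * 128), 16, 128)
    lhs <- sum(model_apply(M1, x) * y)
    rhs <- sum(x * model_adjoint(M1, y))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  # linearity
  x1 <- matrix(rnorm(400), 20, 20); x2 <- matrix(rnorm(400), 20, 20)
  expect_equal(model_apply(M1, 2 * x1 - 3 * x2),
               2 * model_apply(M1, x1) - 3 * model_apply(M1, x2),
               tolerance = 1e-12)

  # dense oracle at tiny scale
  dense <- as.matrix(M1$matrix)
  v <- rnorm(400)
  expect_equal(as.numeric(M1$matrix %*% v), as.numeric(dense %*% v),
               tolerance = 1e-13)

  # model output on a rasterized phantom approximates the analytical
  # signal (coarse 20-pixel grid: discretization error is still large;
  # the resolution study quantifies the convergence)
  spec <- sample_phantom(n_sources_range = c(2L, 2L), fov = ts$fov,
                         seed = 5)
  pred <- model_apply(M1, rasterize(spec, ts$coords))
  ref <- analytical_signal(spec, ts$geometry, ts$time_axis)$samples
  expect_lt(rel_l2(pred, ref), 0.8)
})

test_that("session model cache returns the assembled operator", {
  ts <- tiny_setup(n_pixels = 10L, n_times = 32L)
  a <- cached_model("cdmmi", ts$coords, ts$geometry, ts$time_axis)
  b <- cached_model("cdmmi", ts$coords, ts$geometry, ts$time_axis)
  expect_identical(a, b)
  expect_identical(a$matrix,
                   assemble_model("cdmmi", ts$coords, ts$geometry,
                                  ts$time_axis)$matrix)
})
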