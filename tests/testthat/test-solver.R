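test_that("grid places uniform nodes within layers and shared interface nodes", {
  g1 <- build_grid(slab_stack(0.1), 3)
  expect_equal(g1$x, c(0, 5e-4, 1e-3))  # {0, L/2, L} in metres
  g <- build_grid(default_layer_stack(), c(4, 4, 4, 4, 6))
  expect_equal(max(g$x), (0.0071 + 0.1) / 100)
  bounds <- cumsum(c(0.001, 0.002, 0.0026, 0.0015, 0.1) / 100)
  expect_true(all(bounds %in% g$x))     # interfaces exactly at cumsums
  expect_true(all(diff(g$x) > 0))
  expect_error(build_grid(default_layer_stack(), 2), "at least 3")
})

test_that("zero input profile yields an identically zero field", {
  f <- solve_diffusion(slab_stack(), constant_profile(0),
                       solver_config(nodes_per_layer = 10, dt_s = 10,
                                     horizon_min = 30))
  expect_true(all(f$C == 0))
  expect_true(all(sensor_series(f)$conc == 0))
})

test_that("closed slab equilibrates to the boundary concentration", {
  f <- solve_diffusion(slab_stack(0.1, 5e-6), constant_profile(2),
                       solver_config(nodes_per_layer = 40, dt_s = 10,
                                     horizon_min = 3000))
  final <- f$C[, ncol(f$C)]
  expect_equal(final, rep(2, length(final)), tolerance = 1e-6)
  expect_equal(f$C[, 1], c(2, rep(0, length(final) - 1)))  # C(x>0, 0) = 0
})

test_that("pre-breakthrough front matches the semi-infinite erfc solution within 1%", {
  D <- 5e-10  # m^2/s (0.1 cm slab at 5e-6 cm^2/s)
  C0 <- 2
  f <- solve_diffusion(slab_stack(0.1, 5e-6), constant_profile(C0),
                       solver_config(nodes_per_layer = 300, dt_s = 0.25,
                                     horizon_min = 2))
  for (tm in c(1, 2)) {
    k <- which.min(abs(f$times_s - tm * 60))
    t <- f$times_s[k]
    # front far from the wall: erfc at x = L is ~1e-5 C0
    ana <- C0 * pracma::erfc(f$grid$x / (2 * sqrt(D * t)))
    expect_lt(max(abs(f$C[, k] - ana)) / C0, 0.01)
  }
})

test_that("discrete mass balance closes against the blood-side influx", {
  f <- solve_diffusion(default_layer_stack(), reference_profile(),
                       coarse_config())
  op <- tracsim:::assemble_operator(f$grid)
  N <- nrow(f$C)
  # interior + wall mass vs theta-weighted flux through the first face
  # (backward Euler: flux evaluated at the new time level)
  mass <- as.numeric(op$vol[-1] %*% f$C[-1, ])
  g1 <- op$Ll[2]  # first-face conductance; u = 0 in the basale
  flux1 <- g1 * (f$C[1, ] - f$C[2, ])
  cum_in <- cumsum(flux1[-1]) * f$config$dt_s
  err <- abs(mass[-1] - cum_in)
  expect_lt(max(err / pmax(cummax(abs(cum_in)), 1e-30)), 0.005)
})

test_that("nonnegative boundary profiles give numerically nonnegative fields", {
  f <- solve_diffusion(default_layer_stack(), reference_profile(),
                       coarse_config())
  expect_gte(min(f$C), -1e-12 * max(f$C))
})

test_that("halving dx and dt changes the sensor series by under 1%", {
  base <- solver_config(nodes_per_layer = c(15, 15, 15, 15, 30), dt_s = 1,
                        horizon_min = 230)
  fine <- solver_config(nodes_per_layer = c(29, 29, 29, 29, 59), dt_s = 0.5,
                        horizon_min = 230)
  s1 <- sensor_series(solve_diffusion(default_layer_stack(),
                                      reference_profile(), base))
  s2 <- sensor_series(solve_diffusion(default_layer_stack(),
                                      reference_profile(), fine))
  v2 <- approx(s2$times_min, s2$conc, xout = s1$times_min)$y
  expect_lt(max(abs(s1$conc - v2)) / max(s1$conc), 0.01)
})

test_that("the response is linear: scaling the input scales the output by k", {
  cfg <- coarse_config(horizon_min = 120)
  k <- 3.7
  p1 <- reference_profile()
  p2 <- piecewise_linear_profile(k * p1$m, p1$t_top, p1$t_max)
  s1 <- sensor_series(solve_diffusion(default_layer_stack(), p1, cfg))
  s2 <- sensor_series(solve_diffusion(default_layer_stack(), p2, cfg))
  expect_equal(s2$conc, k * s1$conc, tolerance = 1e-12)
})

test_that("sensor series is the outermost spatial row, in minutes", {
  f <- solve_diffusion(default_layer_stack(), reference_profile(),
                       coarse_config(horizon_min = 60))
  ss <- sensor_series(f)
  expect_identical(unname(ss$conc), unname(f$C[nrow(f$C), ]))
  expect_equal(ss$times_min, f$times_s / 60)
  gm <- sensor_series(f, node = "gap_mean")
  expect_equal(length(gm$conc), length(ss$conc))
  surf <- sensor_series(f, node = "skin_surface")
  expect_identical(unname(surf$conc),
                   unname(f$C[f$grid$layer_first[5], ]))
})

test_that("layer slices honour the initial condition and layer bounds", {
  f <- solve_diffusion(default_layer_stack(), reference_profile(),
                       coarse_config(horizon_min = 60))
  s0 <- layer_slice(f, "stratum_corneum", 0)
  expect_true(all(s0$conc == 0))
  expect_error(layer_slice(f, "dermis", 10), "unknown layer")
  expect_error(layer_slice(f, "stratum_corneum", 1000), "horizon")
  # slice x-range equals the corneum extent
  expect_equal(range(s0$x_m), c(0.0056, 0.0071) / 100)
})
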