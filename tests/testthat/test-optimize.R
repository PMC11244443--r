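# Tiny data/config so each objective evaluation is one cheap solve.
tiny_fit_setup <- function() {
  cfg <- coarse_config(horizon_min = 120)
  dat <- forward_synthetic(piecewise_linear_profile(0.3, 40, 110),
                           default_layer_stack(), cfg, sigma = 0,
                           every = 60)
  list(cfg = cfg, dat = dat)
}

test_that("the L1 objective matches a direct summation oracle", {
  s <- tiny_fit_setup()
  p <- c(m = 0.25, t_top = 50, t_max = 100)
  got <- objective_l1(p, "piecewise_linear", default_layer_stack(),
                      s$dat, s$cfg)
  ss <- sensor_series(solve_diffusion(default_layer_stack(),
                                      make_profile("piecewise_linear", p),
                                      s$cfg))
  acc <- 0
  for (k in seq_along(s$dat$times_min)) {
    mk <- approx(ss$times_min, ss$conc, xout = s$dat$times_min[k])$y
    acc <- acc + abs(mk - s$dat$conc[k])
  }
  expect_equal(got, acc)
})

test_that("the objective vanishes on self-generated data and adds constants", {
  s <- tiny_fit_setup()
  truth <- c(m = 0.3, t_top = 40, t_max = 110)
  expect_lt(objective_l1(truth, "piecewise_linear", default_layer_stack(),
                         s$dat, s$cfg), 1e-10)
  shifted <- s$dat
  shifted$conc <- shifted$conc + 0.05
  n <- length(shifted$times_min)
  expect_equal(objective_l1(truth, "piecewise_linear",
                            default_layer_stack(), shifted, s$cfg),
               n * 0.05, tolerance = 1e-8)
})

test_that("the objective is invariant to the order of data time points", {
  s <- tiny_fit_setup()
  p <- c(m = 0.2, t_top = 30, t_max = 90)
  perm <- sample(length(s$dat$times_min))
  shuf <- list(times_min = s$dat$times_min[perm], conc = s$dat$conc[perm])
  expect_equal(objective_l1(p, "piecewise_linear", default_layer_stack(),
                            s$dat, s$cfg),
               objective_l1(p, "piecewise_linear", default_layer_stack(),
                            shuf, s$cfg))
})

test_that("invalid parameter vectors are penalized, not fatal", {
  s <- tiny_fit_setup()
  bad <- c(m = 0.3, t_top = 100, t_max = 50)  # t_top >= t_max
  expect_gt(objective_l1(bad, "piecewise_linear", default_layer_stack(),
                         s$dat, s$cfg), 1e9)
})

test_that("Monte Carlo search is seeded, exhaustive and reproducible", {
  s <- tiny_fit_setup()
  box <- default_parameter_box("piecewise_linear", s$dat,
                               scale = input_scale(s$dat,
                                                   default_layer_stack(),
                                                   s$cfg))
  spec1 <- optimization_spec("piecewise_linear", box$lower, box$upper,
                             n_samples = 1, seed = 13)
  mc1 <- monte_carlo_search(spec1, default_layer_stack(), s$dat, s$cfg)
  expect_length(mc1$values, 1)
  expect_equal(mc1$best_value, mc1$values[1])

  spec <- optimization_spec("piecewise_linear", box$lower, box$upper,
                            n_samples = 40, seed = 13)
  a <- monte_carlo_search(spec, default_layer_stack(), s$dat, s$cfg)
  b <- monte_carlo_search(spec, default_layer_stack(), s$dat, s$cfg)
  expect_identical(a, b)                       # bit-identical under the seed
  expect_true(all(a$best_value <= a$values))   # argmin definition
  expect_true(all(a$samples >= rep(box$lower, each = 40) &
                    a$samples <= rep(box$upper, each = 40)))
})

test_that("refinement starting at the optimum stays there", {
  s <- tiny_fit_setup()
  box <- default_parameter_box("piecewise_linear", s$dat,
                               scale = input_scale(s$dat,
                                                   default_layer_stack(),
                                                   s$cfg))
  spec <- optimization_spec("piecewise_linear", box$lower, box$upper,
                            n_samples = 10, seed = 1, maxfun = 90,
                            restarts = 1)
  truth <- c(m = 0.3, t_top = 40, t_max = 110)
  res <- local_refine(truth, spec, default_layer_stack(), s$dat, s$cfg)
  expect_lt(res$objective, 1e-8)
  expect_equal(unname(res$params), unname(truth), tolerance = 0.02)
  expect_error(local_refine(box$upper * 2, spec, default_layer_stack(),
                            s$dat, s$cfg), "inside")
})

test_that("the hybrid result is never worse than the Monte Carlo stage", {
  s <- tiny_fit_setup()
  fit <- fit_profile("piecewise_linear", s$dat,
                     stack = default_layer_stack(), config = s$cfg,
                     seed = 21, n_samples = 60)
  expect_lte(fit$objective, fit$mc_best_value)
  expect_gte(fit$objective, 0)
  again <- fit_profile("piecewise_linear", s$dat,
                       stack = default_layer_stack(), config = s$cfg,
                       seed = 21, n_samples = 60)
  expect_identical(fit$params, again$params)   # reproducible end to end
})

test_that("scaling data and box by k scales Monte Carlo objectives by k", {
  s <- tiny_fit_setup()
  box <- default_parameter_box("piecewise_linear", s$dat,
                               scale = input_scale(s$dat,
                                                   default_layer_stack(),
                                                   s$cfg))
  k <- 2.5
  dat_k <- list(times_min = s$dat$times_min, conc = k * s$dat$conc)
  spec <- optimization_spec("piecewise_linear", box$lower, box$upper,
                            n_samples = 25, seed = 8)
  box_k <- list(lower = box$lower * c(k, 1, 1), upper = box$upper * c(k, 1, 1))
  spec_k <- optimization_spec("piecewise_linear", box_k$lower, box_k$upper,
                              n_samples = 25, seed = 8)
  a <- monte_carlo_search(spec, default_layer_stack(), s$dat, s$cfg)
  b <- monte_carlo_search(spec_k, default_layer_stack(), dat_k, s$cfg)
  expect_equal(b$values, k * a$values, tolerance = 1e-10)
})

test_that("optimization specs validate their box and demand a seed", {
  expect_error(optimization_spec("piecewise_linear",
                                 c(m = 1, t_top = 10, t_max = 50),
                                 c(m = 0.5, t_top = 20, t_max = 100),
                                 seed = 1), "lower < upper")
  expect_error(optimization_spec("piecewise_linear",
                                 c(m = 0, t_top = 10, t_max = 50),
                                 c(m = Inf, t_top = 20, t_max = 100),
                                 seed = 1), "finite")
  expect_error(optimization_spec("piecewise_linear",
                                 c(m = 0, t_top = 10, t_max = 50),
                                 c(m = 1, t_top = 20, t_max = 100)),
               "seed")
})
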