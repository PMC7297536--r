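test_that("bound trajectories follow the hyperbolic collapse with clamping", {
  bt <- bound_trajectory(a = 2, tau = 1, t = c(0, 0.5, 1, 2, 5))
  expect_equal(bt$a_up[1], 2)            # starts at a
  expect_equal(bt$a_down[1], 0)
  expect_equal(bt$a_up[2], 4 / 3)        # direct evaluation at t = tau/2
  expect_equal(bt$a_down[2], 2 / 3)
  expect_equal(bt$a_up[3], 1)            # bounds meet at a/2 at t = tau
  expect_equal(bt$a_down[3], 1)
  expect_true(all(bt$a_up[4:5] == 1))    # and stay met
  expect_error(bound_trajectory(1, 1, -0.1), "must be >= 0")

  const <- bound_trajectory(1.5, Inf, c(0, 3))
  expect_equal(const$a_up, c(1.5, 1.5))
  expect_equal(const$a_down, c(0, 0))
})

test_that("simulator matches analytic first-passage probability and timing", {
  # unbiased symmetric diffusion: P(yes) = 1/2
  s0 <- simulate_ddm(ddm_params(v = 0, a = 1, t0 = 0), n_trials = 20000,
                     seed = 11)
  expect_lt(abs(mean(s0$choice == 1) - 0.5), 3 * sqrt(0.25 / 20000))

  # drifted: P(upper) = (1 - exp(-2 v z)) / (1 - exp(-2 v a)) = 0.7311
  s1 <- simulate_ddm(ddm_params(v = 1, a = 1, t0 = 0.3),
                     n_trials = 20000, seed = 12)
  p_ana <- (1 - exp(-1)) / (1 - exp(-2))
  expect_lt(abs(mean(s1$choice == 1) - p_ana),
            3 * sqrt(p_ana * (1 - p_ana) / 20000))

  # zero-drift mean decision time z (a - z) / s^2 = 0.25 s
  expect_lt(abs(mean(s0$rt) - 0.25), 3 * sd(s0$rt) / sqrt(20000))
})

test_that("collapsing bounds force termination by tau + t0", {
  p <- ddm_params(v = 0, a = 1, t0 = 0.2, tau_urgency = 1.5)
  sim <- simulate_ddm(p, n_trials = 5000, seed = 13)
  expect_true(all(is.finite(sim$rt)))
  expect_true(all(sim$rt <= 1.5 + 0.2 + 1e-9))
  expect_false(any(sim$censored))
})

test_that("rt_quantiles returns interpolated order-statistic edges", {
  e <- rt_quantiles(1:10)
  expect_equal(e[3], 5.5)
  expect_length(e, 5)
  expect_true(all(diff(e) >= 0))
  # degenerate input: all edges equal
  expect_true(all(rt_quantiles(rep(2, 10)) == 2))
  # large-sample match with analytic quantiles of an exponential
  set.seed(14)
  x <- qexp(runif(200000))
  expect_lt(max(abs(rt_quantiles(x) -
                      qexp(c(.1, .3, .5, .7, .9)))), 0.02)
  expect_warning(rt_quantiles(1:3), "collapsing")
})

test_that("G-square statistic matches the hand formula", {
  # observed proportional to expected: 0
  expect_equal(gsquare_statistic(c(50, 50), c(0.5, 0.5)), 0)
  # O = [10, 0], p = [.5, .5]: 2 * 10 * ln 2
  expect_equal(gsquare_statistic(c(10, 0), c(0.5, 0.5)), 20 * log(2))
  # linear in counts at fixed proportions
  g1 <- gsquare_statistic(c(30, 10), c(0.5, 0.5))
  g3 <- gsquare_statistic(3 * c(30, 10), c(0.5, 0.5))
  expect_equal(g3, 3 * g1)
  expect_error(gsquare_statistic(c(-1, 2), c(0.5, 0.5)), "negative")
})

test_that("conditional response function separates bias mechanisms", {
  crf_all_yes <- conditional_response_function(rep(1, 100),
                                               runif(100, 0.3, 1))
  expect_true(all(crf_all_yes$frac_yes == 1))

  sym <- simulate_ddm(ddm_params(v = 0, a = 1, t0 = 0.3),
                      n_trials = 20000, seed = 15)
  crf <- conditional_response_function(sym$choice, sym$rt)
  expect_true(all(abs(crf$frac_yes - 0.5) < 0.05))

  # starting point loads on the fastest quantile; drift bias shifts all
  sp <- simulate_ddm(ddm_params(v = 0, a = 1, z_rel = 0.65, t0 = 0.3),
                     n_trials = 20000, seed = 16)
  db <- simulate_ddm(ddm_params(v = 0, v_bias = 0.8, a = 1, t0 = 0.3),
                     n_trials = 20000, seed = 17)
  crf_sp <- conditional_response_function(sp$choice, sp$rt)
  crf_db <- conditional_response_function(db$choice, db$rt)
  dev_sp <- crf_sp$frac_yes - 0.5
  expect_gt(dev_sp[1], dev_sp[5] + 0.05)   # front-loaded
  dev_db <- crf_db$frac_yes - 0.5
  expect_true(all(dev_db > 0.05))          # shifted across the range
})

test_that("halving dt barely changes choice probabilities", {
  p <- ddm_params(v = 1, a = 1, t0 = 0.3)
  p1 <- mean(simulate_ddm(p, n_trials = 40000, seed = 18,
                          dt = 0.001)$choice == 1)
  p2 <- mean(simulate_ddm(p, n_trials = 40000, seed = 19,
                          dt = 0.0005)$choice == 1)
  expect_lt(abs(p1 - p2), 0.005 + 2 * sqrt(2 * 0.2 / 40000))
})
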