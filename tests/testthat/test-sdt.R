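test_that("d-prime and criterion match the probit oracle", {
  # HR = FAR = 0.5: no sensitivity, no bias
  m <- sdt_d_prime_criterion(50, 50, 50, 50, correct = FALSE)
  expect_equal(m$d_prime, 0)
  expect_equal(m$criterion, 0)

  # rates chosen so z = +-1: d' = 2, c = 0
  m <- sdt_d_prime_criterion(8413, 10000 - 8413, 1587, 10000 - 1587,
                             correct = FALSE)
  expect_equal(m$d_prime, qnorm(0.8413) - qnorm(0.1587), tolerance = 1e-6)
  expect_lt(abs(m$criterion), 1e-3)

  # HR = 0.9772, FAR = 0.5: d' ~ 2, c ~ -1
  m <- sdt_d_prime_criterion(9772, 228, 5000, 5000, correct = FALSE)
  expect_equal(m$d_prime, qnorm(0.9772) - qnorm(0.5), tolerance = 1e-6)
  expect_equal(m$criterion, -(qnorm(0.9772) + qnorm(0.5)) / 2,
               tolerance = 1e-6)

  # extreme rates survive via the log-linear correction
  m <- sdt_d_prime_criterion(10, 0, 0, 10)
  expect_true(is.finite(m$d_prime) && m$d_prime > 0)
  expect_error(sdt_d_prime_criterion(0, 0, 5, 5), "at least one trial")
})

test_that("composite overall bias reduces to the criterion for one loudness", {
  # d' = 1, c = 0.5: crossing of two unit normals at their midpoint
  m <- list(d_prime = 1, criterion = 0.5)
  cb <- composite_overall_bias(list(m))
  expect_equal(cb$zero_bias_point, 0.5, tolerance = 1e-7)
  expect_equal(cb$choice_point, 1.0)
  expect_equal(cb$overall_bias, 0.5, tolerance = 1e-7)

  # C = Z gives zero overall bias
  m0 <- list(d_prime = 1.2, criterion = 0)   # C = 0.6 = crossing
  cb0 <- composite_overall_bias(list(m0))
  expect_equal(cb0$overall_bias, 0, tolerance = 1e-7)
})

test_that("multi-loudness crossing agrees with a dense-grid oracle", {
  far <- 0.1587
  d <- c(1, 3)
  cc <- -(qnorm(0.5) + qnorm(far)) / 2  # unused guard
  mets <- lapply(d, function(di) {
    hr <- pnorm(di + qnorm(far))
    list(d_prime = qnorm(hr) - qnorm(far),
         criterion = -(qnorm(hr) + qnorm(far)) / 2)
  })
  cb <- composite_overall_bias(mets)
  # C from either loudness must be identical (shared FAR)
  C_each <- vapply(mets, function(m) 0.5 * m$d_prime + m$criterion, 0)
  expect_lt(diff(range(C_each)), 1e-9)
  expect_equal(cb$choice_point, -qnorm(far), tolerance = 1e-9)
  # independent dense-grid sign-change oracle for the crossing
  f <- function(x) (dnorm(x - 1) + dnorm(x - 3)) / 2 - dnorm(x)
  xs <- seq(-3, 5, by = 1e-5)
  fx <- f(xs)
  flip <- which(fx[-1] * fx[-length(fx)] < 0)
  roots <- (xs[flip] + xs[flip + 1]) / 2
  z_oracle <- roots[which.min(abs(roots - 1))]
  expect_equal(cb$zero_bias_point, z_oracle, tolerance = 1e-4)
  expect_equal(cb$overall_bias, cb$choice_point - z_oracle,
               tolerance = 1e-4)
})

test_that("composite bias rejects degenerate or inconsistent inputs", {
  expect_error(composite_overall_bias(list(list(d_prime = -0.5,
                                                criterion = 0.2))),
               "degenerate")
  # criteria not derived from a shared FAR
  bad <- list(list(d_prime = 1, criterion = 0.5),
              list(d_prime = 2, criterion = 0.5))
  expect_error(composite_overall_bias(bad), "inconsistent")
})

test_that("raising hit rates (FAR fixed) liberalizes criterion and bias", {
  far <- 0.2
  bias_at <- function(hr) {
    m <- list(d_prime = qnorm(hr) - qnorm(far),
              criterion = -(qnorm(hr) + qnorm(far)) / 2)
    composite_overall_bias(list(m))$overall_bias
  }
  b <- vapply(c(0.6, 0.7, 0.8, 0.9), bias_at, 0)
  expect_true(all(diff(b) < 0))
})

test_that("bias shift metrics summarize suppression toward zero", {
  out <- bias_shift_metrics(c(-0.4, -0.1), overall_bias = -0.3)
  expect_equal(out$shift, 0.3)
  expect_equal(out$abs_bias, c(0.4, 0.1))
  expect_true(out$flipped)           # liberal subject sign-flipped
  expect_equal(out$bias_flipped, c(0.4, 0.1))
  same <- bias_shift_metrics(c(0.2, 0.2, 0.2), overall_bias = 0.2)
  expect_equal(same$shift, 0)
  expect_equal(same$slope, 0, tolerance = 1e-12)
  expect_error(bias_shift_metrics(0.1, 0.1), "two bins")
})
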