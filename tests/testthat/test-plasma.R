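test_that("the default input starts at zero, peaks at end of infusion, and is continuous", {
  cp <- default_input()
  expect_equal(plasma_conc(cp, 0), 0)
  expect_equal(plasma_conc(cp, 1), 100)
  # continuity at the end of infusion
  d <- abs(plasma_conc(cp, 1 - 1e-9) - plasma_conc(cp, 1 + 1e-9))
  expect_lt(d, 1e-5)
  expect_lt(abs(cp$amplitude * (1 - exp(-cp$alpha)) - sum(cp$coef)), 1e-12)
  # unimodal: rises during infusion, strictly decreases after
  tt <- seq(0, 1, by = 0.005)
  expect_true(all(diff(plasma_conc(cp, tt)) > 0))
  tt <- seq(1, 90, by = 0.05)
  expect_true(all(diff(plasma_conc(cp, tt)) < 0))
})

test_that("piecewise evaluation matches a direct hand computation", {
  cp <- default_input()
  A <- 100 / (1 - exp(-6))
  expect_equal(plasma_conc(cp, 0.5), A * (1 - exp(-3)))
  hand <- function(t) 76 * exp(-2 * (t - 1)) + 18 * exp(-0.2 * (t - 1)) +
    6 * exp(-0.012 * (t - 1))
  expect_equal(plasma_conc(cp, 5), hand(5))
  expect_equal(plasma_conc(cp, 40), hand(40))
})

test_that("time vectors must be sorted and non-negative", {
  cp <- default_input()
  expect_error(plasma_conc(cp, c(2, 1)), "sorted")
  expect_error(plasma_conc(cp, -1), "non-negative")
  expect_error(conv_exp_input(cp, 0.1, c(3, 2)), "sorted")
  expect_error(conv_exp_input(cp, -0.1, 5), "non-negative")
})

test_that("closed-form exponential convolution matches adaptive quadrature", {
  cp <- default_input()
  for (theta in c(0.05, 0.18, 2.0)) {
    for (t in c(0.5, 5, 40, 90)) {
      expect_lt(abs(conv_exp_input(cp, theta, t) -
                      quad_conv_oracle(cp, theta, t)) /
                  quad_conv_oracle(cp, theta, t), 1e-6)
    }
  }
  # theta = 0 is the running integral of the input
  expect_lt(abs(plasma_integral(cp, 40) - quad_conv_oracle(cp, 0, 40)) /
              quad_conv_oracle(cp, 0, 40), 1e-8)
  # kernel rate coincident with an input decay rate (degenerate branch)
  mu2 <- cp$rates[2]
  expect_lt(abs(conv_exp_input(cp, mu2, 40) -
                  quad_conv_oracle(cp, mu2, 40)) /
              quad_conv_oracle(cp, mu2, 40), 1e-6)
})

test_that("constructor enforces validity and continuity", {
  expect_error(plasma_input(100, 6, c(50, 30, 20), c(2, 0.2, 0.01)),
               "discontinuous")
  expect_error(plasma_input(100, -1, c(1, 1, 1), c(2, 0.2, 0.01)),
               "positive")
  expect_error(default_input(rates = c(2, 2, 0.01)), "distinct")
})

test_that("the plasma model is recovered from noise-free samples", {
  cp <- default_input()
  # 27-sample arterial schedule: 10 x 10 s, 1 x 30 s, 9 x 2 min,
  # 6 x 10 min, 1 x 5 min
  dur <- c(rep(10 / 60, 10), 0.5, rep(2, 9), rep(10, 6), 5)
  times <- cumsum(dur)
  expect_length(times, 27L)
  fit <- fit_plasma_input(times, plasma_conc(cp, times))
  expect_true(attr(fit, "converged"))
  tt <- seq(0, 85, by = 0.1)
  rms <- sqrt(mean((plasma_conc(fit, tt) - plasma_conc(cp, tt))^2))
  expect_lt(rms, 0.001 * 100)   # < 0.1% of the peak
  expect_equal(fit$rates, cp$rates, tolerance = 1e-3)
})

test_that("a single-exponential decay is fitted gracefully", {
  times <- c(seq(0.2, 1, by = 0.2), seq(2, 80, by = 4))
  vals <- ifelse(times <= 1, 50 * (1 - exp(-5 * times)) / (1 - exp(-5)),
                 50 * exp(-0.15 * (times - 1)))
  fit <- fit_plasma_input(times, vals)
  pred <- plasma_conc(fit, times)
  expect_lt(sqrt(mean((pred - vals)^2)), 0.005 * max(vals))
})
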