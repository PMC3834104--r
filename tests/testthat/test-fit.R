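cp <- default_input()
sch <- pib_schedule()

test_that("fit weights follow duration, decay and amplitude exactly", {
  s <- frame_schedule(c(0, 1, 3), c(1, 2, 2))
  x <- tac(s, c(10, 10, 5))
  w <- frame_weights(x, lambda = 0)       # isolate the duration term
  expect_equal(w[2] / w[1], 2)            # same C and t-decay, double dt
  x2 <- tac(s, c(10, 20, 5))
  w2 <- frame_weights(x2, lambda = lambda_c11)
  dt <- s$duration; tm <- s$mid; C <- x2$values
  expect_equal(w2[1] / w2[2],
               (dt[1] * exp(-lambda_c11 * tm[1]) / C[1]) /
                 (dt[2] * exp(-lambda_c11 * tm[2]) / C[2]))
  expect_equal(max(w2), 1)
  # w * sigma^2 is constant across frames (weights are 1/sigma^2 up to a
  # constant) for values above the weight floor
  x3 <- tac_1t(0.18, 0.18, cp, sch)
  w3 <- frame_weights(x3)
  sg <- noise_sigma(x3$values, sch$duration, sch$mid, 0.1, floor = 0)
  prod <- w3 * sg^2
  expect_lt(diff(range(prod)) / mean(prod), 1e-10)
})

test_that("every fitter recovers its own noise-free generating parameters", {
  ref <- tac_1t(0.18, 0.18, cp, sch)
  f1 <- fit_1t(ref, cp)
  expect_lt(max(abs(coef(f1) / c(0.18, 0.18) - 1)), 0.001)
  t3 <- tac_2t_irr(0.18, 0.18, 0.018, cp, sch)
  f3 <- fit_2t_irr(t3, cp)
  expect_lt(max(abs(coef(f3) / c(0.18, 0.18, 0.018) - 1)), 0.001)
  t4 <- tac_2t_rev(0.18, 0.18, 0.018, 0.018, cp, sch)
  f4 <- fit_2t_rev(t4, cp)
  expect_lt(max(abs(coef(f4) / c(0.18, 0.18, 0.018, 0.018) - 1)), 0.005)
  # reference-input fit: quadrature-limited recovery
  fr <- fit_ref3p(t3, ref, k2r_fixed = 0.18)
  expect_lt(max(abs(coef(fr) / c(1, 0.18, 0.018) - 1)), 0.02)
  expect_true(all(vapply(list(f1, f3, f4, fr), function(f) f$converged,
                         TRUE)))
})

test_that("estimates are never negative, even on noisy or degenerate data", {
  base <- tac_2t_rev(0.18, 0.18, 0.018, 0.018, cp, sch)
  ref <- tac_1t(0.18, 0.18, cp, sch)
  for (i in 1:5) {
    noisy <- add_noise(base, 0.3, seed = i)
    expect_true(all(coef(fit_2t_irr(noisy, cp)) >= 0))
    expect_true(all(coef(fit_ref3p(noisy, ref, 0.18)) >= 0))
    expect_true(all(coef(fit_2t_rev(noisy, cp)) >= 0))
  }
  # all-zero TAC drives K1 to the lower bound
  f0 <- fit_1t(tac(sch, rep(0, 19)), cp)
  expect_lt(coef(f0)[["K1"]], 1e-8)
})

test_that("nested models: a 2P-generated TAC yields k3 ~ 0 in the 3P fit, and a 4P truth biases the truncated 3P fit low", {
  ref <- tac_1t(0.18, 0.18, cp, sch)
  f <- fit_2t_irr(ref, cp)
  expect_gte(coef(f)[["k3"]], 0)
  expect_lt(coef(f)[["k3"]], 1e-4)
  # dissociation during the 40-min window truncates into negative k3 bias
  t4 <- tac_2t_rev(0.18, 0.18, 0.018, 0.018, cp, sch)
  f3 <- fit_2t_irr(t4, cp)
  expect_lt(coef(f3)[["k3"]], 0.018)
  # k4 = 0 truth pins the 4P k4 estimate at the bound
  t3 <- tac_2t_irr(0.18, 0.18, 0.018, cp, sch)
  expect_lt(coef(fit_2t_rev(t3, cp))[["k4"]], 1e-4)
})

test_that("weighted RSS is monotone under model nesting on a common window", {
  noisy <- add_noise(tac_2t_rev(0.18, 0.18, 0.018, 0.018, cp, sch),
                     0.1, seed = 9)
  r2 <- fit_1t(noisy, cp, window_end = 40)$rss
  r3 <- fit_2t_irr(noisy, cp, window_end = 40)$rss
  r4 <- fit_2t_rev(noisy, cp, window_end = 40)$rss
  expect_lte(r4, r3 * (1 + 1e-8))
  expect_lte(r3, r2 * (1 + 1e-8))
})

test_that("rate constants are invariant to a common amplitude rescaling", {
  base <- tac_2t_irr(0.18, 0.18, 0.018, cp, sch)
  f <- fit_2t_irr(base, cp)
  cp10 <- plasma_input(cp$amplitude * 10, cp$alpha, cp$coef * 10,
                       cp$rates, cp$t_infusion)
  base10 <- tac(sch, base$values * 10)
  f10 <- fit_2t_irr(base10, cp10)
  expect_equal(coef(f10), coef(f), tolerance = 1e-6)
  # K1 scales with the TAC/input amplitude ratio
  f_half <- fit_2t_irr(tac(sch, base$values / 2), cp)
  expect_equal(coef(f_half)[["K1"]], coef(f)[["K1"]] / 2,
               tolerance = 1e-4)
  expect_equal(coef(f_half)[["k3"]], coef(f)[["k3"]], tolerance = 1e-4)
})

test_that("multi-start fitting is deterministic", {
  noisy <- add_noise(tac_2t_rev(0.18, 0.18, 0.018, 0.018, cp, sch),
                     0.1, seed = 5)
  f1 <- fit_2t_irr(noisy, cp)
  f2 <- fit_2t_irr(noisy, cp)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$rss, f2$rss)
})

test_that("a reference fitted to itself returns R1 = 1 and k3 = 0", {
  ref <- tac_1t(0.18, 0.18, cp, sch)
  f <- fit_ref3p(ref, ref, k2r_fixed = 0.18)
  expect_equal(coef(f)[["R1"]], 1, tolerance = 1e-6)
  expect_lt(coef(f)[["k3"]], 1e-8)
})

test_that("blood-pool correction subtracts the vascular fraction per frame", {
  tissue <- tac_1t(0.18, 0.18, cp, sch)
  blood <- tac(sch, plasma_conc(cp, mid_times(sch)), "blood")
  expect_equal(blood_pool_correct(tissue, blood, 0)$values, tissue$values)
  zero <- tac(sch, rep(0, 19), "blood")
  expect_equal(blood_pool_correct(tissue, zero, 0.05)$values,
               tissue$values)
  expect_equal(blood_pool_correct(tissue, tissue, 0.05)$values,
               0.95 * tissue$values)
  short <- tac(frame_schedule(0, 1), 1)
  expect_error(blood_pool_correct(tissue, short), "schedule")
})

test_that("the reference-trapping correction is an exact sum", {
  expect_equal(k3_prime(0.01, 0), 0.01)
  expect_equal(k3_prime(0, 0.008), 0.008)
  expect_equal(k3_prime(0.005, 0.007), 0.012)
  expect_error(k3_prime(-0.01, 0), "non-negative")
})

test_that("fit objects support the standard modelling methods", {
  t3 <- tac_2t_irr(0.18, 0.18, 0.018, cp, sch)
  f <- fit_2t_irr(t3, cp)
  expect_named(coef(f), c("K1", "k2", "k3"))
  expect_length(fitted(f), f$frames)
  expect_equal(residuals(f), f$observed - fitted(f))
  expect_lt(max(abs(residuals(f, "weighted"))), 1e-4)
  s <- summary(f)
  expect_s3_class(s, "summary.k3fit")
  expect_output(print(f), "2T irreversible")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})
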