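cp <- default_input()
sch <- pib_schedule()

test_that("model reductions collapse exactly: 4P -> 3P -> 2P", {
  for (p in list(c(0.18, 0.18, 0.018), c(0.1, 0.3, 0.05))) {
    t4 <- tac_2t_rev(p[1], p[2], p[3], 0, cp, sch)
    t3 <- tac_2t_irr(p[1], p[2], p[3], cp, sch)
    expect_lt(rel_err(t4$values, t3$values), 1e-10)
    t3z <- tac_2t_irr(p[1], p[2], 0, cp, sch)
    t1 <- tac_1t(p[1], p[2], cp, sch)
    expect_lt(rel_err(t3z$values, t1$values), 1e-10)
    t4z <- tac_2t_rev(p[1], p[2], 0, 0.02, cp, sch)
    expect_lt(rel_err(t4z$values, t1$values), 1e-10)
  }
  # k2 = 0: pure trapping
  expect_lt(rel_err(tac_2t_irr(0.2, 0, 0.03, cp, sch)$values,
                    0.2 * plasma_integral(cp, mid_times(sch))), 1e-12)
  expect_equal(tac_1t(0, 0.2, cp, sch)$values, rep(0, 19))
})

test_that("forward models agree with a stiff-ODE oracle over a parameter grid", {
  skip_if_not_installed("deSolve")
  tm <- mid_times(sch)
  grid <- expand.grid(K1 = c(0.12, 0.18, 0.24), k2 = c(0.12, 0.18, 0.24),
                      k3 = c(0.009, 0.018, 0.036))
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    o <- ode_tac_oracle(g$K1, g$k2, g$k3, 0.018, cp, tm)
    v <- tac_2t_rev(g$K1, g$k2, g$k3, 0.018, cp, sch)$values
    worst <- max(worst, rel_err(v, o))
  }
  expect_lt(worst, 1e-4)
  # irreversible and one-tissue baselines
  expect_lt(rel_err(tac_2t_irr(0.18, 0.18, 0.018, cp, sch)$values,
                    ode_tac_oracle(0.18, 0.18, 0.018, 0, cp, tm)), 1e-4)
  expect_lt(rel_err(tac_1t(0.18, 0.18, cp, sch)$values,
                    ode_tac_oracle(0.18, 0.18, 0, 0, cp, tm)), 1e-4)
})

test_that("the repeated-eigenvalue branch matches the ODE oracle", {
  skip_if_not_installed("deSolve")
  # k3 = 0, k2 = k4 makes the two eigenrates coincide
  tm <- mid_times(sch)
  v <- tac_2t_rev(0.18, 0.02, 0, 0.02, cp, sch)$values
  o <- ode_tac_oracle(0.18, 0.02, 0, 0.02, cp, tm)
  expect_lt(rel_err(v, o), 1e-4)
})

test_that("TAC operators are linear in the input amplitude", {
  cp2 <- plasma_input(cp$amplitude * 2, cp$alpha, cp$coef * 2, cp$rates,
                      cp$t_infusion)
  expect_equal(tac_2t_rev(0.18, 0.18, 0.018, 0.018, cp2, sch)$values,
               2 * tac_2t_rev(0.18, 0.18, 0.018, 0.018, cp, sch)$values,
               tolerance = 1e-12)
  expect_equal(tac_1t(0.18, 0.18, cp2, sch)$values,
               2 * tac_1t(0.18, 0.18, cp, sch)$values, tolerance = 1e-12)
})

test_that("reference working equation collapses to identity when target = reference kinetics", {
  ref <- tac_1t(0.18, 0.18, cp, sch)
  pred <- ref_forward(1, 0.18, 0, 0.18, ref, window_end = 40)
  keep <- mid_times(sch) <= 40
  expect_equal(pred, ref$values[keep], tolerance = 1e-12)
})

test_that("expanded working-equation coefficients match the delta-form kernel", {
  # kernel: R1 [delta(t) + c0 + c1 exp(-theta t)] (*) Cr with
  # c0 = k2r k3 / theta, c1 = k2r - k2 - k2r k3 / theta; the expanded form
  # uses -k2 (theta - k2r) / theta for the convolution coefficient.
  for (p in list(c(k2 = 0.15, k3 = 0.02, k2r = 0.18),
                 c(k2 = 0.3, k3 = 0.005, k2r = 0.1))) {
    theta <- p[["k2"]] + p[["k3"]]
    c1 <- p[["k2r"]] - p[["k2"]] - p[["k2r"]] * p[["k3"]] / theta
    expect_equal(c1, -p[["k2"]] * (theta - p[["k2r"]]) / theta,
                 tolerance = 1e-14)
  }
  # and the prediction assembled from the delta-form coefficients equals
  # ref_forward, using the same grid quadrature
  ref <- tac_1t(0.18, 0.18, cp, sch)
  keep <- mid_times(sch) <= 40
  t <- c(0, mid_times(sch)[keep]); crv <- c(0, ref$values[keep])
  n <- length(t); dt <- diff(t)
  cum <- c(0, cumsum(dt * (crv[-1] + crv[-n]) / 2))
  R1 <- 0.9; k2 <- 0.15; k3 <- 0.02; k2r <- 0.18
  theta <- k2 + k3
  c0 <- k2r * k3 / theta
  c1 <- k2r - k2 - k2r * k3 / theta
  conv <- numeric(n)
  for (i in 2:n) {
    e <- exp(-theta * (t[i] - t[1:i])) * crv[1:i]
    conv[i] <- sum(dt[1:(i - 1)] * (e[-1] + e[-i])) / 2
  }
  delta_form <- R1 * (crv + c0 * cum + c1 * conv)[-1]
  expect_equal(ref_forward(R1, k2, k3, k2r, ref, 40), delta_form,
               tolerance = 1e-12)
})

test_that("reference prediction converges to the plasma-input 3P curve as the grid refines", {
  pred_err <- function(h) {
    nfr <- round(40 / h)
    fine <- frame_schedule(seq(0, by = h, length.out = nfr),
                           rep(h, nfr))
    ref <- tac_1t(0.18, 0.18, cp, fine)
    tgt <- tac_2t_irr(0.16, 0.15, 0.025, cp, fine)
    pred <- ref_forward(0.16 / 0.18, 0.15, 0.025, 0.18, ref)
    sel <- mid_times(fine) > 2
    max(abs(pred[sel] - tgt$values[sel]) / tgt$values[sel])
  }
  e1 <- pred_err(0.5)
  e2 <- pred_err(0.25)
  expect_lt(e1, 0.01)            # < 1% at frame mid-times past 2 min
  expect_gt(e1 / e2, 3.5)        # empirical order >= 2
})

test_that("k3 = 0 reduces the working equation to its algebraic special case", {
  ref <- tac_1t(0.18, 0.2, cp, sch)
  R1 <- 1.2; k2 <- 0.25; k2r <- 0.18
  keep <- mid_times(sch) <= 40
  t <- c(0, mid_times(sch)[keep]); crv <- c(0, ref$values[keep])
  n <- length(t); dt <- diff(t)
  conv <- numeric(n)
  for (i in 2:n) {
    e <- exp(-k2 * (t[i] - t[1:i])) * crv[1:i]
    conv[i] <- sum(dt[1:(i - 1)] * (e[-1] + e[-i])) / 2
  }
  special <- R1 * (crv - (k2 - k2r) * conv)[-1]
  expect_equal(ref_forward(R1, k2, 0, k2r, ref, 40), special,
               tolerance = 1e-12)
})

test_that("degenerate window and rate inputs are handled", {
  ref <- tac_1t(0.18, 0.18, cp, sch)
  expect_error(ref_forward(1, 0.1, 0.01, 0.18, ref, window_end = 0.05),
               "empty fit window")
  # theta = 0 with nonzero k2r: series limit Cr + k2r * integral
  keep <- mid_times(sch) <= 40
  t <- c(0, mid_times(sch)[keep]); crv <- c(0, ref$values[keep])
  n <- length(t); dt <- diff(t)
  cum <- c(0, cumsum(dt * (crv[-1] + crv[-n]) / 2))
  expect_equal(ref_forward(1, 0, 0, 0.18, ref, 40),
               (crv + 0.18 * cum)[-1], tolerance = 1e-12)
})
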