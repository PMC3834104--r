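# Independent oracles used across the test files.

# Stiff-ODE oracle for the two-tissue compartment system driven by a
# parametric plasma input; returns total tissue concentration at `times`.
ode_tac_oracle <- function(K1, k2, k3, k4, input, times) {
  derivs <- function(t, y, p) {
    cp <- plasma_conc(input, t)
    list(c(K1 * cp - (k2 + k3) * y[1] + k4 * y[2],
           k3 * y[1] - k4 * y[2]))
  }
  out <- deSolve::lsoda(c(0, 0), c(0, times), derivs, parms = NULL,
                        rtol = 1e-10, atol = 1e-13)
  rowSums(out[-1, 2:3, drop = FALSE])
}

# Adaptive-quadrature oracle for the exponential-kernel convolution of the
# plasma input.
quad_conv_oracle <- function(input, theta, t) {
  cpv <- function(u) vapply(u, function(x) plasma_conc(input, x), 0)
  stats::integrate(function(u) exp(-theta * (t - u)) * cpv(u), 0, t,
                   rel.tol = 1e-10, subdivisions = 2000L)$value
}

rel_err <- function(x, ref) {
  scale <- pmax(abs(ref), 1e-8 * max(abs(ref)))
  max(abs(x - ref) / scale)
}
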