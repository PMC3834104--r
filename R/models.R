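#' Frame-wise time-activity curve
#'
#' A TAC binds one concentration value per frame mid-time to a
#' [frame_schedule()]. Values may be negative (after noise addition) but
#' must be finite.
#'
#' @param schedule a [frame_schedule()].
#' @param values numeric vector, one value per frame.
#' @param label free-text region label (e.g. "target", "reference").
#' @return An object of class `"tac"`.
#' @export
tac <- function(schedule, values, label = "") {
  stopifnot(inherits(schedule, "frame_schedule"))
  values <- as.numeric(values)
  if (length(values) != length(schedule$start))
    stop("'values' must have one entry per frame")
  if (anyNA(values) || any(!is.finite(values)))
    stop("TAC values must be finite")
  structure(list(schedule = schedule, values = values,
                 label = as.character(label)[1L]),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("TAC '%s': %d frames, range [%.4g, %.4g]\n",
              x$label, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  cbind(as.data.frame(x$schedule), value = x$values)
}

.check_rates <- function(...) {
  v <- c(...)
  if (anyNA(v) || any(!is.finite(v))) stop("rate constants must be finite")
  if (any(v < 0)) stop("rate constants must be non-negative")
  invisible(v)
}

#' One-tissue compartment (2P) model TAC
#'
#' `Ct(t) = K1 * int_0^t exp(-k2 (t - tau)) Cp(tau) dtau`, evaluated at the
#' frame mid-times. This is the model applied to the reference tissue,
#' whose specific binding is negligible.
#'
#' @param K1 blood-to-tissue transport constant (mL/g/min).
#' @param k2 tissue-to-blood efflux rate (1/min).
#' @param input a [plasma_input()].
#' @param schedule a [frame_schedule()].
#' @param label TAC label.
#' @return A [tac()].
#' @export
tac_1t <- function(K1, k2, input, schedule = pib_schedule(),
                   label = "reference") {
  .check_rates(K1, k2)
  tm <- mid_times(schedule)
  tac(schedule, K1 * conv_exp_input(input, k2, tm), label)
}

#' Two-tissue irreversible (3P) model TAC
#'
#' The `k4 = 0` two-tissue model with total tissue concentration
#' `Ct = K1 * ((k3/theta) * int Cp + (k2/theta) * conv(theta))`,
#' `theta = k2 + k3`. For `theta = 0` the model reduces to pure trapping
#' `K1 * int Cp`.
#'
#' @inheritParams tac_1t
#' @param k3 binding (trapping) rate constant (1/min).
#' @export
tac_2t_irr <- function(K1, k2, k3, input, schedule = pib_schedule(),
                       label = "target") {
  .check_rates(K1, k2, k3)
  tm <- mid_times(schedule)
  theta <- k2 + k3
  v <- if (theta < 1e-9) {
    K1 * plasma_integral(input, tm)
  } else {
    K1 * ((k3 / theta) * plasma_integral(input, tm) +
            (k2 / theta) * conv_exp_input(input, theta, tm))
  }
  tac(schedule, v, label)
}

#' Two-tissue reversible (4P) model TAC
#'
#' Standard two-tissue compartment solution with eigenrates
#' `alpha_{1,2} = ((k2+k3+k4) -/+ sqrt((k2+k3+k4)^2 - 4 k2 k4)) / 2`:
#' `Ct = K1/(alpha2-alpha1) * ((k3+k4-alpha1) conv(alpha1) +
#' (alpha2-k3-k4) conv(alpha2))`. The repeated-eigenvalue case is handled
#' by its analytic limit (a `t * exp(-alpha t)` kernel).
#'
#' @inheritParams tac_2t_irr
#' @param k4 dissociation rate constant (1/min).
#' @export
tac_2t_rev <- function(K1, k2, k3, k4, input, schedule = pib_schedule(),
                       label = "target") {
  .check_rates(K1, k2, k3, k4)
  tm <- mid_times(schedule)
  tac(schedule, .tac_2t_rev_values(K1, k2, k3, k4, input, tm), label)
}

.tac_2t_rev_values <- function(K1, k2, k3, k4, input, tm) {
  if (k4 < 1e-12) {
    theta <- k2 + k3
    if (theta < 1e-9) return(K1 * plasma_integral(input, tm))
    return(K1 * ((k3 / theta) * plasma_integral(input, tm) +
                   (k2 / theta) * conv_exp_input(input, theta, tm)))
  }
  beta <- k2 + k3 + k4
  disc <- beta^2 - 4 * k2 * k4   # = (k2-k4)^2 + k3*(k3 + 2*k2 + 2*k4) >= 0
  root <- sqrt(max(disc, 0))
  a1 <- (beta - root) / 2
  a2 <- (beta + root) / 2
  if (root < 1e-9) {
    cv <- .conv_plasma(input, a1, tm, deriv = TRUE)
    # limit of the two-exponential form as a2 -> a1
    return(K1 * (cv$value + (k3 + k4 - a1) * (-cv$dtheta)))
  }
  K1 / root * ((k3 + k4 - a1) * .conv_plasma(input, a1, tm) +
                 (a2 - k3 - k4) * .conv_plasma(input, a2, tm))
}

# Precompute the grid quantities the working equation needs for a reference TAC
# restricted to a fit window: mid-time grid with a virtual (t=0, Cr=0)
# origin sample, trapezoid weights, cumulative integral and the pairwise
# time-difference matrix.
.ref_precompute <- function(reference, window_end) {
  stopifnot(inherits(reference, "tac"))
  tm <- mid_times(reference$schedule)
  keep <- tm <= window_end + 1e-9
  if (!any(keep)) stop("empty fit window: no frame mid-time <= window_end")
  t <- c(0, tm[keep])
  cr <- c(0, reference$values[keep])
  n <- length(t)
  dt <- diff(t)
  cum <- c(0, cumsum(dt * (cr[-1L] + cr[-n]) / 2))
  list(t = t, cr = cr, n = n, dt = dt, cum = cum,
       tdiff = outer(t, t, "-"), keep = keep)
}

# Evaluate the expanded reference-tissue working equation on a precomputed
# grid. Both integral terms use trapezoid quadrature on the discrete
# mid-time grid (origin sample prepended), without interpolation.
.ref_predict <- function(R1, k2, k3, k2r, pre) {
  theta <- k2 + k3
  if (theta < 1e-9) {
    # series limit of the kernel as k2, k3 -> 0
    pred <- pre$cr + k2r * pre$cum
  } else {
    g <- exp(-theta * pre$tdiff) * rep(pre$cr, each = pre$n)
    conv <- numeric(pre$n)
    for (i in 2:pre$n)
      conv[i] <- sum(pre$dt[1:(i - 1L)] *
                       (g[i, 2:i] + g[i, 1:(i - 1L)])) / 2
    pred <- pre$cr + (k2r * k3 / theta) * pre$cum -
      (k2 * (theta - k2r) / theta) * conv
  }
  R1 * pred[-1L]
}

#' Reference-tissue working-equation prediction
#'
#' Predicts the target-tissue TAC from a reference-tissue TAC under the
#' three-parameter reference-tissue model for a nearly irreversible tracer:
#' \deqn{C_t(t) = R_1\Big[C_r(t) + \frac{k_{2r} k_3}{k_2+k_3}\int_0^t C_r\,
#' d\tau - \frac{k_2 (k_2+k_3-k_{2r})}{k_2+k_3}\int_0^t
#' e^{-(k_2+k_3)(t-\tau)} C_r(\tau)\, d\tau\Big].}
#' The running integral and the exponential convolution are computed by
#' trapezoid quadrature directly on the frame mid-time grid (with a virtual
#' origin sample at `t = 0`, `Cr = 0`), without interpolating the data.
#'
#' @param R1 ratio of target to reference `K1` (unitless).
#' @param k2 target efflux rate (1/min).
#' @param k3 target binding rate (1/min).
#' @param k2r reference efflux rate (1/min); a fixed constant of the
#'   analysis, not a free parameter.
#' @param reference reference-tissue [tac()].
#' @param window_end only frames with mid-time `<= window_end` (minutes)
#'   are used; defaults to the full schedule.
#' @return Predicted target concentrations at the retained frame mid-times.
#' @export
ref_forward <- function(R1, k2, k3, k2r, reference, window_end = NULL) {
  .check_rates(R1, k2, k3, k2r)
  if (is.null(window_end)) window_end <- max(mid_times(reference$schedule))
  pre <- .ref_precompute(reference, window_end)
  .ref_predict(R1, k2, k3, k2r, pre)
}
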