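#' Carbon-11 decay constant
#'
#' `log(2) / 20.385` per minute, used by the frame-based PET noise model
#' and the fitting weights.
#' @export
lambda_c11 <- log(2) / 20.385

#' Frame-wise noise standard deviation of a PET measurement
#'
#' The count-statistics noise model for a decay-corrected frame value `Ci`
#' acquired over duration `dt` centred at time `t`:
#' \deqn{\sigma_i = \epsilon \sqrt{C_i / (\Delta t_i\, e^{-\lambda t_i})},}
#' so that the weighted-least-squares weights
#' `w_i = dt_i * exp(-lambda * t_i) / C_i` are proportional to
#' `1 / sigma_i^2`.
#'
#' @param values frame concentrations (noise-free at generation time).
#' @param dt frame durations (minutes), > 0.
#' @param t frame mid-times (minutes).
#' @param epsilon unitless noise scale, >= 0.
#' @param lambda isotope decay constant (1/min), default [lambda_c11].
#' @param floor lower bound applied to `values` inside the square root;
#'   default `1e-6 * max(values)` guards early near-zero frames.
#' @return Per-frame standard deviations.
#' @export
noise_sigma <- function(values, dt, t, epsilon, lambda = lambda_c11,
                        floor = NULL) {
  stopifnot(all(dt > 0), epsilon >= 0, lambda > 0)
  if (is.null(floor)) floor <- 1e-6 * max(values, 0)
  epsilon * sqrt(pmax(values, floor) / (dt * exp(-lambda * t)))
}

#' Add frame-based PET noise to a TAC
#'
#' Adds independent Gaussian perturbations `Rand * sigma(Ci)` per frame,
#' with `sigma` from [noise_sigma()] computed on the noise-free values.
#' Negative noisy values are retained. Reproducible under a fixed seed.
#'
#' @param x a noise-free [tac()].
#' @param epsilon noise scale (unitless); the simulation studies use
#'   levels 0.025 to 0.3 with 0.1 as the working level.
#' @param seed optional integer seed for the Gaussian draws.
#' @param lambda isotope decay constant (1/min).
#' @return A [tac()] with perturbed values.
#' @export
#' @examples
#' noisy <- add_noise(tac_1t(0.18, 0.18, default_input()), 0.1, seed = 1)
add_noise <- function(x, epsilon, seed = NULL, lambda = lambda_c11) {
  stopifnot(inherits(x, "tac"), epsilon >= 0)
  if (!is.null(seed)) set.seed(seed)
  sig <- noise_sigma(x$values, x$schedule$duration, x$schedule$mid,
                     epsilon, lambda)
  tac(x$schedule, x$values + stats::rnorm(length(x$values)) * sig, x$label)
}

#' Frame weights for weighted least squares
#'
#' `w_i = dt_i * exp(-lambda * t_i) / Ci`, normalised so the maximum weight
#' is 1 (the proportionality constant is arbitrary). Measured (possibly
#' noisy) frame values are used, with a positive floor
#' `floor_frac * max(Ci)` to keep near-zero or negative frames from
#' dominating.
#'
#' @param x a [tac()].
#' @param lambda isotope decay constant (1/min).
#' @param floor_frac floor on `Ci` as a fraction of the TAC maximum.
#' @return Per-frame weights, maximum 1.
#' @export
frame_weights <- function(x, lambda = lambda_c11, floor_frac = 1e-3) {
  stopifnot(inherits(x, "tac"))
  mx <- max(x$values)
  floor <- if (mx > 0) floor_frac * mx else 1e-12
  w <- x$schedule$duration * exp(-lambda * x$schedule$mid) /
    pmax(x$values, floor)
  w / max(w)
}
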