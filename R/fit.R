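#' @importFrom stats rnorm sd coef fitted residuals predict lm setNames
NULL

# Multi-start bounded Levenberg-Marquardt on weighted residuals.
# `starts` is a matrix with one start per row (named columns); the best
# weighted RSS wins, with ties (relative difference < 1e-9) broken by the
# smaller k3 when the model has one.
.wnls <- function(resid_fn, starts, lower, upper, maxiter = 200) {
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(starts[r, ], lower), upper)
    fit <- try(minpack.lm::nls.lm(
      par = p0, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                           ftol = 1e-10, ptol = 1e-10)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (!is.finite(rss)) next
    cand <- list(par = setNames(fit$par, colnames(starts)), rss = rss,
                 info = fit$info, niter = fit$niter, hessian = fit$hessian)
    if (is.null(best)) { best <- cand; next }
    tol <- 1e-9 * max(best$rss, .Machine$double.eps)
    if (rss < best$rss - tol) {
      best <- cand
    } else if (abs(rss - best$rss) <= tol && "k3" %in% colnames(starts) &&
               cand$par[["k3"]] < best$par[["k3"]]) {
      best <- cand
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")
  best$converged <- best$info %in% 1:4
  best
}

.start_grid <- function(...) {
  g <- expand.grid(..., KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

.fit_window <- function(x, window_end) {
  tm <- mid_times(x$schedule)
  keep <- tm <= window_end + 1e-9
  if (!any(keep)) stop("empty fit window")
  keep
}

.new_k3fit <- function(model, best, window_end, times, observed, weights,
                       fitted, extra = list(), call = sys.call(-1)) {
  structure(c(list(model = model, coefficients = best$par,
                   rss = best$rss, converged = best$converged,
                   iterations = best$niter, window = window_end,
                   frames = length(times), times = times,
                   observed = observed, weights = weights,
                   fitted = fitted, hessian = best$hessian,
                   call = call), extra),
            class = "k3fit")
}

#' Fit the one-tissue (2P) model to a TAC
#'
#' Weighted nonlinear least squares of `K1`, `k2` under non-negativity
#' bounds, with weights `dt * exp(-lambda t) / Ci` from [frame_weights()].
#' Used for the reference tissue, whose specific binding is negligible.
#'
#' @param x a target [tac()].
#' @param input a [plasma_input()].
#' @param window_end fit window end (minutes); frames with mid-time beyond
#'   it are excluded. Default 40.
#' @param lambda isotope decay constant for the weights (1/min).
#' @return A `"k3fit"` object; see [coef.k3fit()], [summary.k3fit()].
#' @export
#' @examples
#' cp <- default_input()
#' ref <- tac_1t(0.18, 0.18, cp)
#' coef(fit_1t(ref, cp))
fit_1t <- function(x, input, window_end = 40, lambda = lambda_c11) {
  keep <- .fit_window(x, window_end)
  if (sum(keep) < 4L) stop("at least 4 frames are required")
  t <- mid_times(x$schedule)[keep]
  y <- x$values[keep]
  w <- frame_weights(x, lambda)[keep]
  w <- w / max(w)
  sw <- sqrt(w)
  fn <- function(p) sw * (p[1L] * .conv_plasma(input, p[2L], t) - y)
  best <- .wnls(fn, .start_grid(K1 = c(0.05, 0.15, 0.3),
                                k2 = c(0.05, 0.15, 0.3)),
                lower = c(0, 0), upper = c(2, 2))
  fitted <- best$par[[1L]] * .conv_plasma(input, best$par[[2L]], t)
  .new_k3fit("1T (2P)", best, window_end, t, y, w, fitted)
}

.pred_2t_irr <- function(p, input, t, cum) {
  theta <- p[2L] + p[3L]
  if (theta < 1e-9) return(p[1L] * cum)
  p[1L] * ((p[3L] / theta) * cum +
             (p[2L] / theta) * .conv_plasma(input, theta, t))
}

#' Fit the irreversible two-tissue (3P) model to a TAC
#'
#' The short-scan plasma-input analysis for nearly irreversible kinetics:
#' `K1`, `k2`, `k3` estimated by weighted NLS under non-negativity bounds
#' over an early fit window (default 40 min) where dissociation is
#' negligible. Multi-start over a coarse grid guards against local minima.
#'
#' @inheritParams fit_1t
#' @export
fit_2t_irr <- function(x, input, window_end = 40, lambda = lambda_c11) {
  keep <- .fit_window(x, window_end)
  if (sum(keep) < 5L) stop("at least 5 frames are required")
  t <- mid_times(x$schedule)[keep]
  y <- x$values[keep]
  w <- frame_weights(x, lambda)[keep]
  w <- w / max(w)
  sw <- sqrt(w)
  cum <- plasma_integral(input, t)
  fn <- function(p) sw * (.pred_2t_irr(p, input, t, cum) - y)
  best <- .wnls(fn, .start_grid(K1 = c(0.05, 0.15, 0.3),
                                k2 = c(0.05, 0.15, 0.3),
                                k3 = c(0.005, 0.02, 0.05)),
                lower = c(0, 0, 0), upper = c(2, 2, 2))
  .new_k3fit("2T irreversible (3P)", best, window_end, t, y, w,
             .pred_2t_irr(best$par, input, t, cum))
}

#' Fit the reversible two-tissue (4P) model to a TAC
#'
#' The standard full-scan plasma-input analysis: `K1` to `k4` estimated by
#' weighted NLS under non-negativity bounds, default window 90 min.
#'
#' @inheritParams fit_1t
#' @export
fit_2t_rev <- function(x, input, window_end = 90, lambda = lambda_c11) {
  keep <- .fit_window(x, window_end)
  if (sum(keep) < 6L) stop("at least 6 frames are required")
  t <- mid_times(x$schedule)[keep]
  y <- x$values[keep]
  w <- frame_weights(x, lambda)[keep]
  w <- w / max(w)
  sw <- sqrt(w)
  fn <- function(p)
    sw * (.tac_2t_rev_values(p[1L], p[2L], p[3L], p[4L], input, t) - y)
  best <- .wnls(fn, .start_grid(K1 = c(0.05, 0.15, 0.3),
                                k2 = c(0.05, 0.15, 0.3),
                                k3 = c(0.005, 0.02, 0.05),
                                k4 = c(0.005, 0.02)),
                lower = c(0, 0, 0, 0), upper = c(2, 2, 2, 2))
  fitted <- .tac_2t_rev_values(best$par[[1L]], best$par[[2L]],
                               best$par[[3L]], best$par[[4L]], input, t)
  .new_k3fit("2T reversible (4P)", best, window_end, t, y, w, fitted)
}

#' Fit the reference-tissue model (noninvasive k3 estimation)
#'
#' Fits the three-parameter reference-tissue working equation (see
#' [ref_forward()]) of a nearly irreversible tracer to a target TAC, using
#' a reference-region TAC in place of the arterial input. The reference
#' efflux rate `k2r` is fixed (not estimated) for stable convergence;
#' `R1 = K1/K1r`, `k2` and `k3` are free, bounded below by 0. Weights come
#' from the target TAC.
#'
#' @param x target [tac()].
#' @param reference reference [tac()] on the same schedule.
#' @param k2r_fixed fixed reference efflux rate (1/min). The clinical
#'   default is 0.178/min (population mean cerebellar k2); the simulation
#'   studies use 0.18/min.
#' @inheritParams fit_1t
#' @return A `"k3fit"` with coefficients `R1`, `k2`, `k3`.
#' @export
#' @examples
#' cp <- default_input()
#' tacs <- make_baseline_tacs(baseline_params("NC"), cp)
#' fit_ref3p(tacs$target, tacs$reference, k2r_fixed = 0.18)
fit_ref3p <- function(x, reference, k2r_fixed = 0.178, window_end = 40,
                      lambda = lambda_c11) {
  stopifnot(inherits(reference, "tac"))
  if (length(reference$values) != length(x$values) ||
      max(abs(mid_times(reference$schedule) - mid_times(x$schedule))) > 1e-9)
    stop("target and reference TACs must share one schedule")
  .check_rates(k2r_fixed)
  keep <- .fit_window(x, window_end)
  if (sum(keep) < 5L) stop("at least 5 frames are required")
  t <- mid_times(x$schedule)[keep]
  y <- x$values[keep]
  w <- frame_weights(x, lambda)[keep]
  w <- w / max(w)
  sw <- sqrt(w)
  pre <- .ref_precompute(reference, window_end)
  fn <- function(p) sw * (.ref_predict(p[1L], p[2L], p[3L], k2r_fixed, pre) - y)
  best <- .wnls(fn, .start_grid(R1 = c(0.5, 1, 1.5),
                                k2 = c(0.05, 0.15, 0.3),
                                k3 = c(0.005, 0.02, 0.05)),
                lower = c(0, 0, 0), upper = c(2, 2, 2))
  fitted <- .ref_predict(best$par[[1L]], best$par[[2L]], best$par[[3L]],
                         k2r_fixed, pre)
  .new_k3fit("reference 3P (3P++)", best, window_end, t, y, w, fitted,
             extra = list(k2r_fixed = k2r_fixed))
}

#' Blood-pool correction of a tissue TAC
#'
#' Removes the intravascular activity fraction from a measured tissue
#' curve: `corrected = measured - vb * blood`, per frame. The simulation
#' studies do not use it (simulated TACs contain no vascular term); it is
#' provided for measured data, where `vb` is conventionally 0.05.
#'
#' @param tissue measured tissue [tac()].
#' @param blood blood-pool [tac()] on the same schedule.
#' @param vb blood volume fraction in `[0, 1)`.
#' @return Corrected [tac()].
#' @export
blood_pool_correct <- function(tissue, blood, vb = 0.05) {
  stopifnot(inherits(tissue, "tac"), inherits(blood, "tac"),
            vb >= 0, vb < 1)
  if (max(abs(mid_times(tissue$schedule) - mid_times(blood$schedule))) > 1e-9)
    stop("tissue and blood TACs must share one schedule")
  tac(tissue$schedule, tissue$values - vb * blood$values, tissue$label)
}

#' Reference-trapping correction of the noninvasive k3 estimate
#'
#' When the reference tissue itself traps tracer at rate `k3r`, the
#' reference-input `k3` estimate is biased low; the empirical correction
#' adds the reference trapping rate back: `k3' = k3 + k3r`.
#'
#' @param k3 noninvasive (reference-input) k3 estimate (1/min).
#' @param k3r reference-tissue trapping rate (1/min), e.g. its k3 estimate
#'   from a plasma-input 3P fit.
#' @return Corrected `k3'` (1/min).
#' @export
k3_prime <- function(k3, k3r) {
  .check_rates(k3, k3r)
  k3 + k3r
}
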