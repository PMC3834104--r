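#' @export
print.k3fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit, %d frames (0-%g min window)\n",
              x$model, x$frames, x$window))
  print(signif(x$coefficients, digits))
  cat(sprintf("weighted RSS %.6g; %s in %d iterations\n", x$rss,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' @export
coef.k3fit <- function(object, ...) object$coefficients

#' @export
fitted.k3fit <- function(object, ...) object$fitted

#' Residuals of a kinetic model fit
#' @param object a `"k3fit"`.
#' @param type `"response"` (observed minus fitted) or `"weighted"`
#'   (scaled by the square root of the fit weights).
#' @param ... unused.
#' @export
residuals.k3fit <- function(object, type = c("response", "weighted"), ...) {
  type <- match.arg(type)
  r <- object$observed - object$fitted
  if (type == "weighted") r <- r * sqrt(object$weights)
  r
}

#' @export
predict.k3fit <- function(object, ...) object$fitted

#' Summary of a kinetic model fit
#'
#' Reports estimates with approximate standard errors from the weighted
#' Jacobian at the solution (Gauss-Newton approximation; errors at an
#' active non-negativity bound are not meaningful and are flagged).
#'
#' @param object a `"k3fit"`.
#' @param ... unused.
#' @export
summary.k3fit <- function(object, ...) {
  p <- object$coefficients
  n <- object$frames
  k <- length(p)
  se <- rep(NA_real_, k)
  if (n > k && !is.null(object$hessian)) {
    # Gauss-Newton covariance from the optimizer's J'J at the solution
    se <- tryCatch(
      sqrt(diag(solve(object$hessian)) * object$rss / (n - k)),
      error = function(e) rep(NA_real_, k))
  }
  out <- list(model = object$model, coefficients = p, se = se,
              rss = object$rss, converged = object$converged,
              frames = n, window = object$window,
              at_bound = names(p)[p <= 1e-10])
  class(out) <- "summary.k3fit"
  out
}

#' @export
print.summary.k3fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit over 0-%g min (%d frames)\n", x$model, x$window,
              x$frames))
  tab <- data.frame(Estimate = signif(x$coefficients, digits),
                    Std.Error = signif(x$se, digits))
  print(tab)
  cat(sprintf("Weighted RSS: %.6g (%s)\n", x$rss,
              if (x$converged) "converged" else "not converged"))
  if (length(x$at_bound))
    cat("At lower bound:", paste(x$at_bound, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a kinetic model fit
#'
#' Observed frame values (points) and the fitted model curve (line) over
#' the fit window.
#'
#' @param x a `"k3fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.k3fit <- function(x, ...) {
  graphics::plot(x$times, x$observed, xlab = "time (min)",
                 ylab = "concentration", main = x$model, ...)
  graphics::lines(x$times, x$fitted, col = "firebrick", lwd = 2)
  graphics::legend("bottomright", legend = c("data", "fit"), bty = "n",
                   pch = c(1, NA), lty = c(NA, 1),
                   col = c("black", "firebrick"))
  invisible(x)
}
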