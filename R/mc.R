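#' Coefficient of variation in percent
#'
#' `CV(%) = (SD / mean) * 100` with the sample (n-1) standard deviation.
#' Returns `NA` with a warning when the mean is numerically zero.
#'
#' @param x numeric vector of estimates.
#' @return CV in percent.
#' @export
#' @examples
#' cv_percent(c(8, 12))  # 28.28
cv_percent <- function(x) {
  m <- mean(x)
  if (abs(m) < 1e-12 * max(abs(x), 1e-300)) {
    warning("mean is numerically zero; CV undefined")
    return(NA_real_)
  }
  100 * stats::sd(x) / m
}

#' Bias in percent relative to a known truth
#'
#' `bias(%) = (estimate / truth - 1) * 100`.
#' @param estimate estimated value (or mean of estimates).
#' @param truth generating value, > 0.
#' @export
bias_percent <- function(estimate, truth) {
  stopifnot(truth > 0)
  100 * (estimate / truth - 1)
}

#' Bias of the reference-input k3 relative to the plasma-input k3
#'
#' `bias(%) = (k3_ref / k3_plasma - 1) * 100`, applied to the mean
#' estimates of the two analyses over shared Monte Carlo replicates.
#' @param k3_ref mean reference-input (noninvasive) k3 estimate.
#' @param k3_plasma mean plasma-input short-scan k3 estimate, > 0.
#' @export
bias_percent_rel3p <- function(k3_ref, k3_plasma) {
  stopifnot(k3_plasma > 0)
  100 * (k3_ref / k3_plasma - 1)
}

# Deterministic per-replicate seeds derived from a master seed.
.derive_seeds <- function(seed, n, streams = 2L) {
  stopifnot(is.finite(seed), n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  matrix(sample.int(2147483646L, n * streams), nrow = n)
}

#' Monte Carlo characterisation of the k3 estimators
#'
#' Generates noise-free baseline target and reference TACs, adds seeded
#' frame-based PET noise per replicate, runs the requested analyses on
#' every replicate and summarises the estimates. The same noisy target
#' replicates are shared by all analyses (paired design). Replicates in
#' which any requested analysis fails to converge are dropped pairwise and
#' counted.
#'
#' @param target named vector `c(K1, k2, k3, k4)` generating the target
#'   TAC (two-tissue reversible model).
#' @param reference named vector `c(K1, k2, k3)` generating the reference
#'   TAC (irreversible two-tissue model; `k3 = 0` gives the one-tissue
#'   model).
#' @param input a [plasma_input()]; its amplitude is multiplied by
#'   `amplitude_scale` before TAC generation (the noise model is
#'   count-based, so the amplitude sets the effective noise level).
#' @param schedule a [frame_schedule()].
#' @param epsilon noise scale of [add_noise()].
#' @param n number of replicates (default 100).
#' @param analyses subset of `c("3p", "3ppp", "4p")`: plasma-input
#'   short-scan 3P, reference-input 3P (noninvasive), plasma-input
#'   full-scan 4P.
#' @param noisy_reference logical: perturb the reference TAC as well
#'   (reference-kinetics sweeps) or keep it noise-free (noise and delivery
#'   sweeps).
#' @param k2r_fixed fixed reference efflux rate for the reference-input
#'   analysis (1/min).
#' @param window short-scan fit window (minutes), default 40.
#' @param window_4p full-scan window (minutes), default 90.
#' @param amplitude_scale multiplier on the input amplitude.
#' @param seed master seed; all replicate seeds derive from it.
#' @return An object of class `"mc_result"`: per-replicate estimates per
#'   analysis, convergence counts, and a summary table (mean, SD, CV% per
#'   parameter).
#' @export
run_mc <- function(target = baseline_params("NC")$target,
                   reference = baseline_params("NC")$reference,
                   input = default_input(), schedule = pib_schedule(),
                   epsilon = 0.1, n = 100,
                   analyses = c("3p", "3ppp", "4p"),
                   noisy_reference = FALSE, k2r_fixed = 0.18,
                   window = 40, window_4p = 90,
                   amplitude_scale = 1, seed = 1) {
  analyses <- match.arg(analyses, c("3p", "3ppp", "4p"),
                        several.ok = TRUE)
  stopifnot(n >= 2)
  inp <- scale_input(input, amplitude_scale)
  ref_k3 <- if ("k3" %in% names(reference)) reference[["k3"]] else 0
  target0 <- tac_2t_rev(target[["K1"]], target[["k2"]], target[["k3"]],
                        target[["k4"]], inp, schedule, "target")
  ref0 <- tac_2t_irr(reference[["K1"]], reference[["k2"]], ref_k3, inp,
                     schedule, "reference")
  seeds <- .derive_seeds(seed, n, streams = 2L)
  est <- lapply(analyses, function(a) vector("list", n))
  names(est) <- analyses
  ok <- matrix(TRUE, n, length(analyses), dimnames = list(NULL, analyses))
  for (i in seq_len(n)) {
    tgt <- add_noise(target0, epsilon, seed = seeds[i, 1L])
    ref <- if (noisy_reference)
      add_noise(ref0, epsilon, seed = seeds[i, 2L]) else ref0
    for (a in analyses) {
      f <- switch(a,
        "3p"   = try(fit_2t_irr(tgt, inp, window_end = window),
                     silent = TRUE),
        "3ppp" = try(fit_ref3p(tgt, ref, k2r_fixed = k2r_fixed,
                               window_end = window), silent = TRUE),
        "4p"   = try(fit_2t_rev(tgt, inp, window_end = window_4p),
                     silent = TRUE))
      if (inherits(f, "try-error") || !f$converged) {
        ok[i, a] <- FALSE
      } else {
        est[[a]][[i]] <- coef(f)
      }
    }
  }
  keep <- rowSums(!ok) == 0L
  mats <- lapply(analyses, function(a)
    do.call(rbind, est[[a]][keep]))
  names(mats) <- analyses
  summ <- do.call(rbind, lapply(analyses, function(a) {
    m <- mats[[a]]
    data.frame(analysis = a, parameter = colnames(m),
               mean = colMeans(m), sd = apply(m, 2, stats::sd),
               cv = apply(m, 2, cv_percent), row.names = NULL)
  }))
  structure(list(estimates = mats, summary = summ,
                 n = n, n_used = sum(keep),
                 n_failed = n - sum(keep),
                 config = list(target = target, reference = reference,
                               epsilon = epsilon,
                               noisy_reference = noisy_reference,
                               k2r_fixed = k2r_fixed, window = window,
                               window_4p = window_4p,
                               amplitude_scale = amplitude_scale,
                               seed = seed, analyses = analyses)),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo: %d replicates (%d used, %d non-converged), epsilon = %g\n",
              x$n, x$n_used, x$n_failed, x$config$epsilon))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Extract the k3 column of an analysis from an mc_result
#' @param x an `"mc_result"`.
#' @param analysis one of the analyses run.
#' @return Numeric vector of per-replicate k3 estimates.
#' @export
mc_k3 <- function(x, analysis) {
  stopifnot(inherits(x, "mc_result"))
  m <- x$estimates[[analysis]]
  if (is.null(m)) stop("analysis not present: ", analysis)
  m[, "k3"]
}
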