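#' Baseline simulation parameter sets
#'
#' Typical [11C]PIB rate constants used to generate error-free baseline
#' TACs: target `K1 = 0.180` mL/g/min, `k2 = 0.180`/min, `k4 = 0.018`/min
#' with `k3 = 0.018`/min for a normal-control (NC) cortex and
#' `k3 = 0.036`/min for an Alzheimer's-disease (AD) cortex; the reference
#' (cerebellar) tissue is identical across groups with `K1 = 0.180`,
#' `k2 = 0.180` and no specific binding.
#'
#' @param group `"NC"` or `"AD"`.
#' @return A list with named numeric vectors `target` (K1, k2, k3, k4) and
#'   `reference` (K1, k2, k3).
#' @export
baseline_params <- function(group = c("NC", "AD")) {
  group <- match.arg(group)
  list(group = group,
       target = c(K1 = 0.180, k2 = 0.180,
                  k3 = if (group == "NC") 0.018 else 0.036, k4 = 0.018),
       reference = c(K1 = 0.180, k2 = 0.180, k3 = 0))
}

#' Generate baseline target and reference TACs
#'
#' Target TACs come from the two-tissue reversible (4P) model; reference
#' TACs from the one-tissue (2P) model, or from the irreversible
#' two-tissue (3P) model when a nonzero reference trapping rate `k3` is
#' requested (as in the reference-trapping sensitivity sweep).
#'
#' @param params a list as returned by [baseline_params()]; individual
#'   entries may be overridden before the call.
#' @param input a [plasma_input()].
#' @param schedule a [frame_schedule()].
#' @return A list with elements `target` and `reference`, both [tac()].
#' @export
#' @examples
#' tacs <- make_baseline_tacs(baseline_params("AD"), default_input())
make_baseline_tacs <- function(params = baseline_params("NC"),
                               input = default_input(),
                               schedule = pib_schedule()) {
  tg <- params$target
  rf <- params$reference
  target <- tac_2t_rev(tg[["K1"]], tg[["k2"]], tg[["k3"]], tg[["k4"]],
                       input, schedule, label = "target")
  ref_k3 <- if ("k3" %in% names(rf)) rf[["k3"]] else 0
  reference <- tac_2t_irr(rf[["K1"]], rf[["k2"]], ref_k3, input, schedule,
                          label = "reference")
  list(target = target, reference = reference)
}
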