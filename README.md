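# refk3 — noninvasive k3 estimation for slowly dissociating PET ligands

`refk3` is an R package for compartmental kinetic analysis of dynamic PET
data from *moderately reversible* tracers — ligands with a slow
dissociation rate, k4 ≤ 0.03 /min, of which the amyloid tracer
[11C]Pittsburgh compound B (PIB, k4 = 0.018 /min) is the canonical
example. It is aimed at PET methodologists who want the binding rate
constant **k3** (an index of available binding sites, Bmax·kon) directly,
without arterial blood sampling.

## The estimator

For such tracers, early-phase (≤ 40 min) kinetics are nearly
irreversible, so the two-tissue three-parameter model (K1, k2, k3 with
k4 = 0) fitted to short-scan data gives a more precise k3 than the full
90-min four-parameter fit. `refk3`'s central estimator goes one step
further and replaces the arterial input with a reference-region TAC
Cr(t) (cerebellar grey matter for PIB), fitting the working equation

    Ct(t) = R1 [ Cr(t) + (k2r·k3)/(k2+k3) ∫₀ᵗ Cr dτ
                 − k2·(k2+k3−k2r)/(k2+k3) ∫₀ᵗ e^−(k2+k3)(t−τ) Cr(τ) dτ ]

for R1 = K1/K1r, k2 and k3 by weighted nonlinear least squares under
non-negativity constraints, with the reference efflux rate k2r *fixed* to
a population value (default 0.178 /min) for stable convergence. Weights
are the count-statistics weights wᵢ = Δtᵢ·e^(−λtᵢ)/Cᵢ (λ = 11C decay
constant). Both integrals are evaluated by trapezoid quadrature directly
on the frame mid-time grid, without interpolation.

Around the estimator the package provides closed-form plasma-input
forward models (`tac_1t`, `tac_2t_irr`, `tac_2t_rev`), a parametric
plasma input model with fitting (`fit_plasma_input`), the frame-based PET
noise model (`add_noise`), plasma-input fitters (`fit_1t`, `fit_2t_irr`,
`fit_2t_rev`), and Monte Carlo drivers (`run_mc`, `exp_noise_sweep`,
`exp_k1_sweep`, `exp_k2r_sweep`, `exp_k3r_sweep`) that characterise the
CV and bias of the k3 estimate. See the vignette
(`vignettes/noninvasive-k3.Rmd`) for the model, its assumptions and the
numerical choices.

## Worked example

```r
library(refk3)

cp  <- default_input()                       # synthetic PIB-like plasma input
tacs <- make_baseline_tacs(baseline_params("NC"), cp)   # 4P target + 2P reference
noisy <- add_noise(tacs$target, epsilon = 0.1, seed = 7)

fit <- fit_ref3p(noisy, tacs$reference, k2r_fixed = 0.18)
fit
#> reference 3P (3P++) fit, 14 frames (0-40 min window)
#>      R1      k2      k3
#> 0.96090 0.16380 0.01275
#> weighted RSS 0.555051; converged in 5 iterations
```

The fitted k3 (0.0128 /min) sits ~30% below the generating value
(0.018 /min): that is the expected k4-truncation bias shared with the
plasma-input short-scan analysis — stable across delivery (K1) and
therefore rank-preserving — not a defect of the reference-input step.
Compare the paired plasma-input fit on the same curve:

```r
coef(fit_2t_irr(noisy, cp))
#>         K1         k2         k3
#> 0.17299669 0.16401500 0.01290745
```

A Monte Carlo summary of precision (100 noisy replicates):

```r
mc <- run_mc(epsilon = 0.1, n = 100, analyses = c("3p", "3ppp", "4p"), seed = 1)
subset(mc$summary, parameter == "k3")
#>   analysis parameter       mean           sd        cv
#> 3       3p        k3 0.01240407 0.0008554543  6.896560
#> 6     3ppp        k3 0.01229090 0.0008800835  7.160449
#> 9       4p        k3 0.01803967 0.0020216059 11.206448
```

The reference-input analysis matches the plasma-input short-scan
precision and clearly beats the 90-min 4P analysis, while needing no
blood sampling.

A command-line front end is installed as `exec/petk3`
(`petk3 simulate`, `petk3 fit`, `petk3 mc-experiment`).

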