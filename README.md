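# fnirsdpf

Sensitivity analysis of fNIRS hemodynamic response estimates to the
differential path-length factor (DPF).

## What problem this solves, and for whom

Continuous-wave functional near-infrared spectroscopy (fNIRS) measures
optical-density changes at two near-infrared wavelengths and converts
them to oxy-/deoxy-hemoglobin concentration changes (ΔHbO, ΔHbR)
through the modified Beer-Lambert law (MBLL):

    ΔOD_λ(k) = (ε_HbO,λ ΔHbO(k) + ε_HbR,λ ΔHbR(k)) · d · DPF_λ

The DPF scales the source-detector separation `d` to the true scattered
photon path. It is wavelength- and age-dependent and almost never
measured per subject — analysts assume a value, usually between 3
and 8. This package is for fNIRS methodologists and BCI researchers who
want to know how much that assumption distorts the hemodynamic response
function (HRF) features they go on to use: peak amplitude, time to
peak, full width at half maximum, and post-stimulus undershoot.

At its core sits a twelve-parameter signal model

    y(k) = a0 + a1·HRF(k) + ac·sin(2π fc k) + ar·sin(2π fr k)
         + am·sin(2π fm k) + ε(k),     HRF = (double-gamma h) * (boxcar u)

fitted to the HbO series reconstructed from an optical-density pair by
the fixed-coefficient combination

    y(k) = 0.2170·ΔOD_λ2(k)/DPF_λ2 − 0.1015·ΔOD_λ1(k)/DPF_λ1

under box constraints (cardiac 0.5–1.5 Hz, respiratory 0.2–0.3 Hz,
Mayer 0.09–0.1 Hz, etc.) with a multi-start Nelder-Mead simplex mapped
through a logistic box bijection. Sweeping DPF_λ1 or DPF_λ2 across 3–8
and refitting (or re-reconstructing a sign-constrained optical-density
split) tabulates the DPF-induced drift of every HRF attribute.

## Worked example

```r
library(fnirsdpf)

## a clean synthetic HbO signal: 10 s rest, 20 s task, 30 s rest
paradigm <- simulated_paradigm(20, "St1")
y <- generate_signal(hrf_params(),
                     nuisance_params(ac = 0, ar = 0, am = 0, noise_sd = 0),
                     paradigm, fs = 10)

## split into sign-constrained optical densities (both non-negative)
s <- split_signal(y, "case1")
s
#> <od_split> case1: 601 samples, J1 residual 0, 0.0% infeasible

## reconstruct while the 830 nm DPF is swept; the true pair is implied
## by the model's fixed constants
implied_true_dpf()
#>   dpf_l1   dpf_l2 
#> 6.173966 5.786667

sweep_reconstruct(s, paradigm, dpf_values = c(3, 5.786667, 8), vary = "l2")
#>   label  case   dpf_l1   dpf_l2 peak_value time_to_peak_s   fwhm_s undershoot_depth baseline_offset
#> 1   St1 case1 6.173966 3.000000  14.895883             22 19.33114        1.3924226        3.857778
#> 2   St1 case1 6.173966 5.786667   7.722519             22 19.33114        0.7218781        2.000000
#> 3   St1 case1 6.173966 8.000000   5.585956             22 19.33114        0.5221585        1.446667
```

Reading the table: at the implied true DPF pair (middle row) the
reconstruction is exact — baseline 2 is the generating `a0` and the
peak of 7.72 is `a0 + a1 · max(HRF)` for the generating `a1 = 6`.
Underestimating DPF_λ2 at 3 inflates the whole curve (peak 14.9,
baseline 3.9); overestimating it at 8 deflates both. Times and
widths are untouched here because this sweep rescales a single
wavelength's contribution; the fitted sweeps (`sweep_fit()`,
`run_fit_study()`) show the corresponding shape changes when the full
model is re-estimated per DPF value.

The estimator itself follows standard R modelling conventions:

```r
fit <- fit_hrf(s$pair, paradigm, n_restarts = 8, seed = 1)
coef(fit); summary(fit); plot(fit)
```

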