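# mendfusion

Microbial-enzyme soil carbon modelling and model–data fusion in R.

Whether soils gain or lose organic carbon (SOC) under warming hinges on
microbial physiology — above all the carbon use efficiency (CUE, here the
intrinsic value `Yg` at 20 °C) with which microbes turn assimilated carbon
into biomass. Those parameters are estimated by calibrating decomposition
models against laboratory soil incubations, and estimates differ
systematically between short (days) and long (years) incubations, with
directly opposing consequences for decadal SOC projections. `mendfusion`
is for biogeochemical modellers who want that entire analysis chain as a
tested, reproducible package:

* **Model core** — a microbial-enzyme decomposition model of the MEND
  family with dormancy: ten carbon pools (particulate ×2,
  mineral-associated, dissolved, adsorbed, active/dormant biomass, three
  enzymes) plus cumulative CO₂. Michaelis–Menten decomposition and DOC
  uptake, substrate-gated dormancy, Arrhenius temperature scaling of rates
  (`Ea_V`) and half-saturations (`Ea_K`), and a CUE that declines with
  warming at `kYg = −0.01` °C⁻¹. Carbon is conserved exactly by
  construction; the RHS is compiled C under `deSolve::lsoda`, with a
  pure-R reference implementation tested against it.
* **Scenarios** — closed-jar incubations at 22 °C with a 1%-of-total-C
  glucose or cellulose pulse on the experimental collection schedules
  (`ST_G`: 6 days; `LT_C`: 729 days); steady-state spin-up under constant
  inputs (annual input = 5% of SOC); five-decade ±ΔT warming projections.
* **Calibration** — the weighted objective
  `J = w1·J1 + (1−w1)·J2`, where `J1` scores CO₂ (MARE for ≤10
  observations, otherwise `1 − R²`) and `J2` scores microbial biomass
  (MARE), minimized over the five microbial parameters
  (`r0`, `Vg`, `alpha`, `KD`, `Yg`) by a from-scratch SCE-UA
  (Shuffled Complex Evolution) optimizer with a full evaluation archive.
  Fit gates: MARE ≤ 0.5, R² ≥ 0.6.
* **Uncertainty** — critical-objective-function (COFI) feasible regions,
  `Jcr = Jopt·(1 + p/(n−p)·F(0.05, p, n−p))`; Kruskal–Wallis ensemble
  comparisons; paired t-tests of best fits; a decades-per-decade
  sensitivity index with a steady-state sweep driver.
* **Meta-analysis** — percent (or log response ratio) SOC effect sizes of
  field-warming experiments, summarized overall and by duration bins
  (<1, 1–10, >10 years).
* **Synthetic data** — generators for soils, noisy incubation datasets on
  the real schedules, duration truncations and field-warming tables, so
  every stage of the pipeline runs and is tested without any download.

## Worked example

Generate a noisy two-year cellulose incubation from a known truth,
calibrate, quantify uncertainty, and project warming:

```r
library(mendfusion)
fp   <- fixed_params()
soil <- generate_soil(seed = 42)
#> Soil S1 (forest): SOC 55.7 mg C cm-3 (POC 6.1+12.2, MOC 36.2, DOC 0.175, MBC 1.062)

truth <- microbial_params(r0 = 0.65, Vg = 0.045, alpha = 0.30, KD = 0.03, Yg = 0.35)
data  <- generate_incubation_dataset(soil, truth, schedule = "LT_C",
                                     noise_cv = c(co2 = 0.05, mbc = 0.10), seed = 11)

fit <- calibrate_case(data, fp, max_evals = 5000, seed = 99)
#> Calibration: Jopt = 0.024958 (J1 = 0.0021573 [one_minus_r2], J2 = 0.047759 [mare]), 2061 evals
#>   r0 = 0.6188  Vg = 0.05135 h-1  alpha = 0.1834  KD = 0.3044 mg C cm-3  Yg = 0.3013
check_fit_criteria(fit)
#>   component metric      value threshold pass
#> 1       CO2     R2 0.99784269       0.6 TRUE
#> 2       MBC   MARE 0.04775931       0.5 TRUE

jcr <- cofi_threshold(fit$Jopt, n = fit$n_obs, p = 5)
ens <- feasible_ensemble(fit$archive, jcr)   # 1707 of 2061 archived vectors
cofi_intervals(ens)
#>   parameter          lo         hi      width
#> 1        r0 0.259857254 0.98980304 0.72994578
#> 2        Vg 0.032734287 0.08179206 0.04905778
#> 3     alpha 0.050060281 0.43736538 0.38730510
#> 4        KD 0.007964918 0.36018336 0.35221844
#> 5        Yg 0.260130937 0.46388956 0.20375862

st   <- spin_up(soil, fit$par, fp, T = 20)
proj <- project_warming(st, fit$par, fp, dT = 5, years = 50)
#> Warming projection (+5 degC, 50 y): SOC 22.46 -> 22.84 mg C cm-3 (+1.73%)
```

Reading the output: the calibration reproduces the observations well
within the fit gates (CO₂ R² ≈ 0.998, MBC MARE ≈ 0.048, at the biomass
noise floor), and the COFI intervals show what two years of CO₂ + biomass
data can and cannot pin down — `Vg` tightly, `Yg` to about ±0.1, `KD`
hardly at all. With the recovered long-term parameters (`Yg ≈ 0.30`,
below the model's CUE threshold of ≈0.32), five decades of +5 °C warming
yield a small SOC *gain* (+1.7%): the warming-driven CUE decline
suppresses biomass and enzymes more than the kinetic speed-up accelerates
decomposition. Re-running the projection with a short-incubation-typical
`Yg` of 0.4 flips the sign to a SOC loss — the central scientific point
the package exists to explore (see `yg_response_curve()`).

The duration experiments are one call each: `truncate_dataset()` emulates
shorter incubations, `duration_contrast()` compares COFI interval widths
between a 6-day and the 729-day calibration, `recovery_experiment()`
scores parameter recovery over 20 synthetic datasets, and
`run_experiment()` orchestrates multi-case scenarios from a config (a thin
CLI wrapper ships in `inst/scripts/run_mend.R`).

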