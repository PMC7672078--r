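---
title: "Microbial-enzyme soil carbon modelling and model-data fusion with mendfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbial-enzyme soil carbon modelling and model-data fusion with mendfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Whether soils gain or lose organic carbon under climate warming depends on
microbial physiology — growth, maintenance, dormancy, and above all the
carbon use efficiency (CUE) with which microbes convert assimilated carbon
into biomass. These quantities cannot be measured in situ at scale, so
models obtain them by calibrating against laboratory incubations: jars of
soil amended with a substrate pulse, whose headspace CO~2~ and microbial
biomass carbon (MBC) are sampled over days to years. `mendfusion`
implements the complete model–data fusion chain around a microbial-enzyme
decomposition model of the MEND family: forward simulation, global
calibration, frequentist parameter-uncertainty analysis, warming
projections, and a meta-analysis module for field-warming observations —
plus synthetic-data generators that emulate every raw input, so the whole
chain is testable end to end without any external download.

## The model

The state comprises ten carbon pools (mg C cm^-3^ soil) plus cumulative
respired CO~2~: two particulate pools (`P1` degraded by oxidative enzymes,
`P2` by hydrolytic enzymes), mineral-associated carbon `M`, dissolved
carbon `D`, a mineral-adsorbed dissolved pool `Q`, active and dormant
microbial biomass `BA`/`BD`, and three enzyme pools `EP1`, `EP2`, `EM`.

Decomposition and uptake are Michaelis–Menten: pool `P1` decomposes at
$V_{P1} \cdot EP_1 \cdot P_1/(K_{P1}+P_1)$ (analogously `P2`, `M`), and
active biomass takes up dissolved carbon at
$F_1 = \frac{1}{Y_g}(V_g + V_{mt})\, S \, BA$, where $S = D/(K_D + D)$ is
the substrate saturation, $V_g$ the maximum specific growth rate, $V_{mt}$
the specific maintenance rate and $Y_g$ the intrinsic CUE. Maintenance and
growth respiration are $V_{mt} S\, BA$ and $(1-Y_g)F_1$. Dormancy is gated
by substrate saturation — active biomass goes dormant at $(1-S)V_{mt}BA$,
dormant biomass reactivates at $S\,V_{mt}BD$ and pays a maintenance cost
reduced by the factor $\beta$. Mortality is first order (`rM`), with a
fraction `gD` of necromass routed to dissolved carbon and the rest to
`P2`; a fraction `fD` of decomposed particulate carbon dissolves and the
rest transfers to the mineral pool. Sorption of `D` onto `Q` follows
Langmuir-style kinetics with capacity `Qmax`. Enzyme production is a
first-order drain on active biomass and spent enzymes return to `D`.

Temperature enters three ways: all V-type maximum rates scale by an
Arrhenius factor with energy `Ea_V`, half-saturation constants with
`Ea_K`, sorption rates with `Ea_ads`, and the CUE declines linearly with
warming, $Y_g(T) = Y_g + k_{Yg}(T - T_{ref})$ with $k_{Yg} = -0.01$
°C^-1^ and $T_{ref} = 20$ °C. The five calibrated microbial parameters
are `r0` (initial active fraction), `Vg`, `alpha`
($= V_{mt}/(V_g+V_{mt})$), `KD` and `Yg`; everything else is a fixed
parameter with a default in the versioned `mend_defaults` configuration.

By construction the right-hand side conserves carbon exactly: the sum of
all pool derivatives plus the CO~2~ rate equals the external input. The
test suite asserts this identity at machine precision pointwise and to
1e-6 relative along solved trajectories. Integration uses `deSolve`'s
`lsoda` on a compiled C right-hand side; an identical pure-R reference
implementation is kept and tested against it.

## Default fixed parameters: what is anchored and what is reconstructed

The fixed-parameter defaults are a reconstruction, assembled in three
tiers and recorded in `inst/extdata/mend_defaults.conf`:

* **Literature-anchored kinetics** — decomposition maxima and
  half-saturations (`VP1`, `VP2`, `VM`, `KP1`, `KP2`, `KM`), sorption
  constants (`Kads`, `Kdes`, `Qmax`), the partition fractions
  (`fD = gD = 0.5`), enzyme turnover (`rE`) and `Ea_V` = 47 kJ mol^-1^
  follow the published MEND lineage.
* **Steady-state consistency** — enzyme production rates (`pEP1`, `pEP2`,
  `pEM`) and mortality (`rM`) were derived analytically (before any code
  ran) so that a representative soil (SOC ≈ 30 mg C cm^-3^, annual input
  5% of SOC) equilibrates near its observed composition: biomass 1–2% of
  SOC, enzymes ~1% of biomass, mineral-associated carbon the largest pool.
* **Behaviour-calibrated temperature sensitivity** — the model family has
  a documented default behaviour: the steady-state SOC response to +5 °C
  warming switches sign at $Y_g \approx 0.32$. Under these flux forms a
  shared Arrhenius factor on uptake and decomposition cancels exactly at
  an input-forced steady state, so the threshold location is controlled
  by `Ea_V − Ea_K` and by the non-Arrhenius biomass loss rates. `Ea_K`
  (19 kJ mol^-1^, a plausible mid-range value for half-saturation
  temperature sensitivity) was therefore set jointly with `Ea_V` to place
  that threshold; this is the one default calibrated to a documented model
  behaviour rather than taken from a table.

Two structural consequences are worth knowing. First, the dormant
maintenance factor must be small ($\beta = 10^{-4}$): if dormant
maintenance were comparable to active maintenance, the active-fraction
balance would be pinned by Arrhenius-scaled terms and the warming response
could never change sign — no CUE threshold would exist. Small $\beta$ is
also what dormancy physiology suggests (dormant metabolism is orders of
magnitude below active maintenance). Second, below $V_g \approx 0.002$
h^-1^ growth cannot offset mortality plus enzyme production at any
substrate saturation, biomass collapses, and the input-forced system has
no steady state; the sensitivity driver therefore sweeps `Vg` from 0.002
h^-1^ instead of the calibration prior's 0.001 (the calibration prior
itself is unchanged — closed incubations need no steady state).

## Scenarios

**Incubation** (`run_incubation`) is a closed jar at 22 °C: no external
inputs, a substrate pulse of 1% of total soil carbon at $t = 0$ (glucose
into `D`, cellulose into `P2`), initial pools taken from the soil record
(`Q` starts at 1% of `M`, biomass split `r0`/`1−r0`, enzymes at 1.1, 1.1
and 1.4 × 10^-3^ mg C cm^-3^). Two built-in schedules mirror the
experimental designs: `ST_G` (6 days; CO~2~ at 2–144 h, MBC at 24/72/144
h) and `LT_C` (729 days; 18 CO~2~ and 8 MBC collections). The CO~2~
observable is the mean respiration rate over the interval ending at each
collection — the discrete analogue of a headspace accumulation
measurement; MBC is `BA + BD`.

**Spin-up** (`spin_up`) runs the model under constant forcing (annual
input 5% of initial total carbon, split 0.4/0.4/0.2 between `P1`, `P2`
and `D` — litter is mostly particulate) until every pool derivative is
below 1e-9 h^-1^ relative to its pool. Long `lsoda` chunks approach the
fixed point and a damped Newton iteration on the ten pool balances then
polishes it several orders below the declared tolerance, so that a
50-year projection started from the fixed point drifts by less than
1e-4 relative.

**Projection** (`project_warming`) restarts from the steady baseline and
integrates 50 years at the reference and at the warmed temperature with
identical constant inputs, reporting the relative SOC difference (%) at
the end plus the transient series. `yg_response_curve` repeats the
steady-state comparison across a grid of CUE values; with the default
parameters the response is positive (warming gains carbon) below
$Y_g \approx 0.32$ and negative above — warming both accelerates
decomposition kinetics and lowers CUE, and which effect wins depends on
where on the CUE axis the system sits.

## Calibration and uncertainty

The objective is $J = w_1 J_1 + (1-w_1) J_2$ with $w_1 = 0.5$ by default
(equal weight to both observables). $J_1$ scores the CO~2~ series — MARE
for 10 or fewer observations, otherwise $1 - R^2$ — and $J_2$ is the MARE
of the biomass series. Replicates are averaged before scoring (the fit is
to case-level series). A failed simulation scores `+Inf` so the global
search continues. Satisfactory fits require MARE ≤ 0.5 and R^2^ ≥ 0.6
(both inclusive).

`sce_optimize` implements SCE-UA: a Latin-hypercube sample of
$ngs(2k{+}1)$ points, rank-partitioned complexes, competitive simplex
evolution (reflection, then contraction, then random replacement within
the bounds), shuffling, and a stopping rule of relative improvement below
1e-4 over 10 shuffling loops or an evaluation budget (default 5,000).
Every evaluation is archived.

Uncertainty follows the critical-objective-function construction: the
feasible region is every archived vector with
$J \le J_{cr} = J_{opt}\,(1 + \frac{p}{n-p}F_{0.05,\,p,\,n-p})$, with
$n$ the total number of fitted observations (CO~2~ plus MBC — the
construction does not say which observations count, and using all fitted
points is the natural reading) and $p = 5$. Ensembles from different
calibrations are compared per parameter with the Kruskal–Wallis rank test;
paired best-fit estimates with a classic paired t-test. The sensitivity
index of a steady output $Y$ to a parameter swept across
$[X_{low}, X_{high}]$ is the ratio of decades moved:
$|\log_{10}|Y_{high}| - \log_{10}|Y_{low}|| / |\log_{10}|X_{high}| -
\log_{10}|X_{low}||$. At an input-forced steady state the CO~2~ efflux
equals the input for every parameter set, so its sensitivity index is
essentially zero by construction — the informative outputs are the pools.

## What the synthetic generators emulate — and what they do not

`generate_soil` draws self-consistent initial conditions (SOC 10–60
mg C cm^-3^; MBC 0.5–2%, DOC 0.2–0.6%, mineral-associated 40–70% of SOC;
the particulate remainder split 1:2 between the oxidative and hydrolytic
pools). `generate_incubation_dataset` forward-simulates a schedule and
applies multiplicative lognormal noise per replicate (unit mean; default
CV 10% for CO~2~ and 15% for MBC, the scale of flask-to-flask variation
in incubation data; recovery experiments use 5%/10%). `truncate_dataset`
emulates shorter experiments on the same soil, and `generate_meta_table`
produces a field-warming observation table from per-duration-group means
and standard deviations.

The default meta-table design uses group means −4.8%, 1.4% and 2.8% with
standard deviations 8.4, 4.1 and 9.1 for the <1-year, 1–10-year and
>10-year duration groups, and group sizes (4, 106, 39). The sizes are the
integer solution under which those group means imply an overall mean of
+1.6% across 149 observations while keeping the sub-year group, as in
real warming syntheses, the smallest.

What passing tests on these synthetic data do **not** show: real
incubations have autocorrelated errors, drifting baselines, substrate
impurities and community shifts that no lognormal noise model captures;
real soils violate the generator's independence of fractions; and the
meta-table emulates only the group structure, not study-level covariates
or publication effects. Recovery results here measure the machinery under
its stated noise model, not field performance.

## Numerical choices

* `lsoda` with `rtol = 1e-8`, `atol = 1e-10` for trajectories (relaxed to
  1e-7/1e-9 inside the calibration objective, where thousands of solves
  occur and the objective is noise-dominated well above that level).
* Pools are clamped at zero inside the RHS so fluxes vanish smoothly as a
  pool empties during solver under-shoot; non-finite states are rejected
  at the integration boundary.
* CUE is clipped to (0.001, 0.999) purely to keep the $1/Y_g$ uptake
  prefactor finite; the clip is never active between −10 and 40 °C for
  realistic `Yg`.
* Spin-up caps at 2,000 simulated years and reports the residual if no
  steady state exists (see the `Vg` viability note above).
* Ties in SCE subcomplex selection are broken by the seeded RNG; with a
  seed every run is bit-reproducible.

## Experiment harnesses and problem sizes

`recovery_experiment` (20 synthetic long-term datasets, 5%/10% noise,
SCE budget 5,000 evaluations each) scores parameter recovery and COFI
coverage; `duration_contrast` calibrates a 6-day truncation against the
full 729-day dataset of the same truth and compares feasible-interval
widths; `schedule_contrast` reproduces the short-versus-long comparison
machinery (best-fit differences and ensemble rank tests). These sizes run
the full pipeline at realistic scale in minutes on one CPU; the diagnosed
limit on recovery precision is informational, not computational — the
optimizer routinely attains objective values at or below the truth's own
score, so remaining error reflects the flat CUE/maintenance trade-off
ridge under measurement noise, a known identifiability feature of
total-CO~2~-plus-biomass calibration.

## Known limitations

* The flux forms are one canonical member of the MEND-with-dormancy
  family; alternatives (ungated maintenance, growth-proportional enzyme
  production, a separate reactivation rate) are deliberately centralized
  in `compute_fluxes`/the C RHS so they can be swapped without touching
  calibration or uncertainty code.
* Temperature response is step-change only; no transient forcing,
  moisture response or isotope tracking.
* The meta-analysis is unweighted percent change by design (matching
  mean ± sd reporting); the inverse-variance lnRR mode is provided but is
  only exercised when per-arm variances exist.
* Projections assume constant inputs — a widely used but acknowledged
  simplification.
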