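# depspec

Dual-cycle dielectrophoretic (DEP) collection-rate spectroscopy: estimate
the dielectric properties of nanoparticles from pulsed-DEP collection
kinetics instead of crossover-frequency measurements.

## The problem

When an AC potential is applied to microelectrodes in a nanoparticle
suspension, positive DEP drives particles into the high-field regions and
they accumulate at a rate approximately proportional to the DEP force,
which is itself proportional to the real part of the Clausius–Mossotti
(CM) factor

```
Re[CM](w) = Re[ (e*_p - e*_m) / (e*_p + 2 e*_m) ],   e* = e e0 - i s / w
```

with particle/medium conductivities `s_p`, `s_m` and relative
permittivities `e_p`, `e_m`. `Re[CM]` is bounded in [-0.5, 1], has a
conductivity-controlled low-frequency plateau
`(s_p - s_m)/(s_p + 2 s_m)`, a permittivity-controlled high-frequency
plateau `(e_p - e_m)/(e_p + 2 e_m)`, and — when the two plateaus have
opposite signs — a crossover frequency `f_x` at which the force vanishes.

The classical route to `s_p` measures `f_x` directly, which needs both
pDEP and nDEP, many medium conductivities and much operator time. The
dual-cycle method instead alternates two collection/release cycles per
period: a *control* cycle at a fixed carrier `f1` and a *probe* cycle
whose carrier `f2` hops across the spectrum. The ratio of the probe to
control initial collection rates,

```
rho = (dn/dt)_probe / (dn/dt)_control  ~  m * Re[CM](f2; s_p),
```

cancels shared experimental factors (local concentration, illumination,
gain). Fitting `m * Re[CM]` to the rate ratios by a two-step bivariate
least-squares procedure — line-of-best-fit initialization, then
alternating Newton–Raphson updates of `s_p` with closed-form updates of
`m` — yields the nanoparticle conductivity, hence the surface conductance
`K_s = (s_p - s_b) r / 2`.

The package provides: the CM spectrum and its crossover analysis
(`re_cm`, `crossover_frequency`, `sigma_p_from_crossover`,
`piecewise_linear_cm`); a dual-cycle collection/release simulator with
exactly solvable cyclic steady state (`simulate_number`, `css_state`,
`am_bandwidth`) plus a 1D drift–diffusion oracle (`simulate_mde_1d`);
rate extraction (`extract_dataset`); the bivariate fit (`fit_cm`); and a
Monte-Carlo benchmark of rate-ratio vs crossover estimation
(`run_comparison`). A CLI is installed under `exec/depspec`.

## Worked example

Simulate a synthetic recording session (seven probe frequencies over
1–4 MHz, five dual cycles each, 15% conductivity noise), extract the
rate ratios, and fit:

```r
library(depspec)

p <- dielectric_params(sigma_p = 26e-3, sigma_m = 2e-3, eps_p = 2.55, eps_m = 78)
p
#> Dielectric parameters:
#>   sigma_p = 0.026 S/m, sigma_m = 0.002 S/m
#>   eps_p   = 2.55,     eps_m   = 78 (relative)
#>   crossover f_x = 4.41e+06 Hz

cfg <- run_config(seed = 42)
fx  <- generate_fixture(cfg)
tab <- extract_dataset(fx$traces)        # 28 rate ratios (7 probes x 4 cSS cycles)
fit <- fit_cm(tab, 2e-3, 2.55, 78, control_frequency = 1e6)
fit
#> Scaled-CM rate-ratio fit
#>   sigma_p = 22.59 mS/m (initial 24.56 mS/m)
#>   scale m = 1.53 (initial 0.9325)
#>   crossover estimate = 3.846e+06 Hz
#>   SSE = 0.359 over 28 samples; 12 iterations (newton)

surface_conductance(fit$sigma_p, sigma_b = 0, radius = 100e-9)
#> [1] 1.129588e-09
```

The fitted conductivity (22.6 mS/m here) sits within the expected spread
of the true 26 mS/m for a single 15%-noise session; across many seeds
the median recovery error is below 10% (see the test suite). The fitted
crossover estimate and surface conductance (1.1 nS vs the true 1.3 nS)
follow from the fitted conductivity.

The same pipeline from the shell:

```sh
CLI=$(Rscript -e 'cat(file.path(find.package("depspec"), "exec", "depspec"))')
Rscript $CLI fixture --seed 42 --out-dir fx
Rscript $CLI extract-rates --in-dir fx --out ratios.csv
Rscript $CLI fit-cm --ratios ratios.csv --out fit.json
Rscript $CLI montecarlo --trials 200 --seed 1 --out mc.json
```

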