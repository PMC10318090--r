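# toxpatch

Survival analysis for a single species living on two patches when one patch
receives periodic pulses of an environmental toxicant. The package is aimed
at theoretical ecologists and ecotoxicological modellers who want to ask:
given pulse size and period, toxicokinetics, migration behaviour and
environmental noise, does the population die out, persist in the mean, or
remain stochastically permanent — and does a simulation agree?

## The model

Densities $x_1, x_2$ on the polluted and clean patch follow

$$
\begin{aligned}
dx_1 &= \Big[x_1\big(r_1(t) - a_1 x_1\big) + d_{21}x_2
        - d_{12}\Big(1+\tfrac{\rho c_e^2}{1+\alpha c_e^2}\Big)x_1\Big]dt
        + \sigma_1(t)x_1\,dB_1,\\
dx_2 &= \Big[x_2\big(r_2(t) - a_2 x_2\big)
        + d_{12}\Big(1+\tfrac{\rho c_e^2}{1+\alpha c_e^2}\Big)x_1
        - d_{21}x_2\Big]dt + \sigma_2(t)x_2\,dB_2,
\end{aligned}
$$

with growth rates driven by mean-reverting (Ornstein–Uhlenbeck) noise —
$r_i(t) = r_{ie} + (r_{i0}-r_{ie})e^{-\mu_i t}$ (patch 1 additionally loses
$\delta c_o(t)$ to toxicity) and
$\sigma_i(t) = \frac{\xi_i}{\sqrt{2\mu_i}}\sqrt{1-e^{-2\mu_i t}}$ — and the
toxicant pair $(c_o, c_e)$ obeying linear uptake/decay with impulses
$\Delta c_e = b$ every $\gamma$ time units. Emigration from the polluted
patch increases with the environmental concentration through a Holling
type-III response.

The package provides:

* `solve_toxicant()`, `periodic_toxicant()` — exact impulsive
  toxicokinetics and the globally attracting periodic orbit with its
  extrema and period averages;
* `derived_constants()`, `extinction_check()`,
  `stochastic_permanence_check()`, `persistence_mean_check()`,
  `mean_lower_bounds()`, `pmoment_bound()`, `unpolluted_thresholds()`,
  `classify()` — every closed-form survival criterion, reported as signed
  margins with `tidy()`/`glance()` accessors;
* `simulate_path()`, `simulate_ensemble()`, `simulate_unpolluted()` — a
  positivity-preserving truncated Euler–Maruyama simulator (floor or
  log-space scheme) with exact toxicant forcing, plus `time_average()`,
  `extinction_flag()`, `empirical_pmoment()` and `autoplot()` methods;
* `fixture()` — the published benchmark parameter sets, and YAML config
  I/O (`read_model_config()` / `write_model_config()`). A thin CLI lives
  in `inst/cli/toxpatch.R`.

## Worked example

The first benchmark set (`set40-fig1a`: strong noise, $\xi_i = 0.4$,
$\mu_i = 0.1$, pulses $b = 0.1$ every $\gamma = 1$) is classified as
extinct, and simulation agrees:

```r
library(toxpatch)
fx <- fixture("set40-fig1a")
classify(fx$model)
#> <threshold_report>
#>   extinction:            case ii  margin -0.20922  FIRES
#>   noise-free extinction: -
#>   stochastic permanence: -
#>   persistence in mean:   case ii  margin -0.61757  -
#>   summary: extinction (case ii)

cfg <- sim_config(t_end = 300, dt = 0.005, n_paths = 50, seed = 42,
                  record_stride = 100)
simulate_ensemble(fx$model, cfg, fx$x0, fx$tox0, ext_dwell = 50,
                  keep_paths = FALSE)
#> <tox_ensemble> 50 paths, t_end = 300 , dt = 0.005 , scheme = ppt-em
#>   extinct fraction: 1.000 (x1: 1.000, x2: 1.000)
#>   mean <x1+x2> over [150, 300]: 0.0000
#>   E[(x1+x2)^2] at t = 300: 2.773e-12 (se 2.77e-12)
```

The extinction margin `-0.20922` is the case-(ii) spectral expression
minus the aggregated noise level $\sigma^2$; its negative sign is the
sufficient condition, and the ensemble's extinction fraction of 1.000
(all 50 paths below density 0.01 for the last 50 time units) shows the
criterion is not vacuous at this parameter point. Dropping the noise to
$\xi_i = 0.1$ (`set40-fig1b`) flips the persistence margin to `+0.13243`
and the same ensemble persists.

See the vignette (`vignettes/toxicant-pulse-model.Rmd`) for the model
assumptions, parameter meanings, numerical choices and limitations.

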