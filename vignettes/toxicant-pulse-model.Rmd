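---
title: "Survival thresholds for a two-patch population under pulsed toxicant input"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival thresholds for a two-patch population under pulsed toxicant input}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxpatch)
```

## The model

`toxpatch` studies a single species living on two patches. Patch 1 is
polluted: a toxicant pulse of size $b$ enters its environment every $\gamma$
time units (think of periodic pesticide application), decays at rate $h$, is
taken up by organisms at rate $f$ and lost from them by egestion and
metabolism at rates $g$ and $m$. The body burden $c_o(t)$ depresses the
patch-1 growth rate by $\delta c_o(t)$, and the environmental concentration
$c_e(t)$ drives extra emigration out of the polluted patch through a
saturating Holling type-III response. The densities obey

$$
\begin{aligned}
dx_1 &= \Big[x_1\big(r_1(t) - a_1 x_1\big) + d_{21}x_2
        - d_{12}\Big(1+\tfrac{\rho c_e^2}{1+\alpha c_e^2}\Big)x_1\Big]dt
        + \sigma_1(t)\,x_1\,dB_1(t),\\
dx_2 &= \Big[x_2\big(r_2(t) - a_2 x_2\big)
        + d_{12}\Big(1+\tfrac{\rho c_e^2}{1+\alpha c_e^2}\Big)x_1
        - d_{21}x_2\Big]dt + \sigma_2(t)\,x_2\,dB_2(t),
\end{aligned}
$$

where the growth rates $r_i$ are not constants but mean-reverting
(Ornstein–Uhlenbeck) processes with asymptotic mean $r_{ie}$, reversion
speed $\mu_i$ and noise intensity $\xi_i$. Substituting the OU pathwise
solution gives the reduced form used throughout the package: a
deterministic transient $r_{ie} + (r_{i0}-r_{ie})e^{-\mu_i t}$ (minus
$\delta c_o(t)$ on patch 1) plus white noise with time-varying amplitude
$\sigma_i(t) = \tfrac{\xi_i}{\sqrt{2\mu_i}}\sqrt{1-e^{-2\mu_i t}}$. We do
not simulate $r_i(t)$ as a separate state because the reduced form is the
model; this also makes the noise amplitude's saturation at
$\xi_i^2/2\mu_i$ explicit, which is exactly the quantity the survival
thresholds trade off against growth.

## The toxicant subsystem is solved exactly

The toxicokinetic pair $(c_o, c_e)$ is linear with impulses, so
`solve_toxicant()` advances it in closed form between pulses and applies
$\Delta c_e = b$ at multiples of $\gamma$ (the value *reported at* a pulse
instant is the pre-pulse left limit, matching the jump convention
$\Delta c_e(t) = c_e(t^+) - c_e(t)$). The subsystem has a unique globally
attracting $\gamma$-periodic orbit, computed by `periodic_toxicant()`:

```{r orbit}
tp <- toxicant_params(f = 0.5, g = 0.3, m = 0.2, h = 0.3, b = 0.1, gamma = 1)
periodic_toxicant(tp, alpha = 0.2)
```

All survival criteria are phrased in the orbit's extrema $c_o^m, c_o^M,
c_e^m, c_e^M$ and the period averages (the mean body burden
$fb/(h(g+m)\gamma)$ and the Holling-III average $\eta$). Numerical care:

* Every formula containing $1/(h-g-m)$ is evaluated through
  $\varphi(z) = (e^z-1)/z$ with a series branch near $z=0$, so the
  degenerate case $h = g+m$ is handled by the same code path with no
  spurious singularity.
* The body-burden extrema over one period are found from the closed-form
  stationary point of the two-exponential difference (at most one interior
  critical point can exist), with the endpoints as candidates and a
  2048-point grid as a safety net for degenerate coefficient signs.
* Parameter validation enforces $f \le g+m$ and
  $b \le 1 - e^{-h\gamma}$, which keep both concentrations inside
  $[0, 1]$; they are errors by default and warnings with `strict = FALSE`.

Concentrations being dimensionless fractions, none of the toxicant
quantities carry units; all rates are per unit time in whatever time unit
$\gamma$ is expressed in.

## Survival thresholds

`derived_constants()` assembles the constants the criteria compare:
effective patch-1 growth at the extreme body burdens
($r_1^* = r_{1e} - \delta c_o^m$, $(r_1)_* = r_{1e} - \delta c_o^M$),
migration at the extreme environmental concentrations ($d_{12}^*$ at
$c_e^M$, $(d_{12})_*$ at $c_e^m$), and two aggregated noise levels,
$\sigma^2 = \xi_1^2\xi_2^2/(2\mu_1\xi_2^2 + 2\mu_2\xi_1^2)$ (a
harmonic-type combination, used against extinction) and
$\hat\sigma^2 = \max_i \xi_i^2/2\mu_i$ (used against persistence).

Each criterion is a *sufficient* condition, reported as a signed margin so
that the verdict is simply the sign:

* **Extinction** (`extinction_check()`): three cases by the sign of
  $r_1^* - r_{2e}$ (equality resolved within $10^{-12}$). The asymmetric
  cases compare
  $(r_1^*+r_{2e}-d-d_{21}) + \sqrt{(r_1^*-r_{2e}+d_{21}-d)^2+4dd_{21}}$
  with $\sigma^2$, where $d$ is $d_{12}^*$ when $r_1^* < r_{2e}$ and
  $(d_{12})_*$ otherwise. The case-(ii) rate is $d_{12}^*$: the worked
  numeric examples only reproduce under that reading, which we take as
  authoritative over a conflicting display elsewhere.
* **Noise-free extinction** (`noise_free_extinction()`): fires when
  $r_1^* < 0$ and $d_{12}^*r_{2e} + r_1^*d_{21} - r_1^*r_{2e} < 0$,
  independent of the noise.
* **Stochastic permanence** (`stochastic_permanence_check()`):
  $\min\{r_{1e}-\delta c_o^M,\ r_{2e}\} > \hat\sigma^2/2$. The body-burden
  maximum $c_o^M$ is the conservative reading of the worst-case burden.
* **Persistence in the mean** (`persistence_mean_check()`): mirror of the
  extinction cases with $(r_1)_*$, the starred migration rates swapped,
  and $\hat\sigma^2$ as the hurdle.
* **Mean lower bounds** (`mean_lower_bounds()`) and the p-moment bound
  `pmoment_bound()` (with the OU reversion speeds entering the moment
  constant) complete the report; `classify()` aggregates everything with
  the precedence extinction, permanence, persistence, else inconclusive.

```{r classify}
classify(fixture("set40-fig1a")$model)
tidy(classify(fixture("set40-fig1b")$model))
```

The margins are continuous across the case boundaries $r_1^* = r_{2e}$
(checked numerically in the tests), and monotone in the noise
ingredients: raising any $\xi_i$ pushes the extinction margin down and the
persistence margin down.

## Simulator

`simulate_path()` integrates the population SDE by truncated
Euler–Maruyama. Two design choices matter:

* **Exact forcing.** The toxicant pair is evaluated by its closed form on
  the simulation grid, so the forcing carries no discretization error; the
  drift on a step beginning at a pulse instant uses the post-pulse
  concentration while recorded output reports the pre-pulse value. The
  step `dt` must divide $\gamma$ (checked to $10^{-9}$) so pulses land on
  grid points; the default used in our experiments is $\gamma/200$.
* **Positivity.** The default `ppt-em` scheme is a plain EM step followed
  by truncation at a floor ($10^{-10}$ by default, far below any
  ecologically meaningful density); `log-em` steps the log-densities with
  Itô-corrected drift and is positive by construction. The reference
  method is cited without formulas in the source literature, so the floor
  truncation is the simplest faithful reading; both schemes pass all
  qualitative checks and agree at the resolution of the summaries.

Gaussian increments are drawn per step and patch from the configured seed
(`seed + i` for path `i` of an ensemble), so runs are bit-reproducible;
`increments` lets callers inject a fixed Brownian path, which the strong
self-convergence test uses (observed error contraction per `dt` halving
$\approx \sqrt 2$, consistent with strong order 1/2). A divergence guard
aborts if $x_1+x_2$ exceeds $10^6$, which the dissipative drift makes
unreachable for sane parameters. `simulate_unpolluted()` enforces
$\delta = \rho = b = 0$ and is regression-tested to be bitwise identical
to the full model under that substitution.

## Finite-horizon survival surrogates

The survival notions are asymptotic and therefore untestable directly;
`summaries` uses documented surrogates. Extinction: the density stays
below a threshold (default 0.01, well above the floor) over the final
dwell span (default 20% of the horizon). Persistence: the trapezoid
time-average over the second half of the horizon exceeds 0.05. The
thresholds are configurable arguments, not constants, and the ensemble
report keeps per-path values so other cutoffs can be applied after the
fact.

## What the built-in experiments show — and what they do not

The packaged parameter sets (`fixture("set40")`, `fixture("set41")` and
their panel variants) are the published worked examples; re-running

```{r margins}
extinction_check(fixture("set40-fig1a")$model)$functional   # about -0.209
persistence_mean_check(fixture("set40-fig1b")$model)$functional # about +0.132
```

reproduces the printed margins to the displayed precision. The simulation
experiments in the test suite use horizons of $T = 300$ with
$dt = 0.005$–$0.01$, 200–500 paths, and seed 42 or 7; these sizes were
chosen to make Monte-Carlo fractions (extinction fraction, share of
persistent paths) stable to a few percent while keeping a full run on one
CPU in tens of seconds. The generator emulates environmental stochasticity
through the reduced OU form with independent Brownian motions between
patches; it does not emulate demographic noise, correlated environments,
toxicant uptake in patch 2, stochastic pulse timing, or parameter
uncertainty — so passing tests support the model's internal consistency,
not the fidelity of any of those real-world features.

## Known limitations

* All criteria are sufficient, not necessary: `classify()` returning
  "inconclusive" says nothing about the true fate of the population.
* One published panel (set (41) with $d_{12}=0.2$, $d_{21}=0.8$,
  $\rho=0.4$) prints threshold values we could not reproduce under any
  reading of the formulas; the corresponding fixture simulates fine but
  its printed margins are not asserted anywhere.
* The set (41) table omits the toxicokinetic rates $f, g, m$; the
  printed patch-1 mean growth rate $-0.0825$ is only consistent with the
  set (40) values carrying over (so $f = g+m$), which is what
  `fixture("set41")` does.
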