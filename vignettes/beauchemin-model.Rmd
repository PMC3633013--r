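---
title: "The Beauchemin model: simulation, closed forms and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Beauchemin model: simulation, closed forms and fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beauchemin)
```

## The model

The Beauchemin model is a minimal particle-based description of lymphocyte
migration in tissue, introduced by Beauchemin, Dixit and Perelson (2007) and
widely used since to interpret two-photon imaging of T cells. A cell is a
massless point that repeats a two-phase cycle:

1. **Pause**: the cell stands still for a fixed time `t_pause` (minutes)
   while it turns — a new direction is drawn uniformly from the unit
   sphere, independent of the previous one.
2. **Free run**: the cell moves in that direction at a fixed speed
   `v_free` (micrometres/minute) for a fixed time `t_free` (minutes).

The triplet `(t_pause, t_free, v_free)` fully parameterizes the walk. With
`t_pause = 0` the model reduces to the freely jointed ("ideal") chain of
polymer physics with rod length `r = v_free * t_free`. The calibration of
the original model against published two-photon track data selected
`t_pause = 0.5`, `t_free = 2.0`, `v_free = 18.8` as the best-fitting
triplet; that triplet is the default study condition throughout this
package's examples and tests.

Each full cycle displaces the cell by a vector uniform on the sphere of
radius `r`. Each Cartesian component of such a vector is marginally uniform
on `[-r, r]` (Archimedes' hat-box property) with variance `r^2/3`, and the
components are pairwise uncorrelated, so the three dimensions decouple into
three one-dimensional random walks. This is the key fact behind every
closed form in the package.

## Closed forms

**Motility coefficient.** Per observed dimension the walk's diffusive
scaling limit has

    M = (v_free * t_free)^2 / (6 * (t_free + t_pause))   [um^2/min]

(`motility_coefficient()`). For the best-fit triplet, `M = 94.25`.

**Single synchronized particle** (`msd_single()`): observed a whole number
of cycles `t` plus an offset `tau` into the current cycle, the expected
square displacement is `2Mt` plus a pulse, `(v_free^2/3) max(tau -
t_pause, 0)^2` — flat while paused, quadratic while running.

**Ensemble / stationary phase** (`msd_ensemble()`): a real population is
not synchronized. Averaging the single-particle expression over a phase
offset uniform on the cycle gives, per dimension,

    E[D^2](t) = 2Mt - 2M t_free * g(t/t_free),
    g(u) = u^3/3 - u^2 + u   (u < 1),   g(u) = 1/3   (u >= 1).

The curve starts at zero with zero slope and from `t = t_free` onward is
*exactly* the line `alpha t + beta` with `alpha = 2M`,
`beta = -2M t_free / 3` (`msd_linear_coeffs()`). Two consequences matter
in practice:

* `beta/alpha = -t_free/3`, so a fitted line identifies `M` **and**
  `t_free`;
* the line has only two degrees of freedom, so `(t_pause, v_free)` cannot
  be separated at fixed `M` and `t_free`: for example `(0.5, 2.0, 18.8)`
  and `(9.32, 2.0, 40)` produce indistinguishable MSD curves. Their *mean
  displacement* curves differ, however, because the mean displacement does
  not decouple across dimensions — mean displacement retains information
  that the MSD discards. `rank_parameter_grid()` demonstrates both sides
  of this.

**Squared confinement ratio** (`sq_confinement()`). The confinement
(meandering, chemotactic) index divides displacement by path length; the
squared variant used here divides the one-dimensional squared displacement
by `(t v_free)^2`. For `t_pause = 0` we derive, from the ensemble MSD,

    E[C^2](t) = (3 max(t, t_free) - min(t, t_free)) * t_free
                / (3 max(t, t_free))^2,

which equals `1/3` at `t = 0` (a 3-D path projected to one observed
dimension), `2/9` at `t = t_free`, and decays like `t_free/(3t)`. We
implement the min/max form above because it is the one consistent with
both branches of the underlying MSD: substituting the cubic branch gives
`(3 t_free - t)/(9 t_free)` below `t_free` and the linear branch gives
`t_free (3t - t_free)/(9 t^2)` above it, and both limits check out. The
time-normalized variant `t * E[C^2](t)` (`normalized_sq_confinement()`)
converges to `t_free/3`, a useful rule of thumb for reading the
persistence time off long experiments. With `t_pause > 0` the denominator
`t v_free` overstates the true path length, so the function refuses a
nonzero pause unless `allow_pause = TRUE` explicitly requests the
extrapolation (which simply scales the ratio by
`t_free/(t_free + t_pause)`).

**Fürth's equation** (`furth_msd()`), `2M(t - P(1 - e^{-t/P}))`, is
provided as the standard comparison model: its persistence decays
exponentially, while the Beauchemin model's persistence vanishes abruptly
after each cycle, making its MSD exactly linear beyond `t_free`. Both
share the asymptotic slope `2M`, which is why `fit_furth()` on Beauchemin
data still recovers `M`.

**Scaling limit** (`gaussian_density()`): on long time scales the walk is
Brownian motion with drift; the position density is Gaussian with mean
`Ct` and variance `2Mt` and solves the convection-diffusion equation. The
tests verify this both by quadrature and by a finite-difference residual,
and check the simulated long-time displacement distribution against it.

## Biased migration (taxis modes)

Bias is spatially and temporally uniform, controlled by a unit direction
`b` and a strength `p` in `[0, 1]` (`taxis_spec()`; `p` above 1 is
rejected — it would produce negative speeds or durations):

* **simple** — during pauses the cell drifts at `p v_free b` instead of
  standing still. Purely deterministic, so it shifts the mean without
  touching the variance; drift speed `||C|| = p v_free t_pause /
  (t_free + t_pause)`.
* **orthotaxis** — run speed `v_free (1 + p <b, d>)`.
* **topotaxis** — the run direction's component along `b` is drawn from
  the skewed density `(1 + p x)/2` on `[-1, 1]` instead of the uniform.
* **klinotaxis** — run duration `t_free (1 + p <b, d>)` (run-and-tumble).

Orthotaxis, topotaxis and klinotaxis all produce exactly the same
convection speed, `||C|| = v_free p t_free / (3 (t_free + t_pause))`
(`convection_speed()`), because in each case a run advances the cell along
`b` by `v_free t_free p/3` on average. Inverting the formula lets you
dial in a target drift speed directly; with the best-fit triplet a
5 um/min drift needs `p = 0.9973`, and 1000 simulated cells then travel
300 um along `b` in one hour, for all three modes. The three mechanisms
are *not* equivalent beyond the mean: all except the simple mode also
distort the random motility component anisotropically, which
`displacement_covariance()` exposes empirically.

## The simulator

`simulate_track()` is event-driven: it generates pause/run breakpoints in
exact floating-point event times, then evaluates the piecewise-linear path
at the requested sample times `0, dt, 2dt, ...` (generated as multiples of
`dt`, not by accumulation, to avoid drift). Observation times therefore
carry no interpolation error and need not align with cycle events.
Zero-length events (a zero pause, or a klinotaxis run at `p = 1` against
the bias) are processed as ordinary events; an event-count guard
(`max_events`, default 1e9) turns a pathological parameter set into an
error instead of a hang.

**Phase initialization.** `synchronized` starts every cell at the top of a
pause, which exposes the pulsed single-particle variance profile;
`stationary` draws the cell's offset within its cycle uniformly,
reproducing the smooth phase-averaged MSD. For klinotaxis with `p > 0`
the cycle duration depends on the run direction, and a uniform offset over
a *nominal* cycle would under-represent long runs (an observation window
is more likely to open inside a long cycle). We therefore draw the
intersected cycle from the renewal-stationary, length-biased law by
rejection — a candidate direction's cycle is accepted with probability
proportional to its duration — which makes the expected drift exactly
`||C|| t` at every `t`. For all other modes the cycle length is constant
and the plain uniform draw is already stationary.

**Reproducibility.** `simulate_ensemble()` derives one L'Ecuyer-CMRG
substream per track from the master seed, so ensembles are bit-reproducible,
track `i` does not depend on how many tracks are requested, and the
caller's RNG state is left untouched.

## Estimators and fitting

`mean_displacement()`, `mean_square_displacement()` and
`empirical_confinement()` operate on zero-aligned track sets sharing one
observation grid (always true for simulated data) and report per-point
sample standard errors (`SD/sqrt(n)`); there is no overlapping-interval
pooling, so points are plain cross-track averages and their SEs are
honest. `zero_align()` implements the alignment and is idempotent.
Imported tracks keep their values bit-exactly through the CSV round trip
(`write_tracks()`/`read_tracks()`, 17 significant digits).

`fit_linear_msd()` fits the linear regime by weighted least squares
(weights `1/SE^2` when available). Because the line only holds beyond
`t_free`, the default window is chosen in two passes: a first fit over the
whole grid yields a `t_free` guess, and the final fit starts at twice that
guess. A positive intercept (possible under noise) is reported as
`t_free = 0` with a warning rather than a negative run time.
`fit_furth()` uses Levenberg-Marquardt with box constraints and a small
multistart grid over persistence scales, keeping the best converged start.

`rank_parameter_grid()` mirrors the original calibration workflow —
simulate each candidate triplet, score by sum of squared residuals against
the reference curve (uniform weights on the reference grid), and report
SSR normalized to the best candidate (best = 1.00). The original workflow
used 1e6 simulations per candidate; the default here is 1e4, exposed as a
parameter — at desk scale the ranking of clearly distinct triplets is
already stable, while M-degenerate triplets remain statistically tied on
MSD references, as they should.

## What the generator does and does not emulate

Simulated tracks are exact draws from the model: no imaging noise, no
finite imaging volume (real two-photon volumes are axially thin and
truncate tracks), no cell-cell collisions, boundaries or tissue structure,
and no turning-angle persistence between successive runs. Tests passing on
simulated data therefore validate the implementation and the closed forms
against each other; they do not establish that real lymphocyte tracks obey
the model. Heterogeneous real data can be imported (tracks are binned to a
common grid only when they already share one; heterogeneous grids are
rejected rather than silently resampled).

## Problem sizes and numerical choices

Test and example ensemble sizes were chosen as the smallest that leave the
statistical checks far from their decision boundaries: 1e4 tracks for MSD
oracle equivalence and parameter recovery (SE of the MSD at 1e4 tracks is
about 1.4% of its value), 1e5 short tracks for the confinement closed
form, 1e3 cells per taxis mode for drift checks (3 SE ~ 10 um against a
300 um signal), and 1e5 draws for sphere-marginal tests at alpha = 0.001.
Stochastic assertions use 3-4 standard errors under fixed seeds.
Direction sampling uses the normalized Gaussian triple; topotaxis
components use the closed-form inverse CDF of `(1 + px)/2` (root of a
quadratic), so both are stream-reproducible with no rejection loop. Fit
positivity is enforced by box constraints, not penalties.

## Known limitations

* No closed form for the mean displacement exists (its dimensions do not
  decouple); it is available only by simulation.
* The motility coefficient of the orthotaxis/topotaxis/klinotaxis walks is
  anisotropic and not derived in closed form; only the empirical
  covariance surface is provided.
* The squared confinement closed form assumes `t_pause = 0`; with a pause
  the function only extrapolates (see above).
* `p` is capped at 1, so the maximum closed-form drift of the
  non-simple modes is `v_free t_free / (3 (t_free + t_pause))` — about
  5.01 um/min at the best-fit triplet; faster drifts require a different
  parameter regime rather than extrapolated `p`.

## A compact worked example

```{r, eval = FALSE}
p <- model_params(t_pause = 0.5, t_free = 2.0, v_free = 18.8)
motility_coefficient(p)          # 94.25067 um^2/min
msd_linear_coeffs(p)             # alpha 188.5013, beta -125.6676

ts <- simulate_ensemble(10000, p, duration = 30, sample_dt = 0.5,
                        phase = "stationary", seed = 42)
cv <- mean_square_displacement(ts, "x")
fit <- fit_linear_msd(cv)
fit$estimates$M                  # ~94 (within a few percent)
fit$estimates$t_free             # ~2.0
```
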