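---
title: "Models and methods behind tdfrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tdfrs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdfrs)
```

## The experiment and its signal model

Thermal diffusion forced Rayleigh scattering (TDFRS) writes a holographic
temperature grating into a solution with two crossed infrared laser beams.
Water absorbs at the writing wavelength, so the interference pattern becomes
a spatially periodic temperature field with grating vector $q$. The Soret
effect then drives solute migration along the temperature modulation, and
the superposition of the temperature and concentration gratings forms a
refractive-index grating that diffracts a readout beam.

In a single-Fourier-mode description both gratings relax exponentially: the
thermal mode with $\tau_{th} = (D_{th} q^2)^{-1}$ and the concentration mode
with $\tau = (D q^2)^{-1}$, where $D_{th}$ is the thermal diffusivity and
$D$ the mass diffusion coefficient. For a protein in water the two times are
separated by two to three orders of magnitude, which is what makes the
two-mode decomposition practical. Writing $\theta(t)$ for the thermal mode
(normalized to a unit plateau) and $g(t)$ for the concentration mode
response, the driven system is

$$\frac{d\theta}{dt} = \frac{s(t) - \theta}{\tau_{th}}, \qquad
  \frac{dg}{dt} = \frac{\theta - g}{\tau},$$

with source $s = 1$ while the grating is written and $s = 0$ after
switch-off. The normalized heterodyne intensity is
$\zeta(t) = \theta(t) - A_0\, g(t)$, which for the excitation phase has the
closed form implemented in `heterodyne_intensity()`:

$$\zeta(t) = 1 - e^{-t/\tau_{th}} -
  \frac{A_0}{\tau - \tau_{th}}
  \left\{\tau\left(1 - e^{-t/\tau}\right) -
         \tau_{th}\left(1 - e^{-t/\tau_{th}}\right)\right\}.$$

$A_0$ is the steady-state concentration amplitude. It is connected to the
Soret coefficient through the optical contrast factors,

$$A_0 = \left(\frac{\partial n}{\partial c}\right)_{p,T}
        \left(\frac{\partial n}{\partial T}\right)_{p,c}^{-1}
        S_T\, c\,(1 - c),$$

inverted by `amplitude_to_soret()`. Because $(\partial n/\partial T)$ is
negative in water, a thermophobic protein ($S_T > 0$) has $A_0 < 0$ and the
signal rises above the thermal plateau. No sign restriction is placed on
$A_0$: proteins are genuinely thermophilic at low temperature.

Two numerical details matter here:

* **Coincident relaxation times.** The closed form divides by
  $\tau - \tau_{th}$. When $|\tau - \tau_{th}| < 10^{-9}\tau_{th}$ the
  package switches to the analytic limit
  $\zeta = 1 - e^{-t/\tau} - A_0\{1 - e^{-t/\tau} - (t/\tau)e^{-t/\tau}\}$,
  so the model is continuous through the degenerate point. The test suite
  checks continuity across the branch.
* **Off phase.** The relaxation after switch-off is the source-free decay
  from the state $(\theta_0, g_0)$ at the switch-off instant
  (`heterodyne_intensity_off()`). The fit assumes the grating was held to
  steady state, $\theta_0 = g_0 = 1$; the default simulated schedules hold
  the excitation for at least seven mass relaxation times, which keeps the
  error of this assumption below $10^{-3}$ in $A_0$ and far below the
  statistical resolution of the pooled estimates.

## Fitting heterodyne traces

`fit_signal()` estimates $(\tau_{th}, \tau, A_0)$ by Levenberg–Marquardt
least squares (`minpack.lm::nls.lm`), weighted by the per-point standard
errors when the trace is a shot average that carries them. The search is
bounded — $\tau_{th} \in [\Delta t, T_{span}]$,
$\tau \in [\Delta t, 100\,T_{span}]$ (log-parameterized),
$A_0 \in [-2, 2]$ — because relaxation times far outside the observation
window are not measurable and only serve as escape directions for the
optimizer.

Starting values come from two layers. Heuristics give a first guess: the
$1 - 1/e$ crossing of the early rise for $\tau_{th}$ (first crossing on
ties), the plateau departure for $A_0$, the $1/e$ relaxation of the late
slow component for $\tau$. Because those heuristics can seed a mode-swapped
local minimum when $A_0$ is negative, the fit then evaluates a coarse
logarithmic grid over $(\tau_{th}, \tau)$ with $A_0$ profiled out exactly
(the model is linear in $A_0$ at fixed times) and starts the polish from
the best candidate. On noiseless synthetic traces the fit recovers the
generating parameters to better than $10^{-4}$ relative; the residual rms
is below $10^{-8}$.

The parameter covariance is evaluated from the Jacobian at the optimum.
With per-point standard errors the covariance is absolute (suitable for
confidence intervals); in the unweighted case it is scaled by the residual
variance. The information matrix is inverted through its SVD with singular
values floored at $10^{-10}$ of the largest, so that directions the data do
not constrain — the mass time when $A_0 \approx 0$ is the canonical case —
are reported with very large rather than spuriously small uncertainties.
Non-convergence is flagged (`converged = FALSE`), never silently imputed.

`normalize_trace()` rescales raw traces to the unit thermal plateau the
model assumes. The plateau is estimated by fitting
$s\cdot\zeta(t;\tau_{th},\tau,A_0)$ — scale plus the full closed form —
rather than a plateau-window median: the median of any finite window after
the rise is biased by the residual thermal transient ($\approx 5\times
10^{-4}$ at $7.5\,\tau_{th}$) and by the growing concentration mode, while
the model-based estimate is exact on conforming input. This makes
normalization idempotent to machine precision, invariant under rescaling,
and accurate to better than 1% at the default noise level.

Measurements repeat each condition: both phases of each signal are fitted
and two fresh samples are measured at least twice, so at least four values
enter each temperature point. `pool_estimates()` combines them by the plain
mean with the standard error of the mean — matching how the measured points
are reported — rather than inverse-variance weighting.

## The temperature law for S_T and its sensitivity statistic

Aqueous solutes commonly show a Soret coefficient that grows with
temperature and changes sign; the package fits the standard empirical law

$$S_T(T) = S_T^{\infty} + A\, e^{-T/T_0},$$

with the sign-change temperature $T^{*} = T_0 \ln(-A/S_T^{\infty})$ defined
whenever $A$ and $S_T^{\infty}$ have opposite signs
(`sign_change_temperature()`; the identity $S_T(T^{*}) = 0$ is maintained
to $10^{-12}$ and tested). Temperatures are handled in degrees Celsius
throughout — so $T_0$ and $T^{*}$ are in °C — because the measured range
and quoted sign-change temperatures are reported on that scale; the law is
reparameterization-equivalent under a unit change.

The three parameters are strongly correlated over a 30 °C window, so
`fit_soret_curve()` profiles the nonlinear scale: for fixed $T_0$ the model
is linear in $(S_T^{\infty}, A)$ and solved exactly on a $T_0$ grid, and the
best profile point seeds the Levenberg–Marquardt polish. Without this the
optimizer failed to converge on roughly a third of noisy draws.

The temperature-sensitivity statistic is
$\Delta S_T(\Delta T) = S_T(40\,°\mathrm{C}) - S_T(15\,°\mathrm{C})$
(`delta_ST()`, endpoints configurable). It is used as a hydrophilicity
proxy: hydrophilic solutes show a stronger temperature dependence of
$S_T$. Two modes are provided, because the definition references measured
temperatures but a fitted curve is also always available: `from_points`
differences the measured values at the endpoints (uncertainty combined in
quadrature), `from_fit` differences the fitted law (uncertainty by the
delta method on the fit covariance). The default prefers measured points
when both endpoints exist within 0.5 °C and falls back to the fit; the mode
used is always recorded.

## Correlating sensitivity with structure

Across solution conditions (pH, buffer), $\Delta S_T(\Delta T)$ is
regressed on the α-helical content of the protein
(`correlate_conditions()`): weighted least squares through `stats::lm` with
weights $1/\sigma_y^2$, the Pearson correlation, and a leave-one-out slope
analysis that flags any condition whose removal changes the slope by more
than 50%. The helix-content uncertainties are reported but not folded into
the fit (no errors-in-variables): with half a dozen folding states the line
is descriptive, and no p-value is attached to $r$ for the same reason. The
50% flag threshold is a package convention for "this single state carries
the trend", motivated by the acid-unfolded state's known departure from the
linear trend. `rank_by_sensitivity()` orders conditions by decreasing
$\Delta S_T$, with lexicographic labels breaking ties.

## Protein and buffer properties

The auxiliary calculations use fixed, documented conventions:

* **Molecular weight**: average (not monoisotopic) residue masses plus one
  water.
* **Extinction at 280 nm**: the Pace/ProtParam convention
  $\varepsilon = 5500\,n_{Trp} + 1490\,n_{Tyr} + 125\,n_{cystine}$ with all
  cysteines reduced by default; $E_{1\%} = 10\,\varepsilon/M_W$. For the
  shipped horse apomyoglobin sequence (P68082 mature chain, 2 Trp, 2 Tyr,
  0 Cys) this gives $E_{1\%} = 8.25$, matching the value used to determine
  sample concentrations.
* **Net charge and pI**: Henderson–Hasselbalch sums over side chains and
  termini. The default pKa table is the Bjellqvist set used by the ExPASy
  Compute pI/MW tool (Asp 4.05, Glu 4.45, His 5.98, Cys 9.0, Tyr 10.0,
  Lys 10.0, Arg 12.0, N-term 7.5, C-term 3.55). The pI depends materially
  on this choice; the Bjellqvist set places apomyoglobin at pI 7.36, close
  to the literature value of 7.2, whereas EMBOSS-style tables push it near
  7.9. The table is an explicit argument everywhere, so other conventions
  can be swapped in.
* **Buffer speciation** is the monoprotic Henderson–Hasselbalch fraction;
  at pH 6 with phosphate p$K_{a2}$ = 7.21 the dihydrogen phosphate fraction
  is 0.94, consistent with the quoted mole fraction of ≈ 0.9.
* **Hydration index**: the mole-fraction-weighted mean of
  dielectric-spectroscopy immobilized-water counts,
  $\sum_i x_i n_i$. For acetate buffer at pH 4
  ($x = 0.2$ sodium acetate with 5 waters, $x = 0.8$ acetic acid with 1)
  this gives 1.8, the quoted value. For phosphate at pH 6 ($x = 0.9$ with
  4 waters, $x = 0.1$ with 11) the same rule gives 4.7, while 5.5 has been
  quoted for this composition; the package reports the arithmetic
  consequence of the stated inputs and weighting rather than adjusting
  either, and the discrepancy is left visible.

## Synthetic data: what it emulates and what it does not

All tests run on synthetic data, generated by three seeded generators.

`simulate_shot_set()` integrates the driven two-mode system with a
hand-written classical RK4 at a fixed step of $\tau_{th}/50$ (an integer
divisor of the sampling interval) and adds i.i.d. Gaussian noise per sample
per shot. A fixed-step integrator was chosen over an adaptive library
solver for two reasons: trajectories are bit-reproducible across platforms,
and the per-seed recovery studies need on the order of $10^5$ steps per
trace, which the loop handles in well under a second. The integrator is
deliberately independent of the closed forms — it is the numerical oracle
against which they are verified (maximum deviation below $10^{-6}$ over
random parameter draws with $\tau/\tau_{th} \in [10, 10^4]$; the test suite
additionally cross-checks the closed forms against `deSolve::lsoda` at
$10^{-12}$ tolerances).

`simulate_averaged_trace()` draws the 3000-shot average directly from the
exact sampling distribution of the shot mean and its standard error
(Normal for the mean, scaled-$\chi$ for the estimated sem). This is
statistically identical to materializing and averaging the shots — a test
verifies the match against `average_shots()` on an explicit shot set — but
avoids allocating ~$10^8$ doubles per replicate in the coverage studies.

Two default parameter sets describe the study conditions:

* the *experiment-like schedule* $\tau_{th} = 5\times10^{-4}$ s,
  $\tau = 0.25$ s, 1.75 s on / 1.75 s off, sampled at $5\times10^{-5}$ s:
  with a 21 μm fringe spacing ($q = 1.17\times10^{5}$ m$^{-1}$) this
  corresponds to $D = 2.9\times10^{-10}$ m²/s and
  $D_{th} = 1.4\times10^{-7}$ m²/s, protein-in-water magnitudes. Per-shot
  noise of 0.01 on the normalized signal with 3000-shot averaging is the
  default noise condition; the per-shot magnitude is not something the
  instrument literature pins down, so it is a package convention chosen to
  stress the fits at realistic averaged noise (~$2\times10^{-4}$).
* the *Soret-law truth* $S_T^{\infty} = 0.025$ K$^{-1}$,
  $A = -0.132$ K$^{-1}$, $T_0 = 12$ °C, giving $T^{*} = 20$ °C and
  $\Delta S_T = 0.033$ K$^{-1}$: Soret coefficients of order
  $10^{-2}$ K$^{-1}$, thermophilic below ~20 °C and thermophobic above —
  the qualitative behaviour observed for this protein. The fitted
  per-condition law parameters of the original experiments are not publicly
  tabulated, so these values are fixed from the qualitative constraints
  plus literature $T_0$ magnitudes for aqueous solutes, and are not tuned
  thereafter. A curve must bend appreciably inside the 15–45 °C window for
  all three parameters to be identifiable at $\sigma = 10^{-3}$ K$^{-1}$;
  with this truth the Cramér–Rao bounds are a few percent and the recovery
  studies show < 2% bias with ~95% CI coverage.

`generate_condition_set()` draws condition records with
$\Delta S_T = \text{slope} \cdot \text{helix} + \text{intercept} + $ noise
over the measured helix contents (51, 50, 43, 34, 33, 4%); the default
slope $4\times10^{-4}$ K$^{-1}$ per % and intercept $2\times10^{-3}$
K$^{-1}$ put $\Delta S_T$ in the observed few-$10^{-2}$ K$^{-1}$ range.

The generators emulate the statistical structure the analysis assumes —
two-exponential dynamics, additive Gaussian detector noise, a linear
sensitivity–helicity trend. They deliberately do **not** emulate
multiplicative or photon noise, baseline drift, convection, multi-species
(tri-exponential) signals, buffer contributions to the concentration
signal, or temperature-dependent $D$ within a measurement series. Passing
tests therefore demonstrate correctness of the estimators under the model's
own assumptions, not robustness to every instrumental pathology of real
traces.

## Problem sizes and numerical conventions

The recovery and coverage studies in the test suite and the acceptance
script use 100 seeds for the parameter-recovery, coverage and
slope-recovery studies, 50 seeds per noise level for the consistency check,
20 random parameter draws for the oracle comparisons, and 7-temperature
synthetic experiments (15–45 °C in 5 °C steps, the measured grid) for the
end-to-end chain. Unit tests run a faster schedule
($\tau = 0.03$ s, 0.35 s phases) whose conclusions match the
experiment-like one. All randomness flows from explicit seeds; generators
save and restore the caller's RNG state.

Ties in the $1-1/e$ crossing search resolve to the first crossing.
Degenerate inputs follow a "report, don't invent" policy: fits that do not
converge are flagged; a flat Soret dataset returns the constant with a null
amplitude rather than an error; condition tables whose removal-sensitive
records dominate the slope are flagged by label; a trace without a positive
thermal plateau is a hard error.

## Known limitations

* The off-phase fit assumes steady state at switch-off; traces cut short
  during the concentration build-up will bias $A_0$ low in that phase.
* $\Delta S_T$ endpoint matching uses a fixed 0.5 °C window.
* The weighted straight line in the structure correlation ignores
  x-uncertainties; with $n = 6$ folding states this is descriptive
  statistics, not inference.
* The pipeline treats buffered protein solutions as pseudobinary (the
  buffer's own concentration signal is neglected), which is valid at the
  20 mM working concentrations but not for the 0.5 mol/kg buffer-only
  measurements — those are analysed as ordinary binary samples instead.
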