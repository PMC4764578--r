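---
title: "Modeling and fitting thymocyte beta-selection kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and fitting thymocyte beta-selection kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thymokin)
```

## The model and its assumptions

`thymokin` models the passage of developing T cells through four
compartments — DN3, DN4, immature CD8 single-positive (ISP) and
double-positive (DP) — as a linear birth–death–differentiation chain.
Progenitor arrival and maturation up to DN3 is collapsed into a constant
influx $K$ (cells/day). Each stage $i$ loses cells by differentiation into
the next stage (rate $K_i$, 1/day) and by *net turnover* ($K_{di}$, 1/day),
a single number combining death and proliferation. The terminal DP pool
only turns over (death by neglect); maturation of the few DP cells that
become single positives is neglected.

Linearity is the key assumption: rates are per-cell constants, so there is
no niche competition, no feedback from downstream pools, and no
density-dependence. That buys closed-form solutions and clean
identifiability analysis, at the price of realism discussed at the end.

Turnover rates are constrained non-negative: a compartment whose
proliferation outpaces its loss (net growth) is outside this model's scope.
`Kd2` and `Kd3` default to 0 — DN4 and ISP cells proliferate heavily with
viability similar to neighbouring stages, so their net turnover is small
compared with their differentiation rates — but both are explicit fields
that users may override.

Time is measured in days throughout; the conventional 3-hour reporting grid
is `seq(0, 3, by = 0.125)`.

## Parameter presets

`preset_parameters()` carries four genotype presets. The two knockout
presets raise all three differentiation rates two- to three-fold
(`K1` 0.1→0.2, `K2` 0.162→0.486, `K3` 0.07→0.21 /day) at unchanged influx
and turnover; the two `Rag2-*` presets set `K = 0` because
recombination-deficient thymocytes are arrested at DN3 and progenitor
influx over the 3-day observation window after anti-CD3 injection is
negligible. The influx `K = 15.4e4` cells/day and DP turnover
`Kd4 = 0.00058`/day are taken as published without re-derivation (they were
evidently chosen to match total thymic cellularity); the presets reproduce
them verbatim.

## Closed-form solutions

**Steady state.** Flux balance gives
$C_1 = K/(K_1+K_{d1})$, and each further pool is the incoming flux divided
by its exit rate. `steady_state_exact()` reports `t = Inf` as an explicit
marker rather than a large number so serialization is unambiguous. When
DN4/ISP turnover is negligible the expression simplifies
(`steady_state_approx()`), which makes the central qualitative prediction
readable directly: raising $K_1, K_2, K_3$ together at fixed $K$ leaves
$C_1$ and $C_4$ comparatively stable while depleting $C_2$ and $C_3$.

**Transient after synchronised release.** With `K = 0`,
`Kd2 = Kd3 = 0` and all cells starting in DN3, the solution is a sum of
four exponentials with decay rates $\tilde K_1 = K_1+K_{d1}$, $K_2$, $K_3$,
$K_{d4}$. `transient_solution()` hard-codes these expressions with terms
grouped exactly as in the hand derivation, so each line can be verified
against it term by term; the $e^{-K_{d4}t}$ coefficient is written as minus
the sum of the other three, which also makes $C_4(0) = 0$ exact in floating
point. The DN4 peak time has the closed form
$\log(K_2/\tilde K_1)/(K_2-\tilde K_1)$ (`dn4_peak_time()`), with limit
$1/K_2$ at degeneracy.

**Degeneracy handling.** The closed form divides by every pairwise gap
among the four decay rates, so near-equal rates cause catastrophic
cancellation. Two rates are declared equal when
$|a-b| \le 10^{-9}\max(a, b, 1/\text{day})$; at or below that gap (or for
non-zero starting DN4/ISP/DP pools, non-zero `Kd2`/`Kd3`, or `K > 0`) the
input is dispatched — with a message, never silently — to
`spectral_solution()`, which evaluates the exact solution by matrix
exponential: around the fixed point
($C(t) = C_{ss} + e^{At}(C_0 - C_{ss})$) when the system matrix is
non-singular, otherwise via the affine system embedded in a 5×5
homogeneous one. The matrix exponential is entire, so repeated eigenvalues
need no special-casing.

A caution on long-time limits: the slowest mode relaxes at $K_{d4}$, i.e. a
time constant of roughly 1/0.00058 ≈ 1724 days for the presets. Trajectories
started far from the fixed point are only within $10^{-6}$ of it after
several times $10^4$ days; tests of the long-time limit use $5\times10^4$
days for this reason.

## Verification engines

Two independent engines guard the closed forms. `integrate_ode()` wraps a
stiff-safe adaptive integrator (default relative tolerance $10^{-8}$,
absolute tolerance $10^{-6}$ cells); agreement with the analytic solvers is
required to relative $10^{-6}$ on the reference grid. `simulate_ssa()`
implements the direct stochastic simulation algorithm for the same eight
reactions in compiled code, driven by R's RNG so a single integer seed
makes trajectories bit-reproducible. Because all rates are per-cell, the
verification runs use initial pools scaled down to $10^4$ cells (not
$3\times10^8$): the same per-cell dynamics, but 200 replicates complete in
seconds, and demographic noise is large enough to make the
mean-versus-ODE comparison a real test (means must fall within three
standard errors per compartment).

## The synthetic-data generator

`generate_dataset()` emulates the two observation designs the model can
confront: a steady-state cross-section of unperturbed mice, and groups of
recombination-deficient mice sampled at fixed days (default
0, 0.5, …, 3) after anti-CD3 injection, starting from $3\times10^8$ DN3
cells. For each virtual mouse the true compartment values come from the
model itself; noise is then applied:

- **Lognormal per-mouse noise** (default, CV 0.05) with unit median, chosen
  over additive Gaussian so counts stay positive and log-scale residuals
  are homoscedastic. Published per-mouse spreads are shown graphically only
  (mean ± SEM error bars), so no printed CV exists to calibrate against; 5%
  is a realistic inter-animal spread for total subset counts that keeps
  the rates comfortably identifiable at 20 mice per time point, and it is
  configurable to stress-test.
- **Finite-event sampling** (optional): `n_events` flow events drawn
  multinomially from the four subset proportions, rescaled to the mouse's
  total cellularity.

Counts are stored as real numbers by default, since the model is
continuous; half-even integer rounding is an opt-in flag. Datasets may
contain zeros in multinomial mode — the fitting loss handles these with a
pseudo-count (below). What the generator does *not* emulate: gating,
compensation, fluorescence intensities, FCS files, inter-run batch effects,
or any misspecification of the kinetic model itself. Passing recovery tests
therefore demonstrate estimator correctness under the model's own
assumptions, not robustness to real cytometry artifacts.

## Rate-constant inference

The estimator is deliberately simple and declared rather than derived: sum
of squared residuals on $\log(\text{count} + 0.5)$. The log scale matches
multiplicative noise; the pseudo-count 0.5 (configurable) keeps the loss
finite at multinomial zeros. No formal likelihood is claimed.

Optimisation runs on log-parameters, making positivity structural, inside
box bounds (default $[10^{-6}, 10]$ /day; $[1, 10^7]$ cells/day for $K$).
Eight restarts are drawn log-uniformly within the bounds (the first at the
box mid-point); each runs L-BFGS-B, then a Nelder–Mead polish, then
L-BFGS-B again — the polish is there because the quasi-Newton step can
report convergence on a bound face of the shallow valley between `K1` and
`Kd1`. A fit is `converged` only when the best restart terminated cleanly
*and* all restart optima agree to within $10^{-3}$ relative (the restart
dispersion), so a multimodal or unidentifiable problem surfaces as
`converged = FALSE` rather than as a silently arbitrary answer.

Identifiability is checked before fitting, not diagnosed after. The steady
state exposes only four observable combinations of the eight rates, so
`fit_influx_steady()` accepts at most `{K, Kd4}` free. In the transient
design, `K1` and `Kd1` enter the DN3 trajectory only through their sum, so
freeing both with only DN3 observed is refused. `Kd4` is fixed by default
in transient fits: over a 3-day window with $K_{d4} \approx 6\times10^{-4}$
/day its signal is negligible, and freeing it mostly inflates the restart
dispersion.

`bootstrap_ci()` resamples mice with replacement within (genotype, time)
strata and refits each replicate from three starts anchored near the point
estimate; percentile 95% intervals are reported, and a replicate failure
rate above 5% is flagged. `compare_genotype_fits()` divides knockout by
wild-type estimates parameter-wise, with fold-change intervals when both
fits carry bootstrap replicates (paired by index, valid because the fits
are independent).

## Numerical choices, tie-breaks, degenerate inputs

- Degeneracy tolerance $10^{-9}$ (relative, floored at 1/day), as above.
- Closed-form outputs are asserted non-negative to within $10^{-9}$ of the
  trajectory scale — a violation errors out rather than being clipped —
  and sub-tolerance floating-point undershoot is zeroed.
- All-zero rate sets are legal and yield constant dynamics; `Kd4 = 0` with
  `K > 0` raises "no finite steady state for DP".
- Genotype labels are normalised case- and punctuation-insensitively, so
  `"Itpkb-/-"` and `"itpkbko"` name the same preset.
- CSV artifacts are comma-separated, UTF-8, `.` decimal; steady states
  serialize their time as an infinity marker.

## Problem sizes used by the test suite

The suite exercises: recovery at the reference design (7 time points × 20
mice, 5% CV) for both no-influx presets plus a 20-seed replication of the
same design; solver cross-checks on 100 random log-uniform parameter sets
over 0–50 days; 200 stochastic replicates at $10^4$ starting cells for the
mean-field comparison; and bootstrap calibration with B = 100 over 10
replications of a 10-mouse cross-section. These sizes were chosen so each
statistical check has enough replication to be meaningful while the whole
suite stays comfortably fast to run during development.

## Known limitations

- Linearity: no feedback, no niche saturation, no density dependence; the
  model cannot represent homeostatic compensation.
- Net turnover conflates death and proliferation; it cannot distinguish a
  fast-dying, fast-dividing pool from a quiescent one, and net-proliferative
  compartments are excluded by the non-negativity constraint.
- Exactly four compartments: the transitional CD25-intermediate population
  between DN3 and DN4 is not a separate stage.
- The noise law is an assumption of the generator, not an estimate from
  data; real mouse-to-mouse variability and cytometry error need not be
  lognormal with constant CV.
- The steady-state design identifies only the four flux combinations; rich
  per-stage inference requires the transient design.
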