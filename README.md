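# thymokin

Kinetic modeling of thymocyte development through β-selection.

Developing T cells pass through the double-negative DN3 and DN4 stages, the
immature CD8 single-positive (ISP) stage, and accumulate as double-positive
(DP) thymocytes. `thymokin` implements a four-compartment linear ODE model
of this chain for quantitative immunologists who want to ask how changes in
per-stage differentiation and turnover rates reshape subset sizes — for
example, why a mutant with accelerated β-selection can show depleted DN4 and
ISP pools while DN3 and DP numbers look normal.

## The model

With subset sizes $C_1$ (DN3), $C_2$ (DN4), $C_3$ (ISP), $C_4$ (DP),
constant progenitor influx $K$ (cells/day), differentiation rates $K_1, K_2,
K_3$ and net turnover rates $K_{d1}\ldots K_{d4}$ (all 1/day):

$$
\begin{aligned}
dC_1/dt &= K - (K_1 + K_{d1})\,C_1\\
dC_2/dt &= K_1 C_1 - (K_2 + K_{d2})\,C_2\\
dC_3/dt &= K_2 C_2 - (K_3 + K_{d3})\,C_3\\
dC_4/dt &= K_3 C_3 - K_{d4}\,C_4
\end{aligned}
$$

The package provides, as separately tested stages:

- **Closed-form solutions** — the exact steady state (flux balance), its
  simplified form when DN4/ISP turnover is negligible, and the
  four-exponential transient solution for the no-influx scenario
  (synchronised release from DN3 arrest after anti-CD3 injection of
  recombination-deficient mice), with a matrix-exponential solver for
  repeated-rate and influx cases.
- **Verification engines** — a stiff-safe numerical ODE integrator and an
  exact Gillespie-type stochastic simulator of the same reaction network.
- **A synthetic-data generator** — per-virtual-mouse noisy subset counts
  under the two observation designs (steady-state cross-section; day 0–3
  anti-CD3 time course), with lognormal per-mouse noise and optional
  finite-event flow sampling.
- **Rate-constant inference** — multi-start least squares on log counts,
  with identifiability guards, case-resampling bootstrap intervals, and
  genotype fold-change comparison.

## Worked example

```r
library(thymokin)

# built-in genotype presets
steady_state_exact(preset_parameters("WT"))
#>         DN3         DN4         ISP          DP
#>    770000.0    475308.6   1100000.0 132758620.7
steady_state_exact(preset_parameters("Itpkb-KO"))
#>         DN3         DN4         ISP          DP
#>    513333.3    211248.3    488888.9 177011494.3
```

The knockout preset (differentiation rates raised two- to three-fold at
fixed influx) depletes DN4 and ISP to 4/9 of wild type while DN3 (2/3) and
DP (4/3) stay near wild-type levels — the steady-state signature of faster
β-selection.

```r
# recover the rate constants from synthetic anti-CD3 time courses
fit_one <- function(g) {
  design <- experiment_design("acd3_timecourse", g, mice_per_group = 20)
  obs <- generate_dataset(design, noise_model(cv = 0.05), seed = 1)
  fit_transient(obs, fit_config(seed = 1))
}
fit_ko <- fit_one("Rag2-ItpkbKO")
fit_ko
#> <fit_result> model: transient | n_obs: 560
#>       K1      Kd1       K2       K3
#> 0.200708 0.100662 0.483571 0.209997
#> loss = 1.272 | converged = TRUE | restart dispersion = 4.31e-06

compare_genotype_fits(fit_one("Rag2-WT"), fit_ko)
#>   parameter     wt    ko fold_change
#> 1 K1        0.101  0.201       2.00
#> 2 Kd1       0.101  0.101       0.999
#> 3 K2        0.161  0.484       3.00
#> 4 K3        0.0700 0.210       3.00
```

From 20 virtual mice per time point at 5% noise, the generating rates
(knockout: `K1 = 0.2`, `K2 = 0.486`, `K3 = 0.21` /day) come back within
~1%, and the genotype comparison recovers the two-fold-or-larger increase
in every differentiation step. The knockout DN4 wave also peaks earlier
(`dn4_peak_time`: 2.59 vs 5.55 days).

## Command line

A thin wrapper over the same functions lives at `inst/cli/thymokin.R`:

```sh
Rscript inst/cli/thymokin.R steady-state --genotype WT --genotype Itpkb-KO --out ss.csv
Rscript inst/cli/thymokin.R simulate --scenario acd3 --genotype Rag2-WT \
    --genotype Rag2-ItpkbKO --engine analytic --dt 0.125 --days 3 --out tc.csv
Rscript inst/cli/thymokin.R generate --scenario acd3 --genotype Rag2-ItpkbKO \
    --mice 20 --cv 0.05 --seed 1 --out obs.csv
Rscript inst/cli/thymokin.R fit --data obs.csv --genotype Rag2-ItpkbKO \
    --model transient --seed 1 --out fit.json
```

Every run writes a `*.manifest.json` recording the command, options and
seeds, so any artifact can be reproduced exactly.

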