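---
title: "Two-state stability analysis of 2D unfolding surfaces"
author: "stabfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state stability analysis of 2D unfolding surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabfit)
```

## The model

`stabfit` analyses equilibrium unfolding experiments in which a protein is
melted thermally at a ladder of chemical denaturant (GuHCl) concentrations
while its intrinsic fluorescence is recorded — the two-dimensional
generalisation of the classic single melt. Under the two-state assumption
only folded (N) and unfolded (U) molecules are populated, and the folding
free energy at temperature $T$ (Kelvin) and denaturant concentration $D$
(molar) is

$$
\Delta G_f(T, D) \;=\; \Delta H_m\left(1 - \frac{T}{T_m}\right)
 + \Delta C_p\left(T - T_m - T \ln \frac{T}{T_m}\right) + m D ,
$$

the Gibbs–Helmholtz relation in $T$ combined with the linear extrapolation
method (LEM) in $D$. We use the *folding* sign convention throughout:
$\Delta G_f < 0$ means the folded state is favoured, $\Delta H_m < 0$ for a
cooperative folder, and the m-value $m > 0$ so that denaturant always
destabilises. The four parameters per variant are

| parameter | meaning | units |
|---|---|---|
| $T_m$ | melting temperature in water, $\Delta G_f(T_m, 0) = 0$ | K |
| $\Delta H_m$ | folding enthalpy at $T_m$ | kJ/mol |
| $\Delta C_p$ | heat-capacity change of folding (curvature of the stability curve; admits cold denaturation) | kJ/mol/K |
| $m$ | LEM sensitivity to GuHCl, proportional to the surface newly exposed on unfolding | kJ/mol/M |

The unfolded population is logistic in $\Delta G_f$,
$f_U = 1/(1 + e^{-\Delta G_f / RT})$ with
$R = 0.008314$ kJ/mol/K, and the measured fluorescence mixes two state
baselines,

$$
F(T, D) = B_N(T, D)\,(1 - f_U) + B_U(T, D)\, f_U ,
\qquad B_X(T,D) = a_X + b_X T + c_X D .
$$

The baseline form is a modelling choice, not physics: linear temperature
drift per state is standard practice for nanoDSF data, and the optional
linear denaturant terms ($c_X$, on by default, removable with
`fit_options(denaturant_baselines = FALSE)`) absorb the common solvent
effect on quantum yield. One baseline pair is shared by all denaturant
series of a replicate; replicates of a variant share thermodynamics but
get their own baselines, which keeps the parameter count identifiable with
the 6–16 series of a typical design.

Derived quantities all flow from $\Delta G_f$: the unfolding midpoint at a
reference temperature $[D]_{50\%} = -\Delta G_f(T, 0)/m$, and the apparent
melting temperature at fixed $D$, the root of $\Delta G_f(\cdot, D) = 0$.
For the latter note that the stability curve is a parabola-like function of
temperature with a maximum at $T_s$; at denaturant concentrations
approaching $[D]_{50\%}$ it crosses zero twice (cold and heat
denaturation). `melting_temperature_at()` deliberately returns the warm
root — the one a melt experiment observes — by bracketing above $T_s$.

## Global fitting

`fit_variant()` minimises the unweighted sum of squared signal residuals
over every unmasked point of every series simultaneously
(Levenberg–Marquardt, via `minpack.lm`), so a 13-series surface constrains
one set of thermodynamic parameters plus baselines. Unweighted least
squares reflects the data source: instrument exports carry no per-point
uncertainties, and the additive-noise model below is homoscedastic.

Starting values come from the data (`initial_guess()`): the $T_m$ guess is
the extremum of the smoothed temperature derivative of the
lowest-denaturant series, baselines come from straight-line fits to the
first and last 15% of each curve, and the remaining parameters start from
values generic for a small single-domain protein
($\Delta H_m = -300$ kJ/mol, $\Delta C_p = -4$ kJ/mol/K, $m = 8$ kJ/mol/M).
A series whose largest derivative excursion does not exceed five times the
noise floor of the derivative (noise estimated from second differences of
the raw signal) is declared transition-free and refused — a max/MAD test
was rejected because broad transitions such as I57A's span most of the
ramp and inflate the MAD. To guard against baseline/transition swaps the
optimiser restarts from five seeded jitters of the guess (2 K on $T_m$, 5%
elsewhere) and keeps the lowest sum of squares, ties broken by first
index. Convergence uses a relative SSR tolerance of $10^{-12}$ with at
most 500 iterations; parameters are softly bounded to the physically
meaningful orthant ($T_m \in [220, 430]$ K, $\Delta H_m < 0$,
$\Delta C_p \le 0$, $m > 0$).

Standard errors use the Gauss–Newton covariance
$\hat\sigma^2 (J^\top J)^{-1}$ with $\hat\sigma^2 = \mathrm{SSR}/\mathrm{dof}$,
the Jacobian evaluated by central differences at the optimum; a singular
$J^\top J$ (e.g. coinciding baselines) raises a `degenerate_fit` error
rather than returning meaningless errors. Derived quantities —
$\Delta G_f(298\,\mathrm{K})$, $[D]_{50\%}$, apparent $T_m(D)$ — get
first-order (delta-method) errors from analytic gradients and the full
parameter covariance (`derived_quantity_error()`); the midpoint and
apparent-$T_m$ gradients use the quotient rule and the implicit-function
theorem respectively. Tests confirm the delta-method errors against
parametric Monte Carlo from the same covariance.

### Common m-values

When variants bury comparable surface area their m-values should agree,
and re-fitting with a single m sharpens comparisons of $\Delta G_f$
between variants. Two constructions are exposed because published analyses
use both and they are not identical:

* **fixed m** (`fit_options(fixed = list(m_value = 8.4))`) — the default
  reading: an average m (e.g. `average_m()` over previously fitted
  variants) is imposed as a constant, exactly the "m fixed at
  8.4 kJ/mol/M" re-analysis of the CI2 cycle variants;
* **jointly estimated m** (`fit_options(share_m = TRUE)`) — one m is a
  free parameter common to all variants of a `fit_joint()` call.

Either way m stops consuming a per-variant degree of freedom and the
standard errors of the remaining parameters drop — which is also why
common-m $\Delta\Delta G_f$ values are not directly comparable with
free-fit ones. The reference temperature for stabilities is 298 K (the
convention of the tabulated panel; configurable everywhere it appears).

## Double-mutant cycles

For a cycle wild-type → two singles → double,
$\Delta\Delta G_f = \Delta G_f(\mathrm{variant}) - \Delta G_f(\mathrm{wt})$
and the coupling energy is the deviation from additivity,

$$
\Delta\Delta\Delta G_f = \Delta\Delta G_{f,12} -
 (\Delta\Delta G_{f,1} + \Delta\Delta G_{f,2}),
$$

negative when the two substitutions stabilise synergistically. Errors
combine in quadrature, treating records as independent Gaussians — the
convention that reproduces published cycle uncertainties; when two
stabilities come from one joint fit and their covariance is known, `ddg()`
accepts it and subtracts the correlation term. Records carry their
provenance (`free-fit`, `common-m`, `external-prediction`) and refuse to
mix across analyses, because a free-fit $\Delta G_f$ and a common-m one
answer subtly different questions. `compare_predictions()` correlates an
experimental $\Delta\Delta G_f$ table with an external predictor table
(FoldX/Rosetta-style output read as input, never recomputed) by Pearson's
r on the label intersection.

Reported tables round half-away-from-zero at one decimal (enthalpy to the
integer), matching the conventions of the published panel;
`report_table()` sorts variants from least to most stable.

## The synthetic-data generator

`simulate_dataset()` forward-simulates the identical model the fitter
minimises — literally the same `predicted_signal()` code path, so the
generator and fitter cannot drift apart — on the published experimental
design: 13 GuHCl levels evenly spaced over 0–5 M, a 15–95 °C ramp, and
additive i.i.d. Gaussian noise. The temperature grid is 0.5 °C by default,
denser than the instrument's 1 °C/min ramp implies per read, purely to
keep fits well-conditioned; it is configurable. The default noise SD is 1%
of the native-to-unfolded amplitude at mid-range conditions: no instrument
noise figure is published for this assay, and 1% reproduces a replicate
scatter of fitted $\Delta G_f(298)$ comfortably inside the pooled
experimental reproducibility of 1.2 kJ/mol. The default baseline truth
(native 1000, −2 signal/K; unfolded 600, −1 signal/K, +20 signal/M) gives
a well-separated, realistically sloped transition. Each series draws its
own RNG substream derived deterministically from the design's master seed:
identical seeds give bit-identical datasets, and per-series noise is
uncorrelated. `simulate_cycle()` derives four independent corner streams
from one master seed. `table1_parameters()` supplies published truths for
all 26 CI2 variants of the panel.

What the generator does *not* emulate — and hence what passing recovery
tests do not certify about real data: autocorrelated or heteroscedastic
instrument noise, baseline curvature, aggregation artefacts (only maskable
via `mask_dataset()`, as for a variant aggregating above 50 °C at low
GuHCl), deviations from two-state behaviour, and replicate-to-replicate
systematic shifts, which in practice dominate the pooled 1.2 kJ/mol
scatter. Simulated standard errors are therefore optimistic relative to
experimental ones.

## Worked cycle, and what the package reproduces

```{r cycle}
tab <- table1_data()
rec <- function(v) {
  row <- tab[tab$variant == v, ]
  stability_record(v, row$ddg_common_m, row$ddg_common_m_se, source = "common-m")
}
coupling_energy(rec("D55G"), rec("I57V"), rec("D55G/I57V"))
coupling_energy(rec("L49I"), rec("I57V"), rec("L49I/I57V"))
average_m(tab$m_value[match(c("wild-type", "L49I", "D55G", "I57V",
                              "D55G/I57V", "L49I/I57V"), tab$variant)])
```

An end-to-end exercise — simulate wild-type and L49I/I57V from their
published parameters, joint-fit with m fixed at the consensus 8.4, and
difference the stabilities at 298 K — recovers the common-m
$\Delta\Delta G_f$ of the double mutant:

```{r endtoend, eval = FALSE}
ds <- list(
  simulate_dataset(table1_parameters("wild-type"), default_baselines(),
                   experiment_design(seed = 421), "wild-type"),
  simulate_dataset(table1_parameters("L49I/I57V"), default_baselines(),
                   experiment_design(seed = 422), "L49I/I57V"))
fits <- fit_joint(ds, fit_options(fixed = list(m_value = 8.4)))
ddg(stability_from_fit(fits[["L49I/I57V"]], source = "common-m"),
    stability_from_fit(fits[["wild-type"]], source = "common-m"))
```

Two numerical honesty notes on this exercise. First, the published
free-fit stabilities differ by only −2.4 kJ/mol, while the common-m
analysis reports −3.8: fixing m rescales each variant's free-energy axis
by $m_{\text{fix}}/m_{\text{true}}$ (the fit pins the midpoints, which are
m-invariant), and the same mechanism acts on the simulation, whose
recovered value settles near −3.75 — the small remaining gap to −3.8 is
the least-squares compromise between matching midpoints and matching
transition widths, plus the rounding of the tabulated truths used as
simulation inputs. Second, the test-suite problem sizes (7 denaturant
levels, 1 °C grid for most fitting tests; the full 13 × 0.5 °C design for
the end-to-end and replicate-scatter checks, 20 seeds for the latter) were
chosen as the smallest designs that still satisfy the design invariants
and exercise every code path.

## Limitations

Strictly two-state: misfit from intermediates or aggregation shows up only
in residual diagnostics (`residual_sd`), never in an automatic model
switch. No Bayesian posterior, no heteroscedastic weighting, no
instrument-export parsers beyond the tidy CSV dialect
(`read_dataset()`/`write_dataset()`). The m-value is treated as
temperature-independent and $\Delta G_f$ as exactly linear in GuHCl over
0–7 M; $\Delta H_m$ and $\Delta C_p$ carry no denaturant dependence —
assumptions inherited from the LEM and appropriate for the data this
package targets.
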