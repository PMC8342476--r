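---
title: "A nitrogen-constrained model of C3, C3-C4 and C4 photosynthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A nitrogen-constrained model of C3, C3-C4 and C4 photosynthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoalloc)
```

## The model

`photoalloc` models a leaf whose photosynthetic proteome is built from a fixed
budget of photosynthetic nitrogen, $N_{ps}$, taken as a fraction of total leaf
nitrogen $N_t$ (shipped map: $N_{ps} = 0.75 \cdot N_t$, linear; the fraction
and the functional form are configurable hooks, since any saturating empirical
relation can be substituted). The budget is split across three pools:

* **Rubisco** ($n_{Etot}$): catalytic sites
  $E_{tot} = n_{Etot} N_{ps} c_E$ with $c_E = 1.27\times 10^{-3}$ µmol sites
  (µmol N)$^{-1}$.
* **C4-cycle enzymes** ($n_{C4}$): PEPC and PPDK co-limit the CO2 pump,
  $V_{pmax} = n_{C4} N_{ps} / (MW^*_{PPDK}/k_{cat,PPDK} +
  MW^*_{PEPC}/k_{cat,PEPC})$. $MW^*$ converts a molecular weight to µmol N per
  µmol catalytic site assuming proteins are 16% nitrogen by mass:
  $MW^* = 0.16 \, MW / 14$ (14 g mol$^{-1}$ N). This mole-basis reading keeps
  the equation dimensionally consistent with $N_{ps}$ in µmol m$^{-2}$ and is
  exposed through `protein_N_fraction`.
* **Thylakoids** ($n_{Jmax}$): chlorophyll is proportional to thylakoid
  nitrogen ($Chl = n_{Chl}\, n_{Jmax} N_{ps}$, $n_{Chl} = 0.0158887$; the
  linear form is a documented assumption with a configurable hook). The
  chlorophyll pool is wired into a linear chain (proportion $p$, carrying PSII
  and producing both ATP and NADPH) and a cyclic chain (proportion $1-p$, PSI
  only, ATP only). After paying the photosystem and light-harvesting nitrogen
  costs per chlorophyll, the remaining thylakoid nitrogen buys cytochrome f,
  whose electron capacity (172 mmol e$^-$ (mmol cyt s)$^{-1}$; three-fold
  higher per cytochrome for the cyclic chain, which forgoes the
  nitrogen-expensive PSII) sets $J_{max,LET}$ and $J_{max,CET}$. Negative
  cytochrome budgets clamp $J_{max}$ at zero; a LET share too small to hold
  the photosystems ($p < 0.2373$ at the reference constants) is an infeasible
  wiring and is excluded from optimization.

Light drives electron transport through the usual non-rectangular hyperbola
(convexity $\Theta = 0.7$) applied per chain, with absorptance 0.84, spectral
correction 0.15, and the LET quanta shared equally between its two
photosystems (factor 0.5). ATP and NADPH supply follow chain stoichiometry:
NADPH only from the linear chain (2 e$^-$ per NADPH), ATP from both
($e_{ATP} = 4/3$ for the linear chain; for the cyclic chain 2 H$^+$ per
e$^-$ with a configurable `h_per_atp`, default 4).

### Energy partition and the light-limited rate

The energy supply is partitioned across five consumers — Calvin–Benson cycle
and photorespiration in each of mesophyll and bundle sheath, plus the C4
pump — by explicit fractions that are decision variables of the optimizer
(the partition principle constrains each process by its allocated pool, so we
optimize the pools rather than impose closed-form splits). Demand
stoichiometry per net carboxylation is 3 ATP + 2 NADPH, per oxygenation
3.5 ATP + 2 NADPH, and 2 ATP per PEP regenerated. Oxygenation is tied to
carboxylation by $\phi = 2\Gamma^*/C$ at the local gas levels, so a pool's
carboxylation runs at the lower of its own cap and its photorespiratory
pool's cap divided by $\phi$. ATP- and NADPH-limited rates are computed
independently and the light-limited rate is their minimum.

### Enzyme-limited rate and the bundle sheath

The enzyme-limited branch distributes Rubisco between mesophyll
(fraction $1-\beta$) and bundle sheath ($\beta$), pumps
$V_p = C_m V_{pmax}/(C_m + K_p)$ into the bundle sheath, routes a fraction
$\xi$ of mesophyll-oxygenation glycine to bundle-sheath decarboxylation (the
C3–C4 shuttle), and solves the bundle-sheath CO2 balance
$V_p + \tfrac12 \xi V_{o,m} + \tfrac12 V_{o,s} = V_{c,s} + g_s (C_s - C_m)$
by bracketed root finding on $C_s$ (absolute tolerance $10^{-10}$ µbar).
Bundle-sheath O2 rises with the PSII fraction operating there, which is set
to $p$; the elevation uses the 0.047 diffusivity/solubility ratio of O2 to
CO2 and is applied in both the enzyme- and light-limited branches for
physical consistency. Net assimilation is carboxylation minus half of
oxygenation in both compartments, minus day respiration (`R_d`, default 0 so
the minimum-of-limitations structure is reproduced literally).

The realized rate is $A = \min(A_j, A_c)$; ties are labeled enzyme-limited
(an arbitrary but fixed rule for reproducibility).

### Temperature

Every temperature-dependent quantity ($V_{pmax}$, Rubisco turnover, the two
$J_{max}$, $K_p$, $K_c$, $K_o$, Rubisco specificity) carries its own peaked
Arrhenius curve with activation energy $E$, deactivation energy $H$ and
entropy factor $S$; $H = \infty$ marks quantities with no deactivation and
reduces the curve to plain Arrhenius. At 298.15 K every curve returns its
reference value exactly. Shipped parameters are standard literature values
(Massad-type peaked curves for the C4 cycle, Rubisco turnover and electron
transport; Bernacchi-type activation energies for the Michaelis constants; a
declining curve, $E = -37.83$ kJ mol$^{-1}$, for specificity). All are
config-overridable, and their provenance is tracked.

### Rubisco kinetics from one parameter

Rubisco kinetics are set by the single turnover rate $k_{ccat}$; $K_c$ and
the CO2/O2 specificity follow from the catalytic trade-off as power laws
anchored at a typical C3 enzyme ($k_{cat}$ 3.5 s$^{-1}$, $K_c$ 650 µbar,
$K_o$ 450 mbar, specificity 2590 on a partial-pressure basis; exponents 2
and −0.5). The anchors and exponents are a documented, configurable default:
they reproduce the classic C3 compensation point
($\Gamma^* \approx 40.5$ µbar at 210 mbar O2) and give a faster, less
specific C4 enzyme.

## Optimization

For a species (defined by $\beta$, $k_{ccat}$, $\xi$, $K_p$, $g_s$ and
allocation bounds — C3 types have a hard zero bound on the C4 pool) and an
environment (irradiance, temperature, mesophyll CO2, O2, leaf nitrogen), the
optimizer maximizes $A$ over the nitrogen fractions, the LET proportion and
the five energy fractions. The two sum-to-one equality constraints are
eliminated by reparameterization — bounded stick-breaking for the nitrogen
simplex, softmax over the *structurally active* energy pools (a C3 plant's
C4 pool is exactly zero, not merely small) — leaving an unconstrained
problem solved by multistart Nelder–Mead (relative objective tolerance
$10^{-8}$, up to 2000 evaluations per start) from a deterministic Halton
sequence plus physiology-informed starts; the default is 20 starts. The
incumbent is then refined in three stages — repeated simplex restarts,
an active-set pass that pins near-bound coordinates exactly at their bound
(sigmoid coordinates approach bounds only asymptotically), and an
energy-only sub-optimization at frozen nitrogen and LET proportion — and
the final optimum is re-verified by a fresh forward simulation. The surface has
kinked ridges where limitations cross (optima are typically tri-co-limited:
ATP-, NADPH- and enzyme-limited rates agree to within a percent), which is
why a multistart direct-search method is used rather than a gradient method.

`grid_oracle()` is the validation reference: exhaustive nitrogen-simplex ×
$p$ grid search with a nested coarse energy search (flux-demand-proportional
candidates, then Nelder–Mead refinement at the best points). Because a grid
at resolution 21 can sit a few tenths of a percent below a continuous
interior optimum, the oracle optionally polishes the best grid point over
all variables; the unpolished grid value is retained for dominance checks.

`optimize_energy_given_nitrogen()` implements the alternative plasticity
model: protein pools frozen, energy fractions and $p$ re-optimized for a new
(measurement) environment.

## Analyses

* `delta_n()` — the required nitrogen re-allocation between two optimal
  allocations, $\delta_n = \sum_{i \in \{Etot, C4, Jmax\}} |n_i^{evo} -
  n_i^{growth}|$. The LET proportion is excluded: it re-wires energy, not
  nitrogen between the three pools.
* `normalized_squared_residuals()` — squared residuals as fractions of the
  experimental mean, computed per quantity (quantities have different
  units); their mean is the scan error.
* `compare_scenarios()` — two-sided Wilcoxon rank-sum on residual
  distributions (exact for combined $n \le 20$ without ties, normal
  approximation with continuity correction otherwise) and a paired sign test
  for $\delta_n$ comparisons.
* `environment_scan()` — optimal allocation and pool predictions for every
  cell of an (I, T, C$_m$) grid at fixed O2, scored against measured
  quantities; the argmin cell is the inferred (e.g. ancestral) environment.
  `scan_predictions()` exposes the expensive per-cell stage for reuse across
  replicate scorings, and can augment the per-cell fingerprint with
  response-curve sweeps (`curve_specs`): the seven pool quantities alone are
  strongly collinear (four scale with the thylakoid pool), so neighbouring
  cells can sit within the noise floor of each other, whereas a multi-point
  A–Ci or A–T curve separates them reliably. Quantities measured as
  identically zero (structurally absent pools) are excluded from scoring
  since they cannot be normalized.
* `response_curves()` — A–Ci, A–T and A–N sweeps at a *fixed* allocation,
  reflecting that protein pools cannot re-adjust on the timescale of a
  measurement.
* `synthetic_measurements()` — the synthetic-data generator: model
  predictions with multiplicative Gaussian noise $(1+\varepsilon)$,
  $\varepsilon \sim N(0, \sigma^2)$, seeded. It emulates the noise structure
  of gas-exchange and proteome-pool measurements; it does not emulate
  instrument drift, systematic calibration bias, or between-plant variance
  components, so recovery results speak to statistical identifiability
  under honest noise, not to robustness against systematic error.

## Shipped parameterization and study conditions

Defaults follow the study design the package addresses: an evolutionary
scenario (1500 µmol quanta m$^{-2}$ s$^{-1}$ — a stated assumption standing
in for "high light" — 30 °C, 280 µbar atmospheric CO2, 200 mbar O2) and
three growth-condition presets (560 µmol, 37 °C and 554 µmol, 30 °C at
380 µbar; 550 µmol at 25 or 35 °C, 380 µbar). Mesophyll CO2 derives from
atmospheric CO2 via $C_a/C_i$ (type defaults 1/0.7 for C3, 1/0.4 for C4 —
flagged assumptions) and $C_m/C_i = 0.85$. The four species archetypes span
the C3→C4 trajectory with provisional literature-typical values
($\beta$ 0 → 0.95, $k_{ccat}$ 3.5 → 5.44 s$^{-1}$, $\xi$ 0/1, $K_p$ 80 µbar,
$g_s$ 0.003 µmol m$^{-2}$ s$^{-1}$ µbar$^{-1}$); they are archetypes, not
transcriptions of measured species, and all values are overridable through
the YAML configuration.

### Worked example

```{r example, eval = FALSE}
arch <- species_archetypes()
evo <- environment_spec(I = 1500, T_leaf = 30, N_t = 130, C_a = 280, O = 200)
gro <- environment_spec(I = 554, T_leaf = 30, N_t = 130, C_a = 380, O = 210)

opt_evo <- optimize_allocation(arch[["C4"]], evo)
opt_gro <- optimize_allocation(arch[["C4"]], gro)
tidy(opt_evo)
delta_n(opt_evo, opt_gro)

aci <- response_curves(arch[["C4"]], gro, opt_evo$alloc, opt_evo$partition,
                       sweep = "Ci", values = seq(50, 600, by = 25))
plot_response_curves(aci)
```

## Numerical choices and problem sizes

* Bundle-sheath CO2: bracketed `uniroot` with absolute tolerance
  $10^{-10}$ µbar; the O2 elevation is an inner fixed point (contraction
  factor well below 1 for physical parameters) iterated to $10^{-10}$
  relative, warm-started across root-finder iterations.
* Exponential arguments in the Arrhenius curve are clamped at ±700 to avoid
  overflow; the curve is positive and never NaN.
* Optimizer: 20 starts by default; analyses that optimize over many
  environment cells (the environment scan) use 4–6 starts and a few hundred
  evaluations per start, which we found sufficient because per-cell optima
  are re-used consistently on both sides of the residual comparison. The
  grid oracle runs at resolution 21 per axis in validation.
* Ties in $\min(A_j, A_c)$ label the result enzyme-limited; ties between
  ATP and NADPH label it ATP-limited.

## Known limitations

* The exact species parameter values and fitted temperature parameters of
  the original *Flaveria* studies reside in supplementary material that is
  not redistributed here; the archetypes are provisional stand-ins, so
  quantitative outputs (e.g. the re-allocation table, absolute cytochrome-f
  contents) should be read as model-structure results, not species
  reproductions, until a user supplies a measured parameterization.
* Under the shipped linear $N_{ps}$ map and the $\Theta = 0.7$ hyperbola,
  low-light optima invest heavily in thylakoids (extra $J_{max}$ always buys
  a little more electron transport). Empirical thylakoid-proportion
  relations would temper this; the hooks exist (`N_ps` map, chlorophyll
  map, allocation bounds) but no such relation is imposed by default.
* Stomata and water relations are not modeled (mesophyll CO2 is an input);
  leaf temperature equals air temperature; Rubisco is fully activated;
  no diurnal or seasonal environmental fluctuation.
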