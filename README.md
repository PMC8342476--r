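# photoalloc

Nitrogen-constrained modeling of C3, C3–C4 intermediate and C4 photosynthesis,
with optimal resource allocation and ancestral-environment inference.

## The problem

C4 plants concentrate CO2 around Rubisco with an energy-hungry biochemical
pump, and pay for it — like every other part of the photosynthetic
apparatus — in **nitrogen**: Rubisco, the C4-cycle enzymes PEPC and PPDK,
and the thylakoid electron-transport chains are the three dominant nitrogen
sinks of a leaf. `photoalloc` models a leaf that must divide a fixed
photosynthetic nitrogen budget `N_ps` between these pools and asks which
division — together with the wiring of the thylakoids between linear and
cyclic electron transport and the partitioning of ATP/NADPH between
consuming processes — maximizes net CO2 assimilation in a given environment
(irradiance, temperature, mesophyll CO2, O2, leaf nitrogen).

Comparing the allocation that is optimal for a plant's *growth* environment
with the one optimal for the environment in which its lineage *evolved*
yields a measure of how much nitrogen would have to move between pools for
the plant to acclimate:

```
delta_n = |n_Etot^evo - n_Etot^growth| + |n_C4^evo - n_C4^growth| + |n_Jmax^evo - n_Jmax^growth|
```

and scanning candidate environments for the one whose optimal-allocation
predictions best explain measured data (mean squared residuals, normalized
to fractions of experimental means) turns the model into an inference tool
for the environment a lineage is adapted to.

The core model couples:

* **nitrogen → capacity** stoichiometry (Rubisco sites `E_tot`, C4-cycle
  `V_pmax`, chlorophyll, photosystem/LHC/cytochrome-f composition, and the
  maximal electron transport rates `Jmax_LET`, `Jmax_CET`),
* **light → electron transport** (non-rectangular hyperbola, convexity 0.7)
  and chain-specific ATP/NADPH yields (NADPH from the linear chain only),
* **enzyme-limited** two-compartment assimilation (PEPC pump, bundle-sheath
  CO2/O2 elevation with leak conductance `g_s`, the C3–C4 glycine shuttle
  `xi`) and **light-limited** assimilation from per-pool ATP/NADPH budgets,
  with `A = min(A_j, A_c)`,
* a **peaked Arrhenius** temperature response per kinetic quantity, and
* a **multistart constrained optimizer** over the nitrogen simplex, the LET
  proportion `p`, and the five-pool energy partition.

## Worked example

```r
library(photoalloc)

arch <- species_archetypes()           # C3, C3-C4, C4-like, C4
evo  <- environment_spec(I = 1500, T_leaf = 30, N_t = 130, C_a = 280, O = 200)
gro  <- environment_spec(I = 554,  T_leaf = 30, N_t = 130, C_a = 380, O = 210)

opt_evo <- optimize_allocation(arch[["C4"]], evo)
opt_evo
#> <photo_optim> C4 archetype @ environment
#>   A* = 48.6442 umol m-2 s-1
#> <photo_allocation>
#>   n_Etot = 0.1181, n_C4 = 0.2065, n_Jmax = 0.6754, p = 1
#> <photo_partition> f_cb_m = 1.769e-18, f_pr_m = 1.769e-18, f_cb_s = 0.5298,
#>   f_pr_s = 0.05394, f_c4 = 0.4163
```

The C4 archetype in the high-light, low-CO2 evolutionary environment fixes
48.6 µmol CO2 m⁻² s⁻¹ at its optimum, investing about 12% of photosynthetic
nitrogen in Rubisco, 21% in the C4-cycle enzymes and 68% in the thylakoids;
42% of the energy supply goes to the CO2 pump. At the optimum the ATP-,
NADPH- and enzyme-limited rates co-limit (they agree to six digits here).

```r
opt_gro <- optimize_allocation(arch[["C4"]], gro)
delta_n(opt_evo, opt_gro)
#> <photo_delta_n> evo vs growth: delta_n = 0.3435
#>   per pool: Etot = 0.05711, C4 = 0.1146, Jmax = 0.1717
```

About 34% of the photosynthetic nitrogen budget would have to move between
pools for this plant to re-optimize from the evolutionary to the growth
environment — the quantitative sense in which acclimation is expensive.

Response curves at a frozen allocation (allocations cannot re-adjust during
a measurement), environment scans and synthetic data:

```r
aci <- response_curves(arch[["C4"]], gro, opt_evo$alloc, opt_evo$partition,
                       sweep = "Ci", values = seq(50, 600, by = 25))
plot_response_curves(aci)

grid <- scan_predictions(arch[["C4"]], I_values = c(600, 1200, 1800),
                         T_values = c(20, 30, 40), Cm_values = c(60, 100, 180))
noisy <- synthetic_measurements(table = grid$prediction[[14]],
                                noise_sd = 0.05, seed = 1)
scan <- environment_scan(measured = noisy, predictions = grid)
scan$argmin     # the inferred environment
autoplot(scan)  # error surface
```

A YAML configuration (`load_config()` / `save_config()`) overrides any
constant, species, environment or temperature parameter; an empty
configuration ships the four archetypes and the study-condition presets.
A thin command-line interface is installed at `inst/photoalloc`
(`photoalloc simulate|optimize|delta-n|scan-env|fit-compare`).

## Caveat on shipped parameters

The four species archetypes and the temperature-response defaults are
provisional literature-typical values, not transcriptions of measured
*Flaveria* species (see the methods vignette,
`vignettes/nitrogen-allocation-model.Rmd`, for what this does and does not
allow you to conclude). Supply a measured parameterization through the YAML
configuration for species-level work.
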