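# nadtherm

Temperature-dependent kinetic analysis of the two bacterial NAD salvage
routes: the four-step PncA/Preiss–Handler pathway
(Nam → NA → NAMN → NAAD → NAD) and the two-step Nampt pathway
(Nam → NMN → NAD). The four-step route costs about twice the ATP per NAD
— the NAD synthase step cleaves ATP to AMP — yet dominates in many
bacteria, especially thermophiles. Its deamidated intermediates, however,
are far more resistant to non-enzymatic glycohydrolysis at high
temperature. `nadtherm` is for modellers who want to weigh that chemical
stability against the extra energetic cost quantitatively.

The package provides, as a single tested pipeline:

* **Arrhenius fitting** of measured thermolysis rates, k = A·exp(−Ea/(R·T)),
  by unweighted nonlinear least squares on the rate scale with a
  deterministic multistart (`fit_arrhenius()`); the measured rate table is
  bundled.
* An 8-species, 18-reaction **kinetic model** of both routes with
  Arrhenius-scaled Michaelis–Menten and first-order rate laws and a
  conserved 0.3 mM pyridine pool (`build_default_model()`).
* A compiled pseudo-transient/**Newton steady-state solver**
  (`solve_steady_state()`), cross-checked against stiff integration.
* **ATP accounting**: J_ATP = J_Nampt + J_PncB + 2·J_NadE + J_NadD + J_NadR,
  J_NAD = J_NadE + J_NadD(NMN), and their ratio (`energy_account()`).
* **Evolutionary-programming optimization** of the nine enzyme abundances
  (population 20, 200 generations, tournament q = 5, log-space
  self-adaptive mutation) under three objectives — minimize J_ATP/J_NAD,
  minimize J_ATP, maximize C_NAD — with bounds, an enzyme budget and an
  NAD feasibility window (`run_ep()`, `repeat_and_classify()`,
  `temperature_sweep()`).
* **Metabolic control analysis**: concentration control coefficients of
  all enzymes and hydrolysis constants, Richardson-verified
  (`control_coefficients()`).
* Seeded **synthetic-data generators** for every input
  (`gen_rate_table()`, `gen_enzyme_profiles()`, `gen_perturbed_configs()`).

## Worked example

```r
library(nadtherm)

# 1. fit the thermolysis measurements
tab <- read_rate_table(nadtherm_example("table1_thermolysis.tsv"))
fit <- fit_arrhenius(dplyr::filter(tab, compound == "NR"))
fit
#> Arrhenius fit (NR)
#>   A  = 28632.7 [fraction_per_ms]
#>   Ea = 72.5851 kJ/mol
#>   SSE = 4.305e-15 on 3 points
```

The riboside NR is the least stable intermediate: an activation energy of
~72.6 kJ/mol means its hydrolysis rate grows ~2.4-fold per 10 K. (The
prefactor sits on a flat ridge of the least-squares surface and is only
meaningful jointly with Ea — see the vignette.)

```r
# 2. build the network and solve a steady state at 37.5 C
model <- build_default_model()
ss <- solve_steady_state(model, default_enzyme_profile(), 310.65)
glance(ss)
#> # A tibble: 1 × 5
#>   temperature_K C_NAD pyridine_total  residual converged
#>           <dbl> <dbl>          <dbl>     <dbl> <lgl>
#> 1          311. 0.238            0.3  6.61e-20 TRUE
```

With 10 nM of every enzyme, 79% of the conserved pyridine pool sits as
free NAD, and the total is exactly the configured 0.3 mM.

```r
# 3. ask how a 1000 nM enzyme budget should be allocated
run <- run_ep(ep_problem(model, "min_ratio", seed = 7))
glance(run)[, c("best_value", "classification", "C_NAD", "feasible")]
#> # A tibble: 1 × 4
#>   best_value classification C_NAD feasible
#>        <dbl> <chr>          <dbl> <lgl>
#> 1       2.00 nampt_pathway  0.104 TRUE
```

The optimizer drives the ATP-per-NAD ratio to its stoichiometric floor of
2 by silencing PncA entirely (E_PncA at its 1e-10 nM bound) — optima
essentially never keep both routes. The four-step route's best attainable
cost, obtained by conditioning the search on it
(`ep_problem(route = "pnca")`), is ≈4 ATP per NAD at every temperature in
the fitted range: under the default kinetics, intermediate stability never
pays back the extra ATP.

```r
# 4. who controls the NAD level? (PncA-dominated operating point)
E <- default_enzyme_profile(); E["Nampt"] <- 1e-10; E["PncA"] <- 50
cc <- control_coefficients(model, E, 310.65)
dplyr::filter(cc, process == "PncA", species %in% c("NAD", "Nam"))
#> # A tibble: 2 × 6
#>   process process_kind species coefficient richardson_rel_diff flagged
#>   <chr>   <chr>        <chr>         <dbl>               <dbl> <lgl>
#> 1 PncA    enzyme       Nam         -1.09           0.00000187  FALSE
#> 2 PncA    enzyme       NAD          0.0466         0.00000354  FALSE
```

The nicotinamidase exerts positive control over NAD and strong negative
control over its substrate Nam, and (summation theorem) each species'
coefficients over all fourteen rate processes sum to zero.

`run_full_study()` chains all stages — fits, sweeps over all three
objectives, control analysis at representative optima — into one output
directory with a seed manifest.

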