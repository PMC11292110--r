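# iadchrom

Binding-parameter estimation from immobilized-receptor affinity
chromatography by the **injection-amount-dependent method**.

## The problem

Immobilized-receptor (affinity) chromatography measures drug–receptor
binding directly on a column: a receptor — here the G-protein-coupled
cysteinyl leukotriene receptor CysLTR1, with rosmarinic acid and the
reference antagonists zafirlukast, pranlukast and MK-571 as ligands — is
coupled to the stationary phase, and an analyte's retention reflects its
affinity. Classical estimators (frontal analysis, zonal elution) need many
runs or column saturation. The injection-amount-dependent method instead
exploits **column overload**: because the column carries a fixed, small
amount of binding sites `n_a`, the capacity factor

```
k' = (t_R − t0) / t0
```

decreases as the injected molar amount `n_b = c · V_inj` increases. Under a
Langmuir (saturable, homogeneous, fast-equilibrium) binding model the
observations linearize as

```
k' n_b / (1 + k')  =  n_a − (k' V_m) / K_A
```

where `V_m = t0 · F / 1000` is the void volume (L). Plotting
`y = k' n_b / (1 + k')` against `x = k' V_m` and fitting an ordinary
least-squares line gives the association constant `K_A = −1/slope`
(L mol⁻¹) and the total binding-site amount `n_a = intercept` (mol), from a
handful of injections at increasing concentration.

The package implements the full pipeline — reading two-column text
chromatograms, baseline and apex detection (with area and tailing
asymmetry), capacity factors, the linearized fit with diagnostics, ligand
ranking, column QC (retention-time RSD, specificity versus a control
column), immobilization-yield quantification from gel densitometry — plus
a synthetic chromatogram generator with exact ground truth (Langmuir
overload retention, exponentially modified Gaussian tailing peaks,
retention-time and detector noise) for recovery testing.

## Worked example

Simulate a rosmarinic-acid-like study (void marker at 0.298 min,
0.6 mL min⁻¹, 10 µL injections of 0.3–1.1 mM in triplicate, 1% relative
retention-time noise) and recover the binding parameters:

```r
library(iadchrom)

col   <- column_system(t0 = 0.298, flow_rate = 0.6)
truth <- simulation_truth(K_A = 7.268e5, n_a = 1.237e-8, column = col,
                          rel_sd_tR = 0.01, seed = 42)
study <- generate_series(truth, concentrations = seq(0.3, 1.1, 0.1) * 1e-3,
                         injection_volume = 10e-6, replicates = 3,
                         with_traces = TRUE)
analyze_series(study$series)
#> <binding_fit> synthetic n = 9
#>   line: y = -1.361e-06 x + 1.232e-08   (r = -0.9999, r^2 = 0.9997)
#>   K_A = 7.347e+05 L/mol (95% CI 7.238e+05-7.457e+05), n_a = 1.232e-08 mol
```

The fitted `K_A = 7.35e5 L/mol` sits about 1% from the simulated truth
(7.268e5), and `n_a` within 0.4% — the intercept is the column's binding
capacity in moles. Retention falls with load, and each rendered trace
shows the tailing peak shape typical of an overloaded column:

```r
head(study$series$injections, 3)
#>   concentration volume   n_b       t_R  k_prime
#> 1         3e-04  1e-05 3e-09 11.786197 38.55100
#> 2         4e-04  1e-05 4e-09 10.606233 34.59139
#> 3         5e-04  1e-05 5e-09  9.525021 30.96316

detect_apex(study$traces[[1]])
#> <peak_summary> apex 11.79 min, height 114.3, area 29.71, asymmetry 2.77
```

Ranking ligands by published association constants:

```r
rank_ligands(c(zafirlukast = 2.193e5, pranlukast = 4.789e5,
               `MK-571` = 4.272e5, `rosmarinic acid` = 7.268e5))
#>           analyte    K_A
#> 1 rosmarinic acid 726800
#> 2      pranlukast 478900
#> 3          MK-571 427200
#> 4     zafirlukast 219300
```

Measured chromatogram files go through the same path:
`read_injection_table()` + `analyze_injection_table()` read a per-series
metadata CSV (`file, analyte, concentration_mM, injection_volume_uL,
flow_rate_mL_min, wavelength_nm`), detect each peak and return one
`binding_fit` per analyte.

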