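---
title: "Estimating drug–receptor binding parameters by the injection-amount-dependent method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating drug–receptor binding parameters by the injection-amount-dependent method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iadchrom)
```

## The model

On an immobilized-receptor column, an analyte's retention is set by its
equilibrium with a fixed pool of binding sites. Let

* `K_A` — association constant of the ligand–receptor complex (L mol⁻¹),
* `n_a` — total amount of accessible binding sites on the column (mol),
* `V_m` — void volume of the system (L), `V_m = t0 · F / 1000` with the
  void time `t0` (min) measured from a non-retained marker (e.g. sodium
  nitrite) and the flow rate `F` (mL min⁻¹),
* `n_b = c · V_inj` — molar amount injected (mol),
* `k' = (t_R − t0)/t0` — the capacity factor of the analyte.

When `n_b` is comparable to `n_a` the column is overloaded: a larger
injection finds proportionally fewer free sites, so retention falls as the
load rises, and the observations obey the linear relation

$$\frac{k' n_b}{1 + k'} \;=\; n_a - \frac{k' V_m}{K_A}.$$

Plotting $y = k' n_b/(1+k')$ against $x = k' V_m$ and fitting a line by
ordinary least squares yields $K_A = -1/\text{slope}$ and
$n_a = \text{intercept}$. Each concentration in the injection series
contributes one point, so eight to ten injections suffice — no column
saturation (frontal analysis) and no competing-marker runs (zonal elution)
are needed.

The method's assumptions, which the package checks where it can:

* **Fast equilibrium, homogeneous sites, negligible longitudinal
  diffusion.** Not directly testable from retention data; the `r` and `r²`
  of the fit are the practical diagnostic.
* **Saturable binding.** The fitted slope must be negative; a non-negative
  slope raises "no saturable binding detected" and leaves `K_A`/`n_a`
  unset.
* **Overload signature.** `k'` must be non-increasing in `n_b`;
  `analyze_series()` flags violations (`monotone_violation`) but still
  returns the fit, since a single noisy inversion should not void a
  series.

Solved for `k'` at a given load, the same relation is the positive root of

$$V_m k'^2 + (V_m + n_b K_A - n_a K_A)\,k' - n_a K_A = 0,$$

which is how the generator produces ground-truth retention
(`apparent_k()`). Its zero-load limit is the linear-regime capacity factor
`K_A n_a / V_m`, and it is strictly decreasing and continuous in `n_b`.
The root is evaluated with the cancellation-free branch of the quadratic
formula, so transformed synthetic points sit on the model line to within
~1e-24 mol — which is what lets the round-trip tests demand relative
recovery errors below 1e-6.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `t0` | min | — (required) | void time **at the flow rate of the binding runs**; using a void time measured at another flow rate biases every `k'` |
| `flow_rate` | mL min⁻¹ | — (required) | sets `V_m`, hence the x-scale of the fit |
| `injection_volume` | L | — (required) | sets `n_b`; constant within a series |
| `snr_threshold` (`detect_apex`) | × baseline noise SD | 5 | a peak must clear 5 standard deviations of the pooled edge-window noise; on exactly constant baselines any positive apex passes |
| `threshold` (`specificity_report`) | fraction | 0.1 | control-column `k'` above 10% of the receptor-column `k'` marks nonspecific retention; the source study reports only a qualitative "no substantial differences", so the ratio is configurable |
| `sigma`, `tau` (generator) | min | 0.05, 0.15 | Gaussian width and exponential tailing constant of the rendered peak; `tau > 0` gives the asymmetry > 1 typical of overloaded affinity columns |
| `dt` (generator) | min | 0.002 | acquisition grid; apex location, and hence the rendered-trace recovery error, is limited by one grid step |
| `rel_sd_tR`, `detector_sd` (generator) | fraction, signal units | 0, 0 | multiplicative retention-time noise (the RSD-style repeatability statistic suggests relative errors) and additive white detector noise |

## What the generator emulates — and what it does not

`generate_series()` reproduces the statistical structure the analysis
assumes: a void marker; Langmuir-overload retention (strictly decreasing
`t_R` with concentration); exponentially modified Gaussian (EMG) tailing
peaks whose apex sits exactly at `t_R = t0 (1 + k')` and whose area is
proportional to `n_b`; multiplicative Gaussian noise on retention times;
additive detector noise; and optional replicate injections averaged at the
`k'` level before regression, matching the one-point-per-concentration
structure of a binding plot.

It deliberately does **not** simulate band-profile physics
(Wade–Thomas/Haarhoff–Van der Linde transport models), column ageing,
mobile-phase composition effects, co-eluting impurities, or baseline
drift. The EMG is a rendering convenience with the apex as the operative
retention measure, not a transport model. Passing recovery tests therefore
demonstrate that the estimator is correct *given the model's assumptions*;
they cannot certify behaviour on real traces whose tailing arises from
overload kinetics, where apex and centroid retention genuinely differ.
Both measures are exposed (`measure = "apex"` or `"centroid"`) so users
can compare them on their own data.

## Numerical and design choices

* **File dialect.** Plain delimited text, two numeric columns
  (time, signal), comma or tab auto-detected, one optional header line,
  time unit declared in the dialect (minutes by default, seconds
  converted on read). Vendor binary formats are out of scope.
* **Baseline** is the pooled median of the first and last 5% of samples:
  robust, deterministic, adequate for isocratic traces whose peak sits
  inside the middle 80% of the window.
* **Apex tie-break**: earliest time, so detection is deterministic on
  plateaus.
* **Integration bounds** at 1% of apex height; peak area and asymmetry
  (right/left half-width at 10% height) are QC quantities only — the
  binding model uses apex time, never area.
* **`t_R < t0`** is an error for binding analysis but tolerated (negative
  `k'`, with a warning) in QC contexts, where control-column runs may
  legitimately elute at the void.
* **Regression** is unweighted OLS via `stats::lm`; no weighting scheme is
  implied by the method. Both the correlation coefficient `r` and `r²` are
  reported since published "correlation coefficients" are ambiguous
  between the two conventions.
* **Uncertainty** for `K_A` by first-order (delta-method) propagation from
  the slope's standard error, with a 95% t-interval. Diagnostics only;
  they never gate results.
* **Minimum series size** is 3 retained injections (the typical design
  uses 8–10 concentrations).
* **Units of `n_a`.** The intercept of the linearized plot has the
  dimension of moles and is carried in moles throughout. Published tables
  sometimes print the same quantity with an mol L⁻¹ unit string; when
  comparing, match numbers, not unit strings.
* **Immobilization yield** is `(fraction_before − fraction_after) ·
  total_protein / gel_mass` from gel-densitometry band fractions. The
  total supernatant protein is an explicit input: it is a measured
  quantity and cannot be inferred from band fractions alone, so the
  package hard-codes no value for it.

## Problem sizes used by the test suite

Round-trip tests use the study-scale design: 9-level (0.3–1.1 mM) and
10-level (0.1–1.0 mM) concentration grids at 10 µL, on a 0.298 min /
0.6 mL min⁻¹ column frame. The noisy-recovery study runs 200 seeded
replicate series at 1% relative retention-time noise and asserts the
median `K_A` error stays below 5% with an empirically unbiased `n_a`;
rendered-trace tests use the default 0.002 min grid, where recovery is
grid-resolution-limited (≤ 1%).

## Known limitations

* Apex-based retention on strongly tailing real peaks can differ from
  centroid-based retention; the choice is exposed but the default follows
  the conventional reading of chromatograms.
* Published slope/intercept pairs are printed at 3–4 significant figures,
  which limits agreement of re-derived `K_A`/`n_a` to roughly 0.1–0.5%;
  one published zafirlukast value is internally inconsistent with its own
  printed slope by ~13% and cannot be reproduced from the printed line by
  any correct implementation.
* Single-peak traces only: no multi-peak deconvolution, no gradient
  elution, no drift correction.
* The specificity threshold is a pragmatic ratio, not an inferential test;
  with replicated control runs a formal comparison would be preferable.
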