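# forcespec

Analysis of single-molecule force spectroscopy, binding titrations, and
enzymatic activity for mechanosensitive protein domains.

## The problem

The von Willebrand factor (VWF) A2 domain unfolds under the hydrodynamic
forces of flowing blood, exposing the scissile bond that the plasma protease
ADAMTS-13 cleaves. Ligands that bind A2 — complement factor H (CFH) and its
disease-associated W1183R mutant among them — can shift this mechanics:
stabilizing the domain at low force yet making it unfold faster at high
force, with direct consequences for VWF multimer size and thrombotic disease.
Quantifying such effects takes three assays and their models:

* **Optical-tweezer pulling.** Force-extension curves of single domains at
  several pulling speeds. Unfolding events appear as a sudden force drop
  with an extension gain; the worm-like chain (WLC, Marko–Siggia) model
  turns extension jumps into contour length `Lc` and persistence length
  `Lp`, and the Bell–Evans model, `k(F) = k0 · exp(γF/kBT)`, turns the most
  probable rupture force at each loading rate `r` (Evans–Ritchie:
  `F* = (kBT/γ)·ln(γr/(k0·kBT))`) into the unstressed unfolding rate `k0`
  and barrier position `γ`. Two fitted parameter sets predict a stability
  crossover at `F× = kBT·ln(k0ᵃ/k0ᵇ)/(γᵇ−γᵃ)`.
* **Binding titrations** (microscale thermophoresis): 15-step 2-fold serial
  dilutions fitted with the Hill model for EC50/Kd, with a principled
  "no binding" call for flat series.
* **Enzymatic kinetics** (FRET-substrate cleavage): initial rates from
  progress curves, calibrated to relative activity (%) against a standard
  curve, summarised as fold enhancement versus ligand concentration.

`forcespec` implements all three analysis chains plus seeded simulators for
every data type — kinetic Monte-Carlo pulling traces with exact closed-form
rupture sampling, Hill titrations, and progress curves — so each estimator is
validated by parameter recovery against known truth. See the methods
vignette (`vignettes/force-spectroscopy-methods.Rmd`) for the models,
assumptions, and numerical choices.

## Worked example

```r
library(forcespec)

# Bell-Evans kinetics of the A2 domain alone and bound to wild-type CFH
free  <- bell_evans_params(k0 = 0.15,  gamma = 0.71)   # 1/s, nm
bound <- bell_evans_params(k0 = 0.017, gamma = 1.88)

crossover_force(free, bound)
#> [1] 7.656337

stability_profile(c(0, 5, 10, 15), free, bound)
#>   force rate_ratio
#> 1     0  0.1133333
#> 2     5  0.4698000
#> 3    10  1.9474592
#> 4    15  8.0727912
```

The bound state unfolds at a ninth of the free rate at zero force
(ratio 0.11) but four times faster at 15 pN (ratio 8.1); the curves cross at
7.66 pN — ligand binding protects below ~8 pN and sensitizes above it.

Recovering the kinetics from simulated rupture-force histograms, the way the
experiment is actually analysed:

```r
rates <- c(1, 3, 10, 30, 100)                  # pN/s
set.seed(42); ss <- sample.int(2^31 - 1, 5)
pts <- do.call(rbind, lapply(seq_along(rates), function(j) {
  f <- simulate_rupture_forces(free, rates[j], n = 300, seed = ss[j])
  data.frame(loading_rate = rates[j], force = most_probable_force(f, 1)$force)
}))
fit_bell_evans(pts)
#> Bell-Evans fit (nls)
#>   k0    = 0.1807 +/- 0.0589 1/s
#>   gamma = 0.7786 +/- 0.121 nm
#>   kBT = 4.114 pN nm (fixed), n = 5, residual sd = 2.98 pN
```

The generating values (0.15 s⁻¹, 0.71 nm) are recovered within the
histogram-mode uncertainty; `k0`, sitting in the intercept of a log-linear
relation, is always the softer of the two.

A binding titration at the A2 affinity (Kd = 6.1 nM) with 2 % noise:

```r
ts <- simulate_titration(ec50 = 6.1e-9, noise_sd = 0.02, seed = 3)
fit_hill(ts)
#> Hill dose-response fit
#>   EC50 (Kd-equivalent) = 5.72e-09 +/- 2.8e-10 M
#>   Hill n = 1.02 +/- 0.046
#>   amplitude = 0.992, baseline = -0.00603, residual sd = 0.0159, n = 16

fold_affinity_change(6.1e-9, 2.3e-9)   # wild-type vs mutant Kd
#> [1] 2.7
```

Full simulate → detect → histogram → fit campaigns (multiple conditions,
several loading rates, hundreds of traces, crossover report) run through
`run_config()` + `run_pipeline()`; traces and events read and write as TSV,
fits and reports as JSON (`read_trace_table()`, `write_fit_json()`,
`write_report()`).

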