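---
title: "Models and methods: force spectroscopy, binding, and kinetics in forcespec"
author: "forcespec authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: force spectroscopy, binding, and kinetics in forcespec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forcespec)
```

## Scope

`forcespec` analyses single-molecule pulling experiments on mechanosensitive
protein domains — the motivating system is the von Willebrand factor (VWF) A2
domain, whose unfolding under flow exposes a protease cleavage site, and how a
bound plasma ligand (complement factor H and a disease-associated mutant)
shifts that mechanics. Three measurement types are covered, each with a
forward model, a simulator, and a fitting routine:

1. optical-tweezer pulling: worm-like chain (WLC) elasticity,
   Bell–Evans/Evans–Ritchie unfolding kinetics, event detection,
   rupture-force histograms, and the force at which two unfolding-rate
   curves cross;
2. binding titrations (microscale-thermophoresis style serial dilutions):
   Hill dose-response fitting with a no-binding classification;
3. enzymatic progress curves (FRET-substrate cleavage): initial rates,
   standard-curve calibration to relative activity, fold-enhancement
   summaries.

Every stochastic generator is seeded, so each analysis claim can be checked
by parameter recovery on synthetic data with known truth.

## Polymer elasticity: the worm-like chain

The entropic force of a worm-like chain at end-to-end extension $x$ follows
the Marko–Siggia interpolation

$$F(x) = \frac{k_BT}{L_p}\left[\frac{1}{4}\left(1 - \frac{x}{L_c}\right)^{-2}
 - \frac{1}{4} + \frac{x}{L_c}\right],$$

with contour length $L_c$ (nm, maximum extension), persistence length $L_p$
(nm, bending stiffness), and thermal energy $k_BT$. The interpolation form is
chosen because it is closed-form, strictly monotone, invertible, and the
standard model for unfolded-polypeptide elasticity in the few-to-tens of pN
range; extensible-WLC and freely-jointed-chain refinements are deliberately
out of scope. All assays the package emulates are run at 25 °C, so
$k_BT = 4.114$ pN nm (`kBT_25C`) is the package-wide default, exposed as an
argument everywhere.

`wlc_extension()` inverts the force relation by bracketed bisection on
$[0, L_c(1 - 10^{-6})]$ with a relative force tolerance of $10^{-12}$;
monotonicity guarantees convergence, and the round trip
`wlc_extension(wlc_force(x))` is exact to $10^{-9} L_c$.

**Fitting orientation.** `fit_wlc()` performs nonlinear least squares of
*extension on force*, $x = L_c\,\varphi(F; L_p)$, where $\varphi$ is the
fractional extension. In pulling data the dominant measurement noise is in
the extension channel; regressing force on noisy extensions through a convex
force law inflates the fitted contour length by several percent
(errors-in-variables bias), while the extension-on-force orientation keeps
the estimates unbiased. $k_BT$ is always held fixed. Starting values are
$L_c = 1.05\,\max(x)$ and $L_p = 0.4$ nm unless overridden; uncertainties are
asymptotic standard errors from the Jacobian. When the persistence length is
already known — e.g. from a well-spread reference condition — it can be fixed
via the `Lp` argument, leaving a one-parameter fit for $L_c$. This matters
for per-step fits (below) whose events span only a narrow force band, where
$L_c$ and $L_p$ are strongly anti-correlated and a joint fit is poorly
identified.

## Unfolding kinetics: Bell–Evans and Evans–Ritchie

The unfolding rate under force follows the Bell–Evans model

$$k(F) = k_0 \exp(\gamma F / k_BT),$$

with unstressed rate $k_0$ (1/s) and energy-barrier position $\gamma$ (nm),
the distance to the transition state that sets the force sensitivity. Under a
force ramp at loading rate $r$ (pN/s) the rupture-force density is closed
form, and its mode is the Evans–Ritchie most probable force

$$F^\* = \frac{k_BT}{\gamma}\,\ln\frac{\gamma r}{k_0 k_BT},$$

affine in $\ln r$ with slope $k_BT/\gamma$. When the logarithm's argument is
$\le 1$ the analytic mode is negative, which is unphysical; the function
clamps to zero with a warning so that fits at very low loading rates stay
defined.

`fit_bell_evans()` estimates $(k_0, \gamma)$ from (loading rate, most
probable force) pairs by nonlinear least squares of the Evans–Ritchie
relation, started from (and on clean data identical to) the linear regression
of $F^\*$ on $\ln r$ with back-transformation. $k_0$ is fitted on the log
scale: it is exponentially sensitive to the intercept, which is why recovery
tolerances for $k_0$ are always much wider than for $\gamma$.

**Stability crossover.** Two parameter sets (reference vs ligand-bound)
cross where their rate curves are equal:

$$F_\times = \frac{k_BT\,\ln(k_0^a/k_0^b)}{\gamma_b - \gamma_a}.$$

`crossover_force()` evaluates this in closed form and `stability_profile()`
reports the per-force rate ratio, below 1 where the bound state is
stabilized and above 1 where it unfolds faster. For the published parameter
columns (free: $k_0 = 0.15\,\mathrm{s^{-1}}, \gamma = 0.71$ nm; bound to the
wild-type ligand: $k_0 = 0.017\,\mathrm{s^{-1}}, \gamma = 1.88$ nm) the
crossover is 7.66 pN — the "about 8 pN" figure at which ligand binding flips
from protective to sensitizing.

## The pulling simulator

`simulate_trace()` generates constant-loading-rate pulls of a protein with
one or more sequential unfolding transitions (`unfolding_pathway()`), each
releasing a contour-length increment with its own Bell–Evans kinetics.

*Sampling of rupture forces is exact.* Between transitions the force ramps
linearly, so the integrated hazard to force $F$ is closed form; each rupture
force is drawn by mapping an exponential waiting time through the inverse
integrated hazard, conditional on the force at which the clock starts. There
is no time-discretization bias to control, and the trace-level rupture
forces agree in distribution with the direct sampler
`simulate_rupture_forces()` (two-sample Kolmogorov–Smirnov checks in the test
suite).

*Mechanical model.* The recorded extension is the molecular extension of two
WLCs in series at common force: a tether (DNA handle plus folded protein,
default $L_c = 800$ nm, $L_p = 45$ nm — double-stranded-DNA stiffness, nearly
inextensible over the 8–20 pN rupture band) and the unfolded polypeptide
(default $L_p = 0.28$ nm), whose contour length grows by one increment per
rupture. Bead and trap hydrodynamics are not modelled; only rupture forces
and extension jumps feed the downstream fits.

*What happens at a rupture.* The trap-to-bead distance is continuous across
the rupture, so the post-rupture force $F'$ solves

$$x(F', L_c + \Delta L_c) + F'/k \;=\; x(F, L_c) + F/k$$

with series stiffness $k$ (`effective_stiffness`, default 0.3 pN/nm). The
recorded force drops suddenly by $F - F'$ while the recorded extension gains
$(F - F')/k$ — the co-occurring signature that event detection looks for.
Once the resumed ramp re-crosses the rupture force, the extension exceeds
its pre-rupture value by exactly the WLC jump of the released chain at that
force. Gaussian noise (defaults 0.3 pN and 2 nm, a typical optical-trap
noise floor) is added to both channels. A transition whose drawn rupture
force exceeds `max_force` marks the trace truncated rather than failing.

The paper-scale campaign — several hundred traces at each of five pulling
speeds — is reproduced by `simulate_experiment()`, which derives independent
per-trace sub-seeds from one master seed. Default loading rates are 1, 3,
10, 30, 100 pN/s, spanning the two decades such experiments typically cover;
the source experiments report pulling speeds (nm/s) without trap stiffness,
so the simulator accepts either a loading rate directly or speed ×
stiffness.

## Event detection and summaries

`detect_unfolding_events()` flags positions where a force drop of at least
`min_force_drop` (default 1 pN) within a five-sample window co-occurs with an
extension gain of at least `min_extension_gain` (default 5 nm). Detection
statistics compare 3-sample running medians on either side of the candidate,
which suppresses single-sample noise excursions; candidates within 2 samples
are merged (largest drop wins) so one rupture is never double-counted. The
rupture force is the raw pre-drop local maximum.

The reported extension gain is referenced at matched force: the post-rupture
branch is interpolated back to the pre-rupture force, where the gain equals
the WLC jump of the released chain — the quantity the per-step contour-length
fits need. When the ramp does not recover before the next event, the gain
cannot be force-matched and is reported as `NA` (the event still counts for
force histograms).

Two consequences of the default thresholds are worth knowing. First,
ruptures below roughly 8 pN release small jumps whose relaxation drop falls
under 1 pN and go undetected — mirroring the experimental reality that
unfolding events are scored in the 8–20 pN band. Second, with the default
0.3 pN noise the drop threshold sits more than 3 standard deviations above
the noise floor, so false positives are negligible; the test suite verifies
recall and precision of 1.0 for in-band events at noise a quarter of the
drop threshold.

`most_probable_force()` reports the centre of the tallest histogram bin
(default width 1 pN, origin 0) with half the bin width as its uncertainty,
ties broken toward the lower-force bin — deterministic and conservative.
`summarize_extensions()` reports the Gaussian mean and half width at half
maximum ($\mathrm{HWHM} = \sigma\sqrt{2\ln 2}$) of the extension gains; the
Gaussian is fitted by maximum likelihood (sample mean and SD) rather than by
least squares on histogram bars, which estimates the same quantities without
binning artifacts. `estimate_loading_rate()` regresses force on time over
the final 20 % of the pre-rupture ramp, falling back to the protocol's
nominal rate (with a warning) below 5 samples.

## Two-step unfolding and contour-length additivity

At low ligand concentrations a single long unfolding event can split into
two shorter sequential steps. The package represents this as a three-state
pathway whose two contour-length increments sum to the one-step total
(27.0 + 28.3 = 55.3 nm in the bundled analyses). The first step is given a
faster unstressed rate (0.30 s⁻¹ vs the control 0.15 s⁻¹, same $\gamma$), so
one signal appears at a lower force and the other at the control-like
higher force; the source experiments report the phenomenology but no
per-step kinetics, so these values are the package's choice and are stated
wherever used. Two-step analyses are run at 20 pN/s, which centres both
rupture-force distributions inside the detectable 8–20 pN band.

The additivity check fits a contour length to each step's (rupture force,
extension gain) pairs with the unfolded-chain persistence length fixed at
the reference value: over the narrow per-step force band a joint
$(L_c, L_p)$ fit is ill-conditioned and its $L_c$ sum wanders by ±10 %
across seeds, while the one-parameter fits recover the 55.3 nm total to
within ~1 %.

## Binding titrations

`serial_dilution()` builds the 15-step 2-fold schedule (16 concentrations,
the last at $2^{-15}$ of the top). `simulate_titration()` evaluates the Hill
dose-response

$$S(c) = \mathrm{baseline} + \mathrm{amplitude}\cdot
 \frac{c^{n}}{\mathrm{EC}_{50}^{n} + c^{n}}$$

and adds i.i.d. Gaussian noise. The default top concentration is 500 nM
(the ceiling used in the companion enzymatic titrations; the binding assays'
own top concentration is not reported).

`fit_hill()` estimates baseline, amplitude, $\mathrm{EC}_{50}$
(log-parameterised) and the Hill coefficient (bounded to $[0.3, 4]$ — the
assays probe multivalent interactions, so $n$ is left free, but the source
reports no coefficients to compare against). The fitted $\mathrm{EC}_{50}$
is reported as the Kd-equivalent affinity when $n \approx 1$, matching how
such assays are usually summarised. A series is flagged `no_binding` when
the fitted signal change *across the measured concentration range* is below
3 residual SDs; using the observable span rather than the asymptotic
amplitude matters because on flat data the optimiser can push
$\mathrm{EC}_{50}$ far outside the range with an arbitrarily large, entirely
unobservable amplitude. The criterion is the package's own (the source
states the outcome, not a rule); it never triggers on noiseless data with
real amplitude. `fold_affinity_change()` is the ratio of wild-type to mutant
dissociation constants rounded to one decimal, the convention of the
affinity tables it mirrors.

## Enzyme kinetics

Progress curves are simulated as single-exponential substrate depletion,
$\mathrm{RFU}(t) = P(1 - e^{-kt})$, sampled every 2 minutes for 60 minutes;
the early slope is $Pk$. The model is the simplest one consistent with a
FRET-substrate assay and is stated rather than inferred. `initial_rate()`
takes the least-squares slope over the first 10 minutes (6 points) by
default — early enough that curvature biases the slope by only a few
percent at realistic rate constants, and configurable where it does not.
`standard_curve()` fits a straight line through rates measured at known
enzyme concentrations (the reference concentration, default 12.5 nM,
defines 100 %), and `relative_activity()` converts a rate into percent of
that reference, clamping rates below the intercept to 0 % with a warning.
`enhancement_profile()` normalises activities by the ligand-free reference
and reports the maximum fold change and where it occurs.

## Numerical and design choices, collected

* $k_BT$ fixed at 4.114 pN nm (25 °C) everywhere, overridable per call.
* WLC inversion: bisection, relative force tolerance $10^{-12}$; fits are
  extension-on-force (errors-in-variables); uncertainties are asymptotic
  SEs (the sources report none, so there is nothing to match).
* Evans–Ritchie log argument $\le 1$: clamp to 0 pN with a warning.
* Histogram ties: lower-force bin; events within 2 samples merged.
* Simulator sampling interval defaults to 0.1 pN of ramp per sample; the
  rupture draw itself is exact regardless of the interval.
* Degenerate inputs error early: equal barrier positions in
  `crossover_force()`, identical loading rates in `fit_bell_evans()`,
  all-equal extension gains in `summarize_extensions()`, flat standard
  curves.
* Pipeline configs (`run_config()`) validate every field before any
  computation and require an explicit seed; reports carry seed, package
  version, and a config hash.

## What the simulators do and do not establish

The generators reproduce the statistical structure the analysis assumes:
Bell–Evans rupture statistics under a linear ramp, WLC-consistent extension
jumps, serial-dilution Hill curves with homoscedastic noise, exponential
progress curves. Passing recovery tests therefore demonstrates that the
estimators are consistent and correctly composed — not that real traces obey
these models. Real data add baseline drift, bead rotation and tether
heterogeneity, correlated low-frequency noise, refolding and missed events
at high speeds, thermophoretic artifacts in titrations, and inner-filter
effects in fluorescence kinetics; none of these are modelled, and all are
out of scope by design. Problem sizes in the bundled tests and acceptance
analyses (50-point WLC fits, 300 rupture forces per rate across 5 rates,
200 two-step traces, 16-point titrations) match the scale of the source
experiments where that scale is stated.
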