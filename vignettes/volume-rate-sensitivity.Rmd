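---
title: "Creatinine kinetics and the volume-rate sensitivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Creatinine kinetics and the volume-rate sensitivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crkinetics)
```

## The model and its assumptions

The package works with a one-compartment mass balance for creatinine in
which the volume of distribution (total body water) changes at a
constant rate:

$$\frac{d}{dt}\bigl[\mathrm{Cr}(t)\,V(t)\bigr] = \mathrm{Gen} -
\mathrm{GFR_K}\,\mathrm{Cr}(t), \qquad V(t) = V_0 + \frac{\Delta V}{\Delta t}\,t.$$

Its closed form is

$$\mathrm{Cr}(t) = \mathrm{Cr}_0 + \underbrace{\Bigl[1 -
\Bigl(\tfrac{V_0}{V(t)}\Bigr)^{1 + \mathrm{GFR_K}/(\Delta V/\Delta t)}\Bigr]}_{E,\ \text{evolution}}
\cdot \underbrace{\Bigl(\tfrac{\mathrm{Gen}}{\mathrm{GFR_K} + \Delta V/\Delta t} -
\mathrm{Cr}_0\Bigr)}_{D,\ \text{spread}}.$$

The assumptions are the standard kinetic-GFR ones: creatinine
generation constant over the horizon (muscle mass is stable on a
24-hour scale), clearance constant (a step change at $t = 0$ rather
than a drift; "clearance" includes extracorporeal routes such as
CRRT), a single well-mixed compartment, and a strictly linear volume
trajectory with $V(t) > 0$ throughout. None of the operations model
measurement noise, time-varying parameters or non-creatinine solutes.

### Units

Scenario fields use the clinical conventions: $V_0$ in litres, time in
hours, $\Delta V/\Delta t$ in L/h, $\mathrm{GFR_K}$ in mL/min and
$\mathrm{Gen}$ in mg/dL·mL/min (so that $\mathrm{Gen}/\text{clearance}$
is a concentration). Internally every flow is converted to L/h — and
$\mathrm{Gen}$ to mg/dL·(L/h) — with the exact rational factor
$3/50$ (its inverse $50/3$ takes L/h to mL/min), which makes the
exponent $\mathrm{GFR_K}/(\Delta V/\Delta t)$ dimensionless and the
spread term a concentration without any per-term fixups, and makes all
derivatives come out directly per L/h. `convert_flow()` exposes the
conversion; a round trip is an identity because $\frac{50}{3}\cdot\frac{3}{50}=1$
exactly.

## Sensitivity derivatives

Writing $y = (V_0/V(t))^{1+g/\delta}$ (flows $g, \delta$ in L/h),
$E = 1-y$ and $D$ as above, the derivatives with respect to
$\delta = \Delta V/\Delta t$ factor through

$$E' = yA, \qquad E'' = y\,(A' - A^2),$$
$$A = \frac{g}{\delta^2}\ln\frac{V_0}{V(t)} + \Bigl(1+\frac{g}{\delta}\Bigr)\frac{t}{V(t)}, \qquad
A' = -\frac{2g}{\delta^3}\ln\frac{V_0}{V(t)} - \frac{2g}{\delta^2}\frac{t}{V(t)} -
\Bigl(1+\frac{g}{\delta}\Bigr)\Bigl(\frac{t}{V(t)}\Bigr)^2,$$

so that the first derivative is $E'D + ED'$ and the second
$E''D + 2E'D' + ED''$ with $D' = -\mathrm{gen}/(g+\delta)^2$,
$D'' = 2\,\mathrm{gen}/(g+\delta)^3$. Both are verified against central
finite differences of the trajectory across hundreds of random
scenarios in the test suite, and the trajectory itself against a
finite-difference residual of the governing mass balance (below
$10^{-4}$ in harmonized units everywhere sampled).

`dcr_dgfrk_numeric()` provides the companion derivative with respect to
clearance by central difference only; it is used to check numerically
the classical invariant that creatinine always moves opposite to
clearance, not as an analytic result of this package.

## Numerical choices

* **Log-space powers.** $y$ is always computed as
  $\exp\{(1+g/\delta)\,L\}$ with $L = -\mathrm{log1p}(\delta t/V_0)$.
  `log1p` keeps $L$ fully accurate when $V(t)/V_0$ is within rounding
  of 1, which is what makes the general formula agree with the
  $\delta\to 0$ limit to $10^{-6}$ relative even at $\delta = 10^{-9}$
  L/h. The domain guard $V_0 + \delta t > 0$ is enforced before any
  logarithm; violations raise classed errors rather than producing
  `NaN`.
* **Limit branches of the trajectory** (threshold $10^{-8}$ L/h):
  $\delta \to 0$ uses the classic fixed-volume kinetics
  $\mathrm{Cr}_0 e^{-gt/V_0} + (\mathrm{gen}/g)(1-e^{-gt/V_0})$;
  $g+\delta \to 0$ resolves the $0\cdot\infty$ product analytically to
  $\mathrm{Cr}_0 + (\mathrm{gen}/g)\ln(V_0/V(t))$; $g = \delta = 0$ is
  pure accumulation $\mathrm{Cr}_0 + \mathrm{gen}\,t/V_0$.
* **Derivative guard** (radius $10^{-6}$ L/h around $\delta = 0$ and
  $\delta = -g$): the analytic forms contain $1/\delta^2$ and
  $1/(g+\delta)^3$ terms that cancel analytically but catastrophically
  in floating point, while the trajectory itself is smooth across both
  lines; inside the guard the derivatives are therefore taken as
  central differences of the trajectory with step $10^{-3}$ L/h
  (roundoff $\sim 10^{-10}$, truncation far below the quantities'
  scale). Outside the guard the analytic forms are accurate to better
  than $10^{-8}$ relative.
* **Root finding.** All roots go through `find_root()`: a sign-change
  bracket (hunted on a grid when the supplied interval does not
  straddle), then Brent refinement with tolerance $10^{-10}$ on the
  root and an iteration cap of 200. Every returned root re-evaluates
  its defining function below $10^{-8}$ in the tests. Scans over the
  volume-rate axis use a grid geometric near the exhaustion wall
  $-V_0/t$ (where everything diverges) and linear out to $+50$ L/h.
* **Extremum location.** `locate_extrema()` detects interior local
  extrema on the first-derivative grid and then refines each as the
  bracketed zero of the second derivative. Detecting on the first
  derivative rather than on second-derivative sign changes is robust
  when the maximum/minimum pair nearly merges and both zeros fall
  between adjacent grid nodes. Absence of an extremum is a result
  (`NA`), not an error.
* **Tangency condition.** Eliminating $D$ between the simultaneous
  equations (first derivative $=0$, second derivative $=0$) gives
  $$\frac{2A(1-y)}{g+\delta} + A'(1-y) - A^2(1+y) = 0,$$
  which contains neither $\mathrm{Gen}$ nor $\mathrm{Cr}_0$. The root
  $\delta^\*$ is searched in $(-V_0/t,\ 0)$ by default — the regime of
  clinical interest is fluid removal, and the search window can be
  widened via the `upper` argument; for clearances far above
  $2V_0/t$ (about $>126$ mL/min at $V_0=42$ L, $t=24$ h) the root
  migrates to positive volume rates and the default search reports
  no-tangency, in which case the classifier falls back to locating the
  curve's maximum directly. Back-substitution into the
  first-derivative zero yields the benchmark $\mathrm{Cr}_0$ for a
  known $\mathrm{Gen}$ (and symmetrically the benchmark
  $\mathrm{Gen}$); their ratio is a fixed attribute of
  $(\mathrm{GFR_K}, V_0, t)$, which the tests verify as a round trip.
* **Tie-breaks.** If several candidate maxima (minima) are ever found,
  the largest (smallest) value wins; in practice the curve has at most
  one of each.

## The classifier

`classify_scenario()` compares $\mathrm{GFR_K}$ with
$t_{\text{low}} = \mathrm{Gen}/\mathrm{Cr}_0 + V_0/t$ and
$t_{\text{high}} = 2V_0/t$ (both in mL/min):

* **bottom** ($\mathrm{GFR_K} < t_{\text{low}}$): the derivative is
  always negative; no paradox.
* **middle**: the derivative can only become positive through its left
  tail diverging to $+\infty$ as $\delta \to -V_0/t$; the verdict is
  `can_be_positive = TRUE` with an `unrealistic` flag, since such
  rates would drain the body water within the horizon.
* **top** ($\mathrm{GFR_K} > t_{\text{high}}$): the tangency machinery
  runs, and the verdict is the benchmark comparison
  ($\mathrm{Cr}_0$ above benchmark $\Leftrightarrow$ $\mathrm{Gen}$
  below benchmark $\Leftrightarrow$ maximum above zero), along with
  the positivity interval and the derivative's sign at the patient's
  actual volume rate.

Two edge policies are deliberate. A clearance exactly equal to a
threshold goes to the *higher* domain and is flagged `on_boundary`
(the theory uses strict inequalities and never addresses equality).
And when the thresholds are in non-permissive order
($t_{\text{low}} \ge t_{\text{high}}$, e.g. severe AKI with a high
$\mathrm{Gen}/\mathrm{Cr}_0$ ratio), a clearance below both thresholds
is still classified bottom — the always-negative conclusion holds
below $t_{\text{low}}$ regardless of the order — while anything higher
raises an unsupported-regime error rather than guessing: the exception
taxonomy for that corner is not implemented here.

## Fixtures and what the tests do and do not show

`reference_scenarios()` encodes the study conditions: a severe-AKI
case (clearance 20 mL/min, $\mathrm{Gen}=100$, $\mathrm{Cr}_0=1$ —
always negative), sweeps of $\mathrm{Gen}$ (10–100), $\mathrm{Cr}_0$
(2–10) and $\mathrm{GFR_K}$ (down through both thresholds) around the
$V_0 = 42$ L / 24 h frame, and the septic-CRRT worked case
($\mathrm{Gen}=40$, $\mathrm{Cr}_0=8$, $\mathrm{GFR_K}=80$) under
ultrafiltration rates of 0.1 and 0.3 L/h. Property tests draw random
scenarios from a clinically plausible envelope ($V_0$ 20–60 L, $t$
6–48 h, $\mathrm{GFR_K}$ 5–150 mL/min, $\mathrm{Gen}$ 10–150,
$\mathrm{Cr}_0$ 0.5–12, $\delta$ from 80% of the exhaustion wall to
+1.5 L/h). Everything is desk-scale: grids of a few hundred points,
suites in seconds.

These are *model-level* checks. Passing them shows the closed form,
its derivatives and the regime logic are mutually consistent and
reproduce the reference numbers; it says nothing about how well a real
patient obeys the assumptions (constant generation and clearance,
single compartment, linear volume). In particular the effect sizes in
the paradox regime are small (thousandths of mg/dL per 0.1 L/h of
ultrafiltration), far below assay noise, so the phenomenon is
conceptual rather than a clinical decision tool.

## Known limitations

* The "stereotypical shape" (rise to a maximum, fall to a minimum,
  rise to the asymptote) is not universal even in the top domain: far
  from tangency on the negative side (e.g. $\mathrm{Gen}=90$,
  $\mathrm{Cr}_0=6$, $\mathrm{GFR_K}=100$) the maximum/minimum pair
  annihilates and the curve is monotone. `locate_extrema()` reports
  absence, and the classifier's benchmark logic is unaffected (the
  verdict there is "always negative", which matches the grid signs).
* Middle-domain exceptions to the diverging left tail are not
  implemented; the flag-and-caveat verdict is as far as the package
  goes.
* Roots are only sought in the scanned ranges ($(-V_0/t, 50]$ L/h for
  extrema, $(-V_0/t, 0)$ by default for tangency); there is no global
  guarantee beyond them, and no complex-valued continuation past the
  exhaustion wall.

```{r example}
s <- kinetic_scenario(v0 = 42, dvdt = -0.1, t = 24,
                      gfrk = 80, gen = 40, cr0 = 8)
classify_scenario(s)
```
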