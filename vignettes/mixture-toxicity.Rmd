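---
title: "Ray-design mixture toxicity: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ray-design mixture toxicity: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raymix)
```

raymix analyses binary chemical mixtures assayed by fixed-ratio ("ray")
growth-inhibition experiments, the standard design in algal ecotoxicology:
each ray holds the mass-concentration ratio of the two components constant
while the total concentration is varied over a geometric ladder. This
vignette explains the models the package implements, the parameters that
matter, what the simulator does and does not emulate, and the design
decisions taken where the methodology is genuinely open.

## The experimental design

A concentration ladder is defined by its range-finding endpoints: the
maximum-effect concentration $C_H$ (inhibition $\ge$ 98%) and the
minimum-effect concentration $C_L$ (inhibition $\le$ 1%). With $n$ gradient
points the dilution factor is

$$F = \left(\frac{C_L}{C_H}\right)^{1/(n-1)}, \qquad
  C_k = C_H \, F^{\,k-1},$$

so concentrations are uniformly spaced on the log axis. `dilution_factor()`
and `concentration_series()` implement this with the endpoints pinned
exactly; the default study shape is 12 points $\times$ 3 replicates.

Mixture ratios follow the direct equipartition ray design (EquRay): ray $k$
of $m$ combines $k$ toxic units of component A with $m+1-k$ toxic units of
B, a toxic unit being the component's own EC50 in mass concentration. The
A mass fraction is therefore

$$p_A(k) = \frac{k\,\mathrm{EC50}_A}{k\,\mathrm{EC50}_A + (m+1-k)\,\mathrm{EC50}_B}.$$

`equray_rays()` returns rays ordered by increasing $p_A$ (R1 has the
smallest A share). Published tables of this design sometimes list the ray
ratios in the opposite prose order; the fractions themselves are
unambiguous, and raymix follows them. Fractions are interpreted as
mass-concentration fractions, which reproduces published EquRay fraction
tables exactly; they are invariant to any common rescaling of the two
EC50s, so the µg/L-versus-g/L ambiguity cannot leak into the design.
`fixed_ratio_ray()` adds rays at stated environmental ratios such as 1:10.

## From optical density to effect

Growth inhibition is computed from OD680 (chlorophyll-a absorbance, the
biomass proxy) against the pooled blank-control mean $I_0$ within the same
plate:

$$E = \frac{I_0 - I_i}{I_0}.$$

Effects are deliberately **not** truncated to $[0,1]$: replicate noise can
produce small negative effects (apparent stimulation), and truncating them
before fitting would bias the curve upward at low concentrations. Negative
effects are reported with a warning instead.

## Concentration-response models

Two 2-parameter sigmoids are fitted on $x = \log_{10}(c)$:

$$\text{Logit:}\quad E = \frac{1}{1+\exp(-\alpha-\beta x)}, \qquad
  \text{Weibull:}\quad E = 1-\exp(-\exp(\alpha+\beta x)).$$

Two parameters (not four) because the chemometric rule of at least five
observations per parameter caps the model size at twelve gradient points.

**Sign and scale conventions.** Published parameter tables in this assay
family are not always on one convention: single-compound tables often
satisfy $\mathrm{EC50} = 10^{+\alpha/\beta}$ with $c$ in µg/L (a mirrored
location), while mixture tables satisfy the canonical
$\mathrm{EC50} = 10^{-\alpha/\beta}$ with $c$ in g/L. A `crc` object
therefore stores the canonical model plus an explicit `conc_scale`
(`"ugL"`/`"gL"`) and an `alpha_sign` flag, so either published convention
can be reconstructed bit-for-bit and every `ecx()` result is returned in
µg/L regardless. The run log records the convention used for every fit so
the two styles are never silently mixed.

**Fitting.** `fit_crc()` minimises the residual sum of squares over the
per-concentration mean effects by Levenberg–Marquardt least squares
(objective tolerance $10^{-10}$), started from a linearised transform
(logit or complementary log-log of clipped effects regressed on $x$) plus a
coarse grid of slope/location pairs; the best converged start wins. The
slope is bounded positive: these assays measure inhibition that increases
with concentration. Goodness of fit uses the adjusted coefficient

$$R^2_{adj} = 1-\frac{(n-1)\sum_i (y_i-\hat y_i)^2}{(n-m)\sum_i (y_i-\bar y)^2},
\qquad \mathrm{RMSE} = \sqrt{\tfrac{1}{n}\sum_i (y_i-\hat y_i)^2},$$

exactly as conventionally printed in this literature (the plain $R^2$ is
also reported). `select_best()` keeps the larger $R^2_{adj}$, breaking ties
(difference $< 10^{-6}$) by smaller RMSE, then by model order with Logit
first — a deterministic rule so reports are reproducible.

**Intervals.** Function-based confidence bands (FCIs) use the delta method
on $(\alpha,\beta)$ with a $t$ quantile on $n-m$ degrees of freedom.
Observation-based intervals (OCIs) are per-concentration $t$-intervals on
the replicate mean — the simplest observation-based construction consistent
with the name; the formula is documented here precisely so it can be
swapped if a different construction is preferred.

**NOEC/LOEC.** The literature rarely states how these were derived. The
default is a one-sided Dunnett many-to-one comparison of replicate effects
against the blank control at the 0.05 level; a threshold rule (lowest
concentration with mean effect above 1%, matching the minimum-effect
design rule) is available as `method = "threshold"`. Out-of-range outcomes
use numeric sentinels: NOEC $-\infty$ when even the lowest concentration
shows an effect, LOEC $+\infty$ when none does.

## Mixture reference models and classification

Concentration Addition (Loewe additivity) treats the components as
dilutions of one another:

$$\mathrm{EC}_{x,\mathrm{mix}} = \left(\sum_i \frac{p_i}{\mathrm{EC}_{x,i}}\right)^{-1},$$

and Independent Action (Bliss independence) treats them as acting on
independent targets:

$$E(c_{tot}) = 1-\prod_i\bigl(1-f_i(p_i\,c_{tot})\bigr),$$

with $f_i$ the component's best-fit CRC. `ca_ecx()` and `ia_effect()`
implement these; `ca_effect()` inverts the CA curve onto the effect axis by
bisection (tolerance $10^{-10}$), since classification happens on that
axis.

Classification is pointwise at the tested concentrations — where OCIs
exist — rather than on a continuous grid: a reference prediction inside the
OCI is *additive*; below the OCI (the organisms were hurt more than
predicted) *synergistic*; above it *antagonistic*. The verbal rule in parts
of the literature ("falls below the prediction line") is ambiguous about
the axis; raymix uses the toxicological effect-axis orientation, which is
equivalent to the observed ECx lying below the predicted ECx, and exposes
`orientation = "flipped"` for the opposite reading.

The ray-level label is the majority point label among points with fitted
effect in the mid-effect window $[0.2, 0.8]$ — the region where the models
genuinely discriminate — with ties resolved conservatively to additive.
Points are also summarised over low / medium / high concentration regions
(default edges $10^3$ and $2\times10^4$ µg/L, configurable).

## The synthetic-data generator

Raw plate readings for published studies of this kind are typically not
deposited, so `simulation_scenario()` + `simulate_single()` /
`simulate_ray()` generate plates with the statistical structure the
analysis assumes: control OD $\sim N(\mu_0, \sigma)$ truncated at zero, and
treatment OD $= \mu_0(1-E_{true}(c)) + b + N(0,\sigma)$, where $b$ is an
optional treatment-only background absorbance (so both blank-subtraction
conventions can be exercised). Noise lives on the OD scale by default
because that is what the instrument measures; an effect-scale option exists
for quick tests. All draws are Mersenne-Twister with inversion normals
under the scenario seed, and simulation never perturbs the caller's RNG
stream.

Mixture truths are `CA_truth` (inverting the CA formula), `IA_truth`, or
`dose_modifier`: the base model evaluated at $\kappa\,c_{tot}$, with
$\kappa>1$ building in synergy and $\kappa<1$ antagonism. The dose-modifier
is a test-harness device for producing curves that genuinely depart from
both references — a crude stand-in for mechanisms like one metal blocking
the efflux of the other — not a biological model.

**Default study conditions.** `scenario_as_pb()` emulates a 96 h
As(V)/Pb(II) *Chlamydomonas* assay: Logit truths centred on the published
single-compound EC50s (374.87 and 19,988.75 µg/L), 12 points $\times$ 3
replicates, OD noise $\sigma = 0.02$ on a control OD of 0.5 (chosen so the
RMSE of fits is of order 0.02, the magnitude such studies print). The
published fitted slopes themselves (about 2.5 and 2.0) do *not* satisfy the
stated range-finding rule on the reconstructed As ladder of 10–10,000 µg/L
(they give 2% inhibition at the bottom and 97% at the top), so the
simulation truths use slightly steeper slopes — 3.2 for the As-like and 2.6
for the Pb-like component — for which the 1%/98% endpoint rule holds. The
Pb ladder endpoints are never printed in such tables; the defaults
(300–1.3 $\times 10^6$ µg/L) are reconstructed from the same rule. Ray
ladders default to applying the range-finding rule to the ray's own truth
curve, exactly as a bench scientist would.

**What the simulator does not emulate:** time-resolved growth, hormesis
(non-monotone low-dose stimulation), chemical speciation or bioavailability
shifts in the medium, inter-plate batch effects, and replicate correlation
beyond the shared control. Passing tests on simulated plates therefore
demonstrate that the pipeline recovers what it assumes — not that any
particular real mixture is additive.

## Numerical choices and known limitations

* Geometric-series endpoints are pinned to $C_H$ and $C_L$ exactly;
  compounding error is below $10^{-9}$ relative by construction.
* CA/effect-axis inversion uses bisection to $10^{-10}$; `ecx()` inverts in
  closed form, and the round trip holds to $10^{-9}$ across both model
  families.
* Degenerate inputs fail fast with typed messages: constant effects, absent
  controls, negative OD, duplicate replicate keys, fractions outside
  $(0,1)$.
* Effects are fitted as per-concentration means (the convention in this
  assay literature), so replicate information enters the fit only through
  the mean; OCIs carry the replicate spread.
* Because every effect shares the *estimated* control mean $\hat I_0$,
  plate-level effects carry a correlated level error the sigmoid cannot
  absorb, concentrated at the ladder ends. Wald intervals and delta-method
  bands are conditional on $\hat I_0$ and measurably undercover the truth
  defined against the true control (about 86–90% instead of 95% at
  $\sigma = 0.02$); on model-consistent data (independent effect noise)
  their coverage is nominal. More control replicates shrink this gap.
* The mid-effect window rule leaves rays whose tested points all sit at
  extreme effects labelled from all points, with a warning.

## Problem sizes used in the test suite

Simulation-backed checks run at the study shape (12 points $\times$ 3
replicates): 100 seeded runs for the CA-truth classification rate, 200 for
Wald coverage, 150 for band coverage, and 40 per noise level for the
noise-monotonicity check — sizes at which the Monte-Carlo error is well
inside the asserted margins while the whole suite stays fast on a single
CPU.
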