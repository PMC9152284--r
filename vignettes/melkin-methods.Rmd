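---
title: "Two-phase kinetics of fed-batch MEL fermentation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase kinetics of fed-batch MEL fermentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melkin)
```

## The process and its model

Mannosylerythritol lipids (MELs) are glycolipid biosurfactants secreted by
Ustilaginaceae fungi such as *Moesziomyces aphidis*. The bioreactor process
`melkin` models is deliberately two-staged: cells are first grown on glucose
with sodium nitrate as nitrogen source, and MEL production is then induced
by adding plant oil after nitrogen depletion. The package mirrors this
separation with two partial ODE models chained by a hand-over state.

### Growth phase

The specific growth rate follows dual-substrate Monod kinetics with a
minimum operator — growth is controlled by whichever of glucose or nitrate
is more limiting, and the two limitations do not multiply:

$$\mu = \mu_{max}\min\!\left\{\frac{c_{gluc}}{K_{gluc}+c_{gluc}},
\frac{c_{NaNO_3}}{K_{NaNO_3}+c_{NaNO_3}}\right\}$$

Biomass, the two substrates and the liquid volume evolve with the usual
fed-batch feed/dilution terms. Substrate-inhibition of growth is not
modelled; the shipped medium (30 g/L glucose, 3 g/L NaNO$_3$) is assumed to
stay below inhibitory levels. A useful property of this medium is that both
substrate ceilings for biomass coincide (30 × 0.17 ≈ 3 × 1.7 ≈ 5.1 g/L), so
glucose and nitrate run out together in a batch.

During the fed-batch part, medium is fed with the open-loop exponential law

$$F_{in}(t) = \frac{(V_L c_x)_0\,\mu_{set}}
{Y_{X/gluc}\,(c_{gluc,Feed}-c_{gluc})}\,e^{\mu_{set}(t-t_{start})}$$

Two conventions matter here. First, the elapsed time is counted from feed
start, and $(V_L c_x)_0$ is the volume–biomass product the pump program was
given — a *setpoint*, not the simulated state. Second, the broth glucose
concentration in the denominator is held at a constant reference (default
0 g/L, i.e. fully glucose-limited feeding): the published feeding is
open-loop, and coupling the law to the simulated glucose would introduce a
state feedback the physical pump never had.

### Production phase

At the configured hand-over time the growth state is frozen: the biomass
concentration at that moment, $c_{x,growth}$, becomes the catalytic biomass
of the production phase. Three Michaelis–Menten reaction terms act on the
lipid phase:

* **hydrolysis** of triglyceride oil to free fatty acids (FA), with
  competitive-type product inhibition by FA
  ($K_{i,hyd}$) — extracellular lipases keep working at frozen capacity;
* **MEL formation** from FA, a single black-box conversion
  (the multi-step biosynthetic pathway is not resolved);
* **lipid inclusion**: FA are stored intracellularly, converting lipid-free
  biomass $c_{x,free}$ into inclusion biomass $c_{x,incl}$ and raising the
  measured dry mass without cell division.

The hydrolysis and MEL fluxes scale with $c_{x,growth}$. The inclusion flux
is $q_{incl}\,c_{x,free}$ — it scales with the *remaining lipid-free*
biomass, because only cells that still have storage capacity take up FA; its
FA drain is $Y_{FA/X,incl}$ (1.128 g/g) times that same flux, so the
inclusion bookkeeping closes exactly: per gram of inclusion biomass formed,
1.128 g FA disappear from the broth and 0.203 g of lipid-free biomass are
re-labelled as inclusion biomass. We adopted this scaling (rather than
scaling the FA drain by $c_{x,growth}$ like the other two fluxes) for two
reasons: it is the only choice under which the FA/biomass bookkeeping is
dimensionally consistent term by term, and scaling the drain by the constant
$c_{x,growth}$ makes the inclusion sink permanent, which suppresses the FA
accumulation that repeated oil feeding demonstrably causes. The two readings
coincide at production start, where $c_{x,free} = c_{x,growth}$. This also
fixes the units of $q_{incl}$ as g inclusion biomass per g biomass per hour.
A configuration switch (`use_total_biomass`) lets the hydrolysis and MEL
fluxes scale with the current total biomass instead, for sensitivity
analysis.

The sign of the lipid-free biomass reaction term is negative — inclusion
*depletes* the lipid-free pool. The two stoichiometric constants of the
inclusion step ($Y_{X,free/incl} = 0.203$, $Y_{FA/X,incl} = 1.128$) are
shipped as given constants derived from the measured elemental compositions
of growth- versus production-phase cells; the package does not attempt to
re-derive them, since the underlying reaction scheme (which lipid species,
how water and CO$_2$ close the balance) is not fully determined by the CHN
data.

### Parameters

`mel_params()` carries the full default calibration. Units: rates in 1/h or
g/(g·h), affinities and inhibition constants in g/L, yields in g/g.

```{r}
print(mel_params())
```

The maximum specific consumption rates are derived, not stored
($q_{max,S} = \mu_{max}/Y_{X/S}$), which keeps the parameter set minimal and
internally consistent.

## Numerical scheme

Both phases are integrated with an **explicit Euler** scheme at fixed steps
of 0.05 h (growth) and 0.2 h (production) — deliberately simple and exactly
reproducible. The test suite checks the scheme against an adaptive
high-order reference integration (lsoda) at a tenfold-refined step on every
shipped scenario, and checks first-order Richardson behaviour of the
endpoint error. Numerical conventions:

* **Non-negativity clamp.** After each step, negative concentrations are
  clamped to zero; a warning is emitted if the pre-clamp value is below
  $-10^{-6}$ g/L. With the shipped parameters the Monod factors throttle
  consumption fast enough that the clamp is a safety net, not a crutch.
* **Feed windows** use left-endpoint semantics ($t_{start} \le t <
  t_{end}$), so the Euler sum of the fed volume and the volume state agree
  exactly — the volume bookkeeping `V_final = V0 + medium + oil` is an
  identity, tested to machine precision.
* **Bolus oil additions** are applied at the nearest Euler grid time at or
  before the event time, as instantaneous perfect mixing: concentrations
  scale by $V_{old}/V_{new}$ and oil gains (added mass)/$V_{new}$. This
  makes event semantics deterministic and grid-independent.
* **Continuous oil feeds** enter through the feed term with an oil feed
  concentration of $1000\,\rho_{oil}$ g/L.

## Scenario reconstructions

The scenario library (`mel_scenarios()`) reconstructs the six reported
bioreactor runs: two two-stage batch processes (B1 single 6% v/v oil feed;
B2 repeated 6 + 4×4% v/v), and four fed-batch processes (FB1–FB4) with
exponential medium feeding at $\mu_{set}$ = 0.08–0.09 1/h and either bolus
or continuous oil feeding. Conventions the source data leave open, decided
once:

* **Oil density 0.92 g/mL** (rapeseed oil literature value) for
  % v/v → mass conversion; a config field, not a constant.
* **% v/v reference volume**: the stated 4 L for the batch processes; for
  fed-batch processes, where no reference is stated, the broth volume at
  the start of the production phase.
* **Initial biomass 0.21 g/L**, from inoculation to OD$_{625}$ 0.6 and the
  linear calibration 0.35 g/L per OD unit.
* **Feed solution**: 300 g/L glucose + 30 g/L NaNO$_3$ at unit density.
* **Fed-batch pump programs**: the reported totals of feed solution
  (460–708 g) are authoritative; where the pump-program biomass behind the
  feeding law is not reported (FB2–FB4) — or disagrees with the reported
  total (FB1, whose printed settings integrate to ~400 g rather than the
  460 g actually delivered) — the program biomass $c_{x,0}$ is
  back-calculated so the feed-law integral reproduces the printed total
  mass. This matches how the simulations being reproduced were driven (by
  the experimental feeding rates) and treats all four fed-batch scenarios
  identically.
* **Sampling losses and titrant volumes are ignored** in the volume
  balance; the model has no such terms.
* The growth→production transition happens at the configured time even if
  substrates remain, mirroring the operator-timed protocol.

## Process analytics

The evaluation equations operate on windows of observation tables. Rates
and yields default to **linear regression** over the window (matching how
the published values were derived); a two-point difference-quotient mode is
kept for worked examples. Where a single representative biomass is needed
(specific rates $q = r/c_x$), the **logarithmic mean** of the window-end
biomasses is used: for exponential growth it equals the true time-average
biomass, and it makes the identity $q_S \cdot Y_{X/S} = \mu$ hold exactly in
two-point mode.

Off-gas analysis computes OUR and CER from dry-gas mole fractions through
the inert-gas balance (nitrogen flow in = out). With airflow in L/h,
pressure in Pa, broth volume in L and temperature in K, the natural output
scale is mmol/(L·h) — the scale on which the reported uptake rates
(~25–75 mmol/(L·h)) live. The algebraic inverse (`invert_off_gas()`)
reconstructs outlet fractions from known OUR/CER; analytics on fractions
generated this way recover the rates to $10^{-6}$ relative — a round-trip
property the acceptance tests enforce.

Windows are always user-supplied. The published analysis chose windows
manually; automatic changepoint detection would add a silent analysis
decision the package should not make.

## Synthetic data generator

`generate_observations()` emulates the measurement regime of the
bioreactor: sparse offline samples (default every 8 h: OD, dry biomass,
glucose, nitrate, oil, FA, MEL) and a continuous off-gas stream (default
every 0.2 h). Design choices:

* **Multiplicative lognormal noise** (default 5% sdlog) respects the
  positivity of concentration data; species that are exactly zero get a
  half-normal draw at a per-species absolute floor. Noise at zero standard
  deviation reproduces the trajectory exactly — the consistency property
  the estimator tests rely on.
* **Off-gas synthesis**: during growth the specific oxygen uptake follows
  the growth rate, $q_{O_2} = \mu/Y_{X/O_2}$, with $Y_{X/O_2}$ fixed
  implicitly so $q_{O_2}$ is 4.3 mmol/(g·h) at $\mu_{max}$ (the reported
  fed-batch value); the respiratory quotient is 1.4. During production a
  constant $q_{O_2}$ of 1.5 mmol/(g·h) acts on $c_{x,growth}$ with RQ 0.52,
  reflecting the oxidative lipid metabolism. These are generator
  conventions chosen to match the reported respiration regime, not model
  claims; outlet fractions are then the exact algebraic inverse of the
  off-gas balance plus mole-fraction noise (default 2×10⁻⁴ absolute).

What the generator does **not** emulate: foam events and MEL bead
formation, deposition of product at vessel internals (the reported cause of
late-process MEL decreases), lipase deactivation over very long runs,
mannitol as a side product, and the biphasic measurement artifacts right
after oil addition. Passing estimator tests on synthetic data therefore
demonstrate correctness of the estimators under the model's assumptions,
not robustness to these real-data effects.

## Parameter estimation

Two layers, mirroring how the constants were originally obtained:

* `fit_yields()` — direct regression: yields as biomass-vs-substrate
  slopes, $\mu_{max}$ as the log-biomass slope over an exponential window,
  and specific consumption rates from a through-origin regression of
  interval consumption rates on the interval's logarithmic-mean biomass.
* `fit_model()` — simulation-based weighted least squares for the
  constants that cannot be read off the data (affinities, inhibition and
  capacity constants). Residuals are normalised per species by the observed
  maximum, so MEL (~tens of g/L) and nitrate (~3 g/L) contribute
  comparably; weights are overridable. Optimisation is derivative-free on
  log-transformed parameters: Brent line search for one free parameter,
  Nelder–Mead with a deterministic five-start multi-start otherwise
  (first start at the defaults, the rest drawn uniformly in log-bounds from
  the seed). Fits are bit-reproducible given the seed. When no growth
  parameter is freed, the growth trajectory is simulated once and cached.

Identifiability is exposed rather than hidden: `profile_objective()`
evaluates the objective along one parameter. The FA inhibition constant
$K_{i,hyd}$ is only weakly identified unless fatty acids actually
accumulate (hence its looser recovery tolerance in the tests, 15% vs 5%),
and it is structurally inert in scenarios where FA stay at zero — the
profile is flat there, and the tests assert exactly that. $Y_{FA/MEL}$ is
treated as fittable but defaults to its calibrated value; it cannot be
obtained by direct regression because FA is an intermediate pool fed and
drained by three fluxes at once.

## Problem sizes and test budgets

The shipped scenarios integrate in milliseconds (≈1000–2400 Euler steps
each), so the test suite runs the full scenario library, the tenfold-refined
oracle comparisons, and single-parameter recovery fits on the full
repeated-oil-feed scenario in well under a minute. Recovery tests use
noiseless tables for the 5%/15% single-parameter checks and a 5%-noise,
fixed-seed table for the noisy MEL-capacity check.

## Known limitations

* The strict phase separation assumes cells are stationary when production
  starts; simultaneous growth and production is outside the model.
* All rate constants are temperature- and pH-independent (the process is
  controlled at 30 °C, pH 6).
* Glycerol released by hydrolysis is tracked only implicitly through
  $Y_{FA/oil} < 1$; mannitol formation is not modelled.
* The model is valid only while lipases and cells stay active; reported
  late-process deviations (after ~350 h) are expected and not captured.
* Explicit Euler at the published step sizes carries a first-order
  discretisation error of order 0.1% on the shipped scenarios; the refined
  oracle tests bound it.
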