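---
title: "Degradation kinetics and thermodynamics of anthocyanins during drying"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degradation kinetics and thermodynamics of anthocyanins during drying}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthokinetics)
```

## The model and its assumptions

Anthocyanin loss during isothermal drying is treated as a single
n-th order reaction, dC/dt = −k·Cⁿ, fitted separately for each compound at
each drying temperature. The package supports the five orders conventional in
food-degradation work, n ∈ {0, 0.5, 1, 1.5, 2}, each through its integrated,
linearized form: a transform y(C₀, Cₜ) that satisfies y = k·t along a
noiseless trajectory. All transforms are oriented so that y is zero at t = 0
and increases as the compound decays, which keeps every fitted rate constant
nonnegative; for the 0.5-order form in particular we use
y = 2(√C₀ − √Cₜ), the grouping consistent with its closed-form half-life.

The modelling assumptions are the usual ones:

* each compound × temperature series decays independently, from a measured
  time-zero concentration C₀ (C₀ is data, not a fitted parameter);
* replicates at a time point are exchangeable and are averaged before the
  fit, so one curve is fitted per temperature;
* temperature is constant within a series (isothermal kinetics);
* concentrations are strictly positive — the fractional and logarithmic
  transforms are undefined at C ≤ 0, and the readers enforce this.

Goodness of fit is R² = 1 − SSE/SST computed **on the transformed scale**,
because that is the scale on which the regression is performed and on which
order comparisons in degradation studies are tabulated. R² on the raw
concentration scale would favour different orders in a way the linearized
fitting procedure never sees. When SST is zero (a constant transformed
series), R² is defined as 1 if the residuals also vanish and as −∞ otherwise,
so a degenerate fit can never win a comparison while division by zero is
avoided.

Two fitting modes exist: the zero-intercept form y = k·t implied by the
integrated laws, and the default intercept form y = a·t + b. The intercept
form is the one whose (a, b) pairs feed the temperature-generalized
prediction model, and it is also more forgiving of a noisy time-zero
measurement; the zero-intercept mode reproduces the strict textbook
formulation. The rate constant is |a| in either mode.

**Order selection.** The best order maximizes R²; when two orders differ by
less than 10⁻⁶ the lower order wins on parsimony. At the table level
(`select_orders()`) the per-temperature R² values are averaged per compound
and one order is chosen per compound, which is how degradation studies report
their model choice; per-series selection (`select_order()`) is available when
temperatures should be allowed to disagree.

## Thermodynamic parameters

With rate constants at two or more temperatures, ln k is regressed on 1/T
(T in Kelvin; T_K = T_°C + 273.15 throughout) and the activation energy is
Ea = −slope·R with R = 8.314 J/(mol·K). Q10, the factor by which the rate
grows over a +10 °C step, is reported as the ratio of the *fitted* rate
constants at tabulated temperatures 10 °C apart — the approximation used in
the drying literature — while the Arrhenius closed form
exp(Ea/R · 10/(T_K(T_K+10))) is exposed separately (`q10_arrhenius()`)
for when an exact law is assumed.

The Eyring parameters at each temperature are

* ΔH = Ea − R·T_K,
* ΔG = −R·T_K · ln(k·h/(k_B·T_K)), with h = 6.6262×10⁻³⁴ J·s and
  k_B = 1.3806×10⁻²³ J/K,
* ΔS = (ΔH − ΔG)/T_K, an identity that holds exactly by construction and is
  asserted in the tests.

One unit convention deserves emphasis: published activation free energies in
this literature insert the rate constant **numerically in min⁻¹** into the
Eyring expression alongside h in J·s. That mixes time units, but it is the
convention under which the reported ΔG values (≈ 90–102 kJ/mol for
anthocyanin degradation at 50–70 °C) arise, so `k_units = "per-min"` is the
default. The dimensionally consistent alternative (`"per-sec"`) divides k by
60 first and shifts every ΔG up by R·T·ln 60 ≈ 11 kJ/mol; both are exposed
and neither is silently "corrected".

Half-lives use the generalized closed form t½ = (2ⁿ⁻¹ − 1)/((n−1)·k·C₀ⁿ⁻¹)
for n ≠ 1 and ln 2/k for n = 1, which reduces to the familiar 1.5- and
2-order expressions. They are provided for all five orders even though
degradation reports typically print only the selected order's values.

## The temperature-generalized prediction model

For prediction at arbitrary (T, t), the per-temperature slope a(T) and
intercept b(T) of the intercept-mode fits are modelled as functions of
temperature **in degrees Celsius** — the coefficient magnitudes of published
prediction equations only make sense in °C, and the package keeps Kelvin for
the thermodynamics only. Candidate bases are constant, linear
(a₁T + a₀), quadratic (a₂T² + a₁T + a₀) and logarithmic (a₁ln T + a₀);
each coefficient's basis is chosen by R² over the temperature grid.

Because three temperatures are common and a quadratic interpolates three
points exactly (R² = 1 always), raw R² would always select the quadratic.
Basis selection therefore applies a parsimony penalty: a basis with fewer
parameters wins unless its R² trails the best by more than 0.01. Signed
coefficients are stored exactly as fitted, and a `direction` field records
the transform orientation of the stored surface (+1 for the package's
canonical orientation, −1 for the opposite convention used by some published
left-hand sides), so inversion back to concentration is well defined either
way. Surface values implying no decay clamp the prediction at C₀; for orders
below 1 the surface stops being invertible at the extinction value
(e.g. y ≥ C₀ at order 0), and predictions beyond it raise an error naming
the offending (T, t) rather than returning a nonpositive concentration.

Validation pools all observations of all series: each series contributes its
own measured C₀, and the pooled R² of predicted versus observed
concentration is reported. The degenerate-SST rule above applies here too.

Models serialize to a YAML document with coefficients written at full double
precision (`%.17g`), so a written-then-read model predicts bit-for-bit
identically.

## The synthetic-data generator

The generator stands in for raw drying measurements. Its default
configuration (`red_cabbage_config()`) encodes the study conditions of
air-impingement jet drying of red cabbage:

* two compound archetypes — a 1.5-order degrader patterned on
  cyanidin-3-diglucoside-5-glucoside with k = 0.0003/0.0006/0.0020 min⁻¹ at
  50/60/70 °C (activation energy 87.19 kJ/mol) and a 2-order degrader
  patterned on the cyanidin aglycone with k = 0.0094/0.0177/0.0229 min⁻¹
  (41.21 kJ/mol);
* sampling grids matching the drying schedules: {0, 150, 300, 480, 720} min
  at 50 °C, {0, 120, 240, 420, 630} at 60 °C, {0, 60, 150, 240, 450} at
  70 °C;
* initial contents: 390.4 µg/g dry basis for the glycoside (25.25% of a
  fresh total anthocyanin content of 1546.18 µg/g d.b.) and
  1/(0.0094 × 74.53) ≈ 1.43 µg/g d.b. for the aglycone, back-derived from
  its 50 °C half-life — both documented as derived, not measured;
* three replicates with 5% multiplicative noise.

Rate constants come from the tabulated per-temperature values by default
(*exact-k mode*), because tabulated constants at three temperatures are
generally not perfectly Arrhenius-consistent; an Arrhenius mode through
(Ea, k_ref, T_ref) is available for archetypes defined by an exact law.

The noise model is multiplicative lognormal with unit mean and a 5%
coefficient of variation, chosen because chromatographic quantification error
scales with signal and concentrations must stay positive; replicate-level
dispersion for individual anthocyanins is rarely published, so the 5% figure
is a stand-in and is exposed in the configuration. An additive Gaussian
alternative exists; under it, draws at or below a configurable floor are
resampled (and logged) so the fractional transforms stay defined. A single
integer seed fully determines the output, and generation restores the
caller's RNG state.

What the generator does *not* emulate: deglycosylation coupling (in real
material the aglycone is produced while its glycosides decay, which the
independent-decay assumption ignores), drying-induced moisture and matrix
changes, instrument drift, and heteroscedasticity beyond the constant-CV
model. Passing tests on synthetic data therefore demonstrate that the
estimation machinery is correct and well calibrated under the stated model,
not that real drying series satisfy that model.

## Numerical choices

* Transforms refuse C ≤ 0 with a domain error naming the order; forward
  simulation clips orders below 1 at zero from their finite extinction time.
* Fits require ≥ 3 distinct time points and a time-zero observation.
* Order-selection and basis-selection ties break toward fewer parameters /
  lower order (tolerances 10⁻⁶ and 0.01 respectively).
* Closed-form trajectories are verified against an independent stiff ODE
  integration (`deSolve::lsoda`, rtol 10⁻¹⁰) to 10⁻⁶ relative, and
  closed-form half-lives against bisection of the forward curve.
* Monte-Carlo checks in the test suite use 40–100 seeded replicates of the
  default two-archetype design — enough for stable medians and hit rates
  while keeping the suite fast.

## Limitations

* One order per series: no joint multi-compound or Arrhenius-constrained
  global likelihood, and no nonlinear least squares on the raw concentration
  scale (the linearized fit weights observations unevenly on that scale).
* Prediction intervals are out of scope; the validation output is a point
  R², not a band.
* The Eyring min⁻¹ convention reproduces published tables but is
  dimensionally inconsistent; cross-study comparisons should fix a
  convention first.
* Extrapolation beyond the calibrated temperature range warns rather than
  fails — coefficient surfaces are empirical, not mechanistic, and should
  not be trusted far outside 50–70 °C for the default configuration.
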