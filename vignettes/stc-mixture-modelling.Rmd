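---
title: "Modelling mixture neurotoxicity in the zebrafish embryo tail-coiling assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mixture neurotoxicity in the zebrafish embryo tail-coiling assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stcmix)
```

## The assay and the modelling problem

Spontaneous tail coiling (STC) is the earliest motor behaviour of the
zebrafish embryo (around 17--24 hours post-fertilization), quantified as
coils per minute from one-minute video recordings. Neuroactive chemicals
shift the coiling frequency up (hyperactivity) or down (hypoactivity), and
the size of that shift follows a classical sigmoidal concentration-response
relationship. Because environmental exposure is almost always to mixtures,
the practical question is whether the response to a mixture can be predicted
from the single-substance curves -- and what happens when the components
push the behaviour in opposite directions.

`stcmix` implements that analysis end to end: normalization of embryo-level
counts against unexposed controls, four-parameter log-logistic (LL.4)
curve fitting, standardization of hyperactivity curves to a common maximum,
equitoxic mixture design, concentration-addition (CA, Loewe additivity) and
independent-action (IA, Bliss independence) prediction, substitution
("dilution of each other") designs, and an antagonism assessment for
opposing-direction mixtures.

## The concentration-response model

All curves use the four-parameter log-logistic function

$$y(x) = c + \frac{d - c}{1 + (e/x)^b}$$

with floor $c$, ceiling $d$, slope $b > 0$ and inflection $e$ (the EC50 when
$c = 0$, $d = 100$). Percent effects are always written so the curve
*increases* with concentration: hypoactivity is expressed as percent
*decrease* in coiling frequency, also running from 0 to 100, with the
direction kept as a flag for reporting. This gives one fitting code path for
both directions.

Numerical choices in `fit_ll4()`:

* Fitting happens on the log10-concentration scale with the inflection
  parameterized as $\log_{10} e$, which conditions the problem well across
  the five orders of magnitude spanned by the tested substances.
* Levenberg-Marquardt least squares is started from three points
  (inflection at the geometric mean of the tested concentrations, one decade
  below, one decade above; slope 1); the best converged fit is kept. On
  noise-free data the generating parameters are recovered to numerical
  precision, which the test suite asserts.
* Standard errors come from the Gauss-Newton approximation of the Hessian,
  and the reported confidence interval is the estimate $\pm 2$ standard
  errors -- the assay's conventional reporting rule, taken literally rather
  than via a $t$ quantile. ECx intervals propagate the inflection's standard
  error by the delta method (the inversion is proportional to $e$).
* Control (zero-concentration) observations never enter the fitter; they are
  consumed by the normalization step. Concentrations are nominal throughout.

## Normalization and hyperactivity standardization

`percent_change()` converts embryo counts to the mean percent change versus
the unexposed controls *of the same independent experiment*, because the
absolute coiling frequency varies between experiments. Per-experiment values
are then pooled by fitting them jointly rather than averaging first: joint
fitting uses the between-experiment spread as information about residual
error instead of discarding it, and the fit is invariant to experiment
relabelling.

The hyperactive substances reach different maximal percent increases, so
their raw curves are standardized to a common ceiling of 100 by dividing by
each substance's maximal percent effect (`standardize_hyperactivity()`).
The divisor is the *fitted* ceiling of the raw curve
(`max_effect_from_fit()`), not the largest observed mean -- observed maxima
are single noisy points, while the fitted ceiling borrows strength from the
whole curve. After standardization the EC50 of a substance equals its raw
effect concentration at half its own maximum (e.g. the raw EC41 for a
substance peaking at 82 percent), a correspondence the acceptance tests
verify. Hyperactivity followed by decline at high concentrations (consistent
with saturation or incipient paralysis) is truncated at the concentration of
maximal mean response before fitting (`truncate_at_peak()`); the decline is
modelled separately by the biphasic tools. Toxic-unit extrapolation for
partial agonists is deliberately not implemented: the observed decline
pattern argues for saturated full responses rather than partial agonism.

## Mixture prediction

For components sharing one effect direction on the standardized scale:

* **Concentration addition** treats components as dilutions of each other:
  $ECx_{Mix} = \left(\sum_i p_i / ECx_i\right)^{-1}$ with molar fractions
  $p_i$. For an *equitoxic* design ($p_i \propto EC50_i$,
  `equitoxic_fractions()`), the CA EC50 collapses to $\sum_i EC50_i / n$ --
  an exact closed form the tests use as an independent oracle.
* **Independent action** multiplies fractional "survivals":
  $E_{Mix} = 1 - \prod_i (1 - E_i)$ with $E_i$ the fractional effect of
  component $i$ at its partial concentration $p_i \cdot c$. `ia_ecx()`
  inverts this by bracketing and bisection on the log scale (relative
  tolerance $10^{-8}$); the effect function is monotone so the root is
  unique, and the tests check equivalence against a million-point grid scan.

Predictions on raw, unstandardized curves with unequal maxima are
unreliable (effects above the smallest ceiling become unpredictable), so the
prediction functions warn and point to the standardization step. Designs
mixing effect directions are rejected with a pointer to the antagonism
tools: neither CA nor IA is defined for counteracting components.

`substitution_design()` encodes the dilution experiment: a slice of one
component's molar fraction is repartitioned between the original substance
and a substitute in the ratio of their EC50s, so the remaining and added
amounts are equitoxic within the slice. Reproducing the study's printed
substituted-mixture ratios fixes this rule exactly. Note that the predicted
EC50 in concentration units *does* shift when the substitute is less potent
-- what is preserved is the CA algebra itself, which the tests state as an
associativity identity: the substituted design's CA ECx equals the CA ECx
obtained by treating the slice as a pseudo-component carrying the slice's
own CA ECx (exact to $10^{-9}$), and substituting an equal-potency
component leaves the prediction unchanged.

## Opposing directions and antagonism

When a hypoactive component joins hyperactive ones, the observed response
rises and then falls, and can flip below the control level at mid-high
concentrations. `fit_biphasic()` models this as a Gaussian in log10
concentration with a free (possibly negative) baseline, and accepts the
Gaussian only when it beats the best monotone LL.4 fit in residual sum of
squares -- monotone data are reported as monotone. `assess_antagonism()`
compares observed means with the additive (CA) expectation of the
same-direction sub-mixture: the verdict is *antagonistic* when the observed
response falls short of the prediction by more than twice its standard
error at two or more consecutive tested concentrations. The threshold count
and multiplier are exposed as arguments: the underlying study states no
quantitative antagonism criterion, so this operationalization -- chosen to
mirror the 2-standard-error interval rule used elsewhere in the assay -- is
a package decision, not a literature value. The reported direction-reversal
concentration is the lowest tested concentration *beyond the observed
maximum* where the mean response has the opposite sign to the reference,
so low-concentration noise around zero cannot register as a reversal.

## The synthetic data generator

`simulate_stc()` emulates the assay's design: 20 embryos per dish, two
replicate dishes per concentration, at least two independent experiments,
controls at concentration zero. Design choices, made once:

* **Count model**: negative binomial with mean
  $\mu = \text{baseline} \times \prod_i m_i$ and variance
  $\mu + \theta \mu^2$ ($\theta = 0$ gives Poisson). Coils per minute are
  small counts and some between-embryo overdispersion is biologically
  expected; the default $\theta = 0.05$ is mild. No noise model is published
  for this assay -- this is a declared assumption.
* **Baseline**: 6 coils/min. The absolute control frequency is not published
  either; 6 is a plausible figure for 24 hpf embryos and is exposed as
  configuration.
* **Between-experiment variation**: the baseline is scaled per experiment by
  a mean-corrected lognormal with relative standard deviation 0.15,
  reflecting the documented variability of absolute coiling frequency
  between independent experiments. It cancels out of within-experiment
  percent changes, exactly as the normalization intends.
* **Combination rule**: components sharing a direction combine by
  concentration addition (so a simulated same-direction mixture is exactly
  CA-additive and the CA prediction is the recoverable truth), and the two
  directions act multiplicatively on the mean:
  $\mu = \text{baseline}\,(1 + h/100)(1 - k/100)$. The cross-direction
  multiplicative rule produces the rise-then-fall pattern; it is a declared
  modelling choice, not a literature result.

The generator is seeded and byte-reproducible, and restores the caller's
RNG state. What it does *not* emulate: malformations and mortality (videos
of malformed embryos are excluded in the real assay), toxicokinetics,
within-dish correlation beyond the shared mean, and any real-data quirks of
the deposited raw dataset. Tests passing on synthetic data therefore
demonstrate correctness of the statistical machinery under the declared
model, not fidelity to every property of laboratory data.

### What the assay's replication can and cannot estimate

A useful by-product of the generator: with the assay's own replication
(20 embryos x 2 dishes x 2 experiments, ~6 coils/min baseline), the
normalize-and-fit pipeline recovers a true EC50 of 2 umol/L *without bias*
(median recovered value 1.94 over 200 seeds in the test conditions), but
with a coefficient of variation near 20 percent: per-concentration percent
changes carry standard errors of roughly 10 points against a curve slope of
about 86 points per decade. Even with Poisson counts -- the variance floor
for count data -- fewer than half of simulated assays land within 15
percent of the true EC50; reaching that precision reliably would take
roughly ten times as many embryos. The package's acceptance suite states
the 15-percent-in-90-percent-of-runs recovery property and reports its
outcome honestly; treat single-assay EC50s from this design as order-of-
magnitude-plus estimates whose 2-standard-error intervals matter.

## Worked example

```{r}
curves <- table1_curves("modeling")
mix_b <- equitoxic_design(curves[c("hexaconazole", "chlorpyrifos")],
                          label = "Hyperactive Mixture B")
mix_b
ca_ecx(50, mix_b)
ia_ecx(50, mix_b)
```

A full simulated round trip -- generate an assay, normalize, fit, compare:

```{r}
sc <- stc_scenario("Hyperactive Mixture B",
                   curves[c("hexaconazole", "chlorpyrifos")],
                   fractions = c(0.65, 0.35),
                   concentrations = c(0, 0.7, 1.4, 2.8, 5.6, 11.2))
rec <- simulate_stc(sc, seed = 21)
pc <- percent_change(rec)
raw <- fit_ll4(data.frame(concentration_um = pc$concentration_um,
                          effect_percent = pc$percent_change),
               fix_ceiling = FALSE, label = "Mixture B (raw)")
std <- normalized_response(pc, "hyperactivity",
                           max_effect_m = max_effect_from_fit(raw))
fit <- fit_ll4(std[, c("concentration_um", "effect_percent")],
               label = "Mixture B (observed)")
summary(fit)
```

## Problem sizes and determinism

The numeric reproduction of the reported mixture predictions runs from the
six-substance parameter table in well under a second. Property checks use a
million-point grid for the IA oracle, 10,000 Monte-Carlo draws for
normalization error bounds, and 200 seeded assay simulations for the
recovery study -- sizes at which the Monte-Carlo error of each check is far
below its tolerance. Every stochastic step takes an explicit seed, and the
pipeline writes byte-identical outputs for identical configuration and
seed.

## Known limitations

* The LL.4 model is the only concentration-response shape offered (no
  five-parameter or Weibull alternatives, no Box-Cox transforms, no model
  averaging), matching the assay's established practice.
* CA/IA predictions require standardized full-range curves; partial-response
  components are handled by standardization, not by toxic-unit
  extrapolation.
* The antagonism verdict is a descriptive interval rule, not a formal
  hypothesis test.
* Dose-ratio-dependent deviation surfaces (synergy/antagonism isoboles) and
  toxicokinetic interactions are out of scope.
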