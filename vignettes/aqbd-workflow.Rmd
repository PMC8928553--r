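---
title: "The AQbD workflow: models, robustness and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The AQbD workflow: models, robustness and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqbd)
```

## The problem

Analytical Quality by Design develops a separation method the way
process engineers develop a manufacturing step: define the target
profile (here, every critical peak pair resolved with *R*ₛ ≥ 2.0,
recovery 70–130%, RSD ≤ 10%), identify the controllable parameters that
drive those attributes, model the attribute–parameter relationship from
designed experiments, and then claim not a single operating point but a
whole region — the Method Operable Design Region — inside which the
method stays acceptable even under realistic parameter wobble.

The package implements that chain for a UHPLC impurity method for
cabotegravir. The four critical method parameters are pump flow rate
(*A*, 0.2–0.4 mL/min), final % mobile phase B in the gradient (*B*,
50–90%), column temperature (*C*, 30–50 °C) and pH of mobile phase A
(*D*, 2.75–3.75); the three critical method attributes are the
resolutions of the peak pairs DP4/HICBG, 2CBG/4CBG and
4CBG/cabotegravir.

## Factor coding and response models

All modelling happens on coded units: the natural range [low, high] of
each factor maps linearly onto [−1, +1], so coefficients are
comparable across factors and pure quadratic terms are well scaled.
`code_point()`/`decode_point()` implement the bijection; round-tripping
is exact to machine precision.

A `response_model()` is a sum of coefficient × monomial terms over the
coded factors, with monomials written `"A"`, `"B^2"`, `"A^2*D"`,
`"A*C*D"`, up to total degree 4 (the richest terms a chromatographic
optimisation practically needs are quadratic-by-linear products). A
model may carry a power transform: the polynomial then predicts
*y*^λ and natural-scale predictions are back-transformed as
value^(1/λ). Fitting all responses on a declared term set by OLS —
with no automatic term selection, which commercial DoE software does
perform but whose selection rule is not reproducible — is a deliberate
simplification: term sets are inputs, not discoveries.

### The packaged cabotegravir models

`cabotegravir_models()` returns the fitted CMA models of the method at
the screening stage (peak-count criteria over flow, %B and pH) and the
optimization stage (the three resolutions over all four factors), with
their reported ANOVA summaries. Two modelling choices deserve
explanation:

* **The inverse-square transform on `Rs_4CBG_cabotegravir`.** The
  reported model for this resolution has intercept 0.175 and
  coefficients two orders of magnitude smaller than its siblings. Read
  on the identity scale it would predict a resolution of ≈ 0.1 at the
  selected working point — physically absurd for a separation reported
  to work, and inconsistent with the reported prediction of 3.2. Read
  as a model of *R*ₛ^−2 (a standard automatic response transform in DoE
  software; back-transform value^(−1/2)) it predicts 3.15 at the
  working point, consistent with 3.2 once one accounts for the
  three-decimal rounding of the published coefficients. The package
  therefore stores this model with `power_transform(-2)`. This is an
  inference from internal consistency, flagged in the fixture file, and
  overridable by reconstructing the model with another transform.
* **The screening pH factor.** The screening stage varied buffer family
  as well as pH; the packaged screening space treats pH as a single
  continuous factor over 2.75–3.75 (the ammonium formate arm), which is
  the range the optimization stage retained. The acetate arm is out of
  fixture scope.

Comparisons against printed one-decimal predictions use
round-half-away-from-zero (`round_half_away()`), the rounding
convention of analytical reporting, not base R's round-half-even.

## Optimal design of experiments

`exchange_design()` selects exact designs from a finite candidate grid
(default three levels per factor) by Fedorov best-swap exchange with
multi-start: from a random subset, repeatedly replace the single run
whose best exchange with a candidate most improves the criterion, until
no swap helps; the criterion value never increases. The A-criterion
trace((XᵀX)⁻¹)/p and G-criterion max xᵀ(XᵀX)⁻¹x are both available;
when ranking multi-start results under A, exact ties are broken by the
G value, giving one scalar ordering that serves both aims. The
exchange algorithm itself is an implementation choice — any exact
optimal-design method would do — and on small instances it is verified
against exhaustive subset enumeration.

Centre-point replicates (default 3) are appended after optimisation and
labelled as a replicate group: without genuine replicates, pure error
is inestimable and the lack-of-fit diagnostic below cannot be computed.

## ANOVA and the lack-of-fit threshold

`anova_stats()` reports *R*², adjusted *R*² and the overall regression
*F*-ratio on the fitting (transformed) scale. With replicate groups the
residual sum of squares is partitioned into pure error and lack of
fit. Method reports print "MS-LOF" with a "threshold" but do not define
the threshold; the package implements it as
*F*₀.₉₅(df_LOF, df_PE) × MS_PE, so that MS-LOF < threshold is exactly a
non-significant lack-of-fit *F*-test at α = 0.05. This is an
interpretation chosen for its equivalence to the standard test, not a
documented convention of the source software. The acceptance rule used
during screening (`significance_check()`) is a strict *F* > 4.00
together with the lack-of-fit gate when available.

## Desirability

Scouting-stage searches grade each criterion linearly between two
anchors (e.g. 8 resolved peaks → 0, 10 → 1, clamped outside) and
combine criteria by the weighted geometric mean, which a single zero
annihilates — one fully failed criterion vetoes a candidate. Weights
default to equal because the source workflow does not state any; the
two-sided (target-is-best) Derringer form and exponents are
deliberately not implemented. The cumulative desirability value 0.6030
reported for the scouting search is treated as a conceptual anchor
only: the underlying scouting responses are not available, so no test
asserts it.

## Monte-Carlo robustness and the MODR

`monte_carlo_cpk()` perturbs the nominal operating point with
independent normal noise per factor, truncated to the natural ranges by
reject-and-redraw, evaluates a CMA model at each draw, and summarises
the result as Cpk = (mean − LSL)/(3·sd) against the resolution limit
LSL = 2.0, with the acceptance rule Cpk ≥ 1.33 (`coverage_for_cpk()`
converts this to the familiar "99.99% within specification"). Two
degenerate contracts are documented rather than left to chance: zero
spread yields a capped index of 999 when the mean clears the limit and
0 otherwise.

The perturbation magnitudes are not stated in the source workflow; the
defaults — flow 0.01 mL/min, %B 0.5 points, temperature 0.5 °C, pH
0.05 — are typical instrument tolerances for a modern UHPLC stack, set
once in `perturbation_spec()` and always reported alongside results.
The default draw budget is 10,000 per node; the Monte-Carlo standard
error of a Cpk near 3 is then about 1%.

`map_modr()` grids a factor box, evaluates every CMA model at every
node, optionally simulates per-node Cpk, and flags nodes where all
predictions (and capabilities) pass. The largest axis-aligned all-pass
box is extracted *exhaustively* over grid-aligned boxes using a
k-dimensional cumulative-sum array, so the reported box is a global
optimum, with ties broken by larger natural volume and then the
lexicographically smallest lower corner. At the default 9 levels per
factor this enumerates 45⁴ ≈ 4.1 million boxes in a few seconds.

The published MODR (flow 0.32–0.40 mL/min, 30–40 °C, pH 3.25–3.75, %B
50–60) is treated as a *verification input*: the package confirms that
every node of a dense grid over that box passes, rather than claiming
to re-derive the box itself, because the robustness engine that
produced it uses an unpublished perturbation model.

## Validation statistics

The validation module is deliberately plain arithmetic with explicit
reporting conventions: recovery 100·found/added at two decimals,
RSD with the n−1 standard deviation, response factors as slope ratios
at two decimals, calibration lines by OLS with Pearson *r* at three
decimals, and signal-to-noise in the European Pharmacopoeia form
S/N = 2H/h (baseline-corrected height over peak-to-peak baseline
noise; an H/sd-of-noise variant is available). The packaged validation
tables are transcriptions of the published method's results; tests
verify their internal arithmetic (all 24 recoveries recompute from
added/found within 0.05 points — the slack absorbs the four-decimal
rounding of the inputs — and all 8 response factors recompute exactly
from the calibration slopes). The replicate areas behind the published
RSD values and the raw chromatograms behind the S/N values are not
available, so those columns are carried as anchors and screened against
criteria, never recomputed.

## What the synthetic generator does and does not emulate

`simulate_doe_responses()` uses the packaged models as ground truth and
adds independent Gaussian measurement noise (σ = 0.05 resolution units
in the shipped recovery configuration — a realistic repeatability for
resolutions in the 2–5 range). This exercises design, fitting and
prediction end-to-end; it does *not* emulate run-order drift,
heteroscedasticity, or model misspecification, so parameter-recovery
tests demonstrate correctness of the estimation machinery, not
real-world model adequacy.

`simulate_chromatogram()` builds traces as sums of exponentially
modified Gaussian peaks — the standard model for tailed
chromatographic peaks, with the Gaussian limit at τ = 0 — plus linear
drift and white noise. The EMG is evaluated in a numerically stable
split form: a scaled-erfcx expression on the leading edge and a direct
exponential-times-erfc expression on the tailing edge, with an
asymptotic series for extreme arguments, so traces remain finite at
any τ/σ ratio. The ten-peak demonstration scenario
(`cabotegravir_demo_peaks()`) reproduces the method's elution order
with invented retention times, areas and widths — the published values
exist only as figures — and deliberately crowds the DP4/unknown pair
below *R*ₛ = 2.0 so that resolution censuses exercise both outcomes.
Peak measurement assumes baseline-resolved peaks and noise well below
the smallest peak height; heavily fused peaks are out of scope.

## Problem sizes used in the shipped tests

The test-suite and example configurations use desk-scale sizes chosen
to finish in seconds while leaving no algorithmic branch unexercised:
3⁴-point candidate grids with 3 centre replicates for fitting (84
runs), exhaustive design enumeration up to C(9,6) subsets, 100
seeded refits for parameter recovery, 50,000 Monte-Carlo draws for the
closed-form capability cross-check, and the full 9⁴ MODR grid for the
verification map.

## Known limitations

* Term sets are declared, never selected; there is no stepwise or
  Box-Cox search (λ is declared per response).
* Designs are exact and unblocked; no split-plot structure, no
  categorical factors, no D- or I-optimality.
* The robustness simulation assumes independent normal perturbations;
  correlated drifts (e.g. pump and gradient coupling) are not modelled.
* Chromatogram measurement is threshold-and-interpolation metrology; it
  does not deconvolve overlapping peaks.
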