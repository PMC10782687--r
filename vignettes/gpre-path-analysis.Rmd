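---
title: "Path analysis of green plant regeneration efficiency: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path analysis of green plant regeneration efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpresem)
```

## The model

Anther culture regenerates triticale plants from microspores; the
efficiency of obtaining *green* regenerants (GPRE, green plants per 100
plated anthers) responds to the Cu(II) content of the induction medium and
to the stress biochemistry of the cultured tissue.  The model at the heart
of this package is a recursive path model over seven observed variables:

- **exogenous**: Cu(II) concentration (`Cu`) and the 990–950 cm⁻¹ FTIR
  absorbance band assigned to low-methylated pectins (`LMP`), freely
  covarying;
- **endogenous**: the 1630…1470 cm⁻¹ band assigned to S-adenosyl-L-
  methionine (`SAM`), the 2550–2540 cm⁻¹ band assigned to glutathione
  (`GSH`), metAFLP de novo CHH methylation (`CHH_DNMV`), metAFLP CHH
  sequence variation (`CHH_SV`), and `GPRE`.

Twelve directed paths (`lambda1`–`lambda12`), one exogenous covariance and
five residual variances (`delta1`–`delta5`) give q = 20 free parameters
against p(p+1)/2 = 28 observed moments, hence 8 degrees of freedom.
`triticale_gpre_model()` returns this structure; `path_model()` builds any
other recursive model in the same class.

Assumptions: all variables observed (no latent structure, no mean
structure); the directed graph is acyclic; residuals are mutually
uncorrelated and uncorrelated with the exogenous variables; estimation
treats the data as multivariate normal, entering only through the sample
covariance and N.  The source description of the diagram uses the phrase
"non-recursive", which in SEM terminology would mean feedback loops; the
printed diagram has none and shows five independent residuals, so we treat
the wording as a terminology slip and implement the recursive (acyclic)
class only.  Cycles are rejected at model-build time with the offending
cycle named.

Two bookkeeping choices the printed tables do not pin down:

- **Residual labels.** The published table lists residual variances
  `delta1`–`delta5` without naming their variables.  We assign them in the
  order each endogenous variable first appears as a path target (SAM,
  CHH_DNMV, GSH, CHH_SV, GPRE); this is also the only assignment consistent
  with the printed magnitudes (the near-zero third residual belongs to the
  tiny-scale GSH band).
- **Free covariances** are restricted to exogenous pairs — the class the
  effect decomposition and the closed-form baseline assume.

## Estimation

`fit_ml()` minimises the ML discrepancy
F = ln|Σ| − ln|S| + tr(SΣ⁻¹) − p over the free RAM parameters with
`nlminb` and an analytic gradient; the implied covariance is
Σ = (I − A)⁻¹S(I − A)⁻ᵀ, always well defined for an acyclic model because
I − A is unit-triangular under a topological order.

Numerical choices:

- **Starting values** are per-equation least squares (each endogenous
  variable regressed on its parents) with residual and exogenous variances
  read off the sample matrix.  For recursive models with a saturated
  exogenous block this start *is* the ML solution (the Gaussian likelihood
  factorises over equations), so the optimiser typically confirms it in
  one iteration; the quasi-Newton step matters for models with
  fixed-at-zero exogenous covariances.
- **Internal rescaling.** Variables are scaled to unit sample variance
  before optimisation and estimates/SEs are back-transformed (path j→i by
  d_i/d_j, (co)variances by d_i·d_j).  This is essential here: the GSH band
  variance is ~1.6·10⁻⁷ while Cu(II)'s is ~12.4, a conditioning spread of
  10⁸ that is also why the published table prints the Cu→GSH coefficient
  and the GSH residual as "0" at four decimals.
- **Convergence** is declared at relative function change < 1e−12 or
  gradient infinity-norm < 1e−8 (at most 500 iterations).  The gradient
  test is scaled by 1 + max|Σ⁻¹| because near-singular implied covariances
  inflate floating-point cancellation in the gradient; an unconverged fit
  with a materially nonzero scaled gradient is an error, not a silent
  result.
- **Standard errors** come from the inverse *expected* information,
  I_jk = ((N−1)/2)·tr(Σ⁻¹ ∂Σ_j Σ⁻¹ ∂Σ_k); critical ratios are b/SE.
- **Chi-square multiplier** is (N−1)·F.  This pairs with the convention of
  fitting the biased (divisor-N) covariance: `reconstruct_covariance()`
  applies (N−1)/N when asked for `divisor = "n"`, which reproduces the
  printed exogenous variances (12.787·36/37 = 12.4414 for Cu) while χ²
  itself is divisor-invariant for this model class (every variance free).
- **Heywood cases** (negative variance estimates) set a warning flag on the
  result instead of erroring.
- **Standardization** uses implied — not sample — standard deviations,
  β(j→i) = b·sd(j)/sd(i), and turns free covariances into implied
  correlations.

## Fit indices

The index battery follows the conventional (AMOS-style) formulas, listed in
`?fit_indices`.  The baseline model frees all variances and fixes all
covariances, with the closed form χ²_b = −(N−1)·ln|R|.  RMSEA confidence
bounds invert the noncentral χ² distribution (P = .95 at the lower bound,
.05 at the upper), PCLOSE tests noncentrality (N−1)·df·0.05², ECVI bounds
reuse the same noncentrality interval, and Hoelter's critical N is
floor(χ²_crit(df, α)/(χ²/(N−1))) + 1 — the floor-then-add-one rounding is
fixed by the published value (15.507/0.23488 = 66.02 → 67).

Two printed statistics resist reproduction from the printed χ² under any
standard convention: the published RMSEA (0.0379; both N and N−1
conventions give 0.039–0.041), and the PNFI/PCFI pair, which appears
swapped relative to the defining formulas PNFI = (df/df_b)·NFI and
PCFI = (df/df_b)·CFI.  The package always reports the computed values; the
fixture file documents the printed ones.

## Effects

`effect_decomposition()` computes total effects as (I−B)⁻¹Γ on exogenous
sources and (I−B)⁻¹ − I on endogenous sources; B is nilpotent for a DAG, so
the inverse equals the finite path-product sum, and the unit tests verify
equality against an exhaustive path-enumeration oracle on random DAGs up to
7 nodes.  `total = direct + indirect` holds to machine precision by
construction.  Exogenous-on-exogenous entries (the Cu↔LMP covariance) are
excluded from the tables, matching the published layout.

One reproducibility caveat: b-metric indirect effects through GSH multiply
a coefficient printed as 0.0006 by one printed as 1535.4, so recomputing
them from the rounded table cannot hit four decimals (the published
unstandardized SAM→GPRE total of −0.3824 requires unrounded inputs).  The
tests therefore check the standardized entries — which are well scaled — at
4 decimals, and validate the unstandardized LMP→GPRE entry through the
mediation chain rule (λ1 × SAM-total) at print precision, the same identity
by which the published value was formed.

## The synthetic generator

`generate_dataset()` emulates the study's unavailable raw 37 × 9 table as
multivariate normal with the printed means and covariance
diag(sd)·R·diag(sd).  Two modes:

- `"paper"`: a joint MVN over all nine variables, including the design
  variables Cu/Ag/Time.  The SEM consumes only the covariance matrix, for
  which this is the exact emulation.
- `"design"`: Cu, Ag and Time fixed at an eight-trial grid; responses drawn
  from their conditional normal given the design values.  The published
  study fixed these by design (trials A–H, Cu 0.1–10, Ag 0–60, 35–49 days,
  3–10 regenerants per trial, 37 total); the per-trial composition is not
  itemised, so `trial_design()` spreads the levels evenly over the printed
  ranges with group sizes 5,5,5,5,4,5,4,4 — chosen once as a realistic
  layout and not tuned thereafter.

What the generator does *not* emulate: the printed skewness/kurtosis (an
MVN has none — the source analysis itself appeals to asymptotic normality),
within-trial clustering beyond the design means, and measurement error
structure in the FTIR bands.  Passing recovery tests therefore demonstrate
estimator correctness under the model's own assumptions, not robustness to
their violation.

`parameter_recovery()` is the consistency harness: at the published
solution (on a unit-variance scale to sidestep the GSH conditioning), 100
replicates per n over n ∈ {50, 200, 1000} show standardized-path bias below
0.01 at n = 1000 and RMSE decreasing in n for every path; under a zero-path
generating model the |CR| > 1.96 rate sits at the nominal 5%.  These
problem sizes keep the default test run comfortably under a minute while
leaving Monte-Carlo error well inside the asserted bands; the functions
accept larger grids.

## FTIR band module

`band_value()` implements the band variables exactly as the published
footnote describes them: the arithmetic mean of absorbances sampled every
10 cm⁻¹ inside the band (LMP at 990…950, GSH at 2550 and 2540), linearly
interpolated from the instrument grid (nominally 600–4000 cm⁻¹ at 4 cm⁻¹).
The SAM region 1630…1470 combines discontinuous sub-segments that the
source does not enumerate (they come from its FTIR-assignment reference);
the default uses the full window and `band_definition()` accepts any
sub-segmentation.

`normalize_unit_area()` scales the whole spectrum so the trapezoidal
integral over 1800–900 cm⁻¹ is one; the factor is global, so the GSH band —
outside the window — lands on the same scale.  Note that a literal
unit-integral spectrum averages ~1/900 absorbance across the fingerprint
region, so the published band means (e.g. LMP 0.5512) imply a different
normalisation constant in the original processing chain; `demo_spectrum()`
therefore calibrates its three flat-topped component peaks to the published
band *values* directly (solving a 3 × 3 linear system, exact by
construction) and is documented as a synthetic stand-in, not a measurement.

Baseline correction offers endpoint-linear (default, optionally per
segment) and rubberband (lower convex hull) methods; the vendor software's
exact algorithm is unspecified, and both are documented approximations.

## Verification strategy and limitations

Because the raw regenerant table is unavailable, all study-level numbers
flow from printed summaries; ML SEM depends on data only through (S, N), so
this is lossless up to print rounding — which is the dominant error term
(χ² 8.485 computed vs 8.4558 printed).  The suite pins three layers:
closed-form oracles (hand-evaluated discrepancies, per-equation OLS for
just-identified models, the factorised Gaussian-DAG MLE as an independent
route to F_min on random models), printed-value agreement at stated
tolerances, and distributional properties (replicate χ² against the central
χ²₈ reference, nominal type-I rates).

Known limitations: no latent variables, means, multi-group or missing-data
support; GLS/ULS/robust discrepancies are out of scope; bootstrap intervals
for indirect effects are not provided; the Ag(I) and Time variables are
carried in the fixtures and generator but enter no path (the source
analysis found they did not enter the model).
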