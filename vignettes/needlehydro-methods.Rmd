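---
title: "Methods: needle hydraulic anatomy, simulation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: needle hydraulic anatomy, simulation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(needlehydro)
```

## The physical model

Each tracheid lumen is treated as an elliptical conduit in laminar flow.
Its theoretical hydraulic conductivity is the Hagen–Poiseuille expression
$k_t = (\pi\rho/8\eta)\,r_{lum}^4$ with the elliptical modification
$r_{lum}^4 = d_{max}^3 d_{min}^3 / (8d_{max}^2 + 8d_{min}^2)$, which
reduces exactly to the circular law $(\pi\rho/8\eta)(d/2)^4$ when
$d_{max} = d_{min}$. Constants are water at 20&nbsp;°C:
$\rho = 998.205$&nbsp;kg&nbsp;m$^{-3}$ and
$\eta = 1.002\times10^{-9}$&nbsp;MPa&nbsp;s. Diameters are measured in µm
and converted to metres inside `tracheid_conductivity()`, so single
tracheids land on the $10^{-12}$–$10^{-11}$&nbsp;kg&nbsp;m&nbsp;s$^{-1}$&nbsp;MPa$^{-1}$
scale.

Assumptions worth keeping in mind: straight parallel tubes, no pit
resistance, no cavitation. Theoretical conductivity computed this way
overestimates measured conductivity substantially (measured values in
conifers are typically 30–50% of theoretical); for the narrow tracheids of
needles (well under 20&nbsp;µm) lumen resistance dominates, so the *relative*
comparisons the package reports are meaningful even though absolute values
are upper bounds. Modelling pit or whole-branch resistance is out of scope.

### Needle-level traits

Tracheid-level measurements are averaged (`d_max`, `d_min`, `A_lum`) or
summed (`N_lum`, `k_th`) per needle; `N_t` is the count. Flatness `F_t` is
the **mean of per-tracheid ratios** $d_{max}/d_{min}$, not the ratio of the
mean diameters. The two conventions genuinely differ under within-needle
variance — in the bundled reference means, sun-control needles have
`F_t` = 1.75 while the diameter-ratio would give 6.2/3.8 ≈ 1.63 — and only
the mean-of-ratios convention is consistent with those reference values.

### The k_s unit convention

Xylem-specific conductivity is $k_s = k_{th}/A_x$. Reported needle-level
values of `k_s` in this literature sit on the $10^{-12}$ scale, which is
only obtained if $A_x$ stays in µm² in the division; converting $A_x$ to m²
moves the result twelve orders of magnitude. The package therefore computes
both: `k_s` (reported-scale, µm² denominator — the default used in
comparisons, chosen for comparability with published tables) and `k_s_si`
(strict SI). Both columns are always present, so nothing is hidden behind
the convention.

## The synthetic-data generator

`simulate_needles()` emulates the sampling design the inference stage
assumes: 2 treatment plots (control, drought) × 3 trees × 2 canopy
positions (sun, shade) × 5 shoots × 7 needles = 420 needles, with families
15/27/29 carried as tree metadata only (never modelled). Group target means
come from `reference_calibration()` — published group means of ~20-year-old
Norway spruce under experimental drought — so the generator's defaults *are*
the study conditions rather than free dials.

Distributional choices:

* **Lognormal sizes and mean-one multiplicative tree/shoot effects.**
  Anatomical dimensions are positive and right-skewed; lognormals guarantee
  both. Tree and shoot effects (defaults: CV 0.08 and 0.05) scale linear
  dimensions by $\sqrt{e}$ and tracheid count by $e$, so area-level traits
  vary roughly twice as much between trees as diameters do — a coherent
  "bigger cross-section, more tracheids" geometry. The magnitudes are free
  parameters: reference tables report confidence intervals, not variance
  components, so the defaults are modest values typical of repeated
  within-stand anatomical sampling.
* **Correlated diameter/flatness draws.** The three per-group targets —
  mean $d_{min}$, mean $d_{max}$ and mean-of-ratios $F_t$ — are mutually
  inconsistent under independence: $E[d_{min}]\cdot E[F_t] = 3.8 \times
  1.75 = 6.65 \neq 6.2$ for sun-control needles. Real data reconcile the
  three because flatter tracheids tend to be the narrower ones. The
  generator reproduces exactly that: per tracheid, $d_{min}$ is lognormal
  (within-needle CV 0.25) and the flatness excess $F_t - 1$ is lognormal
  (log-scale spread `flatness_sdlog` = 0.8), joined by a Gaussian copula
  whose correlation is solved per group so that all three means are matched
  simultaneously in expectation. The solved correlations for the default
  calibration lie between −0.6 and −0.95. If a configuration makes the
  required correlation unattainable (|r| > 1 — e.g. very small CVs), it is
  clamped with a warning: diameter means remain exact and the flatness mean
  drifts toward the diameter ratio, which is forced in the zero-variance
  limit anyway.
* **Tracheid count** is a rounded lognormal around the group target
  (CV 0.12, minimum 1), so its dispersion is controllable independently of
  the mean.
* **Areas.** Lumen areas are exact ellipse areas $\pi d_{max} d_{min}/4$.
  Xylem area is total lumen area divided by a per-needle packing-fraction
  draw; the packing mean is calibrated per group in closed form as
  (expected total lumen area)/(xylem-area target), including the second
  moment of the tree×shoot effect, so the whole area chain — $A_x$, and
  $A_n$, $A_v$, $A_p$ scaled from it by the calibration's area ratios with
  CV-0.06 lognormal noise — recovers its targets without bias. For the
  default calibration the implied packing means are ≈ 0.31–0.35, matching
  the ≈ 0.35 one gets directly from reference N_lum/A_x. A fixed
  `packing_mean` can be supplied instead; requests implying packing above
  0.6 are refused with the offending group named.

With every CV set to zero the generator degenerates to one identical
needle per group whose traits equal the calibration targets up to
tracheid-count rounding — a useful oracle for the model-fitting code.

What the generator does **not** emulate: measurement error (lumens are
perfect ellipses; see the section surrogate below for that), non-elliptical
lumen shapes, within-shoot positional trends along the needle axis, genetic
(family) effects, and any weather or sap-flow dynamics. Passing tests
therefore validate the pipeline's statistical machinery under a idealised
but structurally faithful data-generating process — not the biology of any
particular stand.

### A note on a tempting convexity "invariant"

Because $k_t$ grows as the fourth power of size, one expects
$\sum k_t \ge N_t\,k_t(\bar d_{max}, \bar d_{min})$ by Jensen's inequality.
That holds whenever diameters vary by a common scale factor ($k_t \propto
s^4$ is convex in $s$) and it holds on average across needles, but it is
**not** a pointwise theorem: $k_t$ is not jointly convex in
$(d_{max}, d_{min})$, and under the negative flatness–size correlation the
calibration itself demands, a few percent of simulated needles fall
slightly below the bound. The test suite asserts the property in the two
forms in which it is actually true.

## Inference

Each trait is analysed at needle level with
`value ~ canopy * drought + (1 | tree / shoot)` via `lme4::lmer()`. Shoot
identifiers are canopy-qualified so the two crown positions of one tree
never share a shoot group. Fixed effects are tested by likelihood-ratio
ladders on maximum-likelihood fits — interaction:
`canopy*drought` vs `canopy+drought`; drought: `canopy+drought` vs
`canopy`; canopy: `canopy+drought` vs `drought` — each a $\chi^2_1$ test,
with the AIC of both models reported per comparison (published summaries of
this kind print a single AIC per factor without saying which model it
belongs to; printing both removes the ambiguity). Likelihood-ratio
statistics are clamped at zero against sub-10⁻⁸ optimizer noise. Group
means come from the REML fit of the full model.

Deliberate choices, made where published practice is underdetermined:

* **ML for comparisons, REML for reported models** — the standard pairing
  when fixed-effect structures differ between compared models.
* **Wald 95% intervals** (normal approximation, `emmeans` with asymptotic
  degrees of freedom) rather than Satterthwaite-based intervals: portable,
  dependency-light, and differing only slightly at these sample sizes. With
  only three trees per plot the drought contrast's interval is the one most
  affected; treat it accordingly.
* **`k_th` on the log scale**, back-transformed group means flagged
  `geometric`. Only `k_th` is transformed by default; its multiplicative
  assembly (count × fourth-power sizes) makes it the clearly right-skewed
  trait.
* **No multiple-testing adjustment** across the 14 traits: each trait is
  reported per-trait, matching how such tables are conventionally read;
  with 42 tests a reader should expect ≈ 2 nominally significant results
  under the global null.
* **Sap flow**: pooled-variance two-sample two-tailed t-test on per-tree
  season totals (three trees per plot). Accumulated totals, not daily
  values, are taken as the unit of analysis.
* Singular or non-converged fits are flagged in the output
  (`singular`, `converged`) and never silently dropped; with three trees
  per plot, near-zero tree-level variance estimates are common and benign.

### Calibration of the test procedures

The package checks its own inference machinery by simulation, at sizes
chosen so the asymptotic $\chi^2$ reference is meaningful for a factor that
varies at tree level: 30 trees per plot. Under a null calibration (drought
targets set equal to control), the drought test's empirical type-I error
over 500 simulated datasets is ≈ 0.05 with uniform p-values; against the
built-in sun/shade response difference in needle area (−17% vs −3%), the
interaction test's power over 200 replicates is ≈ 1. Parameter recovery is
verified on seed-averaged group means (15 seeds; residual generator bias is
below 0.5%). These sizes are the package's validation design, balancing
Monte Carlo error against runtime.

## The cross-section surrogate

`layout_section()` + `rasterize_section()` + `measure_section()` form a
round-trip harness for the image-measurement step: concentric ellipses with
exactly the needle's areas (needle outline aspect 2.0, vascular/xylem
aspect 1.5), tracheid ellipses placed by dart throwing with rejection on a
4 px/µm occupancy grid (one-pixel clearance guarantees non-overlap), then
pixel-centre rasterization with no anti-aliasing so masks are bit-identical
across platforms. Measured lumen `d_max` is the maximum pairwise
pixel-centre distance and `d_min` the minimal convex-hull caliper width,
each padded by one pixel for the pixel extent — stated explicitly because
image-analysis tools offer several diameter conventions, and where real
lumens are irregular the caliper convention is a choice, not a
reconstruction. Lumens covering fewer than 4 pixels are flagged. At
4 px/µm, section areas round-trip well within 2% and re-measured traits
rank-correlate ≥ 0.95 with their true values; refining the resolution never
worsens the error. The surrogate is optional at runtime — the analysis
pipeline consumes measurement tables directly — and makes no claim about
segmenting real micrographs.

## Limitations

* The reference calibration encodes printed group means; within-group
  dispersion is invented (intervals constrain but do not determine it), so
  simulated p-values are illustrative, not reconstructions of any field
  dataset's inference.
* The elliptical Hagen–Poiseuille value is an upper bound on true
  conductivity; no vulnerability or pit-level modelling is attempted.
* Wald intervals are slightly anticonservative for tree-level contrasts at
  n = 3 trees per plot.
* The aggregate "sun–shade gap shrinkage" style summaries depend on which
  traits one averages over; `results_comparisons()` therefore reports only
  per-trait statistics with their rounding rules attached.
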