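---
title: "Methods: the fuzzy-hybrid PASI index and the sedentarism probit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fuzzy-hybrid PASI index and the sedentarism probit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasindex)
```

## The measurement problem

Physical-activity surveys ask about the same construct — how active a
person is — through items with incompatible answer formats: times per
month, days per week, minutes per day, hours of sitting. The nine items
this package works with (QB1–QB9) come in four formats: a 6-point
times-per-month scale (QB1, QB2), an 8-point days-per-week scale (QB3,
QB5, QB7), a 6-point time-per-day scale (QB4, QB6, QB8) and a 10-point
sitting-time scale (QB9). All are coded so that a **higher code means more
activity** (for sitting, higher codes mean less sitting); no reversal step
exists anywhere in the pipeline, by design.

Two features make naive averaging of the raw codes unattractive: the
scales have different lengths and time bases, and ordinal spacing is not
linear (the jump from "never" to "less than 1–3 times a month" is not the
jump from "3–4 times a week" to "5+ times a week").

## Stage 1: fuzzification and TOPSIS

### Triangular fuzzy numbers

Each ordinal point maps to a fixed triangular fuzzy number
(lower, mode, upper) on the shared universe of discourse [0, 100]; the
dictionary ships as a plain-text lookup table
(`inst/extdata/tfn_scales.csv`) rather than code, so alternative
fuzzification dictionaries can be swapped in for sensitivity analysis.
The registered mappings satisfy three structural properties, asserted in
the test suite over every point of every scale:

* all components lie in [0, 100] with lower ≤ mode ≤ upper;
* centroids are strictly increasing in the ordinal point, so the
  fuzzification preserves order;
* consecutive TFNs overlap (`upper[k] > lower[k+1]`), encoding the genuine
  vagueness of adjacent ordinal categories.

The two 6-point formats (per-month and per-day) deliberately share a
single mapping: they have the same length and the same qualitative
anchors, and a single 6-point dictionary keeps the universe of discourse
interpretation uniform.

Because every cell of the decision matrix already lives on [0, 100], no
separate TOPSIS normalization step is needed.

### Ideal solutions and the closeness coefficient

`defuzzify()` collapses a TFN to its centroid `(l + m + u) / 3` — the
standard choice for triangular shapes; nothing in the pipeline depends on
sub-percent differences between defuzzifiers, and the fully fuzzy distance
mode (below) is available to check that.

The reference set for the ideal solutions is configurable:

* **segment mode (default)**: profiles are the component-wise mean TFNs of
  covariate segments (country × category, age band, …); A⁺/A⁻ per
  indicator are the extrema of the defuzzified profiles, and the attaining
  segment is reported as the "representative". This mirrors published
  ideal-solution tables, where representatives are countries or
  education/social-class segments.
* **individual mode**: the extrema over respondents — the most and least
  active individuals in the sample anchor the index.

Ties in ideal selection are broken by first occurrence in input order and
reported via a message.

Distances are, by default, **crisp**: unweighted Euclidean distance across
the nine centroid-defuzzified indicators between a unit and the A⁺/A⁻
vectors. A **fuzzy** variant (per-indicator vertex distance
`sqrt(((Δl)² + (Δm)² + (Δu)²)/3)` to the fuzzy ideals, aggregated in the
Euclidean sense) is available behind `distance = "fuzzy"` for sensitivity
analysis. Indicator weights are equal throughout.

`PASI = d⁻ / (d⁺ + d⁻)` is exactly 1 at A⁺ and 0 at A⁻. If a unit is
equidistant at zero distance from both ideals (a fully degenerate
reference set) the convention is 0.5, with a warning.

Two properties give the index its interpretation and are tested
exhaustively: PASI stays in [0, 1], and — with ideals held fixed and the
sample spanning the scale endpoints — raising any single item code never
lowers an individual's PASI (monotonicity follows from the strictly
increasing centroids). Note the qualifier: if a respondent could exceed
the positive ideal on an indicator (possible when the reference set does
not contain the scale maximum), the closeness ratio is no longer
guaranteed monotone; the test fixture therefore includes all-minimum and
all-maximum respondents, which is also the realistic situation in any
large survey.

### Quintiles

`quintile_assign()` is rank-based: five groups of n/5, remainder to the
lower quintiles, ties broken by stable input order (with a warning when
tied values straddle a boundary). Quintile 1 collects the most sedentary
fifth and is the outcome of interest in stage 2.

### Missing data

Complete-case deletion: a respondent missing (or out of range on) any of
the nine items is dropped, with the count logged. No survey weights are
applied anywhere; aggregates are unweighted means.

## Stage 2: ordered probit with Daly normalization

The latent model is `y* = x'β + ε`, `ε ~ N(0, 1)`, observed as quintile
`j` when `η_{j−1} < y* ≤ η_j` (η₀ = −∞, η₅ = +∞), giving
`P(y = j | x) = Φ(η_j − x'β) − Φ(η_{j−1} − x'β)` and the usual
multinomial log-likelihood. There is no intercept — it is absorbed into
the thresholds.

### Daly encoding

Each categorical covariate with K categories and sample shares w₁..w_K
contributes K−1 columns: category k < K scores 1 on its own column, the
reference category K scores −w_k/w_K on every column k. The implied
reference coefficient is −Σ_{k<K}(w_k/w_K)β_k, so the share-weighted
coefficients sum to zero *exactly* and each coefficient is a deviation
from the share-weighted average — the "average citizen". Shares are
observed sample shares (no population weights are available or assumed).
The reference category is the last in order of first appearance; the
constraint makes the choice irrelevant for the implied coefficient set.

### Estimation

The likelihood is maximized by BFGS with the analytic score, on a
reparameterized threshold vector (η₁ free, subsequent increments as
exponentials) so ordering holds at every iterate; increments that
underflow to zero during a line search are handled by a finite penalty
rather than an error. BFGS is followed by Newton polishing in the
original (β, η) parameterization — using central finite differences of
the analytic score for the Hessian — until the score norm falls below
1e-8 (the `converged` flag is honest, and non-convergence is a warning,
not an exception). Standard errors come from the inverse observed
Hessian; p-values are two-sided z-tests (no clustering). Probabilities
are floored at 1e-300 inside the log. Starting values are β = 0 with
thresholds at Φ⁻¹ of the cumulative outcome shares — the exact MLE when
β = 0, which is also the closed form the test suite checks with zero
regressors. The ordered probit likelihood is concave, and refits from
dispersed random starts agree to 1e-6 in the test suite;
`MASS::polr(method = "probit")` serves as an independent cross-check of
the optimum (run at tightened optimizer tolerance, since its defaults
stop ~1e-6 short).

### Marginal effects

The effect of a category on the most-sedentary outcome is the **average
discrete change**: over the estimation sample, the covariate's encoded
columns are switched from all-zero (the Daly average citizen) to the
category's encoding, and the change in `P(y = 1)` is averaged, reported
in percentage points. Averaging over the sample (rather than evaluating
at covariate means) is the more robust convention for nonlinear models
and is recorded in the output. Standard errors are delta-method over the
full (β, η) covariance. Because the index shift is constant across rows,
the sign of an effect is exactly opposite to the sign of the category's
implied coefficient, and effects across the five outcomes sum to zero
identically — both are tested at 1e-10. Significance flags: `***`
p < 0.001, `**` p < 0.01, `*` p < 0.05, `.` p < 0.1.

## The synthetic-data generator

`generate()` emulates the structure — not the margins — of an EU-wide
activity survey. Each respondent draws covariate categories from
configured shares; a latent activity propensity is the sum of the segment
effects plus N(0, trait_sd) noise; each item's code is obtained by
thresholding loading × trait + N(0, noise_sd) against item-specific
strictly increasing cut points, clamped to the scale range. All loadings
are positive, matching the direction alignment of the real items. Default
cut points are quantile-spaced on the implied latent-signal distribution
so every ordinal category is populated. The defaults are unit loadings,
item noise SD 0.8 and trait SD 1 — item noise a bit smaller than the
trait signal, which yields inter-item correlations in the range typical
of activity batteries.

One master seed drives per-component substreams (covariate draws, trait
noise, per-item noise), so regeneration is deterministic and individual
components can be varied independently.

`make_eu_like_config()` encodes the qualitative gradients such surveys
show: 27 country labels with a monotone South-to-North effect gradient
(−0.9 to +0.9 trait SDs), seven age bands with activity declining in age,
and education, social-class and life-satisfaction gradients, with
realistic category shares. The configured effects are returned as ground
truth, so ordering checks (does the top-configured country get the top
segment PASI? is the youngest band above the oldest?) are exact.

`generate_probit_data()` simulates from the ordered probit itself
(latent draw, threshold mapping) for exact parameter-recovery testing.

**What passing tests do not show.** The generator is unidimensional by
construction — one latent propensity drives all nine items — which is
exactly the situation a unidimensional synthetic index assumes. Real
survey data have multidimensional structure (sitting time correlates
imperfectly with sport frequency), item-specific response styles, and
informative missingness, none of which are emulated. Tests passing on
synthetic data validate the *pipeline arithmetic and its contracts*, not
the substantive fit of a one-factor model to any real population. For the
same reason the package makes no claim to reproduce published
segment-PASI values or marginal effects estimated on real microdata; only
the percentage-variation column of the ideal-solutions table is
recomputable from published numbers, and it is.

## Problem sizes and numerical tolerances

The test suite exercises: oracle equivalence of the TOPSIS stage on 200
random small matrices at 1e-12; an exhaustive monotonicity sweep on a
20-respondent fixture; parameter recovery at n = 5000 (each estimate
within 3 SEs of truth; 100-replicate bias of each coefficient below
0.05); the zero-regressor closed form at 1e-6; Daly and adding-up
identities at 1e-10; and qualitative gradient recovery on an EU-like run
at n = 20,000 — sizes chosen so each property is measured with comfortable
Monte-Carlo margin while the whole suite stays in well under a minute.

The null check (all segment effects zero) uses a configuration with two
four-category equal-share covariates at n = 20,000, i.e. ~5,000
respondents per segment, and individual-mode ideals: with fixed external
anchors and adequately sized segments, spurious segment-PASI spread stays
below 0.02. Two caveats are intrinsic rather than fixable: small segments
(a few hundred respondents) carry Monte-Carlo spread of a few hundredths
on the PASI scale, and *segment-mode* ideals are a relative ranking device
— under a true null they amplify noise by construction (the ideals are
the extrema of the noisy segments themselves), so segment-mode PASI
differences should only be read against segment sizes, as with any
rank-based indicator.

## Known limitations

* The fuzzification dictionary is fixed per scale; the package supports
  swapping dictionaries but provides no fitting of TFN parameters.
* The probit assumes independent observations; no clustered or robust
  standard errors (country-clustered SEs would be the natural extension).
* Complete-case deletion is the only missing-data policy.
* No survey weighting; all aggregates are unweighted.
* Segment-mode ideal solutions depend on which covariates define the
  segment set; adding a covariate with extreme small segments can move
  A⁺/A⁻ and hence every PASI value. The run log records the segmentation
  used.
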