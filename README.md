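# pasindex

Physical inactivity is one of the main modifiable risk factors for chronic
disease, and EU-wide surveys measure it with batteries of ordinal items —
how often people play sport, how many days they did vigorous or moderate
activity, how long they walk, how long they sit. `pasindex` is an R toolkit
for analysts who want to turn such heterogeneous ordinal batteries into a
single **Physical Activity Synthetic Indicator (PASI)** and then model who
ends up sedentary.

The package implements a two-stage analysis:

1. **Fuzzy-hybrid TOPSIS.** Each ordinal answer is converted to a
   triangular fuzzy number (TFN) on a common universe of discourse
   \[0, 100\], which makes 6-, 8- and 10-point scales with different time
   frames comparable and softens the non-linear spacing of ordinal
   categories. Respondents (or population segments) are scored by their
   TOPSIS closeness coefficient

   `PASI = d⁻ / (d⁺ + d⁻)`,

   where `d⁺` and `d⁻` are distances across the nine indicators to the
   positive ideal solution A⁺ (the most active reference unit per
   indicator) and the negative ideal solution A⁻ (the least active). PASI
   is 1 at A⁺, 0 at A⁻.

2. **Ordered probit on PASI quintiles.** The PASI distribution is split
   into quintiles (quintile 1 = most sedentary) and modelled with a
   hand-coded maximum-likelihood ordered probit, `y* = x'β + ε`,
   `ε ~ N(0,1)`, with thresholds `η₁ < η₂ < η₃ < η₄`. Categorical
   covariates use the **Daly normalization** (share-weighted sum-to-zero
   coefficients), so every coefficient and marginal effect reads as a
   deviation from the *average citizen*. Marginal effects on
   `P(quintile = 1)` classify categories as drivers or barriers of
   sedentarism.

A synthetic-microdata generator with known ground truth (latent activity
propensity + segment effects + thresholded item responses) makes the whole
pipeline testable without access to survey microdata.

## Worked example

```r
library(pasindex)

## EU-like synthetic survey: 27 countries with a South-North activity
## gradient, age/education/class/satisfaction effects, known ground truth
ds  <- generate(make_eu_like_config(n = 5000, seed = 42))
fdm <- build_decision_matrix(ds$records)        # fuzzify the 9 items

profiles <- segment_profiles(fdm, c("country", "age"))
ideals   <- ideal_solutions(profiles)           # A+ / A- per indicator
head(as.data.frame(ideals), 3)
#>   item_id   a_plus              rep_plus  a_minus              rep_minus
#> 1     QB1 68.65000 country: DK - Denmark 34.00000   country: PL - Poland
#> 2     QB2 70.48193 country: FI - Finland 31.62651 country: PT - Portugal
#> 3     QB3 69.34167 country: DK - Denmark 34.60000   country: PL - Poland

segs <- pasi_segment(profiles, ideals)
head(segs[order(-segs$pasi), c("segment", "n", "pasi")], 4)
#>                          segment   n      pasi
#> 11         country: DK - Denmark 200 0.9748329
#> 12         country: FI - Finland 166 0.9489570
#> 1  country: NL - The Netherlands 182 0.9239763
#> 16          country: SE - Sweden 208 0.8949970

## quintiles + Daly-normalized ordered probit + marginal effects
indiv  <- pasi_individual(fdm, ideals)
q      <- quintile_assign(indiv$pasi)
design <- daly_encode(fdm$covariates,
                      daly_spec(fdm$covariates, c("country", "age")))
fit    <- fit_ordered_probit(design, q)
head(marginal_effects_table(fit)[, c("category", "effect_pp", "stars", "role")], 5)
#>         category effect_pp stars   role
#> 2    PL - Poland  24.87716   *** driver
#> 21   GR - Greece  22.62262   *** driver
#> 17 PT - Portugal  20.97784   *** driver
#> 5     IT - Italy  17.20293   *** driver
#> 19    MT - Malta  16.38179   *** driver
```

Reading the output: Nordic countries sit closest to the positive ideal
(PASI near 1), Southern/Eastern countries closest to the negative ideal —
the gradient the generator was configured with. A marginal effect of
+24.9 pp for Poland means that, all else at the average-citizen reference,
being Polish raises the probability of landing in the most-sedentary PASI
quintile by 24.9 percentage points (`***` = p < 0.001).

`run_pipeline(pipeline_config(...))` wraps all of the above and writes
`ideal_solutions.csv`, `segment_pasi.csv`, `marginal_effects.csv` and a
settings log; re-running the same config reproduces the files
bit-identically.

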