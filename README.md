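# pmvcal

Thermal-comfort analysis of field surveys with the Fanger heat-balance
model: per-respondent calibration of the metabolic rate against thermal
sensation votes, and affine extension of the PMV index with the running
mean outdoor temperature (RMOT).

## The problem

Indoor-comfort standards predict the mean thermal sensation of a
population with the Predicted Mean Vote (PMV), a heat-balance index
computed from air and radiant temperature, humidity, air speed, clothing
insulation and metabolic rate:

```
PMV = (0.303 e^{-0.036 M} + 0.028) · L(M, W, I_cl, t_a, t_r, p_a, v)
```

where `L` is the thermal load on the body (internal production minus the
six standard loss terms) and the clothing surface temperature inside `L`
solves an implicit balance equation. Two of the inputs — clothing and
especially the metabolic rate `M` — are in practice taken from activity
tables that ignore who the occupants are. But basal metabolic rate falls
with age and differs between sexes (Harris–Benedict/Roza–Shizgal
equations; DuBois surface area), so a venue visited mostly by elderly
females should not be modelled with a young-male metabolic rate.

This package implements, for survey campaigns in climate-controlled
public venues:

* a forward **PMV/PPD engine** (iterative clothing-temperature solution,
  vectorised over respondents);
* **anthropometric metabolic-rate prediction** (`bmr_watts()`,
  `one_met_equivalent_wm2()`): the heat equivalent of 1 Met is ~58 W/m²
  for a young adult male but ~51 W/m² for his female counterpart, and
  ~9 % lower again for the elderly;
* **inverse calibration**: for every respondent, the metabolic rate that
  makes PMV equal their thermal sensation vote (`calibrate_cohort()`),
  with median-based subgroup comparison (Wilcoxon rank-sum,
  `compare_age_groups()`);
* the **running mean outdoor temperature**
  `RMOT = (T_i + 0.8 T_{i-1} + 0.4 T_{i-2} + 0.2 T_{i-3}) / 2.4` and the
  extended predictors `PMV* = PMV_met + b·RMOT + c` (adaptive-comfort
  correction) and `PMV** = PMV* + b'·Preference + c'` (diagnostic);
* a **synthetic survey-campaign generator** with known ground truth
  (`simulate_campaign()`), so every stage of the analysis can be tested
  for parameter recovery.

## Worked example

```r
library(pmvcal)

camp <- simulate_campaign(seed = 1)   # 1,121 respondents, 35 survey days
res  <- run_comfort_pipeline(camp$survey, camp$indoor, camp$outdoor)
print(res)
```

```
Thermal-sensation analysis of 1121 respondents over 35 survey days

Median calibrated metabolic rate: 88.1 W/m2 (1.51 Met)

AMV ~ PMV   (a-priori Met):   Actual = 1.294 Predicted -0.145   (R2 = 0.93, n = 35)
  slope 95% CI: 1.164 to 1.423, p = 3.15e-20
AMV ~ PMV_met (median Met):   Actual = 1.305 Predicted -0.171   (R2 = 0.93, n = 35)
  slope 95% CI: 1.174 to 1.436, p = 3.47e-20
AMV ~ PMV*  (RMOT-extended):  Actual = 1.036 Predicted -0.016   (R2 = 0.98, n = 35)
  slope 95% CI: 0.986 to 1.087, p = 3.08e-30
AMV ~ PMV** (+ preference):   Actual = 0.986 Predicted +0.006   (R2 = 0.98, n = 35)
  slope 95% CI: 0.940 to 1.031, p = 6.86e-31

Extended PMV model (fitted on 35 survey days)
  PMV*  = PMV_met -0.0266 RMOT +0.2734
  PMV** = PMV*  -0.0546 Preference -0.0211

Subpopulation comparison of calibrated metabolic rates
  male   adult 99 W/m2 (n=60) vs elderly 91 W/m2 (n=128): +8.3%, p=0.0153 *
  female adult 87 W/m2 (n=50) vs elderly 82 W/m2 (n=224): +6.2%, p=0.015 *
```

Reading this output: the identity regression of the actual mean votes
(AMV, daily means of the sensation votes) on the plain PMV has a slope
well above 1 — the model under-predicts the more extreme sensations.
The daily prediction errors correlate strongly with the RMOT
(r ≈ −0.92 before extension); regressing them on RMOT and folding the
fitted affine correction into PMV* brings the slope to ~1 and raises R².
The calibrated metabolic rates recover the generator's built-in
age effect: adults' median rates are higher than the elderly's for both
genders, both differences significant by rank-sum test. The cohort
median (1.51 Met) sits close to the usual a-priori museum assumption of
1.5 Met precisely because the simulated venue is dominated by elderly
females.

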