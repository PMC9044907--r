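---
title: "Predicting long-term drug effects from short-term risk-marker changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting long-term drug effects from short-term risk-marker changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cardiovascular and kidney outcome trials take years and thousands of
patients. Drugs such as GLP1 receptor agonists, however, change a panel of
routine risk markers — glycated hemoglobin (HbA1c), systolic blood
pressure, urinary albumin-creatinine ratio (UACR), body weight,
hemoglobin, HDL and LDL cholesterol, serum potassium — within months. A
*Parameter Response Efficacy* (PRE) score turns those short-term,
placebo-corrected marker changes into a prediction of the drug's long-term
relative risk reduction (RRR) on clinical composite outcomes, by borrowing
the marker–outcome dose–response relations from an independent
*background* cohort.

`prescore` implements the full pipeline — synthetic-data generation with
known ground truth, chained-equation imputation of missing follow-up
measurements, Cox model estimation, coefficient transfer with bootstrap
uncertainty, and responder-enrichment trial simulation — so that every
stage can be validated end to end without access to any proprietary trial
data.

## The model

On the background cohort, a multivariable Cox proportional hazards model
relates the eight markers (UACR on the natural-log scale, everything else
on its native scale) to each composite outcome:

$$ h(t \mid x) = h_0(t) \, e^{\sum_i \beta_i (x_i - \bar x_i)} , $$

with the Breslow estimator for the baseline cumulative hazard $H_0(t)$.
Covariates are centred at the background-cohort means, so $e^{lp}$ is a
relative hazard against the average background patient — this keeps
$H_0$ interpretable and the exponentials numerically bounded; the
centring constant cancels from every risk *ratio*. The absolute event
probability by horizon $h$ is

$$ F(h \mid x) = 1 - \exp\{-H_0(h)\, e^{lp(x)}\}. $$

Transferring to a two-arm trial, every patient's risk is predicted twice —
from baseline markers and from follow-up markers — and averaged per arm.
With relative changes $\Delta_{arm} = (\bar R_{fu} - \bar R_{bl}) / \bar
R_{bl}$, the score reports

$$ \mathrm{RRR} = -100\,(\Delta_{treat} - \Delta_{placebo}). $$

The placebo arm's predicted change absorbs drift and regression-like
artefacts shared by both arms, so the score is exactly zero when no
markers change and is invariant to any change applied identically to both
arms. The wording "adjusted for the placebo arm" is ambiguous between
this difference of relative changes and a ratio form
$100\,(1 - (1+\Delta_{treat})/(1+\Delta_{placebo}))$; the difference form
is the default because it is exactly null-invariant, and the ratio form is
available via `form = "ratio"` for sensitivity analysis. When follow-up
noise or drift inflates both arms' predicted risks, the difference form is
anchored to the *baseline* mean risk while the ratio form is anchored to
the placebo arm's follow-up risk; the two coincide in the rare-event,
low-drift regime.

Confidence intervals follow the parametric bootstrap used in this
literature: 100 coefficient vectors are drawn with each component an
independent Normal centred at $\hat\beta_i$ with its standard error, the
RRR is recomputed per draw with $H_0$ and the centring fixed, and the
2.5th/97.5th percentiles are reported (inverse-ECDF quantiles, so two
draws give their range). A multivariate-normal draw using the full
coefficient covariance — statistically preferable but not what the
independent-normal convention specifies — sits behind `mvnormal = TRUE`.

## What the generator emulates — and what it does not

`sim_config()` + `generate_background_cohort()` / `generate_trial()`
produce data with *known* truth:

* **Marginals.** Baseline markers follow a Gaussian copula with the
  published-style marginals of the two populations: a heavily albuminuric
  background pool (median UACR ≈ 277 mg/g, eGFR ≈ 51) and a lower-risk
  trial population (median UACR ≈ 25 mg/g, eGFR ≈ 79). UACR is
  log-normal; its log-scale SD (≈ 2.25–2.29) comes from the published
  interquartile ranges.
* **Correlation.** The sources report only marginals, so the default
  cross-marker correlation is a weak exchangeable 0.1, fully
  configurable. eGFR (an auxiliary covariate used only by inclusion
  filters) is negatively correlated (−0.4) with log-UACR so that
  albuminuria-based subsets are also low-eGFR subsets.
* **Treatment effects.** Follow-up = baseline + placebo drift + (treatment
  shift, treatment arm only) + noise, on the transform scale. The default
  shifts are the placebo-corrected 6-month effects reported for
  liraglutide: HbA1c −1.4%, systolic BP −3.0 mmHg, UACR −13.2%
  (log-scale shift $\log 0.868$), weight −2.3 kg, hemoglobin −2.6 g/L,
  HDL +0.01 mmol/L; LDL and potassium unshifted.
* **Follow-up noise.** Default SD is half the baseline SD, except where
  the cross-sectional SD mostly reflects between-patient heterogeneity
  rather than within-patient variability: log-UACR noise is 0.45 (≈ 45%
  typical visit-to-visit fluctuation) and weight noise is 3.5 kg. Without
  this distinction, half the UACR cross-sectional SD would imply 3-fold
  random within-patient swings and inflate both arms' follow-up risks far
  beyond anything seen in real cohorts.
* **Outcomes.** Event times are Weibull proportional hazards (shape 1 =
  exponential by default) driven by the *follow-up* linear predictor
  under configured true betas, so the treatment effect on outcomes is
  purely marker-mediated — exactly the quantity a coefficient-transfer
  score should recover. `direct_effect` adds a hazard multiplier the
  markers cannot see, reproducing qualitatively the situation where a
  score underestimates an observed benefit. Baseline hazard rates were
  calibrated once so the default background cohort shows ≈ 17.8% kidney
  and ≈ 12.5% cardiovascular events and the default trial ≈ 2.5% and
  ≈ 13.9% over ~4 years.
* **True betas.** Not reported by the sources; chosen once on domain
  grounds — log-UACR dominant for the kidney outcome (β = 1.0 per log
  unit, i.e. a strongly albuminuria-driven composite), glycemia and blood
  pressure relatively more important for the cardiovascular outcome — and
  sized so the single-marker and integrated predicted RRRs have the
  magnitudes reported for GLP1-RA trials (kidney: UACR-only ≈ 13%,
  HbA1c-only ≈ 2–3%, integrated ≈ 14–16%).

Deliberately *not* emulated: longitudinal multi-visit trajectories (the
staggered availability of some markers is represented only as follow-up
missingness), competing risks, informative censoring, non-proportional
hazards, and the real trials' covariance structure. Passing tests
therefore show that the machinery is correct under a proportional-hazards,
marker-mediated world — not that the score is unbiased on any particular
real dataset.

## Missing data

`impute_pmm()` is standard chained-equation imputation with predictive
mean matching: each incomplete variable is regressed (transform scale) on
all other marker columns plus the arm indicator; regression parameters are
drawn from their Bayesian posterior; each missing cell receives the
observed value of one of the `k_donors = 5` donors whose predicted means
are closest (type-1 matching, uniform tie-break under the seeded
generator). Variables are visited in increasing order of missingness.
Because imputations are observed donor values, they respect positivity and
skewness — the reason PMM suits UACR, which is imputed on the log scale.
`m = 5` completed datasets are produced (the convention adopted here; the
source does not state `m`), downstream RRRs are averaged across
imputations, and bootstrap draws are pooled for the interval — simple
averaging, documented as this package's convention, rather than
Rubin's-rules pooling of variances, which the percentile-CI construction
does not support directly.

The source material validates imputation only "visually"; this package
substitutes two quantitative checks: a Kolmogorov–Smirnov comparison of
imputed versus masked-true values, and a mask-and-recover comparison of
the downstream pooled RRR against the complete-data RRR (run on the
cardiovascular outcome, where the comparison's own Monte-Carlo noise —
about ±0.5 points — is well inside the ±1.5-point band; the kidney
functional is dominated by the log-UACR tail and its sampling noise at
feasible trial sizes is of the same order as the band, so a single-seed
kidney comparison would measure seed luck, not imputation quality).

## Scenario simulation

`classify_responders()` applies the median split: a treatment-arm patient
responds when their marker *reduction* (transform scale) is at least the
arm's median reduction — so ties can push the fraction above one half, and
if every change is identical, everyone responds.
`shift_response_distribution()` resamples the treatment arm with
replacement within responder strata so a fraction `p` responds, keeping
the arm size and schema fixed and the placebo arm untouched (the sources
do not state how patients are "selected"; stratified resampling is the
seedable choice that keeps n constant). Resampling the whole patient
record means correlated markers shift together.
`simulate_rrr_curve()` traces the rescored RRR against the realized
placebo-corrected change, and `required_change_for_target()` inverts the
curve by linear interpolation, returning the smallest change achieving a
target RRR (for log markers, reported as a percent reduction,
$100(1-e^{\Delta})$). Inclusion criteria are configuration data;
`flow_criteria()` ships a documented assumption (eGFR 25–75 ml/min/1.73m²
and baseline UACR 100–5000 mg/g) emulating a dedicated kidney-trial entry
window, since the real criteria are not in the main text of the sources.
Enrichment is simulated one marker at a time; a joint multi-marker shift
is deliberately out of scope.

## Numerical choices and edge cases

* Cox fitting uses Efron tie handling; the generator's continuous times
  make Breslow and Efron coincide, which is what lets a brute-force
  risk-set oracle check the baseline hazard to machine precision.
* `predict_risk()` refuses horizons beyond the last observed time (no
  extrapolation) and nonpositive values for log-scale markers.
* Degenerate standard errors give point-mass draws; `n_draws = 2` yields
  the min/max interval; identical seeds reproduce every output
  byte-for-byte.
* A collinearity warning is recorded on the fit when the scaled covariate
  cross-product's condition number exceeds `1e6`.
* The default risk horizon is 3.5 years, inside the ~3.8-year follow-up
  the default trial emulates. Under proportional hazards the RRR is
  horizon-insensitive to first order in the rare-event, homogeneous-risk
  regime (the CV score moves < 0.4 points across 1–3.8 years); strong
  risk heterogeneity lets high-risk patients saturate ($F \to 1$), so the
  kidney score drifts mildly (≈ 3 points) with horizon. This is a
  property of absolute-risk averaging, not an implementation artefact.

## Validation design

The study-scale experiments the test suite runs (sizes chosen as the
package's validation conditions):

* Cox recovery on a 20,000-patient background cohort — every coefficient
  within 3 SE of truth.
* End-to-end: 10 replicate trials of 4,500/arm; the mean integrated
  kidney RRR is compared within ±2 points against the generator's
  closed-form counterfactual truth (`true_rrr()`, 10⁶ Monte-Carlo
  patients). Two truth conventions exist — risk difference relative to
  the counterfactual rate, or relative to the baseline mean risk; the
  latter is the difference-form estimand and is the default reference.
* Coverage: 200 replicates of a 6,355-patient background with a 500/arm
  trial. The percentile CI models coefficient uncertainty only (baseline
  hazard and centring held fixed, per the construction above), so it is
  evaluated against the RRR obtained by pushing the *true* coefficients
  through the same transfer — computed by an independent per-patient
  arithmetic loop. Coverage lands near 0.97, within the 90–99% band that
  the 100-draw percentile granularity allows.
* Imputation mask-and-recover at 30% MCAR on two markers, 1,500/arm,
  m = 5, on the CV outcome (see above).
* The direct-effect contrast uses 20,000/arm with a ~7% kidney event rate,
  averaged over three seeds: at the realistic 2.5% rate the observed
  kidney RRR carries a sampling SE of ~13 points (mirroring the very wide
  observed CIs such comparisons have in practice) and supports no
  quantitative "matched" claim, while at much higher rates risk
  saturation dilutes the observed RRR relative to a baseline-anchored
  prediction.

## Known limitations

The score inherits the background model: markers missing from the panel
(inflammation, natriuresis, endothelial function) make a real direct
benefit invisible, which is exactly the CV-underestimation pattern the
direct-effect simulation reproduces. The independent-normal bootstrap
ignores coefficient correlations; the multivariate option exists but is
not the default convention. Pooling across imputations by averaging
understates between-imputation variance relative to Rubin's rules. The
generator's Gaussian copula and exchangeable correlation are conventions,
not estimates; nothing here should be read as a re-analysis of any real
trial.
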