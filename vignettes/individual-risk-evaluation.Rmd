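---
title: "Evaluating cardiovascular risk scores at the individual level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating cardiovascular risk scores at the individual level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cox-form 10-year cardiovascular risk scores — the Framingham, ASSIGN and
QRISK2 family — are validated almost exclusively on population averages:
observed versus predicted event rates in broad risk groups. Averages can hide
large disagreements about *individual* people, and clinical decisions (statin
initiation at a fixed threshold such as a 20% 10-year risk) are made about
individuals. riskconcord implements the individual-level evaluation: it
estimates each person's 10-year risk of a first cardiovascular (CVD) event
from a competing-risk regression fitted to the cohort itself, evaluates any
number of published-style risk scores on the same people, and tabulates where
and by how much the two disagree.

Real primary-care research databases of this kind are access-restricted, so
the package ships a synthetic cohort generator with known ground truth. The
generator defines the study conditions; every downstream stage is exercised
and tested against analytic oracles on data the generator produced.

## The models

### Risk-score engine

Every score in the family has the form

$$\text{risk} = 1 - S_0(t)^{\exp(L)}, \qquad
  L = \sum_j \beta_j\,\{g_j(x_j) - g_j(\bar x_j)\},$$

with $t = 10$ years, sex-specific baseline survival $S_0(t)$, and transformed,
centred covariates. `load_score_spec()` reads $\beta$, the centring constants
$\bar x$, $S_0$ and the term grammar (identity/log transforms, categorical
levels, age-by-covariate interactions, per-sex terms) from a JSON file, so the
engine carries no hard-coded coefficients. The three shipped spec files are
*synthetic fixtures* shaped like each family — the exact published
coefficient sets are not reproduced here (QRISK2's 2012 release is
commercial), and every test that touches them treats them as fixtures, never
as the published scores. A reparameterisation invariance (centring constants
can be absorbed into $S_0$ without changing any risk) is asserted in the test
suite.

Missing covariates at evaluation time follow a per-covariate `missing_policy`
(substitute a default, or reject the person into an explicit rejects table).
In the full pipeline scores are evaluated on multiply-imputed data, so the
policy only catches strays; unknown smoking maps to never-smoker by default.

### Competing-risk individual risk

The reference for "the person's actual risk" is a pair of cause-specific
proportional-hazards models — one for CVD, one for death from other causes,
the competing event that can preclude CVD. Each is a Cox partial-likelihood
fit (Efron tie handling; day-resolution synthetic data produce many ties) with
the Breslow baseline cumulative hazard anchored at the fitted covariate means.
The absolute risk is the product-integral cumulative incidence

$$F_{\text{cvd}}(t \mid x) = \sum_{u \le t} S(u^- \mid x)\,
  \Delta H_{\text{cvd}}(u \mid x), \qquad
  S(u^- \mid x) = \prod_{v < u} \bigl\{1 - \Delta H_{\text{cvd}}(v \mid x)
  - \Delta H_{\text{death}}(v \mid x)\bigr\}.$$

We use the discrete product-limit form of $S$ rather than
$\exp\{-H(u^-)\}$ because it conserves
$F_{\text{cvd}} + F_{\text{death}} + S = 1$ exactly at every event time (the
test suite asserts this to $10^{-12}$), and because it makes the
no-covariate fit reduce exactly to the nonparametric Aalen–Johansen estimate.
The two forms differ only at second order in the hazard increments.

Two numerical details. First, a person-specific discrete hazard mass
$\Delta H \,e^{\hat\beta' z}$ can exceed 1 for extreme covariates; it is
capped at 1 (the probability interpretation) rather than allowed to drive the
survival factor negative. Second, on large cohorts the merged event-time grid
is coarsened to at most `max_steps` bins (default 1024) by summing increments
within bins; the error is second-order and measured at under $5\times10^{-4}$
on a cohort with ~1,300 distinct event times, while small fits (below
`max_steps` distinct times) are computed exactly. A horizon beyond the last
observed event time holds the cumulative hazard at its last step and flags
the prediction `extrapolated`.

Continuous covariates can enter through fractional polynomials with powers
from $\{-2,-1,-0.5,0,0.5,1,2,3\}$ (0 meaning $\log$, a repeated power $(p,p)$
meaning $x^p$ and $x^p\log x$). `select_fractional_polynomial()` runs the
standard closed test — best FP2 against no effect (4 df), against linear
(3 df), then against best FP1 (2 df), each at $\alpha = 0.05$ — and returns
the simplest adequate transform. On data simulated with an exactly linear
log-hazard the test keeps "linear" at roughly the nominal rate (asserted at
$\ge 85\%$ over 30 replicates of $n = 4000$, sizes chosen so the whole suite
stays quick).

Covariates with no variation, or binary indicators whose exposed group has no
events (monotone likelihood, formally infinite hazard ratio), are dropped with
a warning and reported with coefficient zero — at desk-scale cohort sizes this
is routine for rare comorbidities. `default_cr_covariates("desk")` therefore
omits the rarest flags; `"full"` is the complete roster. The regression can be
fitted as one model or separately by sex and three age groups (35–49 / 50–59 /
60–74 by default; the cut points are configurable because only the *number* of
groups is conventional).

### Multiple imputation

Smoking status, systolic blood pressure, cholesterol/HDL ratio and BMI are
imputed by chained equations: Bayesian linear-regression draws (posterior
$\sigma^2$, then $\beta$, then noise) for the continuous targets, a
multinomial-regression draw for smoking, with predictive-mean matching
available for continuous targets when implausible values must be avoided. The
predictor set is the full risk-factor roster plus CVD occurrence, non-CVD
death, follow-up time, and the event-by-time interactions — outcome
information belongs in imputation models used for survival analysis. Five
completed datasets and ten burn-in cycles per chain are the defaults (m = 5 is
the convention for this family of analyses; ten cycles is the standard chained
equations default, and a per-cycle trace of imputed means is retained for
convergence checking). Observed values are never altered — asserted
bit-exactly. The multinomial draw conditions on the fitted class probabilities
without redrawing the multinomial coefficients, a standard shortcut that
slightly understates between-imputation variance for smoking; the continuous
draws are fully Bayesian, and the nominal-coverage property test (95% CIs for
a mean under MCAR covering at 92–98% across 200 replicates) runs the
package's own chains end to end.

Pooling follows Rubin's rules: $\bar Q$, $\bar W$, $B$,
$T = \bar W + (1 + 1/m)B$, small-sample degrees of freedom, t-based 95%
intervals. Per-person risks are pooled as arithmetic means; count and
percentage tables are instead computed per imputed dataset and averaged, which
is also the default for the report builder (`pooling = "per_dataset_average"`
is recorded in the report metadata).

### Agreement analytics

* **ICC.** Pairwise intraclass correlation, two-way absolute-agreement
  single-measure (McGraw–Wong ICC(A,1)), computed from the mean squares of the
  persons-by-methods layout. Absolute agreement is the right variant when a
  fixed treatment threshold is applied to either method: a systematic offset
  is a real disagreement even when Pearson correlation is 1, and the tests
  assert exactly that contrast.
* **Difference bands.** Differences in percentage points binned into
  $(-\infty,-10]$, $(-10,-5]$, $(-5,-2]$, $(-2,+2)$, $[+2,+5)$, $[+5,+10)$,
  $[+10,\infty)$. Published table headers of this kind are ambiguous about
  edge membership; these half-open bins are exactly anti-symmetric under
  swapping the two methods, which the suite asserts.
* **Vigintile calibration.** Persons ranked by predicted risk into 20
  equal-frequency groups (stable tie-break on person id; group sizes within
  1), mean predicted risk against the Aalen–Johansen observed cumulative
  incidence and its standard error per group, plus the per-vigintile band
  profile of each score against the competing-risk prediction.
* **Threshold consistency and case capture.** For each method as reference at
  the $\ge 20\%$ (high) and $< 15\%$ (low) thresholds: among its positives,
  how many of the other methods agree. For persons who went on to a CVD event:
  the distribution of their index-date predictions over $[0,10)$, $[10,15)$,
  $[15,20)$, $[20,100]$ percentage-point bins (left-closed, so exactly 15%
  falls in 15–20).
* **Bias analyses.** Age- and sex-adjusted rate ratios of CVD by calendar year
  of the index date (the secular trend a fixed risk equation cannot follow),
  and adjusted hazard ratios comparing people with missing versus measured
  values of each risk factor (a direct check on the missing-at-random premise
  of the imputation).

Percentages are reported at full precision internally; `round_percent_100()`
applies largest-remainder rounding at one decimal when tables are printed so
every row still sums to exactly 100.

## The synthetic cohort and what it does (not) show

`generate_cohort()` draws covariates from marginals loosely matched to a large
UK primary-care population (about half missing ethnicity, a quarter in the
most deprived quintile, mean SBP 130 mmHg, and so on — fixtures, not
estimates), assigns each person a registration window, an administrative end
of data collection, and a random index date drawn uniformly over the days of
the eligible window (one year after registration or 1998-01-01, whichever is
later, to the end of data collection; the per-person draw is hashed from the
person id so it is reproducible independent of cohort order).

Ground truth is a pair of cause-specific hazards
$h_k(t\mid x) = h_{0k}(t)\exp(\beta_k'x + \gamma_k\,\text{calendar})$ with
piecewise-constant baselines. Event times are simulated by inverting the
all-cause cumulative hazard and assigning the cause with probability
$h_k/\sum h$ at the drawn time — exact for piecewise-constant hazards, which
is why closed-form oracles exist: the stored per-person 10-year cumulative
incidence equals the analytic value exactly, and with constant hazards
$\lambda_1 = 0.02$, $\lambda_2 = 0.01$ the population value is
$(\lambda_1/(\lambda_1+\lambda_2))\{1 - e^{-(\lambda_1+\lambda_2)10}\}
= 0.1727879$, which the fitted pipeline must reproduce within $\pm 0.003$ at
$n = 100{,}000$. Calendar year enters as a per-year log rate ratio (default
$-0.04$ for CVD, so 2010 versus 1998 is $e^{-0.48} \approx 0.62$), giving the
secular-trend analysis a known answer. Censoring combines the administrative
end of records with exponential statin initiation (follow-up is censored at a
first statin prescription, since initiation changes the risk being predicted).

Missingness is injected by per-variable logistic models with a logit intercept
anchored at 1998 and a per-year slope (defaults anchored to observed 1998 and
2010 missing fractions for each variable: BMI 47.3% → 32.7%, smoking 47.3% →
14.3%, SBP 33.4% → 22.3%, cholesterol ratio 97.8% → 72.2%). Informative
missingness is modelled by a latent *non-attender* trait that both multiplies
the CVD hazard by $e^{0.5}$ (configurable) and drives the missingness — people
whose risk factors were never measured are people who rarely see their
practice, and are at different risk. This construction makes the
imputed-versus-measured hazard ratio analytically equal to the configured
value, so the bias analysis has an exact target; a variant that shifts the
missingness log-odds by the latent event indicator is also available.

What passing tests on this cohort do **not** show: the generator draws
covariates independently (no age–SBP correlation unless a test constructs
one), has no practice-level clustering, no longitudinal consultation
histories, no coding drift, and its "scores" are fixtures rather than the
published equations. Results on synthetic data validate the *machinery* —
estimators against oracles, recovery of known parameters, directional
signatures — not the clinical performance of any real score.

## Design choices where the design was open

* **Cause-specific hazards, not subdistribution regression.** Absolute risks
  are predicted from the two cause-specific fits via the product integral;
  this composes naturally with per-cause modelling and reduces to
  Aalen–Johansen nonparametrically. Fine–Gray subdistribution fits answer a
  different question and are not implemented.
* **Dates are whole days**; "one year after" is the same month/day next year
  with Feb 29 clamped to Feb 28. Ties among terminal events resolve CVD >
  death > censoring, so a same-day CVD event is still captured as an event.
  A person with a CVD event *on* the index date is excluded (strictly
  prior-or-same-day), since a risk assessment on the day of the event is not a
  prediction.
* **Consultation counts** are banded 0 / 1–3 / 4–8 / 9–18 / 19–49 / 50+ for
  tabulation and enter the regression as $\log(1 + \text{count})$.
* **Desk-scale problem sizes.** The test suite runs the oracle simulations at
  $n$ between 20,000 and 200,000 where the property demands it and at a few
  thousand elsewhere; the pipeline smoke runs use $n \approx 1{,}200$–$8{,}000$
  with $m = 2$. These sizes are the package's chosen study conditions for a
  single-workstation run; all are configurable upward.
* **Separation handling.** Dropping separated indicators (instead of
  reporting $\pm\infty$) biases toward the null for that covariate but keeps
  every fit usable and every prediction finite; the dropped names are recorded
  on the fit object.

## Known limitations

* The multinomial imputation draw is not fully Bayesian (see above).
* The Efron-tie baseline makes the fitted single-cause reduction agree with
  the Kaplan–Meier complement only to ~$10^{-5}$ on heavily tied data; the
  tie-free reduction is exact.
* `secular_trend()` uses calendar year *at the index date* as a fixed
  covariate; follow-up that spans many years attenuates a true per-year trend
  slightly (the recovery test passes within Monte-Carlo error, but long
  follow-up plus steep trends would need a time-split analysis).
* No discrimination statistics (c-index) and no net-reclassification
  statistics are provided, deliberately: the evaluation here is about
  individual-level agreement and calibration.
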