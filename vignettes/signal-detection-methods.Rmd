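---
title: "Methods: disproportionality, time-to-onset and adjusted signal models for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality, time-to-onset and adjusted signal models for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srssignal)
```

## The problem

Spontaneous reporting system (SRS) databases such as JADER (Japan) or FAERS
(US) collect voluntary reports of suspected adverse drug events. Each report
carries banded demographics (DEMO), the drugs the patient received with
start dates (DRUG), and coded adverse reactions with onset dates and
outcomes (REAC). For a rare event — here the MedDRA preferred term
*Colitis microscopic*, PT code 10056979, is the running example and the
default target — three questions recur:

1. **Which drugs are disproportionately co-reported with the event?**
   (reporting odds ratio screen)
2. **How long after starting a drug does the event arise, and is the hazard
   rising or falling?** (Weibull time-to-onset profile)
3. **Which drug associations survive adjustment for demographic
   confounding?** (multiple logistic regression with forced-entry
   confounders and stepwise drug selection)

`srssignal` implements this workflow end-to-end and couples it to a
synthetic report generator with injected ground truth, so every stage can
be validated against effects that are known by construction.

## Cohort construction

JADER stores height in 10-cm and weight in 10-kg bands. The continuous
stand-in for band $[L, L+9]$ is the *intermediate value* $L + 5$ (so
`"160-169"` cm becomes 165 cm), and the estimated BMI is

$$\mathrm{eBMI} = \frac{\text{intermediate weight (kg)}}
{[\text{intermediate height (m)}]^2},$$

reported to one decimal (165 cm and 55 kg give 20.2 kg/m²). Note the
intermediate value is *not* the arithmetic midpoint ($L + 4.5$); the
lower-bound-plus-5 convention is the one used with these banded data.

Construction order, with every exclusion counted:

1. Reports missing (or carrying unparseable) sex, age band, height band or
   weight band are excluded.
2. eBMI is computed for the remainder, and outliers are removed by the
   boxplot rule: outside $Q_1 - 1.5\,\mathrm{IQR}$ to
   $Q_3 + 1.5\,\mathrm{IQR}$, with the quartiles computed **once on the
   pooled post-exclusion distribution**, not per subgroup. Freezing the
   bounds makes the exclusion idempotent.
3. The surviving cases form the analysis table. eBMI is classed as
   underweight ($< 18.5$), normal ($[18.5, 25.0)$) or obese ($\ge 25.0$);
   the intervals are half-open exactly as stated, so 18.5 is normal and
   25.0 is obese. Age is stratified at $\ge 60$ versus $< 60$ using the
   band's lower bound (the WHO "elderly" cut-off of 65 exists, but the
   60-year split is the implemented convention). The event flag is "any
   REAC row with the target PT code".

**Quantile rule.** Quartiles and medians use linear interpolation between
order statistics at positions $(n+1)p$ (`stats::quantile` type 6)
throughout; the type is configurable (`quantile_type`) because commercial
statistics packages differ in this choice, and third-decimal discrepancies
between tools are usually traceable to it.

## Time-to-onset

Time-to-onset is onset date minus drug start date in days, computed only
from fully dated (8-digit `YYYYMMDD`) records; 6-digit partial dates are
retained in the tables but never enter durations. Per (case, drug) pair the
*shortest* duration is kept. Negative durations are data errors — dropped
and counted. Same-day onsets (duration 0) map to 0.5 days so they stay in
the strictly positive Weibull domain; dropping them would bias the early
hazard downward.

For each drug with strictly more than `min_tto_cases` (default 10) onset
records, the durations $t_i$ are fitted by maximum likelihood to the
Weibull density

$$f(t) = \frac{\beta}{\alpha}\left(\frac{t}{\alpha}\right)^{\beta-1}
e^{-(t/\alpha)^\beta}, \qquad \alpha, \beta > 0,$$

with scale $\alpha$ in days and dimensionless shape $\beta$. The MLE
reduces exactly to a one-dimensional root-finding problem: $\hat\beta$
solves

$$\frac{1}{\beta} + \overline{\log t} -
\frac{\sum_i t_i^\beta \log t_i}{\sum_i t_i^\beta} = 0,$$

whose left side is strictly decreasing, so the root is unique when it
exists; $\hat\alpha = (\tfrac1n \sum_i t_i^{\hat\beta})^{1/\hat\beta}$
follows in closed form. The implementation uses a safeguarded Newton
iteration (bisection bracket, tolerance $10^{-10}$, at most 200 steps) and
evaluates the power sums on the log scale to avoid overflow with
multi-year durations. 95% Wald intervals for both parameters are formed on
the log scale from the observed information matrix and exponentiated,
guaranteeing positive bounds. Degenerate samples (all durations equal)
have no root and are reported as non-converged rather than fitted.

The shape CI classifies the hazard: upper bound below 1 → *early failure*
(decreasing hazard); interval containing 1 (boundaries included) → *random
failure*; lower bound above 1 → *wear-out failure* (increasing hazard).

All durations are treated as observed events; there is no censoring model,
matching how SRS onset data are reported.

## Disproportionality

For each drug of interest — a drug administered in at least
`min_drug_cases` (default 5) distinct event cases, binned for reporting
into the frequency strata $>100$, $20\text{–}100$, $10\text{–}19$,
$5\text{–}9$ — a two-by-two table partitions the analysis table:

|            | event | no event |
|------------|-------|----------|
| drug       | $a$   | $c$      |
| no drug    | $b$   | $d$      |

The reporting odds ratio is $\mathrm{ROR} = ad/bc$ with the Woolf
(log-normal) 95% CI
$\exp\{\ln \mathrm{ROR} \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d}\}$, and a
signal is positive when the lower bound exceeds 1. Woolf is the standard
ROR interval in pharmacovigilance and is the documented choice here. Zero
cells leave the estimate undefined by default (the $\ge 5$-case threshold
makes $a \ge 5$ for every screened drug, so this arises only in reuse on
other events); an optional Haldane–Anscombe $+0.5$ correction is available
by configuration. No multiplicity adjustment is applied — the screen is a
hypothesis-generating device, not a confirmatory test.

Drug exposure is defined from any DRUG row regardless of its role
(suspected / concomitant / interacting): restricting to suspected drugs is
a configuration choice, not the default, since the reported role is
inconsistently coded in SRS data.

## The adjusted signal model

Sex, age class and eBMI class are treated as confounders and **forced**
into a multiple logistic regression of the event flag; eBMI enters as two
indicators (obese, underweight) against the normal reference. Candidate
drug indicators are then selected by **forward and backward stepwise
selection at significance level 0.05**: repeatedly, the excluded candidate
with the smallest likelihood-ratio-test p-value enters if $p < 0.05$, then
the included non-forced term with the largest p-value leaves if
$p \ge 0.05$, until no change. Likelihood-ratio tests (not Wald) drive the
stepping because they are invariant to parameterization; software using
Wald-based stepping can differ near the threshold. Ties are broken by
lexicographic drug name so the selection is reproducible. Drugs used to
*treat* the target condition (default: albumin tannate, prednisolone,
loperamide) are excluded from candidacy — their association is
protopathic.

The fitter is iteratively reweighted least squares with step-halving (the
log-likelihood never decreases), convergence on a maximum coefficient
change below $10^{-8}$ within 100 iterations, and a divergence guard: any
coefficient passing 30 in absolute value aborts with an error naming the
separating covariate (|log-odds| of 30 is far beyond anything estimable
from report data and indicates complete separation). Adjusted reporting
odds ratios are $e^{\hat\beta}$ with Wald 95% intervals; multicollinearity
is checked by variance inflation factors computed on the plain linear
design matrix, $\mathrm{VIF}_j = 1/(1 - R_j^2)$, with VIF < 2 the
conventional comfort zone for this model family.

Subset models by sex refit, in female and male cases separately, a fixed
model (no stepwise): age class, the two eBMI indicators and the headline
drugs — by default the stepwise-selected drugs that also pass the
time-to-onset threshold.

## The synthetic data generator

`simulate_srs()` emits DEMO/DRUG/REAC/HIST tables plus the generating
truth. Design choices:

* **Latent-then-band**: continuous height and weight are drawn per sex and
  then banded, so a well-defined latent BMI exists; the event model uses
  the eBMI class *computed from the bands* with the same functions the
  pipeline uses, so generator and pipeline share one covariate definition
  and the injected coefficients are recoverable without banding bias. The
  latent BMI class agrees with the banded eBMI class in over 80% of cases;
  the remainder is banding error, which is exactly what eBMI carries in
  real data.
* **Event model**: logit of the event probability is the configured
  baseline plus log-odds terms for female sex, age ≥ 60, obese,
  underweight, plus the log odds ratio of every exposed effect drug.
  Drug exposures are independent Bernoulli draws per catalog entry;
  co-prescription correlation is deliberately out of scope (no joint
  structure is available to calibrate it).
* **Onset**: when the event fires, one exposed effect drug is chosen
  uniformly as the carrier, and the onset date is its start date plus a
  Weibull draw rounded **up** to whole days (reports carry dates, not
  times, and a ceiling keeps durations positive). Events with no exposed
  effect drug get a configured background latency.
* **Missingness**: each demographic field is blanked independently at its
  configured rate; start and onset dates are degraded at their configured
  rates, half to 6-digit partial dates and half to blanks, so the
  time-to-onset table is a proper subset of the event cases as in real
  extracts.

Default study conditions: 20,000 reports; 46% female; 66% of reports aged
≥ 60; sex-specific heights/weights giving mean eBMI ≈ 22 kg/m²; heavy
height/weight missingness (40% each, with 1%/5% for sex/age) so roughly a
third of reports survive the completeness exclusion; a 22-drug catalog
with exposure prevalences between 1.6% and 10.5%; injected effects
lansoprazole OR 35 and aspirin OR 2 among 20 null drugs; covariate effects
female OR 3.26, age ≥ 60 OR 3.94, obese OR 1.21, underweight OR 1.17;
onset models Weibull(α = 107, β = 0.93) for lansoprazole and
Weibull(α = 221, β = 0.57) for aspirin; outcome profile dominated by
Recovered/Improved. The baseline event log-odds is `qlogis(0.01)`: a
per-report event prevalence high enough that a 20,000-report run yields a
few hundred analysable cases — scaled up from the per-report rarity of a
real SRS event so that all effects are recoverable at desk scale, while
keeping the event rare in the logistic sense.

**What the generator does not emulate.** Duplicate and follow-up reports,
reporter notoriety and competition biases, dose information, correlated
co-prescription, multi-event reports beyond one target PT plus background
noise PTs, and calendar trends. Passing the pipeline's recovery tests
therefore demonstrates statistical correctness of the machinery on a
well-specified generative model — not robustness to the reporting biases
of a real SRS, which no simulation of this kind can certify.

**A deliberate realism in the onset model**: the time-to-onset table
computes durations for *every* exposed drug of an event case, but only the
carrier drug's duration is the true latency. A case exposed to both
lansoprazole and aspirin contributes a genuine latency for one and an
incidental duration for the other, so fitted shape parameters are
attenuated toward the contaminating distribution relative to the injected
values. This mirrors the real analytical situation (the database cannot
say which drug caused the event) and is why the Weibull recovery tests
assert calibration on clean draws and qualitative recovery on pipeline
output.

## Numerical and reporting conventions

* Quantiles: type 6, configurable (see above).
* Weibull: profile-Newton tolerance $10^{-10}$; score equations satisfied
  to $10^{-8}$ at the reported MLE; log-scale Wald CIs.
* Logistic: IRLS coefficient tolerance $10^{-8}$, max 100 iterations,
  separation bound 30, step-halving for monotone likelihood.
* Report TSVs are byte-stable: fixed column order and fixed rounding —
  RORs/aRORs and CI bounds to 2 decimals, eBMI and day quantities to 1
  decimal, shape parameters to 2, p-values to 3.
* One seed governs a pipeline run end to end; identical config and seed
  give byte-identical outputs.

## Worked example

```{r example, eval = FALSE}
run <- run_pipeline(run_config(simulation = sim_config(), seed = 1))
print(run)
head(run$screen)
run$profile$table
run$model
```

On the default conditions above the run recovers the injected structure:
the OR-35 drug tops the crude screen and is signal-positive, stepwise
selection retains both effect drugs (null drugs enter at roughly the
nominal 5% rate), the adjusted ROR intervals cover the injected odds
ratios, and the onset profile classifies the β < 1 drug's hazard as
early/random failure. The problem sizes used by the validation suite —
20,000-report runs, 50 seeded recovery replicates, 200 null replicates for
selection and screen calibration, 500 replicates of n = 100 for Weibull CI
coverage — were chosen as the smallest at which the statistical assertions
are stable.

## Limitations

* PT codes are opaque strings; no MedDRA hierarchy resolution, so class
  effects across related terms are invisible.
* No deduplication of suspected duplicate reports and no imputation of
  missing demographics; both are upstream curation steps, not performed
  here.
* The stepwise procedure inherits the usual caveat: it is a screening
  device, and selected null drugs at the nominal rate are expected, not a
  defect.
* Crude and adjusted RORs from SRS data measure reporting
  disproportionality, not incidence or causal risk; the pipeline's output
  is hypothesis-generating.
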