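---
title: "Profiling facility performance on HIV quality-of-care indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling facility performance on HIV quality-of-care indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`qocprofile` detects health facilities whose compliance with HIV care
guidelines is unusually poor or unusually good, from patient-level EMR
extracts. This vignette is the package's account of its statistical
model: what is assumed, which knobs matter, what the synthetic data
generator does and does not emulate, and where genuinely open design
choices were resolved.

## 1. The model

### Indicators and failure scale

Six indicators are computed per facility, each a proportion of
*failures* so that every scale points the same way (higher = worse):
three process-of-care indicators (ART not started within 30 days of
diagnosis; not up to date with viral-load testing; multi-month scripting
given to a non-stable patient) and three continuity-of-care indicators
(late ART pick-up per prescription; not retained at 6 months, separately
for non-pregnant adults and for women pregnant or post-partum at ART
initiation). Units differ: indicators 1, 2, 5, 6 count patients,
indicator 4 counts prescriptions, indicator 3 counts multi-month
prescriptions. A unit enters a denominator only if its outcome window
closes inside the observation window — censored outcomes are excluded,
never counted as failures.

### Nulls and tests

Process indicators are modelled as binomial draws around the national
pooled failure proportion $\pi_0$ (pooled, not the mean of facility
proportions: under the funnel-plot null every unit shares a common
failure probability, and pooling is the MLE of that probability).
Facilities are tested with exact binomial tails (both tails include the
observed point; two-sided $p = \min(1, 2\min(\text{tails}))$).

Continuity indicators are confounded by case-mix, so each facility's
observed proportion $p_i$ is compared with the proportion expected from
its own patients under a national logistic regression (indirect
standardization). The contrast is taken on the logit scale,

$$y_i = \mathrm{logit}(p_i) - \mathrm{logit}(\hat E_i), \qquad
  s_i = \frac{1}{\sqrt{n_i \hat E_i (1 - \hat E_i)}},$$

and $y_i/s_i$ is treated as standard normal under the null. $s_i$
treats $\hat E_i$ as known — the standard provider-profiling
approximation; coefficient uncertainty of the national model is
second-order at these denominators. Everything is computed on the
failure scale ($y_i > 0$ = worse than expected), which differs from a
"proportion of success" formulation only by sign.

With $I$ facilities tested per indicator, flags use the
Bonferroni-corrected threshold $\alpha/I$ (strict inequality), which
controls the familywise probability of any false flag at $\alpha$.

### Over-dispersion

True facility effects beyond sampling noise are the rule, not the
exception. The primary treatment is multiplicative: standard errors are
inflated by $\sqrt{\varphi}$, where $\varphi$ is estimated from the
facility z-scores with 10% two-sided winsorization. Two numerical
choices deserve note:

* **Debiasing.** The winsorized mean square of a standard normal sample
  has expectation $c(w) = (1-2w) - 2q\phi(q) + 2wq^2$ with
  $q = \Phi^{-1}(1-w)$ ($c(0.1) \approx 0.679$), so the raw winsorized
  mean square would *under*-state dispersion by a third under the null.
  We divide by $c(w)$, making $\hat\varphi$ unbiased at $\varphi = 1$
  and identical to the plain mean square at $w = 0$.
* **Floor and decision rule.** $\varphi$ is floored at 1 (standard
  errors are never deflated), and inflation is actually applied only
  when the unfloored estimate exceeds $1 + 2\sqrt{2/I}$ — roughly two
  null standard errors — so small-sample noise does not trigger
  spurious widening.

An exact binomial tail has no $\sqrt{\varphi}$ analogue, so whenever
inflation is in effect the process indicators are tested on the
normal-approximation z scale; exact tails remain the method of record
when over-dispersion handling is off. This also makes funnel
classification and hypothesis tests agree exactly (section 3).

The sensitivity analysis replaces inflation with an additive
random-effects model: each facility's true level is
$N(\text{national mean}, \tau^2)$, with $\tau^2$ the DerSimonian–Laird
method-of-moments estimate floored at 0, and
$z_i = y_i / \sqrt{s_i^2 + \tau^2}$. Its known behaviour — flagging more
small facilities and fewer large ones than the multiplicative model —
is asserted in the test suite.

### Funnel plots

Each indicator is plotted against its precision (denominator for
proportions, $1/s_i$ for contrasts) with control limits
$\pi_0 \pm z^* \sqrt{\varphi}\sqrt{\pi_0(1-\pi_0)/n}$ (or
$\pm z^*\sqrt{\varphi}/\rho$), truncated to $[0,1]$ on the proportion
scale. Two levels are drawn per variant: conventional 95% and the
Bonferroni-corrected $1-\alpha/I$. Under the additive variant the limits
are $\pm z^*\sqrt{1/\rho^2 + \tau^2}$ and asymptote to $\pm z^*\tau$
rather than closing onto the target — visually, why that model treats
large facilities leniently.

### Composite

Per-indicator z-scores are capped at $\pm 3$ so no single dimension can
dominate, then combined as

$$Z_i^{raw} = \frac{\sum_k w_k z^*_{ik}}{\sqrt{w^\top R\, w}},$$

with relevance weights $w = (1.5, 1.5, 1.5, 0.5, 0.5, 1)$ and $R$ the
empirical correlation matrix of the capped z-scores
(pairwise-complete; repaired by eigenvalue clipping if estimation left
it non-PSD). The normalizer is the standard deviation of the weighted
sum when each component is standard normal with correlation $R$ — the
minimal construction that both uses the inter-indicator correlation and
yields a z-like scale. A final empirical standardization enforces
mean 0 / sd 1 exactly across included facilities, which also makes the
$|Z| > 2$ classification robust to the choice of normalizer. Facilities
with more than two missing indicators are excluded (mirroring the
practical rule that a composite on half the information is not
comparable); for the rest, the sums and the normalizer are restricted
to the available indicators.

The exact correlation-adjustment formula and the cap→weight→standardize
order are design decisions here: the published description names the
ingredients (capping at ±3, relevance weights, "adjust for correlation",
mean 0 / sd 1) without the algebra, and this construction is the
simplest one delivering all the stated properties.

## 2. The synthetic world

The generator emulates a national HIV EMR at its documented scale
(default: 90 facilities, uniform volumes 100–1400, ≈65–70k patients,
observation window 2016-06-01 to 2018-03-31) with covariate
distributions matched to the published national summary: age
36.7 (13.3) truncated at 15 (the pre-truncation location is solved so
the *realized* mean hits the target), 63.5% female, BMI 22.1 (4.1), WHO
stage frequencies (28/22/23/28%), marital-status frequencies,
pregnancy in 45.9% of women (29.1% overall), year-of-initiation
profile, and facility-level travel time as a log-normal with mean 67.6
and sd 67.3 minutes. "Slope" is simulated as an opaque positive
facility covariate (gamma with mean 3.2, sd 2.2): its real-world
meaning is not documented, and nothing downstream depends on it beyond
being a case-mix column.

Facility effects are additive on the logit scale (logit-normal mixing,
not beta-binomial) so planted shifts compose linearly with case-mix
effects. The default effect sds $(0.5, 0.5, 0.5, 0.15, 0, 0)$ encode
the empirically observed pattern for this class of data: strong
heterogeneity in guideline uptake, mild residual heterogeneity in
refill timeliness, none in case-mix-adjusted retention. Continuity
outcomes add a centered covariate linear predictor (defaults: younger,
male, low-BMI, WHO-stage-4, long-travel patients do worse), and
indicator 4 adds a patient-level random effect (sd 0.5) so refill
lateness is a correlated repeated measure — the documented source of
indicator 4's over-dispersion.

Dispense histories are a renewal process: each pickup schedules the next
expected refill at pickup + days supplied (30, or 90 for the 40% of
patients on multi-month scripting); per-event lateness is Bernoulli in
the patient's logit rate, with on-time delays uniform on 0–30 days and
late delays on 31–60.

**Retention enforcement.** The 6-month outcome is evaluated at the
expected refill *nearest* day 182. That anchor is selected from the
realized schedule, so with i.i.d. per-event lateness the selection is
informative (a late gap shifts the later candidates) and would bias the
evaluated failure rate upward by ~3 percentage points. The generator
therefore draws each eligible patient's retention outcome once from the
logistic model and enforces it mechanically: failures stop picking up at
a uniform day 30–120 (certain failure at the dangling refill), successes
have every refill in the plausible anchor band (182 ± (45 + grace) days)
picked up on time (certain success). The realized failure probability
then equals the model value exactly — the property the planted-outlier
and recovery tests rely on. The cost is that indicator 4's marginal
event-level rate absorbs this enforcement; the ground-truth table
accounts for it event by event, and the null-world binomial test for
indicator 4 is framed as a homogeneity (no-over-dispersion) check
rather than a check against the nominal baseline rate.

Eligibility for the retention indicators requires ART start at least
182 + 2·grace + 45 days before the window end — wide enough that the
whole anchor band is ascertainable for everyone, keeping censoring
independent of the outcome.

**What the generator does not emulate:** transfer-in/out and death
(a non-returning patient is a retention failure regardless of cause, as
in the operational definitions), data-entry error, informative
missingness (only missing-at-random BMI), seasonal or secular trends,
and geography (travel time is sampled, not computed). A green test
establishes that the statistical machinery recovers what this stated
world plants — not that real EMR extracts are this clean.

## 3. Numerical choices and degenerate inputs

* Boundary proportions (0 or $n$ failures) get the continuity
  correction $(x + 0.5)/(n + 1)$ *only at the boundary*, keeping $y_i$
  finite without biasing interior facilities.
* Zero-denominator facilities carry an undefined proportion, are
  excluded from $\pi_0$ and from contrasts (with a logged notice), and
  appear as missing entries in the composite.
* Ties: a p-value exactly at $\alpha/I$ is not flagged; a composite
  exactly at ±2 is "typical"; the retention anchor tie (two refills
  equidistant from day 182) resolves to the earlier refill.
* The funnel/flag equivalence is exact by construction: "outside the
  Bonferroni over-dispersed limits" and "inflated two-sided
  $p < \alpha/I$" are the same inequality.
* Complete separation in a case-mix model falls back to ridge
  regression (small penalty, with a warning); a constant covariate in a
  cohort (gender among pregnant women) is dropped from the formula
  automatically.
* At desk scale (a few dozen facilities) the facility-level categorical
  covariates are near-saturated: a department containing a single
  facility is an exact facility dummy, and the logistic score equations
  then absorb that facility's true effect into its expected value
  (observed = expected to machine precision). The 90-facility /
  9-department design dilutes this to partial absorption. Small-world
  planted-outlier scenarios therefore adjust on patient-level
  covariates plus the continuous facility context, via the
  `casemix_formula` configuration; the default formula keeps the full
  covariate set.

## 4. Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | familywise level per indicator |
| `winsor` | 0.10 | winsorizing fraction for $\hat\varphi$ |
| `overdispersion` | multiplicative | or additive / none |
| `cap` | 3 | z-score cap (dimensionless) |
| `weights` | 1.5, 1.5, 1.5, 0.5, 0.5, 1 | relevance weights |
| `threshold` | 2 | composite classification cut (1.25 = permissive) |
| `min_indicators` | 4 | minimum available indicators for a composite |
| `grace_days` | 30 | refill grace window, inclusive (days) |
| `ttt_window_days` | 30 | "1 month" for test-and-start (days) |
| `vl_eligibility_lag_days` | 180 | days on ART before VL is expected |
| `vl_recency_window_days` | 365 | maximum age of an up-to-date VL test |

The viral-load window parameters are explicit configuration because the
published indicator defers to national guidelines without printing the
rule; the defaults follow common national-guideline practice (eligible
after 6 months on ART, test within the last year). MMS stability is
consumed as a precomputed flag on the dispense event for the same
reason: the underlying clinical definition lives outside the data.

## 5. Known limitations

* The case-mix model is only as good as the covariates; unmeasured
  confounding (e.g. socio-economic status) leaks into facility
  contrasts. High residual over-dispersion on an adjusted indicator is
  the diagnostic symptom.
* $\hat\varphi$ with 10% winsorization is not robust to more than ~10%
  of facilities being genuine outliers per side; with 4 planted
  outliers among 20 facilities the inflation is already visibly driven
  by the outliers themselves.
* The normal approximation behind the funnel limits is poor at very
  small denominators (n below ~20 with extreme $\pi_0$); exact-tail
  p-values are retained for flagging when over-dispersion handling is
  off, and the discrepancy otherwise only affects the plotted limits.
* The composite's correlation matrix is estimated from at most I rows;
  with few facilities it is noisy, and the final standardization (not
  the normalizer) is what guarantees the z-like scale.
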