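# qocprofile

Facility performance profiling for HIV quality-of-care indicators from
EMR data.

## The problem

National HIV programs in low-resource settings need to know *which
facilities* are failing to implement care guidelines so that scarce
inspection and support resources go where they matter. Routine EMR data
make this possible, but naive scorecards mislead: small facilities
fluctuate wildly, patient case-mix confounds retention comparisons, and
testing 90 facilities at once guarantees false alarms. `qocprofile`
implements the standard provider-profiling answer to each of these
problems, end to end, for six HIV care indicators:

| # | Indicator | Unit | Type |
|---|-----------|------|------|
| 1 | ART started within 1 month of HIV diagnosis ("test and start") | patient | process |
| 2 | Up to date with viral-load testing | patient | process |
| 3 | Multi-month scripting (MMS) only for stable patients | prescription | process |
| 4 | ART picked up within 30 days of the expected refill date | prescription | continuity |
| 5 | Retained on ART 6 months after initiation (non-pregnant adults) | patient | continuity |
| 6 | Retained on ART 6 months after initiation (pregnant/post-partum women) | patient | continuity |

Every indicator is expressed as a *failure* proportion (higher = worse).

## The statistics

- **Targets.** Process indicators are compared with the national pooled
  failure proportion pi0; continuity indicators are case-mix adjusted by
  indirect standardization: a national logistic regression on patient
  covariates gives each facility an expected proportion E_i, and the
  facility contrast is the logit difference
  `y_i = logit(p_i) - logit(E_i)` with standard error
  `s_i = 1 / sqrt(n_i E_i (1 - E_i))`.
- **Tests.** Exact binomial tails for indicators 1-3, standard-normal
  tests of `y_i / s_i` for 4-6, flagged at the Bonferroni-corrected
  threshold alpha / I (I = number of facilities).
- **Over-dispersion.** Standard errors are inflated by sqrt(phi), with
  phi a winsorized z-score estimator (debiased, floored at 1); an
  additive random-effects variant (method-of-moments tau^2) is available
  as a sensitivity analysis.
- **Funnel plots.** Proportions (or contrasts) against precision, with
  plain and over-dispersion-adjusted control limits at the 95% and
  Bonferroni-corrected levels.
- **Composite.** Per-indicator z-scores capped at +/-3, combined as a
  relevance-weighted mean (weights 1.5, 1.5, 1.5, 0.5, 0.5, 1),
  normalized by the standard deviation of the weighted sum under the
  empirical inter-indicator correlation, then standardized so the
  composite has mean 0 / sd 1 across facilities. |Z| > 2 marks outlying
  performance.

Because the real national EMR is governed and not public, the package
ships a **synthetic EMR generator** (`sim_config()`, `simulate_emr()`)
with known ground truth: logit-normal facility effects, case-mix
confounding through the covariate mix, planted outlier facilities, and a
renewal-process dispense history that reproduces the repeated-measures
structure of refill adherence.

## Worked example

```r
library(qocprofile)
cfg <- pipeline_config(sim = sim_config(seed = 20160601), seed = 20160601)
bundle <- run_pipeline(cfg)
print(bundle$composite)
```

```
<qoc_composite> 90 facilities (90 included)
  composite: mean -2.18e-17, sd 1.000000
  classes: low_performer=3 typical=87
```

The composite is mean-0 / sd-1 by construction; in this seeded synthetic
world (true between-facility sd 0.5 on the logit scale for the process
indicators) three facilities fall beyond Z > 2, i.e. they fail markedly
more often than their peers. Per-indicator detail, funnel coordinates and
Bonferroni flags live in `bundle$profile` and `bundle$funnel`;
`render_report(bundle)` turns the run into a markdown report, and
`plot_funnel(bundle$funnel, 1)` draws the classic funnel for indicator 1.

A command-line interface with `simulate`, `indicators`, `run` and
`report` subcommands is installed at
`system.file("scripts", "qoc_pipeline.R", package = "qocprofile")`.

## Scope

The package profiles facilities from patient-level extracts with the
documented CSV schema; it does not connect to an EMR, derive travel
times from maps, or run the stakeholder elicitation that produced the
relevance weights (they are configuration).
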